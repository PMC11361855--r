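# Synthetic cyclic-peptide datasets with a known structure-to-label
# relationship, so every pipeline stage is testable without external data.

#' Load the built-in monomer alphabet
#'
#' A library of amino-acid building blocks (natural, N-methylated and
#' D-variants) used by the synthetic generator.  Each row describes one
#' monomer: backbone N-methylation flag, alpha-carbon stereochemistry and
#' side-chain SMILES.
#'
#' @return Data frame with columns `monomer_id`, `n_methyl`, `stereo`,
#'   `side_smiles`, plus derived `fragment` (chain-assembly piece) and
#'   `capped_smiles` (the free monomer after methyl/aldehyde capping).
#' @export
monomer_alphabet <- function() {
  path <- system.file("extdata", "monomer_alphabet.csv", package = "pepperm")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(side_smiles = "character"))
  df$side_smiles[is.na(df$side_smiles)] <- ""
  alpha <- function(stereo, side) {
    if (side == "") "C"
    else if (stereo == "D") sprintf("[C@H](%s)", side)
    else sprintf("[C@@H](%s)", side)
  }
  df$alpha <- mapply(alpha, df$stereo, df$side_smiles, USE.NAMES = FALSE)
  nme <- ifelse(df$n_methyl == 1, "(C)", "")
  df$fragment <- paste0("N", nme, df$alpha, "C(=O)")
  df$capped_smiles <- paste0("CN", nme, df$alpha, "C=O")
  df
}

#' Configuration for the synthetic generator
#'
#' The generator emulates head-to-tail macrocycles of 5-12 monomers drawn
#' from [monomer_alphabet()], with log10 permeability labels driven by
#' whole-molecule lipophilicity, polar surface area and hydrogen-bond
#' donor count plus Gaussian noise, clipped to `[-8, -4]`.
#'
#' @param n_peptides Number of peptides.
#' @param length_range Monomer-count range, default `c(5, 12)` (minimum 3).
#' @param alphabet Monomer library data frame (default the built-in one).
#' @param label_coefficients Weights `c1, c2, c3` of the z-scored drivers
#'   logP, TPSA and H-bond donors in the ground-truth label function.
#' @param noise_sd Label noise standard deviation in log10 units
#'   (default 0.3).
#' @param seed Integer seed.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_peptides = 100, length_range = c(5, 12),
                         alphabet = monomer_alphabet(),
                         label_coefficients = c(0.8, 0.5, 0.4),
                         noise_sd = 0.3, seed = 1) {
  if (length_range[1] < 3) input_error("minimum length is 3 monomers")
  if (noise_sd < 0) input_error("noise_sd must be >= 0")
  stopifnot(length(label_coefficients) == 3)
  structure(
    list(n_peptides = as.integer(n_peptides),
         length_range = as.integer(length_range), alphabet = alphabet,
         label_coefficients = as.numeric(label_coefficients),
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_config"
  )
}

# assemble a head-to-tail macrocyclic SMILES from alphabet row indices;
# ring-closure digit 1 is reserved for the backbone, side chains use 2+
assemble_cyclic_smiles <- function(alphabet, idx) {
  L <- length(idx)
  pieces <- character(L)
  for (i in seq_len(L)) {
    row <- alphabet[idx[i], ]
    nme <- if (row$n_methyl == 1) "(C)" else ""
    open <- if (i == 1) "1" else ""
    tail <- if (i == L) "C1=O" else "C(=O)"
    pieces[i] <- paste0("N", open, nme, row$alpha, tail)
  }
  paste(pieces, collapse = "")
}

#' Sample one synthetic cyclic peptide
#'
#' Length and monomers are drawn uniformly; the record is assembled as a
#' head-to-tail amide macrocycle and carries its generating monomer
#' annotation (capped SMILES in cyclic order), so division can be checked
#' against ground truth.  Deterministic given `(config$seed, index)`.
#'
#' @param config A [synth_config()].
#' @param index 1-based peptide index.
#' @return A `peptide_record` (without label; see [synth_label()]).
#' @export
sample_peptide <- function(config, index) {
  stopifnot(inherits(config, "synth_config"))
  d <- sample_peptide_raw(config, index)
  parse_peptide(d$id, d$smiles, monomer_smiles = d$monomers)
}

# the RNG-only part, shared with make_dataset so cohorts can be built with
# one batched backend call
sample_peptide_raw <- function(config, index) {
  rng <- local_rng(stable_hash(config$seed, "peptide", index) %% 2147483647)
  lr <- config$length_range
  L <- lr[1] + rng$sample_int(lr[2] - lr[1] + 1L, 1L) - 1L
  idx <- vapply(seq_len(L), function(i)
    rng$sample_int(nrow(config$alphabet), 1L), integer(1))
  list(
    id = sprintf("synth%04d", index),
    smiles = assemble_cyclic_smiles(config$alphabet, idx),
    monomers = config$alphabet$capped_smiles[idx],
    monomer_ids = config$alphabet$monomer_id[idx]
  )
}

#' Ground-truth label function of the synthetic generator
#'
#' `label = clip(-6.5 + c1 z(logP) - c2 z(TPSA) - c3 z(HBD) + eps, -8, -4)`
#' with `eps ~ N(0, noise_sd^2)`; z-scores are taken over the generated
#' cohort, so the function needs the cohort statistics.
#'
#' @param props Data frame row(s) with columns `MolLogP`, `TPSA`,
#'   `NumHDonors`.
#' @param stats List with `means` and `stds` of the three drivers over the
#'   cohort.
#' @param config A [synth_config()].
#' @param eps Noise value(s); pass 0 for the noiseless label.
#' @return Numeric label(s) in `[-8, -4]`.
#' @export
synth_label <- function(props, stats, config, eps = 0) {
  z <- function(x, k) (x - stats$means[k]) / stats$stds[k]
  co <- config$label_coefficients
  pre <- -6.5 +
    co[1] * z(props$MolLogP, 1) -
    co[2] * z(props$TPSA, 2) -
    co[3] * z(props$NumHDonors, 3) +
    eps
  clip_labels(pre)
}

#' Generate a synthetic labelled dataset
#'
#' Draws `n_peptides` records, computes the label drivers in one batched
#' backend call, z-scores them over the cohort and applies the ground-truth
#' label function with seeded noise.  The returned manifest (config +
#' seed) regenerates the dataset exactly.
#'
#' @param config A [synth_config()].
#' @return Object of class `pepperm_synth`: `records` (labelled
#'   `peptide_record`s), `props` (driver table), `stats`, `manifest`.
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  raw <- lapply(seq_len(config$n_peptides), function(i)
    sample_peptide_raw(config, i))
  parse <- run_backend("parse", list(jobs = lapply(raw, function(d)
    list(id = d$id, smiles = d$smiles))))
  props <- run_backend("synthprops", list(jobs = lapply(raw, function(d)
    list(id = d$id, smiles = d$smiles))))
  ptab <- do.call(rbind, lapply(props$results, function(r) {
    if (!isTRUE(r$ok)) chem_error(r$error)
    data.frame(MolLogP = r$MolLogP, TPSA = r$TPSA,
               NumHDonors = r$NumHDonors, MolWt = r$MolWt)
  }))
  drivers <- as.matrix(ptab[, c("MolLogP", "TPSA", "NumHDonors")])
  mu <- colMeans(drivers)
  sd_pop <- sqrt(colMeans(sweep(drivers, 2, mu)^2))
  if (any(sd_pop == 0)) sd_pop[sd_pop == 0] <- 1
  stats <- list(means = unname(mu), stds = unname(sd_pop))
  rng <- local_rng(stable_hash(config$seed, "labels") %% 2147483647)
  eps <- if (config$noise_sd > 0) rng$norm(config$n_peptides) * config$noise_sd
         else numeric(config$n_peptides)
  labels <- synth_label(ptab, stats, config, eps)
  records <- lapply(seq_along(raw), function(i) {
    pr <- parse$results[[i]]
    if (!isTRUE(pr$ok)) chem_error(pr$error)
    monomers <- lapply(seq_along(raw[[i]]$monomers), function(k) {
      list(position = k - 1L, atom_indices = NULL,
           capped_smiles = raw[[i]]$monomers[[k]])
    })
    structure(
      list(id = raw[[i]]$id, smiles = raw[[i]]$smiles,
           canonical = pr$canonical, n_heavy = pr$n_heavy,
           monomers = monomers, label = labels[i], assay = "synthetic"),
      class = "peptide_record"
    )
  })
  manifest <- list(
    n_peptides = config$n_peptides, length_range = config$length_range,
    label_coefficients = config$label_coefficients,
    noise_sd = config$noise_sd, seed = config$seed
  )
  structure(
    list(records = records, props = ptab, stats = stats,
         manifest = manifest),
    class = "pepperm_synth"
  )
}

#' @export
print.pepperm_synth <- function(x, ...) {
  labs <- vapply(x$records, `[[`, numeric(1), "label")
  cat(sprintf("<pepperm_synth: %d peptides, labels %.2f .. %.2f (seed %d)>\n",
              length(x$records), min(labs), max(labs), x$manifest$seed))
  invisible(x)
}

#' Write a synthetic dataset to the standard CSV interface
#'
#' Produces the peptide table (`id,smiles,helm,label`) and the monomer
#' library (`monomer_id,smiles`) consumed by [read_peptides_csv()], plus a
#' JSON manifest for exact regeneration.
#'
#' @param dataset A `pepperm_synth` from [make_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pepperm_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- monomer_alphabet()
  helm <- vapply(dataset$records, function(rec) {
    caps <- vapply(rec$monomers, `[[`, "", "capped_smiles")
    ids <- alpha$monomer_id[match(caps, alpha$capped_smiles)]
    paste(ids, collapse = ".")
  }, "")
  df <- data.frame(
    id = vapply(dataset$records, `[[`, "", "id"),
    smiles = vapply(dataset$records, `[[`, "", "smiles"),
    helm = helm,
    label = vapply(dataset$records, `[[`, numeric(1), "label")
  )
  utils::write.csv(df, file.path(dir, "peptides.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(monomer_id = alpha$monomer_id, smiles = alpha$capped_smiles),
    file.path(dir, "monomer_library.csv"), row.names = FALSE)
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
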