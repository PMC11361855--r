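# Replica augmentation: SMILES enumeration, cyclic sequence arrangement,
# and assembly of multi-level replica feature bundles.

#' Enumerate random SMILES renderings of one molecule
#'
#' Atom orders are drawn by a seeded random permutation; every output
#' canonicalizes back to the parent's canonical form.
#'
#' @param smiles Molecule SMILES.
#' @param n Number of renderings (>= 1).
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
enumerate_smiles <- function(smiles, n, seed) {
  if (n < 1) input_error("n must be >= 1")
  res <- backend_jobs("enumerate",
                      list(list(smiles = smiles, n = n, seed = seed)),
                      error_class = "pepperm_input_error")
  as.character(res[[1]]$smiles)
}

#' Cyclic sequence arrangements of a monomer descriptor matrix
#'
#' Each arrangement places one cyclic rotation of the `L` rows at one
#' translated offset inside a zero-padded `max_len` frame, so the
#' arrangement grid has `L * (max_len - L + 1)` cells.  Arrangements are
#' sampled uniformly without replacement from the grid, and with
#' replacement once the grid is exhausted.
#'
#' @param matrix L x D numeric matrix (rows in cyclic order).
#' @param max_len Frame length (>= L).
#' @param n Number of arrangements.
#' @param seed Integer seed.
#' @return List of `n` elements, each with `matrix` (max_len x D), `offset`
#'   (0-based translation) and `rotation` (0-based start row).
#' @export
sequence_arrangements <- function(matrix, max_len, n, seed) {
  m <- as.matrix(matrix)
  L <- nrow(m)
  if (L > max_len) size_error(sprintf("L = %d exceeds max_len = %d", L, max_len))
  n_off <- max_len - L + 1L
  grid <- expand.grid(rotation = 0:(L - 1L), offset = 0:(n_off - 1L))
  rng <- local_rng(seed)
  picks <- integer(0)
  while (length(picks) < n) {
    take <- min(nrow(grid), n - length(picks))
    picks <- c(picks, rng$sample_int(nrow(grid), take))
  }
  lapply(picks[seq_len(n)], function(g) {
    rot <- grid$rotation[g]
    off <- grid$offset[g]
    rows <- ((seq_len(L) - 1L + rot) %% L) + 1L
    out <- base::matrix(0, max_len, ncol(m))
    out[off + seq_len(L), ] <- m[rows, , drop = FALSE]
    list(matrix = out, offset = off, rotation = rot, length = L)
  })
}

# seeded RNG scoped to a closure so library code never disturbs the
# caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sample_int = function(n, k) with_state(function() sample.int(n, k)),
    runif = function(k) with_state(function() stats::runif(k)),
    norm = function(k) with_state(function() stats::rnorm(k))
  )
}

#' Build augmented replica inputs for a set of peptide records
#'
#' Replica `k` (0-based) of a peptide combines: the `k`-th enumerated atom
#' ordering (node/bond/graph features), the `k`-th peptide conformer (Conf
#' matrix and 3D peptide descriptors), the `k`-th monomer conformers
#' (monomer descriptor rows) and the `k`-th cyclic sequence arrangement.
#' All replicas carry the parent's label.  Per-replica seeds are hashed
#' from `(seed, peptide id, k)` so generation is reproducible and
#' independent of dataset order; identical capped monomers share conformers
#' across peptides at the same replica index.
#'
#' @param records List of `peptide_record`s, each with a monomer
#'   annotation (see [divide_monomers()]).
#' @param r Replicas per peptide (default 60).
#' @param seed Integer run seed.
#' @param max_len Monomer frame length (default 16).
#' @param uff_iters,retries,method Conformer settings, see
#'   [generate_conformers()].
#' @return Object of class `pepperm_replicas`: a list with `records` (raw
#'   per-replica features), `desc_names`, and the call settings.
#' @export
build_replicas <- function(records, r = 60, seed = 1, max_len = 16,
                           uff_iters = 200, retries = 5, method = "etdg") {
  if (r < 1) input_error("r must be >= 1")
  if (inherits(records, "peptide_record")) records <- list(records)
  jobs <- lapply(records, function(rec) {
    stopifnot(inherits(rec, "peptide_record"))
    if (is.null(rec$monomers)) {
      input_error(sprintf("record '%s' has no monomer annotation; run divide_monomers()",
                          rec$id))
    }
    list(id = rec$id, smiles = rec$smiles,
         monomers = vapply(rec$monomers, `[[`, "", "capped_smiles"))
  })
  out <- run_backend("featurize", list(
    records = jobs, replicas = r, seed = seed,
    uff_iters = uff_iters, retries = retries, method = method
  ))
  recs <- lapply(seq_along(out$records), function(i) {
    fr <- out$records[[i]]
    rec <- records[[i]]
    L <- length(rec$monomers)
    arr <- sequence_arrangements(diag(L), max_len, r,
                                 seed = stable_hash(seed, rec$id, "arr") %% 2147483647)
    reps <- lapply(seq_len(r), function(k) {
      rep_k <- fr$replicas[[k]]
      mono <- rep_k$monomer_desc
      if (!is.matrix(mono)) mono <- do.call(rbind, mono)
      list(
        replica_index = k - 1L,
        smiles = rep_k$smiles,
        atoms = rep_k$atoms,
        bonds = rep_k$bonds,
        coords = as_coord_matrix(rep_k$coords),
        desc16 = stats::setNames(as.numeric(rep_k$desc16),
                                 as.character(out$desc_names)),
        monomer_desc = mono,
        arrangement = arr[[k]][c("offset", "rotation", "length")],
        label = rec$label
      )
    })
    fp <- integer(2048)
    fp[as.integer(fr$fp_bits) + 1L] <- 1L
    list(id = rec$id, label = rec$label, fingerprint = fp,
         n_monomers = L, replicas = reps)
  })
  structure(
    list(records = recs, desc_names = as.character(out$desc_names),
         r = r, seed = seed, max_len = max_len),
    class = "pepperm_replicas"
  )
}

#' Write replica feature tables to CSV
#'
#' Flat-text export of a replica bundle: one peptide-level table (one row
#' per peptide and replica: id, replica, the 16 descriptors, and the
#' fingerprint as a 2048-character bitstring) and one monomer-level table
#' (one row per peptide, replica and monomer position).
#'
#' @param features A `pepperm_replicas` bundle.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the two CSV files.
#' @export
write_feature_csv <- function(features, dir) {
  stopifnot(inherits(features, "pepperm_replicas"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pep_rows <- list()
  mono_rows <- list()
  for (rec in features$records) {
    fp_str <- paste(rec$fingerprint, collapse = "")
    for (rp in rec$replicas) {
      d <- as.list(rp$desc16)
      pep_rows[[length(pep_rows) + 1]] <- data.frame(
        id = rec$id, replica = rp$replica_index, d, fingerprint = fp_str,
        check.names = FALSE)
      md <- as.data.frame(rp$monomer_desc)
      names(md) <- features$desc_names
      mono_rows[[length(mono_rows) + 1]] <- cbind(
        data.frame(id = rec$id, replica = rp$replica_index,
                   position = seq_len(nrow(md)) - 1L),
        md)
    }
  }
  pep_path <- file.path(dir, "peptide_features.csv")
  mono_path <- file.path(dir, "monomer_features.csv")
  utils::write.csv(do.call(rbind, pep_rows), pep_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, mono_rows), mono_path, row.names = FALSE)
  invisible(c(peptide = pep_path, monomer = mono_path))
}

#' Subset a replica bundle by replica index
#'
#' Keeps only the replicas whose 0-based index is in `indices`, e.g. to
#' compare an unaugmented (first-replica-only) pipeline against the full
#' ensemble without re-running featurization.
#'
#' @param features A `pepperm_replicas` bundle.
#' @param indices Integer vector of 0-based replica indices to keep.
#' @return A `pepperm_replicas` with the reduced replica count.
#' @export
subset_replicas <- function(features, indices) {
  stopifnot(inherits(features, "pepperm_replicas"))
  features$records <- lapply(features$records, function(rec) {
    keep <- vapply(rec$replicas, function(rp)
      rp$replica_index %in% indices, logical(1))
    rec$replicas <- rec$replicas[keep]
    rec
  })
  features$r <- length(features$records[[1]]$replicas)
  features
}

#' @export
print.pepperm_replicas <- function(x, ...) {
  cat(sprintf("<pepperm_replicas: %d peptides x %d replicas (seed %d)>\n",
              length(x$records), x$r, x$seed))
  invisible(x)
}
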