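# Molecule handling: peptide records, macrocycle division, conformers.

#' Parse and validate a cyclic peptide record
#'
#' Builds a `peptide_record`: the canonical SMILES, heavy-atom count and,
#' optionally, an ordered monomer annotation and an experimental label
#' (log10 permeability in cm/s).
#'
#' @param id Identifier string.
#' @param smiles SMILES of the (single, connected) molecule.
#' @param monomer_smiles Optional character vector of capped monomer SMILES
#'   in cyclic order; attached as the record's monomer annotation.
#' @param label Optional numeric log10 permeability (cm/s).
#' @param assay Optional assay tag (e.g. `"PAMPA"`).
#' @param max_heavy Maximum allowed heavy-atom count (default 128, the
#'   padding size of the atom model).
#' @return An object of class `peptide_record`.
#' @export
parse_peptide <- function(id, smiles, monomer_smiles = NULL, label = NULL,
                          assay = NULL, max_heavy = 128) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(trimws(smiles))) {
    input_error("smiles must be a non-empty string")
  }
  res <- run_backend("parse", list(jobs = list(list(id = id, smiles = smiles))))
  r <- res$results[[1]]
  if (!isTRUE(r$ok)) input_error(sprintf("peptide '%s': %s", id, r$error))
  if (r$n_frags != 1) input_error(sprintf("peptide '%s': disconnected molecule", id))
  if (r$n_heavy > max_heavy) {
    size_error(sprintf("peptide '%s': %d heavy atoms exceeds maximum %d",
                       id, r$n_heavy, max_heavy))
  }
  if (!is.null(label)) {
    label <- as.numeric(label)
    if (!is.finite(label)) input_error("label must be finite")
  }
  monomers <- NULL
  if (!is.null(monomer_smiles)) {
    monomers <- lapply(seq_along(monomer_smiles), function(i) {
      list(position = i - 1L, atom_indices = NULL,
           capped_smiles = monomer_smiles[[i]])
    })
  }
  structure(
    list(id = as.character(id), smiles = smiles, canonical = r$canonical,
         n_heavy = r$n_heavy, monomers = monomers, label = label,
         assay = assay),
    class = "peptide_record"
  )
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf("<peptide_record %s: %d heavy atoms%s%s>\n", x$id, x$n_heavy,
              if (!is.null(x$monomers))
                sprintf(", %d monomers", length(x$monomers)) else "",
              if (!is.null(x$label)) sprintf(", label %.3g", x$label) else ""))
  invisible(x)
}

#' Divide a macrocyclic peptide into capped monomers
#'
#' Cleaves only backbone amide `C(=O)-N` and ester `C(=O)-O` single bonds
#' lying inside the largest ring of size >= `min_ring`; bonds outside the
#' macrocycle are never divided.  Each cut is capped: the amine nitrogen or
#' ester oxygen gains a methyl group and the acyl carbon becomes an
#' aldehyde.  Units are returned in cyclic order (N-to-C traversal starting
#' from the unit holding the atom of lowest canonical rank).
#'
#' If `record` carries a monomer annotation it is passed through unchanged.
#'
#' @param record A `peptide_record`.
#' @param min_ring Minimum ring size treated as the macrocycle (default 9).
#' @return List of monomer units (`position`, `atom_indices` 1-based,
#'   `capped_smiles`).
#' @export
divide_monomers <- function(record, min_ring = 9) {
  stopifnot(inherits(record, "peptide_record"))
  if (!is.null(record$monomers)) return(record$monomers)
  res <- run_backend("divide", list(
    jobs = list(list(id = record$id, smiles = record$smiles)),
    min_ring = min_ring
  ))
  r <- res$results[[1]]
  if (!isTRUE(r$ok)) {
    pepperm_error("pepperm_division_error",
                  sprintf("peptide '%s': %s", record$id, r$error))
  }
  lapply(r$units, function(u) {
    list(position = as.integer(u$position),
         atom_indices = as.integer(u$atom_indices) + 1L,
         capped_smiles = u$capped_smiles)
  })
}

#' Cap a cleaved monomer fragment
#'
#' The fragment SMILES marks each cleaved bond end with a dummy atom
#' (`[*]` or its isotope-labelled forms, as produced by bond
#' fragmentation).  Dummies attached to an amine nitrogen or ester oxygen
#' are replaced by a methyl carbon; dummies attached to an acyl carbon are
#' removed, leaving an aldehyde.  A fragment without markers is returned
#' canonicalized but otherwise unchanged.
#'
#' @param fragment_smiles SMILES with `[*]` end markers.
#' @return Canonical SMILES of the capped fragment.
#' @export
cap_fragment <- function(fragment_smiles) {
  res <- backend_jobs("cap", list(list(smiles = fragment_smiles)))
  res[[1]]$capped_smiles
}

#' Generate seeded 3D conformers
#'
#' Distance-geometry embedding (experimental-torsion variants as
#' implemented in RDKit) followed by UFF energy minimization.  Conformer
#' `k` (0-based) uses seed `base_seed + k`; embedding is retried up to
#' `retries` times per conformer with a random-coordinate fallback.
#' Coordinates are heavy atoms only, in the parent atom order, in Angstrom.
#'
#' @param smiles Molecule SMILES.
#' @param n Number of conformers (>= 1).
#' @param base_seed Integer base seed.
#' @param uff_iters Maximum UFF minimization iterations (default 200).
#' @param retries Embedding attempts per conformer (default 5).
#' @param method One of `"etdg"`, `"etkdg"`, `"etkdgv2"`, `"etkdgv3"`.  The
#'   default `"etdg"` keeps macrocycle embedding times bounded; see the
#'   package vignette for the trade-off.
#' @param id Identifier used in error messages and SDF output.
#' @return An object of class `conformer_set` with fields `parent_id`,
#'   `coordinates` (list of N x 3 matrices) and `seeds`.
#' @export
generate_conformers <- function(smiles, n, base_seed, uff_iters = 200,
                                retries = 5, method = "etdg", id = "mol") {
  if (n < 1) input_error("n must be >= 1")
  res <- run_backend("conformers", list(
    jobs = list(list(id = id, smiles = smiles, n = n, base_seed = base_seed)),
    uff_iters = uff_iters, retries = retries, method = method
  ))
  r <- res$results[[1]]
  if (!isTRUE(r$ok)) {
    pepperm_error("pepperm_conformer_error",
                  sprintf("molecule '%s': %s", id, r$error))
  }
  coords <- r$coords
  if (is.array(coords) && length(dim(coords)) == 3) {
    coords <- lapply(seq_len(dim(coords)[1]), function(k) {
      m <- coords[k, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      m
    })
  } else {
    coords <- lapply(coords, as_coord_matrix)
  }
  structure(
    list(parent_id = id, smiles = smiles, coordinates = coords,
         seeds = as.integer(r$seeds)),
    class = "conformer_set"
  )
}

#' Write a conformer set to an SDF file
#'
#' One record per conformer; the parent id and embedding seed are stored as
#' SDF properties.
#'
#' @param conformers A `conformer_set` from [generate_conformers()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conformers_sdf <- function(conformers, path) {
  stopifnot(inherits(conformers, "conformer_set"))
  run_backend("sdf", list(
    id = conformers$parent_id, smiles = conformers$smiles,
    coords = lapply(conformers$coordinates, function(m)
      lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))),
    seeds = conformers$seeds, path = path
  ))
  invisible(path)
}

#' Read peptide records from a CSV table
#'
#' Expected columns: `id`, `smiles`, optional `helm` (monomer ids joined in
#' a HELM-style simple polymer, parsed only as an ordered id list) and
#' optional `label`.  When `helm` and a monomer library are supplied, the
#' per-monomer SMILES are attached in sequence order.
#'
#' @param path CSV path.
#' @param monomer_library Optional data frame (or CSV path) with columns
#'   `monomer_id`, `smiles`.
#' @param max_heavy Passed to [parse_peptide()].
#' @return List of `peptide_record`s.
#' @export
read_peptides_csv <- function(path, monomer_library = NULL, max_heavy = 128) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smiles") %in% names(df))) {
    input_error("peptide CSV needs columns id, smiles")
  }
  lib <- NULL
  if (!is.null(monomer_library)) {
    lib <- if (is.character(monomer_library)) {
      utils::read.csv(monomer_library, stringsAsFactors = FALSE)
    } else monomer_library
    if (!all(c("monomer_id", "smiles") %in% names(lib))) {
      input_error("monomer library needs columns monomer_id, smiles")
    }
  }
  lapply(seq_len(nrow(df)), function(i) {
    mono <- NULL
    if (!is.null(lib) && "helm" %in% names(df) && nzchar(df$helm[i] %||% "")) {
      ids <- parse_helm_ids(df$helm[i])
      idx <- match(ids, lib$monomer_id)
      if (anyNA(idx)) {
        input_error(sprintf("row %d: unknown monomer id(s): %s", i,
                            paste(ids[is.na(idx)], collapse = ", ")))
      }
      mono <- lib$smiles[idx]
    }
    parse_peptide(df$id[i], df$smiles[i], monomer_smiles = mono,
                  label = if ("label" %in% names(df)) df$label[i] else NULL,
                  max_heavy = max_heavy)
  })
}

# "PEPTIDE1{Gly.meAla.dLeu}$$$$" -> c("Gly","meAla","dLeu"); also accepts a
# bare dot-separated list.  Deliberately not a full HELM parser.
parse_helm_ids <- function(helm) {
  inner <- sub("^[^{]*\\{", "", sub("\\}.*$", "", helm))
  ids <- strsplit(inner, ".", fixed = TRUE)[[1]]
  ids[nzchar(ids)]
}
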