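# Whole-molecule and monomer descriptor vectors, Morgan fingerprints,
# Z-score standardization and the constant/correlation/importance
# descriptor-selection pipeline.

#' Names of the 16 modelled descriptors, in importance order
#'
#' The vector mirrors the descriptor panel used for both peptides and
#' monomers: van der Waals surface area weighted by EState indices, two
#' density variants, Wildman-Crippen logP, aliphatic hydroxyl count, an
#' independent octanol/water logP estimate, Lipinski violations, a logD
#' surrogate, and a charged-partial-surface-area family computed from
#' Gasteiger charges and heavy-atom solvent-accessible surface areas.
#' Commercial-only descriptors are replaced by documented open equivalents;
#' see the package vignette for the mapping table.
#'
#' @export
DESCRIPTOR_NAMES <- c(
  "VSA_EState9", "density", "MolLogP", "fr_Al_OH", "logP_ow",
  "lip_violation", "h_logD", "dens3D", "FNSA4", "RNCS", "FASA_neg",
  "FCASA_pos", "FASA_P", "FNSA2", "FNSA5", "Wp2"
)

#' Compute the 16-descriptor vector for one molecule
#'
#' 2D descriptors are computed from the molecular graph; 3D descriptors
#' (3D density and the charged-partial-surface-area family) use the
#' supplied conformer coordinates.
#'
#' @param smiles Molecule SMILES.
#' @param coordinates N x 3 heavy-atom coordinates matching the SMILES
#'   atom order.
#' @return Named numeric vector of length 16 in [DESCRIPTOR_NAMES] order
#'   (unstandardized).
#' @export
compute_descriptors <- function(smiles, coordinates) {
  coordinates <- as_coord_matrix(coordinates)
  res <- backend_jobs("descriptors16", list(list(
    smiles = smiles,
    coords = lapply(seq_len(nrow(coordinates)), function(i)
      unname(coordinates[i, ]))
  )))
  stats::setNames(as.numeric(res[[1]]$values), as.character(res[[1]]$names))
}

#' Fit a Z-score standardizer
#'
#' Column means and population standard deviations (denominator `n`) of a
#' numeric feature table.  Columns with zero spread are rejected by
#' default; `on_constant = "unit"` instead assigns them unit scale so they
#' pass through centred (used by the training pipeline, where e.g. a
#' Lipinski-violation count can be constant across all monomers).
#'
#' @param table Numeric matrix or data frame, rows = samples.
#' @param on_constant `"error"` (default) or `"unit"`.
#' @return Object of class `pepperm_standardizer`.
#' @export
fit_standardizer <- function(table, on_constant = c("error", "unit")) {
  on_constant <- match.arg(on_constant)
  m <- as.matrix(table)
  if (nrow(m) < 2) input_error("standardizer needs at least 2 rows")
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2, mu)^2))
  if (any(sd_pop <= 0)) {
    if (on_constant == "error") {
      bad <- colnames(m)[sd_pop <= 0] %||% which(sd_pop <= 0)
      pepperm_error("pepperm_fit_error",
                    sprintf("zero-spread column(s): %s",
                            paste(bad, collapse = ", ")))
    }
    sd_pop[sd_pop <= 0] <- 1
  }
  structure(list(means = mu, stds = sd_pop), class = "pepperm_standardizer")
}

#' Apply or invert a fitted standardizer
#'
#' @param standardizer A `pepperm_standardizer`.
#' @param table Matrix (or vector interpreted as one row) to transform.
#' @return Standardized matrix of the same shape.
#' @export
standardize <- function(standardizer, table) {
  stopifnot(inherits(standardizer, "pepperm_standardizer"))
  v <- is.null(dim(table))
  m <- if (v) matrix(table, nrow = 1) else as.matrix(table)
  out <- sweep(sweep(m, 2, standardizer$means), 2, standardizer$stds, "/")
  if (v) out[1, ] else out
}

#' @rdname standardize
#' @export
unstandardize <- function(standardizer, table) {
  stopifnot(inherits(standardizer, "pepperm_standardizer"))
  v <- is.null(dim(table))
  m <- if (v) matrix(table, nrow = 1) else as.matrix(table)
  out <- sweep(sweep(m, 2, standardizer$stds, "*"), 2, standardizer$means, "+")
  if (v) out[1, ] else out
}

#' 2048-bit Morgan fingerprint
#'
#' Concatenation of a 1024-bit radius-2 and a 1024-bit radius-3 Morgan
#' fingerprint; invariant under SMILES enumeration of the same molecule.
#'
#' @param smiles Molecule SMILES.
#' @return Integer 0/1 vector of length 2048 (radius-2 bits first).
#' @export
morgan_fingerprint <- function(smiles) {
  res <- backend_jobs("fingerprint", list(list(smiles = smiles)),
                      error_class = "pepperm_input_error")
  bits <- integer(2048)
  bits[as.integer(res[[1]]$bits_on) + 1L] <- 1L
  bits
}

#' Descriptor pool for selection experiments
#'
#' A pool of >= 100 named descriptors (the full RDKit 2D set plus 3D shape
#' and charged-partial-surface-area descriptors), each tagged `"2D"` or
#' `"3D"`, for exercising [select_descriptors()].
#'
#' @inheritParams compute_descriptors
#' @return List with `values` (named numeric) and `tags` (named character).
#' @export
descriptor_pool <- function(smiles, coordinates) {
  coordinates <- as_coord_matrix(coordinates)
  res <- backend_jobs("pool", list(list(
    smiles = smiles,
    coords = lapply(seq_len(nrow(coordinates)), function(i)
      unname(coordinates[i, ]))
  )))
  r <- res[[1]]
  list(values = stats::setNames(as.numeric(r$values), as.character(r$names)),
       tags = stats::setNames(as.character(r$tags), as.character(r$names)))
}

#' Select descriptors by constancy, correlation and forest importance
#'
#' Three-step pipeline: (1) drop constant columns; (2) for column pairs
#' with `|Pearson r| >= cor_cutoff` (processed in descending pair `|r|`,
#' ties broken by column order) drop the member with the lower absolute
#' Pearson correlation with the labels; (3) rank survivors by random-forest
#' impurity importance, fitted separately on the 2D and 3D blocks, and
#' keep the top `k2d` + `k3d`.
#'
#' @param table Numeric matrix, samples x descriptors, with column names.
#' @param labels Numeric response aligned with rows.
#' @param tags Character vector (`"2D"`/`"3D"`) per column.
#' @param k2d,k3d Number of 2D and 3D descriptors to keep.
#' @param cor_cutoff Absolute pairwise correlation threshold (default 0.9).
#' @param seed Random seed for the forests.
#' @param ntree Trees per forest (default 500).
#' @return Character vector of selected descriptor names (2D block first,
#'   each block in decreasing importance).
#' @export
select_descriptors <- function(table, labels, tags, k2d, k3d,
                               cor_cutoff = 0.9, seed = 1, ntree = 500) {
  m <- as.matrix(table)
  if (is.null(colnames(m))) input_error("table must have column names")
  stopifnot(length(labels) == nrow(m), length(tags) == ncol(m))

  # (1) constant columns
  keep <- apply(m, 2, function(x) stats::sd(x) > 0)
  m <- m[, keep, drop = FALSE]
  tags <- tags[keep]

  # (2) correlated pairs, highest |pair r| first
  cm <- suppressWarnings(abs(stats::cor(m)))
  cm[!is.finite(cm)] <- 0
  lab_cor <- abs(suppressWarnings(stats::cor(m, labels)))[, 1]
  lab_cor[!is.finite(lab_cor)] <- 0
  pairs <- which(upper.tri(cm) & cm >= cor_cutoff, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    ord <- order(-cm[pairs], pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    dropped <- logical(ncol(m))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (dropped[i] || dropped[j]) next
      # drop the member correlating less with the labels
      if (lab_cor[i] < lab_cor[j]) dropped[i] <- TRUE else dropped[j] <- TRUE
    }
    m <- m[, !dropped, drop = FALSE]
    tags <- tags[!dropped]
  }

  # (3) per-block random-forest importance
  pick <- function(block, k) {
    cols <- which(tags == block)
    if (length(cols) < k) {
      pepperm_error("pepperm_selection_error",
                    sprintf("only %d %s descriptors survive, %d requested",
                            length(cols), block, k))
    }
    sub <- m[, cols, drop = FALSE]
    set.seed(seed)
    rf <- randomForest::randomForest(x = sub, y = labels, ntree = ntree,
                                     importance = FALSE)
    imp <- randomForest::importance(rf)[, 1]
    colnames(sub)[order(-imp)][seq_len(k)]
  }
  c(pick("2D", k2d), pick("3D", k3d))
}
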