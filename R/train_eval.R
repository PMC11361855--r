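# Dataset preparation (label clipping, diversity splits), the training
# loop over replica-expanded rows, ensemble inference and metrics.

#' Clip log10 permeability labels to the assay detection window
#'
#' Values below -8 (the detection limit of most permeability assays) are
#' rounded up to -8; values above -4 are rounded down to -4.  Idempotent.
#'
#' @param values Numeric vector of log10 permeabilities (cm/s).
#' @return Clipped vector.
#' @export
clip_labels <- function(values) {
  if (any(!is.finite(values))) input_error("labels must be finite")
  pmin(pmax(values, -8), -4)
}

#' Kennard-Stone diversity selection
#'
#' Classic deterministic greedy selection: seed with the pair at maximum
#' Euclidean distance, then repeatedly add the sample whose minimum
#' distance to the already-selected set is largest, until
#' `ceiling(fraction * n)` samples are selected.  Ties break towards the
#' lower row index.
#'
#' @param x Numeric matrix, rows = samples (e.g. fingerprint bits).
#' @param fraction Fraction of rows to select, in (0, 1).
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone_split <- function(x, fraction) {
  m <- as.matrix(x)
  n <- nrow(m)
  if (n < 2) input_error("need at least 2 samples")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    input_error("fraction must lie in (0, 1)")
  }
  k <- ceiling(fraction * n)
  d <- as.matrix(stats::dist(m))
  # seed: max-distance pair (lowest indices on ties)
  best <- which(d == max(d), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  sel <- as.integer(c(min(best), max(best)))
  if (k <= 2) return(sel[seq_len(k)])
  mind <- unname(pmin(d[, sel[1]], d[, sel[2]]))
  mind[sel] <- -Inf
  while (length(sel) < k) {
    nxt <- unname(which.max(mind))  # which.max takes the first maximum
    sel <- c(sel, nxt)
    mind <- pmin(mind, d[, nxt])
    mind[nxt] <- -Inf
  }
  as.integer(sel)
}

#' Build a test/validation/train split plan
#'
#' The test set (default 5%) is chosen by Kennard-Stone on the peptide
#' fingerprints so it covers the structural space; three mutually disjoint
#' validation folds (default 5% each) are then drawn at random from the
#' remainder.  The training set for fold `j` is everything outside the
#' test set and fold `j`.
#'
#' @param ids Character vector of peptide ids.
#' @param fingerprints Matrix of fingerprint rows aligned with `ids`.
#' @param test_fraction,val_fraction Fractions for the test set and each
#'   validation fold.
#' @param n_folds Number of validation folds (default 3).
#' @param seed Integer seed for the random folds.
#' @return Object of class `pepperm_split` with `test_ids`,
#'   `validation_ids` (list of folds) and `all_ids`.
#' @export
split_plan <- function(ids, fingerprints, test_fraction = 0.05,
                       val_fraction = 0.05, n_folds = 3, seed = 1) {
  stopifnot(length(ids) == nrow(fingerprints))
  test_idx <- kennard_stone_split(fingerprints, test_fraction)
  rest <- setdiff(seq_along(ids), test_idx)
  per_fold <- ceiling(val_fraction * length(ids))
  if (n_folds * per_fold > length(rest)) {
    size_error("not enough samples for disjoint validation folds")
  }
  rng <- local_rng(stable_hash(seed, "folds") %% 2147483647)
  shuffled <- rest[rng$sample_int(length(rest), length(rest))]
  folds <- lapply(seq_len(n_folds), function(j) {
    sort(shuffled[((j - 1) * per_fold + 1):(j * per_fold)])
  })
  structure(
    list(test_ids = ids[test_idx],
         validation_ids = lapply(folds, function(f) ids[f]),
         all_ids = ids),
    class = "pepperm_split"
  )
}

#' Training ids for one fold of a split plan
#' @param plan A `pepperm_split`.
#' @param fold Validation fold index.
#' @return Character vector of training ids.
#' @export
train_ids <- function(plan, fold = 1) {
  stopifnot(inherits(plan, "pepperm_split"))
  setdiff(plan$all_ids, c(plan$test_ids, plan$validation_ids[[fold]]))
}

#' @export
print.pepperm_split <- function(x, ...) {
  cat(sprintf("<pepperm_split: %d peptides; %d test, %s validation>\n",
              length(x$all_ids), length(x$test_ids),
              paste(lengths(x$validation_ids), collapse = "/")))
  invisible(x)
}

# --- model-ready rows -------------------------------------------------------

# Convert one raw replica (from build_replicas) into the trimmed matrices
# consumed by forward_sample().  Standardizers must be fitted on training
# rows only.
replica_to_row <- function(rep, record, std_desc, std_mono, cf) {
  tb <- list(atoms = rep$atoms, bonds = rep$bonds)
  node <- node_features(tb)
  n <- nrow(node)
  if (n > cf$n_max) {
    size_error(sprintf("peptide '%s' has %d heavy atoms, padding size is %d",
                       record$id, n, cf$n_max))
  }
  bond <- bond_matrix(tb)
  graph <- graph_distance_matrix(tb)
  conf <- conf_distance_matrix(rep$coords)
  bond_pad <- cbind(bond, matrix(0, n, cf$n_max - n))
  mono_std <- standardize(std_mono, rep$monomer_desc)
  arr <- rep$arrangement
  L <- arr$length
  if (arr$offset + L > cf$max_len) {
    size_error(sprintf(
      "arrangement frame (offset %d + %d monomers) exceeds config max_len %d",
      arr$offset, L, cf$max_len))
  }
  rows <- ((seq_len(L) - 1L + arr$rotation) %% L) + 1L
  mono <- matrix(0, cf$max_len, ncol(mono_std))
  mono[arr$offset + seq_len(L), ] <- mono_std[rows, , drop = FALSE]
  list(
    id = record$id,
    node = node, bond = bond_pad,
    sg = attenuation(graph), sc = attenuation(conf),
    mono = mono, span_offset = arr$offset, span_len = L,
    desc = standardize(std_desc, rep$desc16),
    fp = as.numeric(record$fingerprint),
    label = rep$label
  )
}

# Fit standardizers on the training peptides of a replica bundle and
# convert every replica into a model-ready row.
prepare_rows <- function(replicas, train_id_set, cf) {
  recs <- replicas$records
  is_train <- vapply(recs, function(r) r$id %in% train_id_set, logical(1))
  if (!any(is_train)) input_error("no training peptides in replica bundle")
  desc_rows <- do.call(rbind, unlist(lapply(recs[is_train], function(r)
    lapply(r$replicas, function(rp) rp$desc16)), recursive = FALSE))
  mono_rows <- do.call(rbind, unlist(lapply(recs[is_train], function(r)
    lapply(r$replicas, function(rp) rp$monomer_desc)), recursive = FALSE))
  std_desc <- fit_standardizer(desc_rows, on_constant = "unit")
  std_mono <- fit_standardizer(mono_rows, on_constant = "unit")
  rows <- unlist(lapply(recs, function(r) {
    lapply(r$replicas, function(rp)
      replica_to_row(rp, r, std_desc, std_mono, cf))
  }), recursive = FALSE)
  list(rows = rows, std_desc = std_desc, std_mono = std_mono)
}

rows_for_ids <- function(rows, ids) {
  rows[vapply(rows, function(r) r$id %in% ids, logical(1))]
}

# --- training loop ----------------------------------------------------------

#' Train the fusion model on replica-expanded rows
#'
#' Minimizes the auxiliary-weighted total loss with Adam over shuffled
#' minibatches of replica rows; logs per-epoch training loss and MAE and
#' validation MAE; early-stops when the validation MAE has not improved
#' for `config$patience` epochs and restores the best parameters.
#' Reproducible given `seed`.
#'
#' @param rows Training rows (see `prepare_rows()`).
#' @param val_rows Validation rows (row-level MAE drives early stopping).
#' @param config A [pepperm_config()].
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @param params Optional warm-start parameters.
#' @param verbose Print per-epoch progress.
#' @return List with `params`, `history` (data frame), `best_epoch`.
#' @export
train_model <- function(rows, val_rows, config, seed = 1, params = NULL,
                        verbose = FALSE) {
  if (length(rows) == 0) input_error("empty training set")
  cf <- config
  if (is.null(params)) params <- init_pepperm_params(cf, seed)
  state <- adam_new(params)
  rng <- local_rng(stable_hash(seed, "train") %% 2147483647)
  best <- list(mae = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), train_total = numeric(),
                     train_fusion = numeric(), train_mae = numeric(),
                     val_mae = numeric())
  n <- length(rows)
  for (epoch in seq_len(cf$epochs)) {
    ord <- rng$sample_int(n, n)
    tot <- 0; fus <- 0; abs_err <- 0
    for (start in seq(1, n, by = cf$batch)) {
      batch <- ord[start:min(start + cf$batch - 1, n)]
      acc <- acc_new()
      for (i in batch) {
        sm <- rows[[i]]
        fw <- forward_sample(sm, params, cf, train = TRUE, rng = rng)
        ls <- sample_losses(fw$preds, sm$label)
        lb <- total_loss(ls, cf$gamma_sub, cf$gamma_layer)
        tot <- tot + lb$total
        fus <- fus + lb$fusion
        abs_err <- abs_err + abs(fw$preds[["fusion"]] - sm$label)
        backward_sample(fw, sm, sm$label, params, cf, acc,
                        scale = 1 / length(batch))
      }
      up <- adam_step(params, acc, state, cf$lr)
      params <- up$params
      state <- up$state
    }
    val_mae <- if (length(val_rows)) {
      mean(abs(predict_rows(val_rows, params, cf) -
                 vapply(val_rows, `[[`, numeric(1), "label")))
    } else NA_real_
    hist <- rbind(hist, data.frame(
      epoch = epoch, train_total = tot / n, train_fusion = fus / n,
      train_mae = abs_err / n, val_mae = val_mae))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train MAE %.4f  val MAE %s",
                      epoch, tot / n, abs_err / n,
                      ifelse(is.na(val_mae), "-", sprintf("%.4f", val_mae))))
    }
    crit <- if (is.na(val_mae)) abs_err / n else val_mae
    if (crit < best$mae - 1e-9) {
      best <- list(mae = crit, params = params, epoch = epoch)
    } else if (epoch - best$epoch >= cf$patience) {
      break
    }
  }
  list(params = best$params, history = hist, best_epoch = best$epoch)
}

#' Row-level fusion predictions
#' @param rows Model-ready rows.
#' @param params,config Parameters and configuration.
#' @return Numeric vector of per-row predictions.
#' @export
predict_rows <- function(rows, params, config) {
  vapply(rows, function(sm)
    forward_sample(sm, params, config)$preds[["fusion"]], numeric(1))
}

#' Ensemble prediction for one peptide
#'
#' The arithmetic mean of the per-replica fusion outputs; replicas must
#' have been generated with the model's featurization settings.
#'
#' @param params,config Parameters and configuration.
#' @param rows The replica rows of one peptide.
#' @return Scalar prediction.
#' @export
predict_ensemble <- function(params, config, rows) {
  if (length(rows) == 0) input_error("no replicas supplied")
  mean(predict_rows(rows, params, config))
}

# --- metrics ----------------------------------------------------------------

#' Regression metrics for permeability prediction
#'
#' Mean absolute error, mean squared error, Pearson correlation and the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`.  With
#' zero-variance labels R is undefined: the report carries `degenerate =
#' TRUE` and `r = NA`.
#'
#' @param predictions,labels Aligned numeric vectors (length >= 2).
#' @return Object of class `pepperm_metrics`: `mae`, `mse`, `r`, `r2`,
#'   `n`, `degenerate`.
#' @export
evaluate <- function(predictions, labels) {
  if (length(predictions) != length(labels)) input_error("length mismatch")
  if (length(labels) < 2) input_error("need at least 2 points")
  err <- predictions - labels
  ss_tot <- sum((labels - mean(labels))^2)
  degenerate <- ss_tot == 0
  r <- if (degenerate) NA_real_ else
    suppressWarnings(stats::cor(predictions, labels))
  structure(
    list(mae = mean(abs(err)), mse = mean(err^2),
         r = r, r2 = if (degenerate) NA_real_ else 1 - sum(err^2) / ss_tot,
         n = length(labels), degenerate = degenerate),
    class = "pepperm_metrics"
  )
}

#' @export
print.pepperm_metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f  MSE %.3f  R %s  R2 %s  (n = %d)\n",
              x$mae, x$mse,
              ifelse(is.na(x$r), "NA", sprintf("%.3f", x$r)),
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2)), x$n))
  invisible(x)
}
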