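# The user-facing fitting interface: one function returning a classed
# model object with the usual methods.

#' Fit the multi-level permeability fusion model
#'
#' End-to-end fit on a set of labelled cyclic peptides: builds augmented
#' replica features (SMILES enumeration + conformer + cyclic sequence
#' arrangement per replica), draws a Kennard-Stone test set and random
#' validation folds, fits the Z-score standardizers on the training
#' peptides only, trains the three-branch fusion network with auxiliary
#' losses, and evaluates ensemble predictions on the held-out test set.
#'
#' @param records List of labelled `peptide_record`s (see
#'   [parse_peptide()], [make_dataset()]); records without a monomer
#'   annotation are divided automatically.
#' @param replicas Augmented replicas per peptide (default 1; the full
#'   augmentation scheme uses 60).
#' @param config A [pepperm_config()].
#' @param seed Integer seed controlling featurization, splits, and
#'   training.
#' @param split Optional precomputed [split_plan()]; built from the
#'   fingerprints when `NULL`.
#' @param fold Validation fold used for early stopping (default 1).
#' @param features Optional precomputed [build_replicas()] bundle
#'   (overrides `records`/`replicas`).
#' @param method Conformer embedding method (see [generate_conformers()]).
#' @param verbose Print training progress.
#' @return Object of class `pepperm`.
#' @export
pepperm_fit <- function(records, replicas = 1, config = pepperm_config(),
                        seed = 1, split = NULL, fold = 1, features = NULL,
                        method = "etdg", verbose = FALSE) {
  if (inherits(records, "pepperm_synth")) records <- records$records
  if (is.null(features)) {
    records <- lapply(records, function(rec) {
      if (is.null(rec$monomers)) rec$monomers <- divide_monomers(rec)
      rec
    })
    features <- build_replicas(records, r = replicas, seed = seed,
                               max_len = config$max_len, method = method)
  }
  labels <- vapply(features$records, function(r) {
    if (is.null(r$label)) input_error(sprintf("record '%s' has no label", r$id))
    r$label
  }, numeric(1))
  labels <- clip_labels(labels)
  ids <- vapply(features$records, `[[`, "", "id")
  if (is.null(split)) {
    fps <- do.call(rbind, lapply(features$records, `[[`, "fingerprint"))
    split <- split_plan(ids, fps, seed = seed)
  }
  tr_ids <- train_ids(split, fold)
  prep <- prepare_rows(features, tr_ids, config)
  fit <- train_model(rows_for_ids(prep$rows, tr_ids),
                     rows_for_ids(prep$rows, split$validation_ids[[fold]]),
                     config, seed = seed, verbose = verbose)
  # held-out ensemble predictions
  test_pred <- vapply(split$test_ids, function(id)
    predict_ensemble(fit$params, config, rows_for_ids(prep$rows, id)),
    numeric(1))
  test_obs <- labels[match(split$test_ids, ids)]
  metrics <- if (length(test_pred) >= 2) evaluate(test_pred, test_obs) else NULL
  structure(
    list(params = fit$params, config = config, history = fit$history,
         best_epoch = fit$best_epoch, std_desc = prep$std_desc,
         std_mono = prep$std_mono, split = split, fold = fold,
         replicas = features$r, seed = seed, method = method,
         desc_names = features$desc_names,
         test = list(ids = split$test_ids, observed = test_obs,
                     predicted = test_pred, metrics = metrics),
         call = match.call()),
    class = "pepperm"
  )
}

#' @export
print.pepperm <- function(x, ...) {
  cat("Multi-level cyclic peptide permeability model\n")
  cat(sprintf("  peptides: %d (test %d), replicas/peptide: %d, seed: %d\n",
              length(x$split$all_ids), length(x$split$test_ids),
              x$replicas, x$seed))
  cat(sprintf("  trained %d epochs (best %d)\n",
              nrow(x$history), x$best_epoch))
  if (!is.null(x$test$metrics)) {
    cat("  held-out test: ")
    print(x$test$metrics)
  }
  invisible(x)
}

#' @export
summary.pepperm <- function(object, ...) {
  h <- object$history
  cat("Multi-level cyclic peptide permeability model\n\n")
  cat(sprintf("Configuration: d_model %d, heads %d, %d layers/block, lambda_g %.2f,\n",
              object$config$d_model, object$config$heads,
              object$config$layers_per_block, object$config$lambda_g))
  cat(sprintf("  %s conv (%s), latent %d, gamma_sub %.2f, gamma_layer %.2f\n",
              object$config$conv_kind,
              paste(object$config$channels, collapse = "-"),
              object$config$latent, object$config$gamma_sub,
              object$config$gamma_layer))
  cat(sprintf("\nTraining: %d rows x %d epochs, best epoch %d\n",
              length(train_ids(object$split, object$fold)) * object$replicas,
              nrow(h), object$best_epoch))
  cat(sprintf("  final train MAE %.3f, validation MAE %.3f\n",
              h$train_mae[nrow(h)], h$val_mae[nrow(h)]))
  if (!is.null(object$test$metrics)) {
    cat("\nHeld-out test (ensemble over replicas):\n  ")
    print(object$test$metrics)
  }
  invisible(object)
}

#' Predict permeability for new peptides
#'
#' Featurizes `newdata` with the model's stored settings (same replica
#' count, conformer method, standardizers), runs the fusion network on
#' every replica and averages per peptide.
#'
#' @param object A fitted `pepperm` model.
#' @param newdata List of `peptide_record`s, a `pepperm_synth`, or a
#'   precomputed `pepperm_replicas` bundle.
#' @param replicas Replicas per peptide (defaults to the fit's setting).
#' @param seed Featurization seed (defaults to the fit's seed).
#' @param ... Unused.
#' @return Named numeric vector of predicted log10 permeabilities.
#' @export
predict.pepperm <- function(object, newdata, replicas = object$replicas,
                            seed = object$seed, ...) {
  if (inherits(newdata, "pepperm_synth")) newdata <- newdata$records
  features <- if (inherits(newdata, "pepperm_replicas")) newdata else {
    newdata <- lapply(newdata, function(rec) {
      if (is.null(rec$monomers)) rec$monomers <- divide_monomers(rec)
      rec
    })
    build_replicas(newdata, r = replicas, seed = seed,
                   max_len = object$config$max_len, method = object$method)
  }
  out <- vapply(features$records, function(rec) {
    rows <- lapply(rec$replicas, function(rp)
      replica_to_row(rp, rec, object$std_desc, object$std_mono, object$config))
    predict_ensemble(object$params, object$config, rows)
  }, numeric(1))
  stats::setNames(out, vapply(features$records, `[[`, "", "id"))
}

#' @export
residuals.pepperm <- function(object, ...) {
  if (is.null(object$test$metrics)) {
    input_error("model has no held-out test set")
  }
  stats::setNames(object$test$observed - object$test$predicted,
                  object$test$ids)
}

#' @export
plot.pepperm <- function(x, ...) {
  if (is.null(x$test$metrics)) input_error("model has no held-out test set")
  rng <- range(c(x$test$observed, x$test$predicted))
  graphics::plot(x$test$observed, x$test$predicted, xlim = rng, ylim = rng,
                 xlab = "observed log10 permeability (cm/s)",
                 ylab = "predicted log10 permeability (cm/s)",
                 main = "Held-out test predictions", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
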