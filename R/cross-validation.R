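# Benchmark harness: repeated stratified k-fold cross-validation of any of
# the four classifiers, reporting accuracy (mean +/- SD, percent) and mean
# model size in unique genes.

#' Repeated cross-validation of a rank-based classifier
#'
#' For each repeat a fresh fold split is drawn (unless `refold = FALSE`),
#' the model is fitted on each training split only and scored on the held
#' out split. Accuracy is aggregated per repeat (pooled over folds) and
#' reported as mean and standard deviation across repeats, in percent, plus
#' the mean model size in unique genes. Every random choice is derived from
#' `seed`, so a report is exactly reproducible.
#'
#' @inheritParams pair_probabilities
#' @param method One of `"tsp"`, `"ktsp"`, `"tst"`, `"evotsp"`.
#' @param folds Number of cross-validation folds (default 10).
#' @param repeats Number of repeated runs (default 20).
#' @param seed Integer master seed.
#' @param stratify Stratify folds by class (default `TRUE`).
#' @param refold Draw new folds for every repeat (default `TRUE`); with
#'   `FALSE` only the classifier's own randomness varies across repeats.
#' @param k_max,inner_folds k-TSP settings (see [fit_ktsp()]).
#' @param config [evo_config()] for `method = "evotsp"`; its `seed` is
#'   overridden per fold from the master seed.
#' @return An object of class `cv_report`.
#' @examples
#' sim <- simulate_rxa_data(plant_spec(n_genes = 30, n_samples = 40,
#'                                     planted_pairs = list(c(1, 2)),
#'                                     noise_eps = 0, seed = 5))
#' cross_validate(sim$expr, sim$labels, "tsp", folds = 4, repeats = 2,
#'                seed = 5)
#' @export
cross_validate <- function(expr, labels, method = c("tsp", "ktsp", "tst",
                                                    "evotsp"),
                           folds = 10L, repeats = 20L, seed = 1L,
                           stratify = TRUE, refold = TRUE,
                           k_max = 10L, inner_folds = 5L,
                           config = evo_config()) {
  method <- match.arg(method)
  folds <- as.integer(folds)
  repeats <- as.integer(repeats)
  # one derived seed per (repeat, fold) plus one per repeat for the split
  derived <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max, repeats * (folds + 1L)),
    nrow = repeats))
  truth <- label_index(labels)
  rows <- vector("list", repeats * folds)
  r_acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    split_seed <- if (refold) derived[r, folds + 1L] else derived[1L, folds + 1L]
    fold_sets <- stratified_kfold(labels, folds, seed = split_seed,
                                  stratify = stratify)
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_sets[[f]]$train
      te <- fold_sets[[f]]$test
      tr_expr <- expr_matrix(unclass(expr)[, tr, drop = FALSE],
                             rownames(expr), colnames(expr)[tr])
      te_expr <- expr_matrix(unclass(expr)[, te, drop = FALSE],
                             rownames(expr), colnames(expr)[te])
      tr_labels <- class_labels(labels$labels[tr], labels$class_order)
      model <- switch(method,
        tsp = fit_tsp(tr_expr, tr_labels),
        ktsp = fit_ktsp(tr_expr, tr_labels, k_max = k_max,
                        inner_folds = inner_folds, seed = derived[r, f]),
        tst = fit_tst(tr_expr, tr_labels),
        evotsp = {
          cfg <- config
          cfg$seed <- derived[r, f]
          fit_evotsp(tr_expr, tr_labels, cfg)
        })
      pred <- predict(model, te_expr)
      n_ok <- sum(pred == labels$labels[te])
      correct <- correct + n_ok
      rows[[(r - 1L) * folds + f]] <- data.frame(
        rep = r, fold = f, n_test = length(te), correct = n_ok,
        accuracy = n_ok / length(te), size = model_size(model),
        seed = derived[r, f])
    }
    r_acc[r] <- correct / length(truth)
  }
  per_fold <- do.call(rbind, rows)
  report <- list(
    method = method, folds = folds, repeats = repeats, seed = seed,
    stratify = stratify, refold = refold,
    per_fold = per_fold,
    per_repeat_accuracy = r_acc,
    mean_accuracy_pct = 100 * mean(r_acc),
    sd_accuracy_pct = 100 * (if (repeats > 1L) stats::sd(r_acc)
                             else stats::sd(per_fold$accuracy)),
    mean_size = mean(per_fold$size),
    class_order = labels$class_order)
  class(report) <- "cv_report"
  report
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation of '%s'\n",
              x$repeats, x$folds, x$method))
  cat(sprintf("  accuracy: %.1f +/- %.1f %%\n",
              x$mean_accuracy_pct, x$sd_accuracy_pct))
  cat(sprintf("  mean model size: %.1f unique genes\n", x$mean_size))
  invisible(x)
}

#' Write a cross-validation report to JSON
#'
#' @param report A `cv_report` from [cross_validate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  out <- unclass(report)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
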