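# Exhaustive rank-based baseline classifiers: the single top-scoring pair
# (TSP), the disjoint-pair ensemble (k-TSP) with inner-CV choice of k, and
# the top-scoring triplet (TST). These serve both as comparators in the
# benchmark harness and as brute-force oracles when testing the
# evolutionary engine.

# order all scored pairs best-first: delta (exact integer key) desc,
# secondary desc, then lexicographic gene ids for full determinism
rank_pair_table <- function(scores) {
  ord <- order(-attr(scores, "delta_num"), -scores$secondary,
               scores$gene_i, scores$gene_j)
  scores[ord, , drop = FALSE]
}

# class index (1/2) that the observed relation x_i < x_j votes for
vote_of_pair <- function(p1, p2) ifelse(p1 >= p2, 1L, 2L)

#' Fit the top-scoring-pair (TSP) classifier
#'
#' Exhaustively scans all gene pairs and returns the pair with the highest
#' delta score; delta ties are broken by the secondary rank score, then by
#' lexicographic gene-id order. The relation `x_i < x_j` votes for the class
#' in which it is the more probable event.
#'
#' @inheritParams pair_probabilities
#' @return An object of class `tsp_model`.
#' @examples
#' sim <- simulate_rxa_data(plant_spec(n_genes = 30, n_samples = 40,
#'                                     planted_pairs = list(c(1, 2)),
#'                                     noise_eps = 0, seed = 7))
#' fit_tsp(sim$expr, sim$labels)
#' @export
fit_tsp <- function(expr, labels) {
  ranked <- rank_pair_table(score_all_pairs(expr, labels))
  best <- ranked[1L, ]
  structure(list(
    pair = best,
    vote_lt = vote_of_pair(best$p1, best$p2),
    class_order = labels$class_order),
    class = "tsp_model")
}

#' @export
print.tsp_model <- function(x, ...) {
  cat(sprintf("TSP model: (%s, %s), delta = %.4f\n",
              x$pair$gene_i, x$pair$gene_j, x$pair$delta))
  cat(sprintf("  %s < %s votes '%s'\n", x$pair$gene_i, x$pair$gene_j,
              x$class_order[x$vote_lt]))
  invisible(x)
}

# greedy gene-disjoint best-first pair list, at most k_max pairs
disjoint_top_pairs <- function(expr, labels, k_max) {
  ranked <- rank_pair_table(score_all_pairs(expr, labels))
  used <- logical(nrow(expr))
  keep <- integer(0L)
  for (r in seq_len(nrow(ranked))) {
    if (length(keep) >= k_max) break
    i <- ranked$i[r]
    j <- ranked$j[r]
    if (!used[i] && !used[j]) {
      keep <- c(keep, r)
      used[c(i, j)] <- TRUE
    }
  }
  ranked[keep, , drop = FALSE]
}

#' Fit the k-TSP classifier
#'
#' Greedily selects the top gene-disjoint pairs (best-first by delta, then
#' secondary score) and combines them by unweighted majority vote. The
#' ensemble size k is chosen over the odd candidates `1, 3, ..., <= k_max`
#' by internal stratified cross-validation on the training set; accuracy
#' ties prefer the smaller k.
#'
#' @inheritParams pair_probabilities
#' @param k_max Maximum number of disjoint pairs considered (default 10).
#' @param inner_folds Folds of the internal cross-validation (default 5).
#' @param seed Integer seed for the internal fold split.
#' @return An object of class `ktsp_model` with the selected pairs (a
#'   `pair_score` table plus per-pair vote directions) and the chosen `k`.
#' @export
fit_ktsp <- function(expr, labels, k_max = 10L, inner_folds = 5L, seed = 0L) {
  folds <- stratified_kfold(labels, inner_folds, seed = seed)
  ks <- seq(1L, max(1L, as.integer(k_max)), by = 2L)
  acc <- matrix(NA_real_, length(folds), length(ks))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    sub_labels <- class_labels(labels$labels[tr], labels$class_order)
    sub_expr <- expr_matrix(unclass(expr)[, tr, drop = FALSE],
                            rownames(expr), colnames(expr)[tr])
    pairs_f <- disjoint_top_pairs(sub_expr, sub_labels, max(ks))
    truth <- label_index(labels)[te]
    for (ki in seq_along(ks)) {
      use <- pairs_f[seq_len(min(ks[ki], nrow(pairs_f))), , drop = FALSE]
      pred <- ktsp_vote(use, vote_of_pair(use$p1, use$p2),
                        unclass(expr)[, te, drop = FALSE])
      acc[f, ki] <- mean(pred == truth)
    }
  }
  mean_acc <- colMeans(acc)
  k_chosen <- ks[which.max(mean_acc)]  # which.max takes the first = smallest k
  pairs <- disjoint_top_pairs(expr, labels, k_max)
  pairs <- pairs[seq_len(min(k_chosen, nrow(pairs))), , drop = FALSE]
  structure(list(
    pairs = pairs,
    vote_lt = vote_of_pair(pairs$p1, pairs$p2),
    k = nrow(pairs),
    inner_cv = data.frame(k = ks, accuracy = mean_acc),
    class_order = labels$class_order),
    class = "ktsp_model")
}

#' @export
print.ktsp_model <- function(x, ...) {
  cat(sprintf("k-TSP model: k = %d disjoint pairs\n", x$k))
  for (r in seq_len(nrow(x$pairs)))
    cat(sprintf("  (%s, %s) delta = %.4f\n",
                x$pairs$gene_i[r], x$pairs$gene_j[r], x$pairs$delta[r]))
  invisible(x)
}

# majority vote of a pair table on raw columns; expects row indices valid
ktsp_vote <- function(pairs, vote_lt, x) {
  less <- x[pairs$i, , drop = FALSE] < x[pairs$j, , drop = FALSE]
  # votes for class 1 per sample
  v1 <- colSums((less & vote_lt == 1L) | (!less & vote_lt == 2L))
  n <- nrow(pairs)
  pred <- ifelse(v1 * 2L > n, 1L, 2L)
  tie <- which(v1 * 2L == n)
  if (length(tie)) {
    # tie resolved by the vote of the highest-delta pair on that sample
    top_vote <- ifelse(less[1L, tie], vote_lt[1L], 3L - vote_lt[1L])
    pred[tie] <- top_vote
  }
  pred
}

# the 6 orderings of three values with ties broken by gene index; returns a
# code 1..6 per sample. i < j < l is assumed so "<=" realises the stable
# index tie-break.
ordering_codes <- function(a, b, c_) {
  key <- 4L * (a <= b) + 2L * (a <= c_) + (b <= c_)
  # key: 7 -> i<j<l, 6 -> i<l<j, 4 -> l<i<j, 3 -> j<i<l, 1 -> j<l<i, 0 -> l<j<i
  code <- c(6L, 5L, NA, 4L, 3L, NA, 2L, 1L)[key + 1L]
  code
}

tst_ordering_names <- c("i<j<l", "i<l<j", "l<i<j", "j<i<l", "j<l<i", "l<j<i")

#' Fit the top-scoring-triplet (TST) classifier
#'
#' For every gene triplet the six possible within-sample orderings of the
#' three expression values form a class-conditional distribution (ties are
#' ordered by gene index, so the orderings partition the samples). The
#' triplet score is the total-variation distance between the two class
#' distributions; the maximal-score triplet is returned. The O(P^3) scan is
#' intended for small gene sets (P up to a few dozen).
#'
#' @inheritParams pair_probabilities
#' @return An object of class `tst_model` holding the triplet, the two
#'   ordering distributions and the score.
#' @export
fit_tst <- function(expr, labels) {
  p <- nrow(expr)
  if (p < 3L) stop("TST needs at least 3 genes")
  idx <- label_index(labels)
  x <- unclass(expr)
  m1 <- sum(idx == 1L)
  m2 <- sum(idx == 2L)
  best <- NULL
  for (i in seq_len(p - 2L)) {
    for (j in seq((i + 1L), p - 1L)) {
      for (l in seq((j + 1L), p)) {
        code <- ordering_codes(x[i, ], x[j, ], x[l, ])
        t1 <- tabulate(code[idx == 1L], 6L) / m1
        t2 <- tabulate(code[idx == 2L], 6L) / m2
        sc <- 0.5 * sum(abs(t1 - t2))
        if (is.null(best) || sc > best$score + 1e-12) {
          best <- list(triplet = c(i, j, l), ordering_p1 = t1,
                       ordering_p2 = t2, score = sc)
        }
      }
    }
  }
  names(best$ordering_p1) <- names(best$ordering_p2) <- tst_ordering_names
  structure(c(best, list(
    gene_ids = rownames(expr)[best$triplet],
    class_sizes = c(m1, m2),
    class_order = labels$class_order)),
    class = "tst_model")
}

#' @export
print.tst_model <- function(x, ...) {
  cat(sprintf("TST model: (%s, %s, %s), score = %.4f\n",
              x$gene_ids[1L], x$gene_ids[2L], x$gene_ids[3L], x$score))
  invisible(x)
}

#' Predict class labels with a fitted rank-based model
#'
#' Applies a fitted [fit_tsp()], [fit_ktsp()], [fit_tst()] or [fit_evotsp()]
#' model to (new) expression data. Genes are matched by identifier; every
#' gene used by the model must be present.
#'
#' @param object A fitted model.
#' @param expr An [expr_matrix] containing all model genes.
#' @param ... Unused.
#' @return Character vector of predicted class labels, named by sample id.
#' @name predict-models
NULL

# resolve stored gene ids against a (possibly different) matrix
model_rows <- function(expr, ids) {
  pos <- match(ids, rownames(expr))
  if (anyNA(pos))
    stop("gene(s) absent from expression matrix: ",
         paste(ids[is.na(pos)], collapse = ", "))
  pos
}

#' @rdname predict-models
#' @export
predict.tsp_model <- function(object, expr, ...) {
  rows <- model_rows(expr, c(object$pair$gene_i, object$pair$gene_j))
  less <- unclass(expr)[rows[1L], ] < unclass(expr)[rows[2L], ]
  pred <- ifelse(less, object$vote_lt, 3L - object$vote_lt)
  stats::setNames(object$class_order[pred], colnames(expr))
}

#' @rdname predict-models
#' @export
predict.ktsp_model <- function(object, expr, ...) {
  pairs <- object$pairs
  pairs$i <- model_rows(expr, pairs$gene_i)
  pairs$j <- model_rows(expr, pairs$gene_j)
  pred <- ktsp_vote(pairs, object$vote_lt, unclass(expr))
  stats::setNames(object$class_order[pred], colnames(expr))
}

#' @rdname predict-models
#' @export
predict.tst_model <- function(object, expr, ...) {
  rows <- model_rows(expr, object$gene_ids)
  x <- unclass(expr)
  code <- ordering_codes(x[rows[1L], ], x[rows[2L], ], x[rows[3L], ])
  p1 <- object$ordering_p1[code]
  p2 <- object$ordering_p2[code]
  larger <- if (object$class_sizes[2L] > object$class_sizes[1L]) 2L else 1L
  pred <- ifelse(p1 > p2, 1L, ifelse(p2 > p1, 2L, larger))
  stats::setNames(object$class_order[pred], colnames(expr))
}

# number of distinct genes in a fitted model (the "size" currency of the
# benchmark reports)
#' Number of unique genes in a fitted model
#'
#' @param object A fitted `tsp_model`, `ktsp_model`, `tst_model` or
#'   `evotsp_model`.
#' @return Integer count of distinct gene identifiers used by the model.
#' @export
model_size <- function(object) {
  UseMethod("model_size")
}

#' @export
model_size.tsp_model <- function(object) 2L

#' @export
model_size.ktsp_model <- function(object)
  length(unique(c(object$pairs$gene_i, object$pairs$gene_j)))

#' @export
model_size.tst_model <- function(object) 3L
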