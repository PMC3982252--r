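# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's vectorised code paths: everything is a plain double
# loop over samples so the main implementation can be checked against them.

# tie-free random dataset: continuous values, two classes
random_dataset <- function(p, m, seed, m1 = ceiling(m / 2)) {
  set.seed(seed)
  x <- matrix(round(stats::runif(p * m, 1, 1000), 6), p, m)
  expr <- expr_matrix(x, paste0("g", seq_len(p)), paste0("s", seq_len(m)))
  labels <- class_labels(rep(c("C1", "C2"), c(m1, m - m1)),
                         class_order = c("C1", "C2"))
  list(expr = expr, labels = labels)
}

# per-pair statistics by explicit per-sample counting
oracle_pair_stats <- function(expr, labels, i, j) {
  x <- unclass(expr)
  cls <- match(labels$labels, labels$class_order)
  n <- c(0L, 0L)
  tot <- c(0L, 0L)
  for (m in seq_len(ncol(x))) {
    tot[cls[m]] <- tot[cls[m]] + 1L
    if (x[i, m] < x[j, m]) n[cls[m]] <- n[cls[m]] + 1L
  }
  p1 <- n[1L] / tot[1L]
  p2 <- n[2L] / tot[2L]
  # secondary: within-sample average ranks, class means of the difference
  d <- numeric(ncol(x))
  for (m in seq_len(ncol(x))) {
    r <- rank(x[, m], ties.method = "average")
    d[m] <- r[i] - r[j]
  }
  sec <- abs(mean(d[cls == 1L]) - mean(d[cls == 2L]))
  list(p1 = p1, p2 = p2, delta = abs(p1 - p2), secondary = sec)
}

# arg-max pair over the full double loop, with (delta, secondary, lex id)
# tie-breaking
oracle_best_pair <- function(expr, labels) {
  p <- nrow(expr)
  best <- NULL
  for (i in seq_len(p - 1L)) {
    for (j in seq((i + 1L), p)) {
      s <- oracle_pair_stats(expr, labels, i, j)
      cand <- c(i = i, j = j, delta = s$delta, secondary = s$secondary)
      if (is.null(best)) { best <- cand; next }
      ids_b <- rownames(expr)[best[c("i", "j")]]
      ids_c <- rownames(expr)[c(i, j)]
      better <-
        (cand["delta"] > best["delta"] + 1e-12) ||
        (abs(cand["delta"] - best["delta"]) <= 1e-12 &&
           cand["secondary"] > best["secondary"] + 1e-12) ||
        (abs(cand["delta"] - best["delta"]) <= 1e-12 &&
           abs(cand["secondary"] - best["secondary"]) <= 1e-12 &&
           (ids_c[1L] < ids_b[1L] ||
              (ids_c[1L] == ids_b[1L] && ids_c[2L] < ids_b[2L])))
      if (better) best <- cand
    }
  }
  best
}

# best triplet by full enumeration; orderings via order() with index
# tie-break, counted per class
oracle_best_triplet <- function(expr, labels) {
  x <- unclass(expr)
  cls <- match(labels$labels, labels$class_order)
  p <- nrow(x)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  best_score <- -1
  best_tri <- NULL
  for (i in seq_len(p - 2L)) for (j in seq((i + 1L), p - 1L))
    for (l in seq((j + 1L), p)) {
      cnt <- matrix(0, 2, 6)
      for (m in seq_len(ncol(x))) {
        vals <- x[c(i, j, l), m]
        o <- order(vals, seq_len(3L))        # stable index tie-break
        code <- which(vapply(perms, identical, logical(1L), as.numeric(o)))
        cnt[cls[m], code] <- cnt[cls[m], code] + 1
      }
      d1 <- cnt[1L, ] / sum(cls == 1L)
      d2 <- cnt[2L, ] / sum(cls == 2L)
      sc <- 0.5 * sum(abs(d1 - d2))
      if (sc > best_score + 1e-12) {
        best_score <- sc
        best_tri <- c(i, j, l)
      }
    }
  list(triplet = best_tri, score = best_score)
}

# a strictly increasing per-sample transform (different per column)
monotone_transform <- function(expr) {
  x <- unclass(expr)
  for (m in seq_len(ncol(x))) x[, m] <- x[, m]^3 + m
  expr_matrix(x, rownames(expr), colnames(expr))
}

# does a fitted pair ensemble contain the unordered gene pair (a, b)?
contains_pair <- function(pairs_df, a, b) {
  any((pairs_df$gene_i == a & pairs_df$gene_j == b) |
        (pairs_df$gene_i == b & pairs_df$gene_j == a))
}
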