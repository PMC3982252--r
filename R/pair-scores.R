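#' Class-conditional ordering probabilities of a gene pair
#'
#' For genes i and j, returns the fraction of samples in each class in which
#' gene i is expressed strictly below gene j within the sample. Equality
#' counts as "not below": the indicator is 1 only when `x_i < x_j`. These two
#' probabilities are the building block of every top-scoring-pair statistic.
#'
#' @param expr An [expr_matrix].
#' @param labels A [class_labels] object aligned with `expr`'s samples.
#' @param i,j Gene row indices (or gene id strings), `i != j`.
#' @return Numeric vector `c(p1, p2)`: the probability of `x_i < x_j` in the
#'   first and second class of `labels$class_order`.
#' @examples
#' x <- expr_matrix(rbind(g1 = c(1, 3, 5, 2, 4), g2 = c(2, 4, 1, 1, 3)),
#'                  c("g1", "g2"), paste0("s", 1:5))
#' y <- class_labels(c("A", "A", "A", "B", "B"))
#' pair_probabilities(x, y, "g1", "g2")
#' @export
pair_probabilities <- function(expr, labels, i, j) {
  ij <- resolve_gene_pair(expr, i, j)
  idx <- label_index(labels)
  less <- expr[ij[1L], ] < expr[ij[2L], ]
  c(mean(less[idx == 1L]), mean(less[idx == 2L]))
}

resolve_gene_pair <- function(expr, i, j) {
  ij <- c(resolve_gene(expr, i), resolve_gene(expr, j))
  if (ij[1L] == ij[2L]) stop("gene indices i and j must differ")
  ij
}

resolve_gene <- function(expr, g) {
  if (is.character(g)) {
    pos <- match(g, rownames(expr))
    if (is.na(pos)) stop("unknown gene id: ", g)
    return(pos)
  }
  g <- as.integer(g)
  if (is.na(g) || g < 1L || g > nrow(expr)) stop("gene index out of range: ", g)
  g
}

#' Top-scoring-pair score of one gene pair
#'
#' The primary pair statistic: `delta = |p1 - p2|`, the absolute difference of
#' the two class-conditional probabilities of the event `x_i < x_j`, together
#' with the secondary rank-difference score used to break delta ties.
#'
#' @inheritParams pair_probabilities
#' @return A one-row data frame of class `pair_score` with columns `i`, `j`
#'   (row indices), `gene_i`, `gene_j` (ids), `p1`, `p2`, `delta`,
#'   `secondary`.
#' @seealso [score_all_pairs()] for the exhaustive scan, [fit_tsp()] for the
#'   arg-max classifier.
#' @export
tsp_score <- function(expr, labels, i, j) {
  ij <- resolve_gene_pair(expr, i, j)
  p <- pair_probabilities(expr, labels, ij[1L], ij[2L])
  out <- data.frame(
    i = ij[1L], j = ij[2L],
    gene_i = rownames(expr)[ij[1L]], gene_j = rownames(expr)[ij[2L]],
    p1 = p[1L], p2 = p[2L],
    delta = abs(p[1L] - p[2L]),
    secondary = secondary_rank_score(expr, labels, ij[1L], ij[2L]),
    stringsAsFactors = FALSE)
  class(out) <- c("pair_score", class(out))
  out
}

#' Secondary rank-difference score for delta ties
#'
#' Each sample's expression vector is converted to within-sample ranks
#' (average ranks on ties). The score is the absolute difference between the
#' two class means of the per-sample rank difference `rank(x_i) - rank(x_j)`.
#' Larger values indicate a more consistent rank separation and win delta
#' ties. Because only ranks enter, the score is invariant to any strictly
#' monotone per-sample transform.
#'
#' @inheritParams pair_probabilities
#' @return A single non-negative number.
#' @export
secondary_rank_score <- function(expr, labels, i, j) {
  ij <- resolve_gene_pair(expr, i, j)
  ranks <- sample_ranks(expr)
  idx <- label_index(labels)
  d <- ranks[ij[1L], ] - ranks[ij[2L], ]
  abs(mean(d[idx == 1L]) - mean(d[idx == 2L]))
}

# within-sample (column-wise) average ranks of an expression matrix
sample_ranks <- function(expr) {
  apply(unclass(expr), 2L, rank, ties.method = "average")
}

#' Score every unordered gene pair
#'
#' Exhaustively scores all P(P-1)/2 unordered gene pairs. The scan is
#' vectorised over samples (per-class probabilities are accumulated as exact
#' integer counts, so delta ties are detected without floating-point slack).
#'
#' @inheritParams pair_probabilities
#' @return A data frame with one row per unordered pair `i < j` and the same
#'   columns as [tsp_score()], ordered by `(i, j)`.
#' @examples
#' x <- expr_matrix(matrix(runif(12), 4, 3,
#'                  dimnames = list(paste0("g", 1:4), paste0("s", 1:3))))
#' y <- class_labels(c("A", "A", "B"))
#' nrow(score_all_pairs(x, y))  # choose(4, 2) = 6
#' @export
score_all_pairs <- function(expr, labels) {
  p <- nrow(expr)
  idx <- label_index(labels)
  counts <- pair_less_counts(expr, idx)
  m1 <- sum(idx == 1L)
  m2 <- sum(idx == 2L)
  ut <- which(upper.tri(counts$n1), arr.ind = TRUE)
  ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  i <- ut[, 1L]
  j <- ut[, 2L]
  n1 <- counts$n1[ut]
  n2 <- counts$n2[ut]
  ranks <- sample_ranks(expr)
  rdiff <- rowMeans(ranks[, idx == 1L, drop = FALSE]) -
    rowMeans(ranks[, idx == 2L, drop = FALSE])
  out <- data.frame(
    i = i, j = j,
    gene_i = rownames(expr)[i], gene_j = rownames(expr)[j],
    p1 = n1 / m1, p2 = n2 / m2,
    delta = abs(n1 / m1 - n2 / m2),
    secondary = abs(rdiff[i] - rdiff[j]),
    stringsAsFactors = FALSE)
  # exact integer tie keys: |n1*m2 - n2*m1| over the common denominator m1*m2
  attr(out, "delta_num") <- abs(n1 * m2 - n2 * m1)
  attr(out, "delta_den") <- m1 * m2
  out
}

# P x P matrices of per-class counts of the event x[i, ] < x[j, ]
pair_less_counts <- function(expr, idx) {
  p <- nrow(expr)
  n1 <- matrix(0L, p, p)
  n2 <- matrix(0L, p, p)
  x <- unclass(expr)
  for (m in seq_len(ncol(x))) {
    less <- outer(x[, m], x[, m], `<`)
    if (idx[m] == 1L) n1 <- n1 + less else n2 <- n2 + less
  }
  list(n1 = n1, n2 = n2)
}
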