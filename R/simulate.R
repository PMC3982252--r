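# Synthetic microarray-like data with planted rank-inversion signals.
# Background expression is i.i.d. log-normal; signal is planted by
# *swapping* background draws between the planted genes, so every gene's
# marginal value distribution is untouched — planted genes are invisible to
# univariate differential-expression statistics, and only the within-sample
# ordering carries class information.

#' Specification of a synthetic dataset with planted ordering signals
#'
#' @param n_genes Number of genes P (>= 2).
#' @param n_samples Number of samples M (>= 2).
#' @param class_fraction Fraction of samples in the first class (default
#'   0.5); class sizes are `round(class_fraction * M)` and the rest.
#' @param planted_pairs List of length-2 integer vectors `(i, j)`: in class 1
#'   the pair is ordered `x_i < x_j`, in class 2 `x_i > x_j`, each with
#'   probability `1 - noise_eps` per sample.
#' @param planted_triplets List of length-3 integer vectors `(i, j, l)`:
#'   class 1 samples carry the ordering `x_i < x_j < x_l`, class 2 the
#'   reverse, with probability `1 - noise_eps`; otherwise a uniformly random
#'   ordering of the three values is used.
#' @param noise_eps Per-sample probability of flipping/randomising a planted
#'   unit, in `[0, 0.5]`.
#' @param background_meanlog,background_sdlog Log-normal background
#'   parameters (defaults give positive continuous values on a microarray-
#'   intensity-like scale).
#' @param seed Integer seed; the same spec always generates the same data.
#' @return A list of class `plant_spec`.
#' @seealso [simulate_rxa_data()], [expected_pair_delta()]
#' @export
plant_spec <- function(n_genes = 1000L, n_samples = 100L,
                       class_fraction = 0.5,
                       planted_pairs = list(), planted_triplets = list(),
                       noise_eps = 0.05,
                       background_meanlog = 5, background_sdlog = 1,
                       seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples = as.integer(n_samples),
               class_fraction = class_fraction,
               planted_pairs = lapply(planted_pairs, as.integer),
               planted_triplets = lapply(planted_triplets, as.integer),
               noise_eps = noise_eps,
               background_meanlog = background_meanlog,
               background_sdlog = background_sdlog,
               seed = as.integer(seed))
  if (spec$n_genes < 2L || spec$n_samples < 2L)
    stop("need at least 2 genes and 2 samples")
  if (class_fraction <= 0 || class_fraction >= 1)
    stop("`class_fraction` must lie strictly between 0 and 1")
  if (noise_eps < 0 || noise_eps > 0.5)
    stop("`noise_eps` must lie in [0, 0.5]")
  units <- c(spec$planted_pairs, spec$planted_triplets)
  sizes <- c(rep(2L, length(spec$planted_pairs)),
             rep(3L, length(spec$planted_triplets)))
  for (u in seq_along(units)) {
    if (length(units[[u]]) != sizes[u] || anyDuplicated(units[[u]]))
      stop("planted unit ", u, " must hold distinct gene indices")
    if (any(units[[u]] < 1L | units[[u]] > spec$n_genes))
      stop("planted gene index out of range in unit ", u)
  }
  if (anyDuplicated(unlist(units)))
    stop("planted units must not share genes")
  structure(spec, class = "plant_spec")
}

#' Generate a synthetic expression dataset with planted ordering signals
#'
#' Draws an i.i.d. log-normal background matrix and then, for every planted
#' pair and sample, reorders (by swapping) the two background draws so that
#' the within-sample ordering inverts between the classes at noise rate
#' `noise_eps`; planted triplets enforce one full ordering per class the
#' same way. Gene `g<index>` / sample `s<index>` identifiers are attached.
#'
#' @param spec A [plant_spec].
#' @return List with `expr` (an [expr_matrix]), `labels` (a [class_labels]
#'   with classes `"C1"`, `"C2"`), and `truth` (the planted units, noise
#'   rate and seed, suitable for JSON export).
#' @examples
#' sim <- simulate_rxa_data(plant_spec(n_genes = 50, n_samples = 40,
#'                                     planted_pairs = list(c(1, 2)),
#'                                     noise_eps = 0, seed = 1))
#' tsp_score(sim$expr, sim$labels, 1, 2)$delta  # 1: perfect inversion
#' @export
simulate_rxa_data <- function(spec = plant_spec()) {
  p <- spec$n_genes
  m <- spec$n_samples
  m1 <- as.integer(round(spec$class_fraction * m))
  if (m1 < 1L || m1 >= m)
    stop("class sizes must both be positive; adjust `class_fraction`")
  idx <- rep(c(1L, 2L), c(m1, m - m1))
  with_seed(spec$seed, {
    x <- matrix(stats::rlnorm(p * m, spec$background_meanlog,
                              spec$background_sdlog), p, m)
    for (pair in spec$planted_pairs) {
      flip <- stats::runif(m) < spec$noise_eps
      lo <- pmin(x[pair[1L], ], x[pair[2L], ])
      hi <- pmax(x[pair[1L], ], x[pair[2L], ])
      # class 1 wants x_i < x_j, class 2 the opposite; noise flips per sample
      want_lt <- (idx == 1L) != flip
      x[pair[1L], ] <- ifelse(want_lt, lo, hi)
      x[pair[2L], ] <- ifelse(want_lt, hi, lo)
    }
    for (tri in spec$planted_triplets) {
      for (s in seq_len(m)) {
        vals <- sort(x[tri, s])
        if (stats::runif(1L) < spec$noise_eps) {
          x[tri, s] <- vals[sample.int(3L)]
        } else if (idx[s] == 1L) {
          x[tri, s] <- vals            # x_i < x_j < x_l
        } else {
          x[tri, s] <- rev(vals)       # x_i > x_j > x_l
        }
      }
    }
  })
  expr <- expr_matrix(x, paste0("g", seq_len(p)), paste0("s", seq_len(m)))
  labels <- class_labels(c("C1", "C2")[idx], class_order = c("C1", "C2"))
  truth <- list(
    planted_pairs = spec$planted_pairs,
    planted_triplets = spec$planted_triplets,
    planted_pair_ids = lapply(spec$planted_pairs,
                              function(u) paste0("g", u)),
    planted_triplet_ids = lapply(spec$planted_triplets,
                                 function(u) paste0("g", u)),
    noise_eps = spec$noise_eps,
    class_sizes = c(C1 = m1, C2 = m - m1),
    seed = spec$seed)
  list(expr = expr, labels = labels, truth = truth)
}

#' Population delta score of a planted pair
#'
#' Closed form for the expected pair score of a planted inversion pair under
#' per-sample flip probability `eps`: the ordering holds with probability
#' `1 - eps` in class 1 and `eps` in class 2, so the population score is
#' `(1 - eps) - eps = 1 - 2 * eps`. Used as the consistency oracle for the
#' generator.
#'
#' @param eps Noise rate in `[0, 0.5]`.
#' @return `1 - 2 * eps`.
#' @export
expected_pair_delta <- function(eps) {
  if (any(eps < 0 | eps > 0.5)) stop("`eps` must lie in [0, 0.5]")
  1 - 2 * eps
}
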