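# The EvoTSP engine: a genetic algorithm over ensembles of signed, weighted
# gene-pair comparison rules. An individual is a set of k pairs; each pair
# casts a weighted vote for the first class when its signed ordering
# relation holds in a sample. Fitness is training accuracy minus a
# complexity penalty, selection is linear-ranking with elitism, and the
# variation operators act directly on the pair list.
#
# Internally an individual is a flat list of parallel vectors
#   i, j    gene row indices (i != j elementwise)
#   sign    +1L: "x_i < x_j votes C1";  -1L: "x_i > x_j votes C1"
#   w       positive vote weight, always an exact power of two
# plus `fitness` (NA when the cache is stale). Equality of two expression
# values never satisfies a strict relation, so a tied pair votes C2; this is
# the same convention as the indicator used in the pair score.

#' Evolution hyper-parameters
#'
#' Collects all tunable parameters of [fit_evotsp()] with their defaults:
#' a population of 100 individuals, complexity weight `alpha = 0.005`,
#' per-individual crossover and mutation probabilities of 0.5, probability
#' 0.9 of the pair-exchange crossover variant (0.1 for injection from the
#' best individual found so far), termination after 1000 stall generations
#' or 10000 generations total, and initial ensemble sizes drawn uniformly
#' from 1..5.
#'
#' @param population_size Number of individuals (default 100).
#' @param alpha Relative weight of the complexity penalty in the fitness
#'   (default 0.005). `alpha = 0` reduces fitness to training accuracy.
#' @param p_crossover Per-individual probability of crossover (default 0.5).
#' @param p_mutation Per-individual probability of mutation (default 0.5).
#' @param p_exchange_variant Probability that a crossover is the symmetric
#'   pair exchange rather than injection from the best-so-far (default 0.9).
#' @param stall_generations Stop after this many generations without
#'   improvement of the best fitness (default 1000).
#' @param max_generations Hard cap on generations (default 10000).
#' @param init_k_max Largest initial ensemble size (default 5).
#' @param dipole_retry_limit Attempts at drawing an effective pair for one
#'   dipole before giving up (default 1000).
#' @param seed Integer seed making the whole run reproducible.
#' @return A list of class `evo_config`.
#' @export
evo_config <- function(population_size = 100L, alpha = 0.005,
                       p_crossover = 0.5, p_mutation = 0.5,
                       p_exchange_variant = 0.9,
                       stall_generations = 1000L, max_generations = 10000L,
                       init_k_max = 5L, dipole_retry_limit = 1000L,
                       seed = 1L) {
  cfg <- list(population_size = as.integer(population_size),
              alpha = alpha, p_crossover = p_crossover,
              p_mutation = p_mutation,
              p_exchange_variant = p_exchange_variant,
              stall_generations = as.integer(stall_generations),
              max_generations = as.integer(max_generations),
              init_k_max = as.integer(init_k_max),
              dipole_retry_limit = as.integer(dipole_retry_limit),
              seed = as.integer(seed))
  probs <- c(cfg$p_crossover, cfg$p_mutation, cfg$p_exchange_variant)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$alpha < 0) stop("`alpha` must be non-negative")
  if (cfg$population_size < 2L) stop("population size must be at least 2")
  if (cfg$stall_generations < 1L || cfg$max_generations < 1L ||
      cfg$init_k_max < 1L || cfg$dipole_retry_limit < 1L)
    stop("limits must be positive")
  structure(cfg, class = "evo_config")
}

new_individual <- function(i, j, sign, w) {
  list(i = as.integer(i), j = as.integer(j), sign = as.integer(sign),
       w = as.numeric(w), fitness = NA_real_)
}

ind_k <- function(ind) length(ind$i)
ind_u <- function(ind) length(unique(c(ind$i, ind$j)))

#' Draw one effective gene pair from a mixed dipole
#'
#' A mixed dipole is a pair of training samples from opposite classes. Two
#' distinct genes are drawn uniformly at random until their ordering relation
#' differs between the two samples (strictly in the first-class sample); the
#' relation observed in the first-class sample fixes the pair's vote sign, so
#' a single-pair classifier built from the result always separates the two
#' dipole samples. Initial weight is 1.
#'
#' Consumes the current RNG stream.
#'
#' @inheritParams pair_probabilities
#' @param retry_limit Attempts before giving up (some inputs, e.g. matrices
#'   constant within every sample, admit no effective pair).
#' @return A one-pair individual component: list with `i`, `j`, `sign`, `w`.
#' @export
dipole_pair <- function(expr, labels, retry_limit = 1000L) {
  idx <- label_index(labels)
  q <- safe_sample(which(idx == 1L), 1L)
  w_ <- safe_sample(which(idx == 2L), 1L)
  x <- unclass(expr)
  p <- nrow(x)
  for (attempt in seq_len(retry_limit)) {
    g <- sample.int(p, 2L)
    xi_q <- x[g[1L], q]; xj_q <- x[g[2L], q]
    xi_w <- x[g[1L], w_]; xj_w <- x[g[2L], w_]
    if (xi_q > xj_q && xi_w <= xj_w)
      return(list(i = g[1L], j = g[2L], sign = -1L, w = 1))
    if (xi_q < xj_q && xi_w >= xj_w)
      return(list(i = g[1L], j = g[2L], sign = +1L, w = 1))
  }
  stop(sprintf(
    "no effective pair found for dipole (sample %d [%s], sample %d [%s]) in %d draws",
    q, labels$class_order[1L], w_, labels$class_order[2L], retry_limit))
}

# draw n elements from the set x (never "1:x"), sidestepping sample()'s
# length-1 surprise
safe_sample <- function(x, n) {
  if (length(x) == 1L) return(rep_len(x, n))
  x[sample.int(length(x), n)]
}

#' Initial population of dipole-seeded individuals
#'
#' Every individual receives `k ~ uniform{1..init_k_max}` pairs, each created
#' with the mixed-dipole strategy, all with weight 1. Seeding from dipoles
#' (rather than fully random pairs) avoids individuals that vote for a single
#' class on the whole training set.
#'
#' Consumes the current RNG stream; [fit_evotsp()] seeds it from the config.
#'
#' @inheritParams pair_probabilities
#' @param config An [evo_config].
#' @return List of `population_size` individuals.
#' @export
init_population <- function(expr, labels, config = evo_config()) {
  lapply(seq_len(config$population_size), function(n) {
    k <- sample.int(config$init_k_max, 1L)
    parts <- lapply(seq_len(k), function(p_)
      dipole_pair(expr, labels, config$dipole_retry_limit))
    new_individual(vapply(parts, `[[`, integer(1L), "i"),
                   vapply(parts, `[[`, integer(1L), "j"),
                   vapply(parts, `[[`, integer(1L), "sign"),
                   vapply(parts, `[[`, numeric(1L), "w"))
  })
}

# weighted-vote classification of an individual on raw matrix columns;
# returns integer class index per sample. Ties in the weighted sums fall to
# `tiebreak` (the majority training class; C1 when classes are balanced).
classify_individual <- function(ind, x, tiebreak = 1L) {
  xi <- x[ind$i, , drop = FALSE]
  xj <- x[ind$j, , drop = FALSE]
  sat <- xi < xj
  neg <- ind$sign == -1L
  if (any(neg)) sat[neg, ] <- xi[neg, , drop = FALSE] > xj[neg, , drop = FALSE]
  v1 <- as.vector(crossprod(ind$w, sat))
  total <- sum(ind$w)
  pred <- rep.int(2L, ncol(x))
  pred[2 * v1 > total] <- 1L
  pred[2 * v1 == total] <- tiebreak
  pred
}

#' Classify samples with a single weighted-pair ensemble
#'
#' Each pair adds its weight to the first class when its signed relation
#' holds in the sample (equality never satisfies a strict relation, so a tied
#' pair votes for the second class); the heavier side wins. An exact tie of
#' the weighted sums falls to the majority training class, then to the first
#' class.
#'
#' @param ind An individual as produced by [init_population()] or
#'   [fit_evotsp()]`$individual`.
#' @inheritParams pair_probabilities
#' @return Character vector of predicted labels, named by sample.
#' @export
classify <- function(ind, expr, labels) {
  idx <- label_index(labels)
  tiebreak <- majority_class(idx)
  pred <- classify_individual(ind, unclass(expr), tiebreak)
  stats::setNames(labels$class_order[pred], colnames(expr))
}

majority_class <- function(idx) {
  if (sum(idx == 2L) > sum(idx == 1L)) 2L else 1L
}

#' Fitness of an individual
#'
#' Training accuracy penalised for complexity:
#' `fitness = Q - alpha * (2k + u)` where `Q` is the fraction of training
#' samples reclassified correctly, `k` the number of pairs and `u` the number
#' of unique genes across the pairs. Unique genes are counted on top of the
#' per-pair term, so compact ensembles sharing genes (triplet-like relations)
#' are penalised less than gene-disjoint ones of equal size.
#'
#' @inheritParams classify
#' @param alpha Non-negative complexity weight.
#' @return The fitness value (at most 1).
#' @export
fitness <- function(ind, expr, labels, alpha = 0.005) {
  idx <- label_index(labels)
  evaluate_individual(ind, unclass(expr), idx, majority_class(idx), alpha)
}

evaluate_individual <- function(ind, x, idx, tiebreak, alpha) {
  q <- mean(classify_individual(ind, x, tiebreak) == idx)
  q - alpha * (2 * ind_k(ind) + ind_u(ind))
}

#' Crossover of two individuals
#'
#' With probability `p_exchange` a uniformly chosen pair of `a` is swapped
#' with a uniformly chosen pair of `b` (both offspring keep their ensemble
#' sizes); otherwise a uniformly chosen pair of the best individual found so
#' far overwrites a uniformly chosen pair of `a` and `b` is left untouched.
#' Fitness caches of modified individuals are invalidated.
#'
#' Consumes the current RNG stream.
#'
#' @param a,b Individuals (non-empty).
#' @param best_so_far The best individual found so far.
#' @param p_exchange Probability of the symmetric exchange variant.
#' @return List with modified individuals `a` and `b`.
#' @export
crossover <- function(a, b, best_so_far, p_exchange = 0.9) {
  if (stats::runif(1L) < p_exchange) {
    pa <- sample.int(ind_k(a), 1L)
    pb <- sample.int(ind_k(b), 1L)
    tmp <- extract_pair(a, pa)
    a <- put_pair(a, pa, extract_pair(b, pb))
    b <- put_pair(b, pb, tmp)
  } else {
    pe <- sample.int(ind_k(best_so_far), 1L)
    pa <- sample.int(ind_k(a), 1L)
    a <- put_pair(a, pa, extract_pair(best_so_far, pe))
  }
  list(a = a, b = b)
}

extract_pair <- function(ind, at)
  list(i = ind$i[at], j = ind$j[at], sign = ind$sign[at], w = ind$w[at])

put_pair <- function(ind, at, pair) {
  ind$i[at] <- pair$i
  ind$j[at] <- pair$j
  ind$sign[at] <- pair$sign
  ind$w[at] <- pair$w
  ind$fitness <- NA_real_
  ind
}

#' Mutate an individual
#'
#' One of six variants, drawn uniformly: (1) append a new dipole-seeded
#' pair; (2) remove a random pair (redrawn as another variant when only one
#' pair remains, so an individual never empties); (3) replace a random pair
#' by a new dipole-seeded pair; (4) exchange one gene of a random pair for a
#' uniform random gene different from its partner; (5) multiply or divide
#' the weight of a random pair by 2 (equal chance); (6) switch the relation
#' sign of a random pair. The fitness cache is invalidated.
#'
#' Consumes the current RNG stream.
#'
#' @param ind Individual to mutate (non-empty).
#' @inheritParams pair_probabilities
#' @param retry_limit Dipole retry limit for variants (1) and (3).
#' @return The mutated individual.
#' @export
mutate <- function(ind, expr, labels, retry_limit = 1000L) {
  k <- ind_k(ind)
  repeat {
    variant <- sample.int(6L, 1L)
    if (variant != 2L || k > 1L) break
  }
  if (variant == 1L) {                      # add a dipole pair
    np <- dipole_pair(expr, labels, retry_limit)
    ind$i <- c(ind$i, np$i); ind$j <- c(ind$j, np$j)
    ind$sign <- c(ind$sign, np$sign); ind$w <- c(ind$w, np$w)
  } else if (variant == 2L) {               # remove a random pair
    at <- sample.int(k, 1L)
    ind$i <- ind$i[-at]; ind$j <- ind$j[-at]
    ind$sign <- ind$sign[-at]; ind$w <- ind$w[-at]
  } else if (variant == 3L) {               # replace by a dipole pair
    at <- sample.int(k, 1L)
    np <- dipole_pair(expr, labels, retry_limit)
    ind$i[at] <- np$i; ind$j[at] <- np$j
    ind$sign[at] <- np$sign; ind$w[at] <- np$w
  } else if (variant == 4L) {               # exchange one gene
    at <- sample.int(k, 1L)
    side <- sample.int(2L, 1L)
    partner <- if (side == 1L) ind$j[at] else ind$i[at]
    repeat {
      g <- sample.int(nrow(expr), 1L)
      if (g != partner) break
    }
    if (side == 1L) ind$i[at] <- g else ind$j[at] <- g
  } else if (variant == 5L) {               # halve or double the weight
    at <- sample.int(k, 1L)
    ind$w[at] <- ind$w[at] * if (stats::runif(1L) < 0.5) 2 else 0.5
  } else {                                  # switch the relation sign
    at <- sample.int(k, 1L)
    ind$sign[at] <- -ind$sign[at]
  }
  ind$fitness <- NA_real_
  ind
}

# deterministic worst-to-best ranking permutation: fitness ascending, then
# larger ensembles first (fewer pairs rank better), then reverse
# lexicographic pair-id key (lexicographically smaller keys rank better)
rank_population <- function(population, fitnesses) {
  k <- vapply(population, ind_k, integer(1L))
  key <- vapply(population, function(ind)
    paste(ind$i, ind$j, ind$sign, ind$w, collapse = ";"), character(1L))
  order(fitnesses, -k, -xtfrm(key))
}

#' Linear-ranking selection with elitism
#'
#' Individuals are ranked worst (t = 1) to best (t = n); a rank-t individual
#' is drawn with probability `t / (n(n+1)/2)`. `n - 1` slots are filled by
#' sampling with replacement and the first slot receives an unmodified copy
#' of the best individual (the elite, exempt from variation in the
#' generation that copies it). Fitness ties rank by fewer pairs, then by a
#' lexicographic key over the pair list, so selection is deterministic given
#' the RNG stream.
#'
#' @param population List of individuals.
#' @param fitnesses Numeric vector of their fitnesses.
#' @return List with `population` (same size, elite at position 1) and
#'   `elite` (index of the elite in the input).
#' @export
select_next_generation <- function(population, fitnesses) {
  n <- length(population)
  ord <- rank_population(population, fitnesses)     # worst ... best
  prob <- seq_len(n) / (n * (n + 1) / 2)
  picks <- ord[sample.int(n, n - 1L, replace = TRUE, prob = prob)]
  best <- ord[n]
  list(population = c(population[best], population[picks]), elite = best)
}

#' Evolve a weighted top-scoring-pair classifier
#'
#' Runs the full genetic algorithm: dipole-seeded initialisation, fitness
#' evaluation, linear-ranking selection with elitism, pairwise crossover and
#' per-individual mutation, until the best fitness stalls for
#' `stall_generations` generations or `max_generations` is reached. The
#' best individual ever seen is returned as the model.
#'
#' @inheritParams pair_probabilities
#' @param config An [evo_config]; its `seed` makes the run reproducible.
#' @return An object of class `evotsp_model`: list with `individual` (the
#'   best pair ensemble), `pairs` (a readable data frame of the ensemble),
#'   `class_order`, `alpha`, `seed`, `training` (accuracy, fitness, k, u,
#'   generations run) and `history` (per-generation best/mean fitness and
#'   best ensemble shape).
#' @examples
#' sim <- simulate_rxa_data(plant_spec(n_genes = 40, n_samples = 60,
#'                                     planted_pairs = list(c(1, 2)),
#'                                     noise_eps = 0, seed = 3))
#' cfg <- evo_config(stall_generations = 30, max_generations = 200, seed = 3)
#' model <- fit_evotsp(sim$expr, sim$labels, cfg)
#' model$pairs
#' @export
fit_evotsp <- function(expr, labels, config = evo_config()) {
  x <- unclass(expr)
  idx <- label_index(labels)
  tiebreak <- majority_class(idx)
  alpha <- config$alpha
  with_seed(config$seed, {
    population <- init_population(expr, labels, config)
    population <- lapply(population, function(ind) {
      ind$fitness <- evaluate_individual(ind, x, idx, tiebreak, alpha)
      ind
    })
    fitnesses <- vapply(population, `[[`, numeric(1L), "fitness")
    best_at <- rank_population(population, fitnesses)[length(population)]
    best_ever <- population[[best_at]]
    stall <- 0L
    hist_best <- numeric(0L)
    hist_mean <- numeric(0L)
    hist_k <- integer(0L)
    hist_u <- integer(0L)
    gen <- 0L
    while (gen < config$max_generations && stall < config$stall_generations) {
      gen <- gen + 1L
      sel <- select_next_generation(population, fitnesses)
      population <- sel$population
      n <- length(population)
      body <- 2:n                           # slot 1 holds the exempt elite
      # crossover: affected individuals paired uniformly; odd one skips
      hit <- body[stats::runif(n - 1L) < config$p_crossover]
      if (length(hit) >= 2L) {
        hit <- safe_sample(hit, length(hit))
        for (h in seq_len(length(hit) %/% 2L)) {
          ia <- hit[2L * h - 1L]
          ib <- hit[2L * h]
          res <- crossover(population[[ia]], population[[ib]], best_ever,
                           config$p_exchange_variant)
          population[[ia]] <- res$a
          population[[ib]] <- res$b
        }
      }
      # mutation: independent coin per individual
      mut <- body[stats::runif(n - 1L) < config$p_mutation]
      for (im in mut)
        population[[im]] <- mutate(population[[im]], expr, labels,
                                   config$dipole_retry_limit)
      population <- lapply(population, function(ind) {
        if (is.na(ind$fitness))
          ind$fitness <- evaluate_individual(ind, x, idx, tiebreak, alpha)
        ind
      })
      fitnesses <- vapply(population, `[[`, numeric(1L), "fitness")
      gen_best_at <- rank_population(population, fitnesses)[n]
      if (fitnesses[gen_best_at] > best_ever$fitness) {
        best_ever <- population[[gen_best_at]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      hist_best <- c(hist_best, best_ever$fitness)
      hist_mean <- c(hist_mean, mean(fitnesses))
      hist_k <- c(hist_k, ind_k(best_ever))
      hist_u <- c(hist_u, ind_u(best_ever))
    }
  })
  q <- mean(classify_individual(best_ever, x, tiebreak) == idx)
  structure(list(
    individual = best_ever,
    pairs = data.frame(
      gene_i = rownames(expr)[best_ever$i],
      gene_j = rownames(expr)[best_ever$j],
      sign = best_ever$sign,
      weight = best_ever$w,
      stringsAsFactors = FALSE),
    class_order = labels$class_order,
    alpha = alpha,
    seed = config$seed,
    training = list(accuracy = q, fitness = best_ever$fitness,
                    k = ind_k(best_ever), u = ind_u(best_ever),
                    generations = gen, tiebreak_class = tiebreak),
    history = data.frame(generation = seq_along(hist_best),
                         best_fitness = hist_best, mean_fitness = hist_mean,
                         best_k = hist_k, best_u = hist_u)),
    class = "evotsp_model")
}

#' @export
print.evotsp_model <- function(x, ...) {
  cat(sprintf(
    "EvoTSP model: k = %d pair(s), %d unique gene(s), fitness = %.4f\n",
    x$training$k, x$training$u, x$training$fitness))
  rel <- ifelse(x$pairs$sign == 1L, "<", ">")
  for (r in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s %s %s  votes '%s'  (weight %g)\n",
                x$pairs$gene_i[r], rel[r], x$pairs$gene_j[r],
                x$class_order[1L], x$pairs$weight[r]))
  cat(sprintf("  training accuracy %.3f over %d generation(s)\n",
              x$training$accuracy, x$training$generations))
  invisible(x)
}

#' @rdname predict-models
#' @export
predict.evotsp_model <- function(object, expr, ...) {
  ind <- object$individual
  ind$i <- model_rows(expr, object$pairs$gene_i)
  ind$j <- model_rows(expr, object$pairs$gene_j)
  pred <- classify_individual(ind, unclass(expr),
                              object$training$tiebreak_class)
  stats::setNames(object$class_order[pred], colnames(expr))
}

#' @export
model_size.evotsp_model <- function(object) object$training$u
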