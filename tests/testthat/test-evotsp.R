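test_that("dipole pairs always separate the two samples that seeded them", {
  d <- random_dataset(12, 20, seed = 5)
  set.seed(123)
  for (draw in 1:300) {
    pr <- dipole_pair(d$expr, d$labels)
    ind <- list(i = pr$i, j = pr$j, sign = pr$sign, w = pr$w)
    pred <- classify(ind, d$expr, d$labels)
    # the relation was strict in some C1 sample and failed in some C2 sample,
    # so a single-pair individual can never be constant across classes
    expect_true(d$labels$class_order[1] %in% pred[d$labels$labels == "C1"])
    expect_true(d$labels$class_order[2] %in% pred[d$labels$labels == "C2"])
    expect_true(pr$i != pr$j && pr$w == 1 && pr$sign %in% c(-1L, 1L))
  }
})

test_that("a matrix with no effective pair exhausts the dipole retry limit", {
  flat <- expr_matrix(matrix(rep(c(1, 2, 3), each = 4), 3, 4, byrow = TRUE),
                      paste0("g", 1:3), paste0("s", 1:4))
  y <- class_labels(c("A", "A", "B", "B"))
  set.seed(1)
  expect_error(dipole_pair(flat, y, retry_limit = 50), "no effective pair")
})

test_that("initial population matches the configured shape exactly", {
  d <- random_dataset(20, 24, seed = 6)
  cfg <- evo_config(population_size = 50, seed = 10)
  set.seed(cfg$seed)
  pop <- init_population(d$expr, d$labels, cfg)
  expect_length(pop, 50L)
  ks <- vapply(pop, function(ind) length(ind$i), integer(1))
  expect_true(all(ks >= 1L & ks <= 5L))
  expect_true(all(unlist(lapply(pop, `[[`, "w")) == 1))
  us <- vapply(pop, function(ind) length(unique(c(ind$i, ind$j))), integer(1))
  expect_true(all(us >= 2L & us <= 2L * ks))
  set.seed(cfg$seed)
  expect_identical(init_population(d$expr, d$labels, cfg), pop)
})

test_that("initial ensemble sizes are uniform on 1..5", {
  d <- random_dataset(15, 16, seed = 7)
  cfg <- evo_config(population_size = 10000, seed = 11)
  set.seed(cfg$seed)
  pop <- init_population(d$expr, d$labels, cfg)
  ks <- vapply(pop, function(ind) length(ind$i), integer(1))
  counts <- tabulate(ks, 5L)
  expect_gt(stats::chisq.test(counts, p = rep(0.2, 5))$p.value, 0.01)
})

test_that("weighted voting follows the stated decision rules", {
  x <- expr_matrix(rbind(g1 = c(0.5, 2), g2 = c(1.0, 1)),
                   c("g1", "g2"), c("s1", "s2"))
  y <- class_labels(c("A", "B"))
  one <- list(i = 1L, j = 2L, sign = 1L, w = 1)
  expect_identical(unname(classify(one, x, y)), c("A", "B"))

  # weights 4 (voting C1) vs 1 + 1 (voting C2) -> C1 wins
  x3 <- expr_matrix(cbind(s1 = c(1, 2, 5, 4, 7, 6), s2 = c(2, 1, 4, 5, 6, 7)),
                    paste0("g", 1:6), c("s1", "s2"))
  heavy <- list(i = c(1L, 3L), j = c(2L, 4L), sign = c(1L, 1L), w = c(4, 1))
  heavy$i <- c(heavy$i, 5L); heavy$j <- c(heavy$j, 6L)
  heavy$sign <- c(heavy$sign, 1L); heavy$w <- c(4, 1, 1)
  expect_identical(evotsp:::classify_individual(heavy, unclass(x3), 2L)[1L], 1L)
  # with equal weights the same pairs vote 1 vs 2 -> majority C2
  equalw <- heavy
  equalw$w <- c(1, 1, 1)
  expect_identical(evotsp:::classify_individual(equalw, unclass(x3), 1L)[1L], 2L)
})

test_that("equal-weight voting reproduces an independent majority count", {
  set.seed(31)
  for (case in 1:50) {
    d <- random_dataset(10, 15, seed = 3000 + case)
    k <- sample(c(1L, 3L, 5L), 1)
    ij <- replicate(k, sample.int(10, 2))
    ind <- list(i = ij[1, ], j = ij[2, ], sign = sample(c(-1L, 1L), k, TRUE),
                w = rep(1, k))
    got <- evotsp:::classify_individual(ind, unclass(d$expr), 1L)
    x <- unclass(d$expr)
    for (s in seq_len(ncol(x))) {
      v1 <- 0L
      for (q in seq_len(k)) {
        holds <- if (ind$sign[q] == 1L) x[ind$i[q], s] < x[ind$j[q], s]
                 else x[ind$i[q], s] > x[ind$j[q], s]
        if (holds) v1 <- v1 + 1L
      }
      expect_identical(got[s], if (2L * v1 > k) 1L else 2L)
    }
  }
})

test_that("fitness is accuracy minus alpha * (2k + u), cached lazily", {
  sim <- simulate_rxa_data(plant_spec(n_genes = 10, n_samples = 20,
                                      planted_pairs = list(c(1, 2)),
                                      noise_eps = 0, seed = 8))
  perfect <- list(i = 1L, j = 2L, sign = 1L, w = 1)
  expect_equal(fitness(perfect, sim$expr, sim$labels, alpha = 0.005), 0.98)
  expect_equal(fitness(perfect, sim$expr, sim$labels, alpha = 0),
               1)  # alpha = 0 -> plain training accuracy
  # affine in alpha with slope -(2k + u)
  ind <- list(i = c(1L, 3L, 5L), j = c(2L, 4L, 3L), sign = c(1L, 1L, -1L),
              w = c(1, 2, 1))
  u <- length(unique(c(ind$i, ind$j)))
  k <- length(ind$i)
  f0 <- fitness(ind, sim$expr, sim$labels, alpha = 0)
  for (a in c(0.005, 0.02, 0.1))
    expect_equal(fitness(ind, sim$expr, sim$labels, alpha = a),
                 f0 - a * (2 * k + u))
})

test_that("an outvoted extra pair changes fitness by exactly the penalty", {
  sim <- simulate_rxa_data(plant_spec(n_genes = 12, n_samples = 20,
                                      planted_pairs = list(c(1, 2)),
                                      noise_eps = 0, seed = 9))
  alpha <- 0.005
  base <- list(i = 1L, j = 2L, sign = 1L, w = 4)
  ext <- list(i = c(1L, 5L), j = c(2L, 6L), sign = c(1L, -1L), w = c(4, 1))
  # weight 4 vs 1: predictions cannot change; u grows by 2, k by 1
  expect_equal(fitness(base, sim$expr, sim$labels, alpha) -
                 fitness(ext, sim$expr, sim$labels, alpha),
               alpha * (2 + 2))
})

test_that("crossover variants preserve and transfer pairs as specified", {
  pair_key <- function(ind) sort(paste(ind$i, ind$j, ind$sign, ind$w))
  a <- list(i = c(1L, 3L), j = c(2L, 4L), sign = c(1L, -1L), w = c(1, 2),
            fitness = 0.5)
  b <- list(i = c(5L, 7L, 9L), j = c(6L, 8L, 10L), sign = c(1L, 1L, -1L),
            w = c(1, 4, 1), fitness = 0.6)
  best <- list(i = 11L, j = 12L, sign = 1L, w = 8, fitness = 0.9)
  set.seed(77)
  for (trial in 1:20) {
    res <- crossover(a, b, best, p_exchange = 1)   # force the swap variant
    expect_length(res$a$i, 2L)
    expect_length(res$b$i, 3L)
    expect_identical(sort(c(pair_key(res$a), pair_key(res$b))),
                     sort(c(pair_key(a), pair_key(b))))  # multiset conserved
    expect_true(is.na(res$a$fitness) && is.na(res$b$fitness))
  }
  for (trial in 1:20) {
    res <- crossover(a, b, best, p_exchange = 0)   # force injection variant
    expect_identical(res$b, b)                     # b untouched
    expect_true("11 12 1 8" %in% pair_key(res$a))
  }
})

test_that("mutation applies exactly one of the six variants and keeps k >= 1", {
  d <- random_dataset(15, 20, seed = 12)
  start <- list(i = c(1L, 4L), j = c(2L, 5L), sign = c(1L, 1L), w = c(1, 2),
                fitness = 0.7)
  seen <- character(0)
  set.seed(13)
  for (trial in 1:400) {
    m <- mutate(start, d$expr, d$labels)
    k0 <- length(start$i)
    k1 <- length(m$i)
    expect_true(k1 >= 1L)
    expect_true(all(m$i != m$j))
    expect_true(is.na(m$fitness))
    if (k1 == k0 + 1L) {
      seen <- c(seen, "add")
    } else if (k1 == k0 - 1L) {
      seen <- c(seen, "remove")
    } else if (!identical(m$w, start$w)) {
      changed <- which(m$w != start$w)
      expect_length(changed, 1L)
      # either the weight variant (x2 or /2) or a replacement resetting to 1
      expect_true((m$w[changed] / start$w[changed]) %in% c(0.5, 2) ||
                    m$w[changed] == 1)
      seen <- c(seen, if (m$w[changed] == 1 &&
                          !identical(m$i, start$i)) "replace" else "weight")
    } else if (!identical(m$sign, start$sign) &&
               identical(m$i, start$i) && identical(m$j, start$j)) {
      expect_identical(sum(m$sign != start$sign), 1L)
      seen <- c(seen, "sign")
    } else {
      # gene exchange (1 gene) or pair replacement (up to 2 genes); either
      # variant may redraw the very same genes, a permitted no-op
      ndiff <- sum(m$i != start$i) + sum(m$j != start$j)
      expect_true(ndiff %in% 0:2)
      seen <- c(seen, if (ndiff == 1L) "exchange" else "replace")
    }
  }
  expect_setequal(unique(seen),
                  c("add", "remove", "replace", "exchange", "weight", "sign"))
})

test_that("a single-pair individual is never emptied and sign flips invert", {
  d <- random_dataset(10, 16, seed = 14)
  solo <- list(i = 3L, j = 7L, sign = 1L, w = 2, fitness = 0.5)
  set.seed(15)
  flips <- 0L
  for (trial in 1:300) {
    m <- mutate(solo, d$expr, d$labels)
    expect_gte(length(m$i), 1L)
    if (identical(m[c("i", "j", "w")], solo[c("i", "j", "w")]) &&
        m$sign == -solo$sign) {
      flips <- flips + 1L
      mm <- m
      repeat {   # a second sign switch restores the original pair exactly
        mm2 <- mutate(mm, d$expr, d$labels)
        if (identical(mm2[c("i", "j", "w")], mm[c("i", "j", "w")]) &&
            mm2$sign == -mm$sign) break
      }
      expect_identical(mm2[c("i", "j", "sign", "w")],
                       solo[c("i", "j", "sign", "w")])
    }
  }
  expect_gt(flips, 10L)
})

test_that("the add variant can grow an ensemble beyond the initial cap", {
  d <- random_dataset(10, 16, seed = 16)
  five <- list(i = c(1L, 3L, 5L, 7L, 9L), j = c(2L, 4L, 6L, 8L, 10L),
               sign = rep(1L, 5), w = rep(1, 5), fitness = NA_real_)
  set.seed(17)
  grew <- FALSE
  for (trial in 1:200) {
    m <- mutate(five, d$expr, d$labels)
    if (length(m$i) == 6L) { grew <- TRUE; break }
  }
  expect_true(grew)
})

test_that("linear-ranking selection weights ranks as t / (n(n+1)/2)", {
  pop <- lapply(1:4, function(g)
    list(i = g, j = g + 4L, sign = 1L, w = 1, fitness = g / 10))
  fits <- vapply(pop, `[[`, numeric(1), "fitness")
  set.seed(18)
  picked <- integer(0)
  for (rep_ in 1:4000) {
    sel <- select_next_generation(pop, fits)
    expect_length(sel$population, 4L)
    expect_identical(sel$population[[1L]], pop[[4L]])  # elite = best
    picked <- c(picked, vapply(sel$population[2:4], `[[`, integer(1), "i"))
  }
  freq_best <- mean(picked == 4L)
  expect_lt(abs(freq_best - 0.4), 0.02)     # rank-4 probability 4/10
  freq_worst <- mean(picked == 1L)
  expect_lt(abs(freq_worst - 0.1), 0.02)    # rank-1 probability 1/10
})

test_that("evolution improves monotonically, stalls, and is reproducible", {
  sim <- simulate_rxa_data(plant_spec(n_genes = 40, n_samples = 40,
                                      planted_pairs = list(c(3, 4)),
                                      noise_eps = 0, seed = 19))
  cfg <- evo_config(stall_generations = 50, max_generations = 1000,
                    seed = 20)
  model <- fit_evotsp(sim$expr, sim$labels, cfg)
  expect_true(all(diff(model$history$best_fitness) >= 0))
  # a perfect compact solution appears quickly, so the stall rule (not the
  # generation cap) must end the run shortly after the last improvement
  expect_lt(model$training$generations, 1000L)
  last_gain <- max(which(c(TRUE, diff(model$history$best_fitness) > 0)))
  expect_identical(model$training$generations - last_gain, 50L)
  model2 <- fit_evotsp(sim$expr, sim$labels, cfg)
  expect_identical(model$pairs, model2$pairs)
  expect_identical(model$history, model2$history)
})

test_that("the whole pipeline is invariant to monotone per-sample maps", {
  sim <- simulate_rxa_data(plant_spec(n_genes = 30, n_samples = 30,
                                      planted_pairs = list(c(1, 2)),
                                      noise_eps = 0.05, seed = 21))
  warped <- monotone_transform(sim$expr)
  cfg <- evo_config(stall_generations = 40, max_generations = 300, seed = 22)
  m1 <- fit_evotsp(sim$expr, sim$labels, cfg)
  m2 <- fit_evotsp(warped, sim$labels, cfg)
  expect_identical(m1$pairs, m2$pairs)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, sim$expr), predict(m2, warped))
})
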