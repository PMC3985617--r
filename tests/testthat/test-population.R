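test_that("cycle application is a monotone union of conversion patterns", {
  mod <- conversion_model("empirical_pattern", L = 10,
                          patterns = rbind(c(1, 1, rep(0, 8))),
                          weights = 1)
  pop <- population_state(rbind(rep(0L, 10), c(1L, rep(0L, 9))))
  out <- simulate_cycle(pop, mod, seed = 1)
  expect_equal(out$genotypes[1, ], c(1L, 1L, rep(0L, 8)))
  expect_equal(out$genotypes[2, ], c(1L, 1L, rep(0L, 8)))
  expect_equal(out$cycle_index, 1L)

  full <- conversion_model("empirical_count", L = 4,
                           count_probs = c(0, 0, 0, 0, 1))
  out2 <- simulate_cycle(new_population(5, 4), full, seed = 2)
  expect_true(all(out2$genotypes == 1L))
})

test_that("conversion counts never decrease and histograms conserve lineages", {
  mod <- fit_conversion_model(1.5, 0.4, 8)
  withr::with_seed(42, {
    pop <- new_population(400, 8)
    prev <- rowSums(pop$genotypes)
    for (cy in 1:6) {
      pop <- simulate_cycle(pop, mod)
      cur <- rowSums(pop$genotypes)
      expect_true(all(cur >= prev))
      s <- summarize_population(pop)
      expect_equal(sum(s$count_histogram), 400)
      prev <- cur
    }
  })
})

test_that("population summaries match hand-computed values", {
  pop <- population_state(rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L)))
  s <- summarize_population(pop)
  expect_equal(s$mean_conversions, 1)
  expect_equal(unname(s$count_histogram), c(1L, 1L, 1L))
  expect_equal(s$unmodified_fraction, 1 / 3)
  expect_equal(s$fully_converted_fraction, 1 / 3)

  ones <- population_state(matrix(1L, 4, 3))
  expect_equal(summarize_population(ones)$fully_converted_fraction, 1)
})

test_that("bottleneck sampling is identity above n, collapses at 1, and is seed-stable", {
  pop <- population_state(matrix(rbinom(600, 1, 0.4), nrow = 100))
  expect_identical(apply_bottleneck(pop, 100, seed = 1), pop)
  expect_identical(apply_bottleneck(pop, 500, seed = 1), pop)
  one <- apply_bottleneck(pop, 1, seed = 3)
  expect_equal(nrow(one$genotypes), 1L)
  expect_identical(apply_bottleneck(pop, 10, seed = 7),
                   apply_bottleneck(pop, 10, seed = 7))
})

test_that("bottleneck sampling is neutral in expectation (hypergeometric)", {
  withr::with_seed(99, {
    g <- matrix(0L, nrow = 300, ncol = 4)
    counts <- rep(0:4, each = 60)
    for (i in seq_len(300)) if (counts[i] > 0) g[i, seq_len(counts[i])] <- 1L
    pop <- population_state(g)
    pre <- summarize_population(pop)$count_histogram / 300
    acc <- numeric(5)
    for (r in 1:1000) {
      s <- summarize_population(apply_bottleneck(pop, 60))
      acc <- acc + s$count_histogram / 60
    }
    post <- acc / 1000
    # each bin: SE of the mean fraction over 1000 hypergeometric draws
    se <- sqrt(pre * (1 - pre) / 60 / 1000) * sqrt((300 - 60) / (300 - 1))
    expect_true(all(abs(post - pre) < 4 * se + 1e-12))
  })
})

test_that("simulated genotype distribution matches exact enumeration for L = 3", {
  patterns <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1), c(1, 1, 1))
  weights <- c(0.4, 0.3, 0.2, 0.1)
  mod <- conversion_model("empirical_pattern", L = 3, patterns = patterns,
                          weights = weights)
  exact <- exact_pattern_distribution(patterns, weights, n_cycles = 3)
  n <- 20000
  tr <- simulate_trajectory(n, 3, mod, seed = 123)
  sim <- tabulate(genotype_bitmask(tr$final_population$genotypes) + 1L,
                  nbins = 8) / n
  tol <- 4 * sqrt(exact * (1 - exact) / n) + 1e-9
  expect_true(all(abs(sim - exact) < tol))
})

test_that("single-cycle simulation recovers calibrated moments (round trip)", {
  for (case in list(c(2.87, 0.096), c(0.43, 0.72))) {
    mod <- fit_conversion_model(case[1], case[2], 10)
    tr <- simulate_trajectory(10000, 1, mod, seed = 7)
    row <- tr$per_cycle[tr$per_cycle$cycle == 1, ]
    sd_zib <- sqrt((1 - mod$pi) * (10 * mod$p * (1 - mod$p) +
                                     mod$pi * (10 * mod$p)^2))
    expect_lt(abs(row$mean_conversions - case[1]), 3 * sd_zib / sqrt(10000))
    expect_lt(abs(row$unmodified_fraction - case[2]),
              3 * sqrt(case[2] * (1 - case[2]) / 10000))
  }
})

test_that("trajectories start unmodified, are seed-stable, and support bottlenecks", {
  mod <- fit_conversion_model(2, 0.2, 10)
  tr0 <- simulate_trajectory(50, 0, mod, seed = 1)
  expect_equal(tr0$per_cycle$unmodified_fraction, 1)
  expect_equal(nrow(tr0$per_cycle), 1L)

  a <- simulate_trajectory(200, 4, mod, seed = 5)
  b <- simulate_trajectory(200, 4, mod, seed = 5)
  expect_identical(a$per_cycle, b$per_cycle)

  bn <- simulate_trajectory(200, 4, mod, seed = 5, bottleneck = 20)
  expect_equal(unname(bn$per_cycle$n[-1]), rep(20, 4))
})
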