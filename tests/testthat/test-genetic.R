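test_that("rank-weighted selection favors better scores with the right odds", {
  withr::local_seed(2)
  # two candidates: the better one carries weight 2 of 3
  picks <- replicate(10000, select_parent(c(5, 1)))
  phat <- mean(picks == 1L)
  expect_lt(abs(phat - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / 10000))

  # equal objectives: uniform selection
  picks4 <- replicate(10000, select_parent(rep(7, 4)))
  expect_gt(chisq.test(table(factor(picks4, levels = 1:4)))$p.value, 0.01)

  # full rank-weight profile for 5 candidates (weights 5:1)
  objs <- c(10, 8, 6, 4, 2)
  picks5 <- replicate(20000, select_parent(objs))
  freq <- tabulate(picks5, 5) / 20000
  expected <- (5:1) / 15
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_true(all(abs(freq - expected) < 4 * se))
})

test_that("crossover of identical parents is a fixed point", {
  withr::local_seed(15)
  si <- random_set(3, 20)
  w <- build_random_pwm(si, 8L)
  child <- crossover_pwm(w, w)
  expect_equal(child$w, w$w, tolerance = 1e-9)
})

test_that("crossover cut points are uniform over 1..L-1", {
  withr::local_seed(19)
  si <- random_set(3, 20)
  a <- build_random_pwm(si, 6L)
  b <- build_random_pwm(si, 6L)
  detect_cut <- function(child) {
    # columns up to the cut are affine images of parent a's columns
    sims <- vapply(1:6, function(j) cor(child$w[, j], a$w[, j]), numeric(1))
    max(which(sims > 0.999))
  }
  cuts <- replicate(2000, detect_cut(crossover_pwm(a, b)))
  expect_true(all(cuts %in% 1:5))
  expect_gt(chisq.test(table(factor(cuts, levels = 1:5)))$p.value, 0.01)
})

test_that("single-column crossover copies one parent", {
  withr::local_seed(22)
  si <- random_set(2, 10)
  a <- build_random_pwm(si, 1L)
  b <- build_random_pwm(si, 1L)
  child <- crossover_pwm(a, b)
  expect_true(identical(child$w, a$w) || identical(child$w, b$w))
})

test_that("children and mutants stay on the normalization constraints", {
  withr::local_seed(28)
  si <- random_set(3, 15)
  a <- build_random_pwm(si, 5L)
  b <- build_random_pwm(si, 5L)
  for (rep in 1:10) {
    child <- crossover_pwm(a, b)
    nrm <- pwm_norms(child)
    expect_equal(nrm[["r2"]], 5 * 20 * 5, tolerance = 1e-6)
    expect_equal(nrm[["kd"]], -1, tolerance = 1e-6)
    mut <- pwmsa:::mutate_pwm(a, scoring_params(), c(-10, 10))
    nrm <- pwm_norms(mut)
    expect_equal(nrm[["r2"]], 5 * 20 * 5, tolerance = 1e-6)
    expect_equal(nrm[["kd"]], -1, tolerance = 1e-6)
  }
})

test_that("the evolution trace is non-decreasing and ends at the reported best", {
  for (seed in 1:5) {
    set.seed(seed)
    si <- random_set(4, 15)
    res <- evolve_population(si, 15L,
                             cfg = ga_config(population_size = 8,
                                             mutants_per_generation = 4,
                                             stagnation_window = 3))
    expect_true(all(diff(res$trace) >= 0))
    expect_equal(res$objective, res$trace[length(res$trace)])
    expect_gte(res$generations, 3L)
    nrm <- pwm_norms(res$pwm)
    expect_equal(nrm[["r2"]], 5 * 20 * 15, tolerance = 1e-6)
    expect_equal(nrm[["kd"]], -1, tolerance = 1e-6)
  }
})

test_that("evolution is bit-identical under a fixed seed", {
  si <- sequence_set(c(a = "ACDEFGHIKLMNPQRST", b = "ACDEFGHIKLMNPQRSW"))
  cfg <- ga_config(population_size = 6, mutants_per_generation = 3,
                   stagnation_window = 2)
  set.seed(77); r1 <- evolve_population(si, 17L, cfg = cfg)
  set.seed(77); r2 <- evolve_population(si, 17L, cfg = cfg)
  expect_identical(r1$pwm$w, r2$pwm$w)
  expect_identical(r1$trace, r2$trace)
})

test_that("the genetic algorithm makes real progress on a planted motif", {
  withr::local_seed(111)
  improved <- logical(10)
  for (r in seq_along(improved)) {
    si <- planted_motif_set(n = 20, len = 30, noise = 0.1)
    res <- evolve_population(si, 30L,
                             cfg = ga_config(population_size = 12,
                                             mutants_per_generation = 6))
    improved[r] <- res$trace[length(res$trace)] > res$trace[1] + 1e-9
  }
  expect_gte(sum(improved), 8)
})

test_that("the length scan covers the right candidate lengths", {
  withr::local_seed(36)
  # identical lengths, zero span: a single candidate length
  si <- random_set(3, 20)
  res <- find_best_pwm(si, cfg = ga_config(population_size = 6,
                                           mutants_per_generation = 2,
                                           stagnation_window = 2,
                                           length_span = 0, length_step = 1))
  expect_equal(res$by_length$L, 20)
  expect_equal(res$best_length, 20L)

  # mean length 30, 10% span, unit step: lengths 27..33
  si2 <- random_set(4, 30)
  res2 <- find_best_pwm(si2, cfg = ga_config(population_size = 6,
                                             mutants_per_generation = 2,
                                             stagnation_window = 1,
                                             length_step = 1))
  expect_equal(res2$by_length$L, 27:33)
  expect_equal(res2$best_objective, max(res2$by_length$objective))
  expect_equal(res2$best_length,
               res2$by_length$L[which.max(res2$by_length$objective)])
})

test_that("configuration bounds are enforced", {
  expect_error(ga_config(population_size = 3), "population_size")
  expect_error(ga_config(stagnation_window = 0), "stagnation_window")
})
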