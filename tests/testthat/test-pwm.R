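test_that("normalization holds after every transform (R^2 and k_d)", {
  withr::local_seed(42)
  si <- random_set(4, 30)
  for (L in c(1L, 5L, 10L, 37L)) {
    w <- build_random_pwm(si, L, k = 200L)
    nrm <- pwm_norms(w)
    expect_equal(nrm[["r2"]], 5 * 20 * L, tolerance = 1e-6)
    expect_equal(nrm[["kd"]], -1, tolerance = 1e-6)
  }
})

test_that("a PWM already satisfying the constraints is a fixed point", {
  withr::local_seed(1)
  w <- build_random_pwm(random_set(3, 20), 8L)
  w2 <- transform_pwm(w)
  expect_equal(w2$w, w$w, tolerance = 1e-9)
})

test_that("arbitrary matrices are driven onto the constraints", {
  withr::local_seed(5)
  for (rep in 1:5) {
    raw <- raw_pwm(matrix(rnorm(100, sd = 3), nrow = 20))
    out <- transform_pwm(raw, scoring_params(r_l = 5, k_d = -1))
    expect_equal(sum(out$w^2), 5 * 20 * 5, tolerance = 1e-6)
    expect_equal(sum(out$w * outer(out$p1, out$p2)), -1, tolerance = 1e-6)
  }
})

test_that("closed-form normalization agrees with a numeric root finder", {
  withr::local_seed(9)
  params <- scoring_params(r_l = 5, k_d = -1)
  for (rep in 1:10) {
    raw <- raw_pwm(matrix(rnorm(100), nrow = 20))
    got <- transform_pwm(raw, params)
    # independent route: scan the positive scale a, with offset b pinned by
    # the weighted-mean constraint, for a zero of the squared-norm residual
    P <- outer(raw$p1, raw$p2)
    m <- sum(raw$w * P)
    g <- function(a) sum((a * raw$w + (-1 - a * m))^2) - 5 * 20 * 5
    a_num <- uniroot(g, c(1e-8, 1e4), tol = 1e-12)$root
    b_num <- -1 - a_num * m
    expect_equal(got$w, a_num * raw$w + b_num, tolerance = 1e-6)
  }
})

test_that("constant matrices cannot be normalized", {
  flat <- raw_pwm(matrix(1, nrow = 20, ncol = 4))
  expect_error(transform_pwm(flat), "degenerate")
})

test_that("doubling r_l doubles the squared norm", {
  withr::local_seed(11)
  si <- random_set(3, 25)
  w1 <- build_random_pwm(si, 6L, params = scoring_params(r_l = 5))
  w2 <- transform_pwm(w1, scoring_params(r_l = 10))
  expect_equal(sum(w2$w^2), 2 * sum(w1$w^2), tolerance = 1e-6)
})

test_that("count standardization has mean ~0 and unit-order spread", {
  withr::local_seed(23)
  cells <- replicate(200, {
    M <- rmultinom(10, size = 500, prob = rep(1 / 20, 20))
    W <- pwmsa:::standardize_counts(M)
    c(mean(W), sd(W))
  })
  expect_lt(abs(mean(cells[1, ])), 0.05)
  expect_gt(mean(cells[2, ]), 0.5)
  expect_lt(mean(cells[2, ]), 2)
})

test_that("degenerate single-residue input still yields finite PWMs", {
  si <- sequence_set(c(a = "AAAAAAAA", b = "AAAAAAAA"))
  withr::local_seed(3)
  w <- build_random_pwm(si, 4L, k = 50L)
  expect_true(all(is.finite(w$w)))
})

test_that("gapless alignments keep every column in the extracted PWM", {
  withr::local_seed(17)
  ma <- random_msa(alpha = 4, K = 12, gap_prob = 0)
  dec <- pwm_from_msa(ma)
  expect_identical(dec$column_map, 1:12)
  expect_equal(dec$pwm$L, 12L)
})

test_that("columns with fewer than alpha/2 residues are dropped", {
  # column 3 has 1 residue among 4 rows (< 2), column 5 exactly 2 (kept)
  ma <- protein_msa(c(a = "AC-DE", b = "AC-D-", c = "ACAD-", d = "AC--E"))
  dec <- pwm_from_msa(ma)
  expect_identical(dec$column_map, c(1L, 2L, 4L, 5L))
  expect_equal(dec$ma_filtered$rows, c("ACDE", "ACD-", "ACD-", "AC-E"))
})

test_that("an all-gappy alignment is rejected", {
  ma <- protein_msa(c(a = "A---", b = "-C--", c = "--D-", d = "---E"))
  expect_error(pwm_from_msa(ma), "too gappy")
})

test_that("extracted PWM matches a plain-loop recount on a toy alignment", {
  withr::local_seed(31)
  ma <- random_msa(alpha = 5, K = 8, gap_prob = 0.2)
  dec <- pwm_from_msa(ma, scoring_params())

  # independent recount with explicit loops
  cm <- as.matrix(ma)
  keep <- which(colSums(cm != "-") >= 5 / 2)
  Vraw <- matrix(0, 20, length(keep))
  for (jj in seq_along(keep)) {
    for (r in 1:5) {
      ch <- cm[r, keep[jj]]
      if (ch != "-") Vraw[match(ch, AA20), jj] <- Vraw[match(ch, AA20), jj] + 1
    }
  }
  V <- Vraw + 1
  U <- sum(V)
  X <- rowSums(V); Y <- colSums(V)
  W <- matrix(0, 20, length(keep))
  for (i in 1:20) for (jj in seq_along(keep)) {
    p <- X[i] * Y[jj] / U^2
    W[i, jj] <- (V[i, jj] - U * p) / sqrt(U * p * (1 - p))
  }
  # same affine normalization applied to the recount
  p1 <- rowSums(Vraw) / sum(Vraw)
  ref <- transform_pwm(raw_pwm(W, p1 = p1), scoring_params())
  expect_identical(dec$column_map, keep)
  expect_equal(dec$pwm$w, ref$w, tolerance = 1e-9)
})

test_that("identical gapless rows give a positive consensus cell and 19 negative cells", {
  rowstr <- "ACDEFG"
  ma <- protein_msa(setNames(rep(rowstr, 6), paste0("r", 1:6)))
  dec <- pwm_from_msa(ma)
  ch <- strsplit(rowstr, "")[[1]]
  for (j in seq_along(ch)) {
    col <- dec$pwm$w[, j]
    hot <- match(ch[j], AA20)
    expect_gt(col[hot], 0)
    expect_true(all(col[-hot] < 0))
  }
})

test_that("PWM TSV dump/load round-trips", {
  withr::local_seed(2)
  w <- build_random_pwm(random_set(3, 15), 7L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pwm(w, f)
  back <- read_pwm(f)
  expect_equal(back$w, w$w, tolerance = 1e-12)
  expect_equal(back$p1, w$p1, tolerance = 1e-12)
  expect_equal(back$p2, w$p2, tolerance = 1e-12)
})
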