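test_that("shuffling preserves length and composition exactly", {
  withr::local_seed(8)
  si <- random_set(5, 40)
  sh <- shuffle_set(si)
  expect_identical(sh$ids, si$ids)
  for (i in 1:5) {
    expect_identical(sort(strsplit(sh$residues[i], "")[[1]]),
                     sort(strsplit(si$residues[i], "")[[1]]))
  }
  # length-1 sequences are unchanged
  one <- sequence_set(c(a = "A", b = "C"))
  expect_identical(shuffle_set(one)$residues, one$residues)
})

test_that("shuffling is uniform over permutations", {
  withr::local_seed(12)
  si <- sequence_set(c(x = "ACDE"))
  draws <- replicate(10000, shuffle_set(si)$residues)
  tab <- table(draws)
  expect_equal(length(tab), 24L)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("Z is computed from the null sample mean and SD", {
  withr::local_seed(21)
  si <- random_set(4, 20)
  w <- build_random_pwm(si, 20L, k = 200L)
  set.seed(5)
  z <- z_for_pwm(si, w, n_shuffles = 40)
  # recompute the same null with the same stream
  set.seed(5)
  obs <- set_objective(si, w)
  null_vals <- vapply(1:40, function(i) set_objective(shuffle_set(si), w),
                 numeric(1))
  expect_equal(z$observed, obs)
  expect_equal(z$z, (obs - mean(null_vals)) / sd(null_vals))
  expect_equal(z$n_shuffles, 40L)
})

test_that("Z for a PWM is invariant to sequence order", {
  withr::local_seed(14)
  si <- random_set(5, 25)
  w <- build_random_pwm(si, 25L, k = 200L)
  rev_si <- sequence_set(rev(si$residues), ids = rev(si$ids))
  set.seed(9); z1 <- z_for_pwm(si, w, n_shuffles = 30)
  set.seed(9); z2 <- z_for_pwm(rev_si, w, n_shuffles = 30)
  expect_equal(z1$observed, z2$observed)
})

test_that("a PWM trained on near-identical sequences is highly significant", {
  withr::local_seed(101)
  si <- sequence_set(setNames(rep(random_seq(50), 20), paste0("c", 1:20)))
  ma <- protein_msa(setNames(si$residues, si$ids))
  dec <- pwm_from_msa(ma)
  set.seed(11)
  z <- z_for_pwm(si, dec$pwm, n_shuffles = 300)
  expect_gt(z$z, 10)
  expect_true(z$significant)
})

test_that("the gap-run spectrum satisfies its counting identities", {
  ma <- protein_msa(c(a = "A--A-", b = "AAAAA"))
  del <- del_vector(ma)
  expect_equal(del, c(1L, 1L))  # one run of 1, one run of 2
  gs <- gap_statistics(ma)
  expect_equal(gs[["gap_openings"]], 2L)
  expect_equal(gs[["total_gaps"]], 3L)

  expect_equal(gap_statistics(protein_msa(c(a = "ACD", b = "ACD"))),
               c(gap_openings = 0L, total_gaps = 0L))

  withr::local_seed(18)
  for (rep in 1:10) {
    ma <- random_msa(alpha = 4, K = 20, gap_prob = 0.3)
    del <- del_vector(ma)
    expect_equal(sum(seq_along(del) * del),
                 sum(as.matrix(ma) == "-"))
    expect_equal(sum(del),
                 sum(vapply(ma$rows, function(r) {
                   rl <- rle(strsplit(r, "")[[1]] == "-")
                   sum(rl$values)
                 }, numeric(1))))
  }
})

test_that("the alignment weight books PWM cells minus affine gap charges", {
  withr::local_seed(25)
  ma <- random_msa(alpha = 4, K = 10, gap_prob = 0.2)
  pr <- scoring_params(d = 40, e = 1)
  dec <- pwm_from_msa(ma, pr)
  got <- ma_weight(ma, dec, pr)

  # independent recount: loop over filtered cells, then charge gap runs
  cm <- as.matrix(dec$ma_filtered)
  s <- 0
  for (r in 1:4) for (j in seq_len(ncol(cm))) {
    if (cm[r, j] != "-") s <- s + unname(dec$pwm$w[match(cm[r, j], AA20), j])
  }
  charge <- 0
  for (r in 1:4) {
    rl <- rle(strsplit(ma$rows[r], "")[[1]] == "-")
    for (len in rl$lengths[rl$values]) charge <- charge + 40 + (len - 1) * 1
  }
  expect_equal(got, s - charge)
})

test_that("a gapless alignment's weight is the bare cell sum", {
  withr::local_seed(26)
  ma <- random_msa(alpha = 3, K = 8, gap_prob = 0)
  pr <- scoring_params()
  dec <- pwm_from_msa(ma, pr)
  cm <- as.matrix(ma)
  s <- sum(vapply(seq_len(8), function(j) {
    sum(dec$pwm$w[match(cm[, j], AA20), j])
  }, numeric(1)))
  expect_equal(ma_weight(ma, dec, pr), s)
})

test_that("one gap run of length 3 at d=40, e=1 costs exactly 42", {
  ma <- protein_msa(c(a = "ACDEFGH", b = "AC---GH", c = "ACDEFGH",
                      d = "ACDEFGH"))
  pr <- scoring_params(d = 40, e = 1)
  dec <- pwm_from_msa(ma, pr)
  cm <- as.matrix(dec$ma_filtered)
  s <- 0
  for (r in 1:4) for (j in seq_len(ncol(cm))) {
    if (cm[r, j] != "-") s <- s + unname(dec$pwm$w[match(cm[r, j], AA20), j])
  }
  expect_equal(ma_weight(ma, dec, pr), s - 42)
})

test_that("Z for an alignment of identical rows is significant", {
  withr::local_seed(71)
  rowstr <- random_seq(40)
  ma <- protein_msa(setNames(rep(rowstr, 20), paste0("r", 1:20)))
  set.seed(31)
  z <- z_for_msa(ma, n_shuffles = 100)
  expect_gt(z$z, 10)
})

test_that("Z for an alignment is invariant under row reordering", {
  withr::local_seed(83)
  ma <- random_msa(alpha = 6, K = 30, gap_prob = 0.1)
  perm <- sample(6)
  ma2 <- protein_msa(ma$rows[perm], ids = ma$ids[perm])
  set.seed(3); z1 <- z_for_msa(ma, n_shuffles = 30)
  set.seed(3); z2 <- z_for_msa(ma2, n_shuffles = 30)
  expect_equal(z1$observed, z2$observed, tolerance = 1e-9)
})

test_that("degenerate nulls are rejected", {
  expect_error(pwmsa:::new_z_result(1, c(2, 2, 2), 10), "degenerate null")
})
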