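# Monte Carlo significance of alignments.
#
# The null model shuffles residues within each sequence, preserving length
# and composition exactly. The Z-score compares the observed alignment
# weight with the mean and standard deviation of the weight over shuffled
# sets; Z >= 10 is the default significance threshold for protein
# alignments.

new_z_result <- function(observed, null_values, threshold) {
  null_mean <- mean(null_values)
  null_sd <- sd(null_values)
  if (!is.finite(null_sd) || null_sd == 0) {
    stop("degenerate null distribution (zero spread)", call. = FALSE)
  }
  z <- (observed - null_mean) / null_sd
  structure(list(observed = observed, null_mean = null_mean,
                 null_sd = null_sd, z = z,
                 n_shuffles = length(null_values),
                 threshold = threshold, significant = z >= threshold),
            class = "z_result")
}

#' @export
print.z_result <- function(x, ...) {
  cat(sprintf(
    "z_result: observed = %.4f, null = %.4f +/- %.4f (n = %d)\n  Z = %.3f (threshold %.1f): %s\n",
    x$observed, x$null_mean, x$null_sd, x$n_shuffles, x$z, x$threshold,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @export
as.data.frame.z_result <- function(x, ...) {
  data.frame(observed = x$observed, null_mean = x$null_mean,
             null_sd = x$null_sd, z = x$z, n_shuffles = x$n_shuffles,
             threshold = x$threshold, significant = x$significant)
}

#' Shuffle residues within each sequence
#'
#' Independent Fisher-Yates permutation of each sequence; lengths and
#' per-sequence residue composition are preserved exactly.
#'
#' @param si A [sequence_set()].
#' @return A shuffled [sequence_set()] with the same ids.
#' @export
shuffle_set <- function(si) {
  shuffled <- vapply(si$residues, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(sample(chars), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  sequence_set(shuffled, ids = si$ids)
}

#' Monte Carlo Z-score of a sequence set against a PWM
#'
#' The observed weight is the objective [set_objective()] of `si` against
#' `pwm_m`; the null distribution is the same objective over `n_shuffles`
#' residue-shuffled copies of the set. `Z = (observed - null mean) / null
#' standard deviation`.
#'
#' @param si A [sequence_set()].
#' @param pwm_m A normalized `weight_matrix`.
#' @param params A [scoring_params()].
#' @param n_shuffles Number of shuffled null sets (default 300).
#' @param threshold Significance threshold on Z (default 10).
#' @return A `z_result`.
#' @export
z_for_pwm <- function(si, pwm_m, params = scoring_params(),
                      n_shuffles = 300L, threshold = 10) {
  stopifnot(n_shuffles >= 2L)
  observed <- set_objective(si, pwm_m, params)
  null_values <- vapply(seq_len(n_shuffles), function(i) {
    set_objective(shuffle_set(si), pwm_m, params)
  }, numeric(1))
  new_z_result(observed, null_values, threshold)
}

#' Gap-run length spectrum of an alignment
#'
#' Counts maximal gap runs per row of the alignment: `del[i]` is the number
#' of maximal runs of exactly `i` consecutive gap characters (runs touching
#' a row end included).
#'
#' @param ma A [protein_msa()].
#' @return Integer vector indexed by run length (possibly length 0).
#' @export
del_vector <- function(ma) {
  lens <- integer(0)
  for (row in ma$rows) {
    r <- rle(strsplit(row, "", fixed = TRUE)[[1]] == GAP_CHAR)
    lens <- c(lens, r$lengths[r$values])
  }
  if (length(lens) == 0L) return(integer(0))
  tabulate(lens)
}

#' Gap statistics of an alignment
#'
#' @param ma A [protein_msa()].
#' @return Named integer vector: `gap_openings` (number of maximal gap runs
#'   over all rows) and `total_gaps` (total gap characters).
#' @export
gap_statistics <- function(ma) {
  del <- del_vector(ma)
  c(gap_openings = sum(del),
    total_gaps = if (length(del)) sum(seq_along(del) * del) else 0L)
}

#' Weight of an arbitrary alignment under its own PWM
#'
#' Sums the PWM cell scores of every residue in the gap-filtered alignment
#' (columns dropped by [pwm_from_msa()] contribute nothing) and charges
#' each maximal gap run of length `i` in the original alignment the affine
#' penalty `d + (i - 1) * e`.
#'
#' @param ma The original [protein_msa()] (used for the gap spectrum).
#' @param decomposition The result of [pwm_from_msa()] on `ma` (list with
#'   `pwm`, `column_map`, `ma_filtered`).
#' @param params A [scoring_params()].
#' @return Numeric scalar `F_MA`.
#' @export
ma_weight <- function(ma, decomposition, params = scoring_params()) {
  pwm <- decomposition$pwm
  maf <- decomposition$ma_filtered
  cmat <- msa_char_matrix_raw(maf$rows)
  total <- 0
  for (j in seq_len(maf$K)) {
    res <- cmat[, j]
    keep <- res != GAP_CHAR
    if (any(keep)) total <- total + sum(pwm$w[aa_to_index(res[keep]), j])
  }
  del <- del_vector(ma)
  gap_cost <- if (length(del)) {
    sum(del * (params$d + (seq_along(del) - 1) * params$e))
  } else 0
  total - gap_cost
}

#' Monte Carlo Z-score of an arbitrary alignment
#'
#' Makes any alignment comparable on the Z scale: a PWM is extracted from
#' the alignment's well-populated columns ([pwm_from_msa()]), the observed
#' weight is [ma_weight()], and the null distribution is built by
#' de-gapping the rows, shuffling each sequence's residues, and globally
#' re-aligning every shuffled sequence to the extracted PWM
#' ([set_objective()]), `n_shuffles` times.
#'
#' @param ma A [protein_msa()] with at least 2 rows.
#' @param params A [scoring_params()].
#' @param n_shuffles Number of shuffled null sets (default 300).
#' @param threshold Significance threshold on Z (default 10).
#' @return A `z_result`.
#' @export
z_for_msa <- function(ma, params = scoring_params(), n_shuffles = 300L,
                      threshold = 10) {
  stopifnot(n_shuffles >= 2L)
  dec <- pwm_from_msa(ma, params)
  observed <- ma_weight(ma, dec, params)
  si <- degap(ma)
  null_values <- vapply(seq_len(n_shuffles), function(i) {
    set_objective(shuffle_set(si), dec$pwm, params)
  }, numeric(1))
  new_z_result(observed, null_values, threshold)
}
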