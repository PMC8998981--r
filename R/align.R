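# Step codes shared with the C++ engine.
STEP_MATCH <- 0L
STEP_GAP_IN_SEQ <- 1L  # gap in the sequence: a PWM column left unmatched
STEP_GAP_IN_PWM <- 2L  # gap in the PWM: a residue inserted relative to it

seqset_indices <- function(si) lapply(si$residues, seq_to_index)

#' Global alignment of one sequence against a PWM
#'
#' Exact affine-gap global dynamic programming: a match of residue `r` to
#' PWM column `j` scores `w[r, j]`; a gap run of length `g` (in either the
#' sequence or the PWM) costs `d + (g - 1) * e`, terminal gaps included.
#' Ties are broken deterministically with preference
#' match > gap-in-sequence > gap-in-PWM.
#'
#' @param seq A single sequence string or a [sequence_set()] of length 1.
#' @param w A `weight_matrix`.
#' @param params A [scoring_params()].
#' @return An object of class `alignment_path`: list with `score` (the
#'   optimal terminal score `Fmax`), and `steps`, an integer vector over
#'   `0` (match), `1` (gap in sequence), `2` (gap in PWM), in left-to-right
#'   order.
#' @export
global_align <- function(seq, w, params = scoring_params()) {
  if (inherits(seq, "sequence_set")) {
    stopifnot(length(seq) == 1L)
    seq <- seq$residues[[1L]]
  }
  idx <- seq_to_index(seq)
  res <- .align_traceback_cpp(idx, w$w, params$d, params$e)
  structure(list(score = res$score, steps = res$steps,
                 seq_length = length(idx), pwm_length = w$L),
            class = "alignment_path")
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf(
    "alignment_path: Fmax = %.4f (%d residues vs %d PWM columns; %d steps)\n",
    x$score, x$seq_length, x$pwm_length, length(x$steps)))
  invisible(x)
}

#' Objective: summed optimal alignment scores of a set against a PWM
#'
#' The similarity measure `mF` between a PWM and a sequence set: the sum
#' over sequences of each one's optimal global alignment score against the
#' PWM. This is the objective the genetic algorithm maximizes.
#'
#' @param si A [sequence_set()].
#' @param w A `weight_matrix`.
#' @param params A [scoring_params()].
#' @return Numeric scalar `mF`.
#' @export
set_objective <- function(si, w, params = scoring_params()) {
  .align_score_sum_cpp(seqset_indices(si), w$w, params$d, params$e)
}

# Replay a path against the scoring scheme; used for validation and tests.
# Returns the recomputed score; errors if the path is inconsistent.
replay_path <- function(path, seq, w, params = scoring_params()) {
  idx <- seq_to_index(seq)
  i <- 0L; j <- 0L
  score <- 0
  run <- 0L  # current gap-run length (0 = in match)
  for (s in path$steps) {
    if (s == STEP_MATCH) {
      i <- i + 1L; j <- j + 1L
      score <- score + unname(w$w[idx[i], j])
      run <- 0L
    } else {
      gap_state <- if (s == STEP_GAP_IN_SEQ) 1L else 2L
      if (run == gap_state) {
        score <- score - params$e
      } else {
        score <- score - params$d
      }
      run <- gap_state
      if (s == STEP_GAP_IN_SEQ) j <- j + 1L else i <- i + 1L
    }
  }
  if (i != length(idx) || j != w$L) {
    stop("path does not consume the full sequence and PWM", call. = FALSE)
  }
  score
}
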