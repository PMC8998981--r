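#' Assemble a multiple alignment from per-sequence PWM alignments
#'
#' Each PWM column becomes one alignment column; a sequence whose path skips
#' a PWM column carries a gap there. Residues inserted relative to the PWM
#' (gap-in-PWM steps) between columns `j` and `j + 1` spawn a shared block
#' of extra columns at that junction, sized by the longest insertion any
#' sequence places there; shorter insertions are left-justified and
#' gap-padded. Junctions before the first and after the last PWM column are
#' handled the same way, so every row de-gaps back to its input sequence.
#'
#' @param si A [sequence_set()].
#' @param pwm_m The optimized `weight_matrix`.
#' @param paths Optional list of `alignment_path` objects, one per sequence
#'   (in `si` order); computed via [global_align()] when omitted.
#' @param params A [scoring_params()] (used only when `paths` is `NULL`).
#' @return A [protein_msa()].
#' @export
assemble_msa <- function(si, pwm_m, paths = NULL,
                         params = scoring_params()) {
  N <- n_seqs(si)
  if (is.null(paths)) {
    paths <- lapply(si$residues, function(s) global_align(s, pwm_m, params))
  }
  if (length(paths) != N) {
    stop("need one alignment path per sequence", call. = FALSE)
  }
  L <- pwm_m$L

  # Per sequence: residues inserted at each junction 0..L, and the cell
  # (residue or gap) at each PWM column.
  ins <- vector("list", N)     # each: list of character vectors, index j+1
  cells <- vector("list", N)   # each: character vector length L
  for (l in seq_len(N)) {
    chars <- strsplit(si$residues[[l]], "", fixed = TRUE)[[1]]
    steps <- paths[[l]]$steps
    i <- 0L; j <- 0L
    row_ins <- rep(list(character(0)), L + 1L)
    row_cells <- character(L)
    for (s in steps) {
      if (s == STEP_MATCH) {
        i <- i + 1L; j <- j + 1L
        row_cells[j] <- chars[i]
      } else if (s == STEP_GAP_IN_SEQ) {
        j <- j + 1L
        row_cells[j] <- GAP_CHAR
      } else {
        i <- i + 1L
        row_ins[[j + 1L]] <- c(row_ins[[j + 1L]], chars[i])
      }
    }
    if (i != length(chars) || j != L) {
      stop(sprintf("path %d does not consume its sequence and the PWM", l),
           call. = FALSE)
    }
    ins[[l]] <- row_ins
    cells[[l]] <- row_cells
  }

  max_ins <- vapply(seq_len(L + 1L), function(jj) {
    max(vapply(ins, function(x) length(x[[jj]]), integer(1)))
  }, integer(1))

  rows <- vapply(seq_len(N), function(l) {
    parts <- character(0)
    for (jj in seq_len(L + 1L)) {
      block <- ins[[l]][[jj]]
      pad <- max_ins[jj] - length(block)
      parts <- c(parts, block, rep(GAP_CHAR, pad))
      if (jj <= L) parts <- c(parts, cells[[l]][jj])
    }
    paste(parts, collapse = "")
  }, character(1))

  # A PWM column skipped by every sequence would leave an all-gap column;
  # drop such columns (they carry no residues) rather than fail.
  cmat <- msa_char_matrix_raw(rows)
  all_gap <- colSums(cmat != GAP_CHAR) == 0L
  if (any(all_gap)) {
    warning(sum(all_gap), " PWM column(s) unmatched by every sequence were ",
            "dropped from the alignment", call. = FALSE)
    rows <- apply(cmat[, !all_gap, drop = FALSE], 1L, paste, collapse = "")
  }

  protein_msa(rows, ids = si$ids)
}
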