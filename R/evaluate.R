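#' Column score of a test alignment against a reference
#'
#' A test column scores 1 when the reference alignment contains a column
#' with exactly the same residue-ordinal/gap configuration over all
#' sequences: every sequence contributes the same residue occurrence (by
#' position in its de-gapped sequence), and the same subset of sequences is
#' gapped. The score is the fraction of such columns, with the denominator
#' taken as the number of columns in the evaluated (test) alignment.
#'
#' @param test The alignment to evaluate, a [protein_msa()].
#' @param reference The reference [protein_msa()]; must align the same
#'   sequences (same ids, identical de-gapped residues). Row order may
#'   differ.
#' @return Column score in `[0, 1]`.
#' @export
column_score <- function(test, reference) {
  if (!setequal(test$ids, reference$ids) ||
      length(test$ids) != length(reference$ids)) {
    stop("alignments do not contain the same sequence ids", call. = FALSE)
  }
  ref_order <- match(test$ids, reference$ids)
  ref_rows <- reference$rows[ref_order]
  tst_degap <- gsub(GAP_CHAR, "", test$rows, fixed = TRUE)
  ref_degap <- gsub(GAP_CHAR, "", ref_rows, fixed = TRUE)
  if (!identical(tst_degap, ref_degap)) {
    stop("de-gapped sequences differ between test and reference alignment",
         call. = FALSE)
  }
  tst_keys <- column_keys(test$rows)
  ref_keys <- column_keys(ref_rows)
  mean(tst_keys %in% ref_keys)
}

# Encode each column as the vector of residue ordinals it consumes
# (0 for a gap), pasted into a comparable key string.
column_keys <- function(rows) {
  cmat <- msa_char_matrix_raw(rows)
  ord <- matrix(0L, nrow = nrow(cmat), ncol = ncol(cmat))
  for (r in seq_len(nrow(cmat))) {
    is_res <- cmat[r, ] != GAP_CHAR
    ord[r, is_res] <- seq_len(sum(is_res))
  }
  apply(ord, 2L, paste, collapse = ",")
}
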