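#' Construct a protein sequence set
#'
#' A `sequence_set` holds the unaligned input sequences: the `N` protein
#' sequences to be aligned, over the 20-letter amino-acid alphabet. The mean
#' sequence length drives the range of candidate PWM lengths scanned by
#' [find_best_pwm()].
#'
#' @param residues Character vector of sequences (uppercase, 20 canonical
#'   amino-acid letters only in `strict` mode).
#' @param ids Character vector of unique, non-empty sequence identifiers.
#'   Defaults to `names(residues)` or `seq1..seqN`.
#' @param strict If `TRUE` (default), ambiguity codes (B, J, O, U, X, Z, `*`)
#'   are an error; if `FALSE` they are replaced by `placeholder` with a
#'   warning.
#' @param placeholder Single canonical residue used for ambiguous characters
#'   in lenient mode (default `"A"`).
#'
#' @return An object of class `sequence_set` with fields `ids` and `residues`.
#' @seealso [read_fasta()], [n_seqs()], [mean_length()]
#' @export
#' @examples
#' si <- sequence_set(c(a = "ACDEF", b = "ACDEFGH"))
#' n_seqs(si)
#' mean_length(si)
sequence_set <- function(residues, ids = NULL, strict = TRUE,
                         placeholder = "A") {
  if (is.null(ids)) {
    ids <- names(residues)
    if (is.null(ids)) ids <- paste0("seq", seq_along(residues))
  }
  ids <- as.character(ids)
  residues <- toupper(unname(as.character(residues)))
  if (length(residues) < 1L) stop("empty sequence set", call. = FALSE)
  if (length(ids) != length(residues)) {
    stop("ids and residues differ in length", call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("empty sequence id", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(residues) < 1L)) {
    stop("zero-length sequence: ", ids[nchar(residues) < 1L][1L],
         call. = FALSE)
  }
  residues <- vapply(seq_along(residues), function(i) {
    check_residues(residues[[i]], ids[[i]], strict = strict,
                   placeholder = placeholder)
  }, character(1))
  structure(list(ids = ids, residues = residues), class = "sequence_set")
}

# Validate one sequence string; returns the (possibly cleaned) string.
check_residues <- function(s, id, strict = TRUE, placeholder = "A") {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) == 0L) return(s)
  if (strict) {
    stop(sprintf(
      "illegal residue '%s' in record '%s' at offset %d (strict alphabet)",
      chars[bad[1L]], id, bad[1L] - 1L), call. = FALSE)
  }
  if (!(placeholder %in% AA_ALPHABET)) {
    stop("placeholder must be one of the 20 canonical residues", call. = FALSE)
  }
  chars[bad] <- placeholder
  warning(sprintf("record '%s': %d non-canonical residue(s) replaced by '%s'",
                  id, length(bad), placeholder), call. = FALSE)
  paste(chars, collapse = "")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d protein sequences, mean length %.2f\n",
              n_seqs(x), mean_length(x)))
  show <- head(seq_along(x$ids), 5L)
  for (i in show) {
    s <- x$residues[[i]]
    cat(sprintf("  %s (%d aa): %s%s\n", x$ids[[i]], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x$ids) > 5L) cat(sprintf("  ... and %d more\n", length(x$ids) - 5L))
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$residues)

#' Number of sequences and mean sequence length
#'
#' @param si A [sequence_set()].
#' @return `n_seqs()` the number of sequences; `mean_length()` the arithmetic
#'   mean of their lengths.
#' @export
n_seqs <- function(si) length(si$residues)

#' @rdname n_seqs
#' @export
mean_length <- function(si) mean(nchar(si$residues))

#' Construct a multiple alignment object
#'
#' A `protein_msa` is a rectangular alignment: `alpha` rows of identical
#' length `K` over the amino-acid alphabet plus the gap symbol `-`. Dots are
#' accepted as gaps on input and normalized to `-`. Columns consisting
#' entirely of gaps are rejected.
#'
#' @param rows Character vector of aligned rows (equal lengths).
#' @param ids Character vector of unique row identifiers.
#' @return An object of class `protein_msa` with fields `ids`, `rows`, `K`
#'   (number of columns) and `alpha` (number of rows).
#' @seealso [read_alignment()], [degap()], [gap_statistics()]
#' @export
#' @examples
#' ma <- protein_msa(c(s1 = "AC-D", s2 = "ACED"))
#' ma$K
#' degap(ma)
protein_msa <- function(rows, ids = NULL) {
  if (is.null(ids)) {
    ids <- names(rows)
    if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  }
  ids <- as.character(ids)
  rows <- toupper(unname(as.character(rows)))
  rows <- gsub(".", GAP_CHAR, rows, fixed = TRUE)
  if (length(rows) < 1L) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(nchar(rows)), collapse = ", "), call. = FALSE)
  }
  K <- nchar(rows[[1L]])
  if (K < 1L) stop("alignment has zero columns", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  mat <- msa_char_matrix_raw(rows)
  legal <- c(AA_ALPHABET, GAP_CHAR)
  if (any(!(mat %in% legal))) {
    bad <- unique(mat[!(mat %in% legal)])
    stop("illegal alignment character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  all_gap <- colSums(mat != GAP_CHAR) == 0L
  if (any(all_gap)) {
    stop("column(s) consisting entirely of gaps: ",
         paste(which(all_gap), collapse = ", "), call. = FALSE)
  }
  structure(list(ids = ids, rows = rows, K = K, alpha = length(rows)),
            class = "protein_msa")
}

msa_char_matrix_raw <- function(rows) {
  matrix(unlist(strsplit(rows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(rows), byrow = TRUE)
}

#' Character matrix view of an alignment
#'
#' @param x A [protein_msa()].
#' @param ... Unused.
#' @return An `alpha` x `K` character matrix with row names from `ids`.
#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- msa_char_matrix_raw(x$rows)
  rownames(m) <- x$ids
  m
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d rows x %d columns\n", x$alpha, x$K))
  show <- head(seq_along(x$ids), 8L)
  for (i in show) {
    cat(sprintf("  %-12s %s%s\n", x$ids[[i]], substr(x$rows[[i]], 1, 60),
                if (x$K > 60) "..." else ""))
  }
  if (x$alpha > 8L) cat(sprintf("  ... and %d more rows\n", x$alpha - 8L))
  invisible(x)
}

#' Remove gaps from alignment rows
#'
#' @param ma A [protein_msa()].
#' @return A [sequence_set()] of the de-gapped rows, in row order.
#' @export
degap <- function(ma) {
  sequence_set(gsub(GAP_CHAR, "", ma$rows, fixed = TRUE), ids = ma$ids)
}

#' Equality of alignments
#'
#' Two alignments are equal when they have the same row ids (in order) and
#' identical row strings.
#' @param a,b [protein_msa()] objects.
#' @return Logical scalar.
#' @export
msa_identical <- function(a, b) {
  identical(a$ids, b$ids) && identical(a$rows, b$rows)
}

#' Scoring parameters for sequence-vs-PWM alignment
#'
#' Bundle of the affine gap penalties and PWM normalization constants. A gap
#' run of length `i` costs `d + (i - 1) * e`. Every PWM used by the method is
#' normalized so that its sum of squared cells equals `R^2 = r_l * 20 * L`
#' and its background-weighted mean cell value equals `k_d`.
#'
#' @param d Gap-opening penalty (default 40).
#' @param e Gap-extension penalty (default 1); requires `d >= e > 0`.
#' @param r_l Multiplier for the squared-norm target `R^2 = r_l * 20 * L`
#'   (default 5.0).
#' @param k_d Background-weighted mean target (default -1.0), playing the
#'   role of an expectation offset: negative values make a random
#'   sequence-vs-PWM match score drift downward.
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(d = 40, e = 1, r_l = 5.0, k_d = -1.0) {
  stopifnot(is.numeric(d), is.numeric(e), is.numeric(r_l), is.numeric(k_d))
  if (!(d >= e && e > 0)) stop("require d >= e > 0", call. = FALSE)
  if (r_l <= 0) stop("require r_l > 0", call. = FALSE)
  structure(list(d = as.numeric(d), e = as.numeric(e),
                 r_l = as.numeric(r_l), k_d = as.numeric(k_d)),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat(sprintf("scoring_params: d = %g, e = %g, r_l = %g, k_d = %g\n",
              x$d, x$e, x$r_l, x$k_d))
  invisible(x)
}
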