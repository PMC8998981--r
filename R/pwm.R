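# Position weight matrices ("images" of multiple alignments).
#
# A PWM here is a 20 x L real matrix scoring each amino acid at each of L
# alignment columns. Random PWMs seed the genetic algorithm; a PWM can also
# be extracted from an existing alignment for standalone significance
# scoring. Every PWM is normalized to a prescribed squared norm
# R^2 = r_l * 20 * L and background-weighted mean k_d, so that alignment
# scores of different PWMs are on a common scale.

new_weight_matrix <- function(w, p1, p2) {
  stopifnot(is.matrix(w), nrow(w) == AA_N)
  rownames(w) <- AA_ALPHABET
  structure(list(w = w, L = ncol(w), p1 = p1, p2 = p2),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  nrm <- pwm_norms(x)
  cat(sprintf("weight_matrix: 20 x %d, sum(w^2) = %.4f, weighted mean = %.4f\n",
              x$L, nrm[["r2"]], nrm[["kd"]]))
  invisible(x)
}

#' Normalization functionals of a PWM
#'
#' @param w A `weight_matrix`.
#' @return Named numeric vector: `r2` is the sum of squared cells, `kd` the
#'   background-weighted mean `sum(w * p1 %o% p2)`.
#' @export
pwm_norms <- function(w) {
  c(r2 = sum(w$w^2), kd = sum(w$w * outer(w$p1, w$p2)))
}

#' Residue frequencies of a sequence set
#'
#' @param si A [sequence_set()].
#' @return Named length-20 probability vector over the amino-acid alphabet.
#' @export
residue_frequencies <- function(si) {
  chars <- unlist(strsplit(si$residues, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  setNames(as.numeric(counts) / length(chars), AA_ALPHABET)
}

# Binomial z-standardization of a count matrix: the deviation of each count
# from its independence expectation, in units of its binomial SD. A unit
# pseudocount keeps p strictly inside (0, 1) for degenerate inputs.
standardize_counts <- function(M) {
  M <- M + 1
  x <- rowSums(M)
  y <- colSums(M)
  total <- sum(M)
  p <- outer(x, y) / total^2
  E <- total * p
  (M - E) / sqrt(E * (1 - p))
}

#' Build a random PWM matched to a sequence set's composition
#'
#' Emulates scoring a random protein sequence against a tandem array of
#' column indices: a random sequence of length `L * k` with the residue
#' frequencies of `si` is laid against `k` repeats of the column sequence
#' `1..L`, and the resulting residue-by-column count matrix is standardized
#' into a PWM. Because each column receives exactly `k` independent draws
#' from the residue distribution, the count matrix is drawn directly as `L`
#' multinomials of size `k`. The PWM is then normalized by
#' [transform_pwm()].
#'
#' @param si A [sequence_set()]; supplies the residue frequencies.
#' @param L Number of PWM columns.
#' @param k Draws per column (default 1000).
#' @param params A [scoring_params()].
#' @return A normalized `weight_matrix`.
#' @export
build_random_pwm <- function(si, L, k = 1000L, params = scoring_params()) {
  stopifnot(L >= 1L, k >= 1L)
  freq <- residue_frequencies(si)
  M <- rmultinom(L, size = k, prob = freq)
  W <- degenerate_guard(standardize_counts(M))
  w <- new_weight_matrix(W, p1 = freq, p2 = rep(1 / L, L))
  transform_pwm(w, params)
}

# When counts factorize exactly (single column, or a single-residue
# composition) every standardized deviation is zero and no affine map can
# reach the normalization targets. Such inputs carry no positional signal,
# so the matrix is reseeded with white noise instead.
degenerate_guard <- function(W) {
  if (stats::sd(W) < 1e-12) {
    W[] <- rnorm(length(W))
  }
  W
}

#' Normalize a PWM to the prescribed squared norm and weighted mean
#'
#' Applies the affine map `w' = a * w + b` with `(a, b)` solved in closed
#' form so that `sum(w'^2) == r_l * 20 * L` and
#' `sum(w' * p1 %o% p2) == k_d`. Eliminating `b` through the weighted-mean
#' constraint leaves a quadratic in `a`; the positive root is taken, which
#' preserves the sign structure of the matrix. A matrix whose cells are all
#' equal carries no information to rescale and is rejected.
#'
#' @param w A `weight_matrix`.
#' @param params A [scoring_params()] giving `r_l` and `k_d`.
#' @return A `weight_matrix` satisfying both constraints.
#' @export
transform_pwm <- function(w, params = scoring_params()) {
  stopifnot(inherits(w, "weight_matrix"))
  n <- AA_N * w$L
  r2_target <- params$r_l * AA_N * w$L
  kd <- params$k_d
  P <- outer(w$p1, w$p2)
  m <- sum(w$w * P)
  s1 <- sum(w$w)
  s2 <- sum(w$w^2)
  # b = kd - a * m; substitute into the squared-norm constraint.
  A <- s2 - 2 * m * s1 + n * m^2
  B <- 2 * kd * (s1 - n * m)
  C <- n * kd^2 - r2_target
  if (A <= 1e-12 * max(1, s2)) {
    stop("degenerate PWM: all cells (effectively) equal, cannot normalize",
         call. = FALSE)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    stop("no real normalization for this PWM (discriminant < 0)",
         call. = FALSE)
  }
  a <- (-B + sqrt(disc)) / (2 * A)
  if (a <= 0) stop("no positive normalization scale for this PWM",
                   call. = FALSE)
  b <- kd - a * m
  new_weight_matrix(a * w$w + b, p1 = w$p1, p2 = w$p2)
}

#' Extract a normalized PWM from an existing alignment
#'
#' Columns holding fewer than `alpha/2` residues (more than half gaps) are
#' dropped; residue counts of the surviving columns are standardized and the
#' result normalized by [transform_pwm()]. The surviving-column index map
#' links PWM columns back to the original alignment columns.
#'
#' @param ma A [protein_msa()] with at least 2 rows.
#' @param params A [scoring_params()].
#' @return A list with elements `pwm` (a `weight_matrix` of `K'` columns),
#'   `column_map` (integer vector: original column index of each surviving
#'   column) and `ma_filtered` (the alignment restricted to surviving
#'   columns).
#' @export
pwm_from_msa <- function(ma, params = scoring_params()) {
  stopifnot(inherits(ma, "protein_msa"))
  if (ma$alpha < 2L) stop("alignment must have at least 2 rows", call. = FALSE)
  cmat <- msa_char_matrix_raw(ma$rows)
  nres <- colSums(cmat != GAP_CHAR)
  keep <- nres >= ma$alpha / 2
  if (!any(keep)) stop("alignment too gappy: no column holds at least half ",
                       "of the rows", call. = FALSE)
  column_map <- which(keep)
  sub <- cmat[, keep, drop = FALSE]
  V <- vapply(seq_len(ncol(sub)), function(j) {
    tabulate(match(sub[, j], AA_ALPHABET), nbins = AA_N)
  }, numeric(AA_N))
  V <- matrix(V, nrow = AA_N)
  W <- degenerate_guard(standardize_counts(V))
  x_raw <- rowSums(V)
  p1 <- if (sum(x_raw) > 0) x_raw / sum(x_raw) else rep(1 / AA_N, AA_N)
  w <- new_weight_matrix(W, p1 = setNames(p1, AA_ALPHABET),
                         p2 = rep(1 / ncol(V), ncol(V)))
  ma_filtered <- protein_msa(apply(sub, 1L, paste, collapse = ""),
                             ids = ma$ids)
  list(pwm = transform_pwm(w, params), column_map = column_map,
       ma_filtered = ma_filtered)
}

#' Write / read a PWM as TSV
#'
#' Debug/fixture format: two comment lines holding the background vectors,
#' then 20 labeled rows by L columns at full double precision.
#'
#' @param w A `weight_matrix`.
#' @param path File path.
#' @return `write_pwm()` invisibly returns `path`; `read_pwm()` returns the
#'   `weight_matrix`.
#' @export
write_pwm <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# p1\t", paste(format(w$p1, digits = 17), collapse = "\t")),
    paste0("# p2\t", paste(format(w$p2, digits = 17), collapse = "\t"))
  ), con)
  write.table(format(w$w, digits = 17), con, sep = "\t", quote = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# p")]
  parse_vec <- function(s) as.numeric(strsplit(s, "\t", fixed = TRUE)[[1]][-1])
  p1 <- setNames(parse_vec(hdr[1]), AA_ALPHABET)
  p2 <- parse_vec(hdr[2])
  body <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                     row.names = 1L)
  w <- as.matrix(body)
  dimnames(w) <- NULL
  new_weight_matrix(w, p1 = p1, p2 = p2)
}
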