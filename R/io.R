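#' Read unaligned protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @inheritParams sequence_set
#' @return A [sequence_set()].
#' @details Parsing is done with [Biostrings::readAAStringSet()]; residue
#'   validation (strict/lenient alphabet policy) is applied afterwards.
#'   Gap characters are not allowed in unaligned input.
#' @export
read_fasta <- function(path, strict = TRUE, placeholder = "A") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  xs <- Biostrings::readAAStringSet(path)
  if (length(xs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(xs))
  sequence_set(as.character(xs), ids = ids, strict = strict,
               placeholder = placeholder)
}

#' Write a sequence set to FASTA
#'
#' @param si A [sequence_set()].
#' @param path Output path.
#' @param width Line-wrapping width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(si, path, width = 60L) {
  xs <- Biostrings::AAStringSet(setNames(si$residues, si$ids))
  Biostrings::writeXStringSet(xs, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a multiple alignment from aligned FASTA or Clustal
#'
#' The format is auto-detected from the first non-blank line (`>` for FASTA,
#' a `CLUSTAL` header otherwise) unless given explicitly. `.` gap characters
#' are normalized to `-`.
#'
#' @param path Path to an aligned FASTA or Clustal file.
#' @param format `"auto"` (default), `"fasta"` or `"clustal"`.
#' @return A [protein_msa()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- ""
    con <- file(path, "r")
    on.exit(close(con))
    repeat {
      ln <- readLines(con, n = 1L)
      if (length(ln) == 0L) break
      if (nzchar(trimws(ln))) { first <- trimws(ln); break }
    }
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  if (format == "fasta") {
    xs <- Biostrings::readAAStringSet(path)
    if (length(xs) == 0L) stop("empty alignment file: ", path, call. = FALSE)
    protein_msa(as.character(xs), ids = sub("\\s.*$", "", names(xs)))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    rows <- as.character(Biostrings::unmasked(aln))
    if (length(rows) == 0L) stop("empty alignment file: ", path,
                                 call. = FALSE)
    protein_msa(rows, ids = names(rows))
  }
}

#' Write a multiple alignment to aligned FASTA or Clustal
#'
#' @param ma A [protein_msa()].
#' @param path Output path.
#' @param format `"fasta"` (default) or `"clustal"`.
#' @param width Block width (default 60 columns per line).
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(ma, path, format = c("fasta", "clustal"),
                            width = 60L) {
  format <- match.arg(format)
  width <- as.integer(width)
  if (format == "fasta") {
    xs <- Biostrings::AAStringSet(setNames(ma$rows, ma$ids))
    Biostrings::writeXStringSet(xs, filepath = path, width = width)
  } else {
    lines <- c("CLUSTAL W multiple sequence alignment", "", "")
    namew <- max(nchar(ma$ids)) + 3L
    starts <- seq(1L, ma$K, by = width)
    for (s in starts) {
      for (i in seq_len(ma$alpha)) {
        lines <- c(lines, sprintf("%-*s%s", namew, ma$ids[[i]],
                                  substr(ma$rows[[i]], s,
                                         min(s + width - 1L, ma$K))))
      }
      lines <- c(lines, "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}
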