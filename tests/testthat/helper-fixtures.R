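# Shared fixtures and independent oracles for the test suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_set <- function(n, len) {
  sequence_set(vapply(seq_len(n), function(i) random_seq(len), character(1)),
               ids = paste0("s", seq_len(n)))
}

# Planted-motif family: n noisy copies of one random motif.
planted_motif_set <- function(n = 20, len = 30, noise = 0.1) {
  motif <- strsplit(random_seq(len), "", fixed = TRUE)[[1]]
  seqs <- vapply(seq_len(n), function(i) {
    ch <- motif
    flip <- runif(len) < noise
    ch[flip] <- sample(AA20, sum(flip), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  sequence_set(seqs, ids = paste0("m", seq_len(n)))
}

# Small weight matrix with given cells (no normalization), for DP tests.
raw_pwm <- function(w, p1 = rep(1 / 20, 20), p2 = rep(1 / ncol(w), ncol(w))) {
  pwmsa:::new_weight_matrix(w, p1 = setNames(p1, AA20), p2 = p2)
}

# Exhaustive-path oracle for global affine-gap sequence-vs-PWM alignment.
# Enumerates every monotone path, charging d for the first step of each
# maximal gap run (per side) and e for each continuation. Exponential;
# only for tiny instances.
bf_align_score <- function(seq, w, d, e) {
  idx <- pwmsa:::seq_to_index(seq)
  L1 <- length(idx)
  L <- ncol(w$w)
  rec <- function(i, j, prev) {
    if (i == L1 && j == L) return(0)
    best <- -Inf
    if (i < L1 && j < L) {
      best <- max(best, w$w[idx[i + 1], j + 1] + rec(i + 1, j + 1, "m"))
    }
    if (j < L) {
      best <- max(best, -(if (prev == "x") e else d) + rec(i, j + 1, "x"))
    }
    if (i < L1) {
      best <- max(best, -(if (prev == "y") e else d) + rec(i + 1, j, "y"))
    }
    best
  }
  rec(0L, 0L, "start")
}

# Random valid alignment (rows over residues and gaps) with no all-gap
# column, by construction: at least one residue per column.
random_msa <- function(alpha = 4, K = 10, gap_prob = 0.25) {
  repeat {
    m <- matrix(sample(AA20, alpha * K, replace = TRUE), nrow = alpha)
    gaps <- matrix(runif(alpha * K) < gap_prob, nrow = alpha)
    # keep at least one residue per column and per row
    for (j in seq_len(K)) if (all(gaps[, j])) gaps[sample(alpha, 1), j] <- FALSE
    m[gaps] <- "-"
    rows <- apply(m, 1, paste, collapse = "")
    if (all(nchar(gsub("-", "", rows)) > 0)) {
      return(protein_msa(rows, ids = paste0("r", seq_len(alpha))))
    }
  }
}

# Independent oracle: compare columns as explicit sets of
# (row id, residue ordinal | gap) pairs, built with plain loops.
bf_column_score <- function(test, reference) {
  col_sets <- function(ma) {
    cm <- as.matrix(ma)
    ords <- list()
    for (id in ma$ids) ords[[id]] <- 0L
    out <- list()
    for (j in seq_len(ncol(cm))) {
      cell <- character(0)
      for (r in seq_len(nrow(cm))) {
        id <- ma$ids[r]
        if (cm[r, j] == "-") {
          cell <- c(cell, paste0(id, ":gap"))
        } else {
          ords[[id]] <- ords[[id]] + 1L
          cell <- c(cell, paste0(id, ":", ords[[id]]))
        }
      }
      out[[j]] <- sort(cell)
    }
    out
  }
  tst <- col_sets(test)
  ref <- col_sets(reference)
  hits <- vapply(tst, function(cs) {
    any(vapply(ref, identical, logical(1), x = cs))
  }, logical(1))
  mean(hits)
}

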