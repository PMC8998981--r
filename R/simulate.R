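# Artificial protein families with calibrated divergence.
#
# A random ancestor of length L is mutated independently into each
# descendant by a fixed number of substitution events (uniform positions,
# sampled with replacement; the replacement residue is uniform over all 20,
# so the incumbent can recur) plus a fixed number of indel events. With s
# substitution events on length L, the probability that a position still
# matches the ancestor is Pm = P0 + (1 - P0)/20 with P0 = (1 - 1/L)^s; for
# two independent descendants carrying s2 events each, the expected
# pairwise divergence is 2 * s2 events, i.e. x = 2 * s2 / L substitutions
# per residue.

#' Simulation configuration for artificial protein families
#'
#' Defaults follow the reference study conditions: ancestor length 600,
#' 100 descendants, 0.3 substitution events per residue, 2 indels of
#' length 1, uniform residue frequencies.
#'
#' @param ancestor_length Ancestor sequence length `L` (default 600).
#' @param n_descendants Number of descendants (default 100).
#' @param subs_per_residue Substitution events per residue applied to each
#'   descendant (`s2`; default 0.3). Each descendant receives
#'   `round(subs_per_residue * ancestor_length)` events.
#' @param indel_count Indel events per descendant (default 2).
#' @param indel_length Residues inserted/deleted per indel event
#'   (default 1).
#' @param residue_frequencies Length-20 probability vector for the ancestor
#'   and for inserted residues (default uniform).
#' @param insertion_prob Probability that an indel event is an insertion
#'   rather than a deletion (default 0.5, a fair coin).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(ancestor_length = 600L, n_descendants = 100L,
                              subs_per_residue = 0.3, indel_count = 2L,
                              indel_length = 1L,
                              residue_frequencies = rep(1 / 20, 20),
                              insertion_prob = 0.5) {
  stopifnot(ancestor_length >= 1L, n_descendants >= 1L,
            subs_per_residue >= 0, indel_count >= 0L, indel_length >= 1L,
            length(residue_frequencies) == 20L,
            insertion_prob >= 0, insertion_prob <= 1)
  if (abs(sum(residue_frequencies) - 1) > 1e-9) {
    stop("residue_frequencies must sum to 1", call. = FALSE)
  }
  structure(list(
    ancestor_length = as.integer(ancestor_length),
    n_descendants = as.integer(n_descendants),
    subs_per_residue = as.numeric(subs_per_residue),
    indel_count = as.integer(indel_count),
    indel_length = as.integer(indel_length),
    residue_frequencies = setNames(as.numeric(residue_frequencies),
                                   AA_ALPHABET),
    insertion_prob = as.numeric(insertion_prob)
  ), class = "simulation_config")
}

#' Generate a random ancestor sequence
#'
#' @param cfg A [simulation_config()].
#' @return A single-sequence character string of i.i.d. residues drawn from
#'   `cfg$residue_frequencies`.
#' @export
make_ancestor <- function(cfg = simulation_config()) {
  paste(sample(AA_ALPHABET, cfg$ancestor_length, replace = TRUE,
               prob = cfg$residue_frequencies), collapse = "")
}

#' Mutate an ancestor into one descendant
#'
#' Applies `round(subs_per_residue * ancestor_length)` substitution events
#' and `indel_count` indel events in a random interleaved order.
#' Substitutions pick a uniform position of the current sequence and
#' replace its residue with a uniform draw from all 20 letters (the
#' incumbent may recur). Each indel event inserts or deletes (fair coin)
#' `indel_length` contiguous residues at a uniform position; inserted
#' residues follow `cfg$residue_frequencies`.
#'
#' @param anc Ancestor sequence string.
#' @param cfg A [simulation_config()].
#' @return The descendant sequence string.
#' @export
make_descendant <- function(anc, cfg = simulation_config()) {
  chars <- strsplit(anc, "", fixed = TRUE)[[1]]
  n_sub <- as.integer(round(cfg$subs_per_residue * cfg$ancestor_length))
  events <- sample(c(rep("sub", n_sub), rep("indel", cfg$indel_count)))
  for (ev in events) {
    len <- length(chars)
    if (ev == "sub") {
      pos <- sample.int(len, 1L)
      chars[pos] <- sample(AA_ALPHABET, 1L)
    } else if (runif(1L) < cfg$insertion_prob) {
      # insertion at a uniform junction 0..len
      at <- sample.int(len + 1L, 1L) - 1L
      block <- sample(AA_ALPHABET, cfg$indel_length, replace = TRUE,
                      prob = cfg$residue_frequencies)
      chars <- append(chars, block, after = at)
    } else {
      if (len <= cfg$indel_length) {
        stop("sequence too short for indel load", call. = FALSE)
      }
      at <- sample.int(len - cfg$indel_length + 1L, 1L)
      chars <- chars[-(at:(at + cfg$indel_length - 1L))]
    }
  }
  paste(chars, collapse = "")
}

#' Generate an artificial protein family
#'
#' One random ancestor, `n_descendants` independently mutated descendants.
#' The ancestor itself is not part of the returned set (it is attached as
#' attribute `"ancestor"`).
#'
#' @param cfg A [simulation_config()].
#' @param id_prefix Prefix for descendant ids (default `"des"`).
#' @return A [sequence_set()] of the descendants.
#' @export
make_family <- function(cfg = simulation_config(), id_prefix = "des") {
  anc <- make_ancestor(cfg)
  des <- vapply(seq_len(cfg$n_descendants), function(i) {
    make_descendant(anc, cfg)
  }, character(1))
  out <- sequence_set(des, ids = paste0(id_prefix, seq_len(cfg$n_descendants)))
  attr(out, "ancestor") <- anc
  out
}

#' Expected ancestor-descendant identity under the substitution model
#'
#' With `s1` substitution events (uniform positions with replacement,
#' replacement uniform over 20) on a sequence of length `L`:
#' `P0 = (1 - 1/L)^s1` is the probability a position was never hit,
#' `P1 = (1 - P0)/20` the probability it was hit but ended on the original
#' residue, and `Pm = P0 + P1` the match probability.
#'
#' @param s1 Number of substitution events (>= 0).
#' @param L Sequence length.
#' @return An object of class `divergence_model`: list with `p0`, `p1`,
#'   `pm`.
#' @export
expected_identity <- function(s1, L) {
  stopifnot(s1 >= 0, L >= 1)
  p0 <- (1 - 1 / L)^s1
  p1 <- (1 - p0) / AA_N
  structure(list(p0 = p0, p1 = p1, pm = p0 + p1),
            class = "divergence_model")
}

#' Expected identity between two independent descendants
#'
#' Each descendant carries `s2` substitution events; two positions match
#' when both survived (`P02^2`) or otherwise coincide by chance
#' (`(1 - P02^2)/20`). Setting this equal to the ancestor-descendant match
#' probability `Pm(s1)` gives the calibration `s1 = 2 * s2`.
#'
#' @param s2 Substitution events per descendant.
#' @param L Sequence length.
#' @return Expected pairwise match probability (numeric scalar).
#' @export
expected_pair_identity <- function(s2, L) {
  p02 <- (1 - 1 / L)^s2
  p02^2 + (1 - p02^2) / AA_N
}

#' Fraction of matching positions between two equal-length sequences
#'
#' @param a,b Sequence strings of equal length.
#' @return Numeric scalar in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) {
    stop("sequences differ in length", call. = FALSE)
  }
  mean(ca == cb)
}

#' Estimate divergence from an observed identity
#'
#' Inverts the match-probability model: from `Pm = P0 + (1 - P0)/20` one
#' gets `P0 = (20 * Pm - 1)/19` and `s1 = log(P0) / log(1 - 1/L)`, reported
#' as `x = s1 / L` substitutions per residue. Identities at or below the
#' chance level 1/20 carry no divergence information.
#'
#' @param observed_identity Match fraction in `(1/20, 1]`.
#' @param L Sequence length.
#' @return Estimated substitutions per residue `x` (numeric scalar).
#' @export
estimate_x <- function(observed_identity, L) {
  stopifnot(L >= 2)
  if (observed_identity <= 1 / AA_N || observed_identity > 1) {
    stop("beyond resolvable divergence: identity must lie in (1/20, 1]",
         call. = FALSE)
  }
  p0 <- (AA_N * observed_identity - 1) / (AA_N - 1)
  s1 <- log(p0) / log(1 - 1 / L)
  s1 / L
}
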