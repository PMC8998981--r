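# High-level pipeline entry points (also backing the command-line wrapper
# in inst/cli/pwmsa).

#' Align a protein family end to end
#'
#' The full pipeline: read sequences, optimize a PWM over the candidate
#' length scan ([find_best_pwm()]), assemble the induced multiple alignment
#' ([assemble_msa()]) and score its Monte Carlo significance
#' ([z_for_pwm()]).
#'
#' @param input A [sequence_set()] or path to a FASTA file with at least 2
#'   sequences.
#' @param output Optional path for the alignment (written via
#'   [write_alignment()]).
#' @param format Output alignment format, `"fasta"` or `"clustal"`.
#' @param params A [scoring_params()].
#' @param cfg A [ga_config()].
#' @param n_shuffles Monte Carlo shuffles for the Z-score (default 300).
#' @param threshold Significance threshold on Z (default 10).
#' @param seed Integer seed; every random choice in the run derives from
#'   it, so identical calls reproduce identical output.
#' @param report Optional path for a one-row TSV report.
#' @return List with `alignment` (a [protein_msa()]), `ga` (the
#'   `ga_result`), `z` (the `z_result`) and `report` (one-row data frame:
#'   best length, objective, Z and the resolved settings).
#' @export
run_align <- function(input, output = NULL, format = c("fasta", "clustal"),
                      params = scoring_params(), cfg = ga_config(),
                      n_shuffles = 300L, threshold = 10, seed = 1L,
                      report = NULL) {
  format <- match.arg(format)
  si <- if (inherits(input, "sequence_set")) input else read_fasta(input)
  if (n_seqs(si) < 2L) {
    stop("need at least 2 sequences to align", call. = FALSE)
  }
  set.seed(seed)
  ga <- find_best_pwm(si, params, cfg)
  ma <- assemble_msa(si, ga$best_pwm, params = params)
  z <- z_for_pwm(si, ga$best_pwm, params, n_shuffles = n_shuffles,
                 threshold = threshold)
  rep_df <- data.frame(
    n_sequences = n_seqs(si), mean_length = mean_length(si),
    best_length = ga$best_length, objective = ga$best_objective,
    z = z$z, null_mean = z$null_mean, null_sd = z$null_sd,
    n_shuffles = z$n_shuffles, significant = z$significant,
    d = params$d, e = params$e, r_l = params$r_l, k_d = params$k_d,
    preset = cfg$preset, seed = seed)
  if (!is.null(output)) write_alignment(ma, output, format = format)
  if (!is.null(report)) {
    write.table(rep_df, report, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(alignment = ma, ga = ga, z = z, report = rep_df)
}

#' Score the significance of an existing alignment
#'
#' @param input A [protein_msa()] or path to an aligned FASTA/Clustal file.
#' @inheritParams run_align
#' @return List with `z` (the `z_result`) and `report` (one-row data
#'   frame).
#' @export
run_zscore <- function(input, params = scoring_params(), n_shuffles = 300L,
                       threshold = 10, seed = 1L, report = NULL) {
  ma <- if (inherits(input, "protein_msa")) input else read_alignment(input)
  set.seed(seed)
  z <- z_for_msa(ma, params, n_shuffles = n_shuffles, threshold = threshold)
  rep_df <- cbind(as.data.frame(z),
                  data.frame(alpha = ma$alpha, K = ma$K,
                             d = params$d, e = params$e, seed = seed))
  if (!is.null(report)) {
    write.table(rep_df, report, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(z = z, report = rep_df)
}

#' Generate artificial families on the divergence grid
#'
#' Writes one FASTA per grid point plus a manifest TSV recording every
#' setting and per-set seed. The default grid is the full study design:
#' substitution loads 0.3 to 2.7 (step 0.3) per residue, crossed with indel
#' counts \{2, 5, 10\} and indel lengths \{1, 5, 20\} - 81 sets. `scale`
#' shrinks the ancestor length and the number of descendants proportionally
#' for desk-scale runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param s2_values Substitution events per residue per descendant.
#' @param indel_counts,indel_lengths Indel grid axes.
#' @param ancestor_length,n_descendants Family dimensions before scaling.
#' @param scale Scale factor in `(0, 1]` applied to `ancestor_length` and
#'   `n_descendants` (default 1).
#' @param seed Base integer seed; grid point `i` uses `seed + i`.
#' @return Invisibly, the manifest data frame (also written to
#'   `manifest.tsv` in `out_dir`).
#' @export
run_simulate <- function(out_dir, s2_values = seq(0.3, 2.7, by = 0.3),
                         indel_counts = c(2L, 5L, 10L),
                         indel_lengths = c(1L, 5L, 20L),
                         ancestor_length = 600L, n_descendants = 100L,
                         scale = 1, seed = 1L) {
  stopifnot(scale > 0, scale <= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(s2 = s2_values, indel_count = indel_counts,
                      indel_length = indel_lengths,
                      KEEP.OUT.ATTRS = FALSE)
  L <- max(1L, as.integer(round(ancestor_length * scale)))
  n_des <- max(2L, as.integer(round(n_descendants * scale)))
  # indel sizes are grid conditions and do not scale; the ancestor must
  # survive the worst case of all-deletion indel events
  worst <- max(indel_counts) * max(indel_lengths)
  if (L <= worst) {
    stop(sprintf(paste0("scaled ancestor length %d cannot absorb up to %d ",
                        "deleted residues; use a larger --scale"), L, worst),
         call. = FALSE)
  }
  manifest <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    set_seed_i <- seed + i
    set.seed(set_seed_i)
    cfg <- simulation_config(
      ancestor_length = L, n_descendants = n_des,
      subs_per_residue = grid$s2[i], indel_count = grid$indel_count[i],
      indel_length = grid$indel_length[i])
    fam <- make_family(cfg)
    fname <- sprintf("des_s2-%.1f_ic-%d_il-%d.fasta", grid$s2[i],
                     grid$indel_count[i], grid$indel_length[i])
    write_fasta(fam, file.path(out_dir, fname))
    data.frame(set = i, file = fname, s2 = grid$s2[i],
               x = 2 * grid$s2[i], indel_count = grid$indel_count[i],
               indel_length = grid$indel_length[i], ancestor_length = L,
               n_descendants = n_des, seed = set_seed_i)
  }))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Column score of a test alignment file against a reference file
#'
#' @param test_path,reference_path Paths to aligned FASTA/Clustal files
#'   over the same sequences.
#' @param quiet If `FALSE` (default), print `CS` to 4 decimals.
#' @return The column score, invisibly when printed.
#' @export
run_cs <- function(test_path, reference_path, quiet = FALSE) {
  cs <- column_score(read_alignment(test_path),
                     read_alignment(reference_path))
  if (!quiet) {
    cat(sprintf("CS = %.4f\n", cs))
    return(invisible(cs))
  }
  cs
}
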