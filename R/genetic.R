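#' Genetic-algorithm configuration
#'
#' Controls the population of candidate PWMs and the stopping rule. The
#' `"paper"` preset is the full-scale configuration (population 500, 50
#' mutants per generation, unit length step); the `"fast"` preset is a
#' reduced desk-scale configuration (population 30, 10 mutants, coarse
#' length step) suitable for interactive use and the test suite.
#'
#' @param population_size Number of PWMs per population (>= 4).
#' @param mutants_per_generation PWMs mutated each generation.
#' @param mutation_range Length-2 numeric: a mutated cell is replaced by a
#'   uniform draw from this interval (default `c(-10, 10)`).
#' @param stagnation_window Stop after this many consecutive generations
#'   without improvement of the best objective (default 10).
#' @param length_span Fraction of the mean sequence length scanned on each
#'   side (default 0.10: candidate PWM lengths run from `0.9 * Lbar` to
#'   `1.1 * Lbar`).
#' @param length_step Stride of the length scan; `NA` picks
#'   `max(1, round(0.02 * Lbar))` (the coarse scan of the fast preset).
#' @param k Multinomial draws per column when seeding random PWMs
#'   (default 1000).
#' @param max_generations Hard cap on generations per length (safety net).
#' @param preset `"paper"` or `"fast"`; explicit arguments override preset
#'   values.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = NULL, mutants_per_generation = NULL,
                      mutation_range = c(-10, 10), stagnation_window = 10L,
                      length_span = 0.10, length_step = NULL, k = 1000L,
                      max_generations = 1000L,
                      preset = c("paper", "fast")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    paper = list(population_size = 500L, mutants_per_generation = 50L,
                 length_step = 1L),
    fast = list(population_size = 30L, mutants_per_generation = 10L,
                length_step = NA_integer_))
  if (is.null(population_size)) population_size <- defaults$population_size
  if (is.null(mutants_per_generation)) {
    mutants_per_generation <- defaults$mutants_per_generation
  }
  if (is.null(length_step)) length_step <- defaults$length_step
  population_size <- as.integer(population_size)
  if (population_size < 4L) stop("population_size must be >= 4", call. = FALSE)
  if (stagnation_window < 1L) stop("stagnation_window must be >= 1",
                                   call. = FALSE)
  stopifnot(length(mutation_range) == 2L,
            mutation_range[1] < mutation_range[2])
  structure(list(
    population_size = population_size,
    mutants_per_generation = as.integer(mutants_per_generation),
    mutation_range = as.numeric(mutation_range),
    stagnation_window = as.integer(stagnation_window),
    length_span = as.numeric(length_span),
    length_step = as.integer(length_step),
    k = as.integer(k),
    max_generations = as.integer(max_generations),
    preset = preset
  ), class = "ga_config")
}

#' @export
print.ga_config <- function(x, ...) {
  cat(sprintf(
    "ga_config (%s): population %d, %d mutants/generation, stop after %d stagnant generations\n",
    x$preset, x$population_size, x$mutants_per_generation,
    x$stagnation_window))
  invisible(x)
}

#' Rank-weighted parent selection
#'
#' Selection probability is linear in rank: with `n` candidates the
#' best-scoring one has weight `n`, the worst weight 1, so higher objective
#' values are strictly favored regardless of the sign of the scores. Tied
#' scores share their average rank, so equal objectives are selected with
#' equal probability.
#'
#' @param objectives Numeric vector of objective values.
#' @return The selected index.
#' @export
select_parent <- function(objectives) {
  n <- length(objectives)
  stopifnot(n >= 1L)
  # average ranks on ties, so equal scores get equal selection probability
  rank_desc <- rank(-objectives, ties.method = "average")
  sample.int(n, 1L, prob = n - rank_desc + 1)
}

#' One-point column crossover of two PWMs
#'
#' A uniformly drawn cut point `c` in `1..L-1` glues columns `1..c` of the
#' first parent to columns `c+1..L` of the second; the child is then
#' re-normalized. With `L = 1` the child is a copy of a randomly chosen
#' parent.
#'
#' @param parent_a,parent_b `weight_matrix` objects of equal length.
#' @param params A [scoring_params()].
#' @return A normalized child `weight_matrix`.
#' @export
crossover_pwm <- function(parent_a, parent_b, params = scoring_params()) {
  stopifnot(parent_a$L == parent_b$L)
  L <- parent_a$L
  if (L == 1L) {
    pick <- sample(c(TRUE, FALSE), 1L)
    return(if (pick) parent_a else parent_b)
  }
  cut <- sample.int(L - 1L, 1L)
  child <- cbind(parent_a$w[, seq_len(cut), drop = FALSE],
                 parent_b$w[, (cut + 1L):L, drop = FALSE])
  transform_pwm(new_weight_matrix(child, p1 = parent_a$p1, p2 = parent_a$p2),
                params)
}

# Replace one random cell by a uniform draw from the mutation interval and
# re-normalize.
mutate_pwm <- function(w, params, range) {
  m <- w$w
  m[sample.int(length(m), 1L)] <- runif(1L, range[1], range[2])
  transform_pwm(new_weight_matrix(m, p1 = w$p1, p2 = w$p2), params)
}

#' Evolve a population of PWMs at a fixed length
#'
#' Runs the genetic algorithm at one candidate PWM length: a population of
#' random PWMs is scored by [set_objective()]; each generation the best
#' matrix is preserved unchanged, the two worst are replaced by children of
#' rank-weighted parents ([crossover_pwm()]), and a fixed number of
#' non-elite, non-child matrices receive a single-cell mutation followed by
#' re-normalization. The run stops once the best objective has failed to
#' increase for `stagnation_window` consecutive generations.
#'
#' @param si A [sequence_set()].
#' @param L PWM length (columns).
#' @param params A [scoring_params()].
#' @param cfg A [ga_config()].
#' @return List with `pwm` (best `weight_matrix`), `objective` (its `mF`),
#'   `trace` (best objective per generation, non-decreasing) and
#'   `generations` (number of update generations run).
#' @export
evolve_population <- function(si, L, params = scoring_params(),
                              cfg = ga_config()) {
  stopifnot(L >= 1L)
  idx <- seqset_indices(si)
  score_one <- function(w) .align_score_sum_cpp(idx, w$w, params$d, params$e)

  P <- cfg$population_size
  pop <- lapply(seq_len(P), function(i) {
    build_random_pwm(si, L, k = cfg$k, params = params)
  })
  obj <- vapply(pop, score_one, numeric(1))

  ord <- order(obj, decreasing = TRUE)
  pop <- pop[ord]; obj <- obj[ord]
  trace <- obj[1L]
  stall <- 0L
  gens <- 0L

  while (stall < cfg$stagnation_window && gens < cfg$max_generations) {
    gens <- gens + 1L
    # drop the two worst, append two children of rank-weighted parents
    keep <- seq_len(P - 2L)
    pool <- pop[keep]; pool_obj <- obj[keep]
    children <- lapply(1:2, function(i) {
      pa <- select_parent(pool_obj)
      pb <- select_parent(pool_obj)
      crossover_pwm(pool[[pa]], pool[[pb]], params)
    })
    pop <- c(pool, children)
    obj <- c(pool_obj, vapply(children, score_one, numeric(1)))

    # Mutate non-elite, non-child matrices. Targets are drawn with the
    # same rank-linear weights as parents: mutation effort concentrates on
    # high-scoring matrices, whose single-cell variants are the only ones
    # with a realistic chance of beating the incumbent best.
    candidates <- setdiff(seq_len(P - 2L), 1L)
    n_mut <- min(cfg$mutants_per_generation, length(candidates))
    if (n_mut > 0L) {
      mut_idx <- if (length(candidates) == 1L) candidates else {
        # candidates are already rank-ordered (descending objective)
        sample(candidates, n_mut,
               prob = rev(seq_along(candidates)))
      }
      for (i in mut_idx) {
        pop[[i]] <- mutate_pwm(pop[[i]], params, cfg$mutation_range)
        obj[i] <- score_one(pop[[i]])
      }
    }

    ord <- order(obj, decreasing = TRUE)
    pop <- pop[ord]; obj <- obj[ord]
    if (obj[1L] > trace[length(trace)] + 1e-9) stall <- 0L else {
      stall <- stall + 1L
    }
    trace <- c(trace, max(obj[1L], trace[length(trace)]))
  }

  list(pwm = pop[[1L]], objective = obj[1L], trace = trace,
       generations = gens)
}

#' Optimize the PWM over the candidate length scan
#'
#' Runs [evolve_population()] for every candidate PWM length in
#' `[round((1 - length_span) * Lbar), round((1 + length_span) * Lbar)]`
#' (stride `length_step`) and keeps the length whose best objective is
#' maximal.
#'
#' @inheritParams evolve_population
#' @return An object of class `ga_result`: list with `best_pwm`,
#'   `best_length`, `best_objective`, `generations_run` (for the winning
#'   length), `objective_trace` (per-generation best objective of the
#'   winning length) and `by_length` (data frame of `L`, `objective`,
#'   `generations` over the scan).
#' @export
find_best_pwm <- function(si, params = scoring_params(), cfg = ga_config()) {
  lbar <- mean_length(si)
  step <- cfg$length_step
  if (is.na(step)) step <- max(1L, as.integer(round(0.02 * lbar)))
  lo <- as.integer(round((1 - cfg$length_span) * lbar))
  hi <- as.integer(round((1 + cfg$length_span) * lbar))
  lo <- max(1L, lo)
  lengths <- seq.int(lo, hi, by = step)

  runs <- lapply(lengths, function(L) evolve_population(si, L, params, cfg))
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- which.max(objs)

  structure(list(
    best_pwm = runs[[best]]$pwm,
    best_length = lengths[[best]],
    best_objective = objs[[best]],
    generations_run = runs[[best]]$generations,
    objective_trace = runs[[best]]$trace,
    by_length = data.frame(
      L = lengths, objective = objs,
      generations = vapply(runs, `[[`, numeric(1), "generations"))
  ), class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "ga_result: best PWM length %d, objective mF = %.4f (%d generations; scanned %d lengths)\n",
    x$best_length, x$best_objective, x$generations_run, nrow(x$by_length)))
  invisible(x)
}
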