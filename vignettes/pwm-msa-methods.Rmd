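---
title: "Aligning highly diverged protein families with optimized PWM images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning highly diverged protein families with optimized PWM images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(pwmsa)
```

## The problem

Progressive and iterative multiple-alignment methods build an alignment
from pairwise comparisons. When protein sequences have accumulated more
than roughly 2.4 substitutions per residue, pairwise similarity drops to
the noise floor and those methods can no longer produce statistically
significant alignments, even when a common ancestry is real. `pwmsa`
implements an alternative that never compares sequences with each other.
Instead it searches the space of *alignment images*: position weight
matrices (PWMs) that stand in for an unknown multiple alignment.

The key objects and steps:

1. A candidate image is a 20 × `L` real matrix `w` scoring each amino acid
   at each of `L` alignment columns.
2. Each input sequence is aligned to the image by exact global dynamic
   programming with affine gap penalties; the optimal score of sequence
   `l` is `Fmax(l)`.
3. The fit of an image to the sequence set is the objective
   `mF = sum_l Fmax(l)`.
4. A genetic algorithm evolves a population of random images to maximize
   `mF`, and repeats the search over candidate lengths `L` spanning 90% to
   110% of the mean sequence length, keeping the best image overall.
5. The traceback paths of every sequence against the winning image induce
   the multiple alignment: image column `j` becomes alignment column `j`;
   residues inserted relative to the image open shared extra columns at
   the junction where they occur.
6. Significance is a Monte Carlo Z-score: the observed `mF` is compared
   with its distribution over sets in which each sequence's residues are
   independently shuffled (composition and length preserved exactly).

Because step 2 compares each sequence with a *profile* rather than with
another noisy sequence, weak column preferences shared by many sequences
accumulate in `mF` even when every pairwise identity is at chance level.

## Scoring parameters

| parameter | default | meaning |
|---|---|---|
| `d` | 40 | gap-opening penalty (score units per run) |
| `e` | 1  | gap-extension penalty per additional gapped position |
| `r_l` | 5.0 | squared-norm scale: every PWM is normalized to `sum(w^2) = r_l * 20 * L` |
| `k_d` | -1.0 | background-weighted mean of the PWM, `sum(w * p1 %o% p2)` |
| `Z_t` | 10 | significance threshold on the Monte Carlo Z-score |
| `k` | 1000 | multinomial draws per column when seeding random PWMs |

A gap run of length `i` costs `d + (i - 1) e`; terminal gaps are charged
(the alignment is global end to end). The normalization keeps every image
in the population on a common score scale, so `mF` values of different
images are comparable; `k_d < 0` makes the expected score of a random
residue against a random column negative, which penalizes padding and
makes the optimal alignment length-sensitive. The defaults are the
combination found to balance alignment quality and significance for
protein alphabets.

The squared-norm target grows linearly with `L` on purpose: a fixed
target would shrink individual cells as images grow and make scores of
different candidate lengths incomparable.

## Building and normalizing images

A random image is seeded from the composition of the input set: each
column receives `k` independent residue draws with the set's frequencies
(equivalent to scoring a random sequence of length `L * k` against a
`k`-fold tandem repeat of the column indices), and the count matrix `M`
is standardized cell by cell,

    w[i, j] = (M[i, j] - E[i, j]) / sqrt(E[i, j] * (1 - p[i, j])),

with `p[i, j] = x[i] y[j] / total^2` the independence model of row and
column sums and `E = total * p`. A unit pseudocount in every cell keeps
`p` strictly inside (0, 1). The same standardization turns the residue
counts of an existing alignment into its image (`pwm_from_msa()`), after
dropping columns that are more than half gaps — such columns say more
about indel placement than about residue preferences.

Normalization to the `r_l`/`k_d` targets is the affine map
`w' = a w + b`: substituting `b` from the weighted-mean constraint into
the squared-norm constraint leaves a quadratic in `a` whose positive root
preserves the sign structure; both constraints then hold to machine
precision (tested to 1e-6). Two degenerate cases are handled explicitly:
a matrix with (effectively) equal cells cannot be mapped onto the targets
and is an error in `transform_pwm()`; count matrices that factorize
exactly (a single column, or a single-residue composition) standardize to
all zeros and are reseeded with white noise before normalization, since
they carry no positional signal.

## The genetic algorithm

Images are organisms; their fitness is `mF`. Each generation:

* the best image is kept unchanged (elitism), so the best objective is
  non-decreasing by construction;
* the two worst images are replaced by children, each a one-point column
  crossover ("gluing") of two parents drawn with rank-linear
  probabilities (weight `n - rank + 1`, average ranks on ties);
* a fixed number of non-elite, non-child images receive a single-cell
  mutation — the cell is replaced by a uniform draw from [-10, 10] — and
  are re-normalized.

The run stops when the best objective has not improved for 10 consecutive
generations, and the whole procedure is repeated for each candidate
length in the scan.

Two details here were genuinely open design choices. First,
fitness-proportional parent selection is ill-defined when `mF` is
negative (it usually is, with `k_d < 0`), so selection is rank-based,
which preserves the stated monotonicity — better images are strictly more
likely to be chosen — for any score sign. Second, mutation *targets* are
drawn with the same rank-linear weights rather than uniformly. With
uniform targeting almost all mutation effort lands on mediocre images
whose single-cell variants have no realistic chance of beating the
incumbent best, and the search stalls at the stagnation floor; targeting
by rank concentrates proposals near the top of the population, where a
single beneficial cell edit can and regularly does improve the best
objective. This is the difference between a decorative GA and one that
actually climbs.

Population sizing follows the same logic, with a twist. Large
populations make the initial best an extreme order statistic that
single-cell proposals almost never beat within the stagnation window, so
— counter-intuitively — *small* populations hill-climb better at desk
scale: with a dozen images the optimizer improves on the best initial
image in well over 95% of planted-motif runs (20 noisy copies of a
30-mer). But optimizer strength cuts both ways: on pure noise a very
small population keeps finding single-cell overfits of the particular
input arrangement, inflating the selection bias of the Z-score. The
`"fast"` preset uses 30 images and 10 mutants per generation with a
coarse length step of about 2% of the mean length — the size at which,
on desk-scale data, the optimizer still climbs real signal but stalls
quickly on noise, keeping the noise-Z mean near the full-scale analog of
about 4 rather than near the significance threshold. For focused motif
searches at short lengths a smaller population (around 12) is the better
tool. The `"paper"` preset (500 images, 50 mutants, unit step)
reproduces the full-scale configuration and is only sensible on
server-class budgets.

## Significance

`Z = (observed - null mean) / null SD`, with the null built from 300
(default) independently shuffled copies of the sequence set scored
against the *same* image. The spread is the sample standard deviation:
the conventional threshold arithmetic (threshold ≈ null mean + 3 spreads
≈ 10) only makes sense in SD units. Two estimators are provided:
`z_for_pwm()` for a pipeline run, and `z_for_msa()` for any externally
produced alignment — the alignment's own image is extracted, the observed
weight is the image score of its residues minus affine charges for every
gap run (`ma_weight()`), and the null re-aligns shuffled de-gapped rows
to that image.

Note an honest caveat: the observed `mF` of a pipeline run is the result
of an optimization over images, so it carries selection bias — even pure
noise yields a positive Z on average (about 4 at full scale). `Z_t = 10`
is deliberately far above that bias floor. The bias grows with optimizer
strength relative to data size; at desk scale the fast preset keeps the
noise mean well below the threshold, which the acceptance tests check
explicitly on 20 noise families.

## The family simulator

`make_family()` emulates a star phylogeny: a random ancestor of length
`L` (default 600, uniform residue frequencies) and `n` descendants
(default 100), each mutated independently by `round(s2 * L)` substitution
events plus a configurable number of indel events (default 2 events of
length 1, insertion or deletion by fair coin, positions uniform,
interleaved with substitutions in random order). Substitution events pick
positions uniformly *with replacement* and replace the residue by a
uniform draw from all 20 letters, incumbent included — exactly the
process under which the match probability has the closed form

    Pm(s1) = P0 + (1 - P0)/20,   P0 = (1 - 1/L)^s1 .

For two independent descendants with `s2` events each, the pairwise match
probability equals `Pm(2 s2)`, so each descendant's load `s2` yields a
pairwise divergence of `x = 2 s2 / L` substitutions per residue —
`estimate_x()` inverts `Pm` in closed form to read `x` off an observed
identity. The acceptance script regenerates 200 descendant pairs at
`s2 = 0.3` per residue and recovers `x = 0.6` to Monte Carlo precision.

What the simulator does *not* emulate: substitution-matrix (PAM/BLOSUM)
biased exchanges, site-rate heterogeneity, tree-structured descent, or
compositional drift. Tests passing on simulated families therefore show
that the machinery behaves as the model predicts, not that real protein
families — whose conserved columns are biochemically structured rather
than i.i.d. — will show the same Z values.

## Numerical and procedural choices

* **DP boundary and ties.** The recurrence is the standard three-state
  affine formulation (match / gap-in-sequence / gap-in-PWM), with
  `F(i, 0) = F(0, i) = -d - (i - 1) e` and ties broken
  match > gap-in-sequence > gap-in-PWM, identically during fill and
  traceback, so results are deterministic. Switching gap sides opens a
  new run. Exactness is tested against exhaustive path enumeration on
  hundreds of small instances.
* **Insertion columns.** Residues inserted relative to the image are
  left-justified within the shared insertion block at their junction;
  end junctions are treated like any other. An image column matched by no
  sequence would produce an all-gap column and is dropped with a warning.
* **Determinism.** All randomness flows through R's RNG; a fixed seed
  reproduces alignments, reports and simulated FASTA byte for byte.
* **Desk-scale test sizes.** The test-suite uses families of 20 sequences
  (lengths 100–150), 50-shuffle nulls, and the fast preset — sizes chosen
  so the whole scientific story (calibration, signal/noise separation,
  optimizer progress) is exercised in minutes on one core. The reduced
  scale shrinks Z roughly with `sqrt(N)` and optimizer depth, which is
  why the desk-scale noise mean (a few units) and signal Z (tens) sit far
  below the full-scale values (hundreds at low divergence).

## Limitations

* The alignment engine is exact but quadratic in time and memory; the
  full-scale configuration (100 × 600 sequences, 121-length scan,
  population 500) is a cluster-sized computation.
* The Z-score is a selection-biased statistic by construction; compare Z
  values only between runs with comparable optimization budgets.
* The normalization transform is an affine two-parameter map; it matches
  the two published constraints but the original procedure it replaces is
  not described in the literature available to us, so cell-level
  agreement with the reference implementation is not guaranteed.
* The column score requires a trusted reference alignment and treats a
  column as correct only when the full residue/gap configuration matches;
  it is deliberately strict and has no notion of partially correct
  columns.
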