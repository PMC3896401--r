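---
title: "Simulating spatial genetic structure at range-expansion fronts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spatial genetic structure at range-expansion fronts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfsim)
set.seed(1)
```

## The model and its assumptions

`surfsim` simulates a haploid, asexual population with discrete,
non-overlapping generations on a rectangular lattice of demes. Each
individual carries one neutral diallelic locus (alleles A and a); there is no
mutation, selection, recombination or diploidy, so the only forces are
reproduction noise, migration and the culling that enforces a local carrying
capacity. Each generation applies three events in a fixed order:

1. **Reproduction.** Every individual in suitable habitat leaves an
   independent Poisson(`r`) number of offspring and dies. Occupants of
   unsuitable habitat leave no offspring, so migrants that strayed beyond the
   habitat boundary die there one generation later. Because sums of
   independent Poissons are Poisson, a deme's per-allele offspring count is
   drawn as Poisson(`r ×` count) — distributionally identical to
   per-individual draws and far cheaper.
2. **Migration.** Offspring migrate to orthogonally adjacent demes (von
   Neumann neighborhood; `n` = 2 at lattice corners, 3 at edges, 4 in the
   interior; the lattice is bounded, not periodic). The migration convention
   is discussed below.
3. **Culling.** Any deme holding more than `K` individuals is thinned to
   exactly `K` by uniform random removal; the retained allele-A count is
   therefore hypergeometric, which is how it is sampled.

The population starts with the leftmost `n_init_cols` columns at carrying
capacity and allele-A frequency `p0`, and expands rightward. Three habitat
scenarios control what limits the expansion: `PhLRE` (all columns suitable
from the start; speed set by `r` and `m`), `BLRE` (columns become suitable
one at a time, evenly spaced in time, so the whole lattice is suitable after
`boundary_duration` generations), and `stationary` (the habitat never grows;
the last suitable column is the zero-speed reference). The suitable-column
count under `BLRE` at generation `g` is
`n_init_cols + floor((n_cols − n_init_cols) · g / boundary_duration)`,
capped at `n_cols` — the minimal, linear reading of "column-by-column"
habitat opening.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `n_rows` | lattice rows (front width, demes) | 75 | must be odd (spectral convention) |
| `n_cols` | lattice columns (expansion axis) | 200 | |
| `K` | carrying capacity per deme (individuals) | 100 | large enough for well-defined domains |
| `r` | mean offspring per individual | 3 | study grid: 1.1, 2, 3, 5 |
| `m` | migration parameter (probability) | 0.2 | study grid: 0.01, 0.1, 0.2, 0.4 |
| `p0` | initial allele-A frequency | 0.5 | study grid adds 0.01, 0.1, 0.2 |
| `n_init_cols` | founding columns | 20 | |
| `max_generations` | generation budget | 8000 | |
| `boundary_duration` | BLRE habitat-opening span | — | study grid: 600–7900 |

These defaults are the reference study conditions; `preset()` bundles the
standard parameter grids (two of which are printed inconsistently in the
source material — both variants are shipped, as `"methods"` and
`"caption"`).

## The migration convention

The per-individual migration probability is the one genuinely open modelling
choice, and it matters: the front of a pulled expansion wave moves at a speed
set by the low-density growth and dispersal rates, so the convention is
directly observable in the pilot expansion time. Two readings of
"individuals migrate with probability related to `m` to any of the `n`
adjacent demes" are implemented:

* `"m_over_n"` (default): an individual with `n` neighbors migrates with
  probability `m/n`, destination uniform over the `n` neighbors (per-neighbor
  probability `m/n²`).
* `"total_m"`: every individual migrates with total probability `m`
  regardless of position (per-neighbor probability `m/n`).

Under the default convention the phenotype-limited pilot (`r = 3`,
`m = 0.2`, 75 × 200 lattice) completes its expansion in ≈ 518 generations
(mean over 20 replicates, sd ≈ 3; the acceptance script recomputes this),
matching the ≈ 534-generation calibration for which the boundary-motion
durations 600–7900 were designed as slight-to-strong constraints on the
front. The `"total_m"` convention roughly doubles the front's axial
diffusion and completes the same expansion in ≈ 338 generations, which is
incompatible with that calibration; it is retained as an explicit option
because it is the more common stepping-stone textbook convention. Both
conventions conserve individuals exactly and are implemented as a binomial
chain over the four directions — an exact uniform multinomial split of each
deme's leavers.

## Frozen records

A column beyond the founding block is "frozen" at the first generation —
evaluated after culling — at which **all** of its demes simultaneously hold
exactly `K` individuals; its vector of allele-A frequencies (each a multiple
of `1/K`) is stored with the recording generation. This whole-column trigger
is the strict reading of a column "reaching carrying capacity"; the
alternative (column mean reaching `K`) fires earlier and was not used. The
expansion time of a replicate is the generation at which the last remaining
column receives its record. On narrow lattices a column occasionally
saturates one generation before its left neighbour, so recording generations
are non-decreasing in column index only up to rare one-generation
inversions; records are kept at their physical trigger rather than forced
into order. For the stationary scenario the last suitable column is
snapshotted at configurable generations (default: the final generation) and
flows through the same analysis.

## Front statistics

Each recorded column of `N` demes is summarised by:

* **Segmentation.** Demes are classed as homogeneous-A (frequency exactly
  1), homogeneous-a (exactly 0) or mixed. A *domain* is a maximal run of
  demes fixed for the same allele — adjacent runs fixed for opposite alleles
  are two domains with no cline between them — and a *cline* is a maximal
  run of mixed demes. Counts use integer allele counts, so exact fixation is
  well defined; an `eps` band (demes within `eps` of fixation count as
  fixed) is exposed for sensitivity analyses but defaults to 0. Segments
  tile the column: domain plus cline widths always sum to `N`.
* **Pairwise differences.** `PX` (within a deme), `PXY` (between two demes)
  and `Pc = PXY − (PX + PY)/2` are computed from exact counts, preserving
  the `n/(n−1)` small-sample correction, and aggregated per column as
  unweighted means over the `N` demes (for `PX`) and over all
  `choose(N, 2)` unordered deme pairs (for `PXY`, `Pc`). The pair means are
  evaluated in closed form from the frequency sums
  (`Σ_{i<j} [p_i(1−p_j)+p_j(1−p_i)] = (N−1)S₁ − (S₁²−S₂)`), and the pair
  mean of `(PX_i + PX_j)/2` reduces to `mean(PX)`; brute-force pair
  enumeration backs both identities in the tests.
* **Mean spectral frequency.** With DFT coefficients `P_k` of the frequency
  vector, amplitudes `|P_k|` for `k = 1 … (N−1)/2` (DC excluded; `N` odd so
  this is the highest resolvable wavenumber) and spatial frequencies
  `f_k = k/N` cycles per deme, `f̄` is the amplitude-weighted mean of the
  `f_k`. A constant column has an empty spectrum and returns 0 by
  convention; any non-constant column lies in `[1/N, (N−1)/(2N)]`. The
  constant-column test uses a tolerance scaled by machine epsilon so that
  numerically-zero FFT residues do not produce spurious values.

Sweeps (`run_sweep()`) average every statistic per column across replicates,
dropping undefined entries (e.g. the mean cline width of a column with no
cline) and recording the contributing count; replicate `i` of every
parameter combination uses seed `base_seed + i − 1`, so matched replicates
across combinations share seeds and a sweep is bit-reproducible.

## What the simulations do and do not show

The simulator *is* the data generator: every test condition is a model
condition, not a fixture. Passing tests show that the implementation has the
model's exact distributions (Poisson reproduction, multinomial migration,
hypergeometric culling), conserves individuals, respects neutrality (the
global allele frequency is a martingale; an isolated deme fixes A with
probability `p0`), and reproduces the expansion phenomenology — collapse of
within-deme diversity and build-up of corrected between-deme differentiation
along the front, broader clines and higher retained diversity under slow
boundary motion, and the widest clines at a stationary front. They say
nothing about real organisms: landscape heterogeneity, long-distance
dispersal, selection, mutation and non-Poisson reproduction are all outside
the model.

## Numerical and scale choices

Simulation state advances on an *active column window* (columns 1 to the
rightmost occupied column + 1); since migration extends occupancy by at most
one column per generation and habitat beyond the window is empty, the window
is exact, not an approximation. The test suite runs the full-lattice pilot
at 20 replicates and the scenario contrasts at 10 replicates — enough for
stable direction-of-effect comparisons, while the published-style experiment
grids at 100 replicates remain a `preset(n_replicates = 100)` away. The
slow-boundary contrast uses `boundary_duration = 4000` and the stationary
reference its standard 8000-generation snapshot. Property tests for the
statistics sweep hundreds of random columns against brute-force oracles
(pair enumeration, direct O(N²) DFT, run-length scanning).

## Known limitations

* The two migration conventions bracket, but do not exactly reproduce, the
  ≈ 534-generation reference calibration (the default lands ≈ 3% fast);
  residual differences in edge handling or sampling order of the original
  implementation of this model class cannot be recovered from its
  description.
* Only rectangular, column-wise habitat schedules are supported; no 2-D
  habitat geometries, corridors or patchiness.
* One locus, two alleles: sequence-based statistics (e.g. nucleotide
  diversity over many sites) are out of scope, as are spatial
  autocorrelation analyses.
* Memory holds the full lattice densely; lattices orders of magnitude larger
  than the defaults would want a sparse frontier representation.
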