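# surfsim

Individual-based simulation of gene surfing at range-expansion fronts, with
the spatial-genetic analysis of the front's "frozen records".

## The problem

When a population expands its range, the few founders at the advancing front
experience amplified genetic drift. For a neutral diallelic locus this
*gene surfing* demixes the population into alternating stripes — genetically
**homogeneous domains** fixed for one allele — separated by **allele-frequency
clines** of mixed demes, orthogonal to the expansion direction. How sharp
that pattern is depends on *what limits the expansion*:

* **PhLRE** (phenotype-limited range expansion): all habitat is suitable from
  the start and the expansion speed is set by the population's reproduction
  rate `r` and migration rate `m`.
* **BLRE** (boundary-limited range expansion): habitat opens column by column
  over a fixed number of generations, so the front repeatedly waits for new
  habitat; migration has time to smear the front's genetic structure.
* **stationary**: the habitat never grows; the last suitable column is the
  zero-expansion-speed reference, shaped by migration–drift balance alone.

## The model

A lattice of demes (default 75 rows × 200 columns) holds asexual haploid
individuals typed at one neutral locus with alleles A and a. Each generation
applies, in order:

1. **Reproduction** — every individual leaves an independent Poisson(`r`)
   number of offspring and dies; occupants of unsuitable habitat leave none.
2. **Migration** — an individual with `n` orthogonally adjacent demes
   (`n` = 2 at corners, 3 at edges, 4 in the interior) migrates with
   probability `m/n`, its destination uniform over those `n` demes
   (`migration_model = "m_over_n"`; a total-emigration-`m` convention is
   available as `"total_m"`).
3. **Culling** — demes above the carrying capacity `K` are thinned to exactly
   `K` by uniform random removal (hypergeometric in the allele counts).

The simulation starts with the first 20 columns at carrying capacity and
allele-A frequency `p0` (default 0.5). When a column beyond that founding
block first has *all* of its demes at `K`, its allele-frequency profile is
captured as that column's **frozen record** — the permanent genetic signature
of the front's passage.

Each frozen column is summarised by eight statistics: the number and mean
width of homogeneous domains and clines; the average pairwise differences
within demes (`PX = 2 n_A n_a / (n(n-1))`), between demes
(`PXY = p_X(1-p_Y) + p_Y(1-p_X)`) and the corrected between-deme difference
(`Pc = PXY − (PX + PY)/2`), averaged over the column's demes / deme pairs;
and the mean frequency of the power spectrum,
`f̄ = Σ f_k |P_k| / Σ |P_k|` over DFT wavenumbers `k = 1 … (N−1)/2`
(`f_k = k/N` cycles per deme), a measure of how fine-grained the allele
frequency fluctuates along the column.

## Worked example

```r
library(surfsim)

params <- sim_params(n_rows = 25, n_cols = 60, K = 50, n_init_cols = 10,
                     max_generations = 2000, seed = 42)
run <- run_simulation(params)
run
#> Simulation run (PhLRE): 25 x 60 lattice, K = 50, r = 3, m = 0.2
#>   50 frozen-record columns; expansion_time = 152; final generation 152

stats <- front_stats_table(run)
round(stats[stats$column_index %in% c(11, 25, 40, 60), ], 4)
#>    replicate column_index generation_recorded n_domains n_clines
#> 1          1           11                   6         1        1
#> 15         1           25                  50         4        3
#> 30         1           40                  94         1        0
#> 50         1           60                 152         1        0
#>    mean_domain_width mean_cline_width     PX    PXY     Pc   fbar
#> 1                1.0          24.0000 0.3592 0.4965 0.1373 0.2343
#> 15               4.5           2.3333 0.0772 0.3458 0.2686 0.1508
#> 30              25.0               NA 0.0000 0.0000 0.0000 0.0000
#> 50              25.0               NA 0.0000 0.0000 0.0000 0.0000
```

The first recorded column (11) is still one broad mixed cline with high
within-deme diversity (`PX` 0.36). By column 25 surfing has carved it into
four narrow domains with clines between them: `PX` has collapsed to 0.08
while the corrected between-deme difference `Pc` has risen to 0.27. From
column 40 onward this replicate's front is fixed for one allele — a single
domain spanning the column, every statistic at 0. `plot_frozen_records(run)`
renders the familiar stripe pattern.

Replicated parameter grids (the standard experiment designs are shipped as
`preset()`s) run through `run_sweep()`, which averages every statistic per
column across replicates and can write per-combination TSV tables and a JSON
manifest. A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/surfsim.R simulate --scenario blre --boundary-duration 6000 \
    --seed 42 --out records.tsv --stats stats.tsv
Rscript inst/cli/surfsim.R sweep --preset fig3_migration --replicates 10 --out sweeps/
```

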