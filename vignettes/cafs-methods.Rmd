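---
title: "Methods: gene-density ridges, Cafs scaffolding, and assembly metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-density ridges, Cafs scaffolding, and assembly metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cafs` re-implements, as reusable and tested components, the bespoke
computations of a chromosome-scale assembly study of a telocentric fish
karyotype (12 chromosomes, ~555 Mb anchored): sliding-window gene-density
and GC tracks, a two-cutoff "ridge" clustering statistic with a permutation
null, regional scans of the GC/gene-density correlation, the Cafs strategy
— chromosome assembly by FISH (fluorescence in situ hybridization) walking
assisted by conserved synteny — and standard assembly summary statistics.
This vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic data do and do
not establish.

## Window tracks

Windows are `[start, start + window_size - 1]` with starts on the lattice
`1 + k * step`; the defaults (1-Mb window, 100-kb step) follow the study's
convention, and trailing partial windows are dropped rather than padded so
that a single gene-count cutoff is comparable across all windows. Genes are
assigned to windows by their start coordinate (point semantics), matching
the permutation null, which permutes gene positions as points; midpoint and
any-overlap assignment are available through the `assign` argument of
`count_genes_in_windows()` because the original convention for
boundary-spanning genes is not documented. GC is `(G+C)/(A+C+G+T)` per
window with `N` excluded from the denominator — assembled chromosomes carry
1-kb runs of `N` at scaffold junctions, which would otherwise dilute GC —
and all-`N` windows are flagged `NA` and dropped from correlations.

## The ridge statistic and its permutation null

A *ridge* is a region of elevated gene density: at least `c_w` consecutive
windows, each containing more than `c_h` genes. Detection
(`detect_ridges()`) reports maximal qualifying runs. Two readings of the
qualification rule circulate — strictly "higher than H" versus "a lower
limit of H" — so both are implemented; strict `>` is the default and the
choice is recorded in the result's attributes.

The genome-wide ridge count `N` is summed over chromosomes and tested
against a null in which each chromosome independently redraws its observed
number of genes `i` uniformly over `1..S` (`S` the chromosome length), the
track and ridge count are recomputed, and the genome count `n` recorded;
with `f` the number of permutations (default 10,000) where `n >= N`, the
p-value is `f/n_perm` when `f > 0` and is reported censored as
`< 1/n_perm` when `f = 0`, never as zero. Null positions are drawn i.i.d.
with replacement at bp resolution (collisions are negligible at these
scales; `replace = FALSE` switches to without-replacement sampling since
the original description does not say). Each (permutation, chromosome)
pair draws from its own seeded substream, so results are independent of
chromosome iteration order and reproduce exactly under a fixed seed.

Two structural facts worth knowing:

* The ridge count is monotone non-increasing in `c_w` (raising it only
  removes runs) but **not** in `c_h`: raising the count cutoff can split
  one long qualifying run into two runs that both still pass `c_w`,
  increasing the count. Counts of qualifying windows, and of windows
  inside ridges, are the monotone quantities in `c_h`. Grid views
  (`cutoff_grid()`) should be read with this in mind.
* The permutation p-value is discrete: `n` has a few dozen support points
  at desk scale. Where a distributional check of the p-value is wanted
  (see calibration below) the cutoffs should sit near the per-window mean
  count so the null count is diffuse; at cutoffs far in the tail the
  p-value collapses onto a handful of atoms.

## Regional GC/gene-density correlation

Association between gene density and GC is measured by Spearman's rank
correlation (average ranks for ties; two-sided asymptotic p — at 31 pairs
per region the asymptotic approximation is adequate, and no exact method
is claimed by the source). The regional scan reconciles a 3-Mb window
specification with 4-Mb regions in the only way that makes both true
simultaneously: a region collects 31 consecutive windows of the shared
1-Mb/100-kb track, whose starts span 3 Mb and whose sequence footprint is
4 Mb; regions advance by one step. Regions with `rho > 0.95` and
`p < 0.01` are flagged high; `rho < 0.7` flags low. The threshold is
applied to `rho` itself, not `rho^2`.

## Cafs: grouping, ordering, orienting

All wet-lab evidence enters through one oracle interface
(`fish_oracle()` provides the simulation backend; real measurements could
implement the same contract): exact same-chromosome co-hybridization
queries, relative-order queries of 2–3 probes, a telomere-end observation
per ordered group, and a per-scaffold direction read from the scaffold's
two end probes. Every query counts one hybridization, matching the
probe-combination bookkeeping style of the study (its printed 78
combinations are an idealized lower bound here; failed or repeated
hybridizations are not modelled).

* **Eligibility.** A BAC qualifies as a probe when both end sequences
  align to one scaffold with identity strictly above 90%.
* **Linked-scaffold prediction.** Scaffold pairs whose anchors sit at
  adjacent ordinals on a reference chromosome in *all three* reference
  species become predicted links. Adjacency of ordinals is the minimal
  faithful reading of "linked"; no distance threshold is imposed.
* **Grouping.** The first scaffold founds group A and becomes its
  landmark. Each candidate is tested first against the landmark of the
  group its links predict, then against remaining landmarks in founding
  order; a candidate negative everywhere founds the next group. First
  founder = landmark and landmark test order = founding order are
  conventions chosen for deterministic budgets; the study does not state
  its own. Hints can only skip queries, never add them.
* **Ordering.** Within a group, scaffolds sort by ascending mean measured
  distance to the centromere (each measurement the mean of ≥ 5 per-cell
  truncated-normal draws). Adjacent pairs closer than `resolution` are
  resolved by order queries, cached per pair; lexicographic id order is
  the final deterministic tie-break.
* **Orientation.** Walking fixes the order but not the polarity of the
  list; the telomere landmark of the metaphase chromosome does. Lists are
  emitted centromere-first (coordinate 1 = centromere; `rel_position` 0 =
  centromere, 1 = telomere — co-monotone with `order_index` on a
  telocentric chromosome) and reversed exactly when the head is telomeric.
* **Building.** Scaffolds concatenate in order with 1 kb of `N` per
  junction; `-` placements are reverse-complemented. AGP v2.1 output uses
  gap type `scaffold`, linkage `yes`, evidence `map`.

Whether annotated chromosome coordinates should reflect reverse-placed
scaffolds is not documented in the source; `project_to_chromosome()`
applies the geometrically necessary rule (reflect within the scaffold,
flip strand).

## Assembly metrics

`nxx_table()` uses the cumulative-scan definition (Nt length = length of
the record where the descending cumulative sum first reaches t% of the
total; Nt count = its rank), with records ≥ 100 bp and ≥ 2 kb counted
alongside. Contigs split at maximal `N` runs of ≥ 10 (a convention, not a
documented choice of the study; configurable) and pieces under 100 bp are
excluded.

Genome size is `K_num / Peak_depth` on the canonical (strand-merged)
17-mer spectrum counted with a 1-bp sliding window. The peak is the modal
depth after excluding the low-depth error slope — depths below the first
local minimum of the histogram — and `K_num` likewise counts only
instances at or above that boundary: at 1% per-base error about one k-mer
in six contains an error and piles up at depths 1–3, and leaving those
instances in `K_num` inflates the estimate by ~20% while the peak drops
by the error-free fraction. A histogram that only decreases (no interior
mode) is an error, with a diagnostic, rather than an estimate.

Per-chromosome summaries print size (kb), scaffold count, gene count and
density per 10 Mb rounded half-away-from-zero — the rule that reproduces
all 12 printed densities of the study's table, which ships as
`monopterus_chromosomes()` — plus a totals row whose density is recomputed
from the totals.

## The synthetic genome: what it emulates, what it does not

`simulation_config()` fixes the study conditions: 12 telocentric
chromosomes whose lengths are the printed per-chromosome sizes divided by
10 (~55.5 Mb total; the division preserves the length ratios while keeping
10,000-permutation runs interactive), gene starts from a
background-plus-ridge inhomogeneous point process calibrated so the
genome-wide mean is 33.6 genes/Mb, per-kilobase GC of `0.408 +
gc_coupling × (normalised local gene intensity)` plus clipped Gaussian
noise with sequences sampled base-by-base from tile GC, an exact scaffold
tiling with random orientations, tri-species anchor maps in which each
true adjacency survives with probability `1 − rearrangement_rate` per
species (broken adjacencies relocate the downstream segment as a block, so
exactly the sampled adjacencies break), and FISH distances as means of ≥ 5
truncated-normal per-cell draws (`fish_noise_sd = 0.02` by default — the
study reports no measurement-error figure, so this is a free parameter
swept in tests, not an estimate of the study's precision). Each generator
draws from its own stream derived from the master seed by a fixed offset,
so adding one never perturbs the others; a fixed seed gives byte-identical
output.

Defaults not stated by the study, chosen once as field-plausible: 2 ridge
blocks of 500 kb per chromosome at 3× background intensity (ridges then
cover ~22% of the genome and the background rate is solved from the 33.6
genes/Mb target), `gc_coupling = 0.08` (≈ 8 GC percentage points between
ridge interior and background, the order of isochore-scale variation),
mean scaffold length 210 kb (the study's scaffold N50 scaled by 10).

What passing tests on this generator shows — and what it does not: the
statistics are exercised under ideal sampling (Poisson genes, exact
same-chromosome answers, no probe failures, no repeats or assembly
errors, uniform read sampling without indels or quality structure). Real
annotations have gene-length and clustering structure beyond a two-level
intensity; real FISH has outliers and failed hybridizations; real read
sets have coverage biases. Recovery and calibration results here validate
the algorithms and their implementations, not the difficulty of any
particular real genome, and the study's own printed full-scale numbers
(90 genome ridges, the 71-gene window, its Table 1, the 806-Mb estimate)
are deliberately out of reach at desk scale.

## Problem sizes and numerical choices in the test suite

The suite runs everything at desk scale: permutation calibration uses 200
null genomes × 1,000 permutations at the 0.2-Mb window of the cutoff grid
with `c_h = 6` (the per-window mean), where the null count is diffuse
(~20 support points) and a Kolmogorov–Smirnov uniformity check is
meaningful; power uses 50 replicates at the default 3× planted intensity
and the headline 1-Mb/40/5 settings; Cafs recovery runs all 12
chromosomes at zero noise and 20 single-chromosome replicates of ~25
scaffolds at `fish_noise_sd = 0.02` with 5 cells and resolution twice the
standard error of the mean; genome-size recovery uses a 1-Mb genome at
30× with 100-bp reads, clean and at 1% error. Ties in rank tests get
average ranks; truncated-normal FISH noise redraws out-of-range cells;
GC clips to (0.01, 0.99) to keep both pair probabilities positive.
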