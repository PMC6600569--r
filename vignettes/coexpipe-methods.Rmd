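---
title: "Methods: no-replicate time-course co-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: no-replicate time-course co-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpipe)
```

This vignette is the package's account of the statistical methods it
implements, the modelling assumptions behind them, the parameters a user may
want to move, and the limits of what the test suite demonstrates.

## The setting

The target design is a short hormone-response time course in a non-model
plant: one RNA-seq library per time point (e.g. 0, 2 and 4 hours after a
gibberellin treatment of lily shoot apices), no biological replicates, gene
models from a de novo assembly, and validation by qPCR and hormone assays.
With a single library per condition, replicate-based tools (DESeq2, limma,
edgeR with estimated dispersions) have nothing to estimate dispersion from;
the classical alternative is an exact count test that models sequencing as
Poisson sampling from each library.

## Normalisation and fold changes

`compute_rpkm()` applies the standard reads-per-kilobase-per-million
transform `1e9 * C / (N * L)`. The library size `N` is the total mapped
reads; when not supplied it defaults to the column sum of the count table
(the mapped-read totals of a published study are rarely recoverable).
Fold changes are computed on pseudocounted RPKM,
`log2((rpkm_later + 1) / (rpkm_earlier + 1))` by default. The pseudocount
of 1 RPKM unit keeps genes expressed in only one condition finite and
shrinks ratios of very low-abundance genes; it can be set to 0 or the ratio
can be computed on raw counts (`ratio_on = "counts"`). Comparisons are
always *later over earlier*, and all three ordered pairs of a three-point
series are evaluated (`2h_vs_0h`, `4h_vs_0h`, `4h_vs_2h`).

## The exact test and its calibration

`ac_pvalue()` implements the conditioned count test: given `x` reads in a
library of `N1`, the probability of `y` reads in a library of `N2` under a
shared underlying abundance is

$$P(y \mid x) = \binom{x+y}{y} q^{y} (1-q)^{x+1}, \qquad q = \frac{N_2}{N_1+N_2},$$

which is the negative-binomial pmf with size `x + 1` and success
probability `1 - q`. Tail sums give one-sided p-values and the two-sided p
is `min(1, 2 * min(tails))`. Numerically, tails are accumulated in log
space with a streaming log-sum-exp; the open upper tail is truncated once
the running term falls below 1e-16 of the accumulated sum (past the
distribution's mode, so truncation error is bounded by a geometric
remainder). Results are clamped at the smallest positive double so extreme
contrasts remain in `(0, 1]`. The test suite checks this implementation two
independent ways: brute-force summation of the series in plain arithmetic,
and the `pnbinom()` closed form.

Two properties deserve explicit statement:

* **Orientation.** The formulation conditions on the first count and sums
  tails over the second, so swapping `(x, N1)` with `(y, N2)` gives a
  *different* (closely agreeing, but not identical) test — even at
  `N1 = N2`. The package always conditions on the earlier library. The
  property tests assert the two orientations agree within an order of
  magnitude and that a symmetric observation (`x = y`, equal libraries) is
  exactly `p = 1`.
* **Poisson assumption.** The test models technical (sampling) variance
  only. On data with replicate-scale biological overdispersion it is
  anticonservative — which is precisely why the no-replicate design it
  serves cannot separate biological variability from treatment effect. The
  null-calibration simulations therefore draw counts with single-library
  technical noise (see the generator section), where the flagged fraction
  stays well below the nominal 5%.

Multiple testing is controlled per comparison with Benjamini–Hochberg
(`bh_fdr()`, a validated wrapper over `stats::p.adjust`); each library pair
is tested separately, so each gets its own correction. Plain Hochberg
step-up is available behind `method = "hochberg"` for compatibility with
tools that label their FDR column that way.

## DEG filters

`call_degs()` flags a gene in a comparison iff all three hold, with
*inclusive* boundaries: `q <= max_fdr`, `|log2 ratio| >= min_abs_log2`,
and `max(RPKM over the two samples) >= min_rpkm`. The max-over-samples
reading of the expression filter keeps genes switched fully on or off by
the treatment eligible — a min-over-samples reading would discard exactly
the most interesting genes. Three presets are provided: the strict default
`(2, 0.05, 2)`, an expression-unfiltered variant `(0, 0.05, 2)`, and the
looser network-gene set `(0, 0.05, 1.5)` used to select genes for
co-expression analysis.

## Trend profiles

Each DEG's three-point series yields two transitions; a transition is `up`
if the pseudocounted log2 change is at least `flat_threshold` (default 1
log2 unit, i.e. 2-fold — chosen to mirror the spirit of the fold-change
filter; there is no canonical value), `down` at or below the negative
threshold, else `flat`. Coding down/flat/up as 0/1/2, the pair
`(s1, s2)` maps to `3*s1 + s2`, the flat–flat cell is excluded, and higher
cells shift down one — a fixed bijection onto profiles 0–7 in which, e.g.,
profile 6 is *up then stable* and profile 7 *continuously rising*.
Genes flat in both transitions are left unassigned rather than forced into
a profile.

Mirroring a series (taking reciprocals of its values, i.e. negating every
log ratio) maps profile *i* to *7 − i* for every profile; this is the
symmetry the test suite asserts by enumeration. Reversing a series in
*time* is a different involution (it maps up–flat to flat–down, 6 to 3),
which is easy to conflate with mirroring; the enumeration tests pin the
implemented convention down.

Per-profile significance is a gene-wise label permutation (STEM-style):
time labels are shuffled independently per gene, profiles recounted, and
`p` is the fraction of permutations whose count reaches the observed count.
With three time points there are only 6 orderings per gene, so the
implementation classifies each gene once under each ordering and then
draws orderings per permutation — 1000 permutations (the default) cost
almost nothing. The permutation p has resolution `1/n_permutations`.

## HRR network construction

Pearson correlation is computed on `log2(RPKM + 1)` (variance
stabilisation; correlations on raw RPKM would be dominated by the largest
values). Genes with zero variance get correlation 0 and a warning rather
than an error — on real filtered data they are rare, and dropping them
silently would desynchronise gene sets.

Each gene ranks all others by descending correlation (rank 1 = best
neighbour; negative correlations rank last), ties broken by ascending gene
order so results are exactly reproducible. The highest reciprocal rank
`HRR(A,B) = max(rank_A(B), rank_B(A))` is symmetric; edges with
`HRR <= 30` (inclusive) survive, weighted `1/HRR` — so mutual best
neighbours weigh 1, and the conventional reporting weights at HRR scores
5/15/25 are 0.2, 0.067 and 0.04 after rounding to three decimals.

`network_stats()` reports the analyser-style topology summary: mean local
clustering coefficient over nodes of degree ≥ 2, mean degree
("average neighbours"), density `mean degree / (n − 1)`, degree
heterogeneity (coefficient of variation of degree), degree centralization
`n/(n−2) · (max_degree/(n−1) − density)`, connected components, isolated
nodes, diameter and radius as the max/min node eccentricity within
components over non-isolated nodes, the count and percentage of ordered
connected node pairs, and the characteristic path length (mean hop distance
over those pairs). Distances are unweighted hop counts. One caveat worth
recording: a radius of 1 is impossible alongside a diameter of 7 under any
single eccentricity definition (a radius-1 node would see every other node
in one hop, capping the diameter at 2), so published tables pairing those
two numbers cannot be reproduced exactly; this package reports the radius
under the stated definition.

**Three-point correlations are near-degenerate.** With `n = 3` samples the
null distribution of Pearson r is arcsine-shaped,
`P(|r| > 0.99) = (2/π)·acos(0.99) ≈ 0.090` — almost a tenth of random gene
pairs look near-perfectly correlated. HRR ranking tolerates this better
than a raw correlation threshold (ranks are relative), but the package
still warns whenever fewer than 4 samples enter `pearson_matrix()`. The
null-network property test asserts the simulated null stays within 3× the
analytic expectation above.

## Markov clustering

`mcl_cluster()` is a from-scratch MCL over sparse matrices: the weighted
adjacency gains one self-loop per node equal to its maximum incident edge
weight (damps odd-cycle periodicity; 1 for isolated nodes), is normalised
column-stochastic, then alternates expansion (matrix power, default 2) and
inflation (elementwise power, default 1.6; entries below 1e-5 pruned;
columns renormalised) until the largest elementwise change is below 1e-6 or
100 iterations elapse — non-convergence returns the current clustering
with a warning, never silently. Clusters are read off the limit matrix's
attractor structure: nodes with positive return flow are attractors,
attractors exchanging flow form systems, and every node joins the system(s)
it flows into. The rare node reached by several systems is assigned to the
largest cluster, ties to the smallest cluster index — a deterministic
resolution of MCL's occasional overlaps. Cluster ids are renumbered by
decreasing size. Clusters with at least `min_module_size = 15` members are
flagged as modules (matching the convention that reported module sizes
start at 15); smaller clusters keep their assignments with
`is_module = FALSE`.

Exactness properties asserted by the suite: disjoint cliques are recovered
exactly at any inflation in [1.2, 5]; complete graphs collapse to one
cluster; clusters never span connected components; the flow matrix stays
column-stochastic through every inflation (1e-10); clustering is invariant
under node relabeling; and a well-separated three-block weight matrix
(within-block weight 1, between 1/30) is recovered with adjusted Rand
index 1.0 at inflation 1.6.

**Granularity on synthetic block networks.** With three time points, the
neighbour ranking *inside* a planted module is ordered purely by count
noise, so a module's internal 1/HRR flow graph acquires arbitrary
nearest-neighbour sub-structure. At inflation 1.6 MCL sometimes resolves
that sub-structure into sub-modules; on block-structured synthetic networks
the end-to-end recovery checks therefore run at the coarser inflation 1.2,
while 1.6 remains the default and the appropriate setting for real,
hub-structured HRR networks (and for the well-separated block-weight case,
where it is exact). This is a statement about the synthetic geometry, not
about the algorithm: a real time course with more samples gives
correlations—and hence ranks—with genuine structure.

## Enrichment

`hypergeom_enrichment()` scores each (module, term) pair with the upper
hypergeometric tail `P(X >= k)` for `k` term carriers among the module's
`n` background genes, given `K` carriers among `N` background genes
(`stats::phyper`; the exhaustive combinatorial sum is the test oracle).
Terms with fewer than `min_mapped = 2` entries in a module are excluded
*before* testing — singleton hits are uninformative and would dilute the
FDR. Adjustment is per module (BH by default), significance at `q < 0.05`.
The background defaults to the annotation universe; restricting it to the
network genes is a one-argument change and the right choice when asking
"what distinguishes this module *within the network*". Terms are flat
identifiers: ontology parent-propagation, if wanted, is a pre-processing
step on the two-column map.

## Assay arithmetic

`ddct()` follows Livak's method exactly: replicates averaged on the Ct
scale, `dCt = Ct_target − mean(Ct_references)` per condition (several
reference genes combine by arithmetic mean of Ct, equivalent to the
geometric mean of their linear quantities), `ddCt` against the calibrator
condition, relative expression `2^-ddCt` — identically 1 for the
calibrator, and invariant under condition-wide Ct shifts.
`hormone_ratio()` is elementwise division of two content series sharing a
time grid, refusing zero denominators by time point. Published hormone
content values are not asserted anywhere in the tests: the source
sentences are grammatically ambiguous about which value belongs to which
time point, and the bundled `synthetic_*` fixtures are exactly that —
synthetic.

## The synthetic-data generator

`simulate_counts()` draws from a two-tier model:

* **Latent biology (log2 scale).** Each gene has a baseline
  `N(5, 2)` log2 abundance. Module members add a shared per-time-point
  profile plus `N(0, within_noise_sd)` noise (default 0.25 log2 units).
  A planted DE gene's later time point sits exactly `log2_fc` above its
  earlier one.
* **Technical counts.** Relative abundance is the length-weighted
  transcript mass `2^latent × length` normalised per sample; expected
  counts are `library_size × relative abundance`; observed counts are
  negative binomial with `size = nb_dispersion`, default 1000 (≈3% extra
  CV over Poisson). The default models the *technical* noise of a single
  library — the design simulated here has one library per time point, so
  there is no biological replicate variance to emulate; users simulating
  replicate designs should lower `size` to the 10–50 range conventional
  for biological variance.

Gene lengths are uniform on 200–3000 bp and carried into the count table so
RPKM is well-defined. All draws come from one RNG stream seeded once per
call in a fixed order (lengths, baselines, module noise, counts
time-point-major), making every output a pure function of (config, seed);
the reproducibility tests assert bit-identical reruns. The expected-count
contract (mean count = library size × implied relative abundance) is
checked by reconstructing the latent model under the same seed and
comparing 200 technical replicate columns against it.

`simulate_annotation()` gives each planted module one dedicated term
carried by members with probability `enriched_rate` and by everyone else
with `background_rate`; remaining terms are pure background. With the
default test rates (0.8 vs 0.1) the planted term's hypergeometric tail is
below 1e-6 in ≥95% of seeds for a 50-gene module in a 1000-gene universe.

**What the generator does not emulate:** read-level artefacts (GC bias,
mappability, positional bias), isoforms, library-preparation batch
effects, correlated background structure, or annotation hierarchies.
Passing tests demonstrate the pipeline's statistical machinery is correct
and calibrated under the stated model — not that the model captures every
feature of real lily RNA-seq data.

## Pipeline and problem sizes

`run_all()` executes input → RPKM → DEGs → Venn → trends → network →
topology → MCL → composition → enrichment, writing each stage as TSV/JSON
plus a manifest of all effective parameters, the seed and per-stage row
counts. Reruns with identical config and seed are byte-identical (the
manifest deliberately records no timestamps). A failing stage aborts with
the stage named; earlier outputs are kept.

The test suite and the acceptance script run on deliberately compact
problems — a few hundred genes, libraries of 1e5–1e6 reads, 20–100
simulation seeds per Monte-Carlo check — sizes at which every quantity is
stable while the full suite completes in well under a minute per file. All
thresholds asserted in the tests (recovery ≥ 90%, top-rank ≥ 95%, null
rate ≤ 5%, ARI = 1.0) were verified to hold with wide margins across
independent seed ranges, not at the boundary.

## Known limitations

* The exact test inherits the no-replicate design's core weakness: it
  cannot distinguish biological variability from treatment effect, and it
  is anticonservative under biological overdispersion.
* Three time points make Pearson correlations near-degenerate (arcsine
  null); HRR ranks mitigate but do not remove this. Results sharpen
  quickly with more time points, which the generator and all downstream
  code accept (`n_timepoints >= 2`; trend profiling is specific to 3).
* Venn partitioning is fixed at three sets — the natural shape of a
  three-point design's pairwise comparisons.
* MCL granularity on rank-weighted graphs depends on the inflation
  parameter; there is no universal value, and the default 1.6 is a
  convention carried from published practice, not an optimum.
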