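---
title: "Integrating chromatin binding with inducible EMT expression programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating chromatin binding with inducible EMT expression programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emtarget` integrates two genome-scale readouts of an
epithelial-to-mesenchymal transition (EMT) experiment — four-arm expression
profiling (baseline/stimulated × mock/knockdown siRNA) and chromatin
binding regions for one or two factors — to classify which inducible genes
a chromatin regulator drives directly, which indirectly, and how its
binding relates to cancer-stem-cell (CSC) expression programs. This
vignette documents the statistical model, the conventions and tunable
parameters, the synthetic-data generator that backs the test suite, and
the package's known limitations.

## Expression calling

All expression values are log2 intensities. Three probe-level calls share
one magnitude threshold, `de_log2 = 0.5`:

* **EMT direction** — induced iff `stim_mock − baseline_mock > 0.5`,
  repressed iff `< −0.5`, otherwise unchanged. Inequalities are strict: a
  difference of exactly 0.5 is unchanged, because the rule is "greater
  than" a half log2 unit.
* **Knockdown sensitivity (reversibility)** — for induced probes,
  `stim_sirna − stim_mock < −0.5`; for repressed probes `> +0.5`; unchanged
  probes are never sensitive. The field reports reversibility without a
  formula, and two readings are possible: a fixed-magnitude shift opposing
  the EMT change (used here, reusing the only stated threshold), or a
  return to within the threshold of the baseline level. We chose the
  fixed-magnitude contrast because it is symmetric, needs no baseline arm,
  and reuses the single published cutoff; the baseline-return reading can
  be emulated by calling `call_emt_direction()` on the knockdown arms.
* **CSC bias** — `csc_log2 − ncsc_log2` against the same ±0.5 band, giving
  `csc`, `ncsc` or `none`. No threshold is published for this contrast; we
  reuse 0.5 and expose it as a parameter.

Reversibility percentages are reported per direction as
`100 × n_reversible / n_total`, rounded half away from zero to one decimal
(the convention of the printed percentages these summaries mirror; base R's
`round()` would round half to even). A direction with no probes reports
`NA`, never 0.

## Region annotation

Intervals are 0-based half-open everywhere — in memory, in BED/bedGraph
files, and in every overlap computation. A region's *center* is the floored
midpoint, so odd widths resolve deterministically.

* **Filtering** keeps regions with `tag_count ≥ 12.2` (inclusive), where
  tag counts are normalized reads on the reads-per-10-million scale of the
  upstream peak caller. The value is a plain parameter.
* **Nearest TSS**: the gene minimizing |center − TSS| on the same
  chromosome (cross-chromosome distance is undefined); exact ties go to the
  lexicographically smallest gene id, which makes the assignment
  reproducible regardless of input order. The signed distance is negative
  when the center lies upstream of the TSS in the gene's direction of
  transcription. Regions on a chromosome with no genes receive the sentinel
  `no_gene` and are excluded from distance statistics.
* **Feature class**: the highest-priority feature overlapping the center,
  with priority promoter > 5utr > 3utr > exon > intron > tts > ncRNA >
  pseudo > rRNA > intergenic. The promoter window is strictly less than
  1 kb either side of a TSS; a center in no interval is intergenic, so the
  labels partition any region set.
* **Chromatin state**: the label of the state segment sharing the most bp
  with the region; exact ties go to the leftmost segment and zero overlap
  yields `none`. Overlapping segments in a state track are an input error,
  not a silent choice.
* **Distance bins** report, per gene subset and cumulative bin bound, the
  proportion of genes with at least one region center within the bound —
  monotone non-decreasing by construction. Distances use region centers
  throughout, matching the center-based nearest-TSS convention (the
  alternative, edge distance, would only shrink every distance by up to
  half a region width).
* **TSS metaprofiles** sum per-bp coverage in 100 bp bins across ±1.5 kb
  windows (30 bins), orienting each window by gene strand; minus-strand
  windows are reflected about the TSS base so bin 1 is always the most
  upstream bin. Genes whose window leaves the chromosome are skipped with
  a warning rather than padded.

## Target classification and enrichment statistics

A gene is a **direct target** when it is knockdown-sensitive and some
region center lies within 5 kb of its TSS, inclusive ("within 5 kb");
sensitive genes without such a region are **indirect**; insensitive genes
are **untargeted**, regardless of binding — sensitivity gates targethood.
The three classes partition the gene universe.

`fisher_exact_2x2()` computes the conventional two-sided exact test by
point-probability ordering: the sum of hypergeometric probabilities of all
tables with the observed margins whose probability is at most that of the
observed table, compared with a relative tolerance of 1e-7 so that
floating-point noise cannot drop a tied table. A zero margin admits only
one arrangement and returns p = 1 with a warning. The test suite verifies
the implementation against exhaustive enumeration for every 2×2 table with
total ≤ 30 and against `stats::fisher.test()`.

`hypergeom_enrichment()` reports the upper tail P[X ≥ overlap] for each
category, the expected overlap nK/N, and Benjamini–Hochberg adjusted
values alongside — never substituted for — the raw p-values. CSC
contingency analyses (`csc_proximity_bias()`, `csc_sensitivity_bias()`)
build the 2×2 tables per distance bin or per direction and reuse the exact
test; degenerate tables (no biased genes, no sensitive genes) report `NA`
markers rather than a 0 or 1 that could be mistaken for evidence.

## Co-binding

Two regions co-bind when their half-open intervals share at least one bp.
Chains of overlaps merge transitively into one merged region (the union
span), which is standardized to a 300 bp window centered on the floored
merged midpoint; windows that would start below position 0 are clipped
with a warning and flagged. Tag counts per factor come either from region
tag counts apportioned by the fraction of the source region overlapping
the window (deterministic and conservative), or from a coverage track
summed over the window. Correlations are plain Pearson r on the raw
counts within the standardized window — no log transform is applied
because none is stated for this statistic, and the standardized window
(rather than original peak widths) is used because the standardization
exists precisely to make tag counts comparable; an original-width mode is
available by passing the un-standardized intervals. Fewer than three
regions or a constant count vector yield `NA`, never a silent 0.

## Signal metrics

Peptide-array hits are signals at or above mean + 2 SD of all peptide
signals on the array. The SD is the population SD (divide by n); with a
couple of hundred peptides the sample/population distinction is
negligible, and the population form matches a threshold computed from the
array itself rather than an estimate for unseen peptides — `sd_type`
switches it. When every signal is equal the SD is 0; the call is flagged
degenerate and no peptide is positive, since a threshold equal to the
common value would otherwise declare *every* peptide a hit.

TNFI/TCFI (total nuclear/cell fluorescence intensity) is the masked
intensity sum minus a scalar per-image background estimate times the mask
area. The background scalar is an input (the generator estimates it as the
constant level outside the cell mask); a negative corrected intensity is
reported with a warning, never clamped. Pixel colocalization is Pearson r
over masked pixels, requiring at least 3 pixels and non-constant channels.
The phenotype partition maps intensities to classes 1/2/3 with strict
outer inequalities (`> hi`, `< lo`) and an inclusive moderate band, so a
value exactly at a threshold is moderate — matching the printed
"> 1100", "500–1100", "< 500" bands (and 1500/600 for the total-protein
channel).

Motif scanning uses a small residue-class notation (`[ST]x[KR]`; `x` is a
wildcard) over the 20-letter amino-acid alphabet and reports all
occurrences including overlapping ones. No default kinase motif is
shipped: the consensus definition is not published alongside the analysis
this package implements, so patterns are always user-supplied.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every generator draws from a
named substream of the root seed (`substream_seed()`), so adding or
re-ordering generators never perturbs another generator's output, and
identical configuration plus seed gives byte-identical results.

Defaults, chosen once as the simulated study conditions:

* 1000 genes on two chromosomes (120 + 80 Mb), TSSs uniform with a 10 kb
  margin, balanced strands; one probe per gene (the probe/gene distinction
  is kept in the types but collapsed in simulation to make truth
  bookkeeping unambiguous).
* 30% of genes induced and 30% repressed on stimulation; 42% of induced
  and 24% of repressed genes knockdown-sensitive — the reversibility rates
  of the experiment the pipeline was built around. Effect sizes are
  N(2.0, 0.25²) log2 units and every arm receives independent N(0, 0.1²)
  noise; no effect-size distribution is published for these contrasts, so
  these are realistic defaults, tunable, not calibrated to any deposited
  dataset. With `noise_sd = 0` all planted contrasts are exact and every
  downstream caller must recover truth exactly — the end-to-end zero-noise
  test.
* 2000 factor-A peaks of 300 bp: 40% centered N(0, 500²) bp from the TSS
  of a random sensitive gene, 30% near a random gene's TSS (binding
  concentrates at promoters genome-wide), the rest uniform. Tag counts are
  N(50, 10²) floored at 12.2 — simulated peaks represent regions that
  survived the upstream caller's enrichment filter, so counts sit at or
  above the filter value.
* The truth `direct` flag records the *realized* placement: a sensitive
  gene with a factor-A peak center within 5 kb of its TSS, whether that
  peak was aimed at it or landed there by chance. A uniformly placed peak
  that falls at a sensitive promoter is a genuine proximal binding event
  in the generated data, and recovery tests must treat it as such.
* Factor-B peaks co-bind promoter-proximal factor-A peaks at rate 0.5
  (0.3 elsewhere), coinciding exactly with their partner; their tag counts
  are bivariate-Gaussian with planted correlation 0.64 at
  induced-sensitive-gene promoters, 0.14 at other promoters and 0
  elsewhere — the nested correlation structure the co-binding analysis is
  designed to expose. Exact coincidence matters: partially overlapping
  pairs would share an overlap fraction with the standardized window,
  multiplying both counts by a common factor and inflating every zone's
  correlation. B-only peaks are placed uniformly and re-sampled on any
  overlap with factor A, so "B-only" is a guarantee.
* Chromatin states tile each chromosome with 5–50 kb segments from a fixed
  seven-label vocabulary (`chromatin_state_vocabulary()`).
* The peptide array has 201 peptides tiling an abstract protein at a
  3-residue step, 15 of them hits at signal 500 against a N(100, 10²)
  background — the array scale of the kinase-profiling experiment. With
  the hit signal at the background mean instead, hits are statistically
  indistinguishable and recovery is *not* expected; the suite documents
  this confound case.
* Cell images are 64×64 grids with concentric circular cell and nuclear
  masks, bivariate-Gaussian channels with planted pixel correlation 0.38
  inside the cell mask and a constant background outside.

`simulate_nested_cobinding()` is a separate, deliberately clean benchmark
for the nested-correlation ordering: genes spaced 100 kb apart and exactly
one co-bound pair per site, with the three zone correlations planted on
disjoint sets. In the full generator, several peaks can target the same
gene and merge into chains whose apportioned counts mix zones, which is
realistic but makes the pooled correlations composition-dependent; the
clean benchmark removes that nuisance so the ordering assertion tests the
analysis chain, not the accident of peak placement.

### What the generator does and does not emulate

It reproduces the *statistical structure* the pipeline consumes: planted
direction/sensitivity/CSC labels with thresholded Gaussian contrasts,
peaks concentrated near sensitive TSSs, promoter-restricted co-binding
with nested correlation, a few strong array hits, and correlated pixel
pairs. It does not simulate raw reads, fragment-length or duplicate
structure, probe-level hybridization, RMA normalization, multi-probe
genes, cell segmentation, or spatial intensity gradients. Passing
recovery tests therefore demonstrates that the integration logic is
correct under the stated noise model — not that the pipeline is robust to
microarray normalization artifacts or peak-caller idiosyncrasies.

## Numerical choices and problem sizes

Exact-test comparisons use a 1e-7 relative tolerance on point
probabilities (tied tables must not be dropped by floating-point noise);
oracle agreement is asserted to 1e-10. Correlation recovery is asserted
within Fisher-z 99% intervals at the simulated sample size. The test suite
and acceptance script run at desk scale — 1000 genes, 2000 peaks, 500
co-bound pairs per planted correlation, enumeration oracles over all 2×2
tables with total ≤ 30 and universes up to 12 — sizes at which the
exhaustive oracles are exact and the whole suite completes in about a
minute.

## Limitations

* The reversibility rule is one of two defensible readings of an
  informally stated criterion (see above); both are easy to express with
  the exported callers, but summaries default to the fixed-magnitude form.
* Genome-wide numbers from the original experiments (region counts,
  pooled correlation magnitudes, promoter fractions, contingency
  p-values) depend on the deposited raw data and annotation versions and
  are not reproduced at desk scale; the package's claims are about the
  correctness of the integration logic, verified against planted truth
  and enumeration oracles.
* Probe-to-gene collapsing beyond "first probe wins" and
  moderated-variance differential-expression statistics are out of scope;
  the callers operate on whatever normalized table they are given.
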