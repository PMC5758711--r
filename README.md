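# emtarget

Integration of chromatin-factor binding with inducible gene-expression
programs during the epithelial-to-mesenchymal transition (EMT).

## The problem

When epithelial breast-cancer cells are driven into EMT, thousands of
microarray probes change expression, and a chromatin regulator such as the
histone demethylase LSD1 may be responsible for part of that program. Two
genome-scale readouts have to be combined to say which part:

* **expression arms** — log2 intensities for each probe under
  baseline/stimulated conditions crossed with mock/knockdown siRNA, plus
  optional cancer-stem-cell (CSC) versus non-CSC compartment profiles;
* **binding regions** — ChIP-seq peaks for the regulator (and optionally a
  second factor, e.g. the kinase PKC-θ), with normalized tag counts.

`emtarget` implements the integration analysis for this design:

* a probe is **induced**/**repressed** when |log2 change| of the stimulated
  versus baseline mock arms exceeds 0.5 (strict), and **knockdown-sensitive**
  when the siRNA arm reverses the change by more than the same threshold in
  the opposing direction;
* regions are filtered at ≥ 12.2 normalized reads, assigned a nearest TSS
  with a strand-signed distance (center-based, lexicographic tie-break), a
  genomic feature class (promoter = strictly < 1 kb from a TSS), and a
  chromatin-state label by maximal base-pair overlap;
* a sensitive gene with a region center within 5 kb of its TSS (inclusive)
  is a **direct target**; sensitive genes without one are **indirect**;
* co-bound regions of two factors (any overlap, half-open intervals) are
  merged transitively, standardized to 300 bp, and their per-factor tag
  counts correlated (Pearson r) over nested subsets — all regions, those
  within 1 kb of a TSS, those at sensitive-gene promoters;
* enrichment and contingency statistics use the hypergeometric upper tail
  P[X ≥ k] and the two-sided Fisher exact test by point-probability
  ordering, with Benjamini–Hochberg values reported alongside raw p;
* peptide-array kinase profiling calls a phospho-hit when the normalized
  mean signal is ≥ mean + 2 SD of all peptides; fluorescence quantification
  provides TNFI/TCFI (masked intensity sum minus background × area),
  pixel-level colocalization (Pearson r in [−1, 1]) and the intensity
  phenotype partition (high/moderate/low).

A first-class synthetic-data module (`sim_config()`, `simulate_*`)
generates genomes, expression tables, peak sets, chromatin states, peptide
arrays and paired-channel cell images with planted, recorded ground truth,
so every stage has a recovery test without any external download.

## Worked example

```r
library(emtarget)

cfg <- run_config(simulate = sim_config(seed = 42), outdir = "demo", seed = 42)
report <- run_pipeline(cfg)

report$reversibility
#>   direction n_total n_reversible percent
#> 1   induced     320          136    42.5
#> 2 repressed     300           70    23.3

report$counts[c("n_genes", "n_peaks_a", "n_direct", "n_indirect")]
#> $n_genes   [1] 1000
#> $n_peaks_a [1] 2000
#> $n_direct  [1] 205
#> $n_indirect [1] 1

report$cobinding$correlations
#> $all                [1] 0.404
#> $promoter           [1] 0.435
#> $promoter_sensitive [1] 0.466
```

Of 1000 simulated genes, 320 probes are induced on stimulation and 136
(42.5%) revert on knockdown — the generator plants a 42% sensitivity rate
among induced genes, so the caller recovers it. 205 of the 206
called-sensitive genes have a binding region within 5 kb of their TSS and
are classified direct. The co-binding tag correlation rises as the region
set narrows from all co-bound regions to promoter-proximal ones to those at
sensitive-gene promoters, reflecting the promoter-restricted co-binding the
generator plants. Per-stage tables (`calls.tsv`, `annotations_a.tsv`,
`targets.tsv`, `cobound_merged.bed`, `truth.json`, `report.json`) are
written to the output directory.

A thin command-line wrapper is installed at
`inst/scripts/run-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run-pipeline.R", package="emtarget"))')" \
    --config run.yaml
```

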