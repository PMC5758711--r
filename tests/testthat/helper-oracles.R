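# Independent oracles and small fixture builders used across test files.

make_genes <- function(tss, chrom = "chr1", strand = "+", ids = NULL) {
  n <- length(tss)
  data.frame(
    gene_id = ids %||% sprintf("g%02d", seq_len(n)),
    chrom = rep_len(chrom, n), tss = tss, strand = rep_len(strand, n),
    stringsAsFactors = FALSE
  )
}

make_regions <- function(start, end, chrom = "chr1", tags = 20, ids = NULL) {
  n <- length(start)
  data.frame(
    chrom = rep_len(chrom, n), start = start, end = end,
    region_id = ids %||% sprintf("r%02d", seq_len(n)),
    tag_count = rep_len(tags, n), stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All-pairs nearest-TSS oracle: scans every gene for every region, applying
# the same-chromosome restriction, the minimum absolute distance rule and
# the lexicographic gene-id tie-break.
brute_force_nearest <- function(regions, genes) {
  center <- floor((regions$start + regions$end) / 2)
  out <- data.frame(region_id = regions$region_id,
                    nearest_gene_id = "no_gene",
                    signed_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- abs(center[i] - g$tss)
    cand <- g[d == min(d), , drop = FALSE]
    pick <- cand[order(cand$gene_id)[1L], ]
    raw <- center[i] - pick$tss
    out$nearest_gene_id[i] <- pick$gene_id
    out$signed_distance[i] <- if (pick$strand == "-") -raw else raw
  }
  out
}

# Exhaustive Fisher oracle: enumerates every 2x2 table with the observed
# margins, computing point probabilities from binomial coefficients
# (conditioning on the column margin, a different route than dhyper).
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- choose(r1, a_vals) * choose(n - r1, c1 - a_vals) / choose(n, c1)
  p_obs <- choose(r1, tab[1L, 1L]) * choose(n - r1, c1 - tab[1L, 1L]) /
    choose(n, c1)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Exhaustive hypergeometric tail oracle: enumerates all C(N, n) draws of a
# query from the universe and counts those overlapping the category by at
# least `ov` elements.
hyper_tail_oracle <- function(N, K, n, ov) {
  if (n == 0L) return(as.numeric(ov <= 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= ov)
}

fisher_z_bounds <- function(rho, n, level = 0.99) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tanh(atanh(rho) + c(-1, 1) * z / sqrt(n - 3))
}

# Run the co-binding chain (overlap, merge, standardize, count) and return
# per-merged-region counts plus the merged table.
run_cobind_chain <- function(set_a, set_b, width = 300L) {
  ov <- overlap_regions(set_a, set_b)
  merged <- merge_and_standardize(set_a, set_b, ov, width)
  list(merged = merged,
       counts_a = count_tags(merged, set_a, mode = "regions"),
       counts_b = count_tags(merged, set_b, mode = "regions"))
}
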