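test_that("region filtering keeps the inclusive 12.2 boundary", {
  regs <- make_regions(c(0, 1000, 2000), c(300, 1300, 2300),
                       tags = c(12.2, 12.1, 30.0))
  regs$tag_count <- c(12.2, 12.1, 30.0)
  out <- filter_regions(regs)
  expect_equal(out$region_id, c("r01", "r03"))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(nrow(filter_regions(regs, min_tags = 0)), 3L)
  empty <- filter_regions(regs, min_tags = 100)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_removed"), 3L)
})

test_that("nearest TSS assignment follows distance, tie-break and sign rules", {
  genes <- make_genes(c(1000, 3000), ids = c("g1", "g2"))
  out <- nearest_tss(make_regions(1200, 1500), genes)
  expect_equal(out$nearest_gene_id, "g1")
  expect_equal(out$signed_distance, 350)

  # equidistant: lexicographically smallest gene id wins
  genes2 <- make_genes(c(1000, 2000), ids = c("g1", "g2"))
  out2 <- nearest_tss(make_regions(1400, 1601), genes2) # center 1500
  expect_equal(out2$nearest_gene_id, "g1")

  # upstream of a plus-strand TSS is negative
  out3 <- nearest_tss(make_regions(800, 1001), genes) # center 900
  expect_equal(out3$signed_distance, -100)

  # minus-strand flips the sign
  genes4 <- make_genes(1000, strand = "-", ids = "g1")
  out4 <- nearest_tss(make_regions(800, 1001), genes4)
  expect_equal(out4$signed_distance, 100)

  # chromosome without genes gets the sentinel
  out5 <- nearest_tss(make_regions(100, 400, chrom = "chrX"), genes)
  expect_equal(out5$nearest_gene_id, "no_gene")
  expect_true(is.na(out5$signed_distance))
})

test_that("nearest TSS matches the all-pairs brute-force oracle", {
  for (i in 1:20) {
    set.seed(1000 + i)
    n_g <- 120; n_r <- 150
    genes <- data.frame(
      gene_id = sample(sprintf("g%03d", 1:n_g)), # shuffled ids stress ties
      chrom = sample(c("chr1", "chr2"), n_g, replace = TRUE),
      tss = sample.int(5e4, n_g, replace = TRUE), # dense: duplicates likely
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      stringsAsFactors = FALSE
    )
    start <- sample.int(5e4, n_r, replace = TRUE)
    regions <- make_regions(start, start + sample.int(500, n_r, TRUE),
                            chrom = sample(c("chr1", "chr2"), n_r, TRUE),
                            ids = sprintf("r%03d", 1:n_r))
    expect_identical(nearest_tss(regions, genes),
                     brute_force_nearest(regions, genes))
  }
})

test_that("gene-to-region minimum distances mirror the region annotation", {
  genes <- make_genes(c(1000, 9000, 40000), ids = c("g1", "g2", "g3"))
  regs <- make_regions(c(1100, 8000), c(1300, 8200)) # centers 1200, 8100
  d <- gene_min_region_distance(genes, regs)
  expect_equal(unname(d), c(200, 900, 31900))
  # no regions on the gene's chromosome
  d2 <- gene_min_region_distance(make_genes(5, chrom = "chrZ"), regs)
  expect_true(is.na(d2))
})

test_that("feature classification honours priority and the strict 1 kb promoter", {
  genes <- make_genes(10000, ids = "g1")
  track <- data.frame(chrom = "chr1", start = c(9000, 20000),
                      end = c(12000, 21000),
                      feature = c("exon", "intron"),
                      stringsAsFactors = FALSE)
  # center 500 bp from the TSS and inside an exon: promoter wins
  expect_equal(classify_feature(make_regions(10400, 10601), genes, track),
               "promoter")
  # center exactly 1000 bp from the TSS: not promoter (strict), exon remains
  expect_equal(classify_feature(make_regions(10900, 11101), genes, track),
               "exon")
  # center in nothing: intergenic
  expect_equal(classify_feature(make_regions(50000, 50300), genes, track),
               "intergenic")
  # malformed track interval reports its line
  bad <- data.frame(chrom = "chr1", start = 10, end = 10, feature = "exon")
  expect_error(classify_feature(make_regions(0, 5), genes, bad), "line 1",
               class = "emtarget_input_error")
})

test_that("chromatin-state labels use maximal overlap with leftmost ties", {
  states <- data.frame(
    chrom = "chr1", start = c(0, 600), end = c(600, 1200),
    state = c("active_promoter", "repressed"), stringsAsFactors = FALSE)
  # region [200,700): 400 bp in the first segment, 100 in the second
  expect_equal(annotate_chromatin_state(make_regions(200, 700), states),
               "active_promoter")
  # fully outside
  expect_equal(annotate_chromatin_state(make_regions(5000, 5300), states),
               "none")
  # exact 50/50 split goes to the left segment
  expect_equal(annotate_chromatin_state(make_regions(500, 700), states),
               "active_promoter")
  overlapping <- data.frame(chrom = "chr1", start = c(0, 500),
                            end = c(600, 900), state = c("a", "b"))
  expect_error(annotate_chromatin_state(make_regions(0, 10), overlapping),
               class = "emtarget_input_error")
})

test_that("distance-bin proportions match the worked example and are cumulative", {
  genes <- make_genes(c(1e4, 1e5, 5e5, 9e5), ids = paste0("g", 1:4))
  # regions 200 bp from g1 and 8 kb from g2
  regs <- make_regions(c(1e4 + 50, 1e5 + 7850), c(1e4 + 350, 1e5 + 8150))
  d <- gene_min_region_distance(genes, regs)
  out <- distance_bin_proportions(d, list(all = paste0("g", 1:4)),
                                  bins = c(1e3, 1e4, 1e5))
  expect_equal(out$proportion, c(0.25, 0.50, 0.50))
  expect_true(all(diff(out$proportion) >= 0))

  none <- distance_bin_proportions(
    gene_min_region_distance(genes, regs[0, ]),
    list(all = paste0("g", 1:4)), bins = c(1e3, 1e4))
  expect_equal(none$proportion, c(0, 0))

  empty <- distance_bin_proportions(d, list(none = character()), bins = 1e3)
  expect_true(is.na(empty$proportion))
  expect_error(distance_bin_proportions(d, list(a = "g1"), bins = c(2, 1)),
               class = "emtarget_input_error")
})

test_that("distance-bin proportions agree with an exhaustive pairwise scan", {
  for (i in 1:50) {
    set.seed(2000 + i)
    genes <- make_genes(sample.int(1e5, 30), ids = sprintf("g%02d", 1:30))
    start <- sample.int(1e5, 40)
    regs <- make_regions(start, start + 200, ids = sprintf("r%02d", 1:40))
    bins <- sort(sample.int(5e4, 3))
    d <- gene_min_region_distance(genes, regs)
    out <- distance_bin_proportions(d, list(all = genes$gene_id), bins)
    center <- floor((regs$start + regs$end) / 2)
    oracle <- vapply(bins, function(b) {
      hit <- vapply(seq_len(nrow(genes)), function(j) {
        any(abs(genes$tss[j] - center) <= b)
      }, logical(1))
      mean(hit)
    }, numeric(1))
    expect_equal(out$proportion, oracle)
  }
})

test_that("feature labels partition the region set", {
  set.seed(33)
  genes <- make_genes(sample.int(1e6, 50))
  start <- sample.int(1e6, 200)
  regs <- make_regions(start, start + 300, ids = sprintf("r%03d", 1:200))
  labels <- classify_feature(regs, genes)
  expect_equal(length(labels), nrow(regs))
  expect_equal(sum(table(labels)), nrow(regs))
})

test_that("TSS metaprofiles are flat under uniform coverage", {
  genes <- make_genes(c(10000, 50000), strand = c("+", "-"))
  cov <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = 2.5)
  prof <- tss_metaprofile(cov, genes)
  expect_equal(nrow(prof), 30L)
  expect_equal(prof$mean_coverage, rep(100 * 2.5, 30))
})

test_that("a block at the TSS peaks at the first downstream bin", {
  genes <- make_genes(10000)
  cov <- data.frame(chrom = "chr1", start = 10000, end = 10100, value = 1)
  prof <- tss_metaprofile(cov, genes)
  expect_equal(which.max(prof$mean_coverage), 16L) # bin [0, 100)
  expect_equal(max(prof$mean_coverage), 100)
  expect_equal(sum(prof$mean_coverage > 0), 1L)
})

test_that("minus-strand profiles mirror plus-strand profiles", {
  t <- 20000
  blocks <- data.frame(chrom = "chr1",
                       start = c(t + 200, t - 1000),
                       end = c(t + 500, t - 800),
                       value = c(3, 7))
  plus <- tss_metaprofile(blocks, make_genes(t, strand = "+"))
  # reflect each block about the TSS base: p -> 2t - p
  mirrored <- data.frame(chrom = "chr1",
                         start = 2 * t - blocks$end + 1,
                         end = 2 * t - blocks$start + 1,
                         value = blocks$value)
  minus <- tss_metaprofile(mirrored, make_genes(t, strand = "-"))
  expect_equal(minus$mean_coverage, plus$mean_coverage)
})

test_that("genes whose window leaves the chromosome are skipped with a warning", {
  genes <- make_genes(c(500, 50000)) # first window would start below 0
  cov <- data.frame(chrom = "chr1", start = 0, end = 1e5, value = 1)
  expect_warning(prof <- tss_metaprofile(cov, genes), "skipping 1")
  expect_equal(attr(prof, "n_genes"), 1L)
})
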