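test_that("overlap detection respects half-open boundaries", {
  a <- make_regions(100, 200, ids = "a1")
  expect_equal(nrow(overlap_regions(a, make_regions(199, 300,
                                                    ids = "b1"))$pairs), 1L)
  expect_equal(nrow(overlap_regions(a, make_regions(200, 300,
                                                    ids = "b1"))$pairs), 0L)
})

test_that("overlap partitions conserve region counts", {
  set.seed(41)
  start_a <- sample.int(1e5, 80)
  start_b <- sample.int(1e5, 60)
  a <- make_regions(start_a, start_a + 300, ids = sprintf("a%02d", 1:80))
  b <- make_regions(start_b, start_b + 300, ids = sprintf("b%02d", 1:60))
  ov <- overlap_regions(a, b)
  expect_equal(length(ov$a_only) + length(ov$a_cobound), nrow(a))
  expect_equal(length(ov$b_only) + length(ov$b_cobound), nrow(b))
})

test_that("merging and standardization match the worked examples", {
  a <- make_regions(100, 300, ids = "a1")
  b <- make_regions(200, 600, ids = "b1")
  m <- merge_and_standardize(a, b)
  expect_equal(m$merged_start, 100)
  expect_equal(m$merged_end, 600)
  expect_equal(m$start, 200) # center 350, width 300
  expect_equal(m$end, 500)
  expect_equal(m$a_ids, "a1")

  ident <- merge_and_standardize(make_regions(0, 300, ids = "a1"),
                                 make_regions(0, 300, ids = "b1"))
  expect_equal(c(ident$start, ident$end), c(0, 300))
})

test_that("overlap chains merge transitively and clip at zero with a warning", {
  a <- make_regions(c(0, 140), c(100, 240), ids = c("a1", "a2"))
  b <- make_regions(50, 150, ids = "b1")
  expect_warning(m <- merge_and_standardize(a, b), "clipped")
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$merged_start, m$merged_end), c(0, 240))
  expect_equal(m$start, 0) # center 120 - 150 clipped
  expect_true(m$clipped)
  expect_equal(m$a_ids, "a1,a2")
})

test_that("standardized widths are exactly 300 bp apart from logged clipping", {
  set.seed(42)
  start_a <- sample.int(1e6, 100) + 500
  a <- make_regions(start_a, start_a + sample.int(400, 100, TRUE) + 50,
                    ids = sprintf("a%03d", 1:100))
  b <- make_regions(start_a - 20, start_a + 250, ids = sprintf("b%03d", 1:100))
  m <- merge_and_standardize(a, b)
  expect_true(all((m$end - m$start)[!m$clipped] == 300))
})

test_that("tag counting apportions by overlap and sums coverage", {
  merged <- data.frame(merged_id = "M1", chrom = "chr1",
                       merged_start = 1000, merged_end = 1300,
                       start = 1000, end = 1300, clipped = FALSE,
                       a_ids = "a1", b_ids = "b1", stringsAsFactors = FALSE)
  # uniform 1x coverage over the window
  cov <- data.frame(chrom = "chr1", start = 0, end = 5000, value = 1)
  expect_equal(as.numeric(count_tags(merged, cov, mode = "coverage")), 300)
  # region fully inside contributes its whole count; half inside, half
  inside <- make_regions(1100, 1200, tags = 10, ids = "a1")
  expect_equal(as.numeric(count_tags(merged, inside, mode = "regions")), 10)
  straddle <- make_regions(900, 1100, tags = 10, ids = "a1")
  expect_equal(as.numeric(count_tags(merged, straddle, mode = "regions")), 5)
  # empty window
  far <- make_regions(4000, 4200, tags = 10, ids = "a1")
  expect_equal(as.numeric(count_tags(merged, far, mode = "regions")), 0)
  expect_error(count_tags(merged, NULL), class = "emtarget_input_error")
})

test_that("binding correlation matches the closed-form and flags degeneracy", {
  expect_equal(binding_correlation(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(binding_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_warning(r <- binding_correlation(c(1, 2), c(1, 2)), "fewer than 3")
  expect_true(is.na(r))
  expect_warning(r2 <- binding_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "constant")
  expect_true(is.na(r2))
  # textbook formula on random vectors
  set.seed(43)
  for (i in 1:20) {
    x <- rnorm(50); y <- rnorm(50)
    manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(binding_correlation(x, y), manual, tolerance = 1e-12)
  }
})

test_that("the co-binding chain recovers a planted tag correlation", {
  cb <- simulate_cobound_regions(500, 0.6, seed = 13L)
  chain <- run_cobind_chain(cb$set_a, cb$set_b)
  expect_equal(nrow(chain$merged), 500L)
  r <- binding_correlation(chain$counts_a, chain$counts_b)
  bounds <- fisher_z_bounds(0.6, 500)
  expect_gte(r, bounds[1])
  expect_lte(r, bounds[2])
})

test_that("nested subsets strictly increase r where co-binding is planted", {
  nb <- simulate_nested_cobinding(seed = 17L)
  chain <- run_cobind_chain(nb$set_a, nb$set_b)
  ann <- nearest_tss(data.frame(chrom = chain$merged$chrom,
                                start = chain$merged$start,
                                end = chain$merged$end,
                                region_id = chain$merged$merged_id),
                     nb$genes)
  prom <- abs(ann$signed_distance) < 1000
  sens <- prom & ann$nearest_gene_id %in%
    nb$calls$gene_id[nb$calls$sensitive]
  r_all <- binding_correlation(chain$counts_a, chain$counts_b)
  r_prom <- binding_correlation(chain$counts_a, chain$counts_b, prom)
  r_sens <- binding_correlation(chain$counts_a, chain$counts_b, sens)
  expect_lt(r_all, r_prom)
  expect_lt(r_prom, r_sens)
})

test_that("co-bound regions concentrate at sensitivity-linked genes", {
  cobound <- data.frame(region_id = c("m1", "m2", "m3"),
                        nearest_gene_id = c("g1", "g1", "g2"),
                        signed_distance = c(0, 10, 20),
                        stringsAsFactors = FALSE)
  single <- data.frame(region_id = c("s1", "s2"),
                       nearest_gene_id = c("g3", "g4"),
                       signed_distance = c(0, 10),
                       stringsAsFactors = FALSE)
  calls <- data.frame(gene_id = paste0("g", 1:4),
                      direction = c("induced", "repressed", "unchanged",
                                    "unchanged"),
                      sensitive = c(TRUE, TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  out <- cobound_gene_proportions(cobound, single, calls)
  expect_equal(out$prop_cobound[out$direction == "induced"], 2 / 3)
  expect_equal(out$prop_single[out$direction == "induced"], 0)
  expect_equal(out$prop_cobound[out$direction == "repressed"], 1 / 3)
  # p from the exact table [[2,1],[0,2]]
  expect_equal(out$fisher_p[out$direction == "induced"],
               fisher_oracle(matrix(c(2, 1, 0, 2), 2, byrow = TRUE)))
  # empty class gives the undefined marker
  none <- cobound_gene_proportions(cobound[0, ], single, calls)
  expect_true(all(is.na(none$prop_cobound)))
  expect_true(all(is.na(none$fisher_p)))
})

test_that("planted promoter-restricted co-binding enriches sensitive genes", {
  cfg <- sim_config(seed = 19L)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  p <- suppressWarnings(simulate_peaks(g, e$truth, cfg))
  af <- filter_regions(p$peaks_a)
  bf <- filter_regions(p$peaks_b)
  ov <- overlap_regions(af, bf)
  merged <- suppressWarnings(merge_and_standardize(af, bf, ov))
  ann_co <- nearest_tss(data.frame(chrom = merged$chrom,
                                   start = merged$start, end = merged$end,
                                   region_id = merged$merged_id), g)
  a_only <- af[af$region_id %in% ov$a_only, ]
  calls <- data.frame(gene_id = e$truth$gene_id,
                      direction = e$truth$direction,
                      sensitive = e$truth$sensitive,
                      stringsAsFactors = FALSE)
  out <- cobound_gene_proportions(ann_co, nearest_tss(a_only, g), calls)
  ind <- out[out$direction == "induced", ]
  expect_gt(ind$prop_cobound, ind$prop_single)
})
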