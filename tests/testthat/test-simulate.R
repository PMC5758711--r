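small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 200L, n_peaks = 300L, n_peaks_b_only = 50L), list(...))
  do.call(sim_config, args)
}

test_that("generators are byte-identical under a fixed config and seed", {
  cfg <- small_cfg(seed = 42L)
  run_all <- function() {
    g <- simulate_genome(cfg)
    e <- simulate_expression(g, cfg)
    p <- suppressWarnings(simulate_peaks(g, e$truth, cfg))
    list(g = g, e = e, p = p,
         pep = simulate_peptide_array(cfg),
         img = simulate_cell_images(cfg))
  }
  expect_identical(serialize(run_all(), NULL), serialize(run_all(), NULL))
})

test_that("substreams keep generators independent of one another", {
  cfg <- small_cfg(seed = 42L)
  pep1 <- simulate_peptide_array(cfg)
  invisible(simulate_genome(cfg)) # interleave another generator
  pep2 <- simulate_peptide_array(cfg)
  expect_identical(pep1, pep2)
})

test_that("simulated genomes have the right size, unique ids and vary by seed", {
  cfg <- small_cfg(seed = 1L, n_genes = 100L)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g), 100L)
  expect_false(anyDuplicated(g$gene_id) > 0)
  expect_true(all(g$strand %in% c("+", "-")))
  expect_true(all(g$tss >= 0 & g$tss < cfg$chrom_sizes[g$chrom]))
  g2 <- simulate_genome(small_cfg(seed = 2L, n_genes = 100L))
  expect_false(identical(sort(g$tss), sort(g2$tss)))
})

test_that("configuration violations are rejected", {
  expect_error(sim_config(frac_induced = 0.7, frac_repressed = 0.6),
               class = "emtarget_config_error")
  expect_error(sim_config(frac_induced = -0.1),
               class = "emtarget_config_error")
  expect_error(sim_config(chrom_sizes = c(chr1 = -5)),
               class = "emtarget_config_error")
  expect_error(sim_config(image = list(size = 4)),
               class = "emtarget_config_error")
  expect_error(sim_config(peptide = list(n_hits = 300)),
               class = "emtarget_config_error")
  expect_error(sim_config(peptide = list(background_mean = -1)),
               class = "emtarget_config_error")
})

test_that("zero-noise expression carries the planted contrasts exactly", {
  cfg <- small_cfg(seed = 3L, noise_sd = 0)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  induced <- e$truth$direction == "induced"
  expect_true(any(induced))
  expect_equal(e$expression$stim_mock[induced] -
                 e$expression$baseline_mock[induced],
               e$truth$effect[induced])
  sens <- e$truth$sensitive
  expect_equal(e$expression$stim_sirna[sens] - e$expression$stim_mock[sens],
               -ifelse(e$truth$direction[sens] == "induced", 1, -1) *
                 e$truth$effect[sens])
})

test_that("planted induced fraction lands inside binomial bounds", {
  cfg <- sim_config(seed = 9L, n_genes = 1000L)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  n_induced <- sum(e$truth$direction == "induced")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(n_induced, bounds[1])
  expect_lte(n_induced, bounds[2])
})

test_that("degenerate sensitivity fraction plants no sensitive genes", {
  cfg <- small_cfg(seed = 4L, frac_sensitive_given_induced = 0,
                   frac_sensitive_given_repressed = 0)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  expect_false(any(e$truth$sensitive))
})

test_that("all peaks near direct targets with zero spread sit on sensitive TSSs", {
  cfg <- small_cfg(seed = 5L, frac_peaks_near_direct = 1,
                   frac_peaks_near_genes = 0, near_distance_sd = 0)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  p <- suppressWarnings(simulate_peaks(g, e$truth, cfg))
  centers <- floor((p$peaks_a$start + p$peaks_a$end) / 2)
  sens_tss <- g$tss[e$truth$sensitive]
  expect_true(all(centers %in% sens_tss))
  expect_true(all(p$truth$direct[match(
    unique(g$gene_id[match(centers, g$tss)]), p$truth$gene_id)]))
})

test_that("zero co-binding rate yields zero overlapping A/B pairs", {
  cfg <- small_cfg(seed = 6L, cobind_rate_at_promoters = 0,
                   cobind_rate_elsewhere = 0)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  p <- simulate_peaks(g, e$truth, cfg)
  ov <- overlap_regions(p$peaks_a, p$peaks_b)
  expect_equal(nrow(ov$pairs), 0L)
})

test_that("zero peaks produce an empty set with a warning", {
  cfg <- small_cfg(seed = 7L, n_peaks = 0L, n_peaks_b_only = 0L)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  expect_warning(p <- simulate_peaks(g, e$truth, cfg), "n_peaks = 0")
  expect_equal(nrow(p$peaks_a), 0L)
})

test_that("chromatin states tile each chromosome disjointly and completely", {
  cfg <- small_cfg(seed = 8L)
  g <- simulate_genome(cfg)
  e <- simulate_expression(g, cfg)
  p <- simulate_peaks(g, e$truth, cfg)
  for (ch in names(cfg$chrom_sizes)) {
    s <- p$states[p$states$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_equal(s$start[1], 0)
    expect_equal(s$end[nrow(s)], unname(cfg$chrom_sizes[[ch]]))
    expect_equal(s$start[-1], s$end[-nrow(s)]) # contiguous, no overlap
    expect_equal(sum(s$end - s$start), unname(cfg$chrom_sizes[[ch]]))
  }
  expect_true(all(p$states$state %in% chromatin_state_vocabulary()))
})

test_that("peptide arrays plant exactly the requested hits", {
  cfg <- small_cfg(seed = 10L)
  pep <- simulate_peptide_array(cfg)
  expect_equal(nrow(pep$signals), 201L)
  expect_equal(sum(pep$truth$is_hit), 15L)
  expect_true(all(pep$signals$mean_signal[pep$truth$is_hit] == 500))
  cfg0 <- small_cfg(seed = 10L, peptide = list(n_hits = 0L))
  pep0 <- simulate_peptide_array(cfg0)
  expect_equal(sum(pep0$truth$is_hit), 0L)
  expect_true(all(pep0$signals$mean_signal < 200))
})

test_that("image channels follow the planted pixel correlation", {
  cfg1 <- small_cfg(seed = 11L, image = list(pixel_correlation = 1,
                                             n_cells = 1L))
  img <- simulate_cell_images(cfg1)$images[[1L]]
  r <- pixel_colocalization(img$channels$ch1, img$channels$ch2,
                            img$cell_mask)
  expect_equal(r, 1.0)

  cfg0 <- small_cfg(seed = 12L, image = list(pixel_correlation = 0,
                                             size = 64L, n_cells = 1L))
  img0 <- simulate_cell_images(cfg0)$images[[1L]]
  expect_gte(sum(img0$cell_mask), 1000)
  r0 <- pixel_colocalization(img0$channels$ch1, img0$channels$ch2,
                             img0$cell_mask)
  expect_lt(abs(r0), 0.1)
  # constant background outside the cell mask
  expect_true(all(img0$channels$ch1[!img0$cell_mask] ==
                    cfg0$image$background))
})

test_that("cell_image enforces mask containment and shapes", {
  m <- matrix(TRUE, 4, 4)
  expect_error(cell_image(list(ch = matrix(1, 4, 4)),
                          nuclear_mask = m, cell_mask = !m,
                          background_value = 0),
               class = "emtarget_input_error")
  expect_error(cell_image(list(ch = matrix(1, 3, 4)),
                          nuclear_mask = m, cell_mask = m,
                          background_value = 0),
               class = "emtarget_input_error")
})
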