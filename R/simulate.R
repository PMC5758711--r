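#' Simulation configuration with planted ground truth
#'
#' Builds and validates the configuration object consumed by the `simulate_*`
#' generators. The defaults describe a desk-scale EMT induction experiment:
#' a two-chromosome genome, 1000 genes each carried by a single probe,
#' four expression arms (baseline/stimulated crossed with mock/knockdown
#' siRNA), a factor-A peak set concentrated near knockdown-sensitive induced
#' genes, a factor-B set co-binding factor A preferentially at promoters with
#' zone-specific tag-count correlation, a chromatin-state tiling, a
#' 201-peptide kinase array with 15 planted phospho-hits, and paired
#' fluorescence channels with a tunable pixel correlation.
#'
#' All proportions must lie in `[0, 1]`, `frac_induced + frac_repressed`
#' must not exceed 1, chromosome lengths must be positive and the image grid
#' must be at least 8 pixels. Identical configuration and seed always yields
#' identical output.
#'
#' @param seed Integer root seed. Each generator draws from a named substream
#'   derived from it (see [substream_seed()]) so generators never perturb one
#'   another.
#' @param n_genes Number of simulated genes (one probe per gene).
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param frac_induced,frac_repressed Proportions of genes induced/repressed
#'   on stimulation.
#' @param frac_sensitive_given_induced,frac_sensitive_given_repressed
#'   Proportion of induced (repressed) genes whose change is reversed by
#'   knockdown.
#' @param effect_log2fc_mean,effect_log2fc_sd Planted effect size
#'   distribution (log2 units).
#' @param noise_sd Gaussian noise added independently to every expression
#'   arm (log2 units). Zero yields exact planted contrasts.
#' @param baseline_mean,baseline_sd Baseline log2 expression distribution.
#' @param n_peaks Number of factor-A binding regions.
#' @param frac_peaks_near_direct Fraction of factor-A peaks centered near the
#'   TSS of a sensitive gene (the realized recipients become the truth
#'   direct-target set).
#' @param frac_peaks_near_genes Fraction of factor-A peaks centered near the
#'   TSS of a randomly chosen gene regardless of sensitivity (binding
#'   concentrates at promoters genome-wide); capped so the near-sensitive
#'   pool takes precedence. The remainder of the peaks is uniform.
#' @param near_distance_sd SD (bp) of the Normal displacement of a planted
#'   near peak from its target TSS.
#' @param peak_width Width (bp) of simulated binding regions.
#' @param tag_mean,tag_sd Normalized tag-count distribution (reads per 10
#'   million scale).
#' @param tag_min Floor applied to simulated tag counts (default 12.2):
#'   simulated peaks represent regions that survived the upstream caller's
#'   enrichment filter, so their normalized counts sit at or above the
#'   filter value.
#' @param direct_threshold_bp Distance (bp) within which a planted peak makes
#'   a sensitive gene a truth direct target.
#' @param promoter_bp Promoter radius (bp) used when deciding whether an A
#'   peak is promoter-proximal for co-binding placement.
#' @param cobind_rate_at_promoters,cobind_rate_elsewhere Probability that a
#'   promoter-proximal (elsewhere) factor-A peak receives an overlapping
#'   factor-B peak.
#' @param cobind_rho_sensitive,cobind_rho_promoter,cobind_rho_background
#'   Planted tag-count correlation between the two factors for co-bound peaks
#'   at sensitive-gene promoters, other promoters, and off-promoter sites.
#' @param n_peaks_b_only Number of factor-B-only peaks, placed uniformly and
#'   guaranteed not to overlap any factor-A peak.
#' @param csc_bias_rate Probability that a sensitive induced (repressed) gene
#'   is expressed higher in the CSC (NCSC) compartment.
#' @param csc_bias_magnitude Planted log2 CSC-vs-NCSC difference for biased
#'   genes.
#' @param csc_background_rate Probability that any other gene carries a CSC
#'   or NCSC bias (each direction equally likely).
#' @param peptide List with `n_peptides`, `n_hits`, `hit_signal`,
#'   `background_mean`, `background_sd`, `peptide_length`, `offset_step`.
#' @param image List with `n_cells`, `size` (square grid side, pixels),
#'   `channel_mean`, `channel_sd`, `pixel_correlation`, `background`.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       chrom_sizes = c(chr1 = 1.2e8, chr2 = 8e7),
                       frac_induced = 0.3,
                       frac_repressed = 0.3,
                       frac_sensitive_given_induced = 0.42,
                       frac_sensitive_given_repressed = 0.24,
                       effect_log2fc_mean = 2.0,
                       effect_log2fc_sd = 0.25,
                       noise_sd = 0.1,
                       baseline_mean = 7.0,
                       baseline_sd = 1.0,
                       n_peaks = 2000L,
                       frac_peaks_near_direct = 0.4,
                       frac_peaks_near_genes = 0.3,
                       near_distance_sd = 500,
                       peak_width = 300L,
                       tag_mean = 50,
                       tag_sd = 10,
                       tag_min = 12.2,
                       direct_threshold_bp = 5000,
                       promoter_bp = 1000,
                       cobind_rate_at_promoters = 0.5,
                       cobind_rate_elsewhere = 0.3,
                       cobind_rho_sensitive = 0.64,
                       cobind_rho_promoter = 0.14,
                       cobind_rho_background = 0.0,
                       n_peaks_b_only = 300L,
                       csc_bias_rate = 0.6,
                       csc_bias_magnitude = 1.5,
                       csc_background_rate = 0.15,
                       peptide = list(),
                       image = list()) {
  peptide_defaults <- list(n_peptides = 201L, n_hits = 15L, hit_signal = 500,
                           background_mean = 100, background_sd = 10,
                           peptide_length = 15L, offset_step = 3L)
  image_defaults <- list(n_cells = 5L, size = 64L,
                         channel_mean = c(500, 500), channel_sd = 80,
                         pixel_correlation = 0.38, background = 50)
  peptide <- utils::modifyList(peptide_defaults, as.list(peptide))
  image <- utils::modifyList(image_defaults, as.list(image))

  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    chrom_sizes = chrom_sizes,
    frac_induced = frac_induced, frac_repressed = frac_repressed,
    frac_sensitive_given_induced = frac_sensitive_given_induced,
    frac_sensitive_given_repressed = frac_sensitive_given_repressed,
    effect_log2fc_mean = effect_log2fc_mean,
    effect_log2fc_sd = effect_log2fc_sd,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    n_peaks = as.integer(n_peaks),
    frac_peaks_near_direct = frac_peaks_near_direct,
    frac_peaks_near_genes = frac_peaks_near_genes,
    near_distance_sd = near_distance_sd,
    peak_width = as.integer(peak_width),
    tag_mean = tag_mean, tag_sd = tag_sd, tag_min = tag_min,
    direct_threshold_bp = direct_threshold_bp,
    promoter_bp = promoter_bp,
    cobind_rate_at_promoters = cobind_rate_at_promoters,
    cobind_rate_elsewhere = cobind_rate_elsewhere,
    cobind_rho_sensitive = cobind_rho_sensitive,
    cobind_rho_promoter = cobind_rho_promoter,
    cobind_rho_background = cobind_rho_background,
    n_peaks_b_only = as.integer(n_peaks_b_only),
    csc_bias_rate = csc_bias_rate,
    csc_bias_magnitude = csc_bias_magnitude,
    csc_background_rate = csc_background_rate,
    peptide = peptide, image = image
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("frac_induced", "frac_repressed", "frac_sensitive_given_induced",
             "frac_sensitive_given_repressed", "frac_peaks_near_direct",
             "frac_peaks_near_genes",
             "cobind_rate_at_promoters", "cobind_rate_elsewhere",
             "csc_bias_rate", "csc_background_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_config("sim_config: ", p, " must be a proportion in [0, 1]")
    }
  }
  if (cfg$frac_induced + cfg$frac_repressed > 1) {
    stop_config("sim_config: frac_induced + frac_repressed must not exceed 1")
  }
  if (is.null(names(cfg$chrom_sizes)) || any(names(cfg$chrom_sizes) == "") ||
      anyDuplicated(names(cfg$chrom_sizes))) {
    stop_config("sim_config: chrom_sizes must have unique non-empty names")
  }
  if (any(!is.finite(cfg$chrom_sizes)) || any(cfg$chrom_sizes <= 0)) {
    stop_config("sim_config: chromosome lengths must be positive")
  }
  if (cfg$n_genes < 1L) stop_config("sim_config: n_genes must be >= 1")
  if (cfg$noise_sd < 0 || cfg$near_distance_sd < 0 || cfg$tag_sd < 0 ||
      cfg$effect_log2fc_sd < 0) {
    stop_config("sim_config: standard deviations must be non-negative")
  }
  if (cfg$tag_min < 0) stop_config("sim_config: tag_min must be non-negative")
  pep <- cfg$peptide
  if (pep$n_hits > pep$n_peptides) {
    stop_config("sim_config: peptide n_hits must not exceed n_peptides")
  }
  if (pep$hit_signal < 0 || pep$background_mean < 0 || pep$background_sd < 0) {
    stop_config("sim_config: peptide signal parameters must be non-negative")
  }
  img <- cfg$image
  if (img$size < 8L) stop_config("sim_config: image grid size must be >= 8")
  if (abs(img$pixel_correlation) > 1) {
    stop_config("sim_config: image pixel_correlation must lie in [-1, 1]")
  }
  rhos <- c(cfg$cobind_rho_sensitive, cfg$cobind_rho_promoter,
            cfg$cobind_rho_background)
  if (any(abs(rhos) > 1)) {
    stop_config("sim_config: co-binding correlations must lie in [-1, 1]")
  }
  invisible(cfg)
}

#' Simulate a gene annotation
#'
#' Places `n_genes` TSSs uniformly within each chromosome (10 kb clear of the
#' chromosome ends so that metaprofile windows and planted peaks never leave
#' the chromosome), with balanced strands and unique gene ids. Chromosomes
#' receive genes proportionally to their length.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame with columns `gene_id`, `chrom`, `tss` (0-based bp)
#'   and `strand`.
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  margin <- 10000
  if (any(cfg$chrom_sizes <= 2 * margin)) {
    stop_config("simulate_genome: chromosomes must be longer than ",
                2 * margin, " bp")
  }
  with_substream(cfg$seed, "genome", {
    n <- cfg$n_genes
    chroms <- sample(names(cfg$chrom_sizes), n, replace = TRUE,
                     prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
    len <- cfg$chrom_sizes[chroms]
    tss <- floor(margin + stats::runif(n) * (len - 2 * margin))
    strand <- sample(rep_len(c("+", "-"), n))
    data.frame(
      gene_id = sprintf("g%05d", seq_len(n)),
      chrom = chroms, tss = as.numeric(tss), strand = strand,
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
}

#' Simulate the four-arm expression table with planted truth
#'
#' Each gene carries one probe with log2 values for the four condition arms
#' (baseline/stimulated crossed with mock/knockdown siRNA) plus CSC and NCSC
#' compartment values. Induced genes gain `+effect` in the stimulated mock
#' arm, repressed genes lose it; sensitive genes have the change fully
#' reversed in the stimulated knockdown arm. Independent Gaussian noise of sd
#' `noise_sd` is added to every arm, so `noise_sd = 0` yields the planted
#' contrasts exactly.
#'
#' @param genes Gene annotation from [simulate_genome()].
#' @param cfg A [sim_config()].
#' @return A list with `expression` (data.frame of probe-level log2 values)
#'   and `truth` (data.frame with per-gene `direction`, `sensitive`,
#'   `csc_bias`, `effect`).
#' @export
simulate_expression <- function(genes, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(genes) == 0L) stop_input("simulate_expression: genes is empty")
  with_substream(cfg$seed, "expression", {
    n <- nrow(genes)
    u <- stats::runif(n)
    direction <- ifelse(u < cfg$frac_induced, "induced",
                 ifelse(u < cfg$frac_induced + cfg$frac_repressed,
                        "repressed", "unchanged"))
    sens_p <- ifelse(direction == "induced", cfg$frac_sensitive_given_induced,
              ifelse(direction == "repressed",
                     cfg$frac_sensitive_given_repressed, 0))
    sensitive <- stats::runif(n) < sens_p

    effect <- stats::rnorm(n, cfg$effect_log2fc_mean, cfg$effect_log2fc_sd)
    dir_sign <- (direction == "induced") - (direction == "repressed")

    # CSC/NCSC compartment bias: sensitive induced genes lean CSC, sensitive
    # repressed genes lean NCSC; every other gene picks up a weak balanced
    # background bias.
    u_csc <- stats::runif(n)
    csc_bias <- rep("none", n)
    lean_csc <- sensitive & direction == "induced" & u_csc < cfg$csc_bias_rate
    lean_ncsc <- sensitive & direction == "repressed" & u_csc < cfg$csc_bias_rate
    u_bg <- stats::runif(n)
    bg_csc <- !(lean_csc | lean_ncsc) & u_bg < cfg$csc_background_rate
    bg_ncsc <- !(lean_csc | lean_ncsc) & !bg_csc &
      u_bg < 2 * cfg$csc_background_rate
    csc_bias[lean_csc | bg_csc] <- "csc"
    csc_bias[lean_ncsc | bg_ncsc] <- "ncsc"

    base <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    noise <- function() stats::rnorm(n, 0, cfg$noise_sd)
    stim_clean <- base + dir_sign * effect
    bias_sign <- (csc_bias == "csc") - (csc_bias == "ncsc")
    csc_base <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)

    expression <- data.frame(
      probe_id = paste0("p_", genes$gene_id),
      gene_id = genes$gene_id,
      baseline_mock = base + noise(),
      baseline_sirna = base + noise(),
      stim_mock = stim_clean + noise(),
      stim_sirna = stim_clean - ifelse(sensitive, dir_sign * effect, 0) + noise(),
      csc_log2 = csc_base + bias_sign * cfg$csc_bias_magnitude / 2 + noise(),
      ncsc_log2 = csc_base - bias_sign * cfg$csc_bias_magnitude / 2 + noise(),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = genes$gene_id, probe_id = expression$probe_id,
      direction = direction, sensitive = sensitive,
      csc_bias = csc_bias, effect = effect,
      stringsAsFactors = FALSE
    )
    list(expression = expression, truth = truth)
  })
}

#' Simulate factor-A/factor-B binding regions and a chromatin-state tiling
#'
#' A fraction `frac_peaks_near_direct` of factor-A peaks are centered within
#' `Normal(0, near_distance_sd)` of the TSS of a randomly chosen sensitive
#' gene; the remainder are uniform. Factor-B peaks are planted overlapping
#' promoter-proximal factor-A peaks at `cobind_rate_at_promoters` (and
#' off-promoter A peaks at `cobind_rate_elsewhere`) with zone-specific
#' tag-count correlation; additional B-only peaks are placed uniformly,
#' rejected on any overlap with factor A. Chromatin-state segments tile each
#' chromosome without gaps or overlap.
#'
#' The returned truth marks a gene `direct` when it is sensitive and some
#' factor-A peak center actually landed within `direct_threshold_bp` of its
#' TSS, i.e. the realized placement, which is the ground truth of the data
#' that was generated (a uniformly placed background peak can by chance
#' create a genuine proximal binding event).
#'
#' @param genes Gene annotation from [simulate_genome()].
#' @param truth Per-gene truth from [simulate_expression()].
#' @param cfg A [sim_config()].
#' @return A list with `peaks_a`, `peaks_b` (0-based half-open region
#'   data.frames with `tag_count`), `states` (chromatin-state tiling),
#'   `truth` (the input truth with `direct` and `min_dist_a` columns added),
#'   and `truth_peaks_b` (per-B-peak zone, planted correlation, paired A
#'   region).
#' @export
simulate_peaks <- function(genes, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!identical(genes$gene_id, truth$gene_id)) {
    stop_input("simulate_peaks: truth must be aligned to genes")
  }
  half <- floor(cfg$peak_width / 2)

  peaks_a <- with_substream(cfg$seed, "peaks_a", {
    if (cfg$n_peaks == 0L) {
      warning("simulate_peaks: n_peaks = 0, returning empty factor-A set")
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 region_id = character(), tag_count = numeric(),
                 stringsAsFactors = FALSE)
    } else {
      sens_idx <- which(truth$sensitive)
      n_near <- if (length(sens_idx) > 0L) {
        round(cfg$frac_peaks_near_direct * cfg$n_peaks)
      } else 0L
      n_gene <- min(round(cfg$frac_peaks_near_genes * cfg$n_peaks),
                    cfg$n_peaks - n_near)
      n_bg <- cfg$n_peaks - n_near - n_gene
      chrom <- character(cfg$n_peaks)
      center <- numeric(cfg$n_peaks)
      if (n_near > 0L) {
        tgt <- sens_idx[sample.int(length(sens_idx), n_near, replace = TRUE)]
        offs <- round(stats::rnorm(n_near, 0, cfg$near_distance_sd))
        chrom[seq_len(n_near)] <- genes$chrom[tgt]
        center[seq_len(n_near)] <- genes$tss[tgt] + offs
      }
      if (n_gene > 0L) {
        i <- n_near + seq_len(n_gene)
        tgt <- sample.int(nrow(genes), n_gene, replace = TRUE)
        offs <- round(stats::rnorm(n_gene, 0, cfg$near_distance_sd))
        chrom[i] <- genes$chrom[tgt]
        center[i] <- genes$tss[tgt] + offs
      }
      if (n_bg > 0L) {
        i <- n_near + n_gene + seq_len(n_bg)
        chrom[i] <- sample(names(cfg$chrom_sizes), n_bg, replace = TRUE,
                           prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
        center[i] <- floor(stats::runif(n_bg) * cfg$chrom_sizes[chrom[i]])
      }
      center <- pmin(pmax(center, half), cfg$chrom_sizes[chrom] - half)
      data.frame(
        chrom = chrom, start = center - half, end = center - half + cfg$peak_width,
        region_id = sprintf("A_%05d", seq_len(cfg$n_peaks)),
        tag_count = pmax(cfg$tag_min, stats::rnorm(cfg$n_peaks, cfg$tag_mean, cfg$tag_sd)),
        stringsAsFactors = FALSE
      )
    }
  })

  # Realized truth: a sensitive gene with an A-peak center inside the direct
  # window is a direct target of the generated dataset.
  min_dist <- gene_min_region_distance(genes, peaks_a)
  truth$min_dist_a <- min_dist
  truth$direct <- truth$sensitive & !is.na(min_dist) &
    min_dist <= cfg$direct_threshold_bp

  cobind <- with_substream(cfg$seed, "peaks_b", {
    n_a <- nrow(peaks_a)
    b_rows <- list()
    truth_b <- list()
    if (n_a > 0L) {
      centers_a <- region_center(peaks_a$start, peaks_a$end)
      near <- nearest_tss(peaks_a, genes)
      prom <- !is.na(near$signed_distance) &
        abs(near$signed_distance) < cfg$promoter_bp
      near_sens <- prom & near$nearest_gene_id %in%
        truth$gene_id[truth$sensitive & truth$direction == "induced"]
      zone <- ifelse(near_sens, "sensitive_promoter",
              ifelse(prom, "promoter", "background"))
      rate <- c(sensitive_promoter = cfg$cobind_rate_at_promoters,
                promoter = cfg$cobind_rate_at_promoters,
                background = cfg$cobind_rate_elsewhere)[zone]
      rho <- c(sensitive_promoter = cfg$cobind_rho_sensitive,
               promoter = cfg$cobind_rho_promoter,
               background = cfg$cobind_rho_background)[zone]
      take <- stats::runif(n_a) < rate
      idx <- which(take)
      if (length(idx) > 0L) {
        # co-bound events coincide with their factor-A partner: the analysis
        # standardizes merged regions to one fixed-width window, and exact
        # coincidence keeps the planted tag correlation undistorted by
        # partial-overlap apportionment
        b_center <- centers_a[idx]
        z <- stats::rnorm(length(idx))
        tag_a_std <- (peaks_a$tag_count[idx] - cfg$tag_mean) / cfg$tag_sd
        tag_b <- cfg$tag_mean + cfg$tag_sd *
          (rho[idx] * tag_a_std + sqrt(1 - rho[idx]^2) * z)
        b_rows$cobound <- data.frame(
          chrom = peaks_a$chrom[idx], start = b_center - half,
          end = b_center - half + cfg$peak_width,
          region_id = sprintf("B_%05d", seq_along(idx)),
          tag_count = pmax(cfg$tag_min, tag_b), stringsAsFactors = FALSE
        )
        truth_b$cobound <- data.frame(
          region_id = b_rows$cobound$region_id,
          paired_a = peaks_a$region_id[idx],
          zone = zone[idx], planted_rho = rho[idx],
          stringsAsFactors = FALSE
        )
      }
    }
    if (cfg$n_peaks_b_only > 0L) {
      n_only <- cfg$n_peaks_b_only
      a_gr <- if (nrow(peaks_a) > 0L) regions_to_granges(peaks_a) else NULL
      chrom <- sample(names(cfg$chrom_sizes), n_only, replace = TRUE,
                      prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
      center <- floor(half + stats::runif(n_only) *
                        (cfg$chrom_sizes[chrom] - cfg$peak_width))
      # Reject B-only placements overlapping factor A so that "B only" is a
      # guarantee, not a tendency.
      if (!is.null(a_gr)) {
        for (tries in 1:50) {
          cand <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(center - half + 1, center - half + cfg$peak_width))
          hit <- unique(S4Vectors::queryHits(
            GenomicRanges::findOverlaps(cand, a_gr)))
          if (length(hit) == 0L) break
          chrom[hit] <- sample(names(cfg$chrom_sizes), length(hit),
                               replace = TRUE,
                               prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
          center[hit] <- floor(half + stats::runif(length(hit)) *
                                 (cfg$chrom_sizes[chrom[hit]] - cfg$peak_width))
        }
      }
      off <- length(b_rows$cobound$region_id %||% character())
      b_rows$only <- data.frame(
        chrom = chrom, start = center - half,
        end = center - half + cfg$peak_width,
        region_id = sprintf("B_%05d", off + seq_len(n_only)),
        tag_count = pmax(cfg$tag_min, stats::rnorm(n_only, cfg$tag_mean, cfg$tag_sd)),
        stringsAsFactors = FALSE
      )
      truth_b$only <- data.frame(
        region_id = b_rows$only$region_id, paired_a = NA_character_,
        zone = "b_only", planted_rho = NA_real_, stringsAsFactors = FALSE
      )
    }
    list(
      peaks_b = if (length(b_rows)) do.call(rbind, unname(b_rows)) else
        data.frame(chrom = character(), start = numeric(), end = numeric(),
                   region_id = character(), tag_count = numeric(),
                   stringsAsFactors = FALSE),
      truth_b = if (length(truth_b)) do.call(rbind, unname(truth_b)) else
        data.frame(region_id = character(), paired_a = character(),
                   zone = character(), planted_rho = numeric(),
                   stringsAsFactors = FALSE)
    )
  })
  rownames(cobind$peaks_b) <- NULL
  rownames(cobind$truth_b) <- NULL

  states <- with_substream(cfg$seed, "states", simulate_states(cfg))

  list(peaks_a = peaks_a, peaks_b = cobind$peaks_b, states = states,
       truth = truth, truth_peaks_b = cobind$truth_b)
}

#' Chromatin-state vocabulary used by the simulator
#' @return Character vector of state labels.
#' @export
chromatin_state_vocabulary <- function() {
  c("active_promoter", "enhancer", "transcribed", "repressed",
    "heterochromatin", "ctcf", "none")
}

# Tile each chromosome with contiguous, non-overlapping state segments.
simulate_states <- function(cfg) {
  vocab <- setdiff(chromatin_state_vocabulary(), "none")
  out <- lapply(names(cfg$chrom_sizes), function(ch) {
    len <- cfg$chrom_sizes[[ch]]
    n_guess <- ceiling(len / 20000) + 10
    widths <- floor(stats::runif(n_guess, 5000, 50000))
    while (sum(widths) < len) {
      widths <- c(widths, floor(stats::runif(n_guess, 5000, 50000)))
    }
    ends <- cumsum(widths)
    k <- which(ends >= len)[1L]
    widths <- widths[seq_len(k)]
    ends <- ends[seq_len(k)]
    ends[k] <- len
    starts <- c(0, ends[-k])
    data.frame(
      chrom = ch, start = starts, end = ends,
      state = sample(vocab, k, replace = TRUE,
                     prob = c(0.1, 0.1, 0.25, 0.2, 0.25, 0.1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a kinase-profiling peptide array
#'
#' Peptides tile an abstract protein at a fixed offset step. A chosen subset
#' of peptides receives the hit signal; all others draw from the Gaussian
#' background distribution (truncated at zero).
#'
#' @param cfg A [sim_config()]; see its `peptide` block.
#' @return A list with `signals` (data.frame `peptide_id`, `protein_offset`,
#'   `sequence`, `mean_signal`) and `truth` (data.frame `peptide_id`,
#'   `is_hit`).
#' @export
simulate_peptide_array <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pep <- cfg$peptide
  with_substream(cfg$seed, "peptide", {
    n <- pep$n_peptides
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(aa, pep$peptide_length, replace = TRUE), collapse = "")
    }, character(1))
    hit_idx <- if (pep$n_hits > 0L) sample.int(n, pep$n_hits) else integer()
    signal <- pmax(0, stats::rnorm(n, pep$background_mean, pep$background_sd))
    signal[hit_idx] <- pep$hit_signal
    is_hit <- logical(n)
    is_hit[hit_idx] <- TRUE
    list(
      signals = data.frame(
        peptide_id = sprintf("pep%03d", seq_len(n)),
        protein_offset = 1L + (seq_len(n) - 1L) * pep$offset_step,
        sequence = seqs, mean_signal = signal, stringsAsFactors = FALSE
      ),
      truth = data.frame(
        peptide_id = sprintf("pep%03d", seq_len(n)), is_hit = is_hit,
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate paired-channel cell images with planted pixel correlation
#'
#' Each cell is a square grid with a circular cell mask and a concentric
#' nuclear mask. Within the cell mask the two channels draw from a bivariate
#' Gaussian with correlation `pixel_correlation`; outside the mask both
#' channels hold the constant background level.
#'
#' @param cfg A [sim_config()]; see its `image` block.
#' @return A list with `images` (list of [cell_image()] objects) and `truth`
#'   (data.frame `image_id`, `rho`).
#' @export
simulate_cell_images <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  img <- cfg$image
  with_substream(cfg$seed, "images", {
    g <- img$size
    ctr <- (g + 1) / 2
    d <- sqrt(outer((seq_len(g) - ctr)^2, (seq_len(g) - ctr)^2, "+"))
    cell_mask <- d <= 0.42 * g
    nuclear_mask <- d <= 0.22 * g
    rho <- img$pixel_correlation
    mu <- rep_len(img$channel_mean, 2L)
    images <- lapply(seq_len(img$n_cells), function(i) {
      n_px <- sum(cell_mask)
      z1 <- stats::rnorm(n_px)
      z2 <- stats::rnorm(n_px)
      ch1 <- matrix(img$background, g, g)
      ch2 <- matrix(img$background, g, g)
      ch1[cell_mask] <- pmax(0, mu[1L] + img$channel_sd * z1)
      ch2[cell_mask] <- pmax(0, mu[2L] + img$channel_sd *
                               (rho * z1 + sqrt(1 - rho^2) * z2))
      cell_image(channels = list(ch1 = ch1, ch2 = ch2),
                 nuclear_mask = nuclear_mask, cell_mask = cell_mask,
                 background_value = img$background,
                 image_id = sprintf("cell%03d", i))
    })
    list(
      images = images,
      truth = data.frame(
        image_id = vapply(images, function(x) x$image_id, character(1)),
        rho = rho, stringsAsFactors = FALSE
      )
    )
  })
}

#' Construct a cell image object
#'
#' Bundles named channel matrices with nuclear/cell masks and a scalar
#' background estimate. The nuclear mask must be contained in the cell mask
#' and all grids must share a shape.
#'
#' @param channels Named list of numeric matrices (equal dimensions).
#' @param nuclear_mask,cell_mask Logical matrices, same shape as channels.
#' @param background_value Non-negative scalar background intensity.
#' @param image_id Identifier string.
#' @return An object of class `"cell_image"`.
#' @export
cell_image <- function(channels, nuclear_mask, cell_mask, background_value,
                       image_id = "cell") {
  stopifnot(is.list(channels), length(channels) >= 1L)
  dims <- dim(channels[[1L]])
  for (ch in channels) {
    if (!identical(dim(ch), dims)) {
      stop_input("cell_image: all channels must share the same shape")
    }
  }
  if (!identical(dim(nuclear_mask), dims) || !identical(dim(cell_mask), dims)) {
    stop_input("cell_image: masks must have the same shape as the channels")
  }
  if (any(nuclear_mask & !cell_mask)) {
    stop_input("cell_image: nuclear mask must be contained in the cell mask")
  }
  if (background_value < 0) {
    stop_input("cell_image: background_value must be non-negative")
  }
  structure(list(channels = channels, nuclear_mask = nuclear_mask,
                 cell_mask = cell_mask, background_value = background_value,
                 image_id = image_id),
            class = "cell_image")
}

#' Simulate a pair of co-bound region sets with a planted tag correlation
#'
#' Produces two factor region sets whose intervals coincide pairwise (spaced
#' along one chromosome so no other overlaps arise) and whose normalized tag
#' counts are bivariate Gaussian with correlation `rho`. Running the
#' co-binding chain (overlap, merge, standardize, count, correlate) on the
#' output recovers `rho` up to sampling error.
#'
#' @param n Number of co-bound pairs.
#' @param rho Planted Pearson correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param tag_mean,tag_sd Tag-count distribution.
#' @param width Region width in bp.
#' @param chrom Chromosome name.
#' @return A list with `set_a`, `set_b` (region data.frames) and `rho`.
#' @export
simulate_cobound_regions <- function(n, rho, seed = 1L, tag_mean = 50,
                                     tag_sd = 10, width = 300L,
                                     chrom = "chr1") {
  if (abs(rho) > 1) stop_config("simulate_cobound_regions: |rho| must be <= 1")
  with_substream(seed, "cobound", {
    start <- (seq_len(n) - 1L) * (width * 10) + 1000
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    tags_a <- pmax(0, tag_mean + tag_sd * z1)
    tags_b <- pmax(0, tag_mean + tag_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
    list(
      set_a = data.frame(chrom = chrom, start = start, end = start + width,
                         region_id = sprintf("A_%05d", seq_len(n)),
                         tag_count = tags_a, stringsAsFactors = FALSE),
      set_b = data.frame(chrom = chrom, start = start, end = start + width,
                         region_id = sprintf("B_%05d", seq_len(n)),
                         tag_count = tags_b, stringsAsFactors = FALSE),
      rho = rho
    )
  })
}

#' Simulate a zone-structured co-binding benchmark
#'
#' Builds a minimal gene annotation plus a pair of factor region sets with
#' co-bound events planted in three zones: at the promoters of
#' induced-sensitive genes (correlation `rho_sensitive`), at the promoters
#' of other genes (`rho_promoter`), and far from any TSS
#' (`rho_background`). Genes are spaced 100 kb apart so every pair is
#' unambiguous for nearest-TSS assignment. Running the co-binding chain and
#' restricting the correlation to nested subsets (all regions, promoter
#' regions, sensitive-gene promoter regions) recovers the planted ordering.
#'
#' @param seed Integer seed.
#' @param n_per_zone Number of co-bound pairs per zone.
#' @param rho_background,rho_promoter,rho_sensitive Planted tag
#'   correlations per zone.
#' @param tag_mean,tag_sd Tag-count distribution.
#' @param width Region width in bp.
#' @return A list with `genes`, `calls` (per-gene `direction`,
#'   `sensitive`), `set_a`, `set_b`, and `zones` (per-pair zone labels).
#' @export
simulate_nested_cobinding <- function(seed = 1L, n_per_zone = 400L,
                                      rho_background = 0,
                                      rho_promoter = 0.14,
                                      rho_sensitive = 0.64,
                                      tag_mean = 50, tag_sd = 10,
                                      width = 300L) {
  rhos <- c(sensitive_promoter = rho_sensitive, promoter = rho_promoter,
            background = rho_background)
  if (any(abs(rhos) > 1)) {
    stop_config("simulate_nested_cobinding: correlations must lie in [-1, 1]")
  }
  with_substream(seed, "nested_cobinding", {
    n_genes <- 2L * n_per_zone
    genes <- data.frame(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      chrom = "chr1",
      tss = seq_len(n_genes) * 1e5,
      strand = rep_len(c("+", "-"), n_genes),
      stringsAsFactors = FALSE
    )
    sens <- seq_len(n_per_zone) # first half: induced-sensitive genes
    calls <- data.frame(
      gene_id = genes$gene_id,
      direction = ifelse(seq_len(n_genes) %in% sens, "induced", "unchanged"),
      sensitive = seq_len(n_genes) %in% sens,
      stringsAsFactors = FALSE
    )
    # pair centers: at sensitive promoters, at other promoters, and midway
    # between genes (50 kb from the nearest TSS)
    centers <- c(genes$tss[sens],
                 genes$tss[n_per_zone + seq_len(n_per_zone)],
                 genes$tss[seq_len(n_per_zone)] + 5e4)
    zones <- rep(names(rhos), each = n_per_zone)
    n <- length(centers)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    rho <- rhos[zones]
    tags_a <- pmax(0, tag_mean + tag_sd * z1)
    tags_b <- pmax(0, tag_mean + tag_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
    half <- floor(width / 2)
    list(
      genes = genes, calls = calls,
      set_a = data.frame(chrom = "chr1", start = centers - half,
                         end = centers - half + width,
                         region_id = sprintf("A_%05d", seq_len(n)),
                         tag_count = tags_a, stringsAsFactors = FALSE),
      set_b = data.frame(chrom = "chr1", start = centers - half,
                         end = centers - half + width,
                         region_id = sprintf("B_%05d", seq_len(n)),
                         tag_count = tags_b, stringsAsFactors = FALSE),
      zones = zones
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
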