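#' Build and validate a pipeline run configuration
#'
#' A run either simulates its inputs (a [sim_config()] in `simulate`) or
#' reads them from files (`inputs`), never both. Thresholds default to the
#' values the analysis is anchored on: a log2 0.5 differential-expression
#' threshold, a 12.2 normalized-read region filter, a 5 kb direct-target
#' window, 300 bp standardized co-bound regions and a strict 1 kb promoter
#' radius.
#'
#' @param simulate A [sim_config()], or `NULL` when reading inputs.
#' @param inputs Named list of file paths (`genes`, `expression`, `peaks_a`,
#'   optionally `peaks_b`, `states`), or `NULL` when simulating.
#' @param thresholds Named list overriding any of `de_log2`, `min_tags`,
#'   `direct_bp`, `cobind_width`, `promoter_bp`, `metaprofile_bin_bp`,
#'   `metaprofile_half_window_bp`, `distance_bins_bp`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed echoed into the report (the simulation seed
#'   lives in `simulate$seed`).
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL, thresholds = list(),
                       outdir = tempfile("emtarget_run_"), seed = 1L) {
  defaults <- list(de_log2 = 0.5, min_tags = 12.2, direct_bp = 5000,
                   cobind_width = 300, promoter_bp = 1000,
                   metaprofile_bin_bp = 100, metaprofile_half_window_bp = 1500,
                   distance_bins_bp = c(1e3, 5e3, 1e4, 5e4, 1e5))
  thresholds <- utils::modifyList(defaults, as.list(thresholds))
  if (!is.null(simulate) && !is.null(inputs)) {
    stop_config("run_config: supply either a simulation block or input ",
                "paths for the data, not both")
  }
  if (is.null(simulate) && is.null(inputs)) {
    stop_config("run_config: one of simulate/inputs is required")
  }
  if (!is.null(simulate) && !inherits(simulate, "sim_config")) {
    stop_config("run_config: simulate must be a sim_config")
  }
  if (!is.null(inputs)) {
    need <- c("genes", "expression", "peaks_a")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0L) {
      stop_config("run_config: inputs must include ",
                  paste(missing, collapse = ", "))
    }
  }
  scalar <- setdiff(names(defaults), "distance_bins_bp")
  for (nm in scalar) {
    if (!is.numeric(thresholds[[nm]]) || thresholds[[nm]] <= 0) {
      stop_config("run_config: threshold ", nm, " must be positive")
    }
  }
  structure(list(simulate = simulate, inputs = inputs,
                 thresholds = thresholds, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' The file mirrors [run_config()]: optional `simulate` block (passed to
#' [sim_config()]), optional `inputs` path map, optional `thresholds`,
#' `outdir` and `seed`.
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim <- if (!is.null(raw$simulate)) {
    if (!is.null(raw$simulate$chrom_sizes)) {
      raw$simulate$chrom_sizes <- unlist(raw$simulate$chrom_sizes)
    }
    do.call(sim_config, raw$simulate)
  }
  run_config(simulate = sim, inputs = raw$inputs,
             thresholds = raw$thresholds %||% list(),
             outdir = raw$outdir %||% tempfile("emtarget_run_"),
             seed = raw$seed %||% 1L)
}

#' Run the integration pipeline end to end
#'
#' Stages, in dependency order: acquire data (simulate or read), call
#' direction/sensitivity/CSC bias, filter regions on normalized tags,
#' annotate regions (nearest TSS, feature class, chromatin state), compute
#' distance-binned proportions per sensitivity group, classify
#' direct/indirect targets, compute CSC contingencies, and run the
#' co-binding analysis when a second factor is present. Every intermediate
#' table is written to `config$outdir` and every reported number is
#' reproducible by calling the owning function on the written intermediates.
#'
#' @param config A [run_config()].
#' @return The run report (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$outdir, name)
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  # --- stage: data ---------------------------------------------------------
  truth <- NULL
  truth_peaks_b <- NULL
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    genes <- simulate_genome(cfg)
    expr_sim <- simulate_expression(genes, cfg)
    expression <- expr_sim$expression
    peaks_sim <- withCallingHandlers(
      simulate_peaks(genes, expr_sim$truth, cfg), warning = log_warning)
    peaks_a <- peaks_sim$peaks_a
    peaks_b <- peaks_sim$peaks_b
    states <- peaks_sim$states
    truth <- peaks_sim$truth
    truth_peaks_b <- peaks_sim$truth_peaks_b
    write_gene_annotation(genes, out("genes.tsv"))
    write_tsv(expression, out("expression.tsv"))
    write_bed_regions(peaks_a, out("peaks_a.bed"))
    write_bed_regions(peaks_b, out("peaks_b.bed"))
    write_states_bed(states, out("states.bed"))
    jsonlite::write_json(
      list(genes = truth, peaks_b = truth_peaks_b),
      out("truth.json"), dataframe = "columns", digits = NA)
  } else {
    genes <- read_gene_annotation(config$inputs$genes)
    expression <- read_expression_table(config$inputs$expression)
    peaks_a <- read_bed_regions(config$inputs$peaks_a)
    peaks_b <- if (!is.null(config$inputs$peaks_b)) {
      read_bed_regions(config$inputs$peaks_b)
    }
    states <- if (!is.null(config$inputs$states)) {
      read_states_bed(config$inputs$states)
    }
  }

  # --- stage: expression calls --------------------------------------------
  calls <- sensitivity_calls(expression, th$de_log2)
  if (!"gene_id" %in% names(calls)) calls$gene_id <- calls$probe_id
  reversibility <- summarize_reversibility(calls$direction, calls$sensitive)
  write_tsv(calls, out("calls.tsv"))
  write_tsv(reversibility, out("reversibility.tsv"))

  # --- stage: region filtering and annotation ------------------------------
  peaks_a_f <- filter_regions(peaks_a, th$min_tags)
  ann_a <- nearest_tss(peaks_a_f, genes)
  ann_a$feature <- classify_feature(peaks_a_f, genes,
                                    promoter_bp = th$promoter_bp)
  if (!is.null(states)) {
    ann_a$state <- annotate_chromatin_state(peaks_a_f, states)
  }
  write_tsv(ann_a, out("annotations_a.tsv"))

  min_dist <- gene_min_region_distance(genes, peaks_a_f)
  gene_calls <- calls[match(genes$gene_id, calls$gene_id), ]
  subsets <- list(
    induced_sensitive = genes$gene_id[gene_calls$direction == "induced" &
                                        gene_calls$sensitive],
    induced_insensitive = genes$gene_id[gene_calls$direction == "induced" &
                                          !gene_calls$sensitive],
    repressed_sensitive = genes$gene_id[gene_calls$direction == "repressed" &
                                          gene_calls$sensitive],
    repressed_insensitive = genes$gene_id[gene_calls$direction == "repressed" &
                                            !gene_calls$sensitive]
  )
  dist_props <- distance_bin_proportions(min_dist, subsets,
                                         th$distance_bins_bp)
  write_tsv(dist_props, out("distance_bin_proportions.tsv"))

  # --- stage: target classification ---------------------------------------
  targets <- withCallingHandlers(
    classify_targets(gene_calls[, c("gene_id", "sensitive")], min_dist,
                     th$direct_bp),
    warning = log_warning)
  write_tsv(targets, out("targets.tsv"))

  # --- stage: CSC contingencies -------------------------------------------
  csc_bias <- csc_sensitivity_bias(gene_calls)
  csc_prox <- csc_proximity_bias(
    min_dist,
    csc_genes = genes$gene_id[gene_calls$csc_bias == "csc"],
    ncsc_genes = genes$gene_id[gene_calls$csc_bias == "ncsc"],
    bins = th$distance_bins_bp)
  write_tsv(csc_prox, out("csc_proximity.tsv"))

  # --- stage: co-binding ---------------------------------------------------
  cobinding <- NULL
  if (!is.null(peaks_b) && nrow(peaks_b) > 0L && nrow(peaks_a_f) > 0L) {
    peaks_b_f <- filter_regions(peaks_b, th$min_tags)
    ov <- overlap_regions(peaks_a_f, peaks_b_f)
    merged <- withCallingHandlers(
      merge_and_standardize(peaks_a_f, peaks_b_f, ov, th$cobind_width),
      warning = log_warning)
    if (nrow(merged) >= 3L) {
      counts_a <- count_tags(merged, peaks_a_f, mode = "regions")
      counts_b <- count_tags(merged, peaks_b_f, mode = "regions")
      merged_regions <- data.frame(
        chrom = merged$chrom, start = merged$start, end = merged$end,
        region_id = merged$merged_id, stringsAsFactors = FALSE)
      merged_ann <- nearest_tss(merged_regions, genes)
      at_promoter <- !is.na(merged_ann$signed_distance) &
        abs(merged_ann$signed_distance) < th$promoter_bp
      sens_induced <- genes$gene_id[gene_calls$direction == "induced" &
                                      gene_calls$sensitive]
      at_sens <- at_promoter & merged_ann$nearest_gene_id %in% sens_induced
      corr <- list(
        all = suppressWarnings(binding_correlation(counts_a, counts_b)),
        promoter = suppressWarnings(
          binding_correlation(counts_a, counts_b, at_promoter)),
        promoter_sensitive = suppressWarnings(
          binding_correlation(counts_a, counts_b, at_sens))
      )
      a_only <- peaks_a_f[peaks_a_f$region_id %in% ov$a_only, , drop = FALSE]
      gene_props <- cobound_gene_proportions(
        merged_ann, nearest_tss(a_only, genes), gene_calls)
      merged_out <- data.frame(
        merged$chrom, format_bp(merged$start), format_bp(merged$end),
        sprintf("%s;tags_a=%.3f;tags_b=%.3f", merged$merged_id, counts_a,
                counts_b),
        0, ".")
      utils::write.table(merged_out, out("cobound_merged.bed"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      jsonlite::write_json(corr, out("correlations.json"), auto_unbox = TRUE,
                           digits = NA)
      cobinding <- list(
        n_pairs = nrow(ov$pairs), n_cobound_a = length(ov$a_cobound),
        n_a_only = length(ov$a_only), n_b_only = length(ov$b_only),
        n_merged = nrow(merged), correlations = corr,
        gene_proportions = gene_props)
    }
  }

  report <- list(
    software = paste0("emtarget ",
                      as.character(utils::packageVersion("emtarget"))),
    seed = config$seed,
    thresholds = th,
    counts = list(
      n_genes = nrow(genes), n_probes = nrow(expression),
      n_peaks_a = nrow(peaks_a), n_peaks_a_filtered = nrow(peaks_a_f),
      n_peaks_b = if (is.null(peaks_b)) 0L else nrow(peaks_b),
      n_direct = sum(targets$directness == "direct"),
      n_indirect = sum(targets$directness == "indirect"),
      n_untargeted = sum(targets$directness == "untargeted")
    ),
    reversibility = reversibility,
    distance_bin_proportions = dist_props,
    csc_sensitivity = list(p_induced = csc_bias$p_induced,
                           p_repressed = csc_bias$p_repressed),
    cobinding = cobinding,
    warnings = warnings_log,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       dataframe = "columns", digits = NA, na = "null",
                       pretty = TRUE)
  invisible(report)
}
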