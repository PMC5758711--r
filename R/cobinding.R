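#' Partition two region sets into co-bound pairs and single-bound regions
#'
#' Two regions co-bind when their half-open intervals share at least one bp
#' (`a.end > b.start` and `b.end > a.start`). A region may take part in
#' several pairs; the single-bound partitions are computed at region level,
#' so `|A-only| + |co-bound A| = |A|`.
#'
#' @param set_a,set_b Region data.frames (0-based half-open).
#' @return A list with `pairs` (data.frame `a_id`, `b_id`), `a_only`,
#'   `b_only`, `a_cobound`, `b_cobound` (character vectors of region ids).
#' @export
overlap_regions <- function(set_a, set_b) {
  check_regions(set_a, "set A")
  check_regions(set_b, "set B")
  if (nrow(set_a) == 0L || nrow(set_b) == 0L) {
    pairs <- data.frame(a_id = character(), b_id = character(),
                        stringsAsFactors = FALSE)
  } else {
    hits <- GenomicRanges::findOverlaps(regions_to_granges(set_a),
                                        regions_to_granges(set_b))
    pairs <- data.frame(
      a_id = set_a$region_id[S4Vectors::queryHits(hits)],
      b_id = set_b$region_id[S4Vectors::subjectHits(hits)],
      stringsAsFactors = FALSE)
  }
  a_cobound <- unique(pairs$a_id)
  b_cobound <- unique(pairs$b_id)
  list(pairs = pairs,
       a_only = setdiff(set_a$region_id, a_cobound),
       b_only = setdiff(set_b$region_id, b_cobound),
       a_cobound = a_cobound, b_cobound = b_cobound)
}

#' Merge co-bound regions and standardize them to a fixed width
#'
#' Regions taking part in any A/B overlap are merged transitively (chained
#' overlaps collapse into one merged region, the union span). Each merged
#' region is then standardized to `width_bp` centered on the floored merged
#' midpoint. A standardized interval that would extend below position 0 is
#' clipped with a warning (and flagged in the output).
#'
#' @param set_a,set_b Region data.frames.
#' @param overlaps Result of [overlap_regions()] on the same sets; computed
#'   if omitted.
#' @param width_bp Standardized width in bp (default 300).
#' @return Data.frame with `merged_id`, `chrom`, `merged_start`,
#'   `merged_end`, `start`, `end` (the standardized interval), `clipped`,
#'   and comma-separated provenance columns `a_ids`, `b_ids`.
#' @export
merge_and_standardize <- function(set_a, set_b, overlaps = NULL,
                                  width_bp = 300L) {
  if (is.null(overlaps)) overlaps <- overlap_regions(set_a, set_b)
  a_in <- set_a[set_a$region_id %in% overlaps$a_cobound, , drop = FALSE]
  b_in <- set_b[set_b$region_id %in% overlaps$b_cobound, , drop = FALSE]
  if (nrow(a_in) == 0L) {
    return(data.frame(merged_id = character(), chrom = character(),
                      merged_start = numeric(), merged_end = numeric(),
                      start = numeric(), end = numeric(), clipped = logical(),
                      a_ids = character(), b_ids = character(),
                      stringsAsFactors = FALSE))
  }
  all_gr <- c(regions_to_granges(a_in), regions_to_granges(b_in))
  merged <- GenomicRanges::reduce(all_gr)
  m_chrom <- as.character(GenomicRanges::seqnames(merged))
  m_start <- GenomicRanges::start(merged) - 1 # back to 0-based
  m_end <- as.numeric(GenomicRanges::end(merged))

  center <- region_center(m_start, m_end)
  half <- floor(width_bp / 2)
  s_start <- center - half
  s_end <- s_start + width_bp
  clipped <- s_start < 0
  if (any(clipped)) {
    warning("merge_and_standardize: ", sum(clipped),
            " standardized interval(s) clipped at position 0")
    s_start[clipped] <- 0
  }

  prov <- function(regions) {
    hits <- GenomicRanges::findOverlaps(merged, regions_to_granges(regions))
    ids <- tapply(regions$region_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(x) paste(sort(x), collapse = ","))
    out <- rep("", length(merged))
    out[as.integer(names(ids))] <- ids
    out
  }
  data.frame(
    merged_id = sprintf("M_%05d", seq_along(merged)),
    chrom = m_chrom, merged_start = m_start, merged_end = m_end,
    start = s_start, end = s_end, clipped = clipped,
    a_ids = prov(a_in), b_ids = prov(b_in),
    stringsAsFactors = FALSE
  )
}

#' Count factor tags within standardized merged regions
#'
#' In `"regions"` mode each source region contributes its normalized tag
#' count apportioned by the fraction of the region's bp overlapping the
#' standardized window. In `"coverage"` mode the per-bp coverage value is
#' summed over the window.
#'
#' @param merged Output of [merge_and_standardize()].
#' @param source Either a region data.frame with `tag_count` (`mode =
#'   "regions"`) or a coverage data.frame with `value` (`mode =
#'   "coverage"`).
#' @param mode `"regions"` or `"coverage"`.
#' @return Numeric vector of counts, one per merged region, with the source
#'   mode recorded in attribute `mode`.
#' @export
count_tags <- function(merged, source, mode = c("regions", "coverage")) {
  mode <- match.arg(mode)
  if (is.null(source)) stop_input("count_tags: a tag source is required")
  counts <- numeric(nrow(merged))
  if (nrow(merged) > 0L) {
    win <- GenomicRanges::GRanges(
      merged$chrom, IRanges::IRanges(merged$start + 1L, merged$end))
    if (mode == "regions") {
      check_regions(source, "tag source", require_tags = TRUE)
      src <- regions_to_granges(source)
      hits <- GenomicRanges::findOverlaps(win, src)
      if (length(hits) > 0L) {
        sj <- S4Vectors::subjectHits(hits)
        w <- GenomicRanges::width(GenomicRanges::pintersect(
          win[S4Vectors::queryHits(hits)], src[sj]))
        contrib <- source$tag_count[sj] * w / (source$end[sj] - source$start[sj])
        agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
        counts[as.integer(names(agg))] <- agg
      }
    } else {
      check_columns(source, c("chrom", "start", "end", "value"),
                    "coverage track")
      src <- GenomicRanges::GRanges(
        source$chrom, IRanges::IRanges(source$start + 1L, source$end))
      hits <- GenomicRanges::findOverlaps(win, src)
      if (length(hits) > 0L) {
        sj <- S4Vectors::subjectHits(hits)
        w <- GenomicRanges::width(GenomicRanges::pintersect(
          win[S4Vectors::queryHits(hits)], src[sj]))
        agg <- tapply(source$value[sj] * w, S4Vectors::queryHits(hits), sum)
        counts[as.integer(names(agg))] <- agg
      }
    }
  }
  attr(counts, "mode") <- mode
  counts
}

#' Pearson correlation of two factors' tag counts over a region subset
#'
#' The standard product-moment correlation on raw counts. Fewer than three
#' regions in the subset, or a constant vector, yields `NA` (never a silent
#' zero) with a warning.
#'
#' @param counts_a,counts_b Numeric tag-count vectors, aligned.
#' @param subset Optional logical or integer index selecting the subset.
#' @return Pearson r in `[-1, 1]`, or `NA` when undefined.
#' @export
binding_correlation <- function(counts_a, counts_b, subset = NULL) {
  if (length(counts_a) != length(counts_b)) {
    stop_input("binding_correlation: count vectors must be aligned")
  }
  if (!is.null(subset)) {
    counts_a <- counts_a[subset]
    counts_b <- counts_b[subset]
  }
  if (length(counts_a) < 3L) {
    warning("binding_correlation: fewer than 3 regions; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) {
    warning("binding_correlation: constant counts; correlation undefined")
    return(NA_real_)
  }
  stats::cor(counts_a, counts_b)
}

#' Sensitivity-linked gene proportions of co-bound versus single-bound regions
#'
#' Using regions as the denominator, the proportion of co-bound regions
#' whose nearest gene is induced-and-sensitive (and, separately,
#' repressed-and-sensitive), compared with the same proportions among
#' single-bound regions by [fisher_exact_2x2()] on the region counts. An
#' empty region class yields `NA` proportions and p-values.
#'
#' @param cobound_annotations,single_annotations Data.frames from
#'   [nearest_tss()] for the co-bound and single-bound region sets.
#' @param calls Per-gene calls with `gene_id`, `direction`, `sensitive`.
#' @return Data.frame with one row per direction: proportions for co-bound
#'   and single-bound regions and the Fisher p-value.
#' @export
cobound_gene_proportions <- function(cobound_annotations, single_annotations,
                                     calls) {
  check_columns(calls, c("gene_id", "direction", "sensitive"), "calls table")
  class_of <- function(ann, dir) {
    ids <- calls$gene_id[calls$direction == dir & calls$sensitive]
    ann$nearest_gene_id %in% ids
  }
  rows <- lapply(c("induced", "repressed"), function(dir) {
    n_co <- nrow(cobound_annotations)
    n_single <- nrow(single_annotations)
    k_co <- sum(class_of(cobound_annotations, dir))
    k_single <- sum(class_of(single_annotations, dir))
    p <- if (n_co == 0L || n_single == 0L) NA_real_ else {
      suppressWarnings(fisher_exact_2x2(matrix(
        c(k_co, n_co - k_co, k_single, n_single - k_single), 2L,
        byrow = TRUE)))
    }
    data.frame(
      direction = dir,
      n_cobound = n_co, n_single = n_single,
      prop_cobound = if (n_co == 0L) NA_real_ else k_co / n_co,
      prop_single = if (n_single == 0L) NA_real_ else k_single / n_single,
      fisher_p = p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
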