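#' Filter binding regions by normalized tag count
#'
#' Keeps regions whose normalized tag count is at least `min_tags`
#' (inclusive), preserving order. The default of 12.2 reads is on the
#' reads-per-10-million scale of the upstream peak caller.
#'
#' @param regions Region data.frame (`chrom`, `start`, `end`, `region_id`,
#'   `tag_count`; 0-based half-open).
#' @param min_tags Minimum normalized tag count (default 12.2).
#' @return The filtered region data.frame; the number removed is attached as
#'   attribute `n_removed`.
#' @export
filter_regions <- function(regions, min_tags = 12.2) {
  check_regions(regions, require_tags = TRUE)
  keep <- regions$tag_count >= min_tags
  out <- regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Per-chromosome lookup of the nearest of a sorted set of anchor positions.
# Among anchors at equal distance the one with the lexicographically smallest
# id wins; anchors sharing a position are collapsed to their smallest id
# first. Returns index into the collapsed anchor table (NA if none on the
# chromosome).
nearest_anchor <- function(query_chrom, query_pos, anchor_chrom, anchor_pos,
                           anchor_id) {
  ord <- order(anchor_chrom, anchor_pos, anchor_id, method = "radix")
  a_chrom <- anchor_chrom[ord]
  a_pos <- anchor_pos[ord]
  # collapse duplicated (chrom, pos): first occurrence has the smallest id
  keep <- !duplicated(paste(a_chrom, a_pos))
  a_chrom <- a_chrom[keep]
  a_pos <- a_pos[keep]
  a_idx <- ord[keep] # index into original anchors
  a_id <- anchor_id[a_idx]

  out <- rep(NA_integer_, length(query_pos))
  for (ch in unique(query_chrom)) {
    qi <- which(query_chrom == ch)
    ai <- which(a_chrom == ch)
    if (length(ai) == 0L) next
    pos <- a_pos[ai]
    ids <- a_id[ai]
    left <- findInterval(query_pos[qi], pos)
    right <- pmin(left + 1L, length(pos))
    left_ok <- left >= 1L
    dl <- ifelse(left_ok, query_pos[qi] - pos[pmax(left, 1L)], Inf)
    dr <- ifelse(right > left, pos[right] - query_pos[qi], Inf)
    pick_left <- dl < dr |
      (dl == dr & ids[pmax(left, 1L)] <= ids[right])
    sel <- ifelse(pick_left, pmax(left, 1L), right)
    out[qi] <- a_idx[ai[sel]]
  }
  out
}

#' Annotate regions with their nearest TSS and signed distance
#'
#' The region center is the floored midpoint of the 0-based half-open
#' interval. The nearest gene minimizes the absolute center-to-TSS distance
#' on the same chromosome; ties are broken by the lexicographically smallest
#' gene id. The distance is signed by gene strand: a center upstream of the
#' TSS (relative to the direction of transcription) is negative.
#'
#' Regions on a chromosome carrying no gene are annotated with the sentinel
#' gene id `"no_gene"` and an `NA` distance, and should be excluded from
#' distance statistics.
#'
#' @param regions Region data.frame.
#' @param genes Gene annotation (`gene_id`, `chrom`, `tss`, `strand`).
#' @return Data.frame with `region_id`, `nearest_gene_id`, `signed_distance`.
#' @export
#' @examples
#' genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
#'                     tss = c(1000, 3000), strand = "+")
#' regs <- data.frame(chrom = "chr1", start = 1200, end = 1500,
#'                    region_id = "r1", tag_count = 20)
#' nearest_tss(regs, genes) # g1, +350
nearest_tss <- function(regions, genes) {
  check_regions(regions)
  check_columns(genes, c("gene_id", "chrom", "tss", "strand"), "gene table")
  if (nrow(regions) == 0L) {
    return(data.frame(region_id = character(), nearest_gene_id = character(),
                      signed_distance = numeric(), stringsAsFactors = FALSE))
  }
  center <- region_center(regions$start, regions$end)
  idx <- nearest_anchor(regions$chrom, center, genes$chrom, genes$tss,
                        genes$gene_id)
  found <- !is.na(idx)
  gid <- rep("no_gene", nrow(regions))
  dist <- rep(NA_real_, nrow(regions))
  gid[found] <- genes$gene_id[idx[found]]
  raw <- center[found] - genes$tss[idx[found]]
  dist[found] <- ifelse(genes$strand[idx[found]] == "-", -raw, raw)
  data.frame(region_id = regions$region_id, nearest_gene_id = gid,
             signed_distance = dist, stringsAsFactors = FALSE)
}

#' Minimum distance from each gene's TSS to any region center
#'
#' The per-gene counterpart of [nearest_tss()]: for every gene, the minimum
#' absolute distance between its TSS and the center of any region on the same
#' chromosome. Genes on a chromosome with no regions get `NA`.
#'
#' @param genes Gene annotation.
#' @param regions Region data.frame.
#' @return Numeric vector named by gene id.
#' @export
gene_min_region_distance <- function(genes, regions) {
  check_columns(genes, c("gene_id", "chrom", "tss"), "gene table")
  check_regions(regions)
  out <- rep(NA_real_, nrow(genes))
  if (nrow(regions) > 0L) {
    center <- region_center(regions$start, regions$end)
    idx <- nearest_anchor(genes$chrom, genes$tss, regions$chrom, center,
                          regions$region_id)
    found <- !is.na(idx)
    out[found] <- abs(genes$tss[found] - center[idx[found]])
  }
  stats::setNames(out, genes$gene_id)
}

feature_priority <- c("promoter", "5utr", "3utr", "exon", "intron", "tts",
                      "ncRNA", "pseudo", "rRNA", "intergenic")

#' Classify regions into genomic feature classes
#'
#' Assigns each region the highest-priority feature overlapping its center,
#' in the order promoter > 5utr > 3utr > exon > intron > tts > ncRNA >
#' pseudo > rRNA > intergenic. The promoter class is derived from the gene
#' table as a strict window of less than 1 kb either side of a TSS; all other
#' classes come from the supplied feature track. A center inside no interval
#' is intergenic.
#'
#' @param regions Region data.frame.
#' @param genes Gene annotation used to derive promoter windows.
#' @param feature_track Data.frame (`chrom`, `start`, `end`, `feature`;
#'   0-based half-open) of typed intervals, or `NULL` for promoter-vs-
#'   intergenic classification only.
#' @param promoter_bp Promoter radius in bp; a center qualifies when its
#'   distance to a TSS is strictly below this value (default 1000).
#' @return Character vector of feature labels, one per region.
#' @export
classify_feature <- function(regions, genes, feature_track = NULL,
                             promoter_bp = 1000) {
  check_regions(regions)
  if (nrow(regions) == 0L) return(character())
  center <- region_center(regions$start, regions$end)
  idx <- nearest_anchor(regions$chrom, center, genes$chrom, genes$tss,
                        genes$gene_id)
  found <- !is.na(idx)
  min_dist <- rep(Inf, nrow(regions))
  min_dist[found] <- abs(center[found] - genes$tss[idx[found]])

  label <- rep("intergenic", nrow(regions))
  if (!is.null(feature_track) && nrow(feature_track) > 0L) {
    check_columns(feature_track, c("chrom", "start", "end", "feature"),
                  "feature track")
    bad <- which(!(feature_track$start < feature_track$end))
    if (length(bad) > 0L) {
      stop_input("feature track: malformed interval (start >= end) at line ",
                 bad[1L])
    }
    unknown <- setdiff(unique(feature_track$feature), feature_priority)
    if (length(unknown) > 0L) {
      stop_input("feature track: unknown feature label(s): ",
                 paste(unknown, collapse = ", "))
    }
    pts <- GenomicRanges::GRanges(regions$chrom,
                                  IRanges::IRanges(center + 1L, center + 1L))
    trk <- GenomicRanges::GRanges(
      feature_track$chrom,
      IRanges::IRanges(feature_track$start + 1L, feature_track$end))
    hits <- GenomicRanges::findOverlaps(pts, trk)
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits)
      f <- feature_track$feature[S4Vectors::subjectHits(hits)]
      rank <- match(f, feature_priority)
      best <- tapply(rank, q, min)
      label[as.integer(names(best))] <- feature_priority[best]
    }
  }
  label[min_dist < promoter_bp] <- "promoter"
  label
}

#' Annotate regions with the maximally overlapping chromatin state
#'
#' Each region takes the label of the state segment sharing the most bp with
#' it; zero overlap yields `"none"`, and an exact tie goes to the leftmost
#' segment. Overlapping state segments are an input error.
#'
#' @param regions Region data.frame.
#' @param states State segmentation data.frame (`chrom`, `start`, `end`,
#'   `state`; 0-based half-open, pairwise disjoint).
#' @return Character vector of state labels, one per region.
#' @export
annotate_chromatin_state <- function(regions, states) {
  check_regions(regions)
  check_columns(states, c("chrom", "start", "end", "state"), "state track")
  if (nrow(states) > 0L) {
    ord <- order(states$chrom, states$start)
    s <- states[ord, ]
    same <- s$chrom[-1L] == s$chrom[-nrow(s)]
    if (any(same & s$start[-1L] < s$end[-nrow(s)])) {
      stop_input("state track: segments overlap")
    }
  }
  if (nrow(regions) == 0L) return(character())
  label <- rep("none", nrow(regions))
  if (nrow(states) == 0L) return(label)
  rg <- regions_to_granges(regions)
  sg <- GenomicRanges::GRanges(states$chrom,
                               IRanges::IRanges(states$start + 1L, states$end))
  hits <- GenomicRanges::findOverlaps(rg, sg)
  if (length(hits) > 0L) {
    q <- S4Vectors::queryHits(hits)
    sj <- S4Vectors::subjectHits(hits)
    w <- GenomicRanges::width(GenomicRanges::pintersect(rg[q], sg[sj]))
    # max overlap, ties to leftmost segment start
    ord <- order(q, -w, states$start[sj])
    first <- !duplicated(q[ord])
    label[q[ord][first]] <- states$state[sj[ord][first]]
  }
  label
}

#' Proportion of genes with a region within each distance bin
#'
#' For each named gene subset and each bin bound `b`, the proportion of
#' subset genes whose minimum TSS-to-region-center distance is at most `b`.
#' Bins are cumulative, so proportions are monotone non-decreasing in `b`.
#' An empty subset reports `NA`.
#'
#' @param min_distances Named numeric vector of per-gene minimum distances,
#'   as from [gene_min_region_distance()]; `NA` means no region on the
#'   gene's chromosome.
#' @param gene_subsets Named list of gene-id vectors.
#' @param bins Strictly increasing numeric vector of distance bounds (bp).
#' @return Data.frame with one row per subset x bin: `subset`, `bin_bp`,
#'   `n_genes`, `n_within`, `proportion`.
#' @export
distance_bin_proportions <- function(min_distances, gene_subsets, bins) {
  if (is.unsorted(bins, strictly = TRUE)) {
    stop_input("distance_bin_proportions: bins must be strictly increasing")
  }
  if (is.null(names(gene_subsets))) {
    stop_input("distance_bin_proportions: gene_subsets must be named")
  }
  d <- ifelse(is.na(min_distances), Inf, min_distances)
  rows <- lapply(names(gene_subsets), function(nm) {
    ids <- gene_subsets[[nm]]
    dd <- d[ids]
    n <- length(ids)
    data.frame(
      subset = nm, bin_bp = bins, n_genes = n,
      n_within = vapply(bins, function(b) sum(dd <= b, na.rm = TRUE),
                        numeric(1)),
      proportion = if (n == 0L) NA_real_ else
        vapply(bins, function(b) sum(dd <= b, na.rm = TRUE) / n, numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Strand-oriented TSS metaprofile of a coverage track
#'
#' For each gene a window of `half_window_bp` either side of the TSS is
#' extracted in the direction of transcription, coverage is summed per
#' `bin_bp` bin (per-bp coverage value times overlap width) and the profile
#' is averaged across genes. Minus-strand windows are reflected about the
#' TSS base, so bin 1 is always the most upstream bin. Genes whose window
#' leaves the chromosome are skipped with a warning.
#'
#' @param coverage Coverage data.frame (`chrom`, `start`, `end`, `value`;
#'   0-based half-open, non-negative values).
#' @param genes Gene annotation.
#' @param bin_bp Bin width in bp (default 100).
#' @param half_window_bp Half window in bp (default 1500, giving 30 bins).
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   detect windows running off the end of a chromosome.
#' @return Data.frame with `offset_bp` (bin start relative to the TSS, gene
#'   orientation) and `mean_coverage`; the number of genes averaged is
#'   attached as attribute `n_genes`.
#' @export
tss_metaprofile <- function(coverage, genes, bin_bp = 100,
                            half_window_bp = 1500, chrom_sizes = NULL) {
  check_columns(coverage, c("chrom", "start", "end", "value"),
                "coverage track")
  if (any(coverage$value < 0)) {
    stop_input("coverage track: values must be non-negative")
  }
  n_bins <- 2 * half_window_bp / bin_bp
  if (n_bins != round(n_bins)) {
    stop_input("tss_metaprofile: window must be a whole number of bins")
  }
  n_bins <- as.integer(n_bins)

  ok <- genes$tss - half_window_bp >= 0
  if (!is.null(chrom_sizes)) {
    ok <- ok & genes$tss + half_window_bp <= chrom_sizes[genes$chrom]
  }
  if (any(!ok)) {
    warning("tss_metaprofile: skipping ", sum(!ok),
            " gene(s) whose window exceeds the chromosome")
  }
  g <- genes[ok, , drop = FALSE]
  offsets <- -half_window_bp + (seq_len(n_bins) - 1L) * bin_bp
  if (nrow(g) == 0L) {
    out <- data.frame(offset_bp = offsets, mean_coverage = NA_real_)
    attr(out, "n_genes") <- 0L
    return(out)
  }

  # genomic bin intervals, one row per gene x bin (0-based half-open)
  tss <- rep(g$tss, each = n_bins)
  minus <- rep(g$strand == "-", each = n_bins)
  o <- rep(offsets, times = nrow(g))
  bin_start <- ifelse(minus, tss - o - bin_bp + 1, tss + o)
  gr <- GenomicRanges::GRanges(
    rep(g$chrom, each = n_bins),
    IRanges::IRanges(bin_start + 1L, bin_start + bin_bp))
  cov_gr <- GenomicRanges::GRanges(
    coverage$chrom,
    IRanges::IRanges(coverage$start + 1L, coverage$end))
  hits <- GenomicRanges::findOverlaps(gr, cov_gr)
  sums <- numeric(length(gr))
  if (length(hits) > 0L) {
    q <- S4Vectors::queryHits(hits)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      gr[q], cov_gr[S4Vectors::subjectHits(hits)]))
    contrib <- w * coverage$value[S4Vectors::subjectHits(hits)]
    agg <- tapply(contrib, q, sum)
    sums[as.integer(names(agg))] <- agg
  }
  mat <- matrix(sums, nrow = n_bins)
  out <- data.frame(offset_bp = offsets, mean_coverage = rowMeans(mat))
  attr(out, "n_genes") <- nrow(g)
  out
}
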