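#' Classify direct, indirect and untargeted genes
#'
#' A gene is a `direct` target when it is knockdown-sensitive and some
#' binding-region center lies within `direct_threshold_bp` of its TSS
#' (inclusive), an `indirect` target when it is sensitive but has no such
#' region, and `untargeted` when it is not sensitive. Genes absent from the
#' distance table are classified `untargeted` with a warning.
#'
#' @param calls Data.frame of per-gene calls with columns `gene_id` and
#'   `sensitive` (as from [sensitivity_calls()], collapsed to genes).
#' @param min_distances Named numeric vector of per-gene minimum
#'   TSS-to-region-center distances (see [gene_min_region_distance()]).
#' @param direct_threshold_bp Direct-target distance threshold in bp,
#'   inclusive (default 5000).
#' @return Data.frame with `gene_id`, `directness`, `min_abs_distance_bp`.
#' @export
classify_targets <- function(calls, min_distances, direct_threshold_bp = 5000) {
  check_columns(calls, c("gene_id", "sensitive"), "calls table")
  absent <- !(calls$gene_id %in% names(min_distances))
  if (any(absent)) {
    warning("classify_targets: ", sum(absent),
            " gene(s) absent from the distance table; classified untargeted")
  }
  d <- min_distances[calls$gene_id]
  directness <- ifelse(!calls$sensitive, "untargeted",
                ifelse(!is.na(d) & d <= direct_threshold_bp,
                       "direct", "indirect"))
  directness[absent] <- "untargeted"
  data.frame(gene_id = calls$gene_id, directness = directness,
             min_abs_distance_bp = unname(d), stringsAsFactors = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by point-probability ordering: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7). A table with a zero margin has no
#' alternative arrangements and returns p = 1 with a warning.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative counts.
#' @return The two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)) # 2/252
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop_input("fisher_exact_2x2: a 2x2 table is required")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_input("fisher_exact_2x2: counts must be non-negative integers")
  }
  if (sum(tab) == 0) stop_input("fisher_exact_2x2: table total must be > 0")
  r1 <- sum(tab[1L, ]) # margin of row 1
  c1 <- sum(tab[, 1L]) # margin of column 1
  n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warning("fisher_exact_2x2: a margin is zero; p = 1 by convention")
    return(1)
  }
  support <- max(0, r1 + c1 - n):min(r1, c1)
  d <- stats::dhyper(support, c1, n - c1, r1)
  d_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' Hypergeometric gene-set enrichment
#'
#' For each category, the upper-tail probability of drawing at least the
#' observed overlap when `|query|` genes are sampled without replacement
#' from the universe, together with the expected overlap and a
#' Benjamini-Hochberg adjusted p-value across categories (reported alongside,
#' never substituted for, the raw p).
#'
#' @param query Character vector of gene ids (must lie in the universe).
#' @param categories Named list of gene-id vectors; each is intersected with
#'   the universe.
#' @param universe Character vector of all gene ids.
#' @return Data.frame with `category`, `size`, `overlap`, `expected`,
#'   `p_upper`, `p_bh`.
#' @export
hypergeom_enrichment <- function(query, categories, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    stop_input("hypergeom_enrichment: the universe is empty")
  }
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop_input("hypergeom_enrichment: query genes must lie in the universe")
  }
  if (is.null(names(categories))) {
    stop_input("hypergeom_enrichment: categories must be named")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(unique(categories[[nm]]), universe)
    K <- length(cat_genes)
    ov <- length(intersect(query, cat_genes))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, size = K, overlap = ov, expected = n * K / N,
               p_upper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_upper, method = "BH")
  rownames(out) <- NULL
  out
}

#' Proximity bias of binding toward CSC- versus NCSC-expressed genes
#'
#' For each distance bin, tabulates how many CSC-biased and NCSC-biased
#' genes have a region center within the bin of their TSS and tests the 2x2
#' table (within/beyond bin x CSC/NCSC) with [fisher_exact_2x2()].
#'
#' @param min_distances Named per-gene minimum distances
#'   (see [gene_min_region_distance()]).
#' @param csc_genes,ncsc_genes Disjoint character vectors of gene ids.
#' @param bins Strictly increasing distance bounds in bp.
#' @return Data.frame with `bin_bp`, `prop_csc`, `prop_ncsc`, `fisher_p`.
#' @export
csc_proximity_bias <- function(min_distances, csc_genes, ncsc_genes, bins) {
  if (length(intersect(csc_genes, ncsc_genes)) > 0L) {
    stop_input("csc_proximity_bias: gene sets must be disjoint")
  }
  if (is.unsorted(bins, strictly = TRUE)) {
    stop_input("csc_proximity_bias: bins must be strictly increasing")
  }
  if (length(csc_genes) == 0L || length(ncsc_genes) == 0L) {
    return(data.frame(bin_bp = bins, prop_csc = NA_real_,
                      prop_ncsc = NA_real_, fisher_p = NA_real_))
  }
  d <- ifelse(is.na(min_distances), Inf, min_distances)
  d_csc <- d[csc_genes]
  d_ncsc <- d[ncsc_genes]
  rows <- lapply(bins, function(b) {
    a <- sum(d_csc <= b, na.rm = TRUE)
    c_ <- sum(d_ncsc <= b, na.rm = TRUE)
    tab <- matrix(c(a, length(csc_genes) - a,
                    c_, length(ncsc_genes) - c_), 2L, byrow = TRUE)
    p <- if (a + c_ == 0L) 1 else
      suppressWarnings(fisher_exact_2x2(tab))
    data.frame(bin_bp = b, prop_csc = a / length(csc_genes),
               prop_ncsc = c_ / length(ncsc_genes), fisher_p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' CSC-bias contingency among sensitive versus insensitive genes
#'
#' Among induced genes with a CSC or NCSC bias, tabulates sensitivity
#' against bias direction and tests the table with [fisher_exact_2x2()];
#' likewise for repressed genes. Directions with no biased genes, or with no
#' sensitive (or no insensitive) genes, report `NA` rather than a p-value.
#'
#' @param calls Data.frame with columns `direction`, `sensitive`,
#'   `csc_bias` (as from [sensitivity_calls()]).
#' @return A list with `induced_table`, `repressed_table` (2x2 matrices,
#'   rows sensitive/insensitive, columns csc/ncsc) and `p_induced`,
#'   `p_repressed`.
#' @export
csc_sensitivity_bias <- function(calls) {
  check_columns(calls, c("direction", "sensitive", "csc_bias"), "calls table")
  one <- function(dir) {
    sub <- calls[calls$direction == dir & calls$csc_bias != "none", ]
    tab <- matrix(
      c(sum(sub$sensitive & sub$csc_bias == "csc"),
        sum(sub$sensitive & sub$csc_bias == "ncsc"),
        sum(!sub$sensitive & sub$csc_bias == "csc"),
        sum(!sub$sensitive & sub$csc_bias == "ncsc")),
      2L, byrow = TRUE,
      dimnames = list(c("sensitive", "insensitive"), c("csc", "ncsc")))
    p <- if (nrow(sub) == 0L || sum(tab[1L, ]) == 0L || sum(tab[2L, ]) == 0L) {
      NA_real_
    } else suppressWarnings(fisher_exact_2x2(tab))
    list(table = tab, p = p)
  }
  ind <- one("induced")
  rep_ <- one("repressed")
  list(induced_table = ind$table, repressed_table = rep_$table,
       p_induced = ind$p, p_repressed = rep_$p)
}
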