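#' Call positive phospho-hits on a peptide array
#'
#' A peptide is positive when its normalized mean signal is equal to or
#' greater than `k_sd` standard deviations above the mean of all peptide
#' signals on the array. The SD is the population SD (divide by n) by
#' default. When the SD is zero every signal equals the mean; no peptide is
#' called positive and the result is flagged degenerate.
#'
#' @param signals Numeric vector of mean signals, or a data.frame with a
#'   `mean_signal` column (and optionally `peptide_id` used for names).
#' @param k_sd Number of SDs above the mean (default 2).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return A list with `positive` (named logical vector), `threshold`,
#'   `mean`, `sd` and `degenerate`.
#' @export
#' @examples
#' call_phospho_hits(c(1, 1, 1, 1, 10)) # threshold 10; the 10 is positive
call_phospho_hits <- function(signals, k_sd = 2,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  ids <- NULL
  if (is.data.frame(signals)) {
    check_columns(signals, "mean_signal", "peptide table")
    ids <- signals$peptide_id
    signals <- signals$mean_signal
  }
  if (length(signals) < 2L) {
    stop_input("call_phospho_hits: at least 2 peptides are required")
  }
  if (any(signals < 0)) {
    stop_input("call_phospho_hits: signals must be non-negative")
  }
  m <- mean(signals)
  s <- if (sd_type == "population") {
    sqrt(sum((signals - m)^2) / length(signals))
  } else {
    stats::sd(signals)
  }
  threshold <- m + k_sd * s
  degenerate <- s == 0
  positive <- if (degenerate) rep(FALSE, length(signals)) else
    signals >= threshold
  if (!is.null(ids)) names(positive) <- ids
  list(positive = positive, threshold = threshold, mean = m, sd = s,
       degenerate = degenerate)
}

#' Scan a protein sequence for residue-class motif patterns
#'
#' Patterns use a small character-class notation over the 20-letter amino
#' acid alphabet: a literal residue matches itself, `[ST]` matches any
#' residue in the class, and `x` (or `X`) is a wildcard. All occurrences are
#' reported, including overlapping ones, at 1-based offsets, optionally
#' restricted to matches overlapping a residue window.
#'
#' @param protein_seq Single amino-acid string.
#' @param patterns Character vector of patterns, e.g. `"[ST]x[KR]"`.
#' @param window Optional integer vector `c(from, to)` (1-based, inclusive);
#'   only matches overlapping the window are kept.
#' @return Data.frame with `pattern`, `offset` (1-based start), `match`
#'   (the matched subsequence), ordered by pattern then offset.
#' @export
#' @examples
#' scan_motif_windows("SAKTAR", "[ST]x[KR]") # offsets 1 and 4
scan_motif_windows <- function(protein_seq, patterns, window = NULL) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  aa <- "ACDEFGHIKLMNPQRSTVWY"
  seq_chars <- strsplit(protein_seq, "")[[1L]]
  if (!all(seq_chars %in% strsplit(aa, "")[[1L]])) {
    stop_input("scan_motif_windows: protein sequence contains a symbol ",
               "outside the 20-letter amino-acid alphabet")
  }
  rows <- lapply(patterns, function(pat) {
    toks <- parse_motif_pattern(pat, aa)
    plen <- length(toks)
    if (plen == 0L || plen > length(seq_chars)) {
      return(NULL)
    }
    offs <- integer()
    for (i in seq_len(length(seq_chars) - plen + 1L)) {
      ok <- TRUE
      for (j in seq_len(plen)) {
        if (!(seq_chars[i + j - 1L] %in% toks[[j]])) { ok <- FALSE; break }
      }
      if (ok) offs <- c(offs, i)
    }
    if (!is.null(window)) {
      if (window[1L] > window[2L]) offs <- integer() # empty window
      else offs <- offs[offs <= window[2L] & (offs + plen - 1L) >= window[1L]]
    }
    if (length(offs) == 0L) return(NULL)
    data.frame(pattern = pat, offset = offs,
               match = vapply(offs, function(o) {
                 paste(seq_chars[o:(o + plen - 1L)], collapse = "")
               }, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pattern = character(), offset = integer(),
                      match = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Tokenize a motif pattern into a list of allowed-residue character sets.
parse_motif_pattern <- function(pattern, aa) {
  aa_chars <- strsplit(aa, "")[[1L]]
  chars <- strsplit(pattern, "")[[1L]]
  toks <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)[1L]
      if (is.na(close) || close == i + 1L) {
        stop_input("motif pattern '", pattern, "': malformed character class")
      }
      cls <- chars[(i + 1L):(close - 1L)]
      if (!all(cls %in% aa_chars)) {
        stop_input("motif pattern '", pattern,
                   "': invalid residue in character class")
      }
      toks[[length(toks) + 1L]] <- cls
      i <- close + 1L
    } else if (ch %in% c("x", "X")) {
      toks[[length(toks) + 1L]] <- aa_chars
      i <- i + 1L
    } else if (ch %in% aa_chars) {
      toks[[length(toks) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop_input("motif pattern '", pattern, "': invalid symbol '", ch, "'")
    }
  }
  toks
}

#' Total nuclear or cell fluorescence intensity (TNFI / TCFI)
#'
#' The sum of channel intensities over the chosen mask minus the per-pixel
#' background estimate times the mask area. A negative result indicates an
#' overestimated background and is flagged with a warning, never silently
#' zeroed. An empty mask is an input error.
#'
#' @param image A [cell_image()].
#' @param mask_kind `"nuclear"` (TNFI) or `"cell"` (TCFI).
#' @param channel Channel name or index (default first channel).
#' @return Background-corrected total intensity (scalar).
#' @export
fluorescence_intensity <- function(image, mask_kind = c("nuclear", "cell"),
                                   channel = 1L) {
  mask_kind <- match.arg(mask_kind)
  stopifnot(inherits(image, "cell_image"))
  mask <- if (mask_kind == "nuclear") image$nuclear_mask else image$cell_mask
  if (!any(mask)) {
    stop_input("fluorescence_intensity: the ", mask_kind, " mask is empty")
  }
  ch <- image$channels[[channel]]
  total <- sum(ch[mask]) - image$background_value * sum(mask)
  if (total < 0) {
    warning("fluorescence_intensity: negative corrected intensity ",
            "(background overestimates the masked signal)")
  }
  total
}

#' Pixel-level colocalization of two channels
#'
#' Pearson correlation of the two channels over the masked pixels: -1 is
#' inverse colocalization, 0 none, +1 perfect. Requires at least three
#' masked pixels; a constant channel within the mask yields `NA` with a
#' warning.
#'
#' @param channel_a,channel_b Numeric matrices of equal shape.
#' @param mask Logical matrix, same shape.
#' @return Pearson r in `[-1, 1]`, or `NA` when undefined.
#' @export
pixel_colocalization <- function(channel_a, channel_b, mask) {
  if (!identical(dim(channel_a), dim(channel_b)) ||
      !identical(dim(channel_a), dim(mask))) {
    stop_input("pixel_colocalization: channels and mask must share a shape")
  }
  if (sum(mask) < 3L) {
    stop_input("pixel_colocalization: at least 3 masked pixels are required")
  }
  a <- channel_a[mask]
  b <- channel_b[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("pixel_colocalization: constant channel; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Partition cells into intensity phenotypes
#'
#' Phenotype 1 (high) for values strictly above `hi`, phenotype 3 (low) for
#' values strictly below `lo`, phenotype 2 (moderate) for the inclusive band
#' between them. The circulating-tumour-cell thresholds used for the
#' phospho-form are `hi = 1100`, `lo = 500` and for the total protein
#' `hi = 1500`, `lo = 600` (TNFI units).
#'
#' @param values Numeric vector of intensities.
#' @param hi,lo Band thresholds (`lo < hi`).
#' @return Integer vector of labels in `{1, 2, 3}`.
#' @export
#' @examples
#' phenotype_partition(c(1200, 1100, 499), hi = 1100, lo = 500) # 1 2 3
phenotype_partition <- function(values, hi, lo) {
  if (!(lo < hi)) stop_input("phenotype_partition: lo must be < hi")
  ifelse(values > hi, 1L, ifelse(values < lo, 3L, 2L))
}
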