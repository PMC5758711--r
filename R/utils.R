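#' Round half away from zero
#'
#' Printed percentages in array summaries are conventionally rounded half-up
#' (41.65 -> 41.7), whereas [base::round()] rounds half to even. Used wherever
#' a percentage is reported to a fixed number of decimals.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(41.65, 1) # 41.7
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Derive a named substream seed from a root seed
#'
#' Each simulator draws from its own substream so that adding or re-ordering
#' generators never perturbs the draws of another. The substream seed is a
#' deterministic hash of the root seed and the stream name, kept below 2^31.
#'
#' @param seed Integer root seed.
#' @param name Character stream name, e.g. `"genome"`.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m)
}

# Evaluate `code` under the substream RNG without touching the caller's
# RNG state.
with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# Stop with a classed condition so callers/tests can distinguish
# configuration errors from input errors.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("emtarget_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("emtarget_input_error", "error")))
}

# Internal: check required columns, naming the offending table and column.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_input(what, " is missing required column(s): ",
               paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Internal: validate a 0-based half-open region data.frame.
check_regions <- function(regions, what = "region set", require_tags = FALSE) {
  cols <- c("chrom", "start", "end", "region_id")
  if (require_tags) cols <- c(cols, "tag_count")
  check_columns(regions, cols, what)
  if (nrow(regions) == 0L) return(invisible(regions))
  bad <- which(!(regions$start < regions$end))
  if (length(bad) > 0L) {
    stop_input(what, ": start must be < end (0-based half-open); first offender row ",
               bad[1L])
  }
  if (anyDuplicated(regions$region_id)) {
    stop_input(what, ": region_id values must be unique")
  }
  if (require_tags && any(regions$tag_count < 0)) {
    stop_input(what, ": tag_count must be non-negative")
  }
  invisible(regions)
}

# Internal: midpoint of a 0-based half-open interval, floored on odd widths.
region_center <- function(start, end) {
  floor((start + end) / 2)
}

# Internal: convert 0-based half-open region df to GRanges (1-based closed).
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}
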