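# Readers and writers for the plain-text formats the pipeline exchanges.
# Genomic intervals are 0-based half-open on disk and in memory. BED score
# columns carry the normalized tag count times 100 (BED scores are
# conventionally integers).

#' Read a gene annotation TSV
#'
#' Expects a header with columns `chrom`, `tss`, `strand`, `gene_id`.
#'
#' @param path File path.
#' @return Gene annotation data.frame.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("chrom", "tss", "strand", "gene_id"), basename(path))
  if (anyDuplicated(df$gene_id)) {
    stop_input(basename(path), ": duplicate gene_id values")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop_input(basename(path), ": strand must be '+' or '-'")
  }
  df
}

#' Write a gene annotation TSV
#' @param genes Gene annotation data.frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "tss", "strand", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read binding regions from a 5-column BED file
#'
#' Uses rtracklayer for parsing; the BED score column is interpreted as the
#' normalized tag count times `tag_scale`.
#'
#' @param path File path.
#' @param tag_scale Divisor applied to the score column (default 100).
#' @return Region data.frame (`chrom`, `start`, `end`, `region_id`,
#'   `tag_count`; 0-based half-open).
#' @export
read_bed_regions <- function(path, tag_scale = 100) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    region_id = if (!is.null(gr$name)) as.character(gr$name) else
      sprintf("region_%05d", seq_along(gr)),
    tag_count = if (!is.null(gr$score)) as.numeric(gr$score) / tag_scale else 0,
    stringsAsFactors = FALSE
  )
  check_regions(df, basename(path), require_tags = TRUE)
}

#' Write binding regions to a 5-column BED file
#' @param regions Region data.frame.
#' @param path File path.
#' @param tag_scale Multiplier applied to `tag_count` for the score column.
#' @return The path, invisibly.
#' @export
write_bed_regions <- function(regions, path, tag_scale = 100) {
  out <- data.frame(regions$chrom, format_bp(regions$start),
                    format_bp(regions$end), regions$region_id,
                    round(regions$tag_count * tag_scale))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation from a 4-column BED file
#' @param path File path.
#' @return State data.frame (`chrom`, `start`, `end`, `state`).
#' @export
read_states_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    state = as.character(gr$name),
    stringsAsFactors = FALSE
  )
}

#' Write a chromatin-state segmentation to a 4-column BED file
#' @param states State data.frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_states_bed <- function(states, path) {
  out <- data.frame(states$chrom, format_bp(states$start),
                    format_bp(states$end), states$state)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path File path.
#' @return Coverage data.frame (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    value = as.numeric(gr$score),
    stringsAsFactors = FALSE
  )
}

#' Read an expression table TSV
#'
#' Columns are matched by header name; `probe_id`, `baseline_mock` and
#' `stim_mock` are required, the knockdown and compartment arms optional.
#'
#' @param path File path.
#' @return Expression data.frame.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("probe_id", "baseline_mock", "stim_mock"),
                basename(path))
  if (anyDuplicated(df$probe_id)) {
    stop_input(basename(path), ": duplicate probe_id values")
  }
  df
}

#' Write a TSV with a header
#' @param df Data.frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-set categories from a GMT-style file
#'
#' One set per line: set name, description, then gene ids, tab-separated.
#'
#' @param path File path.
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop_input(basename(path), ": GMT line needs name, description and ",
                 "at least one gene")
    }
    out[[parts[1L]]] <- parts[-(1:2)]
  }
  out
}

# bp coordinates may exceed integer range as doubles; print without
# scientific notation.
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Validate pipeline input files
#'
#' Line-level validation without aborting at the first problem: for each
#' file, the detected format, the row count and any violations (malformed
#' intervals, negative widths, duplicate ids, non-numeric values, missing
#' columns) with 1-based line numbers.
#'
#' @param paths Named character vector or list; names among `genes`,
#'   `expression`, `peaks_a`, `peaks_b`, `states`, `coverage`.
#' @return A list with `files` (data.frame file, format, n_rows) and
#'   `violations` (data.frame file, line, violation).
#' @export
validate_inputs <- function(paths) {
  files <- list()
  violations <- list()
  note <- function(file, line, msg) {
    violations[[length(violations) + 1L]] <<-
      data.frame(file = file, line = line, violation = msg,
                 stringsAsFactors = FALSE)
  }
  for (kind in names(paths)) {
    path <- paths[[kind]]
    if (!file.exists(path)) {
      stop(errorCondition(paste0("validate_inputs: cannot read ", path),
                          class = c("emtarget_io_error", "error")))
    }
    fmt <- if (grepl("\\.bed$", path)) "BED"
           else if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE)) "bedGraph"
           else "TSV"
    nm <- basename(path)
    if (fmt %in% c("BED", "bedGraph")) {
      raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                               colClasses = "character")
      n <- nrow(raw)
      start <- suppressWarnings(as.numeric(raw[[2L]]))
      end <- suppressWarnings(as.numeric(raw[[3L]]))
      for (i in seq_len(n)) {
        if (is.na(start[i]) || is.na(end[i])) {
          note(nm, i, "non-numeric interval bound")
        } else if (!(start[i] < end[i])) {
          note(nm, i, "start >= end (intervals are 0-based half-open)")
        } else if (start[i] < 0) {
          note(nm, i, "negative start coordinate")
        }
      }
      if (fmt == "BED" && ncol(raw) >= 4L && anyDuplicated(raw[[4L]]) &&
          kind %in% c("peaks_a", "peaks_b")) {
        first_dup <- which(duplicated(raw[[4L]]))[1L]
        note(nm, first_dup, "duplicate region id")
      }
    } else {
      df <- utils::read.delim(path, stringsAsFactors = FALSE)
      n <- nrow(df)
      if (kind == "genes") {
        miss <- setdiff(c("chrom", "tss", "strand", "gene_id"), names(df))
        for (m in miss) note(nm, NA_integer_, paste0("missing column ", m))
        if ("gene_id" %in% names(df) && anyDuplicated(df$gene_id)) {
          note(nm, which(duplicated(df$gene_id))[1L] + 1L, "duplicate gene_id")
        }
      }
      if (kind == "expression") {
        miss <- setdiff(c("probe_id", "baseline_mock", "stim_mock",
                          "stim_sirna"), names(df))
        for (m in miss) note(nm, NA_integer_, paste0("missing column ", m))
        for (col in intersect(c("baseline_mock", "stim_mock", "stim_sirna"),
                              names(df))) {
          if (!is.numeric(df[[col]])) {
            note(nm, NA_integer_, paste0("non-numeric values in ", col))
          }
          nas <- which(is.na(df[[col]]))
          for (i in nas) note(nm, i + 1L, paste0("missing value in ", col))
        }
        if ("probe_id" %in% names(df) && anyDuplicated(df$probe_id)) {
          note(nm, which(duplicated(df$probe_id))[1L] + 1L,
               "duplicate probe_id")
        }
      }
    }
    files[[length(files) + 1L]] <- data.frame(
      file = nm, kind = kind, format = fmt, n_rows = n,
      stringsAsFactors = FALSE)
  }
  list(
    files = do.call(rbind, files),
    violations = if (length(violations)) do.call(rbind, violations) else
      data.frame(file = character(), line = integer(),
                 violation = character(), stringsAsFactors = FALSE)
  )
}
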