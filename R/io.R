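#' Read cluster-level interactions from a BEDPE file
#'
#' Expects the BEDPE dialect written by upstream ChIA-PET cluster callers:
#' `chromA startA endA chromB startB endB [name] count [...]`, tab- or
#' space-delimited, coordinates 0-based half-open. The column holding the
#' inter-ligation PET count is configurable because upstream versions
#' differ. Anchors are canonicalized so anchor A sorts first.
#'
#' @param path BEDPE file path.
#' @param count_col 1-based index of the count column (default 8).
#' @param zero_based If `FALSE`, input start coordinates are 1-based
#'   inclusive and are shifted to the internal 0-based half-open convention.
#' @return Canonical pair data frame (see [pet_dataset()]).
#' @export
read_interactions <- function(path, count_col = 8L, zero_based = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no interaction records in ", path)
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < max(7L, count_col))
  if (length(bad))
    stop(sprintf("malformed BEDPE line %d in %s: %d field(s), need at least %d",
                 bad[1], path, nf[bad[1]], max(7L, count_col)))
  getcol <- function(j) vapply(fields, `[[`, character(1), j)
  suppress_na <- function(x) suppressWarnings(as.numeric(x))
  starts_a <- suppress_na(getcol(2)); ends_a <- suppress_na(getcol(3))
  starts_b <- suppress_na(getcol(5)); ends_b <- suppress_na(getcol(6))
  cnt <- suppress_na(getcol(count_col))
  bad <- which(is.na(starts_a) | is.na(ends_a) | is.na(starts_b) |
                 is.na(ends_b))
  if (length(bad))
    stop(sprintf("malformed BEDPE line %d in %s: non-numeric coordinate",
                 bad[1], path))
  bad <- which(is.na(cnt) | cnt != floor(cnt))
  if (length(bad))
    stop(sprintf("malformed BEDPE line %d in %s: non-integer count %s",
                 bad[1], path, getcol(count_col)[bad[1]]))
  if (!zero_based) { starts_a <- starts_a - 1; starts_b <- starts_b - 1 }
  name <- if (count_col > 7L) getcol(7) else sprintf("pair_%05d", seq_along(lines))
  pairs <- data.frame(
    chrom_a = getcol(1), start_a = as.integer(starts_a),
    end_a = as.integer(ends_a),
    chrom_b = getcol(4), start_b = as.integer(starts_b),
    end_b = as.integer(ends_b),
    count = as.integer(cnt), pair_id = name, stringsAsFactors = FALSE)
  if (any(pairs$start_a < 0 | pairs$start_b < 0 |
            pairs$end_a <= pairs$start_a | pairs$end_b <= pairs$start_b))
    stop("invalid anchor coordinates (need 0 <= start < end) in ", path)
  canonicalize_pairs(pairs)
}

#' Read self-ligation PET spans from BED or BEDPE
#'
#' Only the first three columns (one span) are used; BEDPE self-ligation
#' records are reduced to the span from the leftmost to the rightmost
#' coordinate of the two ends.
#'
#' @param path BED/BEDPE file path.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_self_ligation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          blank.lines.skip = TRUE)
  if (nrow(dt) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  if (ncol(dt) >= 6 && is.character(dt[[4]]) && !anyNA(
        suppressWarnings(as.numeric(dt[[5]]))) &&
      all(dt[[1]] == dt[[4]])) {
    # BEDPE with both ends on one chromosome: use the full span
    return(data.frame(chrom = as.character(dt[[1]]),
                      start = pmin(as.integer(dt[[2]]), as.integer(dt[[5]])),
                      end = pmax(as.integer(dt[[3]]), as.integer(dt[[6]]))))
  }
  data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]))
}

#' Read a scored interval track (bedGraph or BED5)
#'
#' Auto-detects the layout: 4 columns with a numeric 4th is bedGraph
#' (`chrom start end score`); 5 or more columns take the score from column
#' 5 (BED5 `chrom start end name score`). Intervals are sorted per
#' chromosome; overlapping intervals are resolved by splitting into
#' disjoint pieces that keep the maximum overlapping score (a message is
#' logged when this happens).
#'
#' @param path Track file path.
#' @return Data frame with columns `chrom`, `start`, `end`, `score`,
#'   non-overlapping and sorted within each chromosome.
#' @export
read_scored_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    log_msg("warn", "empty interval track: ", path)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("malformed track line %d in %s: fewer than 4 fields",
                 which(nf < 4L)[1], path))
  getcol <- function(j) vapply(fields, `[[`, character(1), j)
  four_col <- all(nf == 4L)
  score <- suppressWarnings(as.numeric(getcol(if (four_col) 4L else 5L)))
  if (anyNA(score))
    stop("non-numeric score values in ", path)
  out <- data.frame(chrom = getcol(1),
                    start = as.integer(suppressWarnings(as.numeric(getcol(2)))),
                    end = as.integer(suppressWarnings(as.numeric(getcol(3)))),
                    score = score, stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end) || any(out$start < 0) ||
        any(out$end <= out$start))
    stop("invalid interval coordinates in ", path)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  gr <- GenomicRanges::GRanges(out$chrom,
                               IRanges::IRanges(out$start + 1L, out$end))
  if (!identical(GenomicRanges::isDisjoint(gr), TRUE)) {
    log_msg("info", "overlapping intervals in ", path,
            ": splitting with max score")
    dj <- GenomicRanges::disjoin(gr)
    hits <- GenomicRanges::findOverlaps(dj, gr)
    mx <- tapply(out$score[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), max)
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(dj)),
      start = GenomicRanges::start(dj) - 1L,
      end = GenomicRanges::end(dj),
      score = as.numeric(mx[as.character(seq_along(dj))]),
      stringsAsFactors = FALSE)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write the per-pair result table and run metadata
#'
#' Emits a BEDPE-plus TSV with a header: the six anchor fields, PET count,
#' the four covariates, the marginal count, the posterior responsibility
#' (printed with 6 decimals) and the signal/noise label, ordered by
#' (chrom_a, start_a, chrom_b, start_b). A companion
#' `<path>.meta.json` always records the configuration, seeds and an Rhat
#' summary, so a result file is never separated from its provenance.
#'
#' @param records Result data frame as built by [build_result_table()].
#' @param path Output TSV path.
#' @param metadata Named list stored as JSON next to the table.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path, metadata = list()) {
  ord <- order(records$chrom_a, records$start_a, records$chrom_b,
               records$start_b)
  records <- records[ord, , drop = FALSE]
  records$responsibility <- sprintf("%.6f", as.numeric(records$responsibility))
  data.table::fwrite(records, path, sep = "\t", col.names = TRUE)
  meta_path <- paste0(path, ".meta.json")
  jsonlite::write_json(metadata, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Assemble per-pair result records from a dataset and fit
#'
#' @param dataset A [pet_dataset()].
#' @param fit A `pet_fit` for that dataset.
#' @param report_min_count Reporting cut-off recorded in the
#'   `passes_report_filter` column (default 3).
#' @return Data frame of result records.
#' @export
build_result_table <- function(dataset, fit, report_min_count = 3L) {
  p <- dataset$pairs; cv <- dataset$covariates
  data.frame(
    chrom_a = p$chrom_a, start_a = p$start_a, end_a = p$end_a,
    chrom_b = p$chrom_b, start_b = p$start_b, end_b = p$end_b,
    pair_id = p$pair_id, count = p$count,
    enrichment = cv$enrichment, gc = cv$gc, mappability = cv$mappability,
    distance = cv$distance, mc = cv$mc,
    responsibility = fit$responsibility, label = fit$labels,
    passes_report_filter = p$count >= report_min_count,
    stringsAsFactors = FALSE)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Result TSV path.
#' @return Data frame with numeric responsibilities.
#' @export
read_results <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chrom_a"))
  as.data.frame(dt)
}

## -- logging ---------------------------------------------------------------

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Timestamped stderr logging
#'
#' Messages below the active level (option `petmix.log_level`, default
#' `"info"`) are suppressed.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @param ... Message parts, concatenated.
#' @return Invisibly, `NULL`.
#' @export
log_msg <- function(level = "info", ...) {
  active <- getOption("petmix.log_level", "info")
  if (log_levels[[level]] < log_levels[[active]]) return(invisible(NULL))
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), paste0(...)))
  invisible(NULL)
}
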