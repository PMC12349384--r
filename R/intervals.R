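#' Construct a genomic interval table
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end` and an
#' optional `name`, using BED semantics throughout: 0-based, half-open
#' `[start, end)`. Strand is deliberately absent — every overlap computation
#' in the package is strand-agnostic.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; `start >= 0`, `end > start`.
#' @param name Optional character vector of labels.
#' @return A tibble of class `mlk_intervals`, sorted by `(chrom, start, end)`.
#' @export
#' @examples
#' intervals(c("chr1", "chr1"), c(100L, 400L), c(200L, 500L))
intervals <- function(chrom, start, end, name = NA_character_) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = if (length(name) == 1L) rep(as.character(name), length(chrom)) else as.character(name)
  )
  validate_intervals(out)
}

validate_intervals <- function(x) {
  if (any(is.na(x$chrom) | x$chrom == "")) {
    stop("interval chromosome names must be non-empty", call. = FALSE)
  }
  if (any(is.na(x$start) | is.na(x$end))) {
    stop("interval coordinates must not be missing", call. = FALSE)
  }
  if (any(x$start < 0L)) {
    stop("interval start must be >= 0", call. = FALSE)
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0L) {
    stop(sprintf("interval end must exceed start (first offender: row %d, %s:%d-%d)",
                 bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]), call. = FALSE)
  }
  out <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  class(out) <- unique(c("mlk_intervals", class(out)))
  out
}

#' Read a BED file of genomic regions
#'
#' Accepts BED3/BED4; lines starting with `#`, `track` or `browser` are
#' skipped. Coordinates keep their native BED semantics (0-based half-open).
#'
#' @param path Path to a BED file.
#' @return An interval tibble (see [intervals()]), sorted by `(chrom, start)`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(intervals(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    i <- which(nf < 3L)[1]
    stop(sprintf("malformed BED line %d in %s: fewer than 3 tab-separated fields",
                 lineno[i], path), call. = FALSE)
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("malformed BED line %d in %s: non-integer coordinates",
                 lineno[i], path), call. = FALSE)
  }
  nm <- vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  intervals(vapply(fields, `[[`, "", 1L), start, end, nm)
}

#' Which probes fall inside a set of intervals?
#'
#' A probe at 0-based position `p` on chromosome `c` overlaps an interval
#' `[start, end)` on `c` iff `start <= p < end`.
#'
#' @param probes Probe manifest: tibble with `probe_id`, `chrom`, `position`.
#' @param regions Interval tibble (BED semantics).
#' @return Character vector of `probe_id`s with at least one overlap,
#'   in manifest order.
#' @export
overlap_probes <- function(probes, regions) {
  stopifnot(all(c("probe_id", "chrom", "position") %in% names(probes)))
  if (nrow(probes) == 0L || nrow(regions) == 0L) return(character())
  hit <- rep(FALSE, nrow(probes))
  for (ch in intersect(unique(probes$chrom), unique(regions$chrom))) {
    pi <- which(probes$chrom == ch)
    ri <- regions[regions$chrom == ch, ]
    # BED [start, end) -> 1-based closed [start+1, end]; point p -> p+1
    q <- IRanges::IRanges(start = probes$position[pi] + 1L, width = 1L)
    s <- IRanges::IRanges(start = ri$start + 1L, end = ri$end)
    hit[pi] <- IRanges::overlapsAny(q, s)
  }
  probes$probe_id[hit]
}
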