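#' Read a probes-by-samples or genes-by-samples TSV matrix
#'
#' The file must carry a header row of sample ids and row ids in the first
#' column. `kind = "beta"` enforces values in \[0, 1\]; `kind = "expression"`
#' accepts any finite value (expression is assumed log-scale normalized
#' upstream). Missing cells (`NA`, empty) stay missing — they are never
#' imputed or zero-filled.
#'
#' @param path Path to a tab-delimited file.
#' @param kind `"beta"` or `"expression"`.
#' @return A numeric matrix with unique row and column names.
#' @export
read_matrix <- function(path, kind = c("beta", "expression")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          na.strings = c("NA", ""))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row id in ", path, ": ", ids[duplicated(ids)][1], call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample id in header of ", path, call. = FALSE)
  }
  if (kind == "beta") {
    bad <- which(!is.na(m) & (m < 0 | m > 1))
    if (length(bad) > 0L) {
      stop(sprintf("beta value outside [0,1] in %s (row '%s'): %g", path,
                   rownames(m)[(bad[1] - 1L) %% nrow(m) + 1L], m[bad[1]]), call. = FALSE)
    }
  }
  m
}

#' Read the sample table (case/control labels plus optional survival)
#'
#' Columns: `sample_id`, `group`, and optionally `survival_time` (days) and
#' `event` (1 = event observed, 0 = censored). Group labels are matched
#' case-insensitively to `case`/`control`.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `sample_id`, `group` (factor case/control),
#'   `survival_time`, `event` (logical; both `NA` when absent).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  grp <- tolower(trimws(as.character(df$group)))
  bad <- setdiff(unique(grp), c("case", "control"))
  if (length(bad) > 0L) {
    stop("unknown group label(s) in ", path, ": ", paste(bad, collapse = ", "),
         " (expected case/control)", call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(df$sample_id),
    group = factor(grp, levels = c("case", "control")),
    survival_time = if ("survival_time" %in% names(df)) as.numeric(df$survival_time) else NA_real_,
    event = if ("event" %in% names(df)) as.logical(as.integer(df$event)) else NA
  )
  validate_sample_table(out)
}

validate_sample_table <- function(x) {
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ", x$sample_id[duplicated(x$sample_id)][1], call. = FALSE)
  }
  if (sum(x$group == "case") < 2L || sum(x$group == "control") < 2L) {
    stop("need at least 2 case and 2 control samples", call. = FALSE)
  }
  if (any(xor(is.na(x$survival_time), is.na(x$event)))) {
    stop("survival_time and event must be present together", call. = FALSE)
  }
  if (any(x$survival_time < 0, na.rm = TRUE)) {
    stop("survival_time must be non-negative", call. = FALSE)
  }
  x
}

#' Read a probe manifest (probe id + genomic coordinate)
#'
#' @param path TSV with columns `probe_id`, `chrom`, `position`.
#' @param coords `"bed"` (default; positions already 0-based) or
#'   `"one-based"` (positions are converted by subtracting 1 at read time, so
#'   all internal coordinates share the BED convention).
#' @return Tibble `probe_id`, `chrom`, `position` (0-based).
#' @export
read_probe_manifest <- function(path, coords = c("bed", "one-based")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("probe manifest not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "chrom", "position") %in% names(df)))
  pos <- as.integer(df$position)
  if (coords == "one-based") pos <- pos - 1L
  out <- tibble::tibble(probe_id = as.character(df$probe_id),
                        chrom = as.character(df$chrom), position = pos)
  if (anyDuplicated(out$probe_id)) {
    stop("duplicate probe_id in manifest: ",
         out$probe_id[duplicated(out$probe_id)][1], call. = FALSE)
  }
  if (any(out$position < 0L)) stop("probe position must be >= 0", call. = FALSE)
  out
}

#' Read a gene annotation table with TSS coordinates and a TF flag
#'
#' @param path TSV with columns `gene_id`, `gene_name`, `chrom`, `tss`
#'   (0-based), `strand` (+/-), `is_tf` (0/1 or TRUE/FALSE).
#' @return Tibble with those columns; `is_tf` logical.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("gene annotation not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "gene_name", "chrom", "tss", "strand", "is_tf") %in% names(df)))
  out <- tibble::tibble(
    gene_id = as.character(df$gene_id),
    gene_name = as.character(df$gene_name),
    chrom = as.character(df$chrom),
    tss = as.integer(df$tss),
    strand = as.character(df$strand),
    is_tf = as.logical(as.integer(as.logical(df$is_tf)))
  )
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id: ", out$gene_id[duplicated(out$gene_id)][1], call. = FALSE)
  }
  if (any(out$tss < 0L)) stop("tss must be >= 0", call. = FALSE)
  if (!all(out$strand %in% c("+", "-"))) stop("strand must be + or -", call. = FALSE)
  out
}

#' Read TF motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with letter-probability matrices over A, C, G, T.
#' Each matrix row must sum to 1 within 1e-3 and motifs must be at least
#' 4 bp wide.
#'
#' @param path Path to a MEME minimal-format file.
#' @return Named list of PWMs; each is a list with `motif_id`,
#'   `matrix` (width x 4, columns A/C/G/T) and `background` (length-4,
#'   uniform 0.25 unless the file declares one).
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_line <- grep("^Background letter frequencies", lines)
  if (length(bg_line) > 0L && bg_line[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_line[1] + 1L]), "\\s+")[[1]]
    if (length(toks) >= 8L) {
      vals <- as.numeric(toks[c(2, 4, 6, 8)])
      names(vals) <- toks[c(1, 3, 5, 7)]
      bg <- vals[c("A", "C", "G", "T")]
    }
  }
  motif_starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (ms in motif_starts) {
    motif_id <- strsplit(trimws(lines[ms]), "\\s+")[[1]][2]
    li <- ms + 1L
    while (li <= length(lines) && !grepl("^letter-probability matrix", lines[li])) li <- li + 1L
    if (li > length(lines)) stop("motif ", motif_id, " lacks a letter-probability matrix", call. = FALSE)
    rows <- list()
    li <- li + 1L
    while (li <= length(lines)) {
      tl <- trimws(lines[li])
      if (!nzchar(tl) || grepl("^(MOTIF|URL)\\b", tl)) break
      vals <- suppressWarnings(as.numeric(strsplit(tl, "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
      li <- li + 1L
    }
    mat <- do.call(rbind, rows)
    if (is.null(mat) || nrow(mat) < 4L) {
      stop("motif ", motif_id, " has width < 4", call. = FALSE)
    }
    sums <- rowSums(mat)
    if (any(abs(sums - 1) > 1e-3)) {
      stop(sprintf("motif %s: probability row %d sums to %.4f (not 1 within 1e-3)",
                   motif_id, which(abs(sums - 1) > 1e-3)[1],
                   sums[which(abs(sums - 1) > 1e-3)[1]]), call. = FALSE)
    }
    colnames(mat) <- c("A", "C", "G", "T")
    out[[motif_id]] <- list(motif_id = motif_id, matrix = mat, background = bg)
  }
  out
}

link_table_cols <- c("probe_id", "gene_id", "gene_name", "quadrant", "z", "p",
                     "p_adj", "wilcoxon_p", "wilcoxon_p_adj", "significant")

#' Write / read a finalized link table
#'
#' The on-disk format is a TSV with a stable column order
#' (`probe_id, gene_id, gene_name, quadrant, z, p, p_adj, wilcoxon_p,
#' wilcoxon_p_adj, significant`); numeric fields round-trip losslessly
#' (full double precision).
#'
#' @param links Link tibble as produced by [run_linking()].
#' @param path Output path.
#' @return `write_link_table()` returns `path` invisibly; `read_link_table()`
#'   returns the link tibble.
#' @export
write_link_table <- function(links, path) {
  stopifnot(all(link_table_cols %in% names(links)))
  out <- links[, link_table_cols]
  out <- dplyr::mutate(out, dplyr::across(dplyr::where(is.double), ~ sprintf("%.17g", .x)))
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), ~ ifelse(.x == "NA" | is.na(.x), "NA", as.character(.x))))
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_link_table
#' @export
read_link_table <- function(path) {
  if (!file.exists(path)) stop("link table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", colClasses = c(
                            probe_id = "character", gene_id = "character",
                            gene_name = "character", quadrant = "character",
                            z = "numeric", p = "numeric", p_adj = "numeric",
                            wilcoxon_p = "numeric", wilcoxon_p_adj = "numeric",
                            significant = "logical"))
  tibble::as_tibble(df[, link_table_cols])
}
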