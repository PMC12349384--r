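#' Split samples into high and low groups on a feature
#'
#' Median rule: high = strictly above the median, low = at or below. Tertile
#' rule: top third vs bottom third (by rank), middle discarded.
#'
#' @param values Named numeric vector (names = sample ids).
#' @param rule `"median"` (default) or `"tertile"`.
#' @return List with `high` and `low` character vectors of sample ids.
#' @export
stratify_samples <- function(values, rule = c("median", "tertile")) {
  rule <- match.arg(rule)
  values <- values[!is.na(values)]
  if (length(values) < 4L) stop("need >= 4 samples with values", call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("all values identical: no stratification possible", call. = FALSE)
  }
  if (rule == "median") {
    md <- stats::median(values)
    list(high = names(values)[values > md], low = names(values)[values <= md])
  } else {
    ord <- names(values)[order(values, names(values))]
    third <- floor(length(ord) / 3)
    list(high = ord[(length(ord) - third + 1L):length(ord)],
         low = ord[seq_len(third)])
  }
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: at each distinct event time the expected
#' events per group are proportional to the at-risk counts; the statistic is
#' `(O - E)^2 / V`, chi-squared with 1 df under the null.
#'
#' @param time Named numeric vector of follow-up times (days).
#' @param event Named logical/0-1 vector (TRUE = event observed), aligned
#'   with `time`.
#' @param high,low Character vectors of sample ids forming the two groups.
#' @return Object of class `mlk_logrank`: list with `statistic`, `p`,
#'   `n_high`, `n_low`, `n_events`.
#' @export
logrank_test <- function(time, event, high, low) {
  ids <- c(high, low)
  ids <- ids[!is.na(time[ids]) & !is.na(event[ids])]
  g <- ifelse(ids %in% high, "high", "low")
  t_ <- time[ids]
  e_ <- as.integer(as.logical(event[ids]))
  if (sum(e_) == 0L) stop("no observed events: log-rank test undefined", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(t_, e_) ~ g)
  structure(list(statistic = unname(sd_$chisq),
                 p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
                 n_high = sum(g == "high"), n_low = sum(g == "low"),
                 n_events = sum(e_)),
            class = "mlk_logrank")
}

#' @export
print.mlk_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4f (1 df), p = %.4g [high n=%d, low n=%d, %d events]\n",
              x$statistic, x$p, x$n_high, x$n_low, x$n_events))
  invisible(x)
}

#' @export
tidy.mlk_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p, df = 1)
}

#' @export
glance.mlk_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p,
                 n_high = x$n_high, n_low = x$n_low, n_events = x$n_events)
}

#' Survival association of one feature (TF expression or probe methylation)
#'
#' Stratifies samples on the feature and runs the log-rank test; the
#' tidy-row output makes per-feature screens a simple `purrr::map_dfr()`.
#'
#' @param values Named numeric vector of the feature across samples.
#' @param samples Sample table with `survival_time` and `event` filled in.
#' @param feature_id Identifier reported in the output.
#' @param feature_kind `"tf_expression"` or `"probe_methylation"`.
#' @param rule Stratification rule, see [stratify_samples()].
#' @return One-row tibble: `feature_id`, `feature_kind`, `n_high`, `n_low`,
#'   `statistic`, `p`.
#' @export
survival_association <- function(values, samples, feature_id,
                                 feature_kind = c("tf_expression", "probe_methylation"),
                                 rule = "median") {
  feature_kind <- match.arg(feature_kind)
  has_surv <- !is.na(samples$survival_time) & !is.na(samples$event)
  ids <- intersect(names(values)[!is.na(values)], samples$sample_id[has_surv])
  if (length(ids) < 4L) stop("need >= 4 samples with both feature and survival data", call. = FALSE)
  strat <- stratify_samples(values[ids], rule = rule)
  tm <- stats::setNames(samples$survival_time, samples$sample_id)
  ev <- stats::setNames(samples$event, samples$sample_id)
  lr <- logrank_test(tm, ev, strat$high, strat$low)
  tibble::tibble(feature_id = feature_id, feature_kind = feature_kind,
                 n_high = lr$n_high, n_low = lr$n_low,
                 statistic = lr$statistic, p = lr$p)
}

#' Assign candidate target genes to probes via TAD co-membership
#'
#' Topologically associating domains (TADs) constrain enhancer-gene
#' contacts; each probe inside a TAD is paired with every gene whose TSS
#' lies in the same TAD. TADs must be non-overlapping within a chromosome.
#'
#' @param probes Probe manifest tibble.
#' @param genes Gene annotation tibble.
#' @param tads Interval tibble of TADs (BED semantics).
#' @return Tibble `probe_id`, `gene_id`, `tad_id`. Probes outside all TADs
#'   contribute no rows.
#' @export
assign_targets_by_tad <- function(probes, genes, tads) {
  if (nrow(tads) > 0L) {
    by_chrom <- split(seq_len(nrow(tads)), tads$chrom)
    for (idx in by_chrom) {
      t_ <- tads[idx, ]
      t_ <- t_[order(t_$start), ]
      if (nrow(t_) > 1L && any(t_$start[-1] < t_$end[-nrow(t_)])) {
        stop("overlapping TADs on ", t_$chrom[1], ": TADs must partition each chromosome",
             call. = FALSE)
      }
    }
  }
  tad_id <- ifelse(is.na(tads$name) | tads$name == "",
                   sprintf("%s:%d-%d", tads$chrom, tads$start, tads$end),
                   tads$name)
  out <- vector("list", nrow(tads))
  for (i in seq_len(nrow(tads))) {
    p_in <- probes$chrom == tads$chrom[i] &
      probes$position >= tads$start[i] & probes$position < tads$end[i]
    g_in <- genes$chrom == tads$chrom[i] &
      genes$tss >= tads$start[i] & genes$tss < tads$end[i]
    if (!any(p_in) || !any(g_in)) next
    out[[i]] <- tidyr::expand_grid(probe_id = probes$probe_id[p_in],
                                   gene_id = genes$gene_id[g_in]) |>
      dplyr::mutate(tad_id = tad_id[i])
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble::tibble(probe_id = character(), gene_id = character(),
                          tad_id = character()))
  }
  dplyr::arrange(res, .data$probe_id, .data$gene_id)
}

#' Probe overlap with ChIP-seq peaks
#'
#' Per-probe logical flag; same half-open overlap contract as
#' [overlap_probes()].
#'
#' @param probes Probe manifest tibble.
#' @param peaks Interval tibble of peaks.
#' @return Logical vector aligned with `probes` rows.
#' @export
overlap_probes_with_peaks <- function(probes, peaks) {
  probes$probe_id %in% overlap_probes(probes, peaks)
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

scan_pwm_one_strand <- function(idx, lo, threshold) {
  w <- nrow(lo)
  nw <- length(idx) - w + 1L
  if (nw < 1L) return(tibble::tibble(offset = integer(), score = double()))
  scores <- numeric(nw)
  valid <- rep(TRUE, nw)
  for (i in seq_len(w)) {
    b <- idx[i:(i + nw - 1L)]
    valid <- valid & !is.na(b)
    s <- unname(lo[i, ifelse(is.na(b), 1L, b)])
    scores <- scores + s
  }
  hit <- valid & scores >= threshold
  tibble::tibble(offset = which(hit) - 1L, score = unname(scores[hit]))
}

#' Scan a DNA sequence with a position weight matrix
#'
#' Each window is scored as the sum of `log2(p_i[base] / bg[base])` over
#' motif positions; both strands are scanned (reverse complement for `-`),
#' windows containing `N` are skipped, and hits scoring at least `threshold`
#' are returned. Offsets are 0-based window starts on the forward sequence
#' for both strands.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pwm PWM list (`matrix` width x 4 over A,C,G,T; `background`), as
#'   produced by [read_meme_motifs()].
#' @param threshold Minimum log2-odds score for a hit.
#' @return Tibble `offset`, `strand` (+/-), `score`, sorted by offset then
#'   strand.
#' @export
scan_pwm <- function(sequence, pwm, threshold) {
  stopifnot(is.finite(threshold))
  sequence <- toupper(sequence)
  mat <- pwm$matrix
  bg <- pwm$background
  lo <- log2(sweep(mat, 2, bg, "/"))  # 0-probability cells give -Inf: never a hit
  w <- nrow(mat)
  L <- nchar(sequence)
  empty <- tibble::tibble(offset = integer(), strand = character(), score = double())
  if (L < w) return(empty)
  bases <- c("A", "C", "G", "T")
  idx_f <- match(strsplit(sequence, "")[[1]], bases)
  fwd <- scan_pwm_one_strand(idx_f, lo, threshold)
  fwd$strand <- rep("+", nrow(fwd))
  idx_r <- match(strsplit(revcomp(sequence), "")[[1]], bases)
  rev_ <- scan_pwm_one_strand(idx_r, lo, threshold)
  # offset o on the reverse complement covers forward window starting L - w - o
  rev_$offset <- L - w - rev_$offset
  rev_$strand <- rep("-", nrow(rev_))
  out <- dplyr::bind_rows(fwd, rev_)[, c("offset", "strand", "score")]
  dplyr::arrange(out, .data$offset, .data$strand)
}

#' Build the TF-expression / probe-methylation heatmap matrices
#'
#' Produces the two aligned sample-ordered matrices conventionally drawn as
#' stacked heatmaps: TF expression on top, linked RE-site methylation below.
#' Rows: TFs ordered by significant linked-probe count in the chosen
#' quadrant (ties by gene name); each probe is grouped under its best-linked
#' TF (largest |z| among its significant links; ties by gene id) and probes
#' within a TF block are ordered by |z| descending (ties by probe id).
#' Columns: control samples first, then case samples, each ordered by
#' ascending mean methylation over the selected probes. Fully deterministic.
#'
#' @param links Finalized link tibble with significant links.
#' @param expr Genes x samples expression matrix.
#' @param beta Probes x samples beta matrix.
#' @param samples Sample table tibble.
#' @param quadrant Which link quadrant to display (default `hypo_up`).
#' @return List with `expression` (TFs x samples), `methylation`
#'   (probes x samples), `tf_order`, `probe_order`, `sample_order`, and
#'   `probe_tf` (tibble mapping each probe to its anchoring TF).
#' @export
heatmap_matrix <- function(links, expr, beta, samples, quadrant = "hypo_up") {
  sig <- dplyr::filter(links, .data$significant, .data$quadrant == !!quadrant)
  if (nrow(sig) == 0L) stop("no significant links in quadrant ", quadrant, call. = FALSE)
  tf_order <- sig |>
    dplyr::distinct(.data$gene_id, .data$gene_name, .data$probe_id) |>
    dplyr::count(.data$gene_id, .data$gene_name) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$gene_name) |>
    dplyr::pull(.data$gene_id)
  probe_tf <- sig |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::arrange(dplyr::desc(abs(.data$z)), .data$gene_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("probe_id", "gene_id", "z")
  probe_order <- probe_tf |>
    dplyr::mutate(tf_pos = match(.data$gene_id, tf_order)) |>
    dplyr::arrange(.data$tf_pos, dplyr::desc(abs(.data$z)), .data$probe_id) |>
    dplyr::pull(.data$probe_id)
  sub_beta <- beta[probe_order, , drop = FALSE]
  mean_meth <- colMeans(sub_beta, na.rm = TRUE)
  order_within <- function(ids) ids[order(mean_meth[ids], ids)]
  sample_order <- c(order_within(samples$sample_id[samples$group == "control"]),
                    order_within(samples$sample_id[samples$group == "case"]))
  list(expression = expr[tf_order, sample_order, drop = FALSE],
       methylation = sub_beta[, sample_order, drop = FALSE],
       tf_order = tf_order, probe_order = probe_order,
       sample_order = sample_order,
       probe_tf = dplyr::select(probe_tf, "probe_id", "gene_id"))
}
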