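#' Build the sample groups used to score one dysregulated probe
#'
#' For a `hypo_in_case` probe the dysregulated group is the set of case
#' samples with beta below the hypomethylation cutoff H; for a
#' `hyper_in_case` probe, case samples with beta at or above the methylation
#' cutoff M. The baseline group is always the control samples with a
#' non-missing beta at that probe.
#'
#' @param probe_id Probe identifier (must be a row of `beta`).
#' @param category `"hypo_in_case"` or `"hyper_in_case"`.
#' @param beta Probes x samples beta matrix.
#' @param samples Sample table tibble.
#' @param cutoffs `meth_cutoffs` object.
#' @return List with `probe_id`, `direction` (hypo/hyper), `dys_samples`,
#'   `baseline_samples`, or `NULL` (with a message) when fewer than 2
#'   baseline samples remain.
#' @export
build_link_group <- function(probe_id, category, beta, samples, cutoffs) {
  stopifnot(category %in% c("hypo_in_case", "hyper_in_case"))
  b <- beta[probe_id, ]
  case_ids <- samples$sample_id[samples$group == "case"]
  ctrl_ids <- samples$sample_id[samples$group == "control"]
  bk <- b[case_ids]
  dys <- if (category == "hypo_in_case") {
    case_ids[!is.na(bk) & bk < cutoffs$hypo]
  } else {
    case_ids[!is.na(bk) & bk >= cutoffs$meth]
  }
  baseline <- ctrl_ids[!is.na(b[ctrl_ids])]
  if (length(baseline) < 2L) {
    message("probe ", probe_id, " skipped: fewer than 2 baseline samples with beta")
    return(NULL)
  }
  list(probe_id = probe_id,
       direction = if (category == "hypo_in_case") "hypo" else "hyper",
       dys_samples = dys, baseline_samples = baseline)
}

#' Group-mean Z statistic linking a probe to one gene's expression
#'
#' `z = (mean(expr[dys]) - mean(expr[baseline])) /
#'      (sd(expr[baseline]) / sqrt(n_dys))`
#' with the sample standard deviation (n - 1 denominator) of the baseline
#' (control) expression. Missing expression values are dropped from the group
#' they occur in.
#'
#' @param expr_gene Named numeric vector: one gene's expression per sample.
#' @param group Link group from [build_link_group()].
#' @return The Z value, or `NA` when either group has < 2 non-missing values
#'   or the baseline standard deviation is zero.
#' @export
compute_z <- function(expr_gene, group) {
  xd <- expr_gene[group$dys_samples]
  xb <- expr_gene[group$baseline_samples]
  xd <- xd[!is.na(xd)]
  xb <- xb[!is.na(xb)]
  if (length(xd) < 2L || length(xb) < 2L) return(NA_real_)
  sdb <- stats::sd(xb)
  if (!is.finite(sdb) || sdb == 0) return(NA_real_)
  (mean(xd) - mean(xb)) / (sdb / sqrt(length(xd)))
}

#' One-sided normal tail probability for a link Z score
#'
#' Both tails are evaluated and the pair is assigned the direction with the
#' smaller p (ties at z = 0 go to "up"), matching how quadrants are oriented.
#'
#' @param z Finite Z value(s).
#' @return Tibble with `p` (the smaller one-sided tail) and `direction`
#'   ("up" for the upper tail, "down" for the lower).
#' @export
z_to_p <- function(z) {
  stopifnot(all(is.finite(z)))
  p_up <- stats::pnorm(z, lower.tail = FALSE)
  p_dn <- stats::pnorm(z)
  up <- p_up <= p_dn
  tibble::tibble(p = pmax(ifelse(up, p_up, p_dn), .Machine$double.xmin),
                 direction = ifelse(up, "up", "down"))
}

#' Benjamini-Hochberg adjustment over the pooled candidate links
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values (same order as input).
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

wilcoxon_p <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) return(NA_real_)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  no_ties <- !any(duplicated(pooled))
  use_exact <- length(x) <= 10L && length(y) <= 10L && no_ties
  suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                      correct = TRUE)$p.value)
}

#' Refine screened links with Wilcoxon rank-sum tests
#'
#' For every link that survived the Z-score screen (`p_adj < alpha`), a
#' two-sided Wilcoxon rank-sum test compares the gene's expression between
#' the probe's dysregulated and baseline samples (exact null when both
#' groups have <= 10 observations and no ties; normal approximation with tie
#' and continuity correction otherwise). The surviving links' Wilcoxon
#' p-values are BH-corrected among themselves, and a link is `significant`
#' only when both adjusted p-values fall below `alpha`.
#'
#' @param links Link tibble with `p_adj` present.
#' @param expr Genes x samples expression matrix.
#' @param groups Named list of link groups (names = probe ids).
#' @param alpha Significance level (default 0.05).
#' @return `links` with `wilcoxon_p`, `wilcoxon_p_adj` and `significant`
#'   filled in (NA / FALSE for links that failed the screen).
#' @export
wilcoxon_refine <- function(links, expr, groups, alpha = 0.05) {
  links$wilcoxon_p <- NA_real_
  links$wilcoxon_p_adj <- NA_real_
  links$significant <- FALSE
  keep <- which(!is.na(links$p_adj) & links$p_adj < alpha)
  if (length(keep) == 0L) return(links)
  wp <- purrr::map_dbl(keep, function(i) {
    g <- groups[[links$probe_id[i]]]
    e <- expr[links$gene_id[i], ]
    wilcoxon_p(e[g$dys_samples], e[g$baseline_samples])
  })
  ok <- !is.na(wp)
  links$wilcoxon_p[keep] <- wp
  links$wilcoxon_p_adj[keep[ok]] <- adjust_bh(wp[ok])
  links$significant <- !is.na(links$wilcoxon_p_adj) & links$wilcoxon_p_adj < alpha
  links
}

#' Score every dysregulated probe against candidate genes (steps 3-5)
#'
#' For each probe classified `hypo_in_case` or `hyper_in_case`, a group-mean
#' Z score is computed against every candidate gene and converted to a
#' one-sided p in the better direction. Benjamini-Hochberg correction is
#' applied over the *total* pool of probe-gene candidates; within each probe
#' the candidates are ranked by |z| and only the top `top_n_genes` are
#' eligible to be called (default 1: each RE site nominates its single
#' best-supported TF). The rank selection is what keeps one chance
#' expression shift in a shared dysregulated subset from fanning out into a
#' correlated block of spurious links across every probe of a regulon.
#' Eligible links that pass the screen (`p_adj < alpha`) are refined with
#' Wilcoxon rank-sum tests. The quadrant crosses the probe's methylation
#' direction with the expression direction: `hypo_up`, `hypo_down`,
#' `hyper_up`, `hyper_down`.
#'
#' @param probe_categories Output of [categorize_probes()].
#' @param beta Probes x samples beta matrix.
#' @param expr Genes x samples expression matrix (log scale).
#' @param samples Sample table tibble.
#' @param genes Gene annotation tibble.
#' @param cutoffs `meth_cutoffs` object (the same one used to categorize).
#' @param alpha Significance level for both screens (default 0.05).
#' @param tf_only Restrict candidate genes to `is_tf` genes (default TRUE).
#' @param top_n_genes Per-probe rank cutoff: the top n candidates by |z| per
#'   probe are eligible for significance (ties broken by gene id). Default
#'   1; `Inf` disables the rank selection (pooled correction only).
#' @return Link tibble: `probe_id`, `gene_id`, `gene_name`, `quadrant`, `z`,
#'   `p`, `p_adj`, `wilcoxon_p`, `wilcoxon_p_adj`, `significant` — one row
#'   per probe-gene candidate (including ineligible ones, whose Wilcoxon
#'   fields stay `NA`). The link groups used are attached as attribute
#'   `"groups"`.
#' @export
run_linking <- function(probe_categories, beta, expr, samples, genes,
                        cutoffs, alpha = 0.05, tf_only = TRUE,
                        top_n_genes = 1) {
  cand_genes <- if (tf_only) dplyr::filter(genes, .data$is_tf) else genes
  if (nrow(cand_genes) == 0L) stop("candidate gene set is empty", call. = FALSE)
  gids <- intersect(cand_genes$gene_id, rownames(expr))
  if (length(gids) == 0L) stop("no candidate gene present in the expression matrix", call. = FALSE)
  gname <- stats::setNames(cand_genes$gene_name, cand_genes$gene_id)[gids]

  dys <- dplyr::filter(probe_categories,
                       .data$category %in% c("hypo_in_case", "hyper_in_case"))
  empty <- tibble::tibble(probe_id = character(), gene_id = character(),
                          gene_name = character(), quadrant = character(),
                          z = double(), p = double(), p_adj = double(),
                          wilcoxon_p = double(), wilcoxon_p_adj = double(),
                          significant = logical())
  if (nrow(dys) == 0L) {
    attr(empty, "groups") <- list()
    return(empty)
  }

  groups <- list()
  rows <- vector("list", nrow(dys))
  em <- expr[gids, , drop = FALSE]
  for (i in seq_len(nrow(dys))) {
    g <- build_link_group(dys$probe_id[i], as.character(dys$category[i]),
                          beta, samples, cutoffs)
    if (is.null(g) || length(g$dys_samples) < 2L) next
    groups[[g$probe_id]] <- g
    ed <- em[, g$dys_samples, drop = FALSE]
    eb <- em[, g$baseline_samples, drop = FALSE]
    nd <- rowSums(!is.na(ed))
    nb <- rowSums(!is.na(eb))
    md <- rowMeans(ed, na.rm = TRUE)
    mb <- rowMeans(eb, na.rm = TRUE)
    # sample sd of the baseline, computed from sums for speed
    ssb <- rowSums(eb^2, na.rm = TRUE)
    sdb <- sqrt(pmax(ssb - nb * mb^2, 0) / pmax(nb - 1, 1))
    valid <- nd >= 2L & nb >= 2L & is.finite(sdb) & sdb > 0
    if (!any(valid)) next
    z <- (md - mb) / (sdb / sqrt(nd))
    z <- z[valid]
    zp <- z_to_p(z)
    ord <- order(-abs(z), names(z))
    elig <- logical(length(z))
    elig[ord[seq_len(min(top_n_genes, length(z)))]] <- TRUE
    rows[[i]] <- tibble::tibble(
      probe_id = g$probe_id, gene_id = names(z),
      gene_name = unname(gname[names(z)]),
      quadrant = paste(g$direction, zp$direction, sep = "_"),
      z = unname(z), p = zp$p, eligible = elig
    )
  }
  links <- dplyr::bind_rows(rows)
  if (nrow(links) == 0L) {
    attr(empty, "groups") <- groups
    return(empty)
  }
  links$p_adj <- adjust_bh(links$p)
  screened <- links
  screened$p_adj[!screened$eligible] <- NA_real_
  screened <- wilcoxon_refine(screened, expr, groups, alpha = alpha)
  links$wilcoxon_p <- screened$wilcoxon_p
  links$wilcoxon_p_adj <- screened$wilcoxon_p_adj
  links$significant <- screened$significant
  links$eligible <- NULL
  links <- dplyr::arrange(links, .data$p_adj, .data$probe_id, .data$gene_id)
  attr(links, "groups") <- groups
  links
}
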