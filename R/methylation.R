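#' Estimate beta-value cutoffs from the control methylation landscape
#'
#' Per-probe mean control beta values across regulatory-element probes form a
#' bimodal distribution (an unmethylated and a methylated mode). A Gaussian
#' kernel density (bandwidth 0.05, 512 grid points on \[0, 1\]) is fitted to
#' these means, the two highest local maxima `u < m` are taken as the mode
#' locations (maxima below 5% of the peak density are ignored as numerical
#' tail noise), and the cutoffs interpolate between them:
#' `H = u + 0.25 (m - u)` (hypomethylation cutoff) and
#' `M = u + 0.75 (m - u)` (methylation cutoff). If the density has fewer than
#' two local maxima the conventional fallback `H = 0.25`, `M = 0.75` is used
#' with a warning.
#'
#' @param beta Numeric matrix (probes x samples) restricted to control
#'   samples and RE probes; `NA`s allowed.
#' @param min_probes Minimum number of probes with >= 2 non-missing control
#'   values required for auto-estimation (default 100).
#' @return An object of class `meth_cutoffs`: list with `hypo` (H), `meth`
#'   (M), `source` ("auto"), `modes` (u, m) and the density grid.
#' @export
estimate_cutoffs <- function(beta, min_probes = 100) {
  n_ok <- rowSums(!is.na(beta))
  usable <- n_ok >= 2L
  if (sum(usable) < min_probes) {
    stop(sprintf(paste0("only %d probes have >= 2 non-missing control values ",
                        "(need %d); supply cutoffs manually via meth_cutoffs()"),
                 sum(usable), min_probes), call. = FALSE)
  }
  means <- rowMeans(beta[usable, , drop = FALSE], na.rm = TRUE)
  dens <- stats::density(means, bw = 0.05, n = 512, kernel = "gaussian",
                         from = 0, to = 1)
  y <- dens$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  # grid endpoints can hold a mode when the data pile up against 0 or 1
  if (length(y) >= 2 && y[1] > y[2]) is_max <- c(1L, is_max)
  if (length(y) >= 2 && y[length(y)] > y[length(y) - 1L]) is_max <- c(is_max, length(y))
  is_max <- is_max[y[is_max] >= 0.05 * max(y)]   # drop numerical tail wiggles
  if (length(is_max) < 2L) {
    warning("control beta density has fewer than two modes; falling back to H = 0.25, M = 0.75",
            call. = FALSE)
    return(new_meth_cutoffs(0.25, 0.75, "auto", modes = c(NA_real_, NA_real_),
                            density = dens))
  }
  top2 <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  u <- min(dens$x[top2])
  m <- max(dens$x[top2])
  new_meth_cutoffs(u + 0.25 * (m - u), u + 0.75 * (m - u), "auto",
                   modes = c(unmeth = u, meth = m), density = dens)
}

#' User-supplied methylation cutoffs
#'
#' @param hypo Hypomethylation cutoff H in (0, 1).
#' @param meth Methylation cutoff M in (0, 1); must exceed `hypo`.
#' @return A `meth_cutoffs` object with `source = "user"`.
#' @export
meth_cutoffs <- function(hypo, meth) {
  new_meth_cutoffs(hypo, meth, "user", modes = c(NA_real_, NA_real_), density = NULL)
}

new_meth_cutoffs <- function(hypo, meth, source, modes, density) {
  stopifnot(hypo > 0, hypo < meth, meth < 1)
  structure(list(hypo = hypo, meth = meth, source = source, modes = modes,
                 density = density),
            class = "meth_cutoffs")
}

#' @export
print.meth_cutoffs <- function(x, ...) {
  cat(sprintf("Methylation beta cutoffs (%s): H = %.4f, M = %.4f\n",
              x$source, x$hypo, x$meth))
  if (!anyNA(x$modes)) {
    cat(sprintf("  density modes: unmethylated %.4f, methylated %.4f\n",
                x$modes[1], x$modes[2]))
  }
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.meth_cutoffs <- function(x, ...) {
  tibble::tibble(cutoff = c("hypo", "meth"), beta = c(x$hypo, x$meth),
                 source = x$source)
}

#' @export
#' @importFrom generics glance
glance.meth_cutoffs <- function(x, ...) {
  tibble::tibble(hypo = x$hypo, meth = x$meth, source = x$source,
                 mode_unmeth = unname(x$modes[1]), mode_meth = unname(x$modes[2]))
}

#' @export
autoplot.meth_cutoffs <- function(object, ...) {
  if (is.null(object$density)) {
    stop("no density stored (user-supplied cutoffs)", call. = FALSE)
  }
  df <- tibble::tibble(beta = object$density$x, density = object$density$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(object$hypo, object$meth),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean control beta", y = "density",
                  title = sprintf("Beta cutoffs: H = %.3f, M = %.3f",
                                  object$hypo, object$meth)) +
    ggplot2::theme_minimal()
}

#' Classify RE probes into four methylation categories
#'
#' With per-probe control mean `c` and cutoffs `H < M`:
#' * `meth_both` — `c >= M` and mean case beta `>= M`;
#' * `unmeth_both` — `c < H` and mean case beta `< H`;
#' * `hypo_in_case` — `c >= M` and at least `min_case` case samples have
#'   beta `< H` (case-specific RE activation);
#' * `hyper_in_case` — `c < H` and at least `min_case` case samples have
#'   beta `>= M`;
#' * `unclassified` otherwise.
#'
#' The dysregulated calls take precedence over the concordant ones when a
#' probe satisfies both (a methylated-in-control probe with a large
#' hypomethylated case subset is `hypo_in_case` even if the case *mean* stays
#' above `M`).
#'
#' @param beta Numeric matrix (probes x samples); columns must cover the
#'   sample table's ids.
#' @param samples Sample table tibble ([read_sample_table()]).
#' @param cutoffs A `meth_cutoffs` object.
#' @param min_case Minimum number of dysregulated case samples required to
#'   call hypo/hyper (default `max(5, ceiling(0.05 * n_case))`).
#' @return Tibble `probe_id`, `category`, `n_case_dysregulated`,
#'   `control_mean`, `case_mean` — one row per probe.
#' @export
categorize_probes <- function(beta, samples, cutoffs, min_case = NULL) {
  stopifnot(inherits(cutoffs, "meth_cutoffs"))
  case_ids <- samples$sample_id[samples$group == "case"]
  ctrl_ids <- samples$sample_id[samples$group == "control"]
  missing_cols <- setdiff(c(case_ids, ctrl_ids), colnames(beta))
  if (length(missing_cols) > 0L) {
    stop("beta matrix lacks sample column(s): ",
         paste(utils::head(missing_cols, 3), collapse = ", "), call. = FALSE)
  }
  if (is.null(min_case)) min_case <- max(5, ceiling(0.05 * length(case_ids)))
  stopifnot(min_case >= 1)
  H <- cutoffs$hypo
  M <- cutoffs$meth
  bc <- beta[, ctrl_ids, drop = FALSE]
  bk <- beta[, case_ids, drop = FALSE]
  ctrl_mean <- rowMeans(bc, na.rm = TRUE)
  case_mean <- rowMeans(bk, na.rm = TRUE)
  n_hypo <- rowSums(bk < H, na.rm = TRUE)
  n_hyper <- rowSums(bk >= M, na.rm = TRUE)
  all_ctrl_missing <- rowSums(!is.na(bc)) == 0L

  category <- rep("unclassified", nrow(beta))
  hi_ctrl <- !all_ctrl_missing & ctrl_mean >= M
  lo_ctrl <- !all_ctrl_missing & ctrl_mean < H
  category[hi_ctrl & !is.na(case_mean) & case_mean >= M] <- "meth_both"
  category[lo_ctrl & !is.na(case_mean) & case_mean < H] <- "unmeth_both"
  category[hi_ctrl & n_hypo >= min_case] <- "hypo_in_case"   # precedence
  category[lo_ctrl & n_hyper >= min_case] <- "hyper_in_case"
  if (any(all_ctrl_missing)) {
    warning(sum(all_ctrl_missing), " probe(s) have all-missing control betas; left unclassified",
            call. = FALSE)
  }
  n_dys <- integer(nrow(beta))
  n_dys[category == "hypo_in_case"] <- n_hypo[category == "hypo_in_case"]
  n_dys[category == "hyper_in_case"] <- n_hyper[category == "hyper_in_case"]
  tibble::tibble(
    probe_id = rownames(beta),
    category = factor(category, levels = c("unmeth_both", "hypo_in_case",
                                           "hyper_in_case", "meth_both",
                                           "unclassified")),
    n_case_dysregulated = n_dys,
    control_mean = unname(ctrl_mean),
    case_mean = unname(case_mean)
  )
}
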