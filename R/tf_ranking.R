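quadrant_levels <- c("hypo_up", "hypo_down", "hyper_up", "hyper_down")

#' Tally significant linked RE sites per TF
#'
#' For each TF gene, counts the number of *distinct* probe ids with a
#' significant link in each quadrant (duplicate probe-gene-quadrant rows
#' count once). TFs with no links appear with zero counts, so the ranking
#' surface always covers the full TF universe.
#'
#' @param links Finalized link tibble ([run_linking()]).
#' @param genes Gene annotation tibble; the TF universe is `is_tf` genes.
#' @return Tibble, one row per TF: `gene_id`, `gene_name`, one count column
#'   per quadrant (`hypo_up`, `hypo_down`, `hyper_up`, `hyper_down`).
#' @export
tally_links <- function(links, genes) {
  tfs <- dplyr::filter(genes, .data$is_tf)
  sig <- dplyr::filter(links, .data$significant)
  unknown <- setdiff(unique(sig$gene_id), genes$gene_id)
  if (length(unknown) > 0L) {
    stop("link table references gene(s) absent from the annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- sig |>
    dplyr::filter(.data$gene_id %in% tfs$gene_id) |>
    dplyr::distinct(.data$gene_id, .data$quadrant, .data$probe_id) |>
    dplyr::count(.data$gene_id, .data$quadrant) |>
    tidyr::pivot_wider(names_from = "quadrant", values_from = "n", values_fill = 0L)
  out <- tibble::tibble(gene_id = tfs$gene_id, gene_name = tfs$gene_name) |>
    dplyr::left_join(counts, by = "gene_id")
  for (q in quadrant_levels) {
    if (!q %in% names(out)) out[[q]] <- 0L
    out[[q]][is.na(out[[q]])] <- 0L
  }
  out[, c("gene_id", "gene_name", quadrant_levels)]
}

#' Rank the key TFs within one quadrant
#'
#' Descending by linked-probe count in the chosen quadrant; count ties are
#' broken by ascending gene name so the ordering is deterministic.
#'
#' @param summaries TF tally tibble ([tally_links()]).
#' @param quadrant One of `hypo_up` (default; case-specific RE activation),
#'   `hypo_down`, `hyper_up`, `hyper_down`.
#' @param n Number of top TFs to return (default 10; capped at the TF count).
#' @return Tibble of the top `n` TFs with columns `rank`, `gene_id`,
#'   `gene_name`, `count`, plus all four quadrant counts.
#' @export
rank_tfs <- function(summaries, quadrant = "hypo_up", n = 10) {
  if (!quadrant %in% quadrant_levels) {
    stop("unknown quadrant '", quadrant, "' (expected one of ",
         paste(quadrant_levels, collapse = ", "), ")", call. = FALSE)
  }
  stopifnot(n >= 1)
  ranked <- summaries |>
    dplyr::mutate(count = .data[[quadrant]]) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$gene_name) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "gene_id", "gene_name", "count",
                  dplyr::all_of(quadrant_levels))
  utils::head(ranked, n)
}

#' Bar plot of the top TFs by linked RE sites
#'
#' Mirrors the conventional "top TFs by hypomethylated enhancer sites"
#' display: one bar per TF, ordered by link count.
#'
#' @param summaries TF tally tibble ([tally_links()]).
#' @inheritParams rank_tfs
#' @return A ggplot object.
#' @export
plot_tf_ranking <- function(summaries, quadrant = "hypo_up", n = 10) {
  top <- rank_tfs(summaries, quadrant = quadrant, n = n)
  ggplot2::ggplot(top, ggplot2::aes(
    x = stats::reorder(.data$gene_name, -.data$count), y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "significant linked RE sites",
                  title = paste("Top TFs,", quadrant, "links")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
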