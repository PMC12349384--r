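#' Distance from each probe to its nearest transcription start site
#'
#' Minimum of `|position - tss|` over genes on the probe's chromosome.
#' Probes on a chromosome carrying no annotated gene get `Inf` — they can
#' never be called promoter probes.
#'
#' @param probes Probe manifest tibble (`probe_id`, `chrom`, `position`).
#' @param genes Gene annotation tibble (needs `chrom`, `tss`).
#' @return Numeric vector of distances (bp), aligned with `probes` rows.
#' @export
nearest_tss_distance <- function(probes, genes) {
  if (nrow(genes) == 0L) stop("gene annotation is empty", call. = FALSE)
  out <- rep(Inf, nrow(probes))
  tss_by_chrom <- split(genes$tss, genes$chrom)
  for (ch in intersect(names(tss_by_chrom), unique(probes$chrom))) {
    pi <- which(probes$chrom == ch)
    tss <- sort(tss_by_chrom[[ch]])
    pos <- probes$position[pi]
    # nearest neighbour in a sorted vector: check flanking entries
    idx <- findInterval(pos, tss)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(tss))
    out[pi] <- pmin(abs(pos - tss[lo]), abs(pos - tss[hi]))
  }
  out
}

#' Classify methylation probes as enhancer, promoter, or neither
#'
#' A probe is an enhancer probe when it falls inside an enhancer histone-mark
#' region (e.g. H3K27ac/H3K4me1 peaks) *and* a nucleosome-depleted region
#' (NDR, from ATAC-/DNase-seq), and lies farther than `tss_distance` from any
#' TSS. A promoter probe falls in a promoter mark (e.g. H3K4me3) and an NDR,
#' within `tss_distance` of a TSS. Probes in both mark sets are resolved by
#' the distance rule alone. All other probes are class `none`.
#'
#' Multiple BED files per mark class should be unioned (row-bound) before
#' calling; overlap is computed on the union.
#'
#' @param probes Probe manifest tibble.
#' @param enhancer_marks,promoter_marks,ndr Interval tibbles ([read_bed()]).
#' @param genes Gene annotation tibble with TSS positions.
#' @param tss_distance Promoter window in bp (default 1500): probes at or
#'   below this distance from a TSS are promoter-range, beyond it
#'   enhancer-range.
#' @param require_ndr If `TRUE` (default) a probe must also overlap an NDR;
#'   with an empty NDR set every probe is classified `none` (with a warning).
#'   Set `FALSE` for cohorts lacking open-chromatin data.
#' @return Tibble `probe_id`, `re_class` (enhancer/promoter/none),
#'   `distance_to_nearest_tss` — one row per manifest probe.
#' @export
classify_re_probes <- function(probes, enhancer_marks, promoter_marks, ndr,
                               genes, tss_distance = 1500, require_ndr = TRUE) {
  stopifnot(tss_distance > 0)
  dist <- nearest_tss_distance(probes, genes)
  in_enh <- probes$probe_id %in% overlap_probes(probes, enhancer_marks)
  in_prom <- probes$probe_id %in% overlap_probes(probes, promoter_marks)
  if (require_ndr) {
    if (nrow(ndr) == 0L) {
      warning("NDR set is empty and require_ndr = TRUE: all probes classified 'none'",
              call. = FALSE)
      in_ndr <- rep(FALSE, nrow(probes))
    } else {
      in_ndr <- probes$probe_id %in% overlap_probes(probes, ndr)
    }
  } else {
    in_ndr <- rep(TRUE, nrow(probes))
  }
  re_class <- dplyr::case_when(
    in_enh & in_ndr & dist > tss_distance ~ "enhancer",
    in_prom & in_ndr & dist <= tss_distance ~ "promoter",
    TRUE ~ "none"
  )
  tibble::tibble(probe_id = probes$probe_id, re_class = re_class,
                 distance_to_nearest_tss = dist)
}
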