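#' Configuration for the synthetic cohort generator
#'
#' Defines a matched methylation + expression cohort with planted TF
#' regulons. Beta values are drawn from a two-mode Beta mixture
#' (unmethylated mode `Beta(2, 10)`, methylated mode `Beta(10, 2)`), giving
#' the bimodal marginal typical of methylation arrays. Expression is
#' log-scale Gaussian around per-gene baselines. Each planted regulon picks
#' one TF and a set of enhancer probes: a fraction `f` of the case samples
#' is hypomethylated at those probes (drawn from the unmethylated mode) and
#' the same samples have the TF's expression raised by `delta_expr`.
#' Regulon case subsets are disjoint whenever the fractions allow, mirroring
#' distinct TF-driven tumor subgroups.
#'
#' @param n_case,n_control Sample counts (defaults 50 / 30).
#' @param n_probes Total methylation probes (default 2000).
#' @param n_genes Total genes (default 200), of which the first `n_tfs`
#'   (default 40) are flagged as TFs.
#' @param regulons List of regulons, each `list(tf = <TF index>,
#'   n_probes = <planted probe count>, delta_expr = <expression shift>,
#'   f = <dysregulated case fraction>)`. Default: two regulons on TFs 1 and
#'   2 with 50 and 30 probes, shift 2 (two noise-sd), `f = 0.5`.
#' @param n_hyper_promoter Promoter probes planted as hypermethylated in the
#'   same case subset as the first regulon (default 0); used to emulate the
#'   tumor-typical promoter hypermethylation direction.
#' @param prop_promoter Fraction of background probes placed at promoters
#'   (unmethylated in all samples; default 0.3). The remaining background
#'   probes are enhancer probes methylated in all samples.
#' @param beta_modes Shape pairs `c(a_unmeth, b_unmeth, a_meth, b_meth)`
#'   (default `c(2, 10, 10, 2)`).
#' @param expr_noise_sd Expression noise sd on the log scale (default 1).
#' @param survival `c(baseline_hazard, hazard_ratio, censor_frac)`
#'   (default `c(1/1000, 3, 0.2)`): exponential event times, the hazard
#'   ratio applied to samples whose first-planted-TF expression exceeds the
#'   cohort median.
#' @param seed Integer seed fixing all randomness (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_case = 50, n_control = 30, n_probes = 2000,
                       n_genes = 200, n_tfs = 40,
                       regulons = list(
                         list(tf = 1L, n_probes = 50L, delta_expr = 2, f = 0.5),
                         list(tf = 2L, n_probes = 30L, delta_expr = 2, f = 0.5)),
                       n_hyper_promoter = 0, prop_promoter = 0.3,
                       beta_modes = c(2, 10, 10, 2), expr_noise_sd = 1,
                       survival = c(baseline_hazard = 1 / 1000,
                                    hazard_ratio = 3, censor_frac = 0.2),
                       seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_probes = as.integer(n_probes), n_genes = as.integer(n_genes),
              n_tfs = as.integer(n_tfs), regulons = regulons,
              n_hyper_promoter = as.integer(n_hyper_promoter),
              prop_promoter = prop_promoter, beta_modes = beta_modes,
              expr_noise_sd = expr_noise_sd, survival = survival,
              seed = as.integer(seed))
  stopifnot(cfg$n_case >= 2, cfg$n_control >= 2, cfg$n_probes >= 1,
            cfg$n_genes >= 1, cfg$n_tfs >= 1, cfg$n_tfs <= cfg$n_genes,
            all(beta_modes > 0), expr_noise_sd > 0,
            cfg$prop_promoter >= 0, cfg$prop_promoter < 1)
  n_planted <- sum(vapply(regulons, function(r) r$n_probes, 1)) + cfg$n_hyper_promoter
  if (n_planted > cfg$n_probes) {
    stop("infeasible config: planted probes (", n_planted,
         ") exceed n_probes (", cfg$n_probes, ")", call. = FALSE)
  }
  for (r in regulons) {
    stopifnot(r$tf >= 1, r$tf <= cfg$n_tfs, r$f > 0, r$f <= 1, r$n_probes >= 1)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' Produces, fully reproducibly from `config$seed`, every input the pipeline
#' consumes: beta and expression matrices, probe manifest, gene annotation,
#' enhancer/promoter/NDR region sets, TAD intervals, a case/control sample
#' table with censored survival, and a truth table listing every planted
#' (probe, TF) pair. Enhancer probes live on a gene-free chromosome (so
#' their nearest-TSS distance exceeds any promoter window) and promoter
#' probes sit 100-150 bp from a TSS; the region BEDs are 200 bp windows
#' around each probe so planted probes pass the step-1 classification as
#' designed.
#'
#' @param config A [sim_config()] object.
#' @return List (class `sim_cohort`): `beta`, `expr`, `probes`, `genes`,
#'   `samples`, `enhancer_bed`, `promoter_bed`, `ndr_bed`, `tads`, `truth`,
#'   `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

#' Generate a coupling-free null cohort
#'
#' Identical to [generate_cohort()] except every regulon's expression shift
#' is zero: methylation dysregulation is retained but carries no expression
#' signal, so the truth table is empty. Used for false-positive calibration.
#'
#' @inheritParams generate_cohort
#' @export
generate_null_cohort <- function(config = sim_config()) {
  config$regulons <- lapply(config$regulons, function(r) {
    r$delta_expr <- 0
    r
  })
  generate_cohort(config)
}

generate_cohort_impl <- function(cfg) {
  n_s <- cfg$n_case + cfg$n_control
  sample_id <- c(sprintf("case_%03d", seq_len(cfg$n_case)),
                 sprintf("ctrl_%03d", seq_len(cfg$n_control)))
  group <- c(rep("case", cfg$n_case), rep("control", cfg$n_control))
  case_ids <- sample_id[group == "case"]

  # gene annotation: all genes on chr2, evenly spaced TSSs
  gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
  gene_name <- ifelse(seq_len(cfg$n_genes) <= cfg$n_tfs,
                      sprintf("TF%02d", seq_len(cfg$n_genes)),
                      sprintf("GENE%04d", seq_len(cfg$n_genes)))
  tss <- 100000L + (seq_len(cfg$n_genes) - 1L) * 200000L
  genes <- tibble::tibble(gene_id = gene_id, gene_name = gene_name,
                          chrom = "chr2", tss = tss,
                          strand = rep(c("+", "-"), length.out = cfg$n_genes),
                          is_tf = seq_len(cfg$n_genes) <= cfg$n_tfs)

  # probe layout
  n_reg <- vapply(cfg$regulons, function(r) as.integer(r$n_probes), 1L)
  n_planted_enh <- sum(n_reg)
  n_background <- cfg$n_probes - n_planted_enh - cfg$n_hyper_promoter
  n_bg_prom <- floor(n_background * cfg$prop_promoter)
  n_bg_enh <- n_background - n_bg_prom
  n_enh <- n_planted_enh + n_bg_enh
  n_prom <- cfg$n_hyper_promoter + n_bg_prom

  probe_id <- sprintf("cg%07d", seq_len(cfg$n_probes))
  kind <- c(rep("planted_enh", n_planted_enh), rep("bg_enh", n_bg_enh),
            rep("hyper_prom", cfg$n_hyper_promoter), rep("bg_prom", n_bg_prom))
  is_enh <- kind %in% c("planted_enh", "bg_enh")
  position <- integer(cfg$n_probes)
  chrom <- character(cfg$n_probes)
  chrom[is_enh] <- "chr1"
  position[is_enh] <- 10000L + (seq_len(n_enh) - 1L) * 5000L
  if (n_prom > 0L) {
    host <- ((seq_len(n_prom) - 1L) %% cfg$n_genes) + 1L
    slot <- (seq_len(n_prom) - 1L) %/% cfg$n_genes
    chrom[!is_enh] <- "chr2"
    position[!is_enh] <- tss[host] + 100L + slot * 50L
  }
  probes <- tibble::tibble(probe_id = probe_id, chrom = chrom, position = position)

  window_bed <- function(sel, label) {
    if (!any(sel)) return(intervals(character(), integer(), integer(), character()))
    intervals(chrom[sel], position[sel] - 100L, position[sel] + 100L,
              paste0(label, seq_len(sum(sel))))
  }
  enhancer_bed <- window_bed(is_enh, "ENH")
  promoter_bed <- window_bed(!is_enh, "PROM")
  ndr_bed <- window_bed(rep(TRUE, cfg$n_probes), "NDR")
  tads <- intervals("chr2", seq(0L, 39000000L, by = 1000000L),
                    seq(1000000L, 40000000L, by = 1000000L),
                    sprintf("TAD%02d", 1:40))

  # disjoint dysregulated case subsets when the fractions allow
  subset_sizes <- vapply(cfg$regulons, function(r) round(r$f * cfg$n_case), 1)
  pool <- sample(case_ids)
  dys_subsets <- list()
  if (sum(subset_sizes) <= cfg$n_case) {
    off <- 0L
    for (i in seq_along(cfg$regulons)) {
      dys_subsets[[i]] <- pool[(off + 1L):(off + subset_sizes[i])]
      off <- off + subset_sizes[i]
    }
  } else {
    for (i in seq_along(cfg$regulons)) {
      dys_subsets[[i]] <- sample(case_ids, subset_sizes[i])
    }
  }

  # beta matrix
  au <- cfg$beta_modes[1]; bu <- cfg$beta_modes[2]
  am <- cfg$beta_modes[3]; bm <- cfg$beta_modes[4]
  r_unmeth <- function(n) stats::rbeta(n, au, bu)
  r_meth <- function(n) stats::rbeta(n, am, bm)
  beta <- matrix(NA_real_, cfg$n_probes, n_s, dimnames = list(probe_id, sample_id))
  beta[kind %in% c("planted_enh", "bg_enh", "hyper_prom"), ] <-
    r_meth(sum(kind %in% c("planted_enh", "bg_enh", "hyper_prom")) * n_s)
  if (n_bg_prom > 0L) beta[kind == "bg_prom", ] <- r_unmeth(n_bg_prom * n_s)
  if (cfg$n_hyper_promoter > 0L) {
    hp <- kind == "hyper_prom"
    beta[hp, ] <- r_unmeth(cfg$n_hyper_promoter * n_s)
    hp_dys <- dys_subsets[[1]]
    beta[hp, hp_dys] <- r_meth(cfg$n_hyper_promoter * length(hp_dys))
  }
  probe_off <- 0L
  regulon_probes <- list()
  for (i in seq_along(cfg$regulons)) {
    idx <- probe_off + seq_len(n_reg[i])
    regulon_probes[[i]] <- probe_id[idx]
    beta[idx, dys_subsets[[i]]] <- r_unmeth(n_reg[i] * length(dys_subsets[[i]]))
    probe_off <- probe_off + n_reg[i]
  }

  # expression matrix: per-gene baseline + Gaussian noise, TF shift in subset
  baseline_mu <- stats::runif(cfg$n_genes, 4, 8)
  expr <- matrix(stats::rnorm(cfg$n_genes * n_s, mean = baseline_mu,
                              sd = cfg$expr_noise_sd),
                 cfg$n_genes, n_s, dimnames = list(gene_id, sample_id))
  for (i in seq_along(cfg$regulons)) {
    r <- cfg$regulons[[i]]
    expr[gene_id[r$tf], dys_subsets[[i]]] <-
      expr[gene_id[r$tf], dys_subsets[[i]]] + r$delta_expr
  }

  # survival: exponential, hazard ratio on first-TF-high samples
  lam0 <- cfg$survival[[1]]; hr <- cfg$survival[[2]]; cf <- cfg$survival[[3]]
  tf1 <- expr[gene_id[cfg$regulons[[1]]$tf], ]
  high <- tf1 > stats::median(tf1)
  t_event <- stats::rexp(n_s, rate = lam0 * ifelse(high, hr, 1))
  censored <- stats::runif(n_s) < cf
  obs_time <- ifelse(censored, t_event * stats::runif(n_s), t_event)
  samples <- tibble::tibble(sample_id = sample_id,
                            group = factor(group, levels = c("case", "control")),
                            survival_time = round(obs_time, 2),
                            event = !censored)

  truth <- purrr::map_dfr(seq_along(cfg$regulons), function(i) {
    r <- cfg$regulons[[i]]
    if (r$delta_expr == 0) return(tibble::tibble(probe_id = character(),
                                                 gene_id = character(),
                                                 quadrant = character()))
    tibble::tibble(probe_id = regulon_probes[[i]], gene_id = gene_id[r$tf],
                   quadrant = "hypo_up")
  })

  structure(list(beta = beta, expr = expr, probes = probes, genes = genes,
                 samples = samples, enhancer_bed = enhancer_bed,
                 promoter_bed = promoter_bed, ndr_bed = ndr_bed, tads = tads,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

#' Write a synthetic cohort bundle to disk
#'
#' Emits every file in the package's native input formats (TSV matrices,
#' TSV tables, BED regions) plus `truth.tsv`, so a written cohort can be
#' read straight back through the io readers. Output is deterministic:
#' rewriting the same cohort gives byte-identical files.
#'
#' @param cohort A `sim_cohort` bundle from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             expression = file.path(dir, "expression.tsv"),
             probes = file.path(dir, "probes.tsv"),
             genes = file.path(dir, "genes.tsv"),
             samples = file.path(dir, "samples.tsv"),
             enhancer = file.path(dir, "enhancer.bed"),
             promoter = file.path(dir, "promoter.bed"),
             ndr = file.path(dir, "ndr.bed"),
             tads = file.path(dir, "tads.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix_tsv(cohort$beta, "probe_id", paths["beta"])
  write_matrix_tsv(cohort$expr, "gene_id", paths["expression"])
  readr::write_tsv(cohort$probes, paths["probes"])
  readr::write_tsv(dplyr::mutate(cohort$genes, is_tf = as.integer(.data$is_tf)),
                   paths["genes"])
  readr::write_tsv(dplyr::mutate(cohort$samples,
                                 group = as.character(.data$group),
                                 event = as.integer(.data$event)),
                   paths["samples"])
  write_bed <- function(x, path) {
    readr::write_tsv(tibble::as_tibble(x)[, c("chrom", "start", "end", "name")],
                     path, col_names = FALSE)
  }
  write_bed(cohort$enhancer_bed, paths["enhancer"])
  write_bed(cohort$promoter_bed, paths["promoter"])
  write_bed(cohort$ndr_bed, paths["ndr"])
  write_bed(cohort$tads, paths["tads"])
  readr::write_tsv(cohort$truth, paths["truth"])
  invisible(paths)
}

write_matrix_tsv <- function(m, id_col, path) {
  df <- tibble::as_tibble(m)
  df <- dplyr::mutate(df, dplyr::across(dplyr::everything(),
                                        ~ sprintf("%.10g", .x)))
  df <- dplyr::bind_cols(stats::setNames(tibble::tibble(rownames(m)), id_col), df)
  readr::write_tsv(df, path)
}
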