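link_fixture <- function(case_betas, ctrl_betas) {
  cat_fixture_env <- new.env()
  n_case <- length(case_betas); n_ctrl <- length(ctrl_betas)
  beta <- matrix(c(case_betas, ctrl_betas), nrow = 1,
                 dimnames = list("p1", c(sprintf("case_%02d", seq_len(n_case)),
                                         sprintf("ctrl_%02d", seq_len(n_ctrl)))))
  samples <- tibble::tibble(
    sample_id = colnames(beta),
    group = factor(rep(c("case", "control"), c(n_case, n_ctrl)),
                   levels = c("case", "control")),
    survival_time = NA_real_, event = NA)
  list(beta = beta, samples = samples)
}

test_that("build_link_group selects dysregulated cases and control baseline", {
  cuts <- meth_cutoffs(0.3, 0.7)
  fx <- link_fixture(c(0.1, 0.2, 0.9), c(0.8, 0.85, NA))
  g <- build_link_group("p1", "hypo_in_case", fx$beta, fx$samples, cuts)
  expect_equal(g$dys_samples, c("case_01", "case_02"))
  expect_equal(g$baseline_samples, c("ctrl_01", "ctrl_02"))
  expect_equal(g$direction, "hypo")

  g2 <- build_link_group("p1", "hyper_in_case", fx$beta, fx$samples, cuts)
  expect_equal(g2$dys_samples, "case_03")

  # direct one-line filter oracle on random betas
  withr::with_seed(9, {
    for (i in 1:20) {
      cb <- runif(15); nb <- runif(8)
      fx <- link_fixture(cb, nb)
      g <- build_link_group("p1", "hypo_in_case", fx$beta, fx$samples, cuts)
      expect_equal(g$dys_samples, colnames(fx$beta)[1:15][cb < 0.3])
    }
  })
})

test_that("build_link_group skips probes with fewer than 2 baseline samples", {
  cuts <- meth_cutoffs(0.3, 0.7)
  fx <- link_fixture(c(0.1, 0.1, 0.1), c(0.8, NA, NA))
  expect_message(g <- build_link_group("p1", "hypo_in_case", fx$beta, fx$samples, cuts),
                 "fewer than 2 baseline")
  expect_null(g)
})

test_that("compute_z equals hand arithmetic and handles degenerate baselines", {
  g <- list(dys_samples = c("a", "b", "c"),
            baseline_samples = c("d", "e", "f", "g", "h"))
  expr <- c(a = 8, b = 9, c = 10, d = 1, e = 2, f = 3, g = 4, h = 5)
  # (9 - 3) / (sd(1:5)/sqrt(3)) = 6 / (1.5811/1.7321)
  expect_equal(compute_z(expr, g), 6.5727, tolerance = 1e-3)

  expr0 <- c(a = 5, b = 5, c = 5, d = 5, e = 5, f = 5, g = 5, h = 5)
  expect_true(is.na(compute_z(expr0, g)))                 # baseline sd = 0
  same <- c(a = 3, b = 4, c = 5, d = 3, e = 4, f = 5, g = 4, h = 4)
  expect_equal(compute_z(same, g), 0)                     # equal means
  expect_true(is.na(compute_z(c(a = 1, b = NA, c = NA, d = 1, e = 2, f = 3, g = 4, h = 5), g)))
})

test_that("z_to_p gives the one-sided tail in the better direction", {
  expect_equal(z_to_p(0)$p, 0.5)
  expect_equal(z_to_p(0)$direction, "up")
  expect_equal(z_to_p(1.6449)$p, 0.05, tolerance = 1e-3)
  expect_equal(z_to_p(1.6449)$direction, "up")
  z <- c(-2.3, 0.4, 1.1)
  expect_equal(z_to_p(z)$p, z_to_p(-z)$p)                 # tail symmetry
  expect_equal(z_to_p(-1.5)$direction, "down")
})

test_that("adjust_bh matches the textbook step-up formula", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(11, {
    for (n in c(10, 1000, 10000)) {
      p <- runif(n)^2
      expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
    }
    # permutation invariance (label-aligned)
    p <- runif(50)
    perm <- sample(50)
    expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
  })
})

test_that("Wilcoxon exact branch matches full enumeration for small groups", {
  # spec example: maximal separation, p = 2 / C(6,3)
  fx <- link_fixture(rep(0.1, 3), rep(0.9, 3))
  cuts <- meth_cutoffs(0.3, 0.7)
  g <- build_link_group("p1", "hypo_in_case", fx$beta, fx$samples, cuts)
  expr <- rbind(G1 = c(10, 11, 12, 1, 2, 3))
  colnames(expr) <- c(g$dys_samples, g$baseline_samples)
  links <- tibble::tibble(probe_id = "p1", gene_id = "G1", gene_name = "TF1",
                          quadrant = "hypo_up", z = 5, p = 1e-6, p_adj = 1e-6)
  out <- wilcoxon_refine(links, expr, list(p1 = g), alpha = 0.05)
  expect_equal(out$wilcoxon_p, 0.1, tolerance = 1e-12)

  withr::with_seed(21, {
    for (i in 1:200) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      x <- round(rnorm(n1), 6); y <- round(rnorm(n2) + runif(1, -1, 1), 6)
      if (any(duplicated(c(x, y)))) next
      expr <- rbind(G1 = c(x, y))
      ids <- c(sprintf("d%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
      colnames(expr) <- ids
      g <- list(dys_samples = ids[seq_len(n1)], baseline_samples = ids[-seq_len(n1)])
      links <- tibble::tibble(probe_id = "p1", gene_id = "G1", gene_name = "T",
                              quadrant = "hypo_up", z = 1, p = 0.001, p_adj = 0.001)
      out <- wilcoxon_refine(links, expr, list(p1 = g), alpha = 0.05)
      expect_equal(out$wilcoxon_p, wilcox_enum_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("identical pooled expression values give Wilcoxon p = 1", {
  ids <- c("d1", "d2", "d3", "b1", "b2", "b3")
  expr <- rbind(G1 = rep(4.2, 6)); colnames(expr) <- ids
  g <- list(dys_samples = ids[1:3], baseline_samples = ids[4:6])
  links <- tibble::tibble(probe_id = "p1", gene_id = "G1", gene_name = "T",
                          quadrant = "hypo_up", z = 1, p = 0.001, p_adj = 0.001)
  out <- wilcoxon_refine(links, expr, list(p1 = g), alpha = 0.05)
  expect_equal(out$wilcoxon_p, 1)
})

sim_linking_inputs <- function(seed = 77) {
  co <- generate_cohort(sim_config(seed = seed))
  ctrl <- co$samples$sample_id[co$samples$group == "control"]
  cuts <- estimate_cutoffs(co$beta[, ctrl])
  cats <- categorize_probes(co$beta, co$samples, cuts)
  list(co = co, cuts = cuts, cats = cats)
}

test_that("run_linking returns an empty table when nothing is dysregulated", {
  fx <- sim_linking_inputs()
  none <- dplyr::filter(fx$cats, category == "meth_both")
  out <- run_linking(none, fx$co$beta, fx$co$expr, fx$co$samples, fx$co$genes, fx$cuts)
  expect_equal(nrow(out), 0L)
  expect_error(run_linking(fx$cats, fx$co$beta, fx$co$expr, fx$co$samples,
                           fx$co$genes[0, ], fx$cuts), "empty")
})

test_that("run_linking recovers a planted regulon and keeps signs coherent", {
  fx <- sim_linking_inputs(seed = 88)
  links <- run_linking(fx$cats, fx$co$beta, fx$co$expr, fx$co$samples,
                       fx$co$genes, fx$cuts)
  truth_keys <- paste(fx$co$truth$probe_id, fx$co$truth$gene_id)
  sig <- dplyr::filter(links, significant)
  sig_keys <- paste(sig$probe_id, sig$gene_id)
  expect_gte(mean(truth_keys %in% sig_keys), 0.9)
  expect_true(all(sig$quadrant[sig_keys %in% truth_keys] == "hypo_up"))

  # sign coherence for every significant hypo_up link
  groups <- attr(links, "groups")
  up <- dplyr::filter(sig, quadrant == "hypo_up")
  for (i in seq_len(nrow(up))) {
    g <- groups[[up$probe_id[i]]]
    e <- fx$co$expr[up$gene_id[i], ]
    expect_gt(mean(e[g$dys_samples]), mean(e[g$baseline_samples]))
  }
  # quadrant label is consistent with the z sign everywhere
  expect_true(all(grepl("_up$", links$quadrant) == (links$z >= 0)))
  expect_true(all(links$p_adj >= links$p - 1e-15))
})

test_that("per-probe rank selection gates significance but not the candidate pool", {
  fx <- sim_linking_inputs(seed = 99)
  ranked <- run_linking(fx$cats, fx$co$beta, fx$co$expr, fx$co$samples,
                        fx$co$genes, fx$cuts, top_n_genes = 1)
  pooled <- run_linking(fx$cats, fx$co$beta, fx$co$expr, fx$co$samples,
                        fx$co$genes, fx$cuts, top_n_genes = Inf)
  # the candidate pool and its BH correction are identical in both modes
  key <- function(d) d[order(d$probe_id, d$gene_id), c("probe_id", "gene_id", "z", "p", "p_adj")]
  expect_equal(key(ranked), key(pooled))
  # with n = 1, at most one significant link per probe, and it is the argmax |z|
  sig <- dplyr::filter(ranked, significant)
  expect_true(all(table(sig$probe_id) == 1))
  best <- ranked |>
    dplyr::group_by(probe_id) |>
    dplyr::slice_max(abs(z), n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  expect_true(all(paste(sig$probe_id, sig$gene_id) %in%
                    paste(best$probe_id, best$gene_id)))
  # ranked significant links are a subset of the pooled ones
  expect_true(all(paste(sig$probe_id, sig$gene_id) %in%
                    paste(pooled$probe_id, pooled$gene_id)[pooled$significant]))
})
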