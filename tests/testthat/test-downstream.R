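test_that("stratify_samples implements median and tertile rules", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  s <- stratify_samples(v, "median")
  expect_setequal(s$high, c("c", "d"))
  expect_setequal(s$low, c("a", "b"))
  expect_error(stratify_samples(c(a = 5, b = 5, c = 5, d = 5)), "identical")

  v9 <- setNames(1:9, letters[1:9])
  t <- stratify_samples(v9, "tertile")
  expect_equal(sort(t$high), c("g", "h", "i"))
  expect_equal(sort(t$low), c("a", "b", "c"))
  expect_length(c(t$high, t$low), 6)
})

test_that("log-rank on identical groups gives statistic 0 and matches a hand risk table", {
  tm <- c(g1 = 5, g2 = 8, g3 = 12, h1 = 5, h2 = 8, h3 = 12)
  ev <- c(g1 = TRUE, g2 = TRUE, g3 = FALSE, h1 = TRUE, h2 = TRUE, h3 = FALSE)
  lr <- logrank_test(tm, ev, c("g1", "g2", "g3"), c("h1", "h2", "h3"))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # fully separated groups: compare with the O/E/V table computed by hand
  tma <- c(a1 = 1, a2 = 2, a3 = 3, b1 = 10, b2 = 20, b3 = 30)
  eva <- setNames(rep(TRUE, 6), names(tma))
  lr2 <- logrank_test(tma, eva, paste0("a", 1:3), paste0("b", 1:3))
  orc <- logrank_oracle(c(1, 2, 3), c(1, 1, 1), c(10, 20, 30), c(1, 1, 1))
  expect_equal(lr2$statistic, orc$statistic, tolerance = 1e-6)
  expect_equal(lr2$p, orc$p, tolerance = 1e-9)
  expect_error(logrank_test(tma, setNames(rep(FALSE, 6), names(tma)),
                            paste0("a", 1:3), paste0("b", 1:3)), "no observed events")
})

test_that("log-rank matches the independent risk-table oracle on random censored data", {
  withr::with_seed(61, {
    for (i in 1:100) {
      n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
      t1 <- round(rexp(n1, 1 / 50), 1) + 0.1
      t2 <- round(rexp(n2, 1 / 30), 1) + 0.1
      e1 <- runif(n1) > 0.3; e2 <- runif(n2) > 0.3
      if (sum(e1) + sum(e2) == 0) next
      ids <- c(sprintf("a%02d", 1:n1), sprintf("b%02d", 1:n2))
      tm <- setNames(c(t1, t2), ids)
      ev <- setNames(c(e1, e2), ids)
      orc <- logrank_oracle(t1, as.integer(e1), t2, as.integer(e2))
      if (!is.finite(orc$statistic)) next
      lr <- logrank_test(tm, ev, ids[1:n1], ids[-(1:n1)])
      expect_equal(lr$statistic, orc$statistic, tolerance = 1e-6)
    }
  })
})

test_that("survival_association returns a tidy row and glance/tidy methods work", {
  withr::with_seed(17, {
    n <- 40
    ids <- sprintf("s%02d", 1:n)
    expr <- setNames(rnorm(n), ids)
    samples <- tibble::tibble(
      sample_id = ids,
      group = factor(rep(c("case", "control"), each = n / 2),
                     levels = c("case", "control")),
      survival_time = rexp(n, 1 / 100), event = runif(n) > 0.2)
    row <- survival_association(expr, samples, "G0001", "tf_expression")
    expect_equal(row$feature_id, "G0001")
    expect_equal(row$n_high + row$n_low, n)
    expect_gte(row$statistic, 0)

    lr <- logrank_test(setNames(samples$survival_time, ids),
                       setNames(samples$event, ids),
                       ids[expr > median(expr)], ids[expr <= median(expr)])
    expect_equal(row$statistic, lr$statistic)
    expect_equal(tidy(lr)$statistic, lr$statistic)
    expect_equal(glance(lr)$n_events, lr$n_events)
  })
})

test_that("TAD assignment matches the brute-force triple loop and rejects overlaps", {
  probes <- tibble::tibble(probe_id = c("p1", "p2"), chrom = "chr1",
                           position = c(500000L, 2500000L))
  genes <- tibble::tibble(gene_id = c("g1", "g2"), gene_name = c("A", "B"),
                          chrom = "chr1", tss = c(100000L, 5000000L),
                          strand = "+", is_tf = TRUE)
  tads <- intervals("chr1", 0L, 1000000L, "T1")
  out <- assign_targets_by_tad(probes, genes, tads)
  expect_equal(out, tibble::tibble(probe_id = "p1", gene_id = "g1", tad_id = "T1"))

  withr::with_seed(29, {
    for (i in 1:30) {
      pr <- random_probes(40, max_pos = 100000)
      gn <- tibble::tibble(gene_id = sprintf("g%02d", 1:15),
                           gene_name = sprintf("G%02d", 1:15),
                           chrom = sample(c("chr1", "chr2"), 15, TRUE),
                           tss = sample.int(100000, 15), strand = "+", is_tf = TRUE)
      # three non-overlapping TADs per chromosome, with inter-TAD gaps
      td <- intervals(rep(c("chr1", "chr2"), each = 3),
                      rep(c(0L, 40000L, 80000L), 2),
                      rep(c(30000L, 70000L, 100001L), 2),
                      sprintf("T%d", 1:6))
      got <- assign_targets_by_tad(pr, gn, td)[, c("probe_id", "gene_id")]
      expect_equal(got, tad_oracle(pr, gn, td))
    }
  })

  bad <- intervals("chr1", c(0L, 500L), c(1000L, 1500L))
  expect_error(assign_targets_by_tad(probes, genes, bad), "overlapping TADs")
})

uniform_pwm <- function(width = 4) {
  list(motif_id = "U", matrix = matrix(0.25, width, 4,
                                       dimnames = list(NULL, c("A", "C", "G", "T"))),
       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

consensus_pwm <- function(consensus, pseudo = 0.01) {
  bases <- c("A", "C", "G", "T")
  m <- t(vapply(strsplit(consensus, "")[[1]], function(b) {
    p <- rep(pseudo, 4); p[match(b, bases)] <- 1
    p / sum(p)
  }, numeric(4)))
  colnames(m) <- bases
  list(motif_id = "C", matrix = m, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
}

test_that("scan_pwm scores consensus and uniform motifs as expected", {
  pwm <- consensus_pwm("ACGTAC")
  hits <- scan_pwm("ACGTAC", pwm, threshold = 0)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$offset, 0L)
  expect_equal(fwd$score, sum(log2((1 / 1.03) / 0.25) * 6), tolerance = 1e-9)

  u <- scan_pwm("ACGTACGTAC", uniform_pwm(4), threshold = -0.5)
  expect_true(all(u$score == 0))                 # log2(1) everywhere
  expect_equal(nrow(u), 7 * 2)                   # all windows, both strands
  expect_equal(nrow(scan_pwm("ACG", uniform_pwm(4), 0)), 0L)  # too short
  # windows containing N are skipped: only offset 4 survives, on both strands
  n_hits <- scan_pwm("ACGNACGT", uniform_pwm(4), -1)
  expect_equal(n_hits$offset, c(4L, 4L))
  expect_setequal(n_hits$strand, c("+", "-"))
})

test_that("scan_pwm matches the naive per-window oracle on random sequences", {
  withr::with_seed(83, {
    pwm <- list(motif_id = "R",
                matrix = {
                  m <- matrix(rgamma(8 * 4, 1), 8, 4)
                  m <- m / rowSums(m)
                  colnames(m) <- c("A", "C", "G", "T")
                  m
                },
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
    for (i in 1:100) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
      got <- scan_pwm(s, pwm, threshold = 2)
      expect_equal(got, pwm_scan_oracle(s, pwm, 2), tolerance = 1e-9)
    }
  })
})

test_that("scan_pwm is mirror-symmetric under reverse complement", {
  withr::with_seed(19, {
    pwm <- consensus_pwm("ACGGTA")
    s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    h1 <- scan_pwm(s, pwm, threshold = 1)
    h2 <- scan_pwm(rc, pwm, threshold = 1)
    # hit at offset o on + in s corresponds to offset L - w - o on - in rc
    L <- nchar(s); w <- nrow(pwm$matrix)
    mirrored <- dplyr::arrange(
      tibble::tibble(offset = L - w - h2$offset,
                     strand = as.character(ifelse(h2$strand == "+", "-", "+")),
                     score = h2$score), offset, strand)
    expect_equal(h1, mirrored, tolerance = 1e-9)
  })
})

test_that("overlap_probes_with_peaks flags probes inside peaks", {
  probes <- tibble::tibble(probe_id = c("p1", "p2"), chrom = "chr1",
                           position = c(150L, 500L))
  peaks <- intervals("chr1", 100L, 200L)
  expect_equal(overlap_probes_with_peaks(probes, peaks), c(TRUE, FALSE))
})

test_that("heatmap_matrix produces deterministic orderings grouped by best TF", {
  co <- generate_cohort(sim_config(seed = 31))
  ctrl <- co$samples$sample_id[co$samples$group == "control"]
  cuts <- estimate_cutoffs(co$beta[, ctrl])
  cats <- categorize_probes(co$beta, co$samples, cuts)
  links <- run_linking(cats, co$beta, co$expr, co$samples, co$genes, cuts)
  hm <- heatmap_matrix(links, co$expr, co$beta, co$samples)
  expect_equal(hm$tf_order[1:2], c("G0001", "G0002"))  # 50-probe regulon first
  expect_equal(dim(hm$methylation), c(length(hm$probe_order), nrow(co$samples)))
  expect_equal(rownames(hm$expression), hm$tf_order)
  expect_equal(colnames(hm$expression), colnames(hm$methylation))
  # controls come first in the column ordering
  expect_true(all(grepl("^ctrl", hm$sample_order[1:30])))

  # probe grouping matches an independent per-probe argmax over |z|
  sig <- dplyr::filter(links, significant, quadrant == "hypo_up")
  best <- sapply(split(sig, sig$probe_id), function(d) {
    d$gene_id[order(-abs(d$z), d$gene_id)][1]
  })
  expect_equal(setNames(hm$probe_tf$gene_id, hm$probe_tf$probe_id),
               best[hm$probe_tf$probe_id])

  # row-order invariance of the input link table
  hm2 <- heatmap_matrix(links[rev(seq_len(nrow(links))), ], co$expr, co$beta,
                        co$samples)
  expect_equal(hm2$probe_order, hm$probe_order)
  expect_equal(hm2$sample_order, hm$sample_order)
  expect_error(heatmap_matrix(links[0, ], co$expr, co$beta, co$samples),
               "no significant links")
})
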