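# Independent brute-force / textbook oracles used across the suite.

# all-pairs point-in-interval scan
brute_overlap <- function(probes, regions) {
  hit <- character()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(regions))) {
      if (probes$chrom[i] == regions$chrom[j] &&
          probes$position[i] >= regions$start[j] &&
          probes$position[i] < regions$end[j]) {
        hit <- c(hit, probes$probe_id[i])
        break
      }
    }
  }
  hit
}

# exhaustive nearest-TSS distance
brute_nearest_tss <- function(probes, genes) {
  vapply(seq_len(nrow(probes)), function(i) {
    d <- Inf
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == probes$chrom[i]) {
        d <- min(d, abs(probes$position[i] - genes$tss[j]))
      }
    }
    d
  }, 0)
}

# textbook BH step-up: min over k >= i of p(k) * m / k, clipped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exact two-sided Wilcoxon p by full enumeration of group assignments
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  r <- rank(pooled)
  s_obs <- sum(r[seq_len(k)])
  combs <- utils::combn(n, k)
  s_all <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(s_all <= s_obs)
  p_ge <- mean(s_all >= s_obs)
  min(1, 2 * min(p_le, p_ge))
}

# hand-computed log-rank O/E/V risk table
logrank_oracle <- function(time1, event1, time2, event2) {
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# naive per-window PWM rescoring on both strands
pwm_scan_oracle <- function(sequence, pwm, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  bases <- c("A", "C", "G", "T")
  lo <- log2(sweep(pwm$matrix, 2, pwm$background, "/"))
  w <- nrow(lo)
  chars <- strsplit(toupper(sequence), "")[[1]]
  res <- list()
  for (o in seq_len(max(0, length(chars) - w + 1)) - 1L) {
    win <- chars[(o + 1):(o + w)]
    if (any(!win %in% bases)) next
    s_fwd <- sum(vapply(seq_len(w), function(i) lo[i, match(win[i], bases)], 0))
    rc <- rev(unname(comp[win]))
    s_rev <- sum(vapply(seq_len(w), function(i) lo[i, match(rc[i], bases)], 0))
    if (s_fwd >= threshold) res[[length(res) + 1]] <- list(o, "+", s_fwd)
    if (s_rev >= threshold) res[[length(res) + 1]] <- list(o, "-", s_rev)
  }
  if (length(res) == 0) {
    return(tibble::tibble(offset = integer(), strand = character(), score = double()))
  }
  out <- tibble::tibble(offset = vapply(res, function(r) r[[1]], 0L),
                        strand = vapply(res, function(r) r[[2]], ""),
                        score = vapply(res, function(r) r[[3]], 0))
  dplyr::arrange(out, offset, strand)
}

# triple-loop TAD co-membership
tad_oracle <- function(probes, genes, tads) {
  rows <- list()
  for (i in seq_len(nrow(tads))) {
    for (p in seq_len(nrow(probes))) {
      if (probes$chrom[p] != tads$chrom[i]) next
      if (probes$position[p] < tads$start[i] || probes$position[p] >= tads$end[i]) next
      for (g in seq_len(nrow(genes))) {
        if (genes$chrom[g] != tads$chrom[i]) next
        if (genes$tss[g] < tads$start[i] || genes$tss[g] >= tads$end[i]) next
        rows[[length(rows) + 1]] <- tibble::tibble(probe_id = probes$probe_id[p],
                                                   gene_id = genes$gene_id[g])
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(tibble::tibble(probe_id = character(), gene_id = character()))
  dplyr::arrange(out, probe_id, gene_id)
}

random_probes <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  tibble::tibble(probe_id = sprintf("p%04d", seq_len(n)),
                 chrom = sample(chroms, n, replace = TRUE),
                 position = sample.int(max_pos, n, replace = TRUE))
}

random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000) {
  start <- sample.int(max_pos, n, replace = TRUE)
  intervals(sample(chroms, n, replace = TRUE), start,
            start + sample.int(300, n, replace = TRUE))
}
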