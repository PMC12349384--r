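---
title: "Methods: linking regulatory-element methylation to transcription factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking regulatory-element methylation to transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
library(dplyr)
```

## The problem

Transcription factors (TFs) act by binding regulatory elements (REs) —
promoters near transcription start sites (TSSs) and enhancers at a distance
from them. Where an RE is active, its DNA is typically unmethylated, so DNA
methylation measured at CpG probes inside REs is an accessible, inverse
readout of RE activity that works even on archival tissue. When a TF is
overexpressed in a disease subgroup (the *case* samples) relative to a
reference group (*controls*), the REs it binds become active and lose
methylation in exactly that subgroup. methlink exploits this coupling: it
finds RE methylation sites that are dysregulated in a subset of cases,
scores each site against TF expression across samples, and ranks TFs by the
number of RE sites whose methylation tracks their expression.

The pipeline has seven conceptual steps; `run_pipeline()` chains the first
six, and the downstream helpers (survival, TADs, motifs, heatmaps)
constitute the seventh.

## Step 1 — annotating probes as enhancer or promoter sites

A probe (a genomic point; all coordinates are 0-based, half-open, BED
convention) is an **enhancer probe** when it falls inside an enhancer
histone-mark region (H3K27ac/H3K4me1-type peaks) *and* a nucleosome-depleted
region (NDR; ATAC-seq/DNase-seq), and lies more than `tss_distance` from
every TSS. It is a **promoter probe** when it falls inside a promoter mark
(H3K4me3-type) and an NDR within `tss_distance` of a TSS. Probes carrying
both mark types are resolved by the distance rule alone; everything else is
class `none` and leaves the analysis.

* `tss_distance` defaults to 1500 bp, a conventional promoter window;
  there is no canonical value and it is exposed as a parameter.
* The NDR intersection is required by default because TF binding happens in
  open chromatin, but `require_ndr = FALSE` supports cohorts without
  open-chromatin data.
* Strand is ignored everywhere except the TSS definition: methylation and
  peak calls are strand-symmetric.
* Multiple BED files per mark class are unioned before overlap.

## Step 2 — beta-value cutoffs and the four methylation categories

Array methylation beta values in a homogeneous tissue are bimodal: an
unmethylated mode near 0 and a methylated mode near 1. `estimate_cutoffs()`
computes per-probe mean control betas over the RE probes, fits a Gaussian
kernel density (bandwidth 0.05, 512 grid points on [0, 1]), and takes the
two highest local maxima `u < m` as the mode locations. The cutoffs
interpolate between the modes:

* hypomethylation cutoff `H = u + 0.25 (m − u)`
* methylation cutoff `M = u + 0.75 (m − u)`

Numerical choices: density maxima below 5% of the peak height are ignored
(they are floating-point wiggles in near-zero tails, not modes); a grid
endpoint counts as a mode when the density increases into it; if fewer than
two modes remain the conventional `(0.25, 0.75)` fallback is used with a
warning; fewer than 100 usable probes is an error directing the user to
supply cutoffs explicitly. User-supplied cutoffs always override the
estimate.

`categorize_probes()` then classifies each RE probe from its control mean
`c` and its case betas: `meth_both` (`c ≥ M`, case mean `≥ M`),
`unmeth_both` (`c < H`, case mean `< H`), `hypo_in_case` (`c ≥ M` and at
least `min_case` case samples below `H`), `hyper_in_case` (`c < H` and at
least `min_case` case samples at or above `M`), otherwise `unclassified`.
The dysregulated calls take precedence over the concordant ones: a probe
methylated in controls whose case *mean* stays high but which has a
sufficiently large hypomethylated case subset is the method's target
signature, and must not be absorbed into `meth_both`. `min_case` defaults
to `max(5, ceiling(0.05 · n_case))` — subgroup statistics on fewer samples
are too unstable to score. Mean (not quantile) summaries are used for the
concordant categories. Samples with missing betas are dropped from the
affected probe's computation, never imputed.

## Steps 3–5 — linking scores

For each dysregulated probe, the **dysregulated group** is the set of case
samples beyond the cutoff (beta `< H` for hypo, `≥ M` for hyper) and the
**baseline group** is the controls with non-missing beta. For every
candidate gene (by default the TF genes only) the link statistic is

$$ z = \frac{\bar e_{dys} - \bar e_{ctrl}}{s_{ctrl} / \sqrt{n_{dys}}} $$

with `s` the sample standard deviation (n − 1) of baseline expression. The
one-sided standard-normal tail is evaluated in both directions and the pair
is assigned the smaller one; the quadrant crosses the probe's methylation
direction with the expression direction (`hypo_up` is the headline class:
case-specific RE activation under an overexpressed TF).

Two properties of this statistic shape the rest of the design:

1. It treats the baseline mean and standard deviation as known, so its null
   distribution is wider than standard normal (variance roughly
   `1 + n_dys/n_ctrl` before estimation noise). The nominal p-values are
   therefore calibrated against an idealized null and are anticonservative
   for individual links.
2. All probes of one regulon share (approximately) one dysregulated case
   subset, so their z-scores against any fixed gene are strongly
   correlated: a single chance expression deviation of an unrelated gene in
   that subset would propagate to a *block* of spurious links.

The multiple-testing design addresses both. Benjamini–Hochberg correction
is computed over the **total** pool of probe–gene candidates, and within
each probe the candidates are ranked by |z|, with only the top
`top_n_genes` (default 1) eligible to be called. A true regulon TF
dominates its probes' rankings by a wide margin (planted-signal z around 9
versus chance blocks around 3), so the per-site rank selection removes the
correlated-block failure mode without touching the correction itself;
`top_n_genes = Inf` restores plain pooled testing for users who want every
candidate evaluated. Eligible links passing the screen (`p_adj < alpha`,
default 0.05) are refined with a two-sided Wilcoxon rank-sum test of
expression between the two groups — exact null when both groups have at
most 10 observations and no ties, normal approximation with tie and
continuity corrections otherwise — followed by BH re-correction over the
surviving links. A link is `significant` only when both adjusted p-values
fall below `alpha`.

## Step 6 — ranking key TFs

`tally_links()` counts, per TF and per quadrant, the number of *distinct*
probes with a significant link (a probe linking one TF through duplicate
rows counts once), keeping zero-count TFs so the ranking covers the whole
TF universe. `rank_tfs()` orders a quadrant's counts descending, breaking
ties by ascending gene name — the tie-break carries no scientific meaning
and exists only to make output deterministic.

## Step 7 — downstream interrogation

* **Survival**: samples are split on a feature (TF expression or probe
  methylation) by median (default; high = strictly above) or by outer
  tertiles, and the two groups are compared with the standard unweighted
  log-rank test (chi-square, 1 df). The grouping rule and test are
  conventional choices; proportional-hazards modelling is out of scope.
* **Target genes by TAD**: topologically associating domains constrain
  enhancer–promoter contacts, so each probe inside a TAD is paired with
  every gene whose TSS shares that TAD. TADs must partition each
  chromosome; overlapping TADs are rejected rather than resolved silently.
* **Motifs**: MEME-minimal motif files are parsed into position weight
  matrices and scanned over DNA with log2-odds scores against a uniform
  0.25 background (a declared background in the file is honored), on both
  strands, skipping windows containing N. Zero-probability cells score
  −Inf and simply never reach a threshold; consensus examples in the test
  suite use a 0.01 pseudocount when constructing matrices from counts.
* **Heatmap matrices**: the conventional stacked display (TF expression
  over linked-probe methylation) needs deterministic orderings — TFs by
  linked-probe count, probes grouped under their best-linked TF (largest
  |z|, ties by gene id) and sorted by |z|, samples control-first then case,
  each ordered by ascending mean methylation over the selected probes.

## The synthetic cohort generator

`generate_cohort()` produces every input the pipeline consumes with planted
ground truth. Its defaults are the package's reference study conditions: 50
case and 30 control samples, 2000 probes, 200 genes of which 40 are TFs,
and two planted regulons (TFs 1 and 2, with 50 and 30 enhancer probes)
whose expression shift is 2 noise-sd in a dysregulated fraction f = 0.5 of
cases. Betas come from a two-mode Beta mixture — Beta(2, 10) unmethylated,
Beta(10, 2) methylated — the standard bounded, bimodal model for array beta
values; 30% of background probes are unmethylated promoter probes, which
also provides the second density mode that cutoff estimation requires.
Expression is log-scale Gaussian around per-gene baselines drawn from
U(4, 8) with sd 1. Regulon case subsets are allocated disjointly when the
fractions allow, mirroring distinct TF-driven subgroups. Survival times are
exponential (baseline hazard 1/1000 per day) with a hazard ratio of 3
applied to samples whose first-planted-TF expression exceeds the cohort
median, and 20% of samples are censored at a uniform fraction of their
event time. `generate_null_cohort()` zeroes every expression shift while
keeping the methylation dysregulation — the calibration null.

The geometry is deliberately minimal: enhancer probes sit on a gene-free
chromosome (their nearest-TSS distance is infinite, beyond any promoter
window), promoter probes sit 100–150 bp from a TSS, and the mark/NDR BEDs
are 200 bp windows around the probes. The generator does **not** emulate
co-methylation structure between neighboring probes, realistic genome
coordinates, purity or cell-type mixtures, batch effects, or read-level
noise. Passing tests on these cohorts therefore demonstrate the pipeline's
internal correctness and its behavior under an idealized signal model — not
robustness to the confounders of real tumor data.

```{r cohort, eval = FALSE}
co <- generate_cohort(sim_config(seed = 1))
dir <- tempfile()
paths <- write_cohort(co, dir)
res <- run_pipeline(pipeline_config(
  inputs = list(beta = paths[["beta"]], expression = paths[["expression"]],
                probes = paths[["probes"]], genes = paths[["genes"]],
                samples = paths[["samples"]], enhancer_bed = paths[["enhancer"]],
                promoter_bed = paths[["promoter"]], ndr_bed = paths[["ndr"]]),
  out_dir = file.path(dir, "out")))
head(res$tf_ranking)
```

## Validation strategy and problem sizes

The test suite validates every combinatorial or distributional primitive
against an independent oracle: interval overlap and TAD assignment against
all-pairs scans (100 random instances each), PWM scanning against naive
per-window rescoring (100 random sequences), the exact Wilcoxon branch
against full enumeration of group assignments for every group-size pair
with n₁ + n₂ ≤ 12, BH against the direct step-up formula on lists up to
10⁴, and the log-rank statistic against a hand-rolled O/E/V risk table on
100 random censored datasets. End-to-end properties run on five replicate
cohorts at the reference conditions: both planted TFs must rank first and
second in the `hypo_up` quadrant, at least 90% of planted links must be
recovered, no more than 5% of reported linked probes may be unplanted, and
on null cohorts the fraction of candidates called significant must stay
within three binomial standard errors of alpha. Survival power is checked
at a hazard ratio of 3 with 100 samples per arm over 200 replicates. These
sizes keep the full suite under a minute while leaving each property's
Monte-Carlo error well below its margin.

## Known limitations

* The Z statistic's anticonservative null means nominal per-link p-values
  should not be read as calibrated error rates; significance is meaningful
  relative to the BH screen plus Wilcoxon refinement, and the candidate-set
  false-positive fraction on null cohorts (~2% at alpha 0.05) is the honest
  calibration summary.
* With `top_n_genes = Inf`, correlated spurious blocks can enter the
  ranking when a chance expression shift aligns with a shared dysregulated
  subset; the default rank selection exists precisely to prevent this.
* Links are statistical associations: an RE site linked to a TF may be an
  indirect partner, and orthogonal evidence (motif hits at the RE, ChIP
  peaks, TAD co-membership) should be consulted before causal reading.
* Cutoff estimation assumes a bimodal control landscape; heavily mixed or
  globally disrupted cohorts should supply cutoffs manually.
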