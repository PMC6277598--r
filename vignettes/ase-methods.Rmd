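---
title: "Methods: DNA-controlled ASE calling, hotspot detection and tumor-specific ASE genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-controlled ASE calling, hotspot detection and tumor-specific ASE genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `aseLandscape`,
the choices made where the design was genuinely open, and what the
synthetic cohorts do and do not establish about real data.

## The site-level test

At a heterozygous site we observe RNA allele counts $(x, n-x)$ and DNA
allele counts defining the reference fraction $p_0$. The null
hypothesis is that transcription is allele-neutral, i.e. the RNA
reference fraction equals the *DNA* fraction — not 0.5 — so that local
copy-number changes and tumor purity, which shift DNA and RNA together,
do not masquerade as allele-specific expression. The statistic is the
binomial log-likelihood ratio

$$\mathrm{LLR} = \max_p \log B(x;n,p) - \log B(x;n,p_0)
  = x\log\frac{\hat p}{p_0} + (n-x)\log\frac{1-\hat p}{1-p_0},$$

with $\hat p = x/n$ and the convention $0\log 0 = 0$. Under the null,
$2\,\mathrm{LLR}$ is asymptotically $\chi^2_1$ (Wilks), giving the
default cutoff `qchisq(1 - alpha, 1) / 2` — 3.317 nats at the default
$\alpha = 0.01$. Sites whose DNA fraction is 0 or 1 while the RNA
counts are discordant are flagged non-testable: the DNA is effectively
homozygous and the null puts no mass on the observation.

Two properties of this *plug-in* test deserve emphasis:

* The cutoff is exact only when $p_0$ is known. In practice $p_0$ is
  estimated from finite DNA coverage, and its sampling noise inflates
  the realized false-positive rate: at DNA and RNA depths near 60 the
  per-site rejection rate at nominal $\alpha = 0.01$ is roughly 0.08.
  This is an inherent property of treating the DNA ratio as fixed, and
  it is why the package's calibration checks simulate the null with the
  DNA ratio held exactly at 0.5, while the cohort-level analyses either
  adapt to the realized rate automatically (the permutation scan and
  the Poisson test both estimate their backgrounds from the data) or
  use the Monte-Carlo calibration below.
* `llr_cutoff_empirical()` offers the alternative calibration —
  simulate null sites at matched depths and take the $(1-\alpha)$
  quantile of the simulated LLR — for users who want the plug-in noise
  folded into the cutoff.

## The gene-level test and its calibration

Phase is unknown, so each SNV's RNA ratio is folded to its major allele
(into $[0.5, 1]$) and the DNA null fraction is folded into the same
orientation. The gene statistic maximizes a single shared folded ratio
$p_g$ over the gene's SNVs and compares it with each SNV's own folded
null:

$$\mathrm{LLR}_g=\max_{p_g}\sum_i \ell_i(p_g) - \sum_i \ell_i(p_{0i}),$$

A heterogeneity likelihood-ratio test — per-SNV free ratios versus the
shared ratio, $\chi^2_{k-1}$ on $k$ SNVs — excludes genes whose SNVs
disagree on ASE status (default p < 0.05); excluded genes carry no
verdict at all, which matters downstream (they do not count as "tested"
for the Poisson test). Single-SNV genes have heterogeneity p = 1 by
convention (zero degrees of freedom).

Folding makes every SNV's deviation point the same way, so under the
null $\mathrm{LLR}_g$ is stochastically larger than $\chi^2_1/2$, and
the bias grows with $k$: with the Wilks cutoff the measured gene-level
false-positive rate at $\alpha = 0.01$ was 0.44 on null cohorts
(rising with $k$). The package therefore classifies genes against an
*empirical null cutoff* by default (`gene_null_cutoff()`): simulate
null genes with the same SNV count, depths resampled from the sample at
hand, true RNA fraction equal to the true DNA fraction, evaluate the
folded statistic, and take its $(1-\alpha)$ quantile. This reproduces
both the folding bias and the plug-in DNA noise; the measured
gene-level false-positive rate after calibration is ≈ 0.013 at
$\alpha = 0.01$. The cutoffs depend on the depth distribution only
weakly, so the pipeline computes them once per cohort (2000 simulated
genes per SNV count, a fixed internal seed, the caller's RNG stream
untouched). `calibration = "wilks"` restores the uncorrected behaviour.

## Hotspot detection

ASE-labelled sites are counted in sliding windows (defaults 100 kb
window, 10 kb step; the final windows of a chromosome are truncated).
The null distribution of window counts comes from shuffling the
observed label multiset over all tested site positions genome-wide,
preserving the total ASE count; with $k$ of $R$ permutations reaching
the observed count, the empirical p-value is the add-one-smoothed
$(k+1)/(R+1)$, never 0 and never below $1/(R+1)$. BH correction runs
across all windows with at least one tested site, windows with adjusted
p < 0.05 are merged when they overlap or are book-ended, and merged
regions are annotated with overlapping genes. On a single-window
genome this null is exactly hypergeometric, which the test suite uses
as an oracle.

Design choices here:

* **Counting unit.** The default unit is the *per-sample event* (one
  site in one sample). The alternative — collapse samples and label a
  position ASE if it is ASE in *any* sample — is available
  (`hotspot_count_mode = "positions"`) but saturates for cohorts of 20+
  samples: with a per-site rate near 0.2, almost every position is ASE
  in at least one of 20 samples and all contrast vanishes. Event
  counting preserves per-sample resolution while still pooling the
  cohort.
* **Permutations are genome-wide**, not stratified per chromosome, and
  the fixed-count shuffle (rather than independent Bernoulli labels) is
  the default because it is the tighter null and makes the
  hypergeometric oracle exact; `mode = "bernoulli"` exists.
* Sites in several overlapping windows count in each; the BH step
  handles the induced multiplicity.

## Somatic mutations and the six groups

Each somatic mutation is tested with the same LLR against its DNA
mutant-allele fraction; for ASE mutations the direction is `over` when
the RNA mutant fraction exceeds the DNA mutant fraction. Genes whose
ASE mutations disagree in direction are excluded. The remaining genes
are crossed with the tumor/normal expression class of the mutation
carrier — up if FPKM(t) ≥ 2·FPKM(n), down if ≤ ½·FPKM(n), thresholds
inclusive — yielding groups a = (over, up), b = (over, unchanged),
c = (over, down), d = (under, up), e = (under, unchanged),
f = (under, down). When several patients carry mutations in one gene,
the majority expression class wins and ties resolve to `unchanged`
(the conservative class), a documented extension for a case the
single-carrier rule does not define.

## Tumor-specific (somatic) ASE genes

For gene $i$, $s_i$ counts pairs where the gene is ASE in the tumor and
not in the matched normal; $t_i$ counts pairs where the gene is
ASE-testable in both tissues (≥ 1 passing SNV in each, heterogeneity
exclusion in neither — the strictest reading that guarantees a verdict
exists on both sides). With the cohort-wide rate $f = \sum s_i / \sum
t_i$, each gene's p-value is the Poisson upper tail $P[X \ge s_i]$ at
$\lambda_i = f\,t_i$, BH-corrected, flagged at adjusted p < 0.05.
Because $f$ is estimated from the same cohort, the test is
self-calibrating: background genes (including false-positive calls)
raise $f$ rather than the flag rate.

Other cohort statistics follow standard forms: two-tailed paired
t-tests for the tumor–normal ASE-fraction contrast and for per-gene
allele-ratio shifts (BH across genes; ≥ 3 complete pairs required);
recurrence at $\lceil 0.20\,N \rceil$ samples (ceiling, because "at
least 20%" of an integer sample count); one-sided Fisher exact tests
for gene-list enrichment with the sample odds ratio $ad/bc$, over a
universe defaulting to the genes testable in the cohort (avoiding
testability bias); Kruskal–Wallis for hotspot-gene expression ratios.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes, with known truth:

* One 10 Mb chromosome, 500 non-overlapping genes on a 20 kb grid
  (3 exons × 800 bp), heterozygous SNVs on a 40 bp exonic sub-grid
  (Poisson mean 4 per gene). The grid guarantees genes never overlap
  and clean sites never trip the clustered-SNV filter, so filter
  behaviour is exercised exclusively through `inject_artifacts()`,
  which plants sites each filter must remove and records them in the
  truth.
* Negative-binomial depths (mean 60, dispersion 5) truncated at the QC
  floors (DNA ≥ 20, RNA ≥ 10): the generator models the sites a
  pipeline would actually test, which keeps the filter-exactness
  checks sharp.
* Per-site, per-pair ASE states: shared between the two tissues,
  tumor-only, normal-only, or absent. Marginal rates default to 0.20
  (tumor) and 0.17 (normal) with the shared component sized
  (`shared_ase_fraction = 0.53`) so that the shared / tumor-only /
  normal-only split of ASE events is roughly 32/39/29 — the three
  defaults are mutually consistent rather than independent knobs. ASE
  sites express the major allele at fraction 0.8; the over-expressed
  allele is chosen per site-pair and held constant across tissues when
  both are ASE, so shared-direction statistics are testable.
* Three planted hotspot regions (blocks of 7 consecutive genes,
  ≈ 125 kb) whose sites are ASE in both tissues in 60% of pairs, and
  5 driver-like genes with concordant tumor-only ASE across all their
  SNVs in 50% of pairs. Driver genes are drawn from genes with ≥ 2
  SNVs: a planted tumor-specific ASE gene must be testable in
  essentially every pair for the planted per-pair event rate to be
  meaningful.
* 50 somatic mutations per tumor (absent from normals), 37.5% truly
  allele-specific, with the mutant allele over-expressed in 78% of
  ASE cases; direction is assigned per gene so planted group labels
  are well-defined. FPKM is log-normal with planted tumor/normal folds
  of 4, 1, or ¼ for mutation-bearing genes (unambiguous relative to
  the 2 / ½ thresholds under the small residual noise, sdlog 0.05).

What the generator does **not** model: reference-mapping bias,
overdispersed (beta-binomial) allele counts, copy-number alterations,
subclonality, linkage between neighbouring sites beyond the planted
features, and within-gene correlation of baseline ASE (baseline states
are independent across a gene's sites, which makes multi-SNV genes with
mixed status — and hence heterogeneity exclusions — more common than in
real tissue, where *cis*-effects shift whole haplotypes). Passing the
recovery checks therefore demonstrates the statistical machinery is
correct and calibrated under its stated model, not that real-data
false-discovery rates will match.

## Numerical and degenerate-input conventions

* $0\log 0 = 0$ throughout; LLR clipped at 0 against rounding.
* DNA fraction 0 or 1 with discordant RNA → non-testable (NA), not an
  error; zero RNA coverage likewise.
* `classify_expression(0, 0)` is `unchanged`; thresholds inclusive.
* Empirical p-values use add-one smoothing; BH inputs are validated to
  (0, 1].
* Paired t-tests with identically zero differences return p = 1;
  constant non-zero differences are reported as untestable rather than
  given a fabricated p.
* All internal coordinates are 0-based half-open; 1-based positions
  appear only in site tables, and a 1-based position $p$ lies in
  $[s,e)$ iff $s < p \le e$.
* One seed drives everything: the pipeline derives fixed stage offsets
  for the two permutation scans, and the Monte-Carlo gene cutoffs use a
  fixed internal seed with the caller's RNG state restored, so a full
  rerun with the same seed is byte-identical.

## Problem sizes in the test suite

The suite exercises the default 20-pair, 500-gene, 10 Mb cohort for
end-to-end recovery checks (20 replicate cohorts for hotspot and
driver-gene recovery, 20 null cohorts for the flag-rate check), 10,000
simulated sites for type-I calibration, 10,000 permutations per toy
genome for the hypergeometric comparison, and smaller 2–8-pair cohorts
for pipeline plumbing; these sizes were chosen so each property is
measured with comfortable Monte-Carlo margins while the whole suite
runs on a laptop in minutes.
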