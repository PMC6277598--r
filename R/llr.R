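#' DNA-controlled binomial log-likelihood ratio for one SNV
#'
#' Tests whether the RNA allele fraction at a heterozygous site departs
#' from the DNA allele fraction, which serves as the per-site null and
#' absorbs local copy-number and purity effects. The statistic is
#' \deqn{LLR = \max_p \log B(x; n, p) - \log B(x; n, p_0)}
#' with \eqn{x} the RNA reference count, \eqn{n} the RNA depth and
#' \eqn{p_0} the DNA reference fraction; the maximum is attained at
#' \eqn{\hat p = x/n}, so the binomial coefficient cancels and
#' \eqn{LLR = x \log(\hat p/p_0) + (n-x)\log((1-\hat p)/(1-p_0))} with the
#' convention \eqn{0 \log 0 = 0}. Twice the LLR is asymptotically
#' chi-square with 1 df under the null (Wilks), which calibrates the
#' cutoff of [llr_cutoff()].
#'
#' All arguments are vectorized.
#'
#' @param rna_ref,rna_alt RNA read counts of the reference and alternate
#'   allele.
#' @param dna_ref,dna_alt DNA read counts.
#' @return numeric LLR in nats; `NA` where the site is non-testable
#'   (DNA fraction 0 or 1 with discordant RNA counts, or zero RNA depth).
#' @export
snv_llr <- function(rna_ref, rna_alt, dna_ref, dna_alt) {
  n <- rna_ref + rna_alt
  n_dna <- dna_ref + dna_alt
  p0 <- dna_ref / n_dna
  phat <- rna_ref / n
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  llr <- xlogy(rna_ref, phat) + xlogy(rna_alt, 1 - phat) -
    xlogy(rna_ref, p0) - xlogy(rna_alt, 1 - p0)
  # DNA effectively homozygous: the null puts zero mass on any discordant
  # RNA read, so the site is flagged non-testable rather than infinite.
  bad <- (p0 == 0 & rna_ref > 0) | (p0 == 1 & rna_alt > 0) |
    n == 0 | n_dna == 0
  llr[bad] <- NA_real_
  llr <- pmax(llr, 0)  # guard tiny negative rounding at phat == p0
  llr
}

#' LLR significance cutoff (Wilks calibration)
#'
#' The cutoff at significance level `alpha` is half the upper-`alpha`
#' quantile of the chi-square distribution with 1 df, since 2*LLR is
#' asymptotically chi-square(1) under the null.
#'
#' @param alpha significance level in (0, 1).
#' @return cutoff in nats (e.g. 3.3174 at alpha = 0.01).
#' @export
llr_cutoff <- function(alpha) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("alpha must be in (0, 1)")
  }
  stats::qchisq(1 - alpha, df = 1) / 2
}

#' Empirical-null LLR cutoff
#'
#' Alternative calibration that simulates null sites (RNA fraction equal
#' to the DNA fraction) at the observed DNA/RNA depths and takes the
#' (1 - alpha) quantile of the simulated LLR distribution. Useful when
#' depths are low enough that the chi-square asymptotics are doubtful.
#'
#' @param alpha significance level.
#' @param rna_depth,dna_depth integer vectors of depths to simulate at
#'   (recycled against each other).
#' @param n_sim number of simulated null sites.
#' @return cutoff in nats.
#' @export
llr_cutoff_empirical <- function(alpha, rna_depth, dna_depth, n_sim = 100000L) {
  stopifnot(alpha > 0, alpha < 1, n_sim >= 1000)
  idx <- sample.int(length(rna_depth), n_sim, replace = TRUE)
  nd <- rep_len(dna_depth, length(rna_depth))[idx]
  nr <- rna_depth[idx]
  dref <- stats::rbinom(n_sim, nd, 0.5)
  # condition on DNA heterozygosity as the pipeline does
  keep <- dref > 0 & dref < nd
  p0 <- dref[keep] / nd[keep]
  rref <- stats::rbinom(sum(keep), nr[keep], p0)
  llr <- snv_llr(rref, nr[keep] - rref, dref[keep], nd[keep] - dref[keep])
  stats::quantile(llr, 1 - alpha, na.rm = TRUE, names = FALSE)
}

#' Call ASE at SNV level for a site table
#'
#' Applies [snv_llr()] to every row and classifies sites against the
#' cutoff at `config$alpha_snv`. The major-allele RNA ratio is the RNA
#' fraction of the more expressed allele, folded to [0.5, 1].
#'
#' @param sites validated site data.frame (post-filtering).
#' @param config [pipeline_config()].
#' @return data.frame: site keys, `llr`, `cutoff`, `is_ase`,
#'   `rna_major_ratio`, `direction` (`ref_over` / `alt_over` /
#'   `balanced`), `testable`.
#' @export
call_ase_snvs <- function(sites, config = pipeline_config()) {
  validate_sites(sites)
  llr <- snv_llr(sites$rna_ref, sites$rna_alt, sites$dna_ref, sites$dna_alt)
  cutoff <- llr_cutoff(config$alpha_snv)
  testable <- !is.na(llr)
  is_ase <- testable & llr > cutoff
  n_rna <- sites$rna_ref + sites$rna_alt
  ref_frac <- ifelse(n_rna > 0, sites$rna_ref / n_rna, NA_real_)
  p0 <- sites$dna_ref / (sites$dna_ref + sites$dna_alt)
  direction <- ifelse(!is_ase, "balanced",
                      ifelse(ref_frac > p0, "ref_over", "alt_over"))
  data.frame(
    chrom = sites$chrom, pos = sites$pos,
    sample_id = sites$sample_id, tissue = sites$tissue,
    origin = sites$origin,
    llr = llr, cutoff = cutoff, testable = testable, is_ase = is_ase,
    rna_major_ratio = pmax(ref_frac, 1 - ref_frac),
    direction = direction,
    ref_frac_rna = ref_frac, ref_frac_dna = p0,
    stringsAsFactors = FALSE
  )
}

# Fold one SNV's counts so its RNA major allele is first, and fold the
# DNA null fraction into the same orientation. Phase across SNVs is
# unknown, so gene-level aggregation works on folded ratios.
fold_to_major <- function(rna_ref, rna_alt, dna_ref, dna_alt) {
  flip <- rna_ref < rna_alt
  x <- ifelse(flip, rna_alt, rna_ref)
  n <- rna_ref + rna_alt
  p0 <- dna_ref / (dna_ref + dna_alt)
  p0 <- ifelse(flip, 1 - p0, p0)
  list(x = x, n = n, p0 = p0)
}

#' Gene-level ASE test with heterogeneity exclusion
#'
#' Aggregates the SNVs of one gene under a shared folded allele ratio.
#' Each SNV's RNA ratio is folded to its major allele (phase unknown);
#' the gene LLR compares the likelihood at the single maximizing shared
#' ratio with the likelihood at each SNV's own DNA null. A heterogeneity
#' LRT (per-SNV free ratios vs the shared ratio, chi-square with k-1 df)
#' flags genes whose SNVs disagree on ASE status; such genes are excluded
#' from downstream analyses rather than called either way.
#'
#' Because the folding step always orients each SNV towards its RNA
#' major allele, the shared-ratio LLR is biased upward under the null
#' and its null distribution depends on the number of SNVs; the
#' chi-square(1)/2 cutoff of [llr_cutoff()] is therefore anti-conservative
#' at gene level. [gene_null_cutoff()] provides a Monte-Carlo cutoff
#' matched to the SNV count and sequencing depths, which
#' [call_ase_genes()] uses by default.
#'
#' @param rna_ref,rna_alt,dna_ref,dna_alt counts of the gene's SNVs.
#' @param config [pipeline_config()].
#' @param cutoff LLR classification cutoff; defaults to the Wilks value
#'   `llr_cutoff(config$alpha_snv)`.
#' @return list: `n_snvs`, `llr`, `cutoff`, `heterogeneity_p`,
#'   `excluded_heterogeneous`, `is_ase` (NA when excluded),
#'   `gene_major_ratio` (the shared folded ratio estimate).
#' @export
gene_llr <- function(rna_ref, rna_alt, dna_ref, dna_alt,
                     config = pipeline_config(), cutoff = NULL) {
  k <- length(rna_ref)
  if (k == 0) stop("gene_llr needs at least one SNV")
  f <- fold_to_major(rna_ref, rna_alt, dna_ref, dna_alt)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  loglik <- function(x, n, p) xlogy(x, p) + xlogy(n - x, 1 - p)
  p_shared <- sum(f$x) / sum(f$n)
  ll_shared <- sum(loglik(f$x, f$n, p_shared))
  ll_null <- sum(loglik(f$x, f$n, f$p0))
  ll_free <- sum(loglik(f$x, f$n, f$x / f$n))
  llr <- ll_shared - ll_null
  het_stat <- 2 * (ll_free - ll_shared)
  het_p <- if (k == 1) 1.0 else
    stats::pchisq(het_stat, df = k - 1, lower.tail = FALSE)
  excluded <- het_p < config$het_p_cutoff
  if (is.null(cutoff)) cutoff <- llr_cutoff(config$alpha_snv)
  list(n_snvs = k, llr = llr, cutoff = cutoff,
       heterogeneity_p = het_p,
       excluded_heterogeneous = excluded,
       is_ase = if (excluded) NA else llr > cutoff,
       gene_major_ratio = p_shared)
}

# evaluate an expression under a fixed seed without disturbing the
# caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Monte-Carlo null cutoff for the gene-level LLR
#'
#' Simulates null genes of `k` heterozygous SNVs (true RNA fraction
#' equal to the true DNA fraction 0.5, DNA and RNA depths resampled from
#' the supplied pools), evaluates the folded shared-ratio gene LLR on
#' each, and returns the (1 - alpha) quantile. This reproduces both
#' sources of null inflation that the Wilks cutoff ignores: the
#' major-allele folding bias, which grows with `k`, and the sampling
#' noise of the plug-in DNA ratio.
#'
#' @param k number of SNVs in the gene.
#' @param alpha significance level.
#' @param dna_depths,rna_depths integer vectors to resample depths from.
#' @param n_sim simulated null genes (default 2000).
#' @param seed RNG seed for the simulation (restored afterwards).
#' @return cutoff in nats.
#' @export
gene_null_cutoff <- function(k, alpha, dna_depths, rna_depths,
                             n_sim = 2000L, seed = 104729L) {
  stopifnot(k >= 1, alpha > 0, alpha < 1, n_sim >= 100)
  with_seed(seed + k, {
    m <- k * n_sim
    nd <- sample(dna_depths, m, replace = TRUE)
    nr <- sample(rna_depths, m, replace = TRUE)
    dref <- stats::rbinom(m, nd, 0.5)
    dref <- pmin(pmax(dref, 1L), nd - 1L)
    rref <- stats::rbinom(m, nr, 0.5)
    f <- fold_to_major(rref, nr - rref, dref, nd - dref)
    gene_id <- rep(seq_len(n_sim), each = k)
    xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
    p_shared <- rowsum(f$x, gene_id)[, 1] / rowsum(f$n, gene_id)[, 1]
    pg <- p_shared[gene_id]
    ll_shared <- rowsum(xlogy(f$x, pg) + xlogy(f$n - f$x, 1 - pg),
                        gene_id)[, 1]
    ll_null <- rowsum(xlogy(f$x, f$p0) + xlogy(f$n - f$x, 1 - f$p0),
                      gene_id)[, 1]
    stats::quantile(ll_shared - ll_null, 1 - alpha, names = FALSE)
  })
}

#' Call gene-level ASE for all genes in a sample
#'
#' Assigns each testable SNV call to the gene whose span contains it and
#' runs [gene_llr()] per gene. A 1-based position p lies in the 0-based
#' half-open gene span [s, e) iff s < p <= e.
#'
#' @param sites filtered site data.frame for one sample (germline sites).
#' @param genes gene model data.frame.
#' @param config [pipeline_config()].
#' @param calibration `"empirical"` (default) classifies each gene
#'   against a [gene_null_cutoff()] matched to its SNV count and the
#'   sample's depth distribution; `"wilks"` uses the chi-square cutoff
#'   of [llr_cutoff()] for every gene.
#' @param cutoffs optional precomputed named vector of empirical cutoffs
#'   (names = SNV counts), e.g. shared across the samples of a cohort;
#'   missing entries are computed from this sample's depths.
#' @return data.frame with one row per gene having >= 1 testable SNV.
#' @export
call_ase_genes <- function(sites, genes, config = pipeline_config(),
                           calibration = c("empirical", "wilks"),
                           cutoffs = NULL) {
  calibration <- match.arg(calibration)
  validate_sites(sites)
  llr <- snv_llr(sites$rna_ref, sites$rna_alt, sites$dna_ref, sites$dna_alt)
  sites <- sites[!is.na(llr), , drop = FALSE]
  if (nrow(sites) == 0) {
    return(data.frame(gene_id = character(), sample_id = character(),
                      tissue = character(), n_snvs = integer(),
                      llr = numeric(), heterogeneity_p = numeric(),
                      excluded_heterogeneous = logical(),
                      is_ase = logical(), gene_major_ratio = numeric(),
                      major_allele = character(),
                      stringsAsFactors = FALSE))
  }
  gene_idx <- assign_sites_to_genes(sites, genes)
  keep <- !is.na(gene_idx)
  sites <- sites[keep, , drop = FALSE]
  gene_idx <- gene_idx[keep]
  by_gene <- split(seq_len(nrow(sites)), gene_idx)
  k <- lengths(by_gene)
  if (calibration == "wilks") {
    cutoffs <- NULL
  } else {
    ks <- setdiff(sort(unique(k)), as.integer(names(cutoffs)))
    if (length(ks) > 0) {
      dna_pool <- sites$dna_ref + sites$dna_alt
      rna_pool <- sites$rna_ref + sites$rna_alt
      extra <- vapply(ks, gene_null_cutoff, 0.0,
                      alpha = config$alpha_snv,
                      dna_depths = dna_pool, rna_depths = rna_pool)
      cutoffs <- c(cutoffs, stats::setNames(extra, ks))
    }
  }
  # vectorized equivalent of per-gene gene_llr() (see test suite for the
  # equivalence check)
  gid <- match(gene_idx, as.integer(names(by_gene)))
  f <- fold_to_major(sites$rna_ref, sites$rna_alt,
                     sites$dna_ref, sites$dna_alt)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  llterm <- function(p) xlogy(f$x, p) + xlogy(f$n - f$x, 1 - p)
  p_shared <- (rowsum(f$x, gid) / rowsum(f$n, gid))[, 1]
  ll_shared <- rowsum(llterm(p_shared[gid]), gid)[, 1]
  ll_null <- rowsum(llterm(f$p0), gid)[, 1]
  ll_free <- rowsum(llterm(f$x / f$n), gid)[, 1]
  llr <- ll_shared - ll_null
  het_stat <- pmax(2 * (ll_free - ll_shared), 0)
  het_p <- ifelse(k == 1, 1,
                  stats::pchisq(het_stat, df = pmax(k - 1, 1),
                                lower.tail = FALSE))
  excluded <- het_p < config$het_p_cutoff
  cutoff <- if (is.null(cutoffs)) rep(llr_cutoff(config$alpha_snv), length(k))
            else unname(cutoffs[as.character(k)])
  # reported allele identity: the most imbalanced SNV's RNA major allele
  dev <- abs(sites$rna_ref / (sites$rna_ref + sites$rna_alt) - 0.5)
  major_allele <- vapply(by_gene, function(ii) {
    first <- ii[which.max(dev[ii])]
    if (sites$rna_ref[first] >= sites$rna_alt[first]) "ref" else "alt"
  }, "")
  first_row <- vapply(by_gene, `[`, 0L, 1L)
  res <- data.frame(
    gene_id = genes$gene_id[gene_idx[first_row]],
    sample_id = sites$sample_id[first_row],
    tissue = sites$tissue[first_row],
    n_snvs = as.integer(k), llr = llr,
    heterogeneity_p = het_p,
    excluded_heterogeneous = excluded,
    is_ase = ifelse(excluded, NA, llr > cutoff),
    gene_major_ratio = p_shared,
    major_allele = major_allele,
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Map each site (1-based pos) to the index of the containing gene span
# (0-based half-open), NA when none or ambiguous (first match wins).
assign_sites_to_genes <- function(sites, genes) {
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr, select = "first")
  hits
}
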