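test_that("snv_llr matches hand-derived values at the DNA-balanced null", {
  expect_equal(snv_llr(50, 50, 50, 50), 0)
  expect_equal(snv_llr(80, 20, 50, 50),
               80 * log(0.8) + 20 * log(0.2) - 100 * log(0.5),
               tolerance = 1e-12)
  expect_equal(snv_llr(80, 20, 50, 50), 19.27448, tolerance = 1e-5)
  # 60/40 vs balanced DNA is below the alpha = 0.01 cutoff
  llr <- snv_llr(60, 40, 50, 50)
  expect_equal(llr, 2.013551, tolerance = 1e-5)
  expect_lt(2 * llr, qchisq(0.99, 1))
})

test_that("snv_llr equals brute-force log-likelihood evaluation", {
  for (p0_counts in list(c(3, 7), c(5, 5), c(7, 3))) {
    p0 <- p0_counts[1] / 10
    for (n in c(1, 5, 13, 30)) {
      x <- 0:n
      got <- snv_llr(x, n - x, p0_counts[1], p0_counts[2])
      want <- llr_brute(x, n, p0)
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("snv_llr is invariant under simultaneous ref/alt swap", {
  set.seed(4)
  rr <- sample(0:60, 50, TRUE); ra <- sample(0:60, 50, TRUE)
  dr <- sample(10:60, 50, TRUE); da <- sample(10:60, 50, TRUE)
  expect_equal(snv_llr(rr, ra, dr, da), snv_llr(ra, rr, da, dr))
})

test_that("snv_llr is monotone in distance from the balanced ratio", {
  x <- 50:100
  llr <- snv_llr(x, 100 - x, 50, 50)
  expect_true(all(diff(llr) >= -1e-12))
})

test_that("degenerate DNA ratios flag sites non-testable", {
  expect_true(is.na(snv_llr(10, 5, 20, 0)))
  expect_true(is.na(snv_llr(5, 10, 0, 20)))
  # concordant RNA with homozygous-looking DNA is still evaluable (llr 0)
  expect_equal(snv_llr(10, 0, 20, 0), 0)
})

test_that("llr_cutoff reproduces chi-square quantile calibration", {
  expect_equal(llr_cutoff(0.01), qchisq(0.99, 1) / 2, tolerance = 1e-12)
  expect_equal(llr_cutoff(0.01), 3.3174, tolerance = 1e-4)
  expect_equal(llr_cutoff(0.05), 1.9207, tolerance = 1e-4)
  expect_lt(llr_cutoff(0.9999), 1e-4)
  expect_error(llr_cutoff(0), "alpha")
  expect_error(llr_cutoff(1), "alpha")
})

test_that("type-I error at the known balanced null is near nominal", {
  set.seed(7)
  n_sites <- 10000
  depth <- pmax(stats::rnbinom(n_sites, size = 5, mu = 60), 50L)
  x <- rbinom(n_sites, depth, 0.5)
  llr <- snv_llr(x, depth - x, 30, 30)  # DNA ratio exactly 0.5
  rate <- mean(llr > llr_cutoff(0.01))
  expect_gte(rate, 0.004)
  expect_lte(rate, 0.018)
})

test_that("gene_llr aggregates folded SNVs and tracks heterogeneity", {
  one <- gene_llr(80, 20, 50, 50)
  expect_equal(one$heterogeneity_p, 1)
  expect_equal(one$llr, snv_llr(80, 20, 50, 50))

  # two concordant folded SNVs: shared ratio 0.8, llr doubles, het p = 1
  two <- gene_llr(c(80, 20), c(20, 80), c(50, 50), c(50, 50))
  expect_equal(two$heterogeneity_p, 1)
  expect_equal(two$llr, 38.54897, tolerance = 1e-5)
  expect_equal(two$gene_major_ratio, 0.8)

  # discordant folded ratios 95/5 and 55/45: heterogeneity LRT computed
  # against a direct log-likelihood oracle
  het <- gene_llr(c(95, 55), c(5, 45), c(50, 50), c(50, 50))
  ll <- function(x, n, p) ifelse(x == 0, 0, x * log(p)) +
    ifelse(n - x == 0, 0, (n - x) * log(1 - p))
  p_shared <- 150 / 200
  stat <- 2 * ((ll(95, 100, 0.95) + ll(55, 100, 0.55)) -
                 (ll(95, 100, p_shared) + ll(55, 100, p_shared)))
  expect_equal(het$heterogeneity_p, pchisq(stat, df = 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(het$heterogeneity_p, 0.05)
  expect_true(het$excluded_heterogeneous)
  expect_true(is.na(het$is_ase))

  expect_error(gene_llr(integer(0), integer(0), integer(0), integer(0)),
               "at least one")
})

test_that("empirical gene cutoffs keep the gene-level false-positive rate near alpha", {
  set.seed(12)
  n_genes <- 2000
  k <- 4
  depth <- function(n) pmax(stats::rnbinom(n, size = 5, mu = 60), 20L)
  nd <- depth(n_genes * k); nr <- depth(n_genes * k)
  dref <- pmin(pmax(rbinom(n_genes * k, nd, 0.5), 1), nd - 1)
  rref <- rbinom(n_genes * k, nr, 0.5)
  cutoff <- gene_null_cutoff(k, 0.01, nd, nr, n_sim = 4000L)
  gid <- rep(seq_len(n_genes), each = k)
  hits <- vapply(split(seq_len(n_genes * k), gid), function(ii) {
    g <- gene_llr(rref[ii], (nr - rref)[ii], dref[ii], (nd - dref)[ii],
                  cutoff = cutoff)
    !g$excluded_heterogeneous && g$llr > cutoff
  }, TRUE)
  rate <- mean(hits)
  expect_lt(rate, 0.03)   # calibrated, unlike the Wilks gene cutoff
  expect_gt(rate, 0.001)
  # the Wilks cutoff is badly anti-conservative for folded multi-SNV genes
  expect_gt(mean(vapply(split(seq_len(n_genes * k), gid), function(ii)
    gene_llr(rref[ii], (nr - rref)[ii], dref[ii], (nd - dref)[ii])$llr, 0)
    > llr_cutoff(0.01)), 0.1)
})

test_that("vectorized gene calling equals per-gene gene_llr evaluation", {
  set.seed(19)
  genes <- do.call(rbind, lapply(1:25, function(i)
    make_gene(sprintf("G%02d", i), start = i * 10000L,
              end = i * 10000L + 5000L)))
  pos <- unlist(lapply(1:25, function(i)
    i * 10000L + sort(sample.int(5000, sample(1:6, 1)))))
  n <- length(pos)
  sites <- make_sites(pos,
                      rna_ref = sample(10:80, n, TRUE),
                      rna_alt = sample(10:80, n, TRUE),
                      dna_ref = sample(10:60, n, TRUE),
                      dna_alt = sample(10:60, n, TRUE))
  got <- call_ase_genes(sites, genes, calibration = "wilks")
  for (i in seq_len(nrow(got))) {
    ii <- which(pos > genes$start[i] & pos <= genes$end[i] &
                  genes$gene_id[i] == got$gene_id[i])
    sub <- sites[sites$pos > genes$start[match(got$gene_id[i],
                                               genes$gene_id)] &
                   sites$pos <= genes$end[match(got$gene_id[i],
                                                genes$gene_id)], ]
    ref <- gene_llr(sub$rna_ref, sub$rna_alt, sub$dna_ref, sub$dna_alt)
    expect_equal(got$llr[i], ref$llr, tolerance = 1e-12)
    expect_equal(got$heterogeneity_p[i], ref$heterogeneity_p,
                 tolerance = 1e-12)
    expect_equal(got$gene_major_ratio[i], ref$gene_major_ratio,
                 tolerance = 1e-12)
    expect_equal(got$excluded_heterogeneous[i], ref$excluded_heterogeneous)
  }
})

test_that("call_ase_snvs classifies against the cutoff and reports direction", {
  sites <- make_sites(c(100, 200, 300),
                      rna_ref = c(80, 20, 50), rna_alt = c(20, 80, 50))
  calls <- call_ase_snvs(sites, pipeline_config())
  expect_equal(calls$is_ase, c(TRUE, TRUE, FALSE))
  expect_equal(calls$direction, c("ref_over", "alt_over", "balanced"))
  expect_equal(calls$rna_major_ratio, c(0.8, 0.8, 0.5))
})

test_that("call_ase_genes maps sites to genes by half-open span", {
  genes <- rbind(make_gene("G1", start = 0L, end = 1000L),
                 make_gene("G2", start = 2000L, end = 3000L))
  sites <- make_sites(c(500, 600, 2500),
                      rna_ref = c(80, 75, 50), rna_alt = c(20, 25, 50))
  calls <- call_ase_genes(sites, genes, calibration = "wilks")
  expect_equal(calls$gene_id, c("G1", "G2"))
  expect_equal(calls$n_snvs, c(2L, 1L))
  expect_true(calls$is_ase[1])
  expect_false(calls$is_ase[2])
})
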