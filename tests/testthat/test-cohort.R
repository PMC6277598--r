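mk_calls <- function(pos, is_ase, direction = "ref_over", sample_id = "S",
                     tissue = "tumor") {
  data.frame(chrom = "chr1", pos = as.integer(pos), sample_id = sample_id,
             tissue = tissue, origin = "germline", llr = ifelse(is_ase, 10, 0),
             cutoff = 3.3174, testable = TRUE, is_ase = is_ase,
             rna_major_ratio = ifelse(is_ase, 0.8, 0.5),
             direction = ifelse(is_ase, direction, "balanced"),
             ref_frac_rna = 0.5, ref_frac_dna = 0.5,
             stringsAsFactors = FALSE)
}

test_that("pair summary partitions shared and specific ASEs by set algebra", {
  # tumor ASE {A,B,C}, normal ASE {B,C,D}, all positions tested in both
  pos <- c(100, 200, 300, 400, 500)
  tum <- mk_calls(pos, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  nor <- mk_calls(pos, c(FALSE, TRUE, TRUE, TRUE, FALSE), tissue = "normal")
  ps <- pair_summary(tum, nor)
  expect_equal(ps$n_shared, 2)
  expect_equal(ps$n_tumor_only, 1)
  expect_equal(ps$n_normal_only, 1)
  expect_equal(ps$n_shared_same_direction, 2)
  expect_equal(ps$frac_ase_tumor, 3 / 5)

  same <- pair_summary(tum, transform(tum, tissue = "normal"))
  expect_equal(same$n_tumor_only, 0)
  expect_equal(same$n_normal_only, 0)
})

test_that("pair summary matches brute-force set computation on random fixtures", {
  set.seed(11)
  for (i in 1:10) {
    pos_t <- sort(sample.int(1000, 30))
    pos_n <- sort(sample.int(1000, 30))
    tum <- mk_calls(pos_t, runif(30) < 0.4)
    nor <- mk_calls(pos_n, runif(30) < 0.4, tissue = "normal")
    ps <- pair_summary(tum, nor)
    common <- intersect(pos_t, pos_n)
    ase_t <- intersect(pos_t[tum$is_ase], common)
    ase_n <- intersect(pos_n[nor$is_ase], common)
    expect_equal(ps$n_shared, length(intersect(ase_t, ase_n)))
    expect_equal(ps$n_tumor_only, length(setdiff(ase_t, ase_n)))
    expect_equal(ps$n_normal_only, length(setdiff(ase_n, ase_t)))
  }
})

test_that("intersection mode restricts fractions to commonly tested sites", {
  tum <- mk_calls(c(100, 200, 300), c(TRUE, TRUE, FALSE))
  nor <- mk_calls(c(200, 300, 400), c(TRUE, FALSE, FALSE), tissue = "normal")
  ps <- pair_summary(tum, nor, mode = "intersection")
  expect_equal(ps$n_tested_tumor, 2)
  expect_equal(ps$frac_ase_tumor, 0.5)
  none <- pair_summary(mk_calls(100, TRUE),
                       mk_calls(900, TRUE, tissue = "normal"),
                       mode = "intersection")
  expect_true(none$empty)
})

test_that("paired fraction test matches the textbook t formula", {
  s <- data.frame(frac_ase_tumor = c(0.22, 0.25, 0.19, 0.24, 0.21),
                  frac_ase_normal = c(0.18, 0.20, 0.17, 0.19, 0.18))
  got <- paired_fraction_test(s)
  d <- s$frac_ase_tumor - s$frac_ase_normal
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(abs(t_hand), df = length(d) - 1, lower.tail = FALSE)
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)

  same <- data.frame(frac_ase_tumor = c(0.2, 0.3), frac_ase_normal = c(0.2, 0.3))
  expect_error(paired_fraction_test(same[1, ]), "2 pairs")
})

test_that("recurrence uses a ceiling threshold on the sample count", {
  # 59 samples at 20%: ceiling(11.8) = 12 samples needed
  calls <- do.call(rbind, lapply(1:59, function(i) {
    data.frame(gene_id = c("G1", "G2"), sample_id = sprintf("S%02d", i),
               tissue = "tumor", n_snvs = 1L, llr = 10,
               heterogeneity_p = 1, excluded_heterogeneous = FALSE,
               is_ase = c(i <= 12, i <= 11), gene_major_ratio = 0.8,
               major_allele = "ref", stringsAsFactors = FALSE)
  }))
  rec <- recurrence(calls, 0.20)
  g <- rec$genes[order(rec$genes$gene_id), ]
  expect_true(g$recurrent[g$gene_id == "G1"])   # 12 of 59
  expect_false(g$recurrent[g$gene_id == "G2"])  # 11 of 59
  expect_equal(dim(rec$ratio_matrix), c(1, 59))

  rec_all <- recurrence(calls, 1.0)
  expect_false(any(rec_all$genes$recurrent))
})

test_that("allele ratio shift runs per-gene paired t-tests with BH", {
  calls <- do.call(rbind, lapply(1:10, function(i) {
    rbind(data.frame(gene_id = "G1", patient_id = sprintf("P%02d", i),
                     tissue = "tumor", gene_major_ratio = 0.95,
                     stringsAsFactors = FALSE),
          data.frame(gene_id = "G1", patient_id = sprintf("P%02d", i),
                     tissue = "normal", gene_major_ratio = 0.60,
                     stringsAsFactors = FALSE))
  }))
  calls$gene_major_ratio <- calls$gene_major_ratio +
    rep(c(0.004, 0), 10) * rep(seq(0, 1, length.out = 10), each = 2)
  got <- allele_ratio_shift(calls)
  expect_lt(got$p_adj, 0.05)

  ident <- transform(calls, gene_major_ratio = rep(c(0.9, 0.9), 10))
  expect_equal(allele_ratio_shift(ident)$p_value, 1)

  few <- calls[1:4, ]
  expect_equal(allele_ratio_shift(few)$skipped, "insufficient_pairs")
})

test_that("allele ratio shift matches a hand-computed t statistic", {
  set.seed(13)
  rt <- runif(6, 0.7, 1); rn <- runif(6, 0.5, 0.9)
  calls <- rbind(
    data.frame(gene_id = "G", patient_id = sprintf("P%d", 1:6),
               tissue = "tumor", gene_major_ratio = rt),
    data.frame(gene_id = "G", patient_id = sprintf("P%d", 1:6),
               tissue = "normal", gene_major_ratio = rn))
  got <- allele_ratio_shift(calls)
  d <- rt - rn
  expect_equal(got$statistic, mean(d) / (sd(d) / sqrt(6)), tolerance = 1e-12)
})

test_that("poisson upper tail matches direct pmf summation", {
  expect_equal(poisson_upper_tail(5, 2),
               1 - sum(exp(-2) * 2^(0:4) / factorial(0:4)),
               tolerance = 1e-12)
  expect_equal(poisson_upper_tail(5, 2), 0.052653, tolerance = 1e-5)
  expect_equal(poisson_upper_tail(0, 3), 1)
})

test_that("somatic ASE gene test computes f, lambda and flags excess genes", {
  calls <- do.call(rbind, lapply(1:20, function(i) {
    pid <- sprintf("P%02d", i)
    rbind(
      data.frame(gene_id = c("HOT", "BG1", "BG2"), patient_id = pid,
                 tissue = "tumor", is_ase = c(i <= 10, i == 1, FALSE),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = c("HOT", "BG1", "BG2"), patient_id = pid,
                 tissue = "normal", is_ase = FALSE,
                 stringsAsFactors = FALSE))
  }))
  got <- somatic_ase_gene_test(calls)
  expect_equal(sum(got$s_i) / sum(got$t_i), got$f[1])
  expect_equal(got$f[1], 11 / 60)
  expect_equal(got$lambda_i, got$f * got$t_i)
  hot <- got[got$gene_id == "HOT", ]
  expect_equal(hot$s_i, 10L)
  expect_equal(hot$p_poisson,
               poisson_upper_tail(10, 11 / 60 * 20), tolerance = 1e-12)
  expect_true(hot$is_somatic_ase)
  expect_equal(got$p_poisson[got$s_i == 0], 1)

  # forced example: s = (1,1), t = (2,2) gives f = 0.5
  small <- rbind(
    data.frame(gene_id = rep(c("A", "B"), each = 2),
               patient_id = rep(c("P1", "P2"), 2), tissue = "tumor",
               is_ase = c(TRUE, FALSE, TRUE, FALSE)),
    data.frame(gene_id = rep(c("A", "B"), each = 2),
               patient_id = rep(c("P1", "P2"), 2), tissue = "normal",
               is_ase = FALSE))
  expect_equal(somatic_ase_gene_test(small)$f[1], 0.5)
})

test_that("enrichment reproduces hypergeometric tails and sample odds ratios", {
  universe <- sprintf("g%02d", 1:40)
  got <- enrichment(universe[1:20], universe[c(1:10, 21:30)], universe)
  expect_equal(unname(got$table[1, ]), c(10, 10))
  expect_equal(unname(got$table[2, ]), c(10, 10))
  expect_equal(got$odds_ratio, 1)
  expect_gt(got$p_value, 0.3)

  # maximal association on a 10-gene universe: one-sided p = 1 / C(10,5)
  uni <- sprintf("h%d", 1:10)
  perfect <- enrichment(uni[1:5], uni[1:5], uni)
  expect_equal(perfect$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  # random tables against a brute-force hypergeometric tail
  set.seed(14)
  for (i in 1:10) {
    uni2 <- sprintf("u%02d", 1:30)
    q <- sample(uni2, sample(5:15, 1))
    r <- sample(uni2, sample(5:15, 1))
    got2 <- enrichment(q, r, uni2)
    a <- length(intersect(q, r))
    tail <- sum(dhyper(a:min(length(q), length(r)), length(r),
                       30 - length(r), length(q)))
    expect_equal(got2$p_value, tail, tolerance = 1e-9)
  }
  expect_error(enrichment("a", "b", character(0)), "empty universe")
})

test_that("hotspot expression comparison is a Kruskal-Wallis rank test", {
  g <- list(shared = c(1.0, 1.1, 0.9, 1.2, 1.05, 0.85),
            tumor = c(1.05, 0.95, 1.0, 1.15, 0.9, 1.1),
            normal = c(1.1, 0.9, 1.0, 0.95, 1.2, 1.0))
  got <- hotspot_expression_compare(g)
  want <- kruskal.test(g)
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p_value, want$p.value)
  expect_gt(got$p_value, 0.5)

  shifted <- g; shifted$tumor <- shifted$tumor + 10
  expect_lt(hotspot_expression_compare(shifted)$p_value, 0.05)

  expect_warning(res <- hotspot_expression_compare(
    list(a = 1:5, b = numeric(0), c = 6:10)), "empty")
  expect_equal(res$df, 1)
  expect_error(hotspot_expression_compare(list(a = 1:5)), "2 non-empty")
})
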