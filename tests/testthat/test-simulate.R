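test_that("simulated cohorts are reproducible and have balanced DNA", {
  dir <- withr::local_tempdir()
  p <- simulation_params(n_pairs = 6,
                         genome = data.frame(chrom = "chr1",
                                             length = 3000000L),
                         n_genes = 150L, rng_seed = 7L)
  co1 <- simulate_cohort(p, file.path(dir, "a"))
  co2 <- simulate_cohort(p, file.path(dir, "b"))
  s1 <- read_site_table(co1$manifest$tumor_sites[1], "tumor", "x")
  s2 <- read_site_table(co2$manifest$tumor_sites[1], "tumor", "x")
  expect_identical(s1, s2)
  expect_identical(co1$truth$site_truth, co2$truth$site_truth)

  # germline DNA allele fraction centers on 0.5 (law of large numbers)
  germ <- do.call(rbind, lapply(seq_len(nrow(co1$manifest)), function(i)
    read_site_table(co1$manifest$tumor_sites[i], "tumor", "x")))
  germ <- germ[germ$origin == "germline", ]
  frac <- germ$dna_ref / (germ$dna_ref + germ$dna_alt)
  expect_lt(abs(mean(frac) - 0.5), 0.01)
})

test_that("true-ASE bookkeeping matches the configured base rates", {
  dir <- withr::local_tempdir()
  p <- simulation_params(n_pairs = 8,
                         genome = data.frame(chrom = "chr1",
                                             length = 4000000L),
                         n_genes = 200L, n_hotspots = 0L,
                         n_driver_like_genes = 0L,
                         n_somatic_per_tumor = 0L, rng_seed = 21L)
  co <- simulate_cohort(p, file.path(dir, "c"))
  tr <- co$truth$site_truth
  for (ts in c("tumor", "normal")) {
    rate <- if (ts == "tumor") p$base_ase_rate_tumor else
      p$base_ase_rate_normal
    sub <- tr[tr$tissue == ts, ]
    se <- sqrt(rate * (1 - rate) / nrow(sub))
    expect_lt(abs(mean(sub$true_ase) - rate), 3 * se + 1e-9)
  }
})

test_that("zero ASE rates and zero hotspots produce a truth with no ASE", {
  dir <- withr::local_tempdir()
  p <- simulation_params(n_pairs = 2, base_ase_rate_normal = 0,
                         base_ase_rate_tumor = 0, n_hotspots = 0L,
                         n_driver_like_genes = 0L, n_somatic_per_tumor = 0L,
                         genome = data.frame(chrom = "chr1",
                                             length = 2000000L),
                         n_genes = 100L, rng_seed = 3L)
  co <- simulate_cohort(p, file.path(dir, "d"))
  expect_equal(sum(co$truth$site_truth$true_ase), 0)
})

test_that("non-ASE sites behave as exact binomial 0.5 draws (generator calibration)", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(
    simulation_params(n_pairs = 4, base_ase_rate_normal = 0,
                      base_ase_rate_tumor = 0, n_hotspots = 0L,
                      n_driver_like_genes = 0L, n_somatic_per_tumor = 0L,
                      genome = data.frame(chrom = "chr1", length = 3000000L),
                      n_genes = 150L, rng_seed = 17L),
    file.path(dir, "e"))
  sites <- do.call(rbind, lapply(seq_len(4), function(i)
    read_site_table(co$manifest$tumor_sites[i], "tumor", "x")))
  pvals <- mapply(function(x, n) binom.test(x, n, 0.5)$p.value,
                  sites$rna_ref, sites$rna_ref + sites$rna_alt)
  rej <- mean(pvals < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pvals))
  # exact binomial tests are conservative on discrete counts, so the
  # rejection rate sits at or below nominal
  expect_lt(rej, 0.05 + 3 * se)
  expect_gt(rej, 0.01)
})

test_that("planted hotspots contain tested SNVs in most pairs", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(file.path(dir, "f"), seed = 5L, n_pairs = 6L)
  hs <- co$truth$hotspots
  expect_equal(nrow(hs), 1)
  tr <- co$truth$site_truth
  in_hs <- tr$chrom == hs$chrom[1] & tr$pos > hs$start[1] &
    tr$pos <= hs$end[1] & tr$tissue == "tumor"
  per_pair <- table(tr$pair[in_hs])
  expect_gte(length(per_pair), 6)  # every pair carries tested hotspot SNVs
  # penetrance: hotspot sites are ASE in about 60% of site-pair draws
  expect_gt(mean(tr$true_ase[in_hs]), 0.45)
})

test_that("somatic truth respects the configured ASE and direction rates", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(simulation_params(n_pairs = 12, rng_seed = 23L),
                        file.path(dir, "g"))
  st <- co$truth$somatic_truth
  n <- nrow(st)
  expect_equal(n, 12 * 50)
  se_ase <- sqrt(0.375 * 0.625 / n)
  expect_lt(abs(mean(st$true_ase) - 0.375), 3 * se_ase)
  over <- st$true_direction[st$true_ase] == "over"
  se_over <- sqrt(0.78 * 0.22 / length(over))
  # direction is assigned per gene, so gene resampling widens the spread
  expect_lt(abs(mean(over) - 0.78), 5 * se_over)
})

test_that("unknown artifact kinds and oversized gene counts error", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(file.path(dir, "h"), seed = 1L, n_pairs = 2L)
  expect_error(inject_artifacts(co, "bogus"), "unknown artifact")
  expect_error(
    simulate_cohort(simulation_params(
      genome = data.frame(chrom = "chr1", length = 100000L),
      n_genes = 500L), file.path(dir, "i")),
    "too small")
})

test_that("injected low-coverage artifacts are below the DNA floor by construction", {
  dir <- withr::local_tempdir()
  co <- tiny_cohort(file.path(dir, "j"), seed = 2L, n_pairs = 2L)
  co <- inject_artifacts(co, "low_coverage", n = 10L)
  planted <- co$truth$must_be_filtered
  sites <- read_site_table(co$manifest$tumor_sites[1], "tumor", "x")
  rows <- sites[match(paste(planted$chrom, planted$pos),
                      paste(sites$chrom, sites$pos)), ]
  expect_true(all(rows$dna_ref + rows$dna_alt < 20))

  co <- inject_artifacts(co, "snv_cluster", n = 3L)
  cl <- co$truth$must_be_filtered
  cl <- cl[cl$reason == "cluster", ]
  expect_equal(nrow(cl) %% 3, 0)
})
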