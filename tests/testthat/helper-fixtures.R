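# Shared fixture builders. Everything is generated in code; no data
# files ship with the package.

make_sites <- function(pos, chrom = "chr1",
                       dna_ref = 30L, dna_alt = 30L,
                       rna_ref = 30L, rna_alt = 30L,
                       origin = "germline", sample_id = "S1",
                       tissue = "tumor", ref = "A", alt = "G") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             dna_ref = rep_len(as.integer(dna_ref), n),
             dna_alt = rep_len(as.integer(dna_alt), n),
             rna_ref = rep_len(as.integer(rna_ref), n),
             rna_alt = rep_len(as.integer(rna_alt), n),
             origin = rep_len(origin, n),
             sample_id = rep_len(sample_id, n),
             tissue = rep_len(tissue, n),
             stringsAsFactors = FALSE)
}

make_gene <- function(gene_id = "G1", chrom = "chr1", start = 100L,
                      end = 1000L, strand = "+", exons = NULL) {
  if (is.null(exons)) exons <- cbind(start = start, end = end)
  g <- data.frame(gene_id = gene_id, chrom = chrom,
                  start = as.integer(start), end = as.integer(end),
                  strand = strand, stringsAsFactors = FALSE)
  g$coding_intervals <- list(exons)
  g
}

# hand step-up BH computation, independent of stats::p.adjust
bh_by_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force LLR: binomial log-likelihood at the MLE minus at the null,
# evaluated with dbinom (independent of the package's closed form)
llr_brute <- function(x, n, p0) {
  phat <- x / n
  stats::dbinom(x, n, phat, log = TRUE) - stats::dbinom(x, n, p0, log = TRUE)
}

# small deterministic cohort for pipeline-level tests
tiny_cohort <- function(dir, seed = 42L, n_pairs = 4L) {
  simulate_cohort(
    simulation_params(n_pairs = n_pairs,
                      genome = data.frame(chrom = "chr1", length = 2000000L),
                      n_genes = 100L, n_hotspots = 1L,
                      n_driver_like_genes = 2L, n_somatic_per_tumor = 20L,
                      rng_seed = seed),
    dir)
}
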