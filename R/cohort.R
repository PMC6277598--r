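#' Summarize ASE in one tumor-normal pair
#'
#' Computes the per-tissue ASE fractions and the shared / tumor-only /
#' normal-only partition over SNV positions. In `"intersection"` mode
#' only positions testable in both tissues enter every statistic; in
#' `"all"` mode the per-tissue fractions use all tested positions of
#' that tissue while the partition still uses the common positions.
#' Direction concordance for shared ASEs compares the identity of the
#' over-expressed allele (ref vs alt).
#'
#' @param tumor_calls,normal_calls SNV call tables from
#'   [call_ase_snvs()] for the two tissues of one patient.
#' @param mode `"all"` or `"intersection"`.
#' @return one-row data.frame: `frac_ase_tumor`, `frac_ase_normal`,
#'   `n_tested_tumor`, `n_tested_normal`, `n_shared`, `n_tumor_only`,
#'   `n_normal_only`, `n_shared_same_direction`, `empty` flag.
#' @export
pair_summary <- function(tumor_calls, normal_calls,
                         mode = c("all", "intersection")) {
  mode <- match.arg(mode)
  tt <- tumor_calls[tumor_calls$testable, , drop = FALSE]
  nn <- normal_calls[normal_calls$testable, , drop = FALSE]
  key_t <- paste(tt$chrom, tt$pos, sep = ":")
  key_n <- paste(nn$chrom, nn$pos, sep = ":")
  common <- intersect(key_t, key_n)
  it <- match(common, key_t)
  im <- match(common, key_n)
  if (mode == "intersection") {
    if (length(common) == 0) {
      return(data.frame(frac_ase_tumor = NA_real_, frac_ase_normal = NA_real_,
                        n_tested_tumor = 0L, n_tested_normal = 0L,
                        n_shared = 0L, n_tumor_only = 0L, n_normal_only = 0L,
                        n_shared_same_direction = 0L, empty = TRUE))
    }
    frac_t <- mean(tt$is_ase[it])
    frac_n <- mean(nn$is_ase[im])
    n_tt <- length(common); n_tn <- length(common)
  } else {
    frac_t <- if (nrow(tt) > 0) mean(tt$is_ase) else NA_real_
    frac_n <- if (nrow(nn) > 0) mean(nn$is_ase) else NA_real_
    n_tt <- nrow(tt); n_tn <- nrow(nn)
  }
  ase_t <- common[tt$is_ase[it]]
  ase_n <- common[nn$is_ase[im]]
  shared <- intersect(ase_t, ase_n)
  same_dir <- 0L
  if (length(shared) > 0) {
    dt <- tt$direction[match(shared, key_t)]
    dn <- nn$direction[match(shared, key_n)]
    same_dir <- sum(dt == dn)
  }
  data.frame(frac_ase_tumor = frac_t, frac_ase_normal = frac_n,
             n_tested_tumor = n_tt, n_tested_normal = n_tn,
             n_shared = length(shared),
             n_tumor_only = length(setdiff(ase_t, ase_n)),
             n_normal_only = length(setdiff(ase_n, ase_t)),
             n_shared_same_direction = as.integer(same_dir),
             empty = FALSE)
}

#' Paired t-test of tumor vs normal ASE fractions
#'
#' Two-tailed paired t-test on the per-pair difference of ASE fractions
#' (tumor minus normal).
#'
#' @param summaries data.frame of pair summaries (one row per pair).
#' @return list with `statistic`, `p_value`, `mean_difference`, `df`.
#' @export
paired_fraction_test <- function(summaries) {
  x <- summaries$frac_ase_tumor
  y <- summaries$frac_ase_normal
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2) stop("need at least 2 pairs")
  tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = unname(tt$estimate), df = unname(tt$parameter))
}

#' Recurrently ASE genes in one tissue
#'
#' A gene is recurrent when it is called ASE in at least
#' `ceiling(threshold_fraction * N)` samples of the tissue, N being the
#' number of samples in which any gene was tested. Heterogeneity-excluded
#' gene calls do not count as ASE. Also returns the gene-by-sample
#' major-allele-ratio matrix of the recurrent genes.
#'
#' @param gene_calls pooled gene call table from [call_ase_genes()]
#'   (single tissue).
#' @param threshold_fraction recurrence threshold in (0, 1].
#' @return list: `genes` (data.frame `gene_id`, `n_ase_samples`,
#'   `n_samples`, `recurrent`), `ratio_matrix` (recurrent genes x
#'   samples).
#' @export
recurrence <- function(gene_calls, threshold_fraction = 0.20) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  n_samples <- length(unique(gene_calls$sample_id))
  need <- ceiling(threshold_fraction * n_samples)
  ase <- gene_calls[!is.na(gene_calls$is_ase) & gene_calls$is_ase, ,
                    drop = FALSE]
  counts <- table(ase$gene_id)
  genes <- data.frame(gene_id = names(counts),
                      n_ase_samples = as.integer(counts),
                      n_samples = n_samples,
                      recurrent = as.integer(counts) >= need,
                      stringsAsFactors = FALSE)
  rec <- genes$gene_id[genes$recurrent]
  ratio_matrix <- NULL
  if (length(rec) > 0) {
    sub <- gene_calls[gene_calls$gene_id %in% rec, , drop = FALSE]
    samples <- sort(unique(gene_calls$sample_id))
    ratio_matrix <- matrix(NA_real_, length(rec), length(samples),
                           dimnames = list(rec, samples))
    ratio_matrix[cbind(match(sub$gene_id, rec),
                       match(sub$sample_id, samples))] <- sub$gene_major_ratio
  }
  list(genes = genes, ratio_matrix = ratio_matrix)
}

#' Per-gene paired test of allele-ratio shift between tissues
#'
#' For genes ASE-testable in both tissues of at least `min_pairs` pairs,
#' runs a two-tailed paired t-test on the folded major-allele ratios
#' (tumor vs normal) and BH-adjusts across genes tested.
#'
#' @param gene_calls pooled gene call table over both tissues, with
#'   `patient_id` attached.
#' @param genes gene ids to test (default: all with enough pairs).
#' @param min_pairs minimum complete pairs (default 3).
#' @return data.frame `gene_id`, `n_pairs`, `mean_tumor`, `mean_normal`,
#'   `statistic`, `p_value`, `p_adj`, plus skipped genes with reason.
#' @export
allele_ratio_shift <- function(gene_calls, genes = NULL, min_pairs = 3L) {
  stopifnot("patient_id" %in% names(gene_calls))
  if (is.null(genes)) genes <- unique(gene_calls$gene_id)
  rows <- lapply(genes, function(g) {
    sub <- gene_calls[gene_calls$gene_id == g, , drop = FALSE]
    tum <- sub[sub$tissue == "tumor", ]
    nor <- sub[sub$tissue == "normal", ]
    common <- intersect(tum$patient_id, nor$patient_id)
    rt <- tum$gene_major_ratio[match(common, tum$patient_id)]
    rn <- nor$gene_major_ratio[match(common, nor$patient_id)]
    if (length(common) < min_pairs) {
      return(data.frame(gene_id = g, n_pairs = length(common),
                        mean_tumor = NA_real_, mean_normal = NA_real_,
                        statistic = NA_real_, p_value = NA_real_,
                        skipped = "insufficient_pairs",
                        stringsAsFactors = FALSE))
    }
    d <- rt - rn
    if (stats::sd(d) == 0) {
      # degenerate paired t (all differences equal): p = 1 iff identical
      pv <- if (all(d == 0)) 1.0 else NA_real_
      stat <- if (all(d == 0)) 0.0 else NA_real_
      skip <- if (all(d == 0)) NA_character_ else "constant_nonzero_difference"
    } else {
      tt <- stats::t.test(rt, rn, paired = TRUE)
      pv <- tt$p.value; stat <- unname(tt$statistic); skip <- NA_character_
    }
    data.frame(gene_id = g, n_pairs = length(common),
               mean_tumor = mean(rt), mean_normal = mean(rn),
               statistic = stat, p_value = pv, skipped = skip,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  ok <- !is.na(res$p_value)
  res$p_adj[ok] <- bh_adjust(res$p_value[ok])
  res
}

#' Upper-tail Poisson probability P[X >= x]
#'
#' @param x observed count (vectorized).
#' @param lambda Poisson mean (vectorized).
#' @return P[X >= x]; 1 when x <= 0.
#' @export
poisson_upper_tail <- function(x, lambda) {
  stopifnot(all(lambda >= 0))
  ifelse(x <= 0, 1, stats::ppois(x - 1, lambda, lower.tail = FALSE))
}

#' Poisson test for tumor-specific ("somatic") ASE genes
#'
#' For each gene, s_i counts the pairs in which the gene is ASE in the
#' tumor and not in the matched normal, and t_i counts the pairs in
#' which the gene is ASE-testable in both tissues (>= 1 passing SNV in
#' each, not heterogeneity-excluded in either). The cohort-wide expected
#' event rate is f = sum(s_i) / sum(t_i) over all genes, the per-gene
#' expectation is lambda_i = f * t_i, and the p-value is the Poisson
#' upper tail P[X >= s_i]. BH correction flags genes at adjusted
#' p < `bh_alpha`.
#'
#' @param gene_calls pooled gene call table over both tissues with
#'   `patient_id` attached.
#' @param bh_alpha significance level on adjusted p (default 0.05).
#' @return data.frame `gene_id`, `s_i`, `t_i`, `f`, `lambda_i`,
#'   `p_poisson`, `p_adj`, `is_somatic_ase`.
#' @export
somatic_ase_gene_test <- function(gene_calls, bh_alpha = 0.05) {
  stopifnot("patient_id" %in% names(gene_calls))
  usable <- gene_calls[!is.na(gene_calls$is_ase), , drop = FALSE]
  tum <- usable[usable$tissue == "tumor", ]
  nor <- usable[usable$tissue == "normal", ]
  key_t <- paste(tum$gene_id, tum$patient_id, sep = "\r")
  key_n <- paste(nor$gene_id, nor$patient_id, sep = "\r")
  common <- intersect(key_t, key_n)
  if (length(common) == 0) stop("no gene tested in both tissues of any pair")
  gene_of <- tum$gene_id[match(common, key_t)]
  ase_t <- tum$is_ase[match(common, key_t)]
  ase_n <- nor$is_ase[match(common, key_n)]
  event <- ase_t & !ase_n
  s_i <- tapply(event, gene_of, sum)
  t_i <- tapply(event, gene_of, length)
  f <- sum(s_i) / sum(t_i)
  lambda_i <- f * t_i
  p <- poisson_upper_tail(as.numeric(s_i), as.numeric(lambda_i))
  p_adj <- bh_adjust(p)
  data.frame(gene_id = names(s_i), s_i = as.integer(s_i),
             t_i = as.integer(t_i), f = f,
             lambda_i = as.numeric(lambda_i),
             p_poisson = as.numeric(p), p_adj = p_adj,
             is_somatic_ase = p_adj < bh_alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-list enrichment by Fisher's exact test
#'
#' Tests whether `query_genes` are enriched for `reference_list` within
#' `universe`: a 2x2 table of query x reference membership, a one-sided
#' (enrichment) Fisher exact p by default, and the sample odds ratio
#' (ad/bc).
#'
#' @param query_genes,reference_list,universe character vectors;
#'   query and reference are intersected with the universe.
#' @param alternative `"greater"` (enrichment, default) or
#'   `"two.sided"`.
#' @return list: `table`, `odds_ratio`, `p_value`, `n_overlap`.
#' @export
enrichment <- function(query_genes, reference_list, universe,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  q <- universe %in% query_genes
  r <- universe %in% reference_list
  tab <- matrix(c(sum(q & r), sum(q & !r), sum(!q & r), sum(!q & !r)),
                2, 2, byrow = TRUE,
                dimnames = list(query = c("in", "out"),
                                reference = c("in", "out")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * cc)
  list(table = tab, odds_ratio = or, p_value = ft$p.value,
       n_overlap = a)
}

#' Compare expression ratios of hotspot gene groups
#'
#' Kruskal-Wallis rank test of the tumor/normal FPKM ratio across
#' hotspot gene groups (shared / tumor-only / normal-only). Empty groups
#' are dropped with a warning.
#'
#' @param groups named list of numeric vectors of FPKM ratios.
#' @return list: `statistic` (H), `df`, `p_value`, `group_sizes`.
#' @export
hotspot_expression_compare <- function(groups) {
  sizes <- vapply(groups, length, 0L)
  if (any(sizes == 0)) {
    warning("dropping empty group(s): ",
            paste(names(groups)[sizes == 0], collapse = ", "))
    groups <- groups[sizes > 0]
  }
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value,
       group_sizes = vapply(groups, length, 0L))
}
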