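#' Allelic expression of somatic mutations
#'
#' Tests each somatic mutation for allele-specific expression with the
#' same DNA-controlled LLR as germline sites: the null RNA mutant-allele
#' fraction is the DNA mutant fraction, which absorbs purity and local
#' copy number. For ASE mutations the direction is `over` when the RNA
#' mutant fraction exceeds the DNA mutant fraction, else `under`.
#'
#' @param somatic_sites site data.frame with `origin == "somatic"`; the
#'   alternate allele is the mutant allele.
#' @param config [pipeline_config()].
#' @return data.frame with `mutant_rna_fraction`, `mutant_dna_fraction`,
#'   `llr`, `testable`, `is_ase`, `mutant_direction` (NA unless ASE).
#' @export
call_somatic_ase <- function(somatic_sites, config = pipeline_config()) {
  validate_sites(somatic_sites)
  stopifnot(all(somatic_sites$origin == "somatic"))
  llr <- snv_llr(somatic_sites$rna_ref, somatic_sites$rna_alt,
                 somatic_sites$dna_ref, somatic_sites$dna_alt)
  cutoff <- llr_cutoff(config$alpha_snv)
  n_rna <- somatic_sites$rna_ref + somatic_sites$rna_alt
  n_dna <- somatic_sites$dna_ref + somatic_sites$dna_alt
  testable <- !is.na(llr) & n_rna > 0
  is_ase <- testable & llr > cutoff
  mut_rna <- ifelse(n_rna > 0, somatic_sites$rna_alt / n_rna, NA_real_)
  mut_dna <- ifelse(n_dna > 0, somatic_sites$dna_alt / n_dna, NA_real_)
  direction <- ifelse(is_ase,
                      ifelse(mut_rna > mut_dna, "over", "under"),
                      NA_character_)
  data.frame(
    chrom = somatic_sites$chrom, pos = somatic_sites$pos,
    sample_id = somatic_sites$sample_id,
    mutant_rna_fraction = mut_rna, mutant_dna_fraction = mut_dna,
    llr = llr, cutoff = cutoff, testable = testable, is_ase = is_ase,
    mutant_direction = direction, stringsAsFactors = FALSE
  )
}

#' Classify tumor/normal expression change
#'
#' Fold-change classification of a gene's expression in the tumor against
#' the matched normal: `up` iff fpkm_t >= fold_up * fpkm_n, `down` iff
#' fpkm_t <= fold_down * fpkm_n, otherwise `unchanged` (thresholds
#' inclusive; both values zero gives `unchanged`). Vectorized.
#'
#' @param fpkm_t,fpkm_n non-negative FPKM in tumor and matched normal.
#' @param fold_up,fold_down ratio thresholds (defaults 2 and 1/2).
#' @return character vector in `{"up", "unchanged", "down"}`.
#' @export
classify_expression <- function(fpkm_t, fpkm_n, fold_up = 2, fold_down = 0.5) {
  if (any(fpkm_t < 0) || any(fpkm_n < 0)) stop("FPKM must be non-negative")
  out <- rep("unchanged", length(fpkm_t))
  both_zero <- fpkm_t == 0 & fpkm_n == 0
  out[!both_zero & fpkm_t >= fold_up * fpkm_n] <- "up"
  out[!both_zero & fpkm_t <= fold_down * fpkm_n] <- "down"
  out
}

#' Assign mutation-bearing genes to the six direction-by-expression groups
#'
#' Genes carrying ASE somatic mutations are split by mutant-allele
#' direction (over- vs under-expressed) and by the tumor/normal
#' expression class of the mutation carrier, yielding six groups:
#' a = (over, up), b = (over, unchanged), c = (over, down),
#' d = (under, up), e = (under, unchanged), f = (under, down).
#' Genes whose ASE mutations disagree in direction are excluded. When a
#' gene's mutations occur in several patients, the expression class is
#' the majority class over carriers, ties resolving to `unchanged`.
#'
#' @param calls output of [call_somatic_ase()].
#' @param gene_models gene model data.frame used to map mutations to
#'   genes.
#' @param fpkm FPKM table (`gene_id`, `sample_id`, `fpkm`).
#' @param manifest cohort manifest (matches tumor to normal sample ids).
#' @param config [pipeline_config()].
#' @return data.frame: `gene_id`, `direction`, `expression_class`,
#'   `group` (a-f or NA), `fpkm_tumor`, `fpkm_normal`,
#'   `excluded_conflicting`.
#' @export
assign_groups <- function(calls, gene_models, fpkm, manifest,
                          config = pipeline_config()) {
  ase <- calls[calls$is_ase, , drop = FALSE]
  empty <- data.frame(gene_id = character(), direction = character(),
                      expression_class = character(), group = character(),
                      fpkm_tumor = numeric(), fpkm_normal = numeric(),
                      excluded_conflicting = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(ase) == 0) return(empty)
  gene_idx <- assign_sites_to_genes(ase, gene_models)
  ase <- ase[!is.na(gene_idx), , drop = FALSE]
  gene_idx <- gene_idx[!is.na(gene_idx)]
  if (nrow(ase) == 0) return(empty)
  ase$gene_id <- gene_models$gene_id[gene_idx]
  normal_of <- stats::setNames(manifest$normal_sample_id,
                               manifest$tumor_sample_id)
  fkey <- paste(fpkm$gene_id, fpkm$sample_id, sep = "\r")
  lookup_fpkm <- function(gene, sample) {
    v <- fpkm$fpkm[match(paste(gene, sample, sep = "\r"), fkey)]
    v
  }
  out <- lapply(split(seq_len(nrow(ase)), ase$gene_id), function(ii) {
    gene <- ase$gene_id[ii[1]]
    dirs <- unique(ase$mutant_direction[ii])
    conflicting <- length(dirs) > 1
    carriers <- unique(ase$sample_id[ii])
    ft <- lookup_fpkm(gene, carriers)
    fn <- lookup_fpkm(gene, normal_of[carriers])
    ok <- !is.na(ft) & !is.na(fn)
    if (!any(ok)) {
      warning("gene ", gene, " absent from expression table; skipped")
      return(NULL)
    }
    cls <- classify_expression(ft[ok], fn[ok], config$fold_up, config$fold_down)
    tab <- table(factor(cls, levels = c("up", "unchanged", "down")))
    expr_class <- if (max(tab) > 0 && sum(tab == max(tab)) == 1) {
      names(tab)[which.max(tab)]
    } else "unchanged"
    grp <- if (conflicting) NA_character_ else {
      key <- paste(dirs, expr_class)
      c("over up" = "a", "over unchanged" = "b", "over down" = "c",
        "under up" = "d", "under unchanged" = "e", "under down" = "f")[key]
    }
    data.frame(gene_id = gene,
               direction = if (conflicting) NA_character_ else dirs,
               expression_class = expr_class,
               group = unname(grp),
               fpkm_tumor = mean(ft[ok]), fpkm_normal = mean(fn[ok]),
               excluded_conflicting = conflicting,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}
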