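#' Pipeline configuration
#'
#' Collects the tunable constants of the ASE pipeline in one validated list.
#' Defaults follow common practice for DNA-controlled ASE calling in bulk
#' cohorts: an LLR significance level of 0.01, a coverage floor of 10 reads
#' in both RNA and DNA at the ASE stage, a 20-read DNA floor at the variant
#' QC stage, a heterogeneity exclusion at p < 0.05, a 100 kb window with
#' 10 kb step and 1000 label permutations for the hotspot scan, FPKM fold
#' thresholds of 2 and 1/2, a 20% recurrence fraction and BH FDR 0.05.
#'
#' @param alpha_snv significance level calibrating the LLR cutoff.
#' @param min_rna_cov,min_dna_cov ASE-stage coverage floors (reads).
#' @param min_dna_reads variant-QC DNA coverage floor (reads).
#' @param cluster_window_bp,cluster_min_count SNV cluster filter: remove runs
#'   of at least `cluster_min_count` SNVs spanning at most `cluster_window_bp`.
#' @param het_p_cutoff genes with SNV-heterogeneity p below this are excluded.
#' @param window_size,step_size,n_permutations hotspot scan geometry and
#'   permutation count.
#' @param hotspot_count_mode `"events"` counts per-sample ASE events in each
#'   window; `"positions"` collapses samples so a position counts once if ASE
#'   in any sample.
#' @param fold_up,fold_down FPKM tumor/normal ratio thresholds for the
#'   up/down expression classes (inclusive).
#' @param recurrence_fraction minimum fraction of samples for a gene to be
#'   called recurrently ASE.
#' @param bh_alpha BH-adjusted significance level for hotspot windows and
#'   somatic ASE genes.
#' @param rng_seed integer seed used by stochastic stages.
#' @return A validated list of class `"ase_config"`.
#' @export
pipeline_config <- function(alpha_snv = 0.01,
                            min_rna_cov = 10L,
                            min_dna_cov = 10L,
                            min_dna_reads = 20L,
                            cluster_window_bp = 35L,
                            cluster_min_count = 3L,
                            het_p_cutoff = 0.05,
                            window_size = 100000L,
                            step_size = 10000L,
                            n_permutations = 1000L,
                            hotspot_count_mode = c("events", "positions"),
                            fold_up = 2.0,
                            fold_down = 0.5,
                            recurrence_fraction = 0.20,
                            bh_alpha = 0.05,
                            rng_seed = 1L) {
  hotspot_count_mode <- match.arg(hotspot_count_mode)
  stopifnot(
    alpha_snv > 0, alpha_snv < 1,
    min_rna_cov >= 0, min_dna_cov >= 0, min_dna_reads >= 0,
    cluster_window_bp >= 1, cluster_min_count >= 2,
    het_p_cutoff > 0, het_p_cutoff < 1,
    window_size >= 1, step_size >= 1, step_size <= window_size,
    n_permutations >= 1,
    fold_up > 0, fold_down > 0, fold_down <= fold_up,
    recurrence_fraction > 0, recurrence_fraction <= 1,
    bh_alpha > 0, bh_alpha < 1
  )
  structure(list(
    alpha_snv = alpha_snv,
    min_rna_cov = as.integer(min_rna_cov),
    min_dna_cov = as.integer(min_dna_cov),
    min_dna_reads = as.integer(min_dna_reads),
    cluster_window_bp = as.integer(cluster_window_bp),
    cluster_min_count = as.integer(cluster_min_count),
    het_p_cutoff = het_p_cutoff,
    window_size = as.integer(window_size),
    step_size = as.integer(step_size),
    n_permutations = as.integer(n_permutations),
    hotspot_count_mode = hotspot_count_mode,
    fold_up = fold_up,
    fold_down = fold_down,
    recurrence_fraction = recurrence_fraction,
    bh_alpha = bh_alpha,
    rng_seed = as.integer(rng_seed)
  ), class = "ase_config")
}

SITE_COLUMNS <- c("chrom", "pos", "ref", "alt",
                  "dna_ref", "dna_alt", "rna_ref", "rna_alt", "origin")

#' Validate a site table
#'
#' A site table is a data.frame with one row per bi-allelic site in one
#' sample: `chrom`, `pos` (1-based), `ref`, `alt` (single bases),
#' `dna_ref`, `dna_alt`, `rna_ref`, `rna_alt` (non-negative read counts),
#' `origin` (`"germline"` or `"somatic"`), plus `sample_id` and `tissue`
#' labels attached by the reader.
#'
#' @param sites data.frame of sites.
#' @return `sites` invisibly; stops with an informative message otherwise.
#' @export
validate_sites <- function(sites) {
  missing_cols <- setdiff(SITE_COLUMNS, names(sites))
  if (length(missing_cols) > 0) {
    stop("site table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  counts <- c("dna_ref", "dna_alt", "rna_ref", "rna_alt")
  for (cc in counts) {
    bad <- which(!is.finite(sites[[cc]]) | sites[[cc]] < 0)
    if (length(bad) > 0) {
      stop("negative or non-finite count in column '", cc,
           "' at line ", bad[1] + 1L, " (row ", bad[1], ")")
    }
  }
  bad_pos <- which(sites$pos < 1)
  if (length(bad_pos) > 0) {
    stop("position < 1 at row ", bad_pos[1])
  }
  bad_allele <- which(sites$ref == sites$alt)
  if (length(bad_allele) > 0) {
    stop("ref equals alt at row ", bad_allele[1])
  }
  bad_origin <- which(!sites$origin %in% c("germline", "somatic"))
  if (length(bad_origin) > 0) {
    stop("origin must be 'germline' or 'somatic' (row ", bad_origin[1], ")")
  }
  invisible(sites)
}

#' Validate a gene model table
#'
#' Gene models are stored as a data.frame with columns `gene_id`, `chrom`,
#' `start`, `end` (0-based half-open), `strand`, and a list-column
#' `coding_intervals` of two-column matrices (0-based half-open exon spans,
#' sorted and non-overlapping, contained in `[start, end)`).
#'
#' @param genes gene model data.frame.
#' @return `genes` invisibly.
#' @export
validate_gene_models <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand",
                  "coding_intervals") %in% names(genes)))
  if (any(genes$start >= genes$end)) {
    stop("gene with start >= end: ",
         genes$gene_id[which(genes$start >= genes$end)[1]])
  }
  for (i in seq_len(nrow(genes))) {
    iv <- genes$coding_intervals[[i]]
    if (is.null(iv) || nrow(iv) == 0) next
    if (any(iv[, 1] >= iv[, 2])) {
      stop("empty or inverted coding interval in gene ", genes$gene_id[i])
    }
    if (is.unsorted(iv[, 1], strictly = TRUE) && nrow(iv) > 1) {
      stop("coding intervals not sorted in gene ", genes$gene_id[i])
    }
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      stop("overlapping coding intervals in gene ", genes$gene_id[i])
    }
    if (iv[1, 1] < genes$start[i] || iv[nrow(iv), 2] > genes$end[i]) {
      stop("coding interval outside gene span in gene ", genes$gene_id[i])
    }
  }
  invisible(genes)
}

#' Validate a cohort manifest
#'
#' A manifest pairs tumor and normal sample identifiers per patient and
#' records the per-sample file paths for site tables and the cohort FPKM
#' table. Columns: `patient_id`, `tumor_sample_id`, `normal_sample_id`,
#' `tumor_sites`, `normal_sites`; attribute `fpkm_path` holds the FPKM file.
#'
#' @param manifest manifest data.frame.
#' @return `manifest` invisibly.
#' @export
validate_manifest <- function(manifest) {
  need <- c("patient_id", "tumor_sample_id", "normal_sample_id",
            "tumor_sites", "normal_sites")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols) > 0) {
    stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(manifest) == 0) stop("empty cohort: manifest has no pairs")
  ids <- c(manifest$tumor_sample_id, manifest$normal_sample_id)
  if (anyDuplicated(ids)) stop("sample ids in manifest are not unique")
  invisible(manifest)
}
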