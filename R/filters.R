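#' Filter reports
#'
#' Every filter returns a report with one row per input site carrying the
#' disposition: `kept = TRUE`, or `kept = FALSE` with a `reason` from the
#' closed set `cluster`, `dna_coverage`, `repeat`, `noncoding`,
#' `somatic_overlap`, `ase_coverage`. Reports from successive filters
#' compose with [combine_reports()]: a site is kept only if every filter
#' kept it, and the first filter (in application order) that removed it
#' supplies the reason.
#'
#' @name filter_report
NULL

FILTER_REASONS <- c("cluster", "dna_coverage", "repeat", "noncoding",
                    "somatic_overlap", "ase_coverage")

new_filter_report <- function(sites, kept, reason) {
  stopifnot(length(kept) == nrow(sites))
  reason <- ifelse(kept, NA_character_, reason)
  if (any(!is.na(reason) & !reason %in% FILTER_REASONS)) {
    stop("unknown filter reason")
  }
  data.frame(chrom = sites$chrom, pos = sites$pos,
             sample_id = sites$sample_id,
             kept = kept, reason = reason, stringsAsFactors = FALSE)
}

#' @rdname filter_report
#' @param ... filter reports over the same sites in application order.
#' @return combined report.
#' @export
combine_reports <- function(...) {
  reports <- list(...)
  out <- reports[[1]]
  for (r in reports[-1]) {
    stopifnot(nrow(r) == nrow(out))
    newly_removed <- out$kept & !r$kept
    out$reason[newly_removed] <- r$reason[newly_removed]
    out$kept <- out$kept & r$kept
  }
  out
}

#' Remove clustered SNVs
#'
#' Clustered SNVs are a classic alignment-artifact signature: any site
#' belonging to a run of at least `min_count` SNVs spanning at most
#' `window_bp` (first to last, inclusive) is removed. Input must already
#' be sorted by (chrom, pos); the filter refuses to sort silently.
#'
#' @param sites site data.frame sorted by (chrom, pos) within sample.
#' @param window_bp span threshold in bp (default 35).
#' @param min_count minimum run length (default 3).
#' @return a filter report (reason `"cluster"`).
#' @export
filter_cluster <- function(sites, window_bp = 35L, min_count = 3L) {
  n <- nrow(sites)
  if (n == 0) return(new_filter_report(sites, logical(0), "cluster"))
  ord_ok <- !is.unsorted(order(sites$chrom, sites$pos)) &&
    all(diff(order(sites$chrom, sites$pos)) == 1)
  if (!ord_ok) stop("sites must be sorted by (chrom, pos)")
  removed <- logical(n)
  if (n >= min_count) {
    for (i in seq_len(n - min_count + 1)) {
      j <- i + min_count - 1L
      if (sites$chrom[i] == sites$chrom[j] &&
          sites$pos[j] - sites$pos[i] + 1L <= window_bp) {
        removed[i:j] <- TRUE
      }
    }
  }
  new_filter_report(sites, !removed, "cluster")
}

#' Remove SNVs with insufficient DNA coverage
#'
#' @param sites site data.frame.
#' @param min_reads strict floor: removed iff dna_ref + dna_alt <
#'   `min_reads` (default 20).
#' @return a filter report (reason `"dna_coverage"`).
#' @export
filter_dna_coverage <- function(sites, min_reads = 20L) {
  kept <- (sites$dna_ref + sites$dna_alt) >= min_reads
  new_filter_report(sites, kept, "dna_coverage")
}

#' Remove SNVs in repeat regions or outside coding regions
#'
#' A site is removed with reason `"repeat"` if it falls inside any mask
#' interval, otherwise with reason `"noncoding"` if it falls outside all
#' coding intervals of all genes; repeat takes precedence. Mask and exon
#' coordinates are 0-based half-open; a 1-based site at pos p is inside
#' [s, e) iff s < p <= e.
#'
#' @param sites site data.frame.
#' @param repeat_mask data.frame `chrom`, `start`, `end` (0-based
#'   half-open, sorted).
#' @param gene_models gene model data.frame.
#' @return a filter report.
#' @export
filter_regions <- function(sites, repeat_mask, gene_models) {
  n <- nrow(sites)
  if (n == 0) return(new_filter_report(sites, logical(0), "repeat"))
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  in_repeat <- rep(FALSE, n)
  if (nrow(repeat_mask) > 0) {
    mask_gr <- GenomicRanges::GRanges(
      repeat_mask$chrom,
      IRanges::IRanges(repeat_mask$start + 1L, repeat_mask$end))
    in_repeat <- GenomicRanges::countOverlaps(site_gr, mask_gr) > 0
  }
  n_exons <- vapply(gene_models$coding_intervals,
                    function(iv) if (is.null(iv)) 0L else nrow(iv), 0L)
  in_coding <- rep(FALSE, n)
  if (sum(n_exons) > 0) {
    exon_gr <- GenomicRanges::GRanges(
      rep(gene_models$chrom, n_exons),
      IRanges::IRanges(
        unlist(lapply(gene_models$coding_intervals,
                      function(iv) iv[, 1])) + 1L,
        unlist(lapply(gene_models$coding_intervals,
                      function(iv) iv[, 2]))))
    in_coding <- GenomicRanges::countOverlaps(site_gr, exon_gr) > 0
  }
  reason <- ifelse(in_repeat, "repeat", "noncoding")
  kept <- !in_repeat & in_coding
  rep_df <- new_filter_report(sites, kept, "noncoding")
  rep_df$reason[!kept] <- reason[!kept]
  rep_df
}

#' Remove germline SNVs that coincide with somatic mutations
#'
#' A putative germline site that was also called somatic in the exome
#' data is unreliable and removed. Matching requires chrom, position and
#' the alternate allele by default; `match_alt = FALSE` matches on
#' position alone.
#'
#' @param sites site data.frame.
#' @param somatic_positions data.frame `chrom`, `pos`, `alt` of somatic
#'   calls.
#' @param match_alt require the alt allele to match (default TRUE).
#' @return a filter report (reason `"somatic_overlap"`).
#' @export
filter_somatic_overlap <- function(sites, somatic_positions, match_alt = TRUE) {
  if (nrow(somatic_positions) == 0) {
    return(new_filter_report(sites, rep(TRUE, nrow(sites)), "somatic_overlap"))
  }
  if (match_alt) {
    key_site <- paste(sites$chrom, sites$pos, sites$alt, sep = ":")
    key_som <- paste(somatic_positions$chrom, somatic_positions$pos,
                     somatic_positions$alt, sep = ":")
  } else {
    key_site <- paste(sites$chrom, sites$pos, sep = ":")
    key_som <- paste(somatic_positions$chrom, somatic_positions$pos, sep = ":")
  }
  hit <- key_site %in% key_som & sites$origin == "germline"
  new_filter_report(sites, !hit, "somatic_overlap")
}

#' Remove sites below the ASE-stage coverage floor
#'
#' @param sites site data.frame.
#' @param min_cov strict floor (default 10): removed iff RNA depth or DNA
#'   depth is below it.
#' @return a filter report (reason `"ase_coverage"`).
#' @export
filter_ase_coverage <- function(sites, min_cov = 10L) {
  kept <- (sites$rna_ref + sites$rna_alt) >= min_cov &
    (sites$dna_ref + sites$dna_alt) >= min_cov
  new_filter_report(sites, kept, "ase_coverage")
}

#' Apply the full germline filter chain
#'
#' Order: cluster, DNA coverage, repeat/noncoding, somatic overlap, then
#' the ASE-stage coverage floor. Only rows with `origin == "germline"`
#' are subject to the cluster and somatic-overlap criteria; all rows pass
#' through the coverage and region criteria.
#'
#' @param sites site data.frame sorted by (chrom, pos).
#' @param repeat_mask BED3 data.frame.
#' @param gene_models gene model data.frame.
#' @param somatic_positions somatic call positions (may be empty).
#' @param config [pipeline_config()].
#' @return list with `kept` (the surviving site rows) and `report`
#'   (combined filter report).
#' @export
apply_site_filters <- function(sites, repeat_mask, gene_models,
                               somatic_positions, config = pipeline_config()) {
  validate_sites(sites)
  r1 <- filter_cluster(sites, config$cluster_window_bp, config$cluster_min_count)
  # cluster criterion is a germline-list QC step; somatic rows exempt
  r1$kept[sites$origin == "somatic"] <- TRUE
  r1$reason[sites$origin == "somatic"] <- NA_character_
  r2 <- filter_dna_coverage(sites, config$min_dna_reads)
  r3 <- filter_regions(sites, repeat_mask, gene_models)
  r4 <- filter_somatic_overlap(sites, somatic_positions)
  r5 <- filter_ase_coverage(sites, min_cov = min(config$min_rna_cov,
                                                 config$min_dna_cov))
  r5$kept <- (sites$rna_ref + sites$rna_alt) >= config$min_rna_cov &
    (sites$dna_ref + sites$dna_alt) >= config$min_dna_cov
  r5$reason <- ifelse(r5$kept, NA_character_, "ase_coverage")
  report <- combine_reports(r1, r2, r3, r4, r5)
  list(kept = sites[report$kept, , drop = FALSE], report = report)
}
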