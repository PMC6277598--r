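#' Sliding windows over a genome
#'
#' Windows start at 0, step, 2*step, ... on each chromosome; the last
#' windows are truncated at the chromosome end, so every base is covered
#' by at least one window. Coordinates are 0-based half-open.
#'
#' @param genome data.frame with `chrom` and `length` (bp).
#' @param window_size,step_size window geometry, `step_size <=
#'   window_size`.
#' @return data.frame `chrom`, `start`, `end`.
#' @export
make_windows <- function(genome, window_size, step_size) {
  if (window_size < 1 || step_size < 1) stop("window and step must be positive")
  if (step_size > window_size) stop("step_size must not exceed window_size")
  out <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq.int(0L, max(0L, len - 1L), by = step_size)
    starts <- starts[starts < len]
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Permutation scan for ASE hotspots
#'
#' Counts ASE-labelled sites in each sliding window and compares against
#' a null obtained by shuffling the observed label multiset over all
#' tested site positions genome-wide, preserving the total ASE count
#' (label-permutation null). The empirical p-value per window uses
#' add-one smoothing, p = (k + 1) / (R + 1) with k the number of
#' permutations whose window count reaches the observed count, so p is
#' never zero and its minimum is 1/(R+1). BH adjustment is applied across
#' all windows with at least one tested site.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based) and logical
#'   `is_ase`; one row per counting unit (a per-sample event, or a
#'   collapsed position).
#' @param windows window data.frame from [make_windows()].
#' @param n_permutations number of label permutations R.
#' @param mode `"shuffle"` permutes the fixed label multiset (default);
#'   `"bernoulli"` draws labels independently at the global ASE rate.
#' @return data.frame of windows with `n_tested`, `n_ase`,
#'   `exceed_count`, `p_emp`, `p_adj`.
#' @export
permutation_scan <- function(sites, windows, n_permutations = 1000L,
                             mode = c("shuffle", "bernoulli")) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("need at least one permutation")
  if (nrow(sites) == 0) stop("zero tested sites")
  stopifnot(is.logical(sites$is_ase))
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  n_sites <- nrow(sites)
  labels <- sites$is_ase
  m <- sum(labels)

  # windows never span chromosomes, and sites are sorted by (chrom, pos),
  # so each window maps to a contiguous index range [lo+1, hi]; counts are
  # then differences of a cumulative sum, making each permutation O(n).
  lo <- integer(nrow(windows))
  hi <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(sites$chrom == ch)
    if (length(si) == 0) { lo[wi] <- 0L; hi[wi] <- 0L; next }
    pos <- sites$pos[si]
    off <- si[1] - 1L
    # 1-based pos p inside [start, end) iff start < p <= end
    lo[wi] <- off + findInterval(windows$start[wi], pos)
    hi[wi] <- off + findInterval(windows$end[wi], pos)
  }
  count_in_windows <- function(lab) {
    cs <- c(0, cumsum(lab))
    cs[hi + 1L] - cs[lo + 1L]
  }
  n_tested <- as.integer(hi - lo)
  obs <- count_in_windows(labels)
  exceed <- integer(nrow(windows))
  for (r in seq_len(n_permutations)) {
    lab <- if (mode == "shuffle") {
      labels[sample.int(n_sites)]
    } else {
      stats::runif(n_sites) < m / n_sites
    }
    exceed <- exceed + (count_in_windows(lab) >= obs)
  }
  p_emp <- (exceed + 1) / (n_permutations + 1)
  res <- cbind(windows,
               data.frame(n_tested = n_tested, n_ase = as.integer(obs),
                          exceed_count = exceed, p_emp = p_emp))
  res$p_adj <- NA_real_
  tested <- res$n_tested > 0
  res$p_adj[tested] <- bh_adjust(res$p_emp[tested])
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' preserved. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param pvalues numeric vector with values in (0, 1].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Merge significant windows into focal hotspot regions
#'
#' Overlapping (or at most `max_gap`-separated) significant windows on
#' the same chromosome merge into one region spanning [min start,
#' max end). Each region is annotated with the gene models it overlaps
#' and carries the smallest adjusted p of its member windows.
#'
#' @param results scan results from [permutation_scan()].
#' @param gene_models gene model data.frame (optional).
#' @param bh_alpha significance level on `p_adj` (default 0.05).
#' @param max_gap maximum separation in bp for merging (default 0:
#'   overlapping or book-ended windows only).
#' @return data.frame `chrom`, `start`, `end`, `n_windows`, `p_adj`,
#'   `genes` (comma-separated ids).
#' @export
merge_hotspots <- function(results, gene_models = NULL, bh_alpha = 0.05,
                           max_gap = 0L) {
  sig <- results[!is.na(results$p_adj) & results$p_adj < bh_alpha, ,
                 drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      p_adj = numeric(), genes = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sig) == 0) return(empty)
  gr <- GenomicRanges::GRanges(sig$chrom,
                               IRanges::IRanges(sig$start + 1L, sig$end))
  merged <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  region_of <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged),
    n_windows = as.integer(table(factor(region_of,
                                        levels = seq_along(merged)))),
    p_adj = as.numeric(tapply(sig$p_adj, region_of, min)),
    stringsAsFactors = FALSE)
  out$genes <- ""
  if (!is.null(gene_models) && nrow(gene_models) > 0) {
    gene_gr <- GenomicRanges::GRanges(
      gene_models$chrom,
      IRanges::IRanges(gene_models$start + 1L, gene_models$end))
    gh <- GenomicRanges::findOverlaps(merged, gene_gr)
    gl <- split(gene_models$gene_id[S4Vectors::subjectHits(gh)],
                factor(S4Vectors::queryHits(gh), levels = seq_along(merged)))
    out$genes <- vapply(gl, paste, "", collapse = ",")
  }
  out
}

#' Hotspot detection from SNV-level ASE calls
#'
#' Convenience wrapper: pools SNV calls of one tissue across samples,
#' builds the counting units according to `config$hotspot_count_mode`
#' (`"events"` keeps one unit per sample-site; `"positions"` collapses to
#' distinct positions labelled ASE when ASE in any sample), scans, and
#' merges significant windows.
#'
#' @param snv_calls output of [call_ase_snvs()] pooled over samples
#'   (single tissue).
#' @param genome data.frame `chrom`, `length`.
#' @param gene_models gene model data.frame (optional).
#' @param config [pipeline_config()].
#' @return list with `windows` (scan table) and `hotspots` (merged).
#' @export
detect_hotspots <- function(snv_calls, genome, gene_models = NULL,
                            config = pipeline_config()) {
  calls <- snv_calls[snv_calls$testable, , drop = FALSE]
  if (config$hotspot_count_mode == "positions") {
    key <- paste(calls$chrom, calls$pos, sep = ":")
    agg <- stats::aggregate(calls$is_ase, by = list(key = key), FUN = any)
    first <- !duplicated(key)
    sites <- data.frame(chrom = calls$chrom[first], pos = calls$pos[first],
                        stringsAsFactors = FALSE)
    sites$is_ase <- agg$x[match(paste(sites$chrom, sites$pos, sep = ":"),
                                agg$key)]
  } else {
    sites <- data.frame(chrom = calls$chrom, pos = calls$pos,
                        is_ase = calls$is_ase, stringsAsFactors = FALSE)
  }
  windows <- make_windows(genome, config$window_size, config$step_size)
  scan <- permutation_scan(sites, windows, config$n_permutations)
  hotspots <- merge_hotspots(scan, gene_models, config$bh_alpha)
  list(windows = scan, hotspots = hotspots)
}
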