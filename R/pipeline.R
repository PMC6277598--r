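#' Run the full ASE pipeline on a cohort
#'
#' Chains the stages end to end for every tumor-normal pair: site QC
#' filters, SNV- and gene-level DNA-controlled ASE calls, per-tissue
#' hotspot scans, somatic-mutation ASE calls and six-group
#' classification, the Poisson somatic-ASE-gene test, and cohort
#' summaries. All result tables are written to `out_dir` as TSV (hotspots
#' additionally as BED); given the same `config$rng_seed` two runs
#' produce byte-identical outputs.
#'
#' @param manifest cohort manifest data.frame with a `paths` attribute
#'   (as returned by [read_manifest()] or [simulate_cohort()]), or the
#'   path to a manifest file.
#' @param config [pipeline_config()].
#' @param out_dir output directory.
#' @return (invisibly) a list with all result tables.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  validate_manifest(manifest)
  paths <- attr(manifest, "paths")
  if (is.null(paths) || is.null(paths$genes) || is.null(paths$genome)) {
    stop("manifest must carry 'genes' and 'genome' paths")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genes <- stage("read_inputs", read_gene_models(paths$genes, "tsv"))
  genome <- stage("read_inputs",
                  utils::read.delim(paths$genome, stringsAsFactors = FALSE))
  mask <- if (!is.null(paths$mask)) stage("read_inputs", read_bed3(paths$mask))
          else data.frame(chrom = character(), start = integer(),
                          end = integer())
  somatic_positions <- if (!is.null(paths$somatic)) {
    stage("read_inputs",
          utils::read.delim(paths$somatic, stringsAsFactors = FALSE))
  } else data.frame(chrom = character(), pos = integer(), alt = character())
  fpkm <- if (!is.null(paths$fpkm)) stage("read_inputs", read_fpkm(paths$fpkm))
          else NULL

  snv_calls <- list(); gene_calls <- list()
  somatic_calls <- list(); reports <- list()
  gene_cutoffs <- NULL  # empirical gene cutoffs, shared across samples
  for (i in seq_len(nrow(manifest))) {
    patient <- manifest$patient_id[i]
    for (tissue in c("tumor", "normal")) {
      sid <- if (tissue == "tumor") manifest$tumor_sample_id[i]
             else manifest$normal_sample_id[i]
      path <- if (tissue == "tumor") manifest$tumor_sites[i]
              else manifest$normal_sites[i]
      sites <- stage("filter", {
        s <- read_site_table(path, tissue, sid)
        apply_site_filters(s, mask, genes, somatic_positions, config)
      })
      reports[[sid]] <- cbind(sites$report, tissue = tissue)
      kept <- sites$kept
      germ <- kept[kept$origin == "germline", , drop = FALSE]
      calls <- stage("call_ase", call_ase_snvs(germ, config))
      calls$patient_id <- patient
      snv_calls[[sid]] <- calls
      if (is.null(gene_cutoffs) && nrow(germ) > 0) {
        # depth distributions are homogeneous across samples, so the
        # Monte-Carlo gene cutoffs are computed once per cohort
        gene_cutoffs <- stage("call_ase", {
          ks <- 1:20
          co <- vapply(ks, gene_null_cutoff, 0.0, alpha = config$alpha_snv,
                       dna_depths = germ$dna_ref + germ$dna_alt,
                       rna_depths = germ$rna_ref + germ$rna_alt)
          stats::setNames(co, ks)
        })
      }
      gcalls <- stage("call_ase",
                      call_ase_genes(germ, genes, config,
                                     cutoffs = gene_cutoffs))
      if (nrow(gcalls) > 0) gcalls$patient_id <- patient
      gene_calls[[sid]] <- gcalls
      if (tissue == "tumor") {
        som <- kept[kept$origin == "somatic", , drop = FALSE]
        if (nrow(som) > 0) {
          scalls <- stage("somatic_ase", call_somatic_ase(som, config))
          scalls$patient_id <- patient
          somatic_calls[[sid]] <- scalls
        }
      }
    }
  }
  snv_calls <- do.call(rbind, snv_calls)
  gene_calls <- do.call(rbind, gene_calls)
  somatic_calls <- if (length(somatic_calls) > 0)
    do.call(rbind, somatic_calls) else NULL
  rownames(snv_calls) <- rownames(gene_calls) <- NULL
  report <- do.call(rbind, reports)
  rownames(report) <- NULL

  hotspot_res <- list()
  for (tissue in c("tumor", "normal")) {
    set.seed(config$rng_seed + if (tissue == "tumor") 1001L else 2002L)
    sub <- snv_calls[snv_calls$tissue == tissue, , drop = FALSE]
    hotspot_res[[tissue]] <- stage("hotspots",
                                   detect_hotspots(sub, genome, genes, config))
  }

  groups <- NULL
  if (!is.null(somatic_calls) && !is.null(fpkm)) {
    groups <- stage("somatic_groups",
                    assign_groups(somatic_calls, genes, fpkm, manifest, config))
  }

  somatic_genes <- stage("somatic_gene_test",
                         somatic_ase_gene_test(gene_calls, config$bh_alpha))

  summaries <- stage("cohort_stats", {
    out <- lapply(seq_len(nrow(manifest)), function(i) {
      tt <- snv_calls[snv_calls$sample_id == manifest$tumor_sample_id[i], ]
      nn <- snv_calls[snv_calls$sample_id == manifest$normal_sample_id[i], ]
      cbind(patient_id = manifest$patient_id[i], pair_summary(tt, nn))
    })
    do.call(rbind, out)
  })
  frac_test <- if (nrow(summaries) >= 2)
    stage("cohort_stats", paired_fraction_test(summaries)) else NULL
  recur <- lapply(c(tumor = "tumor", normal = "normal"), function(ts)
    stage("cohort_stats",
          recurrence(gene_calls[gene_calls$tissue == ts, , drop = FALSE],
                     config$recurrence_fraction)))

  summary_row <- data.frame(
    n_pairs = nrow(manifest),
    mean_frac_ase_tumor = mean(summaries$frac_ase_tumor, na.rm = TRUE),
    mean_frac_ase_normal = mean(summaries$frac_ase_normal, na.rm = TRUE),
    paired_t_p = if (is.null(frac_test)) NA_real_ else frac_test$p_value,
    pct_somatic_ase = if (is.null(somatic_calls)) NA_real_ else
      100 * mean(somatic_calls$is_ase[somatic_calls$testable]),
    pct_somatic_over = if (is.null(somatic_calls)) NA_real_ else
      100 * mean(somatic_calls$mutant_direction[somatic_calls$is_ase] ==
                   "over"),
    n_hotspots_tumor = nrow(hotspot_res$tumor$hotspots),
    n_hotspots_normal = nrow(hotspot_res$normal$hotspots),
    n_somatic_ase_genes = sum(somatic_genes$is_somatic_ase),
    n_recurrent_tumor = sum(recur$tumor$genes$recurrent),
    n_recurrent_normal = sum(recur$normal$genes$recurrent))

  write_tsv(snv_calls, file.path(out_dir, "snv_calls.tsv"))
  write_tsv(gene_calls, file.path(out_dir, "gene_calls.tsv"))
  write_tsv(report, file.path(out_dir, "filter_report.tsv"))
  for (tissue in c("tumor", "normal")) {
    write_tsv(hotspot_res[[tissue]]$windows,
              file.path(out_dir, paste0("hotspot_windows_", tissue, ".tsv")))
    write_tsv(hotspot_res[[tissue]]$hotspots,
              file.path(out_dir, paste0("hotspots_", tissue, ".tsv")))
    write_hotspot_bed(hotspot_res[[tissue]]$hotspots,
                      file.path(out_dir, paste0("hotspots_", tissue, ".bed")))
  }
  if (!is.null(somatic_calls)) {
    write_tsv(somatic_calls, file.path(out_dir, "somatic_mutation_calls.tsv"))
  }
  if (!is.null(groups)) {
    write_tsv(groups, file.path(out_dir, "somatic_groups.tsv"))
  }
  write_tsv(somatic_genes, file.path(out_dir, "somatic_ase_genes.tsv"))
  write_tsv(summaries, file.path(out_dir, "pair_summaries.tsv"))
  write_tsv(summary_row, file.path(out_dir, "cohort_summary.tsv"))

  invisible(list(snv_calls = snv_calls, gene_calls = gene_calls,
                 filter_report = report, hotspots = hotspot_res,
                 somatic_calls = somatic_calls, groups = groups,
                 somatic_genes = somatic_genes, pair_summaries = summaries,
                 paired_fraction_test = frac_test, recurrence = recur,
                 cohort_summary = summary_row))
}
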