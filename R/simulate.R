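#' Synthetic cohort parameters
#'
#' Defaults emulate the statistical structure of a paired tumor-normal
#' ASE cohort at desk scale: 20 pairs on one 10 Mb chromosome carrying
#' 500 non-overlapping genes with on average 4 exonic heterozygous SNVs
#' each; negative-binomial sequencing depths (mean 60, dispersion 5,
#' truncated at the pipeline's QC floors so that every generated site is
#' "clean" with respect to the coverage filters); per-site DNA allele
#' fraction 0.5; per-site ASE states with marginal rates 0.20 in tumor
#' and 0.17 in normal tissue and a shared component sized so that
#' roughly a third of ASE events are common to the two tissues of a
#' pair; an ASE RNA major-allele fraction of 0.8;
#' 3 planted hotspot regions penetrant in 60% of pairs; 50 somatic
#' mutations per tumor of which 37.5% show allele-specific expression,
#' 78% of those over-expressing the mutant allele; and log-normal FPKM
#' with planted tumor/normal fold changes of 4, 1 or 1/4 for
#' mutation-bearing genes.
#'
#' @param n_pairs number of tumor-normal pairs.
#' @param genome data.frame `chrom`, `length`.
#' @param n_genes genes placed without overlap across the genome.
#' @param snvs_per_gene Poisson mean of heterozygous SNVs per gene.
#' @param dna_depth_mean,rna_depth_mean,depth_dispersion negative
#'   binomial depth model (mu, size).
#' @param base_ase_rate_normal,base_ase_rate_tumor marginal gene-by-pair
#'   ASE rates.
#' @param shared_ase_fraction fraction of the smaller marginal rate that
#'   is common to both tissues of a pair.
#' @param ase_allele_fraction RNA fraction of the over-expressed allele
#'   at true-ASE sites.
#' @param n_hotspots,hotspot_sample_penetrance planted recurrently ASE
#'   regions and the fraction of pairs in which they are ASE.
#' @param n_somatic_per_tumor somatic mutations per tumor sample.
#' @param somatic_ase_rate fraction of somatic mutations with ASE.
#' @param mutant_over_rate fraction of ASE somatic mutations whose
#'   mutant allele is the over-expressed one.
#' @param n_driver_like_genes genes with strongly elevated tumor-specific
#'   ASE (per-pair event probability `driver_event_rate`).
#' @param driver_event_rate per-pair tumor-only ASE probability of
#'   driver-like genes.
#' @param fpkm_meanlog,fpkm_sdlog,fpkm_noise_sdlog log-normal expression
#'   baseline and residual noise.
#' @param fold_up_true,fold_down_true planted unambiguous tumor/normal
#'   folds for up- and down-regulated mutation-bearing genes.
#' @param rng_seed integer seed; same seed, same cohort.
#' @return validated list of class `"ase_sim_params"`.
#' @export
simulation_params <- function(n_pairs = 20L,
                              genome = data.frame(chrom = "chr1",
                                                  length = 10000000L),
                              n_genes = 500L,
                              snvs_per_gene = 4,
                              dna_depth_mean = 60, rna_depth_mean = 60,
                              depth_dispersion = 5,
                              base_ase_rate_normal = 0.17,
                              base_ase_rate_tumor = 0.20,
                              shared_ase_fraction = 0.53,
                              ase_allele_fraction = 0.8,
                              n_hotspots = 3L,
                              hotspot_sample_penetrance = 0.6,
                              n_somatic_per_tumor = 50L,
                              somatic_ase_rate = 0.375,
                              mutant_over_rate = 0.78,
                              n_driver_like_genes = 5L,
                              driver_event_rate = 0.5,
                              fpkm_meanlog = log(10), fpkm_sdlog = 1,
                              fpkm_noise_sdlog = 0.05,
                              fold_up_true = 4, fold_down_true = 0.25,
                              rng_seed = 1L) {
  rates <- c(base_ase_rate_normal, base_ase_rate_tumor,
             shared_ase_fraction, ase_allele_fraction,
             hotspot_sample_penetrance, somatic_ase_rate,
             mutant_over_rate, driver_event_rate)
  stopifnot(all(rates >= 0), all(rates <= 1),
            n_pairs >= 1, n_genes >= 1, snvs_per_gene >= 0,
            dna_depth_mean >= 1, rna_depth_mean >= 1,
            depth_dispersion > 0, n_hotspots >= 0,
            n_somatic_per_tumor >= 0, n_driver_like_genes >= 0,
            fold_up_true > 1, fold_down_true < 1, fold_down_true > 0)
  shared_rate <- shared_ase_fraction * min(base_ase_rate_normal,
                                           base_ase_rate_tumor)
  structure(list(
    n_pairs = as.integer(n_pairs), genome = genome,
    n_genes = as.integer(n_genes), snvs_per_gene = snvs_per_gene,
    dna_depth_mean = dna_depth_mean, rna_depth_mean = rna_depth_mean,
    depth_dispersion = depth_dispersion,
    base_ase_rate_normal = base_ase_rate_normal,
    base_ase_rate_tumor = base_ase_rate_tumor,
    shared_rate = shared_rate,
    tumor_only_rate = base_ase_rate_tumor - shared_rate,
    normal_only_rate = base_ase_rate_normal - shared_rate,
    ase_allele_fraction = ase_allele_fraction,
    n_hotspots = as.integer(n_hotspots),
    hotspot_sample_penetrance = hotspot_sample_penetrance,
    n_somatic_per_tumor = as.integer(n_somatic_per_tumor),
    somatic_ase_rate = somatic_ase_rate,
    mutant_over_rate = mutant_over_rate,
    n_driver_like_genes = as.integer(n_driver_like_genes),
    driver_event_rate = driver_event_rate,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    fpkm_noise_sdlog = fpkm_noise_sdlog,
    fold_up_true = fold_up_true, fold_down_true = fold_down_true,
    rng_seed = as.integer(rng_seed)
  ), class = "ase_sim_params")
}

# negative binomial truncated from below so QC-passing coverage is
# guaranteed for clean sites
rnbinom_trunc <- function(n, mu, size, floor) {
  lo <- stats::pnbinom(floor - 1, size = size, mu = mu)
  u <- pmin(stats::runif(n, lo, 1), 1 - 1e-12)
  stats::qnbinom(u, size = size, mu = mu)
}

BASES <- c("A", "C", "G", "T")

#' Generate a paired tumor-normal cohort with known truth
#'
#' Writes the complete set of input files the pipeline consumes (site
#' tables per sample, gene models, repeat mask, genome table, somatic
#' call list, FPKM table, manifest) into `out_dir` and returns the
#' manifest together with the generative truth. Genes sit on a regular
#' grid so they never overlap; SNVs sit on a 40 bp exonic sub-grid so
#' clean sites are never removed by the cluster filter; the repeat mask
#' covers intergenic gaps only. ASE status is drawn per site and pair
#' (shared between the two tissues, tumor-only, normal-only, or absent),
#' the over-expressed allele is chosen at random per site-pair and held
#' constant across tissues when both are ASE; hotspot sites are ASE in
#' both tissues in a penetrant fraction of pairs, and driver-like genes
#' carry concordant tumor-only ASE across all their SNVs so they survive
#' the gene-level heterogeneity exclusion.
#'
#' @param params [simulation_params()].
#' @param out_dir output directory (created if needed).
#' @return list: `manifest` (with `paths` attribute), `truth` (see
#'   below), `params`. Truth components: `gene_truth`, `site_truth`
#'   (per site, sample and tissue: true RNA fraction and ASE label),
#'   `hotspots`, `somatic_truth`, `gene_groups`, `driver_genes`,
#'   `must_be_filtered`.
#' @export
simulate_cohort <- function(params = simulation_params(), out_dir) {
  set.seed(params$rng_seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- params$genome

  ## --- gene placement on a per-chromosome grid -------------------------
  slots_per_chrom <- pmax(1L, floor(genome$length / 20000))
  total_slots <- sum(slots_per_chrom)
  if (total_slots < params$n_genes) {
    stop("genome too small for n_genes (", params$n_genes, " genes, ",
         total_slots, " 20 kb slots)")
  }
  chrom_of_slot <- rep(genome$chrom, slots_per_chrom)
  slot_start <- unlist(lapply(slots_per_chrom,
                              function(k) seq.int(0L, by = 20000L,
                                                  length.out = k)))
  take <- sort(sample.int(total_slots, params$n_genes))
  gene_start <- slot_start[take] + 2000L
  n_exons <- 3L
  exon_len <- 800L
  intron_len <- 1200L
  gene_len <- n_exons * exon_len + (n_exons - 1L) * intron_len
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(params$n_genes)),
    chrom = chrom_of_slot[take],
    start = gene_start, end = gene_start + gene_len,
    strand = sample(c("+", "-"), params$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  genes$coding_intervals <- lapply(gene_start, function(s) {
    es <- s + (0:(n_exons - 1)) * (exon_len + intron_len)
    cbind(start = es, end = es + exon_len)
  })
  validate_gene_models(genes)

  ## --- repeat mask in intergenic gaps ----------------------------------
  mask <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    g <- genes[genes$chrom == genome$chrom[i], , drop = FALSE]
    if (nrow(g) < 2) return(NULL)
    gaps_start <- utils::head(g$end, -1) + 500L
    gaps_end <- gaps_start + 1000L
    keep <- gaps_end < g$start[-1]
    idx <- which(keep)[seq_len(min(20, sum(keep)))]
    if (length(idx) == 0) return(NULL)
    data.frame(chrom = genome$chrom[i], start = gaps_start[idx],
               end = gaps_end[idx], stringsAsFactors = FALSE)
  }))
  if (is.null(mask)) {
    mask <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }

  ## --- heterozygous germline SNVs on a 40 bp exonic sub-grid ------------
  snv_rows <- lapply(seq_len(params$n_genes), function(i) {
    k <- stats::rpois(1, params$snvs_per_gene)
    if (k == 0) return(NULL)
    iv <- genes$coding_intervals[[i]]
    grid <- unlist(lapply(seq_len(nrow(iv)),
                          function(j) seq.int(iv[j, 1] + 1L, iv[j, 2],
                                              by = 40L)))
    k <- min(k, length(grid))
    pos <- sort(sample(grid, k))
    ref <- sample(BASES, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
    data.frame(chrom = genes$chrom[i], pos = pos, ref = ref, alt = alt,
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  })
  snvs <- do.call(rbind, snv_rows)
  rownames(snvs) <- NULL
  n_snv <- nrow(snvs)

  ## --- planted hotspots: blocks of consecutive genes --------------------
  hotspot_regions <- data.frame(chrom = character(), start = integer(),
                                end = integer(), stringsAsFactors = FALSE)
  hotspot_gene <- rep(FALSE, params$n_genes)
  if (params$n_hotspots > 0) {
    block <- 7L
    ok_anchor <- which(seq_len(params$n_genes) <= params$n_genes - block + 1)
    anchors <- integer(0)
    cand <- sample(ok_anchor)
    for (a in cand) {
      if (length(anchors) == params$n_hotspots) break
      same_chrom <- genes$chrom[a] == genes$chrom[a + block - 1]
      far <- all(abs(a - anchors) > 3 * block)
      if (same_chrom && far) anchors <- c(anchors, a)
    }
    if (length(anchors) < params$n_hotspots) {
      stop("could not place ", params$n_hotspots, " separated hotspots")
    }
    for (a in anchors) {
      idx <- a:(a + block - 1)
      hotspot_gene[idx] <- TRUE
      hotspot_regions <- rbind(hotspot_regions, data.frame(
        chrom = genes$chrom[a], start = genes$start[a],
        end = genes$end[a + block - 1], stringsAsFactors = FALSE))
    }
  }

  ## --- driver-like genes (tumor-specific ASE) ---------------------------
  driver_genes <- character(0)
  if (params$n_driver_like_genes > 0) {
    # a planted tumor-specific ASE gene must be ASE-testable in every
    # pair, so drivers are drawn from genes with at least 2 het SNVs
    k_per_gene <- table(snvs$gene_id)
    testable <- genes$gene_id %in%
      names(k_per_gene)[as.integer(k_per_gene) >= 2]
    pool <- which(!hotspot_gene & testable)
    if (length(pool) < params$n_driver_like_genes) {
      stop("not enough multi-SNV genes for n_driver_like_genes")
    }
    driver_idx <- sample(pool, params$n_driver_like_genes)
    driver_genes <- genes$gene_id[driver_idx]
  } else {
    driver_idx <- integer(0)
  }

  ## --- site-by-pair ASE states ------------------------------------------
  # state: 0 none, 1 shared (both tissues), 2 tumor-only, 3 normal-only.
  # Baseline states are independent per site and pair with marginal rates
  # base_ase_rate_tumor (shared + tumor-only) and base_ase_rate_normal
  # (shared + normal-only). Sites inside a planted hotspot are instead
  # ASE in both tissues with probability hotspot_sample_penetrance.
  # Driver-like genes get a gene-by-pair tumor-only event (all their
  # sites concordantly ASE in the tumor) so they survive the gene-level
  # heterogeneity exclusion and show up as tumor-specific ASE genes.
  pair_ids <- sprintf("P%02d", seq_len(params$n_pairs))
  tumor_ids <- paste0(pair_ids, "_T")
  normal_ids <- paste0(pair_ids, "_N")
  gene_row <- match(snvs$gene_id, genes$gene_id)
  long <- expand.grid(snv = seq_len(n_snv), pair = seq_len(params$n_pairs),
                      KEEP.OUT.ATTRS = FALSE)
  u <- stats::runif(nrow(long))
  cs <- cumsum(c(params$shared_rate, params$tumor_only_rate,
                 params$normal_only_rate))
  st <- integer(nrow(long))
  st[u < cs[3]] <- 3L
  st[u < cs[2]] <- 2L
  st[u < cs[1]] <- 1L
  in_hotspot <- hotspot_gene[gene_row[long$snv]]
  st[in_hotspot] <- ifelse(
    stats::runif(sum(in_hotspot)) < params$hotspot_sample_penetrance, 1L, 0L)
  driver_events <- NULL
  if (length(driver_idx) > 0) {
    driver_events <- matrix(
      stats::runif(length(driver_idx) * params$n_pairs) <
        params$driver_event_rate,
      length(driver_idx), params$n_pairs,
      dimnames = list(genes$gene_id[driver_idx], pair_ids))
    is_driver_row <- match(gene_row[long$snv], driver_idx)
    dr <- !is.na(is_driver_row)
    st[dr] <- ifelse(driver_events[cbind(is_driver_row[dr], long$pair[dr])],
                     2L, 0L)
  }
  # over-expressed allele per site-pair, constant across tissues
  ref_is_major <- stats::runif(nrow(long)) < 0.5
  af <- params$ase_allele_fraction
  p_ase <- ifelse(ref_is_major, af, 1 - af)
  floor_cov <- 20L  # clean sites must clear both QC floors
  draw_tissue <- function(tissue_state_codes) {
    is_ase <- st %in% tissue_state_codes
    p <- ifelse(is_ase, p_ase, 0.5)
    dna_depth <- rnbinom_trunc(nrow(long), params$dna_depth_mean,
                               params$depth_dispersion, floor_cov)
    rna_depth <- rnbinom_trunc(nrow(long), params$rna_depth_mean,
                               params$depth_dispersion, 10L)
    dna_ref <- stats::rbinom(nrow(long), dna_depth, 0.5)
    dna_ref <- pmin(pmax(dna_ref, 1L), dna_depth - 1L)
    rna_ref <- stats::rbinom(nrow(long), rna_depth, p)
    data.frame(chrom = snvs$chrom[long$snv], pos = snvs$pos[long$snv],
               ref = snvs$ref[long$snv], alt = snvs$alt[long$snv],
               dna_ref = dna_ref, dna_alt = dna_depth - dna_ref,
               rna_ref = rna_ref, rna_alt = rna_depth - rna_ref,
               origin = "germline", gene_id = snvs$gene_id[long$snv],
               pair = long$pair, true_p = p, true_ase = is_ase,
               stringsAsFactors = FALSE)
  }
  tumor_sites <- draw_tissue(c(1L, 2L))
  normal_sites <- draw_tissue(c(1L, 3L))

  ## --- somatic mutations (tumor only) -----------------------------------
  somatic_grid <- do.call(rbind, lapply(seq_len(params$n_genes), function(i) {
    iv <- genes$coding_intervals[[i]]
    pos <- unlist(lapply(seq_len(nrow(iv)),
                         function(j) seq.int(iv[j, 1] + 21L, iv[j, 2],
                                             by = 40L)))
    data.frame(chrom = genes$chrom[i], pos = pos,
               gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
  }))
  gene_direction <- ifelse(stats::runif(params$n_genes) <
                             params$mutant_over_rate, "over", "under")
  gene_expr_class <- sample(c("up", "unchanged", "down"),
                            params$n_genes, replace = TRUE)
  somatic_truth <- NULL
  if (params$n_somatic_per_tumor > 0) {
    som_rows <- lapply(seq_len(params$n_pairs), function(pp) {
      pick <- sample.int(nrow(somatic_grid), params$n_somatic_per_tumor)
      g <- somatic_grid[pick, , drop = FALSE]
      ref <- sample(BASES, nrow(g), replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
      is_ase <- stats::runif(nrow(g)) < params$somatic_ase_rate
      dirs <- gene_direction[match(g$gene_id, genes$gene_id)]
      p_alt <- ifelse(!is_ase, 0.5,
                      ifelse(dirs == "over", af, 1 - af))
      dna_depth <- rnbinom_trunc(nrow(g), params$dna_depth_mean,
                                 params$depth_dispersion, floor_cov)
      rna_depth <- rnbinom_trunc(nrow(g), params$rna_depth_mean,
                                 params$depth_dispersion, 10L)
      dna_alt <- stats::rbinom(nrow(g), dna_depth, 0.5)
      dna_alt <- pmin(pmax(dna_alt, 1L), dna_depth - 1L)
      rna_alt <- stats::rbinom(nrow(g), rna_depth, p_alt)
      data.frame(chrom = g$chrom, pos = g$pos, ref = ref, alt = alt,
                 dna_ref = dna_depth - dna_alt, dna_alt = dna_alt,
                 rna_ref = rna_depth - rna_alt, rna_alt = rna_alt,
                 origin = "somatic", gene_id = g$gene_id, pair = pp,
                 true_p = 1 - p_alt, true_ase = is_ase,
                 true_direction = ifelse(is_ase, dirs, NA_character_),
                 stringsAsFactors = FALSE)
    })
    somatic_truth <- do.call(rbind, som_rows)
  }

  ## --- FPKM with planted folds ------------------------------------------
  baseline <- stats::rlnorm(params$n_genes, params$fpkm_meanlog,
                            params$fpkm_sdlog)
  mutated <- if (is.null(somatic_truth)) character(0) else
    unique(somatic_truth$gene_id[somatic_truth$true_ase])
  fold <- rep(1, params$n_genes)
  planted <- genes$gene_id %in% mutated
  fold[planted & gene_expr_class == "up"] <- params$fold_up_true
  fold[planted & gene_expr_class == "down"] <- params$fold_down_true
  noise <- function(n) stats::rlnorm(n, 0, params$fpkm_noise_sdlog)
  fpkm <- do.call(rbind, lapply(seq_len(params$n_pairs), function(pp) {
    rbind(
      data.frame(gene_id = genes$gene_id, sample_id = tumor_ids[pp],
                 fpkm = baseline * fold * noise(params$n_genes),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = genes$gene_id, sample_id = normal_ids[pp],
                 fpkm = baseline * noise(params$n_genes),
                 stringsAsFactors = FALSE))
  }))

  ## --- write cohort files ------------------------------------------------
  site_paths_t <- file.path(out_dir, paste0("sites_", tumor_ids, ".tsv"))
  site_paths_n <- file.path(out_dir, paste0("sites_", normal_ids, ".tsv"))
  for (pp in seq_len(params$n_pairs)) {
    tum <- tumor_sites[tumor_sites$pair == pp, , drop = FALSE]
    if (!is.null(somatic_truth)) {
      tum <- rbind(tum[, SITE_COLUMNS],
                   somatic_truth[somatic_truth$pair == pp, SITE_COLUMNS])
    } else {
      tum <- tum[, SITE_COLUMNS]
    }
    tum <- tum[order(tum$chrom, tum$pos), , drop = FALSE]
    write_site_table(tum, site_paths_t[pp])
    nor <- normal_sites[normal_sites$pair == pp, SITE_COLUMNS]
    nor <- nor[order(nor$chrom, nor$pos), , drop = FALSE]
    write_site_table(nor, site_paths_n[pp])
  }
  gene_path <- file.path(out_dir, "genes.tsv")
  write_gene_models(genes, gene_path)
  mask_path <- file.path(out_dir, "repeat_mask.bed")
  utils::write.table(mask, mask_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  genome_path <- file.path(out_dir, "genome.tsv")
  write_tsv(genome, genome_path)
  somatic_path <- file.path(out_dir, "somatic_calls.tsv")
  som_list <- if (is.null(somatic_truth)) {
    data.frame(chrom = character(), pos = integer(), alt = character())
  } else {
    unique(somatic_truth[, c("chrom", "pos", "alt")])
  }
  write_tsv(som_list, somatic_path)
  fpkm_path <- file.path(out_dir, "fpkm.tsv")
  write_tsv(fpkm, fpkm_path)
  drivers_path <- file.path(out_dir, "driver_like_genes.txt")
  writeLines(driver_genes, drivers_path)

  manifest <- data.frame(patient_id = pair_ids,
                         tumor_sample_id = tumor_ids,
                         normal_sample_id = normal_ids,
                         tumor_sites = site_paths_t,
                         normal_sites = site_paths_n,
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  write_manifest(manifest, manifest_path,
                 paths = list(fpkm = fpkm_path, genes = gene_path,
                              mask = mask_path, genome = genome_path,
                              somatic = somatic_path,
                              drivers = drivers_path))
  attr(manifest, "paths") <- list(fpkm = fpkm_path, genes = gene_path,
                                  mask = mask_path, genome = genome_path,
                                  somatic = somatic_path,
                                  drivers = drivers_path)

  site_truth <- rbind(
    cbind(tumor_sites[, c("chrom", "pos", "gene_id", "pair",
                          "true_p", "true_ase")],
          tissue = "tumor", sample_id = tumor_ids[tumor_sites$pair]),
    cbind(normal_sites[, c("chrom", "pos", "gene_id", "pair",
                           "true_p", "true_ase")],
          tissue = "normal", sample_id = normal_ids[normal_sites$pair]))
  gene_groups <- data.frame(
    gene_id = genes$gene_id,
    direction = gene_direction,
    expression_class = gene_expr_class, stringsAsFactors = FALSE)
  gene_groups$group <- c("over up" = "a", "over unchanged" = "b",
                         "over down" = "c", "under up" = "d",
                         "under unchanged" = "e", "under down" = "f")[
                           paste(gene_groups$direction,
                                 gene_groups$expression_class)]
  gene_groups <- gene_groups[gene_groups$gene_id %in% mutated, ,
                             drop = FALSE]
  truth <- list(
    genes = genes,
    driver_events = driver_events,
    site_truth = site_truth,
    hotspots = hotspot_regions,
    somatic_truth = somatic_truth,
    gene_groups = gene_groups,
    driver_genes = driver_genes,
    must_be_filtered = data.frame(sample_id = character(),
                                  chrom = character(), pos = integer(),
                                  reason = character(),
                                  stringsAsFactors = FALSE))
  write_tsv(site_truth, file.path(out_dir, "truth_sites.tsv"))
  if (!is.null(somatic_truth)) {
    write_tsv(somatic_truth, file.path(out_dir, "truth_somatic.tsv"))
  }
  list(manifest = manifest, truth = truth, params = params,
       manifest_path = manifest_path)
}

#' Inject filterable artifacts into a simulated cohort
#'
#' Adds sites that a specific QC filter must remove, so filter behavior
#' can be verified exactly against the bookkeeping in
#' `truth$must_be_filtered`. Artifact kinds: `snv_cluster` (runs of 3
#' SNVs within 35 bp inside an exon), `low_coverage` (DNA depth below
#' 20), `repeat_overlap` (inside the repeat mask), `noncoding` (inside
#' an intron), `somatic_overlap` (a germline row duplicating a somatic
#' call's position and alt allele).
#'
#' @param cohort result of [simulate_cohort()].
#' @param kind one of the five artifact kinds.
#' @param n number of artifact sites (per affected sample; artifacts go
#'   into the first tumor sample's table).
#' @return the modified cohort (files rewritten, truth updated).
#' @export
inject_artifacts <- function(cohort, kind, n = 5L) {
  kinds <- c("snv_cluster", "low_coverage", "repeat_overlap",
             "noncoding", "somatic_overlap")
  if (!kind %in% kinds) stop("unknown artifact kind: ", kind)
  manifest <- cohort$manifest
  genes <- cohort$truth$genes
  path <- manifest$tumor_sites[1]
  sample_id <- manifest$tumor_sample_id[1]
  sites <- read_site_table(path, "tumor", sample_id)
  used <- paste(sites$chrom, sites$pos)

  mk <- function(chrom, pos, dna_depth = 60L, reason) {
    k <- length(pos)
    ref <- sample(BASES, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
    dna_ref <- pmax(1L, as.integer(round(dna_depth / 2)))
    data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
               dna_ref = dna_ref, dna_alt = dna_depth - dna_ref,
               rna_ref = 30L, rna_alt = 30L, origin = "germline",
               stringsAsFactors = FALSE)
  }
  reason <- switch(kind, snv_cluster = "cluster",
                   low_coverage = "dna_coverage",
                   repeat_overlap = "repeat", noncoding = "noncoding",
                   somatic_overlap = "somatic_overlap")
  new_rows <- switch(kind,
    snv_cluster = {
      # placed in intron 1, at least 150 bp from any other site, so the
      # run removes only itself (the cluster criterion is checked first)
      picks <- genes[sample.int(nrow(genes), n), , drop = FALSE]
      do.call(rbind, lapply(seq_len(n), function(i) {
        iv <- picks$coding_intervals[[i]]
        base <- iv[1, 2] + 200L
        mk(picks$chrom[i], base + c(0L, 10L, 20L), reason = reason)
      }))
    },
    low_coverage = {
      # intron placement keeps clustered-run and exon-grid interactions
      # impossible; the DNA-coverage criterion fires before the region one
      picks <- genes[sample.int(nrow(genes), n), , drop = FALSE]
      pos <- vapply(seq_len(n), function(i)
        as.integer(picks$coding_intervals[[i]][1, 2] + 300L), 0L)
      mk(picks$chrom, pos, dna_depth = 10L, reason = reason)
    },
    repeat_overlap = {
      mask <- read_bed3(attr(manifest, "paths")$mask)
      if (nrow(mask) == 0) stop("cohort has no repeat mask intervals")
      rows <- mask[sample.int(nrow(mask), n, replace = TRUE), ]
      mk(rows$chrom, rows$start + sample.int(500, n), reason = reason)
    },
    noncoding = {
      picks <- genes[sample.int(nrow(genes), n), , drop = FALSE]
      pos <- vapply(seq_len(n), function(i) {
        iv <- picks$coding_intervals[[i]]
        as.integer(iv[1, 2] + 100L)  # inside the first intron
      }, 0L)
      mk(picks$chrom, pos, reason = reason)
    },
    somatic_overlap = {
      som <- utils::read.delim(attr(manifest, "paths")$somatic,
                               stringsAsFactors = FALSE)
      if (nrow(som) == 0) stop("cohort has no somatic calls")
      rows <- som[sample.int(nrow(som), min(n, nrow(som))), ]
      out <- mk(rows$chrom, rows$pos, reason = reason)
      out$alt <- rows$alt
      out$ref <- vapply(rows$alt, function(b) sample(setdiff(BASES, b), 1), "")
      out
    })
  new_rows <- new_rows[!paste(new_rows$chrom, new_rows$pos) %in% used, ,
                       drop = FALSE]
  new_rows <- new_rows[!duplicated(paste(new_rows$chrom, new_rows$pos)), ,
                       drop = FALSE]
  combined <- rbind(sites[, SITE_COLUMNS], new_rows[, SITE_COLUMNS])
  combined <- combined[order(combined$chrom, combined$pos), , drop = FALSE]
  write_site_table(combined, path)
  cohort$truth$must_be_filtered <- rbind(
    cohort$truth$must_be_filtered,
    data.frame(sample_id = sample_id, chrom = new_rows$chrom,
               pos = new_rows$pos, reason = reason,
               stringsAsFactors = FALSE))
  cohort
}
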