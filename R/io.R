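#' Read a per-sample site table
#'
#' Site tables are tab-separated with a fixed header
#' (`chrom pos ref alt dna_ref dna_alt rna_ref rna_alt origin`); positions
#' are 1-based. The tissue and sample labels are attached as columns so
#' tables from many samples can be concatenated.
#'
#' @param path path to a TSV file.
#' @param tissue `"tumor"` or `"normal"`.
#' @param sample_id sample identifier attached to every row.
#' @return data.frame of sites, row order preserved.
#' @export
read_site_table <- function(path, tissue, sample_id) {
  stopifnot(file.exists(path), tissue %in% c("tumor", "normal"))
  sites <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = c(chrom = "character",
                                            ref = "character",
                                            alt = "character"),
                             stringsAsFactors = FALSE)
  missing_cols <- setdiff(SITE_COLUMNS, names(sites))
  if (length(missing_cols) > 0) {
    stop("file '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sites <- sites[, SITE_COLUMNS, drop = FALSE]
  sites$sample_id <- rep_len(sample_id, nrow(sites))
  sites$tissue <- rep_len(tissue, nrow(sites))
  validate_sites(sites)
  sites
}

#' Write a site table
#'
#' Inverse of [read_site_table()]: drops the sample/tissue columns and
#' writes the fixed-header TSV.
#'
#' @param sites site data.frame.
#' @param path output path.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites[, SITE_COLUMNS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Two dialects are accepted. `"bed12"` is standard BED12 (0-based
#' half-open, blocks = coding intervals). `"tsv"` is a simple table with
#' header `gene_id chrom start end strand exon_starts exon_ends` where
#' `start`/`end`/`exon_starts`/`exon_ends` are 1-based inclusive and the
#' exon columns are comma-separated. Either way, coordinates are
#' normalized to 0-based half-open internally.
#'
#' @param path input file.
#' @param dialect `"bed12"` or `"tsv"`.
#' @return gene model data.frame (see [validate_gene_models()]).
#' @export
read_gene_models <- function(path, dialect = c("bed12", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") {
    bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 12) stop("BED12 file must have 12 columns")
    names(bed)[1:12] <- c("chrom", "start", "end", "name", "score", "strand",
                          "thickStart", "thickEnd", "itemRgb",
                          "blockCount", "blockSizes", "blockStarts")
    ivs <- lapply(seq_len(nrow(bed)), function(i) {
      sizes <- suppressWarnings(as.integer(strsplit(bed$blockSizes[i], ",")[[1]]))
      starts <- suppressWarnings(as.integer(strsplit(bed$blockStarts[i], ",")[[1]]))
      if (anyNA(sizes) || anyNA(starts) ||
          length(sizes) != bed$blockCount[i] ||
          length(starts) != bed$blockCount[i]) {
        stop("malformed blockSizes/blockStarts for gene ", bed$name[i])
      }
      cbind(start = bed$start[i] + starts,
            end = bed$start[i] + starts + sizes)
    })
    genes <- data.frame(gene_id = bed$name, chrom = as.character(bed$chrom),
                        start = bed$start, end = bed$end,
                        strand = bed$strand, stringsAsFactors = FALSE)
    genes$coding_intervals <- ivs
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand",
              "exon_starts", "exon_ends")
    if (!all(need %in% names(tab))) {
      stop("TSV gene models need columns: ", paste(need, collapse = ", "))
    }
    ivs <- lapply(seq_len(nrow(tab)), function(i) {
      s <- suppressWarnings(as.integer(strsplit(as.character(tab$exon_starts[i]), ",")[[1]]))
      e <- suppressWarnings(as.integer(strsplit(as.character(tab$exon_ends[i]), ",")[[1]]))
      if (anyNA(s) || anyNA(e) || length(s) != length(e)) {
        stop("malformed exon list for gene ", tab$gene_id[i])
      }
      cbind(start = s - 1L, end = e)  # 1-based inclusive -> 0-based half-open
    })
    genes <- data.frame(gene_id = tab$gene_id, chrom = as.character(tab$chrom),
                        start = tab$start - 1L, end = tab$end,
                        strand = tab$strand, stringsAsFactors = FALSE)
    genes$coding_intervals <- ivs
  }
  validate_gene_models(genes)
  genes
}

#' Write gene models in the TSV dialect
#' @param genes gene model data.frame.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  tab <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    start = genes$start + 1L, end = genes$end, strand = genes$strand,
    exon_starts = vapply(genes$coding_intervals,
                         function(iv) paste(iv[, 1] + 1L, collapse = ","), ""),
    exon_ends = vapply(genes$coding_intervals,
                       function(iv) paste(iv[, 2], collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3 interval file (e.g., a repeat mask)
#'
#' @param path BED3 file; 0-based half-open.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
}

#' Read a cohort FPKM table
#'
#' @param path TSV with header `gene_id sample_id fpkm`.
#' @return data.frame.
#' @export
read_fpkm <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene_id", "sample_id", "fpkm") %in% names(tab))) {
    stop("FPKM table needs columns gene_id, sample_id, fpkm")
  }
  if (any(tab$fpkm < 0)) stop("negative FPKM value")
  tab
}

#' Read a plain gene list (one identifier per line)
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read and write a cohort manifest
#'
#' The manifest TSV has columns `patient_id`, `tumor_sample_id`,
#' `normal_sample_id`, `tumor_sites`, `normal_sites`; a comment line
#' `#fpkm=<path>` records the cohort FPKM table. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest file.
#' @return manifest data.frame with attribute `fpkm_path`.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#[A-Za-z_]+=", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  manifest <- utils::read.delim(text = paste(body, collapse = "\n"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  manifest$tumor_sites <- resolve(manifest$tumor_sites)
  manifest$normal_sites <- resolve(manifest$normal_sites)
  if (length(meta_lines) > 0) {
    keys <- sub("^#([A-Za-z_]+)=.*$", "\\1", meta_lines)
    vals <- resolve(sub("^#[A-Za-z_]+=", "", meta_lines))
    attr(manifest, "paths") <- stats::setNames(as.list(vals), keys)
  }
  validate_manifest(manifest)
  manifest
}

#' @rdname read_manifest
#' @param manifest manifest data.frame.
#' @param paths named list of auxiliary cohort files (fpkm, genes, mask,
#'   genome, somatic), stored as `#key=value` comment lines.
#' @export
write_manifest <- function(manifest, path, paths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(paths)) writeLines(paste0("#", k, "=", paths[[k]]), con)
  utils::write.table(manifest[, c("patient_id", "tumor_sample_id",
                                  "normal_sample_id", "tumor_sites",
                                  "normal_sites")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hotspot regions as BED with score -log10(adjusted p)
#'
#' @param hotspots merged hotspot data.frame with `chrom`, `start`, `end`,
#'   `p_adj`.
#' @param path output BED path.
#' @export
write_hotspot_bed <- function(hotspots, path) {
  if (nrow(hotspots) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  score <- round(-log10(hotspots$p_adj), 4)
  bed <- data.frame(hotspots$chrom, hotspots$start, hotspots$end,
                    paste0("hotspot_", seq_len(nrow(hotspots))), score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
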