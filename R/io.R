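# File formats: BED3+ bin grids and blacklists, TSV count/log2r/segment
# tables, JSON score reports, and optional BAM ingestion for real data.
# Coordinates are 0-based half-open throughout, matching BED natively.

#' Write / read a bin grid as BED3+
#'
#' Columns: chrom, start, end, gc, mappability, static_blacklist.
#' @param grid a `bin_grid`.
#' @param path file path.
#' @return `read_bin_grid_bed` returns a `bin_grid`.
#' @export
write_bin_grid_bed <- function(grid, path) {
  d <- as.data.frame(grid)
  d$gc <- sprintf("%.10g", d$gc)
  d$mappability <- sprintf("%.10g", d$mappability)
  d$static_blacklist <- as.integer(d$static_blacklist)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_grid_bed
#' @param bin_size bin width recorded on the grid attribute.
#' @export
read_bin_grid_bed <- function(path, bin_size = NULL) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("chrom", "start", "end", "gc", "mappability",
                "static_blacklist")
  d$static_blacklist <- d$static_blacklist != 0
  attr(d, "bin_size") <- as.integer(bin_size %||% (d$end[1] - d$start[1]))
  class(d) <- c("bin_grid", "data.frame")
  d
}

#' Write / read a bins x samples count matrix as TSV
#' @param counts integer matrix with sample IDs as column names.
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Write / read a log2-ratio profile (with mask column) as TSV
#' @param profile a `log2r_profile`.
#' @param path file path.
#' @export
write_log2r_tsv <- function(profile, path) {
  d <- data.frame(chrom = profile$chrom,
                  log2r = ifelse(profile$mask, "NA",
                                 sprintf("%.10g", profile$log2r)),
                  mask = as.integer(profile$mask))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_log2r_tsv
#' @param sample_id label for the re-read profile.
#' @export
read_log2r_tsv <- function(path, sample_id = "sample") {
  d <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id,
                 log2r = suppressWarnings(as.numeric(d$log2r)),
                 mask = d$mask != 0, chrom = d$chrom),
            class = "log2r_profile")
}

#' Write segments as BED-like TSV
#'
#' Columns: chrom, start (first bin, 0-based), end (last bin, exclusive),
#' mean_log2r, algorithm. Bin indices are converted to coordinates via the
#' grid.
#' @param seg a `segmentation_result`.
#' @param grid the bin grid.
#' @param path file path.
#' @export
write_segments_tsv <- function(seg, grid, path) {
  s <- seg$segments
  d <- data.frame(chrom = s$chrom, start = grid$start[s$first_bin],
                  end = grid$end[s$last_bin],
                  mean_log2r = sprintf("%.10g", s$mean_log2r),
                  algorithm = seg$algorithm)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an empirical blacklist as BED
#' @param blacklist an `empirical_blacklist`.
#' @param grid the bin grid.
#' @param path file path.
#' @export
write_blacklist_bed <- function(blacklist, grid, path) {
  i <- blacklist$flagged_bins
  d <- data.frame(chrom = grid$chrom[i], start = grid$start[i],
                  end = grid$end[i])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write t-MAD results as JSON
#' @param results a `tmad_result` or list of them.
#' @param path file path.
#' @export
write_tmad_json <- function(results, path) {
  if (inherits(results, "tmad_result")) results <- list(results)
  out <- lapply(results, function(r)
    list(sample_id = r$sample_id, tmad = r$tmad,
         n_bins_used = r$n_bins_used, n_trimmed = r$n_trimmed))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Count aligned reads per bin from a BAM file
#'
#' Optional real-data ingestion (requires the `Rsamtools` package): counts
#' primary, non-duplicate alignments with mapping quality >= `mapq_min`,
#' assigning each read to the bin containing its leftmost aligned base
#' (0-based).
#'
#' @param path coordinate-sorted, indexed BAM file.
#' @param grid bin grid whose `chrom` labels match the BAM header.
#' @param mapq_min minimum mapping quality (default 30).
#' @param sample_id sample label.
#' @return a `sample_counts` object.
#' @export
ingest_bam <- function(path, grid, mapq_min = 30, sample_id = basename(path)) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("ingest_bam requires the Rsamtools package", call. = FALSE)
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path)))
    stop("BAM file must be coordinate-sorted and indexed (run samtools sort/index)",
         call. = FALSE)
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flags, what = c("rname", "pos"),
                                 mapqFilter = mapq_min)
  aln <- Rsamtools::scanBam(path, param = par)[[1]]
  bin_size <- attr(grid, "bin_size")
  counts <- integer(nrow(grid))
  if (length(aln$pos)) {
    pos0 <- aln$pos - 1L                 # BAM pos is 1-based
    key <- paste0(aln$rname, ":", (pos0 %/% bin_size) * bin_size)
    grid_key <- paste0(grid$chrom, ":", grid$start)
    tab <- table(key)
    hit <- match(names(tab), grid_key)
    ok <- !is.na(hit)
    counts[hit[ok]] <- as.integer(tab[ok])
  }
  structure(list(sample_id = sample_id, counts = counts,
                 total_reads = sum(counts), truth = NULL),
            class = "sample_counts")
}
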