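#' Construct a per-base coverage track
#'
#' A `CoverageTrack` holds one chromosome's per-base genome coverage
#' \eqn{C_b} (number of reads mapped over each base), the 1-based position of
#' its first base, and whether the chromosome is circular (windows and event
#' clusters may then wrap around the origin).
#'
#' @param coverage Integer-valued, non-negative vector of per-base coverage.
#' @param chrom Chromosome / contig label.
#' @param position_start 1-based position of the first element of `coverage`.
#' @param circular Logical; `TRUE` for circular chromosomes (plasmids,
#'   most bacterial chromosomes).
#' @return An object of class `CoverageTrack`.
#' @examples
#' coverage_track(c(10L, 12L, 0L), chrom = "chr1")
#' @export
coverage_track <- function(coverage, chrom = "chr1", position_start = 1L,
                           circular = FALSE) {
  if (length(coverage) < 1L) stop("coverage must have length >= 1")
  if (anyNA(coverage)) stop("coverage must not contain NA")
  if (any(coverage < 0)) stop("coverage values must be >= 0")
  structure(
    list(chrom = as.character(chrom),
         position_start = as.integer(position_start),
         coverage = as.numeric(coverage),
         circular = isTRUE(circular)),
    class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %d bases starting at %d (%s)\n",
              x$chrom, length(x$coverage), x$position_start,
              if (x$circular) "circular" else "linear"))
  cat(sprintf("  mean depth %.2fX, range [%g, %g]\n",
              mean(x$coverage), min(x$coverage), max(x$coverage)))
  invisible(x)
}

#' @export
length.CoverageTrack <- function(x) length(x$coverage)

#' Read a per-base coverage BED file
#'
#' Reads the three-column tab-delimited dialect produced by
#' `bedtools genomecov -d`: chromosome, 1-based position, integer coverage.
#' Within each chromosome positions must be contiguous (strictly increasing
#' by one). BAM/CRAM input is not parsed; convert externally with
#' `bedtools genomecov -d -ibam file.bam`. The four-column bedGraph interval
#' dialect is rejected explicitly.
#'
#' @param path Path to the BED file.
#' @param circular Logical (recycled over chromosomes): mark the resulting
#'   tracks as circular.
#' @return A named list of [coverage_track()] objects, one per chromosome in
#'   order of first appearance in the file.
#' @export
read_coverage_bed <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty coverage file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          showProgress = FALSE)
  if (nrow(dt) == 0L) stop("empty coverage file: ", path)
  if (ncol(dt) == 4L)
    stop("4-column input looks like bedGraph intervals; expected the ",
         "3-column per-base dialect of 'bedtools genomecov -d'")
  if (ncol(dt) != 3L)
    stop("expected 3 tab-separated columns, found ", ncol(dt))
  chrom <- dt[[1L]]
  pos <- suppressWarnings(as.numeric(dt[[2L]]))
  cov <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(!is.finite(pos) | !is.finite(cov) |
                 pos != floor(pos) | cov != floor(cov))
  if (length(bad))
    stop("malformed line ", bad[1L], ": position and coverage must be integers")
  if (any(cov < 0)) stop("negative coverage at line ", which(cov < 0)[1L])
  if (any(cov > 2^31 - 1))
    stop("coverage value exceeds 2^31-1 at line ", which(cov > 2^31 - 1)[1L])

  chroms <- unique(chrom)
  circular <- rep_len(circular, length(chroms))
  tracks <- vector("list", length(chroms))
  names(tracks) <- chroms
  for (i in seq_along(chroms)) {
    idx <- which(chrom == chroms[i])
    if (any(diff(idx) != 1L))
      stop("chromosome '", chroms[i], "' appears in non-contiguous blocks")
    p <- pos[idx]
    if (length(p) > 1L && any(diff(p) != 1))
      stop("positions not contiguous for chromosome '", chroms[i],
           "' near line ", idx[which(diff(p) != 1)[1L] + 1L])
    tracks[[i]] <- coverage_track(cov[idx], chrom = chroms[i],
                                  position_start = as.integer(p[1L]),
                                  circular = circular[i])
  }
  tracks
}

#' Write coverage tracks back to the 3-column BED dialect
#'
#' @param tracks A `CoverageTrack` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_bed <- function(tracks, path) {
  if (inherits(tracks, "CoverageTrack")) tracks <- list(tracks)
  parts <- lapply(tracks, function(tr) {
    data.table::data.table(
      chrom = tr$chrom,
      pos = seq.int(tr$position_start, length.out = length(tr$coverage)),
      cov = format(tr$coverage, scientific = FALSE, trim = TRUE))
  })
  data.table::fwrite(data.table::rbindlist(parts), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

roi_csv_columns <- c("chrom", "start", "end", "size", "mean_cov", "max_cov",
                     "mean_rm", "mean_zscore", "max_zscore", "log2_ratio")

fmt6 <- function(x) {
  out <- ifelse(is.na(x) | !is.finite(x), "NA", sprintf("%.6f", x))
  out
}

#' Write detected ROIs to CSV
#'
#' One row per ROI with columns `chrom, start, end, size, mean_cov, max_cov,
#' mean_rm, mean_zscore, max_zscore, log2_ratio`. Real values are written
#' with six decimals; undefined statistics (e.g. the log2 ratio of a fully
#' deleted region) are written as `NA`.
#'
#' @param rois ROI data frame from [annotate_rois()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(rois, path) {
  out <- data.frame(
    chrom = if (nrow(rois)) rois$chrom else character(0),
    start = rois$start,
    end = rois$end,
    size = rois$size,
    mean_cov = fmt6(rois$mean_cov),
    max_cov = fmt6(rois$max_cov),
    mean_rm = fmt6(rois$mean_rm),
    mean_zscore = fmt6(rois$mean_zscore),
    max_zscore = fmt6(rois$max_zscore),
    log2_ratio = fmt6(rois$log2_ratio),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(roi_csv_columns, collapse = ","), con)
  if (nrow(out))
    utils::write.table(out, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ROI CSV written by [write_roi_csv()]
#'
#' @param path Path to the CSV.
#' @return A data frame with the ROI columns; `NA` strings become `NA_real_`.
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(chrom = "character"))
  num <- setdiff(roi_csv_columns, c("chrom", "start", "end", "size"))
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Write the per-chromosome summary JSON
#'
#' Records the whole-track metrics (depth of coverage, breadth of coverage,
#' coefficient of variation, centralness), the running-median window used,
#' the z-score thresholds, the fitted central-distribution parameters and
#' the ROI counts on each side.
#'
#' @param stats A [summary_stats()] object (with `centralness` and `W_used`
#'   filled in).
#' @param fit A [fit_mixture()] object.
#' @param path Output path.
#' @param thresholds A [threshold_spec()].
#' @param n_rois_low,n_rois_high ROI counts per side.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(stats, fit, path,
                               thresholds = threshold_spec(),
                               n_rois_low = 0L, n_rois_high = 0L) {
  obj <- list(
    length = stats$G,
    doc_mean = stats$doc_mean,
    doc_median = stats$doc_median,
    boc = stats$boc,
    sigma = stats$sigma,
    cv = stats$cv,
    centralness = stats$centralness,
    W = stats$W_used,
    thresholds = list(n_high = thresholds$n_high, n_low = thresholds$n_low,
                      alpha = thresholds$alpha, m_high = thresholds$m_high,
                      m_low = thresholds$m_low),
    mu0 = fit$mu0, sigma0 = fit$sigma0, pi0 = fit$pi0,
    n_rois_low = n_rois_low, n_rois_high = n_rois_high)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
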