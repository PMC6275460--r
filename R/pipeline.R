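#' Analyze a single coverage track
#'
#' Runs the full detection chain on one chromosome: optional binning,
#' running-median detrending, normalization, Gaussian-mixture fit,
#' z-scores, double-threshold clustering on both sides, optional merging of
#' nearby ROIs, optional copy-number filtering, and annotation. When
#' binning is used, ROI coordinates are mapped back to unbinned base
#' coordinates.
#'
#' @param track A [coverage_track()].
#' @param W Odd running-median window, or `"auto"` (see [default_window()]).
#' @param thresholds A [threshold_spec()].
#' @param binning Optional bin width (NULL disables).
#' @param cnv_mode Logical; apply the copy-number filter
#'   (`|mean z| >= 5`, `size >= 100`).
#' @param merge_gap Merge same-side ROIs closer than this many bases
#'   (0 disables).
#' @return List with `stats` (centralness and window filled in), `fit`,
#'   `rois`, `detrended`, `z`, `thresholds` and the resolved `W`.
#' @examples
#' spec <- simulation_spec(G = 20000, depth = 200, noise = "poisson")
#' tr <- simulate_coverage(spec, seed = 7)
#' res <- analyze_track(tr, W = 4001)
#' res$fit
#' @export
analyze_track <- function(track, W = "auto", thresholds = threshold_spec(),
                          binning = NULL, cnv_mode = FALSE, merge_gap = 0L) {
  stopifnot(inherits(track, "CoverageTrack"))
  stats <- summary_stats(track)

  work <- track
  if (!is.null(binning) && binning > 1L) work <- bin_track(track, binning)
  det <- detrend_track(work, W = W)
  W_used <- attr(det, "W")
  fit <- fit_mixture(det)
  z <- zscores(det, fit)

  iv_high <- cluster_rois(z, thresholds, "high", circular = work$circular)
  iv_low <- cluster_rois(z, thresholds, "low", circular = work$circular)
  rois <- rbind(annotate_rois(iv_high, work, det, z, side = "high"),
                annotate_rois(iv_low, work, det, z, side = "low"))
  if (merge_gap > 0L && nrow(rois))
    rois <- merge_close_rois(rois, merge_gap, work, det, z)
  if (cnv_mode) rois <- filter_rois(rois, min_mean_z = 5, min_size = 100L)

  if (!is.null(binning) && binning > 1L && nrow(rois)) {
    bs <- attr(work, "bin_start"); be <- attr(work, "bin_end")
    nb <- length(bs)
    # end > nb means an origin-spanning ROI on a circular binned track
    rois$end <- ifelse(rois$end > nb,
                       be[nb] + be[((rois$end - 1L) %% nb) + 1L],
                       be[rois$end])
    rois$start <- bs[rois$start]
    rois$size <- rois$end - rois$start + 1L
  }
  rois <- rois[order(rois$start, rois$side), , drop = FALSE]
  rownames(rois) <- NULL

  stats$centralness <- centralness(z, thresholds$n_high)
  stats$W_used <- W_used
  list(stats = stats, fit = fit, rois = rois, detrended = det, z = z,
       thresholds = thresholds, W = W_used)
}

#' Pipeline run configuration
#'
#' @param input Path to a 3-column per-base coverage BED file.
#' @param W Running-median window, or `"auto"`.
#' @param circular Logical; treat chromosomes as circular.
#' @param chromosome Optional chromosome name to analyze (default: all).
#' @param n_high,n_low,alpha Detection thresholds (see [threshold_spec()]).
#' @param binning Optional bin width.
#' @param cnv_mode Logical; apply the copy-number filter.
#' @param merge_gap Merge same-side ROIs closer than this (bases).
#' @param output_dir Directory for `<chrom>.rois.csv` and
#'   `<chrom>.summary.json` (NULL: no files written).
#' @return A `RunConfig` list.
#' @export
run_config <- function(input, W = "auto", circular = FALSE,
                       chromosome = NULL, n_high = 4, n_low = -4,
                       alpha = 0.5, binning = NULL, cnv_mode = FALSE,
                       merge_gap = 0L, output_dir = "coverage_results") {
  structure(list(input = input, W = W, circular = circular,
                 chromosome = chromosome,
                 thresholds = threshold_spec(n_high, n_low, alpha),
                 binning = binning, cnv_mode = cnv_mode,
                 merge_gap = as.integer(merge_gap),
                 output_dir = output_dir),
            class = "RunConfig")
}

#' Run the detection pipeline on a coverage BED file
#'
#' Reads the file, analyzes each (or the selected) chromosome with
#' [analyze_track()], and writes one ROI CSV and one summary JSON per
#' chromosome into the output directory.
#'
#' @param config A [run_config()].
#' @return Named list (per chromosome) of [analyze_track()] results,
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  tracks <- read_coverage_bed(config$input, circular = config$circular)
  if (!is.null(config$chromosome)) {
    if (!config$chromosome %in% names(tracks))
      stop("chromosome '", config$chromosome, "' not found; available: ",
           paste(names(tracks), collapse = ", "))
    tracks <- tracks[config$chromosome]
  }
  if (!is.null(config$output_dir) &&
      !dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)

  results <- lapply(tracks, function(tr) {
    message(sprintf("[depthscan] %s: %d bases (%s)", tr$chrom,
                    length(tr$coverage),
                    if (tr$circular) "circular" else "linear"))
    res <- analyze_track(tr, W = config$W, thresholds = config$thresholds,
                         binning = config$binning,
                         cnv_mode = config$cnv_mode,
                         merge_gap = config$merge_gap)
    message(sprintf(
      "[depthscan] %s: W = %d, mu0 = %.4f, sigma0 = %.4f, %d ROIs (%d low, %d high)",
      tr$chrom, res$W, res$fit$mu0, res$fit$sigma0, nrow(res$rois),
      sum(res$rois$side == "low"), sum(res$rois$side == "high")))
    if (!is.null(config$output_dir)) {
      write_roi_csv(res$rois,
                    file.path(config$output_dir,
                              paste0(tr$chrom, ".rois.csv")))
      write_summary_json(res$stats, res$fit,
                         file.path(config$output_dir,
                                   paste0(tr$chrom, ".summary.json")),
                         thresholds = res$thresholds,
                         n_rois_low = sum(res$rois$side == "low"),
                         n_rois_high = sum(res$rois$side == "high"))
    }
    res
  })
  invisible(results)
}
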