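# Runs of cond == TRUE as [start, end] intervals (1-based).
runs_of <- function(cond) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Cluster threshold-crossing bases into candidate ROIs
#'
#' Double-threshold (hysteresis) clustering: scanning left to right, a
#' cluster opens at the first base whose z-score reaches the inner threshold
#' `m` (`>= m_high` on the high side, `<= m_low` on the low side, ties at
#' exactly `m` belong to the cluster), accumulates while the condition
#' holds, and closes when it fails. The cluster is reported only if its
#' most extreme z-score reaches the outer threshold `n`. Bases with
#' sentinel z (`-Inf`, undefined running median) always satisfy the
#' low-side condition.
#'
#' On circular tracks the scan starts from a position quiet on the scanned
#' side (if one exists), so an event spanning the origin is reported as a
#' single interval; its `end` may then exceed the chromosome length, with
#' coordinates understood modulo the length.
#'
#' @param z Z-score vector.
#' @param spec A [threshold_spec()].
#' @param side `"high"` or `"low"`.
#' @param circular Logical.
#' @return Integer matrix with columns `start`, `end` (1-based inclusive).
#' @export
cluster_rois <- function(z, spec = threshold_spec(),
                         side = c("high", "low"), circular = FALSE) {
  side <- match.arg(side)
  n <- length(z)
  offset <- 0L
  zs <- z
  if (circular) {
    quiet <- if (side == "high") which(z < spec$m_high)
             else which(z > spec$m_low)
    if (length(quiet)) {
      offset <- quiet[1L] - 1L
      if (offset > 0L) zs <- z[c((offset + 1L):n, 1L:offset)]
    }
    # no quiet position: the whole chromosome is one candidate cluster,
    # which the linear scan below yields unchanged
  }
  if (side == "high") {
    iv <- runs_of(zs >= spec$m_high)
    pass <- vapply(seq_len(nrow(iv)), function(i)
      max(zs[iv[i, 1L]:iv[i, 2L]]) >= spec$n_high, logical(1))
  } else {
    iv <- runs_of(zs <= spec$m_low)
    pass <- vapply(seq_len(nrow(iv)), function(i)
      min(zs[iv[i, 1L]:iv[i, 2L]]) <= spec$n_low, logical(1))
  }
  iv <- iv[pass, , drop = FALSE]
  if (offset > 0L && nrow(iv)) {
    iv <- iv + offset                      # back to original coordinates,
    wrap <- iv[, "start"] > n              # starts beyond n wrap fully
    iv[wrap, ] <- iv[wrap, ] - n
    iv <- iv[order(iv[, "start"]), , drop = FALSE]
  }
  iv
}

roi_indices <- function(start, end, n) {
  ((seq.int(start, end) - 1L) %% n) + 1L
}

#' Annotate one candidate interval as an ROI
#'
#' Computes the ROI statistics: mean and max coverage, mean running median,
#' mean and max z-score (the max is the signed extremum, i.e. the most
#' negative value for low-side ROIs), the copy-number ratio
#' `cn_ratio = mean_cov / mean_rm` (the CN estimate for the event) and its
#' `log2_ratio`. Z statistics are computed over bases with defined
#' normalization only; a fully masked ROI gets `NA`.
#'
#' @param interval Length-2 vector or 1-row matrix `(start, end)`,
#'   1-based inclusive (`end` may exceed the length on circular tracks).
#' @param track The [coverage_track()].
#' @param detrended The matching `DetrendedTrack`.
#' @param z Z-score vector.
#' @param side `"high"` or `"low"`.
#' @return One-row data frame of ROI fields.
#' @export
annotate_roi <- function(interval, track, detrended, z,
                         side = c("high", "low")) {
  side <- match.arg(side)
  start <- as.integer(interval[1L]); end <- as.integer(interval[2L])
  if (end < start) stop("zero-length interval: end < start")
  n <- length(track$coverage)
  idx <- roi_indices(start, end, n)
  cov <- track$coverage[idx]
  rmv <- detrended$rm[idx]
  zz <- z[idx][!detrended$undefined_mask[idx]]
  mean_rm <- mean(rmv)
  cn <- if (mean_rm > 0) mean(cov) / mean_rm else NA_real_
  l2 <- if (is.na(cn)) NA_real_ else if (cn > 0) log2(cn) else -Inf
  data.frame(
    chrom = track$chrom,
    start = start, end = end, size = end - start + 1L,
    side = side,
    mean_cov = mean(cov), max_cov = max(cov),
    mean_rm = mean_rm,
    mean_zscore = if (length(zz)) mean(zz) else NA_real_,
    max_zscore = if (!length(zz)) NA_real_
                 else if (side == "high") max(zz) else min(zz),
    cn_ratio = cn, log2_ratio = l2,
    stringsAsFactors = FALSE)
}

#' Annotate a set of candidate intervals
#'
#' @param intervals Matrix from [cluster_rois()].
#' @param side `"high"` or `"low"` (recycled).
#' @inheritParams annotate_roi
#' @return ROI data frame, one row per interval.
#' @export
annotate_rois <- function(intervals, track, detrended, z, side = "high") {
  side <- rep_len(side, max(nrow(intervals), 1L))
  rows <- lapply(seq_len(nrow(intervals)), function(i)
    annotate_roi(intervals[i, ], track, detrended, z, side[i]))
  if (!length(rows)) return(empty_roi_frame())
  do.call(rbind, rows)
}

empty_roi_frame <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             size = integer(0), side = character(0), mean_cov = numeric(0),
             max_cov = numeric(0), mean_rm = numeric(0),
             mean_zscore = numeric(0), max_zscore = numeric(0),
             cn_ratio = numeric(0), log2_ratio = numeric(0),
             stringsAsFactors = FALSE)
}

#' Merge nearby ROIs of the same side
#'
#' Same-side ROIs separated by a gap (`start_next - end_prev - 1`) of at
#' most `max_gap` bases are merged into a single spanning ROI and
#' re-annotated; opposite sides never merge. `max_gap = 0` is the identity.
#'
#' @param rois ROI data frame (single chromosome, sorted by start).
#' @param max_gap Maximum gap in bases (>= 0).
#' @inheritParams annotate_roi
#' @return Merged, re-annotated ROI data frame.
#' @export
merge_close_rois <- function(rois, max_gap, track, detrended, z) {
  if (!is.numeric(max_gap) || max_gap < 0) stop("max_gap must be >= 0")
  if (nrow(rois) < 2L || max_gap == 0) return(rois)
  out <- list()
  for (sd in unique(rois$side)) {
    rs <- rois[rois$side == sd, , drop = FALSE]
    rs <- rs[order(rs$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(
      rs$start[-1L] - rs$end[-nrow(rs)] - 1L > max_gap)))
    iv <- cbind(start = tapply(rs$start, grp, min),
                end = tapply(rs$end, grp, max))
    out[[sd]] <- annotate_rois(iv, track, detrended, z, side = sd)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter ROIs by mean z-score and size
#'
#' In copy-number mode, chance events produced by counting noise alone are
#' removed by keeping only ROIs with `|mean z| >= min_mean_z` and
#' `size >= min_size` (defaults 5 and 100, calibrated on null simulations
#' where no event reaches either bound). An undefined mean z-score (fully
#' deleted region with zero running median) passes the z criterion.
#'
#' @param rois ROI data frame.
#' @param min_mean_z Minimum |mean z-score| (0 disables).
#' @param min_size Minimum ROI length in bases (1 disables).
#' @return Filtered ROI data frame.
#' @export
filter_rois <- function(rois, min_mean_z = 5, min_size = 100L) {
  z_ok <- is.na(rois$mean_zscore) | abs(rois$mean_zscore) >= min_mean_z
  rois[z_ok & rois$size >= min_size, , drop = FALSE]
}
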