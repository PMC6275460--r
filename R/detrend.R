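as_coverage_vector <- function(track) {
  if (inherits(track, "CoverageTrack")) track$coverage else as.numeric(track)
}

track_is_circular <- function(track, circular) {
  if (!is.null(circular)) return(isTRUE(circular))
  if (inherits(track, "CoverageTrack")) track$circular else FALSE
}

# Validates the window length against the series; even W is bumped to the
# next odd value with a warning so that the window is symmetric.
resolve_window <- function(W, n, circular) {
  W <- as.integer(W)
  if (is.na(W) || W < 1L) stop("W must be a positive integer")
  if (W %% 2L == 0L) {
    W <- W + 1L
    warning("window length must be odd; using W = ", W)
  }
  if (circular && W > n)
    stop("W (", W, ") exceeds the chromosome length (", n,
         ") on a circular track")
  W
}

#' Default running-median window for a chromosome
#'
#' 20,001 bases for chromosomes longer than 100,000 bases, otherwise one
#' fifth of the chromosome length, forced odd. The window must be (at least)
#' twice the longest atypical region expected in the data so that the median
#' is not dragged by the region itself.
#'
#' @param G Chromosome length in bases.
#' @return An odd integer window length.
#' @export
default_window <- function(G) {
  W <- if (G > 100000L) 20001L else as.integer(floor(G / 5))
  W <- max(W, 3L)
  if (W %% 2L == 0L) W <- W + 1L
  W
}

#' Moving average of a coverage track
#'
#' Mean of the `W` values centred on each position. On circular tracks the
#' window wraps around the origin; on linear tracks edge windows are
#' truncated to the available positions, so the first and last `(W-1)/2`
#' values average fewer than `W` points.
#'
#' @param track A [coverage_track()] or numeric vector.
#' @param W Odd window length in bases.
#' @param circular Logical; defaults to the track's own flag.
#' @return Numeric vector, same length as the input.
#' @export
moving_average <- function(track, W, circular = NULL) {
  x <- as_coverage_vector(track)
  circ <- track_is_circular(track, circular)
  n <- length(x)
  W <- resolve_window(W, n, circ)
  V <- (W - 1L) %/% 2L
  if (circ) {
    xp <- c(tail(x, V), x, head(x, V))
    cs <- c(0, cumsum(xp))
    idx <- seq_len(n) + V
    (cs[idx + V + 1L] - cs[idx - V]) / W
  } else {
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - V, 1L)
    hi <- pmin(seq_len(n) + V, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
}

#' Running median of a coverage track
#'
#' Median of the `W` values centred on each position, computed with an
#' incremental sorted-window structure (insert/evict one value per step,
#' O(N log W) in total) whose output equals the naive per-window sorted
#' median exactly. Truncated edge windows on linear tracks may hold an even
#' number of points, in which case the two central order statistics are
#' averaged. The running median is the trend estimator of choice here: a
#' deleted or duplicated region shorter than `W/2` leaves the window median
#' untouched, where a moving average would be dragged.
#'
#' @inheritParams moving_average
#' @return Numeric vector, same length as the input.
#' @export
running_median <- function(track, W, circular = NULL) {
  x <- as_coverage_vector(track)
  circ <- track_is_circular(track, circular)
  W <- resolve_window(W, length(x), circ)
  rolling_median_cpp(x, W, circ)
}

#' Normalize a coverage track by its running median
#'
#' Forms the normalized coverage (coverage divided by the running
#' median), centred on 1 for trend-free data. Where the running median is
#' zero (long fully deleted regions) the ratio is undefined: those bases get
#' normalized coverage 0 and are flagged in `undefined_mask`; they are
#' excluded from mixture fitting and force-classified as low-side candidates
#' downstream.
#'
#' @param track A [coverage_track()].
#' @param rm Running-median vector of the same length (from
#'   [running_median()]).
#' @return A `DetrendedTrack`: list with `track`, `rm`, `normalized` and
#'   `undefined_mask`.
#' @export
normalize_track <- function(track, rm) {
  if (!inherits(track, "CoverageTrack")) stop("track must be a CoverageTrack")
  x <- track$coverage
  if (length(rm) != length(x))
    stop("rm length (", length(rm), ") does not match track length (",
         length(x), ")")
  if (any(rm < 0)) stop("running median must be >= 0")
  mask <- rm == 0
  normalized <- numeric(length(x))
  normalized[!mask] <- x[!mask] / rm[!mask]
  structure(list(track = track, rm = rm, normalized = normalized,
                 undefined_mask = mask),
            class = "DetrendedTrack")
}

#' @export
print.DetrendedTrack <- function(x, ...) {
  cat(sprintf("DetrendedTrack '%s': %d bases, %d with undefined RM\n",
              x$track$chrom, length(x$normalized), sum(x$undefined_mask)))
  invisible(x)
}

#' Detrend a track: running median + normalization in one call
#'
#' @param track A [coverage_track()].
#' @param W Odd window length, or `"auto"` for [default_window()].
#' @param circular Logical; defaults to the track's own flag.
#' @return A `DetrendedTrack` (see [normalize_track()]); the resolved window
#'   is attached as attribute `"W"`.
#' @export
detrend_track <- function(track, W = "auto", circular = NULL) {
  if (identical(W, "auto")) W <- default_window(length(track$coverage))
  rm_vec <- running_median(track, W, circular)
  out <- normalize_track(track, rm_vec)
  attr(out, "W") <- resolve_window(W, length(track$coverage),
                                   track_is_circular(track, circular))
  out
}

#' Bin a coverage track
#'
#' Merges consecutive runs of `k` bases into their mean coverage before
#' analysis (useful for very long chromosomes); a trailing partial bin is
#' the mean of its members. Bin `i` maps back to original coordinates
#' `[(i-1)*k + 1, min(i*k, N)]`, recorded in the `bin_start`/`bin_end`
#' attributes for reporting.
#'
#' @param track A [coverage_track()].
#' @param k Bin width in bases (`k = 1` is the identity).
#' @return A `CoverageTrack` of the binned series with attributes
#'   `bin_start`, `bin_end` and `bin_width`.
#' @export
bin_track <- function(track, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  x <- track$coverage
  n <- length(x)
  grp <- (seq_len(n) - 1L) %/% k
  means <- as.numeric(rowsum(x, grp)) / tabulate(grp + 1L)
  nb <- length(means)
  out <- coverage_track(means, chrom = track$chrom,
                        position_start = track$position_start,
                        circular = track$circular)
  attr(out, "bin_start") <- (seq_len(nb) - 1L) * k + 1L
  attr(out, "bin_end") <- pmin(seq_len(nb) * k, n)
  attr(out, "bin_width") <- k
  out
}
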