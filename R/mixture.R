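#' Z-score thresholds for event detection
#'
#' The double-threshold clustering uses, on each side, an outer threshold
#' `n` that a cluster must reach to be reported and an inner threshold
#' `m = alpha * n` that sets the cluster extent. `alpha = 0.5` (the usual
#' choice) makes clusters reach half-way back to the baseline before they
#' close.
#'
#' @param n_high Outer threshold on the high side (z-score units, > 0).
#' @param n_low Outer threshold on the low side (< 0).
#' @param alpha Ratio of inner to outer threshold, in (0, 1].
#' @return A `ThresholdSpec` with derived `m_high`, `m_low`.
#' @export
threshold_spec <- function(n_high = 4, n_low = -4, alpha = 0.5) {
  if (!is.numeric(n_high) || n_high <= 0) stop("n_high must be > 0")
  if (!is.numeric(n_low) || n_low >= 0) stop("n_low must be < 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  structure(list(n_high = n_high, n_low = n_low, alpha = alpha,
                 m_high = alpha * n_high, m_low = alpha * n_low),
            class = "ThresholdSpec")
}

SIGMA_FLOOR <- 1e-6

#' Fit the two-component Gaussian mixture to normalized coverage
#'
#' Models the normalized coverage as a mixture of a dominant central
#' component (mean near 1) and a low-weight outlier component, fitted by
#' expectation maximization. Only the central component's parameters
#' (`mu0`, `sigma0`, `pi0`) matter downstream: they define the per-base
#' z-scores. Bases where the running median is zero, and exact zeros of the
#' normalized coverage (deleted bases), are excluded from the fit.
#'
#' Initialization is robust: `mu0` starts at the median of the data and
#' `sigma0` at 1.4826 times the median absolute deviation; the outlier
#' component starts at the mean of the points further than three `sigma0`
#' from `mu0`, provided that mean itself lies outside the central region
#' `mu0 +/- 3 sigma0` (on outlier-free data the far points are symmetric
#' tails whose mean sits on top of `mu0`, and starting the outlier
#' component inside the bulk makes EM split the central distribution in
#' two); otherwise it starts at 0.5, the typical location of depleted
#' events. It gets twice the central spread, and `pi0` starts at 0.95. A
#' floor of `1e-6` on both standard deviations prevents component collapse.
#'
#' For speed the likelihood is evaluated on a 2^15-bin histogram of the
#' values (weighted EM); the discretization error on the fitted parameters
#' is below 1e-6 relative, far inside the statistical uncertainty.
#'
#' @param normalized Normalized coverage vector, or a `DetrendedTrack`.
#' @param exclude Logical vector of values to ignore. Defaults to the
#'   undefined-mask of the detrended track plus exact zeros.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood change below which EM stops.
#' @return A `MixtureFit` with fields `mu0, sigma0, pi0, mu1, sigma1, pi1`,
#'   `n_iter`, `loglik`, `loglik_trace` and `converged`. Component 0 is the
#'   central one (mean nearest 1; ties broken by larger weight).
#' @export
fit_mixture <- function(normalized, exclude = NULL, max_iter = 200L,
                        tol = 1e-6) {
  if (inherits(normalized, "DetrendedTrack")) {
    if (is.null(exclude))
      exclude <- normalized$undefined_mask | normalized$normalized == 0
    normalized <- normalized$normalized
  }
  if (is.null(exclude)) exclude <- normalized == 0
  x <- normalized[!exclude]
  if (length(x) < 100L)
    stop("insufficient data: need at least 100 unmasked values, got ",
         length(x))
  if (any(x < 0)) stop("normalized coverage must be >= 0")
  if (max(x) == min(x))
    stop("degenerate data: all unmasked normalized values are identical")

  mu0 <- median(x)
  s0 <- max(mad(x, center = mu0), SIGMA_FLOOR)
  far <- x[abs(x - mu0) > 3 * s0]
  mu1 <- if (length(far) && abs(mean(far) - mu0) > 3 * s0) mean(far) else 0.5
  s1 <- 2 * s0

  # weighted EM on a fine histogram of the values
  nb <- 32768L
  rng <- range(x)
  mids <- rng[1L] + (seq_len(nb) - 0.5) * diff(rng) / nb
  cnt <- tabulate(pmin(floor((x - rng[1L]) / diff(rng) * nb) + 1L, nb), nb)
  keep <- cnt > 0L
  res <- em_gauss2_cpp(mids[keep], as.numeric(cnt[keep]), mu0, s0, 0.95,
                       mu1, s1, as.integer(max_iter), tol, SIGMA_FLOOR)

  # relabel: the central component is the one whose mean is nearest 1
  d <- abs(res$mu - 1)
  central <- if (d[1] == d[2]) which.max(res$pi) else which.min(d)
  other <- 3L - central
  structure(list(
    mu0 = res$mu[central], sigma0 = res$sigma[central], pi0 = res$pi[central],
    mu1 = res$mu[other], sigma1 = res$sigma[other], pi1 = res$pi[other],
    n_iter = res$n_iter,
    loglik = res$loglik_trace[res$n_iter],
    loglik_trace = res$loglik_trace,
    converged = res$converged,
    n_used = length(x)),
    class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit (k = 2, EM, %d iterations%s)\n",
              x$n_iter, if (x$converged) "" else ", not converged"))
  cat(sprintf("  central: mu0 = %.4f, sigma0 = %.4f, pi0 = %.4f\n",
              x$mu0, x$sigma0, x$pi0))
  cat(sprintf("  outlier: mu1 = %.4f, sigma1 = %.4f, pi1 = %.4f\n",
              x$mu1, x$sigma1, x$pi1))
  invisible(x)
}

#' Per-base z-scores of the normalized coverage
#'
#' `z(b) = (normalized(b) - mu0) / sigma0` against the fitted central
#' distribution. Bases with undefined normalization (running median zero)
#' receive `-Inf`, which is more extreme than any finite threshold and
#' classifies them as low-side candidates. For all other bases the
#' reconstruction identity `(mu0 + z * sigma0) * rm == coverage` holds
#' exactly.
#'
#' @param detrended A `DetrendedTrack`.
#' @param fit A `MixtureFit`.
#' @return Numeric vector of z-scores.
#' @export
zscores <- function(detrended, fit) {
  if (fit$sigma0 <= 0) stop("sigma0 must be positive")
  z <- (detrended$normalized - fit$mu0) / fit$sigma0
  z[detrended$undefined_mask] <- -Inf
  z
}

#' Adaptive coverage thresholds in the original space
#'
#' Maps the fixed z-score thresholds back to coverage units as a function of
#' genome position: `(mu0 + n * sigma0) * RM(b)` on each side. The lower
#' threshold is clipped at zero.
#'
#' @param rm Running-median vector.
#' @param fit A `MixtureFit`.
#' @param spec A [threshold_spec()].
#' @return List with numeric vectors `lower` and `upper`.
#' @export
adaptive_thresholds <- function(rm, fit, spec = threshold_spec()) {
  upper <- (fit$mu0 + spec$n_high * fit$sigma0) * rm
  lower <- pmax((fit$mu0 + spec$n_low * fit$sigma0) * rm, 0)
  list(lower = lower, upper = upper)
}

#' Central mass of the standard normal within +/- n
#'
#' The tolerance interval for a z-score threshold `n`: the fraction of a
#' standard normal between `-n` and `+n`, i.e. `erf(n / sqrt(2))`. For
#' n = 3, 4, 5 this is 99.73%, 99.994%, 99.9999427%.
#'
#' @param n Threshold in z-score units (> 0).
#' @return Fraction in (0, 1).
#' @export
tolerance_interval <- function(n) {
  if (!is.numeric(n) || any(n <= 0)) stop("n must be > 0")
  2 * pnorm(n) - 1
}

#' Expected number of chance outliers in a genome of length G
#'
#' Under a pure standard-normal z-score track, the expected count of bases
#' beyond `+/- n` is `G * (1 - tolerance_interval(n))`: about 2,700 per Mbp
#' at n = 3, about 60-70 at n = 4, about 1 at n = 5.
#'
#' @param G Genome length in bases.
#' @param n Threshold in z-score units.
#' @return Expected outlier count.
#' @export
expected_chance_outliers <- function(G, n) {
  if (!is.numeric(G) || any(G < 0)) stop("G must be >= 0")
  G * (1 - tolerance_interval(n))
}

#' Centralness of a coverage track
#'
#' One minus the proportion of outlier bases (|z| >= n): how preponderant
#' the central distribution is. Equals 1 when there are no outliers; values
#' below 0.5 mean the "central" distribution is not central, and a warning
#' is emitted.
#'
#' @param z Z-score vector over the whole chromosome.
#' @param n Threshold in z-score units.
#' @return Value in \[0, 1\].
#' @export
centralness <- function(z, n) {
  if (length(z) == 0L) stop("empty z-score vector")
  theta <- 1 - sum(z >= n | z <= -n) / length(z)
  if (theta < 0.5)
    warning("centralness ", sprintf("%.3f", theta),
            " is below 0.5: the central distribution is not central")
  theta
}
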