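test_that("EM recovers the generating parameters of a 95/5 mixture", {
  set.seed(11)
  n <- 100000
  lab <- runif(n) < 0.95
  x <- ifelse(lab, rnorm(n, 1, 0.05), rnorm(n, 2, 0.1))
  x <- pmax(x, 0)
  fit <- fit_mixture(x, exclude = rep(FALSE, n))
  expect_lt(abs(fit$mu0 - 1), 0.01)
  expect_lt(abs(fit$sigma0 - 0.05) / 0.05, 0.10)
  expect_lt(abs(fit$pi0 - 0.95), 0.02)
  expect_lt(abs(fit$mu1 - 2), 0.05)
})

test_that("EM is stable in the single-population limit", {
  set.seed(12)
  x <- rnorm(50000, 1, 0.05)
  fit <- fit_mixture(pmax(x, 0), exclude = rep(FALSE, 50000))
  expect_lt(abs(fit$mu0 - 1), 0.01)
  expect_gt(fit$pi0, 0.9)
})

test_that("EM input validation", {
  expect_error(fit_mixture(rep(1.0, 50), exclude = rep(FALSE, 50)),
               "at least 100")
  expect_error(fit_mixture(rep(1.0, 500), exclude = rep(FALSE, 500)),
               "degenerate")
  expect_error(fit_mixture(c(rep(-1, 200)), exclude = rep(FALSE, 200)),
               ">= 0")
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(13)
  x <- pmax(c(rnorm(20000, 1, 0.1), rnorm(1000, 0.4, 0.05)), 0)
  fit <- fit_mixture(x, exclude = rep(FALSE, length(x)))
  expect_true(all(diff(fit$loglik_trace) > -1e-7))
})

test_that("EM parameter recovery holds across a seeded grid of mixtures", {
  grid <- expand.grid(pi0 = c(0.9, 0.95, 0.99), sigma0 = c(0.05, 0.1, 0.2))
  grid <- grid[rep(seq_len(nrow(grid)), length.out = 20), ]
  ok <- logical(20)
  for (i in 1:20) {
    set.seed(100 + i)
    n <- 1e5
    lab <- runif(n) < grid$pi0[i]
    x <- pmax(ifelse(lab, rnorm(n, 1, grid$sigma0[i]), rnorm(n, 2, 0.1)), 0)
    fit <- fit_mixture(x, exclude = rep(FALSE, n))
    ok[i] <- abs(fit$mu0 - 1) < 0.02 &&
      abs(fit$sigma0 - grid$sigma0[i]) / grid$sigma0[i] < 0.15
  }
  expect_gte(sum(ok), 19)
})

test_that("central parameters are stable with respect to the window W", {
  spec <- simulation_spec(G = 1e6, depth = 100, noise = "poisson")
  tr <- simulate_coverage(spec, seed = 5)
  fits <- lapply(c(5001L, 20001L, 100001L), function(W)
    fit_mixture(detrend_track(tr, W = W)))
  mu <- vapply(fits, `[[`, numeric(1), "mu0")
  sg <- vapply(fits, `[[`, numeric(1), "sigma0")
  expect_lt(diff(range(mu)) / mu[2], 0.005)
  expect_lt(diff(range(sg)) / sg[2], 0.10)
})

test_that("z-scores follow the definition and the reconstruction identity", {
  fx <- small_detrended_fixture()
  z <- fx$z
  # definition at single points
  expect_equal(z[100], (fx$det$normalized[100] - fx$fit$mu0) / fx$fit$sigma0)
  d_at <- function(v, mu0, s0) (v - mu0) / s0
  expect_equal(d_at(1.2, 1, 0.1), 2.0)
  expect_equal(d_at(fx$fit$mu0, fx$fit$mu0, fx$fit$sigma0), 0)
  # reconstruction: (mu0 + z sigma0) * RM == coverage, exactly
  unmasked <- !fx$det$undefined_mask
  rec <- (fx$fit$mu0 + z[unmasked] * fx$fit$sigma0) * fx$det$rm[unmasked]
  expect_lt(max(abs(rec - fx$track$coverage[unmasked]) /
                  pmax(fx$track$coverage[unmasked], 1)), 1e-9)
})

test_that("masked bases receive the low-side sentinel z", {
  tr <- coverage_track(c(rep(100, 300), rep(0, 60), rep(100, 300)))
  det <- normalize_track(tr, c(rep(100, 300), rep(0, 60), rep(100, 300)))
  set.seed(30)
  fit <- fit_mixture(pmax(rnorm(5000, 1, 0.1), 0),
                     exclude = rep(FALSE, 5000))
  z <- zscores(det, fit)
  expect_true(all(z[301:360] == -Inf))
  expect_true(all(is.finite(z[-(301:360)])))
})

test_that("adaptive thresholds scale linearly with the running median", {
  fit <- structure(list(mu0 = 1, sigma0 = 0.1), class = "MixtureFit")
  th <- adaptive_thresholds(500, fit, threshold_spec(4, -4, 0.5))
  expect_equal(th$upper, 700)
  expect_equal(th$lower, 300)
  th2 <- adaptive_thresholds(c(400, 500), fit, threshold_spec(4, -4, 0.5))
  expect_equal(th2$upper, c(560, 700))
  # degenerate width: both thresholds collapse onto mu0 * rm
  fit0 <- structure(list(mu0 = 1, sigma0 = 1e-6), class = "MixtureFit")
  th0 <- adaptive_thresholds(500, fit0, threshold_spec(4, -4, 0.5))
  expect_equal(th0$upper, 500, tolerance = 1e-5)
  expect_equal(th0$lower, 500, tolerance = 1e-5)
  # lower threshold clipped at zero
  fitw <- structure(list(mu0 = 1, sigma0 = 0.5), class = "MixtureFit")
  expect_equal(adaptive_thresholds(100, fitw, threshold_spec(4, -4, 1))$lower, 0)
})

test_that("threshold_spec validates and derives inner thresholds", {
  ts <- threshold_spec(4, -4, 0.5)
  expect_equal(ts$m_high, 2)
  expect_equal(ts$m_low, -2)
  expect_error(threshold_spec(-1, -4, 0.5), "n_high")
  expect_error(threshold_spec(4, 1, 0.5), "n_low")
  expect_error(threshold_spec(4, -4, 1.5), "alpha")
})

test_that("tolerance interval equals the normal central mass", {
  # printed as 99.73%, 99.993%, 99.999942% (truncated at the last digit)
  expect_equal(tolerance_interval(3), 0.9973002, tolerance = 1e-6)
  expect_lt(abs(tolerance_interval(4) - 0.99993), 1e-5)
  expect_lt(abs(tolerance_interval(5) - 0.99999942), 1e-8)
  expect_error(tolerance_interval(0), "> 0")
  # Monte-Carlo cross-check at n = 1, 2, 3
  set.seed(21)
  zmc <- rnorm(1e6)
  for (n in 1:3) {
    p <- tolerance_interval(n)
    se <- sqrt(p * (1 - p) / 1e6)
    expect_lt(abs(mean(abs(zmc) <= n) - p), 3 * se)
  }
})

test_that("expected chance outliers match the analytic rate", {
  expect_equal(expected_chance_outliers(1e6, 3), 2699.796, tolerance = 1e-4)
  # quoted as "about 70" for n = 4; exact value is 63.3
  expect_lt(abs(expected_chance_outliers(1e6, 4) - 70), 10)
  expect_lt(expected_chance_outliers(1e6, 5), 1)
  expect_equal(expected_chance_outliers(0, 3), 0)
})

test_that("centralness counts outliers and warns below 0.5", {
  expect_equal(centralness(rep(0, 100), 4), 1)
  z <- c(rep(0, 975), rep(5, 25))
  expect_equal(centralness(z, 4), 0.975)
  expect_warning(centralness(c(rep(10, 60), rep(0, 40)), 4), "below 0.5")
  expect_error(centralness(numeric(0), 4), "empty")
  # sentinel -Inf counts as an outlier
  expect_equal(centralness(c(rep(0, 99), -Inf), 4), 0.99)
})
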