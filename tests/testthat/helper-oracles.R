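# Independent brute-force oracles: each statistic is recomputed per window
# from an explicit sort, with no sharing of state between positions.

# middle order statistic; even counts average the two central values
sorted_median <- function(v) {
  s <- sort(v)
  k <- length(s)
  if (k %% 2L == 1L) s[(k + 1L) %/% 2L] else (s[k %/% 2L] + s[k %/% 2L + 1L]) / 2
}

naive_running_median <- function(x, W, circular = FALSE) {
  n <- length(x)
  V <- (W - 1L) %/% 2L
  vapply(seq_len(n), function(b) {
    idx <- (b - V):(b + V)
    if (circular) {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- idx[idx >= 1L & idx <= n]
    }
    sorted_median(x[idx])
  }, numeric(1))
}

naive_moving_average <- function(x, W, circular = FALSE) {
  n <- length(x)
  V <- (W - 1L) %/% 2L
  vapply(seq_len(n), function(b) {
    idx <- (b - V):(b + V)
    if (circular) {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      idx <- idx[idx >= 1L & idx <= n]
    }
    mean(x[idx])
  }, numeric(1))
}

write_bed_lines <- function(lines, dir = tempdir()) {
  path <- tempfile("cov", tmpdir = dir, fileext = ".bed")
  writeLines(lines, path)
  path
}

# trend-free detrended fixture with a known fitted mixture
small_detrended_fixture <- function(G = 5000, depth = 500, seed = 99) {
  spec <- simulation_spec(G = G, depth = depth, noise = "poisson", seed = seed)
  tr <- simulate_coverage(spec)
  det <- detrend_track(tr, W = 501)
  fit <- fit_mixture(det)
  list(track = tr, det = det, fit = fit, z = zscores(det, fit))
}
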