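test_that("double-threshold clustering follows the hand-worked scans", {
  ts <- threshold_spec(4, -4, 0.5)
  iv <- cluster_rois(c(0, 1, 3, 5, 3, 1, 0), ts, "high")
  expect_equal(unname(iv), cbind(3L, 5L))
  # cluster whose peak stays below n is discarded
  expect_equal(nrow(cluster_rois(c(0, 3, 3, 0), ts, "high")), 0L)
  ivl <- cluster_rois(c(0, -1, -5, -2.5, -1, 0), ts, "low")
  expect_equal(unname(ivl), cbind(3L, 4L))
})

test_that("every n-crossing base is inside an ROI and each ROI reaches n", {
  set.seed(41)
  ts <- threshold_spec(4, -4, 0.5)
  for (rep in 1:20) {
    z <- rnorm(2000, 0, 2)
    for (side in c("high", "low")) {
      iv <- cluster_rois(z, ts, side)
      inside <- logical(2000)
      for (i in seq_len(nrow(iv))) {
        seg <- z[iv[i, 1]:iv[i, 2]]
        if (side == "high") expect_gte(max(seg), 4) else expect_lte(min(seg), -4)
        # every base in the cluster satisfies the inner threshold
        if (side == "high") expect_true(all(seg >= 2))
        else expect_true(all(seg <= -2))
        inside[iv[i, 1]:iv[i, 2]] <- TRUE
      }
      beyond <- if (side == "high") z >= 4 else z <= -4
      expect_true(all(inside[beyond]))
    }
  }
})

test_that("clustering is invariant to flanking sub-threshold noise", {
  set.seed(42)
  ts <- threshold_spec(4, -4, 0.5)
  z <- c(0, 1, 3, 5, 3, 1, 0)
  pad <- runif(50, -1.9, 1.9)
  iv0 <- cluster_rois(z, ts, "high")
  iv1 <- cluster_rois(c(pad, z, pad), ts, "high")
  expect_equal(iv1[, "start"] - 50L, iv0[, "start"])
  expect_equal(iv1[, "end"] - 50L, iv0[, "end"])
})

test_that("an event spanning the circular origin is one ROI", {
  n <- 400L
  z <- rep(0, n)
  z[c(391:400, 1:10)] <- 5          # 20-base event across the origin
  iv <- cluster_rois(z, threshold_spec(), "high", circular = TRUE)
  expect_equal(nrow(iv), 1L)
  expect_equal(unname(iv[1, ]), c(391L, 410L))  # end beyond n = wraps
  # and detection is rotation invariant: rotating z rotates the single ROI
  for (r in c(5L, 200L)) {
    zr <- c(z[(r + 1):n], z[1:r])
    ivr <- cluster_rois(zr, threshold_spec(), "high", circular = TRUE)
    expect_equal(nrow(ivr), 1L)
    expect_equal((ivr[1, "end"] - ivr[1, "start"]) %% n,
                 (iv[1, "end"] - iv[1, "start"]) %% n)
    expect_equal((ivr[1, "start"] + r - 1L) %% n + 1L,
                 (iv[1, "start"] - 1L) %% n + 1L)
  }
})

test_that("masked sentinel bases cluster on the low side", {
  z <- c(rep(0, 10), rep(-Inf, 5), rep(0, 10))
  iv <- cluster_rois(z, threshold_spec(), "low")
  expect_equal(unname(iv), cbind(11L, 15L))
  expect_equal(nrow(cluster_rois(z, threshold_spec(), "high")), 0L)
})

test_that("ROI annotation computes the copy-number ratio and z statistics", {
  tr <- coverage_track(c(200, 220))
  det <- normalize_track(tr, c(100, 110))
  fit <- structure(list(mu0 = 1, sigma0 = 0.1), class = "MixtureFit")
  z <- zscores(det, fit)
  roi <- annotate_roi(c(1L, 2L), tr, det, z, side = "high")
  expect_equal(roi$cn_ratio, 2.0)
  expect_equal(roi$log2_ratio, 1.0)
  expect_equal(roi$mean_cov, 210)
  expect_equal(roi$mean_rm, 105)
  expect_equal(roi$max_zscore, max(z[1:2]))

  # coverage equal to RM: cn 1, log2 0
  tr1 <- coverage_track(c(100, 100))
  det1 <- normalize_track(tr1, c(100, 100))
  roi1 <- annotate_roi(c(1L, 2L), tr1, det1, zscores(det1, fit), "high")
  expect_equal(roi1$cn_ratio, 1)
  expect_equal(roi1$log2_ratio, 0)

  # fully masked ROI: z statistics undefined, low-side max is the minimum
  tr0 <- coverage_track(c(0, 0, 50))
  det0 <- normalize_track(tr0, c(0, 0, 50))
  roi0 <- annotate_roi(c(1L, 2L), tr0, det0, zscores(det0, fit), "low")
  expect_true(is.na(roi0$mean_zscore))
  expect_true(is.na(roi0$cn_ratio))
  expect_error(annotate_roi(c(3L, 2L), tr0, det0, zscores(det0, fit), "low"),
               "zero-length")
})

test_that("low-side max_zscore is the signed extremum", {
  fx <- small_detrended_fixture()
  iv <- cluster_rois(fx$z, threshold_spec(2.5, -2.5, 0.5), "low")
  if (nrow(iv)) {
    rois <- annotate_rois(iv, fx$track, fx$det, fx$z, side = "low")
    expect_true(all(rois$max_zscore <= rois$mean_zscore))
  }
  expect_gt(nrow(iv), 0)  # 2.5 sigma events exist in 5 kb of Poisson noise
})

test_that("merging joins nearby same-side ROIs only", {
  fx <- small_detrended_fixture()
  ts <- threshold_spec(2.5, -2.5, 0.5)
  ivh <- cluster_rois(fx$z, ts, "high")
  ivl <- cluster_rois(fx$z, ts, "low")
  rois <- rbind(annotate_rois(ivh, fx$track, fx$det, fx$z, "high"),
                annotate_rois(ivl, fx$track, fx$det, fx$z, "low"))
  rois <- rois[order(rois$start), ]
  expect_identical(merge_close_rois(rois, 0L, fx$track, fx$det, fx$z), rois)
  merged <- merge_close_rois(rois, 5000L, fx$track, fx$det, fx$z)
  expect_equal(sum(merged$side == "high"), 1L)  # gap 5000 >= track span
  expect_equal(sum(merged$side == "low"), 1L)   # sides never merge
  expect_error(merge_close_rois(rois, -1L, fx$track, fx$det, fx$z), "max_gap")

  # hand-worked merge of two high ROIs
  tr <- coverage_track(rep(100, 50))
  det <- normalize_track(tr, rep(100, 50))
  fit <- structure(list(mu0 = 1, sigma0 = 0.1), class = "MixtureFit")
  z <- zscores(det, fit)
  r2 <- annotate_rois(cbind(start = c(10L, 31L), end = c(20L, 40L)),
                      tr, det, z, side = "high")
  m2 <- merge_close_rois(r2, 50L, tr, det, z)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$start, 10L)
  expect_equal(m2$end, 40L)
})

test_that("the copy-number filter removes weak and short events", {
  base <- empty_roi <- annotate_rois(
    cbind(start = 1L, end = 2L),
    coverage_track(c(100, 100)),
    normalize_track(coverage_track(c(100, 100)), c(100, 100)),
    c(0, 0), side = "high")
  mk <- function(mean_z, size) {
    r <- base
    r$mean_zscore <- mean_z
    r$size <- size
    r
  }
  expect_equal(nrow(filter_rois(mk(4.2, 300), 5, 100)), 0L)
  expect_equal(nrow(filter_rois(mk(6, 50), 5, 100)), 0L)
  expect_equal(nrow(filter_rois(mk(6, 300), 5, 100)), 1L)
  expect_equal(nrow(filter_rois(mk(-6, 300), 5, 100)), 1L)
  # plain ROI mode defaults keep everything
  expect_equal(nrow(filter_rois(mk(0.1, 1), 0, 1)), 1L)
  # undefined mean z (fully deleted region) passes the z criterion
  expect_equal(nrow(filter_rois(mk(NA_real_, 300), 5, 100)), 1L)
})
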