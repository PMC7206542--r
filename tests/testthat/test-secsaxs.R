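test_that("series construction enforces ordering and shapes", {
  q <- seq(0.01, 1, length.out = 20)
  X <- matrix(1, 20, 10)
  expect_error(sec_series(X, q, 10:1), "increasing")
  expect_error(sec_series(X, q[1:5], 1:10), "one row per q")
  expect_error(sec_series(X, q, 1:9), "one column per frame")
  s <- sec_series(X, q, 1:10)
  expect_s3_class(s, "sec_series")
})

test_that("chromatograms integrate q-ranges and are additive", {
  q <- seq(0.01, 1, length.out = 50)
  tt <- seq(2, 40, by = 2)
  X <- matrix(3, 50, length(tt))
  ser <- sec_series(X, q, tt)
  ch <- xray_chromatogram(ser, list(c(0.02, 0.5)))
  expect_true(all(ch[[2]] == 3))                 # flat series, flat trace
  expect_error(xray_chromatogram(ser, list(c(2, 3))), "empty q-range")
  # additivity: chromatogram(A + B) = chromatogram(A) + chromatogram(B)
  set.seed(2)
  XA <- matrix(runif(50 * 20), 50, 20); XB <- matrix(runif(50 * 20), 50, 20)
  sA <- sec_series(XA, q, tt); sB <- sec_series(XB, q, tt)
  sAB <- sec_series(XA + XB, q, tt)
  expect_equal(xray_chromatogram(sAB, list(c(0.05, 0.9)))[[2]],
               xray_chromatogram(sA, list(c(0.05, 0.9)))[[2]] +
                 xray_chromatogram(sB, list(c(0.05, 0.9)))[[2]])
  # string q-range parsing
  ch2 <- xray_chromatogram(ser, "0.02:0.5,0.6:0.9")
  expect_identical(ncol(ch2), 3L)
})

test_that("elution peaks appear at the right time and separate by q-range", {
  ser <- generate_sec_run(fix_sec_spec(), seed = 42)
  ch <- xray_chromatogram(ser, list(c(0.02, 0.12)))
  pk_t <- ch$time[which.max(ch[[2]])]
  expect_lt(abs(pk_t - 600), 2.01)               # within one frame interval
  # two species with different q-dependence and elution times
  spec2 <- sec_run_spec(
    species = list(
      list(model = function(q) 1.5 * sphere_intensity(q, 45), center = 400,
           width = 30, conc = 1),
      list(model = function(q) 0.8 * sphere_intensity(q, 15), center = 700,
           width = 30, conc = 1)),
    drift_alpha = 0, run_length = 1200, counts_scale = 2000)
  ser2 <- generate_sec_run(spec2, seed = 5)
  chA <- xray_chromatogram(ser2, list(c(0.01, 0.03)))[[2]]   # very low q
  chB <- xray_chromatogram(ser2, list(c(0.15, 0.3)))[[2]]    # higher q
  tt <- ser2$frame_times
  # big species dominates at very low q, small species relatively stronger
  # at higher q: the peak-height ratio between species flips between ranges
  hA <- c(max(chA[tt < 550]), max(chA[tt > 550]))
  hB <- c(max(chB[tt < 550]), max(chB[tt > 550]))
  expect_gt(hA[1] / hA[2], hB[1] / hB[2])
  # 2D map carries both ridges: two local maxima in the low-q chromatogram
  sm <- stats::filter(chA, rep(1 / 9, 9))
  pk <- which(diff(sign(diff(sm))) == -2) + 1
  pk <- pk[sm[pk] > stats::median(sm, na.rm = TRUE) + 3 * stats::mad(sm, na.rm = TRUE)]
  expect_gte(length(pk), 2)
})

test_that("intensity map mirrors the frame matrix", {
  ser <- generate_sec_run(fix_sec_spec(frame_interval = 20),
                          q = seq(0.01, 2.4, length.out = 80), seed = 1)
  m <- intensity_map(ser)
  expect_identical(dim(m$z), dim(ser$frames))
  expect_identical(m$z[, 7], ser$frames[, 7])
  ml <- intensity_map(ser, log_intensity = TRUE)
  expect_equal(ml$z[, 3], log10(ser$frames[, 3]))
})

test_that("UV/X-ray time offset is recovered from the split flow", {
  ser <- generate_sec_run(fix_sec_spec(), seed = 42)
  off <- align_uv_offset(ser)
  expect_lt(abs(off - 30), 2.01)                 # within one frame
  # identical traces align at zero
  ch <- xray_chromatogram(ser, list(c(0.005, 0.26)))
  ser_id <- ser; ser_id$uv <- data.frame(time = ch$time, value = ch[[2]])
  expect_identical(align_uv_offset(ser_id), 0)
  # featureless UV trace warns and returns 0
  set.seed(3)
  ser_n <- ser; ser_n$uv <- data.frame(time = ch$time, value = rnorm(nrow(ch)))
  expect_warning(off0 <- align_uv_offset(ser_n), "alignment failure")
  expect_identical(off0, 0)
})

test_that("normal-mode background averages the selected frames", {
  q <- seq(0.01, 1, length.out = 30)
  X <- matrix(rep(water_intensity(q, amplitude = 0), 12), 30, 12)
  ser <- sec_series(X, q, 1:12, sigma = matrix(0.1, 30, 12))
  nb <- normal_background(ser, c(1, 5, 9))
  expect_equal(nb$I, X[, 1])                     # identical frames
  expect_error(normal_background(ser, integer(0)), "non-empty")
  # pre-peak selection matches the generator buffer within noise
  run <- generate_sec_run(fix_sec_spec(drift_alpha = 0), seed = 6)
  pre <- 1:40
  nb2 <- normal_background(run, pre)
  truth <- run$meta$truth$water
  z <- (nb2$I - truth) / nb2$sigma
  expect_gt(mean(abs(z) < 3), 0.99)
  # selecting elution frames inflates the low-q background (documented misuse)
  bad <- normal_background(run, 295:305)
  lowq <- run$q < 0.1
  expect_gt(mean(bad$I[lowq] - truth[lowq]), 10 * mean(nb2$sigma[lowq]))
})

test_that("SVD background is exact for separable rank-1 drift", {
  q <- seq(0.01, 2.5, length.out = 120)
  tt <- seq(1, 600, by = 3)
  B <- water_intensity(q)
  for (slope in c(0.001, -0.0008)) {             # rising and falling drifts
    X <- outer(B, 1 + slope * tt)
    ser <- sec_series(X, q, tt)
    bg <- svd_background(ser, c(80, 120), rank = 1, interp = "linear")
    expect_lt(max(abs(bg$background - X)), 1e-12 * max(X))
    bg_s <- svd_background(ser, c(80, 120), rank = 1, interp = "spline")
    expect_lt(max(abs(bg_s$background - X)), 1e-9 * max(X))
  }
})

test_that("SVD background never sees the window frames", {
  q <- seq(0.01, 2.5, length.out = 60)
  tt <- seq(1, 300, by = 3)
  set.seed(12)
  X <- outer(water_intensity(q), 1 + 0.001 * tt) +
    matrix(rnorm(60 * length(tt), 0, 0.01), 60)
  ser <- sec_series(X, q, tt)
  bg1 <- svd_background(ser, c(40, 60), rank = 2)
  X2 <- X; X2[, 45:55] <- X2[, 45:55] * 7       # perturb inside the window
  bg2 <- svd_background(sec_series(X2, q, tt), c(40, 60), rank = 2)
  expect_identical(bg1$background, bg2$background)
  # window validation
  expect_error(svd_background(ser, c(2, 50)), "5 frames")
  expect_error(svd_background(ser, c(40, length(tt))), "5 frames")
  expect_error(svd_background(ser, c(40, 60), rank = 1e5), "rank")
})

test_that("noisy drifting run: background recovery and end-to-end Rg", {
  ser <- generate_sec_run(fix_sec_spec(), seed = 42)
  win <- c(250, 350)                             # 500-700 s at 2 s frames
  bg <- svd_background(ser, win, rank = "auto")
  expect_lte(bg$k, 5)
  truth <- ser$meta$truth$buffer_matrix
  inwin <- seq(win[1], win[2])
  rmse <- sqrt(mean((bg$background[, inwin] - truth[, inwin])^2))
  expect_lt(rmse, 2 * mean(ser$sigma[, inwin]))
  sub <- subtract_sec_background(ser, bg)
  # protein profile at the elution peak within 3 sigma of generator truth
  pkf <- which.min(abs(ser$frame_times - 600))
  prot_truth <- 0.6 * sphere_intensity(ser$q, 30) *
    ser$meta$truth$conc[pkf, 1] / 0.6 * 0.6
  z <- (sub$frames[, pkf] - prot_truth) / sub$sigma[, pkf]
  expect_gt(mean(abs(z) < 3, na.rm = TRUE), 0.99)
  gf <- guinier_fit(sec_frame_profile(sub, pkf))
  expect_lt(abs(gf$Rg - 30 * sqrt(3 / 5)) / (30 * sqrt(3 / 5)), 0.05)
  # subtract-then-re-add reproduces the original frames
  neg <- bg; neg$background <- -bg$background
  re <- subtract_sec_background(sub, neg)
  expect_equal(re$frames, ser$frames, tolerance = 1e-12)
})
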