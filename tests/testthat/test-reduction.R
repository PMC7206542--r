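test_that("constant field averages exactly with Poisson sigma", {
  g <- fix_geom(shape = c(96, 96))
  pat <- xs_pattern(matrix(7, 96, 96), g)
  pr <- azimuthal_average(pat, n_bins = 200)
  ok <- !pr$empty
  expect_true(all(pr$I[ok] == 7))
  expect_equal(pr$sigma[ok], sqrt(7 / pr$n[ok]))
  # conservation: sum I*n over bins equals the summed pixel counts exactly
  expect_identical(sum(pr$I[ok] * pr$n[ok]), sum(pat$counts))
})

test_that("masked pixels never contribute; checkerboard halves counts", {
  g <- fix_geom(shape = c(96, 96))
  pat_full <- xs_pattern(matrix(9, 96, 96), g)
  chk <- outer(1:96, 1:96, function(i, j) (i + j) %% 2 == 0)
  pat_half <- xs_pattern(matrix(9, 96, 96), g, mask = chk)
  edges <- q_bin_edges(0.05, 3.5, 60)   # coarse bins so each keeps pixels
  pf <- azimuthal_average(pat_full, q_edges = edges)
  ph <- azimuthal_average(pat_half, q_edges = edges)
  both <- !pf$empty & !ph$empty & ph$n > 10
  expect_true(all(ph$I[both] == 9))
  # roughly half the pixels -> sigma inflated by ~sqrt(2)
  expect_equal(ph$sigma[both] / pf$sigma[both],
               sqrt(pf$n[both] / ph$n[both]), tolerance = 1e-12)
  expect_equal(median(pf$n[both] / ph$n[both]), 2, tolerance = 0.05)
  # fully masked pattern is an error
  expect_error(azimuthal_average(
    xs_pattern(matrix(1, 96, 96), g, mask = matrix(FALSE, 96, 96))),
    "masked")
  # shape mismatch is an error
  qm_other <- qmap_from_geometry(fix_geom(shape = c(64, 64)))
  expect_error(azimuthal_average(pat_full, qmap = qm_other), "shape")
})

test_that("rendered images round-trip to the generating profile", {
  g <- fix_geom(shape = c(128, 128))
  model <- fix_water_model(500)
  hits <- 0; total <- 0
  for (seed in 1:5) {
    pat <- render_detector_image(model, g, seed = seed)
    pr <- azimuthal_average(pat, n_bins = 300)
    ok <- !pr$empty & pr$n >= 20
    truth <- model(pr$q[ok])
    z <- abs(pr$I[ok] - truth) / pr$sigma[ok]
    hits <- hits + sum(z < 3); total <- total + length(z)
  }
  expect_gt(hits / total, 0.99)
})

test_that("exposure scaling cancels in normalized profiles", {
  g <- fix_geom(shape = c(64, 64))
  base <- matrix(40, 64, 64)
  p1 <- azimuthal_average(xs_pattern(base, g, exposure = 1), n_bins = 100,
                          normalize = TRUE)
  p3 <- azimuthal_average(xs_pattern(3 * base, g, exposure = 3), n_bins = 100,
                          normalize = TRUE)
  ok <- !p1$empty
  expect_equal(p1$I[ok], p3$I[ok])
})

test_that("merge scale factor is the squared distance ratio", {
  ref <- fix_geom(distance = 1000, label = "saxs")
  expect_identical(merge_scale_factor(ref, ref), 1)
  g2 <- fix_geom(distance = 2000, label = "x")
  expect_equal(merge_scale_factor(g2, ref), 4)
  g3 <- fix_geom(distance = 300, label = "waxs")
  expect_equal(merge_scale_factor(g3, ref), 0.09)
  g4 <- fix_geom(distance = 300, pixel = 0.5)
  expect_error(merge_scale_factor(g4, ref), "pixel size")
})

test_that("merging two copies of a profile reproduces it", {
  q <- seq(0.01, 1, length.out = 120)
  set.seed(4)
  p <- fix_noisy_profile(sphere_intensity(q, 30, I0 = 50) + 1, q)
  m <- merge_profiles(list(p, p))
  expect_equal(m$q, p$q)
  expect_equal(m$I, p$I)
  # commutativity in input order
  p2 <- fix_noisy_profile(sphere_intensity(q, 30, I0 = 50) + 1, q)
  m12 <- merge_profiles(list(p, p2))
  m21 <- merge_profiles(list(p2, p))
  expect_equal(m12$I, m21$I)
})

test_that("two-detector render merges within noise after distance scaling", {
  g_s <- fix_geom(distance = 1000, shape = c(160, 160), label = "saxs")
  g_w <- fix_geom(distance = 300, shape = c(160, 160), label = "waxs")
  model <- function(q) 200 * sphere_intensity(q, 30) + 20
  ps <- azimuthal_average(
    render_detector_image(model, g_s, seed = 2, ref_distance = 1000),
    n_bins = 300)
  pw <- azimuthal_average(
    render_detector_image(model, g_w, seed = 3, ref_distance = 1000),
    n_bins = 300)
  cfg <- detector_config(list(g_s, g_w), reference = "saxs")
  m <- merge_profiles(list(ps, pw), cfg)
  expect_equal(m$meta$scales, c(1, 0.09))
  expect_lt(m$meta$overlap_discrepancy[["1-2"]], 3)
  # union property: endpoints equal min/max of the inputs
  expect_equal(min(m$q), min(ps$q))
  expect_equal(max(m$q), max(pw$q))
})

test_that("disjoint q ranges merge with flagged gap bins", {
  q1 <- seq(0.01, 0.2, length.out = 50)
  q2 <- seq(0.8, 1.2, length.out = 50)
  p1 <- xs_profile(q1, rep(2, 50), sigma = rep(0.1, 50))
  p2 <- xs_profile(q2, rep(1, 50), sigma = rep(0.1, 50))
  expect_warning(m <- merge_profiles(list(p1, p2)), "gap")
  expect_true(any(m$empty))
  expect_false(is.null(m$meta$gaps))
})

test_that("frame averaging weights, excludes and propagates correctly", {
  q <- seq(0.1, 1, length.out = 40)
  mk <- function(v) xs_profile(q, rep(v, 40), sigma = rep(0.2, 40))
  frames <- list(mk(1), mk(1), mk(1), mk(1), mk(10))
  avg <- average_profiles(frames, exclude = 5)
  expect_true(all(avg$I == 1))
  expect_identical(avg$meta$excluded_frames, 5)
  # excluding the first of five identical frames returns the common frame
  same <- replicate(5, mk(3), simplify = FALSE)
  expect_true(all(average_profiles(same, exclude = 1)$I == 3))
  expect_error(average_profiles(frames, exclude = 1:5), "all frames")
  # Poisson replicates: averaged sigma ~ single/sqrt(n)
  set.seed(8)
  reps <- replicate(16, fix_noisy_profile(water_intensity(q), q, scale = 500),
                    simplify = FALSE)
  av <- average_profiles(reps)
  ratio <- mean(reps[[1]]$sigma / av$sigma)
  expect_equal(ratio, 4, tolerance = 0.1)
})

test_that("ASCII export writes a parseable header and survives a round trip", {
  q <- seq(0.02, 0.5, length.out = 3)
  p <- xs_profile(q, c(1.23456789, 2.3456, 0.0012345),
                  sigma = c(0.1, 0.02, 0.0001))
  f <- withr::local_tempfile(fileext = ".dat")
  export_ascii(p, f, sample = "lys1", buffer = "buf1",
               geometry = fix_geom(distance = 1000, label = "saxs"))
  ln <- readLines(f)
  expect_length(grep("^#", ln), 5)
  expect_true(any(grepl("wavelength_A: 0.918400", ln)))
  expect_true(any(grepl("buffer: buf1", ln)))
  expect_identical(sum(!grepl("^#", ln)), 3L)
  p2 <- read_ascii(f)
  expect_equal(p2$q, p$q, tolerance = 1e-6)
  expect_equal(p2$I, p$I, tolerance = 1e-6)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-6)
})

test_that("bundles round-trip profiles, SEC records and attributes exactly", {
  q <- seq(0.01, 2.4, length.out = 100)
  set.seed(21)
  prof <- fix_noisy_profile(water_intensity(q), q)
  ser <- generate_sec_run(fix_sec_spec(frame_interval = 20),
                          q = seq(0.01, 2.4, length.out = 60), seed = 3)
  d <- withr::local_tempdir()
  bpath <- file.path(d, "run1")
  cfg <- detector_config(list(fix_geom(distance = 1000, label = "saxs")))
  pack_bundle(list(lys1 = list(processed = prof, buffer_name = "buf1",
                               holder = "H1", channel = "A"),
                   buf1 = list(processed = prof),
                   secrun = list(sec = ser)),
              bpath, instrument = cfg)
  b <- read_bundle(bpath)
  expect_identical(b$samples$lys1$buffer_name, "buf1")
  expect_identical(b$samples$lys1$processed$I, prof$I)
  expect_identical(b$samples$lys1$processed$sigma, prof$sigma)
  expect_identical(b$samples$secrun$sec$frames, ser$frames)
  expect_identical(b$samples$secrun$sec$frame_times, ser$frame_times)
  expect_identical(nrow(b$samples$secrun$sec$uv), length(ser$frame_times))
  expect_equal(b$meta$instrument$saxs$distance_mm, 1000)
  expect_error(pack_bundle(list(a = list(), a = list()), file.path(d, "x")),
               "unique")
})
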