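test_that("static dose at the printed beam conditions is about 3.5 kGy", {
  d <- dose_static(beam_conditions())
  expect_equal(d, 3.5, tolerance = 0.15)
  # exact linearity in flux
  b2 <- beam_conditions(flux = 4.6e12)
  expect_equal(dose_static(b2), 2 * d)
  # thin-sample limit: dose -> flux E mu t_exp / (rho area)
  b <- beam_conditions()
  mu <- 1e-6
  thin <- b$flux * b$energy * 1.602176634e-16 * mu * (b$path / 10) *
    b$exposure / ((b$beam_w / 10) * (b$beam_h / 10) * (b$path / 10) * 1e-3) / 1000
  expect_equal(dose_static(b, mu_en_over_rho = mu), thin, tolerance = 1e-4)
})

test_that("flowing dose is bounded by the static dose", {
  b <- beam_conditions()
  df <- dose_flowing(b)
  expect_lt(df, dose_static(b))
  expect_match(attr(df, "assumption"), "uniform absorption")
  # order of magnitude 0.1-0.3 kGy at the typical 10 ul/s flow
  expect_gt(as.numeric(df), 0.1)
  expect_lt(as.numeric(df), 0.3)
  # flow -> 0 limit recovers the static dose
  b0 <- b; b0$flow_rate <- 1e-12
  expect_equal(as.numeric(dose_flowing(b0)), dose_static(b), tolerance = 1e-6)
  # at large flow, doubling the rate nearly halves the dose
  bf <- b; bf$flow_rate <- 1000
  bf2 <- b; bf2$flow_rate <- 2000
  expect_equal(as.numeric(dose_flowing(bf)) / as.numeric(dose_flowing(bf2)), 2,
               tolerance = 0.001)
})

test_that("energy-absorption interpolation matches the NIST anchors", {
  expect_equal(mu_en_water(10), 4.944)
  expect_equal(mu_en_water(15), 1.374)
  expect_equal(mu_en_water(20), 0.5503)
  expect_true(mu_en_water(13.5) < 4.944 && mu_en_water(13.5) > 1.374)
  expect_warning(mu_en_water(25), "extrapolation")
})

test_that("tubing metrics follow the geometry formulas", {
  r <- tubing_metrics(1, 0.01, 0.5)
  expect_equal(r$volume_ul, 50.7, tolerance = 0.005)
  expect_equal(r$transit_s, 6.1, tolerance = 0.005)
  # consistent with the printed "<50 ul, <6 s" rounding
  expect_lt(r$volume_ul, 51)
  expect_lt(r$transit_s, 6.2)
  z <- tubing_metrics(0, 0.01, 0.5)
  expect_identical(z$volume_ul, 0)
  expect_identical(z$transit_s, 0)
  # quadratic in diameter, linear in length
  expect_equal(tubing_metrics(1, 0.02, 0.5)$volume_ul, 4 * r$volume_ul)
  expect_equal(tubing_metrics(2, 0.01, 0.5)$volume_ul, 2 * r$volume_ul)
  expect_equal(tubing_metrics(2, 0.01, 0.5)$transit_s, 2 * r$transit_s)
})

test_that("concurrent scheduling overlaps wash with measurement", {
  # typical timings: 90 s measure, 60 s wash
  seq1 <- schedule_sim(90, 60, 360, n_channels = 1)
  con2 <- schedule_sim(90, 60, 360, n_channels = 2)
  expect_equal(seq1$cycle_s, 150)
  expect_equal(con2$cycle_s, 90)
  expect_equal(1 - con2$cycle_s / seq1$cycle_s, 0.4)    # 40% shorter
  expect_equal(con2$makespan_h, 9.0)                    # 360 samples, 9 h
  # zero wash: concurrency gains nothing
  expect_equal(schedule_sim(90, 0, 50, 1)$makespan_s,
               schedule_sim(90, 0, 50, 2)$makespan_s)
  # wash longer than measure: the two alternating channels deliver one
  # sample per (measure + wash) / 2 at steady state
  expect_equal(schedule_sim(60, 100, 50, 2)$cycle_s, 80)
  # concurrent never slower than sequential (randomized timings)
  set.seed(14)
  for (i in 1:25) {
    m <- runif(1, 10, 200); w <- runif(1, 0, 200)
    n <- sample(5:50, 1)
    expect_lte(schedule_sim(m, w, n, 2)$makespan_s,
               schedule_sim(m, w, n, 1)$makespan_s)
  }
})

test_that("SEC run duration doubles the bed volume", {
  expect_equal(sec_run_duration(3, 0.35), 17.1, tolerance = 0.005)
  expect_equal(sec_run_duration(24, 0.5), 96)
  expect_equal(sec_run_duration(3, 0.7), sec_run_duration(3, 0.35) / 2)
})

test_that("sample-sheet validation enumerates the scheduling rules", {
  ok_sheet <- sample_sheet(data.frame(
    holder = "H1", position = 1:4, row = c("A", "A", "B", "B"),
    name = c("lys1", "bufA", "vir1", "bufB"),
    buffer = c("bufA", "", "bufB", ""),
    is_buffer = c(FALSE, TRUE, FALSE, TRUE)))
  expect_identical(nrow(validate_sample_sheet(ok_sheet)), 0L)
  # duplicate names
  dup <- sample_sheet(data.frame(
    holder = "H1", position = 1:2, row = "A", name = c("lys1", "lys1"),
    buffer = "", is_buffer = TRUE))
  expect_true("duplicate_name" %in% validate_sample_sheet(dup)$type)
  # sample in row A, buffer in row B -> channel mismatch
  mis <- sample_sheet(data.frame(
    holder = "H1", position = 1:2, row = c("A", "B"),
    name = c("lys1", "bufA"), buffer = c("bufA", ""),
    is_buffer = c(FALSE, TRUE)))
  expect_true("channel_mismatch" %in% validate_sample_sheet(mis)$type)
  # missing buffer
  nob <- sample_sheet(data.frame(
    holder = "H1", position = 1, row = "A", name = "lys1", buffer = "bufZ",
    is_buffer = FALSE))
  expect_true("missing_buffer" %in% validate_sample_sheet(nob)$type)
  # duplicate position and out-of-range position
  posbad <- sample_sheet(data.frame(
    holder = "H1", position = c(3, 3, 25), row = "A",
    name = c("b1", "b2", "b3"), buffer = "", is_buffer = TRUE))
  v <- validate_sample_sheet(posbad)
  expect_true(all(c("duplicate_position", "invalid_position") %in% v$type))
  # storage slots: duplicates and out of range
  cfg <- data.frame(holder = c("H1", "H2", "H3"), slot = c(4, 4, 33))
  v2 <- validate_sample_sheet(sample_sheet(ok_sheet$holders, cfg))
  expect_true(all(c("slot_conflict", "invalid_slot") %in% v2$type))
  # order independence of the violation set
  shuf <- sample_sheet(posbad$holders[c(3, 1, 2), ])
  expect_identical(validate_sample_sheet(shuf)$detail,
                   validate_sample_sheet(posbad)$detail)
  # empty sheet passes
  empty <- sample_sheet(ok_sheet$holders[0, ])
  expect_identical(nrow(validate_sample_sheet(empty)), 0L)
})

test_that("sample sheets load from CSV with violations located", {
  d <- withr::local_tempdir()
  f <- file.path(d, "holders.csv")
  writeLines(c("holder,position,row,name,buffer,is_buffer",
               "H1,1,A,lys1,bufA,FALSE",
               "H1,2,A,bufA,,TRUE"), f)
  sheet <- read_sample_sheet(f)
  expect_identical(nrow(validate_sample_sheet(sheet)), 0L)
  f2 <- file.path(d, "bad.csv")
  writeLines(c("holder,position", "H1,1"), f2)
  expect_error(read_sample_sheet(f2), "missing columns")
})

test_that("sample arrival is the first sustained pulse above median + 6 MAD", {
  set.seed(19)
  base <- rnorm(100, 10, 0.5)
  expect_identical(detect_sample_arrival(base), NA_integer_)
  pulse <- base; pulse[40:45] <- 100
  expect_identical(detect_sample_arrival(pulse), 40L)
  # single-point spike does not satisfy the sustain rule
  spike <- base; spike[100] <- 100
  expect_identical(detect_sample_arrival(spike), NA_integer_)
  expect_error(detect_sample_arrival(1:5), "at least 10")
})
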