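test_that("missingness fraction follows the duration x rate denominator", {
  # 301 frames spanning 60 s at 5 Hz, all valid -> 0
  full <- make_raw_recording(seq(0, 60, by = 0.2))
  expect_equal(missingness_fraction(full, 5), 0)
  # half the expected frames valid -> 0.5
  half <- make_raw_recording(seq(0, 60, by = 0.2),
                             valid = rep(c(TRUE, FALSE), length.out = 301))
  expect_equal(missingness_fraction(half, 5), 1 - 151 / 300,
               tolerance = 0.01)
  single <- make_raw_recording(3)
  expect_error(missingness_fraction(single, 5), "single timestamp")
})

test_that("generator drop fraction is recovered from the data", {
  fr <- vapply(1:4, function(s) {
    dir <- withr::local_tempdir()
    simulate_raw_trace_csv(dir, n_subjects = 2, duration = 120,
                           drop_fraction = 0.2, seed = s)
    raws <- read_trace_folder(dir, trace_column_map())
    mean(vapply(raws, missingness_fraction, numeric(1), expected_rate = 5))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.2), 0.02)
})

test_that("missingness filtering is strict at the threshold", {
  mk <- function(frac) {
    t_n <- 301
    make_raw_recording(seq(0, 60, by = 0.2),
                       valid = seq_len(t_n) <= round((1 - frac) * 300),
                       participant = sprintf("P%.2f", frac))
  }
  raws <- list(mk(0.1), mk(0.29), mk(0.31))
  res <- suppressMessages(
    filter_by_missingness(raws, preproc_config(max_missing_fraction = 0.3)))
  expect_length(res$kept, 2)
  expect_equal(nrow(res$excluded), 1)
  expect_equal(res$excluded$participant, "P0.31")
  # vacuous threshold keeps everything
  all_kept <- filter_by_missingness(raws,
                                    preproc_config(max_missing_fraction = 1))
  expect_length(all_kept$kept, 3)
  expect_equal(length(res$kept) + nrow(res$excluded), length(raws))
})

test_that("linear resampling is exact on affine signals and preserves constants", {
  set.seed(1)
  times <- sort(runif(80, 0, 20))
  affine <- lapply(times, function(t) {
    tpl <- as.matrix(face_template()[, c("x", "y")])
    tpl + 2 * t + 1          # every channel follows 2t + 1 up to offset
  })
  raw <- make_raw_recording(times, coords = affine)
  rec <- resample_to_grid(raw, preproc_config(target_rate = 5))
  expect_equal(diff(rec$time), rep(0.2, length(rec$time) - 1))
  tpl <- as.matrix(face_template()[, c("x", "y")])
  for (i in c(1, length(rec$time))) {
    expect_equal(rec$landmarks[i, , 1], tpl[, 1] + 2 * rec$time[i] + 1,
                 tolerance = 1e-10)
  }
  # constant positions survive 40% dropped frames untouched
  set.seed(2)
  keep <- runif(80) > 0.4
  raw_c <- make_raw_recording(times, valid = keep)
  rec_c <- resample_to_grid(raw_c, preproc_config(target_rate = 5))
  expect_equal(rec_c$landmarks[1, , 1],
               rec_c$landmarks[length(rec_c$time), , 1])
  expect_false(anyNA(rec_c$landmarks))
})

test_that("dense irregular sampling of a sine resamples to analytic accuracy", {
  set.seed(3)
  times <- sort(c(0, runif(4000, 0, 20), 20))
  sine <- lapply(times, function(t) {
    tpl <- as.matrix(face_template()[, c("x", "y")])
    tpl[1, 1] <- tpl[1, 1] + sin(2 * pi * 0.5 * t)
    tpl
  })
  raw <- make_raw_recording(times, coords = sine)
  rec <- resample_to_grid(raw, preproc_config(target_rate = 5))
  tpl1 <- face_template()$x[1]
  expect_equal(rec$landmarks[, 1, 1],
               tpl1 + sin(2 * pi * 0.5 * rec$time), tolerance = 1e-3)
})

test_that("common-overlap alignment lands on the shared phase grid", {
  cfg <- preproc_config(target_rate = 5)
  r1 <- make_recording(t_n = 301, rate = 5)                 # [0, 60]
  r2 <- make_recording(t_n = 281, rate = 5)
  r2$time <- r2$time + 2                                    # [2, 58]
  set <- align_group(list(r1, r2), cfg)
  expect_equal(length(set$time), 281)
  expect_equal(range(set$time), c(2, 58))
  lens <- vapply(set$recordings, function(r) length(r$time), integer(1))
  expect_equal(unique(lens), 281L)
  # identical spans: a no-op on the grid
  set2 <- align_group(list(r1, make_recording(t_n = 301, rate = 5)), cfg)
  expect_equal(set2$time, r1$time)
  # fixed duration: 30 s at 5 Hz -> 151 samples from each start
  cfg_fd <- preproc_config(trim_policy = "fixed-duration",
                           fixed_duration_seconds = 30, target_rate = 5)
  set3 <- align_group(list(r1, make_recording(t_n = 301, rate = 5)), cfg_fd)
  expect_equal(length(set3$time), 30 * 5 + 1)
  # disjoint spans fail loudly
  r3 <- make_recording(t_n = 301, rate = 5)
  r3$time <- r3$time + 100
  expect_error(align_group(list(r1, r3), cfg), "overlap")
})

test_that("head movement converts nose path length to centimetres via the IOD", {
  iod <- template_iod_px()
  # stationary nose -> all-zero series
  still <- make_recording(t_n = 26, rate = 5)
  hm0 <- head_movement_series(still, preproc_config())
  expect_true(all(hm0$head_movement == 0))
  # nose moving d px per frame at 5 Hz: every full bin = 5 d (6.3 / IOD)
  d <- 3
  path <- cbind(320 + d * (0:25), rep(270, 26))
  rec <- make_recording(t_n = 26, rate = 5, nose_path = path)
  hm <- head_movement_series(rec, preproc_config())
  expect_equal(hm$head_movement[1:4], rep(5 * d * 6.3 / iod, 4))
  # nose travelling exactly one IOD within one second -> exactly 6.3 cm
  step <- iod / 5
  path1 <- cbind(320 + step * c(0:5, rep(5, 20)), rep(270, 26))
  rec1 <- make_recording(t_n = 26, rate = 5, nose_path = path1)
  hm1 <- head_movement_series(rec1, preproc_config())
  expect_equal(hm1$head_movement[1], 6.3)
})

test_that("head movement is translation invariant and zoom invariant", {
  d <- 2
  path <- cbind(320 + d * (0:25), rep(270, 26))
  base <- head_movement_series(
    make_recording(t_n = 26, rate = 5, nose_path = path), preproc_config())
  shifted <- head_movement_series(
    make_recording(t_n = 26, rate = 5, nose_path = path,
                   shift = c(57, -13)), preproc_config())
  expect_equal(shifted$head_movement, base$head_movement)
  zoomed <- head_movement_series(
    make_recording(t_n = 26, rate = 5, nose_path = path, scale = 2),
    preproc_config())
  expect_equal(zoomed$head_movement, base$head_movement, tolerance = 1e-12)
})

test_that("degenerate inter-ocular distance is an error", {
  rec <- make_recording(t_n = 11, rate = 5)
  rec$landmarks[, 37:48, 1] <- 300   # both eyes collapse to one point
  rec$landmarks[, 37:48, 2] <- 200
  expect_error(head_movement_series(rec, preproc_config()),
               "inter-ocular")
})

test_that("scalarisation follows the vector-norm and motion-amplitude identities", {
  arr <- array(0, dim = c(2, 68, 2, 10))
  arr[, , 1, ] <- 100; arr[, , 2, ] <- 50       # static face
  # landmark 5 of subject 1 sits at a constant (3, 4) offset from its mean:
  # impossible while constant, so alternate around the mean instead
  fm0 <- scalarize(arr, mode = "vector_norm")
  expect_true(all(fm0$data == 0))               # fixed at mean -> 0
  arr2 <- arr
  arr2[1, 5, 1, ] <- 100 + c(rep(3, 5), rep(-3, 5))
  arr2[1, 5, 2, ] <- 50 + c(rep(4, 5), rep(-4, 5))
  fm <- scalarize(arr2, mode = "vector_norm")
  expect_equal(unname(fm$data[1, 5, ]), rep(5, 10))   # 3-4-5 at every t
  # motion amplitude: single (0,0) -> (3,4) step
  arr3 <- arr
  arr3[1, 7, 1, 6:10] <- 103
  arr3[1, 7, 2, 6:10] <- 54
  fma <- scalarize(arr3, mode = "motion_amplitude")
  expect_equal(unname(fma$data[1, 7, ]), c(rep(0, 5), 5, rep(0, 4)))
  expect_equal(unname(fma$data[1, 7, 1]), 0)          # d(1) = 0 by definition
  # offset invariance of both modes
  arr4 <- arr2
  arr4[1, , 1, ] <- arr4[1, , 1, ] + 31
  arr4[1, , 2, ] <- arr4[1, , 2, ] - 12
  expect_equal(scalarize(arr4, "vector_norm")$data, fm$data)
  expect_equal(scalarize(arr4, "motion_amplitude")$data,
               scalarize(arr2, "motion_amplitude")$data)
})

test_that("movement summaries aggregate at the documented levels", {
  mk <- function(id, value) {
    r <- make_recording(t_n = 26, rate = 5, participant = id)
    r$head_movement <- tibble::tibble(second = 0:4,
                                      head_movement = rep(value, 5))
    r
  }
  set <- structure(list(recordings = list(mk("P1", 1), mk("P2", 3)),
                        time = (0:25) / 5, rate = 5, settings = list()),
                   class = "recording_set")
  whole <- movement_summary(set, "whole-recording")
  expect_equal(whole$mean, c(1, 3))
  expect_equal(whole$se, c(0, 0))             # constant series: SE 0
  cond <- movement_summary(set, "condition")
  expect_equal(cond$mean, 2)
  expect_equal(cond$se, 1)                    # two-point SE = sd/sqrt(2) = 1
  per_sec <- movement_summary(set, "per-second")
  expect_equal(nrow(per_sec), 5)
  expect_equal(per_sec$mean, rep(2, 5))
})
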