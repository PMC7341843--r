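test_that("movie generator honours its construction contract", {
  p <- movie_params(height = 24, width = 24, frame_interval = 0.5,
                    n_cycles = 4, period = 22, phase_gradient_span = 0,
                    damping_rate = 0, mask_shape = "disc", seed = 1)
  sim <- make_movie(p)
  expect_equal(dim(sim$movie$data)[3], ceiling(4 * 22 / 0.5))
  # span 0, no noise: every masked pixel peaks at the same frame
  mi <- which(sim$truth$mask)
  flat <- matrix(sim$movie$data, 24 * 24, dim(sim$movie$data)[3])
  peak_frames <- apply(flat[mi, ], 1, which.max)
  expect_equal(length(unique(peak_frames)), 1L)
  # period 22: successive peaks of any pixel trace 22 h apart
  tr <- flat[mi[1], ]
  tt <- (seq_along(tr) - 1) * 0.5
  pk <- find_peaks(condition_ts(circa_ts(tr, dt = 0.5)))
  expect_equal(unique(round(peak_to_peak_periods(pk), 6)), 22)
  # ground truth: phases in [0, 24), masked pixels only
  expect_true(all(sim$truth$phase_ct[mi] >= 0 & sim$truth$phase_ct[mi] < 24))
  expect_true(all(is.na(sim$truth$phase_ct[-mi])))
  expect_error(movie_params(period = -1), "period")
  expect_error(movie_params(frame_interval = 0), "frame_interval")
})

test_that("identical parameters and seed give bit-identical outputs", {
  p <- movie_params(height = 16, width = 16, n_cycles = 2,
                    noise = list(type = "poisson", gain = 4), seed = 99)
  expect_identical(make_movie(p)$movie$data, make_movie(p)$movie$data)
  expect_identical(make_spike_train(8, "gamma", shape = 4, duration = 30, seed = 5)$times,
                   make_spike_train(8, "gamma", shape = 4, duration = 30, seed = 5)$times)
  expect_identical(make_actogram(27, days = 3, seed = 11)$counts,
                   make_actogram(27, days = 3, seed = 11)$counts)
  expect_identical(make_pmt_trace(noise_sd = 3, duration = 48, seed = 2)$values,
                   make_pmt_trace(noise_sd = 3, duration = 48, seed = 2)$values)
})

test_that("gaussian noise scale matches the requested sigma", {
  p0 <- movie_params(height = 24, width = 24, n_cycles = 3, seed = 21)
  p1 <- movie_params(height = 24, width = 24, n_cycles = 3, seed = 21,
                     noise = list(type = "gaussian", sd = 4))
  sim0 <- make_movie(p0); sim1 <- make_movie(p1)
  resid <- (sim1$movie$data - sim0$movie$data)[sim0$truth$mask]  # on-tissue px
  expect_gt(length(resid), 1e4)
  expect_equal(sd(resid), 4, tolerance = 0.05)
})

test_that("PMT generator produces exact cosines and step phase shifts", {
  # exact sampled cosine when noiseless/undamped/undrifting
  tr <- make_pmt_trace(period = 24, amplitude = 10, duration = 72, dt = 0.5)
  tt <- seq(0, 72, by = 0.5)
  expect_equal(tr$values, 10 * cos(2 * pi * (tt - 12) / 24), tolerance = 1e-12)
  # shift_h = 0: peaks equal the unshifted prediction
  tr0 <- make_pmt_trace(duration = 96, dt = 0.1, shift_time = 50, shift_h = 0)
  expect_equal(tr0$values, make_pmt_trace(duration = 96, dt = 0.1)$values)
  # +2 h advance at shift_time: subsequent peaks 2 h earlier than extrapolation
  tr2 <- make_pmt_trace(duration = 120, dt = 0.1, shift_time = 50, shift_h = 2)
  v <- tr2$values
  tt <- seq(0, 120, by = 0.1)
  late_peaks <- tt[tt > 50][which(diff(sign(diff(v[tt > 50]))) == -2) + 1]
  expect_equal(late_peaks %% 24, rep(10, length(late_peaks)), tolerance = 0.11)
  expect_error(make_pmt_trace(shift_time = 500, duration = 100), "shift_time")
})

test_that("spike-train generator respects rate, mode and refractoriness", {
  # regular: all ISIs equal 1/rate
  tr <- make_spike_train(5, "regular", duration = 20)
  expect_equal(unique(round(diff(tr$times), 12)), 0.2)
  expect_equal(sfr(tr), 5)
  # poisson at 10 Hz over 60 s: count within 3*sqrt(600) of 600
  tr <- make_spike_train(10, "poisson", duration = 60, seed = 8)
  expect_lt(abs(length(tr$times) - 600), 3 * sqrt(600))
  # refractoriness: all ISIs >= refractory, mean rate preserved
  tr <- make_spike_train(20, "poisson", refractory = 0.01, duration = 500, seed = 3)
  expect_true(all(diff(tr$times) >= 0.01))
  expect_equal(sfr(tr), 20, tolerance = 0.05)
  expect_error(make_spike_train(100, "poisson", refractory = 0.02),
               "infeasible")
})

test_that("actogram generator concentrates activity in subjective night", {
  # all activity nocturnal -> zero counts in subjective day bins
  a <- make_actogram(24, days = 4, night_fraction = 1, seed = 2)
  centres <- ((seq_along(a$counts) - 0.5) * a$bin_min) / 60
  day <- (centres %% 24) >= 12
  expect_true(all(a$counts[day] == 0))
  expect_gt(sum(a$counts[!day]), 0)
  # night fraction 0.5 -> approximately even split
  a <- make_actogram(24, days = 20, night_fraction = 0.5, seed = 4)
  centres <- ((seq_along(a$counts) - 0.5) * a$bin_min) / 60
  frac <- sum(a$counts[(centres %% 24) < 12]) / sum(a$counts)
  expect_equal(frac, 0.5, tolerance = 0.02)
  expect_error(make_actogram(night_fraction = 1.2), "night_fraction")
})

test_that("period-27 actograms recur with 27 h onset spacing", {
  a <- make_actogram(27, days = 10, night_fraction = 1, seed = 6)
  centres <- ((seq_along(a$counts) - 0.5) * a$bin_min) / 60
  active <- which(a$counts > 0)
  # first active bin of each cycle sits at a multiple of 27 h
  onsets <- centres[active][c(TRUE, diff(centres[active]) > 5)]
  expect_true(all(abs((onsets %% 27) - min(onsets %% 27)) < 0.2))
  expect_equal(length(onsets), 9, tolerance = 1)
})

test_that("movie TIFF and CSV round-trips preserve content", {
  p <- movie_params(height = 12, width = 12, n_cycles = 2, seed = 1)
  sim <- make_movie(p)
  tf <- tempfile(fileext = ".tif")
  write_movie_tiff(sim$movie, tf)
  back <- read_movie_tiff(tf, frame_interval = 1)
  expect_equal(dim(back$data), dim(sim$movie$data))
  expect_lt(max(abs(back$data - round(sim$movie$data))), 0.5)
  cf <- tempfile(fileext = ".csv")
  write_truth_csv(sim$truth, cf, params = p)
  d <- read.csv(cf)
  expect_equal(nrow(d), sum(sim$truth$mask))
  expect_true(file.exists(sub("\\.csv$", ".json", cf)))
  # time-series / spikes / actogram CSV round-trips
  ts <- make_pmt_trace(duration = 24, dt = 0.5)
  f <- tempfile(fileext = ".csv"); write_ts_csv(ts, f)
  expect_equal(read_ts_csv(f)$values, ts$values)
  sp <- make_spike_train(5, "poisson", duration = 10, seed = 2)
  f <- tempfile(fileext = ".csv"); write_spikes_csv(sp, f)
  expect_equal(read_spikes_csv(f)$times, sp$times)
  ac <- make_actogram(days = 2, seed = 3)
  f <- tempfile(fileext = ".csv"); write_actogram_csv(ac, f)
  expect_equal(read_actogram_csv(f)$counts, ac$counts)
})
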