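t05 <- seq(0, 120, by = 0.5)

test_that("detrend removes slow baselines and passes a window-period cosine", {
  # constant series -> all-zero interior
  d <- detrend_ts(circa_ts(rep(7, 241), dt = 0.5))
  expect_true(all(abs(d$values[!is.na(d$values)]) < 1e-12))
  # pure 24 h cosine under a 24 h window is returned unchanged (interior)
  cosv <- cos(2 * pi * t05 / 24)
  d <- detrend_ts(circa_ts(cosv, dt = 0.5), window = 24)
  ok <- !is.na(d$values)
  expect_lt(max(abs(d$values[ok] - cosv[ok])), 1e-12)
  # cosine + linear drift -> pure cosine on interior samples
  d <- detrend_ts(circa_ts(cosv + 0.3 * t05 + 5, dt = 0.5), window = 24)
  expect_lt(max(abs(d$values[ok] - cosv[ok])), 1e-6)
  # edges flagged missing where the full window does not fit
  expect_true(all(is.na(d$values[1:24])))
  expect_error(detrend_ts(circa_ts(rep(1, 10), dt = 1), window = 24),
               "shorter than the detrend window")
})

test_that("smoothing preserves constants and attenuates by the discrete MA gain", {
  s <- smooth_ts(circa_ts(rep(3, 50), dt = 0.5), window = 2.5)
  expect_equal(s$values, rep(3, 50))
  # impulse -> rectangular pulse of the window width, area preserved
  x <- rep(0, 51); x[26] <- 1
  s <- smooth_ts(circa_ts(x, dt = 0.5), window = 2.5)
  expect_equal(sum(s$values[22:30] > 0), 5)
  expect_equal(sum(s$values), 1, tolerance = 1e-12)
  # 24 h cosine through a 2.5 h window: amplitude scaled by the closed-form gain
  cosv <- cos(2 * pi * t05 / 24)
  s <- smooth_ts(circa_ts(cosv, dt = 0.5), window = 2.5)
  gain <- ma_cosine_gain(5, 0.5, 24)
  mid <- 30:212
  expect_lt(max(abs(s$values[mid] - gain * cosv[mid])), 1e-12)
  expect_error(smooth_ts(circa_ts(1:10, dt = 1), window = 0.5),
               "shorter than the sampling interval")
})

test_that("find_peaks locates and refines cosine peaks, and rejects ramps", {
  ts <- circa_ts(100 + 50 * cos(2 * pi * (seq(0, 120, 0.5) - 12) / 24), dt = 0.5)
  pk <- find_peaks(condition_ts(ts))
  # interior peaks at 36, 60, 84 (edge peaks fall in the NA-flagged margins)
  expect_equal(pk$peak_time, c(36, 60, 84), tolerance = 1e-6)
  expect_equal(peak_to_peak_periods(pk), c(24, 24), tolerance = 1e-6)
  # monotone ramp -> empty
  expect_equal(nrow(find_peaks(circa_ts(1:100, dt = 1))), 0)
  # noisy cosine (sigma = 5% of amplitude): peak times within 0.25 h of
  # truth under the wide-neighbourhood quadratic refinement
  set.seed(42)
  v <- 100 + 50 * cos(2 * pi * (t05 - 12) / 24) + rnorm(length(t05), sd = 2.5)
  pk <- find_peaks(condition_ts(circa_ts(v, dt = 0.5)), refine_window = 3)
  expect_true(all(abs(pk$peak_time - c(36, 60, 84)) < 0.25))
})

test_that("peak-to-peak periods are successive differences and conserve the span", {
  expect_equal(peak_to_peak_periods(c(10, 34, 58)), c(24, 24))
  expect_equal(peak_to_peak_periods(c(10, 32, 56.5)), c(22, 24.5))
  expect_error(peak_to_peak_periods(c(10)), "at least 2 peaks")
  set.seed(7)
  pt <- cumsum(runif(8, 20, 28))
  expect_equal(sum(peak_to_peak_periods(pt)), pt[8] - pt[1])
})

test_that("conditioning is linear in amplitude scaling", {
  set.seed(3)
  v <- 10 * cos(2 * pi * t05 / 24) + 0.1 * t05 + rnorm(length(t05))
  a <- condition_ts(circa_ts(v, dt = 0.5))
  b <- condition_ts(circa_ts(3.5 * v, dt = 0.5))
  expect_equal(b$values, 3.5 * a$values, tolerance = 1e-12)
})

test_that("period ramps are resolved cycle by cycle", {
  # frequency sweep emulating progressive period lengthening after genetic
  # complementation: instantaneous period ramps 22 -> 24.5 h
  dur <- 240
  tt <- seq(0, dur, by = 0.1)
  per <- 22 + (24.5 - 22) * tt / dur
  phase <- cumsum(2 * pi * 0.1 / per)
  ts <- circa_ts(100 + 40 * cos(phase), dt = 0.1)
  pk <- find_peaks(condition_ts(ts), refine_window = 2)
  pp <- peak_to_peak_periods(pk)
  expect_gte(length(pp), 5)
  expect_true(all(diff(pp) > 0))
  expect_true(all(pp > 21 & pp < 25))
})

test_that("windowing helpers cut and report analysis intervals", {
  ts <- circa_ts(seq_len(100), dt = 1)
  w <- window_ts(ts, from = 10, to = 20)
  expect_equal(ts_times(w), 10:20)
  expect_equal(w$values, 11:21)
  aw <- ablation_windows(120)
  expect_equal(aw$pre, c(24, 120))
  expect_equal(aw$post, c(156, 252))
})
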