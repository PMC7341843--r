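test_that("periodogram pinpoints block-periodic activity", {
  # deterministic block activity: Qp maximal exactly at the block period
  counts <- rep(c(rep(10, 60), rep(0, 60)), 12)  # 24 h blocks at 12-min bins
  act <- circa_actogram(counts, bin_min = 12)
  cp <- chi_square_periodogram(act)
  expect_equal(cp$best_period, 24)
  expect_true(cp$significant)
  # synthetic 27 h nocturnal record
  act <- make_actogram(period = 27, days = 10, night_fraction = 0.64, seed = 3)
  cp <- chi_square_periodogram(act)
  expect_equal(cp$best_period, 27, tolerance = 0.2)
  expect_gt(cp$amplitude, 0)
  expect_error(chi_square_periodogram(make_actogram(days = 2, seed = 1)),
               "at least twice")
})

test_that("rhythm-free records stay below the significance line", {
  nullamp <- vapply(1:50, function(s) {
    set.seed(s)
    chi_square_periodogram(circa_actogram(rpois(2400, 10), bin_min = 6))$amplitude
  }, numeric(1))
  expect_gte(mean(nullamp <= 0), 0.9)
})

test_that("relative amplitude matches its closed forms", {
  # all activity inside one 10 h window -> RA = 1
  prof <- c(rep(12, 50), rep(0, 70))  # 10 h active of a 24 h, 12-min profile
  act <- circa_actogram(rep(prof, 8), bin_min = 12)
  expect_equal(relative_amplitude(act, period = 24), 1)
  # constant activity -> RA = 0 exactly
  expect_equal(relative_amplitude(circa_actogram(rep(4, 1350), 12), period = 27), 0)
  # block design with night fraction f -> RA = 2f - 1
  act <- make_actogram(period = 27, days = 10, night_fraction = 0.8, seed = 9)
  expect_equal(relative_amplitude(act, period = 27), 2 * 0.8 - 1,
               tolerance = 0.05)
  expect_true(is.na(relative_amplitude(circa_actogram(rep(0, 300), 12))))
})

test_that("onset detection finds the activity block and resists isolated bins", {
  prof <- rep(0, 135)
  prof[40:100] <- 8
  expect_equal(detect_onset(prof, smooth_bins = 1), 40)
  # one isolated earlier bin does not move the onset
  prof2 <- prof; prof2[10] <- 9
  expect_equal(detect_onset(prof2, smooth_bins = 1), 40)
  # constant profile defaults to bin 1; silent profile is undefined
  expect_equal(detect_onset(rep(5, 100)), 1L)
  expect_true(is.na(detect_onset(rep(0, 100))))
  # wrap-around block is still a single run
  prof3 <- rep(0, 100); prof3[c(90:100, 1:20)] <- 5
  expect_equal(detect_onset(prof3, smooth_bins = 1), 90)
  # generator actograms: onset near the subjective-night start across seeds
  hits <- vapply(1:20, function(s) {
    act <- make_actogram(period = 27, days = 10, night_fraction = 0.64,
                         bin_min = 12, seed = 200 + s)
    prof <- rowMeans(matrix(act$counts[1:1080], nrow = 135))  # fold 8 cycles
    on <- detect_onset(prof)
    min((on - 1) %% 135, (1 - on) %% 135) <= 3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("aligned profiles superpose animals on their onsets", {
  act <- make_actogram(period = 27, days = 10, night_fraction = 0.9,
                       bin_min = 12, seed = 31)
  # identical animals -> SEM identically zero
  pr <- aligned_profile(list(act, act, act), profile_period = 27)
  expect_true(all(pr$sem == 0))
  expect_equal(max(pr$mean), 1)
  expect_equal(pr$onset_bin, 68)
  # two deterministic animals with onsets offset by 2 h superpose exactly
  pat <- c(rep(8, 67), rep(1, 68))            # one 27 h cycle at 12-min bins
  a1 <- circa_actogram(rep(pat, 8), bin_min = 12)
  pat2 <- c(pat[-(1:10)], pat[1:10])          # onset 2 h (10 bins) earlier
  a2 <- circa_actogram(rep(pat2, 8), bin_min = 12)
  pr2 <- aligned_profile(list(a1, a2), profile_period = 27)
  expect_true(all(pr2$sem == 0))
  # arrhythmic (uniform) animal: flat profile near its own mean
  set.seed(8)
  flat <- circa_actogram(rpois(1350, 20), bin_min = 12)
  prf <- aligned_profile(list(flat), profile_period = 27)
  expect_lt(stats::sd(prf$mean) / mean(prf$mean), 0.2)
})

test_that("day/night split conserves totals and matches the generator design", {
  # all activity in the half cycle after onset -> 0/100
  prof <- rep(0, 134); prof[10:76] <- 3
  sp <- day_night_split(prof, onset_bin = 10)
  expect_equal(unname(sp["night_pct"]), 100)
  # uniform activity -> exactly 50/50 (odd and even bin counts)
  for (n in c(134, 135)) {
    sp <- day_night_split(rep(2, n), onset_bin = 17)
    expect_equal(unname(sp["day_pct"]), 50)
    expect_equal(sum(sp), 100)
  }
  # generator night fraction 0.64 across seeds
  nf <- vapply(1:20, function(s) {
    acts <- list(make_actogram(period = 27, days = 10, night_fraction = 0.64,
                               bin_min = 12, seed = 400 + s))
    pr <- aligned_profile(acts, profile_period = 27)
    unname(day_night_split(pr)["night_pct"])
  }, numeric(1))
  expect_lt(max(abs(nf - 64)), 2)
})
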