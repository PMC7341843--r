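# Wheel-running actogram analysis: chi-square periodogram, nonparametric
# relative amplitude, onset detection, onset-aligned activity profiles and
# the subjective day/night activity split.

# fold counts at a candidate period of m bins: column means and sizes
fold_counts <- function(counts, m) {
  idx <- ((seq_along(counts) - 1L) %% m) + 1L
  list(means = as.numeric(tapply(counts, idx, mean)),
       sizes = as.numeric(tapply(counts, idx, length)))
}

#' Chi-square (Sokolove-Bushell) periodogram
#'
#' For each candidate period (an integer number of bins) the record is folded
#' and the periodogram statistic computed as the between-column sum of
#' squares divided by the total variance:
#' `Qp = sum_h N_h (M_h - M)^2 / (sum_i (x_i - M)^2 / n)`, which is
#' approximately chi-square distributed with (columns - 1) degrees of freedom
#' under the null of no rhythm. Because that null df grows with the candidate
#' period, the best period is taken at the maximum of Qp minus the
#' significance line, and the reported amplitude is that maximal excess
#' (positive = significant rhythm).
#'
#' The default significance line applies a Bonferroni correction for the
#' number of candidate periods scanned, so a rhythm-free record exceeds it
#' with family-wise probability ~`alpha`; set `correct = FALSE` for the
#' per-period line.
#'
#' @param act A [circa_actogram].
#' @param period_range Candidate period range in hours (default
#'   `c(20, 34)`).
#' @param alpha Significance level of the chi-square line (default 0.05).
#' @param correct Bonferroni-correct the line across candidates (default
#'   `TRUE`).
#' @return List with `periodogram` (data frame `period_h`, `Qp`,
#'   `sig_line`), `best_period` (h), `amplitude` (Qp excess over the line at
#'   the best period; `<= 0` means no significant rhythm) and `significant`.
#' @export
chi_square_periodogram <- function(act, period_range = c(20, 34),
                                   alpha = 0.05, correct = TRUE) {
  counts <- act$counts
  bin_h <- act$bin_min / 60
  span_h <- length(counts) * bin_h
  if (span_h < 2 * max(period_range))
    stop("insufficient data: record must span at least twice the longest candidate period")
  m_range <- seq(ceiling(period_range[1] / bin_h), floor(period_range[2] / bin_h))
  if (!length(m_range)) stop("no candidate period in range at this bin width")
  gm <- mean(counts)
  denom <- sum((counts - gm)^2) / length(counts)
  if (denom == 0) stop("degenerate input: constant activity record")
  n_cand <- length(m_range)
  a_eff <- if (correct) alpha / n_cand else alpha
  Qp <- numeric(n_cand); sig <- numeric(n_cand)
  for (i in seq_len(n_cand)) {
    f <- fold_counts(counts, m_range[i])
    Qp[i] <- sum(f$sizes * (f$means - gm)^2) / denom
    sig[i] <- stats::qchisq(1 - a_eff, df = m_range[i] - 1L)
  }
  excess <- Qp - sig
  best <- which.max(excess)
  list(periodogram = data.frame(period_h = m_range * bin_h, Qp = Qp,
                                sig_line = sig),
       best_period = m_range[best] * bin_h,
       amplitude = excess[best],
       significant = excess[best] > 0)
}

# circular rolling mean of a profile with window w bins
circ_roll_mean <- function(x, w) {
  n <- length(x)
  xx <- c(x, x[seq_len(min(w - 1L, n))])
  cs <- c(0, cumsum(xx))
  (cs[(seq_len(n)) + w] - cs[seq_len(n)]) / w
}

fold_profile <- function(counts, n_prof) {
  fold_counts(counts, n_prof)$means
}

#' Nonparametric relative amplitude of an activity record
#'
#' Folds the record at the profile period and computes
#' `RA = (M10 - L5) / (M10 + L5)` where M10 and L5 are the mean counts of
#' the most-active 10 h and least-active 5 h windows of the mean profile
#' (window lengths scale as 10/24 and 5/24 of non-24 h profile periods).
#' RA = 1 when all activity is consolidated into the M10 window, 0 for
#' constant activity.
#'
#' @param act A [circa_actogram].
#' @param period Profile (free-running) period in hours (default 24).
#' @return RA in `[0, 1]`, or `NA` for an all-zero record.
#' @export
relative_amplitude <- function(act, period = 24) {
  bin_h <- act$bin_min / 60
  n_prof <- round(period / bin_h)
  if (length(act$counts) < n_prof)
    stop("insufficient data: record shorter than one profile period")
  prof <- fold_profile(act$counts, n_prof)
  if (all(prof == 0)) return(NA_real_)
  w10 <- max(1L, round(n_prof * 10 / 24))
  w5 <- max(1L, round(n_prof * 5 / 24))
  M10 <- max(circ_roll_mean(prof, w10))
  L5 <- min(circ_roll_mean(prof, w5))
  (M10 - L5) / (M10 + L5)
}

#' Detect activity onset in a circular profile
#'
#' Smooths the profile with a short circular moving average, thresholds it at
#' a fraction of the smoothed dynamic range above the smoothed minimum, and
#' returns the first bin of the longest circular run of supra-threshold bins,
#' provided the run lasts at least `min_run` bins. An isolated noise bin
#' before the main activity bout therefore does not capture the onset.
#' Thresholding on the range (rather than the raw maximum) keeps the onset
#' detectable when the animal is also active, at a lower rate, in subjective
#' day. When every bin is supra-threshold (e.g. constant activity) the onset
#' defaults to bin 1.
#'
#' @param profile Numeric vector of per-bin activity (one profile period), or
#'   a `circa_profile` from [aligned_profile()].
#' @param threshold Fraction of the smoothed range above the smoothed
#'   minimum (default 0.5, the midrange crossing, which discriminates the
#'   active bout whenever its rate exceeds the rest-phase rate).
#' @param min_run Minimum run length in bins (default 6).
#' @param smooth_bins Circular smoothing window, bins (default 3).
#' @return Onset bin index (1-based), or `NA` when no qualifying run exists.
#' @export
detect_onset <- function(profile, threshold = 0.5, min_run = 6,
                         smooth_bins = 3) {
  x <- if (inherits(profile, "circa_profile")) profile$mean else as.numeric(profile)
  if (all(x == 0)) return(NA_integer_)
  n <- length(x)
  if (smooth_bins > 1) {
    # centred circular smoothing: rotate so each window is centred on its bin
    half <- floor(smooth_bins / 2)
    sm <- circ_roll_mean(x[((seq_len(n) - 1L - half) %% n) + 1L], smooth_bins)
  } else sm <- x
  above <- sm >= min(sm) + threshold * (max(sm) - min(sm))
  if (all(above)) return(1L)
  if (!any(above)) return(NA_integer_)
  # circular runs: rotate so position 1 is below threshold, then use rle
  start0 <- which(!above)[1]
  rot <- ((seq_len(n) + start0 - 2L) %% n) + 1L
  r <- rle(above[rot])
  runs <- which(r$values)
  if (!length(runs)) return(NA_integer_)
  lens <- r$lengths[runs]
  if (max(lens) < min_run) return(NA_integer_)
  best <- runs[which.max(lens)]
  first_in_rot <- cumsum(c(1L, r$lengths))[best]
  rot[first_in_rot]
}

#' Onset-aligned mean activity profile across animals
#'
#' Per animal: the last `last_days` days of the record are folded at the
#' profile period, averaged per bin, peak-normalised (maximum = 1) and
#' circularly rotated so the detected activity onset sits at the profile
#' mid-point; the per-animal profiles are then averaged with SEM. Animals
#' with undefined onset are excluded with a warning.
#'
#' @param acts List of [circa_actogram] (one per animal).
#' @param profile_period Profile fold period in hours (default 27).
#' @param bin_min Profile bin width in minutes (default 12); each actogram's
#'   native bins are aggregated to this width (must be an integer multiple).
#' @param last_days Number of trailing days used (default 7).
#' @param ... Passed to [detect_onset()].
#' @return An object of class `circa_profile`: list with `period_h`,
#'   `bin_min`, `mean`, `sem`, `onset_bin` (profile mid-point), `n_animals`.
#' @export
aligned_profile <- function(acts, profile_period = 27, bin_min = 12,
                            last_days = 7, ...) {
  if (inherits(acts, "circa_actogram")) acts <- list(acts)
  n_prof <- round(profile_period * 60 / bin_min)
  mid <- floor(n_prof / 2) + 1L
  profs <- list()
  for (a in acts) {
    fac <- bin_min / a$bin_min
    if (abs(fac - round(fac)) > 1e-9)
      stop("profile bin width must be an integer multiple of the actogram bin width")
    counts <- a$counts
    if (fac > 1) {
      fac <- as.integer(round(fac))
      nfull <- (length(counts) %/% fac) * fac
      counts <- colSums(matrix(counts[seq_len(nfull)], nrow = fac))
    }
    need <- round(last_days * 24 * 60 / bin_min)
    if (length(counts) < need)
      stop("insufficient data: actogram shorter than `last_days`")
    counts <- counts[(length(counts) - need + 1L):length(counts)]
    prof <- fold_profile(counts, n_prof)
    if (max(prof) > 0) prof <- prof / max(prof)
    onset <- detect_onset(prof, ...)
    if (is.na(onset)) {
      warning("animal excluded: activity onset undefined")
      next
    }
    rot <- ((seq_len(n_prof) - 1L + onset - mid) %% n_prof) + 1L
    profs[[length(profs) + 1L]] <- prof[rot]
  }
  if (!length(profs)) stop("no animal with a defined onset")
  m <- do.call(rbind, profs)
  structure(list(period_h = profile_period, bin_min = bin_min,
                 mean = colMeans(m),
                 sem = if (nrow(m) > 1) apply(m, 2, stats::sd) / sqrt(nrow(m))
                       else rep(0, ncol(m)),
                 onset_bin = mid, n_animals = nrow(m)),
            class = "circa_profile")
}

#' @export
print.circa_profile <- function(x, ...) {
  cat(sprintf("<circa_profile> %g h profile, %g-min bins, %d animal(s), onset at bin %d\n",
              x$period_h, x$bin_min, x$n_animals, x$onset_bin))
  invisible(x)
}

#' Subjective day/night split of an activity profile
#'
#' Subjective night is the half cycle starting at the activity onset
#' (nocturnal convention); subjective day is the complement. Returns the
#' percentage of total profile activity in each. A bin straddling the
#' half-cycle boundary contributes proportionally, so a uniform profile
#' splits exactly 50/50.
#'
#' @param profile A `circa_profile`, or a numeric per-bin profile.
#' @param onset_bin Onset bin index (taken from the object when a
#'   `circa_profile` is given).
#' @return Named numeric vector `c(day_pct, night_pct)`, summing to 100.
#' @export
day_night_split <- function(profile, onset_bin = NULL) {
  if (inherits(profile, "circa_profile")) {
    x <- profile$mean
    if (is.null(onset_bin)) onset_bin <- profile$onset_bin
  } else {
    x <- as.numeric(profile)
    if (is.null(onset_bin)) onset_bin <- detect_onset(x)
  }
  if (is.na(onset_bin)) stop("activity onset undefined")
  n <- length(x)
  tot <- sum(x)
  if (tot == 0) stop("degenerate input: profile has no activity")
  # night weight of each bin: overlap of the bin with the circular interval
  # [onset, onset + n/2), in bin units
  pos <- (seq_len(n) - onset_bin) %% n       # bin start offset from onset
  half <- n / 2
  w_night <- pmax(0, pmin(pos + 1, half) - pos)
  night <- sum(x * w_night) / tot * 100
  c(day_pct = 100 - night, night_pct = night)
}

#' Double-plot an actogram
#'
#' Classic double-plotted raster on a configurable time base: each row shows
#' two consecutive periods, successive rows advance by one period.
#'
#' @param act A [circa_actogram].
#' @param time_base Row length in hours (default 24; use the free-running
#'   period, e.g. 27, for a subjective-time plot).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_actogram <- function(act, time_base = 24, ...) {
  m <- round(time_base * 60 / act$bin_min)
  n_rows <- floor(length(act$counts) / m) - 1L
  if (n_rows < 1L) stop("record too short to double-plot")
  z <- t(vapply(seq_len(n_rows), function(r)
    act$counts[((r - 1L) * m + 1L):((r + 1L) * m)], numeric(2L * m)))
  graphics::image(x = seq_len(2L * m) * act$bin_min / 60, y = seq_len(n_rows),
                  z = t(z)[, n_rows:1, drop = FALSE],
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = sprintf("time (h, %g h base)", time_base),
                  ylab = "day", ...)
  invisible(z)
}
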