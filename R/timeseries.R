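#' Uniformly sampled time series
#'
#' Lightweight container for a uniformly sampled scalar signal, the unit of
#' analysis shared by all conditioning and fitting functions. Time is measured
#' in hours throughout the package; missing (edge-flagged) samples are `NA`.
#'
#' @param values Numeric vector of samples (a.u.); length >= 2. `NA` marks
#'   flagged-missing samples.
#' @param dt Sampling interval in hours (> 0).
#' @param start_time Time of the first sample in hours (default 0).
#' @return An object of class `circa_ts` with fields `start_time`, `dt`,
#'   `values`.
#' @examples
#' ts <- circa_ts(cos(2 * pi * seq(0, 120, by = 0.5) / 24), dt = 0.5)
#' head(as.data.frame(ts))
#' @export
circa_ts <- function(values, dt, start_time = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (hours)")
  if (!is.numeric(values) || length(values) < 2L)
    stop("`values` must be a numeric vector of length >= 2")
  if (any(is.infinite(values)))
    stop("`values` must be finite or NA (flagged missing)")
  structure(list(start_time = as.numeric(start_time), dt = dt,
                 values = as.numeric(values)),
            class = "circa_ts")
}

#' @export
print.circa_ts <- function(x, ...) {
  cat(sprintf("<circa_ts> %d samples, dt = %g h, span %.4g-%.4g h (%d missing)\n",
              length(x$values), x$dt, x$start_time,
              x$start_time + (length(x$values) - 1) * x$dt,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
as.data.frame.circa_ts <- function(x, ...) {
  data.frame(time_h = ts_times(x), value = x$values)
}

#' Sample times of a time series
#'
#' @param ts A [circa_ts] object.
#' @return Numeric vector of sample times in hours.
#' @export
ts_times <- function(ts) {
  ts$start_time + (seq_along(ts$values) - 1L) * ts$dt
}

#' Read / write a time series as two-column CSV
#'
#' CSV schema: `time_h,value`, one row per sample. Sampling must be uniform.
#'
#' @param path File path.
#' @return `read_ts_csv` returns a [circa_ts]; `write_ts_csv` invisibly
#'   returns `path`.
#' @export
read_ts_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_h", "value") %in% names(d)))
    stop("expected columns `time_h` and `value` in ", path)
  dts <- diff(d$time_h)
  if (length(dts) < 1L || any(abs(dts - dts[1]) > 1e-6 * abs(dts[1])))
    stop("time series in ", path, " is not uniformly sampled")
  circa_ts(d$value, dt = dts[1], start_time = d$time_h[1])
}

#' @rdname read_ts_csv
#' @param ts A [circa_ts] object.
#' @export
write_ts_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}

# --- moving averages ---------------------------------------------------------

# Centred moving average over exactly `window_h` hours; NA where the full
# window does not fit. When window_h/dt is an even integer the two endpoint
# samples get half weight (symmetric scheme spanning exactly the window), so a
# pure cosine whose period equals the window averages to exactly zero and a
# linear ramp is reproduced exactly.
ma_exact_window <- function(x, window_h, dt) {
  m <- window_h / dt
  if (abs(m - round(m)) < 1e-8 && round(m) %% 2 == 0) {
    h <- round(m) / 2
    w <- c(0.5, rep(1, round(m) - 1), 0.5) / round(m)
  } else {
    n_odd <- max(1L, round(m))
    if (n_odd %% 2 == 0) n_odd <- n_odd + 1L
    h <- (n_odd - 1L) / 2L
    w <- rep(1 / n_odd, n_odd)
  }
  as.numeric(stats::filter(x, w, sides = 2))
}

# Centred moving average with an odd sample count; edges use the partial
# window that fits, and NA samples are excluded from each window mean.
ma_partial <- function(x, n_win) {
  stopifnot(n_win >= 1, n_win %% 2 == 1)
  h <- (n_win - 1L) / 2L
  n <- length(x)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xz))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Detrend a time series by subtracting a centred moving average
#'
#' Removes the slow baseline by subtracting a centred moving average whose
#' window defaults to one circadian day, leaving the oscillatory component.
#' Edge samples where the full window does not fit are flagged missing (`NA`),
#' which downstream peak search then ignores.
#'
#' @param ts A [circa_ts] object.
#' @param window Moving-average window in hours (default 24).
#' @return A [circa_ts] of the same length with detrended values and `NA`
#'   edges.
#' @details A cosine whose period equals the window is passed through
#'   unchanged on interior samples (its windowed mean is zero), and any linear
#'   drift is removed exactly.
#' @export
detrend_ts <- function(ts, window = 24) {
  span <- (length(ts$values) - 1L) * ts$dt
  if (span < window)
    stop(sprintf("series span (%.3g h) is shorter than the detrend window (%.3g h)",
                 span, window))
  base <- ma_exact_window(ts$values, window, ts$dt)
  circa_ts(ts$values - base, dt = ts$dt, start_time = ts$start_time)
}

#' Smooth a time series with a centred moving average
#'
#' The window is expressed in hours and rounded to the nearest odd sample
#' count. Edge samples use the partial window that fits so a constant series
#' is returned unchanged everywhere.
#'
#' @param ts A [circa_ts] object.
#' @param window Smoothing window in hours (default 2.5).
#' @return Smoothed [circa_ts].
#' @export
smooth_ts <- function(ts, window = 2.5) {
  if (window < ts$dt)
    stop(sprintf("smoothing window (%.3g h) is shorter than the sampling interval (%.3g h)",
                 window, ts$dt))
  n_win <- round(window / ts$dt)
  if (n_win %% 2 == 0) n_win <- n_win + 1L
  circa_ts(ma_partial(ts$values, as.integer(max(1L, n_win))),
           dt = ts$dt, start_time = ts$start_time)
}

# prominence of a local maximum at index i: height above the higher of the two
# lowest points separating it from higher terrain (or the series edge)
peak_prominence <- function(v, i) {
  n <- length(v)
  pv <- v[i]
  lmin <- pv
  j <- i - 1L
  while (j >= 1L && !is.na(v[j]) && v[j] <= pv) {
    if (v[j] < lmin) lmin <- v[j]
    j <- j - 1L
  }
  rmin <- pv
  j <- i + 1L
  while (j <= n && !is.na(v[j]) && v[j] <= pv) {
    if (v[j] < rmin) rmin <- v[j]
    j <- j + 1L
  }
  pv - max(lmin, rmin)
}

#' Find circadian peaks in a conditioned time series
#'
#' Locates local maxima with a minimum mutual separation and a minimum
#' prominence (expressed as a fraction of the finite signal range), then
#' refines each peak time by fitting a parabola through the three samples
#' around the maximum. Intended for detrended/smoothed input. Missing samples
#' (and their immediate neighbours) are excluded from the search.
#'
#' @param ts A [circa_ts] object.
#' @param min_separation Minimum separation between retained peaks, hours
#'   (default 16; rejects sub-circadian maxima while admitting 18-34 h
#'   rhythms).
#' @param min_prominence Minimum peak prominence as a fraction of the signal
#'   range (default 0.1).
#' @param refine_window `NULL` (default) refines each peak by the parabola
#'   through the 3 samples around the maximum; a numeric value refines by the
#'   vertex of a least-squares quadratic over all samples within that many
#'   hours of the maximum, which is markedly less noise-sensitive on densely
#'   sampled (e.g. 6-min PMT) traces.
#' @return A `circa_peaks` data frame with columns `peak_time` (h, ascending,
#'   sub-sample refined) and `peak_value`. Zero rows when no peak qualifies.
#' @export
find_peaks <- function(ts, min_separation = 16, min_prominence = 0.1,
                       refine_window = NULL) {
  v <- ts$values
  n <- length(v)
  times <- ts_times(ts)
  rng <- diff(range(v, na.rm = TRUE))
  empty <- structure(data.frame(peak_time = numeric(0), peak_value = numeric(0)),
                     class = c("circa_peaks", "data.frame"))
  if (!is.finite(rng) || rng == 0) return(empty)
  cand <- integer(0)
  for (i in 2:(n - 1L)) {
    if (is.na(v[i - 1L]) || is.na(v[i]) || is.na(v[i + 1L])) next
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) {
      if (peak_prominence(v, i) >= min_prominence * rng) cand <- c(cand, i)
    }
  }
  if (length(cand) == 0L) return(empty)
  # greedy selection by height, enforcing the separation constraint
  cand <- cand[order(v[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(times[i] - times[keep]) >= min_separation)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  # sub-sample refinement: 3-sample parabola by default, or a least-squares
  # quadratic over a wider neighbourhood when `refine_window` is set
  pt <- numeric(length(keep))
  pv <- numeric(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    if (!is.null(refine_window) && refine_window > ts$dt) {
      hw <- floor(refine_window / ts$dt)
      lo <- max(1L, i - hw); hi <- min(n, i + hw)
      idx <- (lo:hi)[!is.na(v[lo:hi])]
      if (length(idx) >= 5L) {
        dtt <- times[idx] - times[i]
        co <- stats::lm.fit(cbind(1, dtt, dtt^2), v[idx])$coefficients
        if (is.finite(co[3]) && co[3] < 0) {
          off_h <- max(-refine_window, min(refine_window, -co[2] / (2 * co[3])))
          pt[k] <- times[i] + off_h
          pv[k] <- co[1] + co[2] * off_h + co[3] * off_h^2
          next
        }
      }
    }
    y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
    denom <- y1 - 2 * y2 + y3
    off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
    off <- max(-0.5, min(0.5, off))
    pt[k] <- times[i] + off * ts$dt
    pv[k] <- y2 - 0.25 * (y1 - y3) * off
  }
  structure(data.frame(peak_time = pt, peak_value = pv),
            class = c("circa_peaks", "data.frame"))
}

#' Per-cycle periods from successive peak times
#'
#' Expresses the interval between each pair of successive peaks as the period
#' for that cycle, the cycle-resolved period readout used to follow transient
#' period changes.
#'
#' @param peaks A `circa_peaks` data frame from [find_peaks()], or a numeric
#'   vector of ascending peak times in hours.
#' @return Numeric vector of per-cycle periods (h), in temporal order.
#' @export
peak_to_peak_periods <- function(peaks) {
  pt <- if (is.data.frame(peaks)) peaks$peak_time else as.numeric(peaks)
  if (length(pt) < 2L)
    stop("at least 2 peaks are required to compute a peak-to-peak period")
  if (any(diff(pt) <= 0)) stop("peak times must be strictly increasing")
  diff(pt)
}

#' Condition a trace for peak analysis
#'
#' Convenience wrapper applying the standard conditioning used throughout the
#' package: moving-average detrend followed by a short moving-average smooth.
#'
#' @inheritParams detrend_ts
#' @param detrend_window Detrend window, hours (default 24).
#' @param smooth_window Smoothing window, hours (default 2.5).
#' @return Conditioned [circa_ts].
#' @export
condition_ts <- function(ts, detrend_window = 24, smooth_window = 2.5) {
  smooth_ts(detrend_ts(ts, window = detrend_window), window = smooth_window)
}

#' Restrict a time series to a time window
#'
#' @param ts A [circa_ts] object.
#' @param from,to Window limits in hours (closed interval).
#' @return A [circa_ts] holding the samples with `from <= t <= to`.
#' @export
window_ts <- function(ts, from = -Inf, to = Inf) {
  t <- ts_times(ts)
  sel <- t >= from & t <= to
  if (sum(sel) < 2L) stop("window retains fewer than 2 samples")
  circa_ts(ts$values[sel], dt = ts$dt, start_time = t[sel][1])
}

#' Pre/post analysis windows around a treatment
#'
#' Returns the standard analysis windows used around an ablation-style
#' intervention: a fixed number of days immediately before treatment, and the
#' same number of days after treatment excluding an initial exclusion period
#' (acute-response transient, default 36 h).
#'
#' @param treatment_time Time of treatment application, hours.
#' @param pre_days,post_days Window lengths in days (default 4).
#' @param exclusion_h Hours excluded immediately after treatment (default 36).
#' @return List with `pre = c(from, to)` and `post = c(from, to)` in hours.
#' @export
ablation_windows <- function(treatment_time, pre_days = 4, post_days = 4,
                             exclusion_h = 36) {
  list(pre = c(treatment_time - pre_days * 24, treatment_time),
       post = c(treatment_time + exclusion_h,
                treatment_time + exclusion_h + post_days * 24))
}
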