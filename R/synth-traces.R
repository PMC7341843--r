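#' Synthetic photomultiplier (PMT) bioluminescence trace
#'
#' Generates a whole-slice bioluminescence record: a damped cosine with linear
#' drift, additive gaussian noise, and an optional step phase shift imposed at
#' a stimulation time. The default sampling interval of 0.1 h corresponds to
#' photon counts binned into 6-min intervals.
#'
#' A positive `shift_h` makes all peaks after `shift_time` occur `shift_h`
#' hours *earlier* than the pre-shift extrapolation (a phase advance);
#' negative values delay them.
#'
#' @param period Oscillation period, h.
#' @param amplitude Oscillation amplitude, a.u.
#' @param damping Exponential damping rate, per h.
#' @param drift Linear drift, a.u. per h.
#' @param noise_sd Gaussian noise SD, a.u.
#' @param shift_time Time of the step phase shift (h), or `NULL` for none.
#' @param shift_h Imposed phase shift in hours (advance positive).
#' @param duration Recording length, h.
#' @param dt Sampling interval, h (default 0.1 = 6 min).
#' @param first_peak Time of the first (unshifted) peak, h.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return A [circa_ts].
#' @export
make_pmt_trace <- function(period = 24, amplitude = 100, damping = 0,
                           drift = 0, noise_sd = 0, shift_time = NULL,
                           shift_h = 0, duration = 192, dt = 0.1,
                           first_peak = period / 2, seed = 1L) {
  if (dt <= 0) stop("`dt` must be positive")
  if (period <= 0) stop("`period` must be positive")
  if (!is.null(shift_time) && (shift_time < 0 || shift_time > duration))
    stop("`shift_time` must lie within [0, duration]")
  t <- seq(0, duration, by = dt)
  s <- if (is.null(shift_time)) 0 else shift_h * (t >= shift_time)
  v <- amplitude * exp(-damping * t) *
    cos(2 * pi * (t + s - first_peak) / period) + drift * t
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  circa_ts(v, dt = dt, start_time = 0)
}

#' Spike-train container
#'
#' @param times Spike times in seconds, strictly increasing, within
#'   `[0, duration]`.
#' @param duration Recording duration, seconds.
#' @return An object of class `circa_spikes`.
#' @export
circa_spikes <- function(times, duration) {
  times <- as.numeric(times)
  if (length(times) && (any(diff(times) <= 0)))
    stop("spike times must be strictly increasing")
  if (length(times) && (times[1] < 0 || times[length(times)] > duration))
    stop("spike times must lie within [0, duration]")
  structure(list(times = times, duration = as.numeric(duration)),
            class = "circa_spikes")
}

#' @export
print.circa_spikes <- function(x, ...) {
  cat(sprintf("<circa_spikes> %d spikes over %g s (%.3g Hz)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Generate a renewal-process spike train
#'
#' Draws interspike intervals (ISIs) from a renewal process with tunable
#' regularity: `"regular"` (constant ISI), `"poisson"` (exponential ISIs) or
#' `"gamma"` (gamma ISIs with shape `shape`; larger shape = more regular).
#' Refractoriness is implemented by dead-time shifting: each stochastic ISI is
#' shifted by `refractory` seconds and the stochastic part's mean is reduced
#' so the requested mean rate is preserved.
#'
#' @param rate Mean firing rate, Hz (> 0).
#' @param mode `"poisson"`, `"regular"` or `"gamma"`.
#' @param shape Gamma shape parameter (mode `"gamma"` only).
#' @param refractory Absolute refractory period, seconds (>= 0).
#' @param duration Recording duration, seconds (> 0).
#' @param seed Integer seed.
#' @return A [circa_spikes] whose ISIs are all `>= refractory`.
#' @export
make_spike_train <- function(rate, mode = c("poisson", "regular", "gamma"),
                             shape = 1, refractory = 0, duration = 60,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (rate <= 0) stop("`rate` must be positive")
  if (duration <= 0) stop("`duration` must be positive")
  if (refractory < 0) stop("`refractory` must be >= 0")
  if (rate * refractory >= 1)
    stop("infeasible parameters: rate * refractory >= 1 (the refractory period ",
         "alone exceeds the mean ISI)")
  mean_free <- 1 / rate - refractory
  if (mode == "regular") {
    times <- seq(1 / rate, duration, by = 1 / rate)
    return(circa_spikes(times, duration))
  }
  if (!is.null(seed)) set.seed(seed)
  draw <- function(n) {
    switch(mode,
           poisson = stats::rexp(n, rate = 1 / mean_free),
           gamma = stats::rgamma(n, shape = shape, scale = mean_free / shape))
  }
  n_guess <- ceiling(rate * duration * 1.5) + 50L
  isis <- refractory + draw(n_guess)
  times <- cumsum(isis)
  while (times[length(times)] < duration) {
    isis2 <- refractory + draw(n_guess)
    times <- c(times, times[length(times)] + cumsum(isis2))
  }
  circa_spikes(times[times <= duration], duration)
}

#' Actogram container
#'
#' Binned locomotor-activity record (e.g. wheel-running event counts).
#'
#' @param counts Nonnegative counts, one per bin.
#' @param bin_min Bin width in minutes.
#' @param start_h Clock time of the start of the first bin, hours (default 0).
#' @return An object of class `circa_actogram`.
#' @export
circa_actogram <- function(counts, bin_min, start_h = 0) {
  if (any(counts < 0, na.rm = TRUE)) stop("activity counts must be >= 0")
  if (bin_min <= 0) stop("`bin_min` must be positive")
  structure(list(counts = as.numeric(counts), bin_min = as.numeric(bin_min),
                 start_h = as.numeric(start_h)),
            class = "circa_actogram")
}

#' @export
print.circa_actogram <- function(x, ...) {
  cat(sprintf("<circa_actogram> %d x %g-min bins (%.2f days)\n",
              length(x$counts), x$bin_min,
              length(x$counts) * x$bin_min / 60 / 24))
  invisible(x)
}

#' Generate a synthetic free-running actogram
#'
#' Emulates a nocturnal rodent free-running with period `period`: Poisson
#' activity counts with a block (square-wave) rate profile in which the
#' subjective night (the first half of each cycle, starting at t = 0) carries
#' the stated fraction of total activity. Activity onsets therefore fall at
#' exact multiples of `period` from the start of the record.
#'
#' @param period Free-running period, h.
#' @param days Record length, days.
#' @param night_fraction Proportion of total activity occurring in subjective
#'   night (in `[0, 1]`; 0.5 = no day/night structure).
#' @param bin_min Bin width in minutes (default 6).
#' @param mean_counts_per_min Overall mean activity rate, counts per minute.
#' @param seed Integer seed.
#' @return A [circa_actogram].
#' @export
make_actogram <- function(period = 24, days = 10, night_fraction = 0.64,
                          bin_min = 6, mean_counts_per_min = 2, seed = 1L) {
  if (night_fraction < 0 || night_fraction > 1)
    stop("`night_fraction` must lie in [0, 1]")
  if (period <= 0) stop("`period` must be positive")
  n_bins <- floor(days * 24 * 60 / bin_min)
  centres_h <- ((seq_len(n_bins) - 0.5) * bin_min) / 60
  in_night <- (centres_h %% period) < period / 2
  mean_per_bin <- mean_counts_per_min * bin_min
  rate <- ifelse(in_night, 2 * night_fraction, 2 * (1 - night_fraction)) *
    mean_per_bin
  if (!is.null(seed)) set.seed(seed)
  circa_actogram(stats::rpois(n_bins, lambda = rate), bin_min = bin_min)
}

#' Read / write spike times as single-column CSV
#'
#' CSV schema: `spike_time_s`, one row per spike; the recording duration is
#' stored as a comment-free extra column `duration_s` on the first row when
#' writing, or supplied on reading.
#'
#' @param path File path.
#' @param duration Recording duration in seconds (reading only; defaults to
#'   the last spike time).
#' @return `read_spikes_csv` returns a [circa_spikes].
#' @export
read_spikes_csv <- function(path, duration = NULL) {
  d <- utils::read.csv(path)
  if (!"spike_time_s" %in% names(d))
    stop("expected column `spike_time_s` in ", path)
  if (is.null(duration)) {
    duration <- if ("duration_s" %in% names(d) && is.finite(d$duration_s[1]))
      d$duration_s[1] else max(d$spike_time_s)
  }
  circa_spikes(d$spike_time_s, duration)
}

#' @rdname read_spikes_csv
#' @param spikes A [circa_spikes] object.
#' @export
write_spikes_csv <- function(spikes, path) {
  d <- data.frame(spike_time_s = spikes$times,
                  duration_s = c(spikes$duration,
                                 rep(NA_real_, max(0L, length(spikes$times) - 1L))))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read / write an actogram as two-column CSV
#'
#' CSV schema: `time_h,counts` with `time_h` the start of each bin.
#'
#' @param path File path.
#' @return `read_actogram_csv` returns a [circa_actogram].
#' @export
read_actogram_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_h", "counts") %in% names(d)))
    stop("expected columns `time_h` and `counts` in ", path)
  dts <- diff(d$time_h)
  if (any(abs(dts - dts[1]) > 1e-6 * dts[1]))
    stop("actogram bins in ", path, " are not uniform")
  circa_actogram(d$counts, bin_min = dts[1] * 60, start_h = d$time_h[1])
}

#' @rdname read_actogram_csv
#' @param act A [circa_actogram] object.
#' @export
write_actogram_csv <- function(act, path) {
  d <- data.frame(
    time_h = act$start_h + (seq_along(act$counts) - 1L) * act$bin_min / 60,
    counts = act$counts)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
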