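# Electrophysiology summary statistics.

spike_isis <- function(x) {
  if (inherits(x, "circa_spikes")) x <- x$times
  x <- as.numeric(x)
  if (any(diff(x) <= 0)) stop("spike times must be strictly increasing")
  diff(x)
}

#' Revised local-variation (LvR) spike-train regularity
#'
#' Rate-independent measure of firing regularity computed over consecutive
#' interspike-interval (ISI) pairs:
#' \deqn{LvR = \frac{3}{n-1} \sum_{i=1}^{n-1}
#'   \left(1 - \frac{4 I_i I_{i+1}}{(I_i + I_{i+1})^2}\right)
#'   \left(1 + \frac{4R}{I_i + I_{i+1}}\right)}
#' where \eqn{I_i} are the ISIs, \eqn{n} the number of ISIs and \eqn{R} the
#' refractoriness constant correcting for the refractory period within each
#' ISI. LvR is near 0 for clock-like (regular) firing and near 1 for
#' Poisson-like (irregular) discharge.
#'
#' @param x A [circa_spikes], or a numeric vector of ascending spike times in
#'   seconds, or (with `is_isi = TRUE`) a vector of ISIs in seconds.
#' @param R Refractoriness constant in seconds (default 0.005 = 5 ms, the
#'   standard value for SCN neurons).
#' @param is_isi Set `TRUE` when `x` already holds ISIs.
#' @return LvR, dimensionless.
#' @export
lvr <- function(x, R = 0.005, is_isi = FALSE) {
  if (R < 0) stop("`R` must be >= 0")
  I <- if (is_isi) as.numeric(x) else spike_isis(x)
  n <- length(I)
  if (n < 2L)
    stop("insufficient data: LvR needs at least 2 ISIs (3 spikes)")
  I1 <- I[-n]; I2 <- I[-1]
  s <- I1 + I2
  3 / (n - 1) * sum((1 - 4 * I1 * I2 / s^2) * (1 + 4 * R / s))
}

#' Spontaneous firing rate
#'
#' @param train A [circa_spikes].
#' @return Firing rate in Hz (0 for an empty train).
#' @export
sfr <- function(train) {
  stopifnot(inherits(train, "circa_spikes"))
  if (train$duration <= 0) stop("`duration` must be positive")
  length(train$times) / train$duration
}

#' Firing index of optogenetic entrainment
#'
#' Fraction of light pulses that evoked a spike: evoked spike count divided
#' by the number of pulses delivered (default 60). Values below 1 indicate
#' failure of the stimulation pattern to drive firing at the commanded rate.
#'
#' @param evoked_count Number of evoked spikes (>= 0).
#' @param n_pulses Number of stimulation pulses (default 60).
#' @return Dimensionless firing index.
#' @export
firing_index <- function(evoked_count, n_pulses = 60) {
  if (n_pulses <= 0) stop("`n_pulses` must be positive")
  if (any(evoked_count < 0)) stop("`evoked_count` must be >= 0")
  evoked_count / n_pulses
}

#' Input resistance from current steps
#'
#' Least-squares slope of the steady-state voltage deflection against the
#' injected current (e.g. -30 pA to 0 pA in 10 pA steps), converted to
#' megaohms (mV / pA = 1000 MOhm).
#'
#' @param currents_pA Injected currents, pA (>= 2 distinct values).
#' @param voltages_mV Steady-state voltage deflections, mV.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(currents_pA, voltages_mV) {
  if (length(currents_pA) != length(voltages_mV))
    stop("`currents_pA` and `voltages_mV` must have equal length")
  if (length(unique(currents_pA)) < 2L)
    stop("degenerate input: need >= 2 distinct current levels")
  slope <- stats::coef(stats::lm(voltages_mV ~ currents_pA))[[2]]
  slope * 1000
}

#' Assign circadian times to 4-h bins
#'
#' Grouping helper mirroring the day/night sampling design of timed
#' electrophysiological recordings (CT0-4, CT4-8, ..., CT20-24).
#'
#' @param ct Circadian times in hours (wrapped to `[0, 24)`).
#' @param width Bin width in hours (default 4; must divide 24).
#' @return Ordered factor of bin labels like `"CT0-4"`.
#' @export
ct_bin <- function(ct, width = 4) {
  if (24 %% width != 0) stop("`width` must divide 24")
  ct <- ct %% 24
  lo <- floor(ct / width) * width
  labs_all <- sprintf("CT%g-%g", seq(0, 24 - width, by = width),
                      seq(width, 24, by = width))
  factor(sprintf("CT%g-%g", lo, lo + width), levels = labs_all,
         ordered = TRUE)
}

#' Summarise a set of spike trains as CSV-ready table
#'
#' @param trains Named list of [circa_spikes].
#' @param R Refractoriness constant for LvR, seconds.
#' @return Data frame `cell_id`, `n_spikes`, `sfr_hz`, `lvr` (NA when the
#'   train has fewer than 3 spikes).
#' @export
spike_summary <- function(trains, R = 0.005) {
  ids <- names(trains) %||% as.character(seq_along(trains))
  do.call(rbind, lapply(seq_along(trains), function(i) {
    tr <- trains[[i]]
    data.frame(cell_id = ids[i], n_spikes = length(tr$times),
               sfr_hz = sfr(tr),
               lvr = if (length(tr$times) >= 3L) lvr(tr, R) else NA_real_)
  }))
}
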