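# Phase-response-curve construction from pre/post-stimulation traces.
#
# Sign convention: phase advances are positive (the observed peak occurs
# earlier than the baseline extrapolation predicts), delays negative. Shifts
# are wrapped into (-12, 12] h since a circadian shift is defined modulo one
# cycle.

wrap_shift <- function(x) {
  w <- ((x + 12) %% 24) - 12
  ifelse(w == -12, 12, w)
}

#' Predict post-stimulation peak times from baseline peaks
#'
#' Fits an ordinary least-squares line through (cycle index, peak time) of
#' the baseline peaks — its slope is the baseline period — and extrapolates
#' to the next `n_future` cycles.
#'
#' @param baseline_peaks A `circa_peaks` data frame or numeric vector of
#'   ascending baseline peak times (h). Fewer than 4 peaks triggers a warning
#'   (the regression is then poorly constrained); fewer than 2 is an error.
#' @param n_future Number of future peaks to predict.
#' @return List with `predicted` (h), `period` (h, the regression slope) and
#'   `intercept` (h, fitted time of cycle 0).
#' @export
predict_peaks <- function(baseline_peaks, n_future = 3) {
  pt <- if (is.data.frame(baseline_peaks)) baseline_peaks$peak_time
        else as.numeric(baseline_peaks)
  n <- length(pt)
  if (n < 2L) stop("insufficient data: need >= 2 baseline peaks")
  if (n < 4L) warning("fewer than 4 baseline peaks; period estimate is weakly constrained")
  k <- seq_len(n) - 1
  fit <- stats::lm(pt ~ k)
  co <- stats::coef(fit)
  list(predicted = co[[1]] + co[[2]] * (n - 1 + seq_len(n_future)),
       period = co[[2]], intercept = co[[1]])
}

#' Phase shift of an ensemble rhythm after a stimulation
#'
#' Conditions the pre- and post-stimulation segments of the trace separately
#' (so the stimulation transient never contaminates the detrend window of a
#' baseline peak), fits the baseline peaks ([predict_peaks()]) and computes,
#' for each of the first `n_post` measurable post-stimulation cycles, the
#' difference between the predicted and the actual peak, normalised into
#' circadian time by the baseline period
#' (`shift_k = (predicted_k - actual_k) * 24 / tau`, wrapped to (-12, 12]).
#' The reported shift is the mean over those cycles; the stimulation phase is
#' the circadian time of `stim_time` under the baseline fit, with CT12 at the
#' rhythm peak.
#'
#' @param trace A [circa_ts] of the ensemble rhythm (e.g. whole-slice
#'   bioluminescence).
#' @param stim_time Stimulation time, h (within the trace span).
#' @param condition Optional label (wavelength / genotype tag).
#' @param n_post Number of post-stimulation cycles averaged (default 3).
#' @param detrend_window,smooth_window,min_separation,min_prominence Trace
#'   conditioning and peak-search settings.
#' @param refine_window Peak-refinement neighbourhood in hours (see
#'   [find_peaks()]); the default +/- 3 h least-squares quadratic suits
#'   densely sampled PMT traces.
#' @return A one-row data frame of class `circa_prcpoint`: `stim_phase_ct`,
#'   `shift_h` (advance positive), `period_h`, `n_baseline_peaks`,
#'   `n_post_used`, `condition`.
#' @export
phase_shift <- function(trace, stim_time, condition = NA_character_,
                        n_post = 3, detrend_window = 24, smooth_window = 2.5,
                        min_separation = 16, min_prominence = 0.1,
                        refine_window = 3) {
  span <- range(ts_times(trace))
  if (stim_time < span[1] || stim_time > span[2])
    stop("`stim_time` lies outside the trace span")
  peaks_of <- function(ts) find_peaks(condition_ts(ts, detrend_window, smooth_window),
                                      min_separation, min_prominence,
                                      refine_window = refine_window)
  base <- peaks_of(window_ts(trace, to = stim_time))$peak_time
  post <- peaks_of(window_ts(trace, from = stim_time))$peak_time
  post <- post[post > stim_time]
  if (length(base) < 2L)
    stop("insufficient data: < 2 baseline peaks before the stimulation")
  if (length(post) < n_post)
    stop(sprintf("insufficient data: %d post-stimulation peaks found, %d required",
                 length(post), n_post))
  pred <- predict_peaks(base, n_future = n_post)
  actual <- post[seq_len(n_post)]
  # wrapped, so the result is independent of which baseline cycle index each
  # post peak is compared against (a circadian shift is defined modulo 24 CT h)
  shifts <- wrap_shift(((pred$intercept - actual) * 24 / pred$period) %% 24)
  frac <- ((stim_time - pred$intercept) / pred$period) %% 1
  out <- data.frame(stim_phase_ct = (12 + 24 * frac) %% 24,
                    shift_h = mean(shifts),
                    period_h = pred$period,
                    n_baseline_peaks = length(base),
                    n_post_used = n_post,
                    condition = condition)
  class(out) <- c("circa_prcpoint", "data.frame")
  out
}

#' Bin phase-response points into a PRC table
#'
#' Groups per-slice phase shifts into circadian-time bins and reports per-bin
#' mean, SEM and n (per condition when a condition tag is present). Bins with
#' fewer than `min_n` points are flagged as under-sampled.
#'
#' @param points Data frame of PRC points (rows from [phase_shift()], or any
#'   data frame with `stim_phase_ct`, `shift_h` and optional `condition`).
#' @param bin_width CT bin width in hours (default 4; must divide 24).
#' @param min_n Minimum per-bin n below which the bin is flagged (default 5).
#' @return Data frame `condition`, `ct_bin` (bin centre, h), `mean_shift`,
#'   `sem`, `n`, `under_sampled`.
#' @export
build_prc <- function(points, bin_width = 4, min_n = 5) {
  if (!nrow(points)) stop("at least one PRC point is required")
  if (24 %% bin_width != 0) stop("`bin_width` must divide 24")
  cond <- if (is.null(points$condition)) rep(NA_character_, nrow(points))
          else as.character(points$condition)
  cond_key <- ifelse(is.na(cond), "", cond)
  bin_lo <- floor((points$stim_phase_ct %% 24) / bin_width) * bin_width
  key <- split(seq_len(nrow(points)),
               list(cond_key, bin_lo), drop = TRUE, sep = "\r")
  rows <- lapply(key, function(idx) {
    s <- points$shift_h[idx]
    data.frame(condition = cond[idx[1]],
               ct_bin = bin_lo[idx[1]] + bin_width / 2,
               mean_shift = mean(s),
               sem = if (length(s) > 1) stats::sd(s) / sqrt(length(s)) else NA_real_,
               n = length(s),
               under_sampled = length(s) < min_n)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$ct_bin), ]
  rownames(out) <- NULL
  out
}
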