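# Circular summary statistics of oscillator phases (Rayleigh analysis).

#' Convert circadian-time phase to an angle
#'
#' Maps a CT phase (hours) onto the circle: `angle = 2 * pi * phase /
#' period_ct`, wrapped to `[0, 2 * pi)`. CT0 maps to 0 rad and CT12 to pi for
#' the default 24 h normalised cycle.
#'
#' @param phase_ct Phase in CT hours (any real; wraps).
#' @param period_ct Hours per full cycle on the CT axis (default 24).
#' @return Angle(s) in radians in `[0, 2 * pi)`.
#' @export
ct_to_angle <- function(phase_ct, period_ct = 24) {
  if (period_ct <= 0) stop("`period_ct` must be positive")
  (2 * pi * phase_ct / period_ct) %% (2 * pi)
}

#' Rayleigh mean vector of a circular phase sample
#'
#' The mean resultant vector of unit vectors at the given angles: its length
#' `R` in `[0, 1]` measures phase synchrony (1 = all oscillators in phase, 0
#' = balanced dispersion) and its argument is the mean phase. One unweighted
#' unit vector per oscillator.
#'
#' @param angles Angles in radians (finite; `n >= 1`).
#' @return List with `n`, `R`, `mean_angle` (radians in `[0, 2 * pi)`; `NA`
#'   with `mean_defined = FALSE` when `R` is numerically zero).
#' @export
rayleigh_vector <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 1L) stop("insufficient data: empty phase sample")
  C <- mean(cos(angles)); S <- mean(sin(angles))
  R <- sqrt(C^2 + S^2)
  defined <- R >= 1e-12
  list(n = n, R = R,
       mean_angle = if (defined) atan2(S, C) %% (2 * pi) else NA_real_,
       mean_defined = defined)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis of uniform phase dispersion using the standard
#' approximation `p = exp(sqrt(1 + 4n + 4(n^2 - Z^2)) - (1 + 2n))` with
#' `Z = n * R^2`.
#'
#' @param angles Angles in radians (`n >= 2`).
#' @return List with `n`, `R`, `Z` and `p_value`.
#' @export
rayleigh_test <- function(angles) {
  angles <- angles[!is.na(angles)]
  n <- length(angles)
  if (n < 2L) stop("insufficient data: Rayleigh test needs n >= 2")
  rv <- rayleigh_vector(angles)
  Z <- n * rv$R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Z^2)) - (1 + 2 * n))
  list(n = n, R = rv$R, Z = Z, p_value = min(1, p))
}

#' Rayleigh summary of a phase map
#'
#' Convenience wrapper: converts each phased ROI's circular-mean CT phase to
#' an angle and returns the Rayleigh vector and uniformity test, the per-slice
#' synchrony summary plotted in Rayleigh diagrams.
#'
#' @param pm A `circa_phasemap` (or a numeric vector of CT phases).
#' @param period_ct Hours per cycle on the CT axis (default 24).
#' @return Data frame with one row: `n`, `R`, `mean_angle_rad`,
#'   `mean_phase_ct`, `p_value`.
#' @export
rayleigh_summary <- function(pm, period_ct = 24) {
  phases <- if (inherits(pm, "circa_phasemap")) pm$phase_ct else as.numeric(pm)
  ang <- ct_to_angle(phases[!is.na(phases)], period_ct)
  rt <- rayleigh_test(ang)
  data.frame(n = rt$n, R = rt$R,
             mean_angle_rad = rayleigh_vector(ang)$mean_angle,
             mean_phase_ct = (rayleigh_vector(ang)$mean_angle %||% NA_real_) *
               period_ct / (2 * pi),
             p_value = rt$p_value)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Polar plot of a circular phase sample
#'
#' Points on the unit circle plus the mean resultant vector as an arrow, the
#' standard Rayleigh-plot idiom.
#'
#' @param angles Angles in radians.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [rayleigh_vector()] of the sample.
#' @export
plot_rayleigh <- function(angles, ...) {
  rv <- rayleigh_vector(angles)
  graphics::plot(cos(angles), sin(angles), asp = 1, xlim = c(-1.1, 1.1),
                 ylim = c(-1.1, 1.1), xlab = "", ylab = "", ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey")
  if (rv$mean_defined)
    graphics::arrows(0, 0, rv$R * cos(rv$mean_angle), rv$R * sin(rv$mean_angle),
                     length = 0.08, lwd = 2)
  invisible(rv)
}

#' Write a Rayleigh summary as CSV
#'
#' CSV schema: `n,R,mean_angle_rad,mean_phase_ct,p_value`.
#'
#' @param summary Data frame from [rayleigh_summary()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rayleigh_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
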