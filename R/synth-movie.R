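#' Parameters for a synthetic circadian movie
#'
#' Bundles the parameters of the synthetic SCN movie generator. The generator
#' emulates a bioluminescence/fluorescence time-lapse recording of an
#' organotypic slice: per-pixel damped sinusoidal oscillations with a linear
#' spatial phase gradient (a travelling wave), a multiplicative amplitude
#' envelope, additive baseline drift and optional shot noise, on a
#' slice-shaped intensity mask.
#'
#' @param height,width Frame size in pixels.
#' @param frame_interval Frame interval in hours (> 0).
#' @param n_cycles Number of circadian cycles to generate.
#' @param period Oscillation period in hours (> 0).
#' @param phase_gradient_span Total peak-time spread (h) across the mask along
#'   `gradient_axis`; 0 gives a standing (spatially uniform-phase) oscillation.
#' @param gradient_axis `"vertical"` (default; rows, emulating the
#'   dorsal-to-ventral wave) or `"horizontal"` (columns).
#' @param amplitude Oscillation amplitude, a.u.
#' @param damping_rate Exponential amplitude damping, per hour.
#' @param baseline Constant baseline intensity of masked pixels, a.u.
#' @param drift_slope Linear baseline drift, a.u. per hour.
#' @param background Constant intensity of pixels outside the mask, a.u.
#' @param noise Noise model: `list(type = "none")`,
#'   `list(type = "gaussian", sd = )`, or `list(type = "poisson", gain = )`.
#'   Poisson noise is applied to the expected photon count after scaling by
#'   `gain` (counts per intensity unit), emulating shot-noise-limited
#'   photon-counting detection.
#' @param mask_shape `"bilateral-ellipse"` (two side-by-side nuclei, default),
#'   `"disc"` or `"full-frame"`.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   stacks.
#' @return A list of class `movie_params`.
#' @export
movie_params <- function(height = 64, width = 64, frame_interval = 1,
                         n_cycles = 5, period = 24, phase_gradient_span = 3,
                         gradient_axis = c("vertical", "horizontal"),
                         amplitude = 50, damping_rate = 0.005, baseline = 100,
                         drift_slope = 0, background = 0,
                         noise = list(type = "none"),
                         mask_shape = c("bilateral-ellipse", "disc", "full-frame"),
                         seed = 1L) {
  if (frame_interval <= 0) stop("`frame_interval` must be positive")
  if (period <= 0) stop("`period` must be positive")
  if (phase_gradient_span < 0) stop("`phase_gradient_span` must be >= 0")
  gradient_axis <- match.arg(gradient_axis)
  mask_shape <- match.arg(mask_shape)
  noise$type <- match.arg(noise$type, c("none", "gaussian", "poisson"))
  if (noise$type == "gaussian" && (is.null(noise$sd) || noise$sd < 0))
    stop("gaussian noise requires `sd` >= 0")
  if (noise$type == "poisson" && (is.null(noise$gain) || noise$gain <= 0))
    stop("poisson noise requires `gain` > 0")
  structure(as.list(environment()), class = "movie_params")
}

#' Multi-frame movie container
#'
#' @param data Numeric array of dimension `c(height, width, n_frames)`.
#' @param frame_interval Frame interval in hours.
#' @param start_time Time of the first frame (h).
#' @return An object of class `circa_movie`.
#' @export
circa_movie <- function(data, frame_interval, start_time = 0) {
  stopifnot(is.array(data), length(dim(data)) == 3L, frame_interval > 0)
  structure(list(data = data, frame_interval = frame_interval,
                 start_time = start_time),
            class = "circa_movie")
}

#' @export
print.circa_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<circa_movie> %dx%d px, %d frames at %g h\n", d[1], d[2], d[3],
              x$frame_interval))
  invisible(x)
}

#' Frame times of a movie
#' @param movie A [circa_movie].
#' @return Numeric vector of frame times (h).
#' @export
movie_times <- function(movie) {
  movie$start_time + (seq_len(dim(movie$data)[3]) - 1L) * movie$frame_interval
}

make_shape_mask <- function(height, width, shape) {
  r <- matrix(seq_len(height), height, width)
  c_ <- matrix(seq_len(width), height, width, byrow = TRUE)
  cy <- (height + 1) / 2
  switch(shape,
    "full-frame" = matrix(TRUE, height, width),
    "disc" = {
      rad <- 0.4 * min(height, width)
      (r - cy)^2 + (c_ - (width + 1) / 2)^2 <= rad^2
    },
    "bilateral-ellipse" = {
      rx <- 0.17 * width; ry <- 0.38 * height
      left <- ((r - cy) / ry)^2 + ((c_ - 0.3 * width) / rx)^2 <= 1
      right <- ((r - cy) / ry)^2 + ((c_ - 0.7 * width) / rx)^2 <= 1
      left | right
    })
}

#' Generate a synthetic circadian movie with exact ground truth
#'
#' Each masked pixel follows
#' `baseline + drift_slope * t + A * exp(-damping_rate * t) *
#'  cos(2 * pi * (t - t_peak) / period)` (clipped at zero), where the first
#' peak time `t_peak` varies linearly along the gradient axis so that the
#' total spread across the mask equals `phase_gradient_span`. Pixels outside
#' the mask sit at the constant `background` level. Noise is applied last.
#'
#' The returned ground truth gives, per pixel, the circadian-time phase under
#' the package convention (CT12 at the mask-mean peak, i.e. at the peak of the
#' ensemble reference signal) and the oscillation amplitude, plus the exact
#' ensemble period and the mask.
#'
#' @param params A [movie_params()] list.
#' @return List with elements `movie` (a [circa_movie] of
#'   `ceiling(n_cycles * period / frame_interval)` frames) and `truth` (list
#'   with `phase_ct` and `amplitude` matrices (`NA` off-mask), `period`,
#'   `mask`, and `t_peak` first-peak times).
#' @export
make_movie <- function(params) {
  stopifnot(inherits(params, "movie_params"))
  p <- params
  n_frames <- ceiling(p$n_cycles * p$period / p$frame_interval)
  t <- (seq_len(n_frames) - 1L) * p$frame_interval
  mask <- make_shape_mask(p$height, p$width, p$mask_shape)

  pos <- if (p$gradient_axis == "vertical")
    matrix(seq_len(p$height), p$height, p$width)
  else
    matrix(seq_len(p$width), p$height, p$width, byrow = TRUE)
  prng <- range(pos[mask])
  rel <- if (diff(prng) == 0 || p$phase_gradient_span == 0) {
    matrix(0.5, p$height, p$width)
  } else {
    (pos - prng[1]) / diff(prng)
  }
  # first-peak time: half a period in, plus the linear gradient centred on it
  t_peak <- p$period / 2 + p$phase_gradient_span * (rel - 0.5)

  arr <- array(p$background, dim = c(p$height, p$width, n_frames))
  mi <- which(mask)
  tp <- t_peak[mi]
  for (k in seq_len(n_frames)) {
    osc <- p$amplitude * exp(-p$damping_rate * t[k]) *
      cos(2 * pi * (t[k] - tp) / p$period)
    frame <- arr[, , k]
    frame[mi] <- p$baseline + p$drift_slope * t[k] + osc
    arr[, , k] <- frame
  }
  arr[arr < 0] <- 0

  if (p$noise$type != "none") {
    if (!is.null(p$seed)) set.seed(p$seed)
    if (p$noise$type == "gaussian") {
      arr <- arr + array(stats::rnorm(length(arr), sd = p$noise$sd), dim = dim(arr))
      arr[arr < 0] <- 0
    } else {
      g <- p$noise$gain
      arr <- array(stats::rpois(length(arr), lambda = g * arr) / g, dim = dim(arr))
    }
  }

  ref_peak <- mean(t_peak[mask])
  phase_ct <- matrix(NA_real_, p$height, p$width)
  phase_ct[mask] <- (12 + 24 * (t_peak[mask] - ref_peak) / p$period) %% 24
  amp <- matrix(NA_real_, p$height, p$width)
  amp[mask] <- p$amplitude
  tpm <- matrix(NA_real_, p$height, p$width)
  tpm[mask] <- t_peak[mask]

  list(movie = circa_movie(arr, frame_interval = p$frame_interval),
       truth = list(phase_ct = phase_ct, amplitude = amp, period = p$period,
                    mask = mask, t_peak = tpm))
}

#' Write / read a movie as multi-frame 16-bit TIFF
#'
#' Frames are stored as 16-bit unsigned grayscale, one page per frame, with
#' intensities rounded to integer counts (values are clipped to
#' `[0, 65535]`). The frame interval is not stored in the TIFF and must be
#' supplied on reading.
#'
#' @param movie A [circa_movie].
#' @param path Output path.
#' @return `write_movie_tiff` invisibly returns `path`; `read_movie_tiff`
#'   returns a [circa_movie].
#' @export
write_movie_tiff <- function(movie, path) {
  arr <- movie$data
  arr[arr < 0] <- 0
  arr[arr > 65535] <- 65535
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(k) round(arr[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_interval Frame interval in hours of the stored movie.
#' @param start_time Time of the first frame (h).
#' @export
read_movie_tiff <- function(path, frame_interval, start_time = 0) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(h, w, length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * 65535
  circa_movie(arr, frame_interval = frame_interval, start_time = start_time)
}

#' Write movie ground truth as CSV (+ JSON parameter sidecar)
#'
#' CSV schema: `pixel_row,pixel_col,phase_ct,amplitude`, masked pixels only.
#'
#' @param truth Ground-truth list from [make_movie()].
#' @param path CSV output path; the JSON sidecar (if `params` is given) is
#'   written next to it with extension `.json`.
#' @param params Optional [movie_params()] to record alongside.
#' @return Invisibly, `path`.
#' @export
write_truth_csv <- function(truth, path, params = NULL) {
  idx <- which(truth$mask, arr.ind = TRUE)
  d <- data.frame(pixel_row = idx[, 1], pixel_col = idx[, 2],
                  phase_ct = truth$phase_ct[truth$mask],
                  amplitude = truth$amplitude[truth$mask])
  utils::write.csv(d, path, row.names = FALSE)
  if (!is.null(params)) {
    side <- sub("\\.csv$", ".json", path)
    keep <- params[!vapply(params, is.function, logical(1))]
    jsonlite::write_json(keep, side, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
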