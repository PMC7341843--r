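# Centre-of-luminescence (CoL) wave statistics.
#
# The CoL tracks where luminescence is currently above its local average, so
# its per-cycle excursion traces the spatiotemporal wave; a standing
# oscillation leaves it parked at the mask centroid.

shoelace_area <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

hull_area <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3L) return(0)  # collinear
  shoelace_area(x[h], y[h])
}

#' Centre-of-luminescence trajectory of a movie
#'
#' Per frame, the intensity-weighted centroid over masked pixels. By default
#' the weights are the mean-subtracted, rectified intensities (each pixel's
#' temporal mean is removed and negative values set to zero), so the centroid
#' follows the currently active region rather than static anatomy; raw
#' intensities are available via `method = "raw"`. Centroid coordinates are
#' smoothed with a centred moving average to suppress shot-noise jitter.
#'
#' @param movie A [circa_movie].
#' @param mask Logical pixel mask.
#' @param method `"rectified"` (default) or `"raw"`.
#' @param smooth_window Centroid smoothing window, hours (default 2.5; 0
#'   disables smoothing).
#' @param min_weight_fraction Frames whose total weight falls below this
#'   fraction of the maximum frame weight are flagged (`NA` centroid); near
#'   the trough of the oscillation the rectified signal approaches zero and
#'   the centroid would otherwise be dominated by noise (default 0.1).
#' @return Data frame of class `circa_col`: `time_h`, `x_px` (column), `y_px`
#'   (row); flagged (zero- or low-weight) frames carry `NA` coordinates.
#' @export
col_series <- function(movie, mask, method = c("rectified", "raw"),
                       smooth_window = 2.5, min_weight_fraction = 0.1) {
  method <- match.arg(method)
  if (!any(mask)) stop("mask is empty")
  d <- dim(movie$data)
  mi <- which(mask)
  rows <- (mi - 1L) %% d[1] + 1L
  cols <- (mi - 1L) %/% d[1] + 1L
  flat <- matrix(movie$data, d[1] * d[2], d[3])[mi, , drop = FALSE]
  if (method == "rectified") {
    flat <- flat - rowMeans(flat)
    flat[flat < 0] <- 0
  }
  wsum <- colSums(flat)
  if (all(wsum == 0)) stop("degenerate input: all frames have zero weight")
  usable <- wsum > max(wsum) * min_weight_fraction
  x <- ifelse(usable, colSums(flat * cols) / wsum, NA_real_)
  y <- ifelse(usable, colSums(flat * rows) / wsum, NA_real_)
  if (smooth_window > 0) {
    n_win <- round(smooth_window / movie$frame_interval)
    if (n_win %% 2 == 0) n_win <- n_win + 1L
    if (n_win > 1) {
      x <- ma_partial(x, as.integer(n_win))
      y <- ma_partial(y, as.integer(n_win))
    }
  }
  structure(data.frame(time_h = movie_times(movie), x_px = x, y_px = y),
            class = c("circa_col", "data.frame"))
}

#' CoL trajectory area as a percentage of the slice area
#'
#' Segments the recording into cycles at the peaks of the conditioned
#' masked-mean trace, takes the convex hull of each cycle's centroid cloud
#' (the perimeter of the CoL excursion), and expresses its area as a
#' percentage of the area of the temporally integrated signal (the pixel
#' count of the thresholded temporal-mean image). Collinear or stationary
#' centroids give area 0.
#'
#' @param traj A `circa_col` trajectory from [col_series()].
#' @param movie The movie the trajectory came from.
#' @param mask Logical pixel mask used for the masked-mean cycle reference.
#' @param threshold Threshold (fraction of robust max) defining the reference
#'   area (default 0.2, as [mask_scn()]).
#' @param per_cycle If `TRUE` (default) the hull is computed per cycle and
#'   the mean reported; if `FALSE` a single hull over the whole recording is
#'   used.
#' @return List with `per_cycle` (data frame `cycle`, `n_frames`,
#'   `area_px2`, `area_pct`), `mean_pct`, and `reference_area_px`.
#' @export
col_trajectory_area <- function(traj, movie, mask, threshold = 0.2,
                                per_cycle = TRUE) {
  ref_area <- sum(mask_scn(movie, threshold = threshold))
  if (!per_cycle) {
    a <- hull_area(traj$x_px, traj$y_px)
    return(list(per_cycle = data.frame(cycle = 1L, n_frames = nrow(traj),
                                       area_px2 = a,
                                       area_pct = 100 * a / ref_area),
                mean_pct = 100 * a / ref_area,
                reference_area_px = ref_area))
  }
  d <- dim(movie$data)
  mean_trace <- circa_ts(colMeans(matrix(movie$data, d[1] * d[2], d[3])[which(mask), ,
                                                                        drop = FALSE]),
                         dt = movie$frame_interval, start_time = movie$start_time)
  pk <- find_peaks(condition_ts(mean_trace))
  if (nrow(pk) < 2L)
    stop("fewer than 2 reference peaks; cannot segment cycles")
  res <- list()
  for (k in seq_len(nrow(pk) - 1L)) {
    sel <- traj$time_h >= pk$peak_time[k] & traj$time_h < pk$peak_time[k + 1L]
    if (sum(is.finite(traj$x_px[sel])) < 3L) next
    a <- hull_area(traj$x_px[sel], traj$y_px[sel])
    res[[length(res) + 1L]] <- data.frame(cycle = k, n_frames = sum(sel),
                                          area_px2 = a,
                                          area_pct = 100 * a / ref_area)
  }
  if (!length(res)) stop("no cycle with >= 3 usable centroids")
  per <- do.call(rbind, res)
  list(per_cycle = per, mean_pct = mean(per$area_pct),
       reference_area_px = ref_area)
}

#' Write a CoL trajectory as CSV
#'
#' CSV schema: `time_h,x_px,y_px`.
#'
#' @param traj A `circa_col`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_col_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
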