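# Phase mapping of circadian movies over a grid of ROIs.
#
# CT convention used throughout: CT12 is the peak of the ensemble reference
# signal (the Per2::Luciferase convention), so an ROI peaking dt hours after
# the reference peak in a cycle of period tau sits at
# CT = (12 + 24 * dt / tau) mod 24.

# 4-connected component labelling (BFS); masks are small so plain R is fine
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  queue <- integer(h * w)
  for (p in which(mask)) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue[1L] <- p; lab[p] <- cur
    head <- 1L; tail <- 1L
    while (head <= tail) {
      q <- queue[head]; head <- head + 1L
      r <- (q - 1L) %% h + 1L
      cc <- (q - 1L) %/% h + 1L
      nbs <- c(if (r > 1L) q - 1L, if (r < h) q + 1L,
               if (cc > 1L) q - h, if (cc < w) q + h)
      for (nb in nbs) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
    }
  }
  lab
}

#' Threshold a movie to the slice (SCN) mask
#'
#' Builds a pixel mask of the tissue by thresholding the temporal-mean
#' intensity at a fraction of its robust maximum (99th percentile, robust to
#' hot pixels), then retaining the largest connected components (up to two,
#' for the bilateral nuclei). Removes extra-slice background signal before
#' ROI extraction.
#'
#' @param movie A [circa_movie].
#' @param threshold Fraction of the robust maximum (default 0.2).
#' @param max_components Number of largest connected components retained
#'   (default 2).
#' @return Logical matrix `height x width`.
#' @export
mask_scn <- function(movie, threshold = 0.2, max_components = 2) {
  m <- rowMeans(movie$data, dims = 2)
  robmax <- stats::quantile(m, 0.99, names = FALSE)
  if (robmax <= 0)
    stop("thresholding produced an empty mask (movie carries no signal)")
  mask <- m >= threshold * robmax
  if (!any(mask))
    stop(sprintf("thresholding produced an empty mask (threshold %.3g of robust max %.4g)",
                 threshold, robmax))
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(max_components, length(sizes)))]
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Extract per-ROI traces from a continuous grid of ROIs
#'
#' Tiles the frame with non-overlapping square cells of `cell_size` pixels
#' and extracts, for each cell with at least half of its pixels inside the
#' mask, the mean masked-pixel intensity per frame.
#'
#' @param movie A [circa_movie].
#' @param mask Logical pixel mask (from [mask_scn()] or a generator).
#' @param cell_size ROI cell edge, pixels (default 8).
#' @param min_mask_fraction Minimum masked fraction for a cell to carry a
#'   trace (default 0.5).
#' @return An object of class `circa_grid`: list with `rois` (data frame:
#'   `roi_row`, `roi_col`, `centre_row`, `centre_col`, `n_masked`), `traces`
#'   (matrix, one row per ROI), `dt`, `start_time`, `cell_size`, `dim`,
#'   `mask`.
#' @export
grid_rois <- function(movie, mask, cell_size = 8, min_mask_fraction = 0.5) {
  d <- dim(movie$data)
  if (cell_size < 1) stop("`cell_size` must be >= 1")
  if (cell_size > max(d[1], d[2]))
    stop("`cell_size` exceeds the frame size")
  row_blocks <- split(seq_len(d[1]), ceiling(seq_len(d[1]) / cell_size))
  col_blocks <- split(seq_len(d[2]), ceiling(seq_len(d[2]) / cell_size))
  flat <- matrix(movie$data, d[1] * d[2], d[3])
  rois <- list(); traces <- list()
  n <- 0L
  for (i in seq_along(row_blocks)) {
    for (j in seq_along(col_blocks)) {
      rr <- row_blocks[[i]]; cc <- col_blocks[[j]]
      cell_idx <- as.vector(outer(rr, (cc - 1L) * d[1], "+"))
      msk <- cell_idx[mask[cell_idx]]
      if (length(msk) < min_mask_fraction * length(cell_idx)) next
      n <- n + 1L
      rois[[n]] <- data.frame(roi_row = i, roi_col = j,
                              centre_row = mean(rr), centre_col = mean(cc),
                              n_masked = length(msk))
      traces[[n]] <- if (length(msk) == 1L) flat[msk, ] else colMeans(flat[msk, , drop = FALSE])
    }
  }
  if (n == 0L) stop("no ROI cell reaches the minimum masked fraction")
  structure(list(rois = do.call(rbind, rois),
                 traces = do.call(rbind, traces),
                 dt = movie$frame_interval, start_time = movie$start_time,
                 cell_size = cell_size, dim = d[1:2], mask = mask),
            class = "circa_grid")
}

#' Whole-field mean trace of a grid
#'
#' Mean of the masked-pixel signal across all ROIs carrying a trace (each ROI
#' weighted by its masked-pixel count, i.e. the plain mean over contributing
#' pixels). This is the default ensemble reference for phase normalisation.
#'
#' @param grid A `circa_grid` from [grid_rois()].
#' @return A [circa_ts].
#' @export
grid_mean_ts <- function(grid) {
  w <- grid$rois$n_masked
  circa_ts(colSums(grid$traces * w) / sum(w), dt = grid$dt,
           start_time = grid$start_time)
}

#' Extract one ROI trace
#' @param grid A `circa_grid`.
#' @param i ROI index (row of `grid$rois`).
#' @return A [circa_ts].
#' @export
roi_ts <- function(grid, i) {
  circa_ts(grid$traces[i, ], dt = grid$dt, start_time = grid$start_time)
}

# circular helpers on the CT (0-24 h) axis
ct_wrap <- function(x) x %% 24
ct_diff <- function(a, b) ((a - b + 12) %% 24) - 12
ct_circ_mean <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  ang <- 2 * pi * x / 24
  ct_wrap(atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi))
}

#' Per-cycle circadian phase map of a movie grid
#'
#' For each reference-signal peak k (at time `t_ref(k)`, cycle period
#' `tau(k)` from the peak-to-peak interval), each ROI's nearest conditioned
#' peak within half a cycle of `t_ref(k)` is converted to circadian time as
#' `CT = (12 + 24 * (t_roi - t_ref) / tau) mod 24`, so an ROI peaking with the
#' reference sits at CT12. Per-cycle phases are combined by circular (vector)
#' averaging. ROIs whose trace yields fewer than two peaks are left unphased.
#'
#' @param grid A `circa_grid` from [grid_rois()].
#' @param reference Optional [circa_ts] reference signal; default is the
#'   whole-field mean of the grid ([grid_mean_ts()]).
#' @param detrend_window,smooth_window Conditioning windows, hours.
#' @param min_separation,min_prominence Peak-search settings (see
#'   [find_peaks()]).
#' @return An object of class `circa_phasemap`: list with `rois`, `phase_ct`
#'   (circular-mean phase per ROI), `per_cycle` (ROI x cycle matrix),
#'   `ensemble_period` (mean reference peak-to-peak period, h),
#'   `reference_peaks` (h), `cell_size`, `dim`.
#' @export
compute_phase_map <- function(grid, reference = NULL, detrend_window = 24,
                              smooth_window = 2.5, min_separation = 16,
                              min_prominence = 0.1) {
  if (is.null(reference)) reference <- grid_mean_ts(grid)
  cond <- function(ts) condition_ts(ts, detrend_window, smooth_window)
  ref_peaks <- find_peaks(cond(reference), min_separation, min_prominence)
  if (nrow(ref_peaks) < 2L)
    stop("reference signal has fewer than 2 peaks; cannot define cycles")
  t_ref <- ref_peaks$peak_time
  n_cyc <- length(t_ref)
  taus <- diff(t_ref)
  tau_k <- c(taus, taus[length(taus)])  # last cycle reuses the final interval

  n_roi <- nrow(grid$rois)
  per_cycle <- matrix(NA_real_, n_roi, n_cyc)
  for (i in seq_len(n_roi)) {
    pk <- find_peaks(cond(roi_ts(grid, i)), min_separation, min_prominence)
    if (nrow(pk) < 2L) next
    for (k in seq_len(n_cyc)) {
      dtk <- pk$peak_time - t_ref[k]
      ok <- abs(dtk) <= tau_k[k] / 2
      if (!any(ok)) next
      j <- which(ok)[which.min(abs(dtk[ok]))]
      per_cycle[i, k] <- ct_wrap(12 + 24 * dtk[j] / tau_k[k])
    }
  }
  structure(list(rois = grid$rois,
                 phase_ct = apply(per_cycle, 1, ct_circ_mean),
                 per_cycle = per_cycle,
                 ensemble_period = mean(taus),
                 reference_peaks = t_ref,
                 cell_size = grid$cell_size, dim = grid$dim),
            class = "circa_phasemap")
}

#' @export
print.circa_phasemap <- function(x, ...) {
  cat(sprintf("<circa_phasemap> %d ROIs (%d phased), %d cycles, ensemble period %.2f h\n",
              nrow(x$rois), sum(!is.na(x$phase_ct)), ncol(x$per_cycle),
              x$ensemble_period))
  invisible(x)
}

#' @export
as.data.frame.circa_phasemap <- function(x, ...) {
  data.frame(roi_row = x$rois$roi_row, roi_col = x$rois$roi_col,
             phase_ct = x$phase_ct)
}

#' Circular span of a set of CT phases
#'
#' Width of the arc covered by the phases: phases are unwrapped around their
#' circular mean and the max-minus-min difference returned. Meaningful for
#' clustered (sub-half-cycle) phase distributions such as a wave's phase map.
#'
#' @param phase_ct Numeric vector of CT phases (h); `NA` ignored.
#' @return Span in hours.
#' @export
phase_span <- function(phase_ct) {
  x <- phase_ct[!is.na(phase_ct)]
  if (length(x) < 2L) return(0)
  d <- ct_diff(x, ct_circ_mean(x))
  max(d) - min(d)
}

#' Categorical phase-cluster map
#'
#' Bins each ROI's phase into ordered CT categories. The default edges give
#' the six categories `<CT10`, `CT10-11`, `CT11-12`, `CT12-13`, `CT13-14`,
#' `>CT14`.
#'
#' @param pm A `circa_phasemap`.
#' @param bin_edges Ascending CT bin edges in hours (default
#'   `c(10, 11, 12, 13, 14)`).
#' @return Data frame `roi_row`, `roi_col`, `phase_ct`, `cluster` (ordered
#'   factor).
#' @export
classify_phase_clusters <- function(pm, bin_edges = c(10, 11, 12, 13, 14)) {
  stopifnot(!is.unsorted(bin_edges))
  ne <- length(bin_edges)
  labs <- c(sprintf("<CT%g", bin_edges[1]),
            if (ne > 1) sprintf("CT%g-%g", bin_edges[-ne], bin_edges[-1]),
            sprintf(">CT%g", bin_edges[ne]))
  cl <- cut(pm$phase_ct, breaks = c(-Inf, bin_edges, Inf), labels = labs,
            ordered_result = TRUE, right = TRUE)
  data.frame(roi_row = pm$rois$roi_row, roi_col = pm$rois$roi_col,
             phase_ct = pm$phase_ct, cluster = cl)
}

#' Label ROIs inside/outside a fluorescence-delineated region
#'
#' Overlays a mean fluorescence image (e.g. an EYFP projection marking a
#' genetically defined cell population) with the movie's ROI grid: each ROI's
#' mean intensity is normalised to the mean over all ROIs, and ROIs with
#' normalised intensity strictly greater than 1 are labelled inside the
#' region, strictly less than 1 outside. Normalised intensity exactly equal
#' to 1 (e.g. a uniform image) is labelled outside, since membership is
#' defined by the strict inequality.
#'
#' @param fluor_image Numeric matrix registered to the movie frame.
#' @param grid A `circa_grid`.
#' @return Data frame `roi_row`, `roi_col`, `norm_intensity`, `inside`
#'   (logical).
#' @export
region_overlay <- function(fluor_image, grid) {
  if (all(fluor_image == 0))
    stop("degenerate input: fluorescence image is all zero")
  d <- grid$dim
  flat <- as.vector(fluor_image)
  vals <- numeric(nrow(grid$rois))
  for (i in seq_len(nrow(grid$rois))) {
    rr <- which(ceiling(seq_len(d[1]) / grid$cell_size) == grid$rois$roi_row[i])
    cc <- which(ceiling(seq_len(d[2]) / grid$cell_size) == grid$rois$roi_col[i])
    vals[i] <- mean(flat[as.vector(outer(rr, (cc - 1L) * d[1], "+"))])
  }
  norm <- vals / mean(vals)
  data.frame(roi_row = grid$rois$roi_row, roi_col = grid$rois$roi_col,
             norm_intensity = norm, inside = norm > 1)
}

#' Baseline-normalised change map
#'
#' Expresses each ROI trace as a relative change from its own baseline: the
#' mean over a stated pre-event window. Used to map acute induction responses
#' (e.g. to optogenetic stimulation).
#'
#' @param grid A `circa_grid`.
#' @param baseline_window `c(from, to)` in hours; must precede the event of
#'   interest.
#' @return List with `times` (h), `rel_change` (ROI x frame matrix of
#'   `(value - baseline) / baseline`; rows of zero-baseline ROIs are `NA` and
#'   listed in `flagged`), and `rois`.
#' @export
normalized_change_map <- function(grid, baseline_window) {
  t <- grid$start_time + (seq_len(ncol(grid$traces)) - 1L) * grid$dt
  sel <- t >= baseline_window[1] & t <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no frames")
  base <- rowMeans(grid$traces[, sel, drop = FALSE])
  rel <- (grid$traces - base) / base
  flagged <- which(base == 0)
  if (length(flagged)) rel[flagged, ] <- NA_real_
  list(times = t, rel_change = rel, rois = grid$rois, flagged = flagged)
}

#' Write a phase map (with optional clusters) as CSV
#'
#' CSV schema: `roi_row,roi_col,phase_ct[,cluster]`.
#'
#' @param pm A `circa_phasemap`.
#' @param path Output path.
#' @param bin_edges If non-`NULL`, cluster labels with these edges are added.
#' @return Invisibly, `path`.
#' @export
write_phasemap_csv <- function(pm, path, bin_edges = c(10, 11, 12, 13, 14)) {
  d <- if (is.null(bin_edges)) as.data.frame(pm)
       else classify_phase_clusters(pm, bin_edges)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Image plot of a phase map
#'
#' Renders the circular-mean phase map with a cyclic HSV colour scale (CT0
#' and CT24 share a hue).
#'
#' @param pm A `circa_phasemap`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the phase matrix that was plotted.
#' @export
plot_phase_map <- function(pm, ...) {
  nr <- max(pm$rois$roi_row); nc <- max(pm$rois$roi_col)
  m <- matrix(NA_real_, nr, nc)
  m[cbind(pm$rois$roi_row, pm$rois$roi_col)] <- pm$phase_ct
  cols <- grDevices::hsv(seq(0, 1, length.out = 65)[-65])
  graphics::image(x = seq_len(nc), y = seq_len(nr), z = t(m)[, nr:1],
                  col = cols, zlim = c(0, 24), xlab = "ROI column",
                  ylab = "ROI row", ...)
  invisible(m)
}
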