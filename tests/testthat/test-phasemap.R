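test_that("slice masking keeps tissue and drops background", {
  # full-frame uniform movie: everything in the mask
  arr <- array(10, dim = c(8, 8, 4))
  expect_true(all(mask_scn(circa_movie(arr, 1), threshold = 0.5)))
  # bilateral blobs on zero background: mask equals the generator mask
  p <- movie_params(height = 48, width = 48, n_cycles = 3,
                    mask_shape = "bilateral-ellipse", seed = 1)
  sim <- make_movie(p)
  expect_identical(mask_scn(sim$movie), sim$truth$mask)
  # 10% background at threshold 0.5 is excluded
  p <- movie_params(height = 48, width = 48, n_cycles = 3, background = 10,
                    baseline = 100, mask_shape = "disc", seed = 1)
  sim <- make_movie(p)
  m <- mask_scn(sim$movie, threshold = 0.5)
  expect_true(all(!m[!sim$truth$mask]))
  expect_gt(mean(m[sim$truth$mask]), 0.95)
  expect_error(mask_scn(circa_movie(array(0, c(4, 4, 2)), 1)), "empty mask")
})

test_that("grid ROI extraction averages masked pixels per cell", {
  arr <- array(rep(1:16, each = 1), dim = c(4, 4, 3))
  mv <- circa_movie(arr, 1)
  mask <- matrix(TRUE, 4, 4)
  # single whole-frame ROI equals the field mean
  g <- grid_rois(mv, mask, cell_size = 4)
  expect_equal(nrow(g$rois), 1)
  expect_equal(as.numeric(g$traces[1, ]), rep(mean(arr[, , 1]), 3))
  # uniform movie: all ROI traces identical
  g <- grid_rois(circa_movie(array(5, c(8, 8, 4)), 1), matrix(TRUE, 8, 8), 2)
  expect_equal(nrow(unique(g$traces)), 1)
  expect_error(grid_rois(mv, mask, cell_size = 10), "exceeds the frame")
  # cells below the masked-fraction floor carry no trace
  mask2 <- matrix(FALSE, 8, 8); mask2[1:4, ] <- TRUE
  g <- grid_rois(circa_movie(array(1, c(8, 8, 2)), 1), mask2, 4)
  expect_equal(unique(g$rois$roi_row), 1L)
})

test_that("phase normalisation follows the CT12-at-reference-peak convention", {
  tt <- seq(0, 120, by = 0.5)
  ref <- circa_ts(100 + 50 * cos(2 * pi * (tt - 12) / 24), dt = 0.5)
  # build a 2-pixel movie: one in phase with the reference, one 1 h earlier
  arr <- array(0, dim = c(1, 2, length(tt)))
  arr[1, 1, ] <- ref$values
  arr[1, 2, ] <- 100 + 50 * cos(2 * pi * (tt - 11) / 24)
  g <- grid_rois(circa_movie(arr, 0.5), matrix(TRUE, 1, 2), cell_size = 1)
  pm <- compute_phase_map(g, reference = ref)
  expect_equal(pm$phase_ct[1], 12, tolerance = 1e-6)
  expect_equal(pm$phase_ct[2], 11, tolerance = 1e-6)
  expect_equal(pm$ensemble_period, 24, tolerance = 1e-6)
})

test_that("a gradient movie's phase map recovers the generator ground truth", {
  p <- movie_params(height = 48, width = 48, frame_interval = 0.5,
                    n_cycles = 5, period = 24, phase_gradient_span = 3,
                    mask_shape = "disc", seed = 13)
  sim <- make_movie(p)
  g <- grid_rois(sim$movie, sim$truth$mask, cell_size = 8)
  pm <- compute_phase_map(g)
  gt <- roi_truth_phases(g, sim$truth)
  err <- ct_delta(pm$phase_ct, gt)
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 0.25)
  expect_equal(phase_span(pm$phase_ct), phase_span(gt), tolerance = 0.3)
  # ordered spatial bands: cluster map follows the gradient row order
  cl <- classify_phase_clusters(pm, bin_edges = c(11, 11.5, 12, 12.5, 13))
  med_row <- tapply(cl$roi_row, cl$cluster, stats::median)
  med_row <- med_row[!is.na(med_row)]
  expect_gte(length(med_row), 4)
  expect_true(all(diff(med_row) > 0))
})

test_that("phase maps are invariant to per-ROI affine intensity rescaling", {
  p <- movie_params(height = 24, width = 24, frame_interval = 0.5,
                    n_cycles = 5, phase_gradient_span = 2, mask_shape = "disc",
                    seed = 5)
  sim <- make_movie(p)
  g <- grid_rois(sim$movie, sim$truth$mask, cell_size = 6)
  ref <- grid_mean_ts(g)
  pm1 <- compute_phase_map(g, reference = ref)
  set.seed(1)
  gains <- runif(nrow(g$rois), 0.5, 2)
  offs <- runif(nrow(g$rois), -20, 20)
  g2 <- g
  g2$traces <- g$traces * gains + offs
  pm2 <- compute_phase_map(g2, reference = ref)
  expect_equal(pm2$phase_ct, pm1$phase_ct, tolerance = 1e-9)
})

test_that("whole-field reference equals an externally supplied identical trace", {
  p <- movie_params(height = 24, width = 24, frame_interval = 0.5, n_cycles = 5,
                    phase_gradient_span = 2, mask_shape = "disc", seed = 9)
  sim <- make_movie(p)
  g <- grid_rois(sim$movie, sim$truth$mask, cell_size = 6)
  pm_int <- compute_phase_map(g)
  pm_ext <- compute_phase_map(g, reference = grid_mean_ts(g))
  expect_identical(pm_int$phase_ct, pm_ext$phase_ct)
})

test_that("phase clusters bin phases on the stated CT edges", {
  pm <- structure(list(rois = data.frame(roi_row = 1:4, roi_col = 1),
                       phase_ct = c(12.5, 9.5, 10.5, 14.5),
                       per_cycle = matrix(12.5, 4, 1),
                       ensemble_period = 24),
                  class = "circa_phasemap")
  cl <- classify_phase_clusters(pm)
  expect_equal(as.character(cl$cluster),
               c("CT12-13", "<CT10", "CT10-11", ">CT14"))
  # single phase value -> single occupied category
  pm$phase_ct <- rep(12.5, 4)
  expect_equal(unique(as.character(classify_phase_clusters(pm)$cluster)),
               "CT12-13")
  # labels exhaust the ordered bin set
  expect_equal(levels(cl$cluster),
               c("<CT10", "CT10-11", "CT11-12", "CT12-13", "CT13-14", ">CT14"))
})

test_that("region overlay uses strict normalised-intensity inequalities", {
  arr <- array(1, dim = c(8, 8, 3))
  g <- grid_rois(circa_movie(arr, 1), matrix(TRUE, 8, 8), 2)
  # uniform image: normalised intensity 1 everywhere -> nothing inside
  ov <- region_overlay(matrix(5, 8, 8), g)
  expect_true(all(ov$norm_intensity == 1))
  expect_true(all(!ov$inside))
  # left half bright: left inside, right outside
  img <- cbind(matrix(2, 8, 4), matrix(0, 8, 4))
  ov <- region_overlay(img, g)
  expect_true(all(ov$inside[ov$roi_col <= 2]))
  expect_true(all(!ov$inside[ov$roi_col > 2]))
  expect_error(region_overlay(matrix(0, 8, 8), g), "all zero")
})

test_that("a fluorescent blob over part of the slice is recovered by the overlay", {
  p <- movie_params(height = 32, width = 32, n_cycles = 3, mask_shape = "disc",
                    seed = 2)
  sim <- make_movie(p)
  g <- grid_rois(sim$movie, sim$truth$mask, cell_size = 4)
  img <- matrix(1, 32, 32)
  img[10:22, 10:16] <- 5  # synthetic reporter-positive territory
  ov <- region_overlay(img, g)
  blob <- g$rois$centre_row >= 10 & g$rois$centre_row <= 22 &
    g$rois$centre_col >= 10 & g$rois$centre_col <= 16
  expect_gt(mean(ov$inside[blob]), 0.9)
  expect_lt(mean(ov$inside[!blob]), 0.1)
})

test_that("normalised change maps express change relative to the ROI baseline", {
  arr <- array(10, dim = c(4, 4, 20))
  arr[, , 11:20] <- 15  # step to 1.5x baseline
  g <- grid_rois(circa_movie(arr, 1), matrix(TRUE, 4, 4), 2)
  nc <- normalized_change_map(g, baseline_window = c(0, 9))
  expect_true(all(abs(nc$rel_change[, 1:10]) < 1e-12))
  expect_true(all(abs(nc$rel_change[, 11:20] - 0.5) < 1e-12))
  # induction transient: ROI-mean change peaks at the generator peak frame
  tt <- 0:47
  resp <- pmax(0, (tt - 10) / 4) * exp(-(tt - 10) / 6)
  arr <- array(rep(20, 4 * 4 * 48), dim = c(4, 4, 48))
  for (k in seq_along(tt)) arr[, , k] <- 20 * (1 + resp[k])
  g <- grid_rois(circa_movie(arr, 1), matrix(TRUE, 4, 4), 2)
  nc <- normalized_change_map(g, baseline_window = c(0, 9))
  expect_equal(which.max(colMeans(nc$rel_change)), which.max(resp))
  # zero-baseline ROI flagged
  arr[1:2, 1:2, 1:10] <- 0
  g <- grid_rois(circa_movie(arr, 1), matrix(TRUE, 4, 4), 2)
  nc <- normalized_change_map(g, baseline_window = c(0, 9))
  expect_true(1 %in% nc$flagged)
  expect_true(all(is.na(nc$rel_change[1, ])))
})
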