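# Shared helpers: ground-truth aggregation and small oracles used across
# test files. Oracles are deliberately naive/brute-force and independent of
# the implementation paths they check.

# circular mean of ground-truth pixel phases within each ROI cell of a grid
roi_truth_phases <- function(grid, truth) {
  d <- grid$dim
  vapply(seq_len(nrow(grid$rois)), function(i) {
    rr <- which(ceiling(seq_len(d[1]) / grid$cell_size) == grid$rois$roi_row[i])
    cc <- which(ceiling(seq_len(d[2]) / grid$cell_size) == grid$rois$roi_col[i])
    px <- as.vector(outer(rr, (cc - 1L) * d[1], "+"))
    ph <- truth$phase_ct[px]
    ph <- ph[!is.na(ph)]
    ang <- 2 * pi * ph / 24
    (atan2(mean(sin(ang)), mean(cos(ang))) * 24 / (2 * pi)) %% 24
  }, numeric(1))
}

# signed circular difference on the CT axis, in (-12, 12]
ct_delta <- function(a, b) ((a - b + 12) %% 24) - 12

# naive loop oracle for the LvR statistic (independent of the vectorised path)
lvr_loop_oracle <- function(isis, R) {
  n <- length(isis)
  acc <- 0
  for (i in seq_len(n - 1)) {
    s <- isis[i] + isis[i + 1]
    acc <- acc + (1 - 4 * isis[i] * isis[i + 1] / s^2) * (1 + 4 * R / s)
  }
  3 / (n - 1) * acc
}

# discrete moving-average gain of a cosine of period `tau` under an n-sample
# window at spacing dt (Dirichlet kernel closed form)
ma_cosine_gain <- function(n_win, dt, tau) {
  sin(n_win * pi * dt / tau) / (n_win * sin(pi * dt / tau))
}
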