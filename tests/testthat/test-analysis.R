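# lightweight series construction for analysis-level tests
forge_series <- function(frames, voxel_mm = 7.5, frame_s = 60) {
  n <- dim(frames[[1]])
  data <- array(0, dim = c(n, length(frames)))
  for (i in seq_along(frames)) data[, , , i] <- frames[[i]]
  ft <- tibble::tibble(frame = seq_along(frames),
                       t_start_s = (seq_along(frames) - 1) * frame_s,
                       t_end_s = seq_along(frames) * frame_s)
  ft$t_mid_s <- (ft$t_start_s + ft$t_end_s) / 2
  structure(list(data = data, grid = grid_spec(n, voxel_mm), frames = ft,
                 frame_duration_s = frame_s, window = 1L,
                 apodization = "none"),
            class = "image_series")
}

forge_tc <- function(values, region = "roi", frame_s = 60) {
  o17mri:::new_roi_timecourse(tibble::tibble(
    region = region, frame = seq_along(values),
    time_s = (seq_along(values) - 0.5) * frame_s, value = values))
}

test_that("roi_mean_series matches a voxel-loop oracle", {
  n <- c(8, 8, 8)
  f1 <- array(3, dim = n)
  chk <- array((1:prod(n)) %% 2, dim = n) * 2 + 1
  ser <- forge_series(list(f1, chk))
  mask <- array(rep(c(TRUE, FALSE), length.out = prod(n)), dim = n)
  tc <- roi_mean_series(ser, mask)
  # uniform frame -> the constant
  expect_equal(tc$value[1], 3)
  acc <- 0; cnt <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    if (mask[i, j, k]) { acc <- acc + chk[i, j, k]; cnt <- cnt + 1 }
  expect_equal(tc$value[2], acc / cnt)
  # single-voxel mask returns that voxel's trace
  mv <- array(FALSE, dim = n); mv[2, 5, 7] <- TRUE
  tv <- roi_mean_series(ser, mv)
  expect_equal(tv$value, c(f1[2, 5, 7], chk[2, 5, 7]))
  expect_error(roi_mean_series(ser, array(FALSE, dim = n)), "empty")
})

test_that("baseline normalization divides by the early-frame mean", {
  expect_equal(normalize_to_baseline(forge_tc(rep(4, 8)), 5)$value, rep(1, 8))
  tc <- normalize_to_baseline(forge_tc(c(2, 2, 2, 2, 2, 3)), 5)
  expect_equal(tc$value, c(1, 1, 1, 1, 1, 1.5))
  expect_true(attr(tc, "normalized"))
  a <- normalize_to_baseline(forge_tc(c(1, 1.1, 0.9, 1, 1, 1.3)), 5)$value
  b <- normalize_to_baseline(forge_tc(2 * c(1, 1.1, 0.9, 1, 1, 1.3)), 5)$value
  expect_equal(a, b)
  expect_error(normalize_to_baseline(forge_tc(c(0, 0, 0, 0, 0, 1)), 5),
               "positive")
  expect_error(normalize_to_baseline(forge_tc(c(1, 1)), 5), "fewer")
})

test_that("switch-window averaging is centred and tie-broken to the later frame", {
  expect_equal(mean_around_switch(forge_tc(rep(1.18, 15)), 11), 1.18)
  ramp <- forge_tc(seq(1, 2, length.out = 15))
  # mid-times are (i - 0.5) min; 11 min ties between frames 11 and 12
  expect_equal(mean_around_switch(ramp, 11), ramp$value[12])
  # off-tie switch centres on the nearest frame
  expect_equal(mean_around_switch(ramp, 10.4), ramp$value[11])
  expect_error(mean_around_switch(forge_tc(rep(1, 4)), 3.5, 5), "outside")
})

test_that("baseline CV uses the sample-sd convention", {
  expect_equal(baseline_cv(forge_tc(rep(2, 6))), 0)
  v <- c(1, 1, 1, 1, 1.1)
  expect_equal(baseline_cv(forge_tc(v)), 100 * sd(v) / mean(v))
  expect_equal(baseline_cv(forge_tc(v)), 4.3844, tolerance = 1e-4)
  expect_equal(baseline_cv(forge_tc(3 * v)), baseline_cv(forge_tc(v)))
  expect_error(baseline_cv(forge_tc(v), 1), "two")
  expect_error(baseline_cv(forge_tc(c(1, 1)), 5), "fewer")
})

test_that("mask mirroring is an exact index reflection and involution", {
  n <- c(10, 9, 8)
  m <- array(runif(prod(n)) > 0.7, dim = n)
  expect_identical(mirror_mask(mirror_mask(m)), m)
  expect_identical(sum(mirror_mask(m)), sum(m))
  sv <- array(FALSE, dim = n); sv[3, 4, 5] <- TRUE   # 0-based x = 2
  mm <- which(mirror_mask(sv), arr.ind = TRUE)
  expect_equal(unname(mm[1, ]), c(10 - 3 + 1, 4, 5))  # 0-based N-1-x
  sym <- array(FALSE, dim = n); sym[c(2, 9), 5, 5] <- TRUE
  expect_identical(mirror_mask(sym), sym)
})

test_that("ventricle-margin exclusion follows 6-connected dilation", {
  n <- c(12, 8, 8)
  roi <- array(FALSE, dim = n); roi[4:9, 1, 1] <- TRUE    # 0-based x 3..8
  vent <- array(FALSE, dim = n); vent[1:2, 1, 1] <- TRUE  # 0-based x 0..1
  out2 <- exclude_ventricle_margin(roi, vent, 2)
  expect_equal(which(out2[, 1, 1]), 5:9)                  # 0-based 4..8
  out0 <- exclude_ventricle_margin(roi, vent, 0)
  expect_equal(which(out0[, 1, 1]), 4:9)
  far <- array(FALSE, dim = n); far[10:11, 5, 5] <- TRUE
  expect_identical(exclude_ventricle_margin(far, vent, 2), far)
  expect_warning(exclude_ventricle_margin(vent, vent, 1), "empty")
})

test_that("dice coefficient matches its definition", {
  n <- c(8, 8, 8)
  a <- array(FALSE, dim = n); a[1:2, 1:2, 1:2] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- array(FALSE, dim = n); b[5:6, 5:6, 5:6] <- TRUE
  expect_equal(dice(a, b), 0)
  c8 <- array(FALSE, dim = n); c8[1:2, 1:2, 1:2] <- TRUE
  c8[1, 1, 1:2] <- FALSE; c8[5, 5, 5:6] <- TRUE   # |A|=|B|=8, overlap 6
  expect_equal(dice(a, c8), 0.75)
  expect_error(dice(array(FALSE, n), array(FALSE, n)), "empty")
})

test_that("relative increase maps divide out the baseline", {
  ph <- tiny_phantom()
  base <- array(0, dim = ph$grid$n)
  base[ph$labels > 0] <- 1
  fr <- function(arr) structure(list(data = arr, grid = ph$grid,
                                     t_start_s = 0, t_end_s = 180,
                                     n_projections = 1, apodization = "none"),
                                class = "image_frame")
  same <- relative_increase_map(fr(base), fr(base), zero_fill_factor = 1)
  expect_equal(max(abs(same$data), na.rm = TRUE), 0)
  up <- relative_increase_map(fr(base), fr(base * 1.2), zero_fill_factor = 1)
  expect_equal(unique(round(up$data[!is.na(up$data) & base > 0], 10)), 0.2)
  expect_true(any(is.na(up$data)))  # background masked out
})

test_that("roi_contrast reproduces the printed stroke deficit", {
  expect_equal(roi_contrast(1.2, 1.2), 0)
  expect_equal(round(roi_contrast(1.158, 1.168), 1), 0.9)
  # antisymmetric to first order in the contrast
  eps <- 1e-3
  expect_equal(roi_contrast(1, 1 + eps), -roi_contrast(1 + eps, 1),
               tolerance = eps)
  expect_error(roi_contrast(-1, 1), "positive")
})
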