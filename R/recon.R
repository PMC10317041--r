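# Gridding machinery ---------------------------------------------------------
#
# Convolution gridding onto a 2x-oversampled Cartesian k-grid with an odd
# matrix size M = 2N + 1 (odd so every frequency has a paired negative and
# left-right-symmetric sample sets grid to exactly mirror-symmetric arrays),
# Kaiser-Bessel kernel of width 4 grid cells, analytic density compensation
# from the radius schedule, and closed-form deapodization. The inverse FFT is
# evaluated at the voxel-centre coordinates j - (N-1)/2 through a half-voxel
# phase ramp, so image indices line up with phantom voxels for any N parity.

GRID_KERNEL_WIDTH <- 4

kb_beta <- function(width, os) pi * sqrt((width / os)^2 * (os - 0.5)^2 - 0.8)

# Image-domain transform of the width-W Kaiser-Bessel kernel (deapodization).
kb_apod <- function(x, M, width, beta) {
  t <- beta^2 - (pi * width * x / M)^2
  ifelse(t > 0, sinh(sqrt(t)) / sqrt(t),
         ifelse(t < 0, sin(sqrt(-t)) / sqrt(-t), 1))
}

# Analytic density-compensation weights (k-space volume per sample) for the
# density-adapted schedule: proportional to k^2 in the linear segment and
# constant beyond k0, where the schedule itself equalizes shell density.
density_weights <- function(traj) {
  pmin(traj$radius_norm, traj$k0_norm)^2
}

# Hamming window as a function of |k|/kmax.
hamming_radial <- function(rnorm) 0.54 + 0.46 * cos(pi * pmin(rnorm, 1))

#' Reconstruct one image frame from radial samples by convolution gridding
#'
#' Density-compensates the samples with the analytic weights of the
#' density-adapted schedule, scatters them onto an oversampled Cartesian
#' k-grid with a separable Kaiser-Bessel kernel, optionally applies a radial
#' Hamming window in k-space, inverse-Fourier transforms, deapodizes, and
#' returns the magnitude image.
#'
#' @param kspace A `kspace_series`.
#' @param grid Target [grid_spec()].
#' @param spokes Integer indices of the spokes to use (default: all).
#' @param apodization `"hamming"` or `"none"`.
#' @return An `image_frame`: list with magnitude array `data`, `grid`,
#'   `t_start_s`/`t_end_s`, `n_projections`, `apodization`.
#' @export
grid_reconstruct <- function(kspace, grid, spokes = NULL,
                             apodization = c("hamming", "none")) {
  stopifnot(inherits(kspace, "kspace_series"), inherits(grid, "grid_spec"))
  apodization <- match.arg(apodization)
  if (is.null(spokes)) spokes <- seq_len(nrow(kspace$samples))
  if (length(spokes) == 0) stop("spoke window is empty")
  traj <- kspace$traj
  if (max(traj$radius_norm) > 1 + 1e-9)
    stop("trajectory contains samples beyond k_max")
  vals <- as.vector(t(kspace$samples[spokes, , drop = FALSE]))  # sample-fastest
  cx <- recon_complex(vals, traj, spokes, grid, apodization)
  structure(list(
    data = array(Mod(cx), dim = grid$n), grid = grid,
    t_start_s = min(kspace$timestamp_s[spokes]),
    t_end_s = max(kspace$timestamp_s[spokes]) + traj$seq$tr_ms / 1000,
    n_projections = length(spokes), apodization = apodization
  ), class = "image_frame")
}

# Complex-valued gridding reconstruction (shared by grid_reconstruct and the
# linearity-preserving internal paths).
recon_complex <- function(vals, traj, spokes, grid, apodization) {
  N <- grid$n
  if (length(unique(N)) != 1)
    stop("gridding reconstruction requires a cubic grid")
  N <- N[1]
  M <- 2L * N + 1L
  os <- M / N
  beta <- kb_beta(GRID_KERNEL_WIDTH, os)
  kmax_vox <- traj$kmax_mm * grid$voxel_mm
  if (kmax_vox > 0.5 + 1e-9) stop("samples beyond the grid Nyquist radius")
  np <- length(traj$radius_norm)
  w <- density_weights(traj)
  if (apodization == "hamming") w <- w * hamming_radial(traj$radius_norm)
  # volume element per sample: dOmega * k^2 dk/dt dt, normalized schedule
  w_full <- rep(w, times = length(spokes)) *
    (4 * pi / length(spokes)) * (kmax_vox^3 / np)
  u <- traj_points(traj, spokes, grid$voxel_mm) * M
  G <- cpp_grid_kspace(u, as.complex(vals), w_full, M,
                       GRID_KERNEL_WIDTH, beta)
  # half-voxel phase ramp: evaluate the interpolant at j - (N-1)/2
  fv <- c(0:((M - 1) / 2), -((M - 1) / 2):-1)
  ramp <- exp(-2i * pi * fv * ((N - 1) / 2) / M)
  G <- G * array(rep(ramp, times = M * M), dim = c(M, M, M))
  G <- G * array(rep(rep(ramp, each = M), times = M), dim = c(M, M, M))
  G <- G * array(rep(ramp, each = M * M), dim = c(M, M, M))
  img <- fft(G, inverse = TRUE)
  img <- img[seq_len(N), seq_len(N), seq_len(N)]
  ax <- kb_apod(seq_len(N) - 1 - (N - 1) / 2, M, GRID_KERNEL_WIDTH, beta)
  deapod <- array(rep(ax, times = N * N), dim = c(N, N, N)) *
    array(rep(rep(ax, each = N), times = N), dim = c(N, N, N)) *
    array(rep(ax, each = N * N), dim = c(N, N, N))
  img / deapod
}

#' Exact (slow) reference reconstruction by direct inverse DFT
#'
#' Evaluates the density-compensated adjoint non-uniform DFT at every voxel
#' centre, with the same analytic weights and optional Hamming window as
#' [grid_reconstruct()], but no gridding kernel. Used as the accuracy
#' reference for the gridding path; cost is O(samples x voxels).
#'
#' @inheritParams grid_reconstruct
#' @return An `image_frame`.
#' @export
direct_reconstruct <- function(kspace, grid, spokes = NULL,
                               apodization = c("hamming", "none")) {
  stopifnot(inherits(kspace, "kspace_series"), inherits(grid, "grid_spec"))
  apodization <- match.arg(apodization)
  if (is.null(spokes)) spokes <- seq_len(nrow(kspace$samples))
  if (length(spokes) == 0) stop("spoke window is empty")
  traj <- kspace$traj
  kmax_vox <- traj$kmax_mm * grid$voxel_mm
  np <- length(traj$radius_norm)
  w <- density_weights(traj)
  if (apodization == "hamming") w <- w * hamming_radial(traj$radius_norm)
  w_full <- rep(w, times = length(spokes)) *
    (4 * pi / length(spokes)) * (kmax_vox^3 / np)
  u <- traj_points(traj, spokes, grid$voxel_mm)
  vals <- as.vector(t(kspace$samples[spokes, , drop = FALSE]))
  cx <- cpp_ndft_adjoint(u, as.complex(vals), w_full, grid_coords(grid))
  structure(list(
    data = array(Mod(cx), dim = grid$n), grid = grid,
    t_start_s = min(kspace$timestamp_s[spokes]),
    t_end_s = max(kspace$timestamp_s[spokes]) + traj$seq$tr_ms / 1000,
    n_projections = length(spokes), apodization = apodization
  ), class = "image_frame")
}

#' Sliding-window reconstruction of the dynamic series
#'
#' Frame `i` is reconstructed from spokes `[(i-1) w + 1, i w]` (stride equal
#' to the window, i.e. contiguous non-overlapping frames, which reproduces
#' the printed frame counts: 90000 projections / 3000 per image = 30 images).
#' Leftover spokes that do not fill a window are discarded with a warning.
#'
#' @param kspace A `kspace_series`.
#' @param window Projections per frame (default 3000).
#' @param grid Target [grid_spec()].
#' @param apodization `"hamming"` or `"none"`.
#' @param frames Optional integer vector of frame indices to reconstruct
#'   (default: all full windows). Frame numbering and timing are unchanged;
#'   unreconstructed frames are simply absent from the output.
#' @return An `image_series`: list with 4D array `data` (x, y, z, frame),
#'   `grid`, tibble `frames` (frame, t_start_s, t_end_s, t_mid_s),
#'   `frame_duration_s`, `window`, `apodization`.
#' @export
sliding_window_series <- function(kspace, window = 3000, grid,
                                  apodization = c("hamming", "none"),
                                  frames = NULL) {
  stopifnot(inherits(kspace, "kspace_series"))
  apodization <- match.arg(apodization)
  if (window <= 0) stop("window must be a positive number of spokes")
  nspk <- nrow(kspace$samples)
  if (window > nspk) stop("window exceeds the number of acquired spokes")
  nframes <- floor(nspk / window)
  left <- nspk - nframes * window
  if (left > 0)
    warning(sprintf("discarding %d leftover spokes (%d full windows)",
                    left, nframes))
  if (is.null(frames)) frames <- seq_len(nframes)
  if (any(frames < 1 | frames > nframes)) stop("frame index out of range")
  recs <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    spk <- ((frames[i] - 1) * window + 1):(frames[i] * window)
    recs[[i]] <- grid_reconstruct(kspace, grid, spokes = spk,
                                  apodization = apodization)
  }
  data <- array(0, dim = c(grid$n, length(frames)))
  for (i in seq_along(frames)) data[, , , i] <- recs[[i]]$data
  ft <- tibble::tibble(
    frame = frames,
    t_start_s = vapply(recs, function(f) f$t_start_s, numeric(1)),
    t_end_s = vapply(recs, function(f) f$t_end_s, numeric(1))
  )
  ft$t_mid_s <- (ft$t_start_s + ft$t_end_s) / 2
  structure(list(data = data, grid = grid, frames = ft,
                 frame_duration_s = window * kspace$traj$seq$tr_ms / 1000,
                 window = as.integer(window), apodization = apodization),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %d frames of %d x %d x %d, %g s per frame\n",
              dim(x$data)[4], x$grid$n[1], x$grid$n[2], x$grid$n[3],
              x$frame_duration_s))
  invisible(x)
}

# Extract frame i of a series as an image_frame.
series_frame <- function(series, i) {
  structure(list(data = series$data[, , , i], grid = series$grid,
                 t_start_s = series$frames$t_start_s[i],
                 t_end_s = series$frames$t_end_s[i],
                 n_projections = series$window,
                 apodization = series$apodization),
            class = "image_frame")
}

#' Zero-fill an image frame to a finer grid
#'
#' Pads the frame's discrete spectrum symmetrically to `factor` times the
#' matrix size per axis before the inverse transform, i.e. sinc-interpolates
#' the image onto a grid with voxel size divided by `factor`. Voxel `[0,0,0]`
#' of the fine grid coincides with voxel `[0,0,0]` of the original, and fine
#' voxel `factor * j` reproduces the original value at voxel `j` exactly; no
#' new spatial frequencies are introduced.
#'
#' @param frame An `image_frame` (or bare 3D array).
#' @param factor Integer upsampling factor >= 1.
#' @return An `image_frame` on the refined grid.
#' @export
zero_fill <- function(frame, factor) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be a single integer >= 1")
  factor <- as.integer(factor)
  arr <- if (inherits(frame, "image_frame")) frame$data else frame
  if (factor > 1) arr <- zero_fill_array(arr, factor)
  g <- if (inherits(frame, "image_frame")) frame$grid else NULL
  fine_grid <- if (!is.null(g))
    grid_spec(g$n * factor, g$voxel_mm / factor) else NULL
  structure(list(
    data = arr, grid = fine_grid,
    t_start_s = if (!is.null(g)) frame$t_start_s else NA_real_,
    t_end_s = if (!is.null(g)) frame$t_end_s else NA_real_,
    n_projections = if (!is.null(g)) frame$n_projections else NA_integer_,
    apodization = if (!is.null(g)) frame$apodization else "none"
  ), class = "image_frame")
}

# Spectrum-padding upsampler with even-size Nyquist-plane splitting (keeps
# the interpolant real and exact at original sample locations).
zero_fill_array <- function(arr, factor) {
  d <- dim(arr)
  S <- fft(arr)
  for (ax in 1:3) S <- pad_axis(S, ax, d[ax], factor)
  Re(fft(S, inverse = TRUE)) / prod(d)
}

pad_axis <- function(S, ax, n, factor) {
  m <- n * factor
  dn <- dim(S)
  dm <- dn; dm[ax] <- m
  out <- array(0 + 0i, dim = dm)
  idx_out <- function(i) {
    ix <- lapply(seq_along(dm), function(a) seq_len(dm[a]))
    ix[[ax]] <- i
    ix
  }
  idx_in <- function(i) {
    ix <- lapply(seq_along(dn), function(a) seq_len(dn[a]))
    ix[[ax]] <- i
    ix
  }
  h <- floor(n / 2)
  lo <- 1:(h + 1)                       # frequencies 0..h
  out_part <- do.call(`[`, c(list(S), idx_in(lo), list(drop = FALSE)))
  out <- do.call(`[<-`, c(list(out), idx_out(lo), list(out_part)))
  if (n > 1) {
    hi_in <- (h + 2):n                  # negative frequencies
    hi_out <- (m - (n - h - 1) + 1):m
    part <- do.call(`[`, c(list(S), idx_in(hi_in), list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_out(hi_out), list(part)))
  }
  if (n %% 2 == 0) {
    # split the Nyquist plane (frequency n/2 appeared once; mirror it)
    nyq <- do.call(`[`, c(list(S), idx_in(h + 1), list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), idx_out(h + 1), list(nyq / 2)))
    out <- do.call(`[<-`, c(list(out), idx_out(m - h + 1), list(nyq / 2)))
  }
  out
}
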