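#' Radial 17O sequence parameters
#'
#' Defaults are the dynamic 17O protocol of the 7 T patient experiment:
#' TE/TR = 0.56/20 ms, flip angle 60 deg, 1 ms excitation pulse, 5.5 ms
#' readout, (7.5 mm)^3 nominal resolution, 90000 projections. The number of
#' samples per spoke is free (uniform in time along the readout); the default
#' 32 satisfies the radial Nyquist condition for a 32^3 matrix.
#'
#' @param te_ms Echo time (ms). @param tr_ms Repetition time (ms).
#' @param flip_deg Flip angle (degrees). @param t_pulse_ms Pulse length (ms).
#' @param readout_ms Readout duration (ms).
#' @param resolution_mm Nominal isotropic resolution (mm).
#' @param n_projections Number of radial projections (spokes).
#' @param samples_per_spoke Samples per spoke along the readout.
#' @return A `sequence_params` object.
#' @export
sequence_params <- function(te_ms = 0.56, tr_ms = 20, flip_deg = 60,
                            t_pulse_ms = 1, readout_ms = 5.5,
                            resolution_mm = 7.5, n_projections = 90000,
                            samples_per_spoke = 32) {
  if (te_ms >= tr_ms) stop("TE must be smaller than TR")
  if (te_ms + readout_ms > tr_ms) stop("readout must finish within TR")
  if (n_projections <= 0) stop("need at least one projection")
  if (samples_per_spoke < 2) stop("need at least two samples per spoke")
  structure(list(te_ms = te_ms, tr_ms = tr_ms, flip_deg = flip_deg,
                 t_pulse_ms = t_pulse_ms, readout_ms = readout_ms,
                 resolution_mm = resolution_mm,
                 n_projections = as.integer(n_projections),
                 samples_per_spoke = as.integer(samples_per_spoke)),
            class = "sequence_params")
}

#' Spoiled steady-state signal amplitude
#'
#' Amplitude factor of an RF-spoiled gradient-echo steady state,
#' `sin(a) (1 - E1) / (1 - cos(a) E1)` with `E1 = exp(-TR/T1)`. With the 17O
#' protocol (TR 20 ms, T1 5 ms) `E1 = exp(-4)` and longitudinal recovery is
#' essentially complete between spokes.
#'
#' @param flip_deg Flip angle in degrees, in (0, 180].
#' @param tr_ms Repetition time (ms). @param t1_ms Longitudinal T1 (ms).
#' @return Dimensionless amplitude in (0, 1].
#' @examples
#' steady_state_weight(60, 20, 5)
#' @export
steady_state_weight <- function(flip_deg, tr_ms, t1_ms) {
  if (t1_ms <= 0) stop("T1 must be positive")
  if (flip_deg <= 0 || flip_deg > 180) stop("flip angle must be in (0, 180]")
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Density-adapted radius schedule
#'
#' Normalized k-space radius `k(t)/k_max` of the density-adapted radial
#' readout: linear (constant gradient) until `t0 = t0_fraction * readout`,
#' then a cube-root law `k = (k0^3 + c (t - t0))^(1/3)` with `c` fixed by
#' continuity of `dk/dt` at `t0`, so that the sample density beyond `k0`
#' falls as `1/k^2` (uniform per spherical k-shell).
#'
#' @param t_ms Times within the readout, in ms.
#' @param readout_ms Readout duration (ms).
#' @param t0_fraction Fraction of the readout spent in the linear segment.
#' @return Normalized radii between 0 and 1.
#' @export
da_radius_schedule <- function(t_ms, readout_ms = 5.5, t0_fraction = 0.3) {
  if (t0_fraction <= 0 || t0_fraction >= 1)
    stop("t0_fraction must be strictly between 0 and 1")
  if (any(t_ms < 0 | t_ms > readout_ms)) stop("times must lie in the readout")
  t0 <- t0_fraction * readout_ms
  k0 <- (1 + 3 * (readout_ms - t0) / t0)^(-1 / 3)   # k0 / kmax
  ifelse(t_ms <= t0,
         k0 * t_ms / t0,
         (k0^3 + (3 * k0^3 / t0) * (t_ms - t0))^(1 / 3))
}

# Normalized k0/kmax of the schedule (end of the linear segment).
da_k0 <- function(t0_fraction = 0.3) (1 + 3 * (1 - t0_fraction) / t0_fraction)^(-1 / 3)

#' Deterministic near-uniform spoke directions
#'
#' Unit direction vectors from the 3D golden-means spherical scheme
#' (low-discrepancy increments in cos(polar) and azimuth), arranged in
#' left-right mirror pairs: spoke `2m+1` is spoke `2m` reflected across the
#' midsagittal plane. Every contiguous block of spokes is itself close to
#' uniform, and each even-length block is exactly mirror-symmetric, so
#' sliding-window frames inherit the left-right symmetry of the object.
#'
#' @param n Number of directions (even numbers preserve mirror pairing).
#' @return `n` x 3 matrix of unit vectors.
#' @export
spoke_directions <- function(n) {
  phi1 <- 0.4656766971  # 3D golden means
  phi2 <- 0.6823278038
  m <- ceiling(n / 2)
  i <- seq_len(m) - 1
  z <- 2 * ((i * phi1) %% 1) - 1
  az <- 2 * pi * ((i * phi2) %% 1)
  s <- sqrt(pmax(0, 1 - z^2))
  base <- cbind(s * cos(az), s * sin(az), z)
  out <- matrix(0, 2 * m, 3)
  out[seq(1, 2 * m, by = 2), ] <- base
  out[seq(2, 2 * m, by = 2), ] <- base * matrix(c(-1, 1, 1), m, 3, byrow = TRUE)
  out[seq_len(n), , drop = FALSE]
}

#' Build the density-adapted 3D radial trajectory
#'
#' Combines the shared radius schedule with the mirror-paired golden-means
#' directions. Radii reach `k_max = 1/(2 * resolution)` at the end of the
#' readout; per-sample times are uniform from 0 to the readout duration.
#'
#' @param seq A [sequence_params()].
#' @param t0_fraction Linear-segment fraction of [da_radius_schedule()].
#' @return A `radial_trajectory`: list with `directions` (n_spokes x 3),
#'   `radius_norm` (per-sample `k/k_max`), `t_sample_ms` (offsets from TE),
#'   `kmax_mm` (cycles/mm), `k0_norm`, and the sequence parameters.
#' @export
make_da_radial_trajectory <- function(seq, t0_fraction = 0.3) {
  stopifnot(inherits(seq, "sequence_params"))
  t_s <- seq(0, seq$readout_ms, length.out = seq$samples_per_spoke)
  structure(list(
    directions = spoke_directions(seq$n_projections),
    radius_norm = da_radius_schedule(t_s, seq$readout_ms, t0_fraction),
    t_sample_ms = t_s,
    kmax_mm = 1 / (2 * seq$resolution_mm),
    k0_norm = da_k0(t0_fraction),
    t0_fraction = t0_fraction,
    seq = seq
  ), class = "radial_trajectory")
}

# k-space sample positions for a set of spokes, in cycles per voxel of a grid
# with voxel size `voxel_mm` (kmax maps to kmax_mm * voxel_mm cycles/voxel;
# 0.5 when voxel size equals the nominal resolution).
traj_points <- function(traj, spokes, voxel_mm) {
  d <- traj$directions[spokes, , drop = FALSE]
  r <- traj$radius_norm * (traj$kmax_mm * voxel_mm)
  ns <- length(spokes); np <- length(r)
  # sample-major within spoke: row index = (spoke, sample)
  cbind(rep(d[, 1], each = np) * r,
        rep(d[, 2], each = np) * r,
        rep(d[, 3], each = np) * r)
}

#' Simulate the dynamic radial k-space acquisition
#'
#' Forward model of the 30-min dynamic experiment: every spoke is acquired at
#' `(n - 1) * TR` after scan start; the phantom is piecewise-constant over
#' `block_min`-minute intervals (evaluated at the block midpoint); each
#' sample is the exact discrete Fourier transform of the per-tissue
#' concentration maps at the spoke's k-space location, weighted by the
#' spoiled steady-state amplitude and `exp(-(TE + t)/T2*)` decay along the
#' readout, plus circular complex Gaussian noise.
#'
#' @param phantom A [build_phantom()] result.
#' @param tissue_table Named list of [tissue_params()] per label.
#' @param protocol An [inhalation_protocol()].
#' @param traj A [make_da_radial_trajectory()] result.
#' @param noise_sd Standard deviation of the complex noise (per sample;
#'   real and imaginary parts each have sd `noise_sd/sqrt(2)`).
#' @param seed Integer seed for the noise stream.
#' @param block_min Temporal granularity of the phantom (minutes).
#' @param spokes Optional integer indices: simulate only these spokes and
#'   leave the rest zero (partial simulation for windowed analyses that will
#'   only reconstruct the corresponding frames).
#' @return A `kspace_series`: list with complex `samples` (spoke x sample),
#'   `timestamp_s`, `traj`, `noise_sd`, `seed`, `block_min`.
#' @export
simulate_kspace <- function(phantom, tissue_table, protocol, traj,
                            noise_sd = 0, seed = 1L, block_min = 1,
                            spokes = NULL) {
  stopifnot(inherits(phantom, "labeled_phantom"),
            inherits(traj, "radial_trajectory"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  sq <- traj$seq
  kmax_vox <- traj$kmax_mm * phantom$grid$voxel_mm
  if (kmax_vox > 0.5 + 1e-9)
    stop("trajectory k_max exceeds the grid Nyquist limit; grids mismatch")
  nspk <- sq$n_projections
  nsmp <- sq$samples_per_spoke
  ts <- (seq_len(nspk) - 1) * sq$tr_ms / 1000
  total_s <- nspk * sq$tr_ms / 1000
  if (total_s / 60 > protocol$total_min + 1e-9)
    stop("acquisition outlasts the inhalation protocol")

  block <- pmin(floor(ts / 60 / block_min), protocol$total_min / block_min - 1)
  relax <- lapply(tissue_table, function(p)
    exp(-(sq$te_ms + traj$t_sample_ms) / p$t2s_ms) *
      steady_state_weight(sq$flip_deg, sq$tr_ms, p$t1_ms))

  coords <- lapply(phantom$masks, function(m)
    grid_coords(phantom$grid, m))

  if (is.null(spokes)) spokes <- seq_len(nspk)
  active <- logical(nspk)
  active[spokes] <- TRUE
  samples <- matrix(0 + 0i, nspk, nsmp)
  for (b in unique(block[active])) {
    spk <- which(block == b & active)
    kpts <- traj_points(traj, spk, phantom$grid$voxel_mm)
    t_mid <- (b + 0.5) * block_min
    acc <- complex(length(spk) * nsmp)
    for (lab in names(phantom$masks)) {
      if (!nrow(coords[[lab]])) next
      if (is.null(tissue_table[[lab]]))
        stop(sprintf("tissue table has no entry for label '%s'", lab))
      conc <- tissue_timecourse(tissue_table[[lab]], protocol, t_mid)
      if (conc == 0) next
      ft <- cpp_ndft_forward(kpts, coords[[lab]],
                             rep(conc, nrow(coords[[lab]])))
      acc <- acc + ft * rep(relax[[lab]], times = length(spk))
    }
    samples[spk, ] <- matrix(acc, length(spk), nsmp, byrow = TRUE)
  }
  if (noise_sd > 0) {
    samples <- samples + with_seed(seed, {
      matrix(complex(real = rnorm(nspk * nsmp, sd = noise_sd / sqrt(2)),
                     imaginary = rnorm(nspk * nsmp, sd = noise_sd / sqrt(2))),
             nspk, nsmp)
    })
  }
  structure(list(samples = samples, timestamp_s = ts, traj = traj,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 block_min = block_min),
            class = "kspace_series")
}

#' Add circular complex Gaussian noise to a noise-free k-space series
#'
#' Convenience for Monte-Carlo studies: the deterministic signal is simulated
#' once and independent noise realizations are layered on top.
#'
#' @param kspace A noise-free `kspace_series`.
#' @param noise_sd Complex noise standard deviation.
#' @param seed Integer seed.
#' @return A new `kspace_series` with noise added.
#' @export
add_kspace_noise <- function(kspace, noise_sd, seed) {
  stopifnot(inherits(kspace, "kspace_series"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  n <- length(kspace$samples)
  kspace$samples <- kspace$samples + with_seed(seed, {
    matrix(complex(real = rnorm(n, sd = noise_sd / sqrt(2)),
                   imaginary = rnorm(n, sd = noise_sd / sqrt(2))),
           nrow(kspace$samples), ncol(kspace$samples))
  })
  kspace$noise_sd <- noise_sd
  kspace$seed <- as.integer(seed)
  kspace
}

#' @export
print.kspace_series <- function(x, ...) {
  cat(sprintf("<kspace_series> %d spokes x %d samples, %.1f s, noise sd %g\n",
              nrow(x$samples), ncol(x$samples),
              nrow(x$samples) * x$traj$seq$tr_ms / 1000, x$noise_sd))
  invisible(x)
}

#' Write / read a k-space series as raw binary plus JSON sidecar
#'
#' Layout: little-endian doubles, spoke-major, interleaved (re, im) pairs;
#' the sidecar records dimensions, trajectory parameters, noise level and
#' seed so the series can be reloaded without the originating session.
#'
#' @param kspace A `kspace_series`.
#' @param path Base path; `<path>.bin` and `<path>.json` are written.
#' @return Invisibly, the two file paths.
#' @export
write_kspace <- function(kspace, path) {
  v <- as.vector(t(kspace$samples))  # sample-fastest, spoke-major on disk
  inter <- as.vector(rbind(Re(v), Im(v)))
  bin <- paste0(path, ".bin"); side <- paste0(path, ".json")
  con <- file(bin, "wb")
  writeBin(as.double(inter), con, size = 8, endian = "little")
  close(con)
  sq <- kspace$traj$seq
  meta <- list(
    n_spokes = nrow(kspace$samples), samples_per_spoke = ncol(kspace$samples),
    layout = "spoke-major, interleaved little-endian float64 (re, im)",
    tr_ms = sq$tr_ms, te_ms = sq$te_ms, flip_deg = sq$flip_deg,
    readout_ms = sq$readout_ms, resolution_mm = sq$resolution_mm,
    t0_fraction = kspace$traj$t0_fraction, noise_sd = kspace$noise_sd,
    seed = kspace$seed, block_min = kspace$block_min
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(bin, side))
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_spokes * meta$samples_per_spoke
  con <- file(paste0(path, ".bin"), "rb")
  raw <- readBin(con, "double", n = 2 * n, size = 8, endian = "little")
  close(con)
  cx <- complex(real = raw[seq(1, 2 * n, by = 2)],
                imaginary = raw[seq(2, 2 * n, by = 2)])
  sq <- sequence_params(te_ms = meta$te_ms, tr_ms = meta$tr_ms,
                        flip_deg = meta$flip_deg, readout_ms = meta$readout_ms,
                        resolution_mm = meta$resolution_mm,
                        n_projections = meta$n_spokes,
                        samples_per_spoke = meta$samples_per_spoke)
  traj <- make_da_radial_trajectory(sq, t0_fraction = meta$t0_fraction)
  structure(list(
    samples = matrix(cx, meta$n_spokes, meta$samples_per_spoke, byrow = TRUE),
    timestamp_s = (seq_len(meta$n_spokes) - 1) * meta$tr_ms / 1000,
    traj = traj, noise_sd = meta$noise_sd, seed = meta$seed,
    block_min = meta$block_min
  ), class = "kspace_series")
}
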