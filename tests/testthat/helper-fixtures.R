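# Shared fixtures. Expensive objects (PSF models, scaled end-to-end
# simulations) are built once per test run and cached in `.fix`.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# Reduced-size phantom: same topology as the default head, small enough that
# exact-DFT simulation of 90000 spokes stays cheap.
tiny_phantom <- function(grid = grid_spec(24, 7.5), lesion_radius_mm = 8) {
  build_phantom(grid, lesion_radius_mm = lesion_radius_mm,
                brain_semi_mm = c(30, 38, 28),
                ventricle_halfwidth_mm = c(4, 12, 5),
                ventricle_offset_mm = 7)
}

# Scaled 30-frame protocol: 300 spokes per 60 s frame at TR 200 ms keeps the
# 30-min x 1-min frame structure of the full experiment.
scaled_seq <- function(n_frames = 30, window = 300) {
  sequence_params(tr_ms = 200, n_projections = n_frames * window,
                  samples_per_spoke = 24)
}

# Minimal hand-built phantom: arbitrary masks on a grid (for point-source
# and zero-phantom forward-model tests).
forge_phantom <- function(grid, masks) {
  all_named <- c("GM", "WM", "CSF", "stroke", "control")
  full <- setNames(lapply(all_named, function(nm) {
    if (!is.null(masks[[nm]])) masks[[nm]] else array(FALSE, dim = grid$n)
  }), all_named)
  labels <- array(0L, dim = grid$n)
  for (i in seq_along(full)) labels[full[[i]]] <- i
  structure(list(labels = labels, masks = full, grid = grid),
            class = "labeled_phantom")
}

# Forge a k-space container around explicit samples and a trajectory.
forge_kspace <- function(samples, traj) {
  structure(list(samples = samples,
                 timestamp_s = (seq_len(nrow(samples)) - 1) *
                   traj$seq$tr_ms / 1000,
                 traj = traj, noise_sd = 0, seed = NA_integer_,
                 block_min = 1),
            class = "kspace_series")
}

# Point-source k-space: every spoke carries the same readout decay profile.
point_kspace <- function(seq, t2s_ms, t1_ms = 5, t0_fraction = 0.3) {
  traj <- make_da_radial_trajectory(seq, t0_fraction)
  decay <- steady_state_weight(seq$flip_deg, seq$tr_ms, t1_ms) *
    exp(-(seq$te_ms + traj$t_sample_ms) / t2s_ms)
  forge_kspace(matrix(complex(real = decay), seq$n_projections,
                      seq$samples_per_spoke, byrow = TRUE), traj)
}

# Plain-R brute-force non-uniform DFT (independent of the compiled path).
r_dft <- function(kpts, coords, vals) {
  vapply(seq_len(nrow(kpts)), function(i) {
    ph <- -2 * pi * (coords %*% kpts[i, ])
    sum(vals * exp(1i * ph))
  }, complex(1))
}

# Cached default-protocol PSF models (WM / GM / CSF / no relaxation).
get_psf <- function(which = c("WM", "GM", "CSF", "none", "none_noapod")) {
  which <- match.arg(which)
  cached(paste0("psf_", which), {
    sq <- sequence_params()
    tt <- default_tissue_table()
    switch(which,
      WM = simulate_psf(sq, tt$WM),
      GM = simulate_psf(sq, tt$GM),
      CSF = simulate_psf(sq, tt$CSF),
      none = simulate_psf(sq, tissue_params(t2s_ms = 1e9, baseline = 1)),
      none_noapod = simulate_psf(sq, tissue_params(t2s_ms = 1e9, baseline = 1),
                                 apodization = "none"))
  })
}

# Cached scaled end-to-end simulations used by the property tests.
# Variants: sym (identical stroke/control kinetics), deficit_near (30% uptake
# deficit, ventricle-adjacent default-size lesion), deficit_far (same lesion
# moved to the cortex), deficit_large_far (4x volume, cortical).
get_endtoend <- function(variant) {
  cached(paste0("e2e_", variant), {
    g <- grid_spec(24, 7.5)
    sq <- scaled_seq()
    proto <- inhalation_protocol()
    traj <- cached("traj_scaled", make_da_radial_trajectory(sq))
    cfg <- switch(variant,
      sym = list(scale = 1, r = 15, centre = NULL),
      deficit_near = list(scale = 0.7, r = 15, centre = NULL),
      deficit_far = list(scale = 0.7, r = 15, centre = c(-22, -40, 0)),
      deficit_large_far = list(scale = 0.7, r = 15 * 4^(1 / 3),
                               centre = c(-22, -40, 0)),
      stop("unknown variant"))
    tt <- default_tissue_table(stroke_uptake_scale = cfg$scale)
    ph <- build_phantom(g, lesion_radius_mm = cfg$r,
                        lesion_centre_mm = cfg$centre)
    ks0 <- simulate_kspace(ph, tt, proto, traj)
    list(grid = g, seq = sq, protocol = proto, phantom = ph, kspace0 = ks0,
         window = 300L)
  })
}

# Baseline (1-5) + switch-window (10-14) frames are all the scaled analyses
# need; reconstruct only those.
analysis_frames <- c(1:5, 10:14)

# Better-sampled runs for the (small) spill-over effect: 1000-spoke frames at
# TR 60 ms, simulating only the spokes of the frames that are analyzed.
get_spillover <- function(variant) {
  cached(paste0("spill_", variant), {
    g <- grid_spec(24, 7.5)
    sq <- sequence_params(tr_ms = 60, n_projections = 30000,
                          samples_per_spoke = 24)
    proto <- inhalation_protocol()
    traj <- cached("traj_spill", make_da_radial_trajectory(sq))
    centre <- switch(variant, near = NULL, far = c(-22, -40, 0))
    ph <- build_phantom(g, lesion_radius_mm = 15, lesion_centre_mm = centre)
    spk <- unlist(lapply(analysis_frames, function(f)
      ((f - 1) * 1000 + 1):(f * 1000)))
    ks <- simulate_kspace(ph, default_tissue_table(stroke_uptake_scale = 0.7),
                          proto, traj, spokes = spk)
    list(grid = g, protocol = proto, phantom = ph, kspace0 = ks,
         window = 1000L)
  })
}

# Stroke / mirrored-control statistics of a scaled run after ventricle-margin
# exclusion: switch-window means, contrast, control baseline CV.
measure_contrast <- function(e2e, kspace = e2e$kspace0, n_dilations = 2) {
  ser <- sliding_window_series(kspace, e2e$window, e2e$grid, "hamming",
                               frames = analysis_frames)
  m <- e2e$phantom$masks
  sx <- exclude_ventricle_margin(m$stroke, m$CSF, n_dilations)
  cx <- exclude_ventricle_margin(m$control, m$CSF, n_dilations)
  ts <- normalize_to_baseline(roi_mean_series(ser, sx, "stroke"))
  tc <- normalize_to_baseline(roi_mean_series(ser, cx, "control"))
  sw_s <- mean_around_switch(ts, e2e$protocol$t2_min)
  sw_c <- mean_around_switch(tc, e2e$protocol$t2_min)
  list(stroke = sw_s, control = sw_c,
       contrast = roi_contrast(sw_s, sw_c),
       control_cv = baseline_cv(tc))
}

# Noise level calibrated once so the control-ROI baseline CV is ~2.2%
# (the volunteer-level anchor), on the near-lesion deficit configuration.
get_noise_sd <- function() {
  cached("noise_sd_22", {
    e2e <- get_endtoend("deficit_near")
    cx <- exclude_ventricle_margin(e2e$phantom$masks$control,
                                   e2e$phantom$masks$CSF, 2)
    calibrate_noise_sd(2.2, e2e$kspace0, e2e$grid, e2e$window, cx,
                       seed = 100L)
  })
}
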