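test_that("steady-state weight matches the closed form and its limits", {
  # independent hand computation with E1 = exp(-4)
  e1 <- exp(-4)
  expect_equal(steady_state_weight(60, 20, 5),
               sin(pi / 3) * (1 - e1) / (1 - cos(pi / 3) * e1),
               tolerance = 1e-12)
  expect_equal(steady_state_weight(60, 20, 5), 0.858021, tolerance = 1e-6)
  # flip 90 with TR >> T1 saturates at 1
  expect_equal(steady_state_weight(90, 2000, 5), 1, tolerance = 1e-12)
  # maximal at the Ernst angle acos(E1) for fixed TR/T1
  tr <- 10; t1 <- 8
  ernst <- acos(exp(-tr / t1)) * 180 / pi
  flips <- seq(1, 179, by = 0.5)
  ws <- vapply(flips, steady_state_weight, numeric(1), tr_ms = tr, t1_ms = t1)
  expect_lt(abs(flips[which.max(ws)] - ernst), 0.5)
  expect_error(steady_state_weight(0, 20, 5), "flip")
  expect_error(steady_state_weight(60, 20, -1), "T1")
})

test_that("density-adapted radius schedule has the defining density property", {
  t <- seq(0, 5.5, length.out = 2001)
  k <- da_radius_schedule(t, 5.5, 0.3)
  expect_equal(k[1], 0)
  expect_equal(k[length(k)], 1)
  expect_true(all(diff(k) >= 0))
  # k^2 dk/dt constant beyond k0 (numerical differentiation)
  k0 <- (1 + 3 * (5.5 - 1.65) / 1.65)^(-1 / 3)
  mid <- (k[-1] + k[-length(k)]) / 2
  dens <- mid^2 * diff(k) / diff(t)
  beyond <- mid > k0 * 1.05
  expect_lt(diff(range(dens[beyond])) / mean(dens[beyond]), 1e-3)
  expect_error(da_radius_schedule(1, 5.5, 0), "t0_fraction")
  expect_error(da_radius_schedule(1, 5.5, 1.2), "t0_fraction")
})

test_that("trajectory reaches the Nyquist k_max of the nominal resolution", {
  traj <- make_da_radial_trajectory(sequence_params(n_projections = 100))
  expect_equal(traj$kmax_mm, 1 / (2 * 7.5))
  expect_equal(traj$kmax_mm, 0.0667, tolerance = 1e-3)
  expect_equal(max(traj$radius_norm), 1)
})

test_that("spoke directions are unit, mirror-paired, and blockwise uniform", {
  d <- spoke_directions(90000)
  expect_equal(rowSums(d^2), rep(1, 90000), tolerance = 1e-12)
  odd <- d[seq(1, 90000, by = 2), ]
  even <- d[seq(2, 90000, by = 2), ]
  expect_equal(even, odd * matrix(c(-1, 1, 1), nrow(odd), 3, byrow = TRUE))
  # mean resultant vector length of every 3000-spoke block below 0.05
  res <- vapply(seq(1, 90000, by = 3000), function(i)
    sqrt(sum(colMeans(d[i:(i + 2999), ])^2)), numeric(1))
  expect_true(all(res < 0.05))
})

test_that("point source gives the closed-form sample magnitudes", {
  g <- grid_spec(9, 7.5)   # odd: centre voxel exactly at the origin
  ctr <- array(FALSE, dim = g$n); ctr[5, 5, 5] <- TRUE
  ph <- forge_phantom(g, list(WM = ctr))
  sq <- sequence_params(n_projections = 40, samples_per_spoke = 12)
  traj <- make_da_radial_trajectory(sq)
  tt <- list(WM = tissue_params(t1_ms = 5, t2s_ms = 2.8, baseline = 1))
  ks <- simulate_kspace(ph, tt, inhalation_protocol(), traj)
  expected <- steady_state_weight(60, 20, 5) *
    exp(-(0.56 + traj$t_sample_ms) / 2.8)
  for (s in c(1, 17, 40))   # independent of spoke direction
    expect_equal(Mod(ks$samples[s, ]), expected, tolerance = 1e-12)
})

test_that("empty phantom yields identically zero samples", {
  g <- grid_spec(8, 7.5)
  ph <- forge_phantom(g, list())
  sq <- sequence_params(n_projections = 10, samples_per_spoke = 6)
  ks <- simulate_kspace(ph, default_tissue_table(), inhalation_protocol(),
                        make_da_radial_trajectory(sq))
  expect_true(all(ks$samples == 0))
})

test_that("noise stream honours the seeding contract", {
  g <- grid_spec(9, 7.5)
  ctr <- array(FALSE, dim = g$n); ctr[5, 5, 5] <- TRUE
  ph <- forge_phantom(g, list(WM = ctr))
  sq <- sequence_params(n_projections = 20, samples_per_spoke = 8)
  traj <- make_da_radial_trajectory(sq)
  tt <- list(WM = tissue_params(t2s_ms = 2.8, baseline = 1))
  a <- simulate_kspace(ph, tt, inhalation_protocol(), traj, 0.5, seed = 11)
  b <- simulate_kspace(ph, tt, inhalation_protocol(), traj, 0.5, seed = 11)
  c <- simulate_kspace(ph, tt, inhalation_protocol(), traj, 0.5, seed = 12)
  expect_identical(a$samples, b$samples)
  expect_false(all(a$samples == c$samples))
  expect_error(simulate_kspace(ph, tt, inhalation_protocol(), traj, -1), "noise")
})

test_that("spoke timestamps advance by TR and span the full acquisition", {
  e2e <- cached("ks_book_90k", {
    ph <- tiny_phantom()
    sq <- sequence_params(samples_per_spoke = 4)   # 90000 spokes at TR 20 ms
    simulate_kspace(ph, default_tissue_table(), inhalation_protocol(),
                    make_da_radial_trajectory(sq))
  })
  expect_equal(diff(e2e$timestamp_s), rep(0.02, 89999))
  expect_equal(nrow(e2e$samples) * 0.02, 1800)
})

test_that("real phantom without relaxation gives conjugate-symmetric samples", {
  g <- grid_spec(9, 7.5)
  m <- array(FALSE, dim = g$n); m[3:7, 4:6, 5] <- TRUE
  ph <- forge_phantom(g, list(GM = m))
  sq <- sequence_params(n_projections = 12, samples_per_spoke = 8)
  traj <- make_da_radial_trajectory(sq)
  traj$directions[seq(2, 12, by = 2), ] <- -traj$directions[seq(1, 12, by = 2), ]
  tt <- list(GM = tissue_params(t2s_ms = 1e12, baseline = 1))
  ks <- simulate_kspace(ph, tt, inhalation_protocol(), traj)
  expect_equal(ks$samples[seq(2, 12, by = 2), ],
               Conj(ks$samples[seq(1, 12, by = 2), ]), tolerance = 1e-10)
})

test_that("simulated samples match a plain-R DFT oracle", {
  g <- grid_spec(8, 7.5)
  m <- array(FALSE, dim = g$n); m[2:4, 3:5, 4:5] <- TRUE
  ph <- forge_phantom(g, list(CSF = m))
  sq <- sequence_params(n_projections = 6, samples_per_spoke = 5)
  traj <- make_da_radial_trajectory(sq)
  tt <- list(CSF = tissue_params(t2s_ms = 5, baseline = 1.3))
  ks <- simulate_kspace(ph, tt, inhalation_protocol(), traj)
  kpts <- o17mri:::traj_points(traj, 1:6, g$voxel_mm)
  coords <- o17mri:::grid_coords(g, m)
  relax <- steady_state_weight(60, 20, 5) *
    exp(-(0.56 + traj$t_sample_ms) / 5)
  oracle <- r_dft(kpts, coords, rep(1.3, nrow(coords))) *
    rep(relax, times = 6)
  expect_equal(as.vector(t(ks$samples)), oracle, tolerance = 1e-10)
})

test_that("k-space containers round-trip through binary + JSON sidecar", {
  ks <- point_kspace(sequence_params(n_projections = 14,
                                     samples_per_spoke = 6), 2.8)
  base <- file.path(tempdir(), "ksround")
  write_kspace(ks, base)
  back <- read_kspace(base)
  expect_equal(back$samples, ks$samples, tolerance = 1e-14)
  expect_equal(back$timestamp_s, ks$timestamp_s)
  expect_equal(back$traj$radius_norm, ks$traj$radius_norm)
})
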