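# helper: delta kernel on an odd grid
delta_kernel <- function(n = 9) {
  k <- array(0, dim = c(n, n, n))
  k[(n + 1) / 2, (n + 1) / 2, (n + 1) / 2] <- 1
  k
}

# isotropic Gaussian kernel array (wide blur for spill-over tests)
gauss_kernel <- function(n = 15, sigma = 2) {
  x <- seq_len(n) - (n + 1) / 2
  k <- outer(outer(exp(-x^2 / (2 * sigma^2)), exp(-x^2 / (2 * sigma^2))),
             exp(-x^2 / (2 * sigma^2)))
  array(k, dim = c(n, n, n))
}

test_that("delta PSFs give the identity transfer matrix", {
  ph <- tiny_phantom()
  masks <- ph$masks[c("GM", "WM", "CSF")]
  psfs <- list(GM = delta_kernel(), WM = delta_kernel(), CSF = delta_kernel())
  gtm <- build_gtm(masks, psfs)
  expect_equal(gtm$G, diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  corr <- apply_gtm(gtm, matrix(c(1.2, 1.1, 1.05), ncol = 1,
                                dimnames = list(c("GM", "WM", "CSF"), NULL)))
  expect_equal(corr$corrected, corr$observed, tolerance = 1e-10)
})

test_that("half-space regions under a wide PSF match a spatial-domain oracle", {
  n <- 16
  left <- array(FALSE, dim = c(n, n, n)); left[1:8, , ] <- TRUE
  right <- !left
  kern <- gauss_kernel(9, 2)
  gtm <- build_gtm(list(L = left, R = right), list(L = kern, R = kern),
                   energy_trunc = 1)
  expect_true(all(gtm$G[row(gtm$G) != col(gtm$G)] > 0))
  expect_true(all(rowSums(gtm$G) <= 1 + 1e-9))
  expect_true(all(gtm$G >= 0 & gtm$G <= 1))
  # brute-force circular convolution oracle for one entry
  kn <- kern / sum(kern)
  ctr <- 5
  sm <- array(0, dim = c(n, n, n))
  riv <- which(right, arr.ind = TRUE)
  kiv <- which(kn > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(riv))) {
    for (q in seq_len(nrow(kiv))) {
      pos <- ((riv[r, ] + kiv[q, ] - ctr - 1) %% n) + 1
      sm[pos[1], pos[2], pos[3]] <- sm[pos[1], pos[2], pos[3]] +
        kn[kiv[q, 1], kiv[q, 2], kiv[q, 3]]
    }
  }
  expect_equal(gtm$G["L", "R"], mean(sm[left]), tolerance = 1e-10)
  expect_equal(gtm$G["R", "R"], mean(sm[right]), tolerance = 1e-10)
})

test_that("diagonal entry shrinks as an isolated region shrinks", {
  n <- 24
  kern <- gauss_kernel(11, 1.5)
  far <- array(FALSE, dim = c(n, n, n)); far[20:22, 20:22, 20:22] <- TRUE
  diags <- vapply(c(5, 3, 2, 1), function(w) {
    blk <- array(FALSE, dim = c(n, n, n))
    blk[seq(4, 3 + w), seq(4, 3 + w), seq(4, 3 + w)] <- TRUE
    g <- build_gtm(list(A = blk, B = far), list(A = kern, B = kern))
    g$G["A", "A"]
  }, numeric(1))
  expect_true(all(diff(diags) < 0))
})

test_that("noise-free forward smear round-trips through the GTM exactly", {
  ph <- tiny_phantom()
  masks <- ph$masks[c("GM", "WM", "CSF", "stroke")]
  psfs <- lapply(list(GM = "GM", WM = "WM", CSF = "CSF", stroke = "WM"),
                 function(w) get_psf(w))
  gtm <- build_gtm(masks, psfs)
  true <- c(GM = 1.21, WM = 1.17, CSF = 1.06, stroke = 1.02)
  sm <- Reduce(`+`, lapply(names(true), function(rg)
    true[[rg]] * o17mri:::convolve_mask(masks[[rg]],
                                        psfs[[rg]]$kernel, 0.999)))
  obs <- vapply(names(true), function(rg) mean(sm[masks[[rg]]]), numeric(1))
  corr <- apply_gtm(gtm, matrix(obs, ncol = 1,
                                dimnames = list(names(true), NULL)))
  expect_equal(corr$corrected, unname(true), tolerance = 1e-6)
})

test_that("PVC amplifies noise, more strongly for small regions", {
  ph <- tiny_phantom()
  masks <- ph$masks[c("GM", "WM", "CSF", "stroke")]
  psfs <- lapply(list(GM = "GM", WM = "WM", CSF = "CSF", stroke = "WM"),
                 function(w) get_psf(w))
  gtm <- build_gtm(masks, psfs)
  true <- c(GM = 1.2, WM = 1.15, CSF = 1.05, stroke = 1.1)
  obs0 <- as.vector(gtm$G %*% true)
  # identical observation noise on every region isolates the geometry effect
  n_seeds <- 25
  res <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    obs <- obs0 + rnorm(4, sd = 0.01)
    corr <- solve(gtm$G, obs)
    c(obs - obs0, corr - true)
  }, numeric(8))
  var_obs <- apply(res[1:4, ], 1, var)
  var_corr <- apply(res[5:8, ], 1, var)
  expect_true(all(var_corr > var_obs))
  amp <- var_corr / var_obs
  # the small stroke and CSF regions amplify more than the large GM region
  expect_gt(amp[4], amp[1])
  expect_gt(amp[3], amp[1])
})

test_that("frame-wise locality: permuting frames permutes outputs", {
  gtm <- build_gtm(list(A = tiny_phantom()$masks$GM,
                        B = tiny_phantom()$masks$WM),
                   list(A = get_psf("GM"), B = get_psf("WM")))
  obs <- matrix(c(1, 1.1, 1.2, 1.05, 1.15, 1.25), nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "B"), NULL))
  a <- apply_gtm(gtm, obs)
  b <- apply_gtm(gtm, obs[, c(3, 1, 2)])
  expect_equal(matrix(b$corrected, nrow = 2)[, c(2, 3, 1)],
               matrix(a$corrected, nrow = 2))
})

test_that("degenerate GTM inputs fail loudly", {
  ph <- tiny_phantom()
  empty <- array(FALSE, dim = ph$grid$n)
  expect_error(build_gtm(list(A = ph$masks$GM, B = empty),
                         list(A = delta_kernel(), B = delta_kernel())),
               "empty")
  expect_error(build_gtm(list(A = ph$masks$GM, B = ph$masks$GM),
                         list(A = delta_kernel(), B = delta_kernel())),
               "overlap")
  gtm <- build_gtm(list(A = ph$masks$GM, B = ph$masks$WM),
                   list(A = delta_kernel(), B = delta_kernel()))
  gtm$condition_number <- 1e9
  expect_error(apply_gtm(gtm, matrix(c(1, 1), ncol = 1,
                                     dimnames = list(c("A", "B"), NULL))),
               "condition")
})
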