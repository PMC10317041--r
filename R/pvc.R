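# Geometric transfer matrix (GTM) partial-volume correction.
#
# With regions r_1..r_R (binary masks) and per-region PSFs, the observed
# regional mean is modeled as a mixture of the true regional values:
#   observed_i = sum_j G[i, j] * true_j,
#   G[i, j] = mean over mask_i of (mask_j convolved with PSF_j),
# and the PV-corrected values are recovered frame by frame as G^{-1} obs.

#' Build the geometric transfer matrix from masks and PSFs
#'
#' Each PSF kernel is normalized to unit DC gain (so smearing conserves
#' total signal), truncated at the radius enclosing 99.9% of its energy, and
#' applied by circular convolution in Fourier space on the mask grid.
#'
#' @param masks Named list of non-overlapping, nonempty logical 3D masks on a
#'   common grid.
#' @param psfs Named list of [simulate_psf()] models (or bare 3D kernel
#'   arrays centred on their middle voxel), one per region; a single PSF may
#'   be shared by passing it under every region name.
#' @param energy_trunc Fraction of kernel energy retained by the radial
#'   truncation.
#' @return A `gtm_matrix`: list with matrix `G` (regions x regions), region
#'   names, `condition_number`, and the smear operators' DC check.
#' @export
build_gtm <- function(masks, psfs, energy_trunc = 0.999) {
  if (is.null(names(masks)) || any(names(masks) == ""))
    stop("masks must be a named list")
  regions <- names(masks)
  if (!all(regions %in% names(psfs)))
    stop("every region needs a PSF entry")
  dims <- dim(masks[[1]])
  counts <- vapply(masks, sum, numeric(1))
  if (any(counts == 0)) stop("empty region mask: ",
                             paste(regions[counts == 0], collapse = ", "))
  total <- Reduce(`+`, lapply(masks, function(m) m * 1))
  if (any(total > 1)) stop("region masks overlap")
  smeared <- lapply(regions, function(rg) {
    k <- psfs[[rg]]
    kern <- if (inherits(k, "psf_model")) k$kernel else k
    convolve_mask(masks[[rg]], kern, energy_trunc)
  })
  R <- length(regions)
  G <- matrix(0, R, R, dimnames = list(regions, regions))
  for (i in seq_len(R))
    for (j in seq_len(R))
      G[i, j] <- mean(smeared[[j]][masks[[i]]])
  structure(list(G = G, regions = regions,
                 condition_number = kappa(G, exact = TRUE),
                 mask_voxels = counts),
            class = "gtm_matrix")
}

# Circular FFT convolution of a binary mask with a centre-peaked kernel,
# after radial energy truncation and unit-sum normalization.
convolve_mask <- function(mask, kernel, energy_trunc) {
  dims <- dim(mask)
  kd <- dim(kernel)
  if (any(kd > dims))
    kernel <- crop_centre(kernel, pmin(kd, dims))
  kernel <- truncate_kernel(kernel, energy_trunc)
  kernel <- kernel / sum(kernel)
  emb <- array(0, dim = dims)
  kd <- dim(kernel)
  ctr <- (kd + 1) %/% 2
  idx <- lapply(1:3, function(a) seq_len(kd[a]))
  emb[idx[[1]], idx[[2]], idx[[3]]] <- kernel
  # circular shift so the kernel peak sits at index [1,1,1]
  for (a in 1:3) {
    perm <- c(ctr[a]:dims[a], if (ctr[a] > 1) 1:(ctr[a] - 1))
    emb <- switch(a, emb[perm, , , drop = FALSE],
                  emb[, perm, , drop = FALSE],
                  emb[, , perm, drop = FALSE])
  }
  Re(fft(fft(mask * 1) * fft(emb), inverse = TRUE)) / prod(dims)
}

crop_centre <- function(kernel, target) {
  kd <- dim(kernel)
  ctr <- (kd + 1) %/% 2
  idx <- lapply(1:3, function(a) {
    half <- (target[a] - 1) %/% 2
    (ctr[a] - half):(ctr[a] + (target[a] - 1 - half))
  })
  kernel[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Zero out kernel values beyond the radius enclosing `energy` of the total
# squared kernel (bounded-support convolution, tested against the full one).
truncate_kernel <- function(kernel, energy) {
  kd <- dim(kernel)
  i <- (seq_len(prod(kd)) - 1)
  x <- i %% kd[1] - (kd[1] - 1) / 2
  y <- (i %/% kd[1]) %% kd[2] - (kd[2] - 1) / 2
  z <- i %/% (kd[1] * kd[2]) - (kd[3] - 1) / 2
  r <- sqrt(x^2 + y^2 + z^2)
  e <- as.vector(kernel)^2
  ord <- order(r)
  cum <- cumsum(e[ord]) / sum(e)
  hit <- which(cum >= min(energy, cum[length(cum)]))[1]
  rmax <- r[ord][hit]
  out <- kernel
  out[array(r > rmax, dim = kd)] <- 0
  out
}

#' Apply the GTM correction to observed regional means
#'
#' Solves `G x = observed` independently for every frame. Fails when the
#' matrix condition number exceeds `max_condition` (severely overlapping
#' smeared regions); merge regions in that case.
#'
#' @param gtm A [build_gtm()] result.
#' @param observed Matrix (regions x frames) of observed regional means, or a
#'   tidy tibble with columns `region`, `frame`, `value`.
#' @param max_condition Condition-number ceiling.
#' @return Tibble with columns `region`, `frame`, `observed`, `corrected`.
#' @export
apply_gtm <- function(gtm, observed, max_condition = 1e6) {
  stopifnot(inherits(gtm, "gtm_matrix"))
  if (gtm$condition_number > max_condition)
    stop(sprintf(paste0("GTM condition number %.3g exceeds the ceiling %.3g; ",
                        "merge small or heavily overlapping regions"),
                 gtm$condition_number, max_condition))
  if (is.data.frame(observed)) {
    obs_m <- stats::xtabs(value ~ region + frame, data = observed)
    obs_m <- obs_m[gtm$regions, , drop = FALSE]
  } else {
    obs_m <- as.matrix(observed)
    if (is.null(rownames(obs_m))) rownames(obs_m) <- gtm$regions
    obs_m <- obs_m[gtm$regions, , drop = FALSE]
  }
  corr <- solve(gtm$G, obs_m)
  nf <- ncol(obs_m)
  tibble::tibble(
    region = rep(gtm$regions, times = nf),
    frame = rep(seq_len(nf), each = length(gtm$regions)),
    observed = as.vector(obs_m),
    corrected = as.vector(corr)
  )
}

#' @export
print.gtm_matrix <- function(x, ...) {
  cat(sprintf("<gtm_matrix> %d regions, condition number %.3g\n",
              length(x$regions), x$condition_number))
  print(round(x$G, 4))
  invisible(x)
}

#' Tidy a GTM matrix into long form
#'
#' @param x A `gtm_matrix`. @param ... Unused.
#' @return Tibble with columns `target`, `source`, `transfer`.
#' @export
tidy.gtm_matrix <- function(x, ...) {
  R <- length(x$regions)
  tibble::tibble(
    target = rep(x$regions, times = R),
    source = rep(x$regions, each = R),
    transfer = as.vector(x$G)
  )
}

#' One-row GTM summary
#'
#' @param x A `gtm_matrix`. @param ... Unused.
#' @return Tibble with `n_regions`, `condition_number`, `min_diag`.
#' @export
glance.gtm_matrix <- function(x, ...) {
  tibble::tibble(n_regions = length(x$regions),
                 condition_number = x$condition_number,
                 min_diag = min(diag(x$G)))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
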