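#' Per-tissue relaxation and H2-17O kinetic parameters
#'
#' Bundles the MR relaxation times of a tissue with the three-phase kinetic
#' parameters of its metabolically produced 17O water signal. Signal levels
#' are in arbitrary concentration units; a tissue's baseline level is
#' proportional to its water content, and the uptake rate is the slope of
#' H2-17O accumulation while enriched gas is breathed (a proxy for CMRO2).
#'
#' @param t1_ms Longitudinal relaxation time in ms (17O T1 is ~5 ms in brain).
#' @param t2s_ms Effective transverse relaxation time T2* in ms.
#' @param baseline Baseline H2-17O signal level (arbitrary units, > 0).
#' @param uptake_per_min Accumulation rate during the inhalation phase
#'   (units/min, usually >= 0).
#' @param post_rate_per_min Rate after the switch back to room air (units/min;
#'   positive for continued accumulation, negative for washout).
#' @return A `tissue_params` object.
#' @export
tissue_params <- function(t1_ms = 5, t2s_ms, baseline,
                          uptake_per_min = 0, post_rate_per_min = 0) {
  if (t1_ms <= 0 || t2s_ms <= 0) stop("T1 and T2* must be positive")
  if (baseline <= 0) stop("baseline level must be positive")
  structure(list(t1_ms = t1_ms, t2s_ms = t2s_ms, baseline = baseline,
                 uptake_per_min = uptake_per_min,
                 post_rate_per_min = post_rate_per_min),
            class = "tissue_params")
}

#' Default tissue table for the dynamic 17O brain experiment
#'
#' Relaxation times are the literature brain values used throughout the
#' package (T1 = 5 ms; T2* = 2.8 ms WM, 2.5 ms GM, 5 ms CSF). Baseline levels
#' scale with water content. Kinetic rates are expressed per unit baseline
#' (relative slope x baseline) and are calibrated so that the default
#' end-to-end pipeline reproduces relative switch-window levels of about 1.18
#' for healthy brain tissue and about 1.14 for CSF; the stroke and mirrored
#' control labels default to healthy tissue kinetics, and experiments impose a
#' deficit by scaling the stroke rates.
#'
#' @param stroke_uptake_scale Multiplier (1 = no deficit) applied to the
#'   stroke label's uptake and post-switch rates.
#' @return Named list of [tissue_params()] for labels `GM`, `WM`, `CSF`,
#'   `stroke`, `control`.
#' @export
default_tissue_table <- function(stroke_uptake_scale = 1) {
  rel <- function(base, up, post, t2s)
    tissue_params(t1_ms = 5, t2s_ms = t2s, baseline = base,
                  uptake_per_min = up * base, post_rate_per_min = post * base)
  list(
    GM      = rel(0.83, 0.030, 0.012, 2.5),
    WM      = rel(0.70, 0.030, 0.012, 2.8),
    CSF     = rel(1.00, 0.0225, 0.010, 5.0),
    stroke  = rel(0.80, 0.030 * stroke_uptake_scale,
                  0.012 * stroke_uptake_scale, 2.65),
    control = rel(0.80, 0.030, 0.012, 2.65)
  )
}

#' Three-phase 17O2 inhalation protocol timing
#'
#' Baseline room air until `t1_min`, 70% 17O2-enriched gas until `t2_min`,
#' room air again until `total_min`.
#'
#' @param t1_min End of the baseline phase (min).
#' @param t2_min End of the inhalation phase (min).
#' @param total_min Total duration of continuous imaging (min).
#' @return An `inhalation_protocol` object.
#' @export
inhalation_protocol <- function(t1_min = 5, t2_min = 11, total_min = 30) {
  if (!(0 < t1_min && t1_min < t2_min && t2_min < total_min))
    stop("protocol requires 0 < t1 < t2 < total duration")
  structure(list(t1_min = t1_min, t2_min = t2_min, total_min = total_min),
            class = "inhalation_protocol")
}

# Integer label codes used in the label volume.
PHANTOM_LABELS <- c(background = 0L, GM = 1L, WM = 2L, CSF = 3L,
                    stroke = 4L, control = 5L)

#' Build the labeled digital brain phantom
#'
#' Constructs a simple head geometry on `grid`: the brain is an ellipsoid
#' split into a white-matter core and a gray-matter shell; the lateral
#' ventricles are a pair of paramedian CSF slabs inside the core; the stroke
#' lesion is a sphere placed against one ventricle (face-adjacent), and the
#' mirrored control label is its exact left-right reflection across the
#' midsagittal plane. Labels are mutually exclusive; on overlap the ventricle
#' label takes precedence over the lesion and control labels, which in turn
#' take precedence over GM/WM.
#'
#' @param grid A [grid_spec()]. The default 32^3 at 7.5 mm covers an adult
#'   head at the nominal resolution of the 17O protocol.
#' @param lesion_radius_mm Stroke sphere radius in mm.
#' @param lesion_centre_mm Length-3 lesion centre in mm relative to the grid
#'   centre (axis 1 = left-right). `NULL` places the lesion against the left
#'   ventricle.
#' @param brain_semi_mm Ellipsoid semi-axes of the brain in mm.
#' @param wm_scale WM core semi-axes as a fraction of the brain semi-axes.
#' @param ventricle_halfwidth_mm Half-widths (mm) of each ventricle slab along
#'   the three axes.
#' @param ventricle_offset_mm Left-right offset (mm) of each ventricle slab
#'   centre from the midline.
#' @param require_ventricle_adjacency Error unless the stroke mask touches
#'   the ventricle mask (the default geometry of a basal-ganglia lesion).
#'   Set to `FALSE` when deliberately placing a ventricle-distant (cortical)
#'   lesion.
#' @return A `labeled_phantom`: list with integer array `labels`, named list
#'   `masks` of logical arrays (`GM`, `WM`, `CSF`, `stroke`, `control`),
#'   `grid`, and the geometry parameters.
#' @examples
#' ph <- build_phantom(grid_spec(32))
#' sapply(ph$masks, sum)
#' @export
build_phantom <- function(grid = grid_spec(),
                          lesion_radius_mm = 15,
                          lesion_centre_mm = NULL,
                          brain_semi_mm = c(67, 82, 62),
                          wm_scale = 0.68,
                          ventricle_halfwidth_mm = c(5, 26, 9),
                          ventricle_offset_mm = 13,
                          require_ventricle_adjacency = is.null(lesion_centre_mm)) {
  stopifnot(inherits(grid, "grid_spec"))
  vx <- grid$voxel_mm
  x <- axis_coords(grid, 1) * vx
  y <- axis_coords(grid, 2) * vx
  z <- axis_coords(grid, 3) * vx
  n <- grid$n
  X <- array(rep(x, times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(y, each = n[1]), times = n[3]), dim = n)
  Z <- array(rep(z, each = n[1] * n[2]), dim = n)

  inside <- function(semi) (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  brain <- inside(brain_semi_mm)
  wm_core <- inside(brain_semi_mm * wm_scale)

  vent_one <- function(sign) {
    abs(X - sign * ventricle_offset_mm) <= ventricle_halfwidth_mm[1] &
      abs(Y) <= ventricle_halfwidth_mm[2] &
      abs(Z) <= ventricle_halfwidth_mm[3] & wm_core
  }
  vent <- vent_one(-1) | vent_one(1)
  if (!any(vent)) stop("ventricle mask is empty; enlarge the grid or slabs")

  if (is.null(lesion_centre_mm)) {
    # push the sphere against the left ventricle slab so the masks share a face
    lesion_centre_mm <- c(-(ventricle_offset_mm + ventricle_halfwidth_mm[1] +
                              lesion_radius_mm - 0.5 * vx), 0, 0)
  }
  R2 <- (X - lesion_centre_mm[1])^2 + (Y - lesion_centre_mm[2])^2 +
    (Z - lesion_centre_mm[3])^2
  stroke_raw <- R2 <= lesion_radius_mm^2
  if (!any(stroke_raw)) stop("lesion sphere contains no voxels at this grid")
  if (any(stroke_raw & !brain)) stop("lesion must fit inside the brain ellipsoid")

  control_raw <- mirror_volume(stroke_raw)

  # precedence: CSF > stroke/control > GM/WM
  stroke <- stroke_raw & !vent
  control <- control_raw & !vent
  if (!any(stroke)) stop("lesion is entirely inside the ventricle label")
  if (require_ventricle_adjacency && !face_adjacent(stroke, vent))
    stop("stroke mask is not face-adjacent to the ventricle mask; move the lesion")

  wm <- wm_core & !vent & !stroke & !control
  gm <- brain & !wm_core & !stroke & !control
  labels <- array(PHANTOM_LABELS[["background"]], dim = n)
  labels[gm] <- PHANTOM_LABELS[["GM"]]
  labels[wm] <- PHANTOM_LABELS[["WM"]]
  labels[vent] <- PHANTOM_LABELS[["CSF"]]
  labels[stroke] <- PHANTOM_LABELS[["stroke"]]
  labels[control] <- PHANTOM_LABELS[["control"]]

  structure(list(
    labels = labels,
    masks = list(GM = gm, WM = wm, CSF = vent, stroke = stroke,
                 control = control),
    grid = grid,
    lesion_radius_mm = lesion_radius_mm,
    lesion_centre_mm = lesion_centre_mm,
    brain_semi_mm = brain_semi_mm
  ), class = "labeled_phantom")
}

#' @export
print.labeled_phantom <- function(x, ...) {
  cat("<labeled_phantom>\n")
  print(x$grid)
  cnt <- vapply(x$masks, sum, integer(1))
  cat(paste(sprintf("  %s: %d voxels", names(cnt), cnt), collapse = "\n"), "\n")
  invisible(x)
}

# Left-right reflection of a 3D array across the midsagittal plane
# (index x -> N - 1 - x on axis 1, 0-based).
mirror_volume <- function(vol) {
  vol[rev(seq_len(dim(vol)[1])), , , drop = FALSE]
}

# TRUE when some voxel of `a` has a 6-connected face neighbour in `b`.
face_adjacent <- function(a, b) {
  grown <- cpp_dilate6(a, dim(a), 1L)
  any(grown & b)
}

#' Piecewise-linear three-phase tissue time course
#'
#' The H2-17O signal of a tissue is modeled as constant at the baseline level
#' while room air is breathed, rising linearly at the uptake rate during
#' 17O2 inhalation, and evolving linearly at the post-inhalation rate after
#' the second switch, continuous at both switches and clipped at zero.
#'
#' @param params A [tissue_params()].
#' @param protocol An [inhalation_protocol()].
#' @param times_min Nondecreasing vector of times (min) within the protocol.
#' @return Numeric vector of signal levels at `times_min`.
#' @examples
#' p <- tissue_params(t2s_ms = 2.8, baseline = 1, uptake_per_min = 0.03)
#' tissue_timecourse(p, inhalation_protocol(), c(0, 5, 8, 11, 20))
#' @export
tissue_timecourse <- function(params, protocol, times_min) {
  stopifnot(inherits(params, "tissue_params"),
            inherits(protocol, "inhalation_protocol"))
  if (is.unsorted(times_min)) stop("times must be nondecreasing")
  if (any(times_min < 0 | times_min > protocol$total_min))
    stop("times must lie within [0, total duration]")
  t1 <- protocol$t1_min; t2 <- protocol$t2_min
  v <- params$baseline +
    params$uptake_per_min * pmax(0, pmin(times_min, t2) - t1) +
    params$post_rate_per_min * pmax(0, times_min - t2)
  pmax(v, 0)
}

#' Evaluate the dynamic phantom as a 3D concentration map
#'
#' Broadcasts each label's [tissue_timecourse()] value at time `t_min` over
#' the label's mask; background voxels are zero.
#'
#' @param phantom A [build_phantom()] result.
#' @param tissue_table Named list of [tissue_params()], one entry per
#'   nonbackground label present in the phantom.
#' @param protocol An [inhalation_protocol()].
#' @param t_min Time in minutes.
#' @return 3D numeric array on the phantom grid.
#' @export
dynamic_image <- function(phantom, tissue_table, protocol, t_min) {
  stopifnot(inherits(phantom, "labeled_phantom"))
  vol <- array(0, dim = phantom$grid$n)
  for (lab in names(phantom$masks)) {
    m <- phantom$masks[[lab]]
    if (!any(m)) next
    if (is.null(tissue_table[[lab]]))
      stop(sprintf("tissue table has no entry for label '%s'", lab))
    vol[m] <- tissue_timecourse(tissue_table[[lab]], protocol, t_min)
  }
  vol
}

#' Write phantom labels and masks as NIfTI-1 volumes
#'
#' @param phantom A `labeled_phantom`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vx <- phantom$grid$voxel_mm
  paths <- character(0)
  save_one <- function(vol, name) {
    img <- RNifti::asNifti(vol * 1, reference = NULL)
    img <- RNifti::`pixdim<-`(img, rep(vx, 3))
    p <- file.path(dir, paste0(name, ".nii.gz"))
    RNifti::writeNifti(img, p)
    p
  }
  paths <- c(paths, save_one(phantom$labels, "labels"))
  for (lab in names(phantom$masks))
    paths <- c(paths, save_one(phantom$masks[[lab]], paste0("mask_", lab)))
  invisible(paths)
}
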