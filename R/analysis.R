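# ROI time-course statistics of the dynamic 17O experiment.

new_roi_timecourse <- function(df, normalized = FALSE, corrected = FALSE) {
  structure(df, class = c("roi_timecourse", class(tibble::as_tibble(df))),
            normalized = normalized, corrected = corrected)
}

#' Per-frame ROI mean of a reconstructed series
#'
#' @param series An [sliding_window_series()] result.
#' @param mask Logical 3D mask on the series grid.
#' @param region Region name carried in the output.
#' @return A `roi_timecourse` tibble with columns `region`, `frame`,
#'   `time_s` (mid-frame) and `value`, plus `normalized`/`corrected`
#'   attributes.
#' @export
roi_mean_series <- function(series, mask, region = "roi") {
  stopifnot(inherits(series, "image_series"))
  if (!any(mask)) stop("mask is empty")
  if (!all(dim(mask) == series$grid$n)) stop("mask is not on the series grid")
  nf <- dim(series$data)[4]
  vals <- vapply(seq_len(nf), function(i) mean(series$data[, , , i][mask]),
                 numeric(1))
  new_roi_timecourse(tibble::tibble(
    region = region, frame = series$frames$frame,
    time_s = series$frames$t_mid_s, value = vals
  ))
}

#' Normalize a time course to its baseline mean
#'
#' Divides every value by the mean of the first `n_baseline` frames (the
#' room-air baseline), making the series a relative H2-17O signal evolution.
#'
#' @param tc A `roi_timecourse`.
#' @param n_baseline Number of baseline frames (default 5, i.e. 5 min at
#'   1-min frames).
#' @return The normalized `roi_timecourse` (attribute `normalized = TRUE`).
#' @export
normalize_to_baseline <- function(tc, n_baseline = 5) {
  stopifnot(inherits(tc, "roi_timecourse"))
  out <- dplyr::group_by(tibble::as_tibble(tc), .data$region)
  out <- dplyr::mutate(out, value = {
    if (n_baseline > dplyr::n()) stop("fewer frames than baseline window")
    b <- mean(.data$value[seq_len(n_baseline)])
    if (b <= 0) stop("baseline mean must be positive")
    .data$value / b
  })
  new_roi_timecourse(dplyr::ungroup(out), normalized = TRUE,
                     corrected = attr(tc, "corrected"))
}

#' Mean signal around the second gas switch
#'
#' Averages `n_points` frames centred on the frame whose mid-time is nearest
#' the switch (for `n = 5`: two before, the centre, two after). When the
#' switch falls exactly between two frame mid-times the later frame is taken
#' as the centre.
#'
#' @param tc A single-region `roi_timecourse`.
#' @param switch_time_min Time of the switch (min), typically the end of the
#'   inhalation phase.
#' @param n_points Number of frames averaged (default 5).
#' @return The mean value over the window.
#' @export
mean_around_switch <- function(tc, switch_time_min, n_points = 5) {
  stopifnot(inherits(tc, "roi_timecourse"))
  if (length(unique(tc$region)) != 1)
    stop("provide a single-region time course")
  dmin <- abs(tc$time_s / 60 - switch_time_min)
  ctr <- max(which(dmin == min(dmin)))  # tie -> later frame
  half_lo <- (n_points - 1) %/% 2
  half_hi <- n_points - 1 - half_lo
  idx <- (ctr - half_lo):(ctr + half_hi)
  if (min(idx) < 1 || max(idx) > nrow(tc))
    stop("switch window extends outside the series")
  mean(tc$value[idx])
}

#' Baseline coefficient of variation
#'
#' Sample standard deviation (n - 1 convention) of the first `n_points`
#' values relative to their mean, in percent.
#'
#' @param tc A single-region `roi_timecourse`.
#' @param n_points Number of leading baseline frames (>= 2).
#' @return CV in percent.
#' @export
baseline_cv <- function(tc, n_points = 5) {
  stopifnot(inherits(tc, "roi_timecourse"))
  if (length(unique(tc$region)) != 1)
    stop("provide a single-region time course")
  if (n_points < 2) stop("need at least two baseline points")
  if (nrow(tc) < n_points) stop("fewer frames than baseline points")
  v <- tc$value[seq_len(n_points)]
  100 * sd(v) / mean(v)
}

#' Mirror a mask across the midsagittal plane
#'
#' Reflects the mask left-right (0-based index `x -> N - 1 - x` on axis 1);
#' voxel count is preserved and the operation is an involution. Real data
#' must be pre-aligned so that the anatomical midline coincides with the
#' central plane of axis 1.
#'
#' @param mask Logical 3D array.
#' @return The mirrored mask.
#' @export
mirror_mask <- function(mask) {
  mirror_volume(mask)
}

#' Remove a dilated ventricle margin from an ROI
#'
#' Dilates the ventricle mask `n_dilations` times with the 6-connected
#' (face-neighbour) structuring element and subtracts the result from the
#' ROI, giving a smaller ROI with a CSF safety margin that limits spillover
#' from the ventricles.
#'
#' @param roi Logical 3D ROI mask.
#' @param ventricles Logical 3D ventricle mask on the same grid.
#' @param n_dilations Number of one-voxel dilations (default 2).
#' @return The reduced ROI (may be empty, with a warning).
#' @export
exclude_ventricle_margin <- function(roi, ventricles, n_dilations = 2) {
  if (!all(dim(roi) == dim(ventricles))) stop("masks are on different grids")
  grown <- if (n_dilations > 0)
    cpp_dilate6(ventricles, dim(ventricles), as.integer(n_dilations))
  else ventricles
  out <- roi & !grown
  if (!any(out)) warning("ROI is empty after ventricle-margin exclusion")
  out
}

#' Dice overlap coefficient of two masks
#'
#' `2 |A . B| / (|A| + |B|)`, the standard agreement measure between two
#' segmentations of the same structure.
#'
#' @param mask_a,mask_b Logical arrays on the same grid.
#' @return Dice coefficient between 0 and 1.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("masks are on different grids")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' Voxel-wise relative 17O signal-increase map
#'
#' `(end - baseline) / baseline` between a baseline room-air image and an
#' image at the end of 17O2 inhalation, computed on Hamming-filtered,
#' zero-filled reconstructions. Voxels whose baseline falls below
#' `floor_frac` times the in-brain median baseline are masked out (`NA`) to
#' avoid division blow-up outside the head; "in-brain" is defined as
#' baseline above `brain_frac` of the maximum.
#'
#' @param baseline_frame,end_frame `image_frame`s on a common grid.
#' @param zero_fill_factor Zero-filling factor applied to both frames
#'   (default 8).
#' @param floor_frac Baseline floor as a fraction of the in-brain median.
#' @param brain_frac Fraction of the maximum defining the in-brain support.
#' @return An `image_frame` whose `data` holds the relative increase (`NA`
#'   outside the supported region).
#' @export
relative_increase_map <- function(baseline_frame, end_frame,
                                  zero_fill_factor = 8, floor_frac = 0.1,
                                  brain_frac = 0.25) {
  stopifnot(inherits(baseline_frame, "image_frame"),
            inherits(end_frame, "image_frame"))
  if (!same_grid(baseline_frame$grid, end_frame$grid))
    stop("frames are on different grids")
  b <- zero_fill(baseline_frame, zero_fill_factor)
  e <- zero_fill(end_frame, zero_fill_factor)
  bb <- b$data; ee <- e$data
  inbrain <- bb > brain_frac * max(bb)
  floor_val <- floor_frac * median(bb[inbrain])
  out <- (ee - bb) / bb
  out[bb < floor_val] <- NA_real_
  res <- b
  res$data <- out
  res
}

#' Percent signal deficit of a test ROI relative to a control ROI
#'
#' `(1 - A/B) * 100`, where `A` and `B` are relative mean signals (e.g. the
#' switch-window means of the stroke and mirrored control ROIs). Positive
#' values mean the test ROI increased less than the control.
#'
#' @param value_test,value_control Positive relative signal values.
#' @return Percent difference.
#' @examples
#' roi_contrast(1.158, 1.168)  # ~0.9
#' @export
roi_contrast <- function(value_test, value_control) {
  if (value_test <= 0 || value_control <= 0)
    stop("relative signal values must be positive")
  (1 - value_test / value_control) * 100
}

#' @export
print.roi_timecourse <- function(x, ...) {
  cat(sprintf("<roi_timecourse> %s%s\n",
              paste(unique(x$region), collapse = ", "),
              if (isTRUE(attr(x, "normalized"))) " (baseline-relative)" else ""))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Plot ROI time courses
#'
#' Line plot of the per-frame (relative) signal per region, with optional
#' vertical markers at the two gas switches.
#'
#' @param object A `roi_timecourse`.
#' @param protocol Optional [inhalation_protocol()] whose switch times are
#'   drawn as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roi_timecourse <- function(object, protocol = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$time_s / 60, y = .data$value,
                                    colour = .data$region)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time [min]",
                  y = if (isTRUE(attr(object, "normalized")))
                    "relative H2-17O signal" else "H2-17O signal",
                  colour = "region") +
    ggplot2::theme_minimal()
  if (!is.null(protocol))
    p <- p + ggplot2::geom_vline(xintercept = c(protocol$t1_min,
                                                protocol$t2_min),
                                 linetype = "dashed", colour = "grey40")
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
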