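#' @keywords internal
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

as_image_matrix <- function(x) {
  if (inherits(x, "radiograph")) x$image
  else if (is.matrix(x)) x
  else stop("expected a radiograph or a numeric matrix", call. = FALSE)
}

#' Signal-to-noise ratio of a region
#'
#' SNR is the mean signal of the ROI divided by its standard deviation.
#' The population convention (divide by N) is used throughout the quality
#' metrics. A constant ROI has zero noise; the SNR is then reported as an
#' infinite sentinel rather than raising an error.
#'
#' @param radiograph A [radiograph()] (or plain matrix).
#' @param roi An [roi_spec()] with at least 2 pixels.
#' @return SNR as a single number (`Inf`/`NaN` when the ROI is constant).
#' @export
compute_snr <- function(radiograph, roi) {
  img <- as_image_matrix(radiograph)
  px <- roi_extract(img, roi)
  if (length(px) < 2) stop("ROI must contain at least 2 pixels", call. = FALSE)
  s <- mean(px)
  sigma <- sd_pop(px)
  if (sigma == 0) return(if (s == 0) NaN else sign(s) * Inf)
  s / sigma
}

#' Contrast-to-noise ratio between two regions
#'
#' CNR is `(mean_a - mean_b) / sigma_b`, where `sigma_b` is the population
#' standard deviation of the low-contrast (background) region `roi_b`. The
#' value is signed, so swapping the two regions flips its sign.
#'
#' @param radiograph A [radiograph()] (or plain matrix).
#' @param roi_a High-contrast (signal) region.
#' @param roi_b Low-contrast (background) region; supplies the noise estimate.
#' @return Signed CNR (`Inf`/`NaN` sentinel when the background is constant).
#' @export
compute_cnr <- function(radiograph, roi_a, roi_b) {
  img <- as_image_matrix(radiograph)
  if (roi_overlaps(roi_a, roi_b)) {
    stop("roi_a and roi_b must be disjoint", call. = FALSE)
  }
  a <- roi_extract(img, roi_a)
  b <- roi_extract(img, roi_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both ROIs must contain at least 2 pixels", call. = FALSE)
  }
  diff <- mean(a) - mean(b)
  sigma <- sd_pop(b)
  if (sigma == 0) return(if (diff == 0) NaN else sign(diff) * Inf)
  diff / sigma
}

#' Width of the scatter-induced edge-enhancement peak
#'
#' Proton scattering redistributes fluence at material boundaries, producing a
#' fluence peak just outside a dense edge. This estimator averages the profile
#' lines of the ROI perpendicular to the edge, locates that peak above the
#' far-field plateau, and returns its full width at half maximum in mm with
#' subpixel (linear-interpolation) crossings.
#'
#' The plateau is estimated in two passes: a crude width from the half level
#' above the profile minimum first, then the plateau as the median of samples
#' farther than 2.5 crude widths from the peak (the higher side is the far
#' field; the other side may contain the in-material valley). A peak is only
#' accepted if it exceeds the plateau by more than three times the far-field
#' noise, otherwise a "no edge enhancement" error is raised.
#'
#' @param radiograph A [radiograph()].
#' @param roi ROI spanning the edge, at least 20 profile lines.
#' @param edge_axis `"vertical"` if the edge runs down the image (profile taken
#'   along columns), `"horizontal"` if it runs across (profile along rows).
#' @return FWHM of the enhancement peak in mm.
#' @export
edge_fwhm <- function(radiograph, roi, edge_axis = c("vertical", "horizontal")) {
  edge_axis <- match.arg(edge_axis)
  img <- as_image_matrix(radiograph)
  region <- roi_extract(img, roi)
  if (edge_axis == "vertical") {
    if (nrow(region) < 20) stop("need >= 20 profile lines", call. = FALSE)
    prof <- colMeans(region)
  } else {
    if (ncol(region) < 20) stop("need >= 20 profile lines", call. = FALSE)
    prof <- rowMeans(region)
  }
  width_px <- profile_peak_fwhm(prof)
  if (inherits(radiograph, "radiograph")) {
    width_px * radiograph$pixel_pitch_mm
  } else {
    width_px
  }
}

# FWHM (in samples) of the dominant peak of a 1D profile above its far-field
# plateau; errors when no significant enhancement is present.
profile_peak_fwhm <- function(prof) {
  n <- length(prof)
  ip <- which.max(prof)
  h <- prof[ip]
  b0 <- min(prof)
  if (h <= b0) stop("no edge enhancement: profile is flat", call. = FALSE)
  # a peak rarely sits exactly on a sample: refine its height by the vertex
  # of the parabola through the top three samples
  if (ip > 1 && ip < n) {
    a <- prof[ip - 1]; c <- prof[ip + 1]
    denom <- 2 * h - a - c
    if (denom > 0) {
      h <- h + (a - c)^2 / (8 * denom)
    }
  }

  # crude width pass; the median is a robust baseline even when the profile
  # also contains the in-material valley
  bm <- stats::median(prof)
  level0 <- bm + (h - bm) / 2
  cr0 <- half_crossings(prof, ip, level0)
  left0 <- if (is.na(cr0[1])) 0 else cr0[1]
  right0 <- if (is.na(cr0[2])) n - 1 else cr0[2]
  w0 <- max(right0 - left0, 1)

  x <- seq_len(n) - 1
  far_left <- prof[x < (ip - 1) - 2.5 * w0]
  far_right <- prof[x > (ip - 1) + 2.5 * w0]
  cand <- list(far_left, far_right)
  meds <- vapply(cand, function(v) if (length(v) >= 3) stats::median(v) else NA_real_,
                 numeric(1))
  if (all(is.na(meds))) {
    plateau <- b0
    noise <- 0
  } else {
    side <- which.max(meds)
    plateau <- meds[side]
    noise <- sd_pop(cand[[side]])
  }
  if (h <= plateau + 3 * noise || h <= plateau) {
    stop("no edge enhancement: peak does not exceed plateau + 3*noise",
         call. = FALSE)
  }
  level <- plateau + (h - plateau) / 2
  cr <- half_crossings(prof, ip, level)
  if (anyNA(cr)) {
    stop("no edge enhancement: peak not localized within ROI", call. = FALSE)
  }
  cr[2] - cr[1]
}

# subpixel positions (0-based) where the profile crosses `level` on either
# side of the peak at index ip (1-based); NA when a side never crosses
half_crossings <- function(prof, ip, level) {
  n <- length(prof)
  left <- NA_real_
  for (j in seq(ip - 1, 1)) {
    if (ip == 1) break
    if (prof[j] < level) {
      left <- (j - 1) + (level - prof[j]) / (prof[j + 1] - prof[j])
      break
    }
    if (j == 1) break
  }
  right <- NA_real_
  if (ip < n) {
    for (j in seq(ip + 1, n)) {
      if (prof[j] < level) {
        right <- (j - 1) - (level - prof[j]) / (prof[j - 1] - prof[j])
        break
      }
      if (j == n) break
    }
  }
  c(left, right)
}

#' Line-pair resolution from a bar-grid radiograph
#'
#' For each bar group the profile across the bars is averaged along the bars,
#' folded at the group's known period (phase averaging) and scored by its
#' Michelson contrast `(max - min) / (max + min)`. A group counts as resolved
#' when its contrast exceeds `min_contrast` (default 0.1) and three times the
#' contrast measured in the background region (rows with `freq_lp_per_mm` of 0
#' or `NA`). The returned resolution is the highest resolved frequency.
#'
#' @param radiograph A [radiograph()].
#' @param grid_spec Tibble with columns `label,row0,row1,col0,col1,
#'   freq_lp_per_mm`; bars are assumed to run vertically so the pattern varies
#'   along the column axis.
#' @param min_contrast Michelson contrast threshold for resolvability.
#' @return Object of class `lp_resolution`: a list with
#'   `resolved_lp_per_mm` (0 when nothing is resolved, with `warning = TRUE`),
#'   the per-group tibble `groups`, and `background_contrast`.
#' @export
line_pair_resolution <- function(radiograph, grid_spec, min_contrast = 0.1) {
  img <- as_image_matrix(radiograph)
  pitch <- if (inherits(radiograph, "radiograph")) radiograph$pixel_pitch_mm else 1
  gs <- tibble::as_tibble(grid_spec)
  if (!"freq_lp_per_mm" %in% names(gs)) {
    stop("grid_spec needs a freq_lp_per_mm column", call. = FALSE)
  }
  is_bg <- is.na(gs$freq_lp_per_mm) | gs$freq_lp_per_mm == 0
  bg_contrast <- 0
  if (any(is_bg)) {
    bg_contrast <- max(vapply(which(is_bg), function(i) {
      r <- roi_spec(gs$row0[i], gs$row1[i], gs$col0[i], gs$col1[i])
      prof <- colMeans(roi_extract(img, r))
      michelson(prof)
    }, numeric(1)))
  }
  grp <- gs[!is_bg, , drop = FALSE]
  contrast <- vapply(seq_len(nrow(grp)), function(i) {
    r <- roi_spec(grp$row0[i], grp$row1[i], grp$col0[i], grp$col1[i])
    prof <- colMeans(roi_extract(img, r))
    period_px <- 1 / grp$freq_lp_per_mm[i] / pitch
    michelson(fold_profile(prof, period_px))
  }, numeric(1))
  resolved <- contrast > min_contrast & contrast > 3 * bg_contrast
  groups <- tibble::tibble(
    label = grp$label, freq_lp_per_mm = grp$freq_lp_per_mm,
    contrast = contrast, resolved = resolved
  )
  res <- if (any(resolved)) max(groups$freq_lp_per_mm[resolved]) else 0
  structure(
    list(resolved_lp_per_mm = res, groups = groups,
         background_contrast = bg_contrast, warning = !any(resolved)),
    class = "lp_resolution"
  )
}

#' @export
print.lp_resolution <- function(x, ...) {
  cat(sprintf("<lp_resolution> %.2g lp/mm resolved%s\n", x$resolved_lp_per_mm,
              if (x$warning) " (warning: no group resolved)" else ""))
  print(x$groups)
  invisible(x)
}

michelson <- function(prof) {
  rng <- range(prof)
  if (sum(rng) == 0) return(0)
  (rng[2] - rng[1]) / (rng[2] + rng[1])
}

# phase-average a profile at a known period (in samples)
fold_profile <- function(prof, period_px) {
  nb <- max(2L, as.integer(round(period_px)))
  x <- seq_along(prof) - 1
  phase <- (x %% period_px) / period_px
  bin <- pmin(floor(phase * nb), nb - 1)
  vapply(split(prof, bin), mean, numeric(1))
}

#' Feature detectability as a function of stacked frames
#'
#' Median-stacks the first `n` corrected frames for `n = 1..N` and records, per
#' `n`, the acquisition time, the imaging dose, the CNR of the reference
#' feature (first row of `features`) and the smallest feature whose CNR exceeds
#' the detection threshold (Rose criterion, CNR > 4, by default).
#'
#' @param frames A corrected [frame_stack()] with at least 2 frames.
#' @param features Tibble with columns `feature` (label), `size_mm`, and
#'   list-columns `roi_a`, `roi_b` of [roi_spec()] objects.
#' @param dose_rate_mGy_per_s Geometry calibration for [imaging_dose()]
#'   (`NA` leaves the dose column `NA`).
#' @param detection_cnr CNR threshold above which a feature counts as detected.
#' @return A tibble with columns `n_frames, time_s, dose_mGy, cnr,
#'   smallest_resolved_feature_mm`, ordered by `n_frames`.
#' @export
detectability_vs_frames <- function(frames, features,
                                    dose_rate_mGy_per_s = NA_real_,
                                    detection_cnr = 4) {
  stopifnot(inherits(frames, "frame_stack"))
  n_tot <- n_frames(frames)
  if (n_tot < 2) stop("need at least 2 frames", call. = FALSE)
  features <- tibble::as_tibble(features)
  purrr::map_dfr(seq_len(n_tot), function(n) {
    sub <- frames
    sub$frames <- frames$frames[seq_len(n)]
    rad <- stack_median(sub)
    cnrs <- purrr::map2_dbl(features$roi_a, features$roi_b,
                            function(a, b) compute_cnr(rad, a, b))
    detected <- is.finite(cnrs) & cnrs > detection_cnr |
      is.infinite(cnrs) & cnrs > 0
    smallest <- if (any(detected)) min(features$size_mm[detected]) else NA_real_
    tibble::tibble(
      n_frames = n,
      time_s = acquisition_time(n, frames$frame_rate_hz),
      dose_mGy = if (is.na(dose_rate_mGy_per_s)) NA_real_ else
        imaging_dose(n, dose_rate_mGy_per_s, frames$frame_rate_hz),
      cnr = cnrs[1],
      smallest_resolved_feature_mm = smallest
    )
  })
}
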