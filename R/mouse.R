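#' Synthetic mouse plan/radiograph pair with landmark ground truth
#'
#' Builds a procedural skull-like plan image (nested ellipses for the skull
#' and brain case, suture lines, five high-contrast landmark structures and
#' an embedded hippocampus-shaped label region), then renders a radiograph
#' whose content is the plan mapped through a known similarity transform
#' plus detector acquisition noise. The true transform, the five landmark
#' positions in both frames and the hippocampus mask are emitted as ground
#' truth, so every downstream estimate (transform fit, target mapping,
#' stage shift) can be scored.
#'
#' @param seed Mandatory seed for the acquisition noise.
#' @param true_transform A [similarity_transform()] mapping plan pixels to
#'   radiograph pixels; scale must lie in `[0.5, 2]` and |rotation| <= 30
#'   degrees.
#' @param shape_px Canvas shape of both frames.
#' @param acq Optional [acquisition_params()]; defaults to 10 frames with
#'   Poisson noise at the given seed.
#' @param pixel_pitch_mm Pixel pitch of the radiograph in mm.
#' @return List with `plan` (matrix), `hippocampus_mask` (logical matrix in
#'   the plan frame), `radiograph_frames` (`raw`/`dark`/`beam` stacks),
#'   `landmarks` (tibble `label, plan_row, plan_col, radio_row, radio_col`)
#'   and `ground_truth` (transform parameters, landmark truth, target).
#' @export
make_mouse_pair <- function(seed, true_transform = similarity_transform(),
                            shape_px = c(256, 256), acq = NULL,
                            pixel_pitch_mm = 0.05) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(inherits(true_transform, "similarity2d"))
  if (true_transform$scale < 0.5 || true_transform$scale > 2) {
    stop("true_transform scale must lie in [0.5, 2]", call. = FALSE)
  }
  if (abs(true_transform$rotation_deg) > 30) {
    stop("|rotation| must be <= 30 degrees", call. = FALSE)
  }
  nr <- shape_px[1]; nc <- shape_px[2]
  plan <- draw_skull_plan(nr, nc)
  hippo <- plan$hippocampus
  landmarks_plan <- plan$landmarks

  # radiograph content: plan intensity pulled back through the transform
  radio_content <- warp_image(plan$image, true_transform, nr, nc)
  transmission <- 0.7 + 0.5 * radio_content
  attr(transmission, "pixel_pitch_mm") <- pixel_pitch_mm
  if (is.null(acq)) {
    acq <- acquisition_params(n_frames = 10, gain = 1e4, poisson_noise = TRUE,
                              seed = seed)
  }
  frames <- render_frames(transmission, acq, pixel_pitch_mm = pixel_pitch_mm)

  lm_radio <- transform_points(true_transform, landmarks_plan)
  landmarks <- tibble::tibble(
    label = sprintf("L%d", seq_len(nrow(landmarks_plan))),
    plan_row = landmarks_plan[, 1], plan_col = landmarks_plan[, 2],
    radio_row = lm_radio[, 1], radio_col = lm_radio[, 2]
  )
  hippo_idx <- which(hippo, arr.ind = TRUE)
  target_plan <- c(row = mean(hippo_idx[, 1]) - 1,
                   col = mean(hippo_idx[, 2]) - 1)
  list(
    plan = plan$image,
    hippocampus_mask = hippo,
    radiograph_frames = frames,
    landmarks = landmarks,
    ground_truth = list(
      transform = true_transform[c("scale", "rotation_deg", "t_row", "t_col")],
      landmarks = landmarks,
      target_plan_px = target_plan,
      target_radio_px = map_target(true_transform, target_plan),
      seed = seed
    )
  )
}

# procedural skull-like plan image in [0, 1] plus hippocampus label mask and
# 5 landmark positions (0-based px)
draw_skull_plan <- function(nr, nc) {
  rr <- matrix(seq_len(nr) - 1, nr, nc)
  cc <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  ell <- function(centre, ar, ac) {
    ((rr - centre[1]) / ar)^2 + ((cc - centre[2]) / ac)^2
  }
  img <- matrix(0.1, nr, nc)
  skull_out <- ell(ctr, 0.42 * nr, 0.36 * nc)
  skull_in <- ell(ctr, 0.36 * nr, 0.30 * nc)
  img[skull_out <= 1] <- 0.75           # bone
  img[skull_in <= 1] <- 0.35            # brain case
  # suture lines
  mid_c <- round(ctr[2]) + 1
  sel <- skull_in <= 1
  img[, mid_c][sel[, mid_c]] <- 0.65
  mid_r <- round(ctr[1] - 0.15 * nr) + 1
  img[mid_r, ][sel[mid_r, ]] <- 0.65
  # hippocampus-shaped label (bean: ellipse minus an off-centre bite)
  hip_ctr <- ctr + c(0.06 * nr, 0.10 * nc)
  hippo <- ell(hip_ctr, 0.08 * nr, 0.12 * nc) <= 1 &
    ell(hip_ctr + c(0.05 * nr, 0), 0.05 * nr, 0.08 * nc) > 1
  img[hippo] <- 0.45
  # five high-contrast landmark structures on the skull
  lms <- rbind(
    ctr + c(-0.38 * nr, 0),
    ctr + c(-0.12 * nr, -0.32 * nc),
    ctr + c(-0.12 * nr, 0.32 * nc),
    ctr + c(0.30 * nr, -0.20 * nc),
    ctr + c(0.30 * nr, 0.20 * nc)
  )
  for (i in seq_len(nrow(lms))) {
    d <- sqrt((rr - lms[i, 1])^2 + (cc - lms[i, 2])^2)
    img[d <= 2.5] <- 1.0
  }
  list(image = img, hippocampus = hippo, landmarks = lms)
}

# inverse-warp `img` through a similarity transform with bilinear sampling
warp_image <- function(img, transform, nr_out, nc_out, fill = 0.1) {
  rr <- matrix(seq_len(nr_out) - 1, nr_out, nc_out)
  cc <- matrix(seq_len(nc_out) - 1, nr_out, nc_out, byrow = TRUE)
  src <- transform_points(transform, cbind(as.vector(rr), as.vector(cc)),
                          inverse = TRUE)
  bilinear_sample(img, src[, 1], src[, 2], fill = fill) |>
    matrix(nr_out, nc_out)
}

bilinear_sample <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    out <- rep(fill, length(ri))
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) + val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc + val(r0 + 1, c0 + 1) * fr * fc
}
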