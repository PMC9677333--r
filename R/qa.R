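#' Daily-QA verification from the steel-ball film
#'
#' The daily QA irradiates a high-Z steel ball: a correctly aligned beam
#' leaves a dark collimator-sized spot on the film with the bright shadow of
#' the ball at its centre. This check segments the dark (irradiated) spot by
#' an Otsu threshold, then the bright shadow region enclosed by it, computes
#' both centres and compares them with the expected position.
#'
#' @param film_image Film scan as a numeric matrix (bright background, dark
#'   spot) or a [radiograph()].
#' @param expected_center Expected spot centre `(row, col)`, 0-based px.
#' @param collimator_radius_mm,ball_radius_mm Nominal radii (recorded in the
#'   result for reporting; segmentation does not assume them).
#' @param tolerance_mm Pass tolerance for both centre offsets.
#' @param pixel_pitch_mm Film pixel pitch in mm.
#' @return Object of class `qa_result`: `pass`, `spot_offset_mm`,
#'   `shadow_offset_mm`, `spot_center`, `shadow_center`, `reason`.
#' @export
qa_ball_shadow <- function(film_image, expected_center,
                           collimator_radius_mm = 1.5, ball_radius_mm = 0.5,
                           tolerance_mm = 0.5, pixel_pitch_mm = 0.05) {
  img <- as_image_matrix(film_image)
  fail <- function(reason) {
    structure(list(pass = FALSE, spot_offset_mm = NA_real_,
                   shadow_offset_mm = NA_real_, spot_center = NULL,
                   shadow_center = NULL, tolerance_mm = tolerance_mm,
                   reason = reason),
              class = "qa_result")
  }
  lo <- min(img); hi <- max(img)
  if (hi <= lo) return(fail("no spot: film is uniform"))
  norm <- (img - lo) / (hi - lo)
  th <- EBImage::otsu(norm, range = c(0, 1))
  dark <- norm < th
  if (!any(dark)) return(fail("no spot: nothing below threshold"))
  lab <- EBImage::bwlabel(dark)
  sizes <- tabulate(lab[lab > 0])
  spot <- lab == which.max(sizes)
  spot_idx <- which(spot, arr.ind = TRUE)
  spot_center <- c(row = mean(spot_idx[, 1]) - 1, col = mean(spot_idx[, 2]) - 1)

  # bright components that do not touch the film border and sit inside the
  # spot's bounding box are shadow candidates
  bright_lab <- EBImage::bwlabel(!dark)
  nb <- max(bright_lab)
  if (nb == 0) return(fail("no shadow: spot has no enclosed bright region"))
  border_ids <- unique(c(bright_lab[1, ], bright_lab[nrow(img), ],
                         bright_lab[, 1], bright_lab[, ncol(img)]))
  bb <- c(range(spot_idx[, 1]), range(spot_idx[, 2]))
  cand <- setdiff(seq_len(nb), border_ids)
  cand_sizes <- vapply(cand, function(id) {
    idx <- which(bright_lab == id, arr.ind = TRUE)
    cr <- mean(idx[, 1]); cc <- mean(idx[, 2])
    if (cr >= bb[1] && cr <= bb[2] && cc >= bb[3] && cc <= bb[4]) {
      nrow(idx)
    } else 0L
  }, integer(1))
  if (length(cand) == 0 || max(cand_sizes) == 0) {
    return(fail("no shadow: spot has no enclosed bright region"))
  }
  shadow <- bright_lab == cand[which.max(cand_sizes)]
  sh_idx <- which(shadow, arr.ind = TRUE)
  shadow_center <- c(row = mean(sh_idx[, 1]) - 1, col = mean(sh_idx[, 2]) - 1)

  off <- function(ctr) {
    sqrt(sum((ctr - expected_center)^2)) * pixel_pitch_mm
  }
  spot_off <- off(spot_center)
  shadow_off <- off(shadow_center)
  pass <- spot_off <= tolerance_mm && shadow_off <= tolerance_mm
  structure(
    list(pass = pass, spot_offset_mm = spot_off,
         shadow_offset_mm = shadow_off, spot_center = spot_center,
         shadow_center = shadow_center, tolerance_mm = tolerance_mm,
         reason = if (pass) "ok" else "offset exceeds tolerance"),
    class = "qa_result"
  )
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf("<qa_result> %s", if (x$pass) "PASS" else "FAIL"))
  if (!is.na(x$spot_offset_mm)) {
    cat(sprintf(" | spot off %.3f mm, shadow off %.3f mm (tol %.2f mm)",
                x$spot_offset_mm, x$shadow_offset_mm, x$tolerance_mm))
  }
  cat(sprintf(" | %s\n", x$reason))
  invisible(x)
}
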