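#' Beam isocenter from a collimator radiograph
#'
#' Segments the bright collimator aperture by a global Otsu threshold on the
#' min-max-normalised image, keeps the largest connected component, and
#' returns its intensity-weighted centroid (subpixel, 0-based) together with
#' the equivalent-disk radius `sqrt(area / pi)`. Because the threshold and
#' the weights are computed on the normalised image, the result is invariant
#' to global intensity scaling. Quality flags report a component touching the
#' image border and low circularity (`area / (pi * r_max^2) < 0.8`, where
#' `r_max` is the largest distance of a component pixel from the centroid).
#'
#' @param collimator_radiograph A [radiograph()] containing one dominant
#'   bright connected region.
#' @return Object of class `isocenter`: `center` (row, col), `radius_px`,
#'   `area_px`, `threshold` (original intensity units), `circularity`,
#'   `flags`.
#' @export
detect_isocenter <- function(collimator_radiograph) {
  img <- as_image_matrix(collimator_radiograph)
  lo <- min(img); hi <- max(img)
  if (hi <= lo) stop("no component above threshold: image is constant",
                     call. = FALSE)
  norm <- (img - lo) / (hi - lo)
  th <- EBImage::otsu(norm, range = c(0, 1))
  mask <- norm > th
  if (!any(mask)) stop("no component above threshold", call. = FALSE)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  sel <- lab == comp
  idx <- which(sel, arr.ind = TRUE)
  r0 <- idx[, 1] - 1; c0 <- idx[, 2] - 1
  w <- norm[sel]
  ctr <- c(row = sum(w * r0) / sum(w), col = sum(w * c0) / sum(w))
  area <- sum(sel)
  r_max <- sqrt(max((r0 - ctr[1])^2 + (c0 - ctr[2])^2))
  circ <- if (r_max > 0) area / (pi * r_max^2) else 1
  touches <- any(idx[, 1] == 1L) || any(idx[, 1] == nrow(img)) ||
    any(idx[, 2] == 1L) || any(idx[, 2] == ncol(img))
  structure(
    list(center = ctr,
         radius_px = sqrt(area / pi),
         area_px = area,
         threshold = lo + th * (hi - lo),
         circularity = circ,
         flags = list(touches_border = touches,
                      low_circularity = circ < 0.8)),
    class = "isocenter"
  )
}

#' @export
print.isocenter <- function(x, ...) {
  cat(sprintf(
    "<isocenter> center (%.2f, %.2f) px | radius %.2f px | circ %.3f%s%s\n",
    x$center[1], x$center[2], x$radius_px, x$circularity,
    if (x$flags$touches_border) " [touches border]" else "",
    if (x$flags$low_circularity) " [low circularity]" else ""))
  invisible(x)
}
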