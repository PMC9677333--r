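#' Fluorescence microscopy channel image
#'
#' @param image Numeric matrix (16-bit intensity scale).
#' @param pixel_size_mm Physical pixel size in mm (default 0.000325, i.e.
#'   0.325 um).
#' @param channel Channel label, `"DAPI"` or `"gH2AX"`.
#' @return Object of class `fluorescence_image`.
#' @export
fluorescence_image <- function(image, pixel_size_mm = 0.000325,
                               channel = c("DAPI", "gH2AX")) {
  channel <- match.arg(channel)
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (pixel_size_mm <= 0) stop("`pixel_size_mm` must be > 0", call. = FALSE)
  structure(list(image = image, pixel_size_mm = pixel_size_mm,
                 channel = channel),
            class = "fluorescence_image")
}

#' @export
print.fluorescence_image <- function(x, ...) {
  cat(sprintf("<fluorescence_image> %s %d x %d px | %.4g um/px\n",
              x$channel, nrow(x$image), ncol(x$image), x$pixel_size_mm * 1e3))
  invisible(x)
}

#' Local maxima with a topographic-prominence threshold
#'
#' Detects the local maxima (8-connectivity) of an image whose topographic
#' prominence exceeds the given threshold: a candidate maximum is rejected
#' exactly when a path to a strictly higher pixel exists that never descends
#' more than `prominence` below the candidate. Plateau maxima yield one
#' representative point (the plateau centroid, rounded). The global maximum
#' has no higher ground, is always kept, and is reported with infinite
#' prominence; a constant image has no maxima. This is the noise-tolerance
#' semantics of the classic maxima-finder used for nucleus counting, fully
#' specified (strict comparisons, plateau centroids, deterministic ordering).
#'
#' @param image A [fluorescence_image()] or a numeric matrix.
#' @param prominence Positive prominence (noise-tolerance) threshold.
#' @return A tibble with columns `row`, `col` (0-based pixel coordinates),
#'   `value` and `prominence`, ordered by descending value then row-major.
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 1000
#' find_maxima(img, 600)
#' @export
find_maxima <- function(image, prominence) {
  if (!is.numeric(prominence) || length(prominence) != 1 || prominence <= 0) {
    stop("`prominence` must be a single positive number", call. = FALSE)
  }
  img <- if (inherits(image, "fluorescence_image")) image$image else image
  if (!is.matrix(img)) stop("`image` must be a matrix", call. = FALSE)
  m <- cpp_find_maxima(img, prominence)
  out <- tibble::tibble(row = unname(floor(m[, 1] + 0.5)),
                        col = unname(floor(m[, 2] + 0.5)),
                        value = unname(m[, 3]),
                        prominence = unname(m[, 4]))
  out[order(-out$value, out$row, out$col), , drop = FALSE]
}
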