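#' TIFF + JSON-sidecar I/O for frame stacks and radiographs
#'
#' Raw detector stacks are stored as multi-page 16-bit TIFF (counts scaled
#' by 1/65535) with a JSON sidecar (`<path>.json`) carrying pitch, frame
#' rate, beam settings, role and the count scale. Corrected radiographs are
#' stored as 32-bit TIFF normalised to `[0, 1]` with the affine scale and
#' offset recorded in the sidecar, so reading reverses the normalisation.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(stack$frames, function(f) {
    pmin(pmax(f / 65535, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar <- list(
    kind = "frame_stack",
    pixel_pitch_mm = stack$pixel_pitch_mm,
    frame_rate_hz = stack$frame_rate_hz,
    beam = as.list(stack$beam),
    role = stack$role,
    scale = 65535
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- lapply(pages, function(p) p * meta$scale)
  frame_stack(frames, pixel_pitch_mm = meta$pixel_pitch_mm,
              frame_rate_hz = meta$frame_rate_hz,
              beam = unlist(meta$beam), role = meta$role)
}

#' @rdname write_frame_stack
#' @param rad A [radiograph()].
#' @export
write_radiograph <- function(rad, path) {
  stopifnot(inherits(rad, "radiograph"))
  lo <- min(rad$image); hi <- max(rad$image)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((rad$image - lo) / scale, path, bits.per.sample = 32L)
  sidecar <- list(kind = "radiograph", pixel_pitch_mm = rad$pixel_pitch_mm,
                  offset = lo, scale = scale,
                  provenance = rad$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_radiograph <- function(path) {
  img <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  radiograph(img * meta$scale + meta$offset,
             pixel_pitch_mm = meta$pixel_pitch_mm,
             provenance = as.list(meta$provenance))
}

#' Write / read a 2D label image as 8-bit TIFF
#' @param labels Integer matrix (labels 0..255).
#' @param path File path.
#' @export
write_label_image <- function(labels, path) {
  tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  m <- round(tiff::readTIFF(path) * 255)
  storage.mode(m) <- "integer"
  m
}

#' Write a 3D volume as multi-page TIFF (16-bit, scaled)
#' @param volume 3D numeric array.
#' @param path File path.
#' @export
write_volume_tiff <- function(volume, path) {
  lo <- min(volume); hi <- max(volume)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(volume)[3]), function(k) {
    (volume[, , k] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(kind = "volume", offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$scale + meta$offset
  arr
}
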