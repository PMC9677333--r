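#' Tile-wise relative DNA-damage map from a DAPI / gammaH2AX pair
#'
#' Detects nuclei as prominence-thresholded maxima of the DAPI channel and
#' damaged nuclei as maxima of the gammaH2AX channel (default prominences
#' 600 and 1400), bins both into tiles (default 256 x 256 px), and reports
#' the per-tile damaged fraction `ratio = n_damage / n_dapi` with
#' `n_damage` clipped to `n_dapi` so the ratio is a fraction of cells.
#' Tiles with fewer than `min_cells` nuclei are flagged invalid (the count
#' statistic is unstable at very low cell density); edge tiles smaller than
#' the full tile size are processed but flagged.
#'
#' @param dapi,gh2ax [fluorescence_image()]s (or matrices) of identical
#'   shape.
#' @param tile_px Tile edge length in pixels.
#' @param prominences Length-2 numeric, prominence thresholds for the DAPI
#'   and gammaH2AX channels.
#' @param min_cells Minimum DAPI count for a valid tile.
#' @return A tibble of class `damage_tile_map` with columns `tile_row`,
#'   `tile_col` (0-based), `n_dapi`, `n_damage`, `ratio` (`NA` on invalid
#'   tiles), `valid`, `edge`; attributes `tile_px` and `image_shape`.
#' @export
damage_map <- function(dapi, gh2ax, tile_px = 256,
                       prominences = c(dapi = 600, gh2ax = 1400),
                       min_cells = 5) {
  di <- if (inherits(dapi, "fluorescence_image")) dapi$image else dapi
  gi <- if (inherits(gh2ax, "fluorescence_image")) gh2ax$image else gh2ax
  if (!identical(dim(di), dim(gi))) {
    stop("DAPI and gammaH2AX images must be congruent", call. = FALSE)
  }
  nr <- nrow(di); nc <- ncol(di)
  mx_d <- find_maxima(di, prominences[[1]])
  mx_g <- find_maxima(gi, prominences[[2]])

  ntr <- ceiling(nr / tile_px); ntc <- ceiling(nc / tile_px)
  lev <- function(m) {
    factor(paste(floor(m$row / tile_px), floor(m$col / tile_px)),
           levels = paste(rep(0:(ntr - 1), ntc),
                          rep(0:(ntc - 1), each = ntr)))
  }
  out <- tibble::tibble(
    tile_row = rep(0:(ntr - 1), ntc),
    tile_col = rep(0:(ntc - 1), each = ntr),
    n_dapi = as.integer(table(lev(mx_d))),
    n_damage = as.integer(table(lev(mx_g)))
  )
  out$n_damage <- pmin(out$n_damage, out$n_dapi)
  out$valid <- out$n_dapi >= min_cells
  out$ratio <- ifelse(out$valid, out$n_damage / out$n_dapi, NA_real_)
  out$edge <- (out$tile_row + 1) * tile_px > nr |
    (out$tile_col + 1) * tile_px > nc
  out <- out[, c("tile_row", "tile_col", "n_dapi", "n_damage", "ratio",
                 "valid", "edge")]
  class(out) <- c("damage_tile_map", class(out))
  attr(out, "tile_px") <- tile_px
  attr(out, "image_shape") <- c(nr, nc)
  attr(out, "min_cells") <- min_cells
  out
}

#' Resample a damage tile map into dose-grid coordinates
#'
#' Maps every dose-grid pixel through the supplied 2D affine transform into
#' damage tile-grid coordinates and takes the nearest tile's ratio (and
#' validity flag). The affine is given as a 2 x 3 matrix `[A | b]` acting on
#' 0-based `(row, col)` dose coordinates, `tile_coord = A %*% px + b`;
#' it must be invertible.
#'
#' @param map A [damage_map()] result.
#' @param dose A `dose_map2d`.
#' @param affine_2d 2 x 3 numeric matrix; defaults to the identity, which
#'   assumes the dose grid and the tile grid coincide.
#' @return Object of class `aligned_damage`: matrices `dose`, `damage`
#'   (`NA` where invalid/outside), `valid`, plus `pixel_size_mm` and
#'   `beam_axis` from the dose map.
#' @export
align_to_dose <- function(map, dose, affine_2d = cbind(diag(2), c(0, 0))) {
  stopifnot(inherits(map, "damage_tile_map"), inherits(dose, "dose_map2d"))
  if (!is.matrix(affine_2d) || !all(dim(affine_2d) == c(2, 3))) {
    stop("`affine_2d` must be a 2 x 3 matrix", call. = FALSE)
  }
  a <- affine_2d[, 1:2]
  if (abs(det(a)) < .Machine$double.eps) {
    stop("singular affine transform", call. = FALSE)
  }
  nr <- nrow(dose$dose); nc <- ncol(dose$dose)
  px <- cbind(rep(0:(nr - 1), nc), rep(0:(nc - 1), each = nr))
  tc <- t(a %*% t(px) + affine_2d[, 3])
  ti <- round(tc[, 1]); tj <- round(tc[, 2])
  ntr <- max(map$tile_row) + 1; ntc_ <- max(map$tile_col) + 1
  ratio_grid <- matrix(NA_real_, ntr, ntc_)
  valid_grid <- matrix(FALSE, ntr, ntc_)
  ratio_grid[cbind(map$tile_row + 1, map$tile_col + 1)] <- map$ratio
  valid_grid[cbind(map$tile_row + 1, map$tile_col + 1)] <- map$valid
  inside <- ti >= 0 & ti < ntr & tj >= 0 & tj < ntc_
  damage <- rep(NA_real_, nr * nc)
  valid <- rep(FALSE, nr * nc)
  damage[inside] <- ratio_grid[cbind(ti[inside] + 1, tj[inside] + 1)]
  valid[inside] <- valid_grid[cbind(ti[inside] + 1, tj[inside] + 1)]
  structure(
    list(dose = dose$dose, damage = matrix(damage, nr, nc),
         valid = matrix(valid, nr, nc), pixel_size_mm = dose$pixel_size_mm,
         beam_axis = dose$beam_axis),
    class = "aligned_damage"
  )
}

#' Dose / damage profile correlation along the beam axis
#'
#' Averages dose and relative damage across a box per along-beam bin
#' (invalid tiles excluded from the damage mean) and reports the Pearson
#' correlation over bins where both are defined.
#'
#' @param aligned An [align_to_dose()] result.
#' @param box [roi_spec()] on the common (dose) grid.
#' @param beam_axis `"col"` or `"row"`; defaults to the aligned pair's.
#' @param n_bins Number of along-axis bins (default: one per grid line).
#' @return Object of class `profile_report`: `profile` tibble
#'   (`coord_mm, dose, damage`), `r`, `n_bins`.
#' @export
profile_correlation <- function(aligned, box, beam_axis = NULL,
                                n_bins = NULL) {
  stopifnot(inherits(aligned, "aligned_damage"))
  if (is.null(beam_axis)) beam_axis <- aligned$beam_axis
  dose_box <- roi_extract(aligned$dose, box)
  dmg_box <- roi_extract(aligned$damage, box)
  val_box <- roi_extract(aligned$valid * 1, box) > 0
  if (beam_axis == "row") {
    dose_box <- t(dose_box); dmg_box <- t(dmg_box); val_box <- t(val_box)
  }
  n_along <- ncol(dose_box)
  if (is.null(n_bins)) n_bins <- n_along
  bin <- pmin(floor((seq_len(n_along) - 1) / n_along * n_bins), n_bins - 1)
  coord0 <- if (beam_axis == "row") box$row0 else box$col0
  prof <- purrr::map_dfr(0:(n_bins - 1), function(b) {
    sel <- bin == b
    dmg <- dmg_box[, sel][val_box[, sel]]
    tibble::tibble(
      coord_mm = (coord0 + mean(which(sel)) - 0.5) * aligned$pixel_size_mm,
      dose = mean(dose_box[, sel]),
      damage = if (length(dmg)) mean(dmg) else NA_real_
    )
  })
  ok <- !is.na(prof$damage)
  if (sum(ok) < 5) {
    stop("fewer than 5 valid bins in the profile box", call. = FALSE)
  }
  r <- if (stats::sd(prof$dose[ok]) == 0 || stats::sd(prof$damage[ok]) == 0) {
    NA_real_
  } else {
    stats::cor(prof$dose[ok], prof$damage[ok])
  }
  structure(list(profile = prof, r = r, n_bins = sum(ok)),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("<profile_report> Pearson r = %.3f over %d bins\n",
              x$r, x$n_bins))
  invisible(x)
}
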