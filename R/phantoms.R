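#' Parametric phantoms and the proton transmission image model
#'
#' Phantoms are described by a canvas, a list of painted primitives
#' (rectangles, antialiased disks, bar groups), and per-beam-energy
#' edge-blur presets. The transmission model turns a phantom into a
#' relative-fluence map: protons are not absorbed but scattered, so fluence
#' lost inside dense material is returned as a broad halo, and every material
#' boundary carries a difference-of-Gaussians redistribution with a valley
#' just inside the dense side and a peak just outside. Preset widths are
#' calibrated so that the edge-peak FWHM grows by 0.08 mm from the 200 MeV to
#' the 150 MeV preset.
#'
#' @name phantoms
NULL

# FWHM of the ideal edge bump in units of the wide blur sigma (narrow sigma
# fixed at half the wide one); computed from Phi_c(u) - Phi_c(2u)
.edge_fwhm_const <- 1.168549

# energy presets: target edge-peak FWHM in mm
.edge_presets <- list(
  `150` = list(fwhm_mm = 0.38),
  `200` = list(fwhm_mm = 0.30)
)

new_phantom_spec <- function(shape_px, primitives, label,
                             pixel_pitch_mm = 0.05, meta = list()) {
  structure(
    list(shape_px = as.integer(shape_px),
         pixel_pitch_mm = pixel_pitch_mm,
         primitives = tibble::as_tibble(primitives),
         presets = .edge_presets,
         label = label,
         meta = meta),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> '%s' %d x %d px @ %.3g mm | %d primitive(s)\n",
              x$label, x$shape_px[1], x$shape_px[2], x$pixel_pitch_mm,
              nrow(x$primitives)))
  invisible(x)
}

prim_row <- function(type, rsp, thickness_mm, r0 = NA, r1 = NA, c0 = NA,
                     c1 = NA, cr = NA, cc = NA, radius = NA, freq = NA) {
  tibble::tibble(type = type, rsp = rsp, thickness_mm = thickness_mm,
                 r0_mm = r0, r1_mm = r1, c0_mm = c0, c1_mm = c1,
                 cr_mm = cr, cc_mm = cc, radius_mm = radius,
                 freq_lp_per_mm = freq)
}

#' Hole-grid resolution phantom
#'
#' A PMMA-like plate with groups of circular air holes of decreasing
#' diameter down to 0.3 mm, 3 x 3 holes per group with spacing 2.5 diameters
#' (the spacing and group arrangement are a generator convention recorded in
#' the phantom metadata).
#'
#' @param shape_px Canvas shape in pixels.
#' @param pixel_pitch_mm Pixel pitch in mm.
#' @return A `phantom_spec`; `$meta$holes` lists every hole with its true
#'   centre and diameter, `$meta$background_roi_mm` a clean plate region.
#' @export
make_hole_grid_phantom <- function(shape_px = c(512, 512),
                                   pixel_pitch_mm = 0.05) {
  diam <- c(1.2, 1.0, 0.8, 0.6, 0.5, 0.4, 0.3)
  centres <- expand.grid(row = c(6.4, 12.8, 19.2), col = c(6.4, 12.8, 19.2))
  centres <- centres[seq_along(diam), ]
  plate <- prim_row("rect", rsp = 1.16, thickness_mm = 5,
                    r0 = 1.6, r1 = 24.0, c0 = 1.6, c1 = 24.0)
  holes <- purrr::map_dfr(seq_along(diam), function(g) {
    d <- diam[g]
    sp <- 2.5 * d
    off <- expand.grid(dr = (-1:1) * sp, dc = (-1:1) * sp)
    purrr::map_dfr(seq_len(nrow(off)), function(k) {
      prim_row("disk", rsp = 0, thickness_mm = 5,
               cr = centres$row[g] + off$dr[k],
               cc = centres$col[g] + off$dc[k],
               radius = d / 2)
    })
  })
  hole_truth <- tibble::tibble(
    group = rep(seq_along(diam), each = 9),
    diameter_mm = rep(diam, each = 9),
    center_row_mm = holes$cr_mm, center_col_mm = holes$cc_mm
  )
  new_phantom_spec(
    shape_px, dplyr::bind_rows(plate, holes), "hole-grid",
    pixel_pitch_mm,
    meta = list(holes = hole_truth, diameters_mm = diam,
                group_centres_mm = centres,
                background_roi_mm = c(r0 = 1.8, r1 = 2.8, c0 = 4, c1 = 22))
  )
}

#' Lead-grid line-pair phantom
#'
#' Bar groups spanning 0.6 to 6.0 line pairs per mm, four line pairs per
#' group (bar and gap each half a period wide).
#'
#' @inheritParams make_hole_grid_phantom
#' @return A `phantom_spec`; `$meta$groups` holds each group's box and
#'   frequency, `$meta$background_roi_mm` an empty region.
#' @export
make_lead_grid_phantom <- function(shape_px = c(560, 192),
                                   pixel_pitch_mm = 0.05) {
  freqs <- c(0.6, 1.0, 1.5, 2.0, 2.5, 3.0, 4.0, 5.0, 6.0)
  n_pairs <- 4
  y0 <- 1.0
  rows <- list()
  groups <- list()
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    width <- n_pairs / f
    box <- c(r0 = y0, r1 = y0 + 2.0, c0 = 1.0, c1 = 1.0 + width)
    rows[[i]] <- prim_row("bars", rsp = 5.0, thickness_mm = 2,
                          r0 = box["r0"], r1 = box["r1"],
                          c0 = box["c0"], c1 = box["c1"], freq = f)
    groups[[i]] <- tibble::tibble(freq_lp_per_mm = f, r0_mm = box[["r0"]],
                                  r1_mm = box[["r1"]], c0_mm = box[["c0"]],
                                  c1_mm = box[["c1"]])
    y0 <- y0 + 2.6
  }
  new_phantom_spec(
    shape_px, dplyr::bind_rows(rows), "lead-grid", pixel_pitch_mm,
    meta = list(groups = dplyr::bind_rows(groups),
                background_roi_mm = c(r0 = y0 + 0.4, r1 = y0 + 1.4,
                                      c0 = 1.0, c1 = 7.0))
  )
}

#' Straight-edge phantom for edge-enhancement measurements
#'
#' A thick PMMA half-plane whose vertical boundary produces the
#' scatter-induced fluence valley/peak pair.
#'
#' @inheritParams make_hole_grid_phantom
#' @param edge_col_mm Column position of the measured (right) material edge
#'   in mm.
#' @param block_width_mm Width of the material block; the block is kept away
#'   from the canvas border so that only its own two edges exist.
#' @return A `phantom_spec` with `$meta$edge_col_mm`.
#' @export
make_edge_phantom <- function(shape_px = c(256, 256), pixel_pitch_mm = 0.05,
                              edge_col_mm = 4.8, block_width_mm = 3) {
  c0 <- edge_col_mm - block_width_mm
  if (c0 <= 0 || edge_col_mm >= shape_px[2] * pixel_pitch_mm ||
      block_width_mm >= edge_col_mm) {
    stop("edge block must lie inside the canvas", call. = FALSE)
  }
  block <- prim_row("rect", rsp = 1.16, thickness_mm = 20,
                    r0 = 0, r1 = shape_px[1] * pixel_pitch_mm,
                    c0 = c0, c1 = edge_col_mm)
  new_phantom_spec(shape_px, block, "edge", pixel_pitch_mm,
                   meta = list(edge_col_mm = edge_col_mm,
                               block_c0_mm = c0))
}

#' Relative-fluence transmission map of a phantom
#'
#' @param phantom A `phantom_spec`.
#' @param energy_preset `"150"` or `"200"` (MeV); selects the edge-blur
#'   width.
#' @param k_areal Scattering coefficient per unit areal density (RSP * mm).
#' @param halo_sigma_mm Width of the broad halo returning scattered fluence.
#' @param edge_strength Amplitude factor of the edge redistribution.
#' @return Numeric matrix of relative fluence (canvas mean exactly 1), with
#'   attributes `pixel_pitch_mm` and `energy_preset`.
#' @export
transmission_map <- function(phantom, energy_preset = c("200", "150"),
                             k_areal = 0.05, halo_sigma_mm = 1.0,
                             edge_strength = 2.0) {
  stopifnot(inherits(phantom, "phantom_spec"))
  energy_preset <- as.character(energy_preset[1])
  if (!energy_preset %in% names(phantom$presets)) {
    stop(sprintf("unknown energy preset '%s'", energy_preset), call. = FALSE)
  }
  pitch <- phantom$pixel_pitch_mm
  a <- paint_areal_density(phantom)
  s <- 1 - exp(-k_areal * a)
  sigma2 <- phantom$presets[[energy_preset]]$fwhm_mm / .edge_fwhm_const / pitch
  sigma1 <- sigma2 / 2
  halo <- halo_sigma_mm / pitch
  map <- 1 - s + blur_gauss_fft(s, halo) +
    edge_strength * (blur_gauss_fft(s, sigma2) - blur_gauss_fft(s, sigma1))
  attr(map, "pixel_pitch_mm") <- pitch
  attr(map, "energy_preset") <- energy_preset
  map
}

# paint RSP * thickness (mm) onto the canvas; later primitives override
# earlier ones, disks with antialiased coverage
paint_areal_density <- function(phantom) {
  nr <- phantom$shape_px[1]; nc <- phantom$shape_px[2]
  pitch <- phantom$pixel_pitch_mm
  rr <- (seq_len(nr) - 0.5) * pitch
  cc <- (seq_len(nc) - 0.5) * pitch
  a <- matrix(0, nr, nc)
  for (i in seq_len(nrow(phantom$primitives))) {
    p <- phantom$primitives[i, ]
    val <- p$rsp * p$thickness_mm
    if (p$type == "rect") {
      sel_r <- rr >= p$r0_mm & rr < p$r1_mm
      sel_c <- cc >= p$c0_mm & cc < p$c1_mm
      a[sel_r, sel_c] <- val
    } else if (p$type == "disk") {
      dist <- sqrt(outer((rr - p$cr_mm)^2, (cc - p$cc_mm)^2, `+`)) / pitch
      cov <- pmin(pmax(p$radius_mm / pitch - dist + 0.5, 0), 1)
      a <- cov * val + (1 - cov) * a
    } else if (p$type == "bars") {
      sel_r <- rr >= p$r0_mm & rr < p$r1_mm
      period <- 1 / p$freq_lp_per_mm
      in_box <- cc >= p$c0_mm & cc < p$c1_mm
      bar <- ((cc - p$c0_mm) %% period) < period / 2
      a[sel_r, in_box & bar] <- val
    } else {
      stop(sprintf("unknown primitive type '%s'", p$type), call. = FALSE)
    }
  }
  a
}

# circular (FFT) Gaussian convolution; conserves the image mean exactly
blur_gauss_fft <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  kr <- circ_kernel(sigma_px, nr)
  kc <- circ_kernel(sigma_px, nc)
  k2 <- outer(kr, kc)
  Re(stats::fft(stats::fft(x) * stats::fft(k2), inverse = TRUE)) / (nr * nc)
}

circ_kernel <- function(sigma_px, n) {
  l <- min(ceiling(5 * sigma_px), floor((n - 1) / 2))
  g <- stats::dnorm(-l:l, sd = sigma_px)
  g <- g / sum(g)
  k <- numeric(n)
  idx <- ((-l:l) %% n) + 1
  for (j in seq_along(idx)) k[idx[j]] <- k[idx[j]] + g[j]
  k
}

#' Line-pair grid specification of a lead-grid phantom, in pixels
#'
#' Converts the group boxes recorded in a [make_lead_grid_phantom()] spec to
#' the pixel-space tibble consumed by [line_pair_resolution()], including the
#' background row (`freq_lp_per_mm = 0`).
#'
#' @param phantom A lead-grid `phantom_spec`.
#' @return Tibble with columns `label,row0,row1,col0,col1,freq_lp_per_mm`.
#' @export
grid_spec_of <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  g <- phantom$meta$groups
  if (is.null(g)) stop("phantom has no line-pair groups", call. = FALSE)
  pitch <- phantom$pixel_pitch_mm
  grp <- tibble::tibble(
    label = sprintf("%.1f lp/mm", g$freq_lp_per_mm),
    row0 = round(g$r0_mm / pitch), row1 = round(g$r1_mm / pitch),
    col0 = round(g$c0_mm / pitch), col1 = round(g$c1_mm / pitch),
    freq_lp_per_mm = g$freq_lp_per_mm
  )
  bg <- phantom$meta$background_roi_mm
  dplyr::bind_rows(grp, tibble::tibble(
    label = "background",
    row0 = round(bg[["r0"]] / pitch), row1 = round(bg[["r1"]] / pitch),
    col0 = round(bg[["c0"]] / pitch), col1 = round(bg[["c1"]] / pitch),
    freq_lp_per_mm = 0
  ))
}

#' Detectability feature specification of a hole-grid phantom
#'
#' One feature per hole group (its central hole as the signal region) plus a
#' shared clean-plate background region.
#'
#' @param phantom A hole-grid `phantom_spec`.
#' @return Tibble with columns `feature`, `size_mm` and list-columns
#'   `roi_a`, `roi_b` as consumed by [detectability_vs_frames()].
#' @export
feature_spec_of <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  pitch <- phantom$pixel_pitch_mm
  diam <- phantom$meta$diameters_mm
  ctr <- phantom$meta$group_centres_mm
  bg <- phantom$meta$background_roi_mm
  roi_b <- roi_spec(round(bg[["r0"]] / pitch), round(bg[["r1"]] / pitch),
                    round(bg[["c0"]] / pitch), round(bg[["c1"]] / pitch),
                    "plate-background")
  purrr::map_dfr(seq_along(diam), function(g) {
    half <- max(diam[g] / 2 / pitch, 1)
    r <- ctr$row[g] / pitch; c <- ctr$col[g] / pitch
    tibble::tibble(
      feature = sprintf("%.1f mm hole", diam[g]),
      size_mm = diam[g],
      roi_a = list(roi_spec(floor(r - half), ceiling(r + half),
                            floor(c - half), ceiling(c + half),
                            sprintf("hole-%d", g))),
      roi_b = list(roi_b)
    )
  })
}
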