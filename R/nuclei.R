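#' Synthetic DAPI / gammaH2AX microscopy pair with per-tile ground truth
#'
#' Nuclei are placed by rejection sampling with a minimum-distance
#' constraint and stamped as Gaussian DAPI blobs. Each nucleus is damaged
#' with probability `p(dose) = p_bg + (p_max - p_bg) * dose / (dose + d50)`
#' (a saturating hyperbolic emulation of the dose-damage relation; the form
#' is a documented stand-in, not a measured response), and damaged nuclei
#' receive a bright gammaH2AX blob. Both channels are 16-bit with Gaussian
#' background noise well below the prominence thresholds used for counting.
#' True per-tile nucleus and damaged-nucleus counts are recorded.
#'
#' @param dose A [analytic_depth_dose()] result (or any `dose_map2d`); dose
#'   is sampled at each nucleus centre by physical position.
#' @param seed Mandatory seed.
#' @param n_nuclei Number of nuclei to place.
#' @param shape_px Image shape in pixels.
#' @param pixel_size_mm Microscopy pixel size in mm (0.325 um default).
#' @param min_dist_px Minimum centre-to-centre distance.
#' @param nucleus_sigma_px Gaussian blob sigma for DAPI, in px.
#' @param dapi_amplitude,gh2ax_amplitude Blob peak amplitudes (counts).
#' @param background_mean,background_sd Background level and noise.
#' @param p_bg,p_max,d50_Gy Damage-probability parameters.
#' @param tile_px Tile size for the truth table.
#' @param max_tries Placement attempts per nucleus before giving up.
#' @return List with `dapi`, `gh2ax` ([fluorescence_image()]s), `truth`
#'   (per-tile tibble `tile_row, tile_col, n_dapi, n_damage`), `centers`
#'   (per-nucleus tibble) and `params`.
#' @export
make_nuclei_pair <- function(dose, seed, n_nuclei = 1500,
                             shape_px = c(512, 512),
                             pixel_size_mm = 0.000325,
                             min_dist_px = 9, nucleus_sigma_px = 2.5,
                             dapi_amplitude = 3000, gh2ax_amplitude = 5000,
                             background_mean = 120, background_sd = 25,
                             p_bg = 0.05, p_max = 0.95, d50_Gy = 2,
                             tile_px = 256, max_tries = 60) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(inherits(dose, "dose_map2d"))
  if (n_nuclei <= 0) stop("`n_nuclei` must be > 0", call. = FALSE)
  nr <- shape_px[1]; nc <- shape_px[2]

  with_seed(seed, {
    ctr <- place_nuclei(n_nuclei, nr, nc, min_dist_px, max_tries)
    # dose at each nucleus centre, by physical position on the dose grid
    pos_r_mm <- (ctr[, 1] + 0.5) * pixel_size_mm
    pos_c_mm <- (ctr[, 2] + 0.5) * pixel_size_mm
    di <- pmin(pmax(floor(pos_r_mm / dose$pixel_size_mm) + 1, 1),
               nrow(dose$dose))
    dj <- pmin(pmax(floor(pos_c_mm / dose$pixel_size_mm) + 1, 1),
               ncol(dose$dose))
    d_gy <- dose$dose[cbind(di, dj)]
    p <- p_bg + (p_max - p_bg) * d_gy / (d_gy + d50_Gy)
    p[d_gy == Inf] <- p_max
    damaged <- stats::runif(nrow(ctr)) < p

    dapi <- matrix(background_mean, nr, nc)
    dapi <- stamp_blobs(dapi, ctr, dapi_amplitude, nucleus_sigma_px)
    gh2ax <- matrix(background_mean, nr, nc)
    if (any(damaged)) {
      gh2ax <- stamp_blobs(gh2ax, ctr[damaged, , drop = FALSE],
                           gh2ax_amplitude, nucleus_sigma_px * 0.9)
    }
    dapi <- quantize16(dapi + matrix(stats::rnorm(nr * nc, sd = background_sd),
                                     nr, nc))
    gh2ax <- quantize16(gh2ax + matrix(stats::rnorm(nr * nc,
                                                    sd = background_sd),
                                       nr, nc))

    # truth tiles follow the nucleus's pixel position (rounded centre), the
    # same raster a maxima detector sees
    tr <- pmin(floor(round(ctr[, 1]) / tile_px), ceiling(nr / tile_px) - 1)
    tc <- pmin(floor(round(ctr[, 2]) / tile_px), ceiling(nc / tile_px) - 1)
    tiles <- expand.grid(tile_row = 0:(ceiling(nr / tile_px) - 1),
                         tile_col = 0:(ceiling(nc / tile_px) - 1))
    truth <- tibble::as_tibble(tiles)
    key <- paste(tr, tc)
    truth$n_dapi <- as.integer(
      table(factor(key, paste(truth$tile_row, truth$tile_col))))
    truth$n_damage <- as.integer(
      table(factor(key[damaged], paste(truth$tile_row, truth$tile_col))))

    list(
      dapi = fluorescence_image(dapi, pixel_size_mm, "DAPI"),
      gh2ax = fluorescence_image(gh2ax, pixel_size_mm, "gH2AX"),
      truth = truth,
      centers = tibble::tibble(row = ctr[, 1], col = ctr[, 2],
                               dose_Gy = d_gy, p_damage = p,
                               damaged = damaged),
      params = list(seed = seed, n_nuclei = n_nuclei, tile_px = tile_px,
                    p_bg = p_bg, p_max = p_max, d50_Gy = d50_Gy,
                    pixel_size_mm = pixel_size_mm)
    )
  })
}

# minimum-distance rejection sampling on a coarse occupancy grid
place_nuclei <- function(n, nr, nc, min_dist, max_tries) {
  margin <- 4
  cell <- max(min_dist, 1)
  gr <- ceiling(nr / cell); gc <- ceiling(nc / cell)
  occupied <- vector("list", gr * gc)
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  total_budget <- max_tries * n
  while (placed < n) {
    if (tries >= total_budget) {
      stop("nucleus placement failed: density too high for min distance",
           call. = FALSE)
    }
    tries <- tries + 1L
    r <- stats::runif(1, margin, nr - 1 - margin)
    c <- stats::runif(1, margin, nc - 1 - margin)
    gi <- floor(r / cell); gj <- floor(c / cell)
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- gi + di; jj <- gj + dj
      if (ii < 0 || ii >= gr || jj < 0 || jj >= gc) next
      for (q in occupied[[ii + jj * gr + 1]]) {
        if ((q[1] - r)^2 + (q[2] - c)^2 < min_dist^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- c(r, c)
      k <- gi + gj * gr + 1
      occupied[[k]] <- c(occupied[[k]], list(c(r, c)))
    }
  }
  pts
}

stamp_blobs <- function(img, centres, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(3.5 * sigma)
  for (i in seq_len(nrow(centres))) {
    r <- centres[i, 1]; c <- centres[i, 2]
    r0 <- max(floor(r) - w, 0); r1 <- min(floor(r) + w, nr - 1)
    c0 <- max(floor(c) - w, 0); c1 <- min(floor(c) + w, nc - 1)
    rows <- r0:r1; cols <- c0:c1
    blob <- amplitude * exp(-(outer((rows - r)^2, (cols - c)^2, `+`)) /
                              (2 * sigma^2))
    img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + blob
  }
  img
}

quantize16 <- function(img) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  img
}
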