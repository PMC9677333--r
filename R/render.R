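#' Acquisition parameters for the synthetic detector
#'
#' @param n_frames Number of raw frames to render.
#' @param gain Detector counts per unit fluence.
#' @param poisson_noise Apply per-pixel per-frame Poisson counting noise.
#' @param salt_pepper_fraction Fraction of pixels per frame replaced by 0 or
#'   full scale (65535); must be in `[0, 1)`.
#' @param dark_amplitude Amplitude of the fixed detector dark pattern.
#' @param beam_sigma_frac Beam-profile Gaussian sigma as a fraction of the
#'   canvas size.
#' @param n_background_frames Frames in the companion dark and beam stacks.
#' @param seed Mandatory seed; every render is a pure function of
#'   (parameters, seed).
#' @return Object of class `acquisition_params`.
#' @export
acquisition_params <- function(n_frames = 30, gain = 1e4,
                               poisson_noise = TRUE,
                               salt_pepper_fraction = 0,
                               dark_amplitude = 100,
                               beam_sigma_frac = 0.8,
                               n_background_frames = 10,
                               seed) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("`seed` is mandatory for any stochastic render", call. = FALSE)
  }
  if (salt_pepper_fraction < 0 || salt_pepper_fraction >= 1) {
    stop("`salt_pepper_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (gain <= 0) stop("`gain` must be > 0", call. = FALSE)
  structure(
    list(n_frames = as.integer(n_frames), gain = gain,
         poisson_noise = isTRUE(poisson_noise),
         salt_pepper_fraction = salt_pepper_fraction,
         dark_amplitude = dark_amplitude,
         beam_sigma_frac = beam_sigma_frac,
         n_background_frames = as.integer(n_background_frames),
         seed = as.integer(seed)),
    class = "acquisition_params"
  )
}

# run code with a local RNG state seeded deterministically
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

beam_profile_matrix <- function(nr, nc, sigma_frac) {
  sr <- sigma_frac * nr; sc <- sigma_frac * nc
  pr <- exp(-((seq_len(nr) - (nr + 1) / 2)^2) / (2 * sr^2))
  pc <- exp(-((seq_len(nc) - (nc + 1) / 2)^2) / (2 * sc^2))
  outer(pr, pc)
}

dark_pattern_matrix <- function(nr, nc, amplitude, seed) {
  with_seed(seed, {
    grad <- outer(seq_len(nr) / nr, seq_len(nc) / nc, function(a, b) {
      0.5 + 0.25 * a + 0.25 * b
    })
    fixed <- matrix(stats::rnorm(nr * nc, sd = 0.05), nr, nc)
    amplitude * (grad + fixed)
  })
}

render_one_stack <- function(lambda, n, acq, role) {
  nr <- nrow(lambda); nc <- ncol(lambda)
  frames <- lapply(seq_len(n), function(k) {
    f <- if (acq$poisson_noise) {
      matrix(stats::rpois(nr * nc, pmax(lambda, 0)), nr, nc)
    } else {
      lambda
    }
    if (acq$salt_pepper_fraction > 0) {
      n_bad <- round(acq$salt_pepper_fraction * nr * nc)
      if (n_bad > 0) {
        idx <- sample.int(nr * nc, n_bad)
        f[idx] <- ifelse(stats::runif(n_bad) < 0.5, 0, 65535)
      }
    }
    f
  })
  frames
}

#' Render detector frame stacks from a transmission map
#'
#' Pixel counts follow `gain * beam_profile * transmission + dark_pattern`,
#' with optional Poisson noise per pixel per frame and salt-and-pepper
#' impulse corruption. Companion dark-only and beam-only stacks are produced
#' with the same conventions so that the correction chain
#' [correct_frames()] + [stack_median()] can be exercised end to end; with
#' noise off it recovers `gain * beam_profile * (transmission - 1)` exactly.
#'
#' @param transmission Relative-fluence matrix (e.g. from
#'   [transmission_map()]).
#' @param acq An [acquisition_params()] object (the seed lives here).
#' @param pixel_pitch_mm,frame_rate_hz,beam Metadata for the emitted stacks;
#'   pitch defaults to the transmission map's own.
#' @return List with elements `raw`, `dark`, `beam` (each a
#'   [frame_stack()]) and `ground_truth` (beam profile, dark pattern,
#'   transmission and the parameters used).
#' @export
render_frames <- function(transmission, acq,
                          pixel_pitch_mm = NULL, frame_rate_hz = 8.4,
                          beam = c(energy_MeV = 200, current_nA = 0.1)) {
  stopifnot(inherits(acq, "acquisition_params"))
  if (is.null(pixel_pitch_mm)) {
    pixel_pitch_mm <- attr(transmission, "pixel_pitch_mm")
    if (is.null(pixel_pitch_mm)) pixel_pitch_mm <- 0.05
  }
  nr <- nrow(transmission); nc <- ncol(transmission)
  profile <- acq$gain * beam_profile_matrix(nr, nc, acq$beam_sigma_frac)
  dark <- dark_pattern_matrix(nr, nc, acq$dark_amplitude, acq$seed)

  stacks <- with_seed(acq$seed + 1L, {
    list(
      raw = render_one_stack(profile * transmission + dark, acq$n_frames,
                             acq, "raw"),
      dark = render_one_stack(dark, acq$n_background_frames, acq, "dark"),
      beam = render_one_stack(profile + dark, acq$n_background_frames, acq,
                              "beam")
    )
  })
  mk <- function(frames, role) {
    frame_stack(frames, pixel_pitch_mm = pixel_pitch_mm,
                frame_rate_hz = frame_rate_hz, beam = beam, role = role)
  }
  list(
    raw = mk(stacks$raw, "raw"),
    dark = mk(stacks$dark, "dark"),
    beam = mk(stacks$beam, "beam"),
    ground_truth = list(
      transmission = transmission, beam_profile = profile,
      dark_pattern = dark, params = unclass(acq)
    )
  )
}

#' Synthetic radiograph of the irradiation collimator
#'
#' A bright disk (the circular aperture) on a near-zero background, rendered
#' through the same detector model; the true centre and radius are recorded.
#'
#' @param center_px True aperture centre `(row, col)` in 0-based pixels.
#' @param diameter_mm Aperture diameter in mm (the beamline uses 3 or 4 mm).
#' @param acq An [acquisition_params()].
#' @param shape_px Canvas shape.
#' @param pixel_pitch_mm Pixel pitch in mm.
#' @return List with `raw`, `dark`, `beam` stacks and `ground_truth`
#'   (`center_px`, `radius_px`, `diameter_mm`, aperture mask).
#' @export
make_collimator_radiograph <- function(center_px, diameter_mm = 3, acq,
                                       shape_px = c(256, 256),
                                       pixel_pitch_mm = 0.05) {
  nr <- shape_px[1]; nc <- shape_px[2]
  radius_px <- diameter_mm / 2 / pixel_pitch_mm
  dist <- sqrt(outer((seq_len(nr) - 1 - center_px[1])^2,
                     (seq_len(nc) - 1 - center_px[2])^2, `+`))
  aperture <- pmin(pmax(radius_px - dist + 0.5, 0), 1)
  transmission <- 0.02 + 0.98 * aperture
  attr(transmission, "pixel_pitch_mm") <- pixel_pitch_mm
  out <- render_frames(transmission, acq, pixel_pitch_mm = pixel_pitch_mm)
  out$ground_truth$center_px <- center_px
  out$ground_truth$radius_px <- radius_px
  out$ground_truth$diameter_mm <- diameter_mm
  out$ground_truth$aperture <- aperture
  out
}

#' Synthetic daily-QA dosimetry film
#'
#' Emulates the film behind the steel-ball phantom: a dark collimator-sized
#' irradiated spot with the bright, unirradiated shadow of the ball at its
#' centre.
#'
#' @param center_px Spot centre `(row, col)`, 0-based pixels.
#' @param collimator_radius_mm,ball_radius_mm Radii in mm.
#' @param shadow_offset_px Offset of the ball shadow relative to the spot
#'   centre (simulates a misaligned beam).
#' @param shape_px Canvas shape; `pixel_pitch_mm` the film scan pitch.
#' @param noise_sd Gaussian film-scan noise level.
#' @param seed Seed (mandatory when `noise_sd > 0`).
#' @return List with `film` (matrix with values between 0 and 1) and
#'   `ground_truth`.
#' @export
make_qa_film <- function(center_px, collimator_radius_mm = 1.5,
                         ball_radius_mm = 0.5,
                         shadow_offset_px = c(0, 0),
                         shape_px = c(256, 256), pixel_pitch_mm = 0.05,
                         noise_sd = 0.01, seed = NULL) {
  nr <- shape_px[1]; nc <- shape_px[2]
  disk_cov <- function(ctr, radius_px) {
    dist <- sqrt(outer((seq_len(nr) - 1 - ctr[1])^2,
                       (seq_len(nc) - 1 - ctr[2])^2, `+`))
    pmin(pmax(radius_px - dist + 0.5, 0), 1)
  }
  spot <- disk_cov(center_px, collimator_radius_mm / pixel_pitch_mm)
  shadow_c <- center_px + shadow_offset_px
  shadow <- disk_cov(shadow_c, ball_radius_mm / pixel_pitch_mm)
  film <- 0.95 - 0.75 * spot + 0.70 * shadow * spot
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` is mandatory when noise_sd > 0",
                            call. = FALSE)
    film <- film + with_seed(seed, matrix(stats::rnorm(nr * nc, sd = noise_sd),
                                          nr, nc))
  }
  film <- pmin(pmax(film, 0), 1)
  list(film = film,
       ground_truth = list(spot_center_px = center_px,
                           shadow_center_px = shadow_c,
                           collimator_radius_mm = collimator_radius_mm,
                           ball_radius_mm = ball_radius_mm,
                           pixel_pitch_mm = pixel_pitch_mm))
}
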