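#' Run configuration
#'
#' All workflow commands share one JSON-serialisable configuration holding
#' the detector defaults (0.05 mm pitch, 8.4 Hz), the named geometry-
#' specific dose-rate calibrations, the stage axis convention, the counting
#' prominences (DAPI 600, gammaH2AX 1400), the tile size (256 px) and QA
#' tolerance. `load_run_config()` reads a JSON file, merges it over the
#' defaults and validates it; `default_run_config()` returns the defaults.
#'
#' @return A validated named list of class `run_config`.
#' @export
default_run_config <- function() {
  validate_run_config(list(
    pixel_pitch_mm = 0.05,
    frame_rate_hz = 8.4,
    dose_rates_mGy_per_s = list(
      `grid-200MeV-0.1nA` = 1.98,
      `mouse-200MeV-0.1nA` = 2.875
    ),
    dose_geometry = "mouse-200MeV-0.1nA",
    axis_convention = "beamline-default",
    prominences = list(dapi = 600, gh2ax = 1400),
    tile_px = 256,
    min_cells = 5,
    detection_cnr = 4,
    min_contrast = 0.1,
    qa_tolerance_mm = 0.5
  ))
}

#' @rdname default_run_config
#' @param path Path to a JSON config file; fields present override the
#'   defaults.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  validate_run_config(cfg)
}

#' @rdname default_run_config
#' @param config A config list to validate.
#' @export
validate_run_config <- function(config) {
  check <- function(cond, msg) if (!cond) stop("config: ", msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  check(num1(config$pixel_pitch_mm) && config$pixel_pitch_mm > 0,
        "pixel_pitch_mm must be a positive number")
  check(num1(config$frame_rate_hz) && config$frame_rate_hz > 0,
        "frame_rate_hz must be a positive number")
  check(is.list(config$dose_rates_mGy_per_s) &&
          length(config$dose_rates_mGy_per_s) > 0 &&
          all(vapply(config$dose_rates_mGy_per_s,
                     function(x) num1(x) && x >= 0, logical(1))),
        "dose_rates_mGy_per_s must be a named list of non-negative numbers")
  check(config$dose_geometry %in% names(config$dose_rates_mGy_per_s),
        "dose_geometry must name an entry of dose_rates_mGy_per_s")
  check(is.character(config$axis_convention),
        "axis_convention must be a string")
  axis_convention(config$axis_convention)  # errors if unregistered
  pr <- config$prominences
  check(is.list(pr) && num1(pr$dapi) && num1(pr$gh2ax) &&
          pr$dapi > 0 && pr$gh2ax > 0,
        "prominences must provide positive dapi and gh2ax values")
  check(num1(config$tile_px) && config$tile_px >= 1 &&
          config$tile_px == round(config$tile_px),
        "tile_px must be a positive integer")
  check(num1(config$min_cells) && config$min_cells >= 0,
        "min_cells must be >= 0")
  check(num1(config$detection_cnr) && config$detection_cnr > 0,
        "detection_cnr must be positive")
  check(num1(config$min_contrast) && config$min_contrast > 0 &&
          config$min_contrast < 1, "min_contrast must be in (0, 1)")
  check(num1(config$qa_tolerance_mm) && config$qa_tolerance_mm > 0,
        "qa_tolerance_mm must be positive")
  structure(config, class = "run_config")
}

#' Dose rate of the configured geometry
#' @param config A `run_config`.
#' @param geometry Optional geometry name overriding `config$dose_geometry`.
#' @return Dose rate in mGy/s.
#' @export
config_dose_rate <- function(config, geometry = NULL) {
  g <- if (is.null(geometry)) config$dose_geometry else geometry
  dr <- config$dose_rates_mGy_per_s[[g]]
  if (is.null(dr)) stop("unknown dose geometry: ", g, call. = FALSE)
  dr
}
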