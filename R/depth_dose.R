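#' Analytic proton depth-dose stand-in
#'
#' A deliberately simple, non-physical parametrisation of a pristine proton
#' depth-dose curve for benchmarking the damage pipeline: the range in water
#' follows the power law `R(E) = alpha * E^p` (alpha = 0.022 mm/MeV^p,
#' p = 1.77, giving R(90 MeV) of about 63.5 mm), a range shifter subtracts
#' its water-equivalent thickness, and the curve is an entrance plateau
#' (complementary error function roll-off) plus a Gaussian Bragg peak at the
#' residual range, extended laterally as a collimated top-hat with Gaussian
#' penumbra and normalised to the prescribed peak dose.
#'
#' @param energy_MeV Beam energy, `> 0`.
#' @param range_shifter_wet_mm Water-equivalent thickness of the range
#'   shifter in mm (e.g. from [wet_of_slab()]).
#' @param field_radius_mm Collimated field radius in mm.
#' @param grid List with `shape_px` `(rows, cols)` and `pixel_size_mm`; the
#'   beam travels along the column axis, entering at column 0, centred on
#'   the row axis.
#' @param peak_dose_Gy Prescribed dose at the Bragg peak.
#' @param entrance_fraction Entrance-plateau level relative to the peak.
#' @param penumbra_mm Lateral penumbra sigma in mm.
#' @return Object of class `dose_map2d`: `dose` matrix (Gy), `pixel_size_mm`,
#'   `beam_axis = "col"`, `entry` (row, col), `residual_range_mm`,
#'   `upstream_stop` flag (TRUE when the shifter exceeds the full range, in
#'   which case the map is zero).
#' @export
analytic_depth_dose <- function(energy_MeV, range_shifter_wet_mm = 0,
                                field_radius_mm = 1.5,
                                grid = list(shape_px = c(64, 128),
                                            pixel_size_mm = 0.1),
                                peak_dose_Gy = 8,
                                entrance_fraction = 0.35,
                                penumbra_mm = 0.3) {
  if (energy_MeV <= 0) stop("`energy_MeV` must be > 0", call. = FALSE)
  alpha <- 0.022; p <- 1.77
  full_range <- alpha * energy_MeV^p
  residual <- full_range - range_shifter_wet_mm
  nr <- grid$shape_px[1]; nc <- grid$shape_px[2]
  px <- grid$pixel_size_mm
  upstream <- residual <= 0
  if (upstream) {
    warning("range shifter WET >= full range: all dose upstream of grid",
            call. = FALSE)
    dose <- matrix(0, nr, nc)
  } else {
    z <- (seq_len(nc) - 0.5) * px
    sigma_b <- 0.012 * full_range^0.96 + 0.3   # straggling-like width, mm
    erfc2 <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
    depth <- entrance_fraction * 0.5 * erfc2((z - residual) / (sqrt(2) * sigma_b)) +
      (1 - entrance_fraction) * exp(-(z - residual)^2 / (2 * sigma_b^2))
    r <- (seq_len(nr) - (nr + 1) / 2) * px
    lateral <- 0.5 * erfc2((abs(r) - field_radius_mm) /
                             (sqrt(2) * penumbra_mm))
    dose <- outer(lateral, depth)
    dose <- dose / max(dose) * peak_dose_Gy
  }
  structure(
    list(dose = dose, pixel_size_mm = px, beam_axis = "col",
         entry = c(row = (nr - 1) / 2, col = 0),
         residual_range_mm = residual, full_range_mm = full_range,
         peak_dose_Gy = peak_dose_Gy, upstream_stop = upstream),
    class = "dose_map2d"
  )
}

#' @export
print.dose_map2d <- function(x, ...) {
  cat(sprintf(
    "<dose_map2d> %d x %d px @ %.3g mm | residual range %.2f mm | peak %.3g Gy%s\n",
    nrow(x$dose), ncol(x$dose), x$pixel_size_mm, x$residual_range_mm,
    x$peak_dose_Gy, if (x$upstream_stop) " [upstream stop]" else ""))
  invisible(x)
}
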