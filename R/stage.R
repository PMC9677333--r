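#' Stage axis conventions
#'
#' The mapping between image `(row, col)` displacements and motor-stage
#' `(x, y)` axes is hardware-specific, so conventions are named, registered
#' entries: a 2 x 2 matrix `M` such that `c(x_mm, y_mm) = M %*% c(d_row,
#' d_col) * pitch`. The built-in `"beamline-default"` maps `x` to `+col` and
#' `y` to `-row` (screen up = stage up).
#'
#' @param id Convention identifier.
#' @param matrix A 2 x 2 numeric matrix.
#' @return `register_axis_convention()` returns `id` invisibly;
#'   `axis_convention()` returns the matrix.
#' @export
register_axis_convention <- function(id, matrix) {
  if (!is.matrix(matrix) || !all(dim(matrix) == c(2, 2))) {
    stop("`matrix` must be 2 x 2", call. = FALSE)
  }
  assign(id, matrix, envir = .axis_registry)
  invisible(id)
}

#' @rdname register_axis_convention
#' @export
axis_convention <- function(id) {
  if (!exists(id, envir = .axis_registry, inherits = FALSE)) {
    stop(sprintf("unknown axis convention '%s' (registered: %s)", id,
                 paste(ls(.axis_registry), collapse = ", ")), call. = FALSE)
  }
  get(id, envir = .axis_registry, inherits = FALSE)
}

.axis_registry <- new.env(parent = emptyenv())
assign("beamline-default", rbind(c(0, 1), c(-1, 0)), envir = .axis_registry)
assign("beamline-identity", diag(2), envir = .axis_registry)

#' Lateral stage shift that brings the target onto the beam isocenter
#'
#' @param target_radio_px Target position `(row, col)` in radiograph pixels
#'   (0-based, subpixel allowed).
#' @param isocenter An [detect_isocenter()] result or a `(row, col)` vector.
#' @param pitch_mm Pixel pitch in mm.
#' @param convention Registered axis-convention id.
#' @return Object of class `stage_target` with `x_mm`, `y_mm` and the
#'   convention id.
#' @export
stage_shift <- function(target_radio_px, isocenter, pitch_mm = 0.05,
                        convention = "beamline-default") {
  m <- axis_convention(convention)
  ctr <- if (inherits(isocenter, "isocenter")) isocenter$center else isocenter
  d <- c(target_radio_px[1] - ctr[1], target_radio_px[2] - ctr[2])
  v <- as.numeric(m %*% d) * pitch_mm
  structure(list(x_mm = v[1], y_mm = v[2], convention = convention),
            class = "stage_target")
}

#' @export
print.stage_target <- function(x, ...) {
  cat(sprintf("<stage_target> x = %+.4f mm, y = %+.4f mm [%s]\n",
              x$x_mm, x$y_mm, x$convention))
  invisible(x)
}

#' Spread of target coordinates across observers
#'
#' The variability statistic is the mean Euclidean distance of the targets
#' from their centroid, with the population standard deviation of those
#' distances alongside.
#'
#' @param targets A list of [stage_shift()] results or a data frame with
#'   columns `x_mm`, `y_mm`; at least 2 targets.
#' @return One-row tibble with `spread_mm`, `sd_mm`, `n`.
#' @export
target_spread <- function(targets) {
  if (is.list(targets) && !is.data.frame(targets) &&
      all(vapply(targets, inherits, logical(1), "stage_target"))) {
    targets <- tibble::tibble(
      x_mm = vapply(targets, `[[`, numeric(1), "x_mm"),
      y_mm = vapply(targets, `[[`, numeric(1), "y_mm")
    )
  }
  targets <- as.data.frame(targets)
  if (nrow(targets) < 2) stop("need at least 2 targets", call. = FALSE)
  cx <- mean(targets$x_mm); cy <- mean(targets$y_mm)
  d <- sqrt((targets$x_mm - cx)^2 + (targets$y_mm - cy)^2)
  tibble::tibble(spread_mm = mean(d), sd_mm = sd_pop(d), n = nrow(targets))
}
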