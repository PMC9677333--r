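#' Isocentric similarity transform in 2D
#'
#' Maps plan pixel coordinates to radiograph pixel coordinates as
#' `q = s * R(theta) * p + t` in `(row, col)` coordinates, where
#' `R(theta) = [[cos, sin], [-sin, cos]]` (positive angles rotate the
#' column axis toward the row axis, i.e. clockwise on screen with the row
#' axis pointing down). Reflections are outside the family.
#'
#' @param scale Isocentric scale factor, `> 0`.
#' @param rotation_deg Rotation angle in degrees.
#' @param t_row,t_col Translation in pixels.
#' @return Object of class `similarity2d`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 t_row = 0, t_col = 0) {
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  structure(
    list(scale = scale, rotation_deg = rotation_deg,
         t_row = t_row, t_col = t_col,
         rms_residual = NA_real_, n = NA_integer_),
    class = "similarity2d"
  )
}

#' @export
print.similarity2d <- function(x, ...) {
  cat(sprintf(
    "<similarity2d> s = %.6g, theta = %.6g deg, t = (%.6g, %.6g) px",
    x$scale, x$rotation_deg, x$t_row, x$t_col))
  if (!is.na(x$rms_residual)) {
    cat(sprintf(" | rms %.3g px on %d landmark(s)", x$rms_residual, x$n))
  }
  cat("\n")
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param transform A `similarity2d`.
#' @param points Matrix/data frame with columns `(row, col)` (0-based px) or
#'   a length-2 vector.
#' @param inverse Apply the inverse mapping instead.
#' @return Matrix with columns `row`, `col`.
#' @export
transform_points <- function(transform, points, inverse = FALSE) {
  stopifnot(inherits(transform, "similarity2d"))
  p <- as_point_matrix(points)
  th <- transform$rotation_deg * pi / 180
  s <- transform$scale
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  tt <- c(transform$t_row, transform$t_col)
  if (!inverse) {
    out <- s * (p %*% t(rot))
    out[, 1] <- out[, 1] + tt[1]
    out[, 2] <- out[, 2] + tt[2]
  } else {
    q <- sweep(p, 2, tt)
    out <- (q %*% rot) / s
  }
  colnames(out) <- c("row", "col")
  out
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (ncol(p) != 2) stop("points must have two columns (row, col)",
                         call. = FALSE)
  p
}

#' Invert a similarity transform
#' @param transform A `similarity2d`.
#' @return The inverse `similarity2d`.
#' @export
invert_transform <- function(transform) {
  inv_t <- transform_points(transform, c(0, 0), inverse = TRUE)
  similarity_transform(1 / transform$scale, -transform$rotation_deg,
                       inv_t[1], inv_t[2])
}

#' Least-squares fit of the plan-to-radiograph similarity transform
#'
#' Closed-form estimate of the uniform scale, rotation and translation
#' minimising the sum of squared landmark residuals
#' `sum || s R p_i + t - q_i ||^2`: both point sets are centred on their
#' centroids and the scale/angle follow from the complex cross-covariance,
#' which excludes reflections by construction. Exact (zero-residual) recovery
#' on consistent pairs for any `n >= 2`.
#'
#' @param pairs Landmark pairs: tibble/data frame with columns
#'   `plan_row, plan_col, radio_row, radio_col` (0-based pixels), `n >= 2`.
#' @return A `similarity2d` with `rms_residual` (px) and `n` filled in.
#' @export
fit_similarity <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("plan_row", "plan_col", "radio_row", "radio_col")
  if (!all(need %in% names(pairs))) {
    stop("pairs needs columns plan_row, plan_col, radio_row, radio_col",
         call. = FALSE)
  }
  n <- nrow(pairs)
  if (n < 2) stop("need at least 2 landmark pairs", call. = FALSE)
  p <- complex(real = pairs$plan_col, imaginary = pairs$plan_row)
  q <- complex(real = pairs$radio_col, imaginary = pairs$radio_row)
  pm <- mean(p); qm <- mean(q)
  pc <- p - pm; qc <- q - qm
  denom <- sum(Mod(pc)^2)
  if (denom == 0) {
    stop("degenerate landmark configuration: plan points coincide",
         call. = FALSE)
  }
  a <- sum(qc * Conj(pc)) / denom
  if (Mod(a) == 0) {
    stop("degenerate landmark configuration: radiograph points coincide",
         call. = FALSE)
  }
  b <- qm - a * pm
  tf <- similarity_transform(Mod(a), Arg(a) * 180 / pi, Im(b), Re(b))
  fitted <- transform_points(tf, cbind(pairs$plan_row, pairs$plan_col))
  res <- sqrt(mean((fitted[, 1] - pairs$radio_row)^2 +
                     (fitted[, 2] - pairs$radio_col)^2))
  tf$rms_residual <- res
  tf$n <- n
  tf
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted similarity transform
#' @param x A `similarity2d`.
#' @param ... Unused.
#' @return One row per parameter with columns `term`, `estimate`.
#' @export
tidy.similarity2d <- function(x, ...) {
  tibble::tibble(
    term = c("scale", "rotation_deg", "t_row", "t_col"),
    estimate = c(x$scale, x$rotation_deg, x$t_row, x$t_col)
  )
}

#' @rdname tidy.similarity2d
#' @return `glance()`: a one-row tibble with `rms_residual` (px) and
#'   `n_landmarks`.
#' @export
glance.similarity2d <- function(x, ...) {
  tibble::tibble(rms_residual = x$rms_residual, n_landmarks = x$n)
}

#' Map a plan target into radiograph coordinates
#'
#' @param transform A `similarity2d`.
#' @param target_plan_px Target point `(row, col)` in plan pixels.
#' @param inverse Map from radiograph back to plan instead.
#' @return Named numeric `(row, col)` in the destination frame.
#' @export
map_target <- function(transform, target_plan_px, inverse = FALSE) {
  out <- transform_points(transform, target_plan_px, inverse = inverse)
  c(row = out[1, 1], col = out[1, 2])
}

#' Read / write landmark-pair CSV files
#'
#' Columns: `label, plan_row, plan_col, radio_row, radio_col` (0-based px).
#'
#' @param path File path.
#' @return A tibble of landmark pairs.
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plan_row", "plan_col", "radio_row", "radio_col")
  if (!all(need %in% names(df))) {
    stop("landmark csv needs columns plan_row, plan_col, radio_row, radio_col",
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_landmarks_csv
#' @param pairs Tibble of landmark pairs.
#' @export
write_landmarks_csv <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}
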