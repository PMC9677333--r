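#' Rectangular region of interest
#'
#' ROI bounds are 0-based half-open pixel ranges `[row0, row1) x [col0, col1)`
#' in the package-wide `(row, col)` convention.
#'
#' @param row0,row1,col0,col1 Integer bounds, half-open, 0-based.
#' @param label Optional character label.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(0, 10, 0, 10, "background")
#' @export
roi_spec <- function(row0, row1, col0, col1, label = "") {
  if (row1 <= row0 || col1 <= col0) {
    stop("ROI must be non-empty (row1 > row0 and col1 > col0)", call. = FALSE)
  }
  if (row0 < 0 || col0 < 0) stop("ROI bounds must be >= 0", call. = FALSE)
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1),
                 label = label),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> '%s' rows [%d, %d) cols [%d, %d)\n",
              x$label, x$row0, x$row1, x$col0, x$col1))
  invisible(x)
}

roi_check_bounds <- function(roi, image) {
  if (roi$row1 > nrow(image) || roi$col1 > ncol(image)) {
    stop(sprintf("ROI '%s' exceeds image bounds (%d x %d)",
                 roi$label, nrow(image), ncol(image)), call. = FALSE)
  }
  invisible(roi)
}

#' Extract the pixels of an ROI from an image matrix
#' @param image Numeric matrix.
#' @param roi An [roi_spec()].
#' @return Numeric matrix of the ROI pixels.
#' @export
roi_extract <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  roi_check_bounds(roi, image)
  image[(roi$row0 + 1L):roi$row1, (roi$col0 + 1L):roi$col1, drop = FALSE]
}

roi_overlaps <- function(a, b) {
  a$row0 < b$row1 && b$row0 < a$row1 && a$col0 < b$col1 && b$col0 < a$col1
}

#' Read / write ROI and line-pair grid specifications as CSV
#'
#' The CSV columns are `label,row0,row1,col0,col1` with an optional
#' `freq_lp_per_mm` column for line-pair groups.
#'
#' @param path File path.
#' @return `read_roi_csv()` returns a tibble; rows can be turned into
#'   [roi_spec()] objects with [as_roi_list()].
#' @export
read_roi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "row0", "row1", "col0", "col1")
  if (!all(need %in% names(df))) {
    stop("ROI csv must have columns label,row0,row1,col0,col1", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_roi_csv
#' @param rois A tibble/data.frame of ROI rows.
#' @export
write_roi_csv <- function(rois, path) {
  utils::write.csv(rois, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_roi_csv
#' @export
as_roi_list <- function(rois) {
  purrr::pmap(
    rois[, c("label", "row0", "row1", "col0", "col1")],
    function(label, row0, row1, col0, col1) {
      roi_spec(row0, row1, col0, col1, label)
    }
  )
}
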