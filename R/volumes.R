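#' Synthetic brain label volume with correlated intensity volume
#'
#' A nested pair of ellipsoids on an empty background: label 1 (brain)
#' contains label 2 (hippocampal region) strictly in its interior. The
#' companion intensity volume assigns each label a base intensity plus
#' seeded Gaussian texture, emulating a reconstructed CBCT around the skull.
#'
#' @param shape 3D shape `(rows, cols, slices)`; at least 25 sagittal
#'   slices (third index).
#' @param seed Mandatory seed for the intensity texture.
#' @return List with `labels` (integer array in `{0, 1, 2}`), `intensity`
#'   (numeric array) and `ground_truth` (ellipsoid parameters and per-label
#'   voxel counts).
#' @export
make_label_volume <- function(shape = c(64, 64, 64), seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (length(shape) != 3) stop("`shape` must have length 3", call. = FALSE)
  if (shape[3] < 25) stop("need at least 25 sagittal slices", call. = FALSE)
  ctr <- (shape + 1) / 2
  brain_ax <- 0.38 * shape
  hippo_ax <- 0.14 * shape
  hippo_ctr <- ctr + c(0.10, 0.08, 0) * shape

  rr <- seq_len(shape[1]); cc <- seq_len(shape[2]); ss <- seq_len(shape[3])
  coords <- list(rr, cc, ss)
  ell <- function(centre, ax) {
    d1 <- ((rr - centre[1]) / ax[1])^2
    d2 <- ((cc - centre[2]) / ax[2])^2
    d3 <- ((ss - centre[3]) / ax[3])^2
    outer(outer(d1, d2, `+`), d3, `+`) <= 1
  }
  brain <- ell(ctr, brain_ax)
  hippo <- ell(hippo_ctr, hippo_ax)
  hippo <- hippo & brain  # construction invariant: hippocampus inside brain
  labels <- array(0L, shape)
  labels[brain] <- 1L
  labels[hippo] <- 2L

  intensity <- with_seed(seed, {
    base <- array(100, shape)
    base[brain] <- 600
    base[hippo] <- 800
    base + array(stats::rnorm(prod(shape), sd = 40), shape)
  })
  list(
    labels = labels, intensity = intensity,
    ground_truth = list(
      brain_centre = ctr, brain_axes = brain_ax,
      hippo_centre = hippo_ctr, hippo_axes = hippo_ax,
      voxels = c(background = sum(labels == 0L), brain = sum(labels == 1L),
                 hippocampus = sum(labels == 2L)),
      seed = seed
    )
  )
}
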