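#' Sagittal maximum-intensity projection
#'
#' Per-pixel maximum across a slab of sagittal planes (the third array
#' index). Slab sizes of 15 to 25 slices are the intended operating range;
#' a warning is issued outside it.
#'
#' @param volume 3D numeric array `(row, col, slice)`.
#' @param slice_range Integer vector of slice indices (1-based as in R
#'   arrays).
#' @return 2D matrix of per-pixel maxima.
#' @export
mip_sagittal <- function(volume, slice_range) {
  if (length(dim(volume)) != 3) stop("`volume` must be a 3D array",
                                     call. = FALSE)
  if (length(slice_range) == 0) stop("empty slice range", call. = FALSE)
  if (any(slice_range < 1) || any(slice_range > dim(volume)[3])) {
    stop("slice range outside volume", call. = FALSE)
  }
  if (length(slice_range) < 15 || length(slice_range) > 25) {
    warning("slab of ", length(slice_range),
            " slices is outside the recommended 15-25 range", call. = FALSE)
  }
  Reduce(pmax, lapply(slice_range, function(k) volume[, , k]))
}

#' Label projection with hippocampus priority
#'
#' Projects a `{0 background, 1 brain, 2 hippocampal region}` label volume
#' along the sagittal axis; each output pixel takes the highest-priority
#' label present in the slab (2 beats 1 beats 0).
#'
#' @param label_volume 3D integer array with values in `{0, 1, 2}`.
#' @param slice_range Slice indices (1-based).
#' @return 2D integer label matrix.
#' @export
project_labels <- function(label_volume, slice_range) {
  if (!all(label_volume %in% c(0, 1, 2))) {
    stop("labels must be in {0, 1, 2}", call. = FALSE)
  }
  out <- suppressWarnings(mip_sagittal(label_volume, slice_range))
  storage.mode(out) <- "integer"
  out
}

#' Jaccard overlap coefficient of two binary masks
#'
#' `|A intersect B| / |A union B|`; two empty masks agree perfectly, so the
#' empty-union case is defined as 1.
#'
#' @param mask_a,mask_b Logical/0-1 matrices of identical shape.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("mask shapes differ", call. = FALSE)
  }
  a <- mask_a != 0; b <- mask_b != 0
  uni <- sum(a | b)
  if (uni == 0) return(1)
  sum(a & b) / uni
}

#' Majority vote of binary masks
#'
#' A pixel is set when it is set in more than half of the input masks. The
#' count must be odd (ties would be ambiguous) and at least 3.
#'
#' @param masks List of logical/0-1 matrices of identical shape.
#' @return Logical matrix.
#' @export
majority_vote <- function(masks) {
  n <- length(masks)
  if (n < 3 || n %% 2 == 0) {
    stop("need an odd number of masks, at least 3", call. = FALSE)
  }
  shp <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), shp), logical(1)))) {
    stop("mask shapes differ", call. = FALSE)
  }
  votes <- Reduce(`+`, lapply(masks, function(m) (m != 0) * 1L))
  votes > n / 2
}

#' Observer-agreement study on projected treatment plans
#'
#' Inter-observer agreement: per animal, the observers' target-label masks
#' (first repeat of each observer) are majority-voted into a reference `F`
#' and each observer is scored by `J_i = jaccard(A_i, F)`. Intra-observer
#' agreement applies the same formula to one observer's repeated plans,
#' with the majority of that observer's repeats as the reference. Summary
#' rows report mean and population standard deviation.
#'
#' @param plans Tibble with columns `animal`, `observer`, `rep` and a
#'   list-column `plan` of 2D label matrices (labels `{0, 1, 2}`).
#' @param target_label Label defining the target mask (default 2, the
#'   projected hippocampal region).
#' @return Object of class `agreement_report`: tibbles `inter` (animal,
#'   observer, jaccard), `intra` (animal, observer, rep, jaccard) and
#'   `summary` (kind, mean, sd, n).
#' @export
agreement_study <- function(plans, target_label = 2) {
  plans <- tibble::as_tibble(plans)
  need <- c("animal", "observer", "rep", "plan")
  if (!all(need %in% names(plans))) {
    stop("plans needs columns animal, observer, rep, plan", call. = FALSE)
  }
  masks <- purrr::map(plans$plan, function(p) p == target_label)
  plans$mask <- masks

  inter <- plans |>
    dplyr::group_by(.data$animal, .data$observer) |>
    dplyr::slice_min(.data$rep, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$animal) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        stop("insufficient replicates: need >= 3 observers per animal",
             call. = FALSE)
      }
      f <- majority_vote(df$mask)
      tibble::tibble(observer = df$observer,
                     jaccard = vapply(df$mask, jaccard, numeric(1), f))
    }) |>
    dplyr::ungroup()

  intra <- plans |>
    dplyr::group_by(.data$animal, .data$observer) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 0) {
        return(tibble::tibble(rep = integer(0), jaccard = numeric(0)))
      }
      f <- majority_vote(df$mask)
      tibble::tibble(rep = df$rep,
                     jaccard = vapply(df$mask, jaccard, numeric(1), f))
    }) |>
    dplyr::ungroup()

  summarise_j <- function(j, kind) {
    tibble::tibble(kind = kind, mean = mean(j), sd = sd_pop(j),
                   n = length(j))
  }
  summary <- dplyr::bind_rows(
    if (nrow(inter)) summarise_j(inter$jaccard, "inter-observer"),
    if (nrow(intra)) summarise_j(intra$jaccard, "intra-observer")
  )
  structure(list(inter = inter, intra = intra, summary = summary),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  print(x$summary)
  invisible(x)
}

#' Synthetic observer plans from a truth label image
#'
#' Emulates inter- and intra-observer variation by perturbing a truth label
#' image: each simulated plan shifts the target mask by a random subpixel-
#' rounded offset and dilates or erodes it by a random radius. Intended for
#' exercising [agreement_study()] with known overlap structure.
#'
#' @param truth_plan 2D label matrix (labels `{0, 1, 2}`).
#' @param n_observers,n_reps Study design.
#' @param seed Mandatory seed.
#' @param max_shift_px Maximum |shift| per axis in pixels.
#' @param max_morph_px Maximum dilation (+) / erosion (-) radius.
#' @param intra_scale Factor < 1 shrinking the perturbations of repeats by
#'   the same observer relative to between-observer perturbations.
#' @param target_label Label to perturb.
#' @return Tibble with columns `animal` (always 1), `observer`, `rep`,
#'   `plan`.
#' @export
make_observer_plans <- function(truth_plan, n_observers = 3, n_reps = 3,
                                seed, max_shift_px = 3, max_morph_px = 2,
                                intra_scale = 0.5, target_label = 2) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  with_seed(seed, {
    rows <- list()
    for (ob in seq_len(n_observers)) {
      base_shift <- round(stats::runif(2, -max_shift_px, max_shift_px))
      base_morph <- sample(-max_morph_px:max_morph_px, 1)
      for (rp in seq_len(n_reps)) {
        jitter <- round(intra_scale *
                          stats::runif(2, -max_shift_px, max_shift_px))
        morph <- base_morph +
          sample(-1:1, 1, prob = c(0.25, 0.5, 0.25))
        plan <- perturb_plan(truth_plan, base_shift + jitter, morph,
                             target_label)
        rows[[length(rows) + 1]] <- tibble::tibble(
          animal = 1L, observer = ob, rep = rp, plan = list(plan))
      }
    }
    dplyr::bind_rows(rows)
  })
}

perturb_plan <- function(plan, shift, morph, target_label) {
  mask <- plan == target_label
  mask <- shift_mask(mask, shift[1], shift[2])
  if (morph > 0) {
    mask <- EBImage::dilate(mask, EBImage::makeBrush(2 * morph + 1, "disc")) > 0
  } else if (morph < 0) {
    mask <- EBImage::erode(mask, EBImage::makeBrush(-2 * morph + 1, "disc")) > 0
  }
  out <- plan
  out[out == target_label] <- 1L   # former target reverts to brain
  out[mask] <- target_label
  out
}

shift_mask <- function(mask, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr
  ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- mask[src_r[ok_r], src_c[ok_c]]
  out
}
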