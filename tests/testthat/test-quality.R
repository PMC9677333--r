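test_that("SNR follows the population-sigma convention", {
  rad <- radiograph(matrix(c(1, 3, 0, 0, 4, 4), 1, 6))
  expect_equal(compute_snr(rad, roi_spec(0, 1, 0, 2)), 2.0)   # {1,3}
  expect_equal(compute_snr(rad, roi_spec(0, 1, 2, 6)), 1.0)   # {0,0,4,4}
  expect_identical(compute_snr(rad, roi_spec(0, 1, 4, 6)), Inf) # constant
})

test_that("CNR is signed and uses the background sigma", {
  img <- matrix(100, 10, 10)
  img[1:5, 1:5] <- 120
  # background with mean 100 and population sd exactly 10 over 25 px
  img[6:10, 6:10] <- 100 + 10 * sqrt(25 / 24) * c(rep(1, 12), rep(-1, 12), 0)
  rad <- radiograph(img)
  a <- roi_spec(0, 5, 0, 5); b <- roi_spec(5, 10, 5, 10)
  expect_equal(compute_cnr(rad, a, b), 2.0)
  expect_equal(compute_cnr(rad, b, a), -Inf)  # roles swapped, constant bg
  # identical statistics in both regions -> 0 (rows of alternating columns)
  img2 <- matrix(rep(c(90, 110), each = 10), 10, 10)
  rad2 <- radiograph(img2)
  expect_equal(compute_cnr(rad2, roi_spec(0, 5, 0, 10),
                           roi_spec(5, 10, 0, 10)), 0)
  expect_error(compute_cnr(rad, a, roi_spec(0, 3, 0, 3)), "disjoint")
})

test_that("adding a constant offset changes SNR as (S+c)/sigma but not CNR", {
  set.seed(3)
  img <- matrix(rnorm(400, 100, 5), 20, 20)
  img[1:10, 1:10] <- img[1:10, 1:10] + 40
  a <- roi_spec(0, 10, 0, 10); b <- roi_spec(10, 20, 10, 20)
  r0 <- radiograph(img); r1 <- radiograph(img + 25)
  expect_equal(compute_cnr(r1, a, b), compute_cnr(r0, a, b))
  s <- mean(roi_extract(img, b))
  sig <- sqrt(mean((roi_extract(img, b) - s)^2))
  expect_equal(compute_snr(r1, b), (s + 25) / sig)
  expect_false(isTRUE(all.equal(compute_snr(r1, b), compute_snr(r0, b))))
})

test_that("edge FWHM recovers 2.3548 sigma within 2 percent", {
  for (sigma in c(2, 3, 5, 7, 10)) {
    rad <- gaussian_peak_radiograph(sigma)
    got <- edge_fwhm(rad, roi_spec(0, 40, 0, 256), "vertical")
    expect_equal(got, 2 * sqrt(2 * log(2)) * sigma * 0.05,
                 tolerance = 0.02)
  }
  # sigma = 0.2 mm at 0.05 mm pitch -> 0.471 mm
  rad <- gaussian_peak_radiograph(4)
  expect_equal(edge_fwhm(rad, roi_spec(0, 40, 0, 256), "vertical"),
               0.471, tolerance = 0.02)
})

test_that("edge FWHM errors without enhancement", {
  step <- matrix(rep(c(rep(50, 128), rep(100, 128)), each = 40), 40, 256)
  expect_error(edge_fwhm(radiograph(step), roi_spec(0, 40, 0, 256)),
               "no edge enhancement")
  flat <- radiograph(matrix(100, 40, 256))
  expect_error(edge_fwhm(flat, roi_spec(0, 40, 0, 256)),
               "no edge enhancement")
  expect_error(edge_fwhm(gaussian_peak_radiograph(3, n_lines = 10),
                         roi_spec(0, 10, 0, 256)), "20 profile lines")
})

make_square_grid <- function(freqs, pitch = 0.05, n_rows = 30,
                             len_px = 140, lo = 50, hi = 150) {
  rows <- list(); spec <- list()
  img <- NULL
  for (i in seq_along(freqs)) {
    period_px <- 1 / freqs[i] / pitch
    x <- seq_len(len_px) - 1
    prof <- ifelse((x %% period_px) < period_px / 2, hi, lo)
    img <- rbind(img, matrix(prof, n_rows, len_px, byrow = TRUE))
    spec[[i]] <- tibble::tibble(
      label = paste0("g", i), row0 = (i - 1) * n_rows, row1 = i * n_rows,
      col0 = 0, col1 = len_px, freq_lp_per_mm = freqs[i])
  }
  img <- rbind(img, matrix((lo + hi) / 2, n_rows, len_px))
  spec[[length(spec) + 1]] <- tibble::tibble(
    label = "background", row0 = length(freqs) * n_rows,
    row1 = (length(freqs) + 1) * n_rows, col0 = 0, col1 = len_px,
    freq_lp_per_mm = 0)
  list(rad = radiograph(img), spec = dplyr::bind_rows(spec))
}

test_that("unblurred bar groups resolve to the highest frequency", {
  g <- make_square_grid(c(0.6, 1.5, 3, 6))
  res <- line_pair_resolution(g$rad, g$spec)
  expect_equal(res$resolved_lp_per_mm, 6.0)
  expect_false(res$warning)
  expect_true(all(res$groups$resolved))
})

test_that("measured group contrast matches a brute-force convolution oracle", {
  freqs <- c(0.6, 1.5, 3, 6)
  g <- make_square_grid(freqs)
  for (sigma_px in c(1.2, 1.67, 2.5)) {
    img <- g$rad$image
    blurred <- t(apply(img, 1, oracle_blur_profile, sigma = sigma_px))
    res <- line_pair_resolution(radiograph(blurred), g$spec)
    for (i in seq_along(freqs)) {
      prof <- blurred[g$spec$row0[i] + 1, (g$spec$col0[i] + 1):g$spec$col1[i]]
      period_px <- 1 / freqs[i] / 0.05
      nb <- max(2, round(period_px))
      phase <- ((seq_along(prof) - 1) %% period_px) / period_px
      bins <- vapply(split(prof, pmin(floor(phase * nb), nb - 1)), mean,
                     numeric(1))
      oracle_c <- (max(bins) - min(bins)) / (max(bins) + min(bins))
      expect_equal(res$groups$contrast[i], oracle_c, tolerance = 1e-10)
    }
  }
})

test_that("resolution is monotone non-increasing in blur", {
  g <- make_square_grid(c(0.6, 1.5, 3, 6))
  prev <- Inf
  for (sigma_px in c(0.5, 1.5, 3, 6, 12)) {
    blurred <- t(apply(g$rad$image, 1, oracle_blur_profile, sigma = sigma_px))
    res <- line_pair_resolution(radiograph(blurred), g$spec)
    expect_lte(res$resolved_lp_per_mm, prev)
    prev <- res$resolved_lp_per_mm
  }
})

test_that("pure noise resolves nothing and warns via the flag", {
  set.seed(9)
  g <- make_square_grid(c(0.6, 3, 6))
  noise <- radiograph(matrix(rnorm(prod(dim(g$rad$image)), 100, 5),
                             nrow(g$rad$image)))
  res <- line_pair_resolution(noise, g$spec)
  expect_equal(res$resolved_lp_per_mm, 0)
  expect_true(res$warning)
})

test_that("detectability table scales as sqrt(n) under Poisson noise", {
  nr <- 64; nc <- 64
  tm <- matrix(0.9, nr, nc)
  dist <- sqrt(outer((1:nr - 20)^2, (1:nc - 20)^2, `+`))
  tm[dist < 5] <- 1.0
  attr(tm, "pixel_pitch_mm") <- 0.05
  # many background frames, as in the imaging workflow, so the fixed
  # correction residual does not cap the sqrt(n) gain of raw-frame stacking
  acq <- acquisition_params(n_frames = 32, gain = 3e3, poisson_noise = TRUE,
                            dark_amplitude = 0, beam_sigma_frac = 50,
                            n_background_frames = 300, seed = 21)
  r <- render_frames(tm, acq)
  corrected <- correct_frames(r$raw, r$dark, r$beam)
  features <- tibble::tibble(
    feature = "hole", size_mm = 0.5,
    roi_a = list(roi_spec(16, 23, 16, 23)),
    roi_b = list(roi_spec(40, 60, 40, 60))
  )
  tbl <- detectability_vs_frames(corrected, features,
                                 dose_rate_mGy_per_s = 1.98)
  expect_equal(tbl$n_frames, 1:32)
  expect_equal(tbl$time_s, (1:32) / 8.4)
  expect_equal(tbl$dose_mGy, 1.98 * (1:32) / 8.4)
  cnr8 <- tbl$cnr[tbl$n_frames == 8]
  cnr32 <- tbl$cnr[tbl$n_frames == 32]
  expect_gt(cnr32, cnr8)
  expect_equal(cnr32 / cnr8, 2, tolerance = 0.25)
})

test_that("noiseless frames make the smallest feature constant from n = 1", {
  tm <- matrix(0.9, 32, 32)
  tm[10:14, 10:14] <- 1.0
  attr(tm, "pixel_pitch_mm") <- 0.05
  acq <- acquisition_params(n_frames = 4, poisson_noise = FALSE,
                            dark_amplitude = 0, beam_sigma_frac = 50,
                            seed = 1)
  r <- render_frames(tm, acq)
  corrected <- correct_frames(r$raw, r$dark, r$beam)
  features <- tibble::tibble(
    feature = "sq", size_mm = 0.25,
    roi_a = list(roi_spec(9, 14, 9, 14)),
    roi_b = list(roi_spec(20, 30, 20, 30))
  )
  tbl <- detectability_vs_frames(corrected, features)
  expect_true(all(tbl$smallest_resolved_feature_mm == 0.25))
})
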