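square_pairs <- function(tf) {
  p <- rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0))
  q <- transform_points(tf, p)
  tibble::tibble(plan_row = p[, 1], plan_col = p[, 2],
                 radio_row = q[, 1], radio_col = q[, 2])
}

test_that("similarity fit recovers exact transforms with zero residual", {
  id <- fit_similarity(square_pairs(similarity_transform()))
  expect_tf_equal(id, 1, 0, 0, 0)
  expect_lt(id$rms_residual, 1e-9)

  tr <- fit_similarity(square_pairs(similarity_transform(1, 0, 3, -4)))
  expect_tf_equal(tr, 1, 0, 3, -4)
  expect_lt(tr$rms_residual, 1e-9)

  sr <- fit_similarity(square_pairs(similarity_transform(2, 90, 0, 0)))
  expect_tf_equal(sr, 2, 90, 0, 0)
  expect_lt(sr$rms_residual, 1e-9)
})

test_that("residual is ~0 on consistent pairs for any n >= 2", {
  set.seed(14)
  for (n in c(2, 3, 5, 9)) {
    tf <- similarity_transform(runif(1, 0.5, 2), runif(1, -30, 30),
                               runif(1, -20, 20), runif(1, -20, 20))
    p <- matrix(runif(2 * n, 0, 100), n, 2)
    q <- transform_points(tf, p)
    fit <- fit_similarity(tibble::tibble(
      plan_row = p[, 1], plan_col = p[, 2],
      radio_row = q[, 1], radio_col = q[, 2]))
    expect_lt(fit$rms_residual, 1e-9)
    expect_tf_equal(fit, tf$scale, tf$rotation_deg, tf$t_row, tf$t_col,
                    tol = 1e-8)
  }
})

test_that("pre-rotating the radiograph points adds to the fitted angle", {
  set.seed(15)
  p <- matrix(runif(10, 0, 50), 5, 2)
  tf <- similarity_transform(1.3, 10, 5, -2)
  q <- transform_points(tf, p)
  base <- fit_similarity(tibble::tibble(plan_row = p[, 1], plan_col = p[, 2],
                                        radio_row = q[, 1],
                                        radio_col = q[, 2]))
  phi <- 25
  q2 <- transform_points(similarity_transform(1, phi, 0, 0), q)
  rot <- fit_similarity(tibble::tibble(plan_row = p[, 1], plan_col = p[, 2],
                                       radio_row = q2[, 1],
                                       radio_col = q2[, 2]))
  expect_equal(rot$rotation_deg, base$rotation_deg + phi, tolerance = 1e-8)
  expect_equal(rot$scale, base$scale, tolerance = 1e-9)
})

test_that("degenerate landmark configurations raise rank errors", {
  same <- tibble::tibble(plan_row = c(5, 5), plan_col = c(5, 5),
                         radio_row = c(1, 2), radio_col = c(3, 4))
  expect_error(fit_similarity(same), "degenerate")
  expect_error(fit_similarity(square_pairs(similarity_transform())[1, ]),
               "at least 2")
})

test_that("tidy and glance expose the fit like other model objects", {
  fit <- fit_similarity(square_pairs(similarity_transform(1.5, 12, 3, 4)))
  td <- tidy(fit)
  expect_equal(td$term, c("scale", "rotation_deg", "t_row", "t_col"))
  expect_equal(td$estimate[1], 1.5, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_landmarks, 4)
  expect_lt(gl$rms_residual, 1e-9)
})

test_that("forward and inverse mapping round-trip below 1e-9 px", {
  tf <- similarity_transform(1.7, -23, 12.5, -3.25)
  pts <- matrix(runif(20, 0, 200), 10, 2)
  back <- transform_points(tf, transform_points(tf, pts), inverse = TRUE)
  expect_lt(max(abs(back - pts)), 1e-9)
  expect_equal(unname(map_target(similarity_transform(), c(7, 9))), c(7, 9))
  inv <- invert_transform(tf)
  expect_equal(transform_points(inv, transform_points(tf, pts)),
               `colnames<-`(pts, c("row", "col")), tolerance = 1e-9)
})

test_that("isocenter detection is subpixel-accurate and scale invariant", {
  acq <- acquisition_params(n_frames = 2, poisson_noise = FALSE, seed = 4)
  col <- make_collimator_radiograph(c(120.5, 131.25), diameter_mm = 3,
                                    acq = acq)
  rad <- stack_median(correct_frames(col$raw, col$dark, col$beam))
  iso <- detect_isocenter(rad)
  expect_equal(unname(iso$center), c(120.5, 131.25), tolerance = 0.05)
  expect_equal(iso$radius_px, 30, tolerance = 0.05)
  expect_false(iso$flags$touches_border)
  expect_false(iso$flags$low_circularity)
  scaled <- radiograph(rad$image * 7.3 + 0, rad$pixel_pitch_mm)
  iso2 <- detect_isocenter(scaled)
  expect_equal(iso2$center, iso$center, tolerance = 1e-9)
  expect_error(detect_isocenter(radiograph(matrix(1, 8, 8))), "constant")
})

test_that("isocenter centroid error stays below half a pixel under noise", {
  errs <- vapply(1:50, function(s) {
    acq <- acquisition_params(n_frames = 1, gain = 500, poisson_noise = TRUE,
                              seed = s)
    col <- make_collimator_radiograph(c(61.3, 66.7), diameter_mm = 3,
                                      acq = acq, shape_px = c(128, 128))
    rad <- stack_median(correct_frames(col$raw, col$dark, col$beam))
    iso <- detect_isocenter(rad)
    sqrt(sum((iso$center - c(61.3, 66.7))^2))
  }, numeric(1))
  expect_lt(stats::quantile(errs, 0.95), 0.5)
})

test_that("stage shifts convert pixel offsets by pitch and convention", {
  iso <- c(100, 100)
  expect_equal(stage_shift(c(100, 100), iso)$x_mm, 0)
  expect_equal(stage_shift(c(100, 100), iso)$y_mm, 0)
  s <- stage_shift(c(100, 200), iso, pitch_mm = 0.05)
  expect_equal(s$x_mm, 5)   # 100 px columns at 0.05 mm
  expect_equal(s$y_mm, 0)
  s2 <- stage_shift(c(120, 100), iso, pitch_mm = 0.05)
  expect_equal(s2$y_mm, -1) # rows increase downward, stage y up
  expect_error(stage_shift(c(0, 0), iso, convention = "nope"),
               "unknown axis convention")
  # every convention maps target == isocenter to a null shift
  for (cv in c("beamline-default", "beamline-identity")) {
    s0 <- stage_shift(c(42.5, 17.25), c(42.5, 17.25), convention = cv)
    expect_equal(c(s0$x_mm, s0$y_mm), c(0, 0))
  }
})

test_that("target spread matches closed-form configurations", {
  t1 <- list(structure(list(x_mm = 0, y_mm = 0), class = "stage_target"),
             structure(list(x_mm = 1, y_mm = 0), class = "stage_target"))
  expect_equal(target_spread(t1)$spread_mm, 0.5)
  same <- tibble::tibble(x_mm = c(2, 2, 2), y_mm = c(1, 1, 1))
  expect_equal(target_spread(same)$spread_mm, 0)
  tri <- tibble::tibble(x_mm = c(0, 1, 0.5), y_mm = c(0, 0, sqrt(3) / 2))
  expect_equal(target_spread(tri)$spread_mm, 1 / sqrt(3), tolerance = 1e-9)
  expect_error(target_spread(same[1, ]), "at least 2")
})

test_that("the full positioning chain recovers the ground-truth target", {
  tf <- similarity_transform(1.08, 7, 12, -9)
  mp <- make_mouse_pair(seed = 19, true_transform = tf,
                        acq = acquisition_params(n_frames = 2,
                                                 poisson_noise = FALSE,
                                                 seed = 19))
  fit <- fit_similarity(mp$landmarks)
  expect_tf_equal(fit, 1.08, 7, 12, -9, tol = 1e-6)
  mapped <- map_target(fit, mp$ground_truth$target_plan_px)
  truth <- mp$ground_truth$target_radio_px
  err_mm <- sqrt(sum((mapped - truth)^2)) * 0.05
  expect_lt(err_mm, 0.01)
  # radiograph content equals plan content up to gain for the identity case
  mp_id <- make_mouse_pair(seed = 20,
                           acq = acquisition_params(n_frames = 1,
                                                    poisson_noise = FALSE,
                                                    seed = 20))
  rf <- mp_id$radiograph_frames
  rad <- stack_median(correct_frames(rf$raw, rf$dark, rf$beam))
  tm_truth <- rf$ground_truth$beam_profile *
    (rf$ground_truth$transmission - 1)
  expect_equal(rad$image, tm_truth, tolerance = 1e-9)
  expect_equal(nrow(mp_id$landmarks), 5)
  lm_mapped <- transform_points(tf, as.matrix(
    mp$landmarks[, c("plan_row", "plan_col")]))
  expect_equal(unname(lm_mapped),
               unname(as.matrix(mp$landmarks[, c("radio_row", "radio_col")])))
})

test_that("transforms outside the generator's envelope are refused", {
  expect_error(make_mouse_pair(1, similarity_transform(3, 0, 0, 0)),
               "scale")
  expect_error(make_mouse_pair(1, similarity_transform(1, 45, 0, 0)),
               "rotation")
})
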