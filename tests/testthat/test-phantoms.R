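test_that("hole-grid phantom matches its documented layout", {
  ph <- make_hole_grid_phantom()
  expect_equal(min(ph$meta$holes$diameter_mm), 0.3)
  disks <- ph$primitives[ph$primitives$type == "disk", ]
  expect_equal(nrow(disks), nrow(ph$meta$holes))
  expect_equal(nrow(disks), 63)           # 7 groups x 3 x 3 holes
  expect_true(all(disks$rsp == 0))        # holes are air
  plate <- ph$primitives[ph$primitives$type == "rect", ]
  expect_true(all(plate$rsp > 0))
})

test_that("hole-grid transmission contrast is positive at the holes", {
  ph <- make_hole_grid_phantom()
  tm <- transmission_map(ph, "200")
  pitch <- ph$pixel_pitch_mm
  plate_level <- stats::median(tm[round(2.3 / pitch), round((4:22) / pitch)])
  for (i in sample(nrow(ph$meta$holes), 10)) {
    r <- round(ph$meta$holes$center_row_mm[i] / pitch)
    c <- round(ph$meta$holes$center_col_mm[i] / pitch)
    expect_gt(tm[r, c], plate_level)
  }
})

test_that("lead-grid groups span 0.6 to 6.0 lp/mm with half-period bars", {
  ph <- make_lead_grid_phantom()
  f <- ph$meta$groups$freq_lp_per_mm
  expect_equal(min(f), 0.6)
  expect_equal(max(f), 6.0)
  # painted bar width equals 1/(2f) within one pixel
  tm0 <- protonrad:::paint_areal_density(ph)
  pitch <- ph$pixel_pitch_mm
  g <- ph$meta$groups[1, ]  # 0.6 lp/mm
  row <- round((g$r0_mm + 1) / pitch)
  strip <- tm0[row, ] > 0
  runs <- rle(strip)
  bar_px <- runs$lengths[runs$values][1]
  expect_equal(bar_px * pitch, 1 / (2 * g$freq_lp_per_mm), tolerance = 0.1)
})

test_that("a uniform phantom yields a flat map of exactly 1", {
  # material block covering the whole canvas: no edges anywhere
  ph <- protonrad:::new_phantom_spec(
    c(64, 64),
    protonrad:::prim_row("rect", rsp = 1.16, thickness_mm = 20,
                         r0 = 0, r1 = 3.2, c0 = 0, c1 = 3.2),
    "uniform")
  tm <- transmission_map(ph, "150")
  expect_equal(as.vector(tm), rep(1, 64 * 64), tolerance = 1e-9)
})

test_that("mean fluence is conserved within 1e-3 for any phantom", {
  for (ph in list(make_hole_grid_phantom(), make_lead_grid_phantom(),
                  make_edge_phantom())) {
    for (preset in c("150", "200")) {
      expect_equal(mean(transmission_map(ph, preset)), 1, tolerance = 1e-3)
    }
  }
})

test_that("a straight edge produces a valley inside and a peak outside", {
  ph <- make_edge_phantom()
  for (preset in c("150", "200")) {
    tm <- transmission_map(ph, preset)
    pitch <- ph$pixel_pitch_mm
    edge_px <- round(ph$meta$edge_col_mm / pitch)
    mid_px <- round((ph$meta$block_c0_mm + ph$meta$edge_col_mm) / 2 / pitch)
    prof <- colMeans(tm[60:200, ])
    # valley hugs the inner side of the edge, below the mid-block level
    expect_lt(min(prof[(edge_px - 8):(edge_px - 1)]), prof[mid_px] - 0.01)
    # fluence peak just outside, above the far field
    expect_gt(max(prof[(edge_px + 1):(edge_px + 30)]), 1 + 1e-3)
    # redistribution conserves fluence across a full band crossing the edges
    band <- tm[100:140, ]
    expect_equal(mean(band - 1), 0, tolerance = 2e-3)
  }
})

test_that("edge-peak FWHM is wider at 150 MeV and differs by 0.08 mm", {
  ph <- make_edge_phantom(shape_px = c(256, 320), edge_col_mm = 6,
                          block_width_mm = 3)
  roi <- roi_spec(40, 216, 90, 320)
  f <- vapply(c("150", "200"), function(p) {
    tm <- transmission_map(ph, p)
    edge_fwhm(radiograph(tm, ph$pixel_pitch_mm), roi, "vertical")
  }, numeric(1))
  expect_gt(f[["150"]], f[["200"]])
  expect_equal(f[["150"]] - f[["200"]], 0.08, tolerance = 0.1)
})

test_that("unknown presets are rejected", {
  expect_error(transmission_map(make_edge_phantom(), "120"),
               "unknown energy preset")
})

test_that("renders are bit-identical for identical seeds", {
  tm <- transmission_map(make_edge_phantom(c(64, 64), edge_col_mm = 1.8,
                                           block_width_mm = 1), "200")
  acq <- acquisition_params(n_frames = 2, salt_pepper_fraction = 0.01,
                            seed = 7)
  a <- render_frames(tm, acq)
  b <- render_frames(tm, acq)
  expect_identical(a$raw$frames, b$raw$frames)
  expect_identical(a$dark$frames, b$dark$frames)
  c <- render_frames(tm, acquisition_params(n_frames = 2,
                                            salt_pepper_fraction = 0.01,
                                            seed = 8))
  expect_false(identical(a$raw$frames, c$raw$frames))
})

test_that("Poisson noise follows 1/sqrt(counts) scaling", {
  tm <- matrix(1, 24, 24)
  acq <- acquisition_params(n_frames = 100, gain = 1e4, dark_amplitude = 0,
                            beam_sigma_frac = 100, seed = 13)
  r <- render_frames(tm, acq)
  arr <- simplify2array(r$raw$frames)
  rel_sd <- apply(arr, c(1, 2), sd) / apply(arr, c(1, 2), mean)
  expect_equal(mean(rel_sd), 1 / sqrt(1e4), tolerance = 0.1)
})

test_that("collimator disk has the right area, centre and radius", {
  acq <- acquisition_params(n_frames = 2, poisson_noise = FALSE, seed = 3)
  col <- make_collimator_radiograph(c(120.5, 130.25), diameter_mm = 3,
                                    acq = acq)
  expect_equal(col$ground_truth$radius_px, 30)  # 3 mm at 0.05 mm pitch
  ap <- col$ground_truth$aperture
  expect_equal(sum(ap), pi * 30^2, tolerance = 0.02)
  idx <- which(ap > 0, arr.ind = TRUE)
  w <- ap[ap > 0]
  expect_equal(sum(w * (idx[, 1] - 1)) / sum(w), 120.5, tolerance = 0.1)
  expect_equal(sum(w * (idx[, 2] - 1)) / sum(w), 130.25, tolerance = 0.1)
})

test_that("label volume nests hippocampus inside brain with 3 labels", {
  v <- make_label_volume(c(48, 48, 32), seed = 2)
  expect_setequal(unique(as.vector(v$labels)), c(0L, 1L, 2L))
  expect_true(all(v$labels[v$labels == 2L] != 0))
  hip <- v$labels == 2L
  brain <- v$labels >= 1L
  expect_true(all(brain[hip]))
  expect_error(make_label_volume(c(48, 48, 10), seed = 2), "25 sagittal")
})

test_that("depth-dose peak translates with the range shifter", {
  grid <- list(shape_px = c(32, 400), pixel_size_mm = 0.1)
  d1 <- analytic_depth_dose(90, range_shifter_wet_mm = 30, grid = grid)
  d2 <- analytic_depth_dose(90, range_shifter_wet_mm = 31, grid = grid)
  p1 <- which.max(d1$dose[16, ])
  p2 <- which.max(d2$dose[16, ])
  expect_equal((p1 - p2) * 0.1, 1, tolerance = 0.11)
  expect_true(all(d1$dose >= 0))
  expect_equal(max(d1$dose), d1$peak_dose_Gy)
  # depth curve translates: compare the common (shifted) support
  expect_equal(d1$dose[16, 11:400], d2$dose[16, 1:390], tolerance = 1e-6)
})

test_that("the 90 MeV beam behind the calibrated shifter stops mid-brain", {
  wet <- wet_of_slab(46.51, "polycarbonate", 90)
  d <- analytic_depth_dose(90, range_shifter_wet_mm = wet,
                           grid = list(shape_px = c(32, 200),
                                       pixel_size_mm = 0.1))
  expect_equal(d$residual_range_mm, 10.3, tolerance = 0.05)
  expect_warning(
    analytic_depth_dose(90, range_shifter_wet_mm = 100,
                        grid = list(shape_px = c(8, 16),
                                    pixel_size_mm = 0.1)),
    "upstream")
})

test_that("nuclei generator bookkeeping matches the placed blobs", {
  dose <- analytic_depth_dose(90, 53.16,
                              grid = list(shape_px = c(4, 8),
                                          pixel_size_mm = 0.64))
  pair <- make_nuclei_pair(dose, seed = 5, n_nuclei = 300,
                           shape_px = c(256, 512), tile_px = 128,
                           pixel_size_mm = 0.01)
  expect_equal(sum(pair$truth$n_dapi), 300)
  expect_equal(sum(pair$truth$n_damage), sum(pair$centers$damaged))
  expect_true(all(pair$truth$n_damage <= pair$truth$n_dapi))
  # same seed, same output
  pair2 <- make_nuclei_pair(dose, seed = 5, n_nuclei = 300,
                            shape_px = c(256, 512), tile_px = 128,
                            pixel_size_mm = 0.01)
  expect_identical(pair$dapi$image, pair2$dapi$image)
})

test_that("damage probability hits its degenerate limits", {
  zero <- analytic_depth_dose(90, 53.16,
                              grid = list(shape_px = c(4, 8),
                                          pixel_size_mm = 0.64))
  zero$dose[] <- 0
  none <- make_nuclei_pair(zero, seed = 6, n_nuclei = 80,
                           shape_px = c(128, 128), p_bg = 0)
  expect_equal(sum(none$centers$damaged), 0)
  hot <- zero; hot$dose[] <- 1e9
  all_hit <- make_nuclei_pair(hot, seed = 6, n_nuclei = 80,
                              shape_px = c(128, 128), p_max = 1)
  expect_equal(sum(all_hit$centers$damaged), 80)
})

test_that("impossible nucleus density fails with a clear error", {
  dose <- analytic_depth_dose(90, 0, grid = list(shape_px = c(4, 4),
                                                 pixel_size_mm = 1))
  expect_error(
    make_nuclei_pair(dose, seed = 1, n_nuclei = 500, shape_px = c(64, 64),
                     min_dist_px = 12, max_tries = 5),
    "placement failed")
})
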