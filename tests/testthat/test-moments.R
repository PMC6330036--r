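test_that("density-weighted centroid follows the weighted-mean rule", {
  # single pixel at its centre
  one <- compute_centroid(matrix(250), matrix(1L), pixel_spacing = 1)
  expect_equal(one, c(x = 0.5, y = 0.5))
  # two equal densities at x = 0.1 and 0.3 cm
  sl <- matrix(c(100, 100), nrow = 1)
  ctr <- compute_centroid(sl, matrix(1L, 1, 2), pixel_spacing = 0.2)
  expect_equal(ctr[["x"]], 0.2)
  # densities 100 and 300 pull the centroid to 0.25 cm
  sl <- matrix(c(100, 300), nrow = 1)
  ctr <- compute_centroid(sl, matrix(1L, 1, 2), pixel_spacing = 0.2)
  expect_equal(ctr[["x"]], 0.25)
  expect_error(compute_centroid(matrix(0), matrix(0L), 1), "empty")
})

test_that("axis moments match hand arithmetic on the two-pixel case", {
  tp <- two_pixel_case()
  ctr <- compute_centroid(tp$slice, tp$mask, tp$spacing)
  expect_equal(ctr, c(x = 1, y = 0.5))
  # vertical axis: each pixel 0.5 cm away, 2 * 0.25 * 100 * 1 = 50 mg cm
  expect_equal(moment_about_axis(tp$slice, tp$mask, ctr, pi / 2,
                                 tp$spacing), 50)
  # horizontal axis through both pixels: zero
  expect_equal(moment_about_axis(tp$slice, tp$mask, ctr, 0, tp$spacing), 0)
  mm <- minimum_cross_sectional_moment(tp$slice, tp$mask, ctr, tp$spacing)
  expect_equal(mm$i_min, 0)
  expect_equal(mm$theta_star, 0)
  expect_equal(polar_moment(tp$slice, tp$mask, ctr, tp$spacing), 50)
})

test_that("a single pixel has zero polar moment", {
  ctr <- compute_centroid(matrix(100), matrix(1L), 1)
  expect_equal(polar_moment(matrix(100), matrix(1L), ctr, 1), 0)
})

test_that("a circular annulus is isotropic: I_min = J/2, theta* = 0", {
  p <- quiet_params()
  st <- ring_state(a = 0.40, t = 0.10, rho_c = 300, rho_t = 0)
  sl <- generate_slice(p, st, seed = 1)
  m <- segment_bone(sl, 100)
  ctr <- compute_centroid(sl, m, p$pixel_spacing)
  mm <- minimum_cross_sectional_moment(sl, m, ctr, p$pixel_spacing)
  j <- polar_moment(sl, m, ctr, p$pixel_spacing)
  expect_equal(mm$i_min, j / 2, tolerance = 1e-3)
  expect_equal(mm$theta_star, 0)
})

test_that("eigen-decomposition minimum equals the theta-grid oracle", {
  set.seed(101)
  for (rep in 1:20) {
    rm <- random_mask_slice()
    ctr <- compute_centroid(rm$slice, rm$mask, rm$spacing)
    mm <- minimum_cross_sectional_moment(rm$slice, rm$mask, ctr,
                                         rm$spacing)
    oracle <- grid_min_moment(rm$slice, rm$mask, ctr, rm$spacing)
    expect_lt(abs(mm$i_min - oracle$i_min) / oracle$i_min, 1e-3)
    # the closed-form angle also attains the oracle minimum
    at_star <- moment_about_axis(rm$slice, rm$mask, ctr, mm$theta_star,
                                 rm$spacing)
    expect_equal(at_star, mm$i_min, tolerance = 1e-9)
  }
})

test_that("perpendicular-axis identity and J >= 2 I_min hold", {
  set.seed(202)
  for (rep in 1:10) {
    rm <- random_mask_slice()
    ctr <- compute_centroid(rm$slice, rm$mask, rm$spacing)
    j <- polar_moment(rm$slice, rm$mask, ctr, rm$spacing)
    for (th in runif(10, 0, pi)) {
      i1 <- moment_about_axis(rm$slice, rm$mask, ctr, th, rm$spacing)
      i2 <- moment_about_axis(rm$slice, rm$mask, ctr, th + pi / 2,
                              rm$spacing)
      expect_lt(abs(i1 + i2 - j) / j, 1e-9)
    }
    mm <- minimum_cross_sectional_moment(rm$slice, rm$mask, ctr,
                                         rm$spacing)
    expect_gte(j, 2 * mm$i_min * (1 - 1e-12))
  }
})

test_that("moments are invariant under whole-pixel translation", {
  st <- ring_state(a = 0.30, t = 0.08, rho_c = 900, rho_t = 300)
  base <- c(0.45, 0.45)
  # noiseless so that the shifted phantom samples identical pixel values
  pq <- quiet_params()
  s1 <- generate_slice(pq, st, seed = 3, dim_px = c(220L, 220L),
                       center = base)
  s2 <- generate_slice(pq, st, seed = 3, dim_px = c(220L, 220L),
                       center = base + 17 * pq$pixel_spacing)
  vals <- lapply(list(s1, s2), function(sl) {
    m <- segment_bone(sl, 160)
    ctr <- compute_centroid(sl, m, pq$pixel_spacing)
    mm <- minimum_cross_sectional_moment(sl, m, ctr, pq$pixel_spacing)
    c(mm$i_min, polar_moment(sl, m, ctr, pq$pixel_spacing))
  })
  expect_equal(vals[[1]], vals[[2]], tolerance = 1e-12)
})

test_that("moments are invariant under analytic rotation of the phantom", {
  p <- quiet_params()
  st <- ring_state(a = 0.30, b = 0.20, t = 0.06, rho_c = 900, rho_t = 300)
  get <- function(rot) {
    sl <- generate_slice(p, st, seed = 1, dim_px = c(200L, 200L),
                         center = c(0.5, 0.5), rotation = rot)
    m <- segment_bone(sl, 160)
    ctr <- compute_centroid(sl, m, p$pixel_spacing)
    mm <- minimum_cross_sectional_moment(sl, m, ctr, p$pixel_spacing)
    c(i_min = mm$i_min, j = polar_moment(sl, m, ctr, p$pixel_spacing))
  }
  v0 <- get(0)
  v30 <- get(pi / 6)
  expect_lt(abs(v30["i_min"] - v0["i_min"]) / v0["i_min"], 0.01)
  expect_lt(abs(v30["j"] - v0["j"]) / v0["j"], 0.01)
})

test_that("physical outputs are invariant to pixel spacing (units audit)", {
  st <- ring_state(a = 0.30, t = 0.10, rho_c = 900, rho_t = 300)
  get <- function(spacing) {
    p <- quiet_params(spacing = spacing)
    sl <- generate_slice(p, st, seed = 1, dim_px = rep(round(1 / spacing),
                                                       2L),
                         center = c(0.5, 0.5))
    m <- segment_bone(sl, 160)
    ctr <- compute_centroid(sl, m, spacing)
    mm <- minimum_cross_sectional_moment(sl, m, ctr, spacing)
    lab <- classify_cortical(m, sl, 500)
    c(i_min = mm$i_min,
      j = polar_moment(sl, m, ctr, spacing),
      area = sum(m > 0) * spacing^2,
      thick = mean_cortical_thickness(list(L2 = list(lab), L3 = list(lab),
                                           L4 = list(lab)), spacing))
  }
  fine <- get(0.005)
  coarse <- get(0.01)
  for (nm in names(fine)) {
    expect_lt(abs(coarse[nm] - fine[nm]) / fine[nm], 0.025)
  }
})

test_that("polar moment of a uniform annulus matches the closed form", {
  p <- quiet_params()
  st <- ring_state(a = 0.40, t = 0.10, rho_c = 300, rho_t = 0)
  sl <- generate_slice(p, st, seed = 1)
  m <- segment_bone(sl, 100)
  ctr <- compute_centroid(sl, m, p$pixel_spacing)
  j <- polar_moment(sl, m, ctr, p$pixel_spacing)
  want <- 300 * (pi / 2) * (0.4^4 - 0.3^4)
  expect_lt(abs(j - want) / want, 0.01)
})

test_that("BMD bookkeeping follows the printed volume and density rules", {
  # two slices of known bone area: S(1) = 2 cm^2, S(2) = 3 cm^2, d = 0.1 cm
  h <- 0.1                     # 0.1 cm pixels: 1 px = 0.01 cm^2
  s1 <- matrix(0, 30, 30)
  s1[1:10, 1:20] <- 400        # 200 px = 2 cm^2
  s2 <- matrix(0, 30, 30)
  s2[1:10, 1:30] <- 400        # 300 px = 3 cm^2
  stack <- calibrated_stack(list(s1, s2), pixel_spacing = h,
                            slice_interval_d = 0.1,
                            vertebra_labels = list(L2 = c(1L, 2L)))
  masks <- list((s1 > 0) * 1L, (s2 > 0) * 1L)
  bv <- bmd_and_volume(stack, masks, "L2")
  expect_equal(bv$volume, 0.5)
  expect_equal(bv$bmd, 400)           # constant density recovers exactly
  expect_equal(bv$bmd * bv$volume, bv$mineral_content)
})

test_that("cortical thickness recovers the analytic shell width", {
  p <- quiet_params()
  st <- ring_state(a = 0.40, t = 0.10, rho_c = 900, rho_t = 300)
  run <- function(rot) {
    sl <- generate_slice(p, st, seed = 1, rotation = rot)
    m <- segment_bone(sl, 160)
    lab <- classify_cortical(m, sl, 500)
    mean_cortical_thickness(list(L2 = list(lab), L3 = list(lab),
                                 L4 = list(lab)), p$pixel_spacing)
  }
  t0 <- run(0)
  expect_lt(abs(t0 - 1.0), 0.5 * p$pixel_spacing * 10)  # half a pixel, mm
  # rotation changes the estimate by < 2%
  t30 <- run(pi / 6)
  expect_lt(abs(t30 - t0) / t0, 0.02)
})

test_that("a one-pixel-wide ring reads one pixel thick", {
  lab <- matrix(0L, 12, 12)
  lab[3:9, 3:9] <- 2L
  ring <- matrix(FALSE, 12, 12)
  ring[3, 3:9] <- ring[9, 3:9] <- TRUE
  ring[3:9, 3] <- ring[3:9, 9] <- TRUE
  lab[ring] <- 1L
  th <- mean_cortical_thickness(list(L2 = list(lab), L3 = list(lab),
                                     L4 = list(lab)), 0.005)
  expect_lte(abs(th - 0.05), 0.05)   # within one pixel (0.05 mm)
})

test_that("vertebral dimensions follow the slice-count and midpoint rules", {
  h <- 0.01
  mk <- function(w_px) {
    m <- matrix(0, 80, 80)
    m[30:50, seq_len(w_px) + 10] <- 500
    m
  }
  slices <- list(mk(50), mk(55), mk(55), mk(55), mk(55), mk(60))
  stack <- calibrated_stack(slices, pixel_spacing = h,
                            slice_interval_d = 0.1,
                            vertebra_labels = list(L2 = c(1L, 6L)))
  masks <- lapply(slices, function(s) (s > 0) * 1L)
  dims <- vertebral_dimensions(stack, masks, "L2")
  expect_equal(dims$body_height, 6)             # 6 slices x 0.1 cm = 6 mm
  expect_equal(dims$body_width, mean(c(5, 6)))  # 5.0 and 6.0 mm ends
  # constant width: equals that width
  slices_c <- list(mk(50), mk(50))
  stack_c <- calibrated_stack(slices_c, pixel_spacing = h,
                              slice_interval_d = 0.1,
                              vertebra_labels = list(L2 = c(1L, 2L)))
  dims_c <- vertebral_dimensions(stack_c, lapply(slices_c,
                                                 function(s) (s > 0) * 1L),
                                 "L2")
  expect_equal(dims_c$body_width, 5)
  # single-slice vertebra rejected
  stack_1 <- calibrated_stack(slices_c, pixel_spacing = h,
                              slice_interval_d = 0.1,
                              vertebra_labels = list(L2 = c(1L, 1L)))
  expect_error(vertebral_dimensions(stack_1, list(masks[[1]]), "L2"),
               "single slice")
})

test_that("vertebra averaging requires all of L2, L3, L4", {
  expect_equal(vertebra_average(c(L2 = 1, L3 = 2, L4 = 3)), 2)
  expect_equal(vertebra_average(c(L2 = 2, L3 = 2, L4 = 2)), 2)
  expect_equal(vertebra_average(c(L2 = 0.9, L3 = 1.0, L4 = 1.4)), 1.1)
  expect_error(vertebra_average(c(L2 = 1, L4 = 3)), "L3")
})
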