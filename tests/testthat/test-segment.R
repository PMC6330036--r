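test_that("a slice entirely below threshold yields an excluded empty mask", {
  m <- segment_bone(matrix(100, 10, 10), bone_threshold = 160)
  expect_true(all(m == 0L))
  expect_true(isTRUE(attr(m, "excluded")))
})

test_that("bone area of a filled noiseless phantom matches the ellipse", {
  p <- quiet_params()
  st <- ring_state(a = 0.40, t = 0.10, rho_c = 300, rho_t = 200)
  sl <- generate_slice(p, st, seed = 1)
  m <- segment_bone(sl, bone_threshold = 100)
  got <- sum(m > 0) * p$pixel_spacing^2
  expect_lt(abs(got - pi * 0.4^2) / (pi * 0.4^2), 0.02)
})

test_that("only the largest connected component survives", {
  sl <- matrix(0, 20, 20)
  sl[2:7, 2:7] <- 500     # 36 px
  sl[14:17, 14:16] <- 500 # 12 px
  m <- segment_bone(sl, 160)
  expect_identical(sum(m > 0), 36L)
  expect_true(all(m[14:17, 14:16] == 0L))
})

test_that("segmentation is monotone in the threshold", {
  p <- phantom_params()
  st <- ring_state(a = 0.30, t = 0.08, rho_c = 900, rho_t = 300,
                   height = 0.3)
  sl <- generate_slice(p, st, seed = 9)
  prev <- segment_bone(sl, 50)
  for (thr in c(100, 160, 250, 450, 600)) {
    cur <- segment_bone(sl, thr)
    # raising the threshold never adds bone pixels
    expect_true(all(cur[prev == 0L] == 0L))
    prev <- cur
  }
})

test_that("shell classification recovers the true cortical ring", {
  p <- quiet_params(texture_sd = 30)
  st <- ring_state(a = 0.40, t = 0.10, rho_c = 900, rho_t = 300)
  sl <- generate_slice(p, st, seed = 2)
  m <- segment_bone(sl, 160)
  lab <- classify_cortical(m, sl, cortical_threshold = 500)
  h <- p$pixel_spacing
  sd_map <- ellipse_signed_distance(
    (col(sl) - 0.5) * h - ncol(sl) * h / 2,
    (row(sl) - 0.5) * h - nrow(sl) * h / 2, st$a, st$b)
  true_ring <- sd_map < 0 & sd_map >= -st$t_eff
  mismatch <- which(xor(lab == 1L, true_ring))
  # disagreements only within one pixel of either ring boundary
  near_edge <- abs(sd_map[mismatch]) < 1.5 * h |
    abs(sd_map[mismatch] + st$t_eff) < 1.5 * h
  expect_true(all(near_edge))
  expect_false(isTRUE(attr(lab, "ring_broken")))
})

test_that("a component uniformly at the cortical threshold is all cortical", {
  sl <- matrix(0, 12, 12)
  sl[4:9, 4:9] <- 500
  m <- segment_bone(sl, 160)
  lab <- classify_cortical(m, sl, cortical_threshold = 500)
  expect_true(all(lab[m > 0] == 1L))
  expect_identical(sum(lab == 2L), 0L)
})

test_that("an empty mask classifies to an empty label map", {
  sl <- matrix(0, 8, 8)
  m <- segment_bone(sl, 160)
  lab <- classify_cortical(m, sl)
  expect_true(all(lab == 0L))
})

test_that("a broken cortical ring is flagged with a warning", {
  sl <- matrix(0, 30, 30)
  sl[8:22, 8:22] <- 900
  sl[11:19, 11:19] <- 300   # interior below the cortical threshold
  sl[14:16, 8:10] <- 300    # gap through the shell
  m <- segment_bone(sl, 160)
  expect_warning(lab <- classify_cortical(m, sl, cortical_threshold = 500),
                 "broken")
  expect_true(isTRUE(attr(lab, "ring_broken")))
})

test_that("an empty edit list leaves the masks untouched", {
  sl <- matrix(300, 6, 6)
  masks <- list(classify_cortical(segment_bone(sl, 160), sl, 250))
  expect_identical(apply_edits(masks, list()), masks)
})

test_that("later overlapping edits win", {
  masks <- list(matrix(0L, 10, 10))
  square <- cbind(c(2, 8, 8, 2), c(2, 2, 8, 8))
  e1 <- roi_edit(1, square, label = 1L)
  e2 <- roi_edit(1, cbind(c(4, 6, 6, 4), c(4, 4, 6, 6)), label = 2L)
  out <- apply_edits(masks, list(e1, e2))[[1]]
  expect_identical(out[5, 5], 2L)
  expect_identical(out[3, 3], 1L)
})

test_that("out-of-bounds edits are rejected and masks unchanged", {
  masks <- list(matrix(0L, 10, 10))
  bad <- roi_edit(1, cbind(c(2, 30, 30), c(2, 2, 8)), label = 1L)
  expect_error(apply_edits(masks, list(bad)), "bounds")
  far <- roi_edit(4, cbind(c(2, 8, 8), c(2, 2, 8)), label = 1L)
  expect_error(apply_edits(masks, list(far)), "slice 4")
})

test_that("an edit that breaks ring enclosure sets the warning flag", {
  sl <- matrix(0, 30, 30)
  sl[8:22, 8:22] <- 900
  sl[11:19, 11:19] <- 300
  m <- segment_bone(sl, 160)
  lab <- classify_cortical(m, sl, cortical_threshold = 500)
  expect_false(isTRUE(attr(lab, "ring_broken")))
  # carve a channel of background through the shell
  hole <- roi_edit(1, cbind(c(7.2, 10.8, 10.8, 7.2),
                            c(13.2, 13.2, 16.8, 16.8)), label = 0L)
  expect_warning(out <- apply_edits(list(lab), list(hole)), "broke")
  expect_true(isTRUE(attr(out[[1]], "ring_broken")))
})

test_that("roi edits round-trip through JSON", {
  edits <- list(list(slice = 1, polygon = list(c(2, 2), c(8, 2), c(8, 8)),
                     label = 2))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(edits, path, auto_unbox = TRUE)
  got <- read_roi_edits(path)
  expect_length(got, 1L)
  expect_identical(got[[1]]$label, 2L)
  expect_identical(nrow(got[[1]]$polygon), 3L)
})
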