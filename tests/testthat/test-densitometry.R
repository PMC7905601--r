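test_that("mean OD honors pixel-center inclusion on uniform and split images", {
  img <- matrix(120, 100, 100)
  expect_equal(mean_od(img, roi_square(c(1, 1), 0.2), 0.02), 120)
  # half-plane 100 | 140 with a square straddling the boundary symmetrically
  img2 <- cbind(matrix(100, 100, 50), matrix(140, 100, 50))
  expect_equal(mean_od(img2, roi_square(c(1.0, 1.0), 0.2), 0.02), 120)
  expect_error(mean_od(img, roi_square(c(50, 50), 0.2), 0.02),
               class = "seasong_invalid_argument")
})

test_that("net OD is an exact difference with negatives flagged", {
  expect_equal(background_subtract(0.8, 0.3), 0.5)
  expect_equal(background_subtract(2, 2), 0)
  neg <- background_subtract(0.3, 0.8)
  expect_equal(as.numeric(neg), -0.5)
  expect_true(attr(neg, "flagged"))
})

test_that("net OD is invariant to a uniform offset and exact on noiseless phantoms", {
  stk <- synth_section_stack(noise_sd = 0, background = 100, signal = 40)
  roi <- roi_square(c(1.28, 1.28), 0.2)
  prof <- expression_profile(stk, roi, c(0.8, 0))
  expect_equal(prof$net_od, 40)
  stk2 <- stk
  stk2$sections <- lapply(stk$sections, function(m) m + 57.3)
  prof2 <- expression_profile(stk2, roi, c(0.8, 0))
  expect_equal(prof2$net_od, prof$net_od)
  expect_error(expression_profile(stk, roi, c(5, 0)), class = "seasong_invalid_argument")
})

test_that("per-section net ODs average across the stack", {
  stk <- synth_section_stack(n_sections = 3, signal = 30)
  stk$sections[[2]] <- stk$sections[[2]] + 10 * stk$truth$masks[[2]]
  stk$sections[[3]] <- stk$sections[[3]] + 20 * stk$truth$masks[[3]]
  prof <- expression_profile(stk, roi_square(c(1.28, 1.28), 0.2), c(0.8, 0))
  expect_equal(prof$per_section$net_od, c(30, 40, 50))
  expect_equal(prof$net_od, 40)
})

test_that("delineation finds the phantom disc within 2% area and reports blob counts", {
  stk <- synth_section_stack(radius_mm = 0.5, noise_sd = 0)
  roi <- delineate_region(stk$sections[[1]], stk$pixel_size_mm)
  expect_equal(roi$area_mm2, pi * 0.25, tolerance = 0.02)
  expect_equal(roi$n_blobs, 1)
  expect_error(delineate_region(matrix(100, 64, 64), 0.02), class = "seasong_not_found")
  # two blobs: the larger is returned
  img <- matrix(100, 128, 128)
  img[20:40, 20:40] <- 150   # 21x21
  img[80:90, 80:90] <- 150   # 11x11
  roi2 <- delineate_region(img, 0.02, close_px = 0)
  expect_equal(roi2$n_pixels, 21 * 21)
  expect_equal(roi2$n_blobs, 2)
})

test_that("volumes follow the area-sum rule and are additive across splits", {
  v <- nucleus_volume(c(0.1, 0.2, 0.1), 0.2)
  expect_equal(v$volume_mm3, 0.08)
  expect_error(nucleus_volume(numeric(0)), class = "seasong_invalid_argument")
  expect_error(nucleus_volume(c(0.1, -0.2)), class = "seasong_invalid_argument")
  areas <- stats::runif(7, 0, 0.5)
  v_all <- nucleus_volume(areas)$volume_mm3
  expect_equal(nucleus_volume(areas[1:3])$volume_mm3 + nucleus_volume(areas[4:7])$volume_mm3,
               v_all)
  # doubling pixel size with the same mask pixels quadruples area and volume
  stk <- synth_section_stack(radius_mm = 0.4, noise_sd = 0)
  r1 <- delineate_region(stk$sections[[1]], stk$pixel_size_mm)
  r2 <- delineate_region(stk$sections[[1]], 2 * stk$pixel_size_mm)
  expect_equal(r2$area_mm2 / r1$area_mm2, 4)
})

test_that("replicate volumes average and stay tight on noisy phantoms", {
  mk <- function(v) structure(list(areas = v / 0.2, spacing_mm = 0.2, volume_mm3 = v),
                              class = "volume_estimate")
  rv <- replicate_volume(list(mk(0.78), mk(0.80), mk(0.79)))
  expect_equal(rv$mean_volume_mm3, 0.79)
  expect_equal(replicate_volume(list(mk(0.5), mk(0.5)))$cv, 0)
  stk <- synth_section_stack(radius_mm = 0.5, noise_sd = 3, seed = 8)
  mv <- measure_nucleus_volume(stk, n_replicates = 3, seed = 21)
  expect_equal(mv$mean_volume_mm3, stk$truth$volume_mm3, tolerance = 0.05)
  expect_lt(mv$cv, 0.05)
})

test_that("phantom recovery holds across seeds (volume within 5%, signal within noise bound)", {
  for (s in 1:8) {
    stk <- synth_section_stack(radius_mm = 0.5, noise_sd = 2, seed = s)
    mv <- measure_nucleus_volume(stk, n_replicates = 3, seed = 100 + s)
    expect_lt(abs(mv$mean_volume_mm3 / stk$truth$volume_mm3 - 1), 0.05)
    prof <- expression_profile(stk, roi_square(c(1.28, 1.28), 0.2), c(0.8, 0))
    npix <- 100  # 0.2 mm square at 0.02 mm/px
    bound <- 3 * 2 * sqrt(2) / sqrt(npix * length(stk$sections))
    expect_lt(abs(prof$net_od - stk$truth$net_signal), bound)
  }
})

test_that("section stacks round-trip through PGM + JSON", {
  dir <- withr::local_tempdir()
  stk <- synth_section_stack(radius_mm = 0.3, n_sections = 2, img_px = c(48, 48),
                             noise_sd = 1.5, seed = 3)
  write_section_stack(stk, dir)
  back <- read_section_stack(dir)
  expect_equal(back$pixel_size_mm, stk$pixel_size_mm)
  expect_equal(back$spacing_mm, stk$spacing_mm)
  expect_equal(back$sections[[1]], round(stk$sections[[1]]), tolerance = 1e-12)
})
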