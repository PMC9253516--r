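test_that("a noise-only image yields no foci", {
  noise <- withr::with_seed(1, matrix(rnorm(64 * 64, 100, 3), 64, 64))
  expect_equal(nrow(detect_foci(noise)), 0)
})

test_that("a uniform saturated image warns and yields no foci", {
  flat <- matrix(4095, 64, 64)
  expect_warning(foci <- detect_foci(flat), "uniform or saturated")
  expect_equal(nrow(foci), 0)
})

test_that("a single spot is localized to sub-pixel accuracy", {
  scene <- one_spot_scene(amp = c(ACA = 1000), noise_sd = 3, seed = 9,
                          x_um = 4.02, y_um = 3.87)
  img <- generate_cell_image(scene)$image$ACA
  foci <- detect_foci(img)
  expect_equal(nrow(foci), 1)
  expect_lt(abs(foci$x_px - 4.02 / 0.0645), 0.5)
  expect_lt(abs(foci$y_px - 3.87 / 0.0645), 0.5)
})

test_that("detection recovers 23 kinetochore pairs at SNR 10", {
  # 23 pair anchors on a grid in a 16.5 um field, sep 1 um, noise SNR 10
  g <- expand.grid(x = seq(2, 14.5, length.out = 5),
                   y = seq(2, 14.5, length.out = 5))[1:23, ]
  spots <- purrr::map_dfr(1:23, function(i)
    spot_truth(g$x[i], g$y[i], sigma_um = 0.15,
               amplitude = c(ACA = 500), pair_id = i))
  scene <- image_scene(width_px = 256, height_px = 256, channels = "ACA",
                       spots = spots, background = 100, noise_sd = 50,
                       seed = 13)
  sp <- generate_spread_image(scene, inter_kt_sep_um = 1)
  foci <- detect_foci(sp$image$ACA)

  truth <- sp$truth
  px <- 0.0645
  dmat <- outer(foci$x_px, truth$x_um / px, "-")^2 +
    outer(foci$y_px, truth$y_um / px, "-")^2
  hit_truth <- apply(dmat, 2, min) <= 3^2   # truth spot recovered
  hit_focus <- apply(dmat, 1, min) <= 3^2   # focus corresponds to a truth spot
  expect_gte(mean(hit_truth), 0.95)  # recall over 46 spots
  expect_gte(mean(hit_focus), 0.95)  # precision
})

test_that("ring measurement subtracts the background region mean", {
  mask <- matrix(FALSE, 40, 40); mask[19:21, 19:21] <- TRUE
  focus <- tibble::tibble(focus_id = 1L, x_px = 19.5, y_px = 19.5,
                          mask = list(mask))
  marker <- matrix(7, 40, 40)
  bg <- matrix(FALSE, 40, 40); bg[1:5, 1:5] <- TRUE
  marker[bg] <- 0
  m <- measure_ring(marker, focus, background_region = bg)
  expect_equal(m$corrected, 7)
  expect_false(m$flagged)
})

test_that("ring and mask are disjoint and the ring is nonempty", {
  scene <- one_spot_scene(amp = c(ACA = 1000, marker = 500))
  img <- generate_cell_image(scene)$image
  focus <- detect_foci(img$ACA)[1, ]
  mask <- focus$mask[[1]]
  brush_sum <- measure_ring(img$marker, focus)
  expect_gt(brush_sum$n_ring_px, 0)
  # recompute the ring exactly as measure_ring defines it and check disjointness
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1),
                                            EBImage::makeBrush(7, "disc"))) > 0
  ring <- dil & !mask
  expect_false(any(ring & mask))
})

test_that("corrected intensity is independent of a constant offset", {
  scene <- one_spot_scene(amp = c(ACA = 1000, marker = 500))
  img <- generate_cell_image(scene)$image
  focus <- detect_foci(img$ACA)[1, ]
  bg <- matrix(FALSE, 128, 128); bg[1:10, 1:10] <- TRUE
  m0 <- measure_ring(img$marker, focus, background_region = bg)
  m50 <- measure_ring(img$marker + 50, focus, background_region = bg)
  expect_equal(m0$corrected, m50$corrected, tolerance = 1e-12)
  # brute-force oracle for the corrected value: mean over ring via pixel sums
  mask <- focus$mask[[1]]
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1),
                                            EBImage::makeBrush(7, "disc"))) > 0
  ring <- dil & !mask
  oracle <- sum(img$marker[ring]) / sum(ring) - sum(img$marker[bg]) / sum(bg)
  expect_equal(m0$corrected, oracle, tolerance = 1e-12)
})

test_that("corrected intensities are linear in the marker scale", {
  scene <- one_spot_scene(amp = c(ACA = 1000, marker = 500))
  img <- generate_cell_image(scene)$image
  focus <- detect_foci(img$ACA)[1, ]
  bg <- matrix(FALSE, 128, 128); bg[1:10, 1:10] <- TRUE
  m1 <- measure_ring(img$marker, focus, background_region = bg)
  m3 <- measure_ring(img$marker * 3, focus, background_region = bg)
  expect_equal(m3$corrected, 3 * m1$corrected, tolerance = 1e-12)
})

test_that("corrected intensities are invariant to integer translation", {
  scene <- one_spot_scene(amp = c(ACA = 1000, marker = 500),
                          x_um = 3.0, y_um = 3.0)
  img <- generate_cell_image(scene)$image
  shift <- function(m, dr, dc) {
    out <- matrix(100, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  img2 <- list(ACA = shift(img$ACA, 5, 7), marker = shift(img$marker, 5, 7))
  bg <- matrix(FALSE, 128, 128); bg[1:10, 1:10] <- TRUE
  f1 <- detect_foci(img$ACA)[1, ]
  f2 <- detect_foci(img2$ACA)[1, ]
  expect_equal(f2$y_px - f1$y_px, 5, tolerance = 1e-6)
  expect_equal(f2$x_px - f1$x_px, 7, tolerance = 1e-6)
  m1 <- measure_ring(img$marker, f1, background_region = bg)
  m2 <- measure_ring(img2$marker, f2, background_region = bg)
  expect_equal(m1$corrected, m2$corrected, tolerance = 1e-9)
})

test_that("two conditions at true ring ratio 2:1 are recovered", {
  cc <- dplyr::bind_rows(
    cell_condition("high", n_cells = 3, n_spots = 12,
                   marker_amplitude = 600, seed = 100),
    cell_condition("low", n_cells = 3, n_spots = 12,
                   marker_amplitude = 300, seed = 200))
  kept <- cc[!cc$flagged, ]
  means <- tapply(kept$corrected, kept$condition, mean)
  expect_equal(unname(means["high"] / means["low"]), 2, tolerance = 0.05)
})

test_that("normalization maps the reference mean to exactly 1", {
  meas <- tibble::tibble(condition = c("ref", "ref", "ref", "kd", "kd"),
                         corrected = c(2, 3, 4, 1.4, 1.6),
                         flagged = FALSE)
  norm <- normalize_condition(meas, "ref")
  expect_equal(mean(norm$normalized[norm$condition == "ref"]), 1)
  expect_equal(mean(norm$normalized[norm$condition == "kd"]), 0.5)
  expect_error(normalize_condition(meas, "absent"), "not present")
  bad <- tibble::tibble(condition = "ref", corrected = -1, flagged = FALSE)
  expect_error(normalize_condition(bad, "ref"), "not positive")
})

test_that("recruitment ratio behaves at the identity and null points", {
  scene <- one_spot_scene(amp = c(GFP = 500), noise_sd = 0,
                          x_um = 4.0, y_um = 4.0)
  gfp <- generate_cell_image(scene)$image$GFP
  focus <- detect_foci(gfp)[1, ]
  bg <- matrix(FALSE, 128, 128); bg[1:10, 1:10] <- TRUE
  same <- recruitment_ratio(gfp, gfp, focus, bg, bg)
  expect_equal(same$ratio, 1)
  flat <- matrix(100, 128, 128)
  null <- recruitment_ratio(flat, gfp, focus, bg, bg)
  expect_equal(null$ratio, 0)
  # nonpositive GFP is excluded with a flag
  bad <- recruitment_ratio(gfp, flat, focus, bg, bg)
  expect_true(bad$flagged)
  expect_true(is.na(bad$ratio))
})

test_that("recruitment ratio recovers a 2x amplitude difference", {
  spots <- spot_truth(4.1, 4.1, sigma_um = 0.2,
                      amplitude = c(GFP = 500, marker = 1000))
  scene <- image_scene(channels = c("marker", "GFP"), spots = spots,
                       background = 100, noise_sd = 2, seed = 21)
  img <- generate_cell_image(scene)$image
  focus <- detect_foci(img$GFP)[1, ]
  rr <- recruitment_ratio(img$marker, img$GFP, focus)
  expect_equal(rr$ratio, 2, tolerance = 0.05)
})
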