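test_that("a spotless noiseless scene renders uniform background", {
  scene <- image_scene(width_px = 32, height_px = 24,
                       channels = c("ACA", "marker"),
                       background = c(ACA = 100, marker = 50))
  out <- generate_cell_image(scene)
  expect_true(all(out$image$ACA == 100))
  expect_true(all(out$image$marker == 50))
  expect_equal(dim(out$image$ACA), c(24, 32))
  expect_equal(nrow(out$truth), 0)
})

test_that("a single spot matches the closed-form Gaussian at the centroid", {
  px <- 0.0645
  # centroid exactly on a pixel centre so the rendered max is the peak value
  cx <- (64 - 0.5) * px
  scene <- image_scene(channels = "ACA",
                       spots = spot_truth(cx, cx, sigma_um = 0.15,
                                          amplitude = c(ACA = 1000)),
                       background = 100)
  img <- generate_cell_image(scene)$image$ACA
  expect_equal(max(img), 1000 + 100, tolerance = 1e-12)
  expect_equal(which(img == max(img), arr.ind = TRUE)[1, ], c(row = 64, col = 64))
  # closed-form value one pixel away
  expect_equal(img[64, 65], 100 + 1000 * exp(-px^2 / (2 * 0.15^2)),
               tolerance = 1e-12)
})

test_that("identical seeds give bit-identical images and event lists", {
  scene <- one_spot_scene(amp = c(ACA = 1000), noise_sd = 10, seed = 42)
  expect_identical(generate_cell_image(scene), generate_cell_image(scene))
  mix <- mass_mixture(data.frame(mean_kD = 193, sd_kD = 29, weight = 1),
                      n_events = 100, seed = 5)
  expect_identical(generate_mass_events(mix), generate_mass_events(mix))
})

test_that("integrated spot intensity above background matches amplitude * 2*pi*sigma_px^2", {
  px <- 0.0645
  for (sigma in c(0.1, 0.15, 0.25)) {
    scene <- one_spot_scene(amp = c(ACA = 800), sigma_um = sigma)
    img <- generate_cell_image(scene)$image$ACA
    integral <- sum(img - 100)
    expect_equal(integral, 800 * 2 * pi * (sigma / px)^2, tolerance = 0.01)
  }
})

test_that("invalid scenes are rejected with explanatory errors", {
  expect_error(image_scene(pixel_size_um = 0),
               "pixel_size_um must be positive")
  expect_error(
    image_scene(width_px = 32, height_px = 32,
                spots = spot_truth(10, 10, amplitude = c(ACA = 1))),
    "outside")
  expect_error(
    image_scene(channels = "ACA",
                spots = spot_truth(1, 1, amplitude = c(GFP = 1))),
    "not in the scene")
})

test_that("spread pairs place two ACA foci at the requested separation", {
  scene <- image_scene(channels = c("ACA", "marker"),
                       spots = spot_truth(4, 4,
                                          amplitude = c(ACA = 1000,
                                                        marker = 800),
                                          pair_id = 1),
                       background = 100)
  sp <- generate_spread_image(scene, inter_kt_sep_um = 1,
                              axis_angle_rad = 0)
  aca <- sp$truth[!is.na(sp$truth$pair_id), ]
  expect_equal(nrow(aca), 2)
  sep <- sqrt(diff(aca$x_um)^2 + diff(aca$y_um)^2)
  expect_equal(sep, 1, tolerance = 1e-12)
})

test_that("spread truth stores the analytic marker FWHM per pool model", {
  mk_scene <- function(pool) {
    image_scene(channels = c("ACA", "marker"),
                spots = spot_truth(4, 4, sigma_um = 0.15,
                                   amplitude = c(ACA = 1000, marker = 800),
                                   pair_id = 1, pool_model = pool),
                background = 0)
  }
  inner <- generate_spread_image(mk_scene("inner_only"), 1, axis_angle_rad = 0)
  expect_equal(inner$pairs$true_fwhm_um, 2 * sqrt(2 * log(2)) * 0.15,
               tolerance = 1e-3)
  # dual pools at +/- 0.4 um: outermost half-max width ~ 0.8 + 2.3548*sigma
  dual <- generate_spread_image(mk_scene("dual_pool"), 1, axis_angle_rad = 0)
  expect_equal(dual$pairs$true_fwhm_um, 0.8 + 0.353, tolerance = 0.01)
  expect_gt(dual$pairs$true_fwhm_um, inner$pairs$true_fwhm_um)
})

test_that("degenerate or oversized separations are rejected", {
  scene <- image_scene(channels = c("ACA", "marker"),
                       spots = spot_truth(4, 4, amplitude = c(ACA = 1),
                                          pair_id = 1))
  expect_error(generate_spread_image(scene, 0), "inter_kt_sep_um")
  expect_error(generate_spread_image(scene, 2), "inter_kt_sep_um")
})

test_that("mass event samples follow the stated mixture", {
  # single component: sample mean within ~2 standard errors
  ev <- generate_mass_events(mass_mixture(
    data.frame(mean_kD = 193, sd_kD = 29, weight = 1), 5000, seed = 2))
  expect_equal(length(ev), 5000)
  expect_lt(abs(mean(ev) - 193), 1.5)
  # sd -> 0 collapses onto the component mean
  one <- generate_mass_events(mass_mixture(
    data.frame(mean_kD = 150, sd_kD = 0, weight = 1), 1, seed = 1))
  expect_equal(one, 150)
  # balanced two-component mixture: mean at the weighted average
  two <- generate_mass_events(mass_mixture(
    data.frame(mean_kD = c(108.8, 94.8), sd_kD = 10, weight = 0.5),
    10000, seed = 3))
  expect_lt(abs(mean(two) - 101.8), 0.5)
  expect_error(mass_mixture(data.frame(mean_kD = numeric(),
                                       sd_kD = numeric(),
                                       weight = numeric()), 10),
               "at least one")
})

test_that("scene TIFF and truth CSV round-trip through disk", {
  scene <- one_spot_scene(amp = c(ACA = 1000, marker = 500))
  out <- generate_cell_image(scene)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_scene_tiff(out$image, tf, pixel_size_um = 0.0645)
  back <- read_scene_tiff(tf)
  expect_equal(names(back$image), c("ACA", "marker"))
  expect_equal(back$pixel_size_um, 0.0645)
  # 16-bit quantization: relative error bounded by scale / 2^16
  expect_lt(max(abs(back$image$ACA - out$image$ACA)), 1100 / 2^16 + 1e-9)

  cf <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(out$truth, cf)
  truth2 <- read_truth_csv(cf)
  expect_equal(truth2$x_um, out$truth$x_um)
  expect_equal(truth2$amplitude[[1]][["marker"]], 500)
})
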