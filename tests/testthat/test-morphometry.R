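test_that("voxel geometry multiplies out and validates", {
  g <- voxel_geometry()
  expect_equal(g$voxel_volume, 1.097^2 * 10)
  expect_error(voxel_geometry(0), "positive")
})

test_that("structure volume counts voxels and interpolates missing sections", {
  # one included section of 1000 px: 1000 * 1.097^2 * 10 um^3
  v <- structure_volume(1000, included = TRUE)
  expect_equal(as.numeric(v) * 1e9, 1000 * 1.097^2 * 10, tolerance = 1e-12)
  # a missing section flanked by 100 and 200 px is filled with 150
  v2 <- structure_volume(c(100, NA, 200), included = c(TRUE, FALSE, TRUE))
  expect_equal(attr(v2, "areas_px"), c(100, 150, 200))
  # no missing sections: plain voxel count times voxel volume
  areas <- c(10, 20, 30)
  v3 <- structure_volume(areas, included = rep(TRUE, 3))
  expect_equal(as.numeric(v3), sum(areas) * 1.097^2 * 10 / 1e9)
  # boundary gaps take the nearest included neighbour
  v4 <- structure_volume(c(NA, 10, 40, NA), included = c(FALSE, TRUE, TRUE,
                                                         FALSE))
  expect_equal(attr(v4, "areas_px"), c(10, 10, 40, 40))
  expect_error(structure_volume(c(NA, NA), included = c(FALSE, FALSE)),
               "all sections excluded")
})

test_that("envelope closes sub-element gaps and preserves larger ones", {
  geom <- voxel_geometry(pixel_size = 4, section_thickness = 10)
  band <- function(gap_px) {
    epi <- matrix(0, 60, 100); epi[20:39, 5:95] <- 1
    osn <- epi
    if (gap_px > 0) osn[, 48:(47 + gap_px)] <- 0
    list(epi = epi, osn = osn)
  }
  # continuous OSN support: closing is the identity on the band
  b0 <- band(0)
  e0 <- olfactory_envelope(list(b0$epi), list(b0$osn), included = TRUE,
                           disk_diameter = 80, geometry = geom)
  expect_equal(e0$masks[[1]], b0$epi)
  # 20 um gap (< 80 um element): closed, envelope continuous
  b1 <- band(5)
  e1 <- olfactory_envelope(list(b1$epi), list(b1$osn), included = TRUE,
                           disk_diameter = 80, geometry = geom)
  expect_equal(e1$masks[[1]], b0$epi)
  # 200 um gap: preserved, and the result equals a direct
  # dilation-then-erosion oracle on the expanded intersection
  b2 <- band(50)
  e2 <- olfactory_envelope(list(b2$epi), list(b2$osn), included = TRUE,
                           disk_diameter = 80, geometry = geom)
  expect_lt(sum(e2$masks[[1]]), sum(b0$epi))
  kern <- EBImage::makeBrush(2 * floor((80 / 4) / 2) + 1, "disc")
  pad <- nrow(kern)
  big <- matrix(0, 60 + 2 * pad, 100 + 2 * pad)
  big[pad + 1:60, pad + 1:100] <- b2$osn  # osn spans full thickness already
  oracle <- EBImage::erode(EBImage::dilate(big, kern), kern)
  expect_equal(e2$masks[[1]], matrix(oracle, nrow(big))[pad + 1:60, pad + 1:100])
  # envelope at least as large as the OSN/epithelium intersection
  expect_gte(sum(e2$masks[[1]]), sum(b2$osn * b2$epi))
  # closing is idempotent
  twice <- olfstereo:::close_disk(e2$masks[[1]], 80 / 4)
  expect_equal(twice, e2$masks[[1]])
  expect_error(olfactory_envelope(list(b0$epi), list(b0$osn), included = TRUE,
                                  disk_diameter = 2, geometry = geom),
               "pixel size")
})

test_that("Abercrombie correction applies the factor T/(T+D)", {
  expect_equal(abercrombie_correct(100, 10, 0), 100)
  expect_equal(abercrombie_correct(100, 10, 10), 50)
  expect_equal(abercrombie_correct(120, 10, 5), 80)
  expect_error(abercrombie_correct(-1, 10, 5), "non-negative")
})

test_that("volumetric density divides by thickness and section depth", {
  # 100 OSNs/mm over 100 um thickness and 10 um sections: 1e5 per mm^3
  d <- volumetric_density(linear_density(100, 0), thickness_estimate(mean = 100,
                                                                     sem = 0))
  expect_equal(d$mean, 1e5)
  expect_equal(d$sem, 0)
  # Fieller and delta SEMs agree to first order as input SEMs shrink
  for (rel in c(0.05, 0.01, 0.001)) {
    lin <- linear_density(80, 80 * rel)
    th <- thickness_estimate(mean = 70, sem = 70 * rel)
    sf <- volumetric_density(lin, th, 10, method = "fieller")$sem
    sd_ <- volumetric_density(lin, th, 10, method = "delta")$sem
    expect_lt(abs(sf - sd_) / sd_, 3 * rel)
  }
  expect_error(volumetric_density(linear_density(80, 1),
                                  thickness_estimate(mean = 1e-9, sem = 0)),
               NA)  # tiny but positive thickness is allowed
})

test_that("totals, surface area and ratios propagate as products/quotients", {
  tot <- total_osn(count_estimate(100, 10), 2)
  expect_equal(tot$mean, 200)
  expect_equal(tot$sem, 20)
  expect_equal(tot$ci90, c(200 - qnorm(0.95) * 20, 200 + qnorm(0.95) * 20))
  z <- total_osn(count_estimate(0, 0), 5)
  expect_equal(z$ci90, c(0, 0))
  a <- epithelium_surface_area(1, thickness_estimate(mean = 1000, sem = 0))
  expect_equal(a$mean, 1)   # 1 mm^3 / 1 mm
  expect_equal(a$sem, 0)
  expect_error(ratio_report(100, 0, 10), "positive")
})

test_that("sphere model divides by the sphere volume and is monotone", {
  one <- 4 / 3 * pi * (50 / 2000)^3
  expect_equal(sphere_glomerulus_count(one, 50)$count, 1L)
  set.seed(9)
  v <- 1.4
  counts <- vapply(c(50, 55, 60, 65, 70), function(d)
    sphere_glomerulus_count(v, d)$count_raw, numeric(1))
  expect_true(all(diff(counts) < 0))
  expect_error(sphere_glomerulus_count(1, 0), "positive")
})

test_that("interleaved sampling is exact for constant and linear profiles", {
  g <- voxel_geometry()
  const <- interleaved_error(rep(50, 40), rep(TRUE, 40), 4, g)
  expect_equal(const$percent_error, 0)
  expect_equal(interleaved_error(rep(50, 40), rep(TRUE, 40), 1, g)$percent_error,
               0)
  # linear ramp: interior interpolation exact, boundary extrapolation error
  # matches the closed-form fill
  areas <- as.numeric(1:40)
  r <- 4
  res <- interleaved_error(areas, rep(TRUE, 40), r, g)
  kept <- seq(1, 40, by = r)                       # 1, 5, ..., 37
  filled <- approx(kept, areas[kept], xout = 1:40, rule = 2)$y
  # oracle: interior is the ramp itself; beyond the last kept section the
  # fill is constant at areas[37]
  oracle <- c(1:37, rep(37, 3))
  expect_equal(filled, oracle)
  expect_equal(res$percent_error, abs(sum(oracle) - sum(areas)) / sum(areas) * 100)
  expect_error(interleaved_error(areas, rep(TRUE, 40), 40, g), "survive")
})

test_that("interleave report covers every structure of a series", {
  ser <- render_sections(make_phantom(tiny_phantom_config(
    n_sections = 16L, seed = 4, dropout_rate = 0, deform_amplitude = 0,
    banana_curvature = 0, noise_sd = 0)))
  rep <- interleave_report(ser, rates = c(2L, 4L))
  expect_equal(nrow(rep), 12)   # 6 structures x 2 rates
  expect_true(all(rep$percent_error >= 0))
  # constant per-section geometry: epithelium and bone interleave exactly
  expect_equal(rep$percent_error[rep$structure == "bone"], c(0, 0))
})

test_that("thickness measurement recovers the phantom epithelium thickness", {
  cfg <- tiny_phantom_config(seed = 6, dropout_rate = 0, deform_amplitude = 0,
                             banana_curvature = 0, noise_sd = 0)
  ser <- render_sections(make_phantom(cfg))
  th <- measure_epithelium_thickness(ser)
  t_px <- max(3, round(cfg$structure_geometry$epithelium_thickness_um /
                         cfg$pixel_size))
  expect_equal(th$mean, t_px * cfg$pixel_size, tolerance = 1e-9)
})
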