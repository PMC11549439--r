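test_that("intensity augmentation shifts whole channels within the amplitude", {
  set.seed(1)
  tile <- array(runif(32 * 32 * 4, 0.3, 0.7), dim = c(32, 32, 4))
  expect_identical(augment_intensity(tile, 0), tile)
  a1 <- augment_intensity(tile, 0.01, seed = 5)
  expect_identical(augment_intensity(tile, 0.01, seed = 5), a1)
  # one uniform offset per channel, |mean shift| bounded by the amplitude
  shifts <- vapply(1:4, function(ch) mean(a1[, , ch] - tile[, , ch]), numeric(1))
  expect_true(all(abs(shifts) <= 0.01 + 1e-12))
  per_px <- vapply(1:4, function(ch) diff(range(a1[, , ch] - tile[, , ch])),
                   numeric(1))
  expect_true(all(per_px < 1e-12))  # constant within each channel (no clip here)
  expect_error(augment_intensity(tile, -0.1), "non-negative")
})

test_that("tile assembly partitions the section and matches a one-pass oracle", {
  set.seed(2)
  ch <- list(a = matrix(runif(150 * 140), 150, 140))
  # coverage: a predictor returning 1 everywhere must tile to exactly 1
  ones <- tile_and_assemble(ch, function(t) matrix(1, dim(t)[1], dim(t)[2]),
                            tile_size = 64L, margin = 8L)
  expect_true(all(ones == 1))
  # a translation-invariant (pixel-wise) model must be seam-free and equal
  # the single-pass prediction
  pixmodel <- function(t) 0.2 + 0.6 * t[, , 1]
  assembled <- tile_and_assemble(ch, pixmodel, tile_size = 64L, margin = 8L)
  onepass <- 0.2 + 0.6 * ch$a
  expect_equal(assembled, onepass, tolerance = 1e-12)
  # section smaller than the tile: zero-padded and cropped back
  small <- list(a = matrix(runif(40 * 52), 40, 52))
  out <- tile_and_assemble(small, pixmodel, tile_size = 64L, margin = 8L)
  expect_equal(dim(out), c(40L, 52L))
  expect_equal(out, 0.2 + 0.6 * small$a, tolerance = 1e-12)
  expect_error(tile_and_assemble(ch, pixmodel, tile_size = 64L, margin = 40L),
               "margin")
})

test_that("metrics satisfy their definitions and the DSC identity", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[1, 1:4] <- 1                      # 4 px
  b[1, 3:4] <- 1; b[2, 1:2] <- 1      # 4 px, overlap 2
  m <- seg_metrics(a, b)
  expect_equal(m$dsc, 0.5)            # 2*2/(4+4)
  perfect <- seg_metrics(a, a)
  expect_equal(unlist(perfect[c("dsc", "precision", "recall")]), c(dsc = 1,
               precision = 1, recall = 1))
  disj <- matrix(0, 4, 4); disj[4, ] <- 1
  expect_equal(seg_metrics(a, disj)$dsc, 0)
  expect_error(seg_metrics(a, matrix(0, 3, 3)), "same")
  # DSC = 2PR/(P+R) on random mask pairs
  set.seed(3)
  for (i in 1:25) {
    x <- random_mask(12, 12, runif(1, 0.1, 0.7))
    y <- random_mask(12, 12, runif(1, 0.1, 0.7))
    mm <- seg_metrics(x, y)
    if (mm$precision + mm$recall > 0)
      expect_equal(mm$dsc, 2 * mm$precision * mm$recall /
                     (mm$precision + mm$recall))
  }
})

test_that("threshold selection equals an exhaustive-scan oracle", {
  set.seed(4)
  truth <- random_mask(20, 20, 0.3)
  # probabilities correlated with the truth
  prob <- 0.9 * truth + 0.1 * matrix(runif(400), 20, 20)
  grid <- seq(0.05, 0.95, by = 0.05)
  got <- select_threshold(prob, truth, grid)
  # plain-loop oracle
  best_t <- NA; best_d <- -1
  for (t in grid) {
    d <- dice((prob >= t) * 1, truth)
    if (d > best_d) { best_d <- d; best_t <- t }
  }
  expect_equal(got$threshold, best_t)
  expect_equal(got$dsc, best_d)
  # prob equal to a 0/1 truth: every interior cut-off is perfect, smallest wins
  perf <- select_threshold(truth, truth, grid)
  expect_equal(perf$threshold, grid[1])
  expect_equal(perf$dsc, 1)
  # all probabilities below the single candidate: DSC 0 at that candidate
  low <- select_threshold(matrix(0.4, 5, 5), matrix(1, 5, 5), grid = 0.5)
  expect_equal(low$threshold, 0.5)
  expect_equal(low$dsc, 0)
  expect_error(select_threshold(prob, matrix(0, 20, 20)), "empty truth")
})

test_that("staged training improves validation Dice and is deterministic", {
  cfg <- phantom_config(grid_shape = c(6L, 64L, 64L), pixel_size = 3.2,
                        noise_sd = 0.02, deform_amplitude = 0.5,
                        banana_curvature = 0, dropout_rate = 0, seed = 31,
                        structure_geometry = list(vessel_radius_um = 18,
                                                  n_vessels = 5L))
  ser <- render_sections(make_phantom(cfg))
  model <- build_unet(unet_config(tile_size = 32L), seed = 42)
  # zero stages: model returned unchanged with empty history
  un <- train_unet(model, ser$sections[1:4], ser$sections[5:6], "vasculature",
                   train_plan(stages = list(), seed = 1))
  expect_identical(un$layers, model$layers)
  expect_equal(nrow(un$history), 0)
  plan <- train_plan(stages = list(c(3e-3, 3)), batch_size = 4L,
                     steps_per_epoch = 6L, seed = 7)
  fit <- train_unet(model, ser$sections[1:4], ser$sections[5:6],
                    "vasculature", plan)
  expect_gt(fit$history$val_dsc[nrow(fit$history)], fit$history$val_dsc[1])
  expect_true(fit$threshold > 0 && fit$threshold < 1)
  # identical seed and data give an identical history
  fit2 <- train_unet(model, ser$sections[1:4], ser$sections[5:6],
                     "vasculature", plan)
  expect_identical(fit$history, fit2$history)
  # training on a structure absent everywhere is a degenerate class balance
  empty <- lapply(ser$sections[1:2], function(s) {
    s$masks$glomeruli <- s$masks$glomeruli * 0
    s
  })
  expect_error(train_unet(model, empty, ser$sections[5:6], "glomeruli", plan),
               "empty")
})

test_that("training plans validate their schedule", {
  expect_error(train_plan(stages = list(c(1e-4, 10), c(1e-4, 10))),
               "strictly decreasing")
  expect_error(train_plan(stages = list(c(1e-4, 0))), "positive")
})
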