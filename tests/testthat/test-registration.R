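test_that("combined mask is the pixel-wise Boolean OR", {
  v <- matrix(c(1, 0), 1, 2); e <- matrix(c(0, 1), 1, 2)
  expect_equal(combined_mask(v, e), matrix(c(1, 1), 1, 2))
  expect_equal(combined_mask(v, v), v)                 # idempotent
  z <- matrix(0, 2, 2)
  expect_equal(combined_mask(z, z), z)
  expect_error(combined_mask(v, matrix(0, 2, 2)), "same")
})

test_that("block partition gives contiguous runs with a remainder block", {
  b <- partition_blocks(1:10, 5)
  expect_length(b, 2)
  expect_equal(b[[2]]$section_indices, 6:10)
  expect_length(partition_blocks(1:3, 5), 1)
  # the complete dataset size of the specimen: 1234 sections -> 247 blocks
  blocks <- partition_blocks(seq_len(1234), 5)
  expect_length(blocks, 247)
  sizes <- vapply(blocks, function(x) length(x$section_indices), integer(1))
  expect_equal(sum(sizes == 5), 246)
  expect_equal(sizes[247], 4L)
  expect_error(partition_blocks(integer(0)), "no included")
})

test_that("intra-block reference maximises the sum of pairwise Dice", {
  A <- matrix(0, 4, 4); A[1:2, 1:2] <- 1
  C <- matrix(0, 4, 4); C[3:4, 3:4] <- 1
  masks <- list(`3` = A, `4` = A, `5` = C)
  expect_equal(select_intrablock_reference(masks), 3)  # tie A/A -> lowest index
  same <- list(`7` = A, `8` = A, `9` = A)
  expect_equal(select_intrablock_reference(same), 7)
  # brute-force oracle on random masks
  set.seed(5)
  for (rep in 1:10) {
    ms <- lapply(1:5, function(i) random_mask(8, 8, 0.4))
    names(ms) <- 10 + 1:5
    score <- vapply(1:5, function(i)
      sum(vapply(1:5, function(j) dice(ms[[i]], ms[[j]]), numeric(1))),
      numeric(1))
    expect_equal(select_intrablock_reference(ms),
                 as.integer(names(ms))[which.max(score)])
  }
  expect_error(select_intrablock_reference(list()), "empty")
})

test_that("interface pair selection equals the 25-pair brute force", {
  A <- matrix(0, 4, 4); A[1:2, ] <- 1
  B <- matrix(0, 4, 4); B[3:4, ] <- 1
  ants <- list(`4` = B, `5` = A)
  post <- list(`6` = A, `7` = B)
  expect_equal(unname(select_interblock_pair(ants, post)), c(4, 7))
  # all pairs tie: lexicographically smallest
  ties <- select_interblock_pair(list(`1` = A, `2` = A), list(`3` = A, `4` = A))
  expect_equal(unname(ties), c(1, 3))
  set.seed(6)
  for (rep in 1:8) {
    ma <- lapply(1:5, function(i) random_mask(8, 8, 0.4)); names(ma) <- 1:5
    mb <- lapply(1:5, function(i) random_mask(8, 8, 0.4)); names(mb) <- 6:10
    best <- c(NA, NA); bd <- -1
    for (i in 1:5) for (j in 1:5) {
      d <- dice(ma[[i]], mb[[j]])
      if (d > bd) { bd <- d; best <- c(i, 5 + j) }
    }
    expect_equal(unname(select_interblock_pair(ma, mb)), best)
  }
})

test_that("interface interpolation scales the field exactly as (i-1)/N", {
  phi <- displacement_field(matrix(8, 6, 6), matrix(0, 6, 6))
  fields <- interblock_interpolate(phi, 4)
  expect_equal(fields[[1]]$r, matrix(0, 6, 6))          # (1-1)/N = 0
  expect_equal(fields[[4]]$r, matrix(6, 6, 6))          # 3/4 of 8
  half <- interblock_interpolate(phi, 2)[[2]]
  expect_equal(half$r, phi$r / 2)
  # exact per-pixel scaling for an arbitrary smooth field
  set.seed(7)
  phi2 <- bspline_field(matrix(rnorm(25), 5, 5), matrix(rnorm(25), 5, 5),
                        c(12, 12))
  fs <- interblock_interpolate(phi2, 5)
  for (i in seq_len(5)) {
    expect_equal(fs[[i]]$r, phi2$r * (i - 1) / 5)
    expect_equal(fs[[i]]$c, phi2$c * (i - 1) / 5)
  }
  expect_error(interblock_interpolate(phi, 0), "at least 1")
})

test_that("field application and composition behave as transforms", {
  img <- matrix(0, 6, 6); img[3, 3] <- 1
  expect_identical(apply_field(img, zero_field(c(6, 6))), img)
  shift <- displacement_field(matrix(2, 6, 6), matrix(0, 6, 6))
  out <- apply_field(img, shift, "nearest")
  expect_equal(which(out == 1, arr.ind = TRUE)[1, ], c(row = 1, col = 3))
  expect_true(all(apply_field(img, shift, "nearest") %in% c(0, 1)))
  expect_error(apply_field(img, zero_field(c(4, 4))), "shape")
  # composing two constant shifts adds them
  s1 <- displacement_field(matrix(1, 9, 9), matrix(0, 9, 9))
  s2 <- displacement_field(matrix(0, 9, 9), matrix(2, 9, 9))
  comp <- compose_fields(s1, s2)
  expect_equal(comp$r, matrix(1, 9, 9))
  expect_equal(comp$c, matrix(2, 9, 9))
})

test_that("pair registration recovers identity and a known translation", {
  cfg <- tiny_phantom_config(n_sections = 4L, side = 96L, pixel = 1.6,
                             seed = 5, noise_sd = 0.01, deform_amplitude = 0,
                             banana_curvature = 0, dropout_rate = 0)
  ph <- make_phantom(cfg)
  fix <- slice_channels(ph, 2)
  rc <- registration_config(bspline_levels = 0, mask_levels = 0)
  f0 <- register_pair_intensity(fix, fix, rc)
  expect_lt(field_magnitude(f0), 0.1)
  # content translated by (5, 3) px (integer shift: exact resampling)
  mov <- lapply(fix, function(m)
    apply_field(m, displacement_field(matrix(-5, 96, 96), matrix(-3, 96, 96)),
                "linear"))
  fld <- register_pair_intensity(fix, mov, rc)
  expect_lt(abs(mean(fld$r) - 5), 0.5)
  expect_lt(abs(mean(fld$c) - 3), 0.5)
  expect_error(register_pair_intensity(fix, lapply(fix, function(m) m * NA),
                                       rc), "finite")
})

test_that("mask refinement never degrades and skips empty fixed masks", {
  cfg <- tiny_phantom_config(n_sections = 4L, side = 64L, pixel = 3.2,
                             seed = 8, noise_sd = 0, deform_amplitude = 0,
                             banana_curvature = 0, dropout_rate = 0)
  ph <- make_phantom(cfg)
  cm <- combined_mask(ph$labels$vasculature[, , 2], ph$labels$nasal_epithelium[, , 2])
  rc <- registration_config()
  z <- zero_field(dim(cm))
  # identical masks under a zero init: near-zero refined field
  f1 <- register_pair_mask(cm, cm, z, rc)
  expect_lt(field_magnitude(f1), 0.25)
  expect_gte(dice(cm, apply_field(cm, f1, "nearest")), dice(cm, cm) - 1e-12)
  # small residual shift: refinement must not reduce the Dice
  mshift <- apply_field(cm, displacement_field(matrix(-2, 64, 64),
                                               matrix(0, 64, 64)), "nearest")
  f2 <- register_pair_mask(cm, mshift, z, rc)
  expect_gte(dice(cm, apply_field(mshift, f2, "nearest")),
             dice(cm, mshift))
  # empty fixed mask: warning, init field returned untouched
  expect_warning(f3 <- register_pair_mask(cm * 0, cm, z, rc), "empty")
  expect_identical(f3, z)
})

test_that("block registration aligns jittered sections to the reference", {
  cfg <- tiny_phantom_config(n_sections = 5L, side = 64L, pixel = 3.2,
                             seed = 12, noise_sd = 0.01, deform_amplitude = 0,
                             banana_curvature = 0, dropout_rate = 0)
  ser <- render_sections(make_phantom(cfg))
  rc <- registration_config(bspline_levels = 0, mask_levels = 0,
                            transform = "translation")
  # identical sections: all fields about zero
  same <- lapply(1:3, function(i) {
    s <- ser$sections[[1]]; s$index <- i; s
  })
  reg0 <- register_block(same, rc)
  for (f in reg0$fields) expect_lt(field_magnitude(f), 0.1)
  # known per-section offsets are recovered
  offs <- list(c(0, 0), c(3, -2), c(-2, 4))
  shifted <- lapply(seq_along(offs), function(i) {
    s <- ser$sections[[1]]
    fld <- displacement_field(matrix(-offs[[i]][1], 64, 64),
                              matrix(-offs[[i]][2], 64, 64))
    s$channels <- lapply(s$channels, apply_field, field = fld, mode = "linear")
    s$masks <- lapply(s$masks, apply_field, field = fld, mode = "nearest")
    s$index <- i
    s
  })
  regs <- register_block(shifted, rc)
  ref_off <- offs[[match(regs$reference_index, 1:3)]]
  for (i in 1:3) {
    expected <- offs[[i]] - ref_off
    fld <- regs$fields[[as.character(i)]]
    expect_lt(abs(mean(fld$r) - expected[1]), 0.5)
    expect_lt(abs(mean(fld$c) - expected[2]), 0.5)
  }
  # jittered phantom block: mean pairwise combined-mask Dice non-decreasing
  cfgj <- tiny_phantom_config(n_sections = 5L, side = 64L, pixel = 3.2,
                              seed = 13, noise_sd = 0.01,
                              deform_amplitude = 1.2, banana_curvature = 0,
                              dropout_rate = 0)
  serj <- render_sections(make_phantom(cfgj))
  regj <- register_block(serj$sections, registration_config(
    bspline_levels = 2, mask_levels = 2, bspline_iterations = 8))
  pair_mean <- function(secs) {
    cms <- lapply(secs, olfstereo:::section_combined)
    mean(unlist(lapply(1:4, function(i)
      vapply((i + 1):5, function(j) dice(cms[[i]], cms[[j]]), numeric(1)))))
  }
  expect_gte(pair_mean(regj$sections), pair_mean(serj$sections))
})

test_that("series registration handles single blocks and improves alignment", {
  cfg <- tiny_phantom_config(n_sections = 4L, side = 64L, pixel = 3.2,
                             seed = 14, noise_sd = 0.01,
                             deform_amplitude = 0, banana_curvature = 0,
                             dropout_rate = 0)
  base <- render_sections(make_phantom(cfg))
  # rigid per-section jitter, which this configuration is built to remove
  set.seed(22)
  jitter <- lapply(1:4, function(i) {
    s <- base$sections[[i]]
    off <- runif(2, -2.5, 2.5)
    fld <- displacement_field(matrix(off[1], 64, 64), matrix(off[2], 64, 64))
    s$channels <- lapply(s$channels, apply_field, field = fld, mode = "linear")
    s$masks <- lapply(s$masks, apply_field, field = fld, mode = "nearest")
    s
  })
  ser <- section_series(jitter, n_cut = 4, pixel_size = 3.2)
  rc <- registration_config(bspline_levels = 0, mask_levels = 2,
                            bspline_iterations = 8)
  reg <- register_series(ser, rc, method = "block")
  # a single-block series equals the plain block registration
  blk <- register_block(ser$sections, rc)
  for (i in 1:4)
    expect_identical(reg$series$sections[[i]]$masks, blk$sections[[i]]$masks)
  expect_gte(adjacent_dice(reg$series), adjacent_dice(ser))
  expect_error(register_series(section_series(ser$sections[1], n_cut = 1),
                               rc), "at least 2")
})

test_that("blocks are processed independently of execution order", {
  cfg <- tiny_phantom_config(n_sections = 10L, side = 64L, pixel = 3.2,
                             seed = 15, noise_sd = 0.01,
                             deform_amplitude = 0.8, banana_curvature = 0,
                             dropout_rate = 0)
  ser <- render_sections(make_phantom(cfg))
  rc <- registration_config(bspline_levels = 0, mask_levels = 0,
                            transform = "translation")
  b1 <- register_block(ser$sections[1:5], rc)
  b2 <- register_block(ser$sections[6:10], rc)
  b2_again <- register_block(ser$sections[6:10], rc)  # after b1, same result
  expect_identical(b2, b2_again)
  # standalone block results match the non-bridged sections of the series run
  reg <- register_series(ser, rc, method = "block")
  expect_identical(reg$series$sections[[2]]$masks, b1$sections[[2]]$masks)
})
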