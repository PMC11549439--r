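# Shared fixture builders: all data is generated in code at test time.

# A small virtual specimen; geometry stays in micrometres, so smaller grids
# use a coarser pixel to keep the anatomy inside the field of view.
tiny_phantom_config <- function(n_sections = 8L, side = 64L, pixel = 3.2,
                                seed = 1L, ...) {
  phantom_config(grid_shape = c(n_sections, side, side), pixel_size = pixel,
                 seed = seed, ...)
}

# Channels of one phantom section as a named list.
slice_channels <- function(phantom, z) {
  ch <- lapply(names(phantom$channels), function(nm) phantom$channels[[nm]][, , z])
  names(ch) <- names(phantom$channels)
  ch
}

# Random binary mask with roughly the given foreground fraction.
random_mask <- function(h, w, p = 0.3) {
  matrix(as.numeric(runif(h * w) < p), h, w)
}

# A pair of images sampled from one supersampled smooth scene displaced by an
# integer number of fine-grid pixels: the subpixel shift at the target
# resolution is exact by construction (no interpolation enters the truth).
supersampled_pair <- function(side = 96L, factor = 10L, shift_fine = c(53L, 20L),
                              seed = 7L) {
  set.seed(seed)
  big <- side * factor + max(shift_fine) + factor
  hi <- matrix(rnorm(big * big), big, big)
  k <- exp(-outer(-30:30, -30:30, function(a, b) a^2 + b^2) / (2 * 8^2))
  hi <- as.matrix(EBImage::filter2(hi, k / sum(k)))
  hi <- (hi - min(hi)) / diff(range(hi))
  n <- side * factor
  fix <- olfstereo:::block_reduce(hi[1:n, 1:n], factor)
  mov <- olfstereo:::block_reduce(hi[1:n + shift_fine[1], 1:n + shift_fine[2]],
                                  factor)
  list(fixed = fix, moving = mov, shift = shift_fine / factor)
}
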