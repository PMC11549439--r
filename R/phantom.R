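# The virtual specimen contains six binary structures rendered into four
# fluorescence channels; names are fixed across the whole package.
STRUCTURES <- c("nasal_epithelium", "osn", "glomeruli", "olfactory_bulb",
                "vasculature", "bone")
CHANNELS <- c("hoechst", "uea1", "omp", "vglut2")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_stain_model <- function() {
  m <- matrix(0, 4, 6, dimnames = list(CHANNELS, STRUCTURES))
  # Hoechst marks nuclei everywhere; UEA1 the epithelium (and vessel walls);
  # OMP mature OSNs and their axon terminals in glomeruli; VGLUT2 glomeruli.
  m["hoechst", ] <- c(0.55, 0.25, 0.30, 0.45, 0.50, 0.20)
  m["uea1", ]    <- c(0.75, 0.10, 0.00, 0.00, 0.35, 0.00)
  m["omp", ]     <- c(0.00, 0.85, 0.55, 0.00, 0.00, 0.00)
  m["vglut2", ]  <- c(0.00, 0.25, 0.85, 0.05, 0.00, 0.00)
  m
}

#' Configuration for the virtual en-bloc specimen
#'
#' Assembles and validates the parameters of the synthetic specimen: grid
#' size, voxel geometry, structure geometry, the per-channel stain model,
#' section-to-section deformation, global curvature, and section dropout.
#'
#' @param grid_shape integer vector `(n_sections, height_px, width_px)`.
#' @param pixel_size in-plane pixel size in micrometres.
#' @param section_thickness section thickness in micrometres.
#' @param structure_geometry list with elements `epithelium_thickness_um`,
#'   `osn_patch_density` (fraction of epithelium columns carrying OSNs),
#'   `n_osn_patches`, `vessel_radius_um`, `n_vessels`, `bulb_axes_um`
#'   (row/column/depth semi-axes), `glomerular_shell_frac` (normalised shell
#'   thickness inside the bulb) and `bone_thickness_um`. Missing elements
#'   fall back to defaults sized for the default grid.
#' @param stain_model 4 x 6 matrix of staining intensities in `[0, 1]`
#'   (channels x structures).
#' @param noise_sd standard deviation of the additive Gaussian channel
#'   noise (clipped to `[0, 1]`).
#' @param deform_amplitude maximum per-section smooth deformation, in px.
#' @param banana_curvature lateral offset per squared section index
#'   (px / section^2) implementing the global specimen curvature.
#' @param dropout_rate fraction of cut sections excluded from the dataset.
#' @param clustered_dropout if `TRUE`, exclusions are drawn as contiguous
#'   runs rather than independently per section.
#' @param seed integer seed; identical configuration and seed give
#'   bit-identical output.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(60L, 128L, 128L),
                           pixel_size = 1.097,
                           section_thickness = 10,
                           structure_geometry = list(),
                           stain_model = default_stain_model(),
                           noise_sd = 0.02,
                           deform_amplitude = 1.5,
                           banana_curvature = 0.001,
                           dropout_rate = 0.358,
                           clustered_dropout = FALSE,
                           seed = 1L) {
  geom <- modifyList(list(
    epithelium_thickness_um = 28,
    osn_patch_density = 0.6,
    n_osn_patches = 4L,
    vessel_radius_um = 5,
    n_vessels = 6L,
    bulb_axes_um = c(26, 34, 160),
    glomerular_shell_frac = 0.25,
    bone_thickness_um = 10
  ), structure_geometry)
  if (length(grid_shape) != 3 || any(grid_shape < 1))
    stop_olf("grid_shape must be three positive integers")
  if (pixel_size <= 0 || section_thickness <= 0)
    stop_olf("voxel geometry must be strictly positive")
  gnum <- unlist(geom[c("epithelium_thickness_um", "osn_patch_density",
                        "vessel_radius_um", "bulb_axes_um",
                        "glomerular_shell_frac", "bone_thickness_um")])
  if (any(gnum <= 0)) stop_olf("all geometric parameters must be strictly positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_olf("dropout_rate must lie in [0, 1)")
  if (deform_amplitude < 0) stop_olf("deform_amplitude must be non-negative")
  if (!identical(dim(stain_model), c(4L, 6L)))
    stop_olf("stain_model must be a 4 x 6 matrix (channels x structures)")
  structure(list(
    grid_shape = as.integer(grid_shape), pixel_size = pixel_size,
    section_thickness = section_thickness, structure_geometry = geom,
    stain_model = stain_model, noise_sd = noise_sd,
    deform_amplitude = deform_amplitude, banana_curvature = banana_curvature,
    dropout_rate = dropout_rate, clustered_dropout = clustered_dropout,
    seed = as.integer(seed)), class = "phantom_config")
}

#' Build the 3D virtual specimen
#'
#' Generates one binary 3D volume per anatomical structure and the four
#' stained channel volumes. Containment invariants hold by construction:
#' glomeruli lie inside the olfactory bulb, OSNs inside the nasal
#' epithelium, and vasculature never intersects the epithelium.
#'
#' @param config a [phantom_config()].
#' @return A list with elements `labels` (named list of six binary
#'   `H x W x Z` arrays), `channels` (named list of four intensity arrays in
#'   `[0, 1]`) and `config`.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  Z <- config$grid_shape[1]; H <- config$grid_shape[2]; W <- config$grid_shape[3]
  px <- config$pixel_size; g <- config$structure_geometry

  epi_t <- max(3L, as.integer(round(g$epithelium_thickness_um / px)))
  epi_top <- as.integer(round(0.52 * H))
  bone_top <- as.integer(round(0.78 * H))
  bone_t <- max(2L, as.integer(round(g$bone_thickness_um / px)))
  if (epi_top + epi_t >= bone_top || bone_top + bone_t > H)
    stop_olf("configuration error: epithelium/bone geometry does not fit the grid")
  c0 <- as.integer(round(0.08 * W)); c1 <- as.integer(round(0.92 * W))

  ar <- g$bulb_axes_um[1] / px; ac <- g$bulb_axes_um[2] / px
  az <- g$bulb_axes_um[3] / config$section_thickness
  bulb_r <- 0.25 * H; bulb_c <- 0.5 * W; bulb_z <- (Z + 1) / 2
  if (bulb_r + ar >= epi_top - 1)
    stop_olf("configuration error: olfactory bulb does not fit above the epithelium")

  vr <- g$vessel_radius_um / px
  if (2 * vr + 4 >= epi_top)
    stop_olf("configuration error: vessel radius too large for the grid")

  with_seed(config$seed, {
    lab <- lapply(STRUCTURES, function(s) array(0, dim = c(H, W, Z)))
    names(lab) <- STRUCTURES
    rows <- seq_len(H); cols <- seq_len(W)

    epi_band <- matrix(0, H, W)
    epi_band[epi_top:(epi_top + epi_t - 1L), c0:c1] <- 1
    bone_band <- matrix(0, H, W)
    bone_band[bone_top:(bone_top + bone_t - 1L), ] <- 1

    # OSN patches: contiguous column intervals covering ~osn_patch_density
    # of the epithelium width, identical across sections (3D coherence).
    np <- g$n_osn_patches
    span <- c1 - c0 + 1L
    wids <- runif(np); wids <- wids / sum(wids) * g$osn_patch_density * span
    gaps <- runif(np + 1); gaps <- gaps / sum(gaps) * (1 - g$osn_patch_density) * span
    osn_cols <- logical(W)
    pos <- c0
    for (p in seq_len(np)) {
      pos <- pos + gaps[p]
      a <- as.integer(round(pos)); b <- as.integer(round(pos + wids[p]))
      osn_cols[max(c0, a):min(c1, max(a, b))] <- TRUE
      pos <- pos + wids[p]
    }
    osn_band <- epi_band * rep(as.numeric(osn_cols), each = H)

    # Vessels: tubes above the epithelium with a sinusoidal in-plane drift.
    nv <- g$n_vessels
    v_r0 <- runif(nv, vr + 2, epi_top - vr - 3)
    v_c0 <- runif(nv, vr + 2, W - vr - 2)
    v_amp <- runif(nv, 0, 0.04 * W)
    v_ph <- runif(nv, 0, 2 * pi)

    rc <- outer(rows, rep(1, W)); cc <- outer(rep(1, H), cols)
    for (z in seq_len(Z)) {
      lab$nasal_epithelium[, , z] <- epi_band
      lab$osn[, , z] <- osn_band
      lab$bone[, , z] <- bone_band
      rho2 <- ((rc - bulb_r) / ar)^2 + ((cc - bulb_c) / ac)^2 +
        ((z - bulb_z) / az)^2
      bulb <- (rho2 <= 1) * 1
      glom <- (rho2 <= 1 & rho2 >= (1 - g$glomerular_shell_frac)^2) * 1
      lab$olfactory_bulb[, , z] <- bulb
      lab$glomeruli[, , z] <- glom
      ves <- matrix(0, H, W)
      for (v in seq_len(nv)) {
        czv <- v_c0[v] + v_amp[v] * sin(2 * pi * z / Z + v_ph[v])
        ves[(rc - v_r0[v])^2 + (cc - czv)^2 <= vr^2] <- 1
      }
      ves[epi_band == 1] <- 0  # no vasculature within the epithelium
      lab$vasculature[, , z] <- ves
    }

    chans <- lapply(CHANNELS, function(ch) {
      v <- array(0, dim = c(H, W, Z))
      for (s in STRUCTURES) v <- v + config$stain_model[ch, s] * lab[[s]]
      v <- pmin(v, 1)
      if (config$noise_sd > 0)
        v <- pmin(pmax(v + rnorm(length(v), 0, config$noise_sd), 0), 1)
      v
    })
    names(chans) <- CHANNELS
    list(labels = lab, channels = chans, config = config)
  })
}

#' Render the phantom into a section series
#'
#' Slices the 3D phantom into serial sections and applies, per section, (i) a
#' rigid lateral shift quadratic in the section index (the "banana"
#' curvature) and (ii) a smooth random deformation of bounded amplitude.
#' Ground-truth masks are warped with the identical transform using
#' nearest-neighbour resampling, so containment invariants survive the warp.
#' Sections are excluded by a seeded Bernoulli draw at the configured
#' dropout rate.
#'
#' @param phantom result of [make_phantom()].
#' @param config the same [phantom_config()]; defaults to the one stored in
#'   the phantom.
#' @return A `section_series` (see [section_series()]).
#' @export
render_sections <- function(phantom, config = phantom$config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$deform_amplitude < 0) stop_olf("deform_amplitude must be non-negative")
  Z <- config$grid_shape[1]; H <- config$grid_shape[2]; W <- config$grid_shape[3]
  with_seed(config$seed + 1L, {
    if (config$clustered_dropout) {
      excl <- logical(Z)
      while (mean(excl) < config$dropout_rate && config$dropout_rate > 0) {
        st <- sample.int(Z, 1); len <- 1 + rpois(1, 3)
        excl[st:min(Z, st + len - 1)] <- TRUE
      }
    } else {
      excl <- runif(Z) < config$dropout_rate
    }
    sections <- vector("list", Z)
    for (z in seq_len(Z)) {
      shift_c <- config$banana_curvature * z^2
      fr <- matrix(0, H, W); fc <- matrix(-shift_c, H, W)
      if (config$deform_amplitude > 0) {
        amp <- config$deform_amplitude
        fr <- fr + .bspline_field_kernel(
          matrix(runif(16, -amp, amp), 4, 4), H, W)
        fc <- fc + .bspline_field_kernel(
          matrix(runif(16, -amp, amp), 4, 4), H, W)
      }
      field <- displacement_field(fr, fc)
      identity_tf <- config$deform_amplitude == 0 && shift_c == 0
      chans <- lapply(CHANNELS, function(ch) {
        sl <- phantom$channels[[ch]][, , z]
        if (identity_tf) sl else apply_field(sl, field, mode = "linear")
      })
      names(chans) <- CHANNELS
      masks <- lapply(STRUCTURES, function(s) {
        sl <- phantom$labels[[s]][, , z]
        if (identity_tf) sl else apply_field(sl, field, mode = "nearest")
      })
      names(masks) <- STRUCTURES
      sections[[z]] <- section_record(z, chans, masks, included = !excl[z])
    }
    section_series(sections, n_cut = Z, pixel_size = config$pixel_size,
                   section_thickness = config$section_thickness)
  })
}

#' Simulate manual OSN counts on a section series
#'
#' Emulates the manual counting step of the stereological chain: for each
#' included section carrying OSNs, the OSN-bearing epithelium length is
#' measured from the ground-truth masks and a Poisson count is drawn at the
#' requested true linear density.
#'
#' @param series a `section_series`.
#' @param linear_density true OSN count per mm of OSN-bearing epithelium.
#' @param seed integer seed for the Poisson draws.
#' @return data frame with columns `index`, `length_mm`, `count`.
#' @export
simulate_osn_counts <- function(series, linear_density, seed = 1L) {
  stopifnot(inherits(series, "section_series"))
  if (linear_density <= 0) stop_olf("linear_density must be positive")
  with_seed(seed, {
    out <- lapply(series$sections, function(s) {
      if (!s$included) return(NULL)
      osn_cols <- colSums(s$masks$osn) > 0
      L <- sum(osn_cols) * series$pixel_size / 1000
      if (L <= 0) return(NULL)
      data.frame(index = s$index, length_mm = L,
                 count = rpois(1, linear_density * L))
    })
    do.call(rbind, out)
  })
}
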