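#' Voxel geometry of the section series
#'
#' @param pixel_size in-plane pixel size, micrometres (default 1.097).
#' @param section_thickness section thickness, micrometres (default 10).
#' @return List with `pixel_size`, `section_thickness` and `voxel_volume`
#'   (um^3, the product `pixel_size^2 * section_thickness`).
#' @export
voxel_geometry <- function(pixel_size = 1.097, section_thickness = 10) {
  if (pixel_size <= 0 || section_thickness <= 0)
    stop_olf("voxel geometry must be strictly positive")
  list(pixel_size = pixel_size, section_thickness = section_thickness,
       voxel_volume = pixel_size^2 * section_thickness)
}

#' A quantity with mean, SEM and 90% confidence interval
#'
#' @param mean,sem the estimate and its standard error.
#' @param ci90 optional `(low, high)`; defaults to the delta-method
#'   interval `mean -/+ 1.645 * sem`.
#' @param method error-propagation label, `"delta"` or `"fieller"`.
#' @export
count_estimate <- function(mean, sem, ci90 = NULL, method = "delta") {
  z <- qnorm(0.95)
  if (is.null(ci90)) ci90 <- c(mean - z * sem, mean + z * sem)
  if (!(ci90[1] <= mean && mean <= ci90[2]))
    stop_olf("confidence interval must bracket the mean")
  structure(list(mean = mean, sem = sem, ci90 = ci90, method = method),
            class = "count_estimate")
}

#' @export
print.count_estimate <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f (SEM), 90%% CI [%.2f, %.2f] (%s)\n",
              x$mean, x$sem, x$ci90[1], x$ci90[2], x$method))
  invisible(x)
}

section_area_px <- function(series, structure) {
  vapply(series$sections, function(s)
    if (is.null(s$masks)) NA_real_ else sum(s$masks[[structure]]), numeric(1))
}

fill_missing_areas <- function(areas, included) {
  n <- length(areas)
  pos <- which(included)
  if (length(pos) == 0) stop_olf("all sections excluded: volume undefined")
  if (length(pos) == 1) return(rep(areas[pos], n))
  # linear interpolation between nearest included neighbours; boundary gaps
  # take the nearest included value
  approx(pos, areas[pos], xout = seq_len(n), rule = 2)$y
}

#' Voxel-count structure volume with interpolation over missing sections
#'
#' Included sections contribute their 2D pixel count; each non-included
#' section's area is linearly interpolated between the nearest preceding
#' and following included sections (nearest-neighbour at the series
#' boundaries). The filled area profile times the voxel volume gives the
#' structure volume.
#'
#' @param x a `section_series`, or a numeric vector of per-section areas in
#'   px (`NA` allowed on excluded sections).
#' @param structure structure name when `x` is a series.
#' @param included logical vector when `x` is numeric.
#' @param geometry a [voxel_geometry()]; defaults to the series geometry.
#' @return Volume in mm^3, with the filled per-section areas attached as
#'   attribute `areas_px`.
#' @export
structure_volume <- function(x, structure = NULL, included = NULL,
                             geometry = NULL) {
  if (inherits(x, "section_series")) {
    areas <- section_area_px(x, structure)
    included <- vapply(x$sections, function(s) s$included && !is.null(s$masks),
                       logical(1))
    geometry <- geometry %||% voxel_geometry(x$pixel_size, x$section_thickness)
  } else {
    areas <- x
    if (is.null(included)) included <- !is.na(areas)
    geometry <- geometry %||% voxel_geometry()
  }
  filled <- fill_missing_areas(areas, included)
  vol <- sum(filled) * geometry$voxel_volume / 1e9
  attr(vol, "areas_px") <- filled
  vol
}

close_disk <- function(mask, diam_px) {
  size <- 2L * floor(diam_px / 2) + 1L
  if (size < 3) return(mask)
  kern <- EBImage::makeBrush(size, shape = "disc")
  pad <- size  # generous zero padding keeps the closing extensive at borders
  H <- nrow(mask); W <- ncol(mask)
  big <- matrix(0, H + 2 * pad, W + 2 * pad)
  big[pad + seq_len(H), pad + seq_len(W)] <- mask
  out <- EBImage::closing(big, kern)
  matrix(as.numeric(out > 0.5), H + 2 * pad, W + 2 * pad)[pad + seq_len(H),
                                                          pad + seq_len(W)]
}

expand_to_thickness <- function(inter, epi) {
  if (sum(inter) == 0) return(inter * 0)
  lab <- EBImage::bwlabel(epi)
  out <- matrix(0, nrow(epi), ncol(epi))
  for (l in seq_len(max(lab))) {
    comp <- lab == l
    cols <- which(colSums(inter * comp) > 0)
    if (length(cols) == 0) next
    sel <- matrix(FALSE, nrow(epi), ncol(epi))
    sel[, cols] <- TRUE
    out[comp & sel] <- 1
  }
  out
}

#' The olfactory-epithelium envelope
#'
#' Per section, the OSN segmentation is intersected with the nasal
#' epithelium, expanded across the full apical-basal thickness of its
#' epithelium component, and the holes along the epithelium are closed by
#' in-plane morphological closing (dilation then erosion) with a disk
#' structuring element. The envelope volume uses the same missing-section
#' interpolation as [structure_volume()].
#'
#' @param epithelium_masks,osn_masks lists of binary matrices (included
#'   sections may be `NULL` on excluded ones), or a `section_series`
#'   as first argument with the other `NULL`.
#' @param included logical vector of inclusion flags.
#' @param disk_diameter structuring-element diameter, micrometres
#'   (default 80, similar to the epithelium thickness).
#' @param geometry a [voxel_geometry()].
#' @return An `envelope_result`: list with `masks`, `volume_mm3`,
#'   `disk_diameter` and the filled `areas_px`.
#' @export
olfactory_envelope <- function(epithelium_masks, osn_masks = NULL,
                               included = NULL, disk_diameter = 80,
                               geometry = voxel_geometry()) {
  if (inherits(epithelium_masks, "section_series")) {
    series <- epithelium_masks
    geometry <- voxel_geometry(series$pixel_size, series$section_thickness)
    included <- vapply(series$sections,
                       function(s) s$included && !is.null(s$masks), logical(1))
    epithelium_masks <- lapply(series$sections, function(s)
      s$masks$nasal_epithelium)
    osn_masks <- lapply(series$sections, function(s) s$masks$osn)
  }
  if (disk_diameter < geometry$pixel_size)
    stop_olf("disk diameter (%g um) below pixel size (%g um)",
             disk_diameter, geometry$pixel_size)
  diam_px <- disk_diameter / geometry$pixel_size
  masks <- vector("list", length(epithelium_masks))
  areas <- rep(NA_real_, length(epithelium_masks))
  for (i in seq_along(epithelium_masks)) {
    if (!included[i] || is.null(epithelium_masks[[i]])) next
    epi <- epithelium_masks[[i]]; osn <- osn_masks[[i]]
    assert_same_shape(epi, osn, "epithelium and OSN masks")
    env <- close_disk(expand_to_thickness(osn * epi, epi), diam_px)
    masks[[i]] <- env
    areas[i] <- sum(env)
  }
  vol <- structure_volume(areas, included = included & !is.na(areas),
                          geometry = geometry)
  structure(list(masks = masks, volume_mm3 = as.numeric(vol),
                 disk_diameter = disk_diameter,
                 areas_px = attr(vol, "areas_px")),
            class = "envelope_result")
}

#' Abercrombie correction for profile overcounting
#'
#' Nuclei split across section faces are counted in more than one section;
#' the classical correction scales raw profile counts by
#' `T / (T + D)` with `T` the section thickness and `D` the mean nuclear
#' diameter.
#'
#' @param raw_count raw profile count.
#' @param section_thickness `T`, micrometres.
#' @param nucleus_diameter `D`, micrometres.
#' @export
abercrombie_correct <- function(raw_count, section_thickness,
                                nucleus_diameter) {
  if (any(raw_count < 0) || section_thickness <= 0 || nucleus_diameter < 0)
    stop_olf("counts must be non-negative, T > 0, D >= 0")
  raw_count * section_thickness / (section_thickness + nucleus_diameter)
}

#' Linear OSN density from per-section manual counts
#'
#' Abercrombie-corrects the raw per-section counts and summarises the
#' per-section densities (counts per mm of OSN-bearing epithelium length)
#' as mean +/- SEM.
#'
#' @param counts raw OSN counts per section.
#' @param lengths_mm measured OSN-bearing epithelium length per section, mm.
#' @param section_thickness micrometres.
#' @param nucleus_diameter mean nuclear diameter for the Abercrombie
#'   factor, micrometres.
#' @return A `linear_density`: list with `mean`, `sem`, `n_counted`,
#'   `n_sections`.
#' @export
estimate_linear_density <- function(counts, lengths_mm, section_thickness = 10,
                                    nucleus_diameter = 0) {
  if (length(counts) != length(lengths_mm) || length(counts) < 1)
    stop_olf("counts and lengths must match and be non-empty")
  corr <- abercrombie_correct(counts, section_thickness, nucleus_diameter)
  d <- corr / lengths_mm
  structure(list(mean = mean(d),
                 sem = if (length(d) > 1) sd(d) / sqrt(length(d)) else 0,
                 n_counted = sum(counts), n_sections = length(counts)),
            class = "linear_density")
}

#' @rdname estimate_linear_density
#' @param mean,sem,n_counted,n_sections direct construction from published
#'   summary numbers.
#' @export
linear_density <- function(mean, sem, n_counted = NA_integer_,
                           n_sections = NA_integer_) {
  if (mean <= 0) stop_olf("linear density mean must be positive")
  structure(list(mean = mean, sem = sem, n_counted = n_counted,
                 n_sections = n_sections), class = "linear_density")
}

#' Epithelial thickness estimate
#'
#' @param measurements thickness measurements, micrometres; or use `mean`
#'   and `sem` for direct construction.
#' @param mean,sem summary construction.
#' @export
thickness_estimate <- function(measurements = NULL, mean = NULL, sem = NULL) {
  if (!is.null(measurements)) {
    mean <- base::mean(measurements)
    sem <- if (length(measurements) > 1)
      sd(measurements) / sqrt(length(measurements)) else 0
    n <- length(measurements)
  } else n <- NA_integer_
  if (mean <= 0) stop_olf("thickness mean must be positive")
  structure(list(mean = mean, sem = sem, n_measurements = n),
            class = "thickness_estimate")
}

#' Measure epithelium thickness on a section series
#'
#' Thickness (apical-basal run length of the epithelium mask, micrometres)
#' is measured at every OSN-bearing column of every included section.
#'
#' @param series a `section_series`.
#' @export
measure_epithelium_thickness <- function(series) {
  meas <- unlist(lapply(series$sections, function(s) {
    if (!s$included || is.null(s$masks)) return(NULL)
    cols <- which(colSums(s$masks$osn) > 0)
    if (length(cols) == 0) return(NULL)
    colSums(s$masks$nasal_epithelium)[cols] * series$pixel_size
  }))
  thickness_estimate(measurements = meas)
}

# Fieller interval for the ratio a/b of two independent estimates.
fieller_ci <- function(a, sea, b, seb, z = qnorm(0.95)) {
  g <- (z * seb / b)^2
  if (g >= 1) stop_olf("Fieller interval unbounded (g >= 1)")
  m <- a / b
  disc <- sea^2 + m^2 * seb^2 - g * sea^2
  half <- (z / b) * sqrt(disc)
  c((m - half) / (1 - g), (m + half) / (1 - g))
}

#' Volumetric OSN density from linear density and thickness
#'
#' Divides the linear density (OSNs per mm of epithelium length, counted on
#' sections of thickness `T`) by the epithelial thickness and the section
#' thickness, both in mm, giving OSNs per mm^3. The SEM of the ratio is
#' propagated with Fieller's theorem by default (SEM = CI width / (2 z));
#' the first-order delta formula is available as an alternative.
#'
#' @param lin a `linear_density`.
#' @param thick a `thickness_estimate` (micrometres).
#' @param section_thickness `T`, micrometres.
#' @param method `"fieller"` or `"delta"`.
#' @return A [count_estimate()] in OSNs per mm^3.
#' @export
volumetric_density <- function(lin, thick, section_thickness = 10,
                               method = c("fieller", "delta")) {
  method <- match.arg(method)
  if (thick$mean <= 0) stop_olf("thickness must be positive")
  k <- 1e6 / section_thickness  # converts (per mm) / um to per mm^3
  m <- lin$mean / thick$mean * k
  z <- qnorm(0.95)
  if (method == "fieller" && thick$sem > 0) {
    ci <- fieller_ci(lin$mean, lin$sem, thick$mean, thick$sem, z) * k
    sem <- diff(ci) / (2 * z)
    count_estimate(m, sem, ci90 = ci, method = "fieller")
  } else {
    sem <- m * sqrt((lin$sem / lin$mean)^2 + (thick$sem / thick$mean)^2)
    count_estimate(m, sem, method = if (method == "fieller") "fieller"
                   else "delta")
  }
}

#' Total OSN count by extrapolation to the envelope volume
#'
#' Multiplies the volumetric density by the envelope volume (treated as a
#' fixed quantity); the 90% confidence interval is the delta-method
#' interval `mean +/- 1.645 * sem`.
#'
#' @param density a [count_estimate()] in OSNs per mm^3.
#' @param envelope_volume envelope volume, mm^3 (number or
#'   `envelope_result`).
#' @export
total_osn <- function(density, envelope_volume) {
  if (inherits(envelope_volume, "envelope_result"))
    envelope_volume <- envelope_volume$volume_mm3
  if (envelope_volume < 0) stop_olf("volume must be non-negative")
  count_estimate(density$mean * envelope_volume,
                 density$sem * envelope_volume, method = "delta")
}

#' Olfactory-epithelium surface area
#'
#' The envelope volume divided by the mean epithelial thickness; the SEM
#' follows from the thickness SEM by the delta method.
#'
#' @param envelope_volume mm^3 (number or `envelope_result`).
#' @param thick a `thickness_estimate` (micrometres).
#' @return A [count_estimate()] in mm^2.
#' @export
epithelium_surface_area <- function(envelope_volume, thick) {
  if (inherits(envelope_volume, "envelope_result"))
    envelope_volume <- envelope_volume$volume_mm3
  if (thick$mean <= 0) stop_olf("thickness must be positive")
  t_mm <- thick$mean / 1000
  area <- envelope_volume / t_mm
  sem <- area * thick$sem / thick$mean
  count_estimate(area, sem, method = "delta")
}

#' Sphere-model glomerulus estimate
#'
#' Treats glomeruli as spheres of a given mean diameter and divides the
#' segmented glomerular volume by the single-sphere volume.
#'
#' @param glomerular_volume mm^3.
#' @param diameter mean glomerular diameter, micrometres.
#' @return A `sphere_model`: list with `diameter`, `glomerular_volume`,
#'   `count` (rounded) and `count_raw`.
#' @export
sphere_glomerulus_count <- function(glomerular_volume, diameter) {
  if (diameter <= 0) stop_olf("diameter must be positive")
  v_sphere <- 4 / 3 * pi * (diameter / 2000)^3  # mm^3
  raw <- glomerular_volume / v_sphere
  structure(list(diameter = diameter, glomerular_volume = glomerular_volume,
                 count = as.integer(round(raw)), count_raw = raw),
            class = "sphere_model")
}

#' Derived OSN ratios
#'
#' OSNs per glomerulus and OSNs per odorant-receptor gene.
#'
#' @param total_osn total OSN count (number or [count_estimate()]).
#' @param glomerulus_counts glomerulus counts to be summed (e.g. left and
#'   right bulb).
#' @param n_genes number of odorant-receptor genes.
#' @return List with raw and rounded ratios.
#' @export
ratio_report <- function(total_osn, glomerulus_counts, n_genes) {
  if (inherits(total_osn, "count_estimate")) total_osn <- total_osn$mean
  ng <- sum(glomerulus_counts)
  if (ng <= 0 || n_genes <= 0) stop_olf("denominators must be positive")
  list(osns_per_glomerulus = total_osn / ng,
       osns_per_glomerulus_rounded = round(total_osn / ng),
       osns_per_gene = total_osn / n_genes,
       osns_per_gene_rounded = round(total_osn / n_genes))
}

#' Interleaved-sampling error of a structure volume
#'
#' Keeps every `rate`-th included section, treats the remainder as
#' non-included, recomputes the volume with the usual interpolation, and
#' reports the absolute percentage change from the complete dataset.
#'
#' @param areas per-section areas in px (full cut series).
#' @param included logical inclusion flags.
#' @param rate sampling rate (every `rate`-th included section; >= 2, or 1
#'   for the complete dataset itself).
#' @param geometry a [voxel_geometry()].
#' @return List with `percent_error`, `volume_complete`,
#'   `volume_interleaved`.
#' @export
interleaved_error <- function(areas, included, rate,
                              geometry = voxel_geometry()) {
  if (rate < 1) stop_olf("rate must be >= 1")
  v0 <- as.numeric(structure_volume(areas, included = included,
                                    geometry = geometry))
  if (rate == 1)
    return(list(percent_error = 0, volume_complete = v0,
                volume_interleaved = v0))
  pos <- which(included)
  keep <- pos[seq(1, length(pos), by = rate)]
  if (length(keep) < 2) stop_olf("fewer than 2 sections survive rate %d", rate)
  inc2 <- rep(FALSE, length(included)); inc2[keep] <- TRUE
  v1 <- as.numeric(structure_volume(areas, included = inc2,
                                    geometry = geometry))
  list(percent_error = abs(v1 - v0) / v0 * 100, volume_complete = v0,
       volume_interleaved = v1)
}

#' Interleaved-sampling report over all structures of a series
#'
#' @param series a `section_series` with ground-truth or predicted masks.
#' @param rates sampling rates (default every 4th, 16th, 32nd section).
#' @return Data frame with one row per structure and rate.
#' @export
interleave_report <- function(series, rates = c(4L, 16L, 32L)) {
  geometry <- voxel_geometry(series$pixel_size, series$section_thickness)
  included <- vapply(series$sections, function(s)
    s$included && !is.null(s$masks), logical(1))
  rates <- rates[vapply(rates, function(r)
    length(seq(1, sum(included), by = max(r, 1))) >= 2, logical(1))]
  if (length(rates) == 0) stop_olf("no sampling rate leaves 2 sections")
  do.call(rbind, lapply(STRUCTURES, function(st) {
    areas <- section_area_px(series, st)
    do.call(rbind, lapply(rates, function(r) {
      res <- interleaved_error(areas, included, r, geometry)
      data.frame(structure = st, rate = r,
                 percent_error = res$percent_error,
                 volume_mm3 = res$volume_complete)
    }))
  }))
}
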