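#' Pipeline configuration
#'
#' Bundles the per-stage configurations and the global seed of one
#' reproducible end-to-end run. With `input_dir = NULL` the pipeline runs
#' on a freshly generated virtual specimen; otherwise sections are read
#' from disk.
#'
#' @param input_dir optional directory holding a written section series.
#' @param output_dir optional directory for the run report and artifacts.
#' @param phantom a [phantom_config()] (used when `input_dir` is `NULL`).
#' @param registration a [registration_config()].
#' @param block_size registration block size.
#' @param true_linear_density linear OSN density used to simulate manual
#'   counts on synthetic data (OSNs per mm).
#' @param nucleus_diameter Abercrombie `D`, micrometres (0 for simulated
#'   counts, which are free of profile overcounting; set the measured
#'   diameter for real manual counts).
#' @param disk_diameter envelope structuring-element diameter, micrometres.
#' @param seed global seed recorded in the run report.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            phantom = phantom_config(),
                            registration = registration_config(),
                            block_size = 5L, true_linear_density = 100,
                            nucleus_diameter = 0, disk_diameter = 80,
                            seed = 1L) {
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 phantom = phantom, registration = registration,
                 block_size = as.integer(block_size),
                 true_linear_density = true_linear_density,
                 nucleus_diameter = nucleus_diameter,
                 disk_diameter = disk_diameter, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash of a configuration's JSON serialisation
# (provenance tag; not cryptographic).
config_hash <- function(config) {
  s <- jsonlite::serializeJSON(unclass(config))
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

series_checksum <- function(series) {
  v <- vapply(series$sections, function(s) {
    if (is.null(s$channels)) return(0)
    sum(vapply(s$channels, sum, numeric(1))) +
      sum(vapply(s$masks, sum, numeric(1)))
  }, numeric(1))
  sprintf("%.6e", sum(v * seq_along(v)))
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or load), register, quantify —
#' on either the synthetic virtual specimen or a user-supplied series, and
#' returns a run report with per-stage metrics. Ground-truth masks drive
#' registration and quantification; segmentation is trained separately with
#' [train_unet()] and can replace the masks upstream.
#'
#' @param config a [pipeline_config()].
#' @return A `run_report`: list with stage results, seeds, configuration
#'   hash, wall-clock seconds and a deterministic series checksum.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir))
      stop_olf("input directory does not exist: %s", config$input_dir)
    series <- read_series(config$input_dir)
  } else {
    ph <- config$phantom
    series <- render_sections(make_phantom(ph))
  }
  dice_before <- adjacent_dice(series)
  reg <- tryCatch(
    register_series(series, config$registration, method = "block",
                    block_size = config$block_size),
    error = function(e) stop_olf("stage registration failed: %s",
                                 conditionMessage(e)))
  dice_after <- adjacent_dice(reg$series)

  counts <- simulate_osn_counts(reg$series, config$true_linear_density,
                                seed = config$seed + 101L)
  lin <- estimate_linear_density(counts$count, counts$length_mm,
                                 section_thickness = series$section_thickness,
                                 nucleus_diameter = config$nucleus_diameter)
  thick <- measure_epithelium_thickness(reg$series)
  env <- olfactory_envelope(reg$series, disk_diameter = config$disk_diameter)
  dens <- volumetric_density(lin, thick,
                             section_thickness = series$section_thickness)
  total <- total_osn(dens, env)
  area <- epithelium_surface_area(env, thick)

  report <- list(
    seed = config$seed, config_hash = config_hash(config),
    n_included = length(included_indices(series)),
    registration = list(adjacent_dice_before = dice_before,
                        adjacent_dice_after = dice_after,
                        dice_gain = dice_after - dice_before),
    morphometry = list(
      envelope_volume_mm3 = env$volume_mm3,
      linear_density = unclass(lin), thickness_um = unclass(thick),
      density_per_mm3 = unclass(dens), total_osn = unclass(total),
      surface_area_mm2 = unclass(area)),
    checksum = series_checksum(reg$series),
    wall_clock_s = proc.time()[["elapsed"]] - t0,
    versions = list(olfstereo = as.character(utils::packageVersion("olfstereo")),
                    R = paste(R.version$major, R.version$minor, sep = ".")))
  class(report) <- "run_report"
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$output_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (seed %d, config %s)\n", x$seed, x$config_hash))
  cat(sprintf("  adjacent Dice %.3f -> %.3f\n",
              x$registration$adjacent_dice_before,
              x$registration$adjacent_dice_after))
  cat(sprintf("  envelope %.4g mm^3; total OSN %.0f +/- %.0f\n",
              x$morphometry$envelope_volume_mm3,
              x$morphometry$total_osn$mean, x$morphometry$total_osn$sem))
  invisible(x)
}

#' Stack a series into a 3D array
#'
#' @param series a `section_series`.
#' @param what a structure name (mask stack) or channel name.
#' @export
series_stack <- function(series, what) {
  grab <- function(s) {
    if (is.null(s$channels)) return(NULL)
    if (what %in% STRUCTURES) s$masks[[what]] else s$channels[[what]]
  }
  mats <- lapply(series$sections, grab)
  keep <- !vapply(mats, is.null, logical(1))
  if (!any(keep)) stop_olf("no image data in series")
  shp <- dim(mats[keep][[1]])
  for (m in mats[keep]) if (!identical(dim(m), shp))
    stop_olf("inconsistent section shapes")
  mats[!keep] <- list(matrix(0, shp[1], shp[2]))
  array(unlist(mats, use.names = FALSE), dim = c(shp, length(mats)))
}

#' Export a volume as NIfTI
#'
#' Writes a 3D stack with the voxel dimensions (default
#' 1.097 x 1.097 x 10 um) recorded in the header; masks are stored as
#' unsigned 8-bit, channels as 16-bit (intensities in `[0, 1]` scaled to
#' the integer range).
#'
#' @param volume `H x W x Z` numeric array.
#' @param geometry a [voxel_geometry()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param kind `"mask"` or `"channel"`.
#' @export
export_nifti <- function(volume, geometry = voxel_geometry(), path,
                         kind = c("mask", "channel")) {
  kind <- match.arg(kind)
  if (length(dim(volume)) != 3 || any(dim(volume) == 0))
    stop_olf("volume must be a non-empty 3D array")
  if (kind == "channel") {
    volume <- round(pmin(pmax(volume, 0), 1) * 65535)
    dtype <- "uint16"
  } else {
    assert_binary(volume, "mask volume")
    dtype <- "uint8"
  }
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- c(geometry$pixel_size, geometry$pixel_size,
                           geometry$section_thickness)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

block_reduce <- function(m, f, fun = c("mean", "majority")) {
  fun <- match.arg(fun)
  Hf <- nrow(m) %/% f; Wf <- ncol(m) %/% f
  if (Hf < 1 || Wf < 1) stop_olf("factor %d larger than the image", f)
  m <- m[seq_len(Hf * f), seq_len(Wf * f), drop = FALSE]
  a <- array(m, dim = c(f, Hf, f, Wf))
  red <- apply(a, c(2, 4), mean)
  if (fun == "majority") (red >= 0.5) * 1 else red
}

#' In-plane downsampling for export
#'
#' Reduces each section by block mean (channels) or block majority vote
#' (masks) and scales the recorded pixel size accordingly (e.g. factor 16
#' at 1.097 um gives 17.559 um).
#'
#' @param volume `H x W x Z` array (or a single matrix).
#' @param factor integer reduction factor (>= 1).
#' @param kind `"channel"` (mean) or `"mask"` (majority).
#' @param geometry a [voxel_geometry()].
#' @return List with `volume` and the scaled `geometry`.
#' @export
downsample_export <- function(volume, factor = 16L,
                              kind = c("channel", "mask"),
                              geometry = voxel_geometry()) {
  kind <- match.arg(kind)
  if (factor < 1) stop_olf("factor must be >= 1")
  fun <- if (kind == "mask") "majority" else "mean"
  geom2 <- voxel_geometry(geometry$pixel_size * factor,
                          geometry$section_thickness)
  if (factor == 1) return(list(volume = volume, geometry = geometry))
  if (length(dim(volume)) == 2) {
    return(list(volume = block_reduce(volume, factor, fun), geometry = geom2))
  }
  slices <- lapply(seq_len(dim(volume)[3]), function(z)
    block_reduce(volume[, , z], factor, fun))
  list(volume = array(unlist(slices), dim = c(dim(slices[[1]]),
                                              length(slices))),
       geometry = geom2)
}
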