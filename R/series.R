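#' A single serial section
#'
#' @param index 1-based position of the section in the cut series.
#' @param channels named list of four grayscale matrices in `[0, 1]`
#'   (`hoechst`, `uea1`, `omp`, `vglut2`).
#' @param masks named list of six binary matrices (see [phantom]).
#' @param included logical; `FALSE` for sections lost to the dataset.
#' @return An object of class `section_record`.
#' @export
section_record <- function(index, channels, masks, included = TRUE) {
  if (!identical(sort(names(channels)), sort(CHANNELS)))
    stop_olf("channels must be named %s", paste(CHANNELS, collapse = ", "))
  if (!identical(sort(names(masks)), sort(STRUCTURES)))
    stop_olf("masks must be named %s", paste(STRUCTURES, collapse = ", "))
  shp <- dim(channels[[1]])
  for (x in c(channels, masks)) {
    if (!identical(dim(x), shp))
      stop_olf("all images of a section must share one (height, width)")
  }
  for (m in names(masks)) assert_binary(masks[[m]], m)
  structure(list(index = as.integer(index),
                 channels = channels[CHANNELS], masks = masks[STRUCTURES],
                 included = isTRUE(included)),
            class = "section_record")
}

#' An ordered series of serial sections
#'
#' @param sections list of [section_record()]s with strictly increasing
#'   indices. The included sections form the "complete dataset"; excluded
#'   sections are retained as placeholders so that volumes can be
#'   interpolated over them.
#' @param n_cut total number of sections cut (including non-included ones).
#' @param pixel_size,section_thickness voxel geometry in micrometres.
#' @return An object of class `section_series`.
#' @export
section_series <- function(sections, n_cut = length(sections),
                           pixel_size = 1.097, section_thickness = 10) {
  idx <- vapply(sections, function(s) s$index, integer(1))
  if (any(diff(idx) <= 0)) stop_olf("section indices must be strictly increasing")
  inc <- vapply(sections, function(s) s$included, logical(1))
  if (sum(inc) > n_cut) stop_olf("included sections cannot exceed n_cut")
  structure(list(sections = sections, n_cut = as.integer(n_cut),
                 pixel_size = pixel_size, section_thickness = section_thickness),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  inc <- sum(vapply(x$sections, function(s) s$included, logical(1)))
  shp <- dim(x$sections[[1]]$channels[[1]])
  cat(sprintf(paste0("section_series: %d/%d sections included, %d x %d px, ",
                     "%.3f um px, %g um thick\n"),
              inc, x$n_cut, shp[1], shp[2], x$pixel_size, x$section_thickness))
  invisible(x)
}

included_indices <- function(series) {
  idx <- vapply(series$sections, function(s) s$index, integer(1))
  idx[vapply(series$sections, function(s) s$included, logical(1))]
}

#' Write a section series to disk
#'
#' Each section is stored as one multi-page 32-bit TIFF (four channel pages
#' followed by six mask pages, page order recorded in the manifest). A JSON
#' manifest lists every cut section with its inclusion flag and filename.
#'
#' @param series a `section_series`.
#' @param directory output directory (created if absent).
#' @param write_excluded if `TRUE` (default) image files are also written
#'   for excluded sections so that the round trip is lossless; if `FALSE`
#'   excluded sections appear in the manifest only.
#' @return The directory, invisibly.
#' @export
write_series <- function(series, directory, write_excluded = TRUE) {
  stopifnot(inherits(series, "section_series"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(series$sections, function(s) {
    fn <- NULL
    if (s$included || write_excluded) {
      fn <- sprintf("section_%04d.tif", s$index)
      pages <- c(unname(s$channels), unname(s$masks))
      tiff::writeTIFF(pages, file.path(directory, fn), bits.per.sample = 32L)
    }
    list(index = s$index, included = s$included, filename = fn)
  })
  manifest <- list(pixel_size = series$pixel_size,
                   section_thickness = series$section_thickness,
                   n_cut = series$n_cut,
                   page_order = list(channels = as.list(CHANNELS),
                                     masks = as.list(STRUCTURES)),
                   sections = entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(directory)
}

#' Read a section series from disk
#'
#' @param directory a directory written by [write_series()].
#' @return A `section_series`.
#' @export
read_series <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop_olf("missing manifest: %s", mf)
  manifest <- jsonlite::read_json(mf)
  sections <- lapply(manifest$sections, function(e) {
    if (is.null(e$filename)) {
      return(structure(list(index = as.integer(e$index), channels = NULL,
                            masks = NULL, included = isTRUE(e$included)),
                       class = "section_record"))
    }
    path <- file.path(directory, e$filename)
    if (!file.exists(path))
      stop_olf("section %d: file %s listed in manifest but absent",
               e$index, e$filename)
    pages <- tiff::readTIFF(path, all = TRUE)
    chans <- pages[seq_along(CHANNELS)]
    names(chans) <- unlist(manifest$page_order$channels)
    masks <- pages[length(CHANNELS) + seq_along(STRUCTURES)]
    masks <- lapply(masks, function(m) (m > 0.5) * 1)
    names(masks) <- unlist(manifest$page_order$masks)
    section_record(e$index, chans, masks, included = isTRUE(e$included))
  })
  section_series(sections, n_cut = manifest$n_cut,
                 pixel_size = manifest$pixel_size,
                 section_thickness = manifest$section_thickness)
}
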