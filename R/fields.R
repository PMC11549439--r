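#' Per-pixel 2D displacement field
#'
#' A displacement field maps a moving section onto a fixed section by
#' backward warping: the warped image at pixel `x` samples the moving image
#' at `x + phi(x)`. The zero field is the identity transform.
#'
#' @param r,c matrices of row and column displacements in px, one value per
#'   pixel of the section.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(r, c) {
  assert_same_shape(r, c, "field components")
  if (!all(is.finite(r)) || !all(is.finite(c)))
    stop_olf("displacement field must be finite everywhere")
  structure(list(r = r, c = c), class = "displacement_field")
}

#' @rdname displacement_field
#' @param shape `(height, width)` of the section.
#' @export
zero_field <- function(shape) {
  displacement_field(matrix(0, shape[1], shape[2]), matrix(0, shape[1], shape[2]))
}

field_shape <- function(field) dim(field$r)

#' Mean displacement magnitude of a field, in px
#' @param field a `displacement_field`.
#' @export
field_magnitude <- function(field) mean(sqrt(field$r^2 + field$c^2))

#' Scale a displacement field by a constant factor
#' @param field a `displacement_field`.
#' @param factor scalar multiplier.
#' @export
scale_field <- function(field, factor) {
  displacement_field(field$r * factor, field$c * factor)
}

#' Warp an image or mask with a displacement field
#'
#' Resamples the input at `x + phi(x)`. Samples falling outside the image
#' domain are set to 0. Use `mode = "linear"` (bilinear) for intensity
#' channels and `mode = "nearest"` for masks, which stay strictly binary.
#'
#' @param image a numeric matrix.
#' @param field a `displacement_field` of the same shape.
#' @param mode `"linear"` or `"nearest"`.
#' @return The warped matrix.
#' @export
apply_field <- function(image, field, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!identical(dim(image), field_shape(field)))
    stop_olf("field shape %s does not match image shape %s",
             paste(field_shape(field), collapse = "x"),
             paste(dim(image), collapse = "x"))
  .warp_kernel(image, field$r, field$c, mode == "nearest")
}

#' Compose two displacement fields
#'
#' Returns the single field equivalent to warping with `second` first and
#' then `first`:  `(first o second)(x) = second(x) + first(x + second(x))`.
#' Applying the composed field to the original image avoids double
#' resampling.
#'
#' @param first,second `displacement_field`s of equal shape.
#' @export
compose_fields <- function(first, second) {
  assert_same_shape(first$r, second$r, "fields")
  out <- .compose_kernel(first$r, first$c, second$r, second$c)
  displacement_field(out$r, out$c)
}

#' Evaluate a cubic B-spline free-form deformation
#'
#' Builds a dense displacement field from a uniform grid of control-point
#' displacements spanning the image. Because cubic B-spline weights form a
#' partition of unity, the field magnitude never exceeds the largest
#' control displacement.
#'
#' @param ctrl_r,ctrl_c control grids (at least 4 x 4) of row/column
#'   displacements in px.
#' @param shape `(height, width)` of the target section.
#' @export
bspline_field <- function(ctrl_r, ctrl_c, shape) {
  displacement_field(.bspline_field_kernel(ctrl_r, shape[1], shape[2]),
                     .bspline_field_kernel(ctrl_c, shape[1], shape[2]))
}

# Rigid transform about the image centre expressed as a displacement field:
# phi(x) = R(theta) (x - c) + c + t - x, warped image samples at x + phi(x).
rigid_field <- function(theta, tr, tc, shape) {
  H <- shape[1]; W <- shape[2]
  cr <- (H - 1) / 2; cc <- (W - 1) / 2
  r <- matrix(0:(H - 1), H, W) - cr
  c <- matrix(0:(W - 1), H, W, byrow = TRUE) - cc
  ct <- cos(theta); st <- sin(theta)
  displacement_field(ct * r - st * c - r + tr, st * r + ct * c - c + tc)
}

# 2x downsampling by block averaging (used for multiresolution pyramids).
pyr_down <- function(img) {
  H <- 2L * (nrow(img) %/% 2L); W <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(H), seq_len(W), drop = FALSE]
  (img[seq(1, H, 2), seq(1, W, 2)] + img[seq(2, H, 2), seq(1, W, 2)] +
   img[seq(1, H, 2), seq(2, W, 2)] + img[seq(2, H, 2), seq(2, W, 2)]) / 4
}

pyr_level <- function(img, level) {
  while (level > 0) { img <- pyr_down(img); level <- level - 1 }
  img
}

# Mutual information between two images on [0, 1], with partial-volume
# (linearly weighted) binning: hard binning makes MI peak artifactually at
# integer displacements, soft binning keeps the surface smooth at subpixel
# offsets.
mi_similarity <- function(a, b, bins = 32L) {
  # keep the joint histogram populated on small pyramid levels
  bins <- max(8L, min(bins, as.integer(floor(sqrt(length(a)) / 2))))
  pm <- .pv_joint_hist(a, b, bins)
  pm <- pm / sum(pm)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / (outer(pa, pb)[nz])))
}

ncc_similarity <- function(a, b) {
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(0)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

similarity_fun <- function(name) {
  switch(name, mi = mi_similarity, ncc = ncc_similarity,
         stop_olf("unknown similarity '%s'", name))
}
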