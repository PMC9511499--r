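#' Ring parameters for cytoplasmic biosensor quantification
#'
#' Cytoplasmic signal is quantified in a 15-pixel ring outside the
#' segmented nucleus, separated from the nuclear boundary by a 2-pixel
#' gap.  Pixel membership uses Chebyshev (chessboard) distance to the
#' nuclear mask: gap-exclusive, width-inclusive.
#'
#' @param width Ring width in pixels (> 0).
#' @param gap Gap between nucleus and ring in pixels (>= 0).
#' @return A list of class `ring_params`.
#' @export
ring_params <- function(width = 15, gap = 2) {
  if (width <= 0) am_abort("Ring width must be > 0.", "arrestmap_config_error")
  if (gap < 0) am_abort("Ring gap must be >= 0.", "arrestmap_config_error")
  structure(list(width = as.integer(width), gap = as.integer(gap)),
            class = "ring_params")
}

#' Render a concentric-disk cell phantom
#'
#' A toy image for validating ring quantification: a nuclear disk at
#' `nuclear_intensity`, a cytoplasmic annulus at `cytoplasm_intensity`,
#' background elsewhere.  Pixel centers sit at integer coordinates; a
#' pixel belongs to a disk when its center is within the radius.
#'
#' @param nucleus_radius,cell_radius Radii in pixels; the cell radius must
#'   exceed `nucleus_radius + 17` so the 2-px gap plus 15-px ring fits
#'   inside the cytoplasm.
#' @param nuclear_intensity,cytoplasm_intensity,background Intensities
#'   (arbitrary units).
#' @param image_size Side length of the square image in pixels.
#' @return List with `image` (numeric matrix) and `nuclear_mask` (logical
#'   matrix).
#' @export
render_cell_image <- function(nucleus_radius = 20, cell_radius = 45,
                              nuclear_intensity = 200,
                              cytoplasm_intensity = 400,
                              background = 100, image_size = 101) {
  if (cell_radius <= nucleus_radius + 17) {
    am_abort("cell_radius must exceed nucleus_radius + 17 (gap + ring).",
             "arrestmap_geometry_error")
  }
  ctr <- (image_size + 1) / 2
  if (ctr - cell_radius < 1 || ctr + cell_radius > image_size) {
    am_abort("Cell (and hence ring) would clip the image border.",
             "arrestmap_geometry_error")
  }
  d <- sqrt(outer((seq_len(image_size) - ctr)^2,
                  (seq_len(image_size) - ctr)^2, "+"))
  img <- matrix(background, image_size, image_size)
  img[d <= cell_radius] <- cytoplasm_intensity
  img[d <= nucleus_radius] <- nuclear_intensity
  list(image = img, nuclear_mask = d <= nucleus_radius)
}

# Chebyshev dilation of a logical mask by k pixels (box structuring
# element), via EBImage.
.cheb_dilate <- function(mask, k) {
  if (k == 0) return(mask)
  brush <- EBImage::makeBrush(2 * k + 1, shape = "box")
  EBImage::dilate(mask * 1, brush) > 0
}

#' CDK2 activity from a biosensor image
#'
#' The cytoplasmic/nuclear translocation readout: median intensity in the
#' perinuclear ring (pixels at Chebyshev distance in `(gap, gap + width]`
#' from the nuclear mask) over median nuclear intensity, both background
#' corrected.
#'
#' @param image Numeric matrix.
#' @param nuclear_mask Logical matrix, same dimensions; must be non-empty.
#' @param params A [ring_params()].
#' @param background Background intensity to subtract from both
#'   compartments.
#' @param guard Small positive floor for the background-corrected nuclear
#'   denominator; below it the measurement is flagged unreliable and `NA`
#'   is returned with a warning.
#' @return The activity ratio (dimensionless), or `NA` when unreliable.
#' @export
measure_cdk2_activity <- function(image, nuclear_mask, params = ring_params(),
                                  background = 0, guard = 1e-6) {
  if (!any(nuclear_mask)) am_abort("Empty nuclear mask.", "arrestmap_geometry_error")
  if (!all(dim(image) == dim(nuclear_mask))) {
    am_abort("image and nuclear_mask dimensions differ.", "arrestmap_geometry_error")
  }
  outer_d <- .cheb_dilate(nuclear_mask, params$gap + params$width)
  border <- rbind(outer_d[c(1, nrow(outer_d)), , drop = FALSE],
                  t(outer_d[, c(1, ncol(outer_d)), drop = FALSE]))
  if (any(border)) {
    am_abort("Ring clips the image border.", "arrestmap_geometry_error")
  }
  inner_d <- .cheb_dilate(nuclear_mask, params$gap)
  ring <- outer_d & !inner_d
  if (!any(ring)) am_abort("Ring is empty.", "arrestmap_geometry_error")
  denom <- median(image[nuclear_mask]) - background
  if (denom <= guard) {
    rlang::warn("Background-corrected nuclear intensity at or below guard; measurement withheld.")
    return(NA_real_)
  }
  (median(image[ring]) - background) / denom
}
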