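#' Tissue label codes
#'
#' Integer codes used throughout the package for the five arm tissues.
#' Numbering follows the layered volume-conductor convention: tissues are
#' counted from the innermost layer outwards, the outermost layer (largest
#' code) being the skin; 0 is background.
#'
#' @return Named integer vector `c(background = 0, marrow = 1, bone = 2,
#'   muscle = 3, fat = 4, skin = 5)`.
#' @export
tissue_codes <- function() {
  c(background = 0L, marrow = 1L, bone = 2L, muscle = 3L, fat = 4L, skin = 5L)
}

tissue_name <- function(code) {
  tc <- tissue_codes()
  names(tc)[match(code, tc)]
}

#' Construct a label volume
#'
#' A 3-D voxel grid of integer tissue labels with physical spacing. Axial
#' slices are stacked along the third (z) array dimension; array indices are
#' 1-based and the physical position of the center of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 0.5) * spacing` (mm).
#'
#' @param labels 3-D integer array, 0 = background.
#' @param spacing numeric length-3, voxel edge lengths in mm (x, y, z).
#' @param origin numeric length-3, physical position (mm) of the corner of
#'   voxel (1, 1, 1).
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) stop_arm("labels must be a 3-D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop_arm("spacing must be positive")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  tab <- table(factor(tissue_name(x$labels),
                      levels = names(tissue_codes())))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("  %-10s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' Physical voxel-center coordinates
#'
#' @param vol a [label_volume].
#' @param index integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(vol, index) {
  sweep(sweep(index - 0.5, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

# inverse: mm point -> 1-based voxel index (matrix in, matrix out)
point_to_voxel <- function(vol, pts) {
  idx <- sweep(pts, 2, vol$origin, `-`)
  idx <- floor(sweep(idx, 2, vol$spacing, `/`)) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' Construct a grayscale slice stack
#'
#' Ordered axial grayscale images with physical spacing metadata; the
#' synthetic stand-in for a serial cryosection acquisition.
#'
#' @param images 3-D numeric array (nx, ny, n_slices) of intensities.
#' @param slice_spacing mm between consecutive slices.
#' @param pixel_spacing mm per pixel (isotropic in-plane).
#' @param bit_depth intensity bit depth (8 or 16).
#' @return Object of class `slice_stack`.
#' @export
slice_stack <- function(images, slice_spacing, pixel_spacing, bit_depth = 8L) {
  if (length(dim(images)) != 3L) stop_arm("images must be a 3-D array")
  if (slice_spacing <= 0 || pixel_spacing <= 0)
    stop_arm("spacings must be positive")
  structure(list(images = images, slice_spacing = as.numeric(slice_spacing),
                 pixel_spacing = as.numeric(pixel_spacing),
                 bit_depth = as.integer(bit_depth)),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "slice_stack: %d slices of %d x %d px, %.3g mm slice / %.3g mm pixel\n",
    d[3], d[1], d[2], x$slice_spacing, x$pixel_spacing))
  invisible(x)
}
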