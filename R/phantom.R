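#' Parametric arm phantom specification
#'
#' Describes a tapered, layered limb: concentric skin/fat annuli around a
#' muscle core, with one eccentric cortical-bone shell enclosing a marrow
#' core. The defaults define the package's reference phantom: a
#' 48 x 48 x 96 voxel grid at 1 mm resolution, outer radius tapering
#' linearly from 20 mm (shoulder end) to 16 mm (wrist end), 1.5 mm skin,
#' 3.5 mm fat, a 5 mm radius bone with 2.5 mm cortical shell offset 4 mm
#' from the limb axis along x (so the inter-electrode center line crosses
#' it).
#'
#' @param n_slices number of axial slices.
#' @param slice_spacing mm between slices.
#' @param pixel_spacing mm per in-plane voxel.
#' @param n_pixels in-plane grid width (square grid).
#' @param outer_radius either length-2 `c(shoulder, wrist)` in mm (linear
#'   taper) or a per-slice vector of length `n_slices`.
#' @param skin_thickness,fat_thickness annulus thicknesses, mm.
#' @param bone_radius outer radius of the cortical shell, mm.
#' @param cortical_thickness thickness of the cortical shell, mm; the
#'   marrow core radius is `bone_radius - cortical_thickness`.
#' @param bone_center in-plane (x, y) offset of the bone axis from the limb
#'   axis, mm.
#' @param rng_seed integer seed consumed by [render_slices()] defaults.
#' @return Object of class `phantom_spec`.
#' @seealso [build_phantom()], [render_slices()]
#' @export
phantom_spec <- function(n_slices = 96L,
                         slice_spacing = 1,
                         pixel_spacing = 1,
                         n_pixels = 48L,
                         outer_radius = c(20, 16),
                         skin_thickness = 1.5,
                         fat_thickness = 3.5,
                         bone_radius = 5,
                         cortical_thickness = 2.5,
                         bone_center = c(4, 0),
                         rng_seed = 20230318L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop_arm("n_slices must be >= 1")
  if (slice_spacing <= 0 || pixel_spacing <= 0)
    stop_arm("spacings must be positive")
  r <- if (length(outer_radius) == n_slices) as.numeric(outer_radius)
       else if (length(outer_radius) == 2L)
         seq(outer_radius[1], outer_radius[2], length.out = n_slices)
       else if (length(outer_radius) == 1L) rep(outer_radius, n_slices)
       else stop_arm("outer_radius must have length 1, 2 or n_slices")
  if (skin_thickness < 0 || fat_thickness < 0 ||
      bone_radius < 0 || cortical_thickness < 0 ||
      cortical_thickness > bone_radius)
    stop_arm("layer thicknesses must be non-negative and consistent")
  bad <- which(skin_thickness + fat_thickness >= r)
  if (length(bad))
    stop_arm("annulus thicknesses (%.3g mm) >= outer radius at slice %d",
             skin_thickness + fat_thickness, bad[1])
  if (bone_radius > 0) {
    bad <- which(vnorm(bone_center) + bone_radius >=
                   r - skin_thickness - fat_thickness)
    if (length(bad))
      stop_arm("bone not strictly inside the muscle region at slice %d",
               bad[1])
  }
  extent <- n_pixels * pixel_spacing / 2
  if (max(r) >= extent)
    stop_arm("outer radius %.3g mm does not fit the %.3g mm half-grid",
             max(r), extent)
  structure(list(n_slices = n_slices, slice_spacing = slice_spacing,
                 pixel_spacing = pixel_spacing, n_pixels = as.integer(n_pixels),
                 outer_radius_profile = r, skin_thickness = skin_thickness,
                 fat_thickness = fat_thickness, bone_radius = bone_radius,
                 cortical_thickness = cortical_thickness,
                 bone_center = as.numeric(bone_center),
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Analytic phantom volume
#'
#' Slice-summed analytic cross-section area times slice spacing; the
#' reference value for the voxelization-consistency check.
#' @param spec a [phantom_spec].
#' @return volume in mm^3.
#' @export
phantom_analytic_volume <- function(spec) {
  sum(pi * spec$outer_radius_profile^2) * spec$slice_spacing
}

# innermost-region classification of one slice's pixel centers.
classify_slice <- function(spec, xc, yc, r_out) {
  tc <- tissue_codes()
  d2 <- outer(xc^2, yc^2, `+`)        # distance^2 from limb axis
  dx <- xc - spec$bone_center[1]
  dy <- yc - spec$bone_center[2]
  db2 <- outer(dx^2, dy^2, `+`)       # distance^2 from bone axis
  r_fat <- r_out - spec$skin_thickness
  r_mus <- r_fat - spec$fat_thickness
  lab <- matrix(tc[["background"]], length(xc), length(yc))
  lab[d2 <= r_out^2] <- tc[["skin"]]
  lab[d2 <= r_fat^2] <- tc[["fat"]]
  lab[d2 <= r_mus^2] <- tc[["muscle"]]
  if (spec$bone_radius > 0) {
    inside_mus <- d2 <= r_mus^2
    lab[inside_mus & db2 <= spec$bone_radius^2] <- tc[["bone"]]
    r_mar <- spec$bone_radius - spec$cortical_thickness
    if (r_mar > 0) lab[inside_mus & db2 <= r_mar^2] <- tc[["marrow"]]
  }
  lab
}

#' Voxelize the arm phantom
#'
#' Assigns every voxel the innermost analytic region whose boundary contains
#' the voxel center. Deterministic given the spec.
#'
#' @param spec a [phantom_spec].
#' @return A [label_volume]; the grid origin is chosen so the limb axis runs
#'   through the in-plane grid center.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_pixels
  s <- spec$pixel_spacing
  labels <- array(0L, dim = c(n, n, spec$n_slices))
  # pixel centers relative to the limb axis (grid center)
  xc <- (seq_len(n) - 0.5) * s - n * s / 2
  for (k in seq_len(spec$n_slices)) {
    labels[, , k] <- classify_slice(spec, xc, xc,
                                    spec$outer_radius_profile[k])
  }
  label_volume(labels, spacing = c(s, s, spec$slice_spacing))
}

#' Per-tissue gray rendering index
#'
#' Mean intensity, noise standard deviation and bit depth used to render a
#' label volume into grayscale sections. The defaults emulate a cryosection
#' appearance on an 8-bit scale: cortical bone and skin bright, muscle dark,
#' fat and marrow intermediate. Means must be pairwise distinct.
#'
#' @param means named numeric vector of per-tissue mean intensities; must
#'   cover `background` plus every tissue to be rendered.
#' @param sds per-tissue noise standard deviations (recycled if scalar).
#' @param bit_depth 8 or 16.
#' @return Object of class `gray_index`.
#' @export
gray_index <- function(means = c(background = 10, muscle = 90, marrow = 135,
                                 fat = 180, skin = 225, bone = 252),
                       sds = 3, bit_depth = 8L) {
  if (anyDuplicated(means)) stop_arm("gray means must be pairwise distinct")
  if (is.null(names(means))) stop_arm("means must be named by tissue")
  sds <- rep_len(as.numeric(sds), length(means))
  names(sds) <- names(means)
  if (any(sds < 0)) stop_arm("noise sds must be >= 0")
  structure(list(means = means, sds = sds, bit_depth = as.integer(bit_depth),
                 max_intensity = 2^as.integer(bit_depth) - 1),
            class = "gray_index")
}

#' Render a label volume into noisy grayscale sections
#'
#' Pixel intensity = tissue mean gray + additive Gaussian noise (per-tissue
#' sd), clipped to the intensity range. Bit-reproducible given `seed`.
#'
#' @param vol a [label_volume].
#' @param gi a [gray_index] covering every label present in `vol`.
#' @param seed integer RNG seed.
#' @return A [slice_stack].
#' @export
render_slices <- function(vol, gi, seed = 1L) {
  stopifnot(inherits(vol, "label_volume"), inherits(gi, "gray_index"))
  present <- sort(unique(as.vector(vol$labels)))
  nm <- tissue_name(present)
  missing <- nm[!nm %in% names(gi$means)]
  if (length(missing))
    stop_arm("gray index has no entry for label(s): %s",
             paste(missing, collapse = ", "))
  labs <- vol$labels
  img <- array(gi$means[tissue_name(labs)], dim = dim(labs))
  sd_arr <- array(gi$sds[tissue_name(labs)], dim = dim(labs))
  if (any(sd_arr > 0)) {
    noise <- with_seed(seed, stats::rnorm(length(img)))
    img <- img + sd_arr * noise
  }
  img[img < 0] <- 0
  img[img > gi$max_intensity] <- gi$max_intensity
  slice_stack(img, slice_spacing = vol$spacing[3],
              pixel_spacing = vol$spacing[1], bit_depth = gi$bit_depth)
}
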