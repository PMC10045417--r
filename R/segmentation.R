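#' Gray-threshold specification for layer stripping
#'
#' Ordered (outer to inner) list of half-open gray intervals `[lo, hi)`,
#' one per tissue, plus a background interval. Ties on an interval edge
#' belong to the lower interval by the half-open convention.
#'
#' @param tissues character vector of tissue names, ordered outermost
#'   (skin) to innermost (marrow).
#' @param intervals numeric matrix (length(tissues) x 2) of `[lo, hi)` gray
#'   bounds, rows in the same order.
#' @param background length-2 `[lo, hi)` interval for background gray.
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(tissues, intervals, background) {
  intervals <- matrix(as.numeric(intervals), ncol = 2)
  if (nrow(intervals) != length(tissues))
    stop_arm("one interval per tissue required")
  if (any(intervals[, 1] >= intervals[, 2]) || background[1] >= background[2])
    stop_arm("intervals must satisfy lo < hi")
  rownames(intervals) <- tissues
  structure(list(tissues = tissues, intervals = intervals,
                 background = as.numeric(background)),
            class = "threshold_spec")
}

#' Derive thresholds from a gray index
#'
#' Interval edges are placed at midpoints between gray-adjacent tissue
#' means, extended to the full intensity range at the extremes, so the
#' intervals partition the gray axis.
#'
#' @param gi a [gray_index].
#' @param order tissue stripping order, outermost first.
#' @return A [threshold_spec].
#' @export
threshold_spec_from_gray_index <- function(gi,
                                           order = c("skin", "fat", "muscle",
                                                     "bone", "marrow")) {
  stopifnot(inherits(gi, "gray_index"))
  m <- sort(gi$means)
  edges <- c(-Inf, (m[-1] + m[-length(m)]) / 2, Inf)
  lo <- edges[match(names(gi$means), names(m))]
  hi <- edges[match(names(gi$means), names(m)) + 1]
  names(lo) <- names(hi) <- names(gi$means)
  present <- order[order %in% names(gi$means)]
  threshold_spec(present, cbind(lo[present], hi[present]),
                 background = c(lo[["background"]], hi[["background"]]))
}

in_interval <- function(x, iv) x >= iv[1] & x < iv[2]

#' Gray-threshold segmentation by layer stripping
#'
#' Implements the splitting method: (1) the total-body mask is the union of
#' all tissue gray intervals with the background removed; (2) the outermost
#' tissue is the Boolean difference between the current mask and the union
#' of all inner-tissue intervals; (3) stripping repeats inward until the
#' innermost tissue remains. Each stage keeps only the largest 26-connected
#' component of the inner mask and fills its internal cavities
#' (6-connected background), which removes singular points introduced by
#' noise.
#'
#' @param stack a [slice_stack].
#' @param spec a [threshold_spec] ordered outer to inner.
#' @return A [label_volume] on the stack's grid.
#' @export
threshold_segment <- function(stack, spec) {
  stopifnot(inherits(stack, "slice_stack"), inherits(spec, "threshold_spec"))
  if (length(spec$tissues) < 1L) stop_arm("spec must cover >= 1 tissue")
  img <- stack$images
  tc <- tissue_codes()
  union_from <- function(i) {
    acc <- array(FALSE, dim = dim(img))
    for (t in spec$tissues[seq(i, length(spec$tissues))])
      acc <- acc | in_interval(img, spec$intervals[t, ])
    acc
  }
  # overall tissue mask = background removed; gray values excluded from
  # every tissue interval (noise outliers, a mis-specified interval) still
  # belong to the body and are absorbed by the stripping order below
  total <- !in_interval(img, spec$background)
  if (!any(total)) {
    warn_arm("no tissue found: total-body mask is empty")
    return(label_volume(array(0L, dim = dim(img)),
                        spacing = c(stack$pixel_spacing, stack$pixel_spacing,
                                    stack$slice_spacing)))
  }
  total <- fill_holes(largest_component(total, 26L))
  labels <- array(0L, dim = dim(img))
  current <- total
  nt <- length(spec$tissues)
  for (i in seq_len(nt)) {
    t <- spec$tissues[i]
    if (i == nt) {
      mask <- current
    } else {
      inner <- union_from(i + 1L) & current
      if (any(inner)) inner <- fill_holes(largest_component(inner, 26L))
      mask <- current & !inner
      current <- inner
    }
    if (!any(mask))
      warn_arm("stripping stage for '%s' produced an empty tissue", t)
    labels[mask] <- tc[[t]]
  }
  label_volume(labels, spacing = c(stack$pixel_spacing, stack$pixel_spacing,
                                   stack$slice_spacing))
}

#' Extract a tissue boundary point cloud
#'
#' Returns the physical centers (mm) of the tissue's boundary-shell voxels:
#' voxels of the tissue having at least one face neighbor with a different
#' label (other tissue, background, or outside the grid).
#'
#' @param vol a [label_volume].
#' @param tissue tissue name or integer code.
#' @return Object of class `point_cloud`: list with `points` (n x 3 mm
#'   matrix) and `tissue`.
#' @export
extract_point_cloud <- function(vol, tissue) {
  stopifnot(inherits(vol, "label_volume"))
  code <- if (is.character(tissue)) tissue_codes()[[tissue]] else
    as.integer(tissue)
  mask <- vol$labels == code
  if (!any(mask)) {
    warn_arm("tissue '%s' absent from volume; empty cloud",
             tissue_name(code))
    return(point_cloud(matrix(numeric(0), 0, 3), tissue_name(code)))
  }
  shell <- boundary_shell(mask)
  idx <- which(shell, arr.ind = TRUE)
  point_cloud(voxel_centers(vol, idx), tissue_name(code))
}

#' @rdname extract_point_cloud
#' @param points n x 3 matrix of mm coordinates.
#' @export
point_cloud <- function(points, tissue) {
  points <- matrix(as.numeric(points), ncol = 3)
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, tissue = tissue), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point_cloud: %d points, tissue '%s'\n",
              nrow(x$points), x$tissue))
  invisible(x)
}
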