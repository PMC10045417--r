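# Plain-text I/O for stacks, volumes, clouds, surfaces and meshes.
# Everything here is deliberately text-based (ASCII PGM, ASCII STL/PLY,
# legacy ASCII VTK, JSON + run-length label volumes) so runs are portable
# and diffable.

#' Write / read a slice stack as numbered ASCII PGM files
#'
#' One P2 (ASCII) PGM per slice plus `manifest.json` with spacing, order
#' and bit depth.
#'
#' @param stack a [slice_stack].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_slice_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "slice_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$images)
  maxval <- 2^stack$bit_depth - 1
  files <- sprintf("slice_%04d.pgm", seq_len(d[3]))
  for (k in seq_len(d[3])) {
    img <- round(stack$images[, , k])
    con <- file(file.path(dir, files[k]), "w")
    writeLines(c("P2", sprintf("%d %d", d[1], d[2]), as.character(maxval)),
               con)
    # one y-scanline per output row; array order (x fastest) matches
    write(as.integer(img), file = con, ncolumns = d[1])
    close(con)
  }
  jsonlite::write_json(
    list(files = files, slice_spacing = stack$slice_spacing,
         pixel_spacing = stack$pixel_spacing, bit_depth = stack$bit_depth,
         width = d[1], height = d[2]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_slice_stack
#' @export
read_slice_stack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  imgs <- array(0, dim = c(man$width, man$height, length(man$files)))
  for (k in seq_along(man$files)) {
    ln <- readLines(file.path(dir, man$files[k]))
    ln <- ln[!startsWith(ln, "#")]
    vals <- scan(text = paste(ln[-(1:3)], collapse = " "), quiet = TRUE)
    imgs[, , k] <- matrix(vals, man$width, man$height)
  }
  slice_stack(imgs, man$slice_spacing, man$pixel_spacing, man$bit_depth)
}

#' Write / read a label volume as JSON + run-length encoding
#' @param vol a [label_volume].
#' @param path output `.json` file.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  r <- rle(as.vector(vol$labels))
  jsonlite::write_json(
    list(dim = dim(vol$labels), spacing = vol$spacing, origin = vol$origin,
         rle_lengths = r$lengths, rle_values = r$values),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- array(inverse.rle(list(lengths = x$rle_lengths,
                                   values = as.integer(x$rle_values))),
                  dim = x$dim)
  label_volume(labels, x$spacing, x$origin)
}

#' Write a point cloud as XYZ CSV (and optionally ASCII PLY)
#' @param pc a [point_cloud].
#' @param path output `.csv` path.
#' @param ply optional `.ply` path for an ASCII PLY copy.
#' @export
write_point_cloud <- function(pc, path, ply = NULL) {
  utils::write.csv(as.data.frame(pc$points), path, row.names = FALSE)
  if (!is.null(ply)) {
    n <- nrow(pc$points)
    con <- file(ply, "w")
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", n),
                 "property float x", "property float y", "property float z",
                 "end_header"), con)
    utils::write.table(pc$points, con, row.names = FALSE,
                       col.names = FALSE)
    close(con)
  }
  invisible(path)
}

#' Write a surface mesh as ASCII STL
#' @param surf a [surface_mesh].
#' @param path output `.stl` path.
#' @export
write_surface_stl <- function(surf, path) {
  v <- surf$vertices; tr <- surf$triangles
  a <- v[tr[, 1], , drop = FALSE]
  n <- row_cross(v[tr[, 2], , drop = FALSE] - a,
                 v[tr[, 3], , drop = FALSE] - a)
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  con <- file(path, "w")
  writeLines(sprintf("solid %s", surf$tissue %||% "surface"), con)
  for (t in seq_len(nrow(tr))) {
    writeLines(c(sprintf("  facet normal %g %g %g", n[t, 1], n[t, 2],
                         n[t, 3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", v[tr[t, ], 1],
                         v[tr[t, ], 2], v[tr[t, ], 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid", con)
  close(con)
  invisible(path)
}

#' Write a tetrahedral mesh (with optional fields) as legacy ASCII VTK
#'
#' @param mesh a [tet_mesh].
#' @param path output `.vtk` path.
#' @param point_data optional named list of per-node numeric vectors.
#' @param cell_data optional named list of per-tet numeric vectors; the
#'   tissue tag is always written.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = NULL, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tets)
  writeLines(c("# vtk DataFile Version 3.0", "armstim tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(mesh$nodes, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS tissue int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$tissue), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(cell_data[[nm]]), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(as.character(point_data[[nm]]), con)
    }
  }
  invisible(path)
}
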