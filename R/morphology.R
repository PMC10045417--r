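# 3-D binary morphology on logical arrays (face = 6-connectivity,
# full = 26-connectivity). All functions are allocation-heavy but fully
# vectorized; voxel grids at desk scale (<= a few hundred thousand voxels)
# stay well under a second per operation.

# shift a 3-D array by (dx, dy, dz), padding with `fill`
shift3 <- function(a, dx, dy, dz, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src_x <- max(1, 1 - dx):min(d[1], d[1] - dx)
  src_y <- max(1, 1 - dy):min(d[2], d[2] - dy)
  src_z <- max(1, 1 - dz):min(d[3], d[3] - dz)
  out[src_x + dx, src_y + dy, src_z + dz] <- a[src_x, src_y, src_z]
  out
}

offsets6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

offsets26 <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

# TRUE where mask has at least one neighbor (under `off`) that is TRUE
neighbor_any <- function(mask, off) {
  acc <- array(FALSE, dim = dim(mask))
  for (r in seq_len(nrow(off)))
    acc <- acc | shift3(mask, off[r, 1], off[r, 2], off[r, 3])
  acc
}

# TRUE where all face neighbors (out-of-bounds = FALSE) are TRUE
erode6 <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    if (!any(mask)) return(mask)
    acc <- mask
    for (r in seq_len(nrow(offsets6)))
      acc <- acc & shift3(mask, offsets6[r, 1], offsets6[r, 2],
                          offsets6[r, 3], fill = FALSE)
    mask <- acc
  }
  mask
}

dilate6 <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) mask <- mask | neighbor_any(mask, offsets6)
  mask
}

# flood fill: grow `seed` within `mask` under the given connectivity until
# fixpoint; returns the reached subset of mask. Frontier BFS on linear
# indices: work proportional to the component size, not the grid.
flood_fill <- function(mask, seed, connectivity = 6L) {
  off <- if (connectivity == 26L) offsets26 else offsets6
  d <- dim(mask)
  stride <- c(1L, d[1], d[1] * d[2])
  lin_off <- as.integer(off %*% stride)
  visited <- seed & mask
  frontier <- which(visited)
  dim(visited) <- NULL
  mask_v <- as.vector(mask)
  n <- length(mask_v)
  while (length(frontier)) {
    nxt <- integer(0)
    # coordinates needed for wrap guards
    fx <- (frontier - 1L) %% d[1]
    fy <- ((frontier - 1L) %/% d[1]) %% d[2]
    fz <- (frontier - 1L) %/% (d[1] * d[2])
    for (r in seq_len(nrow(off))) {
      ok <- rep(TRUE, length(frontier))
      if (off[r, 1] == 1L) ok <- fx < d[1] - 1L
      else if (off[r, 1] == -1L) ok <- fx > 0L
      if (off[r, 2] == 1L) ok <- ok & fy < d[2] - 1L
      else if (off[r, 2] == -1L) ok <- ok & fy > 0L
      if (off[r, 3] == 1L) ok <- ok & fz < d[3] - 1L
      else if (off[r, 3] == -1L) ok <- ok & fz > 0L
      nb <- frontier[ok] + lin_off[r]
      nb <- nb[mask_v[nb] & !visited[nb]]
      if (length(nb)) {
        visited[nb] <- TRUE
        nxt <- c(nxt, nb)
      }
    }
    frontier <- nxt
  }
  dim(visited) <- d
  visited
}

# label connected components; returns integer array (0 outside mask)
connected_components <- function(mask, connectivity = 26L) {
  lab <- array(0L, dim = dim(mask))
  remaining <- mask
  k <- 0L
  while (any(remaining)) {
    k <- k + 1L
    seed <- array(FALSE, dim = dim(mask))
    seed[which(remaining)[1]] <- TRUE
    comp <- flood_fill(remaining, seed, connectivity)
    lab[comp] <- k
    remaining <- remaining & !comp
  }
  lab
}

# keep only the largest connected component of mask
largest_component <- function(mask, connectivity = 26L) {
  if (!any(mask)) return(mask)
  lab <- connected_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# fill internal cavities: background components (6-connectivity) that do not
# touch the array border become foreground
fill_holes <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, dim = d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- flood_fill(!mask, border & !mask, connectivity = 6L)
  mask | (!mask & !outside)
}

# voxels of mask with >= 1 face neighbor outside the mask (incl. border)
boundary_shell <- function(mask) {
  mask & !erode6(mask)
}

# erosion that treats the axial stack ends as continuing tissue (cut
# planes, not anatomy): the end slices are replicated before eroding so
# only the lateral surface counts as body boundary
erode6_lateral <- function(mask, iterations = 1L) {
  d <- dim(mask)
  # more iterations than the largest in-plane half-width always empties
  # the mask; clamp so absurd thickness requests fail fast
  r <- min(iterations, ceiling(max(d[1], d[2]) / 2) + 1L)
  pad <- array(FALSE, dim = c(d[1], d[2], d[3] + 2L * r))
  pad[, , r + seq_len(d[3])] <- mask
  for (i in seq_len(r)) {
    pad[, , i] <- mask[, , 1]
    pad[, , d[3] + r + i] <- mask[, , d[3]]
  }
  erode6(pad, r)[, , r + seq_len(d[3]), drop = FALSE]
}
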