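#' Statistical outlier removal for point clouds
#'
#' Removes points whose mean distance to their `k` nearest neighbors
#' exceeds the global mean of that statistic by more than `sd_factor`
#' standard deviations. Order-preserving.
#'
#' @param pc a [point_cloud].
#' @param k neighborhood size (>= 3).
#' @param sd_factor rejection threshold in standard deviations.
#' @return Filtered [point_cloud].
#' @export
clean_point_cloud <- function(pc, k = 8L, sd_factor = 2) {
  stopifnot(inherits(pc, "point_cloud"))
  if (k < 3L) stop_arm("k must be >= 3")
  p <- pc$points
  n <- nrow(p)
  if (n == 0L) return(pc)
  if (n < k + 1L) {
    warn_arm("only %d points (< k + 1 = %d): cloud returned unchanged",
             n, k + 1L)
    return(pc)
  }
  sq <- rowSums(p^2)
  mean_knn <- numeric(n)
  chunk <- max(1L, floor(2e6 / n))
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    # squared distances chunk x n
    d2 <- outer(sq[idx], sq, `+`) - 2 * p[idx, , drop = FALSE] %*% t(p)
    d2[cbind(seq_along(idx), idx)] <- Inf
    d2[d2 < 0] <- 0
    mean_knn[idx] <- apply(d2, 1L, function(r)
      mean(sqrt(sort.int(r, partial = k)[seq_len(k)])))
  }
  m <- mean(mean_knn)
  # fp guard: a perfectly regular cloud has sd ~ eps and must stay intact
  cut <- m + sd_factor * stats::sd(mean_knn) + 1e-9 * m
  point_cloud(p[mean_knn <= cut, , drop = FALSE], pc$tissue)
}

#' Construct a surface mesh object
#' @param vertices n x 3 mm coordinates.
#' @param triangles t x 3 vertex indices, outward-consistent orientation.
#' @param tissue tissue name.
#' @export
surface_mesh <- function(vertices, triangles, tissue = NA_character_) {
  structure(list(vertices = matrix(as.numeric(vertices), ncol = 3),
                 triangles = matrix(as.integer(triangles), ncol = 3),
                 tissue = tissue),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, tissue '%s'\n",
              nrow(x$vertices), nrow(x$triangles), x$tissue))
  invisible(x)
}

#' Enclosed volume of a closed surface (mm^3)
#' @param surf a [surface_mesh].
#' @export
surface_volume <- function(surf) {
  v <- surf$vertices; tr <- surf$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Total surface area (mm^2)
#' @param surf a [surface_mesh].
#' @export
surface_area <- function(surf) {
  v <- surf$vertices; tr <- surf$triangles
  a <- v[tr[, 1], , drop = FALSE]
  n <- row_cross(v[tr[, 2], , drop = FALSE] - a,
                 v[tr[, 3], , drop = FALSE] - a)
  sum(sqrt(rowSums(n^2))) / 2
}

#' Watertightness / orientation check
#'
#' A closed orientable surface has every directed edge appearing exactly
#' once (hence every undirected edge shared by exactly two triangles with
#' opposite directions) and no zero-area triangle.
#'
#' @param surf a [surface_mesh].
#' @return TRUE, or a character description of the first defect.
#' @export
surface_is_watertight <- function(surf) {
  tr <- surf$triangles
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key_dir <- paste(ed[, 1], ed[, 2])
  if (anyDuplicated(key_dir)) return("duplicated directed edge")
  key_und <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key_und)
  if (any(cnt != 2L)) return("edge not shared by exactly 2 triangles")
  v <- surf$vertices
  a <- v[tr[, 1], , drop = FALSE]
  n2 <- rowSums(row_cross(v[tr[, 2], , drop = FALSE] - a,
                          v[tr[, 3], , drop = FALSE] - a)^2)
  if (any(n2 <= 0)) return("degenerate (zero-area) triangle")
  TRUE
}

#' Euler characteristic V - E + F
#' @param surf a [surface_mesh].
#' @export
surface_euler <- function(surf) {
  tr <- surf$triangles
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  n_e <- length(unique(paste(pmin(ed[, 1], ed[, 2]),
                             pmax(ed[, 1], ed[, 2]))))
  length(unique(as.vector(tr))) - n_e + nrow(tr)
}

# boundary quad faces of a voxel occupancy -> triangle soup on the corner
# grid; returns list(vertices, triangles) with outward orientation
occupancy_boundary_mesh <- function(occ, spacing, origin) {
  d <- dim(occ)
  nxc <- d[1] + 1L; nyc <- d[2] + 1L
  cid <- function(i, j, k) i + (j - 1L) * nxc + (k - 1L) * nxc * nyc
  tris <- vector("list", 6L)
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  # quad corner offsets (0/1 on the two tangential axes) for each direction,
  # wound counterclockwise seen from outside
  for (f in seq_along(dirs)) {
    dr <- dirs[[f]]
    faces <- occ & !shift3(occ, -dr[1], -dr[2], -dr[3], fill = FALSE)
    if (!any(faces)) { tris[[f]] <- matrix(0L, 0, 3); next }
    ai <- which(faces, arr.ind = TRUE)
    base <- ai       # voxel (i,j,k): face on the +dr side uses corner i+1
    pos <- (dr > 0) * 1L
    ax <- which(dr != 0)
    t_axes <- setdiff(1:3, ax)
    corner <- function(o1, o2) {
      off <- integer(3)
      off[ax] <- pos[ax]
      off[t_axes[1]] <- o1; off[t_axes[2]] <- o2
      cid(base[, 1] + off[1], base[, 2] + off[2], base[, 3] + off[3])
    }
    c00 <- corner(0L, 0L); c10 <- corner(1L, 0L)
    c11 <- corner(1L, 1L); c01 <- corner(0L, 1L)
    q <- if (sum(dr) > 0) cbind(c00, c10, c11, c01)
         else cbind(c00, c01, c11, c10)
    # wind so the normal points along +dr (outward); axis parity fix
    if (ax == 2L) q <- q[, c(1, 4, 3, 2), drop = FALSE]
    tris[[f]] <- rbind(q[, c(1, 2, 3), drop = FALSE],
                       q[, c(1, 3, 4), drop = FALSE])
  }
  tri <- do.call(rbind, tris)
  used <- sort(unique(as.vector(tri)))
  tri <- matrix(match(tri, used), ncol = 3)
  ck <- (used - 1L) %/% (nxc * nyc)
  cj <- (used - 1L - ck * nxc * nyc) %/% nxc
  ci <- used - 1L - ck * nxc * nyc - cj * nxc
  verts <- sweep(sweep(cbind(ci, cj, ck), 2, spacing, `*`), 2, origin, `+`)
  list(vertices = verts, triangles = tri)
}

# resolve non-manifold voxel configurations (two solids sharing only an
# edge or corner) by filling one adjacent empty voxel; rare after closing
fix_nonmanifold <- function(occ) {
  for (pass in seq_len(10L)) {
    d <- dim(occ)
    # edge-adjacent diagonal pairs in each coordinate plane
    bad <- array(FALSE, dim = d)
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    found <- FALSE
    for (pl in pairs) {
      for (s1 in c(-1L, 1L)) for (s2 in c(-1L, 1L)) {
        off <- integer(3); off[pl[1]] <- s1; off[pl[2]] <- s2
        o1 <- integer(3); o1[pl[1]] <- s1
        o2 <- integer(3); o2[pl[2]] <- s2
        diag_occ <- shift3(occ, off[1], off[2], off[3])
        n1 <- shift3(occ, o1[1], o1[2], o1[3])
        n2 <- shift3(occ, o2[1], o2[2], o2[3])
        culprit <- occ & diag_occ & !n1 & !n2
        if (any(culprit)) {
          found <- TRUE
          # fill the face neighbor along the first axis of the pair
          fill_at <- which(culprit, arr.ind = TRUE)
          fill_at[, pl[1]] <- fill_at[, pl[1]] - s1
          keep <- fill_at[, pl[1]] >= 1 & fill_at[, pl[1]] <= d[pl[1]]
          occ[fill_at[keep, , drop = FALSE]] <- TRUE
        }
      }
    }
    if (!found) return(occ)
  }
  occ
}

#' Reconstruct a watertight surface from a boundary point cloud
#'
#' Re-voxelizes point occupancy at the requested voxel size, applies a
#' morphological closing (radius 1), fills internal cavities, extracts the
#' 0.5-occupancy isosurface (the boundary of the voxel solid, triangulated
#' with outward orientation), and smooths it with volume-compensated
#' Laplacian smoothing (10 iterations, lambda = 0.5; the enclosed volume is
#' restored by uniform rescaling about the centroid).
#'
#' @param pc a [point_cloud].
#' @param voxel reconstruction voxel size, mm.
#' @param smooth_iterations,lambda smoothing parameters.
#' @return A watertight [surface_mesh].
#' @export
reconstruct_surface <- function(pc, voxel = 1, smooth_iterations = 10L,
                                lambda = 0.5) {
  stopifnot(inherits(pc, "point_cloud"))
  p <- pc$points
  if (nrow(p) == 0L) stop_arm("surface reconstruction failed: empty cloud")
  rng <- apply(p, 2, range)
  if (any(rng[2, ] - rng[1, ] <= 0) && nrow(p) > 1)
    stop_arm("surface reconstruction failed: degenerate (coplanar) cloud")
  pad <- 3L
  origin <- rng[1, ] - voxel / 2 - pad * voxel
  idx <- floor(sweep(sweep(p, 2, origin, `-`), 2, rep(voxel, 3), `/`)) + 1L
  d <- apply(idx, 2, max) + pad
  occ <- array(FALSE, dim = d)
  occ[idx] <- TRUE
  occ <- erode6(dilate6(occ))                  # closing, radius 1
  occ <- fill_holes(occ)
  occ <- fix_nonmanifold(occ)
  occ <- fill_holes(occ)
  if (!any(occ)) stop_arm("surface reconstruction failed: empty solid")
  bm <- occupancy_boundary_mesh(occ, rep(voxel, 3), origin)
  v <- bm$vertices; tr <- bm$triangles
  surf0 <- surface_mesh(v, tr, pc$tissue)
  target_vol <- surface_volume(surf0)
  if (smooth_iterations > 0L) {
    ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
    Adj <- Matrix::sparseMatrix(i = ed[, 1], j = ed[, 2], x = 1,
                                dims = c(nrow(v), nrow(v)))
    Adj <- ((Adj + Matrix::t(Adj)) > 0) * 1
    deg <- Matrix::rowSums(Adj)
    for (it in seq_len(smooth_iterations)) {
      avg <- as.matrix(Adj %*% v) / deg
      v <- v + lambda * (avg - v)
    }
    surf <- surface_mesh(v, tr, pc$tissue)
    vol <- surface_volume(surf)
    if (vol > 0 && target_vol > 0) {
      ctr <- colMeans(v)
      v <- sweep(sweep(v, 2, ctr, `-`) * (target_vol / vol)^(1 / 3),
                 2, ctr, `+`)
    }
    surf0 <- surface_mesh(v, tr, pc$tissue)
  }
  surf0
}

# inside mask of a closed surface on a voxel grid via vertical-ray parity;
# grid: list(dim, spacing, origin). Fully vectorized over (triangle, column)
# candidate pairs.
surface_inside_mask <- function(surf, grid) {
  d <- grid$dim; sp <- grid$spacing; or <- grid$origin
  # column sample coordinates, with an irrational nudge to dodge edge hits
  eps <- c(pi * 1e-7, exp(1) * 1e-7) * sp[1:2]
  xs <- or[1] + (seq_len(d[1]) - 0.5) * sp[1] + eps[1]
  ys <- or[2] + (seq_len(d[2]) - 0.5) * sp[2] + eps[2]
  v <- surf$vertices; tr <- surf$triangles
  ax <- v[tr[, 1], 1]; ay <- v[tr[, 1], 2]; az <- v[tr[, 1], 3]
  bx <- v[tr[, 2], 1]; by <- v[tr[, 2], 2]; bz <- v[tr[, 2], 3]
  cx <- v[tr[, 3], 1]; cy <- v[tr[, 3], 2]; cz <- v[tr[, 3], 3]
  # candidate columns per triangle from 2-D bounding boxes
  ix_lo <- pmax(1L, findInterval(pmin(ax, bx, cx), xs) + 1L - 1L)
  ix_hi <- pmin(d[1], findInterval(pmax(ax, bx, cx), xs) + 1L)
  iy_lo <- pmax(1L, findInterval(pmin(ay, by, cy), ys) + 1L - 1L)
  iy_hi <- pmin(d[2], findInterval(pmax(ay, by, cy), ys) + 1L)
  nx_c <- pmax(0L, ix_hi - ix_lo + 1L)
  ny_c <- pmax(0L, iy_hi - iy_lo + 1L)
  n_cand <- nx_c * ny_c
  keep <- which(n_cand > 0L)
  if (!length(keep)) return(array(FALSE, dim = d))
  tri_id <- rep(keep, n_cand[keep])
  # within-triangle candidate enumeration
  off <- sequence(n_cand[keep]) - 1L
  ox <- off %% rep(nx_c[keep], n_cand[keep])
  oy <- off %/% rep(nx_c[keep], n_cand[keep])
  ci <- rep(ix_lo[keep], n_cand[keep]) + ox
  cj <- rep(iy_lo[keep], n_cand[keep]) + oy
  px <- xs[ci]; py <- ys[cj]
  # barycentric point-in-triangle in the xy projection
  v0x <- cx[tri_id] - ax[tri_id]; v0y <- cy[tri_id] - ay[tri_id]
  v1x <- bx[tri_id] - ax[tri_id]; v1y <- by[tri_id] - ay[tri_id]
  v2x <- px - ax[tri_id];         v2y <- py - ay[tri_id]
  den <- v0x * v1y - v1x * v0y
  ok <- abs(den) > 1e-14
  u <- (v2x * v1y - v1x * v2y) / den
  w <- (v0x * v2y - v2x * v0y) / den
  inside <- ok & u >= 0 & w >= 0 & (u + w) <= 1
  tri_id <- tri_id[inside]; ci <- ci[inside]; cj <- cj[inside]
  u <- u[inside]; w <- w[inside]
  zc <- az[tri_id] + u * (cz[tri_id] - az[tri_id]) +
    w * (bz[tri_id] - az[tri_id])
  col <- ci + (cj - 1L) * d[1]
  # parity fill per column
  mask <- array(FALSE, dim = d)
  if (!length(col)) return(mask)
  o <- order(col, zc)
  col <- col[o]; zc <- zc[o]
  starts <- which(c(TRUE, col[-1] != col[-length(col)]))
  ends <- c(starts[-1] - 1L, length(col))
  zs_grid <- or[3] + (seq_len(d[3]) - 0.5) * sp[3]
  for (g in seq_along(starts)) {
    z <- zc[starts[g]:ends[g]]
    if (length(z) %% 2L != 0L) next          # grazing hit; skip column
    cl <- col[starts[g]]
    for (q in seq(1L, length(z), by = 2L)) {
      k <- which(zs_grid > z[q] & zs_grid < z[q + 1L])
      if (length(k)) {
        i <- (cl - 1L) %% d[1] + 1L
        j <- (cl - 1L) %/% d[1] + 1L
        mask[i, j, k] <- TRUE
      }
    }
  }
  mask
}

#' Solidify nested surfaces into a label volume
#'
#' Labels each voxel by the innermost watertight surface containing its
#' center (surfaces ordered outer to inner); voxels inside no surface are
#' background.
#'
#' @param surfaces list of [surface_mesh], outer to inner.
#' @param grid list with `dim` (voxel counts), `spacing` (mm) and `origin`
#'   (mm), e.g. taken from a reference [label_volume].
#' @return A [label_volume].
#' @export
solidify <- function(surfaces, grid) {
  if (inherits(grid, "label_volume"))
    grid <- list(dim = dim(grid$labels), spacing = grid$spacing,
                 origin = grid$origin)
  labels <- array(0L, dim = grid$dim)
  for (s in surfaces) {
    wt <- surface_is_watertight(s)
    if (!isTRUE(wt))
      stop_arm("surface for tissue '%s' is not watertight: %s", s$tissue, wt)
    mask <- surface_inside_mask(s, grid)
    labels[mask] <- tissue_codes()[[s$tissue]]
  }
  label_volume(labels, spacing = grid$spacing, origin = grid$origin)
}

#' Grow a thin surface layer to a minimum thickness
#'
#' Ensures the given tissue forms a rind of at least `min_thickness` along
#' the body's outer boundary: every body voxel within
#' `ceiling(min_thickness / voxel)` face-steps of the background is
#' converted to the tissue. The outer silhouette (background mask) is never
#' changed, and the axial stack ends are treated as cut planes through a
#' continuing limb rather than body surface.
#'
#' @param vol a [label_volume].
#' @param tissue the rind tissue (name or code), normally `"skin"`.
#' @param min_thickness mm.
#' @return Updated [label_volume].
#' @export
compensate_thin_layers <- function(vol, tissue, min_thickness = 1) {
  stopifnot(inherits(vol, "label_volume"))
  if (min_thickness <= 0) stop_arm("min_thickness must be > 0")
  code <- if (is.character(tissue)) tissue_codes()[[tissue]] else
    as.integer(tissue)
  if (!any(vol$labels == code))
    stop_arm("tissue '%s' not present in volume", tissue_name(code))
  r <- as.integer(ceiling(min_thickness / min(vol$spacing) - 1e-9))
  body <- vol$labels > 0L
  # the axial stack ends are cut planes (the limb continues), not surface
  core <- erode6_lateral(body, r)
  if (!any(core))
    stop_arm("min_thickness %.3g mm exceeds the local body radius",
             min_thickness)
  rind <- body & !core
  labels <- vol$labels
  labels[rind & labels != code] <- code
  label_volume(labels, vol$spacing, vol$origin)
}
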