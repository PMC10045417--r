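# Kuhn (diagonal-consistent) split of the unit cube into 6 tetrahedra.
# Each tet walks from corner (0,0,0) to (1,1,1) adding one axis at a time;
# identical in every voxel, so shared cube faces carry matching triangles.
kuhn_templates <- local({
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  parity <- c(1, -1, -1, 1, 1, -1)
  tpl <- vector("list", 6L)
  for (p in seq_len(6L)) {
    e <- diag(3)[perms[p, ], , drop = FALSE]
    verts <- rbind(c(0, 0, 0), e[1, ], e[1, ] + e[2, ], c(1, 1, 1))
    if (parity[p] < 0) verts <- verts[c(1, 3, 2, 4), ]  # fix orientation
    tpl[[p]] <- verts
  }
  tpl
})

#' Convert a label volume into a tagged tetrahedral mesh
#'
#' Splits every non-background voxel into 6 tetrahedra by the Kuhn
#' decomposition (conforming across voxels by construction), deduplicates
#' nodes, and extracts the outward-oriented boundary triangles. Node
#' numbering is lexicographic in (z, y, x) for reproducible matrices.
#'
#' @param vol a [label_volume].
#' @return Object of class `tet_mesh`: `nodes` (n x 3 mm), `tets` (m x 4
#'   node indices, positive signed volume), `tissue` (per-tet label),
#'   `voxel` (per-tet linear voxel index in the source grid),
#'   `voxel_linear` (non-background voxel list; tets of list entry g are
#'   rows `6 (g-1) + 1:6`), `boundary_faces` (B x 3, outward), and
#'   `boundary_tet` (owning tet per boundary face).
#' @export
voxel_to_tet <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  d <- dim(vol$labels)
  vox <- which(vol$labels > 0L)
  if (!length(vox)) stop_arm("empty volume: no non-background voxel")
  ai <- arrayInd(vox, d)                       # voxel (i, j, k), 1-based
  nxc <- d[1] + 1L; nyc <- d[2] + 1L           # corner grid
  corner_id <- function(ci, cj, ck)
    ci + (cj - 1L) * nxc + (ck - 1L) * nxc * nyc
  n_vox <- nrow(ai)
  tets_cid <- matrix(0L, n_vox * 6L, 4L)
  for (p in seq_len(6L)) {
    tpl <- kuhn_templates[[p]]
    for (v in seq_len(4L)) {
      tets_cid[seq_len(n_vox) * 6L - 6L + p, v] <-
        corner_id(ai[, 1] + tpl[v, 1], ai[, 2] + tpl[v, 2],
                  ai[, 3] + tpl[v, 3])
    }
  }
  used <- sort(unique(as.vector(tets_cid)))    # ascending = (z, y, x) lex
  tets <- matrix(match(tets_cid, used), ncol = 4L)
  ck <- (used - 1L) %/% (nxc * nyc)
  cj <- (used - 1L - ck * nxc * nyc) %/% nxc
  ci <- used - 1L - ck * nxc * nyc - cj * nxc
  nodes <- cbind(ci, cj, ck)                    # 0-based corner index
  nodes <- sweep(sweep(nodes, 2, vol$spacing, `*`), 2, vol$origin, `+`)
  colnames(nodes) <- c("x", "y", "z")

  mesh <- structure(list(
    nodes = nodes, tets = tets,
    tissue = rep(as.integer(vol$labels[vox]), each = 6L),
    voxel = rep(vox, each = 6L), voxel_linear = vox,
    grid_dim = d, spacing = vol$spacing, origin = vol$origin),
    class = "tet_mesh")
  bf <- boundary_faces_of(mesh)
  mesh$boundary_faces <- bf$faces
  mesh$boundary_tet <- bf$tet
  mesh
}

# faces occurring in exactly one tet, oriented outward
boundary_faces_of <- function(mesh) {
  tets <- mesh$tets
  m <- nrow(tets)
  fidx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- rbind(tets[, fidx[1, ]], tets[, fidx[2, ]],
                 tets[, fidx[3, ]], tets[, fidx[4, ]])
  opp <- c(tets[, 4], tets[, 3], tets[, 2], tets[, 1])
  owner <- rep(seq_len(m), 4L)
  # per-row sorted vertex triple (min, median, max), vectorized
  key <- matrix(c(pmin(faces[, 1], pmin(faces[, 2], faces[, 3])),
                  pmax(pmin(faces[, 1], faces[, 2]),
                       pmin(pmax(faces[, 1], faces[, 2]), faces[, 3])),
                  pmax(faces[, 1], pmax(faces[, 2], faces[, 3]))),
                ncol = 3L)
  o <- order(key[, 1], key[, 2], key[, 3])
  k <- key[o, , drop = FALSE]
  same_next <- c(rowSums(k[-1, , drop = FALSE] ==
                           k[-nrow(k), , drop = FALSE]) == 3L, FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  single <- o[!(same_next | same_prev)]
  f <- faces[single, , drop = FALSE]
  op <- opp[single]
  # orient outward: flip faces whose normal points toward the opposite node
  a <- mesh$nodes[f[, 1], , drop = FALSE]
  n <- row_cross(mesh$nodes[f[, 2], , drop = FALSE] - a,
                 mesh$nodes[f[, 3], , drop = FALSE] - a)
  inwards <- rowSums(n * (mesh$nodes[op, , drop = FALSE] - a)) > 0
  f[inwards, c(2, 3)] <- f[inwards, c(3, 2)]
  list(faces = f, tet = owner[single])
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d nodes, %d tets, %d boundary faces\n",
              nrow(x$nodes), nrow(x$tets), nrow(x$boundary_faces)))
  invisible(x)
}

# signed tet volumes in the mesh's native units (mm^3)
tet_volumes <- function(mesh) {
  p0 <- mesh$nodes[mesh$tets[, 1], , drop = FALSE]
  e1 <- mesh$nodes[mesh$tets[, 2], , drop = FALSE] - p0
  e2 <- mesh$nodes[mesh$tets[, 3], , drop = FALSE] - p0
  e3 <- mesh$nodes[mesh$tets[, 4], , drop = FALSE] - p0
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
   e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Mesh quality report
#'
#' Node/tet/boundary-face counts, min and mean dihedral angle (degrees),
#' total volume and per-tissue tet counts.
#'
#' @param mesh a [tet_mesh].
#' @return Object of class `mesh_quality` (a list).
#' @export
mesh_quality <- function(mesh) {
  if (!inherits(mesh, "tet_mesh") || is.null(mesh$tets) ||
      !nrow(mesh$tets))
    stop_arm("mesh_quality requires a built tet_mesh")
  nd <- mesh$nodes
  tets <- mesh$tets
  # outward face normals: face opposite vertex i, oriented away from it
  normals <- vector("list", 4L)
  fidx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  for (i in seq_len(4L)) {
    a <- nd[tets[, fidx[i, 1]], , drop = FALSE]
    n <- row_cross(nd[tets[, fidx[i, 2]], , drop = FALSE] - a,
                   nd[tets[, fidx[i, 3]], , drop = FALSE] - a)
    flip <- rowSums(n * (nd[tets[, i], , drop = FALSE] - a)) > 0
    n[flip, ] <- -n[flip, ]
    normals[[i]] <- n / sqrt(rowSums(n^2))
  }
  dihedrals <- matrix(0, nrow(tets), 6L)
  pair <- 0L
  for (i in 1:3) for (j in (i + 1):4) {
    pair <- pair + 1L
    cosang <- rowSums(normals[[i]] * normals[[j]])
    cosang <- pmin(1, pmax(-1, cosang))
    dihedrals[, pair] <- pi - acos(cosang)
  }
  per_tissue <- table(factor(tissue_name(mesh$tissue),
                             levels = names(tissue_codes())[-1]))
  structure(list(
    n_nodes = nrow(nd), n_tets = nrow(tets),
    n_boundary_faces = nrow(mesh$boundary_faces),
    min_dihedral_deg = min(dihedrals) * 180 / pi,
    mean_dihedral_deg = mean(dihedrals) * 180 / pi,
    total_volume_mm3 = sum(tet_volumes(mesh)),
    tets_per_tissue = per_tissue[per_tissue > 0]),
    class = "mesh_quality")
}

#' @export
print.mesh_quality <- function(x, ...) {
  cat(sprintf(
    "mesh: %d nodes, %d tets, %d boundary faces\n",
    x$n_nodes, x$n_tets, x$n_boundary_faces))
  cat(sprintf("dihedral angle: min %.1f deg, mean %.1f deg; volume %.4g mm^3\n",
              x$min_dihedral_deg, x$mean_dihedral_deg, x$total_volume_mm3))
  for (nm in names(x$tets_per_tissue))
    cat(sprintf("  %-10s %d tets\n", nm, x$tets_per_tissue[[nm]]))
  invisible(x)
}
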