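# Derived quantities of a stimulation run: contact-potential traces,
# current-density line profiles, effective depth, section sampling.

#' Contact-potential time trace
#'
#' The potential history at the mesh node nearest the electrode-center
#' skin contact (recorded during [solve_transient()]).
#'
#' @param sol a transient [field_solution].
#' @param electrode 1-based index into the solve's electrode pair, or an
#'   [electrode_spec] matched by position.
#' @return data.frame of class `time_series_trace`: `time_s`, `value_v`,
#'   plus the probe location as an attribute.
#' @export
probe_trace <- function(sol, electrode = 1L) {
  stopifnot(inherits(sol, "field_solution"))
  if (sol$mode != "transient")
    stop_arm("probe_trace requires a transient solution")
  k <- if (inherits(electrode, "electrode_spec")) {
    ctrs <- vapply(sol$load$electrodes, function(e) e$spec$center,
                   numeric(3))
    which.min(colSums((ctrs - electrode$center)^2))
  } else as.integer(electrode)
  out <- data.frame(time_s = sol$times, value_v = sol$traces[k, ])
  attr(out, "probe_node") <- sol$probe_nodes[k]
  class(out) <- c("time_series_trace", "data.frame")
  out
}

# locate points (n x 3 mm) in the mesh: voxel -> owning Kuhn tet
locate_points <- function(mesh, pts) {
  d <- mesh$grid_dim
  idx <- sweep(pts, 2, mesh$origin, `-`)
  idx <- floor(sweep(idx, 2, mesh$spacing, `/`)) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  lin <- rep(NA_integer_, nrow(pts))
  lin[ok] <- idx[ok, 1] + (idx[ok, 2] - 1L) * d[1] +
    (idx[ok, 3] - 1L) * d[1] * d[2]
  grp <- match(lin, mesh$voxel_linear)         # NA if background/outside
  tet <- rep(NA_integer_, nrow(pts))
  bary <- matrix(NA_real_, nrow(pts), 4L)
  cand <- which(!is.na(grp))
  for (q in cand) {
    rows <- (grp[q] - 1L) * 6L + 1:6
    for (t in rows) {
      vts <- mesh$nodes[mesh$tets[t, ], , drop = FALSE]
      M <- t(vts[2:4, , drop = FALSE]) - vts[1, ]
      xi <- solve(M, pts[q, ] - vts[1, ])
      bc <- c(1 - sum(xi), xi)
      if (all(bc >= -1e-9)) { tet[q] <- t; bary[q, ] <- bc; break }
    }
  }
  list(tet = tet, bary = bary)
}

#' Current-density profile along the inter-electrode center line
#'
#' Samples the element current-density magnitude at `n` uniform points on
#' the segment joining the two electrodes' skin-contact points, recording
#' the tissue label per sample. Arc positions are measured in mm from the
#' first electrode's skin entry.
#'
#' @param sol a phasor [field_solution] (steady amplitude) solved on `sys`.
#' @param sys the [fem_system].
#' @param load the [electrode_load] used for the solve.
#' @param n number of samples (>= 2).
#' @return data.frame of class `line_profile`: `pos_mm`, `j_mag`, `tissue`.
#' @export
line_profile <- function(sol, sys, load, n = 200L) {
  stopifnot(inherits(sys, "fem_system"), inherits(load, "electrode_load"))
  if (n < 2L) stop_arm("n must be >= 2")
  mesh <- sys$mesh
  p1 <- mesh$nodes[load$electrodes[[1]]$contact_node, ]
  p2 <- mesh$nodes[load$electrodes[[2]]$contact_node, ]
  tvec <- seq(0, 1, length.out = n)
  pts <- outer(tvec, p2 - p1) + rep(1, n) %o% p1
  # nudge endpoints inside the body
  pts[1, ] <- pts[1, ] + (p2 - p1) * 1e-6
  pts[n, ] <- pts[n, ] - (p2 - p1) * 1e-6
  loc <- locate_points(mesh, pts)
  if (anyNA(loc$tet))
    stop_arm("segment leaves the mesh at %d of %d samples",
             sum(is.na(loc$tet)), n)
  J <- current_density(sol, sys)
  jmag <- attr(J, "Jmag")[loc$tet]
  out <- data.frame(pos_mm = tvec * vnorm(p2 - p1),
                    j_mag = jmag,
                    tissue = tissue_name(mesh$tissue[loc$tet]))
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Effective stimulation depth
#'
#' The depth (mm from the skin entry along the inter-electrode line) down
#' to which the current-density magnitude stays at or above `threshold`:
#' the linearly interpolated position of the first downward threshold
#' crossing. If the profile never drops below threshold the depth
#' saturates at half the segment length (the far half belongs to the exit
#' electrode); if the entry sample is already below threshold the depth
#' is 0. Reported to one decimal.
#'
#' @param profile a [line_profile].
#' @param threshold effective current density, A/m^2 (default 10).
#' @return depth in mm.
#' @export
effective_depth <- function(profile, threshold = 10) {
  if (threshold < 0) stop_arm("threshold must be >= 0")
  if (!nrow(profile)) stop_arm("empty profile")
  pos <- profile$pos_mm; j <- profile$j_mag
  if (j[1] < threshold) return(0)
  below <- which(j < threshold)
  if (!length(below)) return(round(max(pos) / 2, 1))
  i <- below[1]
  # interpolate the crossing between samples i-1 and i
  w <- (j[i - 1L] - threshold) / (j[i - 1L] - j[i])
  round(pos[i - 1L] + w * (pos[i] - pos[i - 1L]), 1)
}

#' Percent excess of a over b
#'
#' `(a / b - 1) * 100`, rounded to one decimal; the tACS-vs-tDCS
#' comparison statistic.
#'
#' @param a,b positive quantities in the same units.
#' @export
percent_excess <- function(a, b) {
  if (any(b <= 0)) stop_arm("reference quantity b must be > 0")
  round((a / b - 1) * 100, 1)
}

#' Sample a field on an axis-aligned section
#'
#' Regular-grid sample of the nodal potential (barycentric interpolation)
#' and element |J| on the plane `axis = offset`; grid cells outside the
#' mesh are NA with `mask = FALSE`.
#'
#' @param sol a phasor [field_solution].
#' @param sys the [fem_system].
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param offset plane position, mm.
#' @param resolution sample spacing, mm.
#' @return list with in-plane coordinates `u`, `v`, matrices `phi` and
#'   `j_mag`, and logical `mask`.
#' @export
export_section <- function(sol, sys, axis = "z", offset, resolution = 1) {
  mesh <- sys$mesh
  ax <- match(axis, c("x", "y", "z"))
  if (is.na(ax)) stop_arm("axis must be x, y or z")
  lo <- mesh$origin; hi <- mesh$origin + mesh$grid_dim * mesh$spacing
  if (offset < lo[ax] || offset > hi[ax])
    stop_arm("plane %s = %.3g mm does not intersect the mesh", axis, offset)
  t_axes <- setdiff(1:3, ax)
  u <- seq(lo[t_axes[1]] + resolution / 2, hi[t_axes[1]], by = resolution)
  v <- seq(lo[t_axes[2]] + resolution / 2, hi[t_axes[2]], by = resolution)
  g <- as.matrix(expand.grid(u = u, v = v))
  pts <- matrix(0, nrow(g), 3)
  pts[, t_axes[1]] <- g[, 1]; pts[, t_axes[2]] <- g[, 2]
  pts[, ax] <- offset
  loc <- locate_points(mesh, pts)
  phi_n <- if (is.complex(sol$phi)) Mod(sol$phi) else sol$phi
  J <- current_density(sol, sys)
  jmag <- attr(J, "Jmag")
  phi_s <- j_s <- rep(NA_real_, nrow(g))
  ok <- which(!is.na(loc$tet))
  for (q in ok) {
    nds <- sys$mesh$tets[loc$tet[q], ]
    phi_s[q] <- sum(loc$bary[q, ] * phi_n[nds])
  }
  j_s[ok] <- jmag[loc$tet[ok]]
  list(u = u, v = v,
       phi = matrix(phi_s, length(u), length(v)),
       j_mag = matrix(j_s, length(u), length(v)),
       mask = matrix(!is.na(phi_s), length(u), length(v)))
}

#' Steady-state amplitude of an AC transient solution
#'
#' Least-squares sine/cosine projection of the stored last cycle of the
#' nodal history, giving the periodic steady-state amplitude per node.
#'
#' @param sol a transient AC [field_solution].
#' @return numeric vector of per-node amplitudes (V).
#' @export
ac_amplitude <- function(sol) {
  stopifnot(inherits(sol, "field_solution"))
  if (sol$mode != "transient" || sol$waveform$mode != "AC")
    stop_arm("ac_amplitude requires a transient AC solution")
  f <- sol$waveform$frequency
  tt <- sol$stored_steps * sol$dt
  n_cycle <- round(1 / (f * sol$dt))
  if (length(tt) < n_cycle)
    stop_arm("stored history shorter than one cycle")
  use <- utils::tail(seq_along(tt), n_cycle)
  S <- sin(2 * pi * f * tt[use]); Cc <- cos(2 * pi * f * tt[use])
  ph <- sol$stored_phi[, use, drop = FALSE]
  a <- 2 * (ph %*% S) / length(use)
  b <- 2 * (ph %*% Cc) / length(use)
  as.numeric(sqrt(a^2 + b^2))
}
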