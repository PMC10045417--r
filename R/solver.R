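#' Surface electrode patch
#'
#' A square current-injection patch pressed onto the body surface. The
#' patch footprint selects boundary faces whose centroid lies within the
#' two tangential half-edges of `center` and whose outward normal points
#' along `axis`; the realized contact area is the summed area of those
#' faces.
#'
#' @param center 3-D mm position of the patch center (on or near the skin).
#' @param axis outward patch normal: one of `"+x", "-x", "+y", "-y", "+z",
#'   "-z"` or a numeric length-3 direction.
#' @param edge tangential edge lengths in mm (default the standard
#'   20 x 20 mm stimulation sheet).
#' @param polarity `+1` (anode) or `-1` (cathode).
#' @return Object of class `electrode_spec`.
#' @export
electrode_spec <- function(center, axis, edge = c(20, 20), polarity = 1L) {
  if (is.character(axis)) {
    sgn <- if (startsWith(axis, "-")) -1 else 1
    ax <- match(substr(axis, 2, 2), c("x", "y", "z"))
    if (is.na(ax)) stop_arm("unknown axis '%s'", axis)
    axis <- sgn * diag(3)[ax, ]
  }
  axis <- as.numeric(axis) / vnorm(as.numeric(axis))
  if (!polarity %in% c(-1, 1)) stop_arm("polarity must be +1 or -1")
  # orthonormal tangential frame
  ref <- diag(3)[which.min(abs(axis)), ]
  t1 <- ref - sum(ref * axis) * axis; t1 <- t1 / vnorm(t1)
  t2 <- c(axis[2] * t1[3] - axis[3] * t1[2],
          axis[3] * t1[1] - axis[1] * t1[3],
          axis[1] * t1[2] - axis[2] * t1[1])
  structure(list(center = as.numeric(center), axis = axis,
                 t1 = t1, t2 = t2, edge = rep_len(as.numeric(edge), 2L),
                 polarity = as.integer(polarity)),
            class = "electrode_spec")
}

#' Stimulus waveform
#'
#' DC (constant `I`) or AC (`A sin(2 pi f t)`) injected current. Amplitudes
#' above the 20 mA tissue-safety limit are rejected. `f_material` is the
#' frequency at which the tissue dielectric table is evaluated; following
#' the controlled DC-vs-AC comparison convention it defaults to 1 kHz for
#' both modes.
#'
#' @param mode `"DC"` or `"AC"`.
#' @param amplitude injected current amplitude in ampere (<= 0.02).
#' @param frequency AC frequency in Hz (ignored for DC).
#' @param f_material material-evaluation frequency in Hz.
#' @return Object of class `stimulus_waveform` with a `current(t)` closure.
#' @export
stimulus_waveform <- function(mode = c("DC", "AC"), amplitude = 0.01,
                              frequency = 1e3, f_material = 1e3) {
  mode <- match.arg(mode)
  if (abs(amplitude) > 0.02)
    stop_arm("|amplitude| = %g A exceeds the 20 mA safety limit", amplitude)
  if (mode == "AC" && frequency <= 0) stop_arm("AC frequency must be > 0")
  current <- if (mode == "DC") function(t) rep(amplitude, length(t))
             else function(t) amplitude * sin(2 * pi * frequency * t)
  structure(list(mode = mode, amplitude = amplitude,
                 frequency = if (mode == "AC") frequency else 0,
                 f_material = f_material, current = current),
            class = "stimulus_waveform")
}

# default mapping from anatomical labels to property-table tissues
default_tag_map <- c(skin = "skin", fat = "fat", muscle = "muscle",
                     bone = "skeleton", marrow = "skeleton")

#' Assemble quasi-static FEM operators
#'
#' Builds the conduction stiffness `Ks` (from per-tet conductivity) and the
#' permittivity stiffness `Ke` (from per-tet `eps0 * eps_r`) with linear
#' (P1) tetrahedral elements. Both are symmetric positive semidefinite with
#' the constants as nullspace (pure-Neumann problem). All geometry is
#' converted to SI meters internally; potentials are volts, currents
#' amperes.
#'
#' @param mesh a [tet_mesh].
#' @param props a [tissue_properties] table.
#' @param f_eval frequency (Hz) at which the property table is evaluated.
#' @param tag_map named character vector mapping anatomical labels to
#'   property-table rows (default sends bone and marrow to "skeleton").
#' @return Object of class `fem_system`: sparse `Ks`, `Ke`, per-tet
#'   `sigma`, `eps`, barycentric gradients, tet volumes (m^3), lumped node
#'   volume weights and boundary-face geometry.
#' @export
assemble <- function(mesh, props, f_eval = 1e3, tag_map = default_tag_map) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(props, "tissue_properties"))
  labs <- sort(unique(mesh$tissue))
  nm <- tissue_name(labs)
  missing <- nm[!nm %in% names(tag_map) | !tag_map[nm] %in% names(props)]
  if (length(missing))
    stop_arm("no tissue properties for tag(s): %s",
             paste(missing, collapse = ", "))
  sig_by <- eps_by <- numeric(max(labs))
  for (i in seq_along(labs)) {
    pr <- tissue_properties_at(props, tag_map[[nm[i]]], f_eval)
    sig_by[labs[i]] <- pr[["sigma"]]
    eps_by[labs[i]] <- EPS0 * pr[["eps_r"]]
  }
  sigma <- sig_by[mesh$tissue]
  eps <- eps_by[mesh$tissue]

  nd <- mesh$nodes * 1e-3                       # mm -> m
  tets <- mesh$tets
  p0 <- nd[tets[, 1], , drop = FALSE]
  e1 <- nd[tets[, 2], , drop = FALSE] - p0
  e2 <- nd[tets[, 3], , drop = FALSE] - p0
  e3 <- nd[tets[, 4], , drop = FALSE] - p0
  cr23 <- row_cross(e2, e3); cr31 <- row_cross(e3, e1)
  cr12 <- row_cross(e1, e2)
  det <- rowSums(e1 * cr23)
  if (any(det <= 0)) stop_arm("non-positive tet volume in mesh")
  vol <- det / 6
  g1 <- cr23 / det; g2 <- cr31 / det; g3 <- cr12 / det
  g0 <- -(g1 + g2 + g3)
  grads <- list(g0, g1, g2, g3)

  n <- nrow(nd); m <- nrow(tets)
  ii <- jj <- integer(16L * m); xs <- xe <- numeric(16L * m)
  pos <- 0L
  for (i in 1:4) for (j in 1:4) {
    gg <- rowSums(grads[[i]] * grads[[j]]) * vol
    idx <- pos + seq_len(m)
    ii[idx] <- tets[, i]; jj[idx] <- tets[, j]
    xs[idx] <- sigma * gg; xe[idx] <- eps * gg
    pos <- pos + m
  }
  Ks <- Matrix::sparseMatrix(i = ii, j = jj, x = xs, dims = c(n, n))
  Ke <- Matrix::sparseMatrix(i = ii, j = jj, x = xe, dims = c(n, n))

  w <- numeric(n)                               # lumped node volumes (m^3)
  for (i in 1:4) {
    acc <- tapply(vol, tets[, i], sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc / 4
  }

  bf <- mesh$boundary_faces
  a <- nd[bf[, 1], , drop = FALSE]
  cr <- row_cross(nd[bf[, 2], , drop = FALSE] - a,
                  nd[bf[, 3], , drop = FALSE] - a)
  face_area <- sqrt(rowSums(cr^2)) / 2          # m^2
  face_normal <- cr / (2 * face_area)
  face_centroid <- (nd[bf[, 1], , drop = FALSE] +
                    nd[bf[, 2], , drop = FALSE] +
                    nd[bf[, 3], , drop = FALSE]) / 3

  structure(list(Ks = Ks, Ke = Ke, sigma = sigma, eps = eps,
                 grads = grads, vol = vol, node_weight = w,
                 face_area = face_area, face_normal = face_normal,
                 face_centroid = face_centroid,
                 mesh = mesh, f_eval = f_eval, tag_map = tag_map),
            class = "fem_system")
}

#' Electrode current load vector
#'
#' Selects the boundary faces under each patch footprint, applies a uniform
#' impressed normal current density and renormalizes so the anode-face
#' integral is exactly `+I` and the cathode exactly `-I` (realized
#' `j = I / s_realized`).
#'
#' @param sys a [fem_system].
#' @param electrodes list of two [electrode_spec] (one anode, one cathode).
#' @param I injected current in ampere.
#' @return Object of class `electrode_load`: load vector `b` (A), realized
#'   current density `j` (A/m^2), covered faces, contact area (m^2) and the
#'   skin contact node per electrode.
#' @export
electrode_load <- function(sys, electrodes, I) {
  stopifnot(inherits(sys, "fem_system"))
  pol <- vapply(electrodes, function(e) e$polarity, integer(1))
  if (length(electrodes) != 2L || sum(pol == 1L) != 1L ||
      sum(pol == -1L) != 1L)
    stop_arm("exactly one anode (+1) and one cathode (-1) required")
  n <- nrow(sys$mesh$nodes)
  b <- numeric(n)
  info <- vector("list", 2L)
  taken <- integer(0)
  for (k in seq_len(2L)) {
    el <- electrodes[[k]]
    ctr <- el$center * 1e-3                     # mm -> m
    rel <- sweep(sys$face_centroid, 2, ctr, `-`)
    u1 <- abs(rel %*% el$t1); u2 <- abs(rel %*% el$t2)
    aligned <- sys$face_normal %*% el$axis > 0.25
    sel <- which(u1 <= el$edge[1] / 2 * 1e-3 &
                 u2 <= el$edge[2] / 2 * 1e-3 & aligned)
    if (!length(sel)) {
      d <- sqrt(rowSums(rel^2))
      stop_arm(paste0("electrode patch covers no boundary face; nearest ",
                      "face centroid is %.2f mm from the patch center"),
               min(d) * 1e3)
    }
    if (length(intersect(sel, taken)))
      stop_arm("electrode patches overlap on %d boundary faces",
               length(intersect(sel, taken)))
    taken <- c(taken, sel)
    area <- sum(sys$face_area[sel])
    jdens <- I / area * el$polarity             # realized impressed j
    fl <- jdens * sys$face_area[sel] / 3        # P1 lumped face load
    fnodes <- sys$mesh$boundary_faces[sel, , drop = FALSE]
    for (v in 1:3) {
      acc <- tapply(fl, fnodes[, v], sum)
      at <- as.integer(names(acc))
      b[at] <- b[at] + acc
    }
    # contact node: face node nearest the patch center
    cand <- unique(as.vector(fnodes))
    d <- rowSums(sweep(sys$mesh$nodes[cand, , drop = FALSE] * 1e-3, 2,
                       ctr, `-`)^2)
    info[[k]] <- list(spec = el, faces = sel, area_m2 = area,
                      j_realized = jdens, contact_node = cand[which.min(d)])
  }
  structure(list(b = b, electrodes = info, I = I), class = "electrode_load")
}

# --- gauge and linear-solve helpers -----------------------------------

apply_gauge <- function(phi, sys, gauge, ground = 1L) {
  if (gauge == "zero-mean") {
    w <- sys$node_weight
    phi - sum(w * phi) / sum(w)
  } else {
    phi - phi[ground]
  }
}

grounded_factor <- function(K, ground) {
  Matrix::Cholesky(Matrix::forceSymmetric(K[-ground, -ground]),
                   LDL = FALSE, perm = TRUE)
}

solve_grounded <- function(fac, rhs, ground, n) {
  x <- numeric(n)
  x[-ground] <- as.numeric(Matrix::solve(fac, rhs[-ground],
                                         system = "A"))
  x
}

#' Phasor (frequency-domain) solve
#'
#' Solves `(Ks + i omega Ke) phi = b` for the complex nodal potential under
#' the requested gauge. The complex system is solved by preconditioned
#' fixed-point iteration on a real Cholesky factorization of `Ks` (the
#' capacitive part is a moderate perturbation for tissue at 1 kHz - 1 MHz),
#' with a real 2n x 2n sparse-LU fallback if the iteration stalls.
#'
#' @param sys a [fem_system].
#' @param load an [electrode_load] (or bare numeric load vector).
#' @param f frequency in Hz (default the assembly's `f_eval`); `f = 0`
#'   gives the purely resistive solve.
#' @param gauge `"zero-mean"` (volume-weighted mean of phi is zero) or
#'   `"ground"` (potential pinned at `ground` node).
#' @param ground node index used to fix the Neumann nullspace.
#' @param tol relative residual tolerance.
#' @return Object of class `field_solution` with complex nodal `phi`.
#' @export
solve_phasor <- function(sys, load, f = sys$f_eval,
                         gauge = c("zero-mean", "ground"), ground = 1L,
                         tol = 1e-8) {
  gauge <- match.arg(gauge)
  b <- if (inherits(load, "electrode_load")) load$b else as.numeric(load)
  bn <- sqrt(sum(abs(b)^2))
  if (bn > 0 && abs(sum(b)) > 1e-9 * sum(abs(b)))
    stop_arm("incompatible load: sum(b) = %g != 0", sum(b))
  n <- nrow(sys$mesh$nodes)
  omega <- 2 * pi * f
  fac <- grounded_factor(sys$Ks, ground)
  if (bn == 0) {
    phi <- complex(real = numeric(n))
    res <- 0
  } else if (omega == 0) {
    phi <- as.complex(solve_grounded(fac, b, ground, n))
    res <- sqrt(sum(abs(sys$Ks %*% Re(phi) - b)^2)) / bn
  } else {
    bg <- b[-ground]
    Ksg <- sys$Ks[-ground, -ground]
    Keg <- sys$Ke[-ground, -ground]
    cmv <- function(M, z)                      # complex sparse matvec
      complex(real = as.numeric(M %*% Re(z)),
              imaginary = as.numeric(M %*% Im(z)))
    x <- as.complex(as.numeric(Matrix::solve(fac, bg, system = "A")))
    res <- Inf; prev <- Inf
    for (it in seq_len(300L)) {
      r <- bg - cmv(Ksg, x) - 1i * omega * cmv(Keg, x)
      res <- sqrt(sum(abs(r)^2)) / bn
      if (res <= tol) break
      if (it > 5L && res > 0.95 * prev) { res <- Inf; break }
      prev <- res
      dx <- complex(
        real = as.numeric(Matrix::solve(fac, Re(r), system = "A")),
        imaginary = as.numeric(Matrix::solve(fac, Im(r), system = "A")))
      x <- x + dx
    }
    if (!is.finite(res) || res > tol) {
      # real block form [[Ks, -wKe], [wKe, Ks]]
      A2 <- rbind(cbind(Ksg, -omega * Keg), cbind(omega * Keg, Ksg))
      xy <- as.numeric(Matrix::solve(A2, c(Re(bg), Im(bg))))
      x <- complex(real = xy[seq_along(bg)],
                   imaginary = xy[-seq_along(bg)])
      r <- bg - cmv(Ksg, x) - 1i * omega * cmv(Keg, x)
      res <- sqrt(sum(abs(r)^2)) / bn
      if (res > 1e-6)
        stop_arm("phasor solve did not converge: residual %g", res)
    }
    phi <- complex(real = numeric(n)); phi[-ground] <- x
  }
  phi <- complex(real = apply_gauge(Re(phi), sys, gauge, ground),
                 imaginary = apply_gauge(Im(phi), sys, gauge, ground))
  structure(list(mode = "phasor", phi = phi, f = f, gauge = gauge,
                 residual = res, load = if (inherits(load, "electrode_load"))
                   load else NULL),
            class = "field_solution")
}

#' Transient (time-domain) solve
#'
#' Theta-scheme time stepping of `(Ke d/dt + Ks) phi = b(t)` from
#' `phi(0) = 0` (the body carries no charge before injection). DC runs use
#' backward Euler with an auto-estimated RC time constant (the largest
#' per-element `eps/sigma` ratio, an upper bound on the generalized
#' Rayleigh quotient of `Ke` against `Ks`) to pick the step and horizon;
#' AC runs use the trapezoidal rule at 64 steps per cycle, which preserves
#' the steady-state amplitude to second order. Full potential history is
#' kept for the probe (electrode contact) nodes; the complete nodal field
#' is stored for the last AC cycle (or the final two DC steps) unless
#' `store = "all"`.
#'
#' @param sys a [fem_system].
#' @param load an [electrode_load] built for unit current (any `I`; the
#'   waveform rescales it).
#' @param waveform a [stimulus_waveform].
#' @param dt time step (s); default `tau/12` (DC) or `1/(64 f)` (AC).
#'   AC steps coarser than `1/(16 f)` are refused.
#' @param t_end simulation horizon (s); default `8 tau` (DC), 4 cycles (AC).
#' @param scheme `"be"` (backward Euler) or `"cn"` (trapezoidal); default
#'   by mode as above.
#' @param store `"auto"` or `"all"`.
#' @param gauge,ground as in [solve_phasor()].
#' @return `field_solution` with `mode = "transient"`, probe traces and the
#'   stored tail of the nodal history.
#' @export
solve_transient <- function(sys, load, waveform, dt = NULL, t_end = NULL,
                            scheme = NULL, store = c("auto", "all"),
                            gauge = c("zero-mean", "ground"), ground = 1L) {
  store <- match.arg(store); gauge <- match.arg(gauge)
  stopifnot(inherits(sys, "fem_system"), inherits(load, "electrode_load"),
            inherits(waveform, "stimulus_waveform"))
  tau <- max(sys$eps / sys$sigma)
  if (waveform$mode == "AC") {
    f <- waveform$frequency
    if (is.null(dt)) dt <- 1 / (64 * f)
    if (dt > 1 / (16 * f))
      stop_arm("dt = %g s under-resolves the %g Hz cycle (max 1/(16 f))",
               dt, f)
    if (is.null(t_end)) t_end <- 4 / f
    if (is.null(scheme)) scheme <- "cn"
  } else {
    if (is.null(dt)) dt <- tau / 12
    if (is.null(t_end)) t_end <- 8 * tau
    if (is.null(scheme)) scheme <- "be"
  }
  if (dt <= 0 || t_end < dt) stop_arm("need dt > 0 and t_end >= dt")
  theta <- switch(scheme, be = 1, cn = 0.5,
                  stop_arm("unknown scheme '%s'", scheme))
  n_steps <- ceiling(t_end / dt)
  times <- seq_len(n_steps) * dt

  n <- nrow(sys$mesh$nodes)
  # unit-current load shape: waveform supplies I(t)
  b_unit <- load$b / load$I
  lhs <- sys$Ke / dt + theta * sys$Ks
  fac <- grounded_factor(lhs, ground)
  Keg <- sys$Ke[-ground, -ground] / dt
  Ksg <- sys$Ks[-ground, -ground]
  bg <- b_unit[-ground]

  probe_nodes <- vapply(load$electrodes, function(e) e$contact_node,
                        integer(1))
  keep_from <- if (store == "all") 1L
               else if (waveform$mode == "AC")
                 max(1L, n_steps - as.integer(round(1 / (waveform$frequency *
                                                           dt))))
               else max(1L, n_steps - 1L)
  stored <- matrix(0, n, n_steps - keep_from + 2L)  # includes step keep_from-1
  traces <- matrix(0, length(probe_nodes), n_steps + 1L)

  xg <- numeric(n - 1L)
  I_t <- waveform$current(c(0, times))
  for (s in seq_len(n_steps)) {
    rhs <- as.numeric(Keg %*% xg) - (1 - theta) * as.numeric(Ksg %*% xg) +
      (theta * I_t[s + 1L] + (1 - theta) * I_t[s]) * bg
    xg <- as.numeric(Matrix::solve(fac, rhs, system = "A"))
    phi <- numeric(n); phi[-ground] <- xg
    phi <- apply_gauge(phi, sys, gauge, ground)
    traces[, s + 1L] <- phi[probe_nodes]
    if (s >= keep_from - 1L && s - keep_from + 2L >= 1L &&
        s - keep_from + 2L <= ncol(stored))
      stored[, s - keep_from + 2L] <- phi
  }
  structure(list(mode = "transient", times = c(0, times), dt = dt,
                 scheme = scheme, waveform = waveform, gauge = gauge,
                 probe_nodes = probe_nodes, traces = traces,
                 stored_phi = stored,
                 stored_steps = seq(keep_from - 1L, n_steps),
                 load = load),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  if (x$mode == "phasor")
    cat(sprintf("field_solution (phasor, %g Hz): max |phi| = %.4g V\n",
                x$f, max(Mod(x$phi))))
  else
    cat(sprintf(
      "field_solution (transient, %s, %d steps of %.3g s)\n",
      x$waveform$mode, length(x$times) - 1L, x$dt))
  invisible(x)
}

# per-tet gradient of a nodal field (m x 3), complex-safe
field_gradient <- function(sys, phi) {
  tets <- sys$mesh$tets
  g <- sys$grads
  out <- g[[1]] * 0
  for (i in 1:4) out <- out + g[[i]] * phi[tets[, i]]
  out
}

#' Per-element current density
#'
#' Phasor mode: `J = -(sigma + i omega eps) grad phi` per element. Transient
#' mode: `J = -sigma grad phi - eps d(grad phi)/dt` with a backward
#' difference over the last two stored steps (or the two steps bracketing
#' `step`).
#'
#' @param sol a [field_solution].
#' @param sys the [fem_system] it was solved on.
#' @param step for transient solutions, index into `sol$stored_steps`
#'   (default the final step).
#' @return m x 3 matrix of element current densities (A/m^2), complex in
#'   phasor mode; attribute `"Jmag"` carries the element magnitude.
#' @export
current_density <- function(sol, sys, step = NULL) {
  stopifnot(inherits(sol, "field_solution"), inherits(sys, "fem_system"))
  if (sol$mode == "phasor") {
    gp <- field_gradient(sys, sol$phi)
    J <- -(sys$sigma + 1i * 2 * pi * sol$f * sys$eps) * gp
    attr(J, "Jmag") <- sqrt(rowSums(Mod(J)^2))
  } else {
    ns <- ncol(sol$stored_phi)
    if (is.null(step)) step <- ns
    if (step < 2L || ns < 2L)
      stop_arm(paste0("transient current density needs two stored time ",
                      "steps for the displacement term"))
    gp1 <- field_gradient(sys, sol$stored_phi[, step])
    gp0 <- field_gradient(sys, sol$stored_phi[, step - 1L])
    J <- -sys$sigma * gp1 - sys$eps * (gp1 - gp0) / sol$dt
    attr(J, "Jmag") <- sqrt(rowSums(J^2))
  }
  J
}

# discrete flux integral of element J over a set of boundary faces
boundary_flux <- function(sys, J, faces) {
  tet <- sys$mesh$boundary_tet[faces]
  jn <- rowSums((if (is.complex(J)) Re(J[tet, , drop = FALSE]) else
    J[tet, , drop = FALSE]) * sys$face_normal[faces, , drop = FALSE])
  sum(jn * sys$face_area[faces])
}
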