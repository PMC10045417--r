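# Closed-form volume-conductor solutions used as independent references
# for the FEM solver.

#' Layered 1-D slab solution
#'
#' Uniform normal current density `J0` driven through a stack of plane
#' layers: the potential drop across layer k is `J0 * d_k / sigma_k~` with
#' the complex conductivity evaluated at `frequency`. Returns the
#' cumulative interface potentials (entry face first), zero-mean gauged
#' with thickness weights.
#'
#' @param thickness_mm layer thicknesses, mm (entry side first).
#' @param sigma layer conductivities, S/m.
#' @param eps_r layer relative permittivities.
#' @param J0 impressed current density, A/m^2 (positive = into the stack).
#' @param frequency Hz (0 for DC).
#' @return list with `interfaces_mm` (depth of each interface, including
#'   both outer faces) and `phi` (complex potentials at those interfaces).
#' @export
slab_solution <- function(thickness_mm, sigma, eps_r = rep(0, length(sigma)),
                          J0, frequency = 0) {
  if (any(thickness_mm <= 0) || any(sigma <= 0))
    stop_arm("layer thicknesses and conductivities must be positive")
  sig_c <- sigma + 1i * 2 * pi * frequency * EPS0 * eps_r
  drop <- J0 * (thickness_mm * 1e-3) / sig_c
  phi <- c(0, -cumsum(drop))                 # potential falls along current
  depth <- c(0, cumsum(thickness_mm))
  # zero-mean gauge weighted by layer thickness of the piecewise-linear phi
  seg_mean <- (phi[-1] + phi[-length(phi)]) / 2
  mean_phi <- sum(seg_mean * thickness_mm) / sum(thickness_mm)
  list(interfaces_mm = depth, phi = phi - mean_phi)
}

#' Two-layer annulus (disk) series solution
#'
#' 2-D conduction in a disk of radius `b` with an inner core of radius `a`
#' (conductivity `sigma1~`) and outer annulus (`sigma2~`), driven by two
#' opposing surface arc electrodes at theta = 0 (anode) and theta = pi
#' (cathode), each of angular half-width `half_angle`. Solved per angular
#' mode with radial transfer matrices; the impressed flux over each arc may
#' be uniform or cosine-weighted (the profile a voxelized electrode of
#' axis-normal faces realizes). Fourier coefficients are computed by dense
#' quadrature so any profile is supported.
#'
#' @param a,b inner interface and outer radius, mm (`0 < a < b`).
#' @param sigma1,sigma2 core and annulus conductivities (possibly complex).
#' @param I_per_height injected current per unit axial height, A/m.
#' @param half_angle electrode angular half-width, radians.
#' @param profile `"uniform"` or `"cosine"` arc flux weighting.
#' @param n_terms number of angular modes (odd modes carry the field).
#' @return list with `phi(r_mm, theta)` evaluator (complex, zero-mean by
#'   symmetry), `flux(theta)` the impressed boundary flux (A/m^2),
#'   `tail_bound` the relative truncation bound, and the mode table.
#' @export
annulus_solution <- function(a, b, sigma1, sigma2, I_per_height,
                             half_angle, profile = c("cosine", "uniform"),
                             n_terms = 64L) {
  profile <- match.arg(profile)
  if (a <= 0 || b <= a) stop_arm("need 0 < a < b")
  if (n_terms < 8L) stop_arm("n_terms must be >= 8")
  bm <- b * 1e-3
  # impressed inward flux on the anode arc, f(theta), A/m^2
  base <- function(th) switch(profile,
    uniform = as.numeric(abs(th) <= half_angle),
    cosine = ifelse(abs(th) <= half_angle, cos(th), 0))
  # normalize: integral of f over the anode arc (times b) = I per height
  arc_integral <- switch(profile, uniform = 2 * half_angle,
                         cosine = 2 * sin(half_angle))
  scale <- I_per_height / (arc_integral * bm)
  ns <- seq_len(n_terms)
  # analytic Fourier cosine coefficients of anode-at-0 / cathode-at-pi
  # flux; even modes cancel between the two arcs
  fcoef <- vapply(ns, function(n) {
    an <- switch(profile,
      uniform = 2 * sin(n * half_angle) / (n * pi),
      cosine = if (n == 1)
        (half_angle + sin(2 * half_angle) / 2) / pi
      else
        (sin((n - 1) * half_angle) / (n - 1) +
           sin((n + 1) * half_angle) / (n + 1)) / pi)
    scale * an * (1 - (-1)^n)
  }, numeric(1))
  beta <- sigma1 / sigma2
  am <- a * 1e-3
  # per-mode radial amplitudes (see derivation in the methods vignette)
  A <- B <- Cc <- rep(0i, n_terms)
  for (n in ns) {
    denom <- sigma2 * n * bm^(n - 1) *
      ((1 + beta) / 2 - (1 - beta) / 2 * (am / bm)^(2 * n))
    A[n] <- fcoef[n] / denom
    B[n] <- A[n] * (1 + beta) / 2
    Cc[n] <- A[n] * (1 - beta) / 2 * am^(2 * n)
  }
  # truncation tail: mode amplitudes decay ~ n^-2 (uniform arc) or faster
  # (cosine); bound the tail sum by amp_N * N / 2 relative to the series
  amp <- Mod(B * bm^ns + Cc * bm^(-ns))
  total <- sqrt(sum(amp^2))
  tail_rel <- (mean(utils::tail(amp, 8)) * n_terms / 2) / max(total, 1e-300)
  phi_eval <- function(r_mm, theta) {
    r <- r_mm * 1e-3
    out <- rep(0i, length(r))
    inner <- r <= am
    for (n in ns) {
      if (Mod(A[n]) == 0) next
      radial <- ifelse(inner, A[n] * r^n, B[n] * r^n + Cc[n] * r^(-n))
      out <- out + radial * cos(n * theta)
    }
    out
  }
  if (tail_rel > 0.01)
    stop_arm("annulus series tail bound %.3g > 1%%: increase n_terms",
             tail_rel)
  list(phi = phi_eval, flux = function(th) scale *
         (base(th) - base(ifelse(th >= 0, th - pi, th + pi))),
       tail_bound = tail_rel,
       modes = data.frame(n = ns, f_n = fcoef, amplitude = amp))
}

#' Separable harmonic box mode
#'
#' Exact potential in a homogeneous box `[0, Lx] x [0, Ly] x [0, Lz]` with
#' insulated sides and the impressed inward flux
#' `g(x, y) = g0 cos(pi x / Lx) cos(pi y / Ly)` on the top face (opposite
#' sign on the bottom face): a single smooth Neumann mode, used to measure
#' the solver's discretization convergence order on a geometry-exact
#' domain.
#'
#' @param L box edge lengths `c(Lx, Ly, Lz)` in mm.
#' @param sigma conductivity, S/m.
#' @param g0 flux amplitude, A/m^2.
#' @return list with `phi(x, y, z)` (mm arguments, volts, zero-mean by
#'   symmetry) and `flux_top(x, y)`.
#' @export
box_mode_solution <- function(L, sigma, g0) {
  Lm <- L * 1e-3
  kx <- pi / Lm[1]; ky <- pi / Lm[2]
  kappa <- sqrt(kx^2 + ky^2)
  # phi = Amp cos(kx x) cos(ky y) sinh(kappa (z - Lz/2));
  # inward flux at top: sigma dphi/dz = g  ->  Amp sigma kappa cosh(...) = g0
  Amp <- g0 / (sigma * kappa * cosh(kappa * Lm[3] / 2))
  list(
    phi = function(x, y, z)
      Amp * cos(kx * x * 1e-3) * cos(ky * y * 1e-3) *
        sinh(kappa * (z * 1e-3 - Lm[3] / 2)),
    flux_top = function(x, y)
      g0 * cos(kx * x * 1e-3) * cos(ky * y * 1e-3))
}
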