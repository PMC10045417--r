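---
title: "A layered digital arm for electrical stimulation simulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A layered digital arm for electrical stimulation simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package computes

`armstim` is an end-to-end pipeline for studying how surface-electrode
current injection (tDCS: constant current; tACS: sinusoidal current)
spreads through a human limb modeled as a passive volume conductor. The
pipeline has a biological-image-analysis front end and a finite-element
physics back end:

1. **Phantom** — a parametric layered arm (skin, fat, muscle, cortical
   bone, bone marrow) is voxelized and rendered into noisy grayscale
   serial sections, emulating a cryosection acquisition such as a visible
   human dataset.
2. **Segmentation** — the sections are segmented back into tissues by
   gray thresholding with layer-by-layer Boolean stripping from the skin
   inward to the marrow.
3. **Reconstruction** — per-tissue boundary point clouds are cleaned,
   turned into watertight surfaces, and solidified back into a conforming
   label volume; thin surface layers are grown to a minimum thickness.
4. **Meshing** — the label volume becomes a tagged tetrahedral mesh by
   the Kuhn 6-tet decomposition of each voxel.
5. **Solver** — the quasi-static potential equation
   $\nabla\cdot(-\tilde\sigma_k\nabla\varphi)\approx 0$ is solved with P1
   elements, where $\tilde\sigma_k=\sigma_k+i\omega\varepsilon_0
   \varepsilon_{r,k}$ is the complex conductivity of tissue layer $k$
   (the outermost layer being the skin), in phasor and time-stepping
   modes.
6. **Post-processing** — contact-potential traces, current-density line
   profiles between the electrodes, the effective stimulation depth at a
   10 A/m² threshold, and tACS-vs-tDCS percent comparisons.

# The physical model and its assumptions

Between 1 kHz and 1 MHz the body behaves as a quasi-static volume
conductor: wave propagation and magnetic induction are negligible, the
field is a scalar potential, and the net charge density is zero. Current
enters only through the electrode patches; everywhere else the surface is
insulating (homogeneous Neumann boundary). The electrodes are ideal
impressed-current sources: a patch of nominal area $s$ (default the
20 × 20 mm stimulation sheet) carries a uniform normal current density
$j = I/s$, positive under the anode and negative under the cathode, with
$I \le 20$ mA enforced as a tissue-safety limit. There is no
electrode-skin contact impedance layer, no Joule heating, and no
hemodynamics; bone and marrow share one "skeleton" dielectric spectrum
because the standard four-tissue table carries no separate marrow row.

A note on the complex conductivity: the governing-equation form
$\sigma + i\varepsilon_0\varepsilon_r$ sometimes seen in print is
dimensionally inconsistent; the package implements the standard
quasi-static $\sigma + i\omega\varepsilon_0\varepsilon_r$.

Tissue dielectric data are tabulated at 1, 10, 100 and 1000 kHz
(`tissue_properties()`), with log-log linear interpolation in between and
no extrapolation outside the range. For controlled DC-vs-AC comparisons
the table is evaluated at 1 kHz for both modes (`f_material`), because a
literal 0 Hz evaluation is outside every measured dispersion table.

# The synthetic phantom: what it emulates and what it does not

The default phantom (`phantom_spec()`) stands in for a visible-human arm
acquisition: 96 axial slices at 1 mm (the full-scale acquisition of ~727
slices at ≤1 mm is reproduced by `n_slices = 727`), a 48 × 48 in-plane
grid at 1 mm, outer radius tapering linearly 20 → 16 mm, 1.5 mm skin and
3.5 mm fat annuli, a single eccentric bone (5 mm cortical outer radius,
2.5 mm shell) offset 4 mm along +x so the inter-electrode center line
passes through it. Gray rendering uses 8-bit means chosen to mimic a
cryosection's appearance — cortical bone (252) and skin (225) bright, fat
(180) and marrow (135) intermediate, muscle (90) dark, background (10) —
with additive Gaussian noise (default sd 3) clipped to the intensity
range. Two deliberate consequences of this gray assignment: every pair of
*spatially adjacent* tissues is at least 45 gray levels apart, and the
closest pair on the gray axis (bone/skin, 27 apart) never touches
anatomically, so threshold errors at the stated noise bound (sd = ¼ of
the minimum adjacent-interval gap) are rare and isolated.

The phantom does **not** emulate: multi-bone anatomy (forearm), intensity
drift across slices, partial-volume blur, photographic color, or any
CT/MRI modality. A green pipeline test therefore establishes that the
algorithms are self-consistent on a body-like layered geometry — not that
they would segment a real cryosection without parameter tuning.

# Numerical choices

* **Segmentation conventions.** Gray intervals are half-open $[lo, hi)$
  (ties to the lower interval); stripping keeps the largest 26-connected
  component of each inner mask and fills 6-connected internal cavities
  (the standard foreground/background connectivity duality). Segmentation
  operates on the full 3-D stack. An empty total-body mask returns an
  all-background volume with a warning rather than an error, matching the
  pure-background contract.
* **Surface reconstruction** is occupancy-grid based: re-voxelize the
  cloud (the voxel must be at least the coarsest source spacing, or the
  shell is not closed), morphologically close with radius 1, fill
  cavities, extract the 0.5-isosurface of the binary solid (the voxel
  boundary, triangulated outward), then 10 iterations of Laplacian
  smoothing with $\lambda = 0.5$ and a final uniform rescale about the
  centroid that restores the enclosed volume. This is deterministic and
  watertight by construction, unlike Poisson or ball-pivoting
  reconstructions. Rare non-manifold voxel configurations (solids
  touching only along an edge) are resolved by filling one adjacent
  voxel.
* **Solidification** labels a voxel by the innermost watertight surface
  containing its center, via vertical-ray parity with an irrational
  half-pixel jitter to dodge edge-grazing rays.
* **Thin-layer compensation** converts every body voxel within
  `ceiling(min_thickness / voxel)` face-steps of the background into the
  rind tissue. The axial stack ends are cut planes through a continuing
  limb, not anatomy, so erosion replicates the end slices rather than
  treating them as boundary; the outer silhouette is never modified and
  the operation is idempotent.
* **Meshing** uses the Kuhn 6-tet split with a shared cube diagonal, so
  the mesh is conforming across voxels by construction, tet volumes sum
  exactly to the voxel volume, and the dihedral-angle spectrum (minimum
  45°) is identical in every voxel. Nodes are numbered lexicographically
  for reproducible matrices. No attempt is made to reproduce the element
  counts of commercial free meshers.
* **Gauge.** The pure-Neumann system has the constants as nullspace. The
  solver grounds one node for factorization and then shifts to a
  volume-weighted zero-mean gauge (default) or leaves the grounded gauge;
  potential *differences* are gauge independent to solver precision,
  which is tested.
* **Complex solve.** The sparse symmetric real part $K_\sigma$ is
  factorized (Cholesky) once; the phasor system
  $(K_\sigma + i\omega K_\varepsilon)\varphi = b$ is solved by
  preconditioned defect correction, which converges geometrically because
  $\omega\varepsilon_0\varepsilon_r/\sigma \lesssim 0.32$ for tissue in
  band; a real $2n \times 2n$ sparse-LU fallback guards the iteration.
  Residual tolerance: $10^{-8}\,\lVert b\rVert$.
* **Time stepping.** DC runs use backward Euler from $\varphi(0)=0$ with
  an auto-estimated RC time constant $\tau = \max_e
  (\varepsilon/\sigma)_e$ (an upper bound for the generalized Rayleigh
  quotient of $K_\varepsilon$ against $K_\sigma$), default
  $\Delta t = \tau/12$ over $8\tau$. AC runs use the trapezoidal
  (Crank–Nicolson) rule at 64 steps per cycle for 4 cycles. The design
  originally called for backward Euler in both modes, but BE's
  first-order frequency warping adds a spurious conductance of order
  $(\omega\Delta t/2)\,\omega\varepsilon$ — about 1.5% of amplitude at
  skin-dominated nodes at 64 steps/cycle — which provably breaks the 1%
  transient-vs-phasor consistency contract; the trapezoidal rule is
  second order with no spurious damping and reproduces the phasor
  amplitude to better than 0.01%. Steps coarser than 1/16 of a cycle are
  refused.
* **Effective depth** is the linearly interpolated position of the first
  downward crossing of the current-density threshold along the
  inter-electrode segment, measured from the skin entry; a profile that
  never drops below threshold saturates at half the segment (the far half
  belongs to the exit electrode), and an entry sample below threshold
  gives 0. This single-sided reading reconciles the saturated case with
  the worked 25 → 5 A/m² example (depth 15 mm at threshold 10). Depths
  and percent comparisons are reported to one decimal.

# Verification strategy

Three closed forms act as independent references (`slab_solution`,
`annulus_solution`, `box_mode_solution`):

* The **layered slab** under uniform flux has a piecewise-linear exact
  potential that lies *inside* the P1 space, so the FEM reproduces it to
  machine precision — a strong identity check, but useless for measuring
  convergence *order*.
* The **two-layer annulus** (Fourier series with per-mode radial transfer
  matrices) validates layered radial attenuation on a curved,
  heterogeneous domain. Because the voxelized cylinder realizes the
  electrode as axis-normal staircase faces, the continuum flux it imposes
  per unit arc is cosine-weighted, and the oracle is evaluated with that
  profile. Voxelized curved boundaries carry an O(h) geometric error, so
  agreement is checked at 3% in relative L2 at 0.5 mm voxels.
* The **harmonic box mode** (a single separable Neumann mode on a
  geometry-exact domain) isolates the element discretization error and is
  where the empirical convergence order (measured ≈ 2.0, required ≥ 1.8)
  is computed. Electrode current recovery from element-constant fluxes is
  checked on the slab, where that recovery is exact; on staircase
  boundaries raw flux summation carries O(h) surface error that is not a
  solver defect.

# Runtime scaling

The FEM acceptance runs use the default phantom geometry, materials and
protocol (10 mA, 1 kHz, 20 × 20 mm electrodes on the ±x flanks at
mid-height) discretized at 2 mm (24 × 24 × 48, ≈ 14k nodes) rather than
1 mm (≈ 106k nodes): the pre-installed linear algebra stack runs
single-threaded reference BLAS, making the 1 mm factorization a
multi-minute job, and every property checked (transient-phasor
consistency, DC > AC contact potential, AC depth ≥ DC depth, >10×
current-density collapse into bone) is resolution independent — a 1 mm
reference run reproduces all orderings. Data-path checks (segmentation
recovery, reconstruction Dice) run at the full 1 mm resolution.

# Known limitations

* The phantom's geometric realism is limited (single bone, circular
  cross sections, no partial-volume effects); absolute potentials and
  depths depend on that geometry and are not comparable to values
  computed on real visible-human anatomy.
* Electrode patches are axis-aligned footprints selected on boundary
  faces; strongly curved or oblique placements should use a fine mesh so
  the staircase normal filter (`n · axis > 0.25`) selects the intended
  faces.
* The solver is direct-factorization based and memory-bound around
  ~10⁵ nodes on a small container; larger meshes need an iterative
  back end.
* File formats are deliberately plain text (ASCII PGM stacks, ASCII
  STL/PLY, legacy ASCII VTK, JSON run-length label volumes); binary
  TIFF/PLY/STL interchange is out of scope.
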