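---
title: "Methods: band-limited spherical-harmonic tensor tomography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band-limited spherical-harmonic tensor tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(saxstt)
```

This vignette documents the model, the numerical choices, and the design
decisions behind `saxstt`, at the level of detail a user needs to judge
what the package computes and what its tests do and do not demonstrate.

## The measurement model

A scanning-SAXS measurement at fixed |q| probes, for each raster position
(j, k) and each sample orientation (α, β), the intensity scattered into
directions orthogonal to the beam.  Per voxel, that intensity is a
function on the unit sphere — the reciprocal-space map (RSM).  Friedel
symmetry (I(q) = I(−q)) makes the RSM antipodally symmetric, so its
spherical-harmonic expansion contains only even orders.  The package uses
real, orthonormal spherical harmonics without the Condon–Shortley phase,
ordered ℓ-major with m = −ℓ…ℓ; with band limit ℓ_max the number of
coefficients is M = (ℓ_max + 1)(ℓ_max + 2)/2.

Two linear operators compose the forward model:

* the **John (X-ray) transform** `john_transform()`: each raster pixel
  casts one ray through the pixel centre along the beam direction
  u(α, β) = (cos α cos β, sin α cos β, sin β); every traversed voxel
  contributes in proportion to the exact length of the intersecting ray
  segment (Siddon-style traversal, compiled).  Rays outside the volume
  contribute zero, and there is no beam-width model.  The adjoint uses the
  identical traversal weights, so the dot-product identity
  ⟨Tx, y⟩ = ⟨x, Tᵀy⟩ holds at machine precision — a property the test
  suite asserts directly, since first-order solvers fail subtly with
  inexact adjoints.
* the **arc-integral matrix** `sh_circle_bins()`: one projection sees the
  great circle C(φ) = cos φ·e_j + sin φ·e_k of directions orthogonal to
  u.  Detector azimuth bin i integrates the basis over
  [φ_i − Δφ/2, φ_i + Δφ/2] along this circle, by 16-point Gauss–Legendre
  quadrature per bin (validated against dense trapezoid quadrature at
  1e−8; closed forms would be an optimization, not an accuracy
  improvement).  φ = 0 is aligned with e_j, and (u, e_j, e_k) is a
  right-handed orthonormal triple with e_j horizontal; these conventions
  are recorded in every dataset container because azimuth-origin and
  handedness mismatches are the classic source of cross-code
  disagreement.

The binned data of all projections form the linear system D = P X Y.
With N azimuthal bins tiling [0, π), the restriction of an even-order
expansion to a great circle is an even trigonometric polynomial with
ℓ_max + 1 independent components, so the bin map has full column rank
exactly when ℓ_max ≤ N − 1: eight bins (the default, matching common
experimental practice) admit even orders up to 6.
`circle_trig_bin_matrix()` exposes this rank argument, and the test suite
verifies both the full-rank and the rank-deficient side.

## The inverse problem

Reconstruction minimizes

loss(X) = ‖P X Y − D‖² + λ/(4π) · Σ over 6-connected neighbour pairs of
|c_i − c_j|²,

which with the orthonormal basis and cross-spectrum normalization
N_ℓ = 1/(4π) is exactly the summed squared spherical-L2 distance between
neighbouring RSMs; minimizing it maximizes neighbour covariance.  Boundary
handling is replicate (no wrap-around pairs), so spatially constant fields
incur zero penalty.  A single global λ multiplies the whole
coefficient-space penalty; no per-order weighting is applied, keeping the
regularizer a literal function-space smoothness term.  Residuals are plain
(unweighted) least squares; masked detector pixels contribute zero
residual and zero gradient, and NaN at unmasked pixels is an error rather
than silently dropped data.

The objective is convex. It is minimized with L-BFGS-B, chosen for
robustness on large convex quadratics; the stopping rule is a relative
loss change below `tolerance` (default 1e−6) or `max_iter` (default 200).
Because the geometry is fixed across iterations, the sparse ray-weight
matrix P is assembled once per reconstruction and each iteration reduces
to two sparse matrix products — the same weights as the ray-traced
operator, which the tests cross-check.  The convergence record reports the
strictly improving subsequence of evaluated losses (the accepted
iterates); line-search probes are excluded.

Parameters that matter:

* **λ** (≥ 0, units of intensity²·per-pair): the only genuinely free
  parameter.  The default heuristic scales the penalty gradient to about
  0.1% of the data gradient at a coefficient contrast estimated from the
  mean nonzero bin value, the mean chord length and the bin width; it is a
  starting point, not a substitute for a small sweep on real data (the
  noise study in the tests uses a fixed λ = 10 at its 16³ scale, chosen by
  such a sweep at high SNR).
* **ell_max** (even): defaults to N_bins − 2, the largest even order below
  the Nyquist limit.  Exceeding N_bins − 1 triggers a warning, not an
  error, since over-complete fits are occasionally useful diagnostics.
* **init_scale**: ensemble runs start from i.i.d. uniform coefficients a
  few orders of magnitude below the expected solution scale (default
  1e−3 of mean-data/mean-chord); with a convex objective all runs meet at
  the same loss, which the tests assert to 0.1%.
* **mode = "rank2"**: forces ℓ_max = 2, reproducing the symmetric rank-2
  tensor model of classical iterative reconstruction while sharing the
  solver, projector and regularizer.  At ℓ_max = 2 the two modes are the
  same model, and their losses agree to within the stopping tolerance.

## Rotation-invariant evaluation

All comparisons between RSMs use rotational invariants built from the
cross-spectrum S_ℓ(g, h) = (1/4π) Σ_m c_ℓ^m(g) c_ℓ^m(h): spherical mean
ḡ = c_0⁰/√(4π), anisotropic power var(g) = Σ_{ℓ≥2} S_ℓ(g, g), relative
anisotropy σ(g)/ḡ (scale-invariant, unbounded above — deliberately not
normalized by the root mean square, which would saturate at 1), and the
squared Pearson correlation R² = cov²/(var·var), which is invariant under
affine maps g → a + b·g and under common rotations.  Voxels with zero
anisotropic power have undefined R² and relative anisotropy; they are
flagged NaN and excluded from summaries rather than imputed.  Box-plot
summaries use Tukey boxes with whiskers spanning the data inside
[Q1 − 1.25·IQR, Q3 + 1.25·IQR]; the 1.25 factor (rather than the more
common 1.5) is the convention adopted for all evaluation reports here.

The ensemble consistency statistic is the anisotropic power quotient
Q = var(mean_i g_i) / mean_i var(g_i), the anisotropic power of the
voxel-wise ensemble average divided by the average anisotropic power.  By
Jensen/Cauchy–Schwarz Q ∈ [0, 1], with Q = 1 exactly when all members
share the same anisotropic part; all-isotropic voxels are NaN.  The
numerator/denominator arrangement (power of the average over average of
powers) is the one satisfying both limiting properties and is fixed as
the package definition.

The principal orientation maps the six ℓ = 2 coefficients to the
symmetric traceless tensor T = ∫ g₂(n)(nnᵀ − I/3) dΩ (computed by exact
quadrature rather than a hard-coded coefficient correspondence, making it
convention-proof) and returns the eigenvector of the most distinct
eigenvalue — the axis about which the ℓ = 2 part is closest to zonal.
Signs are fixed to the +z hemisphere (ties: +x, then +y); degenerate
eigenvalue pairs are flagged.

Squared-representation reconstructions (from methods that fit squared
polynomials) are brought into the plain representation by
`expand_squared()`: the square of a band-limit-L function is a spherical
polynomial of band limit 2L, sampled on an equiangular polar grid with
quadrature weights solved exactly for all Legendre degrees the integrand
contains, and re-projected.  The grid density is derived from the input
and output band limits, so the expansion is exact to rounding; the
acceptance check measures the variance error against a dense-quadrature
oracle and finds it at the 1e−12 % level, comfortably below the 0.1%
accuracy that ensemble analysis of squared representations requires.

## The phantom simulator

`synthesize_field()` generates textured ground-truth volumes intended to
emulate the structure of real anisotropic samples:

1. **Sources.**  `n_sources` texture seeds are placed by greedy
   farthest-point sampling under the interior (geodesic) distance — the
   shortest path through the support mask's 26-connected voxel graph with
   Euclidean edge weights (igraph Dijkstra).  The greedy start is the
   voxel nearest the mask centroid; it is itself returned for n = 1 and
   discarded otherwise, which makes the two-source solution on a rod its
   exact end voxels.  The seed only breaks ties.
2. **Source spectra.**  Each source carries a band-limited function whose
   per-order power follows ℓ^(−1.5) (exponent exposed in the spec),
   normalized to a chosen total anisotropy (default: relative anisotropy
   0.4 at unit mean — a realistic mid-range texture strength).  The three
   symmetry classes are: `zonal` (ℓ-weighted zonal delta about a random
   axis, weights 1/(2ℓ+1), band limit 12), `rank2` (orders {0, 2} only),
   and `high_order` (band limit 8 with the ℓ = 2 power damped to equal
   the ℓ = 4 power, mimicking RSMs where meridional and equatorial ℓ = 2
   contributions cancel).
3. **Field synthesis.**  Every voxel mixes the unit-power source
   directions, weighted by the Gaussian kernel exp(−d²/2σ²) of interior
   distance (σ = correlation length, default a quarter of the mask
   diameter), with a spatially smoothed unit-power noise texture that is
   orthogonalized against the source mixture.  The construction is closed
   form and gives three guarantees by design rather than by iterative
   fitting: per-order power equals the kernel-weighted average of source
   powers exactly; the per-order correlation between a voxel and its
   source equals the Gaussian kernel weight exactly (single source) and
   approximately under source competition; and the field is continuous
   because every ingredient varies smoothly in space.  An iteratively
   solved penalized program could trade these exact properties against
   e.g. strict zonality; the closed form was chosen because it is
   deterministic, fast, and each advertised property is directly
   testable.
4. **Non-negativity.**  Each voxel function is sampled on a dense
   direction grid and the isotropic coefficient is raised just enough to
   lift the sampled minimum to zero — only ℓ = 0 changes and the
   operation is idempotent (to grid resolution, which is the stated
   contract).

Measurements add Gaussian noise with standard deviation
(mean nonzero clean signal)/SNR, clipped at zero with the clipped count
reported; a Poisson option scales the clean signal to snr² expected
counts per mean bin.  The Gaussian definition was chosen because it makes
the realized SNR directly verifiable (the tests recover the requested SNR
within 10% over realizations); the noise model is an argument, not a
hard-wired choice.

The default acquisition is two tilt series, β ∈ {0°, 45°}, α from 0° to
170° in 10° steps — 36 projections with a realistic missing wedge.  The
canonical full-scale phantom shapes (50³ with 4 zonal sources, 50³ with 2
rank-2 sources, 60×60×80 with 5 high-order sources) are supported, but
tests and examples default to 16³ so the whole suite runs in minutes on
one CPU; the study conditions (8 bins, band limits 12/2/8, two tilt
series, SNR endpoints 37 and 4 with geometric intermediates 17 and 8)
are preserved at that scale.

## What the tests show, and what they do not

The synthetic studies demonstrate: exact forward/adjoint pairing;
agreement of the discrete forward model with dense double quadrature to
1%; gradient correctness to 1e−5; recovery of band-limit-matched
noiseless phantoms to median voxel R² > 0.95 from 36 projections;
monotone degradation with noise; the band-limit ceiling of binned data;
and the material advantage of band limit 6 over rank-2 fitting on
high-order textures.  They do not demonstrate robustness to effects the
simulator does not model: detector-level physics (form factors,
q-resolution, beam width), self-absorption, per-projection intensity
drift, alignment errors, or non-Gaussian detector noise.  Conclusions
about real experiments therefore rest on the linearity of the model and
the invariance of the evaluation metrics, not on the phantom studies
alone.

## Numerical choices and degenerate inputs

* Sphere integration uses Gauss–Legendre × uniform-azimuth product
  quadrature internally (exact for band-limited integrands); the
  equiangular grid is used where squared representations are expanded.
* Expansion rotation is performed by exact quadrature re-projection
  (sample at back-rotated nodes, re-project), which is exact for
  band-limited functions and avoids Wigner-matrix bookkeeping entirely.
* Associated Legendre functions come from a stable library routine; the
  Condon–Shortley phase is removed so the basis matches the common
  geophysical real convention.  Any self-consistent sign convention
  passes the package's own tests; comparing coefficients with other codes
  may require a documented per-m sign remapping.
* Rays parallel to a volume face, bins that do not tile [0, π), improper
  rotations, non-unit directions, negative λ, and coefficient/convention
  mismatches are rejected with diagnostics rather than silently handled.
* Reconstruction problem sizes in the tests (16³ voxels, 36 projections,
  ℓ_max ≤ 6, ≤ 400 iterations) were chosen as the smallest scale at which
  every qualitative phenomenon of the full-scale studies (missing wedge,
  band-limit ceiling, noise response) is still visible.
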