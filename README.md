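# saxstt

Small-angle scattering tensor tomography (SAXSTT) reconstructs, in every
voxel of a three-dimensional sample, the *reciprocal-space map* (RSM): the
angular distribution of scattered intensity at fixed |q|, a function on the
unit sphere that encodes the local nanostructure texture — fiber
orientation in bone collagen, mineral platelet alignment, polymer chain
orientation.  The inputs are scanning-SAXS rasters acquired at many sample
rotations and tilts, with each detector pattern azimuthally integrated into
a small number of bins.

`saxstt` is an R package for scientists running or simulating such
experiments.  It implements a fully linear reconstruction: each voxel's RSM
is expanded in real, orthonormal, even-order spherical harmonics (odd
orders vanish by Friedel symmetry, I(q) = I(-q)),

    f(r, θ, φ) = Σ_{ℓ even} Σ_m  a_ℓ^m(r) Y_ℓ^m(θ, φ),

and the measurement is modelled as the John (X-ray) transform of the
coefficient fields contracted with great-circle arc integrals of the basis:
one projection at rotation/tilt (α, β) probes the great circle of
directions orthogonal to the beam, and bin *i* of pixel (j, k) is

    D[j,k,i] = Σ_m  (P a_m)[j,k] · Y[m,i],   i.e.   D = P X Y

with **P** the sparse ray-tracing matrix (exact ray–voxel intersection
lengths) and **Y** the matrix of arc integrals of the basis over each
azimuthal bin.  The coefficients **X** are recovered by regularized least
squares,

    min_X  ‖P X Y − D‖²  +  λ Σ_{⟨i,j⟩} ‖g_i − g_j‖²_{S²},

where the penalty sums squared spherical-L2 distances between 6-connected
neighbour voxels and the problem is convex; a limited-memory quasi-Newton
method solves it.  With N azimuthal bins on [0, π), the band limit that the
data can uniquely constrain is ℓ_max = N − 1 (Nyquist); the default 8 bins
admit even orders up to 6.  A `rank2` mode restricts the expansion to
ℓ_max = 2, the symmetric rank-2 tensor model of classical iterative
reconstruction, sharing the same solver.

The package also provides:

* a **synthetic-phantom simulator** with three texture symmetry classes
  (approximately zonal at ℓ_max = 12, pure rank-2, and high-order with
  matched ℓ = 2 / ℓ = 4 power), Gaussian correlation decay from
  farthest-point-placed texture sources through interior (geodesic)
  distances, plus a calibrated noise model;
* **rotation-invariant evaluation metrics**: per-order cross-spectrum
  S_ℓ, spherical mean, anisotropic power var(g), relative anisotropy
  σ(g)/ḡ, voxel-wise squared Pearson correlation R²(g, h) =
  cov²/(var·var), the principal ℓ = 2 orientation, and the ensemble
  anisotropic power quotient Q = var(mean g_i) / mean var(g_i) ∈ [0, 1]
  (Q = 1 iff all ensemble members share the same anisotropy);
* **ensemble reconstructions** from randomized initial conditions, and an
  exact expansion of *squared* band-limited functions into the plain
  coefficient representation via equiangular spherical quadrature;
* an RDS **dataset container** with a documented layout, flat-binary +
  JSON export for external visualization, and a command-line interface
  (`inst/scripts/saxstt-cli.R`) with `simulate`, `reconstruct`,
  `analyze` and `ensemble` subcommands.

## Worked example

Simulate a 16³ rank-2 textured sample, reconstruct it from 36 projections
(two tilt series), and compare with the ground truth:

```r
library(saxstt)

spec <- phantom_spec(volume_shape = c(16, 16, 16),
                     symmetry_class = "rank2", seed = 1)
ph  <- tt_phantom(spec)                      # noiseless measurements
fit <- tt_reconstruct(ph$measurement, ph$geometry,
                      ell_max = 2, lambda = 1e-3, max_iter = 400)
print(fit)
#> Tensor-tomography reconstruction (regularized least squares)
#>   mode: full  ell_max: 2  lambda: 0.001
#>   volume: 16 x 16 x 16 voxels x 6 coefficients
#>   final loss: 1.1967258 after 407 accepted iterations ( 416 objective evaluations )

r2 <- r_squared_map(coef(fit), ph$ground_truth)
median(r2[is.finite(r2)])
#> [1] 0.997956
```

The printed loss is the residual sum of squares plus the smoothness
penalty; the R² map is the voxel-wise squared Pearson correlation between
the reconstructed and true reciprocal-space maps (empty voxels, which have
no anisotropy, are excluded), and a median of 0.998 means the texture is
recovered essentially exactly from noiseless, band-limit-matched data.
Adding noise (`simulate_measurements(..., snr = 10)`), removing a tilt
series, or reconstructing a phantom whose band limit exceeds the binning
Nyquist limit all degrade this figure in the ways the evaluation metrics
quantify.

From the shell, the same pipeline:

```sh
Rscript inst/scripts/saxstt-cli.R simulate    --out data.rds --seed 1
Rscript inst/scripts/saxstt-cli.R reconstruct --in data.rds --out recon.rds
Rscript inst/scripts/saxstt-cli.R analyze     --in recon.rds --out report.csv
```

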