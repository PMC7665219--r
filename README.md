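# rmclass

Computational adaptive optics for coherent reflectance imaging through
strongly aberrating layers: a forward simulator of laser-scanning,
time-gated reflection-matrix acquisition, and the **CLASS** algorithm
(closed-loop accumulation of single scattering) that retrieves the input and
output pupil aberrations from the measured matrix and reconstructs an
aberration-corrected confocal image — including a locally varying variant
for media whose aberrations change across the field of view.

It is aimed at microscopists and algorithm developers who want to study or
extend matrix-based aberration correction without hardware: every quantity
the method relies on (object reflectance, pupil screens, noise level, patch
layout) is an explicit, seedable simulation input with stored ground truth.

## The model and the algorithm

Each focused illumination at $r_i$ yields a de-scanned complex field frame

$$E_{cam}(r_{cam}; r_i) = \int P_o(r_{cam}; r)\,O(r)\,P_i(r; r_i)\,d^2r + E_M,$$

and the frames assemble into the reflection matrix $R = P_o O P_i + M$. In
the spatial-frequency basis $\tilde R = F R F^{-1}$, shift-invariant PSFs
make the pupils diagonal:
$\tilde R(k_o;k_i) = e^{i\phi_o(k_o)}\tilde O(k_o-k_i)e^{i\phi_i(k_i)} + \tilde M$.
CLASS iterates

$$\phi_i^{(n)}(k_i) = \arg\sum_{\Delta k}
  \tilde R^{(n-1)}(\Delta k;k_i)^{*}\,\tilde R^{(n-1)}_{CLASS}(\Delta k),
  \qquad
  \tilde R^{(n)}_{CLASS}(\Delta k) = \sum_{k_i}\tilde R^{(n)}(\Delta k;k_i),$$

with the analogous row-wise step for $\phi_o^{(n)}$, applying both as pure
phase factors each sweep until the increments' RMS falls below a tolerance.
Single-scattered signal adds coherently in the $\Delta k$ sums, so the total
reconstructed confocal intensity grows monotonically while the accumulated
phases converge to the correction (conjugate) maps. For anisoplanatic media
the field is tiled; each tile keeps the full detection window as a
rectangular, zero-padded matrix (grid spacing
$2\pi/(\sqrt{FOD}+\sqrt{FOI})$), iterating the output map and its reciprocal
mirror $\phi_i(k)=\phi_o(-k)$, and the corrected tiles are stitched with
raised-cosine weights.

## Worked example

```r
library(rmclass)

## analytic acquisition planning (50 x 50 um field, camera rate 40000/sqrt(FOD))
plan_acquisition(optics_config(0.9, 1.0), foi_side = 50, fod_side = 50, r = 40000)
#> Acquisition plan (FOI 50 um, FOD 50 um):
#>   correction modes N_c = 9696
#>   scan positions  N_s = 12346
#>   camera rate f_cam = 800 Hz; total time T = 15.43 s

## simulate a scan through a speckle-like aberrating layer and correct it
opt   <- optics_config(wavelength = 0.9, na = 1.0, grid_size = 32)
obj   <- make_siemens_star(8, 32)
phi_i <- make_pupil_phase(opt, "speckle", list(n_modes = 40, rms = 1.2), seed = 1)
phi_o <- make_pupil_phase(opt, "speckle", list(n_modes = 40, rms = 1.2), seed = 2,
                          side = "output")
stack <- simulate_scan(obj, phi_i, phi_o, opt)
fit   <- run_class(stack, max_iter = 80)
summary(fit)
#> CLASS aberration retrieval
#>   iterations:        62 (converged)
#>   NA-disk modes:     193
#>   retrieved RMS phase (rad): input 1.18, output 1.12
#>   confocal intensity gain over OCM: 14.95

## compare the retrieved input map with the injected truth
truth <- sample_pupil(phi_i, fit$spectral$ky, fit$spectral$kx)
phase_agreement(fit$phi_i$phase, truth, fit$spectral$mask)$pearson
#> [1] 0.9864381
```

The correction raised the total confocal intensity ~15x (the inverse
round-trip Strehl of the injected screens) and the retrieved pupil map
matches the injected one with correlation 0.99, piston and tilt removed.
`plot(fit)` shows the uncorrected/corrected images, the retrieved pupil
phase and the convergence curve; `coef`, `fitted` and `residuals` expose
the maps, the corrected image and the non-confocal residual energy. For
spatially varying media see `tile_foi()`, `run_local_class()` and
`estimate_isoplanatic_size()`; `make_fixture()` regenerates the benchmark
data sets used throughout the tests.

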