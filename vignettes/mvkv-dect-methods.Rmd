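---
title: "Dual-energy MV-kV CT: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-energy MV-kV CT: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dexct)
```

## The problem

Radiotherapy treatment machines carry two X-ray sources: a megavoltage (MV)
treatment beam and a kilovoltage (kV) imaging source. Used together they form
a dual-energy (DE) CT system at no extra hardware cost. Whether MV-kV DE-CT
can beat a dose-matched single-energy kV scan — and under which conditions —
is a quantitative question about spectra, detector efficiency, object
composition, and how a fixed dose budget is split between the two beams.

`dexct` answers it with two linked models:

1. **A single-line estimation-theory model.** One polychromatic ray crosses a
   two-material object (soft tissue plus bone). The detected signal per
   spectrum is compound Poisson: each energy bin contributes an independent
   Poisson photon count weighted by the energy-integrating detector response
   D(E) = E and the detective efficiency eta(E). Approximating that
   distribution by a Gaussian matched to its first two moments gives a Fisher
   information matrix for the two basis mass thicknesses A_t, A_b (g/cm^2),

   F_jk = sum_i sigma_i^-2 (dlambda_i/dA_j)(dlambda_i/dA_k)
        + 1/2 sum_i sigma_i^-4 (dsigma_i^2/dA_j)(dsigma_i^2/dA_k),

   with lambda_i = sum_E D I_i T eta and sigma_i^2 = sum_E D^2 I_i T eta.
   The Cramer-Rao lower bound is the diagonal of F^-1 and
   SNR_j = A_j / sqrt(CRLB_j). Splitting a fixed dose budget (1 uGy at the
   centre of a 40 cm water cylinder) between the two spectra with fraction
   `r` to the high-energy beam and sweeping r over 1%...99% maps out the
   optimal allocation.

2. **A fan-beam CT simulator.** The same signal model drives a polychromatic
   equiangular fan-beam projector (exact Siddon path lengths through a
   material-label raster, per-energy-bin Poisson noise), sinogram-domain
   Gauss-Newton decomposition into tissue/bone mass thicknesses, filtered
   backprojection into basis density images, virtual monoenergetic images
   (VMIs) mu(E0) = rho_t (mu/rho)_t(E0) + rho_b (mu/rho)_b(E0), and CNR /
   RMSE evaluation against the monoenergetic ground truth. Single-energy
   comparison scans receive a two-stage beam-hardening correction (BHC).

## Synthetic study conditions

The packaged generators define the study conditions; none of their
parameters are tuned against outcomes.

* **kV spectra** (80, 120, 140 kV): Kramers bremsstrahlung, fluence
  proportional to (kVp - E)/E on 1 keV bins, filtered through 2.5 mm Al
  (a typical diagnostic inherent-plus-added filtration). Characteristic
  lines are omitted; they carry little weight after 40 cm of water.
* **MV spectra**: thin-target form (1 - E/E_max)/E on 10 keV bins. The
  treatment beam uses E_max = 6 MeV with 15 cm water-equivalent flattening;
  the detuned imaging beam uses E_max = 2.5 MeV with 5 cm. The resulting
  mean energies (about 1.4 MeV and 0.46 MeV) give the expected softening of
  the detuned beam. Real measured spectra can replace the generators through
  `read_spectrum()`.
* **Detector**: energy-integrating with a thick-absorber efficiency
  eta(E) = 1 - exp(-(mu/rho)_Xe m_eff), calibrated so eta(1 MeV) = 0.20,
  emulating the high-DQE pressurised-xenon detectors of fan-beam MV CT.
  Below 150 keV eta is essentially 1; at 6 MeV it is about 0.13. The xenon
  curve is a synthetic Klein-Nishina-plus-photoelectric model (see
  `inst/extdata/xenon_synthetic.txt`), with the MeV tail kept monotone as an
  effective-efficiency choice.
* **Attenuation tables**: transcribed NIST-compilation values for water,
  ICRU soft tissue (1.00 g/cm^3), cortical bone (1.85 g/cm^3), PMMA, Al, Ti
  and iron-based surgical steel, on the standard grid from 1 keV to 10 MeV,
  interpolated log-log. Held-out grid values (150, 600, 1250 keV) serve as
  an independent interpolation check at the 2% level.
* **Phantom**: the anatomical phantom used in the original imaging studies
  is licensed, so the package ships a parametric pelvis: elliptical body
  (34 x 22 cm), cortical-bone pelvic ring, two femoral heads, and a
  bladder-like soft-tissue inset (tissue curve at 1.06 g/cm^3) that provides
  the CNR signal ROI against a plain-tissue background ROI. Implant variants
  replace one femoral head with a titanium or steel head and hemispherical
  shell plus a PMMA lining. All variants share anatomy outside the implant.
  Geometry is fixed in code, so phantoms are bit-reproducible.

## Dose model and units

Energies are keV throughout; fluence is photons per bin (per cm^2,
implicitly); dose is uGy. `dose_at_depth()` evaluates
sum_E I(E) exp(-mu_w d) (mu_en/rho)_w E, converted once from keV to joules.
Every acquisition first normalises its spectrum to the prescribed dose at
20 cm depth in water; a CT scan divides that dose uniformly over views. The
DE-CT budget is 10 mGy, split 9:1 (MV:kV) for the MV-kV pair and 5:5 for the
kV-kV pair — the allocations indicated by the single-line optima.

## Numerical choices

* **Quadrature** is a plain bin sum on each spectrum's own grid; attenuation
  curves are interpolated onto it log-log. Deterministic and adequate for
  smooth integrands.
* **Fisher matrices** are inverted with the closed-form 2x2 inverse. A
  condition number above 1e12 flags the ray as singular: CRLB = Inf, SNR = 0,
  and sweeps continue instead of aborting.
* **Peak finding** for allocation curves is grid argmax on the 1% grid with
  ties broken toward smaller r; no sub-grid refinement, matching the survey
  resolution. (For exactly identical spectra the curve is constant in r and
  the reported argmax is simply the first grid point.)
* **Gauss-Newton decomposition** minimises the moment-matched Gaussian
  misfit with variance weights recomputed each iteration (iteratively
  reweighted), an analytic Jacobian, backtracking step halving, and
  convergence at relative step norm < 1e-8 or 50 iterations. Rays warm-start
  from their converged neighbour; failures fall back to a water-equivalent
  initialisation (tissue thickness from the low-energy log signal, zero
  bone). Raw signals below 0.1 (energy-weighted counts) are floored and
  flagged as photon-starved; basis thicknesses are not clipped at zero, so
  downstream VMIs stay unbiased.
* **Reconstruction** is equiangular fan-beam FBP: cosine pre-weighting, ramp
  filtering in the channel angle built from the discrete band-unlimited
  kernel (avoiding the DC bias of a naive |f| filter) with the
  (gamma/sin gamma)^2 equiangular modification, a sinc^k apodisation window
  cut at 80% of Nyquist (k = 1 by default), and 1/L^2-weighted
  backprojection over the full 360 degree arc. On a noiseless monoenergetic
  water disk the central region reconstructs within 0.01% of the true mu.
* **Geometry**: 1200 views x 800 equiangular channels over a 47 degree fan.
  The source-to-isocentre distance defaults to fov / (2 sin(fan/2)) =
  62.7 cm so the fan exactly subtends the 50 cm field of view; it is
  configurable.
* **Beam-hardening correction**: the water stage fits a degree-4 polynomial
  from the model's polychromatic log-signal versus water-thickness curve
  (0-50 cm) to the monoenergetic line integral at the spectrum's
  detected-fluence-weighted mean energy, and remaps every ray. The bone
  stage segments bone above +300 HU, forward-projects the segmented bone and
  water-equivalent remainder, reconstructs the modelled residual-hardening
  sinogram into an artifact-only image, and subtracts the multiple of it
  (21-point grid over 0...2) that minimises soft-tissue-band variance. Both
  thresholds are exposed as arguments since no canonical values exist.

## Problem sizes

The full study geometry (1200 x 800, 512 grid) is available through
`experiment_config("full")`. The test suite and the acceptance script use
the half-scale configuration (600 views x 400 channels, 256 grid, 2 mm
pixels) and a 192-grid noiseless fixture, sizes at which every qualitative
ordering of the full study is preserved while a complete run takes minutes.
The VMI metric grid is 40-350 keV.

## What the synthetic data do and do not show

The generators reproduce the physics that drives the study's conclusions —
dose-matched spectra, energy-integrating detection with realistic MV
efficiency, beam hardening, photon starvation behind metal — so trend-level
results transfer: the MV-heavy allocation optimum (r about 0.9 against
r about 0.5 for kV-kV), the decline of the optimum with bone thickness, the
kV-kV-to-MV-kV SNR crossover near 7-8 cm of bone, and the CNR/RMSE
orderings with and without a steel implant. Absolute Table-style numbers
depend on the exact spectral shapes, the full eta(E) curve and the licensed
anatomical phantom, none of which are published as data; with the authors'
spectrum files supplied via `read_spectrum()` the exact single-line peak
coordinates become checkable (see `tests/testthat/test-acceptance.R`).
Scatter, electronic noise, motion, bowtie filtration, tube-current
modulation, cone-beam geometry and iterative or learned reconstruction are
out of scope.

## A worked single-line example

```{r model1, eval = FALSE}
det <- detector()
sp <- study_spectra()
curve <- sweep_allocation(sp$kV80, sp$detunedMV, line_object(40, 1), det)
allocation_peaks(curve)
autoplot(curve)
```

With one centimetre of bone the tissue-SNR peak sits at r = 0.89 (SNR 82.5)
for the detuned-MV/80 kV pair and at r = 0.51 (SNR 169.5) for the
140/80 kV pair, the characteristic asymmetry of MV-kV imaging.
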