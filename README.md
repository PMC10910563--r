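# dexct

Dual-energy CT with megavoltage and kilovoltage X-ray spectra: an
estimation-theory engine for basis-material SNR along a single polychromatic
line integral, and a fan-beam polychromatic CT simulator with two-material
decomposition, virtual monoenergetic imaging (VMI), beam-hardening
correction, and CNR / RMSE evaluation.

## Who this is for

Medical-physics researchers studying whether the MV treatment beam and kV
imaging source already mounted on radiotherapy machines can be combined into
a dual-energy CT system that beats a dose-matched single-energy kV scan —
and under which object compositions and dose splits.

## The models

**Single-line model.** A ray crosses tissue and bone with mass thicknesses
`A = (A_t, A_b)` (g/cm²). Each of two spectra *i* produces a compound-Poisson
signal with moments

    λ_i  = Σ_E D(E) I_i(E) T(E) η(E),      σ²_i = Σ_E D²(E) I_i(E) T(E) η(E),

with `T(E) = exp(−(μ/ρ)_t A_t − (μ/ρ)_b A_b)`, energy-integrating response
`D(E) = E`, and detective efficiency `η(E)` (≈1 at kV, 0.20 at 1 MeV).
The Gaussian moment-matched Fisher matrix

    F_jk = Σ_i σ_i⁻² ∂λ_i/∂A_j ∂λ_i/∂A_k + ½ Σ_i σ_i⁻⁴ ∂σ²_i/∂A_j ∂σ²_i/∂A_k

gives the Cramér–Rao bound and `SNR_j = A_j / √(F⁻¹)_jj`. A fixed 1 µGy dose
(at the centre of a 40 cm water cylinder) is split between the spectra with
fraction `r` to the high-energy beam; sweeping `r` locates the optimum.

**CT model.** The same signal model drives an equiangular fan-beam projector
(exact Siddon paths, per-energy-bin Poisson noise), sinogram-domain
Gauss–Newton decomposition into tissue/bone mass thicknesses, fan-beam FBP
with a sinc window cut at 80% Nyquist, VMI synthesis
`μ(E₀) = ρ_t (μ/ρ)_t(E₀) + ρ_b (μ/ρ)_b(E₀)`, and CNR / RMSE metrics on a
parametric pelvis phantom with an optional titanium or steel hip prosthesis.
Single-energy comparison scans get a water-polynomial plus bone
artifact-image beam-hardening correction.

## Worked example

```r
library(dexct)

det <- detector()                       # EID, eta(1 MeV) = 0.20
sp  <- study_spectra()                  # 80/120/140 kV, 6 MV, detuned MV

# optimal dose allocation, 40 cm tissue + 1 cm bone, 1 uGy total
allocation_peaks(sweep_allocation(sp$kV80, sp$detunedMV,
                                  line_object(40, 1), det))
#> # A tibble: 2 x 3
#>   material r_max snr_max
#> 1 tissue    0.89   82.5
#> 2 bone      0.83    5.56

allocation_peaks(sweep_allocation(sp$kV80, sp$kV140,
                                  line_object(40, 1), det))
#> 1 tissue    0.51  169.
#> 2 bone      0.45   10.7
```

The MV–kV pair is optimised by giving ~90% of the dose to the MV beam
(its photons deposit far more dose each, so they are scarce at fixed dose),
whereas the diagnostic kV–kV pair prefers a near-equal split. Tissue SNR at
equal dose favours kV–kV for thin bone, but the ordering reverses once the
ray crosses ~7–8 cm of bone and the kV beam starves.

A scaled-down CT study (600 views × 400 channels, 256² grid, 10 mGy per
acquisition):

```r
cfg <- experiment_config("test", seed = 1,
                         vmi_energies = seq(40, 350, by = 4),
                         implants = c("none", "steel"))
run_model2(cfg, det, with_se = FALSE)$metrics
#>   phantom acquisition type   cnr cnr_energy rmse_min
#> 1 none    MVKV        DE    6.36        350     145.
#> 2 none    KVKV        DE    7.23        190     145.
#> 3 steel   MVKV        DE    2.30        350     555.
#> 4 steel   KVKV        DE    1.15        134     684.
```

Without metal the kV–kV VMIs win on CNR; with a steel prosthesis the MV–kV
pair gives both the higher peak CNR and the lower minimum RMSE — the
metal-artifact use case for MV information.

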