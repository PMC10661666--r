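---
title: "hpMRSI: models and methods"
author: "hpMRSI authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hpMRSI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpMRSI)
```

# Overview

`hpMRSI` models and analyses a parallel dissolution-DNP experiment: one
hyperpolarized [1-¹³C]pyruvate dissolution is distributed across the eight
6 mm wells of a microfluidic plate and the whole plate is imaged with a
chemical-shift-imaging (CSI) sequence — an 8×8 grid of 5×5×12 mm voxels
over a 40 mm field of view, one full spectroscopic frame every 4 s. Three
wells contain H₂O₂ (the decarboxylation reaction runs), three contain only
base (controls), and two corner wells hold ¹³C-urea for geometry
verification.

The package has two halves that meet in the middle: a **forward model**
(kinetics → spin physics → spectra) that generates realistic synthetic
datasets under known ground truth, and an **analysis pipeline**
(reconstruction → peak quantification → decay fitting → concentration
recovery) whose correctness is established by round-tripping the forward
model.

# The device model

## Volume distribution

The plate splits an injected volume $V_t$ eight ways after a dead volume
$V_d$ is retained in tubing and channels:

$$V_w = \frac{V_t - V_d}{8}.$$

With the slope pinned to $1/8$, least squares gives the closed form
$\hat V_d = \mathrm{mean}(V_t - 8 V_w)$, which `fitDeadVolume()` returns;
an unconstrained regression of $V_w$ on $V_t$ is reported alongside purely
as a diagnostic (its slope should be near 1/8 if the split is even). The
constrained fit defines $V_d$ because the 8-way split is a property of the
device, not a free parameter. Fits with fewer than two pairs are refused;
a negative fitted dead volume is allowed but flagged, since it indicates
inconsistent measurements rather than physics.

## Geometry and the voxel map

`ChamberLayout` places the 4×2 chamber array in the imaging frame (mm,
origin at the centre of the field of view). The default layout puts the
chamber centres on a 10 mm pitch, x ∈ {−15, −5, 5, 15}, y ∈ {−5, 5}. Two
constraints drove this choice: every 6 mm chamber must lie fully inside the
40 mm field of view, and each chamber should be quantified by summing 4
voxels, as in the physical experiment. A 15 mm pitch (the physical device)
spans 51 mm including the chamber diameter and cannot satisfy the first
constraint at this field of view, so the synthetic layout compresses the
pitch; the chosen centres additionally fall exactly on corners shared by
four voxels, which makes the 4-voxel-per-chamber aggregation exact rather
than approximate.

`voxelChamberMap()` assigns to each chamber the $k = 4$ voxels with the
largest circle–square overlap area, ties broken by ascending row-major
voxel index, never assigning a voxel twice. Overlap areas are computed by
adaptive 1-D quadrature of the clipped chord length (accurate to ~10
significant digits; the test suite checks them against a brute-force 2-D
sub-grid oracle). Voxel indices in the R API are 1-based linear row-major
(rows by ascending y), stated once here as the package convention.

# The forward model

## Reaction kinetics

The decarboxylation cascade is modelled as a first-order network over the
five observable ¹³C-labelled pools:

* pyruvate → 2-hydroperoxy-2-hydroxypropanoate (pseudo-first-order; H₂O₂
  at ~8 M is in vast excess, so its concentration is absorbed into the
  rate),
* intermediate → CO₂ (the decarboxylation; the C1 label leaves as CO₂),
* CO₂ → peroxymonocarbonate (pseudo-first-order in H₂O₂),
* pyruvate ⇌ pyruvate hydrate (hydration exchange),
* optionally CO₂ → ∅ (outgassing; off by default — bubbles are visible in
  the real experiment but their rate is unknown).

Each edge moves the label from exactly one species to exactly one other
(or to a sink), so with escape off the per-chamber label sum is conserved;
this is a tested invariant (relative drift < 10⁻⁸). The linear system
$\dot c = K c$ is integrated with `deSolve::ode` (lsoda, rtol 10⁻¹⁰,
atol 10⁻¹²). Edges flagged oxidant-dependent are silenced in control
chambers.

**Default rates.** No rate law is available for these exact conditions, so
the defaults were fixed once to reproduce the qualitative behaviour of the
experiment and not revisited: k₁ = 0.30 s⁻¹ (pyruvate is >99.9% consumed
during the 25 s between dissolution and the first frame, so its
concentration plateaus near zero), k₂ = 0.04 s⁻¹ (the intermediate is the
reservoir that keeps draining throughout acquisition), k₃ = 0.015 s⁻¹
(both end products still accumulate over the first ~15 s of acquisition),
hydration 0.01/0.15 s⁻¹ (≈6% hydrate at equilibrium). A caveat worth
stating plainly: the *apparent signal decay rates* of the products depend
on the ratio of production flux to pool size and change over the
acquisition window, so no time-invariant first-order rate set can
simultaneously reproduce every reported per-species decay number; analyses
that need a specific apparent decay constant should set it directly via
the effective flip angle (below), which is also how the acceptance script
constructs its generator truths.

## Hyperpolarized spin physics

The state variable is the polarization-weighted concentration $m_s$ of
each species — hyperpolarized label density in concentration units. Three
processes act on it:

1. **T₁ relaxation** toward zero. The thermal-equilibrium floor is
   neglected (hyperpolarized ≫ thermal). Uniform T₁ = 60 s across species
   is the default — the same simplification the quantification step relies
   on — with per-species T₁ supported.
2. **RF sampling.** Each excitation converts $\sin\theta$ of the
   longitudinal magnetization into signal and leaves $\cos\theta$; a frame
   of $n = 64$ phase-encoding pulses therefore costs a factor
   $\cos^{64}\theta$ (≈ 0.109 at 15°) — the dominant loss, an order of
   magnitude faster than T₁. All pulses excite every chamber (volume coil,
   single slice, no slice-profile modelling).
3. **Chemical exchange.** The label carries its polarization through
   reactions with no loss on conversion — the standard dDNP assumption,
   without which product signals could not exist.

Between RF events the system is linear and time-invariant
($\dot m = (K - \mathrm{diag}(1/T_1))\,m$), so propagation uses exact
matrix exponentials (`Matrix::expm`), precomputed once per step size —
there is no step-size error to tune. Two integration modes exist:
`"frame-lumped"` applies $\cos^n\theta$ once per frame and evolves over
the nominal 4 s interval; `"per-pulse"` interleaves each pulse with
evolution over one repetition time (66.907 ms). The printed protocol is
internally inconsistent by ~0.3 s (64 × 66.907 ms = 4.282 s > 4 s), so the
acquisition validity check carries a 0.5 s timing tolerance and per-pulse
mode spaces frames by the pulse-train duration. The two modes agree within
a few percent when kinetic rates are slow against 1/RT (tested); the
residual difference is exactly the 0.282 s timing discrepancy acting
through T₁ and kinetics.

**Effective flip angle.** The nominal depletion at 15° predicts an
apparent decay rate of ≈0.57 s⁻¹ (τ ≈ 1.75 s), faster than apparent
constants measured in practice (τ ≈ 3 s); transmit calibration is not part
of the model. `flipAngleForApparentRate()` inverts
$r = n(-\ln\cos\theta)/\Delta t + 1/T_1$ so a generator can be configured
to any target apparent constant without guessing the real B₁.

The 25 s between dissolution and the first frame (transfer + injection) is
modelled as kinetics + T₁ evolution with no RF. Frame times are reported
with $t = 0$ at the first frame, matching how decay constants are fitted.

## Spectral synthesis

Each voxel's FID is the overlap-weighted sum of its chambers' signals;
each species contributes
$\exp(i 2\pi \Delta f_s t - t/T_2^*)$ with $\Delta f_s$ from its shift
relative to the 170 ppm carrier (32.13 MHz; all five resonances, 125–184
ppm, sit well inside the 20 kHz width) and $T_2^* = 1/(\pi \cdot
\mathrm{FWHM})$. The default linewidth is 53 Hz; the printed "1.8 ppm
(53 Hz)" pair is internally inconsistent at this field (1.8 ppm ≈ 58 Hz)
and the package standardizes on the Hz figure. Chamber weights are overlap
area divided by chamber area, so a chamber's voxel-summed signal recovers
its full amplitude. Noise is i.i.d. complex Gaussian per point with a
mandatory seed; identical configuration + seed is bit-reproducible
(tested). Data are synthesized voxel-wise — at the post-reconstruction
level at which such experiments are analysed. The generator therefore does
**not** emulate: k-space encoding artifacts, B₀/B₁ inhomogeneity,
off-resonance excitation profiles, structured or correlated noise,
frequency drift, or imperfect phasing. Passing round-trip tests shows the
analysis is correct *given* those idealizations, not that it is robust to
their violation.

# The analysis pipeline

## Reconstruction

Chamber spectra are formed by summing the mapped voxels' **complex** FIDs,
then transforming and taking the lineshape — complex summation first,
because the synthetic phases are coherent, and coherent summation is what
yields the expected ~2× SNR gain of a 4-voxel sum (signal ×4, noise ×2;
tested). Optional exponential apodization adds its bandwidth to the
linewidth; a single zero-filling factor is supported; defaults are 0 Hz
and 1.

Both the magnitude spectrum and the phased real (absorption) spectrum are
retained. The distinction matters: the magnitude lineshape has $1/\Delta$
tails, so at the 3 ppm (96 Hz) spacing of the crowded 181/184 ppm pair a
peak's magnitude tail is still 27% of its height, and the ~300×-larger
intermediate swamps the tiny hydrate; the absorption lineshape's
$1/\Delta^2$ tails (7% at 96 Hz) keep neighbours apart. Since the
synthetic data are zero-phase by construction, the real part *is* the
absorption spectrum exactly.

## Peak measurement

For each frame × chamber × species, `measurePeaks()` reports:

* **height** — maximum magnitude in the species window (default ±1.5 ppm;
  the 181/184 pair splits at the 182.5 ppm midpoint; windows whose
  interiors overlap are refused),
* **amplitude** — cubic-spline-interpolated absorption value at the
  assigned shift. Two systematic errors motivated this statistic: a 53 Hz
  line sampled on the 19.5 Hz grid loses up to ~6% of its windowed-max
  height depending on where it falls between grid points (differently per
  species), and the windowed max of a small species is captured by a large
  neighbour's shoulder. Interpolating at the assigned shift on the
  absorption spectrum removes both.
* **integral** — window sum × ppm step,
* **SNR** — height / sd of the magnitude in a signal-free noise region
  (default 135–150 ppm, per frame and chamber), and a detectability flag
  (SNR > 5 by default).

SNR and detectability deliberately stay on the magnitude surface (its
noise is Rayleigh, and the detection behaviour is tested against a
Rayleigh-quantile oracle); concentration work uses the amplitude.

## Decay fitting

`fitMonoexponential()` fits $A e^{-rt}$ by Levenberg–Marquardt
(`minpack.lm::nlsLM`, ftol/ptol 10⁻¹⁵) started from the log-linear
regression. Noiseless exponentials are recovered to solver precision
(residual norm < 10⁻¹⁰, tested). Degenerate inputs are handled explicitly:
constant series return rate 0 with a warning; non-positive values are
excluded from the log-linear start and flagged; if the nonlinear
refinement fails the log-linear estimate is returned, flagged.

## Concentration recovery

Under uniform T₁ and a shared flip angle, every species' polarization
decays by the same factor $D(t)$, measured directly as the normalized
pyruvate signal of a control chamber (no oxidant, so no kinetics).
`correctConcentration()` divides every series by $D(t)$ framewise and
scales so the species-summed corrected signal at the first frame equals
the supplied initial substrate concentration — valid because the label sum
is conserved. Frames where the reference drops below its SNR threshold
terminate the series (masked, never extrapolated or interpolated). On
noiseless fixtures the round trip recovers the generator's concentration
trajectories within a few percent of the initial pyruvate concentration
(tested at 5%); the residual error is the remaining lineshape overlap of
the downfield triplet, which the package deliberately does not deconvolve.

# Reproducibility and problem sizes

`runPipeline()` writes tidy CSVs plus a JSON manifest embedding the full
configuration, its FNV-1a hash, the seed and package/R versions; the
manifest alone suffices to regenerate every output byte-exactly. The
CSI container is a plain-text pair (JSON metadata + CSV with 17
significant digits) that round-trips doubles bit-exactly. Configurations
round-trip through YAML losslessly.

Simulations throughout the package and its tests use the experiment's own
acquisition geometry (8×8 voxels, 1024 spectral points) with 5–10 frames
and a 0.5 s kinetics grid — sizes chosen because they resolve everything
the models contain; a full pipeline run takes a few seconds.

# Known limitations

* Pseudo-first-order kinetics with constant rates; no mixing/transport
  delay within wells, no temperature or pH dependence.
* Uniform-T₁ concentration correction is approximate when product T₁s
  differ — the same approximation the experimental analysis makes.
* No lineshape deconvolution of the 176/181/184 ppm triplet; absolute
  (external-standard) quantification is out of scope.
* The urea reference wells are geometry QC only and are not given a
  hyperpolarized signal model.
* Hardware-dependent quantities (absolute SNR, thermal-equilibrium
  comparisons) are not modelled; mass sensitivity is computed from
  supplied SNR, amount and time, not predicted. The amount of substance
  per chamber is nominally 10 µmol (125 µL × 80 mM); note that a reported
  sensitivity of 352 µmol⁻¹ s⁻¹ᐟ² at SNR 4229 and t = 4 s implies ~6 µmol,
  a discrepancy the package documents but cannot resolve.
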