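# hpMRSI

Simulation and quantification of **parallel hyperpolarized ¹³C
chemical-shift-imaging (CSI) experiments in microfluidic multiwell
devices**.

Dissolution dynamic nuclear polarization (dDNP) boosts ¹³C NMR sensitivity
by >10⁴, but each dissolution yields one short-lived (~tens of seconds)
sample, so throughput is the bottleneck. A microfluidic plate that splits a
single hyperpolarized [1-¹³C]pyruvate dissolution across eight 6 mm wells,
imaged together on an 8×8 CSI grid, turns one dissolution into eight
parallel experiments — here, three replicates of the pyruvate + H₂O₂
decarboxylation cascade (pyruvate → 2-hydroperoxy-2-hydroxypropanoate →
CO₂ ⇌ peroxymonocarbonate), three controls and two urea geometry
references.

`hpMRSI` is aimed at researchers designing or analysing such experiments.
It implements, as tested S4 building blocks:

* **Device model** — the fluidic volume-distribution law
  *V*<sub>w</sub> = (*V*<sub>t</sub> − *V*<sub>d</sub>)/8 with closed-form
  dead-volume calibration (`fitDeadVolume`, `predictChamberVolume`), and the
  voxel-to-chamber mapping by circle–square overlap area
  (`voxelChamberMap`).
* **Forward model (synthetic-data generator)** — first-order reaction
  kinetics (`simulateKinetics`), hyperpolarized longitudinal magnetization
  under T₁ relaxation and repeated RF sampling, where each of the 64 pulses
  per frame leaves cos θ of the polarization
  (`simulateHpSignal`, `rfDepletionFactor`: cos⁶⁴15° ≈ 0.1087 per 4 s
  frame), and voxel-wise spectral synthesis with Lorentzian lineshapes and
  seeded complex noise (`synthesizeCSI`).
* **Reconstruction** — FID apodization/FFT (`fidToSpectrum`) and coherent
  per-chamber voxel summation (`aggregateChamber`).
* **Quantification** — peak height/amplitude/integral + SNR
  (`measurePeaks`), apparent decay constants (`fitMonoexponential`),
  polarization-corrected concentration recovery using the control-well
  pyruvate decay as the uniform reference (`correctConcentration`),
  time-normalized mass sensitivity S<sub>m</sub> = SNR/(m·√t)
  (`massSensitivity`) and replicate dispersion (`replicateDispersion`).
* **Orchestration** — `runPipeline()` (simulate → reconstruct → quantify,
  with CSV/JSON/YAML round-tripping and a reproducibility manifest) and the
  `makeFixture()` registry.

## Worked example

```r
library(hpMRSI)

## dead-volume calibration from measured (injected, delivered) volumes
cal <- fitDeadVolume(cbind(c(1000, 1400, 1800, 2200),
                           c(59, 108, 154, 191)))
cal
#> VolumeCalibration: Vd = 576.0 uL (slope fixed 1/8)
#>   diagnostic free fit: slope 0.1105, intercept -48.8 uL, R2 0.9961
predictChamberVolume(1600, cal)
#> [1] 128     # uL delivered per chamber for a 1.6 mL injection

## full synthetic experiment: 8 chambers, 10 frames every 4 s
res <- runPipeline(defaultRunConfig(seed = 1L, noiseSd = 2e-4, nFrames = 10L))
res$fits[, c("chamber", "role", "rate", "tau")]
#>   chamber     role   rate   tau
#> 1       2 reaction 0.6217 1.609
#> 2       3 reaction 0.6216 1.609
#> 3       4 reaction 0.6221 1.607
#> 4       5  control 0.5715 1.750
#> 5       6  control 0.5715 1.750
#> 6       7  control 0.5715 1.750
```

The control-chamber pyruvate decay (rate 0.5715 s⁻¹) is exactly the
RF + T₁ prediction `apparentDecayRate(15, T1 = 60)` for a 15° flip angle:
RF pulsing, not T₁, dominates the signal lifetime. Reaction chambers decay
faster because the oxidation consumes pyruvate. The polarization-corrected
concentrations (`res$concentration`) reproduce the generator kinetics: a
near-zero pyruvate plateau, a decreasing intermediate and rising CO₂ /
peroxymonocarbonate:

```r
head(concentrationTable(res$concentration))   # mM vs initial 80 mM pyruvate
#> frame 1..4, chamber 2: intermediate 32.3 -> 20.6, CO2 36.1 -> 42.7,
#> peroxymonocarbonate 7.5 -> 14.8, pyruvate ~1-2 (plateau)
```

Other one-liners: `dissolutionConcentration(15, 24, 4.5)` gives the 0.080 mM
(80 µM) trityl concentration after dissolving 24 µL of 15 mM stock into
4.5 mL buffer; `massSensitivity(4229, 6e-6, 4)` gives 352 µmol⁻¹ s⁻¹ᐟ² for a
single 4 s scan at SNR 4229.

## Documentation

The methods vignette (`vignettes/hpMRSI-methods.Rmd`) describes the forward
model and its assumptions, the default parameter choices, the numerical
design decisions (absorption-mode amplitudes, interpolated peak readout,
timing conventions) and what the synthetic generator does and does not
emulate about real data.
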