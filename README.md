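# lipidquant

Label-free quantification of liver lipid from multispectral optoacoustic
tomography (MSOT) images, for imaging scientists and biostatisticians
working on non-invasive assessment of hepatic steatosis.

MSOT records one image per illumination wavelength across the near
infrared; lipids absorb strongly near 930 nm, so lipid-rich tissue —
subcutaneous adipose tissue (SAT), or a steatotic liver — stands out at
that wavelength. The package implements the full analysis chain around
this effect:

* **Normalized ROI/BGR ratio spectra** — for each wavelength λ, the mean
  intensity in an ROI (liver or SAT) over the mean intensity in the
  background region (BGR, the entire imaged tissue), normalized by the
  curve's maximum across wavelengths:

  `r̃(λ) = [ Ī_ROI(λ) / Ī_BGR(λ) ] / max_μ [ Ī_ROI(μ) / Ī_BGR(μ) ]`

  Pulse-energy fluctuations cancel exactly in the ratio; `r̃(930 nm)` is
  the per-subject lipid score.
* **Group inference at 930 nm** — Shapiro–Wilk normality gate, pooled
  (Student) unpaired t-test with `df = n1 + n2 − 2`, and Cohen's
  `d = (m1 − m2)/s_p`, computable either from raw per-subject values or
  from published `(mean, SEM, n)` summaries (both routes are exactly
  equivalent).
* **SNR-versus-depth profiling** — the liver mask tiled into 5 mm depth
  slabs; per-slab SNR = mean signal / noise SD, with noise estimated from
  the coupling-medium region above the skin line; linear and dB (20·log10)
  reported, plus per-step and per-centimeter percent decreases.
* **Pooled pixel classification** — pooled liver-pixel density curves per
  group (Gaussian KDE, Silverman bandwidth), a classification threshold at
  the curves' intersection between their modes, per-subject proportions of
  pixels above the threshold, and a two-proportion z-test (with a
  cluster-aware subject-level alternative).
* **A synthetic phantom generator** — layered skin/SAT/liver stacks with
  tabulated chromophore spectra, exponential depth attenuation, pulse
  jitter, a coupling-medium noise floor, and matched healthy/steatosis
  cohorts for the clinical (28-wavelength) and small-animal
  (29-wavelength) presets, so the entire pipeline is testable without any
  acquired data.

## Worked example

```r
library(lipidquant)
bundle <- simulate_study(n_per_group = 5, seed = 1, species = "human",
                         pixel_pitch_cm = 0.02, image_width_px = 32L)
bundle
#> <analysis_bundle>
#>   SAT @ 930 nm: steatosis 1.000 +/- 0.000 vs healthy 1.000 +/- 0.000, p=1, d=0.00
#>   liver @ 930 nm: steatosis 0.740 +/- 0.019 vs healthy 0.256 +/- 0.001, p=5.539e-09, d=16.29
#>   pixel threshold 0.001857: p=0 (pooled)
```

The simulated study reproduces the designed pattern: the liver lipid score
separates the cohorts decisively while the SAT score (a within-subject
positive control — fat is fat in both groups) does not. Per-subject SNR
profiles show the exponential falloff with depth:

```r
as.data.frame(bundle$snr[["human_healthy_01"]])
#>    segment centroid_depth_cm snr_linear snr_db n_pixels
#> 1      SAT              0.54     751.52  57.52     1440
#> 2 liver_01              2.60      17.73  24.98      800
#> 3 liver_02              3.10       9.31  19.38      800
#> 4 liver_03              3.60       4.87  13.75      800
#> 5 liver_04              4.10       2.42   7.68      800
#> 6 liver_05              4.42       1.85   5.32      224
```

The built-in reference summary table recomputes the 930 nm group
statistics from published `(mean ± SEM, n = 5)` pairs:

```r
recompute_reference_stats()
#>    comparison p_reported p_recomputed d_reported d_recomputed ... reproducible
#> 1 human_liver      0.011      0.01166       2.07       2.0569          TRUE
#> 2   human_SAT      0.675      0.71577       0.27       0.2386          FALSE
#> 3 mouse_liver      0.005      0.00543       2.39       2.3870          TRUE
#> 4   mouse_SAT      0.923      0.92290       0.06       0.0632          TRUE
```

Three of the four comparisons reproduce to printed rounding; the human SAT
row cannot be recovered from its rounded means and is flagged rather than
fudged.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "lipidquant.R", package = "lipidquant"))') \
    simulate --preset human --n 5 --seed 7 --out phantoms/
```

with `analyze` and `reproduce-stats` subcommands over the same functions.

## Documentation

The methods vignette (`vignettes/lipidquant-methods.Rmd`) describes the
model and its assumptions, the phantom's forward model and calibration,
the statistical choices (pooled vs Welch, pixel pooling vs subject-level
clustering), degenerate-input behavior, and known limitations.
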