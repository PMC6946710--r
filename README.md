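# psafret

Homo-FRET quantification from fluorescence anisotropy changes during
photoswitching.

## The problem

FRET between two copies of the *same* fluorescent protein (homo-FRET) is a
sensitive reporter of protein self-association, but it leaves intensity,
spectrum and lifetime unchanged — only the emission polarization responds.
Under polarized excitation an immobile fluorophore emits with high
anisotropy; energy transfer to a partner with a different dipole
orientation depolarizes the emission and lowers the anisotropy

    r = (I_par − g·I_perp) / (I_par + 2·g·I_perp)

where `g` calibrates the polarization bias of the detection path. The
catch is that a single anisotropy value cannot tell homo-FRET apart from
other depolarization sources: you need the same specimen with and without
energy transfer.

Photoswitchable fluorescent proteins solve this. As the imaging light
drives them to the off state, off molecules stop accepting energy, the
surviving emitters lose their FRET partners, and the anisotropy climbs
from its FRET value `r_et1` toward the no-transfer value `r_et0`. This
package fits the anisotropy against the surviving signal fraction
`x = 1 − F(t)` (where `F(t)` is the fraction photoswitched, from the total
fluorescence `I_par + 2g·I_perp`), extrapolates the line to `x = 1` and
`x = 0` to read off `r_et1` and `r_et0`, and converts the change to an
efficiency-like quantity

    drFRET = 6·(r_et0 − r_et1) / (1 + 8·r_et0 − 4·r_et1 + 4·r_et0·r_et1)

— the fractional gain of perpendicular-channel signal caused by energy
transfer. Unlike the raw anisotropy change, drFRET is stable across
objective lenses and optical configurations, which makes homo-FRET results
comparable between instruments. An optional correction inverts the
polarization mixing of high-NA objectives (collection half-angle
`θ = arcsin(NA/n)`) before the anisotropy is computed.

The package is aimed at cell biologists and microscopists running
dual-view polarization splitter experiments: it reads multi-page TIFF
stacks, calibrates `g` from an isotropic dye reference, extracts per-frame
ROI means with per-frame background subtraction, runs the estimator, and
reports group statistics (Welch t, ANOVA + Tukey–Kramer, Cohen's d) with
publication-style figures. A physics-based simulator of photoswitching
oligomers — binomial mixtures of clusters with steady-state transfer
anisotropy, Poisson/Gaussian camera noise, rendered dual-view stacks —
provides ground truth for every stage.

## Worked example

Simulate a strongly coupled Dronpa-like tandem dimer (10,000 oligomers,
50 frames, 8% off-switching per frame, sCMOS-like noise) and analyze it:

```r
library(psafret)

model <- oligomer_model(2, r_mono = 0.35, r_et = 0, coupling = 1)
sim <- simulate_trace(model, switching_params(0.08, 50), camera_model(),
                      optics_config(), n_oligomers = 10000, seed = 42)
res <- analyze_trace(sim$trace)
res
#> psAFRET result (uncorrected)
#>   r_et1   = 0.2329   (anisotropy under homo-FRET)
#>   r_et0   = 0.3513   (anisotropy, no energy transfer)
#>   delta r = 0.1183
#>   drFRET  = 0.2215
#>   fit: n=19 frames (cutoff 0.80), slope SE 0.001
sim$truth$drfret_true
#> [1] 0.2192067
```

`r_et1` is the fitted anisotropy with every fluorophore on (full
homo-FRET); `r_et0` is the extrapolation to complete photoswitching, i.e.
the same molecules with no acceptors left; their difference (delta r
= 0.1183) converts to drFRET = 0.2215, within 0.003 of the simulator's
closed-form ground truth. `plot_switching_trace(res)` draws the
anisotropy-vs-fraction-switched trace with the fitted line and both
extrapolated endpoints.

The same pipeline runs from files: `read_stack()` + `extract_trace()` for
dual-view TIFFs with ROI JSON, `estimate_g()` on an isotropic reference,
and `optics_config(na = 1.4, refractive_index = 1.515, apply_axelrod =
TRUE)` to unmix high-NA polarization scrambling. `inst/scripts/psafret`
wraps the workflow as `simulate` / `gfactor` / `analyze` / `compare`
subcommands over YAML configs.

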