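---
title: "Quantifying homo-FRET by photoswitching anisotropy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying homo-FRET by photoswitching anisotropy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psafret)
```

## The measurement problem

Energy transfer between two spectrally identical fluorophores (homo-FRET)
leaves total intensity, spectrum and lifetime unchanged, so the usual FRET
readouts are blind to it. What it does change is the polarization of the
emission: polarized excitation photoselects fluorophores whose absorption
dipoles align with the excitation field (a cos² weighting), and for an
immobile fluorophore the emission stays strongly polarized. If the excited
state hops to a neighboring fluorophore whose dipole points elsewhere, the
sensitized emission is depolarized and the steady-state anisotropy

$$r = \frac{I_\parallel - g\,I_\perp}{I_\parallel + 2\,g\,I_\perp}$$

drops. For an isotropic, immobile population, photoselection bounds $r$ to
$[-0.2,\,0.4]$. The instrument factor $g$ corrects the polarization bias of
the detection path and is calibrated on a fast-rotating dye solution whose
true anisotropy is zero (`estimate_g()`): $g$ is the ratio of
background-subtracted channel means that forces $r = 0$ on that reference.

A single anisotropy value cannot separate homo-FRET from other
depolarization sources. The trick this package implements is to record
anisotropy *while the fluorophores are switched off*: photoswitchable
fluorescent proteins (e.g. Dronpa) are driven to a dark state by the
imaging light itself. An off fluorophore neither absorbs, emits, nor
accepts energy, so as the population switches off the surviving emitters
progressively lose their FRET partners and the anisotropy rises from its
FRET value toward the no-transfer value. One time series therefore yields
both endpoints in the same specimen.

## The estimator

Per frame the pipeline computes background-subtracted channel means, the
total fluorescence $F_{tot} = I_\parallel + 2 g I_\perp$, the fraction
photoswitched $F(t) = (I(t_0) - I(t)) / I(t_0)$, and the anisotropy. The
anisotropy is close to linear in the surviving signal fraction
$x = 1 - F(t)$ for dimers, so an ordinary least squares line $r = a + b x$
is fit over the retained frames and evaluated at the two ends:

* $x = 1$ (all fluorophores on): $r_{et1} = a + b$, the anisotropy under
  homo-FRET;
* $x = 0$ (complete photoswitching): $r_{et0} = a$, the anisotropy without
  energy transfer, which no raw frame reaches — it is an extrapolation, not
  the last data point.

The anisotropy change $\Delta r = r_{et0} - r_{et1} = -b$ depends on the
optical configuration, so it is converted to

$$\mathrm{drFRET} = \frac{6\,(r_{et0} - r_{et1})}
  {1 + 8 r_{et0} - 4 r_{et1} + 4\,r_{et0}\,r_{et1}}$$

the fractional gain of perpendicular-channel signal attributable to energy
transfer, treating the perpendicular channel as the acceptor channel of a
sensitized-emission experiment. drFRET is zero exactly when
$r_{et1} = r_{et0}$ (the denominator then collapses to $(1+2r_{et0})^2$),
strictly increasing in $\Delta r$ at fixed $r_{et0}$, and — the property
that makes it worth the algebra — stable across objective lenses, because
the polarization mixing that lowers both anisotropies also rescales the
conversion.

Fit diagnostics follow the standard regression formulas: residual standard
error $s = \sqrt{\sum (r_t - \hat r_t)^2 / (n-2)}$, abscissa sum of squares
$SS_{xx} = \sum x_t^2 - (\sum x_t)^2 / n$, and slope standard error
$s_{\beta_1} = s / \sqrt{SS_{xx}}$. These are computed from the normal
equations directly (`fit_anisotropy_line()`), and the test suite checks
them against an independent textbook oracle at 1e-10.

### Frame selection

Two guards control which frames enter the fit, both configurable:

* `cutoff` (default **0.8**): frames with $F(t) > 0.8$ are excluded. Late
  in the switching cycle little signal remains and the anisotropy becomes
  very noisy; experimentally the usable range ends around 0.8–0.9 of the
  fluorophore switched, and 0.8 is adopted as the fixed default.
* `low_signal_frac` (default **0.05**): frames whose total fluorescence has
  fallen below 5% of the initial value are dropped even if they pass the
  cutoff, since the anisotropy ratio degenerates as both channels approach
  the noise floor.

Excluded frames are retained in the result object (flagged `used = FALSE`)
so plots can show the full trace.

## High-NA polarization mixing and its correction

A wide collection cone mixes the dipole-frame intensity components into the
measured channels. With the collection half-angle
$\theta = \arcsin(\mathrm{NA}/n)$ and weighting factors

$$K_a = \tfrac{2 - 3\cos\theta + \cos^3\theta}{3},\quad
  K_b = \tfrac{1 - 3\cos\theta + 3\cos^2\theta - \cos^3\theta}{12},\quad
  K_c = \tfrac{5 - 3\cos\theta - \cos^2\theta - \cos^3\theta}{4}$$

the measured channels are $I_\parallel = K_c I_z + K_b I_y + K_a I_x$ and
$g I_\perp = K_b I_z + K_c I_y + K_a I_x$. Assuming randomly oriented
fluorophores ($I_x = I_y$), `axelrod_unmix()` inverts the 2×2 system and
recomputes $r = (I_z - I_y)/(I_z + 2 I_y)$. Numerical choices:

* $g$ is applied *before* unmixing — the mixing equations operate on
  $(I_\parallel,\, g I_\perp)$ exactly as written above.
* The inversion denominator $D = K_b^2 + K_a K_b - K_c^2 - K_a K_c$
  vanishes as $\theta \to 0$; correction is refused when
  $|D| < 10^{-9}\max(K_c^2, 1)$ with advice to use the uncorrected mode
  (at such small angles the two agree to better than $10^{-3}$ anyway).
* All public interfaces take degrees; trig is done in radians internally.
* The $I_x = I_y$ assumption is stated for randomly oriented fluorophores;
  under homo-FRET between oriented pairs it is an approximation, applied
  as written and noted here rather than patched.

A point worth flagging for anyone comparing lenses: the mixing depends on
$\theta$, not on NA itself. An air lens at NA 0.75 has a *wider* cone
(48.6°) than an oil lens at NA 1.0 (41.3°), so the uncorrected $\Delta r$
ordering across lenses follows $\theta$, not NA. Empirical comparisons
across objectives also fold in excitation-side depolarization at high NA,
which this package does not model (see Limitations). The drFRET conversion
is what restores comparability: across the three standard lens conditions
(20×/0.75 air, 40×/1.0 oil, 100×/1.4 oil) the simulated drFRET of a fixed
dimer varies by under 2% relative while $\Delta r$ moves by ~12%.

## The oligomer simulator

Validation needs data with known ground truth, so the package ships a
physics-based generator rather than canned fixtures.

**Cluster anisotropy.** For a complex of $N$ identical fluorophores with
$k$ in the on state and equal pairwise coupling $\omega\tau$ (transfer rate
× lifetime; $\omega\tau = (d/R_0)^{-6}$ for separation $d$), the excitation
equilibrates over the on-state members and the emission anisotropy is the
steady-state mixture

$$r(k) = r_{mono}\frac{1 + \omega\tau}{1 + k\,\omega\tau}
       + r_{et}\frac{(k-1)\,\omega\tau}{1 + k\,\omega\tau}.$$

The equal-all-pairs form is a modeling choice: it is the simplest
steady-state expression consistent with a symmetric oligomer, and reduces
correctly to $r_{mono}$ for $k = 1$ or $\omega\tau = 0$.

**Ensemble mixing.** At on-fraction $p$ the number of on partners of an
emitter is binomial over the other $N-1$ subunits, so the
intensity-weighted ensemble anisotropy is
$r(p) = \sum_j \binom{N-1}{j} p^j (1-p)^{N-1-j}\, r(j+1)$ (equal quantum
yields). For $N = 2$ this is exactly affine in $p$ — the theoretical basis
for the linear fit. For $N \ge 3$ with tight coupling ($d \lesssim 0.8
R_0$) the on-fraction curve is convex: plotted against fraction switched it
hugs the FRET value and shoots up late (the "upward curvature" regime).
The curvature, measured as chord minus midpoint, is positive at
$d/R_0 = 0.8$ and decays monotonically toward zero by $d/R_0 = 1.5$, which
is why real tandem constructs at typical fluorescent-protein separations
still look linear.

**Stochastic layer.** `simulate_trace()` switches each on fluorophore off
independently with probability `p_off_per_frame` per frame (geometric
decay, so the total-fluorescence rate constant is
$-\log(1 - p_{off})$; illumination-intensity dependence is deliberately not
modeled), computes the exact anisotropy and brightness of the realized
population, projects onto channels (optionally with mixing and a g-factor
bias), and adds Poisson shot noise, Gaussian read noise and the camera
offset. `render_stack()` distributes the same photon flux over the pixels
of a cell polygon in a 16-bit dual-view TIFF (parallel left, perpendicular
right, configurable translation between halves) with per-pixel noise, and
writes companion ROI and ground-truth JSON. A single integer seed drives
all draws; identical seeds give byte-identical stacks.

**Ground truth.** $r_{et1}^{true} = r(p{=}1)$, $r_{et0}^{true} =
r_{mono}$, and the true drFRET is the conversion formula evaluated on that
pair — so end-to-end recovery tests close the loop through an independent
closed form.

### Default study conditions

| parameter | default | rationale |
|---|---|---|
| `r_mono` | 0.35 | near the immobile-fluorophore photoselection limit, typical of fluorescent proteins |
| `r_et` | 0 | sensitized emission from an uncorrelated acceptor dipole is taken as fully depolarized; configurable |
| `coupling` | 1 | $d = R_0$; the reference dimer used across the validation suite |
| `p_off_per_frame` | 0.08 | 50 frames carry the population to ~98% switched, covering the full fit range |
| `photons_per_fluor` | 100 | moderate widefield signal; with 10⁴ dimers the ROI collects ~2×10⁶ photons in frame 1 |
| `read_noise_sd`, `offset`, `gain` | 1.5, 100, 1 | representative sCMOS settings |
| `n_oligomers` | 10⁴ | per-frame anisotropy SE of a few 10⁻³, matching decent live-cell ROIs |

Validation problem sizes: the recovery suites run 20 seeded simulations of
10⁴ dimers × 50 frames (trace level) and rendered 48×96-pixel stacks at the
same depth; these reproduce the true drFRET to within ±0.02 with typical
errors under ±0.005, and a monomer control reads |drFRET| < 0.01.

### What the simulator does and does not emulate

It emulates photoselection, intra-oligomer homo-FRET depolarization,
stochastic off-switching, NA mixing, channel bias and camera noise. It does
**not** emulate rotational diffusion during the excited-state lifetime,
spectral bleed-through, reactivation cycles, cell morphology,
focus/stage drift, or spatial heterogeneity of expression. Passing
recovery tests therefore demonstrate the correctness of the estimator
under the stated physics, not robustness to every artifact of live-cell
data.

## Group statistics

Per-cell results are compared the way imaging papers report them: mean ±
sem summaries, two-tailed Welch t-tests for two groups, one-way ANOVA with
Tukey–Kramer pairwise comparisons (studentized-range quantiles computed
numerically, unequal group sizes handled) for three or more, and Cohen's
d. Cohen's d divides the absolute mean difference by the pooled *standard
deviation*; a compatibility mode (`denominator = "variance"`) divides by
the pooled variance instead, for reproducing analyses that normalized that
way. The variance form is dimensionally inconsistent and not recommended.

## Design decisions

* **Background** is subtracted per frame from a no-cell region, not as one
  global constant, so slow baseline drifts are tracked. For stationary
  backgrounds the two are equivalent.
* **Registration** of the dual-view halves uses a configured integer
  translation, optionally refined by integer-pixel cross-correlation;
  sub-pixel registration is out of scope for ROI-mean analysis.
* **ROI rasterization** uses pixel-center containment with an even-odd
  rule, so integer-vertex rectangles behave half-open and membership is
  identical across channels after offset mapping.
* **Degenerate inputs** fail loudly: zero anisotropy denominators,
  non-positive calibration intensities, abscissae without spread, fewer
  than three retained frames, and out-of-domain drFRET inputs all raise
  errors rather than returning clamped values. Negative drFRET (noise
  pushing $r_{et1}$ above $r_{et0}$) is reported as-is with a warning.
* **Configuration** is YAML with strict key validation; every simulate run
  logs its config, seed and package version to a JSON run log, and seeds
  are mandatory for simulation.
* **Analysis granularity**: the estimator operates on per-frame ROI means
  (including the high-NA correction), not per-pixel values; pixel-wise
  anisotropy maps are out of scope.

## Limitations

drFRET is an efficiency-like index, not a transfer efficiency with a
distance calibration: no attempt is made to invert it to separations or
$R_0$. The high-NA correction addresses emission-side mixing only;
excitation-side depolarization at high NA is not modeled, which is one
reason corrected $\Delta r$ from different lenses need not coincide even
though drFRET approximately does. Anisotropy extrapolation assumes the
switching process itself does not change the rotational mobility of the
remaining fluorophores.

## A worked run

```{r example}
model <- oligomer_model(2, r_mono = 0.35, r_et = 0, coupling = 1)
sim <- simulate_trace(model, switching_params(0.08, 50), camera_model(),
                      optics_config(), n_oligomers = 10000, seed = 42)
res <- analyze_trace(sim$trace)
res
sim$truth$drfret_true
```

```{r plot, fig.width = 5, fig.height = 4}
plot_switching_trace(res)
```
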