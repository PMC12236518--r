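---
title: "Models and methods behind stabscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stabscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabscreen)
```

# The problem

Orphan sensor proteins — here modeled on a PAS-HTH one-component
transcription factor with a ligand-binding cavity but no known ligand — are
screened against a fragment library for small molecules that stabilize the
fold. The campaign has three stages, each with its own physics and its own
estimator:

1. **DSF (thermal shift).** A hydrophobicity-sensitive dye reports
   unfolding as fluorescence versus temperature; a compound that raises the
   melting temperature $T_m$ above a threshold is a hit.
2. **STD NMR.** Saturation transferred from protein to a bound ligand
   produces difference-spectrum intensity; titrating ligand concentration
   and saturation time yields a dissociation constant $K_d$.
3. **MMS (amide-I IR).** Differential absorbance across 1588–1712 cm$^{-1}$
   is deconvolved into secondary-structure classes; per-class melting
   temperatures and a ligand EC50 of thermal stabilization quantify *where*
   the stabilization acts.

No raw plate, NMR or IR data accompany the campaign this package models, so
every stage ships with a seeded generator that draws data from exactly the
statistical structure the estimators assume, with known ground truth. That
is what the test suite and the acceptance script exercise.

# Stage models

## DSF: Boltzmann rising limb

A well's trace is fitted with the two-state Boltzmann sigmoid

$$F(T) = f_{pre} + \frac{f_{post} - f_{pre}}{1 + e^{(T_m - T)/s}}$$

on the *rising limb only*, from the trace start to the global fluorescence
maximum. Past the peak the dye dissociates and fluorescence decays; the
two-state model is invalid there, so those points are excluded rather than
modeled. Non-convergent fits fall back to the derivative-maximum $T_m$ and
are flagged `poor_fit`; transitions below 5 % of the signal scale are
`low_amplitude` (no $T_m$); wells whose smoothed derivative (moving window
of 5 grid points) has two or more maxima above 20 % of the tallest are
`biphasic`. Replicates disagreeing by more than 2 °C are discarded as
irreproducible. All of these defaults are arguments.

**Hit rule.** A compound is a hit when its mean $T_m$ *strictly* exceeds
the control mean plus **one standard deviation of the compound mean-$T_m$
distribution across the screen**. The campaign this package models reports
a control of 53.4 °C with a threshold of 55.7 °C; that 2.3 °C gap is ~30×
the control replicate SE, so the only spread that reproduces it is the
library-wide $T_m$ distribution (hits included). `callHits()` therefore
computes the SD over all compounds with a usable mean $T_m$. Ties at the
threshold resolve as non-hits (strict inequality).

## STD NMR: amplification factor → buildup → Langmuir

Per epitope region (a ligand ppm window) and condition, the amplification
factor is
$$\mathrm{STD\text{-}AF} = \varepsilon \cdot \frac{I_{diff}}{I_{ref}},
  \qquad \varepsilon = \frac{[L]_{tot}}{[P]_{tot}},$$
fitted over saturation time with the buildup law
$$\mathrm{AF}(t) = \mathrm{AF}_{max}\left(1 - e^{-k_{sat} t}\right),$$
whose initial slope $\mathrm{AF}_0 = \mathrm{AF}_{max} k_{sat}$ is robust
to rebinding and relaxation bias. $\mathrm{AF}_0$ versus ligand
concentration is then fitted to the Langmuir isotherm
$$\mathrm{AF}_0([L]) = \frac{\alpha_{STD} [L]}{[L] + K_d},$$
weighted by $1/\mathrm{se}^2$ with the $\mathrm{AF}_0$ standard errors
propagated from the buildup covariance by the delta method. Per-epitope
$K_d$ values are combined by the inverse-variance weighted mean,
$\mathrm{SE} = (\sum \mathrm{se}_i^{-2})^{-1/2}$ — the standard fixed-effect
combination matching a "weighted average ± SE" presentation.

Two deliberate choices:

* **Unscaled covariance under known weights.** With only five
  concentrations the residual-variance estimate behind the usual `vcov`
  rescaling has 3 degrees of freedom; its sampling noise systematically
  understates the $K_d$ SE. When $\mathrm{AF}_0$ SEs are supplied, they are
  treated as known variances and the covariance is left unscaled. In the
  packaged 50-replicate calibration this brings the 2-SE coverage of the
  truth from ~72 % to ~90 % (the suite asserts ≥ 80 %).
* **Free ligand ≈ total ligand** throughout, valid in the
  $[L] \gg [P]$ regime of the design (200–1000 μM ligand vs 20 μM protein).
  Protein concentration is a *required* input, never defaulted, because the
  source campaign reports different values in different experiments.

Region integrals use the trapezoidal rule on absolute intensity over the
native ppm grid, with boundary interpolation so the integral covers the
exact window.

## MMS: band deconvolution and melt analysis

The amide-I band model is a table of Gaussian sub-bands (center, width
expressed as the Gaussian SD, width bounds 3–12 cm$^{-1}$, structure
class): side-chain 1605; intermolecular β-sheet 1619 and 1691; native
β-sheet 1633 and 1640; unordered 1645; coiled-coil helix 1651; canonical
helix 1656; turn 1667 and 1678 cm$^{-1}$. These are literature-informed
defaults and fully user-overridable via YAML. The coiled-coil/canonical
helix split reflects the 1650–1652 cm$^{-1}$ signature of coiled-coil
formation; the side-chain band (mainly Tyr) is excluded from the fraction
normalization by default so reported fractions are secondary-structure
fractions (includable by argument).

Processing per ramp temperature:

1. differential → absolute rescaling by the nominal displacement factor
   0.63 (a pure scalar; all fractional results are invariant to it);
2. similarity spectrum: Savitzky–Golay second derivative (window 19
   wavenumbers, polynomial order 3 — the order is a package choice),
   negated, linearly baselined through the end-region minima, floored at 0;
3. Gaussian band deconvolution into per-band amplitudes and areas
   ($a w \sqrt{2\pi}$), class fractions = class area / total area.

**Where the deconvolution is fitted.** Two domains are offered. The default
fits the band model to the *absolute* spectra. The `"similarity"` option
fits the floored similarity spectra, which resist baseline drift in real
data, but the floor irreversibly clips a weak band's signature once a
strong neighbour's negative second-derivative side lobes overlap it — in
ramp series this biases late-melt class midpoints by a couple of degrees.
Because the package's accuracy contract is per-class $T_m$ recovery to
< 1 °C, the absolute domain is the default; the similarity spectra are
always computed and drive the global melt metric.

**Width estimation.** Band widths are physical properties of the
vibrational modes and do not change along a 25–75 °C ramp. The pipeline
therefore estimates one width per band *jointly across all ramp spectra*
by variable projection: an outer bounded Levenberg–Marquardt over the
widths with inner non-negative least squares (NNLS) amplitudes per
spectrum. Per-spectrum width refitting is deliberately avoided: the
amide-I design is heavily collinear (neighbouring bands 5–11 cm$^{-1}$
apart at SD ≈ 6 cm$^{-1}$), and letting each temperature choose its own
widths makes the NNLS active set jump between neighbours under noise.
Single-spectrum `deconvolveBands()` instead profiles a shared width scale
by 1-D optimization, with an optional bounded polish (`refine`); exact
duplicate bands are collapsed with a warning rather than fitted through a
singular design.

**Melting temperatures.** The class melting profile is by default the
class's fitted band area versus temperature — the quantity a signal-change
heat map tracks, and an exact logistic in the generator's midpoint. The
compositional fraction profile is available (`profile = "fraction"`) but
its midpoints are coupled across classes because fractions are ratios: a
class can *appear* to transition when a neighbour melts. Each profile is
fitted with a free-direction logistic inside a ±12 °C window centered on
the temperature of maximal |rate of change| (so secondary features do not
drag the midpoint); the derivative-maximum estimate is reported alongside
and used when the sigmoid fails, and flat profiles are flagged with an
undefined $T_m$. The global $T_m$ applies the same machinery to
$1 - \rho(T)$, the Pearson dissimilarity of each similarity spectrum from
the lowest-temperature one.

**EC50.** Global $T_m$ versus ligand concentration is fitted with the
rectangular hyperbola
$T_m([L]) = T_{m,0} + \Delta T_{m,max}\,[L]/([L] + EC_{50})$ — a Hill
coefficient of 1, since the modeled campaign presents no cooperativity
evidence. A stabilization amplitude whose SE spans zero is flagged
`no_stabilization`.

# The generators

Each generator draws from the model family its estimator fits, plus noise;
they are phenomenological at exactly that level (no NOE transfer, spin
relaxation, dye photophysics or IR optics are simulated).

* **DSF.** Boltzmann rise times an exponential dye-dissociation factor
  beyond a decay onset (default $T_m$ + 12 °C, rate 0.12 /°C), additive
  Gaussian noise. Grid 25–95 °C at 0.25 °C; plateaus 1000/10000 a.u.;
  noise default 1 % of amplitude (the campaign reports no noise magnitudes
  for any assay — 1 % DSF, 3 % STD CV and 0.5 %-of-peak IR noise are
  package choices). An optional second transition makes a biphasic well.
* **Screen.** 760 compounds in duplicate plus 8 control wells. Non-hits
  get a *bounded* uniform $T_m$ jitter (SD 1.21 °C, half-width 2.1 °C);
  the ~6.6 % planted hits get uniform shifts of 3–12 °C. This mixture has
  an analytic SD of ≈ 2.30 °C (`screenTmSd()`), putting the analytic hit
  threshold at ≈ 55.7 °C, while the bounded supports keep non-hits
  strictly below and hits strictly above it — so the planted hit set is
  exactly recoverable at zero noise. A normal jitter of the same SD would
  place ~16 % of non-hits over the threshold and make exact recovery
  impossible; the bounded design is what "planted ground truth" requires.
* **STD.** Noiseless records obey the buildup law with the Langmuir
  constraint $\mathrm{AF}_{max} k_{sat} = \alpha_{STD}[L]/([L]+K_d)$ and
  epitope-constant $k_{sat}$ (the standard initial-slope simplification).
  Difference integrals carry multiplicative lognormal noise
  (CV-parameterized) because integrals are positive and their errors scale
  with signal. Design: 3 epitopes × 5 concentrations (200–1000 μM) × 8
  saturation times (0.5–5 s) at 20 μM protein.
* **IR.** Gaussian band sums whose native amplitudes follow falling
  logistics toward a retained post-melt fraction (values > 1 describe
  bands, like unordered, that grow on melting) and whose aggregation band
  rises with its own logistic; total area is *not* conserved, matching the
  intensity changes a real ramp shows. Grid 1588–1712 cm$^{-1}$ at 1
  cm$^{-1}$, 25–75 °C at 1 °C. The bound fixture raises the native-β
  midpoints by 14 °C, the helix classes by 4–5 °C, turn/unordered/side
  chain by 2 °C, and delays aggregation by 14 °C.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: plate-position and liquid-handling artifacts,
compound autofluorescence and inner-filter effects, exchange-regime and
$T_1$-relaxation bias in STD intensities, water-vapor and baseline drift
in IR, and model misspecification (real amide-I bands are not exactly
Gaussian, real melts are not exactly two-state). The package's claims are
about estimator correctness under the stated models.

# Numerical choices

* All nonlinear fits use Levenberg–Marquardt (`minpack.lm`), bounded where
  a parameter has a physical range ($K_d \in (0, 100 \max[L]]$, widths in
  their bounds, $k_{sat} > 0$), initialized from the data (derivative
  maximum for $T_m$; $\alpha = \max \mathrm{AF}_0$, $K_d$ = median
  concentration; first-point slope for buildups).
* Grid argmax positions are refined by three-point quadratic
  interpolation, so derivative-based $T_m$ estimates are not quantized to
  the grid.
* Degenerate inputs have defined behaviour rather than failures: flat
  traces → `low_amplitude`; all-zero buildups → $\mathrm{AF}_{max} = 0$;
  plateau Langmuir data → `saturated` with $K_d$ at its lower bound;
  concentration ranges under 2-fold → `narrow_range` warning; flat melt
  profiles → flagged, $T_m$ undefined; constant $T_m$ vs concentration →
  `no_stabilization`.
* Every generator draws from a sub-seed derived deterministically from the
  master seed and a stream label, so datasets are reproducible bit-for-bit
  and independent across stages.

# Problem sizes

The suite and the acceptance script run the full packaged designs: the
760-compound screen in duplicate (1528 curve fits), the 120-record STD
design per ligand (15 buildup + 3 Langmuir fits), 50-replicate noisy-
recovery calibrations for the $K_d$ chain, and two 125 × 51 amide-I ramp
series through the complete deconvolution and melt analysis.

# Known limitations

* The hit rule assumes the compound $T_m$ distribution is dominated by
  true spread, not by fit noise; screens with very noisy wells would need
  a robust SD.
* The fixed-effect $K_d$ combination assumes per-epitope estimates are
  independent and unbiased; strong epitope heterogeneity would call for a
  random-effects model.
* Band deconvolution quality is bounded by the band table: classes whose
  bands are absent from the model are silently absorbed by neighbours.
* The global melt metric (correlation dissimilarity) is one reasonable
  choice among several; it is not claimed to match any vendor's
  proprietary metric.
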