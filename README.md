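# stabscreen

Analysis toolkit for three-stage small-molecule stabilization screening of
orphan sensor proteins — the campaign design in which a fragment library is
screened by **differential scanning fluorimetry (DSF)**, hits are validated
and quantified by **saturation transfer difference (STD) NMR**, and the
structural locus of stabilization is resolved by **microfluidic modulation
spectroscopy (MMS)** across the amide-I IR band. It is written for
biophysics and early-discovery groups who run such campaigns and want the
estimation chain to be open, tested and reproducible.

## What it computes

**DSF.** Each well's fluorescence trace is fitted on its rising limb with
the Boltzmann sigmoid

    F(T) = f_pre + (f_post − f_pre) / (1 + exp((Tm − T)/s))

with QC flags for low-amplitude, biphasic and irreproducible wells. A
compound is a hit when its mean Tm strictly exceeds the control mean plus
one standard deviation of the compound mean-Tm distribution across the
screen.

**STD NMR.** Per epitope region the amplification factor
`STD-AF = ([L]/[P]) · I_diff/I_ref` is fitted over saturation time with the
buildup law `AF(t) = AF_max (1 − exp(−k_sat t))`; the initial growth rates
`AF0 = AF_max · k_sat` are fitted over ligand concentration with the
Langmuir isotherm `AF0([L]) = α_STD [L]/([L] + K_d)`, and the per-epitope
dissociation constants are combined by the inverse-variance weighted mean.

**MMS.** Differential amide-I spectra (1588–1712 cm⁻¹) are rescaled to
absolute, converted to similarity spectra (inverted, baselined
Savitzky–Golay second derivative), deconvolved into Gaussian sub-bands by
structure class (β-sheet, α-helix — coiled-coil and canonical — turn,
unordered, aggregated β, side chain), and each class's melting temperature
is the logistic midpoint of its melting profile. The global Tm versus
ligand concentration yields an EC50 of thermal stabilization.

Every stage has a seeded synthetic-data generator with known ground truth
(`simulateMeltCurves`, `simulateScreen`, `simulateStdDataset`,
`simulateIRSeries`) plus packaged fixture presets (`dsfFixture`,
`stdFixture`, `screenFixture`, `irFixture`), so the whole chain is testable
without instrument data. See the methods vignette
(`vignettes/stabscreen-methods.Rmd`) for the models, defaults and design
choices.

## Worked example

```r
library(stabscreen)

# DSF: fit a synthetic control melt curve (Tm preset 53.4 degC, 1% noise)
curves <- simulateMeltCurves(dsfFixture("control"), seed = 1,
                             compoundId = "DMSO")
fitMeltCurve(curves[[1]])
#> MeltFit [DMSO/W01 rep 1]
#>   Tm = 53.40 +- 0.016 degC (slope 1.01, R2 0.9991)

# STD NMR: full pipeline on a synthetic titration (Kd preset 171 uM, 3% CV)
ds <- simulateStdDataset(stdFixture("KG-96"), noiseCv = 0.03, seed = 1)
ds
#> STDDataset: 120 records (3 epitopes x 5 ligand concs x 8 sat times), [P] = 20 uM
runStdPipeline(ds)
#> KdEstimate: Kd = 183.6 +- 15.1 uM (weighted over 3 epitopes)
#>   8.42-8.39ppm: 172.0 +- 24.3 uM
#>   7.83-7.78ppm: 195.8 +- 25.1 uM
#>   7.42-7.26ppm: 183.8 +- 30.4 uM
```

The fitted Tm reproduces the generating 53.4 °C to within its standard
error, and the combined K_d estimate (183.6 ± 15.1 μM) covers the
generating 171 μM — at 3 % integral noise the K_d of a 171 μM binder
sampled only up to 1000 μM is determined to roughly ±10 %.

File-based workflows use the CSV readers/writers (`readMeltCurves`,
`readStdDataset`, `readIRSeries`, ...) and the subcommand wrapper in
`inst/scripts/stabscreen.R`; `runEndToEnd()` executes the whole demo
campaign from the packaged fixtures and writes a JSON run report.

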