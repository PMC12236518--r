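# Packaged fixture presets. Tm and Kd presets mirror the screening campaign
# the package models (control 53.4 degC; KG-96 / KG-408 / KG-484 Tm and Kd
# presets); amplitudes, rates and noise levels are package choices (see the
# methods vignette).

.fixtureYaml <- function() {
  path <- system.file("extdata", "fixtures.yaml", package = "stabscreen")
  .stopif(path == "", "fixtures.yaml not found; is the package installed?")
  yaml::read_yaml(path)
}

#' Default ligand epitope regions
#'
#' The three aromatic ppm windows integrated in the STD difference spectra.
#'
#' @return list of \linkS4class{EpitopeRegion}.
#' @export
defaultEpitopeRegions <- function() {
  fx <- .fixtureYaml()
  lapply(fx$std$regions, function(r)
    EpitopeRegion(r$label, r$ppm_lo, r$ppm_hi))
}

#' DSF fixture preset
#'
#' Generator parameters for the packaged DSF conditions: the DMSO control
#' (Tm 53.4 degC) and the three characterized hits (KG-96 57.2, KG-408 57.3,
#' KG-484 63.4 degC), all sharing the control's curve shape and 1%-amplitude
#' noise.
#'
#' @param name one of \code{"control"}, \code{"KG-96"}, \code{"KG-408"},
#'   \code{"KG-484"}.
#' @param noiseSd override the preset noise sd (a.u.); use 0 for noiseless.
#' @return a \linkS4class{DSFGenParams}.
#' @export
dsfFixture <- function(name = c("control", "KG-96", "KG-408", "KG-484"),
                       noiseSd = NULL) {
  name <- match.arg(name)
  fx <- .fixtureYaml()$dsf
  base <- fx$control
  tm <- if (name == "control") base$tm else fx[[name]]$tm
  dsfGenParams(
    tmTrue = tm,
    transitionSlope = base$transition_slope,
    fPre = base$f_pre, fPost = base$f_post,
    decayOnset = tm + base$decay_onset_offset,
    decayRate = base$decay_rate,
    noiseSd = if (is.null(noiseSd)) base$noise_sd else noiseSd,
    nReplicates = base$n_replicates,
    tempGrid = seq(base$temp_min, base$temp_max, by = base$temp_step))
}

#' STD NMR fixture preset
#'
#' Ground-truth binding parameters for the packaged titration designs:
#' Kd presets 171 (KG-96), 376 (KG-408) and 841 uM (KG-484) over the
#' standard design of 5 ligand concentrations (200-1000 uM) x 8 saturation
#' times (0.5-5 s) x 3 epitope regions at 20 uM protein.
#'
#' @param name one of \code{"KG-96"}, \code{"KG-408"}, \code{"KG-484"}.
#' @return a \linkS4class{BindingTruth}.
#' @export
stdFixture <- function(name = c("KG-96", "KG-408", "KG-484")) {
  name <- match.arg(name)
  fx <- .fixtureYaml()$std
  lig <- fx[[name]]
  regions <- lapply(fx$regions, function(r)
    EpitopeRegion(r$label, r$ppm_lo, r$ppm_hi))
  labels <- vapply(regions, function(r) r@label, character(1))
  bindingTruth(
    kdTrue = lig$kd_uM,
    alphaStd = setNames(unlist(lig$alpha_std), labels),
    ksatRef = setNames(unlist(lig$ksat_ref), labels),
    proteinConc = fx$protein_conc_uM,
    ligandConcs = unlist(fx$ligand_concs_uM),
    satTimes = unlist(fx$sat_times_s),
    regions = regions)
}

#' Fragment-screen fixture preset
#'
#' The 760-compound screen design: control Tm 53.4 degC, ~50 planted hits
#' with uniform Tm shifts of 3-12 degC, bounded non-hit jitter sized so the
#' compound-Tm mixture SD is ~2.3 degC (analytic hit threshold ~55.7 degC;
#' see \code{\link{screenTmSd}}).
#'
#' @param seed integer seed for the screen draw.
#' @return a \linkS4class{ScreenSpec}.
#' @export
screenFixture <- function(seed = 1L) {
  fx <- .fixtureYaml()$screen
  screenSpec(nCompounds = fx$n_compounds, controlTm = fx$control_tm,
             libraryDeltaSd = fx$library_delta_sd,
             hitFraction = fx$hit_fraction,
             hitDeltaRange = c(fx$hit_delta_lo, fx$hit_delta_hi),
             seed = seed, nControlWells = fx$n_control_wells)
}

#' Amide-I thermal-ramp fixture preset
#'
#' Generator parameters for the apo series and the ligand-bound series in
#' which the native beta-sheet melt midpoint is raised by 14 degC, the helix
#' classes by 4-5 degC and the aggregation onset is delayed accordingly.
#'
#' @param name \code{"apo"} or \code{"bound"}.
#' @param noiseSd override the preset noise sd (absorbance a.u.).
#' @return an \linkS4class{IRGenParams}.
#' @export
irFixture <- function(name = c("apo", "bound"), noiseSd = NULL) {
  name <- match.arg(name)
  fx <- .fixtureYaml()$mms
  bands <- do.call(rbind, lapply(fx$apo$bands, as.data.frame))
  agg <- fx$apo$aggregate
  aggVec <- c(center = agg$center, width = agg$width,
              amplitude = agg$amplitude, growth_tm = agg$growth_tm,
              growth_slope = agg$growth_slope)
  if (name == "bound") {
    sh <- fx$bound_shifts
    bands$melt_tm <- bands$melt_tm +
      unlist(sh[bands$structure_class], use.names = FALSE)
    aggVec[["growth_tm"]] <- aggVec[["growth_tm"]] + sh$aggregate
  }
  irGenParams(
    bandTruth = bands, aggregateBand = aggVec,
    wavenumberGrid = seq(fx$wavenumber_min, fx$wavenumber_max,
                         by = fx$wavenumber_step),
    tempGrid = seq(fx$temp_min, fx$temp_max, by = fx$temp_step),
    noiseSd = if (is.null(noiseSd)) fx$noise_sd else noiseSd)
}

#' Ground-truth class melt shifts of the bound IR fixture
#'
#' @return named numeric of degC shifts per structure class (plus
#'   \code{aggregate}).
#' @export
irFixtureShifts <- function() {
  sh <- .fixtureYaml()$mms$bound_shifts
  setNames(unlist(sh), names(sh))
}

#' Default amide-I Gaussian band model
#'
#' Literature-informed sub-band table: intermolecular beta-sheet 1619 and
#' 1691, native beta-sheet 1633 and 1640, unordered 1645, coiled-coil helix
#' 1651, canonical helix 1656, turn 1667 and 1678, Tyr/side-chain 1605 cm-1.
#' Widths default to 6 cm-1 (Gaussian sd) with bounds 3-12; centers may move
#' by \code{center_tol} when refinement is enabled in
#' \code{\link{deconvolveBands}}.
#'
#' @return a \linkS4class{BandModel}.
#' @export
defaultBandModel <- function() {
  BandModel(data.frame(
    label = c("sc1605", "inter1619", "nb1633", "nb1640", "un1645",
              "hcc1651", "h1656", "t1667", "t1678", "inter1691"),
    class = c("side_chain", "intermolecular_beta", "native_beta",
              "native_beta", "unordered", "alpha_helix_cc", "alpha_helix",
              "turn", "turn", "intermolecular_beta"),
    center = c(1605, 1619, 1633, 1640, 1645, 1651, 1656, 1667, 1678, 1691),
    center_tol = 2,
    width = 6, width_lo = 3, width_hi = 12,
    stringsAsFactors = FALSE))
}
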