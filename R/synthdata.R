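# Seeded generators for all three assay stages. Each generator is
# phenomenological at the level the downstream fits assume: it draws from the
# exact functional families the estimators fit, plus noise, so parameter
# recovery is well defined.

# noiseless DSF trace: Boltzmann rise(s) multiplied past the decay onset by
# an exponential dye-dissociation factor that relaxes the signal back to the
# pre-transition baseline
.dsfNoiseless <- function(params) {
  tt <- params@tempGrid
  amp <- params@fPost - params@fPre
  if (length(params@biphasic) == 3L) {
    a2 <- params@biphasic[3]
    rise <- (1 - a2) * .logisticRise(tt, params@tmTrue, params@transitionSlope) +
      a2 * .logisticRise(tt, params@biphasic[1], params@biphasic[2])
  } else {
    rise <- .logisticRise(tt, params@tmTrue, params@transitionSlope)
  }
  decay <- exp(-params@decayRate * pmax(0, tt - params@decayOnset))
  params@fPre + amp * rise * decay
}

#' Simulate replicate DSF melt curves
#'
#' Generates \code{nReplicates} fluorescence traces from a two-state (or
#' optionally biphasic) melt with dye-dissociation decay and additive
#' Gaussian noise. Identical seeds reproduce identical traces.
#'
#' @param params a \linkS4class{DSFGenParams}.
#' @param seed integer seed.
#' @param compoundId,wellPrefix identifiers stamped on the curves.
#' @return list of \linkS4class{MeltCurve}, one per replicate.
#' @examples
#' curves <- simulateMeltCurves(dsfGenParams(noiseSd = 0), seed = 1)
#' @export
simulateMeltCurves <- function(params, seed = 1L, compoundId = "compound",
                               wellPrefix = "W") {
  stopifnot(is(params, "DSFGenParams"))
  validObject(params)
  base <- .dsfNoiseless(params)
  set.seed(.subSeed(seed, paste0("dsf:", compoundId)))
  lapply(seq_len(params@nReplicates), function(r) {
    noise <- if (params@noiseSd > 0)
      rnorm(length(base), sd = params@noiseSd) else 0
    MeltCurve(params@tempGrid, base + noise,
              wellId = sprintf("%s%02d", wellPrefix, r),
              compoundId = compoundId, replicateIndex = r)
  })
}

#' Simulate a full fragment screen with planted hits
#'
#' Draws a library of compounds around the control Tm: non-hits get a bounded
#' uniform jitter (sd \code{libraryDeltaSd}), planted hits a uniform shift
#' from \code{hitDeltaRange}. Every compound is measured in duplicate
#' (\code{nReplicates} of the curve template), plus control wells.
#'
#' @param spec a \linkS4class{ScreenSpec}.
#' @param curveParams \linkS4class{DSFGenParams} template for every well
#'   (its \code{tmTrue} is replaced per compound); defaults to the control
#'   fixture shape.
#' @param noiseSd trace noise sd (a.u.); overrides the template when given.
#' @param controlId label for control wells.
#' @return list with \code{curves} (flat list of \linkS4class{MeltCurve})
#'   and \code{truth} (data.frame: compound_id, tm_true, delta_true, is_hit).
#' @export
simulateScreen <- function(spec, curveParams = dsfGenParams(),
                           noiseSd = NULL, controlId = "DMSO") {
  stopifnot(is(spec, "ScreenSpec"))
  validObject(spec)
  if (!is.null(noiseSd)) curveParams@noiseSd <- noiseSd
  set.seed(.subSeed(spec@seed, "screen:truth"))
  n <- spec@nCompounds
  nHit <- round(spec@hitFraction * n)
  isHit <- rep(FALSE, n)
  if (nHit > 0) isHit[sample.int(n, nHit)] <- TRUE
  halfWidth <- sqrt(3) * spec@libraryDeltaSd   # uniform sd -> half width
  delta <- runif(n, -halfWidth, halfWidth)
  if (nHit > 0)
    delta[isHit] <- runif(nHit, spec@hitDeltaRange[1], spec@hitDeltaRange[2])
  truth <- data.frame(
    compound_id = sprintf("CMP%04d", seq_len(n)),
    tm_true = spec@controlTm + delta,
    delta_true = delta,
    is_hit = isHit,
    stringsAsFactors = FALSE)

  curves <- vector("list", 0L)
  for (i in seq_len(n)) {
    p <- curveParams
    p@tmTrue <- truth$tm_true[i]
    p@decayOnset <- truth$tm_true[i] + (curveParams@decayOnset - curveParams@tmTrue)
    curves <- c(curves, simulateMeltCurves(
      p, seed = .subSeed(spec@seed, paste0("screen:", i)),
      compoundId = truth$compound_id[i],
      wellPrefix = sprintf("P%04d_", i)))
  }
  pc <- curveParams
  pc@tmTrue <- spec@controlTm
  pc@nReplicates <- spec@nControlWells
  curves <- c(curves, simulateMeltCurves(
    pc, seed = .subSeed(spec@seed, "screen:control"),
    compoundId = controlId, wellPrefix = "CTRL_"))
  list(curves = curves, truth = truth)
}

#' Analytic Tm spread of a screen design
#'
#' Standard deviation of the compound true-Tm mixture distribution implied by
#' a \linkS4class{ScreenSpec} (bounded-uniform non-hits plus uniform hits),
#' from the closed-form mixture moments. The hit-calling threshold this
#' design targets is \code{controlTm + screenTmSd(spec)}.
#'
#' @param spec a \linkS4class{ScreenSpec}.
#' @return standard deviation in degC.
#' @export
screenTmSd <- function(spec) {
  p <- spec@hitFraction
  lo <- spec@hitDeltaRange[1]; hi <- spec@hitDeltaRange[2]
  muH <- (lo + hi) / 2
  m2H <- muH^2 + (hi - lo)^2 / 12
  m2N <- spec@libraryDeltaSd^2           # zero-mean jitter
  mu <- p * muH
  sqrt((1 - p) * m2N + p * m2H - mu^2)
}

#' Simulate an STD NMR titration dataset
#'
#' For each (epitope, ligand concentration, saturation time) the noiseless
#' amplification factor follows the buildup law
#' \eqn{AF(t) = AF_{max}(1 - e^{-k_{sat} t})} with the Langmuir constraint
#' \eqn{AF_{max} k_{sat} = \alpha_{STD} [L] / ([L] + K_d)} and
#' epitope-constant \eqn{k_{sat}}. Difference integrals are emitted against a
#' constant reference integral via \eqn{\epsilon = [L]/[P]} and carry
#' multiplicative lognormal noise with the requested coefficient of
#' variation.
#'
#' @param truth a \linkS4class{BindingTruth}.
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (0 for noiseless).
#' @param seed integer seed.
#' @param iRefBase reference integral scale (a.u.).
#' @return an \linkS4class{STDDataset}; the generating truth is kept in
#'   \code{metadata}.
#' @export
simulateStdDataset <- function(truth, noiseCv = 0.03, seed = 1L,
                               iRefBase = 1000) {
  stopifnot(is(truth, "BindingTruth"))
  validObject(truth)
  .stopif(noiseCv < 0, "noiseCv must be >= 0")
  .stopif(length(truth@ligandConcs) == 0 || length(truth@satTimes) == 0,
          "ligandConcs and satTimes must be non-empty")
  grid <- expand.grid(epitope = names(truth@alphaStd),
                      ligand_conc_uM = truth@ligandConcs,
                      sat_time_s = truth@satTimes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alpha <- truth@alphaStd[grid$epitope]
  ksat <- truth@ksatRef[grid$epitope]
  L <- grid$ligand_conc_uM
  af0 <- alpha * L / (L + truth@kdTrue)        # initial slope (1/s)
  afmax <- af0 / ksat
  af <- afmax * (1 - exp(-ksat * grid$sat_time_s))
  epsilon <- L / truth@proteinConc
  iRef <- rep(iRefBase, nrow(grid))
  iDiff <- af / epsilon * iRef                 # invert AF = eps * Idiff/Iref
  set.seed(.subSeed(seed, "std"))
  iDiff <- iDiff * .lognormalFactors(nrow(grid), noiseCv)
  records <- cbind(grid, i_diff = iDiff, i_ref = iRef)
  STDDataset(records, proteinConc = truth@proteinConc,
             metadata = list(truth = truth, noise_cv = noiseCv, seed = seed))
}

# band amplitude profile over temperature: falling logistic toward
# post_melt_fraction (values > 1 grow on melting)
.bandAmplitude <- function(base, postFrac, tm, slope, temp) {
  base * (postFrac + (1 - postFrac) * (1 - .logisticRise(temp, tm, slope)))
}

#' Simulate an amide-I thermal-ramp spectral series
#'
#' Each temperature's spectrum is the sum of the model's Gaussian sub-bands
#' with amplitudes following logistic melting transitions, plus an
#' aggregation band rising with its own logistic, plus additive Gaussian
#' noise.
#'
#' @param params an \linkS4class{IRGenParams}.
#' @param seed integer seed.
#' @param sample,ligandId,ligandConc series metadata.
#' @return an \linkS4class{IRSpectrumSeries} (absolute-absorbance scale).
#' @export
simulateIRSeries <- function(params, seed = 1L, sample = "synthetic",
                             ligandId = NA_character_, ligandConc = NA_real_) {
  stopifnot(is(params, "IRGenParams"))
  validObject(params)
  wn <- params@wavenumberGrid
  tt <- params@tempGrid
  bt <- params@bandTruth
  agg <- params@aggregateBand
  mat <- matrix(0, nrow = length(wn), ncol = length(tt))
  profiles <- vapply(seq_len(nrow(bt)), function(b)
    .gauss(wn, bt$center[b], bt$width[b]), numeric(length(wn)))
  aggProfile <- .gauss(wn, agg[["center"]], agg[["width"]])
  for (j in seq_along(tt)) {
    amps <- .bandAmplitude(bt$base_amplitude, bt$post_melt_fraction,
                           bt$melt_tm, bt$melt_slope, tt[j])
    aggAmp <- agg[["amplitude"]] *
      .logisticRise(tt[j], agg[["growth_tm"]], agg[["growth_slope"]])
    mat[, j] <- profiles %*% amps + aggAmp * aggProfile
  }
  if (params@noiseSd > 0) {
    set.seed(.subSeed(seed, paste0("ir:", sample)))
    mat <- mat + matrix(rnorm(length(mat), sd = params@noiseSd),
                        nrow = nrow(mat))
  }
  IRSpectrumSeries(wn, tt, mat, sample = sample, ligandId = ligandId,
                   ligandConc = ligandConc)
}
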