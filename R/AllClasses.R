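#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# DSF stage
# ---------------------------------------------------------------------------

#' MeltCurve: one well's fluorescence-vs-temperature trace
#'
#' Container for a single differential scanning fluorimetry (DSF) trace:
#' fluorescence of an environment-sensitive dye recorded along a temperature
#' ramp for one well.
#'
#' @slot wellId well identifier.
#' @slot compoundId compound identifier (or the control label).
#' @slot replicateIndex replicate number within the compound.
#' @slot temperature strictly increasing temperatures (degC).
#' @slot fluorescence fluorescence readings (a.u.), same length as
#'   \code{temperature}.
#' @export
setClass("MeltCurve",
  representation(wellId = "character", compoundId = "character",
                 replicateIndex = "integer",
                 temperature = "numeric", fluorescence = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@temperature) != length(object@fluorescence))
      msg <- c(msg, "temperature and fluorescence lengths differ")
    if (length(object@temperature) >= 2 && any(diff(object@temperature) <= 0))
      msg <- c(msg, "temperature must be strictly increasing")
    if (anyNA(object@temperature) || anyNA(object@fluorescence))
      msg <- c(msg, "NA values not allowed")
    if (length(msg)) msg else TRUE
  })

#' Construct a MeltCurve
#'
#' @param temperature strictly increasing temperatures (degC).
#' @param fluorescence fluorescence values (a.u.).
#' @param wellId,compoundId,replicateIndex identifiers.
#' @return a \linkS4class{MeltCurve}.
#' @export
MeltCurve <- function(temperature, fluorescence, wellId = "W01",
                      compoundId = "compound", replicateIndex = 1L) {
  new("MeltCurve", wellId = as.character(wellId),
      compoundId = as.character(compoundId),
      replicateIndex = as.integer(replicateIndex),
      temperature = as.numeric(temperature),
      fluorescence = as.numeric(fluorescence))
}

#' MeltFit: fitted two-state melt transition for one well
#'
#' Result of the Boltzmann rising-limb fit of a \linkS4class{MeltCurve}:
#' \deqn{F(T) = f_{pre} + (f_{post} - f_{pre}) / (1 + \exp((T_m - T)/s))}
#' together with quality-control flags.
#'
#' @slot tm melting temperature (degC); midpoint of the transition.
#' @slot slope transition steepness scale (degC).
#' @slot fPre,fPost pre- and post-transition plateaus (a.u.).
#' @slot tmSe standard error of \code{tm} from the fit covariance (degC).
#' @slot rSquared coefficient of determination on the fitted window.
#' @slot flags subset of \code{c("biphasic","low_amplitude","poor_fit")}.
#' @slot window fitted temperature window (degC, length 2).
#' @slot wellId,compoundId,replicateIndex identifiers carried from the curve.
#' @export
setClass("MeltFit",
  representation(tm = "numeric", slope = "numeric", fPre = "numeric",
                 fPost = "numeric", tmSe = "numeric", rSquared = "numeric",
                 flags = "character", window = "numeric",
                 wellId = "character", compoundId = "character",
                 replicateIndex = "integer"),
  validity = function(object) {
    ok <- c("biphasic", "low_amplitude", "poor_fit")
    if (!all(object@flags %in% ok))
      return(sprintf("flags must be a subset of {%s}", paste(ok, collapse = ", ")))
    if (length(object@rSquared) == 1 && is.finite(object@rSquared) &&
        object@rSquared > 1 + 1e-8)
      return("rSquared must be <= 1")
    TRUE
  })

#' HitTable: per-compound screen summary and hit calls
#'
#' @slot table data.frame with one row per compound: \code{compound_id},
#'   \code{n_replicates}, \code{mean_tm}, \code{tm_sd}, \code{delta_tm},
#'   \code{hit}, \code{discard_reason}.
#' @slot threshold hit-calling threshold (degC): control mean Tm plus one
#'   standard deviation of the compound mean-Tm distribution.
#' @slot controlMean control mean Tm (degC).
#' @slot tmSd standard deviation of the compound mean-Tm distribution (degC).
#' @slot controlId control compound identifier.
#' @export
setClass("HitTable",
  representation(table = "data.frame", threshold = "numeric",
                 controlMean = "numeric", tmSd = "numeric",
                 controlId = "character"))

# ---------------------------------------------------------------------------
# STD NMR stage
# ---------------------------------------------------------------------------

#' EpitopeRegion: a ligand ppm window receiving saturation transfer
#'
#' @slot label region identifier.
#' @slot ppmLo,ppmHi chemical-shift bounds (ppm), \code{ppmLo < ppmHi}.
#' @export
setClass("EpitopeRegion",
  representation(label = "character", ppmLo = "numeric", ppmHi = "numeric"),
  validity = function(object) {
    if (object@ppmLo >= object@ppmHi) "ppmLo must be < ppmHi" else TRUE
  })

#' @rdname EpitopeRegion-class
#' @param label region identifier.
#' @param ppmLo,ppmHi chemical-shift bounds (ppm).
#' @export
EpitopeRegion <- function(label, ppmLo, ppmHi)
  new("EpitopeRegion", label = as.character(label),
      ppmLo = as.numeric(ppmLo), ppmHi = as.numeric(ppmHi))

#' STDDataset: region integrals of an STD NMR titration
#'
#' Long table of difference and reference integrals per (epitope region,
#' ligand concentration, saturation time), plus the protein concentration
#' needed for the amplification-factor scaling.
#'
#' @slot records data.frame with columns \code{epitope},
#'   \code{ligand_conc_uM}, \code{sat_time_s}, \code{i_diff}, \code{i_ref}.
#' @slot proteinConc total protein concentration (uM).
#' @slot metadata free-form provenance list (e.g. generator truth).
#' @export
setClass("STDDataset",
  representation(records = "data.frame", proteinConc = "numeric",
                 metadata = "list"),
  validity = function(object) {
    need <- c("epitope", "ligand_conc_uM", "sat_time_s", "i_diff", "i_ref")
    miss <- setdiff(need, names(object@records))
    if (length(miss))
      return(sprintf("records missing column(s): %s", paste(miss, collapse = ", ")))
    r <- object@records
    if (nrow(r)) {
      if (any(r$i_ref <= 0)) return("i_ref must be > 0")
      if (any(r$sat_time_s <= 0)) return("sat_time_s must be > 0")
      if (any(r$ligand_conc_uM <= 0)) return("ligand_conc_uM must be > 0")
    }
    if (!.isScalarNum(object@proteinConc) || object@proteinConc <= 0)
      return("proteinConc must be a positive scalar (uM)")
    TRUE
  })

#' @rdname STDDataset-class
#' @param records data.frame of integrals (see slots).
#' @param proteinConc protein concentration (uM).
#' @param metadata provenance list.
#' @export
STDDataset <- function(records, proteinConc, metadata = list())
  new("STDDataset", records = as.data.frame(records),
      proteinConc = as.numeric(proteinConc), metadata = metadata)

#' BuildupFit: saturation-time buildup parameters for one condition
#'
#' Least-squares fit of the STD amplification-factor buildup
#' \deqn{AF(t) = AF_{max} (1 - e^{-k_{sat} t})}
#' for one (epitope, ligand concentration) pair; the initial growth rate
#' \eqn{AF_0 = AF_{max} k_{sat}} is the bias-reduced quantity carried into
#' the Langmuir stage.
#'
#' @slot afMax plateau amplification factor (dimensionless).
#' @slot kSat saturation rate constant (1/s).
#' @slot af0 initial slope \code{afMax * kSat} (1/s).
#' @slot af0Se delta-method standard error of \code{af0} (1/s).
#' @slot cov 2x2 covariance matrix of (afMax, kSat).
#' @slot epitope,ligandConc condition identifiers.
#' @slot converged logical; FALSE when the fallback estimate was used.
#' @export
setClass("BuildupFit",
  representation(afMax = "numeric", kSat = "numeric", af0 = "numeric",
                 af0Se = "numeric", cov = "matrix", epitope = "character",
                 ligandConc = "numeric", converged = "logical"),
  validity = function(object) {
    if (length(object@afMax) && is.finite(object@afMax) && object@afMax < 0)
      return("afMax must be >= 0")
    TRUE
  })

#' LangmuirFit: per-epitope single-site binding isotherm fit
#'
#' Weighted least-squares fit of
#' \deqn{AF_0([L]) = \alpha_{STD} [L] / ([L] + K_d)}
#' for one epitope region.
#'
#' @slot alphaStd saturation amplitude (1/s).
#' @slot kd dissociation constant (uM).
#' @slot kdSe standard error of \code{kd} (uM).
#' @slot alphaSe standard error of \code{alphaStd} (1/s).
#' @slot rss residual sum of squares of the (weighted) fit.
#' @slot epitope region label.
#' @slot flags e.g. \code{"saturated"} when the isotherm is plateau-degenerate,
#'   \code{"narrow_range"} when concentrations span < 2-fold.
#' @export
setClass("LangmuirFit",
  representation(alphaStd = "numeric", kd = "numeric", kdSe = "numeric",
                 alphaSe = "numeric", rss = "numeric", epitope = "character",
                 flags = "character"),
  validity = function(object) {
    if (length(object@kd) && is.finite(object@kd) && object@kd <= 0)
      return("kd must be > 0")
    TRUE
  })

#' KdEstimate: combined dissociation constant across epitopes
#'
#' Inverse-variance weighted mean of the per-epitope Langmuir dissociation
#' constants, with its standard error, plus the per-condition fit objects for
#' provenance.
#'
#' @slot kdCombined weighted-mean Kd (uM).
#' @slot kdCombinedSe standard error of the weighted mean (uM).
#' @slot perEpitope list of \linkS4class{LangmuirFit}.
#' @slot buildups list of \linkS4class{BuildupFit}.
#' @export
setClass("KdEstimate",
  representation(kdCombined = "numeric", kdCombinedSe = "numeric",
                 perEpitope = "list", buildups = "list"),
  validity = function(object) {
    kds <- vapply(object@perEpitope, function(f) f@kd, numeric(1))
    kds <- kds[is.finite(kds)]
    if (length(kds) && is.finite(object@kdCombined) &&
        (object@kdCombined < min(kds) - 1e-8 ||
         object@kdCombined > max(kds) + 1e-8))
      return("kdCombined must lie within the span of per-epitope kd values")
    TRUE
  })

# ---------------------------------------------------------------------------
# MMS stage
# ---------------------------------------------------------------------------

#' IRSpectrumSeries: amide-I absorbance over a thermal ramp
#'
#' A \linkS4class{SummarizedExperiment} whose rows are wavenumbers (cm-1),
#' columns are ramp temperatures (degC), and single assay
#' \code{"absorbance"} holds the (differential or absolute) absorbance
#' matrix. Sample metadata (label, ligand, ligand concentration in uM) live
#' in \code{metadata()}.
#'
#' @export
setClass("IRSpectrumSeries", contains = "SummarizedExperiment",
  validity = function(object) {
    if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
      return("assay 'absorbance' required")
    wn <- SummarizedExperiment::rowData(object)$wavenumber_cm1
    tt <- SummarizedExperiment::colData(object)$temperature_C
    if (is.null(wn) || is.null(tt))
      return("rowData$wavenumber_cm1 and colData$temperature_C required")
    if (length(wn) >= 2 && any(diff(wn) <= 0))
      return("wavenumbers must be strictly increasing")
    if (length(tt) >= 2 && any(diff(tt) <= 0))
      return("temperatures must be strictly increasing")
    TRUE
  })

#' Construct an IRSpectrumSeries
#'
#' @param wavenumbers strictly increasing wavenumbers (cm-1).
#' @param temperatures strictly increasing ramp temperatures (degC).
#' @param absorbance matrix, wavenumber x temperature (a row per wavenumber).
#' @param sample sample label.
#' @param ligandId ligand identifier (or NA).
#' @param ligandConc ligand concentration (uM; NA for apo).
#' @return an \linkS4class{IRSpectrumSeries}.
#' @export
IRSpectrumSeries <- function(wavenumbers, temperatures, absorbance,
                             sample = "sample", ligandId = NA_character_,
                             ligandConc = NA_real_) {
  absorbance <- as.matrix(absorbance)
  stopifnot(nrow(absorbance) == length(wavenumbers),
            ncol(absorbance) == length(temperatures))
  dimnames(absorbance) <- list(format(wavenumbers, trim = TRUE),
                               format(temperatures, trim = TRUE))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(wavenumber_cm1 = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(temperature_C = as.numeric(temperatures)),
    metadata = list(sample = sample, ligand_id = ligandId,
                    ligand_conc_uM = as.numeric(ligandConc)))
  new("IRSpectrumSeries", se)
}

#' SimilaritySpectrum: processed second-derivative amide-I spectrum
#'
#' Inverted, baselined, Savitzky-Golay-smoothed second derivative of an
#' absolute amide-I spectrum; non-negative by construction and fitted by
#' Gaussian band deconvolution.
#'
#' @slot wavenumbers wavenumber grid (cm-1).
#' @slot values processed intensities (>= 0).
#' @export
setClass("SimilaritySpectrum",
  representation(wavenumbers = "numeric", values = "numeric"),
  validity = function(object) {
    if (length(object@wavenumbers) != length(object@values))
      return("wavenumbers and values lengths differ")
    if (any(object@values < -1e-10)) return("values must be non-negative")
    TRUE
  })

#' Structure classes recognized by the amide-I band model
#' @export
HOS_CLASSES <- c("intermolecular_beta", "native_beta", "alpha_helix_cc",
                 "alpha_helix", "turn", "unordered", "side_chain")

#' BandModel: Gaussian sub-band table for amide-I deconvolution
#'
#' @slot bands data.frame with columns \code{label}, \code{class},
#'   \code{center} (cm-1), \code{center_tol} (cm-1), \code{width} (cm-1,
#'   Gaussian sd), \code{width_lo}, \code{width_hi}.
#' @export
setClass("BandModel", representation(bands = "data.frame"),
  validity = function(object) {
    need <- c("label", "class", "center", "center_tol", "width",
              "width_lo", "width_hi")
    miss <- setdiff(need, names(object@bands))
    if (length(miss))
      return(sprintf("bands missing column(s): %s", paste(miss, collapse = ", ")))
    b <- object@bands
    if (!all(b$class %in% HOS_CLASSES))
      return("unknown structure class in band model")
    if (any(b$width <= 0) || any(b$width_lo <= 0) || any(b$width_hi < b$width_lo))
      return("band widths and bounds must be positive with width_hi >= width_lo")
    TRUE
  })

#' @rdname BandModel-class
#' @param bands data.frame of bands (see slots).
#' @export
BandModel <- function(bands) new("BandModel", bands = as.data.frame(bands))

#' HOSComposition: fractional secondary-structure composition of one spectrum
#'
#' @slot fractions named numeric of class fractions over the included
#'   classes (sum to 1).
#' @slot bandTable data.frame with per-band \code{label}, \code{class},
#'   \code{center}, \code{width}, \code{amplitude}, \code{area}.
#' @slot temperature spectrum temperature (degC; NA when unknown).
#' @slot excludedClasses classes excluded from the normalization
#'   (default the side-chain class).
#' @export
setClass("HOSComposition",
  representation(fractions = "numeric", bandTable = "data.frame",
                 temperature = "numeric", excludedClasses = "character"),
  validity = function(object) {
    s <- sum(object@fractions)
    if (length(object@fractions) && abs(s - 1) > 1e-6 && s > 0)
      return("fractions must sum to 1")
    if (any(object@fractions < -1e-9 | object@fractions > 1 + 1e-9))
      return("fractions must lie in [0, 1]")
    TRUE
  })

#' ThermalAnalysis: per-class and global melting temperatures
#'
#' @slot classTm data.frame with \code{class}, \code{tm}, \code{tm_se},
#'   \code{tm_derivative} (derivative-maximum estimate), \code{method},
#'   \code{flagged}.
#' @slot globalTm melting temperature of the whole-spectrum dissimilarity
#'   trace (degC).
#' @slot globalTmSe its standard error (degC).
#' @export
setClass("ThermalAnalysis",
  representation(classTm = "data.frame", globalTm = "numeric",
                 globalTmSe = "numeric"))

#' EC50Fit: saturating ligand-concentration dependence of the global Tm
#'
#' Fit of \eqn{T_m([L]) = T_{m,0} + \Delta T_{m,max} [L]/([L] + EC_{50})}.
#'
#' @slot tm0 apo melting temperature (degC).
#' @slot deltaTmMax maximal stabilization (degC).
#' @slot deltaTmMaxSe its standard error (degC).
#' @slot ec50 half-maximal stabilizing concentration (uM).
#' @slot ec50Se its standard error (uM).
#' @slot flags e.g. \code{"no_stabilization"} when the stabilization
#'   amplitude is not distinguishable from zero.
#' @export
setClass("EC50Fit",
  representation(tm0 = "numeric", deltaTmMax = "numeric",
                 deltaTmMaxSe = "numeric", ec50 = "numeric",
                 ec50Se = "numeric", flags = "character"),
  validity = function(object) {
    if (length(object@ec50) && is.finite(object@ec50) && object@ec50 <= 0)
      return("ec50 must be > 0")
    TRUE
  })

# ---------------------------------------------------------------------------
# Generator parameter objects
# ---------------------------------------------------------------------------

#' DSFGenParams: ground-truth parameters for synthetic melt curves
#'
#' Phenomenological two-state melt with dye dissociation: the noiseless trace
#' rises sigmoidally with midpoint \code{tmTrue} and then decays
#' exponentially beyond \code{decayOnset} back toward the pre-transition
#' baseline, mirroring dye association/dissociation.
#'
#' @slot tmTrue true melting temperature (degC).
#' @slot transitionSlope transition steepness scale (degC).
#' @slot fPre,fPost pre-/post-transition plateaus (a.u.), \code{fPost > fPre}.
#' @slot decayOnset temperature (degC) at which dye dissociation starts.
#' @slot decayRate exponential decay rate (1/degC).
#' @slot noiseSd additive Gaussian noise sd (a.u.).
#' @slot nReplicates number of replicate traces.
#' @slot tempGrid strictly increasing temperature grid (degC).
#' @slot biphasic numeric(0) for monophasic, else \code{c(tm2, slope2, amp2)}
#'   where \code{amp2} is the amplitude fraction of the second transition.
#' @export
setClass("DSFGenParams",
  representation(tmTrue = "numeric", transitionSlope = "numeric",
                 fPre = "numeric", fPost = "numeric", decayOnset = "numeric",
                 decayRate = "numeric", noiseSd = "numeric",
                 nReplicates = "integer", tempGrid = "numeric",
                 biphasic = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@tempGrid) < 2 || any(diff(object@tempGrid) <= 0))
      msg <- c(msg, "tempGrid must be strictly increasing")
    if (object@fPost < object@fPre)
      msg <- c(msg, "fPost must be >= fPre")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@tmTrue < min(object@tempGrid) || object@tmTrue > max(object@tempGrid))
      msg <- c(msg, "tmTrue must lie within tempGrid")
    if (!length(object@biphasic) %in% c(0L, 3L))
      msg <- c(msg, "biphasic must be numeric(0) or c(tm2, slope2, amp2)")
    if (length(msg)) msg else TRUE
  })

#' @rdname DSFGenParams-class
#' @param tmTrue,transitionSlope,fPre,fPost,decayOnset,decayRate,noiseSd,nReplicates,tempGrid,biphasic see slots.
#' @export
dsfGenParams <- function(tmTrue = 53.4, transitionSlope = 1.0,
                         fPre = 1000, fPost = 10000,
                         decayOnset = tmTrue + 12, decayRate = 0.12,
                         noiseSd = 0.01 * (fPost - fPre), nReplicates = 2L,
                         tempGrid = seq(25, 95, by = 0.25),
                         biphasic = numeric(0)) {
  new("DSFGenParams", tmTrue = tmTrue, transitionSlope = transitionSlope,
      fPre = fPre, fPost = fPost, decayOnset = decayOnset,
      decayRate = decayRate, noiseSd = noiseSd,
      nReplicates = as.integer(nReplicates), tempGrid = tempGrid,
      biphasic = as.numeric(biphasic))
}

#' BindingTruth: ground truth for a synthetic STD titration
#'
#' @slot kdTrue true dissociation constant (uM).
#' @slot alphaStd per-epitope saturation amplitudes (named numeric, 1/s).
#' @slot ksatRef per-epitope saturation rate constants (named numeric, 1/s);
#'   held constant across concentrations (initial-slope assumption).
#' @slot proteinConc protein concentration (uM).
#' @slot ligandConcs ligand concentrations (uM).
#' @slot satTimes saturation times (s).
#' @slot regions list of \linkS4class{EpitopeRegion}, one per epitope.
#' @export
setClass("BindingTruth",
  representation(kdTrue = "numeric", alphaStd = "numeric",
                 ksatRef = "numeric", proteinConc = "numeric",
                 ligandConcs = "numeric", satTimes = "numeric",
                 regions = "list"),
  validity = function(object) {
    msg <- character(0)
    if (object@kdTrue <= 0) msg <- c(msg, "kdTrue must be > 0")
    if (any(object@ligandConcs <= 0) || object@proteinConc <= 0)
      msg <- c(msg, "all concentrations must be > 0")
    if (any(object@satTimes <= 0)) msg <- c(msg, "satTimes must be > 0")
    if (length(object@alphaStd) != length(object@ksatRef))
      msg <- c(msg, "alphaStd and ksatRef must have one value per epitope")
    if (length(msg)) msg else TRUE
  })

#' @rdname BindingTruth-class
#' @param kdTrue,alphaStd,ksatRef,proteinConc,ligandConcs,satTimes,regions see slots.
#' @export
bindingTruth <- function(kdTrue, alphaStd, ksatRef, proteinConc = 20,
                         ligandConcs = c(200, 400, 600, 800, 1000),
                         satTimes = c(0.5, 0.75, 1, 1.5, 2, 2.5, 3.5, 5),
                         regions = defaultEpitopeRegions()) {
  if (is.null(names(alphaStd)))
    names(alphaStd) <- vapply(regions, function(r) r@label, character(1))
  if (is.null(names(ksatRef))) names(ksatRef) <- names(alphaStd)
  new("BindingTruth", kdTrue = kdTrue, alphaStd = alphaStd,
      ksatRef = ksatRef, proteinConc = proteinConc,
      ligandConcs = ligandConcs, satTimes = satTimes, regions = regions)
}

#' IRGenParams: ground truth for synthetic amide-I thermal-ramp series
#'
#' Each spectrum is a sum of Gaussian sub-bands whose amplitudes follow
#' falling logistic melting transitions (native structure) plus one
#' aggregation band whose amplitude follows a rising logistic.
#'
#' @slot bandTruth data.frame with \code{center} (cm-1), \code{width} (cm-1,
#'   Gaussian sd), \code{base_amplitude}, \code{structure_class},
#'   \code{melt_tm} (degC), \code{melt_slope} (degC),
#'   \code{post_melt_fraction} (amplitude fraction retained above the melt;
#'   values > 1 describe bands that grow on melting, e.g. unordered).
#' @slot aggregateBand named numeric \code{c(center, width, amplitude,
#'   growth_tm, growth_slope)} for the intermolecular beta-sheet band that
#'   grows as the protein aggregates.
#' @slot wavenumberGrid wavenumber grid (cm-1), default 1588-1712 at 1 cm-1.
#' @slot tempGrid ramp temperatures (degC).
#' @slot noiseSd additive Gaussian noise sd (absorbance a.u.).
#' @export
setClass("IRGenParams",
  representation(bandTruth = "data.frame", aggregateBand = "numeric",
                 wavenumberGrid = "numeric", tempGrid = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    need <- c("center", "width", "base_amplitude", "structure_class",
              "melt_tm", "melt_slope", "post_melt_fraction")
    miss <- setdiff(need, names(object@bandTruth))
    if (length(miss))
      return(sprintf("bandTruth missing column(s): %s", paste(miss, collapse = ", ")))
    if (any(object@bandTruth$width <= 0)) return("band widths must be > 0")
    if (any(object@bandTruth$base_amplitude < 0))
      return("base amplitudes must be >= 0")
    agg <- object@aggregateBand
    need2 <- c("center", "width", "amplitude", "growth_tm", "growth_slope")
    if (!all(need2 %in% names(agg)))
      return("aggregateBand must name center, width, amplitude, growth_tm, growth_slope")
    if (agg[["width"]] <= 0) return("aggregate band width must be > 0")
    if (length(object@wavenumberGrid) < 2 || any(diff(object@wavenumberGrid) <= 0))
      return("wavenumberGrid must be strictly increasing")
    TRUE
  })

#' @rdname IRGenParams-class
#' @param bandTruth,aggregateBand,wavenumberGrid,tempGrid,noiseSd see slots.
#' @export
irGenParams <- function(bandTruth, aggregateBand,
                        wavenumberGrid = seq(1588, 1712, by = 1),
                        tempGrid = seq(25, 75, by = 1), noiseSd = 0) {
  new("IRGenParams", bandTruth = as.data.frame(bandTruth),
      aggregateBand = aggregateBand, wavenumberGrid = wavenumberGrid,
      tempGrid = tempGrid, noiseSd = noiseSd)
}

#' ScreenSpec: design of a synthetic fragment screen
#'
#' Non-hit compounds get a bounded uniform Tm jitter around the control
#' (standard deviation \code{libraryDeltaSd}, support
#' \code{+- sqrt(3) * libraryDeltaSd}); planted hits get a uniform Tm shift
#' drawn from \code{hitDeltaRange}.
#'
#' @slot nCompounds number of library compounds.
#' @slot controlTm control melting temperature (degC).
#' @slot libraryDeltaSd standard deviation of the non-hit Tm jitter (degC).
#' @slot hitFraction proportion of planted hits.
#' @slot hitDeltaRange uniform range of hit Tm shifts (degC, length 2).
#' @slot seed generator seed.
#' @slot nControlWells number of control wells.
#' @export
setClass("ScreenSpec",
  representation(nCompounds = "integer", controlTm = "numeric",
                 libraryDeltaSd = "numeric", hitFraction = "numeric",
                 hitDeltaRange = "numeric", seed = "integer",
                 nControlWells = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@nCompounds < 1) msg <- c(msg, "nCompounds must be >= 1")
    if (object@libraryDeltaSd < 0) msg <- c(msg, "libraryDeltaSd must be >= 0")
    if (object@hitFraction < 0 || object@hitFraction > 1)
      msg <- c(msg, "hitFraction must lie in [0, 1]")
    if (length(object@hitDeltaRange) != 2 ||
        object@hitDeltaRange[1] > object@hitDeltaRange[2])
      msg <- c(msg, "hitDeltaRange must be an increasing length-2 interval")
    if (length(msg)) msg else TRUE
  })

#' @rdname ScreenSpec-class
#' @param nCompounds,controlTm,libraryDeltaSd,hitFraction,hitDeltaRange,seed,nControlWells see slots.
#' @export
screenSpec <- function(nCompounds = 760, controlTm = 53.4,
                       libraryDeltaSd = 2.1 / sqrt(3),
                       hitFraction = 50 / 760,
                       hitDeltaRange = c(3, 12), seed = 1L,
                       nControlWells = 8L) {
  new("ScreenSpec", nCompounds = as.integer(nCompounds), controlTm = controlTm,
      libraryDeltaSd = libraryDeltaSd, hitFraction = hitFraction,
      hitDeltaRange = as.numeric(hitDeltaRange), seed = as.integer(seed),
      nControlWells = as.integer(nControlWells))
}
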