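# Accessor generics and show methods.

#' Melting temperature accessor
#' @param object a fitted object.
#' @param ... unused.
#' @return melting temperature(s) in degC.
#' @export
setGeneric("meltTm", function(object, ...) standardGeneric("meltTm"))

#' Dissociation constant accessor
#' @param object a fitted object.
#' @param ... unused.
#' @return Kd in uM.
#' @export
setGeneric("kd", function(object, ...) standardGeneric("kd"))

#' QC flag accessor
#' @param object a fitted object.
#' @return character vector of flags.
#' @export
setGeneric("qcFlags", function(object) standardGeneric("qcFlags"))

#' Structure-class fraction accessor
#' @param object an object carrying class fractions.
#' @return named numeric of fractions.
#' @export
setGeneric("hosFractions", function(object) standardGeneric("hosFractions"))

#' Hit table accessor
#' @param object a \linkS4class{HitTable}.
#' @return data.frame of per-compound calls.
#' @export
setGeneric("hitCalls", function(object) standardGeneric("hitCalls"))

#' Hit threshold accessor
#' @param object a \linkS4class{HitTable}.
#' @return threshold in degC.
#' @export
setGeneric("hitThreshold", function(object) standardGeneric("hitThreshold"))

#' Wavenumber grid accessor
#' @param object a spectral object.
#' @return wavenumbers in cm-1.
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' Ramp temperature accessor
#' @param object a spectral series.
#' @return temperatures in degC.
#' @export
setGeneric("temperatures", function(object) standardGeneric("temperatures"))

#' Absorbance matrix accessor
#' @param object an \linkS4class{IRSpectrumSeries}.
#' @return matrix (wavenumber x temperature).
#' @export
setGeneric("absorbance", function(object) standardGeneric("absorbance"))

#' @describeIn MeltFit-class melting temperature (degC).
#' @export
setMethod("meltTm", "MeltFit", function(object, ...) object@tm)

#' @describeIn ThermalAnalysis-class named per-class Tm plus \code{global}.
#' @export
setMethod("meltTm", "ThermalAnalysis", function(object, ...) {
  c(setNames(object@classTm$tm, object@classTm$class),
    global = object@globalTm)
})

#' @describeIn LangmuirFit-class Kd (uM).
#' @export
setMethod("kd", "LangmuirFit", function(object, ...) object@kd)

#' @describeIn KdEstimate-class combined Kd (uM).
#' @export
setMethod("kd", "KdEstimate", function(object, ...) object@kdCombined)

#' @describeIn MeltFit-class QC flags.
#' @export
setMethod("qcFlags", "MeltFit", function(object) object@flags)

#' @describeIn HOSComposition-class class fractions.
#' @export
setMethod("hosFractions", "HOSComposition", function(object) object@fractions)

#' @describeIn HitTable-class per-compound calls.
#' @export
setMethod("hitCalls", "HitTable", function(object) object@table)

#' @describeIn HitTable-class threshold (degC).
#' @export
setMethod("hitThreshold", "HitTable", function(object) object@threshold)

#' @describeIn IRSpectrumSeries-class wavenumber grid (cm-1).
#' @export
setMethod("wavenumbers", "IRSpectrumSeries", function(object)
  SummarizedExperiment::rowData(object)$wavenumber_cm1)

#' @describeIn SimilaritySpectrum-class wavenumber grid (cm-1).
#' @export
setMethod("wavenumbers", "SimilaritySpectrum", function(object)
  object@wavenumbers)

#' @describeIn IRSpectrumSeries-class ramp temperatures (degC).
#' @export
setMethod("temperatures", "IRSpectrumSeries", function(object)
  SummarizedExperiment::colData(object)$temperature_C)

#' @describeIn IRSpectrumSeries-class absorbance matrix.
#' @export
setMethod("absorbance", "IRSpectrumSeries", function(object)
  SummarizedExperiment::assay(object, "absorbance"))

setMethod("show", "MeltCurve", function(object) {
  cat(sprintf("MeltCurve %s (%s, rep %d): %d points, %.2f-%.2f degC\n",
              object@wellId, object@compoundId, object@replicateIndex,
              length(object@temperature), min(object@temperature),
              max(object@temperature)))
})

setMethod("show", "MeltFit", function(object) {
  cat(sprintf("MeltFit [%s/%s rep %d]\n", object@compoundId, object@wellId,
              object@replicateIndex))
  if (is.finite(object@tm))
    cat(sprintf("  Tm = %.2f +- %.3f degC (slope %.2f, R2 %.4f)\n",
                object@tm, object@tmSe, object@slope, object@rSquared))
  else cat("  Tm = NA\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "HitTable", function(object) {
  tab <- object@table
  cat(sprintf("HitTable: %d compounds vs control '%s'\n", nrow(tab),
              object@controlId))
  cat(sprintf("  control mean Tm %.2f degC; compound-Tm SD %.2f degC\n",
              object@controlMean, object@tmSd))
  cat(sprintf("  threshold %.2f degC -> %d hits, %d discarded\n",
              object@threshold, sum(tab$hit),
              sum(!is.na(tab$discard_reason))))
})

setMethod("show", "STDDataset", function(object) {
  r <- object@records
  cat(sprintf(paste0("STDDataset: %d records (%d epitopes x %d ligand concs",
                     " x %d sat times), [P] = %g uM\n"),
              nrow(r), length(unique(r$epitope)),
              length(unique(r$ligand_conc_uM)),
              length(unique(r$sat_time_s)), object@proteinConc))
})

setMethod("show", "BuildupFit", function(object) {
  cat(sprintf("BuildupFit [%s, %g uM]: AFmax %.4g, ksat %.4g /s, AF0 %.4g +- %.2g /s\n",
              object@epitope, object@ligandConc, object@afMax, object@kSat,
              object@af0, object@af0Se))
})

setMethod("show", "LangmuirFit", function(object) {
  cat(sprintf("LangmuirFit [%s]: Kd %.1f +- %.1f uM, alphaSTD %.4g /s%s\n",
              object@epitope, object@kd, object@kdSe, object@alphaStd,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})

setMethod("show", "KdEstimate", function(object) {
  cat(sprintf("KdEstimate: Kd = %.1f +- %.1f uM (weighted over %d epitopes)\n",
              object@kdCombined, object@kdCombinedSe,
              length(object@perEpitope)))
  for (f in object@perEpitope)
    cat(sprintf("  %s: %.1f +- %.1f uM\n", f@epitope, f@kd, f@kdSe))
})

setMethod("show", "IRSpectrumSeries", function(object) {
  cat(sprintf("IRSpectrumSeries '%s': %d wavenumbers (%g-%g cm-1) x %d temperatures (%g-%g degC)\n",
              S4Vectors::metadata(object)$sample, nrow(object),
              min(wavenumbers(object)), max(wavenumbers(object)),
              ncol(object), min(temperatures(object)),
              max(temperatures(object))))
})

setMethod("show", "HOSComposition", function(object) {
  cat(sprintf("HOSComposition (T = %g degC):\n", object@temperature))
  f <- object@fractions
  for (k in names(f)) cat(sprintf("  %-19s %6.3f\n", k, f[[k]]))
})

setMethod("show", "ThermalAnalysis", function(object) {
  cat("ThermalAnalysis:\n")
  tab <- object@classTm
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-19s Tm %6.2f degC (%s)%s\n", tab$class[i], tab$tm[i],
                tab$method[i], if (tab$flagged[i]) " [flagged]" else ""))
  cat(sprintf("  %-19s Tm %6.2f degC\n", "global", object@globalTm))
})

setMethod("show", "EC50Fit", function(object) {
  cat(sprintf("EC50Fit: Tm0 %.2f degC, dTmMax %.2f degC, EC50 %.0f +- %.0f uM%s\n",
              object@tm0, object@deltaTmMax, object@ec50, object@ec50Se,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})
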