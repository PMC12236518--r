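# DSF melt-curve fitting and hit calling.
#
# The two-state transition is fitted with the Boltzmann sigmoid
#   F(T) = f_pre + (f_post - f_pre) / (1 + exp((Tm - T)/s))
# on the rising limb only (trace start to the global fluorescence maximum):
# past the peak the dye dissociates and the model no longer applies.

#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

# rising-limb window: trace start to the global maximum (smoothed to be
# robust against picking a noise spike)
.risingWindow <- function(curve, smoothWindow = 5L) {
  sm <- .movavg(curve@fluorescence, smoothWindow)
  iMax <- which.max(sm)
  seq_len(max(iMax, 2L))
}

# derivative-maximum Tm over the rising limb (fallback and oracle path)
.derivativeTm <- function(temp, fluo, smoothWindow = 5L) {
  d <- diff(.movavg(fluo, smoothWindow)) / diff(temp)
  mid <- (temp[-1] + temp[-length(temp)]) / 2
  i <- which.max(d)
  .refineArgmax(mid, d, i)
}

#' Fit a Boltzmann melt transition to one DSF trace
#'
#' Least-squares fit of the two-state Boltzmann sigmoid on the rising limb
#' (trace start to global fluorescence maximum). Non-convergent fits fall
#' back to the derivative-maximum Tm and are flagged \code{poor_fit};
#' transitions smaller than \code{minAmplitudeFrac} of the observed signal
#' range scale are flagged \code{low_amplitude} (no Tm reported); biphasic
#' traces are flagged via \code{\link{detectBiphasic}}.
#'
#' @param curve a \linkS4class{MeltCurve}.
#' @param windowStrategy \code{"rising"} (start to global maximum; default)
#'   or \code{"full"} (entire trace; for traces without dye dissociation).
#' @param minAmplitudeFrac minimum fitted amplitude as a fraction of the
#'   trace's overall level (max fluorescence), below which the well is
#'   flagged \code{low_amplitude}.
#' @param prominenceFrac passed to \code{\link{detectBiphasic}}.
#' @return a \linkS4class{MeltFit}.
#' @examples
#' curve <- simulateMeltCurves(dsfFixture("control", noiseSd = 0), 1)[[1]]
#' fitMeltCurve(curve)
#' @export
fitMeltCurve <- function(curve, windowStrategy = c("rising", "full"),
                         minAmplitudeFrac = 0.05, prominenceFrac = 0.2) {
  stopifnot(is(curve, "MeltCurve"))
  validObject(curve)
  windowStrategy <- match.arg(windowStrategy)
  idx <- if (windowStrategy == "rising") .risingWindow(curve)
         else seq_along(curve@temperature)
  tt <- curve@temperature[idx]
  ff <- curve@fluorescence[idx]

  mk <- function(tm, slope, fPre, fPost, tmSe, r2, flags, conv = TRUE)
    new("MeltFit", tm = tm, slope = slope, fPre = fPre, fPost = fPost,
        tmSe = tmSe, rSquared = r2, flags = flags,
        window = range(tt), wellId = curve@wellId,
        compoundId = curve@compoundId,
        replicateIndex = curve@replicateIndex)

  # amplitude gate on the full trace, before any window-size requirement:
  # a flat well has no transition to fit at all
  scaleRef <- max(abs(curve@fluorescence))
  if (scaleRef <= 0) scaleRef <- 1
  if (diff(range(curve@fluorescence)) < minAmplitudeFrac * scaleRef) {
    m <- mean(curve@fluorescence)
    return(mk(NA_real_, NA_real_, m, m, NA_real_, NA_real_, "low_amplitude"))
  }
  .stopif(length(idx) < 10L,
          "need >= 10 points on the rising limb to fit a melt transition")

  flags <- character(0)
  if (detectBiphasic(curve, prominenceFrac = prominenceFrac))
    flags <- c(flags, "biphasic")

  tm0 <- .derivativeTm(tt, ff)
  start <- list(tm = tm0, slope = 1, fPre = min(ff), fPost = max(ff))
  fit <- tryCatch(
    nlsLM(ff ~ fPre + (fPost - fPre) / (1 + exp((tm - tt) / slope)),
          start = start,
          lower = c(tm = min(tt), slope = 1e-3, fPre = -Inf, fPost = -Inf),
          upper = c(tm = max(tt), slope = diff(range(tt)), fPre = Inf,
                    fPost = Inf),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(mk(tm0, NA_real_, min(ff), max(ff), NA_real_, NA_real_,
              c(flags, "poor_fit"), conv = FALSE))
  }
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  r2 <- 1 - sum(residuals(fit)^2) / sum((ff - mean(ff))^2)
  fitAmp <- abs(cf[["fPost"]] - cf[["fPre"]])
  flags2 <- flags
  if (fitAmp < minAmplitudeFrac * scaleRef)
    flags2 <- c(flags2, "low_amplitude")
  mk(cf[["tm"]], cf[["slope"]], cf[["fPre"]], cf[["fPost"]],
     sqrt(vc["tm", "tm"]), r2, flags2)
}

#' Detect biphasic melt transitions
#'
#' A trace is biphasic when the smoothed first derivative of its rising
#' region has two or more local maxima, each taller than
#' \code{prominenceFrac} of the largest.
#'
#' @param curve a \linkS4class{MeltCurve}.
#' @param prominenceFrac relative height threshold for counting a second
#'   derivative peak.
#' @param smoothWindow moving-average window (grid points) applied before
#'   differentiation.
#' @return logical.
#' @export
detectBiphasic <- function(curve, prominenceFrac = 0.2, smoothWindow = 5L) {
  stopifnot(is(curve, "MeltCurve"))
  idx <- .risingWindow(curve, smoothWindow)
  if (length(idx) < smoothWindow + 2L) return(FALSE)
  tt <- curve@temperature[idx]
  ff <- .movavg(curve@fluorescence[idx], smoothWindow)
  d <- diff(ff) / diff(tt)
  d <- .movavg(d, smoothWindow)
  if (max(d) <= 0) return(FALSE)     # flat or falling: no transition at all
  peaks <- .localMaxima(d)
  # ignore ripples: a counted peak must also rise clearly above the noise
  # floor of the derivative
  peaks <- peaks[d[peaks] > prominenceFrac * max(d)]
  # merge maxima closer than the smoothing window (same transition)
  if (length(peaks) >= 2L) {
    keep <- c(TRUE, diff(tt[peaks]) > smoothWindow * mean(diff(tt)))
    peaks <- peaks[keep]
  }
  length(peaks) >= 2L
}

#' Call screen hits against a control
#'
#' Groups per-well fits by compound, averages Tm over usable replicates,
#' discards compounds with irreproducible replicates
#' (|replicate Tm spread| > \code{reproducibilityTol}) or any
#' biphasic/poor-fit replicate, and calls a hit when the compound mean Tm
#' strictly exceeds \emph{control mean Tm + 1 standard deviation of the
#' compound mean-Tm distribution}.
#'
#' @param fits list of \linkS4class{MeltFit} (all wells, control included).
#' @param controlId compound id of the control wells.
#' @param reproducibilityTol maximum allowed replicate Tm spread (degC).
#' @return a \linkS4class{HitTable}.
#' @export
callHits <- function(fits, controlId = "DMSO", reproducibilityTol = 2) {
  stopifnot(length(fits) > 0, all(vapply(fits, is, logical(1), "MeltFit")))
  df <- data.frame(
    compound_id = vapply(fits, function(f) f@compoundId, character(1)),
    tm = vapply(fits, function(f) f@tm, numeric(1)),
    biphasic = vapply(fits, function(f) "biphasic" %in% f@flags, logical(1)),
    poor = vapply(fits, function(f) "poor_fit" %in% f@flags, logical(1)),
    lowamp = vapply(fits, function(f) "low_amplitude" %in% f@flags, logical(1)),
    stringsAsFactors = FALSE)
  .stopif(!any(df$compound_id == controlId),
          sprintf("no control wells with compound id '%s'", controlId))

  perCompound <- function(sub) {
    usable <- is.finite(sub$tm) & !sub$lowamp
    reason <- NA_character_
    if (any(sub$biphasic)) reason <- "biphasic"
    else if (any(sub$poor) || !any(usable)) reason <- "poor_fit"
    else if (sum(usable) >= 2 &&
             diff(range(sub$tm[usable])) > reproducibilityTol)
      reason <- "irreproducible"
    data.frame(
      n_replicates = nrow(sub),
      mean_tm = if (any(usable)) mean(sub$tm[usable]) else NA_real_,
      tm_sd = if (sum(usable) >= 2) sd(sub$tm[usable]) else NA_real_,
      discard_reason = reason, stringsAsFactors = FALSE)
  }
  split_ <- split(df, df$compound_id)
  summ <- do.call(rbind, lapply(split_, perCompound))
  summ$compound_id <- names(split_)

  ctrl <- summ[summ$compound_id == controlId, ]
  .stopif(!is.finite(ctrl$mean_tm), "control wells yielded no usable Tm")
  comp <- summ[summ$compound_id != controlId, , drop = FALSE]
  # spread of the compound mean-Tm distribution across the screen (hits
  # included): this is the SD the threshold is built from
  tmSd <- sd(comp$mean_tm[is.finite(comp$mean_tm)])
  if (!is.finite(tmSd)) tmSd <- 0
  threshold <- ctrl$mean_tm + tmSd

  comp$delta_tm <- comp$mean_tm - ctrl$mean_tm
  comp$hit <- !is.na(comp$mean_tm) & comp$mean_tm > threshold &
    is.na(comp$discard_reason)
  comp <- comp[order(comp$compound_id),
               c("compound_id", "n_replicates", "mean_tm", "tm_sd",
                 "delta_tm", "hit", "discard_reason")]
  rownames(comp) <- NULL
  new("HitTable", table = comp, threshold = threshold,
      controlMean = ctrl$mean_tm, tmSd = tmSd, controlId = controlId)
}

#' Fit every curve of a screen
#'
#' Convenience wrapper mapping \code{\link{fitMeltCurve}} over a list of
#' curves.
#'
#' @param curves list of \linkS4class{MeltCurve}.
#' @param ... passed to \code{\link{fitMeltCurve}}.
#' @return list of \linkS4class{MeltFit}.
#' @export
fitScreen <- function(curves, ...) lapply(curves, fitMeltCurve, ...)
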