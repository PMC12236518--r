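# STD NMR analysis: region integration, amplification factors, buildup and
# Langmuir fits, and the combined dissociation constant.
#
# The chain is: per (epitope, [L]) the amplification factor
#   STD-AF(t) = eps * Idiff/Iref,  eps = [L]/[P]
# is fitted over saturation time to AF(t) = AFmax (1 - exp(-ksat t)); the
# initial growth rate AF0 = AFmax * ksat removes rebinding/relaxation bias;
# AF0 vs [L] is fitted to the Langmuir isotherm
#   AF0([L]) = alphaSTD [L] / ([L] + Kd)
# and the per-epitope Kd values are combined by inverse-variance weighting.

#' Integrate a ppm region of a 1D spectrum
#'
#' Trapezoidal integral of the absolute intensity over an epitope region, on
#' the spectrum's native ppm grid.
#'
#' @param spectrum data.frame (or list) with \code{ppm} and
#'   \code{intensity}; ppm may run in either direction.
#' @param region an \linkS4class{EpitopeRegion}.
#' @return integral (a.u. x ppm).
#' @export
integrateRegion <- function(spectrum, region) {
  stopifnot(is(region, "EpitopeRegion"))
  ppm <- as.numeric(spectrum$ppm)
  y <- abs(as.numeric(spectrum$intensity))
  o <- order(ppm)
  ppm <- ppm[o]; y <- y[o]
  .stopif(region@ppmLo < min(ppm) || region@ppmHi > max(ppm),
          sprintf("region [%g, %g] ppm outside the spectral width [%g, %g]",
                  region@ppmLo, region@ppmHi, min(ppm), max(ppm)))
  keep <- ppm >= region@ppmLo & ppm <= region@ppmHi
  # include the exact boundaries by linear interpolation so the integral is
  # over [ppm_lo, ppm_hi] rather than the nearest grid points
  xs <- unique(sort(c(region@ppmLo, ppm[keep], region@ppmHi)))
  ys <- approx(ppm, y, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' STD amplification factor
#'
#' \eqn{AF = \epsilon \cdot I_{diff}/I_{ref}} with
#' \eqn{\epsilon = [L]_{total}/[P]_{total}}, proportional to the bound
#' protein fraction.
#'
#' @param iDiff difference-spectrum integral (a.u.).
#' @param iRef reference integral (a.u.), > 0.
#' @param ligandConc total ligand concentration (uM).
#' @param proteinConc total protein concentration (uM), > 0.
#' @return dimensionless amplification factor (vectorized).
#' @examples
#' computeStdAf(iDiff = 10, iRef = 1000, ligandConc = 1000, proteinConc = 20)
#' @export
computeStdAf <- function(iDiff, iRef, ligandConc, proteinConc) {
  .stopif(any(iRef <= 0), "i_ref must be > 0")
  .stopif(any(proteinConc <= 0), "protein concentration must be > 0")
  (ligandConc / proteinConc) * (iDiff / iRef)
}

#' Fit an STD buildup curve
#'
#' Least squares of \eqn{AF(t) = AF_{max}(1 - e^{-k_{sat} t})} over
#' saturation time for one (epitope, ligand concentration) condition. The
#' initial growth rate \eqn{AF_0 = AF_{max} k_{sat}} gets its standard error
#' by the delta method from the fit covariance.
#'
#' @param satTime saturation times (s), >= 3 distinct values.
#' @param stdAf amplification factors.
#' @param epitope,ligandConc condition labels carried into the result.
#' @return a \linkS4class{BuildupFit}.
#' @export
fitBuildup <- function(satTime, stdAf, epitope = "region",
                       ligandConc = NA_real_) {
  .stopif(length(satTime) != length(stdAf), "satTime/stdAf length mismatch")
  .stopif(length(unique(satTime)) < 3, "need >= 3 distinct saturation times")
  .stopif(any(satTime <= 0), "saturation times must be > 0")

  if (all(abs(stdAf) < .Machine$double.eps^0.5)) {
    return(new("BuildupFit", afMax = 0, kSat = NA_real_, af0 = 0,
               af0Se = 0, cov = matrix(NA_real_, 2, 2), epitope = epitope,
               ligandConc = ligandConc, converged = TRUE))
  }
  # crude initial slope from the earliest points
  o <- order(satTime)
  slope0 <- stdAf[o][1] / satTime[o][1]
  .stopif(slope0 < 0 && mean(stdAf) < 0,
          "negative initial-slope data: buildup model does not apply")
  af0max <- max(stdAf)
  start <- list(afMax = max(af0max, 1e-6), kSat = max(slope0 / max(af0max, 1e-6), 0.1))
  fit <- tryCatch(
    nlsLM(stdAf ~ afMax * (1 - exp(-kSat * satTime)), start = start,
          lower = c(afMax = 0, kSat = 1e-6),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) e)
  .stopif(inherits(fit, "error"),
          paste0("buildup fit failed to converge: ", conditionMessage(fit)))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(vc) <- list(names(cf), names(cf))
  af0 <- cf[["afMax"]] * cf[["kSat"]]
  grad <- c(cf[["kSat"]], cf[["afMax"]])          # d(af0)/d(afMax, kSat)
  af0Se <- sqrt(max(0, drop(t(grad) %*% vc %*% grad)))
  new("BuildupFit", afMax = cf[["afMax"]], kSat = cf[["kSat"]], af0 = af0,
      af0Se = af0Se, cov = vc, epitope = epitope,
      ligandConc = as.numeric(ligandConc), converged = TRUE)
}

#' Fit a Langmuir binding isotherm to initial growth rates
#'
#' (Weighted) least squares of
#' \eqn{AF_0([L]) = \alpha_{STD}[L]/([L] + K_d)}; weights are
#' \eqn{1/se^2} when standard errors are supplied. Initialized at
#' \eqn{\alpha_{STD} = \max(AF_0)}, \eqn{K_d} = median concentration;
#' \eqn{K_d} bounded in \eqn{(0, 100 \max[L]]}.
#'
#' @param ligandConc ligand concentrations (uM), >= 3 distinct values.
#' @param af0 initial growth rates (1/s).
#' @param af0Se optional standard errors of \code{af0}. When given, the
#'   weights are treated as known variances and the parameter covariance is
#'   left unscaled by the residual variance (with only a few concentrations
#'   the estimated residual variance is so noisy that rescaling
#'   systematically understates the Kd uncertainty).
#' @param epitope label carried into the result.
#' @return a \linkS4class{LangmuirFit}; plateau-degenerate data (no
#'   concentration dependence) are flagged \code{"saturated"} with Kd pinned
#'   at the lower bound, and concentration ranges under 2-fold are flagged
#'   \code{"narrow_range"} with a warning.
#' @export
fitLangmuir <- function(ligandConc, af0, af0Se = NULL, epitope = "region") {
  .stopif(length(unique(ligandConc)) < 3, "need >= 3 distinct concentrations")
  flags <- character(0)
  if (max(ligandConc) / min(ligandConc) < 2) {
    warning("ligand concentrations span < 2-fold; Kd poorly constrained")
    flags <- c(flags, "narrow_range")
  }
  knownWeights <- FALSE
  w <- if (!is.null(af0Se)) {
    .stopif(any(af0Se < 0), "af0Se must be >= 0")
    se <- ifelse(is.finite(af0Se) & af0Se > 0, af0Se, NA)
    if (all(is.na(se))) rep(1, length(af0)) else {
      se[is.na(se)] <- min(se, na.rm = TRUE)
      knownWeights <- TRUE
      1 / se^2
    }
  } else rep(1, length(af0))

  kdLo <- 1e-6 * max(ligandConc)
  start <- list(alphaStd = max(af0), kdPar = median(ligandConc))
  fit <- tryCatch(
    nlsLM(af0 ~ alphaStd * ligandConc / (ligandConc + kdPar),
          start = start, weights = w,
          lower = c(alphaStd = 0, kdPar = kdLo),
          upper = c(alphaStd = Inf, kdPar = 100 * max(ligandConc)),
          control = nls.lm.control(maxiter = 500)),
    error = function(e) e)
  .stopif(inherits(fit, "error"),
          paste0("Langmuir fit failed to converge: ", conditionMessage(fit)))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  dimnames(vc) <- list(names(cf), names(cf))
  if (knownWeights) {
    # undo the residual-variance rescaling: weights are known 1/se^2
    sig2 <- summary(fit)$sigma^2
    if (is.finite(sig2) && sig2 > 0) vc <- vc / sig2
  }
  kdHat <- cf[["kdPar"]]
  if (kdHat <= kdLo * (1 + 1e-6)) flags <- c(flags, "saturated")
  new("LangmuirFit", alphaStd = cf[["alphaStd"]], kd = kdHat,
      kdSe = sqrt(vc["kdPar", "kdPar"]),
      alphaSe = sqrt(vc["alphaStd", "alphaStd"]),
      rss = sum(residuals(fit)^2), epitope = epitope, flags = flags)
}

#' Combine per-epitope dissociation constants
#'
#' Inverse-variance weighted mean of the per-epitope Kd values; the combined
#' standard error is \eqn{\sqrt{1/\sum 1/se^2}}. Fits without a finite
#' standard error are excluded from the weighting; if none has one, the
#' unweighted mean is returned with a warning.
#'
#' @param fits list of \linkS4class{LangmuirFit}.
#' @param buildups optional list of \linkS4class{BuildupFit} for provenance.
#' @return a \linkS4class{KdEstimate}.
#' @export
combineKd <- function(fits, buildups = list()) {
  stopifnot(length(fits) >= 1, all(vapply(fits, is, logical(1), "LangmuirFit")))
  kds <- vapply(fits, function(f) f@kd, numeric(1))
  ses <- vapply(fits, function(f) f@kdSe, numeric(1))
  usable <- is.finite(kds) & is.finite(ses) & ses > 0
  if (any(usable)) {
    w <- 1 / ses[usable]^2
    kdC <- sum(w * kds[usable]) / sum(w)
    seC <- sqrt(1 / sum(w))
  } else {
    warning("no finite Kd standard errors; returning unweighted mean")
    kdC <- mean(kds[is.finite(kds)])
    seC <- NA_real_
  }
  new("KdEstimate", kdCombined = kdC, kdCombinedSe = seC,
      perEpitope = fits, buildups = buildups)
}

#' Run the full STD pipeline on a titration dataset
#'
#' Per (epitope, concentration): amplification factors and a buildup fit;
#' per epitope: a weighted Langmuir fit of the initial growth rates; then
#' the inverse-variance combined Kd. Epitopes whose buildup fits all fail
#' are dropped with a warning.
#'
#' @param dataset an \linkS4class{STDDataset} spanning >= 3 concentrations
#'   and >= 3 saturation times per epitope.
#' @return a \linkS4class{KdEstimate} carrying all per-condition fits.
#' @export
runStdPipeline <- function(dataset) {
  stopifnot(is(dataset, "STDDataset"))
  validObject(dataset)
  rec <- dataset@records
  rec$std_af <- computeStdAf(rec$i_diff, rec$i_ref, rec$ligand_conc_uM,
                             dataset@proteinConc)
  buildups <- list()
  langmuirs <- list()
  for (ep in unique(rec$epitope)) {
    sub <- rec[rec$epitope == ep, ]
    concs <- sort(unique(sub$ligand_conc_uM))
    .stopif(length(concs) < 3,
            sprintf("epitope %s: need >= 3 ligand concentrations", ep))
    fits <- list()
    for (L in concs) {
      pts <- sub[sub$ligand_conc_uM == L, ]
      f <- tryCatch(fitBuildup(pts$sat_time_s, pts$std_af, epitope = ep,
                               ligandConc = L),
                    error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
    if (!length(fits)) {
      warning(sprintf("epitope %s: all buildup fits failed; dropped", ep))
      next
    }
    buildups <- c(buildups, fits)
    lf <- fitLangmuir(vapply(fits, function(f) f@ligandConc, numeric(1)),
                      vapply(fits, function(f) f@af0, numeric(1)),
                      vapply(fits, function(f) f@af0Se, numeric(1)),
                      epitope = ep)
    langmuirs[[length(langmuirs) + 1L]] <- lf
  }
  .stopif(!length(langmuirs), "no epitope produced a Langmuir fit")
  combineKd(langmuirs, buildups = buildups)
}
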