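# MMS amide-I processing: similarity spectra, Gaussian band deconvolution
# into higher-order-structure (HOS) fractions, per-structure and global
# melting temperatures, and the EC50 of ligand-driven thermal stabilization.

#' Rescale differential absorbance to the absolute scale
#'
#' Scalar normalization of modulated differential absorbance by the nominal
#' displacement factor (default 0.63). Downstream fractional compositions
#' are invariant to this factor; it only sets the absolute absorbance scale.
#'
#' @param differential numeric vector/matrix of differential absorbance, or
#'   an \linkS4class{IRSpectrumSeries}.
#' @param displacementFactor positive scalar, default 0.63.
#' @return same shape as the input, on the absolute scale.
#' @export
normalizeSpectrum <- function(differential, displacementFactor = 0.63) {
  .stopif(!.isScalarNum(displacementFactor) || displacementFactor <= 0,
          "displacementFactor must be a positive scalar")
  if (is(differential, "IRSpectrumSeries")) {
    out <- differential
    SummarizedExperiment::assay(out, "absorbance") <-
      absorbance(differential) / displacementFactor
    return(out)
  }
  differential / displacementFactor
}

#' Compute a similarity spectrum
#'
#' Savitzky-Golay second derivative of an absolute amide-I spectrum,
#' inverted (negated), linearly baselined through the end-region minima and
#' floored at zero. Band maxima of the input reappear as sharpened positive
#' peaks at the same centers.
#'
#' @param absolute absolute absorbance values on \code{wavenumbers}.
#' @param wavenumbers uniform wavenumber grid (cm-1).
#' @param sgWindow odd Savitzky-Golay window length (wavenumber points),
#'   default 19.
#' @param sgOrder Savitzky-Golay polynomial order, default 3.
#' @param baselineEdge number of points at each spectral edge searched for
#'   the baseline anchor minima.
#' @return a \linkS4class{SimilaritySpectrum}.
#' @export
similaritySpectrum <- function(absolute, wavenumbers, sgWindow = 19L,
                               sgOrder = 3L, baselineEdge = 10L) {
  .stopif(sgWindow %% 2 == 0, "sgWindow must be odd")
  .stopif(sgWindow > length(absolute), "sgWindow exceeds the grid length")
  .stopif(sgOrder >= sgWindow, "sgOrder must be < sgWindow")
  .checkStrictlyIncreasing(wavenumbers, "wavenumbers")
  dx <- mean(diff(wavenumbers))
  d2 <- signal::sgolayfilt(absolute, p = sgOrder, n = sgWindow, m = 2,
                           ts = dx)
  v <- -d2
  # linear baseline through the minimum of each end region, then floor at 0
  n <- length(v)
  k <- min(baselineEdge, n %/% 2)
  iL <- which.min(v[seq_len(k)])
  iR <- n - k + which.min(v[seq(n - k + 1L, n)])
  xL <- wavenumbers[iL]; xR <- wavenumbers[iR]
  slope <- (v[iR] - v[iL]) / (xR - xL)
  base <- v[iL] + slope * (wavenumbers - xL)
  new("SimilaritySpectrum", wavenumbers = as.numeric(wavenumbers),
      values = pmax(0, v - base))
}

# Gaussian design matrix for a band table at given widths
.bandDesign <- function(wn, centers, widths)
  vapply(seq_along(centers), function(b) .gauss(wn, centers[b], widths[b]),
         numeric(length(wn)))

#' Deconvolve a similarity spectrum into Gaussian sub-bands
#'
#' Non-negative least-squares fit of band amplitudes on a Gaussian design.
#' Band widths are profiled through a single shared scale factor (each
#' band's width clamped to its bounds) chosen by 1-D optimization of the
#' residual sum of squares; with \code{refine = TRUE} a bounded
#' Levenberg-Marquardt polish then lets each center move within
#' \code{center_tol} and each width within its bounds (falling back to the
#' profiled solution if it fails). Class fractions are band-area sums over
#' the total fitted area, excluding \code{excludeClasses} (side chains by
#' default, so the reported fractions are secondary-structure fractions).
#'
#' @param sim a \linkS4class{SimilaritySpectrum} (or numeric values with
#'   \code{wavenumbers} supplied).
#' @param model a \linkS4class{BandModel}.
#' @param wavenumbers required when \code{sim} is a bare numeric vector.
#' @param excludeClasses classes left out of the fraction normalization.
#' @param widthScaleRange search interval for the shared width scale.
#' @param widths optional fixed per-band widths (cm-1); skips the width
#'   profiling (used by \code{\link{runMmsPipeline}}, which estimates one
#'   width per band jointly across the whole ramp).
#' @param refine logical; polish the band widths (and, when
#'   \code{refineCenters = TRUE}, the centers within \code{center_tol}) by
#'   bounded nonlinear least squares.
#' @param refineCenters logical; also let centers move. Off by default:
#'   center freedom makes the heavily overlapped amide-I design nearly
#'   degenerate.
#' @param temperature optional temperature tag (degC).
#' @return an \linkS4class{HOSComposition}.
#' @export
deconvolveBands <- function(sim, model, wavenumbers = NULL,
                            excludeClasses = "side_chain",
                            widthScaleRange = c(0.3, 2), widths = NULL,
                            refine = FALSE, refineCenters = FALSE,
                            temperature = NA_real_) {
  stopifnot(is(model, "BandModel"))
  validObject(model)
  if (is(sim, "SimilaritySpectrum")) {
    wn <- sim@wavenumbers; y <- sim@values
  } else {
    .stopif(is.null(wavenumbers), "wavenumbers required for bare input")
    wn <- wavenumbers; y <- as.numeric(sim)
  }
  b <- model@bands
  dup <- duplicated(b[, c("center", "width")])
  if (any(dup)) {
    warning("duplicate bands collapsed before deconvolution")
    b <- b[!dup, , drop = FALSE]
  }

  if (is.null(widths)) {
    clampW <- function(s) pmin(pmax(b$width * s, b$width_lo), b$width_hi)
    sse <- function(s) {
      G <- .bandDesign(wn, b$center, clampW(s))
      fit <- pracma::lsqnonneg(G, y)
      sum((y - G %*% fit$x)^2)
    }
    opt <- optimize(sse, interval = widthScaleRange, tol = 1e-5)
    widths <- clampW(opt$minimum)
  } else {
    .stopif(length(widths) != nrow(b), "widths must have one value per band")
  }
  G <- .bandDesign(wn, b$center, widths)
  amps <- pracma::lsqnonneg(G, y)$x
  centers <- b$center

  if (refine) {
    nb <- nrow(b)
    # variable projection: nonlinear shape parameters outer, NNLS amplitudes
    # inner, so every evaluation is optimal in the amplitudes
    if (refineCenters) {
      p0 <- c(centers, widths)
      shape <- function(p) list(centers = p[seq_len(nb)],
                                widths = p[nb + seq_len(nb)])
      lower <- c(b$center - b$center_tol, b$width_lo)
      upper <- c(b$center + b$center_tol, b$width_hi)
    } else {
      p0 <- widths
      shape <- function(p) list(centers = b$center, widths = p)
      lower <- b$width_lo
      upper <- b$width_hi
    }
    innerAmps <- function(p) {
      sp <- shape(p)
      pracma::lsqnonneg(.bandDesign(wn, sp$centers, sp$widths), y)$x
    }
    resFun <- function(p) {
      sp <- shape(p)
      Gp <- .bandDesign(wn, sp$centers, sp$widths)
      y - drop(Gp %*% pracma::lsqnonneg(Gp, y)$x)
    }
    ref <- tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resFun, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (!is.null(ref) && sum(ref$fvec^2) <= sum((y - G %*% amps)^2)) {
      sp <- shape(ref$par)
      centers <- sp$centers
      widths <- sp$widths
      amps <- innerAmps(ref$par)
    }
  }

  area <- amps * widths * sqrt(2 * pi)
  bandTable <- data.frame(label = b$label, class = b$class,
                          center = centers, width = widths,
                          amplitude = amps, area = area,
                          stringsAsFactors = FALSE)
  keep <- !(bandTable$class %in% excludeClasses)
  classes <- setdiff(unique(b$class), excludeClasses)
  classArea <- vapply(classes, function(k)
    sum(area[keep & bandTable$class == k]), numeric(1))
  tot <- sum(classArea)
  fractions <- if (tot > 0) classArea / tot else classArea * 0
  new("HOSComposition", fractions = fractions, bandTable = bandTable,
      temperature = as.numeric(temperature),
      excludedClasses = as.character(excludeClasses))
}

# windowed logistic fit of a melting profile; returns c(tm, se) or NULL.
# `tmDeriv` anchors the window at the dominant-transition temperature.
.sigmoidTm <- function(temp, y, tmDeriv, windowHalfWidth = 12) {
  keep <- abs(temp - tmDeriv) <= windowHalfWidth
  if (sum(keep) < 6) keep <- rep(TRUE, length(temp))
  tt <- temp[keep]; yy <- y[keep]
  start <- list(lo = yy[1], delta = yy[length(yy)] - yy[1],
                tm = tmDeriv, s = 2)
  fit <- tryCatch(
    nlsLM(yy ~ lo + delta / (1 + exp((tm - tt) / s)), start = start,
          lower = c(lo = -Inf, delta = -Inf, tm = min(tt), s = 0.1),
          upper = c(lo = Inf, delta = Inf, tm = max(tt), s = 30),
          control = nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) NA_real_ else sqrt(vc["tm", "tm"])
  c(tm = cf[["tm"]], se = se)
}

# derivative-maximum melting temperature of a profile (quadratic-refined)
.derivTmProfile <- function(temp, y, smoothWindow = 3L) {
  d <- abs(diff(.movavg(y, smoothWindow)) / diff(temp))
  mid <- (temp[-1] + temp[-length(temp)]) / 2
  .refineArgmax(mid, d, which.max(d))
}

#' Per-structure and global melting temperatures
#'
#' For each structure class, fits its melting profile over the ramp with a
#' logistic sigmoid in a window centered on the temperature of maximal
#' |rate of change| (the dominant transition); the midpoint is the class Tm,
#' with the derivative-maximum estimate reported alongside and used as
#' fallback when the sigmoid fails. The default profile is the class's
#' fitted band \emph{area} (the temperature dependence of its IR signal,
#' i.e. what a signal-change heat map tracks); \code{profile = "fraction"}
#' instead uses the compositional fraction, whose midpoints are coupled
#' across classes because fractions are ratios. Classes with a flat profile
#' are flagged with an undefined Tm. The global Tm is obtained the same way
#' from the whole-spectrum dissimilarity trace, 1 minus the Pearson
#' correlation of each similarity spectrum with the lowest-temperature one.
#'
#' @param compositions list of \linkS4class{HOSComposition}, one per ramp
#'   temperature (>= 8 temperatures spanning the transition).
#' @param temperatures ramp temperatures (degC); taken from the
#'   compositions when omitted.
#' @param simSpectra optional list of \linkS4class{SimilaritySpectrum}
#'   matching \code{temperatures}; enables the global Tm.
#' @param profile \code{"area"} (default) or \code{"fraction"}.
#' @param windowHalfWidth half-width (degC) of the sigmoid fitting window.
#' @param flatTol profile range below which a class is called flat
#'   (absolute for fractions, relative to the profile maximum for areas).
#' @return a \linkS4class{ThermalAnalysis}.
#' @export
meltAnalysis <- function(compositions, temperatures = NULL,
                         simSpectra = NULL, profile = c("area", "fraction"),
                         windowHalfWidth = 12, flatTol = 0.005) {
  stopifnot(all(vapply(compositions, is, logical(1), "HOSComposition")))
  profile <- match.arg(profile)
  if (is.null(temperatures))
    temperatures <- vapply(compositions, function(x) x@temperature, numeric(1))
  .stopif(length(temperatures) < 8,
          "need >= 8 ramp temperatures spanning the transition")
  .checkStrictlyIncreasing(temperatures, "temperatures")
  if (profile == "fraction") {
    fracMat <- vapply(compositions, hosFractions,
                      numeric(length(hosFractions(compositions[[1]]))))
  } else {
    bt0 <- compositions[[1]]@bandTable
    cls <- unique(bt0$class)
    fracMat <- vapply(compositions, function(x) {
      vapply(cls, function(k)
        sum(x@bandTable$area[x@bandTable$class == k]), numeric(1))
    }, numeric(length(cls)))
    rownames(fracMat) <- cls
  }
  classes <- rownames(fracMat)

  rows <- lapply(classes, function(k) {
    y <- fracMat[k, ]
    tol <- if (profile == "fraction") flatTol
           else flatTol * max(max(abs(y)), .Machine$double.eps)
    if (diff(range(y)) < tol)
      return(data.frame(class = k, tm = NA_real_, tm_se = NA_real_,
                        tm_derivative = NA_real_, method = "flat",
                        flagged = TRUE, stringsAsFactors = FALSE))
    tmD <- .derivTmProfile(temperatures, y)
    sg <- .sigmoidTm(temperatures, y, tmD, windowHalfWidth)
    if (is.null(sg))
      data.frame(class = k, tm = tmD, tm_se = NA_real_, tm_derivative = tmD,
                 method = "derivative", flagged = TRUE,
                 stringsAsFactors = FALSE)
    else
      data.frame(class = k, tm = unname(sg["tm"]), tm_se = unname(sg["se"]),
                 tm_derivative = tmD, method = "sigmoid", flagged = FALSE,
                 stringsAsFactors = FALSE)
  })
  classTm <- do.call(rbind, rows)

  globalTm <- NA_real_; globalSe <- NA_real_
  if (!is.null(simSpectra)) {
    ref <- simSpectra[[1]]@values
    dis <- vapply(simSpectra, function(s) 1 - cor(s@values, ref), numeric(1))
    tmD <- .derivTmProfile(temperatures, dis)
    sg <- .sigmoidTm(temperatures, dis, tmD, windowHalfWidth)
    if (is.null(sg)) globalTm <- tmD
    else { globalTm <- unname(sg["tm"]); globalSe <- unname(sg["se"]) }
  }
  new("ThermalAnalysis", classTm = classTm, globalTm = globalTm,
      globalTmSe = globalSe)
}

#' Fit the EC50 of ligand-driven thermal stabilization
#'
#' Least squares of the rectangular hyperbola
#' \eqn{T_m([L]) = T_{m,0} + \Delta T_{m,max}[L]/([L] + EC_{50})} over
#' ligand concentration (including 0). When the stabilization amplitude is
#' not distinguishable from zero (its standard error spans 0, or the Tm
#' values are constant) the fit is flagged \code{"no_stabilization"}.
#'
#' @param ligandConc ligand concentrations (uM), >= 4 values including 0.
#' @param globalTm global melting temperatures (degC).
#' @return an \linkS4class{EC50Fit}.
#' @export
fitEc50 <- function(ligandConc, globalTm) {
  .stopif(length(ligandConc) != length(globalTm),
          "ligandConc/globalTm length mismatch")
  .stopif(length(unique(ligandConc)) < 4 || !any(ligandConc == 0),
          "need >= 4 concentrations including 0")
  tm0Init <- mean(globalTm[ligandConc == 0])
  if (diff(range(globalTm)) < 1e-9) {
    return(new("EC50Fit", tm0 = tm0Init, deltaTmMax = 0,
               deltaTmMaxSe = NA_real_, ec50 = NA_real_, ec50Se = NA_real_,
               flags = "no_stabilization"))
  }
  pos <- ligandConc[ligandConc > 0]
  start <- list(tm0 = tm0Init, delta = max(globalTm) - tm0Init,
                ec50 = median(pos))
  fit <- tryCatch(
    nlsLM(globalTm ~ tm0 + delta * ligandConc / (ligandConc + ec50),
          start = start,
          lower = c(tm0 = -Inf, delta = -Inf, ec50 = 1e-9),
          upper = c(tm0 = Inf, delta = Inf, ec50 = 1e4 * max(pos)),
          control = nls.lm.control(maxiter = 500)),
    error = function(e) e)
  .stopif(inherits(fit, "error"),
          paste0("EC50 fit failed to converge: ", conditionMessage(fit)))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3,
    dimnames = list(names(cf), names(cf))))
  flags <- character(0)
  dse <- sqrt(vc["delta", "delta"])
  if (is.finite(dse) && abs(cf[["delta"]]) <= 2 * dse)
    flags <- "no_stabilization"
  new("EC50Fit", tm0 = cf[["tm0"]], deltaTmMax = cf[["delta"]],
      deltaTmMaxSe = dse, ec50 = cf[["ec50"]],
      ec50Se = sqrt(vc["ec50", "ec50"]), flags = flags)
}

# Estimate one width per band jointly across all ramp spectra: outer
# bounded Levenberg-Marquardt over the widths, inner NNLS amplitudes per
# spectrum (variable projection). Widths are physical band properties and do
# not change along the ramp, so coupling them across temperatures makes the
# heavily overlapped amide-I attribution stable under noise.
.estimateSeriesWidths <- function(mat, wn, bands) {
  resFun <- function(w) {
    G <- .bandDesign(wn, bands$center, w)
    as.vector(apply(mat, 2, function(y) y - drop(G %*% pracma::lsqnonneg(G, y)$x)))
  }
  ref <- tryCatch(
    minpack.lm::nls.lm(par = bands$width, fn = resFun,
                       lower = bands$width_lo, upper = bands$width_hi,
                       control = minpack.lm::nls.lm.control(maxiter = 50)),
    error = function(e) NULL)
  if (is.null(ref)) bands$width else ref$par
}

#' Run the full MMS processing chain on a spectral series
#'
#' Normalization to the absolute scale, similarity-spectrum conversion per
#' ramp temperature, Gaussian band deconvolution into HOS fractions, and
#' per-class plus global melt analysis.
#'
#' @param series an \linkS4class{IRSpectrumSeries} (differential scale
#'   unless \code{normalized = TRUE}).
#' @param model a \linkS4class{BandModel}; default
#'   \code{\link{defaultBandModel}()}.
#' @param fitOn domain of the band deconvolution: \code{"absolute"}
#'   (default) fits the Gaussian model to the absolute spectra, which keeps
#'   low-amplitude bands quantifiable throughout the melt;
#'   \code{"similarity"} fits the floored similarity spectra, whose
#'   sharpened peaks resist baseline drift in real data but clip weak bands
#'   once strong neighbours dominate. The similarity spectra are always
#'   computed (global melt metric).
#' @param displacementFactor differential-to-absolute factor (default 0.63).
#' @param normalized set TRUE when the series is already absolute-scale.
#' @param sgWindow,sgOrder Savitzky-Golay settings.
#' @param excludeClasses passed to \code{\link{deconvolveBands}}.
#' @param refineWidths estimate one width per band jointly across the whole
#'   ramp (bounded variable-projection least squares) before the
#'   per-temperature amplitude fits; default TRUE. With FALSE the
#'   per-spectrum shared width-scale profiling is used instead.
#' @param profile,windowHalfWidth passed to \code{\link{meltAnalysis}}.
#' @return list with \code{similarity} (list of
#'   \linkS4class{SimilaritySpectrum}), \code{compositions} (list of
#'   \linkS4class{HOSComposition}), \code{fractions} (long data.frame:
#'   temperature_C, class, fraction) and \code{thermal}
#'   (\linkS4class{ThermalAnalysis}).
#' @export
runMmsPipeline <- function(series, model = defaultBandModel(),
                           fitOn = c("absolute", "similarity"),
                           displacementFactor = 0.63, normalized = FALSE,
                           sgWindow = 19L, sgOrder = 3L,
                           excludeClasses = "side_chain",
                           refineWidths = TRUE,
                           profile = c("area", "fraction"),
                           windowHalfWidth = 12) {
  stopifnot(is(series, "IRSpectrumSeries"))
  validObject(series)
  fitOn <- match.arg(fitOn)
  mat <- absorbance(series)
  if (!normalized) mat <- normalizeSpectrum(mat, displacementFactor)
  wn <- wavenumbers(series)
  tt <- temperatures(series)
  sims <- lapply(seq_along(tt), function(j)
    similaritySpectrum(mat[, j], wn, sgWindow = sgWindow, sgOrder = sgOrder))
  targets <- if (fitOn == "similarity")
    vapply(sims, function(s) s@values, numeric(length(wn)))
  else mat
  fixedWidths <- if (refineWidths)
    .estimateSeriesWidths(targets, wn, model@bands) else NULL
  comps <- lapply(seq_along(tt), function(j)
    deconvolveBands(targets[, j], model, wavenumbers = wn,
                    excludeClasses = excludeClasses, widths = fixedWidths,
                    temperature = tt[j]))
  thermal <- meltAnalysis(comps, temperatures = tt, simSpectra = sims,
                          profile = profile,
                          windowHalfWidth = windowHalfWidth)
  fractions <- do.call(rbind, lapply(seq_along(tt), function(j) {
    f <- hosFractions(comps[[j]])
    data.frame(temperature_C = tt[j], class = names(f), fraction = unname(f),
               stringsAsFactors = FALSE)
  }))
  list(similarity = sims, compositions = comps, fractions = fractions,
       thermal = thermal)
}
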