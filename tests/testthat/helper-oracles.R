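# Brute-force oracles kept independent of the package's fitting code paths.

# Boltzmann grid search: for each (tm, slope) lattice point the plateaus are
# profiled out by ordinary linear least squares on the logistic regressor.
oracleBoltzmannGrid <- function(tt, ff, tmGrid, slopeGrid) {
  best <- c(sse = Inf, tm = NA, slope = NA)
  for (tm in tmGrid) for (s in slopeGrid) {
    z <- 1 / (1 + exp((tm - tt) / s))
    fit <- stats::lm.fit(cbind(1, z), ff)
    sse <- sum(fit$residuals^2)
    if (sse < best["sse"]) best <- c(sse = sse, tm = tm, slope = s)
  }
  best
}

# exhaustive SSE grid for the saturation buildup AF(t) = a (1 - exp(-k t))
oracleBuildupGrid <- function(t, af, aGrid, kGrid) {
  best <- c(sse = Inf, afMax = NA, kSat = NA)
  for (a in aGrid) for (k in kGrid) {
    sse <- sum((af - a * (1 - exp(-k * t)))^2)
    if (sse < best["sse"]) best <- c(sse = sse, afMax = a, kSat = k)
  }
  best
}

# exhaustive SSE grid for the Langmuir isotherm af0 = alpha L / (L + Kd)
oracleLangmuirGrid <- function(L, af0, alphaGrid, kdGrid) {
  best <- c(sse = Inf, alpha = NA, kd = NA)
  for (a in alphaGrid) for (k in kdGrid) {
    sse <- sum((af0 - a * L / (L + k))^2)
    if (sse < best["sse"]) best <- c(sse = sse, alpha = a, kd = k)
  }
  best
}

# exhaustive SSE grid for Tm(L) = tm0 + d L / (L + ec50), tm0 profiled out
oracleEc50Grid <- function(L, tm, dGrid, eGrid) {
  best <- c(sse = Inf, delta = NA, ec50 = NA)
  for (d in dGrid) for (e in eGrid) {
    tm0 <- mean(tm - d * L / (L + e))
    sse <- sum((tm - tm0 - d * L / (L + e))^2)
    if (sse < best["sse"]) best <- c(sse = sse, delta = d, ec50 = e)
  }
  best
}

# argmax of the numerical first derivative of a trace (grid resolution)
oracleDerivativeArgmax <- function(tt, ff) {
  d <- diff(ff) / diff(tt)
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  mid[which.max(d)]
}

# count of derivative local maxima above a relative height threshold
oracleDerivativePeakCount <- function(tt, ff, frac, smooth = 5L) {
  sm <- stats::filter(ff, rep(1 / smooth, smooth), sides = 2)
  sm[is.na(sm)] <- ff[is.na(sm)]
  d <- diff(as.numeric(sm)) / diff(tt)
  n <- length(d)
  peaks <- which(d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n]) + 1L
  sum(d[peaks] > frac * max(d))
}
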