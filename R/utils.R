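# Internal numerical helpers shared across modules.

#' @importFrom stats coef vcov median sd setNames approx cor optimize nls
#' @importFrom stats rnorm runif predict quantile residuals
NULL

# unit-amplitude Gaussian profile; `width` is the standard deviation (cm^-1)
.gauss <- function(x, center, width) exp(-((x - center)^2) / (2 * width^2))

# rising logistic in temperature; midpoint `tm`, steepness scale `slope` (degC)
.logisticRise <- function(temp, tm, slope) 1 / (1 + exp((tm - temp) / slope))

.isScalarNum <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopif <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

.checkStrictlyIncreasing <- function(x, what) {
  .stopif(length(x) < 2L || any(diff(x) <= 0),
          sprintf("%s must be strictly increasing", what))
  invisible(TRUE)
}

# moving-average smoother with edge truncation (odd window)
.movavg <- function(y, window = 5L) {
  n <- length(y)
  if (n == 0L || window <= 1L) return(y)
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- mean(y[j])
  }
  out
}

# indices of strict local maxima of y
.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# quadratic (three-point) interpolation of the abscissa of a grid maximum
.refineArgmax <- function(x, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(x[i])
  d1 <- y[i] - y[i - 1L]; d2 <- y[i] - y[i + 1L]
  denom <- d1 + d2
  if (!is.finite(denom) || denom <= 0) return(x[i])
  # offset in units of (uniform-ish) grid step
  x[i] + 0.5 * (d1 - d2) / denom * mean(diff(x[max(1L, i - 1L):min(n, i + 1L)]))
}

# derive a reproducible 32-bit sub-seed from a master seed and a stream label
.subSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 69069 + h * 1234567) %% .Machine$integer.max)
}

# multiplicative lognormal noise factors with unit mean and coefficient of
# variation `cv`
.lognormalFactors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(rnorm(n, mean = -sigma2 / 2, sd = sqrt(sigma2)))
}
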