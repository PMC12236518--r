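# MMS processing: normalization, similarity spectra, band deconvolution,
# melt analysis and the stabilization EC50.

wn <- seq(1588, 1712, by = 1)

test_that("displacement-factor normalization is a pure invertible rescaling", {
  y <- exp(-(wn - 1650)^2 / 72)
  expect_identical(normalizeSpectrum(y, 1.0), y)
  expect_equal(normalizeSpectrum(y, 0.63) * 0.63, y, tolerance = 1e-12)
  expect_error(normalizeSpectrum(y, 0), "positive")
})

test_that("similarity spectrum peaks at band centers and kills flat input", {
  g <- exp(-(wn - 1652)^2 / (2 * 6^2))
  sim <- similaritySpectrum(g, wn)
  expect_equal(wn[which.max(sim@values)], 1652)
  expect_true(all(sim@values >= 0))

  flat <- similaritySpectrum(rep(2.5, length(wn)), wn)
  expect_equal(max(abs(flat@values)), 0)

  two <- exp(-(wn - 1620)^2 / (2 * 5^2)) + exp(-(wn - 1680)^2 / (2 * 5^2))
  s2 <- similaritySpectrum(two, wn)
  h1 <- max(s2@values[wn < 1650]); h2 <- max(s2@values[wn >= 1650])
  expect_lt(abs(h1 - h2) / max(h1, h2), 0.02)

  expect_error(similaritySpectrum(g, wn, sgWindow = 18L), "odd")
})

test_that("deconvolution recovers its own band model exactly", {
  model <- defaultBandModel()
  b <- model@bands
  amps <- c(0.1, 0.3, 0.5, 0.45, 0.3, 0.55, 0.6, 0.35, 0.25, 0.2)
  spec <- rowSums(sapply(seq_len(nrow(b)), function(i)
    amps[i] * exp(-(wn - b$center[i])^2 / (2 * b$width[i]^2))))
  comp <- deconvolveBands(spec, model, wavenumbers = wn)
  area <- amps * b$width * sqrt(2 * pi)
  keep <- b$class != "side_chain"
  tr <- tapply(area[keep], b$class[keep], sum)
  truth <- setNames(as.vector(tr) / sum(tr), dimnames(tr)[[1]])
  expect_equal(hosFractions(comp)[names(truth)], truth, tolerance = 1e-3)
  expect_equal(sum(hosFractions(comp)), 1, tolerance = 1e-9)
})

test_that("single-band and 3:1 two-band spectra give the analytic fractions", {
  model <- BandModel(data.frame(
    label = c("b1", "h1"), class = c("native_beta", "alpha_helix"),
    center = c(1633, 1656), center_tol = 2, width = 6,
    width_lo = 3, width_hi = 12))
  single <- 0.7 * exp(-(wn - 1633)^2 / (2 * 36))
  f1 <- hosFractions(deconvolveBands(single, model, wavenumbers = wn))
  expect_equal(unname(f1["native_beta"]), 1, tolerance = 1e-6)

  # equal widths, amplitudes 3:1 -> areas 3:1 -> fractions 0.75/0.25
  two <- 0.9 * exp(-(wn - 1633)^2 / (2 * 36)) +
    0.3 * exp(-(wn - 1656)^2 / (2 * 36))
  f2 <- hosFractions(deconvolveBands(two, model, wavenumbers = wn))
  expect_equal(unname(f2["native_beta"]), 0.75, tolerance = 0.01)
  expect_equal(unname(f2["alpha_helix"]), 0.25, tolerance = 0.01)

  # amplitude-scale invariance of the fractions
  f3 <- hosFractions(deconvolveBands(13 * two, model, wavenumbers = wn))
  expect_equal(f3, f2, tolerance = 1e-9)
})

test_that("fractions sum to one and stay in [0,1] along a generated ramp", {
  p <- irFixture("apo")
  p@tempGrid <- seq(25, 75, by = 5)
  out <- runMmsPipeline(simulateIRSeries(p, seed = 21), refineWidths = FALSE)
  for (comp in out$compositions) {
    f <- hosFractions(comp)
    expect_equal(sum(f), 1, tolerance = 1e-6)
    expect_true(all(f >= -1e-9 & f <= 1 + 1e-9))
  }
  # fractional composition is invariant to the displacement factor
  f05 <- hosFractions(deconvolveBands(
    absorbance(simulateIRSeries(p, seed = 21))[, 1] / 0.5,
    defaultBandModel(), wavenumbers = wavenumbers(simulateIRSeries(p, seed = 21))))
  f063 <- hosFractions(deconvolveBands(
    absorbance(simulateIRSeries(p, seed = 21))[, 1] / 0.63,
    defaultBandModel(), wavenumbers = wavenumbers(simulateIRSeries(p, seed = 21))))
  expect_equal(f05, f063, tolerance = 1e-6)
})

test_that("melt analysis returns the exact logistic midpoint and derivative agreement", {
  tt <- seq(25, 75, by = 1)
  frac <- 0.6 - 0.4 / (1 + exp((55 - tt) / 2))   # falls with midpoint 55
  comps <- lapply(seq_along(tt), function(j) {
    f <- c(native_beta = frac[j], alpha_helix = 1 - frac[j])
    bt <- data.frame(label = c("nb", "ah"),
                     class = c("native_beta", "alpha_helix"),
                     center = c(1633, 1656), width = 6,
                     amplitude = f, area = f * 6 * sqrt(2 * pi),
                     stringsAsFactors = FALSE)
    new("HOSComposition", fractions = f, bandTable = bt,
        temperature = tt[j], excludedClasses = "side_chain")
  })
  ta <- meltAnalysis(comps, profile = "fraction")
  tmNb <- ta@classTm[ta@classTm$class == "native_beta", ]
  expect_equal(tmNb$tm, 55, tolerance = 0.02)
  expect_equal(tmNb$method, "sigmoid")
  # sigmoid midpoint vs derivative maximum agree within the 1 degC grid
  expect_lt(abs(tmNb$tm - tmNb$tm_derivative), 1)

  taArea <- meltAnalysis(comps, profile = "area")
  expect_equal(taArea@classTm$tm[taArea@classTm$class == "native_beta"], 55,
               tolerance = 0.02)

  # flat class profile: flagged, undefined Tm
  compsFlat <- lapply(comps, function(x) {
    x@fractions <- c(native_beta = 0.5, alpha_helix = 0.5)
    x@bandTable$area <- c(1, 1)
    x
  })
  taFlat <- meltAnalysis(compsFlat, profile = "fraction")
  expect_true(all(taFlat@classTm$flagged))
  expect_true(all(is.na(taFlat@classTm$tm)))
})

test_that("EC50 fit recovers exact parameters, flags flat input, matches its oracle", {
  L <- c(0, 100, 250, 500, 1000, 2000)
  tm <- 53.4 + 6 * L / (L + 400)
  fit <- fitEc50(L, tm)
  expect_equal(fit@tm0, 53.4, tolerance = 1e-6)
  expect_equal(fit@deltaTmMax, 6, tolerance = 1e-6)
  expect_equal(fit@ec50, 400, tolerance = 1e-4)
  expect_length(fit@flags, 0)

  orc <- oracleEc50Grid(L, tm, seq(4, 8, length.out = 201),
                        seq(300, 500, length.out = 201))
  expect_lt(abs(fit@ec50 - orc["ec50"]), 1)
  expect_lt(abs(fit@deltaTmMax - orc["delta"]), 0.02)

  flatFit <- fitEc50(L, rep(55, 6))
  expect_true("no_stabilization" %in% flatFit@flags)

  expect_error(fitEc50(c(100, 200, 300, 400), c(53, 54, 55, 55)),
               "including 0")
})
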