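# Generators: determinism, analytic shape properties, fixture designs.

test_that("identical seeds reproduce identical datasets bit for bit", {
  p <- dsfFixture("control")
  a <- simulateMeltCurves(p, seed = 11)
  b <- simulateMeltCurves(p, seed = 11)
  expect_identical(lapply(a, function(x) x@fluorescence),
                   lapply(b, function(x) x@fluorescence))
  expect_false(identical(a[[1]]@fluorescence,
                         simulateMeltCurves(p, seed = 12)[[1]]@fluorescence))

  s1 <- simulateScreen(screenSpec(nCompounds = 12, seed = 5L))
  s2 <- simulateScreen(screenSpec(nCompounds = 12, seed = 5L))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$curves[[3]]@fluorescence, s2$curves[[3]]@fluorescence)

  d1 <- simulateStdDataset(stdFixture("KG-96"), noiseCv = 0.03, seed = 9)
  d2 <- simulateStdDataset(stdFixture("KG-96"), noiseCv = 0.03, seed = 9)
  expect_identical(d1@records, d2@records)

  i1 <- simulateIRSeries(irFixture("apo"), seed = 4)
  i2 <- simulateIRSeries(irFixture("apo"), seed = 4)
  expect_identical(absorbance(i1), absorbance(i2))
})

test_that("noiseless melt trace has its rising-limb derivative maximum at the true Tm", {
  p <- dsfFixture("control", noiseSd = 0)
  cv <- simulateMeltCurves(p, seed = 1)[[1]]
  rising <- seq_len(which.max(cv@fluorescence))
  tmDeriv <- oracleDerivativeArgmax(cv@temperature[rising],
                                    cv@fluorescence[rising])
  expect_lt(abs(tmDeriv - 53.4), 0.25)   # grid step 0.25 degC
})

test_that("zero-amplitude and biphasic trace shapes behave as designed", {
  flat <- dsfGenParams(tmTrue = 53, fPre = 5000, fPost = 5000, noiseSd = 0)
  tr <- simulateMeltCurves(flat, seed = 1)[[1]]
  expect_equal(diff(range(tr@fluorescence)), 0)

  bip <- dsfGenParams(tmTrue = 50, biphasic = c(58, 1, 0.5), noiseSd = 0,
                      decayOnset = 70)
  cv <- simulateMeltCurves(bip, seed = 1)[[1]]
  rising <- seq_len(which.max(cv@fluorescence))
  expect_gte(oracleDerivativePeakCount(cv@temperature[rising],
                                       cv@fluorescence[rising], 0.2), 2)

  expect_error(dsfGenParams(tempGrid = c(30, 29, 40)), "increasing")
})

test_that("screen generator emits duplicate wells, controls and a truth table", {
  spec <- screenSpec(nCompounds = 20, hitFraction = 0.2, seed = 3L,
                     nControlWells = 4L)
  scr <- simulateScreen(spec)
  expect_length(scr$curves, 20 * 2 + 4)
  expect_equal(nrow(scr$truth), 20)
  expect_equal(sum(scr$truth$is_hit), 4)
  expect_error(screenSpec(hitFraction = 1.5), "hitFraction")

  # hit_fraction = 0: all true Tm within the bounded zero-mean jitter
  spec0 <- screenSpec(nCompounds = 50, hitFraction = 0, seed = 2L,
                      libraryDeltaSd = 0.5)
  tr0 <- simulateScreen(spec0)$truth
  expect_false(any(tr0$is_hit))
  expect_lt(max(abs(tr0$delta_true)), sqrt(3) * 0.5 + 1e-12)
})

test_that("analytic screen Tm spread matches the empirical mixture", {
  spec <- screenFixture(seed = 7L)
  tr <- simulateScreen(spec)$truth
  expect_lt(abs(sd(tr$tm_true) - screenTmSd(spec)), 0.2)
  expect_lt(abs(screenTmSd(spec) - 2.3), 0.05)
})

test_that("STD generator satisfies the buildup and Langmuir laws at zero noise", {
  truth <- bindingTruth(kdTrue = 400, alphaStd = c(a = 0.6), ksatRef = c(a = 0.8),
                        proteinConc = 20, ligandConcs = c(200, 400, 800),
                        satTimes = c(0.5, 1, 2, 4),
                        regions = list(EpitopeRegion("a", 7, 8)))
  ds <- simulateStdDataset(truth, noiseCv = 0, seed = 1)
  r <- ds@records
  af <- computeStdAf(r$i_diff, r$i_ref, r$ligand_conc_uM, ds@proteinConc)

  # half-saturation: at [L] = Kd the initial slope is alpha/2
  atKd <- r$ligand_conc_uM == 400
  expected <- (0.6 / 2) / 0.8 * (1 - exp(-0.8 * r$sat_time_s[atKd]))
  expect_equal(af[atKd], expected, tolerance = 1e-12)

  # plateau limit: k*t >> 1 approaches AFmax
  big <- bindingTruth(kdTrue = 400, alphaStd = c(a = 0.6), ksatRef = c(a = 5),
                      proteinConc = 20, ligandConcs = 400,
                      satTimes = c(0.5, 1, 5),
                      regions = list(EpitopeRegion("a", 7, 8)))
  rb <- simulateStdDataset(big, noiseCv = 0, seed = 1)@records
  afb <- computeStdAf(rb$i_diff, rb$i_ref, rb$ligand_conc_uM, 20)
  afMaxTrue <- (0.6 * 400 / 800) / 5      # AF0 / ksat
  expect_equal(afb[rb$sat_time_s == 5], afMaxTrue, tolerance = 1e-6)

  # monotone non-decreasing in saturation time at zero noise
  for (L in unique(r$ligand_conc_uM)) {
    sub <- r[r$ligand_conc_uM == L, ]
    expect_true(all(diff(sub$i_diff[order(sub$sat_time_s)]) >= 0))
  }
})

test_that("STD fixture design yields the full factorial record set", {
  ds <- simulateStdDataset(stdFixture("KG-96"), noiseCv = 0, seed = 1)
  expect_equal(nrow(ds@records), 3 * 5 * 8)
  expect_setequal(unique(ds@records$ligand_conc_uM),
                  c(200, 400, 600, 800, 1000))
  expect_length(unique(ds@records$sat_time_s), 8)
})

test_that("IR generator matches the analytic band sum and Gaussian areas", {
  bt <- data.frame(center = c(1630, 1655), width = c(5, 7),
                   base_amplitude = c(0.5, 0.8),
                   structure_class = c("native_beta", "alpha_helix"),
                   melt_tm = c(60, 62), melt_slope = 2,
                   post_melt_fraction = 0.1)
  agg <- c(center = 1619, width = 6, amplitude = 0.4, growth_tm = 62,
           growth_slope = 2)
  p <- irGenParams(bt, agg, tempGrid = seq(25, 75, 5), noiseSd = 0)
  ser <- simulateIRSeries(p, seed = 1)
  wn <- wavenumbers(ser)

  # far below every melt midpoint the spectrum is the base band sum
  spec25 <- absorbance(ser)[, 1]
  manual <- 0.5 * exp(-(wn - 1630)^2 / (2 * 5^2)) +
    0.8 * exp(-(wn - 1655)^2 / (2 * 7^2))
  expect_equal(spec25, manual, tolerance = 1e-6, ignore_attr = TRUE)

  # trapezoidal integral vs closed-form sum of a*w*sqrt(2*pi)
  analytic <- 0.5 * 5 * sqrt(2 * pi) + 0.8 * 7 * sqrt(2 * pi)
  expect_equal(as.numeric(pracma::trapz(wn, spec25)), analytic,
               tolerance = 1e-3)

  expect_error(irGenParams(transform(bt, width = 0), agg), "width")
})
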