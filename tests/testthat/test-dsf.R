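# Melt-curve fitting, biphasic QC and hit calling.

mkFit <- function(compound, tm, rep = 1L, flags = character(0)) {
  new("MeltFit", tm = tm, slope = 1, fPre = 0, fPost = 1, tmSe = 0.05,
      rSquared = 0.999, flags = flags, window = c(25, 70),
      wellId = sprintf("%s_%d", compound, rep), compoundId = compound,
      replicateIndex = rep)
}

test_that("noiseless control curve is recovered at the derivative-maximum Tm", {
  cv <- simulateMeltCurves(dsfFixture("control", noiseSd = 0), seed = 1)[[1]]
  fit <- fitMeltCurve(cv)
  expect_lt(abs(meltTm(fit) - 53.4), 0.05)
  expect_length(qcFlags(fit), 0)
  rising <- seq_len(which.max(cv@fluorescence))
  tmOracle <- oracleDerivativeArgmax(cv@temperature[rising],
                                     cv@fluorescence[rising])
  expect_lt(abs(meltTm(fit) - tmOracle), 0.25)
  expect_gt(fit@rSquared, 0.999)
})

test_that("Boltzmann fit agrees with a coarse grid-search oracle on noiseless data", {
  cv <- simulateMeltCurves(dsfFixture("KG-484", noiseSd = 0), seed = 1)[[1]]
  fit <- fitMeltCurve(cv)
  rising <- seq_len(which.max(cv@fluorescence))
  orc <- oracleBoltzmannGrid(cv@temperature[rising], cv@fluorescence[rising],
                             tmGrid = seq(62, 65, by = 0.05),
                             slopeGrid = seq(0.6, 1.6, by = 0.05))
  expect_lt(abs(meltTm(fit) - orc["tm"]), 0.05)
  expect_lt(abs(fit@slope - orc["slope"]), 0.05)
})

test_that("flat traces are flagged low-amplitude with no Tm", {
  flat <- dsfGenParams(tmTrue = 53, fPre = 5000, fPost = 5000, noiseSd = 0)
  fit <- fitMeltCurve(simulateMeltCurves(flat, seed = 1)[[1]])
  expect_true("low_amplitude" %in% qcFlags(fit))
  expect_true(is.na(meltTm(fit)))
})

test_that("biphasic detection counts prominent derivative maxima only", {
  bip <- dsfGenParams(tmTrue = 50, biphasic = c(58, 1, 0.5), noiseSd = 0,
                      decayOnset = 70)
  expect_true(detectBiphasic(simulateMeltCurves(bip, seed = 1)[[1]]))
  expect_true("biphasic" %in%
                qcFlags(fitMeltCurve(simulateMeltCurves(bip, seed = 1)[[1]])))

  mono <- simulateMeltCurves(dsfFixture("control", noiseSd = 0), seed = 1)[[1]]
  expect_false(detectBiphasic(mono))

  # a second transition at 1% amplitude sits below a 20% prominence cut
  tiny <- dsfGenParams(tmTrue = 50, biphasic = c(58, 1, 0.01), noiseSd = 0,
                       decayOnset = 70)
  cv <- simulateMeltCurves(tiny, seed = 1)[[1]]
  expect_false(detectBiphasic(cv, prominenceFrac = 0.2))
  rising <- seq_len(which.max(cv@fluorescence))
  expect_lt(oracleDerivativePeakCount(cv@temperature[rising],
                                      cv@fluorescence[rising], 0.2), 2)
})

test_that("Tm recovery at 1% amplitude noise is accurate on average", {
  p <- dsfFixture("control")   # noise sd = 1% of amplitude
  p@nReplicates <- 100L
  curves <- simulateMeltCurves(p, seed = 123)
  errs <- vapply(curves, function(cv) meltTm(fitMeltCurve(cv)) - 53.4,
                 numeric(1))
  expect_lt(mean(abs(errs)), 0.2)
})

test_that("hit calling applies the control + 1 SD rule with QC discards", {
  # all compounds identical to the control: SD = 0, strict inequality, no hits
  fits <- c(lapply(1:6, function(i) mkFit(sprintf("C%02d", i), 50)),
            list(mkFit("DMSO", 50), mkFit("DMSO", 50, rep = 2L)))
  ht <- callHits(fits, controlId = "DMSO")
  expect_equal(hitThreshold(ht), 50)
  expect_equal(sum(hitCalls(ht)$hit), 0)

  expect_error(callHits(fits, controlId = "missing"), "control")

  # discards: irreproducible replicates and biphasic wells are never hits
  fits2 <- list(
    mkFit("DMSO", 50), mkFit("DMSO", 50, rep = 2L),
    mkFit("HIT", 60), mkFit("HIT", 60.2, rep = 2L),
    mkFit("IRRE", 60), mkFit("IRRE", 65, rep = 2L),           # spread 5 > 2
    mkFit("BIPH", 62, flags = "biphasic"),
    mkFit("BIPH", 62.1, rep = 2L),
    mkFit("LOW", 50.5), mkFit("LOW", 50.4, rep = 2L))
  ht2 <- callHits(fits2, controlId = "DMSO", reproducibilityTol = 2)
  tab <- hitCalls(ht2)
  expect_true(tab$hit[tab$compound_id == "HIT"])
  expect_false(tab$hit[tab$compound_id == "IRRE"])
  expect_equal(tab$discard_reason[tab$compound_id == "IRRE"], "irreproducible")
  expect_false(tab$hit[tab$compound_id == "BIPH"])
  expect_equal(tab$discard_reason[tab$compound_id == "BIPH"], "biphasic")
  expect_equal(tab$delta_tm[tab$compound_id == "HIT"], 60.1 - 50)
})

test_that("raising a compound's Tm never turns a hit into a non-hit", {
  base <- c(seq(49, 51, length.out = 40), 56, 57, 58)
  mk <- function(tmTarget) {
    fits <- c(lapply(seq_along(base), function(i)
      mkFit(sprintf("C%02d", i), base[i])),
      list(mkFit("TGT", tmTarget), mkFit("DMSO", 50)))
    tab <- hitCalls(callHits(fits, controlId = "DMSO"))
    tab$hit[tab$compound_id == "TGT"]
  }
  states <- vapply(seq(50, 70, by = 0.5), mk, logical(1))
  expect_true(all(diff(as.integer(states)) >= 0))  # once a hit, always a hit
})
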