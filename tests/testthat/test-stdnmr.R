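# STD NMR: integration, amplification factors, buildup + Langmuir fits,
# combination, and the end-to-end pipeline.

test_that("region integration matches analytic areas", {
  ppm <- seq(9, 6.5, by = -0.001)          # NMR convention: decreasing ppm
  zero <- data.frame(ppm = ppm, intensity = 0)
  r1 <- EpitopeRegion("r1", 8.39, 8.42)
  expect_equal(integrateRegion(zero, r1), 0)

  rect <- data.frame(ppm = ppm,
                     intensity = as.numeric(ppm >= 8.39 & ppm <= 8.42))
  expect_equal(integrateRegion(rect, r1), 0.03, tolerance = 0.05)

  # Lorentzian of HWHM g: integral g * (atan(u2) - atan(u1)) in units of u
  g <- 0.01; p0 <- 8.405
  lor <- data.frame(ppm = ppm, intensity = 1 / (1 + ((ppm - p0) / g)^2))
  analytic <- g * (atan((8.42 - p0) / g) - atan((8.39 - p0) / g))
  expect_equal(integrateRegion(lor, r1), analytic, tolerance = 0.01)

  expect_error(integrateRegion(zero, EpitopeRegion("out", 10, 11)),
               "outside")
})

test_that("amplification factor is the epsilon-scaled normalized difference", {
  expect_equal(computeStdAf(0, 1000, 500, 20), 0)
  expect_equal(computeStdAf(7, 7, 30, 30), 1)
  expect_equal(computeStdAf(10, 1000, 1000, 20), 0.5)  # 50 x 0.01
  expect_error(computeStdAf(1, 0, 100, 20), "i_ref")
  # linear in both ligand concentration and difference integral
  expect_equal(computeStdAf(3, 100, 800, 20),
               4 * computeStdAf(3, 100, 200, 20))
  expect_equal(computeStdAf(6, 100, 200, 20),
               2 * computeStdAf(3, 100, 200, 20))
})

test_that("buildup fit recovers noiseless parameters and the af0 identity", {
  tsat <- c(0.5, 0.75, 1, 1.5, 2, 2.5, 3.5, 5)
  af <- 1 * (1 - exp(-0.8 * tsat))
  fit <- fitBuildup(tsat, af)
  expect_equal(fit@afMax, 1, tolerance = 1e-5)
  expect_equal(fit@kSat, 0.8, tolerance = 1e-5)
  expect_equal(fit@af0, fit@afMax * fit@kSat)    # exact identity by slot
  expect_equal(fit@af0, 0.8, tolerance = 1e-5)

  # fitted curve is non-decreasing in t for ksat > 0
  tt <- seq(0.1, 6, by = 0.1)
  expect_true(all(diff(fit@afMax * (1 - exp(-fit@kSat * tt))) >= 0))

  z <- fitBuildup(tsat, rep(0, 8))
  expect_equal(z@afMax, 0)
  expect_equal(z@af0, 0)

  expect_error(fitBuildup(c(1, 2), c(0.1, 0.2)), "distinct")
})

test_that("buildup optimizer equals the brute-force SSE grid", {
  tsat <- c(0.5, 1, 2, 3.5, 5)
  af <- 0.55 * (1 - exp(-0.6 * tsat))
  fit <- fitBuildup(tsat, af)
  orc <- oracleBuildupGrid(tsat, af, seq(0.35, 0.75, length.out = 201),
                           seq(0.4, 0.8, length.out = 201))
  expect_lt(abs(fit@afMax - orc["afMax"]), 0.4 / 200)
  expect_lt(abs(fit@kSat - orc["kSat"]), 0.4 / 200)
})

test_that("Langmuir fit recovers Kd, flags degenerate input, and matches its oracle", {
  L <- c(200, 400, 600, 800, 1000)
  af0 <- 0.6 * L / (L + 171)
  fit <- fitLangmuir(L, af0)
  expect_equal(kd(fit), 171, tolerance = 1e-4)
  expect_equal(fit@alphaStd, 0.6, tolerance = 1e-4)
  # half-saturation identity at [L] = Kd
  expect_equal(fit@alphaStd * kd(fit) / (kd(fit) + kd(fit)),
               fit@alphaStd / 2)

  orc <- oracleLangmuirGrid(L, af0, seq(0.5, 0.7, length.out = 201),
                            seq(71, 271, length.out = 201))
  expect_lt(abs(kd(fit) - orc["kd"]), 1)

  plateau <- fitLangmuir(L, rep(0.5, 5))
  expect_true("saturated" %in% plateau@flags)

  expect_warning(fitLangmuir(c(500, 600, 700), 0.5 * c(500, 600, 700) /
                               (c(500, 600, 700) + 171)), "2-fold")
  expect_error(fitLangmuir(c(100, 100, 100), c(0.1, 0.1, 0.1)), "distinct")
})

test_that("Kd combination is the inverse-variance weighted mean", {
  mkL <- function(kd, se, ep) new("LangmuirFit", alphaStd = 0.5, kd = kd,
                                  kdSe = se, alphaSe = 0.01, rss = 0,
                                  epitope = ep, flags = character(0))
  eq <- combineKd(list(mkL(376, 20, "a"), mkL(376, 35, "b"), mkL(376, 50, "c")))
  expect_equal(kd(eq), 376)

  single <- combineKd(list(mkL(212, 15, "a")))
  expect_equal(kd(single), 212)
  expect_equal(single@kdCombinedSe, 15)

  two <- combineKd(list(mkL(100, 10, "a"), mkL(300, 30, "b")))
  expect_equal(kd(two), (100 / 100 + 300 / 900) / (1 / 100 + 1 / 900))
  expect_equal(kd(two), 120)

  expect_warning(noSe <- combineKd(list(mkL(100, NA_real_, "a"),
                                        mkL(200, NA_real_, "b"))), "unweighted")
  expect_equal(kd(noSe), 150)
})

test_that("zero-noise pipeline recovers the fixture Kd with full provenance", {
  ds <- simulateStdDataset(stdFixture("KG-96"), noiseCv = 0, seed = 1)
  est <- runStdPipeline(ds)
  expect_equal(kd(est), 171, tolerance = 1e-3)
  expect_length(est@buildups, 15)       # 3 epitopes x 5 concentrations
  expect_length(est@perEpitope, 3)
})

test_that("Kd is invariant to integral rescaling while alpha scales with it", {
  ds <- simulateStdDataset(stdFixture("KG-408"), noiseCv = 0, seed = 1)
  est1 <- runStdPipeline(ds)
  ds2 <- ds
  ds2@records$i_diff <- ds2@records$i_diff * 3.7
  est2 <- runStdPipeline(ds2)
  expect_equal(kd(est2), kd(est1), tolerance = 1e-6)
  expect_equal(est2@perEpitope[[1]]@alphaStd,
               3.7 * est1@perEpitope[[1]]@alphaStd, tolerance = 1e-6)
  expect_equal(est2@buildups[[1]]@af0, 3.7 * est1@buildups[[1]]@af0,
               tolerance = 1e-6)
})

test_that("noisy-recovery calibration: median Kd error < 10% and SEs cover truth", {
  nSim <- 50
  res <- vapply(seq_len(nSim), function(s) {
    est <- runStdPipeline(simulateStdDataset(stdFixture("KG-96"),
                                             noiseCv = 0.03, seed = 1000 + s))
    c(kd = kd(est), se = est@kdCombinedSe)
  }, numeric(2))
  relErr <- abs(res["kd", ] - 171) / 171
  expect_lt(median(relErr), 0.10)
  covered <- abs(res["kd", ] - 171) <= 2 * res["se", ]
  expect_gte(mean(covered), 0.8)
})
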