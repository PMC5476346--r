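test_that("the SRTM forward model honours its degenerate cases", {
  s <- standardSchedule()
  ft <- fineTimeGrid(s)
  ref <- referenceInputCurve(ft, 300, 10)

  expect_equal(srtmForward(1, 0.15, 0, ref, ft), ref)  # theta2 = 0, R1 = 1
  expect_lt(max(abs(srtmForward(0, 1e-12, 0, ref, ft))), 1e-8)

  expect_error(srtmForward(1, 0.15, -0.2, ref, ft), "bpnd")
  expect_error(srtmForward(1, 0, 0.5, ref, ft), "k2")
  expect_error(srtmForward(1, 0.1, 0.5, ref[1:10], c(0, 1, 3, 4:10)),
               "uniform")
})

test_that("exponential convolution matches the analytic single-exponential result", {
  s <- standardSchedule()
  ft <- fineTimeGrid(s)
  lambda <- 0.05  # per minute
  tmin <- ft / 60
  ref <- exp(-lambda * tmin)
  k2a <- 0.2
  # with r1 = 0, k2 = theta2: C_T = theta2 * (C_R conv exp(-k2a t))
  ct <- srtmForward(0, 0.3, 0.3 / k2a - 1, ref, ft)
  analytic <- 0.3 * (1 - 0) * (exp(-lambda * tmin) - exp(-k2a * tmin)) /
    (k2a - lambda)
  # skip t = 0 where both are zero
  rel <- abs(ct[-1] - analytic[-1]) / pmax(abs(analytic[-1]), 1e-9)
  expect_lt(max(rel), 1e-3)
})

test_that("fitting a region against itself returns BPnd ~ 0 and R1 ~ 1", {
  s <- standardSchedule()
  ref <- simulateReferenceTac(s, 300, 20)
  fit <- suppressWarnings(srtmBasisFit(ref, ref))
  expect_lte(abs(bpnd(fit)), 0.02)
  expect_lt(abs(fit@r1 - 1), 0.02)
})

test_that("noiseless forward curves are recovered within 2% and agree with an NLS oracle", {
  s <- standardSchedule()
  ft <- fineTimeGrid(s)
  refFine <- referenceInputCurve(ft, 300, 20)
  ref <- simulateReferenceTac(s, 300, 20)
  tgt <- simulateTargetTac(refFine, ft, 1.2, 0.12, 0.8, s)
  fit <- srtmBasisFit(tgt, ref)
  expect_lt(abs(bpnd(fit) - 0.8) / 0.8, 0.02)
  expect_lt(abs(fit@r1 - 1.2) / 1.2, 0.02)

  oracle <- srtmNlsOracle(tgt, ref, start = c(1.1, log(0.1), log(0.6)))
  gridRes <- max(diff(log(defaultTheta3Grid())))  # log-spacing of k2a grid
  expect_lt(abs(log(1 + bpnd(fit)) - log(1 + oracle$bpnd)), 2 * gridRes)
})

test_that("the selected basis minimizes the weighted residual sum of squares", {
  s <- standardSchedule()
  ft <- fineTimeGrid(s)
  refFine <- referenceInputCurve(ft, 300, 20)
  ref <- simulateReferenceTac(s, 300, 20)
  set.seed(14)
  tgt <- simulateTargetTac(refFine, ft, 1.1, 0.13, 0.6, s, noise_cv = 0.05)
  grid <- defaultTheta3Grid(32)
  fit <- srtmBasisFit(tgt, ref, grid)

  # oracle: per-theta3 weighted least squares via lm on the same design
  bases <- neurochron:::.srtmBases(
    neurochron:::.refFineFromTac(ref, ft), ft, s, grid)
  wrssAll <- vapply(seq_along(grid), function(g) {
    d <- data.frame(y = activity(tgt), x1 = bases$refFramed, x2 = bases$B[, g])
    sum(fitWeights(tgt) * resid(lm(y ~ 0 + x1 + x2, data = d,
                                   weights = fitWeights(tgt)))^2)
  }, numeric(1))
  expect_equal(fit@gridIndex, which.min(wrssAll))
  expect_lt(abs(fit@wrss - min(wrssAll)), 1e-6 * max(fit@wrss, 1))
  expect_true(all(fit@wrss <= wrssAll + 1e-9))
})

test_that("SRTM estimates are scale invariant and monotone in true BPnd", {
  s <- standardSchedule()
  ft <- fineTimeGrid(s)
  refFine <- referenceInputCurve(ft, 300, 20)
  ref <- simulateReferenceTac(s, 300, 20)
  tgt <- simulateTargetTac(refFine, ft, 1.2, 0.12, 0.5, s)

  f1 <- srtmBasisFit(tgt, ref)
  refScaled <- tac(s, 3 * activity(ref), roiId = "reference")
  tgtScaled <- tac(s, 3 * activity(tgt), roiId = "target")
  f2 <- srtmBasisFit(tgtScaled, refScaled)
  expect_equal(f2@r1, f1@r1, tolerance = 1e-8)
  expect_equal(bpnd(f2), bpnd(f1), tolerance = 1e-8)
  expect_equal(f2@k2aPerMin, f1@k2aPerMin)
  expect_equal(f2@wrss, 9 * f1@wrss, tolerance = 1e-6)

  fits <- vapply(c(0.2, 0.5, 1, 2), function(bp)
    bpnd(srtmBasisFit(simulateTargetTac(refFine, ft, 1.0, 0.15, bp, s), ref)),
    numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("region-batch fitting equals per-region fitting", {
  s <- standardSchedule()
  ft <- fineTimeGrid(s)
  refFine <- referenceInputCurve(ft, 300, 20)
  ref <- simulateReferenceTac(s, 300, 20)
  m <- cbind(a = activity(simulateTargetTac(refFine, ft, 1.2, 0.12, 0.4, s)),
             b = activity(simulateTargetTac(refFine, ft, 0.9, 0.15, 1.3, s)))
  batch <- srtmFitRegions(m, ref)
  fa <- srtmBasisFit(tac(s, m[, "a"], roiId = "a"), ref)
  expect_equal(batch$bpnd[1], bpnd(fa))
  expect_equal(batch$r1[1], fa@r1)
  expect_equal(batch$roi_id, c("a", "b"))
})

test_that("mismatched schedules and bad grids are rejected", {
  s <- standardSchedule()
  s2 <- frameSchedule(rep(60, 90))
  ref <- simulateReferenceTac(s, 300, 20)
  tgt <- tac(s2, rep(1, 90))
  expect_error(srtmBasisFit(tgt, ref), "schedule")
  expect_error(srtmBasisFit(ref, ref, theta3_grid = 0.1), "ascending|2")
})
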