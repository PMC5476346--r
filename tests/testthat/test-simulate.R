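test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- tinyConfig()
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(lapply(a$maps, gmMap), lapply(b$maps, gmMap))
  expect_identical(a$tacs, b$tacs)
  expect_identical(a$regional_bpnd_true, b$regional_bpnd_true)
})

test_that("the test cohort has the configured 46 + 30 = 76 subjects", {
  cfg <- simulationConfig(n_train = 5, n_ds = 46, n_control = 30,
                          grid_dims = c(4, 4, 4))
  sim <- generateCohort(cfg, maps = FALSE, tacs = FALSE)
  expect_equal(sum(sim$cohort$group %in% c("DS", "control")), 76L)
  expect_equal(sum(sim$cohort$group == "DS"), 46L)
  # dementia-class DS subjects may be unable to complete the CAMCOG
  expect_lte(sum(is.na(sim$cohort$camcog[sim$cohort$group == "DS"])), 3L)
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(simulationConfig(n_ds = 0), "nDs")
  expect_error(simulationConfig(age_range_test = c(50, 50)), "ageRangeTest")
  expect_error(simulationConfig(atrophy_rate = 0.02), "atrophyRate")
  expect_error(simulationConfig(grid_dims = c(3, 8, 8)), "gridDims")
  expect_error(simulationConfig(pib_pos_fraction = 1.4), "pibPosFraction")
})

test_that("tissue maps atrophy monotonically and stay valid probabilities", {
  cfg <- tinyConfig(atrophy_rate = 0, feature_noise_sd = 0)
  m1 <- simulateTissueMaps(20, cfg)
  m2 <- simulateTissueMaps(80, cfg)
  expect_identical(gmMap(m1), gmMap(m2))  # no atrophy, no noise

  cfg2 <- tinyConfig(feature_noise_sd = 0)
  young <- simulateTissueMaps(18, cfg2)
  old <- simulateTissueMaps(90, cfg2)
  expect_lt(mean(gmMap(old)), mean(gmMap(young)))

  # exhaustive per-voxel scan across random subjects
  set.seed(11)
  for (i in 1:100) {
    m <- simulateTissueMaps(runif(1, 18, 98), tinyConfig())
    tot <- gmMap(m) + wmMap(m) + csfMap(m)
    expect_true(all(tot >= 0 & tot <= 1 + 1e-9))
    expect_true(all(gmMap(m) >= 0 & gmMap(m) <= 1))
  }
})

test_that("control-stratum GM volume regressed on age recovers the atrophy slope", {
  cfg <- tinyConfig(feature_noise_sd = 0.02)
  fields <- neurochron:::.spatialFields(cfg@gridDims)
  voxL <- prod(cfg@voxelSizeMm) * 1e-6
  expectedSlope <- -cfg@atrophyRate * sum(fields$pattern) * voxL
  set.seed(21)
  ages <- runif(200, 20, 85)
  gmvol <- vapply(ages, function(a)
    sum(gmMap(simulateTissueMaps(a, cfg))) * voxL, numeric(1))
  fit <- summary(lm(gmvol ~ ages))
  expect_lt(abs(fit$coefficients[2, 1] - expectedSlope),
            2 * fit$coefficients[2, 2])
})

test_that("the reference input curve peaks at its mode and rejects bad peaks", {
  expect_equal(referenceInputCurve(300, peak_time_s = 300, scale = 7), 7)
  expect_equal(referenceInputCurve(0, 300, 7), 0)
  expect_error(referenceInputCurve(10, peak_time_s = 0), "peak")
})

test_that("simulated target TACs honour the SRTM degenerate cases", {
  s <- standardSchedule()
  ft <- fineTimeGrid(s)
  refFine <- referenceInputCurve(ft, 300, 20)
  ref <- simulateReferenceTac(s, 300, 20)

  # R1 = 1, BPnd = 0: target is the reference
  t1 <- simulateTargetTac(refFine, ft, 1, 0.15, 0, s)
  expect_lt(max(abs(activity(t1) - activity(ref))), 1e-9)

  # R1 = 0 with theta2 -> 0: flat zero curve
  t2 <- simulateTargetTac(refFine, ft, 0, 1e-9, 0, s)
  expect_lt(max(abs(activity(t2))), 1e-6)

  expect_error(simulateTargetTac(refFine, ft, 1, 0.15, -0.1, s), "bpnd")

  # noiseless frame noise path: noise_cv = 0 reproduces exactly
  t3a <- simulateTargetTac(refFine, ft, 1.1, 0.12, 0.6, s, noise_cv = 0)
  t3b <- simulateTargetTac(refFine, ft, 1.1, 0.12, 0.6, s, noise_cv = 0)
  expect_identical(activity(t3a), activity(t3b))
})

test_that("striatal BP_ND truth is bimodal with well-separated components", {
  cfg <- simulationConfig(n_train = 2, n_ds = 400, n_control = 2,
                          grid_dims = c(4, 4, 4), seed = 9)
  sim <- generateCohort(cfg, maps = FALSE, tacs = FALSE)
  ds <- sim$cohort[sim$cohort$group == "DS", ]
  posv <- ds$striatal_bpnd_true[ds$pib_positive_true]
  negv <- ds$striatal_bpnd_true[!ds$pib_positive_true]
  sep <- (mean(posv) - mean(negv)) / mean(c(sd(posv), sd(negv)))
  expect_gte(sep, 3.5)
  # and the configured components themselves satisfy the design separation
  cfgSep <- (cfg@bpndPosMean - cfg@bpndNegMean) /
    mean(c(cfg@bpndNegSd, cfg@bpndPosSd))
  expect_gte(cfgSep, 4)
})

test_that("null group offset gives equal DS and control age-slopes in GM volume", {
  cfg <- tinyConfig(group_offset_years = 0, pad_sd_years = 0,
                    csf_shrink_ds = 1, n_train = 2, n_ds = 120,
                    n_control = 120, seed = 31)
  sim <- generateCohort(cfg, tacs = FALSE)
  voxL <- prod(cfg@voxelSizeMm) * 1e-6
  gmvol <- vapply(sim$maps, function(m) sum(gmMap(m)) * voxL, numeric(1))
  keep <- sim$cohort$group != "train"
  d <- data.frame(gm = gmvol[keep], age = sim$cohort$age_years[keep],
                  grp = factor(sim$cohort$group[keep],
                               levels = c("control", "DS")))
  fit <- summary(lm(gm ~ age * grp, data = d))
  expect_gt(fit$coefficients["age:grpDS", 4], 0.05)
})
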