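test_that("the catalog holds 30 non-reference ROIs with a 4-region striatal set", {
  cat <- roiCatalog()
  expect_equal(sum(cat$class != "reference"), 30L)
  expect_setequal(cat$roi_id[cat$class == "striatal"],
                  c("caudate_l", "caudate_r", "putamen_l", "putamen_r"))
  expect_equal(sum(cat$class == "cortical"), 20L)
})

test_that("striatal BPnd is the unweighted mean over caudate and putamen", {
  cat <- roiCatalog()
  v <- c(caudate_l = 0.2, caudate_r = 0.2, putamen_l = 0.4, putamen_r = 0.4)
  expect_equal(striatalBpnd(v, cat), 0.3)
  expect_equal(striatalBpnd(c(v * 0), cat), 0)
  v4 <- c(caudate_l = 0.1, caudate_r = 0.3, putamen_l = 0.25, putamen_r = 0.15)
  expect_equal(striatalBpnd(v4, cat), mean(v4))
  expect_error(striatalBpnd(v[-1], cat), "caudate_l")
})

test_that("PiB-status classification handles degenerate and boundary cases", {
  z <- rep(0, 10)
  cls <- classifyPibStatus(z)
  expect_true(all(cls$status == "negative"))
  expect_equal(cls$sigma0, 1e-6)

  # fixed-sigma boundary: >= sigma is positive
  cls2 <- classifyPibStatus(c(0.04, 0.06, 0.01), sd_mode = "fixed",
                            fixed_sd = 0.05)
  expect_equal(as.character(cls2$status), c("negative", "positive", "negative"))

  expect_error(classifyPibStatus(c(0, 0.1)), "3 subjects")
  expect_error(classifyPibStatus(c(1, 2), sd_mode = "fixed"), "3 subjects")
})

test_that("classification agrees with the generating labels on the bimodal mixture", {
  set.seed(33)
  agree <- replicate(40, {
    lab <- rbinom(46, 1, 19 / 46)
    x <- ifelse(lab == 1, rnorm(46, 0.4, 0.15), rnorm(46, 0, 0.05))
    cls <- classifyPibStatus(x)
    mean((cls$status == "positive") == (lab == 1))
  })
  expect_gte(mean(agree), 0.9)
})

test_that("classification is order invariant and monotone under fixed sigma", {
  set.seed(34)
  x <- c(rnorm(30, 0, 0.05), rnorm(16, 0.4, 0.15))
  p <- sample(length(x))
  a <- classifyPibStatus(x)
  b <- classifyPibStatus(x[p])
  expect_identical(as.character(a$status)[p], as.character(b$status))

  # raising one subject's value can never flip positive -> negative
  fx <- classifyPibStatus(x, sd_mode = "fixed", fixed_sd = 0.1)
  x2 <- x; x2[5] <- x2[5] + 0.5
  fx2 <- classifyPibStatus(x2, sd_mode = "fixed", fixed_sd = 0.1)
  expect_false(fx$status[5] == "positive" && fx2$status[5] == "negative")
})

test_that("regional abnormality applies the >= 2 SD rule including degenerate SD", {
  bp <- rbind(s1 = c(r1 = 0.0, r2 = 0.5), s2 = c(0.02, 0.5),
              s3 = c(-0.02, 0.5), s4 = c(0.3, 0.5))
  status <- c("negative", "negative", "negative", "positive")
  fl <- regionalAbnormality(bp, status)
  # r1 over negatives: mean 0, sd 0.02 -> threshold 0.04
  expect_false(fl["s1", "r1"]); expect_true(fl["s4", "r1"])
  # r2 is constant (sd 0): equality with the mean counts as abnormal
  expect_true(all(fl[, "r2"]))

  # exact boundary: value == mean + 2 sd is abnormal
  bp2 <- rbind(c(0, 1), c(0.02, 1), c(0.04, 1))
  fl2 <- regionalAbnormality(bp2, c("negative", "negative", "positive"))
  expect_true(fl2[3, 1])  # 0.04 == 0.01 + 2 * 0.015... check numerically
  mu <- mean(c(0, 0.02)); s <- sd(c(0, 0.02))
  expect_equal(bp2[3, 1] >= mu + 2 * s, fl2[3, 1])

  expect_error(regionalAbnormality(bp, rep("positive", 4)), "2 PiB-negative")
})

test_that("abnormality flags match a brute-force recomputation", {
  set.seed(35)
  cat <- roiCatalog()
  rois <- cat$roi_id[cat$class != "reference"]
  bp <- matrix(rnorm(20 * 30, 0.1, 0.1), 20,
               dimnames = list(sprintf("s%02d", 1:20), rois))
  status <- sample(c("negative", "positive"), 20, TRUE, prob = c(0.6, 0.4))
  fl <- regionalAbnormality(bp, status)
  for (r in sample(rois, 6)) {
    mu <- mean(bp[status == "negative", r])
    s <- sd(bp[status == "negative", r])
    expect_identical(unname(fl[, r]), unname(bp[, r] >= mu + 2 * s))
  }
})

test_that("profile summaries count abnormal ROIs over the 30-ROI catalog", {
  cat <- roiCatalog()
  rois <- cat$roi_id[cat$class != "reference"]
  bp <- matrix(0.1, 3, 30, dimnames = list(c("a", "b", "c"), rois))
  flNone <- matrix(FALSE, 3, 30, dimnames = dimnames(bp))
  prof <- summarizeProfiles(flNone, bp, cat, striatal = rep(0.1, 3),
                            status = rep("negative", 3))
  expect_equal(prof$abnormal_count, c(0, 0, 0))

  flAll <- matrix(TRUE, 3, 30, dimnames = dimnames(bp))
  profAll <- summarizeProfiles(flAll, bp, cat, rep(0.1, 3),
                               rep("positive", 3))
  expect_equal(profAll$abnormal_count, c(30, 30, 30))

  set.seed(36)
  fl <- matrix(runif(90) < 0.3, 3, 30, dimnames = dimnames(bp))
  profR <- summarizeProfiles(fl, bp, cat, rep(0.1, 3), rep("negative", 3))
  expect_equal(profR$abnormal_count, unname(rowSums(fl)))
  expect_equal(profR$mean_cortical_bpnd,
               unname(rowMeans(bp[, cat$roi_id[cat$class == "cortical"]])))
})

test_that("synthetic PiB-negative subjects rarely show non-striatal abnormality", {
  cleanFrac <- vapply(1:20, function(s) {
    cfg <- simulationConfig(n_ds = 46, n_control = 2, n_train = 2,
                            grid_dims = c(4, 4, 4), seed = s)
    sim <- generateCohort(cfg, maps = FALSE, tacs = FALSE)
    am <- amyloidProfiles(sim$regional_bpnd_true, sim$catalog)
    ns <- sim$catalog$roi_id[!sim$catalog$class %in%
                               c("striatal", "reference")]
    neg <- !sim$cohort$pib_positive_true[sim$cohort$group == "DS"]
    mean(rowSums(am$flags[neg, ns, drop = FALSE]) == 0)
  }, numeric(1))
  expect_gte(mean(cleanFrac), 0.95)
})
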