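test_that("a binary-predictor OLS coefficient is exactly the group-mean difference", {
  # groups constructed to have the cohort's printed means: 2.49 and -5.20
  ds <- 2.49 + c(-3, -1, 0, 1, 3)
  ctl <- -5.20 + c(-2, -1, 0, 1, 2)
  d <- data.frame(pad = c(ds, ctl),
                  group = factor(rep(c("DS", "control"), c(5, 5)),
                                 levels = c("control", "DS")))
  fit <- linearModel(pad ~ group, d)
  b <- fit@terms$estimate[fit@terms$term == "groupDS"]
  expect_equal(b, mean(ds) - mean(ctl))
  expect_equal(b, 7.69, tolerance = 1e-12)
})

test_that("OLS matches the normal-equations oracle and flags collinearity", {
  set.seed(41)
  d <- data.frame(x1 = rnorm(6), x2 = rnorm(6))
  d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(6, 0, 0.1)
  fit <- linearModel(y ~ x1 + x2, d)
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_lt(max(abs(fit@terms$estimate - drop(beta))), 1e-10)
  expect_true(all(fit@terms$ci_low <= fit@terms$estimate))

  d$x3 <- d$x1  # perfect duplicate
  expect_error(linearModel(y ~ x1 + x3, d), "collinear")
})

test_that("logistic regression matches a Newton-Raphson oracle and its symmetries", {
  # intercept-only with 25% positives: log odds = log(1/3)
  d0 <- data.frame(y = c(1, 0, 0, 0, 1, 0, 0, 0))
  f0 <- logisticModel(y ~ 1, d0)
  expect_equal(f0@terms$estimate, log(1 / 3), tolerance = 1e-8)

  set.seed(42)
  d <- data.frame(x = rnorm(10))
  d$y <- as.integer(plogis(0.5 + d$x) > runif(10))
  fit <- logisticModel(y ~ x, d)
  oracle <- logisticOracle(cbind(1, d$x), d$y)
  expect_lt(max(abs(fit@terms$estimate - oracle$beta)), 1e-8)
  expect_lt(max(abs(fit@terms$se - oracle$se)), 1e-6)

  d$y2 <- 1 - d$y
  flipped <- logisticModel(y2 ~ x, d)
  expect_equal(flipped@terms$estimate, -fit@terms$estimate, tolerance = 1e-6)
})

test_that("ordinal regression collapses to logistic with two levels and recovers beta", {
  set.seed(43)
  n <- 80
  x <- rnorm(n)
  y2 <- factor(ifelse(plogis(-0.3 + 0.9 * x) > runif(n), "hi", "lo"),
               levels = c("lo", "hi"))
  d2 <- data.frame(y = y2, x = x)
  ofit <- ordinalLogistic(y ~ x, d2, levels = c("lo", "hi"))
  gfit <- logisticModel(I(y == "hi") ~ x, d2)
  expect_equal(ofit@terms$estimate[ofit@terms$term == "x"],
               gfit@terms$estimate[gfit@terms$term == "x"], tolerance = 1e-6)

  # proportional-odds recovery: latent logistic with beta = 1, cuts 0 and 2
  set.seed(44)
  n <- 500
  x <- rnorm(n)
  lat <- x + rlogis(n)
  y <- cut(lat, c(-Inf, 0, 2, Inf), labels = c("a", "b", "c"))
  d <- data.frame(y = y, x = x)
  fit <- ordinalLogistic(y ~ x, d, levels = c("a", "b", "c"))
  bx <- fit@terms[fit@terms$term == "x", ]
  expect_lt(abs(bx$estimate - 1), 2 * bx$se)
  thr <- fit@terms$estimate[grepl("^threshold", fit@terms$term)]
  expect_true(all(diff(thr) > 0))

  expect_error(ordinalLogistic(y ~ x, d[d$y == "a", , drop = FALSE]),
               "level")
})

test_that("t-tests match hand formulas and their invariances", {
  g <- c(1.2, 3.1, 2.2, 4.0)
  expect_equal(twoSampleT(g, g)$statistic, 0)
  expect_equal(twoSampleT(g, g)$p, 1)

  x <- c(5.1, 4.2, 6.3, 5.5, 4.9)
  y <- c(3.0, 3.8, 2.9, 3.6)
  tt <- twoSampleT(x, y)
  seW <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_lt(abs(tt$statistic - (mean(x) - mean(y)) / seW), 1e-12)
  expect_equal(twoSampleT(3 * x, 3 * y)$statistic, tt$statistic,
               tolerance = 1e-12)

  o <- oneSampleT(x, mu = 5)
  expect_lt(abs(o$statistic - (mean(x) - 5) / (sd(x) / sqrt(5))), 1e-12)
  refl <- oneSampleT(2 * 5 - x, mu = 5)
  expect_equal(refl$statistic, -o$statistic, tolerance = 1e-12)
  expect_equal(oneSampleT(c(4, 5, 6), mu = 5)$statistic, 0)
  expect_error(oneSampleT(rep(2, 5), 1), "variance")
})

test_that("Pearson correlation matches the closed form", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearsonCor(x, x)$r, 1)
  expect_equal(pearsonCor(x, -x)$r, -1)
  set.seed(45)
  a <- rnorm(12); b <- rnorm(12)
  pc <- pearsonCor(a, b)
  rHand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_lt(abs(pc$r - rHand), 1e-12)
  tHand <- rHand * sqrt(10 / (1 - rHand^2))
  expect_lt(abs(pc$p - 2 * pt(-abs(tHand), 10)), 1e-12)
  expect_warning(pearsonCor(rep(1, 5), rnorm(5)), "variance")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  even <- matrix(c(5, 5, 5, 5), 2)
  fe <- fisherExact(even)
  expect_equal(fe$p, 1)
  expect_equal(fe$odds_ratio, 1)

  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisherExact(tab)$p, fisherOracle(tab), tolerance = 1e-12)
  tab2 <- matrix(c(7, 2, 3, 8), 2)
  expect_equal(fisherExact(tab2)$p, fisherOracle(tab2), tolerance = 1e-12)
  expect_equal(fisherExact(tab2)$odds_ratio, (7 * 8) / (2 * 3))

  expect_error(fisherExact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  expect_error(fisherExact(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("the association battery emits the twelve documented models", {
  cfg <- simulationConfig(n_train = 2, n_ds = 46, n_control = 30,
                          grid_dims = c(4, 4, 4), seed = 5)
  sim <- generateCohort(cfg, maps = FALSE, tacs = FALSE)
  tbl <- sim$cohort[sim$cohort$group != "train", ]
  set.seed(51)
  tbl$brain_pad <- tbl$brainpad_true + rnorm(nrow(tbl), 0, 1)
  tbl$icv_l <- rnorm(nrow(tbl), 1.4, 0.1) -
    0.12 * (tbl$group == "DS")
  tbl$pib_status <- ifelse(is.na(tbl$pib_positive_true), "negative",
                           ifelse(tbl$pib_positive_true, "positive",
                                  "negative"))
  tbl$mean_cortical_bpnd <- ifelse(tbl$group == "DS",
                                   pmax(0, 0.9 * tbl$striatal_bpnd_true), NA)
  tbl$abnormal_count <- ifelse(tbl$pib_status == "positive",
                               rbinom(nrow(tbl), 30, 0.8), 0)
  models <- suppressWarnings(runAssociationModels(tbl))
  expect_length(models, 12L)
  expect_named(models, c("brainpad_group", "icv_group",
                         "pibstatus_brainpad_age",
                         "cortical_bpnd_brainpad_age",
                         "abnormal_count_brainpad_age", "camcog_brainpad",
                         "camcog_brainpad_x_pib", "camdex_brainpad",
                         "camdex_brainpad_pib", "camcog_bpnd_brainpad",
                         "brainpad_group_stable", "brainpad_icv_cor"))
  tab <- associationTable(models)
  expect_true(all(c("model_name", "term", "estimate", "p") %in% names(tab)))
  # the generated DS offset shows up in the group model
  bg <- models$brainpad_group@terms
  expect_gt(bg$estimate[bg$term == "groupDS"], 0)
  # ICV is reduced in DS
  ig <- models$icv_group@terms
  expect_lt(ig$estimate[ig$term == "groupDS"], 0)

  expect_error(runAssociationModels(tbl[, setdiff(names(tbl), "camcog")]),
               "camcog")

  dem <- demographicTests(tbl)
  expect_true(all(c("sex_ttest", "sex_group_fisher", "camdex_pib_fisher") %in%
                    names(dem)))
  expect_true(dem$camdex_pib_fisher$p >= 0 && dem$camdex_pib_fisher$p <= 1)
})

test_that("the generated CAMCOG interaction is recovered with the right sign", {
  cfg <- simulationConfig(n_train = 2, n_ds = 46, n_control = 2,
                          grid_dims = c(4, 4, 4), seed = 61)
  sim <- generateCohort(cfg, maps = FALSE, tacs = FALSE)
  ds <- sim$cohort[sim$cohort$group == "DS", ]
  ds$brain_pad <- ds$brainpad_true
  ds$pib_status <- factor(ifelse(ds$pib_positive_true, "positive",
                                 "negative"), c("negative", "positive"))
  fit <- linearModel(camcog ~ brain_pad * pib_status, ds)
  it <- fit@terms[fit@terms$term == "brain_pad:pib_statuspositive", ]
  expect_lt(it$estimate, 0)
  expect_lt(abs(it$estimate - (-cfg@camcogInteractionSlope)), 2.5 * it$se)
})
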