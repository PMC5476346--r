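## Association statistics: OLS, logistic and ordinal (proportional-odds)
## regression, t-tests, Pearson correlations, Fisher's exact test, and the
## cohort model battery relating brain-PAD to group, amyloid and cognition.
## Estimation is delegated to the standard fitters (stats::lm, stats::glm,
## MASS::polr, stats::t.test, stats::cor.test, stats::fisher.test); this
## module defines the model surface and tidy reporting.

.termTable <- function(est, se, statistic, p, ci) {
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(statistic), p = unname(p),
             ci_low = unname(ci[, 1L]), ci_high = unname(ci[, 2L]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ordinary least-squares linear model with tidy output
#'
#' Wald t statistics and 95\% CIs \code{estimate +/- t(0.975, n - p) * SE}.
#' Listwise deletion of missing data.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @param model_name label for the result.
#' @return A \linkS4class{ModelResult} (with R-squared).
#' @export
linearModel <- function(formula, data, model_name = deparse(formula)) {
  fit <- stats::lm(formula, data = data)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  sm <- summary(fit)
  ci <- stats::confint(fit)
  .modelResult(model_name,
               .termTable(cf, sm$coefficients[, 2L], sm$coefficients[, 3L],
                          sm$coefficients[, 4L], ci),
               n = length(stats::resid(fit)), kind = "t",
               r2 = sm$r.squared)
}

#' Logistic regression with tidy Wald output
#'
#' Maximum likelihood via iteratively reweighted least squares; Wald z
#' statistics and CIs on the log-odds scale. Complete separation is flagged
#' with a warning and the estimates are still reported.
#'
#' @param formula model formula with a binary (0/1 or two-level) outcome.
#' @param data data.frame.
#' @param model_name label.
#' @return A \linkS4class{ModelResult}.
#' @export
logisticModel <- function(formula, data, model_name = deparse(formula)) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, family = stats::binomial(), data = data),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged)
    warning(sprintf("possible complete separation in '%s'; estimates unstable",
                    model_name), call. = FALSE)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design; collinear term(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")))
  sm <- summary(fit)
  se <- sm$coefficients[, 2L]
  z <- sm$coefficients[, 3L]
  ci <- cbind(cf - stats::qnorm(0.975) * se, cf + stats::qnorm(0.975) * se)
  .modelResult(model_name, .termTable(cf, se, z, sm$coefficients[, 4L], ci),
               n = length(stats::resid(fit)), kind = "z")
}

#' Proportional-odds ordinal logistic regression
#'
#' Cumulative-logit maximum likelihood (via \code{MASS::polr}); slope terms
#' are reported with Wald z statistics, followed by the strictly increasing
#' thresholds. With a two-level outcome this reduces to plain logistic
#' regression.
#'
#' @param formula model formula; the outcome is coerced to an ordered factor.
#' @param data data.frame.
#' @param model_name label.
#' @param levels optional explicit level order for the outcome.
#' @return A \linkS4class{ModelResult}; threshold rows are named
#'   \code{"threshold: a|b"}.
#' @export
ordinalLogistic <- function(formula, data, model_name = deparse(formula),
                            levels = NULL) {
  resp <- all.vars(formula)[1L]
  y <- data[[resp]]
  if (!is.null(levels)) y <- factor(y, levels = levels)
  y <- droplevels(factor(y, ordered = TRUE,
                         levels = if (is.factor(y)) base::levels(y) else sort(unique(y))))
  if (nlevels(y) < 2L)
    stop(sprintf("outcome '%s' has an empty level structure (< 2 observed levels)",
                 resp))
  data[[resp]] <- y
  if (nlevels(y) == 2L) {
    ## collapse case: the cumulative-logit model with one threshold is plain
    ## logistic regression on the upper level (threshold = -intercept)
    hi <- levels(y)[2L]
    data$.y01 <- as.integer(y == hi)
    f2 <- stats::update(formula, .y01 ~ .)
    lr <- logisticModel(f2, data, model_name = model_name)
    tt <- lr@terms
    int <- tt$term == "(Intercept)"
    tt[int, c("estimate", "ci_low", "ci_high", "statistic")] <-
      -tt[int, c("estimate", "ci_high", "ci_low", "statistic")]
    tt$term[int] <- sprintf("threshold: %s|%s", levels(y)[1L], hi)
    tt <- rbind(tt[!int, , drop = FALSE], tt[int, , drop = FALSE])
    return(.modelResult(model_name, tt, n = lr@n, kind = "z"))
  }
  fit <- MASS::polr(formula, data = data, Hess = TRUE)
  sm <- summary(fit)
  tab <- sm$coefficients  # slopes then zeta thresholds
  nslope <- length(stats::coef(fit))
  est <- tab[, 1L]; se <- tab[, 2L]; z <- tab[, 3L]
  p <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(est - stats::qnorm(0.975) * se, est + stats::qnorm(0.975) * se)
  nm <- rownames(tab)
  if (nrow(tab) > nslope)
    nm[(nslope + 1L):nrow(tab)] <-
      paste0("threshold: ", nm[(nslope + 1L):nrow(tab)])
  zeta <- fit$zeta
  if (length(zeta) > 1L && any(diff(zeta) <= 0))
    stop("fitted thresholds are not strictly increasing")
  tt <- .termTable(stats::setNames(est, nm), se, z, p, ci)
  .modelResult(model_name, tt, n = fit$n, kind = "z")
}

#' Two-sample t-test (Welch by default)
#'
#' @param x,y the two groups (each n >= 2).
#' @param var_equal use the pooled-variance Student test instead of Welch.
#' @return list: statistic, p, df, estimate (mean difference x - y), ci.
#' @export
twoSampleT <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::var(x) < 1e-24 && stats::var(y) < 1e-24) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, p = 1, df = NA_real_,
                  estimate = mean(x) - mean(y), ci = c(NA_real_, NA_real_)))
    stop("degenerate zero variance in both groups")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), estimate = mean(x) - mean(y),
       ci = unname(tt$conf.int))
}

#' One-sample t-test against a reference mean
#'
#' @param x values (n >= 2); \code{mu} the reference mean.
#' @param mu reference mean.
#' @return list: statistic, p, df, estimate (mean), ci.
#' @export
oneSampleT <- function(x, mu = 0) {
  if (length(x) < 2L) stop("need n >= 2")
  if (stats::var(x) < 1e-24) stop("zero variance")
  tt <- stats::t.test(x, mu = mu)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), estimate = mean(x),
       ci = unname(tt$conf.int))
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @return list: r, p, df, ci.
#' @export
pearsonCor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 complete pairs")
  if (stats::var(x) < 1e-24 || stats::var(y) < 1e-24) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, df = NA_real_,
                ci = c(NA_real_, NA_real_), statistic = NA_real_))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), ci = unname(ct$conf.int),
       statistic = unname(ct$statistic))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by point-probability hypergeometric enumeration (the classic
#' rule implemented by \code{stats::fisher.test}); the reported odds ratio is
#' the sample cross-product ratio ad/bc (the conditional-MLE estimate is
#' returned alongside).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list: odds_ratio (ad/bc), conditional_or, p.
#' @export
fisherExact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a table margin is all zero")
  ft <- stats::fisher.test(tab)
  list(odds_ratio = (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]),
       conditional_or = unname(ft$estimate), p = ft$p.value)
}

.requireColumns <- function(tbl, cols) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
}

#' The cohort association-model battery
#'
#' Fits, in a fixed documented order, the twelve models relating brain-PAD to
#' group, amyloid measures and cognition: (1) brain-PAD ~ group;
#' (2) ICV ~ group; (3) logistic PiB-status ~ brain-PAD + age;
#' (4) mean cortical BP_ND ~ brain-PAD + age;
#' (5) abnormal-ROI count ~ brain-PAD + age; (6) CAMCOG ~ brain-PAD;
#' (7) CAMCOG ~ brain-PAD x PiB-status; (8) ordinal CAMDEX ~ brain-PAD;
#' (9) ordinal CAMDEX ~ brain-PAD + PiB-status;
#' (10) CAMCOG ~ mean cortical BP_ND + brain-PAD;
#' (11) brain-PAD ~ group restricted to CAMDEX-stable DS plus controls;
#' (12) Pearson correlations brain-PAD ~ ICV within each group.
#' Models 3-10 use DS subjects only; CAMCOG models drop subjects with missing
#' scores (listwise deletion). Group is coded with controls as reference, so
#' the group coefficient is the DS - control difference.
#'
#' @param tbl merged analysis table with columns subject_id, age_years,
#'   group ("DS"/"control"; training rows are ignored), brain_pad, icv_l and,
#'   for DS rows, pib_status ("negative"/"positive"), mean_cortical_bpnd,
#'   abnormal_count, camcog, camdex_class.
#' @return named list of twelve \linkS4class{ModelResult}s; see
#'   \code{\link{associationTable}} for a single tidy table.
#' @export
runAssociationModels <- function(tbl) {
  .requireColumns(tbl, c("subject_id", "age_years", "group", "brain_pad",
                         "icv_l", "pib_status", "mean_cortical_bpnd",
                         "abnormal_count", "camcog", "camdex_class"))
  test <- tbl[tbl$group %in% c("DS", "control"), , drop = FALSE]
  test$group <- factor(test$group, levels = c("control", "DS"))
  ds <- test[test$group == "DS", , drop = FALSE]
  ds$pib_status <- factor(ds$pib_status, levels = c("negative", "positive"))
  ds$pib01 <- as.integer(ds$pib_status == "positive")

  out <- list(
    brainpad_group = linearModel(brain_pad ~ group, test, "brainpad_group"),
    icv_group = linearModel(icv_l ~ group, test, "icv_group"),
    pibstatus_brainpad_age = logisticModel(pib01 ~ brain_pad + age_years, ds,
                                           "pibstatus_brainpad_age"),
    cortical_bpnd_brainpad_age = linearModel(
      mean_cortical_bpnd ~ brain_pad + age_years, ds,
      "cortical_bpnd_brainpad_age"),
    abnormal_count_brainpad_age = linearModel(
      abnormal_count ~ brain_pad + age_years, ds,
      "abnormal_count_brainpad_age"),
    camcog_brainpad = linearModel(camcog ~ brain_pad, ds, "camcog_brainpad"),
    camcog_brainpad_x_pib = linearModel(camcog ~ brain_pad * pib_status, ds,
                                        "camcog_brainpad_x_pib"),
    camdex_brainpad = ordinalLogistic(
      camdex_class ~ brain_pad, ds, "camdex_brainpad",
      levels = c("stable", "declining", "dementia")),
    camdex_brainpad_pib = ordinalLogistic(
      camdex_class ~ brain_pad + pib_status, ds, "camdex_brainpad_pib",
      levels = c("stable", "declining", "dementia")),
    camcog_bpnd_brainpad = linearModel(
      camcog ~ mean_cortical_bpnd + brain_pad, ds, "camcog_bpnd_brainpad"),
    brainpad_group_stable = linearModel(
      brain_pad ~ group,
      test[test$group == "control" |
             (!is.na(test$camdex_class) & test$camdex_class == "stable"), ],
      "brainpad_group_stable"))

  corRows <- lapply(c("DS", "control"), function(g) {
    sub <- test[test$group == g, ]
    pc <- pearsonCor(sub$brain_pad, sub$icv_l)
    data.frame(term = g, estimate = pc$r, se = NA_real_,
               statistic = pc$statistic, p = pc$p, ci_low = pc$ci[1L],
               ci_high = pc$ci[2L], stringsAsFactors = FALSE)
  })
  out$brainpad_icv_cor <- .modelResult("brainpad_icv_cor",
                                       do.call(rbind, corRows),
                                       n = nrow(test), kind = "r")
  out
}

#' Stack association results into one tidy table
#'
#' @param models list of \linkS4class{ModelResult}s (as returned by
#'   \code{\link{runAssociationModels}}).
#' @return data.frame: model_name, term, estimate, se, statistic, p, ci_low,
#'   ci_high, n, statistic_kind, r_squared.
#' @export
associationTable <- function(models) {
  do.call(rbind, lapply(models, resultsTable))
}

#' Demographic and categorical comparisons
#'
#' The simple group comparisons surrounding the model battery: brain-PAD
#' t-tests by sex and by APOE-e4 carrier status (DS subjects with known
#' genotype), Fisher's exact test of sex by group, and the binary CAMDEX
#' collapse (stable vs not stable): its Fisher test against PiB status and
#' the brain-PAD t-test between the two CAMDEX subgroups.
#'
#' @param tbl merged analysis table (see \code{\link{runAssociationModels}}).
#' @return named list: sex_ttest, apoe_ttest, sex_group_fisher,
#'   camdex_pib_fisher, camdex_binary_ttest.
#' @export
demographicTests <- function(tbl) {
  .requireColumns(tbl, c("group", "brain_pad", "sex"))
  test <- tbl[tbl$group %in% c("DS", "control"), , drop = FALSE]
  ds <- test[test$group == "DS", , drop = FALSE]
  out <- list()
  out$sex_ttest <- twoSampleT(test$brain_pad[test$sex == "male"],
                              test$brain_pad[test$sex == "female"])
  if ("apoe_e4_carrier" %in% names(tbl)) {
    keep <- !is.na(ds$apoe_e4_carrier)
    out$apoe_ttest <- twoSampleT(ds$brain_pad[keep & ds$apoe_e4_carrier == "yes"],
                                 ds$brain_pad[keep & ds$apoe_e4_carrier == "no"])
  }
  out$sex_group_fisher <- fisherExact(table(test$sex, as.character(test$group)))
  if (all(c("camdex_class", "pib_status") %in% names(tbl))) {
    stable <- ifelse(ds$camdex_class == "stable", "stable", "not_stable")
    out$camdex_pib_fisher <- fisherExact(table(stable, ds$pib_status))
    out$camdex_binary_ttest <- twoSampleT(ds$brain_pad[stable == "stable"],
                                          ds$brain_pad[stable == "not_stable"])
  }
  out
}
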