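## Kernel Gaussian-process age regression: hyperparameter estimation by
## marginal likelihood, mean predictions, k-fold cross-validation, accuracy
## metrics, permutation significance and brain-PAD.

.JITTER_SCALE <- 1e-8

## negative log marginal likelihood in the eigenbasis of the normalized kernel
.gpNll <- function(par, evals, z2, jit) {
  d <- exp(par[1L]) * evals + exp(par[2L]) + jit
  0.5 * sum(z2 / d) + 0.5 * sum(log(d))
}

#' Fit a Gaussian-process age regression on a kernel matrix
#'
#' The kernel is first double-centred (equivalent to removing the feature
#' mean, which otherwise dominates the spectrum through the constant anatomy
#' component) and then normalized by its mean diagonal; ages are centred on
#' their mean. Unless fixed hyperparameters are supplied, the signal and noise
#' variances maximize the GP log marginal likelihood under covariance
#' \code{signalVar * Ktilde + noiseVar * I}, optimized by L-BFGS-B in
#' \code{(log signalVar, log noiseVar)} from the fixed start
#' \code{(0, log(var(ages)) / 2)}. A diagonal jitter of
#' \code{1e-8 * trace / N} stabilizes the solve.
#'
#' @param K N x N training kernel (positive semidefinite).
#' @param ages chronological ages in years.
#' @param subject_ids training subject identifiers (default: K's row names).
#' @param hyper optional list(signal_var, noise_var) of fixed
#'   hyperparameters, skipping optimization.
#' @return A \linkS4class{GPRModel}.
#' @export
fitGPR <- function(K, ages, subject_ids = rownames(K), hyper = NULL) {
  if (!is.matrix(K) || nrow(K) != ncol(K)) stop("K must be square")
  n <- nrow(K)
  if (length(ages) != n) stop("length(ages) != nrow(K)")
  if (n < 3L) stop("need at least 3 training subjects")
  if (max(abs(K - t(K))) > 1e-8 * max(abs(K), 1e-300))
    stop("K is not symmetric")
  if (is.null(subject_ids)) subject_ids <- sprintf("s%04d", seq_len(n))
  ## double-centre: Kc[i,j] = (x_i - xbar).(x_j - xbar)
  rm <- rowMeans(K)
  gm <- mean(K)
  Kc <- K - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + gm
  knorm <- mean(diag(Kc))
  degenerate <- knorm <= 1e-12 * max(mean(abs(diag(K))), 1e-300)
  if (degenerate) {
    ## identical feature vectors: no usable signal, predict the mean age
    return(new("GPRModel", dualWeights = rep(0, n), trainMeanAge = mean(ages),
               signalVar = 1, noiseVar = 1e-6, kernelNorm = 1,
               centerMeans = rm, centerGrand = gm,
               trainIds = as.character(subject_ids)))
  }
  Kt <- Kc / knorm
  mu <- mean(ages)
  yc <- ages - mu
  jit <- .JITTER_SCALE * sum(diag(Kt)) / n

  if (!is.null(hyper)) {
    sf2 <- hyper$signal_var; sn2 <- hyper$noise_var
    if (is.null(sf2) || is.null(sn2) || sf2 <= 0 || sn2 < 0)
      stop("hyper must supply signal_var > 0 and noise_var >= 0")
    C <- sf2 * Kt
    diag(C) <- diag(C) + sn2 + jit
    R <- tryCatch(chol(C), error = function(e)
      stop("singular covariance; consider adding jitter or noise variance"))
    dual <- backsolve(R, forwardsolve(t(R), yc))
  } else {
    eg <- eigen(Kt, symmetric = TRUE)
    if (min(eg$values) < -1e-8 * sum(diag(Kt)) / n)
      stop("K is not positive semidefinite")
    evals <- pmax(eg$values, 0)
    z <- drop(crossprod(eg$vectors, yc))
    vy <- stats::var(ages)
    if (vy < 1e-12) {
      ## zero-variance target: predictions collapse to the constant mean
      sf2 <- 1; sn2 <- 1e-6
      dual <- rep(0, n)
    } else {
      opt <- stats::optim(c(0, log(vy) / 2), .gpNll, evals = evals, z2 = z^2,
                          jit = jit, method = "L-BFGS-B",
                          lower = c(-20, -20), upper = c(20, 20))
      sf2 <- exp(opt$par[1L]); sn2 <- exp(opt$par[2L])
      d <- sf2 * evals + sn2 + jit
      dual <- drop(eg$vectors %*% (z / d))
    }
  }
  new("GPRModel", dualWeights = as.numeric(dual), trainMeanAge = mu,
      signalVar = sf2, noiseVar = sn2, kernelNorm = knorm,
      centerMeans = rm, centerGrand = gm,
      trainIds = as.character(subject_ids))
}

#' @describeIn GPRModel-class mean GP prediction from a cross-kernel whose
#'   columns align with the training subjects (raw dot products; the model
#'   applies its own kernel normalization)
#' @param object a \linkS4class{GPRModel}
#' @param Kcross n_test x n_train cross-kernel
#' @param ... unused
#' @export
setMethod("predict", "GPRModel", function(object, Kcross, ...) {
  if (is.null(dim(Kcross))) Kcross <- matrix(Kcross, nrow = 1L)
  if (ncol(Kcross) != length(object@dualWeights))
    stop("cross-kernel columns do not match the training subjects")
  if (!is.null(colnames(Kcross)) &&
      !identical(colnames(Kcross), object@trainIds))
    stop("cross-kernel column ids do not match training ids")
  ## apply the training centring: (x_t - xbar).(x_i - xbar)
  Kc <- Kcross - rowMeans(Kcross) -
    matrix(object@centerMeans, nrow(Kcross), ncol(Kcross), byrow = TRUE) +
    object@centerGrand
  drop(object@trainMeanAge +
         object@signalVar * (Kc / object@kernelNorm) %*%
           object@dualWeights)
})

#' Brain-predicted ages and brain-PAD for test subjects
#'
#' brain-PAD = brain-predicted age - chronological age; positive values mean
#' the brain is predicted "older" than its chronological age.
#'
#' @param model a fitted \linkS4class{GPRModel}.
#' @param Kcross n_test x n_train cross-kernel.
#' @param ages chronological ages of the test subjects (years).
#' @param subject_ids test subject identifiers.
#' @return data.frame: subject_id, age_years, brain_predicted_age, brain_pad.
#' @export
brainAgePredictions <- function(model, Kcross, ages,
                                subject_ids = rownames(Kcross)) {
  pred <- predict(model, Kcross)
  if (is.null(subject_ids)) subject_ids <- sprintf("t%04d", seq_along(pred))
  data.frame(subject_id = as.character(subject_ids), age_years = ages,
             brain_predicted_age = pred, brain_pad = pred - ages,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Deterministic k-fold assignment
#'
#' Subject indices are shuffled with the given seed and dealt round-robin, so
#' fold sizes differ by at most one.
#'
#' @param n number of subjects; \code{k} folds; \code{seed} RNG seed.
#' @param k,seed see above.
#' @return integer fold labels of length n.
#' @export
foldAssignment <- function(n, k, seed) {
  if (k > n) stop("k must not exceed the number of subjects")
  if (k < 2L) stop("need at least 2 folds")
  set.seed(as.integer(seed))
  fold <- integer(n)
  fold[sample.int(n)] <- rep_len(seq_len(k), n)
  fold
}

#' Cross-validated brain-age predictions
#'
#' Each subject's prediction comes from a model fitted without its fold.
#' Fold assignment depends only on (n, k, seed), never on the ages.
#'
#' @param K N x N kernel matrix.
#' @param ages chronological ages (years).
#' @param k number of folds (default 10).
#' @param seed RNG seed for the fold shuffle.
#' @param hyper optional fixed hyperparameters passed to \code{\link{fitGPR}}
#'   (skips per-fold optimization).
#' @param subject_ids subject identifiers.
#' @return data.frame: subject_id, age_years, brain_predicted_age, brain_pad,
#'   fold; rows in the input subject order.
#' @export
crossvalPredict <- function(K, ages, k = 10, seed = 1, hyper = NULL,
                            subject_ids = rownames(K)) {
  n <- length(ages)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%04d", seq_len(n))
  fold <- foldAssignment(n, k, seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    m <- fitGPR(K[tr, tr, drop = FALSE], ages[tr],
                subject_ids = subject_ids[tr], hyper = hyper)
    pred[te] <- predict(m, K[te, tr, drop = FALSE])
  }
  data.frame(subject_id = as.character(subject_ids), age_years = ages,
             brain_predicted_age = pred, brain_pad = pred - ages,
             fold = fold, stringsAsFactors = FALSE, row.names = NULL)
}

#' Prediction accuracy metrics
#'
#' Pearson's r between age and predicted age, R-squared (the square of r,
#' with the sum-of-squares version reported alongside), mean absolute error
#' and root mean squared error.
#'
#' @param ages chronological ages (years).
#' @param predictions brain-predicted ages (years).
#' @return one-row data.frame: pearson_r, r_squared, r_squared_ss, mae_years,
#'   rmse_years, n. With zero variance in either vector r is NA (flagged by a
#'   warning).
#' @export
performanceMetrics <- function(ages, predictions) {
  n <- length(ages)
  if (n < 3L) stop("need at least 3 subjects")
  if (length(predictions) != n) stop("length mismatch")
  err <- predictions - ages
  if (stats::var(ages) < 1e-12 || stats::var(predictions) < 1e-12) {
    warning("zero variance: correlation undefined", call. = FALSE)
    r <- NA_real_
  } else r <- stats::cor(ages, predictions)
  sst <- sum((ages - mean(ages))^2)
  data.frame(pearson_r = r, r_squared = r^2,
             r_squared_ss = if (sst > 0) 1 - sum(err^2) / sst else NA_real_,
             mae_years = mean(abs(err)), rmse_years = sqrt(mean(err^2)),
             n = n)
}

#' Permutation test of cross-validated prediction accuracy
#'
#' Age labels are permuted \code{n_perm} times; each permutation repeats the
#' full cross-validation (labels are permuted before fold assignment, and by
#' default hyperparameters are re-optimized each time).
#' \code{p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)}, so the smallest
#' attainable p is \code{1 / (n_perm + 1)}.
#'
#' @param K kernel matrix; \code{ages} chronological ages.
#' @param ages ages in years.
#' @param n_perm number of permutations (default 1000).
#' @param k folds; \code{seed} RNG seed.
#' @param seed RNG seed.
#' @param hyper optional fixed hyperparameters; when supplied (or when
#'   \code{optimize_hyper = FALSE}, which fixes them at the full-data fit)
#'   permutations skip hyperparameter re-optimization for speed.
#' @param optimize_hyper logical, re-optimize hyperparameters per permutation.
#' @return list: p, r_obs, r_perm (length n_perm).
#' @export
permutationTest <- function(K, ages, n_perm = 1000, k = 10, seed = 1,
                            hyper = NULL, optimize_hyper = is.null(hyper)) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!optimize_hyper && is.null(hyper)) {
    full <- fitGPR(K, ages)
    hyper <- list(signal_var = full@signalVar, noise_var = full@noiseVar)
  }
  cv <- crossvalPredict(K, ages, k = k, seed = seed, hyper = hyper)
  rObs <- stats::cor(cv$age_years, cv$brain_predicted_age)
  rPerm <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    permSeed <- as.integer(seed + j)
    set.seed(permSeed)
    yp <- sample(ages)
    cvp <- crossvalPredict(K, yp, k = k, seed = permSeed, hyper = hyper)
    sdp <- stats::sd(cvp$brain_predicted_age)
    rPerm[j] <- if (is.na(sdp) || sdp < 1e-12) 0
                else stats::cor(cvp$age_years, cvp$brain_predicted_age)
  }
  list(p = (1 + sum(rPerm >= rObs)) / (n_perm + 1), r_obs = rObs,
       r_perm = rPerm)
}

#' One-sample t-test of brain-PAD against a reference mean
#'
#' Tests whether a group's mean brain-PAD differs from a reference value
#' (default 0, the expectation under unbiased prediction).
#'
#' @param brain_pad brain-PAD values (years).
#' @param reference_mean reference mean (years).
#' @return list: statistic, p, df, mean, reference_mean.
#' @export
brainPadVsReference <- function(brain_pad, reference_mean = 0) {
  tt <- oneSampleT(brain_pad, reference_mean)
  c(tt, list(mean = mean(brain_pad), reference_mean = reference_mean))
}
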