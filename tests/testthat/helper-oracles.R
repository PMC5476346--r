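# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: dense convolutions, direct matrix solves,
# hypergeometric enumeration, hand-rolled IRLS.

# brute-force 3D Gaussian convolution with zero padding, matching the
# truncated unit-sum kernel definition
denseGaussSmooth <- function(vol, fwhm, voxel) {
  if (length(voxel) == 1L) voxel <- rep(voxel, 3L)
  sigma <- fwhm / (voxel * 2 * sqrt(2 * log(2)))
  ks <- lapply(sigma, function(s) {
    r <- max(1L, ceiling(4 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k / sum(k)
  })
  d <- dim(vol)
  out <- array(0, d)
  rs <- vapply(ks, function(k) (length(k) - 1L) / 2L, numeric(1))
  for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    acc <- 0
    for (a in -rs[1]:rs[1]) for (b in -rs[2]:rs[2]) for (c in -rs[3]:rs[3]) {
      ii <- i + a; jj <- j + b; ll <- l + c
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          ll >= 1 && ll <= d[3])
        acc <- acc + vol[ii, jj, ll] * ks[[1]][a + rs[1] + 1] *
          ks[[2]][b + rs[2] + 1] * ks[[3]][c + rs[3] + 1]
    }
    out[i, j, l] <- acc
  }
  out
}

# closed-form GP prediction with explicit feature centring and a plain solve
gpOracle <- function(Xtrain, Xtest, ages, sf2, sn2, jitter_scale = 1e-8) {
  xbar <- colMeans(Xtrain)
  Xc <- sweep(Xtrain, 2, xbar)
  Xt <- sweep(Xtest, 2, xbar)
  K <- Xc %*% t(Xc)
  knorm <- mean(diag(K))
  Kt <- K / knorm
  n <- nrow(K)
  C <- sf2 * Kt + (sn2 + jitter_scale * sum(diag(Kt)) / n) * diag(n)
  mu <- mean(ages)
  kstar <- (Xt %*% t(Xc)) / knorm
  drop(mu + sf2 * kstar %*% solve(C, ages - mu))
}

# SRTM forward model by direct O(n^2) trapezoidal convolution (no recursion)
srtmForwardDirect <- function(r1, k2, bp, ref, times_s) {
  k2a <- k2 / (1 + bp)
  theta2 <- k2 - r1 * k2a
  tmin <- times_s / 60
  n <- length(tmin)
  conv <- numeric(n)
  for (i in 2:n) {
    integrand <- ref[1:i] * exp(-k2a * (tmin[i] - tmin[1:i]))
    conv[i] <- sum(diff(tmin[1:i]) * (integrand[-1] + integrand[-i]) / 2)
  }
  r1 * ref + theta2 * conv
}

# unconstrained nonlinear least squares SRTM oracle on a coarse independent
# grid (dt = 5 s), Nelder-Mead over (r1, log k2, log bpnd)
srtmNlsOracle <- function(target, reference, start = c(1, log(0.1), log(0.5))) {
  sched <- target@schedule
  times <- seq(0, totalDuration(sched), by = 5)
  refFine <- approx(c(0, frameMid(sched)), c(0, activity(reference)),
                    xout = times, rule = 2)$y
  w <- fitWeights(target)
  y <- activity(target)
  frameIdx <- findInterval(times, c(frameStart(sched), totalDuration(sched)))
  keep <- frameIdx >= 1 & frameIdx <= nFrames(sched)
  favg <- function(fine) as.numeric(rowsum(fine[keep], frameIdx[keep])) /
    tabulate(frameIdx[keep], nFrames(sched))
  obj <- function(p) {
    ct <- srtmForwardDirect(p[1], exp(p[2]), exp(p[3]), refFine, times)
    sum(w * (y - favg(ct))^2)
  }
  fit <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(r1 = fit$par[1], k2 = exp(fit$par[2]), bpnd = exp(fit$par[3]),
       wrss = fit$value)
}

# two-sided Fisher p by point-probability hypergeometric enumeration
fisherOracle <- function(tab) {
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - nn):min(k, m)
  probs <- dhyper(support, m, nn, k)
  pObs <- dhyper(tab[1, 1], m, nn, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# logistic regression by hand-rolled Newton-Raphson (IRLS)
logisticOracle <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- rep(0, ncol(X))
  for (it in 1:maxit) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    score <- crossprod(X, y - p)
    H <- crossprod(X * W, X)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(crossprod(X * (plogis(drop(X %*% beta)) *
                                         (1 - plogis(drop(X %*% beta)))), X))))
  list(beta = drop(beta), se = se)
}

# a small, fast simulation configuration for unit tests
tinyConfig <- function(...) {
  base <- list(n_train = 30, n_ds = 10, n_control = 8,
               grid_dims = c(8, 8, 8), seed = 123)
  do.call(simulationConfig, utils::modifyList(base, list(...)))
}
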