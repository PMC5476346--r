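## Basis-function simplified reference tissue model (SRTM).
##
## Model: C_T(t) = R1 C_R(t) + (k2 - R1 k2a) * (C_R conv exp(-k2a t)),
## k2a = k2 / (1 + BP_ND). The basis-function scheme grids the nonlinear rate
## k2a (= theta3), precomputes the convolution bases, solves the remaining two
## parameters by weighted linear least squares per grid point and keeps the
## grid point with minimal weighted residual sum of squares.

#' Uniform fine time grid spanning a schedule
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param fine_dt_s grid step in seconds.
#' @return numeric times from 0 to the scan end.
#' @export
fineTimeGrid <- function(schedule, fine_dt_s = 1) {
  seq(0, totalDuration(schedule), by = fine_dt_s)
}

#' Average a fine-grid curve over each frame interval
#'
#' Frame value = average of the curve over \code{[start, start + duration)}.
#' When the frame boundaries lie on the (uniform) fine grid the average is
#' trapezoidal (second-order accurate in the grid step); otherwise it falls
#' back to the mean of the samples falling inside the interval.
#'
#' @param fine_values curve sampled on \code{fine_times_s}.
#' @param fine_times_s sample times in seconds.
#' @param schedule a \linkS4class{FrameSchedule}.
#' @return numeric, one value per frame.
#' @export
frameAverage <- function(fine_values, fine_times_s, schedule) {
  stopifnot(length(fine_values) == length(fine_times_s))
  nf <- nFrames(schedule)
  st <- frameStart(schedule)
  en <- st + frameDuration(schedule)
  n <- length(fine_times_s)
  dt <- if (n > 1L) (fine_times_s[n] - fine_times_s[1L]) / (n - 1L) else 0
  i0 <- round((st - fine_times_s[1L]) / dt) + 1L
  i1 <- round((en - fine_times_s[1L]) / dt) + 1L
  aligned <- dt > 0 && all(i1 <= n) && all(i0 >= 1L) && all(i1 - i0 >= 1L) &&
    max(abs(fine_times_s[pmin(i0, n)] - st), abs(fine_times_s[pmin(i1, n)] - en)) < 1e-6 * max(dt, 1)
  if (aligned) {
    cums <- cumsum(fine_values)
    ## trapezoid over [i0, i1]: interior sum plus half-weighted endpoints
    inner <- (cums[i1] - cums[i0]) - (fine_values[i1] - fine_values[i0]) / 2
    return(inner / (i1 - i0))
  }
  bounds <- c(st, totalDuration(schedule))
  bin <- findInterval(fine_times_s, bounds)
  keep <- bin >= 1L & bin <= nf
  counts <- tabulate(bin[keep], nbins = nf)
  if (any(counts == 0L))
    stop("fine grid too coarse: a frame contains no samples")
  as.numeric(rowsum(fine_values[keep], bin[keep])) / counts
}

## Trapezoidal exponential convolution y(t) = int_0^t x(s) exp(-lambda (t-s)) ds
## on a uniform grid, via the exact recursion
## y_i = a y_{i-1} + dt/2 (x_i + a x_{i-1}), a = exp(-lambda dt).
.expConvolve <- function(x, lambda, dt) {
  n <- length(x)
  if (n == 1L) return(0)
  a <- exp(-lambda * dt)
  u <- numeric(n)
  u[-1L] <- dt / 2 * (x[-1L] + a * x[-n])
  as.numeric(stats::filter(u, a, method = "recursive"))
}

.checkUniformGrid <- function(fine_times_s) {
  dts <- diff(fine_times_s)
  if (length(dts) == 0L) stop("fine grid needs >= 2 points")
  if (max(abs(dts - dts[1L])) > 1e-9 * max(dts[1L], 1))
    stop("fine time grid must be uniform")
  dts[1L]
}

#' SRTM forward model on a fine time grid
#'
#' @param r1 delivery ratio R1 (>= 0).
#' @param k2_per_min reference-region efflux rate in 1/min (> 0).
#' @param bpnd nondisplaceable binding potential (>= 0).
#' @param ref_fine reference curve sampled on \code{fine_times_s}.
#' @param fine_times_s uniform time grid in seconds.
#' @return the target-region curve on the same grid.
#' @export
srtmForward <- function(r1, k2_per_min, bpnd, ref_fine, fine_times_s) {
  if (bpnd < 0) stop("bpnd must be >= 0")
  if (k2_per_min <= 0) stop("k2_per_min must be > 0")
  if (r1 < 0) stop("r1 must be >= 0")
  dtMin <- .checkUniformGrid(fine_times_s) / 60
  k2a <- k2_per_min / (1 + bpnd)
  theta2 <- k2_per_min - r1 * k2a
  r1 * ref_fine + theta2 * .expConvolve(ref_fine, k2a, dtMin)
}

#' Default theta3 (k2a) basis grid
#'
#' 64 logarithmically spaced rates covering the kinetic range relevant for
#' PiB basis-function fitting.
#'
#' @param n number of grid points.
#' @param range (lo, hi) in 1/min.
#' @return numeric ascending grid in 1/min.
#' @export
defaultTheta3Grid <- function(n = 64, range = c(0.006, 0.6)) {
  exp(seq(log(range[1]), log(range[2]), length.out = n))
}

## Reconstruct a fine-grid reference curve from a frame-averaged TAC: linear
## interpolation through (0, 0) and the frame midpoints, then a few fixed-
## point corrections of the knot values so that the reconstruction's own
## frame averages reproduce the observed TAC (raw midpoint interpolation is
## biased wherever the curve bends inside long frames).
.refFineFromTac <- function(reference, fine_times_s, n_correct = 8L) {
  sched <- reference@schedule
  knotsX <- c(0, frameMid(sched))
  knotsY <- c(0, activity(reference))
  fine <- stats::approx(knotsX, knotsY, xout = fine_times_s, rule = 2)$y
  for (it in seq_len(n_correct)) {
    gap <- activity(reference) - frameAverage(fine, fine_times_s, sched)
    knotsY[-1L] <- knotsY[-1L] + gap
    fine <- stats::approx(knotsX, knotsY, xout = fine_times_s, rule = 2)$y
  }
  fine
}

## Precompute the frame-averaged basis design for one reference curve and
## theta3 grid: list with framed reference and a frames x grid basis matrix.
.srtmBases <- function(ref_fine, fine_times_s, schedule, theta3_grid) {
  dtMin <- .checkUniformGrid(fine_times_s) / 60
  refFramed <- frameAverage(ref_fine, fine_times_s, schedule)
  B <- vapply(theta3_grid, function(th) {
    frameAverage(.expConvolve(ref_fine, th, dtMin), fine_times_s, schedule)
  }, numeric(nFrames(schedule)))
  list(refFramed = refFramed, B = B)
}

## Weighted 2-parameter least squares of y on [ref, basis] for every grid
## point; returns the winning fit. Shared by srtmBasisFit and srtmFitRegions.
.srtmSolve <- function(y, w, bases, theta3_grid, roi_id) {
  ng <- length(theta3_grid)
  sw <- sqrt(w)
  y1 <- sw * y
  x1 <- sw * bases$refFramed
  best <- NULL
  wrssAll <- rep(Inf, ng)
  for (g in seq_len(ng)) {
    x2 <- sw * bases$B[, g]
    X <- cbind(x1, x2)
    qrX <- qr(X)
    if (qrX$rank < 2L) next
    beta <- qr.coef(qrX, y1)
    res <- y1 - X %*% beta
    wrssAll[g] <- sum(res^2)
    if (is.null(best) || wrssAll[g] < best$wrss)
      best <- list(theta1 = beta[1L], theta2 = beta[2L], wrss = wrssAll[g],
                   g = g)
  }
  if (is.null(best))
    stop(sprintf("rank-deficient SRTM design at every theta3 for ROI '%s'",
                 roi_id))
  th3 <- theta3_grid[best$g]
  k2 <- best$theta2 + best$theta1 * th3
  bp <- k2 / th3 - 1
  if (bp < 0)
    warning(sprintf("negative fitted BP_ND (%.3f) for ROI '%s'", bp, roi_id),
            call. = FALSE)
  new("SRTMFit", r1 = unname(best$theta1), k2PerMin = unname(k2),
      k2aPerMin = th3, theta2PerMin = unname(best$theta2),
      bpnd = unname(bp), wrss = unname(best$wrss),
      gridIndex = as.integer(best$g), roiId = roi_id)
}

#' Basis-function SRTM fit of a target TAC against a reference TAC
#'
#' The reference curve is linearly interpolated to a uniform fine grid, the
#' convolution bases \code{C_R conv exp(-theta3 t)} are computed by
#' trapezoidal recursion and frame-averaged, and for each theta3 the linear
#' parameters are solved by weighted least squares (weights from the target
#' TAC). The theta3 with minimal weighted residual sum of squares wins.
#'
#' @param target,reference \linkS4class{TAC}s sharing one schedule.
#' @param theta3_grid ascending k2a candidate grid in 1/min (>= 2 points).
#' @param fine_dt_s fine-grid step in seconds.
#' @return An \linkS4class{SRTMFit}.
#' @examples
#' sched <- standardSchedule()
#' ref <- simulateReferenceTac(sched, peak_time_s = 300, scale = 20)
#' ft <- fineTimeGrid(sched)
#' refFine <- referenceInputCurve(ft, 300, 20)
#' tgt <- simulateTargetTac(refFine, ft, 1.2, 0.12, 0.8, sched)
#' fit <- srtmBasisFit(tgt, ref)
#' bpnd(fit)
#' @export
srtmBasisFit <- function(target, reference, theta3_grid = defaultTheta3Grid(),
                         fine_dt_s = 1) {
  stopifnot(is(target, "TAC"), is(reference, "TAC"))
  if (length(theta3_grid) < 2L || is.unsorted(theta3_grid, strictly = TRUE))
    stop("theta3_grid must be >= 2 strictly ascending values")
  sT <- target@schedule; sR <- reference@schedule
  if (nFrames(sT) != nFrames(sR) ||
      max(abs(frameStart(sT) - frameStart(sR))) > 1e-9 ||
      max(abs(frameDuration(sT) - frameDuration(sR))) > 1e-9)
    stop("target and reference must share a frame schedule")
  ft <- fineTimeGrid(sT, fine_dt_s)
  refFine <- .refFineFromTac(reference, ft)
  bases <- .srtmBases(refFine, ft, sT, theta3_grid)
  .srtmSolve(activity(target), fitWeights(target), bases, theta3_grid,
             roiId(target))
}

#' Fit SRTM to every region of one subject
#'
#' Precomputes the basis set once for the subject's reference TAC and reuses
#' it across regions, which is much faster than region-by-region fitting.
#'
#' @param tac_matrix frames x ROI activity matrix (column names = ROI ids).
#' @param reference the subject's reference \linkS4class{TAC}.
#' @param theta3_grid,fine_dt_s as in \code{\link{srtmBasisFit}}.
#' @param weights per-frame weights applied to every region; defaults to
#'   frame durations.
#' @return data.frame: roi_id, r1, k2_per_min, k2a_per_min, bpnd, wrss.
#' @export
srtmFitRegions <- function(tac_matrix, reference,
                           theta3_grid = defaultTheta3Grid(), fine_dt_s = 1,
                           weights = frameDuration(reference@schedule)) {
  stopifnot(is(reference, "TAC"),
            nrow(tac_matrix) == nFrames(reference@schedule))
  ft <- fineTimeGrid(reference@schedule, fine_dt_s)
  refFine <- .refFineFromTac(reference, ft)
  bases <- .srtmBases(refFine, ft, reference@schedule, theta3_grid)
  rois <- colnames(tac_matrix)
  if (is.null(rois)) rois <- sprintf("roi%02d", seq_len(ncol(tac_matrix)))
  rows <- lapply(seq_along(rois), function(r) {
    fit <- .srtmSolve(tac_matrix[, r], weights, bases, theta3_grid, rois[r])
    data.frame(roi_id = rois[r], r1 = fit@r1, k2_per_min = fit@k2PerMin,
               k2a_per_min = fit@k2aPerMin, bpnd = fit@bpnd, wrss = fit@wrss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
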