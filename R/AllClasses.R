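## Central S4 containers: PET frame schedules, time-activity curves, tissue
## probability maps, simulation configuration, the GP age model, SRTM fits and
## tidy statistical results.

#' Frame schedule for a dynamic PET acquisition
#'
#' Frames are contiguous, non-overlapping, half-open intervals
#' \code{[start, start + duration)} in seconds, starting at zero.
#'
#' @slot start numeric, frame start times in seconds.
#' @slot duration numeric, frame durations in seconds.
#' @export
setClass("FrameSchedule",
  representation(start = "numeric", duration = "numeric"))

setValidity("FrameSchedule", function(object) {
  s <- object@start; d <- object@duration
  if (length(s) != length(d)) return("start and duration lengths differ")
  if (length(s) == 0L) return("empty schedule")
  if (any(!is.finite(s)) || any(!is.finite(d))) return("non-finite frame times")
  if (any(d <= 0)) return("frame durations must be > 0")
  if (abs(s[1L]) > 1e-9) return("first frame must start at 0")
  gaps <- s[-1L] - (s[-length(s)] + d[-length(d)])
  if (length(gaps) && any(abs(gaps) > 1e-9))
    return("frames must be contiguous and non-overlapping")
  TRUE
})

#' Construct a frame schedule
#'
#' @param durations numeric vector of frame durations in seconds; starts are
#'   their cumulative sum beginning at zero.
#' @return A \linkS4class{FrameSchedule}.
#' @examples
#' sched <- frameSchedule(c(rep(5, 4), rep(60, 2)))
#' nFrames(sched)
#' @export
frameSchedule <- function(durations) {
  durations <- as.numeric(durations)
  new("FrameSchedule",
      start = cumsum(c(0, durations[-length(durations)])),
      duration = durations)
}

#' The 58-frame PiB acquisition schedule
#'
#' Ninety minutes of dynamic PET: 18 x 5 s, 6 x 15 s, 10 x 30 s, 7 x 60 s,
#' 4 x 150 s and 13 x 300 s frames.
#'
#' @return A \linkS4class{FrameSchedule} with 58 frames totalling 5400 s.
#' @export
standardSchedule <- function() {
  frameSchedule(c(rep(5, 18), rep(15, 6), rep(30, 10),
                  rep(60, 7), rep(150, 4), rep(300, 13)))
}

#' @describeIn FrameSchedule-class number of frames
#' @param x object
#' @export
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))

#' @describeIn FrameSchedule-class frame start times (s)
#' @export
setMethod("frameStart", "FrameSchedule", function(x) x@start)

#' @describeIn FrameSchedule-class frame durations (s)
#' @export
setMethod("frameDuration", "FrameSchedule", function(x) x@duration)

#' @describeIn FrameSchedule-class frame midpoints (s)
#' @export
setMethod("frameMid", "FrameSchedule", function(x) x@start + x@duration / 2)

#' @describeIn FrameSchedule-class total scan duration (s)
#' @export
setMethod("totalDuration", "FrameSchedule", function(x)
  x@start[length(x@start)] + x@duration[length(x@duration)])

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.0f s (%.1f min) total\n",
              nFrames(object), totalDuration(object),
              totalDuration(object) / 60))
})

#' Regional time-activity curve
#'
#' Frame-averaged activity concentration for one region, with the acquisition
#' schedule and per-frame fit weights (default: frame durations).
#'
#' @slot schedule a \linkS4class{FrameSchedule}.
#' @slot activity numeric, per-frame activity (arbitrary units).
#' @slot weights numeric, non-negative per-frame fit weights.
#' @slot roiId character, region identifier.
#' @export
setClass("TAC",
  representation(schedule = "FrameSchedule", activity = "numeric",
                 weights = "numeric", roiId = "character"))

setValidity("TAC", function(object) {
  n <- nFrames(object@schedule)
  if (length(object@activity) != n) return("activity length != frame count")
  if (length(object@weights) != n) return("weights length != frame count")
  if (any(!is.finite(object@activity))) return("non-finite activity")
  if (any(object@weights < 0)) return("negative weights")
  if (length(object@roiId) != 1L) return("roiId must be a single string")
  TRUE
})

#' Construct a time-activity curve
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param activity per-frame activity values.
#' @param weights per-frame fit weights; defaults to frame durations.
#' @param roiId region identifier.
#' @return A \linkS4class{TAC}.
#' @export
tac <- function(schedule, activity, weights = frameDuration(schedule),
                roiId = "roi") {
  new("TAC", schedule = schedule, activity = as.numeric(activity),
      weights = as.numeric(weights), roiId = roiId)
}

#' @describeIn TAC-class per-frame activity
#' @param x object
#' @export
setMethod("activity", "TAC", function(x) x@activity)

#' @describeIn TAC-class per-frame fit weights
#' @export
setMethod("fitWeights", "TAC", function(x) x@weights)

#' @describeIn TAC-class region identifier
#' @export
setMethod("roiId", "TAC", function(x) x@roiId)

#' @describeIn TAC-class number of frames
#' @export
setMethod("nFrames", "TAC", function(x) nFrames(x@schedule))

setMethod("show", "TAC", function(object) {
  cat(sprintf("TAC '%s': %d frames, peak %.3g\n", object@roiId,
              nFrames(object), max(object@activity)))
})

#' Voxelwise tissue-probability maps for one subject
#'
#' Grey matter, white matter and CSF probability volumes on a common grid in a
#' shared template space. Values lie in [0, 1]; per-voxel GM + WM + CSF sums
#' do not exceed 1 (up to rounding).
#'
#' @slot gm,wm,csf 3D arrays of tissue probabilities.
#' @slot voxelSizeMm numeric length 3, voxel edge lengths in mm.
#' @slot spaceTag character, identifier of the common space.
#' @export
setClass("TissueMaps",
  representation(gm = "array", wm = "array", csf = "array",
                 voxelSizeMm = "numeric", spaceTag = "character"))

setValidity("TissueMaps", function(object) {
  dg <- dim(object@gm)
  if (length(dg) != 3L) return("maps must be 3D arrays")
  if (!identical(dg, dim(object@wm)) || !identical(dg, dim(object@csf)))
    return("gm, wm, csf must share a common shape")
  for (nm in c("gm", "wm", "csf")) {
    v <- slot(object, nm)
    if (any(!is.finite(v))) return(sprintf("non-finite values in %s", nm))
    if (min(v) < -1e-9 || max(v) > 1 + 1e-9)
      return(sprintf("%s probabilities outside [0, 1]", nm))
  }
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    return("voxelSizeMm must be 3 positive values")
  TRUE
})

#' Construct tissue maps
#'
#' @param gm,wm,csf 3D probability arrays of a common shape.
#' @param voxelSizeMm voxel edge lengths in mm (length 1 or 3).
#' @param spaceTag label of the common space the maps live in.
#' @return A \linkS4class{TissueMaps}.
#' @export
tissueMaps <- function(gm, wm, csf, voxelSizeMm = c(1.5, 1.5, 1.5),
                       spaceTag = "template") {
  if (length(voxelSizeMm) == 1L) voxelSizeMm <- rep(voxelSizeMm, 3L)
  new("TissueMaps", gm = gm, wm = wm, csf = csf,
      voxelSizeMm = as.numeric(voxelSizeMm), spaceTag = spaceTag)
}

#' @describeIn TissueMaps-class grey-matter probability volume
#' @param x object
#' @export
setMethod("gmMap", "TissueMaps", function(x) x@gm)

#' @describeIn TissueMaps-class white-matter probability volume
#' @export
setMethod("wmMap", "TissueMaps", function(x) x@wm)

#' @describeIn TissueMaps-class CSF probability volume
#' @export
setMethod("csfMap", "TissueMaps", function(x) x@csf)

#' @describeIn TissueMaps-class voxel size in mm
#' @export
setMethod("voxelSize", "TissueMaps", function(x) x@voxelSizeMm)

setMethod("show", "TissueMaps", function(object) {
  d <- dim(object@gm)
  cat(sprintf("TissueMaps %dx%dx%d @ %.2gx%.2gx%.2g mm (%s)\n",
              d[1], d[2], d[3], object@voxelSizeMm[1], object@voxelSizeMm[2],
              object@voxelSizeMm[3], object@spaceTag))
})

#' Fitted kernel Gaussian-process age regression model
#'
#' Stores the dual representation of a GP regression of age on a normalized
#' linear kernel: predictions at new subjects are
#' \code{mu + signalVar * (Kcross / kernelNorm) \%*\% dualWeights}.
#'
#' @slot dualWeights numeric, \eqn{(\sigma_f^2 \tilde K + \sigma_n^2 I)^{-1}(y - \mu)}.
#' @slot trainMeanAge numeric, training mean age (years).
#' @slot signalVar,noiseVar numeric, kernel signal and noise variances.
#' @slot kernelNorm numeric, the mean diagonal of the centred training kernel
#'   used to normalize it.
#' @slot centerMeans,centerGrand kernel-centring statistics (per-training-
#'   subject kernel row means and the grand mean), applied to cross-kernels
#'   at predict time; centring the kernel is equivalent to removing the
#'   feature mean.
#' @slot trainIds character, ordered training subject identifiers.
#' @export
setClass("GPRModel",
  representation(dualWeights = "numeric", trainMeanAge = "numeric",
                 signalVar = "numeric", noiseVar = "numeric",
                 kernelNorm = "numeric", centerMeans = "numeric",
                 centerGrand = "numeric", trainIds = "character"))

setValidity("GPRModel", function(object) {
  if (any(!is.finite(object@dualWeights))) return("non-finite dual weights")
  if (object@signalVar <= 0) return("signalVar must be > 0")
  if (object@noiseVar < 0) return("noiseVar must be >= 0")
  if (object@kernelNorm <= 0) return("kernelNorm must be > 0")
  if (length(object@trainIds) != length(object@dualWeights))
    return("trainIds length != dualWeights length")
  TRUE
})

setMethod("show", "GPRModel", function(object) {
  cat(sprintf(paste0("GPRModel: N = %d, mean age %.2f y, ",
                     "signal var %.3g, noise var %.3g\n"),
              length(object@dualWeights), object@trainMeanAge,
              object@signalVar, object@noiseVar))
})

#' Basis-function SRTM fit for one region
#'
#' Parameterization: target = theta1 * C_R + theta2 * (C_R conv exp(-theta3 t))
#' with R1 = theta1, k2a = theta3, k2 = theta2 + R1 * k2a and
#' BP_ND = k2 / k2a - 1.
#'
#' @slot r1 unitless delivery ratio (theta1).
#' @slot k2PerMin,k2aPerMin,theta2PerMin rate constants in 1/min.
#' @slot bpnd unitless nondisplaceable binding potential.
#' @slot wrss weighted residual sum of squares at the selected basis.
#' @slot gridIndex integer, selected position in the theta3 grid.
#' @slot roiId character, region identifier.
#' @export
setClass("SRTMFit",
  representation(r1 = "numeric", k2PerMin = "numeric", k2aPerMin = "numeric",
                 theta2PerMin = "numeric", bpnd = "numeric", wrss = "numeric",
                 gridIndex = "integer", roiId = "character"))

setValidity("SRTMFit", function(object) {
  if (abs(object@bpnd - (object@k2PerMin / object@k2aPerMin - 1)) > 1e-10)
    return("bpnd != k2/k2a - 1")
  if (abs(object@k2PerMin -
          (object@theta2PerMin + object@r1 * object@k2aPerMin)) > 1e-10)
    return("k2 != theta2 + r1 * k2a")
  TRUE
})

#' @describeIn SRTMFit-class fitted nondisplaceable binding potential
#' @param object object
#' @export
setMethod("bpnd", "SRTMFit", function(object) object@bpnd)

#' @describeIn SRTMFit-class region identifier
#' @param x object
#' @export
setMethod("roiId", "SRTMFit", function(x) x@roiId)

setMethod("show", "SRTMFit", function(object) {
  cat(sprintf(
    "SRTMFit '%s': R1 = %.3f, k2 = %.4f /min, k2a = %.4f /min, BPnd = %.3f\n",
    object@roiId, object@r1, object@k2PerMin, object@k2aPerMin, object@bpnd))
})

#' Tidy result of one statistical model
#'
#' @slot modelName character label.
#' @slot terms data.frame with columns term, estimate, se, statistic, p,
#'   ci_low, ci_high.
#' @slot n number of observations used.
#' @slot statisticKind "t" or "z".
#' @slot rSquared numeric, R-squared for linear models (NA otherwise).
#' @export
setClass("ModelResult",
  representation(modelName = "character", terms = "data.frame", n = "numeric",
                 statisticKind = "character", rSquared = "numeric"))

setValidity("ModelResult", function(object) {
  need <- c("term", "estimate", "se", "statistic", "p", "ci_low", "ci_high")
  if (!all(need %in% names(object@terms)))
    return(sprintf("terms must have columns: %s", paste(need, collapse = ", ")))
  p <- object@terms$p
  if (any(!is.na(p) & (p < 0 | p > 1))) return("p outside [0, 1]")
  ok <- stats::complete.cases(object@terms[, c("estimate", "ci_low", "ci_high")])
  if (any(ok & (object@terms$ci_low > object@terms$estimate + 1e-8 |
                object@terms$ci_high < object@terms$estimate - 1e-8)))
    return("confidence interval does not bracket the estimate")
  if (!object@statisticKind %in% c("t", "z", "r"))
    return("statisticKind must be 't', 'z' or 'r'")
  TRUE
})

#' @describeIn ModelResult-class tidy per-term coefficient table
#' @param object object
#' @param ... unused
#' @export
setMethod("resultsTable", "ModelResult", function(object, ...) {
  cbind(model_name = object@modelName, object@terms,
        n = object@n, statistic_kind = object@statisticKind,
        r_squared = object@rSquared, stringsAsFactors = FALSE,
        row.names = NULL)
})

#' @describeIn ModelResult-class model label
#' @export
setMethod("modelName", "ModelResult", function(object) object@modelName)

setMethod("show", "ModelResult", function(object) {
  cat(sprintf("ModelResult '%s' (n = %d, %s statistics)\n",
              object@modelName, object@n, object@statisticKind))
  print(object@terms, digits = 4, row.names = FALSE)
})

## internal constructor
.modelResult <- function(name, terms, n, kind, r2 = NA_real_) {
  new("ModelResult", modelName = name, terms = terms, n = as.numeric(n),
      statisticKind = kind, rSquared = r2)
}
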