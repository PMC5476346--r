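## Synthetic cohort generator. Emulates the statistical structure the
## downstream analyses assume: tissue maps whose GM fraction declines with an
## effective age (chronological age + a group offset for DS + an individual
## brain-ageing deviation), dynamic PET TACs from the SRTM forward model with
## a bimodal striatal BP_ND mixture, and CAMCOG scores carrying a
## brain-PAD x PiB-status interaction.

#' Configuration of the synthetic cohort generator
#'
#' @slot nTrain,nDs,nControl subject counts for the healthy training set, the
#'   Down-syndrome group and the typically developing control group.
#' @slot ageRangeTrain,ageRangeTest chronological age ranges (years) for
#'   training and test subjects (uniform draws).
#' @slot groupOffsetYears effective-age shift applied to DS subjects (years).
#' @slot padSdYears SD of the individual brain-ageing deviation (years) added
#'   to every subject's effective age.
#' @slot gridDims voxel counts per axis; \code{voxelSizeMm} mm per axis.
#' @slot atrophyRate GM-probability decline per effective-age year at the
#'   pattern maximum.
#' @slot featureNoiseSd per-voxel Gaussian noise SD on tissue probabilities.
#' @slot tacNoiseCv fractional frame-level noise on simulated TACs.
#' @slot bpndNegMean,bpndNegSd,bpndPosMean,bpndPosSd striatal BP_ND mixture
#'   components for PiB-negative and PiB-positive subjects.
#' @slot pibPosFraction probability a DS subject is PiB-positive.
#' @slot roiBpndNoiseSd regional scatter of true BP_ND about the subject
#'   burden times the ROI class loading.
#' @slot camcogBaseline,camcogInteractionSlope,camcogNoiseSd CAMCOG model:
#'   score = baseline - slope * brainPAD_true * 1[PiB+] + noise.
#' @slot csfShrinkDs multiplicative CSF shrink factor for DS subjects (drives
#'   the reduced-ICV group difference without touching GM/WM features).
#' @slot peakTimeS,refScale gamma-variate reference input curve peak time (s)
#'   and scale.
#' @slot tacR1,tacK2PerMin true delivery ratio and reference efflux rate used
#'   when simulating target TACs.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(
    nTrain = "numeric", nDs = "numeric", nControl = "numeric",
    ageRangeTrain = "numeric", ageRangeTest = "numeric",
    groupOffsetYears = "numeric", padSdYears = "numeric",
    gridDims = "numeric", voxelSizeMm = "numeric",
    atrophyRate = "numeric", featureNoiseSd = "numeric",
    tacNoiseCv = "numeric",
    bpndNegMean = "numeric", bpndNegSd = "numeric",
    bpndPosMean = "numeric", bpndPosSd = "numeric",
    pibPosFraction = "numeric", roiBpndNoiseSd = "numeric",
    camcogBaseline = "numeric", camcogInteractionSlope = "numeric",
    camcogNoiseSd = "numeric", csfShrinkDs = "numeric",
    peakTimeS = "numeric", refScale = "numeric",
    tacR1 = "numeric", tacK2PerMin = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  bad <- function(field, msg) sprintf("invalid %s: %s", field, msg)
  for (f in c("nTrain", "nDs", "nControl"))
    if (slot(object, f) < 1) return(bad(f, "count must be > 0"))
  for (f in c("ageRangeTrain", "ageRangeTest")) {
    r <- slot(object, f)
    if (length(r) != 2L || diff(r) <= 0)
      return(bad(f, "must be a non-degenerate (lo, hi) interval"))
  }
  if (length(object@gridDims) != 3L || any(object@gridDims < 4))
    return(bad("gridDims", "need >= 4 voxels per axis"))
  if (any(object@voxelSizeMm <= 0))
    return(bad("voxelSizeMm", "must be positive"))
  for (f in c("featureNoiseSd", "tacNoiseCv", "padSdYears", "roiBpndNoiseSd",
              "camcogNoiseSd", "bpndNegSd", "bpndPosSd"))
    if (slot(object, f) < 0) return(bad(f, "must be >= 0"))
  if (object@pibPosFraction < 0 || object@pibPosFraction > 1)
    return(bad("pibPosFraction", "must lie in [0, 1]"))
  if (object@csfShrinkDs <= 0 || object@csfShrinkDs > 1)
    return(bad("csfShrinkDs", "must lie in (0, 1]"))
  if (object@atrophyRate < 0) return(bad("atrophyRate", "must be >= 0"))
  maxAge <- max(object@ageRangeTrain[2],
                object@ageRangeTest[2] + object@groupOffsetYears)
  if (object@atrophyRate * maxAge >= 1)
    return(bad("atrophyRate", "atrophy_rate x max effective age must be < 1"))
  if (object@peakTimeS <= 0) return(bad("peakTimeS", "must be > 0"))
  if (object@tacK2PerMin <= 0) return(bad("tacK2PerMin", "must be > 0"))
  if (object@tacR1 < 0) return(bad("tacR1", "must be >= 0"))
  if (object@seed != round(object@seed)) return(bad("seed", "must be integer"))
  TRUE
})

#' Build a simulation configuration
#'
#' Defaults mirror the cohort the analyses target: 46 DS and 30 control test
#' subjects alongside an independent healthy training set, a 1.5 mm template
#' grid, 4 mm feature smoothing downstream, an 8-year DS effective-age offset
#' and a bimodal striatal BP_ND mixture (N(0, 0.05^2) vs N(0.4, 0.15^2),
#' positive fraction 19/46).
#'
#' @param n_train,n_ds,n_control subject counts.
#' @param age_range_train,age_range_test age ranges in years.
#' @param group_offset_years DS effective-age offset (years).
#' @param pad_sd_years SD of individual brain-ageing deviations (years).
#' @param grid_dims,voxel_size_mm spatial grid definition.
#' @param atrophy_rate GM-probability units lost per effective-age year.
#' @param feature_noise_sd per-voxel probability noise SD.
#' @param tac_noise_cv fractional TAC noise.
#' @param bpnd_neg_mean,bpnd_neg_sd,bpnd_pos_mean,bpnd_pos_sd striatal BP_ND
#'   mixture parameters.
#' @param pib_pos_fraction PiB-positive probability among DS subjects.
#' @param roi_bpnd_noise_sd regional BP_ND scatter.
#' @param camcog_baseline,camcog_interaction_slope,camcog_noise_sd CAMCOG
#'   generative model parameters.
#' @param csf_shrink_ds CSF shrink factor for DS subjects.
#' @param peak_time_s,ref_scale reference input curve parameters.
#' @param tac_r1,tac_k2_per_min kinetic truth for simulated target TACs.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(n_train = 300, n_ds = 46, n_control = 30,
                             age_range_train = c(18, 90),
                             age_range_test = c(28, 65),
                             group_offset_years = 8, pad_sd_years = 5,
                             grid_dims = c(12, 14, 12),
                             voxel_size_mm = c(1.5, 1.5, 1.5),
                             atrophy_rate = 0.002, feature_noise_sd = 0.02,
                             tac_noise_cv = 0.05,
                             bpnd_neg_mean = 0, bpnd_neg_sd = 0.05,
                             bpnd_pos_mean = 0.4, bpnd_pos_sd = 0.15,
                             pib_pos_fraction = 19 / 46,
                             roi_bpnd_noise_sd = 0.03,
                             camcog_baseline = 80,
                             camcog_interaction_slope = 1.75,
                             camcog_noise_sd = 10, csf_shrink_ds = 0.85,
                             peak_time_s = 300, ref_scale = 20,
                             tac_r1 = 1, tac_k2_per_min = 0.15, seed = 42) {
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  new("SimulationConfig",
      nTrain = n_train, nDs = n_ds, nControl = n_control,
      ageRangeTrain = as.numeric(age_range_train),
      ageRangeTest = as.numeric(age_range_test),
      groupOffsetYears = group_offset_years, padSdYears = pad_sd_years,
      gridDims = as.numeric(grid_dims), voxelSizeMm = as.numeric(voxel_size_mm),
      atrophyRate = atrophy_rate, featureNoiseSd = feature_noise_sd,
      tacNoiseCv = tac_noise_cv,
      bpndNegMean = bpnd_neg_mean, bpndNegSd = bpnd_neg_sd,
      bpndPosMean = bpnd_pos_mean, bpndPosSd = bpnd_pos_sd,
      pibPosFraction = pib_pos_fraction, roiBpndNoiseSd = roi_bpnd_noise_sd,
      camcogBaseline = camcog_baseline,
      camcogInteractionSlope = camcog_interaction_slope,
      camcogNoiseSd = camcog_noise_sd, csfShrinkDs = csf_shrink_ds,
      peakTimeS = peak_time_s, refScale = ref_scale,
      tacR1 = tac_r1, tacK2PerMin = tac_k2_per_min, seed = seed)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d train / %d DS / %d control, ",
                     "grid %dx%dx%d, offset %.1f y, seed %d\n"),
              object@nTrain, object@nDs, object@nControl,
              object@gridDims[1], object@gridDims[2], object@gridDims[3],
              object@groupOffsetYears, as.integer(object@seed)))
})

## Fixed smooth spatial fields on the normalized [-1, 1]^3 grid. Deterministic
## (no RNG): baseline GM/WM probability fields and the atrophy weighting
## patterns.
.spatialFields <- function(gridDims) {
  ax <- lapply(gridDims, function(d) seq(-1, 1, length.out = d))
  U <- array(rep(ax[[1]], times = gridDims[2] * gridDims[3]), dim = gridDims)
  V <- array(rep(rep(ax[[2]], each = gridDims[1]), times = gridDims[3]),
             dim = gridDims)
  W <- array(rep(ax[[3]], each = gridDims[1] * gridDims[2]), dim = gridDims)
  r2 <- U^2 + V^2 + W^2
  list(
    g0 = 0.25 + 0.40 * exp(-r2 / 0.6),
    w0 = 0.12 + 0.30 * exp(-r2 / 1.5) - 0.15 * exp(-r2 / 0.4),
    pattern = exp(-((U - 0.15)^2 + V^2 + W^2) / 0.5),
    patternW = exp(-(U^2 + (V + 0.1)^2 + W^2) / 0.7))
}

#' Simulate tissue maps for one effective age
#'
#' GM declines linearly with effective age under a fixed smooth spatial
#' pattern; WM declines at half the rate under its own pattern; CSF fills the
#' remaining probability (optionally shrunk, which lowers ICV without touching
#' the GM/WM features). Noise is drawn from the current RNG state.
#'
#' @param age_effective effective age in years.
#' @param config a \linkS4class{SimulationConfig}.
#' @param noise_sd per-voxel noise SD; defaults to the configured value.
#' @param csf_scale multiplicative CSF factor in (0, 1].
#' @return A \linkS4class{TissueMaps}.
#' @export
simulateTissueMaps <- function(age_effective, config,
                               noise_sd = config@featureNoiseSd,
                               csf_scale = 1) {
  validObject(config)
  f <- .spatialFields(config@gridDims)
  nv <- prod(config@gridDims)
  eps1 <- if (noise_sd > 0) array(stats::rnorm(nv, 0, noise_sd),
                                  dim = config@gridDims) else 0
  eps2 <- if (noise_sd > 0) array(stats::rnorm(nv, 0, noise_sd),
                                  dim = config@gridDims) else 0
  gm <- pmin(pmax(f$g0 - config@atrophyRate * age_effective * f$pattern +
                    eps1, 0), 1)
  wm <- pmin(pmax(f$w0 - config@atrophyRate / 2 * age_effective * f$patternW +
                    eps2, 0), 1)
  wm <- pmin(wm, 1 - gm)
  csf <- (1 - gm - wm) * csf_scale
  tissueMaps(gm, wm, csf, voxelSizeMm = config@voxelSizeMm,
             spaceTag = "synthetic-template")
}

#' Gamma-variate reference input curve on a fine time grid
#'
#' \code{C_R(t) = scale * (t / peak) * exp(1 - t / peak)} (a shape-2
#' gamma variate): zero at t = 0, maximum \code{scale} at t = peak.
#'
#' @param fine_times_s time points in seconds.
#' @param peak_time_s time of the curve maximum in seconds (> 0).
#' @param scale activity at the peak.
#' @return numeric curve values.
#' @export
referenceInputCurve <- function(fine_times_s, peak_time_s = 300, scale = 1) {
  if (peak_time_s <= 0) stop("peak_time_s must be > 0")
  u <- fine_times_s / peak_time_s
  scale * u * exp(1 - u)
}

#' Simulate a noiseless reference-region TAC
#'
#' Frame-averages the gamma-variate input curve over each frame interval.
#'
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param peak_time_s,scale curve parameters (see
#'   \code{\link{referenceInputCurve}}).
#' @param fine_dt_s fine-grid step in seconds.
#' @return A \linkS4class{TAC} with roiId "reference".
#' @export
simulateReferenceTac <- function(schedule, peak_time_s = 300, scale = 1,
                                 fine_dt_s = 1) {
  ft <- fineTimeGrid(schedule, fine_dt_s)
  fine <- referenceInputCurve(ft, peak_time_s, scale)
  tac(schedule, frameAverage(fine, ft, schedule), roiId = "reference")
}

#' Simulate a target-region TAC from the SRTM forward model
#'
#' Runs the SRTM forward model on the fine grid, frame-averages it, and adds
#' Gaussian noise with per-frame SD
#' \code{noise_cv * value * sqrt(max(duration) / duration)} (shorter frames
#' are noisier). Noise is drawn from the current RNG state.
#'
#' @param ref_fine reference curve on the fine grid.
#' @param fine_times_s fine time grid in seconds (uniform).
#' @param r1 delivery ratio (>= 0).
#' @param k2_per_min reference efflux rate in 1/min (> 0).
#' @param bpnd true binding potential (>= 0).
#' @param schedule a \linkS4class{FrameSchedule}.
#' @param noise_cv fractional noise level; 0 gives a noiseless curve.
#' @param roi_id region label for the returned TAC.
#' @return A \linkS4class{TAC}.
#' @export
simulateTargetTac <- function(ref_fine, fine_times_s, r1, k2_per_min, bpnd,
                              schedule, noise_cv = 0, roi_id = "target") {
  if (bpnd < 0) stop("bpnd must be >= 0")
  ct <- srtmForward(r1, k2_per_min, bpnd, ref_fine, fine_times_s)
  framed <- frameAverage(ct, fine_times_s, schedule)
  if (noise_cv > 0) {
    dur <- frameDuration(schedule)
    sdv <- noise_cv * abs(framed) * sqrt(max(dur) / dur)
    framed <- framed + stats::rnorm(length(framed), 0, sdv)
  }
  tac(schedule, framed, roiId = roi_id)
}

## Per-subject deterministic sub-seed blocks. Demographics + maps use
## seed + index; TACs use seed + 100000 + index, so toggling map generation
## never perturbs TACs and vice versa.
.subjectSeed <- function(config, index) as.integer(config@seed + index)
.tacSeed <- function(config, index) as.integer(config@seed + 100000 + index)

#' Generate a complete synthetic cohort
#'
#' Draws, per subject in a fixed documented order (age, sex, brain-ageing
#' deviation, then group-specific amyloid/cognition variables, then map and
#' TAC noise), a healthy training set plus DS and control test groups.
#' DS subjects have effective age = age + group offset + individual deviation;
#' everyone else omits the offset. PiB-positive DS subjects receive striatal
#' BP_ND from the positive mixture component, and CAMCOG =
#' baseline - slope * brainPAD_true * 1[PiB+] + noise.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param maps logical, generate per-subject tissue maps.
#' @param tacs logical, generate dynamic TACs for DS subjects.
#' @param schedule frame schedule for TAC simulation.
#' @param fine_dt_s fine-grid step for the SRTM forward model (s).
#' @return A list with elements \code{cohort} (data.frame; includes generative
#'   truth columns prefixed by the variables they drive), \code{maps} (named
#'   list of \linkS4class{TissueMaps} or NULL), \code{tacs} (named list, one
#'   frames x ROI activity matrix per DS subject, reference column
#'   "cerebellum_sup", or NULL), \code{regional_bpnd_true} (DS x ROI matrix),
#'   \code{schedule}, \code{catalog} and \code{config}.
#' @export
generateCohort <- function(config = simulationConfig(), maps = TRUE,
                           tacs = TRUE, schedule = standardSchedule(),
                           fine_dt_s = 1) {
  validObject(config)
  catalog <- roiCatalog()
  nonref <- catalog[catalog$class != "reference", ]
  nT <- config@nTrain; nD <- config@nDs; nC <- config@nControl
  n <- nT + nD + nC
  grp <- rep(c("train", "DS", "control"), c(nT, nD, nC))
  ids <- c(sprintf("train%03d", seq_len(nT)), sprintf("ds%03d", seq_len(nD)),
           sprintf("ctl%03d", seq_len(nC)))

  age <- sex <- padDev <- numeric(n)
  pibPos <- rep(NA, n); burden <- rep(NA_real_, n)
  camdex <- rep(NA_character_, n); camcog <- rep(NA_real_, n)
  apoe <- rep(NA_character_, n)
  camdexProbNeg <- c(stable = 24, declining = 1, dementia = 2) / 27
  camdexProbPos <- c(stable = 7, declining = 5, dementia = 7) / 19
  mapList <- if (maps) vector("list", n) else NULL
  regTrue <- matrix(NA_real_, nD, nrow(nonref),
                    dimnames = list(ids[grp == "DS"], nonref$roi_id))
  tacList <- if (tacs) vector("list", nD) else NULL

  csfScale <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.subjectSeed(config, i))
    rng <- if (grp[i] == "train") config@ageRangeTrain else config@ageRangeTest
    age[i] <- stats::runif(1, rng[1], rng[2])
    sex[i] <- stats::rbinom(1, 1, 0.5)
    padDev[i] <- stats::rnorm(1, 0, config@padSdYears)
    ## individual head-size variation through the CSF compartment; DS heads
    ## are additionally shrunk so ICV is reduced without touching GM/WM
    base <- 0.92 * if (grp[i] == "DS") config@csfShrinkDs else 1
    csfScale[i] <- min(max(stats::rnorm(1, base, 0.04), 0.5), 1)
    if (grp[i] == "DS") {
      j <- i - nT
      pibPos[i] <- stats::rbinom(1, 1, config@pibPosFraction) == 1
      burden[i] <- if (pibPos[i])
        stats::rnorm(1, config@bpndPosMean, config@bpndPosSd)
      else stats::rnorm(1, config@bpndNegMean, config@bpndNegSd)
      pr <- if (pibPos[i]) camdexProbPos else camdexProbNeg
      camdex[i] <- sample(names(pr), 1, prob = pr)
      ## amyloid-negative subjects carry no specific binding outside the
      ## striatal mixture: only striatal ROIs track the (near-zero) burden
      load <- nonref$pib_loading
      if (!pibPos[i]) load[nonref$class != "striatal"] <- 0
      regTrue[i - nT, ] <- pmax(0, load * burden[i] +
                                  stats::rnorm(nrow(nonref), 0,
                                               config@roiBpndNoiseSd))
      padTrue <- config@groupOffsetYears + padDev[i]
      camcog[i] <- config@camcogBaseline -
        config@camcogInteractionSlope * padTrue * as.numeric(pibPos[i]) +
        stats::rnorm(1, 0, config@camcogNoiseSd)
      camcog[i] <- min(max(camcog[i], 0), 107)
      apoe[i] <- if (stats::rbinom(1, 1, 0.13) == 1) NA_character_
                 else c("no", "yes")[stats::rbinom(1, 1, 0.3) + 1]
    }
    if (maps) {
      effAge <- age[i] + padDev[i] +
        if (grp[i] == "DS") config@groupOffsetYears else 0
      mapList[[i]] <- simulateTissueMaps(effAge, config,
                                         csf_scale = csfScale[i])
    }
  }

  if (tacs) {
    ft <- fineTimeGrid(schedule, fine_dt_s)
    refFine <- referenceInputCurve(ft, config@peakTimeS, config@refScale)
    refFramedIdeal <- frameAverage(refFine, ft, schedule)
    dur <- frameDuration(schedule)
    noiseScale <- sqrt(max(dur) / dur)
    for (j in seq_len(nD)) {
      i <- nT + j
      set.seed(.tacSeed(config, i))
      m <- matrix(NA_real_, nFrames(schedule), nrow(nonref) + 1,
                  dimnames = list(NULL, c(nonref$roi_id, "cerebellum_sup")))
      for (r in seq_len(nrow(nonref))) {
        m[, r] <- activity(simulateTargetTac(
          refFine, ft, config@tacR1, config@tacK2PerMin, regTrue[j, r],
          schedule, noise_cv = config@tacNoiseCv, roi_id = nonref$roi_id[r]))
      }
      refAct <- refFramedIdeal
      if (config@tacNoiseCv > 0)
        refAct <- refAct + stats::rnorm(length(refAct), 0,
                                        config@tacNoiseCv * abs(refAct) *
                                          noiseScale)
      m[, "cerebellum_sup"] <- refAct
      tacList[[j]] <- m
    }
    names(tacList) <- ids[grp == "DS"]
  }
  if (maps) names(mapList) <- ids

  effAge <- age + padDev + ifelse(grp == "DS", config@groupOffsetYears, 0)
  cohort <- data.frame(
    subject_id = ids, age_years = age,
    sex = c("male", "female")[sex + 1], group = grp,
    camdex_class = camdex, camcog = camcog, apoe_e4_carrier = apoe,
    effective_age_years = effAge, brainpad_true = effAge - age,
    pib_positive_true = pibPos, striatal_bpnd_true = burden,
    stringsAsFactors = FALSE)

  ## up to 3 dementia-class DS subjects fail to complete the CAMCOG:
  ## deterministically the lowest-index dementia cases
  dem <- which(cohort$group == "DS" &
                 !is.na(cohort$camdex_class) &
                 cohort$camdex_class == "dementia")
  if (length(dem)) cohort$camcog[dem[seq_len(min(3, length(dem)))]] <- NA

  list(cohort = cohort, maps = mapList, tacs = tacList,
       regional_bpnd_true = regTrue, schedule = schedule,
       catalog = catalog, config = config)
}
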