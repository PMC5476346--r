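## ROI time-activity curve extraction from 4D PET with GM thresholding and
## voxelwise CSF partial-volume correction.

.extractTacImpl <- function(pet_4d, mask, gm_prob, csf_prob, schedule,
                            gm_thresh, csf_cap, roi_id) {
  d <- dim(pet_4d)
  if (length(d) != 4L) stop("pet_4d must be a 4D array")
  if (d[4L] != nFrames(schedule))
    stop(sprintf("PET has %d frames but schedule has %d", d[4L],
                 nFrames(schedule)))
  d3 <- d[1:3]
  for (nm in list(mask = mask, gm_prob = gm_prob, csf_prob = csf_prob))
    if (!identical(dim(nm), d3)) stop("mask/probability volumes must match PET grid")
  include <- (mask > 0) & (gm_prob >= gm_thresh)
  if (!any(include))
    stop(sprintf("ROI '%s': no voxels survive the %.0f%% GM threshold",
                 roi_id, 100 * gm_thresh))
  capped <- include & (csf_prob > csf_cap)
  if (any(capped)) {
    message(sprintf("ROI '%s': excluded %d voxel(s) with CSF probability > %.2f",
                    roi_id, sum(capped), csf_cap))
    include <- include & !capped
  }
  if (!any(include))
    stop(sprintf("ROI '%s': no voxels remain after the CSF cap", roi_id))
  idx <- which(include)
  petMat <- matrix(pet_4d, prod(d3), d[4L])[idx, , drop = FALSE]
  ## voxelwise partial-volume correction: divide each voxel TAC by
  ## (1 - CSF probability) before averaging over the ROI
  corr <- petMat / (1 - csf_prob[idx])
  tac(schedule, colMeans(corr), roiId = roi_id)
}

#' Extract a CSF-corrected ROI time-activity curve
#'
#' Voxels enter the ROI if they carry the label and have GM probability at or
#' above \code{gm_thresh} (default 65\%). Each included voxel's TAC is divided
#' by (1 - CSF probability) at that voxel; voxels with CSF probability above
#' \code{csf_cap} are excluded (with a logged count) rather than divided. The
#' ROI TAC is the unweighted mean over included voxels; fit weights default to
#' frame durations.
#'
#' @param pet_4d 4D PET array (x, y, z, frame).
#' @param roi_mask 3D array, nonzero inside the ROI.
#' @param gm_prob,csf_prob 3D tissue-probability arrays aligned with the PET.
#' @param schedule a \linkS4class{FrameSchedule} matching the 4th dimension.
#' @param gm_thresh GM inclusion threshold (default 0.65).
#' @param csf_cap CSF exclusion cap (default 0.95).
#' @param roi_id label used in messages and the returned TAC.
#' @return A \linkS4class{TAC}.
#' @export
extractRoiTac <- function(pet_4d, roi_mask, gm_prob, csf_prob, schedule,
                          gm_thresh = 0.65, csf_cap = 0.95, roi_id = "roi") {
  .extractTacImpl(pet_4d, roi_mask, gm_prob, csf_prob, schedule, gm_thresh,
                  csf_cap, roi_id)
}

#' Extract the reference-region (superior cerebellum) TAC
#'
#' Identical to \code{\link{extractRoiTac}} but with the stricter 90\% GM
#' probability threshold used for the reference region.
#'
#' @inheritParams extractRoiTac
#' @param cerebellum_mask 3D array, nonzero inside the reference region.
#' @return A \linkS4class{TAC}.
#' @export
extractReferenceTac <- function(pet_4d, cerebellum_mask, gm_prob, csf_prob,
                                schedule, gm_thresh = 0.90, csf_cap = 0.95,
                                roi_id = "cerebellum_sup") {
  .extractTacImpl(pet_4d, cerebellum_mask, gm_prob, csf_prob, schedule,
                  gm_thresh, csf_cap, roi_id)
}
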