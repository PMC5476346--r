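## Amyloid (PiB) status: striatal summary, SD-from-zero positivity
## classification, regional abnormality flags and per-subject profiles.

#' Read a ROI catalog CSV
#'
#' Columns: roi_id, class (cortical / striatal / other_subcortical /
#' reference) and pib_loading (the regional loading used by the synthetic
#' generator). Any 30-ROI atlas can be slotted in by editing the CSV.
#'
#' @param path CSV path; defaults to the catalog shipped with the package.
#' @return data.frame catalog.
#' @export
readRoiCatalog <- function(path = system.file("extdata", "roi_catalog.csv",
                                              package = "neurochron")) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "class", "pib_loading")
  miss <- setdiff(need, names(cat))
  if (length(miss))
    stop(sprintf("ROI catalog missing column(s): %s",
                 paste(miss, collapse = ", ")))
  bad <- setdiff(unique(cat$class),
                 c("cortical", "striatal", "other_subcortical", "reference"))
  if (length(bad))
    stop(sprintf("unknown ROI class(es): %s", paste(bad, collapse = ", ")))
  cat
}

#' The default 30-ROI catalog (plus the cerebellar reference region)
#'
#' Twenty cortical regions, bilateral caudate and putamen (the striatal set),
#' six other subcortical regions, and the superior cerebellum reference.
#'
#' @return data.frame: roi_id, class, pib_loading.
#' @export
roiCatalog <- function() readRoiCatalog()

.striatalIds <- function(catalog) catalog$roi_id[catalog$class == "striatal"]

#' Striatal BP_ND summary for one subject
#'
#' Unweighted mean of BP_ND over the striatal ROIs (lateralized caudate and
#' putamen).
#'
#' @param regional_bpnd named numeric vector of per-ROI BP_ND.
#' @param catalog ROI catalog (default \code{\link{roiCatalog}}).
#' @return numeric scalar.
#' @export
striatalBpnd <- function(regional_bpnd, catalog = roiCatalog()) {
  ids <- .striatalIds(catalog)
  miss <- setdiff(ids, names(regional_bpnd))
  if (length(miss))
    stop(sprintf("missing striatal ROI(s): %s", paste(miss, collapse = ", ")))
  mean(regional_bpnd[ids])
}

#' Classify PiB status from striatal BP_ND across a cohort
#'
#' A subject is PiB-negative iff striatal BP_ND is less than one SD from
#' zero, and PiB-positive iff at or above it. Three readings of "one SD" are
#' offered. \code{"cohort"} (default): sigma0 is the sample SD of the
#' striatal values across the whole (bimodal) cohort. \code{"iterative"}:
#' the SD of the negative mode is estimated self-consistently - initialize
#' sigma0 = SD of all values, classify, re-estimate sigma0 as the
#' root-mean-square of the currently negative values about zero, and repeat
#' to a fixed point (at most 50 iterations, sigma floor 1e-6); note this
#' fixed point is the negative-mode SD, whose 1-sigma threshold flips the
#' upper tail of the negatives, so it is deliberately not the default.
#' \code{"fixed"}: \code{fixed_sd} is used directly.
#'
#' @param striatal numeric striatal BP_ND values (>= 3 subjects).
#' @param sd_mode "cohort", "iterative" or "fixed".
#' @param fixed_sd the SD to use in fixed mode.
#' @param max_iter iteration cap.
#' @return list: status (factor, levels negative/positive), sigma0,
#'   iterations, sd_mode.
#' @export
classifyPibStatus <- function(striatal,
                              sd_mode = c("cohort", "iterative", "fixed"),
                              fixed_sd = NULL, max_iter = 50) {
  sd_mode <- match.arg(sd_mode)
  if (length(striatal) < 3L) stop("need at least 3 subjects")
  floorSd <- 1e-6
  if (sd_mode == "fixed") {
    if (is.null(fixed_sd) || fixed_sd <= 0)
      stop("fixed mode requires fixed_sd > 0")
    sigma <- fixed_sd
    iterations <- 0L
  } else if (sd_mode == "cohort") {
    sigma <- max(stats::sd(striatal), floorSd)
    iterations <- 0L
  } else {
    sigma <- max(stats::sd(striatal), floorSd)
    iterations <- 0L
    repeat {
      pos <- striatal >= sigma
      if (all(pos))
        stop("degenerate all-positive split; supply fixed_sd")
      signew <- max(sqrt(mean(striatal[!pos]^2)), floorSd)
      iterations <- iterations + 1L
      if (identical(striatal >= signew, pos)) { sigma <- signew; break }
      sigma <- signew
      if (iterations >= max_iter)
        stop("PiB-status classification did not converge; supply fixed_sd")
    }
  }
  status <- factor(ifelse(striatal >= sigma, "positive", "negative"),
                   levels = c("negative", "positive"))
  list(status = status, sigma0 = sigma, iterations = iterations,
       sd_mode = sd_mode)
}

#' Regional abnormality flags
#'
#' For each ROI, the mean and SD of BP_ND are computed over the PiB-negative
#' subjects; a subject is abnormal in that ROI iff its BP_ND is at or above
#' mean + 2 SD. When the negative group is constant in a ROI (SD = 0),
#' equality with the mean still counts as abnormal (the >= rule applied
#' literally).
#'
#' @param bpnd_matrix subjects x ROI matrix of BP_ND.
#' @param status factor/character of per-subject PiB status
#'   ("negative"/"positive"), aligned with the rows.
#' @return logical subjects x ROI matrix of abnormality flags.
#' @export
regionalAbnormality <- function(bpnd_matrix, status) {
  stopifnot(is.matrix(bpnd_matrix), nrow(bpnd_matrix) == length(status))
  neg <- status == "negative"
  if (sum(neg) < 2L) stop("need at least 2 PiB-negative subjects")
  mu <- colMeans(bpnd_matrix[neg, , drop = FALSE])
  s <- apply(bpnd_matrix[neg, , drop = FALSE], 2L, stats::sd)
  thr <- mu + 2 * s
  flags <- sweep(bpnd_matrix, 2L, thr, ">=")
  dimnames(flags) <- dimnames(bpnd_matrix)
  flags
}

#' Complete per-subject PiB profiles
#'
#' Counts abnormal ROIs over the 30-ROI catalog (bounded 0-30) and computes
#' the unweighted mean BP_ND over the cortical ROIs.
#'
#' @param flags logical subjects x ROI abnormality matrix.
#' @param bpnd_matrix subjects x ROI BP_ND matrix.
#' @param catalog ROI catalog.
#' @param striatal per-subject striatal BP_ND.
#' @param status per-subject PiB status.
#' @return data.frame: subject_id, striatal_bpnd, status, abnormal_count,
#'   mean_cortical_bpnd.
#' @export
summarizeProfiles <- function(flags, bpnd_matrix, catalog = roiCatalog(),
                              striatal, status) {
  nonref <- intersect(colnames(bpnd_matrix),
                      catalog$roi_id[catalog$class != "reference"])
  cort <- intersect(colnames(bpnd_matrix),
                    catalog$roi_id[catalog$class == "cortical"])
  ids <- rownames(bpnd_matrix)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(nrow(bpnd_matrix)))
  data.frame(
    subject_id = ids, striatal_bpnd = striatal,
    status = as.character(status),
    abnormal_count = rowSums(flags[, nonref, drop = FALSE]),
    mean_cortical_bpnd = rowMeans(bpnd_matrix[, cort, drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Full amyloid profiling of a BP_ND table
#'
#' Convenience wrapper: striatal summaries, PiB-status classification,
#' regional abnormality flags and profile completion in one call.
#'
#' @param bpnd_matrix subjects x ROI BP_ND matrix (ROI ids as column names).
#' @param catalog ROI catalog.
#' @param sd_mode,fixed_sd passed to \code{\link{classifyPibStatus}}.
#' @return list: profiles (data.frame), flags (logical matrix), sigma0,
#'   sd_mode.
#' @export
amyloidProfiles <- function(bpnd_matrix, catalog = roiCatalog(),
                            sd_mode = "cohort", fixed_sd = NULL) {
  striatal <- apply(bpnd_matrix, 1L, striatalBpnd, catalog = catalog)
  cls <- classifyPibStatus(striatal, sd_mode = sd_mode, fixed_sd = fixed_sd)
  flags <- regionalAbnormality(bpnd_matrix, cls$status)
  prof <- summarizeProfiles(flags, bpnd_matrix, catalog, striatal, cls$status)
  list(profiles = prof, flags = flags, sigma0 = cls$sigma0,
       sd_mode = cls$sd_mode)
}
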