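## File interfaces: cohort CSV, NIfTI volumes (via RNifti), TAC TSV, kernel
## CSV, and YAML round-tripping of the simulation configuration.
## Conventions: UTF-8 comma CSV with a header row and "." decimal; missing
## values are empty strings; voxel indices 0-based on disk; frame intervals
## half-open [start, start + duration); ages in years; BP_ND unitless.

.COHORT_MANDATORY <- c("subject_id", "age_years", "sex", "group")

#' Read a cohort table
#'
#' Mandatory columns: subject_id, age_years, sex (male/female), group
#' (train/DS/control); optional: camdex_class (stable/declining/dementia),
#' camcog (0-107, may be missing), apoe_e4_carrier (yes/no, may be missing).
#' Unknown categorical levels and non-numeric ages are rejected with the
#' offending row named.
#'
#' @param path CSV file path.
#' @return typed data.frame.
#' @export
readCohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(.COHORT_MANDATORY, names(raw))
  if (length(miss))
    stop(sprintf("cohort file missing mandatory column(s): %s",
                 paste(miss, collapse = ", ")))
  num <- function(col, name) {
    blank <- is.na(raw[[col]]) | raw[[col]] == ""
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !blank)
    if (length(bad))
      stop(sprintf("non-numeric %s '%s' in row %d", name, raw[[col]][bad[1L]],
                   bad[1L]))
    v
  }
  lev <- function(col, allowed) {
    if (!col %in% names(raw)) return(NULL)
    v <- raw[[col]]
    v[v == ""] <- NA_character_
    bad <- which(!is.na(v) & !v %in% allowed)
    if (length(bad))
      stop(sprintf("unknown %s level '%s' in row %d", col, v[bad[1L]],
                   bad[1L]))
    v
  }
  out <- data.frame(subject_id = raw$subject_id,
                    age_years = num("age_years", "age"),
                    sex = lev("sex", c("male", "female")),
                    group = lev("group", c("train", "DS", "control")),
                    stringsAsFactors = FALSE)
  if (anyNA(out$age_years)) {
    bad <- which(is.na(out$age_years))
    stop(sprintf("missing age in row %d", bad[1L]))
  }
  cd <- lev("camdex_class", c("stable", "declining", "dementia", "missing"))
  if (!is.null(cd)) out$camdex_class <- cd
  if ("camcog" %in% names(raw)) out$camcog <- num("camcog", "CAMCOG score")
  ap <- lev("apoe_e4_carrier", c("yes", "no", "missing"))
  if (!is.null(ap)) out$apoe_e4_carrier <- ap
  out
}

#' Write a cohort (or any) table as CSV
#'
#' Missing values become empty strings.
#'
#' @param tbl data.frame; \code{path} destination.
#' @param path destination path.
#' @export
writeCohort <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path .nii or .nii.gz file.
#' @param expect_dims optional expected dimensionality (3 or 4); mismatches
#'   raise an error.
#' @return list: data (array), voxel_size_mm (per spatial axis).
#' @export
readVolume <- function(path, expect_dims = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (!is.null(expect_dims) && length(dim(arr)) != expect_dims)
    stop(sprintf("expected a %dD volume, got %dD", expect_dims,
                 length(dim(arr))))
  pd <- RNifti::pixdim(img)
  list(data = arr, voxel_size_mm = pd[seq_len(min(3L, length(pd)))])
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric array.
#' @param path destination (.nii or .nii.gz).
#' @param voxel_size_mm spatial voxel dimensions in mm.
#' @param datatype storage type (default single-precision float).
#' @export
writeVolume <- function(data, path, voxel_size_mm = c(1.5, 1.5, 1.5),
                        datatype = "float") {
  arr <- data
  attr(arr, "pixdim") <- c(voxel_size_mm,
                           rep(1, max(0L, length(dim(data)) - 3L)))
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = datatype), path,
                     datatype = datatype)
  invisible(path)
}

#' Write per-ROI TACs as TSV
#'
#' Columns: frame_start_s, frame_duration_s, then one activity column per
#' ROI id.
#'
#' @param tac_matrix frames x ROI matrix (ROI ids as column names).
#' @param schedule the \linkS4class{FrameSchedule}.
#' @param path destination TSV.
#' @export
writeTacs <- function(tac_matrix, schedule, path) {
  stopifnot(nrow(tac_matrix) == nFrames(schedule))
  df <- data.frame(frame_start_s = frameStart(schedule),
                   frame_duration_s = frameDuration(schedule),
                   tac_matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-ROI TACs from TSV
#'
#' @param path TSV written by \code{\link{writeTacs}}.
#' @return list: schedule (\linkS4class{FrameSchedule}), activity (frames x
#'   ROI matrix).
#' @export
readTacs <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("frame_start_s", "frame_duration_s")
  if (!all(need %in% names(df)))
    stop("TAC file must have frame_start_s and frame_duration_s columns")
  sched <- frameSchedule(df$frame_duration_s)
  if (max(abs(frameStart(sched) - df$frame_start_s)) > 1e-6)
    stop("frame starts are not contiguous with durations")
  act <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  list(schedule = sched, activity = act)
}

#' Write / read a kernel matrix as CSV with subject-id headers
#'
#' @param K matrix with subject ids as dimnames.
#' @param path CSV path.
#' @export
writeKernel <- function(K, path) {
  utils::write.csv(K, path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

.configSlots <- function() {
  methods::slotNames("SimulationConfig")
}

#' Serialize a simulation configuration to YAML
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path destination YAML file.
#' @export
writeConfig <- function(config, path) {
  vals <- lapply(.configSlots(), function(s) as.numeric(slot(config, s)))
  names(vals) <- .configSlots()
  yaml::write_yaml(vals, path, precision = 15)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' Round-trips \code{\link{writeConfig}} exactly.
#'
#' @param path YAML file.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  miss <- setdiff(.configSlots(), names(vals))
  if (length(miss))
    stop(sprintf("config file missing field(s): %s",
                 paste(miss, collapse = ", ")))
  vals <- lapply(vals[.configSlots()], as.numeric)
  cfg <- do.call(methods::new, c(list("SimulationConfig"), vals))
  validObject(cfg)
  cfg
}
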