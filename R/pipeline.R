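## End-to-end orchestration: simulate -> features -> train/CV -> predict ->
## kinetics -> amyloid -> association statistics, with stage outputs written
## as CSV and the run stamped with its configuration and seed.

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a cohort, builds smoothed GM+WM feature vectors and kernels,
#' fits the GP age model on the training subjects with 10-fold
#' cross-validation and a permutation test, predicts brain age (and
#' brain-PAD) for the DS and control test subjects, quantifies regional
#' BP_ND by basis-function SRTM from the simulated dynamic TACs, classifies
#' PiB status and regional abnormality, and fits the association-model
#' battery on the merged table.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param out_dir optional directory; when given, stage outputs are written
#'   as CSV (cohort, kernel, predictions, accuracy, bpnd, profiles,
#'   associations) plus a \code{run_info.yaml} stamped with the full
#'   configuration, the seed and the config file's MD5 hash.
#' @param seed run seed (defaults to the config seed; overrides it).
#' @param fwhm_mm feature smoothing FWHM in mm (default 4).
#' @param folds cross-validation folds (default 10).
#' @param n_perm permutations for the significance test (default 100;
#'   0 skips the test).
#' @param optimize_hyper_perm re-optimize GP hyperparameters inside each
#'   permutation (conservative but slow); default FALSE reuses the full-fit
#'   hyperparameters.
#' @param sd_mode PiB classification mode ("cohort", "iterative" or "fixed").
#' @param fixed_sd fixed sigma for \code{sd_mode = "fixed"}.
#' @param theta3_grid SRTM basis grid (1/min).
#' @param write_volumes also write every subject's tissue maps as NIfTI
#'   (slow; default FALSE).
#' @return (invisibly) a list: cohort, model, cv, accuracy, permutation,
#'   predictions, volumes, bpnd, amyloid, merged, models, demographics,
#'   config.
#' @export
runPipeline <- function(config = simulationConfig(), out_dir = NULL,
                        seed = NULL, fwhm_mm = 4, folds = 10, n_perm = 100,
                        optimize_hyper_perm = FALSE,
                        sd_mode = "cohort", fixed_sd = NULL,
                        theta3_grid = defaultTheta3Grid(),
                        write_volumes = FALSE) {
  if (!is.null(seed)) config@seed <- as.numeric(seed)
  validObject(config)
  seed <- as.integer(config@seed)

  sim <- generateCohort(config)
  cohort <- sim$cohort
  isTrain <- cohort$group == "train"
  trainIds <- cohort$subject_id[isTrain]
  testIds <- cohort$subject_id[!isTrain]

  ## features and kernels
  X <- featureMatrix(sim$maps, fwhm_mm = fwhm_mm)
  Ktrain <- linearKernel(X[trainIds, , drop = FALSE])
  Kcross <- crossKernel(X[trainIds, , drop = FALSE],
                        X[testIds, , drop = FALSE])

  ## GP age model: training-set cross-validation + permutation significance,
  ## then unbiased test-set predictions from the full training fit
  agesTrain <- cohort$age_years[isTrain]
  model <- fitGPR(Ktrain, agesTrain)
  cv <- crossvalPredict(Ktrain, agesTrain, k = folds, seed = seed)
  accuracy <- performanceMetrics(cv$age_years, cv$brain_predicted_age)
  permutation <- if (n_perm > 0)
    permutationTest(Ktrain, agesTrain, n_perm = n_perm, k = folds,
                    seed = seed, optimize_hyper = optimize_hyper_perm)
  else NULL
  predictions <- brainAgePredictions(model, Kcross,
                                     cohort$age_years[!isTrain], testIds)

  ## summary volumes for the test subjects
  volumes <- do.call(rbind, lapply(testIds, function(id)
    cbind(subject_id = id, summaryVolumes(sim$maps[[id]]))))

  ## SRTM kinetics for DS subjects, then amyloid profiling
  dsIds <- cohort$subject_id[cohort$group == "DS"]
  nonrefIds <- sim$catalog$roi_id[sim$catalog$class != "reference"]
  bpndTab <- t(vapply(dsIds, function(id) {
    m <- sim$tacs[[id]]
    ref <- tac(sim$schedule, m[, "cerebellum_sup"], roiId = "cerebellum_sup")
    fits <- suppressWarnings(
      srtmFitRegions(m[, nonrefIds, drop = FALSE], ref,
                     theta3_grid = theta3_grid))
    stats::setNames(fits$bpnd, fits$roi_id)
  }, numeric(length(nonrefIds))))
  amyloid <- amyloidProfiles(bpndTab, sim$catalog, sd_mode = sd_mode,
                             fixed_sd = fixed_sd)

  ## merged analysis table and association battery
  merged <- merge(cohort[!isTrain, ], predictions[, c("subject_id",
                                                      "brain_predicted_age",
                                                      "brain_pad")],
                  by = "subject_id")
  merged <- merge(merged, volumes, by = "subject_id")
  prof <- amyloid$profiles
  names(prof)[names(prof) == "status"] <- "pib_status"
  merged <- merge(merged, prof, by = "subject_id", all.x = TRUE)
  models <- runAssociationModels(merged)
  demographics <- demographicTests(merged)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeCohort(cohort, file.path(out_dir, "cohort.csv"))
    writeKernel(Ktrain, file.path(out_dir, "kernel_train.csv"))
    writeCohort(cv, file.path(out_dir, "cv_predictions.csv"))
    writeCohort(accuracy, file.path(out_dir, "accuracy.csv"))
    writeCohort(predictions, file.path(out_dir, "predictions.csv"))
    writeCohort(as.data.frame(bpndTab), file.path(out_dir, "bpnd.csv"))
    writeCohort(prof, file.path(out_dir, "profiles.csv"))
    writeCohort(associationTable(models), file.path(out_dir,
                                                    "associations.csv"))
    cfgPath <- file.path(out_dir, "config.yaml")
    writeConfig(config, cfgPath)
    yaml::write_yaml(list(seed = seed,
                          config_md5 = unname(tools::md5sum(cfgPath)),
                          n_perm = n_perm, folds = folds, fwhm_mm = fwhm_mm,
                          sd_mode = sd_mode,
                          permutation_p = if (is.null(permutation)) NA
                                          else permutation$p),
                     file.path(out_dir, "run_info.yaml"))
    if (write_volumes) {
      volDir <- file.path(out_dir, "maps")
      dir.create(volDir, showWarnings = FALSE)
      for (id in cohort$subject_id) {
        m <- sim$maps[[id]]
        writeVolume(gmMap(m), file.path(volDir, paste0(id, "_gm.nii.gz")),
                    voxelSize(m))
        writeVolume(wmMap(m), file.path(volDir, paste0(id, "_wm.nii.gz")),
                    voxelSize(m))
        writeVolume(csfMap(m), file.path(volDir, paste0(id, "_csf.nii.gz")),
                    voxelSize(m))
      }
    }
  }

  invisible(list(cohort = cohort, model = model, cv = cv,
                 accuracy = accuracy, permutation = permutation,
                 predictions = predictions, volumes = volumes,
                 bpnd = bpndTab, amyloid = amyloid, merged = merged,
                 models = models, demographics = demographics,
                 config = config))
}
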