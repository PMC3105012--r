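#' Voxel-wise deformation statistics for an atlas
#'
#' Convenience wrapper running the deformation-based morphometry stage on a
#' built atlas: per-subject Jacobian determinant maps of the nonlinear
#' fields on the model grid, Gaussian blurring (8 mm FWHM by default), the
#' face-region search mask, the voxel-wise GLM and the random-field
#' correction.
#'
#' @param atlas A `cranio_atlas`.
#' @param covariates data.frame with `subject`, `sex`, `age_months` (rows in
#'   atlas subject order); head size is taken from the atlas.
#' @param contrast `"sex"` or `"age"` (or a numeric contrast over the design
#'   columns intercept, sex, age, headsize).
#' @param blur_fwhm_mm Jacobian smoothing FWHM.
#' @param forehead_plane_y Coronal plane (world y, mm) bounding the face
#'   region; voxels posterior to it are excluded.
#' @param alpha Family-wise level for the correction.
#' @param subset Optional logical vector selecting subjects (e.g. one sex
#'   for the within-sex age analyses).
#' @return List with `stat` (`cranio_statmap`), `clusters`
#'   (`cranio_clustertable`), `jacobians` and `mask`.
#' @export
dbm_stats <- function(atlas, covariates, contrast = "sex", blur_fwhm_mm = 8,
                      forehead_plane_y = 0, alpha = 0.05, subset = NULL) {
  stopifnot(inherits(atlas, "cranio_atlas"))
  n <- length(atlas$nonlinear)
  if (nrow(covariates) != n) stop("covariate rows must match atlas subjects")
  keep <- if (is.null(subset)) rep(TRUE, n) else subset
  geom <- geometry(atlas$model)
  jac <- lapply(atlas$nonlinear[keep], function(f)
    gaussian_blur(jacobian_map(f, geom), blur_fwhm_mm))
  mask <- make_face_mask(atlas$model, forehead_plane_y)
  cv <- covariates[keep, , drop = FALSE]
  X <- cbind(intercept = 1, sex = sex_code(cv$sex),
             age = cv$age_months - mean(cv$age_months),
             headsize = atlas$headsize[keep] - mean(atlas$headsize[keep]))
  same_sex <- length(unique(cv$sex)) == 1
  if (same_sex) X <- X[, colnames(X) != "sex", drop = FALSE]
  cvec <- if (is.numeric(contrast)) contrast
          else as.numeric(colnames(X) == match.arg(contrast, colnames(X)))
  if (length(cvec) != ncol(X) || all(cvec == 0))
    stop("contrast does not match the design columns: ",
         paste(colnames(X), collapse = ", "))
  stat <- fit_glm(jac, X, cvec, mask, fwhm_mm = blur_fwhm_mm)
  clusters <- rft_correct(stat, alpha = alpha)
  list(stat = stat, clusters = clusters, jacobians = jac, mask = mask)
}

#' Pipeline configuration
#'
#' Bundles and validates everything [run_pipeline()] needs. Defaults
#' reproduce the package's standard settings: the full six-generation
#' registration schedule for 1 mm human data (or the scaled phantom schedule
#' when `cohort` is synthetic), 8 mm Jacobian blur, face mask plane at
#' y = 0 mm, alpha = 0.05 and five analysed principal components.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param cohort A [cohort_spec()] to synthesise inputs, or `NULL` when
#'   `input_volumes`/`input_covariates` point at existing data.
#' @param input_volumes Character vector of NIfTI paths (one per subject).
#' @param input_covariates TSV path with subject, sex, age_months columns.
#' @param schedule A [nonlinear_schedule()].
#' @param blur_fwhm_mm,forehead_plane_y,alpha,n_pcs,seed Stage parameters.
#' @param write_volumes Also write model/phantom volumes as NIfTI.
#' @return Validated config list of class `cranio_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_spec(),
                            input_volumes = NULL, input_covariates = NULL,
                            schedule = NULL, blur_fwhm_mm = 8,
                            forehead_plane_y = 0, alpha = 0.05, n_pcs = 5,
                            seed = 1L, write_volumes = FALSE) {
  if (is.null(cohort)) {
    if (is.null(input_volumes) || is.null(input_covariates))
      stop("configuration error: either a synthetic cohort spec or input ",
           "volumes plus a covariate table must be provided")
    missing <- input_volumes[!file.exists(input_volumes)]
    if (length(missing))
      stop("configuration error: missing input volume(s): ",
           paste(missing, collapse = ", "))
    if (!file.exists(input_covariates))
      stop("configuration error: covariate file not found: ", input_covariates)
  }
  if (is.null(schedule))
    schedule <- if (is.null(cohort)) full_schedule() else phantom_schedule()
  stopifnot(inherits(schedule, "cranio_schedule"))
  structure(list(out_dir = out_dir, cohort = cohort,
                 input_volumes = input_volumes,
                 input_covariates = input_covariates, schedule = schedule,
                 blur_fwhm_mm = blur_fwhm_mm,
                 forehead_plane_y = forehead_plane_y, alpha = alpha,
                 n_pcs = n_pcs, seed = as.integer(seed),
                 write_volumes = isTRUE(write_volumes)),
            class = "cranio_config")
}

#' Run the full craniofacial morphometry pipeline
#'
#' Executes, in order: input synthesis (or loading), group-wise atlas
#' construction, voxel-wise Jacobian statistics with random-field
#' correction, landmark propagation, anthropometric distance models, the
#' point-distribution model with PC-score models, and thin-plate-spline
#' simulation of the leading component. Every stage writes its tabular
#' outputs under `out_dir`, and a `config.json` snapshot (settings, seed,
#' package version, per-stage log) makes the run reproducible; identical
#' configs and seeds give byte-identical tabular outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `atlas`, `dbm`, `landmarks`, `anthro`, `pdm`, `simulation`) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "cranio_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage_log <- character(0)
  log_stage <- function(name) {
    stage_log <<- c(stage_log, name)
    if (verbose) message("[", name, "]")
  }

  log_stage("inputs")
  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort, verbose = verbose)
    volumes <- cohort$volumes
    covariates <- cohort$covariates
  } else {
    volumes <- lapply(config$input_volumes, read_volume)
    covariates <- read.delim(config$input_covariates, stringsAsFactors = FALSE)
    need <- c("subject", "sex", "age_months")
    if (!all(need %in% names(covariates)))
      stop("configuration error: covariate table must have columns ",
           paste(need, collapse = ", "))
    if (length(volumes) != nrow(covariates))
      stop("configuration error: ", length(volumes), " volumes but ",
           nrow(covariates), " covariate rows")
    names(volumes) <- covariates$subject
    cohort <- list(volumes = volumes, covariates = covariates, truth = NULL)
  }
  wt <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(covariates, "covariates.tsv")

  log_stage("build-atlas")
  atlas <- build_atlas(volumes, schedule = config$schedule, verbose = verbose)
  wt(data.frame(subject = covariates$subject, headsize = atlas$headsize),
     "headsize.tsv")
  wt(cbind(subject_id = covariates$subject, atlas$qc[-1]), "qc_report.tsv")
  if (config$write_volumes)
    write_volume(atlas$model, file.path(out, "model.nii.gz"))

  log_stage("dbm-stats")
  dbm <- dbm_stats(atlas, covariates, contrast = "sex",
                   blur_fwhm_mm = config$blur_fwhm_mm,
                   forehead_plane_y = config$forehead_plane_y,
                   alpha = config$alpha)
  wt(as.data.frame(dbm$clusters), "dbm_clusters_sex.tsv")
  jsonlite::write_json(list(df = dbm$stat$df,
                            fwhm_est_mm = as.numeric(dbm$stat$fwhm_est_mm),
                            threshold = attr(dbm$clusters, "threshold"),
                            n_mask_voxels = sum(dbm$mask$data != 0)),
                       file.path(out, "dbm_stats_sex.json"),
                       auto_unbox = TRUE, digits = NA)

  log_stage("propagate-landmarks")
  template <- face_template_landmarks()
  dir.create(file.path(out, "landmarks"), showWarnings = FALSE)
  propagated <- lapply(seq_along(atlas$nonlinear), function(i) {
    lm <- propagate_landmarks(template, atlas$nonlinear[[i]])
    write_landmarks(lm, file.path(out, "landmarks",
                                  paste0(covariates$subject[i], ".tsv")))
    lm
  })
  names(propagated) <- covariates$subject

  log_stage("anthropometrics")
  spec <- default_anthro_spec()
  meas <- do.call(rbind, lapply(covariates$subject, function(id) {
    cbind(subject = id, anthropometrics(propagated[[id]], spec))
  }))
  wt(meas, "anthro_measures.tsv")
  anthro <- fit_anthro_models(meas, covariates)
  wt(anthro$coefficients, "anthro_coefficients.tsv")
  wt(anthro$age_slopes, "anthro_age_slopes.tsv")

  log_stage("pdm-fit")
  pdm <- fit_pdm(propagated, template)
  write_pdm(pdm, file.path(out, "pdm"))
  scores <- analyze_scores(pdm, covariates, n_pcs = config$n_pcs)
  wt(scores$coefficients, "pc_coefficients.tsv")
  wt(scores$age_slopes, "pc_age_slopes.tsv")

  log_stage("pdm-simulate")
  sims <- simulate_pc(pdm, 1)
  for (s in sims)
    write_landmarks(s$landmarks,
                    file.path(out, sprintf("sim_pc1_p%03d.tsv",
                                           round(100 * s$proportion))))

  jsonlite::write_json(list(package_version = as.character(utils::packageVersion("craniomorph")),
                            seed = config$seed,
                            schedule = as.data.frame(config$schedule),
                            blur_fwhm_mm = config$blur_fwhm_mm,
                            forehead_plane_y = config$forehead_plane_y,
                            alpha = config$alpha, n_pcs = config$n_pcs,
                            stages = stage_log),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, atlas = atlas, dbm = dbm,
                 landmarks = propagated, anthro = anthro, pdm = pdm,
                 simulation = sims, out_dir = out))
}
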