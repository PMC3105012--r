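#' Iterative minimally biased group-wise atlas construction
#'
#' Builds a population-average head volume and per-subject transforms by the
#' hierarchical scheme:
#' \enumerate{
#'   \item rigid (6-parameter) alignment of every volume to a seed subject;
#'   \item all-pairs 9-parameter registrations; for each subject the
#'     matrix-logarithm average of the transforms from every other subject's
#'     space into its own is applied, scaling each scan to the average head
#'     and face size of the population, and the scans are intensity-averaged;
#'   \item 12-parameter registration of the (rigid-aligned) scans to that
#'     average and a new average;
#'   \item one nonlinear generation per schedule row: every subject is
#'     nonlinearly registered to the previous generation's average and the
#'     voxel-wise mean of the resampled scans becomes the next model.
#' }
#' Each unordered 9-parameter pair is registered once and the matrix inverse
#' reused for the reverse direction (identical in exact arithmetic, half the
#' cost). The per-subject head-size factor is the product of the three scale
#' factors of the averaged 9-parameter transform; it grows with head volume
#' and is the standard covariate for the voxel-wise models.
#'
#' @param volumes List of >= 3 [cranio_volume] objects (brain-stripped heads).
#' @param schedule [nonlinear_schedule()]; one generation per row.
#' @param seed_index Index of the initial target scan (default 1; the choice
#'   only seeds the rigid stage and has negligible effect on the final model).
#' @param config [optimizer_config()] for the nonlinear stages.
#' @param qc_threshold_ncc Subjects whose final-model NCC falls below this are
#'   flagged in the QC report (never silently dropped).
#' @param verbose Print per-stage progress.
#' @return An object of class `cranio_atlas`: fields `model` (final
#'   [cranio_volume]), `models` (per-stage averages, named), `linear`
#'   (per-subject total linear pull-back, model space to native),
#'   `affine12`, `nonlinear` (per-subject [cranio_field], model to
#'   subject-linear space), `headsize`, `variance_trace` (mean voxel-wise
#'   across-subject intensity variance in the head mask after each stage) and
#'   `qc` (see [qc_registration()]).
#' @export
build_atlas <- function(volumes, schedule = phantom_schedule(), seed_index = 1L,
                        config = optimizer_config(), qc_threshold_ncc = 0.85,
                        verbose = FALSE) {
  n <- length(volumes)
  if (n < 3) stop("atlas construction needs at least 3 volumes")
  stopifnot(all(vapply(volumes, is_volume, logical(1))))
  say <- function(...) if (verbose) message(sprintf(...))

  seed <- volumes[[seed_index]]
  geom <- geometry(seed)

  ## stage 1: rigid alignment to the seed
  say("stage 1: rigid alignment of %d volumes to seed %d", n, seed_index)
  rigid <- vector("list", n)
  aligned <- vector("list", n)
  for (i in seq_len(n)) {
    rigid[[i]] <- if (i == seed_index) affine_transform()
                  else register_linear(volumes[[i]], seed, dof = 6)
    aligned[[i]] <- resample(volumes[[i]], rigid[[i]], geom)
  }

  ## stage 2: all-pairs 9-parameter, log-space average per subject
  say("stage 2: %d pairwise 9-parameter registrations", n * (n - 1) / 2)
  pair <- vector("list", n)
  for (i in seq_len(n)) pair[[i]] <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      # pull-back from j's space into i's space
      pij <- register_linear(aligned[[i]], aligned[[j]], dof = 9)
      pair[[i]][[j]] <- pij
      pair[[j]][[i]] <- invert_affine(pij)
    }
  }
  avg9 <- vector("list", n)
  headsize <- numeric(n)
  for (i in seq_len(n)) {
    # transforms from every subject's space into subject i's space (the
    # self-transform is the identity); their geometric mean maps the average
    # space into subject i. Including the identity keeps the average exactly
    # centred on the population for small cohorts - without it, log-scales
    # are inflated by n/(n-1).
    pair[[i]][[i]] <- affine_transform()
    avg9[[i]] <- average_affines(pair[[i]])
    headsize[i] <- prod(avg9[[i]]$scales)
  }
  aligned9 <- lapply(seq_len(n), function(i) resample(aligned[[i]], avg9[[i]], geom))
  model9 <- average_volumes(aligned9)

  ## stage 3: 12-parameter to the 9-parameter average
  say("stage 3: 12-parameter registration to the linear average")
  affine12 <- vector("list", n)
  aligned12 <- vector("list", n)
  for (i in seq_len(n)) {
    affine12[[i]] <- register_linear(aligned[[i]], model9, dof = 12, init = avg9[[i]])
    aligned12[[i]] <- resample(aligned[[i]], affine12[[i]], geom)
  }
  model12 <- average_volumes(aligned12)

  mask <- head_mask(model12)
  variance_trace <- c(linear = mean_cross_subject_variance(aligned12, mask))

  ## stage 4: nonlinear generations
  models <- list(`9param` = model9, `12param` = model12)
  fields <- vector("list", n)
  warped <- aligned12
  model_prev <- model12
  for (g in seq_len(nrow(schedule))) {
    say("generation %d/%d: step %g mm, blur %g mm", g, nrow(schedule),
        schedule$step_mm[g], schedule$blur_fwhm_mm[g])
    gen_sched <- nonlinear_schedule(schedule$step_mm[g], schedule$iterations[g],
                                    schedule$blur_fwhm_mm[g])
    for (i in seq_len(n)) {
      fields[[i]] <- register_nonlinear(aligned12[[i]], model_prev, gen_sched,
                                        config = config, init = fields[[i]])
      warped[[i]] <- resample(aligned12[[i]], fields[[i]], geom)
    }
    model_prev <- average_volumes(warped)
    models[[paste0("nonlinear", g)]] <- model_prev
    variance_trace <- c(variance_trace,
                        setNames(mean_cross_subject_variance(warped, mask),
                                 paste0("nonlinear", g)))
  }

  linear_total <- lapply(seq_len(n), function(i)
    affine_from_matrix(rigid[[i]]$matrix %*% affine12[[i]]$matrix))

  res <- structure(list(model = model_prev, models = models,
                        rigid = rigid, avg9 = avg9, affine12 = affine12,
                        linear = linear_total, nonlinear = fields,
                        aligned12 = aligned12, warped = warped,
                        headsize = headsize,
                        variance_trace = variance_trace,
                        schedule = schedule, seed_index = seed_index),
                   class = "cranio_atlas")
  res$qc <- qc_registration(res, threshold_ncc = qc_threshold_ncc)
  res
}

mean_cross_subject_variance <- function(volumes, mask) {
  mat <- vapply(volumes, function(v) as.numeric(v$data)[as.logical(mask)],
                numeric(sum(mask)))
  mean(apply(mat, 1, var))
}

#' @export
print.cranio_atlas <- function(x, ...) {
  cat(sprintf("<cranio_atlas> %d subjects, %d nonlinear generations\n",
              length(x$nonlinear), nrow(x$schedule)))
  cat(sprintf("  head-size factors: %s\n",
              paste(sprintf("%.3f", x$headsize), collapse = " ")))
  cat(sprintf("  QC: %d flagged of %d\n", sum(x$qc$flagged), nrow(x$qc)))
  invisible(x)
}

#' Automated registration quality control
#'
#' Scores every subject by the normalised cross-correlation between its
#' nonlinearly warped scan and the final model inside the head mask, and
#' flags subjects below a threshold. This is an automated surrogate for
#' visual inspection of registration failures; flagged subjects are reported,
#' never silently dropped.
#'
#' @param atlas A `cranio_atlas` from [build_atlas()].
#' @param threshold_ncc Flagging threshold on the per-subject NCC.
#' @return A data.frame with `subject`, `ncc` and `flagged`.
#' @export
qc_registration <- function(atlas, threshold_ncc = 0.85) {
  stopifnot(inherits(atlas, "cranio_atlas"))
  mask <- head_mask(atlas$model)
  ncc <- vapply(atlas$warped, function(w) volume_ncc(w, atlas$model, mask), numeric(1))
  data.frame(subject = seq_along(ncc), ncc = ncc, flagged = ncc < threshold_ncc)
}
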