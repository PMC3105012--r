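#' Ordered, named 3D landmark sets
#'
#' Landmarks are world-mm points with unique names and a `space` tag:
#' `"model"` for points defined on the population atlas, `"subject_linear"`
#' for points propagated to an individual's linearly aligned (head-size-free)
#' space.
#'
#' @param names Character vector of unique labels.
#' @param points n x 3 numeric matrix of world coordinates (mm).
#' @param space `"model"` or `"subject_linear"`.
#' @return An object of class `cranio_landmarks`.
#' @export
landmark_set <- function(names, points, space = c("model", "subject_linear")) {
  space <- match.arg(space)
  points <- matrix(as.numeric(as.matrix(points)), ncol = 3)
  if (length(names) != nrow(points)) stop("one name per point required")
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  rownames(points) <- names
  colnames(points) <- c("x", "y", "z")
  structure(list(names = as.character(names), points = points, space = space),
            class = "cranio_landmarks")
}

is_landmarks <- function(x) inherits(x, "cranio_landmarks")

#' @export
print.cranio_landmarks <- function(x, ...) {
  cat(sprintf("<cranio_landmarks> %d points in %s space\n", length(x$names), x$space))
  invisible(x)
}

#' Read / write landmark TSV files
#'
#' Tab-separated with columns `name`, `x_mm`, `y_mm`, `z_mm`, `space_tag`.
#' @param path File path.
#' @export
read_landmarks <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm", "space_tag")
  if (!all(need %in% names(tab)))
    stop("landmark file must have columns ", paste(need, collapse = ", "))
  landmark_set(tab$name, cbind(tab$x_mm, tab$y_mm, tab$z_mm),
               space = tab$space_tag[1])
}

#' @rdname read_landmarks
#' @param landmarks A [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(is_landmarks(landmarks))
  tab <- data.frame(name = landmarks$names,
                    x_mm = landmarks$points[, 1],
                    y_mm = landmarks$points[, 2],
                    z_mm = landmarks$points[, 3],
                    space_tag = landmarks$space)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The 56-point facial landmark template
#'
#' Loads the landmark template shipped with the package: 56 named facial
#' landmarks (eyes, nose, lips, jaw/chin, ears, forehead/brow, zygomatic
#' region) in the model space of the synthetic canonical head. The set
#' follows the naming and anatomical coverage conventional in facial
#' morphometry; a few entries are semi-landmarks (points defined by their
#' relative position along a feature, e.g. the mid-jaw point halfway between
#' chin and maxillary process) whose correspondence is carried entirely by
#' the registration. The shipped coordinates are synthetic: they sit on the
#' package's canonical phantom, not on any real cohort's atlas. Users
#' analysing real data should supply their own template placed on their own
#' model with [read_landmarks()].
#'
#' @return A `cranio_landmarks` in model space.
#' @export
face_template_landmarks <- function() {
  read_landmarks(system.file("extdata", "face_landmarks_56_synthetic.tsv",
                             package = "craniomorph", mustWork = TRUE))
}

#' Propagate model landmarks to a subject
#'
#' Maps each model-space landmark through the subject's inverse nonlinear
#' transform (the pull-back field from model space to the subject's linearly
#' aligned scan, as stored in a [build_atlas()] result). Because the linear
#' (12-parameter) stage has already removed global position, orientation and
#' head-size differences, the output lives in the head-size-free
#' `subject_linear` space - the registration-based analogue of a Procrustes
#' superposition.
#'
#' @param model_landmarks `cranio_landmarks` tagged `model`.
#' @param subject_inverse [cranio_field] mapping model space to the subject's
#'   linear space.
#' @return A `cranio_landmarks` tagged `subject_linear`; logical attribute
#'   `inside` flags points that fell outside the field lattice (evaluated by
#'   edge clamping, per-point flag rather than global failure).
#' @export
propagate_landmarks <- function(model_landmarks, subject_inverse) {
  stopifnot(is_landmarks(model_landmarks), is_field(subject_inverse))
  if (model_landmarks$space != "model")
    stop("input landmarks must be in model space")
  ev <- eval_field(subject_inverse, model_landmarks$points)
  out <- landmark_set(model_landmarks$names, model_landmarks$points + ev$disp,
                      space = "subject_linear")
  attr(out, "inside") <- ev$inside
  out
}

#' Euclidean distances between homologous landmarks
#'
#' The per-landmark agreement measure used to validate automatic propagation
#' against manual placements: the Euclidean distance (mm) between points of
#' the same name.
#'
#' @param auto,manual `cranio_landmarks` with identical names in the same
#'   space.
#' @return data.frame with `name` and `distance_mm`.
#' @export
landmark_error <- function(auto, manual) {
  stopifnot(is_landmarks(auto), is_landmarks(manual))
  if (!setequal(auto$names, manual$names)) {
    off <- c(setdiff(auto$names, manual$names), setdiff(manual$names, auto$names))
    stop("landmark names do not pair up; offending: ", paste(off, collapse = ", "))
  }
  m <- manual$points[auto$names, , drop = FALSE]
  data.frame(name = auto$names,
             distance_mm = sqrt(rowSums((auto$points - m)^2)))
}

#' Anthropometric distance specifications and measurement
#'
#' `read_anthro_spec()` loads a TSV (`measure`, `landmark_a`, `landmark_b`);
#' `default_anthro_spec()` returns the shipped set of facial distances (eye
#' lengths and heights, mouth width, ear-to-ear and zygomatic craniofacial
#' widths, nose width, filtrum, nose-to-chin and lip-to-chin lengths).
#' `anthropometrics()` measures the Euclidean distances on one landmark set.
#'
#' @param path TSV file path.
#' @return A data.frame specification, or for `anthropometrics()` a
#'   data.frame with `measure` and `distance_mm`.
#' @export
read_anthro_spec <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("measure", "landmark_a", "landmark_b")
  if (!all(need %in% names(tab)))
    stop("anthropometric spec must have columns ", paste(need, collapse = ", "))
  tab
}

#' @rdname read_anthro_spec
#' @export
default_anthro_spec <- function() {
  read_anthro_spec(system.file("extdata", "anthro_measures.tsv",
                               package = "craniomorph", mustWork = TRUE))
}

#' @rdname read_anthro_spec
#' @param landmarks A `cranio_landmarks`.
#' @param spec Specification data.frame (default: the shipped measures).
#' @export
anthropometrics <- function(landmarks, spec = default_anthro_spec()) {
  stopifnot(is_landmarks(landmarks))
  missing <- setdiff(unique(c(spec$landmark_a, spec$landmark_b)), landmarks$names)
  if (length(missing))
    stop("landmarks missing from the set: ", paste(missing, collapse = ", "))
  a <- landmarks$points[spec$landmark_a, , drop = FALSE]
  b <- landmarks$points[spec$landmark_b, , drop = FALSE]
  data.frame(measure = spec$measure,
             distance_mm = sqrt(rowSums((a - b)^2)))
}

#' Linear models of anthropometric measures
#'
#' For every measure fits `distance ~ sex + age + sex:age` with sex coded
#' female-positive ([sex_code()]) and age centred (months), reporting
#' coefficient estimates and t statistics, plus the within-sex age slopes
#' that are the natural follow-up to a significant interaction.
#'
#' @param measures data.frame with `subject`, `measure`, `distance_mm` (long
#'   format, one row per subject x measure).
#' @param covariates data.frame with `subject`, `sex`, `age_months`.
#' @return List with `coefficients` (per measure x term: estimate, t, p) and
#'   `age_slopes` (per measure x sex: slope, t, p).
#' @export
fit_anthro_models <- function(measures, covariates) {
  need <- c("subject", "sex", "age_months")
  if (!all(need %in% names(covariates)))
    stop("covariates must have columns ", paste(need, collapse = ", "))
  if (length(unique(covariates$sex)) < 2) stop("sex is constant in the design")
  if (var(covariates$age_months) == 0) stop("age is constant in the design")
  cov <- covariates
  cov$sexc <- sex_code(cov$sex)
  cov$agec <- cov$age_months - mean(cov$age_months)
  res_coef <- list(); res_slope <- list()
  for (ms in unique(measures$measure)) {
    sub <- measures[measures$measure == ms, ]
    dat <- merge(sub, cov, by = "subject")
    fit <- lm(distance_mm ~ sexc + agec + sexc:agec, data = dat)
    sm <- summary(fit)$coefficients
    res_coef[[ms]] <- data.frame(measure = ms,
                                 term = c("intercept", "sex", "age", "age_sex"),
                                 estimate = sm[, 1], t = sm[, 3], p = sm[, 4],
                                 row.names = NULL)
    for (sx in c("male", "female")) {
      sel <- dat[sex_code(dat$sex) == (if (sx == "female") 0.5 else -0.5), ]
      fs <- lm(distance_mm ~ agec, data = sel)
      ss <- summary(fs)$coefficients
      ci <- stats::confint(fs)["agec", ]
      res_slope[[paste(ms, sx)]] <- data.frame(measure = ms, sex = sx,
                                               slope = ss["agec", 1],
                                               t = ss["agec", 3], p = ss["agec", 4],
                                               ci_lo = ci[1], ci_hi = ci[2],
                                               row.names = NULL)
    }
  }
  list(coefficients = do.call(rbind, res_coef),
       age_slopes = do.call(rbind, res_slope))
}
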