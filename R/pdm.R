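#' Point-distribution model of facial landmarks
#'
#' Concatenates the (x, y, z) coordinates of the 56 landmarks of every
#' subject into a 168-vector, subtracts the model's reference coordinates
#' (the atlas landmark positions, so scores measure deviation from the
#' population average face rather than from the sample mean), and
#' eigendecomposes the covariance of the centred vectors across subjects.
#' Eigenvector signs are fixed so the largest-magnitude loading of each
#' component is positive.
#'
#' @param landmark_sets Named list of per-subject `cranio_landmarks`, all in
#'   `subject_linear` space with identical names.
#' @param reference `cranio_landmarks` in model space (the atlas template).
#' @param center_on Either `"reference"` (default: subtract the model
#'   coordinates) or `"sample_mean"`.
#' @return An object of class `cranio_pdm`: `mean_reference` (168-vector),
#'   `eigenvectors` (168 x K, orthonormal), `eigenvalues` (mm^2, descending),
#'   `scores` (subjects x K, mm), `cumulative_variance` (fractions),
#'   `landmark_names`, `center_on`.
#' @export
fit_pdm <- function(landmark_sets, reference, center_on = c("reference", "sample_mean")) {
  center_on <- match.arg(center_on)
  stopifnot(is.list(landmark_sets), length(landmark_sets) >= 3,
            is_landmarks(reference))
  nm <- reference$names
  X <- t(vapply(landmark_sets, function(ls) {
    stopifnot(is_landmarks(ls))
    if (!setequal(ls$names, nm))
      stop("landmark names inconsistent with the reference")
    as.numeric(t(ls$points[nm, , drop = FALSE])) # x1 y1 z1 x2 y2 z2 ...
  }, numeric(3 * length(nm))))
  ref_vec <- as.numeric(t(reference$points[nm, , drop = FALSE]))
  centre <- if (center_on == "reference") ref_vec else colMeans(X)
  Xc <- sweep(X, 2, centre)
  n <- nrow(Xc)
  sv <- svd(Xc)
  k <- sum(sv$d > max(sv$d) * 1e-10)
  k <- max(k, 1L)
  vecs <- sv$v[, seq_len(k), drop = FALSE]
  vals <- sv$d[seq_len(k)]^2 / (n - 1)
  # sign convention: largest |loading| positive
  for (j in seq_len(k)) {
    im <- which.max(abs(vecs[, j]))
    if (vecs[im, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- Xc %*% vecs
  rownames(scores) <- names(landmark_sets)
  total_var <- sum(Xc^2) / (n - 1)
  structure(list(mean_reference = ref_vec, centre = centre,
                 eigenvectors = vecs, eigenvalues = vals, scores = scores,
                 cumulative_variance = cumsum(vals) / total_var,
                 total_variance = total_var,
                 landmark_names = nm, center_on = center_on),
            class = "cranio_pdm")
}

#' @export
print.cranio_pdm <- function(x, ...) {
  cat(sprintf("<cranio_pdm> %d subjects x %d coordinates, %d components\n",
              nrow(x$scores), length(x$mean_reference), length(x$eigenvalues)))
  k <- min(5, length(x$eigenvalues))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", 100 * x$eigenvalues[1:k] / x$total_variance), collapse = " "), "\n")
  invisible(x)
}

#' Linear models of principal-component scores
#'
#' For each of the first `n_pcs` components fits
#' `score ~ sex + age + sex:age` (female-positive sex coding, centred age in
#' months). With `residualize_bodyfat = TRUE` each PC score is first replaced
#' by its residual from a simple regression on total body fat, and the model
#' is fit to those residuals - the robustness analysis separating facial
#' shape variation from adiposity.
#'
#' @param model A `cranio_pdm`.
#' @param covariates data.frame with `subject`, `sex`, `age_months` and,
#'   when residualising, `bodyfat_pct`.
#' @param n_pcs Number of leading components to analyse.
#' @param residualize_bodyfat Regress out total body fat first.
#' @return List with `coefficients` (per PC x term) and `age_slopes` (per
#'   PC x sex, with 95% CI).
#' @export
analyze_scores <- function(model, covariates, n_pcs = 5,
                           residualize_bodyfat = FALSE) {
  stopifnot(inherits(model, "cranio_pdm"))
  n_pcs <- min(n_pcs, ncol(model$scores))
  cov <- covariates
  if (!all(c("subject", "sex", "age_months") %in% names(cov)))
    stop("covariates must have columns subject, sex, age_months")
  if (residualize_bodyfat && !"bodyfat_pct" %in% names(cov))
    stop("residualize_bodyfat = TRUE requires a bodyfat_pct column")
  sc <- model$scores
  ids <- rownames(sc)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(sc)))
  cov <- cov[match(ids, as.character(cov$subject)), ]
  if (any(is.na(cov$subject))) stop("covariates missing for some subjects")
  cov$sexc <- sex_code(cov$sex)
  cov$agec <- cov$age_months - mean(cov$age_months)
  res_coef <- list(); res_slope <- list()
  for (k in seq_len(n_pcs)) {
    y <- sc[, k]
    if (residualize_bodyfat)
      y <- stats::resid(lm(y ~ cov$bodyfat_pct))
    fit <- lm(y ~ sexc + agec + sexc:agec, data = cov)
    sm <- summary(fit)$coefficients
    res_coef[[k]] <- data.frame(pc = k,
                                term = c("intercept", "sex", "age", "age_sex"),
                                estimate = sm[, 1], t = sm[, 3], p = sm[, 4],
                                row.names = NULL)
    for (sx in c("male", "female")) {
      sel <- cov$sexc == (if (sx == "female") 0.5 else -0.5)
      fs <- lm(y[sel] ~ cov$agec[sel])
      ss <- summary(fs)$coefficients
      ci <- stats::confint(fs)[2, ]
      res_slope[[paste(k, sx)]] <- data.frame(pc = k, sex = sx,
                                              slope = ss[2, 1], t = ss[2, 3],
                                              p = ss[2, 4],
                                              ci_lo = ci[1], ci_hi = ci[2],
                                              row.names = NULL)
    }
  }
  list(coefficients = do.call(rbind, res_coef),
       age_slopes = do.call(rbind, res_slope))
}

#' Simulate a principal component as displaced landmark sets
#'
#' Displaces the reference landmarks along one eigenvector at a sequence of
#' proportions and returns, for each proportion, the displaced set together
#' with the thin-plate-spline warp from the reference to it - ready to warp
#' the atlas volume (or a surface) to visualise what facial features the
#' component couples. At proportion `p` the displacement is
#' `p * amplitude_sd * sqrt(eigenvalue) * eigenvector`, i.e. the full
#' (`p = 1`) simulation shows the component at `amplitude_sd` standard
#' deviations of its score distribution, deliberately exaggerated so the
#' coupled features are visible.
#'
#' @param model A `cranio_pdm`.
#' @param pc_index Component to simulate (1-based).
#' @param proportions Increasing proportions of the full displacement.
#' @param amplitude_sd Amplitude of the full displacement in score standard
#'   deviations.
#' @return List with one element per proportion: `proportion`, `landmarks`
#'   (a `cranio_landmarks`), `warp` (a [tps_fit()] warp from the reference).
#' @export
simulate_pc <- function(model, pc_index, proportions = c(0.2, 0.4, 0.6, 0.8, 1),
                        amplitude_sd = 3) {
  stopifnot(inherits(model, "cranio_pdm"))
  if (pc_index < 1 || pc_index > length(model$eigenvalues))
    stop("pc_index outside the model rank")
  lam <- model$eigenvalues[pc_index]
  if (lam <= model$total_variance * 1e-12)
    stop("component ", pc_index, " has (numerically) zero eigenvalue; nothing to simulate")
  ref_pts <- matrix(model$mean_reference, ncol = 3, byrow = TRUE)
  ref <- landmark_set(model$landmark_names, ref_pts, space = "model")
  dir_pts <- matrix(model$eigenvectors[, pc_index], ncol = 3, byrow = TRUE)
  lapply(proportions, function(p) {
    disp <- p * amplitude_sd * sqrt(lam) * dir_pts
    lm_p <- landmark_set(model$landmark_names, ref_pts + disp, space = "model")
    list(proportion = p, landmarks = lm_p, warp = tps_fit(ref, lm_p))
  })
}

#' Serialise a PDM to a directory of TSV files
#'
#' Writes `mean.tsv`, `eigenvectors.tsv`, `eigenvalues.tsv`, `scores.tsv`.
#' @param model A `cranio_pdm`.
#' @param dir Output directory (created if needed).
#' @export
write_pdm <- function(model, dir) {
  stopifnot(inherits(model, "cranio_pdm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(data.frame(coordinate = seq_along(model$mean_reference),
                value_mm = model$mean_reference), "mean.tsv")
  wt(as.data.frame(model$eigenvectors), "eigenvectors.tsv")
  wt(data.frame(pc = seq_along(model$eigenvalues),
                eigenvalue_mm2 = model$eigenvalues,
                cumulative_variance = model$cumulative_variance), "eigenvalues.tsv")
  sc <- as.data.frame(model$scores)
  sc <- cbind(subject = rownames(model$scores), sc)
  wt(sc, "scores.tsv")
  invisible(dir)
}
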