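# First-level task GLM: gamma HRF, boxcar convolution, motion/spike/drift
# nuisance columns, per-vertex OLS, contrasts and percent signal change.

#' Canonical HRF parameters
#'
#' Gamma-shaped hemodynamic response `h(tau) = ((tau-d)/t)^a *
#' exp(-(tau-d)/t)` for `tau >= d`. Defaults d = 2.25 s, t = 1.25 s, a = 2
#' (the FS-FAST convention), peaking at `d + a*t` = 4.75 s.
#'
#' @param delay onset delay d in seconds.
#' @param dispersion time constant t in seconds.
#' @param exponent shape exponent a.
#' @return an `hrf_params` list.
#' @export
hrf_params <- function(delay = 2.25, dispersion = 1.25, exponent = 2) {
  if (delay < 0) abort("delay must be >= 0")
  if (dispersion <= 0) abort("dispersion must be > 0")
  structure(list(delay = delay, dispersion = dispersion, exponent = exponent),
            class = "hrf_params")
}

#' Sample the HRF kernel
#'
#' @param params [hrf_params()].
#' @param dt sampling interval, seconds.
#' @param duration kernel support length, seconds (default 32).
#' @return list with `time` and `values` (peak-normalized to 1).
#' @export
hrf_kernel <- function(params = hrf_params(), dt = 1, duration = 32) {
  if (dt <= 0) abort("dt must be positive")
  if (duration < params$delay) abort("duration must cover the HRF delay")
  tau <- seq(0, duration, by = dt)
  u <- (tau - params$delay) / params$dispersion
  h <- ifelse(tau >= params$delay, u^params$exponent * exp(-u), 0)
  peak <- max(h)
  if (peak > 0) h <- h / peak
  list(time = tau, values = h)
}

# condition regressors sampled at TR: boxcar convolved with the HRF, each
# peak-normalized so a unit amplitude produces a unit beta. Returns a
# (conditions x volumes) matrix.
.condition_regressors <- function(design, hrf, conditions) {
  T <- design$total_volumes
  tr <- design$tr
  k <- hrf_kernel(hrf, dt = tr)$values
  t_i <- (seq_len(T) - 1L) * tr
  R <- matrix(0, nrow = length(conditions), ncol = T,
              dimnames = list(conditions, NULL))
  for (ci in seq_along(conditions)) {
    b <- design$blocks[design$blocks$condition == conditions[ci], , drop = FALSE]
    box <- numeric(T)
    for (j in seq_len(nrow(b))) {
      box[t_i >= b$onset[j] & t_i < b$onset[j] + b$duration[j]] <- 1
    }
    conv <- stats::convolve(box, rev(k), type = "open")[seq_len(T)]
    if (max(conv) > 0) conv <- conv / max(conv)
    R[ci, ] <- conv
  }
  R
}

#' Flag high-motion task frames
#'
#' Frames whose between-TR total vector movement strictly exceeds the
#' threshold are flagged; each gets its own indicator (spike) regressor in
#' the GLM.
#'
#' @param run a `task_run`, or a numeric movement trace (mm).
#' @param threshold_mm threshold in mm (default 1).
#' @return integer vector of flagged frame indices (1-based).
#' @export
flag_motion_frames <- function(run, threshold_mm = 1) {
  mv <- if (inherits(run, "task_run")) run$movement else run
  if (!is.numeric(mv) || anyNA(mv)) abort("movement trace must be numeric and complete")
  which(mv > threshold_mm)
}

#' Build the first-level GLM design matrix
#'
#' Columns: one HRF-convolved, peak-normalized boxcar regressor per stimulus
#' condition; 6 demeaned motion regressors (if supplied); one indicator
#' column per flagged spike frame; an intercept; and a linear drift term.
#'
#' @param design a `block_design`.
#' @param hrf [hrf_params()].
#' @param motion optional volumes x 6 motion-parameter matrix.
#' @param spikes integer vector of flagged frames (see
#'   [flag_motion_frames()]).
#' @param drift include a linear drift column (default TRUE).
#' @param conditions condition names (default the 5 localizer conditions).
#' @return a `glm_design`: list with `X` (volumes x regressors),
#'   `conditions`, `design`, `hrf`.
#' @export
build_glm_design <- function(design, hrf = hrf_params(), motion = NULL,
                             spikes = integer(0), drift = TRUE,
                             conditions = localizer_conditions()) {
  validate_block_design(design)
  T <- design$total_volumes
  R <- t(.condition_regressors(design, hrf, conditions))
  zero <- colSums(abs(R)) == 0
  if (any(zero)) {
    abort("condition(s) with no blocks yield all-zero regressors: %s",
          paste(conditions[zero], collapse = ", "))
  }
  X <- R
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != T) abort("motion trace length != volumes")
    mc <- sweep(motion, 2L, colMeans(motion))
    colnames(mc) <- sprintf("motion%d", seq_len(ncol(mc)))
    X <- cbind(X, mc)
  }
  if (length(spikes) > 0L) {
    S <- matrix(0, nrow = T, ncol = length(spikes),
                dimnames = list(NULL, sprintf("spike_%03d", spikes)))
    S[cbind(spikes, seq_along(spikes))] <- 1
    X <- cbind(X, S)
  }
  X <- cbind(X, intercept = 1)
  if (drift) X <- cbind(X, drift = seq(-1, 1, length.out = T))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    abort("design matrix is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  structure(list(X = X, conditions = conditions, design = design, hrf = hrf),
            class = "glm_design")
}

#' Fit the first-level GLM
#'
#' Ordinary least squares per vertex, shared design factorization.
#'
#' @param run a `task_run` (or any list with a vertices x volumes `signal`).
#' @param glm_design a [build_glm_design()] result.
#' @return a `beta_map`: list with `beta` (vertices x regressors), `sigma2`
#'   (residual variance per vertex), `df`, `cov_unscaled`
#'   (`(X'X)^-1`), `columns`, `vertices` (0-based ids).
#' @export
fit_glm <- function(run, glm_design) {
  X <- glm_design$X
  Y <- t(run$signal)
  if (nrow(Y) != nrow(X)) abort("design rows != run volumes")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) abort("rank-deficient design")
  beta <- qr.coef(qr_x, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - qr_x$rank
  if (df <= 0) abort("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  structure(list(beta = t(beta), sigma2 = sigma2, df = df,
                 cov_unscaled = chol2inv(chol(crossprod(X))),
                 columns = colnames(X),
                 vertices = seq_len(ncol(Y)) - 1L),
            class = "beta_map")
}

#' Define a contrast
#'
#' @param name contrast label, e.g. "faces_gt_objects".
#' @param positive positive condition.
#' @param negative negative condition.
#' @return a `contrast_spec` list.
#' @export
contrast_spec <- function(name, positive, negative) {
  structure(list(name = name, positive = positive, negative = negative),
            class = "contrast_spec")
}

#' The four localizer contrasts
#'
#' Faces > Objects, Bodies > Objects, Scenes > Objects, Objects > Scrambled.
#'
#' @return named list of [contrast_spec()] objects keyed by category.
#' @export
localizer_contrasts <- function() {
  list(
    face = contrast_spec("faces_gt_objects", "faces", "objects"),
    body = contrast_spec("bodies_gt_objects", "bodies", "objects"),
    scene = contrast_spec("scenes_gt_objects", "scenes", "objects"),
    object = contrast_spec("objects_gt_scrambled", "objects", "scrambled")
  )
}

#' Compute a contrast map
#'
#' Effect = beta(positive) - beta(negative) per vertex; t = effect / SE with
#' SE from the residual variance and the design covariance. t is defined as
#' 0 where both effect and SE are 0.
#'
#' @param betamap a [fit_glm()] result.
#' @param spec a [contrast_spec()].
#' @return a `contrast_map`: list with `effect` and `t` (named by 0-based
#'   vertex id), `spec`, `df`.
#' @export
compute_contrast <- function(betamap, spec) {
  cols <- betamap$columns
  ip <- match(spec$positive, cols); im <- match(spec$negative, cols)
  if (is.na(ip) || is.na(im)) {
    abort("contrast condition(s) missing from beta map: %s",
          paste(setdiff(c(spec$positive, spec$negative), cols), collapse = ", "))
  }
  effect <- betamap$beta[, ip] - betamap$beta[, im]
  cu <- betamap$cov_unscaled
  var_c <- cu[ip, ip] + cu[im, im] - 2 * cu[ip, im]
  se <- sqrt(pmax(betamap$sigma2 * var_c, 0))
  tval <- ifelse(se > 0, effect / se, 0)
  names(effect) <- names(tval) <- betamap$vertices
  structure(list(effect = effect, t = tval, spec = spec, df = betamap$df),
            class = "contrast_map")
}

#' Percent signal change in a vertex set
#'
#' `PSC = 100 * mean_v(beta_condition / beta_intercept)`. Condition
#' regressors are peak-normalized, so condition betas are in raw signal
#' units and the intercept beta is the baseline.
#'
#' @param betamap a [fit_glm()] result.
#' @param vertices 0-based vertex ids of the fROI.
#' @param condition condition name.
#' @return scalar PSC value.
#' @export
compute_psc <- function(betamap, vertices, condition) {
  if (length(vertices) == 0L) abort("empty vertex set")
  rows <- match(vertices, betamap$vertices)
  if (anyNA(rows)) abort("vertex missing from beta map")
  ic <- match(condition, betamap$columns)
  ii <- match("intercept", betamap$columns)
  if (is.na(ic)) abort("condition %s missing from beta map", condition)
  if (is.na(ii)) abort("beta map has no intercept")
  b0 <- betamap$beta[rows, ii]
  if (any(b0 <= 0)) abort("non-positive baseline beta in vertex set")
  100 * mean(betamap$beta[rows, ic] / b0)
}
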