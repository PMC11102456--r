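# l2-regularized linear models predicting task contrasts from connectivity
# features, with nested leave-one-subject-out cross-validation for lambda.
#
# The inner lambda search runs on per-subject sufficient statistics
# (X'X, X'y, column sums): training-fold standardization, the eigenbasis
# ridge path over the whole grid, and held-out MSE are all computed from
# those cross-products, so fold cost is O(p^3) independent of vertex count.
# Equivalence with the direct ridge_fit/predict route is asserted in tests.

#' Logarithmically spaced regularization grid
#'
#' @param n number of values (default 100).
#' @param lo smallest lambda (default 1e-5).
#' @param hi largest lambda (default 1e2).
#' @return strictly increasing numeric vector, log-uniformly spaced, with
#'   first element `lo` and last `hi`.
#' @export
lambda_grid <- function(n = 100L, lo = 1e-5, hi = 1e2) {
  if (!is_count(n) || n < 2L) abort("n must be an integer >= 2")
  if (!(lo > 0 && hi > lo)) abort("need 0 < lo < hi")
  g <- exp(seq(log(lo), log(hi), length.out = n))
  g[1] <- lo
  g[n] <- hi
  g
}

#' Fit a ridge model
#'
#' Features are standardized by training mean/SD (zero-SD columns dropped
#' with a warning); the intercept is the unpenalized training mean of `y`;
#' weights solve `(Z'Z + lambda I) w = Z'(y - mean(y))` on standardized `Z`.
#'
#' @param X numeric matrix (rows = training vertices) with column names, or
#'   a `feature_matrix`.
#' @param y numeric target vector, one per row.
#' @param lambda ridge penalty (>= 0).
#' @param standardize standardize columns by training mean/SD (default TRUE).
#' @param intercept fit an unpenalized intercept (default TRUE).
#' @return a `ridge_model`: list with `weights` (standardized space, named),
#'   `intercept`, `lambda`, `center`, `scale`, `columns` (kept),
#'   `dropped`, `n_train`.
#' @export
ridge_fit <- function(X, y, lambda, standardize = TRUE, intercept = TRUE) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  if (!all(is.finite(X)) || !all(is.finite(y))) abort("non-finite inputs")
  if (nrow(X) != length(y)) abort("rows(X) != length(y)")
  if (nrow(X) < 2L) abort("need at least 2 rows")
  if (lambda < 0) abort("lambda must be >= 0")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    keep <- scl > 1e-10
    if (!all(keep)) {
      warning(sprintf("dropping zero-variance column(s): %s",
                      paste(colnames(X)[!keep], collapse = ", ")), call. = FALSE)
    }
    Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, ctr[keep]), 2L, scl[keep], "/")
    ctr <- ctr[keep]; scl <- scl[keep]
  } else {
    keep <- rep(TRUE, ncol(X))
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
    names(ctr) <- names(scl) <- colnames(X)
    Z <- X
  }
  b0 <- if (intercept) mean(y) else 0
  yc <- y - b0
  p <- ncol(Z)
  w <- solve(crossprod(Z) + diag(lambda, p), crossprod(Z, yc))
  structure(list(weights = stats::setNames(as.numeric(w), colnames(Z)),
                 intercept = b0, lambda = lambda, center = ctr, scale = scl,
                 columns = colnames(Z), dropped = colnames(X)[!keep],
                 n_train = nrow(X)),
            class = "ridge_model")
}

#' Predict from a ridge model
#'
#' Columns are mapped by name, so models whose zero-variance columns were
#' dropped still apply to full feature matrices.
#'
#' @param object a `ridge_model`.
#' @param newdata matrix or `feature_matrix` with (at least) the model's
#'   columns.
#' @param ... unused.
#' @return numeric predictions, one per row.
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$columns, colnames(newdata))
  if (length(miss) > 0L) abort("newdata lacks column(s): %s", paste(miss, collapse = ", "))
  Z <- sweep(sweep(newdata[, object$columns, drop = FALSE], 2L, object$center),
             2L, object$scale, "/")
  as.numeric(object$intercept + Z %*% object$weights)
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("<ridge_model> %d features, lambda=%.4g, n_train=%d%s\n",
              length(x$weights), x$lambda, x$n_train,
              if (length(x$dropped)) sprintf(" (%d dropped)", length(x$dropped)) else ""))
  invisible(x)
}

# ---- sufficient statistics machinery -------------------------------------

# per-subject cross-products, enough to standardize, fit and score folds
.ridge_suffstats <- function(X, y) {
  if (inherits(X, "feature_matrix")) X <- X$X
  list(n = nrow(X), xs = colSums(X), G = crossprod(X),
       xy = as.numeric(crossprod(X, y)), ys = sum(y), yy = sum(y * y))
}

.add_stats <- function(a, b, sign = 1) {
  list(n = a$n + sign * b$n, xs = a$xs + sign * b$xs, G = a$G + sign * b$G,
       xy = a$xy + sign * b$xy, ys = a$ys + sign * b$ys, yy = a$yy + sign * b$yy)
}

# Held-out MSE of the standardized ridge path for every lambda in `grid`,
# training on `tr` (summed stats) and scoring on `out`. Algebra: with
# Z = (X - 1 m') D^-1 on kept columns, w(lambda) solves the penalized normal
# equations in the eigenbasis of Z'Z; predictions on the held-out subject
# expand as quadratic forms in its raw cross-products.
.fold_mse <- function(tr, out, grid) {
  n <- tr$n
  m <- tr$xs / n
  v <- (diag(tr$G) - n * m^2) / (n - 1)
  s <- sqrt(pmax(v, 0))
  keep <- s > 1e-10
  ybar <- tr$ys / n
  if (!any(keep)) {
    # all features constant: every lambda predicts the training mean
    mse0 <- (out$yy - 2 * ybar * out$ys + out$n * ybar^2) / out$n
    return(rep(mse0, length(grid)))
  }
  m_k <- m[keep]; s_k <- s[keep]
  Gk <- tr$G[keep, keep, drop = FALSE]
  ZtZ <- (Gk - n * outer(m_k, m_k)) / outer(s_k, s_k)
  b <- (tr$xy[keep] - m_k * tr$ys) / s_k
  eg <- eigen(ZtZ, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  bt <- as.numeric(crossprod(eg$vectors, b))
  Q <- eg$vectors / s_k                      # maps eigen-space w to raw-space slope
  # held-out pieces in eigen coordinates
  Qxy <- as.numeric(crossprod(Q, out$xy[keep]))
  Qxs <- as.numeric(crossprod(Q, out$xs[keep]))
  Qm <- as.numeric(crossprod(Q, m_k) * 1)    # note: m'v with v in raw space
  # m'v where v = Q wt  ->  (Q'm)' wt; but m is raw-space, so use t(Q) %*% m
  Gout <- out$G[keep, keep, drop = FALSE]
  At <- crossprod(Q, Gout %*% Q)
  WT <- bt / outer(d, grid, "+")             # p x L matrix of eigen-space weights
  cc <- ybar - colSums(Qm * WT)              # per-lambda intercept in raw space
  t1 <- colSums(Qxy * WT) + cc * out$ys
  q1 <- colSums((At %*% WT) * WT) + 2 * cc * colSums(Qxs * WT) + out$n * cc^2
  sse <- out$yy - 2 * t1 + q1
  pmax(sse, 0) / out$n
}

#' Inner-loop lambda selection
#'
#' Leaves each training subject out once; for every lambda, fits on the
#' remaining subjects' stacked vertex rows (training-fold standardization)
#' and scores MSE on the left-out subject's vertices. Selects the lambda
#' minimizing the MSE averaged over inner folds; ties go to the smaller
#' lambda.
#'
#' @param data named list, one element per training subject, each a list
#'   with `X` (vertices x features, or a `feature_matrix`) and `y`.
#' @param grid a [lambda_grid()].
#' @param pooled if TRUE, pool squared errors over all held-out vertices
#'   instead of averaging per-fold MSEs (default FALSE).
#' @param stats optional precomputed per-subject sufficient statistics.
#' @return list with `lambda`, `mse` (inner-subject x lambda matrix),
#'   `mean_mse` (per lambda), `grid`.
#' @export
select_lambda_inner <- function(data, grid = lambda_grid(), pooled = FALSE,
                                stats = NULL) {
  if (length(data) < 2L) abort("inner cross-validation needs >= 2 subjects")
  if (is.null(stats)) {
    stats <- lapply(data, function(d) .ridge_suffstats(d$X, d$y))
  }
  total <- Reduce(.add_stats, stats)
  mse <- matrix(NA_real_, nrow = length(stats), ncol = length(grid),
                dimnames = list(names(stats), NULL))
  ns <- numeric(length(stats))
  for (i in seq_along(stats)) {
    mse[i, ] <- .fold_mse(.add_stats(total, stats[[i]], sign = -1),
                          stats[[i]], grid)
    ns[i] <- stats[[i]]$n
  }
  mean_mse <- if (pooled) {
    colSums(mse * ns) / sum(ns)
  } else {
    colMeans(mse)
  }
  sel <- which.min(mean_mse)  # grid ascending: first minimum = smallest lambda
  list(lambda = grid[sel], mse = mse, mean_mse = mean_mse, grid = grid)
}

#' Nested leave-one-subject-out prediction
#'
#' Outer loop: each subject is left out once; lambda is chosen by
#' [select_lambda_inner()] on the remaining subjects; a ridge model is fit on
#' their stacked vertices and applied to the left-out subject. The left-out
#' subject never enters its fold's inner loop or standardization statistics.
#'
#' @param data named list per subject: `X` (vertices x features or
#'   `feature_matrix`) and `y` (per-vertex target).
#' @param grid a [lambda_grid()].
#' @param pooled passed to [select_lambda_inner()].
#' @return a `cv_report`: list with `folds` (per subject: `subject`,
#'   `lambda`, `train_subjects`, `inner_mean_mse`), `predicted` (named list
#'   of per-vertex predictions), `lambda` (named vector), `grid`.
#' @export
loso_predict <- function(data, grid = lambda_grid(), pooled = FALSE) {
  if (length(data) < 3L) abort("nested LOSO needs >= 3 subjects")
  ids <- names(data)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) abort("subjects must be named")
  data <- lapply(data, function(d) {
    if (inherits(d$X, "feature_matrix")) d$X <- d$X$X
    if (nrow(d$X) == 0L) abort("subject with empty search-space data")
    d
  })
  stats <- lapply(data, function(d) .ridge_suffstats(d$X, d$y))
  folds <- vector("list", length(ids))
  names(folds) <- ids
  predicted <- vector("list", length(ids))
  names(predicted) <- ids
  for (id in ids) {
    train_ids <- setdiff(ids, id)
    inner <- select_lambda_inner(data[train_ids], grid, pooled = pooled,
                                 stats = stats[train_ids])
    Xtr <- do.call(rbind, lapply(data[train_ids], `[[`, "X"))
    ytr <- unlist(lapply(data[train_ids], `[[`, "y"), use.names = FALSE)
    fit <- ridge_fit(Xtr, ytr, inner$lambda)
    pred <- predict(fit, data[[id]]$X)
    names(pred) <- rownames(data[[id]]$X)
    folds[[id]] <- list(subject = id, lambda = inner$lambda,
                        train_subjects = train_ids,
                        inner_mean_mse = inner$mean_mse,
                        model = fit)
    predicted[[id]] <- pred
  }
  structure(list(folds = folds, predicted = predicted,
                 lambda = vapply(folds, `[[`, numeric(1), "lambda"),
                 grid = grid),
            class = "cv_report")
}

#' Fit the final all-subject model
#'
#' Lambda is chosen by an inner LOSO over all subjects, then the model is fit
#' on everyone's stacked vertices.
#'
#' @inheritParams loso_predict
#' @param froi fROI id recorded in the model metadata.
#' @return a `ridge_model` with extra fields `froi`, `subjects`,
#'   `inner_mean_mse`.
#' @export
fit_final_model <- function(data, grid = lambda_grid(), pooled = FALSE,
                            froi = NA_character_) {
  if (length(data) < 2L) abort("need >= 2 subjects")
  data <- lapply(data, function(d) {
    if (inherits(d$X, "feature_matrix")) d$X <- d$X$X
    d
  })
  inner <- select_lambda_inner(data, grid, pooled = pooled)
  X <- do.call(rbind, lapply(data, `[[`, "X"))
  y <- unlist(lapply(data, `[[`, "y"), use.names = FALSE)
  fit <- ridge_fit(X, y, inner$lambda)
  fit$froi <- froi
  fit$subjects <- names(data)
  fit$inner_mean_mse <- inner$mean_mse
  fit
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d outer folds, lambda in [%.3g, %.3g]\n",
              length(x$folds), min(x$lambda), max(x$lambda)))
  invisible(x)
}
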