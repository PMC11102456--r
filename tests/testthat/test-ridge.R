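test_that("lambda grid spans 1e-5..1e2 with log-uniform spacing", {
  g <- lambda_grid()
  expect_length(g, 100L)
  expect_equal(g[1], 1e-5)
  expect_equal(g[100], 1e2)
  ratios <- g[-1] / g[-length(g)]
  expect_lt(max(ratios) - min(ratios), 1e-12)
  expect_true(all(diff(g) > 0))
  expect_equal(lambda_grid(3, 1, 100), c(1, 10, 100))
  expect_error(lambda_grid(1), ">= 2")
  expect_error(lambda_grid(10, 1, 0.5), "lo < hi")
})

test_that("ridge_fit reduces to OLS at lambda 0 and to the mean at huge lambda", {
  set.seed(7)
  X <- matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(12)
  fit0 <- ridge_fit(X, y, 0)
  Z <- scale(X)
  ols <- as.numeric(solve(crossprod(Z), crossprod(Z, y - mean(y))))
  expect_equal(unname(fit0$weights), ols, tolerance = 1e-10)
  fit_inf <- ridge_fit(X, y, 1e12)
  expect_lt(sqrt(sum(fit_inf$weights^2)), 1e-6)
  expect_equal(predict(fit_inf, X), rep(mean(y), 12), tolerance = 1e-5)
})

test_that("unstandardized single-feature closed form: w = X'y / (X'X + lambda)", {
  X <- matrix(c(1, 2), ncol = 1, dimnames = list(NULL, "f1"))
  fit <- ridge_fit(X, c(1, 2), lambda = 1, standardize = FALSE, intercept = FALSE)
  expect_equal(unname(fit$weights), 5 / 6, tolerance = 1e-12)
})

test_that("ridge_fit matches the penalized normal-equation oracle on a 10x6 toy", {
  set.seed(31)
  X <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rnorm(10)
  for (lam in c(0.01, 1, 50)) {
    fit <- ridge_fit(X, y, lam)
    expect_equal(unname(fit$weights), oracle_ridge(X, y, lam), tolerance = 1e-10)
  }
})

test_that("zero-variance columns are dropped with a warning; predictions map by name", {
  set.seed(8)
  X <- cbind(f1 = rnorm(10), f2 = rep(3, 10), f3 = rnorm(10))
  y <- rnorm(10)
  expect_warning(fit <- ridge_fit(X, y, 1), "f2")
  expect_identical(fit$dropped, "f2")
  expect_length(fit$weights, 2L)
  # prediction works on full and reordered matrices
  p1 <- predict(fit, X)
  p2 <- predict(fit, X[, c("f3", "f2", "f1")])
  expect_equal(p1, p2)
  expect_error(predict(fit, X[, "f1", drop = FALSE]), "lacks column")
  expect_error(ridge_fit(cbind(f1 = c(1, NA)), c(1, 2), 1), "non-finite")
})

test_that("monotone shrinkage: weight norm is non-increasing in lambda", {
  set.seed(9)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- rnorm(20)
  norms <- sapply(lambda_grid(25, 1e-4, 1e4),
                  function(l) sqrt(sum(ridge_fit(X, y, l)$weights^2)))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("inner-loop MSE equals the direct fit/predict route", {
  data <- make_ridge_data(n_sub = 4, n = 12, p = 6)
  grid <- lambda_grid(9, 1e-3, 10)
  inner <- select_lambda_inner(data, grid)
  direct <- sapply(seq_along(grid), function(j) {
    sapply(names(data), function(id) {
      tr <- setdiff(names(data), id)
      X <- do.call(rbind, lapply(data[tr], `[[`, "X"))
      y <- unlist(lapply(data[tr], `[[`, "y"))
      fit <- ridge_fit(X, y, grid[j])
      mean((data[[id]]$y - predict(fit, data[[id]]$X))^2)
    })
  })
  expect_equal(unname(inner$mse), unname(direct), tolerance = 1e-10)
  expect_identical(inner$lambda, grid[which.min(colMeans(direct))])
  # pooled variant weights folds by vertex count
  ip <- select_lambda_inner(data, grid, pooled = TRUE)
  ns <- sapply(data, function(d) nrow(d$X))
  expect_equal(ip$mean_mse, colSums(direct * ns) / sum(ns), tolerance = 1e-10)
})

test_that("exact ties select the smallest lambda", {
  # all-constant features: every lambda predicts mean(y), MSEs tie exactly
  data <- lapply(1:3, function(i) {
    list(X = cbind(f1 = rep(1, 5), f2 = rep(2, 5)), y = rnorm(5))
  })
  names(data) <- paste0("s", 1:3)
  grid <- lambda_grid(5, 1e-2, 1e2)
  sel <- suppressWarnings(select_lambda_inner(data, grid))
  expect_equal(max(sel$mean_mse) - min(sel$mean_mse), 0)
  expect_identical(sel$lambda, grid[1])
})

test_that("noise-free linear targets give small lambda and near-perfect held-out R2", {
  data <- make_ridge_data(n_sub = 5, n = 30, p = 6, sd_noise = 0, seed = 77)
  grid <- lambda_grid(30, 1e-5, 1e2)
  cv <- loso_predict(data, grid)
  expect_true(all(cv$lambda <= median(grid)))
  r2 <- sapply(names(data), function(id) {
    cor(cv$predicted[[id]], data[[id]]$y)^2
  })
  expect_true(all(r2 > 0.99))
})

test_that("LOSO protocol: one fold per subject, no leakage, order-invariant", {
  data <- make_ridge_data(n_sub = 5, n = 10, p = 4, seed = 3)
  grid <- lambda_grid(5, 1e-3, 10)
  cv <- loso_predict(data, grid)
  expect_length(cv$folds, 5L)
  expect_setequal(names(cv$predicted), names(data))
  for (id in names(data)) {
    expect_false(id %in% cv$folds[[id]]$train_subjects)
    expect_setequal(cv$folds[[id]]$train_subjects, setdiff(names(data), id))
    # standardization recomputed from training rows only
    Xtr <- do.call(rbind, lapply(data[cv$folds[[id]]$train_subjects], `[[`, "X"))
    expect_equal(cv$folds[[id]]$model$center, colMeans(Xtr), tolerance = 1e-12)
    expect_equal(cv$folds[[id]]$model$scale, apply(Xtr, 2, sd), tolerance = 1e-12)
  }
  # permuting subject order changes nothing
  cv2 <- loso_predict(data[rev(names(data))], grid)
  expect_equal(cv$predicted[names(data)], cv2$predicted[names(data)])
  expect_equal(cv$lambda[names(data)], cv2$lambda[names(data)])
  expect_error(loso_predict(data[1:2], grid), ">= 3")
})

test_that("final model: 184 features on cohort data, deterministic, optimism holds", {
  co <- tiny_cohort()
  dat <- cached("tiny_rffa_data", {
    glm <- tiny_glm()
    feats <- list(rFFA = lapply(names(co$subjects), function(id) {
      surf <- co$surface
      ssv <- surf$vertex[!is.na(surf$froi) & surf$froi == "rFFA"]
      sub <- co$subjects[[id]]
      cn <- compute_connectome(sub$rest, censor_frames(sub$rest), ssv, surf, "rFFA")
      build_feature_matrix(cn, surf)$X
    }))
    names(feats$rFFA) <- names(co$subjects)
    connfroi:::.froi_model_data(feats, glm$cmaps, co, "rFFA", 1)
  })
  grid <- lambda_grid(20, 1e-4, 1e2)
  fm <- fit_final_model(dat, grid, froi = "rFFA")
  expect_length(fm$weights, 184L)
  expect_identical(fm$froi, "rFFA")
  expect_identical(fm, fit_final_model(dat, grid, froi = "rFFA"))
  # in-sample R2 >= mean held-out R2 (optimism inequality, empirical)
  cv <- loso_predict(dat, grid)
  r2_out <- mean(sapply(names(dat), function(id) {
    1 - mean((dat[[id]]$y - cv$predicted[[id]])^2) / var(dat[[id]]$y)
  }))
  yhat <- unlist(lapply(names(dat), function(id) predict(fm, dat[[id]]$X)))
  yall <- unlist(lapply(dat, `[[`, "y"))
  r2_in <- 1 - mean((yall - yhat)^2) / var(yall)
  expect_gte(r2_in, r2_out)
})
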