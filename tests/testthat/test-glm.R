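test_that("HRF kernel: zero before delay, peak at d + a*t, normalized to 1", {
  p <- hrf_params()
  k <- hrf_kernel(p, dt = 0.01, duration = 32)
  expect_equal(k$values[k$time <= 1.0], rep(0, sum(k$time <= 1.0)))
  # analytic argmax: dh/dtau = 0 at tau = d + a * t = 4.75 s
  expect_equal(k$time[which.max(k$values)], 2.25 + 2 * 1.25, tolerance = 0.011)
  expect_equal(max(k$values), 1.0)
  expect_error(hrf_kernel(p, dt = 1, duration = 2), "delay")
  expect_error(hrf_params(dispersion = 0), "> 0")
})

test_that("motion frames are flagged by strict > 1 mm rule", {
  expect_identical(flag_motion_frames(c(0.2, 1.5, 0.3)), 2L)
  expect_identical(flag_motion_frames(c(0.2, 1.0, 0.3)), integer(0))
})

test_that("design matrix has condition + motion + spike + intercept + drift columns", {
  co <- tiny_cohort()
  run <- co$subjects[[1]]$task[[1]]
  spikes <- flag_motion_frames(run)
  dsn <- build_glm_design(run$design, motion = run$motion, spikes = spikes)
  expect_identical(ncol(dsn$X), 5L + 6L + length(spikes) + 2L)
  # spike columns are identity indicators
  for (s in seq_along(spikes)) {
    col <- dsn$X[, sprintf("spike_%03d", spikes[s])]
    expect_identical(which(col == 1), spikes[s])
    expect_equal(sum(col), 1)
  }
})

test_that("condition regressors match a brute-force convolution oracle", {
  d <- make_block_design(seed = 4)
  hrf <- hrf_params()
  R <- connfroi:::.condition_regressors(d, hrf, localizer_conditions())
  k <- hrf_kernel(hrf, dt = 1)$values
  for (cond in c("faces", "scrambled")) {
    b <- d$blocks[d$blocks$condition == cond, ]
    box <- numeric(d$total_volumes)
    for (j in seq_len(nrow(b))) {
      box[seq(b$onset[j] + 1, b$onset[j] + b$duration[j])] <- 1
    }
    conv <- numeric(d$total_volumes)
    for (t in seq_len(d$total_volumes)) {
      for (l in seq_along(k)) {
        if (t - l + 1 >= 1) conv[t] <- conv[t] + box[t - l + 1] * k[l]
      }
    }
    conv <- conv / max(conv)
    expect_equal(unname(R[cond, ]), conv, tolerance = 1e-10)
  }
})

test_that("a condition without blocks is rejected as an all-zero regressor", {
  d <- make_block_design(seed = 4)
  d$blocks$condition[d$blocks$condition == "faces"] <- "objects"
  expect_error(build_glm_design(d), "faces")
})

test_that("noise-free task runs are recovered exactly by the GLM", {
  cfg <- cohort_config(n_subjects = 1, vertices_per_hemi = 250,
                       rest_volumes = 40, noise_task = 0, drift_task = 0,
                       motion_spike_prob = 0, seed = 6)
  co <- generate_cohort(cfg)
  sub <- co$subjects[[1]]
  run <- sub$task[[1]]
  dsn <- build_glm_design(run$design, motion = run$motion,
                          spikes = flag_motion_frames(run))
  bm <- fit_glm(run, dsn)
  # true amplitudes: amp_base + s for each category condition
  s <- sub$ground_truth$s
  for (cat in c("face", "scene")) {
    cond <- c(face = "faces", scene = "scenes")[[cat]]
    expect_equal(unname(bm$beta[, cond]), cfg$amp_base + unname(s[, cat]),
                 tolerance = 1e-6)
  }
  expect_equal(unname(bm$beta[, "scrambled"]), rep(cfg$amp_base, nrow(s)),
               tolerance = 1e-6)
  expect_equal(unname(bm$beta[, "intercept"]), rep(cfg$baseline, nrow(s)),
               tolerance = 1e-6)
  # zero-amplitude contrast is zero on noise-free data
  cm <- compute_contrast(bm, localizer_contrasts()$object)
  outside <- which(s[, "object"] == 0)
  expect_equal(unname(cm$effect[outside]), rep(0, length(outside)), tolerance = 1e-8)
})

test_that("GLM matches the pseudoinverse oracle on a toy and has orthogonal residuals", {
  set.seed(12)
  T <- 10L
  X <- cbind(a = rnorm(T), b = rnorm(T), intercept = 1)
  Y <- matrix(rnorm(T * 3), T, 3)
  run <- list(signal = t(Y))
  dsn <- structure(list(X = X), class = "glm_design")
  bm <- fit_glm(run, dsn)
  expect_equal(unname(t(bm$beta)), unname(oracle_ols(X, Y)), tolerance = 1e-10)
  res <- Y - X %*% t(bm$beta)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)
  expect_identical(bm$df, T - 3L)
})

test_that("pure-noise runs give near-zero mean betas and sigma-proportional RMSE", {
  d <- make_block_design(seed = 8)
  rmse <- sapply(c(0.5, 1.0), function(sig) {
    cfg <- cohort_config(n_subjects = 1, vertices_per_hemi = 250,
                         rest_volumes = 40, amp_base = 0, amp_select = 0,
                         noise_task = sig, drift_task = 0,
                         motion_spike_prob = 0, seed = 30)
    co <- generate_cohort(cfg)
    run <- co$subjects[[1]]$task[[1]]
    dsn <- build_glm_design(run$design, motion = run$motion)
    bm <- fit_glm(run, dsn)
    b <- bm$beta[, "faces"]
    se <- sd(b) / sqrt(length(b))
    expect_lt(abs(mean(b)), 3 * se)
    sqrt(mean(b^2))
  })
  expect_equal(rmse[2] / rmse[1], 2, tolerance = 0.15)
})

test_that("contrasts: effect arithmetic, linearity, and closed-form t", {
  set.seed(5)
  T <- 40L
  X <- cbind(faces = rnorm(T), objects = rnorm(T), intercept = 1)
  beta_true <- c(2, 0.5, 100)
  Y <- matrix(X %*% beta_true + rnorm(T, sd = 0.3), ncol = 1)
  bm <- fit_glm(list(signal = t(Y)), structure(list(X = X), class = "glm_design"))
  cm <- compute_contrast(bm, contrast_spec("f_gt_o", "faces", "objects"))
  expect_equal(unname(cm$effect),
               unname(bm$beta[, "faces"] - bm$beta[, "objects"]))
  # closed-form SE oracle: sqrt(sigma2 * c' (X'X)^-1 c)
  cvec <- c(1, -1, 0)
  se <- sqrt(bm$sigma2 * as.numeric(t(cvec) %*% solve(crossprod(X)) %*% cvec))
  expect_equal(unname(cm$t), unname(cm$effect / se), tolerance = 1e-10)
  # linear in beta: scaling y scales the effect
  bm2 <- fit_glm(list(signal = t(3 * Y)), structure(list(X = X), class = "glm_design"))
  cm2 <- compute_contrast(bm2, contrast_spec("f_gt_o", "faces", "objects"))
  expect_equal(unname(cm2$effect), unname(3 * cm$effect), tolerance = 1e-10)
  # equal betas -> 0 effect, 0 t
  bm0 <- bm
  bm0$beta[, "objects"] <- bm0$beta[, "faces"]
  bm0$sigma2[] <- 0
  cm0 <- compute_contrast(bm0, contrast_spec("f_gt_o", "faces", "objects"))
  expect_identical(unname(cm0$effect), 0)
  expect_identical(unname(cm0$t), 0)
  expect_error(compute_contrast(bm, contrast_spec("x", "faces", "scenes")), "missing")
})

test_that("PSC follows its definition and guards the baseline", {
  bm <- structure(list(
    beta = matrix(c(2, 1, 3, 100, 100, 100), nrow = 3,
                  dimnames = list(NULL, c("faces", "intercept"))),
    columns = c("faces", "intercept"),
    vertices = 0:2), class = "beta_map")
  expect_equal(compute_psc(bm, 0L, "faces"), 2.0)
  expect_equal(compute_psc(bm, c(1L, 2L), "faces"), 2.0)  # mean of 1% and 3%
  bm$beta[2, "intercept"] <- -1
  expect_error(compute_psc(bm, 0:2, "faces"), "non-positive baseline")
  expect_error(compute_psc(bm, integer(0), "faces"), "empty")
})

test_that("preferred-category PSC beats the contrast category inside true fROIs", {
  co <- tiny_cohort()
  glm <- tiny_glm()
  reg <- co$registry
  pref <- c(); con <- c()
  for (id in names(co$subjects)) {
    bm <- glm$betamaps[[2]][[id]]
    for (i in seq_len(nrow(reg))) {
      tf <- co$subjects[[id]]$ground_truth$true_frois[[reg$froi[i]]]
      pref <- c(pref, compute_psc(bm, tf, reg$preferred_condition[i]))
      con <- c(con, compute_psc(bm, tf, reg$contrast_condition[i]))
    }
  }
  tt <- paired_ttest(pref, con)
  expect_gt(tt$statistic, 0)
  expect_lt(tt$p, 0.01)
})
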