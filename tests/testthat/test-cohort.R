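test_that("resting run has the acquisition length and valid FD trace", {
  co <- tiny_cohort()
  run <- co$subjects[[1]]$rest
  # default run length: 9.67 min at TR 1 s
  expect_identical(cohort_config()$rest_volumes, 580L)
  expect_identical(ncol(run$signal), co$cfg$rest_volumes)
  expect_length(run$fd, ncol(run$signal))
  expect_true(all(run$fd >= 0))
})

test_that("task runs have 234 volumes and complete motion traces", {
  co <- tiny_cohort()
  for (r in 1:2) {
    run <- co$subjects[[2]]$task[[r]]
    expect_identical(ncol(run$signal), 234L)
    expect_identical(dim(run$motion), c(234L, 6L))
    expect_length(run$movement, 234L)
    expect_silent(validate_block_design(run$design))
  }
})

test_that("cohort layout: 1 rest + 2 task runs per subject, registries attached", {
  co <- tiny_cohort()
  expect_length(co$subjects, co$cfg$n_subjects)
  for (sub in co$subjects) {
    expect_s3_class(sub$rest, "resting_run")
    expect_length(sub$task, 2L)
    expect_s3_class(sub$ground_truth, "ground_truth")
  }
  expect_identical(co$registry, froi_registry())
  # independently randomized run orders (almost surely differ)
  o1 <- co$subjects[[1]]$task[[1]]$design$blocks$condition
  o2 <- co$subjects[[1]]$task[[2]]$design$blocks$condition
  expect_false(identical(o1, o2))
})

test_that("cohort generation is deterministic per seed and seed-sensitive", {
  cfg <- cohort_config(n_subjects = 2, vertices_per_hemi = 250,
                       rest_volumes = 60, seed = 13)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(n_subjects = 2, vertices_per_hemi = 250,
                        rest_volumes = 60, seed = 14)
  c <- generate_cohort(cfg2, seed = 14)
  expect_false(identical(a$subjects[[1]]$rest$signal, c$subjects[[1]]$rest$signal))
})

test_that("true fROIs lie inside their search spaces with the top-fraction size", {
  co <- tiny_cohort()
  surf <- co$surface
  for (sub in co$subjects) {
    for (f in co$registry$froi) {
      ss <- surf$vertex[!is.na(surf$froi) & surf$froi == f]
      tf <- sub$ground_truth$true_frois[[f]]
      expect_true(all(tf %in% ss))
      expect_length(tf, max(1L, floor(co$cfg$froi_frac * length(ss) + 0.5)))
    }
  }
})

test_that("zero jitter makes every subject's true fROIs identical", {
  cfg <- cohort_config(n_subjects = 3, vertices_per_hemi = 250,
                       rest_volumes = 40, jitter = 0, size_jitter = 0, seed = 2)
  co <- generate_cohort(cfg)
  tf <- lapply(co$subjects, function(s) s$ground_truth$true_frois)
  expect_identical(tf[[1]], tf[[2]])
  expect_identical(tf[[1]], tf[[3]])
})

test_that("FD spike fraction matches the configured probability (binomial 99% CI)", {
  co <- tiny_cohort()
  fd <- unlist(lapply(co$subjects, function(s) s$rest$fd))
  n <- length(fd)
  p <- co$cfg$fd_spike_prob
  k <- sum(fd > 0.5)
  ci <- qbinom(c(0.005, 0.995), n, p)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("null coupling leaves fingerprints uninformative about selectivity", {
  base <- list(n_subjects = 5, vertices_per_hemi = 250, rest_volumes = 400,
               noise_rest = 0.2, seed = 21)
  co0 <- generate_cohort(do.call(cohort_config, c(base, coupling = 0)))
  co1 <- generate_cohort(do.call(cohort_config, c(base, coupling = 1)))
  # subject-demeaned fingerprint/selectivity correlation, pooled over parcels
  fingerprint_cor <- function(co, froi = "rFFA") {
    surf <- co$surface
    ssv <- surf$vertex[!is.na(surf$froi) & surf$froi == froi]
    Zs <- lapply(co$subjects, function(sub) {
      compute_connectome(sub$rest, censor_frames(sub$rest), ssv, surf, froi)$z
    })
    Ss <- lapply(co$subjects, function(sub) sub$ground_truth$s[ssv + 1, "face"])
    Zm <- Reduce(`+`, Zs) / length(Zs)
    Sm <- Reduce(`+`, Ss) / length(Ss)
    Zd <- do.call(rbind, lapply(Zs, function(z) z - Zm))
    Sd <- unlist(lapply(Ss, function(s) s - Sm))
    mean(abs(suppressWarnings(cor(Zd, Sd))), na.rm = TRUE)
  }
  c0 <- fingerprint_cor(co0)
  c1 <- fingerprint_cor(co1)
  expect_lt(c0, 0.15)
  expect_gt(c1, 2 * c0)
})

test_that("noiseless single-parcel world gives unit vertex-parcel correlation", {
  cfg <- cohort_config(n_subjects = 1, vertices_per_hemi = 250, n_parcels = 1,
                       rest_volumes = 80, noise_rest = 0, coupling = 0,
                       fd_spike_prob = 0, seed = 3)
  co <- generate_cohort(cfg)
  surf <- co$surface
  ssv <- surf$vertex[!is.na(surf$froi) & surf$froi == "lFFA"]
  cn <- compute_connectome(co$subjects[[1]]$rest,
                           censor_frames(co$subjects[[1]]$rest), ssv, surf, "lFFA")
  expect_equal(unname(cn$z[, 1]), rep(atanh(1 - 1e-7), length(ssv)), tolerance = 1e-10)
})

test_that("coupling matrix is recovered exactly from true loadings (generator identity)", {
  co <- tiny_cohort()
  surf <- co$surface
  idx <- which(surf$hemi == "right")
  b <- connfroi:::.base_loadings(surf[idx, , drop = FALSE],
                                 ell = co$cfg$rest_smoothness)
  sub <- co$subjects[[1]]
  W <- b + co$cfg$coupling * (sub$ground_truth$s[idx, ] %*% co$coupling$right)
  # OLS of the loading perturbation on the 4 selectivity fields, per parcel
  Sm <- sub$ground_truth$s[idx, ]
  est <- qr.solve(Sm, W - b)
  expect_equal(est, co$coupling$right * co$cfg$coupling, tolerance = 1e-6)
})

test_that("group atlases: union threshold, dilation superset, brute-force q=0.5", {
  cfg <- cohort_config(n_subjects = 2, vertices_per_hemi = 250,
                       rest_volumes = 40, seed = 17)
  co <- generate_cohort(cfg)
  uni <- make_group_atlas(co, "union", q = 0.5)
  dil <- make_group_atlas(co, "dilated", q = 0.5)
  for (f in co$registry$froi) {
    # brute force: vertices in >= 1 of the 2 subjects' fROIs
    counts <- table(c(co$subjects[[1]]$ground_truth$true_frois[[f]],
                      co$subjects[[2]]$ground_truth$true_frois[[f]]))
    expect_setequal(uni[[f]], as.integer(names(counts)))
    expect_true(all(uni[[f]] %in% dil[[f]]))
  }
  # q = 1 with zero jitter: atlas equals every subject's fROI
  cfg0 <- cohort_config(n_subjects = 3, vertices_per_hemi = 250,
                        rest_volumes = 40, jitter = 0, size_jitter = 0, seed = 2)
  co0 <- generate_cohort(cfg0)
  uni0 <- make_group_atlas(co0, "union", q = 1)
  for (f in co0$registry$froi) {
    expect_setequal(uni0[[f]], co0$subjects[[1]]$ground_truth$true_frois[[f]])
  }
})
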