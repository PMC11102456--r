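# Shared fixtures and independent oracles. Everything is generated in code;
# expensive cohorts are built once per test run and cached in this env.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small but complete world: 6 subjects, 300 vertices/hemi, full 179 parcels
tiny_cohort <- function() {
  cached("tiny_cohort", generate_cohort(
    cohort_config(n_subjects = 6, vertices_per_hemi = 300, seed = 5)))
}

# GLM + contrasts for the tiny cohort
tiny_glm <- function() {
  cached("tiny_glm", compute_glm_all(tiny_cohort()))
}

# random per-subject (X, y) sets for ridge tests
make_ridge_data <- function(n_sub = 4, n = 12, p = 6, sd_noise = 1, seed = 42) {
  set.seed(seed)
  w <- rnorm(p)
  out <- lapply(seq_len(n_sub), function(i) {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
    list(X = X, y = as.numeric(X %*% w + rnorm(n, sd = sd_noise)))
  })
  names(out) <- paste0("s", seq_len(n_sub))
  out
}

# ---- oracles -------------------------------------------------------------

# brute-force per-pair Pearson correlation loop (independent of cor())
oracle_connectome <- function(vertex_series, parcel_mean_series) {
  S <- nrow(vertex_series); P <- nrow(parcel_mean_series)
  out <- matrix(NA_real_, S, P)
  pearson <- function(a, b) {
    am <- a - sum(a) / length(a); bm <- b - sum(b) / length(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  for (i in seq_len(S)) for (j in seq_len(P)) {
    r <- pearson(vertex_series[i, ], parcel_mean_series[j, ])
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    out[i, j] <- 0.5 * log((1 + r) / (1 - r))
  }
  out
}

# penalized normal equations solved by generic inversion
oracle_ridge <- function(X, y, lambda) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)
  as.numeric(solve(t(Z) %*% Z + lambda * diag(ncol(Z))) %*% t(Z) %*% yc)
}

# OLS via explicit Moore-Penrose pseudoinverse
oracle_ols <- function(X, Y) {
  sv <- svd(X)
  pinv <- sv$v %*% diag(1 / sv$d, length(sv$d)) %*% t(sv$u)
  pinv %*% Y
}

# Type III sums of squares by explicit projection matrices: for each term,
# SS = y' (P_full - P_reduced) y with sum-to-zero coded design blocks
oracle_anova_ss <- function(records) {
  y <- records$selectivity
  D <- stats::C(factor(records$category), stats::contr.sum)
  H <- stats::C(factor(records$hemi), stats::contr.sum)
  S <- stats::C(factor(records$subject), stats::contr.sum)
  mm <- function(f) stats::model.matrix(f, data.frame(D, H, S))
  Xd <- mm(~D)[, -1, drop = FALSE]; Xh <- mm(~H)[, -1, drop = FALSE]
  Xs <- mm(~S)[, -1, drop = FALSE]
  prod_cols <- function(A, B) {
    do.call(cbind, lapply(seq_len(ncol(A)), function(i) A[, i] * B))
  }
  blocks <- list(Domain = Xd, Hemisphere = Xh, Subject = Xs,
                 `Domain:Hemisphere` = prod_cols(Xd, Xh),
                 `Domain:Subject` = prod_cols(Xd, Xs),
                 `Hemisphere:Subject` = prod_cols(Xh, Xs))
  proj <- function(X) X %*% solve(t(X) %*% X) %*% t(X)
  X_all <- do.call(cbind, c(list(rep(1, length(y))), blocks))
  P_full <- proj(X_all)
  ss <- sapply(names(blocks), function(nm) {
    X_red <- do.call(cbind, c(list(rep(1, length(y))), blocks[setdiff(names(blocks), nm)]))
    as.numeric(t(y) %*% (P_full - proj(X_red)) %*% y)
  })
  err <- as.numeric(t(y) %*% (diag(length(y)) - P_full) %*% y)
  c(ss, Error = err)
}

# synthetic complete selectivity table (no cohort needed): s subjects x the
# 18 registry fROIs
synth_records <- function(n_subjects, seed = 1, effect = NULL) {
  reg <- froi_registry()
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    data.frame(subject = sprintf("sub-%02d", i), froi = reg$froi,
               category = reg$category, hemi = reg$hemi,
               selectivity = rnorm(nrow(reg), sd = 0.2),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(effect)) out$selectivity <- out$selectivity + effect(out)
  out
}
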