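# Synthetic cohort generator: ground-truth selectivity fields, resting runs
# whose parcel loadings are linearly coupled to those fields, and task runs
# embedding them as condition amplitudes.

# Gaussian base loadings of every vertex onto its hemisphere's parcels:
# vertices load most on nearby parcels, giving smooth, realistic resting
# correlation structure. ell is the spatial length scale in grid units.
.base_loadings <- function(surf_h, ell = 6) {
  cx <- tapply(surf_h$gx, surf_h$parcel, mean)
  cy <- tapply(surf_h$gy, surf_h$parcel, mean)
  d2 <- outer(surf_h$gx, as.numeric(cx), "-")^2 +
    outer(surf_h$gy, as.numeric(cy), "-")^2
  exp(-d2 / (2 * ell^2))
}

# cohort-level coupling matrices: one (categories x parcels) matrix per
# hemisphere mapping latent selectivity to resting parcel loadings
.make_coupling <- function(cfg, seed) {
  cats <- froi_categories()
  with_seed(seed, {
    out <- lapply(c(left = "left", right = "right"), function(h) {
      m <- matrix(stats::rnorm(length(cats) * cfg$n_parcels, sd = 0.3),
                  nrow = length(cats), dimnames = list(cats, NULL))
      m
    })
    out
  })
}

#' Generate per-subject ground truth
#'
#' Draws each subject's fROI centers as the group template centers plus a
#' rigid Gaussian displacement (SD `cfg$jitter`) and a log-normal size
#' jitter, builds the latent selectivity field s_v per category (a Gaussian
#' bump around each center, peak `cfg$amp_select`), and defines the true fROI
#' of each region as the top `cfg$froi_frac` fraction of s within its search
#' space.
#'
#' @param surf a `surface_model`.
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @return a `ground_truth`: list with `s` (vertices x 4 category matrix),
#'   `true_frois` (named list of 0-based vertex id vectors), `centers`
#'   (data.frame of jittered centers and radii).
#' @export
generate_ground_truth <- function(surf, cfg, seed) {
  reg <- froi_registry()
  cats <- froi_categories()
  tmpl <- attr(surf, "ss_centers")
  with_seed(seed, {
    s <- matrix(0, nrow = nrow(surf), ncol = length(cats),
                dimnames = list(NULL, cats))
    centers <- tmpl
    centers$cx <- centers$cx + stats::rnorm(nrow(tmpl), 0, cfg$jitter)
    centers$cy <- centers$cy + stats::rnorm(nrow(tmpl), 0, cfg$jitter)
    centers$r <- 0.6 * tmpl$radius * exp(stats::rnorm(nrow(tmpl), 0, cfg$size_jitter))
    true_frois <- vector("list", nrow(reg))
    names(true_frois) <- reg$froi
    for (i in seq_len(nrow(reg))) {
      ctr <- centers[centers$froi == reg$froi[i], ]
      hmask <- surf$hemi == ctr$hemi
      d2 <- (surf$gx - ctr$cx)^2 + (surf$gy - ctr$cy)^2
      sigma <- ctr$r / 1.2
      bump <- cfg$amp_select * exp(-d2 / (2 * sigma^2))
      bump[!hmask] <- 0
      s[, reg$category[i]] <- s[, reg$category[i]] + bump
      ss <- which(!is.na(surf$froi) & surf$froi == reg$froi[i])
      k <- max(1L, round_half_up(cfg$froi_frac * length(ss)))
      ord <- ss[order(-bump[ss], surf$vertex[ss])]
      true_frois[[reg$froi[i]]] <- sort(surf$vertex[ord[seq_len(k)]])
    }
    structure(list(s = s, true_frois = true_frois, centers = centers),
              class = "ground_truth")
  })
}

# smooth unit-variance latent parcel timeseries: MA(5)-filtered white noise
.latent_series <- function(P, T) {
  w <- matrix(stats::rnorm(P * (T + 4L)), nrow = P)
  k <- rep(1 / sqrt(5), 5)
  out <- t(apply(w, 1L, function(x) stats::filter(x, k, sides = 1)[-(1:4)]))
  matrix(out, nrow = P)
}

#' Generate a resting-state run
#'
#' Vertex signal is `w_v' eta(t) + noise`, where `eta` are P independent
#' smooth latent parcel series per hemisphere and the loadings `w_v` are the
#' Gaussian base loadings plus `cfg$coupling` times the coupling matrix
#' applied to the subject's latent selectivity `s_v`. A framewise
#' displacement trace with occasional >0.5 mm spikes is attached.
#'
#' @param gt the subject's [generate_ground_truth()] output.
#' @param surf a `surface_model`.
#' @param cfg a [cohort_config()].
#' @param coupling cohort-level coupling matrices (per hemisphere).
#' @param seed integer seed.
#' @param volumes run length in TRs (default `cfg$rest_volumes`).
#' @return a `resting_run`: list with `signal` (vertices x time), `fd`
#'   (framewise displacement, mm; fd[1] = 0), `tr`.
#' @export
generate_resting_run <- function(gt, surf, cfg, coupling, seed,
                                 volumes = cfg$rest_volumes) {
  if (volumes < 1L) abort("zero-length resting run")
  with_seed(seed, {
    signal <- matrix(0, nrow = nrow(surf), ncol = volumes)
    for (h in c("left", "right")) {
      idx <- which(surf$hemi == h)
      W <- .base_loadings(surf[idx, , drop = FALSE], ell = cfg$rest_smoothness)
      W <- W + cfg$coupling * (gt$s[idx, , drop = FALSE] %*% coupling[[h]])
      eta <- .latent_series(cfg$n_parcels, volumes)
      signal[idx, ] <- W %*% eta
    }
    signal <- signal +
      matrix(stats::rnorm(length(signal), sd = cfg$noise_rest), nrow = nrow(signal))
    fd <- abs(stats::rnorm(volumes, 0.15, 0.08))
    spikes <- stats::runif(volumes) < cfg$fd_spike_prob
    fd[spikes] <- 0.5 + stats::rexp(sum(spikes), rate = 5)
    fd[1] <- 0
    structure(list(signal = signal, fd = fd, tr = cfg$tr), class = "resting_run")
  })
}

#' Generate a task (localizer) run
#'
#' Vertex signal = baseline + sum over conditions of amplitude x
#' (HRF-convolved, peak-normalized boxcar) + linear drift + white noise.
#' The amplitude of each category condition is `cfg$amp_base + s_v` for that
#' category (so the latent selectivity field is embedded in the preferred
#' condition); scrambled objects get the base amplitude only. Six
#' random-walk motion parameters and a total-vector-movement trace with
#' occasional >1 mm frames are attached.
#'
#' @param gt subject ground truth.
#' @param surf a `surface_model`.
#' @param design a [make_block_design()] result.
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @param hrf HRF parameters, see [hrf_params()].
#' @return a `task_run`: list with `signal` (vertices x time), `design`,
#'   `motion` (time x 6), `movement` (mm per frame, movement[1] = 0), `tr`.
#' @export
generate_task_run <- function(gt, surf, design, cfg, seed, hrf = hrf_params()) {
  validate_block_design(design)
  T <- design$total_volumes
  conds <- localizer_conditions()
  R <- .condition_regressors(design, hrf, conds)  # conditions x time
  cats <- froi_categories()
  A <- matrix(cfg$amp_base, nrow = nrow(surf), ncol = length(conds),
              dimnames = list(NULL, conds))
  for (cat in cats) {
    A[, category_condition(cat)] <- A[, category_condition(cat)] + gt$s[, cat]
  }
  with_seed(seed, {
    drift <- cfg$drift_task * seq(-1, 1, length.out = T)
    signal <- cfg$baseline + A %*% R +
      matrix(drift, nrow = nrow(surf), ncol = T, byrow = TRUE) +
      matrix(stats::rnorm(nrow(surf) * T, sd = cfg$noise_task), nrow = nrow(surf))
    motion <- apply(matrix(stats::rnorm(T * 6L, sd = 0.02), ncol = 6L), 2L, cumsum)
    movement <- abs(stats::rnorm(T, 0.1, 0.05))
    spikes <- stats::runif(T) < cfg$motion_spike_prob
    movement[spikes] <- 1 + stats::rexp(sum(spikes), rate = 2)
    movement[1] <- 0
    structure(list(signal = signal, design = design, motion = motion,
                   movement = movement, tr = design$tr),
              class = "task_run")
  })
}

#' Generate a full synthetic cohort
#'
#' For each subject: ground truth (template fROI centers plus per-subject
#' jitter), one resting run, and two task runs with independently randomized
#' condition orders. Per-subject seeds are derived from the master seed by a
#' labelled counter scheme, so a given subject's data do not depend on cohort
#' size.
#'
#' @param cfg a [cohort_config()].
#' @param seed master seed (default `cfg$seed`).
#' @return a `cohort`: list with `cfg`, `surface`, `registry`, `coupling`,
#'   and `subjects` — a named list (`sub-01`, ...) each holding
#'   `ground_truth`, `rest`, and `task` (list of 2 runs).
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = cfg$seed) {
  surf <- generate_surface(cfg, derive_seed(seed, "surface"))
  validate_surface(surf)
  coupling <- .make_coupling(cfg, derive_seed(seed, "coupling"))
  ids <- sprintf("sub-%02d", seq_len(cfg$n_subjects))
  subjects <- lapply(seq_len(cfg$n_subjects), function(i) {
    gt <- generate_ground_truth(surf, cfg, derive_seed(seed, "gt", i))
    rest <- generate_resting_run(gt, surf, cfg, coupling,
                                 derive_seed(seed, "rest", i))
    task <- lapply(1:2, function(r) {
      dsn <- make_block_design(tr = cfg$tr, seed = derive_seed(seed, "design", i, r))
      generate_task_run(gt, surf, dsn, cfg, derive_seed(seed, "task", i, r))
    })
    list(ground_truth = gt, rest = rest, task = task)
  })
  names(subjects) <- ids
  structure(list(cfg = cfg, surface = surf, registry = froi_registry(),
                 coupling = coupling, subjects = subjects),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d vertices, %d parcels/hemi, seed %d\n",
              length(x$subjects), nrow(x$surface), x$cfg$n_parcels, x$cfg$seed))
  invisible(x)
}

#' Build a group atlas from a cohort's ground truth
#'
#' Emulates group-level atlas parcels for the method comparison:
#' `union` keeps vertices belonging to at least a fraction `q` of subjects'
#' true fROIs (probabilistic-parcel-like); `dilated` morphologically grows
#' that set (coarse multimodal-parcellation-like); `shifted` displaces it by
#' a fixed grid offset (systematically mismatched atlas).
#'
#' @param cohort a [generate_cohort()] result.
#' @param mode one of "union", "dilated", "shifted".
#' @param q membership fraction threshold for the union atlas (default 0.25,
#'   the lenient end of typical probabilistic-parcel thresholds; small
#'   jittered fROIs rarely share vertices across most of a cohort).
#' @param grow dilation radius in grid units (default 1.5).
#' @param shift length-2 grid offset for the shifted atlas (default c(3, 0));
#'   if the offset pushes a border fROI entirely off the sheet, the opposite
#'   offset is used for that fROI.
#' @return named list (by fROI id) of 0-based vertex id vectors.
#' @export
make_group_atlas <- function(cohort, mode = c("union", "dilated", "shifted"),
                             q = 0.25, grow = 1.5, shift = c(3, 0)) {
  mode <- match.arg(mode)
  surf <- cohort$surface
  n_sub <- length(cohort$subjects)
  out <- lapply(cohort$registry$froi, function(f) {
    counts <- integer(nrow(surf))
    for (s in cohort$subjects) {
      v <- s$ground_truth$true_frois[[f]]
      counts[v + 1L] <- counts[v + 1L] + 1L
    }
    base <- which(counts / n_sub >= q)  # 1-based row indices
    set <- switch(mode,
      union = base,
      dilated = {
        h <- surf$hemi[base][1]
        idx <- which(surf$hemi == h)
        d2 <- outer(surf$gx[idx], surf$gx[base], "-")^2 +
          outer(surf$gy[idx], surf$gy[base], "-")^2
        idx[apply(d2 <= grow^2, 1L, any)]
      },
      shifted = {
        key <- paste(surf$hemi, surf$gx, surf$gy)
        move <- function(sh) {
          tgt <- paste(surf$hemi[base], surf$gx[base] + sh[1], surf$gy[base] + sh[2])
          which(key %in% tgt)
        }
        got <- move(shift)
        # border search spaces: displace inward instead of off the sheet
        if (length(got) == 0L) got <- move(-shift)
        got
      }
    )
    if (length(set) == 0L) abort("empty atlas set for fROI %s (mode %s)", f, mode)
    sort(surf$vertex[set])
  })
  names(out) <- cohort$registry$froi
  out
}

#' Ground-truth contrast values for one subject and fROI
#'
#' The latent contrast the predictive model is asked to recover:
#' s(preferred category) - s(contrast category) on the fROI's search-space
#' vertices.
#'
#' @param cohort a cohort.
#' @param subject subject id (e.g. "sub-01").
#' @param froi fROI id (e.g. "rFFA").
#' @return named numeric vector keyed by 0-based vertex id.
#' @export
true_contrast <- function(cohort, subject, froi) {
  reg <- cohort$registry
  row <- reg[reg$froi == froi, ]
  if (nrow(row) != 1L) abort("unknown fROI %s", froi)
  surf <- cohort$surface
  ss <- which(!is.na(surf$froi) & surf$froi == froi)
  s <- cohort$subjects[[subject]]$ground_truth$s
  contrast_cat <- names(which(sapply(froi_categories(), category_condition) == row$contrast_condition))
  neg <- if (length(contrast_cat) == 1L) s[ss, contrast_cat] else 0
  out <- s[ss, row$category] - neg
  names(out) <- surf$vertex[ss]
  out
}
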