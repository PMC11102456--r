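# Synthetic cortical surface: a flat 2-D vertex sheet per hemisphere embedded
# in 3-D, carrying smooth anatomy fields, a 179-parcel parcellation and the
# 18 fROI search spaces.

#' Cohort configuration
#'
#' Collects every knob of the synthetic world. Defaults emulate the target
#' acquisition: 40 subjects, one 580-volume resting run (TR = 1 s), two
#' 234-volume localizer runs, 179 ipsilateral connectivity-target parcels.
#'
#' @param n_subjects number of subjects (default 40).
#' @param vertices_per_hemi vertices per hemisphere (default 900, a 30 x 30
#'   sheet).
#' @param n_parcels ipsilateral target parcels per hemisphere (default 179).
#' @param tr repetition time, seconds (default 1).
#' @param rest_volumes resting-run length in TRs (default 580, i.e. 9.67 min).
#' @param noise_rest white-noise SD added to the resting signal (latent
#'   parcel series have unit variance; default 0.5).
#' @param noise_task white-noise SD of the task signal (baseline 100,
#'   condition amplitudes ~1-2 signal units; default 1).
#' @param jitter SD (grid units) of the rigid displacement of each subject's
#'   fROI center from the group template (default 1).
#' @param size_jitter log-normal SD of per-subject fROI size (default 0.15).
#' @param coupling strength of the linear map from latent selectivity to
#'   resting-state parcel loadings (default 1; 0 = connectivity carries no
#'   information about activation).
#' @param rest_smoothness spatial length scale (grid units) of the Gaussian
#'   base loadings of vertices onto parcels (default 6). Large values give
#'   realistic, spatially overlapping loadings but smear the coupling across
#'   neighbouring parcels; values below the inter-parcel spacing make each
#'   parcel an independent target so the coupling vector itself is
#'   identifiable from model weights.
#' @param baseline task signal baseline (default 100).
#' @param amp_base common response amplitude of every stimulus condition
#'   (default 1).
#' @param amp_select peak of the latent selectivity field added for the
#'   preferred category (default 1; ~1% signal change over baseline 100).
#' @param drift_task amplitude of the linear scanner drift across a task run
#'   (default 0.5).
#' @param fd_spike_prob probability a resting frame is a motion spike with
#'   framewise displacement > 0.5 mm (default 0.05).
#' @param motion_spike_prob probability a task frame exceeds 1 mm total
#'   vector movement (default 0.02).
#' @param froi_frac fraction of a search space forming the true fROI
#'   (default 0.10, matching the top-10% extraction rule).
#' @param seed master seed; all sub-streams are derived from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 40L, vertices_per_hemi = 900L,
                          n_parcels = 179L, tr = 1, rest_volumes = 580L,
                          noise_rest = 0.5, noise_task = 1, jitter = 1,
                          size_jitter = 0.15, coupling = 1, rest_smoothness = 6,
                          baseline = 100,
                          amp_base = 1, amp_select = 1, drift_task = 0.5,
                          fd_spike_prob = 0.05, motion_spike_prob = 0.02,
                          froi_frac = 0.10, seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    vertices_per_hemi = as.integer(vertices_per_hemi),
    n_parcels = as.integer(n_parcels),
    tr = tr, rest_volumes = as.integer(rest_volumes),
    noise_rest = noise_rest, noise_task = noise_task,
    jitter = jitter, size_jitter = size_jitter, coupling = coupling,
    rest_smoothness = rest_smoothness,
    baseline = baseline, amp_base = amp_base, amp_select = amp_select,
    drift_task = drift_task, fd_spike_prob = fd_spike_prob,
    motion_spike_prob = motion_spike_prob, froi_frac = froi_frac,
    seed = as.integer(seed)
  )
  for (k in c("n_subjects", "vertices_per_hemi", "n_parcels", "rest_volumes")) {
    if (!is_count(cfg[[k]])) abort("%s must be a positive integer", k)
  }
  if (cfg$rest_smoothness <= 0) abort("rest_smoothness must be > 0")
  for (k in c("noise_rest", "noise_task", "jitter", "size_jitter")) {
    if (cfg[[k]] < 0) abort("%s must be >= 0", k)
  }
  if (cfg$fd_spike_prob < 0 || cfg$fd_spike_prob > 1) abort("fd_spike_prob in [0,1]")
  if (cfg$motion_spike_prob < 0 || cfg$motion_spike_prob > 1) abort("motion_spike_prob in [0,1]")
  if (cfg$froi_frac <= 0 || cfg$froi_frac > 1) abort("froi_frac in (0,1]")
  if (cfg$vertices_per_hemi < cfg$n_parcels) abort("need at least as many vertices as parcels")
  structure(cfg, class = "cohort_config")
}

# grid layout of one hemisphere: n vertices filled row-wise on an
# approximately square lattice
.hemi_grid <- function(n) {
  side_y <- max(1L, floor(sqrt(n)))
  side_x <- ceiling(n / side_y)
  idx <- seq_len(n) - 1L
  data.frame(gx = idx %% side_x, gy = idx %/% side_x,
             side_x = side_x, side_y = side_y)
}

# smooth random scalar field on the grid (sum of a few seeded harmonics)
.smooth_field <- function(gx, gy, k = 4L) {
  f <- numeric(length(gx))
  for (i in seq_len(k)) {
    fx <- stats::runif(1, 0.05, 0.3); fy <- stats::runif(1, 0.05, 0.3)
    ph <- stats::runif(2, 0, 2 * pi); a <- stats::rnorm(1, 0, 1 / k)
    f <- f + a * sin(fx * gx + ph[1]) * cos(fy * gy + ph[2])
  }
  f
}

#' Generate a synthetic cortical surface
#'
#' Builds the two-hemisphere vertex sheet: smooth curvature/thickness fields,
#' 3-D coordinates (hemispheres occupy disjoint x ranges), a contiguous
#' Voronoi parcellation into `n_parcels` parcels per hemisphere, and 9
#' disjoint circular search spaces per hemisphere placed on a 3 x 3 template
#' lattice, one per registry fROI.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed (default derived from `cfg$seed`).
#' @return a `surface_model`: data.frame with columns `vertex` (0-based,
#'   left hemisphere first), `hemi`, `gx`, `gy`, `x`, `y`, `z`, `curvature`,
#'   `thickness`, `parcel` (1..P), `froi` (search-space id or NA). Search
#'   space template centers are attached as attribute `ss_centers`.
#' @export
generate_surface <- function(cfg = cohort_config(), seed = derive_seed(cfg$seed, "surface")) {
  n <- cfg$vertices_per_hemi
  P <- cfg$n_parcels
  reg <- froi_registry()
  with_seed(seed, {
    hemis <- lapply(c("left", "right"), function(h) {
      g <- .hemi_grid(n)
      curv <- 0.3 * sin(g$gx / 3) + 0.3 * cos(g$gy / 4) + .smooth_field(g$gx, g$gy)
      thick <- 2.5 + 0.3 * .smooth_field(g$gx, g$gy)
      xoff <- if (h == "left") -(g$side_x[1] + 2) else 2
      df <- data.frame(
        hemi = h, gx = g$gx, gy = g$gy,
        x = g$gx + xoff, y = g$gy, z = 2 * curv,
        curvature = curv, thickness = thick,
        stringsAsFactors = FALSE
      )
      # contiguous parcels: Voronoi cells of P seed vertices
      seeds <- sample.int(n, P)
      d2 <- outer(df$gx, df$gx[seeds], "-")^2 + outer(df$gy, df$gy[seeds], "-")^2
      df$parcel <- max.col(-d2, ties.method = "first")
      # search spaces: 9 discs on a 3x3 lattice, registry order
      sx <- g$side_x[1]; sy <- g$side_y[1]
      cx <- rep(sx * c(1, 3, 5) / 6 - 0.5, times = 3)
      cy <- rep(sy * c(1, 3, 5) / 6 - 0.5, each = 3)
      radius <- 0.42 * min(sx, sy) / 3
      rnames <- reg$froi[reg$hemi == h]
      dss <- outer(df$gx, cx, "-")^2 + outer(df$gy, cy, "-")^2
      nearest <- max.col(-dss, ties.method = "first")
      inside <- dss[cbind(seq_len(n), nearest)] <= radius^2
      df$froi <- ifelse(inside, rnames[nearest], NA_character_)
      attr(df, "centers") <- data.frame(froi = rnames, hemi = h, cx = cx,
                                        cy = cy, radius = radius,
                                        stringsAsFactors = FALSE)
      df
    })
    centers <- rbind(attr(hemis[[1]], "centers"), attr(hemis[[2]], "centers"))
    surf <- rbind(hemis[[1]], hemis[[2]])
    surf <- cbind(vertex = seq_len(nrow(surf)) - 1L, surf)
    rownames(surf) <- NULL
    counts <- table(surf$froi)
    if (length(counts) < 18L || any(counts == 0)) {
      abort("surface too small: fewer than 18 non-empty search spaces")
    }
    structure(surf, ss_centers = centers, class = c("surface_model", "data.frame"))
  })
}

#' Validate surface invariants
#' @param surf a `surface_model`.
#' @return `surf` invisibly; errors on violation.
#' @export
validate_surface <- function(surf) {
  if (!inherits(surf, "surface_model")) abort("not a surface_model")
  if (anyNA(surf$parcel)) abort("every vertex needs a parcel label")
  tab <- table(surf$hemi)
  if (length(unique(tab)) != 1L) abort("hemispheres must have equal vertex counts")
  if (any(duplicated(surf$vertex))) abort("duplicate vertex ids")
  invisible(surf)
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d vertices (%d per hemisphere), %d parcels/hemi, %d search spaces\n",
              nrow(x), nrow(x) / 2L, max(x$parcel), length(unique(stats::na.omit(x$froi)))))
  invisible(x)
}
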