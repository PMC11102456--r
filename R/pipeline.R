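# Pipeline orchestration: simulate -> connectome -> GLM -> train/predict ->
# define fROIs -> evaluate, as one reproducible, configured, logged run.

#' Validate a pipeline configuration
#'
#' Fills defaults (0.5 mm resting censoring, 1 mm task spike threshold,
#' d = 2.25 / t = 1.25 HRF, 100-point lambda grid over 1e-5..1e2, top-10%
#' fROI fraction, 40-subject cohort) and rejects unknown keys and out-of-range
#' values.
#'
#' @param x named list of overrides, or path to a JSON file of them. Keys:
#'   `cohort` (list passed to [cohort_config()]), `censor_threshold`,
#'   `motion_threshold`, `hrf` (list: delay, dispersion, exponent),
#'   `lambda` (list: n, lo, hi), `fractions`, `eval_run`, `train_run`,
#'   `seed`, `log_level` ("quiet", "info" or "debug").
#' @return a `pipeline_config` list with fields `cohort` (a
#'   [cohort_config()]), `censor_threshold`, `motion_threshold`, `hrf`,
#'   `grid`, `fractions`, `eval_run`, `train_run`, `seed`, `log_level`.
#' @export
validate_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort("config file not found: %s", x)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  if (!is.list(x)) abort("config must be a list or a JSON file path")
  known <- c("cohort", "censor_threshold", "motion_threshold", "hrf",
             "lambda", "fractions", "eval_run", "train_run", "seed",
             "log_level")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) abort("unknown config key(s): %s", paste(unknown, collapse = ", "))
  errs <- character(0)
  note <- function(fmt, ...) errs[[length(errs) + 1L]] <<- sprintf(fmt, ...)

  seed <- x$seed %||% 1L
  cohort_args <- as.list(x$cohort %||% list())
  if (!"seed" %in% names(cohort_args)) cohort_args$seed <- seed
  cohort <- tryCatch(do.call(cohort_config, cohort_args),
                     error = function(e) { note("cohort: %s", conditionMessage(e)); NULL })
  censor <- x$censor_threshold %||% 0.5
  motion <- x$motion_threshold %||% 1.0
  if (!is.numeric(censor) || censor <= 0) note("censor_threshold must be positive")
  if (!is.numeric(motion) || motion <= 0) note("motion_threshold must be positive")
  hrf_args <- as.list(x$hrf %||% list())
  hrf <- tryCatch(do.call(hrf_params, hrf_args),
                  error = function(e) { note("hrf: %s", conditionMessage(e)); NULL })
  lam <- as.list(x$lambda %||% list())
  grid <- tryCatch(lambda_grid(lam$n %||% 100L, lam$lo %||% 1e-5, lam$hi %||% 1e2),
                   error = function(e) { note("lambda: %s", conditionMessage(e)); NULL })
  fractions <- x$fractions %||% 0.10
  if (!is.numeric(fractions) || any(fractions <= 0) || any(fractions > 1)) {
    note("fractions must lie in (0, 1]")
  }
  eval_run <- x$eval_run %||% 2L
  train_run <- x$train_run %||% 1L
  if (!eval_run %in% 1:2 || !train_run %in% 1:2) note("eval_run/train_run must be 1 or 2")
  log_level <- x$log_level %||% "info"
  if (!log_level %in% c("quiet", "info", "debug")) note("log_level must be quiet/info/debug")
  if (length(errs) > 0L) abort("invalid config:\n- %s", paste(errs, collapse = "\n- "))
  structure(list(cohort = cohort, censor_threshold = censor,
                 motion_threshold = motion, hrf = hrf, grid = grid,
                 fractions = fractions, eval_run = as.integer(eval_run),
                 train_run = as.integer(train_run), seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[connfroi seed=%d] %s", config$seed, sprintf(fmt, ...)))
}

# ---- reusable pipeline stages (in-memory) --------------------------------

#' Compute feature matrices for every fROI and subject
#'
#' Censors resting frames, builds each fROI's vertex-to-parcel connectome and
#' appends vertex anatomy.
#'
#' @param cohort a [generate_cohort()] result.
#' @param censor_threshold FD censoring threshold, mm (default 0.5).
#' @return nested list `features[[froi]][[subject]]` of S x (P+5) matrices
#'   with vertex-id rownames.
#' @export
compute_features <- function(cohort, censor_threshold = 0.5) {
  surf <- cohort$surface
  reg <- cohort$registry
  ss <- lapply(reg$froi, function(f) surf$vertex[!is.na(surf$froi) & surf$froi == f])
  names(ss) <- reg$froi
  out <- lapply(reg$froi, function(f) {
    lapply(cohort$subjects, function(sub) {
      mask <- censor_frames(sub$rest, censor_threshold)
      cn <- compute_connectome(sub$rest, mask, ss[[f]], surf, froi = f)
      build_feature_matrix(cn, surf)$X
    })
  })
  names(out) <- reg$froi
  out
}

#' Fit first-level GLMs and contrasts for every subject and run
#'
#' @param cohort a cohort.
#' @param motion_threshold spike threshold, mm (default 1).
#' @param hrf [hrf_params()].
#' @return list with `betamaps[[run]][[subject]]` and
#'   `cmaps[[run]][[subject]][[category]]` (`contrast_map`s for the four
#'   localizer contrasts).
#' @export
compute_glm_all <- function(cohort, motion_threshold = 1, hrf = hrf_params()) {
  specs <- localizer_contrasts()
  betamaps <- list(); cmaps <- list()
  for (r in 1:2) {
    betamaps[[r]] <- lapply(cohort$subjects, function(sub) {
      run <- sub$task[[r]]
      spikes <- flag_motion_frames(run, motion_threshold)
      dsn <- build_glm_design(run$design, hrf, motion = run$motion, spikes = spikes)
      fit_glm(run, dsn)
    })
    cmaps[[r]] <- lapply(betamaps[[r]], function(bm) {
      lapply(specs, function(sp) compute_contrast(bm, sp))
    })
  }
  list(betamaps = betamaps, cmaps = cmaps)
}

# per-subject (X, y) pairs for one fROI: features plus the training-run
# contrast effect on the search-space vertices
.froi_model_data <- function(features, cmaps, cohort, froi, run) {
  reg <- cohort$registry
  category <- reg$category[reg$froi == froi]
  lapply(stats::setNames(nm = names(cohort$subjects)), function(id) {
    X <- features[[froi]][[id]]
    y <- cmaps[[run]][[id]][[category]]$effect[rownames(X)]
    list(X = X, y = as.numeric(y))
  })
}

#' Assemble per-subject model data for one fROI
#'
#' Convenience wrapper computing features and training targets from scratch
#' for a single fROI (the full pipeline shares these computations across
#' fROIs instead).
#'
#' @param cohort a cohort.
#' @param froi fROI id.
#' @param run training run supplying the contrast targets (default 1).
#' @param censor_threshold,motion_threshold,hrf pipeline constants.
#' @return named list per subject with `X` and `y`.
#' @export
froi_training_data <- function(cohort, froi, run = 1,
                               censor_threshold = 0.5, motion_threshold = 1,
                               hrf = hrf_params()) {
  surf <- cohort$surface
  ss <- surf$vertex[!is.na(surf$froi) & surf$froi == froi]
  reg <- cohort$registry
  category <- reg$category[reg$froi == froi]
  spec <- localizer_contrasts()[[category]]
  lapply(stats::setNames(nm = names(cohort$subjects)), function(id) {
    sub <- cohort$subjects[[id]]
    mask <- censor_frames(sub$rest, censor_threshold)
    cn <- compute_connectome(sub$rest, mask, ss, surf, froi = froi)
    X <- build_feature_matrix(cn, surf)$X
    trun <- sub$task[[run]]
    spikes <- flag_motion_frames(trun, motion_threshold)
    dsn <- build_glm_design(trun$design, hrf, motion = trun$motion, spikes = spikes)
    cm <- compute_contrast(fit_glm(trun, dsn), spec)
    list(X = X, y = as.numeric(cm$effect[rownames(X)]))
  })
}

#' Run the full pipeline
#'
#' Simulates the cohort, computes connectomes and GLMs, runs nested LOSO
#' ridge prediction for all 18 fROIs, defines fROIs by every method
#' (connectivity, localizer run, three synthetic group atlases, ground
#' truth), computes overlap metrics and the selectivity evaluation on the
#' held-out run, and (optionally) writes all artifacts plus a manifest with
#' checksums.
#'
#' @param config a [validate_config()] result (or a list/path accepted by
#'   it).
#' @param out_dir optional output directory for artifacts.
#' @param cohort optionally, a pre-generated cohort (must match the config).
#' @return a `pipeline_result` list: `config`, `cohort`, `features`,
#'   `glm`, `cvreports`, `final_models`, `frois`, `overlap`, `selectivity`,
#'   `comparison`, `anova`, `manifest`.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = NULL,
                         cohort = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    t_all[[name]] <<- round(tic() - t0, 2)
    .log(config, "stage %-12s done in %6.1f s", name, t_all[[name]])
    res
  }
  if (is.null(cohort)) {
    cohort <- stage("simulate", generate_cohort(config$cohort, seed = config$seed))
  }
  reg <- cohort$registry
  surf <- cohort$surface
  ss <- lapply(reg$froi, function(f) surf$vertex[!is.na(surf$froi) & surf$froi == f])
  names(ss) <- reg$froi

  features <- stage("connectome", compute_features(cohort, config$censor_threshold))
  glm <- stage("glm", compute_glm_all(cohort, config$motion_threshold, config$hrf))

  fit <- stage("train", {
    cvreports <- list(); final_models <- list()
    for (f in reg$froi) {
      dat <- .froi_model_data(features, glm$cmaps, cohort, f, config$train_run)
      cvreports[[f]] <- loso_predict(dat, config$grid)
      final_models[[f]] <- fit_final_model(dat, config$grid, froi = f)
      .log(config, "  fROI %-5s median lambda %.3g", f, stats::median(cvreports[[f]]$lambda))
    }
    list(cvreports = cvreports, final_models = final_models)
  })

  frois <- stage("define-froi", {
    atlases <- list(atlas_union = make_group_atlas(cohort, "union"),
                    atlas_dilated = make_group_atlas(cohort, "dilated"),
                    atlas_shifted = make_group_atlas(cohort, "shifted"))
    subj_ids <- names(cohort$subjects)
    per_frac <- lapply(config$fractions, function(f) {
      conn <- lapply(stats::setNames(nm = subj_ids), function(id) {
        lapply(stats::setNames(nm = reg$froi), function(fr) {
          define_froi(fit$cvreports[[fr]]$predicted[[id]], ss[[fr]], f,
                      method = "connectivity", froi = fr)
        })
      })
      loc <- lapply(1:2, function(r) {
        lapply(stats::setNames(nm = subj_ids), function(id) {
          lapply(stats::setNames(nm = reg$froi), function(fr) {
            cat <- reg$category[reg$froi == fr]
            define_froi(glm$cmaps[[r]][[id]][[cat]], ss[[fr]], f,
                        method = sprintf("localizer-run%d", r), froi = fr)
          })
        })
      })
      list(connectivity = conn, localizer_run1 = loc[[1]], localizer_run2 = loc[[2]])
    })
    names(per_frac) <- sprintf("f%.2f", config$fractions)
    truth <- lapply(stats::setNames(nm = subj_ids), function(id) {
      cohort$subjects[[id]]$ground_truth$true_frois
    })
    list(per_fraction = per_frac, atlases = atlases, truth = truth)
  })

  overlap <- stage("overlap", {
    rows <- list()
    for (fn in names(frois$per_fraction)) {
      pf <- frois$per_fraction[[fn]]
      for (id in names(pf$connectivity)) {
        for (fr in reg$froi) {
          om <- overlap_metrics(pf$connectivity[[id]][[fr]],
                                pf$localizer_run1[[id]][[fr]],
                                pf$localizer_run2[[id]][[fr]])
          rows[[length(rows) + 1L]] <- data.frame(
            fraction = om$f, subject = id, froi = fr,
            dice_pred = om$dice_pred, dice_actual = om$dice_actual,
            explainable_ratio = om$explainable_ratio,
            chance_adjusted = om$chance_adjusted, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  eval_res <- stage("evaluate", {
    f1 <- frois$per_fraction[[1]]
    methods <- list(
      connectivity = f1$connectivity,
      localizer = f1[[sprintf("localizer_run%d", config$train_run)]],
      atlas_union = lapply(stats::setNames(nm = names(f1$connectivity)),
                           function(id) frois$atlases$atlas_union),
      atlas_dilated = lapply(stats::setNames(nm = names(f1$connectivity)),
                             function(id) frois$atlases$atlas_dilated),
      atlas_shifted = lapply(stats::setNames(nm = names(f1$connectivity)),
                             function(id) frois$atlases$atlas_shifted)
    )
    sel <- selectivity_table(methods, glm$betamaps[[config$eval_run]], reg)
    cmp <- compare_methods(sel)
    anova <- anova_selectivity(sel[sel$method == "connectivity", ])
    list(selectivity = sel, comparison = cmp, anova = anova)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("connfroi")),
    seed = config$seed,
    n_subjects = length(cohort$subjects),
    fractions = config$fractions,
    timings_s = t_all,
    config = unclass(config[c("censor_threshold", "motion_threshold",
                              "fractions", "eval_run", "train_run", "seed")])
  )
  result <- structure(list(config = config, cohort = cohort,
                           features = features, glm = glm,
                           cvreports = fit$cvreports,
                           final_models = fit$final_models,
                           frois = frois, overlap = overlap,
                           selectivity = eval_res$selectivity,
                           comparison = eval_res$comparison,
                           anova = eval_res$anova,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, out_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$comparison$summary
  cat(sprintf("<pipeline_result> %d subjects, %d fROIs\n",
              length(x$cohort$subjects), nrow(x$cohort$registry)))
  cat(sprintf("  %s: %d/%d selective (mean selectivity %.3f)\n",
              s$method, s$n_selective, s$n_frois, s$mean_selectivity), sep = "")
  invisible(x)
}
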