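# Serialization: pipeline artifacts (TSV/JSON with a checksummed manifest)
# and the cohort directory layout (plain delimited text + JSON).

.write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  path
}

# gz-transparent TSV reader (fread's own gz support needs R.utils)
.read_tsv <- function(path) {
  if (endsWith(path, ".gz")) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    as.data.frame(data.table::fread(text = readLines(con)))
  } else {
    as.data.frame(data.table::fread(path))
  }
}

#' Write pipeline artifacts
#'
#' Writes selectivity.tsv, tests.tsv, anova.tsv, overlap.tsv, cvreport.tsv,
#' frois/<method>.tsv, models/<froi>.json, a plain-text report and
#' manifest.json (with md5 checksums of every artifact).
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "frois"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
  files <- character(0)
  files <- c(files, .write_tsv(result$selectivity, file.path(out_dir, "selectivity.tsv")))

  st <- result$comparison$selectivity_tests
  st$test <- "selectivity_vs_zero"
  mt <- result$comparison$method_tests
  mt$test <- "connectivity_vs_method"
  tests <- rbind(
    st[, c("test", "froi", "method", "n", "t", "p", "significant")],
    mt[, c("test", "froi", "method", "n", "t", "p", "significant")]
  )
  files <- c(files, .write_tsv(tests, file.path(out_dir, "tests.tsv")))

  an <- result$anova
  names(an) <- c("Predictor", "SS", "df", "MS", "F", "p")
  files <- c(files, .write_tsv(an, file.path(out_dir, "anova.tsv")))
  files <- c(files, .write_tsv(result$overlap, file.path(out_dir, "overlap.tsv")))

  cv <- do.call(rbind, lapply(names(result$cvreports), function(f) {
    data.frame(froi = f, subject = names(result$cvreports[[f]]$lambda),
               lambda = as.numeric(result$cvreports[[f]]$lambda),
               stringsAsFactors = FALSE)
  }))
  files <- c(files, .write_tsv(cv, file.path(out_dir, "cvreport.tsv")))

  f1 <- result$frois$per_fraction[[1]]
  for (m in names(f1)) {
    rows <- do.call(rbind, lapply(names(f1[[m]]), function(id) {
      do.call(rbind, lapply(f1[[m]][[id]], function(fr) {
        data.frame(subject = id, froi = fr$froi, vertex = fr$vertices,
                   f = fr$f, stringsAsFactors = FALSE)
      }))
    }))
    files <- c(files, .write_tsv(rows, file.path(out_dir, "frois", paste0(m, ".tsv"))))
  }
  for (m in names(result$frois$atlases)) {
    rows <- do.call(rbind, lapply(names(result$frois$atlases[[m]]), function(f) {
      data.frame(froi = f, vertex = result$frois$atlases[[m]][[f]],
                 stringsAsFactors = FALSE)
    }))
    files <- c(files, .write_tsv(rows, file.path(out_dir, "frois", paste0(m, ".tsv"))))
  }
  for (f in names(result$final_models)) {
    path <- file.path(out_dir, "models", paste0(f, ".json"))
    write_ridge_model(result$final_models[[f]], path)
    files <- c(files, path)
  }

  s <- result$comparison$summary
  report <- c(
    sprintf("connfroi pipeline report (seed %d, %d subjects)",
            result$config$seed, length(result$cohort$subjects)),
    sprintf("Bonferroni threshold 0.05/%d = %.6f",
            nrow(result$cohort$registry),
            result$comparison$thresholds[["selectivity"]]),
    sprintf("%-16s %2d/%2d fROIs selective, mean selectivity %6.3f",
            s$method, s$n_selective, s$n_frois, s$mean_selectivity)
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  files <- c(files, file.path(out_dir, "report.txt"))

  manifest <- result$manifest
  manifest$files <- lapply(stats::setNames(files, basename(files)), function(p) {
    list(path = sub(paste0("^", out_dir, "/?"), "", p),
         md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Serialize a ridge model to JSON
#'
#' Weights, intercept, lambda and standardization statistics keyed by column
#' name, plus training metadata.
#'
#' @param model a `ridge_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ridge_model <- function(model, path) {
  payload <- list(
    weights = as.list(model$weights),
    intercept = model$intercept,
    lambda = model$lambda,
    center = as.list(model$center),
    scale = as.list(model$scale),
    dropped = model$dropped,
    froi = model$froi %||% NA,
    subjects = model$subjects %||% character(0),
    n_train = model$n_train,
    package_version = as.character(utils::packageVersion("connfroi"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized ridge model
#' @param path JSON path written by [write_ridge_model()].
#' @return a `ridge_model`.
#' @export
read_ridge_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = unlist(p$weights), intercept = p$intercept,
                 lambda = p$lambda, center = unlist(p$center),
                 scale = unlist(p$scale), columns = names(unlist(p$weights)),
                 dropped = p$dropped %||% character(0), froi = p$froi,
                 subjects = p$subjects, n_train = p$n_train),
            class = "ridge_model")
}

# ---- cohort directory ----------------------------------------------------

#' Write a cohort to a directory
#'
#' Layout: `config.json`, `surface.tsv` (vertex table), `parcels.tsv`,
#' `searchspaces.tsv`, `coupling_<hemi>.tsv`, and per subject `rest.tsv.gz`,
#' `fd.tsv`, `task_run{1,2}.tsv.gz`, `design_run{1,2}.tsv`,
#' `motion_run{1,2}.tsv` (6 params + movement trace) and
#' `ground_truth.json`. All tables are tab-delimited text with headers.
#'
#' @param cohort a cohort.
#' @param dir target directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cohort$cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  surf <- as.data.frame(cohort$surface)
  .write_tsv(surf[, c("vertex", "hemi", "gx", "gy", "x", "y", "z",
                      "curvature", "thickness")],
             file.path(dir, "surface.tsv"))
  .write_tsv(surf[, c("vertex", "parcel")], file.path(dir, "parcels.tsv"))
  sspace <- surf[!is.na(surf$froi), c("vertex", "froi")]
  .write_tsv(sspace, file.path(dir, "searchspaces.tsv"))
  .write_tsv(attr(cohort$surface, "ss_centers"), file.path(dir, "ss_centers.tsv"))
  for (h in c("left", "right")) {
    .write_tsv(as.data.frame(cohort$coupling[[h]]),
               file.path(dir, sprintf("coupling_%s.tsv", h)))
  }
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    sd <- file.path(dir, id)
    dir.create(sd, showWarnings = FALSE)
    data.table::fwrite(as.data.frame(sub$rest$signal),
                       file.path(sd, "rest.tsv.gz"), sep = "\t")
    .write_tsv(data.frame(fd = sub$rest$fd), file.path(sd, "fd.tsv"))
    for (r in 1:2) {
      run <- sub$task[[r]]
      data.table::fwrite(as.data.frame(run$signal),
                         file.path(sd, sprintf("task_run%d.tsv.gz", r)), sep = "\t")
      b <- run$design$blocks
      names(b) <- c("condition", "onset_s", "duration_s")
      .write_tsv(b, file.path(sd, sprintf("design_run%d.tsv", r)))
      mo <- as.data.frame(run$motion)
      names(mo) <- sprintf("m%d", 1:6)
      mo$movement <- run$movement
      .write_tsv(mo, file.path(sd, sprintf("motion_run%d.tsv", r)))
    }
    gt <- sub$ground_truth
    jsonlite::write_json(
      list(s = as.data.frame(gt$s), true_frois = gt$true_frois,
           centers = gt$centers),
      file.path(sd, "ground_truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' Inverse of [write_cohort()].
#'
#' @param dir directory written by [write_cohort()].
#' @return a `cohort`.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir) || !file.exists(file.path(dir, "config.json"))) {
    abort("not a cohort directory (no config.json): %s", dir)
  }
  cfg <- do.call(cohort_config, jsonlite::read_json(file.path(dir, "config.json"),
                                                    simplifyVector = TRUE))
  surf <- as.data.frame(data.table::fread(file.path(dir, "surface.tsv")))
  parc <- as.data.frame(data.table::fread(file.path(dir, "parcels.tsv")))
  sspace <- as.data.frame(data.table::fread(file.path(dir, "searchspaces.tsv")))
  surf$parcel <- parc$parcel[match(surf$vertex, parc$vertex)]
  surf$froi <- sspace$froi[match(surf$vertex, sspace$vertex)]
  centers <- as.data.frame(data.table::fread(file.path(dir, "ss_centers.tsv")))
  surf <- structure(surf, ss_centers = centers,
                    class = c("surface_model", "data.frame"))
  coupling <- lapply(c(left = "left", right = "right"), function(h) {
    m <- as.matrix(data.table::fread(file.path(dir, sprintf("coupling_%s.tsv", h))))
    rownames(m) <- froi_categories()
    dimnames(m)[2] <- list(NULL)
    m
  })
  ids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  ids <- ids[grepl("^sub-", ids)]
  subjects <- lapply(ids, function(id) {
    sd <- file.path(dir, id)
    rest_sig <- as.matrix(.read_tsv(file.path(sd, "rest.tsv.gz")))
    dimnames(rest_sig) <- NULL
    fd <- data.table::fread(file.path(sd, "fd.tsv"))$fd
    rest <- structure(list(signal = rest_sig, fd = fd, tr = cfg$tr),
                      class = "resting_run")
    task <- lapply(1:2, function(r) {
      sig <- as.matrix(.read_tsv(file.path(sd, sprintf("task_run%d.tsv.gz", r))))
      dimnames(sig) <- NULL
      b <- as.data.frame(data.table::fread(file.path(sd, sprintf("design_run%d.tsv", r))))
      names(b) <- c("condition", "onset", "duration")
      dsn <- structure(list(blocks = b, tr = cfg$tr,
                            total_volumes = ncol(sig)), class = "block_design")
      validate_block_design(dsn)
      mo <- as.data.frame(data.table::fread(file.path(sd, sprintf("motion_run%d.tsv", r))))
      structure(list(signal = sig, design = dsn,
                     motion = as.matrix(mo[, 1:6]), movement = mo$movement,
                     tr = cfg$tr), class = "task_run")
    })
    gt <- jsonlite::read_json(file.path(sd, "ground_truth.json"), simplifyVector = TRUE)
    s <- as.matrix(gt$s)
    dimnames(s) <- list(NULL, froi_categories())
    gt <- structure(list(s = s,
                         true_frois = lapply(gt$true_frois, as.integer),
                         centers = gt$centers), class = "ground_truth")
    list(ground_truth = gt, rest = rest, task = task)
  })
  names(subjects) <- ids
  structure(list(cfg = cfg, surface = surf, registry = froi_registry(),
                 coupling = coupling, subjects = subjects),
            class = "cohort")
}
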