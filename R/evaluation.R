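# Selectivity statistics: per-fROI percent-signal-change selectivity, paired
# t-tests, Bonferroni correction, the category x hemisphere ANOVA with
# subject as a random factor, and method comparisons.

#' Selectivity table
#'
#' For every subject, fROI and method, computes the PSC of each condition on
#' the evaluation run's betas within the fROI's vertex set, and selectivity =
#' PSC(preferred) - PSC(contrast category).
#'
#' @param frois nested list: `frois[[method]][[subject]][[froi id]]` is a
#'   `froi` (or a plain vertex id vector, e.g. an atlas set).
#' @param betamaps named list per subject of evaluation-run [fit_glm()]
#'   results.
#' @param registry the fROI registry (default [froi_registry()]).
#' @return data.frame with subject, froi, method, one `psc_*` column per
#'   condition, and `selectivity`. Missing fROIs are skipped with a warning.
#' @export
selectivity_table <- function(frois, betamaps, registry = froi_registry()) {
  conds <- localizer_conditions()
  rows <- list()
  for (method in names(frois)) {
    for (subject in names(frois[[method]])) {
      bm <- betamaps[[subject]]
      if (is.null(bm)) abort("no beta map for subject %s", subject)
      for (i in seq_len(nrow(registry))) {
        fid <- registry$froi[i]
        fr <- frois[[method]][[subject]][[fid]]
        if (is.null(fr)) {
          warning(sprintf("missing fROI %s for %s/%s: skipped", fid, method, subject),
                  call. = FALSE)
          next
        }
        verts <- if (inherits(fr, "froi")) fr$vertices else fr
        psc <- vapply(conds, function(cn) compute_psc(bm, verts, cn), numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subject, froi = fid, method = method,
          hemi = registry$hemi[i], category = registry$category[i],
          as.list(stats::setNames(psc, paste0("psc_", conds))),
          selectivity = psc[registry$preferred_condition[i]] -
            psc[registry$contrast_condition[i]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired two-sided t-test
#'
#' One-sample t on the paired differences with df = n - 1.
#'
#' @param x,y numeric vectors paired by subject (equal length, n >= 2).
#' @return a `test_result`: list with `statistic`, `df`, `p` (two-sided),
#'   `mean_diff`, `n`. Errors on zero-variance differences.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  n <- length(x)
  if (n < 2L) abort("need n >= 2 pairs")
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) abort("zero-variance differences: t undefined")
  t_stat <- mean(d) / (sd_d / sqrt(n))
  structure(list(statistic = t_stat, df = n - 1L,
                 p = 2 * stats::pt(-abs(t_stat), df = n - 1L),
                 mean_diff = mean(d), n = n),
            class = "test_result")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is_count(m)) abort("m must be a positive integer")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  alpha / m
}

#' Category x hemisphere ANOVA of selectivity with subject as random factor
#'
#' Fits the crossed model Domain (4 categories) x Hemisphere (2) x Subject
#' on per-fROI selectivity values (18 observations per subject; categories
#' are unbalanced across fROIs, so Type III / constrained sums of squares
#' are used: each effect is adjusted for all others under sum-to-zero
#' coding). By default every F ratio is formed against the Error mean
#' square; `denominators = "mixed"` instead tests Domain against the
#' Domain x Subject MS and Hemisphere against the Hemisphere x Subject MS
#' (classical random-subject denominators).
#'
#' @param records data.frame with columns `subject`, `category`, `hemi`,
#'   `selectivity` (one row per subject x fROI; typically one method's rows
#'   of [selectivity_table()]).
#' @param denominators "error" (default) or "mixed".
#' @return an `anova_result` data.frame with rows Domain, Hemisphere,
#'   Subject, Domain:Hemisphere, Domain:Subject, Hemisphere:Subject, Error,
#'   Total and columns `term`, `ss`, `df`, `ms`, `F`, `p`.
#' @export
anova_selectivity <- function(records, denominators = c("error", "mixed")) {
  denominators <- match.arg(denominators)
  need <- c("subject", "category", "hemi", "selectivity")
  if (!all(need %in% names(records))) {
    abort("records need columns: %s", paste(need, collapse = ", "))
  }
  # complete crossing: every subject contributes the same froi count
  tab <- table(records$subject)
  if (length(unique(tab)) != 1L) {
    bad <- names(tab)[tab != max(tab)]
    abort("incomplete design; subjects with missing cells: %s",
          paste(bad, collapse = ", "))
  }
  cell <- table(records$subject, records$category, records$hemi)
  if (any(cell == 0)) abort("incomplete design: empty subject x category x hemisphere cell(s)")
  y <- records$selectivity
  N <- length(y)
  D <- stats::C(factor(records$category), stats::contr.sum)
  H <- stats::C(factor(records$hemi), stats::contr.sum)
  S <- stats::C(factor(records$subject), stats::contr.sum)
  mm <- function(fml) stats::model.matrix(fml, data = data.frame(D, H, S))
  Xd <- mm(~D)[, -1, drop = FALSE]
  Xh <- mm(~H)[, -1, drop = FALSE]
  Xs <- mm(~S)[, -1, drop = FALSE]
  # interaction columns as products of main-effect contrast columns
  colprod <- function(A, B) {
    out <- matrix(0, nrow = nrow(A), ncol = ncol(A) * ncol(B))
    k <- 0L
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      k <- k + 1L; out[, k] <- A[, i] * B[, j]
    }
    out
  }
  terms <- list(
    Domain = Xd, Hemisphere = Xh, Subject = Xs,
    `Domain:Hemisphere` = colprod(Xd, Xh),
    `Domain:Subject` = colprod(Xd, Xs),
    `Hemisphere:Subject` = colprod(Xh, Xs)
  )
  X_full <- do.call(cbind, c(list(`(Intercept)` = rep(1, N)), terms))
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(X_full)
  df_terms <- vapply(terms, ncol, integer(1))
  ss <- vapply(names(terms), function(tm) {
    keep <- setdiff(names(terms), tm)
    X_red <- do.call(cbind, c(list(rep(1, N)), terms[keep]))
    rss(X_red) - rss_full
  }, numeric(1))
  ss <- pmax(ss, 0)
  df_err <- N - 1L - sum(df_terms)
  ss_err <- rss_full
  ms <- ss / df_terms
  ms_err <- ss_err / df_err
  denom_ms <- rep(ms_err, length(terms))
  denom_df <- rep(df_err, length(terms))
  names(denom_ms) <- names(denom_df) <- names(terms)
  if (denominators == "mixed") {
    denom_ms["Domain"] <- ms["Domain:Subject"]
    denom_df["Domain"] <- df_terms["Domain:Subject"]
    denom_ms["Hemisphere"] <- ms["Hemisphere:Subject"]
    denom_df["Hemisphere"] <- df_terms["Hemisphere:Subject"]
  }
  Fv <- ms / denom_ms
  pv <- stats::pf(Fv, df_terms, denom_df, lower.tail = FALSE)
  out <- data.frame(
    term = c(names(terms), "Error", "Total"),
    ss = unname(c(ss, ss_err, sum((y - mean(y))^2))),
    df = as.integer(unname(c(df_terms, df_err, N - 1L))),
    ms = unname(c(ms, ms_err, NA_real_)),
    F = unname(c(Fv, NA_real_, NA_real_)),
    p = unname(c(pv, NA_real_, NA_real_)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  attr(out, "denominators") <- denominators
  out
}

#' Compare fROI-definition methods
#'
#' Per fROI and method: a one-sample t-test of selectivity against zero
#' (is the region selective?), and paired t-tests of the reference method's
#' selectivity against every other method. Bonferroni flags use
#' 0.05 / n_frois for selectivity and 0.05 / (n_pairs * n_frois) for method
#' contrasts. Identical records across methods (zero-variance differences)
#' are reported as "no difference" (t = NA).
#'
#' @param records a [selectivity_table()] result covering >= 2 methods.
#' @param reference method name compared against the others (default
#'   "connectivity").
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `selectivity_tests` (froi x method), `method_tests`
#'   (froi x comparison method; positive mean_diff favours the reference),
#'   and `summary` (selective-region counts per method).
#' @export
compare_methods <- function(records, reference = "connectivity", alpha = 0.05) {
  methods <- unique(records$method)
  keep <- vapply(methods, function(m) {
    ok <- sum(records$method == m) > 0
    if (!ok) warning(sprintf("method %s has no records: excluded", m), call. = FALSE)
    ok
  }, logical(1))
  methods <- methods[keep]
  if (length(methods) < 2L) abort("need >= 2 methods with records")
  if (!reference %in% methods) abort("reference method %s missing", reference)
  frois <- unique(records$froi)
  thr_sel <- bonferroni_threshold(alpha, length(frois))
  others <- setdiff(methods, reference)
  thr_cmp <- bonferroni_threshold(alpha, length(others) * length(frois))

  sel_rows <- list()
  for (m in methods) for (f in frois) {
    r <- records[records$method == m & records$froi == f, ]
    r <- r[order(r$subject), ]
    tt <- tryCatch(paired_ttest(r$selectivity, rep(0, nrow(r))),
                   error = function(e) NULL)
    sel_rows[[length(sel_rows) + 1L]] <- data.frame(
      froi = f, method = m, n = nrow(r),
      mean_selectivity = mean(r$selectivity),
      t = if (is.null(tt)) NA_real_ else tt$statistic,
      p = if (is.null(tt)) NA_real_ else tt$p,
      significant = if (is.null(tt)) FALSE else tt$p < thr_sel,
      stringsAsFactors = FALSE
    )
  }
  sel_tab <- do.call(rbind, sel_rows)

  cmp_rows <- list()
  for (m in others) for (f in frois) {
    a <- records[records$method == reference & records$froi == f, ]
    b <- records[records$method == m & records$froi == f, ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    common <- intersect(a$subject, b$subject)
    a <- a[match(common, a$subject), ]; b <- b[match(common, b$subject), ]
    tt <- tryCatch(paired_ttest(a$selectivity, b$selectivity),
                   error = function(e) NULL)
    cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
      froi = f, method = m, n = length(common),
      mean_diff = mean(a$selectivity - b$selectivity),
      t = if (is.null(tt)) NA_real_ else tt$statistic,
      p = if (is.null(tt)) NA_real_ else tt$p,
      note = if (is.null(tt)) "no difference" else "",
      significant = if (is.null(tt)) FALSE else tt$p < thr_cmp,
      stringsAsFactors = FALSE
    )
  }
  cmp_tab <- do.call(rbind, cmp_rows)

  summary_tab <- do.call(rbind, lapply(methods, function(m) {
    s <- sel_tab[sel_tab$method == m, ]
    data.frame(method = m, n_frois = nrow(s),
               n_selective = sum(s$significant, na.rm = TRUE),
               mean_selectivity = mean(s$mean_selectivity),
               stringsAsFactors = FALSE)
  }))
  list(selectivity_tests = sel_tab, method_tests = cmp_tab,
       summary = summary_tab,
       thresholds = c(selectivity = thr_sel, comparison = thr_cmp))
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("ANOVA of selectivity (Type III SS, F vs %s MS)\n",
              attr(x, "denominators")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.4f, p = %.3g, mean diff = %.4g (n = %d)\n",
              x$df, x$statistic, x$p, x$mean_diff, x$n))
  invisible(x)
}
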