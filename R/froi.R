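# fROI definition by top-fraction thresholding of contrast maps, and overlap
# metrics between fROI definitions.

#' Define an fROI from a contrast map
#'
#' Selects the `k = max(1, round(f * S))` vertices (round-half-up) with the
#' largest map values within the search space; ties broken by smaller vertex
#' id.
#'
#' @param map a `contrast_map`, or a numeric vector named by 0-based vertex
#'   id (e.g. a predicted map).
#' @param search_space 0-based vertex ids of the search space.
#' @param f threshold fraction in (0, 1] (default 0.10; 0.20/0.30 supported
#'   for the threshold-robustness variants).
#' @param method provenance label ("connectivity", "localizer", an atlas
#'   name, "ground-truth", ...).
#' @param froi fROI id.
#' @return a `froi`: list with `froi`, `method`, `vertices` (sorted 0-based
#'   ids), `f`, `k`.
#' @export
define_froi <- function(map, search_space, f = 0.10, method = "connectivity",
                        froi = NA_character_) {
  if (length(search_space) == 0L) abort("empty search space")
  if (!(f > 0 && f <= 1)) abort("f must be in (0, 1]")
  vals <- if (inherits(map, "contrast_map")) map$effect else map
  v <- vals[as.character(search_space)]
  if (anyNA(v)) abort("map does not cover the search space")
  k <- max(1L, round_half_up(f * length(search_space)))
  ord <- order(-v, search_space)
  structure(list(froi = froi, method = method,
                 vertices = sort(search_space[ord[seq_len(k)]]),
                 f = f, k = k),
            class = "froi")
}

#' Dice overlap coefficient
#'
#' `2|A & B| / (|A| + |B|)`. Errors if both sets are empty.
#'
#' @param A,B vertex id vectors or `froi` objects.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(A, B) {
  if (inherits(A, "froi")) A <- A$vertices
  if (inherits(B, "froi")) B <- B$vertices
  if (length(A) == 0L && length(B) == 0L) abort("both sets empty: Dice undefined")
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

#' Overlap metrics between predicted and localizer-defined fROIs
#'
#' Explainable overlap ratio = Dice(pred, actual run 1) / Dice(actual run 1,
#' actual run 2): run-to-run overlap bounds what any prediction could
#' achieve. Chance-adjusted overlap = (Dice - f) / (1 - f), since two
#' independent top-f selections in the same search space have expected Dice
#' f (hypergeometric: E|A & B| = f^2 S, |A| = |B| = fS).
#'
#' @param pred,actual_run1,actual_run2 `froi` objects sharing id and
#'   fraction.
#' @return an `overlap_result`: list with `dice_pred` (pred vs run-1
#'   actual), `dice_actual` (run 1 vs run 2), `explainable_ratio` (NA if
#'   run-to-run Dice is 0), `chance_adjusted`, `f`, `froi`.
#' @export
overlap_metrics <- function(pred, actual_run1, actual_run2) {
  ids <- c(pred$froi, actual_run1$froi, actual_run2$froi)
  fs <- c(pred$f, actual_run1$f, actual_run2$f)
  if (length(unique(ids)) != 1L) abort("fROI ids differ")
  if (length(unique(fs)) != 1L) abort("threshold fractions differ")
  f <- pred$f
  d_pred <- dice(pred, actual_run1)
  d_act <- dice(actual_run1, actual_run2)
  structure(list(
    dice_pred = d_pred,
    dice_actual = d_act,
    explainable_ratio = if (d_act > 0) d_pred / d_act else NA_real_,
    chance_adjusted = (d_pred - f) / (1 - f),
    f = f, froi = pred$froi
  ), class = "overlap_result")
}

#' @export
print.froi <- function(x, ...) {
  cat(sprintf("<froi> %s [%s]: %d vertices (top %d%%)\n",
              x$froi, x$method, length(x$vertices), round(100 * x$f)))
  invisible(x)
}
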