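# Vertex-to-parcel functional connectomes: motion censoring, Fisher-z
# correlation of each search-space vertex with every ipsilateral parcel's
# mean timeseries, and assembly of the model feature matrix.

#' Censor high-motion frames
#'
#' Drops frames whose framewise displacement strictly exceeds the threshold.
#'
#' @param run a `resting_run`, or a numeric FD trace (mm).
#' @param threshold_mm censoring threshold in mm (default 0.5).
#' @return a `frame_mask`: list with `keep` (logical per volume) and
#'   `threshold`. Errors if fewer than 2 frames survive.
#' @export
censor_frames <- function(run, threshold_mm = 0.5) {
  fd <- if (inherits(run, "resting_run")) run$fd else run
  if (!is.numeric(fd) || anyNA(fd)) abort("FD trace must be numeric and complete")
  if (any(fd < 0)) abort("FD must be >= 0")
  if (threshold_mm <= 0) abort("threshold must be positive")
  keep <- fd <= threshold_mm  # drop strictly greater
  if (sum(keep) < 2L) abort("fewer than 2 frames survive censoring")
  structure(list(keep = keep, threshold = threshold_mm), class = "frame_mask")
}

#' Fisher z-transform of a Pearson correlation
#'
#' `z = arctanh(r)`, with inputs within 1e-7 of +/-1 clipped to avoid
#' divergence.
#'
#' @param r numeric vector/matrix of correlations, |r| <= 1.
#' @return transformed values, same shape.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r))) abort("non-finite correlation")
  if (any(abs(r) > 1 + 1e-12)) abort("|r| must be <= 1")
  lim <- 1 - 1e-7
  r <- pmin(pmax(r, -lim), lim)
  atanh(r)
}

#' Compute a per-fROI connectome
#'
#' Correlates each search-space vertex's resting timeseries (censored frames
#' removed) with the mean timeseries of every parcel on the same hemisphere,
#' and Fisher-z transforms the result. A vertex's own parcel is not excluded,
#' so every row has the full P targets. Zero-variance series yield r = 0 with
#' a warning.
#'
#' @param run a `resting_run`.
#' @param mask a [censor_frames()] mask.
#' @param search_vertices 0-based vertex ids of the search space (one
#'   hemisphere).
#' @param surface a `surface_model` supplying parcel labels.
#' @param froi fROI id recorded in the result.
#' @return a `connectome`: list with `z` (S x P matrix, rownames = vertex
#'   ids, colnames = `parcel_001`...), `vertices`, `froi`, `threshold`.
#' @export
compute_connectome <- function(run, mask, search_vertices, surface, froi = NA_character_) {
  if (length(mask$keep) != ncol(run$signal)) abort("mask length != run volumes")
  rows <- match(search_vertices, surface$vertex)
  if (anyNA(rows)) abort("search vertices missing from surface")
  hemi <- unique(surface$hemi[rows])
  if (length(hemi) != 1L) abort("search space spans hemispheres")
  hidx <- which(surface$hemi == hemi)
  P <- max(surface$parcel[hidx])
  keep <- which(mask$keep)
  # parcel mean series on kept frames: indicator crossprod, then scale
  lab <- surface$parcel[hidx]
  M <- run$signal[hidx, keep, drop = FALSE]
  sums <- rowsum(M, lab)                      # P x T (by sorted label)
  cnt <- as.numeric(table(factor(lab, levels = seq_len(P))))
  pm <- sums / cnt                            # parcel means
  V <- t(run$signal[rows, keep, drop = FALSE])  # T x S
  r <- suppressWarnings(stats::cor(V, t(pm)))   # S x P
  if (anyNA(r)) {
    warning("zero-variance series: correlations set to 0", call. = FALSE)
    r[is.na(r)] <- 0
  }
  z <- fisher_z(r)
  dimnames(z) <- list(search_vertices, sprintf("parcel_%03d", seq_len(P)))
  structure(list(z = z, vertices = search_vertices, froi = froi,
                 threshold = mask$threshold),
            class = "connectome")
}

#' Build the model feature matrix for one fROI
#'
#' Columns are the P connectivity features followed by the vertex anatomy:
#' curvature, thickness and x, y, z coordinates. No standardization is
#' applied here (done at model fitting on training rows only).
#'
#' @param connectome a [compute_connectome()] result.
#' @param surface a `surface_model`.
#' @return a `feature_matrix`: list with `X` (S x (P+5), rownames = vertex
#'   ids), `vertices`, `froi`.
#' @export
build_feature_matrix <- function(connectome, surface) {
  rows <- match(connectome$vertices, surface$vertex)
  if (anyNA(rows)) abort("connectome vertex missing anatomy on surface")
  anat <- as.matrix(surface[rows, c("curvature", "thickness", "x", "y", "z")])
  X <- cbind(connectome$z, anat)
  rownames(X) <- connectome$vertices
  structure(list(X = X, vertices = connectome$vertices, froi = connectome$froi),
            class = "feature_matrix")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s: %d vertices x %d parcels (FD > %g mm censored)\n",
              x$froi, nrow(x$z), ncol(x$z), x$threshold))
  invisible(x)
}
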