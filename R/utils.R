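# Internal helpers: seeded RNG scoping and deterministic sub-seed derivation.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generation never disturbs the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Folds the master seed and an arbitrary sequence of labels/counters into a
#' 31-bit integer. Per-subject streams derived this way do not depend on
#' cohort size or generation order.
#'
#' @param master integer master seed.
#' @param ... character or integer stream labels (e.g. "rest", subject index).
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
derive_seed <- function(master, ...) {
  mod <- 2147480009  # largest prime < 2^31 - 1 minus a margin
  h <- as.numeric(master) %% mod
  for (part in list(...)) {
    vals <- if (is.character(part)) utf8ToInt(paste(part, collapse = "/")) else as.numeric(part)
    for (v in vals) h <- (h * 7919 + v + 1) %% mod
  }
  as.integer(h)
}

# stop() with sprintf-style formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0 && x == as.integer(x)
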