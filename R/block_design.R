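# Localizer block design: 2 blocks per condition (18 s each) plus rest blocks
# at the beginning, middle and end of the run.

#' Build a localizer block design
#'
#' Lays out 10 stimulus blocks (two 18-s blocks per condition, order
#' randomized by seed) with rest blocks at the beginning, middle and end.
#' Rest blocks are 18 s each (three 6-s alternating-color segments), so a run
#' with TR = 1 s totals exactly 234 volumes.
#'
#' @param tr repetition time in seconds (default 1).
#' @param block_dur stimulus block duration, seconds (default 18).
#' @param rest_dur rest block duration, seconds (default 18).
#' @param conditions stimulus condition names (default the 5 localizer
#'   categories).
#' @param order optional explicit order of the 10 stimulus blocks (condition
#'   names, each appearing exactly twice); overrides `seed`.
#' @param seed integer seed for the random condition order.
#' @return a `block_design`: list with `blocks` (data.frame: condition,
#'   onset, duration, all in seconds), `tr` and `total_volumes`.
#' @export
make_block_design <- function(tr = 1, block_dur = 18, rest_dur = 18,
                              conditions = localizer_conditions(),
                              order = NULL, seed = 1L) {
  if (!is.numeric(tr) || tr <= 0) abort("tr must be positive")
  if (block_dur <= 0 || rest_dur <= 0) abort("block durations must be positive")
  if (length(conditions) != 5L) abort("exactly 5 stimulus conditions required")
  stim <- rep(conditions, each = 2L)
  if (is.null(order)) {
    order <- with_seed(seed, sample(stim))
  } else {
    if (!identical(sort(order), sort(stim))) {
      abort("order must contain each condition exactly twice")
    }
  }
  seq_conds <- c("rest", order[1:5], "rest", order[6:10], "rest")
  dur <- ifelse(seq_conds == "rest", rest_dur, block_dur)
  onset <- cumsum(c(0, dur[-length(dur)]))
  total_s <- sum(dur)
  total_volumes <- total_s / tr
  if (abs(total_volumes - round(total_volumes)) > 1e-9) {
    abort("run duration (%g s) is not a whole number of TRs", total_s)
  }
  out <- structure(
    list(
      blocks = data.frame(condition = seq_conds, onset = onset,
                          duration = dur, stringsAsFactors = FALSE),
      tr = tr,
      total_volumes = as.integer(round(total_volumes))
    ),
    class = "block_design"
  )
  validate_block_design(out)
  out
}

#' Validate a block design
#'
#' Checks blocks are non-overlapping, sorted by onset, and that durations sum
#' to `total_volumes * tr`.
#'
#' @param x a `block_design`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_block_design <- function(x) {
  if (!inherits(x, "block_design")) abort("not a block_design")
  b <- x$blocks
  if (is.unsorted(b$onset, strictly = TRUE)) abort("block onsets must be strictly increasing")
  ends <- b$onset + b$duration
  if (any(b$onset[-1] < ends[-nrow(b)] - 1e-9)) abort("blocks overlap")
  if (any(b$duration <= 0)) abort("non-positive block duration")
  if (abs(sum(b$duration) - x$total_volumes * x$tr) > 1e-9) {
    abort("durations do not sum to total_volumes * tr")
  }
  invisible(x)
}

#' @export
print.block_design <- function(x, ...) {
  n_stim <- sum(x$blocks$condition != "rest")
  cat(sprintf("<block_design> %d blocks (%d stimulus), TR=%gs, %d volumes\n",
              nrow(x$blocks), n_stim, x$tr, x$total_volumes))
  invisible(x)
}
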