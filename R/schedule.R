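#' Generate a session's block/trial schedule
#'
#' Blocks alternate between the short- and long-fricative conditions starting
#' with `start_condition`; within a block every continuum step appears exactly
#' `reps_per_step` times in seeded random order.
#'
#' @param spec a [continuum_spec()] (only `n_steps` is used).
#' @param start_condition `"short"` or `"long"`; the condition of block 1.
#' @param reps_per_step presentations of each step per block.
#' @param n_blocks total number of blocks; must be even so the two conditions
#'   are balanced.
#' @param seed integer seed for the within-block shuffles.
#' @return a data.frame with columns `block`, `condition`, `step`, `trial`
#'   (trial index within block) and attribute `start_condition`.
#' @export
make_session_schedule <- function(spec, start_condition = c("short", "long"),
                                  reps_per_step = 5, n_blocks = 6, seed) {
  stopifnot(inherits(spec, "continuum_spec"))
  start_condition <- match.arg(start_condition)
  check_scalar(reps_per_step, "reps_per_step", lower = 1)
  check_scalar(n_blocks, "n_blocks", lower = 2)
  if (n_blocks %% 2 != 0)
    stop("'n_blocks' must be even so condition alternation is balanced",
         call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for a reproducible schedule", call. = FALSE)

  conds <- c("short", "long")
  if (start_condition == "long") conds <- rev(conds)
  block_cond <- rep(conds, length.out = n_blocks)
  steps <- rep(seq_len(spec$n_steps), each = reps_per_step)
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      data.frame(block = b, condition = block_cond[b],
                 step = sample(steps), trial = seq_along(steps))
    }))
  })
  attr(out, "start_condition") <- start_condition
  out
}
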