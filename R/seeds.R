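# One global seed fans out to fixed per-stage child seeds so that disabling
# a pipeline stage does not shift the random streams of the stages after it.

stage_offsets <- c(
  cohort  = 101L,
  nirs    = 211L,
  nmr     = 307L,
  echoes  = 401L,
  sensory = 503L,
  fits    = 601L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(stage_offsets))
  as.integer((as.numeric(seed) * 7919 + stage_offsets[[stage]]) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
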