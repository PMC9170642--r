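#' Derive a per-trial seed from a master seed
#'
#' Counter-based seed derivation: every trial's seed is a pure function of
#' `(master_seed, stream, index)`, so individual trials are reproducible
#' without replaying a session and no global RNG state is shared between
#' trials. Stream ids distinguish task contexts (1 = MOA, 2 = MOT,
#' 3 = DSST, 4 = cohort parameter draws).
#'
#' The mixer is a double-round Lehmer-style hash modulo the Mersenne prime
#' 2^31 - 1; all arithmetic stays below 2^53 so it is exact in doubles.
#'
#' @param master_seed integer master seed.
#' @param stream integer stream id (task context).
#' @param index integer counter (e.g. trial index).
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(master_seed, stream, index) {
  m <- 2147483647
  h <- 1
  for (k in c(master_seed, stream, index, master_seed)) {
    h <- ((h + (as.numeric(k) %% m)) * 48271 + 11) %% m
    h <- (h * 16807 + 2531011) %% m
  }
  as.integer(h %% (m - 2) + 1)
}
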