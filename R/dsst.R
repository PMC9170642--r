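#' Generate a DSST form
#'
#' Builds a Digit Symbol Substitution Test form: 93 prompt digits (the
#' published maximum number of fillable boxes), each drawn uniformly from
#' 1-9 with no two consecutive prompts equal (the standard form-building
#' convention), plus a fresh random key mapping the digits 1-9 bijectively
#' to nine abstract symbol ids. Symbols are opaque integers; glyph
#' rendering is presentation-layer only and irrelevant to scoring.
#'
#' @param seed integer seed; identical seeds give identical forms.
#' @param length form length (default 93).
#' @return an object of class `dsst_form`: `prompts` (integer vector),
#'   `key` (integer vector of length 9, `key[d]` = symbol id for digit d).
#' @export
dsst_generate_form <- function(seed, length = 93L) {
  set.seed(as.integer(seed))
  n <- as.integer(length)
  stopifnot(n >= 1L)
  prompts <- integer(n)
  prompts[1] <- sample.int(9L, 1L)
  for (i in seq_len(n - 1L)) {
    # uniform over the 8 digits differing from the previous prompt
    d <- sample.int(8L, 1L)
    prompts[i + 1L] <- if (d >= prompts[i]) d + 1L else d
  }
  key <- sample.int(9L)
  structure(list(prompts = prompts, key = key), class = "dsst_form")
}

#' Score a DSST response sheet
#'
#' The score is the count of positions where the written symbol equals the
#' key's symbol for that position's prompt digit. Unattempted boxes score
#' nothing.
#'
#' @param form a [dsst_generate_form()] form.
#' @param response integer vector of written symbol ids, length at most
#'   the form length.
#' @return integer `n_correct` in `[0, length(form$prompts)]`.
#' @export
dsst_score <- function(form, response) {
  stopifnot(inherits(form, "dsst_form"))
  n <- length(response)
  if (n > length(form$prompts)) stop("response longer than the form")
  if (n == 0L) return(0L)
  sum(response == form$key[form$prompts[seq_len(n)]])
}

#' Simulate a parametric DSST responder
#'
#' A synthetic participant working at `rate` symbols per second for
#' `duration` seconds attempts `floor(rate * duration)` boxes (capped at
#' the form length); each attempt writes the correct symbol with
#' probability `1 - error_prob`, otherwise a uniformly chosen wrong
#' symbol. Expected score is
#' `min(floor(rate * duration), 93) * (1 - error_prob)`.
#'
#' @param form a [dsst_generate_form()] form.
#' @param rate symbols per second, > 0.
#' @param error_prob per-symbol substitution-error probability in `[0, 1]`.
#' @param duration time budget in seconds (default 60, the published
#'   limit).
#' @param seed integer seed.
#' @return an object of class `dsst_response`: `entries` (symbol ids),
#'   `n_attempted`.
#' @export
dsst_simulate_responder <- function(form, rate, error_prob, duration = 60,
                                    seed = 1L) {
  stopifnot(inherits(form, "dsst_form"))
  if (!(rate > 0)) stop("rate must be > 0")
  if (error_prob < 0 || error_prob > 1) stop("error_prob must be in [0, 1]")
  if (!(duration > 0)) stop("duration must be > 0")
  set.seed(as.integer(seed))
  n <- min(floor(rate * duration), length(form$prompts))
  entries <- integer(n)
  for (i in seq_len(n)) {
    correct <- form$key[form$prompts[i]]
    if (error_prob > 0 && runif(1) < error_prob) {
      wrong <- sample.int(8L, 1L)
      entries[i] <- if (wrong >= correct) wrong + 1L else wrong
    } else {
      entries[i] <- correct
    }
  }
  structure(list(entries = entries, n_attempted = n),
            class = "dsst_response")
}
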