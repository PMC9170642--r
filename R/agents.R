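#' Synthetic MOA controller specification
#'
#' Parametric stand-ins for the human mouse controller:
#' * `stationary` — parks at the trial's starting position (lower bound on
#'   skill).
#' * `random_walk` — a uniformly random heading each tick at the capped
#'   pointer speed.
#' * `greedy_avoid` — the canonical "skilled" agent: computes a
#'   time-to-collision (TTC) for every live threat and steps directly away
#'   from the most imminent one (the task's motion is fully predictable,
#'   so TTC is well defined).
#'
#' Human-like imperfection is parameterized by `reaction_latency` (the
#' agent perceives the world as it was `latency` seconds ago, rounded to
#' whole ticks), `max_pointer_speed` (px/s cap on hand movement) and
#' `motor_noise_sd` (isotropic Gaussian jitter, px per tick, added to each
#' proposed displacement).
#'
#' @param kind one of `"stationary"`, `"random_walk"`, `"greedy_avoid"`.
#' @param reaction_latency perceptual delay in s, >= 0.
#' @param max_pointer_speed pointer speed cap in px/s, > 0 (ignored by
#'   `stationary`).
#' @param motor_noise_sd motor noise SD in px, >= 0.
#' @return an object of class `controller_spec`.
#' @export
controller_spec <- function(kind = c("greedy_avoid", "stationary", "random_walk"),
                            reaction_latency = 0,
                            max_pointer_speed = 600,
                            motor_noise_sd = 0) {
  kind <- match.arg(kind)
  if (reaction_latency < 0) stop("reaction_latency must be >= 0")
  if (!(max_pointer_speed > 0)) stop("max_pointer_speed must be > 0")
  if (motor_noise_sd < 0) stop("motor_noise_sd must be >= 0")
  structure(list(kind = kind, reaction_latency = reaction_latency,
                 max_pointer_speed = max_pointer_speed,
                 motor_noise_sd = motor_noise_sd),
            class = "controller_spec")
}

controller_kind_code <- function(kind) {
  match(kind, c("stationary", "random_walk", "greedy_avoid"))
}

#' Synthetic MOT observer specification
#'
#' A capacity-limited tracking model: the observer tracks `capacity_k`
#' targets perfectly through the movement phase and fills the rest of the
#' selection by guessing uniformly among the squares it was not tracking.
#' Expected correct selections per trial are
#' `k + (n_targets - k)^2 / (n_squares - k)` (hypergeometric fill).
#'
#' @param capacity_k number of targets tracked perfectly, 0..n_targets.
#' @return an object of class `observer_spec`.
#' @export
observer_spec <- function(capacity_k) {
  if (capacity_k < 0 || capacity_k != floor(capacity_k)) {
    stop("capacity_k must be a non-negative integer")
  }
  structure(list(capacity_k = as.integer(capacity_k)),
            class = "observer_spec")
}

# sample() without its scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

#' Greedy time-to-collision avoidance policy
#'
#' For each live threat (filled hazards, plus unfilled hazards that will
#' activate within the agent's reaction latency) computes the
#' time-to-collision from relative position and velocity: the closing
#' speed is the projection of the relative velocity onto the center line;
#' receding hazards have infinite TTC. The pointer steps directly away
#' from the minimum-TTC threat, with magnitude `max_pointer_speed * tick`,
#' perturbed by motor noise. With no approaching threat the pointer holds
#' position (and no noise is drawn, so RNG consumption is
#' state-dependent but deterministic).
#'
#' @param state an `moa_state` (the snapshot the agent perceives; pass a
#'   delayed state to model latency).
#' @param spec a [controller_spec()] of kind `greedy_avoid`.
#' @param cfg the [moa_config()].
#' @param base the current pointer position the displacement is applied
#'   to; defaults to the snapshot's user position.
#' @return a length-2 pointer proposal in px.
#' @export
greedy_avoid_pointer <- function(state, spec, cfg, base = state$user) {
  if (state$terminated) stop("state is terminated")
  n <- nrow(state$pos)
  if (n == 0) return(base)
  rsum <- cfg$disc_diameter
  threat <- state$filled |
    (state$activation - state$clock < spec$reaction_latency)
  if (!any(threat)) return(base)
  px <- state$pos[, 1] - state$user[1]
  py <- state$pos[, 2] - state$user[2]
  dist <- sqrt(px^2 + py^2)
  gap <- dist - rsum
  closing <- ifelse(dist > 0,
                    -(px * state$vel[, 1] + py * state$vel[, 2]) / dist, 0)
  ttc <- ifelse(gap <= 0, 0, ifelse(closing > 0, gap / closing, Inf))
  ttc[!threat] <- Inf
  if (all(is.infinite(ttc))) return(base)
  i <- which.min(ttc)
  dir <- if (dist[i] > 0) c(-px[i], -py[i]) / dist[i] else c(1, 0)
  prop <- base + dir * spec$max_pointer_speed * cfg$tick
  if (spec$motor_noise_sd > 0) {
    prop <- prop + c(rnorm(1, 0, spec$motor_noise_sd),
                     rnorm(1, 0, spec$motor_noise_sd))
  }
  prop
}

# Per-tick pointer callback used by the pure-R trial loop. `snap` is the
# latency-delayed state (NULL before the agent's first percept arrives).
make_controller <- function(spec, cfg) {
  switch(spec$kind,
    stationary = function(state, snap, cfg2) state$user,
    random_walk = function(state, snap, cfg2) {
      ang <- runif(1, 0, 2 * pi)
      prop <- state$user +
        c(cos(ang), sin(ang)) * spec$max_pointer_speed * cfg2$tick
      if (spec$motor_noise_sd > 0) {
        prop <- prop + c(rnorm(1, 0, spec$motor_noise_sd),
                         rnorm(1, 0, spec$motor_noise_sd))
      }
      prop
    },
    greedy_avoid = function(state, snap, cfg2) {
      if (is.null(snap)) return(state$user)
      greedy_avoid_pointer(snap, spec, cfg2, base = state$user)
    }
  )
}

#' Capacity-limited MOT target selection
#'
#' Selects `min(capacity_k, n_targets)` true targets (uniformly among the
#' targets) and fills the remaining picks uniformly at random from the
#' squares the observer was not tracking, for a total of `n_targets`
#' selections.
#'
#' @param state a `mot_state` in phase `select`.
#' @param spec an [observer_spec()].
#' @param cfg the [mot_config()].
#' @return integer vector of `n_targets` distinct square ids.
#' @export
capacity_k_select <- function(state, spec, cfg) {
  if (state$phase != "select") stop("trial is not in the select phase")
  k <- min(spec$capacity_k, cfg$n_targets)
  tracked <- resample(state$target_indices, k)
  remaining <- setdiff(seq_len(cfg$n_squares), tracked)
  fill <- resample(remaining, cfg$n_targets - k)
  sort(c(tracked, fill))
}
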