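#' MOA task configuration
#'
#' Builds the configuration of the Multiple Object Avoidance task with the
#' published task parameters as defaults: an 800 x 800 px window, 40-px
#' circles, three initial hazards plus one more every 10 s, a 1-s unfilled
#' grace period for every new hazard, per-hazard speeds drawn uniformly
#' from 0-680 px/s, and an 85 Hz tick. A session is 2 practice + 8 recorded
#' trials; the score is the mean survival time of the recorded trials.
#'
#' @param window a [playfield()] (default 800 x 800 px).
#' @param disc_diameter disc diameter in px (default 40).
#' @param n_initial_hazards hazards present at trial start (default 3).
#' @param spawn_interval seconds between new hazards (default 10).
#' @param grace_duration unfilled (non-lethal) time for a new hazard in s
#'   (default 1).
#' @param speed_min,speed_max per-hazard speed range in px/s (default 0,
#'   680); each hazard keeps its drawn speed for the whole trial.
#' @param tick simulation step in s (default 1/85, the display refresh).
#' @param n_practice_trials,n_recorded_trials session composition
#'   (defaults 2 and 8).
#' @param max_trial_duration censoring cap in s (default 300); trials that
#'   reach it end without a collision and are flagged censored.
#' @param master_seed integer session seed.
#' @return an object of class `moa_config`.
#' @export
moa_config <- function(window = playfield(800, 800),
                       disc_diameter = 40,
                       n_initial_hazards = 3,
                       spawn_interval = 10,
                       grace_duration = 1,
                       speed_min = 0,
                       speed_max = 680,
                       tick = 1 / 85,
                       n_practice_trials = 2,
                       n_recorded_trials = 8,
                       max_trial_duration = 300,
                       master_seed = 1L) {
  cfg <- structure(list(
    window = window, disc_diameter = disc_diameter,
    n_initial_hazards = n_initial_hazards, spawn_interval = spawn_interval,
    grace_duration = grace_duration, speed_min = speed_min,
    speed_max = speed_max, tick = tick,
    n_practice_trials = n_practice_trials,
    n_recorded_trials = n_recorded_trials,
    max_trial_duration = max_trial_duration,
    master_seed = as.integer(master_seed)
  ), class = "moa_config")
  validate_moa_config(cfg)
}

validate_moa_config <- function(cfg) {
  stopifnot(inherits(cfg$window, "playfield"))
  if (!(cfg$disc_diameter > 0)) stop("disc_diameter must be > 0")
  if (cfg$speed_min > cfg$speed_max) stop("speed_min must be <= speed_max")
  if (cfg$speed_min < 0) stop("speed_min must be >= 0")
  if (!(cfg$spawn_interval > 0)) stop("spawn_interval must be > 0")
  if (cfg$grace_duration < 0) stop("grace_duration must be >= 0")
  if (!(cfg$tick > 0)) stop("tick must be > 0")
  if (!(cfg$max_trial_duration > 0)) stop("max_trial_duration must be > 0")
  counts <- c(cfg$n_initial_hazards, cfg$n_practice_trials, cfg$n_recorded_trials)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("hazard/trial counts must be non-negative integers")
  }
  cfg
}

# One rejection-sampled hazard placement. Consumes RNG draws in the order
# (x, y)* until accepted, then angle (deg), then speed. The compiled trial
# loop consumes the identical sequence, which is what makes the R and C++
# paths bit-identical under a shared seed.
place_hazard <- function(cfg, user, pos, max_attempts = 1000L) {
  r <- cfg$disc_diameter / 2
  w <- cfg$window$width
  h <- cfg$window$height
  if (w < 2 * r || h < 2 * r) stop("window too small for disc placement")
  for (i in seq_len(max_attempts)) {
    x <- runif(1, r, w - r)
    y <- runif(1, r, h - r)
    d_user <- sqrt((x - user[1])^2 + (y - user[2])^2)
    ok <- d_user >= 2 * r
    if (ok && nrow(pos) > 0) {
      dd <- sqrt((pos[, 1] - x)^2 + (pos[, 2] - y)^2)
      ok <- all(dd >= 2 * r)
    }
    if (ok) {
      ang <- runif(1, 0, 360) * pi / 180
      speed <- runif(1, cfg$speed_min, cfg$speed_max)
      return(c(x, y, speed * cos(ang), speed * sin(ang), speed))
    }
  }
  stop("hazard placement failed after ", max_attempts,
       " attempts: window too small for the configured disc count")
}

#' Initialize an MOA trial
#'
#' Places the user disc at the window center and `n_initial_hazards`
#' hazards uniformly at random (mutually non-overlapping, none overlapping
#' the user), each with a uniform random direction and a speed drawn
#' uniformly from `[speed_min, speed_max]`. All initial hazards start
#' unfilled and become lethal at `grace_duration`.
#'
#' @param cfg a [moa_config()].
#' @param trial_seed integer seed; identical seeds give field-for-field
#'   identical states.
#' @return an object of class `moa_state`.
#' @export
moa_init_trial <- function(cfg, trial_seed) {
  validate_moa_config(cfg)
  set.seed(as.integer(trial_seed))
  n <- cfg$n_initial_hazards
  user <- c(cfg$window$width / 2, cfg$window$height / 2)
  pos <- matrix(numeric(0), 0, 2)
  vel <- matrix(numeric(0), 0, 2)
  spawn_speed <- numeric(0)
  for (i in seq_len(n)) {
    hz <- place_hazard(cfg, user, pos)
    pos <- rbind(pos, hz[1:2])
    vel <- rbind(vel, hz[3:4])
    spawn_speed <- c(spawn_speed, hz[5])
  }
  structure(list(
    clock = 0, ticks = 0L, user = user,
    pos = pos, vel = vel,
    activation = rep(cfg$grace_duration, n),
    filled = rep(cfg$grace_duration <= 0, n),
    spawn_speed = spawn_speed,
    next_spawn_time = cfg$spawn_interval,
    terminated = FALSE, censored = FALSE, survival_time = NA_real_,
    wall_bounces = 0L, pair_bounces = 0L
  ), class = "moa_state")
}

#' Advance an MOA trial by one tick
#'
#' One fixed-timestep update: the user disc teleports to the (clamped)
#' pointer sample; hazards advance with wall reflection and hazard-hazard
#' collision resolution (sub-stepped if a hazard could move more than half
#' a radius per step, never at defaults); hazards past their activation
#' time fill in; a new hazard spawns at every multiple of
#' `spawn_interval`; finally, overlap between any *filled* hazard and the
#' user terminates the trial with `survival_time = clock`. Reaching
#' `max_trial_duration` terminates the trial as censored. Unfilled hazards
#' move and bounce normally; only the user collision is disabled for them.
#'
#' @param state an unterminated `moa_state`.
#' @param pointer numeric length-2 pointer sample in px.
#' @param cfg the [moa_config()] the trial was initialized with.
#' @return the updated `moa_state`.
#' @export
moa_step <- function(state, pointer, cfg) {
  if (state$terminated) stop("cannot step a terminated trial")
  r <- cfg$disc_diameter / 2
  w <- cfg$window$width
  h <- cfg$window$height
  eps <- 1e-9

  state$user <- c(min(max(pointer[1], r), w - r),
                  min(max(pointer[2], r), h - r))

  n <- nrow(state$pos)
  if (n > 0) {
    # NOTE: all physics arithmetic here is written as plain elementwise /
    # scalar double operations (no sum()/rowSums(), which accumulate in
    # extended precision) so the compiled trial loop can reproduce this
    # path bit-for-bit.
    vmax <- max(sqrt(state$vel[, 1]^2 + state$vel[, 2]^2))
    nsub <- max(1L, as.integer(ceiling(vmax * cfg$tick / (r / 2))))
    sdt <- cfg$tick / nsub
    for (s in seq_len(nsub)) {
      state$pos <- state$pos + state$vel * sdt
      # wall reflection, mirrored clamp; speed preserved exactly
      for (ax in 1:2) {
        lim <- if (ax == 1) w else h
        lo <- state$pos[, ax] <= r
        hi <- state$pos[, ax] >= lim - r
        if (any(lo)) {
          state$pos[lo, ax] <- 2 * r - state$pos[lo, ax]
          state$vel[lo, ax] <- abs(state$vel[lo, ax])
          state$wall_bounces <- state$wall_bounces + sum(lo)
        }
        if (any(hi)) {
          state$pos[hi, ax] <- 2 * (lim - r) - state$pos[hi, ax]
          state$vel[hi, ax] <- -abs(state$vel[hi, ax])
          state$wall_bounces <- state$wall_bounces + sum(hi)
        }
      }
      if (n > 1) {
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
          dx <- state$pos[j, 1] - state$pos[i, 1]
          dy <- state$pos[j, 2] - state$pos[i, 2]
          dist <- sqrt(dx * dx + dy * dy)
          if (dist < 2 * r) {
            nx <- if (dist > 0) dx / dist else 1
            ny <- if (dist > 0) dy / dist else 0
            closing <- (state$vel[i, 1] - state$vel[j, 1]) * nx +
                       (state$vel[i, 2] - state$vel[j, 2]) * ny
            if (dist == 0 || closing > 0) {
              if (dist > 0) {
                di <- state$vel[i, 1] * nx + state$vel[i, 2] * ny
                dj <- state$vel[j, 1] * nx + state$vel[j, 2] * ny
                state$vel[i, 1] <- state$vel[i, 1] - 2 * di * nx
                state$vel[i, 2] <- state$vel[i, 2] - 2 * di * ny
                state$vel[j, 1] <- state$vel[j, 1] - 2 * dj * nx
                state$vel[j, 2] <- state$vel[j, 2] - 2 * dj * ny
                state$pair_bounces <- state$pair_bounces + 1L
              }
              push <- (2 * r - dist) / 2
              state$pos[i, 1] <- state$pos[i, 1] - nx * push
              state$pos[i, 2] <- state$pos[i, 2] - ny * push
              state$pos[j, 1] <- state$pos[j, 1] + nx * push
              state$pos[j, 2] <- state$pos[j, 2] + ny * push
            }
          }
        }
      }
    }
  }

  state$ticks <- state$ticks + 1L
  state$clock <- state$ticks * cfg$tick
  state$filled <- state$clock >= state$activation - eps

  while (state$clock >= state$next_spawn_time - eps) {
    hz <- place_hazard(cfg, state$user, state$pos)
    state$pos <- rbind(state$pos, hz[1:2])
    state$vel <- rbind(state$vel, hz[3:4])
    state$spawn_speed <- c(state$spawn_speed, hz[5])
    state$activation <- c(state$activation, state$clock + cfg$grace_duration)
    state$filled <- c(state$filled, cfg$grace_duration <= 0)
    state$next_spawn_time <- state$next_spawn_time + cfg$spawn_interval
  }

  n <- nrow(state$pos)
  if (n > 0 && any(state$filled)) {
    du <- sqrt((state$pos[, 1] - state$user[1])^2 +
               (state$pos[, 2] - state$user[2])^2)
    if (any(state$filled & du < 2 * r)) {
      state$terminated <- TRUE
      state$survival_time <- state$clock
      return(state)
    }
  }
  if (state$clock >= cfg$max_trial_duration - eps) {
    state$terminated <- TRUE
    state$censored <- TRUE
    state$survival_time <- cfg$max_trial_duration
  }
  state
}

#' Run one MOA trial to termination
#'
#' Loops [moa_step()] with pointer samples supplied by a controller until
#' the trial terminates, and returns the trial record. `controller` is
#' either a [controller_spec()] (built-in synthetic agents) or an R
#' function `function(state, cfg) -> c(x, y)` for custom policies.
#'
#' For built-in controller specs the whole trial (including placement and
#' controller noise) runs in compiled code; the pure-R loop is the
#' reference implementation and produces bit-identical records for the
#' same seed (`use_compiled = FALSE`).
#'
#' @param cfg a [moa_config()].
#' @param controller a [controller_spec()] or an R function.
#' @param trial_seed integer seed for this trial.
#' @param trial_index,practice metadata copied into the record.
#' @param use_compiled use the C++ fast path for built-in controllers.
#' @return a one-row `data.frame`: `trial_index`, `practice`, `seed`,
#'   `survival_time`, `censored`.
#' @export
moa_run_trial <- function(cfg, controller, trial_seed,
                          trial_index = 1L, practice = FALSE,
                          use_compiled = TRUE) {
  validate_moa_config(cfg)
  if (inherits(controller, "controller_spec") && use_compiled) {
    set.seed(as.integer(trial_seed))
    res <- moa_trial_cpp(
      cfg$window$width, cfg$window$height, cfg$disc_diameter / 2,
      as.integer(cfg$n_initial_hazards), cfg$spawn_interval,
      cfg$grace_duration, cfg$speed_min, cfg$speed_max, cfg$tick,
      cfg$max_trial_duration,
      controller_kind_code(controller$kind),
      controller$reaction_latency, controller$max_pointer_speed,
      controller$motor_noise_sd)
    return(data.frame(trial_index = as.integer(trial_index),
                      practice = practice, seed = as.integer(trial_seed),
                      survival_time = res$survival_time,
                      censored = res$censored))
  }
  state <- moa_init_trial(cfg, trial_seed)
  ctrl_fun <- if (is.function(controller)) {
    function(state, snap, cfg) controller(state, cfg)
  } else {
    make_controller(controller, cfg)
  }
  lag <- if (inherits(controller, "controller_spec")) {
    as.integer(round(controller$reaction_latency / cfg$tick))
  } else 0L
  snaps <- vector("list", lag + 1L)
  snaps[[1L]] <- state
  while (!state$terminated) {
    snap <- if (state$ticks >= lag) {
      snaps[[((state$ticks - lag) %% (lag + 1L)) + 1L]]
    } else NULL
    pointer <- ctrl_fun(state, snap, cfg)
    state <- moa_step(state, pointer, cfg)
    snaps[[(state$ticks %% (lag + 1L)) + 1L]] <- state
  }
  data.frame(trial_index = as.integer(trial_index), practice = practice,
             seed = as.integer(trial_seed),
             survival_time = state$survival_time, censored = state$censored)
}

#' Run a full MOA session
#'
#' Runs `n_practice_trials + n_recorded_trials` trials with per-trial
#' seeds derived from `master_seed` (see [derive_seed()]); the session
#' score is the mean survival time over the recorded (non-practice)
#' trials only.
#'
#' @param cfg a [moa_config()].
#' @param controller a [controller_spec()] or R function controller.
#' @param use_compiled use the C++ fast path for built-in controllers.
#' @return an object of class `moa_session`: list with `records` (one row
#'   per trial) and `moa_score` (seconds).
#' @export
moa_run_session <- function(cfg, controller, use_compiled = TRUE) {
  validate_moa_config(cfg)
  n_total <- cfg$n_practice_trials + cfg$n_recorded_trials
  records <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    records[[i]] <- moa_run_trial(
      cfg, controller, derive_seed(cfg$master_seed, 1L, i),
      trial_index = i, practice = i <= cfg$n_practice_trials,
      use_compiled = use_compiled)
  }
  records <- do.call(rbind, records)
  structure(list(records = records,
                 moa_score = mean(records$survival_time[!records$practice])),
            class = "moa_session")
}

#' @export
print.moa_session <- function(x, ...) {
  n_rec <- sum(!x$records$practice)
  cat("MOA session:", nrow(x$records), "trials (", n_rec, "recorded )\n")
  cat("  moa_score (mean recorded survival):",
      format(x$moa_score, digits = 4), "s\n")
  invisible(x)
}
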