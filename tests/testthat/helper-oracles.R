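# Independent oracles used across the suite. Each is deliberately written
# against a different route than the implementation it checks.

# Exact expected number of correct selections for a capacity-k observer:
# k tracked targets plus a uniformly random fill of (n_t - k) picks from
# the (n_sq - k) untracked squares, of which (n_t - k) are targets.
# Computed by exhaustive enumeration of all fill subsets via combn().
enum_capacity_expected_correct <- function(k, n_sq = 10, n_t = 5) {
  if (k >= n_t) return(n_t)
  remaining <- n_sq - k          # untracked squares
  rem_targets <- n_t - k         # targets among them
  fills <- utils::combn(remaining, n_t - k)
  # label untracked squares 1..remaining, targets are 1..rem_targets
  hits <- apply(fills, 2, function(f) sum(f <= rem_targets))
  k + mean(hits)
}

# Textbook normal-equations OLS: b = (X'X)^-1 X'y, with classical SEs.
ols_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  XtX <- t(X1) %*% X1
  b <- solve(XtX, t(X1) %*% y)
  res <- y - X1 %*% b
  n <- nrow(X1)
  p <- ncol(X1)
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * s2)
  list(b = drop(b), se = se, t = drop(b) / se, rss = sum(res^2))
}

# Numerical model of per-disc specular reflection: integrate each disc
# separately against the contact plane (held fixed at the instant of
# contact) with a stiff linear penalty spring, and return its outgoing
# velocity direction. An equal-mass pair-spring would instead exchange
# normal components, which is NOT the collision model in use.
penalty_reflect_oracle <- function(vel, normal, speed, dt = 1e-6, k_spring = 1e6) {
  # position along the normal axis; start just touching (penetration 0)
  x <- 0
  v <- vel
  repeat {
    pen <- -x              # penetration depth beyond the plane
    if (pen < 0 && sum(v * normal) > 0) break
    a <- if (pen > 0) k_spring * pen * normal else c(0, 0)
    v <- v + a * dt
    x <- x + sum(v * normal) * dt
  }
  v / sqrt(sum(v^2)) * speed
}

angle_between <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# Build an moa_state by hand (bypasses random placement) for scenario
# tests: one or more hazards with given positions/velocities.
make_moa_state <- function(user, pos, vel, activation, clock = 0,
                           next_spawn_time = 1e9) {
  n <- nrow(pos)
  structure(list(
    clock = clock, ticks = as.integer(round(clock * 85)), user = user,
    pos = pos, vel = vel, activation = activation,
    filled = clock >= activation - 1e-9,
    spawn_speed = sqrt(vel[, 1]^2 + vel[, 2]^2),
    next_spawn_time = next_spawn_time,
    terminated = FALSE, censored = FALSE, survival_time = NA_real_,
    wall_bounces = 0L, pair_bounces = 0L
  ), class = "moa_state")
}

make_mot_state <- function(pos, direction, speed, targets,
                           phase = "moving", clock = 0) {
  structure(list(pos = pos, direction = direction, speed = speed,
                 target_indices = targets, phase = phase, clock = clock),
            class = "mot_state")
}
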