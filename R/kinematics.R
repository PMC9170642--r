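#' Construct a moving disc
#'
#' A disc is the basic kinematic entity shared by both task engines: a
#' circular body with a continuous center position (pixels, origin at the
#' top-left of the screen, x rightwards, y downwards), a velocity in px/s
#' and a radius in px.
#'
#' @param x,y center coordinates in px.
#' @param vx,vy velocity components in px/s.
#' @param radius disc radius in px, must be positive. Default 20 (the tasks
#'   use 40-px-diameter circles).
#' @return an object of class `moving_disc`: a list with numeric fields
#'   `center`, `velocity` (length-2) and `radius`.
#' @examples
#' d <- disc(100, 100, vx = 50, vy = 0)
#' disc_advance(d, 0.5)$center
#' @export
disc <- function(x, y, vx = 0, vy = 0, radius = 20) {
  stopifnot(is.finite(x), is.finite(y), is.finite(vx), is.finite(vy),
            is.finite(radius), radius > 0)
  structure(list(center = c(x, y), velocity = c(vx, vy), radius = radius),
            class = "moving_disc")
}

#' Construct playfield bounds
#'
#' @param width,height window size in px, both positive.
#' @return an object of class `playfield` with fields `width`, `height`.
#' @export
playfield <- function(width, height) {
  stopifnot(is.finite(width), is.finite(height), width > 0, height > 0)
  structure(list(width = width, height = height), class = "playfield")
}

#' Advance a disc along its straight-line trajectory
#'
#' Pure linear motion: `center' = center + velocity * dt`. Velocity is
#' unchanged; between wall/disc contacts motion is piecewise linear, so
#' explicit Euler integration is exact.
#'
#' @param d a [disc()].
#' @param dt time step in seconds, strictly positive.
#' @return the advanced `moving_disc`.
#' @export
disc_advance <- function(d, dt) {
  stopifnot(inherits(d, "moving_disc"), is.finite(dt), dt > 0)
  d$center <- d$center + d$velocity * dt
  d
}

#' Reflect a disc off the playfield walls
#'
#' If the disc touches or crosses an edge, the velocity component normal to
#' that edge is negated and the center is clamped so the disc lies fully
#' inside `[radius, width - radius] x [radius, height - radius]`. Speed is
#' preserved exactly (components are only negated, never rescaled). A disc
#' strictly interior to the bounds is returned unchanged.
#'
#' @param d a [disc()].
#' @param bounds a [playfield()].
#' @return the reflected `moving_disc`.
#' @export
disc_reflect_wall <- function(d, bounds) {
  stopifnot(inherits(d, "moving_disc"), inherits(bounds, "playfield"))
  r <- d$radius
  lim <- c(bounds$width, bounds$height)
  for (ax in 1:2) {
    if (d$center[ax] <= r) {
      d$center[ax] <- r + (r - d$center[ax])
      d$velocity[ax] <- abs(d$velocity[ax])
      if (d$center[ax] > lim[ax] - r) d$center[ax] <- r    # degenerate: tiny box
    } else if (d$center[ax] >= lim[ax] - r) {
      d$center[ax] <- (lim[ax] - r) - (d$center[ax] - (lim[ax] - r))
      d$velocity[ax] <- -abs(d$velocity[ax])
      if (d$center[ax] < r) d$center[ax] <- lim[ax] - r
    }
  }
  d
}

#' Collision predicate for two discs
#'
#' Strict overlap test: `TRUE` iff the center distance is strictly less
#' than the sum of the radii. Exact tangency is deliberately *not* a
#' collision (a measure-zero configuration, resolved deterministically).
#'
#' @param a,b [disc()] objects.
#' @return logical scalar.
#' @export
discs_overlap <- function(a, b) {
  dx <- a$center - b$center
  sqrt(sum(dx * dx)) < (a$radius + b$radius)
}

#' Resolve a disc-disc collision by per-disc specular reflection
#'
#' Both discs' velocities are specularly reflected about the collision
#' normal (the center-to-center unit vector); each disc keeps its own speed
#' exactly, so a disc's randomized trial speed is a per-disc invariant
#' across any number of bounces. Centers are pushed apart symmetrically
#' along the normal to exact tangency.
#'
#' The operation is a no-op unless the discs overlap *and* are approaching
#' (relative velocity has a closing component along the center line); this
#' prevents re-colliding a pair that is already separating.
#'
#' Coincident centers (normal undefined) fall back to separating along +x.
#'
#' @param a,b [disc()] objects.
#' @return a list `list(a = , b = )` with the updated discs.
#' @export
disc_collide_pair <- function(a, b) {
  dvec <- b$center - a$center
  dist <- sqrt(sum(dvec * dvec))
  rsum <- a$radius + b$radius
  if (dist >= rsum) return(list(a = a, b = b))
  n <- if (dist > 0) dvec / dist else c(1, 0)
  # closing speed along the center line (positive when approaching)
  closing <- sum((a$velocity - b$velocity) * n)
  if (dist > 0 && closing <= 0) return(list(a = a, b = b))
  if (dist > 0) {
    a$velocity <- a$velocity - 2 * sum(a$velocity * n) * n
    b$velocity <- b$velocity - 2 * sum(b$velocity * n) * n
  }
  push <- (rsum - dist) / 2
  a$center <- a$center - n * push
  b$center <- b$center + n * push
  list(a = a, b = b)
}
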