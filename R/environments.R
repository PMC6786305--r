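#' Initial reaching-environment state
#'
#' @param env a [reaching_config()].
#' @param pos optional starting ball position; defaults to a fixed
#'   off-center point.
#' @return A list with the ball position (meters).
#' @export
reaching_state <- function(env = reaching_config(), pos = NULL) {
  lim <- env$plane_half - env$ball_radius
  if (is.null(pos)) pos <- c(0.6, 0.6) * lim
  stopifnot(length(pos) == 2, all(abs(pos) <= env$plane_half))
  list(pos = as.numeric(pos))
}

#' One kinematic step of the reaching environment
#'
#' The ball follows the commanded instantaneous velocity; its center is
#' clamped so the ball stays inside the walls. When the center enters the
#' target disc at the origin the ball is reset to a uniformly random
#' position (two draws from the global RNG) — the reset is not signalled
#' to the network and does not end an episode.
#'
#' @param state a [reaching_state()].
#' @param v_cmd commanded velocity \code{c(xdot, ydot)}, m/s.
#' @param dt step length, seconds.
#' @param env a [reaching_config()].
#' @return A list: \code{state} (advanced) and \code{reset} (logical).
#' @export
reaching_step <- function(state, v_cmd, dt, env = reaching_config()) {
  stopifnot(dt > 0, length(v_cmd) == 2)
  lim <- env$plane_half - env$ball_radius
  p <- state$pos + v_cmd * dt
  p <- pmin(pmax(p, -lim), lim)
  reset <- sqrt(sum(p * p)) <= env$target_radius
  if (reset)
    p <- stats::runif(2, -lim, lim)
  state$pos <- p
  list(state = state, reset = reset)
}

#' Reaching-task reward
#'
#' \eqn{r = c\, r_v\,(r_\beta + 1)^p} with
#' \eqn{r_\beta = 1 - \beta_{err}/\beta_{lim}} if the angle
#' \eqn{\beta_{err}} between the commanded direction and the straight line
#' to the goal is below \eqn{\beta_{lim}} (else 0), and \eqn{r_v = |v|}
#' if the speed exceeds \eqn{v_{lim}} (else 0, making the whole reward 0).
#' Always non-negative.
#'
#' @param v_cmd commanded velocity \code{c(xdot, ydot)}, m/s.
#' @param goal_dir direction from the ball toward the goal (need not be
#'   normalized).
#' @param rw a [reward_config()].
#' @return A single non-negative reward value.
#' @export
reaching_reward <- function(v_cmd, goal_dir, rw = reward_config()) {
  speed <- sqrt(sum(v_cmd * v_cmd))
  if (speed <= rw$v_lim) return(0)
  gn <- sqrt(sum(goal_dir * goal_dir))
  if (gn == 0) return(0)
  cosb <- sum(v_cmd * goal_dir) / (speed * gn)
  cosb <- min(max(cosb, -1), 1)
  beta_err <- acos(cosb)
  r_beta <- if (beta_err < rw$beta_lim) 1 - beta_err / rw$beta_lim else 0
  rw$coef * speed * (r_beta + 1)^rw$exponent
}

#' Render the top-down reaching view
#'
#' A dark ball disc on a light plane, sampled at pixel centers on a square
#' grid covering the whole plane.
#'
#' @param state a [reaching_state()].
#' @param env a [reaching_config()].
#' @return An \code{n_px x n_px} intensity matrix in \code{[0,1]}; row 1 is
#'   the top sensor row (largest y on the plane).
#' @export
render_reaching <- function(state, env = reaching_config()) {
  n <- env$n_px
  px <- -env$plane_half + (seq_len(n) - 0.5) * (2 * env$plane_half / n)
  py <- rev(px)                         # top row = largest y
  dx2 <- outer(py, px, function(yy, xx)
    (xx - state$pos[1])^2 + (yy - state$pos[2])^2)
  ifelse(dx2 <= env$ball_radius^2, 0, 1)
}

#' Closed stadium-circuit centerline
#'
#' The centerline of the right lane: two straights of length
#' \code{env$straight} joined by two semicircular arcs of radius
#' \code{env$radius}, discretized into \code{env$n_track} points at equal
#' arc-length spacing. The curve is closed and smooth and supports
#' nearest-point queries by exhaustive (or windowed) search.
#'
#' @param env a [lane_config()].
#' @return A list with \code{x}, \code{y}, \code{tx}, \code{ty} (unit
#'   tangents), \code{s} (arc length) and \code{length} (total length).
#' @export
make_track <- function(env = lane_config()) {
  L <- env$straight; R <- env$radius
  total <- 2 * L + 2 * pi * R
  s <- (seq_len(env$n_track) - 1) / env$n_track * total
  x <- numeric(length(s)); y <- numeric(length(s))
  tx <- numeric(length(s)); ty <- numeric(length(s))
  for (i in seq_along(s)) {
    si <- s[i]
    if (si < L) {                       # bottom straight, heading +x
      x[i] <- si; y[i] <- 0; tx[i] <- 1; ty[i] <- 0
    } else if (si < L + pi * R) {       # right arc, counter-clockwise
      a <- (si - L) / R
      x[i] <- L + R * sin(a); y[i] <- R - R * cos(a)
      tx[i] <- cos(a); ty[i] <- sin(a)
    } else if (si < 2 * L + pi * R) {   # top straight, heading -x
      d <- si - L - pi * R
      x[i] <- L - d; y[i] <- 2 * R; tx[i] <- -1; ty[i] <- 0
    } else {                            # left arc
      a <- (si - 2 * L - pi * R) / R
      x[i] <- -R * sin(a); y[i] <- R + R * cos(a)
      tx[i] <- -cos(a); ty[i] <- -sin(a)
    }
  }
  list(x = x, y = y, tx = tx, ty = ty, s = s, length = total)
}

#' Initial lane-following state
#'
#' The vehicle starts at a fixed point on the centerline, aligned with the
#' lane.
#'
#' @param env a [lane_config()].
#' @param track a [make_track()] result (rebuilt if omitted).
#' @return A list: \code{pos}, \code{heading} (radians), \code{track_idx}
#'   (index of the last nearest centerline point, used to warm-start the
#'   nearest-point search), and \code{track}.
#' @export
lane_state <- function(env = lane_config(), track = NULL) {
  if (is.null(track)) track <- make_track(env)
  list(pos = c(track$x[1], track$y[1]),
       heading = atan2(track$ty[1], track$tx[1]),
       track_idx = 1L, track = track)
}

nearest_track_point <- function(track, pos, idx_hint = NULL, window = 80L) {
  n <- length(track$x)
  if (is.null(idx_hint)) {
    cand <- seq_len(n)
  } else {
    cand <- ((idx_hint - 1L + seq(-window, window)) %% n) + 1L
  }
  d2 <- (track$x[cand] - pos[1])^2 + (track$y[cand] - pos[2])^2
  cand[which.min(d2)]
}

#' Angular and lateral error of the vehicle
#'
#' The lateral error is the distance to the nearest centerline point of the
#' right lane; the angular error is the absolute angle between the vehicle
#' heading and the lane tangent there, wrapped to \code{[0, 180]} degrees.
#' Nearest-point ties between track branches are broken by arc length via
#' the warm-started search window around the previously nearest point.
#'
#' @param state a [lane_state()].
#' @param warm logical; use the warm-started windowed search (default) or
#'   an exhaustive search over the whole centerline.
#' @return \code{c(beta_err, d_err)} in degrees and meters, plus the
#'   nearest index as attribute \code{idx}.
#' @export
lane_errors <- function(state, warm = TRUE) {
  idx <- nearest_track_point(state$track, state$pos,
                             if (warm) state$track_idx else NULL)
  tr <- state$track
  d_err <- sqrt((tr$x[idx] - state$pos[1])^2 + (tr$y[idx] - state$pos[2])^2)
  ang <- atan2(tr$ty[idx], tr$tx[idx]) - state$heading
  ang <- atan2(sin(ang), cos(ang))      # wrap to (-pi, pi]
  out <- c(beta_err = abs(ang) * 180 / pi, d_err = d_err)
  attr(out, "idx") <- idx
  out
}

#' Lane-following reward
#'
#' \eqn{r = \exp(-0.03\,\beta_{err}^2)\,\exp(-70\,d_{err}^2)} with the
#' angular error in degrees: the score halves every 5 degrees of angular
#' error or 0.1 m of lateral error. Bounded in \code{(0, 1]} and strictly
#' decreasing in each error.
#'
#' @param beta_err angular error, degrees, >= 0.
#' @param d_err lateral error, meters, >= 0.
#' @param rw a [reward_config()].
#' @return Reward in \code{(0, 1]}.
#' @export
lane_reward <- function(beta_err, d_err, rw = reward_config()) {
  stopifnot(all(beta_err >= 0), all(d_err >= 0))
  exp(-rw$lane_angle_coef * beta_err^2) * exp(-rw$lane_dist_coef * d_err^2)
}

#' One kinematic step of the lane environment
#'
#' Kinematic bicycle model at constant speed: the heading rate is
#' \eqn{(v/L)\tan(\delta)} for steering angle \eqn{\delta} and wheelbase
#' \eqn{L}. If the lateral error exceeds the lane half-width the vehicle
#' has left the track and is reset to the fixed start pose; the reset is
#' not signalled to the network.
#'
#' @param state a [lane_state()].
#' @param steering steering angle, degrees (one of the discrete commands).
#' @param dt step length, seconds.
#' @param env a [lane_config()].
#' @return A list: \code{state}, \code{reset} (logical), \code{beta_err}
#'   (degrees), \code{d_err} (meters) measured after the move (pre-reset
#'   pose).
#' @export
lane_step <- function(state, steering, dt, env = lane_config()) {
  stopifnot(dt > 0, length(steering) == 1)
  state$heading <- state$heading +
    (env$speed / env$wheelbase) * tan(steering * pi / 180) * dt
  state$pos <- state$pos +
    env$speed * c(cos(state$heading), sin(state$heading)) * dt
  err <- lane_errors(state)
  state$track_idx <- attr(err, "idx")
  reset <- err[["d_err"]] > env$half_width
  if (reset) {
    tr <- state$track
    state$pos <- c(tr$x[1], tr$y[1])
    state$heading <- atan2(tr$ty[1], tr$tx[1])
    state$track_idx <- 1L
  }
  list(state = state, reset = reset,
       beta_err = err[["beta_err"]], d_err = err[["d_err"]])
}

#' Render the forward lane view
#'
#' Pinhole projection of the two boundary lines of the right lane
#' (centerline offset by the lane half-width along the track normal) onto
#' the sensor from a camera at the vehicle pose, \code{env$cam_height}
#' above the ground, looking along the heading. Boundary points between
#' the near and far clipping distances are projected and drawn dark on a
#' light background; everything else is background.
#'
#' @param state a [lane_state()].
#' @param env a [lane_config()].
#' @return A \code{height_px x width_px} intensity matrix in \code{[0,1]};
#'   row 1 is the top of the image (far ahead).
#' @export
render_lane <- function(state, env = lane_config()) {
  tr <- state$track
  frame <- matrix(1, env$height_px, env$width_px)
  ch <- cos(state$heading); sh <- sin(state$heading)
  # normals point left of travel; boundaries at +/- half_width
  for (side in c(-1, 1)) {
    bx <- tr$x - side * env$half_width * tr$ty
    by <- tr$y + side * env$half_width * tr$tx
    rx <- bx - state$pos[1]
    ry <- by - state$pos[2]
    f <- rx * ch + ry * sh                # forward distance
    l <- -rx * sh + ry * ch               # lateral, left positive
    keep <- f > env$f_min & f < env$f_max
    if (!any(keep)) next
    col <- floor(env$width_px / 2 - env$focal * l[keep] / f[keep]) + 1L
    row <- floor(env$focal * env$cam_height / f[keep]) + 1L
    ok <- col >= 1L & col <= env$width_px & row >= 1L & row <= env$height_px
    if (any(ok))
      frame[cbind(row[ok], col[ok])] <- 0
  }
  frame
}
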