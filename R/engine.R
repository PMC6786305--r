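#' Run a closed-loop learning experiment
#'
#' Simulates the full loop at a 1 ms resolution: render the scene, convert
#' intensity changes to address events, encode events as input spikes, step
#' the spiking network, advance the fast plasticity traces under the
#' smoothed global reward, decode a motor command from 100 ms low-passed
#' motor activities, step the environment and compute the reward. Synaptic
#' parameters and weights advance only on the 100 ms slow grid (weights are
#' constant in between), and the learning rate follows the annealing
#' schedule in 10 min steps when enabled. The run is fully reproducible
#' from \code{seed}: every stochastic draw flows through the global R RNG
#' in a documented order, identically in the compiled and the pure-R
#' engine.
#'
#' @param task \code{"reaching"} or \code{"lane"}.
#' @param duration simulated seconds, >= 0.
#' @param seed integer seed for the whole run (network initialization and
#'   simulation).
#' @param spore a [spore_config()].
#' @param net a [network_config()]; defaults to the task's standard sizes.
#' @param codec a [codec_config()].
#' @param reward a [reward_config()].
#' @param env a [reaching_config()] or [lane_config()]; defaults per task.
#' @param anneal logical; apply learning-rate annealing (default on for the
#'   lane task, off for reaching).
#' @param learn logical; \code{FALSE} freezes the weights (equivalent to a
#'   zero learning rate) for baseline comparisons.
#' @param snapshot_interval seconds between weight snapshots.
#' @param record_dt seconds between recorded reward samples (default: every
#'   fast step).
#' @param engine \code{"cpp"} (compiled fast path) or \code{"r"} (pure-R
#'   reference composed from the exported per-operation functions).
#' @return An object of class \code{spore_run}: a list with the metrics log
#'   (\code{log}: data.frame of \code{t}, \code{reward}; \code{resets}:
#'   reset times), weight \code{snapshots} (\code{t} and a column-per-time
#'   matrix \code{w}), the final \code{topology} (with learned parameters),
#'   final trace state, \code{beta_final}, counters and all configuration.
#' @seealso [summary.spore_run()], [reach_rate()], [weak_weight_count()],
#'   [policy_map()].
#' @examples
#' \donttest{
#' run <- run_experiment("reaching", duration = 2, seed = 1,
#'                       env = reaching_config(n_px = 8),
#'                       net = network_config(n_motor = 4, multiplicity = 2))
#' summary(run)
#' }
#' @export
run_experiment <- function(task = c("reaching", "lane"),
                           duration = 10, seed = 1,
                           spore = spore_config(), net = NULL,
                           codec = codec_config(), reward = reward_config(),
                           env = NULL, anneal = (task == "lane"),
                           learn = TRUE,
                           snapshot_interval = 60, record_dt = NULL,
                           engine = c("cpp", "r")) {
  task <- match.arg(task)
  engine <- match.arg(engine)
  stopifnot(duration >= 0, is.logical(anneal), is.logical(learn))
  if (is.null(net))
    net <- if (task == "reaching") network_config()
           else network_config(multiplicity = 1, exploration = FALSE)
  if (is.null(env))
    env <- if (task == "reaching") reaching_config() else lane_config()
  if (!identical(env$task, task))
    stop("run_experiment: env config does not match task '", task, "'")
  if (is.null(record_dt)) record_dt <- spore$dt_fast
  record_every <- max(1L, as.integer(round(record_dt / spore$dt_fast)))
  n_steps <- as.integer(round(duration / spore$dt_fast))
  n_slow <- as.integer(round(spore$dt_slow / spore$dt_fast))
  snap_every <- max(n_slow,
                    as.integer(round(snapshot_interval / spore$dt_fast)))

  set.seed(as.integer(seed))
  topo <- if (task == "reaching")
    build_reaching_network(spore, net, env) else
    build_lane_network(spore, net, env)

  res <- if (engine == "cpp")
    run_loop_cpp(task, topo, n_steps, spore, net, codec, reward, env,
                 anneal, learn, snap_every, record_every)
  else
    run_loop_r(task, topo, n_steps, spore, net, codec, reward, env,
               anneal, learn, snap_every, record_every)

  topo$theta <- matrix(res$theta, nrow(topo$theta), ncol(topo$theta))
  topo$w <- matrix(res$w, nrow(topo$w), ncol(topo$w))
  structure(list(task = task, duration = duration, seed = seed,
                 engine = engine,
                 log = data.frame(t = res$log_t, reward = res$log_reward),
                 resets = res$resets,
                 snapshots = list(t = res$snap_t,
                                  w = matrix(res$snap_w,
                                             ncol = length(res$snap_t))),
                 topology = topo,
                 final_traces = list(e = res$e, g = res$g, y_in = res$y_in),
                 beta_final = res$beta_final,
                 n_slow_updates = res$n_slow_updates,
                 config = list(spore = spore, net = net, codec = codec,
                               reward = reward, env = env,
                               anneal = anneal, learn = learn,
                               snapshot_interval = snapshot_interval,
                               record_dt = record_dt)),
            class = "spore_run")
}

# Pure-R closed loop, composed from the exported per-operation functions.
# Serves as the readable reference and as the oracle the compiled engine is
# checked against (identical RNG draw order and arithmetic).
run_loop_r <- function(task, topo, n_steps, spore, net, codec, rw, env,
                       anneal, learn, snap_every, record_every) {
  dt <- spore$dt_fast
  n_slow <- as.integer(round(spore$dt_slow / dt))
  nstate <- network_state(topo)
  a <- numeric(topo$n_motor)
  r_smooth <- 0
  resets <- numeric(0)
  n_rec <- n_steps %/% record_every
  log_t <- numeric(n_rec); log_reward <- numeric(n_rec); i_rec <- 0L
  snap_t <- 0
  snap_w <- list(as.numeric(topo$w))
  n_slow_updates <- 0L
  beta_now <- if (learn) spore$beta0 else 0

  if (task == "reaching") {
    estate <- reaching_state(env)
    ref <- render_reaching(estate, env)
  } else {
    estate <- lane_state(env)
    ref <- render_lane(estate, env)
  }

  for (n in seq_len(n_steps)) {
    t_now <- n * dt
    if (task == "reaching") {
      frame <- render_reaching(estate, env)
      dv <- dvs_frame_diff(ref, frame, env$dvs_threshold, t_now)
      ref <- dv$ref
      counts <- encode_reaching_spikes(dv$events, env$n_px)
      if (!env$axis_neurons) counts <- counts[seq_len(topo$n_input)]
      st <- step_network(topo, nstate, counts, spore, net, r_smooth)
      nstate <- st$state
      a <- flush_zero(lowpass_activity(a, st$motor_spikes, dt,
                                       codec$tau_a))
      v_cmd <- codec$velocity_gain * decode_velocity(a)
      speed <- sqrt(sum(v_cmd * v_cmd))
      if (speed > codec$v_max) v_cmd <- v_cmd * (codec$v_max / speed)
      r_raw <- reaching_reward(v_cmd, -estate$pos, rw)
      es <- reaching_step(estate, v_cmd, dt, env)
      estate <- es$state
      if (es$reset) resets <- c(resets, t_now)
    } else {
      frame <- render_lane(estate, env)
      dv <- dvs_frame_diff(ref, frame, env$dvs_threshold, t_now)
      ref <- dv$ref
      rates <- encode_lane_rates(dv$events, env, env$rate_gain, net$rho_max)
      z_vis <- sample_spikes(rates, dt)
      st <- step_network(topo, nstate, as.numeric(z_vis), spore, net,
                         r_smooth)
      nstate <- st$state
      a <- flush_zero(lowpass_activity(a, st$motor_spikes, dt,
                                       codec$tau_a))
      steer <- decode_steering(a, codec)
      es <- lane_step(estate, steer, dt, env)
      estate <- es$state
      if (es$reset) resets <- c(resets, t_now)
      r_raw <- lane_reward(es$beta_err, es$d_err, rw)
    }
    r_smooth <- flush_zero(smooth_reward(r_raw, r_smooth, dt,
                                         codec$tau_r))
    if (n %% record_every == 0L) {
      i_rec <- i_rec + 1L
      log_t[i_rec] <- t_now
      log_reward[i_rec] <- r_raw
    }
    if (n %% n_slow == 0L) {
      if (learn) {
        beta_now <- if (anneal) beta_at(t_now, spore) else spore$beta0
        noise <- matrix(stats::rnorm(topo$n_plastic), nrow(topo$theta))
        topo$theta <- update_parameter(topo$theta, nstate$g, beta_now,
                                       noise, spore)
        topo$w <- parameter_to_weight(topo$theta, spore)
        dim(topo$w) <- dim(topo$theta)
      }
      n_slow_updates <- n_slow_updates + 1L
    }
    if (n %% snap_every == 0L) {
      snap_t <- c(snap_t, t_now)
      snap_w[[length(snap_w) + 1L]] <- as.numeric(topo$w)
    }
  }
  list(theta = as.numeric(topo$theta), w = as.numeric(topo$w),
       e = as.numeric(nstate$e), g = as.numeric(nstate$g),
       y_in = nstate$y_in,
       log_t = log_t, log_reward = log_reward, resets = resets,
       snap_t = snap_t, snap_w = unlist(snap_w),
       beta_final = beta_now, n_slow_updates = n_slow_updates)
}

run_loop_cpp <- function(task, topo, n_steps, spore, net, codec, rw, env,
                         anneal, learn, snap_every, record_every) {
  p <- list(
    n_steps = n_steps,
    dt = spore$dt_fast,
    n_slow = as.integer(round(spore$dt_slow / spore$dt_fast)),
    snap_every = snap_every, record_every = record_every,
    learn = learn, anneal = anneal,
    # plasticity
    tau_psp = spore$tau_psp, tau_e = spore$tau_e, tau_g = spore$tau_g,
    c_p = spore$c_p, c_g = spore$c_g, mu = spore$mu,
    temperature = spore$temperature, beta0 = spore$beta0,
    lambda_decay = spore$lambda_decay,
    anneal_interval = spore$anneal_interval,
    theta_min = spore$theta_min, theta_max = spore$theta_max,
    dtheta_max = spore$dtheta_max, w0 = spore$w0, theta0 = spore$theta0,
    dt_slow = spore$dt_slow,
    # network
    n_input = topo$n_input, n_visual = topo$n_visual,
    n_axis = topo$n_axis, n_motor = topo$n_motor,
    multiplicity = topo$multiplicity,
    rho0 = net$rho0, du = net$du, rho_max = net$rho_max,
    theta_init = as.numeric(topo$theta), w_init = as.numeric(topo$w),
    has_expl = !is.null(topo$static),
    noise_rate = if (is.null(topo$static)) 0 else topo$static$noise_rate,
    w_noise_expl = if (is.null(topo$static)) 0 else
      topo$static$w_noise_expl,
    w_vis_expl = if (is.null(topo$static)) numeric(0) else
      topo$static$w_vis_expl,
    w_expl_motor = if (is.null(topo$static)) 0 else
      topo$static$w_expl_motor,
    # codec
    tau_a = codec$tau_a, tau_r = codec$tau_r,
    velocity_gain = codec$velocity_gain, v_max = codec$v_max,
    steer_scale = codec$steer_scale,
    steer_boundaries = codec$steer_boundaries,
    steer_angles = codec$steer_angles,
    # reward
    beta_lim = rw$beta_lim, v_lim = rw$v_lim, coef = rw$coef,
    exponent = rw$exponent, lane_angle_coef = rw$lane_angle_coef,
    lane_dist_coef = rw$lane_dist_coef)
  if (task == "reaching") {
    p$n_px <- env$n_px
    p$plane_half <- env$plane_half
    p$ball_radius <- env$ball_radius
    p$target_radius <- env$target_radius
    p$dvs_threshold <- env$dvs_threshold
    p$axis_neurons <- env$axis_neurons
    st <- reaching_state(env)
    p$pos0 <- st$pos
    cpp_run_reaching(p)
  } else {
    track <- make_track(env)
    p$width_px <- env$width_px; p$height_px <- env$height_px
    p$window_px <- env$window_px
    p$half_width <- env$half_width; p$speed <- env$speed
    p$wheelbase <- env$wheelbase
    p$cam_height <- env$cam_height; p$focal <- env$focal
    p$f_min <- env$f_min; p$f_max <- env$f_max
    p$dvs_threshold <- env$dvs_threshold; p$rate_gain <- env$rate_gain
    p$track_x <- track$x; p$track_y <- track$y
    p$track_tx <- track$tx; p$track_ty <- track$ty
    cpp_run_lane(p)
  }
}
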