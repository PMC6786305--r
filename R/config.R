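#' Plasticity rule configuration
#'
#' Collects every constant of the synaptic-sampling rule: time constants of
#' the fast traces, prior and gradient gains of the parameter SDE, the
#' temperature driving parameter diffusion, the learning-rate annealing
#' schedule, clipping bounds, the exponential weight projection, the two
#' integration time steps, and the initial parameter distribution.
#'
#' The parameter SDE reads
#' \deqn{d\theta = \beta\,(c_p(\mu - \theta) + c_g\,g)\,dt + \sqrt{2 T \beta}\, dW,}
#' integrated on the slow grid \code{dt_slow}, while the traces \eqn{y}
#' (filtered pre-synaptic spikes), \eqn{e} (eligibility) and \eqn{g}
#' (reward-gradient estimate) are integrated on the fast grid \code{dt_fast}.
#' Weights are the projection \eqn{w = w_0 \exp(\theta - \theta_0)} for
#' \eqn{\theta > 0} and 0 otherwise.
#'
#' @param tau_psp time constant of the post-synaptic-potential kernel applied
#'   to pre-synaptic spikes, seconds.
#' @param tau_e eligibility-trace time constant, seconds.
#' @param tau_g reward-gradient integration time constant, seconds.
#' @param c_p prior strength; 0 is a flat (non-informative) prior.
#' @param c_g reward-gradient gain.
#' @param mu prior mean of the synaptic parameters.
#' @param temperature diffusion coefficient T of the parameter SDE.
#' @param beta0 initial learning rate.
#' @param lambda_decay annealing rate (per second) of the learning rate.
#' @param anneal_interval seconds between learning-rate updates.
#' @param theta_min,theta_max clip bounds for the synaptic parameter.
#' @param dtheta_max symmetric clip applied to the gradient estimate when it
#'   enters a parameter update.
#' @param w0,theta0 scale and offset of the exponential weight projection.
#' @param theta_init_mean,theta_init_var mean and variance of the Gaussian
#'   from which initial synaptic parameters are drawn (draws below 0 are set
#'   to 0).
#' @param dt_fast fast integration step, seconds.
#' @param dt_slow parameter/weight update interval, seconds.
#' @return An object of class \code{spore_config} (a validated list).
#' @examples
#' cfg <- spore_config()
#' parameter_to_weight(1, cfg)
#' @export
spore_config <- function(tau_psp = 0.02, tau_e = 2, tau_g = 50,
                         c_p = 0, c_g = 1, mu = 0, temperature = 0.1,
                         beta0 = 1e-7, lambda_decay = 8.5e-5,
                         anneal_interval = 600,
                         theta_min = -2, theta_max = 5, dtheta_max = 1,
                         w0 = 1, theta0 = 0,
                         theta_init_mean = 0.8, theta_init_var = 0.6,
                         dt_fast = 0.001, dt_slow = 0.1) {
  cfg <- list(tau_psp = tau_psp, tau_e = tau_e, tau_g = tau_g,
              c_p = c_p, c_g = c_g, mu = mu, temperature = temperature,
              beta0 = beta0, lambda_decay = lambda_decay,
              anneal_interval = anneal_interval,
              theta_min = theta_min, theta_max = theta_max,
              dtheta_max = dtheta_max, w0 = w0, theta0 = theta0,
              theta_init_mean = theta_init_mean,
              theta_init_var = theta_init_var,
              dt_fast = dt_fast, dt_slow = dt_slow)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("spore_config: '", nm, "' must be a single finite number")
  }
  stopifnot(tau_psp > 0, tau_e > 0, tau_g > 0, c_p >= 0, temperature >= 0,
            beta0 >= 0, lambda_decay >= 0, anneal_interval > 0,
            theta_min < theta_max, dtheta_max > 0, w0 > 0,
            theta_init_var > 0, dt_fast > 0, dt_slow > 0,
            dt_fast <= dt_slow)
  if (abs(dt_slow / dt_fast - round(dt_slow / dt_fast)) > 1e-9)
    stop("spore_config: dt_slow must be an integer multiple of dt_fast")
  structure(cfg, class = "spore_config")
}

#' Point-process neuron and network configuration
#'
#' Neurons are inhomogeneous Poisson processes with exponential intensity
#' \eqn{\rho(u) = \rho_0 \exp(u/\Delta u)} capped at \code{rho_max}, so the
#' instantaneous post-synaptic rate entering the eligibility dynamics is well
#' defined. The reaching network additionally carries an exploration neuron:
#' excited by a Poisson noise source, inhibited by the pixel neurons, and
#' exciting every motor neuron, it prevents long periods of immobility when
#' the event camera sees no change.
#'
#' @param n_motor number of motor neurons.
#' @param multiplicity number of plastic synapses per (input, motor) pair.
#' @param rho0 baseline firing rate at zero potential, Hz.
#' @param du potential scale of the exponential intensity. The default of
#'   20 places the network's typical potentials (tens of units, given the
#'   published static weights and unit-jump PSP traces) in the sensitive
#'   part of the intensity curve; much smaller values drive every motor
#'   neuron to the rate cap, where the decoded command no longer depends
#'   on the synaptic weights.
#' @param rho_max rate cap, Hz.
#' @param noise_rate rate of the exploration noise source, Hz.
#' @param w_noise_expl static weight from noise source to exploration neuron.
#' @param w_vis_expl_mean,w_vis_expl_sd mean and sd of the Gaussian static
#'   inhibitory weights from each pixel neuron to the exploration neuron.
#' @param w_expl_motor static weight from exploration neuron to each motor
#'   neuron.
#' @param exploration logical; include the exploration pathway.
#' @return An object of class \code{network_config}.
#' @export
network_config <- function(n_motor = 8, multiplicity = 10,
                           rho0 = 10, du = 20, rho_max = 500,
                           noise_rate = 35, w_noise_expl = 750,
                           w_vis_expl_mean = -500, w_vis_expl_sd = 50,
                           w_expl_motor = 10, exploration = TRUE) {
  stopifnot(n_motor >= 1, multiplicity >= 1, rho0 > 0, du > 0,
            rho_max >= rho0, noise_rate >= 0, w_vis_expl_sd >= 0,
            is.logical(exploration))
  structure(list(n_motor = as.integer(n_motor),
                 multiplicity = as.integer(multiplicity),
                 rho0 = rho0, du = du, rho_max = rho_max,
                 noise_rate = noise_rate, w_noise_expl = w_noise_expl,
                 w_vis_expl_mean = w_vis_expl_mean,
                 w_vis_expl_sd = w_vis_expl_sd,
                 w_expl_motor = w_expl_motor,
                 exploration = exploration),
            class = "network_config")
}

#' Motor decoding and reward smoothing configuration
#'
#' @param tau_a low-pass time constant for motor spike activity, seconds.
#' @param tau_r time constant of the exponential reward smoother, seconds.
#' @param velocity_gain scale from the population-vector read-out to a ball
#'   velocity command, m/s per activity unit.
#' @param v_max magnitude cap on the commanded velocity, m/s.
#' @param steer_scale scale applied to the left/right activity ratio before
#'   the decision boundaries (the printed boundaries live on a percent
#'   scale).
#' @param steer_boundaries increasing decision boundaries on the scaled
#'   ratio.
#' @param steer_angles the five steering commands, degrees, ordered from the
#'   command chosen at the most negative scaled ratio to the most positive.
#'   With the default sign convention a dominant left population (positive
#'   ratio) steers left (negative angle).
#' @return An object of class \code{codec_config}.
#' @export
codec_config <- function(tau_a = 0.1, tau_r = 0.1,
                         velocity_gain = 0.5, v_max = 5,
                         steer_scale = 100,
                         steer_boundaries = c(-10, -2.5, 2.5, 10),
                         steer_angles = c(30, 15, 0, -15, -30)) {
  stopifnot(tau_a > 0, tau_r > 0, velocity_gain > 0, v_max > 0,
            steer_scale > 0, length(steer_boundaries) + 1L ==
              length(steer_angles), !is.unsorted(steer_boundaries))
  structure(list(tau_a = tau_a, tau_r = tau_r,
                 velocity_gain = velocity_gain, v_max = v_max,
                 steer_scale = steer_scale,
                 steer_boundaries = steer_boundaries,
                 steer_angles = steer_angles),
            class = "codec_config")
}

#' Reward function configuration
#'
#' Reaching reward: \eqn{r = c\, r_v (r_\beta + 1)^p} with
#' \eqn{r_\beta = 1 - \beta_{err}/\beta_{lim}} when the heading error is
#' inside the tolerance (else 0) and \eqn{r_v = |v|} above the speed
#' threshold (else 0). Lane reward:
#' \eqn{r = \exp(-a\,\beta_{err}^2)\exp(-b\,d_{err}^2)} with the angular
#' error in degrees; the default constants halve the score every 5 degrees
#' of angular error or 0.1 m of lateral error.
#'
#' @param beta_lim angular tolerance of the reaching reward, radians.
#' @param v_lim speed threshold of the reaching reward, m/s.
#' @param coef,exponent coefficient \eqn{c} and exponent \eqn{p} of the
#'   reaching reward.
#' @param lane_angle_coef coefficient on squared angular error, per degree^2.
#' @param lane_dist_coef coefficient on squared distance error, per m^2.
#' @return An object of class \code{reward_config}.
#' @export
reward_config <- function(beta_lim = pi / 4, v_lim = 0.1,
                          coef = 3 / 5, exponent = 5,
                          lane_angle_coef = 0.03, lane_dist_coef = 70) {
  stopifnot(beta_lim > 0, v_lim >= 0, coef >= 0, exponent >= 0,
            lane_angle_coef >= 0, lane_dist_coef >= 0)
  structure(list(beta_lim = beta_lim, v_lim = v_lim, coef = coef,
                 exponent = exponent, lane_angle_coef = lane_angle_coef,
                 lane_dist_coef = lane_dist_coef),
            class = "reward_config")
}

#' Reaching environment configuration
#'
#' A ball of radius \code{ball_radius} on a walled square plane of half-side
#' \code{plane_half}, observed top-down by an event camera of
#' \code{n_px} x \code{n_px} pixels. The ball is reset to a uniformly random
#' position when its center enters the target disc at the origin; the reset
#' is never signalled to the network.
#'
#' @param n_px sensor resolution (square), pixels.
#' @param plane_half half-side of the plane, meters.
#' @param ball_radius,target_radius ball and target radii, meters.
#' @param dvs_threshold intensity-change threshold of the event camera.
#' @param axis_neurons logical; add one axis feature neuron per sensor row
#'   and per sensor column, each firing for every event in its row/column.
#' @return An object of class \code{reaching_config}.
#' @export
reaching_config <- function(n_px = 16, plane_half = 10, ball_radius = 2,
                            target_radius = 2, dvs_threshold = 0.1,
                            axis_neurons = TRUE) {
  stopifnot(n_px >= 2, plane_half > 0, ball_radius > 0, target_radius > 0,
            ball_radius < plane_half, dvs_threshold > 0,
            is.logical(axis_neurons))
  structure(list(task = "reaching", n_px = as.integer(n_px),
                 plane_half = plane_half, ball_radius = ball_radius,
                 target_radius = target_radius,
                 dvs_threshold = dvs_threshold,
                 axis_neurons = axis_neurons),
            class = "reaching_config")
}

#' Lane-following environment configuration
#'
#' A vehicle driving at constant speed on the right lane of a closed stadium
#' circuit (two straights joined by two semicircular arcs), steered by
#' discrete angles through a kinematic bicycle model, observed by a
#' forward-facing event camera. The vehicle is reset to the fixed start pose
#' as soon as its lateral error exceeds the lane half-width; the reset is
#' never signalled to the network.
#'
#' @param width_px,height_px sensor resolution, pixels.
#' @param window_px side of the square pixel window each visual neuron
#'   covers.
#' @param straight length of each straight segment, meters.
#' @param radius radius of the semicircular arcs, meters.
#' @param half_width lane half-width, meters (also the off-track bound).
#' @param speed constant vehicle speed, m/s.
#' @param wheelbase wheelbase of the kinematic steering model, meters.
#' @param n_track number of points in the discretized centerline.
#' @param cam_height camera height above the ground plane, meters.
#' @param focal focal length of the pinhole projection, pixels.
#' @param f_min,f_max near and far clipping distance of the projection,
#'   meters.
#' @param dvs_threshold intensity-change threshold of the event camera.
#' @param rate_gain firing rate contributed per event in a visual neuron's
#'   window, Hz.
#' @return An object of class \code{lane_config}.
#' @export
lane_config <- function(width_px = 128, height_px = 32, window_px = 8,
                        straight = 8, radius = 3, half_width = 0.4,
                        speed = 1, wheelbase = 0.3, n_track = 3500,
                        cam_height = 0.5, focal = 60,
                        f_min = 0.95, f_max = 30,
                        dvs_threshold = 0.1, rate_gain = 10) {
  stopifnot(width_px %% window_px == 0, height_px %% window_px == 0,
            straight > 0, radius > half_width, half_width > 0, speed > 0,
            wheelbase > 0, n_track >= 100, cam_height > 0, focal > 0,
            f_min > 0, f_max > f_min, dvs_threshold > 0, rate_gain > 0)
  structure(list(task = "lane", width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 window_px = as.integer(window_px),
                 straight = straight, radius = radius,
                 half_width = half_width, speed = speed,
                 wheelbase = wheelbase, n_track = as.integer(n_track),
                 cam_height = cam_height, focal = focal,
                 f_min = f_min, f_max = f_max,
                 dvs_threshold = dvs_threshold, rate_gain = rate_gain),
            class = "lane_config")
}

#' @export
print.spore_config <- function(x, ...) {
  cat("Synaptic-sampling configuration\n")
  cat(sprintf("  traces: tau_psp = %g s, tau_e = %g s, tau_g = %g s\n",
              x$tau_psp, x$tau_e, x$tau_g))
  cat(sprintf("  SDE: c_p = %g, c_g = %g, mu = %g, T = %g\n",
              x$c_p, x$c_g, x$mu, x$temperature))
  cat(sprintf("  learning rate: beta0 = %g, lambda = %g /s (every %g s)\n",
              x$beta0, x$lambda_decay, x$anneal_interval))
  cat(sprintf("  clips: theta in [%g, %g], |g| <= %g\n",
              x$theta_min, x$theta_max, x$dtheta_max))
  cat(sprintf("  projection: w0 = %g, theta0 = %g\n", x$w0, x$theta0))
  cat(sprintf("  steps: dt_fast = %g s, dt_slow = %g s\n",
              x$dt_fast, x$dt_slow))
  invisible(x)
}
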