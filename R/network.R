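#' Exponential point-process intensity
#'
#' Neurons are inhomogeneous Poisson processes with instantaneous rate
#' \eqn{\rho(u) = \rho_0 \exp(u / \Delta u)}, capped at \eqn{\rho_{max}}.
#' The membrane potential \eqn{u} is the weighted sum of afferent PSP
#' traces.
#'
#' @param u membrane potential(s), finite.
#' @param net a [network_config()].
#' @return Firing rate(s), Hz, in \code{[0, rho_max]}.
#' @export
neuron_rate <- function(u, net = network_config()) {
  if (any(!is.finite(u))) stop("neuron_rate: u must be finite")
  pmin(net$rho0 * exp(u / net$du), net$rho_max)
}

#' Sample Poisson spikes over one time step
#'
#' A neuron with rate \eqn{\rho} spikes within a step of length \eqn{dt}
#' with probability \eqn{1 - \exp(-\rho\,dt)} (at most one spike per step).
#' Draws come from the global R RNG, so a seed set by the caller makes
#' rasters reproducible.
#'
#' @param rho rate(s), Hz, >= 0.
#' @param dt step length, seconds, > 0.
#' @return Logical vector of spike indicators.
#' @export
sample_spikes <- function(rho, dt) {
  stopifnot(all(rho >= 0), dt > 0)
  stats::runif(length(rho)) < 1 - exp(-rho * dt)
}

# Flush-to-zero for exponentially decaying traces: values below this are
# physically meaningless and would otherwise reach the subnormal range,
# where floating-point arithmetic is drastically slower. The compiled
# engine applies the identical flush so both paths stay bit-compatible.
flush_zero <- function(x, eps = 1e-90) {
  x[abs(x) < eps] <- 0
  x
}

new_topology <- function(task, n_visual, n_axis, n_motor, multiplicity,
                         syn, static, geom) {
  n_input <- n_visual + n_axis
  structure(list(task = task, n_visual = n_visual, n_axis = n_axis,
                 n_input = n_input, n_motor = n_motor,
                 multiplicity = multiplicity,
                 n_plastic = n_input * n_motor * multiplicity,
                 theta = matrix(syn$theta, n_input * multiplicity, n_motor),
                 w = matrix(syn$w, n_input * multiplicity, n_motor),
                 static = static, geom = geom),
            class = "spore_topology")
}

#' Build the reaching-task network
#'
#' Feed-forward topology: one visual neuron per sensor pixel plus one axis
#' feature neuron per row and per column, all connected to every motor
#' neuron with \code{net$multiplicity} plastic synapses. At the default
#' sizes (16 x 16 pixels, 2 x 16 axis neurons, 8 motor neurons,
#' multiplicity 10) this gives 23,040 plastic synapses. An exploration
#' neuron — excited by a Poisson noise source, inhibited by every pixel
#' neuron with Gaussian static weights, and exciting every motor neuron —
#' keeps the agent moving when the event camera is silent.
#'
#' @param cfg a [spore_config()].
#' @param net a [network_config()].
#' @param env a [reaching_config()].
#' @param seed optional integer seed for the parameter draws and static
#'   inhibitory weights.
#' @return A \code{spore_topology} object. Plastic state is stored as
#'   matrices of dimension \code{(n_input * multiplicity) x n_motor}; row
#'   block \code{k} holds the \code{k}-th synapse of every input neuron in
#'   input order (pixels in row-major order, then row-axis, then
#'   column-axis neurons).
#' @export
build_reaching_network <- function(cfg = spore_config(),
                                   net = network_config(),
                                   env = reaching_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_visual <- env$n_px^2
  n_axis <- if (env$axis_neurons) 2L * env$n_px else 0L
  n <- (n_visual + n_axis) * net$n_motor * net$multiplicity
  syn <- init_parameters(n, cfg)
  static <- if (net$exploration) {
    list(w_noise_expl = net$w_noise_expl,
         w_vis_expl = stats::rnorm(n_visual, net$w_vis_expl_mean,
                                   net$w_vis_expl_sd),
         w_expl_motor = net$w_expl_motor,
         noise_rate = net$noise_rate)
  } else NULL
  new_topology("reaching", n_visual, n_axis, net$n_motor,
               net$multiplicity, syn, static,
               geom = list(n_px = env$n_px))
}

#' Build the lane-following network
#'
#' Feed-forward topology: one visual neuron per sensor window (16 x 4 = 64
#' at the default 128 x 32 resolution with 8 x 8 windows), each connected
#' to all motor neurons with one plastic synapse — 512 plastic synapses at
#' the default 8 motor neurons. The motor layer is split into a left half
#' and a right half for the ratio decoder. There is no exploration neuron.
#'
#' @param cfg a [spore_config()].
#' @param net a [network_config()]; its \code{multiplicity} defaults are
#'   overridden to 1 and \code{exploration} to FALSE for this task.
#' @param env a [lane_config()].
#' @param seed optional integer seed.
#' @return A \code{spore_topology} object.
#' @export
build_lane_network <- function(cfg = spore_config(),
                               net = network_config(multiplicity = 1,
                                                    exploration = FALSE),
                               env = lane_config(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (net$n_motor %% 2L != 0L)
    stop("build_lane_network: n_motor must be even (left/right split)")
  nwx <- env$width_px %/% env$window_px
  nwy <- env$height_px %/% env$window_px
  n_visual <- nwx * nwy
  n <- n_visual * net$n_motor * net$multiplicity
  syn <- init_parameters(n, cfg)
  new_topology("lane", n_visual, 0L, net$n_motor, net$multiplicity,
               syn, static = NULL,
               geom = list(nwx = nwx, nwy = nwy, window_px = env$window_px))
}

#' @export
print.spore_topology <- function(x, ...) {
  cat(sprintf("Spiking network topology (%s task)\n", x$task))
  cat(sprintf("  inputs: %d (%d visual + %d axis), motors: %d\n",
              x$n_input, x$n_visual, x$n_axis, x$n_motor))
  cat(sprintf("  plastic synapses: %d (multiplicity %d)\n",
              x$n_plastic, x$multiplicity))
  if (!is.null(x$static))
    cat("  exploration neuron wired (noise ->+ exploration ->+ motors,",
        "pixels ->- exploration)\n")
  invisible(x)
}

#' Fresh fast-timescale network state
#'
#' @param topology a \code{spore_topology}.
#' @return A list of quiescent PSP traces: \code{y_in} (one per input
#'   neuron), and for exploration-wired networks \code{y_noise} and
#'   \code{y_expl}; plus \code{e} and \code{g} matrices shaped like the
#'   plastic weight matrix.
#' @export
network_state <- function(topology) {
  list(y_in = numeric(topology$n_input),
       y_noise = 0, y_expl = 0,
       e = matrix(0, nrow(topology$w), ncol(topology$w)),
       g = matrix(0, nrow(topology$w), ncol(topology$w)))
}

#' One fast network step
#'
#' Fixed update order within a step: (1) input spikes update the input PSP
#' traces, (2) membrane potentials are formed as weighted sums of the
#' traces (exploration pathway first, so its spike feeds the motor
#' potentials of the same step), (3) rates via [neuron_rate()], (4) spikes
#' are sampled, (5) plasticity traces (eligibility and, by the caller,
#' reward gradient) advance. RNG draw order: noise-source spike, then the
#' exploration-neuron spike, then motor spikes in index order.
#'
#' @param topology a \code{spore_topology}.
#' @param state a [network_state()] (is advanced and returned).
#' @param input_spikes numeric vector of per-input spike counts for this
#'   step (length \code{n_input}).
#' @param cfg a [spore_config()].
#' @param net a [network_config()].
#' @param reward current global (smoothed) reward for the gradient trace.
#' @return A list: \code{state} (advanced), \code{motor_spikes} (logical),
#'   \code{motor_rates} (Hz), \code{expl_spike}.
#' @export
step_network <- function(topology, state, input_spikes,
                         cfg = spore_config(), net = network_config(),
                         reward = 0) {
  if (length(input_spikes) != topology$n_input)
    stop("step_network: input_spikes must have length n_input")
  dt <- cfg$dt_fast
  expl <- !is.null(topology$static)
  z_noise <- FALSE
  if (expl)
    z_noise <- sample_spikes(topology$static$noise_rate, dt)
  state$y_in <- flush_zero(update_psp_trace(state$y_in, input_spikes, cfg))
  expl_spike <- FALSE
  if (expl) {
    state$y_noise <- flush_zero(update_psp_trace(state$y_noise, z_noise,
                                                 cfg))
    u_expl <- topology$static$w_noise_expl * state$y_noise +
      sum(topology$static$w_vis_expl *
            state$y_in[seq_len(topology$n_visual)])
    expl_spike <- sample_spikes(neuron_rate(u_expl, net), dt)
    state$y_expl <- flush_zero(update_psp_trace(state$y_expl, expl_spike,
                                                cfg))
  }
  y_rep <- rep.int(state$y_in, topology$multiplicity)
  u_motor <- colSums(topology$w * y_rep)
  if (expl)
    u_motor <- u_motor + topology$static$w_expl_motor * state$y_expl
  motor_rates <- neuron_rate(u_motor, net)
  motor_spikes <- sample_spikes(motor_rates, dt)
  z_mat <- matrix(rep(as.numeric(motor_spikes), each = nrow(topology$w)),
                  nrow(topology$w))
  rho_mat <- matrix(rep(motor_rates, each = nrow(topology$w)),
                    nrow(topology$w))
  state$e <- flush_zero(update_eligibility(state$e, topology$w, y_rep,
                                           z_mat, rho_mat, cfg))
  state$g <- flush_zero(update_reward_gradient(state$g, reward, state$e,
                                               cfg))
  list(state = state, motor_spikes = motor_spikes,
       motor_rates = motor_rates, expl_spike = expl_spike)
}
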