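#' One fast-step update of the filtered pre-synaptic trace
#'
#' The pre-synaptic spike train is filtered with a single-exponential
#' post-synaptic-potential kernel: forward-Euler decay with time constant
#' \code{cfg$tau_psp} plus a unit increment per spike.
#'
#' @param y current trace value(s), non-negative.
#' @param pre_spike logical or 0/1 spike indicator (may be a count when
#'   several input events arrive in one step); recycled against \code{y}.
#' @param cfg a [spore_config()].
#' @return Updated trace, same length as \code{y}.
#' @examples
#' cfg <- spore_config()
#' update_psp_trace(1, FALSE, cfg)  # 1 - dt/tau_psp = 0.95
#' @export
update_psp_trace <- function(y, pre_spike, cfg) {
  if (any(y < 0)) stop("update_psp_trace: y must be non-negative")
  y * (1 - cfg$dt_fast / cfg$tau_psp) + as.numeric(pre_spike)
}

#' One fast-step update of the eligibility trace
#'
#' Forward-Euler step of
#' \deqn{\dot e = -e/\tau_e + w\,y\,(z_{post} - \rho_{post}),}
#' where the post-synaptic spike train \eqn{z_{post}} is a sum of unit-area
#' Dirac pulses. A spike inside a fast step contributes area 1 (an
#' indicator, not indicator/dt), so the spike term and the rate term
#' \eqn{\rho_{post}\,dt} are commensurate.
#'
#' @param e current eligibility value(s).
#' @param w synaptic weight(s), non-negative.
#' @param y filtered pre-synaptic trace(s).
#' @param post_spike logical/0-1 post-synaptic spike indicator.
#' @param rho_post instantaneous post-synaptic firing rate, Hz, >= 0.
#' @param cfg a [spore_config()].
#' @return Updated eligibility, same length as the longest argument.
#' @export
update_eligibility <- function(e, w, y, post_spike, rho_post, cfg) {
  if (any(rho_post < 0)) stop("update_eligibility: rho_post must be >= 0")
  e + cfg$dt_fast * (-e / cfg$tau_e) +
    w * y * (as.numeric(post_spike) - rho_post * cfg$dt_fast)
}

#' One fast-step update of the reward-gradient estimate
#'
#' Forward-Euler step of \eqn{\dot g = -g/\tau_g + r\,e}. The reward must be
#' non-negative; the sampling framework assumes \eqn{r(t) \ge 0}.
#'
#' @param g current gradient estimate(s).
#' @param r global reward signal, a single non-negative number.
#' @param e eligibility trace(s).
#' @param cfg a [spore_config()].
#' @return Updated gradient estimate.
#' @export
update_reward_gradient <- function(g, r, e, cfg) {
  if (any(r < 0)) stop("update_reward_gradient: reward must be non-negative")
  g + cfg$dt_fast * (-g / cfg$tau_g + r * e)
}

#' One slow-step update of the synaptic parameter
#'
#' Euler-Maruyama step of the parameter SDE
#' \deqn{d\theta = \beta\,(c_p(\mu - \theta) + c_g\,\bar g)\,dt
#'   + \sqrt{2 T \beta}\, dW,}
#' where \eqn{\bar g} is the gradient estimate clipped at
#' \code{cfg$dtheta_max} (clipping is applied at read time; the stored
#' \code{g} is untouched). The result is clipped to
#' \code{[cfg$theta_min, cfg$theta_max]}. Weights between slow updates are
#' constant; recompute them with [parameter_to_weight()] after each call.
#'
#' @param theta current synaptic parameter(s).
#' @param g reward-gradient estimate(s) (unclipped).
#' @param beta current learning rate.
#' @param noise standard-normal draw(s), one per synapse.
#' @param cfg a [spore_config()].
#' @return Updated, clipped parameter(s).
#' @export
update_parameter <- function(theta, g, beta, noise, cfg) {
  if (any(!is.finite(noise))) stop("update_parameter: noise must be finite")
  gc <- pmin(pmax(g, -cfg$dtheta_max), cfg$dtheta_max)
  th <- theta +
    beta * (cfg$c_p * (cfg$mu - theta) + cfg$c_g * gc) * cfg$dt_slow +
    sqrt(2 * cfg$temperature * beta * cfg$dt_slow) * noise
  pmin(pmax(th, cfg$theta_min), cfg$theta_max)
}

#' Exponential projection from synaptic parameter to weight
#'
#' \eqn{w = w_0 \exp(\theta - \theta_0)} for \eqn{\theta > 0}, and 0
#' otherwise: synapses whose parameter has drifted non-positive are
#' retracted and transmit nothing.
#'
#' @param theta synaptic parameter(s).
#' @param cfg a [spore_config()].
#' @return Non-negative weight(s), same length as \code{theta}.
#' @export
parameter_to_weight <- function(theta, cfg) {
  ifelse(theta > 0, cfg$w0 * exp(theta - cfg$theta0), 0)
}

#' Learning-rate annealing schedule
#'
#' The learning rate decays exponentially, \eqn{\dot\beta = -\lambda\beta},
#' applied in discrete multiplicative steps every \code{cfg$anneal_interval}
#' seconds (10 simulated minutes by default), so
#' \eqn{\beta(t) = \beta_0 \exp(-\lambda \Delta \lfloor t/\Delta \rfloor)}.
#'
#' @param sched a list with \code{beta_t} (current rate) and
#'   \code{t_last_update} (simulated time of the last applied step), as
#'   returned by \code{anneal_schedule()} or a previous call.
#' @param t_now current simulated time, seconds, \code{>= t_last_update}.
#' @param cfg a [spore_config()].
#' @return The updated schedule list.
#' @seealso [beta_at()] for the closed form.
#' @export
anneal_learning_rate <- function(sched, t_now, cfg) {
  stopifnot(t_now >= sched$t_last_update)
  n_steps <- floor(t_now / cfg$anneal_interval) -
    floor(sched$t_last_update / cfg$anneal_interval)
  if (n_steps > 0)
    sched$beta_t <- sched$beta_t *
      exp(-cfg$lambda_decay * cfg$anneal_interval)^n_steps
  sched$t_last_update <- t_now
  sched
}

#' @rdname anneal_learning_rate
#' @export
anneal_schedule <- function(cfg) {
  list(beta_t = cfg$beta0, t_last_update = 0)
}

#' Closed-form annealed learning rate
#'
#' @param t simulated time(s), seconds.
#' @param cfg a [spore_config()].
#' @return \eqn{\beta_0 \exp(-\lambda \Delta \lfloor t/\Delta\rfloor)} with
#'   \eqn{\Delta} = \code{cfg$anneal_interval}.
#' @export
beta_at <- function(t, cfg) {
  cfg$beta0 * exp(-cfg$lambda_decay * cfg$anneal_interval *
                    floor(t / cfg$anneal_interval))
}

#' Initialize a population of synapses
#'
#' Synaptic parameters are drawn from a Gaussian with mean
#' \code{cfg$theta_init_mean} and variance \code{cfg$theta_init_var}; draws
#' below zero are set to zero (such synapses start retracted, since the
#' weight projection maps \eqn{\theta \le 0} to 0). The fast traces start
#' quiescent and weights are set by the projection.
#'
#' @param n number of synapses, > 0.
#' @param cfg a [spore_config()].
#' @param seed optional integer; when given, the draw is made reproducible
#'   with [set.seed()] (otherwise the current RNG stream is used).
#' @return A data.frame with columns \code{y}, \code{e}, \code{g},
#'   \code{theta}, \code{w} and attribute \code{theta_raw} holding the
#'   pre-clip draws.
#' @export
init_parameters <- function(n, cfg, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("init_parameters: n must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  raw <- stats::rnorm(n, cfg$theta_init_mean, sqrt(cfg$theta_init_var))
  theta <- pmax(raw, 0)
  out <- data.frame(y = numeric(n), e = numeric(n), g = numeric(n),
                    theta = theta, w = parameter_to_weight(theta, cfg))
  attr(out, "theta_raw") <- raw
  out
}

#' Simulate the parameter SDE with a frozen likelihood
#'
#' Iterates [update_parameter()] with the reward-gradient term held at zero,
#' which reduces the slow dynamics to an Ornstein-Uhlenbeck process with
#' mean \code{cfg$mu} and stationary variance \code{temperature / c_p}.
#' Used to check that the sampler reproduces its target prior.
#'
#' @param n_synapses number of independent synapses.
#' @param n_steps number of slow steps to take after burn-in.
#' @param beta learning rate used for every step.
#' @param cfg a [spore_config()] (its \code{c_p} must be > 0 for a
#'   stationary distribution to exist).
#' @param burn_in number of initial steps discarded.
#' @param keep_every thin the recorded trajectory to every so-many steps
#'   (moments are always accumulated over every post-burn-in step).
#' @return A list with \code{mean} and \code{var} (pooled over all synapses
#'   and post-burn-in steps), \code{n} (number of pooled samples), and
#'   \code{trajectory}, a thinned matrix with one column per synapse.
#' @export
sample_stationary_parameters <- function(n_synapses, n_steps, beta, cfg,
                                         burn_in = 0, keep_every = 100L) {
  stopifnot(n_synapses >= 1, n_steps >= 1, burn_in >= 0, keep_every >= 1)
  theta <- rep(cfg$mu, n_synapses)
  g <- numeric(n_synapses)
  for (i in seq_len(burn_in))
    theta <- update_parameter(theta, g, beta, stats::rnorm(n_synapses), cfg)
  n_rec <- n_steps %/% keep_every
  rec <- matrix(NA_real_, n_rec, n_synapses)
  s1 <- 0; s2 <- 0; j <- 0L
  for (i in seq_len(n_steps)) {
    theta <- update_parameter(theta, g, beta, stats::rnorm(n_synapses), cfg)
    s1 <- s1 + sum(theta)
    s2 <- s2 + sum(theta * theta)
    if (i %% keep_every == 0L) {
      j <- j + 1L
      rec[j, ] <- theta
    }
  }
  n_tot <- as.numeric(n_steps) * n_synapses
  m <- s1 / n_tot
  list(mean = m, var = s2 / n_tot - m * m, n = n_tot, trajectory = rec)
}
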