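#' Low-pass filtered motor activity
#'
#' Motor spike trains are turned into graded activities by an exponential
#' low-pass filter with time constant \code{tau}: exact decay
#' \eqn{a \leftarrow a\,e^{-dt/\tau}} plus a unit jump per spike.
#'
#' @param a current activity vector, non-negative.
#' @param spikes logical/0-1 spike indicators, same length.
#' @param dt step length, seconds, > 0.
#' @param tau filter time constant, seconds (100 ms by default).
#' @return Updated activity vector.
#' @export
lowpass_activity <- function(a, spikes, dt, tau = 0.1) {
  stopifnot(dt > 0, tau > 0)
  a * exp(-dt / tau) + as.numeric(spikes)
}

#' Population-vector velocity decoder
#'
#' N motor neurons are placed evenly on the unit circle at angles
#' \eqn{\beta_k = 2k\pi/N}, \eqn{k = 1 \dots N}; the decoded planar
#' velocity is the activity-weighted sum of their unit vectors:
#' \eqn{\dot x = \sum_k \cos(\beta_k) a_k},
#' \eqn{\dot y = \sum_k \sin(\beta_k) a_k}. Linear in the activities; a
#' uniform activity vector decodes to zero by symmetry.
#'
#' @param a motor activity vector (length N).
#' @return \code{c(xdot, ydot)}.
#' @export
decode_velocity <- function(a) {
  n <- length(a)
  beta <- 2 * seq_len(n) * pi / n
  c(sum(cos(beta) * a), sum(sin(beta) * a))
}

#' Ratio-based discrete steering decoder
#'
#' The motor layer is split into a left half (first N/2 activities) and a
#' right half; the decoder forms the normalized difference
#' \eqn{(a_L - a_R)/(a_L + a_R)}, expresses it on a percent scale
#' (\code{cod$steer_scale} = 100 by default, since the printed decision
#' boundaries exceed the raw ratio's \code{[-1, 1]} range), and maps it
#' through the boundaries \code{\{-10, -2.5, 2.5, 10\}} to one of five
#' commands: hard left (-30), left (-15), straight (0), right (15), hard
#' right (30) degrees. A dominant left population steers left (negative
#' angle) under the default sign convention. Zero total activity maps to
#' straight. Scale-invariant in the activities; swapping the two halves
#' negates the command.
#'
#' @param a motor activity vector of even length.
#' @param cod a [codec_config()].
#' @return A steering angle, degrees, one of \code{cod$steer_angles}.
#' @export
decode_steering <- function(a, cod = codec_config()) {
  n <- length(a)
  if (n %% 2L != 0L) stop("decode_steering: activity length must be even")
  a_l <- sum(a[seq_len(n %/% 2L)])
  a_r <- sum(a[(n %/% 2L + 1L):n])
  tot <- a_l + a_r
  ratio <- if (tot == 0) 0 else cod$steer_scale * (a_l - a_r) / tot
  cod$steer_angles[findInterval(ratio, cod$steer_boundaries,
                                left.open = TRUE) + 1L]
}

#' Exponentially smoothed reward stream
#'
#' First-order filter \eqn{r_s \leftarrow r_s + (dt/\tau_r)(r - r_s)}
#' applied to the raw reward before it is streamed to every synapse as the
#' single global reward signal.
#'
#' @param r_raw raw reward, >= 0.
#' @param r_smooth current smoothed value.
#' @param dt step length, seconds.
#' @param tau_r filter time constant, seconds, > 0.
#' @return Updated smoothed reward.
#' @export
smooth_reward <- function(r_raw, r_smooth, dt, tau_r = 0.1) {
  stopifnot(tau_r > 0, dt > 0)
  r_smooth + (dt / tau_r) * (r_raw - r_smooth)
}
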