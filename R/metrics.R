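#' Target-reach rate per time window
#'
#' Counts reset events (the ball reaching the target, or the vehicle
#' leaving the track) in tiled half-open windows
#' \code{[k*window, (k+1)*window)}. An event exactly on a boundary counts
#' toward the later window. The final, possibly partial, window is
#' included.
#'
#' @param x a \code{spore_run} or a numeric vector of reset times.
#' @param window window length, seconds, > 0.
#' @param duration total duration covered (taken from the run when \code{x}
#'   is a \code{spore_run}).
#' @return A data.frame with \code{window_start} and \code{count}.
#' @export
reach_rate <- function(x, window = 250, duration = NULL) {
  stopifnot(window > 0)
  if (inherits(x, "spore_run")) {
    duration <- x$duration
    x <- x$resets
  }
  if (is.null(duration)) duration <- if (length(x)) max(x) else window
  starts <- seq(0, by = window,
                length.out = max(1L, ceiling(duration / window)))
  idx <- findInterval(x, starts)          # [start, next_start)
  data.frame(window_start = starts,
             count = tabulate(idx, nbins = length(starts)))
}

#' Count weak synaptic weights
#'
#' Number of weights strictly below the threshold. Retracted synapses
#' (parameter at or below zero, hence weight exactly 0) are always
#' counted as weak. The default threshold is the one used to track
#' sparsification of the learned networks.
#'
#' @param weights numeric vector or matrix of non-negative weights, or a
#'   \code{spore_run} (its final weights are used).
#' @param threshold weakness threshold.
#' @return Integer count.
#' @export
weak_weight_count <- function(weights, threshold = 0.07) {
  if (inherits(weights, "spore_run")) weights <- weights$topology$w
  if (length(weights) == 0) stop("weak_weight_count: empty snapshot")
  sum(weights < threshold)
}

#' Fraction of active synapses, integer percent
#'
#' \code{100 * (total - weak) / total}, rounded to the nearest integer
#' percent for reporting.
#'
#' @param total total synapse count, > 0.
#' @param weak weak-synapse count, \code{0 <= weak <= total}.
#' @return Integer percent.
#' @export
active_fraction <- function(total, weak) {
  if (total <= 0 || weak < 0 || weak > total)
    stop("active_fraction: need 0 <= weak <= total, total > 0")
  round(100 * (total - weak) / total)
}

#' Per-pixel policy vector field of a reaching network
#'
#' For every sensor pixel, the motion that an event at that pixel
#' contributes: the sum over motor neurons of the summed synaptic weight
#' from the pixel (over the synapse multiplicity, plus the pixel's row-axis
#' and column-axis neuron weights) times the motor neuron's unit vector on
#' the circle. The angular correctness of a pixel is the cosine of the
#' angle between its vector and the direction from the pixel toward the
#' frame center (\code{NA} where that direction or the vector is
#' undefined, e.g. a pixel exactly at the center or a zero vector).
#'
#' @param x a \code{spore_run} from a reaching experiment, or a
#'   \code{spore_topology} of task \code{"reaching"}.
#' @return A data.frame with one row per pixel: \code{px}, \code{py}
#'   (1-based column/row), \code{vx}, \code{vy}, \code{correctness}.
#' @export
policy_map <- function(x) {
  topo <- if (inherits(x, "spore_run")) x$topology else x
  if (!inherits(topo, "spore_topology") || topo$task != "reaching")
    stop("policy_map: needs a reaching topology")
  n_px <- topo$geom$n_px
  n_motor <- topo$n_motor
  # per (input, motor) weight summed over the multiplicity
  wbar <- matrix(0, topo$n_input, n_motor)
  for (k in seq_len(topo$multiplicity)) {
    rows <- (k - 1L) * topo$n_input + seq_len(topo$n_input)
    wbar <- wbar + topo$w[rows, , drop = FALSE]
  }
  beta <- 2 * seq_len(n_motor) * pi / n_motor
  has_axis <- topo$n_axis > 0
  out <- data.frame(px = integer(n_px^2), py = integer(n_px^2),
                    vx = numeric(n_px^2), vy = numeric(n_px^2),
                    correctness = numeric(n_px^2))
  center <- (n_px + 1) / 2
  i <- 0L
  for (py in seq_len(n_px)) {
    for (px in seq_len(n_px)) {
      i <- i + 1L
      wp <- wbar[(py - 1L) * n_px + px, ]
      if (has_axis)
        wp <- wp + wbar[n_px^2 + py, ] + wbar[n_px^2 + n_px + px, ]
      v <- c(sum(cos(beta) * wp), sum(sin(beta) * wp))
      # plane coords: +x right, +y up; sensor row 1 is the top row, so the
      # pixel sits at plane position ~ (px - center, center - py) and the
      # direction toward the center is its negation
      dir <- c(center - px, py - center)
      vn <- sqrt(sum(v * v)); dn <- sqrt(sum(dir * dir))
      corr <- if (vn == 0 || dn == 0) NA_real_ else
        sum(v * dir) / (vn * dn)
      out[i, ] <- list(px, py, v[1], v[2], corr)
    }
  }
  out
}

#' Mean continuous time on track between resets
#'
#' For lane runs: the average spacing between consecutive resets (episode
#' boundaries as seen by the analyst, not the network), with the leading
#' segment from t = 0 included.
#'
#' @param run a \code{spore_run}.
#' @return Mean time on track, seconds (the full duration if no reset
#'   occurred).
#' @export
time_on_track <- function(run) {
  stopifnot(inherits(run, "spore_run"))
  r <- run$resets
  if (length(r) == 0) return(run$duration)
  mean(diff(c(0, r)))
}
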