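#' Event-camera frame difference
#'
#' Simulates a dynamic vision sensor on rendered intensity frames: a pixel
#' emits one ON event when its intensity rises more than \code{threshold}
#' above its per-pixel reference level, one OFF event when it falls more
#' than \code{threshold} below it, and nothing otherwise. Where an event is
#' emitted the reference resets to the current intensity (per-pixel
#' memory); elsewhere it is kept, so slow drifts accumulate until they
#' cross the threshold. Thresholding is on linear intensity and at most
#' one event per pixel per frame is emitted.
#'
#' @param ref reference intensity frame (matrix, rows = sensor rows).
#' @param curr current intensity frame, same shape, values in \code{[0,1]}.
#' @param threshold positive intensity-change threshold.
#' @param t time stamp attached to the events, seconds.
#' @return A list: \code{events}, a data.frame with 0-based coordinates
#'   \code{x} (column), \code{y} (row, origin top-left), \code{polarity}
#'   (+1 ON / -1 OFF) and \code{t}; and \code{ref}, the updated reference
#'   frame.
#' @export
dvs_frame_diff <- function(ref, curr, threshold, t = 0) {
  if (!all(dim(ref) == dim(curr)))
    stop("dvs_frame_diff: frame shape mismatch")
  stopifnot(threshold > 0)
  d <- curr - ref
  on <- which(d > threshold)
  off <- which(d < -threshold)
  idx <- c(on, off)
  pol <- c(rep(1L, length(on)), rep(-1L, length(off)))
  ref[idx] <- curr[idx]
  nr <- nrow(ref)
  events <- data.frame(x = ((idx - 1L) %/% nr),
                       y = ((idx - 1L) %% nr),
                       polarity = pol,
                       t = rep(t, length(idx)))
  list(events = events, ref = ref)
}

#' Encode events as reaching-task input spikes
#'
#' Each address event (polarity ignored) produces one spike on the visual
#' neuron of its pixel, one on the axis neuron of its row and one on the
#' axis neuron of its column — exactly three spikes per event. Returned as
#' per-neuron spike counts for one fast step, in the input ordering used by
#' the reaching topology: pixels in row-major order (rows scan fastest
#' along columns), then the row-axis neurons, then the column-axis
#' neurons.
#'
#' @param events event data.frame from [dvs_frame_diff()].
#' @param n_px sensor side length, pixels.
#' @return Numeric vector of spike counts, length \code{n_px^2 + 2 n_px}.
#' @export
encode_reaching_spikes <- function(events, n_px = 16) {
  if (nrow(events) > 0 &&
      (any(events$x < 0) || any(events$x >= n_px) ||
       any(events$y < 0) || any(events$y >= n_px)))
    stop("encode_reaching_spikes: event out of sensor bounds")
  counts <- numeric(n_px^2 + 2L * n_px)
  if (nrow(events) == 0) return(counts)
  pix <- events$y * n_px + events$x + 1L          # row-major pixel index
  row_axis <- n_px^2 + events$y + 1L
  col_axis <- n_px^2 + n_px + events$x + 1L
  tab <- tabulate(c(pix, row_axis, col_axis), nbins = length(counts))
  counts + tab
}

#' Encode events as lane-task visual firing rates
#'
#' The sensor is partitioned into non-overlapping square windows
#' (8 x 8 pixels by default, so a 128 x 32 sensor maps to 16 x 4 = 64
#' visual neurons). Each visual neuron's rate is \code{gain} times the
#' number of events inside its window, capped at \code{rho_max}. Spikes
#' are drawn from these rates by the caller via [sample_spikes()].
#'
#' @param events event data.frame from [dvs_frame_diff()].
#' @param env a [lane_config()].
#' @param gain firing rate per event, Hz.
#' @param rho_max rate cap, Hz.
#' @return Numeric rate vector, one entry per window, windows in row-major
#'   order (left-to-right, then top-to-bottom).
#' @export
encode_lane_rates <- function(events, env = lane_config(),
                              gain = env$rate_gain, rho_max = 500) {
  if (nrow(events) > 0 &&
      (any(events$x < 0) || any(events$x >= env$width_px) ||
       any(events$y < 0) || any(events$y >= env$height_px)))
    stop("encode_lane_rates: event out of sensor bounds")
  nwx <- env$width_px %/% env$window_px
  nwy <- env$height_px %/% env$window_px
  n <- nwx * nwy
  if (nrow(events) == 0) return(numeric(n))
  wx <- events$x %/% env$window_px
  wy <- events$y %/% env$window_px
  idx <- wy * nwx + wx + 1L
  pmin(gain * tabulate(idx, nbins = n), rho_max)
}
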