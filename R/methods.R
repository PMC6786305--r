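#' @export
print.spore_run <- function(x, ...) {
  cat(sprintf("Closed-loop synaptic-sampling run (%s task)\n", x$task))
  cat(sprintf("  %g simulated s, seed %d, engine '%s'\n",
              x$duration, as.integer(x$seed), x$engine))
  cat(sprintf("  %d plastic synapses, %d slow updates, %d resets\n",
              x$topology$n_plastic, x$n_slow_updates, length(x$resets)))
  cat(sprintf("  final learning rate: %g\n", x$beta_final))
  invisible(x)
}

#' Summarize a closed-loop run
#'
#' Reports the task metrics: reach/reset rate per window, mean reward,
#' weak-weight counts at the first and last snapshot, and the active
#' synapse percentage.
#'
#' @param object a \code{spore_run}.
#' @param window reporting window for the reset rate, seconds.
#' @param weak_threshold weight threshold below which a synapse counts as
#'   weak.
#' @param ... unused.
#' @return An object of class \code{summary.spore_run}.
#' @export
summary.spore_run <- function(object, window = 250, weak_threshold = 0.07,
                              ...) {
  rr <- reach_rate(object, window = window)
  weak_first <- sum(object$snapshots$w[, 1] < weak_threshold)
  weak_last <- weak_weight_count(object$topology$w, weak_threshold)
  out <- list(task = object$task, duration = object$duration,
              seed = object$seed,
              n_resets = length(object$resets),
              reach_rate = rr,
              mean_reward = if (nrow(object$log)) mean(object$log$reward)
                            else NA_real_,
              weak_first = weak_first, weak_last = weak_last,
              n_plastic = object$topology$n_plastic,
              active_percent = active_fraction(object$topology$n_plastic,
                                               weak_last),
              time_on_track = if (object$task == "lane")
                time_on_track(object) else NA_real_)
  class(out) <- "summary.spore_run"
  out
}

#' @export
print.summary.spore_run <- function(x, ...) {
  cat(sprintf("%s run, %g s (seed %d)\n", x$task, x$duration,
              as.integer(x$seed)))
  cat(sprintf("  resets: %d; mean reward: %.4g\n", x$n_resets,
              x$mean_reward))
  if (x$task == "lane")
    cat(sprintf("  mean time on track: %.1f s\n", x$time_on_track))
  cat(sprintf("  weak weights (< 0.07): %d -> %d of %d (%d%% active)\n",
              x$weak_first, x$weak_last, x$n_plastic, x$active_percent))
  cat("  resets per window:\n")
  print(x$reach_rate, row.names = FALSE)
  invisible(x)
}

#' Final synaptic weights of a run
#'
#' @param object a \code{spore_run}.
#' @param ... unused.
#' @return Numeric vector of the final plastic weights.
#' @export
coef.spore_run <- function(object, ...) {
  as.numeric(object$topology$w)
}

#' Plot the reward trace and weight distribution of a run
#'
#' Left panel: raw reward over simulated time (thinned) with reset times
#' marked. Right panel: histogram of the final synaptic weights with the
#' weak-weight threshold.
#'
#' @param x a \code{spore_run}.
#' @param weak_threshold threshold drawn on the weight histogram.
#' @param ... passed to [graphics::plot()].
#' @return \code{x}, invisibly.
#' @export
plot.spore_run <- function(x, weak_threshold = 0.07, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lg <- x$log
  if (nrow(lg) > 5000) lg <- lg[seq(1, nrow(lg), length.out = 5000), ]
  graphics::plot(lg$t, lg$reward, type = "l", xlab = "time [s]",
                 ylab = "reward", main = paste(x$task, "reward"), ...)
  if (length(x$resets))
    graphics::abline(v = x$resets, col = "#d0d0d0")
  w <- coef(x)
  graphics::hist(w, breaks = 40, main = "final weights",
                 xlab = "synaptic weight")
  graphics::abline(v = weak_threshold, col = "red", lty = 2)
  invisible(x)
}
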