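#' Write a weight snapshot with a manifest
#'
#' Stores the weight snapshots of a run as a plain-text array file (one
#' column per snapshot time) next to a JSON manifest carrying the time
#' stamps, the seed, and a hash of the configuration, so stored arrays can
#' be matched to the run that produced them.
#'
#' @param run a \code{spore_run}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_snapshots <- function(run, dir) {
  stopifnot(inherits(run, "spore_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$snapshots$w,
                     file.path(dir, "weights.tsv"),
                     sep = "\t", row.names = FALSE,
                     col.names = sprintf("t%g", run$snapshots$t))
  manifest <- list(task = run$task, seed = run$seed,
                   duration = run$duration,
                   snapshot_times = run$snapshots$t,
                   n_plastic = run$topology$n_plastic,
                   config_hash = config_hash(run$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write the metrics log of a run to CSV
#'
#' @param run a \code{spore_run}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics <- function(run, path) {
  stopifnot(inherits(run, "spore_run"))
  lg <- run$log
  lg$reset <- lg$t %in% run$resets
  utils::write.csv(lg, path, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  # small stable polynomial checksum; avoids a digest dependency
  h <- 17
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
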