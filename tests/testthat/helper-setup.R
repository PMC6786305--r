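# Shared fixtures: small, fast configurations built in code.

default_cfg <- spore_config()

# tiny reaching setup used where full sizes are not the point
tiny_reaching <- function(beta0 = 1e-3) {
  list(spore = spore_config(beta0 = beta0, c_p = 0),
       net = network_config(n_motor = 4, multiplicity = 2),
       env = reaching_config(n_px = 8))
}

# small lane setup with a short track discretization for quick runs
tiny_lane <- function() {
  list(spore = spore_config(),
       net = network_config(multiplicity = 1, exploration = FALSE),
       env = lane_config(n_track = 1200))
}

# run both engines on identical settings and return the pair
run_both <- function(task, duration, seed, ...) {
  list(cpp = run_experiment(task, duration = duration, seed = seed,
                            engine = "cpp", ...),
       r = run_experiment(task, duration = duration, seed = seed,
                          engine = "r", ...))
}
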