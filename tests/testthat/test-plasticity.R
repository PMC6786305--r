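cfg <- spore_config()

test_that("PSP trace decays by Euler and jumps by one per spike", {
  expect_equal(update_psp_trace(1, FALSE, cfg), 0.95)   # 1 - 1/20
  expect_equal(update_psp_trace(0, FALSE, cfg), 0)
  expect_equal(update_psp_trace(0, TRUE, cfg), 1)
  # vectorized over synapses, counts allowed
  expect_equal(update_psp_trace(c(1, 0), c(0, 2), cfg), c(0.95, 2))
  expect_error(update_psp_trace(-0.1, FALSE, cfg), "non-negative")
})

test_that("eligibility update matches the hand-computed Euler step", {
  expect_equal(update_eligibility(e = 0.2, w = 1, y = 0.5,
                                  post_spike = TRUE, rho_post = 10, cfg),
               0.2 - 1e-4 + 0.5 * (1 - 0.01))           # 0.6949
  expect_equal(update_eligibility(1, w = 1, y = 0, FALSE, 0, cfg), 0.9995)
  expect_equal(update_eligibility(0, 1, 0, FALSE, 0, cfg), 0)
  expect_error(update_eligibility(0, 1, 0, FALSE, -1, cfg), "rho_post")
})

test_that("eligibility decays as exp(-t/tau_e) when the synapse is silent", {
  e <- 1
  n <- round(cfg$tau_e / cfg$dt_fast)
  for (i in seq_len(n))
    e <- update_eligibility(e, w = 1, y = 0, FALSE, 0, cfg)
  expect_equal(e, exp(-1), tolerance = 1e-3)
})

test_that("reward-gradient estimate integrates r*e and finds its fixed point", {
  expect_equal(update_reward_gradient(0, r = 0.5, e = 0.2, cfg), 1e-4)
  expect_equal(update_reward_gradient(0, 0, 0, cfg), 0)
  expect_error(update_reward_gradient(0, -0.1, 1, cfg), "non-negative")
  # constant drive r*e = 0.1 -> g converges to tau_g * r * e = 5
  g <- 0
  for (i in seq_len(round(400 / cfg$dt_fast)))
    g <- update_reward_gradient(g, r = 0.5, e = 0.2, cfg)
  expect_equal(g, cfg$tau_g * 0.5 * 0.2, tolerance = 1e-2)
})

test_that("parameter update drifts, diffuses and clips as specified", {
  c1 <- spore_config(c_p = 1, c_g = 1, mu = 0, temperature = 0)
  # fixed point of the drift
  expect_equal(update_parameter(0, g = 0, beta = 0.01, noise = 0, c1), 0)
  # drift-only Euler step with unclipped gradient
  c2 <- spore_config(c_p = 1, c_g = 1, mu = 0, temperature = 0,
                     dtheta_max = 5)
  expect_equal(update_parameter(1, g = 2, beta = 0.01, noise = 0, c2),
               1.001)
  # gradient clipping at dtheta_max changes the same step
  expect_equal(update_parameter(1, g = 2, beta = 0.01, noise = 0, c1), 1)
  # parameter clipping at theta_max
  big <- update_parameter(4.999, g = 0, beta = 1, noise = 100,
                          spore_config(temperature = 1))
  expect_equal(big, cfg$theta_max)
  expect_error(update_parameter(0, 0, 0.01, NaN, cfg), "finite")
})

test_that("weight projection is exponential above zero and zero below", {
  expect_equal(parameter_to_weight(-0.5, cfg), 0)
  expect_equal(parameter_to_weight(0, cfg), 0)
  c3 <- spore_config(w0 = 0.7, theta0 = 1.2)
  expect_equal(parameter_to_weight(1.2, c3), 0.7)
  expect_equal(parameter_to_weight(log(2), cfg), 2)
  # monotone non-decreasing over a grid spanning the clip range
  th <- seq(-2, 5, by = 0.01)
  w <- parameter_to_weight(th, cfg)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w[th <= 0] == 0))
  expect_true(all(w >= 0))
})

test_that("learning-rate annealing follows the stepped exponential decay", {
  # ~3 h of decay brings beta to 40% of its initial value
  expect_equal(round(100 * beta_at(10800, cfg) / cfg$beta0), 40)
  expect_equal(beta_at(600, cfg) / cfg$beta0, exp(-8.5e-5 * 600),
               tolerance = 1e-7)
  c0 <- spore_config(lambda_decay = 0)
  expect_equal(beta_at(c(0, 599, 10 * 3600), c0), rep(c0$beta0, 3))
  # piecewise-constant between boundaries, exact on the closed form
  tt <- seq(0, 7200, by = 50)
  b <- beta_at(tt, cfg)
  expect_true(all(diff(b) <= 0))
  expect_equal(b, cfg$beta0 * exp(-cfg$lambda_decay * 600 *
                                    floor(tt / 600)))
  # the stateful schedule agrees with the closed form
  sched <- anneal_schedule(cfg)
  for (t_now in c(0, 100, 600, 601, 1800, 10800)) {
    sched <- anneal_learning_rate(sched, t_now, cfg)
    expect_equal(sched$beta_t, beta_at(t_now, cfg))
  }
})

test_that("parameter initialization draws, clips and starts quiescent", {
  syn <- init_parameters(1e5, cfg, seed = 42)
  raw <- attr(syn, "theta_raw")
  sdev <- sqrt(cfg$theta_init_var)
  expect_equal(mean(raw), cfg$theta_init_mean,
               tolerance = 3 * sdev / sqrt(1e5) / 0.8)
  expect_true(any(raw < 0))
  expect_true(all(syn$theta >= 0))
  expect_equal(syn$theta[raw < 0], rep(0, sum(raw < 0)))
  expect_equal(syn$w, parameter_to_weight(syn$theta, cfg))
  one <- init_parameters(1, cfg, seed = 1)
  expect_equal(unlist(one[, c("y", "e", "g")]), c(y = 0, e = 0, g = 0))
  # reproducible
  expect_equal(init_parameters(10, cfg, seed = 7),
               init_parameters(10, cfg, seed = 7),
               ignore_attr = TRUE)
  expect_error(init_parameters(0, cfg), "positive")
})

test_that("weights stay frozen between slow updates (two-timescale contract)", {
  set.seed(3)
  setup <- tiny_reaching()
  topo <- build_reaching_network(setup$spore, setup$net, setup$env)
  st <- network_state(topo)
  w0 <- topo$w
  for (n in 1:250) {
    input <- rbinom(topo$n_input, 1, 0.05)
    out <- step_network(topo, st, input, setup$spore, setup$net, reward = 0.1)
    st <- out$state
    expect_identical(topo$w, w0)    # fast steps never touch w
    if (n %% 100 == 0) {            # slow grid: parameters and weights move
      topo$theta <- update_parameter(topo$theta, st$g, 0.05,
                                     matrix(rnorm(topo$n_plastic),
                                            nrow(topo$theta)),
                                     setup$spore)
      topo$w <- parameter_to_weight(topo$theta, setup$spore)
      dim(topo$w) <- dim(topo$theta)
      expect_false(identical(topo$w, w0))
      w0 <- topo$w
    }
  }
})
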