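test_that("timing arithmetic: samples, slow updates, empty runs", {
  setup <- tiny_reaching()
  run <- run_experiment("reaching", duration = 10, seed = 1,
                        spore = setup$spore, net = setup$net,
                        env = setup$env)
  expect_equal(nrow(run$log), 10000)     # one reward sample per 1 ms
  expect_equal(run$n_slow_updates, 100)  # one parameter update per 100 ms
  expect_equal(run$log$t[1], 0.001)
  expect_equal(run$log$t[nrow(run$log)], 10)
  empty <- run_experiment("reaching", duration = 0, seed = 1,
                          spore = setup$spore, net = setup$net,
                          env = setup$env)
  expect_equal(nrow(empty$log), 0)
  expect_length(empty$snapshots$t, 1)    # initial snapshot only
  expect_equal(empty$n_slow_updates, 0)
})

test_that("identical seeds give bit-identical runs", {
  setup <- tiny_reaching()
  r1 <- run_experiment("reaching", duration = 5, seed = 42,
                       spore = setup$spore, net = setup$net,
                       env = setup$env)
  r2 <- run_experiment("reaching", duration = 5, seed = 42,
                       spore = setup$spore, net = setup$net,
                       env = setup$env)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$resets, r2$resets)
  expect_identical(r1$topology$w, r2$topology$w)
  r3 <- run_experiment("reaching", duration = 5, seed = 43,
                       spore = setup$spore, net = setup$net,
                       env = setup$env)
  expect_false(identical(r1$log$reward, r3$log$reward))
})

test_that("compiled engine reproduces the pure-R reference loop", {
  setup <- tiny_reaching()
  pair <- run_both("reaching", duration = 2, seed = 5,
                   spore = setup$spore, net = setup$net, env = setup$env)
  expect_equal(pair$cpp$topology$w, pair$r$topology$w, tolerance = 1e-9)
  expect_equal(pair$cpp$final_traces$e, pair$r$final_traces$e,
               tolerance = 1e-9)
  expect_equal(pair$cpp$log$reward, pair$r$log$reward, tolerance = 1e-9)
  expect_identical(length(pair$cpp$resets), length(pair$r$resets))

  lane <- tiny_lane()
  pair2 <- run_both("lane", duration = 2, seed = 6, spore = lane$spore,
                    net = lane$net, env = lane$env)
  expect_equal(pair2$cpp$topology$w, pair2$r$topology$w, tolerance = 1e-9)
  expect_equal(pair2$cpp$log$reward, pair2$r$log$reward, tolerance = 1e-9)
  expect_equal(pair2$cpp$final_traces$g, pair2$r$final_traces$g,
               tolerance = 1e-9)
})

test_that("reach rate uses tiled half-open windows", {
  expect_equal(reach_rate(numeric(0), 250, duration = 1000)$count,
               rep(0, 4))
  rr <- reach_rate(c(10, 20, 100, 200, 249.9), 250, duration = 500)
  expect_equal(rr$count, c(5, 0))
  expect_equal(rr$window_start, c(0, 250))
  # an event exactly on the boundary belongs to the later window
  expect_equal(reach_rate(c(250), 250, duration = 500)$count, c(0, 1))
  # partial final window is reported
  expect_equal(nrow(reach_rate(c(1), 250, duration = 300)), 2)
})

test_that("weak-weight counting uses a strict threshold", {
  expect_equal(weak_weight_count(c(0.05, 0.07, 0.1)), 1)
  expect_equal(weak_weight_count(rep(0, 12)), 12)
  expect_equal(weak_weight_count(c(0, 0.5, 1), threshold = 0), 0)
  expect_error(weak_weight_count(numeric(0)), "empty")
})

test_that("active fraction reproduces the published percentages", {
  expect_equal(active_fraction(23040, 14753), 36)
  expect_equal(active_fraction(512, 342), 33)
  expect_equal(active_fraction(100, 0), 100)
  expect_error(active_fraction(10, 11), "weak")
  expect_error(active_fraction(0, 0), "total")
})

test_that("policy map sums synapse and axis contributions per pixel", {
  cfg <- spore_config()
  topo <- build_reaching_network(cfg,
                                 network_config(n_motor = 4,
                                                multiplicity = 1,
                                                exploration = FALSE),
                                 reaching_config(n_px = 4), seed = 1)
  topo$w[] <- 0
  pm0 <- policy_map(topo)
  expect_true(all(pm0$vx == 0 & pm0$vy == 0))
  expect_true(all(is.na(pm0$correctness)))
  # single synapse pixel (2,3) -> motor 4 (angle 2*pi = (1, 0)) weight 0.8
  topo$w[(3 - 1) * 4 + 2, 4] <- 0.8
  pm <- policy_map(topo)
  row <- pm[pm$px == 2 & pm$py == 3, ]
  expect_equal(c(row$vx, row$vy), c(0.8, 0), tolerance = 1e-12)
  # axis-neuron weights add to every pixel in their row/column
  topo$w[4^2 + 3, 4] <- 0.2              # row-axis neuron of row 3
  pm2 <- policy_map(topo)
  row2 <- pm2[pm2$px == 2 & pm2$py == 3, ]
  expect_equal(row2$vx, 1.0, tolerance = 1e-12)
  # a vector pointing straight at the center has correctness 1
  # pixel (1, 3): center direction = (center - 1, 3 - center) = (1.5, 0.5)
  topo$w[] <- 0
  topo$w[(3 - 1) * 4 + 1, 4] <- 3 * 0.4  # +x motor
  topo$w[(3 - 1) * 4 + 1, 1] <- 0.4      # +y motor (angle pi/2)
  pm3 <- policy_map(topo)
  row3 <- pm3[pm3$px == 1 & pm3$py == 3, ]
  expect_equal(row3$correctness, 1, tolerance = 1e-12)
  expect_error(policy_map(build_lane_network(seed = 1)), "reaching")
})

test_that("summary, coef, print and time-on-track report run metrics", {
  lane <- tiny_lane()
  run <- run_experiment("lane", duration = 3, seed = 2, spore = lane$spore,
                        net = lane$net, env = lane$env, record_dt = 0.01)
  s <- summary(run)
  expect_s3_class(s, "summary.spore_run")
  expect_equal(s$n_plastic, 512)
  expect_equal(s$active_percent,
               active_fraction(512, weak_weight_count(run)))
  expect_length(coef(run), 512)
  expect_true(all(coef(run) >= 0))
  expect_output(print(run), "lane task")
  expect_output(print(s), "weak weights")
  expect_equal(time_on_track(run),
               if (length(run$resets)) mean(diff(c(0, run$resets)))
               else run$duration)
  # reward of the lane task is bounded in [0, 1]
  expect_true(all(run$log$reward >= 0 & run$log$reward <= 1))
})

test_that("snapshots and metrics round-trip through their file formats", {
  setup <- tiny_reaching()
  run <- run_experiment("reaching", duration = 1, seed = 3,
                        spore = setup$spore, net = setup$net,
                        env = setup$env, record_dt = 0.1)
  dir <- withr::local_tempdir()
  write_snapshots(run, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$task, "reaching")
  expect_equal(man$n_plastic, run$topology$n_plastic)
  w <- utils::read.delim(file.path(dir, "weights.tsv"))
  expect_equal(nrow(w), run$topology$n_plastic)
  csv <- file.path(dir, "metrics.csv")
  write_metrics(run, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(run$log))
})

test_that("annealing retains the policy: late weight drift shrinks", {
  # constant-beta comparator matched to the annealed run's mean
  # exploration budget (time-averaged learning rate)
  lam <- 1.5e-3
  mean_beta <- 1e-3 * mean(exp(-lam * 600 * 0:2))
  late_drift <- function(run) {
    w <- run$snapshots$w
    n <- ncol(w)
    mean(abs(w[, n] - w[, n - 5]))
  }
  net <- network_config(n_motor = 4, multiplicity = 2)
  env <- reaching_config(n_px = 8)
  for (seed in 1:2) {
    annealed <- run_experiment("reaching", duration = 1800, seed = seed,
                               spore = spore_config(beta0 = 1e-3, c_p = 0,
                                                    lambda_decay = lam),
                               net = net, env = env, anneal = TRUE,
                               record_dt = 1)
    constant <- run_experiment("reaching", duration = 1800, seed = seed,
                               spore = spore_config(beta0 = mean_beta,
                                                    c_p = 0),
                               net = net, env = env, anneal = FALSE,
                               record_dt = 1)
    expect_lt(late_drift(annealed), late_drift(constant))
    # annealing followed the stepped exponential during the run
    expect_equal(annealed$beta_final,
                 1e-3 * exp(-lam * 600 * floor(1800 / 600)))
  }
})
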