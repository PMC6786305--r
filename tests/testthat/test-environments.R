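env_r <- reaching_config()
rw <- reward_config()

test_that("ball kinematics: Euler integration, wall clamping, target reset", {
  st <- reaching_state(env_r, pos = c(5, 0))
  out <- reaching_step(st, c(0, 0), 0.1, env_r)
  expect_equal(out$state$pos, c(5, 0))
  expect_false(out$reset)
  out <- reaching_step(st, c(1, 0), 0.1, env_r)
  expect_equal(out$state$pos, c(5.1, 0))
  # walls: ball center clamped to plane_half - ball_radius
  st2 <- reaching_state(env_r, pos = c(7.9, 0))
  out2 <- reaching_step(st2, c(100, 0), 0.1, env_r)
  expect_equal(out2$state$pos[1], env_r$plane_half - env_r$ball_radius)
  # entering the target disc resets to a random in-bounds position
  set.seed(21)
  st3 <- reaching_state(env_r, pos = c(0, 2.05))
  out3 <- reaching_step(st3, c(0, -1), 0.1, env_r)
  expect_true(out3$reset)
  expect_true(all(abs(out3$state$pos) <=
                    env_r$plane_half - env_r$ball_radius))
  expect_gt(sqrt(sum(out3$state$pos^2)), 0)
})

test_that("ball never leaves the walled plane under random commands", {
  set.seed(8)
  st <- reaching_state(env_r)
  lim <- env_r$plane_half - env_r$ball_radius
  for (i in 1:500) {
    out <- reaching_step(st, rnorm(2, sd = 30), 0.05, env_r)
    st <- out$state
    expect_true(all(abs(st$pos) <= lim))
  }
})

test_that("reaching reward combines direction and speed terms", {
  # aligned, unit speed: r = (3/5) * 1 * (1+1)^5 = 19.2
  expect_equal(reaching_reward(c(1, 0), c(2, 0), rw), 19.2)
  # below the speed threshold the reward vanishes entirely
  expect_equal(reaching_reward(c(0.05, 0), c(1, 0), rw), 0)
  # outside the angular tolerance only the speed term remains: c * |v| * 1
  expect_equal(reaching_reward(c(-1, 0), c(1, 0), rw), 3 / 5)
  # non-negative over random inputs
  set.seed(2)
  for (i in 1:200)
    expect_gte(reaching_reward(rnorm(2), rnorm(2), rw), 0)
})

test_that("track is closed, smooth and arc-length parameterized", {
  env <- lane_config(n_track = 2000)
  tr <- make_track(env)
  expect_equal(tr$length, 2 * env$straight + 2 * pi * env$radius)
  # uniform spacing, closure
  d <- sqrt(diff(c(tr$x, tr$x[1]))^2 + diff(c(tr$y, tr$y[1]))^2)
  expect_equal(max(d), min(d), tolerance = 1e-2)
  expect_equal(sum(d), tr$length, tolerance = 1e-4)
  # unit tangents consistent with the curve direction
  expect_equal(sqrt(tr$tx^2 + tr$ty^2), rep(1, length(tr$x)))
})

test_that("lane errors measure heading and lateral deviation", {
  env <- lane_config()
  st <- lane_state(env)
  e0 <- lane_errors(st)
  expect_equal(e0[["beta_err"]], 0)
  expect_equal(e0[["d_err"]], 0)
  # 5 degrees off-heading on the centerline
  st5 <- st; st5$heading <- st5$heading + 5 * pi / 180
  e5 <- lane_errors(st5)
  expect_equal(e5[["beta_err"]], 5, tolerance = 1e-6)
  expect_equal(e5[["d_err"]], 0)
  # 0.1 m lateral offset, aligned (start is on the bottom straight)
  sto <- st; sto$pos <- st$pos + c(0, 0.1)
  eo <- lane_errors(sto)
  expect_equal(eo[["d_err"]], 0.1, tolerance = 5e-3)
  expect_equal(eo[["beta_err"]], 0)
})

test_that("lane reward halves every 5 degrees or 0.1 m", {
  expect_equal(lane_reward(0, 0), 1)
  expect_equal(lane_reward(0, 0.1), exp(-0.7))
  expect_equal(round(lane_reward(0, 0.1), 4), 0.4966)
  expect_equal(lane_reward(5, 0), exp(-0.75))
  expect_equal(round(lane_reward(5, 0), 4), 0.4724)
  # strictly decreasing in each error, bounded in (0, 1]
  b <- seq(0, 40, by = 0.5)
  expect_true(all(diff(lane_reward(b, 0)) < 0))
  d <- seq(0, 0.5, by = 0.01)
  expect_true(all(diff(lane_reward(0, d)) < 0))
  expect_true(all(lane_reward(b, 0.2) > 0 & lane_reward(b, 0.2) <= 1))
})

test_that("vehicle kinematics: constant speed, bicycle steering, off-track reset", {
  env <- lane_config(n_track = 2000)
  st <- lane_state(env)
  # straight steering on a straight keeps the lateral error near zero
  for (i in 1:100) {
    out <- lane_step(st, 0, 0.001, env)
    st <- out$state
  }
  expect_lt(lane_errors(st)[["d_err"]], 5e-3)
  # heading change follows (v/L) tan(delta) * t
  st2 <- lane_state(env)
  h0 <- st2$heading
  for (i in 1:100) st2 <- lane_step(st2, 15, 0.001, env)$state
  expect_equal(st2$heading - h0,
               (env$speed / env$wheelbase) * tan(15 * pi / 180) * 0.1,
               tolerance = 1e-9)
  # constant speed: displacement per step has magnitude speed * dt
  st3 <- lane_state(env)
  p0 <- st3$pos
  out3 <- lane_step(st3, -15, 0.001, env)
  expect_equal(sqrt(sum((out3$state$pos - p0)^2)), env$speed * 0.001,
               tolerance = 1e-9)
  # leaving the lane resets to the start pose
  st4 <- lane_state(env)
  st4$pos <- st4$pos + c(0, env$half_width + 0.05)
  out4 <- lane_step(st4, 0, 0.001, env)
  expect_true(out4$reset)
  tr <- st4$track
  expect_equal(out4$state$pos, c(tr$x[1], tr$y[1]))
  expect_equal(out4$state$heading, atan2(tr$ty[1], tr$tx[1]))
})

test_that("rendered views produce events only under motion", {
  st <- reaching_state(reaching_config(), pos = c(0, 0))
  f <- render_reaching(st, reaching_config())
  expect_equal(dim(f), c(16, 16))
  expect_equal(f[8, 8], 0)              # ball covers the center
  expect_equal(f[1, 1], 1)              # corners are background
  # moving the ball between frames triggers events
  st2 <- reaching_state(reaching_config(), pos = c(1.3, 0))
  ev <- dvs_frame_diff(f, render_reaching(st2, reaching_config()), 0.1)
  expect_gt(nrow(ev$events), 0)
  # lane view: boundary lines visible, static scene silent
  env <- lane_config(n_track = 1500)
  ls <- lane_state(env)
  lf <- render_lane(ls, env)
  expect_equal(dim(lf), c(32, 128))
  expect_gt(sum(lf == 0), 10)
  expect_equal(nrow(dvs_frame_diff(lf, render_lane(ls, env), 0.1)$events),
               0)
})
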