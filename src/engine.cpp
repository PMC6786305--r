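// Compiled fast path for the closed-loop simulator.
//
// Mirrors the pure-R reference loop (run_loop_r) operation for operation:
// identical arithmetic expression order and identical draw order from the
// global R RNG (unif_rand / norm_rand), so both engines produce the same
// trajectories from the same seed. Any change here must be matched in the
// R engine and is guarded by the engine-parity test.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Plasticity {
  double dt, tau_psp, tau_e, tau_g, c_p, c_g, mu, temperature;
  double beta0, lambda_decay, anneal_interval;
  double theta_min, theta_max, dtheta_max, w0, theta0, dt_slow;
};

struct Neurons {
  double rho0, du, rho_max;
};

// Traces of silent synapses decay exponentially toward zero and would
// enter the subnormal range (where x86 arithmetic slows down by orders of
// magnitude); values this small are physically meaningless and are
// flushed to exact zero. The pure-R engine applies the same flush so the
// two paths stay identical.
constexpr double kFlush = 1e-90;
inline double flush0(double x) { return std::fabs(x) < kFlush ? 0.0 : x; }

inline double rate_of(double u, const Neurons &nn) {
  return std::min(nn.rho0 * std::exp(u / nn.du), nn.rho_max);
}

inline bool spike_of(double rho, double dt) {
  return unif_rand() < 1.0 - std::exp(-rho * dt);
}

// One slow-grid parameter/weight update; noise drawn inside in index order.
inline void slow_update(std::vector<double> &theta, std::vector<double> &w,
                        const std::vector<double> &g, double beta,
                        const Plasticity &pl) {
  const double sd = std::sqrt(2.0 * pl.temperature * beta * pl.dt_slow);
  for (size_t i = 0; i < theta.size(); ++i) {
    double gc = std::min(std::max(g[i], -pl.dtheta_max), pl.dtheta_max);
    double th = theta[i] +
      beta * (pl.c_p * (pl.mu - theta[i]) + pl.c_g * gc) * pl.dt_slow +
      sd * norm_rand();
    th = std::min(std::max(th, pl.theta_min), pl.theta_max);
    theta[i] = th;
    w[i] = th > 0 ? pl.w0 * std::exp(th - pl.theta0) : 0.0;
  }
}

inline double annealed_beta(double t, const Plasticity &pl, bool anneal) {
  if (!anneal) return pl.beta0;
  return pl.beta0 * std::exp(-pl.lambda_decay * pl.anneal_interval *
                             std::floor(t / pl.anneal_interval));
}

struct RunLog {
  std::vector<double> log_t, log_reward, resets, snap_t, snap_w;
  int n_slow_updates = 0;
};

List pack_result(const RunLog &lg, const std::vector<double> &theta,
                 const std::vector<double> &w, const std::vector<double> &e,
                 const std::vector<double> &g,
                 const std::vector<double> &y_in, double beta_final) {
  return List::create(
      _["theta"] = theta, _["w"] = w, _["e"] = e, _["g"] = g,
      _["y_in"] = y_in, _["log_t"] = lg.log_t,
      _["log_reward"] = lg.log_reward, _["resets"] = lg.resets,
      _["snap_t"] = lg.snap_t, _["snap_w"] = lg.snap_w,
      _["beta_final"] = beta_final,
      _["n_slow_updates"] = lg.n_slow_updates);
}

} // namespace

// [[Rcpp::export]]
List cpp_run_reaching(List p) {
  const int n_steps = p["n_steps"];
  const double dt = p["dt"];
  const int n_slow = p["n_slow"], snap_every = p["snap_every"],
            record_every = p["record_every"];
  const bool learn = p["learn"], anneal = p["anneal"];
  Plasticity pl{dt,
                p["tau_psp"], p["tau_e"], p["tau_g"],
                p["c_p"], p["c_g"], p["mu"], p["temperature"],
                p["beta0"], p["lambda_decay"], p["anneal_interval"],
                p["theta_min"], p["theta_max"], p["dtheta_max"],
                p["w0"], p["theta0"], p["dt_slow"]};
  Neurons nn{p["rho0"], p["du"], p["rho_max"]};

  const int n_input = p["n_input"], n_visual = p["n_visual"],
            n_motor = p["n_motor"], mult = p["multiplicity"];
  const int nrow = n_input * mult;
  std::vector<double> theta = as<std::vector<double>>(p["theta_init"]);
  std::vector<double> w = as<std::vector<double>>(p["w_init"]);
  std::vector<double> e(theta.size(), 0.0), g(theta.size(), 0.0);
  std::vector<double> y_in(n_input, 0.0);

  const bool has_expl = p["has_expl"];
  const double noise_rate = p["noise_rate"],
               w_noise_expl = p["w_noise_expl"],
               w_expl_motor = p["w_expl_motor"];
  std::vector<double> w_vis_expl =
      as<std::vector<double>>(p["w_vis_expl"]);
  double y_noise = 0.0, y_expl = 0.0;

  const double tau_a = p["tau_a"], tau_r = p["tau_r"],
               velocity_gain = p["velocity_gain"], v_max = p["v_max"];
  const double beta_lim = p["beta_lim"], v_lim = p["v_lim"],
               coef = p["coef"], exponent = p["exponent"];

  const int n_px = p["n_px"];
  const bool axis_neurons = p["axis_neurons"];
  const double plane_half = p["plane_half"], ball_radius = p["ball_radius"],
               target_radius = p["target_radius"],
               dvs_threshold = p["dvs_threshold"];
  const double lim = plane_half - ball_radius;
  std::vector<double> pos = as<std::vector<double>>(p["pos0"]);

  const double px_step = 2.0 * plane_half / n_px;
  const double ball_r2 = ball_radius * ball_radius;
  auto render = [&](std::vector<double> &frame) {
    for (int c = 0; c < n_px; ++c) {
      const double xx = -plane_half + (c + 0.5) * px_step;
      for (int r = 0; r < n_px; ++r) {
        const double yy = -plane_half + (n_px - r - 0.5) * px_step;
        const double d2 = (xx - pos[0]) * (xx - pos[0]) +
                          (yy - pos[1]) * (yy - pos[1]);
        frame[r + c * n_px] = d2 <= ball_r2 ? 0.0 : 1.0;
      }
    }
  };

  std::vector<double> ref(n_px * n_px), frame(n_px * n_px);
  render(ref);

  std::vector<double> counts(n_input, 0.0), a(n_motor, 0.0),
      u_motor(n_motor, 0.0), rho_motor(n_motor, 0.0);
  std::vector<int> z_motor(n_motor, 0);
  double r_smooth = 0.0;
  double beta_now = learn ? pl.beta0 : 0.0;

  RunLog lg;
  lg.snap_t.push_back(0.0);
  lg.snap_w.insert(lg.snap_w.end(), w.begin(), w.end());

  const double psp_keep = 1.0 - dt / pl.tau_psp;
  const double act_keep = std::exp(-dt / tau_a);

  for (int n = 1; n <= n_steps; ++n) {
    const double t_now = n * dt;

    // render + DVS + encode
    render(frame);
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int idx = 0; idx < n_px * n_px; ++idx) {
      const double d = frame[idx] - ref[idx];
      if (d > dvs_threshold || d < -dvs_threshold) {
        ref[idx] = frame[idx];
        const int row = idx % n_px, col = idx / n_px;
        counts[row * n_px + col] += 1.0; // pixel neuron, row-major
        if (axis_neurons) {
          counts[n_px * n_px + row] += 1.0;         // row axis
          counts[n_px * n_px + n_px + col] += 1.0;  // column axis
        }
      }
    }

    // network step (draw order: noise, exploration, motors)
    const bool z_noise = has_expl && spike_of(noise_rate, dt);
    for (int i = 0; i < n_input; ++i)
      y_in[i] = flush0(y_in[i] * psp_keep + counts[i]);
    if (has_expl) {
      y_noise = flush0(y_noise * psp_keep + (z_noise ? 1.0 : 0.0));
      double u_expl = w_noise_expl * y_noise;
      double acc = 0.0;
      for (int i = 0; i < n_visual; ++i) acc += w_vis_expl[i] * y_in[i];
      u_expl += acc;
      const bool z_expl = spike_of(rate_of(u_expl, nn), dt);
      y_expl = flush0(y_expl * psp_keep + (z_expl ? 1.0 : 0.0));
    }
    for (int j = 0; j < n_motor; ++j) {
      double acc = 0.0;
      const double *wj = &w[(size_t)j * nrow];
      for (int k = 0; k < mult; ++k) {
        const double *wk = wj + (size_t)k * n_input;
        for (int i = 0; i < n_input; ++i) acc += wk[i] * y_in[i];
      }
      if (has_expl) acc += w_expl_motor * y_expl;
      u_motor[j] = acc;
      rho_motor[j] = rate_of(acc, nn);
      z_motor[j] = spike_of(rho_motor[j], dt) ? 1 : 0;
    }

    // fast plasticity traces
    for (int j = 0; j < n_motor; ++j) {
      const double zj = z_motor[j], rj = rho_motor[j];
      const size_t off = (size_t)j * nrow;
      for (int k = 0; k < mult; ++k) {
        const size_t off2 = off + (size_t)k * n_input;
        for (int i = 0; i < n_input; ++i) {
          const size_t s = off2 + i;
          const double yv = y_in[i];
          e[s] = flush0(e[s] + dt * (-e[s] / pl.tau_e) +
                        w[s] * yv * (zj - rj * dt));
          g[s] = flush0(g[s] + dt * (-g[s] / pl.tau_g + r_smooth * e[s]));
        }
      }
    }

    // decode velocity command
    double vx = 0.0, vy = 0.0;
    for (int k = 1; k <= n_motor; ++k) {
      a[k - 1] = flush0(a[k - 1] * act_keep + z_motor[k - 1]);
      const double bk = 2.0 * k * M_PI / n_motor;
      vx += std::cos(bk) * a[k - 1];
      vy += std::sin(bk) * a[k - 1];
    }
    vx *= velocity_gain;
    vy *= velocity_gain;
    double speed = std::sqrt(vx * vx + vy * vy);
    if (speed > v_max) {
      const double sc = v_max / speed;
      vx *= sc;
      vy *= sc;
      speed = std::sqrt(vx * vx + vy * vy);
    }

    // reward w.r.t. pre-move position, then environment step
    double r_raw = 0.0;
    if (speed > v_lim) {
      const double gx = -pos[0], gy = -pos[1];
      const double gn = std::sqrt(gx * gx + gy * gy);
      if (gn > 0) {
        double cosb = (vx * gx + vy * gy) / (speed * gn);
        cosb = std::min(std::max(cosb, -1.0), 1.0);
        const double beta_err = std::acos(cosb);
        const double r_beta =
            beta_err < beta_lim ? 1.0 - beta_err / beta_lim : 0.0;
        r_raw = coef * speed * ::R_pow(r_beta + 1.0, exponent);
      }
    }
    pos[0] = std::min(std::max(pos[0] + vx * dt, -lim), lim);
    pos[1] = std::min(std::max(pos[1] + vy * dt, -lim), lim);
    if (std::sqrt(pos[0] * pos[0] + pos[1] * pos[1]) <= target_radius) {
      pos[0] = -lim + (lim - -lim) * unif_rand();
      pos[1] = -lim + (lim - -lim) * unif_rand();
      lg.resets.push_back(t_now);
    }

    r_smooth = flush0(r_smooth + (dt / tau_r) * (r_raw - r_smooth));

    if (n % record_every == 0) {
      lg.log_t.push_back(t_now);
      lg.log_reward.push_back(r_raw);
    }
    if (n % n_slow == 0) {
      if (learn) {
        beta_now = annealed_beta(t_now, pl, anneal);
        slow_update(theta, w, g, beta_now, pl);
      }
      ++lg.n_slow_updates;
    }
    if (n % snap_every == 0) {
      lg.snap_t.push_back(t_now);
      lg.snap_w.insert(lg.snap_w.end(), w.begin(), w.end());
    }
    if (n % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return pack_result(lg, theta, w, e, g, y_in, beta_now);
}

// [[Rcpp::export]]
List cpp_run_lane(List p) {
  const int n_steps = p["n_steps"];
  const double dt = p["dt"];
  const int n_slow = p["n_slow"], snap_every = p["snap_every"],
            record_every = p["record_every"];
  const bool learn = p["learn"], anneal = p["anneal"];
  Plasticity pl{dt,
                p["tau_psp"], p["tau_e"], p["tau_g"],
                p["c_p"], p["c_g"], p["mu"], p["temperature"],
                p["beta0"], p["lambda_decay"], p["anneal_interval"],
                p["theta_min"], p["theta_max"], p["dtheta_max"],
                p["w0"], p["theta0"], p["dt_slow"]};
  Neurons nn{p["rho0"], p["du"], p["rho_max"]};

  const int n_input = p["n_input"], n_motor = p["n_motor"],
            mult = p["multiplicity"];
  const int nrow = n_input * mult;
  std::vector<double> theta = as<std::vector<double>>(p["theta_init"]);
  std::vector<double> w = as<std::vector<double>>(p["w_init"]);
  std::vector<double> e(theta.size(), 0.0), g(theta.size(), 0.0);
  std::vector<double> y_in(n_input, 0.0);

  const double tau_a = p["tau_a"], tau_r = p["tau_r"],
               steer_scale = p["steer_scale"];
  std::vector<double> bnd = as<std::vector<double>>(p["steer_boundaries"]);
  std::vector<double> ang = as<std::vector<double>>(p["steer_angles"]);
  const double lane_angle_coef = p["lane_angle_coef"],
               lane_dist_coef = p["lane_dist_coef"];

  const int W = p["width_px"], H = p["height_px"], win = p["window_px"];
  const int nwx = W / win;
  const double half_width = p["half_width"], speed = p["speed"],
               wheelbase = p["wheelbase"], cam_height = p["cam_height"],
               focal = p["focal"], f_min = p["f_min"], f_max = p["f_max"],
               dvs_threshold = p["dvs_threshold"],
               rate_gain = p["rate_gain"];
  std::vector<double> tx_ = as<std::vector<double>>(p["track_x"]);
  std::vector<double> ty_ = as<std::vector<double>>(p["track_y"]);
  std::vector<double> ttx = as<std::vector<double>>(p["track_tx"]);
  std::vector<double> tty = as<std::vector<double>>(p["track_ty"]);
  const int n_track = (int)tx_.size();
  const int search_window = 80;

  double posx = tx_[0], posy = ty_[0];
  double heading = std::atan2(tty[0], ttx[0]);
  int track_idx = 0;

  auto render = [&](std::vector<double> &frame) {
    std::fill(frame.begin(), frame.end(), 1.0);
    const double ch = std::cos(heading), sh = std::sin(heading);
    for (int side = -1; side <= 1; side += 2) {
      for (int i = 0; i < n_track; ++i) {
        const double bx = tx_[i] - side * half_width * tty[i];
        const double by = ty_[i] + side * half_width * ttx[i];
        const double rx = bx - posx, ry = by - posy;
        const double f = rx * ch + ry * sh;
        if (!(f > f_min && f < f_max)) continue;
        const double l = -rx * sh + ry * ch;
        const int col = (int)std::floor(W / 2 - focal * l / f);
        const int row = (int)std::floor(focal * cam_height / f);
        if (col >= 0 && col < W && row >= 0 && row < H)
          frame[row + col * H] = 0.0;
      }
    }
  };

  std::vector<double> ref(W * H), frame(W * H);
  render(ref);

  std::vector<double> rates(n_input, 0.0), a(n_motor, 0.0),
      rho_motor(n_motor, 0.0);
  std::vector<int> counts_win(n_input, 0), z_vis(n_input, 0),
      z_motor(n_motor, 0);
  double r_smooth = 0.0;
  double beta_now = learn ? pl.beta0 : 0.0;

  RunLog lg;
  lg.snap_t.push_back(0.0);
  lg.snap_w.insert(lg.snap_w.end(), w.begin(), w.end());

  const double psp_keep = 1.0 - dt / pl.tau_psp;
  const double act_keep = std::exp(-dt / tau_a);

  for (int n = 1; n <= n_steps; ++n) {
    const double t_now = n * dt;

    render(frame);
    std::fill(counts_win.begin(), counts_win.end(), 0);
    for (int idx = 0; idx < W * H; ++idx) {
      const double d = frame[idx] - ref[idx];
      if (d > dvs_threshold || d < -dvs_threshold) {
        ref[idx] = frame[idx];
        const int row = idx % H, col = idx / H;
        counts_win[(row / win) * nwx + (col / win)] += 1;
      }
    }
    for (int i = 0; i < n_input; ++i) {
      rates[i] = std::min(rate_gain * counts_win[i], nn.rho_max);
      z_vis[i] = spike_of(rates[i], dt) ? 1 : 0;
    }

    for (int i = 0; i < n_input; ++i)
      y_in[i] = flush0(y_in[i] * psp_keep + z_vis[i]);
    for (int j = 0; j < n_motor; ++j) {
      double acc = 0.0;
      const double *wj = &w[(size_t)j * nrow];
      for (int k = 0; k < mult; ++k) {
        const double *wk = wj + (size_t)k * n_input;
        for (int i = 0; i < n_input; ++i) acc += wk[i] * y_in[i];
      }
      rho_motor[j] = rate_of(acc, nn);
      z_motor[j] = spike_of(rho_motor[j], dt) ? 1 : 0;
    }
    for (int j = 0; j < n_motor; ++j) {
      const double zj = z_motor[j], rj = rho_motor[j];
      const size_t off = (size_t)j * nrow;
      for (int k = 0; k < mult; ++k) {
        const size_t off2 = off + (size_t)k * n_input;
        for (int i = 0; i < n_input; ++i) {
          const size_t s = off2 + i;
          const double yv = y_in[i];
          e[s] = flush0(e[s] + dt * (-e[s] / pl.tau_e) +
                        w[s] * yv * (zj - rj * dt));
          g[s] = flush0(g[s] + dt * (-g[s] / pl.tau_g + r_smooth * e[s]));
        }
      }
    }

    // steering decode
    double a_l = 0.0, a_r = 0.0;
    for (int k = 0; k < n_motor; ++k) {
      a[k] = flush0(a[k] * act_keep + z_motor[k]);
      if (k < n_motor / 2) a_l += a[k];
      else a_r += a[k];
    }
    const double tot = a_l + a_r;
    const double ratio = tot == 0.0 ? 0.0
                                    : steer_scale * (a_l - a_r) / tot;
    int bi = 0;
    for (size_t b = 0; b < bnd.size(); ++b)
      if (ratio > bnd[b]) ++bi;
    const double steer = ang[bi];

    // kinematic step, errors, reward, possible reset
    heading += (speed / wheelbase) * std::tan(steer * M_PI / 180.0) * dt;
    posx += speed * std::cos(heading) * dt;
    posy += speed * std::sin(heading) * dt;
    int best = -1;
    double best_d2 = 0.0;
    for (int k = -search_window; k <= search_window; ++k) {
      const int j = ((track_idx + k) % n_track + n_track) % n_track;
      const double d2 = (tx_[j] - posx) * (tx_[j] - posx) +
                        (ty_[j] - posy) * (ty_[j] - posy);
      if (best < 0 || d2 < best_d2) {
        best = j;
        best_d2 = d2;
      }
    }
    track_idx = best;
    const double d_err = std::sqrt(best_d2);
    double angerr = std::atan2(tty[best], ttx[best]) - heading;
    angerr = std::atan2(std::sin(angerr), std::cos(angerr));
    const double beta_err = std::fabs(angerr) * 180.0 / M_PI;
    if (d_err > half_width) {
      posx = tx_[0];
      posy = ty_[0];
      heading = std::atan2(tty[0], ttx[0]);
      track_idx = 0;
      lg.resets.push_back(t_now);
    }
    const double r_raw = std::exp(-lane_angle_coef * beta_err * beta_err) *
                         std::exp(-lane_dist_coef * d_err * d_err);

    r_smooth = flush0(r_smooth + (dt / tau_r) * (r_raw - r_smooth));

    if (n % record_every == 0) {
      lg.log_t.push_back(t_now);
      lg.log_reward.push_back(r_raw);
    }
    if (n % n_slow == 0) {
      if (learn) {
        beta_now = annealed_beta(t_now, pl, anneal);
        slow_update(theta, w, g, beta_now, pl);
      }
      ++lg.n_slow_updates;
    }
    if (n % snap_every == 0) {
      lg.snap_t.push_back(t_now);
      lg.snap_w.insert(lg.snap_w.end(), w.begin(), w.end());
    }
    if (n % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return pack_result(lg, theta, w, e, g, y_in, beta_now);
}
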