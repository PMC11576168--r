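// Online one-step semi-gradient TD training loop with weight decay.
// Mirrors the pure-R engine in R/agent.R operation-for-operation, consuming
// the identical sequence of R RNG draws, so (seed, config) determines the
// run regardless of engine.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// headings 1=N,2=E,3=S,4=W; forward displacement per heading
static const int FDC[5] = {0, 0, 1, 0, -1};
static const int FDR[5] = {0, -1, 0, 1, 0};

struct World {
  int W, H, sc, sr, sh, rc, rr, n_opt, max_steps;
  double r_opt, r_req, r_haz;
  std::vector<int> haz_c, haz_r;
};

struct State {
  int ac, ar, h, steps;
  bool done;
  std::vector<int> opt_c, opt_r;
};

static inline bool inb(const World& w, int c, int r) {
  return c >= 1 && c <= w.W && r >= 1 && r <= w.H;
}

static void observe(const World& w, const State& s, std::vector<double>& obs,
                    std::vector<int>& active) {
  std::fill(obs.begin(), obs.end(), 0.0);
  active.clear();
  int hr = (s.h == 4) ? 1 : s.h + 1;
  for (int f = 0; f <= 4; ++f) {
    for (int l = -2; l <= 2; ++l) {
      int c = s.ac + f * FDC[s.h] + l * FDC[hr];
      int r = s.ar + f * FDR[s.h] + l * FDR[hr];
      int cell = (5 - f - 1) * 5 + (l + 3); // 1-based window cell
      int base = (cell - 1) * 4;            // 0-based into obs
      if (!inb(w, c, r)) {
        obs[base] = 1.0; active.push_back(base);
      } else {
        for (size_t k = 0; k < s.opt_c.size(); ++k)
          if (s.opt_c[k] == c && s.opt_r[k] == r) {
            obs[base + 1] = 1.0; active.push_back(base + 1); break;
          }
        if (c == w.rc && r == w.rr) { obs[base + 2] = 1.0; active.push_back(base + 2); }
        for (size_t k = 0; k < w.haz_c.size(); ++k)
          if (w.haz_c[k] == c && w.haz_r[k] == r) {
            obs[base + 3] = 1.0; active.push_back(base + 3); break;
          }
      }
    }
  }
}

static void reset_world(const World& w, const std::vector<int>& free_ids, State& s) {
  s.ac = w.sc; s.ar = w.sr; s.h = w.sh; s.steps = 0; s.done = false;
  s.opt_c.clear(); s.opt_r.clear();
  int n = w.n_opt;
  if (n > 0) {
    std::vector<int> ids(free_ids);
    int m = (int)ids.size();
    for (int k = 1; k <= n; ++k) { // partial Fisher-Yates, same draws as R
      int j = k + (int)std::floor(unif_rand() * (m - k + 1));
      if (j > m) j = m;
      std::swap(ids[k - 1], ids[j - 1]);
    }
    for (int k = 0; k < n; ++k) {
      int id = ids[k];
      s.opt_c.push_back((id - 1) % w.W + 1);
      s.opt_r.push_back((id - 1) / w.W + 1);
    }
  }
}

// returns reward; sets event: 0 none, 1 optional, 2 required, 3 hazard
static double step_world(const World& w, State& s, int action, int& event) {
  double reward = 0.0;
  event = 0;
  if (action == 1) {        // turn_left
    s.h = (s.h == 1) ? 4 : s.h - 1;
  } else if (action == 2) { // turn_right
    s.h = (s.h == 4) ? 1 : s.h + 1;
  } else {                  // forward
    int nc = s.ac + FDC[s.h], nr = s.ar + FDR[s.h];
    if (inb(w, nc, nr)) {
      s.ac = nc; s.ar = nr;
      for (size_t k = 0; k < s.opt_c.size(); ++k)
        if (s.opt_c[k] == nc && s.opt_r[k] == nr) {
          reward += w.r_opt;
          s.opt_c.erase(s.opt_c.begin() + k);
          s.opt_r.erase(s.opt_r.begin() + k);
          event = 1;
          break;
        }
      for (size_t k = 0; k < w.haz_c.size(); ++k)
        if (w.haz_c[k] == nc && w.haz_r[k] == nr) {
          reward += w.r_haz; event = 3; break;
        }
      if (nc == w.rc && nr == w.rr) {
        reward += w.r_req; s.done = true; event = 2;
      }
    }
  }
  s.steps += 1;
  if (!s.done && s.steps >= w.max_steps) s.done = true;
  return reward;
}

static void forward(const NumericMatrix& w_in, const NumericVector& b_h,
                    const NumericMatrix& w_out, const NumericVector& b_o,
                    const std::vector<int>& active,
                    std::vector<double>& hid, double v[3]) {
  int nh = b_h.size();
  for (int j = 0; j < nh; ++j) {
    double z = b_h[j];
    for (size_t k = 0; k < active.size(); ++k) z += w_in(active[k], j);
    hid[j] = std::tanh(z);
  }
  for (int a = 0; a < 3; ++a) {
    double s = b_o[a];
    for (int j = 0; j < nh; ++j) s += w_out(j, a) * hid[j];
    v[a] = s;
  }
}

static int select_action(const double v[3], double epsilon, double tau, int policy) {
  if (policy == 1) { // egreedy
    double u = unif_rand();
    if (u < epsilon) {
      int a = 1 + (int)std::floor(unif_rand() * 3.0);
      return a > 3 ? 3 : a;
    }
    int a = 0;
    for (int i = 1; i < 3; ++i) if (v[i] > v[a]) a = i;
    return a + 1;
  }
  // softmax with max-subtraction
  double m = std::max(v[0], std::max(v[1], v[2]));
  double e[3], tot = 0.0;
  for (int i = 0; i < 3; ++i) { e[i] = std::exp((v[i] - m) / tau); tot += e[i]; }
  double u = unif_rand(), cum = 0.0;
  int a = 1;
  cum = e[0] / tot;
  while (a < 3 && u > cum) { cum += e[a] / tot; a += 1; }
  return a;
}

// [[Rcpp::export]]
List train_loop_cpp(NumericMatrix w_in_, NumericVector b_hidden_,
                    NumericMatrix w_out_, NumericVector b_out_,
                    NumericMatrix mask_in, NumericMatrix mask_out,
                    int width, int height,
                    int start_c, int start_r, int start_h,
                    int req_c, int req_r,
                    IntegerMatrix hazards,
                    int n_optional, IntegerVector free_ids_,
                    double reward_optional, double reward_required, double reward_hazard,
                    int max_steps,
                    double alpha, double gamma, double lambda,
                    double epsilon, double tau, int policy,
                    double rpe_scale, double neg_scale, double pos_scale,
                    int episodes, bool record_updates) {
  NumericMatrix w_in = clone(w_in_), w_out = clone(w_out_);
  NumericVector b_h = clone(b_hidden_), b_o = clone(b_out_);
  int ni = w_in.nrow(), nh = b_h.size();

  World w;
  w.W = width; w.H = height; w.sc = start_c; w.sr = start_r; w.sh = start_h;
  w.rc = req_c; w.rr = req_r; w.n_opt = n_optional; w.max_steps = max_steps;
  w.r_opt = reward_optional; w.r_req = reward_required; w.r_haz = reward_hazard;
  for (int k = 0; k < hazards.nrow(); ++k) {
    w.haz_c.push_back(hazards(k, 0)); w.haz_r.push_back(hazards(k, 1));
  }
  std::vector<int> free_ids(free_ids_.begin(), free_ids_.end());

  NumericMatrix trace(episodes, 7);
  std::vector<double> upd_d2, upd_dw;
  std::vector<int> upd_ep;

  std::vector<double> obs(ni), obs2(ni), hid(nh), hid2(nh);
  std::vector<int> active, active2;
  std::vector<char> act_flag(ni, 0);
  double v[3], v2[3];
  double al = alpha * lambda;
  bool decay = lambda > 0.0;

  State s;
  for (int ep = 0; ep < episodes; ++ep) {
    reset_world(w, free_ids, s);
    observe(w, s, obs, active);
    double reward_sum = 0.0, s_d2 = 0.0, s_dw = 0.0;
    int n_opt_col = 0, n_haz = 0, steps = 0, reached = 0;
    while (true) {
      forward(w_in, b_h, w_out, b_o, active, hid, v);
      int a = select_action(v, epsilon, tau, policy);
      int event;
      double r = step_world(w, s, a, event);
      observe(w, s, obs2, active2);
      bool terminal = (event == 2);
      double r_eff = (r < 0) ? r * neg_scale : ((r > 0) ? r * pos_scale : 0.0);
      double target = r_eff;
      if (!terminal) {
        forward(w_in, b_h, w_out, b_o, active2, hid2, v2);
        double mx = std::max(v2[0], std::max(v2[1], v2[2]));
        target += gamma * mx;
      }
      double delta = (target - v[a - 1]) * rpe_scale;

      // semi-gradient update; d(delta^2)/d(theta) = -2 delta dV/d(theta)
      double dw2 = 0.0;
      double g_base = 2.0 * alpha * delta; // -alpha * (-2 delta)
      b_o[a - 1] += g_base;
      for (size_t k = 0; k < active.size(); ++k) act_flag[active[k]] = 1;
      for (int j = 0; j < nh; ++j) {
        double wja = w_out(j, a - 1);
        double dz = g_base * wja * (1.0 - hid[j] * hid[j]); // -alpha * grad_z
        // hidden->output weights (decay applies to the whole matrix)
        if (decay) {
          for (int b = 0; b < 3; ++b) {
            double old = w_out(j, b);
            double nw = old * (1.0 - al);
            if (b == a - 1) nw += g_base * hid[j];
            if (mask_out(j, b) == 0.0) nw = 0.0;
            w_out(j, b) = nw;
            double d = nw - old; dw2 += d * d;
          }
        } else {
          double old = w_out(j, a - 1);
          double nw = old + g_base * hid[j];
          if (mask_out(j, a - 1) == 0.0) nw = 0.0;
          w_out(j, a - 1) = nw;
          double d = nw - old; dw2 += d * d;
        }
        b_h[j] += dz;
        // input->hidden weights: gradient on active bits, decay on all
        for (size_t k = 0; k < active.size(); ++k) {
          int i = active[k];
          double old = w_in(i, j);
          double nw = decay ? old * (1.0 - al) + dz : old + dz; // obs bit is 1
          if (mask_in(i, j) == 0.0) nw = 0.0;
          w_in(i, j) = nw;
          double d = nw - old; dw2 += d * d;
        }
        if (decay) {
          for (int i = 0; i < ni; ++i) {
            if (act_flag[i]) continue;
            double old = w_in(i, j);
            double nw = old * (1.0 - al);
            w_in(i, j) = nw;
            double d = nw - old; dw2 += d * d;
          }
        }
      }
      for (size_t k = 0; k < active.size(); ++k) act_flag[active[k]] = 0;
      double dwn = std::sqrt(dw2);
      s_d2 += delta * delta; s_dw += dwn;
      if (record_updates) {
        upd_d2.push_back(delta * delta); upd_dw.push_back(dwn);
        upd_ep.push_back(ep + 1);
      }

      reward_sum += r;
      if (event == 1) n_opt_col += 1;
      if (event == 3) n_haz += 1;
      if (terminal) reached = 1;
      steps += 1;
      obs.swap(obs2); active.swap(active2);
      if (s.done) break;
    }
    trace(ep, 0) = steps; trace(ep, 1) = reward_sum; trace(ep, 2) = n_opt_col;
    trace(ep, 3) = n_haz; trace(ep, 4) = reached; trace(ep, 5) = s_d2;
    trace(ep, 6) = s_dw;
  }

  List out = List::create(
    _["w_in"] = w_in, _["b_hidden"] = b_h, _["w_out"] = w_out, _["b_out"] = b_o,
    _["trace"] = trace);
  if (record_updates) {
    out["delta2"] = NumericVector(upd_d2.begin(), upd_d2.end());
    out["dw_norm"] = NumericVector(upd_dw.begin(), upd_dw.end());
    out["update_episode"] = IntegerVector(upd_ep.begin(), upd_ep.end());
  }
  return out;
}
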