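// Event-driven spiking network engine: two-layer efficient-coding encoder
// (simple cells with shared exponential-STDP weights; complex cells with
// step-STDP pooling; static, lateral and top-down inhibition) plus a
// continuous-time spiking actor-critic with eligibility traces.
//
// Times are in milliseconds (double) throughout; potentials in mV.
// All randomness goes through R's RNG so set.seed() controls the engine.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const double NEVER = -1e300; // "no spike yet" sentinel

struct LifParams {
  double V_thresh, V_reset, tau_m, tau_SRA, eta_SRA, tau_RP, eta_RP;
};

struct StdpParams {
  double eta_LTP, eta_LTD, tau_LTP, tau_LTD;
};

struct CellArrays {
  std::vector<double> V, VSRA, Vtheta, t_s, t_sm1, last_up, S;
  std::vector<int> bin_count;      // spikes in the current 1 ms bin
  std::vector<double> cum_count;   // resettable per-cell counters
  void init(int n, double vth) {
    V.assign(n, 0.0); VSRA.assign(n, 0.0); Vtheta.assign(n, vth);
    t_s.assign(n, NEVER); t_sm1.assign(n, NEVER); last_up.assign(n, 0.0);
    S.assign(n, 0.0); bin_count.assign(n, 0); cum_count.assign(n, 0.0);
  }
};

struct Net {
  // geometry
  int W, H, s_gw, s_gh, s_maps, s_rfw, s_rfh, s_sx, s_sy;
  int c_gw, c_gh, c_maps, c_rfw, c_rfh, c_sx, c_sy;
  int n_sloc, n_simple, n_cloc, n_complex, n_src;

  LifParams p_s, p_c, p_rl;
  StdpParams stdp_s, stdp_c, stdp_rl, stdp_inh;
  double eta_I_s, eta_I_c, eta_TA, S_star, theta_floor;
  double lambda_s, lambda_c, lambda_lat, lambda_td;
  double V_min, history, rate_alpha, theta_interval;
  int lateral_radius;

  // reinforcement learner
  int n_critic, n_actor_per, n_actor;
  double nu, V0, tau_r, eta_actor_gain; int Nwin;
  double tau_e, tau_k, nu_k;
  bool normalize_value;
  double rw_gamma, rw_beta, rw_alpha, rw_eps;

  // learned state
  std::vector< std::vector<double> > map_w;     // per simple map, rfw*rfh*2
  std::vector< std::vector<double> > complex_w; // per complex cell, c_rfw*c_rfh*s_maps
  std::vector< std::vector<double> > lat_w;     // per simple cell, n_neigh*s_maps
  std::vector< std::vector<double> > td_w;      // per simple cell, c_maps
  std::vector< std::vector<double> > critic_w, actor_w;          // per neuron, n_src
  std::vector< std::vector<double> > critic_e, actor_e;          // eligibility values
  std::vector< std::vector<double> > critic_el, actor_el;        // eligibility last-update
  std::vector<double> actor_norm;  // fixed L1 budget of each actor neuron

  CellArrays sc, cc, rlc; // simple, complex, critic+actor (critic first)

  // rate estimators for critic/actor neurons (double-exponential kernel)
  std::vector<double> rl_A, rl_B, rl_rate_last;
  std::vector<double> actor_counts; // per action, spikes since last selection

  // spike histories
  std::vector< std::deque<double> > pix_hist;     // W*H*2
  std::vector< std::deque<double> > src_hist;     // n_src (simple then complex)
  struct LogEntry { int slot; double t; };
  std::vector< std::deque<LogEntry> > lat_log, td_log; // per simple cell

  // neighborhood precomputation
  std::vector< std::vector<int> > neigh;      // per location: neighbor locs
  std::vector< std::vector<int> > neigh_slot; // slot of this loc in the neighbor's list
  int n_neigh_max;

  // per-bin population counters and trackers
  double bin_events, bin_simple;
  double trk_S, trk_E, trk_E_slow;
  std::deque<double> value_buf;
  double cur_V, cur_vdot, cur_delta, cur_R;
  double t_last_tick;

  // cumulative counters (resettable)
  double tot_events, tot_simple, tot_complex;

  // stage flags
  bool learn_simple, learn_complex, learn_inh, learn_rl, rl_active;
  bool ta_active;
  bool reward_override; double reward_value;
  int prev_action; // action executed since the last selection (-1: none)

  // ---- helpers ------------------------------------------------------------

  inline double eff_pot(const CellArrays& a, const LifParams& p, int i,
                        double t) const {
    double rp = (p.eta_RP > 0.0 && a.t_s[i] > NEVER)
      ? p.eta_RP * std::exp((a.t_s[i] - t) / p.tau_RP) : 0.0;
    return a.V[i] - a.VSRA[i] - rp;
  }

  // threshold test: the refractory term is non-negative, so the exp() is
  // only needed when the cell would fire without it
  inline bool fires(const CellArrays& a, const LifParams& p, int i,
                    double t) const {
    double base = a.V[i] - a.VSRA[i];
    if (base < a.Vtheta[i]) return false;
    return eff_pot(a, p, i, t) >= a.Vtheta[i];
  }

  inline void decay(CellArrays& a, const LifParams& p, int i, double t) {
    double dt = t - a.last_up[i];
    if (dt > 0.0) {
      a.V[i] *= std::exp(-dt / p.tau_m);
      if (a.VSRA[i] != 0.0) {
        a.VSRA[i] *= std::exp(-dt / p.tau_SRA);
        if (a.VSRA[i] < 1e-12) a.VSRA[i] = 0.0;
      }
      a.last_up[i] = t;
    }
  }

  // decay all maps of one simple-cell location; they share last_update in
  // every pathway (events, static, lateral, top-down all touch whole
  // locations), so the decay factors are computed once
  inline void decay_simple_loc(int loc, double t) {
    double lu = sc.last_up[loc];
    bool uniform = true;
    for (int m = 1; m < s_maps; ++m)
      if (sc.last_up[m * n_sloc + loc] != lu) { uniform = false; break; }
    if (!uniform || t < lu) {
      for (int m = 0; m < s_maps; ++m) decay(sc, p_s, m * n_sloc + loc, t);
      return;
    }
    double dt = t - lu;
    if (dt <= 0.0) return;
    double em = std::exp(-dt / p_s.tau_m);
    double es = std::exp(-dt / p_s.tau_SRA);
    for (int m = 0; m < s_maps; ++m) {
      int i = m * n_sloc + loc;
      sc.V[i] *= em;
      if (sc.VSRA[i] != 0.0) {
        sc.VSRA[i] *= es;
        if (sc.VSRA[i] < 1e-12) sc.VSRA[i] = 0.0;
      }
      sc.last_up[i] = t;
    }
  }

  inline void prune(std::deque<double>& q, double t) {
    while (!q.empty() && q.front() < t - history) q.pop_front();
  }
  inline void prune(std::deque<LogEntry>& q, double t) {
    while (!q.empty() && q.front().t < t - history) q.pop_front();
  }

  static void clamp_norm(std::vector<double>& w, double lambda) {
    double s = 0.0;
    for (double& x : w) { if (x < 0.0) x = 0.0; s += x; }
    if (s > 0.0) { double f = lambda / s; for (double& x : w) x *= f; }
  }

  // inhibitory stores grow freely until the L1 norm reaches lambda, which
  // acts as a cap ("avoid unbounded growth"); rescale only above it
  static void clamp_cap(std::vector<double>& w, double lambda) {
    double s = 0.0;
    for (double& x : w) { if (x < 0.0) x = 0.0; s += x; }
    if (s > lambda) { double f = lambda / s; for (double& x : w) x *= f; }
  }

  // exponential STDP sum over one source's history in [lo, ts]
  inline double stdp_exp_sum(const std::deque<double>& hist, double ts,
                             double tsm1, const StdpParams& sp) const {
    double lo = std::max(tsm1, ts - history);
    double acc = 0.0;
    for (auto it = hist.rbegin(); it != hist.rend(); ++it) {
      double ti = *it;
      if (ti > ts) continue;
      if (ti < lo) break;
      acc += sp.eta_LTP * std::exp((ti - ts) / sp.tau_LTP);
      if (tsm1 > NEVER)
        acc -= sp.eta_LTD * std::exp((tsm1 - ti) / sp.tau_LTD);
    }
    return acc;
  }

  // ---- construction -------------------------------------------------------

  void build(List cfg) {
    List g = cfg["geometry"];
    W = g["width"]; H = g["height"];
    s_gw = g["s_gw"]; s_gh = g["s_gh"]; s_maps = g["s_maps"];
    s_rfw = g["s_rfw"]; s_rfh = g["s_rfh"];
    s_sx = g["s_stride_x"]; s_sy = g["s_stride_y"];
    c_gw = g["c_gw"]; c_gh = g["c_gh"]; c_maps = g["c_maps"];
    c_rfw = g["c_rfw"]; c_rfh = g["c_rfh"];
    c_sx = g["c_stride_x"]; c_sy = g["c_stride_y"];
    n_sloc = s_gw * s_gh; n_simple = n_sloc * s_maps;
    n_cloc = c_gw * c_gh; n_complex = n_cloc * c_maps;
    n_src = n_simple + n_complex;

    List ps = cfg["simple"], pc = cfg["complex"], pk = cfg["critic"],
         pa = cfg["actor"], rl = cfg["rl"], rw = cfg["reward"];
    p_s = { as<double>(ps["V_thresh"]), as<double>(ps["V_reset"]),
            as<double>(ps["tau_m"]), as<double>(ps["tau_SRA"]),
            as<double>(ps["eta_SRA"]), as<double>(ps["tau_RP"]),
            as<double>(ps["eta_RP"]) };
    p_c = { as<double>(pc["V_thresh"]), as<double>(pc["V_reset"]),
            as<double>(pc["tau_m"]), 1.0, 0.0,
            as<double>(pc["tau_RP"]), as<double>(pc["eta_RP"]) };
    p_rl = { as<double>(pk["V_thresh"]), as<double>(pk["V_reset"]),
             as<double>(pk["tau_m"]), 1.0, 0.0, 1.0, 0.0 };
    stdp_s = { as<double>(ps["eta_LTP"]), as<double>(ps["eta_LTD"]),
               as<double>(ps["tau_LTP"]), as<double>(ps["tau_LTD"]) };
    stdp_c = { as<double>(pc["eta_LTP"]), as<double>(pc["eta_LTD"]),
               as<double>(pc["tau_LTP"]), as<double>(pc["tau_LTD"]) };
    stdp_rl = { as<double>(pk["eta_LTP"]), as<double>(pk["eta_LTD"]),
                as<double>(pk["tau_LTP"]), as<double>(pk["tau_LTD"]) };
    stdp_inh = { as<double>(ps["eta_ILTP"]), as<double>(ps["eta_ILTD"]),
                 as<double>(ps["tau_LTP"]), as<double>(ps["tau_LTD"]) };
    eta_I_s = as<double>(ps["eta_I"]); eta_I_c = as<double>(pc["eta_I"]);
    eta_TA = as<double>(ps["eta_TA"]); S_star = as<double>(ps["S_star"]);
    theta_floor = as<double>(ps["V_theta_floor"]);
    lambda_s = as<double>(ps["lambda"]); lambda_c = as<double>(pc["lambda"]);
    lambda_lat = as<double>(ps["lambda_lateral"]);
    lambda_td = as<double>(ps["lambda_topdown"]);
    V_min = as<double>(cfg["V_min"]);
    history = as<double>(cfg["history_ms"]);
    rate_alpha = as<double>(cfg["rate_alpha"]);
    theta_interval = as<double>(cfg["theta_update_ms"]);
    lateral_radius = as<int>(cfg["lateral_radius"]);

    n_critic = as<int>(rl["n_critic"]);
    n_actor_per = as<int>(rl["n_actor_per_action"]);
    n_actor = 2 * n_actor_per;
    nu = as<double>(rl["nu"]); V0 = as<double>(rl["V0"]);
    tau_r = as<double>(rl["tau_r"]);
    eta_actor_gain = as<double>(rl["eta_actor"]);
    Nwin = as<int>(rl["N"]);
    normalize_value = as<bool>(rl["normalize_value"]);
    tau_e = as<double>(pk["tau_e"]);
    tau_k = as<double>(pk["tau_k"]); nu_k = as<double>(pk["nu_k"]);
    rw_gamma = as<double>(rw["gamma"]); rw_beta = as<double>(rw["beta"]);
    rw_alpha = as<double>(rw["alpha"]); rw_eps = as<double>(rw["epsilon"]);

    sc.init(n_simple, p_s.V_thresh);
    cc.init(n_complex, p_c.V_thresh);
    rlc.init(n_critic + n_actor, p_rl.V_thresh);
    rl_A.assign(n_critic + n_actor, 0.0);
    rl_B.assign(n_critic + n_actor, 0.0);
    rl_rate_last.assign(n_critic + n_actor, 0.0);
    actor_counts.assign(2, 0.0);

    pix_hist.assign(W * H * 2, std::deque<double>());
    src_hist.assign(n_src, std::deque<double>());
    lat_log.assign(n_simple, std::deque<LogEntry>());
    td_log.assign(n_simple, std::deque<LogEntry>());

    // 8-connected (radius r) neighborhood of simple-cell locations
    neigh.assign(n_sloc, std::vector<int>());
    neigh_slot.assign(n_sloc, std::vector<int>());
    int r = lateral_radius;
    for (int gy = 0; gy < s_gh; ++gy)
      for (int gx = 0; gx < s_gw; ++gx) {
        int loc = gy * s_gw + gx;
        for (int dy = -r; dy <= r; ++dy)
          for (int dx = -r; dx <= r; ++dx) {
            if (dx == 0 && dy == 0) continue;
            int nx = gx + dx, ny = gy + dy;
            if (nx < 0 || nx >= s_gw || ny < 0 || ny >= s_gh) continue;
            neigh[loc].push_back(ny * s_gw + nx);
          }
      }
    n_neigh_max = (2 * r + 1) * (2 * r + 1) - 1;
    for (int loc = 0; loc < n_sloc; ++loc) {
      neigh_slot[loc].assign(neigh[loc].size(), -1);
      for (size_t k = 0; k < neigh[loc].size(); ++k) {
        int other = neigh[loc][k];
        // position of `loc` within `other`'s neighbor list
        for (size_t m = 0; m < neigh[other].size(); ++m)
          if (neigh[other][m] == loc) { neigh_slot[loc][k] = (int)m; break; }
      }
    }

    // weight allocation + random init (R RNG), normalized to lambda
    map_w.assign(s_maps, std::vector<double>());
    for (int m = 0; m < s_maps; ++m) {
      map_w[m].resize(s_rfw * s_rfh * 2);
      for (double& x : map_w[m]) x = unif_rand();
      clamp_norm(map_w[m], lambda_s);
    }
    complex_w.assign(n_complex, std::vector<double>());
    for (int i = 0; i < n_complex; ++i) {
      complex_w[i].resize(c_rfw * c_rfh * s_maps);
      for (double& x : complex_w[i]) x = unif_rand();
      clamp_norm(complex_w[i], lambda_c);
    }
    lat_w.assign(n_simple, std::vector<double>());
    td_w.assign(n_simple, std::vector<double>());
    for (int i = 0; i < n_simple; ++i) {
      int loc = i % n_sloc;
      lat_w[i].resize(neigh[loc].size() * s_maps);
      for (double& x : lat_w[i]) x = unif_rand();
      clamp_cap(lat_w[i], lambda_lat);
      td_w[i].resize(c_maps);
      for (double& x : td_w[i]) x = unif_rand();
      clamp_cap(td_w[i], lambda_td);
    }
    double gain = as<double>(rl["input_gain"]);
    double again = gain * as<double>(rl["actor_gain_mult"]);
    critic_w.assign(n_critic, std::vector<double>());
    critic_e.assign(n_critic, std::vector<double>(n_src, 0.0));
    critic_el.assign(n_critic, std::vector<double>(n_src, 0.0));
    for (int j = 0; j < n_critic; ++j) {
      critic_w[j].resize(n_src);
      for (double& x : critic_w[j]) x = unif_rand() * gain;
    }
    actor_w.assign(n_actor, std::vector<double>());
    actor_e.assign(n_actor, std::vector<double>(n_src, 0.0));
    actor_el.assign(n_actor, std::vector<double>(n_src, 0.0));
    actor_norm.assign(n_actor, 0.0);
    for (int j = 0; j < n_actor; ++j) {
      actor_w[j].resize(n_src);
      double tot = 0.0;
      for (double& x : actor_w[j]) { x = unif_rand() * again; tot += x; }
      actor_norm[j] = tot;
    }

    bin_events = bin_simple = 0.0;
    trk_S = trk_E = 0.0; trk_E_slow = 0.0;
    cur_V = V0; cur_vdot = 0.0; cur_delta = 0.0; cur_R = 0.0;
    t_last_tick = 0.0;
    tot_events = tot_simple = tot_complex = 0.0;
    learn_simple = learn_complex = learn_inh = true;
    ta_active = true;
    learn_rl = rl_active = false;
    reward_override = false; reward_value = 0.0;
    prev_action = -1;
  }

  // ---- spiking dynamics ---------------------------------------------------

  void rl_neuron_spike(int j, double t) {
    // j indexes the combined critic+actor array
    rlc.t_sm1[j] = rlc.t_s[j];
    rlc.t_s[j] = t;
    rlc.V[j] = p_rl.V_reset;
    rlc.bin_count[j] += 1;
    rlc.cum_count[j] += 1.0;
    // kernel rate estimator
    double dt = t - rl_rate_last[j];
    if (dt > 0.0) {
      rl_A[j] *= std::exp(-dt / tau_k);
      rl_B[j] *= std::exp(-dt / nu_k);
      rl_rate_last[j] = t;
    }
    rl_A[j] += 1.0; rl_B[j] += 1.0;
    if (j >= n_critic)
      actor_counts[(j - n_critic) / n_actor_per] += 1.0;
    if (learn_rl) {
      bool is_critic = j < n_critic;
      std::vector<double>& ev = is_critic ? critic_e[j] : actor_e[j - n_critic];
      std::vector<double>& el = is_critic ? critic_el[j] : actor_el[j - n_critic];
      double ts = rlc.t_s[j], tsm1 = rlc.t_sm1[j];
      for (int i = 0; i < n_src; ++i) {
        if (src_hist[i].empty()) continue;
        double inc = stdp_exp_sum(src_hist[i], ts, tsm1, stdp_rl);
        if (inc != 0.0) {
          double d = t - el[i];
          if (d > 0.0) ev[i] *= std::exp(-d / tau_e);
          el[i] = t;
          ev[i] += inc;
        }
      }
    }
  }

  void drive_rl(int src, double t, double w_scale = 1.0) {
    if (!rl_active) return;
    int n_rl = n_critic + n_actor;
    for (int j = 0; j < n_rl; ++j) {
      double w = (j < n_critic) ? critic_w[j][src]
                                : actor_w[j - n_critic][src];
      decay(rlc, p_rl, j, t);
      rlc.V[j] += w * w_scale;
      if (rlc.V[j] >= rlc.Vtheta[j]) rl_neuron_spike(j, t);
    }
  }

  void rep_spike(int src, double t) {
    std::deque<double>& q = src_hist[src];
    q.push_back(t);
    prune(q, t);
    drive_rl(src, t);
  }

  void on_complex_spike(int cell, double t) {
    int loc = cell % n_cloc, cmap = cell / n_cloc;
    int cx = loc % c_gw, cy = loc / c_gw;
    cc.t_sm1[cell] = cc.t_s[cell];
    cc.t_s[cell] = t;
    cc.V[cell] = p_c.V_reset;
    cc.bin_count[cell] += 1;
    cc.cum_count[cell] += 1.0;
    tot_complex += 1.0;

    // (1) step STDP on excitatory weights from simple cells, then normalize
    if (learn_complex) {
      std::vector<double>& w = complex_w[cell];
      double ts = cc.t_s[cell], tsm1 = cc.t_sm1[cell];
      int k = 0;
      for (int ry = 0; ry < c_rfh; ++ry)
        for (int rx = 0; rx < c_rfw; ++rx) {
          int sloc = (cy * c_sy + ry) * s_gw + (cx * c_sx + rx);
          for (int m = 0; m < s_maps; ++m, ++k) {
            const std::deque<double>& h = src_hist[m * n_sloc + sloc];
            if (h.empty()) continue;
            int n_ltp = 0, n_ltd = 0;
            for (auto it = h.rbegin(); it != h.rend(); ++it) {
              double ti = *it;
              if (ti < ts - history) break;
              if (std::fabs(ti - ts) <= stdp_c.tau_LTP) ++n_ltp;
              if (tsm1 > NEVER && std::fabs(tsm1 - ti) <= stdp_c.tau_LTD) ++n_ltd;
            }
            w[k] += stdp_c.eta_LTP * n_ltp + stdp_c.eta_LTD * n_ltd;
          }
        }
      clamp_norm(w, lambda_c);
    }

    // (2) static inhibition of same-location complex cells in other maps
    for (int m = 0; m < c_maps; ++m) {
      if (m == cmap) continue;
      int tgt = m * n_cloc + loc;
      decay(cc, p_c, tgt, t);
      cc.V[tgt] = std::max(V_min, cc.V[tgt] - eta_I_c);
    }

    // (3) top-down inhibitory spikes to all simple cells in the RF
    for (int ry = 0; ry < c_rfh; ++ry)
      for (int rx = 0; rx < c_rfw; ++rx) {
        int sloc = (cy * c_sy + ry) * s_gw + (cx * c_sx + rx);
        decay_simple_loc(sloc, t);
        for (int m = 0; m < s_maps; ++m) {
          int tgt = m * n_sloc + sloc;
          sc.V[tgt] = std::max(V_min, sc.V[tgt] - td_w[tgt][cmap]);
          td_log[tgt].push_back({cmap, t});
          prune(td_log[tgt], t);
        }
      }

    rep_spike(n_simple + cell, t);
  }

  void on_simple_spike(int cell, double t) {
    int loc = cell % n_sloc, map = cell / n_sloc;
    int gx = loc % s_gw, gy = loc / s_gw;
    sc.t_sm1[cell] = sc.t_s[cell];
    sc.t_s[cell] = t;
    sc.V[cell] = p_s.V_reset;
    sc.VSRA[cell] += p_s.eta_SRA;
    sc.bin_count[cell] += 1;
    sc.cum_count[cell] += 1.0;
    tot_simple += 1.0;
    bin_simple += 1.0;

    double ts = sc.t_s[cell], tsm1 = sc.t_sm1[cell];

    // (1) shared excitatory weights of the map: exponential STDP + normalize
    if (learn_simple) {
      std::vector<double>& w = map_w[map];
      int x0 = gx * s_sx, y0 = gy * s_sy;
      int k = 0;
      for (int pol = 0; pol < 2; ++pol)
        for (int ry = 0; ry < s_rfh; ++ry)
          for (int rx = 0; rx < s_rfw; ++rx, ++k) {
            const std::deque<double>& h =
              pix_hist[(pol * H + (y0 + ry)) * W + (x0 + rx)];
            if (h.empty()) continue;
            w[k] += stdp_exp_sum(h, ts, tsm1, stdp_s);
          }
      clamp_norm(w, lambda_s);
    }

    // (2) incoming inhibitory weights (lateral + top-down): STDP + normalize
    if (learn_inh) {
      std::vector<double>& wl = lat_w[cell];
      bool touched = false;
      for (const LogEntry& e : lat_log[cell]) {
        if (e.t > ts || e.t < std::max(tsm1, ts - history)) continue;
        double d = stdp_inh.eta_LTP * std::exp((e.t - ts) / stdp_inh.tau_LTP);
        if (tsm1 > NEVER)
          d -= stdp_inh.eta_LTD * std::exp((tsm1 - e.t) / stdp_inh.tau_LTD);
        wl[e.slot] += d;
        touched = true;
      }
      if (touched) clamp_cap(wl, lambda_lat);
      std::vector<double>& wt = td_w[cell];
      touched = false;
      for (const LogEntry& e : td_log[cell]) {
        if (e.t > ts || e.t < std::max(tsm1, ts - history)) continue;
        double d = stdp_inh.eta_LTP * std::exp((e.t - ts) / stdp_inh.tau_LTP);
        if (tsm1 > NEVER)
          d -= stdp_inh.eta_LTD * std::exp((tsm1 - e.t) / stdp_inh.tau_LTD);
        wt[e.slot] += d;
        touched = true;
      }
      if (touched) clamp_cap(wt, lambda_td);
    }

    // (3) static inhibition of same-location cells in other maps
    decay_simple_loc(loc, t);
    for (int m = 0; m < s_maps; ++m) {
      if (m == map) continue;
      int tgt = m * n_sloc + loc;
      sc.V[tgt] = std::max(V_min, sc.V[tgt] - eta_I_s);
    }

    // (4) lateral inhibitory spikes to neighboring locations, all maps
    const std::vector<int>& nb = neigh[loc];
    for (size_t k = 0; k < nb.size(); ++k) {
      int slot_base = neigh_slot[loc][k] * s_maps + map;
      decay_simple_loc(nb[k], t);
      for (int m = 0; m < s_maps; ++m) {
        int tgt = m * n_sloc + nb[k];
        sc.V[tgt] = std::max(V_min, sc.V[tgt] - lat_w[tgt][slot_base]);
        lat_log[tgt].push_back({slot_base, t});
        prune(lat_log[tgt], t);
      }
    }

    // (5) log for complex cells / RL populations and drive the complex layer
    rep_spike(cell, t);
    int cx = gx / c_sx, cy = gy / c_sy;
    if (cx < c_gw && cy < c_gh) {
      int cloc = cy * c_gw + cx;
      int rslot = ((gy - cy * c_sy) * c_rfw + (gx - cx * c_sx)) * s_maps + map;
      for (int m = 0; m < c_maps; ++m) {
        int tgt = m * n_cloc + cloc;
        decay(cc, p_c, tgt, t);
        cc.V[tgt] += complex_w[tgt][rslot];
        if (fires(cc, p_c, tgt, t))
          on_complex_spike(tgt, t);
      }
    }
  }

  void process_event(double t, int x, int y, int pol) {
    if (x < 0 || x >= W || y < 0 || y >= H)
      stop("event outside the retina");
    tot_events += 1.0;
    bin_events += 1.0;
    std::deque<double>& q = pix_hist[(pol * H + y) * W + x];
    q.push_back(t);
    prune(q, t);
    int gx = x / s_sx, gy = y / s_sy;
    if (gx >= s_gw || gy >= s_gh) return;       // outside the tiled area
    if (x - gx * s_sx >= s_rfw || y - gy * s_sy >= s_rfh) return;
    int loc = gy * s_gw + gx;
    int src = (pol * s_rfh + (y - gy * s_sy)) * s_rfw + (x - gx * s_sx);
    // weight layout: (pol, ry, rx) -> (pol*rfh + ry)*rfw + rx
    decay_simple_loc(loc, t);
    for (int m = 0; m < s_maps; ++m) {
      int cellI = m * n_sloc + loc;
      sc.V[cellI] += map_w[m][src];
      if (fires(sc, p_s, cellI, t))
        on_simple_spike(cellI, t);
    }
  }

  // ---- clocked bookkeeping ------------------------------------------------

  void tick(double t) {
    // per-cell rolling rates (EMA over 1 ms bins, in spikes/s)
    for (int i = 0; i < n_simple; ++i) {
      sc.S[i] = (1.0 - rate_alpha) * sc.S[i] +
                rate_alpha * (sc.bin_count[i] * 1000.0);
      sc.bin_count[i] = 0;
    }
    for (int i = 0; i < n_complex; ++i) cc.bin_count[i] = 0;
    // threshold adaptation on the configured interval
    long tick = (long)(t + 0.5);
    long theta_every = (long)(theta_interval + 0.5);
    if (ta_active && eta_TA > 0.0 && theta_every > 0 && tick % theta_every == 0) {
      for (int i = 0; i < n_simple; ++i) {
        sc.Vtheta[i] = std::max(theta_floor,
          sc.Vtheta[i] + eta_TA * (sc.S[i] - S_star) / S_star);
      }
    }
    // population activity trackers
    trk_S = rw_alpha * bin_simple + (1.0 - rw_alpha) * trk_S;
    trk_E = rw_alpha * bin_events + (1.0 - rw_alpha) * trk_E;
    // slow reference rate (~10 s memory) for relative value normalization
    trk_E_slow = 1e-4 * bin_events + (1.0 - 1e-4) * trk_E_slow;
    bin_simple = bin_events = 0.0;
    // reward (overridable for programmed-reward experiments)
    cur_R = reward_override ? reward_value
            : (trk_E < rw_eps) ? 0.0
            : rw_gamma * (rw_beta - trk_S) / trk_E;

    if (rl_active) {
      // critic value from kernel-decoded rates (per-ms units)
      double sum_rho = 0.0;
      for (int j = 0; j < n_critic; ++j) {
        double dt = t - rl_rate_last[j];
        double A = rl_A[j] * std::exp(-dt / tau_k);
        double B = rl_B[j] * std::exp(-dt / nu_k);
        sum_rho += (A - B) / (tau_k - nu_k);
      }
      // relative event-rate normalization: divide by E / <E>, so the value
      // is insensitive to input-rate fluctuations but keeps its scale
      double En = normalize_value
        ? std::max(std::max(trk_E, rw_eps) / std::max(trk_E_slow, rw_eps),
                   0.5)
        : 1.0;
      cur_V = (nu / n_critic) * sum_rho / En + V0;
      value_buf.push_back(cur_V);
      while ((int)value_buf.size() > Nwin + 2) value_buf.pop_front();
      if ((int)value_buf.size() >= Nwin + 2) {
        double s = 0.0;
        int n = value_buf.size();
        for (int j = n - 1 - Nwin; j <= n - 2; ++j)
          s += (value_buf[j + 1] - value_buf[j - 1]) / 2.0;
        cur_vdot = (eta_actor_gain / Nwin) * s;
      } else cur_vdot = 0.0;
      cur_delta = cur_vdot - cur_V / tau_r + cur_R;
    }
    t_last_tick = t;
  }

  List action_step(double t, double lambda_exp, double eta_c, double eta_a) {
    // (1) reward transmission: three-factor update of the critic and of the
    // actor group whose action was executed over the elapsed interval
    if (learn_rl && cur_delta != 0.0) {
      for (int j = 0; j < n_critic; ++j) {
        std::vector<double>& w = critic_w[j];
        std::vector<double>& ev = critic_e[j];
        std::vector<double>& el = critic_el[j];
        for (int i = 0; i < n_src; ++i) {
          if (ev[i] == 0.0) continue;
          double d = t - el[i];
          if (d > 0.0) { ev[i] *= std::exp(-d / tau_e); el[i] = t; }
          w[i] += eta_c * ev[i] * cur_delta;
          if (w[i] < 0.0) w[i] = 0.0;
        }
      }
      if (prev_action >= 0) {
        int j0 = prev_action * n_actor_per;
        for (int j = j0; j < j0 + n_actor_per; ++j) {
          std::vector<double>& w = actor_w[j];
          std::vector<double>& ev = actor_e[j];
          std::vector<double>& el = actor_el[j];
          for (int i = 0; i < n_src; ++i) {
            if (ev[i] == 0.0) continue;
            double d = t - el[i];
            if (d > 0.0) { ev[i] *= std::exp(-d / tau_e); el[i] = t; }
            w[i] += eta_a * ev[i] * cur_delta;
            if (w[i] < 0.0) w[i] = 0.0;
          }
          // each actor neuron keeps a fixed synaptic budget: learning
          // reshapes its state preference, not its overall excitability,
          // so the winner-take-all readout compares patterns
          clamp_norm(w, actor_norm[j]);
        }
      }
    }
    // (2) winner-take-all selection with exploration
    double c0 = actor_counts[0], c1 = actor_counts[1];
    int action;
    bool explored = false;
    if (lambda_exp > 0.0 && unif_rand() < lambda_exp) {
      action = (unif_rand() < 0.5) ? 0 : 1;
      explored = true;
    } else if (c0 > c1) action = 0;
    else if (c1 > c0) action = 1;
    else action = (unif_rand() < 0.5) ? 0 : 1;
    prev_action = action;
    actor_counts[0] = actor_counts[1] = 0.0;
    return List::create(_["action"] = action + 1, _["explored"] = explored,
                        _["V"] = cur_V, _["v_dot"] = cur_vdot,
                        _["delta"] = cur_delta, _["R"] = cur_R,
                        _["counts"] = NumericVector::create(c0, c1));
  }
};


// ---- closed-loop driver -----------------------------------------------------
//
// The environment (striped ball over a dotted world, or bar grating in an
// aperture), the log-threshold event emulator and the action/schedule logic
// run inside the engine so long closed-loop trainings stay cheap. All
// randomness (OU jitter, resets, exploration) uses R's RNG.

struct ClosedLoopEnv {
  bool tracking;
  int W, H;
  double fov_half, error, gaze, drift_dir, action_vel;
  double oux, ouy, ou_theta, ou_sigma;
  double cam_speed, drift_speed;       // rad/s
  double ball_r, stripe_w;             // px
  int n_stripes;
  double n_bars, duty, aperture;
  std::vector<double> ref;             // converter reference log-luminance
  double thresh, I_floor;
  bool ref_ready;

  double lum(int x0, int y0) const {
    double xs = x0 + 0.5, ys = y0 + 0.5;
    if (tracking) {
      double jx = oux, jy = ouy;
      double cx = (error / fov_half) * (W / 2.0) + W / 2.0 + jx;
      double cy = H / 2.0 + jy;
      double gaze_px = (gaze / fov_half) * (W / 2.0);
      long xi = (long)std::floor(xs - 0.5 + gaze_px + jx);
      long yi = (long)std::floor(ys - 0.5 + jy);
      long m = (7 * xi + 13 * yi) % 19; if (m < 0) m += 19;
      double f = (m == 0) ? 0.35 : 0.1;
      double dx = xs - cx, dy = ys - cy;
      if (dx * dx + dy * dy <= ball_r * ball_r) {
        long band = (long)std::floor((xs - cx + ball_r) / stripe_w) % 2;
        if (band < 0) band += 2;
        f = (band == 0) ? 1.0 : 0.4;
      }
      return f;
    } else {
      double xsc = xs - W / 2.0 - oux, ysc = ys - H / 2.0 - ouy;
      double yr = -xsc * std::sin(error) + ysc * std::cos(error);
      double xr = xsc * std::cos(error) + ysc * std::sin(error);
      long xi = (long)std::floor(xr), yi = (long)std::floor(yr);
      long m = (7 * xi + 13 * yi) % 19; if (m < 0) m += 19;
      double f = (m == 0) ? 0.35 : 0.1;
      if (xsc * xsc + ysc * ysc <= aperture * aperture) {
        double period = H / n_bars;
        double ph = yr / period - std::floor(yr / period);
        f = (ph < duty) ? 1.0 : 0.1;
      }
      return f;
    }
  }

  // advance dynamics by 1 ms; action: -1 keep, 0 none, 1 left, 2 right
  void step(int action, double dt = 0.001) {
    if (action >= 0)
      action_vel = (action == 1) ? -cam_speed : (action == 2) ? cam_speed
                   : 0.0;
    gaze += action_vel * dt;
    error += -action_vel * dt + drift_dir * drift_speed * dt;
    if (tracking) {
      error -= 2.0 * M_PI * std::floor((error + M_PI) / (2.0 * M_PI));
    } else {
      error -= M_PI * std::floor((error + M_PI_2) / M_PI);
    }
    oux += ou_theta * (0.0 - oux) * dt + ou_sigma * std::sqrt(dt) * norm_rand();
    ouy += ou_theta * (0.0 - ouy) * dt + ou_sigma * std::sqrt(dt) * norm_rand();
  }

  void reset(int dist, int& border_side, double& drift_dir_out) {
    double half = tracking ? fov_half : M_PI_2;
    if (dist == 0) {                       // uniform
      error = unif_rand() * 1.8 * half - 0.9 * half;
    } else if (dist == 1) {                // centered-normal
      double d = norm_rand() * half / 3.0;
      error = std::max(-0.9 * half, std::min(0.9 * half, d));
    } else {                               // border, alternating
      error = 0.85 * half * border_side;
      border_side = -border_side;
    }
    drift_dir = (unif_rand() < 0.5) ? -1.0 : 1.0;
    drift_dir_out = drift_dir;
  }

  // render + event conversion for one tick ending at t_ms; feeds the net
  void tick_events(Net* net, double t_ms) {
    int n = W * H;
    if (!ref_ready) {
      ref.resize(n);
      for (int y = 0; y < H; ++y)
        for (int x = 0; x < W; ++x)
          ref[y * W + x] = std::log(lum(x, y) + I_floor);
      ref_ready = true;
      return;
    }
    // events sorted by (t, y, x, pol): collect then stable emit
    struct Ev { double t; int x, y, pol; };
    static std::vector<Ev> evs;
    evs.clear();
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        double L = std::log(lum(x, y) + I_floor);
        double d = L - ref[y * W + x];
        int k = (int)std::floor(std::fabs(d) / thresh);
        if (k <= 0) continue;
        int pol = d > 0 ? 1 : 0;
        double sgn = d > 0 ? 1.0 : -1.0;
        ref[y * W + x] += sgn * k * thresh;
        for (int j = 1; j <= k; ++j) {
          double frac = (double)j / (k + 1);
          evs.push_back({t_ms - 1.0 + frac, x, y, pol});
        }
      }
    std::stable_sort(evs.begin(), evs.end(),
                     [](const Ev& a, const Ev& b) {
                       if (a.t != b.t) return a.t < b.t;
                       if (a.y != b.y) return a.y < b.y;
                       if (a.x != b.x) return a.x < b.x;
                       return a.pol < b.pol;
                     });
    for (const Ev& e : evs) net->process_event(e.t, e.x, e.y, e.pol);
  }
};

static ClosedLoopEnv make_env(List envp) {
  ClosedLoopEnv env;
  env.tracking = as<std::string>(envp["task"]) == "tracking";
  env.W = envp["width"]; env.H = envp["height"];
  env.fov_half = envp["fov_half"];
  env.error = envp["error"]; env.gaze = envp["gaze"];
  env.drift_dir = envp["drift_dir"]; env.action_vel = 0.0;
  env.oux = env.ouy = 0.0;
  env.ou_theta = envp["ou_theta"]; env.ou_sigma = envp["ou_sigma"];
  env.cam_speed = envp["cam_speed"]; env.drift_speed = envp["drift_speed"];
  env.ball_r = envp["ball_r"]; env.n_stripes = envp["n_stripes"];
  env.stripe_w = env.n_stripes > 0 ? 2.0 * env.ball_r / env.n_stripes : 1.0;
  env.n_bars = envp["n_bars"]; env.duty = envp["duty"];
  env.aperture = 0.45 * std::min(env.W, env.H);
  env.thresh = envp["threshold"]; env.I_floor = envp["I_floor"];
  env.ref_ready = false;
  return env;
}

// [[Rcpp::export]]
NumericMatrix eng_render_frame(List envp, double oux, double ouy) {
  // debug/parity hook: the closed-loop renderer's frame at a given state
  ClosedLoopEnv env = make_env(envp);
  env.oux = oux; env.ouy = ouy;
  NumericMatrix out(env.H, env.W);
  for (int y = 0; y < env.H; ++y)
    for (int x = 0; x < env.W; ++x)
      out(y, x) = env.lum(x, y);
  return out;
}

// [[Rcpp::export]]
List eng_closed_loop(SEXP p, List envp, List ctrl) {
  XPtr<Net> net(p);
  ClosedLoopEnv env = make_env(envp);
  double t0 = ctrl["t0"];
  int n_ticks = ctrl["n_ticks"];
  bool act = ctrl["act"];
  bool learn_sched = ctrl["decay_schedule"];
  bool exit_resets = ctrl["exit_resets"];
  int reset_every = ctrl["reset_every_ms"];
  int reset_dist = ctrl["reset_dist"];   // 0 uniform, 1 centered, 2 border
  double interval = ctrl["action_interval"];
  double interval_min = ctrl["action_interval_min"];
  double lambda_exp = ctrl["lambda_EXP"];
  double eta_c = ctrl["eta_critic"], eta_a = ctrl["eta_actor"];
  double fc = 1.0 - as<double>(ctrl["eta_decay_critic"]) / 100.0;
  double fa = 1.0 - as<double>(ctrl["eta_decay_actor"]) / 100.0;
  double Delta_decay = ctrl["Delta_decay"];
  int border_side = ctrl["border_side"];

  double next_action = interval, next_decay = Delta_decay;
  int last_reset = -100000;
  std::vector<double> tr_err(n_ticks);
  std::vector<int> tr_reset(n_ticks);
  std::vector<double> m_t, m_action, m_explored, m_V, m_delta, m_R, m_l,
    m_r, m_lambda, m_interval;
  double dd;

  env.tick_events(net.get(), t0);  // initialize the converter reference
  for (int k = 1; k <= n_ticks; ++k) {
    bool reset_now = (reset_every > 0) && (k % reset_every == 0);
    if (exit_resets && env.tracking &&
        std::fabs(env.error) > 0.95 * env.fov_half && k - last_reset > 300)
      reset_now = true;
    if (reset_now) { env.reset(reset_dist, border_side, dd); last_reset = k; }
    env.step(-1);
    double t_ms = t0 + k;
    env.tick_events(net.get(), t_ms);
    net->tick(t_ms);
    tr_err[k - 1] = env.error;
    tr_reset[k - 1] = reset_now ? 1 : 0;
    if (act && k >= next_action) {
      List res = net->action_step(t_ms, lambda_exp, eta_c, eta_a);
      int action = res["action"];
      env.step(action);   // switch the commanded velocity only
      env.gaze -= env.action_vel * 0.001;   // undo the dt advance of step()
      env.error += env.action_vel * 0.001 - env.drift_dir * env.drift_speed * 0.001;
      m_t.push_back(t_ms); m_action.push_back(action);
      m_explored.push_back(as<bool>(res["explored"]) ? 1.0 : 0.0);
      m_V.push_back(as<double>(res["V"]));
      m_delta.push_back(as<double>(res["delta"]));
      m_R.push_back(as<double>(res["R"]));
      NumericVector cc = res["counts"];
      m_l.push_back(cc[0]); m_r.push_back(cc[1]);
      m_lambda.push_back(lambda_exp); m_interval.push_back(interval);
      next_action = k + interval;
    }
    if (learn_sched && k >= next_decay) {
      lambda_exp *= fc; eta_c *= fc; eta_a *= fa;
      interval = std::max(interval_min, interval * fc);
      next_decay = k + Delta_decay;
    }
  }
  return List::create(
    _["trace_error"] = tr_err, _["trace_reset"] = tr_reset,
    _["m"] = List::create(_["t_ms"] = m_t, _["action"] = m_action,
                          _["explored"] = m_explored, _["V"] = m_V,
                          _["delta"] = m_delta, _["R"] = m_R,
                          _["left"] = m_l, _["right"] = m_r,
                          _["lambda_EXP"] = m_lambda,
                          _["interval"] = m_interval),
    _["schedule"] = List::create(_["lambda_EXP"] = lambda_exp,
                                 _["eta_critic"] = eta_c,
                                 _["eta_actor"] = eta_a,
                                 _["action_interval"] = interval,
                                 _["border_side"] = border_side),
    _["env"] = List::create(_["error"] = env.error, _["gaze"] = env.gaze,
                            _["drift_dir"] = env.drift_dir));
}

// ---- R interface -----------------------------------------------------------

// [[Rcpp::export]]
SEXP aec_engine_new(List cfg) {
  Net* net = new Net();
  net->build(cfg);
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
void eng_set_flags(SEXP p, bool learn_simple, bool learn_complex,
                   bool learn_inh, bool learn_rl, bool rl_active,
                   bool ta_active) {
  XPtr<Net> net(p);
  net->learn_simple = learn_simple;
  net->learn_complex = learn_complex;
  net->learn_inh = learn_inh;
  net->learn_rl = learn_rl;
  net->rl_active = rl_active;
  net->ta_active = ta_active;
}

// [[Rcpp::export]]
void eng_feed_events(SEXP p, NumericVector t_ms, IntegerVector x,
                     IntegerVector y, IntegerVector pol) {
  XPtr<Net> net(p);
  int n = t_ms.size();
  for (int i = 0; i < n; ++i)
    net->process_event(t_ms[i], x[i], y[i], pol[i]);
}

// [[Rcpp::export]]
List eng_replay(SEXP p, double t_start, NumericVector rel_t, IntegerVector x,
                IntegerVector y, IntegerVector pol, int n_ticks, int repeats) {
  // replay one recorded stream `repeats` times back to back, entirely in C++
  XPtr<Net> net(p);
  int n = rel_t.size();
  NumericMatrix out(repeats, 3);
  double t0 = t_start;
  for (int r = 0; r < repeats; ++r) {
    double e0 = net->tot_events, s0 = net->tot_simple, c0 = net->tot_complex;
    int i = 0;
    for (int k = 1; k <= n_ticks; ++k) {
      while (i < n && rel_t[i] <= (double)k) {
        net->process_event(t0 + rel_t[i], x[i], y[i], pol[i]);
        ++i;
      }
      net->tick(t0 + k);
    }
    while (i < n) { net->process_event(t0 + rel_t[i], x[i], y[i], pol[i]); ++i; }
    out(r, 0) = net->tot_events - e0;
    out(r, 1) = net->tot_simple - s0;
    out(r, 2) = net->tot_complex - c0;
    t0 += n_ticks;
  }
  return List::create(_["counts"] = out, _["t_end"] = t0);
}

// [[Rcpp::export]]
void eng_tick(SEXP p, double t_ms) {
  XPtr<Net> net(p);
  net->tick(t_ms);
}

// [[Rcpp::export]]
List eng_action_step(SEXP p, double t_ms, double lambda_exp,
                     double eta_c, double eta_a) {
  XPtr<Net> net(p);
  return net->action_step(t_ms, lambda_exp, eta_c, eta_a);
}

// [[Rcpp::export]]
void eng_set_reward_override(SEXP p, bool on, double value) {
  XPtr<Net> net(p);
  net->reward_override = on;
  net->reward_value = value;
}

// [[Rcpp::export]]
void eng_inject_spikes(SEXP p, IntegerVector src, NumericVector t_ms) {
  // inject representation-layer spikes directly (toy / probe experiments)
  XPtr<Net> net(p);
  for (int i = 0; i < src.size(); ++i) {
    if (src[i] < 0 || src[i] >= net->n_src) stop("bad source index");
    net->rep_spike(src[i], t_ms[i]);
  }
}

// [[Rcpp::export]]
void eng_inject_rep_spike(SEXP p, int src, double t_ms) {
  XPtr<Net> net(p);
  if (src < 0 || src >= net->n_src) stop("bad source index");
  net->rep_spike(src, t_ms);
}

// [[Rcpp::export]]
List eng_status(SEXP p) {
  XPtr<Net> net(p);
  return List::create(
    _["events"] = net->tot_events, _["simple"] = net->tot_simple,
    _["complex"] = net->tot_complex,
    _["S"] = net->trk_S, _["E"] = net->trk_E,
    _["V"] = net->cur_V, _["v_dot"] = net->cur_vdot,
    _["delta"] = net->cur_delta, _["R"] = net->cur_R,
    _["actor_counts"] = NumericVector(net->actor_counts.begin(),
                                      net->actor_counts.end()));
}

// [[Rcpp::export]]
List eng_cell_counts(SEXP p, bool reset) {
  XPtr<Net> net(p);
  NumericVector s(net->sc.cum_count.begin(), net->sc.cum_count.end());
  NumericVector c(net->cc.cum_count.begin(), net->cc.cum_count.end());
  NumericVector r(net->rlc.cum_count.begin(), net->rlc.cum_count.end());
  if (reset) {
    std::fill(net->sc.cum_count.begin(), net->sc.cum_count.end(), 0.0);
    std::fill(net->cc.cum_count.begin(), net->cc.cum_count.end(), 0.0);
    std::fill(net->rlc.cum_count.begin(), net->rlc.cum_count.end(), 0.0);
  }
  return List::create(_["simple"] = s, _["complex"] = c, _["rl"] = r);
}

// [[Rcpp::export]]
void eng_reset_totals(SEXP p) {
  XPtr<Net> net(p);
  net->tot_events = net->tot_simple = net->tot_complex = 0.0;
}

// [[Rcpp::export]]
List eng_get_weights(SEXP p) {
  XPtr<Net> net(p);
  List maps(net->s_maps);
  for (int m = 0; m < net->s_maps; ++m)
    maps[m] = NumericVector(net->map_w[m].begin(), net->map_w[m].end());
  List cw(net->n_complex);
  for (int i = 0; i < net->n_complex; ++i)
    cw[i] = NumericVector(net->complex_w[i].begin(), net->complex_w[i].end());
  List lw(net->n_simple), tw(net->n_simple);
  for (int i = 0; i < net->n_simple; ++i) {
    lw[i] = NumericVector(net->lat_w[i].begin(), net->lat_w[i].end());
    tw[i] = NumericVector(net->td_w[i].begin(), net->td_w[i].end());
  }
  int n_rl_c = net->n_critic, n_rl_a = net->n_actor, ns = net->n_src;
  NumericMatrix kw(n_rl_c, ns), aw(n_rl_a, ns);
  for (int j = 0; j < n_rl_c; ++j)
    for (int i = 0; i < ns; ++i) kw(j, i) = net->critic_w[j][i];
  for (int j = 0; j < n_rl_a; ++j)
    for (int i = 0; i < ns; ++i) aw(j, i) = net->actor_w[j][i];
  return List::create(_["simple_maps"] = maps, _["complex"] = cw,
                      _["lateral"] = lw, _["topdown"] = tw,
                      _["critic"] = kw, _["actor"] = aw);
}

static void shuffle_tensor(std::vector< std::vector<double> >& store) {
  // Fisher-Yates over the concatenation of all cells' weight vectors
  std::vector<double*> flat;
  for (auto& v : store)
    for (double& x : v) flat.push_back(&x);
  for (size_t k = flat.size() - 1; k > 0; --k) {
    size_t j = (size_t)std::floor(unif_rand() * (k + 1));
    if (j > k) j = k;
    std::swap(*flat[k], *flat[j]);
  }
}

// [[Rcpp::export]]
void eng_shuffle_inhibition(SEXP p) {
  // control condition: permute the learned inhibitory weights uniformly at
  // random within each weight tensor (lateral store, top-down store)
  XPtr<Net> net(p);
  shuffle_tensor(net->lat_w);
  shuffle_tensor(net->td_w);
}

// [[Rcpp::export]]
NumericVector eng_membrane(SEXP p, std::string layer) {
  XPtr<Net> net(p);
  CellArrays* a = (layer == "simple") ? &net->sc :
                  (layer == "complex") ? &net->cc : &net->rlc;
  return NumericVector(a->V.begin(), a->V.end());
}

// [[Rcpp::export]]
NumericVector eng_thresholds(SEXP p) {
  XPtr<Net> net(p);
  return NumericVector(net->sc.Vtheta.begin(), net->sc.Vtheta.end());
}

// [[Rcpp::export]]
NumericVector eng_rates(SEXP p, std::string layer, double t_ms) {
  XPtr<Net> net(p);
  if (layer == "simple")
    return NumericVector(net->sc.S.begin(), net->sc.S.end());
  // kernel-decoded rates of the RL populations, per-ms units
  int n = net->n_critic + net->n_actor;
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    double dt = t_ms - net->rl_rate_last[j];
    double A = net->rl_A[j] * std::exp(-dt / net->tau_k);
    double B = net->rl_B[j] * std::exp(-dt / net->nu_k);
    out[j] = (A - B) / (net->tau_k - net->nu_k);
  }
  return out;
}

// [[Rcpp::export]]
List eng_eligibility(SEXP p, double t_ms) {
  XPtr<Net> net(p);
  int ns = net->n_src;
  NumericMatrix ke(net->n_critic, ns), ae(net->n_actor, ns);
  for (int j = 0; j < net->n_critic; ++j)
    for (int i = 0; i < ns; ++i)
      ke(j, i) = net->critic_e[j][i] *
        std::exp(-(t_ms - net->critic_el[j][i]) / net->tau_e);
  for (int j = 0; j < net->n_actor; ++j)
    for (int i = 0; i < ns; ++i)
      ae(j, i) = net->actor_e[j][i] *
        std::exp(-(t_ms - net->actor_el[j][i]) / net->tau_e);
  return List::create(_["critic"] = ke, _["actor"] = ae);
}

// ---- checkpointing ---------------------------------------------------------

static List deque_list(const std::vector< std::deque<double> >& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    out[i] = NumericVector(v[i].begin(), v[i].end());
  return out;
}
static void list_deque(List in, std::vector< std::deque<double> >& v) {
  for (size_t i = 0; i < v.size(); ++i) {
    NumericVector x = in[i];
    v[i].assign(x.begin(), x.end());
  }
}
static List log_list(const std::vector< std::deque<Net::LogEntry> >& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int n = v[i].size();
    IntegerVector slot(n); NumericVector t(n);
    for (int k = 0; k < n; ++k) { slot[k] = v[i][k].slot; t[k] = v[i][k].t; }
    out[i] = List::create(_["slot"] = slot, _["t"] = t);
  }
  return out;
}
static void list_log(List in, std::vector< std::deque<Net::LogEntry> >& v) {
  for (size_t i = 0; i < v.size(); ++i) {
    List e = in[i];
    IntegerVector slot = e["slot"]; NumericVector t = e["t"];
    v[i].clear();
    for (int k = 0; k < slot.size(); ++k)
      v[i].push_back({slot[k], t[k]});
  }
}
static List cells_list(const CellArrays& a) {
  return List::create(
    _["V"] = NumericVector(a.V.begin(), a.V.end()),
    _["VSRA"] = NumericVector(a.VSRA.begin(), a.VSRA.end()),
    _["Vtheta"] = NumericVector(a.Vtheta.begin(), a.Vtheta.end()),
    _["t_s"] = NumericVector(a.t_s.begin(), a.t_s.end()),
    _["t_sm1"] = NumericVector(a.t_sm1.begin(), a.t_sm1.end()),
    _["last_up"] = NumericVector(a.last_up.begin(), a.last_up.end()),
    _["S"] = NumericVector(a.S.begin(), a.S.end()),
    _["cum"] = NumericVector(a.cum_count.begin(), a.cum_count.end()));
}
static void list_cells(List in, CellArrays& a) {
  NumericVector V = in["V"], VS = in["VSRA"], Vt = in["Vtheta"],
    ts = in["t_s"], tsm = in["t_sm1"], lu = in["last_up"], S = in["S"],
    cum = in["cum"];
  a.V.assign(V.begin(), V.end()); a.VSRA.assign(VS.begin(), VS.end());
  a.Vtheta.assign(Vt.begin(), Vt.end()); a.t_s.assign(ts.begin(), ts.end());
  a.t_sm1.assign(tsm.begin(), tsm.end());
  a.last_up.assign(lu.begin(), lu.end()); a.S.assign(S.begin(), S.end());
  a.cum_count.assign(cum.begin(), cum.end());
  a.bin_count.assign(a.V.size(), 0);
}
static List vecs_list(const std::vector< std::vector<double> >& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    out[i] = NumericVector(v[i].begin(), v[i].end());
  return out;
}
static void list_vecs(List in, std::vector< std::vector<double> >& v) {
  for (size_t i = 0; i < v.size(); ++i) {
    NumericVector x = in[i];
    v[i].assign(x.begin(), x.end());
  }
}

// [[Rcpp::export]]
List eng_get_state(SEXP p) {
  XPtr<Net> net(p);
  return List::create(
    _["simple"] = cells_list(net->sc),
    _["complex"] = cells_list(net->cc),
    _["rl"] = cells_list(net->rlc),
    _["map_w"] = vecs_list(net->map_w),
    _["complex_w"] = vecs_list(net->complex_w),
    _["lat_w"] = vecs_list(net->lat_w),
    _["td_w"] = vecs_list(net->td_w),
    _["critic_w"] = vecs_list(net->critic_w),
    _["actor_w"] = vecs_list(net->actor_w),
    _["critic_e"] = vecs_list(net->critic_e),
    _["actor_e"] = vecs_list(net->actor_e),
    _["critic_el"] = vecs_list(net->critic_el),
    _["actor_el"] = vecs_list(net->actor_el),
    _["actor_norm"] = NumericVector(net->actor_norm.begin(),
                                    net->actor_norm.end()),
    _["rl_A"] = NumericVector(net->rl_A.begin(), net->rl_A.end()),
    _["rl_B"] = NumericVector(net->rl_B.begin(), net->rl_B.end()),
    _["rl_rate_last"] = NumericVector(net->rl_rate_last.begin(),
                                      net->rl_rate_last.end()),
    _["actor_counts"] = NumericVector(net->actor_counts.begin(),
                                      net->actor_counts.end()),
    _["pix_hist"] = deque_list(net->pix_hist),
    _["src_hist"] = deque_list(net->src_hist),
    _["lat_log"] = log_list(net->lat_log),
    _["td_log"] = log_list(net->td_log),
    _["value_buf"] = NumericVector(net->value_buf.begin(),
                                   net->value_buf.end()),
    _["scalars"] = NumericVector::create(
      net->trk_S, net->trk_E, net->cur_V, net->cur_vdot, net->cur_delta,
      net->cur_R, net->t_last_tick, net->tot_events, net->tot_simple,
      net->tot_complex, net->bin_events, net->bin_simple,
      net->trk_E_slow, (double)net->prev_action));
}

// [[Rcpp::export]]
void eng_set_state(SEXP p, List st) {
  XPtr<Net> net(p);
  list_cells(st["simple"], net->sc);
  list_cells(st["complex"], net->cc);
  list_cells(st["rl"], net->rlc);
  list_vecs(st["map_w"], net->map_w);
  list_vecs(st["complex_w"], net->complex_w);
  list_vecs(st["lat_w"], net->lat_w);
  list_vecs(st["td_w"], net->td_w);
  list_vecs(st["critic_w"], net->critic_w);
  list_vecs(st["actor_w"], net->actor_w);
  list_vecs(st["critic_e"], net->critic_e);
  list_vecs(st["actor_e"], net->actor_e);
  list_vecs(st["critic_el"], net->critic_el);
  list_vecs(st["actor_el"], net->actor_el);
  if (st.containsElementNamed("actor_norm")) {
    NumericVector AN = st["actor_norm"];
    net->actor_norm.assign(AN.begin(), AN.end());
  }
  NumericVector A = st["rl_A"], B = st["rl_B"], RL = st["rl_rate_last"],
    AC = st["actor_counts"], VB = st["value_buf"], SC = st["scalars"];
  net->rl_A.assign(A.begin(), A.end());
  net->rl_B.assign(B.begin(), B.end());
  net->rl_rate_last.assign(RL.begin(), RL.end());
  net->actor_counts.assign(AC.begin(), AC.end());
  list_deque(st["pix_hist"], net->pix_hist);
  list_deque(st["src_hist"], net->src_hist);
  list_log(st["lat_log"], net->lat_log);
  list_log(st["td_log"], net->td_log);
  net->value_buf.assign(VB.begin(), VB.end());
  net->trk_S = SC[0]; net->trk_E = SC[1]; net->cur_V = SC[2];
  net->cur_vdot = SC[3]; net->cur_delta = SC[4]; net->cur_R = SC[5];
  net->t_last_tick = SC[6]; net->tot_events = SC[7];
  net->tot_simple = SC[8]; net->tot_complex = SC[9];
  net->bin_events = SC[10]; net->bin_simple = SC[11];
  net->trk_E_slow = (SC.size() > 12) ? SC[12] : net->trk_E;
  net->prev_action = (SC.size() > 13) ? (int)SC[13] : -1;
}
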