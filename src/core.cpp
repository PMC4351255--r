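// Core simulation engine: the attention-gated tag/trace SARSA(lambda) agent
// and the four discrete-time task environments. All state lives behind
// external pointers; R orchestrates trials and experiments.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// small dense matrix (column indexing (i,j) = i + j*nr)
// ---------------------------------------------------------------------------
struct Mat {
  int nr = 0, nc = 0;
  std::vector<double> v;
  Mat() {}
  Mat(int r, int c) : nr(r), nc(c), v((size_t)r * c, 0.0) {}
  double& operator()(int i, int j) { return v[(size_t)i + (size_t)j * nr]; }
  double operator()(int i, int j) const { return v[(size_t)i + (size_t)j * nr]; }
  void zero() { std::fill(v.begin(), v.end(), 0.0); }
  void scale(double s) { for (double& x : v) x *= s; }
};

static NumericMatrix asR(const Mat& m) {
  NumericMatrix out(m.nr, m.nc);
  std::copy(m.v.begin(), m.v.end(), out.begin());
  return out;
}
static Mat fromR(const NumericMatrix& m) {
  Mat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.v.begin());
  return out;
}

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// logistic activation with offset theta; saturates gracefully
static inline double sigmoid(double inp, double theta) {
  double z = theta - inp;
  if (z > 500.0) z = 500.0;
  if (z < -500.0) z = -500.0;
  return 1.0 / (1.0 + std::exp(z));
}

// ---------------------------------------------------------------------------
// Agent
// ---------------------------------------------------------------------------
struct Net {
  int n_inst, n_reg, n_mem, n_q;
  double beta, lambda, gamma, alpha, epsilon, theta;

  // weights (bias = last row of V_reg / W_reg; memory units have no bias)
  Mat V_reg;   // (n_inst+1) x n_reg
  Mat V_mem;   // (2*n_inst) x n_mem, rows [0,n_inst) on-, [n_inst,2n) off-units
  Mat W_reg;   // (n_reg+1)  x n_q
  Mat W_mem;   // n_mem x n_q
  Mat FB_reg;  // n_q x n_reg  (feedback, updated by the same tag rule)
  Mat FB_mem;  // n_q x n_mem

  // plasticity state
  Mat tV_reg, tV_mem, tW_reg, tW_mem, tFB_reg, tFB_mem;
  Mat trace;  // sTrace, congruent to V_mem

  // activities
  std::vector<double> x_prev, x_inst, x_on, x_off, inp_mem, y_reg, y_mem, q;
  double q_stored = 0.0;
  bool has_q = false;
  int action = -1;
  int t = 0;
  double last_delta = NA_REAL;

  std::mt19937_64 rng_act;

  Net(int ninst, int nreg, int nmem, int nq, double init_lo, double init_hi,
      double beta_, double lambda_, double gamma_, double epsilon_,
      double theta_, uint32_t seed)
      : n_inst(ninst), n_reg(nreg), n_mem(nmem), n_q(nq),
        beta(beta_), lambda(lambda_), gamma(gamma_),
        alpha(1.0 - lambda_ * gamma_), epsilon(epsilon_), theta(theta_),
        V_reg(ninst + 1, nreg), V_mem(2 * ninst, nmem),
        W_reg(nreg + 1, nq), W_mem(nmem, nq),
        FB_reg(nq, nreg), FB_mem(nq, nmem),
        tV_reg(ninst + 1, nreg), tV_mem(2 * ninst, nmem),
        tW_reg(nreg + 1, nq), tW_mem(nmem, nq),
        tFB_reg(nq, nreg), tFB_mem(nq, nmem),
        trace(2 * ninst, nmem),
        x_prev(ninst, 0.0), x_inst(ninst, 0.0), x_on(ninst, 0.0),
        x_off(ninst, 0.0), inp_mem(nmem, 0.0), y_reg(nreg, 0.0),
        y_mem(nmem, 0.0), q(nq, 0.0) {
    std::seed_seq sinit{seed, (uint32_t)0xA5A5u};
    std::mt19937_64 rng_init(sinit);
    std::seed_seq sact{seed, (uint32_t)0x5A5Au};
    rng_act.seed(sact);
    std::uniform_real_distribution<double> U(init_lo, init_hi);
    for (Mat* m : {&V_reg, &V_mem, &W_reg, &W_mem, &FB_reg, &FB_mem})
      for (double& x : m->v) x = U(rng_init);
  }

  void set_params(double beta_, double lambda_, double gamma_,
                  double epsilon_) {
    beta = beta_; lambda = lambda_; gamma = gamma_; epsilon = epsilon_;
    alpha = 1.0 - lambda * gamma;
  }

  void reset_trial() {
    for (Mat* m : {&tV_reg, &tV_mem, &tW_reg, &tW_mem, &tFB_reg, &tFB_mem,
                   &trace})
      m->zero();
    std::fill(x_prev.begin(), x_prev.end(), 0.0);
    std::fill(x_inst.begin(), x_inst.end(), 0.0);
    std::fill(x_on.begin(), x_on.end(), 0.0);
    std::fill(x_off.begin(), x_off.end(), 0.0);
    std::fill(inp_mem.begin(), inp_mem.end(), 0.0);
    std::fill(y_reg.begin(), y_reg.end(), 0.0);
    std::fill(y_mem.begin(), y_mem.end(), 0.0);
    std::fill(q.begin(), q.end(), 0.0);
    has_q = false;
    action = -1;
    t = 0;
  }

  void forward() {
    for (int j = 0; j < n_reg; ++j) {
      double s = V_reg(n_inst, j);  // bias
      for (int i = 0; i < n_inst; ++i) s += V_reg(i, j) * x_inst[i];
      y_reg[j] = sigmoid(s, theta);
    }
    for (int m = 0; m < n_mem; ++m) {
      double s = 0.0;
      for (int l = 0; l < n_inst; ++l) {
        s += V_mem(l, m) * x_on[l];
        s += V_mem(n_inst + l, m) * x_off[l];
      }
      inp_mem[m] += s;  // accumulator persists within the trial
      y_mem[m] = sigmoid(inp_mem[m], theta);
    }
    for (int k = 0; k < n_q; ++k) {
      double s = W_reg(n_reg, k);  // bias
      for (int j = 0; j < n_reg; ++j) s += W_reg(j, k) * y_reg[j];
      for (int m = 0; m < n_mem; ++m) s += W_mem(m, k) * y_mem[m];
      q[k] = s;
    }
  }

  // Max-Boltzmann controller; exactly two uniform draws per call so that the
  // action stream is reproducible independently of the Q-values.
  int select_action() {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    double u_branch = U(rng_act);
    double u_choice = U(rng_act);
    if (u_branch >= epsilon) {  // greedy, ties broken uniformly at random
      double best = q[0];
      for (int k = 1; k < n_q; ++k) if (q[k] > best) best = q[k];
      int nties = 0;
      for (int k = 0; k < n_q; ++k) if (q[k] == best) ++nties;
      int pick = (int)(u_choice * nties);
      if (pick >= nties) pick = nties - 1;
      for (int k = 0; k < n_q; ++k) {
        if (q[k] == best) {
          if (pick == 0) return k;
          --pick;
        }
      }
      return n_q - 1;  // unreachable
    }
    // Boltzmann sample (max-subtracted)
    double mx = q[0];
    for (int k = 1; k < n_q; ++k) if (q[k] > mx) mx = q[k];
    double z = 0.0;
    std::vector<double> p(n_q);
    for (int k = 0; k < n_q; ++k) { p[k] = std::exp(q[k] - mx); z += p[k]; }
    double cum = 0.0, tgt = u_choice * z;
    for (int k = 0; k < n_q; ++k) {
      cum += p[k];
      if (tgt <= cum) return k;
    }
    return n_q - 1;
  }

  void apply_plasticity(double delta) {
    double f = beta * delta;
    if (f == 0.0) return;
    const Mat* tags[6] = {&tV_reg, &tV_mem, &tW_reg, &tW_mem, &tFB_reg,
                          &tFB_mem};
    Mat* wts[6] = {&V_reg, &V_mem, &W_reg, &W_mem, &FB_reg, &FB_mem};
    for (int s = 0; s < 6; ++s) {
      const std::vector<double>& tg = tags[s]->v;
      std::vector<double>& w = wts[s]->v;
      for (size_t i = 0; i < w.size(); ++i) w[i] += f * tg[i];
    }
  }

  void update_tags(int a) {
    double keep = lambda * gamma;  // = 1 - alpha
    for (Mat* m : {&tV_reg, &tV_mem, &tW_reg, &tW_mem, &tFB_reg, &tFB_mem})
      m->scale(keep);
    for (int j = 0; j < n_reg; ++j) {
      tW_reg(j, a) += y_reg[j];
      tFB_reg(a, j) += y_reg[j];
    }
    tW_reg(n_reg, a) += 1.0;  // bias synapse, presynaptic activity 1
    for (int m = 0; m < n_mem; ++m) {
      tW_mem(m, a) += y_mem[m];
      tFB_mem(a, m) += y_mem[m];
    }
    for (int j = 0; j < n_reg; ++j) {
      double g = y_reg[j] * (1.0 - y_reg[j]) * FB_reg(a, j);
      if (g != 0.0) {
        for (int i = 0; i < n_inst; ++i) tV_reg(i, j) += x_inst[i] * g;
        tV_reg(n_inst, j) += g;
      }
    }
    for (int m = 0; m < n_mem; ++m) {
      double g = y_mem[m] * (1.0 - y_mem[m]) * FB_mem(a, m);
      if (g != 0.0)
        for (int l = 0; l < 2 * n_inst; ++l) tV_mem(l, m) += trace(l, m) * g;
    }
  }

  // One agent step; returns the selected action or -1 on the terminal step.
  int step(const double* x, double r, bool terminal, int forced) {
    ++t;
    // (1) encode sensory transients
    for (int i = 0; i < n_inst; ++i) {
      double d = x[i] - x_prev[i];
      x_on[i] = d > 0.0 ? d : 0.0;
      x_off[i] = d < 0.0 ? -d : 0.0;
      x_inst[i] = x[i];
    }
    // (2) synaptic traces (before tag formation; never decay within a trial)
    for (int m = 0; m < n_mem; ++m)
      for (int l = 0; l < n_inst; ++l) {
        trace(l, m) += x_on[l];
        trace(n_inst + l, m) += x_off[l];
      }
    // (3) feedforward
    forward();
    // (4) terminal transition: q of terminal state is zero
    if (terminal) {
      if (has_q) {
        last_delta = r - q_stored;
        apply_plasticity(last_delta);
      } else {
        last_delta = NA_REAL;  // trial ended before any action
      }
      reset_trial();
      return -1;
    }
    // (5) action selection
    int a = (forced >= 0) ? forced : select_action();
    // (6) SARSA update with the tags laid down through the previous action
    if (has_q) {
      last_delta = r + gamma * q[a] - q_stored;
      apply_plasticity(last_delta);
    } else {
      last_delta = NA_REAL;
    }
    // (7) tag decay + formation gated by the newly selected action
    update_tags(a);
    // (8) bookkeeping
    q_stored = q[a];
    has_q = true;
    action = a;
    for (int i = 0; i < n_inst; ++i) x_prev[i] = x[i];
    return a;
  }
};

// ---------------------------------------------------------------------------
// Environments
// ---------------------------------------------------------------------------
struct Step {
  std::vector<double> x;
  double r = 0.0;
  bool terminal = false;
};

struct Env {
  int n_inputs = 0;
  std::mt19937_64 rng;
  double ri = 0.2, rf = 1.5;

  // per-trial bookkeeping, read back by the trainer
  int trial_type = 0;
  bool fix_attained = false, reached_go = false, correct = false,
       responded = false;
  double total_reward = 0.0;
  int phase = 0;  // 0 start, 1 fixation wait, 2 stimulus, 3 delay, 4 go
  double extra1 = 0.0, extra2 = 0.0;

  virtual ~Env() {}
  virtual Step reset(const NumericVector& spec) = 0;
  virtual Step step(int a) = 0;
  virtual void set_option(const std::string& k, double v) {
    if (k == "ri") ri = v;
    else if (k == "rf") rf = v;
    else stop("unknown environment option '%s'", k.c_str());
  }
  void begin_trial() {
    fix_attained = reached_go = correct = responded = false;
    total_reward = 0.0;
    phase = 0;
  }
  Step terminal_step(double r) {
    Step s; s.x.assign(n_inputs, 0.0); s.r = r; s.terminal = true;
    total_reward += r;
    return s;
  }
  Step obs(const std::vector<double>& x, double r = 0.0) {
    Step s; s.x = x; s.r = r; s.terminal = false;
    total_reward += r;
    return s;
  }
  double runif() {
    return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
  }
  double rnorm(double sd) {
    return std::normal_distribution<double>(0.0, sd)(rng);
  }
  int rint(int n) {  // uniform on 0..n-1
    return (int)std::uniform_int_distribution<int>(0, n - 1)(rng);
  }
};

// --- saccade / antisaccade -------------------------------------------------
// inputs: fix-black, fix-white, cue-left, cue-right; actions L=0, C=1, R=2
struct SaccadeEnv : Env {
  bool pro_only = false;

  bool anti = false, cue_right = false;
  int fix_count = 0, wait_t = 0, resp_t = 0;

  SaccadeEnv() { n_inputs = 4; }
  void set_option(const std::string& k, double v) override {
    if (k == "pro_only") pro_only = v != 0.0;
    else Env::set_option(k, v);
  }
  std::vector<double> screen(bool mark, bool cue) {
    std::vector<double> x(4, 0.0);
    if (mark) x[anti ? 1 : 0] = 1.0;
    if (cue) x[cue_right ? 3 : 2] = 1.0;
    return x;
  }
  Step reset(const NumericVector& spec) override {
    begin_trial();
    if (spec.size() >= 1) {
      int ty = (int)spec[0];
      anti = ty >= 2;
      cue_right = (ty % 2) == 1;
    } else {
      anti = runif() < 0.5;
      cue_right = runif() < 0.5;
    }
    trial_type = 2 * (anti ? 1 : 0) + (cue_right ? 1 : 0);
    fix_count = wait_t = resp_t = 0;
    phase = 0;
    return obs(std::vector<double>(4, 0.0));  // one step of empty screen
  }
  int target_action() const {
    bool go_right = pro_only ? cue_right : (anti ? !cue_right : cue_right);
    return go_right ? 2 : 0;
  }
  Step step(int a) override {
    switch (phase) {
      case 0:  // action on the empty screen is unconstrained
        phase = 1;
        return obs(screen(true, false));
      case 1:  // fixation acquisition, 10-step window
        ++wait_t;
        // gaze may wander before fixation begins, but leaving the mark
        // after fixating aborts the trial
        if (a == 1) ++fix_count;
        else if (fix_count > 0) return terminal_step(0.0);
        if (fix_count == 2) {
          fix_attained = true;
          phase = 2;
          return obs(screen(true, true), ri);  // cue + shaping reward
        }
        if (wait_t >= 10) return terminal_step(0.0);
        return obs(screen(true, false));
      case 2:  // action on the cue step
        if (a != 1) return terminal_step(0.0);  // broke fixation
        phase = 3;
        wait_t = 0;
        return obs(screen(true, false));
      case 3:  // two-step memory delay
        if (a != 1) return terminal_step(0.0);
        if (++wait_t < 2) return obs(screen(true, false));
        phase = 4;
        reached_go = true;
        return obs(screen(false, false));  // mark off = go
      case 4:  // response window, centre = wait
        if (a == 1) {
          if (++resp_t >= 8) return terminal_step(0.0);
          return obs(screen(false, false));
        }
        responded = true;
        correct = (a == target_action());
        return terminal_step(correct ? rf : 0.0);
    }
    stop("saccade environment: step after terminal");
    return Step();
  }
};

// --- delayed match-to-category ---------------------------------------------
// inputs: fixation + 20 direction-tuned units; actions L=0, C=1, R=2
struct CategoryEnv : Env {
  double tuning_sd = 12.0, noise_sd = 5.0;
  int cue1 = 0, cue2 = 0;
  double ang1 = 0.0, ang2 = 0.0;  // noisy angles (drawn once per cue)
  int fix_count = 0, wait_t = 0, resp_t = 0;

  CategoryEnv() { n_inputs = 21; }
  void set_option(const std::string& k, double v) override {
    if (k == "noise_sd") noise_sd = v;
    else if (k == "tuning_sd") tuning_sd = v;
    else Env::set_option(k, v);
  }
  static double dir_of(int idx) { return 15.0 + 30.0 * idx; }   // deg
  static int category(int idx) { return idx < 6 ? 0 : 1; }      // boundary 0/180
  std::vector<double> screen(bool mark, bool stim, double ang) {
    std::vector<double> x(21, 0.0);
    if (mark) x[0] = 1.0;
    if (stim) {
      for (int u = 0; u < 20; ++u) {
        double pref = 18.0 * u;
        double d = std::fabs(ang - pref);
        d -= 360.0 * std::floor(d / 360.0);
        if (d > 180.0) d = 360.0 - d;
        x[1 + u] = std::exp(-(d * d) / (2.0 * tuning_sd * tuning_sd));
      }
    }
    return x;
  }
  Step reset(const NumericVector& spec) override {
    begin_trial();
    if (spec.size() >= 2) { cue1 = (int)spec[0]; cue2 = (int)spec[1]; }
    else { cue1 = rint(12); cue2 = rint(12); }
    ang1 = dir_of(cue1) + (noise_sd > 0 ? rnorm(noise_sd) : 0.0);
    ang2 = dir_of(cue2) + (noise_sd > 0 ? rnorm(noise_sd) : 0.0);
    trial_type = cue1;
    extra1 = cue1; extra2 = cue2;
    fix_count = wait_t = resp_t = 0;
    phase = 0;
    return obs(std::vector<double>(21, 0.0));
  }
  int target_action() const {
    return category(cue1) == category(cue2) ? 0 : 2;  // match -> left
  }
  Step step(int a) override {
    switch (phase) {
      case 0:
        phase = 1;
        return obs(screen(true, false, 0));
      case 1:
        ++wait_t;
        if (a == 1) ++fix_count;
        else if (fix_count > 0) return terminal_step(0.0);
        if (fix_count == 2) {
          fix_attained = true;
          phase = 2;
          return obs(screen(true, true, ang1), ri);  // cue-1
        }
        if (wait_t >= 10) return terminal_step(0.0);
        return obs(screen(true, false, 0));
      case 2:
        if (a != 1) return terminal_step(0.0);
        phase = 3;
        wait_t = 0;
        return obs(screen(true, false, 0));
      case 3:
        if (a != 1) return terminal_step(0.0);
        if (++wait_t < 2) return obs(screen(true, false, 0));
        phase = 4;
        reached_go = true;
        return obs(screen(true, true, ang2));  // cue-2; mark stays on
      case 4:
        if (a == 1) {
          if (++resp_t >= 8) return terminal_step(0.0);
          return obs(screen(true, true, ang2));
        }
        responded = true;
        correct = (a == target_action());
        return terminal_step(correct ? rf : 0.0);
    }
    stop("category environment: step after terminal");
    return Step();
  }
};

// --- probabilistic classification ------------------------------------------
// inputs: fixation + 4 target units (left-red, left-green, right-red,
// right-green) + 10 symbols x 4 locations; actions L=0, C=1, R=2.
// symbol order: 0 trump-red, 1 trump-green, then +-0.9, +-0.7, +-0.5, +-0.3
struct ClassificationEnv : Env {
  int n_sym = 10, seq_len = 4;
  std::vector<double> w = {INFINITY, -INFINITY, 0.9, -0.9, 0.7, -0.7,
                           0.5, -0.5, 0.3, -0.3};
  std::vector<int> seq, loc;
  bool red_right = false;
  double Wsum = 0.0, p_red = 0.5;
  bool bait_red = false;
  int best = -1;  // -1 either, 0 left, 2 right
  int fix_count = 0, wait_t = 0, resp_t = 0, shown = 0;

  ClassificationEnv() { n_inputs = 45; }
  void set_option(const std::string& k, double v) override {
    if (k == "n_symbols") n_sym = (int)v;
    else if (k == "seq_len") seq_len = (int)v;
    else Env::set_option(k, v);
  }
  std::vector<double> screen(bool mark, bool targets, int nshow) {
    std::vector<double> x(45, 0.0);
    if (mark) x[0] = 1.0;
    if (targets) {
      if (red_right) { x[4] = 1.0; x[2] = 1.0; }  // right-red on, left-green
      else { x[1] = 1.0; x[3] = 1.0; }            // left-red, right-green
    }
    for (int k = 0; k < nshow; ++k) x[5 + 10 * loc[k] + seq[k]] = 1.0;
    return x;
  }
  Step reset(const NumericVector& spec) override {
    begin_trial();
    if (spec.size() >= 1) {
      seq.clear();
      for (int i = 0; i < spec.size() && i < 4; ++i) {
        double v = spec[i];
        if (v < 0) break;
        seq.push_back((int)v);
      }
      red_right = runif() < 0.5;
    } else {
      seq.resize(seq_len);
      for (int& s : seq) s = rint(n_sym);
      red_right = runif() < 0.5;
    }
    // distinct random locations for the successive symbols
    std::vector<int> perm = {0, 1, 2, 3};
    for (int i = 3; i > 0; --i) std::swap(perm[i], perm[rint(i + 1)]);
    loc.assign(perm.begin(), perm.begin() + seq.size());
    // reward probability for the red target
    int trump = 0;
    Wsum = 0.0;
    for (int s : seq) {
      if (s == 0) ++trump;
      else if (s == 1) --trump;
      else Wsum += w[s];
    }
    if (trump > 0) p_red = 1.0;
    else if (trump < 0) p_red = 0.0;
    else p_red = std::pow(10.0, Wsum) / (1.0 + std::pow(10.0, Wsum));
    bait_red = runif() < p_red;
    if (p_red == 0.5) best = -1;
    else {
      bool red_better = p_red > 0.5;
      best = (red_better == red_right) ? 2 : 0;
    }
    extra1 = p_red;
    extra2 = red_right ? 1.0 : 0.0;
    trial_type = 0;
    fix_count = wait_t = resp_t = 0;
    shown = 0;
    phase = 0;
    return obs(std::vector<double>(45, 0.0));
  }
  Step step(int a) override {
    switch (phase) {
      case 0:
        phase = 1;
        return obs(screen(true, false, 0));
      case 1:
        ++wait_t;
        if (a == 1) ++fix_count;
        else if (fix_count > 0) return terminal_step(0.0);
        if (fix_count == 2) {
          fix_attained = true;
          phase = 2;
          shown = 1;
          return obs(screen(true, true, 1), ri);  // targets + first symbol
        }
        if (wait_t >= 10) return terminal_step(0.0);
        return obs(screen(true, false, 0));
      case 2:  // successive symbols, cumulative
        if (a != 1) return terminal_step(0.0);
        if (shown < (int)seq.size()) {
          ++shown;
          return obs(screen(true, true, shown));
        }
        phase = 3;
        wait_t = 1;
        return obs(screen(true, true, 0));  // delay: fix + targets
      case 3:
        if (a != 1) return terminal_step(0.0);
        if (++wait_t < 3) return obs(screen(true, true, 0));
        phase = 4;
        reached_go = true;
        return obs(screen(false, true, 0));  // mark off = go, targets stay
      case 4:
        if (a == 1) {
          if (++resp_t >= 8) return terminal_step(0.0);
          return obs(screen(false, true, 0));
        }
        responded = true;
        correct = (best == -1) || (a == best);
        {
          int bait_side = (bait_red == red_right) ? 2 : 0;
          return terminal_step(a == bait_side ? rf : 0.0);
        }
    }
    stop("classification environment: step after terminal");
    return Step();
  }
};

// --- vibrotactile two-frequency comparison ----------------------------------
// inputs: 20 frequency-tuned units + 1 skin-contact unit (index 20);
// actions L=0 (F2 < F1), hold=1, R=2 (F2 > F1)
struct VibroEnv : Env {
  int mode = 1;            // 1 variable F1, 2 fixed F1
  double fixed_f1 = 30.0, noise_sd = 0.075, steep = 5.0;
  int delay_len = 3;
  double F1 = 0.0, F2 = 0.0;
  int hold_count = 0, wait_t = 0, resp_t = 0;

  VibroEnv() { n_inputs = 21; }
  void set_option(const std::string& k, double v) override {
    if (k == "mode") mode = (int)v;
    else if (k == "fixed_f1") fixed_f1 = v;
    else if (k == "noise_sd") noise_sd = v;
    else if (k == "steep") steep = v;
    else if (k == "delay_len") delay_len = (int)v;
    else Env::set_option(k, v);
  }
  // tuned units carry rate noise on every step (silent rate 0 between
  // stimuli); the binary contact unit is noise-free
  std::vector<double> screen(bool stim, double f) {
    std::vector<double> x(21, 0.0);
    x[20] = 1.0;  // probe contact throughout the trial
    for (int c = 0; c < 10; ++c) {
      double up = 0.0, dn = 0.0;
      if (stim) {
        double th = 5.5 + c * (44.0 / 9.0);  // centres 5.5 .. 49.5 Hz
        up = 1.0 / (1.0 + std::exp(steep * (th - f)));
        dn = 1.0 / (1.0 + std::exp(-steep * (th - f)));
      }
      if (noise_sd > 0) {
        up = clip01(up + rnorm(noise_sd));
        dn = clip01(dn + rnorm(noise_sd));
      }
      x[2 * c] = up;
      x[2 * c + 1] = dn;
    }
    return x;
  }
  Step reset(const NumericVector& spec) override {
    begin_trial();
    if (spec.size() >= 2) {
      F1 = spec[0];
      F2 = spec[1];
    } else if (mode == 1) {
      F1 = 5.0 + 45.0 * runif();
      do { F2 = 5.0 + 45.0 * runif(); } while (std::fabs(F2 - F1) < 2.0);
    } else {
      F1 = fixed_f1;
      std::vector<double> grid;
      for (double f = 5.0; f <= 50.0 + 1e-9; f += 2.5)
        if (std::fabs(f - F1) >= 10.0) grid.push_back(f);
      F2 = grid[rint((int)grid.size())];
    }
    extra1 = F1;
    extra2 = F2;
    if (mode == 2) {
      // stratum = index of F2 on the admissible 2.5-Hz grid
      int idx = 0, me = 0;
      for (double f = 5.0; f <= 50.0 + 1e-9; f += 2.5) {
        if (std::fabs(f - fixed_f1) < 10.0) continue;
        if (std::fabs(f - F2) < 1.25) me = idx;
        ++idx;
      }
      trial_type = me;
    } else {
      trial_type = std::min((int)((F1 - 5.0) / 5.0), 8);  // 9 F1 bins
    }
    hold_count = wait_t = resp_t = 0;
    phase = 1;  // trial starts when the probe touches the skin
    return obs(screen(false, 0));
  }
  int target_action() const { return F2 < F1 ? 0 : 2; }
  Step step(int a) override {
    switch (phase) {
      case 1:  // key-hold acquisition, 10-step window
        ++wait_t;
        if (a == 1) ++hold_count;
        else if (hold_count > 0) return terminal_step(0.0);
        if (hold_count == 2) {
          fix_attained = true;
          phase = 2;
          return obs(screen(true, F1), ri);  // F1, one step
        }
        if (wait_t >= 10) return terminal_step(0.0);
        return obs(screen(false, 0));
      case 2:
        if (a != 1) return terminal_step(0.0);  // released the key
        phase = 3;
        wait_t = 0;
        return obs(screen(false, 0));
      case 3:  // memory delay
        if (a != 1) return terminal_step(0.0);
        if (++wait_t < delay_len) return obs(screen(false, 0));
        phase = 4;
        reached_go = true;
        return obs(screen(true, F2));  // comparison stimulus on
      case 4:
        if (a == 1) {
          if (++resp_t >= 8) return terminal_step(0.0);
          return obs(screen(true, F2));
        }
        responded = true;
        correct = (a == target_action());
        return terminal_step(correct ? rf : 0.0);
    }
    stop("vibrotactile environment: step after terminal");
    return Step();
  }
};

// ---------------------------------------------------------------------------
// exported interface
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP net_create(int n_inst, int n_regular, int n_memory, int n_q,
                double init_low, double init_high, double beta, double lambda,
                double gamma, double epsilon, double theta, int seed) {
  XPtr<Net> p(new Net(n_inst, n_regular, n_memory, n_q, init_low, init_high,
                      beta, lambda, gamma, epsilon, theta, (uint32_t)seed),
              true);
  return p;
}

// [[Rcpp::export]]
void net_set_params(SEXP net, double beta, double lambda, double gamma,
                    double epsilon) {
  XPtr<Net>(net)->set_params(beta, lambda, gamma, epsilon);
}

// [[Rcpp::export]]
List net_params(SEXP net) {
  XPtr<Net> p(net);
  return List::create(_["beta"] = p->beta, _["lambda"] = p->lambda,
                      _["gamma"] = p->gamma, _["alpha"] = p->alpha,
                      _["epsilon"] = p->epsilon, _["theta"] = p->theta);
}

// [[Rcpp::export]]
void net_reset(SEXP net) { XPtr<Net>(net)->reset_trial(); }

// [[Rcpp::export]]
List net_step_r(SEXP net, NumericVector x, double reward, bool terminal,
                int forced = -1) {
  XPtr<Net> p(net);
  if ((int)x.size() != p->n_inst)
    stop("observation has length %d, expected %d", (int)x.size(), p->n_inst);
  int a = p->step(REAL(x), reward, terminal, forced);
  return List::create(
      _["action"] = a < 0 ? NA_INTEGER : a, _["delta"] = p->last_delta,
      _["q"] = NumericVector(p->q.begin(), p->q.end()),
      _["y_regular"] = NumericVector(p->y_reg.begin(), p->y_reg.end()),
      _["y_memory"] = NumericVector(p->y_mem.begin(), p->y_mem.end()));
}

// [[Rcpp::export]]
List net_state(SEXP net) {
  XPtr<Net> p(net);
  return List::create(
      _["weights"] = List::create(
          _["V_regular"] = asR(p->V_reg), _["V_memory"] = asR(p->V_mem),
          _["W_regular"] = asR(p->W_reg), _["W_memory"] = asR(p->W_mem),
          _["FB_regular"] = asR(p->FB_reg), _["FB_memory"] = asR(p->FB_mem)),
      _["tags"] = List::create(
          _["V_regular"] = asR(p->tV_reg), _["V_memory"] = asR(p->tV_mem),
          _["W_regular"] = asR(p->tW_reg), _["W_memory"] = asR(p->tW_mem),
          _["FB_regular"] = asR(p->tFB_reg), _["FB_memory"] = asR(p->tFB_mem)),
      _["trace"] = asR(p->trace),
      _["inp_memory"] = NumericVector(p->inp_mem.begin(), p->inp_mem.end()),
      _["y_regular"] = NumericVector(p->y_reg.begin(), p->y_reg.end()),
      _["y_memory"] = NumericVector(p->y_mem.begin(), p->y_mem.end()),
      _["q"] = NumericVector(p->q.begin(), p->q.end()),
      _["q_stored"] = p->has_q ? p->q_stored : NA_REAL,
      _["action"] = p->action < 0 ? NA_INTEGER : p->action,
      _["x_prev"] = NumericVector(p->x_prev.begin(), p->x_prev.end()),
      _["t"] = p->t);
}

// [[Rcpp::export]]
void net_set_weights(SEXP net, List w) {
  XPtr<Net> p(net);
  Mat* slots[6] = {&p->V_reg, &p->V_mem, &p->W_reg, &p->W_mem, &p->FB_reg,
                   &p->FB_mem};
  const char* names[6] = {"V_regular", "V_memory", "W_regular", "W_memory",
                          "FB_regular", "FB_memory"};
  for (int s = 0; s < 6; ++s) {
    if (!w.containsElementNamed(names[s])) continue;
    NumericMatrix m = w[names[s]];
    if (m.nrow() != slots[s]->nr || m.ncol() != slots[s]->nc)
      stop("weight array %s has the wrong shape", names[s]);
    *slots[s] = fromR(m);
  }
}

// tie feedback weights to the transpose of the feedforward weights
// (used by the gradient oracle, where the derivation assumes proportionality)
// [[Rcpp::export]]
void net_tie_feedback(SEXP net) {
  XPtr<Net> p(net);
  for (int k = 0; k < p->n_q; ++k) {
    for (int j = 0; j < p->n_reg; ++j) p->FB_reg(k, j) = p->W_reg(j, k);
    for (int m = 0; m < p->n_mem; ++m) p->FB_mem(k, m) = p->W_mem(m, k);
  }
}

// [[Rcpp::export]]
SEXP net_clone(SEXP net) {
  XPtr<Net> p(net);
  XPtr<Net> q(new Net(*p), true);
  return q;
}

// [[Rcpp::export]]
SEXP env_create(std::string task, int seed) {
  Env* e = nullptr;
  if (task == "saccade") e = new SaccadeEnv();
  else if (task == "category") e = new CategoryEnv();
  else if (task == "classification") e = new ClassificationEnv();
  else if (task == "vibrotactile") e = new VibroEnv();
  else stop("unknown task '%s'", task.c_str());
  std::seed_seq s{(uint32_t)seed, (uint32_t)0x7E57u};
  e->rng.seed(s);
  XPtr<Env> p(e, true);
  return p;
}

// [[Rcpp::export]]
void env_set_option(SEXP env, std::string key, double value) {
  XPtr<Env>(env)->set_option(key, value);
}

// [[Rcpp::export]]
int env_n_inputs(SEXP env) { return XPtr<Env>(env)->n_inputs; }

// [[Rcpp::export]]
void env_reseed(SEXP env, int seed) {
  std::seed_seq s{(uint32_t)seed, (uint32_t)0x7E57u};
  XPtr<Env>(env)->rng.seed(s);
}

static List step_as_list(const Step& s) {
  return List::create(_["x"] = NumericVector(s.x.begin(), s.x.end()),
                      _["reward"] = s.r, _["terminal"] = s.terminal);
}

// [[Rcpp::export]]
List env_reset_r(SEXP env, NumericVector spec) {
  return step_as_list(XPtr<Env>(env)->reset(spec));
}

// [[Rcpp::export]]
List env_step_r(SEXP env, int action) {
  if (action < 0 || action > 2) stop("invalid action %d", action);
  return step_as_list(XPtr<Env>(env)->step(action));
}

// [[Rcpp::export]]
List env_info(SEXP env) {
  XPtr<Env> p(env);
  return List::create(
      _["trial_type"] = p->trial_type, _["fix_attained"] = p->fix_attained,
      _["reached_go"] = p->reached_go, _["responded"] = p->responded,
      _["correct"] = p->correct, _["total_reward"] = p->total_reward,
      _["extra1"] = p->extra1, _["extra2"] = p->extra2);
}

// Run one full trial (agent + environment) without leaving C++.
// Returns c(trial_type, correct, total_reward, n_steps, fix_attained,
//           reached_go, responded, extra1, extra2).
// [[Rcpp::export]]
NumericVector run_trial_cpp(SEXP net, SEXP env, NumericVector spec,
                            int max_steps = 100) {
  XPtr<Net> n(net);
  XPtr<Env> e(env);
  if (n->n_inst != e->n_inputs)
    stop("network has %d sensory inputs but the task provides %d", n->n_inst,
         e->n_inputs);
  Step s = e->reset(spec);
  int steps = 0;
  while (true) {
    int a = n->step(s.x.data(), s.r, s.terminal, -1);
    if (s.terminal) break;
    s = e->step(a);
    if (++steps > max_steps)
      stop("trial exceeded %d steps: environment failed to terminate",
           max_steps);
  }
  return NumericVector::create(
      (double)e->trial_type, e->correct ? 1.0 : 0.0, e->total_reward,
      (double)steps, e->fix_attained ? 1.0 : 0.0, e->reached_go ? 1.0 : 0.0,
      e->responded ? 1.0 : 0.0, e->extra1, e->extra2);
}

// Logged variant: per-step record of activities, Q-values, action, RPE and
// reward. `forced` supplies actions for leading steps (-1 = policy).
// [[Rcpp::export]]
List run_trial_logged_cpp(SEXP net, SEXP env, NumericVector spec,
                          IntegerVector forced, int max_steps = 100) {
  XPtr<Net> n(net);
  XPtr<Env> e(env);
  if (n->n_inst != e->n_inputs)
    stop("network has %d sensory inputs but the task provides %d", n->n_inst,
         e->n_inputs);
  int nq = n->n_q, nr = n->n_reg, nm = n->n_mem;
  int ncol = 5 + nq + nr + nm;
  NumericMatrix log(max_steps + 1, ncol);
  Step s = e->reset(spec);
  int steps = 0, row = 0;
  while (true) {
    int f = (row < (int)forced.size()) ? forced[row] : -1;
    int a = n->step(s.x.data(), s.r, s.terminal, f);
    log(row, 0) = row + 1;
    log(row, 1) = e->phase;
    log(row, 2) = a < 0 ? NA_REAL : (double)a;
    log(row, 3) = s.r;
    log(row, 4) = n->last_delta;
    for (int k = 0; k < nq; ++k) log(row, 5 + k) = n->q[k];
    for (int j = 0; j < nr; ++j) log(row, 5 + nq + j) = n->y_reg[j];
    for (int m = 0; m < nm; ++m) log(row, 5 + nq + nr + m) = n->y_mem[m];
    ++row;
    if (s.terminal) break;
    s = e->step(a);
    if (++steps > max_steps)
      stop("trial exceeded %d steps: environment failed to terminate",
           max_steps);
  }
  NumericMatrix out(row, ncol);
  for (int j = 0; j < ncol; ++j)
    for (int i = 0; i < row; ++i) out(i, j) = log(i, j);
  CharacterVector cn(ncol);
  cn[0] = "t"; cn[1] = "phase"; cn[2] = "action"; cn[3] = "reward";
  cn[4] = "delta";
  for (int k = 0; k < nq; ++k) cn[5 + k] = "q_" + std::to_string(k);
  for (int j = 0; j < nr; ++j) cn[5 + nq + j] = "y_reg_" + std::to_string(j + 1);
  for (int m = 0; m < nm; ++m)
    cn[5 + nq + nr + m] = "y_mem_" + std::to_string(m + 1);
  colnames(out) = cn;
  List info = List::create(
      _["trial_type"] = e->trial_type, _["fix_attained"] = e->fix_attained,
      _["reached_go"] = e->reached_go, _["responded"] = e->responded,
      _["correct"] = e->correct, _["total_reward"] = e->total_reward,
      _["extra1"] = e->extra1, _["extra2"] = e->extra2);
  return List::create(_["log"] = out, _["info"] = info);
}
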