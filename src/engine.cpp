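#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fixed 512-node tanh-sinh quadrature on (0, 1).
//
// All arbitration and cache-update integrals are over Beta densities whose
// shape parameters need not be integers, so the integrands can carry
// algebraic endpoint singularities; the double-exponential node clustering
// keeps the fixed-node rule accurate there (and for near-point-mass
// distributions such as Beta(1e6, 1)).
// ---------------------------------------------------------------------------

struct Quad {
  std::vector<double> x, xm, lx, lxm, w; // node, 1-node (stable), logs, weight
};

static Quad make_ts(int n) {
  Quad q;
  const double tmax = 4.0;
  const double h = 2.0 * tmax / (n - 1);
  for (int i = 0; i < n; ++i) {
    double t = -tmax + i * h;
    double s = M_PI_2 * std::sinh(t);
    double x  = 1.0 / (1.0 + std::exp(-2.0 * s));
    double xm = 1.0 / (1.0 + std::exp( 2.0 * s)); // 1 - x without cancellation
    double ch = std::cosh(s);
    double w = h * M_PI_2 * std::cosh(t) / (2.0 * ch * ch);
    if (!(w > 1e-280) || x <= 0.0 || xm <= 0.0) continue;
    q.x.push_back(x); q.xm.push_back(xm);
    q.lx.push_back(std::log(x)); q.lxm.push_back(std::log(xm));
    q.w.push_back(w);
  }
  return q;
}

static const Quad& quad512() { static Quad q = make_ts(512); return q; }

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

static inline double clamp_unit(double x) { // open-interval clamp used for target means
  if (x < 1e-3) return 1e-3;
  if (x > 1.0 - 1e-3) return 1.0 - 1e-3;
  return x;
}

static inline double beta_var(double a, double b) {
  double s = a + b;
  return a * b / (s * s * (s + 1.0));
}

// ---------------------------------------------------------------------------
// reshape_to_mean: fix alpha or beta of the base so the mean equals m, keep
// the larger-variance candidate (tree search adds uncertainty).
// ---------------------------------------------------------------------------
static inline void reshape_core(double a, double b, double m,
                                double& oa, double& ob) {
  double a1 = a, b1 = a * (1.0 - m) / m;   // alpha fixed
  double a2 = b * m / (1.0 - m), b2 = b;   // beta fixed
  if (beta_var(a1, b1) >= beta_var(a2, b2)) { oa = a1; ob = b1; }
  else { oa = a2; ob = b2; }
}

// [[Rcpp::export]]
NumericVector reshape_to_mean_cpp(double alpha, double beta, double target_mean) {
  double oa, ob;
  reshape_core(alpha, beta, target_mean, oa, ob);
  return NumericVector::create(oa, ob);
}

// ---------------------------------------------------------------------------
// mixture_update: moment-match int Beta(a + x, b + (1 - x)) target(x) dx.
// Mixture moments given the target's first two moments are linear/quadratic
// in x, so they are computed under the target density by quadrature and
// normalised by the computed mass.
// ---------------------------------------------------------------------------
static inline void beta_match(double m, double v, double& a, double& b) {
  const double floor_ = 1e-3;
  if (!(v > 0.0)) v = 1e-12;
  double nu = m * (1.0 - m) / v - 1.0;
  a = m * nu;
  b = (1.0 - m) * nu;
  if (!(a >= floor_)) a = floor_;
  if (!(b >= floor_)) b = floor_;
}

static void mixture_core(double pa, double pb, double ta, double tb,
                         double& oa, double& ob) {
  const Quad& q = quad512();
  double lB = R::lbeta(ta, tb);
  double mass = 0.0, e1 = 0.0, e2 = 0.0;
  for (size_t i = 0; i < q.x.size(); ++i) {
    double lf = (ta - 1.0) * q.lx[i] + (tb - 1.0) * q.lxm[i] - lB;
    double wf = q.w[i] * std::exp(lf);
    mass += wf;
    e1 += wf * q.x[i];
    e2 += wf * q.x[i] * q.x[i];
  }
  if (!(mass > 0.0) || !std::isfinite(mass))
    stop("mixture_update quadrature failed (mass=%g for target Beta(%g, %g))",
         mass, ta, tb);
  e1 /= mass; e2 /= mass;
  double s = pa + pb;
  double m1 = (pa + e1) / (s + 1.0);
  double m2 = (pa * pa + pa + (2.0 * pa + 1.0) * e1 + e2) /
              ((s + 1.0) * (s + 2.0));
  beta_match(m1, m2 - m1 * m1, oa, ob);
}

// [[Rcpp::export]]
NumericVector mixture_update_cpp(double prior_alpha, double prior_beta,
                                 double target_alpha, double target_beta) {
  double oa, ob;
  mixture_core(prior_alpha, prior_beta, target_alpha, target_beta, oa, ob);
  return NumericVector::create(oa, ob);
}

// [[Rcpp::export]]
NumericVector mixture_moments_cpp(double prior_alpha, double prior_beta,
                                  double target_alpha, double target_beta) {
  // mean and variance of the mixture before moment matching (for oracle tests)
  const Quad& q = quad512();
  double lB = R::lbeta(target_alpha, target_beta);
  double mass = 0.0, e1 = 0.0, e2 = 0.0;
  for (size_t i = 0; i < q.x.size(); ++i) {
    double lf = (target_alpha - 1.0) * q.lx[i] +
                (target_beta - 1.0) * q.lxm[i] - lB;
    double wf = q.w[i] * std::exp(lf);
    mass += wf; e1 += wf * q.x[i]; e2 += wf * q.x[i] * q.x[i];
  }
  e1 /= mass; e2 /= mass;
  double s = prior_alpha + prior_beta;
  double m1 = (prior_alpha + e1) / (s + 1.0);
  double m2 = (prior_alpha * prior_alpha + prior_alpha +
               (2.0 * prior_alpha + 1.0) * e1 + e2) / ((s + 1.0) * (s + 2.0));
  return NumericVector::create(m1, m2 - m1 * m1);
}

// ---------------------------------------------------------------------------
// VPI: E[gain] over the cache posterior, integrating only the sub-interval
// where the gain is nonzero (the integrand has a kink at the threshold).
// ---------------------------------------------------------------------------
static double vpi_core(double a, double b, bool is_best,
                       double best_mean, double second_mean) {
  double lo, hi;
  if (is_best) { lo = 0.0; hi = second_mean; }
  else { lo = best_mean; hi = 1.0; }
  if (!(hi > lo)) return 0.0;
  const Quad& q = quad512();
  double lB = R::lbeta(a, b);
  double len = hi - lo;
  double acc = 0.0;
  for (size_t i = 0; i < q.x.size(); ++i) {
    double x = lo + len * q.x[i];
    double xm = (1.0 - hi) + len * q.xm[i]; // 1 - x, stable at hi = 1
    if (!(x > 0.0) || !(xm > 0.0)) continue;
    double lf = (a - 1.0) * std::log(x) + (b - 1.0) * std::log(xm) - lB;
    double g = is_best ? (second_mean - x) : (x - best_mean);
    acc += q.w[i] * g * std::exp(lf);
  }
  acc *= len;
  return acc > 0.0 ? acc : 0.0;
}

// [[Rcpp::export]]
double vpi_cpp(double alpha, double beta, bool is_best,
               double best_mean, double second_mean) {
  return vpi_core(alpha, beta, is_best, best_mean, second_mean);
}

// [[Rcpp::export]]
double vpi_mc_cpp(double alpha, double beta, bool is_best,
                  double best_mean, double second_mean, int n_samples) {
  // Monte-Carlo backend (paper wording: "by sampling"); uses R's RNG.
  double acc = 0.0;
  for (int i = 0; i < n_samples; ++i) {
    double x = R::rbeta(alpha, beta);
    double g = 0.0;
    if (is_best) { if (x < second_mean) g = second_mean - x; }
    else { if (x > best_mean) g = x - best_mean; }
    acc += g;
  }
  return acc / n_samples;
}

// ---------------------------------------------------------------------------
// Value iteration on the learned Dirichlet model. counts is laid out like an
// R array of dim (S, A, S): counts[s + S*a + S*A*s2]. Terminal states carry
// V = mean of their reward Beta; intrinsic rewards enter the backup only in
// global scope (iota_global > 0).
// ---------------------------------------------------------------------------
struct VIResult { bool converged; int sweeps; };

static VIResult vi_core(const std::vector<double>& counts, int S, int A,
                        const std::vector<int>& term,
                        const std::vector<double>& rmean,
                        const std::vector<double>& ra, double gamma,
                        const std::vector<double>& shift, double iota_global,
                        double tol, int max_sweeps, std::vector<double>& Q) {
  std::vector<double> P(counts.size(), 0.0);
  for (int s = 0; s < S; ++s) {
    if (term[s]) continue;
    for (int a = 0; a < A; ++a) {
      double tot = 0.0;
      for (int s2 = 0; s2 < S; ++s2) tot += counts[s + S * a + S * A * s2];
      for (int s2 = 0; s2 < S; ++s2)
        P[s + S * a + S * A * s2] = counts[s + S * a + S * A * s2] / tot;
    }
  }
  std::vector<double> V(S);
  for (int s = 0; s < S; ++s) {
    if (term[s]) { V[s] = rmean[s]; continue; }
    double best = Q[s];
    for (int a = 1; a < A; ++a) best = std::max(best, Q[s + S * a]);
    V[s] = best;
  }
  VIResult res{false, 0};
  for (int it = 0; it < max_sweeps; ++it) {
    double diff = 0.0;
    for (int s = 0; s < S; ++s) {
      if (term[s]) continue;
      for (int a = 0; a < A; ++a) {
        double acc = 0.0;
        const double* p = &P[s + S * a];
        for (int s2 = 0; s2 < S; ++s2) acc += p[(size_t)S * A * s2] * V[s2];
        double nq = ra[a] + iota_global * shift[s + S * a] + gamma * acc;
        double d = std::fabs(nq - Q[s + S * a]);
        if (d > diff) diff = d;
        Q[s + S * a] = nq;
      }
    }
    for (int s = 0; s < S; ++s) {
      if (term[s]) continue;
      double best = Q[s];
      for (int a = 1; a < A; ++a) best = std::max(best, Q[s + S * a]);
      V[s] = best;
    }
    res.sweeps = it + 1;
    if (diff <= tol) { res.converged = true; break; }
  }
  return res;
}

// [[Rcpp::export]]
List value_iteration_cpp(NumericVector counts, int S, int A,
                         LogicalVector terminal, NumericVector reward_mean,
                         NumericVector action_rewards, double gamma,
                         double tol, int max_sweeps,
                         NumericVector shift, double iota_global,
                         Nullable<NumericVector> init_q = R_NilValue) {
  std::vector<double> cnt(counts.begin(), counts.end());
  std::vector<int> term(terminal.begin(), terminal.end());
  std::vector<double> rmean(reward_mean.begin(), reward_mean.end());
  std::vector<double> ra(action_rewards.begin(), action_rewards.end());
  std::vector<double> sh(shift.begin(), shift.end());
  std::vector<double> Q((size_t)S * A, 0.0);
  if (init_q.isNotNull()) {
    NumericVector q0(init_q);
    for (int i = 0; i < S * A; ++i) Q[i] = q0[i];
  }
  VIResult r = vi_core(cnt, S, A, term, rmean, ra, gamma, sh, iota_global,
                       tol, max_sweeps, Q);
  NumericMatrix qm(S, A);
  for (int a = 0; a < A; ++a)
    for (int s = 0; s < S; ++s) qm(s, a) = Q[s + S * a];
  return List::create(_["q"] = qm, _["converged"] = r.converged,
                      _["sweeps"] = r.sweeps);
}

// ---------------------------------------------------------------------------
// Full simulation loop: decide -> act -> transition -> model observation ->
// cache update -> reward-model update -> R-bar update -> forgetting decay.
// All randomness is drawn from R's RNG so set.seed() governs a run.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List run_sim_cpp(List env, List cfg, int n_episodes, List schedule) {
  // --- environment -------------------------------------------------------
  const int St = as<int>(env["n_true"]);
  const int So = as<int>(env["n_obs"]);
  const int A  = as<int>(env["n_actions"]);
  NumericVector trans = env["trans"];            // dim (St, A, St)
  IntegerVector obs_map1 = env["obs_map"];       // 1-based
  LogicalVector term_true = env["terminal_true"];
  LogicalVector term_obs = env["terminal_obs"];
  IntegerVector rew_kind = clone(as<IntegerVector>(env["reward_kind"]));
  NumericVector rew_val = clone(as<NumericVector>(env["reward_value"]));
  NumericVector rew_a = clone(as<NumericVector>(env["reward_alpha"]));
  NumericVector rew_b = clone(as<NumericVector>(env["reward_beta"]));
  NumericVector act_rew = env["action_rewards"];
  const int start = as<int>(env["start"]) - 1;
  const int step_cap = as<int>(env["step_cap"]);

  std::vector<int> obs(St);
  for (int i = 0; i < St; ++i) obs[i] = obs_map1[i] - 1;

  // --- configuration ------------------------------------------------------
  const double epsilon = as<double>(cfg["epsilon"]);
  const double gamma = as<double>(cfg["gamma"]);
  const double theta = as<double>(cfg["theta"]);
  const double iota = as<double>(cfg["iota"]);
  const double tau = as<double>(cfg["tau"]);
  const double eta = as<double>(cfg["eta"]);
  const double tprior = as<double>(cfg["transition_prior"]);
  const bool intrinsic = as<bool>(cfg["intrinsic_enabled"]);
  const bool scope_global = as<bool>(cfg["scope_global"]);
  const bool fixed_mode = as<bool>(cfg["fixed_mode"]);
  const double fixed_value = as<double>(cfg["fixed_value"]);
  const double tol = as<double>(cfg["vi_tol"]);
  const int max_sweeps = as<int>(cfg["vi_max_sweeps"]);
  const bool warm = as<bool>(cfg["vi_warm_start"]);
  const double rpa = as<double>(cfg["reward_prior_alpha"]);
  const double rpb = as<double>(cfg["reward_prior_beta"]);

  // --- agent state --------------------------------------------------------
  std::vector<double> ca((size_t)So * A, 1.0), cb((size_t)So * A, 1.0);
  std::vector<double> counts((size_t)So * A * So, tprior);
  std::vector<double> rma(So, rpa), rmb(So, rpb);  // reward model
  std::vector<double> pra(So, rpa), prb(So, rpb);  // its priors (devaluable)
  std::vector<double> last_shift((size_t)So * A, 0.0);
  std::vector<double> treeQ((size_t)So * A, 0.0);
  // terminality is learned: a state enters the planner's terminal set only
  // once an episode has actually ended there (unseen goals are not targets)
  std::vector<int> term_known(So, 0);
  bool have_tree = false;
  double avg = 0.0;
  long tree_count = 0;

  // --- devaluation schedule ----------------------------------------------
  const int n_ev = schedule.size();
  std::vector<int> ev_ep(n_ev);
  std::vector<IntegerVector> ev_obs(n_ev), ev_true(n_ev);
  std::vector<double> ev_a(n_ev), ev_b(n_ev);
  for (int k = 0; k < n_ev; ++k) {
    List e = schedule[k];
    ev_ep[k] = as<int>(e["after_episode"]) + 1; // applied before this episode
    ev_obs[k] = as<IntegerVector>(e["obs_states"]);
    ev_true[k] = as<IntegerVector>(e["true_states"]);
    ev_a[k] = as<double>(e["alpha"]);
    ev_b[k] = as<double>(e["beta"]);
  }

  const int NC = 16 + A;
  NumericMatrix trace((size_t)n_episodes * step_cap, NC);
  long row = 0;

  std::vector<double> means(A), qstar(A), rmean(So);
  std::vector<int> sys_tree(A), ties(A);
  std::vector<double> ra_vec(act_rew.begin(), act_rew.end());

  for (int ep = 1; ep <= n_episodes; ++ep) {
    for (int k = 0; k < n_ev; ++k) {
      if (ev_ep[k] != ep) continue;
      for (int j = 0; j < ev_obs[k].size(); ++j) {
        int o = ev_obs[k][j] - 1;
        rma[o] = ev_a[k]; rmb[o] = ev_b[k];
        pra[o] = ev_a[k]; prb[o] = ev_b[k];
      }
      for (int j = 0; j < ev_true[k].size(); ++j) {
        int t = ev_true[k][j] - 1;
        rew_kind[t] = 1; rew_a[t] = ev_a[k]; rew_b[t] = ev_b[k];
      }
    }

    int cur = start;
    for (int st = 1; st <= step_cap; ++st) {
      int s = obs[cur];

      // -- decide ---------------------------------------------------------
      for (int a = 0; a < A; ++a)
        means[a] = ca[s + So * a] / (ca[s + So * a] + cb[s + So * a]);
      int a1 = 0;
      for (int a = 1; a < A; ++a) if (means[a] > means[a1]) a1 = a;
      int a2 = (a1 == 0) ? 1 : 0;
      for (int a = 0; a < A; ++a)
        if (a != a1 && means[a] > means[a2]) a2 = a;

      double rbar = fixed_mode ? fixed_value : avg;
      double thr = rbar * tau;
      bool anytree = false;
      int mask = 0;
      for (int a = 0; a < A; ++a) {
        double v = vpi_core(ca[s + So * a], cb[s + So * a], a == a1,
                            means[a1], means[a2]);
        sys_tree[a] = (v > thr) ? 1 : 0;
        if (sys_tree[a]) { anytree = true; mask |= (1 << a); }
      }

      int searched = 0;
      if (anytree) {
        if (!(warm && have_tree && gamma < 1.0))
          std::fill(treeQ.begin(), treeQ.end(), 0.0);
        for (int o = 0; o < So; ++o) rmean[o] = rma[o] / (rma[o] + rmb[o]);
        double ig = (scope_global && intrinsic) ? iota : 0.0;
        vi_core(counts, So, A, term_known, rmean, ra_vec, gamma, last_shift,
                ig, tol, max_sweeps, treeQ);
        have_tree = true;
        ++tree_count;
        searched = 1;
      }

      for (int a = 0; a < A; ++a) {
        if (sys_tree[a]) {
          double bonus = (intrinsic && !scope_global)
                           ? iota * last_shift[s + So * a] : 0.0;
          qstar[a] = treeQ[s + So * a] + bonus;
        } else {
          qstar[a] = means[a];
        }
      }

      // -- act (epsilon-greedy; uniform tie-break on the greedy max) ------
      double mx = qstar[0];
      for (int a = 1; a < A; ++a) if (qstar[a] > mx) mx = qstar[a];
      int nt = 0;
      for (int a = 0; a < A; ++a) if (qstar[a] == mx) ties[nt++] = a;
      int greedy = ties[0];
      if (nt > 1) {
        int j = (int)(unif_rand() * nt);
        if (j >= nt) j = nt - 1;
        greedy = ties[j];
      }
      int executed = greedy;
      if (epsilon > 0.0 && unif_rand() < epsilon) {
        int j = (int)(unif_rand() * A);
        if (j >= A) j = A - 1;
        executed = j;
      }

      // -- environment transition ----------------------------------------
      double u = unif_rand();
      int nxt = St - 1;
      double cum = 0.0;
      for (int s2 = 0; s2 < St; ++s2) {
        cum += trans[cur + St * executed + (size_t)St * A * s2];
        if (u <= cum) { nxt = s2; break; }
      }
      bool is_term = term_true[nxt];
      double r_ext = 0.0;
      if (is_term)
        r_ext = (rew_kind[nxt] == 0) ? rew_val[nxt]
                                     : R::rbeta(rew_a[nxt], rew_b[nxt]);
      double r_act = ra_vec[executed];
      int s2o = obs[nxt];

      // -- transition-model observation and learning progress -------------
      double tot = 0.0;
      size_t base = (size_t)s + (size_t)So * executed;
      for (int o = 0; o < So; ++o) tot += counts[base + (size_t)So * A * o];
      double shift = 0.0;
      for (int o = 0; o < So; ++o) {
        double c = counts[base + (size_t)So * A * o];
        double nm = (o == s2o) ? (c + 1.0) / (tot + 1.0) : c / (tot + 1.0);
        shift += std::fabs(nm - c / tot);
      }
      counts[base + (size_t)So * A * s2o] += 1.0;
      last_shift[s + So * executed] = shift;
      double r_int = intrinsic ? iota * shift : 0.0;

      // -- cache update ----------------------------------------------------
      if (is_term) {
        double tr = clamp01(r_ext + r_act);
        ca[s + So * executed] += tr;
        cb[s + So * executed] += 1.0 - tr;
      } else {
        int ab = 0;
        double bm = -1.0;
        for (int a = 0; a < A; ++a) {
          double m = ca[s2o + So * a] / (ca[s2o + So * a] + cb[s2o + So * a]);
          if (m > bm) { bm = m; ab = a; }
        }
        double target = clamp_unit(gamma * bm + r_act);
        double qa, qb;
        reshape_core(ca[s2o + So * ab], cb[s2o + So * ab], target, qa, qb);
        double na, nb;
        mixture_core(ca[s + So * executed], cb[s + So * executed], qa, qb,
                     na, nb);
        ca[s + So * executed] = na;
        cb[s + So * executed] = nb;
      }

      // -- reward model update --------------------------------------------
      if (is_term) {
        double rr = clamp01(r_ext);
        rma[s2o] += rr;
        rmb[s2o] += 1.0 - rr;
        term_known[s2o] = 1;
      }

      // -- average reward --------------------------------------------------
      double r_t = r_ext + r_act;
      if (!fixed_mode) avg = (1.0 - eta) * avg + eta * r_t;

      // -- forgetting decay ------------------------------------------------
      if (theta < 1.0) {
        double om = 1.0 - theta;
        for (size_t i = 0; i < ca.size(); ++i) {
          ca[i] = theta * ca[i] + om;
          cb[i] = theta * cb[i] + om;
        }
        double tp = om * tprior;
        for (size_t i = 0; i < counts.size(); ++i)
          counts[i] = theta * counts[i] + tp;
        for (int o = 0; o < So; ++o) {
          rma[o] = theta * rma[o] + om * pra[o];
          rmb[o] = theta * rmb[o] + om * prb[o];
        }
      }

      // -- trace row -------------------------------------------------------
      trace(row, 0) = ep;
      trace(row, 1) = st;
      trace(row, 2) = s + 1;
      trace(row, 3) = cur + 1;
      trace(row, 4) = greedy + 1;
      trace(row, 5) = executed + 1;
      trace(row, 6) = searched;
      trace(row, 7) = mask;
      trace(row, 8) = tree_count;
      trace(row, 9) = r_ext;
      trace(row, 10) = r_act;
      trace(row, 11) = r_int;
      trace(row, 12) = fixed_mode ? fixed_value : avg;
      trace(row, 13) = nxt + 1;
      trace(row, 14) = s2o + 1;
      trace(row, 15) = is_term ? 1 : 0;
      for (int a = 0; a < A; ++a) trace(row, 16 + a) = qstar[a];
      ++row;

      if (is_term) break;
      cur = nxt;
    }
  }

  NumericMatrix cam(So, A), cbm(So, A), lsm(So, A), tqm(So, A);
  for (int a = 0; a < A; ++a)
    for (int o = 0; o < So; ++o) {
      cam(o, a) = ca[o + So * a];
      cbm(o, a) = cb[o + So * a];
      lsm(o, a) = last_shift[o + So * a];
      tqm(o, a) = treeQ[o + So * a];
    }
  NumericVector cnt_out(counts.begin(), counts.end());
  cnt_out.attr("dim") = IntegerVector::create(So, A, So);

  return List::create(
    _["trace"] = trace, _["rows"] = (double)row,
    _["cache_alpha"] = cam, _["cache_beta"] = cbm,
    _["counts"] = cnt_out,
    _["reward_alpha"] = NumericVector(rma.begin(), rma.end()),
    _["reward_beta"] = NumericVector(rmb.begin(), rmb.end()),
    _["last_shift"] = lsm, _["tree_q"] = tqm,
    _["terminal_known"] = LogicalVector(term_known.begin(), term_known.end()),
    _["avg_reward"] = avg, _["tree_searches"] = (double)tree_count);
}
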