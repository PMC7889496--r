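#include <Rcpp.h>
using namespace Rcpp;

// Cross-term delta-rule recursion shared by the likelihood, the trajectory
// extractor and the agent simulator. Stimuli are coded 1=A, 2=B, 3=C;
// h = (H_AB, H_AC, H_BC); outcomes y in {-1,+1}; beliefs g reset to 0 at
// every block boundary. Updates are applied only on feedback trials.

static inline int pair_index(int a, int b) {
  // unordered pair -> index into h: (1,2)->0 AB, (1,3)->1 AC, (2,3)->2 BC
  int lo = a < b ? a : b, hi = a < b ? b : a;
  if (lo == 1 && hi == 2) return 0;
  if (lo == 1 && hi == 3) return 1;
  return 2;
}

static inline void apply_update(double g[3], int s, double y,
                                double alpha, const double* h) {
  for (int k = 1; k <= 3; ++k) {
    if (k == s) {
      g[k - 1] = (1.0 - alpha) * g[k - 1] + alpha * y;
    } else {
      double hx = h[pair_index(s, k)];
      g[k - 1] = (1.0 - alpha * std::fabs(hx)) * g[k - 1] + alpha * hx * y;
    }
  }
}

// [[Rcpp::export]]
List cpp_belief_pass(IntegerVector stimulus, NumericVector outcome,
                     LogicalVector feedback, IntegerVector block,
                     double alpha, double beta, NumericVector h,
                     Nullable<IntegerVector> choice_ = R_NilValue) {
  int n = stimulus.size();
  NumericMatrix g_pre(n, 3);     // beliefs before the trial's update
  NumericVector g_stim(n);       // presented stimulus's pre-update belief
  NumericVector p_acc(n);
  double nll = 0.0;
  bool have_choice = choice_.isNotNull();
  IntegerVector choice;
  if (have_choice) choice = choice_.get();

  double g[3] = {0.0, 0.0, 0.0};
  int cur_block = NA_INTEGER;
  const double floor_p = 1e-12;

  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != cur_block) {
      g[0] = g[1] = g[2] = 0.0;
      cur_block = block[t];
    }
    int s = stimulus[t];
    for (int k = 0; k < 3; ++k) g_pre(t, k) = g[k];
    g_stim[t] = g[s - 1];
    double p = 1.0 / (1.0 + std::exp(-beta * g[s - 1]));
    p_acc[t] = p;
    if (have_choice) {
      double pc = (choice[t] == 1) ? p : 1.0 - p;
      if (pc < floor_p) pc = floor_p;
      nll -= std::log(pc);
    }
    if (feedback[t]) apply_update(g, s, outcome[t], alpha, h.begin());
  }
  return List::create(_["g_pre"] = g_pre, _["g_stim"] = g_stim,
                      _["p_accept"] = p_acc, _["nll"] = nll);
}

// [[Rcpp::export]]
double cpp_nll(IntegerVector stimulus, NumericVector outcome,
               LogicalVector feedback, IntegerVector block,
               IntegerVector choice,
               double alpha, double beta, NumericVector h) {
  int n = stimulus.size();
  double g[3] = {0.0, 0.0, 0.0};
  int cur_block = NA_INTEGER;
  double nll = 0.0;
  const double floor_p = 1e-12;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != cur_block) {
      g[0] = g[1] = g[2] = 0.0;
      cur_block = block[t];
    }
    int s = stimulus[t];
    double p = 1.0 / (1.0 + std::exp(-beta * g[s - 1]));
    double pc = (choice[t] == 1) ? p : 1.0 - p;
    if (pc < floor_p) pc = floor_p;
    nll -= std::log(pc);
    if (feedback[t]) apply_update(g, s, outcome[t], alpha, h.begin());
  }
  return nll;
}

// Simulates an agent on a fixed schedule. `tail` marks trials where feedback
// is withheld if (and only if) the agent rejects; `unif` supplies one U(0,1)
// draw per trial so randomness stays under R's RNG.
// [[Rcpp::export]]
List cpp_simulate_agent(IntegerVector stimulus, NumericVector outcome,
                        LogicalVector tail, IntegerVector block,
                        double alpha, double beta, NumericVector h,
                        NumericVector unif) {
  int n = stimulus.size();
  IntegerVector choice(n);       // 1 = accept, 0 = reject
  LogicalVector feedback(n);
  NumericVector g_stim(n);
  double g[3] = {0.0, 0.0, 0.0};
  int cur_block = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (t == 0 || block[t] != cur_block) {
      g[0] = g[1] = g[2] = 0.0;
      cur_block = block[t];
    }
    int s = stimulus[t];
    g_stim[t] = g[s - 1];
    double p = 1.0 / (1.0 + std::exp(-beta * g[s - 1]));
    int c = (unif[t] < p) ? 1 : 0;
    choice[t] = c;
    bool fb = !(tail[t] && c == 0);
    feedback[t] = fb;
    if (fb) apply_update(g, s, outcome[t], alpha, h.begin());
  }
  return List::create(_["choice"] = choice, _["feedback"] = feedback,
                      _["g_stim"] = g_stim);
}
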