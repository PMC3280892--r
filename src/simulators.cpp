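#include <Rcpp.h>
using namespace Rcpp;

// All kernels draw from R's RNG so that set.seed() in R gives
// bit-reproducible paths.

static inline double sigmoid(double u, double gamma, double F0) {
  return F0 / (1.0 + std::exp(-gamma * u));
}

// ---------------------------------------------------------------------------
// Gillespie direct method for the M-population birth-death master equation.
// Channels: birth n_k -> n_k + 1 at rate N*F(sum_l w_kl n_l/N + I_k),
//           death n_k -> n_k - 1 at rate alpha_k * n_k.
// Transitions that would leave [0, N] are assigned zero rate (absorbing
// boundary convention: zero probability flux outside the lattice).
// States are recorded by exact piecewise-constant sampling at sample_times.
// [[Rcpp::export]]
IntegerMatrix ssa_sample_cpp(NumericMatrix W, NumericVector I,
                             NumericVector alpha, double gamma, double F0,
                             int N, IntegerVector n0,
                             NumericVector sample_times) {
  int M = n0.size(), ns = sample_times.size();
  IntegerMatrix out(ns, M);
  std::vector<int> n(M);
  for (int k = 0; k < M; k++) n[k] = n0[k];
  std::vector<double> rate(2 * M);
  double t = 0.0;
  int isamp = 0;
  while (isamp < ns) {
    double tot = 0.0;
    for (int k = 0; k < M; k++) {
      double u = I[k];
      for (int l = 0; l < M; l++) u += W(k, l) * n[l] / (double)N;
      rate[k] = (n[k] < N) ? N * sigmoid(u, gamma, F0) : 0.0; // birth
      rate[M + k] = alpha[k] * n[k];                          // death
      tot += rate[k] + rate[M + k];
    }
    double tnext = (tot > 0.0) ? t + R::exp_rand() / tot : R_PosInf;
    while (isamp < ns && sample_times[isamp] < tnext) {
      for (int k = 0; k < M; k++) out(isamp, k) = n[k];
      isamp++;
    }
    if (!R_FINITE(tnext)) break; // absorbing state
    t = tnext;
    double u = unif_rand() * tot, acc = 0.0;
    for (int k = 0; k < 2 * M; k++) {
      acc += rate[k];
      if (u <= acc) { if (k < M) n[k]++; else n[k - M]--; break; }
    }
  }
  return out;
}

// Event-resolved variant for small fixtures (inter-event statistics etc.).
// [[Rcpp::export]]
List ssa_events_cpp(NumericMatrix W, NumericVector I, NumericVector alpha,
                    double gamma, double F0, int N, IntegerVector n0,
                    double horizon, int max_events) {
  int M = n0.size();
  std::vector<int> n(M);
  for (int k = 0; k < M; k++) n[k] = n0[k];
  std::vector<double> rate(2 * M), times;
  std::vector<int> states;
  double t = 0.0;
  bool absorbed = false;
  times.push_back(t);
  for (int k = 0; k < M; k++) states.push_back(n[k]);
  while ((int)times.size() <= max_events) {
    double tot = 0.0;
    for (int k = 0; k < M; k++) {
      double u = I[k];
      for (int l = 0; l < M; l++) u += W(k, l) * n[l] / (double)N;
      rate[k] = (n[k] < N) ? N * sigmoid(u, gamma, F0) : 0.0;
      rate[M + k] = alpha[k] * n[k];
      tot += rate[k] + rate[M + k];
    }
    if (tot <= 0.0) { absorbed = true; break; }
    t += R::exp_rand() / tot;
    if (t > horizon) break;
    double u = unif_rand() * tot, acc = 0.0;
    for (int k = 0; k < 2 * M; k++) {
      acc += rate[k];
      if (u <= acc) { if (k < M) n[k]++; else n[k - M]--; break; }
    }
    times.push_back(t);
    for (int k = 0; k < M; k++) states.push_back(n[k]);
  }
  int ne = times.size();
  IntegerMatrix st(ne, M);
  for (int i = 0; i < ne; i++)
    for (int k = 0; k < M; k++) st(i, k) = states[i * M + k];
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = st, _["absorbed"] = absorbed);
}

// ---------------------------------------------------------------------------
// Piecewise-deterministic simulation of the one-population depression hybrid
// model.  Between jumps q relaxes exactly: dq/dt = k+(1-q) - k- (n/N) q is
// linear in q while n is constant, so q(t) = qbar + (q0-qbar) exp(-r t) with
// r = k+ + k- n/N, qbar = k+/r.  Jumps sampled by thinning against the
// global bound N*F0 (birth) + N*alpha (death); acceptance uses the
// instantaneous rates at the candidate time.
static inline double q_flow(double q0, double x, double kp, double km,
                            double dt) {
  double r = kp + km * x;
  if (r <= 0.0) return q0;
  double qbar = kp / r;
  return qbar + (q0 - qbar) * std::exp(-r * dt);
}

// [[Rcpp::export]]
NumericMatrix pdmp_sample_cpp(int N, double k_plus, double k_minus,
                              double w_self, double h, double gamma,
                              double F0, double alpha, int n0, double q0,
                              NumericVector sample_times) {
  int ns = sample_times.size();
  NumericMatrix out(ns, 2);
  int n = n0;
  double q = q0, t = 0.0;
  double bound = N * F0 + N * alpha;
  int isamp = 0;
  while (isamp < ns) {
    double tau = R::exp_rand() / bound;
    double tnext = t + tau;
    while (isamp < ns && sample_times[isamp] < tnext) {
      double x = n / (double)N;
      out(isamp, 0) = x;
      out(isamp, 1) = q_flow(q, x, k_plus, k_minus, sample_times[isamp] - t);
      isamp++;
    }
    double x = n / (double)N;
    q = q_flow(q, x, k_plus, k_minus, tau);
    t = tnext;
    double birth = (n < N) ? N * sigmoid(w_self * q * x + h, gamma, F0) : 0.0;
    double death = alpha * n;
    double u = unif_rand() * bound;
    if (u < birth) n++;
    else if (u < birth + death) n--;
    // else: thinned candidate, no transition
  }
  return out;
}

// Event-resolved PDMP (jump times only), for exactness checks.
// [[Rcpp::export]]
List pdmp_events_cpp(int N, double k_plus, double k_minus, double w_self,
                     double h, double gamma, double F0, double alpha, int n0,
                     double q0, double horizon, int max_events) {
  std::vector<double> times, qs;
  std::vector<int> ns_;
  int n = n0;
  double q = q0, t = 0.0;
  double bound = N * F0 + N * alpha;
  times.push_back(0.0); ns_.push_back(n); qs.push_back(q);
  while ((int)times.size() <= max_events) {
    double tau = R::exp_rand() / bound;
    double x = n / (double)N;
    q = q_flow(q, x, k_plus, k_minus, tau);
    t += tau;
    if (t > horizon) break;
    double birth = (n < N) ? N * sigmoid(w_self * q * x + h, gamma, F0) : 0.0;
    double death = alpha * n;
    double u = unif_rand() * bound;
    if (u < birth) n++;
    else if (u < birth + death) n--;
    else continue; // thinned
    times.push_back(t); ns_.push_back(n); qs.push_back(q);
  }
  return List::create(_["times"] = NumericVector(times.begin(), times.end()),
                      _["n"] = IntegerVector(ns_.begin(), ns_.end()),
                      _["q"] = NumericVector(qs.begin(), qs.end()));
}

// ---------------------------------------------------------------------------
// Euler-Maruyama for the Ito phase ensemble.  Tabulated coefficients on a
// uniform grid over [-pi, pi) are interpolated linearly with wraparound.
// Every oscillator receives the same common increment dW scaled by its
// common coefficient; the M independent channels are equivalent in law to a
// single channel with the root-sum-square amplitude, tabulated in indep.
static inline double interp_circ(const NumericVector& tab, double theta,
                                 int ng) {
  double s = (theta + M_PI) / (2.0 * M_PI); // in [0,1)
  s -= std::floor(s);
  double pos = s * ng;
  int j = (int)pos;
  double w = pos - j;
  int j1 = (j + 1 == ng) ? 0 : j + 1;
  return tab[j] * (1.0 - w) + tab[j1] * w;
}

// [[Rcpp::export]]
NumericMatrix em_phase_cpp(NumericVector drift_tab, NumericVector common_tab,
                           NumericVector indep_tab, double sigma, double eps,
                           NumericVector theta0, double dt,
                           NumericVector sample_times) {
  int nosc = theta0.size(), ns = sample_times.size();
  int ng = drift_tab.size();
  NumericMatrix out(ns, nosc);
  std::vector<double> th(nosc);
  for (int m = 0; m < nosc; m++) th[m] = theta0[m];
  double sq = std::sqrt(dt);
  long step = 0;
  double t = 0.0;
  int isamp = 0;
  while (isamp < ns) {
    while (isamp < ns && sample_times[isamp] <= t) {
      for (int m = 0; m < nosc; m++) {
        double s = (th[m] + M_PI) / (2.0 * M_PI);
        out(isamp, m) = (s - std::floor(s)) * 2.0 * M_PI - M_PI;
      }
      isamp++;
    }
    if (isamp >= ns) break;
    double dW = norm_rand() * sq;
    for (int m = 0; m < nosc; m++) {
      double a = interp_circ(drift_tab, th[m], ng);
      double c = interp_circ(common_tab, th[m], ng);
      double b = interp_circ(indep_tab, th[m], ng);
      th[m] += a * dt + sigma * c * dW + eps * b * norm_rand() * sq;
    }
    step++;
    t = step * dt;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Euler-Maruyama for an ensemble of full M-population Langevin oscillators
// sharing one common (Stratonovich) noise source.  The Stratonovich common
// term is stepped in Ito form with the drift correction
// (sigma^2/2) sum_l a_l da_k/dx_l, a_k = chi_k F'(u_k),
// da_k/dx_l = chi_k F''(u_k) w_kl.  Intrinsic channels are Ito as given.
// Returns sampled states, row = sample time, columns oscillator-major.
// [[Rcpp::export]]
NumericMatrix em_network_cpp(NumericMatrix W, NumericVector I,
                             NumericVector alpha, double gamma, double F0,
                             double sigma, NumericVector chi, double eps,
                             NumericMatrix x0, double dt,
                             NumericVector sample_times) {
  int nosc = x0.nrow(), M = x0.ncol(), ns = sample_times.size();
  NumericMatrix out(ns, nosc * M);
  std::vector<double> x(nosc * M);
  for (int m = 0; m < nosc; m++)
    for (int k = 0; k < M; k++) x[m * M + k] = x0(m, k);
  std::vector<double> u(M), Fv(M), Fp(M), a(M);
  double sq = std::sqrt(dt);
  long step = 0;
  double t = 0.0;
  int isamp = 0;
  while (isamp < ns) {
    while (isamp < ns && sample_times[isamp] <= t) {
      for (int m = 0; m < nosc; m++)
        for (int k = 0; k < M; k++) out(isamp, m * M + k) = x[m * M + k];
      isamp++;
    }
    if (isamp >= ns) break;
    double dW = norm_rand() * sq;
    for (int m = 0; m < nosc; m++) {
      double* xm = &x[m * M];
      for (int k = 0; k < M; k++) {
        double uk = I[k];
        for (int l = 0; l < M; l++) uk += W(k, l) * xm[l];
        u[k] = uk;
        Fv[k] = sigmoid(uk, gamma, F0);
        Fp[k] = gamma * Fv[k] * (1.0 - Fv[k] / F0);
        a[k] = chi[k] * Fp[k];
      }
      for (int k = 0; k < M; k++) {
        double A = -alpha[k] * xm[k] + Fv[k];
        double Fpp = gamma * Fp[k] * (1.0 - 2.0 * Fv[k] / F0);
        double corr = 0.0;
        for (int l = 0; l < M; l++) corr += a[l] * chi[k] * Fpp * W(k, l);
        corr *= 0.5 * sigma * sigma;
        double b2 = Fv[k] + alpha[k] * xm[k];
        double b = (b2 > 0.0) ? std::sqrt(b2) : 0.0;
        xm[k] += (A + corr) * dt + sigma * a[k] * dW +
                 eps * b * norm_rand() * sq;
      }
    }
    step++;
    t = step * dt;
  }
  return out;
}

// Planar Langevin ensemble for the depression model: state (x, q) per
// oscillator, noise (common Stratonovich + intrinsic Ito) in x only,
// q deterministic.  u = w_self*q*x + h; a = F'(u); da/dx = F''(u)*w_self*q.
// [[Rcpp::export]]
NumericMatrix em_depression_cpp(double k_plus, double k_minus, double w_self,
                                double h, double gamma, double F0,
                                double alpha, double sigma, double eps,
                                NumericMatrix x0, double dt,
                                NumericVector sample_times) {
  int nosc = x0.nrow(), ns = sample_times.size();
  NumericMatrix out(ns, nosc * 2);
  std::vector<double> x(nosc), q(nosc);
  for (int m = 0; m < nosc; m++) { x[m] = x0(m, 0); q[m] = x0(m, 1); }
  double sq = std::sqrt(dt);
  long step = 0;
  double t = 0.0;
  int isamp = 0;
  while (isamp < ns) {
    while (isamp < ns && sample_times[isamp] <= t) {
      for (int m = 0; m < nosc; m++) {
        out(isamp, 2 * m) = x[m];
        out(isamp, 2 * m + 1) = q[m];
      }
      isamp++;
    }
    if (isamp >= ns) break;
    double dW = norm_rand() * sq;
    for (int m = 0; m < nosc; m++) {
      double u = w_self * q[m] * x[m] + h;
      double F = sigmoid(u, gamma, F0);
      double Fp = gamma * F * (1.0 - F / F0);
      double Fpp = gamma * Fp * (1.0 - 2.0 * F / F0);
      double corr = 0.5 * sigma * sigma * Fp * Fpp * w_self * q[m];
      double b2 = x[m] * alpha + F;
      double b = (b2 > 0.0) ? std::sqrt(b2) : 0.0;
      double dq = k_plus * (1.0 - q[m]) - k_minus * x[m] * q[m];
      x[m] += (-alpha * x[m] + F + corr) * dt + sigma * Fp * dW +
              eps * b * norm_rand() * sq;
      q[m] += dq * dt;
    }
    step++;
    t = step * dt;
  }
  return out;
}

// Nearest-orbit-point phase projection: for each state row, the phase of the
// closest point on the tabulated orbit (grid over [-pi, pi)).
// [[Rcpp::export]]
NumericVector project_phase_cpp(NumericMatrix states, NumericMatrix orbit) {
  int n = states.nrow(), d = states.ncol(), ng = orbit.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < ng; j++) {
      double dist = 0.0;
      for (int k = 0; k < d; k++) {
        double dd = states(i, k) - orbit(j, k);
        dist += dd * dd;
      }
      if (dist < best) { best = dist; bj = j; }
    }
    out[i] = -M_PI + 2.0 * M_PI * bj / ng;
  }
  return out;
}
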