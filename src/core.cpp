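#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout (shared with R side, see par_vec()):
//   0:vs 1:kI 2:vm 3:km 4:ks 5:vd 6:kd 7:k1 8:k2 9:N 10:omega
// Protocol vector layout: 0:is_ld 1:thetaM 2:t_dawn 3:t_dusk

static double light_theta_c(double t, const double* prot) {
  if (prot[0] < 0.5) return 0.0;
  double tm = t - 24.0 * std::floor(t / 24.0);  // mod(t, 24) in [0, 24)
  return (tm >= prot[2] && tm <= prot[3]) ? prot[1] : 0.0;
}

// Birth/death rates per species on the count scale.  Saturating (Hill /
// Michaelis-Menten) terms see concentrations (count / omega); first-order
// rates act on counts; the zero-order transcription term carries a factor
// omega.  out6 = {bM, dM, bPc, dPc, bPn, dPn}, all in molecules per hour.
static void bd_rates_c(const double* s, double t, const double* p,
                       const double* prot, double* out6) {
  const double M = s[0], Pc = s[1], Pn = s[2];
  const double omega = p[10], N = p[9];
  const double theta = light_theta_c(t, prot);
  const double kIN = std::pow(p[1], N);
  const double pn_conc = Pn / omega;
  out6[0] = omega * (p[0] + theta) * kIN / (kIN + std::pow(pn_conc, N));
  out6[1] = p[2] * M / (p[3] + M / omega);
  out6[2] = p[4] * M + p[8] * Pn;
  out6[3] = p[5] * Pc / (p[6] + Pc / omega) + p[7] * Pc;
  out6[4] = p[7] * Pc;
  out6[5] = p[8] * Pn;
}

// [[Rcpp::export]]
NumericMatrix cpp_bd_rates(NumericVector state, double t, NumericVector params,
                           NumericVector protocol) {
  double out6[6];
  bd_rates_c(state.begin(), t, params.begin(), protocol.begin(), out6);
  NumericMatrix out(3, 2);
  for (int d = 0; d < 3; d++) { out(d, 0) = out6[2 * d]; out(d, 1) = out6[2 * d + 1]; }
  return out;
}

// log(Phi(b) - Phi(a)) for standardized a < b, stable in far tails.
static double log_pnorm_diff(double a, double b) {
  if (a > 0.0) {
    double la = R::pnorm(a, 0.0, 1.0, 0, 1), lb = R::pnorm(b, 0.0, 1.0, 0, 1);
    return la + log1p(-std::exp(lb - la));
  } else if (b < 0.0) {
    double la = R::pnorm(a, 0.0, 1.0, 1, 1), lb = R::pnorm(b, 0.0, 1.0, 1, 1);
    return lb + log1p(-std::exp(la - lb));
  }
  return std::log(R::pnorm(b, 0.0, 1.0, 1, 0) - R::pnorm(a, 0.0, 1.0, 1, 0));
}

// Normalized transitional log-density: the interval probability of a normal
// increment around dY divided by its maximum (the same window centred on the
// mean), so the value is <= 0 with equality iff dY == mu.
static double trans_logdens_c(double dY, double mu, double sigma, double eps,
                              double floor_) {
  double v;
  if (sigma <= 0.0) {
    v = (std::fabs(dY - mu) < eps) ? 0.0 : floor_;
  } else {
    double num = log_pnorm_diff((dY - eps - mu) / sigma, (dY + eps - mu) / sigma);
    double den = log_pnorm_diff(-eps / sigma, eps / sigma);
    v = num - den;
  }
  if (!std::isfinite(v) || v < floor_) v = floor_;
  if (v > 0.0) v = 0.0;
  return v;
}

// [[Rcpp::export]]
NumericVector cpp_trans_logdens(NumericVector dY, NumericVector mu,
                                NumericVector sigma, double eps, double floor_) {
  int n = dY.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = trans_logdens_c(dY[i], mu[i % mu.size()], sigma[i % sigma.size()],
                             eps, floor_);
  return out;
}

// Drift-propagated bridge with multiplicative end-error correction.
// B has l+1 rows; row 0 is the start observation, row l the end observation.
// Interior rows 1..l-1 come from the deterministic drift recursion; the
// projected endpoint from row l-1 defines per-species correction ratios.
// literal = true uses the ratio projected/observed; the default orientation
// observed/projected makes the corrected path terminate at the data.
static void build_bridge_c(const double* start, const double* end,
                           double t_start, double dt, int l, const double* p,
                           const double* prot, bool literal, double* B,
                           double* bend, double* r) {
  double rates[6];
  for (int d = 0; d < 3; d++) B[d] = start[d];
  for (int i = 1; i < l; i++) {
    bd_rates_c(B + 3 * (i - 1), t_start + (i - 1) * dt, p, prot, rates);
    for (int d = 0; d < 3; d++) {
      double v = B[3 * (i - 1) + d] + (rates[2 * d] - rates[2 * d + 1]) * dt;
      B[3 * i + d] = (v > 0.0) ? v : 0.0;
    }
  }
  bd_rates_c(B + 3 * (l - 1), t_start + (l - 1) * dt, p, prot, rates);
  for (int d = 0; d < 3; d++) {
    double v = B[3 * (l - 1) + d] + (rates[2 * d] - rates[2 * d + 1]) * dt;
    bend[d] = (v > 0.0) ? v : 0.0;
    B[3 * l + d] = end[d];
  }
  for (int d = 0; d < 3; d++) {
    double num = literal ? bend[d] : end[d];
    double den = literal ? end[d] : bend[d];
    if (den < 1e-6) den = 1e-6;
    r[d] = num / den;
  }
  for (int i = 1; i < l; i++)
    for (int d = 0; d < 3; d++) {
      double v = B[3 * i + d] * (1.0 + i * (r[d] - 1.0) / l);
      B[3 * i + d] = (v > 0.0) ? v : 0.0;
    }
}

// [[Rcpp::export]]
List cpp_build_bridge(NumericVector start, NumericVector end, double t_start,
                      double dt, int l, NumericVector params,
                      NumericVector protocol, bool literal) {
  std::vector<double> B(3 * (l + 1));
  double bend[3], r[3];
  build_bridge_c(start.begin(), end.begin(), t_start, dt, l, params.begin(),
                 protocol.begin(), literal, B.data(), bend, r);
  NumericMatrix pts(l + 1, 3);
  for (int i = 0; i <= l; i++)
    for (int d = 0; d < 3; d++) pts(i, d) = B[3 * i + d];
  return List::create(_["points"] = pts,
                      _["end_projection"] = NumericVector(bend, bend + 3),
                      _["r"] = NumericVector(r, r + 3));
}

// Per-step, per-species normalized transitional log-densities along the
// (corrected) bridge; mu and sigma at step i use the rates at the corrected
// predecessor point.  out is l x 3.
static void bridge_steps_c(const double* B, double t_start, double dt, int l,
                           const double* p, const double* prot, double eps,
                           double floor_, double* out) {
  double rates[6];
  for (int i = 0; i < l; i++) {
    bd_rates_c(B + 3 * i, t_start + i * dt, p, prot, rates);
    for (int d = 0; d < 3; d++) {
      double mu = (rates[2 * d] - rates[2 * d + 1]) * dt;
      double sig = std::sqrt((rates[2 * d] + rates[2 * d + 1]) * dt);
      double dY = B[3 * (i + 1) + d] - B[3 * i + d];
      out[i + l * d] = trans_logdens_c(dY, mu, sig, eps, floor_);
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_interval_steps(NumericVector start, NumericVector end,
                                 double t_start, double dt, int l,
                                 NumericVector params, NumericVector protocol,
                                 double eps, bool literal, double floor_) {
  std::vector<double> B(3 * (l + 1)), steps(3 * l);
  double bend[3], r[3];
  build_bridge_c(start.begin(), end.begin(), t_start, dt, l, params.begin(),
                 protocol.begin(), literal, B.data(), bend, r);
  bridge_steps_c(B.data(), t_start, dt, l, params.begin(), protocol.begin(),
                 eps, floor_, steps.data());
  NumericMatrix out(l, 3);
  std::copy(steps.begin(), steps.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
double cpp_dataset_loglik(NumericVector times, NumericMatrix counts,
                          NumericVector params, NumericVector protocol,
                          double eps, int l, bool literal, double floor_) {
  int m = times.size();
  std::vector<double> B(3 * (l + 1)), steps(3 * l);
  double bend[3], r[3], start[3], end[3];
  double total = 0.0;
  for (int i = 0; i + 1 < m; i++) {
    double dt = (times[i + 1] - times[i]) / l;
    for (int d = 0; d < 3; d++) { start[d] = counts(i, d); end[d] = counts(i + 1, d); }
    build_bridge_c(start, end, times[i], dt, l, params.begin(),
                   protocol.begin(), literal, B.data(), bend, r);
    bridge_steps_c(B.data(), times[i], dt, l, params.begin(), protocol.begin(),
                   eps, floor_, steps.data());
    for (int k = 0; k < 3 * l; k++) total += steps[k];
  }
  return total;
}

// [[Rcpp::export]]
double cpp_dataset_entropy(NumericVector times, NumericMatrix counts,
                           NumericVector params, NumericVector protocol,
                           double eps, int l, bool literal, double floor_) {
  int m = times.size();
  std::vector<double> B(3 * (l + 1)), steps(3 * l);
  double bend[3], r[3], start[3], end[3];
  double total = 0.0;
  for (int i = 0; i + 1 < m; i++) {
    double dt = (times[i + 1] - times[i]) / l;
    for (int d = 0; d < 3; d++) { start[d] = counts(i, d); end[d] = counts(i + 1, d); }
    build_bridge_c(start, end, times[i], dt, l, params.begin(),
                   protocol.begin(), literal, B.data(), bend, r);
    bridge_steps_c(B.data(), times[i], dt, l, params.begin(), protocol.begin(),
                   eps, floor_, steps.data());
    for (int k = 0; k < 3 * l; k++) {
      double lp = steps[k];
      if (lp > -700.0) total += std::exp(lp) * lp;  // p log p; p = 0 contributes 0
    }
  }
  return total;
}

// Path log-likelihood of an arbitrary bridge (rows of P, (l+1) x 3 flattened
// row-major as 3*i+d) -- the objective the simulated-annealing oracle searches.
static double path_loglik_c(const double* P, double t_start, double dt, int l,
                            const double* p, const double* prot, double eps,
                            double floor_) {
  std::vector<double> steps(3 * l);
  bridge_steps_c(P, t_start, dt, l, p, prot, eps, floor_, steps.data());
  double s = 0.0;
  for (int k = 0; k < 3 * l; k++) s += steps[k];
  return s;
}

// Log-likelihood of steps i-1 and i only (those touched when interior point i
// moves); used for incremental simulated-annealing updates.
static double local_loglik_c(const double* P, int i, double t_start, double dt,
                             int l, const double* p, const double* prot,
                             double eps, double floor_) {
  double rates[6], s = 0.0;
  for (int j = i - 1; j <= i && j < l; j++) {
    if (j < 0) continue;
    bd_rates_c(P + 3 * j, t_start + j * dt, p, prot, rates);
    for (int d = 0; d < 3; d++) {
      double mu = (rates[2 * d] - rates[2 * d + 1]) * dt;
      double sig = std::sqrt((rates[2 * d] + rates[2 * d + 1]) * dt);
      double dY = P[3 * (j + 1) + d] - P[3 * j + d];
      s += trans_logdens_c(dY, mu, sig, eps, floor_);
    }
  }
  return s;
}

// Simulated-annealing search for the best bridge between two observations:
// geometric cooling, per-coordinate Gaussian proposals over the (l-1) x 3
// free interior coordinates, initialized at linear interpolation (independent
// of the drift-correction heuristic).  Returns the best path log-likelihood.
// [[Rcpp::export]]
double cpp_sa_bridge(NumericVector start, NumericVector end, double t_start,
                     double dt, int l, NumericVector params,
                     NumericVector protocol, double eps, double floor_,
                     int n_sweeps, double t0, double cool, double prop_frac) {
  std::vector<double> P(3 * (l + 1));
  for (int d = 0; d < 3; d++) {
    P[d] = start[d];
    P[3 * l + d] = end[d];
    for (int i = 1; i < l; i++)
      P[3 * i + d] = start[d] + (end[d] - start[d]) * i / double(l);
  }
  double scale[3];
  for (int d = 0; d < 3; d++) {
    double m = std::max(std::fabs(start[d]), std::fabs(end[d]));
    scale[d] = prop_frac * std::max(m, 1.0);
  }
  double cur = path_loglik_c(P.data(), t_start, dt, l, params.begin(),
                             protocol.begin(), eps, floor_);
  double best = cur;
  double T = t0;
  for (int s = 0; s < n_sweeps; s++, T *= cool) {
    for (int i = 1; i < l; i++) {
      for (int d = 0; d < 3; d++) {
        double old = P[3 * i + d];
        double old_loc = local_loglik_c(P.data(), i, t_start, dt, l,
                                        params.begin(), protocol.begin(), eps,
                                        floor_);
        double prop = old + norm_rand() * scale[d];
        if (prop < 0.0) prop = 0.0;
        P[3 * i + d] = prop;
        double new_loc = local_loglik_c(P.data(), i, t_start, dt, l,
                                        params.begin(), protocol.begin(), eps,
                                        floor_);
        double delta = new_loc - old_loc;
        if (delta > 0.0 || unif_rand() < std::exp(delta / T)) {
          cur += delta;
          if (cur > best) best = cur;
        } else {
          P[3 * i + d] = old;
        }
      }
    }
  }
  return best;
}

// Propensities of the six elementary reactions (count scale):
// 0 transcription (M+1), 1 mRNA degradation (M-1), 2 translation (Pc+1),
// 3 protein degradation (Pc-1), 4 nuclear import (Pc-1, Pn+1),
// 5 nuclear export (Pn-1, Pc+1).  The per-species birth/death rates of
// bd_rates_c are sums of these channels.
static void propensities_c(const double* s, double t, const double* p,
                           const double* prot, double* a6) {
  const double M = s[0], Pc = s[1], Pn = s[2];
  const double omega = p[10], N = p[9];
  const double theta = light_theta_c(t, prot);
  const double kIN = std::pow(p[1], N);
  a6[0] = omega * (p[0] + theta) * kIN / (kIN + std::pow(Pn / omega, N));
  a6[1] = p[2] * M / (p[3] + M / omega);
  a6[2] = p[4] * M;
  a6[3] = p[5] * Pc / (p[6] + Pc / omega);
  a6[4] = p[7] * Pc;
  a6[5] = p[8] * Pn;
}

// Exact stochastic simulation (direct method) of the six reaction channels,
// recorded on a fixed grid.  Light switching is handled by capping each
// exponential waiting time at the next dawn/dusk boundary and redrawing,
// which is exact because propensities are constant within a light segment.
// [[Rcpp::export]]
NumericMatrix cpp_ssa(NumericVector init, double t_end, NumericVector params,
                      NumericVector protocol, double record_dt,
                      double max_events) {
  int n_grid = (int)std::floor(t_end / record_dt + 1e-9) + 1;
  NumericMatrix out(n_grid, 4);
  double s[3] = { init[0], init[1], init[2] };
  double t = 0.0, a[6];
  bool is_ld = protocol[0] > 0.5;
  int next_rec = 0;
  double events = 0.0;
  while (true) {
    // light segment boundary strictly after t
    double t_seg = t_end + 1.0;
    if (is_ld) {
      double base = 24.0 * std::floor(t / 24.0);
      double cand[4] = { base + protocol[2], base + protocol[3],
                         base + 24.0 + protocol[2], base + 24.0 + protocol[3] };
      for (int k = 0; k < 4; k++)
        if (cand[k] > t + 1e-12 && cand[k] < t_seg) t_seg = cand[k];
    }
    if (t_seg > t_end) t_seg = t_end;
    propensities_c(s, t, params.begin(), protocol.begin(), a);
    double a0 = 0.0;
    for (int k = 0; k < 6; k++) {
      if (a[k] < 0 || !std::isfinite(a[k]))
        stop("negative or non-finite propensity at t=%f", t);
      a0 += a[k];
    }
    double t_next = (a0 > 0.0) ? t + exp_rand() / a0 : t_end + 1.0;
    double t_adv = std::min(t_next, t_seg);
    while (next_rec < n_grid && next_rec * record_dt <= t_adv + 1e-9) {
      out(next_rec, 0) = next_rec * record_dt;
      for (int d = 0; d < 3; d++) out(next_rec, d + 1) = s[d];
      next_rec++;
    }
    if (next_rec >= n_grid) break;
    t = t_adv;
    if (t_next > t_seg) continue;  // segment boundary first: redraw with new theta
    double u = unif_rand() * a0, c = 0.0;
    int j = 0;
    for (; j < 5; j++) { c += a[j]; if (u <= c) break; }
    switch (j) {
      case 0: s[0] += 1; break;                 // transcription
      case 1: s[0] -= 1; break;                 // mRNA degradation
      case 2: s[1] += 1; break;                 // translation
      case 3: s[1] -= 1; break;                 // protein degradation
      case 4: s[1] -= 1; s[2] += 1; break;      // nuclear import (Pc -> Pn)
      case 5: s[2] -= 1; s[1] += 1; break;      // nuclear export (Pn -> Pc)
    }
    if (s[0] < 0) s[0] = 0;
    if (s[1] < 0) s[1] = 0;
    if (s[2] < 0) s[2] = 0;
    if (++events > max_events)
      stop("event budget exceeded (%.0f events) at t=%f", events, t);
  }
  return out;
}
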