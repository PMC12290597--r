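#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time machinery for the two-boundary Wiener diffusion with
// unit diffusion coefficient, absorbing barriers at 0 and alpha, start at
// alpha * beta and drift delta.  The defective density of hitting the LOWER
// barrier is evaluated through the standard pair of series expansions
// (small-time and large-time), choosing whichever needs fewer terms for the
// requested absolute truncation error.

// standardized lower-barrier density f(u | 0, 1, w) at normalised time u
static double wfpt_std(double u, double w, double eps) {
  // number of terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double f = 0.0;
  if (ks < kl) {            // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -(int)std::floor((K - 1) / 2.0);
    int hi = (int)std::ceil((K - 1) / 2.0);
    for (int k = lo; k <= hi; k++) {
      double q = w + 2.0 * k;
      f += q * std::exp(-q * q / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {                  // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) *
           std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

// defective density (in decision time t > 0) of absorption at the lower
// barrier for parameters (alpha, beta, delta)
static double wfpt_lower(double t, double alpha, double beta, double delta,
                         double eps) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  double u = t / (alpha * alpha);
  double f = wfpt_std(u, beta, eps);
  if (f < 0.0) f = 0.0;  // truncation can produce tiny negatives
  return f / (alpha * alpha) *
         std::exp(-delta * alpha * beta - delta * delta * t / 2.0);
}

static bool valid_params(double alpha, double beta, double tau, double delta) {
  return R_finite(alpha) && R_finite(beta) && R_finite(tau) &&
         R_finite(delta) && alpha > 0.0 && beta > 0.0 && beta < 1.0 &&
         tau >= 0.0;
}

//' @noRd
// [[Rcpp::export]]
NumericVector wiener_fpt_density_cpp(NumericVector t, bool upper,
                                     double alpha, double beta, double tau,
                                     double delta, double tol) {
  if (!valid_params(alpha, beta, tau, delta))
    stop("invalid Wiener parameters: need alpha > 0, 0 < beta < 1, tau >= 0, all finite");
  if (tol <= 0.0) stop("tol must be positive");
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double td = t[i];
    // reflection: the upper-barrier density equals the lower-barrier
    // density with beta -> 1 - beta and delta -> -delta
    out[i] = upper ? wfpt_lower(td, alpha, 1.0 - beta, -delta, tol)
                   : wfpt_lower(td, alpha, beta, delta, tol);
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
double wiener_loglik_cpp(NumericVector rt, IntegerVector upper,
                         NumericVector delta, NumericVector beta,
                         NumericVector tau, NumericVector alpha,
                         double tol) {
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    if (!valid_params(alpha[i], beta[i], tau[i], delta[i])) return R_NegInf;
    double td = rt[i] - tau[i];
    if (td <= 0.0) return R_NegInf;
    double f = upper[i]
        ? wfpt_lower(td, alpha[i], 1.0 - beta[i], -delta[i], tol)
        : wfpt_lower(td, alpha[i], beta[i], delta[i], tol);
    if (f <= 0.0) return R_NegInf;
    ll += std::log(f);
  }
  return ll;
}

//' @noRd
// [[Rcpp::export]]
List wiener_sample_cpp(int n, double alpha, double beta, double tau,
                       NumericVector delta, double dt, double deadline) {
  // Euler-Maruyama simulation of the diffusion path; delta may be length 1
  // or length n (per-trial drift).  Absorption later than the deadline (on
  // the response-time scale, i.e. including tau) yields choice NA.
  if (n < 1) stop("n must be >= 1");
  if (dt <= 0.0) stop("dt must be positive");
  if (!(alpha > 0.0) || !(beta > 0.0) || !(beta < 1.0) || tau < 0.0)
    stop("invalid Wiener parameters");
  bool scalar_d = delta.size() == 1;
  if (!scalar_d && delta.size() != n)
    stop("delta must have length 1 or n");
  NumericVector rt(n);
  IntegerVector choice(n);
  double sdt = std::sqrt(dt);
  double t_max = R_finite(deadline) ? (deadline - tau) : R_PosInf;
  for (int i = 0; i < n; i++) {
    double d = scalar_d ? delta[0] : delta[i];
    double x = alpha * beta;
    double t = 0.0;
    int hit = NA_INTEGER;
    while (t < t_max) {
      double x_old = x;
      x += d * dt + sdt * norm_rand();
      t += dt;
      if (x >= alpha) { hit = 1; break; }
      if (x <= 0.0)   { hit = 0; break; }
      // Brownian-bridge correction: the path may have touched a barrier
      // inside the step even though both endpoints are interior
      double p_up = std::exp(-2.0 * (alpha - x_old) * (alpha - x) / dt);
      if (unif_rand() < p_up) { hit = 1; break; }
      double p_lo = std::exp(-2.0 * x_old * x / dt);
      if (unif_rand() < p_lo) { hit = 0; break; }
    }
    if (hit == NA_INTEGER) {
      choice[i] = NA_INTEGER;
      rt[i] = NA_REAL;
    } else {
      choice[i] = hit;
      rt[i] = t + tau;
    }
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}

//' @noRd
// [[Rcpp::export]]
double wiener_loglik_sv_cpp(NumericVector rt, IntegerVector upper,
                            NumericVector delta, double beta, double tau,
                            double alpha, double tol) {
  // scalar beta/tau/alpha with per-trial drift: the common case inside
  // hierarchical updates, avoiding per-call vector replication
  if (!(alpha > 0.0) || !(beta > 0.0) || !(beta < 1.0) || tau < 0.0 ||
      !R_finite(alpha) || !R_finite(beta) || !R_finite(tau))
    return R_NegInf;
  int n = rt.size();
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    if (!R_finite(delta[i])) return R_NegInf;
    double td = rt[i] - tau;
    if (td <= 0.0) return R_NegInf;
    double f = upper[i]
        ? wfpt_lower(td, alpha, 1.0 - beta, -delta[i], tol)
        : wfpt_lower(td, alpha, beta, delta[i], tol);
    if (f <= 0.0) return R_NegInf;
    ll += std::log(f);
  }
  return ll;
}
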