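// Forward model core: gastrointestinal / plasma / liver / tracer / insulin
// modules as one ODE system, plus an adaptive Dormand-Prince 5(4) integrator.
//
// Internal units: mass mg/kg body weight, time days, rates per day.
// State layout per block (unlabeled first, labeled twin second), block size
// m = 5*n + 7 with n = n_delay:
//   0            stomach TG
//   1            gut lumen TG
//   2 .. n+1     chylomicron secretion-delay chain
//   n+2          plasma CM TG
//   n+3 .. 2n+2  hepatic VLDL1 apoB secretion chain
//   2n+3 .. 3n+2 hepatic VLDL2 apoB secretion chain
//   3n+3 .. 4n+2 hepatic VLDL1 TG secretion chain
//   4n+3 .. 5n+2 hepatic VLDL2 TG secretion chain
//   5n+3         plasma VLDL1 apoB
//   5n+4         plasma VLDL2 apoB
//   5n+5         plasma VLDL1 TG
//   5n+6         plasma VLDL2 TG
// The first block carries TOTAL pool masses; the second block carries the
// LABELED sub-mass of each pool (leucine label for apoB, glycerol label for
// TG; meal-path pools stay unlabeled by default). Treating the label as a
// massless sub-pool (labeled <= total, identical rate constants) makes the
// labeled subsystem exactly linear in tracer dose at a fixed total
// trajectory, the standard tracer idealization.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct Forcing {
  // monotone cubic Hermite interpolant (insulin), constant extrapolation
  std::vector<double> t, y, m;
  double eval(double x) const {
    const int n = (int)t.size();
    if (n == 0) return 0.0;
    if (x <= t.front()) return y.front();
    if (x >= t.back()) return y.back();
    int lo = (int)(std::upper_bound(t.begin(), t.end(), x) - t.begin()) - 1;
    double h = t[lo + 1] - t[lo];
    double s = (x - t[lo]) / h;
    double s2 = s * s, s3 = s2 * s;
    double h00 = 2 * s3 - 3 * s2 + 1, h10 = s3 - 2 * s2 + s;
    double h01 = -2 * s3 + 3 * s2, h11 = s3 - s2;
    return h00 * y[lo] + h10 * h * m[lo] + h01 * y[lo + 1] + h11 * h * m[lo + 1];
  }
};

struct Model {
  int n;                                   // delay sub-compartments
  double k_ge, k_ch;                       // gastric emptying, chain rate (/d)
  double P_B1, P_B2d, P_T1, P_T2d;         // production (mg/kg/d)
  double kftrB, kfdcB1, kfcrB2;            // apoB fractional rates (/d)
  double kftrT, kfdcT1, kfcrT2, kCM;       // TG fractional rates (/d)
  double f_abs, ISI, I_b;
  double w_cm, w_v2, K_lip, fc_ss;         // competition
  double meal_t0, meal_t1, meal_rate;      // days, mg/kg/d
  bool meal_on = false;                    // set per integration segment
  std::vector<double> A_leu, lam_leu, A_gly, lam_gly;  // MPE %, per day
  double scale_leu, scale_gly;
  Forcing insulin;

  int m() const { return 5 * n + 7; }

  double mpe(const std::vector<double>& A, const std::vector<double>& lam,
             double t) const {
    double s = 0.0;
    for (size_t i = 0; i < A.size(); ++i) s += A[i] * std::exp(-lam[i] * t);
    return s;
  }

  void rhs(double t, const double* y, double* dy) const {
    const int mm = m();
    const double* u = y;            // total-mass block
    const double* l = y + mm;       // labeled sub-mass block
    double* du = dy;
    double* dl = dy + mm;

    const int iCM = n + 2;
    const int b1 = n + 3, b2 = 2 * n + 3, t1 = 3 * n + 3, t2 = 4 * n + 3;
    const int pB1 = 5 * n + 3, pB2 = 5 * n + 4, pT1 = 5 * n + 5, pT2 = 5 * n + 6;

    // insulin multiplier (clamped below at 1)
    double I = insulin.eval(t);
    double phi = 1.0;
    if (I_b > 0 && I > I_b) phi = 1.0 + ISI * (I - I_b) / I_b;

    // shared-capacity competition on total TG masses, normalised to fasting
    double tgCM = std::max(0.0, u[iCM]);
    double tgV1 = std::max(0.0, u[pT1]);
    double tgV2 = std::max(0.0, u[pT2]);
    double fc_raw = K_lip / (K_lip + w_cm * tgCM + tgV1 + w_v2 * tgV2);
    double fc = (fc_ss > 0) ? fc_raw / fc_ss : 1.0;

    double lip = phi * fc;          // multiplies every LPL-mediated flux

    // labeled fraction of hepatic/no meal synthesis fluxes
    double fl_leu = scale_leu * mpe(A_leu, lam_leu, t) / 100.0;
    double fl_gly = scale_gly * mpe(A_gly, lam_gly, t) / 100.0;
    fl_leu = std::min(1.0, std::max(0.0, fl_leu));
    fl_gly = std::min(1.0, std::max(0.0, fl_gly));

    // ---- gastrointestinal (unlabeled only; meal TG carries no tracer) ----
    // segment-constant indicator: segments never straddle the boxcar edges
    double meal = meal_on ? meal_rate : 0.0;
    du[0] = meal - k_ge * u[0];
    du[1] = k_ge * u[0] - k_ch * u[1];
    dl[0] = -k_ge * l[0];
    dl[1] = k_ge * l[0] - k_ch * l[1];
    // CM secretion-delay chain; absorbed fraction enters, rest is lost
    du[2] = f_abs * k_ch * u[1] - k_ch * u[2];
    dl[2] = f_abs * k_ch * l[1] - k_ch * l[2];
    for (int i = 1; i < n; ++i) {
      du[2 + i] = k_ch * (u[1 + i] - u[2 + i]);
      dl[2 + i] = k_ch * (l[1 + i] - l[2 + i]);
    }
    du[iCM] = k_ch * u[n + 1] - kCM * lip * u[iCM];
    dl[iCM] = k_ch * l[n + 1] - kCM * lip * l[iCM];

    // ---- liver: Erlang secretion-delay chains ----
    // chain with total production P, of which the fraction fl is labeled
    auto chain = [&](int base, double P, double fl) {
      du[base] = P - k_ch * u[base];
      dl[base] = P * fl - k_ch * l[base];
      for (int i = 1; i < n; ++i) {
        du[base + i] = k_ch * (u[base + i - 1] - u[base + i]);
        dl[base + i] = k_ch * (l[base + i - 1] - l[base + i]);
      }
    };
    chain(b1, P_B1, fl_leu);
    chain(b2, P_B2d, fl_leu);
    chain(t1, P_T1, fl_gly);
    chain(t2, P_T2d, fl_gly);

    // ---- plasma ----
    // apoB: transfer is LPL-mediated; direct catabolism is not
    du[pB1] = k_ch * u[b1 + n - 1] - (kftrB * lip + kfdcB1) * u[pB1];
    dl[pB1] = k_ch * l[b1 + n - 1] - (kftrB * lip + kfdcB1) * l[pB1];
    du[pB2] = k_ch * u[b2 + n - 1] + kftrB * lip * u[pB1] - kfcrB2 * u[pB2];
    dl[pB2] = k_ch * l[b2 + n - 1] + kftrB * lip * l[pB1] - kfcrB2 * l[pB2];
    // TG: transfer and catabolism are both LPL-mediated
    du[pT1] = k_ch * u[t1 + n - 1] - (kftrT + kfdcT1) * lip * u[pT1];
    dl[pT1] = k_ch * l[t1 + n - 1] - (kftrT + kfdcT1) * lip * l[pT1];
    du[pT2] = k_ch * u[t2 + n - 1] + kftrT * lip * u[pT1] - kfcrT2 * lip * u[pT2];
    dl[pT2] = k_ch * l[t2 + n - 1] + kftrT * lip * l[pT1] - kfcrT2 * lip * l[pT2];
  }
};

static Model model_from_list(const List& pars) {
  Model md;
  md.n = as<int>(pars["n_delay"]);
  md.k_ge = as<double>(pars["k_ge_d"]);
  md.k_ch = as<double>(pars["k_chain_d"]);
  md.P_B1 = as<double>(pars["P_B1"]);
  md.P_B2d = as<double>(pars["P_B2d"]);
  md.P_T1 = as<double>(pars["P_T1"]);
  md.P_T2d = as<double>(pars["P_T2d"]);
  md.kftrB = as<double>(pars["k_FTR_B"]);
  md.kfdcB1 = as<double>(pars["k_FDC_B1"]);
  md.kfcrB2 = as<double>(pars["k_FCR_B2"]);
  md.kftrT = as<double>(pars["k_FTR_T"]);
  md.kfdcT1 = as<double>(pars["k_FDC_T1"]);
  md.kfcrT2 = as<double>(pars["k_FCR_T2"]);
  md.kCM = as<double>(pars["k_CM"]);
  md.f_abs = as<double>(pars["f_abs"]);
  md.ISI = as<double>(pars["ISI"]);
  md.I_b = as<double>(pars["I_b"]);
  md.w_cm = as<double>(pars["w_cm"]);
  md.w_v2 = as<double>(pars["w_v2"]);
  md.K_lip = as<double>(pars["K_lip"]);
  md.fc_ss = as<double>(pars["fc_ss"]);
  md.meal_t0 = as<double>(pars["meal_t0_d"]);
  md.meal_t1 = as<double>(pars["meal_t1_d"]);
  md.meal_rate = as<double>(pars["meal_rate"]);
  md.A_leu = as<std::vector<double>>(pars["A_leu"]);
  md.lam_leu = as<std::vector<double>>(pars["lam_leu_d"]);
  md.A_gly = as<std::vector<double>>(pars["A_gly"]);
  md.lam_gly = as<std::vector<double>>(pars["lam_gly_d"]);
  md.scale_leu = as<double>(pars["scale_leu"]);
  md.scale_gly = as<double>(pars["scale_gly"]);
  md.insulin.t = as<std::vector<double>>(pars["ins_t_d"]);
  md.insulin.y = as<std::vector<double>>(pars["ins_y"]);
  md.insulin.m = as<std::vector<double>>(pars["ins_m_d"]);
  return md;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1c = 35.0 / 384, b3c = 500.0 / 1113, b4c = 125.0 / 192,
                    b5c = -2187.0 / 6784, b6c = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate y through [t0, t1]; y updated in place. Returns steps taken.
static int dopri_segment(const Model& md, double t0, double t1,
                         std::vector<double>& y, double rtol, double atol,
                         double& h, int max_steps) {
  const int dim = 2 * md.m();
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim), yt(dim), ynew(dim);
  double t = t0;
  int steps = 0;
  bool have_k1 = false;
  while (t < t1 - 1e-14) {
    if (++steps > max_steps)
      stop("ODE integration exceeded %d steps in [%g, %g] days", max_steps, t0, t1);
    if (h > t1 - t) h = t1 - t;
    if (!have_k1) md.rhs(t, y.data(), k1.data());
    for (int i = 0; i < dim; ++i) yt[i] = y[i] + h * a21 * k1[i];
    md.rhs(t + c2 * h, yt.data(), k2.data());
    for (int i = 0; i < dim; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    md.rhs(t + c3 * h, yt.data(), k3.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    md.rhs(t + c4 * h, yt.data(), k4.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    md.rhs(t + c5 * h, yt.data(), k5.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    md.rhs(t + h, yt.data(), k6.data());
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h * (b1c * k1[i] + b3c * k3[i] + b4c * k4[i] +
                            b5c * k5[i] + b6c * k6[i]);
    md.rhs(t + h, ynew.data(), k7.data());

    double errnorm = 0.0;
    for (int i = 0; i < dim; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / dim);

    if (errnorm <= 1.0) {
      t += h;
      y.swap(ynew);
      k1.swap(k7);  // FSAL
      have_k1 = true;
      double fac = (errnorm > 0) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      double fac = 0.9 * std::pow(errnorm, -0.2);
      h *= std::max(0.1, fac);
      have_k1 = true;  // k1 still valid at t
    }
    if (h < 1e-12)
      stop("ODE step size underflow at t = %g days", t);
  }
  return steps;
}

//' @noRd
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(List pars, NumericVector y0, NumericVector out_times_d,
                  double rtol, double atol) {
  Model md = model_from_list(pars);
  const int dim = 2 * md.m();
  if ((int)y0.size() != dim)
    stop("state vector has length %d, expected %d", (int)y0.size(), dim);

  // breakpoints: meal boxcar edges (derivative discontinuities)
  std::vector<double> outs(out_times_d.begin(), out_times_d.end());
  std::vector<double> brk;
  if (md.meal_rate > 0) {
    brk.push_back(md.meal_t0);
    brk.push_back(md.meal_t1);
  }

  NumericMatrix out(outs.size(), dim);
  std::vector<double> y(y0.begin(), y0.end());
  double t = 0.0, h = 1e-4;
  int total_steps = 0;
  for (size_t j = 0; j < outs.size(); ++j) {
    double tj = outs[j];
    if (tj < t - 1e-12) stop("output times must be non-decreasing");
    // split at any breakpoint inside (t, tj)
    std::vector<double> seg;
    for (double b : brk) if (b > t + 1e-12 && b < tj - 1e-12) seg.push_back(b);
    seg.push_back(tj);
    std::sort(seg.begin(), seg.end());
    for (double s : seg) {
      double mid = 0.5 * (t + s);
      md.meal_on = (md.meal_rate > 0 && mid >= md.meal_t0 && mid < md.meal_t1);
      total_steps += dopri_segment(md, t, s, y, rtol, atol, h, 1000000);
      t = s;
    }
    for (int i = 0; i < dim; ++i) out(j, i) = y[i];
  }

  // negative-state audit (tolerated numerical noise only)
  double ymax = 0.0, yneg = 0.0;
  for (int j = 0; j < out.nrow(); ++j)
    for (int i = 0; i < dim; ++i) {
      ymax = std::max(ymax, out(j, i));
      yneg = std::min(yneg, out(j, i));
    }
  if (yneg < -1e-6 * std::max(1.0, ymax))
    stop("negative state beyond tolerance in trajectory (min %g)", yneg);

  return List::create(_["states"] = out, _["steps"] = total_steps);
}

//' @noRd
// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(List pars, NumericVector y, double t_d) {
  Model md = model_from_list(pars);
  const int dim = 2 * md.m();
  if ((int)y.size() != dim) stop("bad state length");
  NumericVector dy(dim);
  md.rhs(t_d, REAL(y), REAL(dy));
  return dy;
}
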