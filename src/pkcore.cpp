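// Closed-form evaluation of linear mammillary models with zero-order
// (infusion) input, cumulative urine output, observation prediction and
// log-likelihood, and the MCMC transition kernels used inside SAEM.
//
// Individual structural parameters are passed in a fixed 8-slot layout
// (natural scale): CL, V1, Q, V2, Q2, V3, CLB, PUR where
//   CL  total elimination clearance from the central compartment (L/min)
//   V1  central volume (L); Q/V2 first peripheral exchange; Q2/V3 second
//   CLB elimination clearance from compartment 2 (0 if absent)
//   PUR fraction of CL excreted in urine (1 when elimination is all renal)
// Spec flags: c(ncmt, dual, elimB) with dual/elimB in {0,1}.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093453;

struct Modes {
  int n;            // number of disposition modes (= compartments)
  double lam[3];    // eigenvalues (all < 0 for an eliminating system)
  double q[3];      // modal weights such that A1(t) = sum_m q_m * z_m(t)
  double k10, V1, pur;
  bool ok;
};

// Eigen-decomposition of the disposition matrix, exploiting the mammillary
// structure (exchange only with the central compartment).
static Modes decompose(const double* psi, int ncmt, int elimB) {
  Modes md;
  double CL = psi[0], V1 = psi[1], Q = psi[2], V2 = psi[3];
  double Q2 = psi[4], V3 = psi[5], CLB = psi[6], pur = psi[7];
  md.ok = false;
  md.V1 = V1; md.pur = pur;
  if (!(CL > 0.0 && V1 > 0.0) || !R_finite(CL) || !R_finite(V1)) return md;
  md.k10 = CL / V1;
  if (ncmt == 1) {
    md.n = 1; md.lam[0] = -md.k10; md.q[0] = 1.0; md.ok = true;
    return md;
  }
  if (!(Q > 0.0 && V2 > 0.0)) return md;
  double k12 = Q / V1, k21 = Q / V2;
  double k20 = (elimB ? CLB / V2 : 0.0);
  if (elimB && !(CLB > 0.0)) return md;
  if (ncmt == 2) {
    double a = -(md.k10 + k12), b = k21, c = k12, d = -(k21 + k20);
    double tr = a + d, det = a * d - b * c;
    double disc = tr * tr - 4.0 * det;
    if (disc < 0.0) disc = 0.0;
    double sq = std::sqrt(disc);
    double l1 = 0.5 * (tr + sq), l2 = 0.5 * (tr - sq);
    // eigenvector for l (first component 1): v2 = (l - a)/b
    double v1m = (l1 - a) / b, v2m = (l2 - a) / b;
    double den = v2m - v1m;
    if (std::fabs(den) < 1e-14) return md;
    md.n = 2;
    md.lam[0] = l1; md.lam[1] = l2;
    md.q[0] = v2m / den; md.q[1] = -v1m / den;
    md.ok = true;
    return md;
  }
  // three compartments (second periphery Q2/V3)
  if (!(Q2 > 0.0 && V3 > 0.0)) return md;
  double k13 = Q2 / V1, k31 = Q2 / V3;
  double a11 = -(md.k10 + k12 + k13), a22 = -(k21 + k20), a33 = -k31;
  double c2 = -(a11 + a22 + a33);
  double c1 = a11 * a22 + a11 * a33 + a22 * a33 - k21 * k12 - k31 * k13;
  double c0 = -(a11 * a22 * a33 - k21 * k12 * a33 - k31 * k13 * a22);
  // depressed cubic, roots are real for this class of matrices
  double p = c1 - c2 * c2 / 3.0;
  double qc = 2.0 * c2 * c2 * c2 / 27.0 - c2 * c1 / 3.0 + c0;
  if (!(p < -1e-300)) return md;
  double mamp = 2.0 * std::sqrt(-p / 3.0);
  double arg = 3.0 * qc / (p * mamp);
  if (arg > 1.0) arg = 1.0;
  if (arg < -1.0) arg = -1.0;
  double th = std::acos(arg) / 3.0;
  double l[3];
  for (int i = 0; i < 3; ++i)
    l[i] = mamp * std::cos(th - 2.0 * M_PI * i / 3.0) - c2 / 3.0;
  double P[3][3];
  for (int i = 0; i < 3; ++i) {
    double d2 = l[i] - a22, d3 = l[i] - a33;
    if (std::fabs(d2) < 1e-12 || std::fabs(d3) < 1e-12) return md;
    P[0][i] = 1.0;
    P[1][i] = k12 / d2;
    P[2][i] = k13 / d3;
  }
  // solve P q = e1 (Cramer)
  double det3 =
    P[0][0] * (P[1][1] * P[2][2] - P[1][2] * P[2][1]) -
    P[0][1] * (P[1][0] * P[2][2] - P[1][2] * P[2][0]) +
    P[0][2] * (P[1][0] * P[2][1] - P[1][1] * P[2][0]);
  if (std::fabs(det3) < 1e-300) return md;
  double q0 = (P[1][1] * P[2][2] - P[1][2] * P[2][1]) / det3;
  double q1 = -(P[1][0] * P[2][2] - P[1][2] * P[2][0]) / det3;
  double q2 = (P[1][0] * P[2][1] - P[1][1] * P[2][0]) / det3;
  md.n = 3;
  md.lam[0] = l[0]; md.lam[1] = l[1]; md.lam[2] = l[2];
  md.q[0] = q0; md.q[1] = q1; md.q[2] = q2;
  md.ok = true;
  return md;
}

// Central amount A1(t) and running integral of A1 at time t by superposition
// over zero-order inputs.
static void eval_point(const Modes& md, int nd, const double* dtime,
                       const double* damt, const double* dtinf,
                       double t, double* A1out, double* Iout) {
  double A1 = 0.0, I = 0.0;
  for (int d = 0; d < nd; ++d) {
    double a = dtime[d];
    if (t <= a) continue;
    double T = dtinf[d] > 0.0 ? dtinf[d] : 1e-6;
    double R = damt[d] / T;
    double b = a + T;
    for (int m = 0; m < md.n; ++m) {
      double lam = md.lam[m], qm = md.q[m];
      double z, Z;
      if (std::fabs(lam) < 1e-12) { // not expected for eliminating systems
        double tau = std::min(t, b) - a;
        z = R * qm * tau;
        Z = 0.5 * R * qm * tau * tau;
        if (t > b) Z += z * (t - b);
      } else if (t < b) {
        double e = std::exp(lam * (t - a));
        z = R * qm * (e - 1.0) / lam;
        Z = R * qm * ((e - 1.0) / (lam * lam) - (t - a) / lam);
      } else {
        double eb = std::exp(lam * (b - a));
        double zb = R * qm * (eb - 1.0) / lam;
        double Zb = R * qm * ((eb - 1.0) / (lam * lam) - (b - a) / lam);
        double et = std::exp(lam * (t - b));
        z = zb * et;
        Z = Zb + zb * (et - 1.0) / lam;
      }
      A1 += z;
      I += Z;
    }
  }
  *A1out = A1;
  if (Iout) *Iout = I;
}

struct DataView {
  int ns, nobs;
  const int *osub, *otype;
  const double *otime, *oy, *oustart, *ouvol;
  const int *dsub;
  const double *dtime, *damt, *dtinf;
  const int *ooff, *doff; // CSR offsets, length ns+1
};

static DataView make_view(const List& dat) {
  DataView v;
  v.ns = as<int>(dat["ns"]);
  IntegerVector osub = dat["obs_subj"], otype = dat["obs_type"];
  NumericVector otime = dat["obs_time"], oy = dat["obs_y"];
  NumericVector oustart = dat["obs_ustart"], ouvol = dat["obs_uvol"];
  IntegerVector dsub = dat["dose_subj"];
  NumericVector dtime = dat["dose_time"], damt = dat["dose_amt"],
    dtinf = dat["dose_tinf"];
  IntegerVector ooff = dat["obs_off"], doff = dat["dose_off"];
  v.nobs = otime.size();
  v.osub = INTEGER(osub); v.otype = INTEGER(otype);
  v.otime = REAL(otime); v.oy = REAL(oy);
  v.oustart = REAL(oustart); v.ouvol = REAL(ouvol);
  v.dsub = INTEGER(dsub);
  v.dtime = REAL(dtime); v.damt = REAL(damt); v.dtinf = REAL(dtinf);
  v.ooff = INTEGER(ooff); v.doff = INTEGER(doff);
  return v;
}

// Predictions for all observations of subject i; fills pred[ooff[i]..).
static bool subject_pred(const double* psi, int ncmt, int elimB,
                         const DataView& v, int i, double* pred) {
  Modes md = decompose(psi, ncmt, elimB);
  if (!md.ok) return false;
  int nd = v.doff[i + 1] - v.doff[i];
  const double* dt = v.dtime + v.doff[i];
  const double* da = v.damt + v.doff[i];
  const double* di = v.dtinf + v.doff[i];
  for (int j = v.ooff[i]; j < v.ooff[i + 1]; ++j) {
    double A1, I;
    if (v.otype[j] == 0) {
      eval_point(md, nd, dt, da, di, v.otime[j], &A1, 0);
      pred[j] = A1 / md.V1;
    } else {
      double I0 = 0.0;
      if (v.oustart[j] > 0.0) {
        eval_point(md, nd, dt, da, di, v.oustart[j], &A1, &I0);
      }
      eval_point(md, nd, dt, da, di, v.otime[j], &A1, &I);
      double amt = md.pur * md.k10 * (I - I0);
      pred[j] = amt / v.ouvol[j];
    }
    if (!R_finite(pred[j])) return false;
  }
  return true;
}

// Gaussian (or log-normal for the exponential model) log-density of one
// observation. Error types: 0 additive, 1 proportional, 2 combined,
// 3 exponential. errpar = (a1, b1, a2, b2); plasma uses (a1, b1), urine
// (a2, b2).
static double obs_ll(double y, double f, int type, const double* errpar,
                     const int* errtype) {
  double a = type == 0 ? errpar[0] : errpar[2];
  double b = type == 0 ? errpar[1] : errpar[3];
  int et = errtype[type];
  if (et == 3) {
    if (f <= 0.0 || y <= 0.0) return R_NegInf;
    double r = std::log(y) - std::log(f);
    double s2 = b * b;
    if (s2 < 1e-12) s2 = 1e-12;
    return -0.5 * (LOG2PI + std::log(s2) + r * r / s2) - std::log(y);
  }
  double s2;
  if (et == 0) s2 = a * a;
  else if (et == 1) s2 = b * b * f * f;
  else s2 = a * a + b * b * f * f;
  if (s2 < 1e-12) s2 = 1e-12;
  double r = y - f;
  return -0.5 * (LOG2PI + std::log(s2) + r * r / s2);
}

static double subject_ll(const double* psi, int ncmt, int elimB,
                         const DataView& v, int i, const double* errpar,
                         const int* errtype, double* work) {
  if (!subject_pred(psi, ncmt, elimB, v, i, work)) return R_NegInf;
  double ll = 0.0;
  for (int j = v.ooff[i]; j < v.ooff[i + 1]; ++j) {
    ll += obs_ll(v.oy[j], work[j], v.otype[j], errpar, errtype);
    if (!R_finite(ll)) return R_NegInf;
  }
  return ll;
}

// ---- exported interfaces ----------------------------------------------

// [[Rcpp::export]]
List cpp_profile(NumericVector psi8, IntegerVector specflags,
                 NumericMatrix doses, NumericVector times) {
  Modes md = decompose(REAL(psi8), specflags[0], specflags[2]);
  if (!md.ok) stop("invalid structural parameters for closed-form evaluation");
  int nd = doses.nrow(), nt = times.size();
  std::vector<double> dt(nd), da(nd), di(nd);
  for (int d = 0; d < nd; ++d) {
    dt[d] = doses(d, 0); da[d] = doses(d, 1); di[d] = doses(d, 2);
  }
  NumericVector conc(nt), ucum(nt);
  for (int j = 0; j < nt; ++j) {
    double A1, I;
    eval_point(md, nd, dt.data(), da.data(), di.data(), times[j], &A1, &I);
    conc[j] = A1 / md.V1;
    ucum[j] = md.pur * md.k10 * I;
  }
  return List::create(_["conc"] = conc, _["ucum"] = ucum);
}

// Profiles for many subjects sharing a dose schedule and time grid.
// [[Rcpp::export]]
NumericMatrix cpp_profile_many(NumericMatrix psi, IntegerVector specflags,
                               NumericMatrix doses, NumericVector times) {
  int ns = psi.nrow(), nt = times.size(), nd = doses.nrow();
  std::vector<double> dt(nd), da(nd), di(nd);
  for (int d = 0; d < nd; ++d) {
    dt[d] = doses(d, 0); da[d] = doses(d, 1); di[d] = doses(d, 2);
  }
  NumericMatrix out(ns, nt);
  std::vector<double> row(8);
  for (int i = 0; i < ns; ++i) {
    for (int k = 0; k < 8; ++k) row[k] = psi(i, k);
    Modes md = decompose(row.data(), specflags[0], specflags[2]);
    if (!md.ok) stop("invalid structural parameters (subject %d)", i + 1);
    for (int j = 0; j < nt; ++j) {
      double A1, I;
      eval_point(md, nd, dt.data(), da.data(), di.data(), times[j], &A1, &I);
      out(i, j) = A1 / md.V1;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_pred(NumericMatrix psi, List dat, IntegerVector specflags) {
  DataView v = make_view(dat);
  NumericVector pred(v.nobs, NA_REAL);
  std::vector<double> row(8);
  for (int i = 0; i < v.ns; ++i) {
    for (int k = 0; k < 8; ++k) row[k] = psi(i, k);
    if (!subject_pred(row.data(), specflags[0], specflags[2], v, i,
                      REAL(pred)))
      stop("prediction failed for subject %d (invalid parameters)", i + 1);
  }
  return pred;
}

// [[Rcpp::export]]
NumericVector cpp_ll(NumericMatrix psi, List dat, IntegerVector specflags,
                     NumericVector errpar, IntegerVector errtype) {
  DataView v = make_view(dat);
  NumericVector ll(v.ns);
  std::vector<double> row(8), work(v.nobs);
  for (int i = 0; i < v.ns; ++i) {
    for (int k = 0; k < 8; ++k) row[k] = psi(i, k);
    ll[i] = subject_ll(row.data(), specflags[0], specflags[2], v, i,
                       REAL(errpar), INTEGER(errtype), work.data());
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_ll_subject(NumericVector psi8, List dat, IntegerVector specflags,
                      int i, NumericVector errpar, IntegerVector errtype) {
  DataView v = make_view(dat);
  std::vector<double> work(v.nobs);
  return subject_ll(REAL(psi8), specflags[0], specflags[2], v, i - 1,
                    REAL(errpar), INTEGER(errtype), work.data());
}

// Log-likelihood of one subject's data under many parameter draws
// (rows of psi are 8-slot parameter vectors). Used by the importance-
// sampling marginal likelihood.
// [[Rcpp::export]]
NumericVector cpp_ll_draws(NumericMatrix psi, List dat,
                           IntegerVector specflags, int i,
                           NumericVector errpar, IntegerVector errtype) {
  DataView v = make_view(dat);
  int S = psi.nrow();
  NumericVector ll(S);
  std::vector<double> row(8), work(v.nobs);
  for (int s = 0; s < S; ++s) {
    for (int k = 0; k < 8; ++k) row[k] = psi(s, k);
    ll[s] = subject_ll(row.data(), specflags[0], specflags[2], v, i - 1,
                       REAL(errpar), INTEGER(errtype), work.data());
  }
  return ll;
}

// Build an 8-slot psi row from phi (= m + eta) using the slot map and
// transform codes (0 log, 1 logit).
static inline void phi_to_psi(const double* base, const double* m,
                              const double* eta, int npar, const int* slot,
                              const int* trans, int ns, int i, double* psi) {
  for (int k = 0; k < 8; ++k) psi[k] = base[k];
  for (int p = 0; p < npar; ++p) {
    double phi = m[i + ns * p] + eta[i + ns * p];
    psi[slot[p]] = trans[p] == 1 ? 1.0 / (1.0 + std::exp(-phi))
                                 : std::exp(phi);
  }
}

// One SAEM iteration of the MCMC conditional sampler for all chains:
// per transition, an independence kernel (proposal = the conditional prior)
// followed by a componentwise random-walk kernel on each random effect.
// Returns the updated etas, final predictions and per-subject log-likelihood
// per chain, and acceptance counts (row 0 = independence kernel, row p =
// random walk on component p).
// [[Rcpp::export]]
List cpp_saem_step(List etas, NumericMatrix m, NumericVector omega,
                   IntegerVector trans, IntegerVector slot,
                   NumericVector base_psi, IntegerVector specflags,
                   List dat, NumericVector errpar, IntegerVector errtype,
                   NumericVector rwsd, int ntrans) {
  DataView v = make_view(dat);
  int ns = v.ns, npar = omega.size(), nchain = etas.size();
  int ncmt = specflags[0], elimB = specflags[2];
  const double* mp = REAL(m);
  const double* ep = REAL(errpar);
  const int* etp = INTEGER(errtype);
  const int* slp = INTEGER(slot);
  const int* trp = INTEGER(trans);
  const double* bp = REAL(base_psi);

  NumericMatrix predout(v.nobs, nchain), llout(ns, nchain);
  int prop_indep = 0, acc_indep = 0;
  IntegerVector acc_p(npar), prop_p(npar);

  std::vector<double> work(v.nobs), psi(8), psin(8);
  List etas_new(nchain);

  for (int c = 0; c < nchain; ++c) {
    NumericMatrix etac = clone(as<NumericMatrix>(etas[c]));
    double* e = REAL(etac);
    // current log-likelihoods
    std::vector<double> llc(ns);
    for (int i = 0; i < ns; ++i) {
      phi_to_psi(bp, mp, e, npar, slp, trp, ns, i, psi.data());
      llc[i] = subject_ll(psi.data(), ncmt, elimB, v, i, ep, etp, work.data());
    }
    for (int t = 0; t < ntrans; ++t) {
      // independence kernel: eta* ~ N(0, diag(omega^2)); prior terms cancel
      for (int i = 0; i < ns; ++i) {
        for (int p = 0; p < npar; ++p)
          psin[p] = omega[p] > 0.0 ? R::rnorm(0.0, omega[p]) : 0.0;
        // psin[0..npar) used as eta proposal scratch
        for (int k = 0; k < 8; ++k) psi[k] = bp[k];
        for (int p = 0; p < npar; ++p) {
          double phi = mp[i + ns * p] + psin[p];
          psi[slp[p]] = trp[p] == 1 ? 1.0 / (1.0 + std::exp(-phi))
                                    : std::exp(phi);
        }
        double lln = subject_ll(psi.data(), ncmt, elimB, v, i, ep, etp,
                                work.data());
        ++prop_indep;
        if (R_finite(lln) &&
            std::log(R::runif(0.0, 1.0)) < lln - llc[i]) {
          for (int p = 0; p < npar; ++p) e[i + ns * p] = psin[p];
          llc[i] = lln;
          ++acc_indep;
        }
      }
      // componentwise random walk
      for (int p = 0; p < npar; ++p) {
        if (!(omega[p] > 0.0)) continue;
        double sd = rwsd[p] * omega[p];
        double o2 = omega[p] * omega[p];
        for (int i = 0; i < ns; ++i) {
          double cur = e[i + ns * p];
          double prop = cur + R::rnorm(0.0, sd);
          e[i + ns * p] = prop;
          phi_to_psi(bp, mp, e, npar, slp, trp, ns, i, psi.data());
          double lln = subject_ll(psi.data(), ncmt, elimB, v, i, ep, etp,
                                  work.data());
          double lr = lln - llc[i] -
            0.5 * (prop * prop - cur * cur) / o2;
          ++prop_p[p];
          if (R_finite(lln) && std::log(R::runif(0.0, 1.0)) < lr) {
            llc[i] = lln;
            ++acc_p[p];
          } else {
            e[i + ns * p] = cur;
          }
        }
      }
    }
    // final predictions for this chain
    for (int i = 0; i < ns; ++i) {
      phi_to_psi(bp, mp, e, npar, slp, trp, ns, i, psi.data());
      subject_pred(psi.data(), ncmt, elimB, v, i, &predout(0, c));
      llout(i, c) = llc[i];
    }
    etas_new[c] = etac;
  }
  return List::create(
    _["etas"] = etas_new,
    _["pred"] = predout,
    _["ll"] = llout,
    _["acc_indep"] = (double)acc_indep / std::max(prop_indep, 1),
    _["acc_rw"] = NumericVector(
        acc_p.begin(), acc_p.end()),
    _["prop_rw"] = NumericVector(
        prop_p.begin(), prop_p.end()));
}
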