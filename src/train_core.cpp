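// Hybrid neural-ODE core: the closed-loop haemodynamic right-hand side with
// the ventricular-interaction terms (V_spt, P_peri) supplied by a small
// fully connected network, a fixed-step RK4 integrator, and a hand-written
// discrete adjoint (backpropagation through the integrator steps) for the
// pooled mean-squared-error training loss.
//
// Gradients are discretize-then-optimize: the loss of the RK4-discretized
// trajectory is differentiated exactly (up to the valve-law and flow-clamp
// subgradients, which are zero on the closed branch).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// parameter vector indices; order matches the canonical R-side parameter set
enum {
  iR_mt, iR_av, iR_tc, iR_pv, iR_sys, iR_pul,
  iL_mt, iL_av, iL_tc, iL_pv,
  iE_lvf, iE_rvf, iE_spt, iE_ao, iE_vc, iE_pa, iE_pu,
  iP0_lvf, iP0_rvf, iP0_spt, iP0_pcd,
  ilam_lvf, ilam_rvf, ilam_spt, ilam_pcd,
  iV0_lvf, iV0_rvf, iV0_spt, iV0_pcd,
  iVd_lvf, iVd_rvf, iVd_spt, iVd_ao, iVd_vc, iVd_pa, iVd_pu,
  iP_th, iA_drv, iB_drv, iC_drv, iperiod, NPAR
};

// network shape: 5 -> 10 -> 10 -> 10 -> 2, ELU hidden activations
static const int NIN = 5, NH = 10, NOUT = 2;
static const int NTHETA = NIN * NH + NH + NH * NH + NH + NH * NH + NH +
                          NH * NOUT + NOUT;  // 302
// flat layout (column-major weight matrices, R convention):
// W1[NH x NIN], b1, W2[NH x NH], b2, W3[NH x NH], b3, W4[NOUT x NH], b4
static const int oW1 = 0, ob1 = oW1 + NH * NIN, oW2 = ob1 + NH,
                 ob2 = oW2 + NH * NH, oW3 = ob2 + NH, ob3 = oW3 + NH * NH,
                 oW4 = ob3 + NH, ob4 = oW4 + NOUT * NH;

static inline double elu(double x) { return x > 0 ? x : expm1(x); }
static inline double elu_d(double x) { return x > 0 ? 1.0 : exp(x); }

struct NetWork {
  double z[NIN];
  double h1p[NH], h1[NH], h2p[NH], h2[NH], h3p[NH], h3[NH];
  double o[NOUT];
};

// forward pass; x = (V_lv, V_rv, V_ao, V_vc, V_pa)
static void nn_forward(const double* th, const double* mu, const double* sd,
                       const double* x, NetWork& w) {
  for (int j = 0; j < NIN; ++j) w.z[j] = (x[j] - mu[j]) / sd[j];
  for (int i = 0; i < NH; ++i) {
    double s = th[ob1 + i];
    for (int j = 0; j < NIN; ++j) s += th[oW1 + j * NH + i] * w.z[j];
    w.h1p[i] = s; w.h1[i] = elu(s);
  }
  for (int i = 0; i < NH; ++i) {
    double s = th[ob2 + i];
    for (int j = 0; j < NH; ++j) s += th[oW2 + j * NH + i] * w.h1[j];
    w.h2p[i] = s; w.h2[i] = elu(s);
  }
  for (int i = 0; i < NH; ++i) {
    double s = th[ob3 + i];
    for (int j = 0; j < NH; ++j) s += th[oW3 + j * NH + i] * w.h2[j];
    w.h3p[i] = s; w.h3[i] = elu(s);
  }
  for (int i = 0; i < NOUT; ++i) {
    double s = th[ob4 + i];
    for (int j = 0; j < NH; ++j) s += th[oW4 + j * NOUT + i] * w.h3[j];
    w.o[i] = s;
  }
}

// reverse pass: given bar_o, accumulate d/dtheta into gth and d/dx into gx
static void nn_backward(const double* th, const double* mu, const double* sd,
                        const NetWork& w, const double* bar_o,
                        double* gth, double* gx) {
  double b3[NH], b2[NH], b1[NH];
  for (int i = 0; i < NOUT; ++i) gth[ob4 + i] += bar_o[i];
  for (int j = 0; j < NH; ++j) {
    double s = 0;
    for (int i = 0; i < NOUT; ++i) {
      gth[oW4 + j * NOUT + i] += bar_o[i] * w.h3[j];
      s += th[oW4 + j * NOUT + i] * bar_o[i];
    }
    b3[j] = s * elu_d(w.h3p[j]);
  }
  for (int i = 0; i < NH; ++i) gth[ob3 + i] += b3[i];
  for (int j = 0; j < NH; ++j) {
    double s = 0;
    for (int i = 0; i < NH; ++i) {
      gth[oW3 + j * NH + i] += b3[i] * w.h2[j];
      s += th[oW3 + j * NH + i] * b3[i];
    }
    b2[j] = s * elu_d(w.h2p[j]);
  }
  for (int i = 0; i < NH; ++i) gth[ob2 + i] += b2[i];
  for (int j = 0; j < NH; ++j) {
    double s = 0;
    for (int i = 0; i < NH; ++i) {
      gth[oW2 + j * NH + i] += b2[i] * w.h1[j];
      s += th[oW2 + j * NH + i] * b2[i];
    }
    b1[j] = s * elu_d(w.h1p[j]);
  }
  for (int i = 0; i < NH; ++i) gth[ob1 + i] += b1[i];
  for (int j = 0; j < NIN; ++j) {
    double s = 0;
    for (int i = 0; i < NH; ++i) {
      gth[oW1 + j * NH + i] += b1[i] * w.z[j];
      s += th[oW1 + j * NH + i] * b1[i];
    }
    gx[j] += s / sd[j];
  }
}

static inline double driver(double t, const double* p) {
  double tau = t - p[iperiod] * std::floor(t / p[iperiod]);
  double d = tau - p[iC_drv];
  return p[iA_drv] * exp(-p[iB_drv] * d * d);
}

// hybrid RHS. Returns false if non-finite.
static bool rhs(const double* u, double t, const double* th, const double* mu,
                const double* sd, const double* p, double* du) {
  double e = driver(t, p), ce = 1.0 - e;
  double x[NIN] = { u[4], u[5], u[6], u[7], u[8] };
  NetWork w;
  nn_forward(th, mu, sd, x, w);
  double Vspt = w.o[0], Pperi = w.o[1];
  double Vlvf = u[4] - Vspt, Vrvf = u[5] + Vspt;
  double elv = exp(p[ilam_lvf] * (Vlvf - p[iV0_lvf]));
  double erv = exp(p[ilam_rvf] * (Vrvf - p[iV0_rvf]));
  double Plvf = e * p[iE_lvf] * (Vlvf - p[iVd_lvf]) + ce * p[iP0_lvf] * (elv - 1);
  double Prvf = e * p[iE_rvf] * (Vrvf - p[iVd_rvf]) + ce * p[iP0_rvf] * (erv - 1);
  double Plv = Plvf + Pperi, Prv = Prvf + Pperi;
  double Pao = p[iE_ao] * (u[6] - p[iVd_ao]);
  double Pvc = p[iE_vc] * (u[7] - p[iVd_vc]);
  double Ppa = p[iE_pa] * (u[8] - p[iVd_pa]) + p[iP_th];
  double Ppu = p[iE_pu] * (u[9] - p[iVd_pu]) + p[iP_th];
  double Qsys = (Pao - Pvc) / p[iR_sys];
  double Qpul = (Ppa - Ppu) / p[iR_pul];
  du[0] = (u[0] > 0 || Ppu - Plv > 0) ? (Ppu - Plv - p[iR_mt] * u[0]) / p[iL_mt] : 0;
  du[1] = (u[1] > 0 || Plv - Pao > 0) ? (Plv - Pao - p[iR_av] * u[1]) / p[iL_av] : 0;
  du[2] = (u[2] > 0 || Pvc - Prv > 0) ? (Pvc - Prv - p[iR_tc] * u[2]) / p[iL_tc] : 0;
  du[3] = (u[3] > 0 || Prv - Ppa > 0) ? (Prv - Ppa - p[iR_pv] * u[3]) / p[iL_pv] : 0;
  double qmt = u[0] > 0 ? u[0] : 0, qav = u[1] > 0 ? u[1] : 0;
  double qtc = u[2] > 0 ? u[2] : 0, qpv = u[3] > 0 ? u[3] : 0;
  du[4] = qmt - qav;
  du[5] = qtc - qpv;
  du[6] = qav - Qsys;
  du[7] = Qsys - qtc;
  du[8] = qpv - Qpul;
  du[9] = Qpul - qmt;
  for (int i = 0; i < 10; ++i) if (!std::isfinite(du[i])) return false;
  return true;
}

// VJP of the hybrid RHS: given adjoint w10 = dL/d(du), accumulate
// dL/du into gu and dL/dtheta into gth. Recomputes the forward pass.
static void rhs_vjp(const double* u, double t, const double* th,
                    const double* mu, const double* sd, const double* p,
                    const double* w10, double* gu, double* gth) {
  double e = driver(t, p), ce = 1.0 - e;
  double x[NIN] = { u[4], u[5], u[6], u[7], u[8] };
  NetWork w;
  nn_forward(th, mu, sd, x, w);
  double Vspt = w.o[0], Pperi = w.o[1];
  double Vlvf = u[4] - Vspt, Vrvf = u[5] + Vspt;
  double elv = exp(p[ilam_lvf] * (Vlvf - p[iV0_lvf]));
  double erv = exp(p[ilam_rvf] * (Vrvf - p[iV0_rvf]));
  double Plvf = e * p[iE_lvf] * (Vlvf - p[iVd_lvf]) + ce * p[iP0_lvf] * (elv - 1);
  double Prvf = e * p[iE_rvf] * (Vrvf - p[iVd_rvf]) + ce * p[iP0_rvf] * (erv - 1);
  double Plv = Plvf + Pperi, Prv = Prvf + Pperi;
  double Pao = p[iE_ao] * (u[6] - p[iVd_ao]);
  double Pvc = p[iE_vc] * (u[7] - p[iVd_vc]);
  double Ppa = p[iE_pa] * (u[8] - p[iVd_pa]) + p[iP_th];
  double Ppu = p[iE_pu] * (u[9] - p[iVd_pu]) + p[iP_th];
  bool o_mt = (u[0] > 0 || Ppu - Plv > 0);
  bool o_av = (u[1] > 0 || Plv - Pao > 0);
  bool o_tc = (u[2] > 0 || Pvc - Prv > 0);
  bool o_pv = (u[3] > 0 || Prv - Ppa > 0);

  // volume bookkeeping rows
  double bqmt = w10[4] - w10[9], bqav = w10[6] - w10[4];
  double bqtc = w10[5] - w10[7], bqpv = w10[8] - w10[5];
  double bQsys = w10[7] - w10[6], bQpul = w10[9] - w10[8];
  if (u[0] > 0) gu[0] += bqmt;
  if (u[1] > 0) gu[1] += bqav;
  if (u[2] > 0) gu[2] += bqtc;
  if (u[3] > 0) gu[3] += bqpv;

  // valve rows
  double bPlv = 0, bPrv = 0, bPao = 0, bPvc = 0, bPpa = 0, bPpu = 0;
  if (o_mt) {
    double c = w10[0] / p[iL_mt];
    bPpu += c; bPlv -= c; gu[0] += -p[iR_mt] * c;
  }
  if (o_av) {
    double c = w10[1] / p[iL_av];
    bPlv += c; bPao -= c; gu[1] += -p[iR_av] * c;
  }
  if (o_tc) {
    double c = w10[2] / p[iL_tc];
    bPvc += c; bPrv -= c; gu[2] += -p[iR_tc] * c;
  }
  if (o_pv) {
    double c = w10[3] / p[iL_pv];
    bPrv += c; bPpa -= c; gu[3] += -p[iR_pv] * c;
  }

  // circulation flows
  bPao += bQsys / p[iR_sys];
  bPvc -= bQsys / p[iR_sys];
  bPpa += bQpul / p[iR_pul];
  bPpu -= bQpul / p[iR_pul];

  // passive chambers
  gu[6] += p[iE_ao] * bPao;
  gu[7] += p[iE_vc] * bPvc;
  gu[8] += p[iE_pa] * bPpa;
  gu[9] += p[iE_pu] * bPpu;

  // ventricular free walls + pericardium
  double bPlvf = bPlv, bPrvf = bPrv;
  double bPperi = bPlv + bPrv;
  double dPlvf = e * p[iE_lvf] + ce * p[iP0_lvf] * p[ilam_lvf] * elv;
  double dPrvf = e * p[iE_rvf] + ce * p[iP0_rvf] * p[ilam_rvf] * erv;
  double bVlvf = dPlvf * bPlvf, bVrvf = dPrvf * bPrvf;
  gu[4] += bVlvf;
  gu[5] += bVrvf;
  double bVspt = bVrvf - bVlvf;

  // network
  double bar_o[2] = { bVspt, bPperi };
  double gx[NIN] = { 0, 0, 0, 0, 0 };
  nn_backward(th, mu, sd, w, bar_o, gth, gx);
  gu[4] += gx[0]; gu[5] += gx[1]; gu[6] += gx[2]; gu[7] += gx[3];
  gu[8] += gx[4];
  (void)Plvf; (void)Prvf;
}

// one RK4 substep; clamps negative valve flows after the update.
// Returns false on non-finite / exploding state.
static bool rk4_step(double* u, double t, double h, const double* th,
                     const double* mu, const double* sd, const double* p,
                     bool* clamped) {
  double k1[10], k2[10], k3[10], k4[10], us[10];
  if (!rhs(u, t, th, mu, sd, p, k1)) return false;
  for (int i = 0; i < 10; ++i) us[i] = u[i] + 0.5 * h * k1[i];
  if (!rhs(us, t + 0.5 * h, th, mu, sd, p, k2)) return false;
  for (int i = 0; i < 10; ++i) us[i] = u[i] + 0.5 * h * k2[i];
  if (!rhs(us, t + 0.5 * h, th, mu, sd, p, k3)) return false;
  for (int i = 0; i < 10; ++i) us[i] = u[i] + h * k3[i];
  if (!rhs(us, t + h, th, mu, sd, p, k4)) return false;
  for (int i = 0; i < 10; ++i)
    u[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  for (int i = 0; i < 4; ++i) {
    clamped[i] = (u[i] < 0);
    if (clamped[i]) u[i] = 0;
  }
  for (int i = 0; i < 10; ++i)
    if (!std::isfinite(u[i]) || std::fabs(u[i]) > 1e8) return false;
  return true;
}

// adjoint of one RK4 substep: in/out adjoint a (dL/d u_new -> dL/d u_old),
// accumulating dL/dtheta. u is the state at the *start* of the substep.
static void rk4_step_vjp(const double* u, double t, double h, const double* th,
                         const double* mu, const double* sd, const double* p,
                         const bool* clamped, double* a, double* gth) {
  double k1[10], k2[10], k3[10], u2[10], u3[10], u4[10];
  rhs(u, t, th, mu, sd, p, k1);
  for (int i = 0; i < 10; ++i) u2[i] = u[i] + 0.5 * h * k1[i];
  rhs(u2, t + 0.5 * h, th, mu, sd, p, k2);
  for (int i = 0; i < 10; ++i) u3[i] = u[i] + 0.5 * h * k2[i];
  rhs(u3, t + 0.5 * h, th, mu, sd, p, k3);
  for (int i = 0; i < 10; ++i) u4[i] = u[i] + h * k3[i];

  // clamped components: d(u_clamped)/d(u_pre) = 0
  for (int i = 0; i < 4; ++i) if (clamped[i]) a[i] = 0;

  double g4[10], g3[10], g2[10], g1[10];
  double v4[10] = {0}, v3[10] = {0}, v2[10] = {0}, v1[10] = {0};
  for (int i = 0; i < 10; ++i) g4[i] = h / 6.0 * a[i];
  rhs_vjp(u4, t + h, th, mu, sd, p, g4, v4, gth);
  for (int i = 0; i < 10; ++i) g3[i] = h / 3.0 * a[i] + h * v4[i];
  rhs_vjp(u3, t + 0.5 * h, th, mu, sd, p, g3, v3, gth);
  for (int i = 0; i < 10; ++i) g2[i] = h / 3.0 * a[i] + 0.5 * h * v3[i];
  rhs_vjp(u2, t + 0.5 * h, th, mu, sd, p, g2, v2, gth);
  for (int i = 0; i < 10; ++i) g1[i] = h / 6.0 * a[i] + 0.5 * h * v2[i];
  rhs_vjp(u, t, th, mu, sd, p, g1, v1, gth);
  for (int i = 0; i < 10; ++i) a[i] += v1[i] + v2[i] + v3[i] + v4[i];
}

//' @noRd
// [[Rcpp::export(name = ".hode_forward_cpp")]]
List hode_forward_cpp(NumericVector theta, NumericVector mu, NumericVector sd,
                      NumericVector u0, NumericVector pvec, double t0,
                      double dt, int nsub, int nsamp) {
  if (theta.size() != NTHETA) stop("theta must have length %d", NTHETA);
  if (pvec.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  NumericMatrix out(nsamp + 1, 10);
  double u[10];
  for (int i = 0; i < 10; ++i) { u[i] = u0[i]; out(0, i) = u[i]; }
  double h = dt / nsub;
  bool cl[4];
  for (int k = 0; k < nsamp; ++k) {
    for (int s = 0; s < nsub; ++s) {
      double t = t0 + k * dt + s * h;
      if (!rk4_step(u, t, h, theta.begin(), mu.begin(), sd.begin(),
                    pvec.begin(), cl)) {
        return List::create(_["states"] = out, _["ok"] = false,
                            _["fail_time"] = t);
      }
    }
    for (int i = 0; i < 10; ++i) out(k + 1, i) = u[i];
  }
  return List::create(_["states"] = out, _["ok"] = true,
                      _["fail_time"] = NA_REAL);
}

//' @noRd
// [[Rcpp::export(name = ".hode_loss_grad_cpp")]]
List hode_loss_grad_cpp(NumericVector theta, NumericVector mu,
                        NumericVector sd, NumericVector u0,
                        NumericMatrix data, NumericVector pvec, double t0,
                        double dt, int nsub, bool want_grad = true) {
  if (theta.size() != NTHETA) stop("theta must have length %d", NTHETA);
  if (pvec.size() != NPAR) stop("parameter vector must have length %d", NPAR);
  if (data.ncol() != 10) stop("data must have 10 columns");
  int nsamp = data.nrow();
  int nsteps = nsamp * nsub;
  double h = dt / nsub;
  std::vector<double> ustore((nsteps + 1) * 10);
  std::vector<char> clstore(nsteps * 4);
  double u[10];
  for (int i = 0; i < 10; ++i) { u[i] = u0[i]; ustore[i] = u[i]; }
  double loss = 0;
  const double N = (double)nsamp * 10.0;
  bool cl[4];
  for (int k = 0; k < nsamp; ++k) {
    for (int s = 0; s < nsub; ++s) {
      int step = k * nsub + s;
      double t = t0 + step * h;
      if (!rk4_step(u, t, h, theta.begin(), mu.begin(), sd.begin(),
                    pvec.begin(), cl)) {
        return List::create(_["loss"] = R_PosInf,
                            _["grad"] = NumericVector(NTHETA),
                            _["ok"] = false, _["fail_time"] = t);
      }
      for (int i = 0; i < 4; ++i) clstore[step * 4 + i] = cl[i];
      for (int i = 0; i < 10; ++i) ustore[(step + 1) * 10 + i] = u[i];
    }
    for (int i = 0; i < 10; ++i) {
      double r = u[i] - data(k, i);
      loss += r * r / N;
    }
  }
  if (!std::isfinite(loss)) {
    return List::create(_["loss"] = R_PosInf,
                        _["grad"] = NumericVector(NTHETA),
                        _["ok"] = false, _["fail_time"] = NA_REAL);
  }
  NumericVector grad(NTHETA);
  if (want_grad) {
    double a[10] = {0};
    for (int k = nsamp - 1; k >= 0; --k) {
      const double* uk = &ustore[(k + 1) * nsub * 10];
      for (int i = 0; i < 10; ++i) a[i] += 2.0 * (uk[i] - data(k, i)) / N;
      for (int s = nsub - 1; s >= 0; --s) {
        int step = k * nsub + s;
        bool clb[4];
        for (int i = 0; i < 4; ++i) clb[i] = clstore[step * 4 + i];
        rk4_step_vjp(&ustore[step * 10], t0 + step * h, h, theta.begin(),
                     mu.begin(), sd.begin(), pvec.begin(), clb, a,
                     grad.begin());
      }
    }
  }
  return List::create(_["loss"] = loss, _["grad"] = grad, _["ok"] = true,
                      _["fail_time"] = NA_REAL);
}

//' @noRd
// [[Rcpp::export(name = ".nn_eval_cpp")]]
NumericMatrix nn_eval_cpp(NumericVector theta, NumericVector mu,
                          NumericVector sd, NumericMatrix X) {
  if (theta.size() != NTHETA) stop("theta must have length %d", NTHETA);
  if (X.ncol() != NIN) stop("X must have %d columns", NIN);
  NumericMatrix out(X.nrow(), NOUT);
  NetWork w;
  double x[NIN];
  for (int r = 0; r < X.nrow(); ++r) {
    for (int j = 0; j < NIN; ++j) x[j] = X(r, j);
    nn_forward(theta.begin(), mu.begin(), sd.begin(), x, w);
    for (int i = 0; i < NOUT; ++i) out(r, i) = w.o[i];
  }
  return out;
}
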