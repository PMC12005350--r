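#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Feed-forward tanh network mapping scaled time to an unbounded pre-activation z.
// theta layout per layer l: W_l (out x in, column-major), then b_l (out).
// Hidden layers use tanh; the final layer is linear. The caller squashes z to
// (0, beta_max). When grad != nullptr, dz/dtheta is written via backpropagation.
static double net_preact(const double* theta, const std::vector<int>& sizes,
                         double tin, double* grad,
                         std::vector<std::vector<double> >& act,
                         std::vector<std::vector<double> >& delta) {
  const int L = (int)sizes.size() - 1;  // number of weight layers
  act[0][0] = tin;
  int off = 0;
  for (int l = 1; l <= L; ++l) {
    const int nin = sizes[l - 1], nout = sizes[l];
    const double* W = theta + off;
    const double* b = theta + off + nin * nout;
    for (int j = 0; j < nout; ++j) {
      double s = b[j];
      for (int i = 0; i < nin; ++i) s += W[j + (size_t)nout * i] * act[l - 1][i];
      act[l][j] = (l < L) ? std::tanh(s) : s;
    }
    off += nin * nout + nout;
  }
  const double z = act[L][0];
  if (grad) {
    delta[L][0] = 1.0;  // output layer is linear
    // walk backwards; weight offsets recomputed per layer
    std::vector<int> offs(L + 1);
    offs[1] = 0;
    for (int l = 2; l <= L; ++l)
      offs[l] = offs[l - 1] + sizes[l - 2] * sizes[l - 1] + sizes[l - 1];
    for (int l = L; l >= 1; --l) {
      const int nin = sizes[l - 1], nout = sizes[l];
      const double* W = theta + offs[l];
      double* gW = grad + offs[l];
      double* gb = grad + offs[l] + nin * nout;
      for (int j = 0; j < nout; ++j) {
        gb[j] = delta[l][j];
        for (int i = 0; i < nin; ++i)
          gW[j + (size_t)nout * i] = delta[l][j] * act[l - 1][i];
      }
      if (l > 1) {
        for (int i = 0; i < nin; ++i) {
          double s = 0.0;
          for (int j = 0; j < nout; ++j) s += W[j + (size_t)nout * i] * delta[l][j];
          delta[l - 1][i] = s * (1.0 - act[l - 1][i] * act[l - 1][i]);
        }
      }
    }
  }
  return z;
}

struct UdeWork {
  std::vector<int> sizes;
  double t_max, beta_max, alpha, gamma, N;
  const double* theta;
  int p_net, p;  // p = 2 + p_net (alpha, gamma, network)
  bool sens;
  std::vector<std::vector<double> > act, delta;
  std::vector<double> gnet;  // dz/dtheta_net scratch

  double beta(double t, double* dbeta_dnet) {
    const double tin = t / t_max;
    double z = net_preact(theta, sizes, tin, dbeta_dnet ? gnet.data() : nullptr,
                          act, delta);
    const double th = std::tanh(z);
    const double b = beta_max * (th + 1.0) * 0.5;
    if (dbeta_dnet) {
      const double dz = beta_max * (1.0 - th * th) * 0.5;
      for (int k = 0; k < p_net; ++k) dbeta_dnet[k] = dz * gnet[k];
    }
    return b;
  }

  // dx = f(t, x); if sens, dS = J_x S + df/dtheta with S column-major 4 x p
  void rhs(double t, const double* x, const double* S, double* dx, double* dS,
           std::vector<double>& dbnet) {
    const double b = beta(t, sens ? dbnet.data() : nullptr);
    const double Sv = x[0], E = x[1], I = x[2];
    const double inf = b * Sv * I / N;  // infection flux
    dx[0] = -inf;
    dx[1] = inf - alpha * E;
    dx[2] = alpha * E - gamma * I;
    dx[3] = gamma * I;
    if (!sens) return;
    // Jacobian wrt states
    const double jSS = -b * I / N, jSI = -b * Sv / N;
    // columns of df/dtheta: alpha, gamma, then net via chain rule on beta
    const double fbS = -Sv * I / N;  // df1/dbeta; df2/dbeta = -fbS
    for (int c = 0; c < p; ++c) {
      const double s0 = S[0 + 4 * c], s1 = S[1 + 4 * c], s2 = S[2 + 4 * c],
                   s3 = S[3 + 4 * c];
      (void)s3;
      double d0 = jSS * s0 + jSI * s2;
      double d1 = -jSS * s0 - jSI * s2 - alpha * s1;
      double d2 = alpha * s1 - gamma * s2;
      double d3 = gamma * s2;
      if (c == 0) {            // alpha
        d1 += -E; d2 += E;
      } else if (c == 1) {     // gamma
        d2 += -I; d3 += I;
      } else {                 // network weight c-2
        const double db = dbnet[c - 2];
        d0 += fbS * db; d1 += -fbS * db;
      }
      dS[0 + 4 * c] = d0; dS[1 + 4 * c] = d1;
      dS[2 + 4 * c] = d2; dS[3 + 4 * c] = d3;
    }
  }
};

// Forward solve of the SEIR universal differential equation with the network
// supplying beta(t), by classical RK4 at fixed step <= dt, optionally
// propagating forward sensitivities d state / d (alpha, gamma, theta_net)
// through the identical discretization (exact gradient of the numerical
// solution for explicit Runge-Kutta schemes).
// [[Rcpp::export]]
List ude_solve_cpp(NumericVector x0, NumericVector times, double t0,
                   double alpha, double gamma, double N,
                   NumericVector theta_net, IntegerVector layer_sizes,
                   double t_max, double beta_max, double dt, bool sens) {
  const int n_t = times.size();
  UdeWork w;
  w.sizes.assign(layer_sizes.begin(), layer_sizes.end());
  w.t_max = t_max; w.beta_max = beta_max;
  w.alpha = alpha; w.gamma = gamma; w.N = N;
  w.theta = theta_net.begin();
  w.p_net = theta_net.size();
  w.p = 2 + w.p_net;
  w.sens = sens;
  const int L = (int)w.sizes.size() - 1;
  w.act.resize(L + 1); w.delta.resize(L + 1);
  for (int l = 0; l <= L; ++l) {
    w.act[l].assign(w.sizes[l], 0.0);
    w.delta[l].assign(w.sizes[l], 0.0);
  }
  w.gnet.assign(w.p_net, 0.0);

  const int p = sens ? w.p : 0;
  const int nS = 4 * p;
  std::vector<double> x(x0.begin(), x0.end()), S(nS, 0.0);
  std::vector<double> k1(4), k2(4), k3(4), k4(4), xt(4);
  std::vector<double> K1(nS), K2(nS), K3(nS), K4(nS), St(nS);
  std::vector<double> dbnet(w.p_net);

  NumericMatrix states(n_t, 4);
  NumericVector beta_out(n_t);
  NumericVector sens_out(sens ? (R_xlen_t)n_t * 4 * w.p : 0);
  bool ok = true;
  double t = t0;

  for (int k = 0; k < n_t && ok; ++k) {
    const double t_end = times[k];
    const double span = t_end - t;
    int nstep = (span <= 0) ? 0 : (int)std::ceil(span / dt - 1e-9);
    const double h = (nstep > 0) ? span / nstep : 0.0;
    for (int s = 0; s < nstep && ok; ++s) {
      w.rhs(t, x.data(), S.data(), k1.data(), K1.data(), dbnet);
      for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
      for (int i = 0; i < nS; ++i) St[i] = S[i] + 0.5 * h * K1[i];
      w.rhs(t + 0.5 * h, xt.data(), St.data(), k2.data(), K2.data(), dbnet);
      for (int i = 0; i < 4; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
      for (int i = 0; i < nS; ++i) St[i] = S[i] + 0.5 * h * K2[i];
      w.rhs(t + 0.5 * h, xt.data(), St.data(), k3.data(), K3.data(), dbnet);
      for (int i = 0; i < 4; ++i) xt[i] = x[i] + h * k3[i];
      for (int i = 0; i < nS; ++i) St[i] = S[i] + h * K3[i];
      w.rhs(t + h, xt.data(), St.data(), k4.data(), K4.data(), dbnet);
      for (int i = 0; i < 4; ++i)
        x[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      for (int i = 0; i < nS; ++i)
        S[i] += h / 6.0 * (K1[i] + 2.0 * K2[i] + 2.0 * K3[i] + K4[i]);
      t += h;
      for (int i = 0; i < 4; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e9 * N) ok = false;
    }
    t = t_end;
    for (int i = 0; i < 4; ++i) states(k, i) = x[i];
    beta_out[k] = w.beta(t_end, nullptr);
    if (sens)
      for (int c = 0; c < w.p; ++c)
        for (int i = 0; i < 4; ++i)
          sens_out[(R_xlen_t)k + (R_xlen_t)n_t * (i + 4 * (R_xlen_t)c)] =
              S[i + 4 * c];
  }

  List out = List::create(_["states"] = states, _["beta"] = beta_out,
                          _["ok"] = ok);
  if (sens) {
    sens_out.attr("dim") = IntegerVector::create(n_t, 4, w.p);
    out["sens"] = sens_out;
  }
  return out;
}
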