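#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Turgor-driven relaxation of the mass-spring wall network.
//
// Overdamped dynamics damping * dp/dt = F(p), where F is the sum of spring
// forces (linear in strain relative to rest length) and turgor forces (normal
// pressure on boundary walls). Steps are backward Euler, linearised about the
// current state: (I - gamma * J) delta = gamma * F(p), gamma = dt / damping,
// solved by Jacobi-preconditioned conjugate gradients on the spring Jacobian.
// A step is accepted only if the global (2-norm) force residual does not
// increase (the update is scaled back otherwise), so that residual is
// non-increasing across accepted steps; convergence is declared when the
// maximum per-vertex force norm falls below `tol`.

static void spring_turgor_forces(const std::vector<double>& px,
                                 const std::vector<double>& py,
                                 const std::vector<int>& e1,
                                 const std::vector<int>& e2,
                                 const std::vector<double>& rest,
                                 const std::vector<int>& bi,
                                 const std::vector<double>& bs,
                                 double k, double P,
                                 std::vector<double>& fx,
                                 std::vector<double>& fy) {
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  size_t E = e1.size();
  for (size_t e = 0; e < E; ++e) {
    int a = e1[e], b = e2[e];
    double dx = px[b] - px[a], dy = py[b] - py[a];
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-14) stop("zero-length spring encountered");
    double c = k * (len / rest[e] - 1.0) / len;
    fx[a] += c * dx; fy[a] += c * dy;
    fx[b] -= c * dx; fy[b] -= c * dy;
  }
  for (size_t q = 0; q < bi.size(); ++q) {
    int e = bi[q];
    int a = e1[e], b = e2[e];
    double dx = px[b] - px[a], dy = py[b] - py[a];
    double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-14) continue;
    // outward unit normal = bs * (dy, -dx) / len; force P * len / 2 on each end
    double fxn = bs[q] * dy * P * 0.5;
    double fyn = bs[q] * (-dx) * P * 0.5;
    fx[a] += fxn; fy[a] += fyn;
    fx[b] += fxn; fy[b] += fyn;
  }
}

static double max_force_norm(const std::vector<double>& fx,
                             const std::vector<double>& fy) {
  double m = 0.0;
  for (size_t i = 0; i < fx.size(); ++i) {
    double n = fx[i] * fx[i] + fy[i] * fy[i];
    if (n > m) m = n;
  }
  return std::sqrt(m);
}

static double l2_force_norm(const std::vector<double>& fx,
                            const std::vector<double>& fy) {
  double s = 0.0;
  for (size_t i = 0; i < fx.size(); ++i)
    s += fx[i] * fx[i] + fy[i] * fy[i];
  return std::sqrt(s);
}

// y = (I - gamma J) x, with J the spring-force Jacobian encoded by per-edge
// rank-two blocks K_e = c1 u u^T + c2 (I - u u^T)
struct EdgeCoef { double ux, uy, c1, c2; };

static void matvec(const std::vector<double>& x,
                   const std::vector<int>& e1, const std::vector<int>& e2,
                   const std::vector<EdgeCoef>& co, double gamma, int V,
                   std::vector<double>& y) {
  for (int i = 0; i < 2 * V; ++i) y[i] = x[i];
  for (size_t e = 0; e < e1.size(); ++e) {
    int a = e1[e], b = e2[e];
    double rx = x[2 * b] - x[2 * a], ry = x[2 * b + 1] - x[2 * a + 1];
    double dot = co[e].ux * rx + co[e].uy * ry;
    double qx = co[e].c1 * co[e].ux * dot + co[e].c2 * (rx - co[e].ux * dot);
    double qy = co[e].c1 * co[e].uy * dot + co[e].c2 * (ry - co[e].uy * dot);
    // (J x)_a += q; (J x)_b -= q; y = x - gamma J x
    y[2 * a]     -= gamma * qx;
    y[2 * a + 1] -= gamma * qy;
    y[2 * b]     += gamma * qx;
    y[2 * b + 1] += gamma * qy;
  }
}

// [[Rcpp::export(name = ".relax_kernel")]]
List relax_kernel(NumericMatrix pos, IntegerVector ev1, IntegerVector ev2,
                  NumericVector rest, IntegerVector bidx, NumericVector bsign,
                  double k, double P, double dt, double damping,
                  double tol, int max_steps, double cg_tol, int cg_max) {
  int V = pos.nrow();
  size_t E = ev1.size();
  std::vector<double> px(V), py(V);
  for (int i = 0; i < V; ++i) { px[i] = pos(i, 0); py[i] = pos(i, 1); }
  std::vector<int> e1(E), e2(E);
  for (size_t e = 0; e < E; ++e) { e1[e] = ev1[e] - 1; e2[e] = ev2[e] - 1; }
  std::vector<int> bi(bidx.size());
  std::vector<double> bs(bsign.size());
  for (int q = 0; q < bidx.size(); ++q) { bi[q] = bidx[q] - 1; bs[q] = bsign[q]; }
  std::vector<double> re(rest.begin(), rest.end());

  double gamma = dt / damping;
  std::vector<double> fx(V), fy(V), rhs(2 * V), x(2 * V), r(2 * V), z(2 * V),
      p(2 * V), Ap(2 * V), dxx(V), dxy(V), dyy(V), ixx(V), ixy(V), iyy(V),
      xprev(2 * V, 0.0);
  std::vector<EdgeCoef> co(E);
  std::vector<double> tx(V), ty(V), tfx(V), tfy(V);

  spring_turgor_forces(px, py, e1, e2, re, bi, bs, k, P, fx, fy);
  double resid = max_force_norm(fx, fy);
  double l2 = l2_force_norm(fx, fy);
  int steps = 0;
  bool converged = resid < tol;

  while (!converged && steps < max_steps) {
    // edge coefficients at the current state
    for (size_t e = 0; e < E; ++e) {
      int a = e1[e], b = e2[e];
      double dx = px[b] - px[a], dy = py[b] - py[a];
      double len = std::sqrt(dx * dx + dy * dy);
      co[e].ux = dx / len; co[e].uy = dy / len;
      co[e].c1 = k / re[e];
      // transverse curvature is negative for compressed springs; clamp it so
      // the implicit matrix stays positive definite (Gauss-Newton filtering)
      double c2 = k * (len / re[e] - 1.0) / len;
      co[e].c2 = c2 > 0.0 ? c2 : 0.0;
    }
    // block-Jacobi (2x2) preconditioner
    std::fill(dxx.begin(), dxx.end(), 1.0);
    std::fill(dyy.begin(), dyy.end(), 1.0);
    std::fill(dxy.begin(), dxy.end(), 0.0);
    for (size_t e = 0; e < E; ++e) {
      int a = e1[e], b = e2[e];
      double kxx = co[e].c1 * co[e].ux * co[e].ux + co[e].c2 * (1.0 - co[e].ux * co[e].ux);
      double kyy = co[e].c1 * co[e].uy * co[e].uy + co[e].c2 * (1.0 - co[e].uy * co[e].uy);
      double kxy = (co[e].c1 - co[e].c2) * co[e].ux * co[e].uy;
      dxx[a] += gamma * kxx; dyy[a] += gamma * kyy; dxy[a] += gamma * kxy;
      dxx[b] += gamma * kxx; dyy[b] += gamma * kyy; dxy[b] += gamma * kxy;
    }
    for (int i = 0; i < V; ++i) {
      double det = dxx[i] * dyy[i] - dxy[i] * dxy[i];
      if (std::fabs(det) < 1e-12) { ixx[i] = 1.0; ixy[i] = 0.0; iyy[i] = 1.0; }
      else { ixx[i] = dyy[i] / det; ixy[i] = -dxy[i] / det; iyy[i] = dxx[i] / det; }
    }
    // CG solve (I - gamma J) x = gamma F
    for (int i = 0; i < V; ++i) { rhs[2 * i] = gamma * fx[i]; rhs[2 * i + 1] = gamma * fy[i]; }
    double rhs2 = 0.0;
    for (int i = 0; i < 2 * V; ++i) rhs2 += rhs[i] * rhs[i];
    if (rhs2 == 0.0) break;
    // warm start from the previous accepted step's solution
    matvec(xprev, e1, e2, co, gamma, V, Ap);
    for (int i = 0; i < 2 * V; ++i) { x[i] = xprev[i]; r[i] = rhs[i] - Ap[i]; }
    for (int i = 0; i < V; ++i) {
      z[2 * i]     = ixx[i] * r[2 * i] + ixy[i] * r[2 * i + 1];
      z[2 * i + 1] = ixy[i] * r[2 * i] + iyy[i] * r[2 * i + 1];
      p[2 * i] = z[2 * i]; p[2 * i + 1] = z[2 * i + 1];
    }
    double rz = 0.0;
    for (int i = 0; i < 2 * V; ++i) rz += r[i] * z[i];
    for (int it = 0; it < cg_max; ++it) {
      matvec(p, e1, e2, co, gamma, V, Ap);
      double pAp = 0.0;
      for (int i = 0; i < 2 * V; ++i) pAp += p[i] * Ap[i];
      if (pAp <= 0.0) break;  // lost positive definiteness; keep partial solution
      double alpha = rz / pAp;
      double r2 = 0.0;
      for (int i = 0; i < 2 * V; ++i) {
        x[i] += alpha * p[i];
        r[i] -= alpha * Ap[i];
        r2 += r[i] * r[i];
      }
      if (r2 < cg_tol * cg_tol * rhs2) break;
      double rz_new = 0.0;
      for (int i = 0; i < V; ++i) {
        z[2 * i]     = ixx[i] * r[2 * i] + ixy[i] * r[2 * i + 1];
        z[2 * i + 1] = ixy[i] * r[2 * i] + iyy[i] * r[2 * i + 1];
        rz_new += r[2 * i] * z[2 * i] + r[2 * i + 1] * z[2 * i + 1];
      }
      double beta = rz_new / rz;
      rz = rz_new;
      for (int i = 0; i < 2 * V; ++i) p[i] = z[i] + beta * p[i];
    }
    // accept the step only if the global force norm does not increase
    double scale = 1.0;
    double trial_l2 = l2;
    bool accepted = false;
    for (int h = 0; h < 30; ++h) {
      for (int i = 0; i < V; ++i) {
        tx[i] = px[i] + scale * x[2 * i];
        ty[i] = py[i] + scale * x[2 * i + 1];
      }
      spring_turgor_forces(tx, ty, e1, e2, re, bi, bs, k, P, tfx, tfy);
      trial_l2 = l2_force_norm(tfx, tfy);
      if (trial_l2 <= l2 * (1.0 + 1e-14)) { accepted = true; break; }
      scale *= 0.5;
    }
    if (!accepted) break;
    for (int i = 0; i < 2 * V; ++i) xprev[i] = scale * x[i];
    px.swap(tx); py.swap(ty);
    fx.swap(tfx); fy.swap(tfy);
    l2 = trial_l2;
    resid = max_force_norm(fx, fy);
    ++steps;
    if (resid < tol) { converged = true; break; }
  }

  NumericMatrix out(V, 2);
  for (int i = 0; i < V; ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return List::create(_["pos"] = out, _["steps"] = steps,
                      _["residual"] = resid, _["converged"] = converged);
}
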