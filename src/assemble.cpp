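#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Assemble one semi-implicit step of the residual-based stabilized
// equal-order P1/P1 incompressible Navier-Stokes formulation (SI units).
//
// Unknown ordering: [u1(1..N), u2(1..N), p(1..N)].
// Galerkin terms: transient (consistent mass), convection at the
// previous-step advection velocity, viscous (2 mu eps:eps), pressure
// gradient (integrated by parts), divergence; nodal-lumped Brinkman
// penalization rho*sigma*chi*u.  Stabilization: SUPG/PSPG tested with
// tau*(a.grad w + grad q / rho) against the kinematic momentum residual,
// plus grad-div (LSIC) with tau_c = c_lsic * h^2 / tau.
//
// [[Rcpp::export]]
List assemble_ns_step(NumericMatrix nodes, IntegerMatrix tri,
                      NumericVector u1p, NumericVector u2p,
                      NumericVector mu_e, NumericVector drag,
                      double rho, double dt,
                      double c_supg, double c_lsic,
                      NumericVector pi1, NumericVector pi2) {
  const int N = nodes.nrow();
  const int M = tri.nrow();
  const int per_elem = 9 * 27;  // generous upper bound
  std::vector<int> ti; ti.reserve((size_t)M * per_elem);
  std::vector<int> tj; tj.reserve((size_t)M * per_elem);
  std::vector<double> tv; tv.reserve((size_t)M * per_elem);
  NumericVector rhs(3 * N);

  auto push = [&](int r, int c, double v) {
    if (v != 0.0) { ti.push_back(r); tj.push_back(c); tv.push_back(v); }
  };

  for (int e = 0; e < M; ++e) {
    int n0 = tri(e, 0) - 1, n1 = tri(e, 1) - 1, n2 = tri(e, 2) - 1;
    int nd[3] = {n0, n1, n2};
    double x0 = nodes(n0, 0), y0 = nodes(n0, 1);
    double x1 = nodes(n1, 0), y1 = nodes(n1, 1);
    double x2 = nodes(n2, 0), y2 = nodes(n2, 1);
    double twoA = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    double A = 0.5 * std::fabs(twoA);
    if (A <= 0) continue;
    double b[3], c[3];
    b[0] = (y1 - y2) / twoA; b[1] = (y2 - y0) / twoA; b[2] = (y0 - y1) / twoA;
    c[0] = (x2 - x1) / twoA; c[1] = (x0 - x2) / twoA; c[2] = (x1 - x0) / twoA;

    double ax = (u1p[n0] + u1p[n1] + u1p[n2]) / 3.0;
    double ay = (u2p[n0] + u2p[n1] + u2p[n2]) / 3.0;
    double mu = mu_e[e];
    double nu = mu / rho;
    double drag_e = (drag[n0] + drag[n1] + drag[n2]) / 3.0;
    double h = std::sqrt(2.0 * A);
    double anorm = std::sqrt(ax * ax + ay * ay);
    double inv2 = (2.0 / dt) * (2.0 / dt)
                + (2.0 * anorm / h) * (2.0 * anorm / h)
                + (4.0 * nu / (h * h)) * (4.0 * nu / (h * h))
                + drag_e * drag_e;
    double tau = c_supg / std::sqrt(inv2);
    double tauc = c_lsic * h * h / tau;

    double g[3];  // a . grad(phi_j), constant per element
    for (int j = 0; j < 3; ++j) g[j] = ax * b[j] + ay * c[j];

    for (int i = 0; i < 3; ++i) {
      int I = nd[i];
      int ru1 = I, ru2 = N + I, rp = 2 * N + I;
      double gi = g[i];
      for (int j = 0; j < 3; ++j) {
        int J = nd[j];
        int cu1 = J, cu2 = N + J, cp = 2 * N + J;
        double mc = A / 12.0 * (i == j ? 2.0 : 1.0);  // consistent mass
        double phi_int = A / 3.0;

        // --- Galerkin momentum ---
        double mom_t = rho / dt * mc;
        double conv = rho * phi_int * g[j];
        double k11 = mu * A * (2.0 * b[i] * b[j] + c[i] * c[j]);
        double k12 = mu * A * (c[i] * b[j]);
        double k21 = mu * A * (b[i] * c[j]);
        double k22 = mu * A * (2.0 * c[i] * c[j] + b[i] * b[j]);
        push(ru1, cu1, mom_t + conv + k11);
        push(ru1, cu2, k12);
        push(ru2, cu1, k21);
        push(ru2, cu2, mom_t + conv + k22);
        push(ru1, cp, -b[i] * phi_int);
        push(ru2, cp, -c[i] * phi_int);
        rhs[ru1] += rho / dt * mc * u1p[J];
        rhs[ru2] += rho / dt * mc * u2p[J];

        // --- Galerkin continuity ---
        push(rp, cu1, phi_int * b[j]);
        push(rp, cu2, phi_int * c[j]);

        // --- SUPG (momentum rows) ---
        double sm = rho * tau * gi;
        push(ru1, cu1, sm * (phi_int / dt + g[j] * A));
        push(ru2, cu2, sm * (phi_int / dt + g[j] * A));
        push(ru1, cp, tau * gi * b[j] * A);
        push(ru2, cp, tau * gi * c[j] * A);
        rhs[ru1] += sm * phi_int / dt * u1p[J];
        rhs[ru2] += sm * phi_int / dt * u2p[J];

        // --- PSPG (pressure rows) ---
        push(rp, cu1, tau * b[i] * (phi_int / dt + g[j] * A));
        push(rp, cu2, tau * c[i] * (phi_int / dt + g[j] * A));
        push(rp, cp, tau / rho * (b[i] * b[j] + c[i] * c[j]) * A);
        rhs[rp] += tau * b[i] * phi_int / dt * u1p[J]
                 + tau * c[i] * phi_int / dt * u2p[J];

        // --- grad-div (LSIC) ---
        push(ru1, cu1, rho * tauc * b[i] * b[j] * A);
        push(ru1, cu2, rho * tauc * b[i] * c[j] * A);
        push(ru2, cu1, rho * tauc * c[i] * b[j] * A);
        push(ru2, cu2, rho * tauc * c[i] * c[j] * A);
      }
      // nodal-lumped Brinkman/porous-screen drag
      double pen = rho * drag[I] * A / 3.0;
      push(ru1, ru1, pen);
      push(ru2, ru2, pen);
      // orthogonal-subscale correction: the projected coarse-scale
      // residual (previous step) is subtracted from the stabilization
      // residual, which restores consistency for smooth fields
      double p1b = (pi1[n0] + pi1[n1] + pi1[n2]) / 3.0;
      double p2b = (pi2[n0] + pi2[n1] + pi2[n2]) / 3.0;
      rhs[ru1] += rho * tau * gi * A * p1b;
      rhs[ru2] += rho * tau * gi * A * p2b;
      rhs[rp] += tau * A * (b[i] * p1b + c[i] * p2b);
    }
  }

  return List::create(Named("i") = IntegerVector(ti.begin(), ti.end()),
                      Named("j") = IntegerVector(tj.begin(), tj.end()),
                      Named("v") = NumericVector(tv.begin(), tv.end()),
                      Named("rhs") = rhs);
}

// Lumped-mass L2 projection of the coarse-scale momentum residual
// (convection + pressure gradient, kinematic units m/s^2) onto the
// P1 nodal space.  Used for the orthogonal-subscale correction.
// [[Rcpp::export]]
List project_residual(NumericMatrix nodes, IntegerMatrix tri,
                      NumericVector u1, NumericVector u2,
                      NumericVector p, double rho) {
  const int N = nodes.nrow();
  const int M = tri.nrow();
  NumericVector r1(N), r2(N), mass(N);
  for (int e = 0; e < M; ++e) {
    int n0 = tri(e, 0) - 1, n1 = tri(e, 1) - 1, n2 = tri(e, 2) - 1;
    int nd[3] = {n0, n1, n2};
    double x0 = nodes(n0, 0), y0 = nodes(n0, 1);
    double x1 = nodes(n1, 0), y1 = nodes(n1, 1);
    double x2 = nodes(n2, 0), y2 = nodes(n2, 1);
    double twoA = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    double A = 0.5 * std::fabs(twoA);
    double b[3], c[3];
    b[0] = (y1 - y2) / twoA; b[1] = (y2 - y0) / twoA; b[2] = (y0 - y1) / twoA;
    c[0] = (x2 - x1) / twoA; c[1] = (x0 - x2) / twoA; c[2] = (x1 - x0) / twoA;
    double ax = (u1[n0] + u1[n1] + u1[n2]) / 3.0;
    double ay = (u2[n0] + u2[n1] + u2[n2]) / 3.0;
    double du1dx = 0, du1dy = 0, du2dx = 0, du2dy = 0, dpdx = 0, dpdy = 0;
    for (int j = 0; j < 3; ++j) {
      du1dx += b[j] * u1[nd[j]]; du1dy += c[j] * u1[nd[j]];
      du2dx += b[j] * u2[nd[j]]; du2dy += c[j] * u2[nd[j]];
      dpdx += b[j] * p[nd[j]]; dpdy += c[j] * p[nd[j]];
    }
    double v1 = ax * du1dx + ay * du1dy + dpdx / rho;
    double v2 = ax * du2dx + ay * du2dy + dpdy / rho;
    for (int j = 0; j < 3; ++j) {
      r1[nd[j]] += v1 * A / 3.0;
      r2[nd[j]] += v2 * A / 3.0;
      mass[nd[j]] += A / 3.0;
    }
  }
  for (int i = 0; i < N; ++i) {
    if (mass[i] > 0) { r1[i] /= mass[i]; r2[i] /= mass[i]; }
  }
  return List::create(Named("pi1") = r1, Named("pi2") = r2);
}

// Element-wise velocity gradient invariants: returns per-element shear
// rate gamma_dot = sqrt(2 eps:eps) and divergence (both 1/s).
// [[Rcpp::export]]
List element_shear_rate(NumericMatrix nodes, IntegerMatrix tri,
                        NumericVector u1, NumericVector u2) {
  const int M = tri.nrow();
  NumericVector gd(M), divu(M), area(M);
  for (int e = 0; e < M; ++e) {
    int n0 = tri(e, 0) - 1, n1 = tri(e, 1) - 1, n2 = tri(e, 2) - 1;
    double x0 = nodes(n0, 0), y0 = nodes(n0, 1);
    double x1 = nodes(n1, 0), y1 = nodes(n1, 1);
    double x2 = nodes(n2, 0), y2 = nodes(n2, 1);
    double twoA = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    double b[3], c[3];
    b[0] = (y1 - y2) / twoA; b[1] = (y2 - y0) / twoA; b[2] = (y0 - y1) / twoA;
    c[0] = (x2 - x1) / twoA; c[1] = (x0 - x2) / twoA; c[2] = (x1 - x0) / twoA;
    int nd[3] = {n0, n1, n2};
    double dudx = 0, dudy = 0, dvdx = 0, dvdy = 0;
    for (int j = 0; j < 3; ++j) {
      dudx += b[j] * u1[nd[j]]; dudy += c[j] * u1[nd[j]];
      dvdx += b[j] * u2[nd[j]]; dvdy += c[j] * u2[nd[j]];
    }
    double e12 = 0.5 * (dudy + dvdx);
    gd[e] = std::sqrt(2.0 * (dudx * dudx + dvdy * dvdy + 2.0 * e12 * e12));
    divu[e] = dudx + dvdy;
    area[e] = 0.5 * std::fabs(twoA);
  }
  return List::create(Named("gamma_dot") = gd, Named("div") = divu,
                      Named("area") = area);
}
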