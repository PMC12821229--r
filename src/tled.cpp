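// Total-Lagrangian explicit-dynamics core for linear tetrahedra.
//
// Constant-gradient elements with nodal-volume-averaged dilatation
// (F-bar type) to mitigate volumetric locking, compressible neo-Hookean
// stress with single-term Prony shear relaxation via an exact
// piecewise-linear internal-variable recurrence, penalty contact against
// a fixed rigid triangulated wall (small-sliding, Coulomb friction), and
// central-difference time stepping with an energy ledger.
//
// Energy bookkeeping: work increments use the exact discrete power
// identity of the central-difference update, f^n . (u^{n+1}-u^{n-1})/2;
// stored energy = volumetric + long-term deviatoric neo-Hookean energy
// + Maxwell branch spring energy h:h/(4 G_k); dashpot dissipation rate
// = h:h/(2 G_k tau_k) (exact for linear viscoelasticity, first-order at
// finite strain).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

namespace {

struct Mat3 {
  double a[9]; // row-major
  double &operator()(int i, int j) { return a[3 * i + j]; }
  double operator()(int i, int j) const { return a[3 * i + j]; }
};

inline Mat3 matmul(const Mat3 &A, const Mat3 &B) {
  Mat3 C;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += A(i, k) * B(k, j);
      C(i, j) = s;
    }
  return C;
}

inline double det3(const Mat3 &A) {
  return A(0,0) * (A(1,1) * A(2,2) - A(1,2) * A(2,1))
       - A(0,1) * (A(1,0) * A(2,2) - A(1,2) * A(2,0))
       + A(0,2) * (A(1,0) * A(2,1) - A(1,1) * A(2,0));
}

inline Mat3 inv3(const Mat3 &A, double d) {
  Mat3 I;
  I(0,0) =  (A(1,1) * A(2,2) - A(1,2) * A(2,1)) / d;
  I(0,1) = -(A(0,1) * A(2,2) - A(0,2) * A(2,1)) / d;
  I(0,2) =  (A(0,1) * A(1,2) - A(0,2) * A(1,1)) / d;
  I(1,0) = -(A(1,0) * A(2,2) - A(1,2) * A(2,0)) / d;
  I(1,1) =  (A(0,0) * A(2,2) - A(0,2) * A(2,0)) / d;
  I(1,2) = -(A(0,0) * A(1,2) - A(0,2) * A(1,0)) / d;
  I(2,0) =  (A(1,0) * A(2,1) - A(1,1) * A(2,0)) / d;
  I(2,1) = -(A(0,0) * A(2,1) - A(0,1) * A(2,0)) / d;
  I(2,2) =  (A(0,0) * A(1,1) - A(0,1) * A(1,0)) / d;
  return I;
}

struct FE {
  int nn, ne;
  std::vector<int> tets;      // column-major ne x 4 (0-based)
  std::vector<double> DmInv;  // ne x 9 row-major per element
  std::vector<double> V0;
  std::vector<double> nodal_vol;
  // workspace
  std::vector<double> J, Jbar, Jnum;
  std::vector<Mat3> Fs;
};

struct ForceResult {
  bool ok = true;
  int bad_elem = -1;
  double strain_energy = 0.0;
  double diss_rate = 0.0; // dashpot power (W)
};

// assemble internal forces; updates s_el_prev and h_state in place when
// dt > 0 (viscous step); dt <= 0 means purely elastic evaluation.
ForceResult assemble(FE &fe, const double *X, const double *u,
                     const double *mu, const double *K,
                     const double *g, const double *tau, double dt,
                     double *s_el_prev, double *h_state, double *f_int,
                     bool fbar) {
  ForceResult res;
  const int nn = fe.nn, ne = fe.ne;
  std::fill(f_int, f_int + 3 * nn, 0.0);

  // pass 1: kinematics
  for (int e = 0; e < ne; ++e) {
    const int n0 = fe.tets[e], n1 = fe.tets[e + ne],
              n2 = fe.tets[e + 2 * ne], n3 = fe.tets[e + 3 * ne];
    Mat3 Ds;
    for (int i = 0; i < 3; ++i) {
      const double x0 = X[n0 + i * nn] + u[n0 + i * nn];
      Ds(i, 0) = X[n1 + i * nn] + u[n1 + i * nn] - x0;
      Ds(i, 1) = X[n2 + i * nn] + u[n2 + i * nn] - x0;
      Ds(i, 2) = X[n3 + i * nn] + u[n3 + i * nn] - x0;
    }
    Mat3 Dm;
    std::memcpy(Dm.a, &fe.DmInv[9 * e], 9 * sizeof(double));
    Mat3 F = matmul(Ds, Dm);
    const double j = det3(F);
    if (!(j > 0.0) || !std::isfinite(j)) {
      res.ok = false; res.bad_elem = e; return res;
    }
    fe.Fs[e] = F; fe.J[e] = j;
  }

  // pass 2: nodal volume-averaged J
  if (fbar) {
    std::fill(fe.Jnum.begin(), fe.Jnum.end(), 0.0);
    for (int e = 0; e < ne; ++e) {
      const double w = fe.V0[e] * 0.25;
      for (int a = 0; a < 4; ++a) fe.Jnum[fe.tets[e + a * ne]] += w * fe.J[e];
    }
    for (int n = 0; n < nn; ++n) fe.Jnum[n] /= fe.nodal_vol[n];
    for (int e = 0; e < ne; ++e) {
      double s = 0;
      for (int a = 0; a < 4; ++a) s += fe.Jnum[fe.tets[e + a * ne]];
      fe.Jbar[e] = 0.25 * s;
      if (!(fe.Jbar[e] > 0.0)) { res.ok = false; res.bad_elem = e;
                                 return res; }
    }
  } else {
    fe.Jbar = fe.J;
  }

  // pass 3: stress + forces
  for (int e = 0; e < ne; ++e) {
    const double Jb = fe.Jbar[e];
    const double scale = std::cbrt(Jb / fe.J[e]);
    Mat3 F = fe.Fs[e];
    for (int i = 0; i < 9; ++i) F.a[i] *= scale;
    // B = F F^T
    Mat3 B;
    for (int i = 0; i < 3; ++i)
      for (int j = i; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += F(i, k) * F(j, k);
        B(i, j) = s; B(j, i) = s;
      }
    const double trB = B(0,0) + B(1,1) + B(2,2);
    const double Jb13 = std::cbrt(Jb);
    const double Jb23 = Jb13 * Jb13;
    const double I1bar = trB / Jb23;

    const double cmu = mu[e] / (Jb23 * Jb); // mu / J^{5/3}
    double s_el[6] = {cmu * (B(0,0) - trB / 3.0),
                      cmu * (B(1,1) - trB / 3.0),
                      cmu * (B(2,2) - trB / 3.0),
                      cmu * B(0,1), cmu * B(1,2), cmu * B(2,0)};
    double s_v[6];
    double branch_energy = 0.0;
    if (g[e] > 0.0) {
      double hh = 0.0;
      if (dt > 0.0) {
        const double x = dt / tau[e];
        const double ex = std::exp(-x);
        const double cfac = g[e] * (1.0 - ex) / x;
        for (int c = 0; c < 6; ++c) {
          const double hk = ex * h_state[e + c * ne] +
                            cfac * (s_el[c] - s_el_prev[e + c * ne]);
          h_state[e + c * ne] = hk;
          s_v[c] = (1.0 - g[e]) * s_el[c] + hk;
        }
      } else {
        for (int c = 0; c < 6; ++c)
          s_v[c] = (1.0 - g[e]) * s_el[c] + h_state[e + c * ne];
      }
      for (int c = 0; c < 3; ++c)
        hh += h_state[e + c * ne] * h_state[e + c * ne];
      for (int c = 3; c < 6; ++c)
        hh += 2.0 * h_state[e + c * ne] * h_state[e + c * ne];
      const double Gk = g[e] * mu[e];
      branch_energy = hh / (4.0 * Gk);
      res.diss_rate += fe.V0[e] * hh / (2.0 * Gk * tau[e]);
    } else {
      for (int c = 0; c < 6; ++c) s_v[c] = s_el[c];
    }
    if (dt > 0.0)
      for (int c = 0; c < 6; ++c) s_el_prev[e + c * ne] = s_el[c];

    const double g_inf = 1.0 - g[e];
    res.strain_energy += fe.V0[e] *
      (g_inf * 0.5 * mu[e] * (I1bar - 3.0) +
       0.5 * K[e] * (Jb - 1.0) * (Jb - 1.0) + branch_energy);

    const double p = K[e] * (Jb - 1.0);
    Mat3 sig;
    sig(0,0) = s_v[0] + p; sig(1,1) = s_v[1] + p; sig(2,2) = s_v[2] + p;
    sig(0,1) = sig(1,0) = s_v[3];
    sig(1,2) = sig(2,1) = s_v[4];
    sig(2,0) = sig(0,2) = s_v[5];

    // P = J sigma F^{-T} with F-bar kinematics
    Mat3 Finv = inv3(F, Jb);
    Mat3 P;
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += sig(i, k) * Finv(j, k);
        P(i, j) = Jb * s;
      }

    // nodal forces f_a = V0 * P * gradN_a (gradN rows from DmInv)
    Mat3 Dm;
    std::memcpy(Dm.a, &fe.DmInv[9 * e], 9 * sizeof(double));
    const int nd[4] = {fe.tets[e], fe.tets[e + ne], fe.tets[e + 2 * ne],
                       fe.tets[e + 3 * ne]};
    double f123[9];
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += P(i, k) * Dm(a, k);
        f123[3 * a + i] = fe.V0[e] * s;
      }
    for (int i = 0; i < 3; ++i) {
      const double f0 = -(f123[i] + f123[3 + i] + f123[6 + i]);
      f_int[nd[0] + i * nn] += f0;
      f_int[nd[1] + i * nn] += f123[i];
      f_int[nd[2] + i * nn] += f123[3 + i];
      f_int[nd[3] + i * nn] += f123[6 + i];
    }
  }
  return res;
}

FE build_fe(const NumericMatrix &nodes, const IntegerMatrix &tets,
            const NumericVector &V0, const NumericVector &DmInv) {
  FE fe;
  fe.nn = nodes.nrow();
  fe.ne = tets.nrow();
  fe.tets.resize(4 * fe.ne);
  for (int e = 0; e < fe.ne; ++e)
    for (int a = 0; a < 4; ++a) fe.tets[e + a * fe.ne] = tets(e, a) - 1;
  fe.V0.assign(V0.begin(), V0.end());
  fe.DmInv.assign(DmInv.begin(), DmInv.end());
  fe.nodal_vol.assign(fe.nn, 0.0);
  for (int e = 0; e < fe.ne; ++e)
    for (int a = 0; a < 4; ++a)
      fe.nodal_vol[fe.tets[e + a * fe.ne]] += 0.25 * fe.V0[e];
  fe.J.resize(fe.ne); fe.Jbar.resize(fe.ne); fe.Jnum.resize(fe.nn);
  fe.Fs.resize(fe.ne);
  return fe;
}

} // namespace

// [[Rcpp::export]]
List cpp_precompute(NumericMatrix nodes, IntegerMatrix tets) {
  int nn = nodes.nrow(), ne = tets.nrow();
  NumericVector DmInv(9 * ne), V0(ne);
  for (int e = 0; e < ne; ++e) {
    int n0 = tets(e, 0) - 1, n1 = tets(e, 1) - 1, n2 = tets(e, 2) - 1,
        n3 = tets(e, 3) - 1;
    if (n0 < 0 || n1 >= nn || n2 >= nn || n3 >= nn)
      stop("tet node index out of range");
    Mat3 Dm;
    for (int i = 0; i < 3; ++i) {
      Dm(i, 0) = nodes(n1, i) - nodes(n0, i);
      Dm(i, 1) = nodes(n2, i) - nodes(n0, i);
      Dm(i, 2) = nodes(n3, i) - nodes(n0, i);
    }
    double d = det3(Dm);
    if (!(d > 0))
      stop("non-positive reference volume in element %d", e + 1);
    V0[e] = d / 6.0;
    Mat3 Di = inv3(Dm, d);
    std::memcpy(&DmInv[9 * e], Di.a, 9 * sizeof(double));
  }
  return List::create(_["DmInv"] = DmInv, _["V0"] = V0);
}

// [[Rcpp::export]]
List cpp_internal_forces(NumericMatrix nodes, IntegerMatrix tets,
                         NumericVector DmInv, NumericVector V0,
                         NumericVector mu, NumericVector K,
                         NumericVector g, NumericVector tau,
                         NumericMatrix u, NumericMatrix s_el_prev,
                         NumericMatrix h_state, double dt, bool fbar) {
  FE fe = build_fe(nodes, tets, V0, DmInv);
  NumericMatrix f_int(fe.nn, 3);
  NumericMatrix s_out(clone(s_el_prev)), h_out(clone(h_state));
  ForceResult r = assemble(fe, REAL(nodes), REAL(u), REAL(mu), REAL(K),
                           REAL(g), REAL(tau), dt, REAL(s_out),
                           REAL(h_out), REAL(f_int), fbar);
  if (!r.ok)
    stop("inverted element %d (det F <= 0)", r.bad_elem + 1);
  return List::create(_["forces"] = f_int, _["s_el"] = s_out,
                      _["history"] = h_out,
                      _["strain_energy"] = r.strain_energy);
}

// [[Rcpp::export]]
List cpp_run_sim(NumericMatrix nodes, IntegerMatrix tets,
                 NumericVector DmInv, NumericVector V0,
                 NumericVector mu, NumericVector K,
                 NumericVector g, NumericVector tau,
                 NumericVector mass, NumericVector gravity,
                 double dt, int nsteps, IntegerVector record_steps,
                 IntegerVector bc_x, IntegerVector bc_z,
                 IntegerVector bc_fixed,
                 IntegerVector contact_nodes,
                 NumericMatrix wall_v, IntegerMatrix wall_f,
                 double penalty_beta, double friction,
                 double damping, int nipple_node, bool fbar,
                 double ramp_time, NumericMatrix u0) {
  FE fe = build_fe(nodes, tets, V0, DmInv);
  const int nn = fe.nn, ne = fe.ne;

  std::vector<double> u(3 * nn, 0.0), v(3 * nn, 0.0), u_prev(3 * nn, 0.0),
      u_new(3 * nn, 0.0), f_int(3 * nn, 0.0), f_ext(3 * nn, 0.0),
      s_el(6 * ne, 0.0), h_state(6 * ne, 0.0);
  if (u0.nrow() == nn && u0.ncol() == 3)
    for (int n = 0; n < nn; ++n)
      for (int i = 0; i < 3; ++i)
        u[n + i * nn] = u_prev[n + i * nn] = u0(n, i);

  const double *X = REAL(nodes);
  const double gx = gravity[0], gy = gravity[1], gz = gravity[2];

  // contact: wall facet planes
  const int nw = wall_f.nrow();
  std::vector<double> wn(3 * nw), wp(9 * nw);
  for (int t = 0; t < nw; ++t) {
    int a = wall_f(t, 0) - 1, b = wall_f(t, 1) - 1, c = wall_f(t, 2) - 1;
    double e1[3], e2[3];
    for (int i = 0; i < 3; ++i) {
      wp[9 * t + i] = wall_v(a, i);
      wp[9 * t + 3 + i] = wall_v(b, i);
      wp[9 * t + 6 + i] = wall_v(c, i);
      e1[i] = wall_v(b, i) - wall_v(a, i);
      e2[i] = wall_v(c, i) - wall_v(a, i);
    }
    double n[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                   e1[2] * e2[0] - e1[0] * e2[2],
                   e1[0] * e2[1] - e1[1] * e2[0]};
    double l = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    for (int i = 0; i < 3; ++i) wn[3 * t + i] = n[i] / l;
  }
  const int nc = contact_nodes.size();
  std::vector<int> anchor(nc, -1);
  std::vector<double> anchor_pt(3 * nc, 0.0), side(nc, 1.0);
  double max_pen = 0.0;

  auto closest_facet = [&](const double *x, int &tf, double *proj) {
    double best = 1e300;
    for (int t = 0; t < nw; ++t) {
      const double *A = &wp[9 * t], *B = &wp[9 * t + 3], *C = &wp[9 * t + 6];
      double AB[3], AC[3], AP[3];
      for (int i = 0; i < 3; ++i) {
        AB[i] = B[i] - A[i]; AC[i] = C[i] - A[i]; AP[i] = x[i] - A[i];
      }
      double d1 = AB[0]*AB[0]+AB[1]*AB[1]+AB[2]*AB[2];
      double d2 = AB[0]*AC[0]+AB[1]*AC[1]+AB[2]*AC[2];
      double d3 = AC[0]*AC[0]+AC[1]*AC[1]+AC[2]*AC[2];
      double r1 = AP[0]*AB[0]+AP[1]*AB[1]+AP[2]*AB[2];
      double r2 = AP[0]*AC[0]+AP[1]*AC[1]+AP[2]*AC[2];
      double den = d1 * d3 - d2 * d2;
      double s = (d3 * r1 - d2 * r2) / den;
      double tt = (d1 * r2 - d2 * r1) / den;
      if (s < 0) s = 0; if (tt < 0) tt = 0;
      if (s + tt > 1) { double sc = 1.0 / (s + tt); s *= sc; tt *= sc; }
      double q[3], d = 0;
      for (int i = 0; i < 3; ++i) {
        q[i] = A[i] + s * AB[i] + tt * AC[i];
        d += (x[i] - q[i]) * (x[i] - q[i]);
      }
      if (d < best) { best = d; tf = t;
        proj[0] = q[0]; proj[1] = q[1]; proj[2] = q[2]; }
    }
  };
  // orient wall normals toward the body: contact nodes may start
  // exactly on the wall (zero offset), so the side is taken from the
  // body centroid, which is always strictly interior
  double cen[3] = {0, 0, 0};
  for (int n = 0; n < nn; ++n) {
    cen[0] += X[n]; cen[1] += X[n + nn]; cen[2] += X[n + 2 * nn];
  }
  for (int i = 0; i < 3; ++i) cen[i] /= nn;
  for (int ci = 0; ci < nc; ++ci) {
    int n = contact_nodes[ci] - 1;
    double x0[3] = {X[n], X[n + nn], X[n + 2 * nn]};
    int tf = 0; double pr[3];
    closest_facet(x0, tf, pr);
    double dotp = 0;
    for (int i = 0; i < 3; ++i) dotp += (cen[i] - pr[i]) * wn[3 * tf + i];
    side[ci] = (dotp >= 0) ? 1.0 : -1.0;
  }

  const int ns = record_steps.size();
  List snapshots(ns);
  NumericVector times(ns);
  NumericMatrix nipple(ns, 3), energy(ns, 6);
  double W_ext = 0.0, W_int = 0.0, diss = 0.0;
  int rec_ptr = 0;
  const double kpen_fac = penalty_beta / (dt * dt);

  auto apply_bc = [&](double *arr) {
    for (int k = 0; k < bc_x.size(); ++k) arr[bc_x[k] - 1] = 0.0;
    for (int k = 0; k < bc_z.size(); ++k) arr[bc_z[k] - 1 + 2 * nn] = 0.0;
    for (int k = 0; k < bc_fixed.size(); ++k) {
      int n = bc_fixed[k] - 1;
      arr[n] = 0.0; arr[n + nn] = 0.0; arr[n + 2 * nn] = 0.0;
    }
  };

  for (int step = 0; step <= nsteps; ++step) {
    ForceResult r = assemble(fe, X, u.data(), REAL(mu), REAL(K), REAL(g),
                             REAL(tau), (step > 0 ? dt : -1.0),
                             s_el.data(), h_state.data(), f_int.data(),
                             fbar);
    if (!r.ok)
      stop("element %d inverted at step %d (t = %g s); reduce the time "
           "step or stiffen K0", r.bad_elem + 1, step, step * dt);
    diss += r.diss_rate * dt;

    // external forces: gravity (optionally ramped) + contact
    double gscale = 1.0;
    if (ramp_time > 0.0) {
      double t_now = step * dt;
      gscale = t_now >= ramp_time ? 1.0 : t_now / ramp_time;
    }
    for (int n = 0; n < nn; ++n) {
      f_ext[n] = mass[n] * gscale * gx;
      f_ext[n + nn] = mass[n] * gscale * gy;
      f_ext[n + 2 * nn] = mass[n] * gscale * gz;
    }
    for (int ci = 0; ci < nc; ++ci) {
      const int n = contact_nodes[ci] - 1;
      double x[3] = {X[n] + u[n], X[n + nn] + u[n + nn],
                     X[n + 2 * nn] + u[n + 2 * nn]};
      int tf; double pr[3];
      if (anchor[ci] < 0) {
        closest_facet(x, tf, pr);
        double gap = 0;
        for (int i = 0; i < 3; ++i)
          gap += (x[i] - pr[i]) * side[ci] * wn[3 * tf + i];
        if (gap >= 0) continue;
        anchor[ci] = tf; // small sliding: keep the first-contact facet
        for (int i = 0; i < 3; ++i) anchor_pt[3 * ci + i] = pr[i];
      }
      tf = anchor[ci];
      const double nrm[3] = {side[ci] * wn[3 * tf],
                             side[ci] * wn[3 * tf + 1],
                             side[ci] * wn[3 * tf + 2]};
      const double rel[3] = {x[0] - anchor_pt[3 * ci],
                             x[1] - anchor_pt[3 * ci + 1],
                             x[2] - anchor_pt[3 * ci + 2]};
      const double gap = rel[0]*nrm[0] + rel[1]*nrm[1] + rel[2]*nrm[2];
      if (gap >= 0) continue; // separated; anchor retained
      if (-gap > max_pen) max_pen = -gap;
      const double kpen = kpen_fac * mass[n];
      const double fn = -kpen * gap;
      double ft[3], tl = 0;
      for (int i = 0; i < 3; ++i) {
        const double t_i = rel[i] - gap * nrm[i];
        ft[i] = -kpen * t_i;
        tl += ft[i] * ft[i];
      }
      tl = std::sqrt(tl);
      const double cap = friction * fn;
      if (tl > cap && tl > 0) {
        const double sc = cap / tl;
        for (int i = 0; i < 3; ++i) {
          ft[i] *= sc;
          // slip: drag the anchor so the spring sits on the cone
          anchor_pt[3 * ci + i] += (1.0 - sc) * (rel[i] - gap * nrm[i]);
        }
      }
      for (int i = 0; i < 3; ++i)
        f_ext[n + i * nn] += fn * nrm[i] + ft[i];
    }
    apply_bc(f_ext.data()); // constrained dofs: no external work

    if (rec_ptr < ns && record_steps[rec_ptr] == step) {
      double ke = 0;
      for (int n = 0; n < nn; ++n)
        ke += 0.5 * mass[n] * (v[n] * v[n] + v[n + nn] * v[n + nn] +
                               v[n + 2 * nn] * v[n + 2 * nn]);
      NumericMatrix snap(nn, 3);
      for (int n = 0; n < nn; ++n) {
        snap(n, 0) = u[n]; snap(n, 1) = u[n + nn]; snap(n, 2) = u[n + 2 * nn];
        if (!std::isfinite(u[n]) || !std::isfinite(u[n + nn]) ||
            !std::isfinite(u[n + 2 * nn]))
          stop("NaN displacement detected at step %d", step);
      }
      snapshots[rec_ptr] = snap;
      times[rec_ptr] = step * dt;
      const int np = nipple_node - 1;
      nipple(rec_ptr, 0) = X[np] + u[np];
      nipple(rec_ptr, 1) = X[np + nn] + u[np + nn];
      nipple(rec_ptr, 2) = X[np + 2 * nn] + u[np + 2 * nn];
      energy(rec_ptr, 0) = ke;
      energy(rec_ptr, 1) = r.strain_energy;
      energy(rec_ptr, 2) = W_ext;
      energy(rec_ptr, 3) = W_int;
      energy(rec_ptr, 4) = diss;
      energy(rec_ptr, 5) = max_pen;
      ++rec_ptr;
    }
    if (step == nsteps) break;

    // central-difference update (half step at start) with optional
    // mass-proportional damping
    const double dteff = (step == 0) ? 0.5 * dt : dt;
    const double cd = damping * dteff;
    for (int i = 0; i < 3 * nn; ++i) {
      const int n = i % nn;
      const double a = (f_ext[i] - f_int[i]) / mass[n];
      v[i] = ((1.0 - 0.5 * cd) * v[i] + dteff * a) / (1.0 + 0.5 * cd);
      u_new[i] = u[i] + dt * v[i];
    }
    apply_bc(u_new.data());
    apply_bc(v.data());
    for (int i = 0; i < 3 * nn; ++i) {
      // discrete power identity: f^n . (u^{n+1} - u^{n-1})/2; the half
      // start (v jumps 0 -> dt/2 a) contributes f . du/4 to the energy
      const double mid = (step == 0) ? 0.25 * (u_new[i] - u[i])
                                     : 0.5 * (u_new[i] - u_prev[i]);
      W_ext += f_ext[i] * mid;
      W_int += f_int[i] * mid;
    }
    std::swap(u_prev, u);
    std::swap(u, u_new);
    if (step == 0) u_new = u_prev; // keep buffers consistent
  }

  return List::create(_["times"] = times, _["snapshots"] = snapshots,
                      _["nipple"] = nipple, _["energy"] = energy,
                      _["max_penetration"] = max_pen);
}
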