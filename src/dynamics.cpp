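#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// C-alpha structure-based (Go-type) two-chain force field with inter-chain
// flat-bottom coupling restraints and a harmonic ligand-site (cluster)
// centroid restraint.  All indices arriving from R are 1-based.

struct Topo {
  int n, nA;
  std::vector<int> b1, b2; std::vector<double> b0; double kb;
  std::vector<int> a1, a2, a3; std::vector<double> a0; double ka;
  std::vector<int> d1, d2, d3, d4; std::vector<double> d0; double kd;
  std::vector<int> c1, c2; std::vector<double> sig; double eps;
  double rep_sigma, rep_eps;
  std::vector<char> excl; // n*n, pairs excluded from generic repulsion
  std::vector<int> r1, r2; std::vector<double> r_up, r_k;
  std::vector<double> g_r0, g_w, g_depth; // Gaussian localization wells
  double r_lin; // harmonic-to-linear switch width (force cap = k * r_lin)
  double res_scale = 1.0; // restraint coupling ramp (slow growth during SA)
  bool has_cluster;
  std::vector<int> clA, clB; double cl_r0, cl_k;
};

static void unpack(const List& topo, Topo& T) {
  T.n = as<int>(topo["n"]); T.nA = as<int>(topo["nA"]);
  IntegerMatrix B = topo["bonds"]; NumericVector b0 = topo["b0"];
  T.kb = as<double>(topo["kb"]);
  for (int i = 0; i < B.nrow(); ++i) {
    T.b1.push_back(B(i, 0) - 1); T.b2.push_back(B(i, 1) - 1);
    T.b0.push_back(b0[i]);
  }
  IntegerMatrix A = topo["angles"]; NumericVector a0 = topo["a0"];
  T.ka = as<double>(topo["ka"]);
  for (int i = 0; i < A.nrow(); ++i) {
    T.a1.push_back(A(i, 0) - 1); T.a2.push_back(A(i, 1) - 1);
    T.a3.push_back(A(i, 2) - 1); T.a0.push_back(a0[i]);
  }
  IntegerMatrix D = topo["dihedrals"]; NumericVector d0 = topo["d0"];
  T.kd = as<double>(topo["kd"]);
  for (int i = 0; i < D.nrow(); ++i) {
    T.d1.push_back(D(i, 0) - 1); T.d2.push_back(D(i, 1) - 1);
    T.d3.push_back(D(i, 2) - 1); T.d4.push_back(D(i, 3) - 1);
    T.d0.push_back(d0[i]);
  }
  IntegerMatrix C = topo["contacts"]; NumericVector sg = topo["sigma"];
  T.eps = as<double>(topo["eps"]);
  for (int i = 0; i < C.nrow(); ++i) {
    T.c1.push_back(C(i, 0) - 1); T.c2.push_back(C(i, 1) - 1);
    T.sig.push_back(sg[i]);
  }
  T.rep_sigma = as<double>(topo["rep_sigma"]);
  T.rep_eps = as<double>(topo["rep_eps"]);
  // repulsion exclusions: same-chain residue separation < 3 and native pairs
  T.excl.assign((size_t)T.n * T.n, 0);
  auto ex = [&](int i, int j) {
    T.excl[(size_t)i * T.n + j] = 1; T.excl[(size_t)j * T.n + i] = 1;
  };
  for (int i = 0; i < T.n; ++i)
    for (int j = i + 1; j < T.n; ++j) {
      bool sameA = (i < T.nA) == (j < T.nA);
      if (sameA && (j - i) < 3) ex(i, j);
    }
  for (size_t k = 0; k < T.c1.size(); ++k) ex(T.c1[k], T.c2[k]);
  IntegerMatrix R = topo["restraints"];
  NumericVector rup = topo["r_up"], rk = topo["r_k"];
  NumericVector gr0 = topo["g_r0"], gw = topo["g_w"], gd = topo["g_depth"];
  for (int i = 0; i < R.nrow(); ++i) {
    T.r1.push_back(R(i, 0) - 1); T.r2.push_back(R(i, 1) - 1);
    T.r_up.push_back(rup[i]); T.r_k.push_back(rk[i]);
    T.g_r0.push_back(gr0[i]); T.g_w.push_back(gw[i]);
    T.g_depth.push_back(gd[i]);
  }
  T.r_lin = as<double>(topo["r_lin"]);
  T.has_cluster = as<bool>(topo["has_cluster"]);
  if (T.has_cluster) {
    IntegerVector cA = topo["cluster_a"], cB = topo["cluster_b"];
    for (int i = 0; i < cA.size(); ++i) T.clA.push_back(cA[i] - 1);
    for (int i = 0; i < cB.size(); ++i) T.clB.push_back(cB[i] - 1);
    T.cl_r0 = as<double>(topo["cluster_r0"]);
    T.cl_k = as<double>(topo["cluster_k"]);
  } else { T.cl_r0 = 0; T.cl_k = 0; }
}

static inline double dist3(const double* x, int i, int j, double* d) {
  d[0] = x[3 * i] - x[3 * j];
  d[1] = x[3 * i + 1] - x[3 * j + 1];
  d[2] = x[3 * i + 2] - x[3 * j + 2];
  return std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
}

// Full potential energy and (optionally) forces; returns component breakdown.
static double energy_forces(const Topo& T, const double* x, double* f,
                            double* comp /* 7 slots or NULL */) {
  const int n = T.n;
  if (f) std::fill(f, f + 3 * n, 0.0);
  double e_bond = 0, e_ang = 0, e_dih = 0, e_con = 0, e_rep = 0,
         e_res = 0, e_clu = 0;
  double d[3];

  for (size_t k = 0; k < T.b1.size(); ++k) {
    int i = T.b1[k], j = T.b2[k];
    double r = dist3(x, i, j, d);
    double dr = r - T.b0[k];
    e_bond += 0.5 * T.kb * dr * dr;
    if (f) {
      double c = -T.kb * dr / r;
      for (int u = 0; u < 3; ++u) { f[3*i+u] += c * d[u]; f[3*j+u] -= c * d[u]; }
    }
  }

  for (size_t k = 0; k < T.a1.size(); ++k) {
    int i = T.a1[k], j = T.a2[k], l = T.a3[k];
    double u[3], v[3];
    double ru = dist3(x, i, j, u), rv = dist3(x, l, j, v);
    double cs = (u[0]*v[0] + u[1]*v[1] + u[2]*v[2]) / (ru * rv);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs);
    double dth = th - T.a0[k];
    e_ang += 0.5 * T.ka * dth * dth;
    if (f) {
      double sn = std::sqrt(std::max(1e-16, 1.0 - cs * cs));
      double dV = T.ka * dth;
      for (int w = 0; w < 3; ++w) {
        double dci = (v[w] / (ru * rv)) - cs * u[w] / (ru * ru);
        double dcl = (u[w] / (ru * rv)) - cs * v[w] / (rv * rv);
        double fi = dV * dci / sn;  // -dV/dth * dth/dri, dth = -dcos/sn
        double fl = dV * dcl / sn;
        f[3*i+w] += fi; f[3*l+w] += fl; f[3*j+w] -= (fi + fl);
      }
    }
  }

  for (size_t k = 0; k < T.d1.size(); ++k) {
    int i = T.d1[k], j = T.d2[k], l = T.d3[k], m = T.d4[k];
    double b1[3], b2[3], b3[3];
    for (int w = 0; w < 3; ++w) {
      b1[w] = x[3*j+w] - x[3*i+w];
      b2[w] = x[3*l+w] - x[3*j+w];
      b3[w] = x[3*m+w] - x[3*l+w];
    }
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                     b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                     b2[0]*b3[1]-b2[1]*b3[0] };
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double b2n = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    double m1[3] = { n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                     n1[0]*n2[1]-n1[1]*n2[0] };
    double sy = (m1[0]*b2[0]+m1[1]*b2[1]+m1[2]*b2[2]) / b2n;
    double cx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double phi = std::atan2(sy, cx);
    double dphi = phi - T.d0[k];
    e_dih += T.kd * ((1.0 - std::cos(dphi)) + 0.5 * (1.0 - std::cos(3.0 * dphi)));
    if (f) {
      double dV = T.kd * (std::sin(dphi) + 1.5 * std::sin(3.0 * dphi));
      double gi[3], gm[3];
      for (int w = 0; w < 3; ++w) {
        gi[w] = -(b2n / n1sq) * n1[w];   // dphi/dri
        gm[w] =  (b2n / n2sq) * n2[w];   // dphi/drm
      }
      double s12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (b2n * b2n);
      double s32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (b2n * b2n);
      for (int w = 0; w < 3; ++w) {
        double gj = -(1.0 + s12) * gi[w] + s32 * gm[w];
        double gl = s12 * gi[w] - (1.0 + s32) * gm[w];
        f[3*i+w] -= dV * gi[w];
        f[3*j+w] -= dV * gj;
        f[3*l+w] -= dV * gl;
        f[3*m+w] -= dV * gm[w];
      }
    }
  }

  for (size_t k = 0; k < T.c1.size(); ++k) {
    int i = T.c1[k], j = T.c2[k];
    double r = dist3(x, i, j, d);
    double sr = T.sig[k] / r;
    double sr2 = sr * sr, sr10 = sr2*sr2*sr2*sr2*sr2, sr12 = sr10 * sr2;
    e_con += T.eps * (5.0 * sr12 - 6.0 * sr10);
    if (f) {
      double dV = 60.0 * T.eps * (sr10 - sr12) / r; // dV/dr
      double c = -dV / r;
      for (int u = 0; u < 3; ++u) { f[3*i+u] += c * d[u]; f[3*j+u] -= c * d[u]; }
    }
  }

  // generic excluded-volume repulsion
  const double rs = T.rep_sigma;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (T.excl[(size_t)i * n + j]) continue;
      double r = dist3(x, i, j, d);
      double sr = rs / r;
      double sr2 = sr*sr, sr6 = sr2*sr2*sr2, sr12 = sr6*sr6;
      e_rep += T.rep_eps * sr12;
      if (f) {
        double dV = -12.0 * T.rep_eps * sr12 / r;
        double c = -dV / r;
        for (int u = 0; u < 3; ++u) { f[3*i+u] += c * d[u]; f[3*j+u] -= c * d[u]; }
      }
    }
  }

  // harmonic-then-linear wall: beyond `lin` the force is capped at k*lin,
  // so distant chains are pulled gently instead of being ripped apart
  const double lin = T.r_lin;
  auto wall = [lin](double dr, double kk, double& dV) {
    if (dr <= lin) { dV += kk * dr; return 0.5 * kk * dr * dr; }
    dV += kk * lin;
    return 0.5 * kk * lin * lin + kk * lin * (dr - lin);
  };

  // coupling restraints: flat-bottom capped wall plus a short-range
  // Gaussian localization well
  for (size_t k = 0; k < T.r1.size(); ++k) {
    int i = T.r1[k], j = T.r2[k];
    double r = dist3(x, i, j, d);
    double dV = 0.0;
    if (r > T.r_up[k])
      e_res += wall(r - T.r_up[k], T.res_scale * T.r_k[k], dV);
    if (T.g_depth[k] > 0.0) {
      double depth = T.res_scale * T.g_depth[k];
      double dr = r - T.g_r0[k];
      double w2 = T.g_w[k] * T.g_w[k];
      double g = std::exp(-0.5 * dr * dr / w2);
      e_res += -depth * g;
      dV += depth * g * dr / w2;
    }
    if (f && dV != 0.0) {
      double c = -dV / r;
      for (int u = 0; u < 3; ++u) { f[3*i+u] += c * d[u]; f[3*j+u] -= c * d[u]; }
    }
  }

  // harmonic cluster (ligand-site centroid) restraint
  if (T.has_cluster) {
    double ca[3] = {0,0,0}, cb[3] = {0,0,0};
    const double na = T.clA.size(), nb = T.clB.size();
    for (size_t k = 0; k < T.clA.size(); ++k)
      for (int u = 0; u < 3; ++u) ca[u] += x[3*T.clA[k]+u] / na;
    for (size_t k = 0; k < T.clB.size(); ++k)
      for (int u = 0; u < 3; ++u) cb[u] += x[3*T.clB[k]+u] / nb;
    double dd[3] = { ca[0]-cb[0], ca[1]-cb[1], ca[2]-cb[2] };
    double r = std::sqrt(dd[0]*dd[0]+dd[1]*dd[1]+dd[2]*dd[2]);
    double dr = r - T.cl_r0;
    double dV = 0.0;
    double sgn = dr >= 0 ? 1.0 : -1.0;
    e_clu += wall(std::fabs(dr), T.res_scale * T.cl_k, dV);
    if (f && r > 1e-12) {
      double c = -sgn * dV / r;
      for (size_t k = 0; k < T.clA.size(); ++k)
        for (int u = 0; u < 3; ++u) f[3*T.clA[k]+u] += c * dd[u] / na;
      for (size_t k = 0; k < T.clB.size(); ++k)
        for (int u = 0; u < 3; ++u) f[3*T.clB[k]+u] -= c * dd[u] / nb;
    }
  }

  if (comp) {
    comp[0] = e_bond; comp[1] = e_ang; comp[2] = e_dih; comp[3] = e_con;
    comp[4] = e_rep; comp[5] = e_res; comp[6] = e_clu;
  }
  return e_bond + e_ang + e_dih + e_con + e_rep + e_res + e_clu;
}

// [[Rcpp::export]]
List cpp_sbm_energy(const NumericMatrix& coords, const List& topo,
                    bool forces = true) {
  Topo T; unpack(topo, T);
  std::vector<double> x(3 * T.n);
  for (int i = 0; i < T.n; ++i)
    for (int u = 0; u < 3; ++u) x[3*i+u] = coords(i, u);
  std::vector<double> f(3 * T.n, 0.0);
  double comp[7];
  double E = energy_forces(T, x.data(), forces ? f.data() : (double*)0, comp);
  NumericMatrix F(T.n, 3);
  double fmax = 0.0;
  if (forces) {
    for (int i = 0; i < T.n; ++i)
      for (int u = 0; u < 3; ++u) {
        F(i, u) = f[3*i+u];
        fmax = std::max(fmax, std::fabs(f[3*i+u]));
      }
  }
  return List::create(
    _["energy"] = E,
    _["components"] = NumericVector::create(
      _["bond"] = comp[0], _["angle"] = comp[1], _["dihedral"] = comp[2],
      _["contact"] = comp[3], _["repulsion"] = comp[4],
      _["restraint"] = comp[5], _["cluster"] = comp[6]),
    _["forces"] = F, _["max_force"] = fmax);
}

// Langevin (BAOAB) dynamics with linear temperature annealing.
// Uses R's RNG for the thermal noise, so R-side set.seed() gives
// bit-reproducible trajectories.
// [[Rcpp::export]]
List cpp_anneal(const NumericMatrix& coords, const List& topo,
                double dt, double gamma, double t_init, double t_final,
                int nsteps, int trace_stride, bool restraint_ramp = true) {
  Topo T; unpack(topo, T);
  const int n = T.n;
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int u = 0; u < 3; ++u) x[3*i+u] = coords(i, u);
  for (int i = 0; i < 3 * n; ++i) v[i] = std::sqrt(t_init) * norm_rand();

  const double c1 = std::exp(-gamma * dt);
  const double c2base = std::sqrt(1.0 - c1 * c1);
  double E = energy_forces(T, x.data(), f.data(), 0);
  std::vector<double> tr_step, tr_temp, tr_e;

  for (int s = 0; s < nsteps; ++s) {
    double frac = (nsteps > 1) ? (double)s / (nsteps - 1) : 1.0;
    double temp = t_init + (t_final - t_init) * frac;
    // slow-growth restraints: chains are reeled in as the bath cools, so
    // they dock after, not before, their folds have re-equilibrated
    if (restraint_ramp) T.res_scale = frac;
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    double c2 = c2base * std::sqrt(temp);
    for (int i = 0; i < 3 * n; ++i) v[i] = c1 * v[i] + c2 * norm_rand();
    for (int i = 0; i < 3 * n; ++i) x[i] += 0.5 * dt * v[i];
    E = energy_forces(T, x.data(), f.data(), 0);
    for (int i = 0; i < 3 * n; ++i) v[i] += 0.5 * dt * f[i];

    if (trace_stride > 0 && (s % trace_stride == 0 || s == nsteps - 1)) {
      tr_step.push_back(s + 1); tr_temp.push_back(temp); tr_e.push_back(E);
    }
    if (s % 1000 == 0) {
      Rcpp::checkUserInterrupt();
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i])) {
          double fm = 0;
          for (int k = 0; k < 3 * n; ++k) fm = std::max(fm, std::fabs(f[k]));
          stop("integration diverged at step %d (max |force| = %g)", s, fm);
        }
    }
  }
  for (int i = 0; i < 3 * n; ++i)
    if (!std::isfinite(x[i]))
      stop("integration diverged at final step: non-finite coordinate");

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int u = 0; u < 3; ++u) out(i, u) = x[3*i+u];
  NumericMatrix trace(tr_step.size(), 3);
  for (size_t k = 0; k < tr_step.size(); ++k) {
    trace(k, 0) = tr_step[k]; trace(k, 1) = tr_temp[k]; trace(k, 2) = tr_e[k];
  }
  colnames(trace) = CharacterVector::create("step", "temperature", "energy");
  return List::create(_["coords"] = out, _["trace"] = trace);
}

// FIRE local energy minimization (Bitzek et al. style parameters).
// [[Rcpp::export]]
List cpp_minimize_fire(const NumericMatrix& coords, const List& topo,
                       double tol, int max_iter) {
  Topo T; unpack(topo, T);
  const int n = T.n, nd = 3 * n;
  std::vector<double> x(nd), v(nd, 0.0), f(nd);
  for (int i = 0; i < n; ++i)
    for (int u = 0; u < 3; ++u) x[3*i+u] = coords(i, u);

  double dt = 1e-3, dtmax = 1e-2, alpha = 0.1;
  const double finc = 1.1, fdec = 0.5, alpha0 = 0.1, falpha = 0.99;
  int npos = 0, it = 0;
  double E = energy_forces(T, x.data(), f.data(), 0);
  double fmax = 0;
  for (int i = 0; i < nd; ++i) fmax = std::max(fmax, std::fabs(f[i]));

  while (fmax > tol && it < max_iter) {
    double P = 0;
    for (int i = 0; i < nd; ++i) P += f[i] * v[i];
    if (P > 0) {
      double vn = 0, fn = 0;
      for (int i = 0; i < nd; ++i) { vn += v[i]*v[i]; fn += f[i]*f[i]; }
      vn = std::sqrt(vn); fn = std::sqrt(std::max(fn, 1e-300));
      for (int i = 0; i < nd; ++i)
        v[i] = (1.0 - alpha) * v[i] + alpha * vn * f[i] / fn;
      if (++npos > 5) { dt = std::min(dt * finc, dtmax); alpha *= falpha; }
    } else {
      // backtrack half a step and restart the velocity (FIRE 2.0)
      for (int i = 0; i < nd; ++i) x[i] -= 0.5 * dt * v[i];
      std::fill(v.begin(), v.end(), 0.0);
      dt *= fdec; alpha = alpha0; npos = 0;
    }
    const double dmax = 0.1; // cap per-step displacement (Angstrom)
    for (int i = 0; i < nd; ++i) {
      v[i] += dt * f[i];
      double dx = dt * v[i];
      if (dx > dmax) dx = dmax; else if (dx < -dmax) dx = -dmax;
      x[i] += dx;
    }
    E = energy_forces(T, x.data(), f.data(), 0);
    fmax = 0;
    for (int i = 0; i < nd; ++i) fmax = std::max(fmax, std::fabs(f[i]));
    if (++it % 500 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int u = 0; u < 3; ++u) out(i, u) = x[3*i+u];
  return List::create(_["coords"] = out, _["energy"] = E,
                      _["max_force"] = fmax, _["iterations"] = it);
}
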