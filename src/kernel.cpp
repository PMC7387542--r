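// Shared Brownian-dynamics / kinetic Monte-Carlo kernel.
//
// One kernel serves every simulation in the package: an isolated
// protofilament (n_pf = 1, lateral interactions off), the 13-PF lattice,
// and either of the mechanical couplers (force bead, Dam1 ring, obstacle
// sphere).  Monomers carry planar coordinates {x = radial deviation from
// the wall cylinder, z = axial, tau = in-plane rotation}; PF n lives in the
// radial plane at azimuth 2*pi*n/13.  Units: nm, s, kcal/mol, rad.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
#include "mtdyn_rng.h"

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif

using namespace Rcpp;

namespace {

struct PFState {
  std::vector<double> x, z, tau;
  std::vector<int> nuc;  // per dimer: 0 = GDP, 1 = GTP
  int mob;               // first mobile monomer (0-based); below is frozen
};

struct Geom {
  int n_pf;
  bool lateral;
  double r_wall, r_tub, s_site;
  std::vector<double> cphi, sphi;
};

struct Mech {
  double k_intra, theta0, k_rep;
  double B[2];  // per nucleotide (GDP, GTP)
};

struct Inter {
  double a_lat, r_lat, a_long, b_long, r_long;
  double b_lat[2];
};

// breakable bond, Morse-like with activation barrier:
// E(r) = 2 a (r/w)^2 exp(-r/w) - b exp(-r^2/w^2)
inline double bond_e(double r, double a, double b, double w) {
  const double p = r / w;
  return 2.0 * a * p * p * std::exp(-p) - b * std::exp(-p * p);
}

// (dE/dr)/r, finite at r = 0
inline double bond_ffac(double r, double a, double b, double w) {
  if (r > 12.0 * w) return 0.0;
  if (r < 1e-10) return (4.0 * a + 2.0 * b) / (w * w);
  const double p = r / w;
  const double dedr = (2.0 * a / w) * p * (2.0 - p) * std::exp(-p) +
                      (2.0 * b / w) * p * std::exp(-p * p);
  return dedr / r;
}

struct Bead {  // single Dam1 subunit dragged axially (single-PF force assay)
  bool on = false;
  double x = 7.0, z = 0.0, R = 3.0, F = 0.0, gamma = 1.0;
};

struct RingC {  // 13-subunit Dam1 ring
  bool on = false;
  double R_dam1 = 3.0, l0 = 5.0, lmax = 6.0, klink = 0.01, Edep = 0.005;
  double F_sub = 0.0, gamma = 1.0, k_ring = 100.0, rest = 0.0;
  int bind_stride = 500;
  std::vector<double> x, z;
  std::vector<int> bound;  // monomer index per subunit, -1 = unbound
};

struct Obst {  // large sphere opposing growth, axial motion only
  bool on = false;
  double R = 2500.0, z = 0.0, F = 0.0, gamma = 1.0;
};

struct Sim {
  std::vector<PFState> pf;
  Geom geom;
  Mech mech;
  Inter inter;
  Bead bead;
  RingC ring;
  Obst obst;

  // scratch gradients and per-step trig caches
  std::vector<std::vector<double>> gx, gz, gt, sq, cq;
  std::vector<double> grx, grz;
  double gbz = 0.0, goz = 0.0;

  int nuc_of(int n, int k) const { return pf[n].nuc[k >> 1]; }

  void ensure_scratch() {
    gx.resize(pf.size());
    gz.resize(pf.size());
    gt.resize(pf.size());
    sq.resize(pf.size());
    cq.resize(pf.size());
    for (size_t n = 0; n < pf.size(); n++) {
      gx[n].assign(pf[n].x.size(), 0.0);
      gz[n].assign(pf[n].x.size(), 0.0);
      gt[n].assign(pf[n].x.size(), 0.0);
      sq[n].assign(pf[n].x.size(), 0.0);
      cq[n].assign(pf[n].x.size(), 0.0);
    }
    if (ring.on) {
      grx.assign(geom.n_pf, 0.0);
      grz.assign(geom.n_pf, 0.0);
    }
  }

  // in-plane longitudinal site: center +/- r_tub * u(tau), u = (sin, cos)
  // gradient of all interactions; fills gx/gz/gt (dU/dcoord)
  void forces() {
    const double rt = geom.r_tub;
    const int npf = geom.n_pf;
    for (int n = 0; n < npf; n++) {
      const PFState& p = pf[n];
      const int K = (int)p.x.size();
      std::memset(gx[n].data(), 0, sizeof(double) * K);
      std::memset(gz[n].data(), 0, sizeof(double) * K);
      std::memset(gt[n].data(), 0, sizeof(double) * K);
      const int kc = p.mob > 3 ? p.mob - 3 : 0;
      double* SQ = sq[n].data();
      double* CQ = cq[n].data();
      for (int k = kc; k < K; k++) {
#if defined(__GNUC__) && defined(__linux__)
        ::sincos(p.tau[k], &SQ[k], &CQ[k]);
#else
        SQ[k] = std::sin(p.tau[k]);
        CQ[k] = std::cos(p.tau[k]);
#endif
      }
    }
    if (ring.on) {
      std::fill(grx.begin(), grx.end(), 0.0);
      std::fill(grz.begin(), grz.end(), 0.0);
    }
    gbz = 0.0;
    goz = 0.0;

    for (int n = 0; n < npf; n++) {
      PFState& p = pf[n];
      const int K = (int)p.x.size();
      const int k0 = p.mob > 2 ? p.mob - 2 : 0;
      double* GX = gx[n].data();
      double* GZ = gz[n].data();
      double* GT = gt[n].data();

      for (int k = k0; k < K; k++) {
        // bending hinge (k-1, k); stiffness from monomer k's dimer
        if (k >= 1) {
          const double th = p.tau[k] - p.tau[k - 1];
          const double tq = mech.B[nuc_of(n, k)] * (th - mech.theta0);
          GT[k] += tq;
          GT[k - 1] -= tq;
        }
        // longitudinal connection (k, k+1)
        if (k + 1 < K) {
          const double sa = sq[n][k], ca = cq[n][k];
          const double sb = sq[n][k + 1], cb = cq[n][k + 1];
          const double ax = p.x[k] + rt * sa, az = p.z[k] + rt * ca;
          const double bx = p.x[k + 1] - rt * sb, bz = p.z[k + 1] - rt * cb;
          const double dx = ax - bx, dz = az - bz;
          const double r = std::sqrt(dx * dx + dz * dz);
          double f;
          if ((k & 1) == 0) {  // intra-dimer Hookean spring
            f = mech.k_intra;
          } else {  // inter-dimer breakable bond
            f = bond_ffac(r, inter.a_long, inter.b_long, inter.r_long);
          }
          GX[k] += f * dx;
          GZ[k] += f * dz;
          GT[k] += f * rt * (dx * ca - dz * sa);
          GX[k + 1] -= f * dx;
          GZ[k + 1] -= f * dz;
          GT[k + 1] += f * rt * (dx * cb - dz * sb);
        }
      }

      // lateral bonds with PF n+1 (3D distance between side sites)
      if (geom.lateral) {
        const int m = (n + 1) % npf;
        if (!(npf == 2 && n == 1)) {
          PFState& q = pf[m];
          const int Km = (int)q.x.size();
          const int kmin = std::min(p.mob, q.mob);
          const int kl0 = kmin > 2 ? kmin - 2 : 0;
          const int kmax = std::min(K, Km);
          const double cA = geom.cphi[n], sA = geom.sphi[n];
          const double cB = geom.cphi[m], sB = geom.sphi[m];
          const double S = geom.s_site, Rw = geom.r_wall;
          // site n->m: C + S*that;   site m->n: C - S*that
          const double oxA = -S * sA, oyA = S * cA;
          const double oxB = S * sB, oyB = -S * cB;
          double* GXm = gx[m].data();
          double* GZm = gz[m].data();
          for (int k = kl0; k < kmax; k++) {
            const double rA = Rw + p.x[k], rB = Rw + q.x[k];
            const double d1 = rA * cA + oxA - (rB * cB + oxB);
            const double d2 = rA * sA + oyA - (rB * sB + oyB);
            const double d3 = p.z[k] - q.z[k];
            const double r = std::sqrt(d1 * d1 + d2 * d2 + d3 * d3);
            const double b =
                0.5 * (inter.b_lat[nuc_of(n, k)] + inter.b_lat[q.nuc[k >> 1]]);
            const double f = bond_ffac(r, inter.a_lat, b, inter.r_lat);
            if (f != 0.0) {
              GX[k] += f * (d1 * cA + d2 * sA);
              GZ[k] += f * d3;
              GXm[k] -= f * (d1 * cB + d2 * sB);
              GZm[k] -= f * d3;
            }
          }
        }
      }

      // bead repulsion (single-PF force assay, in-plane)
      if (bead.on) {
        const double Rc = bead.R + geom.r_tub;
        for (int k = k0; k < K; k++) {
          const double dx = p.x[k] - bead.x, dz = p.z[k] - bead.z;
          const double d = std::sqrt(dx * dx + dz * dz);
          if (d < Rc && d > 1e-12) {
            const double f = -2.0 * mech.k_rep * (Rc - d) / d;
            GX[k] += f * dx;
            GZ[k] += f * dz;
            gbz -= f * dz;
          }
        }
      }

      // obstacle repulsion (3D, obstacle centred on the MT axis)
      if (obst.on) {
        const double Rc = obst.R + geom.r_tub;
        for (int k = k0; k < K; k++) {
          const double rho = geom.r_wall + p.x[k];
          const double dz = p.z[k] - obst.z;
          const double d = std::sqrt(rho * rho + dz * dz);
          if (d < Rc && d > 1e-12) {
            const double dedd = -2.0 * mech.k_rep * (Rc - d);
            GX[k] += dedd * rho / d;
            GZ[k] += dedd * dz / d;
            goz -= dedd * dz / d;
          }
        }
      }

      // ring subunit n interacts with tubulins of PF n (in-plane)
      if (ring.on) {
        const double Rc = ring.R_dam1 + geom.r_tub;
        const double xr = ring.x[n], zr = ring.z[n];
        for (int k = k0; k < K; k++) {
          const double dx = p.x[k] - xr, dz = p.z[k] - zr;
          const double d = std::sqrt(dx * dx + dz * dz);
          if (d < Rc && d > 1e-12) {
            const double f = -2.0 * mech.k_rep * (Rc - d) / d;
            GX[k] += f * dx;
            GZ[k] += f * dz;
            grx[n] -= f * dx;
            grz[n] -= f * dz;
          }
        }
        const int kb = ring.bound[n];
        if (kb >= 0 && kb < K) {
          const double dx = p.x[kb] - xr, dz = p.z[kb] - zr;
          const double d = std::sqrt(dx * dx + dz * dz);
          if (d >= ring.l0 && d <= ring.lmax && d > 1e-12) {
            const double f = ring.klink * (d - ring.l0) / d;
            GX[kb] += f * dx;
            GZ[kb] += f * dz;
            grx[n] -= f * dx;
            grz[n] -= f * dz;
          }
        }
      }
    }

    // ring internal springs (3D neighbour distance) + external load
    if (ring.on) {
      const int npf = geom.n_pf;
      for (int n = 0; n < npf; n++) {
        const int m = (n + 1) % npf;
        const double cA = geom.cphi[n], sA = geom.sphi[n];
        const double cB = geom.cphi[m], sB = geom.sphi[m];
        const double rA = geom.r_wall + ring.x[n];
        const double rB = geom.r_wall + ring.x[m];
        const double d1 = rA * cA - rB * cB;
        const double d2 = rA * sA - rB * sB;
        const double d3 = ring.z[n] - ring.z[m];
        const double d = std::sqrt(d1 * d1 + d2 * d2 + d3 * d3);
        if (d > 1e-12) {
          const double f = ring.k_ring * (d - ring.rest) / d;
          grx[n] += f * (d1 * cA + d2 * sA);
          grz[n] += f * d3;
          grx[m] -= f * (d1 * cB + d2 * sB);
          grz[m] -= f * d3;
        }
        grz[n] -= ring.F_sub;  // w(z) = -F z per subunit
      }
    }
    if (bead.on) gbz -= bead.F;
    if (obst.on) goz += obst.F;  // opposing load pushes minus-ward
  }

  double max_grad() const {
    double g = 0.0;
    for (int n = 0; n < geom.n_pf; n++) {
      const int K = (int)pf[n].x.size();
      for (int k = pf[n].mob; k < K; k++) {
        g = std::max(g, std::fabs(gx[n][k]));
        g = std::max(g, std::fabs(gz[n][k]));
        g = std::max(g, std::fabs(gt[n][k]));
      }
    }
    if (bead.on) g = std::max(g, std::fabs(gbz));
    if (obst.on) g = std::max(g, std::fabs(goz));
    if (ring.on)
      for (int n = 0; n < geom.n_pf; n++) {
        g = std::max(g, std::fabs(grx[n]));
        g = std::max(g, std::fabs(grz[n]));
      }
    return g;
  }
};

Geom geom_from(List g) {
  Geom out;
  out.n_pf = as<int>(g["n_pf"]);
  out.lateral = as<bool>(g["lateral"]);
  out.r_wall = as<double>(g["r_wall"]);
  out.r_tub = as<double>(g["r_tub"]);
  out.cphi.resize(out.n_pf);
  out.sphi.resize(out.n_pf);
  const double phi = 2.0 * M_PI / out.n_pf;
  out.s_site = out.r_wall * std::tan(phi / 2.0);
  for (int n = 0; n < out.n_pf; n++) {
    out.cphi[n] = std::cos(phi * n);
    out.sphi[n] = std::sin(phi * n);
  }
  return out;
}

Mech mech_from(List m) {
  Mech out;
  out.k_intra = as<double>(m["k_intra"]);
  out.theta0 = as<double>(m["theta0"]);
  out.k_rep = as<double>(m["k_rep"]);
  NumericVector B = m["B"];  // c(GDP, GTP)
  out.B[0] = B[0];
  out.B[1] = B[1];
  return out;
}

Inter inter_from(List v) {
  Inter out;
  out.a_lat = as<double>(v["a_lat"]);
  out.r_lat = as<double>(v["r_lat"]);
  out.a_long = as<double>(v["a_long"]);
  out.b_long = as<double>(v["b_long"]);
  out.r_long = as<double>(v["r_long"]);
  NumericVector b = v["b_lat"];
  out.b_lat[0] = b[0];
  out.b_lat[1] = b[1];
  return out;
}

std::vector<PFState> state_from(List pfs, List nucs, IntegerVector mob) {
  const int npf = pfs.size();
  std::vector<PFState> out(npf);
  for (int n = 0; n < npf; n++) {
    NumericMatrix m = pfs[n];
    const int K = m.nrow();
    out[n].x.resize(K);
    out[n].z.resize(K);
    out[n].tau.resize(K);
    for (int k = 0; k < K; k++) {
      out[n].x[k] = m(k, 0);
      out[n].z[k] = m(k, 1);
      out[n].tau[k] = m(k, 2);
    }
    IntegerVector nv = nucs[n];
    out[n].nuc.assign(nv.begin(), nv.end());
    out[n].mob = mob[n];
  }
  return out;
}

List state_to(const std::vector<PFState>& pf) {
  const int npf = (int)pf.size();
  List pfs(npf), nucs(npf);
  IntegerVector mob(npf);
  for (int n = 0; n < npf; n++) {
    const int K = (int)pf[n].x.size();
    NumericMatrix m(K, 3);
    for (int k = 0; k < K; k++) {
      m(k, 0) = pf[n].x[k];
      m(k, 1) = pf[n].z[k];
      m(k, 2) = pf[n].tau[k];
    }
    colnames(m) = CharacterVector::create("x", "z", "tau");
    pfs[n] = m;
    nucs[n] = IntegerVector(pf[n].nuc.begin(), pf[n].nuc.end());
    mob[n] = pf[n].mob;
  }
  return List::create(_["pf"] = pfs, _["nuc"] = nucs, _["mobile_from"] = mob);
}

// innermost separated inter-dimer bond above the frozen base, or -1.
// separated: beyond the barrier (r > 2 w) with |E_long| < thr.
int detach_bond(const PFState& p, const Geom& g, const Inter& in, double thr) {
  const int K = (int)p.x.size();
  const int ndim = K / 2;
  const int dmin = std::max(1, (p.mob + 1) / 2);
  for (int d = dmin; d < ndim; d++) {
    const int k = 2 * d - 1;  // monomer below the bond
    const double sa = std::sin(p.tau[k]), ca = std::cos(p.tau[k]);
    const double sb = std::sin(p.tau[k + 1]), cb = std::cos(p.tau[k + 1]);
    const double dx = p.x[k] + g.r_tub * sa - (p.x[k + 1] - g.r_tub * sb);
    const double dz = p.z[k] + g.r_tub * ca - (p.z[k + 1] - g.r_tub * cb);
    const double r = std::sqrt(dx * dx + dz * dz);
    if (r > 2.0 * in.r_long &&
        std::fabs(bond_e(r, in.a_long, in.b_long, in.r_long)) < thr)
      return d;
  }
  return -1;
}

}  // namespace

// [[Rcpp::export]]
List total_energy_cpp(List pfs, List nucs, IntegerVector mobile_from,
                      List geom, List mech, List inter) {
  Sim s;
  s.geom = geom_from(geom);
  s.mech = mech_from(mech);
  s.inter = inter_from(inter);
  s.pf = state_from(pfs, nucs, mobile_from);
  const double rt = s.geom.r_tub;
  double e_bend = 0, e_spring = 0, e_long = 0, e_lat = 0;
  for (int n = 0; n < s.geom.n_pf; n++) {
    const PFState& p = s.pf[n];
    const int K = (int)p.x.size();
    for (int k = 1; k < K; k++) {
      const double th = p.tau[k] - p.tau[k - 1];
      const double dd = th - s.mech.theta0;
      e_bend += 0.5 * s.mech.B[s.nuc_of(n, k)] * dd * dd;
    }
    for (int k = 0; k + 1 < K; k++) {
      const double ax = p.x[k] + rt * std::sin(p.tau[k]);
      const double az = p.z[k] + rt * std::cos(p.tau[k]);
      const double bx = p.x[k + 1] - rt * std::sin(p.tau[k + 1]);
      const double bz = p.z[k + 1] - rt * std::cos(p.tau[k + 1]);
      const double r = std::hypot(ax - bx, az - bz);
      if ((k & 1) == 0)
        e_spring += 0.5 * s.mech.k_intra * r * r;
      else
        e_long += bond_e(r, s.inter.a_long, s.inter.b_long, s.inter.r_long);
    }
    if (s.geom.lateral && s.geom.n_pf > 1) {
      const int m = (n + 1) % s.geom.n_pf;
      if (!(s.geom.n_pf == 2 && n == 1)) {
        const PFState& q = s.pf[m];
        const int kmax = std::min(K, (int)q.x.size());
        const double cA = s.geom.cphi[n], sA = s.geom.sphi[n];
        const double cB = s.geom.cphi[m], sB = s.geom.sphi[m];
        const double S = s.geom.s_site, Rw = s.geom.r_wall;
        for (int k = 0; k < kmax; k++) {
          const double rA = Rw + p.x[k], rB = Rw + q.x[k];
          const double d1 = rA * cA - S * sA - (rB * cB + S * sB);
          const double d2 = rA * sA + S * cA - (rB * sB - S * cB);
          const double d3 = p.z[k] - q.z[k];
          const double r = std::sqrt(d1 * d1 + d2 * d2 + d3 * d3);
          const double b = 0.5 * (s.inter.b_lat[s.nuc_of(n, k)] +
                                  s.inter.b_lat[q.nuc[k >> 1]]);
          e_lat += bond_e(r, s.inter.a_lat, b, s.inter.r_lat);
        }
      }
    }
  }
  return List::create(_["bend"] = e_bend, _["spring"] = e_spring,
                      _["longitudinal"] = e_long, _["lateral"] = e_lat,
                      _["total"] = e_bend + e_spring + e_long + e_lat);
}

// [[Rcpp::export]]
List detach_scan_cpp(List pfs, List nucs, IntegerVector mobile_from,
                     List geom, List inter, double thr_energy) {
  Geom g = geom_from(geom);
  Inter in = inter_from(inter);
  std::vector<PFState> pf = state_from(pfs, nucs, mobile_from);
  IntegerVector cut((int)pf.size());
  for (size_t n = 0; n < pf.size(); n++) {
    const int d = detach_bond(pf[n], g, in, thr_energy);
    cut[n] = d;  // -1 = intact; else dimers d..end detach (0-based)
  }
  return List::create(_["cut_dimer"] = cut);
}

// Main entry: propagate the system.  Returns final state, coarse trace,
// snapshots, event log and counters.  Errors on numerical instability.
// [[Rcpp::export]]
List bd_run_cpp(List pfs, List nucs, IntegerVector mobile_from, List geom,
                List mech, List inter, List kin, List coupler, List ctrl) {
  Sim s;
  s.geom = geom_from(geom);
  s.mech = mech_from(mech);
  s.inter = inter_from(inter);
  s.pf = state_from(pfs, nucs, mobile_from);

  // kinetics
  const bool kin_on = as<bool>(kin["enabled"]);
  const double p_add = kin_on ? as<double>(kin["p_add"]) : 0.0;
  const double p_hyd = kin_on ? as<double>(kin["p_hyd"]) : 0.0;
  const int kin_stride = kin_on ? as<int>(kin["kin_stride"]) : 0;
  const int detach_stride = as<int>(kin["detach_stride"]);
  const double detach_thr = as<double>(kin["detach_thr_energy"]);
  const int window_dimers = as<int>(kin["window_dimers"]);
  const bool detach_on = as<bool>(kin["detach_enabled"]);

  // coupler
  const std::string ctype = as<std::string>(coupler["type"]);
  if (ctype == "bead") {
    s.bead.on = true;
    s.bead.x = as<double>(coupler["x"]);
    s.bead.z = as<double>(coupler["z"]);
    s.bead.R = as<double>(coupler["R"]);
    s.bead.F = as<double>(coupler["F"]);
    s.bead.gamma = as<double>(coupler["gamma"]);
  } else if (ctype == "ring") {
    s.ring.on = true;
    s.ring.R_dam1 = as<double>(coupler["R_dam1"]);
    s.ring.l0 = as<double>(coupler["l0"]);
    s.ring.lmax = as<double>(coupler["l_max"]);
    s.ring.klink = as<double>(coupler["k_linker"]);
    s.ring.Edep = 0.5 * s.ring.klink * (s.ring.lmax - s.ring.l0) *
                  (s.ring.lmax - s.ring.l0);
    s.ring.F_sub = as<double>(coupler["F"]) / s.geom.n_pf;
    s.ring.gamma = as<double>(coupler["gamma"]);
    s.ring.k_ring = as<double>(coupler["k_ring"]);
    s.ring.bind_stride = as<int>(coupler["bind_stride"]);
    NumericVector rx = coupler["x"], rz = coupler["z"];
    s.ring.x.assign(rx.begin(), rx.end());
    s.ring.z.assign(rz.begin(), rz.end());
    s.ring.bound.assign(s.geom.n_pf, -1);
    const double Rr = s.geom.r_wall + rx[0];
    s.ring.rest = 2.0 * Rr * std::sin(M_PI / s.geom.n_pf);
  } else if (ctype == "obstacle") {
    s.obst.on = true;
    s.obst.R = as<double>(coupler["R"]);
    s.obst.z = as<double>(coupler["z"]);
    s.obst.F = as<double>(coupler["F"]);
    s.obst.gamma = as<double>(coupler["gamma"]);
  }

  // control
  const double dt = as<double>(ctrl["dt"]);
  const double nsteps_d = as<double>(ctrl["n_steps"]);
  const long long nsteps = (long long)nsteps_d;
  const double kBT = as<double>(ctrl["kBT"]);
  const double gamma_q = as<double>(ctrl["gamma_q"]);
  const double gamma_t = as<double>(ctrl["gamma_tau"]);
  const uint64_t seed = (uint64_t)as<double>(ctrl["seed"]);
  const int record_stride = as<int>(ctrl["record_stride"]);
  const int snap_stride = as<int>(ctrl["snap_stride"]);  // 0 = none
  const int monitor = as<int>(ctrl["monitor_index"]);    // -1 = off (0-based)
  const double th_hi = as<double>(ctrl["theta_curved"]);
  const double th_lo = as<double>(ctrl["theta_straight"]);
  const double relax_tol = as<double>(ctrl["relax_tol"]);  // 0 = plain BD
  const double max_disp = as<double>(ctrl["max_disp"]);

  const double cq = dt / gamma_q, ct = dt / gamma_t;
  const double nq = std::sqrt(2.0 * kBT * dt / gamma_q);
  const double nt = std::sqrt(2.0 * kBT * dt / gamma_t);
  const double cb = s.bead.on ? dt / s.bead.gamma : 0.0;
  const double nb = s.bead.on ? std::sqrt(2.0 * kBT * dt / s.bead.gamma) : 0.0;
  const double cr = s.ring.on ? dt / s.ring.gamma : 0.0;
  const double nr = s.ring.on ? std::sqrt(2.0 * kBT * dt / s.ring.gamma) : 0.0;
  const double co = s.obst.on ? dt / s.obst.gamma : 0.0;
  const double no = s.obst.on ? std::sqrt(2.0 * kBT * dt / s.obst.gamma) : 0.0;
  const bool noise = kBT > 0.0;

  mtdyn::Rng rng(seed);
  s.ensure_scratch();

  // straightening hysteresis state: 1 curved, 0 straight, -1 unset
  int mon_state = -1;
  long long n_straight = 0;
  if (monitor >= 1) {
    const double th = s.pf[0].tau[monitor] - s.pf[0].tau[monitor - 1];
    mon_state = th > th_hi ? 1 : (th < th_lo ? 0 : -1);
  }

  const long long nrec = record_stride > 0 ? nsteps / record_stride + 1 : 1;
  NumericMatrix trace((int)std::min<long long>(nrec, 2000000LL), 8);
  colnames(trace) = CharacterVector::create("t", "n_monomers", "n_gtp",
                                            "tip_z", "ring_z", "obstacle_z",
                                            "n_straightening", "theta_mon");
  int irec = 0;
  std::vector<List> snaps;
  std::vector<double> ev_t, ev_pf, ev_type, ev_val;

  bool converged = false, bead_escaped = false, ring_lost = false,
       exhausted = false;
  int bead_free_checks = 0;
  double bead_z_mark = s.bead.on ? s.bead.z : 0.0;
  long long steps_done = 0;

  auto record_row = [&](double t) {
    if (irec >= trace.nrow()) return;
    long long ktot = 0, ngtp = 0;
    double tipz = 0.0;
    for (int n = 0; n < s.geom.n_pf; n++) {
      ktot += s.pf[n].x.size();
      for (int d : s.pf[n].nuc) ngtp += d;
      tipz += s.pf[n].z.back();
    }
    trace(irec, 0) = t;
    trace(irec, 1) = (double)ktot;
    trace(irec, 2) = (double)ngtp;
    trace(irec, 3) = tipz / s.geom.n_pf;
    double rz = NA_REAL, oz = NA_REAL;
    if (s.ring.on) {
      rz = 0.0;
      for (double v : s.ring.z) rz += v;
      rz /= s.geom.n_pf;
    }
    if (s.obst.on) oz = s.obst.z;
    trace(irec, 4) = rz;
    trace(irec, 5) = oz;
    trace(irec, 6) = (double)n_straight;
    trace(irec, 7) =
        monitor >= 1 ? s.pf[0].tau[monitor] - s.pf[0].tau[monitor - 1]
                     : NA_REAL;
    irec++;
  };

  auto take_snapshot = [&](double t) {
    List st = state_to(s.pf);
    List snap = List::create(
        _["t"] = t, _["pf"] = st["pf"], _["nuc"] = st["nuc"],
        _["mobile_from"] = st["mobile_from"],
        _["ring_x"] = s.ring.on ? NumericVector(s.ring.x.begin(),
                                                s.ring.x.end())
                                : NumericVector(0),
        _["ring_z"] = s.ring.on ? NumericVector(s.ring.z.begin(),
                                                s.ring.z.end())
                                : NumericVector(0),
        _["obstacle_z"] = s.obst.on ? s.obst.z : NA_REAL);
    snaps.push_back(snap);
  };

  record_row(0.0);
  if (snap_stride > 0) take_snapshot(0.0);

  for (long long step = 1; step <= nsteps; step++) {
    s.forces();

    // integrate monomers
    for (int n = 0; n < s.geom.n_pf; n++) {
      PFState& p = s.pf[n];
      const int K = (int)p.x.size();
      double* GX = s.gx[n].data();
      double* GZ = s.gz[n].data();
      double* GT = s.gt[n].data();
      for (int k = p.mob; k < K; k++) {
        double dx = -cq * GX[k], dz = -cq * GZ[k], dtau = -ct * GT[k];
        if (noise) {
          dx += nq * rng.normal();
          dz += nq * rng.normal();
          dtau += nt * rng.normal();
        }
        if (std::fabs(dx) > max_disp || std::fabs(dz) > max_disp ||
            std::fabs(dtau) > 1.0 || dx != dx || dz != dz || dtau != dtau)
          stop("integration instability at step %d (pf %d, monomer %d)",
               (double)step, n + 1, k + 1);
        p.x[k] += dx;
        p.z[k] += dz;
        p.tau[k] += dtau;
      }
    }
    if (s.bead.on) {
      double dz = -cb * s.gbz;
      if (noise) dz += nb * rng.normal();
      if (std::fabs(dz) > max_disp || dz != dz)
        stop("integration instability at step %d (bead)", (double)step);
      s.bead.z += dz;
    }
    if (s.obst.on) {
      double dz = -co * s.goz;
      if (noise) dz += no * rng.normal();
      s.obst.z += dz;
    }
    if (s.ring.on) {
      const int npf = s.geom.n_pf;
      static thread_local std::vector<double> dxr, dzr;
      dxr.assign(npf, 0.0);
      dzr.assign(npf, 0.0);
      for (int n = 0; n < npf; n++) {
        dxr[n] = -cr * s.grx[n];
        dzr[n] = -cr * s.grz[n];
        if (noise) {
          dxr[n] += nr * rng.normal();
          dzr[n] += nr * rng.normal();
        }
      }
      // keep the ring centre on the MT axis: remove the two lateral
      // centre-translation modes from the radial displacement field
      double c1 = 0.0, c2 = 0.0;
      for (int n = 0; n < npf; n++) {
        c1 += dxr[n] * s.geom.cphi[n];
        c2 += dxr[n] * s.geom.sphi[n];
      }
      for (int n = 0; n < npf; n++) {
        dxr[n] -= (2.0 / npf) * (c1 * s.geom.cphi[n] + c2 * s.geom.sphi[n]);
        if (std::fabs(dxr[n]) > max_disp || std::fabs(dzr[n]) > max_disp ||
            dxr[n] != dxr[n] || dzr[n] != dzr[n])
          stop("integration instability at step %d (ring %d)", (double)step,
               n + 1);
        s.ring.x[n] += dxr[n];
        s.ring.z[n] += dzr[n];
      }
    }

    // straightening monitor
    if (monitor >= 1) {
      const double th = s.pf[0].tau[monitor] - s.pf[0].tau[monitor - 1];
      if (mon_state == 1) {
        if (th < th_lo) {
          mon_state = 0;
          n_straight++;
        }
      } else if (mon_state == 0) {
        if (th > th_hi) mon_state = 1;
      } else {
        if (th > th_hi) mon_state = 1;
        else if (th < th_lo) mon_state = 0;
      }
    }

    const double t = step * dt;

    // ring linker (re)binding and loss check
    if (s.ring.on && step % s.ring.bind_stride == 0) {
      for (int n = 0; n < s.geom.n_pf; n++) {
        PFState& p = s.pf[n];
        const int K = (int)p.x.size();
        const int kb = s.ring.bound[n];
        if (kb >= 0 && kb < K) {
          const double d =
              std::hypot(p.x[kb] - s.ring.x[n], p.z[kb] - s.ring.z[n]);
          if (d > s.ring.lmax) s.ring.bound[n] = -1;
        } else if (kb >= K) {
          s.ring.bound[n] = -1;  // partner detached with an oligomer
        }
        if (s.ring.bound[n] < 0) {
          int best = -1;
          double bestd = s.ring.lmax;
          for (int k = 0; k < K; k++) {
            const double d =
                std::hypot(p.x[k] - s.ring.x[n], p.z[k] - s.ring.z[n]);
            if (d <= bestd) {
              bestd = d;
              best = k;
            }
          }
          if (best >= 0) {
            s.ring.bound[n] = best;
            ev_t.push_back(t);
            ev_pf.push_back(n + 1);
            ev_type.push_back(4);
            ev_val.push_back(best + 1);
          }
        }
      }
      double mz = 0.0, mt2 = 0.0;
      for (int n = 0; n < s.geom.n_pf; n++) {
        mz += s.ring.z[n];
        mt2 = std::max(mt2, s.pf[n].z.back());
      }
      mz /= s.geom.n_pf;
      if (mz > mt2 + 10.0) {
        ring_lost = true;
        ev_t.push_back(t);
        ev_pf.push_back(0);
        ev_type.push_back(5);
        ev_val.push_back(0);
        steps_done = step;
        record_row(t);
        break;
      }
    }

    // kinetic Monte-Carlo layer
    if (kin_on && kin_stride > 0 && step % kin_stride == 0) {
      for (int n = 0; n < s.geom.n_pf; n++) {
        PFState& p = s.pf[n];
        if (rng.unif() < p_add) {
          const int K = (int)p.x.size();
          const double rt = s.geom.r_tub;
          const double t0 = p.tau[K - 1];
          const double t1 = t0 + s.mech.theta0, t2 = t1 + s.mech.theta0;
          const double x1 = p.x[K - 1] + rt * std::sin(t0) + rt * std::sin(t1);
          const double z1 = p.z[K - 1] + rt * std::cos(t0) + rt * std::cos(t1);
          const double x2 = x1 + rt * std::sin(t1) + rt * std::sin(t2);
          const double z2 = z1 + rt * std::cos(t1) + rt * std::cos(t2);
          bool blocked = false;
          if (s.obst.on) {
            const double Rc = s.obst.R + rt;
            const double r1 = s.geom.r_wall + x1, r2 = s.geom.r_wall + x2;
            if (std::sqrt(r1 * r1 + (z1 - s.obst.z) * (z1 - s.obst.z)) < Rc ||
                std::sqrt(r2 * r2 + (z2 - s.obst.z) * (z2 - s.obst.z)) < Rc)
              blocked = true;
          }
          if (!blocked) {
            p.x.push_back(x1);
            p.z.push_back(z1);
            p.tau.push_back(t1);
            p.x.push_back(x2);
            p.z.push_back(z2);
            p.tau.push_back(t2);
            p.nuc.push_back(1);
            ev_t.push_back(t);
            ev_pf.push_back(n + 1);
            ev_type.push_back(1);
            ev_val.push_back(1);
          }
        }
        if (p_hyd > 0.0) {
          for (size_t d = 0; d < p.nuc.size(); d++) {
            if (p.nuc[d] == 1 && rng.unif() < p_hyd) {
              p.nuc[d] = 0;
              ev_t.push_back(t);
              ev_pf.push_back(n + 1);
              ev_type.push_back(2);
              ev_val.push_back((double)(d + 1));
            }
          }
        }
      }
      s.ensure_scratch();
    }

    // detachment scan + window refresh
    if (detach_on && detach_stride > 0 && step % detach_stride == 0) {
      bool changed = false;
      for (int n = 0; n < s.geom.n_pf; n++) {
        PFState& p = s.pf[n];
        const int d = detach_bond(p, s.geom, s.inter, detach_thr);
        if (d >= 0) {
          const int ndim = (int)p.nuc.size();
          const int nrm = ndim - d;
          p.x.resize(2 * d);
          p.z.resize(2 * d);
          p.tau.resize(2 * d);
          p.nuc.resize(d);
          ev_t.push_back(t);
          ev_pf.push_back(n + 1);
          ev_type.push_back(3);
          ev_val.push_back((double)nrm);
          changed = true;
          if (s.ring.on && s.ring.bound[n] >= 2 * d) s.ring.bound[n] = -1;
        }
      }
      for (int n = 0; n < s.geom.n_pf; n++) {
        PFState& p = s.pf[n];
        p.mob = std::max(2, (int)p.x.size() - 2 * window_dimers);
        if ((int)p.x.size() <= 4) exhausted = true;
      }
      (void)changed;
      s.ensure_scratch();
      if (exhausted) {
        ev_t.push_back(t);
        ev_pf.push_back(0);
        ev_type.push_back(6);
        ev_val.push_back(0);
        steps_done = step;
        record_row(t);
        break;
      }
    }

    if (record_stride > 0 && step % record_stride == 0) record_row(t);
    if (snap_stride > 0 && step % snap_stride == 0) take_snapshot(t);

    if (relax_tol > 0.0 && step % 100 == 0) {
      if (s.max_grad() < relax_tol) {
        converged = true;
        steps_done = step;
        record_row(t);
        break;
      }
      if (s.bead.on) {
        // escaped when nothing ahead of the bead blocks its axial path:
        // no monomer above bead level within steric reach of the offset
        const double reach = s.bead.R + s.geom.r_tub + 0.3;
        bool blocked = false;
        const PFState& p0 = s.pf[0];
        for (int k = 0; k < (int)p0.x.size(); k++) {
          if (p0.z[k] > s.bead.z - 1.0 &&
              std::fabs(p0.x[k] - s.bead.x) < reach) {
            blocked = true;
            break;
          }
        }
        if (!blocked) bead_free_checks++; else bead_free_checks = 0;
        if (bead_free_checks >= 3 ||
            s.bead.z > p0.z.back() + s.bead.R + s.geom.r_tub + 2.0) {
          bead_escaped = true;
          steps_done = step;
          break;
        }
        // stationarity by stall: gradient nearly flat and the bead has
        // stopped advancing => a force-balanced configuration exists
        if (step % 100000 == 0) {
          if (s.max_grad() < 5e-2 &&
              std::fabs(s.bead.z - bead_z_mark) < 1e-3) {
            converged = true;
            steps_done = step;
            break;
          }
          bead_z_mark = s.bead.z;
        }
      }
    }
    if (step % 2000000 == 0) Rcpp::checkUserInterrupt();
    steps_done = step;
  }

  List st = state_to(s.pf);
  NumericMatrix ev((int)ev_t.size(), 4);
  for (int i = 0; i < (int)ev_t.size(); i++) {
    ev(i, 0) = ev_t[i];
    ev(i, 1) = ev_pf[i];
    ev(i, 2) = ev_type[i];
    ev(i, 3) = ev_val[i];
  }
  colnames(ev) = CharacterVector::create("t", "pf", "type", "value");

  List out = List::create(
      _["state"] = st, _["trace"] = trace(Range(0, std::max(0, irec - 1)), _),
      _["events"] = ev, _["snapshots"] = wrap(snaps),
      _["n_straightening"] = (double)n_straight,
      _["steps"] = (double)steps_done, _["converged"] = converged,
      _["bead_escaped"] = bead_escaped, _["ring_lost"] = ring_lost,
      _["window_exhausted"] = exhausted,
      _["final_max_grad"] = relax_tol > 0.0 ? s.max_grad() : NA_REAL);
  if (s.bead.on) out["bead_z"] = s.bead.z;
  if (s.obst.on) out["obstacle_z"] = s.obst.z;
  if (s.ring.on) {
    out["ring_x"] = NumericVector(s.ring.x.begin(), s.ring.x.end());
    out["ring_z"] = NumericVector(s.ring.z.begin(), s.ring.z.end());
    out["ring_bound"] = IntegerVector(s.ring.bound.begin(),
                                      s.ring.bound.end());
  }
  return out;
}
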