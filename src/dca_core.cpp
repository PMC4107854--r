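// Core time steppers for buffered calcium reaction-diffusion.
//
// Two solvers share the same reaction network (free Ca, first-order buffer
// site classes with optional Mg competition, a surface pump with extrusion,
// compensating leak) and the same Strang splitting per step: a half-step of
// the local reactions (classical RK4 sub-steps; the stiffest local rate is
// the pump extrusion, ~90 /ms, well inside the RK4 stability region at the
// sub-step sizes used), a full Crank-Nicolson tridiagonal diffusion solve per
// mobile species (unconditionally stable, exactly conservative in flux form),
// the second reaction half-step, then any cross-compartment (longitudinal /
// axial) exchange applied explicitly (those couplings are weak: areas over
// multi-um distances).
//
// Unit system: um, ms, mM, mV, mA/cm^2. FLUXA converts a current density to
// an amount rate: amount (mM um^3) per ms = -I * FLUXA * area(um^2) / z=2
// folded in (see R constants table).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double FARADAY = 96485.33212;
static const double FLUXA = 1e4 / FARADAY / 2.0; // per mA/cm^2, divalent

// x / (1 - exp(-x)) with series fallback
static inline double xi_factor(double x) {
  if (std::fabs(x) < 1e-8) return 1.0 + 0.5 * x;
  return x / (-std::expm1(-x));
}

// GHK current density, mA/cm^2 (inward negative), divalent ion
static inline double ghk_I(double V, double cai, double cao, double peff,
                           double rtf) {
  double xi = 2.0 * V / rtf;
  double drive = (cai - cao * std::exp(-xi)) * 1e-6; // mM -> mol/cm^3
  return 1e3 * peff * 2.0 * FARADAY * xi_factor(xi) * drive;
}

// Thomas solver for (I - dt*L) c = rhs given sub/diag/sup in place
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d) {
  int n = (int)b.size();
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  d[n - 1] /= b[n - 1];
  for (int i = n - 2; i >= 0; --i) d[i] = (d[i] - c[i] * d[i + 1]) / b[i];
}

// Theta-scheme diffusion along a 1D chain of cells with volumes V and face
// conductances g (area/dist between cell i and i+1), coefficient D.
// theta = 0.5 is Crank-Nicolson (2nd order), theta = 1 backward Euler.
// Flux form on shared faces, so the cell-volume-weighted total is conserved
// to round-off.
static void diffuse_theta(std::vector<double>& conc, const double* V,
                          const double* g, int n, double D, double dt,
                          double theta = 0.5) {
  if (n < 2 || D <= 0) return;
  std::vector<double> a(n, 0.0), b(n, 0.0), c(n, 0.0), d(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double gl = (i > 0) ? D * g[i - 1] : 0.0;
    double gr = (i < n - 1) ? D * g[i] : 0.0;
    b[i] = 1.0 + theta * dt * (gl + gr) / V[i];
    if (i > 0) a[i] = -theta * dt * gl / V[i];
    if (i < n - 1) c[i] = -theta * dt * gr / V[i];
    // explicit part
    double expl = conc[i];
    if (i > 0) expl += (1 - theta) * dt * gl * (conc[i - 1] - conc[i]) / V[i];
    if (i < n - 1) expl += (1 - theta) * dt * gr * (conc[i + 1] - conc[i]) / V[i];
    d[i] = expl;
  }
  thomas(a, b, c, d);
  for (int i = 0; i < n; ++i) conc[i] = d[i];
}

struct BufPar {
  double kon, koff, D;
  bool has_mg;
  double mgkon, mgkoff; // mgkon already multiplied by free [Mg]
};

// ---------------------------------------------------------------------------
// Shared reaction system over an arbitrary set of cells.
//
// Flat state layout: ca[ncell], then per buffer: free[ncell], bound[ncell],
// (mgbound[ncell] if has_mg), then pump free[ncell], pump bound[ncell],
// then 3 tallies: influx_in, extruded, leak_in (amounts, mM um^3).
struct ReactSys {
  int ncell;
  std::vector<BufPar> buf;
  double kf, kb, kext;                // pump rates
  std::vector<double> vol;            // cell volumes
  std::vector<double> amem;           // membrane area attached to each cell
  std::vector<double> ptot;           // pump total conc per cell (mM)
  std::vector<double> leak;           // leak amount rate per cell (mM um^3/ms)
  std::vector<double> iscale;         // influx scale per cell
  // drive
  int drive_type;                     // 0 none, 1 current, 2 ghk
  NumericVector ivec, vvec, pvec;
  double cao, rtf;

  int nb() const { return (int)buf.size(); }
  int buf_fields() const {
    int nf = 0;
    for (auto& b : buf) nf += b.has_mg ? 3 : 2;
    return nf;
  }
  int nstate() const { return ncell * (1 + buf_fields() + 2) + 3; }
  int off_buf(int b) const { // offset of buffer b's free field
    int o = ncell;
    for (int k = 0; k < b; ++k) o += ncell * (buf[k].has_mg ? 3 : 2);
    return o;
  }
  int off_pump() const { return ncell * (1 + buf_fields()); }
  int off_tally() const { return off_pump() + 2 * ncell; }

  // reaction right-hand side; step index k selects the drive sample
  void deriv(const std::vector<double>& y, std::vector<double>& dy, int k) const {
    std::fill(dy.begin(), dy.end(), 0.0);
    const double* ca = &y[0];
    double* dca = &dy[0];
    for (int b = 0; b < nb(); ++b) {
      const BufPar& bp = buf[b];
      int o = off_buf(b);
      const double* bf = &y[o];
      const double* bb = &y[o + ncell];
      double* dbf = &dy[o];
      double* dbb = &dy[o + ncell];
      for (int i = 0; i < ncell; ++i) {
        double r = bp.kon * ca[i] * bf[i] - bp.koff * bb[i];
        dbf[i] -= r;
        dbb[i] += r;
        dca[i] -= r;
      }
      if (bp.has_mg) {
        const double* bm = &y[o + 2 * ncell];
        double* dbm = &dy[o + 2 * ncell];
        for (int i = 0; i < ncell; ++i) {
          double rm = bp.mgkon * bf[i] - bp.mgkoff * bm[i];
          dbf[i] -= rm;
          dbm[i] += rm;
        }
      }
    }
    // membrane terms: influx, pump, leak
    int op = off_pump(), ot = off_tally();
    const double* pf = &y[op];
    const double* pb = &y[op + ncell];
    double* dpf = &dy[op];
    double* dpb = &dy[op + ncell];
    for (int i = 0; i < ncell; ++i) {
      if (amem[i] <= 0.0) continue;
      double inv_v = 1.0 / vol[i];
      // influx
      if (drive_type != 0) {
        double I;
        if (drive_type == 1) I = ivec[k];
        else I = ghk_I(vvec[k], ca[i], cao, pvec[k], rtf);
        I *= iscale[i];
        double amt = -I * FLUXA * amem[i]; // amount/ms, inward positive
        dca[i] += amt * inv_v;
        dy[ot] += amt;
      }
      // pump
      if (ptot[i] > 0.0) {
        double ron = kf * ca[i] * pf[i];
        double roff = kb * pb[i];
        double rext = kext * pb[i];
        dpf[i] += -ron + roff + rext;
        dpb[i] += ron - roff - rext;
        // pump states are concentrations in the same cell volume, so the
        // calcium exchange is the plain rate difference
        dca[i] += -ron + roff;
        dy[ot + 1] += rext * vol[i];
      }
      // leak
      if (leak[i] != 0.0) {
        dca[i] += leak[i] * inv_v;
        dy[ot + 2] += leak[i];
      }
    }
  }

  void rk4(std::vector<double>& y, int k, double h, int nsub,
           std::vector<double>& k1, std::vector<double>& k2,
           std::vector<double>& k3, std::vector<double>& k4,
           std::vector<double>& tmp) const {
    int n = (int)y.size();
    double hs = h / nsub;
    for (int s = 0; s < nsub; ++s) {
      deriv(y, k1, k);
      for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * hs * k1[i];
      deriv(tmp, k2, k);
      for (int i = 0; i < n; ++i) tmp[i] = y[i] + 0.5 * hs * k2[i];
      deriv(tmp, k3, k);
      for (int i = 0; i < n; ++i) tmp[i] = y[i] + hs * k3[i];
      deriv(tmp, k4, k);
      for (int i = 0; i < n; ++i)
        y[i] += hs / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
    }
  }

  // total calcium bookkeeping: free + buffer-bound + pump-bound + extruded
  // - influx - leak (amounts); constant when the scheme is conservative.
  double audit(const std::vector<double>& y) const {
    double tot = 0.0;
    for (int i = 0; i < ncell; ++i) tot += y[i] * vol[i];
    for (int b = 0; b < nb(); ++b) {
      int o = off_buf(b);
      for (int i = 0; i < ncell; ++i) tot += y[o + ncell + i] * vol[i];
    }
    int op = off_pump(), ot = off_tally();
    for (int i = 0; i < ncell; ++i) tot += y[op + ncell + i] * vol[i];
    return tot + y[ot + 1] - y[ot] - y[ot + 2];
  }
};

static std::vector<BufPar> parse_buffers(List buffers) {
  std::vector<BufPar> out;
  for (int b = 0; b < buffers.size(); ++b) {
    List bl = buffers[b];
    BufPar bp;
    bp.kon = as<double>(bl["kon"]);
    bp.koff = as<double>(bl["koff"]);
    bp.D = as<double>(bl["D"]);
    bp.has_mg = as<bool>(bl["has_mg"]);
    bp.mgkon = bp.has_mg ? as<double>(bl["mgkon"]) : 0.0;
    bp.mgkoff = bp.has_mg ? as<double>(bl["mgkoff"]) : 0.0;
    out.push_back(bp);
  }
  return out;
}

static void setup_drive(ReactSys& rs, List drive) {
  rs.drive_type = as<int>(drive["type"]);
  if (rs.drive_type == 1) rs.ivec = as<NumericVector>(drive["ivec"]);
  else if (rs.drive_type == 2) {
    rs.vvec = as<NumericVector>(drive["vvec"]);
    rs.pvec = as<NumericVector>(drive["pvec"]);
    rs.cao = as<double>(drive["cao"]);
    rs.rtf = as<double>(drive["rtf"]);
  }
}

// ---------------------------------------------------------------------------
// 1D radial shells, possibly several compartments with longitudinal coupling.
//
// sys fields (from R):
//  volumes: list of numeric vectors (outermost shell first) per compartment
//  gface:   list of face conductance-geometry vectors (area/dist), len n-1
//  outer_area: lateral membrane area per compartment
//  ptot, leak, cscale: per-compartment pump conc, leak amount rate, influx scale
//  kf, kb, kext, d_ca, ca0: scalars
//  buffers: list of buffer parameter lists incl. initial concentrations
//  pf0, pb0: initial pump concentrations (fractions of ptot)
//  pairs: matrix (compA, shellA, compB, shellB, g) 1-based comp/shell indices
// [[Rcpp::export]]
List rd_simulate_cpp(List sys, List drive, double dt, int nsteps, int nsub,
                     int record_every, bool record_shells) {
  List volumes = sys["volumes"];
  List gface = sys["gface"];
  NumericVector outer_area = sys["outer_area"];
  NumericVector ptot_c = sys["ptot"];
  NumericVector leak_c = sys["leak"];
  NumericVector cscale = sys["cscale"];
  double kf = as<double>(sys["kf"]), kb = as<double>(sys["kb"]),
         kext = as<double>(sys["kext"]);
  double d_ca = as<double>(sys["d_ca"]), ca0 = as<double>(sys["ca0"]);
  List buffers = sys["buffers"];
  NumericMatrix pairs = sys["pairs"];

  int ncomp = volumes.size();
  std::vector<int> nsh(ncomp), cell0(ncomp);
  int ncell = 0;
  for (int c = 0; c < ncomp; ++c) {
    cell0[c] = ncell;
    nsh[c] = as<NumericVector>(volumes[c]).size();
    ncell += nsh[c];
  }

  ReactSys rs;
  rs.ncell = ncell;
  rs.buf = parse_buffers(buffers);
  rs.kf = kf; rs.kb = kb; rs.kext = kext;
  rs.vol.assign(ncell, 0.0);
  rs.amem.assign(ncell, 0.0);
  rs.ptot.assign(ncell, 0.0);
  rs.leak.assign(ncell, 0.0);
  rs.iscale.assign(ncell, 1.0);
  std::vector<double> gflat; gflat.reserve(ncell);
  std::vector<int> goff(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    NumericVector V = volumes[c];
    NumericVector g = gface[c];
    goff[c] = (int)gflat.size();
    for (int i = 0; i < nsh[c]; ++i) rs.vol[cell0[c] + i] = V[i];
    for (int i = 0; i < g.size(); ++i) gflat.push_back(g[i]);
    rs.amem[cell0[c]] = outer_area[c];
    rs.ptot[cell0[c]] = ptot_c[c];
    rs.leak[cell0[c]] = leak_c[c];
    for (int i = 0; i < nsh[c]; ++i) rs.iscale[cell0[c] + i] = cscale[c];
  }
  setup_drive(rs, drive);

  // initial state
  std::vector<double> y(rs.nstate(), 0.0);
  for (int i = 0; i < ncell; ++i) y[i] = ca0;
  for (int b = 0; b < rs.nb(); ++b) {
    List bl = buffers[b];
    double f0 = as<double>(bl["free0"]), b0 = as<double>(bl["bound0"]);
    double m0 = rs.buf[b].has_mg ? as<double>(bl["mgb0"]) : 0.0;
    int o = rs.off_buf(b);
    for (int i = 0; i < ncell; ++i) {
      y[o + i] = f0;
      y[o + ncell + i] = b0;
      if (rs.buf[b].has_mg) y[o + 2 * ncell + i] = m0;
    }
  }
  {
    int op = rs.off_pump();
    for (int c = 0; c < ncomp; ++c) {
      int i = cell0[c];
      double pt = ptot_c[c];
      if (pt > 0) {
        double pb0 = pt * kf * ca0 / (kf * ca0 + kb + kext);
        y[op + i] = pt - pb0;
        y[op + ncell + i] = pb0;
      }
    }
  }

  int nrec = nsteps / record_every + 1;
  NumericVector time(nrec);
  NumericMatrix sm_ca(ncomp, nrec);
  NumericMatrix shell_ca = record_shells ? NumericMatrix(nsh[0], nrec)
                                         : NumericMatrix(1, 1);
  NumericVector audit(nrec);

  std::vector<double> k1(y.size()), k2(y.size()), k3(y.size()), k4(y.size()),
      tmp(y.size());

  // mobile fields: offsets + diffusion coefficient
  std::vector<std::pair<int, double>> mob;
  mob.push_back({0, d_ca});
  for (int b = 0; b < rs.nb(); ++b) {
    if (rs.buf[b].D > 0) {
      int o = rs.off_buf(b);
      mob.push_back({o, rs.buf[b].D});
      mob.push_back({o + ncell, rs.buf[b].D});
      if (rs.buf[b].has_mg) mob.push_back({o + 2 * ncell, rs.buf[b].D});
    }
  }

  int irec = 0;
  auto record = [&](int k) {
    time[irec] = k * dt;
    for (int c = 0; c < ncomp; ++c) sm_ca(c, irec) = y[cell0[c]];
    if (record_shells)
      for (int i = 0; i < nsh[0]; ++i) shell_ca(i, irec) = y[i];
    audit[irec] = rs.audit(y);
    ++irec;
  };
  record(0);

  std::vector<double> slice;
  for (int k = 0; k < nsteps; ++k) {
    // Strang splitting: half-step reactions, full-step diffusion, half-step
    rs.rk4(y, k, 0.5 * dt, nsub, k1, k2, k3, k4, tmp);
    for (auto& mf : mob) {
      for (int c = 0; c < ncomp; ++c) {
        int n = nsh[c];
        if (n < 2) continue;
        slice.assign(y.begin() + mf.first + cell0[c],
                     y.begin() + mf.first + cell0[c] + n);
        diffuse_theta(slice, &rs.vol[cell0[c]], &gflat[goff[c]], n, mf.second, dt);
        std::copy(slice.begin(), slice.end(), y.begin() + mf.first + cell0[c]);
      }
    }
    rs.rk4(y, k, 0.5 * dt, nsub, k1, k2, k3, k4, tmp);
    // longitudinal coupling, explicit
    for (int p = 0; p < pairs.nrow(); ++p) {
      int ia = cell0[(int)pairs(p, 0) - 1] + (int)pairs(p, 1) - 1;
      int ib = cell0[(int)pairs(p, 2) - 1] + (int)pairs(p, 3) - 1;
      double g = pairs(p, 4);
      for (auto& mf : mob) {
        double ca_ = y[mf.first + ia], cb_ = y[mf.first + ib];
        double amt = mf.second * g * (cb_ - ca_) * dt;
        y[mf.first + ia] += amt / rs.vol[ia];
        y[mf.first + ib] -= amt / rs.vol[ib];
      }
    }
    if ((k + 1) % record_every == 0) record(k + 1);
  }

  int ot = rs.off_tally();
  return List::create(
      _["time"] = time, _["sm_ca"] = sm_ca,
      _["shell_ca"] = record_shells ? shell_ca : NumericMatrix(0, 0),
      _["audit"] = audit,
      _["influx_amount"] = y[ot], _["extruded_amount"] = y[ot + 1],
      _["leak_amount"] = y[ot + 2],
      _["state"] = NumericVector(y.begin(), y.end()));
}

// ---------------------------------------------------------------------------
// Axisymmetric (r,z) finite-volume solver on stacked frusta.
//
// grid fields:
//  nr, nz: cell counts; vol: matrix (nr x nz); gr: matrix (nr-1 x nz) radial
//  face conductances; amem: matrix (nr x nz) membrane area per cell
//  (lateral + exposed steps + optional caps); zpairs: matrix
//  (cellA, cellB, g) with 1-based flat indices (j + (k-1)*nr);
//  ptot, leak: matrices (nr x nz); sm_weight: matrix (nr x nz) of
//  volume weights for the per-slab submembrane average (rows sum to 1 per
//  slab where defined).
// [[Rcpp::export]]
List axisym_simulate_cpp(List grid, List spec, List drive, double dt,
                         int nsteps, int nsub, int record_every) {
  int nr = as<int>(grid["nr"]), nz = as<int>(grid["nz"]);
  NumericMatrix vol = grid["vol"], gr = grid["gr"], amem = grid["amem"],
                ptot = grid["ptot"], leak = grid["leak"],
                smw = grid["sm_weight"];
  NumericMatrix zpairs = grid["zpairs"];
  double kf = as<double>(spec["kf"]), kb = as<double>(spec["kb"]),
         kext = as<double>(spec["kext"]);
  double d_ca = as<double>(spec["d_ca"]), ca0 = as<double>(spec["ca0"]);
  List buffers = spec["buffers"];

  int ncell = nr * nz;
  ReactSys rs;
  rs.ncell = ncell;
  rs.buf = parse_buffers(buffers);
  rs.kf = kf; rs.kb = kb; rs.kext = kext;
  rs.vol.assign(ncell, 0.0);
  rs.amem.assign(ncell, 0.0);
  rs.ptot.assign(ncell, 0.0);
  rs.leak.assign(ncell, 0.0);
  rs.iscale.assign(ncell, 1.0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < nr; ++j) {
      int i = k * nr + j;
      rs.vol[i] = vol(j, k);
      rs.amem[i] = amem(j, k);
      rs.ptot[i] = ptot(j, k);
      rs.leak[i] = leak(j, k);
    }
  setup_drive(rs, drive);

  std::vector<double> y(rs.nstate(), 0.0);
  for (int i = 0; i < ncell; ++i) y[i] = ca0;
  for (int b = 0; b < rs.nb(); ++b) {
    List bl = buffers[b];
    double f0 = as<double>(bl["free0"]), b0 = as<double>(bl["bound0"]);
    double m0 = rs.buf[b].has_mg ? as<double>(bl["mgb0"]) : 0.0;
    int o = rs.off_buf(b);
    for (int i = 0; i < ncell; ++i) {
      y[o + i] = f0;
      y[o + ncell + i] = b0;
      if (rs.buf[b].has_mg) y[o + 2 * ncell + i] = m0;
    }
  }
  {
    int op = rs.off_pump();
    for (int i = 0; i < ncell; ++i) {
      if (rs.ptot[i] > 0) {
        double pb0 = rs.ptot[i] * kf * ca0 / (kf * ca0 + kb + kext);
        y[op + i] = rs.ptot[i] - pb0;
        y[op + ncell + i] = pb0;
      }
    }
  }

  int nrec = nsteps / record_every + 1;
  NumericVector time(nrec);
  NumericMatrix sm_ca(nz, nrec);   // per-slab submembrane average
  NumericMatrix ca_field(0, 0);
  NumericVector audit(nrec);

  std::vector<double> k1(y.size()), k2(y.size()), k3(y.size()), k4(y.size()),
      tmp(y.size());
  std::vector<std::pair<int, double>> mob;
  mob.push_back({0, d_ca});
  for (int b = 0; b < rs.nb(); ++b) {
    if (rs.buf[b].D > 0) {
      int o = rs.off_buf(b);
      mob.push_back({o, rs.buf[b].D});
      mob.push_back({o + ncell, rs.buf[b].D});
      if (rs.buf[b].has_mg) mob.push_back({o + 2 * ncell, rs.buf[b].D});
    }
  }

  int irec = 0;
  auto record = [&](int k) {
    time[irec] = k * dt;
    for (int kz = 0; kz < nz; ++kz) {
      double s = 0;
      for (int j = 0; j < nr; ++j) s += smw(j, kz) * y[kz * nr + j];
      sm_ca(kz, irec) = s;
    }
    audit[irec] = rs.audit(y);
    ++irec;
  };
  record(0);

  std::vector<double> slice(nr), gcol(nr > 1 ? nr - 1 : 0), vcol(nr);
  for (int k = 0; k < nsteps; ++k) {
    // Strang splitting: half-step reactions, diffusion, half-step reactions
    rs.rk4(y, k, 0.5 * dt, nsub, k1, k2, k3, k4, tmp);
    // radial implicit per slab per mobile field
    for (auto& mf : mob) {
      for (int kz = 0; kz < nz; ++kz) {
        if (nr < 2) continue;
        for (int j = 0; j < nr; ++j) {
          slice[j] = y[mf.first + kz * nr + j];
          vcol[j] = rs.vol[kz * nr + j];
        }
        for (int j = 0; j < nr - 1; ++j) gcol[j] = gr(j, kz);
        diffuse_theta(slice, vcol.data(), gcol.data(), nr, mf.second, dt);
        for (int j = 0; j < nr; ++j) y[mf.first + kz * nr + j] = slice[j];
      }
    }
    rs.rk4(y, k, 0.5 * dt, nsub, k1, k2, k3, k4, tmp);
    // axial coupling, explicit
    for (int p = 0; p < zpairs.nrow(); ++p) {
      int ia = (int)zpairs(p, 0) - 1;
      int ib = (int)zpairs(p, 1) - 1;
      double g = zpairs(p, 2);
      for (auto& mf : mob) {
        double amt = mf.second * g * (y[mf.first + ib] - y[mf.first + ia]) * dt;
        y[mf.first + ia] += amt / rs.vol[ia];
        y[mf.first + ib] -= amt / rs.vol[ib];
      }
    }
    if ((k + 1) % record_every == 0) record(k + 1);
  }

  int ot = rs.off_tally();
  // final free-calcium field for profile checks
  NumericMatrix ca_end(nr, nz);
  for (int kz = 0; kz < nz; ++kz)
    for (int j = 0; j < nr; ++j) ca_end(j, kz) = y[kz * nr + j];

  return List::create(
      _["time"] = time, _["sm_ca"] = sm_ca, _["audit"] = audit,
      _["ca_end"] = ca_end,
      _["influx_amount"] = y[ot], _["extruded_amount"] = y[ot + 1],
      _["leak_amount"] = y[ot + 2]);
}
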