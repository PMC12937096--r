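// Core DPD engine: cell-list pair search, conservative (linear and
// exponential gas-bead) forces, pairwise dissipative/random thermostat,
// harmonic bonds/angles, smeared-charge electrostatics, modified
// velocity-Verlet integration, Berendsen barostat, virial pressure tensor.
//
// Internal units: length Rc, mass m0, energy eps with k_B T_DPD = T * eps.
// Interaction constants arrive from R already scaled to internal units
// (a_int = a[kBT] * T_DPD); pressures/energies are returned in internal
// units and rescaled to kBT units on the R side.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Symmetric per-pair, per-step uniform noise with zero mean, unit variance.
// Counter-based so trajectories are reproducible and theta_ij == theta_ji.
static inline double pair_noise(uint64_t stepkey, int i, int j) {
  uint64_t a = (uint64_t)(i < j ? i : j), b = (uint64_t)(i < j ? j : i);
  uint64_t h = sm64(stepkey ^ (a << 32) ^ b);
  double u = (double)(h >> 11) * (1.0 / 9007199254740992.0);
  return 3.4641016151377544 * (u - 0.5); // sqrt(12)*(U-1/2)
}

static inline double wrap(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}
static inline double mi(double d, double L) { // minimum image
  return d - L * std::round(d / L);
}

struct Tables {
  int nt;
  const double *A, *Rc, *Gam, *Bexp;
  const int *style; // 0 linear DPD, 1 exponential (gas)
  double rmax;
  // tabulated exponential force/energy (linear interpolation), per pair
  std::vector<std::vector<double>> TF, TV;
  std::vector<double> invdr;
  int ntab;
  void build_exp_tables() {
    ntab = 4096;
    TF.assign(nt * nt, {});
    TV.assign(nt * nt, {});
    invdr.assign(nt * nt, 0.0);
    for (int p = 0; p < nt * nt; p++) {
      if (style[p] != 1) continue;
      double a = A[p], R = Rc[p], b = Bexp[p];
      double eb = std::exp(b);
      double dr = R / (ntab - 1);
      invdr[p] = 1.0 / dr;
      TF[p].resize(ntab + 1);
      TV[p].resize(ntab + 1);
      for (int k = 0; k <= ntab; k++) {
        double r = std::min(R, k * dr);
        double ebr = std::exp(b * r / R);
        TF[p][k] = a * (ebr - eb) / (1.0 - eb);
        TV[p][k] = a / (1.0 - eb) * ((r - R) * eb + (R / b) * (eb - ebr));
      }
    }
  }
};

// Build cell list; returns head/next arrays. ncell per dim >= 1.
struct CellList {
  int nx, ny, nz;
  std::vector<int> head, nxt;
  bool brute;
};

static void build_cells(const std::vector<double>& x, const std::vector<double>& y,
                        const std::vector<double>& z, const double L[3],
                        double rc, CellList& cl) {
  int n = (int)x.size();
  cl.nx = (int)std::floor(L[0] / rc);
  cl.ny = (int)std::floor(L[1] / rc);
  cl.nz = (int)std::floor(L[2] / rc);
  cl.brute = (cl.nx < 3 || cl.ny < 3 || cl.nz < 3);
  if (cl.brute) return;
  cl.head.assign((size_t)cl.nx * cl.ny * cl.nz, -1);
  cl.nxt.assign(n, -1);
  for (int i = 0; i < n; i++) {
    int cx = (int)(x[i] / L[0] * cl.nx); if (cx >= cl.nx) cx = cl.nx - 1; if (cx < 0) cx = 0;
    int cy = (int)(y[i] / L[1] * cl.ny); if (cy >= cl.ny) cy = cl.ny - 1; if (cy < 0) cy = 0;
    int cz = (int)(z[i] / L[2] * cl.nz); if (cz >= cl.nz) cz = cl.nz - 1; if (cz < 0) cz = 0;
    int c = (cz * cl.ny + cy) * cl.nx + cx;
    cl.nxt[i] = cl.head[c];
    cl.head[c] = i;
  }
}

struct ForceOut {
  std::vector<double> fx, fy, fz;
  double W[3];      // conservative virial (pair+bond+angle+elec), per axis
  double e_pair, e_bond, e_angle, e_elec;
};

// Deterministic tie-break direction for exactly overlapping beads.
static inline void tiebreak(int i, int j, double& ex, double& ey, double& ez) {
  uint64_t h = sm64(((uint64_t)(i < j ? i : j) << 32) ^ (uint64_t)(i < j ? j : i));
  double vx = (double)((h >> 1) & 1023) / 511.5 - 1.0;
  double vy = (double)((h >> 11) & 1023) / 511.5 - 1.0;
  double vz = (double)((h >> 21) & 1023) / 511.5 - 1.0;
  double nn = std::sqrt(vx * vx + vy * vy + vz * vz);
  if (nn < 1e-12) { vx = 1; vy = 0; vz = 0; nn = 1; }
  double s = (i < j) ? 1.0 : -1.0;
  ex = s * vx / nn; ey = s * vy / nn; ez = s * vz / nn;
}

static void compute_forces(const std::vector<double>& x, const std::vector<double>& y,
                           const std::vector<double>& z,
                           const std::vector<double>& vx, const std::vector<double>& vy,
                           const std::vector<double>& vz,
                           const std::vector<int>& typ, const double L[3],
                           const Tables& tb,
                           const IntegerMatrix& bonds, const NumericVector& kb,
                           const NumericVector& r0,
                           const IntegerMatrix& angles, const NumericVector& ka,
                           const NumericVector& th0,
                           const std::vector<double>& q, bool elec_on,
                           double elec_pref, double elec_beta, double elec_rc,
                           bool with_dr, double T, double invsqrtdt,
                           uint64_t stepkey, ForceOut& out) {
  int n = (int)x.size();
  out.fx.assign(n, 0.0); out.fy.assign(n, 0.0); out.fz.assign(n, 0.0);
  out.W[0] = out.W[1] = out.W[2] = 0.0;
  out.e_pair = out.e_bond = out.e_angle = out.e_elec = 0.0;
  double rc = tb.rmax;
  if (elec_on && elec_rc > rc) rc = elec_rc;

  CellList cl;
  build_cells(x, y, z, L, rc, cl);

  std::vector<double> sig(tb.nt * tb.nt);
  for (int p = 0; p < tb.nt * tb.nt; p++)
    sig[p] = std::sqrt(2.0 * T * tb.Gam[p]);

  // sorted (cell-contiguous) working copies for cache locality
  std::vector<int> perm(n);
  for (int i = 0; i < n; i++) perm[i] = i;
  std::vector<double> xs, ys, zs, vxs, vys, vzs, qs, gx, gy, gz;
  std::vector<int> ts;

  std::vector<double> R2(tb.nt * tb.nt);
  for (int p = 0; p < tb.nt * tb.nt; p++) R2[p] = tb.Rc[p] * tb.Rc[p];

  auto do_core = [&](int u, int v, double dx, double dy, double dz) {
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc * rc) return;
    int p = ts[u] * tb.nt + ts[v];
    if (r2 >= R2[p] && !elec_on) return; // outside this pair's cutoff
    int i = perm[u], j = perm[v]; // original ids (noise, tie-breaks)
    double r = std::sqrt(r2);
    double R = tb.Rc[p];
    double ex, ey, ez;
    if (r < 1e-10) { tiebreak(i, j, ex, ey, ez); r = 0.0; }
    else { ex = dx / r; ey = dy / r; ez = dz / r; }
    double fc = 0.0;   // conservative part (enters the virial)
    double fmag = 0.0; // total pairwise force magnitude
    if (r < R) {
      double a = tb.A[p];
      double w = 1.0 - r / R;
      if (tb.style[p] == 0) {
        fc = a * w;
        out.e_pair += 0.5 * a * R * w * w;
      } else { // tabulated exponential law
        double t = r * tb.invdr[p];
        int k = (int)t;
        double fr = t - k;
        fc = tb.TF[p][k] * (1.0 - fr) + tb.TF[p][k + 1] * fr;
        out.e_pair += tb.TV[p][k] * (1.0 - fr) + tb.TV[p][k + 1] * fr;
      }
      fmag = fc;
      if (with_dr) {
        double g = tb.Gam[p];
        double dvx = vxs[u] - vxs[v], dvy = vys[u] - vys[v], dvz = vzs[u] - vzs[v];
        double vdotr = dvx * ex + dvy * ey + dvz * ez;
        double th = pair_noise(stepkey, i, j);
        fmag += -g * w * w * vdotr + sig[p] * w * th * invsqrtdt;
      }
    }
    if (elec_on && qs[u] != 0.0 && qs[v] != 0.0 && r < elec_rc && r > 1e-10) {
      double br = elec_beta * r;
      double e2 = std::exp(-2.0 * br);
      double fe = elec_pref * qs[u] * qs[v] / r2 *
        (1.0 - e2 * (1.0 + 2.0 * br * (1.0 + br)));
      fc += fe;
      fmag += fe;
      out.e_elec += elec_pref * qs[u] * qs[v] / r * (1.0 - (1.0 + br) * e2);
    }
    if (fmag != 0.0) {
      gx[u] += fmag * ex; gy[u] += fmag * ey; gz[u] += fmag * ez;
      gx[v] -= fmag * ex; gy[v] -= fmag * ey; gz[v] -= fmag * ez;
    }
    out.W[0] += fc * ex * (r * ex);
    out.W[1] += fc * ey * (r * ey);
    out.W[2] += fc * ez * (r * ez);
  };
  auto do_pair = [&](int u, int v) {
    do_core(u, v, mi(xs[u] - xs[v], L[0]), mi(ys[u] - ys[v], L[1]),
            mi(zs[u] - zs[v], L[2]));
  };

  if (cl.brute) {
    xs = x; ys = y; zs = z; vxs = vx; vys = vy; vzs = vz; qs = q; ts = typ;
    gx.assign(n, 0.0); gy.assign(n, 0.0); gz.assign(n, 0.0);
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) do_pair(i, j);
    for (int i = 0; i < n; i++) {
      out.fx[i] += gx[i]; out.fy[i] += gy[i]; out.fz[i] += gz[i];
    }
  } else {
    // cell-sorted traversal for cache locality
    int ncx = cl.nx, ncy = cl.ny, ncz = cl.nz;
    int ncell = ncx * ncy * ncz;
    std::vector<int> cellof(n), cstart(ncell + 1, 0);
    for (int i = 0; i < n; i++) {
      int cx = (int)(x[i] / L[0] * ncx); if (cx >= ncx) cx = ncx - 1;
      int cy = (int)(y[i] / L[1] * ncy); if (cy >= ncy) cy = ncy - 1;
      int cz = (int)(z[i] / L[2] * ncz); if (cz >= ncz) cz = ncz - 1;
      int c = (cz * ncy + cy) * ncx + cx;
      cellof[i] = c;
      cstart[c + 1]++;
    }
    for (int c = 0; c < ncell; c++) cstart[c + 1] += cstart[c];
    {
      std::vector<int> fill(cstart.begin(), cstart.end() - 1);
      for (int i = 0; i < n; i++) perm[fill[cellof[i]]++] = i;
    }
    xs.resize(n); ys.resize(n); zs.resize(n);
    vxs.resize(n); vys.resize(n); vzs.resize(n);
    qs.resize(n); ts.resize(n);
    for (int u = 0; u < n; u++) {
      int i = perm[u];
      xs[u] = x[i]; ys[u] = y[i]; zs[u] = z[i];
      vxs[u] = vx[i]; vys[u] = vy[i]; vzs[u] = vz[i];
      qs[u] = q[i]; ts[u] = typ[i];
    }
    gx.assign(n, 0.0); gy.assign(n, 0.0); gz.assign(n, 0.0);
    static const int off[14][3] = {
      {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
      {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
      {-1,1,1},{0,1,1},{1,1,1}};
    for (int cz = 0; cz < ncz; cz++)
      for (int cy = 0; cy < ncy; cy++)
        for (int cx = 0; cx < ncx; cx++) {
          int c = (cz * ncy + cy) * ncx + cx;
          for (int s = 0; s < 14; s++) {
            int axr = cx + off[s][0], ayr = cy + off[s][1], azr = cz + off[s][2];
            // known periodic shift of the neighbour cell: no minimum image
            double shx = (axr < 0) ? -L[0] : (axr >= ncx ? L[0] : 0.0);
            double shy = (ayr < 0) ? -L[1] : (ayr >= ncy ? L[1] : 0.0);
            double shz = (azr < 0) ? -L[2] : (azr >= ncz ? L[2] : 0.0);
            int ax = (axr + ncx) % ncx;
            int ay = (ayr + ncy) % ncy;
            int az = (azr + ncz) % ncz;
            int c2 = (az * ncy + ay) * ncx + ax;
            if (s == 0) {
              for (int u = cstart[c]; u < cstart[c + 1]; u++)
                for (int v = u + 1; v < cstart[c + 1]; v++)
                  do_core(u, v, xs[u] - xs[v], ys[u] - ys[v], zs[u] - zs[v]);
            } else {
              for (int u = cstart[c]; u < cstart[c + 1]; u++) {
                double xu = xs[u] - shx, yu = ys[u] - shy, zu = zs[u] - shz;
                for (int v = cstart[c2]; v < cstart[c2 + 1]; v++)
                  do_core(u, v, xu - xs[v], yu - ys[v], zu - zs[v]);
              }
            }
          }
        }
    for (int u = 0; u < n; u++) {
      int i = perm[u];
      out.fx[i] += gx[u]; out.fy[i] += gy[u]; out.fz[i] += gz[u];
    }
  }

  // bonds: U = (k/2)(r-r0)^2
  int nb = bonds.nrow();
  for (int b = 0; b < nb; b++) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = mi(x[i] - x[j], L[0]);
    double dy = mi(y[i] - y[j], L[1]);
    double dz = mi(z[i] - z[j], L[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double ex, ey, ez;
    if (r < 1e-10) { tiebreak(i, j, ex, ey, ez); }
    else { ex = dx / r; ey = dy / r; ez = dz / r; }
    double fmag = -kb[b] * (r - r0[b]);
    out.fx[i] += fmag * ex; out.fy[i] += fmag * ey; out.fz[i] += fmag * ez;
    out.fx[j] -= fmag * ex; out.fy[j] -= fmag * ey; out.fz[j] -= fmag * ez;
    out.e_bond += 0.5 * kb[b] * (r - r0[b]) * (r - r0[b]);
    out.W[0] += fmag * ex * (r * ex);
    out.W[1] += fmag * ey * (r * ey);
    out.W[2] += fmag * ez * (r * ez);
  }

  // angles: U = (k/2)(theta-theta0)^2, j is the central bead (i-j-k)
  int na = angles.nrow();
  for (int a = 0; a < na; a++) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double ux = mi(x[i] - x[j], L[0]), uy = mi(y[i] - y[j], L[1]), uz = mi(z[i] - z[j], L[2]);
    double wx = mi(x[k] - x[j], L[0]), wy = mi(y[k] - y[j], L[1]), wz = mi(z[k] - z[j], L[2]);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nw = std::sqrt(wx * wx + wy * wy + wz * wz);
    if (nu < 1e-10 || nw < 1e-10) continue;
    double c = (ux * wx + uy * wy + uz * wz) / (nu * nw);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - th0[a];
    out.e_angle += 0.5 * ka[a] * dth * dth;
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-6) continue; // at/near colinear: restoring force vanishes with dth
    double coef = ka[a] * dth / s;
    double fix = coef * (wx / (nu * nw) - c * ux / (nu * nu));
    double fiy = coef * (wy / (nu * nw) - c * uy / (nu * nu));
    double fiz = coef * (wz / (nu * nw) - c * uz / (nu * nu));
    double fkx = coef * (ux / (nu * nw) - c * wx / (nw * nw));
    double fky = coef * (uy / (nu * nw) - c * wy / (nw * nw));
    double fkz = coef * (uz / (nu * nw) - c * wz / (nw * nw));
    out.fx[i] += fix; out.fy[i] += fiy; out.fz[i] += fiz;
    out.fx[k] += fkx; out.fy[k] += fky; out.fz[k] += fkz;
    out.fx[j] -= (fix + fkx); out.fy[j] -= (fiy + fky); out.fz[j] -= (fiz + fkz);
    out.W[0] += fix * ux + fkx * wx;
    out.W[1] += fiy * uy + fky * wy;
    out.W[2] += fiz * uz + fkz * wz;
  }
}

static Tables make_tables(const NumericMatrix& A, const NumericMatrix& Rcm,
                          const NumericMatrix& Gam, const NumericMatrix& Bexp,
                          const IntegerMatrix& style) {
  Tables tb;
  tb.nt = A.nrow();
  tb.A = A.begin(); tb.Rc = Rcm.begin(); tb.Gam = Gam.begin();
  tb.Bexp = Bexp.begin();
  tb.style = style.begin();
  double m = 0;
  for (int i = 0; i < tb.nt * tb.nt; i++) if (Rcm[i] > m) m = Rcm[i];
  tb.rmax = m;
  tb.build_exp_tables();
  return tb;
}

// [[Rcpp::export]]
List cpp_forces(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                NumericVector box,
                NumericMatrix A, NumericMatrix Rcm, NumericMatrix Gam,
                NumericMatrix Bexp, IntegerMatrix style,
                IntegerMatrix bonds, NumericVector kb, NumericVector r0,
                IntegerMatrix angles, NumericVector ka, NumericVector th0,
                NumericVector charge, bool elec_on, double elec_pref,
                double elec_beta, double elec_rc,
                bool with_dr, double T, double dt, double seed, double step) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), q(n);
  double L[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; i++) {
    x[i] = wrap(pos(i, 0), L[0]); y[i] = wrap(pos(i, 1), L[1]); z[i] = wrap(pos(i, 2), L[2]);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    q[i] = charge[i];
  }
  std::vector<int> typ(type.begin(), type.end());
  Tables tb = make_tables(A, Rcm, Gam, Bexp, style);
  ForceOut out;
  uint64_t stepkey = sm64((uint64_t)seed ^ sm64((uint64_t)step));
  compute_forces(x, y, z, vx, vy, vz, typ, L, tb, bonds, kb, r0, angles, ka, th0,
                 q, elec_on, elec_pref, elec_beta, elec_rc, with_dr, T,
                 1.0 / std::sqrt(dt), stepkey, out);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; i++) { F(i, 0) = out.fx[i]; F(i, 1) = out.fy[i]; F(i, 2) = out.fz[i]; }
  return List::create(_["forces"] = F,
                      _["virial"] = NumericVector::create(out.W[0], out.W[1], out.W[2]),
                      _["e_pair"] = out.e_pair, _["e_bond"] = out.e_bond,
                      _["e_angle"] = out.e_angle, _["e_elec"] = out.e_elec);
}

// [[Rcpp::export]]
List cpp_pairs(NumericMatrix pos, NumericVector box, double rcut) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  double L[3] = {box[0], box[1], box[2]};
  if (rcut > L[0] || rcut > L[1] || rcut > L[2])
    stop("cutoff exceeds a box dimension");
  for (int i = 0; i < n; i++) {
    x[i] = wrap(pos(i, 0), L[0]); y[i] = wrap(pos(i, 1), L[1]); z[i] = wrap(pos(i, 2), L[2]);
  }
  CellList cl;
  build_cells(x, y, z, L, rcut, cl);
  std::vector<int> pi, pj;
  std::vector<double> pr;
  auto try_pair = [&](int i, int j) {
    double dx = mi(x[i] - x[j], L[0]);
    double dy = mi(y[i] - y[j], L[1]);
    double dz = mi(z[i] - z[j], L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < rcut * rcut) {
      pi.push_back(i + 1); pj.push_back(j + 1); pr.push_back(std::sqrt(r2));
    }
  };
  if (cl.brute) {
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) try_pair(i, j);
  } else {
    static const int off[14][3] = {
      {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
      {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
      {-1,1,1},{0,1,1},{1,1,1}};
    for (int cz = 0; cz < cl.nz; cz++)
      for (int cy = 0; cy < cl.ny; cy++)
        for (int cx = 0; cx < cl.nx; cx++) {
          int c = (cz * cl.ny + cy) * cl.nx + cx;
          for (int s = 0; s < 14; s++) {
            int ax = (cx + off[s][0] + cl.nx) % cl.nx;
            int ay = (cy + off[s][1] + cl.ny) % cl.ny;
            int az = (cz + off[s][2] + cl.nz) % cl.nz;
            int c2 = (az * cl.ny + ay) * cl.nx + ax;
            for (int i = cl.head[c]; i >= 0; i = cl.nxt[i]) {
              int jstart = (s == 0) ? cl.nxt[i] : cl.head[c2];
              for (int j = jstart; j >= 0; j = cl.nxt[j]) try_pair(i, j);
            }
          }
        }
  }
  int m = (int)pi.size();
  IntegerMatrix P(m, 2);
  NumericVector D(m);
  for (int k = 0; k < m; k++) { P(k, 0) = pi[k]; P(k, 1) = pj[k]; D[k] = pr[k]; }
  return List::create(_["pairs"] = P, _["dist"] = D);
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
             NumericVector mass, NumericVector box,
             NumericMatrix A, NumericMatrix Rcm, NumericMatrix Gam,
             NumericMatrix Bexp, IntegerMatrix style,
             IntegerMatrix bonds, NumericVector kb, NumericVector r0,
             IntegerMatrix angles, NumericVector ka, NumericVector th0,
             NumericVector charge, bool elec_on, double elec_pref,
             double elec_beta, double elec_rc,
             int nsteps, double dt, double T, double lambda,
             double seed, double step0,
             int ensemble, int pmode, double ptarget, double taup,
             int traj_stride, int obs_stride) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n), q(n), m(n);
  double L[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; i++) {
    x[i] = wrap(pos(i, 0), L[0]); y[i] = wrap(pos(i, 1), L[1]); z[i] = wrap(pos(i, 2), L[2]);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
    q[i] = charge[i]; m[i] = mass[i];
  }
  std::vector<int> typ(type.begin(), type.end());
  Tables tb = make_tables(A, Rcm, Gam, Bexp, style);
  double invsqrtdt = 1.0 / std::sqrt(dt);

  ForceOut F;
  uint64_t sd = (uint64_t)seed;
  uint64_t stepkey = sm64(sd ^ sm64((uint64_t)step0));
  compute_forces(x, y, z, vx, vy, vz, typ, L, tb, bonds, kb, r0, angles, ka, th0,
                 q, elec_on, elec_pref, elec_beta, elec_rc, true, T, invsqrtdt,
                 stepkey, F);

  int nobs = (obs_stride > 0) ? nsteps / obs_stride + 1 : 0;
  NumericMatrix obs(nobs > 0 ? nobs : 1, 9); // step Tkin Pxx Pyy Pzz Lx Ly Lz Epot
  int iobs = 0;
  List frames;
  std::vector<double> fx0(n), fy0(n), fz0(n);

  auto record_obs = [&](long step) {
    if (obs_stride <= 0) return;
    double ke = 0, kx = 0, ky = 0, kz = 0;
    for (int i = 0; i < n; i++) {
      kx += m[i] * vx[i] * vx[i]; ky += m[i] * vy[i] * vy[i]; kz += m[i] * vz[i] * vz[i];
    }
    ke = kx + ky + kz;
    double V = L[0] * L[1] * L[2];
    obs(iobs, 0) = (double)step;
    obs(iobs, 1) = ke / (3.0 * n);
    obs(iobs, 2) = (kx + F.W[0]) / V;
    obs(iobs, 3) = (ky + F.W[1]) / V;
    obs(iobs, 4) = (kz + F.W[2]) / V;
    obs(iobs, 5) = L[0]; obs(iobs, 6) = L[1]; obs(iobs, 7) = L[2];
    obs(iobs, 8) = F.e_pair + F.e_bond + F.e_angle + F.e_elec;
    iobs++;
  };
  auto record_frame = [&]() {
    NumericMatrix P(n, 3);
    for (int i = 0; i < n; i++) { P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i]; }
    frames.push_back(List::create(_["pos"] = P,
      _["box"] = NumericVector::create(L[0], L[1], L[2])));
  };

  record_obs((long)step0);
  if (traj_stride > 0) record_frame();

  for (int s = 1; s <= nsteps; s++) {
    long gstep = (long)step0 + s;
    for (int i = 0; i < n; i++) { fx0[i] = F.fx[i]; fy0[i] = F.fy[i]; fz0[i] = F.fz[i]; }
    // position update + lambda velocity prediction (Groot-Warren)
    for (int i = 0; i < n; i++) {
      double im = dt / m[i];
      x[i] = wrap(x[i] + dt * vx[i] + 0.5 * dt * im * fx0[i], L[0]);
      y[i] = wrap(y[i] + dt * vy[i] + 0.5 * dt * im * fy0[i], L[1]);
      z[i] = wrap(z[i] + dt * vz[i] + 0.5 * dt * im * fz0[i], L[2]);
      vx[i] += lambda * im * fx0[i];
      vy[i] += lambda * im * fy0[i];
      vz[i] += lambda * im * fz0[i];
    }
    stepkey = sm64(sd ^ sm64((uint64_t)gstep));
    compute_forces(x, y, z, vx, vy, vz, typ, L, tb, bonds, kb, r0, angles, ka, th0,
                   q, elec_on, elec_pref, elec_beta, elec_rc, true, T, invsqrtdt,
                   stepkey, F);
    for (int i = 0; i < n; i++) {
      double im = dt / m[i];
      vx[i] += 0.5 * im * (fx0[i] + F.fx[i]) - lambda * im * fx0[i];
      vy[i] += 0.5 * im * (fy0[i] + F.fy[i]) - lambda * im * fy0[i];
      vz[i] += 0.5 * im * (fz0[i] + F.fz[i]) - lambda * im * fz0[i];
      if (!std::isfinite(x[i]) || !std::isfinite(vx[i]))
        stop("non-finite coordinate/velocity at step %d, bead %d", s, i + 1);
    }
    if (ensemble == 1) { // Berendsen barostat
      double kx = 0, ky = 0, kz = 0;
      for (int i = 0; i < n; i++) {
        kx += m[i] * vx[i] * vx[i]; ky += m[i] * vy[i] * vy[i]; kz += m[i] * vz[i] * vz[i];
      }
      double V = L[0] * L[1] * L[2];
      double Pxx = (kx + F.W[0]) / V, Pyy = (ky + F.W[1]) / V, Pzz = (kz + F.W[2]) / V;
      double mu[3] = {1.0, 1.0, 1.0};
      double c = dt / taup;
      auto mscale = [&](double P) {
        double u = std::cbrt(1.0 - c * (ptarget - P));
        if (u < 0.998) u = 0.998;
        if (u > 1.002) u = 1.002;
        return u;
      };
      if (pmode == 0) {
        double u = mscale((Pxx + Pyy + Pzz) / 3.0);
        mu[0] = mu[1] = mu[2] = u;
      } else if (pmode == 1) { // semi-isotropic: xy together, z separate
        double ul = mscale(0.5 * (Pxx + Pyy));
        mu[0] = mu[1] = ul; mu[2] = mscale(Pzz);
      } else { // z only
        mu[2] = mscale(Pzz);
      }
      for (int d = 0; d < 3; d++) L[d] *= mu[d];
      for (int i = 0; i < n; i++) {
        x[i] = wrap(x[i] * mu[0], L[0]);
        y[i] = wrap(y[i] * mu[1], L[1]);
        z[i] = wrap(z[i] * mu[2], L[2]);
      }
    }
    if (obs_stride > 0 && s % obs_stride == 0) record_obs(gstep);
    if (traj_stride > 0 && s % traj_stride == 0) record_frame();
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix P(n, 3), Vl(n, 3);
  for (int i = 0; i < n; i++) {
    P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i];
    Vl(i, 0) = vx[i]; Vl(i, 1) = vy[i]; Vl(i, 2) = vz[i];
  }
  colnames(obs) = CharacterVector::create("step", "Tkin", "Pxx", "Pyy", "Pzz",
                                          "Lx", "Ly", "Lz", "Epot");
  return List::create(_["pos"] = P, _["vel"] = Vl,
                      _["box"] = NumericVector::create(L[0], L[1], L[2]),
                      _["obs"] = obs, _["frames"] = frames,
                      _["step_end"] = step0 + nsteps);
}

// Soft-push relaxation: steepest descent on conservative forces with a
// per-step displacement cap; used to remove builder overlaps.
// [[Rcpp::export]]
List cpp_minimize(NumericMatrix pos, IntegerVector type, NumericVector box,
                  NumericMatrix A, NumericMatrix Rcm, NumericMatrix Gam,
                  NumericMatrix Bexp, IntegerMatrix style,
                  IntegerMatrix bonds, NumericVector kb, NumericVector r0,
                  IntegerMatrix angles, NumericVector ka, NumericVector th0,
                  int niter, double dmax) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), v0(n, 0.0), q(n, 0.0);
  double L[3] = {box[0], box[1], box[2]};
  for (int i = 0; i < n; i++) {
    x[i] = wrap(pos(i, 0), L[0]); y[i] = wrap(pos(i, 1), L[1]); z[i] = wrap(pos(i, 2), L[2]);
  }
  std::vector<int> typ(type.begin(), type.end());
  Tables tb = make_tables(A, Rcm, Gam, Bexp, style);
  ForceOut F;
  for (int it = 0; it < niter; it++) {
    compute_forces(x, y, z, v0, v0, v0, typ, L, tb, bonds, kb, r0, angles, ka, th0,
                   q, false, 0, 0, 0, false, 0, 1.0, 0, F);
    double fmax = 1e-12;
    for (int i = 0; i < n; i++) {
      double f = std::sqrt(F.fx[i] * F.fx[i] + F.fy[i] * F.fy[i] + F.fz[i] * F.fz[i]);
      if (f > fmax) fmax = f;
    }
    double al = dmax / fmax;
    for (int i = 0; i < n; i++) {
      x[i] = wrap(x[i] + al * F.fx[i], L[0]);
      y[i] = wrap(y[i] + al * F.fy[i], L[1]);
      z[i] = wrap(z[i] + al * F.fz[i], L[2]);
    }
  }
  NumericMatrix P(n, 3);
  for (int i = 0; i < n; i++) { P(i, 0) = x[i]; P(i, 1) = y[i]; P(i, 2) = z[i]; }
  return List::create(_["pos"] = P);
}
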