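// Core molecular-dynamics engine.
//
// Internal units: nm, ps, kJ/mol (= amu nm^2/ps^2), amu, elementary
// charge; dipole moments are passed in e nm.  All nonbonded terms use
// shifted-force truncation (dipole-dipole: C1 cubic switch), so the
// potential surface is C1 and velocity-Verlet conserves energy to O(dt^2).
//
// The rotational state of a point dipole is a unit axis plus an angular
// velocity kept perpendicular to it (linear rotor: the axial component is
// unphysical).  Orientations are advanced by an exact rotation about the
// angular-velocity axis, so |u| is preserved to round-off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const double KCOUL = 138.935458;   // kJ nm/(mol e^2)
static const double KB    = 0.0083144621; // kJ/(mol K)
static const double PATM  = 16.38855;     // atm per kJ/(mol nm^3)

struct Engine {
  // ---- state ----
  int n = 0, ntypes = 0;
  std::vector<double> x, v, u, w;          // 3n each; x unwrapped
  std::vector<int> type, leaflet, group;   // group: 0 water, 1 lipid
  double box[3] = {0, 0, 0};
  double tnow = 0.0;

  // ---- per-type / per-pair tables ----
  std::vector<double> psig2, p4eps, prc, prc2, prs, psc6, psc12; // ntypes^2
  std::vector<double> q, mu, mass, inertia;
  std::vector<char> hasdip;

  // ---- topology ----
  std::vector<int> bi, bj;              std::vector<double> bk, br0;
  std::vector<int> ai, aj, ak;          std::vector<double> angk, angc0, angt0;
  int angle_style = 0;                  // 0: (k/2)(th-th0)^2, 1: cosine-harmonic
  std::vector<int> rd, ra, rb;          std::vector<double> rkd;
  std::vector<std::vector<int>> excl;   // 1-2 exclusions, sorted

  // ---- neighbour list ----
  double skin = 0.2, maxrc = 1.2;
  std::vector<int> nbi, nbj;
  std::vector<double> xbuild;
  double boxbuild[3] = {0, 0, 0};

  // ---- force/energy accumulators ----
  std::vector<double> f, tq;
  double elj = 0, eqq = 0, eqd = 0, edd = 0, ebond = 0, eang = 0, erest = 0;
  double vir[3] = {0, 0, 0};

  // ---- slab profile accumulation ----
  bool prof_collect = false;
  int nslab = 0;
  std::vector<int> slab_of;
  std::vector<double> slab_wlat, slab_wnorm;

  inline double mi(double d, int a) const {
    return d - box[a] * std::nearbyint(d / box[a]);
  }
  inline bool excluded(int i, int j) const {
    const std::vector<int>& e = excl[i];
    for (size_t k = 0; k < e.size(); ++k) if (e[k] == j) return true;
    return false;
  }

  void build_list() {
    for (int a = 0; a < 3; ++a)
      if (box[a] < 2.0 * maxrc)
        stop("box length %g nm along axis %d is below twice the maximum "
             "cutoff (%g nm): minimum-image convention invalid",
             box[a], a + 1, maxrc);
    nbi.clear(); nbj.clear();
    const double rl = maxrc + skin, rl2 = rl * rl;
    int nc[3];
    for (int a = 0; a < 3; ++a) nc[a] = (int)std::floor(box[a] / rl);
    bool cells = nc[0] >= 3 && nc[1] >= 3 && nc[2] >= 3 && n > 200;
    if (!cells) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = mi(x[3*i] - x[3*j], 0);
          double dy = mi(x[3*i+1] - x[3*j+1], 1);
          double dz = mi(x[3*i+2] - x[3*j+2], 2);
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 < rl2 && !excluded(i, j)) { nbi.push_back(i); nbj.push_back(j); }
        }
    } else {
      int ncell = nc[0] * nc[1] * nc[2];
      std::vector<int> head(ncell, -1), nxt(n, -1), cidx(n);
      for (int i = 0; i < n; ++i) {
        int c[3];
        for (int a = 0; a < 3; ++a) {
          double xa = x[3*i+a] - box[a] * std::floor(x[3*i+a] / box[a]);
          int ca = (int)(xa / box[a] * nc[a]);
          if (ca >= nc[a]) ca = nc[a] - 1;
          if (ca < 0) ca = 0;
          c[a] = ca;
        }
        int cc = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
        cidx[i] = cc; nxt[i] = head[cc]; head[cc] = i;
      }
      for (int cz = 0; cz < nc[2]; ++cz)
        for (int cy = 0; cy < nc[1]; ++cy)
          for (int cx = 0; cx < nc[0]; ++cx) {
            int cc = (cz * nc[1] + cy) * nc[0] + cx;
            for (int ddz = -1; ddz <= 1; ++ddz)
              for (int ddy = -1; ddy <= 1; ++ddy)
                for (int ddx = -1; ddx <= 1; ++ddx) {
                  int ox = (cx + ddx + nc[0]) % nc[0];
                  int oy = (cy + ddy + nc[1]) % nc[1];
                  int oz = (cz + ddz + nc[2]) % nc[2];
                  int oc = (oz * nc[1] + oy) * nc[0] + ox;
                  if (oc < cc) continue;        // visit each cell pair once
                  for (int i = head[cc]; i >= 0; i = nxt[i])
                    for (int j = (oc == cc ? nxt[i] : head[oc]); j >= 0; j = nxt[j]) {
                      double dx = mi(x[3*i] - x[3*j], 0);
                      double dy = mi(x[3*i+1] - x[3*j+1], 1);
                      double dz = mi(x[3*i+2] - x[3*j+2], 2);
                      double r2 = dx*dx + dy*dy + dz*dz;
                      if (r2 < rl2 && !excluded(i, j)) {
                        nbi.push_back(i); nbj.push_back(j);
                      }
                    }
                }
          }
    }
    xbuild = x;
    for (int a = 0; a < 3; ++a) boxbuild[a] = box[a];
  }

  bool need_rebuild() const {
    const double thr2 = 0.25 * skin * skin;   // (skin/2)^2 per particle
    for (int a = 0; a < 3; ++a)
      if (std::fabs(box[a] - boxbuild[a]) > 5e-4 * boxbuild[a]) return true;
    for (int i = 0; i < 3 * n; ++i) {
      double d = x[i] - xbuild[i];
      if (d * d > thr2) return true;
    }
    return false;
  }

  void slab_index() {
    // z origin at the lipid mass centre (or box centre for pure water)
    double zc = 0, msum = 0;
    bool anylip = false;
    for (int i = 0; i < n; ++i) if (group[i] == 1) {
      anylip = true;
      double m = mass[type[i]];
      zc += m * x[3*i+2]; msum += m;
    }
    zc = anylip ? zc / msum : 0.5 * box[2];
    slab_of.resize(n);
    for (int i = 0; i < n; ++i) {
      double z = x[3*i+2] - zc + 0.5 * box[2];
      z -= box[2] * std::floor(z / box[2]);
      int s = (int)(z / box[2] * nslab);
      if (s >= nslab) s = nslab - 1;
      if (s < 0) s = 0;
      slab_of[i] = s;
    }
  }

  inline void slab_pair(int i, int j, double wlat, double wnorm) {
    slab_wlat[slab_of[i]] += 0.5 * wlat;  slab_wlat[slab_of[j]] += 0.5 * wlat;
    slab_wnorm[slab_of[i]] += 0.5 * wnorm; slab_wnorm[slab_of[j]] += 0.5 * wnorm;
  }

  void forces() {
    std::fill(f.begin(), f.end(), 0.0);
    std::fill(tq.begin(), tq.end(), 0.0);
    elj = eqq = eqd = edd = ebond = eang = erest = 0;
    vir[0] = vir[1] = vir[2] = 0;
    if (prof_collect) {
      slab_wlat.assign(nslab, 0.0);
      slab_wnorm.assign(nslab, 0.0);
      slab_index();
    }

    const int nt = ntypes;
    const size_t npair = nbi.size();
    for (size_t p = 0; p < npair; ++p) {
      const int i = nbi[p], j = nbj[p];
      const int ti = type[i], tj = type[j], tt = ti * nt + tj;
      double dx = mi(x[3*i] - x[3*j], 0);
      double dy = mi(x[3*i+1] - x[3*j+1], 1);
      double dz = mi(x[3*i+2] - x[3*j+2], 2);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= prc2[tt]) continue;
      if (r2 < 1e-12)
        stop("overlapping sites (%d, %d): r < 1e-6 nm", i + 1, j + 1);
      const double r = std::sqrt(r2), rinv = 1.0 / r;
      const double rcv = prc[tt];
      double fx = 0, fy = 0, fz = 0;

      // Lennard-Jones, Stoddard-Ford shifted force
      {
        const double s2 = psig2[tt] / r2;
        const double sr6 = s2 * s2 * s2, sr12 = sr6 * sr6;
        const double A = p4eps[tt], sc6 = psc6[tt], sc12 = psc12[tt];
        elj += A * (sr12 - sr6 + (6*sc12 - 3*sc6) * (r2 / (rcv*rcv))
                    - 7*sc12 + 4*sc6);
        const double fr = A * ((12*sr12 - 6*sr6) * rinv
                               - 2 * (6*sc12 - 3*sc6) * r / (rcv*rcv));
        fx += fr * dx * rinv; fy += fr * dy * rinv; fz += fr * dz * rinv;
      }

      const double qi = q[ti], qj = q[tj];
      const bool di = hasdip[ti], dj = hasdip[tj];

      if (qi != 0.0 && qj != 0.0) {  // shifted-force Coulomb
        const double k = KCOUL * qi * qj;
        eqq += k * (rinv - 1.0/rcv + (r - rcv)/(rcv*rcv));
        const double fr = k * (rinv*rinv - 1.0/(rcv*rcv));
        fx += fr * dx * rinv; fy += fr * dy * rinv; fz += fr * dz * rinv;
      }

      // charge(i)-dipole(j): r runs from the dipole to the charge
      if (qi != 0.0 && dj) {
        const double pxj = mu[tj]*u[3*j], pyj = mu[tj]*u[3*j+1],
                     pzj = mu[tj]*u[3*j+2];
        const double a = (pxj*dx + pyj*dy + pzj*dz) * rinv;
        const double g  = rinv*rinv - 3.0/(rcv*rcv) + 2.0*r/(rcv*rcv*rcv);
        const double dg = -2.0*rinv*rinv*rinv + 2.0/(rcv*rcv*rcv);
        const double k = KCOUL * qi;
        eqd += k * a * g;
        const double c1 = k * g * rinv;   // multiplies (p - a rhat)
        fx += -(c1 * (pxj - a*dx*rinv) + k*a*dg * dx*rinv);
        fy += -(c1 * (pyj - a*dy*rinv) + k*a*dg * dy*rinv);
        fz += -(c1 * (pzj - a*dz*rinv) + k*a*dg * dz*rinv);
        // torque on dipole j: -k g (p x rhat)
        tq[3*j]   += -k*g*( pyj*dz*rinv - pzj*dy*rinv);
        tq[3*j+1] += -k*g*( pzj*dx*rinv - pxj*dz*rinv);
        tq[3*j+2] += -k*g*( pxj*dy*rinv - pyj*dx*rinv);
      }
      // charge(j)-dipole(i): separation from dipole i to charge j = -d
      if (qj != 0.0 && di) {
        const double pxi = mu[ti]*u[3*i], pyi = mu[ti]*u[3*i+1],
                     pzi = mu[ti]*u[3*i+2];
        const double a = -(pxi*dx + pyi*dy + pzi*dz) * rinv;
        const double g  = rinv*rinv - 3.0/(rcv*rcv) + 2.0*r/(rcv*rcv*rcv);
        const double dg = -2.0*rinv*rinv*rinv + 2.0/(rcv*rcv*rcv);
        const double k = KCOUL * qj;
        eqd += k * a * g;
        const double c1 = k * g * rinv;
        // force on charge j along -rhat geometry; force on i is its negative,
        // accumulate as force on i (+fx convention):
        fx += (c1 * (pxi + a*dx*rinv) - k*a*dg * dx*rinv);
        fy += (c1 * (pyi + a*dy*rinv) - k*a*dg * dy*rinv);
        fz += (c1 * (pzi + a*dz*rinv) - k*a*dg * dz*rinv);
        tq[3*i]   += -k*g*(-(pyi*dz - pzi*dy)*rinv);
        tq[3*i+1] += -k*g*(-(pzi*dx - pxi*dz)*rinv);
        tq[3*i+2] += -k*g*(-(pxi*dy - pyi*dx)*rinv);
      }

      if (di && dj) {  // switched dipole-dipole
        const double rsv = prs[tt];
        const double pxi = mu[ti]*u[3*i], pyi = mu[ti]*u[3*i+1],
                     pzi = mu[ti]*u[3*i+2];
        const double pxj = mu[tj]*u[3*j], pyj = mu[tj]*u[3*j+1],
                     pzj = mu[tj]*u[3*j+2];
        const double ai_ = (pxi*dx + pyi*dy + pzi*dz) * rinv;
        const double aj_ = (pxj*dx + pyj*dy + pzj*dz) * rinv;
        const double dot = pxi*pxj + pyi*pyj + pzi*pzj;
        double S = 1.0, dS = 0.0;
        if (r > rsv) {
          const double d3 = (rcv - rsv)*(rcv - rsv)*(rcv - rsv);
          S  = 1.0 - (r - rsv)*(r - rsv)*(3*rcv - rsv - 2*r) / d3;
          dS = -6.0 * (r - rsv) * (rcv - r) / d3;
        }
        const double r3i = rinv*rinv*rinv;
        const double u0 = KCOUL * (dot - 3.0*ai_*aj_) * r3i;
        edd += S * u0;
        const double c = 3.0 * KCOUL * r3i * rinv;
        const double fr0x = c * ((dot - 5.0*ai_*aj_)*dx*rinv + aj_*pxi + ai_*pxj);
        const double fr0y = c * ((dot - 5.0*ai_*aj_)*dy*rinv + aj_*pyi + ai_*pyj);
        const double fr0z = c * ((dot - 5.0*ai_*aj_)*dz*rinv + aj_*pzi + ai_*pzj);
        fx += S * fr0x - dS * u0 * dx * rinv;
        fy += S * fr0y - dS * u0 * dy * rinv;
        fz += S * fr0z - dS * u0 * dz * rinv;
        // field of j at i and of i at j (switched)
        const double exj = KCOUL * (3.0*aj_*dx*rinv - pxj) * r3i;
        const double eyj = KCOUL * (3.0*aj_*dy*rinv - pyj) * r3i;
        const double ezj = KCOUL * (3.0*aj_*dz*rinv - pzj) * r3i;
        tq[3*i]   += S * (pyi*ezj - pzi*eyj);
        tq[3*i+1] += S * (pzi*exj - pxi*ezj);
        tq[3*i+2] += S * (pxi*eyj - pyi*exj);
        const double exi = KCOUL * (3.0*ai_*dx*rinv - pxi) * r3i;
        const double eyi = KCOUL * (3.0*ai_*dy*rinv - pyi) * r3i;
        const double ezi = KCOUL * (3.0*ai_*dz*rinv - pzi) * r3i;
        tq[3*j]   += S * (pyj*ezi - pzj*eyi);
        tq[3*j+1] += S * (pzj*exi - pxj*ezi);
        tq[3*j+2] += S * (pxj*eyi - pyj*exi);
      }

      f[3*i] += fx;   f[3*i+1] += fy;   f[3*i+2] += fz;
      f[3*j] -= fx;   f[3*j+1] -= fy;   f[3*j+2] -= fz;
      vir[0] += dx*fx; vir[1] += dy*fy; vir[2] += dz*fz;
      if (prof_collect) slab_pair(i, j, 0.5*(dx*fx + dy*fy), dz*fz);
    }

    // bonds
    for (size_t b = 0; b < bi.size(); ++b) {
      const int i = bi[b], j = bj[b];
      double dx = mi(x[3*i] - x[3*j], 0);
      double dy = mi(x[3*i+1] - x[3*j+1], 1);
      double dz = mi(x[3*i+2] - x[3*j+2], 2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double dr = r - br0[b];
      ebond += 0.5 * bk[b] * dr * dr;
      double fr = -bk[b] * dr / r;
      double fx = fr*dx, fy = fr*dy, fz = fr*dz;
      f[3*i] += fx; f[3*i+1] += fy; f[3*i+2] += fz;
      f[3*j] -= fx; f[3*j+1] -= fy; f[3*j+2] -= fz;
      vir[0] += dx*fx; vir[1] += dy*fy; vir[2] += dz*fz;
      if (prof_collect) slab_pair(i, j, 0.5*(dx*fx + dy*fy), dz*fz);
    }

    // cosine-harmonic angles
    for (size_t t = 0; t < ai.size(); ++t) {
      const int i = ai[t], j = aj[t], k = ak[t];
      double axv = mi(x[3*i] - x[3*j], 0), ayv = mi(x[3*i+1] - x[3*j+1], 1),
             azv = mi(x[3*i+2] - x[3*j+2], 2);
      double bxv = mi(x[3*k] - x[3*j], 0), byv = mi(x[3*k+1] - x[3*j+1], 1),
             bzv = mi(x[3*k+2] - x[3*j+2], 2);
      double la2 = axv*axv + ayv*ayv + azv*azv;
      double lb2 = bxv*bxv + byv*byv + bzv*bzv;
      double la = std::sqrt(la2), lb = std::sqrt(lb2);
      double cth = (axv*bxv + ayv*byv + azv*bzv) / (la * lb);
      if (cth > 1) cth = 1; if (cth < -1) cth = -1;
      double pref;  // dU/dcos(theta)
      if (angle_style == 1) {
        double diff = cth - angc0[t];
        eang += 0.5 * angk[t] * diff * diff;
        pref = angk[t] * diff;
      } else {
        double th = std::acos(cth), dth = th - angt0[t];
        eang += 0.5 * angk[t] * dth * dth;
        double sth = std::sin(th);
        pref = -angk[t] * dth / (sth > 1e-8 ? sth : 1e-8);
      }
      // dc/dri and dc/drk
      double dcix = bxv/(la*lb) - cth*axv/la2;
      double dciy = byv/(la*lb) - cth*ayv/la2;
      double dciz = bzv/(la*lb) - cth*azv/la2;
      double dckx = axv/(la*lb) - cth*bxv/lb2;
      double dcky = ayv/(la*lb) - cth*byv/lb2;
      double dckz = azv/(la*lb) - cth*bzv/lb2;
      double fix = -pref*dcix, fiy = -pref*dciy, fiz = -pref*dciz;
      double fkx = -pref*dckx, fky = -pref*dcky, fkz = -pref*dckz;
      f[3*i] += fix; f[3*i+1] += fiy; f[3*i+2] += fiz;
      f[3*k] += fkx; f[3*k+1] += fky; f[3*k+2] += fkz;
      f[3*j] -= fix + fkx; f[3*j+1] -= fiy + fky; f[3*j+2] -= fiz + fkz;
      vir[0] += axv*fix + bxv*fkx;
      vir[1] += ayv*fiy + byv*fky;
      vir[2] += azv*fiz + bzv*fkz;
      if (prof_collect) {
        double wlat = 0.5*(axv*fix + ayv*fiy + bxv*fkx + byv*fky);
        double wn = azv*fiz + bzv*fkz;
        slab_wlat[slab_of[j]] += wlat;  // whole 3-body term to the apex slab
        slab_wnorm[slab_of[j]] += wn;
      }
    }

    // dipole orientation restraints
    for (size_t t = 0; t < rd.size(); ++t) {
      const int d = rd[t], a = ra[t], b = rb[t];
      double dx = mi(x[3*b] - x[3*a], 0);
      double dy = mi(x[3*b+1] - x[3*a+1], 1);
      double dz = mi(x[3*b+2] - x[3*a+2], 2);
      double lb_ = std::sqrt(dx*dx + dy*dy + dz*dz);
      double bx = dx/lb_, by = dy/lb_, bz = dz/lb_;
      double ux = u[3*d], uy = u[3*d+1], uz = u[3*d+2];
      double cd = ux*bx + uy*by + uz*bz;
      erest += rkd[t] * (1.0 - cd);
      tq[3*d]   += rkd[t] * (uy*bz - uz*by);
      tq[3*d+1] += rkd[t] * (uz*bx - ux*bz);
      tq[3*d+2] += rkd[t] * (ux*by - uy*bx);
      double fbx = rkd[t] * (ux - cd*bx) / lb_;
      double fby = rkd[t] * (uy - cd*by) / lb_;
      double fbz = rkd[t] * (uz - cd*bz) / lb_;
      f[3*b] += fbx; f[3*b+1] += fby; f[3*b+2] += fbz;
      f[3*a] -= fbx; f[3*a+1] -= fby; f[3*a+2] -= fbz;
      vir[0] += dx*fbx; vir[1] += dy*fby; vir[2] += dz*fbz;
      if (prof_collect) slab_pair(a, b, 0.5*(dx*fbx + dy*fby), dz*fbz);
    }
  }

  // ---- integration ----
  void halfkick(double hdt) {
    for (int i = 0; i < n; ++i) {
      const double im = hdt / mass[type[i]];
      v[3*i] += f[3*i]*im; v[3*i+1] += f[3*i+1]*im; v[3*i+2] += f[3*i+2]*im;
      if (hasdip[type[i]]) {
        const double ii = hdt / inertia[type[i]];
        double ux = u[3*i], uy = u[3*i+1], uz = u[3*i+2];
        double tx = tq[3*i], ty = tq[3*i+1], tz = tq[3*i+2];
        double ta = tx*ux + ty*uy + tz*uz;   // axial part is unphysical
        w[3*i]   += (tx - ta*ux) * ii;
        w[3*i+1] += (ty - ta*uy) * ii;
        w[3*i+2] += (tz - ta*uz) * ii;
        double wa = w[3*i]*ux + w[3*i+1]*uy + w[3*i+2]*uz;
        w[3*i] -= wa*ux; w[3*i+1] -= wa*uy; w[3*i+2] -= wa*uz;
      }
    }
  }

  void drift(double dt) {
    for (int i = 0; i < n; ++i) {
      x[3*i] += v[3*i]*dt; x[3*i+1] += v[3*i+1]*dt; x[3*i+2] += v[3*i+2]*dt;
      if (hasdip[type[i]]) {
        double wx = w[3*i], wy = w[3*i+1], wz = w[3*i+2];
        double wm = std::sqrt(wx*wx + wy*wy + wz*wz);
        if (wm > 1e-14) {
          double phi = wm * dt, c = std::cos(phi), s = std::sin(phi);
          double kx = wx/wm, ky = wy/wm, kz = wz/wm;
          double ux = u[3*i], uy = u[3*i+1], uz = u[3*i+2];
          // u perp k: Rodrigues reduces to u c + (k x u) s
          double nx = ux*c + (ky*uz - kz*uy)*s;
          double ny = uy*c + (kz*ux - kx*uz)*s;
          double nz = uz*c + (kx*uy - ky*ux)*s;
          double nm = std::sqrt(nx*nx + ny*ny + nz*nz);
          u[3*i] = nx/nm; u[3*i+1] = ny/nm; u[3*i+2] = nz/nm;
        }
      }
    }
  }

  // ---- kinetic bookkeeping ----
  void kinetic(double ke_t[2], double ke_r[2]) const {
    ke_t[0] = ke_t[1] = ke_r[0] = ke_r[1] = 0;
    for (int i = 0; i < n; ++i) {
      const int g = group[i];
      ke_t[g] += 0.5 * mass[type[i]] *
        (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
      if (hasdip[type[i]])
        ke_r[g] += 0.5 * inertia[type[i]] *
          (w[3*i]*w[3*i] + w[3*i+1]*w[3*i+1] + w[3*i+2]*w[3*i+2]);
    }
  }

  void thermostat(double dt, double tau, const double T0[2],
                  const double dof_t[2], const double dof_r[2]) {
    double ke_t[2], ke_r[2];
    kinetic(ke_t, ke_r);
    double lam_t[2] = {1, 1}, lam_r[2] = {1, 1};
    for (int g = 0; g < 2; ++g) {
      if (dof_t[g] > 0 && ke_t[g] > 0) {
        double T = 2*ke_t[g] / (dof_t[g]*KB);
        double l2 = 1 + dt/tau * (T0[g]/T - 1);
        lam_t[g] = std::sqrt(std::min(std::max(l2, 0.64), 1.5625));
      }
      if (dof_r[g] > 0 && ke_r[g] > 0) {
        double T = 2*ke_r[g] / (dof_r[g]*KB);
        double l2 = 1 + dt/tau * (T0[g]/T - 1);
        lam_r[g] = std::sqrt(std::min(std::max(l2, 0.64), 1.5625));
      }
    }
    for (int i = 0; i < n; ++i) {
      const int g = group[i];
      v[3*i] *= lam_t[g]; v[3*i+1] *= lam_t[g]; v[3*i+2] *= lam_t[g];
      if (hasdip[type[i]]) {
        w[3*i] *= lam_r[g]; w[3*i+1] *= lam_r[g]; w[3*i+2] *= lam_r[g];
      }
    }
  }

  void remove_com_drift() {
    double px = 0, py = 0, pz = 0, M = 0;
    for (int i = 0; i < n; ++i) {
      double m = mass[type[i]];
      px += m*v[3*i]; py += m*v[3*i+1]; pz += m*v[3*i+2]; M += m;
    }
    px /= M; py /= M; pz /= M;
    for (int i = 0; i < n; ++i) { v[3*i] -= px; v[3*i+1] -= py; v[3*i+2] -= pz; }
  }

  // Zero the lateral momentum of each monolayer and, so the total
  // momentum stays zero alongside, of the water group.
  void remove_leaflet_drift() {
    for (int g = 0; g < 3; ++g) {
      double px = 0, py = 0, M = 0;
      for (int i = 0; i < n; ++i) {
        bool in = (g < 2) ? (group[i] == 1 && leaflet[i] == g)
                          : (group[i] == 0);
        if (in) {
          double m = mass[type[i]];
          px += m*v[3*i]; py += m*v[3*i+1]; M += m;
        }
      }
      if (M == 0) continue;
      px /= M; py /= M;
      for (int i = 0; i < n; ++i) {
        bool in = (g < 2) ? (group[i] == 1 && leaflet[i] == g)
                          : (group[i] == 0);
        if (in) { v[3*i] -= px; v[3*i+1] -= py; }
      }
    }
  }

  void pressure(double P[3]) const {
    double V = box[0]*box[1]*box[2];
    double kxx = 0, kyy = 0, kzz = 0;
    for (int i = 0; i < n; ++i) {
      double m = mass[type[i]];
      kxx += m*v[3*i]*v[3*i]; kyy += m*v[3*i+1]*v[3*i+1];
      kzz += m*v[3*i+2]*v[3*i+2];
    }
    P[0] = (kxx + vir[0]) / V * PATM;
    P[1] = (kyy + vir[1]) / V * PATM;
    P[2] = (kzz + vir[2]) / V * PATM;
  }

  void barostat(int mode, double dt, double tau, double kappa, double P0) {
    double P[3];
    pressure(P);
    double s[3] = {1, 1, 1};
    const double c = kappa * dt / tau / 3.0;  // cube-root linearised factor
    if (mode == 1) {                           // isotropic
      double Pm = (P[0] + P[1] + P[2]) / 3.0;
      s[0] = s[1] = s[2] = 1.0 - c * (P0 - Pm);
    } else if (mode == 2) {                    // semi-isotropic (z | xy)
      double Pl = 0.5 * (P[0] + P[1]);
      s[0] = s[1] = 1.0 - c * (P0 - Pl);
      s[2] = 1.0 - c * (P0 - P[2]);
    } else if (mode == 3) {                    // anisotropic
      for (int a = 0; a < 3; ++a) s[a] = 1.0 - c * (P0 - P[a]);
    }
    for (int a = 0; a < 3; ++a) {
      if (s[a] < 0.98) s[a] = 0.98;
      if (s[a] > 1.02) s[a] = 1.02;
      box[a] *= s[a];
    }
    for (int i = 0; i < n; ++i) {
      x[3*i] *= s[0]; x[3*i+1] *= s[1]; x[3*i+2] *= s[2];
    }
  }
};

static Engine make_engine(List state, List ff, List topo) {
  Engine E;
  NumericMatrix pos = state["pos"], vel = state["vel"],
                uu = state["u"], om = state["omega"];
  IntegerVector ty = state["type"], lf = state["leaflet"],
                gr = state["group"];
  NumericVector bx = state["box"];
  E.n = pos.nrow();
  E.x.resize(3*E.n); E.v.resize(3*E.n); E.u.resize(3*E.n); E.w.resize(3*E.n);
  E.type.resize(E.n); E.leaflet.resize(E.n); E.group.resize(E.n);
  for (int i = 0; i < E.n; ++i) {
    for (int a = 0; a < 3; ++a) {
      E.x[3*i+a] = pos(i, a); E.v[3*i+a] = vel(i, a);
      E.u[3*i+a] = uu(i, a);  E.w[3*i+a] = om(i, a);
    }
    E.type[i] = ty[i] - 1;
    E.leaflet[i] = lf[i] == NA_INTEGER ? -1 : lf[i];
    E.group[i] = gr[i];
  }
  for (int a = 0; a < 3; ++a) E.box[a] = bx[a];
  E.tnow = as<double>(state["time"]);

  NumericMatrix sig = ff["sigma_ij"], eps = ff["eps_ij"],
                rc = ff["rc_ij"], rs = ff["rs_ij"];
  NumericVector qv = ff["charge"], muv = ff["mu"],
                mv = ff["mass"], iv = ff["inertia"];
  E.ntypes = sig.nrow();
  int nt = E.ntypes;
  E.psig2.resize(nt*nt); E.p4eps.resize(nt*nt); E.prc.resize(nt*nt);
  E.prc2.resize(nt*nt); E.prs.resize(nt*nt);
  E.psc6.resize(nt*nt); E.psc12.resize(nt*nt);
  std::vector<char> present(nt, 0);
  for (int i = 0; i < E.n; ++i) present[E.type[i]] = 1;
  E.maxrc = 0;
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < nt; ++j) {
      int t = i*nt + j;
      E.psig2[t] = sig(i, j)*sig(i, j);
      E.p4eps[t] = 4.0*eps(i, j);
      E.prc[t] = rc(i, j); E.prc2[t] = rc(i, j)*rc(i, j);
      E.prs[t] = rs(i, j);
      double sc2 = sig(i, j)*sig(i, j)/(rc(i, j)*rc(i, j));
      E.psc6[t] = sc2*sc2*sc2; E.psc12[t] = E.psc6[t]*E.psc6[t];
      if (present[i] && present[j] && rc(i, j) > E.maxrc)
        E.maxrc = rc(i, j);
    }
  E.q.assign(qv.begin(), qv.end());
  E.mu.assign(muv.begin(), muv.end());
  E.mass.assign(mv.begin(), mv.end());
  E.inertia.assign(iv.begin(), iv.end());
  E.hasdip.resize(nt);
  for (int i = 0; i < nt; ++i) E.hasdip[i] = E.mu[i] > 0;

  IntegerMatrix bonds = topo["bonds"];
  NumericVector bkv = topo["bond_k"], br0v = topo["bond_r0"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    E.bi.push_back(bonds(b, 0) - 1); E.bj.push_back(bonds(b, 1) - 1);
    E.bk.push_back(bkv[b]); E.br0.push_back(br0v[b]);
  }
  IntegerMatrix angs = topo["angles"];
  NumericVector akv = topo["angle_k"], ac0 = topo["angle_cos0"],
                at0 = topo["angle_theta0"];
  E.angle_style = as<int>(topo["angle_style"]);
  for (int t = 0; t < angs.nrow(); ++t) {
    E.ai.push_back(angs(t, 0) - 1); E.aj.push_back(angs(t, 1) - 1);
    E.ak.push_back(angs(t, 2) - 1);
    E.angk.push_back(akv[t]); E.angc0.push_back(ac0[t]);
    E.angt0.push_back(at0[t]);
  }
  IntegerMatrix res = topo["restraints"];
  NumericVector rkv = topo["restraint_k"];
  for (int t = 0; t < res.nrow(); ++t) {
    E.rd.push_back(res(t, 0) - 1); E.ra.push_back(res(t, 1) - 1);
    E.rb.push_back(res(t, 2) - 1);
    E.rkd.push_back(rkv[t]);
  }
  E.excl.assign(E.n, {});
  for (size_t b = 0; b < E.bi.size(); ++b) {
    E.excl[E.bi[b]].push_back(E.bj[b]);
    E.excl[E.bj[b]].push_back(E.bi[b]);
  }
  E.f.assign(3*E.n, 0.0); E.tq.assign(3*E.n, 0.0);
  return E;
}

static List state_out(const Engine& E) {
  NumericMatrix pos(E.n, 3), vel(E.n, 3), uu(E.n, 3), om(E.n, 3);
  for (int i = 0; i < E.n; ++i)
    for (int a = 0; a < 3; ++a) {
      pos(i, a) = E.x[3*i+a]; vel(i, a) = E.v[3*i+a];
      uu(i, a) = E.u[3*i+a];  om(i, a) = E.w[3*i+a];
    }
  return List::create(_["pos"] = pos, _["vel"] = vel, _["u"] = uu,
                      _["omega"] = om,
                      _["box"] = NumericVector::create(E.box[0], E.box[1],
                                                       E.box[2]),
                      _["time"] = E.tnow);
}

// [[Rcpp::export]]
List eval_forces_cpp(List state, List ff, List topo, double skin = 0.2) {
  Engine E = make_engine(state, ff, topo);
  E.skin = skin;
  E.build_list();
  E.forces();
  NumericMatrix fo(E.n, 3), to(E.n, 3);
  for (int i = 0; i < E.n; ++i)
    for (int a = 0; a < 3; ++a) { fo(i, a) = E.f[3*i+a]; to(i, a) = E.tq[3*i+a]; }
  NumericVector en = NumericVector::create(
    _["lj"] = E.elj, _["coulomb"] = E.eqq, _["charge_dipole"] = E.eqd,
    _["dipole_dipole"] = E.edd, _["bond"] = E.ebond, _["angle"] = E.eang,
    _["restraint"] = E.erest);
  return List::create(_["forces"] = fo, _["torques"] = to,
                      _["energies"] = en,
                      _["virial"] = NumericVector::create(E.vir[0], E.vir[1],
                                                          E.vir[2]),
                      _["npairs"] = (int)E.nbi.size());
}

// [[Rcpp::export]]
IntegerMatrix neighbor_pairs_cpp(List state, List ff, List topo,
                                 double skin = 0.2) {
  Engine E = make_engine(state, ff, topo);
  E.skin = skin;
  E.build_list();
  // trim to the per-pair cutoff + skin (the internal list is built with
  // the global maximum cutoff and filtered in the force kernel)
  std::vector<int> oi, oj;
  for (size_t p = 0; p < E.nbi.size(); ++p) {
    int i = E.nbi[p], j = E.nbj[p];
    double dx = E.mi(E.x[3*i] - E.x[3*j], 0);
    double dy = E.mi(E.x[3*i+1] - E.x[3*j+1], 1);
    double dz = E.mi(E.x[3*i+2] - E.x[3*j+2], 2);
    double rc = E.prc[E.type[i]*E.ntypes + E.type[j]] + skin;
    if (dx*dx + dy*dy + dz*dz < rc*rc) { oi.push_back(i); oj.push_back(j); }
  }
  IntegerMatrix out(oi.size(), 2);
  for (size_t p = 0; p < oi.size(); ++p) {
    out(p, 0) = oi[p] + 1; out(p, 1) = oj[p] + 1;
  }
  return out;
}

// [[Rcpp::export]]
List md_run_cpp(List state, List ff, List topo, List ctrl) {
  Engine E = make_engine(state, ff, topo);

  const int nsteps = as<int>(ctrl["nsteps"]);
  const double dt = as<double>(ctrl["dt"]);
  E.skin = as<double>(ctrl["skin"]);
  const bool thermo_on = as<bool>(ctrl["thermo_on"]);
  const double tau_t = as<double>(ctrl["tau_t"]);
  const double T0[2] = {as<double>(ctrl["T0_water"]), as<double>(ctrl["T0_lipid"])};
  NumericVector dtv = ctrl["dof_trans"], drv = ctrl["dof_rot"];
  const double dof_t[2] = {dtv[0], dtv[1]};
  const double dof_r[2] = {drv[0], drv[1]};
  const double dof_total = as<double>(ctrl["dof_total"]);
  const int baro_mode = as<int>(ctrl["baro_mode"]);
  const double tau_p = as<double>(ctrl["tau_p"]);
  const double kappa = as<double>(ctrl["kappa"]);
  const double P0 = as<double>(ctrl["P0"]);
  const bool com_remove = as<bool>(ctrl["com_remove"]);
  const bool leaflet_remove = as<bool>(ctrl["leaflet_remove"]);
  const int e_stride = as<int>(ctrl["e_stride"]);
  const int x_stride = as<int>(ctrl["x_stride"]);
  const int prof_stride = as<int>(ctrl["prof_stride"]);
  E.nslab = as<int>(ctrl["prof_nslab"]);

  const int nlog = e_stride > 0 ? nsteps / e_stride : 0;
  const int ncol = 19;
  NumericMatrix elog(nlog, ncol);
  const int nframes = x_stride > 0 ? nsteps / x_stride : 0;
  std::vector<double> tr_pos, tr_u, tr_box, tr_time;
  if (nframes > 0) {
    tr_pos.reserve((size_t)nframes * 3 * E.n);
    tr_u.reserve((size_t)nframes * 3 * E.n);
  }
  std::vector<double> prof_PT, prof_PN;
  int prof_nacc = 0;
  if (prof_stride > 0) {
    prof_PT.assign(E.nslab, 0.0);
    prof_PN.assign(E.nslab, 0.0);
  }

  E.build_list();
  E.forces();

  Engine last_good = E;
  std::string status = "ok";
  int ilog = 0;

  for (int step = 1; step <= nsteps; ++step) {
    E.halfkick(0.5*dt);
    E.drift(dt);
    if (E.need_rebuild()) E.build_list();
    E.prof_collect = prof_stride > 0 && step % prof_stride == 0;
    E.forces();
    E.halfkick(0.5*dt);
    E.tnow += dt;

    if (thermo_on) E.thermostat(dt, tau_t, T0, dof_t, dof_r);
    if (com_remove) E.remove_com_drift();
    if (leaflet_remove) E.remove_leaflet_drift();
    if (baro_mode > 0) E.barostat(baro_mode, dt, tau_p, kappa, P0);

    if (E.prof_collect) {
      // kinetic slab contribution at the synchronised step
      std::vector<double> klat(E.nslab, 0.0), knorm(E.nslab, 0.0);
      E.slab_index();
      for (int i = 0; i < E.n; ++i) {
        double m = E.mass[E.type[i]];
        klat[E.slab_of[i]] += 0.5*m*(E.v[3*i]*E.v[3*i] + E.v[3*i+1]*E.v[3*i+1]);
        knorm[E.slab_of[i]] += m*E.v[3*i+2]*E.v[3*i+2];
      }
      double vslab = E.box[0]*E.box[1]*E.box[2] / E.nslab;
      for (int s = 0; s < E.nslab; ++s) {
        prof_PT[s] += (klat[s] + E.slab_wlat[s]) / vslab * PATM;
        prof_PN[s] += (knorm[s] + E.slab_wnorm[s]) / vslab * PATM;
      }
      ++prof_nacc;
      E.prof_collect = false;
    }

    if (e_stride > 0 && step % e_stride == 0) {
      double ke_t[2], ke_r[2], P[3];
      E.kinetic(ke_t, ke_r);
      E.pressure(P);
      double pe = E.elj + E.eqq + E.eqd + E.edd + E.ebond + E.eang + E.erest;
      double ke = ke_t[0] + ke_t[1] + ke_r[0] + ke_r[1];
      double etot = pe + ke;
      if (!std::isfinite(etot)) { status = "unstable"; break; }
      double row[ncol] = {
        (double)step, E.tnow, E.elj, E.eqq, E.eqd, E.edd, E.ebond, E.eang,
        E.erest, ke_t[0] + ke_t[1], ke_r[0] + ke_r[1],
        dof_total > 0 ? 2*ke/(dof_total*KB) : 0.0,
        P[0], P[1], P[2], E.box[0], E.box[1], E.box[2], etot };
      for (int c = 0; c < ncol; ++c) elog(ilog, c) = row[c];
      ++ilog;
      last_good = E;
    }
    if (x_stride > 0 && step % x_stride == 0) {
      for (int i = 0; i < 3*E.n; ++i) tr_pos.push_back(E.x[i]);
      for (int i = 0; i < 3*E.n; ++i) tr_u.push_back(E.u[i]);
      tr_box.push_back(E.box[0]); tr_box.push_back(E.box[1]);
      tr_box.push_back(E.box[2]);
      tr_time.push_back(E.tnow);
    }
  }

  const Engine& F = (status == "ok") ? E : last_good;
  NumericMatrix elog_out =
    ilog > 0 ? NumericMatrix(elog(Range(0, ilog - 1), _))
             : NumericMatrix(0, ncol);
  List out = List::create(
    _["state"] = state_out(F),
    _["elog"] = elog_out,
    _["nlog"] = ilog,
    _["status"] = status,
    _["traj_pos"] = NumericVector(tr_pos.begin(), tr_pos.end()),
    _["traj_u"] = NumericVector(tr_u.begin(), tr_u.end()),
    _["traj_box"] = NumericVector(tr_box.begin(), tr_box.end()),
    _["traj_time"] = NumericVector(tr_time.begin(), tr_time.end()),
    _["prof_PT"] = NumericVector(prof_PT.begin(), prof_PT.end()),
    _["prof_PN"] = NumericVector(prof_PN.begin(), prof_PN.end()),
    _["prof_nacc"] = prof_nacc,
    _["prof_nslab"] = E.nslab);
  return out;
}
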