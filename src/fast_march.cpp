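// Forward upwind fast marching for the image-ratio depth PDE.
//
// Per pixel the discrete equation is
//   Z * (|F1| + |F2|) = |F1| * Z_up1 + |F2| * Z_up2 + step * s(Z)
// where (F1, F2) are the PDE coefficients resolved along either the axial
// directions (F_xi, F_eta; step = delta) or the two diagonals
// ((F_xi +- F_eta)/sqrt2; step = delta*sqrt2), and the upwind neighbours
// are selected by the signs of the coefficients.  Both orientations of a
// pair are admissible (swapping the pair negates F and s, which turns the
// one-sided differences around), so the march couples image pairs,
// orientations and the two stencils to difference toward the accepted
// region -- the eight-principal-direction coupling.  F and s depend on the
// unknown Z itself and are resolved by damped fixed-point iteration.  The
// march finalises each pixel once, expanding from the seed in a
// deterministic order: more accepted neighbours first, then smaller
// Chebyshev distance from the seed, then pixel index.

#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Lights {
  double xi[4], eta[4], zeta[4];
};

struct PixCtx {
  double x, y, f;
  double I[4];
};

// F_xi, F_eta, s for ordered pair (a, b) at depth z.
inline void pde_coeffs(const PixCtx& P, const Lights& L, int a, int b,
                       double z, double& Fxi, double& Feta, double& s,
                       double& csum) {
  const double f = P.f;
  double lax = L.xi[a] * f / z + P.x;
  double lay = L.eta[a] * f / z + P.y;
  double laz = L.zeta[a] * f / z - f;
  double q2a = lax * lax + lay * lay + laz * laz;
  double lbx = L.xi[b] * f / z + P.x;
  double lby = L.eta[b] * f / z + P.y;
  double lbz = L.zeta[b] * f / z - f;
  double q2b = lbx * lbx + lby * lby + lbz * lbz;
  double ca = P.I[a] * q2a * q2a;
  double cb = P.I[b] * q2b * q2b;
  Fxi  = ca * (L.xi[b] * f + L.zeta[b] * P.x) -
         cb * (L.xi[a] * f + L.zeta[a] * P.x);
  Feta = ca * (L.eta[b] * f + L.zeta[b] * P.y) -
         cb * (L.eta[a] * f + L.zeta[a] * P.y);
  double Fzeta = cb * (L.zeta[a] - z) - ca * (L.zeta[b] - z);
  s = z * Fzeta;
  csum = ca + cb;
}

struct NbrDepths {
  // 0 W (col-1), 1 E, 2 N (row-1), 3 S, 4 NW, 5 NE, 6 SW, 7 SE
  double z[8];
  bool ok[8];
};

struct Option {
  double w[2], zn[2];
  int nterm;
  double miss;    // |F| weight of significant terms without accepted upwind
  double step;
  int orient;     // +1 / -1
  int stencil;    // 0 axial, 1 diagonal
  bool usable;
};

inline void build_option(double F1, double F2, int up1p, int up1n,
                         int up2p, int up2n, double thr, double step,
                         int orient, int stencil, const NbrDepths& nb,
                         Option& o) {
  o.nterm = 0;
  o.miss = 0;
  o.step = step;
  o.orient = orient;
  o.stencil = stencil;
  if (std::fabs(F1) > thr) {
    int up = (F1 > 0) ? up1p : up1n;
    if (nb.ok[up]) { o.w[o.nterm] = std::fabs(F1); o.zn[o.nterm] = nb.z[up]; ++o.nterm; }
    else o.miss += std::fabs(F1);
  }
  if (std::fabs(F2) > thr) {
    int up = (F2 > 0) ? up2p : up2n;
    if (nb.ok[up]) { o.w[o.nterm] = std::fabs(F2); o.zn[o.nterm] = nb.z[up]; ++o.nterm; }
    else o.miss += std::fabs(F2);
  }
  o.usable = o.nterm > 0;
}

// One damped fixed-point solve for a pixel with a given (unordered) pair.
// strict: only accept full stencils (no significant term dropped).
// Returns true on convergence to an interior depth.
bool solve_pixel(const PixCtx& P, const Lights& L, int a, int b,
                 const NbrDepths& nb, double z_init, double delta,
                 double zmin, double zmax, double tol, int maxit,
                 bool strict, double& z_out, int& orient_out,
                 int& stencil_out) {
  const double SQRT2 = std::sqrt(2.0);
  double z = z_init;
  double prev_step = R_PosInf;
  double damp = 1.0;
  orient_out = 0;
  stencil_out = -1;
  for (int it = 0; it < maxit; ++it) {
    double Fxi, Feta, s, csum;
    pde_coeffs(P, L, a, b, z, Fxi, Feta, s, csum);
    double thr = 1e-13 * csum * P.f;
    if (std::fabs(Fxi) + std::fabs(Feta) <= 1e-10 * csum * P.f)
      return false;  // characteristic direction undefined
    double F1 = (Fxi + Feta) / SQRT2;   // diag (1,1): upwind NW when > 0
    double F2 = (Fxi - Feta) / SQRT2;   // diag (1,-1): upwind SW when > 0
    Option opt[4];
    build_option( Fxi,  Feta, 0, 1, 2, 3, thr, delta,        +1, 0, nb, opt[0]);
    build_option(-Fxi, -Feta, 0, 1, 2, 3, thr, delta,        -1, 0, nb, opt[1]);
    build_option( F1,  F2, 4, 7, 6, 5, thr, delta * SQRT2, +1, 1, nb, opt[2]);
    build_option(-F1, -F2, 4, 7, 6, 5, thr, delta * SQRT2, -1, 1, nb, opt[3]);
    int best = -1;
    double best_frac = R_PosInf;
    for (int k = 0; k < 4; ++k) {
      if (!opt[k].usable) continue;
      double wa = opt[k].w[0] + (opt[k].nterm > 1 ? opt[k].w[1] : 0.0);
      double frac = opt[k].miss / (opt[k].miss + wa);
      if (frac < best_frac - 1e-12) { best = k; best_frac = frac; }
    }
    if (best < 0) return false;
    if (strict && best_frac > 0) return false;
    const Option& o = opt[best];
    double W = 0, acc = 0;
    for (int k = 0; k < o.nterm; ++k) { W += o.w[k]; acc += o.w[k] * o.zn[k]; }
    double znew = (acc + o.step * o.orient * s) / W;
    if (znew < zmin) znew = zmin;
    if (znew > zmax) znew = zmax;
    double dz = znew - z;
    if (std::fabs(dz) < tol) {
      z_out = znew;
      orient_out = o.orient;
      stencil_out = o.stencil;
      if (znew <= zmin + tol || znew >= zmax - tol) return false;
      return true;
    }
    if (std::fabs(dz) > prev_step) damp = std::max(0.1, damp * 0.5);
    prev_step = std::fabs(dz);
    z += damp * dz;
  }
  return false;
}

struct QEntry {
  int nacc;
  int cheb;
  int idx;
};
struct QCmp {
  bool operator()(const QEntry& l, const QEntry& r) const {
    if (l.nacc != r.nacc) return l.nacc < r.nacc;   // more accepted first
    if (l.cheb != r.cheb) return l.cheb > r.cheb;   // closer to seed first
    return l.idx > r.idx;                           // lower index first
  }
};

}  // namespace

// [[Rcpp::export(.fm_march)]]
List fm_march(List illum, List usable, NumericMatrix lights,
              double f, double cx, double cy,
              int seed_col, int seed_row, double seed_depth,
              double delta, double zmin, double zmax,
              double fp_tol, int fp_maxit) {
  const int nimg = illum.size();
  if (nimg != 4) stop("expected a four-image stack");
  NumericMatrix I0(as<NumericMatrix>(illum[0]));
  const int h = I0.nrow(), w = I0.ncol(), N = h * w;
  std::vector<const double*> Ip(nimg);
  std::vector<const int*> Up(nimg);
  std::vector<LogicalMatrix> Um(nimg);
  std::vector<NumericMatrix> Im(nimg);
  for (int k = 0; k < nimg; ++k) {
    Im[k] = as<NumericMatrix>(illum[k]);
    Um[k] = as<LogicalMatrix>(usable[k]);
    if (Im[k].nrow() != h || Im[k].ncol() != w) stop("image size mismatch");
    Ip[k] = Im[k].begin();
    Up[k] = Um[k].begin();
  }
  Lights L;
  for (int k = 0; k < nimg; ++k) {
    L.xi[k] = lights(k, 0); L.eta[k] = lights(k, 1); L.zeta[k] = lights(k, 2);
  }

  std::vector<char> accepted(N, 0);
  std::vector<int> nacc(N, 0), status(N, 3), pairA(N, 0), pairB(N, 0);
  std::vector<int> orientv(N, 0), stencilv(N, -1);
  std::vector<double> Z(N, NA_REAL);
  std::vector<char> usablepx(N, 0);
  for (int p = 0; p < N; ++p) {
    int cnt = 0;
    for (int k = 0; k < nimg; ++k) if (Up[k][p]) ++cnt;
    usablepx[p] = (cnt >= 2);
  }

  const int seed_p = (seed_col - 1) * h + (seed_row - 1);
  if (seed_p < 0 || seed_p >= N) stop("seed pixel outside the image");
  const int drs[8] = {0, 0, -1, 1, -1, -1, 1, 1};
  const int dcs[8] = {-1, 1, 0, 0, -1, 1, -1, 1};

  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> q;
  auto cheb_of = [&](int p) {
    int r = p % h, c = p / h;
    return std::max(std::abs(r - (seed_row - 1)),
                    std::abs(c - (seed_col - 1)));
  };
  auto accept = [&](int p, double z, int st, int a, int b, int ori, int ste) {
    accepted[p] = 1;
    Z[p] = z;
    status[p] = st;
    pairA[p] = a + 1;
    pairB[p] = b + 1;
    orientv[p] = ori;
    stencilv[p] = ste;
    int r = p % h, c = p / h;
    for (int d = 0; d < 8; ++d) {
      int nr = r + drs[d], ncol = c + dcs[d];
      if (nr < 0 || nr >= h || ncol < 0 || ncol >= w) continue;
      int np = ncol * h + nr;
      if (accepted[np] || !usablepx[np]) continue;
      nacc[np] += 1;
      q.push(QEntry{nacc[np], cheb_of(np), np});
    }
  };

  // try all usable pairs at p (strict pass, then lenient); brightest first
  auto try_pixel = [&](int p, bool allow_partial) {
    int r = p % h, c = p / h;
    PixCtx P;
    P.f = f;
    P.x = (c + 1) - cx;
    P.y = (r + 1) - cy;
    for (int k = 0; k < nimg; ++k) P.I[k] = Ip[k][p];
    NbrDepths nb;
    double zsum = 0;
    int nz = 0;
    for (int d = 0; d < 8; ++d) {
      int nr = r + drs[d], ncol = c + dcs[d];
      bool in = (nr >= 0 && nr < h && ncol >= 0 && ncol < w);
      int np = in ? ncol * h + nr : -1;
      nb.ok[d] = in && accepted[np];
      nb.z[d] = nb.ok[d] ? Z[np] : NA_REAL;
      if (nb.ok[d]) { zsum += Z[np]; ++nz; }
    }
    if (nz == 0) return false;
    double z_init = zsum / nz;
    std::vector<std::pair<double, std::pair<int, int> > > cand;
    for (int a = 0; a < nimg; ++a) {
      if (!Up[a][p]) continue;
      for (int b = a + 1; b < nimg; ++b) {
        if (!Up[b][p]) continue;
        cand.push_back(std::make_pair(-(P.I[a] + P.I[b]),
                                      std::make_pair(a, b)));
      }
    }
    std::sort(cand.begin(), cand.end());
    for (int strict = 1; strict >= (allow_partial ? 0 : 1); --strict) {
      for (size_t k = 0; k < cand.size(); ++k) {
        int a = cand[k].second.first, b = cand[k].second.second;
        double zout;
        int ori, ste;
        if (solve_pixel(P, L, a, b, nb, z_init, delta, zmin, zmax,
                        fp_tol, fp_maxit, strict != 0, zout, ori, ste)) {
          accept(p, zout, 1, a, b, ori, ste);
          return true;
        }
      }
    }
    return false;
  };

  accept(seed_p, seed_depth, 0, -1, -1, 0, -1);
  while (!q.empty()) {
    QEntry e = q.top();
    q.pop();
    if (accepted[e.idx] || e.nacc != nacc[e.idx]) continue;  // stale
    try_pixel(e.idx, false);  // failures wait for a fresher push
  }
  // lenient sweeps: remaining pixels may use partial stencils; anything
  // still failing is assigned the mean of its accepted neighbours
  bool progress = true;
  int round = 0;
  while (progress) {
    progress = false;
    ++round;
    std::vector<std::pair<int, int> > open;
    for (int p = 0; p < N; ++p)
      if (!accepted[p] && usablepx[p] && nacc[p] > 0)
        open.push_back(std::make_pair(cheb_of(p), p));
    std::sort(open.begin(), open.end());
    for (size_t k = 0; k < open.size(); ++k) {
      int p = open[k].second;
      if (accepted[p]) continue;
      if (try_pixel(p, true)) { progress = true; continue; }
      if (round < 2) continue;  // give the solver another lenient round
      int r = p % h, c = p / h;
      double zsum = 0;
      int nz = 0;
      for (int d = 0; d < 8; ++d) {
        int nr = r + drs[d], ncol = c + dcs[d];
        if (nr < 0 || nr >= h || ncol < 0 || ncol >= w) continue;
        int np = ncol * h + nr;
        if (accepted[np]) { zsum += Z[np]; ++nz; }
      }
      if (nz > 0) {
        accept(p, zsum / nz, 2, -1, -1, 0, -1);
        progress = true;
      }
    }
  }

  NumericMatrix Zout(h, w);
  IntegerMatrix st(h, w), pa(h, w), pb(h, w), ov(h, w), sv(h, w);
  LogicalMatrix mask(h, w);
  for (int p = 0; p < N; ++p) {
    Zout[p] = Z[p];
    st[p] = status[p];
    pa[p] = pairA[p];
    pb[p] = pairB[p];
    ov[p] = orientv[p];
    sv[p] = stencilv[p];
    mask[p] = accepted[p] != 0;
  }
  return List::create(_["z"] = Zout, _["mask"] = mask, _["status"] = st,
                      _["pair_a"] = pa, _["pair_b"] = pb,
                      _["orient"] = ov, _["stencil"] = sv);
}
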