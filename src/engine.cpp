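// Core lattice engine: adhesion-gated cell movement, age-based proliferation
// with quiescence, hypoxic death, oxygen reaction-diffusion, and grid
// morphometrics. All stochasticity goes through R's RNG (unif_rand) so a
// set.seed() on the R side fully determines every run.
//
// Lattice layout matches R matrices (column-major): idx = i + nr * j, 0-based.
// occ holds 0 for empty or the 1-based cell id; ids are allocated
// monotonically and never reused, so id k is row k of the cell registry.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Cells {
  std::vector<int> ci, cj, ph;
  std::vector<double> age;
  std::vector<char> quiescent, alive;
  int size() const { return static_cast<int>(ci.size()); }
};

struct Events {
  std::vector<double> time;
  std::vector<int> type;  // 1 division, 2 death, 3 switch, 4 move
  std::vector<int> cell;
  std::vector<int> detail;
  void add(double t, int ty, int c, int d) {
    time.push_back(t); type.push_back(ty); cell.push_back(c); detail.push_back(d);
  }
};

inline bool inb(int i, int j, int n) { return i >= 0 && i < n && j >= 0 && j < n; }

// Occupied Moore neighbours of (i,j), excluding the site (ei,ej) (pass -1,-1
// for no exclusion). Out-of-bounds sites count as empty (truncated stencil).
int count_nb(const std::vector<int>& occ, int n, int i, int j, int ei, int ej) {
  int c = 0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      int ii = i + di, jj = j + dj;
      if (!inb(ii, jj, n)) continue;
      if (ii == ei && jj == ej) continue;
      if (occ[ii + n * jj]) ++c;
    }
  return c;
}

int gather_empty(const std::vector<int>& occ, int n, int i, int j, int* ei, int* ej) {
  int k = 0;
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj) {
      if (di == 0 && dj == 0) continue;
      int ii = i + di, jj = j + dj;
      if (!inb(ii, jj, n)) continue;
      if (!occ[ii + n * jj]) { ei[k] = ii; ej[k] = jj; ++k; }
    }
  return k;
}

// Empty Moore neighbours of the cell's site whose occupied-neighbour count
// (excluding the mover itself) equals the adhesion preference.
int gather_admissible(const std::vector<int>& occ, int n, int i, int j, int pref,
                      int* ai, int* aj) {
  int ei[8], ej[8];
  int ne = gather_empty(occ, n, i, j, ei, ej);
  int k = 0;
  for (int s = 0; s < ne; ++s)
    if (count_nb(occ, n, ei[s], ej[s], i, j) == pref) { ai[k] = ei[s]; aj[k] = ej[s]; ++k; }
  return k;
}

inline int rint_below(int k) {  // uniform integer in [0, k)
  int r = static_cast<int>(unif_rand() * k);
  return r >= k ? k - 1 : r;
}

// One cell's movement turn: n_substeps Bernoulli(p_move) attempts. Under the
// default "proposal" rule an attempt proposes one of the 8 Moore directions
// uniformly (per-direction rate p_move/8, the diffusion-derived flux) and
// relocates only if the proposed site is empty and matches the adhesion
// preference; under the "renormalised" rule an attempt relocates uniformly
// among all admissible destinations whenever there is one. Both give a free
// walker the same law. Other cells are frozen during the turn, so once the
// cell has no empty neighbour (and cannot have moved) the rest of the turn
// is a no-op and is skipped.
const int MOORE_DI[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int MOORE_DJ[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

void move_turn(std::vector<int>& occ, int n, Cells& C, int id,
               double p_move, int nsub, bool renormalised,
               bool log_moves, Events* ev, double tnow) {
  int x = id - 1;
  if (!C.alive[x] || p_move <= 0) return;
  for (int s = 0; s < nsub; ++s) {
    int i = C.ci[x], j = C.cj[x];
    int ei[8], ej[8];
    if (gather_empty(occ, n, i, j, ei, ej) == 0) break;
    if (unif_rand() >= p_move) continue;
    int ti, tj;
    if (renormalised) {
      int ai[8], aj[8];
      int k = gather_admissible(occ, n, i, j, C.ph[x], ai, aj);
      if (k == 0) continue;
      int pick = rint_below(k);
      ti = ai[pick]; tj = aj[pick];
    } else {
      int dir = rint_below(8);
      ti = i + MOORE_DI[dir]; tj = j + MOORE_DJ[dir];
      if (!inb(ti, tj, n) || occ[ti + n * tj]) continue;
      if (count_nb(occ, n, ti, tj, i, j) != C.ph[x]) continue;
    }
    occ[i + n * j] = 0;
    occ[ti + n * tj] = id;
    C.ci[x] = ti;
    C.cj[x] = tj;
    if (log_moves && ev) ev->add(tnow, 4, id, ti + n * tj);
  }
}

struct DivOut {
  bool divided = false, switched = false, went_quiescent = false, aged = false;
  int daughter = 0, new_ph = -1;
};

// One cell's lifecycle turn. Below division age: the age clock advances by
// t_r. At or past it (or quiescent): search the Moore neighbourhood of radius
// r for an empty site; none -> quiescence (age frozen); otherwise place a
// daughter uniformly on one, reset both ages, and apply the mitotic
// phenotype switch (the sampled phenotype is given to BOTH daughters).
DivOut division_turn(std::vector<int>& occ, int n, Cells& C, int id,
                     const double* Tp8, int r, double t_r, double p_mut,
                     const std::vector<int>& target) {
  DivOut out;
  int x = id - 1;
  if (!C.alive[x]) return out;
  double Tp = Tp8[C.ph[x]];
  if (C.age[x] < Tp && !C.quiescent[x]) {
    C.age[x] += t_r;
    out.aged = true;
    return out;
  }
  int i = C.ci[x], j = C.cj[x];
  std::vector<int> ei, ej;
  ei.reserve((2 * r + 1) * (2 * r + 1));
  ej.reserve((2 * r + 1) * (2 * r + 1));
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj) {
      if (di == 0 && dj == 0) continue;
      int ii = i + di, jj = j + dj;
      if (!inb(ii, jj, n)) continue;
      if (!occ[ii + n * jj]) { ei.push_back(ii); ej.push_back(jj); }
    }
  if (ei.empty()) {
    C.quiescent[x] = true;
    out.went_quiescent = true;
    return out;
  }
  int pick = rint_below(static_cast<int>(ei.size()));
  int nph = C.ph[x];
  if (p_mut > 0 && unif_rand() < p_mut) {
    nph = target[rint_below(static_cast<int>(target.size()))];
    out.switched = true;
  }
  out.new_ph = nph;
  C.ph[x] = nph;
  C.age[x] = 0.0;
  C.quiescent[x] = false;
  C.ci.push_back(ei[pick]); C.cj.push_back(ej[pick]); C.ph.push_back(nph);
  C.age.push_back(0.0); C.quiescent.push_back(false); C.alive.push_back(true);
  int did = C.size();
  occ[ei[pick] + n * ej[pick]] = did;
  out.divided = true;
  out.daughter = did;
  return out;
}

// Explicit FTCS update of D_o lap(o) - (alpha + gamma c) o with Dirichlet
// boundaries clamped to o_max; optional mirrored (zero-flux) rows for
// quasi-1D strips. Substep honours the diffusive stability bound
// 0.9 h^2/(4 D_o) and a positivity bound on the reaction term.
void ox_transient(std::vector<double>& f, const std::vector<int>& occ,
                  int nr, int nc, double D, double alpha, double gamma,
                  double omax, double h_cm, double dur_s, bool neum_rows) {
  if (dur_s <= 0) return;
  double dt = std::min(dur_s, 0.9 * h_cm * h_cm / (4.0 * D));
  double rmax = alpha + gamma;
  if (rmax > 0) dt = std::min(dt, 0.9 / rmax);
  int nsub = static_cast<int>(std::ceil(dur_s / dt - 1e-12));
  if (nsub < 1) nsub = 1;
  dt = dur_s / nsub;
  double lam = D * dt / (h_cm * h_cm);
  std::vector<double> g(f.size());
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        bool brow = (i == 0 || i == nr - 1), bcol = (j == 0 || j == nc - 1);
        int idx = i + nr * j;
        if (bcol || (brow && !neum_rows)) { g[idx] = omax; continue; }
        double o = f[idx];
        double up = (i == 0) ? f[idx + 1] : f[idx - 1];
        double dn = (i == nr - 1) ? f[idx - 1] : f[idx + 1];
        double lf = f[idx - nr], rt = f[idx + nr];
        double react = (alpha + (occ[idx] > 0 ? gamma : 0.0)) * o;
        g[idx] = o + lam * (up + dn + lf + rt - 4.0 * o) - dt * react;
      }
    f.swap(g);
  }
}

// SOR relaxation to the steady state D_o lap(o) = (alpha + gamma c) o with
// Dirichlet o_max boundaries. Warm-started from the supplied field; returns
// the iteration count.
int ox_steady(std::vector<double>& f, const std::vector<int>& occ,
              int nr, int nc, double D, double alpha, double gamma,
              double omax, double h_cm, double tol, int maxit) {
  double h2D = h_cm * h_cm / D;
  double omega = 2.0 / (1.0 + std::sin(M_PI / std::max(nr, nc)));
  for (int j = 0; j < nc; ++j) { f[0 + nr * j] = omax; f[nr - 1 + nr * j] = omax; }
  for (int i = 0; i < nr; ++i) { f[i] = omax; f[i + nr * (nc - 1)] = omax; }
  int it = 0;
  for (; it < maxit; ++it) {
    double md = 0.0;
    for (int j = 1; j < nc - 1; ++j)
      for (int i = 1; i < nr - 1; ++i) {
        int idx = i + nr * j;
        double react = (alpha + (occ[idx] > 0 ? gamma : 0.0)) * h2D;
        double nb = f[idx - 1] + f[idx + 1] + f[idx - nr] + f[idx + nr];
        double gs = nb / (4.0 + react);
        double d = gs - f[idx];
        f[idx] += omega * d;
        double ad = std::fabs(d);
        if (ad > md) md = ad;
      }
    if (md < tol) { ++it; break; }
  }
  return it;
}

// ---- geometric multigrid for the steady state (large grids) ----
//
// Solves A u = b on an ni x nj cell grid with A u = -(D/h^2) lap(u) + sig u,
// homogeneous Dirichlet outside (ghost values enter through b on the fine
// level). Cell-centred coarsening (4 children -> 1 parent), full-weighting
// restriction, piecewise-constant prolongation, red-black Gauss-Seidel
// smoothing, SOR at the coarsest level.

struct MgLevel {
  int ni, nj;
  double h;
  std::vector<double> sig, u, b, r;
};

inline double mg_aii(const MgLevel& L, int idx, double Dh2) {
  return 4.0 * Dh2 + L.sig[idx];
}

void mg_smooth(MgLevel& L, double D, int sweeps) {
  double Dh2 = D / (L.h * L.h);
  int ni = L.ni, nj = L.nj;
  for (int s = 0; s < sweeps; ++s)
    for (int colour = 0; colour < 2; ++colour)
      for (int j = 0; j < nj; ++j)
        for (int i = (j + colour) % 2; i < ni; i += 2) {
          int idx = i + ni * j;
          double nb = 0.0;
          if (i > 0) nb += L.u[idx - 1];
          if (i < ni - 1) nb += L.u[idx + 1];
          if (j > 0) nb += L.u[idx - ni];
          if (j < nj - 1) nb += L.u[idx + ni];
          L.u[idx] = (L.b[idx] + Dh2 * nb) / mg_aii(L, idx, Dh2);
        }
}

double mg_residual(MgLevel& L, double D) {
  double Dh2 = D / (L.h * L.h);
  int ni = L.ni, nj = L.nj;
  double mr = 0.0;
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i) {
      int idx = i + ni * j;
      double nb = 0.0;
      if (i > 0) nb += L.u[idx - 1];
      if (i < ni - 1) nb += L.u[idx + 1];
      if (j > 0) nb += L.u[idx - ni];
      if (j < nj - 1) nb += L.u[idx + ni];
      L.r[idx] = L.b[idx] + Dh2 * nb - mg_aii(L, idx, Dh2) * L.u[idx];
      double ar = std::fabs(L.r[idx]);
      if (ar > mr) mr = ar;
    }
  return mr;
}

void mg_vcycle(std::vector<MgLevel>& lv, size_t l, double D) {
  MgLevel& L = lv[l];
  if (l + 1 == lv.size()) {
    mg_smooth(L, D, 200);  // coarsest grid is tiny; smooth to convergence
    return;
  }
  mg_smooth(L, D, 2);
  mg_residual(L, D);
  MgLevel& C = lv[l + 1];
  std::fill(C.u.begin(), C.u.end(), 0.0);
  for (int J = 0; J < C.nj; ++J)
    for (int I = 0; I < C.ni; ++I) {
      int i = 2 * I, j = 2 * J;
      C.b[I + C.ni * J] = 0.25 * (L.r[i + L.ni * j] + L.r[i + 1 + L.ni * j] +
                                  L.r[i + L.ni * (j + 1)] +
                                  L.r[i + 1 + L.ni * (j + 1)]);
    }
  mg_vcycle(lv, l + 1, D);
  for (int J = 0; J < C.nj; ++J)
    for (int I = 0; I < C.ni; ++I) {
      double e = C.u[I + C.ni * J];
      int i = 2 * I, j = 2 * J;
      L.u[i + L.ni * j] += e;
      L.u[i + 1 + L.ni * j] += e;
      L.u[i + L.ni * (j + 1)] += e;
      L.u[i + 1 + L.ni * (j + 1)] += e;
    }
  mg_smooth(L, D, 2);
}

// Multigrid steady solve on the full nr x nc field (boundary ring fixed at
// omax). Returns V-cycle count. Falls back to SOR for small grids.
int ox_steady_mg(std::vector<double>& f, const std::vector<int>& occ,
                 int nr, int nc, double D, double alpha, double gamma,
                 double omax, double h_cm, double tol, int maxit) {
  int ni = nr - 2, nj = nc - 2;
  if (ni < 16 || nj < 16 || ni % 2 || nj % 2)
    return ox_steady(f, occ, nr, nc, D, alpha, gamma, omax, h_cm, tol, maxit);
  for (int j = 0; j < nc; ++j) { f[0 + nr * j] = omax; f[nr - 1 + nr * j] = omax; }
  for (int i = 0; i < nr; ++i) { f[i] = omax; f[i + nr * (nc - 1)] = omax; }

  std::vector<MgLevel> lv;
  {
    MgLevel L;
    L.ni = ni; L.nj = nj; L.h = h_cm;
    L.sig.resize(ni * nj); L.u.resize(ni * nj);
    L.b.assign(ni * nj, 0.0); L.r.resize(ni * nj);
    double Dh2 = D / (h_cm * h_cm);
    for (int j = 0; j < nj; ++j)
      for (int i = 0; i < ni; ++i) {
        int fidx = (i + 1) + nr * (j + 1);
        L.sig[i + ni * j] = alpha + (occ[fidx] > 0 ? gamma : 0.0);
        L.u[i + ni * j] = f[fidx];
        double bb = 0.0;
        if (i == 0 || i == ni - 1) bb += Dh2 * omax;
        if (j == 0 || j == nj - 1) bb += Dh2 * omax;
        L.b[i + ni * j] = bb;
      }
    lv.push_back(std::move(L));
  }
  while (lv.back().ni % 2 == 0 && lv.back().nj % 2 == 0 &&
         lv.back().ni >= 32 && lv.back().nj >= 32) {
    const MgLevel& F = lv.back();
    MgLevel C;
    C.ni = F.ni / 2; C.nj = F.nj / 2; C.h = 2.0 * F.h;
    C.sig.resize(C.ni * C.nj); C.u.resize(C.ni * C.nj);
    C.b.assign(C.ni * C.nj, 0.0); C.r.resize(C.ni * C.nj);
    for (int J = 0; J < C.nj; ++J)
      for (int I = 0; I < C.ni; ++I) {
        int i = 2 * I, j = 2 * J;
        C.sig[I + C.ni * J] =
            0.25 * (F.sig[i + F.ni * j] + F.sig[i + 1 + F.ni * j] +
                    F.sig[i + F.ni * (j + 1)] + F.sig[i + 1 + F.ni * (j + 1)]);
      }
    lv.push_back(std::move(C));
  }

  // the residual tolerance matching a max-update tolerance `tol` on the
  // solution scale: |r| ~ |A| * |du|, |A| ~ 4 D / h^2
  double rtol = tol * 4.0 * D / (h_cm * h_cm);
  int cyc = 0;
  for (; cyc < maxit; ++cyc) {
    if (mg_residual(lv[0], D) < rtol) break;
    mg_vcycle(lv, 0, D);
  }
  for (int j = 0; j < nj; ++j)
    for (int i = 0; i < ni; ++i)
      f[(i + 1) + nr * (j + 1)] = lv[0].u[i + ni * j];
  return cyc;
}

// 8-connected component labelling of occupied sites (0 = empty).
void label_components(const std::vector<int>& occ, int n,
                      std::vector<int>& lab, std::vector<int>& sizes) {
  lab.assign(occ.size(), 0);
  sizes.clear();
  std::vector<int> stack;
  int next = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) {
      int idx = i + n * j;
      if (!occ[idx] || lab[idx]) continue;
      ++next;
      int sz = 0;
      stack.push_back(idx);
      lab[idx] = next;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        ++sz;
        int ci = cur % n, cj = cur / n;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ii = ci + di, jj = cj + dj;
            if (!inb(ii, jj, n)) continue;
            int nidx = ii + n * jj;
            if (occ[nidx] && !lab[nidx]) { lab[nidx] = next; stack.push_back(nidx); }
          }
      }
      sizes.push_back(sz);
    }
}

// Mean over live cells of the nearest-other-cell Euclidean distance in site
// units (1.0 = perfectly packed). Expanding Chebyshev ring search; a ring at
// Chebyshev radius m has minimum Euclidean distance m, so the scan can stop
// once m exceeds the best distance found.
double sparseness_grid(const std::vector<int>& occ, int n,
                       const std::vector<int>& xi, const std::vector<int>& xj) {
  int N = static_cast<int>(xi.size());
  if (N < 2) return NA_REAL;
  double total = 0.0;
  for (int c = 0; c < N; ++c) {
    int i = xi[c], j = xj[c];
    double best = R_PosInf;
    for (int m = 1; m < n; ++m) {
      if (static_cast<double>(m) > best) break;
      for (int di = -m; di <= m; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= n) continue;
        bool edge_row = (di == -m || di == m);
        int step = edge_row ? 1 : 2 * m;
        for (int dj = -m; dj <= m; dj += step) {
          int jj = j + dj;
          if (jj < 0 || jj >= n) continue;
          if (occ[ii + n * jj]) {
            double d = std::sqrt(static_cast<double>(di) * di +
                                 static_cast<double>(dj) * dj);
            if (d < best) best = d;
          }
        }
      }
    }
    total += best;
  }
  return total / N;
}

struct MetricsRow {
  double time, n_cells, inv_r, core_r, lcc_frac, compact, sparse;
  double freq[8];
};

MetricsRow compute_metrics(const std::vector<int>& occ, int n, const Cells& C,
                           double h_um, double c0, double tnow) {
  MetricsRow m;
  m.time = tnow;
  std::vector<int> xi, xj, xph;
  for (int id = 0; id < C.size(); ++id)
    if (C.alive[id]) { xi.push_back(C.ci[id]); xj.push_back(C.cj[id]); xph.push_back(C.ph[id]); }
  int N = static_cast<int>(xi.size());
  m.n_cells = N;
  for (int p = 0; p < 8; ++p) m.freq[p] = NA_REAL;
  if (N == 0) {
    m.inv_r = m.core_r = m.lcc_frac = m.compact = m.sparse = NA_REAL;
    return m;
  }
  int cnt[8] = {0};
  double maxd = 0.0, bestc = R_PosInf;
  int centre_cell = 0;
  double csum = 0.0;
  for (int c = 0; c < N; ++c) {
    double dx = xi[c] - c0, dy = xj[c] - c0;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d > maxd) maxd = d;
    if (d < bestc) { bestc = d; centre_cell = c; }
    ++cnt[xph[c]];
    csum += count_nb(occ, n, xi[c], xj[c], -1, -1) / 8.0;
  }
  m.inv_r = maxd * h_um;
  m.compact = csum / N;
  for (int p = 0; p < 8; ++p) m.freq[p] = static_cast<double>(cnt[p]) / N;
  std::vector<int> lab, sizes;
  label_components(occ, n, lab, sizes);
  int core_lab = lab[xi[centre_cell] + n * xj[centre_cell]];
  double core_max = 0.0;
  for (int c = 0; c < N; ++c) {
    if (lab[xi[c] + n * xj[c]] != core_lab) continue;
    double dx = xi[c] - c0, dy = xj[c] - c0;
    double d = std::sqrt(dx * dx + dy * dy);
    if (d > core_max) core_max = d;
  }
  m.core_r = core_max * h_um;
  int lcc = *std::max_element(sizes.begin(), sizes.end());
  m.lcc_frac = static_cast<double>(lcc) / N;
  m.sparse = sparseness_grid(occ, n, xi, xj);
  return m;
}

// ----- packing helpers between R state lists and internal vectors -----

void unpack_cells(const List& cells, Cells& C) {
  IntegerVector i = cells["i"], j = cells["j"], ph = cells["phenotype"];
  NumericVector age = cells["age"];
  LogicalVector q = cells["quiescent"], al = cells["alive"];
  int N = i.size();
  C.ci.assign(i.begin(), i.end());
  C.cj.assign(j.begin(), j.end());
  C.ph.assign(ph.begin(), ph.end());
  C.age.assign(age.begin(), age.end());
  C.quiescent.resize(N);
  C.alive.resize(N);
  for (int k = 0; k < N; ++k) { C.quiescent[k] = q[k]; C.alive[k] = al[k]; }
}

List pack_cells(const Cells& C) {
  int N = C.size();
  IntegerVector i(N), j(N), ph(N);
  NumericVector age(N);
  LogicalVector q(N), al(N);
  for (int k = 0; k < N; ++k) {
    i[k] = C.ci[k]; j[k] = C.cj[k]; ph[k] = C.ph[k];
    age[k] = C.age[k]; q[k] = C.quiescent[k] == 1; al[k] = C.alive[k] == 1;
  }
  return List::create(_["i"] = i, _["j"] = j, _["phenotype"] = ph,
                      _["age"] = age, _["quiescent"] = q, _["alive"] = al);
}

void unpack_grid_int(const IntegerMatrix& m, std::vector<int>& v) {
  v.assign(m.begin(), m.end());
}

void shuffle_ids(std::vector<int>& ids) {
  for (int k = static_cast<int>(ids.size()) - 1; k > 0; --k) {
    int m = rint_below(k + 1);
    std::swap(ids[k], ids[m]);
  }
}

DataFrame events_df(const Events& ev) {
  return DataFrame::create(_["time_h"] = NumericVector(ev.time.begin(), ev.time.end()),
                           _["event"] = IntegerVector(ev.type.begin(), ev.type.end()),
                           _["cell"] = IntegerVector(ev.cell.begin(), ev.cell.end()),
                           _["detail"] = IntegerVector(ev.detail.begin(), ev.detail.end()));
}

}  // namespace

// [[Rcpp::export]]
int cpp_count_occupied_neighbours(IntegerMatrix occ, int i, int j,
                                  int exclude_i, int exclude_j) {
  int n = occ.nrow();
  std::vector<int> o;
  unpack_grid_int(occ, o);
  return count_nb(o, n, i, j, exclude_i, exclude_j);
}

// [[Rcpp::export]]
IntegerMatrix cpp_admissible_destinations(IntegerMatrix occ, int i, int j, int pref) {
  int n = occ.nrow();
  std::vector<int> o;
  unpack_grid_int(occ, o);
  int ai[8], aj[8];
  int k = gather_admissible(o, n, i, j, pref, ai, aj);
  IntegerMatrix out(k, 2);
  for (int s = 0; s < k; ++s) { out(s, 0) = ai[s]; out(s, 1) = aj[s]; }
  return out;
}

// [[Rcpp::export]]
List cpp_move_turn(IntegerMatrix occ, List cells, int id, double p_move,
                   int n_substeps, bool renormalised, bool log_moves,
                   double time_h) {
  int n = occ.nrow();
  std::vector<int> o;
  unpack_grid_int(occ, o);
  Cells C;
  unpack_cells(cells, C);
  Events ev;
  move_turn(o, n, C, id, p_move, n_substeps, renormalised, log_moves, &ev, time_h);
  IntegerMatrix occ2(n, n);
  std::copy(o.begin(), o.end(), occ2.begin());
  return List::create(_["occ"] = occ2, _["cells"] = pack_cells(C),
                      _["events"] = events_df(ev));
}

// [[Rcpp::export]]
List cpp_division_turn(IntegerMatrix occ, List cells, int id, NumericVector Tp8,
                       int r, double t_r, double p_mut, IntegerVector target_set) {
  int n = occ.nrow();
  std::vector<int> o;
  unpack_grid_int(occ, o);
  Cells C;
  unpack_cells(cells, C);
  std::vector<int> target(target_set.begin(), target_set.end());
  DivOut res = division_turn(o, n, C, id, REAL(Tp8), r, t_r, p_mut, target);
  IntegerMatrix occ2(n, n);
  std::copy(o.begin(), o.end(), occ2.begin());
  return List::create(_["occ"] = occ2, _["cells"] = pack_cells(C),
                      _["divided"] = res.divided, _["daughter"] = res.daughter,
                      _["switched"] = res.switched, _["new_ph"] = res.new_ph,
                      _["went_quiescent"] = res.went_quiescent);
}

// [[Rcpp::export]]
List cpp_death_pass(IntegerMatrix occ, List cells, NumericMatrix field,
                    double o_deadly, double time_h) {
  int n = occ.nrow();
  std::vector<int> o;
  unpack_grid_int(occ, o);
  Cells C;
  unpack_cells(cells, C);
  Events ev;
  for (int id = 1; id <= C.size(); ++id) {
    int x = id - 1;
    if (!C.alive[x]) continue;
    if (field(C.ci[x], C.cj[x]) < o_deadly) {
      o[C.ci[x] + n * C.cj[x]] = 0;
      C.alive[x] = false;
      ev.add(time_h, 2, id, 0);
    }
  }
  IntegerMatrix occ2(n, n);
  std::copy(o.begin(), o.end(), occ2.begin());
  return List::create(_["occ"] = occ2, _["cells"] = pack_cells(C),
                      _["events"] = events_df(ev));
}

// [[Rcpp::export]]
NumericMatrix cpp_oxygen_advance(NumericMatrix field, IntegerMatrix occ,
                                 double D_o, double alpha_o, double gamma_o,
                                 double o_max, double h_cm, double duration_s,
                                 bool neumann_rows) {
  int nr = field.nrow(), nc = field.ncol();
  if (occ.nrow() != nr || occ.ncol() != nc)
    stop("occupancy dimensions (%d x %d) do not match field (%d x %d)",
         occ.nrow(), occ.ncol(), nr, nc);
  std::vector<double> f(field.begin(), field.end());
  std::vector<int> o;
  unpack_grid_int(occ, o);
  ox_transient(f, o, nr, nc, D_o, alpha_o, gamma_o, o_max, h_cm, duration_s,
               neumann_rows);
  NumericMatrix out(nr, nc);
  std::copy(f.begin(), f.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_oxygen_steady(NumericMatrix field, IntegerMatrix occ, double D_o,
                       double alpha_o, double gamma_o, double o_max,
                       double h_cm, double tol, int max_iter) {
  int nr = field.nrow(), nc = field.ncol();
  if (occ.nrow() != nr || occ.ncol() != nc)
    stop("occupancy dimensions (%d x %d) do not match field (%d x %d)",
         occ.nrow(), occ.ncol(), nr, nc);
  std::vector<double> f(field.begin(), field.end());
  std::vector<int> o;
  unpack_grid_int(occ, o);
  int it = ox_steady_mg(f, o, nr, nc, D_o, alpha_o, gamma_o, o_max, h_cm, tol, max_iter);
  NumericMatrix out(nr, nc);
  std::copy(f.begin(), f.end(), out.begin());
  return List::create(_["field"] = out, _["iterations"] = it);
}

// [[Rcpp::export]]
List cpp_label_components(IntegerMatrix occ) {
  int n = occ.nrow();
  std::vector<int> o, lab, sizes;
  unpack_grid_int(occ, o);
  label_components(o, n, lab, sizes);
  IntegerMatrix L(n, n);
  std::copy(lab.begin(), lab.end(), L.begin());
  return List::create(_["labels"] = L,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}

// [[Rcpp::export]]
double cpp_compactness(IntegerMatrix occ) {
  int n = occ.nrow();
  std::vector<int> o;
  unpack_grid_int(occ, o);
  double s = 0.0;
  int N = 0;
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (o[i + n * j]) { s += count_nb(o, n, i, j, -1, -1) / 8.0; ++N; }
  if (N == 0) return NA_REAL;
  return s / N;
}

// [[Rcpp::export]]
double cpp_sparseness(IntegerMatrix occ) {
  int n = occ.nrow();
  std::vector<int> o, xi, xj;
  unpack_grid_int(occ, o);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (o[i + n * j]) { xi.push_back(i); xj.push_back(j); }
  return sparseness_grid(o, n, xi, xj);
}

// Full simulation loop. Per macro-step of t_r hours: movement pass (fresh
// random permutation of live cells), oxygen update over t_r with the current
// occupancy, lifecycle pass (fresh permutation; divisions then a hypoxic
// death sweep), clock advance, stopping checks, metric recording.
// [[Rcpp::export]]
List cpp_run(IntegerMatrix occ0, List cells0, NumericMatrix field0,
             double time0, List cfg) {
  int n = occ0.nrow();
  std::vector<int> occ;
  unpack_grid_int(occ0, occ);
  Cells C;
  unpack_cells(cells0, C);
  std::vector<double> field(field0.begin(), field0.end());

  double h_um = cfg["h_um"], t_r = cfg["t_r_h"], t_max = cfg["t_max_h"];
  double rec_every = cfg["record_every_h"];
  int edge_margin = cfg["edge_margin"];
  NumericVector Tp8 = cfg["T_p8_h"];
  int prolif_r = cfg["prolif_radius"];
  NumericVector phase_end = cfg["phase_end_h"], phase_D = cfg["phase_D"];
  double p_mut = cfg["p_mut"];
  IntegerVector tset = cfg["target_set"];
  std::vector<int> target(tset.begin(), tset.end());
  double D_o = cfg["D_o"], alpha_o = cfg["alpha_o"], gamma_o = cfg["gamma_o"];
  double o_max = cfg["o_max"], o_deadly = cfg["o_deadly"];
  int solver = cfg["oxygen_solver_code"];  // 0 frozen, 1 steady, 2 transient
  double steady_tol = cfg["steady_tol"];
  bool log_moves = cfg["log_moves"], log_lifecycle = cfg["log_lifecycle"];
  bool renormalised = cfg["move_renormalised"];
  bool stop_first_death = cfg["stop_at_first_death"];
  double h_cm = h_um * 1e-4, c0 = cfg["centre0"];  // centre site, 0-based

  Events ev;
  double first_death = NA_REAL;
  std::string stop_reason = "t_max";
  std::vector<MetricsRow> rows;
  double tnow = time0;
  rows.push_back(compute_metrics(occ, n, C, h_um, c0, tnow));
  double next_rec = tnow + rec_every;

  auto live_ids = [&]() {
    std::vector<int> ids;
    ids.reserve(C.size());
    for (int id = 1; id <= C.size(); ++id)
      if (C.alive[id - 1]) ids.push_back(id);
    return ids;
  };

  bool stopped = false;
  long macro_step = 0;
  while (!stopped && tnow < t_max - 1e-9) {
    // motility phase for the step starting at tnow
    double D_c = phase_D[phase_D.size() - 1];
    for (int p = 0; p < phase_end.size(); ++p)
      if (tnow < phase_end[p] - 1e-9) { D_c = phase_D[p]; break; }

    // 1) movement pass
    if (D_c > 0) {
      double t_r_s = t_r * 3600.0;
      double k = std::min(t_r_s, h_cm * h_cm / (4.0 * D_c));
      int nsub = static_cast<int>(std::ceil(t_r_s / k - 1e-12));
      if (nsub < 1) nsub = 1;
      k = t_r_s / nsub;
      double p_move = 4.0 * D_c * k / (h_cm * h_cm);
      std::vector<int> ids = live_ids();
      shuffle_ids(ids);
      for (int id : ids)
        move_turn(occ, n, C, id, p_move, nsub, renormalised, log_moves, &ev, tnow);
    }

    // 2) oxygen update with post-movement occupancy
    if (solver == 1)
      ox_steady_mg(field, occ, n, n, D_o, alpha_o, gamma_o, o_max, h_cm,
                   steady_tol, 500);
    else if (solver == 2)
      ox_transient(field, occ, n, n, D_o, alpha_o, gamma_o, o_max, h_cm,
                   t_r * 3600.0, false);

    // 3) lifecycle pass: divisions in fresh random order, then hypoxic deaths
    {
      std::vector<int> ids = live_ids();
      shuffle_ids(ids);
      for (int id : ids) {
        DivOut res = division_turn(occ, n, C, id, REAL(Tp8), prolif_r, t_r,
                                   p_mut, target);
        if (res.divided && log_lifecycle) {
          ev.add(tnow + t_r, 1, res.daughter, id);
          if (res.switched) ev.add(tnow + t_r, 3, id, res.new_ph);
        }
      }
      if (solver != 0) {
        for (int id = 1; id <= C.size(); ++id) {
          int x = id - 1;
          if (!C.alive[x]) continue;
          if (field[C.ci[x] + n * C.cj[x]] < o_deadly) {
            occ[C.ci[x] + n * C.cj[x]] = 0;
            C.alive[x] = false;
            if (log_lifecycle) ev.add(tnow + t_r, 2, id, 0);
            if (ISNA(first_death)) first_death = tnow + t_r;
          }
        }
      }
    }

    ++macro_step;
    tnow = time0 + macro_step * t_r;

    // stopping rules
    int n_live = 0;
    bool near_edge = false;
    for (int id = 1; id <= C.size(); ++id) {
      int x = id - 1;
      if (!C.alive[x]) continue;
      ++n_live;
      int d = std::min(std::min(C.ci[x], n - 1 - C.ci[x]),
                       std::min(C.cj[x], n - 1 - C.cj[x]));
      if (d < edge_margin) near_edge = true;
    }
    if (near_edge) { stop_reason = "edge"; stopped = true; }
    if (n_live == 0) { stop_reason = "extinct"; stopped = true; }
    if (stop_first_death && !ISNA(first_death)) { stop_reason = "first_death"; stopped = true; }
    if (tnow >= t_max - 1e-9) stopped = true;

    if (tnow >= next_rec - 1e-9 || stopped) {
      rows.push_back(compute_metrics(occ, n, C, h_um, c0, tnow));
      while (next_rec <= tnow + 1e-9) next_rec += rec_every;
    }
    Rcpp::checkUserInterrupt();
  }

  int R = static_cast<int>(rows.size());
  NumericVector mt(R), mn(R), mir(R), mcr(R), mlcc(R), mcp(R), msp(R);
  NumericMatrix mfreq(R, 8);
  for (int r = 0; r < R; ++r) {
    mt[r] = rows[r].time; mn[r] = rows[r].n_cells; mir[r] = rows[r].inv_r;
    mcr[r] = rows[r].core_r; mlcc[r] = rows[r].lcc_frac;
    mcp[r] = rows[r].compact; msp[r] = rows[r].sparse;
    for (int p = 0; p < 8; ++p) mfreq(r, p) = rows[r].freq[p];
  }
  DataFrame metrics = DataFrame::create(
      _["time_h"] = mt, _["n_cells"] = mn, _["invasive_radius_um"] = mir,
      _["core_radius_um"] = mcr, _["largest_cc_frac"] = mlcc,
      _["compactness"] = mcp, _["sparseness"] = msp);

  IntegerMatrix occ2(n, n);
  std::copy(occ.begin(), occ.end(), occ2.begin());
  NumericMatrix field2(n, n);
  std::copy(field.begin(), field.end(), field2.begin());

  return List::create(_["metrics"] = metrics, _["freq"] = mfreq,
                      _["occ"] = occ2, _["cells"] = pack_cells(C),
                      _["field"] = field2, _["time_h"] = tnow,
                      _["stop_reason"] = stop_reason,
                      _["first_death_h"] = first_death,
                      _["events"] = events_df(ev));
}
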