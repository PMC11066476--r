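#include <Rcpp.h>
#include <map>
#include <set>
#include <utility>
using namespace Rcpp;

// The lattice is an integer matrix of compartment ids (0 = medium). Compartment
// attributes are parallel vectors indexed by id. Contact energies are dense
// matrices indexed by label code (0 = medium): Jext between compartments of
// different clusters, Jint between compartments of the same cluster. The
// Hamiltonian is
//   H = sum_{neighbour pairs, different compartment} J(label_i, label_j)
//     + sum_{compartments} lambda * (volume - target)^2
// with neighbour pairs taken over the configured neighbour order (12 offsets
// at order 3). Fixed boundaries are no-flux: sites outside the lattice carry
// no energy and no copy may originate from or land on them.

static inline bool wrap_site(int &x, int &y, int W, int H, bool periodic) {
  if (x >= 0 && x < W && y >= 0 && y < H) return true;
  if (!periodic) return false;
  x = ((x % W) + W) % W;
  y = ((y % H) + H) % H;
  return true;
}

static inline double pair_j(int a, int b,
                            const IntegerVector &comp_label,
                            const IntegerVector &comp_cluster,
                            const NumericMatrix &Jext,
                            const NumericMatrix &Jint) {
  if (a == b) return 0.0;
  int la = (a > 0) ? comp_label[a - 1] : 0;
  int lb = (b > 0) ? comp_label[b - 1] : 0;
  double j;
  if (a > 0 && b > 0 && comp_cluster[a - 1] == comp_cluster[b - 1]) {
    j = Jint(la, lb);
  } else {
    j = Jext(la, lb);
  }
  if (NumericVector::is_na(j)) {
    stop("missing contact energy entry for label codes %d and %d", la, lb);
  }
  return j;
}

static double delta_h(const IntegerMatrix &sid,
                      const IntegerVector &comp_label,
                      const IntegerVector &comp_cluster,
                      const IntegerVector &comp_volume,
                      const NumericVector &comp_target,
                      const NumericVector &comp_lambda,
                      const NumericMatrix &Jext, const NumericMatrix &Jint,
                      const IntegerVector &offx, const IntegerVector &offy,
                      bool periodic,
                      int sx, int sy, int tx, int ty) {
  const int W = sid.nrow(), H = sid.ncol();
  const int a = sid(sx, sy);  // id copied in
  const int b = sid(tx, ty);  // id overwritten
  double dh = 0.0;
  for (int k = 0; k < offx.size(); ++k) {
    int nx = tx + offx[k], ny = ty + offy[k];
    if (!wrap_site(nx, ny, W, H, periodic)) continue;
    if (nx == tx && ny == ty) continue;
    int idn = sid(nx, ny);
    dh += pair_j(a, idn, comp_label, comp_cluster, Jext, Jint) -
          pair_j(b, idn, comp_label, comp_cluster, Jext, Jint);
  }
  if (b > 0) {
    double v = comp_volume[b - 1], t = comp_target[b - 1], l = comp_lambda[b - 1];
    dh += l * ((v - 1 - t) * (v - 1 - t) - (v - t) * (v - t));
  }
  if (a > 0) {
    double v = comp_volume[a - 1], t = comp_target[a - 1], l = comp_lambda[a - 1];
    dh += l * ((v + 1 - t) * (v + 1 - t) - (v - t) * (v - t));
  }
  return dh;
}

// Local connectivity test: removing site (tx, ty) from compartment b must not
// split b. The b-members of the 8-neighbourhood ring must form one 8-connected
// component; an empty ring (last pixel) is a vanish event, allowed only when
// the compartment's target volume is (effectively) zero. Applied only to
// guarded compartments (thin membrane films and pseudo-cells); the cytosol is
// unguarded so growth pressure can move it past one-pixel films.
static bool removal_safe(const IntegerMatrix &sid, int tx, int ty, int b,
                         double target_b, bool periodic) {
  if (b == 0) return true;
  const int W = sid.nrow(), H = sid.ncol();
  static const int rx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const int ry[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  bool in_b[8];
  int n_in = 0;
  for (int i = 0; i < 8; ++i) {
    int x = tx + rx[i], y = ty + ry[i];
    in_b[i] = wrap_site(x, y, W, H, periodic) && sid(x, y) == b;
    if (in_b[i]) ++n_in;
  }
  if (n_in == 0) return target_b <= 0.5;  // vanish of last pixel
  // BFS over ring members with 8-adjacency on their offsets
  int comp[8];
  for (int i = 0; i < 8; ++i) comp[i] = -1;
  int n_comp = 0;
  for (int i = 0; i < 8; ++i) {
    if (!in_b[i] || comp[i] >= 0) continue;
    int stack[8], top = 0;
    stack[top++] = i;
    comp[i] = n_comp;
    while (top > 0) {
      int c = stack[--top];
      for (int j = 0; j < 8; ++j) {
        if (!in_b[j] || comp[j] >= 0) continue;
        int dx = rx[c] - rx[j], dy = ry[c] - ry[j];
        if (dx >= -1 && dx <= 1 && dy >= -1 && dy <= 1) {
          comp[j] = n_comp;
          stack[top++] = j;
        }
      }
    }
    ++n_comp;
  }
  return n_comp == 1;
}

// Gain-side guard: the copied-in compartment must already own a pixel
// 8-adjacent to the target site, otherwise an order-3 copy could seed a
// disconnected satellite two pixels away.
static bool gain_adjacent(const IntegerMatrix &sid, int tx, int ty, int a,
                          bool periodic) {
  if (a == 0) return true;
  const int W = sid.nrow(), H = sid.ncol();
  static const int rx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const int ry[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int i = 0; i < 8; ++i) {
    int x = tx + rx[i], y = ty + ry[i];
    if (wrap_site(x, y, W, H, periodic) && sid(x, y) == a) return true;
  }
  return false;
}

// [[Rcpp::export]]
double cpp_total_hamiltonian(const IntegerMatrix &sid,
                             const IntegerVector &comp_label,
                             const IntegerVector &comp_cluster,
                             const IntegerVector &comp_volume,
                             const NumericVector &comp_target,
                             const NumericVector &comp_lambda,
                             const NumericMatrix &Jext, const NumericMatrix &Jint,
                             const IntegerVector &offx, const IntegerVector &offy,
                             bool periodic) {
  const int W = sid.nrow(), H = sid.ncol();
  double contact = 0.0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int a = sid(x, y);
      for (int k = 0; k < offx.size(); ++k) {
        int nx = x + offx[k], ny = y + offy[k];
        if (!wrap_site(nx, ny, W, H, periodic)) continue;
        contact += pair_j(a, sid(nx, ny), comp_label, comp_cluster, Jext, Jint);
      }
    }
  }
  contact /= 2.0;  // each unordered pair visited twice
  double volume = 0.0;
  for (int i = 0; i < comp_volume.size(); ++i) {
    double d = comp_volume[i] - comp_target[i];
    volume += comp_lambda[i] * d * d;
  }
  return contact + volume;
}

// [[Rcpp::export]]
List cpp_delta_hamiltonian(const IntegerMatrix &sid,
                           const IntegerVector &comp_label,
                           const IntegerVector &comp_cluster,
                           const IntegerVector &comp_volume,
                           const NumericVector &comp_target,
                           const NumericVector &comp_lambda,
                           const NumericMatrix &Jext, const NumericMatrix &Jint,
                           const IntegerVector &offx, const IntegerVector &offy,
                           bool periodic,
                           int sx, int sy, int tx, int ty) {
  if (sid(sx, sy) == sid(tx, ty)) {
    return List::create(_["dh"] = 0.0, _["null_move"] = true);
  }
  double dh = delta_h(sid, comp_label, comp_cluster, comp_volume, comp_target,
                      comp_lambda, Jext, Jint, offx, offy, periodic,
                      sx, sy, tx, ty);
  return List::create(_["dh"] = dh, _["null_move"] = false);
}

// Single copy attempt between a forced site pair; used by attempt_copy() and
// by tests that measure the empirical acceptance law through the same code
// path as the MCS loop. Mutates state when commit = true and the move is
// accepted.
// [[Rcpp::export]]
List cpp_try_copy(IntegerMatrix sid,
                  const IntegerVector &comp_label,
                  const IntegerVector &comp_cluster,
                  IntegerVector comp_volume,
                  const NumericVector &comp_target,
                  const NumericVector &comp_lambda,
                  const NumericMatrix &Jext, const NumericMatrix &Jint,
                  double temp,
                  const IntegerVector &offx, const IntegerVector &offy,
                  bool periodic, bool guard,
                  const LogicalVector &comp_guard,
                  int sx, int sy, int tx, int ty, bool commit) {
  int a = sid(sx, sy), b = sid(tx, ty);
  if (a == b) {
    return List::create(_["accepted"] = false, _["dh"] = 0.0,
                        _["null_move"] = true);
  }
  double dh = delta_h(sid, comp_label, comp_cluster, comp_volume, comp_target,
                      comp_lambda, Jext, Jint, offx, offy, periodic,
                      sx, sy, tx, ty);
  bool ok = true;
  if (guard) {
    bool gb = b > 0 && comp_guard[b - 1];
    bool ga = a > 0 && comp_guard[a - 1];
    if (gb) {
      double tb = comp_target[b - 1];
      ok = removal_safe(sid, tx, ty, b, tb, periodic);
      if (ok && comp_volume[b - 1] == 1 && comp_target[b - 1] > 0.5)
        ok = false;
    }
    if (ok && ga) ok = gain_adjacent(sid, tx, ty, a, periodic);
  }
  bool accepted = false;
  if (ok) {
    accepted = (dh <= 0.0) || (unif_rand() < std::exp(-dh / temp));
  }
  if (accepted && commit) {
    sid(tx, ty) = a;
    if (b > 0) comp_volume[b - 1] -= 1;
    if (a > 0) comp_volume[a - 1] += 1;
  }
  return List::create(_["accepted"] = accepted, _["dh"] = dh,
                      _["null_move"] = false);
}

// One Monte Carlo Step: n_attempts random copy attempts (target site and a
// random neighbour as source, independent uniform picks with replacement).
// Mutates sid and comp_volume in place; returns the number of accepted copies.
// [[Rcpp::export]]
int cpp_mcs(IntegerMatrix sid,
            const IntegerVector &comp_label,
            const IntegerVector &comp_cluster,
            IntegerVector comp_volume,
            const NumericVector &comp_target,
            const NumericVector &comp_lambda,
            const NumericMatrix &Jext, const NumericMatrix &Jint,
            double temp,
            const IntegerVector &offx, const IntegerVector &offy,
            bool periodic, bool guard,
            const LogicalVector &comp_guard, int n_attempts) {
  const int W = sid.nrow(), H = sid.ncol();
  const int nOff = offx.size();
  int accepted = 0;
  for (int it = 0; it < n_attempts; ++it) {
    int tx = (int)(unif_rand() * W); if (tx == W) --tx;
    int ty = (int)(unif_rand() * H); if (ty == H) --ty;
    int k = (int)(unif_rand() * nOff); if (k == nOff) --k;
    int sx = tx + offx[k], sy = ty + offy[k];
    if (!wrap_site(sx, sy, W, H, periodic)) continue;  // counted as rejected
    int a = sid(sx, sy), b = sid(tx, ty);
    if (a == b) continue;  // null move
    if (guard) {
      if (b > 0 && comp_guard[b - 1]) {
        if (!removal_safe(sid, tx, ty, b, comp_target[b - 1], periodic)) continue;
        if (comp_volume[b - 1] == 1 && comp_target[b - 1] > 0.5) continue;
      }
      if (a > 0 && comp_guard[a - 1] &&
          !gain_adjacent(sid, tx, ty, a, periodic)) continue;
    }
    double dh = delta_h(sid, comp_label, comp_cluster, comp_volume, comp_target,
                        comp_lambda, Jext, Jint, offx, offy, periodic,
                        sx, sy, tx, ty);
    if (dh <= 0.0 || unif_rand() < std::exp(-dh / temp)) {
      sid(tx, ty) = a;
      if (b > 0) comp_volume[b - 1] -= 1;
      if (a > 0) comp_volume[a - 1] += 1;
      ++accepted;
    }
  }
  return accepted;
}

// Boundary-pair counts between distinct compartments (0 = medium), over
// unordered neighbour pairs within the configured offsets.
// [[Rcpp::export]]
IntegerMatrix cpp_comp_adjacency(const IntegerMatrix &sid,
                                 const IntegerVector &offx,
                                 const IntegerVector &offy,
                                 bool periodic) {
  const int W = sid.nrow(), H = sid.ncol();
  std::map<std::pair<int, int>, int> counts;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int a = sid(x, y);
      for (int k = 0; k < offx.size(); ++k) {
        int dx = offx[k], dy = offy[k];
        // half of the offsets so each unordered pair is counted once
        if (dy < 0 || (dy == 0 && dx <= 0)) continue;
        int nx = x + dx, ny = y + dy;
        if (!wrap_site(nx, ny, W, H, periodic)) continue;
        int b = sid(nx, ny);
        if (a == b) continue;
        std::pair<int, int> key = (a < b) ? std::make_pair(a, b)
                                          : std::make_pair(b, a);
        counts[key] += 1;
      }
    }
  }
  IntegerMatrix out(counts.size(), 3);
  int i = 0;
  for (std::map<std::pair<int, int>, int>::const_iterator it = counts.begin();
       it != counts.end(); ++it, ++i) {
    out(i, 0) = it->first.first;
    out(i, 1) = it->first.second;
    out(i, 2) = it->second;
  }
  colnames(out) = CharacterVector::create("comp_a", "comp_b", "boundary");
  return out;
}

// For each cluster, whether it touches (within the neighbour offsets) any
// OTHER cluster flagged in `is_epi`. Used by the contact-inhibition rule.
// [[Rcpp::export]]
LogicalVector cpp_epithelial_contact(const IntegerMatrix &sid,
                                     const IntegerVector &comp_cluster,
                                     const LogicalVector &is_epi,
                                     const IntegerVector &offx,
                                     const IntegerVector &offy,
                                     bool periodic) {
  const int W = sid.nrow(), H = sid.ncol();
  int ncl = is_epi.size();
  LogicalVector touched(ncl, false);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int a = sid(x, y);
      if (a == 0) continue;
      int ca = comp_cluster[a - 1];
      if (ca <= 0 || ca > ncl || !is_epi[ca - 1]) continue;
      for (int k = 0; k < offx.size(); ++k) {
        int nx = x + offx[k], ny = y + offy[k];
        if (!wrap_site(nx, ny, W, H, periodic)) continue;
        int b = sid(nx, ny);
        if (b == 0 || b == a) continue;
        int cb = comp_cluster[b - 1];
        if (cb != ca && cb > 0 && cb <= ncl && is_epi[cb - 1]) {
          touched[ca - 1] = true;
          break;
        }
      }
    }
  }
  return touched;
}

// Medium sites adjacent (order-1) to apical pixels of flagged clusters;
// returns one row per (site, cluster) pair. Used by mucus secretion.
// [[Rcpp::export]]
IntegerMatrix cpp_medium_adjacent_apical(const IntegerMatrix &sid,
                                         const IntegerVector &comp_label,
                                         const IntegerVector &comp_cluster,
                                         const LogicalVector &is_apical_label,
                                         const LogicalVector &is_secreting_cluster,
                                         bool periodic) {
  const int W = sid.nrow(), H = sid.ncol();
  static const int rx[4] = {1, -1, 0, 0};
  static const int ry[4] = {0, 0, 1, -1};
  std::set<std::pair<int, int> > hits;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (sid(x, y) != 0) continue;
      for (int k = 0; k < 4; ++k) {
        int nx = x + rx[k], ny = y + ry[k];
        if (!wrap_site(nx, ny, W, H, periodic)) continue;
        int b = sid(nx, ny);
        if (b == 0) continue;
        int lb = comp_label[b - 1], cb = comp_cluster[b - 1];
        if (lb > 0 && lb <= is_apical_label.size() && is_apical_label[lb - 1] &&
            cb > 0 && cb <= is_secreting_cluster.size() &&
            is_secreting_cluster[cb - 1]) {
          hits.insert(std::make_pair(y * W + x + 1, cb));  // 1-based linear index
        }
      }
    }
  }
  IntegerMatrix out(hits.size(), 2);
  int i = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = hits.begin();
       it != hits.end(); ++it, ++i) {
    out(i, 0) = it->first;
    out(i, 1) = it->second;
  }
  colnames(out) = CharacterVector::create("site", "cluster");
  return out;
}
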