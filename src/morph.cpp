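// Binary morphology primitives for skeleton tracing: iterative thinning
// (Zhang-Suen), spur pruning, 8-connected labelling, hit-miss seed
// detection and neighbour counting. Images are logical/integer matrices,
// row = frame (time), column = position.
#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline int at(const IntegerMatrix& m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix img) {
  IntegerMatrix m = clone(img);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!m(r, c)) continue;
          // neighbours clockwise from north: p2..p9
          int p2 = at(m, r - 1, c),     p3 = at(m, r - 1, c + 1);
          int p4 = at(m, r,     c + 1), p5 = at(m, r + 1, c + 1);
          int p6 = at(m, r + 1, c),     p7 = at(m, r + 1, c - 1);
          int p8 = at(m, r,     c - 1), p9 = at(m, r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int a = 0;
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++a;
          if (a != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k) m(kill[k].first, kill[k].second) = 0;
    }
  }
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_count(IntegerMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!m(r, c)) { out(r, c) = 0; continue; }
      int s = 0;
      for (int dr = -1; dr <= 1; ++dr)
        for (int dc = -1; dc <= 1; ++dc)
          if (dr || dc) s += at(m, r + dr, c + dc);
      out(r, c) = s;
    }
  return out;
}

// Remove spur branches shorter than min_branch pixels. Walk inward from
// each endpoint collecting the chain of simple (single-continuation)
// pixels. The walk stops at a pixel q with several continuations:
// if q's non-chain neighbours form one 8-connected group, q is an
// attachment pixel of the spur itself (removing it cannot disconnect
// anything) and joins the chain; otherwise q is a genuine junction on a
// through-going line and stays. A chain that stopped at a junction and
// is shorter than min_branch is deleted. Isolated short segments (no
// junction) are kept; track-length filters handle them downstream.
// Repeats until stable.
static bool in_chain(const std::vector<std::pair<int,int> >& chain,
                     int r, int c) {
  for (size_t k = 0; k < chain.size(); ++k)
    if (chain[k].first == r && chain[k].second == c) return true;
  return false;
}

// [[Rcpp::export]]
IntegerMatrix cpp_prune(IntegerMatrix img, int min_branch) {
  IntegerMatrix m = clone(img);
  int nr = m.nrow(), nc = m.ncol();
  bool changed = true;
  while (changed) {
    changed = false;
    IntegerMatrix ncount = cpp_neighbor_count(m);
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        if (!m(r, c) || ncount(r, c) != 1) continue;
        std::vector<std::pair<int,int> > chain;
        chain.push_back(std::make_pair(r, c));
        int cr = r, cc = c;
        bool hit_junction = false;
        while ((int)chain.size() < min_branch) {
          std::vector<std::pair<int,int> > cand;
          for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              if (!dr && !dc) continue;
              int rr = cr + dr, cco = cc + dc;
              if (at(m, rr, cco) && !in_chain(chain, rr, cco))
                cand.push_back(std::make_pair(rr, cco));
            }
          if (cand.empty()) break;        // natural end: isolated segment
          if (cand.size() > 1) { hit_junction = true; break; }
          int qr = cand[0].first, qc = cand[0].second;
          std::vector<std::pair<int,int> > nb;
          for (int dr = -1; dr <= 1; ++dr)
            for (int dc = -1; dc <= 1; ++dc) {
              if (!dr && !dc) continue;
              int rr = qr + dr, cco = qc + dc;
              if (at(m, rr, cco) && !in_chain(chain, rr, cco))
                nb.push_back(std::make_pair(rr, cco));
            }
          if (nb.size() <= 1) {           // simple chain pixel
            chain.push_back(cand[0]);
            cr = qr; cc = qc;
            continue;
          }
          // several continuations: one connected group -> attachment
          // pixel of the spur; several groups -> real junction
          std::vector<int> grp(nb.size());
          for (size_t k = 0; k < nb.size(); ++k) grp[k] = (int)k;
          bool merged = true;
          while (merged) {
            merged = false;
            for (size_t i = 0; i < nb.size(); ++i)
              for (size_t j = i + 1; j < nb.size(); ++j)
                if (grp[i] != grp[j] &&
                    std::abs(nb[i].first - nb[j].first) <= 1 &&
                    std::abs(nb[i].second - nb[j].second) <= 1) {
                  int from = grp[j], to = grp[i];
                  for (size_t k = 0; k < nb.size(); ++k)
                    if (grp[k] == from) grp[k] = to;
                  merged = true;
                }
          }
          bool oneGroup = true;
          for (size_t k = 1; k < nb.size(); ++k)
            if (grp[k] != grp[0]) oneGroup = false;
          hit_junction = true;
          if (oneGroup) chain.push_back(cand[0]);
          break;
        }
        if (hit_junction && (int)chain.size() < min_branch) {
          for (size_t k = 0; k < chain.size(); ++k)
            m(chain[k].first, chain[k].second) = 0;
          changed = true;
        }
      }
    }
  }
  return m;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!img(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int dr = -1; dr <= 1; ++dr)
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
            if (img(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
      }
    }
  return lab;
}

// Track-seed detection: hit-miss with kernel
//   -1 -1 -1
//   -1  1 -1
//    0  0  0
// i.e. centre on, all three pixels in the previous row off, both lateral
// same-row pixels off, next row unconstrained. Off-image pixels count as
// background, so seeds in the first row match.
// [[Rcpp::export]]
IntegerMatrix cpp_hitmiss_seeds(IntegerMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<int> rows, cols;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!skel(r, c)) continue;
      if (at(skel, r - 1, c - 1) || at(skel, r - 1, c) || at(skel, r - 1, c + 1))
        continue;
      if (at(skel, r, c - 1) || at(skel, r, c + 1)) continue;
      rows.push_back(r); cols.push_back(c);
    }
  IntegerMatrix out(rows.size(), 2);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k]; out(k, 1) = cols[k];
  }
  return out;
}
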