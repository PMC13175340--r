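// Persistent homology of the V-construction cubical complex of a 2-D
// integer image, dimensions 0 and 1, by two union-find passes:
//   dim 0: ascending Kruskal-style pass over vertices/edges (elder rule);
//   dim 1: descending pass over the dual graph (squares + outside node),
//          the planar-duality algorithm for top-dimensional holes.
// Cell values: vertex = pixel value; edge/square = max over faces.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) { int nx = parent[x]; parent[x] = r; x = nx; }
    return r;
  }
};

// enumeration order of primal edges: horizontal row-major, then vertical
// row-major; used for deterministic tie-breaking.
inline int n_hedges(int H, int W) { return H * (W - 1); }

} // namespace

// [[Rcpp::export]]
List cubical_pairs_cpp(IntegerMatrix img, bool representatives) {
  const int H = img.nrow(), W = img.ncol();
  const int n = H * W;
  std::vector<int> val(n);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) val[r * W + c] = img(r, c);

  // ---- enumerate primal edges -------------------------------------------
  const int nh = n_hedges(H, W), nv = (H - 1) * W, ne = nh + nv;
  std::vector<int> eu(ne), ev(ne), eval_(ne);
  {
    int k = 0;
    for (int r = 0; r < H; ++r)
      for (int c = 0; c + 1 < W; ++c, ++k) {
        eu[k] = r * W + c; ev[k] = r * W + c + 1;
        eval_[k] = std::max(val[eu[k]], val[ev[k]]);
      }
    for (int r = 0; r + 1 < H; ++r)
      for (int c = 0; c < W; ++c, ++k) {
        eu[k] = r * W + c; ev[k] = (r + 1) * W + c;
        eval_[k] = std::max(val[eu[k]], val[ev[k]]);
      }
  }

  // ---- dimension 0: ascending union-find --------------------------------
  std::vector<int> eord(ne);
  for (int i = 0; i < ne; ++i) eord[i] = i;
  std::stable_sort(eord.begin(), eord.end(),
                   [&](int a, int b) { return eval_[a] < eval_[b]; });

  DSU dsu0(n);
  // per-root component data: birth value and anchor vertex (smallest id
  // among vertices attaining the birth value -> lexicographic (row,col))
  std::vector<int> cbirth(val), canchor(n);
  for (int i = 0; i < n; ++i) canchor[i] = i;

  std::vector<int> d0_birth, d0_death, d0_anchor;
  for (int idx : eord) {
    int ra = dsu0.find(eu[idx]), rb = dsu0.find(ev[idx]);
    if (ra == rb) continue;
    // elder: smaller birth, tie -> smaller anchor id
    int elder = ra, younger = rb;
    if (cbirth[rb] < cbirth[ra] ||
        (cbirth[rb] == cbirth[ra] && canchor[rb] < canchor[ra])) {
      elder = rb; younger = ra;
    }
    if (eval_[idx] > cbirth[younger]) {         // skip zero-persistence bars
      d0_birth.push_back(cbirth[younger]);
      d0_death.push_back(eval_[idx]);
      d0_anchor.push_back(canchor[younger]);
    }
    dsu0.parent[younger] = elder;
  }
  // essential class (grid is connected): death capped at 255
  int root = dsu0.find(0);
  const int ess_birth = cbirth[root], ess_anchor = canchor[root];

  // ---- dimension 1: descending union-find on the dual -------------------
  const int SH = H - 1, SW = W - 1, nsq = SH * SW;
  const int OUT = nsq;                           // outside node
  const int64_t INF = INT64_MAX / 4;
  std::vector<int64_t> sval(nsq + 1);
  for (int r = 0; r < SH; ++r)
    for (int c = 0; c < SW; ++c) {
      int a = val[r * W + c], b = val[r * W + c + 1];
      int d = val[(r + 1) * W + c], e = val[(r + 1) * W + c + 1];
      sval[r * SW + c] = std::max(std::max(a, b), std::max(d, e));
    }
  sval[OUT] = INF;

  // dual endpoints of each primal edge
  std::vector<int> da(ne), db(ne);
  for (int k = 0; k < ne; ++k) {
    if (k < nh) {                                 // horizontal edge (r,c)-(r,c+1)
      int r = k / (W - 1), c = k % (W - 1);
      da[k] = (r >= 1) ? (r - 1) * SW + c : OUT;
      db[k] = (r <= H - 2) ? r * SW + c : OUT;
    } else {                                      // vertical edge (r,c)-(r+1,c)
      int kk = k - nh;
      int r = kk / W, c = kk % W;
      da[k] = (c >= 1) ? r * SW + (c - 1) : OUT;
      db[k] = (c <= W - 2) ? r * SW + c : OUT;
    }
  }

  std::vector<int> dord(ne);
  for (int i = 0; i < ne; ++i) dord[i] = i;
  std::stable_sort(dord.begin(), dord.end(),
                   [&](int a, int b) { return eval_[a] > eval_[b]; });

  DSU dsu1(nsq + 1);
  std::vector<int64_t> dbirth(sval);              // descending birth = max square
  std::vector<int> danchor(nsq + 1);
  for (int i = 0; i <= nsq; ++i) danchor[i] = i;

  std::vector<int> d1_birth, d1_death, d1_edge, d1_sq;
  for (int idx : dord) {
    if (da[idx] == db[idx]) continue;             // both sides outside (1-D strip)
    int ra = dsu1.find(da[idx]), rb = dsu1.find(db[idx]);
    if (ra == rb) continue;
    int elder = ra, younger = rb;                 // elder: larger descending birth
    if (dbirth[rb] > dbirth[ra] ||
        (dbirth[rb] == dbirth[ra] && danchor[rb] < danchor[ra])) {
      elder = rb; younger = ra;
    }
    int64_t dd = dbirth[younger];                 // hole's death in primal terms
    if (dd > eval_[idx]) {                        // skip zero-persistence
      d1_birth.push_back(eval_[idx]);
      d1_death.push_back((int)dd);
      d1_edge.push_back(idx);
      d1_sq.push_back(danchor[younger]);          // a square inside the hole
    }
    dsu1.parent[younger] = elder;
  }

  // ---- dimension-1 representatives --------------------------------------
  // The hole born at level b is the bounded complement region R: squares
  // with value > b connected through primal edges of value > b (recovered
  // by BFS from the dying dual component's root).  Every edge on the
  // boundary of R has value <= b, so the outer contour of R is a closed
  // loop of birth-level edges enclosing the hole; it is traced with the
  // region kept on the left (left-hand turn rule at pinch vertices).
  List reps(d1_birth.size());
  if (representatives && !d1_birth.empty()) {
    std::vector<int> sq_stamp(nsq, -1);
    std::vector<int> q(nsq);
    // directed boundary edges per vertex (at most 2 outgoing), stamped
    std::vector<int> v_stamp(n, -1);
    std::vector<int> out_to[2] = { std::vector<int>(n, -1),
                                   std::vector<int>(n, -1) };
    std::vector<unsigned char> used0(n, 0), used1(n, 0);
    auto sq_edge_val = [&](int r, int c, int t) {
      // value of the primal edge between square (r,c) and its t-neighbour
      switch (t) {
        case 0: return std::max(val[r * W + c], val[r * W + c + 1]);          // up
        case 1: return std::max(val[(r + 1) * W + c], val[(r + 1) * W + c + 1]); // down
        case 2: return std::max(val[r * W + c], val[(r + 1) * W + c]);        // left
        default: return std::max(val[r * W + c + 1], val[(r + 1) * W + c + 1]); // right
      }
    };
    for (size_t bi = 0; bi < d1_birth.size(); ++bi) {
      const int b = d1_birth[bi];
      const int a = d1_sq[bi];
      // BFS for the complement region R
      int head = 0, tail = 0;
      std::vector<int> region;
      q[tail++] = a; sq_stamp[a] = (int)bi;
      while (head < tail) {
        int cur = q[head++];
        region.push_back(cur);
        int r = cur / SW, c = cur % SW;
        const int nbr[4] = { (r > 0) ? cur - SW : -1,
                             (r + 1 < SH) ? cur + SW : -1,
                             (c > 0) ? cur - 1 : -1,
                             (c + 1 < SW) ? cur + 1 : -1 };
        for (int t = 0; t < 4; ++t) {
          int nb = nbr[t];
          if (nb < 0 || sq_stamp[nb] == (int)bi) continue;
          if (sval[nb] <= b) continue;
          if (sq_edge_val(r, c, t) <= b) continue;
          sq_stamp[nb] = (int)bi; q[tail++] = nb;
        }
      }
      // directed boundary edges, region on the left
      int start = INT32_MAX;
      auto add_dir = [&](int from, int to) {
        if (v_stamp[from] != (int)bi) {
          v_stamp[from] = (int)bi; out_to[0][from] = to; out_to[1][from] = -1;
          used0[from] = 0; used1[from] = 0;
        } else {
          out_to[1][from] = to; used1[from] = 0;
        }
        if (from < start) start = from;
        if (to < start) { /* targets are also sources elsewhere */ }
      };
      for (int cur : region) {
        int r = cur / SW, c = cur % SW;
        int tl = r * W + c, tr = r * W + c + 1;
        int bl = (r + 1) * W + c, br = (r + 1) * W + c + 1;
        bool up    = (r > 0)      && sq_stamp[cur - SW] == (int)bi;
        bool down  = (r + 1 < SH) && sq_stamp[cur + SW] == (int)bi;
        bool left  = (c > 0)      && sq_stamp[cur - 1] == (int)bi;
        bool right = (c + 1 < SW) && sq_stamp[cur + 1] == (int)bi;
        if (!up)    add_dir(tr, tl);   // walk west, region below on the left
        if (!down)  add_dir(bl, br);   // walk east
        if (!left)  add_dir(tl, bl);   // walk south
        if (!right) add_dir(br, tr);   // walk north
      }
      // trace from the topmost-leftmost boundary vertex
      std::vector<int> loop;
      int v = start;
      int prev_dr = 0, prev_dc = 0;
      do {
        loop.push_back(v);
        int cand[2] = { (v_stamp[v] == (int)bi && !used0[v]) ? out_to[0][v] : -1,
                        (v_stamp[v] == (int)bi && !used1[v]) ? out_to[1][v] : -1 };
        int pick = -1, slot = -1;
        if (cand[0] >= 0 && cand[1] >= 0) {
          // pinch vertex: prefer the leftmost turn relative to heading
          int best_rank = 99;
          for (int s = 0; s < 2; ++s) {
            int dr = cand[s] / W - v / W, dc = cand[s] % W - v % W;
            // rank 0: left of heading, 1: straight, 2: right, 3: back
            int ldr = -prev_dc, ldc = prev_dr;
            int rank;
            if (dr == ldr && dc == ldc) rank = 0;
            else if (dr == prev_dr && dc == prev_dc) rank = 1;
            else if (dr == -ldr && dc == -ldc) rank = 2;
            else rank = 3;
            if (rank < best_rank) { best_rank = rank; pick = cand[s]; slot = s; }
          }
        } else if (cand[0] >= 0) { pick = cand[0]; slot = 0; }
        else if (cand[1] >= 0) { pick = cand[1]; slot = 1; }
        if (pick < 0) break;                      // should not happen
        if (slot == 0) used0[v] = 1; else used1[v] = 1;
        prev_dr = pick / W - v / W; prev_dc = pick % W - v % W;
        v = pick;
      } while (v != start);
      IntegerMatrix m(loop.size(), 2);
      for (size_t i = 0; i < loop.size(); ++i) {
        m(i, 0) = loop[i] / W + 1;                 // 1-based row
        m(i, 1) = loop[i] % W + 1;                 // 1-based col
      }
      reps[bi] = m;
    }
  }

  // ---- assemble ----------------------------------------------------------
  const int n0 = (int)d0_birth.size();
  IntegerVector b0(n0 + 1), dth0(n0 + 1), ar0(n0 + 1), ac0(n0 + 1);
  LogicalVector ess0(n0 + 1);
  for (int i = 0; i < n0; ++i) {
    b0[i] = d0_birth[i]; dth0[i] = d0_death[i]; ess0[i] = false;
    ar0[i] = d0_anchor[i] / W + 1; ac0[i] = d0_anchor[i] % W + 1;
  }
  b0[n0] = ess_birth; dth0[n0] = 255; ess0[n0] = true;
  ar0[n0] = ess_anchor / W + 1; ac0[n0] = ess_anchor % W + 1;

  const int n1 = (int)d1_birth.size();
  IntegerVector b1(n1), dth1(n1), ar1(n1), ac1(n1);
  for (int i = 0; i < n1; ++i) {
    b1[i] = d1_birth[i]; dth1[i] = d1_death[i];
    ar1[i] = eu[d1_edge[i]] / W + 1; ac1[i] = eu[d1_edge[i]] % W + 1;
  }

  return List::create(
    _["dim0"] = List::create(_["birth"] = b0, _["death"] = dth0,
                             _["essential"] = ess0,
                             _["anchor_row"] = ar0, _["anchor_col"] = ac0),
    _["dim1"] = List::create(_["birth"] = b1, _["death"] = dth1,
                             _["anchor_row"] = ar1, _["anchor_col"] = ac1),
    _["dim1_reps"] = reps);
}

// Count 4-connected components of a logical mask.
// [[Rcpp::export]]
int label4_count_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> seen(H * W, 0);
  std::vector<int> q(H * W);
  int comps = 0;
  for (int s = 0; s < H * W; ++s) {
    if (seen[s] || !mask(s / W, s % W)) continue;
    ++comps;
    int head = 0, tail = 0;
    q[tail++] = s; seen[s] = 1;
    while (head < tail) {
      int cur = q[head++];
      int r = cur / W, c = cur % W;
      const int nbr[4] = { (r > 0) ? cur - W : -1, (r + 1 < H) ? cur + W : -1,
                           (c > 0) ? cur - 1 : -1, (c + 1 < W) ? cur + 1 : -1 };
      for (int t = 0; t < 4; ++t) {
        int nb = nbr[t];
        if (nb < 0 || seen[nb] || !mask(nb / W, nb % W)) continue;
        seen[nb] = 1; q[tail++] = nb;
      }
    }
  }
  return comps;
}
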