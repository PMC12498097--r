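#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Moore-neighborhood ray directions (E, NE, N, NW, W, SW, S, SE).
static const int DX[8] = {1, 1, 0, -1, -1, -1, 0, 1};
static const int DY[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// Fitness class of a cell under the constant-selection model:
//   class 0 -> base rate 1, class 1 -> 1 + s_a, class 2 -> 1 + s_b.
// model 0: single species (positive iff c1 > 0, s_a is the selection
// coefficient); model 1: wild-type (c1) + variant (c2), any variant copy
// dominates (s_b = variant selection, s_a = wt-only selection); model 2:
// two species, class 1 = exactly one species present (pure, s_a = s_p),
// class 2 = both present (mixed, s_b = s_m).
static inline int fitness_class(int model, long c1, long c2) {
  switch (model) {
  case 0:
    return c1 > 0 ? 1 : 0;
  case 1:
    return c2 > 0 ? 2 : (c1 > 0 ? 1 : 0);
  default: {
    bool a = c1 > 0, b = c2 > 0;
    return (a && b) ? 2 : ((a || b) ? 1 : 0);
  }
  }
}

// Duplicate (c1, c2) to (2c1, 2c2) and split between daughters A and B.
// round(rho * min(2c1, 2c2)) cross-species pairs each follow a single fair
// coin (correlated inheritance); all unpaired copies segregate
// independently Binomial(., 1/2).  rho = 0 is plain binomial partitioning.
static inline void segregate_pair(long c1, long c2, double rho,
                                  long &a1, long &a2) {
  long t1 = 2 * c1, t2 = 2 * c2;
  long np = 0;
  if (rho > 0.0 && t1 > 0 && t2 > 0) {
    // round-half-to-even on rho * min(2c1, 2c2)
    np = (long) std::nearbyint(rho * (double) std::min(t1, t2));
  }
  long pairsA = (np > 0) ? (long) R::rbinom((double) np, 0.5) : 0;
  a1 = pairsA + (long) R::rbinom((double) (t1 - np), 0.5);
  a2 = pairsA + (long) R::rbinom((double) (t2 - np), 0.5);
}

// Rejection-free (BKL) event pick: division classes weighted by
// count * rate, death weighted by n * d; waiting time is exponential with
// mean 1 / total rate.  kind: 0 division, 1 death; cls set for divisions.
static inline void pick_event(const long ncls[3], const double rate[3],
                              double d, long n, int &kind, int &cls,
                              double &dt) {
  double rdiv = ncls[0] * rate[0] + ncls[1] * rate[1] + ncls[2] * rate[2];
  double rtot = rdiv + n * d;
  if (!(rtot > 0)) stop("total event rate is not positive");
  dt = R::exp_rand() / rtot;
  double u = unif_rand() * rtot;
  kind = 1;
  cls = -1;
  if (u < rdiv) {
    kind = 0;
    double acc = 0;
    for (int c = 0; c < 3; ++c) {
      acc += ncls[c] * rate[c];
      if (u < acc) { cls = c; return; }
    }
    cls = 2; // guard against floating-point edge
  }
}

static inline int unif_index(int size) {
  int i = (int) (unif_rand() * size);
  return i >= size ? size - 1 : i;
}

// ---------------------------------------------------------------------------
// Population bookkeeping shared by the lattice and well-mixed engines: cells
// live in flat arrays, each cell belongs to one fitness class, and class
// membership lists allow O(1) uniform picks within a class.

struct Cells {
  std::vector<long> c1, c2;
  std::vector<int> cls, posc;
  std::vector<int> members[3];
  long ncls[3] = {0, 0, 0};
  long tot1 = 0, tot2 = 0; // running copy totals (conservation check)

  int n() const { return (int) c1.size(); }

  int add(long k1, long k2, int model) {
    int i = (int) c1.size();
    c1.push_back(k1);
    c2.push_back(k2);
    int c = fitness_class(model, k1, k2);
    cls.push_back(c);
    posc.push_back((int) members[c].size());
    members[c].push_back(i);
    ncls[c]++;
    tot1 += k1;
    tot2 += k2;
    return i;
  }

  void drop_member(int i) {
    int c = cls[i], p = posc[i];
    int last = members[c].back();
    members[c][p] = last;
    posc[last] = p;
    members[c].pop_back();
    ncls[c]--;
  }

  void set_class(int i, int cnew) {
    if (cls[i] == cnew) return;
    drop_member(i);
    cls[i] = cnew;
    posc[i] = (int) members[cnew].size();
    members[cnew].push_back(i);
    ncls[cnew]++;
  }

  // swap-remove cell i; returns the old index of the cell moved into slot i
  // (or -1 if none) so spatial callers can fix coordinates.
  int remove(int i) {
    tot1 -= c1[i];
    tot2 -= c2[i];
    drop_member(i);
    int last = (int) c1.size() - 1;
    int moved = -1;
    if (i != last) {
      c1[i] = c1[last];
      c2[i] = c2[last];
      cls[i] = cls[last];
      posc[i] = posc[last];
      members[cls[i]][posc[i]] = i;
      moved = last;
    }
    c1.pop_back();
    c2.pop_back();
    cls.pop_back();
    posc.pop_back();
    return moved;
  }

  void check_integrity(int model) const {
    long s1 = 0, s2 = 0, nc[3] = {0, 0, 0};
    for (int i = 0; i < n(); ++i) {
      if (c1[i] < 0 || c2[i] < 0) stop("negative copy count");
      if (cls[i] != fitness_class(model, c1[i], c2[i]))
        stop("stale fitness class");
      if (members[cls[i]][posc[i]] != i) stop("class membership corrupted");
      s1 += c1[i];
      s2 += c2[i];
      nc[cls[i]]++;
    }
    if (s1 != tot1 || s2 != tot2)
      stop("ecDNA copy conservation violated");
    for (int c = 0; c < 3; ++c)
      if (nc[c] != ncls[c]) stop("class counts corrupted");
  }
};

struct Lattice {
  int span, L;
  std::vector<int> grid; // cell index + 1; 0 = empty
  std::vector<int> xs, ys;
  Cells cells;

  Lattice(int span_) : span(span_), L(2 * span_ + 1),
                       grid((size_t) L * (size_t) L, 0) {}

  inline size_t gidx(int x, int y) const {
    return (size_t) (x + span) + (size_t) L * (size_t) (y + span);
  }
  inline bool inside(int x, int y) const {
    return x > -span && x < span && y > -span && y < span;
  }

  void add(int x, int y, long k1, long k2, int model) {
    int i = cells.add(k1, k2, model);
    xs.push_back(x);
    ys.push_back(y);
    grid[gidx(x, y)] = i + 1;
  }

  void remove(int i) {
    grid[gidx(xs[i], ys[i])] = 0;
    int moved = cells.remove(i);
    int last = (int) xs.size() - 1;
    if (moved >= 0) {
      xs[i] = xs[last];
      ys[i] = ys[last];
      grid[gidx(xs[i], ys[i])] = i + 1;
    }
    xs.pop_back();
    ys.pop_back();
  }

  // steps (>= 1) to the nearest empty site along ray `dir`, or 0 if none
  // within reach; q_inf lifts the range cap.
  int ray_steps(int x, int y, int dir, bool q_inf, int q) const {
    int t = 0;
    while (true) {
      ++t;
      if (!q_inf && t > q) return 0;
      int px = x + t * DX[dir], py = y + t * DY[dir];
      if (!inside(px, py))
        stop("tumor reached the lattice boundary; increase lattice_span");
      if (grid[gidx(px, py)] == 0) return t;
    }
  }

  // attempt division of mother m: pick a direction uniformly among those
  // whose nearest empty site lies within reach, push the contiguous run one
  // step outward, place the daughter adjacent to the mother, and apply
  // binomial (co)segregation.  Returns false if blocked.
  bool divide(int m, int model, double rho, bool q_inf, int q) {
    int elig[8], steps[8], ne = 0;
    int mx = xs[m], my = ys[m];
    for (int dir = 0; dir < 8; ++dir) {
      int t = ray_steps(mx, my, dir, q_inf, q);
      if (t > 0) {
        elig[ne] = dir;
        steps[ne] = t;
        ++ne;
      }
    }
    if (ne == 0) return false;
    int pick = unif_index(ne);
    int dir = elig[pick], t = steps[pick];
    for (int j = t; j >= 2; --j) { // shift run, farthest cell first
      int ox = mx + (j - 1) * DX[dir], oy = my + (j - 1) * DY[dir];
      int nx = mx + j * DX[dir], ny = my + j * DY[dir];
      int ci = grid[gidx(ox, oy)];
      grid[gidx(nx, ny)] = ci;
      grid[gidx(ox, oy)] = 0;
      xs[ci - 1] = nx;
      ys[ci - 1] = ny;
    }
    long a1, a2;
    long m1 = cells.c1[m], m2 = cells.c2[m];
    segregate_pair(m1, m2, rho, a1, a2);
    cells.c1[m] = a1;
    cells.c2[m] = a2;
    cells.tot1 += a1 - m1;
    cells.tot2 += a2 - m2;
    cells.set_class(m, fitness_class(model, a1, a2));
    // daughter gets the complementary share; with add()'s contribution the
    // population totals grow by exactly the mother's pre-division counts.
    add(mx + DX[dir], my + DY[dir], 2 * m1 - a1, 2 * m2 - a2, model);
    return true;
  }

  void check_integrity(int model) const {
    cells.check_integrity(model);
    for (int i = 0; i < (int) xs.size(); ++i)
      if (grid[gidx(xs[i], ys[i])] != i + 1)
        stop("occupancy map corrupted");
  }

  void check_grid_full(void) const {
    long occ = 0;
    for (size_t g = 0; g < grid.size(); ++g) occ += grid[g] != 0;
    if (occ != (long) xs.size())
      stop("occupied-site count does not match cell count");
  }
};

// Convert one wild-type copy to a variant copy, with each wt copy in the
// population equally likely to be the mutating one.
static bool convert_one_wt_copy(Cells &cells, int model) {
  double tot = (double) cells.tot1;
  if (tot <= 0) return false;
  double r = unif_rand() * tot;
  double acc = 0;
  int i = 0, n = cells.n();
  for (; i < n; ++i) {
    acc += (double) cells.c1[i];
    if (r < acc) break;
  }
  if (i >= n) i = n - 1;
  cells.c1[i] -= 1;
  cells.c2[i] += 1;
  cells.tot1 -= 1;
  cells.tot2 += 1;
  cells.set_class(i, fitness_class(model, cells.c1[i], cells.c2[i]));
  return true;
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_run_lattice(int k1, int k2, int model, double s_a, double s_b,
                     double rho, double d, bool q_inf, int q, int n_final,
                     int span, int vvar, bool check) {
  Lattice lat(span);
  lat.add(0, 0, k1, k2, model);
  const double rate[3] = {1.0, 1.0 + s_a, 1.0 + s_b};
  double time = 0;
  long blocked = 0, events = 0;
  bool pending = (model == 1 && vvar >= 1);
  int arrival_n = NA_INTEGER;
  if (pending && lat.cells.n() >= vvar) { // Vvar = 1: mutate at initiation
    if (convert_one_wt_copy(lat.cells, model)) arrival_n = lat.cells.n();
    pending = false;
  }

  while (lat.cells.n() > 0 && lat.cells.n() < n_final) {
    int kind, cls;
    double dt;
    pick_event(lat.cells.ncls, rate, d, lat.cells.n(), kind, cls, dt);
    time += dt;
    ++events;
    if (kind == 0) {
      int m = lat.cells.members[cls][unif_index((int) lat.cells.members[cls].size())];
      if (!lat.divide(m, model, rho, q_inf, q)) ++blocked;
    } else {
      lat.remove(unif_index(lat.cells.n()));
    }
    if (pending && lat.cells.n() >= vvar) {
      if (convert_one_wt_copy(lat.cells, model)) arrival_n = lat.cells.n();
      pending = false;
    }
    if (check) {
      lat.check_integrity(model);
      if (events % 512 == 0) lat.check_grid_full();
    }
    if (events % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  if (check && lat.cells.n() > 0) {
    lat.check_integrity(model);
    lat.check_grid_full();
  }

  int n = lat.cells.n();
  IntegerVector x(n), y(n), cc1(n), cc2(n);
  for (int i = 0; i < n; ++i) {
    x[i] = lat.xs[i];
    y[i] = lat.ys[i];
    cc1[i] = (int) lat.cells.c1[i];
    cc2[i] = (int) lat.cells.c2[i];
  }
  return List::create(
      _["x"] = x, _["y"] = y, _["copies1"] = cc1, _["copies2"] = cc2,
      _["time"] = time, _["n_cells"] = n, _["extinct"] = (n == 0),
      _["events"] = (double) events, _["blocked"] = (double) blocked,
      _["variant_arrival_n"] = arrival_n);
}

// [[Rcpp::export]]
List cpp_run_wellmixed(int k1, int k2, int model, double s_a, double s_b,
                       double rho, double d, int n_final, int vvar,
                       bool record_history, int passage_n0, int passage_g,
                       int passage_rounds, bool check) {
  Cells cells;
  cells.add(k1, k2, model);
  const double rate[3] = {1.0, 1.0 + s_a, 1.0 + s_b};
  double time = 0;
  long events = 0;
  bool pending = (model == 1 && vvar >= 1);
  int arrival_n = NA_INTEGER;
  if (pending && cells.n() >= vvar) {
    if (convert_one_wt_copy(cells, model)) arrival_n = cells.n();
    pending = false;
  }

  bool passaging = passage_n0 >= 1 && passage_g >= 1 && passage_rounds >= 1;
  long trigger = passaging ? ((long) passage_n0 << passage_g) : -1;
  int rounds_done = 0;

  std::vector<double> h_time, h_n, h_pos, h_sum1, h_sum2;
  auto record = [&]() {
    if (!record_history) return;
    h_time.push_back(time);
    h_n.push_back((double) cells.n());
    h_pos.push_back((double) (cells.n() - cells.ncls[0]));
    h_sum1.push_back((double) cells.tot1);
    h_sum2.push_back((double) cells.tot2);
  };
  record();

  while (cells.n() > 0) {
    if (passaging) {
      if (rounds_done >= passage_rounds) break;
      if (cells.n() >= trigger) {
        // subsample without replacement down to passage_n0 cells: partial
        // Fisher-Yates leaves a uniform subset in slots [0, passage_n0)
        int n = cells.n();
        for (int i = n - 1; i >= passage_n0; --i) {
          int j = unif_index(i + 1);
          if (j != i) {
            std::swap(cells.c1[i], cells.c1[j]);
            std::swap(cells.c2[i], cells.c2[j]);
          }
        }
        cells.c1.resize(passage_n0);
        cells.c2.resize(passage_n0);
        cells.cls.resize(passage_n0);
        cells.posc.resize(passage_n0);
        // rebuild class membership and totals from the surviving cells
        for (int c = 0; c < 3; ++c) cells.members[c].clear();
        cells.ncls[0] = cells.ncls[1] = cells.ncls[2] = 0;
        cells.tot1 = cells.tot2 = 0;
        for (int i = 0; i < cells.n(); ++i) {
          int c = fitness_class(model, cells.c1[i], cells.c2[i]);
          cells.cls[i] = c;
          cells.posc[i] = (int) cells.members[c].size();
          cells.members[c].push_back(i);
          cells.ncls[c]++;
          cells.tot1 += cells.c1[i];
          cells.tot2 += cells.c2[i];
        }
        ++rounds_done;
        record();
        continue;
      }
    } else if (cells.n() >= n_final) {
      break;
    }
    int kind, cls;
    double dt;
    pick_event(cells.ncls, rate, d, cells.n(), kind, cls, dt);
    time += dt;
    ++events;
    if (kind == 0) {
      int m = cells.members[cls][unif_index((int) cells.members[cls].size())];
      long a1, a2;
      long m1 = cells.c1[m], m2 = cells.c2[m];
      segregate_pair(m1, m2, rho, a1, a2);
      cells.c1[m] = a1;
      cells.c2[m] = a2;
      cells.tot1 += a1 - m1;
      cells.tot2 += a2 - m2;
      cells.set_class(m, fitness_class(model, a1, a2));
      cells.add(2 * m1 - a1, 2 * m2 - a2, model);
    } else {
      cells.remove(unif_index(cells.n()));
    }
    if (pending && cells.n() >= vvar) {
      if (convert_one_wt_copy(cells, model)) arrival_n = cells.n();
      pending = false;
    }
    record();
    if (check) cells.check_integrity(model);
    if (events % 65536 == 0) Rcpp::checkUserInterrupt();
  }

  int n = cells.n();
  IntegerVector cc1(n), cc2(n);
  for (int i = 0; i < n; ++i) {
    cc1[i] = (int) cells.c1[i];
    cc2[i] = (int) cells.c2[i];
  }
  return List::create(
      _["copies1"] = cc1, _["copies2"] = cc2, _["time"] = time,
      _["n_cells"] = n, _["extinct"] = (n == 0),
      _["events"] = (double) events,
      _["variant_arrival_n"] = arrival_n,
      _["history"] = List::create(
          _["time"] = h_time, _["n_cells"] = h_n, _["n_positive"] = h_pos,
          _["total_copies1"] = h_sum1, _["total_copies2"] = h_sum2));
}

// Per replicate: grow a wild-type-only population from one cell with k
// copies; every newly replicated copy mutates with probability mu.  The
// recorded value is the wild-type copy number of the cell that ends up
// carrying the first variant copy (founder convention: a mutation among the
// founder's k copies gives k - 1).  NA when no mutation occurs by n_final.
// [[Rcpp::export]]
IntegerVector cpp_mutation_origin(int k, double s, double mu, int n_final,
                                  int replicates) {
  IntegerVector out(replicates);
  const double rate[3] = {1.0, 1.0 + s, 1.0};
  for (int rep = 0; rep < replicates; ++rep) {
    if (mu > 0 && R::rbinom((double) k, mu) >= 1) {
      out[rep] = k - 1; // mutation at initiation
      continue;
    }
    Cells cells;
    cells.add(k, 0, 0);
    bool found = false;
    while (cells.n() < n_final && cells.n() > 0) {
      int kind, cls;
      double dt;
      pick_event(cells.ncls, rate, 0.0, cells.n(), kind, cls, dt);
      int m = cells.members[cls][unif_index((int) cells.members[cls].size())];
      long c = cells.c1[m];
      long nmut = (mu > 0 && c > 0) ? (long) R::rbinom((double) c, mu) : 0;
      if (nmut >= 1) {
        // first mutation: one of the 2c copies is the variant; the other
        // 2c - 1 wt copies split binomially, the variant follows a fair
        // coin; report the wt count of the daughter receiving the variant.
        long aw = (long) R::rbinom((double) (2 * c - 1), 0.5);
        bool varA = unif_rand() < 0.5;
        out[rep] = (int) (varA ? aw : (2 * c - 1 - aw));
        found = true;
        break;
      }
      long a = (long) R::rbinom((double) (2 * c), 0.5);
      cells.c1[m] = a;
      cells.tot1 += a - c;
      cells.set_class(m, fitness_class(0, a, 0));
      cells.add(2 * c - a, 0, 0);
    }
    if (!found) out[rep] = NA_INTEGER;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// ---------------------------------------------------------------------------
// Small exported hooks so the unit-level operations can be exercised on the
// same code paths the engines use.

// [[Rcpp::export]]
IntegerMatrix cpp_segregate(int copies, int n) {
  if (copies < 0) stop("copy count must be non-negative");
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    long a1, a2;
    segregate_pair(copies, 0, 0.0, a1, a2);
    out(i, 0) = (int) a1;
    out(i, 1) = (int) (2L * copies - a1);
    (void) a2;
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_cosegregate(int c1, int c2, double rho, int n) {
  if (c1 < 0 || c2 < 0) stop("copy counts must be non-negative");
  IntegerMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    long a1, a2;
    segregate_pair(c1, c2, rho, a1, a2);
    out(i, 0) = (int) a1;
    out(i, 1) = (int) a2;
    out(i, 2) = (int) (2L * c1 - a1);
    out(i, 3) = (int) (2L * c2 - a2);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_pick_events(double n0, double n1, double n2, double s_a,
                              double s_b, double d, int ndraws) {
  const double rate[3] = {1.0, 1.0 + s_a, 1.0 + s_b};
  long ncls[3] = {(long) n0, (long) n1, (long) n2};
  long n = ncls[0] + ncls[1] + ncls[2];
  NumericMatrix out(ndraws, 3);
  for (int i = 0; i < ndraws; ++i) {
    int kind, cls;
    double dt;
    pick_event(ncls, rate, d, n, kind, cls, dt);
    out(i, 0) = kind;
    out(i, 1) = cls;
    out(i, 2) = dt;
  }
  colnames(out) = CharacterVector::create("kind", "class", "dt");
  return out;
}

// Eligible division directions for cell `mother` (1-based) in an occupancy
// snapshot given as coordinate vectors.  Returns the 1-based direction ids
// and the ray distance to the nearest empty site for each.
// [[Rcpp::export]]
List cpp_eligible_directions(IntegerVector xs, IntegerVector ys, int mother,
                             bool q_inf, int q, int span) {
  Lattice lat(span);
  for (int i = 0; i < xs.size(); ++i) {
    if (!lat.inside(xs[i], ys[i])) stop("coordinate outside lattice");
    if (lat.grid[lat.gidx(xs[i], ys[i])] != 0)
      stop("duplicate occupied site");
    lat.add(xs[i], ys[i], 1, 0, 0);
  }
  int m = mother - 1;
  std::vector<int> dirs, steps;
  for (int dir = 0; dir < 8; ++dir) {
    int t = lat.ray_steps(lat.xs[m], lat.ys[m], dir, q_inf, q);
    if (t > 0) {
      dirs.push_back(dir + 1);
      steps.push_back(t);
    }
  }
  return List::create(_["direction"] = wrap(dirs), _["steps"] = wrap(steps),
                      _["dx"] = IntegerVector(DX, DX + 8),
                      _["dy"] = IntegerVector(DY, DY + 8));
}
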