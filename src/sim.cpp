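#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Core of the colony simulation. All stochastic draws come from R's RNG
// (unif_rand), so set.seed() at the R level makes every run bit-reproducible.
// The exported single-ant helpers below wrap the same internal routines the
// full run uses, so tests exercise the production code path.

namespace {

struct Arena {
  int width, total_rows, cache_row, drop_row, nest_col, nest_row;
};

enum Goal { TO_FORAGE = 0, TO_NEST = 1, TO_LEAF = 2, TO_FORAGE_CELL = 3 };

struct Ant {
  int col, row;
  bool carrying;
  int goal;
  int tcol, trow;  // target cell for TO_LEAF / TO_FORAGE_CELL, else -1
  bool scan;       // false after declining a pick-up, until next state change
};

struct Events {
  int cut, dropped, picked, delivered;
};

// uniform integer in [0, n)
int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

bool bern(double p) { return unif_rand() < p; }

inline int sgn(int x) { return (x > 0) - (x < 0); }

// nearest occupied cache cell within Chebyshev radius; ties uniform at random
int detect_leaf_col(int col, int row, const std::vector<int>& cache,
                    int cache_row, int radius) {
  int dr = row >= cache_row ? row - cache_row : cache_row - row;
  if (dr > radius) return -1;
  int best = INT_MAX;
  std::vector<int> ties;
  for (int c = 0; c < (int)cache.size(); ++c) {
    if (cache[c] < 1) continue;
    int dc = col >= c ? col - c : c - col;
    int d = dc > dr ? dc : dr;
    if (d > radius) continue;
    if (d < best) {
      best = d;
      ties.clear();
      ties.push_back(c);
    } else if (d == best) {
      ties.push_back(c);
    }
  }
  if (ties.empty()) return -1;
  if (ties.size() == 1) return ties[0];
  return ties[runif_int((int)ties.size())];
}

// one cell along the discrete straight line to the target (path integration)
void greedy_step(int& col, int& row, int tcol, int trow) {
  col += sgn(tcol - col);
  row += sgn(trow - row);
}

// uniform draw over the in-bounds subset of {forward, two forward diagonals,
// left, right}; forward is up for ascent, down for descent (olfactory noise)
void random_step(int& col, int& row, bool upward, const Arena& ar) {
  int dr = upward ? 1 : -1;
  int cand[5][2] = {{col, row + dr},
                    {col - 1, row + dr},
                    {col + 1, row + dr},
                    {col - 1, row},
                    {col + 1, row}};
  int ok[5], n = 0;
  for (int i = 0; i < 5; ++i) {
    if (cand[i][0] >= 0 && cand[i][0] < ar.width && cand[i][1] >= 0 &&
        cand[i][1] < ar.total_rows)
      ok[n++] = i;
  }
  if (n == 0) return;
  int pick = ok[runif_int(n)];
  col = cand[pick][0];
  row = cand[pick][1];
}

// taken at the drop row on the way up: forage (pick a random canopy cell to
// cut at) with probability forage_prob, else climb back down empty
void forage_decision(Ant& a, const Arena& ar, double forage_prob) {
  if (bern(forage_prob)) {
    a.goal = TO_FORAGE_CELL;
    a.tcol = runif_int(ar.width);
    a.trow = ar.drop_row + 1 + runif_int(ar.total_rows - ar.drop_row - 1);
  } else {
    a.goal = TO_NEST;
    a.tcol = a.trow = -1;
  }
  a.scan = true;
}

// scan the cache; on detection draw the pick-up Bernoulli once: accept sets
// a leaf target, decline commits to TO_FORAGE and stops scanning
void scan_for_leaf(Ant& a, const std::vector<int>& cache, const Arena& ar,
                   double pp, int radius) {
  int c = detect_leaf_col(a.col, a.row, cache, ar.cache_row, radius);
  if (c < 0) return;
  if (bern(pp)) {
    a.goal = TO_LEAF;
    a.tcol = c;
    a.trow = ar.cache_row;
  } else {
    a.goal = TO_FORAGE;
    a.tcol = a.trow = -1;
    a.scan = false;
  }
}

// One activation of one ant. Leaf manipulations (picking up, cutting,
// dropping, delivering) are handling actions that consume the whole
// activation: the ant acts instead of moving on that timestep. Decisions
// (the pick-up, drop and forage Bernoullis) are instantaneous.
void ant_step(Ant& a, std::vector<int>& cache, const Arena& ar, double pp,
              double pd, double forage_prob, int radius, Events& ev) {
  // handling actions at the current cell
  if (a.carrying) {
    if (a.col == ar.nest_col && a.row == ar.nest_row) {
      a.carrying = false;  // deliver the leaf at the nest
      a.goal = TO_FORAGE;
      a.scan = true;
      ev.delivered += 1;
      return;
    }
    if (a.row == ar.drop_row) {
      // just entered the drop row from above: draw the drop Bernoulli once
      if (bern(pd)) {
        cache[a.col] += 1;  // leaf falls into the cache row, same column
        a.carrying = false;
        a.goal = TO_FORAGE;
        a.scan = true;
        ev.dropped += 1;
        return;
      }
      // declined: keep carrying and continue down (moves this activation)
    }
  } else if (a.goal == TO_LEAF && a.col == a.tcol && a.row == a.trow) {
    if (cache[a.tcol] > 0) {
      cache[a.tcol] -= 1;  // pick the leaf up
      a.carrying = true;
      a.goal = TO_NEST;
      a.tcol = a.trow = -1;
      a.scan = true;
      ev.picked += 1;
      return;
    }
    // another ant got there first: rescan from scratch below
    a.goal = TO_FORAGE;
    a.tcol = a.trow = -1;
    a.scan = true;
  } else if (a.goal == TO_FORAGE_CELL && a.col == a.tcol && a.row == a.trow) {
    a.carrying = true;  // cut a leaf; canopy supply is unlimited
    a.goal = TO_NEST;
    a.tcol = a.trow = -1;
    ev.cut += 1;
    return;
  }

  // pre-move decisions
  if (!a.carrying && a.goal == TO_FORAGE && a.row >= ar.drop_row)
    forage_decision(a, ar, forage_prob);
  if (!a.carrying && a.scan && a.row == ar.cache_row &&
      (a.goal == TO_FORAGE || a.goal == TO_NEST))
    scan_for_leaf(a, cache, ar, pp, radius);

  // movement: one cell per timestep
  if (a.carrying) {
    greedy_step(a.col, a.row, ar.nest_col, ar.nest_row);
  } else if (a.goal == TO_LEAF || a.goal == TO_FORAGE_CELL) {
    greedy_step(a.col, a.row, a.tcol, a.trow);
  } else {
    random_step(a.col, a.row, a.goal == TO_FORAGE, ar);
  }

  if (!a.carrying && a.goal == TO_NEST && a.row < ar.cache_row) {
    a.goal = TO_FORAGE;  // reached the ground empty: head back up
    a.scan = true;
  }
}

Arena arena_from_list(const List& arena) {
  Arena ar;
  ar.width = as<int>(arena["width"]);
  ar.total_rows = as<int>(arena["total_rows"]);
  ar.cache_row = as<int>(arena["cache_row"]);
  ar.drop_row = as<int>(arena["drop_row"]);
  IntegerVector nest = arena["nest_cell"];
  ar.nest_col = nest[0];
  ar.nest_row = nest[1];
  return ar;
}

}  // namespace

// [[Rcpp::export]]
List run_colony_cpp(int n_ants, int t_max, int width, int total_rows,
                    int cache_row, int drop_row, int nest_col, int nest_row,
                    double pp, double pd, double forage_prob, int radius) {
  Arena ar{width, total_rows, cache_row, drop_row, nest_col, nest_row};
  std::vector<Ant> ants(n_ants);
  for (int i = 0; i < n_ants; ++i) {
    ants[i].col = runif_int(width);
    ants[i].row = runif_int(total_rows);
    ants[i].carrying = false;
    ants[i].goal = TO_FORAGE;
    ants[i].tcol = ants[i].trow = -1;
    ants[i].scan = true;
  }
  std::vector<int> cache(width, 0);
  Events ev{0, 0, 0, 0};
  IntegerMatrix occ(t_max, 3);
  IntegerVector cache_series(t_max), w_series(t_max), cut_series(t_max),
      carried_series(t_max);
  std::vector<int> order(n_ants);
  for (int i = 0; i < n_ants; ++i) order[i] = i;

  for (int t = 0; t < t_max; ++t) {
    // fresh random activation order every timestep (Fisher-Yates)
    for (int i = n_ants - 1; i > 0; --i) {
      int j = runif_int(i + 1);
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < n_ants; ++k)
      ant_step(ants[order[k]], cache, ar, pp, pd, forage_prob, radius, ev);

    // record after all ants have moved
    int ground = 0, tree = 0, canopy = 0, carried = 0, ctot = 0;
    for (int i = 0; i < n_ants; ++i) {
      if (ants[i].row <= cache_row)
        ++ground;
      else if (ants[i].row >= drop_row)
        ++canopy;
      else
        ++tree;
      if (ants[i].carrying) ++carried;
    }
    for (int c = 0; c < width; ++c) ctot += cache[c];
    occ(t, 0) = ground;
    occ(t, 1) = tree;
    occ(t, 2) = canopy;
    cache_series[t] = ctot;
    w_series[t] = ev.delivered;
    cut_series[t] = ev.cut;
    carried_series[t] = carried;
  }

  return List::create(
      _["W"] = ev.delivered, _["cut"] = ev.cut, _["dropped"] = ev.dropped,
      _["picked_up"] = ev.picked, _["occupancy"] = occ,
      _["cache_series"] = cache_series, _["w_series"] = w_series,
      _["cut_series"] = cut_series, _["carried_series"] = carried_series);
}

// [[Rcpp::export]]
IntegerVector greedy_step_cpp(IntegerVector pos, IntegerVector target) {
  int col = pos[0], row = pos[1];
  greedy_step(col, row, target[0], target[1]);
  return IntegerVector::create(col, row);
}

// [[Rcpp::export]]
IntegerVector random_step_cpp(IntegerVector pos, bool upward, int width,
                              int total_rows) {
  Arena ar{width, total_rows, 0, 0, 0, 0};
  int col = pos[0], row = pos[1];
  random_step(col, row, upward, ar);
  return IntegerVector::create(col, row);
}

// [[Rcpp::export]]
int detect_leaf_cpp(IntegerVector pos, IntegerVector cache, int cache_row,
                    int radius) {
  std::vector<int> cv(cache.begin(), cache.end());
  return detect_leaf_col(pos[0], pos[1], cv, cache_row, radius);
}

// [[Rcpp::export]]
List transition_cpp(List state, List arena, IntegerVector cache, List params) {
  Arena ar = arena_from_list(arena);
  Ant a;
  IntegerVector pos = state["pos"];
  a.col = pos[0];
  a.row = pos[1];
  a.carrying = as<bool>(state["carrying"]);
  a.goal = as<int>(state["goal"]);
  if (state.containsElementNamed("target") &&
      !Rf_isNull(state["target"])) {
    IntegerVector tg = state["target"];
    a.tcol = tg[0];
    a.trow = tg[1];
  } else {
    a.tcol = a.trow = -1;
  }
  a.scan = state.containsElementNamed("scan") ? as<bool>(state["scan"]) : true;
  if (a.carrying && a.goal != TO_NEST)
    stop("inconsistent ant state: carrying but goal is not TO_NEST");

  std::vector<int> cv(cache.begin(), cache.end());
  Events ev{0, 0, 0, 0};
  double pp = as<double>(params["pickup_prob"]);
  double pd = as<double>(params["drop_prob"]);
  double fp = as<double>(params["forage_prob"]);
  int radius = as<int>(params["detection_radius"]);
  ant_step(a, cv, ar, pp, pd, fp, radius, ev);

  List st = List::create(
      _["pos"] = IntegerVector::create(a.col, a.row),
      _["carrying"] = a.carrying, _["goal"] = a.goal,
      _["target"] = a.tcol < 0
                        ? R_NilValue
                        : (SEXP)IntegerVector::create(a.tcol, a.trow),
      _["scan"] = a.scan);
  return List::create(
      _["state"] = st, _["cache"] = IntegerVector(cv.begin(), cv.end()),
      _["events"] = List::create(_["cut"] = ev.cut, _["dropped"] = ev.dropped,
                                 _["picked_up"] = ev.picked,
                                 _["delivered"] = ev.delivered));
}
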