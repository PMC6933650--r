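#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Simulated-annealing kernel over subsets of candidate match edges.
//
// The objective f(A) sums, over every connected component (matchset) of the
// selected-edge graph, the combined pair score
//   alpha * s_h(i,j) + (1-alpha) * exp(-||F_i - F_j||^2 / 2)
// over all unordered pairs inside the component. Only the partition into
// components matters, so the score change of a move is the sum of
// cross-component pair scores gained (merge) or lost (split).
//
// All randomness comes from R's RNG (unif_rand), so set.seed() in R gives
// bit-identical trajectories.

namespace {

struct Instance {
  int n_nodes, n_cand, cap;
  double alpha;
  std::vector<int> cu, cv;                 // candidate endpoints (0-based)
  std::vector<double> feat;                // n_nodes x 5, row-major
  std::unordered_map<long long, double> sh;

  double pair_score(int i, int j) const {
    const double *a = &feat[5 * i], *b = &feat[5 * j];
    double d2 = 0.0;
    for (int t = 0; t < 5; ++t) {
      double d = a[t] - b[t];
      d2 += d * d;
    }
    double st = std::exp(-0.5 * d2);
    long long key = (long long)std::min(i, j) * n_nodes + std::max(i, j);
    auto it = sh.find(key);
    double h = (it == sh.end()) ? 0.0 : it->second;
    return alpha * h + (1.0 - alpha) * st;
  }
};

struct State {
  const Instance &ins;
  std::vector<char> sel;
  std::vector<std::vector<int>> adj;  // node -> selected candidate indices
  std::vector<int> sel_list, unsel_list, pos;  // O(1) uniform sampling
  std::vector<int> mark;
  int stamp;

  explicit State(const Instance &I)
      : ins(I), sel(I.n_cand, 0), adj(I.n_nodes),
        pos(I.n_cand), mark(I.n_nodes, -1), stamp(0) {
    unsel_list.reserve(I.n_cand);
    for (int e = 0; e < I.n_cand; ++e) {
      unsel_list.push_back(e);
      pos[e] = e;
    }
  }

  void list_move(std::vector<int> &from, std::vector<int> &to, int e) {
    int p = pos[e];
    int last = from.back();
    from[p] = last;
    pos[last] = p;
    from.pop_back();
    pos[e] = (int)to.size();
    to.push_back(e);
  }

  void add_edge(int e) {
    sel[e] = 1;
    list_move(unsel_list, sel_list, e);
    adj[ins.cu[e]].push_back(e);
    adj[ins.cv[e]].push_back(e);
  }

  void remove_edge(int e) {
    sel[e] = 0;
    list_move(sel_list, unsel_list, e);
    for (int node : {ins.cu[e], ins.cv[e]}) {
      auto &a = adj[node];
      for (size_t i = 0; i < a.size(); ++i) {
        if (a[i] == e) {
          a[i] = a.back();
          a.pop_back();
          break;
        }
      }
    }
  }

  // connected component of `start` in the selected-edge graph, optionally
  // treating edge `skip` as absent; components are small in practice
  std::vector<int> component(int start, int skip) {
    ++stamp;
    std::vector<int> comp{start};
    mark[start] = stamp;
    for (size_t h = 0; h < comp.size(); ++h) {
      int node = comp[h];
      for (int e : adj[node]) {
        if (e == skip) continue;
        int other = ins.cu[e] == node ? ins.cv[e] : ins.cu[e];
        if (mark[other] != stamp) {
          mark[other] = stamp;
          comp.push_back(other);
        }
      }
    }
    return comp;
  }

  double cross_score(const std::vector<int> &a, const std::vector<int> &b) {
    double s = 0.0;
    for (int i : a)
      for (int j : b) s += ins.pair_score(i, j);
    return s;
  }

  // delta of adding e; feasible=false when a matchset-size cap is violated
  double delta_add(int e, bool &feasible) {
    feasible = true;
    std::vector<int> comp_u = component(ins.cu[e], -1);
    for (int x : comp_u)
      if (x == ins.cv[e]) return 0.0;  // same component already
    std::vector<int> comp_v = component(ins.cv[e], -1);
    if (ins.cap > 0 &&
        (int)(comp_u.size() + comp_v.size()) > ins.cap) {
      feasible = false;
      return 0.0;
    }
    return cross_score(comp_u, comp_v);
  }

  double delta_remove(int e) {
    std::vector<int> comp_u = component(ins.cu[e], e);
    for (int x : comp_u)
      if (x == ins.cv[e]) return 0.0;  // parallel path keeps it connected
    std::vector<int> comp_v = component(ins.cv[e], e);
    return -cross_score(comp_u, comp_v);
  }

  int sample_from(const std::vector<int> &list) {
    int i = (int)(unif_rand() * list.size());
    if (i >= (int)list.size()) i = (int)list.size() - 1;
    return list[i];
  }
};

}  // namespace

// [[Rcpp::export]]
List anneal_cpp(IntegerVector cand_u, IntegerVector cand_v,
                NumericVector cand_sh, NumericMatrix feat, double alpha,
                int cap, double t0, double cooling, int steps, int levels,
                double s_const, int patience) {
  Instance ins;
  ins.n_nodes = feat.nrow();
  ins.n_cand = cand_u.size();
  ins.cap = cap;
  ins.alpha = alpha;
  ins.cu.assign(cand_u.begin(), cand_u.end());
  ins.cv.assign(cand_v.begin(), cand_v.end());
  ins.feat.resize(5 * ins.n_nodes);
  for (int i = 0; i < ins.n_nodes; ++i)
    for (int t = 0; t < 5; ++t) ins.feat[5 * i + t] = feat(i, t);
  for (int e = 0; e < ins.n_cand; ++e) {
    int a = std::min(ins.cu[e], ins.cv[e]);
    int b = std::max(ins.cu[e], ins.cv[e]);
    ins.sh[(long long)a * ins.n_nodes + b] = cand_sh[e];
  }

  State st(ins);
  double cur_f = 0.0, best_f = 0.0;
  std::vector<char> best_sel(ins.n_cand, 0);

  std::vector<double> cur_trace, best_trace, acc_trace;
  double best_prev = 0.0;
  int stall = 0, levels_run = 0;

  for (int level = 0; level < levels; ++level) {
    double ti = t0 * std::pow(cooling, level);
    int accepted = 0;
    for (int step = 0; step < steps; ++step) {
      int n_sel = (int)st.sel_list.size();
      int n_unsel = (int)st.unsel_list.size();
      double r = unif_rand();
      int type = r < 0.45 ? 0 : (r < 0.90 ? 1 : 2);  // add / remove / swap
      if (type == 0 && n_unsel == 0) type = 1;
      if (type == 1 && n_sel == 0) type = 0;
      if (type == 2) {
        if (n_sel == 0) type = 0;
        else if (n_unsel == 0) type = 1;
      }

      bool accept = false;
      double total = 0.0;
      if (type == 0) {
        int e = st.sample_from(st.unsel_list);
        bool feasible;
        total = st.delta_add(e, feasible);
        if (feasible &&
            (total >= 0 || unif_rand() < std::exp(total / (ti * s_const)))) {
          st.add_edge(e);
          accept = true;
        }
      } else if (type == 1) {
        int e = st.sample_from(st.sel_list);
        total = st.delta_remove(e);
        if (total >= 0 || unif_rand() < std::exp(total / (ti * s_const))) {
          st.remove_edge(e);
          accept = true;
        }
      } else {
        int e_rm = st.sample_from(st.sel_list);
        int e_ad = st.sample_from(st.unsel_list);
        double d1 = st.delta_remove(e_rm);
        st.remove_edge(e_rm);
        bool feasible;
        double d2 = st.delta_add(e_ad, feasible);
        if (!feasible) {
          st.add_edge(e_rm);  // revert
        } else {
          st.add_edge(e_ad);
          total = d1 + d2;
          if (total >= 0 || unif_rand() < std::exp(total / (ti * s_const))) {
            accept = true;
          } else {
            st.remove_edge(e_ad);
            st.add_edge(e_rm);
          }
        }
      }

      if (accept) {
        ++accepted;
        cur_f += total;
        if (cur_f > best_f + 1e-12) {
          best_f = cur_f;
          best_sel = st.sel;
        }
      }
    }
    cur_trace.push_back(cur_f);
    best_trace.push_back(best_f);
    acc_trace.push_back((double)accepted / steps);
    ++levels_run;
    if (best_f <= best_prev + 1e-12) {
      if (++stall >= patience) break;
    } else {
      stall = 0;
    }
    best_prev = best_f;
  }

  IntegerVector final_sel, best_out;
  for (int e = 0; e < ins.n_cand; ++e) {
    if (st.sel[e]) final_sel.push_back(e + 1);
    if (best_sel[e]) best_out.push_back(e + 1);
  }
  return List::create(
      _["best_selected"] = best_out, _["final_selected"] = final_sel,
      _["best_score"] = best_f, _["final_score"] = cur_f,
      _["current_trace"] = NumericVector(cur_trace.begin(), cur_trace.end()),
      _["best_trace"] = NumericVector(best_trace.begin(), best_trace.end()),
      _["accept_trace"] = NumericVector(acc_trace.begin(), acc_trace.end()),
      _["levels_run"] = levels_run);
}
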