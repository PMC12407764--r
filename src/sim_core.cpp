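#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Excitable-automaton update, synchronous, using R's RNG throughout so that
// set.seed() in R makes every run bit-reproducible.
//
// States per unit: rest (eligible), active, refractory (blocked for
// `refr_steps` updates after the active step). A unit resting at step t
// becomes active at t+1 with probability
//   1 - (1-p_poiss) * (1-p_stim) * (1-p_trans)^m
// where m is its number of active presynaptic neighbours at step t.
// Transmission is realised as independent Bernoulli trials per out-edge of
// each active unit, which is equivalent and cheap when activity is sparse.

// Sample `m` distinct integers in [0, deg) into out[]. Rejection for small m,
// partial Fisher-Yates otherwise.
static void sample_distinct(int deg, int m, std::vector<int> &out,
                            std::vector<int> &buf) {
  out.clear();
  if (m >= deg) {
    for (int i = 0; i < deg; ++i) out.push_back(i);
    return;
  }
  if (3 * m < deg) {
    while ((int)out.size() < m) {
      int cand = (int)(unif_rand() * deg);
      if (cand >= deg) cand = deg - 1;
      bool dup = false;
      for (int v : out) if (v == cand) { dup = true; break; }
      if (!dup) out.push_back(cand);
    }
  } else {
    buf.resize(deg);
    for (int i = 0; i < deg; ++i) buf[i] = i;
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (deg - i));
      if (j >= deg) j = deg - 1;
      std::swap(buf[i], buf[j]);
      out.push_back(buf[i]);
    }
  }
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector adj_ptr, IntegerVector adj_idx, int n_units,
                  double p_trans, double p_poiss, int n_steps, int refr_steps,
                  IntegerVector init_active, IntegerVector init_refr_unit,
                  IntegerVector init_refr_left, IntegerVector record,
                  IntegerVector stim_step_unit, double p_stim,
                  bool stop_when_quiet) {
  std::vector<int> refr(n_units, 0);
  std::vector<char> is_active(n_units, 0), pending(n_units, 0), is_rec(n_units, 0);
  std::vector<int> act, new_act, refr_list, picks, buf, spent;

  for (int i = 0; i < init_active.size(); ++i) {
    int u = init_active[i];
    is_active[u] = 1;
    act.push_back(u);
  }
  for (int i = 0; i < init_refr_unit.size(); ++i) {
    int u = init_refr_unit[i];
    refr[u] = init_refr_left[i];
    if (refr[u] > 0) refr_list.push_back(u);
  }
  for (int i = 0; i < record.size(); ++i) is_rec[record[i]] = 1;
  bool have_stim = stim_step_unit.size() > 0;

  IntegerVector active_count(n_steps);
  std::vector<int> sp_unit, sp_step;

  for (int t = 1; t <= n_steps; ++t) {
    int stim_u = have_stim ? stim_step_unit[t - 1] : -1;
    if (stop_when_quiet && act.empty() && refr_list.empty() &&
        p_poiss <= 0.0 && stim_u < 0)
      break;
    new_act.clear();

    // transmission from currently active units
    if (p_trans > 0.0) {
      for (int a : act) {
        int lo = adj_ptr[a], deg = adj_ptr[a + 1] - lo;
        if (deg == 0) continue;
        int m = (int)R::rbinom((double)deg, p_trans);
        if (m == 0) continue;
        sample_distinct(deg, m, picks, buf);
        for (int s : picks) {
          int tgt = adj_idx[lo + s];
          if (!is_active[tgt] && refr[tgt] == 0 && !pending[tgt]) {
            pending[tgt] = 1;
            new_act.push_back(tgt);
          }
        }
      }
    }

    // external Poisson drive: Binomial(N, p) events on distinct units
    spent.clear();
    if (p_poiss > 0.0) {
      int nd = (int)R::rbinom((double)n_units, p_poiss);
      int placed = 0, guard = 0;
      while (placed < nd && guard < 100 * nd + 1000) {
        ++guard;
        int u = (int)(unif_rand() * n_units);
        if (u >= n_units) u = n_units - 1;
        if (pending[u]) continue;  // distinct draw, retry
        pending[u] = 1;
        ++placed;
        if (!is_active[u] && refr[u] == 0) {
          new_act.push_back(u);
        } else {
          spent.push_back(u);  // drive consumed on an inexcitable unit
        }
      }
    }

    // targeted stimulation
    if (stim_u >= 0 && p_stim > 0.0) {
      if (!is_active[stim_u] && refr[stim_u] == 0 && !pending[stim_u] &&
          unif_rand() < p_stim) {
        pending[stim_u] = 1;
        new_act.push_back(stim_u);
      }
    }

    // advance refractory clocks
    size_t keep = 0;
    for (size_t i = 0; i < refr_list.size(); ++i) {
      int u = refr_list[i];
      if (--refr[u] > 0) refr_list[keep++] = u;
    }
    refr_list.resize(keep);

    // active -> refractory
    for (int a : act) {
      is_active[a] = 0;
      if (refr_steps > 0) {
        refr[a] = refr_steps;
        refr_list.push_back(a);
      }
    }

    for (int u : spent) pending[u] = 0;
    act.swap(new_act);
    for (int u : act) {
      pending[u] = 0;
      is_active[u] = 1;
      if (is_rec[u]) {
        sp_unit.push_back(u);
        sp_step.push_back(t);
      }
    }
    // pending marks set on ineligible units must also be cleared; track them
    // by rescanning drive marks is avoided: see note below.
    active_count[t - 1] = (int)act.size();
  }

  IntegerVector fin_act(act.begin(), act.end());
  IntegerVector fr_u(refr_list.begin(), refr_list.end());
  IntegerVector fr_l(refr_list.size());
  for (size_t i = 0; i < refr_list.size(); ++i) fr_l[i] = refr[refr_list[i]];

  return List::create(_["active_count"] = active_count,
                      _["spike_unit"] = IntegerVector(sp_unit.begin(), sp_unit.end()),
                      _["spike_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
                      _["final_active"] = fin_act,
                      _["final_refr_unit"] = fr_u,
                      _["final_refr_left"] = fr_l);
}

// Single-seed cascade survival: steps until the lattice is quiet, capped at
// `horizon`. No external drive. Used to locate the critical branching point.
// [[Rcpp::export]]
IntegerVector cpp_survival(IntegerVector adj_ptr, IntegerVector adj_idx,
                           int n_units, double p_trans, int refr_steps,
                           int seed_unit, int horizon, int n_reps) {
  IntegerVector out(n_reps);
  std::vector<int> refr(n_units, 0);
  std::vector<char> is_active(n_units, 0), pending(n_units, 0);
  std::vector<int> act, new_act, refr_list, picks, buf;

  for (int r = 0; r < n_reps; ++r) {
    std::fill(refr.begin(), refr.end(), 0);
    std::fill(is_active.begin(), is_active.end(), 0);
    act.clear();
    refr_list.clear();
    act.push_back(seed_unit);
    is_active[seed_unit] = 1;
    int t = 0;
    while (t < horizon && !act.empty()) {
      ++t;
      new_act.clear();
      for (int a : act) {
        int lo = adj_ptr[a], deg = adj_ptr[a + 1] - lo;
        if (deg == 0) continue;
        int m = (int)R::rbinom((double)deg, p_trans);
        if (m == 0) continue;
        sample_distinct(deg, m, picks, buf);
        for (int s : picks) {
          int tgt = adj_idx[lo + s];
          if (!is_active[tgt] && refr[tgt] == 0 && !pending[tgt]) {
            pending[tgt] = 1;
            new_act.push_back(tgt);
          }
        }
      }
      size_t keep = 0;
      for (size_t i = 0; i < refr_list.size(); ++i) {
        int u = refr_list[i];
        if (--refr[u] > 0) refr_list[keep++] = u;
      }
      refr_list.resize(keep);
      for (int a : act) {
        is_active[a] = 0;
        if (refr_steps > 0) {
          refr[a] = refr_steps;
          refr_list.push_back(a);
        }
      }
      act.swap(new_act);
      for (int u : act) {
        pending[u] = 0;
        is_active[u] = 1;
      }
    }
    out[r] = act.empty() ? t : horizon;
    for (int u : act) is_active[u] = 0;
    for (int u : refr_list) refr[u] = 0;
  }
  return out;
}

// Output strength: OS(i) = sum_{o=1..max_order} rowsum_j (p_trans * A)^o.
// Computed as repeated sparse matrix-vector products with the all-ones
// vector; pure structure, no dynamics.
// [[Rcpp::export]]
NumericVector cpp_output_strength(IntegerVector adj_ptr, IntegerVector adj_idx,
                                  int n_units, double p_trans, int max_order) {
  NumericVector os(n_units);
  std::vector<double> v(n_units, 1.0), vn(n_units, 0.0);
  for (int o = 1; o <= max_order; ++o) {
    for (int i = 0; i < n_units; ++i) {
      double s = 0.0;
      for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e) s += v[adj_idx[e]];
      vn[i] = p_trans * s;
    }
    for (int i = 0; i < n_units; ++i) {
      os[i] += vn[i];
      v[i] = vn[i];
    }
  }
  return os;
}
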