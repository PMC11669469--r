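// Single nearest-neighbour matching with replacement over quarter-grid
// covariates (binary indicators plus a 0..4 ordinal score), as used by the
// moderation-effect estimator. Covariates arrive as integers on a x4 scale
// (binary columns hold {0,4}, the score column 0..4), so distances are exact
// integer arithmetic:
//   L1  ("hamming"):  4 * popcount(xor of binary coords) + sum |a - b|
//   L2^2("euclidean"): 16 * popcount + sum (a - b)^2
// both on the x4 (resp. x16) scale. Ties break to the lowest pool position.
// Binary coordinates are packed into a 64-bit word; when the whole profile
// fits in 64 bits an exact-match hash gives O(1) hits, with an early-exit
// linear scan as fallback.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

struct PackedCohort {
  std::vector<uint64_t> bits;              // packed binary coords, per row
  std::vector<std::vector<int>> resid;     // non-binary coords, per row
  std::vector<uint64_t> key;               // exact profile key (if keyable)
  bool keyable;
  int n_bin;
};

static std::vector<bool> find_binary_cols(const IntegerMatrix& X) {
  int n = X.nrow(), p = X.ncol();
  std::vector<bool> bin(p, true);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      int v = X(i, j);
      if (v != 0 && v != 4) { bin[j] = false; break; }
    }
  }
  return bin;
}

static PackedCohort pack_rows(const IntegerMatrix& X,
                              const std::vector<bool>& bin) {
  int n = X.nrow(), p = X.ncol();
  PackedCohort pc;
  pc.n_bin = 0;
  for (int j = 0; j < p; ++j) if (bin[j]) ++pc.n_bin;
  int n_res = p - pc.n_bin;
  if (pc.n_bin > 64) stop("more than 64 binary covariates are not supported");
  pc.keyable = (pc.n_bin + 3 * n_res) <= 64;
  pc.bits.assign(n, 0);
  pc.resid.assign(n, std::vector<int>(n_res));
  if (pc.keyable) pc.key.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    uint64_t b = 0, k = 0;
    int bpos = 0, rpos = 0;
    for (int j = 0; j < p; ++j) {
      if (bin[j]) {
        if (X(i, j) == 4) b |= (uint64_t(1) << bpos);
        ++bpos;
      } else {
        pc.resid[i][rpos++] = X(i, j);
      }
    }
    pc.bits[i] = b;
    if (pc.keyable) {
      k = b;
      for (int r = 0; r < n_res; ++r) {
        k |= (uint64_t(pc.resid[i][r] & 7) << (pc.n_bin + 3 * r));
      }
      pc.key[i] = k;
    }
  }
  return pc;
}

static inline int pair_dist(const PackedCohort& pc, int i, int j, int metric,
                            int resid_weight) {
  int d = popcount64(pc.bits[i] ^ pc.bits[j]) * (metric == 0 ? 4 : 16);
  const std::vector<int>& ri = pc.resid[i];
  const std::vector<int>& rj = pc.resid[j];
  for (size_t r = 0; r < ri.size(); ++r) {
    int dv = ri[r] - rj[r];
    d += (metric == 0) ? resid_weight * (dv < 0 ? -dv : dv)
                       : resid_weight * resid_weight * dv * dv;
  }
  return d;
}

// Nearest pool row (by position in `pool`) for target row `ti`; rows index a
// shared PackedCohort. `skip_id`: pool entries whose id equals tid are not
// eligible (self-match exclusion for bootstrap duplicates). Returns the pool
// *position*; -1 when no eligible pool unit exists.
static int nn_scan(const PackedCohort& pc, int ti,
                   const std::vector<int>& pool, int metric, int resid_weight,
                   const int* tid_ptr, const int* pid_ptr, int tid,
                   int* best_dist_out) {
  int best = -1, best_d = INT32_MAX;
  for (size_t j = 0; j < pool.size(); ++j) {
    if (pid_ptr && pid_ptr[j] == tid) continue;
    int d = pair_dist(pc, ti, pool[j], metric, resid_weight);
    if (d < best_d) {
      best_d = d;
      best = (int)j;
      if (d == 0) break;
    }
  }
  *best_dist_out = best_d;
  return best;
}

// [[Rcpp::export]]
List nn_match_cpp(IntegerMatrix Xt, IntegerMatrix Xp, int metric,
                  Nullable<IntegerVector> target_id = R_NilValue,
                  Nullable<IntegerVector> pool_id = R_NilValue,
                  int resid_weight = 1) {
  int nt = Xt.nrow(), np = Xp.nrow(), p = Xt.ncol();
  if (Xp.ncol() != p) stop("target and pool covariate dimensions differ");
  if (np == 0) stop("pool is empty");

  // Stack target + pool so binary-ness is judged on the union.
  IntegerMatrix X(nt + np, p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < nt; ++i) X(i, j) = Xt(i, j);
    for (int i = 0; i < np; ++i) X(nt + i, j) = Xp(i, j);
  }
  std::vector<bool> bin = find_binary_cols(X);
  PackedCohort pc = pack_rows(X, bin);

  std::vector<int> pool(np);
  for (int i = 0; i < np; ++i) pool[i] = nt + i;

  bool have_ids = target_id.isNotNull() && pool_id.isNotNull();
  IntegerVector tid, pid;
  if (have_ids) { tid = target_id.get(); pid = pool_id.get(); }

  std::unordered_map<uint64_t, int> exact;
  if (pc.keyable && !have_ids) {
    exact.reserve(np * 2);
    for (int j = 0; j < np; ++j) exact.emplace(pc.key[nt + j], j);
  }

  IntegerVector match(nt), dist(nt);
  for (int i = 0; i < nt; ++i) {
    int pos = -1, d = 0;
    if (pc.keyable && !have_ids) {
      std::unordered_map<uint64_t, int>::iterator it = exact.find(pc.key[i]);
      if (it != exact.end()) { pos = it->second; d = 0; }
    }
    if (pos < 0) {
      pos = nn_scan(pc, i, pool, metric, resid_weight,
                    have_ids ? &tid[0] : nullptr,
                    have_ids ? &pid[0] : nullptr,
                    have_ids ? tid[i] : 0, &d);
    }
    if (pos < 0) stop("no eligible pool unit for target %d (all excluded by id)", i + 1);
    match[i] = pos + 1;
    dist[i] = d;
  }
  return List::create(_["match"] = match, _["dist_scaled"] = dist);
}

// Mean of delta over the full argmin (tie) set of pool units for target row
// ti — the expected matched outcome under random tie-breaking.
static double nn_tie_mean(const PackedCohort& pc, int ti,
                          const std::vector<int>& pl,
                          const NumericVector& delta, int metric,
                          int resid_weight) {
  int best_d = INT32_MAX, cnt = 0;
  double sum = 0.0;
  for (size_t j = 0; j < pl.size(); ++j) {
    int d = pair_dist(pc, ti, pl[j], metric, resid_weight);
    if (d < best_d) {
      best_d = d;
      sum = delta[pl[j]];
      cnt = 1;
    } else if (d == best_d) {
      sum += delta[pl[j]];
      ++cnt;
    }
  }
  return sum / cnt;
}

// Tie-averaged matched outcome per target against an explicit pool: returns
// the mean delta over the argmin set and the minimum (scaled-integer)
// distance for every target row of Xt.
// [[Rcpp::export]]
List nn_match_avg_cpp(IntegerMatrix Xt, IntegerMatrix Xp,
                      NumericVector delta_pool, int metric,
                      int resid_weight = 1) {
  int nt = Xt.nrow(), np = Xp.nrow(), p = Xt.ncol();
  if (Xp.ncol() != p) stop("target and pool covariate dimensions differ");
  if (np == 0) stop("pool is empty");
  if (delta_pool.size() != np) stop("delta_pool length must match pool rows");
  IntegerMatrix X(nt + np, p);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < nt; ++i) X(i, j) = Xt(i, j);
    for (int i = 0; i < np; ++i) X(nt + i, j) = Xp(i, j);
  }
  PackedCohort pc = pack_rows(X, find_binary_cols(X));
  std::vector<int> pool(np);
  for (int i = 0; i < np; ++i) pool[i] = nt + i;

  NumericVector avg(nt), dist(nt);
  for (int i = 0; i < nt; ++i) {
    int best_d = INT32_MAX, cnt = 0;
    double sum = 0.0;
    for (int j = 0; j < np; ++j) {
      int d = pair_dist(pc, i, nt + j, metric, resid_weight);
      if (d < best_d) { best_d = d; sum = delta_pool[j]; cnt = 1; }
      else if (d == best_d) { sum += delta_pool[j]; ++cnt; }
    }
    avg[i] = sum / cnt;
    dist[i] = best_d;
  }
  return List::create(_["matched_mean"] = avg, _["dist_scaled"] = dist);
}

// Moderation-effect bootstrap: for the original sample and each resample,
// split rows into group (targets) and pool, compute each target's
// tie-averaged matched outcome, and return
// mean(delta[target]) - mean(matched mean). `resamples` holds 1-based row
// indices, one column per bootstrap replicate. Replicates where either side
// is empty yield NA. An exact-profile hash accumulates (sum, count) of delta
// per pool profile so targets with an exact match are resolved in O(1).
// [[Rcpp::export]]
NumericVector moderation_boot_cpp(IntegerMatrix X, LogicalVector group,
                                  NumericVector delta, IntegerMatrix resamples,
                                  int metric, int resid_weight = 1) {
  int n = X.nrow();
  int B = resamples.ncol();
  if (group.size() != n || delta.size() != n) {
    stop("group/delta length must match covariate rows");
  }
  std::vector<bool> bin = find_binary_cols(X);
  PackedCohort pc = pack_rows(X, bin);

  NumericVector out(B + 1);
  std::vector<int> tg, pl;
  tg.reserve(n); pl.reserve(n);
  struct Cell { double sum; int cnt; };
  std::unordered_map<uint64_t, Cell> exact;

  for (int b = 0; b <= B; ++b) {
    tg.clear(); pl.clear();
    for (int i = 0; i < n; ++i) {
      int idx = (b == 0) ? i : (resamples(i, b - 1) - 1);
      if (group[idx]) tg.push_back(idx); else pl.push_back(idx);
    }
    if (tg.empty() || pl.empty()) { out[b] = NA_REAL; continue; }

    if (pc.keyable) {
      exact.clear();
      exact.reserve(pl.size() * 2);
      for (size_t j = 0; j < pl.size(); ++j) {
        Cell& c = exact[pc.key[pl[j]]];
        c.sum += delta[pl[j]];
        c.cnt += 1;
      }
    }
    double sum_t = 0.0, sum_m = 0.0;
    for (size_t i = 0; i < tg.size(); ++i) {
      int ti = tg[i];
      bool hit = false;
      if (pc.keyable) {
        std::unordered_map<uint64_t, Cell>::iterator it = exact.find(pc.key[ti]);
        if (it != exact.end()) {
          sum_m += it->second.sum / it->second.cnt;
          hit = true;
        }
      }
      if (!hit) sum_m += nn_tie_mean(pc, ti, pl, delta, metric, resid_weight);
      sum_t += delta[ti];
    }
    out[b] = (sum_t - sum_m) / (double)tg.size();
  }
  return out;
}
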