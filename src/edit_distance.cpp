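#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Weighted Levenshtein via Wagner-Fischer. Costs are per operation type;
// no transposition. Rows index `a` (deletions), columns index `b` (insertions).
static double wl_dist(const std::string& a, const std::string& b,
                      double del, double ins, double sub) {
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = j * ins;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = i * del;
    for (size_t j = 1; j <= m; ++j) {
      double c_sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : sub);
      double c_del = prev[j] + del;
      double c_ins = cur[j - 1] + ins;
      cur[j] = std::min(c_sub, std::min(c_del, c_ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Early-exit variant: returns -1 when the distance certainly exceeds `cutoff`.
// Exact whenever the true distance is <= cutoff (row-minimum pruning; the
// row minimum is a lower bound on any extension of the alignment).
static double wl_dist_bounded(const std::string& a, const std::string& b,
                              double del, double ins, double sub,
                              double cutoff) {
  const double indel = std::min(del, ins);
  double len_gap = std::abs((double)a.size() - (double)b.size()) * indel;
  if (len_gap > cutoff + 1e-12) return -1.0;
  const size_t n = a.size(), m = b.size();
  std::vector<double> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = j * ins;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = i * del;
    double rowmin = cur[0];
    for (size_t j = 1; j <= m; ++j) {
      double c_sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0.0 : sub);
      double c_del = prev[j] + del;
      double c_ins = cur[j - 1] + ins;
      cur[j] = std::min(c_sub, std::min(c_del, c_ins));
      if (cur[j] < rowmin) rowmin = cur[j];
    }
    if (rowmin > cutoff + 1e-12) return -1.0;
    std::swap(prev, cur);
  }
  return prev[m] <= cutoff + 1e-12 ? prev[m] : -1.0;
}

// [[Rcpp::export(name = ".wl_pairwise_cpp")]]
NumericVector wl_pairwise_cpp(CharacterVector a, CharacterVector b,
                              double del, double ins, double sub) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = wl_dist(as<std::string>(a[i]), as<std::string>(b[i]), del, ins, sub);
  }
  return out;
}

// [[Rcpp::export(name = ".wl_bounded_cpp")]]
NumericVector wl_bounded_cpp(CharacterVector a, CharacterVector b,
                             double del, double ins, double sub, double cutoff) {
  R_xlen_t n = a.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = wl_dist_bounded(as<std::string>(a[i]), as<std::string>(b[i]),
                             del, ins, sub, cutoff);
  }
  return out;
}

// [[Rcpp::export(name = ".wl_cross_cpp")]]
NumericMatrix wl_cross_cpp(CharacterVector a, CharacterVector b,
                           double del, double ins, double sub) {
  R_xlen_t n = a.size(), m = b.size();
  std::vector<std::string> av(n), bv(m);
  for (R_xlen_t i = 0; i < n; ++i) av[i] = as<std::string>(a[i]);
  for (R_xlen_t j = 0; j < m; ++j) bv[j] = as<std::string>(b[j]);
  NumericMatrix out(n, m);
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = 0; j < m; ++j)
      out(i, j) = wl_dist(av[i], bv[j], del, ins, sub);
  return out;
}

// Greedy single-pass clustering over pre-sorted unique sequences.
//
// For each sequence: scan existing clusters in creation order, computing the
// distance to each cluster representative (bounded at lambda). Under
// first-fit, join the first cluster within lambda; under nearest-fit, join
// the closest (ties -> earliest-created). Otherwise found a new cluster.
// After every association the representative is refreshed to the medoid
// (member minimizing the summed distance to all other members; ties ->
// shorter sequence, then lexicographic), using cached per-member distance
// sums so each update is O(|members|).
//
// Returns 1-based cluster assignments, the representative index per cluster,
// and the distance at association (0 for founders).
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
List greedy_cluster_cpp(CharacterVector seqs, double del, double ins,
                        double sub, double lambda, bool nearest) {
  const R_xlen_t n = seqs.size();
  std::vector<std::string> sv(n);
  for (R_xlen_t i = 0; i < n; ++i) sv[i] = as<std::string>(seqs[i]);
  std::vector<int> slen(n);
  for (R_xlen_t i = 0; i < n; ++i) slen[i] = (int)sv[i].size();
  const double indel = std::min(del, ins);

  std::vector<int> assign(n, -1);
  std::vector<double> assoc_dist(n, 0.0);
  std::vector<std::vector<int>> members;   // per cluster, indices into sv
  std::vector<std::vector<double>> dsum;   // per cluster, per member sum of dists
  std::vector<int> rep;                    // per cluster, index into sv

  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string& x = sv[i];
    int best = -1;
    double best_d = std::numeric_limits<double>::infinity();
    const int xl = slen[i];
    for (size_t c = 0; c < members.size(); ++c) {
      // O(1) length-gap rejection before the DP
      if (std::abs(xl - slen[rep[c]]) * indel > lambda + 1e-12) continue;
      double d = wl_dist_bounded(x, sv[rep[c]], del, ins, sub, lambda);
      if (d < 0) continue;
      if (!nearest) { best = (int)c; best_d = d; break; }
      if (d < best_d - 1e-12) { best = (int)c; best_d = d; }
    }
    if (best < 0) {
      members.push_back(std::vector<int>(1, i));
      dsum.push_back(std::vector<double>(1, 0.0));
      rep.push_back((int)i);
      assign[i] = (int)members.size();  // 1-based
      assoc_dist[i] = 0.0;
    } else {
      std::vector<int>& mem = members[best];
      std::vector<double>& ds = dsum[best];
      double newsum = 0.0;
      for (size_t k = 0; k < mem.size(); ++k) {
        double d = wl_dist(x, sv[mem[k]], del, ins, sub);
        ds[k] += d;
        newsum += d;
      }
      mem.push_back((int)i);
      ds.push_back(newsum);
      assign[i] = best + 1;
      assoc_dist[i] = best_d;
      // medoid refresh
      int arg = 0;
      for (size_t k = 1; k < mem.size(); ++k) {
        double a = ds[k], b = ds[arg];
        if (a < b - 1e-12) { arg = (int)k; continue; }
        if (std::abs(a - b) <= 1e-12) {
          const std::string& sk = sv[mem[k]];
          const std::string& sa = sv[mem[arg]];
          if (sk.size() < sa.size() ||
              (sk.size() == sa.size() && sk < sa)) arg = (int)k;
        }
      }
      rep[best] = mem[arg];
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  IntegerVector rass(assign.begin(), assign.end());
  NumericVector rdist(assoc_dist.begin(), assoc_dist.end());
  IntegerVector rrep(rep.size());
  for (size_t c = 0; c < rep.size(); ++c) rrep[c] = rep[c] + 1;  // 1-based
  return List::create(_["assignment"] = rass,
                      _["assoc_distance"] = rdist,
                      _["rep_index"] = rrep);
}

// Minimum distance from each query to any of `refs`, bounded; used for
// database matching and separation checks. Returns -1 where all exceed cutoff.
// [[Rcpp::export(name = ".wl_min_cpp")]]
List wl_min_cpp(CharacterVector query, CharacterVector refs,
                double del, double ins, double sub, double cutoff) {
  R_xlen_t n = query.size(), m = refs.size();
  std::vector<std::string> qv(n), rv(m);
  for (R_xlen_t i = 0; i < n; ++i) qv[i] = as<std::string>(query[i]);
  for (R_xlen_t j = 0; j < m; ++j) rv[j] = as<std::string>(refs[j]);
  NumericVector dmin(n);
  IntegerVector which(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = -1.0; int arg = NA_INTEGER;
    for (R_xlen_t j = 0; j < m; ++j) {
      double d = wl_dist_bounded(qv[i], rv[j], del, ins, sub, cutoff);
      if (d < 0) continue;
      if (best < 0 || d < best - 1e-12) { best = d; arg = (int)j + 1; }
    }
    dmin[i] = best; which[i] = arg;
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["dist"] = dmin, _["which"] = which);
}
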