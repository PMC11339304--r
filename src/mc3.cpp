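#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Metropolis-coupled structure MCMC over discrete Bayesian networks with a
// BDeu marginal-likelihood score and a uniform prior over valid structures.
// Nodes flagged as "prev" (earlier time slice) may only act as parents.
// Parent sets are bitmasks, so the sampler is limited to 32 variables; the
// R wrapper enforces this.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint32_t seed) : s(seed ? seed : 0x9E3779B9u) {
    for (int i = 0; i < 8; ++i) next();
  }
  // splitmix64
  uint64_t next() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(((next() >> 32) * (uint64_t)n) >> 32); }
};

class Scorer {
 public:
  Scorer(const IntegerMatrix& data, const IntegerVector& arity, double ess)
      : n_(data.nrow()), p_(data.ncol()), ess_(ess) {
    cols_.resize(p_);
    arity_.resize(p_);
    for (int j = 0; j < p_; ++j) {
      arity_[j] = arity[j];
      cols_[j].resize(n_);
      for (int i = 0; i < n_; ++i) cols_[j][i] = data(i, j);
    }
    cache_.resize(p_);
  }

  // log BDeu family score of `child` with parent set `mask` (bitmask).
  double family(int child, uint32_t mask) {
    auto& m = cache_[child];
    auto it = m.find(mask);
    if (it != m.end()) return it->second;
    double sc = compute(child, mask);
    m.emplace(mask, sc);
    return sc;
  }

 private:
  double compute(int child, uint32_t mask) const {
    std::vector<int> pa;
    long long q = 1;
    for (int j = 0; j < p_; ++j)
      if (mask & (1u << j)) {
        pa.push_back(j);
        q *= arity_[j];
      }
    const int r = arity_[child];
    const double aj = ess_ / (double)q;
    const double ajk = ess_ / (double)(q * r);
    // counts indexed by parent configuration * r + child value
    std::vector<int> cnt((size_t)q * r, 0);
    const std::vector<int>& cc = cols_[child];
    for (int i = 0; i < n_; ++i) {
      long long idx = 0;
      for (size_t t = 0; t < pa.size(); ++t)
        idx = idx * arity_[pa[t]] + cols_[pa[t]][i];
      ++cnt[(size_t)idx * r + cc[i]];
    }
    double sc = 0.0;
    for (long long j = 0; j < q; ++j) {
      int nj = 0;
      for (int k = 0; k < r; ++k) nj += cnt[(size_t)j * r + k];
      if (nj == 0) continue;
      sc += R::lgammafn(aj) - R::lgammafn(aj + nj);
      for (int k = 0; k < r; ++k) {
        int njk = cnt[(size_t)j * r + k];
        if (njk > 0) sc += R::lgammafn(ajk + njk) - R::lgammafn(ajk);
      }
    }
    return sc;
  }

  int n_, p_;
  double ess_;
  std::vector<int> arity_;
  std::vector<std::vector<int>> cols_;
  mutable std::vector<std::unordered_map<uint32_t, double>> cache_;
};

struct Chain {
  std::vector<uint32_t> parents;   // parents[j]: bitmask of parents of j
  std::vector<uint32_t> children;  // children[j]: bitmask of children of j
  std::vector<double> fam;         // cached family score per node
  double score;
};

inline int popcount32(uint32_t x) {
  int c = 0;
  while (x) {
    x &= x - 1;
    ++c;
  }
  return c;
}

// does `from` reach `to` along directed edges? (cycle check)
bool reaches(const std::vector<uint32_t>& children, int from, int to, int p) {
  uint32_t visited = 1u << from, frontier = children[from];
  while (frontier) {
    if (frontier & (1u << to)) return true;
    uint32_t fresh = frontier & ~visited;
    visited |= frontier;
    frontier = 0;
    for (int j = 0; j < p; ++j)
      if (fresh & (1u << j)) frontier |= children[j];
    frontier &= ~visited;
  }
  return false;
}

}  // namespace

// [[Rcpp::export]]
List mc3_structure_sample(IntegerMatrix data, IntegerVector arity, int target,
                          LogicalVector is_prev, double ess, int max_parents,
                          NumericVector temperatures, double burn_in,
                          double n_samples, int thin, int swap_every,
                          int seed) {
  const int p = data.ncol();
  const int nc = temperatures.size();
  if (p > 32) stop("at most 32 variables are supported");
  Scorer scorer(data, arity, ess);
  Rng rng((uint32_t)seed);

  std::vector<double> beta(nc);
  for (int c = 0; c < nc; ++c) beta[c] = 1.0 / temperatures[c];

  std::vector<Chain> chains(nc);
  for (int c = 0; c < nc; ++c) {
    chains[c].parents.assign(p, 0u);
    chains[c].children.assign(p, 0u);
    chains[c].fam.assign(p, 0.0);
    double s = 0.0;
    for (int j = 0; j < p; ++j) {
      chains[c].fam[j] = scorer.family(j, 0u);
      s += chains[c].fam[j];
    }
    chains[c].score = s;
  }

  const long long nburn = (long long)burn_in;
  const long long nsamp = (long long)n_samples;
  const long long nrec = thin > 0 ? nsamp / thin : 0;

  std::vector<int> cand;
  for (int j = 0; j < p; ++j)
    if (j != target) cand.push_back(j);
  IntegerMatrix trace((int)nrec, (int)cand.size());
  NumericVector logscore((int)nrec);

  long long proposals = 0, accepts = 0, swap_prop = 0, swap_acc = 0;
  long long rec = 0;

  for (long long step = 0; step < nburn + nsamp; ++step) {
    for (int c = 0; c < nc && p >= 2; ++c) {
      Chain& ch = chains[c];
      ++proposals;
      const bool rev = rng.unif() < 0.15;
      int i = rng.below(p);
      int j = rng.below(p - 1);
      if (j >= i) ++j;  // ordered pair (i, j), i != j
      if (rev) {
        // reverse existing edge i -> j
        if (!(ch.children[i] & (1u << j))) continue;
        if (is_prev[i]) continue;  // reversed edge would point into slice t-1
        if (popcount32(ch.parents[i]) >= max_parents) continue;
        // acyclicity: after removing i->j, adding j->i must not close a cycle
        ch.children[i] &= ~(1u << j);
        bool cyc = reaches(ch.children, i, j, p);
        ch.children[i] |= (1u << j);
        if (cyc) continue;
        double fj = scorer.family(j, ch.parents[j] & ~(1u << i));
        double fi = scorer.family(i, ch.parents[i] | (1u << j));
        double delta = (fj - ch.fam[j]) + (fi - ch.fam[i]);
        if (delta >= 0 || std::log(rng.unif()) < delta * beta[c]) {
          ch.children[i] &= ~(1u << j);
          ch.parents[j] &= ~(1u << i);
          ch.children[j] |= (1u << i);
          ch.parents[i] |= (1u << j);
          ch.fam[j] = fj;
          ch.fam[i] = fi;
          ch.score += delta;
          ++accepts;
        }
      } else {
        // toggle edge i -> j
        if (is_prev[j]) continue;
        const bool present = (ch.children[i] & (1u << j)) != 0;
        if (!present) {
          if (popcount32(ch.parents[j]) >= max_parents) continue;
          if (reaches(ch.children, j, i, p)) continue;  // i->j closes cycle
        }
        uint32_t newpa =
            present ? (ch.parents[j] & ~(1u << i)) : (ch.parents[j] | (1u << i));
        double fj = scorer.family(j, newpa);
        double delta = fj - ch.fam[j];
        if (delta >= 0 || std::log(rng.unif()) < delta * beta[c]) {
          ch.parents[j] = newpa;
          if (present)
            ch.children[i] &= ~(1u << j);
          else
            ch.children[i] |= (1u << j);
          ch.fam[j] = fj;
          ch.score += delta;
          ++accepts;
        }
      }
    }

    if (nc > 1 && swap_every > 0 && (step + 1) % swap_every == 0) {
      int c = rng.below(nc - 1);
      ++swap_prop;
      double logr =
          (beta[c] - beta[c + 1]) * (chains[c + 1].score - chains[c].score);
      if (logr >= 0 || std::log(rng.unif()) < logr) {
        std::swap(chains[c], chains[c + 1]);
        ++swap_acc;
      }
    }

    if (step >= nburn && thin > 0 && (step - nburn) % thin == thin - 1 &&
        rec < nrec) {
      const Chain& cold = chains[0];
      for (size_t k = 0; k < cand.size(); ++k) {
        int x = cand[k];
        int ind = ((cold.children[x] >> target) & 1u) ||
                  ((cold.children[target] >> x) & 1u) ||
                  ((cold.children[x] & cold.children[target]) != 0u);
        trace((int)rec, (int)k) = ind;
      }
      logscore[(int)rec] = cold.score;
      ++rec;
    }
  }

  IntegerVector cand_out((int)cand.size());
  for (size_t k = 0; k < cand.size(); ++k) cand_out[(int)k] = cand[k] + 1;

  return List::create(
      Named("indicators") = trace, Named("candidates") = cand_out,
      Named("log_score") = logscore,
      Named("accept_rate") = proposals ? (double)accepts / proposals : NA_REAL,
      Named("swap_rate") = swap_prop ? (double)swap_acc / swap_prop : NA_REAL);
}
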