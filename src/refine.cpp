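// Modified-CANON refinement core. Scores are exact products of powered
// primes; a hashed or floating representation could silently level two
// distinct ranks, which is precisely the failure mode the powered-prime
// scheme exists to rule out, so the arithmetic uses multi-limb naturals.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

typedef std::vector<uint32_t> bignat; // little-endian limbs, base 2^32

static void mul_small(bignat &a, uint64_t m) {
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t v = (uint64_t)a[i] * m + carry;
    a[i] = (uint32_t)(v & 0xffffffffULL);
    carry = v >> 32;
  }
  while (carry) {
    a.push_back((uint32_t)(carry & 0xffffffffULL));
    carry >>= 32;
  }
}

static int cmp_big(const bignat &a, const bignat &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

static std::vector<int> first_primes(int n) {
  int limit = std::max(30, (int)(n * (std::log(n + 1.0) + std::log(std::log(n + 3.0)) + 1.0)) + 10);
  for (;;) {
    std::vector<bool> comp(limit + 1, false);
    std::vector<int> primes;
    for (int p = 2; p <= limit; ++p) {
      if (!comp[p]) {
        primes.push_back(p);
        for (long long q = (long long)p * p; q <= limit; q += p) comp[q] = true;
      }
    }
    if ((int)primes.size() >= n) {
      primes.resize(n);
      return primes;
    }
    limit *= 2;
  }
}

// consecutive 1-based ranks from arbitrary positive keys (equal key = equal rank)
static std::vector<int> consecutive(const std::vector<int> &keys) {
  std::vector<int> uq(keys);
  std::sort(uq.begin(), uq.end());
  uq.erase(std::unique(uq.begin(), uq.end()), uq.end());
  std::vector<int> out(keys.size());
  for (size_t i = 0; i < keys.size(); ++i)
    out[i] = (int)(std::lower_bound(uq.begin(), uq.end(), keys[i]) - uq.begin()) + 1;
  return out;
}

// score[i] = prime(rank[i])^power * prod over neighbours prime(rank[nbr])^exp
static std::vector<bignat> score_pass(const std::vector<std::vector<int>> &nbr,
                                      const std::vector<std::vector<int>> &expo,
                                      const std::vector<int> &ranks, int power) {
  int n = ranks.size();
  int maxr = 0;
  for (int r : ranks) maxr = std::max(maxr, r);
  std::vector<int> primes = first_primes(maxr);
  std::vector<bignat> scores(n);
  for (int i = 0; i < n; ++i) {
    bignat s(1, 1u);
    uint64_t p = primes[ranks[i] - 1];
    for (int k = 0; k < power; ++k) mul_small(s, p);
    for (size_t j = 0; j < nbr[i].size(); ++j) {
      uint64_t q = primes[ranks[nbr[i][j] - 1] - 1];
      for (int k = 0; k < expo[i][j]; ++k) mul_small(s, q);
    }
    scores[i] = s;
  }
  return scores;
}

// ascending consecutive ranks of big scores
static std::vector<int> rank_scores(const std::vector<bignat> &scores) {
  int n = scores.size();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    int c = cmp_big(scores[a], scores[b]);
    if (c != 0) return c < 0;
    return a < b;
  });
  std::vector<int> out(n);
  int rank = 1;
  out[idx[0]] = 1;
  for (int t = 1; t < n; ++t) {
    if (cmp_big(scores[idx[t]], scores[idx[t - 1]]) != 0) ++rank;
    out[idx[t]] = rank;
  }
  return out;
}

static std::vector<std::vector<int>> as_adj(List lst) {
  std::vector<std::vector<int>> out(lst.size());
  for (int i = 0; i < lst.size(); ++i) {
    IntegerVector v = lst[i];
    out[i] = std::vector<int>(v.begin(), v.end());
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_refine(List adj_nbr, List adj_exp, IntegerVector ranks0, int power) {
  std::vector<std::vector<int>> nbr = as_adj(adj_nbr);
  std::vector<std::vector<int>> expo = as_adj(adj_exp);
  int n = ranks0.size();
  std::vector<int> ranks = consecutive(std::vector<int>(ranks0.begin(), ranks0.end()));
  int dist = *std::max_element(ranks.begin(), ranks.end());
  int prevdist = dist - 1;
  while (dist < n && dist > prevdist) {
    prevdist = dist;
    std::vector<int> prev = ranks;
    std::vector<bignat> scores = score_pass(nbr, expo, prev, power);
    ranks = rank_scores(scores);
    // invariant: the new partition refines the old one (no leveling): all
    // members of a new class must come from one old class
    dist = *std::max_element(ranks.begin(), ranks.end());
    std::vector<int> seen_old(dist + 1, 0);
    for (int i = 0; i < n; ++i) {
      int &s = seen_old[ranks[i]];
      if (s == 0) s = prev[i];
      else if (s != prev[i]) stop("refinement leveled two distinct ranks");
    }
  }
  return IntegerVector(ranks.begin(), ranks.end());
}

// One scoring pass, scores returned as decimal strings (exact).
// [[Rcpp::export]]
CharacterVector cpp_score_pass(List adj_nbr, List adj_exp, IntegerVector ranks0, int power) {
  std::vector<std::vector<int>> nbr = as_adj(adj_nbr);
  std::vector<std::vector<int>> expo = as_adj(adj_exp);
  std::vector<int> ranks(ranks0.begin(), ranks0.end());
  std::vector<bignat> scores = score_pass(nbr, expo, ranks, power);
  CharacterVector out(scores.size());
  for (size_t i = 0; i < scores.size(); ++i) {
    bignat cur = scores[i];
    std::string dec;
    bool zero = true;
    for (uint32_t l : cur) if (l) zero = false;
    if (zero) dec = "0";
    while (!zero) {
      uint64_t rem = 0;
      for (size_t j = cur.size(); j-- > 0;) {
        uint64_t v = (rem << 32) | cur[j];
        cur[j] = (uint32_t)(v / 1000000000ULL);
        rem = v % 1000000000ULL;
      }
      while (!cur.empty() && cur.back() == 0) cur.pop_back();
      zero = cur.empty();
      char buf[16];
      snprintf(buf, sizeof(buf), zero ? "%llu" : "%09llu", (unsigned long long)rem);
      dec = std::string(buf) + dec;
    }
    out[i] = dec;
  }
  return out;
}
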