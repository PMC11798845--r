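#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Minimum-weight perfect matching on a complete graph with an even number
// of vertices. Exact bitmask dynamic program for n <= MAX_EXACT; above that
// a deterministic greedy construction refined by exhaustive re-matching of
// every 2- and 3-subset of pairs until locally optimal.

static const int MAX_EXACT = 22;

// exhaustive best perfect matching on the (even, <= 6) vertices in idx;
// fills best_mate with local partner indices, returns its cost
static double tiny_best(const NumericMatrix& D, const std::vector<int>& idx,
                        std::vector<int>& best_mate) {
  int k = (int)idx.size();
  std::vector<int> cur(k, -1);
  double best = R_PosInf;
  std::vector<std::pair<int, int> > stack;
  // simple recursive enumeration (k <= 6 so depth <= 3)
  struct Rec {
    const NumericMatrix& D;
    const std::vector<int>& idx;
    std::vector<int>& cur;
    double& best;
    std::vector<int>& best_mate;
    void run(double cost) {
      int k = (int)idx.size(), i = -1;
      for (int v = 0; v < k; ++v) if (cur[v] < 0) { i = v; break; }
      if (i < 0) {
        if (cost < best) { best = cost; best_mate = cur; }
        return;
      }
      for (int j = i + 1; j < k; ++j) {
        if (cur[j] >= 0) continue;
        double c = cost + D(idx[i], idx[j]);
        if (c >= best) continue;
        cur[i] = j; cur[j] = i;
        run(c);
        cur[i] = -1; cur[j] = -1;
      }
    }
  } rec{D, idx, cur, best, best_mate};
  rec.run(0.0);
  return best;
}

static void dp_exact(const NumericMatrix& D, int n, std::vector<int>& mate) {
  size_t M = (size_t)1 << n;
  std::vector<double> f(M, R_PosInf);
  std::vector<int8_t> ch(M, -1);
  f[0] = 0.0;
  for (size_t S = 1; S < M; ++S) {
    int pc = __builtin_popcountll((unsigned long long)S);
    if (pc & 1) continue;
    int i = __builtin_ctzll((unsigned long long)S);
    size_t S2 = S & ~((size_t)1 << i);
    size_t T = S2;
    double best = R_PosInf;
    int bj = -1;
    while (T) {
      int j = __builtin_ctzll((unsigned long long)T);
      T &= T - 1;
      double v = f[S2 & ~((size_t)1 << j)] + D(i, j);
      if (v < best) { best = v; bj = j; }
    }
    f[S] = best;
    ch[S] = (int8_t)bj;
  }
  mate.assign(n, -1);
  size_t S = M - 1;
  while (S) {
    int i = __builtin_ctzll((unsigned long long)S);
    int j = ch[S];
    mate[i] = j; mate[j] = i;
    S &= ~((size_t)1 << i);
    S &= ~((size_t)1 << j);
  }
}

// try re-matching the endpoints of the pair subset; true if improved
static bool try_improve(const NumericMatrix& D, std::vector<int>& mate,
                        const std::vector<int>& idx) {
  double cur = 0.0;
  for (size_t u = 0; u < idx.size(); ++u)
    if (mate[idx[u]] > idx[u]) cur += D(idx[u], mate[idx[u]]);
  std::vector<int> bm;
  double best = tiny_best(D, idx, bm);
  if (best < cur - 1e-12) {
    for (size_t u = 0; u < idx.size(); ++u) mate[idx[u]] = idx[bm[u]];
    return true;
  }
  return false;
}

static double match_cost(const NumericMatrix& D, const std::vector<int>& mate) {
  double c = 0.0;
  for (int i = 0; i < (int)mate.size(); ++i)
    if (mate[i] > i) c += D(i, mate[i]);
  return c;
}

// variable-neighborhood local search: exhaustively re-match every 2-, 3-
// and (when smaller moves stall) 4-subset of pairs until locally optimal
static void refine(const NumericMatrix& D, int n, std::vector<int>& mate) {
  bool improved = true;
  while (improved) {
    improved = false;
    std::vector<int> heads;
    for (int i = 0; i < n; ++i) if (mate[i] > i) heads.push_back(i);
    int m = (int)heads.size();
    for (int a = 0; a < m && !improved; ++a)
      for (int b = a + 1; b < m && !improved; ++b) {
        std::vector<int> idx = {heads[a], mate[heads[a]],
                                heads[b], mate[heads[b]]};
        if (try_improve(D, mate, idx)) improved = true;
      }
    if (improved) continue;
    for (int a = 0; a < m && !improved; ++a)
      for (int b = a + 1; b < m && !improved; ++b)
        for (int c = b + 1; c < m && !improved; ++c) {
          std::vector<int> idx = {heads[a], mate[heads[a]],
                                  heads[b], mate[heads[b]],
                                  heads[c], mate[heads[c]]};
          if (try_improve(D, mate, idx)) improved = true;
        }
    if (improved) continue;
    for (int a = 0; a < m && !improved; ++a)
      for (int b = a + 1; b < m && !improved; ++b)
        for (int c = b + 1; c < m && !improved; ++c)
          for (int d = c + 1; d < m && !improved; ++d) {
            std::vector<int> idx = {heads[a], mate[heads[a]],
                                    heads[b], mate[heads[b]],
                                    heads[c], mate[heads[c]],
                                    heads[d], mate[heads[d]]};
            if (try_improve(D, mate, idx)) improved = true;
          }
  }
}

static void heuristic(const NumericMatrix& D, int n, std::vector<int>& mate) {
  // greedy start: cheapest edge among unmatched vertices
  mate.assign(n, -1);
  int left = n;
  while (left > 0) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      if (mate[i] >= 0) continue;
      for (int j = i + 1; j < n; ++j) {
        if (mate[j] >= 0) continue;
        if (D(i, j) < best) { best = D(i, j); bi = i; bj = j; }
      }
    }
    mate[bi] = bj; mate[bj] = bi;
    left -= 2;
  }
  refine(D, n, mate);
  double best_cost = match_cost(D, mate);
  std::vector<int> best_mate = mate;
  // deterministic multi-start: refine from shuffled sequential pairings
  uint64_t state = 0x9E3779B97F4A7C15ull;  // fixed xorshift stream
  auto next_rand = [&state]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return state;
  };
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int rs = 0; rs < 20; ++rs) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(next_rand() % (uint64_t)(i + 1));
      std::swap(perm[i], perm[j]);
    }
    std::vector<int> cand(n, -1);
    for (int i = 0; i < n; i += 2) {
      cand[perm[i]] = perm[i + 1];
      cand[perm[i + 1]] = perm[i];
    }
    refine(D, n, cand);
    double c = match_cost(D, cand);
    if (c < best_cost - 1e-12) { best_cost = c; best_mate = cand; }
  }
  mate = best_mate;
}

// [[Rcpp::export]]
IntegerVector min_weight_matching_cpp(NumericMatrix D,
                                      bool force_heuristic = false) {
  int n = D.nrow();
  if (n != D.ncol()) stop("distance matrix must be square");
  if (n % 2 != 0) stop("internal: matching needs an even vertex count");
  std::vector<int> mate;
  if (n <= MAX_EXACT && !force_heuristic) dp_exact(D, n, mate);
  else heuristic(D, n, mate);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mate[i] + 1;  // 1-based
  return out;
}
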