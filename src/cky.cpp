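// Probabilistic CKY chart parsing for grammars in Chomsky Form with
// Contacts (CNF plus contact rules V_N -> V_T V_N V_T).
//
// Symbol encoding (0-based): lexical non-terminals 0..n_lex-1, structural
// non-terminals n_lex..n_lex+n_nt-1.  Sequences arrive as 0-based terminal
// indices.  Contact pairs arrive 1-based, CF-compatible (non-crossing,
// endpoint-disjoint).
//
// Contact constraints follow the modified-CKY scheme: lexical probabilities
// at in-contact positions are removed from the base chart row and reserved
// in a side table usable only by contact rules completing the exact pair;
// the two flanking lexical non-terminals of a contact rule must both come
// from the base row or both from the side table, never mixed.
//
// The inside chart is kept in linear space with one log-scale per span
// length (cells of equal span share a scale, and a span-j cell combines
// spans k and j-k, so scales compose additively); this keeps the inner
// loop free of exp/log while supporting sequences far beyond the linear-
// space underflow limit.  Viterbi uses plain log space (max, no sums).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Fill pairof[pos] = contact-pair index, or -1.
static std::vector<int> make_pairof(int n, const IntegerMatrix& contacts) {
  std::vector<int> pairof(n, -1);
  for (int p = 0; p < contacts.nrow(); ++p) {
    int i = contacts(p, 0) - 1, j = contacts(p, 1) - 1;
    if (i < 0 || j >= n || i >= j) stop("contact pair out of range");
    if (pairof[i] != -1 || pairof[j] != -1)
      stop("contact map has overlapping pairs (shared endpoint)");
    pairof[i] = p;
    pairof[j] = p;
  }
  return pairof;
}

// Lexical emission table lexP[i * n_lex + t] = theta(t -> x_i), or 1 for
// every (i, t) in skeleton-mass mode (total emission mass of a proper
// lexical non-terminal is 1).
static std::vector<double> make_lexP(const IntegerVector& seq, int n_lex,
                                     const IntegerVector& lex_lhs,
                                     const IntegerVector& lex_term,
                                     const NumericVector& lex_prob,
                                     bool lex_ones) {
  int n = seq.size();
  std::vector<double> lexP((size_t)n * n_lex, 0.0);
  if (lex_ones) {
    std::fill(lexP.begin(), lexP.end(), 1.0);
    return lexP;
  }
  for (int i = 0; i < n; ++i) {
    int a = seq[i];
    for (int r = 0; r < lex_lhs.size(); ++r)
      if (lex_term[r] == a)
        lexP[(size_t)i * n_lex + lex_lhs[r]] += lex_prob[r];
  }
  return lexP;
}

// [[Rcpp::export]]
double cpp_inside(IntegerVector seq, int n_lex, int n_nt,
                  IntegerVector lex_lhs, IntegerVector lex_term,
                  NumericVector lex_prob,
                  IntegerVector br_lhs, IntegerVector br_b, IntegerVector br_c,
                  NumericVector br_prob,
                  IntegerVector ct_lhs, IntegerVector ct_t, IntegerVector ct_w,
                  IntegerVector ct_u, NumericVector ct_prob,
                  IntegerMatrix contacts, bool lex_ones, int start) {
  const int n = seq.size();
  const int nV = n_lex + n_nt;
  if (n == 0) stop("empty sequence");
  if (n == 1) return NEG_INF;  // structural start cannot yield one terminal

  std::vector<int> pairof = make_pairof(n, contacts);
  std::vector<double> lexP =
      make_lexP(seq, n_lex, lex_lhs, lex_term, lex_prob, lex_ones);

  std::vector<double> P((size_t)n * n * nV, 0.0);
  std::vector<double> S(n + 1, 0.0);  // log-scale per span length

  // span 1: lexical entries, contact endpoints masked out
  double mx = 0.0;
  for (int i = 0; i < n; ++i) {
    if (pairof[i] != -1) continue;
    for (int t = 0; t < n_lex; ++t) {
      double v = lexP[(size_t)i * n_lex + t];
      P[((size_t)0 * n + i) * nV + t] = v;
      if (v > mx) mx = v;
    }
  }
  if (mx > 0.0) {
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < n_lex; ++t)
        P[((size_t)0 * n + i) * nV + t] /= mx;
    S[1] = std::log(mx);
  }
  // mx == 0 with n > 1 means every position is a contact endpoint; the
  // innermost pair is then unrealisable and the chart stays at zero.

  const int nbr = br_lhs.size(), nct = ct_lhs.size();

  for (int j = 2; j <= n; ++j) {
    std::vector<double> f(j, 0.0);  // f[k], k = 1..j-1
    double targetS = NEG_INF;
    for (int k = 1; k < j; ++k) {
      double sc = S[k] + S[j - k];
      if (sc > targetS) targetS = sc;
    }
    bool has_ct = (nct > 0 && j >= 4);
    double Sct = has_ct ? S[j - 2] : NEG_INF;
    if (has_ct && Sct > targetS) targetS = Sct;
    if (targetS == NEG_INF) targetS = 0.0;
    for (int k = 1; k < j; ++k) f[k] = std::exp(S[k] + S[j - k] - targetS);
    double fct = has_ct ? std::exp(Sct - targetS) : 0.0;

    double rowmax = 0.0;
    std::vector<double> T((size_t)nV * nV);
    for (int i = 0; i + j <= n; ++i) {
      double* cell = &P[((size_t)(j - 1) * n + i) * nV];
      // accumulate split products per (B, C) child pair, skipping zero
      // children, then apply the branching rules once per cell
      std::fill(T.begin(), T.end(), 0.0);
      for (int k = 1; k < j; ++k) {
        double fk = f[k];
        if (fk == 0.0) continue;
        const double* L = &P[((size_t)(k - 1) * n + i) * nV];
        const double* Rr = &P[((size_t)(j - k - 1) * n + (i + k)) * nV];
        for (int b = 0; b < nV; ++b) {
          double lb = L[b];
          if (lb == 0.0) continue;
          lb *= fk;
          double* Tb = &T[(size_t)b * nV];
          for (int c = 0; c < nV; ++c)
            if (Rr[c] != 0.0) Tb[c] += lb * Rr[c];
        }
      }
      for (int r = 0; r < nbr; ++r) {
        double t = T[(size_t)br_b[r] * nV + br_c[r]];
        if (t != 0.0) cell[n_lex + br_lhs[r]] += br_prob[r] * t;
      }
      if (has_ct && fct != 0.0) {
        int e = i + j - 1;
        bool allowed = (pairof[i] == -1 && pairof[e] == -1) ||
                       (pairof[i] != -1 && pairof[i] == pairof[e]);
        if (allowed) {
          const double* inner = &P[((size_t)(j - 3) * n + (i + 1)) * nV];
          const double* Le = &lexP[(size_t)i * n_lex];
          const double* Re = &lexP[(size_t)e * n_lex];
          for (int r = 0; r < nct; ++r) {
            double t = Le[ct_t[r]] * inner[n_lex + ct_w[r]] * Re[ct_u[r]];
            if (t != 0.0) cell[n_lex + ct_lhs[r]] += ct_prob[r] * fct * t;
          }
        }
      }
      for (int v = 0; v < nV; ++v)
        if (cell[v] > rowmax) rowmax = cell[v];
    }
    if (rowmax > 0.0) {
      for (int i = 0; i + j <= n; ++i) {
        double* cell = &P[((size_t)(j - 1) * n + i) * nV];
        for (int v = 0; v < nV; ++v) cell[v] /= rowmax;
      }
      S[j] = targetS + std::log(rowmax);
    } else {
      S[j] = targetS;
    }
  }

  double v = P[((size_t)(n - 1) * n + 0) * nV + n_lex + start];
  return v > 0.0 ? std::log(v) + S[n] : NEG_INF;
}

// Viterbi: most probable parse, log space.  Backpointers: for each
// (span, start, structural non-terminal) the rule kind (1 branching,
// 2 contact), the rule row, and the split point (branching only).
// Tie-break: branching rules before contact rules, then lowest rule row,
// then leftmost split; only strictly better candidates replace the
// incumbent, so the first-listed optimum wins.
// [[Rcpp::export]]
List cpp_viterbi(IntegerVector seq, int n_lex, int n_nt,
                 IntegerVector lex_lhs, IntegerVector lex_term,
                 NumericVector lex_prob,
                 IntegerVector br_lhs, IntegerVector br_b, IntegerVector br_c,
                 NumericVector br_prob,
                 IntegerVector ct_lhs, IntegerVector ct_t, IntegerVector ct_w,
                 IntegerVector ct_u, NumericVector ct_prob,
                 IntegerMatrix contacts, int start) {
  const int n = seq.size();
  const int nV = n_lex + n_nt;
  if (n == 0) stop("empty sequence");

  std::vector<int> pairof = make_pairof(n, contacts);
  std::vector<double> lexP =
      make_lexP(seq, n_lex, lex_lhs, lex_term, lex_prob, false);

  std::vector<double> V((size_t)n * n * nV, NEG_INF);
  IntegerVector btype((size_t)n * n * n_nt, 0);
  IntegerVector brule((size_t)n * n * n_nt, -1);
  IntegerVector bsplit((size_t)n * n * n_nt, -1);

  for (int i = 0; i < n; ++i) {
    if (pairof[i] != -1) continue;
    for (int t = 0; t < n_lex; ++t) {
      double v = lexP[(size_t)i * n_lex + t];
      if (v > 0.0) V[((size_t)0 * n + i) * nV + t] = std::log(v);
    }
  }

  const int nbr = br_lhs.size(), nct = ct_lhs.size();

  for (int j = 2; j <= n; ++j) {
    for (int i = 0; i + j <= n; ++i) {
      double* cell = &V[((size_t)(j - 1) * n + i) * nV];
      size_t boff = ((size_t)(j - 1) * n + i) * n_nt;
      for (int r = 0; r < nbr; ++r) {
        if (br_prob[r] <= 0.0) continue;
        double lp = std::log(br_prob[r]);
        for (int k = 1; k < j; ++k) {
          double L = V[((size_t)(k - 1) * n + i) * nV + br_b[r]];
          if (L == NEG_INF) continue;
          double Rr = V[((size_t)(j - k - 1) * n + (i + k)) * nV + br_c[r]];
          if (Rr == NEG_INF) continue;
          double cand = lp + L + Rr;
          if (cand > cell[n_lex + br_lhs[r]]) {
            cell[n_lex + br_lhs[r]] = cand;
            btype[boff + br_lhs[r]] = 1;
            brule[boff + br_lhs[r]] = r;
            bsplit[boff + br_lhs[r]] = k;
          }
        }
      }
      if (nct > 0 && j >= 4) {
        int e = i + j - 1;
        bool allowed = (pairof[i] == -1 && pairof[e] == -1) ||
                       (pairof[i] != -1 && pairof[i] == pairof[e]);
        if (allowed) {
          for (int r = 0; r < nct; ++r) {
            if (ct_prob[r] <= 0.0) continue;
            double Le = lexP[(size_t)i * n_lex + ct_t[r]];
            double Re = lexP[(size_t)e * n_lex + ct_u[r]];
            if (Le <= 0.0 || Re <= 0.0) continue;
            double inner =
                V[((size_t)(j - 3) * n + (i + 1)) * nV + n_lex + ct_w[r]];
            if (inner == NEG_INF) continue;
            double cand = std::log(ct_prob[r]) + std::log(Le) + inner +
                          std::log(Re);
            if (cand > cell[n_lex + ct_lhs[r]]) {
              cell[n_lex + ct_lhs[r]] = cand;
              btype[boff + ct_lhs[r]] = 2;
              brule[boff + ct_lhs[r]] = r;
              bsplit[boff + ct_lhs[r]] = -1;
            }
          }
        }
      }
    }
  }

  double logprob = (n >= 2) ? V[((size_t)(n - 1) * n + 0) * nV + n_lex + start]
                            : NEG_INF;
  return List::create(_["logprob"] = logprob, _["btype"] = btype,
                      _["brule"] = brule, _["bsplit"] = bsplit);
}
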