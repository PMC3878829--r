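#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Allowed error budget for a matched adapter length L at error rate e.
// The tiny epsilon guards against binary floating-point representation of
// e*L landing just below an integer (e.g. 0.1*30).
static inline int allowed_errors(double e, int L) {
  return (int) std::floor(e * (double) L + 1e-9);
}

static inline bool base_match(char a, char b) {
  // 'N' mismatches everything, including another 'N'.
  return a == b && a != 'N';
}

// Error-tolerant 3' adapter search over a vector of read sequences.
//
// Candidate matches at read start position s (0-based) are:
//  (a) the full adapter aligned against some prefix of the read suffix
//      s..end (internal occurrence): matched length L = adapter length,
//      errors = minimum edit distance over all suffix prefixes;
//  (b) an adapter prefix of length L aligned against the entire read
//      suffix (3' overlap): errors = edit distance(prefix, suffix).
// A candidate is admissible iff L >= min_overlap and
// errors <= floor(error_rate * L). The winner has minimal errors, then the
// 5'-most start, then the earliest adapter in the list. Everything from
// the match start to the read end is removed by the caller.
// [[Rcpp::export]]
List cpp_trim_adapters(CharacterVector seqs, CharacterVector adapters,
                       double error_rate, int min_overlap) {
  const int n = seqs.size();
  const int na = adapters.size();
  std::vector<std::string> ad(na);
  int mmax = 0;
  for (int k = 0; k < na; ++k) {
    ad[k] = as<std::string>(adapters[k]);
    mmax = std::max(mmax, (int) ad[k].size());
  }
  IntegerVector out_keep(n);    // number of 5' bases kept (= trim start, 0-based)
  IntegerVector out_err(n);     // errors in the winning match
  IntegerVector out_len(n);     // matched adapter length of the winning match
  IntegerVector out_ad(n);      // 1-based adapter index, 0 = no match
  std::vector<int> prev, cur, lastcol((size_t) mmax + 1);

  for (int r = 0; r < n; ++r) {
    std::string s = std::string(CHAR(STRING_ELT(seqs, r)));
    const int nlen = (int) s.size();
    int bestE = INT_MAX, bestS = -1, bestA = -1, bestL = -1;
    for (int k = 0; k < na; ++k) {
      const std::string& A = ad[k];
      const int m = (int) A.size();
      const int allow_full = allowed_errors(error_rate, m);
      for (int st = 0; st < nlen; ++st) {
        const int Ls = nlen - st;
        prev.assign((size_t) Ls + 1, 0);
        for (int j = 0; j <= Ls; ++j) prev[j] = j;
        int rowmin_m = INT_MAX;
        for (int i = 1; i <= m; ++i) {
          cur.assign((size_t) Ls + 1, 0);
          cur[0] = i;
          const char ac = A[(size_t) i - 1];
          for (int j = 1; j <= Ls; ++j) {
            const char rc = s[(size_t) st + j - 1];
            int v = prev[j - 1] + (base_match(ac, rc) ? 0 : 1);
            const int del = prev[j] + 1;
            const int ins = cur[j - 1] + 1;
            if (del < v) v = del;
            if (ins < v) v = ins;
            cur[j] = v;
          }
          lastcol[i] = cur[Ls];
          if (i == m) {
            for (int j = 0; j <= Ls; ++j)
              if (cur[j] < rowmin_m) rowmin_m = cur[j];
          }
          prev.swap(cur);
        }
        // Candidate (a): full adapter, internal occurrence.
        if (m >= min_overlap && rowmin_m <= allow_full) {
          const int E = rowmin_m;
          bool better = E < bestE ||
            (E == bestE && (st < bestS ||
              (st == bestS && (k < bestA ||
                (k == bestA && m > bestL)))));
          if (better) { bestE = E; bestS = st; bestA = k; bestL = m; }
        }
        // Candidates (b): adapter prefix vs the whole suffix.
        for (int L = min_overlap; L <= m; ++L) {
          const int E = lastcol[L];
          if (E > allowed_errors(error_rate, L)) continue;
          bool better = E < bestE ||
            (E == bestE && (st < bestS ||
              (st == bestS && (k < bestA ||
                (k == bestA && L > bestL)))));
          if (better) { bestE = E; bestS = st; bestA = k; bestL = L; }
        }
      }
    }
    if (bestA < 0) {
      out_keep[r] = nlen; out_err[r] = 0; out_len[r] = 0; out_ad[r] = 0;
    } else {
      out_keep[r] = bestS; out_err[r] = bestE; out_len[r] = bestL;
      out_ad[r] = bestA + 1;
    }
  }
  return List::create(_["keep"] = out_keep, _["errors"] = out_err,
                      _["matched_len"] = out_len, _["adapter"] = out_ad);
}

// All occurrences of `query` as a substring of any reference with at most
// max_mm mismatches (substitutions only). Rows sorted by (mismatches,
// reference order, start).
// [[Rcpp::export]]
IntegerMatrix cpp_map_all(std::string query, CharacterVector refs, int max_mm) {
  const int q = (int) query.size();
  struct Hit { int mm, ref, start; };
  std::vector<Hit> hits;
  for (int rix = 0; rix < refs.size(); ++rix) {
    std::string ref = std::string(CHAR(STRING_ELT(refs, rix)));
    const int L = (int) ref.size();
    for (int st = 0; st + q <= L; ++st) {
      int mm = 0;
      for (int j = 0; j < q; ++j) {
        if (!base_match(query[(size_t) j], ref[(size_t) st + j])) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) hits.push_back({mm, rix, st});
    }
  }
  std::stable_sort(hits.begin(), hits.end(),
                   [](const Hit& a, const Hit& b) { return a.mm < b.mm; });
  IntegerMatrix out((int) hits.size(), 3);
  for (int i = 0; i < (int) hits.size(); ++i) {
    out(i, 0) = hits[(size_t) i].ref + 1;  // 1-based reference index
    out(i, 1) = hits[(size_t) i].start;    // 0-based offset
    out(i, 2) = hits[(size_t) i].mm;
  }
  colnames(out) = CharacterVector::create("ref", "start", "mismatches");
  return out;
}

// Best hit per query under the (mismatches, reference order, start)
// ordering; ref column is 0 when a query has no hit.
// [[Rcpp::export]]
IntegerMatrix cpp_map_best(CharacterVector queries, CharacterVector refs,
                           int max_mm) {
  const int nq = queries.size();
  const int nr = refs.size();
  std::vector<std::string> rf((size_t) nr);
  for (int i = 0; i < nr; ++i) rf[(size_t) i] = as<std::string>(refs[i]);
  IntegerMatrix out(nq, 3);
  for (int qi = 0; qi < nq; ++qi) {
    std::string query = std::string(CHAR(STRING_ELT(queries, qi)));
    const int q = (int) query.size();
    int bmm = INT_MAX, bref = -1, bst = -1;
    for (int rix = 0; rix < nr && bmm > 0; ++rix) {
      const std::string& ref = rf[(size_t) rix];
      const int L = (int) ref.size();
      for (int st = 0; st + q <= L; ++st) {
        int mm = 0;
        for (int j = 0; j < q; ++j) {
          if (!base_match(query[(size_t) j], ref[(size_t) st + j])) {
            if (++mm >= bmm || mm > max_mm) break;
          }
        }
        if (mm <= max_mm && mm < bmm) {
          bmm = mm; bref = rix; bst = st;
          if (bmm == 0) break;
        }
      }
    }
    if (bref < 0) {
      out(qi, 0) = 0; out(qi, 1) = -1; out(qi, 2) = -1;
    } else {
      out(qi, 0) = bref + 1; out(qi, 1) = bst; out(qi, 2) = bmm;
    }
  }
  colnames(out) = CharacterVector::create("ref", "start", "mismatches");
  return out;
}
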