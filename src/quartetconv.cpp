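#include <Rcpp.h>
using namespace Rcpp;

// Ruzzo-Tompa: all maximal-scoring subsequences of a score array.
// Returns a 3-column matrix (start, end, score), 1-based inclusive,
// sorted by start. Only segments with positive total score are maximal.
// [[Rcpp::export(name = ".rt_segments_cpp")]]
NumericMatrix rt_segments_cpp(NumericVector scores) {
  int n = scores.size();
  // working list of candidate subsequences: start idx, end idx, L, R
  std::vector<int> st, en;
  std::vector<double> Lv, Rv;
  double cum = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = scores[i];
    if (s <= 0) { cum += s; continue; }
    double L = cum;       // cumulative before this element
    cum += s;
    double R = cum;       // cumulative after
    int cst = i, cen = i;
    // integrate into the list (Ruzzo & Tompa 1999, steps 1-4)
    for (;;) {
      // find max j with Lv[j] < L (search from right)
      int j = (int)st.size() - 1;
      while (j >= 0 && Lv[j] >= L) --j;
      if (j < 0 || Rv[j] >= R) {
        // no such j, or I_j already dominates: append as new candidate
        st.push_back(cst); en.push_back(cen);
        Lv.push_back(L); Rv.push_back(R);
        break;
      }
      // merge: extend I_j to include current, drop I_{j+1..}
      cst = st[j];
      L = Lv[j];
      st.resize(j); en.resize(j); Lv.resize(j); Rv.resize(j);
    }
  }
  int k = st.size();
  NumericMatrix out(k, 3);
  for (int i = 0; i < k; ++i) {
    out(i, 0) = st[i] + 1;
    out(i, 1) = en[i] + 1;
    out(i, 2) = Rv[i] - Lv[i];
  }
  colnames(out) = CharacterVector::create("start", "end", "score");
  return out;
}

// Best (max) Ruzzo-Tompa segment score with span >= min_len on B
// column-resampled replicates of the score array. Uses the R RNG.
// Replicates with no qualifying segment score -Inf.
// [[Rcpp::export(name = ".boot_max_seg_cpp")]]
NumericVector boot_max_seg_cpp(NumericVector scores, int B, int min_len) {
  int n = scores.size();
  NumericVector out(B);
  NumericVector resamp(n);
  std::vector<int> st;
  std::vector<double> Lv, Rv;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int idx = (int)(unif_rand() * n);
      if (idx == n) idx = n - 1;
      resamp[i] = scores[idx];
    }
    st.clear(); Lv.clear(); Rv.clear();
    std::vector<int> en;
    double cum = 0.0, best = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double s = resamp[i];
      if (s <= 0) { cum += s; continue; }
      double L = cum;
      cum += s;
      double R = cum;
      int cst = i, cen = i;
      for (;;) {
        int j = (int)st.size() - 1;
        while (j >= 0 && Lv[j] >= L) --j;
        if (j < 0 || Rv[j] >= R) {
          st.push_back(cst); en.push_back(cen);
          Lv.push_back(L); Rv.push_back(R);
          break;
        }
        cst = st[j];
        L = Lv[j];
        st.resize(j); en.resize(j); Lv.resize(j); Rv.resize(j);
      }
    }
    for (size_t i = 0; i < st.size(); ++i) {
      if (en[i] - st[i] + 1 >= min_len) {
        double sc = Rv[i] - Lv[i];
        if (sc > best) best = sc;
      }
    }
    out[b] = best;
  }
  return out;
}

// Codon-sequence evolution along one branch.
// codons: 0-based codon indices (16*b1 + 4*b2 + b3; bases A,C,G,T = 0..3).
// d: expected synonymous substitutions per synonymous site on the branch.
// omega: relative fixation probability of nonsynonymous changes.
// aa: amino-acid class per codon (stop codons flagged by is_stop).
// Mutations are proposed per nucleotide position as a Poisson process with
// mean d per position; proposals to stop codons are rejected, synonymous
// proposals always fix, nonsynonymous fix with probability omega. Under
// this scheme the expected NG86 synonymous distance of the branch is d.
// Uses the R RNG.
// [[Rcpp::export(name = ".evolve_codons_cpp")]]
IntegerVector evolve_codons_cpp(IntegerVector codons, double d, double omega,
                                IntegerVector aa, LogicalVector is_stop) {
  int n = codons.size();
  IntegerVector out = clone(codons);
  static const int place[3] = {16, 4, 1};
  for (int i = 0; i < n; ++i) {
    int nprop = (int)R::rpois(3.0 * d);
    for (int k = 0; k < nprop; ++k) {
      int cur = out[i];
      int pos = (int)(unif_rand() * 3.0); if (pos == 3) pos = 2;
      int base = (cur / place[pos]) % 4;
      int shift = 1 + (int)(unif_rand() * 3.0); if (shift == 4) shift = 3;
      int nb = (base + shift) % 4;
      int cand = cur + (nb - base) * place[pos];
      if (is_stop[cand]) continue;
      if (aa[cand] == aa[cur]) {
        out[i] = cand;
      } else if (unif_rand() < omega) {
        out[i] = cand;
      }
    }
  }
  return out;
}
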