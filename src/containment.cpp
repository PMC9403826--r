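#include <Rcpp.h>
using namespace Rcpp;

// Sequences and patterns arrive integer-encoded: every item is its rank in
// the database's canonical alphabet (variable name, then bin index), so
// integer order coincides with canonical item order.  A sequence is a list
// of day itemsets, a pattern a list of itemsets; all itemsets are sorted
// ascending.  NA codes mark pattern items absent from the alphabet: they
// can never match.

static bool subset_sorted(const IntegerVector& a, const IntegerVector& b) {
  int j = 0, nb = b.size();
  for (int i = 0; i < a.size(); ++i) {
    int x = a[i];
    if (x == NA_INTEGER) return false;
    while (j < nb && b[j] < x) ++j;
    if (j >= nb || b[j] != x) return false;
    ++j;
  }
  return true;
}

// Greedy earliest embedding.  Returns the 0-based day index at which the
// last pattern itemset matches, or -2 when the pattern does not embed.
// Greedy matching is exact for subsequence containment: mapping each
// itemset to the earliest admissible day never forecloses a later match.
static int greedy_end_day(const List& days, const List& pat) {
  int d = 0, nd = days.size(), last = -1;
  for (int k = 0; k < pat.size(); ++k) {
    IntegerVector is = pat[k];
    bool ok = false;
    while (d < nd) {
      IntegerVector day = days[d];
      ++d;
      if (subset_sorted(is, day)) { ok = true; last = d - 1; break; }
    }
    if (!ok) return -2;
  }
  return last;
}

// [[Rcpp::export]]
LogicalVector cpp_contains_many(List seqs, List pattern) {
  int n = seqs.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    List days = seqs[i];
    out[i] = greedy_end_day(days, pattern) != -2;
  }
  return out;
}

static bool day_has(const IntegerVector& day, int x) {
  int lo = 0, hi = day.size() - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (day[mid] == x) return true;
    if (day[mid] < x) lo = mid + 1; else hi = mid - 1;
  }
  return false;
}

// Batch support counting for all one-item extensions of `pattern` over the
// sequences indexed by `cover` (1-based).  For an S-extension it suffices
// to know the greedy (earliest) end day e of the parent embedding: the
// child embeds iff the new item occurs on any day > e.  I-extensions
// modify the final itemset, so they are re-checked in full.
// [[Rcpp::export]]
List cpp_extend_covers(List seqs, IntegerVector cover, List pattern,
                       IntegerVector s_items, IntegerVector i_items) {
  int nc = cover.size(), ns = s_items.size(), ni = i_items.size();
  std::vector< std::vector<int> > scov(ns), icov(ni);

  List ipat(pattern.size());
  for (int k = 0; k < pattern.size(); ++k) ipat[k] = pattern[k];

  for (int c = 0; c < nc; ++c) {
    int si = cover[c];                     // 1-based index into seqs
    List days = seqs[si - 1];
    int e = greedy_end_day(days, pattern); // -1 for the empty pattern
    if (e == -2) continue;                 // parent not contained

    if (ns > 0) {
      int nd = days.size();
      for (int j = 0; j < ns; ++j) {
        int x = s_items[j];
        if (x == NA_INTEGER) continue;
        for (int d = e + 1; d < nd; ++d) {
          IntegerVector day = days[d];
          if (day_has(day, x)) { scov[j].push_back(si); break; }
        }
      }
    }

    if (ni > 0 && pattern.size() > 0) {
      IntegerVector last = pattern[pattern.size() - 1];
      for (int j = 0; j < ni; ++j) {
        int x = i_items[j];
        if (x == NA_INTEGER) continue;
        IntegerVector ext(last.size() + 1);
        for (int t = 0; t < last.size(); ++t) ext[t] = last[t];
        ext[last.size()] = x;              // x > max(last): stays sorted
        ipat[ipat.size() - 1] = ext;
        if (greedy_end_day(days, ipat) != -2) icov[j].push_back(si);
      }
      ipat[ipat.size() - 1] = last;
    }
  }

  List sout(ns), iout(ni);
  for (int j = 0; j < ns; ++j) sout[j] = wrap(scov[j]);
  for (int j = 0; j < ni; ++j) iout[j] = wrap(icov[j]);
  return List::create(Named("s_covers") = sout, Named("i_covers") = iout);
}
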