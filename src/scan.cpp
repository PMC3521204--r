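#include <Rcpp.h>
#include <set>
#include <tuple>
using namespace Rcpp;

// Base encoding used throughout: A=0, C=1, G=2, T=3, N=4.
// A position pair (tr, vr) is a "hard" mismatch when the bases differ and the
// TR base is not the wildcard, or when either base is N (N matches nothing).
static inline bool hard_mismatch(int tr_base, int vr_base, int wildcard) {
    if (tr_base == 4 || vr_base == 4) return true;
    if (tr_base == wildcard) return false;
    return tr_base != vr_base;
}

// Seed-and-extend repeat scan. Every window start (step increments) is taken
// as a TR candidate; every placement at offset >= window (so that maximally
// extended intervals can stay disjoint) is checked for a wildcard-tolerant
// match, then extended greedily leftward first and rightward second, one
// position at a time, while the match rule holds and neither interval crosses
// a region boundary or the other interval. Distinct maximal pairs are
// returned (0-based starts; converted to 1-based in R).
// [[Rcpp::export]]
DataFrame scan_pairs_cpp(IntegerVector seq, int window, int step, int wildcard) {
    int L = seq.size();
    std::vector<int> s(seq.begin(), seq.end());
    std::set<std::tuple<int, int, int> > found; // (tr_start, vr_start, len)
    if (L >= window) {
        const int *sp = s.data();
        for (int t = 0; t + window <= L; t += step) {
            for (int v = 0; v + window <= L; ++v) {
                int d = v > t ? v - t : t - v;
                if (d < window) continue; // overlapping seed cannot yield disjoint repeats
                bool ok = true;
                for (int k = 0; k < window; ++k) {
                    if (hard_mismatch(sp[t + k], sp[v + k], wildcard)) { ok = false; break; }
                }
                if (!ok) continue;
                int ts = t, vs = v, len = window;
                // leftward, then rightward; len may never exceed d (disjointness)
                while (len < d && ts > 0 && vs > 0 &&
                       !hard_mismatch(sp[ts - 1], sp[vs - 1], wildcard)) {
                    --ts; --vs; ++len;
                }
                while (len < d && ts + len < L && vs + len < L &&
                       !hard_mismatch(sp[ts + len], sp[vs + len], wildcard)) {
                    ++len;
                }
                found.insert(std::make_tuple(ts, vs, len));
            }
        }
    }
    int n = found.size();
    IntegerVector tr_start(n), vr_start(n), lens(n);
    int i = 0;
    for (std::set<std::tuple<int, int, int> >::const_iterator it = found.begin();
         it != found.end(); ++it, ++i) {
        tr_start[i] = std::get<0>(*it);
        vr_start[i] = std::get<1>(*it);
        lens[i] = std::get<2>(*it);
    }
    return DataFrame::create(_["tr_start"] = tr_start,
                             _["vr_start"] = vr_start,
                             _["length"] = lens);
}

// Single-pair maximal extension (exposed for extend_match()).
// [[Rcpp::export]]
IntegerVector extend_pair_cpp(IntegerVector seq, int tr_start, int vr_start,
                              int length, int wildcard) {
    int L = seq.size();
    int d = vr_start > tr_start ? vr_start - tr_start : tr_start - vr_start;
    int ts = tr_start, vs = vr_start, len = length;
    while (len < d && ts > 0 && vs > 0 &&
           !hard_mismatch(seq[ts - 1], seq[vs - 1], wildcard)) {
        --ts; --vs; ++len;
    }
    while (len < d && ts + len < L && vs + len < L &&
           !hard_mismatch(seq[ts + len], seq[vs + len], wildcard)) {
        ++len;
    }
    return IntegerVector::create(ts, vs, len);
}
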