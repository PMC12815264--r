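#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <tuple>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Hamming count with optional early abandon (maxMismatch < 0 disables it).
static long hamming_count(const char* a, const char* b, long n, long maxMismatch) {
    long mism = 0;
    for (long i = 0; i < n; ++i) {
        if (a[i] != b[i]) {
            ++mism;
            if (maxMismatch >= 0 && mism > maxMismatch) return mism;
        }
    }
    return mism;
}

// Plain Levenshtein distance, two-row DP.
static long edit_distance(const std::string& a, const std::string& b) {
    const size_t n = a.size(), m = b.size();
    std::vector<long> prev(m + 1), cur(m + 1);
    for (size_t j = 0; j <= m; ++j) prev[j] = (long)j;
    for (size_t i = 1; i <= n; ++i) {
        cur[0] = (long)i;
        for (size_t j = 1; j <= m; ++j) {
            long sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            long del = prev[j] + 1;
            long ins = cur[j - 1] + 1;
            cur[j] = std::min(sub, std::min(del, ins));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export(name = ".hammingCount")]]
double hammingCountCpp(std::string a, std::string b) {
    if (a.size() != b.size()) stop("sequences must have equal length");
    return (double)hamming_count(a.c_str(), b.c_str(), (long)a.size(), -1);
}

// [[Rcpp::export(name = ".editDistance")]]
double editDistanceCpp(std::string a, std::string b) {
    return (double)edit_distance(a, b);
}

// Identity between two nucleotide strings: equal lengths use Hamming,
// unequal lengths fall back to Levenshtein over the longer length.
static double seq_identity(const std::string& a, const std::string& b) {
    if (a.empty() || b.empty()) stop("empty sequence");
    if (a.size() == b.size()) {
        long h = hamming_count(a.c_str(), b.c_str(), (long)a.size(), -1);
        return 1.0 - (double)h / (double)a.size();
    }
    size_t mx = std::max(a.size(), b.size());
    return 1.0 - (double)edit_distance(a, b) / (double)mx;
}

// [[Rcpp::export(name = ".seqIdentity")]]
double seqIdentityCpp(std::string a, std::string b) { return seq_identity(a, b); }

// Greedy incremental clustering. `seqs` must already be ordered by the
// caller (descending length, ties broken upstream). Each sequence joins the
// first existing cluster whose REPRESENTATIVE satisfies identity >= idThr and
// min(len)/max(len) >= cov; otherwise it founds a new cluster. Returns
// 1-based cluster ids in input order; the representative of cluster c is the
// first sequence assigned to it.
// [[Rcpp::export(name = ".greedyCluster")]]
IntegerVector greedyClusterCpp(CharacterVector seqs, double idThr, double cov) {
    int n = seqs.size();
    IntegerVector out(n);
    std::vector<std::string> sv(n);
    for (int i = 0; i < n; ++i) sv[i] = std::string(seqs[i]);
    std::vector<int> reps;  // indices of representatives
    const double eps = 1e-12;
    for (int i = 0; i < n; ++i) {
        int assigned = 0;
        const std::string& s = sv[i];
        long slen = (long)s.size();
        for (size_t r = 0; r < reps.size(); ++r) {
            const std::string& rep = sv[reps[r]];
            long rlen = (long)rep.size();
            long mn = std::min(slen, rlen), mx = std::max(slen, rlen);
            if ((double)mn / (double)mx < cov - eps) continue;
            double id;
            if (slen == rlen) {
                // early abandon once identity can no longer reach idThr
                long maxMism = (long)std::floor((1.0 - idThr) * (double)slen + eps);
                long h = hamming_count(s.c_str(), rep.c_str(), slen, maxMism);
                if (h > maxMism) continue;
                id = 1.0 - (double)h / (double)slen;
            } else {
                id = 1.0 - (double)edit_distance(s, rep) / (double)mx;
            }
            if (id >= idThr - eps) {
                out[i] = (int)r + 1;
                assigned = 1;
                break;
            }
        }
        if (!assigned) {
            reps.push_back(i);
            out[i] = (int)reps.size();
        }
    }
    return out;
}

// ---- seed-and-extend identity segments -------------------------------------

static inline int base_code(char c) {
    switch (c) {
        case 'A': return 0;
        case 'C': return 1;
        case 'G': return 2;
        case 'T': return 3;
        default: return -1;
    }
}

struct Seg {
    int ca, sa, ea, cb, sb, eb;
    double identity;
    long score;
};

// Ungapped X-drop extension from an exact k-mer seed. Positions are 0-based;
// the returned interval is half-open on both sequences. Extension uses an
// internal mismatch penalty of 3 so that runs below ~75% identity descend
// and trigger the X-drop (a +1/-1 walk would drift upward through any
// region above 50% identity and never terminate); the reported score stays
// matches - mismatches.
static const long EXT_MISMATCH_PENALTY = 3;

static bool extend_seed(const std::string& A, const std::string& B, long sa, long sb,
                        int k, long xdrop, long min_len, double min_id, Seg& out) {
    // right extension from seed end
    long score = k, best = k;
    long ea = sa + k, eb = sb + k;
    long bestEa = ea;
    while (ea < (long)A.size() && eb < (long)B.size()) {
        score += (A[ea] == B[eb]) ? 1 : -EXT_MISMATCH_PENALTY;
        ++ea;
        ++eb;
        if (score > best) {
            best = score;
            bestEa = ea;
        }
        if (score < best - xdrop) break;
    }
    // left extension from seed start
    long scoreL = best, bestL = best;
    long ia = sa, ib = sb, bestSa = sa;
    while (ia > 0 && ib > 0) {
        --ia;
        --ib;
        scoreL += (A[ia] == B[ib]) ? 1 : -EXT_MISMATCH_PENALTY;
        if (scoreL > bestL) {
            bestL = scoreL;
            bestSa = ia;
        }
        if (scoreL < bestL - xdrop) break;
    }
    long fa = bestSa, faEnd = bestEa;
    long len = faEnd - fa;
    long fb = sb - (sa - fa);
    long matches = 0;
    for (long i = 0; i < len; ++i)
        if (A[fa + i] == B[fb + i]) ++matches;
    out.sa = (int)fa;
    out.ea = (int)faEnd;
    out.sb = (int)fb;
    out.eb = (int)(fb + len);
    out.identity = (double)matches / (double)len;
    out.score = 2 * matches - len;  // matches - mismatches
    return len >= min_len && out.identity >= min_id - 1e-12;
}

// Find ungapped high-identity segments between two sets of contig sequences
// by exact k-mer seeding and X-drop extension. Deterministic for fixed input.
// [[Rcpp::export(name = ".findSegments")]]
DataFrame findSegmentsCpp(CharacterVector contigsA, CharacterVector contigsB, int k,
                          int minLen, double minId, int xdrop) {
    std::vector<std::string> A(contigsA.size()), B(contigsB.size());
    for (int i = 0; i < contigsA.size(); ++i) A[i] = std::string(contigsA[i]);
    for (int i = 0; i < contigsB.size(); ++i) B[i] = std::string(contigsB[i]);

    // index k-mers of A
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> idx;
    for (size_t c = 0; c < A.size(); ++c) {
        const std::string& s = A[c];
        if ((long)s.size() < k) continue;
        uint64_t h = 0;
        int run = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int code = base_code(s[i]);
            if (code < 0) {
                run = 0;
                h = 0;
                continue;
            }
            h = ((h << 2) | (uint64_t)code) & mask;
            if (++run >= k) idx[h].push_back({(int)c, (int)(i + 1 - k)});
        }
    }

    // covered intervals per (contigA, contigB, diagonal) to avoid re-extending
    // seeds inside an already-processed extension
    std::map<std::tuple<int, int, long>, std::vector<std::pair<int, int>>> covered;
    std::vector<Seg> segs;

    for (size_t cb = 0; cb < B.size(); ++cb) {
        const std::string& s = B[cb];
        if ((long)s.size() < k) continue;
        uint64_t h = 0;
        int run = 0;
        for (size_t i = 0; i < s.size(); ++i) {
            int code = base_code(s[i]);
            if (code < 0) {
                run = 0;
                h = 0;
                continue;
            }
            h = ((h << 2) | (uint64_t)code) & mask;
            if (++run < k) continue;
            long posB = (long)(i + 1 - k);
            auto hit = idx.find(h);
            if (hit == idx.end()) continue;
            for (auto& pr : hit->second) {
                int ca = pr.first;
                long posA = pr.second;
                long diag = posA - posB;
                auto key = std::make_tuple(ca, (int)cb, diag);
                bool skip = false;
                auto cit = covered.find(key);
                if (cit != covered.end()) {
                    for (auto& iv : cit->second) {
                        if (posA >= iv.first && posA + k <= iv.second) {
                            skip = true;
                            break;
                        }
                    }
                }
                if (skip) continue;
                Seg sg;
                sg.ca = ca;
                sg.cb = (int)cb;
                bool ok = extend_seed(A[ca], s, posA, posB, k, xdrop, minLen, minId, sg);
                covered[key].push_back({sg.sa, sg.ea});
                if (ok) segs.push_back(sg);
            }
        }
    }

    int n = (int)segs.size();
    IntegerVector ca(n), sa(n), ea(n), cbv(n), sb(n), eb(n), len(n);
    NumericVector ident(n), score(n);
    for (int i = 0; i < n; ++i) {
        ca[i] = segs[i].ca + 1;
        sa[i] = segs[i].sa;
        ea[i] = segs[i].ea;
        cbv[i] = segs[i].cb + 1;
        sb[i] = segs[i].sb;
        eb[i] = segs[i].eb;
        len[i] = segs[i].ea - segs[i].sa;
        ident[i] = segs[i].identity;
        score[i] = (double)segs[i].score;
    }
    return DataFrame::create(_["contig_a"] = ca, _["start_a"] = sa, _["end_a"] = ea,
                             _["contig_b"] = cbv, _["start_b"] = sb, _["end_b"] = eb,
                             _["length"] = len, _["identity"] = ident,
                             _["score"] = score);
}
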