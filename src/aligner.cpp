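#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Unit-cost Levenshtein distance, full dynamic programme.
static int lev(const std::string& a, const std::string& b) {
    const int n = a.size(), m = b.size();
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        for (int j = 1; j <= m; ++j) {
            int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// [[Rcpp::export]]
int cpp_levenshtein(std::string a, std::string b) { return lev(a, b); }

// All unordered pairwise Levenshtein distances of a sequence set.
// [[Rcpp::export]]
IntegerVector cpp_lev_pairs(CharacterVector seqs) {
    const int n = seqs.size();
    std::vector<std::string> s(n);
    for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
    IntegerVector out(n * (n - 1) / 2);
    int k = 0;
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) out[k++] = lev(s[i], s[j]);
    return out;
}

// Semi-global scan of a short pattern against read[lo..hi] (0-based,
// inclusive): pattern fully aligned, free start/end within the window.
// Returns best edit distance plus the 0-based start/end (inclusive)
// columns of the best alignment.
struct Hit { int dist, start, end; };

static Hit scan_window(const std::string& read, const std::string& pat,
                       int lo, int hi) {
    const int m = pat.size();
    Hit h; h.dist = INT_MAX; h.start = -1; h.end = -1;
    if (lo > hi) return h;
    const int W = hi - lo + 1;
    // D[i][j]: pattern[0..i) vs window[0..j); free leading window gap.
    std::vector<int> prev(W + 1), cur(W + 1);
    std::vector<int> sprev(W + 1), scur(W + 1); // alignment start column
    for (int j = 0; j <= W; ++j) { prev[j] = 0; sprev[j] = j; }
    for (int i = 1; i <= m; ++i) {
        cur[0] = i; scur[0] = 0;
        for (int j = 1; j <= W; ++j) {
            const char rc = read[lo + j - 1];
            int sub = prev[j - 1] + (pat[i - 1] == rc ? 0 : 1);
            int del = prev[j] + 1;   // consume pattern base
            int ins = cur[j - 1] + 1; // consume read base
            int best = sub, src = sprev[j - 1];
            if (del < best) { best = del; src = sprev[j]; }
            if (ins < best) { best = ins; src = scur[j - 1]; }
            cur[j] = best; scur[j] = src;
        }
        std::swap(prev, cur); std::swap(sprev, scur);
    }
    for (int j = 1; j <= W; ++j) {
        if (prev[j] < h.dist) {
            h.dist = prev[j];
            h.start = lo + sprev[j];
            h.end = lo + j - 1;
        }
    }
    return h;
}

// Align the fixed label scaffold (anchor + N-masked barcode slots +
// linkers) semi-globally against the trimmed read ('N' in the scaffold
// matches any read base at no cost; leading/trailing read bases are
// free) and report, via traceback, the read interval covered by each of
// the three masked slots. slot_start/slot_end give the scaffold
// coordinates (0-based, end exclusive) of the slots.
struct SlotPos { int start[3], end[3]; int dist; bool ok; };

static SlotPos locate_slots(const std::string& read,
                            const std::string& scaffold,
                            const int* slot_s, const int* slot_e) {
    const int m = scaffold.size(), n = read.size();
    SlotPos sp; sp.ok = false; sp.dist = INT_MAX;
    if (n == 0) return sp;
    // D has (m+1) x (n+1); keep full matrix for traceback
    std::vector<int> D((m + 1) * (n + 1));
    for (int j = 0; j <= n; ++j) D[j] = 0;           // free leading read
    for (int i = 1; i <= m; ++i) D[i * (n + 1)] = i;
    for (int i = 1; i <= m; ++i) {
        const char tc = scaffold[i - 1];
        for (int j = 1; j <= n; ++j) {
            int sub = D[(i - 1) * (n + 1) + j - 1] +
                ((tc == 'N' || tc == read[j - 1]) ? 0 : 1);
            int del = D[(i - 1) * (n + 1) + j] + 1;
            int ins = D[i * (n + 1) + j - 1] + 1;
            D[i * (n + 1) + j] = std::min(sub, std::min(del, ins));
        }
    }
    int jend = 0;
    for (int j = 0; j <= n; ++j)
        if (D[m * (n + 1) + j] < sp.dist) { sp.dist = D[m * (n + 1) + j]; jend = j; }
    // traceback, recording the read column at each scaffold row boundary
    std::vector<int> row_col(m + 1, -1);
    int i = m, j = jend;
    row_col[m] = j;
    while (i > 0) {
        const char tc = scaffold[i - 1];
        int cur = D[i * (n + 1) + j];
        if (j > 0 && cur == D[(i - 1) * (n + 1) + j - 1] +
            ((tc == 'N' || tc == read[j - 1]) ? 0 : 1)) { --i; --j; }
        else if (cur == D[(i - 1) * (n + 1) + j] + 1) { --i; }
        else { --j; continue; }   // read insertion: stay on same row
        row_col[i] = j;
    }
    for (int p = 0; p < 3; ++p) {
        sp.start[p] = row_col[slot_s[p]];
        sp.end[p] = row_col[slot_e[p]];
        if (sp.start[p] < 0 || sp.end[p] <= sp.start[p]) return sp;
    }
    sp.ok = true;
    return sp;
}

// First-round demultiplexing kernel, in two stages per read:
//   1. prescreen -- the scaffold alignment locates the three barcode
//      slots; each pool is scored against its located slot (+/- pad
//      bases) by semi-global alignment, and barcodes within one edit of
//      the slot's best form the candidate set;
//   2. full alignment -- every surviving candidate label (anchor +
//      bc1 + linker1 + bc2 + linker2 + bc3) is aligned against the
//      read region around the located label; the best-scoring label is
//      reported, with the margin to the best label differing in at
//      least one barcode.
// The refinement stage uses the linker/anchor context, so a wrong
// barcode that fits its 9 bp slot via spurious indels still loses on
// the full label.
// Returns a matrix with columns: b1,b2,b3 (1-based barcode index),
// label_dist (full-label edit distance), margin, umi_start (1-based,
// 0 if unknown), scaffold_dist.
// [[Rcpp::export]]
IntegerMatrix cpp_demux_round1(CharacterVector reads, List pools,
                               std::string scaffold,
                               IntegerVector slot_start,
                               IntegerVector slot_end,
                               int pad, int max_cand = 6, int band = 1) {
    const int n = reads.size();
    std::vector<std::vector<std::string> > bc(3);
    for (int p = 0; p < 3; ++p) {
        CharacterVector v = pools[p];
        bc[p].resize(v.size());
        for (int i = 0; i < v.size(); ++i) bc[p][i] = as<std::string>(v[i]);
    }
    int slot_s[3], slot_e[3];
    for (int p = 0; p < 3; ++p) { slot_s[p] = slot_start[p]; slot_e[p] = slot_end[p]; }
    const int anchor_len = slot_s[0];
    const std::string anchor = scaffold.substr(0, anchor_len);
    const std::string linker1 = scaffold.substr(slot_e[0], slot_s[1] - slot_e[0]);
    const std::string linker2 = scaffold.substr(slot_e[1], slot_s[2] - slot_e[1]);
    IntegerMatrix out(n, 7);
    for (int r = 0; r < n; ++r) {
        std::string rd = as<std::string>(reads[r]);
        const int L = rd.size();
        SlotPos sp = locate_slots(rd, scaffold, slot_s, slot_e);
        out(r, 6) = (sp.dist == INT_MAX) ? NA_INTEGER : sp.dist;
        if (!sp.ok) {
            for (int c = 0; c < 6; ++c) out(r, c) = NA_INTEGER;
            out(r, 4) = 0; out(r, 5) = 0;
            continue;
        }
        // stage 1: candidate barcodes per slot
        std::vector<int> cand[3];
        int slot_gap[3];
        for (int p = 0; p < 3; ++p) {
            int lo = sp.start[p] - pad, hi = sp.end[p] - 1 + pad;
            if (lo < 0) lo = 0;
            if (hi > L - 1) hi = L - 1;
            std::vector<int> dist(bc[p].size());
            int best = INT_MAX, second = INT_MAX;
            for (size_t b = 0; b < bc[p].size(); ++b) {
                dist[b] = scan_window(rd, bc[p][b], lo, hi).dist;
                if (dist[b] < best) { second = best; best = dist[b]; }
                else if (dist[b] < second) second = dist[b];
            }
            slot_gap[p] = (second == INT_MAX) ? 0 : second - best;
            std::vector<std::pair<int, int> > inband;  // (dist, index)
            for (size_t b = 0; b < bc[p].size(); ++b)
                if (dist[b] <= best + band)
                    inband.push_back(std::make_pair(dist[b], (int)b));
            std::sort(inband.begin(), inband.end());
            for (size_t b = 0; b < inband.size() &&
                     (int)cand[p].size() < max_cand; ++b)
                cand[p].push_back(inband[b].second);
        }
        // stage 2: full-label alignment of all candidate combinations
        int wlo = sp.start[0] - anchor_len - 8, whi = sp.end[2] - 1 + 8;
        if (wlo < 0) wlo = 0;
        if (whi > L - 1) whi = L - 1;
        int best = INT_MAX, second = INT_MAX;
        int bi[3] = {-1, -1, -1};
        for (size_t a = 0; a < cand[0].size(); ++a)
            for (size_t b = 0; b < cand[1].size(); ++b)
                for (size_t c = 0; c < cand[2].size(); ++c) {
                    std::string label = anchor + bc[0][cand[0][a]] +
                        linker1 + bc[1][cand[1][b]] +
                        linker2 + bc[2][cand[2][c]];
                    int d = scan_window(rd, label, wlo, whi).dist;
                    if (d < best) {
                        second = best;
                        best = d;
                        bi[0] = cand[0][a]; bi[1] = cand[1][b];
                        bi[2] = cand[2][c];
                    } else if (d < second) second = d;
                }
        if (bi[0] < 0) {
            for (int c = 0; c < 6; ++c) out(r, c) = NA_INTEGER;
            out(r, 4) = 0; out(r, 5) = 0;
            continue;
        }
        // a unique candidate combination has no enumerated competitor:
        // the margin is then the smallest slot-wise gap to the next
        // barcode, the prescreen's bound on any competing label
        int margin;
        if (second == INT_MAX)
            margin = std::min(slot_gap[0],
                              std::min(slot_gap[1], slot_gap[2]));
        else margin = second - best;
        out(r, 0) = bi[0] + 1; out(r, 1) = bi[1] + 1; out(r, 2) = bi[2] + 1;
        out(r, 3) = best;
        out(r, 4) = margin;
        out(r, 5) = sp.end[2] + 1;   // 1-based first base after bc3
    }
    colnames(out) = CharacterVector::create("b1", "b2", "b3", "label_dist",
                                            "margin", "umi_start",
                                            "scaffold_dist");
    return out;
}

// Per-pool hit collection for the rescue round: semi-global DP of every
// barcode against the whole read, keeping, per end column, the best
// (distance, barcode, start); hits with distance <= max_edits are
// thinned to non-overlapping local optima.
struct PoolHit { int dist, bc, start, end; };

static std::vector<PoolHit> pool_hits(const std::string& read,
                                      const std::vector<std::string>& bcs,
                                      int max_edits, int min_hit_margin) {
    const int n = read.size();
    std::vector<int> bestd(n + 1, INT_MAX), secondd(n + 1, INT_MAX),
        bestb(n + 1, -1), bests(n + 1, -1);
    for (size_t b = 0; b < bcs.size(); ++b) {
        const std::string& pat = bcs[b];
        const int m = pat.size();
        std::vector<int> prev(n + 1), cur(n + 1), sprev(n + 1), scur(n + 1);
        for (int j = 0; j <= n; ++j) { prev[j] = 0; sprev[j] = j; }
        for (int i = 1; i <= m; ++i) {
            cur[0] = i; scur[0] = 0;
            for (int j = 1; j <= n; ++j) {
                int sub = prev[j - 1] + (pat[i - 1] == read[j - 1] ? 0 : 1);
                int del = prev[j] + 1, ins = cur[j - 1] + 1;
                int best = sub, src = sprev[j - 1];
                if (del < best) { best = del; src = sprev[j]; }
                if (ins < best) { best = ins; src = scur[j - 1]; }
                cur[j] = best; scur[j] = src;
            }
            std::swap(prev, cur); std::swap(sprev, scur);
        }
        for (int j = 1; j <= n; ++j) {
            if (prev[j] < bestd[j]) {
                secondd[j] = bestd[j];
                bestd[j] = prev[j]; bestb[j] = (int)b; bests[j] = sprev[j];
            } else if (prev[j] < secondd[j]) secondd[j] = prev[j];
        }
    }
    std::vector<PoolHit> hits;
    for (int j = 1; j <= n; ++j) {
        if (bestd[j] > max_edits) continue;
        // ambiguous locus: another barcode fits nearly as well
        if (secondd[j] != INT_MAX && secondd[j] - bestd[j] < min_hit_margin)
            continue;
        PoolHit h; h.dist = bestd[j]; h.bc = bestb[j];
        h.start = bests[j]; h.end = j - 1;
        hits.push_back(h);
    }
    // thin to non-overlapping optima (greedy by distance)
    std::sort(hits.begin(), hits.end(),
              [](const PoolHit& a, const PoolHit& b) {
                  return a.dist < b.dist ||
                      (a.dist == b.dist && a.start < b.start);
              });
    std::vector<PoolHit> kept;
    for (size_t k = 0; k < hits.size(); ++k) {
        bool clash = false;
        for (size_t q = 0; q < kept.size(); ++q)
            if (hits[k].start <= kept[q].end && kept[q].start <= hits[k].end) {
                clash = true; break;
            }
        if (!clash) kept.push_back(hits[k]);
        if (kept.size() >= 12) break;
    }
    return kept;
}

// Second-round rescue kernel: all three pools are scanned over the
// whole read; a read is rescued iff one barcode hit from each pool
// occurs in order with inter-barcode gaps within gap_window of the
// linker lengths. Among consistent triples the smallest total distance
// wins, and the winning triple is verified by aligning its full
// composed label (anchor + barcodes + linkers, from the scaffold)
// around the hit locus. Columns: b1,b2,b3 (1-based; NA if not
// rescued), dist (total barcode edits), umi_start (1-based),
// label_dist (full-label verification distance).
// [[Rcpp::export]]
IntegerMatrix cpp_demux_round2(CharacterVector reads, List pools,
                               int max_edits, int linker1_len,
                               int linker2_len, int gap_window,
                               int min_hit_margin,
                               std::string scaffold,
                               IntegerVector slot_start,
                               IntegerVector slot_end) {
    const int n = reads.size();
    std::vector<std::vector<std::string> > bc(3);
    for (int p = 0; p < 3; ++p) {
        CharacterVector v = pools[p];
        bc[p].resize(v.size());
        for (int i = 0; i < v.size(); ++i) bc[p][i] = as<std::string>(v[i]);
    }
    const int anchor_len = slot_start[0];
    const std::string anchor = scaffold.substr(0, anchor_len);
    const std::string linker1 = scaffold.substr(slot_end[0],
                                                slot_start[1] - slot_end[0]);
    const std::string linker2 = scaffold.substr(slot_end[1],
                                                slot_start[2] - slot_end[1]);
    IntegerMatrix out(n, 6);
    for (int r = 0; r < n; ++r) {
        std::string rd = as<std::string>(reads[r]);
        std::vector<PoolHit> h1 = pool_hits(rd, bc[0], max_edits, min_hit_margin);
        std::vector<PoolHit> h2 = pool_hits(rd, bc[1], max_edits, min_hit_margin);
        std::vector<PoolHit> h3 = pool_hits(rd, bc[2], max_edits, min_hit_margin);
        int best = INT_MAX; PoolHit b1, b2, b3;
        for (size_t a = 0; a < h1.size(); ++a)
            for (size_t b = 0; b < h2.size(); ++b) {
                int gap1 = h2[b].start - h1[a].end - 1;
                if (h2[b].start <= h1[a].end ||
                    gap1 < linker1_len - gap_window ||
                    gap1 > linker1_len + gap_window) continue;
                for (size_t c = 0; c < h3.size(); ++c) {
                    int gap2 = h3[c].start - h2[b].end - 1;
                    if (h3[c].start <= h2[b].end ||
                        gap2 < linker2_len - gap_window ||
                        gap2 > linker2_len + gap_window) continue;
                    int tot = h1[a].dist + h2[b].dist + h3[c].dist;
                    if (tot < best) {
                        best = tot; b1 = h1[a]; b2 = h2[b]; b3 = h3[c];
                    }
                }
            }
        if (best == INT_MAX) {
            for (int c = 0; c < 6; ++c) out(r, c) = NA_INTEGER;
        } else {
            out(r, 0) = b1.bc + 1; out(r, 1) = b2.bc + 1;
            out(r, 2) = b3.bc + 1;
            out(r, 3) = best;
            out(r, 4) = b3.end + 2;  // 1-based first base after bc3
            std::string label = anchor + bc[0][b1.bc] + linker1 +
                bc[1][b2.bc] + linker2 + bc[2][b3.bc];
            int wlo = b1.start - anchor_len - 5, whi = b3.end + 5;
            if (wlo < 0) wlo = 0;
            if (whi > (int)rd.size() - 1) whi = rd.size() - 1;
            out(r, 5) = scan_window(rd, label, wlo, whi).dist;
        }
    }
    colnames(out) = CharacterVector::create("b1", "b2", "b3", "dist",
                                            "umi_start", "label_dist");
    return out;
}

// Longest run of a given base inside read[lo..hi] (0-based inclusive).
// [[Rcpp::export]]
int cpp_longest_run(std::string read, char base, int lo, int hi) {
    int best = 0, cur = 0;
    if (lo < 0) lo = 0;
    if (hi > (int)read.size() - 1) hi = read.size() - 1;
    for (int i = lo; i <= hi; ++i) {
        if (read[i] == base) { if (++cur > best) best = cur; }
        else cur = 0;
    }
    return best;
}
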