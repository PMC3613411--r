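#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise aligner (Gotoh three-state DP) for short DNA
// segments.  Scoring: match +1, mismatch -1; a gap of length L costs
// open + L * extend (defaults 4 and 1).  'N' never matches anything.
//
// mode 0 ("global"): both sequences aligned end to end.
// mode 1 ("fit"):    the reference is aligned globally, but leading and
//                    trailing target bases are free -- used to place an
//                    exon (plus intronic flanks) inside a larger locus.
//
// Tie-break at equal score: diagonal (match/mismatch) is preferred over
// a gap in the target, which is preferred over a gap in the reference;
// in fit mode the leftmost maximal end column is taken.  The traceback
// is therefore fully deterministic.

static const double NEG = -1e15;

// state codes for traceback provenance
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_START = 3 };

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string ref, std::string tgt, int mode,
                 double match = 1.0, double mismatch = -1.0,
                 double gap_open = 4.0, double gap_extend = 1.0) {
    const int m = ref.size(), n = tgt.size();
    if (m == 0 || n == 0)
        stop("empty sequence passed to the aligner");

    // M: ends in an aligned pair; X: ends with gap in target (consumes
    // reference); Y: ends with gap in reference (consumes target).
    std::vector<double> M((m + 1) * (n + 1), NEG);
    std::vector<double> X((m + 1) * (n + 1), NEG);
    std::vector<double> Y((m + 1) * (n + 1), NEG);
    std::vector<unsigned char> pM((m + 1) * (n + 1), 0);
    std::vector<unsigned char> pX((m + 1) * (n + 1), 0);
    std::vector<unsigned char> pY((m + 1) * (n + 1), 0);
    const int W = n + 1;
#define AT(i, j) ((i) * W + (j))

    M[AT(0, 0)] = 0.0;
    pM[AT(0, 0)] = FROM_START;
    for (int i = 1; i <= m; ++i) {
        X[AT(i, 0)] = -(gap_open + gap_extend * i);
        pX[AT(i, 0)] = (i == 1) ? FROM_M : FROM_X;
    }
    if (mode == 1) {
        // free leading target bases: a fresh start at any column
        for (int j = 1; j <= n; ++j) {
            M[AT(0, j)] = 0.0;
            pM[AT(0, j)] = FROM_START;
        }
    } else {
        for (int j = 1; j <= n; ++j) {
            Y[AT(0, j)] = -(gap_open + gap_extend * j);
            pY[AT(0, j)] = (j == 1) ? FROM_M : FROM_Y;
        }
    }

    for (int i = 1; i <= m; ++i) {
        const char rc = ref[i - 1];
        for (int j = 1; j <= n; ++j) {
            const char tc = tgt[j - 1];
            const double s =
                (rc == tc && rc != 'N' && rc != 'n') ? match : mismatch;
            // M: preference M > X > Y on ties
            {
                double bm = M[AT(i - 1, j - 1)];
                unsigned char pr = FROM_M;
                if (X[AT(i - 1, j - 1)] > bm) { bm = X[AT(i - 1, j - 1)]; pr = FROM_X; }
                if (Y[AT(i - 1, j - 1)] > bm) { bm = Y[AT(i - 1, j - 1)]; pr = FROM_Y; }
                M[AT(i, j)] = (bm <= NEG / 2) ? NEG : s + bm;
                pM[AT(i, j)] = pr;
            }
            // X: gap in target; prefer extension over fresh open on ties
            {
                double ext = X[AT(i - 1, j)] - gap_extend;
                double opn = M[AT(i - 1, j)] - (gap_open + gap_extend);
                if (ext >= opn) { X[AT(i, j)] = ext; pX[AT(i, j)] = FROM_X; }
                else            { X[AT(i, j)] = opn; pX[AT(i, j)] = FROM_M; }
                if (X[AT(i, j)] <= NEG / 2) X[AT(i, j)] = NEG;
            }
            // Y: gap in reference
            {
                double ext = Y[AT(i, j - 1)] - gap_extend;
                double opn = M[AT(i, j - 1)] - (gap_open + gap_extend);
                if (ext >= opn) { Y[AT(i, j)] = ext; pY[AT(i, j)] = FROM_Y; }
                else            { Y[AT(i, j)] = opn; pY[AT(i, j)] = FROM_M; }
                if (Y[AT(i, j)] <= NEG / 2) Y[AT(i, j)] = NEG;
            }
        }
    }

    // locate the end cell
    int ei = m, ej = n, state;
    double best;
    if (mode == 1) {
        best = NEG;
        state = FROM_M;
        ej = 1;
        for (int j = 1; j <= n; ++j) {
            // preference M > X at equal score; leftmost j wins ties
            if (M[AT(m, j)] > best) { best = M[AT(m, j)]; ej = j; state = FROM_M; }
            if (X[AT(m, j)] > best) { best = X[AT(m, j)]; ej = j; state = FROM_X; }
        }
    } else {
        best = M[AT(m, n)];
        state = FROM_M;
        if (X[AT(m, n)] > best) { best = X[AT(m, n)]; state = FROM_X; }
        if (Y[AT(m, n)] > best) { best = Y[AT(m, n)]; state = FROM_Y; }
    }

    // traceback
    std::string ra, ta;
    ra.reserve(m + n);
    ta.reserve(m + n);
    int i = ei, j = ej;
    int tgt_end = ej;
    while (i > 0 || (mode == 0 && j > 0)) {
        if (state == FROM_M) {
            unsigned char pr = pM[AT(i, j)];
            ra.push_back(ref[i - 1]);
            ta.push_back(tgt[j - 1]);
            --i; --j;
            state = pr;
            if (i == 0 && mode == 1) break;
            if (i == 0 && j == 0) break;
        } else if (state == FROM_X) {
            unsigned char pr = pX[AT(i, j)];
            ra.push_back(ref[i - 1]);
            ta.push_back('-');
            --i;
            state = pr;
            if (i == 0 && (mode == 1 || j == 0)) break;
        } else { // FROM_Y
            unsigned char pr = pY[AT(i, j)];
            ra.push_back('-');
            ta.push_back(tgt[j - 1]);
            --j;
            state = pr;
            if (i == 0 && j == 0) break;
        }
    }
    int tgt_start = j + 1; // first target base inside the aligned region
    std::reverse(ra.begin(), ra.end());
    std::reverse(ta.begin(), ta.end());

    return List::create(_["ref_aln"] = ra, _["tgt_aln"] = ta,
                        _["score"] = best, _["tgt_start"] = tgt_start,
                        _["tgt_end"] = tgt_end);
#undef AT
}
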