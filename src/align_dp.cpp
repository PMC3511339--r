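#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdlib>
using namespace Rcpp;

// Global affine-gap (Gotoh) alignment with optional banding.
//
// Scoring: +match for identical non-N residues, -mismatch otherwise;
// a gap run of length k costs gapOpen + k * gapExtend.
// State X = gap in target (baseline residue over '-'),
// state Y = gap in baseline ('-' over target residue).
// Traceback tie order: M (diagonal) > X > Y, so results are deterministic.

static const double NEG_INF = -1e30;
static const double TIE_EPS = 1e-9;

static inline double subst(char a, char b, double match, double mismatch) {
    if (a == b && a != 'N') return match;
    return -mismatch;
}

// pick the first state (in order M=0, X=1, Y=2) attaining the max
static inline int argmax3(double m, double x, double y) {
    double best = m;
    if (x > best) best = x;
    if (y > best) best = y;
    if (m >= best - TIE_EPS) return 0;
    if (x >= best - TIE_EPS) return 1;
    return 2;
}

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gapOpen, double gapExtend,
                      int band) {
    const int n = (int) a.size();
    const int m = (int) b.size();
    if (n == 0 || m == 0) stop("sequences must be nonempty");
    const bool banded = band >= 0;
    if (banded && std::abs(n - m) > band) {
        stop("band width %d cannot admit a global path for lengths %d and %d; widen the band to at least %d",
             band, n, m, std::abs(n - m));
    }

    const size_t W = (size_t) m + 1;
    // traceback: predecessor state per cell per state
    std::vector<unsigned char> ptrM(((size_t) n + 1) * W, 0);
    std::vector<unsigned char> ptrX(((size_t) n + 1) * W, 0);
    std::vector<unsigned char> ptrY(((size_t) n + 1) * W, 0);

    std::vector<double> Mprev(W), Xprev(W), Yprev(W), Mcur(W), Xcur(W), Ycur(W);

    Mprev[0] = 0.0;
    Xprev[0] = Yprev[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        Mprev[j] = NEG_INF;
        Xprev[j] = NEG_INF;
        if (!banded || j <= band) {
            Yprev[j] = -(gapOpen + j * gapExtend);
            ptrY[(size_t) j] = (j == 1) ? 0 : 2;
        } else {
            Yprev[j] = NEG_INF;
        }
    }

    for (int i = 1; i <= n; ++i) {
        const int jlo = banded ? std::max(1, i - band) : 1;
        const int jhi = banded ? std::min(m, i + band) : m;
        for (int j = 0; j <= m; ++j) { Mcur[j] = Xcur[j] = Ycur[j] = NEG_INF; }
        if (!banded || i <= band) {
            Xcur[0] = -(gapOpen + i * gapExtend);
            ptrX[(size_t) i * W] = (i == 1) ? 0 : 1;
        }
        for (int j = jlo; j <= jhi; ++j) {
            const size_t idx = (size_t) i * W + j;
            // M: diagonal from any state at (i-1, j-1)
            {
                double dm = Mprev[j - 1], dx = Xprev[j - 1], dy = Yprev[j - 1];
                int from = argmax3(dm, dx, dy);
                double base = (from == 0) ? dm : (from == 1) ? dx : dy;
                if (base > NEG_INF / 2) {
                    Mcur[j] = base + subst(a[i - 1], b[j - 1], match, mismatch);
                    ptrM[idx] = (unsigned char) from;
                }
            }
            // X: consume a[i-1] against a gap, from (i-1, j)
            {
                double om = Mprev[j] - (gapOpen + gapExtend);
                double ox = Xprev[j] - gapExtend;
                double oy = Yprev[j] - (gapOpen + gapExtend);
                int from = argmax3(om, ox, oy);
                double val = (from == 0) ? om : (from == 1) ? ox : oy;
                if (val > NEG_INF / 2) { Xcur[j] = val; ptrX[idx] = (unsigned char) from; }
            }
            // Y: consume b[j-1] against a gap, from (i, j-1)
            {
                double om = Mcur[j - 1] - (gapOpen + gapExtend);
                double ox = Xcur[j - 1] - (gapOpen + gapExtend);
                double oy = Ycur[j - 1] - gapExtend;
                int from = argmax3(om, ox, oy);
                double val = (from == 0) ? om : (from == 1) ? ox : oy;
                if (val > NEG_INF / 2) { Ycur[j] = val; ptrY[idx] = (unsigned char) from; }
            }
        }
        std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }

    int state = argmax3(Mprev[m], Xprev[m], Yprev[m]);
    double score = (state == 0) ? Mprev[m] : (state == 1) ? Xprev[m] : Yprev[m];
    if (score <= NEG_INF / 2) stop("no global path found within the band; widen the band");

    std::string alnA, alnB;
    alnA.reserve(n + m); alnB.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        const size_t idx = (size_t) i * W + j;
        if (state == 0) {
            alnA.push_back(a[i - 1]); alnB.push_back(b[j - 1]);
            state = ptrM[idx]; --i; --j;
        } else if (state == 1) {
            alnA.push_back(a[i - 1]); alnB.push_back('-');
            state = ptrX[idx]; --i;
        } else {
            alnA.push_back('-'); alnB.push_back(b[j - 1]);
            state = ptrY[idx]; --j;
        }
    }
    std::reverse(alnA.begin(), alnA.end());
    std::reverse(alnB.begin(), alnB.end());

    return List::create(_["aligned_a"] = alnA,
                        _["aligned_b"] = alnB,
                        _["score"] = score);
}
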