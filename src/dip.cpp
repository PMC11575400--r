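#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Hartigan dip statistic: the sup-norm distance from the empirical CDF to
// the closest unimodal CDF.
//
// Derivation used here: a unimodal CDF g (convex up to the mode m, concave
// after, with an atom allowed at m) lies within eps of the empirical step
// function F_n iff, at every sample value, g passes through the band
// [top_k - eps, bot_k + eps], where bot_k/top_k are the cumulative
// fractions just below/at the value, and g is convex on the values left of
// the mode and concave on the right.  Feasibility of a convex function
// through bands is a greatest-convex-minorant condition: every band top
// must lie within 2*eps above the chord of band bottoms that spans it
// (mirrored for the concave side).  Minimising over the mode position
// (taken at a sample value, with the atom absorbing the jump) gives
//
//   dip = (1/2) * min over j of max( preX[j], sufX[j] )
//
// where preX[j] is the largest violation of the lower-convex-hull chords of
// (x, bot) over points strictly left of j, and sufX[j] mirrors it on the
// right with the upper hull of (x, top).  Ties are collapsed into single
// points carrying the full jump.  The implementation below maintains the
// hulls incrementally; deviations only grow when hull vertices pop, so a
// running maximum is exact.  Correctness is checked in the test suite
// against an independent linear-programming oracle that encodes the
// definition directly.

struct Collapsed {
    std::vector<double> x, bot, top;
};

static Collapsed collapse_sorted(const std::vector<double>& xs) {
    Collapsed c;
    const double n = static_cast<double>(xs.size());
    size_t i = 0;
    while (i < xs.size()) {
        size_t j = i;
        while (j + 1 < xs.size() && xs[j + 1] == xs[i]) ++j;
        c.x.push_back(xs[i]);
        c.bot.push_back(static_cast<double>(i) / n);
        c.top.push_back(static_cast<double>(j + 1) / n);
        i = j + 1;
    }
    return c;
}

// one-sided scan: for each point j, the largest chord violation among
// points strictly before j (in scan order), where the hull is the lower
// convex hull of (pos, base) and violations are demand[k] - chord(pos[k]).
static std::vector<double> scan_violations(const std::vector<double>& pos,
                                           const std::vector<double>& base,
                                           const std::vector<double>& demand) {
    const size_t N = pos.size();
    std::vector<double> outX(N, 0.0);
    std::vector<size_t> hull;
    std::vector<double> dev(N, 0.0);
    double runmax = 0.0;
    for (size_t j = 0; j < N; ++j) {
        // pop while the turn (hull[-2], hull[-1], j) is not convex
        while (hull.size() >= 2) {
            size_t a = hull[hull.size() - 2], p = hull.back();
            double lhs = (base[p] - base[a]) * (pos[j] - pos[p]);
            double rhs = (base[j] - base[p]) * (pos[p] - pos[a]);
            if (lhs > rhs) hull.pop_back(); else break;
        }
        if (!hull.empty()) {
            size_t a = hull.back();
            // rescan every point between the closing vertex and j
            for (size_t k = a + 1; k < j; ++k) {
                double t = (pos[k] - pos[a]) / (pos[j] - pos[a]);
                double chord = base[a] + t * (base[j] - base[a]);
                double d = demand[k] - chord;
                if (d > dev[k]) dev[k] = d;
                if (dev[k] > runmax) runmax = dev[k];
            }
        }
        outX[j] = runmax;
        dev[j] = demand[j] - base[j];   // own jump, under the hull end
        if (dev[j] > runmax) runmax = dev[j];
        hull.push_back(j);
    }
    return outX;
}

// join feasibility for the mode at collapsed point j and distance eps:
// the smallest left-limit value u the convex side can reach at x_j must
// not exceed the largest value v the concave side allows there.  Every
// chord of the bands gives a valid bound: a forced positive slope between
// two left points persists (convexity) up to x_j, pushing u up; mirrored
// chords on the right pull v down.
static bool join_feasible(const Collapsed& c, size_t j, double eps) {
    const size_t N = c.x.size();
    double vmax = c.top[j] + eps;
    for (size_t cc = j + 1; cc < N; ++cc) {
        double Uc = c.bot[cc] + eps;
        if (Uc < vmax) vmax = Uc;
        double best_s = 0.0;           // steepest forced slope below cc
        for (size_t d = cc + 1; d < N; ++d) {
            double s = (c.top[d] - eps - Uc) / (c.x[d] - c.x[cc]);
            if (s > best_s) best_s = s;
        }
        if (best_s > 0) {
            double bound = Uc - best_s * (c.x[cc] - c.x[j]);
            if (bound < vmax) vmax = bound;
        }
    }
    double umin = c.bot[j] - eps;
    if (umin > vmax + 1e-15) return false;
    for (size_t b = 0; b < j; ++b) {
        double Lb = c.top[b] - eps;
        if (Lb > umin) umin = Lb;
        double best_s = 0.0;
        for (size_t a = 0; a < b; ++a) {
            double s = (Lb - (c.bot[a] + eps)) / (c.x[b] - c.x[a]);
            if (s > best_s) best_s = s;
        }
        if (best_s > 0) {
            double bound = Lb + best_s * (c.x[j] - c.x[b]);
            if (bound > umin) umin = bound;
        }
        if (umin > vmax + 1e-15) return false;
    }
    return umin <= vmax + 1e-15;
}

static double dip_from_sorted(const std::vector<double>& xs) {
    if (xs.size() < 2 || xs.front() == xs.back()) return 0.0;
    Collapsed c = collapse_sorted(xs);
    const size_t N = c.x.size();
    if (N == 1) return 0.0;

    // prefix: convex side, hull on (x, bot), demands top
    std::vector<double> preX = scan_violations(c.x, c.bot, c.top);

    // suffix: concave side; mirror x -> -x reversed, swap roles:
    // upper hull of (x, top) with demands bot is the lower hull of
    // (-x, -top) with demands -bot.
    std::vector<double> rx(N), rbase(N), rdem(N);
    for (size_t i = 0; i < N; ++i) {
        rx[i] = -c.x[N - 1 - i];
        rbase[i] = -c.top[N - 1 - i];
        rdem[i] = -c.bot[N - 1 - i];
    }
    // violations: (-bot) - chord(-top) = chord(top) - bot, as required
    std::vector<double> sufRev = scan_violations(rx, rbase, rdem);

    // per-mode lower bounds (band/shape feasibility of each side alone),
    // cheapest first; the join pushes some candidates up, so refine in
    // ascending order until the next lower bound cannot beat the best
    std::vector<std::pair<double, size_t> > cand(N);
    for (size_t j = 0; j < N; ++j) {
        cand[j] = std::make_pair(std::max(preX[j], sufRev[N - 1 - j]) / 2.0, j);
    }
    std::sort(cand.begin(), cand.end());

    double best = R_PosInf;
    for (size_t idx = 0; idx < N; ++idx) {
        double lo = cand[idx].first;
        size_t j = cand[idx].second;
        if (lo >= best) break;
        if (join_feasible(c, j, lo + 1e-14)) {
            best = lo;
            continue;
        }
        double hi = std::min(best, 0.25);
        if (!join_feasible(c, j, hi)) continue;  // cannot beat best
        for (int it = 0; it < 60 && hi - lo > 1e-14; ++it) {
            double mid = 0.5 * (lo + hi);
            if (join_feasible(c, j, mid)) hi = mid; else lo = mid;
        }
        if (hi < best) best = hi;
    }
    return best;
}

//' @keywords internal
// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
    std::vector<double> xs(x.begin(), x.end());
    std::sort(xs.begin(), xs.end());
    return dip_from_sorted(xs);
}

// bootstrap null sample of dip statistics for Uniform(0,1) samples of size
// n, using R's RNG so results are reproducible under set.seed()
// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int n_boot) {
    NumericVector out(n_boot);
    std::vector<double> xs(n);
    GetRNGstate();
    for (int b = 0; b < n_boot; ++b) {
        for (int i = 0; i < n; ++i) xs[i] = unif_rand();
        std::sort(xs.begin(), xs.end());
        out[b] = dip_from_sorted(xs);
    }
    PutRNGstate();
    return out;
}
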