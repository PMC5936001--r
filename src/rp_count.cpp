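#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact null count for the rank product statistic.
//
// C_k(rho) = #{ (r_1,...,r_k) in {1..n}^k : prod_j r_j <= rho }
// via the recursion C_k(rho) = sum_{r=1}^{min(n,rho)} C_{k-1}(floor(rho/r)),
// grouping runs of r that share the same floor(rho/r) (divisor blocking),
// memoised on (k, floor(rho)).  All counts are integers < 2^53 and therefore
// exact in doubles; the caller guards n^k against that limit.

static const double MAX_EXACT = 9007199254740992.0; // 2^53

struct DpCtx {
    std::unordered_map<long long, double> memo;
    std::vector<double> npow;
    int n;
    long long ops;
    long long budget;
};

static double count_rec(double rho, int k, DpCtx& ctx) {
    if (rho < 1.0) return 0.0;
    double rf = std::floor(rho);
    if (rf >= ctx.npow[k]) return ctx.npow[k];
    if (k == 1) return std::min(static_cast<double>(ctx.n), rf);

    long long key = static_cast<long long>(rf) * 32LL + k;
    std::unordered_map<long long, double>::iterator it = ctx.memo.find(key);
    if (it != ctx.memo.end()) return it->second;

    double total = 0.0;
    double rmax = std::min(static_cast<double>(ctx.n), rf);
    double r = 1.0;
    while (r <= rmax) {
        if (++ctx.ops > ctx.budget)
            stop("rank-product DP budget exceeded");
        double q = std::floor(rf / r);
        double rhi = std::min(rmax, std::floor(rf / q));
        total += (rhi - r + 1.0) * count_rec(q, k - 1, ctx);
        r = rhi + 1.0;
    }
    ctx.memo[key] = total;
    return total;
}

// [[Rcpp::export]]
NumericVector rp_count_tuples(NumericVector rho, int n, int k,
                              double budget = 5e7) {
    if (n < 1) stop("n must be a positive integer");
    if (k < 1) stop("k must be a positive integer");
    DpCtx ctx;
    ctx.n = n;
    ctx.ops = 0;
    ctx.budget = static_cast<long long>(budget);
    ctx.npow.assign(k + 1, 1.0);
    for (int j = 1; j <= k; ++j) {
        ctx.npow[j] = ctx.npow[j - 1] * n;
        if (ctx.npow[j] > MAX_EXACT)
            stop("n^k exceeds the exact integer range of doubles (2^53)");
    }
    NumericVector out(rho.size());
    for (R_xlen_t i = 0; i < rho.size(); ++i) {
        double r = rho[i];
        if (!R_finite(r) || r < 1.0 || r > ctx.npow[k])
            stop("rank product out of range [1, n^k]");
        out[i] = count_rec(r, k, ctx);
    }
    return out;
}
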