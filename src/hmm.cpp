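#include <Rcpp.h>
using namespace Rcpp;

// Diploid haplotype-copying (Li-Stephens) forward-backward.
//
// Hidden state = ordered pair (j, k) of panel haplotypes (K^2 states),
// uniform initial distribution. Per-haplotype transition between adjacent
// sites: stay with probability s_m = exp(-rho_m), otherwise jump to a
// haplotype drawn uniformly from all K (including the current one). The
// factorised structure lets each transition be applied in O(K^2) via row
// and column sums.
//
// Emission at site m for state (j, k):
//   e_m(j,k) = sum_g gl_m(g) * A(g | h_j[m], h_k[m], eps)
// where A convolves two independent miscopy-eps allele draws. Because
// alleles are 0/1, e_m takes at most 4 distinct values per site.
//
// Per-site rescaling keeps M = 1e4, K = 100 instances in range; the
// log-likelihood is recovered from the scaling constants.

// A(g | a, b, eps) for a,b in {0,1}: P(dosage g) with per-haplotype
// miscopy probability eps.
static void fill_emission_table(double eps, double A[2][2][3]) {
    for (int a = 0; a < 2; ++a) {
        for (int b = 0; b < 2; ++b) {
            double p1 = a ? 1.0 - eps : eps;  // P(target allele 1 | copied a)
            double p2 = b ? 1.0 - eps : eps;
            A[a][b][0] = (1.0 - p1) * (1.0 - p2);
            A[a][b][1] = p1 * (1.0 - p2) + (1.0 - p1) * p2;
            A[a][b][2] = p1 * p2;
        }
    }
}

// Apply the factorised two-haplotype transition to the K x K matrix `cur`
// (column-major K*K vector), writing into `nxt`:
//   nxt = (s I + (1-s)/K J) cur (s I + (1-s)/K J)'
static void transition(const std::vector<double>& cur, std::vector<double>& nxt,
                       int K, double s) {
    const double jump = (1.0 - s) / K;
    // rows: over first haplotype index j (within each column k)
    static thread_local std::vector<double> tmp;
    tmp.resize((size_t)K * K);
    for (int k = 0; k < K; ++k) {
        const double* col = &cur[(size_t)k * K];
        double colsum = 0.0;
        for (int j = 0; j < K; ++j) colsum += col[j];
        double* out = &tmp[(size_t)k * K];
        const double add = jump * colsum;
        for (int j = 0; j < K; ++j) out[j] = s * col[j] + add;
    }
    // columns: over second haplotype index k (row sums across columns)
    for (int j = 0; j < K; ++j) {
        double rowsum = 0.0;
        for (int k = 0; k < K; ++k) rowsum += tmp[(size_t)k * K + j];
        const double add = jump * rowsum;
        for (int k = 0; k < K; ++k)
            nxt[(size_t)k * K + j] = s * tmp[(size_t)k * K + j] + add;
    }
}

// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(IntegerMatrix hap,     // K x M, 0/1 alleles
            NumericMatrix gl,      // M x 3, normalised likelihoods
            NumericVector rho,     // length M-1, per-interval switch rate
            double eps) {
    const int K = hap.nrow();
    const int M = hap.ncol();
    if (K < 1 || M < 1) stop("empty panel");
    if (gl.nrow() != M) stop("gl and panel site counts differ");
    if (eps <= 0.0 || eps >= 0.5) stop("copy_error must be in (0, 0.5)");

    double A[2][2][3];
    fill_emission_table(eps, A);

    const size_t S = (size_t)K * K;
    std::vector<double> alpha((size_t)M * S);     // scaled, includes emission
    std::vector<double> scale(M);
    std::vector<double> cur(S), nxt(S);

    // per-site emission values by allele pair
    std::vector<double> eab(4);
    auto site_emissions = [&](int m) {
        for (int a = 0; a < 2; ++a)
            for (int b = 0; b < 2; ++b)
                eab[a * 2 + b] = gl(m, 0) * A[a][b][0] + gl(m, 1) * A[a][b][1] +
                                 gl(m, 2) * A[a][b][2];
    };

    // forward
    double loglik = 0.0;
    site_emissions(0);
    {
        const double init = 1.0 / (double)S;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
            const int bk = hap(k, 0);
            for (int j = 0; j < K; ++j) {
                double v = init * eab[hap(j, 0) * 2 + bk];
                cur[(size_t)k * K + j] = v;
                tot += v;
            }
        }
        if (tot <= 0.0) stop("zero forward mass at site 1");
        for (size_t i = 0; i < S; ++i) cur[i] /= tot;
        std::copy(cur.begin(), cur.end(), alpha.begin());
        scale[0] = tot;
        loglik += std::log(tot);
    }
    for (int m = 1; m < M; ++m) {
        const double s = std::exp(-rho[m - 1]);
        transition(cur, nxt, K, s);
        site_emissions(m);
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
            const int bk = hap(k, m);
            double* col = &nxt[(size_t)k * K];
            for (int j = 0; j < K; ++j) {
                col[j] *= eab[hap(j, m) * 2 + bk];
                tot += col[j];
            }
        }
        if (tot <= 0.0) stop("zero forward mass; degenerate likelihoods");
        for (size_t i = 0; i < S; ++i) nxt[i] /= tot;
        std::copy(nxt.begin(), nxt.end(), alpha.begin() + (size_t)m * S);
        scale[m] = tot;
        loglik += std::log(tot);
        cur.swap(nxt);
    }

    // backward + posterior accumulation
    NumericMatrix gp(M, 3);
    std::vector<double> beta(S, 1.0), g(S);
    for (int m = M - 1; m >= 0; --m) {
        site_emissions(m);
        // S_ab = sum over states with allele pair (a,b) of alpha*beta/e
        double Sab[4] = {0.0, 0.0, 0.0, 0.0};
        const double* al = &alpha[(size_t)m * S];
        for (int k = 0; k < K; ++k) {
            const int bk = hap(k, m);
            for (int j = 0; j < K; ++j) {
                const int cell = hap(j, m) * 2 + bk;
                Sab[cell] += al[(size_t)k * K + j] * beta[(size_t)k * K + j] /
                             eab[cell];
            }
        }
        double num[3];
        double tot = 0.0;
        for (int gidx = 0; gidx < 3; ++gidx) {
            double v = 0.0;
            v += Sab[0] * A[0][0][gidx];
            v += Sab[1] * A[0][1][gidx];
            v += Sab[2] * A[1][0][gidx];
            v += Sab[3] * A[1][1][gidx];
            num[gidx] = gl(m, gidx) * v;
            tot += num[gidx];
        }
        for (int gidx = 0; gidx < 3; ++gidx) gp(m, gidx) = num[gidx] / tot;

        if (m > 0) {
            // beta_{m-1} = T' (e_m . beta_m) / scale_m
            for (int k = 0; k < K; ++k) {
                const int bk = hap(k, m);
                for (int j = 0; j < K; ++j)
                    g[(size_t)k * K + j] = beta[(size_t)k * K + j] *
                                           eab[hap(j, m) * 2 + bk];
            }
            const double s = std::exp(-rho[m - 1]);
            transition(g, beta, K, s);   // transition matrix is symmetric
            const double inv = 1.0 / scale[m];
            for (size_t i = 0; i < S; ++i) beta[i] *= inv;
        }
    }

    return List::create(_["gp"] = gp, _["loglik"] = loglik);
}
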