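#include <Rcpp.h>
using namespace Rcpp;

static inline double softThreshold(double z, double g) {
    if (z > g) return z - g;
    if (z < -g) return z + g;
    return 0.0;
}

// One coordinate-descent solve on the precomputed Gram system:
//   G = Xc'Xc/n, c = Xc'yc/n, objective
//   (1/2n)||yc - Xc b||^2 + lambda*(alpha|b|_1 + (1-alpha)/2 |b|_2^2).
// b and grad (grad_j = c_j - (G b)_j) are updated in place; returns sweeps.
static int cdSolve(const std::vector<double> &G, const std::vector<double> &c,
                   int p, double alpha, double lam, double tol, int maxit,
                   std::vector<double> &b, std::vector<double> &grad,
                   double cmax, double ySq = 0.0,
                   std::vector<double> *objTrace = 0) {
    double g = lam * alpha;
    double ridge = lam * (1.0 - alpha);
    bool allZero = true;
    for (int j = 0; j < p; ++j) if (b[j] != 0.0) { allZero = false; break; }
    if (allZero && alpha > 0.0 && g >= cmax && !objTrace)
        return 0;                                        // 0 is optimal
    int it = 0;
    for (; it < maxit; ++it) {
        double maxDelta = 0.0;
        for (int j = 0; j < p; ++j) {
            double Gjj = G[static_cast<size_t>(j) * p + j];
            if (Gjj <= 0.0) continue;
            double old = b[j];
            double z = grad[j] + Gjj * old;
            double bn = softThreshold(z, g) / (Gjj + ridge);
            if (bn != old) {
                double d = bn - old;
                const double *Gj = &G[static_cast<size_t>(j) * p];
                for (int k = 0; k < p; ++k) grad[k] -= Gj[k] * d;
                b[j] = bn;
                double ad = std::fabs(d);
                if (ad > maxDelta) maxDelta = ad;
            }
        }
        if (objTrace) {
            double quad = 0.0, lin = 0.0, l1 = 0.0, l2 = 0.0;
            for (int j = 0; j < p; ++j) {
                lin += b[j] * c[j];
                l1 += std::fabs(b[j]);
                l2 += b[j] * b[j];
                const double *Gj = &G[static_cast<size_t>(j) * p];
                for (int k = 0; k < p; ++k) quad += b[j] * Gj[k] * b[k];
            }
            objTrace->push_back((ySq - 2.0 * lin + quad) / 2.0 +
                                lam * (alpha * l1 +
                                       (1.0 - alpha) / 2.0 * l2));
        }
        if (maxDelta < tol) { ++it; break; }
    }
    return it;
}

static void gramFromRows(const NumericMatrix &X, const NumericVector &y,
                         const std::vector<int> &rows,
                         std::vector<double> &G, std::vector<double> &c,
                         std::vector<double> &xm, double &ym) {
    int n = rows.size(), p = X.ncol();
    std::vector<double> Xc(static_cast<size_t>(n) * p);
    ym = 0.0;
    for (int i = 0; i < n; ++i) ym += y[rows[i]];
    ym /= n;
    for (int j = 0; j < p; ++j) {
        double m = 0.0;
        for (int i = 0; i < n; ++i) m += X(rows[i], j);
        m /= n;
        xm[j] = m;
        for (int i = 0; i < n; ++i)
            Xc[static_cast<size_t>(j) * n + i] = X(rows[i], j) - m;
    }
    for (int j = 0; j < p; ++j) {
        const double *xj = &Xc[static_cast<size_t>(j) * n];
        for (int k = j; k < p; ++k) {
            const double *xk = &Xc[static_cast<size_t>(k) * n];
            double s = 0.0;
            for (int i = 0; i < n; ++i) s += xj[i] * xk[i];
            s /= n;
            G[static_cast<size_t>(j) * p + k] = s;
            G[static_cast<size_t>(k) * p + j] = s;
        }
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += xj[i] * (y[rows[i]] - ym);
        c[j] = s / n;
    }
}

// Elastic-net solution along a decreasing lambda path with warm starts.
// Returns beta (p x L), intercepts, sweep counts and (optionally) the
// objective after every sweep of every lambda.
// [[Rcpp::export]]
List enetPathCpp(NumericMatrix X, NumericVector y, double alpha,
                 NumericVector lambdas, double tol, int maxit,
                 bool trace) {
    int n = X.nrow(), p = X.ncol(), L = lambdas.size();
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    std::vector<double> G(static_cast<size_t>(p) * p), c(p), xm(p);
    double ym;
    gramFromRows(X, y, rows, G, c, xm, ym);
    double ySq = 0.0;
    for (int i = 0; i < n; ++i) ySq += (y[i] - ym) * (y[i] - ym);
    ySq /= n;
    double cmax = 0.0;
    for (int j = 0; j < p; ++j)
        if (std::fabs(c[j]) > cmax) cmax = std::fabs(c[j]);
    // tolerance is relative to the response scale so count-scale and
    // unit-scale problems converge to the same relative precision
    double sdY = std::sqrt(ySq);
    double tolEff = tol * (sdY > 0.0 ? sdY : 1.0);

    NumericMatrix beta(p, L);
    NumericVector b0(L);
    IntegerVector iters(L);
    std::vector<double> b(p, 0.0), grad(c);
    List traces(L);

    for (int l = 0; l < L; ++l) {
        double lam = lambdas[l];
        if (!trace) {
            iters[l] = cdSolve(G, c, p, alpha, lam, tolEff, maxit, b, grad,
                               cmax);
        } else {
            std::vector<double> objTrace;
            iters[l] = cdSolve(G, c, p, alpha, lam, tolEff, maxit, b, grad,
                               cmax, ySq, &objTrace);
            traces[l] = wrap(objTrace);
        }
        double dot = 0.0;
        for (int j = 0; j < p; ++j) {
            beta(j, l) = b[j];
            dot += b[j] * xm[j];
        }
        b0[l] = ym - dot;
    }
    List out = List::create(_["beta"] = beta, _["b0"] = b0,
                            _["iterations"] = iters);
    if (trace) out["objective_trace"] = traces;
    return out;
}

// Held-out MSE over an (alpha, lambda) grid for repeated leave-days-out
// validation of a single design. heldout is R x H (1-based row indices of
// X). lambdas must be decreasing. Returns an array (nA x nL x R).
// [[Rcpp::export]]
NumericVector enetCvCpp(NumericMatrix X, NumericVector y,
                        NumericVector alphas, NumericVector lambdas,
                        IntegerMatrix heldout, double tol, int maxit) {
    int n = X.nrow(), p = X.ncol();
    int nA = alphas.size(), nL = lambdas.size(), R = heldout.nrow();
    int H = heldout.ncol();
    NumericVector mse(static_cast<R_xlen_t>(nA) * nL * R);
    mse.attr("dim") = IntegerVector::create(nA, nL, R);
    std::vector<double> G(static_cast<size_t>(p) * p), c(p), xm(p);
    std::vector<double> b(p), grad(p);
    std::vector<bool> isHeld(n);
    for (int r = 0; r < R; ++r) {
        std::fill(isHeld.begin(), isHeld.end(), false);
        for (int h = 0; h < H; ++h) {
            int idx = heldout(r, h) - 1;
            if (idx < 0 || idx >= n) stop("held-out index out of range");
            isHeld[idx] = true;
        }
        std::vector<int> train;
        train.reserve(n - H);
        for (int i = 0; i < n; ++i) if (!isHeld[i]) train.push_back(i);
        double ym;
        gramFromRows(X, y, train, G, c, xm, ym);
        double cmax = 0.0;
        for (int j = 0; j < p; ++j)
            if (std::fabs(c[j]) > cmax) cmax = std::fabs(c[j]);
        double ySq = 0.0;
        for (size_t i = 0; i < train.size(); ++i)
            ySq += (y[train[i]] - ym) * (y[train[i]] - ym);
        ySq /= train.size();
        double sdY = std::sqrt(ySq);
        double tolEff = tol * (sdY > 0.0 ? sdY : 1.0);
        for (int a = 0; a < nA; ++a) {
            std::fill(b.begin(), b.end(), 0.0);
            std::copy(c.begin(), c.end(), grad.begin());
            for (int l = 0; l < nL; ++l) {
                cdSolve(G, c, p, alphas[a], lambdas[l], tolEff, maxit, b,
                        grad, cmax);
                double dot = 0.0;
                for (int j = 0; j < p; ++j) dot += b[j] * xm[j];
                double b0 = ym - dot;
                double err = 0.0;
                for (int h = 0; h < H; ++h) {
                    int i = heldout(r, h) - 1;
                    double pred = b0;
                    for (int j = 0; j < p; ++j) pred += X(i, j) * b[j];
                    double d = y[i] - pred;
                    err += d * d;
                }
                mse[static_cast<R_xlen_t>(r) * nA * nL +
                    static_cast<R_xlen_t>(l) * nA + a] = err / H;
            }
        }
    }
    return mse;
}
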