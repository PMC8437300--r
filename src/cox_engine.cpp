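// Penalized Cox partial-likelihood engine with Efron tie handling.
//
// Supports the Cox mixed-effects fit used for the expression->survival
// stage: CpG direct effects gamma get a ridge penalty gamma'gamma/(2*tau3)
// (the Laplace/PQL representation of iid normal random effects), while the
// mediator and clinical covariates stay unpenalized.  Inputs must be sorted
// by increasing time; subjects with equal event times form Efron tie
// groups.  Inner loops are hand-rolled over the upper triangle to avoid
// small-matrix temporaries: the engine is called tens of times per gene
// across a whole-genome scan.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Unpenalized partial log-likelihood, score and negative Hessian at theta.
// Z: n x p design (sorted by increasing time), status: 0/1, same order.
static void cox_derivs(const mat& Z, const vec& time, const vec& status,
                       const vec& theta, double& loglik, vec& score, mat& nhess)
{
    const int n = Z.n_rows, p = Z.n_cols;
    vec eta = Z * theta;
    eta -= eta.max();                    // guard exp overflow; cancels in ratios
    vec w = exp(eta);

    loglik = 0.0;
    score.zeros(p);
    nhess.zeros(p, p);                   // accumulate upper triangle only

    double S0 = 0.0;
    vec S1(p, fill::zeros), s1(p), z1(p);
    mat S2(p, p, fill::zeros), s2(p, p);

    int i = n - 1;
    while (i >= 0) {
        const double t_i = time(i);
        int j = i;
        while (j >= 0 && time(j) == t_i) --j;
        // subjects j+1..i share this time; all enter the risk set now
        for (int k = j + 1; k <= i; ++k) {
            const double wk = w(k);
            const double* zk = Z.colptr(0) + k;   // row k, strided by n
            S0 += wk;
            for (int a = 0; a < p; ++a) {
                const double za = zk[(size_t)a * n];
                S1(a) += wk * za;
                const double wza = wk * za;
                double* col = S2.colptr(a);
                for (int b = 0; b <= a; ++b)
                    col[b] += wza * zk[(size_t)b * n];
            }
        }
        // Efron adjustment over tied events at t_i
        int d = 0;
        double s0 = 0.0, sum_eta = 0.0;
        for (int k = j + 1; k <= i; ++k) if (status(k) == 1.0) ++d;
        if (d > 0) {
            s1.zeros();
            s2.zeros();
            for (int k = j + 1; k <= i; ++k) {
                if (status(k) != 1.0) continue;
                const double wk = w(k);
                const double* zk = Z.colptr(0) + k;
                s0 += wk;
                sum_eta += eta(k);
                for (int a = 0; a < p; ++a) {
                    const double za = zk[(size_t)a * n];
                    s1(a) += wk * za;
                    score(a) += za;               // sum of covariates over events
                    if (d > 1) {
                        const double wza = wk * za;
                        double* col = s2.colptr(a);
                        for (int b = 0; b <= a; ++b)
                            col[b] += wza * zk[(size_t)b * n];
                    }
                }
            }
            loglik += sum_eta;
            for (int l = 0; l < d; ++l) {
                const double f = (double)l / d;
                const double denom = S0 - f * s0;
                const double id = 1.0 / denom;
                const double id2 = id * id;
                loglik -= std::log(denom);
                for (int a = 0; a < p; ++a)
                    z1(a) = S1(a) - f * s1(a);
                for (int a = 0; a < p; ++a) {
                    score(a) -= z1(a) * id;
                    const double z1a = z1(a);
                    double* hc = nhess.colptr(a);
                    const double* S2c = S2.colptr(a);
                    const double* s2c = s2.colptr(a);
                    if (d > 1) {
                        for (int b = 0; b <= a; ++b)
                            hc[b] += (S2c[b] - f * s2c[b]) * id - z1a * z1(b) * id2;
                    } else {
                        for (int b = 0; b <= a; ++b)
                            hc[b] += S2c[b] * id - z1a * z1(b) * id2;
                    }
                }
            }
        }
        i = j;
    }
    // accumulation used the upper triangle (b <= a in column-major colptr(a))
    nhess = symmatu(nhess);
}

// [[Rcpp::export(name = ".cox_derivs_cpp")]]
Rcpp::List cox_derivs_cpp(const arma::mat& Z, const arma::vec& time,
                          const arma::vec& status, const arma::vec& theta)
{
    double ll;
    vec U;
    mat H;
    cox_derivs(Z, time, status, theta, ll, U, H);
    return Rcpp::List::create(Rcpp::Named("loglik") = ll,
                              Rcpp::Named("score") = U,
                              Rcpp::Named("nhess") = H);
}

// Partial log-likelihood only (cheap step-halving checks).
static double cox_loglik(const mat& Z, const vec& time, const vec& status,
                         const vec& theta)
{
    const int n = Z.n_rows;
    vec eta = Z * theta;
    eta -= eta.max();
    vec w = exp(eta);
    double loglik = 0.0, S0 = 0.0;
    int i = n - 1;
    while (i >= 0) {
        const double t_i = time(i);
        int j = i;
        while (j >= 0 && time(j) == t_i) --j;
        for (int k = j + 1; k <= i; ++k) S0 += w(k);
        int d = 0;
        double s0 = 0.0;
        for (int k = j + 1; k <= i; ++k) {
            if (status(k) == 1.0) { ++d; s0 += w(k); loglik += eta(k); }
        }
        for (int l = 0; l < d; ++l)
            loglik -= std::log(S0 - (double)l / d * s0);
        i = j;
    }
    return loglik;
}

// Newton-Raphson maximization of l(theta) - 0.5 * sum(pen_j * theta_j^2)
// with step-halving so the penalized log-likelihood never decreases.
// [[Rcpp::export(name = ".cox_newton_cpp")]]
Rcpp::List cox_newton_cpp(const arma::mat& Z, const arma::vec& time,
                          const arma::vec& status, const arma::vec& penalty,
                          const arma::vec& theta0, const int max_iter,
                          const double tol, const int max_halving)
{
    const int p = Z.n_cols;
    vec theta = theta0;
    double ll;
    vec U;
    mat H;
    cox_derivs(Z, time, status, theta, ll, U, H);
    double pll = ll - 0.5 * dot(penalty, square(theta));
    bool converged = false;
    int iter = 0;

    for (iter = 1; iter <= max_iter; ++iter) {
        mat Hp = H;
        Hp.diag() += penalty;
        vec g = U - penalty % theta;
        vec step;
        bool ok = solve(step, symmatu(Hp), g,
                        solve_opts::likely_sympd + solve_opts::no_approx);
        if (!ok) {
            Hp.diag() += 1e-8 * (trace(Hp) / p + 1.0);
            step = solve(symmatu(Hp), g);
        }
        double scale = 1.0;
        vec theta_new;
        double pll_new = 0.0;
        int h = 0;
        for (h = 0; h <= max_halving; ++h) {
            theta_new = theta + scale * step;
            const double ll_try = cox_loglik(Z, time, status, theta_new);
            pll_new = ll_try - 0.5 * dot(penalty, square(theta_new));
            if (std::isfinite(pll_new) && pll_new >= pll - 1e-12) break;
            scale *= 0.5;
        }
        if (h > max_halving) break;  // no ascent direction found
        const double delta = std::fabs(pll_new - pll);
        theta = theta_new;
        cox_derivs(Z, time, status, theta, ll, U, H);
        pll = ll - 0.5 * dot(penalty, square(theta));
        if (delta < tol * (std::fabs(pll) + 1.0)) { converged = true; break; }
    }

    return Rcpp::List::create(Rcpp::Named("theta") = theta,
                              Rcpp::Named("loglik") = ll,
                              Rcpp::Named("ploglik") = pll,
                              Rcpp::Named("score") = U,
                              Rcpp::Named("nhess") = H,
                              Rcpp::Named("converged") = converged,
                              Rcpp::Named("iter") = iter);
}
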