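// Polya-Gamma Gibbs sampler for the hierarchical Bayesian logistic model:
//
//   y_i ~ Bernoulli(inv_logit(eta_i)),  eta_i = x_i' beta + u_{cluster(i)}
//   beta_j | sigma_{g(j)} ~ N(0, sigma_{g(j)}^2)   (g(j) = 0 => fixed sd)
//   sigma_g ~ Half-Normal(scale_g),  u_c ~ N(0, sigma_loc^2),
//   sigma_loc ~ Half-Normal(loc_scale)
//
// Augmentation: omega_i ~ PG(1, eta_i) gives exact Gaussian full
// conditionals for beta and u (Polson, Scott & Windle 2013); the
// group scales are updated by univariate slice sampling on log(sigma).
// All randomness flows through R's RNG so set.seed() controls the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double PG_TRUNC = 0.64;

// a_n(x): terms of the alternating series for the Jacobi J*(1,0) density.
static double pg_a_term(int n, double x)
{
    double h = n + 0.5;
    double lg = std::log(M_PI) + std::log(h);
    if (x <= PG_TRUNC) {
        lg += 1.5 * (std::log(2.0 / M_PI) - std::log(x)) - 2.0 * h * h / x;
    } else {
        lg += -0.5 * h * h * M_PI * M_PI * x;
    }
    return std::exp(lg);
}

// Inverse-Gaussian(mu = 1/z, lambda = 1) truncated to (0, t]; z >= 0.
static double pg_rtigauss(double z, double t)
{
    double x = t + 1.0;
    if (z < 1.0 / t) { // mode region: rejection via transformed exponentials
        double alpha = 0.0;
        while (R::unif_rand() > alpha) {
            double e1 = R::exp_rand(), e2 = R::exp_rand();
            while (e1 * e1 > 2.0 * e2 / t) {
                e1 = R::exp_rand();
                e2 = R::exp_rand();
            }
            x = t / ((1.0 + t * e1) * (1.0 + t * e1));
            alpha = std::exp(-0.5 * z * z * x);
        }
    } else {
        double mu = 1.0 / z;
        while (x > t) {
            double y = R::norm_rand();
            y *= y;
            double muy = mu * y;
            x = mu + 0.5 * mu * muy - 0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
            if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
        }
    }
    return x;
}

// P(InvGauss(1/z, 1) <= t), evaluated stably through log Phi terms.
static double pg_pigauss(double z, double t)
{
    double rt = 1.0 / std::sqrt(t);
    double a = R::pnorm(rt * (t * z - 1.0), 0.0, 1.0, 1, 1);
    double b = 2.0 * z + R::pnorm(-rt * (t * z + 1.0), 0.0, 1.0, 1, 1);
    return std::exp(a) + std::exp(b);
}

// One draw from PG(1, psi) by Devroye-type rejection (exact).
static double rpg1(double psi)
{
    double z = 0.5 * std::fabs(psi);
    double t = PG_TRUNC;
    double K = 0.125 * M_PI * M_PI + 0.5 * z * z;
    // mixture weights of the two proposal pieces
    double lp = std::log(0.5 * M_PI / K) - K * t;
    double lq = std::log(2.0) - z + std::log(pg_pigauss(z, t));
    double p_frac = 1.0 / (1.0 + std::exp(lq - lp));

    for (;;) {
        double x;
        if (R::unif_rand() < p_frac) {
            x = t + R::exp_rand() / K; // truncated exponential, x > t
        } else {
            x = pg_rtigauss(z, t); // truncated inverse-Gaussian, x <= t
        }
        // squeeze accept/reject with the alternating series
        double s = pg_a_term(0, x);
        double y = R::unif_rand() * s;
        int n = 0;
        for (;;) {
            ++n;
            if (n % 2 == 1) {
                s -= pg_a_term(n, x);
                if (y <= s) return 0.25 * x;
            } else {
                s += pg_a_term(n, x);
                if (y > s) break; // reject, redraw proposal
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector rpg_vec(NumericVector psi)
{
    int n = psi.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) out[i] = rpg1(psi[i]);
    return out;
}

// log p(log sigma | beta-block) up to a constant: m coefficients with
// sum of squares ssq, Half-Normal(scale) prior on sigma.
static double lsig_logpost(double th, int m, double ssq, double scale)
{
    double s2 = std::exp(2.0 * th);
    return -(double)(m - 1) * th - 0.5 * ssq / s2 - 0.5 * s2 / (scale * scale);
}

// Univariate slice sampler (stepping out + shrinkage) for log sigma.
static double slice_sigma(double sigma, int m, double ssq, double scale)
{
    double th = std::log(std::max(sigma, 1e-10));
    double ly = lsig_logpost(th, m, ssq, scale) - R::exp_rand();
    double w = 1.0;
    double L = th - w * R::unif_rand();
    double Rr = L + w;
    for (int k = 0; k < 50 && lsig_logpost(L, m, ssq, scale) > ly; ++k) L -= w;
    for (int k = 0; k < 50 && lsig_logpost(Rr, m, ssq, scale) > ly; ++k) Rr += w;
    for (int k = 0; k < 100; ++k) {
        double th1 = L + R::unif_rand() * (Rr - L);
        if (lsig_logpost(th1, m, ssq, scale) > ly) return std::exp(th1);
        if (th1 < th) L = th1; else Rr = th1;
    }
    return std::exp(th);
}

static double softplus(double x)
{
    return (x > 0) ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

// Bernoulli log-likelihood of eta = base + sigma * v, plus Half-Normal(scale)
// prior and the log-sigma Jacobian; used by the non-centered scale update.
static double nc_sigma_logpost(double th, const arma::vec& y,
                               const arma::vec& base, const arma::vec& v,
                               double scale)
{
    double sg = std::exp(th);
    double ll = 0.0;
    const int n = y.n_elem;
    for (int i = 0; i < n; ++i) {
        double e = base[i] + sg * v[i];
        ll += y[i] * e - softplus(e);
    }
    return ll - 0.5 * sg * sg / (scale * scale) + th;
}

// Slice sampler for the non-centered scale; returns the new sigma.
static double nc_slice_sigma(double sigma, const arma::vec& y,
                             const arma::vec& base, const arma::vec& v,
                             double scale)
{
    double th = std::log(std::max(sigma, 1e-10));
    double ly = nc_sigma_logpost(th, y, base, v, scale) - R::exp_rand();
    double w = 0.7;
    double L = th - w * R::unif_rand();
    double Rr = L + w;
    for (int k = 0; k < 30 && nc_sigma_logpost(L, y, base, v, scale) > ly; ++k)
        L -= w;
    for (int k = 0; k < 30 && nc_sigma_logpost(Rr, y, base, v, scale) > ly; ++k)
        Rr += w;
    for (int k = 0; k < 100; ++k) {
        double th1 = L + R::unif_rand() * (Rr - L);
        if (nc_sigma_logpost(th1, y, base, v, scale) > ly)
            return std::exp(th1);
        if (th1 < th) L = th1; else Rr = th1;
    }
    return std::exp(th);
}

// [[Rcpp::export]]
List gibbs_logit_cpp(const arma::mat& X,
                     const arma::vec& y,
                     const arma::ivec& col_group, // 0 = fixed-prior column
                     const arma::vec& group_scale, // Half-Normal scales, length G
                     double fixed_sd,
                     const arma::ivec& cluster, // 0-based, length n (or empty)
                     int n_cluster,
                     double loc_scale,
                     int n_warmup,
                     int n_keep)
{
    const int n = X.n_rows, p = X.n_cols;
    const int G = group_scale.n_elem;
    const bool has_clust = (n_cluster > 0) && ((int)cluster.n_elem == n);

    arma::vec beta(p, arma::fill::zeros);
    arma::vec u(std::max(n_cluster, 1), arma::fill::zeros);
    arma::vec sigma(G);
    for (int g = 0; g < G; ++g) sigma[g] = 0.5 * group_scale[g];
    double sigma_loc = 0.5 * (loc_scale > 0 ? loc_scale : 1.0);

    arma::vec kappa = y - 0.5;
    arma::vec eta(n, arma::fill::zeros), omega(n);

    // group bookkeeping
    std::vector<std::vector<int>> gcols(G);
    for (int j = 0; j < p; ++j)
        if (col_group[j] > 0) gcols[col_group[j] - 1].push_back(j);

    arma::mat beta_draws(n_keep, p);
    arma::mat u_draws(n_keep, has_clust ? n_cluster : 0);
    arma::mat sigma_draws(n_keep, G);
    arma::vec sloc_draws(n_keep);

    const int total = n_warmup + n_keep;
    for (int it = 0; it < total; ++it) {
        // eta and omega
        eta = X * beta;
        if (has_clust)
            for (int i = 0; i < n; ++i) eta[i] += u[cluster[i]];
        for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);

        // beta | omega, u  ~  N(V b, V),  V^{-1} = X'Omega X + P
        arma::vec resid = kappa;
        if (has_clust)
            for (int i = 0; i < n; ++i) resid[i] -= omega[i] * u[cluster[i]];
        arma::mat Xw = X.each_col() % omega;
        arma::mat Vinv = X.t() * Xw;
        for (int j = 0; j < p; ++j) {
            double sd = (col_group[j] == 0) ? fixed_sd : sigma[col_group[j] - 1];
            sd = std::max(sd, 1e-8);
            Vinv(j, j) += 1.0 / (sd * sd);
        }
        arma::vec b = X.t() * resid;
        arma::mat L = arma::chol(Vinv, "lower");
        arma::vec mu_b = arma::solve(arma::trimatu(L.t()),
                                     arma::solve(arma::trimatl(L), b));
        arma::vec zdraw(p);
        for (int j = 0; j < p; ++j) zdraw[j] = R::norm_rand();
        beta = mu_b + arma::solve(arma::trimatu(L.t()), zdraw);

        // cluster effects
        if (has_clust) {
            arma::vec xb = X * beta;
            arma::vec prec(n_cluster, arma::fill::zeros);
            arma::vec rsum(n_cluster, arma::fill::zeros);
            for (int i = 0; i < n; ++i) {
                int c = cluster[i];
                prec[c] += omega[i];
                rsum[c] += kappa[i] - omega[i] * xb[i];
            }
            double pl = 1.0 / (sigma_loc * sigma_loc);
            for (int c = 0; c < n_cluster; ++c) {
                double pc = prec[c] + pl;
                u[c] = rsum[c] / pc + R::norm_rand() / std::sqrt(pc);
            }
            double ssq_u = arma::dot(u.head(n_cluster), u.head(n_cluster));
            sigma_loc = slice_sigma(sigma_loc, n_cluster, ssq_u, loc_scale);
        }

        // order-group scales: centered (sufficient) update ...
        for (int g = 0; g < G; ++g) {
            int m = (int)gcols[g].size();
            if (m == 0) {
                sigma[g] = std::fabs(R::norm_rand()) * group_scale[g];
                continue;
            }
            double ssq = 0.0;
            for (int j : gcols[g]) ssq += beta[j] * beta[j];
            sigma[g] = slice_sigma(sigma[g], m, ssq, group_scale[g]);
        }

        // ... interwoven with a non-centered (ancillary) update of every
        // scale against the likelihood, which breaks the funnel coupling
        // between a block's scale and its shrunken coefficients.
        {
            arma::vec eta_full = X * beta;
            if (has_clust)
                for (int i = 0; i < n; ++i) eta_full[i] += u[cluster[i]];
            for (int g = 0; g < G; ++g) {
                if (gcols[g].empty() || sigma[g] < 1e-9) continue;
                arma::vec v(n, arma::fill::zeros);
                for (int j : gcols[g]) v += X.col(j) * beta[j];
                arma::vec base = eta_full - v;
                v /= sigma[g];
                double s_new = nc_slice_sigma(sigma[g], y, base, v,
                                              group_scale[g]);
                double ratio = s_new / sigma[g];
                for (int j : gcols[g]) beta[j] *= ratio;
                eta_full = base + s_new * v;
                sigma[g] = s_new;
            }
            if (has_clust && sigma_loc > 1e-9) {
                arma::vec v(n);
                for (int i = 0; i < n; ++i) v[i] = u[cluster[i]];
                arma::vec base = eta_full - v;
                v /= sigma_loc;
                double s_new = nc_slice_sigma(sigma_loc, y, base, v,
                                              loc_scale);
                u.head(n_cluster) *= s_new / sigma_loc;
                sigma_loc = s_new;
            }
        }

        if (it >= n_warmup) {
            int s = it - n_warmup;
            beta_draws.row(s) = beta.t();
            if (has_clust) u_draws.row(s) = u.head(n_cluster).t();
            sigma_draws.row(s) = sigma.t();
            sloc_draws[s] = sigma_loc;
        }
    }

    return List::create(_["beta"] = beta_draws,
                        _["u"] = u_draws,
                        _["sigma"] = sigma_draws,
                        _["sigma_loc"] = sloc_draws);
}
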