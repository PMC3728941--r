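// Metropolis-within-Gibbs sampler for the two-state switching first-difference
// correlated random walk (DCRW) state-space model.
//
// Process (planar km, node index t on a regular step grid):
//   d_t = X_t - X_{t-1}
//   d_t | d_{t-1}, b_t ~ N( gamma_{b_t} R(theta_{b_t}) d_{t-1}, Sigma )
//   b_t in {1 = migration, 2 = foraging}, Markov with
//   alpha_k = P(b_t = 1 | b_{t-1} = k).
// Observation (Argos fix j in interval i with fraction w):
//   y_j = (1 - w) X_i + w X_{i+1} + t_nu(scale psi) per axis.
// Identifiability: gamma_1 > gamma_2 enforced through the prior support.
//
// Latent positions, states and parameters are updated in turn; proposal
// scales adapt during burn-in toward a 0.25-0.45 acceptance band.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List dcrw_chain(NumericVector ox, NumericVector oy,
                IntegerVector oint, NumericVector ow,
                NumericVector opsi, NumericVector onu,
                NumericVector X0, NumericVector Y0, IntegerVector b0,
                NumericVector par0,
                int n_retain, int burn_in, int thin,
                double sigma_prior_sd, double d1_sd) {
  const int N = X0.size();          // nodes 0..N-1
  const int T = N - 1;              // displacements 1..T
  const int F = ox.size();
  if (N < 4) stop("need at least 4 grid nodes");

  std::vector<double> X(X0.begin(), X0.end()), Y(Y0.begin(), Y0.end());
  std::vector<int> b(b0.begin(), b0.end());   // b[t] valid for t >= 2
  double gam[2] = { par0[0], par0[1] };
  double th[2]  = { par0[2], par0[3] };
  double sx = par0[4], sy = par0[5], rho = par0[6];
  double alpha[2] = { par0[7], par0[8] };

  // observation CSR by interval
  std::vector<int> cnt(T, 0), start(T + 1, 0), idx(F);
  for (int j = 0; j < F; ++j) {
    if (oint[j] < 0 || oint[j] >= T) stop("fix interval out of range");
    cnt[oint[j]]++;
  }
  for (int i = 0; i < T; ++i) start[i + 1] = start[i] + cnt[i];
  {
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int j = 0; j < F; ++j) idx[pos[oint[j]]++] = j;
  }
  // per-fix t-density constants
  std::vector<double> tcst(F);
  for (int j = 0; j < F; ++j) {
    double nu = onu[j], psi = opsi[j];
    tcst[j] = R::lgammafn((nu + 1) / 2) - R::lgammafn(nu / 2) -
      0.5 * std::log(nu * M_PI) - std::log(psi);
  }

  double ixx, ixy, iyy, ldet;
  auto update_cov = [&]() {
    double om = 1.0 - rho * rho;
    ldet = std::log(sx * sx * sy * sy * om);
    ixx = 1.0 / (sx * sx * om);
    iyy = 1.0 / (sy * sy * om);
    ixy = -rho / (sx * sy * om);
  };
  update_cov();

  // process log-density of displacement t under state k (k = 1 or 2)
  auto proc_ld = [&](int t, int k) -> double {
    double dx = X[t] - X[t - 1], dy = Y[t] - Y[t - 1];
    if (t == 1)
      return -0.5 * (dx * dx + dy * dy) / (d1_sd * d1_sd);
    double px = X[t - 1] - X[t - 2], py = Y[t - 1] - Y[t - 2];
    double c = std::cos(th[k - 1]), s = std::sin(th[k - 1]);
    double mx = gam[k - 1] * (c * px - s * py);
    double my = gam[k - 1] * (s * px + c * py);
    double ex = dx - mx, ey = dy - my;
    return -0.5 * ldet -
      0.5 * (ex * ex * ixx + 2.0 * ex * ey * ixy + ey * ey * iyy);
  };
  auto obs_ld_interval = [&](int i) -> double {
    double s = 0.0;
    for (int p = start[i]; p < start[i + 1]; ++p) {
      int j = idx[p];
      double px = (1.0 - ow[j]) * X[i] + ow[j] * X[i + 1];
      double py = (1.0 - ow[j]) * Y[i] + ow[j] * Y[i + 1];
      double rx = ox[j] - px, ry = oy[j] - py;
      double nu = onu[j], psi = opsi[j];
      s += 2.0 * tcst[j] -
        0.5 * (nu + 1) * (std::log1p(rx * rx / (nu * psi * psi)) +
                          std::log1p(ry * ry / (nu * psi * psi)));
    }
    return s;
  };
  auto ltrans = [&](int from, int to) -> double {
    double a = alpha[from - 1];
    a = std::min(1.0 - 1e-9, std::max(1e-9, a));
    return to == 1 ? std::log(a) : std::log(1.0 - a);
  };
  // joint log-density terms touched by node t
  auto node_ld = [&](int t) -> double {
    double s = 0.0;
    for (int tt = t; tt <= t + 2; ++tt)
      if (tt >= 1 && tt <= T) s += proc_ld(tt, tt >= 2 ? b[tt] : 1);
    if (t - 1 >= 0 && t - 1 < T) s += obs_ld_interval(t - 1);
    if (t < T) s += obs_ld_interval(t);
    return s;
  };

  // proposal scales + acceptance counters
  std::vector<double> sX(N, 1.0);
  double s_g[2] = { 0.05, 0.05 }, s_t[2] = { 0.2, 0.2 };
  double s_lsx = 0.2, s_lsy = 0.2, s_zr = 0.3;
  std::vector<int> accX(N, 0), tryX(N, 0);
  int acc_g[2] = {0, 0}, try_g[2] = {0, 0}, acc_t[2] = {0, 0}, try_t[2] = {0, 0};
  int acc_sx = 0, try_sx = 0, acc_sy = 0, try_sy = 0, acc_r = 0, try_r = 0;
  auto tune = [](double sc, int acc, int tries) -> double {
    if (tries == 0) return sc;
    double r = double(acc) / tries;
    if (r < 0.25) return sc * 0.8;
    if (r > 0.45) return sc * 1.25;
    return sc;
  };

  const int n_total = burn_in + n_retain * thin;
  NumericMatrix params(n_retain, 9);
  std::vector<double> xs(N, 0), ys(N, 0), xs2(N, 0), ys2(N, 0), bs(N, 0);
  int kept = 0;

  RNGScope scope;
  for (int iter = 1; iter <= n_total; ++iter) {
    // --- latent positions ---
    for (int t = 0; t < N; ++t) {
      double old_ld = node_ld(t);
      double oxv = X[t], oyv = Y[t];
      X[t] += R::norm_rand() * sX[t];
      Y[t] += R::norm_rand() * sX[t];
      double new_ld = node_ld(t);
      tryX[t]++;
      if (std::log(R::unif_rand()) < new_ld - old_ld) accX[t]++;
      else { X[t] = oxv; Y[t] = oyv; }
    }
    // --- behavioural states: joint forward-filter backward-sample ---
    {
      std::vector<double> f1(T + 1), f2(T + 1);
      for (int t = 2; t <= T; ++t) {
        double l1 = proc_ld(t, 1), l2 = proc_ld(t, 2);
        double mx = std::max(l1, l2);
        double e1 = std::exp(l1 - mx), e2 = std::exp(l2 - mx);
        double p1, p2;
        if (t == 2) { p1 = 0.5 * e1; p2 = 0.5 * e2; }
        else {
          double a1 = alpha[0], a2 = alpha[1];
          p1 = e1 * (f1[t - 1] * a1 + f2[t - 1] * a2);
          p2 = e2 * (f1[t - 1] * (1 - a1) + f2[t - 1] * (1 - a2));
        }
        double z = p1 + p2;
        if (z <= 0) { p1 = p2 = 0.5; z = 1.0; }
        f1[t] = p1 / z; f2[t] = p2 / z;
      }
      b[T] = (R::unif_rand() < f1[T]) ? 1 : 2;
      for (int t = T - 1; t >= 2; --t) {
        double a_to = (b[t + 1] == 1) ? alpha[0] : 1 - alpha[0];
        double b_to = (b[t + 1] == 1) ? alpha[1] : 1 - alpha[1];
        double p1 = f1[t] * a_to;
        double p2 = f2[t] * b_to;
        double z = p1 + p2;
        b[t] = (z > 0 && R::unif_rand() < p1 / z) ? 1 : 2;
      }
    }
    // --- switch probabilities (conjugate Beta) ---
    {
      int n11 = 0, n12 = 0, n21 = 0, n22 = 0;
      for (int t = 3; t <= T; ++t) {
        if (b[t - 1] == 1) { if (b[t] == 1) n11++; else n12++; }
        else { if (b[t] == 1) n21++; else n22++; }
      }
      alpha[0] = R::rbeta(1.0 + n11, 1.0 + n12);
      alpha[1] = R::rbeta(1.0 + n21, 1.0 + n22);
    }
    // --- per-state move persistence and mean turn ---
    for (int k = 1; k <= 2; ++k) {
      double lik_state = 0.0;
      for (int t = 2; t <= T; ++t) if (b[t] == k) lik_state += proc_ld(t, k);
      // gamma
      double gold = gam[k - 1];
      double gnew = gold + R::norm_rand() * s_g[k - 1];
      try_g[k - 1]++;
      bool ok = gnew >= 0.0 && gnew <= 1.0 &&
        (k == 1 ? gnew > gam[1] : gnew < gam[0]);
      if (ok) {
        gam[k - 1] = gnew;
        double lik_new = 0.0;
        for (int t = 2; t <= T; ++t) if (b[t] == k) lik_new += proc_ld(t, k);
        if (std::log(R::unif_rand()) < lik_new - lik_state) {
          acc_g[k - 1]++; lik_state = lik_new;
        } else gam[k - 1] = gold;
      }
      // theta (wrapped); occasional half-turn jump crosses between the
      // forward-persistence and reversal modes
      double told = th[k - 1];
      double tnew = (R::unif_rand() < 0.3)
        ? told + M_PI + R::norm_rand() * s_t[k - 1]
        : told + R::norm_rand() * s_t[k - 1];
      tnew = std::atan2(std::sin(tnew), std::cos(tnew));
      try_t[k - 1]++;
      th[k - 1] = tnew;
      double lik_new = 0.0;
      for (int t = 2; t <= T; ++t) if (b[t] == k) lik_new += proc_ld(t, k);
      if (std::log(R::unif_rand()) < lik_new - lik_state) acc_t[k - 1]++;
      else th[k - 1] = told;
    }
    // --- process covariance ---
    auto full_proc = [&]() {
      double s = 0.0;
      for (int t = 2; t <= T; ++t) s += proc_ld(t, b[t]);
      return s;
    };
    {
      double cur = full_proc();
      // sigma_x
      double old = sx;
      sx = std::exp(std::log(sx) + R::norm_rand() * s_lsx);
      update_cov();
      double prop = full_proc();
      double lr = prop - cur +
        (-0.5 * sx * sx + 0.5 * old * old) / (sigma_prior_sd * sigma_prior_sd) +
        std::log(sx) - std::log(old);
      try_sx++;
      if (std::log(R::unif_rand()) < lr) { acc_sx++; cur = prop; }
      else { sx = old; update_cov(); }
      // sigma_y
      old = sy;
      sy = std::exp(std::log(sy) + R::norm_rand() * s_lsy);
      update_cov();
      prop = full_proc();
      lr = prop - cur +
        (-0.5 * sy * sy + 0.5 * old * old) / (sigma_prior_sd * sigma_prior_sd) +
        std::log(sy) - std::log(old);
      try_sy++;
      if (std::log(R::unif_rand()) < lr) { acc_sy++; cur = prop; }
      else { sy = old; update_cov(); }
      // rho
      old = rho;
      rho = std::tanh(std::atanh(rho) + R::norm_rand() * s_zr);
      update_cov();
      prop = full_proc();
      lr = prop - cur + std::log1p(-rho * rho) - std::log1p(-old * old);
      try_r++;
      if (std::log(R::unif_rand()) < lr) acc_r++;
      else { rho = old; update_cov(); }
    }
    // --- adaptation during burn-in ---
    if (iter <= burn_in && iter % 50 == 0) {
      for (int t = 0; t < N; ++t) {
        sX[t] = tune(sX[t], accX[t], tryX[t]);
        accX[t] = tryX[t] = 0;
      }
      for (int k = 0; k < 2; ++k) {
        s_g[k] = tune(s_g[k], acc_g[k], try_g[k]); acc_g[k] = try_g[k] = 0;
        s_t[k] = tune(s_t[k], acc_t[k], try_t[k]); acc_t[k] = try_t[k] = 0;
      }
      s_lsx = tune(s_lsx, acc_sx, try_sx); acc_sx = try_sx = 0;
      s_lsy = tune(s_lsy, acc_sy, try_sy); acc_sy = try_sy = 0;
      s_zr = tune(s_zr, acc_r, try_r); acc_r = try_r = 0;
    }
    // --- retention ---
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      params(kept, 0) = gam[0]; params(kept, 1) = gam[1];
      params(kept, 2) = th[0];  params(kept, 3) = th[1];
      params(kept, 4) = sx;     params(kept, 5) = sy;
      params(kept, 6) = rho;
      params(kept, 7) = alpha[0]; params(kept, 8) = alpha[1];
      for (int t = 0; t < N; ++t) {
        xs[t] += X[t]; ys[t] += Y[t];
        xs2[t] += X[t] * X[t]; ys2[t] += Y[t] * Y[t];
        bs[t] += (t >= 2 ? b[t] : b[2]);
      }
      kept++;
    }
    if (iter % 500 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector xmean(N), ymean(N), xsd(N), ysd(N), bmean(N);
  for (int t = 0; t < N; ++t) {
    xmean[t] = xs[t] / kept;
    ymean[t] = ys[t] / kept;
    double vx = xs2[t] / kept - xmean[t] * xmean[t];
    double vy = ys2[t] / kept - ymean[t] * ymean[t];
    xsd[t] = std::sqrt(std::max(vx, 0.0));
    ysd[t] = std::sqrt(std::max(vy, 0.0));
    bmean[t] = bs[t] / kept;
  }
  colnames(params) = CharacterVector::create("gamma1", "gamma2", "theta1",
                                             "theta2", "sigma_x", "sigma_y",
                                             "rho", "alpha1", "alpha2");
  double accx_all = 0;
  return List::create(_["params"] = params,
                      _["xmean"] = xmean, _["ymean"] = ymean,
                      _["xsd"] = xsd, _["ysd"] = ysd,
                      _["bmean"] = bmean,
                      _["accept_x"] = accx_all);
}
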