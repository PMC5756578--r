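#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin particles on the periodic interval [-L, L) with
// dynamical spring links (finite epsilon) or instantaneously equilibrated
// links (epsilon = 0, mean-field normalized pair interaction).
// Uses R's RNG so runs are reproducible under set.seed().

static inline double wrap_pos(double x, double L) {
  double y = x - 2.0 * L * std::floor((x + L) / (2.0 * L));
  if (y >= L) y -= 2.0 * L;
  if (y < -L) y += 2.0 * L;
  return y;
}

static inline long long pair_key(int i, int j, int N) {
  if (i > j) std::swap(i, j);
  return (long long)i * N + j;
}

// enumerate unordered pairs with min-image distance <= R (requires R < L):
// sort particles, sweep forward with wrap-around
template <typename F>
static void for_pairs_within(const std::vector<double>& x, double L, double R,
                             std::vector<int>& order, F&& fun) {
  const int N = (int)x.size();
  for (int i = 0; i < N; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  for (int a = 0; a < N; ++a) {
    const int i = order[a];
    for (int bo = 1; bo < N; ++bo) {
      int b = a + bo;
      double shift = 0.0;
      if (b >= N) { b -= N; shift = 2.0 * L; }
      const int j = order[b];
      double gap = x[j] + shift - x[i];  // distance from i forward to j
      if (gap > R) break;
      fun(i, j, gap);                     // j is ahead of i by gap in (0, R]
    }
  }
}

static double circ_mean(const std::vector<double>& x, double L, bool* ok) {
  double c = 0.0, s = 0.0;
  for (double xi : x) { c += std::cos(M_PI * xi / L); s += std::sin(M_PI * xi / L); }
  double r = std::sqrt(c * c + s * s);
  *ok = r > 1e-12 * x.size();
  return L / M_PI * std::atan2(s, c);
}

// [[Rcpp::export]]
List micro_run_cpp(NumericVector x0, IntegerMatrix links0,
                   double L, double R, double ell, double kappa, double D,
                   double nu_f, double nu_d, double epsilon, double drift_norm,
                   double t_final, double dt_max, double delta_step,
                   double c_eps, int n_bins, double avg_start,
                   double sample_dt) {
  const int N = x0.size();
  std::vector<double> x(x0.begin(), x0.end());
  for (int i = 0; i < N; ++i) x[i] = wrap_pos(x[i], L);

  std::vector<std::pair<int, int>> links;
  std::unordered_set<long long> linkset;
  const bool dynamic_links = epsilon > 0;
  if (dynamic_links) {
    for (int k = 0; k < links0.nrow(); ++k) {
      int i = links0(k, 0) - 1, j = links0(k, 1) - 1;
      long long key = pair_key(i, j, N);
      if (linkset.insert(key).second) links.emplace_back(std::min(i, j), std::max(i, j));
    }
  }

  std::vector<double> drift(N), xr(N);
  std::vector<int> order(N);
  std::vector<double> hist(n_bins, 0.0);
  double n_samples = 0.0;
  std::vector<double> tr_t, tr_q, tr_k;
  const double dxb = 2.0 * L / n_bins;

  double t = 0.0, steps = 0.0;
  double next_sample = avg_start;

  auto take_sample = [&](double tc) {
    bool ok = true;
    double xm = circ_mean(x, L, &ok);
    std::vector<double> cnt(n_bins, 0.0);
    for (int i = 0; i < N; ++i) {
      double xi = ok ? wrap_pos(x[i] - xm, L) : x[i];
      xr[i] = xi;
      int b = (int)std::floor((xi + L) / dxb);
      if (b < 0) b = 0; if (b >= n_bins) b = n_bins - 1;
      cnt[b] += 1.0;
    }
    // instantaneous order parameter from the binned density (midpoint rule)
    double c1 = 0.0, s1 = 0.0;
    for (int b = 0; b < n_bins; ++b) {
      double xc = -L + (b + 0.5) * dxb;
      double fb = cnt[b] / (N * dxb);
      c1 += fb * std::cos(M_PI * xc / L) * dxb;
      s1 += fb * std::sin(M_PI * xc / L) * dxb;
    }
    c1 /= L; s1 /= L;
    tr_t.push_back(tc);
    tr_q.push_back(std::sqrt(c1 * c1 + s1 * s1));
    tr_k.push_back((double)links.size());
    for (int b = 0; b < n_bins; ++b) hist[b] += cnt[b];
    n_samples += 1.0;
  };

  while (t < t_final) {
    // drift from the current interaction structure
    std::fill(drift.begin(), drift.end(), 0.0);
    if (dynamic_links) {
      for (auto& lk : links) {
        double d = x[lk.first] - x[lk.second];
        d -= 2.0 * L * std::round(d / (2.0 * L));
        double r = std::fabs(d);
        if (r > 0) {
          double g = kappa * (r - ell) * (d / r);
          drift[lk.first] -= g;
          drift[lk.second] += g;
        }
      }
    } else {
      for_pairs_within(x, L, R, order, [&](int i, int j, double gap) {
        if (gap <= 0) return;
        double g = drift_norm * kappa * (gap - ell);  // j ahead of i
        drift[i] += g;
        drift[j] -= g;
      });
    }

    // adaptive time step
    double dmax = 0.0;
    for (int i = 0; i < N; ++i) dmax = std::max(dmax, std::fabs(drift[i]));
    double dt = dt_max;
    if (dmax > 0) dt = std::min(dt, delta_step / dmax);
    if (dynamic_links)
      dt = std::min(dt, c_eps * epsilon * epsilon / std::max(nu_f, nu_d));
    if (t + dt > t_final) dt = t_final - t;

    // Euler-Maruyama update
    double sig = std::sqrt(2.0 * D * dt);
    for (int i = 0; i < N; ++i)
      x[i] = wrap_pos(x[i] + drift[i] * dt + sig * norm_rand(), L);

    // link turnover (after the move, with the step just taken)
    if (dynamic_links) {
      double pd = 1.0 - std::exp(-nu_d * dt / (epsilon * epsilon));
      double pf = 1.0 - std::exp(-nu_f * dt / ((N - 1.0) * epsilon * epsilon));
      size_t keep = 0;
      for (size_t k = 0; k < links.size(); ++k) {
        if (unif_rand() < pd) {
          linkset.erase(pair_key(links[k].first, links[k].second, N));
        } else {
          links[keep++] = links[k];
        }
      }
      links.resize(keep);
      for_pairs_within(x, L, R, order, [&](int i, int j, double gap) {
        (void)gap;
        long long key = pair_key(i, j, N);
        if (linkset.count(key)) return;
        if (unif_rand() < pf) {
          linkset.insert(key);
          links.emplace_back(std::min(i, j), std::max(i, j));
        }
      });
    }

    t += dt; steps += 1.0;
    if (t >= next_sample && t <= t_final) {
      take_sample(t);
      next_sample += sample_dt;
    }
    if (((long long)steps) % 5000 == 0) Rcpp::checkUserInterrupt();
  }
  if (n_samples == 0.0) take_sample(t);

  // mean recentered density over samples, normalized to unit mass
  NumericVector dens(n_bins);
  double tot = 0.0;
  for (int b = 0; b < n_bins; ++b) tot += hist[b];
  for (int b = 0; b < n_bins; ++b) dens[b] = hist[b] / (tot * dxb);

  int nt = (int)tr_t.size();
  NumericMatrix trace(nt, 3);
  for (int r = 0; r < nt; ++r) {
    trace(r, 0) = tr_t[r]; trace(r, 1) = tr_q[r]; trace(r, 2) = tr_k[r];
  }
  colnames(trace) = CharacterVector::create("t", "Q", "K");

  IntegerMatrix lout((int)links.size(), 2);
  for (int k = 0; k < (int)links.size(); ++k) {
    lout(k, 0) = links[k].first + 1; lout(k, 1) = links[k].second + 1;
  }

  return List::create(_["positions"] = wrap(x), _["t"] = t, _["steps"] = steps,
                      _["density"] = dens, _["n_samples"] = n_samples,
                      _["trace"] = trace, _["links"] = lout,
                      _["q_final"] = tr_q[nt - 1], _["k_final"] = (double)links.size());
}
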