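// Compiled fast path for one MOA trial with a built-in controller.
//
// This mirrors the pure-R reference loop (moa_init_trial + moa_step +
// make_controller) operation-for-operation: identical RNG draw order via
// R's own generators (R::runif / R::rnorm), identical IEEE double
// arithmetic (the R side deliberately avoids extended-precision
// accumulators), identical tie-breaks and epsilons. The test suite
// asserts bit-identical trial records between the two paths under shared
// seeds; any edit here must keep that contract.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Hazards {
  std::vector<double> px, py, vx, vy, act, spawn_speed;
  std::vector<char> filled;
  size_t n() const { return px.size(); }
};

struct Snap {
  std::vector<double> px, py, vx, vy, act;
  std::vector<char> filled;
  double clock, ux, uy;
};

// One rejection-sampled placement; draw order (x, y)* then angle then
// speed, exactly as the R place_hazard().
void place_hazard(double r, double w, double h, double smin, double smax,
                  double ux, double uy, Hazards& hz) {
  const int max_attempts = 1000;
  for (int a = 0; a < max_attempts; ++a) {
    double x = R::runif(r, w - r);
    double y = R::runif(r, h - r);
    double du = std::sqrt((x - ux) * (x - ux) + (y - uy) * (y - uy));
    bool ok = du >= 2 * r;
    if (ok) {
      for (size_t k = 0; k < hz.n(); ++k) {
        double dd = std::sqrt((hz.px[k] - x) * (hz.px[k] - x) +
                              (hz.py[k] - y) * (hz.py[k] - y));
        if (!(dd >= 2 * r)) { ok = false; break; }
      }
    }
    if (ok) {
      double ang = R::runif(0.0, 360.0) * M_PI / 180.0;
      double spd = R::runif(smin, smax);
      hz.px.push_back(x);
      hz.py.push_back(y);
      hz.vx.push_back(spd * std::cos(ang));
      hz.vy.push_back(spd * std::sin(ang));
      hz.spawn_speed.push_back(spd);
      return;
    }
  }
  stop("hazard placement failed after 1000 attempts: window too small for the configured disc count");
}

void take_snap(Snap& s, const Hazards& hz, double clock, double ux, double uy) {
  s.px = hz.px; s.py = hz.py; s.vx = hz.vx; s.vy = hz.vy;
  s.act = hz.act; s.filled = hz.filled;
  s.clock = clock; s.ux = ux; s.uy = uy;
}

} // namespace

// [[Rcpp::export]]
List moa_trial_cpp(double w, double h, double r, int n_init,
                   double spawn_interval, double grace,
                   double smin, double smax, double dt, double maxdur,
                   int kind, double latency, double max_ptr_speed,
                   double noise_sd) {
  const double eps = 1e-9;
  double ux = w / 2.0, uy = h / 2.0;

  Hazards hz;
  for (int i = 0; i < n_init; ++i) {
    place_hazard(r, w, h, smin, smax, ux, uy, hz);
    hz.act.push_back(grace);
    hz.filled.push_back(grace <= 0);
  }

  // perceptual delay in whole ticks; R's round() is half-to-even
  int lag = (int)R::fround(latency / dt, 0.0);
  std::vector<Snap> ring(lag + 1);
  take_snap(ring[0], hz, 0.0, ux, uy);

  double next_spawn = spawn_interval;
  double clock = 0.0, survival = NA_REAL;
  long ticks = 0;
  bool terminated = false, censored = false;
  long wall_bounces = 0, pair_bounces = 0;

  while (!terminated) {
    // ---- controller: propose a pointer sample -------------------------
    double pxp = ux, pyp = uy;
    if (kind == 2) {                       // random_walk
      double ang = R::runif(0.0, 2.0 * M_PI);
      pxp = ux + std::cos(ang) * max_ptr_speed * dt;
      pyp = uy + std::sin(ang) * max_ptr_speed * dt;
      if (noise_sd > 0) {
        pxp += R::rnorm(0.0, noise_sd);
        pyp += R::rnorm(0.0, noise_sd);
      }
    } else if (kind == 3 && ticks >= lag) { // greedy_avoid
      const Snap& s = ring[(size_t)((ticks - lag) % (lag + 1))];
      size_t ns = s.px.size();
      double best = R_PosInf;
      int best_i = -1;
      for (size_t i = 0; i < ns; ++i) {
        bool threat = s.filled[i] || (s.act[i] - s.clock < latency);
        if (!threat) continue;
        double dx = s.px[i] - s.ux, dy = s.py[i] - s.uy;
        double dist = std::sqrt(dx * dx + dy * dy);
        double gap = dist - 2 * r;
        double closing = dist > 0 ? -(dx * s.vx[i] + dy * s.vy[i]) / dist : 0.0;
        double ttc = gap <= 0 ? 0.0 : (closing > 0 ? gap / closing : R_PosInf);
        if (ttc < best) { best = ttc; best_i = (int)i; }
      }
      if (best_i >= 0) {
        double dx = s.px[best_i] - s.ux, dy = s.py[best_i] - s.uy;
        double dist = std::sqrt(dx * dx + dy * dy);
        double nx = dist > 0 ? -dx / dist : 1.0;
        double ny = dist > 0 ? -dy / dist : 0.0;
        pxp = ux + nx * max_ptr_speed * dt;
        pyp = uy + ny * max_ptr_speed * dt;
        if (noise_sd > 0) {
          pxp += R::rnorm(0.0, noise_sd);
          pyp += R::rnorm(0.0, noise_sd);
        }
      }
    }
    // kind == 1 (stationary) and greedy-before-first-percept: hold

    // ---- step: user clamp, hazard physics -----------------------------
    ux = std::min(std::max(pxp, r), w - r);
    uy = std::min(std::max(pyp, r), h - r);

    size_t n = hz.n();
    if (n > 0) {
      double vmax = 0.0;
      for (size_t i = 0; i < n; ++i) {
        double sp = std::sqrt(hz.vx[i] * hz.vx[i] + hz.vy[i] * hz.vy[i]);
        if (sp > vmax) vmax = sp;
      }
      int nsub = std::max(1, (int)std::ceil(vmax * dt / (r / 2.0)));
      double sdt = dt / nsub;
      for (int ss = 0; ss < nsub; ++ss) {
        for (size_t i = 0; i < n; ++i) {
          hz.px[i] += hz.vx[i] * sdt;
          hz.py[i] += hz.vy[i] * sdt;
        }
        for (int ax = 0; ax < 2; ++ax) {
          double lim = ax == 0 ? w : h;
          std::vector<double>& p = ax == 0 ? hz.px : hz.py;
          std::vector<double>& v = ax == 0 ? hz.vx : hz.vy;
          for (size_t i = 0; i < n; ++i) {
            bool lo = p[i] <= r;
            bool hi = p[i] >= lim - r;
            if (lo) {
              p[i] = 2 * r - p[i];
              v[i] = std::fabs(v[i]);
              ++wall_bounces;
            }
            if (hi) {
              p[i] = 2 * (lim - r) - p[i];
              v[i] = -std::fabs(v[i]);
              ++wall_bounces;
            }
          }
        }
        for (size_t i = 0; i + 1 < n; ++i) for (size_t j = i + 1; j < n; ++j) {
          double dx = hz.px[j] - hz.px[i];
          double dy = hz.py[j] - hz.py[i];
          double dist = std::sqrt(dx * dx + dy * dy);
          if (dist < 2 * r) {
            double nx = dist > 0 ? dx / dist : 1.0;
            double ny = dist > 0 ? dy / dist : 0.0;
            double closing = (hz.vx[i] - hz.vx[j]) * nx +
                             (hz.vy[i] - hz.vy[j]) * ny;
            if (dist == 0 || closing > 0) {
              if (dist > 0) {
                double di = hz.vx[i] * nx + hz.vy[i] * ny;
                double dj = hz.vx[j] * nx + hz.vy[j] * ny;
                hz.vx[i] -= 2 * di * nx; hz.vy[i] -= 2 * di * ny;
                hz.vx[j] -= 2 * dj * nx; hz.vy[j] -= 2 * dj * ny;
                ++pair_bounces;
              }
              double push = (2 * r - dist) / 2.0;
              hz.px[i] -= nx * push; hz.py[i] -= ny * push;
              hz.px[j] += nx * push; hz.py[j] += ny * push;
            }
          }
        }
      }
    }

    ++ticks;
    clock = (double)ticks * dt;
    for (size_t i = 0; i < hz.n(); ++i) hz.filled[i] = clock >= hz.act[i] - eps;

    while (clock >= next_spawn - eps) {
      place_hazard(r, w, h, smin, smax, ux, uy, hz);
      hz.act.push_back(clock + grace);
      hz.filled.push_back(grace <= 0);
      next_spawn += spawn_interval;
    }

    for (size_t i = 0; i < hz.n(); ++i) {
      if (!hz.filled[i]) continue;
      double dx = hz.px[i] - ux, dy = hz.py[i] - uy;
      if (std::sqrt(dx * dx + dy * dy) < 2 * r) {
        terminated = true;
        survival = clock;
        break;
      }
    }
    if (!terminated && clock >= maxdur - eps) {
      terminated = true;
      censored = true;
      survival = maxdur;
    }
    if (!terminated && lag >= 0) {
      take_snap(ring[(size_t)(ticks % (lag + 1))], hz, clock, ux, uy);
    }
  }

  std::vector<double> final_speed(hz.n());
  for (size_t i = 0; i < hz.n(); ++i) {
    final_speed[i] = std::sqrt(hz.vx[i] * hz.vx[i] + hz.vy[i] * hz.vy[i]);
  }

  return List::create(
    _["survival_time"] = survival,
    _["censored"] = censored,
    _["n_hazards"] = (int)hz.n(),
    _["spawn_speeds"] = hz.spawn_speed,
    _["final_speeds"] = final_speed,
    _["wall_bounces"] = (double)wall_bounces,
    _["pair_bounces"] = (double)pair_bounces);
}
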