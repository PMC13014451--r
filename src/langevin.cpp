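// Overdamped (Brownian) dynamics on a 1-D Gaussian-mixture landscape with a
// harmonic bias and position-dependent diffusivity. Ito Euler-Maruyama with
// the spurious-drift term D'(z), reflecting boundaries, deterministic for a
// fixed seed (Box-Muller on mt19937_64, so results do not depend on the C++
// library's normal_distribution implementation).
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct GaussSum {
  std::vector<double> c, h, w2;  // center, height, width^2
  void init(const NumericVector& center, const NumericVector& height,
            const NumericVector& width) {
    int n = center.size();
    c.assign(center.begin(), center.end());
    h.assign(height.begin(), height.end());
    w2.resize(n);
    for (int i = 0; i < n; ++i) w2[i] = width[i] * width[i];
  }
  double value(double z) const {
    double s = 0.0;
    for (size_t i = 0; i < c.size(); ++i) {
      double d = z - c[i];
      s += h[i] * std::exp(-d * d / (2.0 * w2[i]));
    }
    return s;
  }
  double deriv(double z) const {
    double s = 0.0;
    for (size_t i = 0; i < c.size(); ++i) {
      double d = z - c[i];
      s -= h[i] * (d / w2[i]) * std::exp(-d * d / (2.0 * w2[i]));
    }
    return s;
  }
};

struct Landscape {
  GaussSum G, Dmod;
  double D_base, clip;
  double Gp(double z) const { return G.deriv(z); }
  double D(double z) const {
    double m = 1.0 + Dmod.value(z);
    return D_base * (m < clip ? clip : m);
  }
  double Dp(double z) const {
    double m = 1.0 + Dmod.value(z);
    return m > clip ? D_base * Dmod.deriv(z) : 0.0;
  }
};

struct Gaussian {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gaussian(uint64_t seed) : eng(seed) {}
  double uniform() {
    // 53-bit uniform in (0, 1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double next() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = uniform(), u2 = uniform();
    double r = std::sqrt(-2.0 * std::log(u1)), t = 6.283185307179586477 * u2;
    spare = r * std::sin(t);
    has_spare = true;
    return r * std::cos(t);
  }
};

inline double reflect(double z, double zmin, double zmax) {
  // fold back into [zmin, zmax]; loop handles overshoot past both walls
  while (z < zmin || z > zmax) {
    if (z < zmin) z = 2.0 * zmin - z;
    if (z > zmax) z = 2.0 * zmax - z;
  }
  return z;
}

Landscape make_landscape(const List& ls) {
  Landscape L;
  DataFrame G = as<DataFrame>(ls["G_terms"]);
  DataFrame Dm = as<DataFrame>(ls["D_terms"]);
  L.G.init(G["center"], G["height"], G["width"]);
  L.Dmod.init(Dm["center"], Dm["height"], Dm["width"]);
  L.D_base = as<double>(ls["D_base"]);
  L.clip = 0.05;
  return L;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_simulate_window(List landscape_spec, double z_init,
                                  double bias_center, double spring_k,
                                  double beta, int n_steps, double dt,
                                  int sample_stride, double zmin, double zmax,
                                  double seed) {
  Landscape L = make_landscape(landscape_spec);
  Gaussian rng(static_cast<uint64_t>(seed));
  int n_out = n_steps / sample_stride;
  NumericVector out(n_out);
  double z = z_init;
  int k = 0;
  for (int i = 1; i <= n_steps; ++i) {
    double D = L.D(z);
    double force = L.Gp(z) + spring_k * (z - bias_center);
    double drift = -beta * D * force + L.Dp(z);
    z += drift * dt + std::sqrt(2.0 * D * dt) * rng.next();
    z = reflect(z, zmin, zmax);
    if (i % sample_stride == 0) out[k++] = z;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_steered_pull(List landscape_spec, double start, double end,
                      double velocity, double spring_k, double spacing,
                      double beta, double dt, double seed) {
  Landscape L = make_landscape(landscape_spec);
  Gaussian rng(static_cast<uint64_t>(seed));
  double dir = (end >= start) ? 1.0 : -1.0;
  double total = std::fabs(end - start);
  int n_seeds = static_cast<int>(std::floor(total / spacing)) + 1;
  NumericVector centers(n_seeds), seeds(n_seeds);
  double zmin = std::min(start, end) - 10.0, zmax = std::max(start, end) + 10.0;
  double z = start;
  centers[0] = start; seeds[0] = start;
  int next = 1;
  double t = 0.0;
  while (next < n_seeds) {
    double z0 = start + dir * velocity * t;
    double D = L.D(z);
    double force = L.Gp(z) + spring_k * (z - z0);
    double drift = -beta * D * force + L.Dp(z);
    z += drift * dt + std::sqrt(2.0 * D * dt) * rng.next();
    z = reflect(z, zmin, zmax);
    t += dt;
    double target = start + dir * next * spacing;
    if (dir * (start + dir * velocity * t) >= dir * target) {
      centers[next] = target;
      seeds[next] = z;
      ++next;
    }
  }
  return List::create(_["bias_center"] = centers, _["start_z"] = seeds);
}
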