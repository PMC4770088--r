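// Monte Carlo loop-closure propensity for a fluctuating rigid base-pair
// chain. Each sample draws the six step parameters per step independently
// Gaussian, chains the frames with the mid-frame composition (same
// convention as the R-level rebuild), and marks the conformation closed
// when the end origin lies within a capture radius of the start, the
// terminal z axes are within an angle cutoff, and (optionally) the summed
// twist is within a register tolerance of a multiple of 360 degrees.
//
// Uses R's RNG (norm_rand) so results are reproducible under set.seed();
// parameters with zero s.d. consume no random draws.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void mat3_mult(const double a[9], const double b[9], double out[9]) {
  // column-major 3x3: out = a * b
  for (int j = 0; j < 3; ++j) {
    for (int i = 0; i < 3; ++i) {
      out[i + 3 * j] = a[i] * b[3 * j] + a[i + 3] * b[1 + 3 * j] +
                       a[i + 6] * b[2 + 3 * j];
    }
  }
}

static inline void rot_z(double a, double m[9]) {
  double c = std::cos(a), s = std::sin(a);
  m[0] = c;  m[1] = s;  m[2] = 0;
  m[3] = -s; m[4] = c;  m[5] = 0;
  m[6] = 0;  m[7] = 0;  m[8] = 1;
}

static inline void rot_y(double a, double m[9]) {
  double c = std::cos(a), s = std::sin(a);
  m[0] = c;  m[1] = 0;  m[2] = -s;
  m[3] = 0;  m[4] = 1;  m[5] = 0;
  m[6] = s;  m[7] = 0;  m[8] = c;
}

// [[Rcpp::export(name = ".closure_mc_cpp")]]
List closure_mc_cpp(int n_samples, int n_steps,
                    NumericMatrix mean, NumericMatrix sd,
                    double r_c, double theta_c, double phi_c,
                    bool register_check, bool return_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1");
  if (mean.nrow() != n_steps || mean.ncol() != 6 ||
      sd.nrow() != n_steps || sd.ncol() != 6) {
    stop("mean and sd must be n_steps x 6 matrices");
  }
  const double deg = M_PI / 180.0;
  long closed = 0;
  NumericMatrix samples;
  if (return_samples) samples = NumericMatrix(n_samples, 3);

  double rz1[9], ry1[9], rz2[9], tmp[9], B[9], Rm[9], Rnew[9];

  for (int s = 0; s < n_samples; ++s) {
    double R[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    double o[3] = {0, 0, 0};
    double twist_sum = 0.0;
    for (int k = 0; k < n_steps; ++k) {
      double p[6];
      for (int j = 0; j < 6; ++j) {
        double sdv = sd(k, j);
        p[j] = (sdv > 0.0) ? mean(k, j) + sdv * norm_rand() : mean(k, j);
      }
      double ax = p[3] * deg, ay = p[4] * deg, w = p[5] * deg;
      twist_sum += p[5];
      double G = std::sqrt(ax * ax + ay * ay);
      double phi = (G == 0.0) ? 0.0 : std::atan2(ax, ay);
      rot_z(w / 2 - phi, rz1);
      rot_y(G, ry1);
      rot_z(w / 2 + phi, rz2);
      mat3_mult(rz1, ry1, tmp);
      mat3_mult(tmp, rz2, B);
      rot_y(G / 2, ry1);
      rot_z(phi, rz2);
      mat3_mult(rz1, ry1, tmp);
      mat3_mult(tmp, rz2, Rm);
      // o += R * (Rm_local * v)
      double v[3] = {p[0], p[1], p[2]}, u[3], g[3];
      for (int i = 0; i < 3; ++i) {
        u[i] = Rm[i] * v[0] + Rm[i + 3] * v[1] + Rm[i + 6] * v[2];
      }
      for (int i = 0; i < 3; ++i) {
        g[i] = R[i] * u[0] + R[i + 3] * u[1] + R[i + 6] * u[2];
        o[i] += g[i];
      }
      mat3_mult(R, B, Rnew);
      for (int i = 0; i < 9; ++i) R[i] = Rnew[i];
    }
    double dist = std::sqrt(o[0] * o[0] + o[1] * o[1] + o[2] * o[2]);
    double cz = R[8];  // z_end . z_start
    if (cz > 1.0) cz = 1.0;
    if (cz < -1.0) cz = -1.0;
    double ang = std::acos(cz) / deg;
    double reg = std::fabs(twist_sum);
    reg -= 360.0 * std::floor(reg / 360.0);
    if (reg > 180.0) reg = 360.0 - reg;
    bool ok = (dist < r_c) && (ang < theta_c);
    if (register_check) ok = ok && (reg <= phi_c);
    if (ok) ++closed;
    if (return_samples) {
      samples(s, 0) = dist;
      samples(s, 1) = ang;
      samples(s, 2) = reg;
    }
  }
  List out = List::create(Named("count") = (double)closed,
                          Named("n") = (double)n_samples);
  if (return_samples) out["samples"] = samples;
  return out;
}
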