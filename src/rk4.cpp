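// Compiled right-hand side of the 13-species model and a fixed-step
// classical Runge-Kutta (RK4) integrator with decoupled output sampling.
// Must stay term-for-term identical to the R reference ccm_rhs().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const char* SPECIES[13] = {
  "cyclin", "mpf", "protease", "p53", "mdm2", "mdm2_p53", "mdm2_mrna",
  "arf", "arf_mdm2", "ir", "damdna", "p21", "p21_mpf"};

// k[0] = k1 ... k[32] = k33 (slots for the composite k5, k9 are unused).
static inline void model_rhs(const double* x, const double* k, double* d) {
  const double k5 = k[13] * x[0] / (k[12] + x[0]);   // k14*x1/(k13+x1)
  const double k9 = k[14] * x[1];                    // k15*x2
  d[0] = k[0] - k[1] * x[0] * x[2] / (k[2] + x[0]) - k[3] * x[0];
  d[1] = k5 * (1.0 - x[1]) / (k[5] + (1.0 - x[1]))
       - k[6] * x[1] / (k[7] + x[1]) - k[30] * x[11] * x[1];
  d[2] = k9 * (1.0 - x[2]) / (k[9] + (1.0 - x[2]))
       - k[10] * x[2] / (k[11] + x[2]);
  d[3] = k[15] + k[17] * x[5] - k[16] * x[3] * x[4];
  d[4] = k[21] * x[6] + k[18] * x[5] + k[17] * x[5] - k[22] * x[4]
       - k[16] * x[3] * x[4] - k[26] * x[4] * x[7];
  d[5] = k[16] * x[3] * x[4] - k[17] * x[5] - k[18] * x[5];
  d[6] = k[19] * x[3] - k[20] * x[6];
  d[7] = k[25] * x[10] + k[28] * x[8] - k[26] * x[4] * x[7] - k[27] * x[7];
  d[8] = k[26] * x[4] * x[7] - k[28] * x[8];
  d[9] = -k[23] * x[9];
  d[10] = k[23] * x[9] - k[24] * x[10];
  d[11] = k[29] * x[3] - k[30] * x[1] * x[11] + k[31] * x[12] - k[32] * x[11];
  d[12] = k[30] * x[11] * x[1] - k[31] * x[12];
}

// [[Rcpp::export(name = ".rk4_core")]]
List rk4_core(NumericVector y0, NumericVector k, double dt, double t0,
              double t_end, int sample_every, double clamp_tol) {
  if (y0.size() != 13) stop("state must have length 13");
  if (k.size() != 33) stop("parameter vector must have length 33");
  if (!(dt > 0.0)) stop("dt must be positive");
  if (!(t_end > t0)) stop("t_end must exceed t0");
  if (sample_every < 1) stop("sample_every must be >= 1");

  const long n_steps = (long)std::lround((t_end - t0) / dt);
  if (n_steps < 1) stop("integration horizon shorter than one step");
  const long n_out = n_steps / sample_every + 1
    + ((n_steps % sample_every) ? 1 : 0);

  NumericVector times(n_out);
  NumericMatrix states(n_out, 13);
  double x[13], xt[13], d1[13], d2[13], d3[13], d4[13];
  for (int i = 0; i < 13; ++i) x[i] = y0[i];
  long clamped = 0;

  long row = 0;
  times[row] = t0;
  for (int i = 0; i < 13; ++i) states(row, i) = x[i];
  ++row;

  const double* kp = REAL(k);
  for (long s = 0; s < n_steps; ++s) {
    const double t = t0 + (double)s * dt;
    model_rhs(x, kp, d1);
    for (int i = 0; i < 13; ++i) xt[i] = x[i] + 0.5 * dt * d1[i];
    model_rhs(xt, kp, d2);
    for (int i = 0; i < 13; ++i) xt[i] = x[i] + 0.5 * dt * d2[i];
    model_rhs(xt, kp, d3);
    for (int i = 0; i < 13; ++i) xt[i] = x[i] + dt * d3[i];
    model_rhs(xt, kp, d4);
    for (int i = 0; i < 13; ++i) {
      x[i] += dt / 6.0 * (d1[i] + 2.0 * d2[i] + 2.0 * d3[i] + d4[i]);
      if (!std::isfinite(x[i]))
        stop("non-finite state: species %s at t = %.6g s", SPECIES[i],
             t + dt);
      if (x[i] < 0.0) {
        if (x[i] >= -clamp_tol) { x[i] = 0.0; ++clamped; }
        else stop("state went negative beyond tolerance: species %s = %.6g "
                  "at t = %.6g s", SPECIES[i], x[i], t + dt);
      }
    }
    // activation fractions live in [0, 1]; clamp numerical overshoot
    for (int i = 1; i <= 2; ++i) {
      if (x[i] > 1.0) {
        if (x[i] <= 1.0 + clamp_tol) { x[i] = 1.0; ++clamped; }
        else stop("activation fraction above 1: species %s = %.6g at "
                  "t = %.6g s", SPECIES[i], x[i], t + dt);
      }
    }
    if (((s + 1) % sample_every == 0) || (s + 1 == n_steps)) {
      times[row] = t0 + (double)(s + 1) * dt;
      for (int i = 0; i < 13; ++i) states(row, i) = x[i];
      ++row;
    }
  }

  return List::create(_["times"] = times[Rcpp::Range(0, row - 1)],
                      _["states"] = states(Rcpp::Range(0, row - 1), _),
                      _["clamped"] = (double)clamped);
}
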