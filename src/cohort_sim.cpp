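#include <Rcpp.h>
using namespace Rcpp;

// Deterministic stage-structured cohort under a repeating diurnal cycle.
//
// The cohort is discretised into K rank-correlated quantile sub-cohorts:
// lane j exits stage s when its accumulated physiological age reaches the
// ((j-0.5)/K)-quantile of the stage's normalized development-time
// distribution, and dies as an adult when senescence age reaches the same
// quantile of the longevity distribution. Survivorship multiplies the
// per-step immature survival factors; stage transitions are resolved at
// fractional-step accuracy so results converge in the step size.
//
// Inputs are per-step lookups over one day's cycle (steps x stage):
//   da     physiological-age increment rate_s(T_i) * dt
//   lsurv  log survival log(1 - m_s(T_i)) * dt
//   sen_da adult senescence-age increment per step
//   fec_w  lifetime-fecundity scale F(T_i) at the step temperature
// Cumulative egg laying follows C(x) = 1 - exp(-(a x + b x^2 + c x^3))
// over normalized female age x.
//
// Returns daily start-of-day survivorship l_x, daily net maternity
// phi_x = l_x * m_x (female eggs per initial female egg), per-lane stage
// exit days, survival to adulthood, and a truncation flag set when any
// lane is still developing (or an adult still alive) at max_days.

static inline double cumfec(double x, double a, double b, double c) {
  return 1.0 - std::exp(-(a * x + b * x * x + c * x * x * x));
}

// [[Rcpp::export]]
List cohort_sim_cpp(NumericMatrix da, NumericMatrix lsurv,
                    NumericMatrix exit_q, NumericVector sen_da,
                    NumericVector long_q, NumericVector fec_w,
                    double cf_a, double cf_b, double cf_c,
                    double sex_ratio, int max_days) {
  const int steps = da.nrow();
  const int n_imm = da.ncol();
  const int K = exit_q.nrow();
  const double w = 1.0 / K;
  const double dead_ls = std::log(1e-14);

  std::vector<double> lx(max_days, 0.0), phi(max_days, 0.0);
  NumericMatrix exit_day(K, n_imm);
  std::fill(exit_day.begin(), exit_day.end(), NA_REAL);
  NumericVector adult_surv(K, 0.0);
  bool truncated = false;
  int days_used = 0;

  for (int j = 0; j < K; ++j) {
    int stage = 0;          // 0..n_imm-1 immature, n_imm adult, n_imm+1 dead
    double a = 0.0, ls = 0.0, af = 0.0;
    for (int d = 0; d < max_days && stage <= n_imm; ++d) {
      if (d + 1 > days_used) days_used = d + 1;
      lx[d] += w * std::exp(ls);
      for (int i = 0; i < steps && stage <= n_imm; ++i) {
        double f = 1.0;     // remaining fraction of this step
        while (f > 1e-12 && stage <= n_imm) {
          if (stage < n_imm) {
            double inc = da(i, stage) * f;
            double q = exit_q(j, stage);
            if (inc > 0.0 && a + inc >= q) {
              double used = (q - a) / da(i, stage); // fraction of full step
              ls += lsurv(i, stage) * used;
              f -= used;
              exit_day(j, stage) = d + (i + (1.0 - f)) / steps;
              a = 0.0;
              ++stage;
              if (stage == n_imm) { af = 0.0; adult_surv[j] = std::exp(ls); }
            } else {
              a += inc;
              ls += lsurv(i, stage) * f;
              f = 0.0;
            }
          } else {          // adult female
            double inc = sen_da[i] * f;
            double qL = long_q[j];
            bool dies = (inc > 0.0 && af + inc >= qL);
            double af_stop = dies ? qL : af + inc;
            double eggs = fec_w[i] * (cumfec(af_stop, cf_a, cf_b, cf_c) -
                                      cumfec(af, cf_a, cf_b, cf_c));
            phi[d] += w * std::exp(ls) * sex_ratio * eggs;
            af = af_stop;
            if (dies) stage = n_imm + 1;
            f = 0.0;
          }
        }
      }
      if (ls < dead_ls) stage = n_imm + 2;  // survivorship vanished
      if (d == max_days - 1 && stage <= n_imm) truncated = true;
    }
  }

  lx.resize(days_used);
  phi.resize(days_used);
  return List::create(_["lx"] = wrap(lx), _["phi"] = wrap(phi),
                      _["exit_day"] = exit_day,
                      _["adult_surv"] = adult_surv,
                      _["truncated"] = truncated,
                      _["days"] = days_used);
}
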