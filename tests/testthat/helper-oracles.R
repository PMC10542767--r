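# Independent brute-force implementations used as oracles. These share no
# code with the package's engine: plain R loops, step-granular transitions.

# Explicit time-stepping cohort simulator. Stage transitions happen at
# whole-step granularity (no fractional steps), so at fine step sizes it
# converges to the same continuous limit as the package kernel.
brute_force_cohort <- function(model, temps, n_quantiles = 6, max_days = 150) {
  steps <- length(temps)
  dt <- 1 / steps
  imm <- model$stages[c("egg", "larva", "pupa")]
  K <- n_quantiles
  qp <- (seq_len(K) - 0.5) / K

  rate <- sapply(imm, function(s) evaluate_rate(s$dev_rate, temps) * dt)
  lsrv <- sapply(imm, function(s) {
    log(pmax(1 - evaluate_mortality(s$mortality, temps), 1e-300)) * dt
  })
  qexit <- sapply(imm, function(s) phenorisk:::devtime_quantile(s$devtime_dist, qp))
  fem <- model$stages$adult_female
  sen <- evaluate_senescence(fem$senescence, temps) * dt
  qlong <- phenorisk:::devtime_quantile(fem$devtime_dist, qp)
  fecw <- evaluate_fecundity(model$fecundity_mean, temps)
  cf <- model$fecundity_cum$params
  C <- function(x) 1 - exp(-(cf$a * x + cf$b * x^2 + cf$c * x^3))

  stage <- rep(1L, K); a <- numeric(K); ls <- numeric(K); af <- numeric(K)
  lx <- numeric(max_days); phi <- numeric(max_days)
  for (d in seq_len(max_days)) {
    alive <- stage <= 4L
    if (!any(alive & exp(ls) > 1e-14)) { lx <- lx[seq_len(d - 1)]; phi <- phi[seq_len(d - 1)]; break }
    lx[d] <- sum(exp(ls[alive])) / K
    for (i in seq_len(steps)) {
      for (j in seq_len(K)) {
        s <- stage[j]
        if (s <= 3L) {
          a[j] <- a[j] + rate[i, s]
          ls[j] <- ls[j] + lsrv[i, s]
          if (a[j] >= qexit[j, s]) {
            stage[j] <- s + 1L
            a[j] <- 0
            if (stage[j] == 4L) af[j] <- 0
          }
        } else if (s == 4L) {
          af_new <- af[j] + sen[i]
          phi[d] <- phi[d] +
            exp(ls[j]) * 0.5 * fecw[i] * (C(af_new) - C(af[j])) / K
          af[j] <- af_new
          if (af[j] >= qlong[j]) stage[j] <- 5L
        }
      }
    }
  }
  list(lx = lx, phi = phi)
}

# dense grid-search for the Lotka-Euler intrinsic rate: locate the sign
# change of f(r) on a coarse grid, then refine on a fine grid.
grid_search_r <- function(x, phi, coarse = 1e-3, fine = 1e-7) {
  f <- function(r) colSums(exp(outer(x, r, function(a, b) -a * b)) * phi) - 1
  rg <- seq(-2, 2, by = coarse)
  fv <- f(rg)
  k <- which(fv[-length(fv)] > 0 & fv[-1] <= 0)[1]
  stopifnot(!is.na(k))
  rf <- seq(rg[k], rg[k + 1], by = fine)
  fvf <- f(rf)
  rf[which.min(abs(fvf))]
}
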