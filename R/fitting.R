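#' Fit a temperature-response function to observations
#'
#' Bounded nonlinear least squares (Levenberg–Marquardt via
#' [minpack.lm::nls.lm()]) with multi-start: `n_starts` jittered initial
#' values are tried under a fixed seed and the best residual sum of squares
#' wins, because thermal-performance curves routinely have local optima.
#' Families with a linearizing transform (`exp_simple_senescence`,
#' `cll_devtime`, `logit_devtime`) are seeded from an exact linear
#' regression before refinement.
#'
#' @param family Function family name (see [fn_spec()]).
#' @param observations Data frame with a `value` column and an abscissa
#'   column: `temperature` (or `temperature_C`) for temperature families,
#'   `x` for the normalized-age families. Extra columns are ignored, so a
#'   pre-filtered slice of [gen_lifetable_observations()] output works
#'   directly.
#' @param init Optional named list of starting parameter values; also the
#'   place to pin the fixed parameters of partially-fitted families
#'   (`wang_mortality_1` `k`; `sharpe_demichele_1` `tl`, `hl`).
#' @param n_starts Number of jittered starts (default 5).
#' @param seed Seed for the start jitter (default 1).
#' @return An object of class `thermal_fit`: the fitted [fn_spec()] plus
#'   diagnostics. Non-convergence is flagged in the result, never thrown.
#'   Use [tidy()] / [glance()] for tabular access.
#' @examples
#' tru <- fn_spec("taylor_fecundity_1", list(f_max = 200, t_opt = 24, sigma = 4))
#' obs <- data.frame(temperature = seq(12, 34, by = 2))
#' obs$value <- evaluate_fecundity(tru, obs$temperature)
#' fit <- fit_function("taylor_fecundity_1", obs)
#' glance(fit)
#' @export
fit_function <- function(family, observations, init = NULL, n_starts = 5,
                         seed = 1L) {
  family <- match.arg(family, names(.fn_families))
  xy <- .fit_extract_xy(family, observations)
  setup <- .fit_setup(family, xy, init)
  free <- setup$free
  if (length(unique(xy$x)) < length(free)) {
    abort(sprintf(
      "fit_function('%s'): need >= %d distinct abscissa values, got %d",
      family, length(free), length(unique(xy$x))))
  }

  make_spec <- function(theta) {
    p <- setup$fixed
    p[free] <- as.list(pmin(pmax(theta, setup$lower), setup$upper))
    fn_spec(family, p, temp_domain = setup$temp_domain)
  }
  resid_fun <- function(theta) {
    evaluate_fn(make_spec(theta), xy$x) - xy$value
  }

  starts <- withr::with_seed(seed, {
    base <- unlist(setup$start[free])
    lapply(seq_len(max(1, n_starts)), function(i) {
      if (i == 1) return(base)
      jit <- base * exp(rnorm(length(base), 0, 0.15)) +
        rnorm(length(base), 0, 0.02 * pmax(abs(base), 1e-8))
      pmin(pmax(jit, setup$lower), setup$upper)
    })
  })

  best <- NULL
  for (s in starts) {
    ans <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = resid_fun,
        lower = setup$lower, upper = setup$upper,
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ans)) next
    rss <- sum(ans$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = ans$par, rss = rss, info = ans$info)
    }
  }
  if (is.null(best)) {
    # every start failed: report the first start, flagged unconverged
    best <- list(par = starts[[1]], rss = sum(resid_fun(starts[[1]])^2),
                 info = 0L)
  }
  spec <- make_spec(best$par)
  fitted <- evaluate_fn(spec, xy$x)
  structure(
    list(
      spec = spec, family = family,
      estimates = setNames(as.numeric(best$par), free),
      fixed = setup$fixed[setdiff(names(setup$fixed), free)],
      rss = sum((fitted - xy$value)^2),
      converged = best$info %in% 1:4,
      n_obs = nrow(xy),
      data = xy, fitted = fitted
    ),
    class = "thermal_fit"
  )
}

.fit_extract_xy <- function(family, observations) {
  observations <- as.data.frame(observations)
  kind <- .fn_families[[family]]$kind
  xcol <- if (kind %in% c("devtime", "cumfec")) {
    intersect(c("x", "normalized_age"), names(observations))[1]
  } else {
    intersect(c("temperature", "temperature_C", "temp"), names(observations))[1]
  }
  if (is.na(xcol) || !"value" %in% names(observations)) {
    abort("observations need a 'value' column and a 'temperature' (or 'x') column")
  }
  xy <- data.frame(x = observations[[xcol]], value = observations$value)
  xy <- xy[is.finite(xy$x) & is.finite(xy$value), , drop = FALSE]
  if (nrow(xy) == 0) abort("no finite observations to fit")
  xy
}

# per-family free parameters, bounds, data-driven starting values and any
# fixed parameters; mortality/CDF families clip through their evaluators.
.fit_setup <- function(family, xy, init) {
  x <- xy$x; v <- xy$value
  init <- as.list(init %||% list())
  pos <- v > max(v, 0) * 1e-6
  dom <- c(-50, 60)
  out <- switch(family,
    briere_1 = {
      xm <- if (any(pos)) min(x[pos]) else min(x)
      xM <- if (any(pos)) max(x[pos]) else max(x)
      xpk <- x[which.max(v)]
      t_min0 <- init$t_min %||% (xm - 3)
      t_max0 <- init$t_max %||% (xM + 3)
      a0 <- init$a %||%
        (max(v) / max(xpk * (xpk - t_min0) * sqrt(max(t_max0 - xpk, 0.5)), 1e-9))
      list(free = c("a", "t_min", "t_max"),
           lower = c(1e-10, -20, xM + 1e-4),
           upper = c(1, xm - 1e-4, 60),
           start = list(a = a0, t_min = min(t_min0, xm - 0.5),
                        t_max = max(t_max0, xM + 0.5)),
           fixed = list(), temp_domain = dom)
    },
    taylor_fecundity_1 = {
      list(free = c("f_max", "t_opt", "sigma"),
           lower = c(1e-8, min(x) - 20, 0.1),
           upper = c(10 * max(v, 1), max(x) + 20, 100),
           start = list(f_max = init$f_max %||% max(v),
                        t_opt = init$t_opt %||% x[which.max(v)],
                        sigma = init$sigma %||% (diff(range(x)) / 4)),
           fixed = list(), temp_domain = dom)
    },
    wang_mortality_1 = {
      list(free = c("s_opt", "t_opt", "b"),
           lower = c(1e-6, min(x) - 20, 0.1),
           upper = c(1, max(x) + 20, 100),
           start = list(s_opt = init$s_opt %||% max(1 - min(v), 0.05),
                        t_opt = init$t_opt %||% x[which.min(v)],
                        b = init$b %||% (diff(range(x)) / 2)),
           fixed = list(k = init$k %||% 1), temp_domain = dom)
    },
    sharpe_demichele_1 = {
      near25 <- v[which.min(abs(x - 25))]
      list(free = c("rho25", "ha", "th", "hh"),
           lower = c(1e-8, 1e3, 273.15, 1e4),
           upper = c(10, 1e5, 273.15 + 60, 1e6),
           start = list(rho25 = init$rho25 %||% max(near25, 1e-4),
                        ha = init$ha %||% 2e4,
                        th = init$th %||% (x[which.max(v)] + 3 + 273.15),
                        hh = init$hh %||% 2e5),
           fixed = list(tl = init$tl %||% 285, hl = init$hl %||% -1e5),
           temp_domain = dom)
    },
    exp_simple_senescence = {
      ok <- v > 0
      cf <- if (sum(ok) >= 2) coef(lm(log(v[ok]) ~ x[ok])) else c(log(1e-2), 0.05)
      list(free = c("a", "b"), lower = c(1e-12, -5), upper = c(1e3, 5),
           start = list(a = init$a %||% exp(cf[[1]]), b = init$b %||% cf[[2]]),
           fixed = list(), temp_domain = dom)
    },
    exp_modified_cumfec_3 = {
      list(free = c("a", "b", "c"), lower = c(0, 0, 0), upper = rep(100, 3),
           start = list(a = init$a %||% 0.5, b = init$b %||% 1,
                        c = init$c %||% 0.5),
           fixed = list(), temp_domain = dom)
    },
    cll_devtime = ,
    logit_devtime = {
      inb <- v > 1e-9 & v < 1 - 1e-9 & x > 0
      cf <- if (sum(inb) >= 2) {
        eta <- if (family == "cll_devtime") log(-log(1 - v[inb])) else
          log(v[inb] / (1 - v[inb]))
        coef(lm(eta ~ log(x[inb])))
      } else c(0, 5)
      list(free = c("a", "b"), lower = c(-50, 1e-3), upper = c(50, 200),
           start = list(a = init$a %||% cf[[1]], b = init$b %||% max(cf[[2]], 0.1)),
           fixed = list(), temp_domain = dom)
    }
  )
  out
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("<thermal_fit: %s on %d observations>\n", x$family, x$n_obs))
  cat("  estimates:",
      paste(sprintf("%s = %.6g", names(x$estimates), x$estimates),
            collapse = ", "), "\n")
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

#' @rdname fit_function
#' @param x,object A `thermal_fit`.
#' @param ... Unused.
#' @export
tidy.thermal_fit <- function(x, ...) {
  tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @rdname fit_function
#' @export
glance.thermal_fit <- function(x, ...) {
  tibble(rss = x$rss,
         sigma = sqrt(x$rss / max(x$n_obs - length(x$estimates), 1)),
         converged = x$converged, n_obs = x$n_obs, family = x$family)
}
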