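#' Abbott correction for natural (control) mortality
#'
#' Rescales treated mortality for the mortality observed in the untreated
#' control: `100 * (T - C) / (100 - C)`, floored at zero when treated
#' mortality falls below the control's.
#'
#' @param treated_pct treated mortality, percent in \[0, 100\].
#' @param control_pct control mortality, percent in \[0, 100).
#' @return corrected percent mortality.
#' @examples
#' abbott_correct(60, 20)
#' @export
abbott_correct <- function(treated_pct, control_pct) {
  check_numeric(treated_pct, "treated_pct")
  check_numeric(control_pct, "control_pct")
  if (any(control_pct >= 100))
    abort("`control_pct` >= 100: the control is fully dead, correction undefined")
  if (any(control_pct < 0) || any(treated_pct < 0 | treated_pct > 100))
    abort("mortalities must lie in [0, 100]")
  pmax(0, 100 * (treated_pct - control_pct) / (100 - control_pct))
}

#' Angular (arcsine square-root) transformation
#'
#' `asin(sqrt(p))` in degrees, the classical variance-stabilising transform
#' for percentage data destined for analysis of variance. Provided as a
#' standalone utility; the probit fits in this package operate on corrected
#' proportions directly (see the package vignette).
#'
#' @param p proportion(s) in \[0, 1\].
#' @return angle in degrees, in \[0, 90\].
#' @examples
#' angular_transform(c(0, 0.5, 1))
#' @export
angular_transform <- function(p) {
  check_numeric(p, "p")
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1]")
  asin(sqrt(p)) * 180 / pi
}

#' Empirical probit of a mortality proportion
#'
#' The classical probit with the +5 offset: `5 + qnorm(p)`. Proportions of
#' exactly 0 or 1 have no finite probit; adjust them first with
#' [continuity_adjust()].
#'
#' @param p proportion(s) strictly inside (0, 1).
#' @return probit value(s).
#' @examples
#' empirical_probit(0.5)
#' @export
empirical_probit <- function(p) {
  check_numeric(p, "p")
  if (any(p <= 0 | p >= 1))
    abort("`p` must lie strictly in (0, 1); use continuity_adjust() for 0%%/100%% groups")
  5 + qnorm(p)
}

#' Continuity adjustment for extreme mortality groups
#'
#' Converts death counts to proportions, replacing 0 with `1/(2n)` and 1
#' with `1 - 1/(2n)` so that every group has a finite probit.
#'
#' @param n_dead death count(s), `0 <= n_dead <= n_exposed`.
#' @param n_exposed positive exposure count(s).
#' @return adjusted proportion(s) strictly inside (0, 1).
#' @examples
#' continuity_adjust(c(0, 125, 250), 250)
#' @export
continuity_adjust <- function(n_dead, n_exposed) {
  check_numeric(n_dead, "n_dead")
  check_numeric(n_exposed, "n_exposed")
  if (any(n_exposed <= 0)) abort("`n_exposed` must be > 0")
  if (any(n_dead < 0) || any(n_dead > n_exposed))
    abort("`n_dead` must lie in [0, n_exposed]")
  p <- n_dead / n_exposed
  p <- ifelse(p == 0, 1 / (2 * n_exposed), p)
  ifelse(p == 1, 1 - 1 / (2 * n_exposed), p)
}

#' Assemble a concentration-mortality series
#'
#' Builds the validated series consumed by [fit_probit()]. Mortality can be
#' given as cumulative percent (`mortality_pct`) or death counts (`n_dead`).
#' If `control_mortality_pct` is non-zero, Abbott's correction is applied to
#' the percentages. Groups at identical concentrations are pooled by summing
#' deaths and exposures.
#'
#' @param concentration positive concentration(s), mg/mL (for mixtures, the
#'   total of the two components).
#' @param mortality_pct cumulative percent mortality in \[0, 100\]; exactly
#'   one of `mortality_pct` / `n_dead` must be supplied.
#' @param n_dead death counts, alternative to `mortality_pct`.
#' @param n_exposed mites per group (default 250 = 50 mites x 5 replicates).
#' @param label treatment name carried through reports.
#' @param time_d post-exposure duration in days (default 4).
#' @param control_mortality_pct control mortality used for Abbott correction
#'   (default 0, i.e. mortalities already corrected).
#' @return an object of class `bioassay_series`: a list with a `groups`
#'   data.frame (`concentration`, `n_exposed`, `n_dead`, `mortality_pct`)
#'   plus `label`, `time_d` and `control_mortality_pct`.
#' @examples
#' bioassay_series(c(0.7, 1.4, 2.1, 2.8, 3.5),
#'                 mortality_pct = c(12.4, 21.6, 28.8, 42.4, 56.8),
#'                 label = "(+)-alpha-Pinene")
#' @export
bioassay_series <- function(concentration, mortality_pct = NULL,
                            n_dead = NULL, n_exposed = 250,
                            label = "series", time_d = 4,
                            control_mortality_pct = 0) {
  check_numeric(concentration, "concentration")
  if (any(concentration <= 0)) abort("`concentration` must be > 0")
  if (is.null(mortality_pct) == is.null(n_dead))
    abort("supply exactly one of `mortality_pct` or `n_dead`")
  n_exposed <- rep_len(n_exposed, length(concentration))
  if (any(n_exposed <= 0)) abort("`n_exposed` must be > 0")
  if (!is.null(mortality_pct)) {
    check_numeric(mortality_pct, "mortality_pct")
    if (any(mortality_pct < 0 | mortality_pct > 100))
      abort("`mortality_pct` must lie in [0, 100]")
    if (control_mortality_pct > 0)
      mortality_pct <- abbott_correct(mortality_pct, control_mortality_pct)
    n_dead <- mortality_pct / 100 * n_exposed
  } else {
    check_numeric(n_dead, "n_dead")
    if (any(n_dead < 0 | n_dead > n_exposed))
      abort("`n_dead` must lie in [0, n_exposed]")
    if (control_mortality_pct > 0) {
      pct <- abbott_correct(100 * n_dead / n_exposed, control_mortality_pct)
      n_dead <- pct / 100 * n_exposed
    }
  }
  g <- data.frame(concentration = concentration, n_exposed = n_exposed,
                  n_dead = n_dead)
  # pool replicated concentrations
  if (anyDuplicated(g$concentration)) {
    g <- aggregate(cbind(n_exposed, n_dead) ~ concentration, data = g, sum)
  }
  g <- g[order(g$concentration), , drop = FALSE]
  g$mortality_pct <- 100 * g$n_dead / g$n_exposed
  rownames(g) <- NULL
  structure(list(label = label, time_d = time_d,
                 control_mortality_pct = control_mortality_pct, groups = g),
            class = "bioassay_series")
}

#' @export
print.bioassay_series <- function(x, ...) {
  cat(sprintf("Concentration-mortality series '%s' (%g d, control mortality %g%%)\n",
              x$label, x$time_d, x$control_mortality_pct))
  print(x$groups, ...)
  invisible(x)
}

#' Probit concentration-mortality regression
#'
#' Fits mortality probability as `Phi(beta0 + beta1 * log10(concentration))`
#' and reports the fit on the conventional probit-plus-5 scale, so that
#' `log10(LC50) = (5 - intercept) / slope`.
#'
#' Two methods are available. `"ml"` (default) is binomial maximum
#' likelihood computed by iteratively reweighted least squares with Finney
#' weights `w = n z^2 / (PQ)`; iteration stops when successive log10-LC50
#' estimates change by less than `tol` (1e-8) or after `max_iter` rounds.
#' `"ols"` is the transparent textbook variant: ordinary least squares of
#' empirical probits (after continuity adjustment) on log10 concentration.
#' The ML fit is initialised from the OLS fit.
#'
#' The heterogeneity chi-square compares observed deaths with fitted
#' binomial expectations over the dose groups; its degrees of freedom are
#' `#groups - 2`.
#'
#' @param series a [bioassay_series()].
#' @param method `"ml"` or `"ols"`.
#' @param tol convergence tolerance on log10-LC50 (ML only).
#' @param max_iter maximum IRLS iterations (ML only).
#' @return object of class `probit_fit`: list with `slope`, `intercept`
#'   (probit-plus-5 scale), `log_lc50`, `cov` (2x2 covariance of
#'   (intercept, slope)), `chi2_het`, `df`, `method`, `converged`,
#'   `iterations` and the input `series`.
#' @examples
#' s <- bioassay_series(c(0.7, 1.4, 2.1, 2.8, 3.5),
#'                      mortality_pct = c(12.4, 21.6, 28.8, 42.4, 56.8))
#' fit_probit(s)
#' @export
fit_probit <- function(series, method = c("ml", "ols"), tol = 1e-8,
                       max_iter = 100L) {
  method <- match.arg(method)
  if (!inherits(series, "bioassay_series"))
    abort("`series` must be a bioassay_series")
  g <- series$groups
  if (nrow(g) < 2L)
    abort("at least 2 dose groups with distinct concentrations required, found %d",
          nrow(g))
  x <- log10(g$concentration)
  n <- g$n_exposed
  p_obs <- continuity_adjust(g$n_dead, g$n_exposed)

  # OLS on empirical probits: both the "ols" answer and the ML start values
  probits <- empirical_probit(p_obs)
  ols <- lm(probits ~ x)
  b0 <- unname(coef(ols)[1]); b1 <- unname(coef(ols)[2])

  if (method == "ols") {
    # vcov warns on an exactly linear (noiseless) series; harmless here
    ols_cov <- suppressWarnings(unname(vcov(ols)))
    fit <- list(slope = b1, intercept = b0, cov = ols_cov,
                converged = TRUE, iterations = 0L)
  } else {
    fit <- probit_irls(x, p_obs, n, alpha = b0 - 5, beta = b1,
                       tol = tol, max_iter = max_iter)
    if (!fit$converged)
      abort("IRLS did not converge in %d iterations (last log10-LC50 %.6f)",
            max_iter, -fit$intercept_z / fit$slope)
    fit$intercept <- fit$intercept_z + 5
  }
  slope <- fit$slope
  if (slope <= 0)
    warning("non-positive probit slope (", signif(slope, 4),
            "): series shows no dose-response", call. = FALSE)
  log_lc50 <- (5 - fit$intercept) / slope

  eta <- (fit$intercept - 5) + slope * x
  p_hat <- pnorm(eta)
  chi2 <- sum((g$n_dead - n * p_hat)^2 / (n * p_hat * (1 - p_hat)))
  structure(list(slope = slope, intercept = fit$intercept,
                 log_lc50 = log_lc50, cov = fit$cov,
                 chi2_het = chi2, df = nrow(g) - 2L, method = method,
                 converged = fit$converged, iterations = fit$iterations,
                 series = series),
            class = "probit_fit")
}

# Finney-weight IRLS on the z scale (eta = alpha + beta x); covariance is
# (X' W X)^{-1}, identical on the probit-plus-5 scale since the shift is
# a constant offset of the intercept.
probit_irls <- function(x, p_obs, n, alpha, beta, tol, max_iter) {
  X <- cbind(1, x)
  lc_old <- -alpha / beta
  converged <- FALSE
  iter <- 0L
  W <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- alpha + beta * x
    P <- pnorm(eta)
    # guard collapse to 0/1 (complete separation pushes eta out)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    z <- dnorm(eta)
    if (any(z < 1e-300))
      abort("complete separation: probit slope diverging (working density underflow)")
    w <- n * z^2 / (P * (1 - P))
    y <- eta + (p_obs - P) / z
    XtW <- t(X * w)
    est <- solve(XtW %*% X, XtW %*% y)
    alpha <- est[1]; beta <- est[2]
    W <- w
    lc_new <- -alpha / beta
    if (is.finite(lc_new) && abs(lc_new - lc_old) < tol) {
      converged <- TRUE
      break
    }
    lc_old <- lc_new
  }
  cov <- solve(t(X * W) %*% X)
  dimnames(cov) <- NULL
  list(slope = beta, intercept_z = alpha, cov = cov,
       converged = converged, iterations = iter)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit fit (%s) for '%s': slope %.4f, intercept %.4f\n",
              x$method, x$series$label, x$slope, x$intercept))
  cat(sprintf("  log10 LC50 = %.4f  (LC50 = %.4g mg/mL)\n",
              x$log_lc50, 10^x$log_lc50))
  cat(sprintf("  heterogeneity chi-square %.3f on %d df\n", x$chi2_het, x$df))
  invisible(x)
}

#' LC50 with Fieller fiducial limits
#'
#' Point estimate `10^log_lc50` with 95% (by default) fiducial limits for
#' the ratio `(5 - intercept) / slope` by Fieller's theorem. When the
#' heterogeneity chi-square exceeds its degrees of freedom, the parameter
#' covariance is inflated by the heterogeneity factor `chi2/df` and the
#' normal critical value is replaced by Student's t on `df` degrees of
#' freedom (Finney's practice). When the Fieller `g` statistic reaches 1 the
#' limits are unbounded; the estimate is returned with `NA` limits and
#' `limits_defined = FALSE`.
#'
#' @param fit a [fit_probit()] result with positive slope.
#' @param level confidence level (default 0.95).
#' @return object of class `lc50_estimate`: list with `lc50`, `lower`,
#'   `upper` (mg/mL), `g`, `heterogeneity_factor`, `limits_defined`,
#'   `level` and the originating `fit`.
#' @examples
#' s <- bioassay_series(c(0.7, 1.4, 2.1, 2.8, 3.5),
#'                      mortality_pct = c(12.4, 21.6, 28.8, 42.4, 56.8))
#' lc50_with_limits(fit_probit(s))
#' @export
lc50_with_limits <- function(fit, level = 0.95) {
  if (!inherits(fit, "probit_fit")) abort("`fit` must be a probit_fit")
  if (fit$slope <= 0) abort("LC50 undefined for non-positive slope")
  h <- max(1, fit$chi2_het / fit$df)
  crit <- if (h > 1 && fit$df > 0) qt(1 - (1 - level) / 2, fit$df)
          else qnorm(1 - (1 - level) / 2)
  # ratio r = a/b with a = 5 - intercept, b = slope
  a <- 5 - fit$intercept
  b <- fit$slope
  va <- h * fit$cov[1, 1]            # var(5 - intercept) = var(intercept)
  vb <- h * fit$cov[2, 2]
  cab <- -h * fit$cov[1, 2]          # cov(5 - intercept, slope)
  g <- crit^2 * vb / b^2
  m <- fit$log_lc50
  if (g >= 1) {
    lo <- hi <- NA_real_
    defined <- FALSE
  } else {
    disc <- b^2 * va - 2 * a * b * cab + a^2 * vb - crit^2 * (va * vb - cab^2)
    if (disc < 0) disc <- 0
    denom <- b^2 - crit^2 * vb
    lo <- ((a * b - crit^2 * cab) - crit * sqrt(disc)) / denom
    hi <- ((a * b - crit^2 * cab) + crit * sqrt(disc)) / denom
    defined <- TRUE
  }
  structure(list(lc50 = 10^m,
                 lower = if (defined) 10^lo else NA_real_,
                 upper = if (defined) 10^hi else NA_real_,
                 g = g, heterogeneity_factor = h,
                 limits_defined = defined, level = level, fit = fit),
            class = "lc50_estimate")
}

#' @export
print.lc50_estimate <- function(x, ...) {
  lim <- if (x$limits_defined)
    sprintf("(%.4g to %.4g)", x$lower, x$upper) else "(limits undefined, g >= 1)"
  cat(sprintf("LC50 = %.4g mg/mL %s  [%d%% fiducial, g = %.3g, h = %.3g]\n",
              x$lc50, lim, round(100 * x$level), x$g, x$heterogeneity_factor))
  invisible(x)
}
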