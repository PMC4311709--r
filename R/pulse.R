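#' Regular sensor time series
#'
#' Equally spaced soil sensor readings: volumetric moisture (m3 H2O m-3
#' soil), CO2 concentration (ppmv) and, optionally, temperature (degC,
#' carried but unused by the pulse regression).
#'
#' @param time_h timestamps in hours, equally spaced, increasing.
#' @param moisture volumetric soil moisture, nonnegative.
#' @param co2 soil CO2 concentration (ppmv).
#' @param temperature optional soil temperature (degC).
#' @return a data.frame of class `sensor_series` with attribute `step_h`.
#' @export
sensor_series <- function(time_h, moisture, co2, temperature = NULL) {
  n <- length(time_h)
  if (n < 2L) stopf("a sensor series needs at least 2 points")
  if (length(moisture) != n || length(co2) != n)
    stopf("time_h, moisture and co2 must have equal length")
  steps <- diff(time_h)
  if (any(steps <= 0)) stopf("time_h must be strictly increasing")
  if (max(steps) - min(steps) > 1e-8 * max(steps))
    stopf("time_h must be equally spaced")
  if (any(!is.finite(moisture)) || any(!is.finite(co2)))
    stopf("moisture and co2 must be finite (no missing values)")
  if (any(moisture < 0)) stopf("moisture must be nonnegative")
  d <- data.frame(time_h = as.numeric(time_h),
                  moisture = as.numeric(moisture),
                  co2 = as.numeric(co2))
  if (!is.null(temperature)) {
    if (length(temperature) != n)
      stopf("temperature must match the series length")
    d$temperature <- as.numeric(temperature)
  }
  structure(d, step_h = steps[1L],
            class = c("sensor_series", "data.frame"))
}

#' Aggregate a sensor series to a coarser time step
#'
#' Block-averages the series into consecutive half-open windows
#' `[t, t + window_h)`: each output point is the arithmetic mean of the
#' input points falling in its window (e.g. 30-min sensor readings averaged
#' to the 12-h analysis step). A trailing partial window is dropped.
#'
#' @param series a [sensor_series()].
#' @param window_h output step in hours; must be a positive multiple of the
#'   input spacing.
#' @return an aggregated [sensor_series()]; output timestamps are the
#'   window start times.
#' @export
aggregate_series <- function(series, window_h) {
  stopifnot(inherits(series, "sensor_series"))
  step <- attr(series, "step_h")
  check_scalar_number(window_h, "window_h", lower = 0, strict_lower = TRUE)
  k <- window_h / step
  if (k < 1 - 1e-8)
    stopf("window_h (%g) is smaller than the series spacing (%g)",
          window_h, step)
  if (abs(k - round(k)) > 1e-8)
    stopf("window_h (%g) must be a multiple of the series spacing (%g)",
          window_h, step)
  k <- as.integer(round(k))
  n_out <- nrow(series) %/% k
  if (n_out < 2L)
    stopf("aggregation would leave fewer than 2 points")
  grp <- rep(seq_len(n_out), each = k)
  used <- seq_len(n_out * k)
  agg <- function(x) as.numeric(tapply(x[used], grp, mean))
  t0 <- series$time_h[1L] + (seq_len(n_out) - 1L) * window_h
  sensor_series(t0, agg(series$moisture), agg(series$co2),
                if ("temperature" %in% names(series)) agg(series$temperature))
}

#' Fit the lagged moisture-to-CO2 pulse regression
#'
#' Fits `co2(t) ~ co2(t-1) + moisture(t) + moisture(t-1)` by ordinary least
#' squares for `t = 2..n`, then corrects for autocorrelated residuals by
#' iterated Cochrane-Orcutt AR(1) quasi-differencing: the AR coefficient
#' `rho` is estimated from the lag-1 autocorrelation of the original-scale
#' residuals, all variables are quasi-differenced (`z*_t = z_t - rho
#' z_{t-1}`, intercept column `1 - rho`), the model refit, and the cycle
#' repeated until `|delta rho| < tol` (default 1e-6) or `max_iter`
#' iterations (a non-converged fit carries a warning flag and the last
#' iterate). `correction = "hac"` instead keeps the OLS point estimates and
#' replaces the covariance with Newey-West HAC standard errors;
#' `correction = "none"` is plain OLS.
#'
#' R-squared is reported on the original (undifferenced) scale —
#' `1 - RSS/TSS` of the one-step predictions — alongside
#' `r_squared_quasi` from the final quasi-differenced regression.
#'
#' Aliased predictors (e.g. constant moisture, which collapses the two
#' moisture columns into the intercept) are dropped with their coefficients
#' set to zero and recorded in `aliased`; if the CO2 lag is aliased too the
#' design is singular and an error is raised.
#'
#' @param series an aggregated [sensor_series()] of length >= 8.
#' @param correction residual correction: `"ar1"` (default), `"hac"`, or
#'   `"none"`.
#' @param max_iter,tol Cochrane-Orcutt iteration controls.
#' @return an object of class `pulse_fit`: coefficients (named `intercept`,
#'   `co2_lag`, `moisture`, `moisture_lag`), `se`, `t_stat`, `r_squared`,
#'   `r_squared_quasi`, `rho`, `n_obs`, `converged`, `aliased`,
#'   `correction`.
#' @export
fit_pulse_model <- function(series, correction = c("ar1", "hac", "none"),
                            max_iter = 50L, tol = 1e-6) {
  stopifnot(inherits(series, "sensor_series"))
  correction <- match.arg(correction)
  n <- nrow(series)
  if (n < 8L)
    stopf("series too short to fit (need >= 8 points, got %d)", n)
  y <- series$co2[-1L]
  X <- cbind(intercept = 1,
             co2_lag = series$co2[-n],
             moisture = series$moisture[-1L],
             moisture_lag = series$moisture[-n])
  qrX <- qr(X)
  keep <- sort(qrX$pivot[seq_len(qrX$rank)])
  aliased <- setdiff(colnames(X), colnames(X)[keep])
  if (length(keep) < 2L)
    stopf("singular design: moisture and CO2 are both constant")
  Xk <- X[, keep, drop = FALSE]

  ols <- function(yv, Xv) {
    fit <- qr(Xv)
    if (fit$rank < ncol(Xv))
      stopf("singular design in pulse-model fit")
    qr.coef(fit, yv)
  }

  beta_k <- ols(y, Xk)
  rho <- 0
  converged <- TRUE
  if (correction == "ar1") {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      e <- y - drop(Xk %*% beta_k)
      denom <- sum(e[-length(e)]^2)
      rho_new <- if (denom < .Machine$double.eps * max(1, sum(y^2)))
        0 else sum(e[-1L] * e[-length(e)]) / denom
      rho_new <- max(min(rho_new, 0.999), -0.999)
      ys <- y[-1L] - rho_new * y[-length(y)]
      Xs <- Xk[-1L, , drop = FALSE] -
        rho_new * Xk[-nrow(Xk), , drop = FALSE]
      beta_k <- ols(ys, Xs)
      if (abs(rho_new - rho) < tol) {
        rho <- rho_new
        converged <- TRUE
        break
      }
      rho <- rho_new
    }
    if (!converged)
      warnf("Cochrane-Orcutt iteration did not converge in %d iterations",
            max_iter)
    ys <- y[-1L] - rho * y[-length(y)]
    Xs <- Xk[-1L, , drop = FALSE] - rho * Xk[-nrow(Xk), , drop = FALSE]
    dfree <- nrow(Xs) - ncol(Xs)
    rss_s <- sum((ys - drop(Xs %*% beta_k))^2)
    sigma2 <- rss_s / max(dfree, 1L)
    cov_k <- sigma2 * chol2inv(chol(crossprod(Xs)))
    tss_s <- sum((ys - mean(ys))^2)
    r2_quasi <- if (tss_s > 0) 1 - rss_s / tss_s else 1
  } else {
    e <- y - drop(Xk %*% beta_k)
    dfree <- length(y) - ncol(Xk)
    if (correction == "hac") {
      lmfit <- stats::lm(y ~ Xk - 1)
      cov_k <- sandwich::NeweyWest(lmfit, prewhite = FALSE)
    } else {
      sigma2 <- sum(e^2) / max(dfree, 1L)
      cov_k <- sigma2 * chol2inv(chol(crossprod(Xk)))
    }
    tss <- sum((y - mean(y))^2)
    r2_quasi <- if (tss > 0) 1 - sum(e^2) / tss else 1
  }

  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  se <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  beta[names(beta_k)] <- beta_k
  se[names(beta_k)] <- sqrt(pmax(diag(cov_k), 0))
  resid_orig <- y - drop(X %*% beta)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(resid_orig^2) / tss else 1

  structure(list(
    coefficients = beta,
    se = se,
    t_stat = beta / se,
    r_squared = min(max(r2, 0), 1),
    r_squared_quasi = min(max(r2_quasi, 0), 1),
    rho = rho,
    n_obs = length(y),
    converged = converged,
    aliased = aliased,
    correction = correction,
    residuals = resid_orig),
    class = "pulse_fit")
}

#' @export
print.pulse_fit <- function(x, ...) {
  cat(sprintf("<pulse_fit> co2(t) ~ co2(t-1) + moisture(t) + moisture(t-1)  [%s]\n",
              x$correction))
  tab <- data.frame(estimate = x$coefficients, se = x$se, t = x$t_stat)
  print(round(tab, 4))
  cat(sprintf("  rho = %.4f, R2 = %.4f (quasi-diff R2 = %.4f), n = %d%s\n",
              x$rho, x$r_squared, x$r_squared_quasi, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$aliased))
    cat("  aliased:", paste(x$aliased, collapse = ", "), "\n")
  invisible(x)
}

#' One-step-ahead predictions from a pulse-model fit
#'
#' Predicts `co2(t)` for `t = 2..n` from the observed `co2(t-1)`,
#' `moisture(t)` and `moisture(t-1)` of `series`.
#'
#' @param object a [fit_pulse_model()] fit.
#' @param series a [sensor_series()] on the same time step as the fit.
#' @param ... unused.
#' @return data.frame with columns `time_h`, `observed`, `predicted`.
#' @export
predict.pulse_fit <- function(object, series, ...) {
  stopifnot(inherits(series, "sensor_series"))
  n <- nrow(series)
  X <- cbind(1, series$co2[-n], series$moisture[-1L], series$moisture[-n])
  data.frame(time_h = series$time_h[-1L],
             observed = series$co2[-1L],
             predicted = drop(X %*% object$coefficients))
}
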