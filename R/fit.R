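# The log-linear DDC model.
#
# Pooled model:     E[dmin](s) = alpha + beta * log(s)
# Observer model:   E[dmin](s) = (alpha + alpha_i') + (beta + beta_i') * log(s),
#                   with sum_i alpha_i' = sum_i beta_i' = 0.
#
# Under the sum-to-zero constraint the observer model is a reparameterised
# collection of independent per-observer lines, so the constrained
# least-squares solution is: fit each observer by OLS (pooling that
# observer's repeated curves), set alpha/beta to the unweighted means of the
# per-observer intercepts/slopes, and the offsets to the differences. This
# separability is exercised against a generic effects-coded constrained
# solve in the test suite.

#' Fit the log-linear difference-detail-curve model
#'
#' Fits `delta_min = alpha + beta * log(s)` (natural log of the rod diameter
#' in mm) to a set of DDC points, either pooled over all observers
#' (`observer_bias = FALSE`) or with per-observer sum-to-zero offsets
#' `alpha_i'`, `beta_i'` (`observer_bias = TRUE`). Diameters an observer did
#' not see (`NA`) are excluded; repeated curves of one observer (different
#' `scan_id`) share that observer's offsets.
#'
#' @param curves Data frame with columns `observer`, `diameter_mm`,
#'   `delta_min_hu` (e.g. from [extract_ddc()], [read_curves()] or
#'   [simulate_ddc_curves()]).
#' @param observer_bias Fit per-observer offsets? Requires at least two
#'   observers, each spanning at least two distinct diameters.
#' @return Object of class `ddc_fit` with components `alpha`, `beta` (HU and
#'   HU per log-mm), `offsets` (per-observer `alpha_i`, `beta_i`),
#'   `r_squared`, `n`, `fitted`, `residuals`, and the model frame `data`.
#'   `beta` is negative whenever larger objects are detected at lower
#'   contrast.
#' @examples
#' curves <- read_curves(system.file("extdata", "observer_curves_120kv_9mgy.csv",
#'                                   package = "ddcqa"))
#' fit <- ddc_fit(curves)
#' coef(fit)
#' predict(fit, s = 9)
#' @export
ddc_fit <- function(curves, observer_bias = TRUE) {
  d <- as.data.frame(curves)
  need <- c("observer", "diameter_mm", "delta_min_hu")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_ddcqa("curves lack column(s): %s", paste(miss, collapse = ", "))
  d <- d[!is.na(d$delta_min_hu), , drop = FALSE]
  if (!nrow(d)) stop_ddcqa("no non-missing DDC points to fit")
  if (any(d$diameter_mm <= 0)) stop_ddcqa("diameters must be positive")
  d$.x <- log(d$diameter_mm)
  if (length(unique(d$diameter_mm)) < 2)
    stop_ddcqa("underdetermined fit: need DDC points at >= 2 distinct diameters")
  cl <- match.call()
  if (!observer_bias) {
    fit <- lm(delta_min_hu ~ .x, data = d)
    alpha <- unname(coef(fit)[1]); beta <- unname(coef(fit)[2])
    offsets <- NULL
    fitted <- unname(fitted(fit))
  } else {
    obs <- unique(d$observer)
    if (length(obs) < 2)
      stop_ddcqa("observer model needs >= 2 observers (got %d); use observer_bias = FALSE",
                 length(obs))
    per <- t(vapply(obs, function(o) {
      g <- d[d$observer == o, ]
      if (length(unique(g$diameter_mm)) < 2)
        stop_ddcqa("observer '%s' has DDC points at < 2 distinct diameters; slope is inestimable", o)
      coef(lm(delta_min_hu ~ .x, data = g))
    }, numeric(2)))
    alpha <- mean(per[, 1]); beta <- mean(per[, 2])
    offsets <- data.frame(observer = obs,
                          alpha_i = per[, 1] - alpha,
                          beta_i = per[, 2] - beta,
                          row.names = NULL, stringsAsFactors = FALSE)
    io <- match(d$observer, obs)
    fitted <- unname(per[io, 1] + per[io, 2] * d$.x)
  }
  res <- d$delta_min_hu - fitted
  sst <- sum((d$delta_min_hu - mean(d$delta_min_hu))^2)
  structure(list(alpha = alpha, beta = beta, offsets = offsets,
                 observer_bias = observer_bias,
                 n = nrow(d), n_observers = length(unique(d$observer)),
                 fitted = fitted, residuals = res,
                 sigma = sqrt(sum(res^2) / max(1, nrow(d) -
                   if (observer_bias) 2 * length(unique(d$observer)) else 2)),
                 r_squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
                 data = d[, c(need, ".x")], log_base = "natural", call = cl),
            class = "ddc_fit")
}

#' @export
print.ddc_fit <- function(x, digits = 4, ...) {
  cat("Difference-detail-curve model: delta_min = alpha + beta * log(s)\n")
  cat(sprintf("  alpha = %s HU, beta = %s HU/log(mm)  (n = %d point%s",
              format(x$alpha, digits = digits), format(x$beta, digits = digits),
              x$n, if (x$n == 1) "" else "s"))
  cat(sprintf(", %d observer%s)\n", x$n_observers, if (x$n_observers == 1) "" else "s"))
  if (x$observer_bias)
    cat(sprintf("  observer offsets fitted (sum-to-zero), R^2 = %s\n",
                format(x$r_squared, digits = digits)))
  else
    cat(sprintf("  pooled fit, R^2 = %s\n", format(x$r_squared, digits = digits)))
  invisible(x)
}

#' @export
coef.ddc_fit <- function(object, ...) c(alpha = object$alpha, beta = object$beta)

#' @export
residuals.ddc_fit <- function(object, ...) object$residuals

#' @export
fitted.ddc_fit <- function(object, ...) object$fitted

#' Predict minimal detectable contrast from a DDC fit
#'
#' @param object A `ddc_fit`.
#' @param s Rod diameter(s), mm; must be positive.
#' @param observer Optional observer id whose offsets are applied; default
#'   uses the population parameters (offsets zero).
#' @param ... Unused.
#' @return Expected minimal detected contrast, HU.
#' @export
predict.ddc_fit <- function(object, s, observer = NULL, ...) {
  if (any(s <= 0)) stop_ddcqa("diameter s must be positive")
  a <- object$alpha; b <- object$beta
  if (!is.null(observer)) {
    if (is.null(object$offsets))
      stop_ddcqa("fit has no observer offsets (fitted with observer_bias = FALSE)")
    i <- match(observer, object$offsets$observer)
    if (is.na(i)) stop_ddcqa("unknown observer '%s'", observer)
    a <- a + object$offsets$alpha_i[i]
    b <- b + object$offsets$beta_i[i]
  }
  a + b * log(s)
}

#' @export
summary.ddc_fit <- function(object, ...) {
  out <- object[c("alpha", "beta", "offsets", "observer_bias", "n",
                  "n_observers", "r_squared", "sigma")]
  if (!is.null(object$offsets)) {
    out$sd_alpha_bias <- sd(object$offsets$alpha_i)
    out$sd_beta_bias <- sd(object$offsets$beta_i)
  }
  class(out) <- "summary.ddc_fit"
  out
}

#' @export
print.summary.ddc_fit <- function(x, digits = 4, ...) {
  cat("Difference-detail-curve model fit\n")
  cat(sprintf("  alpha: %s HU   beta: %s HU/log(mm)\n",
              format(x$alpha, digits = digits), format(x$beta, digits = digits)))
  cat(sprintf("  n = %d points, %d observer(s), R^2 = %s, residual sd = %s HU\n",
              x$n, x$n_observers, format(x$r_squared, digits = digits),
              format(x$sigma, digits = digits)))
  if (!is.null(x$offsets)) {
    cat("  observer offsets (sum to zero):\n")
    o <- x$offsets
    for (i in seq_len(nrow(o)))
      cat(sprintf("    %-12s alpha_i' = %9.4f   beta_i' = %8.4f\n",
                  o$observer[i], o$alpha_i[i], o$beta_i[i]))
    cat(sprintf("  sd of offsets: alpha' %s HU, beta' %s HU/log(mm)\n",
                format(x$sd_alpha_bias, digits = digits),
                format(x$sd_beta_bias, digits = digits)))
  }
  invisible(x)
}

#' Plot a DDC fit
#'
#' Plots the DDC points on a log-diameter axis with the pooled model line
#' and, when fitted, one line per observer.
#'
#' @param x A `ddc_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.ddc_fit <- function(x, ...) {
  d <- x$data
  obs <- unique(d$observer)
  cols <- setNames(grDevices::hcl.colors(max(3, length(obs)), "Dark 3")[seq_along(obs)], obs)
  plot(d$diameter_mm, d$delta_min_hu, log = "x", col = cols[d$observer],
       pch = 19, xlab = "rod diameter s (mm)",
       ylab = expression(Delta[min] * " HU"), ...)
  ss <- exp(seq(log(min(d$diameter_mm)), log(max(d$diameter_mm)), length.out = 64))
  lines(ss, x$alpha + x$beta * log(ss), lwd = 2)
  if (!is.null(x$offsets))
    for (o in obs)
      lines(ss, predict(x, ss, observer = o), col = cols[o], lty = 2)
  if (length(obs) > 1)
    legend("topright", legend = obs, col = cols, pch = 19, cex = 0.8, bty = "n")
  invisible(x)
}

#' Simulate DDC points from a fitted model
#'
#' Draws new responses at the fitted design points by adding Gaussian noise
#' with the residual standard deviation; a diagnostic device, not a model of
#' the discrete nominal-contrast grid.
#'
#' @param object A `ddc_fit`.
#' @param nsim Number of simulated replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of `nsim` data frames shaped like the model frame.
#' @export
simulate.ddc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    d <- object$data
    d$delta_min_hu <- object$fitted + rnorm(object$n, 0, object$sigma)
    d
  }
  if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
}
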