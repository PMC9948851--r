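# Bootstrap standard errors of the pooled DDC parameters.
#
# For each of m draws, k curves are sampled uniformly with replacement from
# the n available DDCs, the pooled log-linear model is fitted to the
# resample, and the standard deviation of the m estimates (1/(m-1) divisor)
# is the bootstrap standard error. Sampling is with replacement so that the
# k = n row remains a nonzero measure of observer variability.
#
# Because pooled-OLS normal equations are sums over points, the per-curve
# sufficient statistics (n, Sx, Sy, Sxx, Sxy with x = log diameter) are
# additive over a resample; each draw is therefore a row-sum of k
# precomputed statistic vectors, which makes m = 1e5 draws cheap. A draw
# whose pooled points span fewer than two distinct diameters has no defined
# slope; such draws are redrawn and counted.

#' Bootstrap standard errors of DDC model parameters
#'
#' @param curves Data frame of DDC points (`observer`, `diameter_mm`,
#'   `delta_min_hu`, optionally `scan_id`). A curve is one observer's
#'   evaluation of one scan (`observer` x `scan_id`).
#' @param k Number of curves per resample, `1 <= k <= n`.
#' @param m Number of resamples (default 1e5, enough to stabilise the
#'   standard errors at one significant digit).
#' @param seed Integer seed; fixed seed gives bit-identical results.
#' @param keep_draws Keep the per-draw `(alpha, beta)` estimates?
#' @return Object of class `ddc_boot` with `se_alpha`, `se_beta`, the draw
#'   means `mean_alpha`/`mean_beta`, `k`, `n`, `m`, `seed`,
#'   `n_degenerate` (redrawn resamples), and (optionally) the draws.
#' @examples
#' curves <- read_curves(system.file("extdata", "observer_curves_120kv_9mgy.csv",
#'                                   package = "ddcqa"))
#' ddc_bootstrap(curves, k = 5, m = 1000, seed = 1)
#' @export
ddc_bootstrap <- function(curves, k, m = 1e5, seed = 1, keep_draws = TRUE) {
  d <- as.data.frame(curves)
  d <- d[!is.na(d$delta_min_hu), , drop = FALSE]
  id <- if ("scan_id" %in% names(d))
    interaction(d$observer, d$scan_id, drop = TRUE)
  else factor(d$observer)
  n <- nlevels(id)
  if (k < 1 || k > n)
    stop_ddcqa("k must satisfy 1 <= k <= n (n = %d curves, got k = %s)", n, format(k))
  if (m < 2) stop_ddcqa("m must be >= 2")
  m <- as.integer(m); k <- as.integer(k)
  x <- log(d$diameter_mm); y <- d$delta_min_hu
  dia_levels <- sort(unique(d$diameter_mm))
  if (length(dia_levels) > 30)
    stop_ddcqa("more than 30 distinct diameters; not a DDC curve table?")
  per <- t(vapply(levels(id), function(l) {
    i <- id == l
    c(n = sum(i), sx = sum(x[i]), sy = sum(y[i]),
      sxx = sum(x[i]^2), sxy = sum(x[i] * y[i]),
      bits = sum(2^(match(unique(d$diameter_mm[i]), dia_levels) - 1)))
  }, numeric(6)))
  pool <- function(idx) {  # idx: m x k matrix of curve indices
    s <- matrix(0, nrow(idx), 5)
    b <- integer(nrow(idx))
    for (j in seq_len(ncol(idx))) {
      s <- s + per[idx[, j], 1:5, drop = FALSE]
      b <- bitwOr(b, as.integer(per[idx[, j], 6]))
    }
    list(s = s, bits = b)
  }
  popcount <- function(b) {
    tot <- integer(length(b))
    for (j in seq_along(dia_levels) - 1) tot <- tot + (bitwAnd(b, 2^j) > 0)
    tot
  }
  n_degenerate <- 0L
  alpha <- beta <- numeric(m)
  with_seed(seed, {
    idx <- matrix(sample.int(n, m * k, replace = TRUE), m, k)
    p <- pool(idx)
    sxx_c <- p$s[, 4] - p$s[, 2]^2 / p$s[, 1]
    bad <- popcount(p$bits) < 2 | sxx_c <= 0
    if (mean(bad) > 0.5)
      stop_ddcqa("%.0f%% of resamples are degenerate (< 2 distinct diameters); k = %d is too small for these curves",
                 100 * mean(bad), k)
    it <- 0L
    while (any(bad)) {
      n_degenerate <- n_degenerate + sum(bad)
      it <- it + 1L
      if (it > 1000L) stop_ddcqa("degenerate resamples persist after 1000 redraws")
      ridx <- matrix(sample.int(n, sum(bad) * k, replace = TRUE), sum(bad), k)
      idx[bad, ] <- ridx
      pr <- pool(ridx)
      p$s[bad, ] <- pr$s; p$bits[bad] <- pr$bits
      sxx_c[bad] <- pr$s[, 4] - pr$s[, 2]^2 / pr$s[, 1]
      bad[bad] <- popcount(pr$bits) < 2 |
        (pr$s[, 4] - pr$s[, 2]^2 / pr$s[, 1]) <= 0
    }
    beta <- (p$s[, 5] - p$s[, 2] * p$s[, 3] / p$s[, 1]) / sxx_c
    alpha <- p$s[, 3] / p$s[, 1] - beta * p$s[, 2] / p$s[, 1]
  })
  structure(list(k = k, n = n, m = m, seed = as.integer(seed),
                 se_alpha = sd(alpha), se_beta = sd(beta),
                 mean_alpha = mean(alpha), mean_beta = mean(beta),
                 n_degenerate = n_degenerate,
                 draws = if (keep_draws) data.frame(alpha = alpha, beta = beta)),
            class = "ddc_boot")
}

#' @export
print.ddc_boot <- function(x, digits = 5, ...) {
  cat(sprintf("DDC bootstrap: k = %d of n = %d curves, m = %d resamples (seed %d)\n",
              x$k, x$n, x$m, x$seed))
  cat(sprintf("  se(alpha) = %s HU   se(beta) = %s HU/log(mm)\n",
              format(x$se_alpha, digits = digits), format(x$se_beta, digits = digits)))
  if (x$n_degenerate > 0)
    cat(sprintf("  %d degenerate resample(s) redrawn\n", x$n_degenerate))
  invisible(x)
}

#' Bootstrap standard errors across resample sizes
#'
#' Runs [ddc_bootstrap()] for each `k` and tabulates the standard errors;
#' the error grows as the number of curves per resample shrinks.
#'
#' @param curves Data frame of DDC points.
#' @param ks Integer vector of resample sizes.
#' @param m,seed Passed to [ddc_bootstrap()] (seed is offset per k).
#' @return Data frame with columns `k`, `se_alpha`, `se_beta`, `n_degenerate`.
#' @export
ddc_bootstrap_profile <- function(curves, ks = NULL, m = 1e4, seed = 1) {
  if (is.null(ks)) {
    d <- curves[!is.na(curves$delta_min_hu), ]
    n <- if ("scan_id" %in% names(d))
      nlevels(interaction(d$observer, d$scan_id, drop = TRUE))
    else length(unique(d$observer))
    ks <- seq_len(n)
  }
  do.call(rbind, lapply(ks, function(k) {
    b <- ddc_bootstrap(curves, k = k, m = m, seed = seed + k, keep_draws = FALSE)
    data.frame(k = k, se_alpha = b$se_alpha, se_beta = b$se_beta,
               n_degenerate = b$n_degenerate)
  }))
}
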