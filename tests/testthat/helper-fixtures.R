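# Shared fixtures and independent oracles.

# Five-observer DDC set (120 kV, CTDIvol 9 mGy) shipped with the package.
ref_curves <- function() {
  read_curves(system.file("extdata", "observer_curves_120kv_9mgy.csv",
                          package = "ddcqa", mustWork = TRUE))
}

# Random multi-observer curve sets on true per-observer lines with Gaussian
# jitter and (optionally) missing entries; every observer keeps >= 2
# distinct diameters so the observer model stays estimable.
random_curves <- function(seed, n_obs = NULL, missing_prob = 0.2, sd = 5) {
  with_seed2(seed, {
    if (is.null(n_obs)) n_obs <- sample(3:6, 1)
    dia <- c(3, 4, 5, 6, 8, 9)
    out <- lapply(seq_len(n_obs), function(i) {
      a <- runif(1, 80, 140); b <- runif(1, -45, -15)
      y <- a + b * log(dia) + rnorm(length(dia), 0, sd)
      drop <- runif(length(dia)) < missing_prob
      # keep at least 2 distinct diameters per observer
      while (sum(!drop) < 2) drop[sample(length(dia), 1)] <- FALSE
      y[drop] <- NA
      data.frame(observer = sprintf("o%02d", i), diameter_mm = dia,
                 delta_min_hu = y, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# Seed scoping for helpers (mirror of the package-internal utility).
with_seed2 <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Hand-rolled OLS via the normal equations (independent of lm and of the
# package's fitting path).
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

# Constrained least squares for the observer-bias model via an explicit
# effects-coded design matrix: columns [1, log s, effects(observer),
# effects(observer) * log s], solved by the normal equations. The last
# observer's offsets are minus the sum of the others (sum-to-zero).
constrained_ls_oracle <- function(curves) {
  d <- curves[!is.na(curves$delta_min_hu), ]
  obs <- sort(unique(d$observer))
  n <- length(obs)
  x <- log(d$diameter_mm)
  E <- matrix(0, nrow(d), n - 1)  # effects coding
  for (j in seq_len(n - 1)) E[d$observer == obs[j], j] <- 1
  E[d$observer == obs[n], ] <- -1
  X <- cbind(1, x, E, E * x)
  th <- solve(t(X) %*% X, t(X) %*% d$delta_min_hu)[, 1]
  th <- unname(th)
  a_off <- c(th[3:(n + 1)], -sum(th[3:(n + 1)]))
  b_off <- c(th[(n + 2):(2 * n)], -sum(th[(n + 2):(2 * n)]))
  list(alpha = th[1], beta = th[2],
       offsets = data.frame(observer = obs, alpha_i = a_off, beta_i = b_off))
}

# Brute-force morphological erosion: a pixel survives iff every disc offset
# lands inside the mask (offsets beyond the border count as outside).
brute_force_erode <- function(mask, disc_diameter_px = 5) {
  r <- disc_diameter_px / 2
  f <- floor(r)
  off <- expand.grid(dr = -f:f, dc = -f:f)
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    keep <- TRUE
    for (k in seq_len(nrow(off))) {
      ii <- i + off$dr[k]; jj <- j + off$dc[k]
      if (ii < 1 || ii > nrow(mask) || jj < 1 || jj > ncol(mask) || !mask[ii, jj]) {
        keep <- FALSE; break
      }
    }
    out[i, j] <- keep
  }
  out
}

# Small fast scan fixtures shared across tests.
quiet_settings <- function(...) {
  acquisition_settings(psf_fwhm_mm = 0, noise_sigma_ref_hu = 0, n_slices = 3, ...)
}
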