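test_that("identical curves give zero bootstrap standard errors", {
  s <- c(3, 4, 5, 6, 8, 9)
  one <- data.frame(diameter_mm = s, delta_min_hu = 100 - 25 * log(s) + c(1, 0, -1, 2, 0, -2))
  cur <- do.call(rbind, lapply(1:4, function(i) cbind(observer = sprintf("o%d", i), one)))
  for (k in c(1, 2, 4)) {
    b <- ddc_bootstrap(cur, k = k, m = 500, seed = 1)
    expect_equal(b$se_alpha, 0)
    expect_equal(b$se_beta, 0)
  }
})

test_that("k = 1 converges to the population spread of per-curve fits", {
  cur <- ref_curves()
  b <- ddc_bootstrap(cur, k = 1, m = 2e4, seed = 3)
  # enumeration oracle: per-curve OLS over the n = 5 curves; sampling one
  # curve uniformly has SD equal to the divisor-n population SD
  per <- t(sapply(split(cur, cur$observer), function(g) {
    g <- g[!is.na(g$delta_min_hu), ]
    ols_oracle(log(g$diameter_mm), g$delta_min_hu)
  }))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(b$se_alpha, pop_sd(per[, 1]), tolerance = 0.03)
  expect_equal(b$se_beta, pop_sd(per[, 2]), tolerance = 0.03)
})

test_that("bootstrap results are bit-reproducible for a fixed seed", {
  cur <- ref_curves()
  a <- ddc_bootstrap(cur, k = 3, m = 2000, seed = 11)
  b <- ddc_bootstrap(cur, k = 3, m = 2000, seed = 11)
  expect_identical(a$draws, b$draws)
  expect_identical(a$se_alpha, b$se_alpha)
  expect_false(identical(a$se_alpha, ddc_bootstrap(cur, k = 3, m = 2000, seed = 12)$se_alpha))
})

test_that("the standard error equals the direct SD of the stored draws", {
  b <- ddc_bootstrap(ref_curves(), k = 4, m = 3000, seed = 5)
  expect_identical(b$se_alpha, sd(b$draws$alpha))
  expect_identical(b$se_beta, sd(b$draws$beta))
  # and the 1/(m-1) arithmetic, recomputed from scratch
  a <- b$draws$alpha
  expect_equal(b$se_alpha, sqrt(sum((a - mean(a))^2) / (length(a) - 1)),
               tolerance = 1e-12)
})

test_that("resample fits equal pooled OLS on the drawn curves", {
  # with n = 2 curves and k = 2 there are only three possible resamples;
  # every draw must equal one of their pooled lm() fits
  s <- c(3, 5, 9)
  cur <- rbind(data.frame(observer = "a", diameter_mm = s,
                          delta_min_hu = 120 - 30 * log(s) + c(1, -1, 2)),
               data.frame(observer = "b", diameter_mm = s,
                          delta_min_hu = 95 - 18 * log(s) + c(-2, 1, 0)))
  fits <- list(
    aa = coef(lm(delta_min_hu ~ log(diameter_mm), cur[cur$observer == "a", ])),
    bb = coef(lm(delta_min_hu ~ log(diameter_mm), cur[cur$observer == "b", ])),
    ab = coef(lm(delta_min_hu ~ log(diameter_mm), cur)))
  b <- ddc_bootstrap(cur, k = 2, m = 200, seed = 2)
  for (i in seq_len(nrow(b$draws))) {
    hit <- any(vapply(fits, function(f)
      abs(f[1] - b$draws$alpha[i]) < 1e-9 && abs(f[2] - b$draws$beta[i]) < 1e-9,
      logical(1)))
    expect_true(hit)
  }
})

test_that("standard errors grow as the resample size shrinks", {
  cur <- random_curves(99, n_obs = 6, missing_prob = 0.1)
  prof <- ddc_bootstrap_profile(cur, ks = c(2, 4, 6), m = 1e4, seed = 7)
  expect_true(all(diff(prof$se_alpha) < 0))
  expect_true(all(diff(prof$se_beta) < 0))
})

test_that("degenerate resamples are redrawn and counted", {
  # one curve spans a single diameter: k = 1 draws hitting it are redrawn
  cur <- rbind(data.frame(observer = "a", diameter_mm = c(3, 5, 9),
                          delta_min_hu = c(80, 64, 48)),
               data.frame(observer = "b", diameter_mm = c(3, 6, 8),
                          delta_min_hu = c(80, 48, 48)),
               data.frame(observer = "c", diameter_mm = c(5, 5),
                          delta_min_hu = c(64, 64)))
  b <- ddc_bootstrap(cur, k = 1, m = 1000, seed = 4)
  expect_gt(b$n_degenerate, 0)
  expect_true(all(is.finite(b$draws$alpha)))
  # a curve set where most draws are degenerate errors out
  bad <- data.frame(observer = "a", diameter_mm = c(5, 5),
                    delta_min_hu = c(64, 64))
  expect_error(ddc_bootstrap(bad, k = 1, m = 1000, seed = 1), "degenerate")
})

test_that("resample size bounds are enforced", {
  cur <- ref_curves()
  expect_error(ddc_bootstrap(cur, k = 0, m = 100), "1 <= k <= n")
  expect_error(ddc_bootstrap(cur, k = 6, m = 100), "1 <= k <= n")
  expect_error(ddc_bootstrap(cur, k = 2, m = 1), "m must be")
})
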