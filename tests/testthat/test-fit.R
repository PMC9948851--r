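test_that("points on an exact log-line are fitted exactly", {
  s <- c(3, 4, 5, 6, 8, 9)
  cur <- data.frame(observer = "o1", diameter_mm = s,
                    delta_min_hu = 100 - 20 * log(s))
  fit <- ddc_fit(cur, observer_bias = FALSE)
  expect_equal(coef(fit), c(alpha = 100, beta = -20))
  expect_equal(fit$r_squared, 1)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
})

test_that("pooled coefficients equal the normal-equations oracle", {
  cur <- ref_curves()
  fit <- ddc_fit(cur, observer_bias = FALSE)
  d <- cur[!is.na(cur$delta_min_hu), ]
  expect_equal(fit$n, 27)
  co <- ols_oracle(log(d$diameter_mm), d$delta_min_hu)
  expect_equal(unname(coef(fit)), unname(co), tolerance = 1e-9)
})

test_that("duplicating every curve leaves the pooled fit unchanged", {
  cur <- ref_curves()
  fit1 <- ddc_fit(cur, observer_bias = FALSE)
  cur2 <- rbind(cur, transform(cur, scan_id = "scan02"))
  fit2 <- ddc_fit(cur2, observer_bias = FALSE)
  expect_equal(coef(fit2), coef(fit1))
})

test_that("identical observers have exactly zero offsets", {
  s <- c(3, 4, 5, 6, 8, 9)
  one <- data.frame(diameter_mm = s, delta_min_hu = 90 - 25 * log(s) + c(2, -1, 0, 1, -2, 0))
  cur <- rbind(cbind(observer = "a", one), cbind(observer = "b", one),
               cbind(observer = "c", one))
  fit <- ddc_fit(cur)
  expect_equal(fit$offsets$alpha_i, c(0, 0, 0))
  expect_equal(fit$offsets$beta_i, c(0, 0, 0))
  single <- ddc_fit(cbind(observer = "a", one), observer_bias = FALSE)
  expect_equal(coef(fit), coef(single))
})

test_that("two exact observer lines recombine by their means", {
  s <- c(3, 5, 9)
  cur <- rbind(data.frame(observer = "a", diameter_mm = s,
                          delta_min_hu = 120 - 30 * log(s)),
               data.frame(observer = "b", diameter_mm = s,
                          delta_min_hu = 100 - 20 * log(s)))
  fit <- ddc_fit(cur)
  expect_equal(fit$alpha, 110)
  expect_equal(fit$beta, -25)
  expect_equal(fit$offsets$alpha_i[fit$offsets$observer == "a"], 10)
  expect_equal(fit$offsets$beta_i[fit$offsets$observer == "a"], -5)
})

test_that("the five-observer reference set reproduces the frozen estimates", {
  # frozen from an independent per-observer lm() + recombination run
  fit <- ddc_fit(ref_curves())
  expect_equal(fit$alpha, 118.698304, tolerance = 1e-6)
  expect_equal(fit$beta, -33.748428, tolerance = 1e-6)
  expect_equal(fit$n, 27)
  expect_equal(fit$n_observers, 5)
})

test_that("observer model equals the effects-coded constrained solve", {
  for (seed in 1:10) {
    cur <- random_curves(seed)
    fit <- ddc_fit(cur)
    or <- constrained_ls_oracle(cur)
    expect_equal(fit$alpha, or$alpha, tolerance = 1e-9)
    expect_equal(fit$beta, or$beta, tolerance = 1e-9)
    o <- merge(fit$offsets, or$offsets, by = "observer")
    expect_equal(o$alpha_i.x, o$alpha_i.y, tolerance = 1e-9)
    expect_equal(o$beta_i.x, o$beta_i.y, tolerance = 1e-9)
  }
})

test_that("degenerate inputs raise informative errors", {
  one_dia <- data.frame(observer = "a", diameter_mm = 5, delta_min_hu = c(32, 48))
  expect_error(ddc_fit(one_dia, observer_bias = FALSE), "2 distinct diameters")
  cur <- rbind(data.frame(observer = "a", diameter_mm = c(3, 9),
                          delta_min_hu = c(80, 48)),
               data.frame(observer = "b", diameter_mm = c(5, 5),
                          delta_min_hu = c(64, 64)))
  expect_error(ddc_fit(cur), "observer 'b'")
  expect_error(ddc_fit(cur[cur$observer == "a", ]), ">= 2 observers")
  allna <- data.frame(observer = "a", diameter_mm = c(3, 9),
                      delta_min_hu = c(NA, NA))
  expect_error(ddc_fit(allna), "no non-missing")
})

test_that("prediction follows the fitted line, per observer or pooled", {
  fit0 <- structure(list(alpha = 100, beta = -20, offsets = NULL,
                         observer_bias = FALSE), class = "ddc_fit")
  expect_equal(predict(fit0, 1), 100)     # log(1) = 0
  expect_equal(predict(fit0, exp(1)), 80)
  expect_error(predict(fit0, -1), "positive")
  fit <- ddc_fit(ref_curves())
  d <- fit$data
  # fit-then-predict reproduces fitted values via the residual identity
  pr <- vapply(seq_len(fit$n),
               function(i) predict(fit, d$diameter_mm[i], observer = d$observer[i]),
               numeric(1))
  expect_equal(pr, d$delta_min_hu - residuals(fit), tolerance = 1e-12)
  expect_error(predict(fit, 5, observer = "nobody"), "unknown observer")
})

test_that("summary, plot and simulate methods work", {
  fit <- ddc_fit(ref_curves())
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ddc_fit")
  expect_equal(sm$sd_alpha_bias, sd(fit$offsets$alpha_i))
  expect_output(print(sm), "observer offsets")
  expect_output(print(fit), "alpha")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(nrow(sims[[1]]), fit$n)
  expect_identical(simulate(fit, seed = 2), simulate(fit, seed = 2))
})
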