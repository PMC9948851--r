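test_that("disc erosion matches the brute-force oracle on a large disc", {
  grid <- expand.grid(r = 1:41, c = 1:41)
  d2 <- (grid$r - 21)^2 + (grid$c - 21)^2
  m10 <- matrix(d2 <= 10^2, 41, 41)
  er <- erode_roi(m10, 5)
  expect_identical(er, brute_force_erode(m10, 5))
  # the disc shrinks by about the element radius: the result contains the
  # radius-7.5 disc and is contained in the radius-8 disc
  expect_true(all(er[matrix(d2 <= 7.5^2, 41, 41)]))
  expect_true(all(!er[matrix(d2 > 8^2, 41, 41)]))
})

test_that("erosion of a mask thinner than the element is empty, and legal", {
  thin <- matrix(FALSE, 20, 20); thin[10, 3:18] <- TRUE  # 1 px line
  expect_false(any(erode_roi(thin, 5)))
  expect_error(erode_roi(matrix(FALSE, 5, 5)), "empty mask")
})

test_that("erosion is anti-extensive and matches the oracle on random masks", {
  for (seed in 1:50) {
    m <- with_seed2(seed, matrix(runif(20 * 20) < 0.6, 20, 20))
    if (!any(m)) next
    er <- erode_roi(m, 5)
    expect_true(all(!er | m))  # output subset of input
    if (seed <= 20) expect_identical(er, brute_force_erode(m, 5))
  }
})

test_that("dilation is extensive and dual to erosion on discs", {
  m <- matrix(FALSE, 31, 31); m[16, 16] <- TRUE
  di <- dilate_roi(m, 5)
  expect_true(all(!m | di))
  grid <- expand.grid(r = 1:31, c = 1:31)
  expect_identical(as.vector(di),
                   (grid$r - 16)^2 + (grid$c - 16)^2 <= 2.5^2)
})

test_that("ROI statistics of a constant image are degenerate", {
  lay <- ddc_layout(seed = 31)
  scan <- simulate_volume(lay, quiet_settings(), seed = 1)
  scan$volume[] <- 7
  st <- rod_statistics(scan)
  r <- st$rods[!st$rods$unmeasurable, ]
  expect_true(all(r$mean == 7 & r$median == 7 & r$min == 7 & r$max == 7 & r$sd == 0))
  expect_equal(st$background$mean, 7)
  expect_equal(r$measured_contrast_hu, rep(0, nrow(r)))
})

test_that("noise-free measured contrast equals the rendered contrast", {
  lay <- ddc_layout(seed = 31)
  scan <- simulate_volume(lay, quiet_settings(), seed = 1)
  st <- rod_statistics(scan)
  r <- st$rods[!st$rods$unmeasurable, ]
  expect_equal(st$background$mean, 60)
  expect_equal(r$measured_contrast_hu, r$rendered_contrast_hu)
  rod48 <- r[r$target_contrast_hu == 48 & r$diameter_mm == 9, ]
  expect_equal(rod48$mean, 108)
  expect_equal(rod48$measured_contrast_hu, 48)
})

test_that("noisy contrast errors follow the two-sample sampling distribution", {
  lay <- ddc_layout(seed = 31)
  clean <- simulate_volume(lay, quiet_settings(), seed = 1)
  masks <- roi_masks(lay, clean$transform, dim(clean$volume)[1:2])
  sigma <- 10
  n_rod <- vapply(masks$rod, sum, numeric(1))
  n_bg <- sum(masks$background)
  bound <- 3 * sigma * sqrt(1 / n_rod + 1 / n_bg)
  sc <- clean
  ok <- 0L; tot <- 0L
  with_seed2(404, for (rep in 1:200) {
    sc$volume <- clean$volume +
      array(rnorm(length(clean$volume), 0, sigma), dim(clean$volume))
    st <- rod_statistics(sc, masks = masks)
    err <- abs(st$rods$measured_contrast_hu - st$rods$rendered_contrast_hu)
    ok <- ok + sum(err <= bound); tot <- tot + length(err)
  })
  expect_gte(ok / tot, 0.99)
})

test_that("per-diameter linearity recovers exact and affine relations", {
  meas <- expand.grid(diameter_mm = c(3, 9), target_contrast_hu = c(16, 32, 48, 64, 80))
  meas$measured_contrast_hu <- meas$target_contrast_hu
  fl <- fit_linearity(meas)
  expect_equal(fl$slope, c(1, 1))
  expect_equal(fl$intercept_hu, c(0, 0), tolerance = 1e-12)
  expect_equal(fl$r_squared, c(1, 1))
  meas$measured_contrast_hu <- 0.8 * meas$target_contrast_hu + 2
  fl <- fit_linearity(meas)
  expect_equal(fl$slope, c(0.8, 0.8))
  expect_equal(fl$intercept_hu, c(2, 2))
})

test_that("linearity coefficients equal the normal-equations oracle", {
  meas <- with_seed2(5, {
    g <- expand.grid(diameter_mm = c(3, 5, 8),
                     target_contrast_hu = c(16, 32, 48, 64, 80))
    g$measured_contrast_hu <- 0.9 * g$target_contrast_hu + rnorm(nrow(g), 0, 3)
    g
  })
  fl <- fit_linearity(meas)
  for (i in seq_len(nrow(fl))) {
    g <- meas[meas$diameter_mm == fl$diameter_mm[i], ]
    co <- ols_oracle(g$target_contrast_hu, g$measured_contrast_hu)
    expect_equal(fl$intercept_hu[i], co[1], tolerance = 1e-9)
    expect_equal(fl$slope[i], co[2], tolerance = 1e-9)
  }
  one <- meas[meas$target_contrast_hu == 16, ]
  expect_error(fit_linearity(one), "2 distinct target contrasts")
})

test_that("energy response separates native and contrast-agent modules", {
  stats_at <- function(module_type, kv) {
    lay <- ddc_layout(seed = 31, module_type = module_type)
    scan <- simulate_volume(lay, quiet_settings(kv = kv, ctdi_vol_mgy = 11), seed = 1)
    rod_statistics(scan)
  }
  nat <- contrast_measurements(stats_at("native", 80), stats_at("native", 120))
  en <- energy_response(nat)
  expect_equal(en$slope[en$kv == 80], en$slope[en$kv == 120], tolerance = 1e-6)
  ca <- contrast_measurements(stats_at("contrast_agent", 80),
                              stats_at("contrast_agent", 120))
  en <- energy_response(ca)
  expect_equal(en$slope[en$kv == 80] / en$slope[en$kv == 120], 1.30,
               tolerance = 1e-6)
  expect_equal(en$slope_ratio_vs_120kv[en$kv == 80], 1.30, tolerance = 1e-6)
  expect_error(energy_response(nat[nat$kv == 120, ]), "2 tube voltages")
})

test_that("drift summary aggregates per date and series", {
  base <- expand.grid(diameter_mm = 9, target_contrast_hu = c(16, 48),
                      scan_date = as.Date("2020-01-01") + c(0, 30, 60))
  base$measured_contrast_hu <- base$target_contrast_hu
  ds <- drift_summary(base)
  expect_equal(ds$per_date$sd_hu, rep(NA_real_, nrow(ds$per_date)))
  expect_equal(ds$series$sd_of_means_hu, c(0, 0))
  expect_equal(ds$series$grand_mean_hu, c(16, 48))
  # alternating +/- 1 around the target keeps the grand mean at the target
  alt <- base
  alt$measured_contrast_hu <- alt$target_contrast_hu +
    rep(c(1, -1), length.out = nrow(alt))
  # make the +/- 1 alternate across dates within each series
  alt$measured_contrast_hu <- alt$target_contrast_hu + c(1, 1, -1, -1, 0, 0)
  ds <- drift_summary(alt)
  expect_equal(ds$series$grand_mean_hu, c(16, 48))
  # random series: grand mean equals direct recomputation
  rnd <- with_seed2(8, {
    b <- base; b$measured_contrast_hu <- b$target_contrast_hu + rnorm(nrow(b)); b
  })
  ds <- drift_summary(rnd)
  for (tc in c(16, 48)) {
    g <- rnd[rnd$target_contrast_hu == tc, ]
    expect_equal(ds$series$grand_mean_hu[ds$series$target_contrast_hu == tc],
                 mean(tapply(g$measured_contrast_hu, g$scan_date, mean)))
  }
  expect_error(drift_summary(base[base$scan_date == base$scan_date[1], ]),
               "2 dates")
})
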