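test_that("identical config and seed give identical scenes", {
  b1 <- simulate_scene(tiny_config(seed = 7))
  b2 <- simulate_scene(tiny_config(seed = 7))
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$composites, b2$composites)
  expect_identical(b1$loss_masks, b2$loss_masks)
  expect_identical(b1$covariates, b2$covariates)
  b3 <- simulate_scene(tiny_config(seed = 8))
  expect_false(identical(b1$truth, b3$truth))
})

test_that("noiseless products equal the truth drained-pixel union", {
  b <- simulate_scene(tiny_noiseless(seed = 3))
  expect_identical(b$loss_masks$jrc_like, b$truth_loss)
  expect_identical(b$loss_masks$glad_like, b$truth_loss)
  drained_union <- matrix(FALSE, nrow(b$truth_loss), ncol(b$truth_loss))
  drained_union[unlist(b$drained_pixels)] <- TRUE
  expect_identical(b$truth_loss, drained_union)
})

test_that("noiseless first-year water mask equals the lake extent", {
  b <- simulate_scene(tiny_noiseless(seed = 3))
  # in the first year nothing has drained yet (drainage years start at
  # years[3]), so AWEI > 0 is exactly the union of lake footprints
  expect_identical(b$water_masks[[1]], b$permanent_water)
})

test_that("drained pixels are a subset of footprints and years in range", {
  b <- simulate_scene(tiny_config(seed = 5))
  for (i in which(b$truth$drained)) {
    expect_true(all(b$drained_pixels[[i]] %in% b$footprints[[i]]))
    expect_true(b$truth$true_drainage_year[i] >= min(b$years))
    expect_true(b$truth$true_drainage_year[i] <= max(b$years))
  }
  expect_true(all(is.na(b$truth$true_drainage_year[!b$truth$drained])))
})

test_that("recovery curve anchors at N0 and approaches the offset asymptote", {
  rp <- sim_config()$recovery_params
  s <- 0.45
  expect_equal(ndvi_recovery(0, rp$very_likely, s), rp$very_likely[["N0"]])
  expect_equal(ndvi_recovery(1e6, rp$very_likely, s), s + 0.06)
  expect_equal(ndvi_recovery(1e6, rp$unlikely, s), s - 0.09)
  # monotone toward the asymptote
  t <- seq(0, 20, by = 0.25)
  expect_true(all(diff(ndvi_recovery(t, rp$very_likely, s)) > 0))
  # very-likely basins cross the surround level near t = 2
  cross <- t[which(ndvi_recovery(t, rp$very_likely, s) >= s)[1]]
  expect_lt(abs(cross - 2), 0.5)
})

test_that("least-squares refit of a sampled recovery curve recovers parameters", {
  p_true <- c(N0 = 0.07, delta_inf = 0.05, tau = 1.7)
  s <- 0.43
  t <- seq(0, 15, by = 0.1)
  y <- ndvi_recovery(t, p_true, s)
  fit <- stats::nls(y ~ ndvi_recovery(t, c(N0 = N0, delta_inf = di, tau = tau), s),
                    start = list(N0 = 0.1, di = 0.02, tau = 2),
                    control = stats::nls.control(maxiter = 500, tol = 1e-10,
                                                 minFactor = 1e-12,
                                                 scaleOffset = 1))
  est <- coef(fit)
  expect_equal(unname(est[["N0"]]), 0.07, tolerance = 1e-6)
  expect_equal(unname(est[["di"]]), 0.05, tolerance = 1e-6)
  expect_equal(unname(est[["tau"]]), 1.7, tolerance = 1e-6)
})

test_that("product degradation follows the omission/commission model", {
  m <- matrix(FALSE, 50, 40)
  m[sample(2000, 1000)] <- TRUE
  zero <- list(jrc_like = c(omission = 0, commission = 0),
               glad_like = c(omission = 0, commission = 0))
  out0 <- degrade_products(m, zero)
  expect_identical(out0$jrc_like, m)
  expect_identical(out0$glad_like, m)
  all_om <- list(jrc_like = c(omission = 1, commission = 0),
                 glad_like = c(omission = 1, commission = 0))
  expect_false(any(degrade_products(m, all_om)$jrc_like))
  # omission 0.5 on 1000 truth pixels: retained count within binomial 99% CI
  half <- list(jrc_like = c(omission = 0.5, commission = 0),
               glad_like = c(omission = 0.5, commission = 0))
  set.seed(42)
  kept <- sum(degrade_products(m, half)$jrc_like)
  ci <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(kept, ci[1])
  expect_lte(kept, ci[2])
})

test_that("drainage frequency increases across temperature quartiles when only temperature drives it", {
  cfg <- sim_config(drain_prob_coefs = c(intercept = -1.5, air_temp_mean = 1.5),
                    seed = 11)
  pop <- simulate_lake_population(4000, cfg)
  q <- cut(pop$lakes$air_temp_mean,
           quantile(pop$lakes$air_temp_mean, 0:4 / 4), include.lowest = TRUE)
  freq <- tapply(pop$lakes$drained, q, mean)
  expect_true(all(diff(freq) > 0))
  # and the empirical frequencies track the logistic model probabilities
  pred <- tapply(pop$lakes$drain_prob, q, mean)
  expect_equal(unname(freq), unname(pred), tolerance = 0.12)
})

test_that("overcrowded grids report a placement failure with the count placed", {
  cfg <- sim_config(grid_rows = 48, grid_cols = 48, n_lakes = 60,
                    area_log10_range = c(0.5, 1.5), years = 2000:2008,
                    obs_per_year = 2, seed = 1)
  expect_warning(b <- simulate_scene(cfg), "placed \\d+ of 60")
  expect_lt(nrow(b$truth), 60)
  expect_identical(b$placement_failures, 60L - nrow(b$truth))
})

test_that("lake footprints never overlap and keep a 2-pixel gap", {
  b <- simulate_scene(tiny_config(seed = 13))
  idx <- unlist(b$footprints)
  expect_identical(anyDuplicated(idx), 0L)
  nr <- b$config$grid_rows
  for (i in seq_along(b$footprints)) {
    fp <- b$footprints[[i]]
    rows <- ((fp - 1) %% nr) + 1; cols <- ((fp - 1) %/% nr) + 1
    others <- setdiff(seq_along(b$footprints), i)
    for (j in others) {
      fq <- b$footprints[[j]]
      r2 <- ((fq - 1) %% nr) + 1; c2 <- ((fq - 1) %/% nr) + 1
      cheb <- min(pmax(outer(rows, r2, function(a, b) abs(a - b)),
                       outer(cols, c2, function(a, b) abs(a - b))))
      expect_gte(cheb, 3)
    }
  }
})
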