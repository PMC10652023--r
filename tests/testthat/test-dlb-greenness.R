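test_that("basin median applies the water and negative-value masks", {
  comp <- matrix(0, 3, 3)
  comp[1:3] <- c(0.5, -0.1, 0.7)
  expect_equal(basin_median_ndvi(comp, 1:3), 0.6)
  wm <- matrix(FALSE, 3, 3); wm[1] <- TRUE
  expect_equal(basin_median_ndvi(comp, 1:3, wm), 0.7)
  all_water <- matrix(TRUE, 3, 3)
  expect_true(is.na(basin_median_ndvi(comp, 1:3, all_water)))
  # random fixtures against a sort-based oracle
  set.seed(5)
  for (i in 1:20) {
    v <- matrix(rnorm(100, 0.3, 0.3), 10, 10)
    idx <- sample(100, 30)
    wm <- matrix(runif(100) < 0.2, 10, 10)
    keep <- v[idx] >= 0 & !wm[idx]
    want <- if (any(keep)) median(sort(v[idx][keep])) else NA_real_
    expect_equal(basin_median_ndvi(v, idx, wm), want)
  }
})

test_that("masking never raises the usable basin pixel count", {
  set.seed(6)
  v <- matrix(rnorm(400, 0.3, 0.3), 20, 20)
  idx <- sample(400, 60)
  wm <- matrix(runif(400) < 0.3, 20, 20)
  n_masked <- sum(v[idx] >= 0 & !wm[idx])
  n_unmasked <- sum(!is.na(v[idx]))
  expect_lte(n_masked, n_unmasked)
})

test_that("surround buffer is the expected annulus", {
  dims <- c(101, 101); ps <- 30
  r_px <- 8
  eq_d <- 2 * r_px * ps                      # lake of radius 8 px
  d2 <- outer((1:101 - 51)^2, (1:101 - 51)^2, "+")
  own <- which(d2 <= r_px^2)
  idx <- surround_pixels(51, 51, eq_d, dims, ps, own_idx = own, factor = 2)
  # ring r < d <= 2r has area ~ 3 pi r^2
  expect_equal(length(idx), 3 * pi * r_px^2, tolerance = 0.1)
  rr <- ((idx - 1) %% 101) + 1; cc <- ((idx - 1) %/% 101) + 1
  dist <- sqrt((rr - 51)^2 + (cc - 51)^2)
  expect_true(all(dist <= 2 * r_px + 1e-9))
  expect_true(all(!idx %in% own))
  # a neighbouring lake inside the buffer is excluded
  mask <- matrix(FALSE, 101, 101)
  nb <- which(outer((1:101 - 51)^2, (1:101 - 62)^2, "+") <= 9)
  mask[nb] <- TRUE
  idx2 <- surround_pixels(51, 51, eq_d, dims, ps, own_idx = own,
                          all_lakes_mask = mask, factor = 2)
  expect_false(any(idx2 %in% nb))
  # factor 1 leaves (almost) nothing after self-exclusion
  idx3 <- surround_pixels(51, 51, eq_d, dims, ps, own_idx = own, factor = 1)
  expect_lt(length(idx3), 0.15 * length(own))
})

# one shared cohort scene for the trajectory tests: moderate grid, drainage
# years early enough that years_since reaches 5-8 for every dated lake
cohort_scene <- local({
  cfg <- sim_config(grid_rows = 192, grid_cols = 192, n_lakes = 35,
                    area_log10_range = c(0, 1.3), years = 2000:2016,
                    drain_year_range = c(2002, 2008),
                    drain_prob_coefs = c(intercept = 0.5, air_temp_mean = 1),
                    field_range_px = 30, obs_per_year = 6, seed = 14)
  b <- simulate_scene(cfg)
  det <- detect_on(b)
  ev <- date_events(det$events, det$lab$pixels, b$composites$awei, det$loss)
  traj <- build_trajectories(ev, det$lab$pixels, b$composites$ndvi,
                             b$water_masks, b$config$pixel_size, quiet = TRUE)
  list(b = b, det = det, ev = ev, traj = traj,
       matched = match_events_to_truth(
         det$lab$pixels[as.character(ev$lake_id)], b$footprints))
})

test_that("trajectories align calendar years to years since drainage", {
  traj <- cohort_scene$traj; ev <- cohort_scene$ev
  expect_gt(nrow(ev), 5)
  one <- traj[traj$lake_id == traj$lake_id[1], ]
  expect_identical(one$years_since, one$year - ev$detected_year[
    match(one$lake_id[1], ev$lake_id)])
  expect_equal(one$delta, one$basin_median - one$surround_median)
  # pre-drainage years: basin mostly water, so medians are missing or low
  pre <- traj[traj$years_since < -1, ]
  expect_true(all(is.na(pre$basin_median) | pre$basin_median < 0.3))
})

test_that("post-drainage deltas track the planted recovery curves", {
  traj <- cohort_scene$traj
  b <- cohort_scene$b; matched <- cohort_scene$matched
  late <- traj[traj$years_since >= 5 & !is.na(traj$delta), ]
  expect_gt(nrow(late), 10)
  err <- vapply(seq_len(nrow(late)), function(k) {
    tr_id <- matched[as.character(late$lake_id[k])]
    tr <- b$truth[b$truth$lake_id == tr_id, ]
    params <- c(N0 = tr$recovery_N0, delta_inf = tr$recovery_delta_inf,
                tau = tr$recovery_tau)
    want <- ndvi_recovery(late$years_since[k], params,
                          late$surround_median[k]) - late$surround_median[k]
    late$delta[k] - want
  }, 1)
  expect_lt(median(abs(err)), 0.02)
  expect_lt(max(abs(err)), 0.07)
})

test_that("group summaries have ordered quartiles and conserve records", {
  rec <- data.frame(lake_id = rep(1:6, each = 3),
                    year = rep(2010:2012, 6),
                    years_since = rep(0:2, 6),
                    basin_median = runif(18, 0.3, 0.7),
                    surround_median = 0.45,
                    basin_valid_px = 5, surround_valid_px = 20)
  rec$delta <- rec$basin_median - rec$surround_median
  rec$class <- rep(c("a", "b"), each = 9)
  g <- group_trajectories(rec, "class", reference_year = 1,
                          years_since_range = 0:2)
  expect_true(all(g$trajectory$q25 <= g$trajectory$median + 1e-12))
  expect_true(all(g$trajectory$median <= g$trajectory$q75 + 1e-12))
  expect_equal(sum(g$trajectory$n), nrow(rec))
  expect_equal(sum(g$reference$n), 6)
  single <- group_trajectories(rec[1:3, ], "class", reference_year = 1,
                               years_since_range = 0:2)
  expect_equal(single$trajectory$median, single$trajectory$q25)
  expect_equal(single$trajectory$median, single$trajectory$q75)
})

test_that("TCG and NDVI reference-year values are rank-correlated across lakes", {
  b <- cohort_scene$b; det <- cohort_scene$det; ev <- cohort_scene$ev
  tj_n <- cohort_scene$traj
  tj_t <- build_trajectories(ev, det$lab$pixels, b$composites$tcg,
                             b$water_masks, b$config$pixel_size, quiet = TRUE)
  a <- tj_n[tj_n$years_since == 5, c("lake_id", "basin_median")]
  d <- tj_t[tj_t$years_since == 5, c("lake_id", "basin_median")]
  m <- merge(a, d, by = "lake_id")
  m <- m[complete.cases(m), ]
  expect_gt(nrow(m), 8)
  expect_gt(cor(m$basin_median.x, m$basin_median.y, method = "spearman"), 0.9)
})
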