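make_population <- function(seed = 9, n = 6000) {
  pop <- simulate_lake_population(n, sim_config(seed = seed))
  ev <- data.frame(lake_id = pop$lakes$lake_id[pop$lakes$drained],
                   detected_year = pop$lakes$true_drainage_year[pop$lakes$drained])
  list(pop = pop, ev = ev)
}

test_that("sample construction follows the positives + sampled-negatives design", {
  d <- make_population(3, 4000)
  n_pos <- nrow(d$ev)
  n_undrained <- nrow(d$pop$lakes) - n_pos
  s <- build_samples(d$pop$lakes, d$ev, d$pop$covariates, neg_fraction = 0.1,
                     seed = 2)
  expect_equal(nrow(s), n_pos + round(0.1 * n_undrained))
  expect_equal(sum(s$label), n_pos)
  s2 <- build_samples(d$pop$lakes, d$ev, d$pop$covariates, neg_fraction = 0.1,
                      seed = 2)
  expect_identical(s, s2)
  # positives take climate at the drainage year
  cy <- attr(s, "climate_year")
  expect_identical(cy[seq_len(n_pos)], d$ev$detected_year)
  expect_error(build_samples(d$pop$lakes, d$ev[0, ], d$pop$covariates),
               "no drained lakes")
})

test_that("negative samples draw climate years uniformly over the span", {
  d <- make_population(5, 9000)
  s <- build_samples(d$pop$lakes, d$ev, d$pop$covariates, neg_fraction = 1,
                     seed = 7)
  cy <- attr(s, "climate_year")[s$label == 0]
  yrs <- sort(unique(d$pop$covariates$year))
  tab <- table(factor(cy, levels = yrs))
  p <- chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("the rank-based AUC agrees with an independent ROC implementation", {
  set.seed(10)
  lab <- rbinom(300, 1, 0.4)
  score <- lab + rnorm(300)
  want <- as.numeric(suppressMessages(pROC::auc(lab, score,
                                                direction = "<")))
  expect_equal(metric_auc(score, lab), want, tolerance = 1e-12)
})

test_that("a label independent of all features scores near-chance AUC", {
  set.seed(11)
  n <- 2000
  tab <- data.frame(label = rbinom(n, 1, 0.5),
                    a = rnorm(n), b = rnorm(n),
                    c = sample(c("u", "v", "w"), n, replace = TRUE))
  fit <- split_and_fit(tab, "classify", n_search = 0, seed = 1)
  expect_gte(fit$metrics$auc, 0.4)
  expect_lte(fit$metrics$auc, 0.6)
})

test_that("a separable planted rule is learned almost perfectly", {
  set.seed(12)
  n <- 1500
  x1 <- rnorm(n); x2 <- rnorm(n)
  tab <- data.frame(label = as.integer(x1 + x2 > 0), x1 = x1, x2 = x2,
                    noise = rnorm(n))
  fit <- split_and_fit(tab, "classify", n_search = 0, seed = 2)
  expect_gte(fit$metrics$auc, 0.99)
})

test_that("regression recovers a noiseless planted function of three features", {
  set.seed(13)
  n <- 2000
  x1 <- runif(n); x2 <- runif(n); x3 <- runif(n)
  tab <- data.frame(label = 0.3 * x1 + 0.5 * x2^2 - 0.2 * x3,
                    x1 = x1, x2 = x2, x3 = x3, irrelevant = rnorm(n))
  fit <- split_and_fit(tab, "regress", n_search = 0, seed = 3)
  expect_gte(fit$metrics$r2, 0.95)
  expect_lt(abs(fit$metrics$mean_bias), 0.02)
})

test_that("random search with cross-validation runs and returns chosen parameters", {
  set.seed(14)
  n <- 400
  x <- rnorm(n)
  tab <- data.frame(label = as.integer(x + rnorm(n, 0, 0.5) > 0), x = x,
                    z = rnorm(n))
  fit <- split_and_fit(tab, "classify", cv_folds = 3, n_search = 2,
                       nrounds = 60, seed = 4)
  expect_true(all(c("eta", "max_depth", "nrounds") %in% names(fit$params)))
  expect_gt(fit$metrics$auc, 0.8)
})

test_that("permutation importance is zero for constants and ranks the planted driver first", {
  set.seed(15)
  n <- 1200
  x <- rnorm(n)
  tab <- data.frame(label = as.integer(x + rnorm(n, 0, 0.3) > 0),
                    driver = x, noise1 = rnorm(n), noise2 = rnorm(n),
                    fixed = rep(1, n))
  fit <- split_and_fit(tab, "classify", n_search = 0, seed = 5)
  test <- tab[fit$test_idx, ]
  pi <- permutation_importance(fit, test, n_repeats = 6, seed = 6)
  expect_equal(pi$importance_mean[pi$feature == "fixed"], 0)
  expect_identical(pi$feature[pi$rank == 1], "driver")
  # independent noise features: |mean| within 2 sd of zero
  for (f in c("noise1", "noise2")) {
    row <- pi[pi$feature == f, ]
    expect_lte(abs(row$importance_mean), max(2 * row$importance_sd, 0.02))
  }
})

test_that("sampled Shapley matches the closed form for an additive model", {
  set.seed(16)
  n <- 800
  x1 <- rnorm(n); x2 <- rnorm(n)
  tab <- data.frame(label = 2 * x1 - 1 * x2, x1 = x1, x2 = x2)
  fit <- split_and_fit(tab, "regress", n_search = 0, nrounds = 400, seed = 7)
  rows <- 1:40
  sh <- shapley_sampling(fit, tab, n_permutations = 60, rows = rows, seed = 8)
  # efficiency against sampled backgrounds holds exactly (telescoping)
  expect_equal(rowSums(sh$phi), sh$prediction - sh$baseline_mean,
               tolerance = 1e-10)
  # for an (approximately) additive fitted model, phi_i ~ f_i(x_i) - E f_i
  pred_all <- predict(fit, tab)
  expect_gt(cor(sh$phi[, "x1"], 2 * (tab$x1[rows] - mean(tab$x1))), 0.95)
  expect_gt(cor(sh$phi[, "x2"], -1 * (tab$x2[rows] - mean(tab$x2))), 0.95)
  # a constant model attributes nothing
  tabc <- data.frame(label = rep(0.7, 300), x1 = rnorm(300), x2 = rnorm(300))
  fitc <- split_and_fit(tabc, "regress", n_search = 0, nrounds = 10, seed = 9)
  shc <- shapley_sampling(fitc, tabc, n_permutations = 10, rows = 1:10, seed = 10)
  expect_equal(max(abs(shc$phi)), 0, tolerance = 1e-8)
})

test_that("pruning removes duplicates and correlated lower-importance features", {
  set.seed(17)
  n <- 500
  a <- rnorm(n)
  tab <- data.frame(label = rbinom(n, 1, plogis(a)), a = a, a_copy = a,
                    b = rnorm(n), cat = sample(c("p", "q"), n, TRUE))
  imp <- data.frame(feature = c("a", "a_copy", "b", "cat"),
                    importance = c(0.5, 0.4, 0.2, 0.1))
  pr <- prune_features(tab, imp, r_threshold = 0.5)
  expect_identical(pr$removed$feature, "a_copy")
  expect_identical(pr$removed$reason, "correlated")
  expect_true(all(c("a", "b", "cat") %in% names(pr$samples)))
  # nothing removed when all pairwise correlations are small
  tab2 <- data.frame(label = rbinom(n, 1, 0.5), x = rnorm(n), y = rnorm(n))
  pr2 <- prune_features(tab2, data.frame(feature = c("x", "y"),
                                         importance = c(0.3, 0.2)))
  expect_identical(nrow(pr2$removed), 0L)
  # three mutually correlated features: only the top-importance one survives
  base <- rnorm(n)
  tab3 <- data.frame(label = rbinom(n, 1, 0.5),
                     f1 = base + rnorm(n, 0, 0.2),
                     f2 = base + rnorm(n, 0, 0.2),
                     f3 = base + rnorm(n, 0, 0.2))
  pr3 <- prune_features(tab3, data.frame(feature = c("f2", "f1", "f3"),
                                         importance = c(0.6, 0.3, 0.1)))
  expect_identical(setdiff(names(pr3$samples), "label"), "f2")
  # the top-ranked feature is never removed, negligible ones are
  pr4 <- prune_features(tab2, data.frame(feature = c("x", "y"),
                                         importance = c(0.3, 0)),
                        min_importance = 0)
  expect_identical(pr4$removed$reason, "negligible")
  expect_true("x" %in% names(pr4$samples))
})

test_that("planted temperature and elevation drivers surface in both importance methods", {
  d <- make_population(21, 5000)
  s <- build_samples(d$pop$lakes, d$ev, d$pop$covariates, neg_fraction = 0.35,
                     seed = 21)
  fit <- split_and_fit(s, "classify", n_search = 0, seed = 21)
  test <- s[fit$test_idx, ]
  pi <- permutation_importance(fit, test, n_repeats = 5, seed = 21)
  sh <- shapley_sampling(fit, test, n_permutations = 15, seed = 21)
  rep <- importance_report(pi, sh$mean_abs)
  top3_perm <- rep$feature[rep$permutation_rank <= 3]
  top3_shap <- rep$feature[rep$shap_rank <= 3]
  expect_true(all(c("air_temp_annual", "elevation") %in% top3_perm))
  expect_true(all(c("air_temp_annual", "elevation") %in% top3_shap))
  expect_gte(fit$metrics$auc, 0.85)
  # ranks are a permutation of the features under each method
  expect_identical(sort(rep$permutation_rank), seq_len(nrow(rep)))
  expect_identical(sort(rep$shap_rank), seq_len(nrow(rep)))
})
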