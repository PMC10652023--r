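#' Build the lake-drainage sample table
#'
#' Positives are all drained lakes, with climate covariates taken at the
#' (detected) drainage year; negatives are a random fraction of the
#' undrained lakes, with climate covariates sampled at a uniformly random
#' year of the span so that negative samples cover the full range of climate
#' conditions. Deterministic under `seed`.
#'
#' @param lakes Lake table (one row per lake; attribute and static
#'   covariate columns).
#' @param events Event table with `lake_id` and `detected_year` (truth
#'   tables with `true_drainage_year` are also accepted).
#' @param covariates Per-lake-year climate table (`lake_id`, `year`, climate
#'   columns).
#' @param neg_fraction Fraction of undrained lakes sampled as negatives.
#' @param features Character vector of feature columns to carry (defaults to
#'   every attribute/covariate column available).
#' @param seed Integer seed.
#' @return A data frame with a binary `label` column (1 = drained) followed
#'   by the feature columns; attribute `climate_year` records the year each
#'   row's climate was sampled at.
#' @export
build_samples <- function(lakes, events, covariates, neg_fraction = 0.01,
                          features = NULL, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  year_col <- if ("detected_year" %in% names(events)) "detected_year" else
    "true_drainage_year"
  ev <- events[!is.na(events[[year_col]]), , drop = FALSE]
  if (nrow(ev) == 0) stop("no drained lakes with a resolved drainage year")
  pos_ids <- ev$lake_id
  neg_pool <- setdiff(lakes$lake_id, events$lake_id)
  n_neg <- round(neg_fraction * length(neg_pool))
  neg_ids <- if (n_neg > 0) sort(sample(neg_pool, n_neg)) else integer(0)
  years <- sort(unique(covariates$year))
  pick_year <- c(setNames(ev[[year_col]], pos_ids),
                 setNames(sample(years, length(neg_ids), replace = TRUE),
                          neg_ids))
  ids <- c(pos_ids, neg_ids)
  lk <- lakes[match(ids, lakes$lake_id), , drop = FALSE]
  cov_key <- paste(covariates$lake_id, covariates$year)
  cv <- covariates[match(paste(ids, pick_year[as.character(ids)]), cov_key), ,
                   drop = FALSE]
  clim_cols <- setdiff(names(covariates), c("lake_id", "year"))
  static_default <- intersect(c("elevation", "air_temp_trend", "active_layer",
                                "area_ha", "thermokarst", "permafrost",
                                "ground_ice", "floodplain"), names(lk))
  if (is.null(features)) features <- c(clim_cols, static_default)
  out <- data.frame(label = as.integer(ids %in% pos_ids))
  for (f in features) {
    out[[f]] <- if (f %in% clim_cols) cv[[f]] else lk[[f]]
  }
  rownames(out) <- NULL
  attr(out, "climate_year") <- unname(pick_year[as.character(ids)])
  out
}

# One-hot encoding with a stable level map; trees see every level column.
encode_features <- function(df, features, levels_map = NULL) {
  cols <- list(); groups <- list(); lmap <- list()
  for (f in features) {
    v <- df[[f]]
    if (is.numeric(v) || is.logical(v)) {
      cols[[f]] <- as.numeric(v)
      groups[[f]] <- f
    } else {
      lv <- if (!is.null(levels_map) && f %in% names(levels_map))
        levels_map[[f]] else sort(unique(as.character(v)))
      lmap[[f]] <- lv
      nm <- paste0(f, "=", lv)
      for (i in seq_along(lv)) cols[[nm[i]]] <- as.numeric(as.character(v) == lv[i])
      groups[[f]] <- nm
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, groups = groups,
       levels = if (is.null(levels_map)) lmap else levels_map)
}

#' Rank-based AUC, average precision, and regression metrics
#'
#' `metric_auc` is the Mann-Whitney rank statistic (probability a random
#' positive outscores a random negative); `metric_ap` is the mean precision
#' at the rank of each positive.
#'
#' @param score Predicted scores or values.
#' @param label Binary labels (AUC/AP) or observed values (regression).
#' @return A single numeric value.
#' @export
metric_auc <- function(score, label) {
  np <- sum(label == 1); nn <- sum(label == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' @rdname metric_auc
#' @export
metric_ap <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  l <- label[ord]
  cum_pos <- cumsum(l)
  prec <- cum_pos / seq_along(l)
  mean(prec[l == 1])
}

#' @rdname metric_auc
#' @export
metric_r2 <- function(score, label) {
  1 - sum((label - score)^2) / sum((label - mean(label))^2)
}

default_search_space <- function() {
  list(eta = function(n) exp(runif(n, log(0.03), log(0.3))),
       max_depth = function(n) sample(2:6, n, replace = TRUE),
       subsample = function(n) runif(n, 0.6, 1),
       colsample_bytree = function(n) runif(n, 0.6, 1),
       min_child_weight = function(n) exp(runif(n, log(1), log(8))))
}

#' Fit a gradient-boosted model with a held-out test split
#'
#' Splits the sample table 70/30, tunes a gradient-boosted tree ensemble by
#' random search with k-fold cross-validation on the training split
#' (`n_search = 0` skips tuning and uses documented defaults), refits on the
#' full training split, and reports metrics on the untouched test split:
#' AUC, average precision, precision and recall at 0.5 for classification;
#' RMSE, R-squared, MAE and mean bias for regression. Categorical features
#' are one-hot encoded; importance methods aggregate them back to the
#' original feature.
#'
#' @param samples Table from [build_samples()] (or any table with a `label`
#'   column and feature columns).
#' @param task `"classify"` or `"regress"`.
#' @param train_fraction Training share (default 0.7).
#' @param cv_folds Cross-validation folds for the random search (default 10).
#' @param n_search Random-search iterations (default 10; 0 = defaults:
#'   eta 0.1, max_depth 4, subsample 0.9, colsample 0.9, min_child_weight 2,
#'   200 rounds).
#' @param nrounds Maximum boosting rounds.
#' @param seed Integer seed (split, search and fit are deterministic).
#' @return A `pl_gbm` object with elements `booster`, `features`, `groups`,
#'   `levels`, `task`, `metrics`, `params`, `test_idx`.
#' @export
split_and_fit <- function(samples, task = c("classify", "regress"),
                          train_fraction = 0.7, cv_folds = 10, n_search = 10,
                          nrounds = 300, seed = 1L) {
  task <- match.arg(task)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  features <- setdiff(names(samples), "label")
  enc <- encode_features(samples, features)
  y <- samples$label
  n <- nrow(samples)
  tr <- sort(sample(n, round(train_fraction * n)))
  te <- setdiff(seq_len(n), tr)
  if (task == "classify" && length(unique(y[tr])) < 2)
    stop("training split contains a single class")
  objective <- if (task == "classify") "binary:logistic" else "reg:squarederror"
  eval_metric <- if (task == "classify") "auc" else "rmse"
  dtrain <- xgboost::xgb.DMatrix(enc$X[tr, , drop = FALSE], label = y[tr])
  base <- list(objective = objective, eval_metric = eval_metric,
               nthread = 1, seed = seed)
  pick <- list(eta = 0.1, max_depth = 4, subsample = 0.9,
               colsample_bytree = 0.9, min_child_weight = 2)
  best_rounds <- 200
  if (n_search > 0) {
    space <- default_search_space()
    draws <- lapply(space, function(f) f(n_search))
    best_score <- if (task == "classify") -Inf else Inf
    for (i in seq_len(n_search)) {
      cand <- lapply(draws, `[[`, i)
      cv <- xgboost::xgb.cv(params = c(base, cand), data = dtrain,
                            nrounds = nrounds, nfold = cv_folds,
                            early_stopping_rounds = 20, verbose = 0)
      log <- cv$evaluation_log
      mcol <- paste0("test_", eval_metric, "_mean")
      it <- if (task == "classify") which.max(log[[mcol]]) else
        which.min(log[[mcol]])
      sc <- log[[mcol]][it]
      improved <- if (task == "classify") sc > best_score else sc < best_score
      if (improved) { best_score <- sc; pick <- cand; best_rounds <- it }
    }
  }
  booster <- xgboost::xgb.train(params = c(base, pick), data = dtrain,
                                nrounds = best_rounds, verbose = 0)
  model <- structure(list(booster = booster, features = features,
                          groups = enc$groups, levels = enc$levels,
                          task = task, params = c(pick, nrounds = best_rounds),
                          test_idx = te),
                     class = "pl_gbm")
  pred <- predict(model, samples[te, , drop = FALSE])
  model$metrics <- if (task == "classify") {
    cls <- as.integer(pred > 0.5)
    tp <- sum(cls == 1 & y[te] == 1)
    list(auc = metric_auc(pred, y[te]), average_precision = metric_ap(pred, y[te]),
         precision = if (sum(cls) > 0) tp / sum(cls) else NA_real_,
         recall = tp / sum(y[te] == 1))
  } else {
    err <- pred - y[te]
    list(rmse = sqrt(mean(err^2)), r2 = metric_r2(pred, y[te]),
         mae = mean(abs(err)), mean_bias = mean(err))
  }
  model
}

#' @export
predict.pl_gbm <- function(object, newdata, ...) {
  enc <- encode_features(newdata, object$features, object$levels)
  predict(object$booster, xgboost::xgb.DMatrix(enc$X))
}

#' @export
print.pl_gbm <- function(x, ...) {
  cat(sprintf("<pl_gbm> %s, %d features; held-out: %s\n", x$task,
              length(x$features),
              paste(sprintf("%s=%.3f", names(x$metrics),
                            unlist(x$metrics)), collapse = " ")))
  invisible(x)
}

#' Permutation importance
#'
#' Mean drop of a performance metric over `n_repeats` when one feature
#' column is permuted while all other columns stay fixed; the baseline is
#' computed once. One-hot columns of a categorical feature are permuted
#' jointly, so importance is reported at the original-feature level.
#'
#' @param model A `pl_gbm` from [split_and_fit()].
#' @param data Evaluation table with `label` (typically the held-out split).
#' @param metric Metric function `f(score, label)`, higher is better;
#'   defaults to AUC (classification) or R-squared (regression).
#' @param n_repeats Number of permutations per feature (>= 5 recommended).
#' @param seed Integer seed.
#' @return Data frame `feature`, `importance_mean`, `importance_sd`, `rank`
#'   with attribute `baseline`.
#' @export
permutation_importance <- function(model, data, metric = NULL,
                                   n_repeats = 10, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  if (is.null(metric))
    metric <- if (model$task == "classify") metric_auc else metric_r2
  y <- data$label
  baseline <- metric(predict(model, data), y)
  res <- lapply(model$features, function(f) {
    drops <- vapply(seq_len(n_repeats), function(r) {
      d <- data
      d[[f]] <- d[[f]][sample(nrow(d))]
      baseline - metric(predict(model, d), y)
    }, 1)
    data.frame(feature = f, importance_mean = mean(drops),
               importance_sd = sd(drops))
  })
  out <- do.call(rbind, res)
  out$rank <- rank(-out$importance_mean, ties.method = "first")
  attr(out, "baseline") <- baseline
  out
}

#' Sampling-based Shapley feature contributions
#'
#' Monte-Carlo estimate of Shapley values by random feature-order sampling
#' with background-replacement imputation: for each explained row and each
#' sampled order, features are switched one at a time from a random
#' background row's values to the explained row's values, and the change in
#' model output is credited to the switched feature. Contributions of one
#' sampled order telescope, so per-row estimates satisfy the efficiency
#' property against the sampled backgrounds exactly.
#'
#' @param model A `pl_gbm`.
#' @param data Feature table (a `label` column is ignored).
#' @param n_permutations Sampled feature orders per explained row.
#' @param rows Row indices to explain (default: up to 200, sampled).
#' @param seed Integer seed.
#' @return List: `phi` (rows x features matrix of Shapley estimates),
#'   `mean_abs` (data frame `feature`, `shap_mean_abs`, `rank`), `rows`,
#'   `baseline_mean` (per-row mean model output over the sampled
#'   backgrounds), `prediction` (model output per explained row).
#' @export
shapley_sampling <- function(model, data, n_permutations = 30, rows = NULL,
                             seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  feats <- model$features
  p <- length(feats)
  if (is.null(rows)) rows <- sort(sample(nrow(data), min(200, nrow(data))))
  nR <- length(rows)
  M <- n_permutations
  blk <- p + 1L
  # per (row, perm): background row index and feature order
  bg_idx <- matrix(sample(nrow(data), nR * M, replace = TRUE), nR, M)
  orders <- replicate(nR * M, sample.int(p), simplify = FALSE)
  # assemble all hybrid instances column-wise: within a block, a feature
  # keeps the background value until its position in the order, then the
  # explained row's value
  nb <- nR * M
  big <- data.frame(row.names = seq_len(nb * blk))
  block_of <- rep(seq_len(nb), each = blk)
  r_of_block <- rep(rows, each = M)
  for (j in seq_len(p)) {
    posj <- vapply(orders, function(o) which(o == j), 1L)
    bgv <- data[[feats[j]]][as.vector(t(bg_idx))]
    xv <- data[[feats[j]]][r_of_block]
    pieces <- mapply(function(b, x, pos) rep(c(b, x), c(pos, blk - pos)),
                     bgv, xv, posj, SIMPLIFY = FALSE)
    big[[feats[j]]] <- unlist(pieces, use.names = FALSE)
  }
  preds <- predict(model, big)
  pm <- matrix(preds, nrow = blk)        # one column per block
  diffs <- pm[-1, , drop = FALSE] - pm[-blk, , drop = FALSE]  # step s = order pos s
  phi <- matrix(0, nR, p, dimnames = list(NULL, feats))
  for (b in seq_len(nb)) {
    r <- ((b - 1L) %/% M) + 1L
    phi[r, orders[[b]]] <- phi[r, orders[[b]]] + diffs[, b]
  }
  phi <- phi / M
  baseline_mean <- vapply(seq_len(nR), function(r)
    mean(pm[1, ((r - 1L) * M + 1L):(r * M)]), 1)
  prediction <- pm[blk, seq(M, nb, by = M)]
  mean_abs <- data.frame(feature = feats,
                         shap_mean_abs = colMeans(abs(phi)))
  mean_abs$rank <- rank(-mean_abs$shap_mean_abs, ties.method = "first")
  list(phi = phi, mean_abs = mean_abs, rows = rows,
       baseline_mean = baseline_mean, prediction = prediction)
}

#' Combined importance report
#'
#' @param perm Output of [permutation_importance()].
#' @param shap `mean_abs` element of [shapley_sampling()] (optional).
#' @return Data frame with both importance measures and per-method ranks.
#' @export
importance_report <- function(perm, shap = NULL) {
  out <- perm[c("feature", "importance_mean", "importance_sd")]
  names(out)[2:3] <- c("permutation_mean", "permutation_sd")
  out$permutation_rank <- rank(-out$permutation_mean, ties.method = "first")
  if (!is.null(shap)) {
    out$shap_mean_abs <- shap$shap_mean_abs[match(out$feature, shap$feature)]
    out$shap_rank <- rank(-out$shap_mean_abs, ties.method = "first")
  }
  out
}

#' Correlation-based feature pruning
#'
#' Walks features in decreasing importance, dropping (a) features whose
#' importance is not above `min_importance` ("negligible") and (b)
#' continuous features correlated with an already-retained, more important
#' continuous feature beyond `|r| > r_threshold`; the higher-importance
#' member of each correlated pair is always kept, so the top-ranked feature
#' is never removed.
#'
#' @param samples Sample table with `label`.
#' @param importance Data frame `feature`, plus an importance column (the
#'   first numeric column is used).
#' @param r_threshold Absolute Pearson correlation threshold (default 0.5).
#' @param min_importance Importance at or below which a non-top feature is
#'   dropped as negligible (default: none dropped).
#' @return List: `samples` (reduced table), `removed` (data frame `feature`,
#'   `reason`, `partner`).
#' @export
prune_features <- function(samples, importance, r_threshold = 0.5,
                           min_importance = -Inf) {
  num_col <- names(importance)[vapply(importance, is.numeric, TRUE)][1]
  imp <- importance[order(-importance[[num_col]]), ]
  feats <- as.character(imp$feature)
  stopifnot(all(feats %in% names(samples)))
  is_cont <- vapply(feats, function(f) is.numeric(samples[[f]]), TRUE)
  kept <- character(0)
  removed <- data.frame(feature = character(0), reason = character(0),
                        partner = character(0))
  for (i in seq_along(feats)) {
    f <- feats[i]
    if (i > 1 && imp[[num_col]][i] <= min_importance) {
      removed <- rbind(removed, data.frame(feature = f, reason = "negligible",
                                           partner = NA_character_))
      next
    }
    drop_for <- NA_character_
    if (is_cont[i]) {
      for (g in kept[kept %in% feats[is_cont]]) {
        r <- suppressWarnings(cor(samples[[f]], samples[[g]],
                                  use = "complete.obs"))
        if (!is.na(r) && abs(r) > r_threshold) { drop_for <- g; break }
      }
    }
    if (!is.na(drop_for)) {
      removed <- rbind(removed, data.frame(feature = f, reason = "correlated",
                                           partner = drop_for))
    } else kept <- c(kept, f)
  }
  list(samples = samples[, c(intersect("label", names(samples)), kept),
                         drop = FALSE],
       removed = removed)
}
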