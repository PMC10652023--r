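# 31-bit polynomial string hash; used for config hashing and stable
# per-stage seed derivation (no external digest dependency). Arithmetic is
# kept below 2^31 so results are exact doubles on every platform.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  h
}

canonicalize <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x))))
      x <- x[order(names(x))]
    return(paste0("{", paste(names(x), vapply(x, canonicalize, ""),
                             sep = ":", collapse = ","), "}"))
  }
  paste(format(x, digits = 15), collapse = ",")
}

#' Hash a pipeline configuration
#'
#' Stable under key reordering: the configuration is canonicalized (names
#' sorted recursively) before hashing.
#'
#' @param config A configuration list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  sprintf("%08x", fnv1a(canonicalize(config)))
}

#' Derive a per-stage seed from the global seed
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + fnv1a(stage)) %% 2147483647)
}

pipeline_stages <- c("simulate", "indices", "detect", "timing",
                     "greenness", "density", "drivers")

#' Default pipeline configuration
#'
#' @param seed Global seed; per-stage seeds are derived by stable hashing of
#'   (seed, stage name).
#' @param grid_rows,grid_cols Scene size for the simulate stage.
#' @return Nested configuration list (serializable to YAML with
#'   [write_pipeline_config()]).
#' @export
default_pipeline_config <- function(seed = 1L, grid_rows = 256,
                                    grid_cols = 256) {
  list(seed = as.integer(seed),
       sim = list(grid_rows = grid_rows, grid_cols = grid_cols),
       detect = list(connectivity = 8, min_area_ha = 1, min_fraction = 0.5),
       timing = list(max_segments = 6, spike_threshold = 0.9,
                     recovery_threshold = 0.25, pval_threshold = 0.05,
                     best_model_proportion = 0.75, min_magnitude = 0.2),
       greenness = list(factor = 2, reference_year = 10),
       drivers = list(neg_fraction = 1.0, n_search = 0, cv_folds = 5,
                      min_class_size = 5))
}

#' Read or write a pipeline configuration (YAML)
#'
#' @param path File path.
#' @param config Configuration list.
#' @return `read_pipeline_config` returns the configuration list.
#' @export
read_pipeline_config <- function(path) yaml::read_yaml(path)

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Match detected events to simulator truth lakes
#'
#' Assigns each detected lake object the truth lake whose footprint overlaps
#' it most (by pixel count); no overlap gives `NA`.
#'
#' @param event_pixels List of detected footprint index vectors, named by
#'   detected `lake_id`.
#' @param truth_footprints List of truth footprint index vectors, named by
#'   truth `lake_id`.
#' @return Named integer vector: detected id -> truth id.
#' @export
match_events_to_truth <- function(event_pixels, truth_footprints) {
  truth_ids <- as.integer(names(truth_footprints))
  vapply(event_pixels, function(idx) {
    ov <- vapply(truth_footprints, function(fp) length(intersect(idx, fp)), 1L)
    if (all(ov == 0)) return(NA_integer_)
    truth_ids[which.max(ov)]
  }, 1L)
}

#' Run the lake-drainage analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate -> indices -> detect -> timing -> greenness -> density ->
#' drivers`), writing each stage's tables and rasters under `outdir` and a
#' `manifest.json` recording the configuration hash, seed, per-stage outputs
#' and record counts. Re-running with an unchanged configuration and seed
#' reproduces identical event and trajectory tables. The scene itself is
#' deterministic given the configuration, so scene-dependent stages
#' regenerate it on demand; stages that consume another stage's *files*
#' (e.g. `drivers` needs the detection outputs) raise an error naming the
#' stage to run first.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file.
#' @param stages Character vector of stages, or `"all"`.
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, stages = "all", outdir = "permalake_run",
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  if (identical(stages, "all")) stages <- pipeline_stages
  stopifnot(all(stages %in% pipeline_stages))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  state <- new.env(parent = emptyenv())
  manifest <- list(package = "permalake",
                   version = as.character(utils::packageVersion("permalake")),
                   config_hash = config_hash(config), seed = seed,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  note <- function(stage, outputs, counts) {
    manifest$stages[[stage]] <<- list(outputs = outputs, counts = counts)
  }
  pth <- function(f) file.path(outdir, f)
  need_file <- function(f, produced_by) {
    if (!file.exists(pth(f)))
      stop(sprintf("missing artifact '%s': run stage '%s' first", f,
                   produced_by), call. = FALSE)
    pth(f)
  }

  get_bundle <- function() {
    if (!is.null(state$bundle)) return(state$bundle)
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- derive_seed(seed, "simulate")
    state$bundle <- do.call(sim_config, sim_args) |> simulate_scene()
    state$bundle
  }
  get_detection <- function() {
    if (is.null(state$lab)) {
      bundle <- get_bundle()
      cleaned <- clean_mask(bundle$permanent_water)
      state$lab <- label_objects(cleaned, config$detect$connectivity,
                                 bundle$config$pixel_size)
      state$lab$objects <- assign_attributes(
        state$lab$objects, state$lab$pixels,
        bundle$attributes[c("thermokarst", "permafrost", "ground_ice",
                            "yedoma", "floodplain")])
      state$loss <- union_loss(bundle$loss_masks$jrc_like,
                               bundle$loss_masks$glad_like)
    }
    state$lab
  }

  for (stage in stages) {
    say("stage %s", stage)
    if (stage == "simulate") {
      bundle <- get_bundle()
      ps <- bundle$config$pixel_size
      write_table(bundle$truth, pth("truth.csv"))
      write_table(bundle$covariates, pth("covariates.csv"))
      write_raster(bundle$permanent_water, pth("water_extent.asc"),
                   cellsize = ps)
      write_raster(bundle$loss_masks$jrc_like, pth("loss_jrc_like.asc"),
                   cellsize = ps)
      write_raster(bundle$loss_masks$glad_like, pth("loss_glad_like.asc"),
                   cellsize = ps)
      write_raster(bundle$attributes$zone, pth("zone.asc"), cellsize = ps)
      note("simulate",
           c("truth.csv", "covariates.csv", "water_extent.asc",
             "loss_jrc_like.asc", "loss_glad_like.asc", "zone.asc"),
           list(lakes = nrow(bundle$truth),
                drained = sum(bundle$truth$drained),
                pixels = prod(dim(bundle$permanent_water))))
    } else if (stage == "indices") {
      bundle <- get_bundle()
      ps <- bundle$config$pixel_size
      outs <- character(0)
      summ <- lapply(names(bundle$composites$ndvi), function(yk) {
        f <- sprintf("water_mask_%s.asc", yk)
        write_raster(bundle$water_masks[[yk]], pth(f), cellsize = ps)
        data.frame(year = as.integer(yk),
                   mean_ndvi = mean(bundle$composites$ndvi[[yk]], na.rm = TRUE),
                   mean_awei = mean(bundle$composites$awei[[yk]], na.rm = TRUE),
                   water_px = sum(bundle$water_masks[[yk]]))
      })
      write_table(do.call(rbind, summ), pth("composite_summary.csv"))
      note("indices", c("composite_summary.csv", "water_mask_<year>.asc"),
           list(years = length(bundle$years)))
    } else if (stage == "detect") {
      lab <- get_detection()
      events <- detect_drainage_events(lab$objects, lab$pixels, state$loss,
                                       config$detect$min_area_ha,
                                       config$detect$min_fraction)
      state$events <- events
      write_table(lab$objects, pth("objects.csv"))
      write_table(events, pth("events.csv"))
      note("detect", c("objects.csv", "events.csv"),
           list(objects = nrow(lab$objects), events = nrow(events)))
    } else if (stage == "timing") {
      if (is.null(state$events)) {
        need_file("events.csv", "detect")
        state$events <- read_table(pth("events.csv"))
        get_detection()
      }
      bundle <- get_bundle()
      tp <- config$timing
      params <- segmentation_params(tp$max_segments, tp$spike_threshold,
                                    tp$recovery_threshold, tp$pval_threshold,
                                    tp$best_model_proportion)
      dated <- date_events(state$events, state$lab$pixels,
                           bundle$composites$awei, state$loss, params,
                           tp$min_magnitude)
      state$dated <- dated
      write_table(dated, pth("events_dated.csv"))
      note("timing", "events_dated.csv",
           list(events = nrow(dated), dated = sum(!is.na(dated$detected_year))))
    } else if (stage == "greenness") {
      if (is.null(state$dated)) {
        need_file("events.csv", "detect")
        need_file("events_dated.csv", "timing")
        state$dated <- read_table(pth("events_dated.csv"))
        get_detection()
      }
      bundle <- get_bundle()
      traj <- build_trajectories(state$dated, state$lab$pixels,
                                 bundle$composites$ndvi, bundle$water_masks,
                                 bundle$config$pixel_size,
                                 config$greenness$factor, quiet = quiet)
      if (!is.null(traj)) {
        traj$thermokarst <- state$dated$thermokarst[
          match(traj$lake_id, state$dated$lake_id)]
        gt <- group_trajectories(traj, "thermokarst",
                                 config$greenness$reference_year)
        write_table(traj, pth("trajectories.csv"))
        write_table(gt$trajectory, pth("trajectory_summary.csv"))
        if (!is.null(gt$reference))
          write_table(gt$reference, pth("trajectory_reference.csv"))
      }
      state$traj <- traj
      note("greenness", c("trajectories.csv", "trajectory_summary.csv"),
           list(records = if (is.null(traj)) 0L else nrow(traj)))
    } else if (stage == "density") {
      if (is.null(state$dated)) {
        need_file("events.csv", "detect")
        need_file("events_dated.csv", "timing")
        state$dated <- read_table(pth("events_dated.csv"))
        get_detection()
      }
      bundle <- get_bundle()
      dens_sp <- spatial_density(state$dated, bundle$attributes$zone,
                                 bundle$config$pixel_size)
      dens_rows <- lapply(c("thermokarst", "permafrost", "ground_ice"),
                          function(s) {
                            d <- lakewise_density(state$lab$objects,
                                                  state$dated, s)
                            d$stratum_type <- s
                            d
                          })
      dens_lw <- do.call(rbind, dens_rows)
      counts <- annual_event_counts(state$dated, bundle$years)
      trend <- tryCatch(ols_trend(counts$year, counts$n_events),
                        error = function(e) NULL)
      write_table(dens_sp, pth("density_spatial.csv"))
      write_table(dens_lw, pth("density_lakewise.csv"))
      write_table(counts, pth("annual_counts.csv"))
      if (!is.null(trend))
        write_table(data.frame(series = "annual_event_count",
                               slope = trend$slope, p_value = trend$p_value,
                               sen_slope = trend$sen_slope),
                    pth("trends.csv"))
      note("density",
           c("density_spatial.csv", "density_lakewise.csv",
             "annual_counts.csv", "trends.csv"),
           list(zones = nrow(dens_sp), strata = nrow(dens_lw)))
    } else if (stage == "drivers") {
      if (is.null(state$dated)) {
        need_file("events.csv", "detect")
        need_file("events_dated.csv", "timing")
        state$dated <- read_table(pth("events_dated.csv"))
        get_detection()
      }
      bundle <- get_bundle()
      dv <- config$drivers
      truth_map <- match_events_to_truth(
        state$lab$pixels[as.character(state$dated$lake_id)],
        bundle$footprints)
      ev <- data.frame(lake_id = unname(truth_map),
                       detected_year = state$dated$detected_year)
      ev <- ev[!is.na(ev$lake_id), , drop = FALSE]
      samples <- build_samples(bundle$truth, ev, bundle$covariates,
                               dv$neg_fraction,
                               seed = derive_seed(seed, "drivers"))
      write_table(samples, pth("samples.csv"))
      outs <- "samples.csv"
      counts <- list(samples = nrow(samples))
      if (sum(samples$label == 1) >= dv$min_class_size &&
          sum(samples$label == 0) >= dv$min_class_size) {
        fit <- split_and_fit(samples, "classify", cv_folds = dv$cv_folds,
                             n_search = dv$n_search,
                             seed = derive_seed(seed, "drivers_fit"))
        test <- samples[fit$test_idx, , drop = FALSE]
        perm <- permutation_importance(fit, test,
                                       seed = derive_seed(seed, "drivers_pi"))
        shap <- shapley_sampling(fit, test,
                                 seed = derive_seed(seed, "drivers_shap"))
        rep <- importance_report(perm, shap$mean_abs)
        write_table(rep, pth("importance.csv"))
        jsonlite::write_json(fit$metrics, pth("metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        outs <- c(outs, "importance.csv", "metrics.json")
        counts$auc <- fit$metrics$auc
      }
      note("drivers", outs, counts)
    }
  }
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
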