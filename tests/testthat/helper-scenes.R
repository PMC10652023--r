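# Small scene configurations shared by tests. Grids are kept small so the
# default suite stays fast; acceptance tests build their own larger scenes.

tiny_config <- function(seed = 1, ...) {
  sim_config(grid_rows = 96, grid_cols = 96, n_lakes = 10,
             area_log10_range = c(0, 1.3), years = 2000:2014,
             obs_per_year = 4, field_range_px = 20, seed = seed, ...)
}

noiseless_args <- function() {
  list(obs_noise_sd = 0, cloud_dropout_prob = 0, spike_prob = 0,
       product_error = list(jrc_like = c(omission = 0, commission = 0),
                            glad_like = c(omission = 0, commission = 0)))
}

tiny_noiseless <- function(seed = 1, ...) {
  do.call(tiny_config, c(list(seed = seed), noiseless_args(), list(...)))
}

# Run detection on a bundle; returns lab, loss and the event table.
detect_on <- function(bundle, connectivity = 8) {
  cleaned <- clean_mask(bundle$permanent_water)
  lab <- label_objects(cleaned, connectivity, bundle$config$pixel_size)
  loss <- union_loss(bundle$loss_masks$jrc_like, bundle$loss_masks$glad_like)
  events <- detect_drainage_events(lab$objects, lab$pixels, loss)
  list(lab = lab, loss = loss, events = events)
}
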