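test_that("morphological cleaning removes isolated pixels and severs thin bridges", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  expect_false(any(clean_mask(m)))
  # two 5x5 blocks joined by a 1-pixel-wide bridge: bridge severed
  m2 <- matrix(FALSE, 7, 15)
  m2[2:6, 2:6] <- TRUE; m2[2:6, 10:14] <- TRUE; m2[4, 7:9] <- TRUE
  out <- clean_mask(m2)
  expect_false(out[4, 8])
  lab <- label_objects(out, 8)
  expect_identical(nrow(lab$objects), 2L)
  expect_identical(out, brute_opening(m2))
})

test_that("opening is anti-extensive and idempotent", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(runif(30 * 30) < 0.45, 30, 30)
    o1 <- clean_mask(m)
    expect_true(all(which(o1) %in% which(m)))      # output subset of input
    expect_identical(clean_mask(o1), o1)           # idempotent
    expect_identical(o1, brute_opening(m))         # matches set-arithmetic oracle
  }
  big <- matrix(FALSE, 24, 24); big[3:22, 3:22] <- TRUE
  out <- clean_mask(big)
  expect_true(all(out[5:20, 5:20]))
  expect_true(all(which(out) %in% which(big)))
})

test_that("labeling respects the connectivity definition", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_identical(nrow(label_objects(m, 8)$objects), 1L)
  expect_identical(nrow(label_objects(m, 4)$objects), 2L)
  expect_identical(nrow(label_objects(matrix(FALSE, 5, 5), 8)$objects), 0L)
})

test_that("labeling matches a flood-fill oracle on random masks", {
  set.seed(9)
  for (i in 1:15) {
    m <- matrix(runif(64 * 64) < runif(1, 0.2, 0.6), 64, 64)
    for (conn in c(8, 4)) {
      got <- label_objects(m, conn)
      want <- flood_fill_label(m, conn)
      expect_identical(max(got$labels), max(want))
      # same partition: label images agree up to renaming
      expect_identical(anyDuplicated(unique(cbind(got$labels[m], want[m]))[, 1]), 0L)
      expect_identical(sum(got$objects$pixel_count), sum(m))
    }
  }
})

test_that("lake objects carry area, centroid and equivalent diameter", {
  m <- matrix(FALSE, 10, 10); m[3:5, 4:6] <- TRUE   # 9 pixels
  obj <- label_objects(m, 8, pixel_size = 30)$objects
  expect_equal(obj$area_ha, 9 * 900 / 1e4)
  expect_equal(obj$centroid_row, 4)
  expect_equal(obj$centroid_col, 5)
  expect_equal(obj$equivalent_diameter_m, 2 * sqrt(9 * 900 / pi))
})

test_that("loss union is a pixelwise OR with shape checking", {
  a <- matrix(FALSE, 5, 5); a[1, 1] <- TRUE
  b <- matrix(FALSE, 5, 5); b[5, 5] <- TRUE
  expect_identical(sum(union_loss(a, b)), 2L)
  expect_identical(union_loss(a, a), a)
  set.seed(4)
  for (i in 1:5) {
    x <- matrix(runif(25) < 0.4, 5, 5); y <- matrix(runif(25) < 0.4, 5, 5)
    u <- union_loss(x, y)
    expect_true(all(which(x) %in% which(u)))
    expect_true(all(which(y) %in% which(u)))
  }
  expect_error(union_loss(a, matrix(FALSE, 4, 5)), "5x5.*4x5")
})

test_that("drainage fraction and event thresholds follow the strict rules", {
  m <- matrix(FALSE, 10, 10)
  lake_idx <- 1:20
  loss <- matrix(FALSE, 10, 10)
  loss[1:11] <- TRUE
  expect_equal(drainage_fraction(lake_idx, loss), 0.55)
  loss10 <- matrix(FALSE, 10, 10); loss10[1:10] <- TRUE
  expect_equal(drainage_fraction(lake_idx, loss10), 0.5)
  lossall <- matrix(TRUE, 10, 10)
  expect_equal(drainage_fraction(lake_idx, lossall), 1)
  expect_error(drainage_fraction(integer(0), loss), "empty")

  # 12-pixel lake (1.08 ha) fully lost -> event; 11-pixel (0.99 ha) -> none;
  # 20-pixel lake with exactly half lost -> none (strict > 50%)
  m <- matrix(FALSE, 20, 30)
  m[2:4, 2:5] <- TRUE                      # 12 px
  m[8:18, 8] <- TRUE                       # 11 px
  m[2:5, 12:16] <- TRUE                    # 20 px
  lab <- label_objects(m, 8, pixel_size = 30)
  loss <- matrix(FALSE, 20, 30)
  loss[2:4, 2:5] <- TRUE
  loss[8:18, 8] <- TRUE
  loss[2:5, 12:16][1:10] <- TRUE
  ev <- detect_drainage_events(lab$objects, lab$pixels, loss)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$area_ha, 1.08)
  expect_equal(ev$loss_fraction, 1)
})

test_that("size classes split at 10 and 100 hectares", {
  expect_identical(as.character(size_class(c(5, 50, 500))),
                   c("small", "medium", "large"))
  expect_identical(as.character(size_class(c(10, 100))),
                   c("medium", "large"))
})

test_that("event counts are monotone in both thresholds", {
  b <- simulate_scene(tiny_noiseless(seed = 6))
  det <- detect_on(b)
  n_base <- nrow(detect_drainage_events(det$lab$objects, det$lab$pixels,
                                        det$loss, 1, 0.5))
  n_area <- nrow(detect_drainage_events(det$lab$objects, det$lab$pixels,
                                        det$loss, 2, 0.5))
  n_frac <- nrow(detect_drainage_events(det$lab$objects, det$lab$pixels,
                                        det$loss, 1, 0.8))
  expect_lte(n_area, n_base)
  expect_lte(n_frac, n_base)
})

test_that("noiseless detection recovers exactly the truth events", {
  b <- simulate_scene(tiny_noiseless(seed = 2))
  det <- detect_on(b)
  matched <- match_events_to_truth(
    det$lab$pixels[as.character(det$events$lake_id)], b$footprints)
  expect_identical(sort(unname(matched)),
                   sort(b$truth$lake_id[b$truth$event_truth]))
})

test_that("majority attributes break ties toward the centroid", {
  m <- matrix(FALSE, 6, 6); m[2:3, 2:4] <- TRUE
  lab <- label_objects(m, 8)
  ras <- matrix("a", 6, 6)
  ras[2, 2:4] <- "b"   # 3 vs 3 tie
  obj <- assign_attributes(lab$objects, lab$pixels, list(x = ras))
  # nearest pixel to the centroid decides the tie deterministically
  expect_true(obj$x %in% c("a", "b"))
  ras2 <- matrix("a", 6, 6); ras2[2:3, 2:3] <- "c"  # 4 vs 2 majority
  expect_identical(assign_attributes(lab$objects, lab$pixels,
                                     list(x = ras2))$x, "c")
})
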