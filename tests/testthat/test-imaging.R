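test_that("max projection equals the element-wise maximum over z", {
  withr::with_seed(1, {
    a <- array(rnorm(40 * 30 * 3), dim = c(40, 30, 3))
    expect_equal(max_project(a), apply(a, c(1, 2), max))
  })
  one <- array(rnorm(20 * 20), dim = c(20, 20, 1))
  expect_equal(max_project(one), one[, , 1])
  # a value on a single plane survives projection
  b <- array(0, dim = c(10, 10, 4))
  b[3, 7, 2] <- 5
  expect_equal(max_project(b)[3, 7], 5)
})

test_that("nuclei are segmented with accurate count, centroid and diameter", {
  cfg <- noiseless(tiny_cfg(n_cells = 20, seed = 21,
                            nuclear_diameter_um = list(lymphocyte = c(9, 0),
                                                       monocyte = c(12, 1.2))))
  set <- simulate_image_set(cfg)
  stopifnot(length(set$fields) == 1)
  nuc <- segment_nuclei(max_project(set$fields[[1]])$DAPI, cfg$pixel_size_um)
  tr <- set$truth
  expect_equal(nrow(nuc), nrow(tr))
  for (i in seq_len(nrow(nuc))) {
    j <- which.min((tr$nucleus_y_um - nuc$y_um[i])^2 +
                     (tr$nucleus_x_um - nuc$x_um[i])^2)
    derr <- sqrt((tr$nucleus_y_um[j] - nuc$y_um[i])^2 +
                   (tr$nucleus_x_um[j] - nuc$x_um[i])^2)
    expect_lt(derr, cfg$pixel_size_um)                       # within 1 px
    expect_lt(abs(nuc$equivalent_diameter_um[i] - 9.0), 0.3) # true diameter 9
  }
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64), 0.1)), 0)
})

test_that("mitotic cells are flagged and interphase cells are not", {
  cfg <- tiny_cfg(n_cells = 30, seed = 31)
  cfg$mitotic_fraction <- 0.2
  set <- simulate_image_set(cfg)
  cells <- analyze_image_set(set, mode = "single_marker_cc")
  tr <- set$truth
  expect_gt(sum(tr$mitotic), 0)
  idx <- match_truth(cells, tr)
  expect_identical(cells$mitotic, tr$mitotic[idx])
})

test_that("single noiseless dots localize to subpixel accuracy", {
  for (off in c(0, 0.17, 0.31, 0.5, 0.74)) {
    img <- gauss_dot_img(64, 64, cbind(30 + off, 33 - off))
    sp <- detect_spots(img, 0.1)
    expect_equal(nrow(sp), 1)
    expect_lt(abs(sp$y_um - (30 + off - 1) * 0.1), 0.025)  # < 0.25 px
    expect_lt(abs(sp$x_um - (33 - off - 1) * 0.1), 0.025)
  }
})

test_that("a noiseless dot pair 2 um apart measures 2 um", {
  img <- gauss_dot_img(100, 100, rbind(c(30.3, 40.7), c(30.3, 60.7)))
  sp <- detect_spots(img, 0.1)
  expect_equal(nrow(sp), 2)
  sep <- sqrt(diff(sp$y_um)^2 + diff(sp$x_um)^2)
  expect_lt(abs(sep - 2.0), 0.05)
})

test_that("blank and flat images yield no spots", {
  expect_equal(nrow(detect_spots(matrix(0, 64, 64), 0.1)), 0)
  expect_equal(nrow(detect_spots(matrix(7, 64, 64), 0.1)), 0)
  withr::with_seed(2, {
    noisy <- matrix(rnorm(256 * 256, 20, 2), 256)
    expect_equal(nrow(detect_spots(noisy, 0.1)), 0)
  })
})

test_that("marker pairing is mutual-nearest-neighbour and channel-symmetric", {
  spots <- function(m) tibble::tibble(spot_id = seq_len(nrow(m)),
                                      y_um = m[, 1], x_um = m[, 2],
                                      peak_intensity = 1, quality = 1)
  # coincident pair collapses to the midpoint
  st <- pair_markers(spots(cbind(5, 5)), spots(cbind(5, 5)))
  expect_true(st$dual_positive)
  expect_equal(c(st$y_um, st$x_um), c(5, 5))
  # lone PCNT spot stays single-positive
  lone <- pair_markers(spots(cbind(1, 1)), spots(cbind(9, 9)), radius_um = 0.5)
  expect_false(any(lone$dual_positive))
  expect_equal(nrow(lone), 2)
  # crossing geometry agrees with the exhaustive oracle, in both channel orders
  withr::with_seed(42, for (rep in 1:20) {
    P <- cbind(runif(3, 0, 3), runif(3, 0, 3))
    G <- P[sample(3), ] + matrix(rnorm(6, 0, 0.3), 3)
    st <- pair_markers(spots(P), spots(G), radius_um = 0.6)
    got <- st[which(st$dual_positive), c("pcnt_id", "gtub_id")]
    want <- mutual_nn_brute(P, G, 0.6)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_setequal(paste(got$pcnt_id, got$gtub_id),
                      paste(want[, 1], want[, 2]))
    }
    swapped <- pair_markers(spots(G), spots(P), radius_um = 0.6)
    sw <- swapped[which(swapped$dual_positive), ]
    expect_setequal(paste(sw$gtub_id, sw$pcnt_id),
                    paste(got$pcnt_id, got$gtub_id))
  })
  # single-marker mode: every PCNT spot is a structure
  sm <- pair_markers(spots(rbind(c(1, 1), c(2, 2))), NULL)
  expect_equal(nrow(sm), 2)
  expect_true(all(is.na(sm$dual_positive)))
})

test_that("structures are assigned to the nearest nucleus with stable ties", {
  labm <- matrix(0L, 40, 60)
  labm[10:20, 5:15] <- 1L    # nucleus 1
  labm[10:20, 45:55] <- 2L   # nucleus 2, same shape
  nuc <- tibble::tibble(label = c(1L, 2L), y_um = c(1.4, 1.4), x_um = c(0.9, 4.9),
                        equivalent_diameter_um = 2, touches_border = FALSE,
                        mitotic = FALSE, mean_dapi = 1, fill_factor = 1)
  attr(nuc, "label_image") <- labm
  st <- function(y, x) tibble::tibble(structure_id = 1L, y_um = y, x_um = x,
                                      dual_positive = NA, pcnt_id = 1L,
                                      gtub_id = NA_integer_, quality = 1)
  inside <- assemble_cells(nuc, st(1.4, 0.9), 0.1)
  expect_equal(inside$nucleus_label, 1L)
  expect_equal(inside$dist_to_nucleus_um, 0)
  # exactly between the two boundaries (cols 15 and 45 -> x index 30 -> 2.9 um)
  expect_message(mid <- assemble_cells(nuc, st(1.4, 2.9), 0.1),
                 "equidistant")
  expect_equal(mid$nucleus_label, 1L)
  expect_true(mid$tie)
  # far structure dropped and counted
  far <- assemble_cells(nuc, st(3.8, 5.9), 0.1, max_dist_um = 0.5)
  expect_equal(nrow(far), 0)
  expect_equal(attr(far, "n_dropped"), 1)
})

test_that("noiseless end-to-end fields recover every dot and distance", {
  cfg <- noiseless(tiny_cfg(n_cells = 30, seed = 12, two_dot_fraction = 0.7))
  set <- simulate_image_set(cfg)
  cells <- analyze_image_set(set, mode = "single_marker_cc")
  tr <- set$truth
  expect_equal(nrow(cells), nrow(tr))
  idx <- match_truth(cells, tr)
  # perfect recall and precision of structure counts per cell
  expect_identical(cells$n_structures, tr$n_dots[idx])
  two <- which(tr$n_dots[idx] == 2L)
  expect_true(all(abs(cells$distance_um[two] - tr$distance_um[idx][two]) < 0.05))
  # ground-truth cell membership is recovered exactly
  expect_identical(unname(cells$mitotic), tr$mitotic[idx])
})

test_that("dual-marker gating drops decoy single-channel dots", {
  cfg <- tiny_cfg(n_cells = 25, seed = 13, dual_marker = TRUE,
                  two_dot_fraction = 1, decoy_rate = 0.5)
  set <- simulate_image_set(cfg)
  expect_gt(nrow(set$decoys), 0)
  cells <- analyze_image_set(set, mode = "dual_marker_duplicated")
  idx <- match_truth(cells, set$truth)
  # scorable (dual-positive) structures match the true dot count despite decoys
  expect_gte(mean(cells$n_structures == set$truth$n_dots[idx]), 0.95)
})

test_that("streaming generation matches the materialized image-set path", {
  cfg <- tiny_cfg(n_cells = 16, seed = 19, two_dot_fraction = 0.8)
  run <- simulate_and_analyze(cfg, mode = "single_marker_cc")
  set <- simulate_image_set(cfg)
  ref <- analyze_image_set(set, mode = "single_marker_cc")
  expect_identical(run$truth, set$truth)
  expect_equal(as.data.frame(run$cells), as.data.frame(ref))
})
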