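cells_row <- function(n_structures, distance_um = NA_real_, mitotic = FALSE,
                      border = FALSE, diameter_um = 8,
                      distance_top2_um = distance_um) {
  tibble::tibble(cell_id = 1L, diameter_um = diameter_um, mitotic = mitotic,
                 border = border, n_structures = as.integer(n_structures),
                 distance_um = distance_um, distance_top2_um = distance_top2_um)
}

test_that("per-cell split calls follow the strict 1.3 um rule", {
  cfg <- scoring_config()
  expect_false(score_cells(cells_row(2, 0), cfg)$split)          # coincident
  expect_true(score_cells(cells_row(2, 1.31), cfg)$split)
  expect_false(score_cells(cells_row(2, 1.29), cfg)$split)
  # structures at (0,0) and (0.5,1.2): distance exactly 1.3, not split
  d <- sqrt(0.5^2 + 1.2^2)
  expect_equal(d, 1.3)
  expect_false(score_cells(cells_row(2, d), cfg)$split)
})

test_that("exclusion reasons are assigned with the documented precedence", {
  cfg <- scoring_config()
  expect_equal(score_cells(cells_row(2, 1.0, mitotic = TRUE), cfg)$exclusion_reason,
               "mitotic")
  expect_equal(score_cells(cells_row(2, 1.0, border = TRUE), cfg)$exclusion_reason,
               "border")
  expect_equal(score_cells(cells_row(0), cfg)$exclusion_reason, "no_staining")
  expect_equal(score_cells(cells_row(3, NA, distance_top2_um = 1.5), cfg)$exclusion_reason,
               "ambiguous_count")
  # mitotic outranks a simultaneous border flag
  expect_equal(score_cells(cells_row(2, 1, mitotic = TRUE, border = TRUE),
                           cfg)$exclusion_reason, "mitotic")
  # split is only defined for included two-structure cells
  sc <- score_cells(cells_row(2, 2.0, mitotic = TRUE), cfg)
  expect_true(is.na(sc$split))
})

test_that("PBMC mode gates lymphocytes by nuclear diameter", {
  cfg <- scoring_config(pbmc_mode = TRUE)
  big <- score_cells(cells_row(2, 1.0, diameter_um = 12), cfg)
  expect_equal(big$exclusion_reason, "too_large_nucleus")
  ok <- score_cells(cells_row(2, 1.0, diameter_um = 9.9), cfg)
  expect_true(ok$included)
  # the gate is strict: exactly 10 um is excluded ("diameter < 10")
  edge <- score_cells(cells_row(2, 1.0, diameter_um = 10), cfg)
  expect_equal(edge$exclusion_reason, "too_large_nucleus")
  # without pbmc_mode the same cell is scored
  expect_true(score_cells(cells_row(2, 1.0, diameter_um = 12),
                          scoring_config())$included)
})

test_that("the two-brightest policy scores multi-structure cells", {
  cfg <- scoring_config(ambiguous_policy = "two_brightest")
  sc <- score_cells(cells_row(3, NA, distance_top2_um = 1.5), cfg)
  expect_true(sc$included)
  expect_true(sc$split)
  expect_equal(sc$score_distance_um, 1.5)
})

test_that("sample aggregation reproduces the defining arithmetic", {
  cfg <- scoring_config()
  mk <- function(n_two, n_split, n_one = 0) {
    tibble::tibble(
      cell_id = seq_len(n_two + n_one), diameter_um = 8, mitotic = FALSE,
      border = FALSE,
      n_structures = c(rep(2L, n_two), rep(1L, n_one)),
      distance_um = c(rep(2, n_split), rep(1, n_two - n_split),
                      rep(NA_real_, n_one)),
      distance_top2_um = NA_real_
    )
  }
  s <- score_sample(score_cells(mk(150, 30), cfg), cfg, sample_id = "a")
  expect_equal(s$pct_split, 20)
  expect_true(s$deficit)          # >= 20 is inclusive
  expect_false(s$low_n)
  s2 <- score_sample(score_cells(mk(60, 5, n_one = 40), cfg), cfg,
                     sample_id = "b")
  expect_equal(s2$pct_two_dot, 60)
  expect_equal(s2$n_included, 100)
  expect_false(s2$low_n)   # exactly at min_cells is not low
  s3 <- NULL
  expect_warning(s3 <- score_sample(score_cells(mk(50, 5, n_one = 20), cfg),
                                    cfg, sample_id = "c"),
                 "70")
  expect_true(s3$low_n)
  expect_error(score_sample(score_cells(cells_row(2, 1, mitotic = TRUE), cfg),
                            cfg),
               class = "ccs_empty_sample_error")
})

test_that("deficit calling is inclusive at the 20% threshold", {
  cfg <- scoring_config()
  expect_true(call_deficit(tibble::tibble(pct_split = 20.0), cfg))
  expect_false(call_deficit(tibble::tibble(pct_split = 19.9), cfg))
  expect_false(call_deficit(tibble::tibble(pct_split = 10.0), cfg))
  expect_true(call_deficit(tibble::tibble(pct_split = 35), cfg))
})

test_that("pct_split equals a brute-force recount on random cell tables", {
  cfg <- scoring_config()
  for (seed in 1:5) {
    cells <- random_cells(300, seed)
    sc <- score_cells(cells, cfg)
    s <- score_sample(sc, cfg, sample_id = "r")
    inc <- !cells$mitotic & !cells$border & cells$n_structures %in% c(1L, 2L) &
      cells$n_structures > 0L
    two <- inc & cells$n_structures == 2L
    expect_equal(s$n_included, sum(inc))
    expect_equal(s$pct_split, 100 * sum(cells$distance_um[two] > 1.3) / sum(two))
    expect_equal(s$pct_two_dot, 100 * sum(two) / sum(inc))
    # histogram counts sum to the two-dot cell count at any bin width
    for (bw in c(0.1, 0.2, 0.37)) {
      cfg_bw <- scoring_config(histogram_bin_um = bw)
      sbw <- score_sample(sc, cfg_bw, sample_id = "r")
      expect_equal(sum(sbw$hist_counts[[1]]), sbw$n_two_dot)
    }
  }
})

test_that("raising the split threshold never increases pct_split", {
  cells <- random_cells(400, 9)
  prev <- Inf
  for (thr in c(0.8, 1.0, 1.3, 1.6, 2.0)) {
    cfg <- scoring_config(split_threshold_um = thr)
    s <- score_sample(score_cells(cells, cfg), cfg, sample_id = "m")
    expect_lte(s$pct_split, prev)
    prev <- s$pct_split
  }
})

test_that("sample scores are invariant to cell order", {
  cfg <- scoring_config()
  cells <- random_cells(200, 4)
  a <- score_sample(score_cells(cells, cfg), cfg, sample_id = "p")
  b <- score_sample(score_cells(cells[sample(nrow(cells)), ], cfg), cfg,
                    sample_id = "p")
  expect_equal(a$pct_split, b$pct_split)
  expect_equal(a$mean_distance_um, b$mean_distance_um)
  expect_equal(a$hist_counts, b$hist_counts)
})

test_that("MLi2 reversal deltas and flags follow the deficit rule", {
  cfg <- scoring_config()
  samp <- function(id, pct) tibble::tibble(sample_id = id, pct_split = pct,
                                           deficit = call_deficit(tibble::tibble(pct_split = pct), cfg))
  r <- mli2_reversal(samp("s", 30), samp("s", 9))
  expect_equal(r$delta, 21)
  expect_true(r$reverted)
  r2 <- mli2_reversal(samp("s", 15), samp("s", 15))
  expect_equal(r2$delta, 0)
  expect_false(r2$reverted)
  # never a deficit: small shifts in the 0-15% band are not reversals
  r3 <- mli2_reversal(samp("s", 15), samp("s", 14))
  expect_equal(r3$delta, 1)
  expect_false(r3$reverted)
  expect_error(mli2_reversal(samp("s", 30), samp("t", 9)),
               class = "ccs_pairing_error")
})

test_that("ground truth flows through the scoring stage unchanged", {
  cfg <- tiny_cfg(n_cells = 200, seed = 6, two_dot_fraction = 1)
  truth <- simulate_ground_truth(cfg)$cells
  sc <- score_cells(truth_as_cells(truth), scoring_config())
  s <- score_sample(sc, scoring_config(), sample_id = "gt")
  expect_equal(s$n_two_dot, 200)
  expect_equal(s$pct_split, 100 * mean(truth$distance_um > 1.3))
})
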