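# small, dense image config for fast unit tests (spacing relaxed so a
# single field carries many cells)
tiny_cfg <- function(n_cells = 20, seed = 1, ...) {
  image_sim_config(n_cells = n_cells, field_shape_px = c(768L, 768L),
                   min_spacing_um = 12, mitotic_fraction = 0,
                   seed = seed, ...)
}

noiseless <- function(cfg) {
  cfg$noise_sd <- 0
  cfg$shot_noise <- FALSE
  cfg
}

# hand-built Gaussian dot image, independent of the package renderer
gauss_dot_img <- function(h, w, dots, amp = 100, sigma_px = 1.5, bg = 0) {
  img <- matrix(bg, h, w)
  for (k in seq_len(nrow(dots))) {
    gy <- exp(-(seq_len(h) - dots[k, 1])^2 / (2 * sigma_px^2))
    gx <- exp(-(seq_len(w) - dots[k, 2])^2 / (2 * sigma_px^2))
    img <- img + amp * outer(gy, gx)
  }
  img
}

# truncated-normal (at 0) upper-tail probability by numerical integration
truncnorm_tail <- function(thr, mean, sd) {
  f <- function(x) dnorm(x, mean, sd)
  upper <- integrate(f, thr, mean + 12 * sd)$value
  total <- integrate(f, 0, mean + 12 * sd)$value
  upper / total
}

# all-pairs AUC by exhaustive counting (ties weight 1/2)
auc_brute <- function(scores, case) {
  cs <- scores[case]; ct <- scores[!case]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# mutual-nearest-neighbour pairs by independent double loop
mutual_nn_brute <- function(P, G, radius) {
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_len(nrow(P))) {
    d_i <- sqrt((G[, 1] - P[i, 1])^2 + (G[, 2] - P[i, 2])^2)
    j <- which.min(d_i)
    d_j <- sqrt((P[, 1] - G[j, 1])^2 + (P[, 2] - G[j, 2])^2)
    if (which.min(d_j) == i && d_i[j] <= radius) pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

# match each detected structure/cell to the nearest ground-truth cell
match_truth <- function(cells, truth) {
  idx <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tf <- which(truth$field == cells$field[i])
    j <- tf[which.min((truth$nucleus_y_um[tf] - cells$y_um[i])^2 +
                        (truth$nucleus_x_um[tf] - cells$x_um[i])^2)]
    idx[i] <- j
  }
  idx
}

# random per-cell score table for scoring-stage property tests
random_cells <- function(n, seed) {
  withr::with_seed(seed, {
    nd <- sample(0:3, n, replace = TRUE, prob = c(0.1, 0.3, 0.55, 0.05))
    tibble::tibble(
      cell_id = seq_len(n),
      diameter_um = runif(n, 6, 13),
      mitotic = runif(n) < 0.05,
      border = runif(n) < 0.05,
      n_structures = nd,
      distance_um = ifelse(nd == 2, abs(rnorm(n, 1.2, 0.3)), NA_real_),
      distance_top2_um = ifelse(nd >= 2, abs(rnorm(n, 1.2, 0.3)), NA_real_)
    )
  })
}

# three-lane-per-gel blot fixture with hand-checkable numbers
blot_fixture <- function() {
  tibble::tribble(
    ~sample_id, ~gel_id, ~condition, ~replicate, ~lrrk2, ~ps935, ~rab10, ~pt73_rab10, ~tubulin,
    "S001", "g1", "basal", 1L, 100, 50, 200, 20, 400,
    "P1",   "g1", "basal", 1L, 150, 60, 180, 36, 360,
    "P2",   "g1", "basal", 1L,  80, 20, 240, 12, 480,
    "S001", "g2", "basal", 1L, 220, 110, 420, 42, 840,
    "P3",   "g2", "basal", 1L, 110,  44, 200, 50, 500,
    "P4",   "g2", "basal", 1L, 330, 176, 600, 30, 600
  )
}
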