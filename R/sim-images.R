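#' Draw centrosomal pair distances (normal truncated at zero)
#'
#' Negative draws are resampled, so the result is the pre-truncation normal
#' conditioned on being non-negative.
#'
#' @param n Number of draws.
#' @param mean_um,sd_um Pre-truncation mean and sd (um).
#' @return Numeric vector of distances (um).
#' @export
rpair_distance <- function(n, mean_um, sd_um) {
  if (sd_um == 0) return(rep(max(mean_um, 0), n))
  d <- rnorm(n, mean_um, sd_um)
  bad <- which(d < 0)
  while (length(bad) > 0) {
    d[bad] <- rnorm(length(bad), mean_um, sd_um)
    bad <- bad[d[bad] < 0]
  }
  d
}

# dart-throwing placement with a minimum centre-to-centre spacing; returns a
# list of n_field matrices of (y_um, x_um) centres
place_cells <- function(n_cells, cfg) {
  h_um <- (cfg$field_shape_px[1] - 1) * cfg$pixel_size_um
  w_um <- (cfg$field_shape_px[2] - 1) * cfg$pixel_size_um
  active <- names(cfg$cell_class_mix)[cfg$cell_class_mix > 0]
  dmax <- max(vapply(cfg$nuclear_diameter_um[active],
                     function(p) p[1] + 3 * p[2], numeric(1)), 0)
  margin <- dmax / 2 + 1
  if (h_um <= 2 * margin || w_um <= 2 * margin) {
    abort("field too small for the nuclear diameter distribution.",
          class = "ccs_config_error")
  }
  fields <- list()
  remaining <- n_cells
  while (remaining > 0) {
    pts <- matrix(numeric(0), ncol = 2)
    consec_fail <- 0
    while (remaining - nrow(pts) > 0 && consec_fail < 60) {
      cand <- c(runif(1, margin, h_um - margin), runif(1, margin, w_um - margin))
      ok <- nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= cfg$min_spacing_um
      if (ok) {
        pts <- rbind(pts, cand)
        consec_fail <- 0
      } else consec_fail <- consec_fail + 1
    }
    if (nrow(pts) == 0) {
      abort("could not place any cell; lower `min_spacing_um` or enlarge the field.",
            class = "ccs_config_error")
    }
    fields[[length(fields) + 1]] <- pts
    remaining <- remaining - nrow(pts)
  }
  if (length(fields) == 0) fields <- list(matrix(numeric(0), ncol = 2))
  fields
}

#' Sample the ground-truth cell population without rendering images
#'
#' Places cells over as many fields as needed, samples nuclear morphology,
#' mitotic status, dot counts and true pair distances, and attaches the true
#' split label (`distance_um > split_threshold_um`; `NA` for one-dot cells).
#' [simulate_image_set()] renders exactly this population, so tests of
#' distributional properties can skip the (costly) rendering.
#'
#' @param config An [image_sim_config()].
#' @return A list with `cells` (one row per cell) and `decoys` (dual-marker
#'   single-channel decoy dots; empty unless `dual_marker`).
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "ccs_image_sim_config"))
  withr::with_seed(config$seed, sample_population(config))
}

sample_population <- function(cfg) {
  fields <- place_cells(cfg$n_cells, cfg)
  n <- sum(vapply(fields, nrow, integer(1)))
  if (n == 0) {
    cells <- tibble(field = integer(), cell_id = integer(), class = character(),
                    mitotic = logical(), nucleus_y_um = numeric(),
                    nucleus_x_um = numeric(), diameter_um = numeric(),
                    axis_ratio = numeric(), theta = numeric(),
                    dapi_level = numeric(), n_dots = integer(),
                    dot1_y_um = numeric(), dot1_x_um = numeric(),
                    dot2_y_um = numeric(), dot2_x_um = numeric(),
                    distance_um = numeric(), split = logical())
    return(list(cells = cells, decoys = empty_decoys()))
  }
  field_id <- rep(seq_along(fields), vapply(fields, nrow, integer(1)))
  centres <- do.call(rbind, fields)
  cls <- sample(names(cfg$cell_class_mix), n, replace = TRUE,
                prob = cfg$cell_class_mix)
  diam <- vapply(cls, function(k) {
    p <- cfg$nuclear_diameter_um[[k]]
    max(rnorm(1, p[1], p[2]), p[1] / 2)
  }, numeric(1))
  mitotic <- runif(n) < cfg$mitotic_fraction
  dapi <- 120 * runif(n, 0.85, 1.15)
  q <- runif(n, 0.85, 1)
  # mitotic cells: condensed (smaller, brighter) chromatin blobs
  diam[mitotic] <- diam[mitotic] * 0.55
  dapi[mitotic] <- dapi[mitotic] * 4
  q[mitotic] <- runif(sum(mitotic), 0.7, 0.85)
  theta <- runif(n, 0, pi)

  n_dots <- ifelse(mitotic, 2L, ifelse(runif(n) < cfg$two_dot_fraction, 2L, 1L))
  dist_um <- rpair_distance(n, cfg$distance_mean_um, cfg$distance_sd_um)
  dist_um[mitotic] <- 0.8 * diam[mitotic]  # spindle-pole separation
  dist_um[n_dots == 1L] <- NA_real_

  # pair midpoint jittered around the nucleus centre, orientation uniform
  r_off <- (diam / 2) * 0.25 * sqrt(runif(n))
  a_off <- runif(n, 0, 2 * pi)
  mid_y <- centres[, 1] + r_off * sin(a_off)
  mid_x <- centres[, 2] + r_off * cos(a_off)
  phi <- runif(n, 0, 2 * pi)
  half <- ifelse(is.na(dist_um), 0, dist_um / 2)
  d1y <- mid_y + half * sin(phi); d1x <- mid_x + half * cos(phi)
  d2y <- mid_y - half * sin(phi); d2x <- mid_x - half * cos(phi)
  d2y[n_dots == 1L] <- NA_real_; d2x[n_dots == 1L] <- NA_real_

  cells <- tibble(
    field = field_id, cell_id = seq_len(n), class = cls, mitotic = mitotic,
    nucleus_y_um = centres[, 1], nucleus_x_um = centres[, 2],
    diameter_um = diam, axis_ratio = q, theta = theta, dapi_level = dapi,
    n_dots = n_dots,
    dot1_y_um = d1y, dot1_x_um = d1x, dot2_y_um = d2y, dot2_x_um = d2x,
    distance_um = dist_um,
    split = dist_um > cfg$split_threshold_um
  )

  decoys <- empty_decoys()
  if (cfg$dual_marker && cfg$decoy_rate > 0 && n > 0) {
    per <- lapply(c("PCNT", "GTUB"), function(ch) {
      k <- rpois(n, cfg$decoy_rate)
      idx <- rep(seq_len(n), k)
      if (length(idx) == 0) return(NULL)
      r <- (diam[idx] / 2) * sqrt(runif(length(idx)))
      a <- runif(length(idx), 0, 2 * pi)
      tibble(field = field_id[idx], cell_id = idx, channel = ch,
             y_um = centres[idx, 1] + r * sin(a),
             x_um = centres[idx, 2] + r * cos(a))
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (length(per) > 0) decoys <- bind_rows(per)
  }
  list(cells = cells, decoys = decoys)
}

empty_decoys <- function() {
  tibble(field = integer(), cell_id = integer(), channel = character(),
         y_um = numeric(), x_um = numeric())
}

# --- rendering -------------------------------------------------------------

add_gaussian_dot <- function(img, y_px, x_px, amp, sigma_px) {
  r <- ceiling(4 * sigma_px)
  rows <- max(1, floor(y_px) - r):min(nrow(img), ceiling(y_px) + r)
  cols <- max(1, floor(x_px) - r):min(ncol(img), ceiling(x_px) + r)
  gy <- exp(-(rows - y_px)^2 / (2 * sigma_px^2))
  gx <- exp(-(cols - x_px)^2 / (2 * sigma_px^2))
  img[rows, cols] <- img[rows, cols] + amp * outer(gy, gx)
  img
}

add_ellipse <- function(img, y_px, x_px, a_px, b_px, theta, level) {
  r <- ceiling(max(a_px, b_px)) + 1
  rows <- max(1, floor(y_px) - r):min(nrow(img), ceiling(y_px) + r)
  cols <- max(1, floor(x_px) - r):min(ncol(img), ceiling(x_px) + r)
  dy <- outer(rows - y_px, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - x_px)
  u <- (dx * cos(theta) + dy * sin(theta)) / a_px
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_px
  # soft 1-px edge so segmentation sees a realistic intensity fall-off
  m <- pmin(pmax(1.5 * (1 - sqrt(u^2 + v^2)) * max(a_px, b_px) / 1.5, 0), 1)
  img[rows, cols] <- img[rows, cols] + level * m
  img
}

render_signal <- function(cells, decoys, cfg) {
  h <- cfg$field_shape_px[1]; w <- cfg$field_shape_px[2]
  ps <- cfg$pixel_size_um
  dapi <- matrix(0, h, w); pcnt <- matrix(0, h, w)
  gtub <- if (cfg$dual_marker) matrix(0, h, w) else NULL
  sig_px <- cfg$psf_sigma_um / ps
  if (nrow(cells) > 0) {
    for (i in seq_len(nrow(cells))) {
      ce <- cells[i, ]
      r_eq <- ce$diameter_um / 2 / ps       # equivalent radius in px
      a <- r_eq / sqrt(ce$axis_ratio); b <- r_eq * sqrt(ce$axis_ratio)
      dapi <- add_ellipse(dapi, um_to_px(ce$nucleus_y_um, ps),
                          um_to_px(ce$nucleus_x_um, ps), a, b, ce$theta,
                          ce$dapi_level)
      amp <- cfg$dot_intensity * runif(1, 0.8, 1.2)
      pcnt <- add_gaussian_dot(pcnt, um_to_px(ce$dot1_y_um, ps),
                               um_to_px(ce$dot1_x_um, ps), amp, sig_px)
      if (!is.null(gtub)) {
        gtub <- add_gaussian_dot(gtub, um_to_px(ce$dot1_y_um, ps),
                                 um_to_px(ce$dot1_x_um, ps),
                                 cfg$dot_intensity * runif(1, 0.8, 1.2), sig_px)
      }
      if (ce$n_dots == 2L) {
        pcnt <- add_gaussian_dot(pcnt, um_to_px(ce$dot2_y_um, ps),
                                 um_to_px(ce$dot2_x_um, ps),
                                 cfg$dot_intensity * runif(1, 0.8, 1.2), sig_px)
        if (!is.null(gtub)) {
          gtub <- add_gaussian_dot(gtub, um_to_px(ce$dot2_y_um, ps),
                                   um_to_px(ce$dot2_x_um, ps),
                                   cfg$dot_intensity * runif(1, 0.8, 1.2), sig_px)
        }
      }
    }
  }
  if (nrow(decoys) > 0) {
    for (i in seq_len(nrow(decoys))) {
      de <- decoys[i, ]
      amp <- cfg$dot_intensity * runif(1, 0.8, 1.2)
      if (de$channel == "PCNT") {
        pcnt <- add_gaussian_dot(pcnt, um_to_px(de$y_um, ps),
                                 um_to_px(de$x_um, ps), amp, sig_px)
      } else if (!is.null(gtub)) {
        gtub <- add_gaussian_dot(gtub, um_to_px(de$y_um, ps),
                                 um_to_px(de$x_um, ps), amp, sig_px)
      }
    }
  }
  chans <- list(DAPI = dapi, PCNT = pcnt)
  if (!is.null(gtub)) chans$GTUB <- gtub
  chans
}

# signal-dependent camera noise: Gaussian approximation to Poisson shot noise
# plus Gaussian read noise, clipped at zero
add_noise <- function(x, cfg) {
  if (!cfg$shot_noise && cfg$noise_sd == 0) return(x)
  s <- if (cfg$shot_noise) sqrt(pmax(x, 0) + cfg$noise_sd^2) else cfg$noise_sd
  pmax(x + rnorm(length(x), 0, 1) * s, 0)
}

stack_channel <- function(sig2d, cfg) {
  h <- nrow(sig2d); w <- ncol(sig2d)
  mid <- ceiling(cfg$n_z / 2)
  arr <- array(0, dim = c(h, w, cfg$n_z))
  for (k in seq_len(cfg$n_z)) {
    wk <- if (k == mid) 1 else 0.6
    plane <- cfg$background_level + wk * sig2d
    arr[, , k] <- add_noise(plane, cfg)
  }
  arr
}

new_image_stack <- function(channels, pixel_size_um, z_step_um, source = NA_character_) {
  shp <- dim(channels[[1]])
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, source = source, dim = shp),
            class = "ccs_image_stack")
}

#' @export
print.ccs_image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image stack> %d x %d px, %d z-plane(s), channels: %s, %.3f um/px\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", "),
              x$pixel_size_um))
  invisible(x)
}

#' Render a synthetic image set with ground truth
#'
#' Generates the ground-truth population of [simulate_ground_truth()] and
#' renders every field as a multi-channel z-stack: DAPI nuclei as soft-edged
#' ellipses (condensed bright blobs for mitotic cells), centrosomal dots as
#' isotropic Gaussians of sigma `psf_sigma_um`, identical scene over a thin
#' z-range with reduced off-focus intensity, and signal-dependent camera
#' noise. In dual-marker mode a gamma-tubulin channel carries dots co-located
#' with the pericentrin dots plus decoy single-marker dots, so colocalization
#' gating can be exercised.
#'
#' @param config An [image_sim_config()].
#' @return A list of class `ccs_image_set` with `fields` (list of
#'   `ccs_image_stack`), `truth` and `decoys` tibbles, and the `config`.
#' @export
#' @examples
#' set <- simulate_image_set(image_sim_config(n_cells = 4, seed = 7))
#' set$fields[[1]]
#' dplyr::glimpse(set$truth)
simulate_image_set <- function(config) {
  stopifnot(inherits(config, "ccs_image_sim_config"))
  withr::with_seed(config$seed, {
    pop <- sample_population(config)
    nf <- max(1L, if (nrow(pop$cells)) max(pop$cells$field) else 1L)
    fields <- lapply(seq_len(nf), function(f) {
      sig <- render_signal(pop$cells[pop$cells$field == f, ],
                           pop$decoys[pop$decoys$field == f, ], config)
      chans <- lapply(sig, stack_channel, cfg = config)
      new_image_stack(chans, config$pixel_size_um, config$z_step_um,
                      source = sprintf("synthetic_field_%03d", f))
    })
    structure(list(fields = fields, truth = pop$cells, decoys = pop$decoys,
                   config = config),
              class = "ccs_image_set")
  })
}

#' Simulate and analyze a large image set field by field
#'
#' Generates the same population (and, for a given config, the bit-identical
#' pixel data) as [simulate_image_set()], but renders, analyzes and discards
#' one field at a time, so arbitrarily large populations run in constant
#' memory. Use this for validation runs of thousands of cells; use
#' [simulate_image_set()] when the pixel data themselves are wanted.
#'
#' @param config An [image_sim_config()].
#' @param mode Scoring mode passed to [analyze_stack()].
#' @param ... Further arguments passed to [analyze_stack()].
#' @return A list with `cells` (per-cell imaging results across all fields,
#'   as from [analyze_image_set()]) and `truth` (the generator ground
#'   truth).
#' @export
simulate_and_analyze <- function(config,
                                 mode = c("single_marker_cc",
                                          "dual_marker_duplicated"),
                                 ...) {
  stopifnot(inherits(config, "ccs_image_sim_config"))
  mode <- match.arg(mode)
  withr::with_seed(config$seed, {
    pop <- sample_population(config)
    nf <- max(1L, if (nrow(pop$cells)) max(pop$cells$field) else 1L)
    out <- vector("list", nf)
    for (f in seq_len(nf)) {
      sig <- render_signal(pop$cells[pop$cells$field == f, ],
                           pop$decoys[pop$decoys$field == f, ], config)
      chans <- lapply(sig, stack_channel, cfg = config)
      stk <- new_image_stack(chans, config$pixel_size_um, config$z_step_um,
                             source = sprintf("synthetic_field_%03d", f))
      cells <- analyze_stack(stk, mode = mode, ...)
      cells$field <- f
      out[[f]] <- cells
    }
    cells <- bind_rows(out)
    if (nrow(cells) > 0) cells$cell_id <- paste0("f", cells$field, "_c", cells$cell_id)
    list(cells = cells[, c("field", setdiff(names(cells), "field"))],
         truth = pop$cells)
  })
}
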