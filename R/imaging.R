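#' Maximum-intensity projection of a z-stack
#'
#' Collapses each channel over z by taking, at every pixel, the maximum
#' across planes (the projection the assay is scored on).
#'
#' @param stack A `ccs_image_stack`, or a single `y * x * z` array.
#' @return For a stack, a named list of 2D matrices (one per channel) with a
#'   `pixel_size_um` attribute; for an array, a single matrix.
#' @export
max_project <- function(stack) {
  proj1 <- function(a) {
    stopifnot(length(dim(a)) == 3, dim(a)[3] >= 1)
    p <- a[, , 1]
    for (k in seq_len(dim(a)[3])[-1]) p <- pmax(p, a[, , k])
    p
  }
  if (inherits(stack, "ccs_image_stack")) {
    out <- lapply(stack$channels, proj1)
    attr(out, "pixel_size_um") <- stack$pixel_size_um
    out
  } else {
    proj1(stack)
  }
}

#' Segment nuclei in a DAPI projection
#'
#' Gaussian smoothing, Otsu thresholding, hole filling and a small opening,
#' then connected-component labelling. Per region the equivalent diameter
#' (diameter of the circle with the region's area, in um), centroid,
#' border-touching flag, mean DAPI intensity and a mitotic flag are
#' computed. A region is flagged mitotic when its mean DAPI intensity
#' exceeds `mitotic_k` times the field's median nucleus intensity:
#' condensed mitotic chromatin is several-fold brighter per pixel than any
#' interphase nucleus, while interphase staining varies only modestly
#' around the median.
#'
#' @param img 2D DAPI projection (matrix, rows = y).
#' @param pixel_size_um Physical pixel size (um).
#' @param params Optional list: `blur_sigma_px` (default 2),
#'   `min_diameter_um` (default 3), `mitotic_k` (2.5).
#' @return A tibble (one row per nucleus: `label`, `y_um`, `x_um`,
#'   `equivalent_diameter_um`, `touches_border`, `mitotic`, `mean_dapi`,
#'   `fill_factor`) carrying the integer label image as attribute
#'   `label_image`. A blank image yields an empty tibble.
#' @export
segment_nuclei <- function(img, pixel_size_um, params = list()) {
  p <- utils::modifyList(list(blur_sigma_px = 2, min_diameter_um = 3,
                              mitotic_k = 2.5), params)
  empty <- tibble(label = integer(), y_um = numeric(), x_um = numeric(),
                  equivalent_diameter_um = numeric(), touches_border = logical(),
                  mitotic = logical(), mean_dapi = numeric(),
                  fill_factor = numeric())
  attr(empty, "label_image") <- matrix(0L, nrow(img), ncol(img))
  rng <- range(img)
  if (diff(rng) <= 0) return(empty)
  sm <- gauss_blur(img, p$blur_sigma_px)
  nm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- EBImage::otsu(EBImage::Image(nm), range = c(0, 1))
  # on a background-only field Otsu bisects the noise; require the threshold
  # to clear the background level by a real margin before segmenting
  thr_raw <- min(sm) + thr * (max(sm) - min(sm))
  if (thr_raw < median(sm) + 5 * mad(sm)) return(empty)
  mask <- EBImage::opening(EBImage::fillHull(nm > thr),
                           EBImage::makeBrush(3, "diamond"))
  lab <- EBImage::bwlabel(mask)
  labm <- EBImage::imageData(lab)
  if (max(labm) == 0) return(empty)

  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  area_um2 <- shp[, "s.area"] * pixel_size_um^2
  eq_diam <- 2 * sqrt(area_um2 / pi)
  keep <- which(eq_diam >= p$min_diameter_um)
  if (length(keep) == 0) return(empty)
  drop <- setdiff(seq_len(nrow(mom)), keep)
  if (length(drop) > 0) labm[labm %in% drop] <- 0L

  border_labels <- unique(c(labm[1, ], labm[nrow(labm), ],
                            labm[, 1], labm[, ncol(labm)]))
  fg <- labm > 0
  mean_int <- tapply(img[fg], labm[fg], mean)
  minor <- mom[, "m.majoraxis"] * sqrt(1 - mom[, "m.eccentricity"]^2)
  fill <- shp[, "s.area"] / (pi * (mom[, "m.majoraxis"] / 2) * (minor / 2))

  out <- tibble(
    label = keep,
    # EBImage m.cx runs along the first array dimension (our y)
    y_um = px_to_um(mom[keep, "m.cx"], pixel_size_um),
    x_um = px_to_um(mom[keep, "m.cy"], pixel_size_um),
    equivalent_diameter_um = eq_diam[keep],
    touches_border = keep %in% border_labels,
    mean_dapi = as.numeric(mean_int[as.character(keep)]),
    fill_factor = fill[keep]
  )
  # condensed mitotic chromatin is several-fold brighter per pixel than any
  # interphase nucleus; the field's median *nucleus* intensity is the robust
  # reference (the median pixel is background and flags everything)
  out$mitotic <- out$mean_dapi > p$mitotic_k * median(out$mean_dapi)
  out <- out[, c("label", "y_um", "x_um", "equivalent_diameter_um",
                 "touches_border", "mitotic", "mean_dapi", "fill_factor")]
  attr(out, "label_image") <- labm
  out
}

#' Detect diffraction-limited spots in a 2D image
#'
#' Band-pass (difference-of-Gaussians at the expected dot sigma) filtering
#' followed by local-maximum extraction with an absolute-plus-relative
#' threshold, and per-axis parabolic subpixel refinement of each peak.
#'
#' @param img 2D projection (matrix, rows = y).
#' @param pixel_size_um Physical pixel size (um).
#' @param params Optional list: `sigma_um` expected dot sigma (default 0.15),
#'   `k_mad` noise multiplier for the absolute response threshold (8),
#'   `rel_floor` fraction of the maximum response below which peaks are
#'   rejected (0.1).
#' @return A tibble of spots sorted by decreasing quality: `spot_id`,
#'   `y_um`, `x_um`, `peak_intensity`, `quality` (band-pass response).
#' @export
detect_spots <- function(img, pixel_size_um, params = list()) {
  p <- utils::modifyList(list(sigma_um = 0.15, k_mad = 8, rel_floor = 0.1),
                         params)
  empty <- tibble(spot_id = integer(), y_um = numeric(), x_um = numeric(),
                  peak_intensity = numeric(), quality = numeric())
  if (diff(range(img)) <= 0) return(empty)
  s_px <- p$sigma_um / pixel_size_um
  r <- gauss_blur(img, s_px) - gauss_blur(img, 1.6 * s_px)
  h <- nrow(r); w <- ncol(r)
  # noise level from a pixel subsample (the response is stationary off-spot)
  noise <- mad(r[seq(1, length(r), by = 7)])
  thr <- max(p$k_mad * noise, p$rel_floor * max(r))
  cand <- which(r > thr & r > 0)
  cand <- cand[{
    ci <- arrayInd(cand, dim(r))
    ci[, 1] > 1 & ci[, 1] < h & ci[, 2] > 1 & ci[, 2] < w
  }]
  if (length(cand) == 0) return(empty)
  # strict on the up/left side, non-strict on the down/right side, so a
  # two-pixel plateau yields exactly one peak
  c0 <- r[cand]
  is_max <- c0 > r[cand - 1L] & c0 >= r[cand + 1L] &
    c0 > r[cand - h] & c0 >= r[cand + h] &
    c0 > r[cand - h - 1L] & c0 >= r[cand + h + 1L] &
    c0 > r[cand + h - 1L] & c0 >= r[cand - h + 1L]
  cand <- cand[is_max]
  if (length(cand) == 0) return(empty)
  ci <- arrayInd(cand, dim(r))
  py <- ci[, 1]; px <- ci[, 2]

  paraboff <- function(m0, c0, p0) {
    den <- m0 + p0 - 2 * c0
    off <- ifelse(abs(den) < .Machine$double.eps, 0, (m0 - p0) / (2 * den))
    pmin(pmax(off, -0.5), 0.5)
  }
  dy <- paraboff(r[cbind(py - 1, px)], r[cbind(py, px)], r[cbind(py + 1, px)])
  dx <- paraboff(r[cbind(py, px - 1)], r[cbind(py, px)], r[cbind(py, px + 1)])
  out <- tibble(
    y_um = px_to_um(py + dy, pixel_size_um),
    x_um = px_to_um(px + dx, pixel_size_um),
    peak_intensity = img[cbind(py, px)],
    quality = r[cbind(py, px)]
  )
  out <- arrange(out, desc(.data$quality))
  out$spot_id <- seq_len(nrow(out))
  out[, c("spot_id", "y_um", "x_um", "peak_intensity", "quality")]
}

#' Pair two-marker spots into centrosomal structures
#'
#' In dual-marker mode, pericentrin and gamma-tubulin spots from the same
#' field are paired by mutual nearest neighbour within `radius_um`; each
#' mutual pair becomes a dual-positive structure at the midpoint of the two
#' spot centroids, and unpaired spots of either channel become structures
#' with `dual_positive = FALSE` (excluded from duplicated-centrosome
#' scoring). In single-marker mode (`spots_gtub = NULL`) every pericentrin
#' spot is a structure.
#'
#' @param spots_pcnt,spots_gtub Spot tibbles from [detect_spots()];
#'   `spots_gtub = NULL` selects single-marker mode.
#' @param radius_um Maximum pairing distance (um).
#' @return A tibble of structures: `structure_id`, `y_um`, `x_um`,
#'   `dual_positive` (`NA` in single-marker mode), `pcnt_id`, `gtub_id`,
#'   `quality`.
#' @export
pair_markers <- function(spots_pcnt, spots_gtub = NULL, radius_um = 0.5) {
  stopifnot(radius_um > 0)
  if (is.null(spots_gtub)) {
    n <- nrow(spots_pcnt)
    return(tibble(structure_id = seq_len(n),
                  y_um = spots_pcnt$y_um, x_um = spots_pcnt$x_um,
                  dual_positive = NA, pcnt_id = spots_pcnt$spot_id,
                  gtub_id = NA_integer_, quality = spots_pcnt$quality))
  }
  np <- nrow(spots_pcnt); ng <- nrow(spots_gtub)
  pair_p <- rep(NA_integer_, np)
  if (np > 0 && ng > 0) {
    d <- outer(spots_pcnt$y_um, spots_gtub$y_um, "-")^2 +
      outer(spots_pcnt$x_um, spots_gtub$x_um, "-")^2
    nn_p <- max.col(-d, ties.method = "first")          # nearest GTUB per PCNT
    nn_g <- apply(d, 2, which.min)                      # nearest PCNT per GTUB
    for (i in seq_len(np)) {
      j <- nn_p[i]
      if (nn_g[j] == i && sqrt(d[i, j]) <= radius_um) pair_p[i] <- j
    }
  }
  rows <- list()
  for (i in seq_len(np)) {
    j <- pair_p[i]
    if (!is.na(j)) {
      rows[[length(rows) + 1]] <- tibble(
        y_um = (spots_pcnt$y_um[i] + spots_gtub$y_um[j]) / 2,
        x_um = (spots_pcnt$x_um[i] + spots_gtub$x_um[j]) / 2,
        dual_positive = TRUE, pcnt_id = spots_pcnt$spot_id[i],
        gtub_id = spots_gtub$spot_id[j],
        quality = (spots_pcnt$quality[i] + spots_gtub$quality[j]) / 2)
    } else {
      rows[[length(rows) + 1]] <- tibble(
        y_um = spots_pcnt$y_um[i], x_um = spots_pcnt$x_um[i],
        dual_positive = FALSE, pcnt_id = spots_pcnt$spot_id[i],
        gtub_id = NA_integer_, quality = spots_pcnt$quality[i])
    }
  }
  unpaired_g <- setdiff(seq_len(ng), pair_p[!is.na(pair_p)])
  for (j in unpaired_g) {
    rows[[length(rows) + 1]] <- tibble(
      y_um = spots_gtub$y_um[j], x_um = spots_gtub$x_um[j],
      dual_positive = FALSE, pcnt_id = NA_integer_,
      gtub_id = spots_gtub$spot_id[j], quality = spots_gtub$quality[j])
  }
  if (length(rows) == 0) {
    return(tibble(structure_id = integer(), y_um = numeric(), x_um = numeric(),
                  dual_positive = logical(), pcnt_id = integer(),
                  gtub_id = integer(), quality = numeric()))
  }
  out <- bind_rows(rows)
  out$structure_id <- seq_len(nrow(out))
  out[, c("structure_id", "y_um", "x_um", "dual_positive", "pcnt_id",
          "gtub_id", "quality")]
}

#' Assign centrosomal structures to nuclei
#'
#' Each structure is assigned to the nucleus whose boundary is nearest
#' (distance 0 when the structure lies inside a nuclear region), provided
#' the boundary distance does not exceed `max_dist_um`; farther structures
#' are dropped and counted in the `n_dropped` attribute. Exact-distance ties
#' go to the lower nucleus label.
#'
#' @param nuclei Tibble from [segment_nuclei()] (must carry the
#'   `label_image` attribute).
#' @param structures Tibble from [pair_markers()].
#' @param pixel_size_um Physical pixel size (um).
#' @param max_dist_um Maximum boundary-to-structure assignment distance.
#' @return `structures` with added columns `nucleus_label`,
#'   `dist_to_nucleus_um` and `tie`; dropped structures removed. Attribute
#'   `n_dropped` counts them.
#' @export
assemble_cells <- function(nuclei, structures, pixel_size_um, max_dist_um = 5) {
  labm <- attr(nuclei, "label_image")
  if (is.null(labm)) {
    abort("`nuclei` must carry a `label_image` attribute (from segment_nuclei()).",
          class = "ccs_input_error")
  }
  ns <- nrow(structures)
  out <- structures
  out$nucleus_label <- NA_integer_
  out$dist_to_nucleus_um <- NA_real_
  out$tie <- FALSE
  if (ns == 0 || nrow(nuclei) == 0) {
    res <- out[0, ]
    attr(res, "n_dropped") <- ns
    return(res)
  }
  fg <- which(labm %in% nuclei$label)
  idx <- arrayInd(fg, dim(labm))
  fy <- px_to_um(idx[, 1], pixel_size_um)
  fx <- px_to_um(idx[, 2], pixel_size_um)
  flab <- labm[fg]
  for (i in seq_len(ns)) {
    d2 <- (fy - structures$y_um[i])^2 + (fx - structures$x_um[i])^2
    m <- min(d2)
    cand <- unique(flab[d2 <= m + 1e-12])
    out$nucleus_label[i] <- min(cand)
    out$dist_to_nucleus_um[i] <- sqrt(m)
    out$tie[i] <- length(cand) > 1
    if (out$tie[i]) {
      message(sprintf("structure %d equidistant to nuclei %s; assigned to %d",
                      structures$structure_id[i],
                      paste(sort(cand), collapse = ", "), min(cand)))
    }
  }
  # a structure inside its nucleus has boundary distance 0 by construction
  inside <- labm[cbind(pmin(pmax(round(um_to_px(structures$y_um, pixel_size_um)), 1), nrow(labm)),
                       pmin(pmax(round(um_to_px(structures$x_um, pixel_size_um)), 1), ncol(labm)))]
  out$dist_to_nucleus_um[inside > 0 & inside == out$nucleus_label] <- 0
  kept <- out$dist_to_nucleus_um <= max_dist_um
  res <- out[kept, ]
  attr(res, "n_dropped") <- sum(!kept)
  res
}

#' Run the imaging stage on one stack
#'
#' Maximum projection, nucleus segmentation on DAPI, spot detection on the
#' marker channel(s), marker pairing (dual-marker if the stack has a GTUB
#' channel and `mode` requests it), and structure-to-nucleus assignment,
#' summarized to one row per segmented cell.
#'
#' @param stack A `ccs_image_stack`.
#' @param mode `"single_marker_cc"` (pericentrin only) or
#'   `"dual_marker_duplicated"` (only dual-positive structures are scorable).
#' @param detect_params,segment_params Passed to [detect_spots()] /
#'   [segment_nuclei()].
#' @param pairing_radius_um Mutual-nearest-neighbour pairing radius (um).
#' @param max_assign_um Maximum structure-to-nucleus distance (um).
#' @return A tibble, one row per nucleus: `cell_id`, `y_um`, `x_um`,
#'   `diameter_um`, `mitotic`, `border`, `n_structures` (scorable under
#'   `mode`), `distance_um` (between the two structure centroids when
#'   exactly two), `distance_top2_um` (between the two brightest when two or
#'   more).
#' @export
analyze_stack <- function(stack, mode = c("single_marker_cc", "dual_marker_duplicated"),
                          detect_params = list(), segment_params = list(),
                          pairing_radius_um = 0.5, max_assign_um = 5) {
  mode <- match.arg(mode)
  ps <- stack$pixel_size_um
  proj <- max_project(stack)
  nuclei <- segment_nuclei(proj$DAPI, ps, segment_params)
  sp_p <- detect_spots(proj$PCNT, ps, detect_params)
  sp_g <- if (mode == "dual_marker_duplicated") {
    if (is.null(proj$GTUB)) {
      abort("dual-marker scoring requested but the stack has no GTUB channel.",
            class = "ccs_input_error")
    }
    detect_spots(proj$GTUB, ps, detect_params)
  } else NULL
  st <- pair_markers(sp_p, sp_g, radius_um = pairing_radius_um)
  asg <- assemble_cells(nuclei, st, ps, max_dist_um = max_assign_um)
  scorable <- if (mode == "dual_marker_duplicated") {
    asg[which(asg$dual_positive), ]
  } else asg
  per_cell <- function(lbl) {
    s <- scorable[scorable$nucleus_label == lbl, ]
    n <- nrow(s)
    d <- NA_real_
    if (n == 2) d <- sqrt(diff(s$y_um)^2 + diff(s$x_um)^2)
    d2 <- NA_real_
    if (n >= 2) {
      top <- s[order(-s$quality)[1:2], ]
      d2 <- sqrt(diff(top$y_um)^2 + diff(top$x_um)^2)
    }
    c(n = n, d = d, d2 = d2)
  }
  stats <- vapply(nuclei$label, per_cell, numeric(3))
  tibble(
    cell_id = nuclei$label,
    y_um = nuclei$y_um, x_um = nuclei$x_um,
    diameter_um = nuclei$equivalent_diameter_um,
    mitotic = nuclei$mitotic, border = nuclei$touches_border,
    n_structures = as.integer(stats["n", ]),
    distance_um = stats["d", ],
    distance_top2_um = stats["d2", ]
  )
}

#' Run the imaging stage on a whole (synthetic or loaded) image set
#'
#' @param set A `ccs_image_set`, or a list of `ccs_image_stack` objects.
#' @inheritParams analyze_stack
#' @param ... Passed to [analyze_stack()].
#' @return Row-bound per-cell tibble with a `field` column; `cell_id` is
#'   unique across fields.
#' @export
analyze_image_set <- function(set, mode = c("single_marker_cc", "dual_marker_duplicated"),
                              ...) {
  mode <- match.arg(mode)
  fields <- if (inherits(set, "ccs_image_set")) set$fields else set
  out <- purrr::imap(fields, function(stk, f) {
    cells <- analyze_stack(stk, mode = mode, ...)
    cells$field <- f
    cells
  })
  out <- bind_rows(out)
  if (nrow(out) > 0) {
    out$cell_id <- paste0("f", out$field, "_c", out$cell_id)
  }
  out[, c("field", setdiff(names(out), "field"))]
}
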