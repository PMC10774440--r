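#' Scoring configuration for the C/C cohesion assay
#'
#' @param mode `"single_marker_cc"`: every pericentrin dot is a scorable
#'   structure (centrosome/centriole splitting). `"dual_marker_duplicated"`:
#'   only structures positive for both pericentrin and gamma-tubulin count
#'   (duplicated centrosomes).
#' @param split_threshold_um A cell with two scorable structures is split
#'   when their distance strictly exceeds this threshold (default 1.3 um).
#' @param deficit_threshold_pct A sample has a cohesion deficit when its
#'   percent splitting is at or above this value (default 20, inclusive).
#' @param min_cells Below this number of included cells a sample is flagged
#'   `low_n` (default 100).
#' @param target_cells Band of cells per sample the assay aims for
#'   (annotation only; default 150-200).
#' @param pbmc_mode PBMC scoring: lymphocytes are gated by nuclear
#'   equivalent diameter strictly below `max_nuclear_diameter_um`; larger
#'   (monocyte-like) nuclei are excluded.
#' @param max_nuclear_diameter_um Lymphocyte gate (default 10 um).
#' @param histogram_bin_um Bin width of the per-sample distance histogram.
#' @param ambiguous_policy Cells with more than two scorable structures are
#'   excluded (`"exclude"`, default) or scored on the two brightest
#'   (`"two_brightest"`).
#' @return A list of class `ccs_scoring_config`.
#' @export
scoring_config <- function(mode = c("single_marker_cc", "dual_marker_duplicated"),
                           split_threshold_um = 1.3,
                           deficit_threshold_pct = 20,
                           min_cells = 100,
                           target_cells = c(150, 200),
                           pbmc_mode = FALSE,
                           max_nuclear_diameter_um = 10,
                           histogram_bin_um = 0.2,
                           ambiguous_policy = c("exclude", "two_brightest")) {
  mode <- match.arg(mode)
  ambiguous_policy <- match.arg(ambiguous_policy)
  if (split_threshold_um <= 0 || histogram_bin_um <= 0 ||
      max_nuclear_diameter_um <= 0) {
    abort("thresholds must be > 0.", class = "ccs_config_error")
  }
  if (deficit_threshold_pct <= 0 || deficit_threshold_pct >= 100) {
    abort("`deficit_threshold_pct` must lie in (0, 100).", class = "ccs_config_error")
  }
  structure(list(mode = mode, split_threshold_um = split_threshold_um,
                 deficit_threshold_pct = deficit_threshold_pct,
                 min_cells = min_cells, target_cells = target_cells,
                 pbmc_mode = isTRUE(pbmc_mode),
                 max_nuclear_diameter_um = max_nuclear_diameter_um,
                 histogram_bin_um = histogram_bin_um,
                 ambiguous_policy = ambiguous_policy),
            class = "ccs_scoring_config")
}

#' Use generator ground truth as the per-cell input of the scoring stage
#'
#' The scoring stage shares one per-cell schema between the imaging pipeline
#' and the synthetic ground truth; this helper renames/pads the truth table
#' accordingly (true dot counts and true distances, no border-touching
#' cells).
#'
#' @param truth The `truth` tibble of a `ccs_image_set` or
#'   [simulate_ground_truth()].
#' @return A per-cell tibble accepted by [score_cells()].
#' @export
truth_as_cells <- function(truth) {
  tibble(cell_id = truth$cell_id,
         diameter_um = truth$diameter_um,
         mitotic = truth$mitotic, border = FALSE,
         n_structures = truth$n_dots,
         distance_um = truth$distance_um,
         distance_top2_um = truth$distance_um)
}

#' Score cells: per-cell split classification with exclusion reasons
#'
#' Applies the assay's per-cell rules: mitotic and border-touching cells are
#' excluded, PBMC mode additionally excludes nuclei at or above the
#' lymphocyte diameter gate, cells without scorable structures are excluded
#' (`no_staining`), and cells with more than two structures are excluded as
#' `ambiguous_count` (or scored on the two brightest, per
#' `ambiguous_policy`). A cell with exactly two scorable structures is split
#' when their centroid distance strictly exceeds `split_threshold_um`.
#'
#' @param cells Per-cell tibble from [analyze_image_set()] /
#'   [analyze_stack()] or [truth_as_cells()]: columns `cell_id`,
#'   `n_structures`, `distance_um`, and optionally `mitotic`, `border`,
#'   `diameter_um`, `distance_top2_um`.
#' @param config A [scoring_config()].
#' @return The input with columns `included`, `exclusion_reason`
#'   (`mitotic`, `border`, `too_large_nucleus`, `no_staining`,
#'   `ambiguous_count` or `none`), `score_distance_um` and `split` appended.
#' @export
score_cells <- function(cells, config = scoring_config()) {
  stopifnot(inherits(config, "ccs_scoring_config"))
  cells <- as_tibble(cells)
  n <- nrow(cells)
  mitotic <- if ("mitotic" %in% names(cells)) cells$mitotic else rep(FALSE, n)
  border <- if ("border" %in% names(cells)) cells$border else rep(FALSE, n)
  diam <- if ("diameter_um" %in% names(cells)) cells$diameter_um else rep(NA_real_, n)

  reason <- rep("none", n)
  reason[cells$n_structures == 0L] <- "no_staining"
  if (config$ambiguous_policy == "exclude") {
    reason[cells$n_structures > 2L] <- "ambiguous_count"
  }
  if (config$pbmc_mode) {
    too_big <- !is.na(diam) & diam >= config$max_nuclear_diameter_um
    reason[too_big] <- "too_large_nucleus"
  }
  reason[border] <- "border"
  reason[mitotic] <- "mitotic"

  d <- cells$distance_um
  if (config$ambiguous_policy == "two_brightest" &&
      "distance_top2_um" %in% names(cells)) {
    many <- cells$n_structures > 2L
    d[many] <- cells$distance_top2_um[many]
  }
  included <- reason == "none"
  two <- included & (cells$n_structures == 2L |
                       (config$ambiguous_policy == "two_brightest" &
                          cells$n_structures > 2L))
  split <- rep(NA, n)
  split[two] <- d[two] > config$split_threshold_um

  out <- cells
  out$included <- included
  out$exclusion_reason <- reason
  out$score_distance_um <- ifelse(two, d, NA_real_)
  out$split <- split
  out
}

#' Aggregate cell scores into a sample score
#'
#' `pct_split` is the percentage of two-structure cells that are split (the
#' distance is only defined when two structures exist); `pct_two_dot` is the
#' percentage of included cells carrying two structures. The distance
#' histogram and mean are computed over two-structure cells.
#'
#' @param cell_scores Output of [score_cells()].
#' @param config A [scoring_config()].
#' @param sample_id,condition Identifiers attached to the output row.
#' @return One-row tibble: `sample_id`, `condition`, `n_included`,
#'   `n_two_dot`, `pct_split`, `pct_two_dot`, `mean_distance_um`, `deficit`,
#'   `low_n`, plus list-columns `hist_breaks`/`hist_counts`.
#' @export
score_sample <- function(cell_scores, config = scoring_config(),
                         sample_id = NA_character_, condition = "vehicle") {
  stopifnot(inherits(config, "ccs_scoring_config"))
  inc <- cell_scores[cell_scores$included, ]
  if (nrow(inc) == 0) {
    abort("no included cells in this sample.", class = "ccs_empty_sample_error")
  }
  two <- inc[!is.na(inc$split), ]
  n_two <- nrow(two)
  pct_split <- if (n_two > 0) 100 * sum(two$split) / n_two else NA_real_
  pct_two <- 100 * n_two / nrow(inc)
  dists <- two$score_distance_um
  if (n_two > 0) {
    bw <- config$histogram_bin_um
    breaks <- seq(0, (floor(max(dists) / bw) + 1) * bw, by = bw)
    counts <- as.integer(table(cut(dists, breaks, right = TRUE,
                                   include.lowest = TRUE)))
  } else {
    breaks <- numeric(0); counts <- integer(0)
  }
  out <- tibble(
    sample_id = sample_id, condition = condition,
    n_included = nrow(inc), n_two_dot = n_two,
    pct_split = pct_split, pct_two_dot = pct_two,
    mean_distance_um = if (n_two > 0) mean(dists) else NA_real_,
    hist_breaks = list(breaks), hist_counts = list(counts),
    low_n = nrow(inc) < config$min_cells
  )
  out$deficit <- call_deficit(out, config)
  if (out$low_n) {
    warn(sprintf("sample '%s': only %d included cells (assay targets %d-%d).",
                 sample_id, nrow(inc), config$target_cells[1],
                 config$target_cells[2]))
  }
  out
}

#' Call a cohesion deficit on a sample score
#'
#' A sample has a cohesion deficit when its percent splitting is at or
#' above the deficit threshold (inclusive; default 20%).
#'
#' @param sample One-row sample-score tibble (needs `pct_split`).
#' @param config A [scoring_config()].
#' @return Logical flag.
#' @export
call_deficit <- function(sample, config = scoring_config()) {
  !is.na(sample$pct_split) & sample$pct_split >= config$deficit_threshold_pct
}

#' Inhibitor-reversal delta for one sample
#'
#' @param vehicle,treated One-row sample scores for the same sample under
#'   vehicle and under MLi2.
#' @return One-row tibble: `sample_id`, `pct_split_vehicle`,
#'   `pct_split_mli2`, `delta` (vehicle minus treated), `reverted` (deficit
#'   in vehicle and none after treatment).
#' @export
mli2_reversal <- function(vehicle, treated) {
  if (!identical(vehicle$sample_id, treated$sample_id)) {
    abort(sprintf("sample ids differ: '%s' vs '%s'.",
                  vehicle$sample_id, treated$sample_id),
          class = "ccs_pairing_error")
  }
  tibble(
    sample_id = vehicle$sample_id,
    pct_split_vehicle = vehicle$pct_split,
    pct_split_mli2 = treated$pct_split,
    delta = vehicle$pct_split - treated$pct_split,
    reverted = isTRUE(vehicle$deficit) && !isTRUE(treated$deficit)
  )
}
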