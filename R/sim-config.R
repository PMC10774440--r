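#' Configuration for the synthetic image generator
#'
#' Builds and validates the parameter set used by [simulate_ground_truth()]
#' and [simulate_image_set()]. The generator emulates fields of view of
#' DAPI/pericentrin(/gamma-tubulin)-stained blood-derived cells: round
#' interphase nuclei drawn from class-specific diameter distributions
#' (lymphocyte-like nuclei with mean diameter below 10 um, larger
#' monocyte-like nuclei), a condensed-chromatin mitotic subpopulation, and
#' per cell one or two diffraction-limited centrosomal dots whose pair
#' distance follows a normal distribution truncated at zero.
#'
#' @param pixel_size_um Physical size of one pixel (um). Default 0.1.
#' @param field_shape_px Integer vector `c(height, width)` of one field.
#' @param n_cells Total number of cells to generate; cells are distributed
#'   over as many fields as the spacing constraint requires.
#' @param two_dot_fraction Probability that a (non-mitotic) cell carries two
#'   centrosomal dots rather than one.
#' @param distance_mean_um,distance_sd_um Mean and sd of the pre-truncation
#'   normal pair-distance distribution (um); negative draws are resampled.
#' @param split_threshold_um Threshold used to attach the ground-truth split
#'   label (distance strictly greater than the threshold).
#' @param mitotic_fraction Probability that a cell is mitotic. Mitotic cells
#'   are rendered as condensed, bright DAPI blobs and carry two widely
#'   separated dots (spindle poles); downstream scoring must exclude them.
#' @param cell_class_mix Named proportions for `lymphocyte` and `monocyte`
#'   nuclei; must sum to 1.
#' @param nuclear_diameter_um Named list giving `c(mean, sd)` of the nuclear
#'   equivalent-diameter distribution (um) per class.
#' @param dual_marker If `TRUE` a gamma-tubulin channel is emitted with dots
#'   co-located with the pericentrin dots, plus decoy single-marker dots.
#' @param decoy_rate Expected number of decoy single-marker dots per cell and
#'   per channel in dual-marker mode (Poisson).
#' @param psf_sigma_um Gaussian PSF sigma used to render dots (um).
#' @param dot_intensity,background_level,noise_sd Rendering parameters in
#'   arbitrary camera counts: dot peak amplitude, constant background, and
#'   Gaussian read-noise sd. Shot noise scales with the signal.
#' @param shot_noise Include signal-dependent (Poisson-like) noise.
#' @param n_z,z_step_um Number of z-planes and step (um); the generator is
#'   z-collapsed (the same 2D scene replicated with reduced off-focus
#'   intensity) because the assay analyses maximum projections.
#' @param min_spacing_um Minimum centre-to-centre nucleus spacing; default
#'   twice the largest plausible nuclear diameter of the active classes, so
#'   nuclei never overlap.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A validated list of class `ccs_image_sim_config`.
#' @export
image_sim_config <- function(pixel_size_um = 0.1,
                             field_shape_px = c(512L, 512L),
                             n_cells = 200,
                             two_dot_fraction = 0.6,
                             distance_mean_um = 1.2,
                             distance_sd_um = 0.15,
                             split_threshold_um = 1.3,
                             mitotic_fraction = 0.04,
                             cell_class_mix = c(lymphocyte = 1, monocyte = 0),
                             nuclear_diameter_um = list(lymphocyte = c(8, 0.8),
                                                        monocyte = c(12, 1.2)),
                             dual_marker = FALSE,
                             decoy_rate = 0.1,
                             psf_sigma_um = 0.15,
                             dot_intensity = 400,
                             background_level = 20,
                             noise_sd = 2,
                             shot_noise = TRUE,
                             n_z = 3L,
                             z_step_um = 0.5,
                             min_spacing_um = NULL,
                             seed = 1L) {
  cfg <- list(
    pixel_size_um = pixel_size_um, field_shape_px = as.integer(field_shape_px),
    n_cells = as.integer(n_cells), two_dot_fraction = two_dot_fraction,
    distance_mean_um = distance_mean_um, distance_sd_um = distance_sd_um,
    split_threshold_um = split_threshold_um,
    mitotic_fraction = mitotic_fraction,
    cell_class_mix = cell_class_mix, nuclear_diameter_um = nuclear_diameter_um,
    dual_marker = isTRUE(dual_marker), decoy_rate = decoy_rate,
    psf_sigma_um = psf_sigma_um, dot_intensity = dot_intensity,
    background_level = background_level, noise_sd = noise_sd,
    shot_noise = isTRUE(shot_noise),
    n_z = as.integer(n_z), z_step_um = z_step_um,
    min_spacing_um = min_spacing_um, seed = as.integer(seed)
  )
  validate_image_sim_config(cfg)
}

validate_image_sim_config <- function(cfg) {
  if (cfg$pixel_size_um <= 0) {
    abort("`pixel_size_um` must be > 0.", class = "ccs_config_error")
  }
  if (length(cfg$field_shape_px) != 2L || any(cfg$field_shape_px <= 0)) {
    abort("`field_shape_px` must be two positive integers (height, width).",
          class = "ccs_config_error")
  }
  if (cfg$n_cells < 0) abort("`n_cells` must be >= 0.", class = "ccs_config_error")
  probs <- c(two_dot_fraction = cfg$two_dot_fraction,
             mitotic_fraction = cfg$mitotic_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("`two_dot_fraction` and `mitotic_fraction` must lie in [0, 1].",
          class = "ccs_config_error")
  }
  mix <- cfg$cell_class_mix
  if (is.null(names(mix)) || !all(names(mix) %in% c("lymphocyte", "monocyte")) ||
      any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort("`cell_class_mix` must be non-negative proportions named 'lymphocyte'/'monocyte' summing to 1.",
          class = "ccs_config_error")
  }
  if (cfg$distance_sd_um < 0) {
    abort("`distance_sd_um` must be >= 0.", class = "ccs_config_error")
  }
  if (cfg$psf_sigma_um <= 0 || cfg$dot_intensity <= 0) {
    abort("`psf_sigma_um` and `dot_intensity` must be > 0.", class = "ccs_config_error")
  }
  if (cfg$n_z < 1L) abort("`n_z` must be >= 1.", class = "ccs_config_error")
  if (is.null(cfg$min_spacing_um)) {
    active <- names(mix)[mix > 0]
    dmax <- max(vapply(cfg$nuclear_diameter_um[active],
                       function(p) p[1] + 3 * p[2], numeric(1)))
    cfg$min_spacing_um <- 2 * dmax
  }
  structure(cfg, class = "ccs_image_sim_config")
}

#' Configuration for the synthetic cohort generator
#'
#' Describes per-group distributions of per-subject percent C/C splitting
#' under vehicle and under the LRRK2 kinase inhibitor MLi2, used by
#' [simulate_cohort_scores()]. Defaults mirror the study design of the
#' assay's LCL cohort: 10 controls, 12 R1441G-PD, 9 R1441G-NMC, 7 G2019S-PD,
#' 6 G2019S-NMC and 4 idiopathic-PD subjects, with splitting elevated in
#' mutation carriers and restored to the control range by MLi2.
#'
#' @param groups A data frame with columns `group`, `n_subjects`,
#'   `split_mean_pct`, `split_sd_pct`, `mli2_split_mean_pct`,
#'   `mli2_split_sd_pct`. Percent draws are truncated to \[0, 100\].
#' @param cells_per_sample Number of cells scored per sample; simulated
#'   percentages are binomially resampled at this count so sampling error
#'   matches an n-cell assay. Use `Inf` to disable resampling.
#' @param seed Integer seed.
#'
#' @return A validated list of class `ccs_cohort_sim_config`.
#' @export
cohort_sim_config <- function(groups = default_cohort_groups(),
                              cells_per_sample = 175,
                              seed = 1L) {
  groups <- as_tibble(groups)
  needed <- c("group", "n_subjects", "split_mean_pct", "split_sd_pct",
              "mli2_split_mean_pct", "mli2_split_sd_pct")
  if (!all(needed %in% names(groups))) {
    abort(paste("`groups` must contain columns:", paste(needed, collapse = ", ")),
          class = "ccs_config_error")
  }
  if (any(groups$n_subjects < 0)) {
    abort("`n_subjects` must be >= 0 for every group.", class = "ccs_config_error")
  }
  if (any(groups$split_sd_pct < 0) || any(groups$mli2_split_sd_pct < 0)) {
    abort("splitting sds must be >= 0.", class = "ccs_config_error")
  }
  if (!(is.infinite(cells_per_sample) || cells_per_sample >= 1)) {
    abort("`cells_per_sample` must be >= 1 (or Inf).", class = "ccs_config_error")
  }
  structure(list(groups = groups, cells_per_sample = cells_per_sample,
                 seed = as.integer(seed)),
            class = "ccs_cohort_sim_config")
}

#' @rdname cohort_sim_config
#' @export
default_cohort_groups <- function() {
  tibble(
    group = c("control", "R1441G_PD", "R1441G_NMC",
              "G2019S_PD", "G2019S_NMC", "iPD"),
    n_subjects = c(10L, 12L, 9L, 7L, 6L, 4L),
    split_mean_pct = c(10, 35, 22, 35, 20, 28),
    split_sd_pct = c(3, 6, 6, 6, 6, 10),
    mli2_split_mean_pct = c(8, 10, 10, 10, 10, 12),
    mli2_split_sd_pct = c(3, 4, 4, 4, 4, 5)
  )
}
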