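#' Normalize multiplexed Western-blot lanes against an internal standard
#'
#' Within-lane ratios (LRRK2/tubulin, pS935/tubulin, pS935/LRRK2,
#' Rab10/tubulin, pT73-Rab10/tubulin, pT73-Rab10/Rab10) are computed first;
#' cross-gel comparable values are then each within-lane ratio divided by
#' the same ratio in that gel's internal-standard lane (the same control
#' sample run on every gel), so the standard lane's standard-relative
#' values are 1 by construction and per-gel imaging gain cancels.
#'
#' @param lanes Tibble with columns `sample_id`, `gel_id`, `condition`,
#'   `replicate` (optional), and band intensities `lrrk2`, `ps935`, `rab10`,
#'   `pt73_rab10`, `tubulin` (arbitrary densitometry units; a `ps106_rab12`
#'   column is carried through untouched if present).
#' @param standard_sample_id Sample id of the internal-standard lane; every
#'   gel must contain it.
#' @param average_replicates Average replicate lanes of the same sample and
#'   condition after normalization (default `TRUE`).
#' @return Tibble of normalized lanes: within-lane ratio columns
#'   (`lrrk2_tubulin`, `ps935_tubulin`, `ps935_lrrk2`, `rab10_tubulin`,
#'   `pt73_tubulin`, `pt73_rab10`) and their standard-relative versions
#'   (suffix `_rel`).
#' @export
normalize_lanes <- function(lanes, standard_sample_id,
                            average_replicates = TRUE) {
  lanes <- as_tibble(lanes)
  needed <- c("sample_id", "gel_id", "condition",
              "lrrk2", "ps935", "rab10", "pt73_rab10", "tubulin")
  miss <- setdiff(needed, names(lanes))
  if (length(miss) > 0) {
    abort(paste("`lanes` is missing columns:", paste(miss, collapse = ", ")),
          class = "ccs_input_error")
  }
  bands <- c("lrrk2", "ps935", "rab10", "pt73_rab10", "tubulin")
  if (any(as.matrix(lanes[bands]) < 0, na.rm = TRUE)) {
    abort("band intensities must be >= 0.", class = "ccs_input_error")
  }
  gels_without_std <- setdiff(unique(lanes$gel_id),
                              unique(lanes$gel_id[lanes$sample_id == standard_sample_id]))
  if (length(gels_without_std) > 0) {
    abort(sprintf("gel(s) lacking the internal-standard lane '%s': %s",
                  standard_sample_id, paste(gels_without_std, collapse = ", ")),
          class = "ccs_normalization_error")
  }
  # lanes with a zero denominator band cannot be ratioed: flag and drop
  bad <- lanes$tubulin <= 0 | lanes$lrrk2 <= 0 | lanes$rab10 <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d lane(s) with zero denominator bands: %s",
                 sum(bad),
                 paste(unique(lanes$sample_id[bad]), collapse = ", ")))
    lanes <- lanes[!bad, ]
  }
  ratios <- mutate(lanes,
    lrrk2_tubulin = .data$lrrk2 / .data$tubulin,
    ps935_tubulin = .data$ps935 / .data$tubulin,
    ps935_lrrk2 = .data$ps935 / .data$lrrk2,
    rab10_tubulin = .data$rab10 / .data$tubulin,
    pt73_tubulin = .data$pt73_rab10 / .data$tubulin,
    pt73_rab10 = .data$pt73_rab10 / .data$rab10
  )
  rat_cols <- c("lrrk2_tubulin", "ps935_tubulin", "ps935_lrrk2",
                "rab10_tubulin", "pt73_tubulin", "pt73_rab10")
  std <- ratios |>
    filter(.data$sample_id == standard_sample_id) |>
    group_by(.data$gel_id) |>
    summarise(across(all_of(rat_cols), mean, .names = "std_{.col}"),
              .groups = "drop")
  out <- left_join(ratios, std, by = "gel_id")
  for (rc in rat_cols) {
    out[[paste0(rc, "_rel")]] <- out[[rc]] / out[[paste0("std_", rc)]]
  }
  out <- select(out, -dplyr::starts_with("std_"))
  if (average_replicates) {
    keep_cols <- c(rat_cols, paste0(rat_cols, "_rel"))
    out <- out |>
      group_by(.data$sample_id, .data$condition) |>
      summarise(n_lanes = dplyr::n(),
                across(all_of(keep_cols), mean), .groups = "drop")
  }
  out
}

#' LLOMe-triggered percent increase in pT73-Rab10/Rab10
#'
#' For each sample with basal, LLOMe and LLOMe+MLi2 lanes, the percent
#' increase is 100 * (ratio\[LLOMe\] - ratio\[basal\]) / ratio\[basal\],
#' with the analogous value under MLi2. Samples whose LLOMe increase is at
#' or below zero are flagged non-responders. Within-gel (not
#' standard-relative) pT73-Rab10/Rab10 is used since the ratio is
#' internally controlled.
#'
#' @param norm Normalized lanes from [normalize_lanes()], containing
#'   conditions `basal`, `LLOMe` and `LLOMe_MLi2` for each sample.
#' @return Tibble: `sample_id`, `basal`, `llome`, `llome_mli2`,
#'   `pct_increase`, `pct_increase_mli2`, `non_responder`.
#' @export
llome_response <- function(norm) {
  wide <- norm |>
    select("sample_id", "condition", "pt73_rab10") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "pt73_rab10")
  miss <- setdiff(c("basal", "LLOMe", "LLOMe_MLi2"), names(wide))
  if (length(miss) > 0) {
    abort(paste("missing condition(s):", paste(miss, collapse = ", ")),
          class = "ccs_input_error")
  }
  incomplete <- wide$sample_id[!stats::complete.cases(wide[c("basal", "LLOMe", "LLOMe_MLi2")])]
  if (length(incomplete) > 0) {
    abort(paste("sample(s) lacking a condition:", paste(incomplete, collapse = ", ")),
          class = "ccs_input_error")
  }
  if (any(wide$basal == 0)) {
    abort("basal pT73-Rab10/Rab10 ratio of 0: percent increase undefined.",
          class = "ccs_undefined_response_error")
  }
  tibble(
    sample_id = wide$sample_id,
    basal = wide$basal, llome = wide$LLOMe, llome_mli2 = wide$LLOMe_MLi2,
    pct_increase = 100 * (wide$LLOMe - wide$basal) / wide$basal,
    pct_increase_mli2 = 100 * (wide$LLOMe_MLi2 - wide$basal) / wide$basal,
    non_responder = 100 * (wide$LLOMe - wide$basal) / wide$basal <= 0
  )
}
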