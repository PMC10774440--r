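#' Simulate a cohort table of per-subject percent C/C splitting
#'
#' Draws one vehicle and one MLi2 (LRRK2-inhibitor) percent-splitting value
#' per subject from the group's stated normal distributions truncated to
#' \[0, 100\], then binomially resamples each value at `cells_per_sample`
#' cells so that per-sample sampling error matches an n-cell assay.
#'
#' @param config A [cohort_sim_config()].
#' @return A tibble with one row per subject x condition: `subject_id`,
#'   `group`, `condition` (`"vehicle"` or `"MLi2"`), `n_cells`, `pct_split`.
#' @export
#' @examples
#' cohort <- simulate_cohort_scores(cohort_sim_config(seed = 42))
#' dplyr::count(cohort, group, condition)
simulate_cohort_scores <- function(config) {
  stopifnot(inherits(config, "ccs_cohort_sim_config"))
  withr::with_seed(config$seed, {
    g <- config$groups
    g <- g[g$n_subjects > 0, , drop = FALSE]
    rows <- purrr::pmap(g, function(group, n_subjects, split_mean_pct,
                                    split_sd_pct, mli2_split_mean_pct,
                                    mli2_split_sd_pct, ...) {
      ids <- sprintf("%s_%02d", group, seq_len(n_subjects))
      veh <- rtrunc_pct(n_subjects, split_mean_pct, split_sd_pct)
      trt <- rtrunc_pct(n_subjects, mli2_split_mean_pct, mli2_split_sd_pct)
      tibble(subject_id = rep(ids, 2L), group = group,
             condition = rep(c("vehicle", "MLi2"), each = n_subjects),
             true_pct = c(veh, trt))
    })
    out <- bind_rows(rows)
    m <- config$cells_per_sample
    if (is.finite(m)) {
      out$pct_split <- 100 * rbinom(nrow(out), size = m, prob = out$true_pct / 100) / m
      out$n_cells <- as.integer(m)
    } else {
      out$pct_split <- out$true_pct
      out$n_cells <- NA_integer_
    }
    out$true_pct <- NULL
    out[, c("subject_id", "group", "condition", "n_cells", "pct_split")]
  })
}

rtrunc_pct <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(max(mean, 0), 100), n))
  x <- rnorm(n, mean, sd)
  bad <- which(x < 0 | x > 100)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < 0 | x[bad] > 100]
  }
  x
}
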