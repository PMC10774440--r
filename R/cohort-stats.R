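#' Compare percent splitting across subject groups
#'
#' Per-group descriptives (n, mean, sd, sem) and Shapiro-Wilk normality p,
#' then one-way ANOVA on the score with Tukey HSD post-hoc comparisons for
#' every group pair. Normality failures do not switch the test (the assay
#' reports parametric results); a warning is emitted instead.
#'
#' @param data Subject-level data frame (e.g. from
#'   [simulate_cohort_scores()], typically filtered to one condition).
#' @param score,group Column names (tidy-eval) of the score and grouping
#'   variable; defaults `pct_split` and `group`.
#' @param alpha Significance level used only for the normality warning.
#' @return Object of class `ccs_group_comparison` with `tidy()` (Tukey
#'   pairs), `glance()` (ANOVA) and `autoplot()` methods.
#' @export
#' @examples
#' cohort <- simulate_cohort_scores(cohort_sim_config(seed = 1))
#' cmp <- compare_groups(dplyr::filter(cohort, condition == "vehicle"))
#' generics::glance(cmp)
#' head(generics::tidy(cmp))
compare_groups <- function(data, score = pct_split, group = group,
                           alpha = 0.05) {
  score <- enquo(score); group <- enquo(group)
  df <- tibble(score = dplyr::pull(data, !!score),
               group = as.character(dplyr::pull(data, !!group)))
  df <- df[is.finite(df$score), ]
  sizes <- table(df$group)
  if (length(sizes) < 2) {
    abort("need at least two groups.", class = "ccs_insufficient_data_error")
  }
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    abort(paste("group(s) with fewer than 3 subjects:",
                paste(small, collapse = ", ")),
          class = "ccs_insufficient_data_error")
  }
  desc <- df |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), mean = mean(.data$score), sd = sd(.data$score),
              sem = sd(.data$score) / sqrt(dplyr::n()),
              shapiro_p = tryCatch(shapiro.test(.data$score)$p.value,
                                   error = function(e) NA_real_),
              .groups = "drop")
  if (any(!is.na(desc$shapiro_p) & desc$shapiro_p < alpha)) {
    warn(paste("Shapiro-Wilk indicates non-normality in group(s):",
               paste(desc$group[!is.na(desc$shapiro_p) &
                                  desc$shapiro_p < alpha], collapse = ", "),
               "- parametric results reported anyway."))
  }
  fit <- aov(score ~ group, data = df)
  atab <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  tukey <- tibble(
    contrast = rownames(tk),
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), adj_p = unname(tk[, "p adj"])
  )
  structure(list(
    groups = desc,
    anova = tibble(term = "group", df = atab$Df[1], df_resid = atab$Df[2],
                   statistic = atab$`F value`[1], p_value = atab$`Pr(>F)`[1]),
    tukey = tukey,
    data = df
  ), class = "ccs_group_comparison")
}

#' @export
print.ccs_group_comparison <- function(x, ...) {
  cat("One-way ANOVA of", nrow(x$data), "subjects in",
      nrow(x$groups), "groups\n")
  print(x$groups)
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g\n", x$anova$df, x$anova$df_resid,
              x$anova$statistic, x$anova$p_value))
  cat("Tukey HSD pairs:\n")
  print(x$tukey)
  invisible(x)
}

#' Paired comparison of two conditions (classical paired t-test)
#'
#' Computes per-subject deltas (condition A minus condition B) for subjects
#' having both conditions, drops (and counts) incomplete subjects, and
#' evaluates the paired t statistic with n - 1 degrees of freedom. A
#' constant zero delta vector yields t = 0, p = 1.
#'
#' @param data Subject-level data frame with one row per subject x
#'   condition.
#' @param condition_a,condition_b Condition labels to compare (A - B).
#' @param score,id,condition Tidy-eval column names (defaults `pct_split`,
#'   `subject_id`, `condition`).
#' @return Object of class `ccs_paired_test` with `tidy()`/`glance()`.
#' @export
paired_condition_test <- function(data, condition_a = "vehicle",
                                  condition_b = "MLi2",
                                  score = pct_split, id = subject_id,
                                  condition = condition) {
  score <- enquo(score); id <- enquo(id); condition <- enquo(condition)
  df <- tibble(id = dplyr::pull(data, !!id),
               condition = as.character(dplyr::pull(data, !!condition)),
               score = dplyr::pull(data, !!score))
  df <- df[df$condition %in% c(condition_a, condition_b), ]
  wide <- tidyr::pivot_wider(df, names_from = "condition",
                             values_from = "score")
  for (cc in c(condition_a, condition_b)) {
    if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  }
  complete <- is.finite(wide[[condition_a]]) & is.finite(wide[[condition_b]])
  n_dropped <- sum(!complete)
  wide <- wide[complete, ]
  n <- nrow(wide)
  if (n < 2) {
    abort("fewer than 2 complete pairs.", class = "ccs_insufficient_data_error")
  }
  delta <- wide[[condition_a]] - wide[[condition_b]]
  m <- mean(delta); s <- sd(delta)
  t_stat <- if (s == 0) {
    if (m == 0) 0 else sign(m) * Inf
  } else m / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  structure(list(
    n = n, n_dropped = n_dropped, mean_delta = m, sd_delta = s,
    statistic = t_stat, df = n - 1, p_value = p,
    condition_a = condition_a, condition_b = condition_b, deltas = delta
  ), class = "ccs_paired_test")
}

#' @export
print.ccs_paired_test <- function(x, ...) {
  cat(sprintf("Paired t-test (%s - %s): n = %d, mean delta = %.3f, t(%d) = %.3f, p = %.4g\n",
              x$condition_a, x$condition_b, x$n, x$mean_delta, x$df,
              x$statistic, x$p_value))
  if (x$n_dropped > 0) cat(x$n_dropped, "subject(s) lacking a condition dropped\n")
  invisible(x)
}

#' Spearman correlation between two columns
#'
#' Rank correlation (average ranks for ties) with a two-sided asymptotic
#' p-value, as used to associate protein levels with splitting values.
#'
#' @param data A data frame.
#' @param x,y Tidy-eval column names.
#' @return Object of class `ccs_correlation` with `tidy()`/`glance()`.
#' @export
correlate_scores <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }}); yv <- dplyr::pull(data, {{ y }})
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) {
    abort("need at least 3 complete pairs.", class = "ccs_insufficient_data_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("correlation undefined for a constant input.",
          class = "ccs_undefined_correlation_error")
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  structure(list(method = "spearman", rho = unname(ct$estimate),
                 p_value = ct$p.value, n = length(xv), x = xv, y = yv),
            class = "ccs_correlation")
}

#' @export
print.ccs_correlation <- function(x, ...) {
  cat(sprintf("Spearman correlation: rho = %.3f, p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' ROC c-statistic (area under the curve) via all-pairs counting
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, with ties counted one half (the Mann-Whitney convention),
#' computed from average ranks.
#'
#' @param data A data frame.
#' @param score Tidy-eval column of the (higher-is-more-case-like) score.
#' @param label Tidy-eval column of class labels.
#' @param positive Label value treated as "case"; defaults to the
#'   lexicographically larger of the two labels.
#' @return Object of class `ccs_roc`: `auc`, `n_cases`, `n_controls`,
#'   `n_ties` (cross-class tied pairs), with `tidy()`/`glance()`/
#'   `autoplot()`.
#' @export
roc_cstat <- function(data, score, label, positive = NULL) {
  sv <- dplyr::pull(data, {{ score }})
  lv <- dplyr::pull(data, {{ label }})
  ok <- is.finite(sv) & !is.na(lv)
  sv <- sv[ok]; lv <- as.character(lv[ok])
  classes <- sort(unique(lv))
  if (length(classes) != 2) {
    abort("`label` must contain exactly two classes.",
          class = "ccs_insufficient_data_error")
  }
  positive <- positive %||% classes[2]
  if (!positive %in% classes) {
    abort(sprintf("positive label '%s' not present.", positive),
          class = "ccs_input_error")
  }
  case <- lv == positive
  n1 <- sum(case); n0 <- sum(!case)
  r <- rank(sv)  # average ranks give ties weight 1/2 in the pair count
  auc <- (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tab <- table(sv, case)
  n_ties <- if (ncol(tab) == 2) sum(tab[, 1] * tab[, 2]) else 0
  structure(list(auc = auc, n_cases = n1, n_controls = n0,
                 n_ties = as.integer(n_ties), positive = positive,
                 scores = sv, case = case),
            class = "ccs_roc")
}

#' @export
print.ccs_roc <- function(x, ...) {
  cat(sprintf("ROC c-statistic = %.4f (%d cases vs %d controls, %d tied pair(s))\n",
              x$auc, x$n_cases, x$n_controls, x$n_ties))
  invisible(x)
}

#' Cohort report: group comparison, paired inhibitor test and ROC
#'
#' Convenience wrapper running the statistics layer on a subject-score
#' table: vehicle-condition group comparison, a paired vehicle-vs-MLi2
#' test, and the ROC c-statistic for case groups against the control group.
#'
#' @param data Subject-score tibble (as from [simulate_cohort_scores()]).
#' @param case_groups Group labels treated as cases in the ROC; default all
#'   non-control groups.
#' @param control_group Label of the control group.
#' @return A list with elements `groups`, `anova`, `tukey`, `paired`, `roc`.
#' @export
cohort_report <- function(data, case_groups = NULL, control_group = "control") {
  veh <- dplyr::filter(data, .data$condition == "vehicle")
  cmp <- compare_groups(veh)
  paired <- paired_condition_test(data)
  case_groups <- case_groups %||% setdiff(unique(veh$group), control_group)
  roc_df <- veh |>
    filter(.data$group %in% c(control_group, case_groups)) |>
    mutate(status = ifelse(.data$group == control_group, "control", "case"))
  roc <- roc_cstat(roc_df, .data$pct_split, .data$status, positive = "case")
  list(groups = cmp$groups, anova = cmp$anova, tukey = cmp$tukey,
       paired = generics::glance(paired), roc = generics::glance(roc))
}
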