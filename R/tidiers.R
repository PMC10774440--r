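#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy ccs_group_comparison
#' @export
tidy.ccs_group_comparison <- function(x, ...) x$tukey

#' @method glance ccs_group_comparison
#' @export
glance.ccs_group_comparison <- function(x, ...) x$anova

#' @method tidy ccs_paired_test
#' @export
tidy.ccs_paired_test <- function(x, ...) glance.ccs_paired_test(x, ...)

#' @method glance ccs_paired_test
#' @export
glance.ccs_paired_test <- function(x, ...) {
  tibble(n = x$n, n_dropped = x$n_dropped, mean_delta = x$mean_delta,
         statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @method tidy ccs_correlation
#' @export
tidy.ccs_correlation <- function(x, ...) glance.ccs_correlation(x, ...)

#' @method glance ccs_correlation
#' @export
glance.ccs_correlation <- function(x, ...) {
  tibble(method = x$method, rho = x$rho, p_value = x$p_value, n = x$n)
}

#' @method tidy ccs_roc
#' @export
tidy.ccs_roc <- function(x, ...) {
  # one row per threshold of the empirical ROC curve
  thr <- c(Inf, sort(unique(x$scores), decreasing = TRUE))
  tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(x$scores[x$case] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(x$scores[!x$case] >= t), numeric(1))
  )
}

#' @method glance ccs_roc
#' @export
glance.ccs_roc <- function(x, ...) {
  tibble(auc = x$auc, n_cases = x$n_cases, n_controls = x$n_controls,
         n_ties = x$n_ties)
}
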