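## Summary statistics over a set of attributable fractions --------------------
##
## Two explicit quantile conventions are exposed because published summaries
## of small samples mix them: "inverse_ecdf" (the smallest sample value whose
## empirical CDF reaches q; always a sample member) and "midpoint" (for even n
## at q = 0.5, the mean of the two central order statistics; elsewhere
## identical to inverse_ecdf). The defaults — inverse_ecdf for the overall
## median/IQR and midpoint for per-category medians — are the pairing that
## reproduces the bundled dataset's published summary sentence; both are
## user-selectable everywhere.

quantile_conventions <- function() c("inverse_ecdf", "midpoint")

#' Empirical quantile under a named convention
#'
#' @param values Non-empty numeric vector.
#' @param q Probability in `[0, 1]`.
#' @param convention `"inverse_ecdf"` or `"midpoint"` (see Details).
#' @details `inverse_ecdf` returns the order statistic `x_(ceil(n*q))`
#'   (type-1 quantile), always an element of `values`. `midpoint` averages
#'   the two central order statistics for even `n` at `q = 0.5` and equals
#'   `inverse_ecdf` otherwise.
#' @return The quantile.
#' @examples
#' paf_quantile(c(9.76, 25.2, 27.1, 32.3), 0.5, "midpoint")  # 26.15
#' @export
paf_quantile <- function(values, q, convention = c("inverse_ecdf", "midpoint")) {
  convention <- match.arg(convention)
  if (length(values) == 0L || anyNA(values))
    stop_validation("quantile requires a non-empty vector without NAs")
  if (q < 0 || q > 1)
    stop_validation("q must lie in [0, 1]")
  if (convention == "midpoint" && q == 0.5)
    return(stats::median(values))
  unname(stats::quantile(values, q, type = 1, names = FALSE))
}

#' Summarise attributable fractions across diseases
#'
#' Computes the range (with disease labels), median, interquartile range and
#' per-category medians of the `paf_pct` column of a set of concordance
#' estimates.
#'
#' @param estimates A `concordance_estimate` data frame from
#'   [estimate_concordance()].
#' @param convention_overall Quantile convention for the overall median and
#'   IQR (default `"inverse_ecdf"`).
#' @param convention_category Quantile convention for per-category medians
#'   (default `"midpoint"`).
#' @return A list of class `paf_summary`: `n_diseases`, `min_paf`, `max_paf`
#'   (each with `value` and `disease`), `median_paf`, `iqr` (`lower`,
#'   `upper`), `category_medians` (named numeric), and the conventions used.
#' @examples
#' s <- summarize_pafs(estimate_concordance(mz_twin_cohorts()))
#' signif(s$median_paf, 3)  # 18.5
#' @export
summarize_pafs <- function(estimates,
                           convention_overall = "inverse_ecdf",
                           convention_category = "midpoint") {
  convention_overall <- match.arg(convention_overall, quantile_conventions())
  convention_category <- match.arg(convention_category, quantile_conventions())
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) == 0L)
    stop_validation("no estimates to summarise")
  paf <- estimates$paf_pct
  cat_medians <- vapply(split(paf, estimates$category), paf_quantile,
                        numeric(1), q = 0.5, convention = convention_category)
  out <- list(
    n_diseases = nrow(estimates),
    min_paf = list(value = min(paf),
                   disease = estimates$disease_name[which.min(paf)]),
    max_paf = list(value = max(paf),
                   disease = estimates$disease_name[which.max(paf)]),
    median_paf = paf_quantile(paf, 0.5, convention_overall),
    iqr = list(lower = paf_quantile(paf, 0.25, convention_overall),
               upper = paf_quantile(paf, 0.75, convention_overall)),
    category_medians = cat_medians,
    convention_overall = convention_overall,
    convention_category = convention_category)
  class(out) <- "paf_summary"
  out
}

#' @export
print.paf_summary <- function(x, ...) {
  s3 <- function(v) format(signif(v, 3))
  cat(sprintf(
    "Attributable fractions for %d diseases ranged from %s%% (%s) to %s%% (%s)\n",
    x$n_diseases, s3(x$min_paf$value), x$min_paf$disease,
    s3(x$max_paf$value), x$max_paf$disease))
  cat(sprintf("with a median of %s%% and interquartile range %s%% to %s%%.\n",
              s3(x$median_paf), s3(x$iqr$lower), s3(x$iqr$upper)))
  cat("Category medians (%):\n")
  for (nm in names(x$category_medians))
    cat(sprintf("  %-20s %s\n", nm, s3(x$category_medians[[nm]])))
  cat(sprintf("(quantile conventions: overall %s, category %s)\n",
              x$convention_overall, x$convention_category))
  invisible(x)
}

#' Turn a summary into a one-row-per-statistic data frame
#'
#' @param summary A `paf_summary` from [summarize_pafs()].
#' @return A data frame with columns `statistic`, `value`, `label`.
#' @export
summary_as_table <- function(summary) {
  rows <- list(
    c("n_diseases", summary$n_diseases, ""),
    c("min_paf", summary$min_paf$value, summary$min_paf$disease),
    c("max_paf", summary$max_paf$value, summary$max_paf$disease),
    c("median_paf", summary$median_paf, summary$convention_overall),
    c("iqr_lower", summary$iqr$lower, summary$convention_overall),
    c("iqr_upper", summary$iqr$upper, summary$convention_overall))
  for (nm in names(summary$category_medians))
    rows <- c(rows, list(c(paste0("median_", nm),
                           summary$category_medians[[nm]],
                           summary$convention_category)))
  data.frame(statistic = vapply(rows, `[`, "", 1L),
             value = as.numeric(vapply(rows, `[`, "", 2L)),
             label = vapply(rows, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Cumulative distribution of attributable fractions
#'
#' One point per disease, sorted by increasing PAF, with cumulative fractions
#' `1/n, 2/n, ..., 1`. Ties are kept as separate points (distinct cumulative
#' fractions), matching a plotted empirical CDF with one symbol per disease.
#'
#' @inheritParams summarize_pafs
#' @return A data frame with columns `disease_name`, `category`, `paf_pct`,
#'   `cumulative_fraction`.
#' @export
paf_cumulative <- function(estimates) {
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) == 0L)
    stop_validation("no estimates to accumulate")
  ord <- order(estimates$paf_pct, estimates$disease_name)
  out <- estimates[ord, c("disease_name", "category", "paf_pct")]
  out$cumulative_fraction <- seq_len(nrow(out)) / nrow(out)
  rownames(out) <- NULL
  out
}
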