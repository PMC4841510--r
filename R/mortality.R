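## Attributable-death linkage -------------------------------------------------
##
## Disease-specific death counts multiplied by the matching disease's PAF give
## the deaths attributable to genetics plus shared exposures; the overall
## attributable percent over a set of diseases is the death-weighted mean PAF.

#' Read a mortality table from CSV
#'
#' Schema: header `disease_name, region, year, deaths`; UTF-8,
#' comma-separated; `deaths` non-negative.
#'
#' @param path Path to the CSV file.
#' @return A data frame with the four columns, `deaths` numeric.
#' @export
read_mortality_table <- function(path) {
  if (!file.exists(path))
    stop_format("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
  missing <- setdiff(c("disease_name", "region", "year", "deaths"), names(raw))
  if (length(missing) > 0L)
    stop_format("missing column(s) in %s: %s", path,
                paste(missing, collapse = ", "))
  if (nrow(raw) == 0L)
    stop_validation("empty mortality table: %s", path)
  if (!is.numeric(raw$deaths) || anyNA(raw$deaths) || any(raw$deaths < 0))
    stop_validation("deaths must be non-negative numbers")
  raw
}

#' Bundled synthetic mortality table
#'
#' An illustrative mortality table (ischemic heart disease and nine cancers,
#' "Western Europe", 2000) with synthetic death counts, provided so that the
#' attribution pipeline can be exercised and tested without external data.
#' The counts are round illustrative numbers, not observed mortality figures.
#'
#' @return A mortality data frame as from [read_mortality_table()].
#' @export
synthetic_mortality <- function() {
  read_mortality_table(system.file("extdata", "synthetic_mortality.csv",
                                   package = "twinpaf", mustWork = TRUE))
}

#' Deaths attributable to a given attributable fraction
#'
#' @param deaths Non-negative death count(s).
#' @param paf_pct Attributable fraction(s) in percent, in `[0, 100]`.
#' @return `deaths * paf_pct / 100`, not rounded. Vectorized.
#' @examples
#' attributable_deaths(1000, 10)  # 100
#' @export
attributable_deaths <- function(deaths, paf_pct) {
  if (any(deaths < 0))
    stop_validation("deaths must be non-negative")
  if (any(paf_pct < 0) || any(paf_pct > 100))
    stop_validation("paf_pct must lie in [0, 100]")
  deaths * paf_pct / 100
}

#' Link mortality counts with disease attributable fractions
#'
#' Matches each mortality record to exactly one concordance estimate by
#' disease name (exact string match, optionally through an alias map),
#' multiplies deaths by the matched PAF, and totals the results. The overall
#' attributable percent is `100 * sum(attributable) / sum(deaths)`, i.e. the
#' death-weighted mean of the matched PAFs.
#'
#' @param estimates A `concordance_estimate` data frame.
#' @param mortality A mortality data frame (see [read_mortality_table()]).
#' @param aliases Optional named character vector mapping mortality disease
#'   names to estimate disease names, e.g.
#'   `c("Ischemic heart disease" = "Coronary heart disease death")`.
#' @return A list of class `attribution_report`: `results` (per-disease data
#'   frame with `disease_name`, `deaths`, `paf_pct`, `attributable_deaths`)
#'   and `totals` (`total_deaths`, `total_attributable`,
#'   `overall_attributable_pct`).
#' @examples
#' est <- estimate_concordance(mz_twin_cohorts())
#' rep <- link_mortality(est, synthetic_mortality(),
#'   aliases = c("Ischemic heart disease" = "Coronary heart disease death"))
#' rep$totals$overall_attributable_pct
#' @export
link_mortality <- function(estimates, mortality, aliases = NULL) {
  estimates <- as.data.frame(estimates)
  if (anyDuplicated(estimates$disease_name))
    stop_linkage("duplicate disease_name among estimates: %s",
                 paste(unique(estimates$disease_name[
                   duplicated(estimates$disease_name)]), collapse = ", "))
  if (anyDuplicated(mortality$disease_name))
    stop_linkage("duplicate disease_name among mortality records: %s",
                 paste(unique(mortality$disease_name[
                   duplicated(mortality$disease_name)]), collapse = ", "))
  target <- mortality$disease_name
  if (!is.null(aliases)) {
    hit <- target %in% names(aliases)
    target[hit] <- unname(aliases[target[hit]])
  }
  idx <- match(target, estimates$disease_name)
  if (anyNA(idx))
    stop_linkage("unmatched disease(s) in mortality table: %s",
                 paste(mortality$disease_name[is.na(idx)], collapse = ", "))
  paf <- estimates$paf_pct[idx]
  results <- data.frame(
    disease_name = mortality$disease_name,
    deaths = mortality$deaths,
    paf_pct = paf,
    attributable_deaths = attributable_deaths(mortality$deaths, paf),
    stringsAsFactors = FALSE)
  totals <- list(
    total_deaths = sum(results$deaths),
    total_attributable = sum(results$attributable_deaths),
    overall_attributable_pct =
      100 * sum(results$attributable_deaths) / sum(results$deaths))
  structure(list(results = results, totals = totals),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  df <- x$results
  df$attributable_deaths <- round(df$attributable_deaths)
  df$paf_pct <- signif(df$paf_pct, 3)
  print(df, row.names = FALSE)
  cat(sprintf("Total: %s deaths, %s attributable (%.1f%%)\n",
              format(round(x$totals$total_deaths)),
              format(round(x$totals$total_attributable)),
              x$totals$overall_attributable_pct))
  invisible(x)
}
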