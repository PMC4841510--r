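## Probandwise concordance, relative risk and PAF -----------------------------
##
## For one disease the N_T pairs imply 2*N_T individuals. Exposure is "my
## co-twin is affected": the exposed group has 2*N_C + N_D individuals of whom
## 2*N_C are affected, the unexposed group has 2*N_T - 2*N_C - N_D individuals
## of whom N_D are affected. Probandwise concordance P is the exposed risk (in
## percent), RR the ratio of exposed to unexposed risk, and the attributable
## fraction follows the case-based formula PAF = P * (RR - 1) / RR.

check_counts <- function(n_pairs_total, n_concordant, n_discordant) {
  if (any(n_pairs_total < 1) || any(n_concordant < 0) || any(n_discordant < 0))
    stop_validation("counts must satisfy n_pairs_total >= 1 and n_concordant, n_discordant >= 0")
  if (any(n_concordant + n_discordant > n_pairs_total))
    stop_validation("n_concordant + n_discordant must not exceed n_pairs_total")
}

#' Probandwise concordance (percent)
#'
#' Among all affected twin individuals, the percentage whose co-twin is also
#' affected: `P = 2 * N_C / (2 * N_C + N_D) * 100`. Each concordant pair
#' contributes two affected individuals with an affected co-twin; each
#' discordant pair contributes one affected individual whose co-twin is not.
#'
#' @param n_concordant Number of concordant pairs (both twins affected), N_C.
#' @param n_discordant Number of discordant pairs (one twin affected), N_D.
#' @return Probandwise concordance in percent, in `[0, 100]`. Vectorized.
#' @examples
#' probandwise_concordance(5, 189)   # 5.03 to 3 significant figures
#' probandwise_concordance(2, 4)     # 50: 4 of the 8 affected have affected co-twins
#' @export
probandwise_concordance <- function(n_concordant, n_discordant) {
  if (any(n_concordant < 0) || any(n_discordant < 0))
    stop_validation("counts must be non-negative")
  affected <- 2 * n_concordant + n_discordant
  if (any(affected < 1))
    stop_undefined("probandwise concordance is undefined with no affected individuals")
  2 * n_concordant / affected * 100
}

#' Relative risk of disease given an affected co-twin
#'
#' The risk ratio from the individual-level 2x2 table implied by the pair
#' counts: exposed risk `2 N_C / (2 N_C + N_D)` over unexposed risk
#' `N_D / (2 N_T - 2 N_C - N_D)`. When `N_D = 0` and `N_C > 0` the unexposed
#' risk is zero and the relative risk is reported as `Inf`.
#'
#' @param n_pairs_total Total MZ pairs, N_T.
#' @inheritParams probandwise_concordance
#' @return The relative risk (possibly `Inf`). Vectorized.
#' @examples
#' relative_risk(15668, 5, 189)  # 8.28 to 3 significant figures
#' relative_risk(10, 2, 4)       # (4/8) / (4/12) = 1.5
#' @export
relative_risk <- function(n_pairs_total, n_concordant, n_discordant) {
  check_counts(n_pairs_total, n_concordant, n_discordant)
  affected <- 2 * n_concordant + n_discordant
  if (any(affected < 1))
    stop_undefined("relative risk is undefined with no affected individuals")
  n_unexposed <- 2 * n_pairs_total - 2 * n_concordant - n_discordant
  if (any(n_unexposed == 0))
    stop_undefined("relative risk is undefined when every individual has an affected co-twin (empty unexposed group)")
  risk_exposed <- 2 * n_concordant / (2 * n_concordant + n_discordant)
  risk_unexposed <- n_discordant / n_unexposed
  ifelse(risk_unexposed == 0,
         ifelse(risk_exposed > 0, Inf, NaN),
         risk_exposed / risk_unexposed)
}

#' Population attributable fraction from twin pair counts (percent)
#'
#' The case-based attributable fraction `PAF = P * (RR - 1) / RR`, the
#' percentage of cases attributable to the co-twin-shared factors (genotype
#' plus shared exposures). Conventions at the degenerate edges: `P = 0` gives
#' `PAF = 0`; an infinite relative risk (`N_D = 0`, `N_C > 0`) gives
#' `PAF = P`, the RR -> Inf limit of the formula. A relative risk below 1
#' yields a negative value, returned as computed with a warning.
#'
#' @inheritParams relative_risk
#' @return The attributable fraction in percent; in `[0, 100]` whenever
#'   `RR >= 1`. Vectorized.
#' @examples
#' population_attributable_fraction(15668, 5, 189)  # 4.42
#' population_attributable_fraction(4307, 3, 20)    # 22.8
#' @export
population_attributable_fraction <- function(n_pairs_total, n_concordant,
                                             n_discordant) {
  n <- max(length(n_pairs_total), length(n_concordant), length(n_discordant))
  nt <- rep_len(n_pairs_total, n)
  nc <- rep_len(n_concordant, n)
  nd <- rep_len(n_discordant, n)
  p <- probandwise_concordance(nc, nd)
  paf <- numeric(n)
  zero <- p == 0
  if (any(!zero)) {
    rr <- relative_risk(nt[!zero], nc[!zero], nd[!zero])
    paf[!zero] <- ifelse(is.infinite(rr), p[!zero], p[!zero] * (rr - 1) / rr)
  }
  if (any(paf < 0))
    warning("negative attributable fraction: relative risk below 1",
            call. = FALSE)
  paf
}

#' Estimate concordance statistics for a twin-cohort table
#'
#' Applies the full estimator to every record: the co-twin risks, probandwise
#' concordance, relative risk and population attributable fraction. All values
#' are kept in full floating precision; round with `signif(x, 3)` to compare
#' with 3-significant-figure presentation.
#'
#' @param records A [twin_cohort] table (or data frame coercible to one).
#' @return A data frame of class `concordance_estimate`: the record columns
#'   plus `risk_cotwin_affected`, `risk_cotwin_unaffected`,
#'   `probandwise_concordance_pct`, `relative_risk`, `paf_pct` and the logical
#'   flags `rr_infinite` and `paf_negative`.
#' @examples
#' est <- estimate_concordance(mz_twin_cohorts())
#' signif(est$paf_pct[est$disease_name == "Asthma"], 3)  # 48.6
#' @export
estimate_concordance <- function(records) {
  records <- twin_cohort(as.data.frame(records))
  out <- as.data.frame(records)
  nt <- out$n_pairs_total; nc <- out$n_concordant; nd <- out$n_discordant
  out$risk_cotwin_affected <- 2 * nc / (2 * nc + nd)
  out$risk_cotwin_unaffected <- nd / (2 * nt - 2 * nc - nd)
  out$probandwise_concordance_pct <- probandwise_concordance(nc, nd)
  out$relative_risk <- relative_risk(nt, nc, nd)
  out$paf_pct <- suppressWarnings(population_attributable_fraction(nt, nc, nd))
  out$rr_infinite <- is.infinite(out$relative_risk)
  out$paf_negative <- out$paf_pct < 0
  if (any(out$paf_negative))
    warning("negative attributable fraction for: ",
            paste(out$disease_name[out$paf_negative], collapse = ", "),
            call. = FALSE)
  class(out) <- c("concordance_estimate", "data.frame")
  out
}

#' Percentile bootstrap interval for a concordance statistic
#'
#' Resamples the `N_T` pairs of one record from the multinomial with cell
#' probabilities `(N_C, N_D, N_T - N_C - N_D) / N_T`, recomputes the chosen
#' statistic for each resample (draws on which it is undefined are skipped),
#' and returns the 2.5 and 97.5 percentile bounds.
#'
#' @param record A one-row [twin_cohort] table.
#' @param statistic One of `"PAF"`, `"P"`, `"RR"`.
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @param seed Integer seed; the interval is reproducible for a fixed seed.
#' @param level Confidence level (default 0.95).
#' @return A list with `lower`, `upper`, `estimate`, `statistic`,
#'   `n_effective` (resamples on which the statistic was defined).
#' @export
bootstrap_ci <- function(record, statistic = c("PAF", "P", "RR"),
                         n_resamples = 2000, seed = 1, level = 0.95) {
  statistic <- match.arg(statistic)
  record <- twin_cohort(as.data.frame(record))
  if (nrow(record) != 1L)
    stop_validation("bootstrap_ci expects a single record")
  if (n_resamples < 1)
    stop_validation("n_resamples must be >= 1")
  nt <- record$n_pairs_total
  probs <- c(record$n_concordant, record$n_discordant,
             nt - record$n_concordant - record$n_discordant) / nt
  stat_fun <- switch(statistic,
    P = function(nc, nd) probandwise_concordance(nc, nd),
    RR = function(nc, nd) relative_risk(nt, nc, nd),
    PAF = function(nc, nd)
      suppressWarnings(population_attributable_fraction(nt, nc, nd)))
  point <- stat_fun(record$n_concordant, record$n_discordant)
  draws <- with_preserved_rng(seed, stats::rmultinom(n_resamples, nt, probs))
  vals <- apply(draws, 2L, function(cells) {
    tryCatch(stat_fun(cells[1L], cells[2L]), twinpaf_error = function(e) NA_real_)
  })
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L)
    stop_undefined("statistic undefined on every bootstrap resample")
  alpha <- (1 - level) / 2
  bounds <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  list(lower = bounds[1L], upper = bounds[2L], estimate = point,
       statistic = statistic, n_effective = length(vals))
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
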