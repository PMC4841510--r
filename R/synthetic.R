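## Synthetic MZ twin cohorts --------------------------------------------------
##
## A twin cohort's (N_C, N_D, N_T - N_C - N_D) counts are multinomial over the
## three pair outcomes (both affected / exactly one / neither). Any
## (p_both, p_one, p_neither) can be injected directly; as a convenient
## generator the liability-threshold model derives them from a per-twin
## lifetime prevalence K and a within-pair correlation r of a standard
## bivariate-normal latent liability, with disease when liability exceeds
## the threshold qnorm(1 - K).

#' Pair-outcome probabilities for a twin cohort
#'
#' @param p_both Probability both twins are affected.
#' @param p_one Probability exactly one twin is affected.
#' @param p_neither Probability neither is affected.
#' @return A list of class `pair_probs`. The three probabilities must each
#'   lie in `[0, 1]` and sum to 1 within `1e-12`.
#' @export
pair_probabilities <- function(p_both, p_one, p_neither) {
  p <- c(p_both, p_one, p_neither)
  if (length(p) != 3L || anyNA(p) || any(p < 0) || any(p > 1))
    stop_validation("pair-outcome probabilities must each lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-12)
    stop_validation("pair-outcome probabilities must sum to 1 (got %.15f)", sum(p))
  structure(list(p_both = p_both, p_one = p_one, p_neither = p_neither),
            class = "pair_probs")
}

#' Liability-threshold model for an MZ twin pair
#'
#' @param prevalence Per-twin lifetime disease probability K, in (0, 1).
#' @param correlation Within-pair correlation r of the standard
#'   bivariate-normal latent liability, in `[0, 1]`.
#' @return A list of class `liability_model` with `prevalence`,
#'   `correlation` and the derived `threshold = qnorm(1 - prevalence)`.
#' @export
liability_model <- function(prevalence, correlation) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1)
    stop_validation("prevalence must lie strictly between 0 and 1")
  if (!is.numeric(correlation) || length(correlation) != 1L ||
      correlation < 0 || correlation > 1)
    stop_validation("correlation must lie in [0, 1]")
  structure(list(prevalence = prevalence, correlation = correlation,
                 threshold = stats::qnorm(1 - prevalence)),
            class = "liability_model")
}

# P(X > t, Y > t) for standard bivariate normal with correlation rho,
# by conditioning: integral over x > t of phi(x) * Phi((rho*x - t)/sqrt(1-rho^2)).
bvn_upper_orthant <- function(threshold, rho, abs_tol = 1e-10) {
  if (rho == 0) return(stats::pnorm(threshold, lower.tail = FALSE)^2)
  if (1 - rho < 1e-12) return(stats::pnorm(threshold, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  integrand <- function(x)
    stats::dnorm(x) * stats::pnorm((rho * x - threshold) / s)
  stats::integrate(integrand, lower = threshold, upper = Inf,
                   abs.tol = abs_tol, rel.tol = abs_tol)$value
}

#' Pair-outcome probabilities implied by a liability model
#'
#' `p_both` is the upper-orthant probability of the bivariate normal above
#' `(threshold, threshold)` (computed by numerical integration to absolute
#' tolerance 1e-8 or better); `p_one = 2 (K - p_both)`;
#' `p_neither = 1 - p_both - p_one`.
#'
#' @param model A [liability_model()].
#' @return A [pair_probabilities()] object.
#' @examples
#' pair_probs_from_liability(liability_model(0.1, 0))$p_both    # 0.01
#' pair_probs_from_liability(liability_model(0.1, 1))$p_both    # 0.1
#' @export
pair_probs_from_liability <- function(model) {
  if (!inherits(model, "liability_model"))
    stop_validation("model must be a liability_model")
  k <- model$prevalence
  p_both <- bvn_upper_orthant(model$threshold, model$correlation)
  p_both <- min(max(p_both, 0), k)
  p_one <- 2 * (k - p_both)
  pair_probabilities(p_both, p_one, 1 - p_both - p_one)
}

#' Population-level concordance statistics of a generating model
#'
#' The analytic ("true") probandwise concordance, relative risk and
#' attributable fraction of the pair-outcome multinomial, obtained by applying
#' the estimator's formulas to population proportions: exposed (affected
#' co-twin) risk `2 p_both / (2 p_both + p_one)`, unexposed risk
#' `p_one / (p_one + 2 p_neither)`. Degenerate conventions match the count
#' estimator: zero exposed risk gives PAF = 0; zero unexposed risk with
#' positive exposed risk gives RR = Inf and PAF = P.
#'
#' @param probs A [pair_probabilities()] object.
#' @return A list with `P`, `RR`, `PAF` (percent scale for `P` and `PAF`),
#'   plus `risk_cotwin_affected` and `risk_cotwin_unaffected`.
#' @examples
#' true_statistics(pair_probabilities(0.01, 0.18, 0.81))$RR  # 1
#' @export
true_statistics <- function(probs) {
  if (!inherits(probs, "pair_probs"))
    stop_validation("probs must be a pair_probs object")
  if (probs$p_both + probs$p_one <= 0)
    stop_undefined("no affected probability mass: statistics undefined")
  risk_exp <- 2 * probs$p_both / (2 * probs$p_both + probs$p_one)
  denom_unexp <- probs$p_one + 2 * probs$p_neither
  risk_unexp <- if (denom_unexp > 0) probs$p_one / denom_unexp else NA_real_
  p <- 100 * risk_exp
  if (risk_exp == 0) {
    rr <- if (!is.na(risk_unexp) && risk_unexp > 0) 0 else NaN
    paf <- 0
  } else if (is.na(risk_unexp) || risk_unexp == 0) {
    rr <- Inf
    paf <- p
  } else {
    rr <- risk_exp / risk_unexp
    paf <- p * (rr - 1) / rr
  }
  list(P = p, RR = rr, PAF = paf,
       risk_cotwin_affected = risk_exp, risk_cotwin_unaffected = risk_unexp)
}

#' Simulate an MZ twin cohort
#'
#' Draws `(N_C, N_D, N_T - N_C - N_D)` from the multinomial with the given
#' pair-outcome probabilities and returns a validated one-row twin-cohort
#' table. Reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param probs A [pair_probabilities()] object.
#' @param n_pairs Number of twin pairs N_T (>= 1).
#' @param seed Integer seed.
#' @param disease_name,category,country Labels for the simulated record.
#' @return A one-row [twin_cohort] table.
#' @examples
#' probs <- pair_probs_from_liability(liability_model(0.05, 0.6))
#' simulate_twin_cohort(probs, 10000, seed = 1)
#' @export
simulate_twin_cohort <- function(probs, n_pairs, seed = 1,
                                 disease_name = "synthetic disease",
                                 category = "other",
                                 country = "synthetic") {
  if (!inherits(probs, "pair_probs"))
    stop_validation("probs must be a pair_probs object")
  if (n_pairs < 1)
    stop_validation("n_pairs must be >= 1")
  cells <- with_preserved_rng(seed, stats::rmultinom(
    1L, n_pairs, c(probs$p_both, probs$p_one, probs$p_neither)))[, 1L]
  twin_cohort(data.frame(
    disease_name = disease_name, category = category, country = country,
    sex_subset = "both",
    n_pairs_total = as.integer(n_pairs),
    n_concordant = as.integer(cells[1L]),
    n_discordant = as.integer(cells[2L]),
    stringsAsFactors = FALSE))
}
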