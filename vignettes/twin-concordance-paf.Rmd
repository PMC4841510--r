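---
title: "Attributable fractions from monozygotic twin concordance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributable fractions from monozygotic twin concordance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinpaf)
```

## The question and the data

How much of the risk of a chronic disease is attributable to a person's
genome together with the exposures shared within a family? Monozygotic (MZ)
twins offer a direct handle: the members of an MZ pair have essentially
identical genomes and share many exposures, especially in early life. If a
disease were driven entirely by those shared factors, affected twins would
nearly always have affected co-twins; if it were driven by non-shared
exposures or chance, concordance would be no better than the population
baseline.

The data unit is a *twin cohort record*: for one disease in one cohort, the
total number of MZ pairs $N_T$, the number of *concordant* pairs $N_C$ (both
twins affected) and the number of *discordant* pairs $N_D$ (exactly one twin
affected). The package bundles a compiled table of such counts for 28 chronic
diseases from large Western European (mostly Swedish, Danish and Finnish)
twin registries reported around the year 2000, available as
`mz_twin_cohorts()`. Where a study reported the sexes separately,
`combine_twin_records()` sums the counts before estimation.

## The estimator

Each pair contributes two individuals, so a cohort implies $2 N_T$ people.
Treat "my co-twin is affected" as the exposure. The exposed group contains
the $2 N_C$ members of concordant pairs (all affected) plus the $N_D$
unaffected members of discordant pairs; the unexposed group contains the
$N_D$ affected members of discordant pairs plus the $2 (N_T - N_C - N_D)$
members of fully unaffected pairs. Three statistics follow:

* **Probandwise concordance** — the exposed risk, in percent: among all
  affected individuals, the share whose co-twin is also affected,
  $$P = \frac{2 N_C}{2 N_C + N_D} \times 100.$$
* **Relative risk** — exposed over unexposed risk,
  $$RR = \frac{2 N_C / (2 N_C + N_D)}{N_D / (2 N_T - 2 N_C - N_D)}.$$
* **Population attributable fraction** — the case-based (Miettinen-type)
  attributable fraction among cases,
  $$\mathrm{PAF} = P \times \frac{RR - 1}{RR},$$
  the percentage of cases that would in theory be prevented by removing the
  factors an MZ co-twin shares: the genotype plus shared exposures. An
  algebraic identity worth knowing for intuition and for proofs:
  $\mathrm{PAF} = 100 \times (\text{exposed risk} - \text{unexposed risk})$.

`estimate_concordance()` computes all three in full floating precision for
every record; rounding to three significant figures is applied only at
presentation, matching the convention of published tables of these
statistics.

### Degenerate inputs

The formulas have removable singularities that the package resolves by their
continuous limits, chosen once and applied everywhere (counts and population
analogues alike):

* $P = 0$ (no concordant pairs): $\mathrm{PAF} = 0$, avoiding $0 \times
  (RR-1)/RR$ with $RR = 0$.
* $N_D = 0$ with $N_C > 0$: the unexposed risk is zero, $RR$ is reported as
  `Inf` and $\mathrm{PAF} = P$ (the $RR \to \infty$ limit).
* No affected individuals ($2 N_C + N_D = 0$), or an empty unexposed group
  ($N_C = N_T$, $N_D = 0$): the statistics are undefined and a typed
  `twinpaf_undefined_statistic` error is raised rather than a silent `NaN`.
* $RR < 1$, which can occur on user data though not in the bundled table:
  the negative PAF is returned as computed, with a warning, rather than
  clamped — the formula is preserved and the flag makes the anomaly visible.

### Uncertainty

The source compilation reports no uncertainty, so interval estimation is a
package addition, not a reproduction: `bootstrap_ci()` resamples the $N_T$
pairs from the multinomial $(N_C, N_D, N_T - N_C - N_D)/N_T$, recomputes the
chosen statistic per resample (draws on which it is undefined are skipped and
counted), and reports percentile bounds. Pairs, not individuals, are the
sampling unit. Results are bit-reproducible for a fixed seed.

## Summary conventions

Published summaries of the 28 attributable fractions mix two quantile
conventions, so both are explicit and selectable in `paf_quantile()` and
`summarize_pafs()`:

* `inverse_ecdf` — the type-1 (order-statistic) quantile: the smallest sample
  value whose empirical CDF reaches $q$. Always a sample member. On 28
  values, the median and quartiles are the 14th, 7th and 21st order
  statistics.
* `midpoint` — for even $n$ at $q = 0.5$, the mean of the two central order
  statistics (`stats::median`); identical to `inverse_ecdf` otherwise.

The defaults — `inverse_ecdf` for the overall median and IQR, `midpoint` for
per-category medians — are the only pairing that reproduces all six summary
numbers of the bundled dataset's source simultaneously (18.5 / 9.9 / 24.2
overall; cancer 8.26, neurological 26.1, lung 33.6). That internal
inconsistency belongs to the source; the package documents it rather than
guessing an intent, and either convention can be applied to either summary.
For odd $n$ the two conventions agree at the median, which is why the
nine-cancer median is convention-independent.

`paf_cumulative()` emits the empirical cumulative distribution as one point
per disease (ties kept as separate points), suitable for plotting with any
graphics front end.

## Mortality attribution

`link_mortality()` multiplies disease-specific death counts by the matching
disease's PAF and totals the products; the overall attributable percent is
$100 \sum_i d_i \, \mathrm{PAF}_i / (100 \sum_i d_i)$, i.e. the
death-weighted mean PAF, and therefore always lies between the smallest and
largest matched PAF. Matching is exact on disease name with an optional alias
map (mortality sources and twin tables label diseases differently, e.g.
"Ischemic heart disease" versus "Coronary heart disease death"). Attributable
deaths are kept fractional internally and rounded only for display, so totals
carry no accumulation error.

The packaged mortality table (`synthetic_mortality()`) is **synthetic**: its
death counts are illustrative round numbers for ischemic heart disease and
nine cancers, present so the linkage arithmetic is testable without external
databases. It is not a source of real burden-of-disease figures, and the
package deliberately does not reproduce any published attributable-death
total that depends on such external counts.

## The synthetic cohort generator

The estimator assumes only that a cohort's $(N_C, N_D, N_T - N_C - N_D)$
counts are multinomial over the three pair outcomes (both affected / exactly
one / neither). The generator mirrors that assumption:

* `pair_probabilities(p_both, p_one, p_neither)` injects any outcome
  distribution directly (probabilities must sum to 1 within $10^{-12}$).
* `liability_model(prevalence, correlation)` is a convenient parametric
  source of such distributions: each twin has a standard-normal latent
  liability, the pair's liabilities are bivariate normal with correlation
  $r \in [0, 1]$, and disease occurs above the threshold
  $\Phi^{-1}(1 - K)$ set by the per-twin lifetime prevalence $K$. Then
  $p_\text{both}$ is the upper-orthant probability above
  $(\text{threshold}, \text{threshold})$, $p_\text{one} = 2 (K -
  p_\text{both})$, and the marginal prevalence is preserved by
  construction.
* `true_statistics()` applies the estimator's formulas to the population
  proportions (exposed risk $2 p_\text{both} / (2 p_\text{both} +
  p_\text{one})$, unexposed risk $p_\text{one} / (p_\text{one} + 2
  p_\text{neither})$), giving the analytic truth a simulated cohort's
  estimates should converge to.
* `simulate_twin_cohort()` draws the multinomial with an explicit seed and
  returns a validated record; no global RNG state is consumed.

The orthant probability has no closed form for general $r$; it is computed by
conditioning — $\int_t^\infty \phi(x)\, \Phi\!\big((r x - t)/\sqrt{1 -
r^2}\big)\, dx$ via `stats::integrate` with absolute tolerance $10^{-10}$ —
with exact shortcuts at $r = 0$ ($K^2$) and $r = 1$ ($K$). The test suite
cross-checks it against two independent oracles: a $10^7$-draw Monte-Carlo
estimate (within three standard errors) and a two-dimensional quadrature of
the bivariate density.

What the generator does and does not emulate: it reproduces the multinomial
pair-count structure, which is *all* the estimator uses, so consistency and
parameter-recovery tests are meaningful. It does not model exposure
covariates, G×E interaction, dizygotic pairs, ascertainment, censoring or
cohort overlap — so passing tests certify the estimator's arithmetic and
sampling behaviour, not the epidemiological validity of any real cohort. In
particular the liability correlation $r$ deliberately bundles genetics with
shared environment, exactly as an MZ-only design must.

Default generator settings (`prevalence = 0.05`, `correlation = 0.6`,
`n_pairs = 100000`) sit in the middle of the bundled cohorts' regime:
per-twin lifetime prevalences there span roughly 0.005–0.2 and the larger
registries contribute $10^4$–$1.6 \times 10^4$ pairs, with $10^5$ chosen for
recovery checks so Monte-Carlo noise is small against a 2% relative-error
yardstick. Recovery tests sweep $K \in \{0.01, 0.05, 0.2\}$ and $r \in \{0,
0.3, 0.6, 0.9\}$ with cohorts of $10^5$ pairs, comparing against
`true_statistics()` within the larger of 2% relative error and three
Monte-Carlo standard errors of the generating multinomial (the binomial noise
floor at small $K$ exceeds 2% even at $10^5$ pairs, so the SE bound is the
binding one there). The exhaustive estimator-versus-enumeration check covers
every cohort with $N_T \le 30$ by explicitly laying out the $2 N_T$
individuals.

## Numerical and design notes

* All statistics are exact rational arithmetic in double precision; no
  intermediate rounding. `signif(x, 3)` is the presentation convention.
* The disease-to-category map (nine cancers; stroke and coronary heart
  disease as cardiovascular; migraine among the neurological diseases;
  asthma and COPD as lung; Type-2 diabetes and gallstone disease as
  obesity-associated; rheumatoid arthritis, Type-1 diabetes and thyroid
  autoimmunity as autoimmune; three genitourinary conditions; three other
  syndromes) is fixed in the package because the per-category medians depend
  on it; user data may use any names, but a name matching a bundled disease
  must carry its fixed category.
* PAF is monotone nondecreasing in $N_C$ at fixed $N_T, N_D$ only while
  affected pairs remain below about a quarter of the cohort (sufficient
  condition $2 N_C + N_D \le \sqrt{2}\,(2 N_T - 2 N_C - N_D)$); near
  saturation the unexposed risk rises faster than the exposed risk and the
  ordering reverses. Every bundled cohort is deep inside the monotone
  regime.
* CSV schemas are strict: exact header names, UTF-8, no thousands
  separators (the bundled table is stored normalized). Violations raise
  typed conditions (`twinpaf_format_error`, `twinpaf_validation_error`,
  `twinpaf_linkage_error`) that the command-line front end maps to exit
  codes 2 and 1.
* The cohorts in the bundled table are treated as independent rows even
  though several share Nordic registry populations; the source provides no
  overlap information, and no pooling beyond the printed counts is
  attempted.

## Limitations

MZ-only concordance cannot separate genetics from shared environment, cannot
estimate non-shared exposure effects or G×E interaction, and inherits any
ascertainment bias of the source registries. The bootstrap intervals describe
multinomial sampling error only. The mortality linkage is arithmetic, not
inference: its outputs are only as good as the death counts supplied.

## A worked example

```{r example}
est <- estimate_concordance(mz_twin_cohorts())
summarize_pafs(est)

rep <- link_mortality(est, synthetic_mortality(),
  aliases = c("Ischemic heart disease" = "Coronary heart disease death"))
rep$totals$overall_attributable_pct

probs <- pair_probs_from_liability(liability_model(0.05, 0.6))
true_statistics(probs)$PAF
estimate_concordance(simulate_twin_cohort(probs, 1e5, seed = 1))$paf_pct
```
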