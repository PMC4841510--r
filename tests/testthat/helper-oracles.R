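# Brute-force oracle: lay out the 2*N_T individuals explicitly, mark each
# one's outcome (affected?) and exposure (co-twin affected?), and compute the
# risks directly from the individual-level vectors. Independent of the
# package's closed-form expressions.
oracle_stats <- function(nt, nc, nd) {
  nn <- nt - nc - nd
  exposed <- c(rep(TRUE, 2 * nc),           # concordant pairs: both twins
               rep(FALSE, nd),              # discordant: the affected twin
               rep(TRUE, nd),               # discordant: the unaffected twin
               rep(FALSE, 2 * nn))          # unaffected pairs
  affected <- c(rep(TRUE, 2 * nc),
                rep(TRUE, nd),
                rep(FALSE, nd),
                rep(FALSE, 2 * nn))
  if (sum(affected) == 0) return(NULL)                 # no cases: undefined
  if (sum(!exposed) == 0) return(NULL)                 # empty unexposed group
  p <- 100 * mean(affected[exposed])
  risk_unexp <- mean(affected[!exposed])
  risk_exp <- mean(affected[exposed])
  rr <- if (risk_unexp == 0) { if (risk_exp > 0) Inf else NaN }
        else risk_exp / risk_unexp
  paf <- if (p == 0) 0 else if (is.infinite(rr)) p else p * (rr - 1) / rr
  list(P = p, RR = rr, PAF = paf)
}

# Minimal valid record builder for tests.
make_record <- function(nt, nc, nd, disease = "test disease",
                        category = "other", country = "testland",
                        sex = "both") {
  twin_cohort(data.frame(
    disease_name = disease, category = category, country = country,
    sex_subset = sex, n_pairs_total = nt, n_concordant = nc,
    n_discordant = nd, stringsAsFactors = FALSE))
}

# The published reference values for the bundled 28-disease dataset, frozen
# at 3 significant figures. The Parkinson concordance cell is stored as the
# value the estimator's formula yields at that precision (10.7); the source
# compilation prints 10.6 there, a one-unit rounding slip inconsistent with
# its own formula (its RR and PAF cells agree with the formula).
reference_statistics <- function() {
  read.csv(text = 'disease_name,P,RR,PAF
Bladder cancer,5.03,8.28,4.42
Breast cancer,14.3,4.60,11.2
Colorectal cancer,12.6,9.35,11.3
Leukemia,3.74,11.3,3.41
Lung cancer,10.8,11.4,9.89
Ovarian cancer,4.58,6.13,3.83
Pancreatic cancer,4.65,11.8,4.26
Prostate cancer,21.1,9.94,19.0
Stomach cancer,8.98,12.5,8.26
Thyroid autoimmunity,45.2,14.3,42.0
Type 1 diabetes,23.1,99.1,22.8
Type 2 diabetes,33.9,25.3,32.6
Gallstone disease,19.0,4.16,14.4
Alzheimer\'s disease,33.3,32.7,32.3
Dementia,27.3,13.2,25.2
Chronic fatigue,31.4,2.10,16.4
Gastroesophageal reflux disorder,33.9,3.48,24.2
Irritable bowel syndrome,22.4,5.49,18.3
Coronary heart disease death,36.4,2.46,21.6
Stroke-related death,18.1,4.20,13.8
General dystocia,31.6,2.93,20.8
Pelvic organ prolapse,30.2,12.6,27.8
Stress urinary incontinence,23.0,17.6,21.7
Migraine,35.7,4.15,27.1
Rheumatoid arthritis,22.0,28.1,21.2
Asthma,53.5,11.0,48.6
Parkinson disease,10.7,12.0,9.76
Chronic obstructive pulmonary disease,19.5,20.0,18.5',
    stringsAsFactors = FALSE)
}
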