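#' @keywords internal
"_PACKAGE"

## Twin-cohort count tables ---------------------------------------------------
##
## A twin cohort record summarises one disease in one MZ (monozygotic) twin
## cohort by three counts: the total number of pairs N_T, the number of
## concordant pairs N_C (both twins affected) and the number of discordant
## pairs N_D (exactly one twin affected). Everything downstream (probandwise
## concordance, relative risk, population attributable fraction) is a function
## of these three counts.

#' Disease categories recognised by the package
#'
#' The grouping used for per-category summaries: nine cancers, cardiovascular,
#' neurological, lung, obesity-associated, autoimmune, genitourinary diseases
#' and a residual "other" group of syndromes.
#'
#' @format A character vector of the eight category labels.
#' @export
twin_categories <- function() {
  c("cancer", "cardiovascular", "neurological", "lung",
    "obesity-associated", "autoimmune", "genitourinary", "other")
}

twin_sex_subsets <- function() c("both", "female", "male")

twin_table_columns <- function() {
  c("disease_name", "category", "country", "sex_subset",
    "n_pairs_total", "n_concordant", "n_discordant")
}

# Fixed disease -> category map for the bundled cohorts; user data may use any
# disease names, but where a name matches a bundled disease its category must
# agree (per-category medians depend on this grouping).
bundled_category_map <- function() {
  c("Bladder cancer" = "cancer",
    "Breast cancer" = "cancer",
    "Colorectal cancer" = "cancer",
    "Leukemia" = "cancer",
    "Lung cancer" = "cancer",
    "Ovarian cancer" = "cancer",
    "Pancreatic cancer" = "cancer",
    "Prostate cancer" = "cancer",
    "Stomach cancer" = "cancer",
    "Thyroid autoimmunity" = "autoimmune",
    "Type 1 diabetes" = "autoimmune",
    "Rheumatoid arthritis" = "autoimmune",
    "Type 2 diabetes" = "obesity-associated",
    "Gallstone disease" = "obesity-associated",
    "Alzheimer's disease" = "neurological",
    "Dementia" = "neurological",
    "Parkinson disease" = "neurological",
    "Migraine" = "neurological",
    "Chronic fatigue" = "other",
    "Gastroesophageal reflux disorder" = "other",
    "Irritable bowel syndrome" = "other",
    "Coronary heart disease death" = "cardiovascular",
    "Stroke-related death" = "cardiovascular",
    "General dystocia" = "genitourinary",
    "Pelvic organ prolapse" = "genitourinary",
    "Stress urinary incontinence" = "genitourinary",
    "Asthma" = "lung",
    "Chronic obstructive pulmonary disease" = "lung")
}

#' Look up the fixed category of a bundled disease
#'
#' @param disease_name Character vector of disease names.
#' @return Character vector of categories; `NA` for names not in the bundled
#'   dataset.
#' @export
disease_category <- function(disease_name) {
  unname(bundled_category_map()[disease_name])
}

#' Construct and validate a twin-cohort table
#'
#' Validates a data frame of twin-cohort records against the count and label
#' invariants and returns it classed as `twin_cohort`. Counts must be
#' non-negative integers with `n_pairs_total >= 1` and
#' `n_concordant + n_discordant <= n_pairs_total`.
#'
#' @param x A data frame with columns `disease_name`, `category`, `country`,
#'   `sex_subset`, `n_pairs_total`, `n_concordant`, `n_discordant`.
#' @return `x`, validated, with class `c("twin_cohort", "data.frame")`.
#' @examples
#' twin_cohort(data.frame(
#'   disease_name = "Asthma", category = "lung", country = "Denmark",
#'   sex_subset = "both", n_pairs_total = 5084,
#'   n_concordant = 257, n_discordant = 447))
#' @export
twin_cohort <- function(x) {
  if (!is.data.frame(x))
    stop_validation("twin cohort input must be a data frame")
  missing <- setdiff(twin_table_columns(), names(x))
  if (length(missing) > 0L)
    stop_format("missing column(s): %s", paste(missing, collapse = ", "))
  if (nrow(x) == 0L)
    stop_validation("empty table: no twin-cohort records")
  x <- x[, twin_table_columns()]
  for (col in c("disease_name", "category", "country", "sex_subset"))
    x[[col]] <- as.character(x[[col]])
  for (col in c("n_pairs_total", "n_concordant", "n_discordant")) {
    v <- x[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != trunc(v)))
      stop_validation("column '%s' must contain non-negative integers", col)
    x[[col]] <- as.integer(v)
  }
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    rule <- validate_record_row(r)
    if (!is.null(rule))
      stop_validation("row %d ('%s') violates: %s", i, r$disease_name, rule)
  }
  class(x) <- c("twin_cohort", "data.frame")
  x
}

# Returns NULL if valid, else a one-line description of the violated rule.
validate_record_row <- function(r) {
  if (r$n_pairs_total < 1L)
    return("n_pairs_total must be >= 1")
  if (r$n_concordant + r$n_discordant > r$n_pairs_total)
    return("n_concordant + n_discordant must not exceed n_pairs_total")
  if (!r$category %in% twin_categories())
    return(sprintf("category '%s' is not one of {%s}", r$category,
                   paste(twin_categories(), collapse = ", ")))
  if (!r$sex_subset %in% twin_sex_subsets())
    return(sprintf("sex_subset '%s' is not one of {both, female, male}",
                   r$sex_subset))
  fixed <- disease_category(r$disease_name)
  if (!is.na(fixed) && fixed != r$category)
    return(sprintf("category '%s' conflicts with the fixed category '%s' for '%s'",
                   r$category, fixed, r$disease_name))
  NULL
}

#' Read a twin-cohort count table from CSV
#'
#' The file must be UTF-8, comma-separated, with one header row naming the
#' seven record fields exactly. Counts must parse as plain non-negative
#' integers; thousands separators are rejected.
#'
#' @param path Path to the CSV file.
#' @return A validated [twin_cohort] table, rows in file order.
#' @export
read_twin_table <- function(path) {
  if (!file.exists(path))
    stop_format("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(twin_table_columns(), names(raw))
  if (length(missing) > 0L)
    stop_format("missing column(s) in %s: %s", path,
                paste(missing, collapse = ", "))
  if (nrow(raw) == 0L)
    stop_validation("empty table: %s has a header but no rows", path)
  for (col in c("n_pairs_total", "n_concordant", "n_discordant")) {
    v <- trimws(raw[[col]])
    if (!all(grepl("^[0-9]+$", v)))
      stop_format("column '%s' must contain plain non-negative integers (no separators); offending value '%s'",
                  col, v[which(!grepl("^[0-9]+$", v))[1L]])
    raw[[col]] <- as.integer(v)
  }
  twin_cohort(raw)
}

#' Write a twin-cohort table to CSV
#'
#' Inverse of [read_twin_table()]: `read_twin_table(write_twin_table(x, p))`
#' returns a table identical to `x`.
#'
#' @param x A [twin_cohort] table (validated on write).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_twin_table <- function(x, path) {
  x <- twin_cohort(as.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Bundled Western European MZ twin dataset (28 chronic diseases)
#'
#' The package's compiled dataset of published monozygotic-twin cohort counts
#' for 28 chronic diseases, primarily from Swedish, Danish and Finnish twin
#' registries reported around the year 2000: nine cancers, two cardiovascular,
#' four neurological, two lung, two obesity-associated, three autoimmune and
#' three genitourinary diseases, plus three other syndromes. Sex-specific
#' diseases (e.g. breast, ovarian and prostate cancer) carry the relevant
#' `sex_subset`; all other rows are sex-combined.
#'
#' @return A validated [twin_cohort] table with 28 rows.
#' @examples
#' cohorts <- mz_twin_cohorts()
#' table(cohorts$category)
#' @export
mz_twin_cohorts <- function() {
  path <- system.file("extdata", "mz_twin_cohorts.csv", package = "twinpaf",
                      mustWork = TRUE)
  x <- read_twin_table(path)
  stopifnot(nrow(x) == 28L)
  x
}

#' Combine per-sex records of one disease into a sex-combined record
#'
#' When a study reports male and female twin pairs separately, the disease's
#' statistics are estimated from the combined counts. Counts are summed
#' element-wise; `sex_subset` becomes `"both"` when the inputs cover both
#' sexes (or already include a `"both"` record).
#'
#' @param records A [twin_cohort] table whose rows all share one
#'   `disease_name` and have pairwise-distinct `sex_subset` values.
#' @return A one-row [twin_cohort] table.
#' @examples
#' recs <- twin_cohort(data.frame(
#'   disease_name = "Example disease", category = "other", country = "Sweden",
#'   sex_subset = c("female", "male"),
#'   n_pairs_total = c(1000L, 1200L),
#'   n_concordant = c(3L, 2L), n_discordant = c(10L, 8L)))
#' combine_twin_records(recs)
#' @export
combine_twin_records <- function(records) {
  records <- twin_cohort(as.data.frame(records))
  if (length(unique(records$disease_name)) != 1L)
    stop_validation("cannot combine records with conflicting disease_name: %s",
                    paste(unique(records$disease_name), collapse = " / "))
  if (anyDuplicated(records$sex_subset))
    stop_validation("duplicate sex_subset among records for '%s'",
                    records$disease_name[1L])
  if (nrow(records) == 1L)
    return(records)
  sexes <- records$sex_subset
  combined_sex <- if ("both" %in% sexes || all(c("female", "male") %in% sexes))
    "both" else sexes[1L]
  out <- data.frame(
    disease_name = records$disease_name[1L],
    category = records$category[1L],
    country = paste(unique(records$country), collapse = "; "),
    sex_subset = combined_sex,
    n_pairs_total = sum(records$n_pairs_total),
    n_concordant = sum(records$n_concordant),
    n_discordant = sum(records$n_discordant),
    stringsAsFactors = FALSE)
  twin_cohort(out)
}
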