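## Pipeline front end ---------------------------------------------------------
##
## Thin wiring of the analysis stages: compute (counts -> estimates CSV),
## summarize (estimates -> summary + cumulative-distribution CSVs), attribute
## (estimates x mortality -> attribution CSV) and simulate (liability model ->
## simulated cohort + recovery report). Each run_* function takes a RunConfig
## list; twin_paf_main() exposes them as shell subcommands (see exec/twinpaf).
## Logs go to stderr via message(); data go to files under output_dir.
## Exit codes: 0 success, 1 validation/linkage, 2 I/O or format.

#' Build a pipeline run configuration
#'
#' @param input `"bundled"` for the packaged 28-disease dataset, or a path to
#'   a twin-cohort CSV.
#' @param convention_overall,convention_category Quantile conventions for
#'   [summarize_pafs()].
#' @param mortality Optional path to a mortality CSV, or `"bundled"` for the
#'   packaged synthetic table.
#' @param aliases Optional path to a YAML alias map (mortality name ->
#'   estimate name) for [link_mortality()].
#' @param output_dir Directory for output files (created if needed).
#' @param seed Integer seed for any stochastic stage.
#' @param prevalence,correlation,n_pairs Liability-model settings for the
#'   simulate stage.
#' @param verbose Emit progress messages on stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = "bundled",
                       convention_overall = "inverse_ecdf",
                       convention_category = "midpoint",
                       mortality = NULL,
                       aliases = NULL,
                       output_dir = ".",
                       seed = 1L,
                       prevalence = 0.05,
                       correlation = 0.6,
                       n_pairs = 100000L,
                       verbose = TRUE) {
  convention_overall <- match.arg(convention_overall, quantile_conventions())
  convention_category <- match.arg(convention_category, quantile_conventions())
  structure(list(input = input,
                 convention_overall = convention_overall,
                 convention_category = convention_category,
                 mortality = mortality, aliases = aliases,
                 output_dir = output_dir, seed = as.integer(seed),
                 prevalence = prevalence, correlation = correlation,
                 n_pairs = as.integer(n_pairs), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys match the arguments of [run_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML (`key: value`) file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_format("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0L)
    stop_validation("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

log_msg <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

log_run <- function(config, stage) {
  log_msg(config, "[twinpaf %s] stage=%s input=%s seed=%d",
          as.character(utils::packageVersion("twinpaf")), stage,
          config$input, config$seed)
}

load_input_records <- function(config) {
  if (identical(config$input, "bundled")) mz_twin_cohorts()
  else read_twin_table(config$input)
}

ensure_output_dir <- function(config) {
  if (!dir.exists(config$output_dir))
    dir.create(config$output_dir, recursive = TRUE)
  config$output_dir
}

write_output_csv <- function(df, config, name) {
  path <- file.path(ensure_output_dir(config), name)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

#' Run the estimation stage
#'
#' Computes the concordance estimates for every input record and writes
#' `estimates.csv` with full-precision and 3-significant-figure columns.
#'
#' @param config A `run_config`.
#' @return The path to the written CSV, invisibly; the estimates are returned
#'   as the attribute `"estimates"`.
#' @export
run_compute <- function(config = run_config()) {
  log_run(config, "compute")
  est <- estimate_concordance(load_input_records(config))
  out <- as.data.frame(est)
  out$P_3sf <- signif(out$probandwise_concordance_pct, 3)
  out$RR_3sf <- signif(out$relative_risk, 3)
  out$PAF_3sf <- signif(out$paf_pct, 3)
  path <- write_output_csv(out, config, "estimates.csv")
  log_msg(config, "wrote %d estimates to %s", nrow(out), path)
  invisible(structure(path, estimates = est))
}

#' Run the summary stage
#'
#' Writes `summary.csv` (one row per statistic), `summary.txt` (the printed
#' paragraph) and `cumulative_distribution.csv` (one point per disease).
#'
#' @param config A `run_config`.
#' @return Named character vector of output paths, invisibly; the
#'   `paf_summary` is attached as attribute `"summary"`.
#' @export
run_summarize <- function(config = run_config()) {
  log_run(config, "summarize")
  est <- estimate_concordance(load_input_records(config))
  s <- summarize_pafs(est, config$convention_overall, config$convention_category)
  csv <- write_output_csv(summary_as_table(s), config, "summary.csv")
  txt <- file.path(ensure_output_dir(config), "summary.txt")
  writeLines(utils::capture.output(print(s)), txt)
  cdf <- write_output_csv(paf_cumulative(est), config,
                          "cumulative_distribution.csv")
  log_msg(config, "wrote summary to %s", csv)
  invisible(structure(c(summary_csv = csv, summary_txt = txt,
                        cumulative_csv = cdf), summary = s))
}

#' Run the mortality-attribution stage
#'
#' Links the input estimates with a mortality table and writes
#' `attribution.csv` with per-disease rows plus a TOTAL row.
#'
#' @param config A `run_config` with `mortality` set.
#' @return The path to the written CSV, invisibly; the `attribution_report`
#'   is attached as attribute `"report"`.
#' @export
run_attribute <- function(config = run_config()) {
  log_run(config, "attribute")
  if (is.null(config$mortality))
    stop_validation("attribute stage requires a mortality table (config$mortality)")
  mort <- if (identical(config$mortality, "bundled")) synthetic_mortality()
          else read_mortality_table(config$mortality)
  aliases <- NULL
  if (!is.null(config$aliases)) {
    if (!file.exists(config$aliases))
      stop_format("alias file not found: %s", config$aliases)
    aliases <- unlist(yaml::read_yaml(config$aliases))
  }
  est <- estimate_concordance(load_input_records(config))
  rep <- link_mortality(est, mort, aliases = aliases)
  out <- rep$results
  out <- rbind(out, data.frame(
    disease_name = "TOTAL", deaths = rep$totals$total_deaths,
    paf_pct = rep$totals$overall_attributable_pct,
    attributable_deaths = rep$totals$total_attributable))
  path <- write_output_csv(out, config, "attribution.csv")
  log_msg(config, "wrote attribution report to %s", path)
  invisible(structure(path, report = rep))
}

#' Run the simulation / recovery stage
#'
#' Simulates a twin cohort from the configured liability model, re-estimates
#' its statistics, compares them with the analytic truth, and writes both the
#' simulated cohort (twin-cohort CSV schema) and `recovery.csv`.
#'
#' @param config A `run_config` with `prevalence`, `correlation`, `n_pairs`,
#'   `seed` set.
#' @return Named character vector of output paths, invisibly; the recovery
#'   table is attached as attribute `"recovery"`.
#' @export
run_simulate <- function(config = run_config()) {
  log_run(config, "simulate")
  probs <- pair_probs_from_liability(
    liability_model(config$prevalence, config$correlation))
  cohort <- simulate_twin_cohort(probs, config$n_pairs, seed = config$seed)
  cohort_path <- file.path(ensure_output_dir(config), "simulated_cohort.csv")
  write_twin_table(cohort, cohort_path)
  est <- estimate_concordance(cohort)
  truth <- true_statistics(probs)
  recovery <- data.frame(
    statistic = c("P", "RR", "PAF"),
    truth = c(truth$P, truth$RR, truth$PAF),
    estimate = c(est$probandwise_concordance_pct, est$relative_risk,
                 est$paf_pct))
  recovery$relative_error <- abs(recovery$estimate - recovery$truth) /
    ifelse(recovery$truth == 0, 1, abs(recovery$truth))
  rec_path <- write_output_csv(recovery, config, "recovery.csv")
  log_msg(config, "PAF truth %.4f, estimate %.4f (rel. err %.4f)",
          truth$PAF, recovery$estimate[3L], recovery$relative_error[3L])
  invisible(structure(c(cohort_csv = cohort_path, recovery_csv = rec_path),
                      recovery = recovery))
}

#' Command-line entry point
#'
#' Dispatches `compute`, `summarize`, `attribute` or `simulate` with flags
#' overriding an optional YAML config file. Used by the `exec/twinpaf`
#' script; returns rather than calls `quit()` so it is testable.
#'
#' @param args Character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status: 0 success, 1 validation/linkage error,
#'   2 I/O or format error.
#' @export
twin_paf_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: twinpaf <compute|summarize|attribute|simulate> [options]"
  if (length(args) < 1L || !args[1L] %in%
      c("compute", "summarize", "attribute", "simulate")) {
    message(usage)
    return(1L)
  }
  stage <- args[1L]
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML config file"),
    optparse::make_option("--input", type = "character", default = NULL,
                          help = "twin-cohort CSV or 'bundled'"),
    optparse::make_option("--mortality", type = "character", default = NULL,
                          help = "mortality CSV or 'bundled'"),
    optparse::make_option("--aliases", type = "character", default = NULL,
                          help = "YAML alias map for mortality names"),
    optparse::make_option("--output-dir", type = "character", default = NULL,
                          dest = "output_dir", help = "output directory"),
    optparse::make_option("--convention-overall", type = "character",
                          default = NULL, dest = "convention_overall"),
    optparse::make_option("--convention-category", type = "character",
                          default = NULL, dest = "convention_category"),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--prevalence", type = "double", default = NULL),
    optparse::make_option("--correlation", type = "double", default = NULL),
    optparse::make_option("--n-pairs", type = "integer", default = NULL,
                          dest = "n_pairs"),
    optparse::make_option("--quiet", action = "store_true", default = FALSE))
  parsed <- tryCatch(
    optparse::parse_args(optparse::OptionParser(option_list = opts,
                                                usage = usage),
                         args = args[-1L]),
    error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed))
    return(1L)
  }
  status <- tryCatch({
    cfg_args <- if (!is.null(parsed$config))
      unclass(read_run_config(parsed$config)) else list()
    flag_names <- intersect(names(parsed), names(formals(run_config)))
    for (nm in flag_names)
      if (!is.null(parsed[[nm]])) cfg_args[[nm]] <- parsed[[nm]]
    if (isTRUE(parsed$quiet)) cfg_args$verbose <- FALSE
    config <- do.call(run_config, cfg_args)
    switch(stage,
           compute = run_compute(config),
           summarize = run_summarize(config),
           attribute = run_attribute(config),
           simulate = run_simulate(config))
    0L
  },
  twinpaf_format_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  twinpaf_error = function(e) { message("error: ", conditionMessage(e)); 1L },
  error = function(e) { message("error: ", conditionMessage(e)); 2L })
  status
}
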