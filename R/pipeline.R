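#' Default pipeline configuration
#'
#' @param input_dir directory of FAERS-style tables, or `NULL` to run on a
#'   synthetic universe.
#' @param out_dir output directory for the result bundle (`NULL`: nothing
#'   written).
#' @param drug_dictionary,smq,pt_soc_map paths; default to the files packaged
#'   under `inst/extdata` (synthetic stand-ins for the licensed MedDRA
#'   terminology).
#' @param levels scan levels to run, subset of `c("smq", "soc", "pt")`.
#' @param counting `"event"` or `"case"`.
#' @param year_field date used for yearly counts (`"fda_dt"` or
#'   `"event_dt"`).
#' @param route_filter optional route restriction passed to [flag_cases()].
#' @param criteria a [signal_criteria()] list.
#' @param synth either `"fixture"` (deterministic reference dataset),
#'   `"fixture_scaled"` (one-tenth), or a [synth_config()]; used when
#'   `input_dir` is `NULL`.
#' @param seed integer seed applied before any sampling.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir = NULL,
                            drug_dictionary = NULL, smq = NULL,
                            pt_soc_map = NULL,
                            levels = c("smq", "soc", "pt"),
                            counting = "event", year_field = "fda_dt",
                            route_filter = NULL,
                            criteria = signal_criteria(),
                            synth = "fixture_scaled", seed = 1L) {
  pkg_file <- function(x) system.file("extdata", x, package = "faersig",
                                      mustWork = TRUE)
  if (is.null(drug_dictionary)) drug_dictionary <-
      pkg_file("drug_dictionary.csv")
  if (is.null(smq)) smq <- pkg_file("smq_oesophageal_synthetic.csv")
  if (is.null(pt_soc_map)) pt_soc_map <-
      pkg_file("pt_soc_map_synthetic.csv")
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 drug_dictionary = drug_dictionary, smq = smq,
                 pt_soc_map = pt_soc_map, levels = levels,
                 counting = counting, year_field = year_field,
                 route_filter = route_filter, criteria = criteria,
                 synth = synth, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; `criteria` may be a mapping of threshold names.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(signal_criteria, as.list(y$criteria))
  args <- y[setdiff(names(y), "criteria")]
  args$criteria <- crit
  do.call(pipeline_config, args)
}

#' Run the full signal-detection pipeline
#'
#' End-to-end orchestration: load (or synthesize) the report tables,
#' deduplicate, assemble, flag target-drug cases against the SMQ, then
#' produce the descriptive table, yearly counts, disproportionality scans at
#' the requested levels, time-to-onset analysis and outcome contrasts. Every
#' stage logs its input/output record counts; if `out_dir` is set the result
#' tables are written as CSV together with a JSON manifest carrying the seed
#' and a hash of the configuration.
#'
#' Missing inputs (dictionary, SMQ, map, input dir) are checked up front and
#' reported together before any computation.
#'
#' @param config a `pipeline_config`, a path to a YAML file, or `NULL` for
#'   the defaults (scaled deterministic fixture).
#' @param verbose log stage counts.
#' @return list of class `pipeline_result`: `flags`, `reports` counts,
#'   `descriptives`, `yearly`, `signals` (named by level), `tto`, `km`,
#'   `logrank`, `outcomes`, `outcome_tests`, `manifest`.
#' @export
run_pipeline <- function(config = NULL, verbose = TRUE) {
  if (is.null(config)) config <- pipeline_config()
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  problems <- character(0)
  for (f in c("drug_dictionary", "smq", "pt_soc_map"))
    if (!file.exists(config[[f]]))
      problems <- c(problems, paste0(f, " not found: ", config[[f]]))
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    problems <- c(problems, paste0("input_dir not found: ",
                                   config$input_dir))
  if (length(problems))
    stop("pipeline configuration problems:\n  ",
         paste(problems, collapse = "\n  "))

  set.seed(config$seed)
  dict <- read_drug_dictionary(config$drug_dictionary)
  smq <- read_smq(config$smq)
  soc_map <- read_pt_soc_map(config$pt_soc_map)

  if (!is.null(config$input_dir)) {
    tables <- read_faers_tables(config$input_dir, verbose = verbose)
    reports <- assemble_reports(tables, verbose = verbose)
  } else {
    synth <- config$synth
    gen <- if (inherits(synth, "synth_config")) synth_generate(synth)
      else if (identical(synth, "fixture")) reference_fixture(1)
      else if (identical(synth, "fixture_scaled")) reference_fixture(0.1)
      else stop("unknown synth specification")
    log_stage("synthetic universe: %d cases", nrow(gen$truth),
              verbose = verbose)
    reports <- as_safety_reports(gen, verbose = verbose)
  }
  n_in <- length(reports$dedup$kept) + nrow(reports$dedup$dropped)
  log_stage("dedup: %d reports in = %d kept + %d dropped", n_in,
            length(reports$dedup$kept), nrow(reports$dedup$dropped),
            verbose = verbose)
  stopifnot(n_in == length(reports$dedup$kept) + nrow(reports$dedup$dropped))

  flags <- flag_cases(reports, dict, smq, route = config$route_filter)
  log_stage("flags: %d drug-report pairs, %d cases", nrow(flags),
            sum(flags$is_case), verbose = verbose)

  desc <- describe_cohort(flags, reports)
  yearly <- yearly_counts(flags, reports, config$year_field)

  signals <- list()
  prior <- if (sum(flags$is_case) > 0)
    fit_mgps_universe(reports, counting = config$counting) else NULL
  for (lv in config$levels) {
    signals[[lv]] <- disprop(reports, flags, level = lv, smq = smq,
                             pt_soc_map = soc_map,
                             counting = config$counting,
                             criteria = config$criteria, prior = prior)
    log_stage("scan %s: %d pairs, %d joint signals", lv,
              nrow(signals[[lv]]$scores),
              sum(signals[[lv]]$scores$joint_significant),
              verbose = verbose)
  }

  tto <- extract_tto(flags, reports)
  km <- if (nrow(tto$tto)) km_onset(tto) else NULL
  lr <- if (length(unique(tto$tto$drug)) >= 2L) logrank_test(tto) else NULL
  outc <- outcome_rates(flags, reports)
  tests <- if (nrow(outc) >= 2L)
    list(hospitalization = pairwise_chi2(outc, "hospitalization"),
         mortality = pairwise_chi2(outc, "mortality")) else list()

  manifest <- list(seed = config$seed,
                   counting = config$counting, levels = config$levels,
                   n_reports_in = n_in,
                   n_reports_kept = length(reports$dedup$kept),
                   n_cases = sum(flags$is_case))
  res <- structure(list(reports = reports, flags = flags,
                        descriptives = desc, yearly = yearly,
                        signals = signals, tto = tto, km = km, logrank = lr,
                        outcomes = outc, outcome_tests = tests,
                        manifest = manifest, config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_bundle(res, config$out_dir)
  res
}

# serialize the result bundle as CSV/JSON under out_dir
write_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report_table(res$descriptives$table,
                     file.path(out_dir, "descriptives.csv"))
  write_report_table(res$yearly, file.path(out_dir, "yearly_counts.csv"))
  for (lv in names(res$signals))
    write_report_table(res$signals[[lv]]$scores,
                       file.path(out_dir, paste0("signals_", lv, ".csv")))
  if (!is.null(res$km))
    write_report_table(res$km$curves, file.path(out_dir, "km_curves.csv"))
  write_report_table(res$tto$tto, file.path(out_dir, "tto_records.csv"))
  write_report_table(as.data.frame(res$outcomes),
                     file.path(out_dir, "outcomes.csv"))
  for (nm in names(res$outcome_tests))
    write_report_table(res$outcome_tests[[nm]],
                       file.path(out_dir, paste0("outcome_tests_", nm,
                                                 ".csv")))
  cfg <- res$config
  cfg$criteria <- unclass(cfg$criteria)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null")
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- res$manifest
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("faersig pipeline result\n")
  cat(sprintf("  reports kept: %d; cases: %d\n",
              x$manifest$n_reports_kept, x$manifest$n_cases))
  for (lv in names(x$signals))
    cat(sprintf("  %s-level joint signals: %d/%d\n", lv,
                sum(x$signals[[lv]]$scores$joint_significant),
                nrow(x$signals[[lv]]$scores)))
  if (!is.null(x$km)) print(x$km)
  if (!is.null(x$logrank)) print(x$logrank)
  print(x$outcomes)
  invisible(x)
}
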