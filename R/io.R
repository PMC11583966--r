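cohort_csv_columns <- c("consultation_id", "clinic_id", "date", "m", "d", "y",
                        "dipstick_used", "microscopy_used", "tested")

#' Write a cohort to CSV
#'
#' One header row; columns \code{consultation_id, clinic_id, date, m, d, y,
#' dipstick_used, microscopy_used, tested}; ISO-8601 dates; missing optional
#' fields written as empty strings.  Risk predictions are written with 17
#' significant digits so that \code{\link{read_cohort}} round-trips them
#' exactly.
#'
#' @param cohort Cohort.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort_data(cohort)
  out <- data.frame(
    consultation_id = as.character(df$consultation_id),
    clinic_id = ifelse(is.na(df$clinic_id), "", as.character(df$clinic_id)),
    date = ifelse(is.na(df$date), "", format(as.Date(df$date), "%Y-%m-%d")),
    m = sprintf("%.17g", df$m),
    d = df$d,
    y = df$y,
    dipstick_used = ifelse(is.na(df$dipstick_used), "", df$dipstick_used),
    microscopy_used = ifelse(is.na(df$microscopy_used), "",
                             df$microscopy_used),
    tested = ifelse(is.na(df$tested), "", df$tested),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads the schema written by \code{\link{write_cohort}}, validating every
#' row against the consultation invariants and reporting the row numbers of
#' violations.  Optional columns may be absent entirely; empty cells become
#' \code{NA}.
#'
#' @param path CSV file path.
#' @return An \code{abx_cohort} (with \code{config = NULL}).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_with("abx_io_error", "cohort file not found: %s", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  for (col in c("consultation_id", "m", "d", "y")) {
    if (is.null(raw[[col]])) {
      stop_with("abx_validation_error",
                "cohort file lacks required column '%s'", col)
    }
  }
  parse_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  df <- data.frame(
    consultation_id = raw$consultation_id,
    clinic_id = if (is.null(raw$clinic_id)) NA_character_ else
      ifelse(raw$clinic_id == "", NA, raw$clinic_id),
    date = if (is.null(raw$date)) as.Date(NA) else
      as.Date(ifelse(raw$date == "", NA, raw$date)),
    m = parse_num(raw$m),
    d = parse_num(raw$d),
    y = parse_num(raw$y),
    dipstick_used = if (is.null(raw$dipstick_used)) NA_real_ else
      parse_num(raw$dipstick_used),
    microscopy_used = if (is.null(raw$microscopy_used)) NA_real_ else
      parse_num(raw$microscopy_used),
    tested = if (is.null(raw$tested)) NA_real_ else parse_num(raw$tested),
    stringsAsFactors = FALSE
  )
  validate_cohort(new_cohort(df))
}

#' Read or write a generator configuration
#'
#' Serialises an \code{abx_generator_config} to YAML (\code{.yml}/
#' \code{.yaml}) or JSON (anything else), and back, losslessly.
#'
#' @param config An \code{abx_generator_config}.
#' @param path File path; the extension selects the format.
#' @return \code{write_generator_config} returns \code{path} invisibly;
#'   \code{read_generator_config} returns the configuration.
#' @export
write_generator_config <- function(config, path) {
  validate_generator_config(config)
  payload <- unclass(config)
  attr(payload, "moments") <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path, precision = 17)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) {
    stop_with("abx_io_error", "config file not found: %s", path)
  }
  payload <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(generator_config, payload)
}

report_to_list <- function(report) {
  if (is.null(report)) return(NULL)
  out <- list(
    counts = list(
      baseline = as.list(stats::setNames(report$counts$baseline,
                                         report$counts$quantity)),
      counterfactual = as.list(stats::setNames(report$counts$counterfactual,
                                               report$counts$quantity))
    ),
    pct = as.list(report$pct)
  )
  if (!is.null(report$ci)) {
    out$ci <- list(low = as.list(report$ci["low", ]),
                   high = as.list(report$ci["high", ]))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: generate (or load) a cohort, compute
#' prediction-quality and information diagnostics, fit the requested
#' policies, evaluate them with bootstrap confidence intervals, and write
#' all artefacts to \code{output_dir}: the cohort CSV, the generator
#' configuration, bin profiles (overall, treated, untreated), a
#' machine-readable \code{results.json} and a provenance log with the seed
#' and a content hash of the configuration.  Re-running with an identical
#' configuration reproduces the outputs bit for bit.
#'
#' @param config An \code{abx_generator_config} used to simulate the cohort;
#'   ignored when \code{cohort_path} is given.
#' @param cohort_path Optional path to an existing cohort CSV.
#' @param policy_kind One of \code{"both"}, \code{"automation"},
#'   \code{"delegation"}.
#' @param bootstrap An \code{abx_bootstrap_spec}.
#' @param bin_size Bin size for the risk profiles.
#' @param output_dir Directory for all outputs (created if needed).
#' @param seed Optional integer overriding the configuration seed.
#' @return The results list, invisibly.
#' @export
run_pipeline <- function(config = generator_config(),
                         cohort_path = NULL,
                         policy_kind = c("both", "automation", "delegation"),
                         bootstrap = bootstrap_spec(),
                         bin_size = 100,
                         output_dir = "abxdelegate-results",
                         seed = NULL) {
  policy_kind <- match.arg(policy_kind)
  if (!is.null(cohort_path) && !is.null(config)) {
    config <- NULL  # exactly one source of consultations
  }
  if (!is.null(config)) validate_generator_config(config)  # before any output
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_with("abx_pipeline_error", "stage '%s' failed: %s",
                name, conditionMessage(e))
    })
  }
  cohort <- if (!is.null(cohort_path)) {
    stage("load_cohort", read_cohort(cohort_path))
  } else {
    stage("generate_cohort", generate_cohort(config, seed = seed))
  }
  df <- cohort_data(cohort)
  used_seed <- if (!is.null(cohort_path)) NA_integer_ else
    as.integer(seed %||% config$seed)

  stage("write_cohort", write_cohort(cohort, file.path(output_dir, "cohort.csv")))
  if (!is.null(config)) {
    stage("write_config",
          write_generator_config(config, file.path(output_dir, "config.yaml")))
  }

  metrics <- stage("metrics", list(
    n = nrow(df),
    bacterial_rate = mean(df$y),
    prescribing_rate = mean(df$d),
    prescribe_given_positive = mean(df$d[df$y == 1]),
    prescribe_given_negative = mean(df$d[df$y == 0]),
    auc = auc_mann_whitney(df$m, df$y),
    mean_private_info = mean(private_info(df$m, df$d, df$y))
  ))

  bins <- stage("risk_bins", risk_bins(cohort, bin_size))
  for (nm in c("overall", "treated", "untreated")) {
    if (!is.null(bins[[nm]])) {
      utils::write.csv(bins[[nm]],
                       file.path(output_dir, sprintf("bins_%s.csv", nm)),
                       row.names = FALSE)
    }
  }

  results <- list(metrics = metrics)
  if (policy_kind %in% c("both", "automation")) {
    pol <- stage("optimize_automation", optimize_automation(cohort))
    rep <- stage("evaluate_automation",
                 bootstrap_policy_ci(cohort, pol, bootstrap))
    results$automation <- c(list(k = pol$k, objective = pol$objective,
                                 constraint = pol$constraint),
                            report_to_list(rep))
  }
  if (policy_kind %in% c("both", "delegation")) {
    pol <- stage("optimize_delegation", optimize_delegation(cohort))
    rep <- stage("evaluate_delegation",
                 bootstrap_policy_ci(cohort, pol, bootstrap))
    results$delegation <- c(list(k_L = pol$k_L, k_H = pol$k_H,
                                 objective = pol$objective,
                                 constraint = pol$constraint),
                            report_to_list(rep))
  }

  jsonlite::write_json(results, file.path(output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("seed: %s", used_seed),
    sprintf("config_hash: %s",
            content_hash(if (is.null(config)) cohort_path else unclass(config))),
    sprintf("n_consultations: %d", nrow(df)),
    sprintf("policy_kind: %s", policy_kind),
    sprintf("bootstrap_samples: %d", bootstrap$n_samples)
  )
  writeLines(log_lines, file.path(output_dir, "log.txt"))
  invisible(results)
}
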