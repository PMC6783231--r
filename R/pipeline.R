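#' Read a survey CSV
#'
#' Reads a respondent-level survey table: a header row, one or more
#' non-negative integer outcome columns, and categorical covariate columns
#' with string labels. Validation failures cite the offending row or column.
#'
#' @param path Path to a CSV file.
#' @param outcome Outcome column name(s) expected to hold non-negative
#'   integer counts. Default `"y"`.
#' @return A tibble; outcome columns are integer, covariates character.
#' @export
read_survey_csv <- function(path, outcome = "y") {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "zicount_io_error")
  }
  if (file.size(path) == 0L) {
    abort(paste0("no data: ", path, " is empty"), class = "zicount_io_error")
  }
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  if (nrow(data) == 0L) {
    abort(paste0("no data: ", path, " has a header but no rows"),
          class = "zicount_io_error")
  }
  for (oc in outcome) {
    if (!oc %in% names(data)) {
      abort(paste0("outcome column '", oc, "' not found in ", path),
            class = "zicount_io_error")
    }
    raw <- data[[oc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) | num < 0 | num != floor(num))
    if (length(bad)) {
      abort(
        paste0("outcome '", oc, "': value '", raw[bad[1]],
               "' at row ", bad[1], " is not a non-negative integer"),
        class = "zicount_io_error"
      )
    }
    data[[oc]] <- as.integer(num)
  }
  data
}

#' Write a survey CSV (with optional config and seed metadata)
#'
#' Writes the dataset as plain CSV. When a [generator_config()] is supplied,
#' the configuration is written alongside as YAML and the seed is recorded in
#' an adjacent `<path>.meta.yaml` file, so a simulated dataset is fully
#' re-creatable from its files.
#'
#' @param data The survey tibble.
#' @param path Output CSV path.
#' @param config Optional `generator_config` that produced the data.
#' @param seed Optional seed actually used (defaults to the config's seed).
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(data, path, config = NULL, seed = NULL) {
  readr::write_csv(data, path, progress = FALSE)
  if (!is.null(config)) {
    cfg_path <- paste0(sub("\\.csv$", "", path), "_config.yaml")
    write_generator_yaml(config, cfg_path)
    meta <- list(
      seed = as.integer(seed %||% config$seed),
      n = nrow(data),
      family = config$family,
      config = basename(cfg_path)
    )
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

## ---- YAML serialization ----------------------------------------------------

#' Serialize a generator config or design spec to YAML
#'
#' @param config A [generator_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_generator_yaml <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  x <- list(
    family = config$family,
    n = config$n,
    seed = config$seed,
    dispersion = config$dispersion,
    truncate_at = config$truncate_at,
    schema = lapply(config$schema, function(v) {
      list(levels = v$levels, probs = v$probs, reference = v$reference)
    }),
    count_terms = config$design$count_terms,
    zero_terms = config$design$zero_terms,
    beta = as.list(config$beta),
    gamma = if (!is.null(config$gamma)) as.list(config$gamma)
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_yaml
#' @export
read_generator_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  generator_config(
    schema = covariate_schema(x$schema),
    family = x$family,
    beta = unlist(x$beta),
    gamma = if (!is.null(x$gamma)) unlist(x$gamma),
    dispersion = x$dispersion,
    n = x$n, seed = x$seed,
    count_terms = x$count_terms, zero_terms = x$zero_terms,
    truncate_at = x$truncate_at
  )
}

#' Serialize a design spec to/from YAML
#'
#' @param design A [design_spec()].
#' @param path YAML path.
#' @return `path` invisibly (write) or a [design_spec()] (read).
#' @export
write_design_yaml <- function(design, path) {
  stopifnot(is_design_spec(design))
  x <- list(
    variables = lapply(design$variables, function(v) {
      list(levels = v$levels, reference = v$reference)
    }),
    count_terms = design$count_terms,
    zero_terms = design$zero_terms,
    count_intercept = design$count_intercept,
    zero_intercept = design$zero_intercept
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  design_spec(
    variables = x$variables,
    count_terms = x$count_terms, zero_terms = x$zero_terms,
    count_intercept = x$count_intercept %||% TRUE,
    zero_intercept = x$zero_intercept %||% TRUE
  )
}

## ---- pipeline --------------------------------------------------------------

#' Configure an end-to-end analysis run
#'
#' Exactly one input mode is used: `simulate` (draw a synthetic survey from
#' generator configs) or `load` (read an existing CSV). In simulate mode,
#' `generators` is a named list mapping each outcome column to its
#' [generator_config()]; covariates are sampled once from the first
#' generator's schema and each outcome is drawn on top of them, mirroring a
#' survey where one respondent table carries several count outcomes.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param input CSV path (load mode).
#' @param generators Named list of [generator_config()] objects, one per
#'   outcome (simulate mode). Defaults to
#'   `list(y = luts_like_preset(), y_bother = bother_like_preset())`.
#' @param design A [design_spec()] or the path to its YAML; defaults (simulate
#'   mode) to the first generator's design.
#' @param outcomes Outcome column name(s) to analyse. Defaults to the
#'   generator names (simulate mode); required in load mode.
#' @param families Families to compare. Default all four.
#' @param n Sample size (simulate mode). Default: first generator's `n`.
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory for result files.
#' @param verbose Print progress? Default `FALSE`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "load"), input = NULL,
                            generators = NULL, design = NULL, outcomes = NULL,
                            families = c("poisson", "nb", "zip", "zinb"),
                            n = NULL, seed = 1L, out_dir = tempfile("zicount_run_"),
                            verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "load") {
    if (is.null(input)) {
      abort("load mode needs `input` (a CSV path)", class = "zicount_config_error")
    }
    if (is.null(design)) {
      abort("load mode needs `design` (a design_spec or YAML path)",
            class = "zicount_config_error")
    }
    if (is.null(outcomes)) {
      abort("load mode needs `outcomes`", class = "zicount_config_error")
    }
  } else {
    if (!is.null(input)) {
      abort("simulate mode must not set `input`: exactly one input mode",
            class = "zicount_config_error")
    }
    generators <- generators %||%
      list(y = luts_like_preset(), y_bother = bother_like_preset())
    if (is.null(names(generators)) || any(names(generators) == "")) {
      abort("`generators` must be a named list (names are outcome columns)",
            class = "zicount_config_error")
    }
    outcomes <- outcomes %||% names(generators)
  }
  if (is.character(design)) design <- read_design_yaml(design)
  structure(
    list(mode = mode, input = input, generators = generators, design = design,
         outcomes = outcomes, families = families, n = n,
         seed = as.integer(seed), out_dir = out_dir, verbose = isTRUE(verbose)),
    class = "pipeline_config"
  )
}

#' Run the full comparison pipeline and write its result tables
#'
#' For each outcome: fits the four families, runs the O and Vuong diagnostics,
#' selects the best-fitting family, and writes (per outcome) a fit-statistics
#' table, the logit-section odds-ratio table and count-section beta table of
#' the selected (or best available zero-inflated) model, a diagnostics
#' summary, and a machine-readable JSON report. Identical config and seed
#' produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list (per outcome) of `zicount_comparison`
#'   objects, with attribute `files` listing everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (config$verbose) message(...)

  if (config$mode == "simulate") {
    gens <- config$generators
    n <- config$n %||% gens[[1]]$n
    say("simulating ", n, " respondents")
    data <- sample_covariates(gens[[1]]$schema, n, seed = config$seed)
    for (oc in names(gens)) {
      data <- simulate_outcome(data, gens[[oc]], outcome = oc, seed = NULL)
    }
    design <- config$design %||% gens[[1]]$design
    write_survey_csv(data, file.path(config$out_dir, "survey.csv"),
                     config = gens[[1]], seed = config$seed)
  } else {
    data <- read_survey_csv(config$input, outcome = config$outcomes)
    design <- config$design
    # rows with missing covariate values cannot be dummy-coded; drop and log
    used <- unique(c(config$outcomes, intersect(
      c(design$count_terms, design$zero_terms), names(data))))
    complete <- stats::complete.cases(data[, used, drop = FALSE])
    if (any(!complete)) {
      say("dropping ", sum(!complete), " rows with missing values")
      data <- data[complete, , drop = FALSE]
    }
  }

  files <- character(0)
  reports <- list()
  for (oc in config$outcomes) {
    say("comparing models for outcome '", oc, "'")
    cmp <- compare_models(data, design, outcome = oc, families = config$families)
    reports[[oc]] <- cmp
    files <- c(files, write_report(cmp, config$out_dir, prefix = oc,
                                   seed = config$seed))
  }
  out <- reports
  attr(out, "files") <- files
  invisible(out)
}

#' Write the result tables of one model comparison
#'
#' Emits `<prefix>_fit_stats.csv`, `<prefix>_logit_or.csv`,
#' `<prefix>_count_beta.csv`, `<prefix>_diagnostics.csv` and
#' `<prefix>_report.json` into `dir`. Coefficient tables come from the
#' selected family when it is zero-inflated, otherwise from the best
#' available converged fit (the logit table is then empty).
#'
#' @param cmp A `zicount_comparison` (see [compare_models()]).
#' @param dir Output directory.
#' @param prefix Filename prefix, usually the outcome name.
#' @param seed Seed to record in the JSON report.
#' @return Character vector of files written.
#' @export
write_report <- function(cmp, dir, prefix = "y", seed = NULL) {
  stopifnot(inherits(cmp, "zicount_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(nm) file.path(dir, paste0(prefix, "_", nm))

  readr::write_csv(cmp$fit_stats, path("fit_stats.csv"), progress = FALSE)

  report_fam <- if (!is.na(cmp$selected)) cmp$selected else {
    ok <- cmp$fit_stats$family[cmp$fit_stats$converged]
    if (length(ok)) ok[[length(ok)]] else NA_character_
  }
  ct <- NULL
  if (!is.na(report_fam)) {
    ct <- coefficient_table(cmp$fits[[report_fam]])
    readr::write_csv(ct[ct$section == "logit", ], path("logit_or.csv"),
                     progress = FALSE)
    readr::write_csv(ct[ct$section == "count", ], path("count_beta.csv"),
                     progress = FALSE)
  }

  diag <- dplyr::bind_rows(
    dplyr::mutate(cmp$o_test, test = "overdispersion_O", .before = 1),
    if (!is.null(cmp$vuong)) {
      tibble(test = "vuong_zinb_vs_nb", statistic = cmp$vuong$statistic,
             n = cmp$vuong$n, p_value = cmp$vuong$p_value)
    }
  )
  readr::write_csv(diag, path("diagnostics.csv"), progress = FALSE)

  report <- list(
    outcome = cmp$outcome,
    n_obs = cmp$n_obs,
    seed = seed,
    fit_stats = cmp$fit_stats,
    o_test = cmp$o_test,
    vuong = cmp$vuong,
    selected = cmp$selected,
    agreement = cmp$agreement,
    rationale = cmp$rationale,
    coefficients = ct
  )
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = 12, na = "null", pretty = TRUE)
  vapply(c("fit_stats.csv", "logit_or.csv", "count_beta.csv",
           "diagnostics.csv", "report.json"), path, "")
}
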