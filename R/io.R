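#' Read a recording TSV/CSV into a raw_recording
#'
#' Expects columns `time_s`, `detector`, `wavelength_nm`, `intensity`
#' (tab- or comma-delimited, header required).
#'
#' @param file path.
#' @param baseline_window passed to [raw_recording()].
#' @return a [raw_recording()].
#' @export
read_recording <- function(file, baseline_window = c(0, 600)) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  raw_recording(read.delim(file, sep = sep), baseline_window = baseline_window)
}

#' Read a reference oximeter trace (TSV with time_s, oxy_pct)
#' @param file path.
#' @return data frame.
#' @export
read_reference <- function(file) {
  d <- read.delim(file)
  stopifnot(all(c("time_s", "oxy_pct") %in% names(d)))
  d
}

#' Packaged subject metadata (demographics and heart-rate summaries)
#'
#' The bundled example cohort: six pediatric patients and six adult
#' controls with their demographics and the group heart-rate summaries
#' (maximum average heart rate during baseline and maximum during the
#' 30-min tilt).
#'
#' @param file CSV path; defaults to the packaged table.
#' @return data frame, one row per subject.
#' @export
read_subjects <- function(file = system.file("extdata", "hut_subjects.csv",
                                             package = "nirstilt")) {
  read.csv(file)
}

#' Write a concentration series as TSV
#' @param conc a `concentration_series`.
#' @param file output path.
#' @export
write_concentrations <- function(conc, file) {
  write.table(as.data.frame(conc), file, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' Default pipeline configuration
#'
#' All tunable pipeline parameters with their defaults; the structure that
#' [run_pipeline()] validates and consumes, and that the command-line
#' `show-config` prints.
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    seed = 42,
    out_dir = "nirstilt-run",
    stages = c("generate", "process", "analyze"),
    cohort = list(n_per_group = 6, sample_rate = 1),
    noise = list(intensity_cv = 0.005, amplitude_sdlog = 0.1,
                 reference_sd_pct = 0.5),
    pathlength = list(separation_cm = 2.0, dpf = 4.0),
    extinction = list(file = system.file("extdata",
                                         "hemoglobin_extinction.tsv",
                                         package = "nirstilt")),
    analysis = list(alpha = 0.01, detector = "mean"))
}

# schema: required leaves and a type predicate for each
config_schema <- function() {
  list("seed" = is.numeric,
       "out_dir" = is.character,
       "cohort.n_per_group" = is.numeric,
       "cohort.sample_rate" = is.numeric,
       "noise.intensity_cv" = is.numeric,
       "noise.amplitude_sdlog" = is.numeric,
       "noise.reference_sd_pct" = is.numeric,
       "pathlength.separation_cm" = is.numeric,
       "pathlength.dpf" = is.numeric,
       "extinction.file" = is.character,
       "analysis.alpha" = is.numeric)
}

get_path <- function(x, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(x) || is.null(x[[p]])) return(NULL)
    x <- x[[p]]
  }
  x
}

#' Validate a pipeline configuration
#'
#' Checks every required field of the schema; all violations are reported
#' together, each named by its field path.
#'
#' @param config nested list (e.g. from [default_config()] or a YAML file).
#' @return the config, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(config) {
  schema <- config_schema()
  bad <- character(0)
  for (field in names(schema)) {
    v <- get_path(config, field)
    if (is.null(v)) bad <- c(bad, paste0("missing field: ", field))
    else if (!schema[[field]](v)) bad <- c(bad, paste0("wrong type: ", field))
  }
  if (length(bad))
    stop("invalid configuration:\n  ", paste(bad, collapse = "\n  "))
  invisible(config)
}

#' Load a configuration from YAML or JSON, filling defaults
#'
#' @param file path to a YAML or JSON config; fields not given fall back
#'   to [default_config()].
#' @return validated config list.
#' @export
load_config <- function(file) {
  user <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  validate_config(merge_lists(default_config(), user))
}

#' Run the generate -> process -> analyze pipeline
#'
#' Executes the configured stages: synthetic cohort generation, inversion
#' of every recording into concentration series, and the group-level tilt
#' analysis. Writes all outputs plus a run manifest (seeds, parameters,
#' file checksums, versions) under `config$out_dir`; identical
#' configuration and seed reproduce identical outputs.
#'
#' @param config nested list as from [default_config()], or a path to a
#'   YAML/JSON config file.
#' @return a `pipeline_run` list: `result` (the [analyze_cohort()] output),
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- load_config(config)
  validate_config(config)
  t0 <- Sys.time()
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  if (is.null(stages)) stages <- c("generate", "process", "analyze")

  eps <- default_extinction(config$extinction$file)
  path <- pathlength_spec(config$pathlength$separation_cm,
                          config$pathlength$dpf)
  spec <- cohort_spec(n_per_group = config$cohort$n_per_group,
                      sample_rate = config$cohort$sample_rate,
                      seed = config$seed,
                      noise = noise_model(config$noise$intensity_cv,
                                          config$noise$amplitude_sdlog,
                                          config$noise$reference_sd_pct),
                      eps = eps, path = path)
  timings <- list()
  cohort <- NULL; processed <- NULL; result <- NULL

  if ("generate" %in% stages) {
    tg <- system.time(cohort <- generate_cohort(spec))["elapsed"]
    cdir <- file.path(out_dir, "cohort")
    if (!file.exists(file.path(cdir, "manifest.json")))
      write_cohort(cohort, cdir)
    timings$generate_s <- unname(tg)
  }
  if ("process" %in% stages) {
    if (is.null(cohort)) stop("'process' stage requires 'generate' (or a cohort)")
    tp <- system.time(
      processed <- process_cohort(cohort, detector = config$analysis$detector)
    )["elapsed"]
    cdir <- file.path(out_dir, "concentrations")
    dir.create(cdir, showWarnings = FALSE)
    for (nm in names(processed))
      write_concentrations(processed[[nm]]$conc,
                           file.path(cdir, paste0(nm, "_concentrations.tsv")))
    timings$process_s <- unname(tp)
  }
  if ("analyze" %in% stages) {
    if (is.null(processed)) stop("'analyze' stage requires 'process'")
    ta <- system.time(
      result <- analyze_cohort(processed, alpha = config$analysis$alpha)
    )["elapsed"]
    jsonlite::write_json(
      list(auc_group = result$auc_group,
           segment_means = result$segment_means,
           slopes = result$slopes,
           tests = lapply(result$tests, function(x) x[c("t", "df", "p",
                                                        "significant")]),
           hr_criterion = result$hr_criterion,
           device_r2 = result$device_r2),
      file.path(out_dir, "cohort_result.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows")
    write.table(result$auc_group, file.path(out_dir, "auc_group.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    timings$analyze_s <- unname(ta)
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "run_manifest.json"))
  checksums <- tools::md5sum(files)
  names(checksums) <- sub(paste0("^", out_dir, "/?"), "", names(checksums))
  manifest <- list(command = paste(stages, collapse = " -> "),
                   seed = config$seed,
                   config = config[setdiff(names(config), "out_dir")],
                   checksums = as.list(checksums),
                   timings_s = timings,
                   tool_version = as.character(packageVersion("nirstilt")),
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(result = result, manifest = manifest, out_dir = out_dir),
            class = "pipeline_run")
}
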