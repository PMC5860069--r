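# Reproducible runs: a validated configuration object, per-step run
# functions (simulate / classify / rain / quantify / pipeline), and JSON
# sidecar metadata sufficient to re-run any step. These back the command-line
# interface in inst/cli/dropgate.R.

#' Default run configuration
#'
#' Every setting has a documented default; a fully-defaulted configuration
#' is valid. Sections: `mode` (gating method), `thresholds`, `kmeans`,
#' `knn`, `rain`, `quant`, `sim` (synthetic-series parameters), `seed`,
#' `log_level`.
#'
#' @return Nested named list of defaults.
#' @export
default_run_config <- function() {
  list(
    mode = "kmeans",
    thresholds = list(ch1 = 6789, ch2 = 3000),
    kmeans = list(centres = NULL, max_iter = 100L, tol = 1e-6,
                  standardize = FALSE),
    knn = list(k = 1L, min_vote_fraction = 0.51, train_well = NULL),
    rain = list(method = "none", n_sd = 5, max_distance = 30),
    quant = list(droplet_volume_nl = 0.85, exclude_rain = TRUE),
    sim = list(mutant_fraction = 0.05,
               total_copies_series = c(15, 60, 240, 960),
               replicates = 3L, n_droplets = 20000L, rain_fraction = 0.002,
               shear = 0.3, cluster_sd = 300),
    seed = 1L,
    log_level = "info")
}

.merge_config <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    if (!key %in% names(defaults)) {
      stop(sprintf("unknown config key '%s%s'; valid keys here: %s",
                   path, key, paste(names(defaults), collapse = ", ")),
           call. = FALSE)
    }
    val <- overrides[[key]]
    if (is.list(defaults[[key]]) && is.list(val)) {
      defaults[[key]] <- .merge_config(defaults[[key]], val,
                                       paste0(path, key, "."))
    } else {
      defaults[key] <- list(val)
    }
  }
  defaults
}

#' Build a run configuration
#'
#' Merges overrides onto [default_run_config()], rejecting unknown keys with
#' a message listing the valid ones.
#'
#' @param overrides Nested named list of settings to override.
#' @return A validated configuration list.
#' @export
#' @examples
#' run_config(list(mode = "threshold", rain = list(method = "sd")))$mode
run_config <- function(overrides = list()) {
  cfg <- .merge_config(default_run_config(), overrides)
  if (!cfg$mode %in% c("threshold", "kmeans", "knn")) {
    stop("config mode must be one of threshold, kmeans, knn", call. = FALSE)
  }
  if (!cfg$rain$method %in% c("none", "sd", "mahalanobis")) {
    stop("config rain.method must be one of none, sd, mahalanobis",
         call. = FALSE)
  }
  cfg
}

#' Read a run configuration from file
#'
#' Accepts a YAML or JSON configuration file, or a sidecar metadata file
#' written by a previous run (its `config` element is used), and validates
#' it via [run_config()].
#'
#' @param path Configuration file path (`.json` or YAML).
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$config)) raw <- raw$config
  run_config(raw)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

.log <- function(config, msg) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[dropgate %s] seed=%s config=%s | %s",
                  as.character(utils::packageVersion("dropgate")),
                  format(config$seed), .config_hash(config), msg))
}

.write_sidecar <- function(path, command, input, output, config) {
  jsonlite::write_json(
    list(tool = "dropgate",
         version = as.character(utils::packageVersion("dropgate")),
         command = command, input = input, output = output,
         config_hash = .config_hash(config), config = config),
    path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

.write_amplitude_csv <- function(table, path) {
  lines <- c("Ch1 Amplitude,Ch2 Amplitude",
             if (nrow(table)) paste(.num_to_text(table$ch1_amplitude),
                                    .num_to_text(table$ch2_amplitude),
                                    sep = ","))
  writeLines(lines, path)
  invisible(path)
}

.input_files <- function(input, pattern) {
  if (length(input) == 1L && dir.exists(input)) {
    files <- sort(list.files(input, pattern = pattern, full.names = TRUE))
    if (!length(files)) {
      stop(sprintf("no files matching '%s' in '%s'", pattern, input),
           call. = FALSE)
    }
    files
  } else {
    missing <- input[!file.exists(input)]
    if (length(missing)) {
      stop("input not found: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    input
  }
}

.require_class_column <- function(paths) {
  for (p in paths) {
    hdr <- .norm_header(strsplit(readLines(p, n = 1L), ",", fixed = TRUE)[[1L]])
    if (!any(hdr %in% c("class", "cluster"))) {
      stop(sprintf("'%s' has no Class column; classify first", p),
           call. = FALSE)
    }
  }
  invisible(paths)
}

# Gate a loaded plate according to a config (classification only).
.classify_plate <- function(plate, config) {
  centres <- config$kmeans$centres
  if (!is.null(centres) && !is.matrix(centres)) {
    centres <- matrix(unlist(centres), ncol = 2L, byrow = TRUE)
  }
  train <- NULL
  if (config$mode == "knn") {
    tw <- config$knn$train_well
    if (is.null(tw) || !tw %in% names(plate)) {
      stop("knn mode needs knn.train_well naming a labelled well of the input",
           call. = FALSE)
    }
    train <- plate[[tw]]
    train <- train[as.character(train$label) %in% .CORE_CLASSES, ,
                   drop = FALSE]
  }
  droplet_gate(plate, method = config$mode,
               thresholds = unlist(config$thresholds),
               centres = centres,
               max_iter = config$kmeans$max_iter, tol = config$kmeans$tol,
               standardize = isTRUE(config$kmeans$standardize),
               train = train, k = config$knn$k,
               min_vote_fraction = config$knn$min_vote_fraction,
               rain = "none",
               droplet_volume_ul = config$quant$droplet_volume_nl * 1e-3,
               exclude_rain = isTRUE(config$quant$exclude_rain))
}

#' Simulate a synthetic plate to disk
#'
#' Writes one amplitude CSV per well (instrument dialect: `Ch1 Amplitude`,
#' `Ch2 Amplitude`), a ground-truth CSV (`Well`, `DropletIndex`,
#' `TrueClass`), and a JSON sidecar with the full configuration.
#'
#' @param output_dir Output directory (created if needed).
#' @param config A [run_config()]; the `sim` section and `seed` drive the
#'   series design.
#' @return Invisibly, the simulated [ddpcr_plate()].
#' @export
run_simulate <- function(output_dir, config = run_config()) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  s <- config$sim
  plate <- simulate_kras_series(
    mutant_fraction = s$mutant_fraction,
    total_copies_series = s$total_copies_series,
    replicates = s$replicates, seed = config$seed,
    n_droplets = s$n_droplets,
    droplet_volume_ul = config$quant$droplet_volume_nl * 1e-3,
    cluster_sd = s$cluster_sd, shear = s$shear,
    rain_fraction = s$rain_fraction)
  for (w in names(plate)) {
    .write_amplitude_csv(plate[[w]],
                         file.path(output_dir,
                                   sprintf("SIM_%s_Amplitude.csv", w)))
  }
  truth <- do.call(rbind, lapply(names(plate), function(w) {
    data.frame(Well = w, DropletIndex = seq_len(nrow(plate[[w]])),
               TrueClass = as.character(plate[[w]]$label),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth, file.path(output_dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  .write_sidecar(file.path(output_dir, "simulate.run.json"), "simulate",
                 input = list(), output = output_dir, config = config)
  .log(config, sprintf("simulated %d wells into %s", length(plate),
                       output_dir))
  invisible(plate)
}

#' Classify a directory of amplitude files
#'
#' Loads every `*_Amplitude.csv` (or the explicitly listed files), gates the
#' plate jointly with the configured method, and writes one
#' `<well>_Classified.csv` per well plus a sidecar.
#'
#' @param input Directory of amplitude CSVs, or a vector of file paths.
#' @param output_dir Output directory.
#' @param config A [run_config()].
#' @return Invisibly, the fitted [droplet_gate()].
#' @export
run_classify <- function(input, output_dir, config = run_config()) {
  files <- .input_files(input, "_Amplitude\\.csv$")
  plate <- load_plate(files)
  gate <- .classify_plate(plate, config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (w in names(gate$plate)) {
    write_classified_csv(gate$plate[[w]],
                         file.path(output_dir,
                                   sprintf("%s_Classified.csv", w)))
  }
  .write_sidecar(file.path(output_dir, "classify.run.json"), "classify",
                 input = files, output = output_dir, config = config)
  .log(config, sprintf("classified %d wells (%s) into %s",
                       length(gate$plate), config$mode, output_dir))
  invisible(gate)
}

#' Apply rain refinement to classified files
#'
#' Loads `*_Classified.csv` files, pools the plate, relabels ambiguous
#' droplets `Rain` by the configured method, and writes refined per-well
#' CSVs.
#'
#' @param input Directory of classified CSVs, or file paths.
#' @param output_dir Output directory.
#' @param config A [run_config()]; `rain$method` of `"none"` copies labels
#'   through unchanged.
#' @return Invisibly, the refined [ddpcr_plate()].
#' @export
run_rain <- function(input, output_dir, config = run_config()) {
  files <- .input_files(input, "_Classified\\.csv$")
  .require_class_column(files)
  plate <- load_plate(files)
  sizes <- vapply(plate, nrow, integer(1))
  pooled <- do.call(rbind, lapply(unname(plate), as.data.frame))
  pooled <- droplet_table(pooled$ch1_amplitude, pooled$ch2_amplitude,
                          pooled$label)
  refined <- switch(config$rain$method,
    none = pooled,
    sd = sd_rain(pooled, n_sd = config$rain$n_sd),
    mahalanobis = mahalanobis_rain(pooled,
                                   max_distance = config$rain$max_distance))
  idx <- split(seq_len(nrow(refined)),
               factor(rep(names(plate), sizes), levels = names(plate)))
  out <- ddpcr_plate(lapply(idx, function(i) refined[i, , drop = FALSE]))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (w in names(out)) {
    write_classified_csv(out[[w]],
                         file.path(output_dir,
                                   sprintf("%s_Classified.csv", w)))
  }
  .write_sidecar(file.path(output_dir, "rain.run.json"), "rain",
                 input = files, output = output_dir, config = config)
  .log(config, sprintf("rain refinement (%s) on %d wells into %s",
                       config$rain$method, length(out), output_dir))
  invisible(out)
}

#' Quantify classified files into a plate summary
#'
#' Loads classified per-well CSVs (a missing `Class` column is a format
#' error), computes per-well Poisson concentration estimates and fractional
#' abundance, and writes the plate summary CSV plus a JSON sidecar
#' sufficient to re-run the step.
#'
#' @param input Directory of classified CSVs, or file paths.
#' @param output_path Path of the summary CSV to write.
#' @param config A [run_config()].
#' @return Invisibly, the summary `data.frame` (full precision).
#' @export
run_quantify <- function(input, output_path, config = run_config()) {
  files <- .input_files(input, "_Classified\\.csv$")
  .require_class_column(files)
  plate <- load_plate(files)
  summary <- summarize_plate(plate,
                             V_ul = config$quant$droplet_volume_nl * 1e-3,
                             exclude_rain = isTRUE(config$quant$exclude_rain))
  dir.create(dirname(output_path), recursive = TRUE, showWarnings = FALSE)
  write_plate_summary_csv(summary, output_path)
  .write_sidecar(paste0(output_path, ".run.json"), "quantify",
                 input = files, output = output_path, config = config)
  .log(config, sprintf("quantified %d wells into %s", nrow(summary),
                       output_path))
  invisible(summary)
}

#' Run classify, rain and quantify in sequence
#'
#' @param input Directory of amplitude CSVs, or file paths.
#' @param output_dir Output directory; classified files go to
#'   `<output_dir>/classified`, refined files to `<output_dir>/refined`, and
#'   the summary to `<output_dir>/summary.csv`.
#' @param config A [run_config()].
#' @return Invisibly, the summary `data.frame`.
#' @export
run_pipeline <- function(input, output_dir, config = run_config()) {
  classified <- file.path(output_dir, "classified")
  refined <- file.path(output_dir, "refined")
  run_classify(input, classified, config)
  run_rain(classified, refined, config)
  run_quantify(refined, file.path(output_dir, "summary.csv"), config)
}
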