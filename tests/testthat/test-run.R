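# End-to-end runs of the config-driven pipeline layer (the CLI backend).

quiet_cfg <- function(overrides = list()) {
  run_config(.merge(list(log_level = "quiet",
                         sim = list(n_droplets = 1500,
                                    total_copies_series = c(500, 2000),
                                    replicates = 2)), overrides))
}
.merge <- function(a, b) {
  for (k in names(b)) {
    a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) .merge(a[[k]], b[[k]])
              else b[[k]]
  }
  a
}

test_that("unknown configuration keys are rejected with the valid ones", {
  expect_error(run_config(list(modes = "kmeans")), "valid keys")
  expect_error(run_config(list(rain = list(radius = 3))), "rain\\.")
  expect_error(run_config(list(mode = "gmm")), "threshold, kmeans, knn")
  # a fully-defaulted config is valid
  expect_equal(run_config()$quant$droplet_volume_nl, 0.85)
})

test_that("simulate -> classify -> rain -> quantify runs end to end", {
  root <- withr::local_tempdir()
  cfg <- quiet_cfg(list(rain = list(method = "mahalanobis",
                                    max_distance = 9)))
  run_simulate(file.path(root, "raw"), cfg)
  expect_length(list.files(file.path(root, "raw"), "_Amplitude\\.csv$"), 4L)
  expect_true(file.exists(file.path(root, "raw", "ground_truth.csv")))

  summary <- run_pipeline(file.path(root, "raw"), file.path(root, "out"), cfg)
  expect_equal(nrow(summary), 4L)
  expect_true(all(summary$Status == "ok"))
  expect_true(file.exists(file.path(root, "out", "summary.csv")))
  written <- read.csv(file.path(root, "out", "summary.csv"))
  expect_equal(written$Well, c("A01", "A02", "A03", "A04"))

  # classified outputs parse back with labels
  cls <- parse_amplitude_csv(file.path(root, "out", "refined",
                                       "A01_Classified.csv"))
  expect_true(any(cls$label != "Unclassified"))
})

test_that("quantify refuses amplitude files without a Class column", {
  root <- withr::local_tempdir()
  cfg <- quiet_cfg()
  run_simulate(file.path(root, "raw"), cfg)
  raw <- list.files(file.path(root, "raw"), "_Amplitude\\.csv$",
                    full.names = TRUE)
  renamed <- sub("_Amplitude", "_Classified", raw[1])
  file.copy(raw[1], renamed)
  expect_error(run_quantify(renamed, file.path(root, "s.csv"), cfg),
               "Class column")
  expect_error(run_classify(file.path(root, "nope"), file.path(root, "o"),
                            cfg), "not found|no files")
})

test_that("identical config and seed reproduce byte-identical outputs", {
  root <- withr::local_tempdir()
  cfg <- quiet_cfg(list(rain = list(method = "sd")))
  run_simulate(file.path(root, "raw"), cfg)

  run_pipeline(file.path(root, "raw"), file.path(root, "out1"), cfg)
  run_pipeline(file.path(root, "raw"), file.path(root, "out2"), cfg)
  f1 <- file.path(root, "out1", "summary.csv")
  f2 <- file.path(root, "out2", "summary.csv")
  expect_identical(readLines(f1), readLines(f2))

  # the sidecar alone is enough to reproduce the run
  sidecar <- file.path(root, "out1", "summary.csv.run.json")
  expect_true(file.exists(sidecar))
  cfg_back <- read_run_config(sidecar)
  run_pipeline(file.path(root, "raw"), file.path(root, "out3"), cfg_back)
  expect_identical(readLines(f1),
                   readLines(file.path(root, "out3", "summary.csv")))
  for (w in c("A01", "A02")) {
    expect_identical(
      readLines(file.path(root, "out1", "refined",
                          paste0(w, "_Classified.csv"))),
      readLines(file.path(root, "out3", "refined",
                          paste0(w, "_Classified.csv"))))
  }
})

test_that("the command-line script gates a plate from a config file", {
  cli <- system.file("cli", "dropgate.R", package = "dropgate")
  root <- withr::local_tempdir()
  cfg_file <- file.path(root, "config.yaml")
  yaml::write_yaml(list(mode = "threshold",
                        thresholds = list(ch1 = 6000, ch2 = 4500),
                        rain = list(method = "sd"),
                        log_level = "quiet",
                        sim = list(n_droplets = 800,
                                   total_copies_series = c(1000),
                                   replicates = 2)), cfg_file)
  run <- function(...) {
    # make sure the subprocess sees the library this package is loaded from
    system2("Rscript", c(cli, ...), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  }
  expect_equal(attr(run("simulate", "--config", cfg_file, "-o",
                        file.path(root, "raw")), "status"), NULL)
  expect_equal(attr(run("pipeline", "--config", cfg_file, "-o",
                        file.path(root, "out"), file.path(root, "raw")),
               "status"), NULL)
  expect_true(file.exists(file.path(root, "out", "summary.csv")))
  # bad input exits non-zero
  bad <- suppressWarnings(run("classify", "-o", file.path(root, "x"),
                              file.path(root, "zzz")))
  expect_equal(attr(bad, "status"), 1L)
})
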