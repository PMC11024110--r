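#' Default pipeline configuration
#'
#' The full run configuration as a named list, the same structure accepted
#' from YAML by [run_pipeline()]. Unknown keys anywhere in the structure are
#' rejected before any stage runs. All randomness is fanned out from the
#' single `seed`.
#'
#' @param seed root RNG seed.
#' @param out_dir output directory (`NULL` for no file output).
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1, out_dir = NULL) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(enabled = TRUE, n_channels = 64, K = 4, snr = 10,
                    n_trials_per_class = 20, trial_length_s = 50,
                    mean_duration_spk1_ms = 100, mean_duration_spk2_ms = 60),
    input = list(path = NULL, labels = NULL),
    preprocess = list(enabled = TRUE, sfreq = 256, band_lo = 0.5,
                      band_hi = 70, ref = c("TP7", "TP8")),
    microstate = list(k = 4, method = "kmeans", n_init = 10,
                      min_distance_ms = 10),
    windows = list(length_s = 1, overlap = 0),
    features = list(mode = "rqa_only", selection = "all",
                    subwindow_s = 0.25, eps_strategy = "std_fraction",
                    eps_value = 0.2, m = 1, tau = 1),
    screen = list(enabled = TRUE, alpha = 0.05, adjust = "none"),
    classify = list(kind = "gcql", train_fraction = 0.7, epochs = 100,
                    batch_size = 512),
    sweep = list(enabled = FALSE, lengths_s = c(0.02, 0.1, 0.5, 1, 2, 5))
  ), class = "run_config")
}

validate_config <- function(config) {
  ref <- unclass(default_config())
  assert_that(is.list(config), "config must be a list")
  bad <- setdiff(names(config), names(ref))
  assert_that(length(bad) == 0,
              sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  for (k in names(config)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      bad <- setdiff(names(config[[k]]), names(ref[[k]]))
      assert_that(length(bad) == 0,
                  sprintf("unknown key(s) under '%s': %s", k,
                          paste(bad, collapse = ", ")))
    }
  }
  merged <- utils::modifyList(ref, config)
  assert_that(is_scalar_num(merged$seed), "seed must be a number")
  class(merged) <- "run_config"
  merged
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring [default_config()]'s structure.
#' @return A validated `run_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

stage_msg <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Run the end-to-end decoding pipeline
#'
#' Executes simulate/load, preprocess, microstate fitting, feature assembly,
#' statistical screening, classifier training and evaluation, and the
#' optional window-length sweep, from a single validated configuration.
#' Per-stage tables are written under `out_dir` (when set) together with a
#' JSON manifest holding the configuration, its hash, package version and the
#' headline metrics; a stage failure aborts with the stage named, keeping
#' earlier outputs.
#'
#' @param config a `run_config` (list, [default_config()] or [read_config()]).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly a list with `config_hash`, `stages`,
#'   `gev`, `screening`, `report` (and `sweep` when enabled).
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- list(config = unclass(config),
                   config_hash = rlang::hash(unclass(config)),
                   package_version = as.character(utils::packageVersion("msrqa")),
                   stages = character())
  done <- function(stage) manifest$stages <<- c(manifest$stages, stage)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline failed in stage '%s': %s", stage,
                    conditionMessage(e)), class = "msrqa_stage_error")
    })
  }

  rec <- run_stage("simulate/load", {
    if (isTRUE(config$simulate$enabled)) {
      sim <- simulate_eeg(synthetic_spec(
        n_channels = config$simulate$n_channels, K = config$simulate$K,
        snr = config$simulate$snr,
        mean_duration_ms = c(SPK1 = config$simulate$mean_duration_spk1_ms,
                             SPK2 = config$simulate$mean_duration_spk2_ms),
        n_trials_per_class = config$simulate$n_trials_per_class,
        trial_length_s = config$simulate$trial_length_s,
        seed = derive_seed(config$seed, "sim")))
      sim$recording
    } else {
      assert_that(!is.null(config$input$path), "input.path required when simulate is off")
      load_recording(config$input$path, labels = config$input$labels)
    }
  })
  done("simulate/load")
  stage_msg(quiet, "recording: %d ch x %d samples", nrow(rec$data), ncol(rec$data))

  if (isTRUE(config$preprocess$enabled)) {
    rec <- run_stage("preprocess", preprocess(
      rec, sfreq = config$preprocess$sfreq,
      band = c(config$preprocess$band_lo, config$preprocess$band_hi),
      ref = config$preprocess$ref))
  }
  done("preprocess")

  proto <- run_stage("microstate", {
    gfp <- compute_gfp(rec$data, rec$sfreq)
    peaks <- find_gfp_peaks(gfp, config$microstate$min_distance_ms, rec$sfreq)
    fit_prototypes(t(rec$data[, peaks, drop = FALSE]), config$microstate$k,
                   method = config$microstate$method,
                   n_init = config$microstate$n_init,
                   seed = derive_seed(config$seed, "proto"))
  })
  done("microstate")
  stage_msg(quiet, "microstates: K = %d, GEV = %.3f", proto$K, proto$gev_total)

  fm <- run_stage("features", {
    windows <- segment_windows(rec, config$windows$length_s,
                               config$windows$overlap)
    build_features(windows, proto, mode = config$features$mode,
                   rqa_cfg = embedding_config(
                     m = config$features$m, tau = config$features$tau,
                     eps_strategy = config$features$eps_strategy,
                     eps_value = config$features$eps_value),
                   subwindow_s = config$features$subwindow_s,
                   selection = config$features$selection)
  })
  done("features")
  stage_msg(quiet, "features: %d windows x %d columns", nrow(fm),
            length(feature_columns(fm)))

  screening <- NULL
  if (isTRUE(config$screen$enabled)) {
    screening <- run_stage("screen",
      screen_features(fm, config$screen$alpha, config$screen$adjust))
    done("screen")
  }

  report <- run_stage("train/evaluate", {
    sp <- split_trials(fm, config$classify$train_fraction,
                       seed = derive_seed(config$seed, "split"))
    spec <- make_clf_spec(config)
    model <- fit_aad(sp$train, spec)
    evaluate_aad(model, sp$test)
  })
  done("train/evaluate")
  stage_msg(quiet, "held-out: ACC %.3f TPR %.3f TNR %.3f",
            report$acc, report$tpr, report$tnr)

  sweep <- NULL
  if (isTRUE(config$sweep$enabled)) {
    sweep <- run_stage("sweep", suppressWarnings(window_sweep(
      rec, lengths_s = config$sweep$lengths_s, spec = make_clf_spec(config),
      prototypes = proto, mode = config$features$mode,
      selection = config$features$selection,
      train_fraction = config$classify$train_fraction,
      seed = derive_seed(config$seed, "sweep"))))
    done("sweep")
  }

  manifest$gev <- proto$gev_total
  manifest$report <- as.list(report[1, ])
  if (!is.null(screening)) manifest$screening <- screening
  if (!is.null(sweep)) manifest$sweep <- sweep
  if (!is.null(out_dir)) {
    utils::write.csv(fm, file.path(out_dir, "features.csv"), row.names = FALSE)
    if (!is.null(screening)) {
      utils::write.csv(screening, file.path(out_dir, "screening.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(as.data.frame(proto$maps),
                     file.path(out_dir, "prototypes.csv"), row.names = FALSE)
    if (!is.null(sweep)) {
      utils::write.csv(sweep, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    }
    json_manifest <- manifest
    json_manifest$screening <- NULL; json_manifest$sweep <- NULL
    jsonlite::write_json(json_manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(manifest)
}

make_clf_spec <- function(config) {
  kind <- config$classify$kind
  seed <- derive_seed(config$seed, "clf")
  switch(kind,
    knn = classifier_spec("knn", seed = seed),
    svm = classifier_spec("svm", seed = seed),
    lstm = classifier_spec("lstm", epochs = config$classify$epochs,
                           batch_size = config$classify$batch_size, seed = seed),
    bilstm = classifier_spec("bilstm", epochs = config$classify$epochs,
                             batch_size = config$classify$batch_size, seed = seed),
    gcql = classifier_spec("gcql", config = gcql_config(
      epochs = config$classify$epochs,
      batch_size = config$classify$batch_size), seed = seed),
    abort(sprintf("unknown classifier kind '%s'", kind))
  )
}
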