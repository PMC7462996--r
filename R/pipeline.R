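#' Pipeline configuration
#'
#' Collects every stage's parameters behind one object. Three run modes:
#'
#' * `simulate_and_train` — generate a synthetic cohort, extract and
#'   filter features, build profiles, cleanse, train both models and
#'   cross-validate them.
#' * `train_from_features` — start from a per-cell feature CSV and a TER
#'   table (`image_id,ter`) instead of simulation.
#' * `predict_only` — score an existing profile CSV with a stored model;
#'   evaluation runs only when the profiles carry TER tags.
#'
#' @param mode Run mode (see above).
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; it determines every stochastic stage
#'   (generator, bootstrap draws, lambda-selection folds).
#' @param n_images Cohort size for `simulate_and_train`.
#' @param params_sampler Per-image parameter sampler (see
#'   [generate_cohort()]).
#' @param morphometry A [morphometry_config()].
#' @param replicates A [replicate_spec()]; its `seed` is overridden by
#'   the master seed.
#' @param cleansing A [cleansing_config()].
#' @param lambda_rule,lambda Passed to the model fits.
#' @param scheme Validation scheme for the evaluation stage.
#' @param features_csv,ter_table_csv Inputs for `train_from_features`.
#' @param profiles_csv,model_json Inputs for `predict_only`.
#' @param write_images Also write every simulated label image as TIFF
#'   (default `FALSE`; the feature tables are what downstream stages use).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate_and_train", "train_from_features",
                                     "predict_only"),
                            out_dir, seed = 1, n_images = 54,
                            params_sampler = default_params_sampler,
                            morphometry = morphometry_config(),
                            replicates = replicate_spec(),
                            cleansing = cleansing_config(),
                            lambda_rule = "inner_cv", lambda = NULL,
                            scheme = "loocv_by_image",
                            features_csv = NULL, ter_table_csv = NULL,
                            profiles_csv = NULL, model_json = NULL,
                            write_images = FALSE) {
  mode <- match.arg(mode)
  if (mode == "train_from_features") {
    for (f in c(features_csv, ter_table_csv)) {
      if (is.null(f) || !file.exists(f)) {
        stop("train_from_features requires existing features_csv and ter_table_csv",
             call. = FALSE)
      }
    }
  }
  if (mode == "predict_only") {
    for (f in c(profiles_csv, model_json)) {
      if (is.null(f) || !file.exists(f)) {
        stop("predict_only requires existing profiles_csv and model_json",
             call. = FALSE)
      }
    }
  }
  structure(
    list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
         n_images = as.integer(n_images), params_sampler = params_sampler,
         morphometry = morphometry, replicates = replicates,
         cleansing = cleansing, lambda_rule = lambda_rule, lambda = lambda,
         scheme = scheme, features_csv = features_csv,
         ter_table_csv = ter_table_csv, profiles_csv = profiles_csv,
         model_json = model_json, write_images = isTRUE(write_images)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; nested
#' `morphometry`, `replicates` and `cleansing` blocks onto their
#' constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("morphometry", "replicates", "cleansing"))]
  if (!is.null(y$morphometry)) args$morphometry <- do.call(morphometry_config, y$morphometry)
  if (!is.null(y$replicates)) args$replicates <- do.call(replicate_spec, y$replicates)
  if (!is.null(y$cleansing)) args$cleansing <- do.call(cleansing_config, y$cleansing)
  do.call(pipeline_config, args)
}

stage_entry <- function(name, counts = list(), files = character()) {
  files <- files[file.exists(files)]
  list(
    name = name,
    counts = counts,
    outputs = if (length(files) > 0) {
      list(path = unname(files), md5 = unname(tools::md5sum(files)))
    } else NULL
  )
}

#' Run the end-to-end pipeline
#'
#' Executes the stages of the configured run mode in order
#' (simulate/ingest, features, filter, profile, cleanse, train,
#' evaluate), writes every artifact under `config$out_dir` and returns a
#' run manifest with per-stage counts and output checksums. A stage error
#' aborts the run with the stage name; artifacts written so far remain on
#' disk next to a `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- list()
  warnings_log <- character()
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  current_stage <- "init"
  on_fail <- function(e) {
    writeLines(paste0("failed at stage: ", current_stage), out("FAILED"))
    stop("pipeline failed at stage '", current_stage, "': ",
         conditionMessage(e), call. = FALSE)
  }

  withCallingHandlers(tryCatch({
    spec <- config$replicates
    spec$seed <- config$seed

    if (config$mode == "simulate_and_train") {
      current_stage <- "simulate"
      cohort <- generate_cohort(config$n_images, config$params_sampler,
                                seed = config$seed)
      img_files <- character()
      if (config$write_images) {
        img_files <- vapply(names(cohort), function(id) {
          write_label_image(cohort[[id]], out(paste0(id, ".tif")))
        }, character(1))
        img_files <- c(img_files, paste0(img_files, ".json"))
      }
      stages <- c(stages, list(stage_entry("simulate",
        list(n_images = length(cohort),
             n_cells_total = sum(vapply(cohort, n_cells, integer(1)))),
        img_files)))

      current_stage <- "features"
      feats <- purrr::imap(cohort, function(sheet, id) {
        extract_cell_morphologies(sheet, config$morphometry) |>
          dplyr::mutate(image_id = id, .before = 1)
      }) |> dplyr::bind_rows()
      write_cell_features(feats, out("features.csv"))
      stages <- c(stages, list(stage_entry("features",
        list(n_cells = nrow(feats)), out("features.csv"))))

      current_stage <- "filter"
      kept <- filter_small_cells(feats, config$morphometry)
      stages <- c(stages, list(stage_entry("filter",
        list(n_kept = nrow(kept), n_deleted = attr(kept, "n_deleted")))))

      current_stage <- "profile"
      ter_tab <- tibble::tibble(
        image_id = names(cohort),
        ter = vapply(cohort, function(s) s$true_ter, numeric(1))
      )
      profiles <- build_profiles_from_features(kept, ter_tab, spec)
    } else if (config$mode == "train_from_features") {
      current_stage <- "ingest"
      feats <- read_cell_features(config$features_csv)
      ter_tab <- readr::read_csv(config$ter_table_csv, show_col_types = FALSE,
                                 col_types = readr::cols(
                                   image_id = readr::col_character(),
                                   ter = readr::col_double()
                                 ))
      check_schema(names(ter_tab), c("image_id", "ter"), "TER table CSV")
      stages <- c(stages, list(stage_entry("ingest",
        list(n_cells = nrow(feats), n_images = nrow(ter_tab)))))

      current_stage <- "filter"
      kept <- filter_small_cells(feats, config$morphometry)
      stages <- c(stages, list(stage_entry("filter",
        list(n_kept = nrow(kept), n_deleted = attr(kept, "n_deleted")))))

      current_stage <- "profile"
      profiles <- build_profiles_from_features(kept, ter_tab, spec)
    } else { # predict_only
      current_stage <- "ingest"
      profiles <- read_profiles(config$profiles_csv)
      model <- read_ter_model(config$model_json)
      stages <- c(stages, list(stage_entry("ingest",
        list(n_profiles = nrow(profiles)))))

      current_stage <- "predict"
      pred <- predict(model, profiles)
      pred <- dplyr::left_join(
        dplyr::select(profiles, "sample_id", observed_ter = "ter"),
        pred, by = "sample_id")
      write_predictions(pred, out("predictions.csv"))
      stages <- c(stages, list(stage_entry("predict",
        list(n_predictions = nrow(pred)), out("predictions.csv"))))

      current_stage <- "evaluate"
      if (all(is.na(profiles$ter))) {
        message("profiles carry no TER values; evaluate stage skipped")
        stages <- c(stages, list(stage_entry("evaluate",
          list(skipped = "no TER tags in profiles"))))
      } else {
        metrics <- if (model$kind == "regression") {
          as.list(c(rmse = sqrt(mean((pred$observed_ter - pred$predicted_ter)^2))))
        } else {
          obs <- ter_class_labels(pred$observed_ter,
                                  model$thresholds[["low_ter_max"]],
                                  model$thresholds[["high_ter_min"]])
          as.list(confusion_metrics(as.character(obs), pred$class))
        }
        jsonlite::write_json(
          list(schema = schema_version, kind = model$kind,
               scheme = "fixed_model", metrics = metrics),
          out("evaluation.json"), auto_unbox = TRUE, digits = I(17))
        stages <- c(stages, list(stage_entry("evaluate", metrics,
                                             out("evaluation.json"))))
      }
      profiles <- NULL
    }

    if (!is.null(profiles)) {
      write_profiles(profiles, out("profiles.csv"))
      stages <- c(stages, list(stage_entry("profile",
        list(n_profiles = nrow(profiles)), out("profiles.csv"))))

      current_stage <- "cleanse"
      cleansed <- cleanse_profiles(profiles, config$cleansing)
      write_profiles(cleansed$selected[, profile_csv_columns()],
                     out("selected_profiles.csv"))
      jsonlite::write_json(
        list(schema = schema_version,
             cluster_sizes = as.list(table(cleansed$assignment$cluster)),
             selected = glance(cleansed),
             assignment = cleansed$assignment,
             excluded = cleansed$excluded),
        out("cleansing_report.json"), auto_unbox = TRUE, digits = I(17))
      stages <- c(stages, list(stage_entry("cleanse",
        as.list(glance(cleansed)),
        c(out("selected_profiles.csv"), out("cleansing_report.json")))))

      current_stage <- "train"
      reg <- fit_ter_regression(cleansed, lambda_rule = config$lambda_rule,
                                lambda = config$lambda, seed = config$seed,
                                low_ter_max = config$cleansing$low_ter_max,
                                high_ter_min = config$cleansing$high_ter_min)
      disc <- fit_ter_discriminator(cleansed, lambda_rule = config$lambda_rule,
                                    lambda = config$lambda, seed = config$seed,
                                    low_ter_max = config$cleansing$low_ter_max,
                                    high_ter_min = config$cleansing$high_ter_min)
      write_ter_model(reg, out("model_regression.json"))
      write_ter_model(disc, out("model_discrimination.json"))
      stages <- c(stages, list(stage_entry("train",
        list(regression_nonzero = sum(reg$coef_std != 0),
             discrimination_nonzero = sum(disc$coef_std != 0)),
        c(out("model_regression.json"), out("model_discrimination.json")))))

      current_stage <- "evaluate"
      ev_reg <- evaluate_ter_model(cleansed, "regression", config$scheme,
                                   lambda_rule = config$lambda_rule,
                                   lambda = config$lambda, seed = config$seed,
                                   low_ter_max = config$cleansing$low_ter_max,
                                   high_ter_min = config$cleansing$high_ter_min)
      ev_disc <- evaluate_ter_model(cleansed, "discrimination", config$scheme,
                                    lambda_rule = config$lambda_rule,
                                    lambda = config$lambda, seed = config$seed,
                                    low_ter_max = config$cleansing$low_ter_max,
                                    high_ter_min = config$cleansing$high_ter_min)
      write_eval_report(ev_reg, out("evaluation_regression.json"))
      write_eval_report(ev_disc, out("evaluation_discrimination.json"))
      stages <- c(stages, list(stage_entry("evaluate",
        c(as.list(ev_reg$metrics), as.list(ev_disc$metrics)),
        c(out("evaluation_regression.json"),
          out("evaluation_discrimination.json")))))
    }
  }, error = on_fail), warning = log_warning)

  manifest <- list(
    tool = "rpeqc",
    version = as.character(utils::packageVersion("rpeqc")),
    schema = schema_version,
    mode = config$mode,
    seed = config$seed,
    scheme = config$scheme,
    stages = stages,
    warnings = warnings_log,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(manifest)
}

# features (with image_id) + TER table -> bootstrap profiles
build_profiles_from_features <- function(features, ter_table, spec) {
  ids <- unique(features$image_id)
  purrr::map(ids, function(id) {
    cells <- dplyr::filter(features, .data$image_id == id)
    ter <- ter_table$ter[match(id, ter_table$image_id)]
    make_sample_profiles(cells, id, ter, spec)
  }) |> dplyr::bind_rows()
}
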