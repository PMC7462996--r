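schema_version <- "rpeqc-1"

feature_csv_columns <- function() {
  c("image_id", "cell_id", "area_px", "area_um2", "perimeter_um",
    "compactness", "inner_radius_um", "outer_radius_um", "length_um",
    "width_um", "lw_ratio")
}

profile_csv_columns <- function() {
  c("sample_id", "image_id", "replicate_index", profile_variables(), "ter")
}

# Format double columns with 17 significant digits so every value
# round-trips bit-exactly through CSV (readr's default 15 digits do not).
format_doubles_full <- function(df) {
  for (nm in names(df)) {
    x <- df[[nm]]
    if (is.double(x)) {
      df[[nm]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    }
  }
  df
}

check_schema <- function(found, expected, what) {
  if (!identical(found, expected)) {
    stop(what, " schema mismatch.\n  expected: ",
         paste(expected, collapse = ","), "\n  found:    ",
         paste(found, collapse = ","), call. = FALSE)
  }
}

#' Write / read a label image as 16-bit TIFF with a JSON sidecar
#'
#' The label matrix is stored as a single-channel 16-bit TIFF (label
#' values preserved exactly, up to 65535 cells); `pixel_area`, `true_ter`
#' and the generating parameters travel in `<path>.json`.
#'
#' @param sheet A `labeled_sheet`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(sheet, path) {
  stopifnot(inherits(sheet, "labeled_sheet"))
  m <- sheet$labels
  if (max(m) > 65535) stop("more than 65535 labels do not fit 16-bit TIFF",
                           call. = FALSE)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16, compression = "none")
  prov <- sheet$provenance
  sidecar <- list(
    schema = schema_version,
    pixel_area = sheet$pixel_area,
    true_ter = if (is.na(sheet$true_ter)) NULL else sheet$true_ter,
    provenance = if (inherits(prov, "sheet_params")) unclass(prov) else "external"
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  sidecar_path <- paste0(path, ".json")
  pixel_area <- 0.61
  true_ter <- NA_real_
  provenance <- "external"
  if (file.exists(sidecar_path)) {
    meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!identical(meta$schema, schema_version)) {
      stop("sidecar ", sidecar_path, ": unsupported schema '", meta$schema, "'",
           call. = FALSE)
    }
    pixel_area <- meta$pixel_area
    true_ter <- meta$true_ter %||% NA_real_
    if (is.list(meta$provenance)) {
      p <- meta$provenance
      provenance <- sheet_params(
        n_cells = p$n_cells, field_size = unlist(p$field_size),
        pixel_area = p$pixel_area, disorder = p$disorder,
        heterogeneity = p$heterogeneity, elongation = p$elongation,
        ter_noise_sd = p$ter_noise_sd, seed = p$seed
      )
    }
  }
  new_labeled_sheet(m, pixel_area, true_ter, provenance)
}

#' Write / read per-cell feature tables as CSV
#'
#' Fixed header `image_id,cell_id,area_px,...,lw_ratio`; numeric fields
#' round-trip at full precision. Reading a file whose header deviates is
#' a hard error.
#'
#' @param cells Tibble of per-cell morphologies.
#' @param path CSV path.
#' @param image_id Image id recorded with each row (ignored if `cells`
#'   already has an `image_id` column).
#' @return `path` invisibly (write); tibble (read).
#' @export
write_cell_features <- function(cells, path, image_id = "img01") {
  if (!"image_id" %in% names(cells)) {
    cells <- dplyr::mutate(cells, image_id = image_id, .before = 1)
  }
  cells <- cells[, feature_csv_columns()]
  readr::write_csv(format_doubles_full(cells), path)
  invisible(path)
}

#' @rdname write_cell_features
#' @export
read_cell_features <- function(path) {
  # numerics come in as text and convert through strtod, which parses
  # %.17g output back bit-exactly (fast CSV double parsers can be 1 ulp off)
  cells <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  check_schema(names(cells), feature_csv_columns(), "feature CSV")
  cells$cell_id <- as.integer(cells$cell_id)
  for (nm in setdiff(names(cells), c("image_id", "cell_id"))) {
    cells[[nm]] <- as.numeric(cells[[nm]])
  }
  cells
}

#' Write / read sample-profile tables as CSV
#'
#' Fixed header `sample_id,image_id,replicate_index,<16 variables>,ter`;
#' an empty `ter` field reads back as `NA` (TER-absent profile).
#'
#' @param profiles Tibble of sample profiles.
#' @param path CSV path.
#' @return `path` invisibly (write); tibble (read).
#' @export
write_profiles <- function(profiles, path) {
  profiles <- profiles[, profile_csv_columns()]
  readr::write_csv(format_doubles_full(profiles), path, na = "")
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  profiles <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                              col_types = readr::cols(.default = readr::col_character()))
  check_schema(names(profiles), profile_csv_columns(), "profile CSV")
  profiles$replicate_index <- as.integer(profiles$replicate_index)
  for (nm in setdiff(names(profiles), c("sample_id", "image_id", "replicate_index"))) {
    profiles[[nm]] <- as.numeric(profiles[[nm]])
  }
  profiles
}

#' Serialize / restore a fitted TER model as JSON
#'
#' Stores variable names, standardized and back-transformed coefficients,
#' intercepts, standardization statistics, lambda, kind, thresholds and
#' seed at full numeric precision, so a restored model predicts
#' bit-identically.
#'
#' @param model A `ter_model`.
#' @param path JSON path.
#' @return `path` invisibly (write); `ter_model` (read).
#' @export
write_ter_model <- function(model, path) {
  stopifnot(inherits(model, "ter_model"))
  payload <- c(list(schema = schema_version), unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_ter_model
#' @export
read_ter_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, schema_version)) {
    stop("model file ", path, ": unsupported schema '", p$schema, "'",
         call. = FALSE)
  }
  vars <- p$variable_names
  structure(
    list(
      kind = p$kind,
      variable_names = vars,
      coef_std = stats::setNames(as.numeric(p$coef_std), vars),
      coef_orig = stats::setNames(as.numeric(p$coef_orig), vars),
      intercept_std = p$intercept_std,
      intercept_orig = p$intercept_orig,
      center = stats::setNames(as.numeric(p$center), vars),
      scale = stats::setNames(as.numeric(p$scale), vars),
      lambda = p$lambda,
      lambda_rule = p$lambda_rule,
      positive_class = p$positive_class %||% NA_character_,
      thresholds = c(low_ter_max = unname(p$thresholds[1]),
                     high_ter_min = unname(p$thresholds[2])),
      n_train = p$n_train,
      seed = p$seed
    ),
    class = "ter_model"
  )
}

#' Write an evaluation report as JSON
#'
#' @param eval A `ter_eval`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  stopifnot(inherits(eval, "ter_eval"))
  payload <- list(
    schema = schema_version,
    kind = eval$kind,
    scheme = eval$scheme,
    n = eval$n,
    metrics = as.list(eval$metrics),
    thresholds = as.list(eval$thresholds),
    per_sample = eval$per_sample
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write model predictions as CSV
#'
#' Columns `sample_id,observed_ter,predicted_ter` for regression models
#' and `sample_id,observed_ter,probability,class` for discrimination.
#'
#' @param predictions Tibble from [predict.ter_model()], optionally with
#'   an `observed_ter` column joined on.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_csv(format_doubles_full(predictions), path, na = "")
  invisible(path)
}
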