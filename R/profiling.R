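#' Bootstrap replicate specification
#'
#' Controls how an image's filtered cell list is resampled into replicate
#' datasets: `n_replicates` replicates, each drawing a size
#' `k ~ Uniform{size_min..size_max}` of cells, with replacement by
#' default.
#'
#' @param n_replicates Replicates per image (default 3).
#' @param size_min,size_max Bounds of the per-replicate cell count
#'   (defaults 100 and 200).
#' @param with_replacement Sample cells with replacement (default `TRUE`);
#'   `FALSE` is provided for sensitivity analysis and requires at least
#'   `size_min` cells.
#' @param seed Integer seed; draws are deterministic given it (combined
#'   with the image id and replicate index, so different images resample
#'   independently).
#' @return An object of class `replicate_spec`.
#' @export
replicate_spec <- function(n_replicates = 3, size_min = 100, size_max = 200,
                           with_replacement = TRUE, seed = 1) {
  stopifnot(n_replicates >= 1, size_min >= 1, size_min <= size_max)
  structure(
    list(
      n_replicates = as.integer(n_replicates),
      size_min = as.integer(size_min),
      size_max = as.integer(size_max),
      with_replacement = isTRUE(with_replacement),
      seed = as.integer(seed)
    ),
    class = "replicate_spec"
  )
}

#' Summarize a cell set into the 16 explanatory variables
#'
#' Mean (`ave_`) and sample standard deviation (`sd_`, n - 1 denominator)
#' of each of the eight shape descriptors, in the fixed
#' [profile_variables()] order.
#'
#' @param cells Tibble of per-cell morphologies with >= 2 rows.
#' @return Named numeric vector of length 16.
#' @export
#' @examples
#' cells <- tibble::tibble(area_um2 = c(1, 2, 3), compactness = 1,
#'   inner_radius_um = 1, length_um = 1, lw_ratio = 1, outer_radius_um = 1,
#'   perimeter_um = 1, width_um = 1)
#' summarize_replicate(cells)[c("ave_area_um2", "sd_area_um2")]
summarize_replicate <- function(cells) {
  missing <- setdiff(rpe_features, names(cells))
  if (length(missing) > 0) {
    stop("cell table lacks feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) < 2) {
    stop("at least 2 cells are required (sample SD undefined otherwise)",
         call. = FALSE)
  }
  out <- numeric(16)
  names(out) <- profile_variables()
  for (f in rpe_features) {
    v <- cells[[f]]
    out[paste0("ave_", f)] <- mean(v)
    out[paste0("sd_", f)] <- sd(v)
  }
  out
}

#' Build bootstrap sample profiles from one image's cells
#'
#' Draws `spec$n_replicates` bootstrap replicates from the (already
#' size-filtered) cell list and summarizes each into the 16 explanatory
#' variables, tagged with the image's TER. Replicate `r` of image `id`
#' uses a seed derived from `spec$seed`, a hash of `id` and `r`, so
#' profiles are deterministic per image yet independent across images.
#'
#' @param cells Tibble of per-cell morphologies (>= 2 rows).
#' @param image_id Character id of the source image.
#' @param ter Measured TER in Ohm.cm2, or `NA` when unknown.
#' @param spec A [replicate_spec()].
#' @return Tibble with one row per replicate: `sample_id`, `image_id`,
#'   `replicate_index` (0-based), the 16 variables, `ter`.
#' @export
make_sample_profiles <- function(cells, image_id, ter = NA_real_,
                                 spec = replicate_spec()) {
  stopifnot(inherits(spec, "replicate_spec"))
  n <- nrow(cells)
  if (n < 2) stop("at least 2 cells are required to build profiles", call. = FALSE)
  if (!spec$with_replacement && n < spec$size_min) {
    stop("image ", image_id, " has ", n, " cells, fewer than size_min = ",
         spec$size_min, " (sampling without replacement)", call. = FALSE)
  }
  if (spec$with_replacement && n < spec$size_min) {
    warning("image ", image_id, " has only ", n, " cells (< size_min = ",
            spec$size_min, "); bootstrap proceeds with replacement",
            call. = FALSE)
  }
  img_hash <- string_seed(as.character(image_id))
  rows <- purrr::map(seq_len(spec$n_replicates), function(r) {
    # double arithmetic: integer addition would overflow for large seeds
    rep_seed <- derive_seed(as.numeric(spec$seed) + as.numeric(img_hash), r)
    drawn <- withr::with_seed(rep_seed, {
      k <- spec$size_min + sample.int(spec$size_max - spec$size_min + 1L, 1) - 1L
      idx <- sample.int(n, k, replace = spec$with_replacement)
      idx
    })
    vars <- summarize_replicate(cells[drawn, , drop = FALSE])
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = paste0(image_id, "_r", r - 1L),
        image_id = as.character(image_id),
        replicate_index = r - 1L
      ),
      tibble::as_tibble(as.list(vars))
    )
  })
  dplyr::bind_rows(rows) |> dplyr::mutate(ter = as.numeric(ter))
}

#' Build sample profiles for a whole cohort of sheets
#'
#' Convenience wrapper: extracts morphologies, applies the minimum-size
#' filter and builds bootstrap profiles for every sheet in a cohort,
#' using each sheet's `true_ter` as the TER tag.
#'
#' @param cohort Named list of `labeled_sheet` objects (see
#'   [generate_cohort()]).
#' @param config A [morphometry_config()].
#' @param spec A [replicate_spec()].
#' @return Tibble of profiles, `n_images * n_replicates` rows.
#' @export
profile_cohort <- function(cohort, config = morphometry_config(),
                           spec = replicate_spec()) {
  ids <- names(cohort) %||% sprintf("img%02d", seq_along(cohort))
  purrr::map2(cohort, ids, function(sheet, id) {
    cells <- extract_cell_morphologies(sheet, config) |>
      filter_small_cells(config)
    make_sample_profiles(cells, id, sheet$true_ter, spec)
  }) |>
    dplyr::bind_rows()
}

#' Net transepithelial electrical resistance
#'
#' `(measured - blank) * membrane_area`: the blank-insert resistance is
#' subtracted from the raw reading and the remainder scaled by the insert
#' membrane area.
#'
#' @param measured Raw resistance reading, Ohm.
#' @param blank Blank-insert reading, Ohm.
#' @param membrane_area Insert membrane area, cm^2 (> 0).
#' @return Net TER in Ohm.cm2.
#' @export
#' @examples
#' net_ter(1200, 200, 0.5)
net_ter <- function(measured, blank, membrane_area) {
  stopifnot(all(membrane_area > 0))
  if (any(measured < blank)) {
    stop("measured resistance below the blank value: non-physical reading",
         call. = FALSE)
  }
  (measured - blank) * membrane_area
}
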