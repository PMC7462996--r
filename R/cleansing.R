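#' Cleansing configuration
#'
#' Thresholds and clustering settings for the clustering-based noise
#' reduction: profiles with TER above `high_ter_min` (strictly) are
#' candidate "high" samples, below `low_ter_max` (strictly) candidate
#' "low" samples; the 150--250 Ohm.cm2 mid-band is always excluded.
#'
#' @param low_ter_max Upper bound of the low-TER group, Ohm.cm2 (default 150).
#' @param high_ter_min Lower bound of the high-TER group, Ohm.cm2 (default 250).
#' @param linkage Agglomeration method; only `"average"` is supported.
#' @param distance Distance; only `"euclidean_zscored"` (Euclidean on
#'   per-variable z-scores) is supported.
#' @return An object of class `cleansing_config`.
#' @export
cleansing_config <- function(low_ter_max = 150, high_ter_min = 250,
                             linkage = "average",
                             distance = "euclidean_zscored") {
  stopifnot(low_ter_max < high_ter_min)
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  structure(
    list(low_ter_max = low_ter_max, high_ter_min = high_ter_min,
         linkage = linkage, distance = distance, n_clusters = 2L),
    class = "cleansing_config"
  )
}

profile_matrix <- function(profiles) {
  vars <- profile_variables()
  missing <- setdiff(vars, names(profiles))
  if (length(missing) > 0) {
    stop("profiles lack variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(profiles[, vars])
  rownames(m) <- profiles$sample_id
  m
}

# z-score columns; zero-variance columns become all-zero instead of NaN
zscore_columns <- function(m, center = NULL, scale = NULL) {
  center <- center %||% colMeans(m)
  scale <- scale %||% apply(m, 2, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(z = sweep(sweep(m, 2, center), 2, scale, "/"), center = center, scale = scale)
}

#' Cluster sample profiles into two morphology groups
#'
#' Agglomerative hierarchical clustering (average linkage) on Euclidean
#' distances over the 16 explanatory variables, each z-scored across
#' profiles; the tree is cut into two clusters. The cluster with the
#' higher median TER is named `A`, the other `B` (ties broken toward the
#' larger cluster).
#'
#' @param profiles Tibble of >= 2 sample profiles, all with TER tags.
#' @param config A [cleansing_config()].
#' @return Tibble `sample_id`, `cluster` (`"A"`/`"B"`).
#' @export
cluster_profiles <- function(profiles, config = cleansing_config()) {
  if (nrow(profiles) < 2) stop("need >= 2 profiles to cluster", call. = FALSE)
  if (!"ter" %in% names(profiles) || anyNA(profiles$ter)) {
    stop("every profile must carry a TER tag for cleansing", call. = FALSE)
  }
  m <- profile_matrix(profiles)
  z <- zscore_columns(m)$z
  d <- dist(z, method = "euclidean")
  if (all(d < 1e-12)) {
    warning("all profiles are identical; the 2-cluster cut is degenerate ",
            "(1-vs-rest split)", call. = FALSE)
  }
  hc <- hclust(d, method = config$linkage)
  grp <- cutree(hc, k = 2)

  med <- tapply(profiles$ter, grp, median)
  if (med[["1"]] == med[["2"]]) {
    a_grp <- names(which.max(table(grp)))
  } else {
    a_grp <- names(which.max(med))
  }
  tibble::tibble(
    sample_id = profiles$sample_id,
    cluster = ifelse(grp == as.integer(a_grp), "A", "B")
  )
}

#' Select primary samples concordant with their morphology cluster
#'
#' Retains high-TER samples (`ter > high_ter_min`) from cluster A and
#' low-TER samples (`ter < low_ter_max`) from cluster B — the "primary"
#' samples in which morphology and barrier function agree. Everything
#' else is excluded: `"mid-band"` for TER between the thresholds
#' (inclusive), `"discordant"` for threshold-passing samples in the wrong
#' cluster.
#'
#' @param profiles Tibble of sample profiles with TER tags.
#' @param cluster_assignment Tibble from [cluster_profiles()] covering all
#'   profiles.
#' @param config A [cleansing_config()].
#' @return An object of class `cleansed_profiles`: list with `selected`
#'   (profiles plus `cluster` and `class` = `"high"`/`"low"`),
#'   `excluded` (`sample_id`, `reason`), `assignment`, `config`.
#' @export
select_primary <- function(profiles, cluster_assignment,
                           config = cleansing_config()) {
  if (!all(profiles$sample_id %in% cluster_assignment$sample_id)) {
    stop("cluster_assignment must cover every profile", call. = FALSE)
  }
  joined <- dplyr::left_join(profiles, cluster_assignment, by = "sample_id")
  joined <- dplyr::mutate(
    joined,
    class = dplyr::case_when(
      .data$ter > config$high_ter_min ~ "high",
      .data$ter < config$low_ter_max ~ "low",
      TRUE ~ "mid"
    ),
    status = dplyr::case_when(
      .data$class == "high" & .data$cluster == "A" ~ "selected",
      .data$class == "low" & .data$cluster == "B" ~ "selected",
      .data$class == "mid" ~ "mid-band",
      TRUE ~ "discordant"
    )
  )
  selected <- joined |>
    dplyr::filter(.data$status == "selected") |>
    dplyr::select(-"status")
  excluded <- joined |>
    dplyr::filter(.data$status != "selected") |>
    dplyr::select("sample_id", reason = "status")
  if (!any(selected$class == "high") || !any(selected$class == "low")) {
    stop("cleansing left an empty TER class; models would be untrainable",
         call. = FALSE)
  }
  structure(
    list(selected = selected, excluded = excluded,
         assignment = cluster_assignment, config = config),
    class = "cleansed_profiles"
  )
}

#' Run the full cleansing step
#'
#' [cluster_profiles()] followed by [select_primary()].
#'
#' @inheritParams cluster_profiles
#' @return A `cleansed_profiles` object.
#' @export
cleanse_profiles <- function(profiles, config = cleansing_config()) {
  assignment <- cluster_profiles(profiles, config)
  select_primary(profiles, assignment, config)
}

#' @export
print.cleansed_profiles <- function(x, ...) {
  cat("<cleansed_profiles> ", nrow(x$selected), " selected (",
      sum(x$selected$class == "high"), " high / ",
      sum(x$selected$class == "low"), " low), ",
      nrow(x$excluded), " excluded\n", sep = "")
  if (nrow(x$excluded) > 0) {
    tab <- table(x$excluded$reason)
    cat("  excluded:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.cleansed_profiles <- function(x, ...) {
  dplyr::bind_rows(
    x$selected |>
      dplyr::select("sample_id", "image_id", "cluster", "class", "ter") |>
      dplyr::mutate(status = "selected"),
    dplyr::left_join(x$excluded, x$assignment, by = "sample_id") |>
      dplyr::mutate(status = .data$reason) |>
      dplyr::select("sample_id", "cluster", "status")
  )
}

#' @export
glance.cleansed_profiles <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x$selected),
    n_high = sum(x$selected$class == "high"),
    n_low = sum(x$selected$class == "low"),
    n_mid_band = sum(x$excluded$reason == "mid-band"),
    n_discordant = sum(x$excluded$reason == "discordant")
  )
}
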