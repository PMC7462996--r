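# Cohort fixtures built in code. Heavy two-class cohorts are cached per
# seed so several tests can share them.

.cohort_cache <- new.env(parent = emptyenv())

# Two-class cohort at generator defaults: half the images drawn at a high
# latent quality (low dials -> high TER), half at a low one, each dial
# jittered +/- 0.1 around the class quality level.
two_class_cohort <- function(seed, n_high = 6, n_low = 6, n_cells = 300,
                             field = c(1024, 1024)) {
  sheets <- list()
  for (i in seq_len(n_high + n_low)) {
    s <- rpeqc:::derive_seed(seed, i)
    q <- withr::with_seed(s, if (i <= n_high) runif(1, 0.05, 0.25) else runif(1, 0.75, 0.95))
    dial <- withr::with_seed(s + 1, pmin(pmax(q + runif(3, -0.1, 0.1), 0), 1))
    sheets[[sprintf("img%02d", i)]] <- generate_sheet(sheet_params(
      n_cells = n_cells, field_size = field, disorder = dial[1],
      heterogeneity = dial[2], elongation = dial[3], seed = s))
  }
  sheets
}

two_class_profiles_cached <- function(seed) {
  key <- paste0("p", seed)
  if (!exists(key, envir = .cohort_cache)) {
    cohort <- two_class_cohort(seed)
    profiles <- suppressWarnings(
      profile_cohort(cohort, morphometry_config(), replicate_spec(seed = seed)))
    assign(key, profiles, envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# Small, fast sheets for unit tests.
small_sheet <- function(seed = 1, n_cells = 120, field = c(448, 448), ...) {
  generate_sheet(sheet_params(n_cells = n_cells, field_size = field,
                              seed = seed, ...))
}

small_sampler <- function(s) {
  p <- default_params_sampler(s)
  p$n_cells <- 120L
  p$field_size <- c(448L, 448L)
  p
}

# Profile-table generator with a known 3-term linear TER model:
# ter = 300 - 40 z(ave_lw_ratio) - 30 z(sd_compactness) + 25 z(ave_width_um)
#       + N(0, noise_sd), with n_per_image profiles sharing an image id.
linear_profile_cohort <- function(n = 98, seed = 1, noise_sd = 10) {
  vars <- profile_variables()
  base_mean <- c(
    ave_area_um2 = 2000, sd_area_um2 = 600, ave_compactness = 0.8,
    sd_compactness = 0.08, ave_inner_radius_um = 14, sd_inner_radius_um = 4,
    ave_length_um = 60, sd_length_um = 15, ave_lw_ratio = 1.6,
    sd_lw_ratio = 0.5, ave_outer_radius_um = 32, sd_outer_radius_um = 8,
    ave_perimeter_um = 160, sd_perimeter_um = 40, ave_width_um = 38,
    sd_width_um = 9
  )
  withr::with_seed(seed, {
    x <- sapply(vars, function(v) {
      mu <- base_mean[[v]]
      rnorm(n, mu, 0.15 * abs(mu))
    })
    z <- scale(x)
    ter <- 300 - 40 * z[, "ave_lw_ratio"] - 30 * z[, "sd_compactness"] +
      25 * z[, "ave_width_um"] + rnorm(n, 0, noise_sd)
    tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      image_id = sprintf("img%02d", ((seq_len(n) - 1) %/% 3) + 1),
      replicate_index = (seq_len(n) - 1) %% 3
    ) |>
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(x))) |>
      dplyr::mutate(ter = as.numeric(ter))
  })
}

# Constructed profile blobs for cleansing tests: n profiles whose 16
# variables sit at `center` + N(0, sd), tagged with TER values.
profile_blob <- function(n, center, ter, id_prefix, seed, sd = 1) {
  vars <- profile_variables()
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * 16, 0, sd), n, 16) +
      matrix(center, n, 16, byrow = TRUE)
    colnames(x) <- vars
    tibble::tibble(
      sample_id = sprintf("%s%03d", id_prefix, seq_len(n)),
      image_id = sprintf("%s_img%02d", id_prefix, ((seq_len(n) - 1) %/% 3) + 1),
      replicate_index = (seq_len(n) - 1) %% 3
    ) |>
      dplyr::bind_cols(tibble::as_tibble(as.data.frame(x))) |>
      dplyr::mutate(ter = rep_len(ter, n))
  })
}
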