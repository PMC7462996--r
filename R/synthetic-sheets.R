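#' Parameters of a synthetic epithelial sheet
#'
#' Bundles the knobs of the synthetic sheet generator. Three unitless dials
#' in \[0, 1\] control the morphological phenotype and, through a linear
#' latent-quality map, the ground-truth transepithelial electrical
#' resistance (TER) attached to the sheet:
#'
#' * `disorder` — 0 gives eight Lloyd relaxation iterations (a
#'   near-regular honeycomb); 1 gives none (a raw Poisson-Voronoi
#'   mosaic).
#' * `heterogeneity` — mixes a clustered high-density seed population with
#'   a uniform one (small and large cells coexist) and gives a growing
#'   fraction of cells a mild randomly oriented aspect stretch whose
#'   strength rises with the dial, so shape regularity spreads as well as
#'   size.
#' * `elongation` — applies a strong area-preserving anisotropic stretch
#'   (factor 1.4--2.8, random orientation) to a random subset of up to
#'   half the cells.
#'
#' Independently of the dials, every sheet draws two nuisance channels
#' that real acquisitions show regardless of quality: a log-normal
#' cell-size factor and a uniform boundary-ruggedness warp of random
#' amplitude.
#'
#' Ground-truth TER is `70 + 320 * (1 - mean(disorder, heterogeneity,
#' elongation))` plus Gaussian noise with SD `ter_noise_sd`, clipped to
#' the physiological range 70--390 Ohm.cm2, so perfectly regular sheets
#' score 390 and maximally disordered ones 70.
#'
#' @param n_cells Nominal number of cells to seed (>= 10). The realized
#'   count varies around it: degraded sheets carry more, smaller cells
#'   (quality-coupled density shift) and every sheet draws a log-normal
#'   size nuisance, as real lots do.
#' @param field_size Integer vector `c(width, height)` in pixels.
#' @param pixel_area Pixel area in um^2/pixel (square pixels assumed).
#' @param disorder,heterogeneity,elongation Unitless dials in \[0, 1\].
#' @param ter_noise_sd SD of the Gaussian TER noise, Ohm.cm2.
#' @param seed Integer seed; the sheet is fully deterministic given it.
#'
#' @return An object of class `sheet_params`.
#' @export
#' @examples
#' sheet_params(n_cells = 50, field_size = c(256, 256), seed = 1)
sheet_params <- function(n_cells = 300, field_size = c(1024, 1024),
                         pixel_area = 0.61, disorder = 0.5,
                         heterogeneity = 0.5, elongation = 0.5,
                         ter_noise_sd = 15, seed = 1) {
  stopifnot(
    length(n_cells) == 1, n_cells >= 10,
    length(field_size) == 2, all(field_size >= 1),
    length(pixel_area) == 1, pixel_area > 0,
    ter_noise_sd >= 0
  )
  for (dial in c(disorder, heterogeneity, elongation)) {
    if (length(dial) != 1 || is.na(dial) || dial < 0 || dial > 1) {
      stop("disorder, heterogeneity and elongation must each be a single value in [0, 1]",
           call. = FALSE)
    }
  }
  structure(
    list(
      n_cells = as.integer(n_cells),
      field_size = as.integer(field_size),
      pixel_area = pixel_area,
      disorder = disorder,
      heterogeneity = heterogeneity,
      elongation = elongation,
      ter_noise_sd = ter_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sheet_params"
  )
}

new_labeled_sheet <- function(labels, pixel_area, true_ter = NA_real_,
                              provenance = "external") {
  structure(
    list(
      labels = labels,
      pixel_area = pixel_area,
      true_ter = true_ter,
      provenance = provenance
    ),
    class = "labeled_sheet"
  )
}

#' @export
print.labeled_sheet <- function(x, ...) {
  n <- n_cells(x)
  cat("<labeled_sheet> ", ncol(x$labels), "x", nrow(x$labels), " px, ",
      n, " cells, pixel_area ", x$pixel_area, " um2/px", sep = "")
  if (!is.na(x$true_ter)) cat(", true TER ", round(x$true_ter, 1), " Ohm.cm2", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of cells in a label image
#'
#' @param sheet A `labeled_sheet`.
#' @return Integer count of distinct positive labels.
#' @export
n_cells <- function(sheet) {
  stopifnot(inherits(sheet, "labeled_sheet"))
  m <- max(sheet$labels)
  if (m == 0L) 0L else m
}

#' Validate the label-image invariants of a sheet
#'
#' Checks that labels are exactly `{0} %union% {1..N}` with no gaps, that
#' every label occupies at least one pixel and forms a single 4-connected
#' component, and that `true_ter` (if present) lies in \[70, 390\].
#'
#' @param sheet A `labeled_sheet`.
#' @return `sheet`, invisibly; errors describe any violated invariant.
#' @export
validate_labeled_sheet <- function(sheet) {
  stopifnot(inherits(sheet, "labeled_sheet"))
  labs <- sheet$labels
  if (!is.integer(labs)) stop("labels must be an integer matrix", call. = FALSE)
  u <- sort(unique(as.vector(labs)))
  u <- u[u > 0]
  if (length(u) > 0 && !identical(u, seq_len(max(u)))) {
    stop("label values must be contiguous 1..N with no gaps", call. = FALSE)
  }
  if (length(u) > 0) {
    info <- cpp_keep_largest_component(labs)
    if (any(info$n_components != 1L)) {
      bad <- which(info$n_components != 1L)
      stop("labels with multiple 4-connected components: ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (!is.na(sheet$true_ter) && (sheet$true_ter < 70 || sheet$true_ter > 390)) {
    stop("true_ter must lie in [70, 390] Ohm.cm2", call. = FALSE)
  }
  invisible(sheet)
}

# Bilinear upsampling of a coarse grid to ny x nx.
bilerp <- function(g, ny, nx) {
  gx <- seq(1, ncol(g), length.out = nx)
  gy <- seq(1, nrow(g), length.out = ny)
  x0 <- pmin(floor(gx), ncol(g) - 1); fx <- gx - x0
  y0 <- pmin(floor(gy), nrow(g) - 1); fy <- gy - y0
  g[y0, x0] * ((1 - fy) %o% (1 - fx)) + g[y0 + 1, x0] * (fy %o% (1 - fx)) +
    g[y0, x0 + 1] * ((1 - fy) %o% fx) + g[y0 + 1, x0 + 1] * (fy %o% fx)
}

# Resample a label image through a smooth random displacement field of the
# given peak amplitude (pixels), wiggling cell boundaries on a sub-cell
# scale. With modulated = TRUE the local amplitude is itself a coarse
# random field, so boundary irregularity is spatially patchy (some regions
# rugged, others regular); with modulated = FALSE the ruggedness is
# uniform across the sheet.
warp_labels <- function(labels, amplitude, modulated = TRUE, wavelength = 14) {
  nr <- nrow(labels); nc <- ncol(labels)
  kx <- max(4L, round(nc / wavelength)); ky <- max(4L, round(nr / wavelength))
  dx <- bilerp(matrix(rnorm(ky * kx), ky, kx), nr, nc)
  dy <- bilerp(matrix(rnorm(ky * kx), ky, kx), nr, nc)
  mod <- if (modulated) bilerp(matrix(rnorm(36), 6, 6), nr, nc)^2 / 2 else 1
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  xw <- pmin(pmax(round(X + amplitude * mod * dx), 1L), nc)
  yw <- pmin(pmax(round(Y + amplitude * mod * dy), 1L), nr)
  matrix(labels[cbind(as.vector(yw), as.vector(xw))], nr, nc)
}

# Zero out the first pixel of every 4-adjacent pair carrying different
# positive labels, leaving a one-pixel background line between cells
# (the synthetic analogue of F-actin border exclusion in segmentation).
erase_cell_borders <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  border <- matrix(FALSE, nr, nc)
  h1 <- labels[, -nc, drop = FALSE]; h2 <- labels[, -1, drop = FALSE]
  border[, -nc] <- border[, -nc] | (h1 != h2 & h1 > 0 & h2 > 0)
  v1 <- labels[-nr, , drop = FALSE]; v2 <- labels[-1, , drop = FALSE]
  border[-nr, ] <- border[-nr, ] | (v1 != v2 & v1 > 0 & v2 > 0)
  labels[border] <- 0L
  labels
}

# Drop empty labels and renumber the survivors 1..N in ascending original
# label order.
relabel_contiguous <- function(labels) {
  u <- sort(unique(as.vector(labels)))
  u <- u[u > 0]
  if (length(u) == 0) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  pos <- labels > 0
  labels[pos] <- map[labels[pos]]
  labels
}

#' Generate one synthetic epithelial label image
#'
#' Builds a Voronoi tessellation of seeded points, relaxed towards a
#' regular honeycomb by Lloyd iterations (the fewer, the higher
#' `disorder`), with a clustered seed sub-population and mild aspect
#' spread under `heterogeneity`, strongly stretched cells under
#' `elongation`, and the quality-independent size and ruggedness
#' nuisances described in [sheet_params()]. One-pixel borders between
#' adjacent cells are assigned to background, mimicking segmentation of
#' F-actin-outlined cells. The ground-truth TER follows the linear
#' latent-quality map documented in [sheet_params()].
#'
#' @param params A [sheet_params()] object.
#' @return A `labeled_sheet`: integer label matrix (0 = background,
#'   1..N = cells), `pixel_area`, `true_ter` and the generating parameters
#'   as provenance. Deterministic given `params$seed`.
#' @export
#' @examples
#' sheet <- generate_sheet(sheet_params(n_cells = 40, field_size = c(192, 192),
#'                                      seed = 7))
#' n_cells(sheet)
generate_sheet <- function(params) {
  stopifnot(inherits(params, "sheet_params"))
  w <- params$field_size[1]; h <- params$field_size[2]
  if (params$n_cells > w * h) {
    stop("field_size ", w, "x", h, " is too small to host ", params$n_cells,
         " cells: at least one cell would rasterize to 0 pixels", call. = FALSE)
  }
  withr::with_seed(params$seed, {
    # Realized cell count: the nominal n_cells modulated by (i) a
    # quality-coupled density shift (degraded sheets carry more, smaller
    # cells) and (ii) a per-sheet log-normal nuisance, emulating the
    # cell-size variation real sheets show between lots.
    quality_mean <- mean(c(params$disorder, params$heterogeneity,
                           params$elongation))
    n <- max(10L, round(params$n_cells * exp(rnorm(1, 0, 0.08)) *
                          (1 + 0.35 * (quality_mean - 0.5))))
    # seed points: clustered sub-population under heterogeneity
    n_dense <- round(params$heterogeneity * n / 8)
    n_unif <- n - n_dense
    sx <- runif(n_unif, 0, w - 1)
    sy <- runif(n_unif, 0, h - 1)
    if (n_dense > 0) {
      n_patch <- max(1L, round(n_dense / 20))
      cx <- runif(n_patch, 0.15 * w, 0.85 * w)
      cy <- runif(n_patch, 0.15 * h, 0.85 * h)
      pick <- sample.int(n_patch, n_dense, replace = TRUE)
      px <- pmin(pmax(rnorm(n_dense, cx[pick], w / 10), 0), w - 1)
      py <- pmin(pmax(rnorm(n_dense, cy[pick], h / 10), 0), h - 1)
      sx <- c(sx, px); sy <- c(sy, py)
    }

    win_r <- 4 * sqrt(w * h / n)
    iters <- round((1 - params$disorder) * 8)
    if (iters > 0) {
      relaxed <- cpp_lloyd(sx, sy, w, h, iters, 8L, win_r)
      sx <- relaxed[, 1]; sy <- relaxed[, 2]
    }

    # anisotropic stretch of a random subset of cells
    stretch <- rep(1, n)
    theta <- rep(0, n)
    n_elong <- round(params$elongation * n / 2)
    idx <- integer(0)
    if (n_elong > 0) {
      idx <- sample.int(n, n_elong)
      stretch[idx] <- runif(n_elong, 1.4, 2.8)
      theta[idx] <- runif(n_elong, 0, pi)
    }
    # heterogeneity also spreads cell aspect mildly (long and short cells
    # coexist) without the strong oriented stretch of the elongation dial
    n_mild <- round(params$heterogeneity * n / 2)
    if (n_mild > 0) {
      pool <- setdiff(seq_len(n), idx)
      idx2 <- if (length(pool) > n_mild) sample(pool, n_mild) else pool
      stretch[idx2] <- runif(length(idx2), 1.2, 1.4 + 0.8 * params$heterogeneity)
      theta[idx2] <- runif(length(idx2), 0, pi)
    }
    labels <- cpp_voronoi_labels(sx, sy, theta, stretch, rep(1, n), w, h, win_r)
    # uniform ruggedness nuisance, independent of sheet quality (emulates
    # staining / focus variation between acquisitions)
    labels <- warp_labels(labels, runif(1, 1, 4), modulated = FALSE, wavelength = 9)
    labels <- erase_cell_borders(labels)
    labels <- cpp_keep_largest_component(labels)$labels
    labels <- relabel_contiguous(labels)
    kept <- max(labels)
    if (kept < n) {
      warning(n - kept, " of ", n, " seeded cells rasterized to 0 pixels ",
              "and were dropped", call. = FALSE)
    }

    quality <- 1 - mean(c(params$disorder, params$heterogeneity, params$elongation))
    ter <- 70 + 320 * quality + rnorm(1, 0, params$ter_noise_sd)
    ter <- min(max(ter, 70), 390)
  })
  new_labeled_sheet(labels, params$pixel_area, ter, provenance = params)
}

#' Default cohort parameter sampler
#'
#' Draws a latent sheet-quality level from an even two-component mixture
#' (U(0.05, 0.45) or U(0.55, 0.95)) and sets `disorder`,
#' `heterogeneity` and `elongation` to that level plus independent
#' U(-0.15, 0.15) jitter, clamped to \[0.05, 0.95\]. Every other parameter
#' keeps its [sheet_params()] default. The mixture spreads ground-truth
#' TER over the 70--390 Ohm.cm2 range while reproducing the mildly
#' bimodal lot structure of real sheet production (lots tend to either
#' mature into high-resistance epithelia or fail), which is the
#' structure the clustering-based cleansing step presupposes.
#'
#' @param seed Integer sub-seed for this image.
#' @return A `sheet_params` object whose `seed` is `seed`.
#' @export
default_params_sampler <- function(seed) {
  dials <- withr::with_seed(derive_seed(seed, 999983L), {
    q <- if (runif(1) < 0.5) runif(1, 0.05, 0.45) else runif(1, 0.55, 0.95)
    pmin(pmax(q + runif(3, -0.15, 0.15), 0.05), 0.95)
  })
  sheet_params(disorder = dials[1], heterogeneity = dials[2],
               elongation = dials[3], seed = seed)
}

#' Generate a cohort of synthetic sheets
#'
#' @param n_images Number of sheets (>= 1).
#' @param params_sampler Function `seed -> sheet_params` drawing per-image
#'   parameters; defaults to [default_params_sampler()].
#' @param seed Master seed; each image receives an independent sub-seed
#'   derived from it, so the cohort is reproducible as a whole.
#' @return A named list of `labeled_sheet` objects (`img01`, `img02`, ...).
#' @export
#' @examples
#' cohort <- generate_cohort(2, seed = 1,
#'   params_sampler = function(s) sheet_params(n_cells = 40,
#'     field_size = c(192, 192), seed = s))
#' length(cohort)
generate_cohort <- function(n_images, params_sampler = default_params_sampler,
                            seed = 1) {
  stopifnot(n_images >= 1)
  sheets <- purrr::map(seq_len(n_images), function(i) {
    generate_sheet(params_sampler(derive_seed(seed, i)))
  })
  names(sheets) <- sprintf("img%02d", seq_len(n_images))
  sheets
}

#' Reduce a sheet to a random traced subset of its cells
#'
#' Emulates the label-free pathway in which only a few hundred clearly
#' visible cells are manually traced from a phase-contrast image: retains
#' `min(n_traced, N)` randomly chosen cells (their masks pixel-identical
#' to the originals), relabeled contiguously, and sets the rest to
#' background.
#'
#' @param sheet A `labeled_sheet` with at least one cell.
#' @param n_traced Number of cells to retain (default 500).
#' @param seed Integer seed for the random choice.
#' @return A `labeled_sheet` with the retained cells only.
#' @export
degrade_to_traced_subset <- function(sheet, n_traced = 500, seed = 1) {
  stopifnot(inherits(sheet, "labeled_sheet"))
  if (n_traced < 1) stop("n_traced must be >= 1", call. = FALSE)
  n <- n_cells(sheet)
  if (n < 1) stop("sheet has no cells", call. = FALSE)
  keep <- if (n_traced >= n) seq_len(n) else {
    sort(withr::with_seed(seed, sample.int(n, n_traced)))
  }
  labels <- sheet$labels
  labels[!(labels %in% keep)] <- 0L
  labels <- relabel_contiguous(labels)
  out <- sheet
  out$labels <- labels
  out
}
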