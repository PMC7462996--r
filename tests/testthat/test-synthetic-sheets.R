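test_that("noise-free TER map hits its boundary values", {
  p0 <- sheet_params(n_cells = 40, field_size = c(224, 224), disorder = 0,
                     heterogeneity = 0, elongation = 0, ter_noise_sd = 0,
                     seed = 5)
  expect_equal(generate_sheet(p0)$true_ter, 390)
  p1 <- sheet_params(n_cells = 40, field_size = c(224, 224), disorder = 1,
                     heterogeneity = 1, elongation = 1, ter_noise_sd = 0,
                     seed = 5)
  expect_equal(generate_sheet(p1)$true_ter, 70)
})

test_that("sheet generation is deterministic given the seed", {
  p <- sheet_params(n_cells = 80, field_size = c(320, 320), seed = 11)
  a <- generate_sheet(p)
  b <- generate_sheet(p)
  expect_identical(a$labels, b$labels)
  expect_identical(a$true_ter, b$true_ter)
})

test_that("generated label maps satisfy the label-image invariants", {
  for (seed in c(2, 9)) {
    sheet <- small_sheet(seed = seed, heterogeneity = 0.8, elongation = 0.7)
    expect_silent(validate_labeled_sheet(sheet))
    u <- sort(unique(as.vector(sheet$labels)))
    expect_identical(u[u > 0], seq_len(n_cells(sheet)))
  }
})

test_that("a too-small field is rejected with the constraint named", {
  expect_error(
    generate_sheet(sheet_params(n_cells = 200, field_size = c(10, 10))),
    "too small to host"
  )
})

test_that("cohorts are reproducible and their TER values stay in range", {
  c1 <- generate_cohort(5, small_sampler, seed = 31)
  c2 <- generate_cohort(5, small_sampler, seed = 31)
  expect_identical(lapply(c1, `[[`, "labels"), lapply(c2, `[[`, "labels"))
  ters <- vapply(c1, function(s) s$true_ter, numeric(1))
  expect_true(all(ters >= 70 & ters <= 390))
  expect_length(generate_cohort(1, small_sampler, seed = 3), 1)
})

test_that("assigned TER decreases in each dial absent noise", {
  base <- list(n_cells = 40, field_size = c(224, 224), ter_noise_sd = 0, seed = 2)
  ter_at <- function(d, h, e) {
    generate_sheet(do.call(sheet_params, c(base, list(
      disorder = d, heterogeneity = h, elongation = e))))$true_ter
  }
  for (dial in 1:3) {
    vals <- sapply(c(0, 0.5, 1), function(v) {
      args <- c(0.3, 0.3, 0.3); args[dial] <- v
      ter_at(args[1], args[2], args[3])
    })
    expect_true(all(diff(vals) < 0))
  }
})

test_that("traced subsets keep pixel-identical masks of the chosen cells", {
  sheet <- small_sheet(seed = 4)
  n <- n_cells(sheet)

  # more traced cells than present: everything retained
  full <- degrade_to_traced_subset(sheet, n_traced = n + 100, seed = 1)
  expect_identical(full$labels, sheet$labels)

  k <- 40
  sub <- degrade_to_traced_subset(sheet, n_traced = k, seed = 7)
  expect_equal(n_cells(sub), k)
  # every retained cell's pixel set equals some original cell's pixel set
  orig_sets <- split(which(sheet$labels > 0), sheet$labels[sheet$labels > 0])
  sub_sets <- split(which(sub$labels > 0), sub$labels[sub$labels > 0])
  orig_keys <- vapply(orig_sets, paste, character(1), collapse = ",")
  sub_keys <- vapply(sub_sets, paste, character(1), collapse = ",")
  expect_true(all(sub_keys %in% orig_keys))

  expect_error(degrade_to_traced_subset(sheet, n_traced = 0), "n_traced")
})

test_that("cell-shape spread rises monotonically with the heterogeneity dial", {
  # sd of compactness per sheet, heterogeneity 0 -> 0.5 -> 1 with the
  # other dials fixed; paired one-sided rank tests across seeds
  seeds <- 1:20
  res <- sapply(seeds, function(sd0) sapply(c(0, 0.5, 1), function(h) {
    sheet <- generate_sheet(sheet_params(
      n_cells = 150, field_size = c(512, 512), disorder = 0.5,
      heterogeneity = h, elongation = 0, seed = sd0))
    cells <- filter_small_cells(extract_cell_morphologies(sheet),
                                morphometry_config())
    sd(cells$compactness)
  }))
  p1 <- wilcox.test(res[2, ], res[1, ], paired = TRUE,
                    alternative = "greater")$p.value
  p2 <- wilcox.test(res[3, ], res[2, ], paired = TRUE,
                    alternative = "greater")$p.value
  expect_lt(p1, 0.01)
  expect_lt(p2, 0.01)
  expect_true(mean(res[1, ]) < mean(res[2, ]))
  expect_true(mean(res[2, ]) < mean(res[3, ]))
})
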