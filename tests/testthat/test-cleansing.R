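high_low_cohort <- function(n_high = 30, n_low = 30, n_mid = 0,
                            n_discordant = 0, seed = 1) {
  high <- profile_blob(n_high, center = rep(6, 16),
                       ter = withr::with_seed(seed, runif(n_high, 260, 380)),
                       id_prefix = "hi", seed = seed)
  low <- profile_blob(n_low, center = rep(0, 16),
                      ter = withr::with_seed(seed + 1, runif(n_low, 80, 140)),
                      id_prefix = "lo", seed = seed + 1)
  out <- dplyr::bind_rows(high, low)
  if (n_mid > 0) {
    out <- dplyr::bind_rows(out, profile_blob(
      n_mid, center = rep(3, 16),
      ter = withr::with_seed(seed + 2, runif(n_mid, 160, 240)),
      id_prefix = "mid", seed = seed + 2))
  }
  if (n_discordant > 0) {
    # high TER tags planted on low-group morphology and vice versa
    k1 <- ceiling(n_discordant / 2); k2 <- n_discordant - k1
    out <- dplyr::bind_rows(
      out,
      profile_blob(k1, center = rep(0, 16), ter = 320, id_prefix = "dhi",
                   seed = seed + 3),
      profile_blob(k2, center = rep(6, 16), ter = 100, id_prefix = "dlo",
                   seed = seed + 4))
  }
  out
}

test_that("two separated morphology blobs are recovered exactly", {
  profiles <- high_low_cohort(30, 30, seed = 2)
  cl <- cluster_profiles(profiles)
  expect_identical(sort(unique(cl$cluster)), c("A", "B"))
  # cluster A = higher-median-TER cluster = the high blob
  expect_true(all(cl$cluster[grepl("^hi", cl$sample_id)] == "A"))
  expect_true(all(cl$cluster[grepl("^lo", cl$sample_id)] == "B"))

  # permutation invariance (as a set)
  perm <- withr::with_seed(8, sample(nrow(profiles)))
  cl2 <- cluster_profiles(profiles[perm, ], cleansing_config())
  merged <- dplyr::inner_join(cl, cl2, by = "sample_id")
  expect_true(all(merged$cluster.x == merged$cluster.y))
})

test_that("identical profiles trigger the degenerate-cut warning", {
  one <- profile_blob(1, center = rep(1, 16), ter = 300, id_prefix = "x",
                      seed = 1)
  same <- dplyr::bind_rows(replicate(6, one, simplify = FALSE)) |>
    dplyr::mutate(sample_id = sprintf("x%03d", 1:6))
  expect_warning(cluster_profiles(same, cleansing_config()), "degenerate")
})

test_that("missing TER tags are rejected at cleansing time", {
  profiles <- high_low_cohort(5, 5, seed = 3)
  profiles$ter[3] <- NA
  expect_error(cluster_profiles(profiles), "TER tag")
})

test_that("primary selection keeps concordant threshold-passing samples only", {
  profiles <- high_low_cohort(30, 30, n_mid = 20, n_discordant = 4, seed = 5)
  cl <- cleanse_profiles(profiles)

  expect_equal(nrow(cl$selected), 60)
  expect_equal(sum(cl$selected$class == "high"), 30)
  expect_equal(sum(cl$selected$class == "low"), 30)
  expect_true(all(grepl("^(hi|lo)", cl$selected$sample_id)))

  expect_equal(nrow(cl$excluded), 24)
  expect_equal(sum(cl$excluded$reason == "mid-band"), 20)
  expect_equal(sum(cl$excluded$reason == "discordant"), 4)
  expect_true(all(grepl("^mid", cl$excluded$sample_id[cl$excluded$reason == "mid-band"])))
  expect_true(all(grepl("^d", cl$excluded$sample_id[cl$excluded$reason == "discordant"])))

  # conservation: selected + excluded cover the input exactly once
  expect_setequal(c(cl$selected$sample_id, cl$excluded$sample_id),
                  profiles$sample_id)

  # a mid-band profile is excluded whatever its cluster
  expect_true(all(!grepl("^mid", cl$selected$sample_id)))

  # idempotence: cleansing the selected set re-selects all of it
  again <- cleanse_profiles(cl$selected[, c("sample_id", "image_id",
                                            "replicate_index",
                                            profile_variables(), "ter")])
  expect_setequal(again$selected$sample_id, cl$selected$sample_id)
})

test_that("an empty selected class is an error", {
  profiles <- high_low_cohort(10, 10, seed = 6)
  profiles$ter[grepl("^lo", profiles$sample_id)] <- 200 # push lows mid-band
  expect_error(cleanse_profiles(profiles), "empty TER class")
})

test_that("tidy and glance summarize a cleansed cohort", {
  cl <- cleanse_profiles(high_low_cohort(12, 12, n_mid = 6, seed = 7))
  g <- glance(cl)
  expect_equal(g$n_selected, 24)
  expect_equal(g$n_mid_band, 6)
  td <- tidy(cl)
  expect_equal(nrow(td), 30)
})
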