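test_that("an overwhelming penalty shrinks every weight to zero", {
  profiles <- linear_profile_cohort(60, seed = 2)
  fit <- fit_ter_regression(profiles, lambda_rule = "fixed", lambda = 1e6)
  expect_true(all(fit$coef_std == 0))
  pred <- predict(fit, profiles)
  expect_equal(pred$predicted_ter, rep(mean(profiles$ter), nrow(profiles)))
})

test_that("noise-free linear data is interpolated at tiny lambda", {
  profiles <- linear_profile_cohort(60, seed = 3, noise_sd = 0)
  fit <- fit_ter_regression(profiles, lambda_rule = "fixed", lambda = 1e-4)
  pred <- predict(fit, profiles)
  rmse <- sqrt(mean((pred$predicted_ter - profiles$ter)^2))
  expect_lt(rmse, 1)
})

test_that("centering identity: the mean profile predicts the intercept", {
  profiles <- linear_profile_cohort(60, seed = 4)
  fit <- fit_ter_regression(profiles, seed = 1)
  mean_profile <- profiles[1, ]
  for (v in profile_variables()) mean_profile[[v]] <- fit$center[[v]]
  pred <- predict(fit, mean_profile)
  # z-scores vanish at the training means, leaving the standardized-scale
  # intercept (equal to mean TER for the gaussian fit)
  expect_equal(pred$predicted_ter, fit$intercept_std, tolerance = 1e-9)
  expect_equal(fit$intercept_std, mean(profiles$ter), tolerance = 1e-6)

  # positive-coefficient monotonicity
  pos <- names(which(fit$coef_orig > 0))
  if (length(pos) > 0) {
    bumped <- mean_profile
    bumped[[pos[1]]] <- bumped[[pos[1]]] + 1
    expect_gt(predict(fit, bumped)$predicted_ter, pred$predicted_ter)
  }
})

test_that("prediction rejects missing variables by name", {
  profiles <- linear_profile_cohort(30, seed = 5)
  fit <- fit_ter_regression(profiles, lambda_rule = "fixed", lambda = 1)
  broken <- profiles
  broken$ave_width_um[2] <- NA
  expect_error(predict(fit, broken), "ave_width_um")
})

test_that("degenerate training inputs are rejected", {
  profiles <- linear_profile_cohort(30, seed = 6)
  profiles$ter <- 300
  expect_error(fit_ter_regression(profiles), "degenerate")
  profiles$ter <- rep(320, 30)
  expect_error(fit_ter_discriminator(profiles), "both TER classes")
  expect_error(fit_ter_regression(linear_profile_cohort(8, seed = 1)), ">= 10")
})

disc_cohort <- function(seed, n = 60) {
  dplyr::bind_rows(
    profile_blob(n / 2, center = rep(5, 16), ter = 320, id_prefix = "hi",
                 seed = seed),
    profile_blob(n / 2, center = rep(0, 16), ter = 100, id_prefix = "lo",
                 seed = seed + 1)
  )
}

test_that("separable classes are classified perfectly in training", {
  profiles <- disc_cohort(7)
  fit <- fit_ter_discriminator(profiles, seed = 1)
  expect_identical(fit$positive_class, "high")
  pred <- predict(fit, profiles)
  truth <- ifelse(grepl("^hi", profiles$sample_id), "high", "low")
  expect_identical(pred$class, truth)
})

test_that("the intercept-only discriminator returns the class prior", {
  profiles <- dplyr::bind_rows(
    profile_blob(20, center = rep(2, 16), ter = 300, id_prefix = "hi", seed = 3),
    profile_blob(40, center = rep(2.2, 16), ter = 100, id_prefix = "lo", seed = 4)
  )
  fit <- fit_ter_discriminator(profiles, lambda_rule = "fixed", lambda = 1e6)
  expect_true(all(fit$coef_std == 0))
  pred <- predict(fit, profiles)
  expect_equal(unique(round(pred$probability, 10)), round(20 / 60, 10))
})

test_that("confusion metrics match hand-computed rates", {
  obs <- c(rep("high", 50), rep("low", 50))
  pred <- obs
  pred[50] <- "low" # one false negative: TP 49, FN 1, TN 50, FP 0
  m <- rpeqc:::confusion_metrics(obs, pred)
  expect_equal(unname(m["accuracy"]), 0.99)
  expect_equal(unname(m["sensitivity"]), 0.98)
  expect_equal(unname(m["specificity"]), 1.00)
})

test_that("evaluation metrics follow their definitions and ignore row order", {
  profiles <- disc_cohort(9)
  ev <- evaluate_ter_model(profiles, "discrimination", "training_fit", seed = 2)
  expect_equal(unname(ev$metrics["accuracy"]), 1)

  reg_profiles <- linear_profile_cohort(45, seed = 10)
  ev1 <- evaluate_ter_model(reg_profiles, "regression", "loocv_by_image", seed = 3)
  perm <- withr::with_seed(4, sample(nrow(reg_profiles)))
  ev2 <- evaluate_ter_model(reg_profiles[perm, ], "regression",
                            "loocv_by_image", seed = 3)
  expect_equal(ev1$metrics["rmse"], ev2$metrics["rmse"], tolerance = 1e-9)

  # RMSE hand check: observed {1, 4}, predicted {1, 2} -> sqrt(2)
  expect_equal(sqrt(mean((c(1, 4) - c(1, 2))^2)), sqrt(2))
  obs_pred <- ev1$per_sample
  expect_equal(unname(ev1$metrics["rmse"]),
               sqrt(mean((obs_pred$observed_ter - obs_pred$predicted_ter)^2)))

  expect_error(evaluate_ter_model(reg_profiles[1:2, ], "regression",
                                  "loocv_by_sample"), ">= 3")
})

test_that("leave-one-image-out excludes all replicates of the held image", {
  profiles <- linear_profile_cohort(30, seed = 11)
  ev <- evaluate_ter_model(profiles, "regression", "loocv_by_image", seed = 5)
  expect_equal(ev$n, 30)
  expect_equal(nrow(ev$per_sample), 30)
  expect_identical(sort(ev$per_sample$sample_id), sort(profiles$sample_id))
})

test_that("model serialization round-trips to identical predictions", {
  profiles <- linear_profile_cohort(50, seed = 12)
  fit <- fit_ter_regression(profiles, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_ter_model(fit, path)
  back <- read_ter_model(path)
  expect_identical(predict(back, profiles), predict(fit, profiles))

  disc <- fit_ter_discriminator(disc_cohort(13), seed = 7)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_ter_model(disc, path2)
  expect_identical(predict(read_ter_model(path2), disc_cohort(13)),
                   predict(disc, disc_cohort(13)))
})

test_that("tidy and glance expose coefficients and fit summary", {
  fit <- fit_ter_regression(linear_profile_cohort(50, seed = 14), seed = 8)
  td <- tidy(fit)
  expect_equal(nrow(td), 17)
  expect_identical(td$term[1], "(Intercept)")
  g <- glance(fit)
  expect_identical(g$kind, "regression")
  expect_equal(g$n_train, 50)
})
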