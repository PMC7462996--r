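#' @title LASSO models linking sheet morphology to TER
#' @description
#' Two L1-penalised models are fitted on the 16 explanatory variables:
#' a linear TER-value prediction model (`kind = "regression"`) and a
#' logistic high-vs-low discrimination model (`kind = "discrimination"`,
#' positive class = high TER). Variables are z-scored with training
#' statistics stored in the model; the penalty weight is chosen by inner
#' 5-fold cross-validation with the 1-SE rule unless fixed.
#' @name ter_models
NULL

training_profiles <- function(x) {
  if (inherits(x, "cleansed_profiles")) x$selected else x
}

ter_class_labels <- function(ter, low, high) {
  if (anyNA(ter)) stop("training profiles must carry TER tags", call. = FALSE)
  cls <- ifelse(ter > high, "high", ifelse(ter < low, "low", NA))
  if (anyNA(cls)) {
    stop("profiles with mid-band TER (between ", low, " and ", high,
         " Ohm.cm2) cannot be class-labeled; cleanse first", call. = FALSE)
  }
  factor(cls, levels = c("low", "high"))
}

fit_lasso_core <- function(profiles, kind, lambda_rule, lambda, seed,
                           low_ter_max, high_ter_min) {
  x <- profile_matrix(profiles)
  zs <- zscore_columns(x)
  n <- nrow(x)

  if (kind == "regression") {
    y <- profiles$ter
    if (anyNA(y)) stop("training profiles must carry TER tags", call. = FALSE)
    if (sd(y) == 0) stop("degenerate response: all TER values equal", call. = FALSE)
    family <- "gaussian"
  } else {
    y <- ter_class_labels(profiles$ter, low_ter_max, high_ter_min)
    if (length(unique(y)) < 2) {
      stop("discrimination needs both TER classes in training data", call. = FALSE)
    }
    family <- "binomial"
  }

  if (lambda_rule == "inner_cv") {
    # Fold labels are drawn for the samples in sample_id order, so the
    # assignment (and hence lambda) does not depend on row order; for the
    # logistic model folds are additionally stratified by class so no
    # inner training set loses a class.
    ord <- order(profiles$sample_id)
    foldid <- integer(n)
    if (family == "binomial") {
      cls_sorted <- y[ord]
      folds_sorted <- integer(n)
      for (lev in levels(cls_sorted)) {
        idx <- which(cls_sorted == lev)
        folds_sorted[idx] <- withr::with_seed(
          derive_seed(seed, 77L + match(lev, levels(cls_sorted))),
          sample(rep_len(1:5, length(idx))))
      }
    } else {
      folds_sorted <- withr::with_seed(derive_seed(seed, 77L),
                                       sample(rep_len(1:5, n)))
    }
    foldid[ord] <- folds_sorted
    cv <- glmnet::cv.glmnet(zs$z, y, family = family, foldid = foldid,
                            standardize = FALSE)
    lambda <- cv$lambda.1se
  } else if (is.null(lambda)) {
    stop("lambda_rule = \"fixed\" requires a lambda value", call. = FALSE)
  }

  fit <- glmnet::glmnet(zs$z, y, family = family, standardize = FALSE,
                        lambda = lambda)
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda))
  intercept_std <- cf[1]
  coef_std <- cf[-1]
  names(coef_std) <- profile_variables()
  coef_orig <- coef_std / zs$scale
  intercept_orig <- intercept_std - sum(coef_std * zs$center / zs$scale)

  structure(
    list(
      kind = kind,
      variable_names = profile_variables(),
      coef_std = coef_std,
      coef_orig = stats::setNames(coef_orig, profile_variables()),
      intercept_std = intercept_std,
      intercept_orig = intercept_orig,
      center = stats::setNames(as.numeric(zs$center), profile_variables()),
      scale = stats::setNames(as.numeric(zs$scale), profile_variables()),
      lambda = lambda,
      lambda_rule = lambda_rule,
      positive_class = if (kind == "discrimination") "high" else NA_character_,
      thresholds = c(low_ter_max = low_ter_max, high_ter_min = high_ter_min),
      n_train = n,
      seed = as.integer(seed)
    ),
    class = "ter_model"
  )
}

#' Fit the LASSO TER-value prediction model
#'
#' @param data A `cleansed_profiles` object or a tibble of sample profiles
#'   with TER tags (>= 10 rows).
#' @param lambda_rule `"inner_cv"` (default: 5-fold CV, 1-SE rule, seeded)
#'   or `"fixed"`.
#' @param lambda Penalty weight when `lambda_rule = "fixed"`.
#' @param seed Integer seed for the inner CV folds.
#' @param low_ter_max,high_ter_min TER class thresholds (Ohm.cm2) recorded
#'   in the model and used by the discriminator.
#' @return A `ter_model` of kind `"regression"` holding standardized and
#'   back-transformed coefficients, the standardization statistics and
#'   the selected lambda.
#' @export
fit_ter_regression <- function(data, lambda_rule = c("inner_cv", "fixed"),
                               lambda = NULL, seed = 1,
                               low_ter_max = 150, high_ter_min = 250) {
  lambda_rule <- match.arg(lambda_rule)
  profiles <- training_profiles(data)
  if (nrow(profiles) < 10) {
    stop("need >= 10 training profiles for the regression model", call. = FALSE)
  }
  fit_lasso_core(profiles, "regression", lambda_rule, lambda, seed,
                 low_ter_max, high_ter_min)
}

#' Fit the LASSO high-vs-low TER discrimination model
#'
#' L1-regularized logistic regression; class labels derive from the
#' cleansing TER thresholds (never from predicted TER), positive class =
#' high, decision threshold 0.5.
#'
#' @inheritParams fit_ter_regression
#' @return A `ter_model` of kind `"discrimination"`.
#' @export
fit_ter_discriminator <- function(data, lambda_rule = c("inner_cv", "fixed"),
                                  lambda = NULL, seed = 1,
                                  low_ter_max = 150, high_ter_min = 250) {
  lambda_rule <- match.arg(lambda_rule)
  profiles <- training_profiles(data)
  fit_lasso_core(profiles, "discrimination", lambda_rule, lambda, seed,
                 low_ter_max, high_ter_min)
}

#' @export
print.ter_model <- function(x, ...) {
  nz <- sum(x$coef_std != 0)
  cat("<ter_model> ", x$kind, ", lambda = ", signif(x$lambda, 4), " (",
      x$lambda_rule, "), ", nz, "/16 non-zero coefficients, n_train = ",
      x$n_train, "\n", sep = "")
  invisible(x)
}

#' Predict TER values or classes for sample profiles
#'
#' @param object A `ter_model`.
#' @param profiles Tibble of sample profiles carrying all 16 variables
#'   (TER tags optional).
#' @param ... Unused.
#' @return For regression: tibble `sample_id`, `predicted_ter` (Ohm.cm2).
#'   For discrimination: tibble `sample_id`, `probability` (of the high
#'   class), `class` (`"high"` if probability > 0.5 else `"low"`).
#' @export
predict.ter_model <- function(object, profiles, ...) {
  x <- profile_matrix(profiles)
  bad <- colnames(x)[colSums(!is.finite(x)) > 0]
  if (length(bad) > 0) {
    stop("missing or non-finite values in variable(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  eta <- as.numeric(z %*% object$coef_std + object$intercept_std)
  if (object$kind == "regression") {
    tibble::tibble(sample_id = profiles$sample_id, predicted_ter = eta)
  } else {
    p <- stats::plogis(eta)
    tibble::tibble(
      sample_id = profiles$sample_id,
      probability = p,
      class = ifelse(p > 0.5, "high", "low")
    )
  }
}

#' @export
tidy.ter_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$variable_names),
    estimate = c(x$intercept_orig, unname(x$coef_orig)),
    estimate_std = c(x$intercept_std, unname(x$coef_std))
  )
}

#' @export
glance.ter_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    lambda = x$lambda,
    lambda_rule = x$lambda_rule,
    n_nonzero = sum(x$coef_std != 0),
    n_train = x$n_train
  )
}

confusion_metrics <- function(observed, predicted, positive = "high") {
  pos <- observed == positive
  tp <- sum(pos & predicted == positive)
  fn <- sum(pos & predicted != positive)
  tn <- sum(!pos & predicted != positive)
  fp <- sum(!pos & predicted == positive)
  c(
    accuracy = (tp + tn) / length(observed),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Evaluate a model family on tagged profiles
#'
#' Refits the requested model under the chosen validation scheme and
#' reports RMSE (regression) or accuracy/sensitivity/specificity
#' (discrimination, positive class = high).
#'
#' * `training_fit` — fit once on all profiles, score on the same data.
#' * `loocv_by_sample` — leave one profile out per fold.
#' * `loocv_by_image` — leave all replicates of one image out per fold
#'   (the default granularity elsewhere in the package, since replicates
#'   of one image share cells and would otherwise leak).
#'
#' @param data A `cleansed_profiles` object or profile tibble with TER
#'   tags (and both classes, for discrimination).
#' @param kind `"regression"` or `"discrimination"`.
#' @param scheme Validation scheme (see above).
#' @inheritParams fit_ter_regression
#' @return An object of class `ter_eval`: metrics plus a `per_sample`
#'   tibble of observed and predicted values.
#' @export
evaluate_ter_model <- function(data, kind = c("regression", "discrimination"),
                               scheme = c("loocv_by_image", "loocv_by_sample",
                                          "training_fit"),
                               lambda_rule = c("inner_cv", "fixed"),
                               lambda = NULL, seed = 1,
                               low_ter_max = 150, high_ter_min = 250) {
  kind <- match.arg(kind)
  scheme <- match.arg(scheme)
  lambda_rule <- match.arg(lambda_rule)
  profiles <- training_profiles(data)
  if (anyNA(profiles$ter)) {
    stop("evaluation requires TER tags on every profile", call. = FALSE)
  }
  n <- nrow(profiles)
  if (scheme != "training_fit" && n < 3) {
    stop("leave-one-out validation needs >= 3 profiles", call. = FALSE)
  }

  fit_fun <- if (kind == "regression") fit_ter_regression else fit_ter_discriminator

  # folds keyed by sorted identifiers so results ignore input row order
  folds <- switch(scheme,
    training_fit = list(integer(0)),
    loocv_by_sample = as.list(order(profiles$sample_id)),
    loocv_by_image = {
      imgs <- sort(unique(profiles$image_id))
      lapply(imgs, function(im) which(profiles$image_id == im))
    }
  )

  preds <- purrr::imap(folds, function(test_idx, k) {
    if (length(test_idx) == 0) {
      train <- profiles; test <- profiles
    } else {
      train <- profiles[-test_idx, , drop = FALSE]
      test <- profiles[test_idx, , drop = FALSE]
    }
    model <- fit_fun(train, lambda_rule = lambda_rule, lambda = lambda,
                     seed = derive_seed(seed, k),
                     low_ter_max = low_ter_max, high_ter_min = high_ter_min)
    predict(model, test)
  })
  pred <- dplyr::bind_rows(preds)

  obs <- profiles |>
    dplyr::select("sample_id", dplyr::any_of("image_id"), observed_ter = "ter")
  per_sample <- dplyr::left_join(obs, pred, by = "sample_id")

  if (kind == "regression") {
    rmse <- sqrt(mean((per_sample$observed_ter - per_sample$predicted_ter)^2))
    metrics <- c(rmse = rmse)
  } else {
    observed_class <- as.character(
      ter_class_labels(per_sample$observed_ter, low_ter_max, high_ter_min))
    per_sample$observed_class <- observed_class
    metrics <- confusion_metrics(observed_class, per_sample$class)
  }

  structure(
    list(kind = kind, scheme = scheme, metrics = metrics,
         per_sample = per_sample, n = n, seed = as.integer(seed),
         thresholds = c(low_ter_max = low_ter_max, high_ter_min = high_ter_min)),
    class = "ter_eval"
  )
}

#' @export
print.ter_eval <- function(x, ...) {
  cat("<ter_eval> ", x$kind, ", ", x$scheme, ", n = ", x$n, "\n  ", sep = "")
  cat(paste(names(x$metrics), signif(x$metrics, 4), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ter_eval <- function(x, ...) {
  x$per_sample
}

#' @export
glance.ter_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(kind = x$kind, scheme = x$scheme, n = x$n),
    tibble::as_tibble(as.list(x$metrics))
  )
}
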