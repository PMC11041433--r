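# Mapping the (tone-calibrated) ratio of ratios to SpO2 percent: a
# fixed linear map, least-squares fits (linear and quadratic), and
# k-fold cross-validated evaluation.

#' Linear R-to-SpO2 model
#'
#' `SpO2 = m * R + b`, clamped to `[0, 100]`. The default slope and
#' intercept (m = 79.3, b = -5.7) are the packaged calibration for the
#' red/blue screen pair.
#'
#' @param m Slope (finite, nonzero).
#' @param b Intercept.
#' @return Object of class `linear_spo2_model`.
#' @export
linear_spo2_model <- function(m = 79.3, b = -5.7) {
  if (!is.finite(m) || !is.finite(b)) {
    ox_stop("model coefficients must be finite", "oxitone_config_error")
  }
  structure(list(m = m, b = b), class = "linear_spo2_model")
}

#' @export
print.linear_spo2_model <- function(x, ...) {
  cat(sprintf("Linear SpO2 model: SpO2 = %.4g R %+.4g (clamped to [0, 100])\n",
              x$m, x$b))
  invisible(x)
}

#' Apply a tone-normalization coefficient to R values
#'
#' Multiplies the ratio of ratios by the calibration coefficient of the
#' measured Fitzpatrick class, mapping it onto the reference tone's scale
#' before the SpO2 model is applied. The reference class has coefficient
#' 1, so its values pass through unchanged.
#'
#' @param r_value Ratio-of-ratios value(s).
#' @param table A [calibration_table].
#' @param tone_class Fitzpatrick class of the subject.
#' @param pair Wavelength pair, `"red_blue"` (default) or `"red_ir"`.
#' @return Calibrated R value(s).
#' @export
apply_calibration <- function(r_value, table, tone_class,
                              pair = c("red_blue", "red_ir")) {
  get_coefficient(table, tone_class, match.arg(pair)) * r_value
}

#' Map R values to SpO2 percent with a linear model
#'
#' @param r_value Ratio-of-ratios value(s).
#' @param model A [linear_spo2_model].
#' @return SpO2 percent in `[0, 100]` (`NA` propagates).
#' @export
#' @examples
#' linear_map(1)  # 79.3 - 5.7 = 73.6
linear_map <- function(r_value, model = linear_spo2_model()) {
  stopifnot(inherits(model, "linear_spo2_model"))
  pmin(pmax(model$m * r_value + model$b, 0), 100)
}

#' @export
predict.linear_spo2_model <- function(object, newdata, ...) {
  linear_map(newdata, object)
}

#' Fit the linear R-to-SpO2 model by least squares
#'
#' @param r_values Ratio-of-ratios values (length >= 3, not all equal).
#' @param spo2_truth Reference SpO2 percent, same length.
#' @return List with `model` (a [linear_spo2_model]) and `metrics`
#'   (training-set [regression_metrics()]).
#' @export
fit_linear <- function(r_values, spo2_truth) {
  ok <- is.finite(r_values) & is.finite(spo2_truth)
  r <- r_values[ok]; y <- spo2_truth[ok]
  if (length(r) < 3 && length(r) != 2) {
    ox_stop("need at least 3 paired points (2 for an exact line)",
            "oxitone_fit_error")
  }
  if (diff(range(r)) == 0) {
    ox_stop("r_values are all equal; slope is unidentifiable",
            "oxitone_fit_error")
  }
  fit <- stats::lm(y ~ r)
  model <- linear_spo2_model(m = unname(stats::coef(fit)[2]),
                             b = unname(stats::coef(fit)[1]))
  pred <- model$m * r + model$b   # unclamped for training metrics
  list(model = model, metrics = regression_metrics(pred, y))
}

#' Fit a quadratic R-to-SpO2 model
#'
#' Degree-2 polynomial least squares on the standardized R value (the
#' documented fallback for the quadratic-kernel regressor; this
#' environment ships no SVM implementation, and on a one-dimensional
#' predictor a degree-2 polynomial spans the same hypothesis class as a
#' quadratic-kernel machine). Deterministic; predictions are clamped to
#' `[0, 100]`.
#'
#' @param r_values Ratio-of-ratios values (length >= 10).
#' @param spo2_truth Reference SpO2 percent, same length.
#' @param standardize Center/scale R before fitting (default `TRUE`).
#' @return Object of class `quadratic_spo2_model` with elements
#'   `coefficients` (intercept, linear, quadratic), `center`, `scale`,
#'   `r_range`, `fitted` flag and training `metrics`.
#' @export
fit_quadratic <- function(r_values, spo2_truth, standardize = TRUE) {
  ok <- is.finite(r_values) & is.finite(spo2_truth)
  r <- r_values[ok]; y <- spo2_truth[ok]
  if (length(r) < 10) {
    ox_stop("need at least 10 paired points for the quadratic model",
            "oxitone_fit_error")
  }
  ctr <- if (standardize) mean(r) else 0
  scl <- if (standardize && stats::sd(r) > 0) stats::sd(r) else 1
  x <- (r - ctr) / scl
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  cf[is.na(cf)] <- 0
  pred <- cf[1] + cf[2] * x + cf[3] * x^2
  structure(list(coefficients = cf, center = ctr, scale = scl,
                 r_range = range(r), fitted = TRUE,
                 metrics = regression_metrics(pred, y)),
            class = "quadratic_spo2_model")
}

#' @export
predict.quadratic_spo2_model <- function(object, newdata, ...) {
  stopifnot(isTRUE(object$fitted))
  x <- (newdata - object$center) / object$scale
  cf <- object$coefficients
  pmin(pmax(cf[1] + cf[2] * x + cf[3] * x^2, 0), 100)
}

#' @export
print.quadratic_spo2_model <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "Quadratic SpO2 model: %.4g %+.4g z %+.4g z^2, z = (R - %.4g)/%.4g\n",
    cf[1], cf[2], cf[3], x$center, x$scale))
  invisible(x)
}

#' k-fold cross-validated evaluation of an R-to-SpO2 model
#'
#' Shuffles the data into `folds` folds with an explicit seed, fits the
#' model on each training partition, pools the out-of-fold predictions,
#' and reports [regression_metrics()] on the pool.
#'
#' @param model_spec `"linear"`, `"quadratic"`, or a function
#'   `(r_train, y_train) -> function(r_new)` for custom models.
#' @param r_values,spo2_truth Paired data (`length >= folds`).
#' @param folds Number of folds (default 10, minimum 2).
#' @param seed Integer seed for the fold shuffle.
#' @return Object of class `cv_report`: list with `folds`, `r2`, `rmse`,
#'   `mse`, `mae` and the pooled `predictions`.
#' @export
cross_validate <- function(model_spec, r_values, spo2_truth,
                           folds = 10, seed = 1) {
  n <- length(r_values)
  stopifnot(length(spo2_truth) == n)
  if (folds < 2 || folds > n) {
    ox_stop(sprintf("folds must be in [2, n]; got %d with n = %d", folds, n),
            "oxitone_config_error")
  }
  fitter <- if (is.function(model_spec)) {
    model_spec
  } else if (identical(model_spec, "linear")) {
    function(r, y) { m <- fit_linear(r, y)$model; function(nr) predict(m, nr) }
  } else if (identical(model_spec, "quadratic")) {
    function(r, y) { m <- fit_quadratic(r, y); function(nr) predict(m, nr) }
  } else {
    ox_stop("model_spec must be 'linear', 'quadratic', or a function",
            "oxitone_config_error")
  }
  assign_fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  pred <- rep(NA_real_, n)
  for (k in seq_len(folds)) {
    test <- assign_fold == k
    f <- fitter(r_values[!test], spo2_truth[!test])
    pred[test] <- f(r_values[test])
  }
  m <- regression_metrics(pred, spo2_truth)
  structure(c(list(folds = folds), m, list(predictions = pred)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: R^2 = %.3f, RMSE = %.3f, MSE = %.3f, MAE = %.3f\n",
              x$folds, x$r2, x$rmse, x$mse, x$mae))
  invisible(x)
}

#' Serialize an SpO2 model to JSON
#' @param model A `linear_spo2_model` or `quadratic_spo2_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spo2_model <- function(model, path) {
  obj <- if (inherits(model, "linear_spo2_model")) {
    list(type = "linear", m = model$m, b = model$b)
  } else if (inherits(model, "quadratic_spo2_model")) {
    list(type = "quadratic", coefficients = model$coefficients,
         center = model$center, scale = model$scale,
         r_range = model$r_range)
  } else {
    ox_stop("not an SpO2 model", "oxitone_config_error")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an SpO2 model from JSON
#' @param path Path written by [write_spo2_model()].
#' @return A model object.
#' @export
read_spo2_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "linear")) {
    linear_spo2_model(obj$m, obj$b)
  } else if (identical(obj$type, "quadratic")) {
    structure(list(coefficients = obj$coefficients, center = obj$center,
                   scale = obj$scale, r_range = obj$r_range,
                   fitted = TRUE, metrics = NULL),
              class = "quadratic_spo2_model")
  } else {
    ox_stop("unrecognized model JSON", "oxitone_parse_error")
  }
}
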