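# Exact additive interpretation of linear-model predictions.

z_quantile <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Per-feature weights with Wald confidence intervals
#'
#' Each weight is reported with the normal-approximation interval
#' `weight +/- z(level) * sqrt(var)` from the model's coefficient covariance.
#' The intercept is included as feature `"(Intercept)"`.
#'
#' @param model A fitted `guidelm` (must carry a coefficient covariance).
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `feature, weight, ci_low, ci_high, level`.
#' @export
weight_summary <- function(model, level = 0.95) {
  covb <- model$coef_covariance
  if (is.null(covb)) gl_abort("model has no coefficient covariance", "missing_covariance")
  w <- coef_full(model)
  se <- sqrt(pmax(diag(covb), 0))
  z <- z_quantile(level)
  data.frame(feature = names(w), weight = unname(w),
             ci_low = unname(w - z * se), ci_high = unname(w + z * se),
             level = level, stringsAsFactors = FALSE, row.names = NULL)
}

# Tukey boxplot statistics with type-7 (linear-interpolation) quantiles
boxplot_stats <- function(values) {
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(q25 = qs[1], median = qs[2], q75 = qs[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}

#' Feature effects for one guide against the training distribution
#'
#' The effect of a feature is its value times its model weight — the exact
#' additive contribution to the linear predictor.  For each feature this
#' returns the instance effect together with Tukey boxplot statistics of the
#' effect distribution over the training set: 25/50/75% quantiles (linear
#' interpolation between order statistics), whiskers clamped to the most
#' extreme points within 1.5 IQR of the box, and the outliers beyond them.
#'
#' @param model A fitted `guidelm`.
#' @param x A single validated 30-mer (or a 1-row design matrix matching the
#'   model schema).
#' @param training_X Design matrix of the training guides over the model
#'   schema.
#' @return Data frame with one row per feature: `feature, weight, value,
#'   effect, median, q25, q75, whisker_low, whisker_high, n_outliers`, plus an
#'   `outliers` list column.
#' @export
feature_effects <- function(model, x, training_X) {
  xv <- if (is.matrix(x)) {
    check_schema_match(x, model$schema)
    x[1L, ]
  } else {
    build_matrix(x, model$schema)[1L, ]
  }
  check_schema_match(training_X, model$schema)
  w <- model$coefficients
  rows <- lapply(seq_along(w), function(j) {
    train_eff <- unname(w[j] * training_X[, j])
    st <- boxplot_stats(train_eff)
    data.frame(feature = names(w)[j], weight = unname(w[j]),
               value = unname(xv[j]), effect = unname(w[j] * xv[j]),
               median = st$median, q25 = st$q25, q75 = st$q75,
               whisker_low = st$whisker_low, whisker_high = st$whisker_high,
               n_outliers = length(st$outliers), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$outliers <- lapply(seq_along(w), function(j) {
    boxplot_stats(unname(w[j] * training_X[, j]))$outliers
  })
  out
}

#' Background-centered additive attribution
#'
#' For a linear model on the linear-predictor scale, the attribution of
#' feature j is `weight_j * (x_j - mean(background_j))`.  The attributions
#' satisfy the completeness identity exactly: they sum to the difference
#' between the instance's linear predictor and the mean linear predictor over
#' the background set.  `scale = "response"` additionally reports the
#' response-scale prediction difference as a clearly separate quantity (the
#' additive identity itself only holds on the link scale).
#'
#' @param model A fitted `guidelm`.
#' @param x A single validated 30-mer or 1-row design matrix.
#' @param background_X Design matrix of background guides over the model
#'   schema.
#' @param scale `"link"` (default) or `"response"` (adds attributes).
#' @return Named numeric vector of per-feature attributions, with attributes
#'   `prediction` (the instance linear predictor) and `background_mean` (mean
#'   background linear predictor).
#' @export
centered_attribution <- function(model, x, background_X,
                                 scale = c("link", "response")) {
  scale <- match.arg(scale)
  xv <- if (is.matrix(x)) {
    check_schema_match(x, model$schema)
    x[1L, ]
  } else {
    build_matrix(x, model$schema)[1L, ]
  }
  if (!is.matrix(background_X) || nrow(background_X) == 0L) {
    gl_abort("background set is empty", "empty_background")
  }
  check_schema_match(background_X, model$schema)
  mu <- colMeans(background_X)
  attr_vec <- model$coefficients * (xv - mu)
  eta_x <- sum(model$coefficients * xv) + model$intercept
  eta_bg <- mean(background_X %*% model$coefficients) + model$intercept
  out <- stats::setNames(as.numeric(attr_vec), names(model$coefficients))
  attr(out, "prediction") <- eta_x
  attr(out, "background_mean") <- eta_bg
  if (scale == "response" && model$family != "ols") {
    attr(out, "prediction_response") <- stats::plogis(eta_x)
    attr(out, "background_mean_response") <- stats::plogis(eta_bg)
  }
  out
}
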