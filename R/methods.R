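# S3 methods for fitted guidelm objects.

coef_full <- function(object) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @method coef guidelm
#' @export
coef.guidelm <- function(object, ...) coef_full(object)

#' @method vcov guidelm
#' @export
vcov.guidelm <- function(object, ...) object$coef_covariance

#' @method fitted guidelm
#' @export
fitted.guidelm <- function(object, ...) object$fitted

#' @method residuals guidelm
#' @export
residuals.guidelm <- function(object, ...) object$residuals

#' @method print guidelm
#' @export
print.guidelm <- function(x, ...) {
  cat(sprintf("guidelm fit: %s model (%s, %s), %d features, n = %d\n",
              x$family, x$promoter, x$task, length(x$coefficients), x$n))
  if (!is.na(x$iterations)) {
    cat(sprintf("  IRLS converged in %d iteration(s)\n", x$iterations))
  }
  cat(sprintf("  intercept %.4f; dispersion %.4g\n", x$intercept, x$dispersion))
  invisible(x)
}

#' @method summary guidelm
#' @export
summary.guidelm <- function(object, level = 0.95, ...) {
  ws <- weight_summary(object, level = level)
  structure(list(model = object, weights = ws, level = level),
            class = "summary.guidelm")
}

#' @method print summary.guidelm
#' @export
print.summary.guidelm <- function(x, ...) {
  print(x$model)
  cat(sprintf("\nWeights with %d%% confidence intervals:\n", round(100 * x$level)))
  w <- x$weights
  w[, c("weight", "ci_low", "ci_high")] <-
    round(w[, c("weight", "ci_low", "ci_high")], 4)
  print.data.frame(w, row.names = FALSE)
  invisible(x)
}

check_schema_match <- function(X, schema) {
  want <- schema_names(schema)
  have <- colnames(X)
  if (identical(have, want)) return(invisible(TRUE))
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  msg <- "design matrix does not match the model schema"
  if (length(missing)) msg <- paste0(msg, "; missing: ", paste(missing, collapse = ", "))
  if (length(extra)) msg <- paste0(msg, "; extra: ", paste(extra, collapse = ", "))
  if (!length(missing) && !length(extra)) msg <- paste0(msg, "; columns out of order")
  gl_abort(msg, "schema_mismatch")
}

#' Predict guide-efficiency scores
#'
#' Deterministic scores for new guides: fractional-logit and logistic models
#' return probabilities in (0,1); ordinary-least-squares models return
#' unbounded continuous scores.  `type = "link"` returns the linear predictor.
#'
#' @param object A fitted `guidelm` model.
#' @param newdata A `guide_set`, a character vector of validated 30-mers, or a
#'   numeric design matrix whose columns match the model schema exactly (names
#'   and order).
#' @param type `"response"` (default) or `"link"`.
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.guidelm <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) {
    check_schema_match(newdata, object$schema)
    newdata
  } else {
    build_matrix(newdata, object$schema)
  }
  eta <- drop(X %*% object$coefficients) + object$intercept
  if (type == "link" || object$family == "ols") eta else stats::plogis(eta)
}

#' Score, rank and optionally label a set of guides
#'
#' Convenience wrapper producing the full prediction table: one row per guide
#' with its score, rank (1 = best, stable ties) and, for classification
#' models, the hard label at the 0.5 probability threshold.
#'
#' @param object A fitted `guidelm` model.
#' @param guides A `guide_set` or character vector of validated 30-mers.
#' @param threshold Probability cutoff for the classification label
#'   (default 0.5).
#' @return Data frame with columns `id, sequence, score, rank, label`
#'   (label `"none"` for regression models).
#' @export
score_guides <- function(object, guides, threshold = 0.5) {
  s <- as_sequence_vector(guides)
  ids <- if (inherits(guides, "guide_set")) guides$id else
    if (!is.null(names(s))) names(s) else paste0("seq_", seq_along(s))
  score <- predict(object, guides)
  label <- if (object$task == "classification") {
    ifelse(score >= threshold, "efficient", "inefficient")
  } else {
    rep("none", length(score))
  }
  data.frame(id = ids, sequence = unname(s), score = unname(score),
             rank = rank_guides(score), label = label,
             stringsAsFactors = FALSE)
}

#' Plot model weights with confidence intervals
#'
#' Point-and-line weight plot: each feature's weight as a point, with its Wald
#' confidence interval as a vertical line.
#'
#' @param x A fitted `guidelm` model.
#' @param level Confidence level (default 0.95).
#' @param ... Passed to [graphics::plot()].
#' @method plot guidelm
#' @export
plot.guidelm <- function(x, level = 0.95, ...) {
  ws <- weight_summary(x, level = level)
  ws <- ws[ws$feature != "(Intercept)", , drop = FALSE]
  idx <- seq_len(nrow(ws))
  graphics::plot(idx, ws$weight, ylim = range(ws$ci_low, ws$ci_high),
                 xaxt = "n", xlab = "", ylab = "weight",
                 pch = 19, ...)
  graphics::segments(idx, ws$ci_low, idx, ws$ci_high)
  graphics::abline(h = 0, lty = 3)
  graphics::axis(1, at = idx, labels = ws$feature, las = 2, cex.axis = 0.7)
  invisible(ws)
}

#' Simulate responses from a fitted model
#'
#' OLS models draw Gaussian responses around the fitted means with the
#' estimated residual variance; logistic models draw Bernoulli labels at the
#' fitted probabilities.  The quasi-likelihood fractional-logit family
#' specifies only a mean-variance relationship, not a full distribution, so it
#' cannot be simulated from.
#'
#' @param object A fitted `guidelm` model.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.guidelm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  sims <- switch(object$family,
    ols = replicate(nsim, stats::rnorm(n, object$fitted, sqrt(object$dispersion))),
    logistic = replicate(nsim, stats::rbinom(n, 1L, object$fitted)),
    gl_abort("the quasi-likelihood fractional-logit family has no full distribution to simulate from",
             "not_simulable")
  )
  as.data.frame(matrix(sims, nrow = n,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}
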