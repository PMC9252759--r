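#' Fit a guide-efficiency linear model
#'
#' The front door of the package: featurizes validated 30-nt targets and fits
#' the linear-family model appropriate to the expression system and task.
#' Guides expressed from the U6 promoter report efficiency as a fraction in
#' \[0,1\], modelled by quasi-likelihood fractional-logit regression; T7
#' (in-vitro) efficiencies are continuous scores, modelled by ordinary least
#' squares.  For the classification task the response is reduced to
#' efficient/inefficient labels for the top and bottom `fraction` of guides
#' (see [label_top_bottom()]) and a logistic model is fitted.
#'
#' @param sequences A `guide_set` (see [read_csv_targets()]), or a character
#'   vector of validated 30-mers.
#' @param response Numeric efficiency vector, one per guide.  Must lie in
#'   \[0,1\] for U6 regression.
#' @param promoter `"U6"` or `"T7"`.
#' @param task `"regression"` or `"classification"`.
#' @param schema [feature_schema()] to featurize with; default
#'   [candidate_schema()].
#' @param select Run [select_features()] on the candidate schema before
#'   fitting (default `TRUE` when `schema` is not supplied).
#' @param fraction Top/bottom labeling fraction for the classification task
#'   (default 0.20).
#' @param config Selection configuration, see [select_config()].
#' @return An object of class `guidelm` with print, summary, coef, vcov,
#'   predict, residuals, fitted, plot and simulate methods.
#' @examples
#' guides <- random_targets(120, seed = 1)
#' truth <- default_truth("fractional")
#' y <- simulate_efficiencies(guides, truth, seed = 2)
#' fit <- guidelm(guides, y, promoter = "U6", schema = truth$schema, select = FALSE)
#' summary(fit)
#' @export
guidelm <- function(sequences, response,
                    promoter = c("U6", "T7"),
                    task = c("regression", "classification"),
                    schema = NULL, select = is.null(schema),
                    fraction = 0.20, config = select_config()) {
  promoter <- match.arg(promoter)
  task <- match.arg(task)
  if (is.null(schema)) schema <- candidate_schema()
  seqs <- as_sequence_vector(sequences)
  if (length(seqs) != length(response)) {
    gl_abort(sprintf("%d sequences but %d responses", length(seqs), length(response)),
             "shape_mismatch")
  }
  X <- build_matrix(sequences, schema)
  if (select) {
    schema <- select_features(X, response, schema, config)
    X <- X[, schema_names(schema), drop = FALSE]
  }
  fit <- if (task == "classification") {
    labels <- label_top_bottom(response, fraction)
    keep <- labels != "unlabeled"
    fit_logistic(X[keep, , drop = FALSE], labels[keep], schema = schema)
  } else if (promoter == "U6") {
    fit_fractional_logit(X, response, schema = schema)
  } else {
    fit_ols(X, response, schema = schema)
  }
  fit$promoter <- promoter
  fit$task <- task
  fit
}

# shared constructor for fitted models
new_guidelm <- function(family, schema, coef_full, cov_full, fitted, residuals,
                        dispersion, n, converged = TRUE, iterations = NA_integer_) {
  nm <- names(coef_full)
  structure(list(
    promoter = NA_character_, task = NA_character_,
    family = family, schema = schema,
    intercept = unname(coef_full[1L]),
    coefficients = coef_full[-1L],
    coef_covariance = cov_full,
    dispersion = dispersion, fitted = fitted, residuals = residuals,
    n = n, converged = converged, iterations = iterations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = c(paste0("guidelm_", gsub("-", "_", family)), "guidelm"))
}

check_design <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) {
    gl_abort(sprintf("design has %d rows but response has length %d",
                     nrow(X), length(y)), "shape_mismatch")
  }
  if (nrow(X) <= ncol(X) + 1L) {
    gl_abort(sprintf("need more observations (%d) than parameters (%d)",
                     nrow(X), ncol(X) + 1L), "shape_mismatch")
  }
  X
}

# names of columns made redundant by collinearity, via pivoted QR
singular_columns <- function(X1, qr_obj) {
  if (qr_obj$rank == ncol(X1)) return(character(0))
  colnames(X1)[qr_obj$pivot[(qr_obj$rank + 1L):ncol(X1)]]
}

default_schema_for <- function(X) {
  # synthesize an opaque schema when fitting a bare matrix (testing/advanced use)
  feature_schema(lapply(colnames(X), function(nm) {
    feature_descriptor(nm, "global-mono", list(kmer = "A", region = "protospacer"))
  }))
}

#' Ordinary least squares fit for continuous guide efficiencies
#'
#' QR-based least squares with an intercept and the classical covariance
#' estimate \eqn{\hat\sigma^2 (X'X)^{-1}}.
#'
#' @param X Numeric design matrix (no intercept column), columns named after
#'   schema features.
#' @param y Continuous response vector.
#' @param schema Optional [feature_schema()] aligned to the columns of `X`.
#' @return A `guidelm` object (`family = "ols"`).
#' @export
fit_ols <- function(X, y, schema = NULL) {
  X <- check_design(X, y)
  X1 <- cbind(`(Intercept)` = 1, X)
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) {
    gl_abort(paste0("singular design; redundant column(s): ",
                    paste(singular_columns(X1, qx), collapse = ", ")),
             "singular_design")
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X1 %*% beta)
  res <- y - fitted
  df <- nrow(X1) - ncol(X1)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * chol2inv(chol(crossprod(X1)))
  dimnames(covb) <- list(colnames(X1), colnames(X1))
  out <- new_guidelm("ols", if (is.null(schema)) default_schema_for(X) else schema,
                     beta, covb, fitted, res, sigma2, nrow(X1))
  out$promoter <- "T7"; out$task <- "regression"
  out
}

# logit-link IRLS shared by the fractional and binary families.
# Primary convergence: successive coefficient vectors differ by < tol in max
# norm.  Under (quasi-)separation the likelihood has no interior maximum and
# the coefficient steps never shrink, while the deviance still plateaus; that
# case is detected by a glm-style relative-deviance criterion and returned
# with a separation warning instead of erroring.
irls_logit <- function(X1, y, tol = 1e-8, maxit = 100L) {
  qx <- qr(X1)
  if (qx$rank < ncol(X1)) {
    gl_abort(paste0("singular design; redundant column(s): ",
                    paste(singular_columns(X1, qx), collapse = ", ")),
             "singular_design")
  }
  binom_dev <- function(y, mu) {
    -2 * sum(ifelse(y > 0, y * log(mu / pmax(y, 1e-300)), 0) +
             ifelse(y < 1, (1 - y) * log((1 - mu) / pmax(1 - y, 1e-300)), 0))
  }
  finish <- function(beta, it, force_warn = FALSE) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    if (force_warn || any(mu > 1 - 1e-8) || any(mu < 1e-8)) {
      gl_warn("fitted probabilities numerically 0 or 1: possible separation",
              "separation")
    }
    w <- pmax(mu * (1 - mu), 1e-12)
    xtwx <- crossprod(X1 * sqrt(w))
    list(beta = beta, mu = mu, w = w, xtwx_inv = solve(xtwx), iterations = it)
  }
  beta <- numeric(ncol(X1))
  delta <- Inf
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X1, z, w)
    beta_new <- fit$coefficients
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) return(finish(beta, it))
    mu_new <- stats::plogis(drop(X1 %*% beta))
    # complete separation: every response is fitted to its boundary value, so
    # the likelihood has no interior maximum and the steps never shrink
    if (all(abs(y - mu_new) < 1e-4) && all(pmin(mu_new, 1 - mu_new) < 0.01)) {
      return(finish(beta, it, force_warn = TRUE))
    }
    dev <- binom_dev(y, mu_new)
    if (is.finite(dev_old) && abs(dev - dev_old) / (abs(dev) + 0.1) < 1e-10) {
      return(finish(beta, it))
    }
    dev_old <- dev
  }
  gl_abort(sprintf("IRLS did not converge in %d iterations (last step %.3g)",
                   maxit, delta), "no_convergence")
}

#' Fractional-logit fit for proportion-valued guide efficiencies
#'
#' Quasi-likelihood logit-link mean model for a response that is a fraction in
#' \[0,1\] without integer trial counts, fitted by iteratively reweighted
#' least squares (coefficient change < 1e-8 in max norm, at most 100
#' iterations).  The coefficient covariance is the inverse weighted
#' information scaled by the Pearson dispersion, matching quasi-binomial GLM
#' practice.
#'
#' @inheritParams fit_ols
#' @param y Fractional response, every value in \[0,1\].
#' @return A `guidelm` object (`family = "fractional-logit"`).
#' @export
fit_fractional_logit <- function(X, y, schema = NULL) {
  if (any(y < 0 | y > 1, na.rm = TRUE) || anyNA(y)) {
    bad <- which(is.na(y) | y < 0 | y > 1)[1L]
    gl_abort(sprintf("fractional response must lie in [0,1]; element %d is %s",
                     bad, format(y[bad])), "range_error")
  }
  X <- check_design(X, y)
  X1 <- cbind(`(Intercept)` = 1, X)
  fit <- irls_logit(X1, y)
  res <- y - fit$mu
  df <- nrow(X1) - ncol(X1)
  phi <- sum(res^2 / fit$w) / df
  covb <- phi * fit$xtwx_inv
  dimnames(covb) <- list(colnames(X1), colnames(X1))
  out <- new_guidelm("fractional-logit",
                     if (is.null(schema)) default_schema_for(X) else schema,
                     fit$beta, covb, fit$mu, res, phi, nrow(X1),
                     iterations = fit$iterations)
  out$promoter <- "U6"; out$task <- "regression"
  out
}

#' Logistic fit for efficient/inefficient guide labels
#'
#' Maximum-likelihood logistic regression (same IRLS convergence contract as
#' [fit_fractional_logit()]); covariance is the inverse observed information.
#'
#' @inheritParams fit_ols
#' @param labels Character/factor vector over `"efficient"` / `"inefficient"`,
#'   or a 0/1 numeric vector (1 = efficient).
#' @return A `guidelm` object (`family = "logistic"`).
#' @export
fit_logistic <- function(X, labels, schema = NULL) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      gl_abort("numeric labels must be 0/1", "range_error")
    }
    y <- as.numeric(labels)
  } else {
    lab <- as.character(labels)
    unknown <- setdiff(unique(lab), c("efficient", "inefficient"))
    if (length(unknown)) {
      gl_abort(paste0("unknown label(s): ", paste(unknown, collapse = ", ")),
               "range_error")
    }
    y <- as.numeric(lab == "efficient")
  }
  if (length(unique(y)) < 2L) {
    gl_abort("both classes (efficient and inefficient) must be present",
             "one_class_only")
  }
  X <- check_design(X, y)
  X1 <- cbind(`(Intercept)` = 1, X)
  fit <- irls_logit(X1, y)
  covb <- fit$xtwx_inv
  dimnames(covb) <- list(colnames(X1), colnames(X1))
  out <- new_guidelm("logistic",
                     if (is.null(schema)) default_schema_for(X) else schema,
                     fit$beta, covb, fit$mu, y - fit$mu, 1, nrow(X1),
                     iterations = fit$iterations)
  out$task <- "classification"
  out
}

#' Label the top and bottom fraction of guides by observed efficiency
#'
#' Exactly `floor(fraction * n)` guides with the highest scores are labeled
#' `"efficient"` and the same number with the lowest scores `"inefficient"`;
#' the remainder are `"unlabeled"`.  Ties at either boundary are broken by
#' stable input order: guides are put in stable descending-score order, the
#' first k become efficient and the last k inefficient.
#'
#' @param scores Numeric vector of observed efficiencies.
#' @param fraction Labeling fraction, `0 < fraction <= 0.5` (default 0.20).
#' @return Character vector over `{"efficient","inefficient","unlabeled"}`.
#' @export
label_top_bottom <- function(scores, fraction = 0.20) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 0.5) {
    gl_abort("fraction must lie in (0, 0.5]", "bad_fraction")
  }
  n <- length(scores)
  if (n < ceiling(1 / fraction)) {
    gl_abort(sprintf("need at least %d guides for fraction %.2f; got %d",
                     ceiling(1 / fraction), fraction, n), "too_few_guides")
  }
  k <- floor(fraction * n)
  ord <- order(-scores)            # stable: ties keep input order
  labels <- rep("unlabeled", n)
  labels[ord[seq_len(k)]] <- "efficient"
  labels[ord[(n - k + 1L):n]] <- "inefficient"
  labels
}

#' Rank guides by predicted score
#'
#' Rank 1 is the highest score; ties are broken by input order (stable), so
#' ranks are always a permutation of `1..n`.
#'
#' @param scores Numeric vector.
#' @return Integer rank vector.
#' @export
rank_guides <- function(scores) {
  if (!length(scores)) gl_abort("cannot rank an empty score vector", "shape_mismatch")
  ord <- order(-scores)
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(ord)
  ranks
}
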