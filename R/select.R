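#' Configuration for multi-step feature selection
#'
#' @param prevalence Minimum fraction of rows in which an indicator feature
#'   must be active to survive step 1 (default 0.01).
#' @param screen_top Number of features retained by the univariate
#'   rank-correlation screen of step 2 (default 100).
#' @param nfolds Cross-validation folds for the L1 step (default 5).
#' @param seed Seed deriving the fold assignment (default 17).
#' @param steps Which steps to run, a subset of
#'   `c("prevalence", "screen", "lasso")`; each is individually switchable.
#' @return A named list used by [select_features()].
#' @export
select_config <- function(prevalence = 0.01, screen_top = 100L, nfolds = 5L,
                          seed = 17L, steps = c("prevalence", "screen", "lasso")) {
  list(prevalence = prevalence, screen_top = as.integer(screen_top),
       nfolds = as.integer(nfolds), seed = as.integer(seed),
       steps = steps)
}

is_indicator_col <- function(x) all(x %in% c(0, 1))

#' Multi-step feature selection
#'
#' Reduces a candidate schema to a minimal, relevant subset via three
#' sequential, individually switchable steps:
#' \enumerate{
#'   \item prevalence filter — drop indicator features active in fewer than
#'     `prevalence` of the rows (and indicators active in none);
#'   \item univariate screen — rank features by the absolute Spearman
#'     correlation of each column with the response and keep the top
#'     `screen_top`;
#'   \item sparsity refinement — L1-penalized linear fit with the penalty
#'     chosen by `nfolds`-fold cross-validation (fold assignment derived from
#'     `seed`), keeping features with nonzero coefficients at the
#'     cross-validated optimum.
#' }
#' Disabling all steps returns the schema unchanged.
#'
#' @param X Design matrix from [build_matrix()] over the candidate schema.
#' @param y Response vector (continuous or fractional).
#' @param schema The candidate [feature_schema()] that produced `X`.
#' @param config See [select_config()].
#' @return The reduced [feature_schema()], order preserved.
#' @export
select_features <- function(X, y, schema, config = select_config()) {
  keep <- schema_names(schema)
  stopifnot(identical(colnames(X), keep))

  if ("prevalence" %in% config$steps) {
    active <- vapply(keep, function(nm) {
      col <- X[, nm]
      if (is_indicator_col(col)) mean(col != 0) else 1
    }, numeric(1))
    keep <- keep[active >= config$prevalence]
    if (!length(keep)) {
      gl_abort("prevalence filter removed every feature", "empty_selection")
    }
  }

  if ("screen" %in% config$steps && length(keep) > config$screen_top) {
    assoc <- vapply(keep, function(nm) {
      col <- X[, nm]
      if (stats::sd(col) == 0 || stats::sd(y) == 0) return(0)
      abs(stats::cor(col, y, method = "spearman"))
    }, numeric(1))
    thr <- sort(assoc, decreasing = TRUE)[config$screen_top]
    kept <- keep[assoc >= thr]
    # respect the cap exactly even under ties at the threshold
    if (length(kept) > config$screen_top) {
      kept <- keep[order(-assoc)[seq_len(config$screen_top)]]
      kept <- keep[keep %in% kept]
    }
    keep <- kept
    if (!length(keep)) {
      gl_abort("univariate screen removed every feature", "empty_selection")
    }
  }

  if ("lasso" %in% config$steps && length(keep) >= 2L) {
    Xs <- X[, keep, drop = FALSE]
    set.seed(config$seed)
    foldid <- sample(rep(seq_len(config$nfolds), length.out = nrow(Xs)))
    cv <- glmnet::cv.glmnet(Xs, y, family = "gaussian", foldid = foldid,
                            standardize = TRUE)
    b <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
    keep <- keep[abs(b) > 0]
    if (!length(keep)) {
      gl_abort("L1 refinement removed every feature", "empty_selection")
    }
  }

  feature_schema(schema$features[match(keep, schema_names(schema))],
                 version = schema$version)
}
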