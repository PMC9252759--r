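#' Train the four-model suite
#'
#' One regression and one classification model per expression system:
#' U6 regression (fractional-logit on efficiencies in \[0,1\]), T7 regression
#' (ordinary least squares on continuous efficiencies), and a logistic
#' classification model per promoter trained on the top/bottom labeled guides
#' using the same selected features as that promoter's regression model.
#'
#' @param u6_table,t7_table `guide_set` data frames with an `efficiency`
#'   column (as produced by [read_csv_targets()] or
#'   [simulate_training_table()]).
#' @param schema Candidate [feature_schema()] (default [candidate_schema()]).
#' @param fraction Top/bottom labeling fraction (default 0.20).
#' @param config Selection configuration, see [select_config()].
#' @return A `guidelm_registry`: a named list of four `guidelm` fits keyed
#'   `"U6-regression"`, `"U6-classification"`, `"T7-regression"`,
#'   `"T7-classification"`.
#' @export
train_model_suite <- function(u6_table, t7_table, schema = candidate_schema(),
                              fraction = 0.20, config = select_config()) {
  one_promoter <- function(table, promoter) {
    if (!"efficiency" %in% names(table)) {
      gl_abort(sprintf("%s table lacks an efficiency column", promoter),
               "missing_column")
    }
    y <- table$efficiency
    task_tag <- function(task) paste0(promoter, "-", task)
    wrap <- function(task, expr) {
      tryCatch(expr, guidelm_error = function(e) gl_abort(
        sprintf("[%s] %s", task_tag(task), conditionMessage(e)),
        sub("^guidelm_", "", class(e)[1L])))
    }
    X <- build_matrix(table, schema)
    sel <- wrap("regression", {
      if (promoter == "U6" && any(y < 0 | y > 1)) {
        gl_abort("fractional response must lie in [0,1]", "range_error")
      }
      select_features(X, y, schema, config)
    })
    Xs <- X[, schema_names(sel), drop = FALSE]
    reg <- wrap("regression", if (promoter == "U6") {
      fit_fractional_logit(Xs, y, schema = sel)
    } else {
      fit_ols(Xs, y, schema = sel)
    })
    reg$promoter <- promoter; reg$task <- "regression"
    labels <- label_top_bottom(y, fraction)
    keep <- labels != "unlabeled"
    cls <- wrap("classification",
                fit_logistic(Xs[keep, , drop = FALSE], labels[keep], schema = sel))
    cls$promoter <- promoter; cls$task <- "classification"
    stats::setNames(list(reg, cls), task_tag(c("regression", "classification")))
  }
  registry <- c(one_promoter(u6_table, "U6"), one_promoter(t7_table, "T7"))
  structure(registry, class = "guidelm_registry")
}

#' @method print guidelm_registry
#' @export
print.guidelm_registry <- function(x, ...) {
  cat(sprintf("guidelm registry: %d model(s)\n", length(x)))
  for (key in names(x)) {
    cat(sprintf("  %-20s %s family, %d features, n = %d\n", key,
                x[[key]]$family, length(x[[key]]$coefficients), x[[key]]$n))
  }
  invisible(x)
}

# full-precision decimal encoding so persisted fits reload bit-identically
num_to_str <- function(x) sprintf("%.17g", x)
str_to_num <- function(s) as.numeric(s)

#' Persist / reload a fitted model as JSON
#'
#' The document stores the schema, intercept, coefficients and coefficient
#' covariance with all numbers written as 17-significant-digit decimal
#' strings, so a reloaded model reproduces bit-identical predictions.
#'
#' @param model A fitted `guidelm`.
#' @param path File path.
#' @return `save_model` the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  doc <- list(
    format = "guidelm-model", version = "1",
    promoter = model$promoter, task = model$task, family = model$family,
    n = model$n, dispersion = num_to_str(model$dispersion),
    iterations = if (!is.na(model$iterations)) model$iterations,
    timestamp = model$timestamp,
    intercept = num_to_str(model$intercept),
    coefficients = as.list(stats::setNames(num_to_str(model$coefficients),
                                           names(model$coefficients))),
    covariance_names = rownames(model$coef_covariance),
    covariance = apply(model$coef_covariance, 1L, num_to_str, simplify = FALSE),
    schema = list(version = model$schema$version,
                  features = lapply(model$schema$features, function(d) {
                    list(name = d$name, kind = d$kind, params = d$params)
                  }))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$format, "guidelm-model")) {
    gl_abort(sprintf("'%s' is not a guidelm model file", path), "io_failure")
  }
  feats <- lapply(doc$schema$features, function(d) {
    params <- lapply(d$params, function(p) {
      p <- if (is.list(p)) unlist(p) else p
      if (is.numeric(p) && all(p == round(p))) as.integer(p) else p
    })
    feature_descriptor(d$name, d$kind, params)
  })
  schema <- feature_schema(feats, version = doc$schema$version)
  coefs <- vapply(doc$coefficients, function(s) str_to_num(s), numeric(1))
  covnm <- unlist(doc$covariance_names)
  covb <- do.call(rbind, lapply(doc$covariance, function(r) str_to_num(unlist(r))))
  dimnames(covb) <- list(covnm, covnm)
  out <- new_guidelm(doc$family, schema,
                     c("(Intercept)" = str_to_num(doc$intercept), coefs),
                     covb, fitted = numeric(0), residuals = numeric(0),
                     dispersion = str_to_num(doc$dispersion), n = doc$n,
                     iterations = if (is.null(doc$iterations)) NA_integer_ else
                       as.integer(doc$iterations))
  out$promoter <- doc$promoter
  out$task <- doc$task
  out$timestamp <- doc$timestamp
  out
}

#' Persist / reload a four-model registry
#'
#' A registry directory holds one JSON file per model plus an `index.json`
#' naming them by `(promoter, task)` key.
#'
#' @param registry A `guidelm_registry` from [train_model_suite()].
#' @param dir Directory path (created if absent).
#' @return `save_registry` the directory invisibly; `load_registry` the
#'   registry.
#' @export
save_registry <- function(registry, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- stats::setNames(paste0(gsub("[^A-Za-z0-9]+", "_", names(registry)),
                                  ".json"),
                           names(registry))
  for (key in names(registry)) {
    save_model(registry[[key]], file.path(dir, files[[key]]))
  }
  jsonlite::write_json(list(format = "guidelm-registry", models = as.list(files)),
                       file.path(dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_registry
#' @export
load_registry <- function(dir) {
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path)) {
    gl_abort(sprintf("no registry index at '%s'", idx_path), "io_failure")
  }
  idx <- jsonlite::read_json(idx_path, simplifyVector = FALSE)
  models <- lapply(idx$models, function(f) load_model(file.path(dir, f)))
  structure(stats::setNames(models, names(idx$models)), class = "guidelm_registry")
}
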