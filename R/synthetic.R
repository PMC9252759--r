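#' Ground-truth generating model for synthetic guides
#'
#' Defines the linear model from which synthetic efficiencies are simulated:
#' a feature schema, an intercept and aligned coefficients, a noise scale, and
#' the response family — `"fractional"` (efficiencies in (0,1), noise injected
#' on the logit scale so responses stay strictly inside the unit interval) or
#' `"continuous"` (additive Gaussian noise).
#'
#' @param schema A [feature_schema()].
#' @param intercept Numeric intercept.
#' @param coefficients Numeric vector aligned to the schema (named vectors are
#'   checked against the schema names).
#' @param noise Noise standard deviation, `>= 0`.
#' @param family `"fractional"` or `"continuous"`.
#' @return A classed `guide_truth` object.
#' @export
guide_truth <- function(schema, intercept, coefficients, noise = 0,
                        family = c("fractional", "continuous")) {
  family <- match.arg(family)
  if (length(coefficients) != length(schema)) {
    gl_abort(sprintf("%d coefficients for a %d-feature schema",
                     length(coefficients), length(schema)), "shape_mismatch")
  }
  if (!is.null(names(coefficients)) &&
      !identical(names(coefficients), schema_names(schema))) {
    gl_abort("coefficient names do not match the schema", "schema_mismatch")
  }
  if (noise < 0) gl_abort("noise scale must be >= 0", "range_error")
  structure(list(schema = schema,
                 intercept = intercept,
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                schema_names(schema)),
                 noise = noise, family = family),
            class = "guide_truth")
}

#' Default ground truth: five interpretable sequence features
#'
#' A compact generating model over features a guide designer would recognize:
#' the near-PAM adenine indicator `A_19`, the global `G count`, the
#' protospacer `GC count` (high GC depresses activity), the poly-T burden
#' `TTT count` (strongly deleterious — TTTT terminates Pol III
#' transcription), and the favourable `AG count`.  Effect sizes are fixed at
#' values of realistic magnitude for guide-activity models; the fractional
#' family carries them on the logit scale.
#'
#' @param family `"fractional"` (default) or `"continuous"`.
#' @param noise Noise scale; defaults to 0.5 on the logit scale for the
#'   fractional family and 0.3 for the continuous family.
#' @return A [guide_truth()].
#' @export
default_truth <- function(family = c("fractional", "continuous"), noise = NULL) {
  family <- match.arg(family)
  schema <- feature_schema(list(
    fd_pos_mono("A", 19L),
    fd_count("G"),
    fd_gc("count"),
    fd_count("TTT"),
    fd_count("AG")
  ))
  if (family == "fractional") {
    guide_truth(schema, intercept = -0.5,
                coefficients = c(0.5, 0.08, -0.06, -0.40, 0.15),
                noise = if (is.null(noise)) 0.5 else noise,
                family = "fractional")
  } else {
    guide_truth(schema, intercept = 0.5,
                coefficients = c(0.25, 0.04, -0.03, -0.20, 0.08),
                noise = if (is.null(noise)) 0.3 else noise,
                family = "continuous")
  }
}

#' Generate random valid 30-nt targets
#'
#' Bases are i.i.d. uniform over A/C/G/T except positions 26-27, which are
#' fixed to "GG" so every sequence carries a canonical NGG PAM and passes
#' [validate_target()].  Identical seeds give identical collections.
#'
#' @param n Number of sequences, `>= 1`.
#' @param seed Integer seed.
#' @return A `guide_set` of `n` validated targets.
#' @export
random_targets <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    gl_abort("n must be a positive integer", "bad_n")
  }
  n <- as.integer(n)
  set.seed(seed)
  mat <- matrix(sample(c("A", "C", "G", "T"), 30L * n, replace = TRUE),
                nrow = n, ncol = 30L)
  mat[, 26L] <- "G"
  mat[, 27L] <- "G"
  seqs <- apply(mat, 1L, paste0, collapse = "")
  ids <- sprintf("guide_%0*d", nchar(as.character(n)), seq_len(n))
  validate_guide_set(ids, seqs, enforce_pam = TRUE)
}

#' Simulate guide efficiencies from a ground-truth model
#'
#' Computes the linear predictor over the truth's schema and adds seeded
#' Gaussian noise: on the response scale for the continuous family, on the
#' logit scale (before the inverse-logit) for the fractional family, which
#' guarantees fractional responses lie strictly in (0,1).
#'
#' @param targets A `guide_set` or character vector of validated 30-mers.
#' @param truth A [guide_truth()].
#' @param seed Integer seed.
#' @return Numeric response vector, one per target.
#' @export
simulate_efficiencies <- function(targets, truth, seed = 1L) {
  if (!inherits(truth, "guide_truth")) {
    gl_abort("truth must be a guide_truth object", "shape_mismatch")
  }
  X <- build_matrix(targets, truth$schema)
  eta <- drop(X %*% truth$coefficients) + truth$intercept
  set.seed(seed)
  eps <- stats::rnorm(length(eta), 0, truth$noise)
  if (truth$family == "continuous") eta + eps else stats::plogis(eta + eps)
}

#' Emit a synthetic training table
#'
#' Generates `n` random targets and simulated efficiencies and returns them in
#' the same CSV dialect [read_csv_targets()] consumes (`id, sequence,
#' efficiency`), optionally writing the file.
#'
#' @param n Number of guides.
#' @param truth A [guide_truth()] (default [default_truth()]).
#' @param seed Integer seed (targets use `seed`, responses `seed + 1`).
#' @param path Optional output CSV path.
#' @return A `guide_set` with an `efficiency` column (invisibly when `path`
#'   is given).
#' @export
simulate_training_table <- function(n, truth = default_truth(), seed = 1L,
                                    path = NULL) {
  guides <- random_targets(n, seed = seed)
  guides$efficiency <- simulate_efficiencies(guides, truth, seed = seed + 1L)
  if (!is.null(path)) {
    utils::write.csv(as.data.frame(guides), path, row.names = FALSE, quote = FALSE)
    return(invisible(guides))
  }
  guides
}
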