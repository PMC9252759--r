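test_that("top/bottom labeling conserves counts and breaks ties stably", {
  set.seed(1)
  lab <- label_top_bottom(sample(100), 0.20)
  expect_equal(sum(lab == "efficient"), 20)
  expect_equal(sum(lab == "inefficient"), 20)
  expect_equal(sum(lab == "unlabeled"), 60)

  lab10 <- label_top_bottom(seq_len(10), 0.20)
  expect_equal(as.vector(table(lab10)[c("efficient", "inefficient", "unlabeled")]),
               c(2L, 2L, 6L))
  expect_equal(which(lab10 == "efficient"), c(9L, 10L))

  # all-tied scores: first element efficient, last element inefficient
  tied <- label_top_bottom(rep(0.5, 5), 0.20)
  expect_equal(tied, c("efficient", "unlabeled", "unlabeled", "unlabeled",
                       "inefficient"))

  expect_error(label_top_bottom(1:3, 0.20), class = "guidelm_too_few_guides")
  expect_error(label_top_bottom(1:100, 0.7), class = "guidelm_bad_fraction")
})

test_that("OLS interpolates noiseless data and matches the normal equations", {
  set.seed(42)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y0 <- 2 * X[, 1] - 1 * X[, 2] + 0.5
  fit0 <- fit_ols(X, y0)
  expect_equal(fit0$intercept, 0.5, tolerance = 1e-10)
  expect_equal(unname(fit0$coefficients), c(2, -1), tolerance = 1e-10)

  set.seed(7)
  n2 <- 500
  X2 <- cbind(x1 = rnorm(n2), x2 = rnorm(n2))
  y2 <- X2[, 1] + rnorm(n2)
  fit2 <- fit_ols(X2, y2)
  expect_equal(unname(c(fit2$intercept, fit2$coefficients)),
               unname(oracle_ols(X2, y2)), tolerance = 1e-10)
  se <- sqrt(diag(fit2$coef_covariance))["x1"]
  expect_lt(abs(fit2$coefficients["x1"] - 1), 3 * se)

  Xdup <- cbind(X2, x3 = X2[, 1])
  err <- expect_error(fit_ols(Xdup, y2), class = "guidelm_singular_design")
  expect_match(conditionMessage(err), "x3")
  expect_error(fit_ols(X2, y2[-1]), class = "guidelm_shape_mismatch")
})

test_that("fractional-logit maximizes the stated quasi-likelihood", {
  set.seed(11)
  n <- 200
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))

  # constant response 0.5: all coefficients and intercept ~ 0
  fit_half <- fit_fractional_logit(X, rep(0.5, n))
  expect_equal(unname(c(fit_half$intercept, fit_half$coefficients)),
               c(0, 0, 0), tolerance = 1e-8)

  # noiseless inverse-logit means are recovered
  set.seed(12)
  n2 <- 2000
  X2 <- cbind(x1 = rnorm(n2), x2 = rnorm(n2))
  y2 <- plogis(1.5 * X2[, 1] - 1.0 * X2[, 2])
  fit2 <- fit_fractional_logit(X2, y2)
  expect_equal(unname(fit2$coefficients), c(1.5, -1.0), tolerance = 0.05)

  # agrees with direct numerical likelihood maximization (small instance)
  y <- plogis(0.4 + X[, 1] - 0.6 * X[, 2] + rnorm(n, 0, 0.5))
  fit <- fit_fractional_logit(X, y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(oracle_logit_ml(X, y)), tolerance = 1e-4)

  # agrees with the quasi-binomial GLM, covariance included
  g <- suppressWarnings(glm(y ~ X, family = quasibinomial()))
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(diag(fit$coef_covariance)),
               unname(diag(vcov(g))), tolerance = 1e-5)

  expect_error(fit_fractional_logit(X, c(1.2, rep(0.5, n - 1))),
               class = "guidelm_range_error")
})

test_that("logistic fits detect signal, nulls, and degenerate labels", {
  set.seed(21)
  n <- 1000
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  # stochastic labels driven by x1 only: a noiseless threshold on x1 would be
  # perfectly separated and the ML estimate would not exist
  labels <- ifelse(rbinom(n, 1, plogis(2 * X[, 1])) == 1,
                   "efficient", "inefficient")
  fit <- fit_logistic(X, labels)
  se1 <- sqrt(diag(fit$coef_covariance))["x1"]
  expect_gt(fit$coefficients["x1"], 3 * se1)

  # deterministically separable labels are detected and signalled
  sep_labels <- ifelse(X[, 1] > median(X[, 1]), "efficient", "inefficient")
  expect_warning(fit_sep <- fit_logistic(X, sep_labels),
                 class = "guidelm_separation")
  expect_equal(unname(round(fitted(fit_sep))),
               as.numeric(sep_labels == "efficient"))

  # permuted labels: every coefficient within 3 SE of zero
  fit0 <- fit_logistic(X, sample(labels))
  se <- sqrt(diag(fit0$coef_covariance))[-1]
  expect_true(all(abs(fit0$coefficients) < 3 * se))

  # matches glm on a small instance
  set.seed(22)
  Xs <- X[1:200, ]
  ls <- labels[1:200]
  fs <- fit_logistic(Xs, ls)
  g <- glm(I(ls == "efficient") ~ Xs, family = binomial())
  expect_equal(unname(c(fs$intercept, fs$coefficients)), unname(coef(g)),
               tolerance = 1e-6)

  expect_error(fit_logistic(X, rep("efficient", n)),
               class = "guidelm_one_class_only")
})

test_that("feature selection keeps informative columns and prunes noise", {
  set.seed(33)
  n <- 1000
  p_inf <- 10
  p_noise <- 200
  X <- matrix(rnorm(n * (p_inf + p_noise)), n)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  beta <- rep(1, p_inf)
  y <- drop(X[, 1:p_inf] %*% beta) + rnorm(n, 0, 1)
  schema <- feature_schema(lapply(colnames(X), function(nm) {
    feature_descriptor(nm, "global-mono", list(kmer = "A", region = "protospacer"))
  }))
  sel <- select_features(X, y, schema)
  kept <- vapply(sel$features, function(d) d$name, character(1))
  expect_true(all(paste0("f", 1:p_inf) %in% kept))
  noise_kept <- sum(kept %in% paste0("f", (p_inf + 1):(p_inf + p_noise)))
  expect_lte(noise_kept, 0.2 * p_noise)

  # disabling every step returns the schema unchanged
  sel_id <- select_features(X, y, schema, select_config(steps = character(0)))
  expect_identical(vapply(sel_id$features, function(d) d$name, character(1)),
                   colnames(X))

  # an indicator active in no rows is dropped at the prevalence step
  X2 <- cbind(X[, 1:5], dead = 0)
  schema2 <- feature_schema(lapply(colnames(X2), function(nm) {
    feature_descriptor(nm, "global-mono", list(kmer = "A", region = "protospacer"))
  }))
  sel2 <- select_features(X2, y, schema2, select_config(steps = "prevalence"))
  expect_false("dead" %in% vapply(sel2$features, function(d) d$name, character(1)))
})

test_that("prediction enforces the schema contract and the link ranges", {
  truth <- default_truth("fractional")
  gs <- random_targets(150, seed = 44)
  y <- simulate_efficiencies(gs, truth, seed = 45)
  fit <- guidelm(gs, y, promoter = "U6", schema = truth$schema, select = FALSE)

  X <- build_matrix(gs, truth$schema)
  expect_equal(predict(fit, X), predict(fit, gs))
  p <- predict(fit, gs)
  expect_true(all(p > 0 & p < 1))

  Xbad <- X
  colnames(Xbad)[2] <- "renamed"
  err <- expect_error(predict(fit, Xbad), class = "guidelm_schema_mismatch")
  expect_match(conditionMessage(err), "G count")
  expect_match(conditionMessage(err), "renamed")

  # all-zero coefficient model scores at the inverse-link of the intercept
  fit0 <- fit
  fit0$coefficients[] <- 0
  fit0$intercept <- 0.3
  expect_equal(unique(round(predict(fit0, gs), 12)), round(plogis(0.3), 12))
})

test_that("ranking is stable, complete, and monotone-invariant", {
  expect_equal(rank_guides(c(0.1, 0.9, 0.5)), c(3L, 1L, 2L))
  expect_equal(rank_guides(rep(1, 5)), 1:5)
  set.seed(55)
  s <- rnorm(40)
  expect_equal(rank_guides(s), rank_guides(exp(2 * s)))
  expect_setequal(rank_guides(s), seq_along(s))
})

test_that("the four-model suite trains, persists, and reloads bit-identically", {
  u6 <- simulate_training_table(300, default_truth("fractional"), seed = 61)
  t7 <- simulate_training_table(300, default_truth("continuous"), seed = 62)
  schema <- candidate_schema(dinucleotide_positions = FALSE,
                             trinucleotide_counts = FALSE)
  registry <- suppressWarnings(train_model_suite(u6, t7, schema = schema))
  expect_s3_class(registry, "guidelm_registry")
  expect_setequal(names(registry),
                  c("U6-regression", "U6-classification",
                    "T7-regression", "T7-classification"))
  expect_equal(registry[["U6-regression"]]$family, "fractional-logit")
  expect_equal(registry[["T7-regression"]]$family, "ols")
  expect_equal(registry[["U6-classification"]]$family, "logistic")
  # classification reuses its promoter's selected schema
  expect_identical(schema_names <- vapply(registry[["U6-regression"]]$schema$features,
                                          function(d) d$name, character(1)),
                   vapply(registry[["U6-classification"]]$schema$features,
                          function(d) d$name, character(1)))

  dir <- tempfile()
  save_registry(registry, dir)
  reloaded <- load_registry(dir)
  probe <- random_targets(25, seed = 63)
  for (key in names(registry)) {
    expect_identical(predict(registry[[key]], probe),
                     predict(reloaded[[key]], probe))
  }

  # a U6 response outside [0,1] is attributed to the failing task
  u6bad <- u6
  u6bad$efficiency[1] <- 1.2
  err <- expect_error(train_model_suite(u6bad, t7, schema = schema),
                      class = "guidelm_range_error")
  expect_match(conditionMessage(err), "U6-regression")
})
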