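test_that("position-specific indicators follow the protospacer coordinate map", {
  # protospacer with A at position 19, G elsewhere near PAM
  proto <- paste0(strrep("G", 18), "AG")
  seq <- make_target(proto)
  expect_identical(position_mono(seq, "A", 19), 1L)
  expect_identical(position_mono(seq, "C", 19), 0L)
  expect_identical(position_mono(seq, "G", 20), 1L)
  # the indicator reads 30-mer position p + 4
  expect_identical(substr(seq, 23, 23), "A")
  expect_error(position_mono(seq, "A", 21), class = "guidelm_position_out_of_range")

  # one-hot completeness at every position
  for (p in c(1, 7, 20)) {
    expect_equal(sum(vapply(c("A", "C", "G", "T"),
                            function(b) position_mono(seq, b, p), integer(1))), 1)
  }
})

test_that("dinucleotide indicators partition each start position", {
  seq <- make_target(paste0("AG", strrep("C", 18)))
  expect_identical(position_di(seq, "AG", 1), 1L)
  expect_identical(position_di(seq, "GC", 2), 1L)
  expect_identical(position_di(seq, "AG", 2), 0L)
  expect_error(position_di(seq, "AG", 20), class = "guidelm_position_out_of_range")
  dimers <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0))
  for (p in c(1, 10, 19)) {
    expect_equal(sum(vapply(dimers, function(d) position_di(seq, d, p), integer(1))), 1)
  }
})

test_that("global counts use the overlapping convention and conserve totals", {
  seq <- make_target(paste0(strrep("G", 5), strrep("A", 15)))
  expect_equal(global_counts(seq, "G"), 5)
  seq2 <- make_target(paste0("TTTT", strrep("A", 16)))
  expect_equal(global_counts(seq2, "TTT"), 2)   # overlapping
  expect_equal(global_counts(seq2, "TT"), 3)
  # mono counts over the protospacer always sum to 20
  rand <- random_targets(25, seed = 5)
  tot <- Reduce(`+`, lapply(c("A","C","G","T"), function(b) global_counts(rand, b)))
  expect_true(all(tot == 20))
  # region variants
  expect_equal(global_counts(seq2, "T", region = c(1, 4)), 4)
  t_in_whole <- sum(strsplit(seq2, "")[[1]] == "T")
  expect_equal(global_counts(seq2, "T", region = "whole30"), t_in_whole)
})

test_that("GC features obey their bounds and mutual exclusion", {
  allG <- make_target(strrep("G", 20))
  allA <- make_target(strrep("A", 20))
  expect_equal(unname(gc_features(allG, 4, 14)), c(20, 0, 1))
  expect_equal(unname(gc_features(allA, 4, 14)), c(0, 1, 0))
  expect_error(gc_features(allG, 14, 4), class = "guidelm_bad_bounds")
  rand <- random_targets(50, seed = 7)
  g <- gc_features(rand, 4, 14)
  expect_true(all(g[, "gc_low"] + g[, "gc_high"] <= 1))
})

test_that("melting-temperature proxies match an independent Wallace transcription", {
  proto <- "ATGCGTACCATGGATCCTAG"
  seq <- make_target(proto)
  tm <- structural_features(seq)
  expect_equal(unname(tm["Tm 1-5"]), oracle_wallace(substr(proto, 1, 5)))
  expect_equal(unname(tm["Tm 6-13"]), oracle_wallace(substr(proto, 6, 13)))
  expect_equal(unname(tm["Tm 14-20"]), oracle_wallace(substr(proto, 14, 20)))
  expect_equal(unname(tm["Tm 1-20"]), oracle_wallace(proto))
  # determinism and GC monotonicity
  expect_identical(structural_features(seq), structural_features(seq))
  expect_true(all(structural_features(make_target(strrep("G", 20))) >
                  structural_features(make_target(strrep("A", 20)))))
})

test_that("build_matrix is deterministic, order-preserving, and schema-driven", {
  schema <- small_schema()
  gs <- random_targets(30, seed = 9)
  X <- build_matrix(gs, schema)
  expect_equal(dim(X), c(30, 5))
  expect_equal(colnames(X), c("A_19", "G count", "GC count", "TTT count", "AG count"))
  expect_equal(rownames(X), gs$id)
  # permuting the input permutes rows identically
  perm <- c(7, 1, 30, 15)
  Xp <- build_matrix(gs[perm, ], schema)
  expect_equal(unname(Xp), unname(X[perm, ]))
  # indicator columns are 0/1; count columns nonnegative integers
  expect_true(all(X[, "A_19"] %in% 0:1))
  expect_true(all(X >= 0 & X == round(X)))
})

test_that("schemas round-trip through JSON with an identical induced matrix", {
  schema <- candidate_schema(dinucleotide_positions = FALSE,
                             trinucleotide_counts = FALSE)
  path <- tempfile(fileext = ".json")
  write_schema(schema, path)
  schema2 <- read_schema(path)
  gs <- random_targets(12, seed = 2)
  expect_identical(build_matrix(gs, schema), build_matrix(gs, schema2))
})

test_that("the full candidate schema satisfies the one-hot invariants", {
  schema <- candidate_schema()
  gs <- random_targets(15, seed = 21)
  X <- build_matrix(gs, schema)
  expect_equal(ncol(X), length(schema))
  expect_false(anyNA(X))
  # one-hot mono indicators sum to 1 at each position
  for (p in c(1, 10, 20)) {
    cols <- paste0(c("A", "C", "G", "T"), "_", p)
    expect_true(all(rowSums(X[, cols]) == 1))
  }
  # the canonical interpretable feature names are all constructible
  expect_true(all(c("A_19", "G count", "GC count", "TTT count", "AG count")
                  %in% colnames(X)))
})
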