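# Featurization: validated 30-mers -> named numeric columns.
# All internals are vectorized over a character vector of 30-mers; the exported
# single-sequence operations delegate to them.

as_sequence_vector <- function(seqs) {
  if (inherits(seqs, "guide_set")) {
    structure(seqs$sequence, names = seqs$id)
  } else if (inherits(seqs, "target_sequence")) {
    unclass(seqs)
  } else {
    as.character(seqs)
  }
}

protospacer <- function(seqs30) substr(seqs30, 5L, 24L)

# overlapping occurrence count of kmer in each string
count_overlapping <- function(strings, kmer) {
  if (nchar(kmer) == 1L) {
    return(nchar(strings) - nchar(gsub(kmer, "", strings, fixed = TRUE)))
  }
  hits <- gregexpr(paste0("(?=", kmer, ")"), strings, perl = TRUE)
  vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), integer(1))
}

#' Position-specific mononucleotide indicator
#'
#' 1 iff protospacer position `pos` (1-based, position 20 PAM-proximal; 30-mer
#' position `pos + 4`) holds `base`.
#'
#' @param seq A validated 30-nt sequence (or vector of them).
#' @param base One of "A","C","G","T".
#' @param pos Protospacer position in 1..20.
#' @return Integer 0/1 (vectorized over `seq`).
#' @export
position_mono <- function(seq, base, pos) {
  if (length(pos) != 1L || pos < 1L || pos > 20L) {
    gl_abort(sprintf("protospacer position %s out of range 1..20", toString(pos)),
             "position_out_of_range")
  }
  s <- as_sequence_vector(seq)
  as.integer(substr(s, pos + 4L, pos + 4L) == base)
}

#' Position-specific dinucleotide indicator
#'
#' 1 iff protospacer positions `pos, pos + 1` spell `dimer`.
#'
#' @inheritParams position_mono
#' @param dimer A 2-mer over A/C/G/T.
#' @param pos Start position in 1..19.
#' @export
position_di <- function(seq, dimer, pos) {
  if (length(pos) != 1L || pos < 1L || pos > 19L) {
    gl_abort(sprintf("dinucleotide start %s out of range 1..19", toString(pos)),
             "position_out_of_range")
  }
  p <- protospacer(as_sequence_vector(seq))
  as.integer(substr(p, pos, pos + 1L) == dimer)
}

#' Global k-mer count
#'
#' Overlapping occurrence count of a 1-, 2- or 3-mer in the protospacer
#' (default), the whole 30-mer, or a protospacer sub-range `region = c(from, to)`.
#'
#' @inheritParams position_mono
#' @param kmer k-mer over A/C/G/T, k in 1..3.
#' @param region `"protospacer"`, `"whole30"`, or integer bounds `c(from, to)`
#'   in protospacer coordinates.
#' @export
global_counts <- function(seq, kmer, region = "protospacer") {
  if (!nchar(kmer) %in% 1:3) {
    gl_abort(sprintf("k-mer '%s' must have length 1-3", kmer), "bad_descriptor")
  }
  s <- as_sequence_vector(seq)
  target <- if (identical(region, "whole30")) {
    s
  } else if (identical(region, "protospacer")) {
    protospacer(s)
  } else {
    from <- as.integer(region[1]); to <- as.integer(region[2])
    if (is.na(from) || is.na(to) || from < 1L || to > 20L || from > to) {
      gl_abort("region bounds must satisfy 1 <= from <= to <= 20", "bad_bounds")
    }
    substr(protospacer(s), from, to)
  }
  count_overlapping(target, kmer)
}

#' GC-content features of the protospacer
#'
#' Returns the G+C count over the 20-nt protospacer together with the
#' extreme-content indicators `gc_low = 1` iff count < `low` and
#' `gc_high = 1` iff count > `high`.
#'
#' @inheritParams position_mono
#' @param low,high Integer bounds, `0 <= low < high <= 20`.
#' @return For a single sequence a named vector `(gc_count, gc_low, gc_high)`;
#'   for several, a 3-column matrix.
#' @export
gc_features <- function(seq, low = 4L, high = 14L) {
  if (!(low >= 0 && low < high && high <= 20)) {
    gl_abort("GC bounds must satisfy 0 <= low < high <= 20", "bad_bounds")
  }
  p <- protospacer(as_sequence_vector(seq))
  gc <- count_overlapping(p, "G") + count_overlapping(p, "C")
  out <- cbind(gc_count = gc, gc_low = as.integer(gc < low),
               gc_high = as.integer(gc > high))
  if (nrow(out) == 1L) out[1L, ] else out
}

#' Melting-temperature structural proxies
#'
#' Wallace-rule melting temperatures, 2(A+T) + 4(G+C) in degrees C, for the
#' whole protospacer and the three fixed sub-segments 1-5, 6-13 and 14-20.
#' Deterministic: identical sequences give bit-identical vectors.
#'
#' @inheritParams position_mono
#' @return For one sequence a named length-4 vector
#'   `(Tm 1-5, Tm 6-13, Tm 14-20, Tm 1-20)`; for several, a 4-column matrix.
#' @export
structural_features <- function(seq) {
  p <- protospacer(as_sequence_vector(seq))
  tm <- function(sub) {
    gc <- count_overlapping(sub, "G") + count_overlapping(sub, "C")
    2 * (nchar(sub) - gc) + 4 * gc
  }
  out <- cbind(`Tm 1-5` = tm(substr(p, 1L, 5L)),
               `Tm 6-13` = tm(substr(p, 6L, 13L)),
               `Tm 14-20` = tm(substr(p, 14L, 20L)),
               `Tm 1-20` = tm(p))
  if (nrow(out) == 1L) out[1L, ] else out
}

# one column of the design matrix for one descriptor
compute_feature <- function(desc, seqs30) {
  pr <- desc$params
  val <- switch(desc$kind,
    "position-mono" = position_mono(seqs30, pr$base, pr$pos),
    "position-di"   = position_di(seqs30, pr$kmer, pr$pos),
    "global-mono"   = ,
    "global-di"     = ,
    "global-tri"    = global_counts(seqs30, pr$kmer,
                                    if (is.null(pr$region)) "protospacer" else pr$region),
    "gc" = {
      g <- gc_features(seqs30, pr$low, pr$high)
      if (is.null(dim(g))) g <- matrix(g, nrow = 1L, dimnames = list(NULL, names(g)))
      g[, c(count = "gc_count", low = "gc_low", high = "gc_high")[[pr$stat]]]
    },
    "structural" = {
      p <- protospacer(seqs30)
      sub <- substr(p, pr$from, pr$to)
      gc <- count_overlapping(sub, "G") + count_overlapping(sub, "C")
      2 * (nchar(sub) - gc) + 4 * gc
    },
    gl_abort(sprintf("unknown descriptor kind '%s'", desc$kind), "bad_descriptor")
  )
  as.numeric(val)
}

#' Build the design matrix for a set of guides
#'
#' One row per sequence (in input order), one column per schema feature (in
#' schema order).  The same (sequences, schema) pair always yields the same
#' matrix.
#'
#' @param seqs A `guide_set`, or a character vector of validated 30-mers.
#' @param schema A [feature_schema()].
#' @return Numeric matrix with row names = identifiers, column names = feature
#'   names.
#' @export
build_matrix <- function(seqs, schema) {
  s <- as_sequence_vector(seqs)
  if (!length(s)) gl_abort("no sequences to featurize", "io_failure")
  if (!inherits(schema, "feature_schema")) {
    gl_abort("schema must be a feature_schema", "bad_descriptor")
  }
  cols <- lapply(schema$features, function(d) {
    tryCatch(compute_feature(d, s),
             guidelm_error = function(e) gl_abort(
               sprintf("feature '%s': %s", d$name, conditionMessage(e)),
               sub("^guidelm_", "", class(e)[1L])))
  })
  X <- do.call(cbind, cols)
  dimnames(X) <- list(if (is.null(names(s))) paste0("seq_", seq_along(s)) else names(s),
                      schema_names(schema))
  X
}
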