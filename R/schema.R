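#' Feature descriptors and schemas
#'
#' A descriptor names one numeric feature of a 30-nt target and carries the
#' parameters needed to compute it; a schema is an ordered list of descriptors.
#' The name fully determines the computation, feature positions are
#' protospacer-relative (1-based, position 20 PAM-proximal), and schema order
#' is stable across runs, so a serialized schema reproduces the same design
#' matrix bit-identically.
#'
#' Descriptor kinds:
#' \describe{
#'   \item{position-mono}{indicator that protospacer position `pos` holds `base`
#'     (name like `"A_19"`).}
#'   \item{position-di}{indicator that protospacer positions `pos, pos+1` spell
#'     `kmer` (name like `"AG_3"`).}
#'   \item{global-mono / global-di / global-tri}{overlapping count of `kmer` in
#'     a region: the protospacer (default), the whole 30-mer, or a protospacer
#'     sub-range `from-to` (names like `"G count"`, `"TTT count"`,
#'     `"A count 6-13"`).}
#'   \item{gc}{GC statistics of the protospacer: the G+C count, or the
#'     extreme-content indicators `gc_count < low` / `gc_count > high`.}
#'   \item{structural}{Wallace-rule melting-temperature proxy
#'     2(A+T) + 4(G+C) over a protospacer segment.}
#' }
#'
#' @param name Unique feature name.
#' @param kind One of the kinds above.
#' @param params Named list of kind-specific parameters.
#' @return `feature_descriptor()` returns a classed descriptor;
#'   `feature_schema()` a classed ordered schema.
#' @export
feature_descriptor <- function(name, kind, params = list()) {
  kinds <- c("position-mono", "position-di", "global-mono", "global-di",
             "global-tri", "gc", "structural")
  if (!kind %in% kinds) {
    gl_abort(sprintf("unknown descriptor kind '%s'", kind), "bad_descriptor")
  }
  structure(list(name = name, kind = kind, params = params),
            class = "feature_descriptor")
}

#' @param descriptors List of `feature_descriptor` objects, in column order.
#' @param version Version tag carried with the schema.
#' @rdname feature_descriptor
#' @export
feature_schema <- function(descriptors, version = "1") {
  if (!length(descriptors)) gl_abort("schema must contain at least one feature",
                                     "empty_selection")
  nm <- vapply(descriptors, function(d) d$name, character(1))
  if (anyDuplicated(nm)) {
    gl_abort(sprintf("duplicate feature name(s): %s",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")),
             "bad_descriptor")
  }
  structure(list(version = as.character(version), features = descriptors),
            class = "feature_schema")
}

#' @method print feature_schema
#' @export
print.feature_schema <- function(x, ...) {
  kinds <- table(vapply(x$features, function(d) d$kind, character(1)))
  cat(sprintf("feature_schema v%s: %d features (%s)\n", x$version,
              length(x$features),
              paste(names(kinds), kinds, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @method length feature_schema
#' @export
length.feature_schema <- function(x) length(x$features)

schema_names <- function(schema) {
  vapply(schema$features, function(d) d$name, character(1))
}

# -- descriptor shorthand constructors ---------------------------------------

fd_pos_mono <- function(base, pos) {
  feature_descriptor(sprintf("%s_%d", base, pos), "position-mono",
                     list(base = base, pos = as.integer(pos)))
}

fd_pos_di <- function(dimer, pos) {
  feature_descriptor(sprintf("%s_%d", dimer, pos), "position-di",
                     list(kmer = dimer, pos = as.integer(pos)))
}

fd_count <- function(kmer, region = "protospacer", name = NULL) {
  kind <- c("global-mono", "global-di", "global-tri")[nchar(kmer)]
  if (is.null(name)) {
    name <- if (identical(region, "protospacer")) {
      sprintf("%s count", kmer)
    } else if (identical(region, "whole30")) {
      sprintf("%s count 30mer", kmer)
    } else {
      sprintf("%s count %d-%d", kmer, region[1], region[2])
    }
  }
  feature_descriptor(name, kind, list(kmer = kmer, region = region))
}

fd_gc <- function(stat = c("count", "low", "high"), low = 4L, high = 14L) {
  stat <- match.arg(stat)
  name <- c(count = "GC count", low = "GC low", high = "GC high")[[stat]]
  feature_descriptor(name, "gc",
                     list(stat = stat, low = as.integer(low), high = as.integer(high)))
}

fd_tm <- function(from, to) {
  feature_descriptor(sprintf("Tm %d-%d", from, to), "structural",
                     list(from = as.integer(from), to = as.integer(to)))
}

#' Full candidate feature schema
#'
#' The superset of sequence features the selection procedure prunes from:
#' one-hot mononucleotide indicators at all 20 protospacer positions,
#' dinucleotide indicators at all 19 adjacent pairs (optional), overlapping
#' global mono-/di-/trinucleotide counts over the protospacer, GC content
#' features (count plus extreme-content indicators), a configurable
#' middle-of-protospacer adenine count, and Wallace-rule melting-temperature
#' proxies for the protospacer and three fixed sub-segments (1-5, 6-13, 14-20).
#'
#' @param dinucleotide_positions Include the 304 position-specific dinucleotide
#'   indicators (default `TRUE`).
#' @param trinucleotide_counts Include the 64 global trinucleotide counts
#'   (default `TRUE`).
#' @param gc_low,gc_high Extreme-GC bounds on the 20-nt protospacer GC count
#'   (defaults 4 and 14): `GC low` fires when the count is strictly below
#'   `gc_low`, `GC high` when strictly above `gc_high`.
#' @param middle Protospacer range for the middle-adenine count
#'   (default `c(6, 13)`).
#' @return A [feature_schema()].
#' @export
candidate_schema <- function(dinucleotide_positions = TRUE,
                             trinucleotide_counts = TRUE,
                             gc_low = 4L, gc_high = 14L, middle = c(6L, 13L)) {
  if (!(gc_low >= 0 && gc_low < gc_high && gc_high <= 20)) {
    gl_abort("GC bounds must satisfy 0 <= low < high <= 20", "bad_bounds")
  }
  bases <- c("A", "C", "G", "T")
  dimers <- as.vector(outer(bases, bases, paste0))
  feats <- list()
  for (p in 1:20) for (b in bases) feats[[length(feats) + 1L]] <- fd_pos_mono(b, p)
  if (dinucleotide_positions) {
    for (p in 1:19) for (d in dimers) feats[[length(feats) + 1L]] <- fd_pos_di(d, p)
  }
  for (b in bases) feats[[length(feats) + 1L]] <- fd_count(b)
  for (d in dimers) {
    # "GC count" is reserved for the G+C base count of the protospacer; the
    # dinucleotide GC occurrence count gets an explicit disambiguated name
    feats[[length(feats) + 1L]] <-
      if (d == "GC") fd_count("GC", name = "GC dinuc count") else fd_count(d)
  }
  if (trinucleotide_counts) {
    trimers <- as.vector(outer(dimers, bases, paste0))
    for (t in trimers) feats[[length(feats) + 1L]] <- fd_count(t)
  }
  feats[[length(feats) + 1L]] <- fd_gc("count", gc_low, gc_high)
  feats[[length(feats) + 1L]] <- fd_gc("low", gc_low, gc_high)
  feats[[length(feats) + 1L]] <- fd_gc("high", gc_low, gc_high)
  feats[[length(feats) + 1L]] <- fd_count("A", as.integer(middle))
  feats[[length(feats) + 1L]] <- fd_tm(1, 5)
  feats[[length(feats) + 1L]] <- fd_tm(6, 13)
  feats[[length(feats) + 1L]] <- fd_tm(14, 20)
  feats[[length(feats) + 1L]] <- fd_tm(1, 20)
  feature_schema(feats)
}

#' Serialize / reload a feature schema as JSON
#'
#' The on-disk form is an ordered array of `{name, kind, params}` objects plus
#' a version tag; reading it back reproduces a schema that induces an
#' identical design matrix.
#'
#' @param schema A [feature_schema()].
#' @param path File path.
#' @return `write_schema` the path invisibly; `read_schema` the schema.
#' @export
write_schema <- function(schema, path) {
  doc <- list(version = schema$version,
              features = lapply(schema$features, function(d) {
                list(name = d$name, kind = d$kind, params = d$params)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- lapply(doc$features, function(d) {
    params <- lapply(d$params, function(p) {
      if (is.list(p)) unlist(p) else p
    })
    # region bounds come back as a list/vector of numbers; keep ints integral
    params <- lapply(params, function(p) {
      if (is.numeric(p) && all(p == round(p))) as.integer(p) else p
    })
    feature_descriptor(d$name, d$kind, params)
  })
  feature_schema(feats, version = doc$version)
}
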