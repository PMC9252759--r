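#' Validate and normalize a 30-nt target sequence
#'
#' A scoring target is a 30-nt window around an SpCas9 site: 4 nt of upstream
#' context, the 20-nt protospacer, the 3-nt NGG PAM, and 3 nt of downstream
#' context.  Protospacer position p (1-based, position 20 PAM-proximal) maps to
#' 30-mer position p + 4; the invariant "GG" of the PAM sits at 30-mer
#' positions 26-27.
#'
#' Input is normalized before checking: lowercase is uppercased and U (RNA) is
#' substituted by T, so guides supplied as RNA are accepted.  Ambiguity codes
#' (N, R, Y, ...) are rejected: a scored sequence must describe one molecule.
#'
#' @param raw Character scalar, the candidate sequence.
#' @param identifier Label used in error messages (default `"target"`).
#' @param enforce_pam If `TRUE` (default), require "GG" at positions 26-27.
#' @return The normalized 30-character sequence, invisibly classed as
#'   `"target_sequence"`.
#' @examples
#' validate_target("aacgACGTACGTACGTACGTACGTaGGacg", "g1")
#' @export
validate_target <- function(raw, identifier = "target", enforce_pam = TRUE) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    gl_abort(sprintf("[%s] sequence must be a single character string", identifier),
             "invalid_base")
  }
  bases <- chartr("acgtuU", "ACGTTT", raw)
  if (nchar(bases) != 30L) {
    gl_abort(sprintf("[%s] sequence has length %d; exactly 30 nt required",
                     identifier, nchar(bases)),
             "wrong_length")
  }
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad)) {
    gl_abort(sprintf("[%s] invalid base '%s' at position %d (alphabet is A/C/G/T/U)",
                     identifier, chars[bad[1L]], bad[1L]),
             "invalid_base")
  }
  if (enforce_pam && substr(bases, 26L, 27L) != "GG") {
    gl_abort(sprintf("[%s] PAM check failed: positions 26-27 are '%s', expected 'GG'",
                     identifier, substr(bases, 26L, 27L)),
             "bad_pam")
  }
  invisible(structure(bases, class = "target_sequence"))
}

# Construct the canonical container for validated guides: a data.frame with
# columns id, sequence (and optionally efficiency), classed "guide_set".
new_guide_set <- function(id, sequence, efficiency = NULL) {
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  if (!is.null(efficiency)) df$efficiency <- as.numeric(efficiency)
  class(df) <- c("guide_set", "data.frame")
  df
}

validate_guide_set <- function(ids, seqs, enforce_pam = TRUE, efficiency = NULL) {
  norm <- character(length(seqs))
  for (i in seq_along(seqs)) {
    norm[i] <- unclass(validate_target(seqs[i], ids[i], enforce_pam = enforce_pam))
  }
  new_guide_set(ids, norm, efficiency)
}

#' Read target sequences from a FASTA file
#'
#' One record per target; the description line supplies the identifier and
#' every sequence is passed through [validate_target()].
#'
#' @param path Path to a plain multi-record FASTA file.
#' @param enforce_pam Passed to [validate_target()].
#' @return A `guide_set` data frame (columns `id`, `sequence`) in file order.
#' @export
read_fasta_targets <- function(path, enforce_pam = TRUE) {
  if (!file.exists(path)) gl_abort(sprintf("file not found: %s", path), "io_failure")
  recs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) gl_abort(
                     sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
                     "malformed_fasta"))
  if (length(recs) == 0L) {
    gl_abort(sprintf("malformed FASTA '%s': no records", path), "malformed_fasta")
  }
  ids <- names(recs)
  ids[is.na(ids) | ids == ""] <- paste0("record_", which(is.na(ids) | ids == ""))
  validate_guide_set(ids, as.character(recs), enforce_pam = enforce_pam)
}

#' Read target sequences (and optional efficiencies) from a CSV file
#'
#' Expects a header row; the identifier and sequence column names are
#' configurable.  When an `efficiency` column is present it is carried along
#' for training use.
#'
#' @param path Path to a CSV file.
#' @param id_col,seq_col Column names (defaults `"id"`, `"sequence"`).
#' @param efficiency_col Optional response column name (default `"efficiency"`);
#'   carried through only if present.
#' @param enforce_pam Passed to [validate_target()].
#' @return A `guide_set` data frame in row order.
#' @export
read_csv_targets <- function(path, id_col = "id", seq_col = "sequence",
                             efficiency_col = "efficiency", enforce_pam = TRUE) {
  if (!file.exists(path)) gl_abort(sprintf("file not found: %s", path), "io_failure")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!seq_col %in% names(df)) {
    gl_abort(sprintf("CSV '%s' is missing required column '%s'", path, seq_col),
             "missing_column")
  }
  ids <- if (id_col %in% names(df)) as.character(df[[id_col]]) else
    paste0("row_", seq_len(nrow(df)))
  eff <- if (efficiency_col %in% names(df)) df[[efficiency_col]] else NULL
  norm <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    norm[i] <- tryCatch(unclass(validate_target(df[[seq_col]][i], ids[i],
                                                enforce_pam = enforce_pam)),
                        guidelm_error = function(e) gl_abort(
                          sprintf("row %d: %s", i, conditionMessage(e)),
                          sub("^guidelm_", "", class(e)[1L])))
  }
  new_guide_set(ids, norm, eff)
}

#' Write a prediction table to CSV
#'
#' Rows are sorted by descending score (stable: ties keep input order) and
#' written with columns `id, sequence, score, rank, label` exactly.  Scores
#' are written at 6 decimal places so the file round-trips losslessly at that
#' precision.  In regression mode the label column is blank.
#'
#' @param records Data frame with columns `id`, `sequence`, `score` and
#'   optionally `rank`, `label` (as produced by [score_guides()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    gl_abort("no prediction records to write", "io_failure")
  }
  needed <- c("id", "sequence", "score")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    gl_abort(paste0("prediction records lack column(s): ", paste(miss, collapse = ", ")),
             "missing_column")
  }
  if (is.null(records$rank)) records$rank <- rank_guides(records$score)
  if (is.null(records$label)) records$label <- ""
  records$label[records$label == "none"] <- ""
  out <- records[order(records$rank), c("id", "sequence", "score", "rank", "label")]
  out$score <- sprintf("%.6f", out$score)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) gl_abort(sprintf("could not write '%s'", path), "io_failure")
  invisible(path)
}

#' @method print guide_set
#' @export
print.guide_set <- function(x, ...) {
  cat(sprintf("guide_set: %d validated 30-nt target(s)%s\n", nrow(x),
              if ("efficiency" %in% names(x)) " with efficiencies" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
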