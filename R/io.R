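## FASTA and table I/O.  FASTA parsing is delegated to Biostrings; this
## module adds the validation the downstream scans rely on (canonical
## alphabet + X, unique ids, non-empty sequences).

#' Read an amino-acid FASTA file
#'
#' Reads a protein FASTA file into a sequence table. Sequences are
#' uppercased, a single terminal stop (`*`) is stripped, and the alphabet
#' is restricted to the 20 canonical residues plus `X`; anything else
#' (including `B`, `Z`, `U`) is rejected with the offending position.
#'
#' @param path Path to a FASTA text file.
#' @return A data frame of class `scl_sequences` with columns `id`
#'   (first whitespace-delimited token of the header), `description`
#'   (remainder of the header) and `seq`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKKL"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    input_error("FASTA file not found: ", path)
  }
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) input_error("cannot parse FASTA file '", path,
                                    "': ", conditionMessage(e))
  )
  if (length(aa) == 0L) input_error("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    input_error("duplicate sequence id in '", path, "': ",
                ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) input_error("empty sequence for id ", ids[i])
    bad <- regexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")),
                   seqs[i])
    if (bad > 0L) {
      input_error("invalid residue '", substr(seqs[i], bad, bad),
                  "' at position ", bad, " in sequence ", ids[i])
    }
  }
  new_sequences(ids, desc, seqs)
}

#' Construct a sequence table
#'
#' Low-level constructor for the `scl_sequences` table returned by
#' [read_fasta()]; useful for building records programmatically.
#'
#' @param id,description,seq Character vectors of equal length.
#' @return An `scl_sequences` data frame.
#' @export
new_sequences <- function(id, description, seq) {
  out <- data.frame(id = as.character(id),
                    description = as.character(description),
                    seq = as.character(seq),
                    stringsAsFactors = FALSE)
  class(out) <- c("scl_sequences", "data.frame")
  out
}

#' Write sequences to FASTA
#'
#' @param records An `scl_sequences` data frame (see [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  headers <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  aa <- Biostrings::AAStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

## Evidence tables ---------------------------------------------------------

EVIDENCE_COLUMNS <- c("protein_id", "source", "kind", "start", "end",
                      "score", "label")

#' Construct an evidence table
#'
#' One row per feature observation. `source` and `kind` must come from the
#' documented vocabularies and respect the source/kind compatibility table
#' (e.g. a `tm_predictor` may only emit `TM_HELIX`). Spans are 1-based,
#' inclusive; a cleavage site at position *k* means cleavage between
#' residues *k* and *k*+1.
#'
#' @param protein_id,source,kind,start,end,score,label Column vectors,
#'   recycled to a common length. `start`, `end`, `score`, `label` may be
#'   `NA` when absent.
#' @return A data frame of class `scl_evidence`.
#' @export
evidence_table <- function(protein_id = character(), source = character(),
                           kind = character(), start = NA_integer_,
                           end = NA_integer_, score = NA_real_,
                           label = NA_character_) {
  if (!length(protein_id) || !length(source) || !length(kind)) {
    return(empty_evidence())
  }
  n <- max(length(protein_id), length(source), length(kind),
           length(start), length(end), length(score), length(label))
  df <- data.frame(protein_id = rep_len(as.character(protein_id), n),
                   source = rep_len(as.character(source), n),
                   kind = rep_len(as.character(kind), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   score = rep_len(as.numeric(score), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  if (n == 0L) df <- df[0L, ]
  validate_evidence(df)
}

empty_evidence <- function() {
  df <- data.frame(protein_id = character(), source = character(),
                   kind = character(), start = integer(), end = integer(),
                   score = numeric(), label = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("scl_evidence", "data.frame")
  df
}

validate_evidence <- function(df, sequences = NULL, where = NULL) {
  loc <- function(i) {
    if (is.null(where)) paste0("evidence row ", i) else
      paste0(where, ", row ", i)
  }
  missing_cols <- setdiff(EVIDENCE_COLUMNS, names(df))
  if (length(missing_cols)) {
    input_error("evidence table lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  df <- df[, EVIDENCE_COLUMNS]
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$protein_id) || !nzchar(r$protein_id)) {
      input_error(loc(i), ": missing protein_id")
    }
    if (!r$source %in% EVIDENCE_SOURCES) {
      input_error(loc(i), ": unknown evidence source '", r$source, "'")
    }
    if (!r$kind %in% EVIDENCE_KINDS) {
      input_error(loc(i), ": unknown evidence kind '", r$kind, "'")
    }
    if (!r$kind %in% EVIDENCE_COMPAT[[r$source]]) {
      input_error(loc(i), ": source '", r$source,
                  "' may not emit kind '", r$kind, "'")
    }
    if (xor(is.na(r$start), is.na(r$end))) {
      input_error(loc(i), ": start/end must both be present or both absent")
    }
    if (!is.na(r$start)) {
      if (r$start < 1L || r$end < r$start) {
        input_error(loc(i), ": invalid span ", r$start, "-", r$end)
      }
      if (!is.null(sequences)) {
        hit <- match(r$protein_id, sequences$id)
        if (!is.na(hit) && r$end > nchar(sequences$seq[hit])) {
          input_error(loc(i), ": span ", r$start, "-", r$end,
                      " exceeds length of ", r$protein_id, " (",
                      nchar(sequences$seq[hit]), ")")
        }
      }
    }
    if (r$kind == "SCL_VOTE" && !(r$label %in% SCL_CLASSES)) {
      input_error(loc(i), ": SCL_VOTE label must be one of ",
                  paste(SCL_CLASSES, collapse = "/"))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("scl_evidence", "data.frame")
  df
}

#' Read a normalized evidence table (TSV or JSON)
#'
#' The TSV encoding has a header row with the seven documented columns
#' (`protein_id`, `source`, `kind`, `start`, `end`, `score`, `label`);
#' absent values are written as `.`. The JSON encoding is an array of
#' objects with the same fields, absent fields omitted. Both encodings of
#' the same rows yield identical tables.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` file.
#' @param sequences Optional `scl_sequences` table; when given, spans are
#'   checked against sequence lengths.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return An `scl_evidence` data frame.
#' @export
read_evidence <- function(path, sequences = NULL,
                          format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) input_error("evidence file not found: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  if (format == "json") {
    raw <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                    error = function(e) input_error(
                      "malformed JSON in '", path, "': ",
                      conditionMessage(e)))
    if (length(raw) == 0L) return(empty_evidence())
    df <- as.data.frame(raw, stringsAsFactors = FALSE)
    for (col in EVIDENCE_COLUMNS) {
      if (!col %in% names(df)) df[[col]] <- NA
    }
  } else {
    df <- tryCatch(read.delim(path, header = TRUE, sep = "\t",
                              na.strings = ".", colClasses = "character",
                              stringsAsFactors = FALSE, comment.char = ""),
                   error = function(e) input_error(
                     "malformed evidence TSV '", path, "': ",
                     conditionMessage(e)))
    if (nrow(df) == 0L) return(empty_evidence())
  }
  df$start <- parse_int_col(df$start, path, "start")
  df$end <- parse_int_col(df$end, path, "end")
  df$score <- parse_num_col(df$score, path, "score")
  df$protein_id <- as.character(df$protein_id)
  df$source <- as.character(df$source)
  df$kind <- as.character(df$kind)
  df$label <- as.character(df$label)
  validate_evidence(df, sequences = sequences, where = path)
}

parse_int_col <- function(x, path, col) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    input_error(path, ", line ", bad[1L] + 1L, ": non-integer ", col,
                " value '", x[bad[1L]], "'")
  }
  out
}

parse_num_col <- function(x, path, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    input_error(path, ", line ", bad[1L] + 1L, ": non-numeric ", col,
                " value '", x[bad[1L]], "'")
  }
  out
}

#' Write an evidence table
#'
#' @param ev An `scl_evidence` table.
#' @param path Output path; extension selects TSV (default) or JSON.
#' @param format `"auto"`, `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(ev, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "tsv"
  }
  ev <- validate_evidence(as.data.frame(ev))
  if (format == "json") {
    jsonlite::write_json(ev, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = ".")
  }
  invisible(path)
}

## Prediction and metrics tables ------------------------------------------

PREDICTION_COLUMNS <- c("protein_id", "true_tags", "predicted_tags",
                        "pathway", "cleavage_site", "wall_interaction",
                        "evidence_summary")

#' Canonical string form of a tag set
#'
#' Tags are sorted lexically and joined by `";"`, making the table
#' representation deterministic.
#' @param tags Character vector of tags.
#' @return Length-one string.
#' @export
format_tags <- function(tags) {
  tags <- tags[!is.na(tags) & nzchar(tags)]
  if (!length(tags)) return(NA_character_)
  paste(sort(unique(tags)), collapse = ";")
}

split_tags <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else
      sort(unique(strsplit(s, ";", fixed = TRUE)[[1L]]))
  })
}

#' Write / read prediction tables
#'
#' Predictions are stored as TSV with a fixed, documented column order:
#' `protein_id`, `true_tags`, `predicted_tags`, `pathway`,
#' `cleavage_site`, `wall_interaction`, `evidence_summary`. Tag sets are
#' `";"`-joined in lexical order; absent values are `.`. Re-reading a
#' written table reproduces it exactly.
#'
#' @param pred A prediction table (class `scl_predictions`).
#' @param path File path.
#' @return `write_predictions` returns `path` invisibly;
#'   `read_predictions` returns an `scl_predictions` data frame.
#' @export
write_predictions <- function(pred, path) {
  df <- as.data.frame(pred)
  missing_cols <- setdiff(PREDICTION_COLUMNS, names(df))
  if (length(missing_cols)) {
    input_error("prediction table lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  write.table(df[, PREDICTION_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) input_error("prediction file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                   colClasses = "character", stringsAsFactors = FALSE)
  missing_cols <- setdiff(PREDICTION_COLUMNS, names(df))
  if (length(missing_cols)) {
    input_error(path, ": not a prediction table, lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  df$cleavage_site <- parse_int_col(df$cleavage_site, path, "cleavage_site")
  pred_sets <- split_tags(df$predicted_tags)
  for (i in seq_along(pred_sets)) {
    bad <- setdiff(pred_sets[[i]], TAG_VOCAB)
    if (length(bad)) {
      input_error(path, ", row ", i, ": unknown tag '", bad[1L], "'")
    }
    if ("Unknown" %in% pred_sets[[i]] && length(pred_sets[[i]]) > 1L) {
      input_error(path, ", row ", i,
                  ": Unknown may not co-occur with another tag")
    }
  }
  class(df) <- c("scl_predictions", "data.frame")
  df
}

#' Write a metrics table
#'
#' One row per class plus an `overall` row; columns `class`, `n`,
#' `sensitivity`, `specificity`, `precision`, `accuracy`, `mcc`,
#' `unknown_rate`. Undefined ratios are written as `NA`.
#'
#' @param metrics A metrics data frame from [evaluate_predictions()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  df <- as.data.frame(metrics)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
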