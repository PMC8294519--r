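## Short-format predictor dialects.  Real subcellular-localization panels
## (SignalP-, LipoP-, TatP-, TMHMM-, Phobius- and InterProScan-style
## scanners) are license-restricted and their exact outputs drift between
## versions, so this package fixes one small "short" dialect per tool
## family, modeled on the published short formats, each with a canonical
## fixture file under inst/extdata/dialects/.  Adapters for real outputs
## can be added as new dialects without touching the engine.

DIALECTS <- c("sp_short", "lipo_short", "tat_short", "tm_short",
              "phobius_short", "signature_tsv")

DIALECT_HEADERS <- list(
  sp_short      = c("protein", "signal", "score", "cleavage"),
  lipo_short    = c("protein", "class", "score", "cleavage"),
  tat_short     = c("protein", "tat", "score", "cleavage"),
  tm_short      = c("protein", "helices", "topology"),
  phobius_short = c("protein", "tm", "sp", "prediction"),
  signature_tsv = c("protein", "accession", "start", "end", "score", "go")
)

DIALECT_DEFAULT_SOURCE <- c(
  sp_short = "sp_predictor_a", lipo_short = "lipo_predictor",
  tat_short = "tat_predictor", tm_short = "tm_predictor",
  phobius_short = "phobius_like", signature_tsv = "signature_scanner")

#' Parse a predictor short-format file into evidence
#'
#' Six fixed, tab-separated dialects are supported; each file starts with a
#' commented header line `# <col> <col> ...` naming exactly the documented
#' columns. Absent values are `-`. Cleavage positions follow the
#' "between residue *k* and *k*+1 reported as *k*" convention, so a
#' reported cleavage of `23` yields a signal-peptide span 1-23 plus a
#' `CLEAVAGE_SITE` at 23.
#'
#' \describe{
#'   \item{`sp_short`}{columns `protein, signal(YES/NO), score, cleavage`;
#'     `YES` emits `SP_SEC` + `CLEAVAGE_SITE`.}
#'   \item{`lipo_short`}{columns `protein, class(SpII/SpI/TMH/CYT), score,
#'     cleavage`; `SpII` emits `SP_LIPO`, `SpI` emits `SP_SEC`, each with a
#'     `CLEAVAGE_SITE`; `TMH`/`CYT` emit nothing.}
#'   \item{`tat_short`}{columns `protein, tat(YES/NO), score, cleavage`;
#'     `YES` emits `SP_TAT` + `CLEAVAGE_SITE`.}
#'   \item{`tm_short`}{columns `protein, helices, topology`; `topology` is
#'     `-` or comma-separated `start-end` spans (one per helix), each
#'     emitted as `TM_HELIX`; zero predicted helices emit no rows.}
#'   \item{`phobius_short`}{columns `protein, tm, sp(Y/0), prediction`;
#'     `prediction` holds `;`-separated fields: an optional `cK/K+1`
#'     cleavage token when `sp == Y` (emits `SP_SEC` + `CLEAVAGE_SITE`)
#'     and optional `start-end` helix spans (emitted as `TM_HELIX`).}
#'   \item{`signature_tsv`}{columns `protein, accession, start, end,
#'     score, go`; each row emits a `SIGNATURE_HIT` labelled with the
#'     accession, plus one `GO_COMPARTMENT` row per `|`-separated GO id in
#'     `go` (`-` for none).}
#' }
#'
#' @param path File in the given dialect.
#' @param dialect One of `"sp_short"`, `"lipo_short"`, `"tat_short"`,
#'   `"tm_short"`, `"phobius_short"`, `"signature_tsv"`.
#' @param source Evidence source to attribute rows to; defaults to the
#'   dialect's canonical source family.
#' @return An `scl_evidence` data frame.
#' @examples
#' f <- system.file("extdata", "dialects", "sp_short.txt",
#'                  package = "sortloc")
#' parse_predictor_output(f, "sp_short")
#' @export
parse_predictor_output <- function(path, dialect,
                                   source = DIALECT_DEFAULT_SOURCE[[dialect]]) {
  if (length(dialect) != 1L || !dialect %in% DIALECTS) {
    input_error("unrecognized dialect '", paste(dialect, collapse = ","),
                "'; expected one of ", paste(DIALECTS, collapse = ", "))
  }
  if (!file.exists(path)) input_error("predictor output not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) input_error("empty predictor output: ", path)
  header <- lines[1L]
  expect <- DIALECT_HEADERS[[dialect]]
  got <- strsplit(trimws(sub("^#", "", header)), "[ \t]+")[[1L]]
  if (!grepl("^#", header) || !identical(got, expect)) {
    input_error(path, ": header mismatch for dialect '", dialect,
                "'; expected '# ", paste(expect, collapse = " "), "'")
  }
  body <- lines[-1L]
  body <- body[!grepl("^#", body)]
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(expect)) {
      input_error(path, ", line ", i + 1L, ": expected ", length(expect),
                  " tab-separated fields, got ", length(fields))
    }
    names(fields) <- expect
    parse_dialect_row(fields, dialect, source, path, i + 1L)
  })
  out <- do.call(rbind, c(list(empty_evidence()), rows))
  validate_evidence(out, where = path)
}

parse_dialect_row <- function(f, dialect, source, path, line) {
  num <- function(x) if (x == "-") NA_real_ else
    parse_num_col(x, path, "score")[1L]
  pos <- function(x, what = "cleavage") if (x == "-") NA_integer_ else
    parse_int_col(x, path, what)[1L]
  sp_rows <- function(kind, cleave, score) {
    if (is.na(cleave)) {
      input_error(path, ", line ", line, ": positive call lacks a ",
                  "cleavage position")
    }
    evidence_table(protein_id = f[["protein"]], source = source,
                   kind = c(kind, "CLEAVAGE_SITE"),
                   start = c(1L, cleave), end = c(cleave, cleave),
                   score = score)
  }
  switch(dialect,
    sp_short = {
      if (toupper(f[["signal"]]) == "YES") {
        sp_rows("SP_SEC", pos(f[["cleavage"]]), num(f[["score"]]))
      } else empty_evidence()
    },
    lipo_short = {
      cls <- f[["class"]]
      if (cls == "SpII") sp_rows("SP_LIPO", pos(f[["cleavage"]]),
                                 num(f[["score"]]))
      else if (cls == "SpI") sp_rows("SP_SEC", pos(f[["cleavage"]]),
                                     num(f[["score"]]))
      else if (cls %in% c("TMH", "CYT")) empty_evidence()
      else input_error(path, ", line ", line, ": unknown lipo class '",
                       cls, "'")
    },
    tat_short = {
      if (toupper(f[["tat"]]) == "YES") {
        sp_rows("SP_TAT", pos(f[["cleavage"]]), num(f[["score"]]))
      } else empty_evidence()
    },
    tm_short = {
      spans <- parse_spans(f[["topology"]], path, line)
      n_declared <- pos(f[["helices"]], "helices")
      if (!is.na(n_declared) && n_declared != nrow(spans)) {
        input_error(path, ", line ", line, ": declared ", n_declared,
                    " helices but topology lists ", nrow(spans))
      }
      if (!nrow(spans)) empty_evidence() else
        evidence_table(protein_id = f[["protein"]], source = source,
                       kind = "TM_HELIX", start = spans$start,
                       end = spans$end)
    },
    phobius_short = {
      tokens <- strsplit(f[["prediction"]], ";", fixed = TRUE)[[1L]]
      tokens <- tokens[nzchar(tokens) & tokens != "-"]
      ctok <- grep("^c[0-9]+/[0-9]+$", tokens, value = TRUE)
      stok <- setdiff(tokens, ctok)
      out <- empty_evidence()
      if (toupper(f[["sp"]]) == "Y") {
        if (!length(ctok)) {
          input_error(path, ", line ", line,
                      ": sp=Y but no cK/K+1 cleavage token")
        }
        cleave <- as.integer(sub("^c([0-9]+)/.*$", "\\1", ctok[1L]))
        out <- rbind(out, sp_rows("SP_SEC", cleave, NA_real_))
      }
      if (length(stok)) {
        spans <- parse_spans(paste(stok, collapse = ","), path, line)
        out <- rbind(out, evidence_table(protein_id = f[["protein"]],
                                         source = source, kind = "TM_HELIX",
                                         start = spans$start,
                                         end = spans$end))
      }
      out
    },
    signature_tsv = {
      out <- evidence_table(protein_id = f[["protein"]], source = source,
                            kind = "SIGNATURE_HIT",
                            start = pos(f[["start"]], "start"),
                            end = pos(f[["end"]], "end"),
                            score = num(f[["score"]]),
                            label = f[["accession"]])
      if (f[["go"]] != "-") {
        gos <- strsplit(f[["go"]], "|", fixed = TRUE)[[1L]]
        if (!all(grepl("^GO:[0-9]{7}$", gos))) {
          input_error(path, ", line ", line, ": malformed GO id in '",
                      f[["go"]], "'")
        }
        out <- rbind(out, evidence_table(protein_id = f[["protein"]],
                                         source = source,
                                         kind = "GO_COMPARTMENT",
                                         label = gos))
      }
      out
    })
}

parse_spans <- function(x, path, line) {
  if (x == "-" || !nzchar(x)) {
    return(data.frame(start = integer(), end = integer()))
  }
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  if (!all(grepl("^[0-9]+-[0-9]+$", parts))) {
    input_error(path, ", line ", line, ": malformed span list '", x, "'")
  }
  start <- as.integer(sub("-.*$", "", parts))
  end <- as.integer(sub("^.*-", "", parts))
  data.frame(start = start, end = end)
}
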