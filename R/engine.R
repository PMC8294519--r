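## The decision engine: evidence -> 14-variable state -> provisional tags
## -> consistency resolution -> secondary annotation.  The architecture is
## scores + Boolean overrides + per-compartment thresholds + an ordered
## consistency-rule table; every constant is a config key.

## Which flag and which score each signature category feeds.  The three
## "second-level" categories (surface, pilin, short secreted peptide) are
## hint-level: they add to score_extra, which alone stays below the EXTRA
## threshold of 2, so a motif that merely suggests a localization never
## decides it by itself.
CATEGORY_FLAG <- c(secretion = "flag_secretion_signature", tat = "flag_tat",
                   lipoprotein = "flag_lipoprotein",
                   cw_covalent = "flag_cw_covalent",
                   cw_noncovalent = "flag_cw_noncovalent",
                   cw_spore = "flag_spore", surface = "flag_surface",
                   pilin_fimbrilin = "flag_pilin",
                   short_secreted_peptide = "flag_short_peptide")

CATEGORY_SCORE <- c(secretion = "extra", tat = "extra",
                    lipoprotein = "lipo", cw_covalent = "cw",
                    cw_noncovalent = "cw", cw_spore = "cw",
                    surface = "extra", pilin_fimbrilin = "extra",
                    short_secreted_peptide = "extra")

FLAG_NAMES <- unname(CATEGORY_FLAG)

#' Fold evidence for one protein into the integration state
#'
#' Computes the engine's 14 variables -- five numeric compartment scores
#' (`extra`, `lipo`, `tm`, `cw`, `cyto`) and nine Boolean override flags
#' (one per signature category) -- from the evidence rows of a single
#' protein. The state is a pure tally, independent of evidence order:
#' \itemize{
#'   \item each distinct source reporting `SP_SEC` adds `weights$sp_sec`
#'     to `extra`; likewise `SP_LIPO` to `lipo` and `SP_TAT` to `extra`
#'     (also raising `flag_tat`);
#'   \item every `TM_HELIX` row adds `weights$tm_helix` to `tm`;
#'   \item a `SIGNATURE_HIT` whose accession the catalog knows raises the
#'     category's flag and adds `weights$signature` to the category's
#'     score; unlisted accessions are inert;
#'   \item `GO_COMPARTMENT` and `SCL_VOTE` rows add to the hinted /
#'     voted tag's score;
#'   \item when the protein's only transmembrane helix starts in the
#'     first 40 residues and coincides with a signal-peptide span (or is
#'     labelled `possible_sp_overlap`), its contribution is discounted by
#'     `weights$sp_tm_overlap` -- the hydrophobic core of a signal
#'     peptide masquerades as a helix. Scores floor at zero.
#' }
#'
#' @param ev Evidence rows, all for one protein.
#' @param catalog An `scl_catalog`.
#' @param weights The `weights` section of the configuration.
#' @return A list of class `evidence_state`: `scores` (named numeric),
#'   `flags` (named logical), plus bookkeeping used by resolution and
#'   annotation (`n_tm`, `n_evidence`, `has_signal`, `has_sp_sec`,
#'   `has_sp_lipo`, `cleavage`, `accessions`, `rationale`).
#' @export
accumulate <- function(ev, catalog, weights = default_config()$weights) {
  ev <- validate_evidence(as.data.frame(ev))
  if (nrow(ev) && length(unique(ev$protein_id)) > 1L) {
    input_error("accumulate() requires evidence for a single protein; got ",
                paste(unique(ev$protein_id), collapse = ", "))
  }
  ## canonical processing order makes the rationale trail deterministic
  if (nrow(ev)) {
    ev <- ev[order(ev$kind, ev$source, ev$start, ev$label,
                   method = "radix"), ]
  }
  scores <- c(extra = 0, lipo = 0, tm = 0, cw = 0, cyto = 0)
  flags <- setNames(rep(FALSE, length(FLAG_NAMES)), FLAG_NAMES)
  rationale <- character()
  note <- function(...) rationale[[length(rationale) + 1L]] <<- paste0(...)

  for (kind in c("SP_SEC", "SP_LIPO", "SP_TAT")) {
    rows <- ev[ev$kind == kind, ]
    n_src <- length(unique(rows$source))
    if (n_src == 0L) next
    w <- switch(kind, SP_SEC = weights$sp_sec, SP_LIPO = weights$sp_lipo,
                SP_TAT = weights$sp_tat)
    target <- if (kind == "SP_LIPO") "lipo" else "extra"
    scores[target] <- scores[target] + n_src * w
    note(kind, " from ", n_src, " source(s): ", target, " +", n_src * w)
    if (kind == "SP_TAT") {
      flags["flag_tat"] <- TRUE
      note("flag_tat set (twin-arginine evidence)")
    }
  }

  tm_rows <- ev[ev$kind == "TM_HELIX", ]
  if (nrow(tm_rows)) {
    scores["tm"] <- scores["tm"] + nrow(tm_rows) * weights$tm_helix
    note(nrow(tm_rows), " TM helix(es): tm +",
         nrow(tm_rows) * weights$tm_helix)
  }

  accessions <- character()
  for (i in seq_len(nrow(ev))) {
    r <- ev[i, ]
    if (r$kind == "SIGNATURE_HIT" && !is.na(r$label)) {
      cat_name <- classify_hit(r$label, catalog)
      if (!is.na(cat_name)) {
        accessions <- c(accessions, r$label)
        flags[CATEGORY_FLAG[[cat_name]]] <- TRUE
        scores[CATEGORY_SCORE[[cat_name]]] <-
          scores[CATEGORY_SCORE[[cat_name]]] + weights$signature
        note("signature ", r$label, " [", cat_name, "]: ",
             CATEGORY_SCORE[[cat_name]], " +", weights$signature,
             ", ", CATEGORY_FLAG[[cat_name]], " set")
      }
    } else if (r$kind == "GO_COMPARTMENT" && !is.na(r$label)) {
      tag <- go_to_tag(r$label, catalog)
      if (!is.na(tag)) {
        sc <- tolower(tag)
        scores[sc] <- scores[sc] + weights$go
        note("GO ", r$label, " -> ", tag, ": ", sc, " +", weights$go)
      }
    } else if (r$kind == "SCL_VOTE") {
      sc <- tolower(r$label)
      scores[sc] <- scores[sc] + weights$vote
      note("SCL vote ", r$label, ": ", sc, " +", weights$vote)
    }
  }

  ## signal peptide / lone N-terminal helix disambiguation
  sp_rows <- ev[ev$kind %in% c("SP_SEC", "SP_LIPO", "SP_TAT") &
                  !is.na(ev$start), ]
  if (nrow(tm_rows) == 1L && !is.na(tm_rows$start[1L]) &&
      tm_rows$start[1L] <= 40L) {
    flagged <- !is.na(tm_rows$label[1L]) &&
      tm_rows$label[1L] == "possible_sp_overlap"
    overlaps <- nrow(sp_rows) > 0L &&
      any(sp_rows$start <= tm_rows$end[1L] &
            sp_rows$end >= tm_rows$start[1L])
    if (flagged || overlaps) {
      scores["tm"] <- scores["tm"] + weights$sp_tm_overlap
      note("lone N-terminal helix overlaps a signal peptide: tm ",
           weights$sp_tm_overlap)
    }
  }
  scores <- pmax(scores, 0)

  cleave_rows <- ev[ev$kind == "CLEAVAGE_SITE" & !is.na(ev$start), ]
  cleavage <- NA_integer_
  if (nrow(cleave_rows)) {
    sc <- ifelse(is.na(cleave_rows$score), 0, cleave_rows$score)
    best <- which(sc == max(sc))
    cleavage <- min(cleave_rows$start[best])
  }

  structure(list(
    protein_id = if (nrow(ev)) ev$protein_id[1L] else NA_character_,
    scores = scores, flags = flags,
    n_tm = nrow(tm_rows), n_evidence = nrow(ev),
    has_signal = any(ev$kind %in% c("SP_SEC", "SP_LIPO", "SP_TAT",
                                    "TM_HELIX", "SIGNATURE_HIT")),
    has_sp_sec = any(ev$kind == "SP_SEC"),
    has_sp_lipo = any(ev$kind == "SP_LIPO"),
    cleavage = cleavage, accessions = unique(accessions),
    rationale = rationale), class = "evidence_state")
}

empty_state <- function() {
  structure(list(protein_id = NA_character_,
                 scores = c(extra = 0, lipo = 0, tm = 0, cw = 0, cyto = 0),
                 flags = setNames(rep(FALSE, length(FLAG_NAMES)),
                                  FLAG_NAMES),
                 n_tm = 0L, n_evidence = 0L, has_signal = FALSE,
                 has_sp_sec = FALSE, has_sp_lipo = FALSE,
                 cleavage = NA_integer_, accessions = character(),
                 rationale = character()), class = "evidence_state")
}

#' Assign provisional localization tags from a state
#'
#' A tag is appended when its compartment score meets its threshold, or
#' when an unequivocal Boolean flag overrides the score:
#' `flag_lipoprotein` forces `LIPO`, any of the three cell-wall flags
#' forces `CW`, and `flag_secretion_signature` forces `EXTRA`. `CYTO` is
#' never assigned here -- it is the fallback applied by [resolve_tags()]
#' -- and an all-quiet state yields the empty set (later resolved to
#' `Unknown`).
#'
#' @param state An `evidence_state`.
#' @param thresholds The `thresholds` section of the configuration.
#' @return Character vector of provisional tags (possibly empty).
#' @export
assign_tags <- function(state, thresholds = default_config()$thresholds) {
  stopifnot(inherits(state, "evidence_state"))
  s <- state$scores
  f <- state$flags
  tags <- character()
  if (s["extra"] >= thresholds$extra || f["flag_secretion_signature"]) {
    tags <- c(tags, "EXTRA")
  }
  if (s["lipo"] >= thresholds$lipo || f["flag_lipoprotein"]) {
    tags <- c(tags, "LIPO")
  }
  if (s["tm"] >= thresholds$tm) tags <- c(tags, "TM")
  if (s["cw"] >= thresholds$cw || f["flag_cw_covalent"] ||
      f["flag_cw_noncovalent"] || f["flag_spore"]) {
    tags <- c(tags, "CW")
  }
  sort(tags)
}

#' Resolve a provisional tag set for consistency
#'
#' Applies the ordered consistency-rule table (rules are appended, never
#' reordered):
#' \enumerate{
#'   \item `Unknown` in the input is absorbing.
#'   \item `EXTRA` alongside `CW` is redundant -- cell-wall proteins are
#'     intrinsically extracellular -- so `EXTRA` is dropped.
#'   \item `EXTRA` alongside `LIPO` likewise drops `EXTRA`.
#'   \item `CYTO` together with any non-cytoplasmic tag is a conflict:
#'     the result is `Unknown`.
#'   \item `TM` alongside `EXTRA`: with at least two helix observations
#'     the protein is called `TM`, otherwise `EXTRA` (a single helix next
#'     to strong export evidence is likely the signal anchor).
#'   \item An empty set falls back to `CYTO` only when nothing
#'     signal-like was seen (no SP/TM/signature evidence) and either the
#'     cytoplasmic score is positive or there was no evidence at all;
#'     any other empty set is `Unknown`.
#' }
#' `CW` and `TM` may legitimately co-exist (multi-location cell
#' wall/membrane proteins). The function is idempotent.
#'
#' @param tags Character vector of provisional tags.
#' @param state Optional `evidence_state` providing the helix count,
#'   cytoplasmic score and evidence-presence facts used by rules 5-6;
#'   defaults to an empty state.
#' @return Character vector: a consistent tag set, `"CYTO"` or
#'   `"Unknown"`.
#' @export
resolve_tags <- function(tags, state = empty_state()) {
  stopifnot(inherits(state, "evidence_state"))
  tags <- unique(tags)
  if ("Unknown" %in% tags) return("Unknown")
  bad <- setdiff(tags, SCL_CLASSES)
  if (length(bad)) input_error("unknown tag '", bad[1L], "'")
  if (all(c("EXTRA", "CW") %in% tags)) tags <- setdiff(tags, "EXTRA")
  if (all(c("EXTRA", "LIPO") %in% tags)) tags <- setdiff(tags, "EXTRA")
  if ("CYTO" %in% tags && length(tags) > 1L) return("Unknown")
  if (all(c("TM", "EXTRA") %in% tags)) {
    tags <- if (state$n_tm >= 2L) setdiff(tags, "EXTRA") else
      setdiff(tags, "TM")
  }
  if (!length(tags)) {
    quiet <- !state$has_signal &&
      (state$scores[["cyto"]] > 0 || state$n_evidence == 0L)
    return(if (quiet) "CYTO" else "Unknown")
  }
  sort(tags)
}

#' Attach secondary annotations to a resolved call
#'
#' Secretion pathway: `Tat` when the twin-arginine flag fired; else `Sec`
#' when any Sec or lipoprotein signal peptide was seen (SpI and SpII are
#' both Sec-pathway); else the `-like` pathway of a fired
#' alternative-route hint (secretion-category accessions resolve through
#' the catalog's pathway map; pilin motifs give `FPE-like`, short
#' secreted peptides `bacteriocin-like`); else `none`. Pathway hints are
#' reported even when the final tag set is `Unknown`. The cleavage site
#' is the highest-scoring `CLEAVAGE_SITE` observation. Wall interaction
#' is `covalent` / `non-covalent` / `spore` by flag priority, but only
#' when `CW` is among the final tags.
#'
#' @param tags Resolved tag vector.
#' @param state An `evidence_state`.
#' @param catalog An `scl_catalog`.
#' @return List with `pathway`, `cleavage_site`, `wall_interaction`.
#' @export
annotate_secondary <- function(tags, state, catalog) {
  stopifnot(inherits(state, "evidence_state"))
  f <- state$flags
  pathway <- "none"
  if (f["flag_tat"]) {
    pathway <- "Tat"
  } else if (state$has_sp_sec || state$has_sp_lipo) {
    pathway <- "Sec"
  } else if (f["flag_secretion_signature"] &&
             any(state$accessions %in% names(catalog$pathways))) {
    hit <- state$accessions[state$accessions %in%
                              names(catalog$pathways)][1L]
    pathway <- unname(catalog$pathways[hit])
  } else if (f["flag_pilin"]) {
    pathway <- "FPE-like"
  } else if (f["flag_short_peptide"]) {
    pathway <- "bacteriocin-like"
  }
  wall <- "none"
  if ("CW" %in% tags) {
    if (f["flag_cw_covalent"]) wall <- "covalent"
    else if (f["flag_cw_noncovalent"]) wall <- "non-covalent"
    else if (f["flag_spore"]) wall <- "spore"
  }
  cleavage <- state$cleavage
  if (!is.na(cleavage) && pathway == "none") cleavage <- NA_integer_
  list(pathway = pathway, cleavage_site = cleavage,
       wall_interaction = wall)
}

#' Predict subcellular localization for a set of proteins
#'
#' The end-to-end engine: per protein, evidence is accumulated into the
#' 14-variable state, provisional tags are assigned by thresholds and
#' overrides, the consistency table resolves them, and secondary
#' annotations (pathway, cleavage site, wall interaction) are attached.
#' Records with no supplied evidence fall back to the built-in detector
#' panel when `config$builtin$mode` is `"auto"` (the default); `"always"`
#' adds built-in panel evidence for every record, `"never"` disables it.
#'
#' @param records An `scl_sequences` table (see [read_fasta()]).
#' @param evidence Optional `scl_evidence` table; every `protein_id` must
#'   occur in `records`.
#' @param catalog An `scl_catalog`; defaults to the shipped starter
#'   catalog.
#' @param config An `scl_config`; defaults to [default_config()].
#' @return A data frame of class `scl_predictions`, one row per record,
#'   with the documented seven columns; the per-protein rule trail is
#'   attached as `attr(, "rationale")` (a named list of character
#'   vectors).
#' @examples
#' recs <- new_sequences("demo", "",
#'   paste0("MKKLLLLLLLLLAVAAQA", strrep("SGNQDET", 20)))
#' predict_scl(recs)
#' @export
predict_scl <- function(records, evidence = NULL,
                        catalog = load_catalog(),
                        config = default_config()) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (anyDuplicated(records$id)) {
    input_error("duplicate record id: ",
                records$id[duplicated(records$id)][1L])
  }
  if (is.null(evidence)) evidence <- empty_evidence()
  evidence <- validate_evidence(as.data.frame(evidence),
                                sequences = records)
  orphan <- setdiff(unique(evidence$protein_id), records$id)
  if (length(orphan)) {
    input_error("evidence refers to unknown protein(s): ",
                paste(orphan, collapse = ", "))
  }
  rows <- vector("list", nrow(records))
  rationale <- vector("list", nrow(records))
  names(rationale) <- records$id
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    ev_p <- evidence[evidence$protein_id == rec$id, , drop = FALSE]
    used_builtin <- FALSE
    if (config$builtin$mode == "always" ||
        (config$builtin$mode == "auto" && nrow(ev_p) == 0L)) {
      ev_b <- builtin_panel(rec, config)
      ev_p <- rbind(ev_p, ev_b)
      used_builtin <- TRUE
    }
    state <- accumulate(ev_p, catalog, config$weights)
    provisional <- assign_tags(state, config$thresholds)
    tags <- resolve_tags(provisional, state)
    sec <- annotate_secondary(tags, state, catalog)
    trail <- state$rationale
    if (used_builtin) trail <- c("built-in detector panel used", trail)
    trail <- c(trail,
               paste0("provisional tags: {",
                      paste(provisional, collapse = ","), "}"),
               paste0("resolved tags: {", paste(tags, collapse = ","), "}"))
    rationale[[rec$id]] <- trail
    kinds <- table(ev_p$kind)
    rows[[i]] <- data.frame(
      protein_id = rec$id,
      true_tags = NA_character_,
      predicted_tags = format_tags(tags),
      pathway = sec$pathway,
      cleavage_site = sec$cleavage_site,
      wall_interaction = sec$wall_interaction,
      evidence_summary = if (length(kinds)) {
        paste(sprintf("%s:%d", names(kinds), as.integer(kinds)),
              collapse = "|")
      } else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scl_predictions", "data.frame")
  attr(out, "rationale") <- rationale
  out
}
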