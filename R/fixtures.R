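## Synthetic labeled proteomes with correlated, noisy evidence.  The
## generator plants the sequence architecture each class's sorting signal
## implies (Sec signal peptide, lipobox, transmembrane helices, LPXTG
## anchor), draws everything else from a polar-biased residue pool that
## cannot fire the detectors by accident, and emits matching predictor
## evidence whose fidelity is controlled by a single per-item noise
## probability.  Default class counts (CW 58, CYTO 88, EXTRA 133, LIPO 9,
## TM 84) follow the composition of a curated Gram-positive benchmark set
## so that size-weighted averages are exercised on realistically
## unbalanced classes.

POLAR_POOL <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "H", "Y", "P")
HYDRO_CORE <- c("L", "I", "V", "F")

DEFAULT_CLASS_COUNTS <- c(CW = 58L, CYTO = 88L, EXTRA = 133L, LIPO = 9L,
                          TM = 84L)

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic proteome fixture
#'
#' @param n_per_class Named integer vector of proteins per class; names
#'   from the five localization classes. Defaults to the benchmark-shaped
#'   composition CW 58, CYTO 88, EXTRA 133, LIPO 9, TM 84.
#' @param noise Per-evidence-item corruption probability in `[0, 1]`:
#'   each truth-consistent item is dropped with probability `noise`, and
#'   each simulated source emits a spurious contradictory item with
#'   probability `noise`.
#' @param n_sources Number of simulated signal-peptide predictors
#'   (1-3; default 3).
#' @param seed Integer seed; identical specs generate byte-identical
#'   output.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_per_class = DEFAULT_CLASS_COUNTS, noise = 0,
                         n_sources = 3L, seed = 1L) {
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% SCL_CLASSES)) {
    input_error("n_per_class must be named with classes from ",
                paste(SCL_CLASSES, collapse = "/"))
  }
  if (any(n_per_class < 0)) input_error("class counts must be >= 0")
  if (!is.numeric(noise) || noise < 0 || noise > 1) {
    input_error("noise must lie in [0, 1]")
  }
  n_sources <- as.integer(n_sources)
  if (is.na(n_sources) || n_sources < 1L || n_sources > 3L) {
    input_error("n_sources must be between 1 and 3")
  }
  structure(list(n_per_class = n_per_class, noise = noise,
                 n_sources = n_sources, seed = as.integer(seed)),
            class = "fixture_spec")
}

rand_polar <- function(n) {
  paste(sample(POLAR_POOL, n, replace = TRUE), collapse = "")
}

rand_hydro <- function(n) {
  paste(sample(HYDRO_CORE, n, replace = TRUE), collapse = "")
}

## Sec signal peptide with n-region KK, h-region of 10 hydrophobics and an
## A-x-A cleavage site at position 16 (detected by scan_sec_sp).
make_sec_sp <- function() paste0("MKK", rand_hydro(10L), "AQA")

build_sequence <- function(class, archetype) {
  switch(class,
    CYTO = paste0("M", rand_polar(sample(150:250, 1L))),
    EXTRA = paste0(make_sec_sp(), rand_polar(sample(100:180, 1L))),
    LIPO = paste0("MKK", rand_hydro(12L), "LAGC",
                  rand_polar(sample(100:180, 1L))),
    TM = {
      k <- sample(1:3, 1L)
      parts <- paste0("M", rand_polar(sample(30:50, 1L)))
      for (j in seq_len(k)) {
        parts <- paste0(parts, rand_hydro(21L),
                        if (j < k) rand_polar(sample(30:45, 1L)) else "")
      }
      paste0(parts, rand_polar(sample(20:40, 1L)))
    },
    CW = {
      core <- paste0(make_sec_sp(), rand_polar(sample(60:120, 1L)))
      if (archetype == "covalent") {
        paste0(core, "LPKTG", rand_hydro(18L), "KKRK")
      } else {
        core
      }
    })
}

#' Generate a labeled synthetic proteome
#'
#' Per class, sequences carry that class's detectable architecture:
#' EXTRA a Sec signal peptide plus a soluble polar mature region; LIPO a
#' lipobox signal peptide; TM one to three internal hydrophobic helices;
#' CW a signal peptide plus either a C-terminal LPXTG anchor (covalent
#' archetype, about two thirds) or a plain secreted architecture whose
#' cell-wall association is carried by signature evidence (non-covalent
#' archetype); CYTO no signals at all. Mature/linker regions are drawn
#' from a polar-biased residue pool.
#'
#' @param spec A [fixture_spec()].
#' @return List with `records` (an `scl_sequences` table) and `truth`
#'   (data frame `protein_id`, `true_tags`, `archetype`).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    ids <- character(); descs <- character(); seqs <- character()
    t_ids <- character(); t_tags <- character(); t_arch <- character()
    for (class in intersect(SCL_CLASSES, names(spec$n_per_class))) {
      n <- spec$n_per_class[[class]]
      for (i in seq_len(n)) {
        arch <- if (class == "CW") {
          if (i %% 3L == 0L) "non-covalent" else "covalent"
        } else NA_character_
        id <- sprintf("%s_%04d", tolower(class), i)
        ids <- c(ids, id)
        descs <- c(descs, paste0("synthetic ", class, " protein"))
        seqs <- c(seqs, build_sequence(class, arch))
        t_ids <- c(t_ids, id)
        t_tags <- c(t_tags, class)
        t_arch <- c(t_arch, arch)
      }
    }
    list(records = new_sequences(ids, descs, seqs),
         truth = data.frame(protein_id = t_ids, true_tags = t_tags,
                            archetype = t_arch, stringsAsFactors = FALSE))
  })
}

#' Generate noisy predictor evidence for a labeled proteome
#'
#' Emulates the predictor panel: each of `n_sources` simulated
#' signal-peptide predictors independently reports the truth-consistent
#' call (Sec signal peptide for EXTRA/CW, lipoprotein signal peptide for
#' LIPO, nothing for CYTO/TM) with probability `1 - noise`, and emits a
#' spurious contradictory item with probability `noise`; a topology
#' predictor reports each true helix with probability `1 - noise`; a
#' signature scanner reports the class's catalog signature (cell-wall
#' covalent/non-covalent, lipoprotein) with probability `1 - noise` and a
#' wrong-category signature with probability `noise`. Signal-peptide
#' spans and helix positions are taken from the built-in detectors run on
#' the generated sequence, so evidence coordinates are sequence-faithful.
#'
#' @param records,truth Output of [generate_proteome()].
#' @param spec The same [fixture_spec()].
#' @param catalog Catalog supplying signature accessions.
#' @return An `scl_evidence` data frame.
#' @export
generate_evidence <- function(records, truth, spec,
                              catalog = load_catalog()) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!setequal(records$id, truth$protein_id)) {
    input_error("records and truth tables disagree on protein ids")
  }
  sp_sources <- c("sp_predictor_a", "sp_predictor_b",
                  "lipo_predictor")[seq_len(spec$n_sources)]
  cov_acc <- setdiff(catalog$categories$cw_covalent, "CW_COVALENT_MOTIF")
  noncov_acc <- catalog$categories$cw_noncovalent
  lipo_acc <- catalog$categories$lipoprotein
  with_seed(spec$seed + 104729L, {
    pieces <- list()
    add <- function(x) pieces[[length(pieces) + 1L]] <<- x
    keep <- function() runif(1L) >= spec$noise
    corrupt <- function() runif(1L) < spec$noise
    for (i in seq_len(nrow(records))) {
      rec <- records[i, ]
      len <- nchar(rec$seq)
      class <- truth$true_tags[truth$protein_id == rec$id]
      arch <- truth$archetype[truth$protein_id == rec$id]
      sp_hit <- switch(class,
        EXTRA = , CW = scan_sec_sp(rec),
        LIPO = scan_lipobox(rec),
        empty_evidence())
      cleave <- if (nrow(sp_hit)) {
        sp_hit$start[sp_hit$kind == "CLEAVAGE_SITE"][1L]
      } else 16L
      sp_kind <- if (identical(class, "LIPO")) "SP_LIPO" else "SP_SEC"
      for (src in sp_sources) {
        if (class %in% c("EXTRA", "CW", "LIPO")) {
          if (keep()) {
            add(evidence_table(protein_id = rec$id, source = src,
                               kind = c(sp_kind, "CLEAVAGE_SITE"),
                               start = c(1L, cleave),
                               end = c(cleave, cleave),
                               score = round(runif(1L, 0.85, 0.99), 3L)))
          }
          if (corrupt()) {
            wrong <- if (sp_kind == "SP_SEC") "SP_LIPO" else "SP_SEC"
            add(evidence_table(protein_id = rec$id, source = src,
                               kind = wrong, start = 1L,
                               end = min(19L, len),
                               score = round(runif(1L, 0.5, 0.9), 3L)))
          }
        } else if (corrupt()) {
          add(evidence_table(protein_id = rec$id, source = src,
                             kind = c("SP_SEC", "CLEAVAGE_SITE"),
                             start = c(1L, min(20L, len)),
                             end = c(min(20L, len), min(20L, len)),
                             score = round(runif(1L, 0.5, 0.9), 3L)))
        }
      }
      if (identical(class, "TM")) {
        helices <- scan_tm_hydropathy(rec)
        for (j in seq_len(nrow(helices))) {
          if (keep()) {
            add(evidence_table(protein_id = rec$id,
                               source = "tm_predictor", kind = "TM_HELIX",
                               start = helices$start[j],
                               end = helices$end[j]))
          }
        }
      }
      if (corrupt() && len > 20L) {
        s <- sample.int(len - 19L, 1L)
        add(evidence_table(protein_id = rec$id, source = "tm_predictor",
                           kind = "TM_HELIX", start = s, end = s + 18L))
      }
      sig_acc <- switch(class,
        CW = if (identical(arch, "covalent")) cov_acc else noncov_acc,
        LIPO = lipo_acc,
        NULL)
      if (!is.null(sig_acc) && length(sig_acc) && keep()) {
        add(evidence_table(protein_id = rec$id,
                           source = "signature_scanner",
                           kind = "SIGNATURE_HIT", start = 1L,
                           end = min(40L, len),
                           score = round(runif(1L, 1, 60), 2L),
                           label = sample(sig_acc, 1L)))
      }
      if (corrupt()) {
        wrong_pool <- switch(class,
          CW = lipo_acc, LIPO = cov_acc,
          c(lipo_acc, cov_acc, noncov_acc))
        add(evidence_table(protein_id = rec$id,
                           source = "signature_scanner",
                           kind = "SIGNATURE_HIT", start = 1L,
                           end = min(40L, len),
                           score = round(runif(1L, 1, 60), 2L),
                           label = sample(wrong_pool, 1L)))
      }
    }
    out <- do.call(rbind, c(list(empty_evidence()), pieces))
    validate_evidence(out, sequences = records)
  })
}

#' Write a complete fixture set to a directory
#'
#' Convenience wrapper used by the command line: writes `proteome.fasta`,
#' `truth.tsv` and `evidence.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param catalog Catalog supplying signature accessions.
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(spec, dir, catalog = load_catalog()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prot <- generate_proteome(spec)
  ev <- generate_evidence(prot$records, prot$truth, spec, catalog)
  write_fasta(prot$records, file.path(dir, "proteome.fasta"))
  write.table(prot$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = ".")
  write_evidence(ev, file.path(dir, "evidence.tsv"))
  invisible(dir)
}
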