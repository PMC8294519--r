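## Built-in sequence-only detectors.  These stand in for the external
## predictor families so the pipeline runs hermetically: simple,
## deterministic positional rules over the canonical alphabet.  All
## windows and thresholds are exposed through the `detectors` section of
## the configuration (see `default_config()`); the decision engine is
## agnostic to whether evidence came from here or from parsed predictor
## output.

chars_of <- function(rec) strsplit(rec$seq, "", fixed = TRUE)[[1L]]

check_record <- function(rec) {
  stopifnot(is.list(rec) || is.data.frame(rec))
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- as.list(rec)
  }
  stopifnot(!is.null(rec$id), !is.null(rec$seq), nzchar(rec$seq))
  rec
}

#' Scan for a lipoprotein lipobox
#'
#' Detects the signal peptidase II lipobox `[LVI][ASTVI][GAS]C`: the
#' invariant cysteine must lie at position `c_min`-`c_max` (default
#' 15-40) and at least `min_hydrophobic` of the up-to-10 residues
#' immediately preceding the lipobox must be hydrophobic
#' (`A F I L M V W`). Each hit emits `SP_LIPO` evidence spanning
#' 1..(C-1) plus a `CLEAVAGE_SITE` at C-1 (SpII cleaves in front of the
#' lipidated cysteine).
#'
#' @param rec A single sequence record (one row of an `scl_sequences`
#'   table, or a list with `id` and `seq`).
#' @param c_min,c_max Allowed window for the cysteine position.
#' @param min_hydrophobic Minimum hydrophobic count in the 10 preceding
#'   residues.
#' @return An `scl_evidence` data frame (possibly empty).
#' @export
scan_lipobox <- function(rec, c_min = 15L, c_max = 40L,
                         min_hydrophobic = 6L) {
  rec <- check_record(rec)
  ch <- chars_of(rec)
  hits <- find_motif(rec$seq, "(?=[LVI][ASTVI][GAS]C)")
  out <- empty_evidence()
  for (s in hits) {
    cpos <- s + 3L
    if (cpos < c_min || cpos > c_max) next
    win <- ch[max(1L, s - 10L):(s - 1L)]
    if (sum(win %in% HYDROPHOBIC) < min_hydrophobic) next
    out <- rbind(out, evidence_table(
      protein_id = rec$id, source = "builtin",
      kind = c("SP_LIPO", "CLEAVAGE_SITE"),
      start = c(1L, cpos - 1L), end = c(cpos - 1L, cpos - 1L),
      label = "lipobox"))
  }
  out
}

#' Scan for a twin-arginine (Tat) motif
#'
#' Detects an S/T-R-R-x-F-L-K-like consensus: the `RR` dipeptide is
#' mandatory and must begin within the first `window` residues (default
#' 35), at least `min_consensus` (default 2) of the four flanking
#' consensus positions (S/T before the RR; F, L, K at offsets +3, +4, +5
#' from the first R) must match, and a hydrophobic stretch (>= 6 of 8
#' consecutive residues in `A F I L M V W`) must start within
#' `hydro_within` residues (default 25) after the RR. Emits one `SP_TAT`
#' hit (the first valid motif) spanning position 1 to the end of the
#' consensus.
#'
#' @inheritParams scan_lipobox
#' @param window Last allowed start position of the RR dipeptide.
#' @param min_consensus Minimum number of matching flanking positions.
#' @param hydro_within Distance after the RR within which the hydrophobic
#'   stretch must begin.
#' @export
scan_twin_arginine <- function(rec, window = 35L, min_consensus = 2L,
                               hydro_within = 25L) {
  rec <- check_record(rec)
  ch <- chars_of(rec)
  n <- length(ch)
  for (p in seq_len(min(window - 1L, n - 1L))) {
    if (ch[p] != "R" || ch[p + 1L] != "R") next
    flank <- c(p > 1L && ch[p - 1L] %in% c("S", "T"),
               p + 3L <= n && ch[p + 3L] == "F",
               p + 4L <= n && ch[p + 4L] == "L",
               p + 5L <= n && ch[p + 5L] == "K")
    if (sum(flank) < min_consensus) next
    q_range <- (p + 2L):min(p + 1L + hydro_within, n - 7L)
    if (length(q_range) < 1L || q_range[1L] > n - 7L) next
    ok <- any(vapply(q_range, function(q) {
      sum(ch[q:(q + 7L)] %in% HYDROPHOBIC) >= 6L
    }, logical(1L)))
    if (!ok) next
    return(evidence_table(protein_id = rec$id, source = "builtin",
                          kind = "SP_TAT", start = 1L,
                          end = min(p + 5L, n), label = "twin_arginine"))
  }
  empty_evidence()
}

#' Scan for a C-terminal LPXTG sortase motif
#'
#' Detects `L-P-x-T-G` starting within the last `window` residues
#' (default 50), followed by at least `min_hydrophobic` (default 15)
#' hydrophobic residues (the membrane-spanning retention segment) and at
#' least `min_positive` (default 2) of `K`/`R` within the final 10
#' residues (the positively charged cytoplasmic tail). Emits a
#' `SIGNATURE_HIT` labelled `CW_COVALENT_MOTIF` covering the motif span;
#' the shipped catalog lists that label under `cw_covalent`, so the
#' engine treats it as an unequivocal covalent cell-wall signature.
#'
#' @inheritParams scan_lipobox
#' @param window Motif must start within this many residues of the C
#'   terminus.
#' @param min_hydrophobic Minimum hydrophobic residue count after the
#'   motif.
#' @param min_positive Minimum `K`+`R` count in the final 10 residues.
#' @export
scan_lpxtg <- function(rec, window = 50L, min_hydrophobic = 15L,
                       min_positive = 2L) {
  rec <- check_record(rec)
  ch <- chars_of(rec)
  n <- length(ch)
  out <- empty_evidence()
  for (s in find_motif(rec$seq, "(?=LP[A-Z]TG)")) {
    if (n - s + 1L > window) next
    if (s + 5L > n) next
    post <- ch[(s + 5L):n]
    if (sum(post %in% HYDROPHOBIC) < min_hydrophobic) next
    tail10 <- ch[max(1L, n - 9L):n]
    if (sum(tail10 %in% c("K", "R")) < min_positive) next
    out <- rbind(out, evidence_table(
      protein_id = rec$id, source = "builtin", kind = "SIGNATURE_HIT",
      start = s, end = s + 4L, label = "CW_COVALENT_MOTIF"))
  }
  out
}

#' Scan for transmembrane helices by sliding-window hydropathy
#'
#' Computes the mean Kyte-Doolittle hydropathy over a sliding window
#' (default 19 residues) and reports maximal runs of window positions
#' whose mean meets `threshold` (default 1.6); overlapping qualifying
#' windows are merged into one `TM_HELIX` span. Runs that overlap a
#' supplied signal-peptide span are labelled `possible_sp_overlap` rather
#' than dropped (the decision engine may then discount a lone N-terminal
#' helix that is really the hydrophobic core of a signal peptide).
#'
#' @inheritParams scan_lipobox
#' @param window Window length in residues.
#' @param threshold Minimum mean hydropathy.
#' @param sp_spans Optional data frame with `start`/`end` columns of
#'   detected signal-peptide spans for this protein.
#' @export
scan_tm_hydropathy <- function(rec, window = 19L, threshold = 1.6,
                               sp_spans = NULL) {
  rec <- check_record(rec)
  ch <- chars_of(rec)
  n <- length(ch)
  if (n < window) {
    warning("sequence ", rec$id, " shorter than hydropathy window (",
            window, "); no scan performed", call. = FALSE)
    return(empty_evidence())
  }
  kd <- unname(KD_SCALE[ch])
  csum <- c(0, cumsum(kd))
  starts <- seq_len(n - window + 1L)
  means <- (csum[starts + window] - csum[starts]) / window
  ## small tolerance so windows whose true mean sits exactly on the
  ## threshold (possible: the scale has one decimal) qualify regardless
  ## of floating-point summation order
  hit <- which(means >= threshold - 1e-9)
  if (!length(hit)) return(empty_evidence())
  ## merge overlapping qualifying windows into maximal spans
  spans <- list()
  s0 <- hit[1L]
  prev <- hit[1L]
  for (h in hit[-1L]) {
    if (h <= prev + window - 1L) {
      prev <- h
    } else {
      spans[[length(spans) + 1L]] <- c(s0, prev + window - 1L)
      s0 <- h
      prev <- h
    }
  }
  spans[[length(spans) + 1L]] <- c(s0, prev + window - 1L)
  out <- empty_evidence()
  for (sp in spans) {
    lab <- NA_character_
    if (!is.null(sp_spans) && nrow(sp_spans)) {
      overlap <- any(sp_spans$start <= sp[2L] & sp_spans$end >= sp[1L])
      if (overlap) lab <- "possible_sp_overlap"
    }
    win_means <- means[starts >= sp[1L] & starts <= sp[2L] - window + 1L]
    out <- rbind(out, evidence_table(
      protein_id = rec$id, source = "builtin", kind = "TM_HELIX",
      start = sp[1L], end = sp[2L], score = max(win_means), label = lab))
  }
  out
}

#' Scan for a tripartite Sec (SpI) signal peptide
#'
#' Heuristic n/h/c-architecture rule: (n) at least one `K`/`R` in the
#' first 5 residues; (h) a run of at least `h_min` (default 7)
#' consecutive hydrophobic residues starting within positions 2-12;
#' (c) a short c-region ending in an A-x-A-like cleavage site -- the
#' first position *p* after the h-region (at most `c_max_after` = 10
#' residues past it) with *p* in `site_min`..`site_max` (default 15-45)
#' and residues *p*-2 and *p* both in `A G S T V`. Emits `SP_SEC`
#' spanning 1..*p* plus a `CLEAVAGE_SITE` at *p*.
#'
#' @inheritParams scan_lipobox
#' @param h_min Minimum h-region run length.
#' @param site_min,site_max Allowed cleavage-position window.
#' @param c_max_after Maximum distance of the cleavage site past the end
#'   of the h-region.
#' @export
scan_sec_sp <- function(rec, h_min = 7L, site_min = 15L, site_max = 45L,
                        c_max_after = 10L) {
  rec <- check_record(rec)
  ch <- chars_of(rec)
  n <- length(ch)
  if (!any(ch[seq_len(min(5L, n))] %in% c("K", "R"))) {
    return(empty_evidence())
  }
  ## maximal hydrophobic runs
  is_h <- ch %in% HYDROPHOBIC
  r <- rle(is_h)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- which(r$values & r$lengths >= h_min &
                  run_start >= 2L & run_start <= 12L)
  if (!length(keep)) return(empty_evidence())
  h_end <- run_end[keep[1L]]
  p_lo <- max(site_min, h_end + 1L)
  p_hi <- min(site_max, h_end + c_max_after, n)
  if (p_lo > p_hi) return(empty_evidence())
  for (p in p_lo:p_hi) {
    if (ch[p] %in% SMALL_RESIDUES && ch[p - 2L] %in% SMALL_RESIDUES) {
      return(evidence_table(protein_id = rec$id, source = "builtin",
                            kind = c("SP_SEC", "CLEAVAGE_SITE"),
                            start = c(1L, p), end = c(p, p),
                            label = "sec_sp"))
    }
  }
  empty_evidence()
}

find_motif <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Run all built-in detectors on one record
#'
#' Runs the signal-peptide scans first and feeds their spans to the
#' hydropathy scan so N-terminal helices overlapping a signal peptide are
#' flagged `possible_sp_overlap`.
#'
#' @inheritParams scan_lipobox
#' @param config A configuration list (see [default_config()]); the
#'   `detectors` section supplies every window/threshold.
#' @return An `scl_evidence` data frame with `source = "builtin"`.
#' @export
scan_builtin <- function(rec, config = default_config()) {
  rec <- check_record(rec)
  d <- config$detectors
  sec <- scan_sec_sp(rec, h_min = d$sec_h_min, site_min = d$sec_site_min,
                     site_max = d$sec_site_max,
                     c_max_after = d$sec_c_max_after)
  lipo <- scan_lipobox(rec, c_min = d$lipobox_c_min,
                       c_max = d$lipobox_c_max,
                       min_hydrophobic = d$lipobox_min_hydrophobic)
  tat <- scan_twin_arginine(rec, window = d$tat_window,
                            min_consensus = d$tat_min_consensus,
                            hydro_within = d$tat_hydro_within)
  sp_ev <- rbind(sec, lipo, tat)
  sp_spans <- sp_ev[sp_ev$kind %in% c("SP_SEC", "SP_LIPO", "SP_TAT") &
                      !is.na(sp_ev$start), c("start", "end")]
  tm <- scan_tm_hydropathy(rec, window = d$tm_window,
                           threshold = d$tm_threshold, sp_spans = sp_spans)
  lpxtg <- scan_lpxtg(rec, window = d$lpxtg_window,
                      min_hydrophobic = d$lpxtg_min_hydrophobic,
                      min_positive = d$lpxtg_min_positive)
  rbind(sp_ev, tm, lpxtg)
}

#' Built-in panel evidence for a set of records
#'
#' Emulates the multi-predictor panel of a real localization
#' meta-predictor using only the built-in detectors: each Sec
#' signal-peptide call is attributed to every configured Sec-predictor
#' slot (default three, mirroring the several Sec-specific predictors a
#' real panel consults), lipobox calls to the lipoprotein-predictor slot,
#' twin-arginine calls to the Tat slot, helices to the topology slot and
#' motif signatures to `builtin`. This is what [predict_scl()] falls back
#' to for records without supplied evidence, and it is what makes
#' sequence-only ("what you see is what you get") prediction possible
#' without any third-party tool.
#'
#' @param records An `scl_sequences` table.
#' @param config Configuration list; `config$builtin$sec_sources` names
#'   the Sec panel slots.
#' @return An `scl_evidence` data frame.
#' @export
builtin_panel <- function(records, config = default_config()) {
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    ev <- scan_builtin(rec, config)
    if (!nrow(ev)) return(ev)
    sec_idx <- ev$kind == "SP_SEC"
    ## cleavage rows emitted by the Sec scan travel with their SP call
    sec_cleave <- ev$kind == "CLEAVAGE_SITE" &
      !is.na(ev$label) & ev$label == "sec_sp"
    repl <- ev[sec_idx | sec_cleave, , drop = FALSE]
    rest <- ev[!(sec_idx | sec_cleave), , drop = FALSE]
    out <- rest
    out$source[out$kind == "SP_LIPO"] <- "lipo_predictor"
    out$source[out$kind == "SP_TAT"] <- "tat_predictor"
    out$source[out$kind == "TM_HELIX"] <- "tm_predictor"
    out$source[out$kind == "CLEAVAGE_SITE"] <- "lipo_predictor"
    if (nrow(repl)) {
      for (src in config$builtin$sec_sources) {
        block <- repl
        block$source <- src
        out <- rbind(out, block)
      }
    }
    out
  })
  out <- do.call(rbind, c(list(empty_evidence()), pieces))
  validate_evidence(out)
}
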