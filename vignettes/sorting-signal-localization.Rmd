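---
title: "Sorting-signal based localization prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting-signal based localization prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortloc)
```

## The prediction model

`sortloc` predicts the subcellular localization (SCL) of Gram-positive
bacterial proteins by integrating sorting-signal evidence, the way the
cell's own export machinery reads it. The model has four stages, all
deterministic given the inputs and the configuration.

**1. Evidence.** Every observation about a protein is a normalized
evidence row: a kind (`SP_SEC`, `SP_LIPO`, `SP_TAT`, `TM_HELIX`,
`SIGNATURE_HIT`, `GO_COMPARTMENT`, `SCL_VOTE`, `CLEAVAGE_SITE`), a
source family, an optional 1-based inclusive span, score and label.
Evidence can come from parsed predictor output (six fixed "short"
dialects), from a supplied table, or from the package's built-in
sequence-only detectors.

**2. Integration state.** `accumulate()` folds a protein's evidence into
14 variables: five non-negative compartment scores (`extra`, `lipo`,
`tm`, `cw`, `cyto`) and nine monotone Boolean flags, one per signature
category. Scores are weighted counts — by default each *distinct source*
reporting a signal peptide contributes +1, each reported helix +1, each
catalog-listed signature +1 to its category's score. Flags, once set,
are never reset within a protein's evaluation. The only negative weight
(−1, flooring at zero) discounts a lone N-terminal helix that coincides
with a signal-peptide span: the hydrophobic h-region of a signal peptide
reliably masquerades as a transmembrane helix, and counting it twice
would turn every secreted protein into a membrane protein.

**3. Tag assignment and consistency resolution.** `assign_tags()`
appends a tag when its score reaches its threshold *or* when an
unequivocal category flag fires (lipoprotein ⇒ `LIPO`; any cell-wall
subcategory ⇒ `CW`; secretion signature ⇒ `EXTRA`). `CYTO` is never
assigned positively — it is the fallback of `resolve_tags()`, which
applies an ordered rule table (rules may be appended, never reordered):

1. `Unknown` in the input is absorbing.
2. `EXTRA` + `CW` → `CW` (cell-wall proteins are intrinsically
   extracellular; the information is redundant).
3. `EXTRA` + `LIPO` → `LIPO` (same logic: the lipoprotein passed the
   membrane but is retained).
4. `CYTO` + any non-cytoplasmic tag → `Unknown` (no combination of
   signals supports both).
5. `TM` + `EXTRA` → `TM` when at least two helices were observed, else
   `EXTRA` (a single helix next to strong export evidence is most likely
   the signal anchor).
6. Empty set → `CYTO` only when no signal-like evidence (signal peptide,
   helix, signature) was seen at all and either the cytoplasmic score is
   positive or there was no evidence whatsoever; any other empty set is
   `Unknown`.

`CW` and `TM` may co-exist: multi-location cell-wall/membrane proteins
are real. The table is idempotent (verified exhaustively over all 32 tag
subsets), so resolution cannot oscillate.

**4. Secondary annotation.** Pathway: `Tat` if the twin-arginine flag
fired, else `Sec` if any Sec *or* lipoprotein signal peptide was seen
(SpI and SpII cleavage are both Sec-pathway transport), else the `-like`
label of a fired alternative-route hint (secretion-category accessions
resolve through the catalog's `pathways.tsv`; pilin motifs give
`FPE-like`, short secreted peptides `bacteriocin-like`). Hints are
reported even when the final call is `Unknown`, because a Tat or pilin
motif suggests a destination without determining it. The cleavage site
is the highest-scoring `CLEAVAGE_SITE` observation (missing scores rank
lowest; ties break to the smallest position). Wall interaction
(covalent > non-covalent > spore, by flag priority) is only reported
when `CW` is among the final tags.

### Assumptions

* Monoderm (Firmicutes-type) cell architecture: no outer membrane, and
  no outer-membrane class — diderm Actinobacteria are outside the model.
* Peripheral membrane proteins carry no detectable sorting signal and
  are therefore called `CYTO`.
* Prediction is strictly sequence-evidence driven: engineering away a
  signal peptide changes the call. This is intended behaviour for
  synthetic constructs and mis-annotated truncations, not a bug.

## Tunable parameters

All constants live in one configuration (`default_config()`, YAML
overridable, unknown keys rejected). The defaults are this package's own
calibration of the printed architecture; they are deliberately exposed
so that alternative constant sets can be dropped in verbatim.

| key | default | why |
|---|---|---|
| `weights.*` | +1 per evidence item | scores are interpretable as "number of concordant evidences" |
| `weights.sp_tm_overlap` | −1 | cancel the SP-as-helix double count |
| `thresholds.extra` | 2 | a secreted call needs two independent sources; single-predictor SP calls are the dominant false-positive mode |
| `thresholds.lipo/tm/cw` | 1 | these signals are individually specific (lipobox, helix, wall signature) |
| `detectors.tm_window` | 19 residues | canonical span of a membrane-crossing helix |
| `detectors.tm_threshold` | 1.6 | Kyte–Doolittle mean identifying candidate membrane spans |
| `detectors.lipobox_c_min/max` | 15–40 | positional window of the lipidated cysteine |
| `detectors.sec_*` | h ≥ 7, site 15–45 | tripartite n/h/c signal-peptide geometry |
| `builtin.sec_sources` | 3 slots | see below |
| `evaluation.unknown` | `"negative"` | see below |

## The built-in detector panel

The real tool panel (several Sec-specific signal-peptide predictors plus
one lipoprotein, one Tat, one topology predictor and a signature
scanner) is license-restricted, so the package ships rule-based
detectors: tripartite Sec SP scan, lipobox `[LVI][ASTVI][GAS]C` with a
hydrophobic context, S/T-R-R-x-F-L-K twin-arginine consensus, sliding
Kyte–Doolittle hydropathy windows, and the LPXTG anchor architecture
(motif in the last 50 residues, ≥ 15 hydrophobics after it, ≥ 2 K/R in
the final 10). They are pure positional rules, verified against naive
brute-force re-scans on random sequences.

When a record arrives without any supplied evidence, `predict_scl()`
falls back to this panel, attributing a built-in Sec call to each of the
configured Sec slots (default three). This mirrors the fact that a
sequence with a genuine tripartite signal peptide would be called
concordantly by the several Sec-specific predictors of a real panel, and
it is what allows a hermetic, sequence-only run to clear the
`extra ≥ 2` threshold. The panel breadth is a config key; setting it to 1
makes built-in evidence count as a single predictor, in which case a
sequence-only run can never call `EXTRA` (by design of the threshold).
The detectors do not attempt to match the third-party tools' accuracy,
and no in/out topology orientation is predicted.

## Evaluation scheme

Metrics are one-vs-rest per class. `Unknown` is handled explicitly
because abstention-heavy predictors otherwise look artificially precise:
under the default `"negative"` policy an `Unknown` prediction is a
negative call for every class (a true member predicted `Unknown` is a
false negative); under `"exclude"` abstentions are dropped before
counting. Either way the per-class `unknown_rate` is reported as its own
column, never folded into the confusion counts. Multi-location truths
(e.g. `CW;TM`) count as positive for each of their classes, and a
multi-tag prediction as a positive call for each predicted class — one
defensible reading among several; it is isolated in
`confusion_counts()` if a different convention is needed. Overall values
are class-size-weighted means; classes with an undefined metric (zero
denominator, reported `NA`, never 0) are excluded from that metric's
average with weights renormalized.

## The synthetic proteome generator

`generate_proteome()` plants, per class, exactly the architecture the
detectors read (Sec SP + polar mature region; lipobox; 1–3 internal
21-residue hydrophobic helices; SP + LPXTG tail or SP + signature-borne
non-covalent wall association; no signals for `CYTO`), with everything
else drawn from a polar-biased residue pool chosen so that no detector
can fire by accident (no cysteines, no hydrophobic runs).
`generate_evidence()` then emulates the predictor panel: each of
`n_sources` (default 3) simulated SP predictors reports the
truth-consistent call independently with probability 1 − `noise` and a
contradictory item with probability `noise`; topology and signature
evidence is corrupted the same way. Default class counts
(58/88/133/9/84) follow the composition of a curated Gram-positive
benchmark set, keeping the weighted averages realistically unbalanced.

What passing tests on these fixtures shows: the engine's integration,
thresholds, overrides and consistency rules recover planted classes
perfectly at zero noise and degrade monotonically as evidence is
corrupted. What they do not show: performance on real proteomes —
residue composition is a crude categorical draw, signal-peptide
variability, real predictor error correlation and borderline motifs are
not modeled, and the starter signature catalog is a small representative
set, not the full curated lists.

## Numerical choices and degenerate inputs

* The MCC denominator is computed as a single square root of the
  four-factor product, which is exact for the degenerate perfect and
  reversed tables (the radicand is a perfect square) — the ±1 limits are
  attained exactly, not approximately.
* Undefined ratios (zero denominators) are `NA`, never 0.
* Hydropathy windows qualify at `mean ≥ threshold − 1e−9`: true window
  means are spaced ≈ 0.005 apart, so the tolerance only stabilizes
  windows sitting exactly on the threshold against summation order.
* Sequences shorter than the hydropathy window yield an empty scan with
  a warning; empty evidence plus a silent built-in scan resolves to
  `CYTO` via rule 6.
* Cleavage positions follow the "between residues *k* and *k*+1,
  reported as *k*" convention everywhere, including the SpII site in
  front of the lipidated cysteine.
* Evidence processing is order-canonicalized, so permuting input rows
  changes neither predictions nor rationale trails; all generators are
  seed-deterministic (byte-identical reruns).

## Design decisions that were genuinely open

* **CYTO as fallback only.** The engine never scores "cytoplasmicness"
  into a positive call; absence of export signals is the defining
  evidence. Compartment votes and GO terms still feed `score_cyto`,
  which rule 6 consults before declaring `Unknown`.
* **Hint-level categories.** Surface, pilin/fimbrilin and
  short-secreted-peptide signatures add to `score_extra` (one unit,
  below the threshold) instead of forcing a tag: these motifs suggest a
  destination without determining it. Secretion and Tat categories feed
  `score_extra` with an overriding flag; lipoprotein feeds `lipo`;
  the three cell-wall subcategories feed `cw`.
* **TM/EXTRA arbitration by helix count** (rule 5): one observed helix
  alongside concordant export evidence is read as the signal anchor, two
  or more as genuine membrane integration.
* **Catalog as configuration.** The shipped accession lists are a
  representative starter set in editable plain text; growing them does
  not touch the engine, and an accession may appear in at most one
  cell-wall subcategory so that the wall-interaction call stays
  unambiguous.

## Problem sizes

The test suite exercises the full benchmark-shaped proteome (372
proteins) at four noise levels over five seeds, 1,000-table
metric-formula cross-checks against Pearson-correlation oracles, and
10,000-protein random-prediction simulations; the acceptance script uses
100 replicates of 10,000 proteins for the random-MCC limit. These sizes
give Monte-Carlo standard errors well below the asserted tolerances
(±0.02 on a quantity whose per-replicate standard deviation is ≈ 0.01).

## Known limitations

* No Actinobacterial outer-membrane class; such proteins will surface
  as secreted.
* No probabilistic calibration: scores are evidence counts, not
  posterior probabilities.
* Built-in detectors are deliberately simple rules; real signal-peptide
  diversity (short SPs, atypical h-regions) will be missed without
  external predictor evidence.
* The Tat/FEA/FPE/bacteriocin routes are annotated at hint level only;
  the generator does not plant dedicated classes for them.
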