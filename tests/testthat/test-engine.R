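CATALOG <- load_catalog()

sp_sec_rows <- function(id, sources, cleave = 24L) {
  do.call(rbind, lapply(sources, function(src)
    evidence_table(id, src, c("SP_SEC", "CLEAVAGE_SITE"),
                   start = c(1L, cleave), end = c(cleave, cleave),
                   score = 0.9)))
}

test_that("accumulate tallies scores and flags under the default weights", {
  ev <- sp_sec_rows("p1", c("sp_predictor_a", "sp_predictor_b",
                            "predisi_like"))
  st <- accumulate(ev, CATALOG)
  expect_equal(st$scores[["extra"]], 3)
  expect_false(any(st$flags))
  expect_equal(st$cleavage, 24L)

  sig <- evidence_table("p1", "signature_scanner", "SIGNATURE_HIT", 1, 20,
                        10, catalog_accession("lipoprotein"))
  st2 <- accumulate(sig, CATALOG)
  expect_true(st2$flags[["flag_lipoprotein"]])
  expect_equal(st2$scores[["lipo"]], 1)

  tat <- evidence_table("p1", "tat_predictor", "SP_TAT", 1, 30)
  st3 <- accumulate(tat, CATALOG)
  expect_true(st3$flags[["flag_tat"]])
  expect_equal(st3$scores[["extra"]], 1)
})

test_that("duplicate kind from one source counts once; helices count per row", {
  dup <- rbind(evidence_table("p1", "sp_predictor_a", "SP_SEC", 1, 24),
               evidence_table("p1", "sp_predictor_a", "SP_SEC", 1, 22))
  expect_equal(accumulate(dup, CATALOG)$scores[["extra"]], 1)

  helices <- rbind(
    evidence_table("p1", "tm_predictor", "TM_HELIX", 50, 70),
    evidence_table("p1", "tm_predictor", "TM_HELIX", 100, 120))
  st <- accumulate(helices, CATALOG)
  expect_equal(st$scores[["tm"]], 2)
  expect_equal(st$n_tm, 2L)
})

test_that("accumulate is order-independent and single-protein only", {
  ev <- rbind(sp_sec_rows("p1", c("sp_predictor_a", "sp_predictor_b")),
              evidence_table("p1", "tm_predictor", "TM_HELIX", 60, 80),
              evidence_table("p1", "signature_scanner", "SIGNATURE_HIT",
                             1, 20, 5, catalog_accession("cw_covalent")),
              evidence_table("p1", "go_compartment", "GO_COMPARTMENT",
                             label = "GO:0005576"))
  base <- accumulate(ev, CATALOG)
  set.seed(3)
  for (i in 1:10) {
    perm <- ev[sample.int(nrow(ev)), ]
    expect_equal(accumulate(perm, CATALOG), base)
  }
  mixed <- rbind(ev, evidence_table("p2", "tm_predictor", "TM_HELIX",
                                    10, 30))
  expect_error(accumulate(mixed, CATALOG), "single protein")
})

test_that("a lone N-terminal helix co-located with an SP is discounted", {
  ev <- rbind(evidence_table("p1", "sp_predictor_a", "SP_SEC", 1, 24),
              evidence_table("p1", "tm_predictor", "TM_HELIX", 5, 23))
  expect_equal(accumulate(ev, CATALOG)$scores[["tm"]], 0)

  # two helices: the protein is genuinely membrane-integral, no discount
  ev2 <- rbind(ev, evidence_table("p1", "tm_predictor", "TM_HELIX",
                                  100, 120))
  expect_equal(accumulate(ev2, CATALOG)$scores[["tm"]], 2)

  # an internal lone helix is never discounted
  ev3 <- rbind(evidence_table("p1", "sp_predictor_a", "SP_SEC", 1, 24),
               evidence_table("p1", "tm_predictor", "TM_HELIX", 120, 140))
  expect_equal(accumulate(ev3, CATALOG)$scores[["tm"]], 1)
})

test_that("tags follow thresholds, and Boolean flags override scores", {
  th <- default_config()$thresholds
  zero <- accumulate(empty_evidence()[0, ], CATALOG)
  expect_equal(assign_tags(zero, th), character())

  three_sp <- accumulate(sp_sec_rows("p1", c("sp_predictor_a",
                                             "sp_predictor_b",
                                             "predisi_like")), CATALOG)
  expect_equal(assign_tags(three_sp, th), "EXTRA")

  # one source is below the EXTRA threshold...
  one_sp <- accumulate(sp_sec_rows("p1", "sp_predictor_a"), CATALOG)
  expect_equal(assign_tags(one_sp, th), character())

  # ...but an unequivocal secretion signature overrides the score:
  # score_extra = 1 stays below the threshold of 2, yet the flag fires
  with_flag <- accumulate(
    evidence_table("p1", "signature_scanner", "SIGNATURE_HIT", 1, 90, 30,
                   catalog_accession("secretion")), CATALOG)
  expect_equal(with_flag$scores[["extra"]], 1)
  expect_true(with_flag$flags[["flag_secretion_signature"]])
  expect_equal(assign_tags(with_flag, th), "EXTRA")
})

test_that("lipoprotein override dominance holds over random evidence", {
  set.seed(5)
  sources <- c("sp_predictor_a", "sp_predictor_b", "tm_predictor")
  kinds <- list(sp_predictor_a = "SP_SEC", sp_predictor_b = "SP_LIPO",
                tm_predictor = "TM_HELIX")
  for (i in 1:20) {
    n <- sample(0:4, 1)
    ev <- empty_evidence()
    for (j in seq_len(n)) {
      src <- sample(sources, 1)
      ev <- rbind(ev, evidence_table("p1", src, kinds[[src]],
                                     start = 1, end = 25))
    }
    ev <- rbind(ev, evidence_table("p1", "signature_scanner",
                                   "SIGNATURE_HIT", 1, 20, 10,
                                   catalog_accession("lipoprotein")))
    tags <- assign_tags(accumulate(ev, CATALOG))
    expect_true("LIPO" %in% tags)
  }
})

test_that("the consistency table rewrites tag sets as documented", {
  expect_equal(resolve_tags(c("EXTRA", "CW")), "CW")
  expect_equal(resolve_tags(c("EXTRA", "LIPO")), "LIPO")
  expect_equal(resolve_tags(c("EXTRA", "CYTO")), "Unknown")
  expect_equal(resolve_tags("CYTO"), "CYTO")
  expect_equal(resolve_tags(c("CW", "TM")), c("CW", "TM"))

  # TM vs EXTRA arbitration uses the helix observation count
  one_tm <- accumulate(rbind(
    sp_sec_rows("p1", c("sp_predictor_a", "sp_predictor_b")),
    evidence_table("p1", "tm_predictor", "TM_HELIX", 100, 120)), CATALOG)
  expect_equal(resolve_tags(c("TM", "EXTRA"), one_tm), "EXTRA")
  two_tm <- accumulate(rbind(
    sp_sec_rows("p1", c("sp_predictor_a", "sp_predictor_b")),
    evidence_table("p1", "tm_predictor", "TM_HELIX", 100, 120),
    evidence_table("p1", "tm_predictor", "TM_HELIX", 150, 170)), CATALOG)
  expect_equal(resolve_tags(c("TM", "EXTRA"), two_tm), "TM")
})

test_that("empty tag sets fall back to CYTO only when nothing fired", {
  # no evidence at all -> CYTO
  expect_equal(resolve_tags(character()), "CYTO")
  # sub-threshold signal evidence -> Unknown, not CYTO
  one_sp <- accumulate(sp_sec_rows("p1", "sp_predictor_a"), CATALOG)
  expect_equal(resolve_tags(character(), one_sp), "Unknown")
  # cytoplasmic votes without signals -> CYTO
  votes <- accumulate(evidence_table("p1", "generic_scl_predictor",
                                     "SCL_VOTE", label = "CYTO"), CATALOG)
  expect_equal(resolve_tags(character(), votes), "CYTO")
})

test_that("resolution is idempotent over every tag subset", {
  classes <- c("CW", "CYTO", "EXTRA", "LIPO", "TM")
  states <- list(
    accumulate(empty_evidence()[0, ], CATALOG),
    accumulate(sp_sec_rows("p1", "sp_predictor_a"), CATALOG),
    accumulate(rbind(sp_sec_rows("p1", "sp_predictor_a"),
                     evidence_table("p1", "tm_predictor", "TM_HELIX",
                                    60, 80),
                     evidence_table("p1", "tm_predictor", "TM_HELIX",
                                    100, 120)), CATALOG))
  for (state in states) {
    for (mask in 0:31) {
      tags <- classes[as.logical(bitwAnd(mask, 2^(0:4)))]
      once <- resolve_tags(tags, state)
      expect_equal(resolve_tags(once, state), once)
      # Unknown is exclusive in every output
      if ("Unknown" %in% once) expect_length(once, 1L)
    }
  }
})

test_that("secondary annotation reports pathway, cleavage and wall type", {
  cw <- accumulate(rbind(
    sp_sec_rows("p1", c("sp_predictor_a", "sp_predictor_b")),
    evidence_table("p1", "signature_scanner", "SIGNATURE_HIT", 180, 215,
                   50, catalog_accession("cw_covalent"))), CATALOG)
  ann <- annotate_secondary("CW", cw, CATALOG)
  expect_equal(ann$wall_interaction, "covalent")
  expect_equal(ann$pathway, "Sec")
  expect_equal(ann$cleavage_site, 24L)

  tat <- accumulate(rbind(sp_sec_rows("p1", c("sp_predictor_a",
                                              "sp_predictor_b")),
                          evidence_table("p1", "tat_predictor", "SP_TAT",
                                         1, 30)), CATALOG)
  expect_equal(annotate_secondary("EXTRA", tat, CATALOG)$pathway, "Tat")

  # pathway hints survive an Unknown call
  pilin <- accumulate(evidence_table("p1", "signature_scanner",
                                     "SIGNATURE_HIT", 1, 30, 12,
                                     catalog_accession("pilin_fimbrilin")),
                      CATALOG)
  expect_equal(annotate_secondary("Unknown", pilin, CATALOG)$pathway,
               "FPE-like")

  # wall interaction is only reported alongside a CW tag
  expect_equal(annotate_secondary("Unknown", cw, CATALOG)$wall_interaction,
               "none")

  # a secretion-category signature resolves its pathway via the catalog
  wss <- accumulate(evidence_table("p1", "signature_scanner",
                                   "SIGNATURE_HIT", 5, 95, 33,
                                   "IPR010310"), CATALOG)
  expect_equal(annotate_secondary("EXTRA", wss, CATALOG)$pathway,
               "Wss/T7SSb-like")
})

test_that("predict_scl mirrors the secreted/truncated (WYSIWYG) contrast", {
  mature <- polar_seq(150)
  recs <- new_sequences(c("full", "trunc"), "",
                        c(paste0(SEC_SP, mature), paste0("M", mature)))
  pred <- predict_scl(recs)
  expect_equal(pred$predicted_tags, c("EXTRA", "CYTO"))
  expect_equal(pred$pathway, c("Sec", "none"))
  expect_equal(pred$cleavage_site[1], 18L)
})

test_that("predict_scl: supplied evidence from two sources yields EXTRA/Sec", {
  recs <- one_rec("q1", secreted_seq())
  ev <- sp_sec_rows("q1", c("sp_predictor_a", "sp_predictor_b"),
                    cleave = 18L)
  pred <- predict_scl(recs, ev)
  expect_equal(pred$predicted_tags, "EXTRA")
  expect_equal(pred$pathway, "Sec")
})

test_that("predict_scl validates ids and is order-independent", {
  recs <- one_rec("q1", secreted_seq())
  bad <- sp_sec_rows("ghost", "sp_predictor_a")
  expect_error(predict_scl(recs, bad), "unknown protein.*ghost")

  spec <- fixture_spec(c(CW = 4, CYTO = 4, EXTRA = 4, LIPO = 2, TM = 4),
                       noise = 0.3, seed = 9)
  prot <- generate_proteome(spec)
  ev <- generate_evidence(prot$records, prot$truth, spec)
  base <- predict_scl(prot$records, ev)
  set.seed(1)
  for (i in 1:5) {
    perm <- ev[sample.int(nrow(ev)), ]
    again <- predict_scl(prot$records, perm)
    expect_equal(as.data.frame(again), as.data.frame(base))
  }
  # Unknown exclusivity on real outputs
  for (tags in strsplit(base$predicted_tags, ";")) {
    if ("Unknown" %in% tags) expect_length(tags, 1L)
  }
})

test_that("extra concordant SP evidence never flips EXTRA to CYTO", {
  set.seed(13)
  recs <- one_rec("q1", secreted_seq())
  for (i in 1:15) {
    n <- sample(1:3, 1)
    srcs <- sample(c("sp_predictor_a", "sp_predictor_b", "predisi_like"),
                   n)
    ev <- sp_sec_rows("q1", srcs, cleave = 18L)
    if (runif(1) < 0.5) {
      ev <- rbind(ev, evidence_table("q1", "tm_predictor", "TM_HELIX",
                                     60, 80))
    }
    before <- predict_scl(recs, ev)$predicted_tags
    extra_src <- setdiff(c("sp_predictor_a", "sp_predictor_b",
                           "predisi_like", "phobius_like"), srcs)[1]
    after <- predict_scl(recs, rbind(
      ev, sp_sec_rows("q1", extra_src, cleave = 18L)))$predicted_tags
    if (grepl("EXTRA", before)) expect_false(identical(after, "CYTO"))
  }
})
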