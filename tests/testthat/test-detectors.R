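HYDRO_SET <- c("A", "F", "I", "L", "M", "V", "W")

test_that("lipobox scan follows the stated positional rule", {
  # M + K + 16xL + LAGC + 20xA: C at 22, hydrophobic context -> one hit
  ev <- scan_lipobox(one_rec("l1", paste0("MK", strrep("L", 16), "LAGC",
                                          strrep("A", 20))))
  expect_equal(ev$kind, c("SP_LIPO", "CLEAVAGE_SITE"))
  expect_equal(ev$start, c(1L, 21L))  # cleavage in front of the cysteine
  expect_equal(ev$end, c(21L, 21L))

  # no cysteine -> no hit
  expect_equal(nrow(scan_lipobox(one_rec("l2", strrep("A", 60)))), 0L)

  # lipobox far from the N terminus is outside the position window
  far <- paste0("M", polar_seq(290), strrep("L", 10), "LAGC",
                polar_seq(95))
  expect_equal(nrow(scan_lipobox(one_rec("l3", far))), 0L)
})

test_that("twin-arginine scan needs RR, consensus support and hydrophobics", {
  hit <- scan_twin_arginine(one_rec("t1", paste0("MSRRQFLK",
                                                 strrep("L", 10),
                                                 polar_seq(60))))
  expect_equal(hit$kind, "SP_TAT")
  expect_equal(hit$start, 1L)

  # no RR dipeptide anywhere
  expect_equal(nrow(scan_twin_arginine(one_rec("t2", paste0(
    "MSTQ", strrep("LS", 30))))), 0L)

  # RR far downstream is outside the N-terminal window
  late_rr <- paste0("M", polar_seq(199) |> gsub("R", "K", x = _),
                    "SRRQFLK", strrep("L", 10), polar_seq(30))
  expect_equal(nrow(scan_twin_arginine(one_rec("t3", late_rr))), 0L)

  # RR present but without flanking consensus or hydrophobic stretch
  expect_equal(nrow(scan_twin_arginine(one_rec("t4", paste0(
    "MGRRGGGG", strrep("S", 60))))), 0L)
})

test_that("LPXTG scan demands the C-terminal anchor architecture", {
  ev <- scan_lpxtg(one_rec("c1", cw_covalent_seq()))
  expect_equal(ev$kind, "SIGNATURE_HIT")
  expect_equal(ev$label, "CW_COVALENT_MOTIF")
  expect_equal(substr(cw_covalent_seq(), ev$start, ev$end), "LPKTG")

  # motif far from the C terminus
  early <- paste0(polar_seq(9), "LPKTG", polar_seq(286))
  expect_equal(nrow(scan_lpxtg(one_rec("c2", early))), 0L)

  # no proline at all
  expect_equal(nrow(scan_lpxtg(one_rec("c3", paste0(
    "M", strrep("LKTGA", 40))))), 0L)

  # anchor without the positively charged tail
  no_tail <- paste0(SEC_SP, polar_seq(100), "LPKTG", strrep("L", 18),
                    "QQQQ")
  expect_equal(nrow(scan_lpxtg(one_rec("c4", no_tail))), 0L)
})

test_that("hydropathy scan finds helices and respects the window", {
  # 19xL flanked by polar residues -> exactly one helix
  ev <- scan_tm_hydropathy(one_rec("m1", paste0(polar_seq(25),
                                                strrep("L", 19),
                                                polar_seq(25))))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "TM_HELIX")

  # poly-D/E never crosses the threshold
  expect_equal(nrow(scan_tm_hydropathy(one_rec("m2", strrep("DE", 40)))),
               0L)

  # two hydrophobic blocks separated by a long polar linker -> 2 helices
  two <- paste0(polar_seq(20), strrep("L", 19), strrep("S", 30),
                strrep("L", 19), polar_seq(20))
  expect_equal(nrow(scan_tm_hydropathy(one_rec("m3", two))), 2L)

  # shorter than the window: empty result with a warning
  expect_warning(short <- scan_tm_hydropathy(one_rec("m4", "MKKL")),
                 "shorter than")
  expect_equal(nrow(short), 0L)

  # helices overlapping a supplied SP span get the overlap label
  sp_over <- scan_tm_hydropathy(
    one_rec("m5", paste0("MKK", strrep("L", 19), polar_seq(60))),
    sp_spans = data.frame(start = 1L, end = 22L))
  expect_equal(sp_over$label, "possible_sp_overlap")
})

test_that("Sec SP scan requires the full n/h/c architecture", {
  ev <- scan_sec_sp(one_rec("s1", secreted_seq()))
  expect_equal(ev$kind, c("SP_SEC", "CLEAVAGE_SITE"))
  expect_equal(ev$end, c(18L, 18L))  # cleavage after the A-Q-A site

  # acidic N terminus: no positive n-region
  expect_equal(nrow(scan_sec_sp(one_rec("s2", paste0(
    "MDDEE", strrep("L", 10), "AQA", polar_seq(60))))), 0L)

  # the same mature domain without its SP is not called (truncation)
  expect_equal(nrow(scan_sec_sp(one_rec("s3", paste0(
    "M", polar_seq(150))))), 0L)
})

# Brute-force re-implementations of the stated rules, used as oracles.

brute_lipobox <- function(seq, c_min = 15, c_max = 40, min_h = 6) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- integer()
  for (s in seq_len(max(0, n - 3))) {
    if (!ch[s] %in% c("L", "V", "I")) next
    if (!ch[s + 1] %in% c("A", "S", "T", "V", "I")) next
    if (!ch[s + 2] %in% c("G", "A", "S")) next
    if (ch[s + 3] != "C") next
    cpos <- s + 3
    if (cpos < c_min || cpos > c_max) next
    win <- ch[max(1, s - 10):(s - 1)]
    if (sum(win %in% HYDRO_SET) < min_h) next
    hits <- c(hits, cpos - 1L)
  }
  hits
}

brute_tm <- function(seq, window = 19, threshold = 1.6) {
  ch <- strsplit(seq, "")[[1]]
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0)
  n <- length(ch)
  if (n < window) return(data.frame(start = integer(), end = integer()))
  qual <- vapply(seq_len(n - window + 1),
                 function(s) mean(kd[ch[s:(s + window - 1)]]) >=
                   threshold - 1e-9,
                 logical(1))
  starts <- which(qual)
  if (!length(starts)) return(data.frame(start = integer(),
                                         end = integer()))
  ivals <- cbind(starts, starts + window - 1L)
  merged <- list(ivals[1, ])
  for (i in seq_len(nrow(ivals))[-1]) {
    last <- merged[[length(merged)]]
    if (ivals[i, 1] <= last[2]) {
      merged[[length(merged)]] <- c(last[1], max(last[2], ivals[i, 2]))
    } else {
      merged[[length(merged) + 1]] <- ivals[i, ]
    }
  }
  data.frame(start = vapply(merged, function(m) as.integer(m[1]),
                            integer(1)),
             end = vapply(merged, function(m) as.integer(m[2]),
                          integer(1)))
}

test_that("detectors agree with naive brute-force oracles on random input", {
  set.seed(11)
  pool <- c(rep(c("L", "I", "V", "F", "A"), 3), "C", "C",
            c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "H", "Y",
              "P", "M", "W"))
  for (i in 1:50) {
    seq <- paste(sample(pool, sample(60:200, 1), replace = TRUE),
                 collapse = "")
    rec <- one_rec(sprintf("r%02d", i), seq)

    got <- scan_lipobox(rec)
    expect_equal(got$start[got$kind == "CLEAVAGE_SITE"],
                 brute_lipobox(seq))

    got_tm <- suppressWarnings(scan_tm_hydropathy(rec))
    oracle_tm <- brute_tm(seq)
    expect_equal(got_tm$start, oracle_tm$start)
    expect_equal(got_tm$end, oracle_tm$end)
  }
})

test_that("detectors are deterministic and position-faithful", {
  rec <- one_rec("d1", cw_covalent_seq())
  a <- scan_builtin(rec)
  b <- scan_builtin(rec)
  expect_identical(a, b)
  # reported substrings re-match their rule
  lp <- a[a$kind == "SIGNATURE_HIT", ]
  expect_match(substr(rec$seq, lp$start, lp$end), "^LP[A-Z]TG$")
})
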