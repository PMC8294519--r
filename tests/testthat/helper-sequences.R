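# Deterministic sequence constructions used across tests.  The signal
# peptide follows the n/h/c architecture the Sec scan detects (cleavage
# after position 18 of "MKKLLLLLLLLLAVAAQA"); mature regions use polar
# residues that cannot fire any detector by accident.

SEC_SP <- "MKKLLLLLLLLLAVAAQA"

polar_seq <- function(n) {
  strrep("SGNQDETKYH", ceiling(n / 10)) |> substr(1, n)
}

secreted_seq <- function(mature_len = 150) {
  paste0(SEC_SP, polar_seq(mature_len))
}

lipo_seq <- function(mature_len = 150) {
  paste0("MK", strrep("L", 16), "LAGC", polar_seq(mature_len))
}

tm_seq <- function(n_helix = 1) {
  parts <- paste0("M", polar_seq(40))
  for (j in seq_len(n_helix)) {
    parts <- paste0(parts, strrep("L", 21), polar_seq(35))
  }
  parts
}

cw_covalent_seq <- function() {
  paste0(SEC_SP, polar_seq(100), "LPKTG", strrep("L", 18), "KKRK")
}

one_rec <- function(id, seq) new_sequences(id, "", seq)

# A private editable copy of the shipped starter catalog.
local_catalog_dir <- function(env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  file.copy(list.files(default_catalog_dir(), full.names = TRUE), dir)
  dir
}

# First accession of a category in the shipped catalog.
catalog_accession <- function(category) {
  cat <- load_catalog()
  setdiff(cat$categories[[category]], "CW_COVALENT_MOTIF")[1]
}
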