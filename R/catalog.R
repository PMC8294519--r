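## Signature catalog: curated accession lists per sorting-signal category
## plus a GO cellular_component -> tag mapping.  The catalog is
## configuration, not code: the shipped starter set under
## inst/extdata/catalog/ is a small, representative selection and is meant
## to be extended by editing the plain-text files.

CATALOG_GO_FILE <- "go_terms.tsv"
CATALOG_PATHWAY_FILE <- "pathways.tsv"

#' Load a signature catalog directory
#'
#' The directory must contain one accession list per category
#' (`secretion.txt`, `tat.txt`, `lipoprotein.txt`, `cw_covalent.txt`,
#' `cw_noncovalent.txt`, `cw_spore.txt`, `surface.txt`,
#' `pilin_fimbrilin.txt`, `short_secreted_peptide.txt`; one accession per
#' line, `#` comments) and a `go_terms.tsv` mapping (columns `go_id`,
#' `tag`). An optional `pathways.tsv` (columns `accession`, `pathway`)
#' maps secretion-category accessions to an alternative-pathway label
#' (`SecA2-like`, `Wss/T7SSb-like`, `FEA-like`). Unknown extra files are
#' ignored with a warning. An accession may appear in at most one `cw_*`
#' subcategory.
#'
#' @param dir Catalog directory; defaults to the shipped starter catalog.
#' @return A list of class `scl_catalog` with elements `categories`
#'   (named list of accession vectors), `go` (named character, GO id ->
#'   tag) and `pathways` (named character, accession -> pathway label).
#' @export
load_catalog <- function(dir = default_catalog_dir()) {
  if (!dir.exists(dir)) input_error("catalog directory not found: ", dir)
  expected <- c(paste0(CATALOG_CATEGORIES, ".txt"), CATALOG_GO_FILE,
                CATALOG_PATHWAY_FILE)
  present <- list.files(dir)
  extra <- setdiff(present, expected)
  if (length(extra)) {
    warning("ignoring unknown catalog file(s): ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  categories <- lapply(CATALOG_CATEGORIES, function(cat) {
    f <- file.path(dir, paste0(cat, ".txt"))
    if (!file.exists(f)) {
      input_error("catalog is missing category file: ", basename(f))
    }
    read_accession_list(f)
  })
  names(categories) <- CATALOG_CATEGORIES
  cw <- unlist(categories[c("cw_covalent", "cw_noncovalent", "cw_spore")])
  if (anyDuplicated(cw)) {
    input_error("accession listed in more than one cw_* subcategory: ",
                cw[duplicated(cw)][1L])
  }
  go_path <- file.path(dir, CATALOG_GO_FILE)
  if (!file.exists(go_path)) {
    input_error("catalog is missing GO mapping file: ", CATALOG_GO_FILE)
  }
  go_df <- read.delim(go_path, header = TRUE, sep = "\t",
                      colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("go_id", "tag") %in% names(go_df))) {
    input_error(go_path, ": expected columns go_id, tag")
  }
  bad <- which(!go_df$tag %in% SCL_CLASSES)
  if (length(bad)) {
    input_error(go_path, ", row ", bad[1L], ": '", go_df$tag[bad[1L]],
                "' is not a valid localization tag")
  }
  go <- setNames(go_df$tag, go_df$go_id)
  pathways <- character()
  pw_path <- file.path(dir, CATALOG_PATHWAY_FILE)
  if (file.exists(pw_path)) {
    pw_df <- read.delim(pw_path, header = TRUE, sep = "\t",
                        colClasses = "character", stringsAsFactors = FALSE)
    if (!all(c("accession", "pathway") %in% names(pw_df))) {
      input_error(pw_path, ": expected columns accession, pathway")
    }
    allowed <- c("SecA2-like", "Wss/T7SSb-like", "FEA-like", "FPE-like",
                 "bacteriocin-like")
    badp <- which(!pw_df$pathway %in% allowed)
    if (length(badp)) {
      input_error(pw_path, ", row ", badp[1L], ": pathway must be one of ",
                  paste(allowed, collapse = ", "))
    }
    pathways <- setNames(pw_df$pathway, pw_df$accession)
  }
  structure(list(categories = categories, go = go, pathways = pathways),
            class = "scl_catalog")
}

read_accession_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' Default (shipped) catalog directory
#' @return Path to the starter catalog installed with the package.
#' @export
default_catalog_dir <- function() {
  system.file("extdata", "catalog", package = "sortloc", mustWork = TRUE)
}

#' Look up the category of a signature accession
#'
#' @param accession Signature accession string (vectorized).
#' @param catalog An `scl_catalog` from [load_catalog()].
#' @return Category name per accession, or `NA` when listed nowhere.
#' @export
classify_hit <- function(accession, catalog) {
  stopifnot(inherits(catalog, "scl_catalog"))
  vapply(as.character(accession), function(a) {
    for (cat in names(catalog$categories)) {
      if (a %in% catalog$categories[[cat]]) return(cat)
    }
    NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

#' Map a GO cellular_component term to a localization tag hint
#'
#' Only terms present in the catalog's compartment mapping return a hint;
#' anything else returns `NA`.
#'
#' @param go_id GO term id (vectorized), e.g. `"GO:0005576"`.
#' @param catalog An `scl_catalog`.
#' @return Tag hint per id, or `NA`.
#' @export
go_to_tag <- function(go_id, catalog) {
  stopifnot(inherits(catalog, "scl_catalog"))
  out <- unname(catalog$go[as.character(go_id)])
  as.character(out)
}

#' @export
print.scl_catalog <- function(x, ...) {
  cat("Signature catalog\n")
  for (cat in names(x$categories)) {
    cat(sprintf("  %-24s %d accession(s)\n", cat,
                length(x$categories[[cat]])))
  }
  cat(sprintf("  %-24s %d term(s)\n", "GO compartments", length(x$go)))
  if (length(x$pathways)) {
    cat(sprintf("  %-24s %d accession(s)\n", "pathway subtypes",
                length(x$pathways)))
  }
  invisible(x)
}
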