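## Print and summary methods for the package's table classes.

#' @export
print.scl_sequences <- function(x, ...) {
  cat(sprintf("%d amino-acid sequence(s), length %d-%d\n", nrow(x),
              if (nrow(x)) min(nchar(x$seq)) else 0L,
              if (nrow(x)) max(nchar(x$seq)) else 0L))
  show <- utils::head(x, 6L)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("  %-16s %5d aa  %s...\n", show$id[i],
                nchar(show$seq[i]), substr(show$seq[i], 1L, 30L)))
  }
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
print.scl_predictions <- function(x, n = 10L, ...) {
  cat(sprintf("Localization predictions for %d protein(s)\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)[
    , c("protein_id", "predicted_tags", "pathway", "cleavage_site",
        "wall_interaction")], n), row.names = FALSE)
  if (nrow(x) > n) cat("  ... (", nrow(x) - n, " more)\n", sep = "")
  invisible(x)
}

#' @method summary scl_predictions
#' @export
summary.scl_predictions <- function(object, ...) {
  tab <- table(object$predicted_tags, useNA = "ifany")
  cat("Predicted tag sets:\n")
  for (nm in names(tab)) {
    cat(sprintf("  %-16s %d\n", nm, tab[[nm]]))
  }
  invisible(tab)
}

#' @export
print.scl_metrics <- function(x, digits = 3L, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) round(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.evidence_state <- function(x, ...) {
  cat("Evidence state", if (!is.na(x$protein_id))
    paste0("for ", x$protein_id) else "", "\n")
  cat("  scores:",
      paste(sprintf("%s=%g", names(x$scores), x$scores), collapse = " "),
      "\n")
  on <- names(x$flags)[x$flags]
  cat("  flags set:", if (length(on)) paste(on, collapse = ", ") else
    "none", "\n")
  invisible(x)
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("Synthetic proteome spec:",
      paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class),
            collapse = " "), "\n")
  cat(sprintf("  noise=%g, n_sources=%d, seed=%d\n", x$noise,
              x$n_sources, x$seed))
  invisible(x)
}
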