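# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Normalize a MedDRA preferred-term string
#'
#' Trims surrounding whitespace, collapses internal runs of whitespace, and
#' sentence-cases the term (first letter upper, rest lower), the convention
#' MedDRA itself uses ("Gastric ulcer").  Reaction capitalization in raw
#' spontaneous-report extracts varies; all PT comparisons in this package go
#' through this normalization.
#'
#' @param x character vector of preferred terms.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_pt(c("  gastric ULCER ", "DRUG  HYPERSENSITIVITY"))
normalize_pt <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  out <- tolower(x)
  substr(out, 1L, 1L) <- toupper(substr(out, 1L, 1L))
  out[is.na(x)] <- NA_character_
  out
}

#' Normalize a drug-name string
#'
#' Lowercases, trims surrounding whitespace and punctuation, and collapses
#' internal whitespace, so that "PIROXICAM." matches a dictionary entry
#' "piroxicam".
#'
#' @param x character vector of drug names.
#' @return character vector of the same length.
#' @export
normalize_drug <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", x)
  gsub("\\s+", " ", x)
}

# Write a data.frame as a tab-separated table (no quoting, no row names):
# the output dialect used for every table the pipeline emits.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# stop() with a consistent "fun: message" prefix and no call
fail <- function(fun, msg) stop(sprintf("%s: %s", fun, msg), call. = FALSE)

# Validate a probability-like scalar field, naming the offending field.
check_prob <- function(value, field, fun) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1)
    fail(fun, sprintf("`%s` must be a single number in [0,1]", field))
  invisible(value)
}
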