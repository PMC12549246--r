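# Ingestion of FAERS-dialect quarterly ASCII tables and FDA-rule
# deduplication of multi-version case reports.

# Column layout of the supported dialect, one entry per table kind.
faers_columns <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country", "occr_country"),
  DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "prod_ai"),
  REAC = c("primaryid", "caseid", "pt"),
  THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
  OUTC = c("primaryid", "caseid", "outc_cod")
)

#' Read one FAERS-dialect ASCII table
#'
#' Parses a '$'-delimited quarterly table with a single header line.  Every
#' field is kept verbatim as a character string; the empty string denotes a
#' missing value.  The header must carry exactly the column set of the
#' requested table kind (order as in the file).
#'
#' @param path path to the table file.
#' @param table_kind one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"THER"`, `"OUTC"`.
#' @return a data.frame of character columns, one row per data line.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("primaryid$caseid$pt", "1001$100$Gastric ulcer"), f)
#' read_faers_table(f, "REAC")
read_faers_table <- function(path, table_kind) {
  table_kind <- toupper(table_kind)
  if (!table_kind %in% names(faers_columns))
    fail("read_faers_table", sprintf("unknown table_kind '%s'", table_kind))
  if (!file.exists(path))
    fail("read_faers_table", sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 1L)
    fail("read_faers_table", sprintf("empty file: %s", path))
  header <- strsplit(lines[[1L]], "$", fixed = TRUE)[[1L]]
  expected <- faers_columns[[table_kind]]
  if (!setequal(tolower(header), expected))
    fail("read_faers_table",
         sprintf("header of %s does not match the %s dialect", path,
                 table_kind))
  body <- lines[-1L]
  n_col <- length(header)
  if (length(body) == 0L) {
    out <- as.data.frame(matrix(character(0), ncol = n_col),
                         stringsAsFactors = FALSE)
    names(out) <- tolower(header)
    return(out)
  }
  # split preserving trailing empty fields (a row ending in '$' has a
  # present-but-missing final field)
  parts <- strsplit(paste0(body, "\x01"), "$", fixed = TRUE)
  lens <- lengths(parts)
  bad <- which(lens != n_col)
  if (length(bad))
    fail("read_faers_table",
         sprintf("malformed line %d in %s: %d fields, expected %d",
                 bad[[1L]] + 1L, path, lens[[bad[[1L]]]], n_col))
  flat <- unlist(parts, use.names = FALSE)
  flat <- sub("\x01$", "", flat)
  out <- as.data.frame(matrix(flat, ncol = n_col, byrow = TRUE),
                       stringsAsFactors = FALSE)
  names(out) <- tolower(header)
  out
}

#' Read all FAERS-dialect tables in a directory
#'
#' Globs per-quarter files named `<TABLE><YY>Q<N>.txt` (any number of
#' quarters) and row-binds each kind.
#'
#' @param dir directory holding the quarterly files.
#' @return an object of class `faers_raw`: a list with elements `demo`,
#'   `drug`, `reac`, `ther`, `outc` (character data.frames) and `files`.
#' @export
read_faers <- function(dir) {
  if (!dir.exists(dir)) fail("read_faers", sprintf("no such directory: %s", dir))
  out <- list()
  all_files <- character(0)
  for (kind in names(faers_columns)) {
    files <- sort(list.files(dir, sprintf("^%s.*\\.txt$", kind),
                             full.names = TRUE, ignore.case = TRUE))
    if (length(files) == 0L)
      fail("read_faers", sprintf("no %s table found in %s", kind, dir))
    tabs <- lapply(files, read_faers_table, table_kind = kind)
    out[[tolower(kind)]] <- do.call(rbind, tabs)
    all_files <- c(all_files, files)
  }
  out$files <- all_files
  class(out) <- "faers_raw"
  out
}

#' Parse a FAERS date string
#'
#' Only complete, calendar-valid 8-digit `YYYYMMDD` strings parse; anything
#' else — empty, 4- or 6-digit partial dates, or an impossible day such as
#' `20040230` — yields `NA`.  Partial dates are deliberately excluded rather
#' than imputed, so downstream onset intervals only ever use exact dates.
#' Never throws: missing is a value here, not an error.
#'
#' @param x character vector of raw date fields.
#' @return a `Date` vector with `NA` for unparseable entries.
#' @export
#' @examples
#' parse_faers_date(c("20040115", "200401", "20040230", ""))
parse_faers_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^[0-9]{8}$", x)
  if (any(ok)) out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

# Conversion factors from FAERS age unit codes to years.
age_unit_factors <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                      DY = 1 / 365.25, HR = 1 / 8766)

#' Convert a raw age field to years
#'
#' Applies the FAERS age-unit codes: `YR` x1, `DEC` x10, `MON` /12,
#' `WK` /52.18, `DY` /365.25, `HR` /8766.  Non-numeric values, unknown unit
#' codes and negative ages give `NA`; never throws.
#'
#' @param value character or numeric vector of age values.
#' @param unit_code character vector of unit codes (recycled if length 1).
#' @return numeric vector of ages in years (`NA` where not interpretable).
#' @export
#' @examples
#' normalize_age(c("6", "18", ""), c("DEC", "MON", "YR"))
normalize_age <- function(value, unit_code) {
  v <- suppressWarnings(as.numeric(as.character(value)))
  u <- toupper(trimws(as.character(unit_code)))
  if (length(u) == 1L) u <- rep(u, length(v))
  fac <- unname(age_unit_factors[u])
  out <- v * fac
  out[is.na(out) | out < 0] <- NA_real_
  out
}

# Total order used by deduplication: latest FDA receipt date wins, ties by
# largest PRIMARYID (numeric when it parses, else lexicographic among the
# non-numeric).  Missing FDA_DT sorts earliest (always loses).
dedup_rank <- function(fda_dt, primaryid) {
  d <- as.numeric(parse_faers_date(fda_dt))
  d[is.na(d)] <- -Inf
  pnum <- suppressWarnings(as.numeric(primaryid))
  pstr <- xtfrm(as.character(primaryid))
  list(date = d, pid_num = ifelse(is.na(pnum), -Inf, pnum), pid_str = pstr)
}

#' Deduplicate case reports by the FDA rule
#'
#' FAERS publishes one row per report *version*; a case (CASEID) may appear
#' many times.  Per CASEID this keeps the version with the most recent FDA
#' receipt date (FDA_DT), breaking ties by the largest PRIMARYID compared
#' numerically.  Child tables (DRUG/REAC/THER/OUTC) are filtered to the
#' retained PRIMARYIDs.  Reports with a missing CASEID cannot be grouped and
#' are retained as singletons; their count is recorded.
#'
#' @param raw a `faers_raw` object from [read_faers()], or a list with the
#'   same `demo`/`drug`/`reac`/`ther`/`outc` elements.
#' @return an object of class `faers_data`: the same five tables restricted
#'   to one version per case (rows ordered by caseid), with attributes
#'   `n_raw`, `n_removed`, `n_missing_caseid`.
#' @export
dedup_reports <- function(raw) {
  demo <- raw$demo
  n_raw <- nrow(demo)
  caseid <- as.character(demo$caseid)
  missing_case <- is.na(caseid) | caseid == ""
  # ungroupable reports form singleton groups keyed by their primaryid
  group <- ifelse(missing_case,
                  paste0("\x02orphan:", demo$primaryid), caseid)
  r <- dedup_rank(demo$fda_dt, demo$primaryid)
  o <- order(group, r$date, r$pid_num, r$pid_str)
  keep_idx <- o[!duplicated(group[o], fromLast = TRUE)]
  demo2 <- demo[sort(keep_idx), , drop = FALSE]
  demo2 <- demo2[order(demo2$caseid, demo2$primaryid), , drop = FALSE]
  rownames(demo2) <- NULL
  kept <- demo2$primaryid
  restrict <- function(tab) {
    out <- tab[tab$primaryid %in% kept, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  out <- list(demo = demo2, drug = restrict(raw$drug),
              reac = restrict(raw$reac), ther = restrict(raw$ther),
              outc = restrict(raw$outc))
  if (any(missing_case))
    message(sprintf("dedup_reports: %d report(s) with missing CASEID kept as singletons",
                    sum(missing_case)))
  structure(out, class = "faers_data",
            n_raw = n_raw, n_removed = n_raw - nrow(demo2),
            n_missing_caseid = sum(missing_case))
}

#' @export
print.faers_data <- function(x, ...) {
  cat("Deduplicated FAERS-style report set\n")
  cat(sprintf("  cases: %d (from %d raw report versions, %d duplicates removed)\n",
              nrow(x$demo), attr(x, "n_raw"), attr(x, "n_removed")))
  cat(sprintf("  drug rows: %d, reaction rows: %d, therapy rows: %d, outcome rows: %d\n",
              nrow(x$drug), nrow(x$reac), nrow(x$ther), nrow(x$outc)))
  invisible(x)
}
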