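# Target-drug cohort selection, PT -> SOC mapping, and the descriptive
# cohort summary.

#' Build a drug-synonym dictionary
#'
#' @param names character vector of drug names (generic plus brands); each is
#'   normalized with [normalize_drug()].
#' @return an object of class `drug_dictionary`.
#' @export
drug_dictionary <- function(names) {
  names <- unique(normalize_drug(names))
  names <- names[!is.na(names) & names != ""]
  if (length(names) == 0L)
    fail("drug_dictionary", "dictionary must contain at least one name")
  structure(list(synonyms = names), class = "drug_dictionary")
}

#' Read a drug-synonym dictionary from a delimited text file
#'
#' The first column of each line is taken as a synonym; a tab-separated
#' second column (e.g., the canonical name) is allowed and ignored.
#'
#' @param path path to the file.
#' @return a `drug_dictionary`.
#' @export
read_drug_dictionary <- function(path) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  drug_dictionary(vapply(strsplit(lines, "\t"), `[[`, character(1), 1L))
}

#' Build a PT to system-organ-class map
#'
#' MedDRA itself is licensed, so the mapping is supplied by the user as a
#' table of (preferred term, SOC name, SOC code).
#'
#' @param pt,soc_name character vectors; `soc_code` integer or character.
#' @return an object of class `meddra_map`.
#' @export
meddra_map <- function(pt, soc_name, soc_code = NA) {
  pt <- normalize_pt(pt)
  if (anyDuplicated(pt))
    fail("meddra_map", "duplicate PT entries after normalization")
  structure(list(pt = pt, soc_name = as.character(soc_name),
                 soc_code = as.character(soc_code)),
            class = "meddra_map")
}

#' Read a PT to SOC map from a tab-separated file
#'
#' Expects columns `pt`, `soc_name` and optionally `soc_code`, with a header
#' line.
#'
#' @param path path to the file.
#' @return a `meddra_map`.
#' @export
read_meddra_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("pt", "soc_name") %in% names(tab)))
    fail("read_meddra_map", "file must have columns pt, soc_name")
  meddra_map(tab$pt, tab$soc_name, tab$soc_code %||% NA)
}

#' Map preferred terms to system organ classes
#'
#' Lookup after the package's PT normalization.  Unmapped PTs return `NA`
#' and are collected on the result as attribute `unmapped`.
#'
#' @param pt character vector of preferred terms.
#' @param map a [meddra_map()].
#' @return data.frame with columns `pt`, `soc_name`, `soc_code`.
#' @export
map_pt_to_soc <- function(pt, map) {
  if (!inherits(map, "meddra_map"))
    fail("map_pt_to_soc", "`map` must be a meddra_map object")
  key <- normalize_pt(pt)
  i <- match(key, map$pt)
  out <- data.frame(pt = key, soc_name = map$soc_name[i],
                    soc_code = map$soc_code[i], stringsAsFactors = FALSE)
  unmapped <- sort(unique(key[is.na(i)]))
  if (length(unmapped))
    message(sprintf("map_pt_to_soc: %d PT(s) unmapped", length(unmapped)))
  attr(out, "unmapped") <- unmapped
  out
}

#' Select the primary-suspect cohort for a target drug
#'
#' Keeps the deduplicated reports that carry at least one drug row with role
#' code `PS` whose drug name or active ingredient matches the dictionary
#' (case-insensitive exact match after trimming and punctuation stripping).
#'
#' @param faers a `faers_data` object from [dedup_reports()].
#' @param dictionary a [drug_dictionary()].
#' @return a `faers_data` object restricted to the cohort, with attribute
#'   `cohort_caseids`.
#' @export
select_primary_suspect <- function(faers, dictionary) {
  if (!inherits(dictionary, "drug_dictionary"))
    fail("select_primary_suspect", "`dictionary` must be a drug_dictionary")
  d <- faers$drug
  hit <- d$role_cod == "PS" &
    (normalize_drug(d$drugname) %in% dictionary$synonyms |
       normalize_drug(d$prod_ai) %in% dictionary$synonyms)
  keep_pid <- unique(d$primaryid[hit])
  out <- lapply(faers[c("demo", "drug", "reac", "ther", "outc")],
                function(tab) {
                  r <- tab[tab$primaryid %in% keep_pid, , drop = FALSE]
                  rownames(r) <- NULL
                  r
                })
  structure(out, class = "faers_data",
            n_raw = attr(faers, "n_raw"),
            n_removed = attr(faers, "n_removed"),
            cohort_caseids = sort(unique(out$demo$caseid)))
}

age_band_of <- function(age_years) {
  # left-closed / right-open bands on age as a real number: 64.99 is 45-64,
  # 65.0 is >=65
  cut(age_years, breaks = c(0, 18, 45, 65, Inf), right = FALSE,
      labels = c("<18", "18-44", "45-64", ">=65"))
}

outcome_labels <- c(DE = "Death", LT = "Life-threatening",
                    HO = "Hospitalization - initial or prolonged",
                    DS = "Disability", OT = "Other serious",
                    CA = "Other serious", RI = "Other serious")

occp_labels <- c(MD = "Physician", PH = "Pharmacist", CN = "Consumer",
                 OT = "Other health-professional", LW = "Lawyer",
                 HP = "Other health-professional")

count_block <- function(values, total) {
  tab <- table(values, useNA = "no")
  data.frame(category = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / total, 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Descriptive summary of a report cohort
#'
#' Tabulates counts and percentages by sex, age band (<18, 18-44, 45-64,
#' >=65, plus "Not specified"), reporter type, reporting country (top `k`),
#' outcome category, and FDA receipt year.  Percentages are over the total
#' case count except for outcomes, where one case may carry several codes.
#'
#' @param cohort a `faers_data` object (typically from
#'   [select_primary_suspect()]).
#' @param top_countries how many countries to list.
#' @param country_field which DEMO field identifies the country
#'   (`"occr_country"` by default, or `"reporter_country"`).
#' @return an object of class `cohort_summary`: a named list of data.frames
#'   (`sex`, `age`, `reporter`, `country`, `outcome`, `year`) plus `n_cases`
#'   and `n_events`.
#' @export
summarize_cohort <- function(cohort, top_countries = 5,
                             country_field = c("occr_country",
                                               "reporter_country")) {
  country_field <- match.arg(country_field)
  demo <- cohort$demo
  n <- nrow(demo)
  if (n == 0L)
    return(structure(list(n_cases = 0L, n_events = 0L, empty = TRUE),
                     class = "cohort_summary"))
  sex <- c(F = "Female", M = "Male")[demo$sex]
  sex[is.na(sex)] <- "Not specified"
  age <- as.character(age_band_of(normalize_age(demo$age, demo$age_cod)))
  age[is.na(age)] <- "Not specified"
  rep_type <- occp_labels[demo$occp_cod]
  rep_type[is.na(rep_type)] <- "Not specified"
  country <- demo[[country_field]]
  country[is.na(country) | country == ""] <- "Not specified"
  year <- format(parse_faers_date(demo$fda_dt), "%Y")
  year[is.na(year)] <- "Not specified"

  ctab <- count_block(country, n)
  ctab <- ctab[order(-ctab$n), , drop = FALSE][seq_len(min(top_countries,
                                                           nrow(ctab))), ]
  rownames(ctab) <- NULL

  outc <- cohort$outc[cohort$outc$primaryid %in% demo$primaryid, ,
                      drop = FALSE]
  olab <- outcome_labels[outc$outc_cod]
  olab <- olab[!is.na(olab)]

  pairs <- unique(data.frame(caseid = cohort$reac$caseid,
                             pt = normalize_pt(cohort$reac$pt)))
  structure(list(sex = count_block(sex, n), age = count_block(age, n),
                 reporter = count_block(rep_type, n), country = ctab,
                 outcome = count_block(olab, n),
                 year = count_block(year, n),
                 n_cases = n, n_events = nrow(pairs), empty = FALSE),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Empty cohort\n")
    return(invisible(x))
  }
  cat(sprintf("Cohort of %d case reports, %d unique case-PT events\n",
              x$n_cases, x$n_events))
  for (blk in c("sex", "age", "reporter", "country", "outcome", "year")) {
    cat("\n--", blk, "--\n")
    print(x[[blk]], row.names = FALSE)
  }
  invisible(x)
}
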