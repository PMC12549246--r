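# Sex- and age-stratified signal re-estimation and outcome-severity
# tabulation.

stratum_levels <- list(sex = c("Female", "Male"),
                       age = c("<18", "18-44", "45-64", ">=65"))

stratum_value <- function(demo, axis) {
  if (axis == "sex") {
    v <- c(F = "Female", M = "Male")[demo$sex]
  } else {
    v <- as.character(age_band_of(normalize_age(demo$age, demo$age_cod)))
  }
  v
}

#' Comparator background for a cohort
#'
#' The deduplicated report set minus the cohort's cases: the "all other
#' drugs" rows of every 2x2 table.
#'
#' @param faers the full deduplicated `faers_data`.
#' @param cohort the `faers_data` cohort to exclude.
#' @return a `faers_data` object.
#' @export
background_reports <- function(faers, cohort) {
  restrict_cases(faers, setdiff(faers$demo$caseid, cohort$demo$caseid))
}

restrict_cases <- function(faers, caseids) {
  out <- lapply(faers[c("demo", "drug", "reac", "ther", "outc")],
                function(tab) {
                  r <- tab[tab$caseid %in% caseids, , drop = FALSE]
                  rownames(r) <- NULL
                  r
                })
  structure(out, class = "faers_data")
}

#' Split cohort and background into strata
#'
#' Both the target-drug cohort *and* the comparator background are
#' restricted to each stratum, so stratified 2x2 tables use a
#' within-stratum denominator.  Cases with an unknown stratum value are
#' excluded from every level and counted.
#'
#' @param cohort,background `faers_data` objects (disjoint case sets).
#' @param axis `"sex"` or `"age"`.
#' @return a list of class `strata`: per level, a list with `cohort` and
#'   `background`; plus attributes `axis`, `n_unknown_cohort`,
#'   `n_unknown_background`.
#' @export
stratify <- function(cohort, background, axis = c("sex", "age")) {
  axis <- match.arg(axis)
  vc <- stratum_value(cohort$demo, axis)
  vb <- stratum_value(background$demo, axis)
  levels <- stratum_levels[[axis]]
  out <- lapply(levels, function(lv) {
    list(cohort = restrict_cases(cohort,
                                 cohort$demo$caseid[!is.na(vc) & vc == lv]),
         background = restrict_cases(
           background, background$demo$caseid[!is.na(vb) & vb == lv]))
  })
  names(out) <- levels
  structure(out, class = "strata", axis = axis,
            n_unknown_cohort = sum(is.na(vc)),
            n_unknown_background = sum(is.na(vb)))
}

#' Disproportionality per stratum
#'
#' Delegates to [disproportionality()] within each stratum level, with the
#' within-stratum pair total as N and identical thresholds.  Empty strata
#' yield an empty table, not an error.
#'
#' @param strata a `strata` object from [stratify()].
#' @param level `"pt"` or `"soc"`.
#' @param soc_map a [meddra_map()] when `level = "soc"`.
#' @param min_count minimum case-count gate passed through.
#' @param prior optional shared `gps_prior`.
#' @return named list of `signal_table`s, one per stratum level.
#' @export
stratum_signals <- function(strata, level = "pt", soc_map = NULL,
                            min_count = 3, prior = NULL) {
  lapply(strata, function(s) {
    cp <- event_pairs(s$cohort, level, soc_map)
    bp <- event_pairs(s$background, level, soc_map)
    if (nrow(cp) == 0L) {
      empty <- data.frame(term = character(0), a = integer(0))
      return(structure(empty, class = c("signal_table", "data.frame"),
                       level = level, N = nrow(bp), empty = TRUE))
    }
    disproportionality(cp, bp, level = level, min_count = min_count,
                       prior = prior)
  })
}

#' Outcome-severity breakdown per term
#'
#' For each PT (or SOC), counts how many of the cases reporting that term
#' carry each outcome code: death (DE), life-threatening (LT),
#' hospitalization (HO), disability (DS), and other serious (OT, with the
#' rarer CA and RI codes folded in).  A case with several codes counts in
#' each category; percentages are over the term's outcome-coded cases, so a
#' term with none gets zero counts and `NA` percentages.
#'
#' @param cohort a `faers_data` object.
#' @param level `"pt"` or `"soc"`.
#' @param soc_map a [meddra_map()] when `level = "soc"`.
#' @return data.frame with one row per (term, category) and columns `term`,
#'   `category`, `n`, `pct`, `n_outcome_cases`.
#' @export
categorize_outcomes <- function(cohort, level = c("pt", "soc"),
                                soc_map = NULL) {
  level <- match.arg(level)
  pairs <- event_pairs(cohort, level, soc_map)
  outc <- cohort$outc
  olab <- outcome_labels[outc$outc_cod]
  oc <- unique(data.frame(caseid = outc$caseid[!is.na(olab)],
                          category = olab[!is.na(olab)],
                          stringsAsFactors = FALSE))
  cats <- unique(unname(outcome_labels))
  res <- lapply(sort(unique(pairs$term)), function(tm) {
    cases <- pairs$caseid[pairs$term == tm]
    sub <- oc[oc$caseid %in% cases, , drop = FALSE]
    denom <- length(unique(sub$caseid))
    n <- vapply(cats, function(cat)
      length(unique(sub$caseid[sub$category == cat])), integer(1))
    data.frame(term = tm, category = cats, n = n,
               pct = if (denom > 0) round(100 * n / denom, 1) else NA_real_,
               n_outcome_cases = denom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
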