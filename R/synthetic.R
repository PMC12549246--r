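# Synthetic FAERS-dialect report generator with known ground truth.
#
# The generative model is deliberately simple: disproportionality statistics
# depend only on the 2x2 margins, so per case we draw sex/age/outcome
# independently, a Bernoulli primary-suspect indicator per drug, and the PT
# list per case with probability baseline x multiplier when a primary-suspect
# drug carries a multiplier for that PT.  Realistic co-reporting structure is
# a non-goal.

default_drugs <- data.frame(
  name = c("PIROXICAM", "IBUPROFEN", "NAPROXEN", "CELECOXIB", "METFORMIN",
           "LISINOPRIL", "OMEPRAZOLE", "ATORVASTATIN"),
  p = c(0.02, 0.12, 0.08, 0.06, 0.10, 0.08, 0.10, 0.12),
  stringsAsFactors = FALSE)

default_events <- data.frame(
  pt = c("Drug hypersensitivity", "Anaphylactic reaction", "Gastric ulcer",
         "Gastrointestinal haemorrhage", "Nausea", "Diarrhoea", "Urticaria",
         "Pruritus", "Rash", "Acute generalized exanthematous pustulosis",
         "Headache", "Dizziness", "Fatigue", "Oedema peripheral",
         "Acute kidney injury", "Hepatitis", "Dyspnoea", "Cough",
         "Insomnia", "Anxiety"),
  soc = c("Immune system disorders", "Immune system disorders",
          "Gastrointestinal disorders", "Gastrointestinal disorders",
          "Gastrointestinal disorders", "Gastrointestinal disorders",
          "Skin and subcutaneous tissue disorders",
          "Skin and subcutaneous tissue disorders",
          "Skin and subcutaneous tissue disorders",
          "Skin and subcutaneous tissue disorders",
          "Nervous system disorders", "Nervous system disorders",
          "General disorders and administration site conditions",
          "General disorders and administration site conditions",
          "Renal and urinary disorders", "Hepatobiliary disorders",
          "Respiratory, thoracic and mediastinal disorders",
          "Respiratory, thoracic and mediastinal disorders",
          "Psychiatric disorders", "Psychiatric disorders"),
  p_base = c(0.005, 0.002, 0.004, 0.003, 0.030, 0.020, 0.008, 0.010, 0.020,
             0.0005, 0.025, 0.020, 0.020, 0.008, 0.005, 0.002, 0.012, 0.010,
             0.012, 0.010),
  stringsAsFactors = FALSE)

# Drug-event reporting-rate multipliers emulating an NSAID hypersensitivity /
# gastrointestinal signal pattern on the target drug.
default_multipliers <- data.frame(
  drug = "PIROXICAM",
  pt = c("Drug hypersensitivity", "Gastric ulcer",
         "Gastrointestinal haemorrhage", "Urticaria",
         "Acute generalized exanthematous pustulosis"),
  rr = c(8, 6, 5, 4, 12),
  stringsAsFactors = FALSE)

#' Configuration of the synthetic report generator
#'
#' Bundles and validates every parameter of the generator.  The defaults
#' emulate the descriptive margins of a 21-year piroxicam extract:
#' about 60% of sex-recorded reports female with 8.4% of sexes unrecorded,
#' age-band weights (<18, 18-44, 45-64, >=65) proportional to
#' 1.9/21.2/36.5/40.4 with 29.7% of ages unrecorded, outcome-code
#' probabilities (DE/LT/HO/DS/OT) 5.8/4.8/29.5/3.4/41.6%, and a Weibull
#' onset-time distribution with shape 0.4 and scale 79 days (a decreasing
#' hazard: most events early in therapy).  A `missing_date_rate` of 0.45 per
#' date field leaves roughly 30% of target-drug reports with a computable
#' onset interval.
#'
#' @param n_cases number of distinct cases to simulate.
#' @param drugs data.frame with columns `name`, `p` (marginal probability
#'   that a case lists the drug as primary suspect).
#' @param events data.frame with columns `pt`, `soc`, `p_base` (baseline
#'   per-case reporting probability of the PT).
#' @param rr_multipliers data.frame with columns `drug`, `pt`, `rr`:
#'   relative reporting-rate multipliers (1 = no association), applied when
#'   the case carries that drug as primary suspect.
#' @param duplicate_rate fraction of cases that receive 1-3 extra report
#'   versions (same payload, later receipt date, new primaryid).
#' @param missing_age_rate,missing_sex_rate fraction of cases with the field
#'   blanked.
#' @param missing_date_rate fraction applied independently to the event date
#'   and the therapy start date; half of the blanked dates are emitted as
#'   6-digit partial dates to exercise the parser's exclusion path.
#' @param onset_shape,onset_scale Weibull parameters of the onset-time
#'   distribution, in days.
#' @param female_fraction probability of female among sex-recorded cases.
#' @param age_mixture data.frame with columns `band` (one of `"<18"`,
#'   `"18-44"`, `"45-64"`, `">=65"`) and `weight`.
#' @param outcome_probs named numeric vector of outcome-code probabilities
#'   (codes among DE, LT, HO, DS, OT, CA, RI), summing to at most 1; the
#'   remainder of cases get no outcome row.
#' @param seed integer seed; identical config and seed give byte-identical
#'   output files.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cases = 5000,
                             drugs = default_drugs,
                             events = default_events,
                             rr_multipliers = default_multipliers,
                             duplicate_rate = 0.10,
                             missing_age_rate = 0.297,
                             missing_sex_rate = 0.0843,
                             missing_date_rate = 0.45,
                             onset_shape = 0.4,
                             onset_scale = 79,
                             female_fraction = 0.652,
                             age_mixture = data.frame(
                               band = c("<18", "18-44", "45-64", ">=65"),
                               weight = c(0.019, 0.212, 0.365, 0.404)),
                             outcome_probs = c(DE = 0.0576, LT = 0.0476,
                                               HO = 0.2947, DS = 0.0342,
                                               OT = 0.4157),
                             seed = 1L) {
  fun <- "synthetic_config"
  if (!is.numeric(n_cases) || length(n_cases) != 1L || is.na(n_cases) ||
      n_cases < 1)
    fail(fun, "`n_cases` must be a positive integer")
  if (!is.data.frame(drugs) || !all(c("name", "p") %in% names(drugs)) ||
      nrow(drugs) < 1)
    fail(fun, "`drugs` must be a data.frame with columns name, p")
  for (p in drugs$p) check_prob(p, "drugs$p", fun)
  if (!is.data.frame(events) ||
      !all(c("pt", "soc", "p_base") %in% names(events)))
    fail(fun, "`events` must be a data.frame with columns pt, soc, p_base")
  for (p in events$p_base) check_prob(p, "events$p_base", fun)
  if (!is.data.frame(rr_multipliers) ||
      !all(c("drug", "pt", "rr") %in% names(rr_multipliers)))
    fail(fun, "`rr_multipliers` must have columns drug, pt, rr")
  if (any(!is.finite(rr_multipliers$rr)) || any(rr_multipliers$rr <= 0))
    fail(fun, "`rr_multipliers` must be strictly positive")
  check_prob(duplicate_rate, "duplicate_rate", fun)
  check_prob(missing_age_rate, "missing_age_rate", fun)
  check_prob(missing_sex_rate, "missing_sex_rate", fun)
  check_prob(missing_date_rate, "missing_date_rate", fun)
  check_prob(female_fraction, "female_fraction", fun)
  if (!is.numeric(onset_shape) || onset_shape <= 0)
    fail(fun, "`onset_shape` must be positive")
  if (!is.numeric(onset_scale) || onset_scale <= 0)
    fail(fun, "`onset_scale` must be positive")
  if (!is.data.frame(age_mixture) ||
      !all(c("band", "weight") %in% names(age_mixture)) ||
      any(age_mixture$weight < 0))
    fail(fun, "`age_mixture` must have columns band, weight (nonnegative)")
  if (is.null(names(outcome_probs)) || any(outcome_probs < 0) ||
      sum(outcome_probs) > 1 + 1e-12)
    fail(fun, "`outcome_probs` must be named, nonnegative, and sum to <= 1")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    fail(fun, "`seed` must be a single integer")
  structure(list(n_cases = as.integer(n_cases), drugs = drugs,
                 events = events, rr_multipliers = rr_multipliers,
                 duplicate_rate = duplicate_rate,
                 missing_age_rate = missing_age_rate,
                 missing_sex_rate = missing_sex_rate,
                 missing_date_rate = missing_date_rate,
                 onset_shape = onset_shape, onset_scale = onset_scale,
                 female_fraction = female_fraction,
                 age_mixture = age_mixture, outcome_probs = outcome_probs,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

age_band_ranges <- list("<18" = c(1, 17.99), "18-44" = c(18, 44.99),
                        "45-64" = c(45, 64.99), ">=65" = c(65, 95))

#' Sample time-to-onset intervals in whole days
#'
#' Draws from a Weibull distribution and rounds to whole days (half-days
#' round up, so an interval under half a day reports as day 0; the fitting
#' code later maps day 0 back to 0.5).
#'
#' @param n number of draws (>= 1).
#' @param shape,scale Weibull parameters (scale in days).
#' @param seed optional integer seed.
#' @return integer vector of day counts.
#' @export
sample_onsets <- function(n, shape, scale, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    fail("sample_onsets", "`n` must be a positive integer")
  if (!is.numeric(shape) || shape <= 0)
    fail("sample_onsets", "`shape` must be positive")
  if (!is.numeric(scale) || scale <= 0)
    fail("sample_onsets", "`scale` must be positive")
  if (!is.null(seed)) set.seed(seed)
  as.integer(floor(stats::rweibull(n, shape, scale) + 0.5))
}

# Sample the in-memory tables for one batch (no duplicates yet).
sample_batch <- function(config) {
  n <- config$n_cases
  drugs <- config$drugs
  events <- config$events
  caseid <- sprintf("%08d", seq_len(n))
  primaryid <- paste0(caseid, "1")     # version suffix 1

  # demographics
  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  sex[stats::runif(n) < config$missing_sex_rate] <- ""
  w <- config$age_mixture$weight / sum(config$age_mixture$weight)
  band <- as.character(config$age_mixture$band[
    sample.int(nrow(config$age_mixture), n, replace = TRUE, prob = w)])
  rng <- do.call(rbind, age_band_ranges[band])
  age <- round(rng[, 1] + stats::runif(n) * (rng[, 2] - rng[, 1]))
  age_chr <- as.character(age)
  age_chr[stats::runif(n) < config$missing_age_rate] <- ""

  # therapy start somewhere in a 21-year reporting window
  t0 <- as.Date("2004-01-01")
  start <- t0 + sample.int(as.integer(as.Date("2024-09-30") - t0), n,
                           replace = TRUE)
  onset <- sample_onsets(n, config$onset_shape, config$onset_scale)
  event <- start + onset
  fda <- event + sample.int(60L, n, replace = TRUE)

  fmt <- function(d) format(d, "%Y%m%d")
  # blank or truncate dates: half of the affected fields become 6-digit
  # partials, the rest empty
  degrade <- function(x) {
    hit <- stats::runif(n) < config$missing_date_rate
    partial <- hit & stats::runif(n) < 0.5
    x[partial] <- substr(x[partial], 1L, 6L)
    x[hit & !partial] <- ""
    x
  }
  event_chr <- degrade(fmt(event))
  start_chr <- degrade(fmt(start))

  occp <- sample(c("MD", "CN", "PH", "OT", ""), n, replace = TRUE,
                 prob = c(0.35, 0.25, 0.14, 0.19, 0.07))
  country <- sample(c("US", "FR", "BR", "IT", "GB", "DE", "JP"), n,
                    replace = TRUE,
                    prob = c(0.43, 0.15, 0.08, 0.06, 0.05, 0.12, 0.11))

  demo <- data.frame(primaryid = primaryid, caseid = caseid,
                     fda_dt = fmt(fda), event_dt = event_chr,
                     age = age_chr, age_cod = ifelse(age_chr == "", "", "YR"),
                     sex = sex, occp_cod = occp, reporter_country = country,
                     occr_country = country, stringsAsFactors = FALSE)

  # primary-suspect indicator per (case, drug)
  ps <- matrix(stats::runif(n * nrow(drugs)), n) <
    matrix(drugs$p, n, nrow(drugs), byrow = TRUE)
  # cases with no PS drug get one concomitant drug so every report lists
  # at least one medication (margins of the PS analysis are untouched)
  none <- rowSums(ps) == 0L
  filler <- sample.int(nrow(drugs), n, replace = TRUE,
                       prob = drugs$p / sum(drugs$p))

  drug_rows <- which(ps, arr.ind = TRUE)
  drug_tab <- data.frame(case = drug_rows[, 1], di = drug_rows[, 2],
                         role = "PS", stringsAsFactors = FALSE)
  if (any(none))
    drug_tab <- rbind(drug_tab,
                      data.frame(case = which(none), di = filler[none],
                                 role = "C", stringsAsFactors = FALSE))
  drug_tab <- drug_tab[order(drug_tab$case, drug_tab$di), , drop = FALSE]
  seq_in_case <- stats::ave(drug_tab$case, drug_tab$case, FUN = seq_along)
  drug <- data.frame(primaryid = primaryid[drug_tab$case],
                     caseid = caseid[drug_tab$case],
                     drug_seq = as.character(seq_in_case),
                     role_cod = drug_tab$role,
                     drugname = drugs$name[drug_tab$di],
                     prod_ai = drugs$name[drug_tab$di],
                     stringsAsFactors = FALSE)

  # per-case PT reporting probability: baseline x (largest multiplier among
  # the case's PS drugs that target the PT)
  m <- nrow(events)
  pmat <- matrix(events$p_base, n, m, byrow = TRUE)
  for (k in seq_len(nrow(config$rr_multipliers))) {
    di <- match(config$rr_multipliers$drug[k], drugs$name)
    ei <- match(config$rr_multipliers$pt[k], events$pt)
    if (is.na(di) || is.na(ei)) next
    hit <- ps[, di]
    pmat[hit, ei] <- pmax(pmat[hit, ei],
                          pmin(1, events$p_base[ei] *
                                 config$rr_multipliers$rr[k]))
  }
  hits <- matrix(stats::runif(n * m), n) < pmat
  ev_rows <- which(hits, arr.ind = TRUE)
  ev_rows <- ev_rows[order(ev_rows[, 1], ev_rows[, 2]), , drop = FALSE]
  reac <- data.frame(primaryid = primaryid[ev_rows[, 1]],
                     caseid = caseid[ev_rows[, 1]],
                     pt = events$pt[ev_rows[, 2]], stringsAsFactors = FALSE)

  # one therapy row per PS drug row (start date shared within case)
  is_ps <- drug$role_cod == "PS"
  ther <- data.frame(primaryid = drug$primaryid[is_ps],
                     caseid = drug$caseid[is_ps],
                     dsg_drug_seq = drug$drug_seq[is_ps],
                     start_dt = start_chr[match(drug$caseid[is_ps], caseid)],
                     end_dt = "", stringsAsFactors = FALSE)

  # at most one outcome code per case
  oc <- names(config$outcome_probs)
  pick <- sample.int(length(oc) + 1L, n, replace = TRUE,
                     prob = c(config$outcome_probs,
                              1 - sum(config$outcome_probs)))
  has_out <- pick <= length(oc)
  outc <- data.frame(primaryid = primaryid[has_out],
                     caseid = caseid[has_out],
                     outc_cod = oc[pick[has_out]], stringsAsFactors = FALSE)

  list(demo = demo, drug = drug, reac = reac, ther = ther, outc = outc,
       ps = ps, hits = hits)
}

#' Inject multi-version duplicate reports into a batch
#'
#' A sampled fraction of cases gains 1-3 extra versions whose receipt date is
#' equal or later and whose PRIMARYID is a higher version number; the
#' clinical payload (drugs, reactions, therapy, outcomes) is copied verbatim,
#' so correct deduplication restores the original case count exactly.
#'
#' @param batch in-memory batch (list of the five tables) as produced inside
#'   [generate_faers()], or a `faers_raw` object.
#' @param duplicate_rate fraction of cases to duplicate.
#' @param seed optional integer seed.
#' @param max_extra maximum extra versions per duplicated case (1-3 by
#'   default).
#' @return the batch with extra report versions appended and an attribute
#'   `n_duplicates_injected`.
#' @export
inject_duplicates <- function(batch, duplicate_rate, seed = NULL,
                              max_extra = 3L) {
  check_prob(duplicate_rate, "duplicate_rate", "inject_duplicates")
  if (!is.null(seed)) set.seed(seed)
  demo <- batch$demo
  n <- nrow(demo)
  pick <- which(stats::runif(n) < duplicate_rate)
  n_injected <- 0L
  if (length(pick)) {
    reps <- sample.int(max_extra, length(pick), replace = TRUE)
    idx <- rep(pick, reps)
    version <- unlist(lapply(reps, seq_len)) + 1L   # versions 2..4
    old_pid <- demo$primaryid[idx]
    new_pid <- paste0(demo$caseid[idx], version)
    lag <- sample.int(91L, length(idx), replace = TRUE) - 1L
    new_demo <- demo[idx, , drop = FALSE]
    new_demo$primaryid <- new_pid
    old_fda <- parse_faers_date(new_demo$fda_dt)
    upd <- !is.na(old_fda)
    new_demo$fda_dt[upd] <- format(old_fda[upd] + lag[upd], "%Y%m%d")
    copy_children <- function(tab) {
      idx <- split(seq_len(nrow(tab)), tab$primaryid)
      sel <- idx[old_pid]                 # absent pids give zero-length picks
      take <- unlist(sel, use.names = FALSE)
      new_rows <- tab[take, , drop = FALSE]
      new_rows$primaryid <- rep(new_pid, vapply(sel, length, integer(1)))
      rbind(tab, new_rows)
    }
    batch$demo <- rbind(demo, new_demo)
    batch$drug <- copy_children(batch$drug)
    batch$reac <- copy_children(batch$reac)
    batch$ther <- copy_children(batch$ther)
    batch$outc <- copy_children(batch$outc)
    n_injected <- length(idx)
  }
  attr(batch, "n_duplicates_injected") <- n_injected
  batch
}

#' Generate a synthetic FAERS-dialect batch on disk
#'
#' Samples a report population from the generative model in `config`,
#' injects duplicate report versions, and writes the five quarterly tables
#' ('$'-delimited, one header line, named `<TABLE><YY>Q<N>.txt` after the
#' latest receipt quarter) plus a flat key-value `ground_truth.txt`.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `files`, `truth` (see Details), and
#'   `config`.  `truth` carries `expected_contingency` (expected a,b,c,d per
#'   drug-PT pair under the model), `true_rr`, `n_duplicates_injected`, and
#'   `n_ps_cases` (cases carrying each drug as primary suspect).
#' @export
generate_faers <- function(config, dir) {
  if (!inherits(config, "synthetic_config"))
    fail("generate_faers", "`config` must be a synthetic_config object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  batch <- sample_batch(config)
  ps <- batch$ps; hits <- batch$hits
  batch$ps <- NULL; batch$hits <- NULL
  batch <- inject_duplicates(batch, config$duplicate_rate)

  drugs <- config$drugs; events <- config$events
  n <- config$n_cases
  mk <- config$rr_multipliers
  truth <- list(true_rr = list(), expected_contingency = list(),
                n_duplicates_injected = attr(batch, "n_duplicates_injected"),
                n_ps_cases = colSums(ps))
  names(truth$n_ps_cases) <- drugs$name
  # expectations to first order in drug co-occurrence (multi-PS overlap is
  # rare at the default marginals, and the default multipliers touch only
  # one drug, where the expressions are exact)
  rr_of <- function(g, e) {
    r <- mk$rr[mk$drug == g & mk$pt == e]
    if (length(r)) r[[1L]] else 1
  }
  p_e_given <- function(gi, ei)            # P(report e | PS for drug gi)
    min(1, events$p_base[ei] * rr_of(drugs$name[gi], events$pt[ei]))
  # overall marginal P(report e) per case
  p_marg <- vapply(seq_len(nrow(events)), function(ei) {
    base <- events$p_base[ei]
    base + sum(vapply(seq_len(nrow(drugs)), function(gi)
      drugs$p[gi] * (p_e_given(gi, ei) - base), numeric(1)))
  }, numeric(1))
  total_pairs <- n * sum(p_marg)
  for (gi in seq_len(nrow(drugs))) {
    cohort_pairs <- n * drugs$p[gi] *
      sum(vapply(seq_len(nrow(events)), function(ei) p_e_given(gi, ei),
                 numeric(1)))
    for (ei in seq_len(nrow(events))) {
      key <- paste(drugs$name[gi], events$pt[ei], sep = "|")
      truth$true_rr[[key]] <- rr_of(drugs$name[gi], events$pt[ei])
      a <- n * drugs$p[gi] * p_e_given(gi, ei)
      b <- cohort_pairs - a
      c_ <- n * p_marg[ei] - a
      d <- total_pairs - a - b - c_
      truth$expected_contingency[[key]] <- c(a = a, b = b, c = c_, d = d)
    }
  }

  last_fda <- max(parse_faers_date(batch$demo$fda_dt), na.rm = TRUE)
  yy <- format(last_fda, "%y")
  qq <- (as.integer(format(last_fda, "%m")) - 1L) %/% 3L + 1L
  tag <- sprintf("%sQ%d", yy, qq)
  files <- character(0)
  for (kind in names(faers_columns)) {
    tab <- batch[[tolower(kind)]]
    path <- file.path(dir, sprintf("%s%s.txt", kind, tag))
    con <- file(path, "wb")   # fixed newline convention => hash-stable
    writeLines(c(paste(faers_columns[[kind]], collapse = "$"),
                 do.call(paste, c(unname(as.list(tab)), sep = "$"))),
               con, sep = "\n")
    close(con)
    files <- c(files, path)
  }
  truth_path <- file.path(dir, "ground_truth.txt")
  tl <- c(sprintf("n_cases=%d", n),
          sprintf("n_duplicates_injected=%d", truth$n_duplicates_injected),
          sprintf("n_ps_cases.%s=%d", names(truth$n_ps_cases),
                  truth$n_ps_cases),
          sprintf("true_rr.%s=%g", names(truth$true_rr),
                  unlist(truth$true_rr)),
          unlist(lapply(names(truth$expected_contingency), function(k) {
            x <- truth$expected_contingency[[k]]
            sprintf("expected.%s.%s=%.6g", k, names(x), x)
          })))
  con <- file(truth_path, "wb")
  writeLines(tl, con, sep = "\n")
  close(con)
  invisible(list(files = c(files, truth_path), truth = truth,
                 config = config))
}
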