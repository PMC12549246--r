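# hand-built report set with a female-only drug-event association
sex_specific_tables <- function(n = 6000, seed = 101) {
  set.seed(seed)
  pid <- as.character(seq_len(n) + 10000)
  cid <- paste0("S", seq_len(n))
  sex <- rep(c("F", "M"), length.out = n)
  drugx <- runif(n) < 0.10
  # ptY: baseline 2%, raised to 16% only for female drugX cases
  p_pty <- ifelse(drugx & sex == "F", 0.16, 0.02)
  pty <- runif(n) < p_pty
  ptz <- runif(n) < 0.25            # neutral filler event
  demo <- data.frame(primaryid = pid, caseid = cid, fda_dt = "20210401",
                     event_dt = "", age = "50", age_cod = "YR", sex = sex,
                     occp_cod = "MD", reporter_country = "US",
                     occr_country = "US", stringsAsFactors = FALSE)
  drug <- data.frame(primaryid = pid, caseid = cid, drug_seq = "1",
                     role_cod = "PS",
                     drugname = ifelse(drugx, "DRUGX", "OTHERDRUG"),
                     prod_ai = ifelse(drugx, "DRUGX", "OTHERDRUG"),
                     stringsAsFactors = FALSE)
  reac <- rbind(
    data.frame(primaryid = pid[pty], caseid = cid[pty], pt = "Pty",
               stringsAsFactors = FALSE),
    data.frame(primaryid = pid[ptz], caseid = cid[ptz], pt = "Ptz",
               stringsAsFactors = FALSE))
  structure(list(demo = demo, drug = drug, reac = reac,
                 ther = data.frame(primaryid = character(0),
                                   caseid = character(0),
                                   dsg_drug_seq = character(0),
                                   start_dt = character(0),
                                   end_dt = character(0),
                                   stringsAsFactors = FALSE),
                 outc = data.frame(primaryid = character(0),
                                   caseid = character(0),
                                   outc_cod = character(0),
                                   stringsAsFactors = FALSE)),
            class = "faers_raw")
}

test_that("stratification restricts cohort and background and counts unknowns", {
  raw <- sex_specific_tables(2000)
  raw$demo$sex[1:100] <- ""                 # unknown sex
  fa <- dedup_reports(raw)
  coh <- select_primary_suspect(fa, drug_dictionary("DRUGX"))
  bg <- background_reports(fa, coh)
  st <- stratify(coh, bg, "sex")
  n_f <- nrow(st$Female$cohort$demo)
  n_m <- nrow(st$Male$cohort$demo)
  expect_equal(n_f + n_m + attr(st, "n_unknown_cohort"), nrow(coh$demo))
  # per-term a-counts over strata sum to pooled a minus unknown-level cases
  pooled <- event_pairs(coh, "pt")
  unknown_cases <- coh$demo$caseid[coh$demo$sex == ""]
  for (tm in c("Pty", "Ptz")) {
    a_pooled <- sum(pooled$term == tm)
    a_unknown <- sum(pooled$term == tm & pooled$caseid %in% unknown_cases)
    a_strata <- sum(event_pairs(st$Female$cohort, "pt")$term == tm) +
      sum(event_pairs(st$Male$cohort, "pt")$term == tm)
    expect_equal(a_strata, a_pooled - a_unknown)
  }
})

test_that("single-level data stratifies to the unstratified table", {
  raw <- sex_specific_tables(1500)
  raw$demo$sex <- "F"
  fa <- dedup_reports(raw)
  coh <- select_primary_suspect(fa, drug_dictionary("DRUGX"))
  bg <- background_reports(fa, coh)
  st <- stratify(coh, bg, "sex")
  sigs <- stratum_signals(st, "pt")
  pooled <- disproportionality(event_pairs(coh, "pt"),
                               event_pairs(bg, "pt"))
  expect_equal(sigs$Female$ror, pooled$ror)
  expect_equal(nrow(sigs$Male), 0L)         # empty stratum, flagged not fatal
})

test_that("a female-only association is flagged in the female stratum alone", {
  raw <- sex_specific_tables(6000)
  fa <- dedup_reports(raw)
  coh <- select_primary_suspect(fa, drug_dictionary("DRUGX"))
  bg <- background_reports(fa, coh)
  st <- stratify(coh, bg, "sex")
  sigs <- stratum_signals(st, "pt")
  f_row <- sigs$Female[sigs$Female$term == "Pty", ]
  m_row <- sigs$Male[sigs$Male$term == "Pty", ]
  expect_true(f_row$flag_ror)
  expect_true(f_row$flag_prr)
  expect_false(isTRUE(m_row$flag_ror) && isTRUE(m_row$flag_prr))
  expect_false(isTRUE(m_row$combined_all))
})

test_that("pooled and stratified ROR agree on homogeneous data", {
  raw <- sex_specific_tables(6000, seed = 55)
  # homogeneous: same elevated rate in both sexes
  set.seed(56)
  drugx_cases <- raw$drug$caseid[raw$drug$drugname == "DRUGX"]
  fa <- dedup_reports(raw)
  coh <- select_primary_suspect(fa, drug_dictionary("DRUGX"))
  bg <- background_reports(fa, coh)
  pooled <- disproportionality(event_pairs(coh, "pt"),
                               event_pairs(bg, "pt"))
  st <- stratify(coh, bg, "sex")
  sigs <- stratum_signals(st, "pt")
  pr <- pooled[pooled$term == "Ptz", ]
  for (lv in c("Female", "Male")) {
    row <- sigs[[lv]][sigs[[lv]]$term == "Ptz", ]
    # CI overlap between stratum and pooled estimate
    expect_true(row$ror_low <= pr$ror_high && pr$ror_low <= row$ror_high)
  }
})

test_that("outcome categories honour code multiplicity and denominators", {
  raw <- tiny_raw()
  fa <- dedup_reports(raw)
  out <- categorize_outcomes(fa, "pt")
  # C1 carries HO and LT: its PTs count once in each category
  gu <- out[out$term == "Gastric ulcer", ]
  expect_equal(gu$n[gu$category == "Hospitalization - initial or prolonged"], 1L)
  expect_equal(gu$n[gu$category == "Life-threatening"], 1L)
  expect_equal(unique(gu$n_outcome_cases), 1L)
  expect_true(all(gu$n <= 1L))
  # a term with no outcome-coded cases: zeros and NA percentages
  nau <- out[out$term == "Nausea", ]
  expect_true(all(nau$n == 0L))
  expect_true(all(is.na(nau$pct)))
})

test_that("outcome proportions track the generator's configured rates", {
  b <- gen_batch(fast_config(n_cases = 4000, seed = 61,
                             duplicate_rate = 0))
  fa <- dedup_reports(read_faers(b$dir))
  s <- summarize_cohort(fa)
  ho <- s$outcome$n[s$outcome$category ==
                      "Hospitalization - initial or prolonged"]
  p <- 0.2947
  se <- sqrt(p * (1 - p) / 4000)
  expect_true(abs(ho / 4000 - p) < 3 * se)
})

test_that("analysis tables are invariant to input row order", {
  raw <- sex_specific_tables(1200, seed = 77)
  perm <- raw
  set.seed(78)
  perm$demo <- perm$demo[sample.int(nrow(perm$demo)), ]
  perm$reac <- perm$reac[sample.int(nrow(perm$reac)), ]
  perm$drug <- perm$drug[sample.int(nrow(perm$drug)), ]
  for (r in list(raw, perm)) {
    fa <- dedup_reports(r)
    coh <- select_primary_suspect(fa, drug_dictionary("DRUGX"))
    bg <- background_reports(fa, coh)
    sig <- disproportionality(event_pairs(coh, "pt"),
                              event_pairs(bg, "pt"))
    if (identical(r, raw)) first <- sig else {
      expect_equal(first$term, sig$term)
      expect_equal(first$ror, sig$ror)
      expect_equal(first$a, sig$a)
    }
  }
})
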