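# Shared fixtures, built in code at test time.

# A minimal in-memory raw report set with known duplicate structure.
# Three cases: C1 has two versions differing in FDA_DT; C2 has two versions
# with equal FDA_DT and primaryids 9 / 21; C3 is a singleton.
tiny_raw <- function() {
  demo <- data.frame(
    primaryid = c("11", "12", "9", "21", "31"),
    caseid = c("C1", "C1", "C2", "C2", "C3"),
    fda_dt = c("20180101", "20190101", "20200601", "20200601", "20150101"),
    event_dt = c("20171201", "20171201", "20200501", "20200501", "20141230"),
    age = c("54", "54", "6", "6", "18"),
    age_cod = c("YR", "YR", "DEC", "DEC", "MON"),
    sex = c("F", "F", "M", "M", ""),
    occp_cod = c("MD", "MD", "CN", "CN", "PH"),
    reporter_country = c("US", "US", "FR", "FR", "BR"),
    occr_country = c("US", "US", "FR", "FR", "BR"),
    stringsAsFactors = FALSE)
  drug <- data.frame(
    primaryid = c("11", "12", "9", "21", "31", "31"),
    caseid = c("C1", "C1", "C2", "C2", "C3", "C3"),
    drug_seq = c("1", "1", "1", "1", "1", "2"),
    role_cod = c("PS", "PS", "PS", "PS", "SS", "PS"),
    drugname = c("PIROXICAM.", "PIROXICAM.", "IBUPROFEN", "IBUPROFEN",
                 "PIROXICAM", "NAPROXEN"),
    prod_ai = c("PIROXICAM", "PIROXICAM", "IBUPROFEN", "IBUPROFEN",
                "PIROXICAM", "NAPROXEN"),
    stringsAsFactors = FALSE)
  reac <- data.frame(
    primaryid = c("11", "12", "12", "9", "21", "31"),
    caseid = c("C1", "C1", "C1", "C2", "C2", "C3"),
    pt = c("Gastric ulcer", "gastric ULCER", "Urticaria", "Nausea",
           "Nausea", "Rash"),
    stringsAsFactors = FALSE)
  ther <- data.frame(
    primaryid = c("11", "12", "31"),
    caseid = c("C1", "C1", "C3"),
    dsg_drug_seq = c("1", "1", "2"),
    start_dt = c("20171101", "20171101", "20141201"),
    end_dt = c("", "", ""),
    stringsAsFactors = FALSE)
  outc <- data.frame(
    primaryid = c("12", "12", "31"),
    caseid = c("C1", "C1", "C3"),
    outc_cod = c("HO", "LT", "OT"),
    stringsAsFactors = FALSE)
  structure(list(demo = demo, drug = drug, reac = reac, ther = ther,
                 outc = outc), class = "faers_raw")
}

toy_soc_map <- function() {
  meddra_map(c("Gastric ulcer", "Urticaria", "Nausea", "Rash"),
             c("Gastrointestinal disorders",
               "Skin and subcutaneous tissue disorders",
               "Gastrointestinal disorders",
               "Skin and subcutaneous tissue disorders"),
             c("10017947", "10040785", "10017947", "10040785"))
}

# Brute-force nested-loop 2x2 oracle over unique (case, term) pairs,
# independent of the package's tabulation path.
brute_contingency <- function(cohort_pairs, background_pairs, term) {
  a <- 0L; b <- 0L; cc <- 0L; d <- 0L
  for (i in seq_len(nrow(cohort_pairs))) {
    if (cohort_pairs$term[i] == term) a <- a + 1L else b <- b + 1L
  }
  for (i in seq_len(nrow(background_pairs))) {
    if (background_pairs$term[i] == term) cc <- cc + 1L else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# small synthetic config for fast generator-based tests
fast_config <- function(n_cases = 2000, seed = 1, ...) {
  synthetic_config(n_cases = n_cases, seed = seed, ...)
}

# generate a batch into a fresh temp dir, returning dir and truth
gen_batch <- function(config) {
  dir <- tempfile("faersbatch")
  sim <- generate_faers(config, dir)
  list(dir = dir, sim = sim)
}
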