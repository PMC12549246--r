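# End-to-end pipeline: ingest -> dedup -> cohort -> signals -> onset ->
# strata / outcomes, driven by a flat key = value configuration, with a
# JSON reproducibility manifest.

#' Read a flat pipeline configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Recognized keys: `input_dir`, `simulate` (logical), `n_cases`, `seed`,
#' `drug_dictionary`, `meddra_map`, `min_count`, `signal_mode`
#' (`any`/`all`), `stratify` (logical), `output_dir`, `country_field`.
#'
#' @param path path to the config file.
#' @return a named list with defaults applied.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    fail("read_run_config", sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- stats::setNames(
    lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
    vapply(kv, function(p) trimws(p[[1]]), character(1)))
  defaults <- list(simulate = "false", n_cases = "5000", seed = "1",
                   min_count = "3", signal_mode = "any", stratify = "true",
                   country_field = "occr_country")
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  cfg$simulate <- tolower(cfg$simulate) %in% c("true", "yes", "1")
  cfg$stratify <- tolower(cfg$stratify) %in% c("true", "yes", "1")
  cfg$n_cases <- as.integer(cfg$n_cases)
  cfg$seed <- as.integer(cfg$seed)
  cfg$min_count <- as.integer(cfg$min_count)
  if (!cfg$signal_mode %in% c("any", "all"))
    fail("read_run_config", "`signal_mode` must be 'any' or 'all'")
  cfg
}

# meddra map covering the generator's default event list
default_soc_map <- function() {
  ev <- default_events
  codes <- c("Immune system disorders" = "10021428",
             "Gastrointestinal disorders" = "10017947",
             "Skin and subcutaneous tissue disorders" = "10040785",
             "Nervous system disorders" = "10029205",
             "General disorders and administration site conditions" =
               "10018065",
             "Renal and urinary disorders" = "10038359",
             "Hepatobiliary disorders" = "10019805",
             "Respiratory, thoracic and mediastinal disorders" = "10038738",
             "Psychiatric disorders" = "10037175")
  meddra_map(ev$pt, ev$soc, unname(codes[ev$soc]))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: read (or simulate) the quarterly tables,
#' deduplicate by the FDA rule, select the target-drug primary-suspect
#' cohort, summarize it, run four-method disproportionality at PT and SOC
#' level, fit the Weibull time-to-onset model, re-run signals within sex and
#' age strata, and tabulate outcome severities.  Every output table is
#' written as TSV under `output_dir`, together with `manifest.json`
#' recording input hashes, record counts before and after deduplication,
#' cohort size, unmapped PTs, thresholds and the seed.
#'
#' @param config a config list from [read_run_config()], or a path to a
#'   config file.
#' @param input_dir,output_dir override the config's directories.
#' @param dictionary a [drug_dictionary()]; default is the generator's
#'   target drug (piroxicam).
#' @param soc_map a [meddra_map()]; default covers the generator's events.
#' @return invisibly, the manifest list (also written as JSON).  The
#'   manifest element `status` is `"ok"` or `"empty-cohort"`.
#' @export
run_pipeline <- function(config, input_dir = NULL, output_dir = NULL,
                         dictionary = NULL, soc_map = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  input_dir <- input_dir %||% config$input_dir
  output_dir <- output_dir %||% config$output_dir
  if (is.null(output_dir)) fail("run_pipeline", "no output_dir given")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- list()
  tick <- function(name) {
    stages[[name]] <<- format(Sys.time(), "%H:%M:%OS2")
    message(sprintf("[%s] stage: %s", stages[[name]], name))
  }

  if (isTRUE(config$simulate)) {
    tick("simulate")
    if (is.null(input_dir)) fail("run_pipeline", "no input_dir to write to")
    sim <- generate_faers(synthetic_config(n_cases = config$n_cases,
                                           seed = config$seed),
                          input_dir)
  } else if (is.null(input_dir) || !dir.exists(input_dir)) {
    fail("run_pipeline", sprintf("input directory not found: %s",
                                 input_dir %||% "<missing>"))
  }

  if (is.null(dictionary)) {
    dictionary <- if (!is.null(config$drug_dictionary))
      read_drug_dictionary(config$drug_dictionary)
    else drug_dictionary("piroxicam")
  }
  if (is.null(soc_map)) {
    soc_map <- if (!is.null(config$meddra_map))
      read_meddra_map(config$meddra_map)
    else default_soc_map()
  }

  tick("ingest")
  raw <- read_faers(input_dir)
  tick("dedup")
  faers <- dedup_reports(raw)

  tick("cohort")
  cohort <- select_primary_suspect(faers, dictionary)
  n_cohort <- nrow(cohort$demo)
  bg_cases <- setdiff(faers$demo$caseid, cohort$demo$caseid)
  background <- restrict_cases(faers, bg_cases)

  manifest <- list(
    input_files = as.list(tools::md5sum(raw$files)),
    seed = config$seed,
    thresholds = list(min_count = config$min_count,
                      signal_mode = config$signal_mode,
                      ror = "lower 95% CI > 1", prr = "PRR>=2 & chi2>4",
                      bcpnn = "IC025 > 0", mgps = "EBGM05 > 2"),
    n_raw_reports = attr(faers, "n_raw"),
    n_duplicates_removed = attr(faers, "n_removed"),
    n_deduplicated = nrow(faers$demo),
    n_cohort = n_cohort,
    package_version = as.character(utils::packageVersion("faersignal")))

  if (n_cohort == 0L) {
    warning("run_pipeline: empty cohort; writing empty outputs")
    manifest$status <- "empty-cohort"
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(manifest))
  }

  tick("summary")
  summ <- summarize_cohort(cohort,
                           country_field = config$country_field %||%
                             "occr_country")
  for (blk in c("sex", "age", "reporter", "country", "outcome", "year")) {
    df <- cbind(block = blk, summ[[blk]])
    if (blk == "sex") all_blocks <- df else all_blocks <- rbind(all_blocks, df)
  }
  write_tsv(all_blocks, file.path(output_dir, "cohort_summary.tsv"))

  tick("signals")
  cp_pt <- event_pairs(cohort, "pt")
  bp_pt <- event_pairs(background, "pt")
  sig_pt <- disproportionality(cp_pt, bp_pt, level = "pt",
                               min_count = config$min_count)
  suppressMessages({
    cp_soc <- event_pairs(cohort, "soc", soc_map)
    bp_soc <- event_pairs(background, "soc", soc_map)
  })
  sig_soc <- disproportionality(cp_soc, bp_soc, level = "soc",
                                min_count = config$min_count)
  write_signal_table(sig_pt, file.path(output_dir, "signals_pt.tsv"))
  write_signal_table(sig_soc, file.path(output_dir, "signals_soc.tsv"))
  unmapped <- attr(suppressMessages(
    map_pt_to_soc(unique(faers$reac$pt), soc_map)), "unmapped")
  manifest$n_unmapped_pt <- length(unmapped)
  manifest$n_signals_any_pt <- sum(sig_pt$combined_any, na.rm = TRUE)
  manifest$n_signals_all_pt <- sum(sig_pt$combined_all, na.rm = TRUE)

  tick("onset")
  onsets <- compute_onsets(cohort, dictionary)
  osum <- onset_summary(onsets)
  fit <- tryCatch(fit_weibull_tto(onsets), error = function(e) NULL)
  tto <- data.frame(
    quantity = c("n_included", "n_excluded", "median_days", "iqr_low",
                 "iqr_high", "shape", "shape_low", "shape_high", "scale",
                 "scale_low", "scale_high"),
    value = c(osum$n, osum$n_excluded, osum$median, osum$iqr,
              if (is.null(fit)) rep(NA_real_, 6)
              else c(fit$shape, fit$shape_ci, fit$scale, fit$scale_ci)))
  write_tsv(tto, file.path(output_dir, "onset_fit.tsv"))
  write_tsv(osum$ecdf, file.path(output_dir, "onset_ecdf.tsv"))
  manifest$n_onset_included <- osum$n

  if (isTRUE(config$stratify)) {
    tick("strata")
    for (axis in c("sex", "age")) {
      st <- stratify(cohort, background, axis)
      sigs <- stratum_signals(st, "pt", min_count = config$min_count,
                              prior = attr(sig_pt, "prior"))
      for (lv in names(sigs)) {
        if (nrow(sigs[[lv]]) == 0L) next
        safe <- gsub("[^A-Za-z0-9]+", "_", lv)
        write_signal_table(sigs[[lv]],
                           file.path(output_dir,
                                     sprintf("signals_%s_%s.tsv", axis,
                                             safe)))
      }
    }
  }

  tick("outcomes")
  write_tsv(categorize_outcomes(cohort, "pt"),
            file.path(output_dir, "outcomes_pt.tsv"))
  write_tsv(categorize_outcomes(cohort, "soc", soc_map),
            file.path(output_dir, "outcomes_soc.tsv"))

  manifest$status <- "ok"
  manifest$stages <- stages
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
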