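# Four-method disproportionality signal detection on 2x2 contingency
# tables of unique (case, term) reporting pairs.
#
# Conventions. Counts are unique (case, PT) EVENT pairs, not report counts:
# a = pairs in the target-drug cohort with the term, b = cohort pairs with
# any other term, c/d the same split in the comparator background, and
# N = a+b+c+d the total pair count of the database at the analysis level.
# At SOC level a case contributes once per distinct SOC.

#' Unique (case, term) event pairs of a report set
#'
#' @param faers a `faers_data` object.
#' @param level `"pt"` (preferred terms, normalized) or `"soc"` (terms
#'   mapped through `soc_map`; unmapped PTs are dropped from the SOC-level
#'   pair set).
#' @param soc_map a [meddra_map()], required when `level = "soc"`.
#' @return data.frame with columns `caseid`, `term`, one row per unique
#'   pair.
#' @export
event_pairs <- function(faers, level = c("pt", "soc"), soc_map = NULL) {
  level <- match.arg(level)
  reac <- faers$reac
  term <- normalize_pt(reac$pt)
  if (level == "soc") {
    if (is.null(soc_map))
      fail("event_pairs", "`soc_map` is required at SOC level")
    term <- map_pt_to_soc(term, soc_map)$soc_name
  }
  out <- data.frame(caseid = as.character(reac$caseid), term = term,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$term), , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Construct a 2x2 disproportionality contingency table
#'
#' @param a,b,c,d nonnegative counts: target drug with/without the target
#'   event, and other drugs with/without it.
#' @return an object of class `contingency_table` (a named numeric vector
#'   with an `N` attribute).
#' @export
contingency_table <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(x)) || any(x < 0))
    fail("contingency_table", "all cells must be nonnegative counts")
  if (sum(x) <= 0) fail("contingency_table", "N must be positive")
  structure(x, N = sum(x), class = "contingency_table")
}

#' Build the 2x2 table for one term
#'
#' @param cohort_pairs unique (case, term) pairs of the target-drug cohort
#'   (from [event_pairs()]).
#' @param background_pairs unique pairs of the comparator (all non-cohort
#'   cases).
#' @param term the target term.
#' @return a [contingency_table()].  A term absent from both pair sets gives
#'   a table with `a = c = 0` (valid but unanalyzable downstream).
#' @export
build_contingency <- function(cohort_pairs, background_pairs, term) {
  a <- sum(cohort_pairs$term == term)
  b <- nrow(cohort_pairs) - a
  cc <- sum(background_pairs$term == term)
  d <- nrow(background_pairs) - cc
  contingency_table(a, b, cc, d)
}

#' Reconstruct a 2x2 table from published margins
#'
#' Published disproportionality tables print, per row, the case count `a`
#' and the statistics but not the full table.  Given the drug's total event
#' count `a + b`, the database total `N`, and the printed PRR, the remaining
#' cells follow: `c = (a/(a+b))/PRR * (N-(a+b))`, `d = N-(a+b)-c`.
#'
#' @param a event-pair count of the drug-term cell.
#' @param drug_total total event pairs of the drug (`a + b`).
#' @param n_total total event pairs of the database (`N`).
#' @param prr the printed proportional reporting ratio of the row.
#' @return a [contingency_table()] (cells are real-valued expectations, not
#'   integers).
#' @export
#' @examples
#' tab <- reconstruct_contingency(314, 3396, 55357463, 8.39)
#' ror(tab)
reconstruct_contingency <- function(a, drug_total, n_total, prr) {
  if (prr <= 0) fail("reconstruct_contingency", "`prr` must be positive")
  b <- drug_total - a
  cc <- (a / drug_total) / prr * (n_total - drug_total)
  d <- n_total - drug_total - cc
  contingency_table(a, b, cc, d)
}

tab_cells <- function(tab) {
  # double precision: cell products overflow 32-bit integers at FAERS scale
  if (inherits(tab, "contingency_table"))
    stats::setNames(as.numeric(unclass(tab)), c("a", "b", "c", "d"))
  else if (is.numeric(tab) && length(tab) == 4L)
    stats::setNames(as.numeric(tab), c("a", "b", "c", "d"))
  else fail("tab_cells", "expected a contingency_table or 4 counts")
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad/(bc); the interval is
#' exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)).  Any zero cell yields
#' an undefined sentinel (`NA`) rather than a continuity correction.
#'
#' @param tab a [contingency_table()] (or a length-4 numeric a,b,c,d).
#' @return named numeric vector `est`, `low`, `high`.
#' @export
#' @examples
#' ror(contingency_table(6, 14, 10, 70))
ror <- function(tab) {
  x <- tab_cells(tab)
  if (any(x == 0)) return(c(est = NA_real_, low = NA_real_, high = NA_real_))
  est <- x["a"] * x["d"] / (x["b"] * x["c"])
  se <- sqrt(sum(1 / x))
  stats::setNames(c(est, est * exp(c(-1, 1) * 1.96 * se)),
                  c("est", "low", "high"))
}

#' Proportional reporting ratio, 95% CI and chi-squared
#'
#' PRR = (a/(a+b)) / (c/(c+d)); interval
#' exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))); the
#' chi-squared statistic is the uncorrected (no Yates)
#' N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @inheritParams ror
#' @return named numeric vector `est`, `low`, `high`, `chi2`.
#' @export
prr_chi2 <- function(tab) {
  x <- tab_cells(tab)
  a <- x["a"]; b <- x["b"]; cc <- x["c"]; d <- x["d"]
  if (a == 0 || cc == 0 || (a + b) == 0 || (cc + d) == 0)
    return(c(est = NA_real_, low = NA_real_, high = NA_real_,
             chi2 = NA_real_))
  est <- (a / (a + b)) / (cc / (cc + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  n <- sum(x)
  chi2 <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  stats::setNames(c(est, est * exp(c(-1, 1) * 1.96 * se), chi2),
                  c("est", "low", "high", "chi2"))
}

#' BCPNN information component and its lower credible bound
#'
#' The information component is the observed-count form
#' IC = log2( a N / ((a+b)(a+c)) ); the 2.5% credible bound uses the
#' normal-approximation rule IC025 = IC - 3.3 a^(-1/2) - 2 a^(-3/2).
#'
#' @inheritParams ror
#' @return named numeric vector `ic`, `ic025`.
#' @export
bcpnn_ic <- function(tab) {
  x <- tab_cells(tab)
  a <- x["a"]
  if (a == 0) return(c(ic = NA_real_, ic025 = NA_real_))
  n <- sum(x)
  ic <- log2(a * n / ((a + x["b"]) * (a + x["c"])))
  stats::setNames(c(ic, ic - 3.3 * a^(-0.5) - 2 * a^(-1.5)),
                  c("ic", "ic025"))
}

# ---------------------------------------------------------------------------
# MGPS: DuMouchel two-gamma-mixture empirical Bayes

# log marginal density of a under one negative-binomial component:
# NB(a; alpha, p) with p = beta/(beta+E)
lnb <- function(a, E, alpha, beta)
  stats::dnbinom(a, size = alpha, prob = beta / (beta + E), log = TRUE)

gps_loglik <- function(theta, a, E) {
  alpha1 <- exp(theta[1]); beta1 <- exp(theta[2])
  alpha2 <- exp(theta[3]); beta2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  # extreme exploratory parameter values can push dnbinom outside its
  # numerically valid range; treat those as an impossible fit
  l1 <- suppressWarnings(lnb(a, E, alpha1, beta1)) + log(w)
  l2 <- suppressWarnings(lnb(a, E, alpha2, beta2)) + log1p(-w)
  m <- pmax(l1, l2)
  ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
  if (!is.finite(ll)) -1e10 else ll
}

default_gps_prior <- function()
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                 w = 1 / 3, loglik = NA_real_, converged = NA,
                 default = TRUE),
            class = "gps_prior")

#' Fit the two-gamma-mixture prior of the gamma Poisson shrinker
#'
#' Maximizes the marginal likelihood of the observed pair counts `a` given
#' their baseline expectations `E`, where the relative reporting rate lambda
#' has prior  w Gamma(alpha1, beta1) + (1-w) Gamma(alpha2, beta2)  and a |
#' lambda is Poisson(lambda E), so marginally a is a mixture of two negative
#' binomials.  Optimization is multi-start BFGS on log/logit-transformed
#' parameters; the start set is fixed (plus seed-jittered extras), so the
#' fit is deterministic given `seed`.
#'
#' With fewer than `min_pairs` usable pairs the conventional default prior
#' (0.2, 0.1, 2, 4, w = 1/3) is returned with a message.
#'
#' @param a integer vector of observed pair counts.
#' @param E positive baseline expectations, same length.
#' @param min_pairs minimum usable pairs before falling back.
#' @param n_starts number of optimizer starts.
#' @param seed integer seed for the jittered starts.
#' @return an object of class `gps_prior` with elements `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `w`, `loglik`, `converged`.
#' @export
fit_gps_prior <- function(a, E, min_pairs = 50, n_starts = 8, seed = 1L) {
  ok <- is.finite(a) & is.finite(E) & E > 0
  a <- a[ok]; E <- E[ok]
  if (length(a) < min_pairs || all(a == 0)) {
    message("fit_gps_prior: insufficient data, using default prior")
    return(default_gps_prior())
  }
  starts <- rbind(
    c(log(0.2), log(0.1), log(2), log(4), stats::qlogis(1 / 3)),
    c(log(1), log(1), log(1), log(1), 0),
    c(log(0.5), log(0.5), log(5), log(5), stats::qlogis(0.2)))
  if (n_starts > nrow(starts)) {
    set.seed(seed)
    extra <- matrix(stats::rnorm((n_starts - nrow(starts)) * 5, 0, 1.5),
                    ncol = 5)
    starts <- rbind(starts, extra)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], function(th) -gps_loglik(th, a, E),
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    fail("fit_gps_prior", "optimizer failed on all starts")
  th <- best$par
  structure(list(alpha1 = exp(th[1]), beta1 = exp(th[2]),
                 alpha2 = exp(th[3]), beta2 = exp(th[4]),
                 w = stats::plogis(th[5]), loglik = -best$value,
                 converged = best$convergence == 0, default = FALSE),
            class = "gps_prior")
}

#' @export
print.gps_prior <- function(x, ...) {
  cat("Gamma Poisson shrinker prior (two-gamma mixture)\n")
  cat(sprintf("  component 1: Gamma(%.4g, %.4g), weight %.3f\n",
              x$alpha1, x$beta1, x$w))
  cat(sprintf("  component 2: Gamma(%.4g, %.4g), weight %.3f\n",
              x$alpha2, x$beta2, 1 - x$w))
  if (isTRUE(x$default)) cat("  (default prior, not fitted)\n")
  else cat(sprintf("  log marginal likelihood %.3f\n", x$loglik))
  invisible(x)
}

#' Empirical Bayes geometric mean and its 5th percentile
#'
#' Under the two-gamma-mixture prior the posterior of the relative
#' reporting rate lambda given (a, E) is again a two-gamma mixture with
#' components Gamma(alpha_j + a, beta_j + E) and weights proportional to the
#' prior weight times the component's marginal.  EBGM = 2^E[log2 lambda | a]
#' (computed via the digamma function) and EBGM05 is the 5th percentile of
#' the posterior mixture, found by bisection on its CDF to 1e-6.
#'
#' @param a observed pair count(s).
#' @param E baseline expectation(s), positive.
#' @param prior a `gps_prior`.
#' @return data.frame with columns `ebgm`, `ebgm05`.
#' @export
#' @examples
#' prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
#'                         w = 1 - 1e-12), class = "gps_prior")
#' ebgm(6, 3.2, prior)
ebgm <- function(a, E, prior) {
  if (any(!is.finite(E)) || any(E <= 0))
    fail("ebgm", "`E` must be positive")
  n <- max(length(a), length(E))
  a <- rep_len(a, n); E <- rep_len(E, n)
  l1 <- lnb(a, E, prior$alpha1, prior$beta1) + log(prior$w)
  l2 <- lnb(a, E, prior$alpha2, prior$beta2) + log1p(-prior$w)
  m <- pmax(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  elog <- q1 * (digamma(a + prior$alpha1) - log(prior$beta1 + E)) +
    (1 - q1) * (digamma(a + prior$alpha2) - log(prior$beta2 + E))
  ebgm_v <- exp(elog)
  post_cdf <- function(x, i)
    q1[i] * stats::pgamma(x, a[i] + prior$alpha1, rate = prior$beta1 + E[i]) +
      (1 - q1[i]) * stats::pgamma(x, a[i] + prior$alpha2,
                                  rate = prior$beta2 + E[i])
  ebgm05 <- vapply(seq_len(n), function(i) {
    hi <- max(ebgm_v[i], 1)
    while (post_cdf(hi, i) < 0.05) hi <- hi * 2
    lo <- 0
    while (hi - lo > 1e-6 * max(1, hi)) {   # bisection to 1e-6
      mid <- (lo + hi) / 2
      if (post_cdf(mid, i) < 0.05) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  data.frame(ebgm = ebgm_v, ebgm05 = ebgm05)
}

# ---------------------------------------------------------------------------

#' Apply the per-method signal thresholds
#'
#' The conventional thresholds: ROR lower 95% bound > 1; PRR >= 2 together
#' with chi-squared > 4; IC025 > 0; EBGM05 > 2.  `combined_any` is their OR,
#' `combined_all` their AND.  Terms with `a < min_count` are not evaluated
#' (`assessed = FALSE`, flags `NA`).
#'
#' @param result a `signal_table` (or data.frame with columns `a`,
#'   `ror_low`, `prr`, `chi2`, `ic025`, `ebgm05`).
#' @param min_count minimum case count gate (default 3).
#' @return the input with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps`, `combined_any`, `combined_all`, `assessed`.
#' @export
flag_signals <- function(result, min_count = 3) {
  assessed <- !is.na(result$a) & result$a >= min_count
  f_ror <- ifelse(assessed, !is.na(result$ror_low) & result$ror_low > 1, NA)
  f_prr <- ifelse(assessed, !is.na(result$prr) & !is.na(result$chi2) &
                    result$prr >= 2 & result$chi2 > 4, NA)
  f_bcp <- ifelse(assessed, !is.na(result$ic025) & result$ic025 > 0, NA)
  f_gps <- ifelse(assessed, !is.na(result$ebgm05) & result$ebgm05 > 2, NA)
  result$flag_ror <- as.logical(f_ror)
  result$flag_prr <- as.logical(f_prr)
  result$flag_bcpnn <- as.logical(f_bcp)
  result$flag_mgps <- as.logical(f_gps)
  result$combined_any <- result$flag_ror | result$flag_prr |
    result$flag_bcpnn | result$flag_mgps
  result$combined_all <- result$flag_ror & result$flag_prr &
    result$flag_bcpnn & result$flag_mgps
  result$assessed <- assessed
  result
}

#' Four-method disproportionality analysis
#'
#' For every term in the cohort's pair set, builds the 2x2 table against the
#' background and computes ROR with 95% CI, PRR with 95% CI and chi-squared,
#' the BCPNN information component with IC025, and EBGM with EBGM05 under a
#' gamma-Poisson-shrinker prior fitted to the supplied pair grid (or the
#' default prior).  Per-method signal flags follow [flag_signals()].
#'
#' @param cohort_pairs,background_pairs unique (case, term) pair sets from
#'   [event_pairs()]; the background must exclude the cohort's cases.
#' @param level `"pt"` or `"soc"` label recorded on the result.
#' @param min_count minimum `a` before a term is assessed.
#' @param prior a `gps_prior`, or `NULL` to fit one on the per-term counts
#'   of this analysis.
#' @return a `signal_table`: a data.frame with one row per term and columns
#'   `term`, `a`, `ror`, `ror_low`, `ror_high`, `prr`, `prr_low`,
#'   `prr_high`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`, the flag columns,
#'   and attributes `level`, `N`, `prior`.
#' @export
disproportionality <- function(cohort_pairs, background_pairs,
                               level = "pt", min_count = 3, prior = NULL) {
  n_coh <- nrow(cohort_pairs)
  n_bg <- nrow(background_pairs)
  terms <- sort(unique(cohort_pairs$term))
  a <- as.integer(table(factor(cohort_pairs$term, levels = terms)))
  cc <- as.integer(table(factor(background_pairs$term, levels = terms)))
  b <- n_coh - a
  d <- n_bg - cc
  N <- n_coh + n_bg
  E <- (a + b) * (a + cc) / N
  if (is.null(prior)) {
    prior <- if (length(a) >= 50) fit_gps_prior(a, E)
             else default_gps_prior()
  }
  rr <- t(vapply(seq_along(terms), function(i)
    ror(c(a[i], b[i], cc[i], d[i])), numeric(3)))
  pr <- t(vapply(seq_along(terms), function(i)
    prr_chi2(c(a[i], b[i], cc[i], d[i])), numeric(4)))
  ic <- t(vapply(seq_along(terms), function(i)
    bcpnn_ic(c(a[i], b[i], cc[i], d[i])), numeric(2)))
  eb <- ebgm(a, pmax(E, .Machine$double.eps), prior)
  out <- data.frame(term = terms, a = a,
                    ror = rr[, 1], ror_low = rr[, 2], ror_high = rr[, 3],
                    prr = pr[, 1], prr_low = pr[, 2], prr_high = pr[, 3],
                    chi2 = pr[, 4], ic = ic[, 1], ic025 = ic[, 2],
                    ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
                    stringsAsFactors = FALSE)
  out <- flag_signals(out, min_count = min_count)
  out <- out[order(-out$a, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, level = level, N = N, prior = prior,
            class = c("signal_table", "data.frame"))
}

#' @export
print.signal_table <- function(x, digits = 2, max_rows = 25, ...) {
  cat(sprintf("Disproportionality signals at %s level (N = %s pairs)\n",
              toupper(attr(x, "level") %||% "?"),
              format(attr(x, "N"), big.mark = ",")))
  f <- function(v) formatC(v, digits = digits, format = "f")
  show <- utils::head(x, max_rows)
  disp <- data.frame(
    term = show$term, a = show$a,
    `ROR (95% CI)` = sprintf("%s (%s, %s)", f(show$ror), f(show$ror_low),
                             f(show$ror_high)),
    `PRR (chi2)` = sprintf("%s (%s)", f(show$prr), f(show$chi2)),
    `IC (IC025)` = sprintf("%s (%s)", f(show$ic), f(show$ic025)),
    `EBGM (EBGM05)` = sprintf("%s (%s)", f(show$ebgm), f(show$ebgm05)),
    signal = ifelse(is.na(show$combined_any), "n/a",
                    ifelse(show$combined_all, "all",
                           ifelse(show$combined_any, "any", "-"))),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  if (nrow(x) > max_rows)
    cat(sprintf("... and %d more terms\n", nrow(x) - max_rows))
  invisible(x)
}

#' Write a signal table in the published column layout
#'
#' @param x a `signal_table`.
#' @param path output path (tab-separated).
#' @export
write_signal_table <- function(x, path) {
  f <- function(v) formatC(v, digits = 2, format = "f")
  out <- data.frame(
    term = x$term, case_reports = x$a,
    ror_ci = sprintf("%s (%s, %s)", f(x$ror), f(x$ror_low), f(x$ror_high)),
    prr_ci = sprintf("%s (%s, %s)", f(x$prr), f(x$prr_low), f(x$prr_high)),
    chi2 = f(x$chi2), ic_ic025 = sprintf("%s (%s)", f(x$ic), f(x$ic025)),
    ebgm_ebgm05 = sprintf("%s (%s)", f(x$ebgm), f(x$ebgm05)),
    flag_ror = x$flag_ror, flag_prr = x$flag_prr,
    flag_bcpnn = x$flag_bcpnn, flag_mgps = x$flag_mgps,
    combined_any = x$combined_any, combined_all = x$combined_all,
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}
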