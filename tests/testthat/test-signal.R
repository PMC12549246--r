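test_that("ROR matches hand-computed values and symmetry", {
  expect_equal(unname(ror(contingency_table(10, 10, 10, 10))["est"]), 1)
  r <- ror(contingency_table(6, 14, 10, 70))
  expect_equal(unname(r["est"]), 3, tolerance = 1e-12)
  expect_equal(unname(r["low"]), 0.937, tolerance = 1e-3)
  expect_equal(unname(r["high"]), 9.603, tolerance = 1e-3)
  # zero cell: undefined sentinel, no continuity correction
  expect_true(all(is.na(ror(contingency_table(0, 14, 10, 70)))))
})

test_that("PRR, its CI and the uncorrected chi-squared match hand arithmetic", {
  p0 <- prr_chi2(contingency_table(2, 8, 20, 80))
  expect_equal(unname(p0["est"]), 1)
  expect_equal(unname(p0["chi2"]), 0)
  p <- prr_chi2(contingency_table(6, 14, 10, 70))
  expect_equal(unname(p["est"]), 2.4, tolerance = 1e-12)
  expect_equal(unname(p["low"]), 0.990, tolerance = 1e-3)
  expect_equal(unname(p["high"]), 5.819, tolerance = 1e-3)
  expect_equal(unname(p["chi2"]), 3.646, tolerance = 1e-3)
  expect_true(all(is.na(prr_chi2(contingency_table(6, 14, 0, 70)))))
})

test_that("information component and its credible bound follow the closed forms", {
  expect_equal(unname(bcpnn_ic(contingency_table(1, 9, 9, 81))["ic"]), 0)
  ic <- bcpnn_ic(contingency_table(6, 14, 10, 70))
  expect_equal(unname(ic["ic"]), 0.9069, tolerance = 1e-4)
  expect_equal(unname(ic["ic025"]), -0.5764, tolerance = 1e-4)
  expect_true(all(is.na(bcpnn_ic(contingency_table(0, 14, 10, 70)))))
})

test_that("contingency tables equal a brute-force nested-loop count", {
  cp <- data.frame(caseid = c("1", "1", "2", "2"),
                   term = c("Pty", "Ptz", "Pty", "Ptz"))
  tab <- build_contingency(cp[1:2, ], cp[3:4, ], "Pty")
  expect_equal(as.vector(unclass(tab)), c(1, 1, 1, 1))
  # empty cohort
  tab0 <- build_contingency(cp[0, ], cp, "Pty")
  expect_equal(as.vector(unclass(tab0))[1:2], c(0, 0))
  # randomized batches against the oracle
  set.seed(42)
  for (i in 1:5) {
    n <- sample(200:2000, 1)
    pairs <- unique(data.frame(
      caseid = as.character(sample.int(n %/% 2, n, replace = TRUE)),
      term = sample(paste0("PT", 1:12), n, replace = TRUE)))
    split_at <- sample(seq_len(nrow(pairs) - 1), 1)
    cohort <- pairs[seq_len(split_at), ]
    backg <- pairs[-seq_len(split_at), ]
    for (tm in sample(paste0("PT", 1:12), 3)) {
      expect_equal(as.vector(unclass(build_contingency(cohort, backg, tm))),
                   as.vector(brute_contingency(cohort, backg, tm)))
    }
  }
})

test_that("ROR, PRR and IC always agree on the direction of disproportion", {
  set.seed(7)
  for (i in 1:200) {
    x <- rpois(4, lambda = sample(c(5, 50, 500), 4, replace = TRUE)) + 1
    tab <- contingency_table(x[1], x[2], x[3], x[4])
    s_ror <- sign(ror(tab)["est"] - 1)
    s_prr <- sign(prr_chi2(tab)["est"] - 1)
    s_ic <- sign(bcpnn_ic(tab)["ic"])
    # direction may legitimately be zero at exact independence
    expect_true(all(abs(c(s_ror - s_prr, s_prr - s_ic)) < 1.5))
    expect_true(s_ror * s_prr >= 0 && s_prr * s_ic >= 0)
  }
})

test_that("published rows reconstruct to tables that return the printed PRR", {
  rows <- list(c(a = 314, prr = 8.39), c(a = 521, prr = 1.81),
               c(a = 249, prr = 22.99), c(a = 31, prr = 2.11))
  for (r in rows) {
    tab <- reconstruct_contingency(r["a"], 3396, 55357463, r["prr"])
    back <- prr_chi2(tab)["est"]
    expect_equal(signif(unname(back), 4), signif(unname(r["prr"]), 4))
  }
})

test_that("the negative-binomial marginal reduces to the geometric case", {
  # a=2, alpha=beta=1, E=1: marginal probability (1/2)^(a+1) = 0.125
  expect_equal(exp(faersignal:::lnb(2, 1, 1, 1)), 0.125, tolerance = 1e-12)
})

test_that("the mixture prior fit recovers a known hyperparameter regime", {
  set.seed(123)
  n <- 5000
  truth <- list(alpha1 = 1.2, beta1 = 0.8, alpha2 = 2.0, beta2 = 4.0,
                w = 0.3)
  E <- exp(runif(n, log(0.5), log(50)))
  comp <- runif(n) < truth$w
  lam <- ifelse(comp, rgamma(n, truth$alpha1, rate = truth$beta1),
                rgamma(n, truth$alpha2, rate = truth$beta2))
  a <- rpois(n, lam * E)
  fit <- fit_gps_prior(a, E, seed = 5)
  theta_true <- c(log(truth$alpha1), log(truth$beta1), log(truth$alpha2),
                  log(truth$beta2), qlogis(truth$w))
  ll_true <- faersignal:::gps_loglik(theta_true, a, E)
  expect_gte(fit$loglik, ll_true - 1)    # fitted likelihood beats the truth
  expect_true(fit$converged)
})

test_that("the prior fit falls back to the default on degenerate data", {
  expect_message(p <- fit_gps_prior(rep(0L, 100), rep(1, 100)),
                 "default prior")
  expect_true(p$default)
  expect_message(p2 <- fit_gps_prior(1:10, rep(1, 10)), "default prior")
  expect_true(p2$default)
})

test_that("EBGM shrinks toward the posterior geometric mean correctly", {
  # single-component prior: EBGM = exp(digamma(a+1) - log(E+1)),
  # EBGM05 = gamma quantile = qchisq(0.05, 2(a+1)) / (2(E+1))
  prior <- structure(list(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1,
                          w = 1 - 1e-12), class = "gps_prior")
  e <- ebgm(6, 3.2, prior)
  expect_equal(e$ebgm, 1.549, tolerance = 1e-3)
  expect_equal(e$ebgm05, 0.782, tolerance = 1e-3)
  expect_equal(e$ebgm05, qchisq(0.05, 14) / (2 * 4.2), tolerance = 1e-5)

  # shrinkage limit: a/E = 1 with huge a gives EBGM -> 1
  e2 <- ebgm(50000, 50000, prior)
  expect_equal(e2$ebgm, 1, tolerance = 0.01)
  # large a converges to a/E within 1% under a weak prior
  e3 <- ebgm(20000, 10000, prior)
  expect_equal(e3$ebgm, 2, tolerance = 0.01)
  # monotone nondecreasing in a at fixed E
  grid <- ebgm(0:50, 7.7, prior)
  expect_true(all(diff(grid$ebgm) > -1e-12))
  expect_error(ebgm(5, -1, prior), "`E`")
})

test_that("signal flags follow the four published thresholds and the count gate", {
  base <- data.frame(a = c(10, 10, 10, 2),
                     ror_low = c(1.01, 0.8, 1.2, 9),
                     prr = c(1.5, 2.5, 3, 9), chi2 = c(3, 5, 10, 99),
                     ic025 = c(-0.2, -0.2, 0.3, 9),
                     ebgm05 = c(1.5, 1.5, 3, 9))
  f <- flag_signals(base, min_count = 3)
  # row 1: only ROR positive -> any TRUE, all FALSE
  expect_true(f$combined_any[1]); expect_false(f$combined_all[1])
  expect_true(f$flag_ror[1]); expect_false(f$flag_prr[1])
  # row 2: only PRR positive
  expect_true(f$flag_prr[2]); expect_false(f$flag_ror[2])
  # row 3: all four positive -> flagged in both modes
  expect_true(f$combined_any[3]); expect_true(f$combined_all[3])
  # row 4: below the count gate -> unassessed
  expect_false(f$assessed[4]); expect_true(is.na(f$combined_any[4]))
})

test_that("disproportionality output preserves interval orderings", {
  b <- gen_batch(fast_config(n_cases = 2500, seed = 31))
  fa <- dedup_reports(read_faers(b$dir))
  coh <- select_primary_suspect(fa, drug_dictionary("ibuprofen"))
  bg <- background_reports(fa, coh)
  sig <- disproportionality(event_pairs(coh, "pt"), event_pairs(bg, "pt"))
  ok <- !is.na(sig$ror)
  expect_true(all(sig$ror_low[ok] <= sig$ror[ok] + 1e-12))
  expect_true(all(sig$ror[ok] <= sig$ror_high[ok] + 1e-12))
  expect_true(all(sig$ic025 <= sig$ic, na.rm = TRUE))
  expect_true(all(sig$ebgm05 <= sig$ebgm + 1e-12, na.rm = TRUE))
  expect_equal(attr(sig, "N"),
               nrow(event_pairs(coh, "pt")) + nrow(event_pairs(bg, "pt")))
})
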