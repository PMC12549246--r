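make_onset_cohort <- function(starts, events) {
  n <- length(starts)
  pid <- as.character(seq_len(n) + 100)
  cid <- paste0("C", seq_len(n))
  list(demo = data.frame(primaryid = pid, caseid = cid,
                         fda_dt = "20200101", event_dt = events,
                         age = "50", age_cod = "YR", sex = "F",
                         occp_cod = "MD", reporter_country = "US",
                         occr_country = "US", stringsAsFactors = FALSE),
       drug = data.frame(primaryid = pid, caseid = cid, drug_seq = "1",
                         role_cod = "PS", drugname = "PIROXICAM",
                         prod_ai = "PIROXICAM", stringsAsFactors = FALSE),
       reac = data.frame(primaryid = pid, caseid = cid, pt = "Rash",
                         stringsAsFactors = FALSE),
       ther = data.frame(primaryid = pid, caseid = cid, dsg_drug_seq = "1",
                         start_dt = starts, end_dt = "",
                         stringsAsFactors = FALSE),
       outc = data.frame(primaryid = character(0), caseid = character(0),
                         outc_cod = character(0), stringsAsFactors = FALSE))
}

test_that("onset intervals are calendar differences with reasoned exclusions", {
  coh <- make_onset_cohort(
    starts = c("20040115", "20040115", "", "200401", "20200110"),
    events = c("20040215", "20040110", "20200101", "20200101", "20200110"))
  on <- compute_onsets(coh)
  expect_equal(on$days[1], 31)                      # calendar arithmetic
  expect_equal(on$reason[2], "negative interval")
  expect_equal(on$reason[3], "missing start")
  expect_equal(on$reason[4], "missing start")       # partial date excluded
  expect_equal(on$days[5], 0)                       # same-day kept
  expect_equal(on$fit_days[5], 0.5)                 # mapped for fitting
  expect_equal(sum(on$included) + sum(!on$included), nrow(coh$demo))
})

test_that("the exponential special case is recovered", {
  set.seed(10)
  x <- rexp(2000, rate = 1 / 10)
  fit <- fit_weibull_tto(x)
  expect_equal(fit$shape, 1, tolerance = 0.05)
  expect_equal(fit$scale, mean(x), tolerance = 0.05 * mean(x))
})

test_that("MLE recovers a sub-one shape at the study's sample size", {
  set.seed(2024)
  x <- rweibull(346, 0.4, 79)
  fit <- fit_weibull_tto(x)
  expect_true(abs(fit$shape - 0.4) < 0.05)
  expect_true(abs(fit$scale - 79) < 25)
  expect_true(fit$shape_ci[1] < fit$shape && fit$shape < fit$shape_ci[2])
  expect_true(fit$scale_ci[1] < fit$scale && fit$scale < fit$scale_ci[2])
})

test_that("the Newton solution dominates a fine grid search", {
  set.seed(77)
  x <- rweibull(50, 0.7, 30)
  fit <- fit_weibull_tto(x)
  shapes <- seq(max(fit$shape - 0.15, 0.01), fit$shape + 0.15, by = 1e-3)
  scales <- seq(max(fit$scale - 15, 0.1), fit$scale + 15, by = 0.1)
  ll <- function(k, lam) sum(dweibull(x, k, lam, log = TRUE))
  best_grid <- max(vapply(shapes, function(k)
    max(vapply(scales, function(lam) ll(k, lam), numeric(1))), numeric(1)))
  expect_gte(fit$loglik, best_grid - 1e-8)
})

test_that("Wald intervals on the shape have near-nominal coverage", {
  hits <- 0L
  for (s in 1:200) {
    set.seed(s)
    f <- fit_weibull_tto(rweibull(346, 0.4, 79))
    if (f$shape_ci[1] <= 0.4 && 0.4 <= f$shape_ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 180L)   # 90%
  expect_lte(hits, 196L)   # 98%
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_weibull_tto(rep(5, 50)), "identical")
  expect_error(fit_weibull_tto(c(1, 2, 3)), "at least")
  expect_error(fit_weibull_tto(c(rep(1.5, 20), -1)), "positive")
})

test_that("cross-check against an independent Weibull fitter", {
  set.seed(99)
  x <- rweibull(300, 0.6, 45)
  fit <- fit_weibull_tto(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(unname(coef(fit)["shape"]), unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(unname(coef(fit)["scale"]), unname(ref$estimate["scale"]),
               tolerance = 1e-3)
  expect_equal(as.numeric(logLik(fit)), as.numeric(ref$loglik),
               tolerance = 1e-6)
})

test_that("onset summaries use order-statistic interpolation and proper bins", {
  s1 <- onset_summary(7)
  expect_equal(unname(s1$median), 7)
  expect_equal(unname(s1$iqr), c(7, 7))
  s2 <- onset_summary(c(1, 2, 7, 30, 100))
  expect_equal(unname(s2$median), 7)
  expect_equal(sum(s2$bins$n), 5)
  expect_equal(s2$bins$n, c(4, 0, 0, 1))   # day 30 falls in the first month
  # empirical CDF is nondecreasing and ends at 1
  expect_true(all(diff(s2$ecdf$cum_fraction) >= 0))
  expect_equal(s2$ecdf$cum_fraction[nrow(s2$ecdf)], 1)
})

test_that("model predictions follow the Weibull closed forms", {
  fit <- structure(list(shape = 0.4, scale = 79), class = "weibull_tto")
  expect_equal(predict(fit, 30), 0.4928, tolerance = 1e-4)
  expect_equal(predict(fit, 30), 1 - exp(-(30 / 79)^0.4), tolerance = 1e-12)
  expect_equal(predict(fit, 30, type = "survival"), 1 - predict(fit, 30))
  set.seed(1)
  sim <- simulate(fit, 50000)
  expect_equal(mean(sim <= 30), 0.4928, tolerance = 0.01)
})

test_that("exclusions never enter the likelihood", {
  coh <- make_onset_cohort(
    starts = c(rep("20200101", 30), rep("", 5)),
    events = c(format(as.Date("2020-01-01") + c(1:30), "%Y%m%d"),
               rep("20200301", 5)))
  on <- compute_onsets(coh)
  expect_equal(sum(on$included), 30)
  fit <- fit_weibull_tto(on)
  expect_equal(fit$n, 30)
  s <- onset_summary(on)
  expect_equal(s$n + s$n_excluded, 35)
})
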