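test_that("mean-odds stratification follows the documented tie rule", {
  expect_equal(stratify_by_mean_odds(c(1, 3)), c("low", "high"))
  expect_warning(s <- stratify_by_mean_odds(rep(2, 4)), "identical")
  expect_equal(s, rep("low", 4))
  # invariant under positive rescaling
  set.seed(1)
  o <- rexp(30)
  expect_equal(stratify_by_mean_odds(o), stratify_by_mean_odds(5 * o))
  expect_error(stratify_by_mean_odds(1), "at least 2")
})

test_that("Kaplan-Meier estimates match the hand product-limit", {
  km <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  censored <- km_fit(c(5, 8, 2), c(0, 0, 0))
  expect_true(all(censored$surv == 1))

  # 6-subject instance with interleaved censoring, against a literal
  # product computation
  time <- c(1, 2, 2, 4, 5, 7); event <- c(1, 1, 0, 1, 0, 1)
  km6 <- km_fit(time, event)
  # event times 1 (1 of 6 at risk), 2 (1 of 5), 4 (1 of 3), 7 (1 of 1)
  hand <- cumprod(c(5 / 6, 4 / 5, 2 / 3, 0))
  expect_equal(km6$surv[km6$n_event > 0], hand, tolerance = 1e-12)

  # without censoring KM equals the empirical survival function
  set.seed(4)
  t0 <- sort(rexp(25))
  kme <- km_fit(t0, rep(1, 25))
  expect_equal(kme$surv, 1 - seq_len(25) / 25, tolerance = 1e-12)
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank statistic matches the O-E computation by hand", {
  # identical groups: statistic 0, p = 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p.value, 1, tolerance = 1e-12)

  # small untied instance, hand evaluation of observed-minus-expected
  tg <- c(1, 3, 5, 2, 4, 6); ev <- rep(1, 6)
  gr <- rep(c("a", "b"), each = 3)
  oe <- 0; v <- 0
  for (tt in sort(tg)) {
    at <- tg >= tt
    n1 <- sum(at & gr == "a"); ntot <- sum(at)
    d <- sum(tg == tt)
    oe <- oe + sum(tg == tt & gr == "a") - d * n1 / ntot
    if (ntot > 1) {
      v <- v + d * (n1 / ntot) * (1 - n1 / ntot) * (ntot - d) / (ntot - 1)
    }
  }
  lr <- logrank_test(tg, ev, gr)
  expect_equal(lr$chisq, oe^2 / v, tolerance = 1e-10)

  expect_error(logrank_test(t0, rep(0, 4), c("a", "a", "b", "b")),
               "no events")
})

test_that("log-rank invariant to common monotone time transforms", {
  set.seed(6)
  tt <- rexp(40); ev <- rbinom(40, 1, 0.8); gr <- rep(c("a", "b"), 20)
  a <- logrank_test(tt, ev, gr)
  b <- logrank_test(log1p(tt) * 10, ev, gr)
  expect_equal(a$chisq, b$chisq, tolerance = 1e-12)
})

test_that("Cox log-hazard maximizes the partial likelihood", {
  # identical groups: coefficient essentially zero
  t0 <- c(1, 2, 3, 4, 5, 6.5)
  cx0 <- cox_hr_binary(c(t0, t0), rep(1, 12),
                       rep(c("high", "low"), each = 6))
  expect_lt(abs(cx0$b), 1e-6)
  expect_true(cx0$ci[1] <= cx0$hr && cx0$hr <= cx0$ci[2])

  # untied instance: compare with a golden-section maximization of the
  # hand-coded partial likelihood
  set.seed(2)
  tt <- rexp(30) * ifelse(rep(c(0, 1), 15) == 1, 0.4, 1)
  ev <- rep(1, 30)
  z <- rep(c(0, 1), 15)
  pll <- function(b) {
    s <- 0
    for (i in which(ev == 1)) {
      risk <- tt >= tt[i]
      s <- s + b * z[i] - log(sum(exp(b * z[risk])))
    }
    s
  }
  opt <- stats::optimize(pll, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum
  cx <- cox_hr_binary(tt, ev, ifelse(z == 1, "low", "high"),
                      reference = "high")
  expect_equal(cx$b, opt, tolerance = 1e-6)

  # score equation residual at the fitted value is ~0
  h <- 1e-5
  expect_lt(abs((pll(cx$b + h) - pll(cx$b - h)) / (2 * h)), 1e-6)

  # monotone likelihood flagged
  mono <- cox_hr_binary(c(1, 2, 3, 4), c(1, 1, 0, 0),
                        c("high", "high", "low", "low"))
  expect_false(mono$converged)
  expect_equal(mono$hr, Inf)
})

test_that("Cox recovers a generative hazard ratio with CI coverage", {
  hits <- 0
  est <- numeric(10)
  for (s in 1:10) {
    sv <- simulate_survival(500, 0.002, 0.006, censor_rate = 0.2, seed = s)
    cx <- cox_hr_binary(sv$time, sv$event, sv$group, reference = "R")
    est[s] <- cx$hr
    if (cx$ci[1] <= 3 && 3 <= cx$ci[2]) hits <- hits + 1
  }
  expect_gt(median(est), 2.4)
  expect_lt(median(est), 3.8)
  expect_gte(hits, 9)
})

test_that("survival reports assemble KM, log-rank, and Cox per stratum", {
  coh <- simulate_cohort(small_sim_config(seed = 55))
  pre <- coh$samples[coh$samples$timepoint == "PRE", ]
  pred <- data.frame(sample_id = pre$sample_id,
                     stratum = ifelse(pre$response == "R", "high", "low"))
  rep_pfs <- survival_report(pred, pre, "pfs")
  expect_named(rep_pfs, c("km", "logrank", "cox", "n"))
  expect_lt(rep_pfs$logrank$p.value, 0.05) # strata follow true response
  expect_gt(rep_pfs$cox$hr, 1)             # low stratum progresses faster
  expect_null(survival_report(pred, pre[, c("sample_id", "recist")], "os"))
})
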