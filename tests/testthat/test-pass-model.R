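test_that("PASS score is the |beta|-normalized weighted average", {
  X <- matrix(c(0.2, 0.6), 2, 1, dimnames = list(c("P1", "P2"), "s1"))
  sig <- list(beta = c(P1 = 1, P2 = 1))
  expect_equal(unname(pass_score(sig, X)), 0.4)

  one <- list(beta = c(P1 = 2, P2 = 0))
  X2 <- matrix(c(0.3, 0.9), 2, 1, dimnames = list(c("P1", "P2"), "s1"))
  expect_equal(unname(pass_score(one, X2)), 0.3) # zero-beta row inert

  set.seed(2)
  Xr <- matrix(rnorm(12), 3, 4,
               dimnames = list(c("P1", "P2", "P3"), sprintf("s%d", 1:4)))
  b <- list(beta = c(P1 = 0.5, P2 = -1.2, P3 = 2))
  scaled <- list(beta = b$beta * 7)
  expect_equal(pass_score(b, Xr), pass_score(scaled, Xr), tolerance = 1e-12)

  expect_error(pass_score(list(beta = c(P1 = 0)), Xr), "all coefficients")
  expect_error(pass_score(list(beta = c(P9 = 1)), Xr), "lacks pathway")
})

test_that("odds follow the logistic linear predictor exactly", {
  X <- matrix(c(0, 0.5), 2, 1, dimnames = list(c("P1", "P2"), "s1"))
  m0 <- list(a0 = 0, beta = c(P1 = 1, P2 = 0))
  expect_equal(unname(sample_odds(m0, X)), 1) # eta = 0

  m3 <- list(a0 = log(3), beta = c(P1 = 1, P2 = 0))
  expect_equal(unname(sample_odds(m3, X)), 3)

  # odds strictly increasing in the PASS score when all beta >= 0
  set.seed(5)
  Xr <- matrix(runif(40), 2, 20, dimnames = list(c("P1", "P2"), NULL))
  colnames(Xr) <- sprintf("s%02d", 1:20)
  m <- list(a0 = -1, beta = c(P1 = 0.8, P2 = 1.7))
  sc <- pass_score(m, Xr)
  od <- sample_odds(m, Xr)
  expect_true(all(diff(od[order(sc)]) > 0))
  # but odds are not invariant to rescaling beta, unlike the score
  expect_false(isTRUE(all.equal(sample_odds(list(a0 = -1, beta = m$beta * 2),
                                            Xr), od)))
})

test_that("Youden cutoff maximizes J and matches exhaustive search", {
  expect_equal(youden_cutoff(c(0.9, 0.8, 0.1, 0.2),
                             c("R", "R", "NR", "NR")), 0.5)
  expect_equal(youden_cutoff(rep(0.3, 6), rep(c("R", "NR"), 3)), -Inf)

  brute_youden <- function(scores, labels) {
    u <- sort(unique(scores))
    thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
    best <- -Inf; arg <- NA
    for (t in thr) {
      j <- mean(scores[labels == "R"] > t) +
        mean(scores[labels == "NR"] <= t) - 1
      if (j > best + 1e-15) { best <- j; arg <- t }
    }
    arg
  }
  set.seed(9)
  for (i in 1:20) {
    sc <- round(rnorm(20), 2)
    lb <- sample(c("R", "NR"), 20, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_identical(youden_cutoff(sc, lb), brute_youden(sc, lb))
  }
  expect_error(youden_cutoff(1:4, rep("R", 4)), "both classes")
})

test_that("training recovers driver pathways and is reproducible", {
  cfg <- small_sim_config(seed = 71)
  coh <- simulate_cohort(cfg)
  opts <- pass_options(n_perm = 1000, seed = 71)
  sig <- train_signature(coh$counts, coh$samples, coh$sets, coh$lengths,
                         "ON", opts)
  expect_s3_class(sig, "pass_signature")
  expect_lte(nrow(sig$candidates), 15)
  expect_gte(length(sig$selected), 2)
  expect_gte(length(intersect(sig$selected, coh$truth$driver_pathways)), 2)
  expect_true(all(sig$selected %in% sig$candidates$pathway))
  expect_true(is.finite(sig$cutoff))

  sig2 <- train_signature(coh$counts, coh$samples, coh$sets, coh$lengths,
                          "ON", opts)
  expect_identical(sig$beta, sig2$beta)
  expect_identical(sig$cutoff, sig2$cutoff)

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, f1)
  write_signature(sig2, f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical artifact

  back <- read_signature(f1)
  expect_equal(back$beta, sig$beta, tolerance = 1e-12)
  expect_equal(back$cutoff, sig$cutoff)
})

test_that("time-response models share one candidate pathway list", {
  coh <- simulate_cohort(small_sim_config(seed = 83))
  opts <- pass_options(n_perm = 1000, seed = 83)
  ts <- train_time_signatures(coh$counts, coh$samples, coh$sets,
                              coh$lengths, opts)
  expect_identical(ts$pre$candidates$pathway, ts$on$candidates$pathway)
  expect_identical(ts$pre$leading_edge, ts$on$leading_edge)
  expect_equal(ts$pre$timepoint, "PRE")
  expect_equal(ts$on$timepoint, "ON")

  no_r <- coh$samples
  no_r$response[no_r$timepoint == "ON"] <- "NR"
  expect_error(train_time_signatures(coh$counts, no_r, coh$sets,
                                     coh$lengths, opts),
               "responders required at both timepoints")
})

test_that("scoring a cohort with its own training data is self-consistent", {
  coh <- simulate_cohort(small_sim_config(seed = 71))
  opts <- pass_options(n_perm = 1000, seed = 71)
  sig <- train_signature(coh$counts, coh$samples, coh$sets, coh$lengths,
                         "ON", opts)
  on_ids <- coh$samples$sample_id[coh$samples$timepoint == "ON"]
  cts <- coh$counts[, on_ids]
  attr(cts, "unit") <- "counts"
  pred <- score_cohort(sig, cts, coh$lengths)
  expect_equal(stats::setNames(pred$score, pred$sample_id),
               sig$training$scores[pred$sample_id], tolerance = 1e-12)
  lab <- coh$samples$response[match(pred$sample_id, coh$samples$sample_id)]
  expect_equal(roc_auc(pred$score, lab)$auc, sig$training$auc)
  expect_true(all(pred$predicted %in% c("R", "NR")))
  expect_true(all(pred$stratum %in% c("high", "low")))
})

test_that("leading-edge genes missing from a cohort are handled by policy", {
  coh <- simulate_cohort(small_sim_config(seed = 71))
  opts <- pass_options(n_perm = 1000, seed = 71)
  sig <- train_signature(coh$counts, coh$samples, coh$sets, coh$lengths,
                         "ON", opts)
  le1 <- sig$leading_edge[[1]]
  drop_few <- utils::head(le1, max(1, floor(length(le1) * 0.2)))
  cts <- coh$counts[setdiff(rownames(coh$counts), drop_few), ]
  attr(cts, "unit") <- "counts"
  expect_warning(score_cohort(sig, cts, coh$lengths), "dropped")

  drop_most <- utils::head(le1, ceiling(length(le1) * 0.6))
  cts2 <- coh$counts[setdiff(rownames(coh$counts), drop_most), ]
  attr(cts2, "unit") <- "counts"
  expect_error(score_cohort(sig, cts2, coh$lengths), "more than half")
})
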