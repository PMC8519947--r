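test_that("AUC counts concordant pairs and equals the trapezoid area", {
  perfect <- roc_auc(c(3, 4, 1, 2), c("R", "R", "NR", "NR"))
  expect_equal(perfect$auc, 1)

  mix <- roc_auc(c(0.8, 0.4, 0.6, 0.2), c("R", "R", "NR", "NR"))
  expect_equal(mix$auc, 0.75) # 3 of 4 pairs concordant

  neg <- roc_auc(-c(0.8, 0.4, 0.6, 0.2), c("R", "R", "NR", "NR"))
  expect_equal(neg$auc, 1 - 0.75)

  trapezoid <- function(rc) {
    sum(diff(rc$fpr) * (rc$tpr[-1] + rc$tpr[-length(rc$tpr)]) / 2)
  }
  set.seed(3)
  for (i in 1:30) {
    n <- sample(6:60, 1)
    sc <- sample(round(rnorm(n), 1)) # ties likely
    lb <- sample(c("R", "NR"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    rc <- roc_auc(sc, lb)
    expect_equal(rc$auc, trapezoid(rc), tolerance = 1e-12)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
  }
  expect_error(roc_auc(1:3, rep("R", 3)), "both classes")
})

test_that("confusion metrics implement accuracy and MCC with guards", {
  perfect <- confusion_metrics(c("R", "NR"), c("R", "NR"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)

  m <- confusion_metrics(
    pred = c(rep("R", 4), rep("NR", 6)),
    truth = c(rep("R", 3), "NR", rep("R", 2), rep("NR", 4)))
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 4, 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$mcc, 10 / sqrt(600))

  allr <- confusion_metrics(rep("R", 5), c("R", "R", "NR", "NR", "NR"))
  expect_equal(allr$mcc, 0) # degenerate denominator guard

  # symmetric under simultaneous class swap
  swap <- function(x) ifelse(x == "R", "NR", "R")
  p <- c("R", "NR", "R", "NR", "R"); t <- c("R", "R", "NR", "NR", "R")
  expect_equal(confusion_metrics(p, t)$mcc,
               confusion_metrics(swap(p), swap(t))$mcc)
  expect_error(confusion_metrics("R", c("R", "NR")), "equal length")
})

test_that("rank-sum test handles sidedness, ties, and small samples", {
  sep <- rank_sum_test(c(1, 2, 3), c(4, 5, 6), "greater")
  expect_equal(sep$statistic, 0)
  expect_gt(sep$p.value, 0.5)
  expect_lt(rank_sum_test(c(4, 5, 6), c(1, 2, 3), "greater")$p.value, 0.06)

  # invariant under common strictly increasing transforms
  set.seed(7)
  x <- rnorm(15); y <- rnorm(12, 0.5)
  a <- rank_sum_test(x, y, "two.sided")
  b <- rank_sum_test(exp(x), exp(y), "two.sided")
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$statistic, b$statistic)

  # null symmetry: one-sided p near 0.5 on exchangeable data
  set.seed(8)
  ps <- replicate(200, rank_sum_test(rnorm(40), rnorm(40), "greater")$p.value)
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("stratified resampling preserves cohort composition and nulls out", {
  set.seed(12)
  n <- 120
  lab <- rep(c("R", "NR"), times = c(40, 80))
  coh <- rep(c("A", "B"), 60)
  informative <- ifelse(lab == "R", 1, 0) + rnorm(n, sd = 0.8)
  noise <- rnorm(n)
  tab <- rbind(signal = informative, noise = noise)

  cmp <- compare_signatures_resampling(tab, lab, coh, n_rep = 200, seed = 1)
  expect_equal(dim(cmp$auc), c(200L, 2L))
  expect_true(all(cmp$auc >= 0 & cmp$auc <= 1))
  expect_gt(cmp$mean["signal"], cmp$mean["noise"])
  expect_lt(cmp$p["noise"], 0.01)

  # identical signature compared with itself: p near 1/2
  selfcmp <- compare_signatures_resampling(
    rbind(a = informative, b = informative), lab, coh, n_rep = 200, seed = 2)
  expect_lt(abs(selfcmp$p["b"] - 0.5), 0.1)

  # determinism
  again <- compare_signatures_resampling(tab, lab, coh, n_rep = 200, seed = 1)
  expect_identical(cmp$auc, again$auc)

  one_class <- rep("R", n)
  expect_error(compare_signatures_resampling(tab, one_class, coh),
               "both classes")
})

test_that("published-signature engine computes each transform", {
  genes <- c("CD8A", "CSF1R", "GZMA", "PRF1", "IFNG", "STAT1", "X1", "X2")
  tpm <- matrix(c(3, 1, 3, 1, 8, 4, 2, 6,
                  1, 2, 1, 3, 2, 2, 9, 1), 8, 2,
                dimnames = list(genes, c("s1", "s2")))
  tpm <- expression_matrix(tpm, "tpm")
  defs <- list(
    cyt = list(type = "geomean", genes = c("GZMA", "PRF1")),
    onegene = list(type = "mean", genes = "IFNG"),
    ratio = list(type = "ratio", num = "CD8A", den = "CSF1R"),
    pairs = list(type = "pairs",
                 pairs = list(c("X1", "X2"), c("CSF1R", "CD8A"))))
  sc <- published_signature_scores(tpm, defs)
  expect_equal(unname(sc["cyt", "s1"]), sqrt((3 + 1) * (1 + 1)))
  expect_equal(unname(sc["onegene", ]), log2(c(8, 2) + 1))
  expect_equal(unname(sc["ratio", "s1"]), log2(4 / 2))
  expect_equal(unname(sc["pairs", ]), c(2, 0))

  bad <- list(x = list(type = "mean", genes = c("NOPE1", "NOPE2", "IFNG")))
  expect_error(published_signature_scores(tpm, bad, max_missing = 0.5),
               "missing gene")

  bundled <- read_signature_definitions()
  expect_true(all(c("IFNg", "CYT", "CD8A.CSF1R") %in% names(bundled)))
  expect_equal(bundled$CYT$type, "geomean")
})
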