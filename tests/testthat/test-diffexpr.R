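test_that("median-of-ratios size factors match hand-derived cases", {
  cnt <- random_counts(100, 4, seed = 2)
  same <- expression_matrix(matrix(cnt[, 1], 100, 4,
                                   dimnames = dimnames(cnt)), "counts")
  expect_equal(unname(size_factors(same)), rep(1, 4))

  two <- expression_matrix(cbind(s1 = cnt[, 1] + 1L, s2 = 2L * (cnt[, 1] + 1L)),
                           "counts")
  expect_equal(unname(size_factors(two)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # uniform scaling of one sample multiplies its factor by c, others by c^(-1/n)
  sf0 <- size_factors(cnt)
  scaled <- cnt
  scaled[, 3] <- 4L * scaled[, 3]
  scaled <- expression_matrix(scaled, "counts")
  sf1 <- size_factors(scaled)
  expect_equal(sf1[3], sf0[3] * 4 * 4^(-1 / 4), tolerance = 1e-12)
  expect_equal(unname(sf1[-3]), unname(sf0[-3] * 4^(-1 / 4)),
               tolerance = 1e-12)

  allzero <- expression_matrix(
    matrix(c(0L, 5L, 3L, 0L), 2, 2,
           dimnames = list(c("a", "b"), c("s1", "s2"))), "counts")
  expect_error(size_factors(allzero), "cannot normalize")
})

test_that("moment dispersion estimates recover generative truth", {
  set.seed(7)
  n <- 200
  pois <- matrix(rpois(n * 40, 50), 40,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("s%03d", 1:n)))
  pois <- expression_matrix(pois, "counts")
  phi <- estimate_dispersion(pois, rep(1, n))
  expect_true(all(phi >= 0 & phi < 0.05))

  nb <- matrix(rnbinom(n * 40, mu = 100, size = 2), 40,
               dimnames = dimnames(pois))
  nb <- expression_matrix(nb, "counts")
  phi2 <- estimate_dispersion(nb, rep(1, n))
  expect_gt(median(phi2), 0.3)
  expect_lt(median(phi2), 0.7)

  const <- expression_matrix(
    matrix(5L, 3, 10, dimnames = list(letters[1:3], sprintf("s%02d", 1:10))),
    "counts")
  expect_equal(unname(estimate_dispersion(const, rep(1, 10), floor = 1e-8)),
               rep(1e-8, 3))
})

test_that("Wald test is antisymmetric and powered on generative effects", {
  set.seed(3)
  n <- 20
  # 60 genes; the first 10 carry a true log2FC of 2 in group A, the rest
  # are null so normalization stays anchored on non-differential genes
  mu_null <- rep(c(50, 150, 400, 900, 2000), 12)
  cnt <- matrix(rnbinom(60 * 2 * n, mu = mu_null, size = 10), 60,
                dimnames = list(sprintf("g%02d", 1:60),
                                sprintf("s%02d", 1:(2 * n))))
  eff <- sprintf("g%02d", 1:10)
  cnt[eff, 1:n] <- matrix(rnbinom(10 * n, mu = 4 * mu_null[1:10], size = 10),
                          10)
  cnt <- expression_matrix(cnt, "counts")
  sf <- size_factors(cnt)
  disp <- estimate_dispersion(cnt, sf)
  a <- colnames(cnt)[1:n]; b <- colnames(cnt)[(n + 1):(2 * n)]
  de <- nb_wald_test(cnt, sf, disp, a, b)
  hits <- de$gene[de$log2FoldChange > 1 & de$pvalue < 0.05]
  expect_gte(length(intersect(hits, eff)), 0.9 * length(eff))

  swap <- nb_wald_test(cnt, sf, disp, b, a)
  expect_equal(swap$log2FoldChange, -de$log2FoldChange)
  expect_equal(swap$stat, -de$stat)
  expect_equal(swap$pvalue, de$pvalue)

  expect_error(nb_wald_test(cnt, sf, disp, a[1], b), "at least 2")
  expect_error(nb_wald_test(cnt, sf, disp, a, c(a[1], b[-1])), "disjoint")
})

test_that("BH adjustment equals the definitional step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  brute_bh <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- p[ord] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(ord)]
  }
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("volcano selection uses raw p and the stated thresholds", {
  de <- data.frame(gene = c("a", "b", "c"),
                   log2FoldChange = c(1.5, 0.9, 2),
                   pvalue = c(0.01, 0.001, 0.2),
                   padj = c(0.05, 0.01, 0.4))
  expect_equal(significant_up(de), "a")
  expect_equal(significant_up(de[0, ]), character(0))
  expect_equal(significant_up(de, lfc_min = 1e9, p_max = 1e-12), character(0))
})

test_that("ranked lists are deterministic with lexicographic tie-breaks", {
  de <- data.frame(gene = c("A", "B", "C"), stat = c(2, -1, 5))
  expect_equal(names(ranked_list(de)), c("C", "A", "B"))

  tie <- data.frame(gene = c("B", "A"), stat = c(1, 1))
  expect_equal(names(ranked_list(tie)), c("A", "B"))

  shuf <- de[c(3, 1, 2), ]
  expect_identical(ranked_list(de), ranked_list(shuf))

  bad <- data.frame(gene = "A", stat = NaN)
  expect_error(ranked_list(bad), "non-finite.*A")
})
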