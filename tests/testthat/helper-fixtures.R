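# Shared fixture builders. Everything is generated in code; no data files.

# A small, fast simulation configuration for pipeline-level tests.
small_sim_config <- function(seed = 1, ...) {
  sim_config(n_genes = 800, n_pathways = 30, set_size = c(20, 40),
             n_patients = 60, seed = seed, ...)
}

# Random count matrix with proper dimnames.
random_counts <- function(ngene = 50, nsample = 6, lambda = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(ngene * nsample, lambda), ngene,
              dimnames = list(sprintf("g%03d", seq_len(ngene)),
                              sprintf("s%02d", seq_len(nsample))))
  expression_matrix(m, "counts")
}

# A ranked list from explicit scores.
make_ranked <- function(scores, genes = names(scores)) {
  ord <- order(-scores, genes)
  stats::setNames(scores[ord], genes[ord])
}

# Brute-force GSEA running sum: O(N * |S|) literal recomputation of the
# weighted Kolmogorov-Smirnov walk, independent of the package's vectorized
# implementation.
brute_gsea_es <- function(ranked, geneset, p = 1) {
  n <- length(ranked)
  ids <- names(ranked)
  hits <- ids %in% geneset
  m <- sum(hits)
  wsum <- 0
  for (i in seq_len(n)) if (hits[i]) wsum <- wsum + abs(ranked[i])^p
  if (wsum == 0) wsum <- m # equal-weight fallback mirrors the contract
  running <- numeric(n)
  acc_hit <- 0; acc_miss <- 0
  for (i in seq_len(n)) {
    if (hits[i]) {
      acc_hit <- acc_hit + (if (sum(abs(ranked[hits])^p) == 0) 1 else
        abs(ranked[i])^p) / wsum
    } else {
      acc_miss <- acc_miss + 1 / (n - m)
    }
    running[i] <- acc_hit - acc_miss
  }
  # prefer the positive extreme on exact magnitude ties
  unname(if (max(running) >= -min(running)) running[which.max(running)] else
    running[which.min(running)])
}

# Brute-force ssGSEA score for one set in one sample: double loop over
# positions of the descending-expression ordering.
brute_ssgsea <- function(expr, genes, set, alpha = 0.25) {
  n <- length(expr)
  r <- rank(expr, ties.method = "average")
  ord <- order(-expr, genes)
  total <- 0
  for (k in seq_len(n)) {
    num <- 0; den_in <- 0; out <- 0
    for (i in seq_len(n)) {
      g <- ord[i]
      if (genes[g] %in% set) {
        den_in <- den_in + r[g]^alpha
        if (i <= k) num <- num + r[g]^alpha
      } else if (i <= k) {
        out <- out + 1
      }
    }
    m <- sum(genes %in% set)
    total <- total + num / den_in - out / (n - m)
  }
  unname(total)
}

# Weighted elastic-net logistic objective on given (possibly standardized)
# features; used by the proximal-gradient oracle and the KKT checks.
enlr_objective <- function(a0, beta, x, y, w, lambda, alpha) {
  eta <- a0 + drop(x %*% beta)
  loss <- sum(w * (log1p(exp(eta)) - y * eta)) / length(y)
  loss + lambda * ((1 - alpha) * sum(beta^2) / 2 + alpha * sum(abs(beta)))
}

# Independent proximal-gradient (ISTA) minimizer of the same objective.
enlr_prox_oracle <- function(x, y, w, lambda, alpha, iters = 20000) {
  n <- length(y); p <- ncol(x)
  a0 <- 0; beta <- rep(0, p)
  xa <- cbind(1, x)
  lip <- max(eigen(crossprod(xa * sqrt(w / n)) / 4,
                   only.values = TRUE)$values) + lambda * (1 - alpha)
  step <- 1 / lip
  for (it in seq_len(iters)) {
    eta <- a0 + drop(x %*% beta)
    pr <- 1 / (1 + exp(-eta))
    g <- w * (pr - y) / n
    a0 <- a0 - step * sum(g)
    grad <- drop(crossprod(x, g)) + lambda * (1 - alpha) * beta
    z <- beta - step * grad
    beta <- sign(z) * pmax(abs(z) - step * lambda * alpha, 0)
  }
  list(a0 = a0, beta = beta)
}
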