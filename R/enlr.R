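# glmnet emits an advisory for classes under 8 observations; fold-level
# fits on small cohorts trip it routinely, so it is muffled here.
.quiet_glmnet <- function(xs, y01, alpha_mix, w, lambda) {
  withCallingHandlers(
    glmnet::glmnet(xs, y01, family = "binomial", alpha = alpha_mix,
                   weights = w, lambda = lambda, standardize = FALSE,
                   thresh = 1e-12, maxit = 1e6),
    warning = function(cnd) {
      if (grepl("fewer than 8", conditionMessage(cnd))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' Cost-sensitive elastic-net penalized logistic regression
#'
#' Fits the penalized logistic objective
#' `(1/n) sum_i w_i [log(1 + e^eta_i) - y_i eta_i] +
#'  lambda ((1 - alpha_mix) ||beta||^2 / 2 + alpha_mix ||beta||_1)`
#' over a 100-point log-spaced lambda path starting at the smallest lambda
#' for which all coefficients are zero. Observation weights are inversely
#' proportional to class frequency (the cost-sensitivity device for
#' imbalanced classes) and normalized to sum to n. Features are
#' standardized internally; reported coefficients are on the original
#' scale. Lambda is chosen by stratified k-fold cross-validation on the
#' weighted binomial deviance with the one-standard-error rule: the largest
#' lambda whose CV error is within one SE of the minimum.
#'
#' @param X Feature matrix, pathways x samples (features in rows).
#' @param y Response labels, `"R"`/`"NR"` (R is the positive class).
#' @param alpha_mix Elastic-net mixing parameter in [0, 1]
#'   (1 = lasso, 0 = ridge).
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @param nlambda Number of lambda-path points.
#' @param lambda_min_ratio Ratio of the smallest to the largest lambda.
#' @return An `enlr_model` list with intercept `a0` and named coefficient
#'   vector `beta` (original scale), the standardized-scale solution, the
#'   lambda path with CV mean/SE, chosen lambda, fold ids, and weights.
#' @export
fit_enlr <- function(X, y, alpha_mix = 0.5, n_folds = 3, seed = 1L,
                     nlambda = 100, lambda_min_ratio = 1e-4) {
  y01 <- as.numeric(y == "R")
  if (length(unique(y01)) < 2) stop("y must contain both classes", call. = FALSE)
  n <- length(y01)
  if (ncol(X) != n) stop("ncol(X) must equal length(y)", call. = FALSE)
  if (min(table(y01)) < n_folds) {
    stop("fewer samples than folds in one class", call. = FALSE)
  }
  x <- t(X)
  # inverse-class-frequency weights, normalized to sum to n
  tab <- table(y01)
  w <- n / (2 * as.numeric(tab[as.character(y01)]))
  w <- w * n / sum(w)

  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2)) # population sd, as glmnet uses
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)

  ybar <- sum(w * y01) / sum(w)
  alpha_eff <- max(alpha_mix, 1e-3) # lambda_max convention for ridge
  lambda_max <- max(abs(crossprod(xs, w * (y01 - ybar)))) / (n * alpha_eff)
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = nlambda))

  fit <- .quiet_glmnet(xs, y01, alpha_mix, w, lambda)

  # stratified fold assignment
  set.seed(as.integer(seed))
  foldid <- integer(n)
  for (cls in unique(y01)) {
    idx <- which(y01 == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }

  errs <- matrix(NA_real_, n_folds, length(lambda))
  for (f in seq_len(n_folds)) {
    tr <- foldid != f
    cvfit <- .quiet_glmnet(xs[tr, , drop = FALSE], y01[tr], alpha_mix,
                           w[tr], lambda)
    pr <- stats::predict(cvfit, xs[!tr, , drop = FALSE], type = "response")
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    yh <- y01[!tr]; wh <- w[!tr]
    dev <- -2 * (yh * log(pr) + (1 - yh) * log(1 - pr))
    errs[f, seq_len(ncol(pr))] <- colSums(wh * dev) / sum(wh)
  }
  cvm <- colMeans(errs)
  cvsd <- apply(errs, 2, stats::sd) / sqrt(n_folds)
  i_min <- which.min(cvm)
  lambda_min <- lambda[i_min]
  ok <- cvm <= cvm[i_min] + cvsd[i_min]
  lambda_1se <- max(lambda[ok])
  i_1se <- which(lambda == lambda_1se)[1]

  beta_std <- as.numeric(fit$beta[, i_1se])
  a0_std <- fit$a0[i_1se]
  beta <- beta_std / scl
  a0 <- a0_std - sum(beta_std * ctr / scl)
  names(beta) <- rownames(X)

  structure(list(
    a0 = unname(a0), beta = beta, a0_std = unname(a0_std),
    beta_std = stats::setNames(beta_std, rownames(X)),
    alpha_mix = alpha_mix, lambda = lambda, lambda_min = lambda_min,
    lambda_1se = lambda_1se, lambda_choice = lambda_1se,
    cvm = cvm, cvsd = cvsd, foldid = foldid, weights = w,
    center = ctr, scale = scl, seed = as.integer(seed),
    glmnet_fit = fit), class = "enlr_model")
}

#' Smallest lambda with an all-zero coefficient vector
#'
#' KKT stationarity of the null model: all coefficients are zero whenever
#' `lambda >= max_k |sum_i w_i x_ik (y_i - ybar_w)| / (n alpha_mix)` on
#' standardized features.
#'
#' @inheritParams fit_enlr
#' @return The critical lambda value.
#' @export
enlr_lambda_max <- function(X, y, alpha_mix = 0.5) {
  y01 <- as.numeric(y == "R")
  n <- length(y01)
  x <- t(X)
  tab <- table(y01)
  w <- n / (2 * as.numeric(tab[as.character(y01)]))
  w <- w * n / sum(w)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2)); scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  ybar <- sum(w * y01) / sum(w)
  max(abs(crossprod(xs, w * (y01 - ybar)))) / (n * max(alpha_mix, 1e-3))
}

#' @export
print.enlr_model <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat("Elastic-net logistic model (alpha_mix =", x$alpha_mix, ")\n")
  cat("  lambda (1-SE rule):", signif(x$lambda_choice, 4),
      " nonzero coefficients:", nz, "/", length(x$beta), "\n")
  invisible(x)
}
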