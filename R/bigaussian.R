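# Log-densities of a multivariate normal via Cholesky; X is N x K.
mvn_logdens <- function(X, mu, sigma) {
  L <- chol(sigma)
  w <- backsolve(L, t(sweep(X, 2, mu)), transpose = TRUE)
  maha <- colSums(w^2)
  -0.5 * (ncol(X) * log(2 * pi) + 2 * sum(log(diag(L))) + maha)
}

# Seed-stable sampler: mu + Z %*% chol(sigma), Z filled row-major from rnorm.
rmvn_chol <- function(n, mu, sigma) {
  K <- length(mu)
  if (n == 0) return(matrix(numeric(0), 0, K))
  Z <- matrix(stats::rnorm(n * K), n, K)
  sweep(Z %*% chol(sigma), 2, mu, "+")
}

# k-means++-style seeding of two groups for the initial responsibilities.
init_split <- function(X) {
  N <- nrow(X)
  c1 <- sample.int(N, 1)
  d2 <- rowSums(sweep(X, 2, X[c1, ])^2)
  c2 <- if (all(d2 == 0)) sample.int(N, 1) else sample.int(N, 1, prob = d2)
  dA <- rowSums(sweep(X, 2, X[c1, ])^2)
  dB <- rowSums(sweep(X, 2, X[c2, ])^2)
  ifelse(dA <= dB, 1L, 2L)
}

em_once <- function(X, ridge, tol, max_iter) {
  N <- nrow(X); K <- ncol(X)
  assign0 <- init_split(X)
  resp <- cbind(as.numeric(assign0 == 1L), as.numeric(assign0 == 2L))
  # soften hard assignment slightly so both components see all points
  resp <- 0.9 * resp + 0.05
  weights <- rep(0.5, 2)
  means <- matrix(0, 2, K)
  covs <- vector("list", 2)
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter + 1L)) {
    # M-step
    Nk <- colSums(resp)
    if (any(Nk / N < 1e-6)) return(list(degenerate = TRUE))
    weights <- Nk / N
    for (k in 1:2) {
      means[k, ] <- colSums(X * resp[, k]) / Nk[k]
      Xc <- sweep(X, 2, means[k, ])
      covs[[k]] <- crossprod(Xc * resp[, k], Xc) / Nk[k] + diag(ridge, K)
      covs[[k]] <- (covs[[k]] + t(covs[[k]])) / 2
    }
    # E-step
    logd <- vapply(1:2, function(k) {
      log(weights[k]) + mvn_logdens(X, means[k, ], covs[[k]])
    }, numeric(N))
    mx <- pmax(logd[, 1], logd[, 2])
    lse <- mx + log(exp(logd[, 1] - mx) + exp(logd[, 2] - mx))
    ll <- mean(lse)
    trace <- c(trace, ll)
    resp <- exp(logd - lse)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(degenerate = FALSE, weights = weights, means = means, covs = covs,
       loglik = trace, converged = iter <= max_iter)
}

#' Fit a two-component Gaussian mixture to eigenvector scores by EM
#'
#' The generative core of the wavefront model: a linear combination of two
#' full-covariance multivariate Gaussians over the K-dimensional
#' eigenvector scores, fitted by expectation-maximization. Each restart is
#' seeded with a k-means++-style split of the scores; a diagonal ridge
#' keeps component covariances positive definite (essential when K
#' approaches the sample size); the best restart by final log-likelihood
#' is kept. The (mean) log-likelihood trace of every run is non-decreasing,
#' and the fitted mixture's pooled mean equals the sample mean exactly (an
#' EM fixed-point property), so back-transformed synthetic wavefronts are
#' unbiased.
#'
#' @param scores Numeric `N x K` score matrix.
#' @param seed Integer RNG seed for reproducible initialization, or `NULL`.
#' @param tol Convergence tolerance on the gain in mean log-likelihood per
#'   observation; default 1e-8.
#' @param max_iter Maximum EM iterations per restart; default 200.
#' @param restarts Number of random restarts; default 5.
#' @param ridge Diagonal ridge added to each component covariance; default
#'   `1e-6 *` mean score variance.
#' @return Object of class `bigaussian_model`: `weights` (2, summing to 1),
#'   `means` (`2 x K`), `covs` (list of 2 `K x K`), `loglik` (trace of the
#'   best run), `converged`, `ridge`, `seed`, `K`.
#' @export
fit_bigaussian <- function(scores, seed = NULL, tol = 1e-8, max_iter = 200,
                           restarts = 5, ridge = NULL) {
  X <- as.matrix(scores)
  if (!all(is.finite(X))) stop("scores must be finite", call. = FALSE)
  N <- nrow(X); K <- ncol(X)
  if (N < 3) stop("need at least 3 observations", call. = FALSE)
  if (N <= 2 * K) {
    warning(sprintf(paste("sample size (%d) is at most twice the score dimension (%d);",
                          "component covariances rely on the ridge"), N, K))
  }
  if (is.null(ridge)) ridge <- 1e-6 * mean(apply(X, 2, stats::var))
  if (ridge <= 0) ridge <- 1e-12
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- em_once(X, ridge, tol, max_iter)
    if (fit$degenerate) next
    if (is.null(best) || fit$loglik[length(fit$loglik)] >
        best$loglik[length(best$loglik)]) best <- fit
  }
  if (is.null(best)) {
    stop("all EM restarts collapsed to a degenerate component", call. = FALSE)
  }
  structure(list(weights = best$weights, means = best$means, covs = best$covs,
                 loglik = best$loglik, converged = best$converged,
                 ridge = ridge, seed = seed, K = K),
            class = "bigaussian_model")
}

#' Moments of the fitted mixture
#'
#' Closed-form mean `sum(w_k mu_k)` and covariance
#' `sum(w_k (Sigma_k + mu_k mu_k')) - mu mu'` of a fitted mixture.
#'
#' @param model A [fit_bigaussian()] result.
#' @return List with `mean` (K) and `cov` (`K x K`).
#' @export
bigaussian_moments <- function(model) {
  mu <- drop(model$weights %*% model$means)
  S <- matrix(0, model$K, model$K)
  for (k in 1:2) {
    S <- S + model$weights[k] * (model$covs[[k]] + tcrossprod(model$means[k, ]))
  }
  list(mean = mu, cov = S - tcrossprod(mu))
}

#' Sample synthetic eigenvector scores from the fitted mixture
#'
#' Draws a component per row according to the mixture weights, then a
#' multivariate normal deviate from that component. Bit-identical under a
#' fixed seed.
#'
#' @param model A [fit_bigaussian()] result.
#' @param n Number of synthetic observations (`>= 0`).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return `n x K` score matrix.
#' @export
sample_scores <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "bigaussian_model"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(0, n, model$K)
  if (n == 0) return(out)
  comp <- sample.int(2, n, replace = TRUE, prob = model$weights)
  for (k in 1:2) {
    idx <- which(comp == k)
    if (length(idx)) out[idx, ] <- rmvn_chol(length(idx), model$means[k, ],
                                             model$covs[[k]])
  }
  out
}

#' Generate a synthetic accommodative-wavefront cohort
#'
#' Samples `n` score vectors from the fitted mixture and back-transforms
#' them through the eigen-wavefront basis (`E %*% s + mean`; the cohort
#' average is added back after generation so synthetic wavefronts carry
#' the population bias). Each row yields six Zernike coefficient vectors,
#' one per accommodative demand, valid at the per-demand standard pupil
#' diameters.
#'
#' @param basis The [fit_basis()] result the model was fitted on.
#' @param model A [fit_bigaussian()] result with `K == basis$K`.
#' @param n Number of synthetic subjects; default 1000.
#' @param seed Integer RNG seed, or `NULL`.
#' @param standard_pupils Named per-demand pupil diameters (mm) attached to
#'   the cohort; defaults to the [cohort_config()] standards.
#' @return Object of class `synthetic_cohort`: `matrix` (`n x 150`,
#'   demand-major columns), `scores` (`n x K`), `standard_pupils`, `seed`.
#' @export
generate_cohort <- function(basis, model, n = 1000, seed = NULL,
                            standard_pupils = cohort_config()$standard_pupils) {
  stopifnot(inherits(basis, "eigen_basis"), inherits(model, "bigaussian_model"))
  if (model$K != basis$K) {
    stop("basis and model disagree on the number of retained eigenvectors",
         call. = FALSE)
  }
  s <- sample_scores(model, n, seed)
  X <- reconstruct_wavefronts(basis, s)
  colnames(X) <- names(basis$mean)
  if (n > 0) rownames(X) <- sprintf("synth_%04d", seq_len(n))
  structure(list(matrix = X, scores = s, standard_pupils = standard_pupils,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.bigaussian_model <- function(x, ...) {
  sep <- sqrt(sum((x$means[1, ] - x$means[2, ])^2))
  cat(sprintf("bigaussian model over %d eigenvector scores\n", x$K))
  cat(sprintf("  weights: %.3f / %.3f; component mean separation: %.4g\n",
              x$weights[1], x$weights[2], sep))
  cat(sprintf("  final mean log-likelihood: %.6g (%d iterations, %sconverged)\n",
              x$loglik[length(x$loglik)], length(x$loglik),
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d wavefront sets x %d parameters\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
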