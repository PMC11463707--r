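#' Fit an eigen-wavefront basis by covariance PCA
#'
#' Centers the cohort matrix, eigendecomposes its sample covariance
#' (`N - 1` denominator), and retains the smallest number `K` of leading
#' orthonormal eigenvectors whose cumulative eigenvalue fraction reaches
#' the cutoff (default 99.97%, chosen to accommodate the large amplitude
#' gap between defocus and the higher-order terms). Eigenvector signs are
#' fixed deterministically: each is flipped so its largest-magnitude
#' loading is positive.
#'
#' @param X Numeric `N x P` cohort matrix (rows = subjects, columns =
#'   demand-major wavefront parameters), `N >= 2`, finite.
#' @param cutoff Cumulative-variance fraction in (0, 1]; default 0.9997.
#' @return Object of class `eigen_basis`: list with `mean` (P), `vectors`
#'   (`P x K`, orthonormal), `values` (all P eigenvalues, descending,
#'   clipped at 0), `cumulative_variance` (P fractions), `K`, `cutoff`,
#'   `scores` (`N x K` training scores), `n`.
#' @export
fit_basis <- function(X, cutoff = 0.9997) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to estimate a covariance", call. = FALSE)
  if (!all(is.finite(X))) stop("cohort matrix must be finite", call. = FALSE)
  stopifnot(cutoff > 0, cutoff <= 1)
  mu <- colMeans(X)
  S <- stats::cov(X)
  e <- eigen(S, symmetric = TRUE)
  values <- pmax(e$values, 0)
  total <- sum(values)
  if (total <= 0) stop("degenerate cohort: zero total variance (constant rows)",
                       call. = FALSE)
  cumfrac <- cumsum(values) / total
  K <- which(cumfrac >= cutoff - 1e-10)[1]
  V <- e$vectors[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- colnames(X)
  scores <- sweep(X, 2, mu) %*% V
  structure(list(mean = mu, vectors = V, values = values,
                 cumulative_variance = cumfrac, K = K, cutoff = cutoff,
                 scores = scores, n = nrow(X)),
            class = "eigen_basis")
}

#' Project wavefront parameters onto the eigen-wavefront basis
#'
#' `project_scores()` computes `t(E) %*% (x - mean)`; its inverse
#' `reconstruct_wavefronts()` computes `E %*% s + mean` (the centering
#' mean -- the cohort's average accommodative wavefront -- is added back).
#' With a full-rank basis the two are mutually inverse; with a truncated
#' basis reconstruction is the least-squares optimal rank-K approximation.
#'
#' @param basis An [fit_basis()] result.
#' @param x Vector of length P or an `N x P` matrix.
#' @return `N x K` score matrix.
#' @export
project_scores <- function(basis, x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != length(basis$mean)) {
    stop("dimension mismatch between data and basis", call. = FALSE)
  }
  sweep(x, 2, basis$mean) %*% basis$vectors
}

#' @rdname project_scores
#' @param scores Vector of length K or an `N x K` score matrix.
#' @return `reconstruct_wavefronts()` returns an `N x P` parameter matrix.
#' @export
reconstruct_wavefronts <- function(basis, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, 1)
  if (ncol(scores) != basis$K) {
    stop("dimension mismatch between scores and basis", call. = FALSE)
  }
  out <- scores %*% t(basis$vectors)
  sweep(out, 2, basis$mean, "+")
}

#' Cumulative variance and score-mapped amplitude limits per eigenvector
#'
#' Reports, for each retained eigenvector, the cumulative percentage of
#' variance explained and the extreme amplitudes (micrometres) that the
#' training cohort maps onto it: the min/max over subjects and parameters
#' of `score_ik * loading_jk`, i.e. the colour-map limits of a per-subject
#' eigen-wavefront rendering. (Which extremum the published limits refer
#' to is not fully specified; score-mapped extrema are this package's
#' documented choice.)
#'
#' @param basis An [fit_basis()] result.
#' @param k_max Number of leading eigenvectors to report; default all K.
#' @return data.frame with columns `eigenvector`, `cumulative_variance_pct`,
#'   `max_um`, `min_um`.
#' @export
cumulative_variance_table <- function(basis, k_max = basis$K) {
  stopifnot(inherits(basis, "eigen_basis"), k_max >= 1, k_max <= basis$K)
  ks <- seq_len(k_max)
  lim <- t(vapply(ks, function(k) {
    amp <- outer(basis$scores[, k], basis$vectors[, k])
    c(max(amp), min(amp))
  }, numeric(2)))
  data.frame(eigenvector = ks,
             cumulative_variance_pct = 100 * basis$cumulative_variance[ks],
             max_um = lim[, 1], min_um = lim[, 2])
}

#' Zernike-mode composition of an eigenvector
#'
#' Reshapes eigenvector `k` to its 6 demands x 25 modes layout and reports
#' each mode's relative RMS contribution: `sum over demands of loading^2`,
#' as a percentage of the eigenvector's total squared loading. The mode
#' with the largest contribution is the eigenvector's fundamental
#' component; eigen-wavefronts whose fundamental exceeds 40% are flagged
#' as dominated by a single Zernike mode (ties broken by OSA index).
#'
#' @param basis An [fit_basis()] result over the standard 150-parameter
#'   layout.
#' @param k Eigenvector index, `1 <= k <= K`.
#' @return List with `table` (data.frame `n`, `m`, `name`,
#'   `contribution_pct`, descending), `fundamental` (mode name),
#'   `fundamental_pct`, and `dominant` (logical, fundamental > 40%).
#' @export
eigenvector_composition <- function(basis, k) {
  stopifnot(inherits(basis, "eigen_basis"), k >= 1, k <= basis$K)
  modes <- zernike_modes()
  p <- nrow(modes)
  if (length(basis$mean) != 6 * p) {
    stop("basis is not over the standard 6-demand x 25-mode layout", call. = FALSE)
  }
  L <- matrix(basis$vectors[, k], nrow = 6, ncol = p, byrow = TRUE)
  contrib <- colSums(L^2)
  pct <- 100 * contrib / sum(contrib)
  ord <- order(-pct, modes$j)
  fundamental <- ord[1]
  list(table = data.frame(n = modes$n[ord], m = modes$m[ord],
                          name = modes$name[ord],
                          contribution_pct = pct[ord]),
       fundamental = modes$name[fundamental],
       fundamental_pct = pct[fundamental],
       dominant = pct[fundamental] > 40)
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("eigen-wavefront basis: %d of %d components retained (cutoff %.4g%%)\n",
              x$K, length(x$values), 100 * x$cutoff))
  cat(sprintf("  variance retained: %.4f%%  (fit on n = %d)\n",
              100 * x$cumulative_variance[x$K], x$n))
  invisible(x)
}
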