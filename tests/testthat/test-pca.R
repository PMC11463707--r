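toy_data <- function() {
  # two uncorrelated columns with sample variances exactly 9 and 1
  u1 <- c(1, 1, -1, -1)
  u2 <- c(1, -1, 1, -1)
  cbind(u1 * sqrt(9 * 3 / 4), u2 * sqrt(3 / 4))
}

test_that("covariance PCA recovers independent component variances", {
  X <- toy_data()
  b <- fit_basis(X, cutoff = 0.9)
  expect_equal(b$values[1], 9, tolerance = 1e-12)
  expect_equal(b$values[2], 1, tolerance = 1e-12)
  expect_equal(b$cumulative_variance[1], 0.9, tolerance = 1e-12)
  expect_identical(b$K, 1L)
  bfull <- fit_basis(X, cutoff = 1)
  tab <- cumulative_variance_table(bfull)
  expect_equal(tab$cumulative_variance_pct, c(90, 100), tolerance = 1e-10)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(fit_basis(matrix(1, 5, 3)), "zero total variance")
  expect_error(fit_basis(matrix(1, 1, 3)), "at least 2 rows")
  expect_error(fit_basis(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("eigendecomposition conserves variance and decorrelates scores", {
  set.seed(21)
  X <- matrix(rnorm(60 * 8), 60, 8) %*% matrix(rnorm(64, sd = 0.5), 8, 8)
  b <- fit_basis(X, cutoff = 1)
  expect_equal(sum(b$values), sum(diag(cov(X))), tolerance = 1e-8)
  G <- crossprod(b$vectors)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-10)
  cors <- cor(b$scores)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)
  # cutoff 1 on full-rank data retains min(N - 1, P) = P components
  expect_identical(b$K, 8L)
  # K never exceeds N - 1 when P > N
  Xw <- matrix(rnorm(5 * 12), 5, 12)
  expect_lte(fit_basis(Xw, cutoff = 1)$K, 4L)
})

test_that("projection and reconstruction invert with a complete basis", {
  set.seed(22)
  X <- matrix(rnorm(30 * 6), 30, 6)
  b <- fit_basis(X, cutoff = 1)
  expect_equal(drop(project_scores(b, b$mean)), numeric(b$K), tolerance = 1e-10)
  Xr <- reconstruct_wavefronts(b, project_scores(b, X))
  expect_equal(Xr, X, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(project_scores(b, numeric(5)), "dimension")
  expect_error(reconstruct_wavefronts(b, numeric(b$K + 1)), "dimension")
})

test_that("truncated reconstruction error respects the cumulative-variance bound", {
  set.seed(23)
  X <- matrix(rnorm(80 * 10), 80, 10) %*% diag(c(5, 3, 2, 1, rep(0.1, 6)))
  cutoff <- 0.97
  b <- fit_basis(X, cutoff = cutoff)
  expect_lt(b$K, 10)
  Xr <- reconstruct_wavefronts(b, project_scores(b, X))
  mean_resid <- mean(rowSums((X - Xr)^2))
  total_var <- sum(diag(cov(X)))
  expect_lte(mean_resid, (1 - cutoff) * total_var + 1e-10)
  expect_gte(b$cumulative_variance[b$K], cutoff)
})

test_that("eigendecomposition matches an independent SVD oracle up to sign", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(10 * 6), 10, 6)
    b <- fit_basis(X, cutoff = 1)
    Xc <- sweep(X, 2, colMeans(X))
    sv <- svd(Xc)
    expect_equal(b$values[1:6], sv$d^2 / (nrow(X) - 1), tolerance = 1e-10)
    for (k in 1:5) { # last component sign/direction may be rank-noise
      dotp <- abs(sum(b$vectors[, k] * sv$v[, k]))
      expect_equal(dotp, 1, tolerance = 1e-8)
    }
  }
})

test_that("eigenvector sign convention puts the largest loading positive", {
  set.seed(24)
  X <- matrix(rnorm(40 * 7), 40, 7)
  b <- fit_basis(X, cutoff = 1)
  for (k in seq_len(b$K)) {
    expect_gt(b$vectors[which.max(abs(b$vectors[, k])), k], 0)
  }
})

test_that("eigenvector composition identifies fundamental modes and ties", {
  set.seed(25)
  raw <- generate_population(population_spec(n_subjects = 150, seed = 25))
  X <- raw_to_matrix(raw)
  b <- fit_basis(X)

  # synthetic eigenvector: pure defocus loading across demands
  b2 <- b
  v <- numeric(150); v[match(sprintf("d%d_c_2_0", 0:5), parameter_names())] <- 1 / sqrt(6)
  b2$vectors[, 1] <- v
  comp <- eigenvector_composition(b2, 1)
  expect_identical(comp$fundamental, "c_2_0")
  expect_equal(comp$fundamental_pct, 100)
  expect_true(comp$dominant)

  # equal loading on two modes: 50/50, tie broken by OSA order
  v <- numeric(150)
  v[match("d0_c_2_-2", parameter_names())] <- 1
  v[match("d0_c_2_2", parameter_names())] <- 1
  b2$vectors[, 1] <- v / sqrt(2)
  comp <- eigenvector_composition(b2, 1)
  expect_equal(comp$table$contribution_pct[1:2], c(50, 50))
  expect_identical(comp$fundamental, "c_2_-2") # lower OSA index wins the tie
  expect_true(comp$dominant) # a 50% fundamental still exceeds the 40% flag

  # spread over four modes: no dominant fundamental
  v <- numeric(150)
  v[match(c("d0_c_2_-2", "d0_c_2_2", "d1_c_3_-3", "d2_c_4_0"),
          parameter_names())] <- 0.5
  b2$vectors[, 1] <- v
  expect_false(eigenvector_composition(b2, 1)$dominant)

  # defocus/astigmatism-dominated cohort: leading EVs have a dominant fundamental
  for (k in 1:4) expect_true(eigenvector_composition(b, k)$dominant)
})

test_that("cumulative variance table reports score-mapped amplitude limits", {
  set.seed(26)
  X <- matrix(rnorm(50 * 150, sd = 0.05), 50, 150)
  colnames(X) <- parameter_names()
  b <- fit_basis(X, cutoff = 0.9)
  tab <- cumulative_variance_table(b, k_max = min(5, b$K))
  expect_true(all(diff(tab$cumulative_variance_pct) >= -1e-12))
  expect_true(all(tab$max_um >= 0 & tab$min_um <= 0))
  amp1 <- outer(b$scores[, 1], b$vectors[, 1])
  expect_equal(tab$max_um[1], max(amp1))
  expect_equal(tab$min_um[1], min(amp1))
})
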