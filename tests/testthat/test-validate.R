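test_that("TOST hits the analytic boundary and limiting cases", {
  set.seed(41)
  x <- rnorm(200)
  y <- x - 0.3               # observed difference exactly +0.3 = margin
  p <- tost_means(x, y, margin = 0.3)
  expect_equal(p, 0.5, tolerance = 1e-9)

  # identical large samples, margin half an SD: clearly equivalent
  x <- rnorm(500)
  expect_lt(tost_means(x, x, margin = 0.5 * sd(x)), 0.001)

  # difference far beyond the margin: p near 1
  expect_gt(tost_means(x, x + 10, margin = 0.5), 0.9)

  expect_error(tost_means(x, x, margin = 0), "positive")
  expect_error(tost_means(x, x, margin = -1), "positive")
})

test_that("TOST is sign-symmetric and monotone in the margin", {
  set.seed(42)
  x <- rnorm(150, 0.1, 1)
  y <- rnorm(150, 0.0, 1.2)
  expect_equal(tost_means(x, y, 0.25), tost_means(-x, -y, 0.25), tolerance = 1e-12)
  margins <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  ps <- vapply(margins, function(d) tost_means(x, y, d), numeric(1))
  expect_true(all(diff(ps) <= 1e-12)) # wider margin, smaller p
})

test_that("F-test of variances is symmetric, calibrated, and matches var.test", {
  set.seed(43)
  x <- rnorm(191); y <- rnorm(191)
  # equal sample variances, equal n -> F = 1, p = 1
  expect_equal(f_test_variances(x, x), 1)
  expect_equal(f_test_variances(x, y), f_test_variances(y, x), tolerance = 1e-12)
  # fourfold variance at n = 191 each: overwhelming evidence
  expect_lt(f_test_variances(2 * x, x), 0.001)
  # agrees with the base implementation
  expect_equal(f_test_variances(x, y), var.test(x, y)$p.value, tolerance = 1e-12)
  expect_error(f_test_variances(rep(1, 10), y), "zero variance")
})

test_that("F-test p-values are uniform under the null", {
  set.seed(44)
  ps <- replicate(2000, f_test_variances(rnorm(25), rnorm(25)))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("KS normality is conservative on normal data and flags gross departures", {
  pass <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(rnorm(1e4)) > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.94)

  expect_lt(ks_normality(c(rep(0, 50), 1)), 1e-6)
  set.seed(45); x <- rexp(5000)
  expect_lt(ks_normality(x), 1e-6)
  set.seed(46); x <- rnorm(100)
  expect_identical(ks_normality(x), ks_normality(x)) # deterministic
  expect_error(ks_normality(1:4), "at least 5")
  expect_warning(p0 <- ks_normality(rep(2, 10)), "zero-variance")
  expect_equal(p0, 0)
})

test_that("Bonferroni adjustment is alpha over m", {
  expect_equal(bonferroni_alpha(0.05, 150), 0.05 / 150)
  expect_equal(round(bonferroni_alpha(0.05, 150), 6), 3.33e-4)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 49), 0.05 / 49, tolerance = 1e-12)
  expect_equal(bonferroni_alpha(0.05, 49), 1.0204e-3, tolerance = 1e-4)
  expect_error(bonferroni_alpha(0.05, 0), ">= 1")
})

test_that("validating a cohort against itself declares full equivalence", {
  set.seed(47)
  raw <- generate_population(population_spec(n_subjects = 191, seed = 47))
  X <- raw_to_matrix(raw)
  b <- fit_basis(X)
  rep <- validate_cohorts(X, X, b)
  for (fam in rep) {
    expect_true(all(fam$table$mean_equivalent))
    expect_true(all(fam$table$f_p > 1 - 1e-9))
    expect_true(all(fam$table$variance_equal))
    expect_equal(fam$adjusted_alpha, 0.05 / fam$m)
    expect_identical(nrow(fam$table), fam$m)
  }
  expect_identical(rep$eigenvectors$m, b$K)
  expect_identical(rep$zernike$m, 150L)
})

test_that("inflated generated variance is flagged by the F-test family", {
  set.seed(48)
  raw <- generate_population(population_spec(n_subjects = 191, seed = 48))
  X <- raw_to_matrix(raw)
  b <- fit_basis(X)
  G <- sweep(2 * sweep(X, 2, colMeans(X)), 2, colMeans(X), "+") # double every SD
  rep <- validate_cohorts(X, G, b)
  expect_true(all(!rep$zernike$table$variance_equal))
  expect_true(all(abs(rep$zernike$table$mean_original -
                      rep$zernike$table$mean_generated) < 1e-10))
})

test_that("schema mismatches between cohorts are rejected", {
  X <- matrix(rnorm(20 * 150), 20, 150, dimnames = list(NULL, parameter_names()))
  b <- fit_basis(X, cutoff = 0.9)
  expect_error(validate_cohorts(X, X[, 1:149], b), "different parameter counts")
  Y <- X; colnames(Y) <- rev(parameter_names())
  expect_error(validate_cohorts(X, Y, b), "disagree on column schema")
})

test_that("imputed cells are masked out of the original-sample statistics", {
  set.seed(49)
  X <- matrix(rnorm(60 * 150), 60, 150, dimnames = list(NULL, parameter_names()))
  b <- fit_basis(X, cutoff = 0.9)
  mask <- matrix(FALSE, 60, 150)
  mask[1:10, 1] <- TRUE
  rep <- validate_cohorts(X, X, b, mask = mask)
  expect_equal(rep$zernike$table$mean_original[1], mean(X[-(1:10), 1]))
  expect_equal(rep$zernike$table$mean_original[2], mean(X[, 2]))
})
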