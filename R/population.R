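#' Published per-demand marginals of a young-adult accommodating cohort
#'
#' Mean and standard deviation (micrometres) of each Zernike coefficient
#' at each accommodative demand, used as the default parameters of the
#' synthetic population. The seven modes whose summary statistics were
#' published for the 191-eye reference cohort -- C(2,-2), C(2,0), C(2,2),
#' C(3,-1), C(3,1), C(4,0), C(6,0) -- carry those values (defocus C(2,0)
#' grows from 1.249 um at 0 D to 2.278 um at 5 D; primary spherical
#' aberration C(4,0) drifts from +0.039 to -0.008 um). The remaining
#' modes, for which no cohort statistics were published, default to zero
#' mean with SDs decaying with radial order, `0.01 * 0.7^(n - 4)` um,
#' echoing that the discarded variance sits in the higher-order terms.
#'
#' @return List with `mean` and `sd`, each a `6 x 25` matrix (rows =
#'   demands 0-5 D, columns = OSA modes).
#' @export
accommodative_marginals <- function() {
  modes <- zernike_modes()
  mu <- matrix(0, 6, 25, dimnames = list(as.character(0:5), modes$name))
  sd <- matrix(rep(0.01 * 0.7^(modes$n - 4), each = 6), 6, 25,
               dimnames = dimnames(mu))
  published <- list(
    `c_2_-2` = list(mean = c(0.017, 0.021, 0.015, 0.014, 0.007, 0.005),
                    sd   = c(0.213, 0.226, 0.192, 0.157, 0.158, 0.135)),
    c_2_0    = list(mean = c(1.249, 1.544, 1.826, 1.948, 2.335, 2.278),
                    sd   = c(1.747, 1.902, 1.757, 1.390, 1.493, 1.312)),
    c_2_2    = list(mean = c(-0.159, -0.129, -0.090, -0.066, -0.035, -0.020),
                    sd   = c(0.362, 0.366, 0.318, 0.271, 0.271, 0.227)),
    `c_3_-1` = list(mean = c(0.024, 0.026, 0.026, 0.023, 0.025, 0.022),
                    sd   = c(0.082, 0.091, 0.074, 0.063, 0.067, 0.052)),
    c_3_1    = list(mean = c(0.000, -0.005, 0.002, 0.007, 0.011, 0.011),
                    sd   = c(0.060, 0.067, 0.059, 0.057, 0.066, 0.060)),
    c_4_0    = list(mean = c(0.039, 0.036, 0.016, 0.002, -0.004, -0.008),
                    sd   = c(0.050, 0.056, 0.049, 0.041, 0.048, 0.041)),
    c_6_0    = list(mean = c(-0.001, -0.001, -0.001, -0.001, -0.002, -0.001),
                    sd   = c(0.013, 0.014, 0.013, 0.009, 0.009, 0.006))
  )
  for (nm in names(published)) {
    mu[, nm] <- published[[nm]]$mean
    sd[, nm] <- published[[nm]]$sd
  }
  list(mean = mu, sd = sd)
}

#' Specification of a synthetic accommodating population
#'
#' All defaults emulate the reference clinical cohort: 191 subjects,
#' published per-parameter marginals, a constant cross-demand correlation
#' of 0.9 for each mode (the same aberration measured at different
#' demands is strongly correlated within an eye), zero cross-mode
#' correlation, natural pupils normal with SD 0.45 mm and per-demand
#' means placed so the 5th percentile equals the standard diameters, a
#' 0.5 left-eye fraction, and a 2 mm pupil floor. The true covariance of
#' the clinical cohort is unpublished; the correlation structure is a
#' fixture parameter, not a claim about the data.
#'
#' @param n_subjects Number of subjects; default 191.
#' @param marginals List with `mean`/`sd` `6 x 25` matrices; default
#'   [accommodative_marginals()].
#' @param r_within Cross-demand correlation of the same mode, `|r| < 1`;
#'   default 0.9.
#' @param r_cross_mode Correlation between different modes; default 0.
#' @param pupil_sd SD of natural pupil diameters (mm); default 0.45.
#' @param pupil_min Truncation floor for pupils (mm); default 2.
#' @param laterality_ratio Probability that a subject is a left eye;
#'   default 0.5.
#' @param standard_pupils Per-demand standard diameters used to place the
#'   pupil means; default the [cohort_config()] standards.
#' @param seed Integer RNG seed, or `NULL`.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 191,
                            marginals = accommodative_marginals(),
                            r_within = 0.9, r_cross_mode = 0,
                            pupil_sd = 0.45, pupil_min = 2,
                            laterality_ratio = 0.5,
                            standard_pupils = cohort_config()$standard_pupils,
                            seed = NULL) {
  stopifnot(n_subjects >= 1, abs(r_within) < 1, abs(r_cross_mode) < 1,
            pupil_sd >= 0, laterality_ratio >= 0, laterality_ratio <= 1,
            all(marginals$sd >= 0),
            identical(dim(marginals$mean), c(6L, 25L)),
            identical(dim(marginals$sd), c(6L, 25L)))
  structure(list(n_subjects = n_subjects, marginals = marginals,
                 r_within = r_within, r_cross_mode = r_cross_mode,
                 pupil_sd = pupil_sd, pupil_min = pupil_min,
                 laterality_ratio = laterality_ratio,
                 standard_pupils = standard_pupils, seed = seed),
            class = "population_spec")
}

# 150 x 150 covariance implied by a population_spec: per-mode constant-
# correlation blocks across demands, a constant cross-mode correlation
# elsewhere, scaled by the demand-major SD vector.
population_covariance <- function(spec) {
  R <- matrix(spec$r_cross_mode, 150, 150)
  for (i in seq_len(25)) {
    idx <- i + 25 * (0:5)
    R[idx, idx] <- spec$r_within
  }
  diag(R) <- 1
  s <- as.vector(t(spec$marginals$sd)) # demand-major flattening
  sigma <- R * tcrossprod(s)
  e <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) < -1e-8 * max(abs(e))) {
    message("population covariance repaired by eigenvalue clipping")
    ed <- eigen(sigma, symmetric = TRUE)
    sigma <- ed$vectors %*% diag(pmax(ed$values, 0)) %*% t(ed$vectors)
    sigma <- (sigma + t(sigma)) / 2
    if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < 0) {
      stop("population covariance is not positive semi-definite after repair",
           call. = FALSE)
    }
  }
  sigma
}

#' Generate a raw synthetic population table
#'
#' Draws per-subject 150-parameter vectors from a multivariate normal
#' with the spec's means and structured covariance, assigns laterality
#' (left-eye subjects receive the mirror sign pattern, so preprocessing
#' must undo it), and draws per-demand natural pupil diameters. Output is
#' the raw measurement schema consumed by [preprocess_cohort()], one row
#' per subject and demand; the drawn coefficients are attached as the
#' measurements at the natural pupil.
#'
#' @param spec A [population_spec()].
#' @return data.frame with columns `subject_id`, `eye`, `demand_D`,
#'   `pupil_mm` and the 25 coefficient columns `c_2_-2` ... `c_6_6`.
#' @export
generate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_subjects
  mu <- as.vector(t(spec$marginals$mean))
  s <- as.vector(t(spec$marginals$sd))
  X <- matrix(rep(mu, each = n), n, 150)
  nz <- s > 0
  if (any(nz)) {
    sigma <- population_covariance(spec)[nz, nz, drop = FALSE]
    L <- tryCatch(chol(sigma),
                  error = function(e) chol(sigma + diag(1e-10 * mean(diag(sigma)),
                                                        nrow(sigma))))
    Z <- matrix(stats::rnorm(n * sum(nz)), n, sum(nz))
    X[, nz] <- X[, nz] + Z %*% L
  }
  pupils <- vapply(0:5, function(d) {
    m <- spec$standard_pupils[as.character(d)] +
      stats::qnorm(0.95) * spec$pupil_sd
    pmax(spec$pupil_min, stats::rnorm(n, m, spec$pupil_sd))
  }, numeric(n))
  if (n == 1) pupils <- matrix(pupils, 1)
  eye <- ifelse(stats::runif(n) < spec$laterality_ratio, "LE", "RE")

  msign <- mirror_signs()
  cn <- cohort_coef_names()
  out <- vector("list", 6)
  for (d in 0:5) {
    block <- X[, d * 25 + seq_len(25), drop = FALSE]
    le <- eye == "LE"
    if (any(le)) block[le, ] <- sweep(block[le, , drop = FALSE], 2, msign, "*")
    colnames(block) <- cn
    out[[d + 1]] <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      eye = eye, demand_D = d, pupil_mm = pupils[, d + 1],
      block, check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$subject_id, res$demand_D), ]
  rownames(res) <- NULL
  res
}

#' Deterministic miniature reference run
#'
#' Generates a small 20-subject population under a fixed seed and runs the
#' full preprocessing chain, returning both the raw table and the
#' assembled cohort. Used as a reproducible end-to-end fixture: the same
#' seed yields a bit-identical cohort.
#'
#' @param seed Integer seed; default 42.
#' @param n_subjects Number of subjects; default 20.
#' @return List with `raw` (measurement table), `cohort`
#'   (`wavefront_cohort`), and `spec`.
#' @export
worked_reference_run <- function(seed = 42, n_subjects = 20) {
  spec <- population_spec(n_subjects = n_subjects, seed = seed)
  raw <- generate_population(spec)
  cohort <- preprocess_cohort(raw)
  list(raw = raw, cohort = cohort, spec = spec)
}
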