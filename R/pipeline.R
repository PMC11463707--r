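#' Pipeline configuration
#'
#' Bundles every stage's settings. The defaults reproduce the reference
#' workflow shape: 6 demands x 25 modes, per-demand standard pupils,
#' 99.97% cumulative-variance cutoff, a 2-component Gaussian mixture, and
#' 1000 generated wavefront sets.
#'
#' @param cohort A [cohort_config()].
#' @param cutoff PCA cumulative-variance cutoff; default 0.9997.
#' @param em_seed,em_tol,em_max_iter,em_restarts,em_ridge EM settings, see
#'   [fit_bigaussian()].
#' @param n_generate Number of synthetic wavefront sets; default 1000.
#' @param generate_seed Seed for cohort generation.
#' @param alpha,margin_factor Validation settings, see [validate_cohorts()].
#' @param simulate `NULL`, or a [population_spec()] to simulate the input
#'   cohort instead of reading one.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), cutoff = 0.9997,
                            em_seed = 1L, em_tol = 1e-8, em_max_iter = 200,
                            em_restarts = 5, em_ridge = NULL,
                            n_generate = 1000, generate_seed = 1L,
                            alpha = 0.05, margin_factor = 0.2,
                            simulate = NULL) {
  structure(list(cohort = cohort, cutoff = cutoff, em_seed = em_seed,
                 em_tol = em_tol, em_max_iter = em_max_iter,
                 em_restarts = em_restarts, em_ridge = em_ridge,
                 n_generate = n_generate, generate_seed = generate_seed,
                 alpha = alpha, margin_factor = margin_factor,
                 simulate = simulate),
            class = "pipeline_config")
}

#' Run the full accommodative-wavefront modelling pipeline
#'
#' Executes the stages in order -- simulate (or read) a raw cohort,
#' preprocess, fit the eigen-wavefront basis, fit the bigaussian score
#' model, generate a synthetic cohort, validate -- and optionally writes
#' all artifacts (basis and model JSON, synthetic cohort CSV, validation
#' CSVs, run log JSON) to `out_dir`. Reruns with the same configuration
#' and seeds are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param raw Raw cohort table, or `NULL` to use `config$simulate`.
#' @param out_dir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return List with `raw`, `cohort`, `basis`, `model`, `synthetic`,
#'   `validation`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), raw = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(raw)) {
    if (is.null(config$simulate)) {
      stop("no input cohort: supply `raw` or set `config$simulate`", call. = FALSE)
    }
    raw <- stage("simulate", generate_population(config$simulate))
  }
  cohort <- stage("preprocess", preprocess_cohort(raw, config$cohort))
  basis <- stage("pca", fit_basis(cohort$matrix, config$cutoff))
  model <- stage("fit", suppressWarnings(
    fit_bigaussian(basis$scores, seed = config$em_seed, tol = config$em_tol,
                   max_iter = config$em_max_iter, restarts = config$em_restarts,
                   ridge = config$em_ridge)
  ))
  synthetic <- stage("generate", generate_cohort(
    basis, model, n = config$n_generate, seed = config$generate_seed,
    standard_pupils = cohort$standard_pupils
  ))
  validation <- stage("validate", validate_cohorts(
    cohort$matrix, synthetic$matrix, basis, alpha = config$alpha,
    margin_factor = config$margin_factor, mask = cohort$mask
  ))
  log <- list(
    n_subjects = nrow(cohort$matrix),
    subjects_dropped = length(unique(
      cohort$exclusion_log$subject_id[cohort$exclusion_log$subject_dropped])),
    imputed_cells = sum(cohort$mask),
    K = basis$K,
    variance_retained = basis$cumulative_variance[basis$K],
    em_loglik = model$loglik[length(model$loglik)],
    em_converged = model$converged,
    n_generated = nrow(synthetic$matrix),
    bonferroni_m = list(eigenvectors = validation$eigenvectors$m,
                        zernike = validation$zernike$m),
    adjusted_alpha = list(eigenvectors = validation$eigenvectors$adjusted_alpha,
                          zernike = validation$zernike$adjusted_alpha),
    seeds = list(em = config$em_seed, generate = config$generate_seed,
                 simulate = if (!is.null(config$simulate)) config$simulate$seed)
  )
  result <- list(raw = raw, cohort = cohort, basis = basis, model = model,
                 synthetic = synthetic, validation = validation, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_basis(basis, file.path(out_dir, "basis.json"))
    write_model(model, file.path(out_dir, "model.json"))
    write_cohort_csv(synthetic_cohort_table(synthetic),
                     file.path(out_dir, "synthetic_cohort.csv"))
    write_validation_csv(validation$eigenvectors,
                         file.path(out_dir, "validation_eigenvectors.csv"))
    write_validation_csv(validation$zernike,
                         file.path(out_dir, "validation_zernike.csv"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  result
}
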