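#' Read and write raw cohort CSV tables
#'
#' The raw measurement schema has one row per subject and demand with
#' columns `subject_id`, `eye` (`"RE"`/`"LE"`), `demand_D` (0-5),
#' `pupil_mm`, and the 25 coefficient columns `c_2_-2` ... `c_6_6`
#' (micrometres, OSA order, signed `m` in the name). Values are written
#' with 17 significant digits so a write/read round trip is lossless.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns the validated data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse cohort CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(raw) == 0) stop("cohort CSV '", path, "' contains no rows", call. = FALSE)
  check_raw_schema(raw)
  raw
}

#' @rdname read_cohort_csv
#' @param raw Cohort table in the raw measurement schema.
#' @export
write_cohort_csv <- function(raw, path) {
  check_raw_schema(raw)
  fmt <- raw
  num <- vapply(fmt, is.numeric, logical(1)) & names(fmt) != "demand_D"
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a synthetic cohort to the raw measurement schema
#'
#' Splits each synthetic 150-parameter row into its six per-demand
#' coefficient vectors, tagged with the standard pupil diameters (the
#' pupils at which the rescaled model coefficients are valid) and `"RE"`
#' laterality (synthetic wavefronts live in the right-eye convention).
#'
#' @param cohort A [generate_cohort()] result.
#' @return data.frame in the schema of [read_cohort_csv()].
#' @export
synthetic_cohort_table <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$matrix)
  cn <- cohort_coef_names()
  out <- vector("list", 6)
  for (d in 0:5) {
    block <- cohort$matrix[, d * 25 + seq_len(25), drop = FALSE]
    colnames(block) <- cn
    out[[d + 1]] <- data.frame(
      subject_id = if (n) rownames(cohort$matrix) else character(0),
      eye = rep("RE", n), demand_D = rep(d, n),
      pupil_mm = rep(unname(cohort$standard_pupils[as.character(d)]), n),
      block, check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$subject_id, res$demand_D), ]
  rownames(res) <- NULL
  res
}

#' Serialize and restore the eigen-wavefront basis and mixture model
#'
#' JSON serialization at full double precision, including the column-order
#' metadata needed to reapply the basis.
#'
#' @param basis An [fit_basis()] result.
#' @param path File path (`.json`).
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "eigen_basis"))
  obj <- list(type = "accwave_eigen_basis", version = 1L,
              parameter_names = names(basis$mean),
              mean = unname(basis$mean),
              vectors = unname(basis$vectors),
              values = basis$values,
              cutoff = basis$cutoff, K = basis$K, n = basis$n)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "accwave_eigen_basis")) {
    stop("not an accwave eigen-basis file: ", path, call. = FALSE)
  }
  mean <- as.numeric(obj$mean)
  names(mean) <- obj$parameter_names
  V <- matrix(as.numeric(obj$vectors), ncol = obj$K)
  rownames(V) <- obj$parameter_names
  values <- as.numeric(obj$values)
  structure(list(mean = mean, vectors = V, values = values,
                 cumulative_variance = cumsum(values) / sum(values),
                 K = as.integer(obj$K), cutoff = obj$cutoff,
                 scores = NULL, n = as.integer(obj$n)),
            class = "eigen_basis")
}

#' @rdname write_basis
#' @param model A [fit_bigaussian()] result.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bigaussian_model"))
  obj <- list(type = "accwave_bigaussian", version = 1L, K = model$K,
              weights = model$weights, means = model$means,
              covs = model$covs, ridge = model$ridge,
              seed = model$seed, loglik = model$loglik,
              converged = model$converged)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "accwave_bigaussian")) {
    stop("not an accwave bigaussian model file: ", path, call. = FALSE)
  }
  K <- as.integer(obj$K)
  covs <- if (is.array(obj$covs) && length(dim(obj$covs)) == 3) {
    list(matrix(obj$covs[1, , ], K, K), matrix(obj$covs[2, , ], K, K))
  } else {
    lapply(obj$covs, function(x) matrix(as.numeric(unlist(x)), K, K, byrow = FALSE))
  }
  structure(list(weights = as.numeric(obj$weights),
                 means = matrix(as.numeric(obj$means), 2, K),
                 covs = covs, loglik = as.numeric(obj$loglik),
                 converged = isTRUE(obj$converged),
                 ridge = as.numeric(obj$ridge),
                 seed = obj$seed, K = K),
            class = "bigaussian_model")
}

#' Export a validation report as a CSV table
#'
#' Writes the per-parameter table (KS, mean (SD) of both cohorts, TOST,
#' F-test, decisions) in the layout of the published comparison tables.
#'
#' @param report A `validation_report` from [validate_cohorts()].
#' @param path File path.
#' @export
write_validation_csv <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
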