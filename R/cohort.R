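#' Cohort preprocessing configuration
#'
#' Holds the per-demand standard pupil diameters, the percentile used to
#' derive them from a cohort, and the exclusion tolerance. The default
#' standard diameters are the fixed per-demand values used for the
#' reference young-adult cohort: 4.66, 4.76, 4.40, 4.09, 4.07 and 3.68 mm
#' for demands 0 to 5 D (each the largest pupil achievable by 95% of eyes
#' at that demand, i.e. the 5th percentile of natural pupil diameters).
#'
#' @param standard_pupils Named numeric vector of 6 diameters (mm), names
#'   `"0"`..`"5"` (dioptres of accommodative demand, stored as positive
#'   magnitudes), or `NULL` to derive them from the cohort at
#'   `pupil_percentile`.
#' @param pupil_percentile Percentile of the natural-pupil distribution
#'   defining the standard diameter when derived from data; default 5.
#' @param max_excluded_vergences Maximum number of per-demand exclusions a
#'   subject may accumulate before being dropped entirely; default 2
#'   (subjects excluded at three or more vergences are removed).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(standard_pupils = c(`0` = 4.66, `1` = 4.76, `2` = 4.40,
                                              `3` = 4.09, `4` = 4.07, `5` = 3.68),
                          pupil_percentile = 5,
                          max_excluded_vergences = 2) {
  if (!is.null(standard_pupils)) {
    stopifnot(length(standard_pupils) == 6, all(standard_pupils > 0))
    names(standard_pupils) <- as.character(0:5)
  }
  stopifnot(pupil_percentile > 0, pupil_percentile < 100,
            max_excluded_vergences >= 0)
  structure(list(standard_pupils = standard_pupils,
                 pupil_percentile = pupil_percentile,
                 max_excluded_vergences = max_excluded_vergences),
            class = "cohort_config")
}

#' Standard pupil diameter from a cohort (percentile rule)
#'
#' The standard diameter for a demand is the pupil diameter achievable by
#' `100 - percentile` percent of eyes, i.e. the `percentile`-th percentile
#' of the empirical natural-pupil distribution, computed with the
#' linear-interpolation quantile ([stats::quantile()] type 7).
#'
#' @param pupils Numeric vector of natural pupil diameters (mm).
#' @param percentile Percentile in (0, 100]; default 5.
#' @return Diameter in mm.
#' @export
standard_pupil_from_cohort <- function(pupils, percentile = 5) {
  if (length(pupils) == 0) stop("no pupil observations", call. = FALSE)
  if (length(pupils) < 20) {
    warning("fewer than 20 pupil observations; percentile estimate is unstable")
  }
  unname(stats::quantile(pupils, percentile / 100, type = 7, names = FALSE))
}

demand_grid <- function() 0:5

cohort_coef_names <- function() zernike_modes()$name

#' Demand-major column names of the assembled 150-parameter matrix
#'
#' Columns are ordered demand-major: the 25 modes at 0 D, then the 25
#' modes at 1 D, and so on (`d0_c_2_-2`, ..., `d5_c_6_6`).
#'
#' @return Character vector of length 150.
#' @export
parameter_names <- function() {
  as.vector(t(outer(demand_grid(), cohort_coef_names(),
                    function(d, nm) sprintf("d%d_%s", d, nm))))
}

check_raw_schema <- function(raw) {
  need <- c("subject_id", "eye", "demand_D", "pupil_mm", cohort_coef_names())
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !raw$eye %in% c("RE", "LE")
  if (any(bad)) {
    stop(sprintf("column 'eye' must be 'RE'/'LE'; first bad row: %d (value '%s')",
                 which(bad)[1], raw$eye[which(bad)[1]]), call. = FALSE)
  }
  if (!all(raw$demand_D %in% demand_grid())) {
    stop("column 'demand_D' must lie on the 0..5 dioptre grid", call. = FALSE)
  }
  if (any(raw$pupil_mm <= 0)) stop("non-positive pupil diameter", call. = FALSE)
  if (anyDuplicated(raw[c("subject_id", "demand_D")])) {
    stop("duplicate (subject_id, demand_D) measurement", call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply the small-pupil exclusion rules
#'
#' A (subject, demand) measurement is excluded when its natural pupil is
#' smaller than the standard diameter for that demand (rescaling to the
#' standard pupil would require extrapolation). Subjects excluded at more
#' than `max_excluded_vergences` demands are dropped from the cohort
#' altogether; remaining excluded cells are marked missing.
#'
#' @param raw Raw cohort table (one row per subject and demand) in the
#'   schema of [read_cohort_csv()].
#' @param config A [cohort_config()]; if its `standard_pupils` is `NULL`
#'   they are derived per demand by [standard_pupil_from_cohort()].
#' @return List with `kept` (raw rows of retained subjects, with logical
#'   column `excluded_cell`), `standard_pupils`, and `log` (a data.frame
#'   recording every exclusion decision).
#' @export
apply_exclusion <- function(raw, config = cohort_config()) {
  check_raw_schema(raw)
  sp <- config$standard_pupils
  if (is.null(sp)) {
    sp <- vapply(demand_grid(), function(d) {
      standard_pupil_from_cohort(raw$pupil_mm[raw$demand_D == d],
                                 config$pupil_percentile)
    }, numeric(1))
    names(sp) <- as.character(demand_grid())
  }
  flagged <- raw$pupil_mm < sp[as.character(raw$demand_D)]
  n_flag <- tapply(flagged, raw$subject_id, sum)
  dropped <- names(n_flag)[n_flag > config$max_excluded_vergences]
  log <- data.frame(
    subject_id = raw$subject_id,
    demand_D = raw$demand_D,
    pupil_mm = raw$pupil_mm,
    standard_mm = unname(sp[as.character(raw$demand_D)]),
    cell_excluded = flagged,
    subject_dropped = raw$subject_id %in% dropped,
    stringsAsFactors = FALSE
  )
  kept <- raw[!raw$subject_id %in% dropped, , drop = FALSE]
  kept$excluded_cell <- flagged[!raw$subject_id %in% dropped]
  list(kept = kept, standard_pupils = sp, log = log)
}

#' Preprocess a raw cohort into the 150-parameter matrix
#'
#' Runs the full preprocessing chain: schema validation, mirroring of
#' left-eye data to the right-eye convention, small-pupil exclusion,
#' rescaling of every retained measurement from its natural pupil to the
#' per-demand standard diameter, and assembly into an `N x 150` matrix
#' (demand-major columns, see [parameter_names()]). Cells excluded at one
#' or two demands are imputed with the column mean of the observed cells
#' (which leaves column means unchanged) and flagged in `mask`.
#'
#' @inheritParams apply_exclusion
#' @return Object of class `wavefront_cohort`: list with `matrix`
#'   (`N x 150`), `mask` (logical, `TRUE` where imputed), `subjects`
#'   (id and eye), `standard_pupils`, `exclusion_log`, `config`.
#' @export
preprocess_cohort <- function(raw, config = cohort_config()) {
  check_raw_schema(raw)
  cn <- cohort_coef_names()
  coefs <- as.matrix(raw[cn])
  le <- raw$eye == "LE"
  if (any(le)) coefs[le, ] <- mirror_to_right_eye(coefs[le, , drop = FALSE], "LE")
  raw[cn] <- coefs

  exc <- apply_exclusion(raw, config)
  kept <- exc$kept
  sp <- exc$standard_pupils

  ids <- unique(kept$subject_id)
  p <- length(cn)
  X <- matrix(NA_real_, length(ids), 6 * p,
              dimnames = list(ids, parameter_names()))
  for (i in seq_len(nrow(kept))) {
    if (kept$excluded_cell[i]) next
    d <- kept$demand_D[i]
    v <- zernike_rescale(as.numeric(kept[i, cn]), kept$pupil_mm[i],
                         sp[as.character(d)])
    X[match(kept$subject_id[i], ids), d * p + seq_len(p)] <- v
  }
  asm <- assemble_matrix(X)
  eyes <- kept$eye[match(ids, kept$subject_id)]
  structure(list(matrix = asm$matrix, mask = asm$mask,
                 subjects = data.frame(subject_id = ids, eye = eyes,
                                       stringsAsFactors = FALSE),
                 standard_pupils = sp, exclusion_log = exc$log,
                 config = config),
            class = "wavefront_cohort")
}

#' Assemble the cohort matrix, imputing missing cells by column means
#'
#' @param X Numeric `N x 150` matrix, `NA` marking missing cells (demands
#'   excluded by the pupil rule for otherwise retained subjects).
#' @return List with `matrix` (complete) and `mask` (logical, `TRUE` at
#'   imputed cells).
#' @export
assemble_matrix <- function(X) {
  if (ncol(X) != 150) {
    stop(sprintf("expected 150 columns (25 modes x 6 demands), got %d", ncol(X)),
         call. = FALSE)
  }
  mask <- is.na(X)
  if (any(colSums(!mask) == 0)) {
    stop("a parameter column has no observed values; cannot impute", call. = FALSE)
  }
  if (any(mask)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(mask, arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  list(matrix = X, mask = mask)
}

#' @export
print.wavefront_cohort <- function(x, ...) {
  cat(sprintf("wavefront cohort: %d subjects x %d parameters (%d modes x 6 demands)\n",
              nrow(x$matrix), ncol(x$matrix), ncol(x$matrix) / 6))
  cat(sprintf("  imputed cells: %d (%.2f%%)\n", sum(x$mask),
              100 * mean(x$mask)))
  cat("  standard pupils (mm):",
      paste(sprintf("%s D = %.2f", names(x$standard_pupils), x$standard_pupils),
            collapse = ", "), "\n")
  invisible(x)
}
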