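make_raw <- function(n, pupils = 5.5, eye = "RE", seed = 5) {
  set.seed(seed)
  spec <- population_spec(n_subjects = n, laterality_ratio = 0, seed = seed)
  raw <- generate_population(spec)
  raw$pupil_mm <- rep_len(pupils, nrow(raw))
  raw$eye <- rep_len(eye, nrow(raw))
  raw
}

test_that("standard pupil derives from the linear-interpolation percentile", {
  expect_equal(standard_pupil_from_cohort(3:22, 5), 3.95)
  expect_equal(standard_pupil_from_cohort(rep(4.5, 50), 5), 4.5)
  expect_equal(suppressWarnings(standard_pupil_from_cohort(c(2, 3, 4), 100)), 4)
  expect_error(standard_pupil_from_cohort(numeric(0)), "no pupil")
  expect_warning(standard_pupil_from_cohort(c(2, 3, 4), 5), "fewer than 20")
})

test_that("small-pupil exclusion drops eyes excluded at three or more vergences", {
  raw <- make_raw(3)
  # subject 1: below standard at 3 demands -> dropped entirely
  raw$pupil_mm[raw$subject_id == "S0001" & raw$demand_D %in% 0:2] <- 3.0
  # subject 2: below standard at exactly 2 demands -> kept, 2 missing cells
  raw$pupil_mm[raw$subject_id == "S0002" & raw$demand_D %in% c(1, 4)] <- 3.0
  exc <- apply_exclusion(raw, cohort_config())
  expect_false("S0001" %in% exc$kept$subject_id)
  expect_true(all(c("S0002", "S0003") %in% exc$kept$subject_id))
  expect_equal(sum(exc$kept$excluded_cell[exc$kept$subject_id == "S0002"]), 2)
  expect_equal(sum(exc$kept$excluded_cell[exc$kept$subject_id == "S0003"]), 0)
  expect_equal(nrow(exc$log), nrow(raw))
  expect_equal(sum(exc$log$subject_dropped), 6)

  cohort <- preprocess_cohort(raw)
  expect_equal(nrow(cohort$matrix), 2)
  expect_equal(sum(cohort$mask), 2 * 25) # two missing demand blocks imputed
})

test_that("standard pupils can be derived from the cohort at the 5th percentile", {
  raw <- make_raw(40)
  set.seed(8)
  raw$pupil_mm <- runif(nrow(raw), 4, 7)
  cfg <- cohort_config(standard_pupils = NULL)
  exc <- apply_exclusion(raw, cfg)
  for (d in 0:5) {
    expect_equal(unname(exc$standard_pupils[as.character(d)]),
                 quantile(raw$pupil_mm[raw$demand_D == d], 0.05, type = 7,
                          names = FALSE))
  }
})

test_that("assembly imputes column means without shifting them and checks shape", {
  X <- matrix(rnorm(10 * 150), 10, 150)
  mu0 <- colMeans(X)
  Xna <- X
  Xna[2, 7] <- NA
  Xna[5, 7] <- NA
  Xna[3, 140] <- NA
  asm <- assemble_matrix(Xna)
  expect_equal(colMeans(asm$matrix), mu0, tolerance = 0.5) # means move little
  # exact invariance: imputed value equals mean of observed cells
  expect_equal(asm$matrix[2, 7], mean(X[-c(2, 5), 7]))
  expect_equal(colMeans(asm$matrix)[7], mean(X[-c(2, 5), 7]))
  expect_identical(asm$mask[2, 7], TRUE)
  expect_identical(sum(asm$mask), 3L)
  # single subject, nothing missing -> verbatim
  one <- matrix(rnorm(150), 1, 150)
  expect_equal(assemble_matrix(one)$matrix, one)
  expect_error(assemble_matrix(matrix(0, 3, 149)), "150 columns")
  allna <- matrix(NA_real_, 2, 150)
  expect_error(assemble_matrix(allna), "no observed values")
})

test_that("a mirrored left eye round-trips to its right-eye source vector", {
  re_vec <- rnorm(25, sd = 0.1)
  names(re_vec) <- zernike_modes()$name
  sp <- cohort_config()$standard_pupils
  raw <- do.call(rbind, lapply(0:5, function(d) {
    data.frame(subject_id = "L1", eye = "LE", demand_D = d,
               pupil_mm = unname(sp[as.character(d)]),
               t(mirror_to_right_eye(re_vec, "LE")),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  cohort <- preprocess_cohort(raw, cohort_config(max_excluded_vergences = 6))
  for (d in 0:5) {
    expect_equal(unname(cohort$matrix[1, d * 25 + seq_len(25)]),
                 unname(re_vec), tolerance = 1e-10)
  }
})

test_that("preprocessing rescales natural-pupil measurements to the standards", {
  # single RE subject with pure defocus 1 um at a 5.825 mm pupil at 0 D:
  # rescaling to the 4.66 mm standard multiplies defocus by 0.8^2
  v <- numeric(25); names(v) <- zernike_modes()$name; v["c_2_0"] <- 1
  sp <- cohort_config()$standard_pupils
  raw <- do.call(rbind, lapply(0:5, function(d) {
    data.frame(subject_id = "R1", eye = "RE", demand_D = d,
               pupil_mm = unname(sp[as.character(d)]) / 0.8, t(v),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  cohort <- preprocess_cohort(raw)
  expect_equal(unname(cohort$matrix[1, "d0_c_2_0"]), 0.64, tolerance = 1e-10)
  expect_equal(unname(cohort$matrix[1, "d5_c_2_0"]), 0.64, tolerance = 1e-10)
})

test_that("raw schema validation names the offending column", {
  raw <- make_raw(2)
  bad <- raw; bad$eye[3] <- "L"
  expect_error(apply_exclusion(bad), "eye")
  bad <- raw; bad$demand_D[1] <- 7
  expect_error(apply_exclusion(bad), "demand_D")
  bad <- raw[, -which(names(raw) == "c_2_0")]
  expect_error(apply_exclusion(bad), "c_2_0")
  bad <- raw; bad <- rbind(bad, bad[1, ])
  expect_error(apply_exclusion(bad), "duplicate")
})
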