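# Least-squares sub-pupil refit oracle for pupil rescaling.
#
# Evaluates a source wavefront (orders 2-6) at the scaled radial argument
# over a dense grid on the target pupil and refits Zernike coefficients by
# least squares in the COMPLETE order 0-6 basis (28 modes), so the fit is
# exact for any polynomial in the span; the order 2-6 rows are returned.
# Independent of zernike_rescale_matrix(): it only uses zernike_eval().
ls_oracle_grid <- function(n_r = 75, n_t = 72) {
  r <- sqrt(seq(1 / (2 * n_r), 1 - 1 / (2 * n_r), length.out = n_r))
  t <- seq(0, 2 * pi, length.out = n_t + 1)[-(n_t + 1)]
  expand.grid(r = r, t = t)
}

ls_rescale_oracle_matrix <- function(ratio, grid = ls_oracle_grid()) {
  full <- diag(28)
  A <- vapply(seq_len(28), function(i) {
    zernike_eval(full[i, ], grid$r, grid$t, 0, 6)
  }, numeric(nrow(grid)))
  B <- vapply(seq_len(25), function(i) {
    v <- numeric(25); v[i] <- 1
    zernike_eval(v, ratio * grid$r, grid$t, 2, 6)
  }, numeric(nrow(grid)))
  fit <- qr.solve(A, B)                  # 28 x 25, exact for polynomials
  keep <- zernike_modes(0, 6)$n >= 2
  M <- fit[keep, , drop = FALSE]
  dimnames(M) <- list(zernike_modes()$name, zernike_modes()$name)
  M
}

# Reshape a raw population table (right-eye convention applied) into the
# demand-major N x 150 matrix without pupil rescaling; used where tests
# need a quick cohort matrix with known marginals.
raw_to_matrix <- function(raw) {
  cn <- zernike_modes()$name
  coefs <- as.matrix(raw[cn])
  le <- raw$eye == "LE"
  if (any(le)) coefs[le, ] <- mirror_to_right_eye(coefs[le, , drop = FALSE], "LE")
  ids <- unique(raw$subject_id)
  X <- matrix(NA_real_, length(ids), 150,
              dimnames = list(ids, parameter_names()))
  for (d in 0:5) {
    rows <- raw$demand_D == d
    X[match(raw$subject_id[rows], ids), d * 25 + seq_len(25)] <- coefs[rows, ]
  }
  X
}

cohort_coef_names_for_test <- function() zernike_modes()$name
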