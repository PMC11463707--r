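#' Zernike pupil-rescaling matrix
#'
#' Builds the exact linear map taking Zernike coefficients defined on a
#' source pupil diameter to the coefficients of the same wavefront
#' restricted to a smaller concentric pupil. Restriction to the sub-pupil
#' of radius ratio `rho = target / source` replaces the radial argument
#' `r` by `rho * r`; the resulting polynomial is re-expanded analytically
#' in the target-pupil Zernike basis using the monomial coefficients of
#' the radial polynomials and the disk-orthogonality integrals. This is
#' algebraically identical to the corrected small-pupil scaling used for
#' aberrometry data, and every matrix is validated in the test suite
#' against a dense least-squares refit of the evaluated wavefront on the
#' sub-pupil.
#'
#' The map only couples modes with the same meridional index and is
#' lower-triangular in radial order: a mode of order `n` feeds modes of
#' order `<= n`. Piston and tilt induced by rescaling fall outside the
#' order range and are dropped (the model's parameter space starts at
#' order 2). A pure highest-order mode scales its own coefficient by
#' exactly `rho^n`.
#'
#' @param source_diameter,target_diameter Pupil diameters in mm with
#'   `0 < target_diameter <= source_diameter` (dilation is not defined:
#'   it would extrapolate the wavefront beyond the measured pupil).
#' @inheritParams zernike_mode_count
#' @return Square matrix over the mode set (OSA order), to be applied as
#'   `M %*% coefficients`.
#' @export
zernike_rescale_matrix <- function(source_diameter, target_diameter,
                                   min_order = 2, max_order = 6) {
  stopifnot(length(source_diameter) == 1, length(target_diameter) == 1)
  if (!(target_diameter > 0) || !(source_diameter > 0)) {
    stop("pupil diameters must be positive", call. = FALSE)
  }
  if (target_diameter > source_diameter + 1e-12) {
    stop("target pupil exceeds source pupil: rescaling only shrinks the pupil",
         call. = FALSE)
  }
  ratio <- target_diameter / source_diameter
  modes <- zernike_modes(min_order, max_order)
  p <- nrow(modes)
  M <- matrix(0, p, p, dimnames = list(modes$name, modes$name))
  pow <- ratio^(0:(max_order))
  for (jin in seq_len(p)) {
    n_in <- modes$n[jin]; m <- modes$m[jin]
    a <- zernike_radial_poly(n_in, m) * pow[seq_len(n_in + 1)] # R_n(ratio * r)
    for (jout in seq_len(p)) {
      if (modes$m[jout] != m || modes$n[jout] > n_in) next
      n_out <- modes$n[jout]
      b <- zernike_radial_poly(n_out, m)
      # int_0^1 R_in(ratio r) R_out(r) r dr via monomial cross products
      ii <- seq_along(a) - 1
      kk <- seq_along(b) - 1
      integral <- sum(outer(a, b) / (outer(ii, kk, "+") + 2))
      fac <- if (m == 0) 2 else 1
      M[jout, jin] <- fac * zernike_norm(n_in, m) * zernike_norm(n_out, m) * integral
    }
  }
  M
}

#' Rescale Zernike coefficients to a smaller pupil diameter
#'
#' Applies [zernike_rescale_matrix()] to a coefficient vector (or to the
#' rows of a matrix of coefficient vectors sharing one source diameter).
#' The order range is preserved; induced piston/tilt are discarded.
#'
#' @param values Coefficient vector in OSA order, or a matrix with one
#'   vector per row.
#' @inheritParams zernike_rescale_matrix
#' @return Rescaled coefficients, same shape as `values`.
#' @examples
#' v <- numeric(25); v[zernike_modes()$name == "c_2_0"] <- 1
#' zernike_rescale(v, 5, 4)[3] # defocus shrinks by ratio^2 = 0.64
#' @export
zernike_rescale <- function(values, source_diameter, target_diameter,
                            min_order = 2, max_order = 6) {
  M <- zernike_rescale_matrix(source_diameter, target_diameter, min_order, max_order)
  if (is.matrix(values)) {
    stopifnot(ncol(values) == ncol(M))
    out <- values %*% t(M)
    dimnames(out) <- dimnames(values)
    out
  } else {
    stopifnot(length(values) == ncol(M))
    out <- drop(M %*% values)
    names(out) <- names(values)
    out
  }
}
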