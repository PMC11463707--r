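#' Number of Zernike modes in a radial-order range
#'
#' Each radial order `n` contributes `n + 1` modes (meridional indices
#' `m = -n, -n + 2, ..., n`), so the count over an order range is
#' `sum(n + 1)`. Orders 2 through 6 -- the range used throughout this
#' package -- contain 25 modes.
#'
#' @param min_order,max_order Integer radial orders, `0 <= min_order <=
#'   max_order`.
#' @return Integer number of modes.
#' @examples
#' zernike_mode_count(2, 6) # 25
#' @export
zernike_mode_count <- function(min_order, max_order) {
  stopifnot(length(min_order) == 1, length(max_order) == 1)
  if (min_order < 0 || max_order < min_order) {
    stop("need 0 <= min_order <= max_order", call. = FALSE)
  }
  sum(seq(min_order, max_order) + 1L)
}

#' Single-index (OSA/ANSI) Zernike numbering
#'
#' Bijection between the double index `(n, m)` and the OSA/ANSI single
#' index `j = (n (n + 2) + m) / 2`; within each radial order `m` runs
#' ascending from `-n` to `n`.
#'
#' @param n Radial order (integer >= 0).
#' @param m Meridional index; `|m| <= n` and `n - |m|` even.
#' @return `zernike_single_index()` returns the integer index `j`;
#'   `zernike_double_index()` returns a list with elements `n` and `m`.
#' @examples
#' zernike_single_index(2, -2) # 3
#' zernike_double_index(12)    # n = 4, m = 0
#' @export
zernike_single_index <- function(n, m) {
  check_nm(n, m)
  as.integer((n * (n + 2) + m) / 2)
}

#' @rdname zernike_single_index
#' @param j OSA/ANSI single index (integer >= 0).
#' @export
zernike_double_index <- function(j) {
  stopifnot(length(j) == 1)
  if (j < 0 || j != round(j)) stop("j must be a non-negative integer", call. = FALSE)
  n <- floor((sqrt(8 * j + 1) - 1) / 2)
  m <- 2 * j - n * (n + 2)
  list(n = as.integer(n), m = as.integer(m))
}

check_nm <- function(n, m) {
  stopifnot(length(n) == 1, length(m) == 1)
  if (n < 0 || abs(m) > n || (n - abs(m)) %% 2 != 0) {
    stop(sprintf("invalid Zernike index (n = %s, m = %s)", n, m), call. = FALSE)
  }
  invisible(TRUE)
}

#' Mode table for a radial-order range
#'
#' Enumerates the modes of an order range in OSA/ANSI order, together
#' with the column names used in cohort tables (`c_n_m`, signed `m`).
#'
#' @inheritParams zernike_mode_count
#' @return data.frame with columns `j`, `n`, `m`, `name`.
#' @export
zernike_modes <- function(min_order = 2, max_order = 6) {
  stopifnot(min_order >= 0, max_order >= min_order)
  n <- unlist(lapply(min_order:max_order, function(k) rep(k, k + 1L)))
  m <- unlist(lapply(min_order:max_order, function(k) seq(-k, k, by = 2L)))
  data.frame(
    j = as.integer((n * (n + 2) + m) / 2),
    n = as.integer(n),
    m = as.integer(m),
    name = sprintf("c_%d_%d", n, m),
    stringsAsFactors = FALSE
  )
}

# Monomial coefficients of the radial polynomial R_n^{|m|}(r); element k + 1
# holds the coefficient of r^k. Orders used here are small enough that the
# factorial form is exact in double precision.
zernike_radial_poly <- function(n, m) {
  am <- abs(m)
  coef <- numeric(n + 1)
  for (s in 0:((n - am) / 2)) {
    coef[n - 2 * s + 1] <- coef[n - 2 * s + 1] +
      (-1)^s * factorial(n - s) /
        (factorial(s) * factorial((n + am) / 2 - s) * factorial((n - am) / 2 - s))
  }
  coef
}

# Unit-variance (Noll) normalization so that a coefficient equals the RMS
# contribution of its mode over the unit pupil.
zernike_norm <- function(n, m) sqrt(2 * (n + 1) / (1 + (m == 0)))

#' Evaluate a Zernike expansion on the unit pupil
#'
#' Computes `sum(c_nm * Z_nm(rho, theta))` with unit-RMS (Noll-normalized)
#' polynomials: `Z_nm = N_nm R_n^{|m|}(rho) * cos(m theta)` for `m > 0`,
#' `sin(|m| theta)` for `m < 0`, and `1` for `m = 0`.
#'
#' @param values Numeric coefficient vector (micrometres) in OSA order for
#'   the given order range.
#' @param rho Normalized radius, all in `[0, 1]`; recycled against `theta`.
#' @param theta Angle in radians.
#' @inheritParams zernike_mode_count
#' @return Wavefront height(s) in micrometres.
#' @export
zernike_eval <- function(values, rho, theta, min_order = 2, max_order = 6) {
  modes <- zernike_modes(min_order, max_order)
  if (length(values) != nrow(modes)) {
    stop(sprintf("expected %d coefficients, got %d", nrow(modes), length(values)),
         call. = FALSE)
  }
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]", call. = FALSE)
  k <- max(length(rho), length(theta))
  rho <- rep_len(rho, k)
  theta <- rep_len(theta, k)
  out <- numeric(k)
  for (i in seq_len(nrow(modes))) {
    if (values[i] == 0) next
    n <- modes$n[i]; m <- modes$m[i]
    p <- zernike_radial_poly(n, m)
    radial <- outer(rho, seq_along(p) - 1, "^") %*% p
    ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
    out <- out + values[i] * zernike_norm(n, m) * drop(radial) * ang
  }
  out
}

#' RMS wavefront error and per-mode RMS shares
#'
#' With unit-variance normalization the RMS wavefront error over the pupil
#' is `sqrt(sum(c^2))`. `zernike_rms_share()` reports each mode's relative
#' contribution `c^2 / sum(c^2)` as a percentage -- the quantity used to
#' identify an eigen-wavefront's fundamental component.
#'
#' @param values Named or unnamed numeric coefficient vector.
#' @param subset Optional index or name vector selecting a subset of modes.
#' @return RMS in micrometres; for `zernike_rms_share()`, a vector of
#'   percentages summing to 100.
#' @export
zernike_rms <- function(values, subset = NULL) {
  if (length(values) == 0) stop("empty coefficient vector", call. = FALSE)
  if (!is.null(subset)) values <- values[subset]
  sqrt(sum(values^2))
}

#' @rdname zernike_rms
#' @export
zernike_rms_share <- function(values) {
  if (length(values) == 0) stop("empty coefficient vector", call. = FALSE)
  tot <- sum(values^2)
  if (tot == 0) stop("all coefficients are zero; shares undefined", call. = FALSE)
  100 * values^2 / tot
}

#' Mirror left-eye coefficients to the right-eye convention
#'
#' Right and left eyes are mirror images across the vertical meridian.
#' Reflecting a wavefront through that meridian (`theta -> pi - theta`)
#' sign-reverses every mode with negative even meridional index or positive
#' odd meridional index, leaving all other modes unchanged. The rule is an
#' involution: applying it twice restores the input.
#'
#' @param values Coefficient vector, or matrix with one coefficient vector
#'   per row, in OSA order for the order range.
#' @param laterality `"RE"` (returned unchanged) or `"LE"` (mirrored).
#' @inheritParams zernike_mode_count
#' @return Coefficients in the right-eye convention, same shape as input.
#' @export
mirror_to_right_eye <- function(values, laterality, min_order = 2, max_order = 6) {
  laterality <- match.arg(laterality, c("RE", "LE"))
  if (laterality == "RE") return(values)
  s <- mirror_signs(min_order, max_order)
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(s))
    sweep(values, 2, s, "*")
  } else {
    stopifnot(length(values) == length(s))
    values * s
  }
}

#' @rdname mirror_to_right_eye
#' @return `mirror_signs()` returns the vector of +/-1 factors applied to
#'   LE data, in OSA mode order.
#' @export
mirror_signs <- function(min_order = 2, max_order = 6) {
  modes <- zernike_modes(min_order, max_order)
  ifelse((modes$m < 0 & modes$m %% 2 == 0) | (modes$m > 0 & modes$m %% 2 == 1),
         -1, 1)
}

#' Sample a wavefront on a Cartesian grid for plotting
#'
#' @param values Coefficient vector in OSA order.
#' @param n Grid resolution per axis.
#' @inheritParams zernike_mode_count
#' @return `n x n` matrix of wavefront heights (micrometres), `NA` outside
#'   the unit pupil; suitable for [graphics::image()].
#' @export
wavefront_grid <- function(values, n = 101, min_order = 2, max_order = 6) {
  x <- seq(-1, 1, length.out = n)
  g <- expand.grid(x = x, y = x)
  r <- sqrt(g$x^2 + g$y^2)
  inside <- r <= 1
  z <- rep(NA_real_, nrow(g))
  z[inside] <- zernike_eval(values, r[inside], atan2(g$y[inside], g$x[inside]),
                            min_order, max_order)
  matrix(z, n, n)
}
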