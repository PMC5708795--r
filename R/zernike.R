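#' Convert a Zernike single index to (n, m)
#'
#' Uses the standard OSA/ANSI single-index convention
#' `j = (n(n+2) + m) / 2`, inverted as `n = ceil((-3 + sqrt(9 + 8j)) / 2)`,
#' `m = 2j - n(n+2)`.
#'
#' @param j Non-negative integer single index (vectorised).
#' @return A data.frame with columns `j`, `n` (radial order) and `m`
#'   (azimuthal frequency).
#' @examples
#' zernike_nm(0:5)
#' zernike_nm(12) # spherical aberration Z(4,0)
#' @export
zernike_nm <- function(j) {
  if (any(j < 0) || any(j != round(j))) {
    stop("'j' must be a non-negative integer")
  }
  j <- as.integer(round(j))
  n <- as.integer(ceiling((-3 + sqrt(9 + 8 * j)) / 2))
  m <- as.integer(2L * j - n * (n + 2L))
  data.frame(j = j, n = n, m = m)
}

#' Convert Zernike (n, m) to the single index j
#'
#' @param n Radial order, integer >= 0.
#' @param m Azimuthal frequency, integer with `|m| <= n` and `n - |m|` even.
#' @return Integer single index `j = (n(n+2) + m) / 2` (vectorised).
#' @examples
#' zernike_j(2, -2) # 3
#' zernike_j(3, -1) # 7
#' @export
zernike_j <- function(n, m) {
  if (any(n < 0) || any(n != round(n)) || any(m != round(m))) {
    stop("'n' must be a non-negative integer and 'm' an integer")
  }
  if (any(abs(m) > n)) stop("|m| must not exceed n")
  if (any((n - abs(m)) %% 2 != 0)) stop("n - |m| must be even")
  as.integer((n * (n + 2) + m) / 2)
}

# Radial polynomial R_n^{|m|}(rho), explicit factorial series. Orders are
# capped well below where factorial cancellation would matter in doubles.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  s_max <- (n - m) / 2
  out <- numeric(length(rho))
  for (s in 0:s_max) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

#' Evaluate a normalized Zernike polynomial
#'
#' RMS-normalized (unit variance over the unit disk) polynomials:
#' normalization constant `sqrt(2(n+1))` for `m != 0`, `sqrt(n+1)` for
#' `m == 0`; `cos(m theta)` terms for `m > 0`, `sin(|m| theta)` for `m < 0`.
#'
#' @param n Radial order (or, if `m` is missing, a single index `j`).
#' @param m Azimuthal frequency.
#' @param rho Normalized radius in \[0, 1\].
#' @param theta Azimuth in radians.
#' @return Numeric vector of polynomial values.
#' @examples
#' zernike_value(0, 0, 0.5, 0)    # piston == 1
#' zernike_value(1, 1, 1, 0)      # 2
#' @export
zernike_value <- function(n, m, rho, theta) {
  if (missing(m)) {
    nm <- zernike_nm(n)
    n <- nm$n
    m <- nm$m
  }
  zernike_j(n, m) # validates the pair
  if (any(rho < 0 | rho > 1 + 1e-12)) {
    stop("'rho' must lie in [0, 1]; no extrapolation outside the unit disk")
  }
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  norm * zernike_radial(n, m, rho) * ang
}

#' Zernike design matrix over sample points
#'
#' One column per single index `j = 0 .. (max_order+1)(max_order+2)/2 - 1`.
#'
#' @param rho Normalized radii in \[0, 1\].
#' @param theta Azimuths in radians.
#' @param max_order Highest radial order (default 8, i.e. 45 columns).
#' @return Matrix with `length(rho)` rows.
#' @export
zernike_basis <- function(rho, theta, max_order = 8) {
  if (any(rho < 0 | rho > 1 + 1e-12)) {
    stop("'rho' must lie in [0, 1]")
  }
  n_coef <- (max_order + 1) * (max_order + 2) / 2
  nm <- zernike_nm(seq_len(n_coef) - 1L)
  B <- matrix(0, nrow = length(rho), ncol = n_coef)
  for (k in seq_len(n_coef)) {
    n <- nm$n[k]
    m <- nm$m[k]
    norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
    ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
    B[, k] <- norm * zernike_radial(n, m, rho) * ang
  }
  colnames(B) <- paste0("Z", seq_len(n_coef) - 1L)
  B
}

#' Construct a Zernike coefficient object
#'
#' @param coeffs Numeric coefficient vector (micrometres), indexed by
#'   `j = 0 .. length-1`.
#' @param pupil_diameter Pupil diameter in mm.
#' @param surface_label One of `"anterior"`, `"posterior"`, `"total"`.
#' @param fit_rms_residual RMS of the fit residual in micrometres.
#' @return An object of class `zernike_coefficients`.
#' @export
zernike_coefficients <- function(coeffs, pupil_diameter,
                                 surface_label = c("total", "anterior", "posterior"),
                                 fit_rms_residual = NA_real_) {
  surface_label <- match.arg(surface_label)
  if (!is.numeric(coeffs) || any(!is.finite(coeffs))) {
    stop("coefficients must be finite numeric values")
  }
  if (pupil_diameter <= 0) stop("pupil_diameter must be positive")
  structure(
    list(
      coeffs = as.numeric(coeffs),
      pupil_diameter = pupil_diameter,
      surface_label = surface_label,
      fit_rms_residual = fit_rms_residual
    ),
    class = "zernike_coefficients"
  )
}

#' @export
print.zernike_coefficients <- function(x, ...) {
  cat(sprintf(
    "Zernike coefficients (%s surface, %.1f-mm pupil, %d terms)\n",
    x$surface_label, x$pupil_diameter, length(x$coeffs)
  ))
  cat(sprintf(
    "  HOA %.4f um | SA %.4f um | Coma %.4f um | fit residual %.2e um\n",
    hoa_rms(x), sa_rms(x), coma_rms(x), x$fit_rms_residual
  ))
  invisible(x)
}

# Fetch c[j] by single index (0-based), 0 for absent orders.
zcoef <- function(c, j) {
  v <- c$coeffs
  ifelse(j + 1 <= length(v), v[j + 1], 0)
}

#' Higher-order aberration RMS
#'
#' Root mean square of all Zernike coefficients of radial orders 3 through 8
#' (single indices j = 6..44).
#'
#' @param c A `zernike_coefficients` object (orders through 8).
#' @return HOA RMS in micrometres.
#' @export
hoa_rms <- function(c) {
  stopifnot(inherits(c, "zernike_coefficients"))
  nm <- zernike_nm(seq_along(c$coeffs) - 1L)
  keep <- nm$n >= 3 & nm$n <= 8
  sqrt(sum(c$coeffs[keep]^2))
}

#' Spherical aberration RMS
#'
#' `sqrt(Z(4,0)^2 + Z(6,0)^2)`: primary plus secondary spherical aberration.
#'
#' @inheritParams hoa_rms
#' @return SA RMS in micrometres.
#' @export
sa_rms <- function(c) {
  stopifnot(inherits(c, "zernike_coefficients"))
  sqrt(zcoef(c, zernike_j(4, 0))^2 + zcoef(c, zernike_j(6, 0))^2)
}

#' Coma RMS
#'
#' `sqrt(Z(3,-1)^2 + Z(3,1)^2)`: vertical plus horizontal coma.
#'
#' @inheritParams hoa_rms
#' @return Coma RMS in micrometres.
#' @export
coma_rms <- function(c) {
  stopifnot(inherits(c, "zernike_coefficients"))
  sqrt(zcoef(c, zernike_j(3, -1))^2 + zcoef(c, zernike_j(3, 1))^2)
}

# Design-matrix cache: QR decompositions keyed by grid geometry + pupil +
# order, so fitting a cohort on a shared grid costs one decomposition total.
.zfit_cache <- new.env(parent = emptyenv())

zfit_qr <- function(map, pupil_diameter, max_order) {
  v <- as.vector(map$valid)
  idx <- as.numeric(which(v))
  key <- paste("k", nrow(map$sag %||% map$opd), format(map$spacing, digits = 12),
               format(pupil_diameter, digits = 12), max_order,
               length(idx), sum(idx) %% 993319, sum(idx * idx) %% 993319,
               sep = "|")
  hit <- .zfit_cache[[key]]
  if (!is.null(hit)) return(hit)
  xy <- em_coords(map)
  r <- sqrt(xy$x^2 + xy$y^2)
  a <- pupil_diameter / 2
  sel <- as.vector(map$valid) & r <= a
  B <- zernike_basis(pmin(r[sel] / a, 1), atan2(xy$y[sel], xy$x[sel]), max_order)
  out <- list(qr = qr(B), B = B, sel = sel, n = sum(sel), p = ncol(B))
  if (length(.zfit_cache) > 32) rm(list = ls(.zfit_cache), envir = .zfit_cache)
  .zfit_cache[[key]] <- out
  out
}

#' Fit Zernike coefficients to an OPD map
#'
#' Ordinary least squares over the valid in-pupil samples of a Cartesian
#' optical-path-difference map; no regularization. Maps with fewer than 10
#' valid samples per coefficient are rejected.
#'
#' @param opd An `opd_map` (see [surface_opd()]).
#' @param max_order Highest radial order fitted (default 8).
#' @return A [zernike_coefficients()] object with the fit residual RMS.
#' @export
fit_zernike <- function(opd, max_order = 8) {
  stopifnot(inherits(opd, "opd_map"))
  a <- opd$pupil_diameter / 2
  if (a > opd$half_width + 1e-9) {
    stop("pupil larger than the map extent")
  }
  f <- zfit_qr(opd, opd$pupil_diameter, max_order)
  if (f$n < 10 * f$p) {
    stop(sprintf(
      "insufficient valid samples inside the pupil (%d < 10 x %d coefficients)",
      f$n, f$p
    ))
  }
  y <- as.vector(opd$opd)[f$sel]
  if (any(!is.finite(y))) stop("OPD contains non-finite values inside the pupil")
  cf <- qr.coef(f$qr, y)
  res <- y - as.vector(f$B %*% cf)
  zernike_coefficients(
    cf, opd$pupil_diameter, opd$surface_label,
    fit_rms_residual = sqrt(mean(res^2))
  )
}

#' Synthesize an OPD map from Zernike coefficients
#'
#' The inverse of [fit_zernike()] on noiseless data; useful for round-trip
#' checks and for constructing test surfaces.
#'
#' @param c A `zernike_coefficients` object.
#' @param grid A grid spec from [make_grid()].
#' @return An `opd_map` over `c$pupil_diameter`.
#' @export
synthesize_opd <- function(c, grid = make_grid()) {
  stopifnot(inherits(c, "zernike_coefficients"))
  n_coef <- length(c$coeffs)
  max_order <- round((-3 + sqrt(9 + 8 * (n_coef - 1))) / 2)
  tpl <- empty_map(grid)
  xy <- em_coords(tpl)
  a <- c$pupil_diameter / 2
  r <- sqrt(xy$x^2 + xy$y^2)
  sel <- r <= a
  vals <- rep(NA_real_, length(r))
  B <- zernike_basis(r[sel] / a, atan2(xy$y[sel], xy$x[sel]), max_order)
  vals[sel] <- as.vector(B %*% c$coeffs)
  structure(
    list(
      opd = matrix(vals, nrow = nrow(tpl$sag)),
      spacing = tpl$spacing, half_width = tpl$half_width,
      valid = matrix(sel, nrow = nrow(tpl$sag)),
      surface_label = c$surface_label, pupil_diameter = c$pupil_diameter
    ),
    class = "opd_map"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
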