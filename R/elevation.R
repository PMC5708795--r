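#' Grid specification for elevation maps
#'
#' Square Cartesian grid with an odd sample count per axis so the corneal
#' vertex falls on a sample. The default (257 x 257 over +/- 3.3 mm) covers
#' the 6-mm analysis zone with margin.
#'
#' @param half_width Half width of the grid in mm.
#' @param n Samples per axis (odd).
#' @return A list with `half_width`, `n` and derived `spacing` (mm).
#' @export
make_grid <- function(half_width = 3.3, n = 257) {
  if (n %% 2 != 1 || n < 9) stop("'n' must be odd and >= 9")
  if (half_width <= 0) stop("'half_width' must be positive")
  list(half_width = half_width, n = as.integer(n),
       spacing = 2 * half_width / (n - 1))
}

#' Construct an elevation map
#'
#' Vertex-referenced corneal surface sag on a square Cartesian grid:
#' `sag(0,0) = 0`, positive sag pointing toward the retina, units
#' micrometres, lateral units mm.
#'
#' @param sag Square numeric matrix of sag values (um); `NA` marks invalid
#'   samples.
#' @param spacing Grid spacing in mm.
#' @param valid Optional logical matrix of valid samples; defaults to
#'   `is.finite(sag)`.
#' @return An object of class `elevation_map` with fields `sag`, `spacing`,
#'   `half_width`, `valid`.
#' @export
elevation_map <- function(sag, spacing, valid = NULL) {
  sag <- as.matrix(sag)
  n <- nrow(sag)
  if (ncol(sag) != n) stop("sag must be a square matrix")
  if (n %% 2 != 1) stop("sample count per axis must be odd (vertex on-grid)")
  if (spacing <= 0) stop("spacing must be positive")
  if (is.null(valid)) valid <- is.finite(sag)
  valid <- valid & is.finite(sag)
  ctr <- (n + 1) / 2
  if (!valid[ctr, ctr] || abs(sag[ctr, ctr]) > 1e-9) {
    stop("map must be vertex-referenced: sag(0,0) = 0 and valid")
  }
  sag[!valid] <- NA_real_
  structure(
    list(sag = sag, spacing = spacing, half_width = (n - 1) / 2 * spacing,
         valid = valid),
    class = "elevation_map"
  )
}

empty_map <- function(grid = make_grid()) {
  elevation_map(matrix(0, grid$n, grid$n), grid$spacing)
}

# x/y coordinates (mm) of every sample, column-major to match as.vector().
# Rows index x, columns index y.
em_coords <- function(map) {
  n <- nrow(map$sag %||% map$opd %||% map$prp)
  ax <- (seq_len(n) - (n + 1) / 2) * map$spacing
  list(x = rep(ax, times = n), y = rep(ax, each = n))
}

#' @export
print.elevation_map <- function(x, ...) {
  cat(sprintf(
    "Elevation map: %d x %d samples, spacing %.4f mm (half width %.2f mm), %d%% valid\n",
    nrow(x$sag), ncol(x$sag), x$spacing, x$half_width,
    round(100 * mean(x$valid))
  ))
  invisible(x)
}

same_grid <- function(a, b) {
  nrow(a$sag %||% a$opd) == nrow(b$sag %||% b$opd) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

#' Construct a cornea model
#'
#' One eye's geometry: anterior and posterior elevation maps (each
#' vertex-referenced) on a shared grid plus the central corneal thickness.
#'
#' @param anterior,posterior `elevation_map` objects on the same grid.
#' @param central_thickness Central corneal thickness in um.
#' @return An object of class `cornea_model`.
#' @export
cornea_model <- function(anterior, posterior, central_thickness) {
  stopifnot(inherits(anterior, "elevation_map"), inherits(posterior, "elevation_map"))
  if (!same_grid(anterior, posterior)) stop("surfaces must share grid geometry")
  if (central_thickness <= 0) stop("central_thickness must be positive")
  structure(
    list(anterior = anterior, posterior = posterior,
         central_thickness = central_thickness),
    class = "cornea_model"
  )
}

#' @export
print.cornea_model <- function(x, ...) {
  cat(sprintf("Cornea model: CCT %.0f um\n", x$central_thickness))
  print(x$anterior)
  print(x$posterior)
  invisible(x)
}

#' Refractive indices used throughout
#'
#' Cornea 1.376, aqueous humor 1.336, air 1.000.
#' @format A named numeric vector.
#' @export
ek_indices <- c(air = 1.000, cornea = 1.376, aqueous = 1.336)

#' Surface optical path difference under the thin-phase approximation
#'
#' `OPD(x, y) = delta_n * sag(x, y)`, masked to the pupil. The anterior
#' surface uses `delta_n = 1.376 - 1.000 = 0.376`; the posterior surface
#' `delta_n = 1.336 - 1.376 = -0.040`.
#'
#' @param surface An `elevation_map`.
#' @param delta_n Refractive index step across the surface (non-zero).
#' @param pupil_diameter Analysis zone diameter in mm.
#' @param surface_label Label carried through to fitted coefficients.
#' @return An object of class `opd_map` (fields `opd` in um, grid geometry,
#'   `valid` pupil mask, `surface_label`, `pupil_diameter`).
#' @export
surface_opd <- function(surface, delta_n, pupil_diameter,
                        surface_label = c("anterior", "posterior", "total")) {
  stopifnot(inherits(surface, "elevation_map"))
  surface_label <- match.arg(surface_label)
  if (delta_n == 0) stop("delta_n must be non-zero")
  if (pupil_diameter <= 0) stop("pupil_diameter must be positive")
  xy <- em_coords(surface)
  r <- matrix(sqrt(xy$x^2 + xy$y^2), nrow = nrow(surface$sag))
  pupil <- r <= pupil_diameter / 2
  if (any(pupil & !surface$valid)) {
    stop("pupil exceeds the valid region of the surface")
  }
  opd <- delta_n * surface$sag
  opd[!pupil] <- NA_real_
  structure(
    list(opd = opd, spacing = surface$spacing, half_width = surface$half_width,
         valid = pupil, surface_label = surface_label,
         pupil_diameter = pupil_diameter),
    class = "opd_map"
  )
}

#' Anterior / posterior OPD convenience wrappers
#'
#' @param surface An `elevation_map`.
#' @param pupil_diameter Zone diameter in mm.
#' @param indices Named refractive indices (defaults [ek_indices]).
#' @return An `opd_map`.
#' @rdname surface_opd_wrappers
#' @export
anterior_opd <- function(surface, pupil_diameter, indices = ek_indices) {
  surface_opd(surface, indices[["cornea"]] - indices[["air"]],
              pupil_diameter, "anterior")
}

#' @rdname surface_opd_wrappers
#' @export
posterior_opd <- function(surface, pupil_diameter, indices = ek_indices) {
  surface_opd(surface, indices[["aqueous"]] - indices[["cornea"]],
              pupil_diameter, "posterior")
}

#' Total corneal OPD as the pointwise two-surface sum
#'
#' Paraxial additivity: the total corneal wavefront is the anterior plus the
#' posterior OPD on a shared grid and pupil. By linearity of least squares
#' the fitted Zernike coefficients are additive too.
#'
#' @param anterior,posterior `opd_map` objects with matching grid and pupil.
#' @return An `opd_map` labelled `"total"`.
#' @export
total_opd <- function(anterior, posterior) {
  stopifnot(inherits(anterior, "opd_map"), inherits(posterior, "opd_map"))
  if (!same_grid(anterior, posterior) ||
      !isTRUE(all.equal(anterior$pupil_diameter, posterior$pupil_diameter))) {
    stop("grid or pupil mismatch between anterior and posterior OPD maps")
  }
  out <- anterior
  out$opd <- anterior$opd + posterior$opd
  out$valid <- anterior$valid & posterior$valid
  out$surface_label <- "total"
  out
}

#' Aberration profile of one cornea
#'
#' HOA, SA and Coma RMS for the anterior, posterior and total corneal
#' wavefront at each requested zone diameter (defaults 4.0 and 6.0 mm),
#' via 8th-order Zernike fits of the thin-phase OPD.
#'
#' @param cornea A [cornea_model()].
#' @param zones Zone diameters in mm.
#' @param max_order Highest Zernike radial order.
#' @param indices Refractive indices, see [ek_indices].
#' @return A data.frame with columns `surface`, `zone_mm`, `hoa`, `sa`,
#'   `coma` (um), one row per surface x zone.
#' @export
aberration_profile <- function(cornea, zones = c(4, 6), max_order = 8,
                               indices = ek_indices) {
  stopifnot(inherits(cornea, "cornea_model"))
  rows <- list()
  for (z in zones) {
    ant <- anterior_opd(cornea$anterior, z, indices)
    post <- posterior_opd(cornea$posterior, z, indices)
    tot <- total_opd(ant, post)
    for (opd in list(tot, ant, post)) {
      cf <- fit_zernike(opd, max_order)
      rows[[length(rows) + 1]] <- data.frame(
        surface = opd$surface_label, zone_mm = z,
        hoa = hoa_rms(cf), sa = sa_rms(cf), coma = coma_rms(cf)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
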