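#' Color-band configuration for posterior refractive power maps
#'
#' The device color scale: green/blue ("cool") for PRP above the yellow
#' band, yellow centred at -6.3 D, orange between the yellow band and the
#' red threshold, red below -6.9 D. The printed yellow value (-6.3 D) is a
#' single contour; a configurable band width (default 0.3 D) turns it into
#' the discrete color step of the instrument scale.
#'
#' @param yellow_center Centre of the yellow band (D).
#' @param yellow_width Width of the yellow band (D), > 0.
#' @param red_threshold PRP below which a sample is red (D).
#' @param red_background_fraction Red area fraction at or above which the
#'   background itself is called red.
#' @return An object of class `band_config`.
#' @export
band_config <- function(yellow_center = -6.3, yellow_width = 0.3,
                        red_threshold = -6.9, red_background_fraction = 0.75) {
  if (yellow_width <= 0) stop("yellow_width must be positive")
  if (red_threshold >= yellow_center) {
    stop("red_threshold must lie below yellow_center")
  }
  if (red_background_fraction <= 0 || red_background_fraction > 1) {
    stop("red_background_fraction must be in (0, 1]")
  }
  structure(
    list(yellow_center = yellow_center, yellow_width = yellow_width,
         red_threshold = red_threshold,
         red_background_fraction = red_background_fraction),
    class = "band_config"
  )
}

band_levels <- c("cool", "yellow", "orange", "red")

#' Classify PRP values into color bands
#'
#' Red if `prp < red_threshold`; yellow if within half a band width of the
#' yellow centre; cool if above the yellow band; orange otherwise.
#'
#' @param prp Numeric PRP values in diopters (vectorised).
#' @param cfg A [band_config()].
#' @return Factor with levels `cool`, `yellow`, `orange`, `red`.
#' @export
classify_band <- function(prp, cfg = band_config()) {
  stopifnot(inherits(cfg, "band_config"))
  out <- rep(NA_character_, length(prp))
  fin <- is.finite(prp)
  eps <- 1e-9  # closed yellow-band edges robust to float arithmetic
  hw <- cfg$yellow_width / 2 + eps
  out[fin & prp < cfg$red_threshold] <- "red"
  yellow <- fin & prp >= cfg$red_threshold & abs(prp - cfg$yellow_center) <= hw
  out[yellow] <- "yellow"
  cool <- fin & prp > cfg$yellow_center + hw
  out[cool & !yellow] <- "cool"
  out[fin & is.na(out)] <- "orange"
  factor(out, levels = band_levels)
}

# Meridional (radial) slope dz/dr on the Cartesian grid via central
# differences; one-sided at map edges. z in the same units as sag.
radial_slope <- function(sag, spacing) {
  n <- nrow(sag)
  zx <- sag
  zy <- sag
  zx[2:(n - 1), ] <- (sag[3:n, ] - sag[1:(n - 2), ]) / (2 * spacing)
  zx[1, ] <- (sag[2, ] - sag[1, ]) / spacing
  zx[n, ] <- (sag[n, ] - sag[n - 1, ]) / spacing
  zy[, 2:(n - 1)] <- (sag[, 3:n] - sag[, 1:(n - 2)]) / (2 * spacing)
  zy[, 1] <- (sag[, 2] - sag[, 1]) / spacing
  zy[, n] <- (sag[, n] - sag[, n - 1]) / spacing
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  x <- matrix(ax, n, n)
  y <- t(x)
  r <- sqrt(x^2 + y^2)
  zr <- (x * zx + y * zy) / r
  list(zr = zr, r = r)
}

#' Axial (sagittal) radius map of a corneal surface
#'
#' Axial radius `R_a(r) = r * sqrt(1 + (dz/dr)^2) / (dz/dr)` with z in mm,
#' the distance from the surface point to the optical axis along the surface
#' normal (the quantity behind device "axial maps"). The meridional slope is
#' computed by central differences on the Cartesian grid. Near the vertex
#' (r < 3 grid steps) the circle-through-vertex form `R = (r^2 + z^2) / (2z)`
#' is used; it is exact for a sphere and is the correct r -> 0 limit. The
#' vertex sample takes the mean of its four neighbours. Locally flat or
#' inverted samples (non-positive slope) are masked invalid.
#'
#' @param posterior An `elevation_map` (sag in um).
#' @return List with `radius` (matrix, mm; NA where invalid), `valid`,
#'   `spacing`, `half_width`.
#' @export
axial_radius_map <- function(posterior) {
  stopifnot(inherits(posterior, "elevation_map"))
  z_mm <- posterior$sag / 1000
  sl <- radial_slope(z_mm, posterior$spacing)
  R <- sl$r * sqrt(1 + sl$zr^2) / sl$zr
  near <- sl$r < 3 * posterior$spacing & sl$r > 0
  R[near] <- (sl$r[near]^2 + z_mm[near]^2) / (2 * z_mm[near])
  n <- nrow(R)
  ctr <- (n + 1) / 2
  nb <- c(R[ctr - 1, ctr], R[ctr + 1, ctr], R[ctr, ctr - 1], R[ctr, ctr + 1])
  R[ctr, ctr] <- mean(nb[is.finite(nb) & nb > 0])
  valid <- posterior$valid & is.finite(R) & R > 0
  R[!valid] <- NA_real_
  list(radius = R, valid = valid, spacing = posterior$spacing,
       half_width = posterior$half_width)
}

#' Posterior refractive power map
#'
#' `PRP(x, y) = (n_aqueous - n_cornea) / R_a(x, y)` with the axial radius in
#' metres, yielding negative diopters for a normal posterior surface
#' (index step -0.040).
#'
#' @param posterior An `elevation_map` of the posterior surface.
#' @param n_cornea,n_aqueous Refractive indices (defaults 1.376 / 1.336).
#' @param zone_diameter Grading zone diameter in mm (default 6).
#' @return An object of class `prp_map` with fields `prp` (D), `valid`,
#'   `spacing`, `half_width`, `zone_diameter`.
#' @export
prp_map <- function(posterior, n_cornea = 1.376, n_aqueous = 1.336,
                    zone_diameter = 6) {
  ax <- axial_radius_map(posterior)
  prp <- (n_aqueous - n_cornea) / (ax$radius / 1000)
  prp[!ax$valid] <- NA_real_
  structure(
    list(prp = prp, valid = ax$valid, spacing = ax$spacing,
         half_width = ax$half_width, zone_diameter = zone_diameter),
    class = "prp_map"
  )
}

#' Build a `prp_map` from explicit PRP values
#'
#' For maps already expressed in diopters (e.g. read from disk or
#' constructed in tests).
#'
#' @param prp Square numeric matrix of PRP values (D).
#' @param spacing Grid spacing in mm.
#' @param zone_diameter Grading zone diameter in mm.
#' @return A `prp_map`.
#' @export
as_prp_map <- function(prp, spacing, zone_diameter = 6) {
  prp <- as.matrix(prp)
  n <- nrow(prp)
  if (ncol(prp) != n || n %% 2 != 1) stop("prp must be a square odd-sized matrix")
  structure(
    list(prp = prp, valid = is.finite(prp), spacing = spacing,
         half_width = (n - 1) / 2 * spacing, zone_diameter = zone_diameter),
    class = "prp_map"
  )
}

zone_values <- function(m) {
  stopifnot(inherits(m, "prp_map"))
  xy <- em_coords(m)
  r <- sqrt(xy$x^2 + xy$y^2)
  inzone <- r <= m$zone_diameter / 2
  ok <- inzone & as.vector(m$valid)
  if (sum(ok) < 0.5 * sum(inzone)) {
    stop("fewer than 50% of the grading-zone samples are valid")
  }
  as.vector(m$prp)[ok]
}

#' Area fractions of the color bands over the grading zone
#'
#' @param m A [prp_map()].
#' @param cfg A [band_config()].
#' @return Named numeric vector over `cool`, `yellow`, `orange`, `red`,
#'   summing to 1 (area-weighted over valid zone samples).
#' @export
band_fractions <- function(m, cfg = band_config()) {
  bands <- classify_band(zone_values(m), cfg)
  tab <- table(bands)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Red area fraction of the grading zone
#'
#' @inheritParams band_fractions
#' @return Fraction in \[0, 1\] of the zone area with PRP below the red
#'   threshold.
#' @export
red_fraction <- function(m, cfg = band_config()) {
  unname(band_fractions(m, cfg)["red"])
}

#' Background color band of a PRP map
#'
#' The background is the modal band by area among the non-red samples of the
#' grading zone; the background is called red only when the red fraction
#' reaches `cfg$red_background_fraction` (default 0.75).
#'
#' @inheritParams band_fractions
#' @return One of `"cool"`, `"yellow"`, `"orange"`, `"red"`.
#' @export
background_band <- function(m, cfg = band_config()) {
  fr <- band_fractions(m, cfg)
  if (fr["red"] >= cfg$red_background_fraction) return("red")
  nr <- fr[setdiff(band_levels, "red")]
  # ties broken toward the steeper (warmer) band, deterministically
  names(nr)[max(which(nr == max(nr)))]
}

#' Posterior color grade (0-5)
#'
#' Automated version of the posterior topography grade: grade 0 for a cool
#' background, 1 for yellow, 2-4 for an orange background depending on the
#' red area fraction (< 1/4, \[1/4, 1/2), >= 1/2; boundaries closed on the
#' higher grade), and 5 when the background itself is red.
#'
#' @inheritParams band_fractions
#' @return An object of class `grade_result`: `grade` (integer 0-5),
#'   `background_band`, `red_fraction`, `band_fractions`.
#' @export
posterior_grade <- function(m, cfg = band_config()) {
  fr <- band_fractions(m, cfg)
  bg <- background_band(m, cfg)
  red <- unname(fr["red"])
  grade <- switch(bg,
    red = 5L,
    cool = 0L,
    yellow = 1L,
    orange = if (red < 0.25) 2L else if (red < 0.5) 3L else 4L
  )
  structure(
    list(grade = grade, background_band = bg, red_fraction = red,
         band_fractions = fr),
    class = "grade_result"
  )
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf(
    "Posterior color grade %d (background %s, red fraction %.3f)\n",
    x$grade, x$background_band, x$red_fraction
  ))
  invisible(x)
}

#' Serialize a grade result to JSON
#'
#' @param x A `grade_result`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
grade_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "grade_result"))
  obj <- list(
    grade = x$grade, background_band = x$background_band,
    red_fraction = x$red_fraction,
    band_fractions = as.list(x$band_fractions)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Grade a cornea's posterior surface
#'
#' Convenience wrapper: posterior elevation map -> PRP map -> grade.
#'
#' @param cornea A [cornea_model()] or posterior `elevation_map`.
#' @param cfg A [band_config()].
#' @param zone_diameter Grading zone diameter in mm.
#' @return A `grade_result`.
#' @export
grade_cornea <- function(cornea, cfg = band_config(), zone_diameter = 6) {
  post <- if (inherits(cornea, "cornea_model")) cornea$posterior else cornea
  posterior_grade(prp_map(post, zone_diameter = zone_diameter), cfg)
}

#' Plot a PRP map with the device-style palette
#'
#' Cool (blue/green), yellow, orange and red bands per the grading scale.
#'
#' @param m A `prp_map`.
#' @param cfg A [band_config()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the band matrix.
#' @export
plot_prp_map <- function(m, cfg = band_config(), ...) {
  stopifnot(inherits(m, "prp_map"))
  bands <- matrix(as.integer(classify_band(as.vector(m$prp), cfg)),
                  nrow = nrow(m$prp))
  n <- nrow(bands)
  ax <- (seq_len(n) - (n + 1) / 2) * m$spacing
  graphics::image(ax, ax, bands, zlim = c(1, 4),
                  col = c("#2c7fb8", "#ffff99", "#fe9929", "#d7301f"),
                  asp = 1, xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(bands)
}
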