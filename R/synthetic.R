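#' Conicoid (conic-section) surface sag
#'
#' Standard rotationally symmetric conic sag
#' `z(r) = r^2 / (R (1 + sqrt(1 - (1+Q) r^2 / R^2)))` with apical radius `R`
#' (mm) and asphericity `Q` (Q = 0 sphere, Q < 0 prolate), returned as a
#' vertex-referenced [elevation_map()] in micrometres. Samples where the
#' conic is undefined are masked invalid.
#'
#' @param R Apical radius of curvature in mm (> 0).
#' @param Q Conic asphericity.
#' @param grid Grid spec from [make_grid()].
#' @return An `elevation_map`.
#' @export
make_conicoid <- function(R, Q = 0, grid = make_grid()) {
  if (R <= 0) stop("'R' must be positive")
  n <- grid$n
  ax <- (seq_len(n) - (n + 1) / 2) * grid$spacing
  r2 <- outer(ax^2, ax^2, "+")
  disc <- 1 - (1 + Q) * r2 / R^2
  ok <- disc > 1e-9 & sqrt(r2) <= grid$half_width + 1e-9
  z <- matrix(NA_real_, n, n)
  z[ok] <- 1000 * r2[ok] / (R * (1 + sqrt(disc[ok])))
  if (!all(ok[sqrt(r2) <= grid$half_width])) {
    # conic undefined inside the nominal map: mark invalid rather than error
    ok <- ok
  }
  elevation_map(z, grid$spacing)
}

# cache of full-disk Zernike basis matrices for perturbation synthesis
.synth_cache <- new.env(parent = emptyenv())

synth_basis <- function(map) {
  key <- paste("b", nrow(map$sag), format(map$spacing, digits = 12), sep = "|")
  hit <- .synth_cache[[key]]
  if (!is.null(hit)) return(hit)
  xy <- em_coords(map)
  r <- sqrt(xy$x^2 + xy$y^2)
  sel <- r <= map$half_width + 1e-9
  B <- zernike_basis(pmin(r[sel] / map$half_width, 1),
                     atan2(xy$y[sel], xy$x[sel]), 8)
  out <- list(B = B, sel = sel)
  .synth_cache[[key]] <- out
  out
}

#' Add a Zernike-expressed perturbation to a surface
#'
#' The perturbation is synthesized from 45 single-index coefficients (um)
#' over a support disk spanning the full map width, then vertex-re-referenced
#' so the result keeps `sag(0,0) = 0`.
#'
#' @param surface An `elevation_map`.
#' @param coeffs Numeric vector of 45 Zernike coefficients (um).
#' @return The perturbed `elevation_map`.
#' @export
add_zernike_perturbation <- function(surface, coeffs) {
  stopifnot(inherits(surface, "elevation_map"), length(coeffs) == 45)
  sb <- synth_basis(surface)
  pert <- rep(0, length(sb$sel))
  pert[sb$sel] <- as.vector(sb$B %*% coeffs)
  pm <- matrix(pert, nrow = nrow(surface$sag))
  ctr <- (nrow(pm) + 1) / 2
  sag <- surface$sag + (pm - pm[ctr, ctr])
  elevation_map(sag, surface$spacing, valid = surface$valid)
}

# Radially symmetric central steepening: vertex-referenced sag increases by
# amplitude * ((1 - cos(pi * min(r, e)/e)) / 2)^p away from the vertex,
# i.e. the central surface is displaced anteriorly by up to `amplitude`
# relative to the feature edge. Steepens central axial power.
central_steepening <- function(surface, amplitude, edge_radius, exponent = 1) {
  stopifnot(inherits(surface, "elevation_map"))
  if (edge_radius <= 0) stop("edge radius must be positive")
  if (amplitude == 0) return(surface)
  n <- nrow(surface$sag)
  ax <- (seq_len(n) - (n + 1) / 2) * surface$spacing
  r <- sqrt(outer(ax^2, ax^2, "+"))
  prof <- ((1 - cos(pi * pmin(r, edge_radius) / edge_radius)) / 2)^exponent
  elevation_map(surface$sag + amplitude * prof, surface$spacing,
                valid = surface$valid)
}

#' DSAEK meniscus lenticule on the posterior surface
#'
#' Models the posterior addition of a meniscus-shaped stromal graft, thicker
#' toward its edge than at its centre: relative to the vertex the posterior
#' sag rises by up to `amplitude` um at `edge_radius`, steepening the central
#' posterior power (the steep red central zone typical after DSAEK) and
#' raising spherical aberration.
#'
#' @param posterior Posterior `elevation_map`.
#' @param amplitude Maximum relative posterior displacement in um (>= 0).
#' @param edge_radius Radius at which the lenticule profile levels off (mm).
#' @param smoothness Exponent of the raised-cosine profile (default 1).
#' @return The modified `elevation_map`.
#' @export
dsaek_meniscus <- function(posterior, amplitude, edge_radius = 2.6,
                           smoothness = 1) {
  central_steepening(posterior, amplitude, edge_radius, smoothness)
}

#' DMEK central dehydration steepening
#'
#' After DMEK the corneal edema clears centrally first; central stromal
#' thinning pulls the central posterior surface anteriorly, steepening
#' central posterior power. Shallower and wider than the DSAEK meniscus.
#'
#' @param posterior Posterior `elevation_map`.
#' @param amplitude Central steepening amplitude in um (>= 0).
#' @param zone_radius Radius of the affected zone (mm).
#' @return The modified `elevation_map`.
#' @export
dmek_dehydration <- function(posterior, amplitude, zone_radius = 3.2) {
  central_steepening(posterior, amplitude, zone_radius, 1)
}

#' Visual-acuity response model
#'
#' Linear logMAR response to the posterior color grade and the total 6-mm
#' HOA, with Gaussian noise and a floor at the best achievable acuity.
#'
#' @param intercept Intercept, logMAR.
#' @param beta_grade logMAR per grade unit.
#' @param beta_hoa logMAR per um of total HOA (6 mm).
#' @param noise_sd Residual SD, logMAR.
#' @param floor Best achievable logMAR (default -0.08).
#' @return An object of class `bscva_model`.
#' @export
bscva_model <- function(intercept = ek_presets$bscva["intercept"],
                        beta_grade = ek_presets$bscva["beta_grade"],
                        beta_hoa = ek_presets$bscva["beta_hoa"],
                        noise_sd = ek_presets$bscva["noise_sd"],
                        floor = ek_presets$bscva["floor"]) {
  noise_sd <- unname(noise_sd)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(intercept = unname(intercept), beta_grade = unname(beta_grade),
         beta_hoa = unname(beta_hoa), noise_sd = noise_sd,
         floor = unname(floor)),
    class = "bscva_model"
  )
}

#' BSCVA from pipeline metrics
#'
#' `max(floor, intercept + beta_grade * grade + beta_hoa * hoa + z * noise_sd)`.
#'
#' @param total_hoa6 Total corneal HOA RMS at 6 mm (um).
#' @param grade Posterior color grade (0-5).
#' @param model A [bscva_model()].
#' @param z Standard-normal noise draw(s); defaults to fresh draws.
#' @return logMAR value(s).
#' @export
bscva_from_metrics <- function(total_hoa6, grade, model = bscva_model(),
                               z = stats::rnorm(length(grade))) {
  stopifnot(inherits(model, "bscva_model"))
  pmax(model$floor,
       model$intercept + model$beta_grade * grade +
         model$beta_hoa * total_hoa6 + z * model$noise_sd)
}

tp_levels <- c("pre", "1m", "3m", "6m")

#' Group preset for the synthetic cohort generator
#'
#' Distributional parameters of one study group. Per-timepoint vectors are
#' named over `pre`, `1m`, `3m`, `6m`. Perturbation scales are surface-sag
#' RMS values in um over the map support; the feature amplitude is lognormal
#' per eye. Shipped calibrated presets live in [ek_presets].
#'
#' @param group Group label.
#' @param anterior_R,anterior_Q,posterior_R,posterior_Q Length-2 vectors
#'   `c(mean, sd)` of the conicoid parameters (radii mm).
#' @param ant_pert_rms,post_pert_rms Per-timepoint HOA perturbation RMS (um).
#' @param ant_sa_shift Per-timepoint deterministic anterior Z(4,0) surface
#'   shift (um), carrying the post-surgical spherical-aberration elevation.
#' @param post_sa_shift Per-timepoint deterministic posterior Z(4,0) surface
#'   shift (um), carrying the posterior spherical-aberration elevation of
#'   grafted / dehydrating corneas.
#' @param feature `"none"`, `"dmek"` or `"dsaek"`.
#' @param feature_meanlog Per-timepoint lognormal meanlog of the feature
#'   amplitude (log um); `-Inf` disables.
#' @param feature_sdlog Lognormal sdlog of the feature amplitude.
#' @param feature_edge Feature edge radius (mm).
#' @param post_R_offset Per-timepoint global posterior steepening (mm
#'   subtracted from the eye's posterior apical radius), modelling the
#'   overall curvature change of the edematous / freshly grafted cornea
#'   that relaxes over follow-up.
#' @param cct_mean,cct_sd Per-timepoint central corneal thickness (um).
#' @param age Length-2 `c(mean, sd)` in years.
#' @param male_p,right_p Probability of male sex / right eye.
#' @return An object of class `group_preset`.
#' @export
group_preset <- function(group, anterior_R, anterior_Q, posterior_R,
                         posterior_Q, ant_pert_rms, post_pert_rms,
                         ant_sa_shift, post_sa_shift = rep(0, 4),
                         feature = "none",
                         feature_meanlog = rep(-Inf, 4), feature_sdlog = 0.35,
                         feature_edge = 2.6, post_R_offset = rep(0, 4),
                         cct_mean, cct_sd,
                         age = c(74, 7), male_p = 0.3, right_p = 0.6) {
  tpv <- function(x) {
    if (is.null(names(x))) names(x) <- tp_levels
    stopifnot(all(tp_levels %in% names(x)))
    x[tp_levels]
  }
  if (anterior_R[1] <= 0 || posterior_R[1] <= 0) stop("radii must be positive")
  structure(
    list(group = group,
         anterior_R = anterior_R, anterior_Q = anterior_Q,
         posterior_R = posterior_R, posterior_Q = posterior_Q,
         ant_pert_rms = tpv(ant_pert_rms), post_pert_rms = tpv(post_pert_rms),
         ant_sa_shift = tpv(ant_sa_shift), post_sa_shift = tpv(post_sa_shift),
         feature = feature,
         feature_meanlog = tpv(feature_meanlog), feature_sdlog = feature_sdlog,
         feature_edge = feature_edge, post_R_offset = tpv(post_R_offset),
         cct_mean = tpv(cct_mean), cct_sd = tpv(cct_sd),
         age = age, male_p = male_p, right_p = right_p),
    class = "group_preset"
  )
}

# spectral weighting of random HOA perturbations: amplitude ~ n^-3 per
# radial order (most irregularity in the low orders, coma-dominated, as in
# topographic HOA spectra), unit-RMS direction vector over indices 6..44
hoa_direction <- function(z39) {
  nm <- zernike_nm(6:44)
  w <- 1 / nm$n^3
  c39 <- z39 * w
  c45 <- numeric(45)
  c45[7:45] <- c39 / sqrt(sum(c39^2))
  c45
}

draw_eye_latents <- function(preset) {
  list(
    aR = preset$anterior_R[1] + preset$anterior_R[2] * stats::rnorm(1),
    aQ = preset$anterior_Q[1] + preset$anterior_Q[2] * stats::rnorm(1),
    pR = preset$posterior_R[1] + preset$posterior_R[2] * stats::rnorm(1),
    pQ = preset$posterior_Q[1] + preset$posterior_Q[2] * stats::rnorm(1),
    ant_dir = hoa_direction(stats::rnorm(39)),
    post_dir = hoa_direction(stats::rnorm(39)),
    pert_lat = stats::rnorm(1),   # lognormal latitude of perturbation scale
    amp_z = stats::rnorm(1),      # feature amplitude latent
    bscva_z = stats::rnorm(4),
    cct_z = stats::rnorm(1),
    age = preset$age[1] + preset$age[2] * stats::rnorm(1),
    sex = if (stats::runif(1) < preset$male_p) "M" else "F",
    eye = if (stats::runif(1) < preset$right_p) "R" else "L"
  )
}

# Deterministic geometry build from latents; no RNG use.
build_eye_cornea <- function(preset, lat, timepoint, grid) {
  tp <- match.arg(timepoint, tp_levels)
  pert_fac <- exp(0.30 * lat$pert_lat)
  ant_c <- lat$ant_dir * preset$ant_pert_rms[tp] * pert_fac
  ant_c[13] <- ant_c[13] + preset$ant_sa_shift[tp]
  anterior <- add_zernike_perturbation(
    make_conicoid(lat$aR, lat$aQ, grid), ant_c
  )
  post_c <- lat$post_dir * preset$post_pert_rms[tp] * pert_fac
  post_c[13] <- post_c[13] + preset$post_sa_shift[[tp]]
  posterior <- add_zernike_perturbation(
    make_conicoid(max(4.5, lat$pR - preset$post_R_offset[[tp]]), lat$pQ, grid),
    post_c
  )
  ml <- preset$feature_meanlog[tp]
  if (is.finite(ml) && preset$feature != "none") {
    amp <- exp(ml + preset$feature_sdlog * lat$amp_z)
    posterior <- if (preset$feature == "dsaek") {
      dsaek_meniscus(posterior, amp, preset$feature_edge)
    } else {
      dmek_dehydration(posterior, amp, preset$feature_edge)
    }
  }
  cct <- preset$cct_mean[tp] + preset$cct_sd[tp] * lat$cct_z
  cornea_model(anterior, posterior, max(300, cct))
}

#' Cohort configuration
#'
#' @param groups Named list; each element a list with `preset`
#'   (a [group_preset()]), `n` (eyes) and `timepoints` (subset of
#'   `c("pre","1m","3m","6m")`).
#' @param grid Grid spec for all surfaces.
#' @param bscva A [bscva_model()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups = default_groups(), grid = make_grid(),
                          bscva = bscva_model()) {
  for (g in groups) {
    stopifnot(inherits(g$preset, "group_preset"), g$n >= 1,
              all(g$timepoints %in% tp_levels))
  }
  structure(list(groups = groups, grid = grid, bscva = bscva),
            class = "cohort_config")
}

#' Default study groups
#'
#' The study sizes: 18 control eyes (single visit), 19 DMEK and 23 DSAEK
#' eyes followed preoperatively and at 1, 3 and 6 months.
#'
#' @return Named list suitable for [cohort_config()].
#' @export
default_groups <- function() {
  list(
    control = list(preset = ek_presets$control, n = 18, timepoints = "pre"),
    DMEK = list(preset = ek_presets$DMEK, n = 19, timepoints = tp_levels),
    DSAEK = list(preset = ek_presets$DSAEK, n = 23, timepoints = tp_levels)
  )
}

#' Sample a synthetic cohort
#'
#' Seeded, deterministic generation of per-eye latent parameters and
#' longitudinal records. Per-eye latents are drawn once and shared across
#' timepoints, so follow-up visits of one eye are correlated; the
#' per-timepoint perturbation and feature scales of the preset then shape
#' each visit. Geometry is built lazily by [eye_cornea()] /
#' [analyze_cohort()] unless `materialize = TRUE`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; required for reproducibility.
#' @param materialize If `TRUE`, store the built `cornea_model` in each
#'   record (memory-heavy for large cohorts).
#' @return An object of class `ek_cohort`: list with `records` and `config`.
#' @export
sample_cohort <- function(config = cohort_config(), seed, materialize = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (missing(seed)) stop("'seed' is required")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  records <- list()
  for (gname in names(config$groups)) {
    g <- config$groups[[gname]]
    for (i in seq_len(g$n)) {
      lat <- draw_eye_latents(g$preset)
      for (tp in g$timepoints) {
        rec <- list(
          eye_id = sprintf("%s_%03d", gname, i),
          group = gname, timepoint = tp,
          age = lat$age, sex = lat$sex, eye = lat$eye,
          cct = max(300, g$preset$cct_mean[[tp]] + g$preset$cct_sd[[tp]] * lat$cct_z),
          bscva_z = lat$bscva_z[match(tp, tp_levels)],
          latents = lat, preset = g$preset
        )
        if (materialize) {
          rec$cornea <- build_eye_cornea(g$preset, lat, tp, config$grid)
        }
        records[[length(records) + 1]] <- rec
      }
    }
  }
  structure(list(records = records, config = config), class = "ek_cohort")
}

#' @export
print.ek_cohort <- function(x, ...) {
  tab <- table(vapply(x$records, `[[`, "", "group"),
               vapply(x$records, `[[`, "", "timepoint"))
  cat(sprintf("Synthetic EK cohort: %d records\n", length(x$records)))
  print(tab)
  invisible(x)
}

#' Build the cornea model of one cohort record
#'
#' @param cohort An `ek_cohort`.
#' @param i Record index.
#' @return A `cornea_model`.
#' @export
eye_cornea <- function(cohort, i) {
  stopifnot(inherits(cohort, "ek_cohort"))
  rec <- cohort$records[[i]]
  rec$cornea %||% build_eye_cornea(rec$preset, rec$latents, rec$timepoint,
                                   cohort$config$grid)
}

#' Run the full per-eye pipeline over a cohort
#'
#' For every record: build the surfaces, compute the anterior/posterior/total
#' Zernike aberration metrics at the requested zones, compute the posterior
#' refractive power map and its color grade, and evaluate the BSCVA response
#' model with the record's frozen noise draw.
#'
#' @param cohort An `ek_cohort` from [sample_cohort()].
#' @param zones Zone diameters in mm.
#' @param cfg A [band_config()].
#' @param progress Print a dot every 25 eyes.
#' @return A data.frame, one row per record: identifiers, demographics,
#'   `cct`, metric columns `hoa_/sa_/coma_<surface>_<zone>`, `grade`,
#'   `red_fraction`, `background`, `bscva`.
#' @export
analyze_cohort <- function(cohort, zones = c(4, 6), cfg = band_config(),
                           progress = FALSE) {
  stopifnot(inherits(cohort, "ek_cohort"))
  model <- cohort$config$bscva
  rows <- vector("list", length(cohort$records))
  for (i in seq_along(cohort$records)) {
    rec <- cohort$records[[i]]
    cornea <- eye_cornea(cohort, i)
    ab <- aberration_profile(cornea, zones)
    gr <- grade_cornea(cornea, cfg)
    met <- list()
    for (k in seq_len(nrow(ab))) {
      base <- paste0(ab$surface[k], "_", ab$zone_mm[k])
      met[[paste0("hoa_", base)]] <- ab$hoa[k]
      met[[paste0("sa_", base)]] <- ab$sa[k]
      met[[paste0("coma_", base)]] <- ab$coma[k]
    }
    hoa6 <- met[["hoa_total_6"]]
    if (is.null(hoa6)) stop("zones must include 6 mm for the BSCVA model")
    rows[[i]] <- data.frame(
      eye_id = rec$eye_id, group = rec$group, timepoint = rec$timepoint,
      age = rec$age, sex = rec$sex, eye = rec$eye, cct = rec$cct,
      as.data.frame(met),
      grade = gr$grade, red_fraction = gr$red_fraction,
      background = gr$background_band,
      bscva = bscva_from_metrics(hoa6, gr$grade, model, rec$bscva_z)
    )
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
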