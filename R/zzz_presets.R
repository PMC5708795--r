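# Calibrated generator presets. The perturbation scales, conicoid
# asphericities, feature amplitudes, posterior steepening offsets and BSCVA
# coefficients were fitted once (inst/scripts/calibrate-presets.R) so that
# the full pipeline applied to large preset cohorts reproduces the
# published group-level means (grade trajectories, 6-mm aberration profile,
# BSCVA) under the thin-phase OPD model; they are generator constructs, not
# measured corneal parameters.

#' Shipped calibrated presets
#'
#' Named list with the three [group_preset()] objects (`control`, `DMEK`,
#' `DSAEK`) and the calibrated [bscva_model()] coefficient vector (`bscva`).
#'
#' @format A named list.
#' @export
ek_presets <- local({
  bscva <- c(intercept = -0.4898, beta_grade = 0.2424, beta_hoa = 0.05,
             noise_sd = 0.3253, floor = -0.08)
  tp <- function(pre, m1, m3, m6) c(pre = pre, `1m` = m1, `3m` = m3, `6m` = m6)
  control <- group_preset(
    group = "control",
    anterior_R = c(7.80, 0.20), anterior_Q = c(-0.7231, 0.06),
    posterior_R = c(6.3042, 0.15), posterior_Q = c(-0.65, 0.08),
    ant_pert_rms = tp(0.4232, 0.4232, 0.4232, 0.4232),
    post_pert_rms = tp(1.40, 1.40, 1.40, 1.40),
    ant_sa_shift = tp(0, 0, 0, 0),
    feature = "none",
    cct_mean = tp(527, 527, 527, 527), cct_sd = tp(27, 27, 27, 27),
    age = c(74.8, 6.7), male_p = 6 / 18, right_p = 14 / 18
  )
  dmek <- group_preset(
    group = "DMEK",
    anterior_R = c(7.80, 0.20), anterior_Q = c(-0.7231, 0.06),
    posterior_R = c(6.3042, 0.15), posterior_Q = c(-0.65, 0.08),
    ant_pert_rms = tp(2.0465, 1.6517, 1.2688, 1.3314),
    post_pert_rms = tp(1.80, 2.9810, 4.0500, 3.3892),
    ant_sa_shift = tp(0.2833, 0.0040, -0.2240, -0.2870),
    post_sa_shift = tp(5.60, 2.4514, -0.7918, -0.8774),
    feature = "dmek",
    feature_meanlog = tp(4.8218, 4.3400, 3.6730, 3.4570),
    feature_sdlog = 0.35, feature_edge = 3.2,
    cct_mean = tp(714, 540, 500, 480), cct_sd = tp(99, 60, 50, 45),
    age = c(72.2, 8.2), male_p = 4 / 19, right_p = 13 / 19
  )
  dsaek <- group_preset(
    group = "DSAEK",
    anterior_R = c(7.80, 0.20), anterior_Q = c(-0.7231, 0.06),
    posterior_R = c(5.90, 0.15), posterior_Q = c(-0.65, 0.08),
    ant_pert_rms = tp(2.8550, 2.6280, 2.3172, 1.9250),
    post_pert_rms = tp(2.20, 0.10, 5.5050, 5.7286),
    ant_sa_shift = tp(1.1518, 0.5633, 0.2180, 0.2756),
    post_sa_shift = tp(3.5224, 0.00, -1.20, -3.60),
    feature = "dsaek",
    feature_meanlog = tp(3.5393, 3.9661, 3.7717, 2.1804),
    feature_sdlog = 0.35, feature_edge = 2.8,
    post_R_offset = tp(0.45, 0.35, 0.15, 0.05),
    cct_mean = tp(759, 650, 620, 600), cct_sd = tp(130, 60, 55, 50),
    age = c(73.7, 5.9), male_p = 5 / 23, right_p = 14 / 23
  )
  list(control = control, DMEK = dmek, DSAEK = dsaek, bscva = bscva)
})
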