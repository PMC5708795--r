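# Surface geometry -> OPD -> aberration metrics.

test_that("conicoid sag matches the closed forms", {
  g <- exact_grid()  # r = 3.0 mm lies on-grid
  m <- make_conicoid(7.8, 0, g)
  ctr <- (nrow(m$sag) + 1) / 2
  i3 <- ctr + round(3 / m$spacing)
  expect_equal(m$sag[ctr, ctr], 0)
  # sphere sag R - sqrt(R^2 - r^2) = 7.8 - 7.2 = 0.6 mm exactly
  expect_equal(m$sag[i3, ctr], 600, tolerance = 1e-9)
  # paraboloid: sag = r^2 / (2R)
  p <- make_conicoid(7.8, -1, g)
  expect_equal(p$sag[i3, ctr], 1000 * 9 / (2 * 7.8), tolerance = 1e-9)
  expect_error(make_conicoid(-1, 0, g), "positive")
})

test_that("surface OPD is delta_n times sag, masked to the pupil", {
  g <- small_grid(129)
  flat <- elevation_map(matrix(0, g$n, g$n), g$spacing)
  opd <- surface_opd(flat, 0.376, 6, "anterior")
  expect_equal(max(abs(opd$opd[opd$valid])), 0)
  m <- make_conicoid(7.8, -0.2, g)
  a <- anterior_opd(m, 6)
  expect_equal(a$opd[a$valid], 0.376 * m$sag[a$valid])
  p <- posterior_opd(m, 6)
  expect_equal(p$opd[p$valid], -0.040 * m$sag[p$valid])
  expect_error(surface_opd(m, 0, 6), "non-zero")
  expect_error(surface_opd(m, 0.376, 8), "exceeds the valid region")
})

test_that("a sphere's OPD carries only rotationally symmetric terms", {
  g <- small_grid(129)
  sp <- make_conicoid(6.5, 0, g)
  fit <- fit_zernike(posterior_opd(sp, 6))
  nm <- zernike_nm(0:44)
  expect_lt(max(abs(fit$coeffs[nm$m != 0])), 1e-6)
  expect_equal(coma_rms(fit), 0, tolerance = 1e-6)
})

test_that("fitted Z(4,0) of a conicoid OPD matches the projection-integral oracle", {
  # independent oracle: 1D radial quadrature of the continuous projection
  # c40 = int_0^1 dn * sag(a rho) * sqrt(5)(6 rho^4 - 6 rho^2 + 1) 2 rho drho
  R <- 7.8; Q <- -0.2; dn <- 0.376; a <- 3
  sag_um <- function(r) 1000 * r^2 / (R * (1 + sqrt(1 - (1 + Q) * r^2 / R^2)))
  oracle <- integrate(function(rho) {
    dn * sag_um(a * rho) * sqrt(5) * (6 * rho^4 - 6 * rho^2 + 1) * 2 * rho
  }, 0, 1, rel.tol = 1e-10)$value
  fit <- fit_zernike(anterior_opd(make_conicoid(R, Q), 6))
  expect_equal(fit$coeffs[13], oracle, tolerance = 1e-4)
})

test_that("total OPD is the pointwise sum with additive coefficients", {
  g <- small_grid(129)
  ant <- anterior_opd(make_conicoid(7.8, -0.2, g), 6)
  zero <- make_conicoid(7.8, -0.2, g)
  zero$sag[] <- 0
  post0 <- posterior_opd(zero, 6)
  tot <- total_opd(ant, post0)
  expect_equal(tot$opd[tot$valid], ant$opd[ant$valid])

  post <- posterior_opd(make_conicoid(6.4, -0.4, g), 6)
  tot2 <- total_opd(ant, post)
  fa <- fit_zernike(ant); fp <- fit_zernike(post); ft <- fit_zernike(tot2)
  expect_lt(max(abs(ft$coeffs - (fa$coeffs + fp$coeffs))), 1e-9)
})

test_that("anterior coma can be compensated by the posterior surface", {
  g <- small_grid(129)
  base_a <- make_conicoid(7.8, -0.2, g)
  base_p <- make_conicoid(6.4, -0.4, g)
  cv <- rep(0, 45); cv[9] <- 0.5 / 0.376  # Z(3,1) on the anterior surface
  ant_s <- add_zernike_perturbation(base_a, cv)
  # posterior perturbation scaled to cancel it through the -0.040 index step
  pv <- rep(0, 45); pv[9] <- 0.5 / 0.040
  post_s <- add_zernike_perturbation(base_p, pv)
  tot <- total_opd(anterior_opd(ant_s, 6), posterior_opd(post_s, 6))
  expect_lt(coma_rms(fit_zernike(tot)), 1e-6)
})

test_that("sag scaling scales every OPD coefficient linearly", {
  g <- small_grid(129)
  cornea <- test_cornea(11, 129)
  post1 <- posterior_opd(cornea$posterior, 6)
  scaled <- cornea$posterior
  scaled$sag <- 2.5 * scaled$sag
  post2 <- posterior_opd(scaled, 6)
  f1 <- fit_zernike(post1); f2 <- fit_zernike(post2)
  expect_equal(f2$coeffs, 2.5 * f1$coeffs, tolerance = 1e-9)
})

test_that("refitting a pure Z(4,0) wavefront over the 4-mm zone matches the analytic rescale", {
  # oracle: continuous projections of Z40(k rho) (k = 2/3) onto the basis
  k <- 4 / 6
  z40 <- function(rho) sqrt(5) * (6 * rho^4 - 6 * rho^2 + 1)
  z20 <- function(rho) sqrt(3) * (2 * rho^2 - 1)
  proj <- function(f, g) {
    integrate(function(r) f(r) * g(r) * 2 * r, 0, 1, rel.tol = 1e-12)$value
  }
  inner <- function(rho) z40(k * rho)
  expect40 <- proj(inner, z40)
  expect20 <- proj(inner, z20)
  c6 <- rep(0, 45); c6[13] <- 0.8
  opd6 <- synthesize_opd(zernike_coefficients(c6, 6), small_grid(257))
  opd4 <- opd6
  opd4$pupil_diameter <- 4
  xy <- expand.grid(
    x = (seq_len(257) - 129) * opd6$spacing,
    y = (seq_len(257) - 129) * opd6$spacing
  )
  r <- sqrt(xy$x^2 + xy$y^2)
  opd4$valid <- matrix(r <= 2, 257, 257)
  f4 <- fit_zernike(opd4)
  expect_equal(f4$coeffs[13], 0.8 * expect40, tolerance = 1e-4)
  expect_equal(f4$coeffs[5], 0.8 * expect20, tolerance = 1e-4)
})

test_that("aberration profile: symmetric corneas have no coma; rotation leaves metrics unchanged", {
  g <- small_grid(129)
  cornea <- cornea_model(make_conicoid(7.8, -0.2, g),
                         make_conicoid(6.4, -0.4, g), 540)
  ab <- aberration_profile(cornea, zones = c(4, 6))
  expect_equal(nrow(ab), 6)
  expect_true(all(ab$coma < 1e-8))
  expect_true(all(ab$hoa >= 0 & ab$sa >= 0))

  pert <- test_cornea(13, 129)
  ab1 <- aberration_profile(pert, zones = 6)
  rotated <- cornea_model(
    elevation_map(rot90(pert$anterior$sag), pert$anterior$spacing),
    elevation_map(rot90(pert$posterior$sag), pert$posterior$spacing),
    pert$central_thickness
  )
  ab2 <- aberration_profile(rotated, zones = 6)
  expect_equal(ab2$hoa, ab1$hoa, tolerance = 1e-8)
  expect_equal(ab2$sa, ab1$sa, tolerance = 1e-8)
  expect_equal(ab2$coma, ab1$coma, tolerance = 1e-8)
})
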