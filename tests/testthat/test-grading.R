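# Posterior refractive power maps and the 0-5 color grade.

test_that("band classification follows the device color scale", {
  cfg <- band_config()
  expect_equal(as.character(classify_band(-6.0, cfg)), "cool")
  expect_equal(as.character(classify_band(-6.6, cfg)), "orange")
  expect_equal(as.character(classify_band(-7.5, cfg)), "red")
  # yellow band is [-6.45, -6.15] at the default width
  expect_equal(as.character(classify_band(c(-6.3, -6.45, -6.15), cfg)),
               rep("yellow", 3))
  expect_equal(as.character(classify_band(c(-6.149, -6.451), cfg)),
               c("cool", "orange"))
  expect_true(is.na(classify_band(NA, cfg)[1]))
  # every finite value maps to exactly one band
  vals <- seq(-9, -4, by = 0.01)
  expect_false(any(is.na(classify_band(vals, cfg))))
})

test_that("band_config rejects inconsistent thresholds", {
  expect_error(band_config(yellow_width = 0), "positive")
  expect_error(band_config(red_threshold = -6.0), "below")
})

test_that("axial radius of a sphere is the sphere radius everywhere", {
  g <- small_grid(129)
  ax <- axial_radius_map(make_conicoid(6.349, 0, g))
  expect_lt(max(abs(ax$radius - 6.349), na.rm = TRUE), 2e-3)
})

test_that("axial radius of a conicoid matches the closed form sqrt(R^2 - Q r^2)", {
  g <- exact_grid()
  R <- 6.5; Q <- -0.3
  ax <- axial_radius_map(make_conicoid(R, Q, g))
  ctr <- (nrow(ax$radius) + 1) / 2
  for (i_px in c(33, 67, 100)) {       # on-grid radii ~ 1, 2, 3 mm
    r_mm <- i_px * ax$spacing
    expect_equal(ax$radius[ctr + i_px, ctr], sqrt(R^2 - Q * r_mm^2),
                 tolerance = 1e-4)
  }
  # rotated surface: rotated axial radius map
  m <- test_cornea(3, 129)$posterior
  a1 <- axial_radius_map(m)
  a2 <- axial_radius_map(elevation_map(rot90(m$sag), m$spacing))
  expect_equal(a2$radius[2:128, 2:128], rot90(a1$radius)[2:128, 2:128],
               tolerance = 1e-9)
})

test_that("PRP of spheres reproduces the color-scale thresholds", {
  g <- small_grid(129)
  p1 <- prp_map(make_conicoid(6.349, 0, g))
  expect_equal(mean(p1$prp, na.rm = TRUE), -6.30, tolerance = 1e-3)
  p2 <- prp_map(make_conicoid(5.797, 0, g))
  expect_equal(mean(p2$prp, na.rm = TRUE), -6.90, tolerance = 1e-3)
  # flatter radius => less negative PRP
  p3 <- prp_map(make_conicoid(7.0, 0, g))
  expect_true(mean(p3$prp, na.rm = TRUE) > mean(p1$prp, na.rm = TRUE))
})

test_that("red fraction is the red area share of the zone", {
  expect_equal(red_fraction(uniform_prp(-7.5)), 1)
  expect_equal(red_fraction(uniform_prp(-6.0)), 0)
  d <- disc_prp(-7.5, -6.6, radius = 1.5, n = 401)
  expect_equal(red_fraction(d), 0.25, tolerance = 0.005)
})

test_that("background band is the modal non-red band unless red dominates", {
  expect_equal(background_band(uniform_prp(-6.6)), "orange")
  expect_equal(background_band(uniform_prp(-7.5)), "red")
  # 60% orange / 40% red: red below the 0.75 background threshold
  d <- disc_prp(-7.5, -6.6, radius = 3 * sqrt(0.4), n = 401)
  expect_equal(background_band(d), "orange")
  # red >= 0.75 makes the background red
  d2 <- disc_prp(-7.5, -6.6, radius = 3 * sqrt(0.8), n = 401)
  expect_equal(background_band(d2), "red")
})

test_that("the grade decision tree reproduces the worked examples", {
  expect_equal(posterior_grade(uniform_prp(-6.0))$grade, 0L)
  expect_equal(posterior_grade(uniform_prp(-6.3))$grade, 1L)
  expect_equal(posterior_grade(uniform_prp(-7.5))$grade, 5L)
  # orange background with red fraction 0.35 -> grade 3
  g3 <- posterior_grade(disc_prp(-7.5, -6.6, radius = 3 * sqrt(0.35), n = 401))
  expect_equal(g3$grade, 3L)
  expect_equal(g3$background_band, "orange")
  expect_equal(g3$red_fraction, 0.35, tolerance = 0.01)
  # orange background, small red area -> grade 2; majority red -> grade 4
  expect_equal(posterior_grade(disc_prp(-7.5, -6.6, 3 * sqrt(0.10), n = 401))$grade, 2L)
  expect_equal(posterior_grade(disc_prp(-7.5, -6.6, 3 * sqrt(0.60), n = 401))$grade, 4L)
})

test_that("band fractions sum to one and grading is rotation invariant", {
  m <- test_cornea(17)$posterior
  pm <- prp_map(m)
  fr <- band_fractions(pm)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  g1 <- posterior_grade(pm)
  pm2 <- prp_map(elevation_map(rot90(m$sag), m$spacing))
  g2 <- posterior_grade(pm2)
  expect_equal(g2$grade, g1$grade)
  expect_equal(g2$red_fraction, g1$red_fraction, tolerance = 5e-3)
})

test_that("a vanishing yellow band removes grade 1 from continuous maps", {
  cfg <- band_config(yellow_width = 1e-9)
  grades <- vapply(c(5, 15, 40, 80), function(amp) {
    post <- dsaek_meniscus(make_conicoid(6.1, -0.5, small_grid(129)), amp, 2.8)
    posterior_grade(prp_map(post), cfg)$grade
  }, 0L)
  expect_true(all(grades %in% c(0L, 2L, 3L, 4L, 5L)))
})

test_that("steepening a map never decreases its grade (spot check)", {
  set.seed(31)
  for (k in 1:50) {
    R <- runif(1, 5.7, 6.6)
    amp <- exp(runif(1, log(3), log(90)))
    post <- dsaek_meniscus(make_conicoid(R, runif(1, -0.8, -0.2), small_grid(129)),
                           amp, runif(1, 2.2, 3.2))
    pm <- prp_map(post)
    g0 <- posterior_grade(pm)$grade
    pm_steep <- pm
    pm_steep$prp <- pm$prp - runif(1, 0, 0.8)
    expect_gte(posterior_grade(pm_steep)$grade, g0)
  }
})

test_that("degenerate maps are rejected", {
  m <- uniform_prp(-6.6, n = 65)
  m$prp[1:55, ] <- NA
  m$valid <- is.finite(m$prp)
  expect_error(posterior_grade(m), "50%")
})

test_that("grade JSON serialization carries the decision fields", {
  g <- posterior_grade(uniform_prp(-7.5))
  js <- jsonlite::fromJSON(grade_to_json(g))
  expect_equal(js$grade, 5)
  expect_equal(js$background_band, "red")
  expect_equal(js$red_fraction, 1)
})
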