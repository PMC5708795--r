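# Index conventions, polynomial values, fitting, and the aberration metrics.

test_that("single-index map is the bijection over orders 0..8", {
  # enumeration oracle: all admissible (n, m) pairs with n <= 8
  pairs <- do.call(rbind, lapply(0:8, function(n) {
    m <- seq(-n, n, by = 2)
    data.frame(n = n, m = m, j = (n * (n + 2) + m) / 2)
  }))
  expect_equal(sort(pairs$j), 0:44)           # bijection onto 0..44
  for (k in seq_len(nrow(pairs))) {
    nm <- zernike_nm(pairs$j[k])
    expect_equal(nm$n, pairs$n[k])
    expect_equal(nm$m, pairs$m[k])
    expect_equal(zernike_j(pairs$n[k], pairs$m[k]), as.integer(pairs$j[k]))
  }
  nm <- zernike_nm(c(0, 12, 44))
  expect_equal(nm$n, c(0L, 4L, 8L))
  expect_equal(nm$m, c(0L, 0L, 8L))
  expect_equal(zernike_j(c(2, 3, 0), c(-2, -1, 0)), c(3L, 7L, 0L))
})

test_that("invalid (n, m) pairs are rejected", {
  expect_error(zernike_j(2, 1), "even")
  expect_error(zernike_j(2, 3), "exceed")
  expect_error(zernike_nm(-1), "non-negative")
})

test_that("normalized polynomial values match closed forms", {
  expect_equal(zernike_value(0, 0, 0.37, 1.2), 1)
  expect_equal(zernike_value(1, 1, 1, 0), 2)
  # defocus sqrt(3)(2 rho^2 - 1), astigmatism sqrt(6) rho^2 sin(2 theta)
  expect_equal(zernike_value(2, 0, 0.5, 0.3), sqrt(3) * (2 * 0.25 - 1))
  expect_equal(zernike_value(2, -2, 0.8, pi / 4), sqrt(6) * 0.64)
  expect_error(zernike_value(2, 0, 1.2, 0), "rho")
})

test_that("each polynomial has unit RMS over the disk (discrete quadrature)", {
  n <- 301
  ax <- (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  x <- rep(ax, times = n); y <- rep(ax, each = n)
  r <- sqrt(x^2 + y^2)
  sel <- r <= 1
  B <- zernike_basis(r[sel], atan2(y[sel], x[sel]), 8)
  msq <- colMeans(B^2)
  expect_true(all(abs(msq - 1) < 6e-3))
})

test_that("noiseless fit round-trips exactly and zero maps give zero", {
  set.seed(42)
  cf <- zernike_coefficients(rnorm(45, 0, 0.2), 6, "total")
  opd <- synthesize_opd(cf, small_grid(129))
  fit <- fit_zernike(opd)
  expect_lt(max(abs(fit$coeffs - cf$coeffs)), 1e-6)
  expect_lt(fit$fit_rms_residual, 1e-9)

  zero <- synthesize_opd(zernike_coefficients(rep(0, 45), 6), small_grid(129))
  expect_equal(max(abs(fit_zernike(zero)$coeffs)), 0)
})

test_that("coefficient recovery under Gaussian noise follows linear theory", {
  set.seed(99)
  cf <- zernike_coefficients(rnorm(45, 0, 0.2), 6, "total")
  opd <- synthesize_opd(cf, small_grid(129))
  sigma <- 0.01
  opd$opd <- opd$opd + matrix(rnorm(length(opd$opd), 0, sigma), nrow(opd$opd))
  fit <- fit_zernike(opd)
  n_samples <- sum(opd$valid)
  err <- fit$coeffs - cf$coeffs
  se <- sigma / sqrt(n_samples)  # near-orthonormal basis: var ~ sigma^2 / N
  expect_lt(max(abs(err)), 4 * se)
  expect_gt(mean(err^2), 0.2 * se^2)
  expect_lt(mean(err^2), 5 * se^2)
})

test_that("fit preconditions are enforced", {
  cf <- zernike_coefficients(rep(0.1, 45), 6)
  opd <- synthesize_opd(cf, small_grid(25))  # far fewer than 10x samples
  expect_error(fit_zernike(opd), "insufficient")
  opd2 <- synthesize_opd(cf, small_grid(129))
  opd2$pupil_diameter <- 20
  expect_error(fit_zernike(opd2), "pupil larger")
})

test_that("HOA / SA / Coma metrics follow their definitions", {
  mk <- function(vals) {
    v <- rep(0, 45)
    for (nm in names(vals)) v[as.integer(nm) + 1] <- vals[[nm]]
    zernike_coefficients(v, 6)
  }
  expect_equal(hoa_rms(mk(list())), 0)
  expect_equal(sa_rms(mk(list())), 0)
  expect_equal(coma_rms(mk(list())), 0)
  # single term: Z(3,-1) = j7
  expect_equal(hoa_rms(mk(list(`7` = 0.2))), 0.2)
  # Pythagorean: Z(3,1)=j8 0.3, Z(5,1)=j18 0.4
  expect_equal(zernike_j(5, 1), 18L)
  expect_equal(hoa_rms(mk(list(`8` = 0.3, `18` = 0.4))), 0.5)
  # SA: j12, j24
  expect_equal(sa_rms(mk(list(`12` = 0.3, `24` = 0.4))), 0.5)
  expect_equal(sa_rms(mk(list(`12` = -0.12))), 0.12)
  # Coma: j7, j8
  expect_equal(coma_rms(mk(list(`7` = 0.06, `8` = 0.08))), 0.1)
  # low orders (n <= 2) never enter HOA
  expect_equal(hoa_rms(mk(list(`0` = 5, `3` = 2, `4` = 1))), 0)
})

test_that("metrics are invariant under rotation of the wavefront", {
  # rotating the map mixes each (m, -m) pair by a rotation matrix;
  # apply the analytic coefficient rotation and check the RMS metrics
  set.seed(5)
  v <- rnorm(45, 0, 0.2)
  rotate_coeffs <- function(v, phi) {
    out <- v
    nm <- zernike_nm(0:44)
    for (n in 0:8) for (m in seq_len(n)) {
      if ((n - m) %% 2 != 0) next
      jc <- zernike_j(n, m) + 1   # cos term
      js <- zernike_j(n, -m) + 1  # sin term
      out[jc] <- cos(m * phi) * v[jc] + sin(m * phi) * v[js]
      out[js] <- -sin(m * phi) * v[jc] + cos(m * phi) * v[js]
    }
    out
  }
  for (phi in c(0.3, pi / 2, 2.1)) {
    vr <- rotate_coeffs(v, phi)
    a <- zernike_coefficients(v, 6)
    b <- zernike_coefficients(vr, 6)
    expect_equal(hoa_rms(b), hoa_rms(a), tolerance = 1e-12)
    expect_equal(sa_rms(b), sa_rms(a), tolerance = 1e-12)
    expect_equal(coma_rms(b), coma_rms(a), tolerance = 1e-12)
  }
  # rotated map itself: 90-degree grid rotation is exact
  set.seed(6)
  cf <- zernike_coefficients(rnorm(45, 0, 0.1), 6)
  opd <- synthesize_opd(cf, small_grid(129))
  rot <- opd
  rot$opd <- rot90(opd$opd)
  rot$valid <- rot90(opd$valid)
  f1 <- fit_zernike(opd); f2 <- fit_zernike(rot)
  expect_equal(hoa_rms(f2), hoa_rms(f1), tolerance = 1e-9)
  expect_equal(sa_rms(f2), sa_rms(f1), tolerance = 1e-9)
  expect_equal(coma_rms(f2), coma_rms(f1), tolerance = 1e-9)
})
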