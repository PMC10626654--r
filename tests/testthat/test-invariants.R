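test_that("cross-spectrum reproduces surface-averaged products", {
  conv <- sh_convention(6)
  # constant function 1: S_0 = 1, higher orders 0
  cone <- numeric(conv$M); cone[1] <- sqrt(4 * pi)
  S <- sh_cross_spectrum(cone, cone, conv)
  expect_equal(unname(S), c(1, 0, 0, 0))
  set.seed(20)
  g <- rnorm(conv$M); h <- rnorm(conv$M)
  q <- dense_sphere()
  Y <- sh_evaluate(q$points, conv)
  avg <- sum(q$weights * (Y %*% g) * (Y %*% h)) / (4 * pi)
  expect_equal(sum(sh_cross_spectrum(g, h, conv)), avg, tolerance = 1e-8)
  # rotational invariance
  R <- random_rotation(21)
  Sg <- sh_cross_spectrum(g, h, conv)
  Sr <- sh_cross_spectrum(sh_rotate(g, R, conv), sh_rotate(h, R, conv),
                          conv)
  expect_lt(max(abs(Sg - Sr)), 1e-10)
})

test_that("moments equal dense-quadrature moments", {
  conv <- sh_convention(6)
  cone <- numeric(conv$M); cone[1] <- sqrt(4 * pi)
  m <- sh_moments(cone, convention = conv)
  expect_equal(m$mean, 1)
  expect_equal(m$var, 0)
  set.seed(22)
  g <- rnorm(conv$M)
  m <- sh_moments(g, g, convention = conv)
  expect_equal(m$cov, m$var, tolerance = 1e-14)
  q <- dense_sphere()
  vals <- sh_evaluate(q$points, conv) %*% g
  mu <- sum(q$weights * vals) / (4 * pi)
  vq <- sum(q$weights * (vals - mu)^2) / (4 * pi)
  expect_equal(m$mean, mu, tolerance = 1e-8)
  expect_equal(m$var, vq, tolerance = 1e-8)
})

test_that("relative anisotropy is scale-invariant and guards the mean", {
  conv <- sh_convention(4)
  set.seed(23)
  g <- rnorm(conv$M); g[1] <- abs(g[1]) + 2
  expect_equal(sh_relative_anisotropy(3 * g, conv),
               sh_relative_anisotropy(g, conv), tolerance = 1e-12)
  gneg <- g; gneg[1] <- -1
  expect_true(is.nan(sh_relative_anisotropy(gneg, conv)))
  # sampling oracle: sigma / mean of dense samples
  q <- dense_sphere()
  vals <- sh_evaluate(q$points, conv) %*% g
  mu <- sum(q$weights * vals) / (4 * pi)
  sg <- sqrt(sum(q$weights * (vals - mu)^2) / (4 * pi))
  expect_equal(sh_relative_anisotropy(g, conv), sg / mu,
               tolerance = 1e-6)
})

test_that("R-squared is affine- and rotation-invariant", {
  conv <- sh_convention(4)
  set.seed(24)
  g <- rnorm(conv$M); h <- rnorm(conv$M)
  expect_equal(sh_r_squared(g, g, conv), 1)
  aff <- h * 0
  aff[1] <- 2 * sqrt(4 * pi)
  expect_equal(sh_r_squared(g, aff + 5 * g, conv), 1, tolerance = 1e-12)
  R <- random_rotation(25)
  expect_equal(sh_r_squared(sh_rotate(g, R, conv),
                            sh_rotate(h, R, conv), conv),
               sh_r_squared(g, h, conv), tolerance = 1e-8)
  expect_true(is.nan(sh_r_squared(g, aff, conv))) # isotropic reference
  # matches squared Pearson correlation of dense samples
  q <- dense_sphere()
  Y <- sh_evaluate(q$points, conv)
  vg <- as.numeric(Y %*% g); vh <- as.numeric(Y %*% h)
  wmu <- function(x) sum(q$weights * x) / (4 * pi)
  wg <- vg - wmu(vg); wh <- vh - wmu(vh)
  pearson2 <- sum(q$weights * wg * wh)^2 /
    (sum(q$weights * wg^2) * sum(q$weights * wh^2))
  expect_equal(sh_r_squared(g, h, conv), pearson2, tolerance = 1e-6)
})

test_that("ensemble Q follows the direct-formula oracle", {
  conv <- sh_convention(2)
  set.seed(26)
  g <- rnorm(conv$M)
  expect_equal(ensemble_q(replicate(10, g, simplify = FALSE), conv), 1)
  expect_equal(ensemble_q(list(g), conv), 1)
  # two members with equal-power l = 2 parts rotated 90 degrees apart
  z <- sh_zonal_delta(c(0, 0, 1), c(0, 1), conv)
  Rx90 <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3)
  z2 <- sh_rotate(z, Rx90, conv)
  qv <- ensemble_q(list(z, z2), conv)
  # independent brute-force arithmetic on raw coefficients
  an <- conv$ell >= 2
  var_mean <- sum(((z[an] + z2[an]) / 2)^2) / (4 * pi)
  mean_var <- (sum(z[an]^2) + sum(z2[an]^2)) / 2 / (4 * pi)
  expect_equal(qv, var_mean / mean_var, tolerance = 1e-12)
  expect_true(qv >= 0 && qv < 1)
  # all-isotropic voxel flagged undefined
  iso <- numeric(conv$M); iso[1] <- 1
  expect_true(is.nan(ensemble_q(list(iso, iso), conv)))
})

test_that("main orientation extracts the zonal axis equivariantly", {
  conv <- sh_convention(2)
  z <- sh_zonal_delta(c(0, 0, 1), c(1, 1), conv)
  o <- main_orientation(z, conv)
  expect_equal(abs(o$orientation[3]), 1, tolerance = 1e-10)
  set.seed(27)
  for (i in 1:5) {
    R <- random_rotation(30 + i)
    zo <- main_orientation(sh_rotate(z, R, conv), conv)$orientation
    tgt <- as.numeric(R %*% c(0, 0, 1))
    expect_lt(min(sum((zo - tgt)^2), sum((zo + tgt)^2)), 1e-8)
  }
  # pure l = 2 function with a known tensor: eigen-decomposition oracle
  g <- numeric(conv$M)
  g[conv$ell == 2] <- rnorm(5)
  q <- dense_sphere()
  vals <- as.numeric(sh_evaluate(q$points, conv) %*% g)
  Tm <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3)
    Tm[a, b] <- sum(q$weights * vals * q$points[, a] * q$points[, b])
  Tm <- Tm - diag(3) * sum(diag(Tm)) / 3
  eg <- eigen(Tm, symmetric = TRUE)
  o2 <- main_orientation(g, conv)
  expect_equal(sort(o2$eigenvalues), sort(eg$values), tolerance = 1e-8)
  lam <- eg$values
  pick <- if (abs(lam[1] - lam[2]) >= abs(lam[3] - lam[2])) 1 else 3
  v <- eg$vectors[, pick]
  expect_lt(min(sum((o2$orientation - v)^2),
                sum((o2$orientation + v)^2)), 1e-10)
})

test_that("squared expansion is exact for band-limited squares", {
  conv2 <- sh_convention(2)
  # square of the constant function stays constant with zero variance
  cone <- numeric(1) + sqrt(4 * pi)
  ex <- expand_squared(c(sqrt(4 * pi)), sh_convention(0), 0)
  expect_equal(sh_moments(ex, convention = sh_convention(0))$var, 0)
  # square of a single Y_2^0 term vs brute-force quadrature projection
  co20 <- numeric(conv2$M)
  co20[conv2$ell == 2 & conv2$m == 0] <- 1
  ex20 <- expand_squared(co20, conv2, 4)
  q <- dense_sphere()
  oracle <- as.numeric(crossprod(
    sh_evaluate(q$points, sh_convention(4)),
    q$weights * (sh_evaluate(q$points, conv2) %*% co20)^2))
  expect_lt(max(abs(ex20 - oracle)), 1e-10)
  expect_error(expand_squared(co20, conv2, 2), ">=")
})

test_that("box summary uses the 1.25 IQR whisker rule", {
  set.seed(28)
  x <- c(rnorm(200), 50, -40, NaN)
  b <- tukey_box_stats(x)
  xf <- x[is.finite(x)]
  qs <- quantile(xf, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(c(b$q1, b$median, b$q3), qs)
  iqr <- qs[3] - qs[1]
  inside <- xf[xf >= qs[1] - 1.25 * iqr & xf <= qs[3] + 1.25 * iqr]
  expect_equal(b$whisker_low, min(inside))
  expect_equal(b$whisker_high, max(inside))
  expect_equal(b$n_outliers, sum(xf < qs[1] - 1.25 * iqr |
                                   xf > qs[3] + 1.25 * iqr))
})

test_that("invariant maps are rotation-invariant as fields", {
  conv <- sh_convention(4)
  set.seed(29)
  d <- c(3, 3, 2)
  A <- matrix(rnorm(prod(d) * conv$M), prod(d))
  A[, 1] <- abs(A[, 1]) + 3
  vol <- tt_volume(array(A, c(d, conv$M)), conv)
  ref <- tt_volume(array(A + 0.3 * matrix(rnorm(length(A)), nrow(A)),
                         c(d, conv$M)), conv)
  R <- random_rotation(33)
  rot_vol <- tt_volume(array(sh_rotate(A, R, conv), c(d, conv$M)), conv)
  Bref <- matrix(as.numeric(ref), prod(d), conv$M)
  rot_ref <- tt_volume(array(sh_rotate(Bref, R, conv), c(d, conv$M)), conv)
  m1 <- invariant_maps(vol, reference = ref)
  m2 <- invariant_maps(rot_vol, reference = rot_ref)
  for (nm in c("mean", "power", "rel_aniso", "r2"))
    expect_lt(max(abs(m1[[nm]] - m2[[nm]]), na.rm = TRUE), 1e-8)
})
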