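test_that("farthest-point placement finds rod ends and reproduces", {
  rod <- array(TRUE, c(1, 1, 20))
  two <- farthest_point_sources(rod, 2, seed = 3)
  # exhaustive oracle: of all voxel pairs on the rod, the two end voxels
  # uniquely maximize the mutual interior distance
  expect_equal(sort(two[, 3]), c(1L, 20L))
  expect_identical(farthest_point_sources(rod, 2, seed = 3),
                   farthest_point_sources(rod, 2, seed = 3))
  # single source: approximate interior centre of the rod
  one <- farthest_point_sources(rod, 1, seed = 1)
  expect_true(one[, 3] %in% 10:11)
  expect_error(farthest_point_sources(array(FALSE, c(2, 2, 2)), 1),
               "empty")
})

test_that("interior distance equals explicit-graph shortest paths", {
  rod <- array(TRUE, c(1, 1, 6))
  d <- interior_distance(rod, matrix(c(1, 1, 1), 1))
  expect_equal(as.numeric(d), 0:5)
  # U-shaped 2-D mask: distances must go around the bend
  U <- array(FALSE, c(5, 3, 1))
  U[, 1, 1] <- TRUE; U[5, 2, 1] <- TRUE; U[, 3, 1] <- TRUE
  du <- array(interior_distance(U, matrix(c(1, 1, 1), 1)), dim(U))
  # brute-force Dijkstra on the explicit small graph
  cells <- which(U, arr.ind = TRUE)
  n <- nrow(cells)
  W <- matrix(Inf, n, n)
  for (i in 1:n) for (j in 1:n) {
    dd <- abs(cells[i, ] - cells[j, ])
    if (i != j && all(dd <= 1)) W[i, j] <- sqrt(sum(dd^2))
  }
  dist <- rep(Inf, n); dist[1] <- 0; done <- rep(FALSE, n)
  for (it in 1:n) {
    u <- which.min(ifelse(done, Inf, dist)); done[u] <- TRUE
    dist <- pmin(dist, dist[u] + W[u, ])
  }
  expect_equal(du[cells], dist, tolerance = 1e-12)
  # target cell across the U opening: path length around the bend
  expect_gt(du[1, 3, 1], 4) # straight-line distance would be 2 voxels
  # convex cube: within sqrt(3) of Euclidean distance
  cube <- array(TRUE, c(5, 5, 5))
  dc <- interior_distance(cube, matrix(c(1, 1, 1), 1))
  idxc <- which(cube, arr.ind = TRUE)
  eu <- sqrt(rowSums(sweep(idxc, 2, c(1, 1, 1), "-")^2))
  expect_true(all(dc[cube] >= eu - 1e-9))
  expect_true(all(dc[cube] <= sqrt(3) * eu + 1e-9))
})

test_that("symmetry classes impose the advertised spectra", {
  # rank2: only orders 0 and 2 populated
  gt <- synthesize_field(small_spec(c(10, 10, 10), "rank2", seed = 4))
  conv <- attr(gt, "convention")
  expect_equal(conv$ell_max, 2L)
  # high_order: S_2 approximately equal to S_4 per voxel
  gh <- synthesize_field(small_spec(c(12, 12, 12), "high_order", seed = 5))
  cv <- attr(gh, "convention")
  A <- matrix(as.numeric(gh), prod(dim(gh)[1:3]), cv$M)
  msk <- attr(gh, "spec")$support_mask
  S2 <- rowSums(A[msk, cv$ell == 2]^2)
  S4 <- rowSums(A[msk, cv$ell == 4]^2)
  ok <- S4 > 0
  ratio <- median(S2[ok] / S4[ok])
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
  # zonal: per-voxel function near the source is zonal about some axis
  gz <- synthesize_field(phantom_spec(volume_shape = c(10, 10, 10),
                                      symmetry_class = "zonal",
                                      n_sources = 1, seed = 6))
  expect_equal(attr(gz, "convention")$ell_max, 12L)
})

test_that("per-order power matches the distance-weighted source average", {
  spec <- phantom_spec(volume_shape = c(12, 12, 12),
                       symmetry_class = "zonal", n_sources = 3, seed = 7)
  gt <- synthesize_field(spec)
  cv <- attr(gt, "convention")
  A <- matrix(as.numeric(gt), prod(dim(gt)[1:3]), cv$M)
  msk <- as.vector(spec$support_mask)
  srcs <- attr(gt, "sources")
  D <- interior_distance(spec$support_mask, srcs)
  nv <- prod(dim(spec$support_mask))
  W <- vapply(seq_len(nrow(srcs)), function(s) {
    dv <- as.numeric(D[seq_len(nv) + (s - 1) * nv])
    exp(-dv^2 / (2 * spec$correlation_length^2))
  }, numeric(nv))
  W[is.na(W)] <- 0
  Wn <- W / pmax(rowSums(W), .Machine$double.eps)
  # source powers: equal by construction across sources, so the l = 2
  # target power is uniform; realized power must match within 10% median
  src_flat <- srcs[, 1] + 12 * (srcs[, 2] - 1) + 144 * (srcs[, 3] - 1)
  P2_src <- rowSums(A[src_flat, cv$ell == 2, drop = FALSE]^2) / (4 * pi)
  target <- as.numeric(Wn %*% P2_src)
  realized <- rowSums(A[, cv$ell == 2]^2) / (4 * pi)
  relerr <- abs(realized[msk] - target[msk]) / target[msk]
  expect_lt(median(relerr), 0.1)
})

test_that("voxel-source correlation decays as the Gaussian kernel", {
  spec <- phantom_spec(volume_shape = c(16, 16, 16),
                       symmetry_class = "rank2", n_sources = 1, seed = 5)
  gt <- synthesize_field(spec)
  cv <- attr(gt, "convention")
  src <- attr(gt, "sources")
  d1 <- interior_distance(spec$support_mask, src)
  A <- matrix(as.numeric(gt), prod(dim(gt)[1:3]), cv$M)
  blk <- which(cv$ell == 2)
  gsrc <- A[src[1] + 16 * (src[2] - 1) + 256 * (src[3] - 1), blk]
  gsrc <- gsrc / sqrt(sum(gsrc^2))
  msk <- as.vector(spec$support_mask)
  corr <- as.numeric((A[msk, blk] /
                        pmax(sqrt(rowSums(A[msk, blk]^2)), 1e-300)) %*%
                       gsrc)
  dd <- as.numeric(d1)[msk]
  fit <- nls(y ~ exp(-x^2 / (2 * s^2)),
             data = data.frame(x = dd, y = corr),
             start = list(s = spec$correlation_length))
  sig <- coef(fit)[["s"]]
  expect_gt(sig, 0.8 * spec$correlation_length)
  expect_lt(sig, 1.2 * spec$correlation_length)
})

test_that("non-negativity enforcement lifts only the isotropic part", {
  conv <- sh_convention(2)
  v <- array(0, c(1, 1, 1, conv$M))
  v[1, 1, 1, conv$ell == 2 & conv$m == 0] <- 1
  vol <- tt_volume(v, conv)
  fixed <- enforce_nonnegativity(vol, n_grid = 20)
  # only c0 changed
  expect_equal(unclass(fixed)[1, 1, 1, -1], unclass(vol)[1, 1, 1, -1])
  # sampled minimum before the lift, scaled to the c0 increment
  q <- sphere_quadrature(20, 40)
  pre_min <- min(sh_evaluate(q$points, conv) %*% v[1, 1, 1, ])
  lift <- unclass(fixed)[1, 1, 1, 1] - unclass(vol)[1, 1, 1, 1]
  expect_equal(lift, -pre_min * sqrt(4 * pi), tolerance = 1e-6)
  post_min <- min(sh_evaluate(q$points, conv) %*% unclass(fixed)[1, 1, 1, ])
  expect_gt(post_min, -1e-9)
  # idempotent; non-negative input unchanged
  again <- enforce_nonnegativity(fixed, n_grid = 20)
  expect_equal(unclass(again), unclass(fixed), tolerance = 1e-9)
  iso <- tt_volume(array(c(1, rep(0, conv$M - 1)), c(1, 1, 1, conv$M)),
                   conv)
  expect_equal(unclass(enforce_nonnegativity(iso)), unclass(iso))
})

test_that("measurement simulation respects SNR and Friedel symmetry", {
  ph <- suppressWarnings(tt_phantom(small_spec(c(10, 10, 10), seed = 6)))
  # snr = Inf returns the exact forward model
  exact <- simulate_measurements(ph$ground_truth, ph$geometry, ph$binning,
                                 snr = Inf)
  for (p in seq_along(exact$data))
    expect_identical(exact$data[[p]], ph$measurement$data[[p]])
  # Friedel: arc integrals at phi and phi + pi coincide
  conv <- attr(ph$ground_truth, "convention")
  b <- ph$binning
  Y1 <- sh_circle_bins(0.6, 0.2, b$centers, b$width, conv)
  Y2 <- sh_circle_bins(0.6, 0.2, b$centers + pi, b$width, conv)
  expect_lt(max(abs(Y1 - Y2)), 1e-12)
  # empirical SNR across realizations within 10% of requested
  cl <- unlist(lapply(exact$data, as.numeric))
  mu <- mean(cl[cl > 0])
  snrs <- vapply(1:40, function(i) {
    ny <- simulate_measurements(ph$ground_truth, ph$geometry, ph$binning,
                                snr = 10, seed = 500 + i)
    nv <- unlist(lapply(ny$data, as.numeric))
    mu / sd((nv - cl)[cl > 0])
  }, numeric(1))
  expect_gt(mean(snrs), 9)
  expect_lt(mean(snrs), 11)
  # reproducible for fixed seed; Poisson option produces valid data
  a <- simulate_measurements(ph$ground_truth, ph$geometry, ph$binning,
                             snr = 5, seed = 9)
  b2 <- simulate_measurements(ph$ground_truth, ph$geometry, ph$binning,
                              snr = 5, seed = 9)
  expect_identical(a$data, b2$data)
  po <- simulate_measurements(ph$ground_truth, ph$geometry, ph$binning,
                              snr = 5, seed = 9, noise = "poisson")
  expect_true(all(unlist(po$data) >= 0))
})
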