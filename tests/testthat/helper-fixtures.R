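# shared fixtures: random rotations, unit directions, tiny geometries

random_rotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd)
  R <- R %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_directions <- function(n, seed) {
  set.seed(seed)
  d <- matrix(rnorm(3 * n), n)
  d / sqrt(rowSums(d^2))
}

# small ball phantom spec used by several tests
small_spec <- function(shape = c(10, 10, 10), class = "rank2", seed = 1) {
  phantom_spec(volume_shape = shape, symmetry_class = class, seed = seed)
}

# dense product quadrature used as the independent sphere-integration oracle
dense_sphere <- function() sphere_quadrature(40L, 80L)
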