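#' Even-order real spherical-harmonic convention
#'
#' Fixes the basis used throughout the package: real, orthonormal spherical
#' harmonics restricted to even orders (Friedel symmetry of kinematic
#' scattering makes reciprocal-space maps antipodally symmetric, so odd
#' orders vanish).  Coefficients are ordered l-major, with degree m running
#' from -l to +l within each order.  The basis excludes the Condon-Shortley
#' phase; the Gram matrix under the uniform sphere measure is the identity.
#'
#' @param ell_max even, non-negative integer band limit.
#' @return An object of class `sh_convention`: list with `ell_max`, the
#'   number of coefficients `M = (ell_max + 1)(ell_max + 2)/2`, and the
#'   per-coefficient order/degree vectors `ell`, `m`.
#' @examples
#' conv <- sh_convention(6)
#' conv$M  # 28
#' @export
sh_convention <- function(ell_max) {
  if (length(ell_max) != 1L || ell_max < 0 || ell_max %% 2 != 0)
    stop("ell_max must be a single even non-negative integer, got ", ell_max)
  ells <- seq(0L, as.integer(ell_max), by = 2L)
  ell <- rep(ells, times = 2L * ells + 1L)
  m <- unlist(lapply(ells, function(l) seq(-l, l)), use.names = FALSE)
  structure(
    list(ell_max = as.integer(ell_max), M = length(ell),
         ell = ell, m = as.integer(m)),
    class = "sh_convention"
  )
}

#' @export
print.sh_convention <- function(x, ...) {
  cat("Real even-order spherical-harmonic basis (orthonormal, no",
      "Condon-Shortley phase)\n")
  cat("  ell_max =", x$ell_max, " M =", x$M, "coefficients, l-major,",
      "m = -l..l\n")
  invisible(x)
}

# normalized associated Legendre values (n x (l+1), columns m = 0..l),
# with the Condon-Shortley phase of pracma::legendre cancelled
.nalf <- function(l, x) {
  if (l == 0L) return(matrix(1 / sqrt(4 * pi), length(x), 1L))
  P <- t(pracma::legendre(l, x)) # n x (l+1), MATLAB convention (CS phase)
  ms <- 0:l
  nrm <- sqrt((2 * l + 1) / (4 * pi) *
                exp(lgamma(l - ms + 1) - lgamma(l + ms + 1)))
  sweep(P, 2L, nrm * (-1)^ms, "*")
}

.check_directions <- function(directions, tol = 1e-9) {
  if (is.null(dim(directions))) directions <- matrix(directions, nrow = 1L)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be n x 3")
  nrm <- sqrt(rowSums(directions^2))
  bad <- abs(nrm - 1) > tol
  if (any(bad))
    stop("non-unit direction(s): max |norm - 1| = ",
         format(max(abs(nrm - 1))), " at row ", which(bad)[1L])
  directions
}

#' Evaluate the basis on a set of directions
#'
#' @param directions numeric n x 3 matrix (or length-3 vector) of unit
#'   vectors; norms must be 1 within 1e-9.
#' @param convention an [sh_convention()].
#' @return n x M matrix of real basis values, columns in convention order.
#' @examples
#' Y <- sh_evaluate(c(0, 0, 1), sh_convention(0))
#' all.equal(Y[1, 1], 1 / sqrt(4 * pi))
#' @export
sh_evaluate <- function(directions, convention) {
  stopifnot(inherits(convention, "sh_convention"))
  directions <- .check_directions(directions)
  n <- nrow(directions)
  z <- pmin(1, pmax(-1, directions[, 3L]))
  phi <- atan2(directions[, 2L], directions[, 1L])
  out <- matrix(0, n, convention$M)
  col0 <- 1L
  for (l in seq(0L, convention$ell_max, by = 2L)) {
    P <- .nalf(l, z)
    if (l == 0L) {
      out[, col0] <- P[, 1L]
    } else {
      blk <- matrix(0, n, 2L * l + 1L)
      blk[, l + 1L] <- P[, 1L]
      for (mm in 1:l) {
        blk[, l + 1L + mm] <- sqrt(2) * P[, mm + 1L] * cos(mm * phi)
        blk[, l + 1L - mm] <- sqrt(2) * P[, mm + 1L] * sin(mm * phi)
      }
      out[, col0:(col0 + 2L * l)] <- blk
    }
    col0 <- col0 + 2L * l + 1L
  }
  out
}

#' Product quadrature grid on the unit sphere
#'
#' Gauss-Legendre nodes in cos(theta) crossed with equispaced azimuths;
#' integrates spherical polynomials of degree up to
#' `min(2 * n_theta - 1, n_phi - 1)` exactly.
#'
#' @param n_theta number of Gauss-Legendre polar nodes.
#' @param n_phi number of equispaced azimuthal nodes.
#' @return list with `points` (n x 3 unit vectors) and `weights` (summing to
#'   4 pi).
#' @export
sphere_quadrature <- function(n_theta, n_phi = 2L * n_theta) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  z <- rep(gl$x, times = n_phi)
  ph <- rep(phi, each = n_theta)
  s <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(s * cos(ph), s * sin(ph), z)
  w <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  list(points = pts, weights = w)
}

#' Driscoll-Healy style equiangular sphere quadrature
#'
#' Equiangular polar grid (midpoint rule in theta) with weights solved to
#' integrate Legendre polynomials up to degree `n_theta - 1` exactly,
#' crossed with equispaced azimuths.  Used for the squared-representation
#' expansion, where sampling on an equiangular grid mirrors the classical
#' band-limited quadrature construction.
#'
#' @inheritParams sphere_quadrature
#' @return list with `points` and `weights` as in [sphere_quadrature()].
#' @export
dh_quadrature <- function(n_theta, n_phi = 2L * n_theta) {
  theta <- pi * (seq_len(n_theta) - 0.5) / n_theta
  x <- cos(theta)
  # exactness conditions: sum_j w_j P_l(x_j) = 2 delta_{l0}, l < n_theta
  A <- matrix(0, n_theta, n_theta)
  Pm1 <- rep(1, n_theta)
  P0 <- x
  A[1L, ] <- Pm1
  if (n_theta > 1L) A[2L, ] <- P0
  if (n_theta > 2L) {
    for (l in 2:(n_theta - 1L)) {
      P1 <- ((2 * l - 1) * x * P0 - (l - 1) * Pm1) / l
      A[l + 1L, ] <- P1
      Pm1 <- P0
      P0 <- P1
    }
  }
  b <- c(2, rep(0, n_theta - 1L))
  wt <- solve(A, b)
  phi <- 2 * pi * (seq_len(n_phi) - 0.5) / n_phi
  z <- rep(x, times = n_phi)
  ph <- rep(phi, each = n_theta)
  s <- sin(rep(theta, times = n_phi))
  pts <- cbind(s * cos(ph), s * sin(ph), z)
  w <- rep(wt, times = n_phi) * (2 * pi / n_phi)
  list(points = pts, weights = w)
}

#' Great-circle arc integrals of the basis (the Y matrix of one projection)
#'
#' For a beam direction fixed by `(alpha, beta)`, the measurement probes the
#' great circle of unit vectors orthogonal to the beam.  Each detector
#' azimuthal bin integrates the basis over an arc of that circle; entry
#' (coefficient, bin) is the integral of the basis function over
#' `[phi_i - width/2, phi_i + width/2]` along `C(tau) = cos(tau) e_j +
#' sin(tau) e_k`.  Arcs are integrated with fixed-order (16-point)
#' Gauss-Legendre quadrature per bin.
#'
#' @param alpha,beta projection angles in radians (see [beam_basis()]).
#' @param bin_centers bin centres `phi_i` in `[0, pi)`; together with
#'   `bin_width` they must tile `[0, pi)` without overlap.
#' @param bin_width common bin width in radians.
#' @param convention an [sh_convention()].
#' @return M x N matrix of arc integrals.
#' @export
sh_circle_bins <- function(alpha, beta, bin_centers, bin_width, convention) {
  stopifnot(inherits(convention, "sh_convention"))
  n <- length(bin_centers)
  ctr <- sort(bin_centers)
  if (abs(n * bin_width - pi) > 1e-9 ||
      (n > 1L && any(abs(diff(ctr) - bin_width) > 1e-9)))
    stop("bins must tile [0, pi) without overlap: need equal widths ",
         "summing to pi")
  fr <- beam_basis(alpha, beta)
  gl <- pracma::gaussLegendre(16L, -0.5, 0.5)
  out <- matrix(0, convention$M, n)
  for (i in seq_len(n)) {
    tau <- bin_centers[i] + bin_width * gl$x
    pts <- outer(cos(tau), fr$e_j) + outer(sin(tau), fr$e_k)
    Y <- sh_evaluate(pts, convention)
    out[, i] <- as.vector(crossprod(Y, gl$w * bin_width))
  }
  out
}

#' Bin design matrix for even trigonometric polynomials
#'
#' The restriction of an even-order spherical-harmonic expansion to a great
#' circle is an even trigonometric polynomial; with band limit `ell_max` it
#' has `ell_max + 1` free components (constant plus cosine/sine pairs at
#' even frequencies).  This returns the linear map from those components to
#' `n_bins` azimuthal bin integrals on `[0, pi)`.  Its column rank is full
#' exactly when `ell_max <= n_bins - 1`, the Nyquist-type rule that limits
#' the band limit recoverable from binned data.
#'
#' @param n_bins number of azimuthal bins tiling `[0, pi)`.
#' @param ell_max even band limit.
#' @return n_bins x (ell_max + 1) matrix.
#' @examples
#' qr(circle_trig_bin_matrix(8, 6))$rank  # 7: full column rank
#' qr(circle_trig_bin_matrix(8, 8))$rank  # 8 < 9: rank deficient
#' @export
circle_trig_bin_matrix <- function(n_bins, ell_max) {
  stopifnot(ell_max %% 2 == 0)
  width <- pi / n_bins
  centers <- (seq_len(n_bins) - 0.5) * width
  lo <- centers - width / 2
  hi <- centers + width / 2
  cols <- list(hi - lo)
  if (ell_max >= 2L) {
    for (f in seq(2L, ell_max, by = 2L)) {
      cols[[length(cols) + 1L]] <- (sin(f * hi) - sin(f * lo)) / f
      cols[[length(cols) + 1L]] <- (cos(f * lo) - cos(f * hi)) / f
    }
  }
  do.call(cbind, cols)
}

#' l-weighted zonal delta expansion
#'
#' Coefficients of the band-limited, order-weighted spherical Dirac delta
#' pointing along `direction`: the (l, m) coefficient is
#' `w(l) * Y_l^m(direction)`.  The resulting function is zonally symmetric
#' about `direction` and is used to seed zonally symmetric phantom textures.
#'
#' @param direction length-3 unit vector.
#' @param weights one weight per even order `0, 2, ..., ell_max`.
#' @param convention an [sh_convention()].
#' @return length-M coefficient vector.
#' @export
sh_zonal_delta <- function(direction, weights, convention) {
  stopifnot(inherits(convention, "sh_convention"))
  ells <- seq(0L, convention$ell_max, by = 2L)
  if (length(weights) != length(ells))
    stop("need one weight per even order: expected ", length(ells),
         ", got ", length(weights))
  Y <- sh_evaluate(direction, convention)[1L, ]
  wfull <- weights[match(convention$ell, ells)]
  wfull * Y
}

#' Rotate a band-limited expansion
#'
#' Returns the coefficients of `g(R^T n)` given the coefficients of `g(n)`.
#' Implemented by exact quadrature re-projection: the rotated function is
#' sampled at back-rotated quadrature nodes and re-projected onto the basis.
#' For band-limited input the product quadrature is exact, so this agrees
#' with the spherical-harmonic rotation theorem to machine precision.
#'
#' @param coefficients length-M vector, or n x M matrix of expansions
#'   (one per row).
#' @param rotation 3 x 3 proper rotation matrix (orthogonal, det +1,
#'   within 1e-9).
#' @param convention an [sh_convention()].
#' @return rotated coefficients, same shape as the input.
#' @export
sh_rotate <- function(coefficients, rotation, convention) {
  stopifnot(inherits(convention, "sh_convention"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be a proper rotation (orthogonal, det = +1)")
  vec_in <- is.null(dim(coefficients))
  C <- if (vec_in) matrix(coefficients, nrow = 1L) else as.matrix(coefficients)
  if (ncol(C) != convention$M) stop("coefficient length does not match basis")
  L <- convention$ell_max
  q <- sphere_quadrature(L + 1L, 2L * L + 1L)
  Yq <- sh_evaluate(q$points, convention)          # nq x M
  back <- q$points %*% rotation                    # rows: R^T n
  Yb <- sh_evaluate(back, convention)
  out <- (C %*% t(Yb)) %*% (q$weights * Yq)        # n x M
  if (vec_in) out[1L, ] else out
}
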