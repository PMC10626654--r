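.coef_mat <- function(g, convention) {
  if (inherits(g, "tt_volume")) {
    d <- dim(g)
    return(matrix(as.numeric(g), prod(d[1:3]), d[4L]))
  }
  if (is.null(dim(g))) matrix(g, nrow = 1L) else as.matrix(g)
}

.conv_of <- function(g, convention = NULL) {
  if (!is.null(convention)) return(convention)
  cv <- attr(g, "convention")
  if (is.null(cv)) stop("supply a convention (none attached to input)")
  cv
}

#' Cross-spectrum of two spherical functions
#'
#' The per-order rotational invariant
#' `S_l(g, h) = (1 / 4 pi) * sum_m c_l^m(g) c_l^m(h)`.  With the
#' orthonormal basis and this normalization, `sum_l S_l` equals the
#' sphere-surface-averaged product of the two functions, so spherical
#' means, variances and covariances are literal surface-averaged moments.
#'
#' @param g,h length-M coefficient vectors (defaults `h = g`).
#' @param convention an [sh_convention()]; taken from attributes if absent.
#' @return named vector of `S_l`, one per even order.
#' @export
sh_cross_spectrum <- function(g, h = g, convention = NULL) {
  cv <- .conv_of(g, convention)
  if (length(g) != cv$M || length(h) != cv$M)
    stop("coefficient length does not match convention (M = ", cv$M, ")")
  prod_lm <- g * h / (4 * pi)
  ells <- seq(0L, cv$ell_max, by = 2L)
  out <- vapply(ells, function(l) sum(prod_lm[cv$ell == l]), numeric(1))
  names(out) <- paste0("l", ells)
  out
}

#' Spherical mean, anisotropic power and covariance
#'
#' `mean(g) = c_0^0 / sqrt(4 pi)` (the isotropic component);
#' `var(g) = sum_{l >= 2} S_l(g, g)` is the anisotropic power;
#' `cov(g, h) = sum_{l >= 2} S_l(g, h)`.
#'
#' @inheritParams sh_cross_spectrum
#' @return list with `mean`, `var`, and (when `h` given) `cov`.
#' @export
sh_moments <- function(g, h = NULL, convention = NULL) {
  cv <- .conv_of(g, convention)
  S <- sh_cross_spectrum(g, g, cv)
  out <- list(mean = g[1L] / sqrt(4 * pi), var = sum(S[-1L]))
  if (!is.null(h)) out$cov <- sum(sh_cross_spectrum(g, h, cv)[-1L])
  out
}

#' Relative anisotropy
#'
#' Standard deviation of the spherical function over the sphere divided by
#' its spherical mean, `sigma(g) / mean(g)`: a scale-invariant texture
#' measure, unbounded above (unlike root-mean-square normalization, which
#' would saturate at 1 for highly anisotropic maps).  Undefined (NaN) when
#' the mean is not positive.
#'
#' @inheritParams sh_cross_spectrum
#' @return scalar (NaN if the spherical mean is <= 0).
#' @export
sh_relative_anisotropy <- function(g, convention = NULL) {
  m <- sh_moments(g, convention = convention)
  if (!is.finite(m$mean) || m$mean <= 0) return(NaN)
  sqrt(m$var) / m$mean
}

#' Squared Pearson correlation of two spherical functions
#'
#' `R^2(g, h) = cov(g, h)^2 / (var(g) var(h))`: invariant under common
#' rotations and under affine maps `g -> a + b g` (`b != 0`).  Undefined
#' (NaN) when either function has zero anisotropic power; such voxels are
#' excluded from summary statistics.
#'
#' @inheritParams sh_cross_spectrum
#' @return scalar in `[0, 1]`, or NaN for degenerate input.
#' @export
sh_r_squared <- function(g, h, convention = NULL) {
  cv <- .conv_of(g, convention)
  mg <- sh_moments(g, h, cv)
  vh <- sh_moments(h, convention = cv)$var
  if (mg$var <= 0 || vh <= 0) return(NaN)
  min(1, mg$cov^2 / (mg$var * vh))
}

#' Voxel-wise R-squared map between two coefficient volumes
#'
#' @param volume,reference [tt_volume()]s with matching shape and
#'   convention (band limits may differ: the comparison uses the common
#'   orders, since higher orders of the wider field are unobservable in
#'   the narrower one only if requested via `common_orders`).
#' @param common_orders if `TRUE` (default) truncate both fields to the
#'   smaller band limit before comparing; if `FALSE`, missing orders are
#'   treated as zeros.
#' @return 3-D array of per-voxel `R^2` (NaN where either field has zero
#'   anisotropic power).
#' @export
r_squared_map <- function(volume, reference, common_orders = FALSE) {
  cv1 <- attr(volume, "convention")
  cv2 <- attr(reference, "convention")
  d1 <- dim(volume)[1:3]
  if (!all(d1 == dim(reference)[1:3])) stop("volume shapes differ")
  A <- .coef_mat(volume)
  B <- .coef_mat(reference)
  if (cv1$ell_max != cv2$ell_max) {
    L <- min(cv1$ell_max, cv2$ell_max)
    if (common_orders) {
      A <- A[, cv1$ell <= L, drop = FALSE]
      B <- B[, cv2$ell <= L, drop = FALSE]
      ell <- cv1$ell[cv1$ell <= L]
    } else {
      # embed the narrower field in the wider basis with zeros
      if (cv1$ell_max < cv2$ell_max) {
        A2 <- matrix(0, nrow(A), cv2$M)
        A2[, cv2$ell <= cv1$ell_max] <- A
        A <- A2
        ell <- cv2$ell
      } else {
        B2 <- matrix(0, nrow(B), cv1$M)
        B2[, cv1$ell <= cv2$ell_max] <- B
        B <- B2
        ell <- cv1$ell
      }
    }
  } else ell <- cv1$ell
  an <- ell >= 2L
  Aa <- A[, an, drop = FALSE]
  Ba <- B[, an, drop = FALSE]
  va <- rowSums(Aa^2)
  vb <- rowSums(Ba^2)
  cab <- rowSums(Aa * Ba)
  r2 <- ifelse(va > 0 & vb > 0, pmin(1, cab^2 / (va * vb)), NaN)
  array(r2, d1)
}

#' Ensemble anisotropic power quotient Q
#'
#' For each voxel, the anisotropic power of the ensemble-average
#' reciprocal-space map divided by the ensemble-average anisotropic power:
#' `Q = var(mean_i g_i) / mean_i var(g_i)`.  `Q = 1` exactly when all
#' members share the same anisotropic part, and `Q` lies in `[0, 1)` when
#' they differ (Cauchy-Schwarz/Jensen).  Voxels whose members are all
#' isotropic get NaN.
#'
#' @param volumes list of [tt_volume()]s (or a list of coefficient
#'   vectors) with matching shapes and conventions.
#' @param convention required when plain vectors are supplied.
#' @return 3-D array (or scalar for vector input) of Q values.
#' @export
ensemble_q <- function(volumes, convention = NULL) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  cv <- .conv_of(volumes[[1L]], convention)
  mats <- lapply(volumes, .coef_mat, convention = cv)
  n <- length(mats)
  an <- cv$ell >= 2L
  mean_mat <- Reduce(`+`, mats) / n
  var_of_mean <- rowSums(mean_mat[, an, drop = FALSE]^2)
  mean_of_var <- Reduce(`+`, lapply(mats, function(m)
    rowSums(m[, an, drop = FALSE]^2))) / n
  q <- ifelse(mean_of_var > 0, pmin(1, var_of_mean / mean_of_var), NaN)
  if (inherits(volumes[[1L]], "tt_volume"))
    array(q, dim(volumes[[1L]])[1:3])
  else if (length(q) == 1L) as.numeric(q) else q
}

#' Principal orientation of the rank-2 component
#'
#' Maps the six `l = 2` coefficients to the symmetric traceless rank-2
#' tensor `T = integral of g_2(n) (n n^T - I/3) dOmega` and returns the
#' eigenvector of the most distinct eigenvalue: the axis about which the
#' `l = 2` part is closest to zonal (the fiber-like orientation).  The
#' sign is fixed to the positive-z hemisphere (ties: positive x, then
#' positive y).
#'
#' @inheritParams sh_cross_spectrum
#' @return list with `orientation` (sign-free unit 3-vector),
#'   `eigenvalues` (sorted decreasing), and `degenerate` (TRUE when the
#'   extremal eigenvalue is not isolated, in which case any vector of the
#'   degenerate subspace is returned).
#' @export
main_orientation <- function(g, convention = NULL) {
  cv <- .conv_of(g, convention)
  if (cv$ell_max < 2L) stop("needs an l = 2 component (ell_max >= 2)")
  g2 <- g
  g2[cv$ell != 2L] <- 0
  if (sum(g2^2) == 0) stop("zero l = 2 component: orientation undefined")
  q <- sphere_quadrature(4L, 8L)
  vals <- as.numeric(sh_evaluate(q$points, cv) %*% g2)
  Tm <- matrix(0, 3L, 3L)
  for (a in 1:3)
    for (b in 1:3)
      Tm[a, b] <- sum(q$weights * vals * q$points[, a] * q$points[, b])
  Tm <- Tm - diag(3) * sum(diag(Tm)) / 3
  eg <- eigen(Tm, symmetric = TRUE)
  lam <- eg$values # decreasing
  # most distinct eigenvalue: farthest from the median one
  pick <- if (abs(lam[1L] - lam[2L]) >= abs(lam[3L] - lam[2L])) 1L else 3L
  degenerate <- abs(lam[1L] - lam[3L]) < 1e-12 ||
    abs(lam[pick] - lam[2L]) < 1e-10 * max(1, abs(lam[pick]))
  v <- eg$vectors[, pick]
  s <- sign(v[3L])
  if (s == 0) s <- sign(v[1L])
  if (s == 0) s <- sign(v[2L])
  if (s == 0) s <- 1
  v <- v * s
  list(orientation = v, eigenvalues = lam, degenerate = degenerate)
}

#' Expand the square of a band-limited function
#'
#' Samples the squared function on an equiangular (Driscoll-Healy style)
#' quadrature grid dense enough for exactness and projects it onto the
#' basis up to `ell_max_out`.  The square of a band-limit `L` function is a
#' spherical polynomial of band limit `2 L`, so with
#' `ell_max_out >= 2 * L` the expansion is exact up to quadrature rounding;
#' this is how squared-representation reconstructions are brought into the
#' plain coefficient representation before ensemble averaging.
#'
#' @param coefficients length-M coefficient vector of the (un-squared)
#'   function.
#' @param convention_in convention of `coefficients`.
#' @param ell_max_out even band limit of the output (must be at least
#'   `2 * convention_in$ell_max`).
#' @return coefficient vector in `sh_convention(ell_max_out)`.
#' @export
expand_squared <- function(coefficients, convention_in, ell_max_out) {
  stopifnot(inherits(convention_in, "sh_convention"))
  if (ell_max_out < 2L * convention_in$ell_max)
    stop("ell_max_out must be >= 2 * ell_max_in = ",
         2L * convention_in$ell_max)
  conv_out <- sh_convention(ell_max_out)
  deg <- 2L * convention_in$ell_max + ell_max_out # integrand degree
  q <- dh_quadrature(deg + 2L, deg + 2L)
  f <- as.numeric(sh_evaluate(q$points, convention_in) %*% coefficients)
  Yo <- sh_evaluate(q$points, conv_out)
  as.numeric(crossprod(Yo, q$weights * f^2))
}

#' Tukey box-plot summary with 1.25 IQR whiskers
#'
#' Boxes span the interquartile range; whiskers span the smallest and
#' largest observations inside
#' `[Q1 - 1.25 (Q3 - Q1), Q3 + 1.25 (Q3 - Q1)]` — the whisker factor used
#' in the evaluation reports is 1.25.  Non-finite values are dropped.
#'
#' @param x numeric vector (e.g. per-voxel R-squared values).
#' @return list with `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `n_outliers`.
#' @export
tukey_box_stats <- function(x) {
  x <- x[is.finite(x)]
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3L] - qs[1L]
  lo <- qs[1L] - 1.25 * iqr
  hi <- qs[3L] + 1.25 * iqr
  inside <- x[x >= lo & x <= hi]
  list(q1 = qs[1L], median = qs[2L], q3 = qs[3L],
       whisker_low = if (length(inside)) min(inside) else NA_real_,
       whisker_high = if (length(inside)) max(inside) else NA_real_,
       n_outliers = sum(x < lo | x > hi))
}

#' Voxel-wise invariant maps of a coefficient volume
#'
#' @param volume a [tt_volume()].
#' @param reference optional reference volume for the R-squared map.
#' @param ensemble optional list of volumes for the Q map.
#' @return list of 3-D arrays: `mean`, `power`, `rel_aniso`, and optionally
#'   `r2`, `q`.
#' @export
invariant_maps <- function(volume, reference = NULL, ensemble = NULL) {
  cv <- attr(volume, "convention")
  A <- .coef_mat(volume)
  d3 <- dim(volume)[1:3]
  an <- cv$ell >= 2L
  mn <- A[, 1L] / sqrt(4 * pi)
  pw <- rowSums(A[, an, drop = FALSE]^2) / (4 * pi)
  ra <- ifelse(mn > 0, sqrt(pw) / mn, NaN)
  out <- list(mean = array(mn, d3), power = array(pw, d3),
              rel_aniso = array(ra, d3))
  if (!is.null(reference)) out$r2 <- r_squared_map(volume, reference)
  if (!is.null(ensemble)) out$q <- ensemble_q(ensemble)
  out
}
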