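#' Azimuthal binning scheme
#'
#' `n_bins` equal-width detector azimuth bins tiling `[0, pi)`; by Friedel
#' symmetry the `[pi, 2 pi)` half of the circle is redundant.  The default
#' of 8 bins limits the exactly recoverable band limit to
#' `ell_max = n_bins - 1 = 7`, i.e. even orders up to 6.
#'
#' @param n_bins number of bins (default 8).
#' @return object of class `tt_binning` with `centers`, `width`, `n_bins`.
#' @export
tt_binning <- function(n_bins = 8L) {
  width <- pi / n_bins
  structure(
    list(n_bins = as.integer(n_bins),
         centers = (seq_len(n_bins) - 0.5) * width,
         width = width),
    class = "tt_binning"
  )
}

#' @export
print.tt_binning <- function(x, ...) {
  cat("Azimuthal binning:", x$n_bins, "bins of width", format(x$width),
      "rad tiling [0, pi)\n")
  invisible(x)
}

# per-projection M x N arc-integral matrices
.circle_bin_matrices <- function(geometry, binning, convention) {
  lapply(seq_len(geometry$n_proj), function(p) {
    sh_circle_bins(geometry$alpha[p], geometry$beta[p],
                   binning$centers, binning$width, convention)
  })
}

# cached linear operator: stacked sparse ray-weight matrix P
# (n_proj * n_pixels x n_voxels) plus the per-projection arc integrals Y.
# Built once per geometry so that solver iterations reduce to sparse
# matrix products with identical weights to john_transform().
.tt_operator <- function(geometry, binning, convention) {
  nj <- geometry$raster[1L]
  nk <- geometry$raster[2L]
  npix <- nj * nk
  h <- geometry$voxel_size
  trips <- lapply(seq_len(geometry$n_proj), function(p) {
    fr <- beam_basis(geometry$alpha[p], geometry$beta[p])
    .cpp_john_triplets(geometry$volume_shape, fr$u, fr$e_j, fr$e_k,
                       nj, nk, h)
  })
  i <- unlist(lapply(seq_along(trips), function(p)
    trips[[p]]$i + (p - 1L) * npix), use.names = FALSE)
  j <- unlist(lapply(trips, `[[`, "j"), use.names = FALSE)
  x <- unlist(lapply(trips, `[[`, "x"), use.names = FALSE)
  P <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(geometry$n_proj * npix,
                                     prod(geometry$volume_shape)))
  list(P = P, Y = .circle_bin_matrices(geometry, binning, convention),
       npix = npix, convention = convention)
}

#' Binned-measurement container
#'
#' @param data list of `(n_j, n_k, n_bins)` arrays, one per projection.
#' @param binning a [tt_binning()].
#' @param mask optional list of logical `(n_j, n_k)` arrays; `FALSE` pixels
#'   are excluded from residuals and gradients.
#' @return object of class `tt_data`.
#' @export
tt_data <- function(data, binning, mask = NULL) {
  stopifnot(is.list(data))
  nb <- unique(vapply(data, function(a) dim(a)[3L], integer(1)))
  if (length(nb) != 1L || nb != binning$n_bins)
    stop("all projections must have n_bins = ", binning$n_bins, " segments")
  structure(list(data = data, binning = binning, mask = mask),
            class = "tt_data")
}

#' @export
print.tt_data <- function(x, ...) {
  d <- dim(x$data[[1L]])
  cat("Binned measurement:", length(x$data), "projections of",
      d[1L], "x", d[2L], "pixels x", d[3L], "azimuthal bins\n")
  invisible(x)
}

#' Forward model: predicted binned intensities
#'
#' Projects each coefficient channel along the beam (John transform) and
#' contracts the result with the per-projection great-circle arc integrals
#' of the basis, giving the linear measurement model `D = P X Y`.
#'
#' @param volume a [tt_volume()].
#' @param geometry a [tt_geometry()].
#' @param binning a [tt_binning()].
#' @return a [tt_data()] of predicted intensities.
#' @export
tt_predict <- function(volume, geometry, binning) {
  volume <- .as_vol4(volume)
  conv <- attr(volume, "convention")
  if (conv$ell_max > binning$n_bins - 1L)
    warning("ell_max = ", conv$ell_max, " exceeds n_bins - 1 = ",
            binning$n_bins - 1L,
            ": the binned data cannot uniquely constrain this band limit")
  Y <- .circle_bin_matrices(geometry, binning, conv)
  imgs <- john_transform(volume, geometry)
  nj <- geometry$raster[1L]
  nk <- geometry$raster[2L]
  out <- lapply(seq_len(geometry$n_proj), function(p) {
    pix <- matrix(imgs[[p]], nj * nk, conv$M)
    array(pix %*% Y[[p]], c(nj, nk, binning$n_bins))
  })
  tt_data(out, binning)
}

# sum of squared nearest-neighbour coefficient differences along one axis
.axis_pairs <- function(v, axis) {
  d <- dim(v)
  n <- d[axis]
  if (n < 2L) return(NULL)
  idx1 <- lapply(d, seq_len)
  idx2 <- idx1
  idx1[[axis]] <- 1:(n - 1L)
  idx2[[axis]] <- 2:n
  list(a = do.call(`[`, c(list(v), idx1, list(drop = FALSE))),
       b = do.call(`[`, c(list(v), idx2, list(drop = FALSE))),
       i1 = idx1, i2 = idx2)
}

#' Nearest-neighbour smoothness penalty
#'
#' The regularizer: `lambda / (4 pi)` times the sum over 6-connected voxel
#' pairs of the squared coefficient-space distance.  With the orthonormal
#' basis and cross-spectrum normalization `1 / (4 pi)` this is the summed
#' squared spherical L2 distance between neighbouring reciprocal-space
#' maps, so minimizing it maximizes neighbour covariance.  Boundaries are
#' replicated (no wrap-around pairs), so spatially constant fields incur
#' zero penalty.
#'
#' @param volume a [tt_volume()].
#' @param lambda non-negative regularization weight.
#' @return list with `value` (scalar) and `gradient` (array like `volume`).
#' @export
laplacian_penalty <- function(volume, lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  volume <- .as_vol4(volume)
  v <- unclass(volume)
  grad <- array(0, dim(v))
  val <- 0
  scale <- lambda / (4 * pi)
  for (axis in 1:3) {
    pr <- .axis_pairs(v, axis)
    if (is.null(pr)) next
    dif <- pr$b - pr$a
    val <- val + sum(dif^2)
    lo <- .axis_assign(array(0, dim(v)), pr$i1, -2 * scale * dif)
    hi <- .axis_assign(array(0, dim(v)), pr$i2, 2 * scale * dif)
    grad <- grad + lo + hi
  }
  list(value = scale * val, gradient = grad)
}

.axis_assign <- function(arr, idx, value) {
  do.call(`[<-`, c(list(arr), idx, list(value)))
}

#' Objective value and gradient of the regularized least-squares problem
#'
#' `loss = || predict(X) - D ||^2 + laplacian_penalty(X, lambda)`, the
#' Frobenius norm taken over valid pixels.  The gradient of the data term
#' is assembled with the adjoint John transform and the transposed arc
#' integrals; masked pixels contribute zero residual and zero gradient.
#'
#' @param volume a [tt_volume()] (the current iterate X).
#' @param data a [tt_data()] of measured intensities.
#' @param geometry a [tt_geometry()].
#' @param binning a [tt_binning()].
#' @param lambda regularization weight.
#' @param op optional precomputed operator from the internal operator
#'   cache (reused across solver iterations).
#' @return list with `value`, `gradient` (a `tt_volume`), and `data_term`.
#' @export
tt_loss_grad <- function(volume, data, geometry, binning, lambda,
                         op = NULL) {
  volume <- .as_vol4(volume)
  conv <- attr(volume, "convention")
  if (is.null(op)) op <- .tt_operator(geometry, binning, conv)
  d <- dim(volume)
  vmat <- matrix(as.numeric(volume), prod(d[1:3]), d[4L])
  proj <- as.matrix(op$P %*% vmat)  # stacked pixel line integrals
  npix <- op$npix
  Rimg <- matrix(0, nrow(proj), conv$M)
  data_term <- 0
  for (p in seq_len(geometry$n_proj)) {
    D <- data$data[[p]]
    if (anyNA(D)) {
      bad <- apply(is.na(D), c(1L, 2L), any)
      if (is.null(data$mask) || any(bad & data$mask[[p]]))
        stop("NaN in data of projection ", p, " at unmasked pixels")
      D[is.na(D)] <- 0
    }
    rows <- (p - 1L) * npix + seq_len(npix)
    R <- proj[rows, , drop = FALSE] %*% op$Y[[p]] -
      matrix(D, npix, binning$n_bins)
    if (!is.null(data$mask)) R[!as.vector(data$mask[[p]]), ] <- 0
    data_term <- data_term + sum(R^2)
    Rimg[rows, ] <- R %*% t(op$Y[[p]])
  }
  gdata <- as.matrix(Matrix::crossprod(op$P, Rimg))
  pen <- laplacian_penalty(volume, lambda)
  grad <- 2 * array(gdata, d) + pen$gradient
  list(value = data_term + pen$value,
       gradient = tt_volume(grad, conv, geometry$voxel_size),
       data_term = data_term)
}
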