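#' Coefficient volume container
#'
#' A per-voxel field of even-order spherical-harmonic coefficients: a 4-D
#' array `(n_x, n_y, n_z, M)` with the basis convention and voxel size
#' attached.  A scalar volume (`M = 1` with `ell_max = 0`) reduces to
#' ordinary absorption tomography.
#'
#' @param values array of dim `(n_x, n_y, n_z, M)`, or `(n_x, n_y, n_z)`
#'   for a scalar volume.
#' @param convention an [sh_convention()]; default inferred as `ell_max = 0`
#'   for 3-D input.
#' @param voxel_size voxel edge length.
#' @return object of class `tt_volume` (the array, with attributes).
#' @export
tt_volume <- function(values, convention = NULL, voxel_size = 1) {
  if (length(dim(values)) == 3L) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 4L)
  if (is.null(convention)) {
    if (dim(values)[4L] != 1L)
      stop("convention required for multi-channel volumes")
    convention <- sh_convention(0L)
  }
  if (dim(values)[4L] != convention$M)
    stop("channel count ", dim(values)[4L], " does not match convention M = ",
         convention$M)
  structure(values, convention = convention, voxel_size = voxel_size,
            class = "tt_volume")
}

#' @export
print.tt_volume <- function(x, ...) {
  d <- dim(x)
  conv <- attr(x, "convention")
  cat("Coefficient volume", paste(d[1:3], collapse = " x "), "voxels, M =",
      d[4L], "coefficients (ell_max =", conv$ell_max,
      "), voxel size", attr(x, "voxel_size"), "\n")
  invisible(x)
}

.as_vol4 <- function(volume) {
  if (inherits(volume, "tt_volume")) return(volume)
  tt_volume(volume)
}

.check_vol_geom <- function(volume, geometry) {
  if (!all(dim(volume)[1:3] == geometry$volume_shape))
    stop("volume shape ", paste(dim(volume)[1:3], collapse = "x"),
         " does not match geometry volume_shape ",
         paste(geometry$volume_shape, collapse = "x"))
}

#' John (X-ray) transform of a multi-channel volume
#'
#' Line integrals of each coefficient channel along the beam direction, one
#' ray per raster pixel through the pixel centre.  Voxels are weighted by
#' the exact length of the ray segment intersecting them; rays outside the
#' volume contribute zero.
#'
#' @param volume a [tt_volume()] (or a 3-D array, treated as scalar).
#' @param geometry a [tt_geometry()].
#' @return list of arrays, one per projection, each `(n_j, n_k, M)`.
#' @export
john_transform <- function(volume, geometry) {
  volume <- .as_vol4(volume)
  .check_vol_geom(volume, geometry)
  d <- dim(volume)
  vmat <- matrix(as.numeric(volume), prod(d[1:3]), d[4L])
  h <- geometry$voxel_size
  nj <- geometry$raster[1L]
  nk <- geometry$raster[2L]
  lapply(seq_len(geometry$n_proj), function(p) {
    fr <- beam_basis(geometry$alpha[p], geometry$beta[p])
    img <- .cpp_john_forward(vmat, d[1:3], fr$u, fr$e_j, fr$e_k, nj, nk, h)
    array(img, c(nj, nk, d[4L]))
  })
}

#' Adjoint of the John transform (backprojection)
#'
#' Exact adjoint of [john_transform()] under the Euclidean inner products:
#' the same ray-traversal weights spread each pixel value back over the
#' voxels its ray crosses, so `<T x, y> == <x, T' y>` to machine precision.
#'
#' @param images list of `(n_j, n_k, M)` arrays, one per projection.
#' @param geometry a [tt_geometry()].
#' @param convention basis convention of the result (default `ell_max` 0
#'   for single-channel input is inferred only when `M = 1`).
#' @return a [tt_volume()].
#' @export
john_adjoint <- function(images, geometry, convention = NULL) {
  stopifnot(is.list(images), length(images) == geometry$n_proj)
  nj <- geometry$raster[1L]
  nk <- geometry$raster[2L]
  d3 <- geometry$volume_shape
  M <- dim(images[[1L]])[3L]
  h <- geometry$voxel_size
  acc <- matrix(0, prod(d3), M)
  for (p in seq_len(geometry$n_proj)) {
    img <- images[[p]]
    if (!all(dim(img) == c(nj, nk, M)))
      stop("image ", p, " has dim ", paste(dim(img), collapse = "x"),
           ", expected ", paste(c(nj, nk, M), collapse = "x"))
    fr <- beam_basis(geometry$alpha[p], geometry$beta[p])
    acc <- acc + .cpp_john_adjoint(matrix(img, nj * nk, M), d3,
                                   fr$u, fr$e_j, fr$e_k, nj, nk, h)
  }
  if (is.null(convention) && M == 1L) convention <- sh_convention(0L)
  tt_volume(array(acc, c(d3, M)), convention = convention, voxel_size = h)
}
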