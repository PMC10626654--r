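#' Beam and projection-plane basis vectors
#'
#' The beam direction for rotation `alpha` (azimuthal) and tilt `beta`
#' (polar, with respect to a fixed plane of the sample coordinate system) is
#' `u = (cos a cos b, sin a cos b, sin b)`.  `e_j` and `e_k` span the plane
#' of projection and complete a right-handed orthonormal triple
#' `(u, e_j, e_k)`; raster coordinate `j` moves along `e_j`, `k` along
#' `e_k`, and the detector azimuth origin `phi = 0` coincides with `e_j`.
#' At `(0, 0)` the triple is the canonical frame `x, y, z`.
#'
#' @param alpha,beta angles in radians.
#' @return list with unit vectors `u`, `e_j`, `e_k`.
#' @examples
#' beam_basis(0, 0)$u  # c(1, 0, 0)
#' @export
beam_basis <- function(alpha, beta) {
  u <- c(cos(alpha) * cos(beta), sin(alpha) * cos(beta), sin(beta))
  e_j <- c(-sin(alpha), cos(alpha), 0)
  e_k <- c(
    u[2L] * e_j[3L] - u[3L] * e_j[2L],
    u[3L] * e_j[1L] - u[1L] * e_j[3L],
    u[1L] * e_j[2L] - u[2L] * e_j[1L]
  )
  list(u = u, e_j = e_j, e_k = e_k)
}

#' Points on the probed great circle
#'
#' One projection probes the great circle of reciprocal-space directions
#' orthogonal to the beam: `C(phi) = cos(phi) e_j + sin(phi) e_k`, so
#' `C(phi) . u = 0` and `C(phi + pi) = -C(phi)`.
#'
#' @param alpha,beta projection angles in radians.
#' @param phi_values azimuths in radians.
#' @return length(phi_values) x 3 matrix of unit vectors.
#' @export
great_circle_points <- function(alpha, beta, phi_values) {
  fr <- beam_basis(alpha, beta)
  outer(cos(phi_values), fr$e_j) + outer(sin(phi_values), fr$e_k)
}

#' Projection geometry
#'
#' Bundles the ordered list of projection angles with the raster grid and
#' the volume metadata.  Raster spacing equals the voxel size (cubic voxels,
#' same size as the scanning step), rays pass through raster pixel centres,
#' and the raster is centred on the volume.
#'
#' @param alpha,beta equal-length vectors of projection angles (radians).
#' @param volume_shape integer 3-vector `(n_x, n_y, n_z)` of voxels.
#' @param raster integer 2-vector `(n_j, n_k)`; default covers the rotated
#'   volume diagonal.
#' @param voxel_size voxel edge length (default 1).
#' @return object of class `tt_geometry`.
#' @export
tt_geometry <- function(alpha, beta, volume_shape,
                        raster = NULL, voxel_size = 1) {
  stopifnot(length(alpha) == length(beta), length(volume_shape) == 3L)
  if (is.null(raster)) {
    n <- ceiling(sqrt(3) * max(volume_shape)) + 1L
    raster <- c(n, n)
  }
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta),
         n_proj = length(alpha),
         raster = as.integer(raster),
         volume_shape = as.integer(volume_shape),
         voxel_size = voxel_size),
    class = "tt_geometry"
  )
}

#' @export
print.tt_geometry <- function(x, ...) {
  cat("Projection geometry:", x$n_proj, "projections, raster",
      paste(x$raster, collapse = " x "), ", volume",
      paste(x$volume_shape, collapse = " x "), ", voxel size",
      x$voxel_size, "\n")
  cat("  tilt series beta:", paste(format(sort(unique(x$beta)), digits = 4),
                                   collapse = ", "), "rad\n")
  invisible(x)
}

#' Default two-tilt-series acquisition
#'
#' The package's standard simulated acquisition: for each tilt
#' `beta` the sample is rotated through `alpha` from 0 up to (not including)
#' 180 degrees in `alpha_step` increments.  The default two series at
#' `beta = 0` and 45 degrees with 10 degree steps give 36 projections and
#' leave a missing wedge, as real tilt-stage acquisitions do.
#'
#' @param volume_shape integer 3-vector of voxels.
#' @param beta tilt angles in radians (default `c(0, pi/4)`).
#' @param alpha_step rotation increment in radians (default 10 degrees).
#' @param raster,voxel_size passed to [tt_geometry()].
#' @return a `tt_geometry`.
#' @export
tt_tilt_series <- function(volume_shape, beta = c(0, pi / 4),
                           alpha_step = pi / 18, raster = NULL,
                           voxel_size = 1) {
  alpha <- seq(0, pi - alpha_step / 2, by = alpha_step)
  tt_geometry(alpha = rep(alpha, times = length(beta)),
              beta = rep(beta, each = length(alpha)),
              volume_shape = volume_shape, raster = raster,
              voxel_size = voxel_size)
}
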