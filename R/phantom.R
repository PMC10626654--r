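#' Phantom specification
#'
#' Describes a synthetic textured sample: a support mask, a small number of
#' texture sources placed at mutually distant interior points, per-source
#' spectral power following a power-law decay over even orders, Gaussian
#' correlation decay with interior distance, and one of three symmetry
#' classes:
#'
#' * `"zonal"` — approximately zonally symmetric maps built from
#'   l-weighted zonal deltas, band limit 12 (texture with an axis of
#'   rotational symmetry, as in fiber-like scattering);
#' * `"rank2"` — maps represented entirely by symmetric rank-2 tensors
#'   (orders 0 and 2 only);
#' * `"high_order"` — band limit 8 with a damped l = 2 component such that
#'   the l = 2 and l = 4 spectral powers are approximately equal
#'   (textures with neither equatorial nor meridional symmetry).
#'
#' Defaults emulate the reference study conditions at test scale: 16^3
#' voxels, a centred spherical support, two sources, power-law exponent
#' 1.5, correlation length one quarter of the mask diameter, zonal
#' l-weights `1 / (2 l + 1)`, and anisotropy giving relative anisotropy
#' around 0.4 at unit mean.  The canonical full-scale shapes are 50^3 with
#' 4 sources (zonal), 50^3 with 2 sources (rank2) and 60 x 60 x 80 with 5
#' sources (high_order).
#'
#' @param volume_shape integer 3-vector (default `c(16, 16, 16)`).
#' @param support_mask logical array; default a centred ball of radius
#'   `0.45 * min(volume_shape)`.
#' @param n_sources number of texture sources (default 2).
#' @param symmetry_class one of `"rank2"`, `"zonal"`, `"high_order"`.
#' @param ell_max band limit; default by class (2 / 12 / 8).
#' @param power_decay exponent of the per-order power law (default 1.5).
#' @param correlation_length voxels; default `diameter / 4` of the mask.
#' @param anisotropy total anisotropic power of each source at unit mean
#'   (default 0.16, i.e. relative anisotropy 0.4).
#' @param zonal_weights function of l giving the zonal-delta weights
#'   (default `1 / (2 l + 1)`).
#' @param seed integer seed controlling sources and textures.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(16L, 16L, 16L),
                         support_mask = NULL, n_sources = 2L,
                         symmetry_class = c("rank2", "zonal", "high_order"),
                         ell_max = NULL, power_decay = 1.5,
                         correlation_length = NULL, anisotropy = 0.16,
                         zonal_weights = function(l) 1 / (2 * l + 1),
                         seed = 1L) {
  symmetry_class <- match.arg(symmetry_class)
  if (is.null(ell_max))
    ell_max <- switch(symmetry_class, rank2 = 2L, zonal = 12L,
                      high_order = 8L)
  if (symmetry_class == "rank2" && ell_max != 2L)
    stop("rank2 phantoms have ell_max = 2")
  if (is.null(support_mask)) {
    r <- 0.45 * min(volume_shape)
    ctr <- (volume_shape + 1) / 2
    idx <- arrayInd(seq_len(prod(volume_shape)), volume_shape)
    support_mask <- array(
      (idx[, 1L] - ctr[1L])^2 + (idx[, 2L] - ctr[2L])^2 +
        (idx[, 3L] - ctr[3L])^2 <= r^2,
      dim = volume_shape)
  }
  stopifnot(n_sources >= 1L, sum(support_mask) >= n_sources,
            power_decay > 0, anisotropy >= 0)
  if (is.null(correlation_length)) {
    ext <- apply(which(support_mask, arr.ind = TRUE), 2L,
                 function(v) diff(range(v)) + 1)
    correlation_length <- sqrt(sum(ext^2)) / 4
  }
  stopifnot(correlation_length > 0)
  structure(
    list(volume_shape = as.integer(volume_shape),
         support_mask = support_mask, n_sources = as.integer(n_sources),
         symmetry_class = symmetry_class, ell_max = as.integer(ell_max),
         power_decay = power_decay,
         correlation_length = correlation_length,
         anisotropy = anisotropy, zonal_weights = zonal_weights,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom spec:", paste(x$volume_shape, collapse = " x "),
      "voxels,", sum(x$support_mask), "in support\n")
  cat("  class", x$symmetry_class, ", ell_max", x$ell_max, ",",
      x$n_sources, "sources, correlation length",
      format(x$correlation_length, digits = 4), "voxels, seed", x$seed,
      "\n")
  invisible(x)
}

# igraph over the 26-connected voxel lattice restricted to the mask
.mask_graph <- function(mask) {
  d <- dim(mask)
  inside <- which(mask)
  vid <- integer(prod(d))
  vid[inside] <- seq_along(inside)
  idx <- arrayInd(inside, d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one direction per pair to avoid duplicate edges
  offs <- offs[offs[, 1L] > 0 |
                 (offs[, 1L] == 0 & offs[, 2L] > 0) |
                 (offs[, 1L] == 0 & offs[, 2L] == 0 & offs[, 3L] > 0), ,
               drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2L, offs[r, ], "+")
    ok <- nb[, 1L] >= 1 & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1 & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1 & nb[, 3L] <= d[3L]
    nb_flat <- nb[ok, 1L] + d[1L] * (nb[ok, 2L] - 1L) +
      d[1L] * d[2L] * (nb[ok, 3L] - 1L)
    hit <- vid[nb_flat] > 0L
    from <- c(from, vid[inside[ok]][hit])
    to <- c(to, vid[nb_flat][hit])
    w <- c(w, rep(sqrt(sum(offs[r, ]^2)), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = length(inside), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  list(graph = g, inside = inside, idx = idx, dims = d)
}

#' Interior (geodesic) distance through a voxel mask
#'
#' Shortest-path distance over the 26-connected voxel adjacency graph of
#' the mask, with Euclidean edge weights — the within-sample distance used
#' to propagate texture away from source points.
#'
#' @param mask logical array.
#' @param sources integer matrix (n x 3) of voxel indices inside the mask.
#' @return array of dim `c(dim(mask), n_sources)`; 0 at each source, `Inf`
#'   in mask components not containing that source, `NA` outside the mask.
#' @export
interior_distance <- function(mask, sources) {
  if (is.null(dim(sources))) sources <- matrix(sources, nrow = 1L)
  if (!all(mask[sources])) stop("all sources must lie inside the mask")
  mg <- .mask_graph(mask)
  src_flat <- sources[, 1L] + dim(mask)[1L] * (sources[, 2L] - 1L) +
    dim(mask)[1L] * dim(mask)[2L] * (sources[, 3L] - 1L)
  src_v <- match(src_flat, mg$inside)
  dm <- igraph::distances(mg$graph, v = src_v, algorithm = "dijkstra")
  out <- array(NA_real_, c(dim(mask), nrow(sources)))
  nvox <- prod(dim(mask))
  for (s in seq_len(nrow(sources))) {
    slab <- rep(NA_real_, nvox)
    slab[mg$inside] <- dm[s, ]
    out[seq_len(nvox) + (s - 1L) * nvox] <- slab
  }
  if (any(is.infinite(dm)))
    warning("mask has components unreachable from some sources ",
            "(infinite distances)")
  out
}

#' Greedy farthest-point source placement
#'
#' Places `n_sources` points in the mask so that mutual interior distances
#' are (greedily) maximized.  The greedy start is the mask voxel nearest
#' the mask centroid; it is discarded for `n_sources >= 2` (the first kept
#' point is the voxel farthest from the start) and returned itself for
#' `n_sources = 1`, approximating the interior centre.  The seed breaks
#' ties between equally distant candidates.
#'
#' @param mask logical array.
#' @param n_sources number of points.
#' @param seed integer seed for tie-breaking.
#' @return n x 3 integer matrix of voxel indices.
#' @export
farthest_point_sources <- function(mask, n_sources, seed = 1L) {
  if (!any(mask)) stop("empty mask")
  stopifnot(sum(mask) >= n_sources)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d2c <- rowSums(sweep(idx, 2L, ctr, "-")^2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tie_pick <- function(score) {
    best <- which(score >= max(score) - 1e-12)
    if (length(best) == 1L) best else sample(best, 1L)
  }
  start <- tie_pick(-d2c)
  if (n_sources == 1L) return(idx[start, , drop = FALSE])
  chosen <- integer(0)
  dmin <- interior_distance(mask, idx[start, , drop = FALSE])[mask]
  dmin[!is.finite(dmin)] <- -Inf
  for (i in seq_len(n_sources)) {
    nxt <- tie_pick(dmin)
    chosen <- c(chosen, nxt)
    dn <- interior_distance(mask, idx[nxt, , drop = FALSE])[mask]
    dn[!is.finite(dn)] <- Inf
    dmin <- pmin(dmin, dn)
  }
  idx[chosen, , drop = FALSE]
}

# separable 3-D Gaussian smoothing (zero-padded)
.gauss_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  sm_axis <- function(a, axis) {
    d <- dim(a)
    out <- array(0, d)
    for (o in -r:r) {
      w <- kern[o + r + 1L]
      src <- lapply(d, seq_len)
      dst <- src
      n <- d[axis]
      lo <- max(1L, 1L - o); hi <- min(n, n - o)
      if (lo > hi) next
      dst[[axis]] <- lo:hi
      src[[axis]] <- (lo:hi) + o
      out <- .axis_assign(out, dst,
                          do.call(`[`, c(list(out), dst,
                                         list(drop = FALSE))) +
                            w * do.call(`[`, c(list(a), src,
                                               list(drop = FALSE))))
    }
    out
  }
  sm_axis(sm_axis(sm_axis(arr, 1L), 2L), 3L)
}

# per-source coefficient vector with the class's symmetry and per-order
# powers; returns list(coeffs, powers) with powers named by even order
.source_function <- function(spec, conv) {
  ells <- seq(0L, conv$ell_max, by = 2L)
  p <- numeric(length(ells))
  names(p) <- paste0("l", ells)
  p[1L] <- 1 # unit spherical mean => S_0 = 1
  hi <- ells[ells >= 2L]
  if (length(hi)) {
    raw <- switch(spec$symmetry_class,
      rank2 = 1,
      zonal = hi^(-spec$power_decay),
      high_order = {
        w <- hi^(-spec$power_decay)
        w[hi == 2L] <- w[hi == 4L] # damped l = 2: S_2 = S_4
        w
      })
    p[ells >= 2L] <- spec$anisotropy * raw / sum(raw)
  }
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  co <- if (spec$symmetry_class == "zonal") {
    sh_zonal_delta(dir, spec$zonal_weights(ells), conv)
  } else {
    rnorm(conv$M)
  }
  # rescale each order block to its target power (S_l = |c_l|^2 / 4pi)
  for (l in ells) {
    blk <- conv$ell == l
    nrm2 <- sum(co[blk]^2)
    tgt <- p[paste0("l", l)] * 4 * pi
    co[blk] <- if (nrm2 > 0) co[blk] * sqrt(tgt / nrm2) else 0
  }
  co[1L] <- abs(co[1L])
  list(coeffs = co, powers = p)
}

#' Synthesize a textured ground-truth coefficient volume
#'
#' Builds the phantom field from its spec: sources are placed by greedy
#' farthest-point sampling; each source carries a band-limited spherical
#' function of the requested symmetry class whose per-order spectral power
#' follows a power-law decay; every voxel mixes the source functions with
#' a smooth unit-power random texture so that (i) per-order correlation
#' with a source decays with interior distance as a Gaussian with the
#' correlation length as its standard deviation, (ii) the per-order power
#' equals the Gaussian-kernel distance-weighted average of the source
#' powers, and (iii) the field is spatially continuous.  Finally the
#' isotropic component is raised where needed so every voxel function is
#' non-negative on a dense direction grid.
#'
#' @param spec a [phantom_spec()].
#' @return a [tt_volume()] with attributes `sources` (voxel indices) and
#'   `spec`.
#' @export
synthesize_field <- function(spec) {
  conv <- sh_convention(spec$ell_max)
  mask <- spec$support_mask
  d <- dim(mask)
  nvox <- prod(d)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  sources <- farthest_point_sources(mask, spec$n_sources, seed = spec$seed)
  dists <- interior_distance(mask, sources)
  srcs <- lapply(seq_len(spec$n_sources), function(s) .source_function(spec, conv))
  ells <- seq(0L, conv$ell_max, by = 2L)

  # Gaussian kernel weights per source, voxels x sources
  W <- matrix(0, nvox, spec$n_sources)
  for (s in seq_len(spec$n_sources)) {
    dv <- as.numeric(dists[seq_len(nvox) + (s - 1L) * nvox])
    dv[!is.finite(dv)] <- Inf
    W[, s] <- exp(-dv^2 / (2 * spec$correlation_length^2))
  }
  W[is.na(W)] <- 0
  Wn <- W / pmax(rowSums(W), .Machine$double.eps) # normalized for powers

  # smooth unit-power noise texture, per coefficient channel
  noise <- matrix(0, nvox, conv$M)
  for (mcol in seq_len(conv$M)) {
    a <- array(rnorm(nvox), d)
    noise[, mcol] <- as.numeric(.gauss_smooth3(a, spec$correlation_length / 2))
  }

  out <- matrix(0, nvox, conv$M)
  inside <- which(as.vector(mask))
  for (l in ells) {
    blk <- which(conv$ell == l)
    # target per-voxel power: kernel-weighted average of source powers
    psrc <- vapply(srcs, function(s) s$powers[paste0("l", l)], numeric(1))
    ptgt <- as.numeric(Wn %*% psrc)
    if (l == 0L) {
      # positive isotropic component, smooth by construction of W
      out[inside, blk] <- sqrt(4 * pi * ptgt[inside])
      next
    }
    # unit-power source directions and aligned mixture
    ghat <- vapply(srcs, function(s) {
      v <- s$coeffs[blk]
      v / sqrt(sum(v^2))
    }, numeric(length(blk)))                      # |blk| x n_sources
    sig <- W %*% t(ghat)                          # voxels x |blk|
    alpha <- pmin(1, sqrt(rowSums(sig^2)))
    shat <- sig / pmax(sqrt(rowSums(sig^2)), .Machine$double.eps)
    nz <- noise[, blk, drop = FALSE]
    nhat <- nz / pmax(sqrt(rowSums(nz^2)), .Machine$double.eps)
    # orthogonalize the texture noise against the source mixture so the
    # voxel-source correlation equals the Gaussian kernel weight exactly
    nperp <- nhat - shat * rowSums(nhat * shat)
    nperp <- nperp / pmax(sqrt(rowSums(nperp^2)), .Machine$double.eps)
    mix <- alpha * shat + sqrt(pmax(0, 1 - alpha^2)) * nperp
    out[inside, blk] <- mix[inside, , drop = FALSE] *
      sqrt(4 * pi * ptgt[inside])
  }
  vol <- tt_volume(array(out, c(d, conv$M)), conv)
  vol <- enforce_nonnegativity(vol)
  attr(vol, "sources") <- sources
  attr(vol, "spec") <- spec
  vol
}

#' Raise isotropic components to enforce non-negativity
#'
#' Samples every voxel function on a dense direction grid and increases the
#' `l = 0` coefficient just enough to lift the sampled minimum to zero.
#' Only the isotropic coefficient changes, and the operation is idempotent.
#'
#' @param volume a [tt_volume()].
#' @param n_grid sphere-quadrature resolution of the sampling grid
#'   (default scales with the band limit).
#' @return the adjusted [tt_volume()].
#' @export
enforce_nonnegativity <- function(volume, n_grid = NULL) {
  conv <- attr(volume, "convention")
  if (is.null(n_grid)) n_grid <- max(16L, 2L * conv$ell_max + 4L)
  q <- sphere_quadrature(n_grid, 2L * n_grid)
  Y <- sh_evaluate(q$points, conv)
  A <- .coef_mat(volume)
  vals <- A %*% t(Y)
  mins <- apply(vals, 1L, min)
  lift <- pmax(0, -mins)
  A[, 1L] <- A[, 1L] + lift * sqrt(4 * pi)
  out <- tt_volume(array(A, dim(volume)), conv, attr(volume, "voxel_size"))
  for (a in c("sources", "spec")) attr(out, a) <- attr(volume, a)
  out
}

#' Simulate noisy binned measurements
#'
#' Applies the forward model to a ground-truth volume and adds noise.  The
#' default noise model is Gaussian with standard deviation
#' `mean(nonzero clean signal) / snr`, clipped at zero (clipped-bin count
#' reported as an attribute); a Poisson option scales the clean signal so
#' that the mean nonzero bin carries `snr^2` expected counts.
#'
#' @param volume ground-truth [tt_volume()].
#' @param geometry a [tt_geometry()].
#' @param binning a [tt_binning()].
#' @param snr requested signal-to-noise ratio (`Inf` for noiseless).
#' @param seed integer seed.
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @return a [tt_data()]; attribute `n_clipped` counts zero-clipped bins.
#' @export
simulate_measurements <- function(volume, geometry, binning = tt_binning(),
                                  snr = Inf, seed = 1L,
                                  noise = c("gaussian", "poisson")) {
  noise <- match.arg(noise)
  if (!(snr > 0)) stop("snr must be positive (or Inf)")
  clean <- tt_predict(volume, geometry, binning)
  if (!is.finite(snr)) return(clean)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  allv <- unlist(lapply(clean$data, as.numeric), use.names = FALSE)
  mu <- mean(allv[allv > 0])
  n_clipped <- 0L
  noisy <- lapply(clean$data, function(a) {
    if (noise == "gaussian") {
      b <- a + array(rnorm(length(a), sd = mu / snr), dim(a))
      n_clipped <<- n_clipped + sum(b < 0 & a > 0)
      pmax(b, 0)
    } else {
      scale <- snr^2 / mu
      array(rpois(length(a), lambda = pmax(a, 0) * scale) / scale, dim(a))
    }
  })
  out <- tt_data(noisy, binning)
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Generate a complete synthetic study dataset
#'
#' Convenience wrapper: synthesizes the ground-truth field from a
#' [phantom_spec()], builds the default two-tilt-series acquisition and
#' 8-bin azimuthal binning, and simulates (optionally noisy) measurements.
#'
#' @param spec a [phantom_spec()].
#' @param geometry optional [tt_geometry()]; default [tt_tilt_series()].
#' @param binning a [tt_binning()] (default 8 bins).
#' @param snr signal-to-noise ratio (default `Inf`).
#' @param seed seed for the measurement noise.
#' @return list with `ground_truth`, `geometry`, `binning`, `measurement`,
#'   `spec`.
#' @export
tt_phantom <- function(spec = phantom_spec(), geometry = NULL,
                       binning = tt_binning(), snr = Inf, seed = spec$seed) {
  gt <- synthesize_field(spec)
  if (is.null(geometry)) geometry <- tt_tilt_series(spec$volume_shape)
  meas <- simulate_measurements(gt, geometry, binning, snr = snr,
                                seed = seed)
  list(ground_truth = gt, geometry = geometry, binning = binning,
       measurement = meas, spec = spec)
}
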