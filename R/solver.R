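#' Random low-amplitude initial volume
#'
#' Coefficients drawn i.i.d. uniform on `[0, init_scale * ref)`,
#' reproducible for a fixed seed.  Used to randomize the starting point of
#' ensemble reconstructions at amplitudes well below the expected solution.
#'
#' @param volume_shape integer 3-vector of voxels.
#' @param convention an [sh_convention()].
#' @param init_scale relative amplitude (>= 0); 0 gives the zero volume.
#' @param seed integer seed.
#' @param ref reference coefficient magnitude (default 1).
#' @param voxel_size voxel edge length.
#' @return a [tt_volume()].
#' @export
randomize_init <- function(volume_shape, convention, init_scale, seed,
                           ref = 1, voxel_size = 1) {
  if (init_scale < 0) stop("init_scale must be non-negative")
  n <- prod(volume_shape) * convention$M
  vals <- if (init_scale == 0) {
    numeric(n)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    runif(n, 0, init_scale * ref)
  }
  tt_volume(array(vals, c(volume_shape, convention$M)), convention,
            voxel_size)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# documented default regularization weight: scales the penalty gradient to
# roughly 1% of the data-term gradient at typical coefficient contrast.
# sigma_c estimates the coefficient scale from the mean nonzero bin value,
# the mean chord length and the bin width.
.lambda_heuristic <- function(data, geometry, binning) {
  dall <- unlist(lapply(data$data, as.numeric), use.names = FALSE)
  dnz <- dall[dall > 0]
  if (!length(dnz)) return(0)
  mean_chord <- mean(geometry$volume_shape) * geometry$voxel_size
  sigma_c <- mean(dnz) * sqrt(4 * pi) / (mean_chord * binning$width *
                                           binning$n_bins)
  n_pairs <- 3 * prod(geometry$volume_shape)
  0.001 * sum(dall^2) * (4 * pi) / (n_pairs * sigma_c^2 + .Machine$double.eps)
}

# reference coefficient magnitude for randomized initialization
.init_ref <- function(data, geometry) {
  dall <- unlist(lapply(data$data, as.numeric), use.names = FALSE)
  dnz <- dall[dall > 0]
  if (!length(dnz)) return(1)
  mean(dnz) / (mean(geometry$volume_shape) * geometry$voxel_size)
}

#' Reconstruct a coefficient volume from binned measurements
#'
#' Fits the regularized least-squares problem
#' `min_X || P X Y - D ||^2 + lambda * L(X)` with a limited-memory
#' quasi-Newton method (L-BFGS-B), where `L` is the nearest-neighbour
#' coefficient smoothness penalty.  The objective is convex, so runs from
#' different small random initializations reach the same loss.
#'
#' `mode = "rank2"` restricts the expansion to `ell_max = 2` (a symmetric
#' rank-2 tensor per voxel), the band limit used by classical
#' iterative-reconstruction SAXS tensor tomography; it shares this solver.
#'
#' @param data a [tt_data()].
#' @param geometry a [tt_geometry()].
#' @param binning a [tt_binning()]; defaults to the binning stored in
#'   `data`.
#' @param ell_max even band limit of the reconstruction (default
#'   `n_bins - 2`, the largest even order below the Nyquist limit).
#' @param lambda regularization weight; `NULL` uses a documented heuristic
#'   scaled to the data norm per voxel pair.
#' @param max_iter maximum L-BFGS iterations (default 200).
#' @param tolerance relative loss-change stopping tolerance (default 1e-6).
#' @param seed seed for the random initialization.
#' @param init_scale relative amplitude of the random initialization
#'   (default 0: start from zero; ensembles use e.g. 1e-3).
#' @param mode `"full"` or `"rank2"`.
#' @return object of class `saxstt_recon`; see [coef.saxstt_recon()],
#'   [predict.saxstt_recon()], [plot.saxstt_recon()].
#' @examples
#' \donttest{
#' ph <- tt_phantom(phantom_spec(volume_shape = c(8, 8, 8),
#'                               symmetry_class = "rank2", seed = 1))
#' fit <- tt_reconstruct(ph$measurement, ph$geometry, lambda = 1e-3,
#'                       max_iter = 50)
#' summary(fit)
#' }
#' @export
tt_reconstruct <- function(data, geometry, binning = data$binning,
                           ell_max = NULL, lambda = NULL, max_iter = 200L,
                           tolerance = 1e-6, seed = 1L, init_scale = 0,
                           mode = c("full", "rank2")) {
  mode <- match.arg(mode)
  if (mode == "rank2") {
    if (!is.null(ell_max) && ell_max != 2L)
      stop("rank2 mode forces ell_max = 2")
    ell_max <- 2L
  }
  if (is.null(ell_max)) ell_max <- binning$n_bins - 2L
  if (ell_max %% 2 != 0) stop("ell_max must be even")
  if (ell_max > binning$n_bins - 1L)
    warning("ell_max exceeds n_bins - 1: solution is not unique; ",
            "expect band-limit artifacts")
  conv <- sh_convention(ell_max)
  if (is.null(lambda)) lambda <- .lambda_heuristic(data, geometry, binning)
  op <- .tt_operator(geometry, binning, conv)
  d4 <- c(geometry$volume_shape, conv$M)
  init <- randomize_init(geometry$volume_shape, conv, init_scale, seed,
                         ref = .init_ref(data, geometry),
                         voxel_size = geometry$voxel_size)

  trace_env <- new.env(parent = emptyenv())
  trace_env$loss <- numeric(0)
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    vol <- tt_volume(array(par, d4), conv, geometry$voxel_size)
    res <- tt_loss_grad(vol, data, geometry, binning, lambda, op = op)
    if (!is.finite(res$value))
      stop("loss diverged (", res$value, "): check data scaling / lambda")
    cache$par <- par
    cache$res <- res
    trace_env$loss <- c(trace_env$loss, res$value)
    res
  }
  fn <- function(par) evaluate(par)$value
  gr <- function(par) as.numeric(evaluate(par)$gradient)

  opt <- optim(as.numeric(init), fn, gr, method = "L-BFGS-B",
               control = list(maxit = max_iter,
                              factr = tolerance / .Machine$double.eps,
                              pgtol = 0))
  vol <- tt_volume(array(opt$par, d4), conv, geometry$voxel_size)
  # accepted iterates: strictly improving subsequence of evaluated losses
  cm <- cummin(trace_env$loss)
  acc <- cm[!duplicated(cm)]
  structure(
    list(volume = vol,
         loss = opt$value,
         convergence = data.frame(iteration = seq_along(acc), loss = acc),
         n_evaluations = length(trace_env$loss),
         config = list(ell_max = ell_max, lambda = lambda,
                       max_iter = max_iter, tolerance = tolerance,
                       seed = seed, init_scale = init_scale, mode = mode),
         optim = list(convergence = opt$convergence,
                      message = opt$message, counts = opt$counts),
         geometry = geometry, binning = binning, data = data,
         call = match.call()),
    class = "saxstt_recon"
  )
}

#' Ensemble reconstruction with randomized initial conditions
#'
#' Runs `n_runs` reconstructions, each starting from a different small
#' random coefficient volume, and averages them voxel by voxel.  Per-run
#' volumes are retained for the ensemble power-quotient analysis
#' ([ensemble_q()]); for a convex objective the runs coincide and Q is 1
#' wherever material is present.
#'
#' @inheritParams tt_reconstruct
#' @param n_runs number of ensemble members (the reference study uses 10).
#' @param seeds integer vector of length `n_runs` (default `1:n_runs`).
#' @param init_scale relative init amplitude (default 1e-3: several orders
#'   of magnitude below the expected solution).
#' @param ... further arguments to [tt_reconstruct()].
#' @return object of class `saxstt_ensemble`: list with `runs` (the fitted
#'   models), `average` (mean coefficient volume), `q` (Q map), `losses`.
#' @export
tt_ensemble <- function(data, geometry, binning = data$binning,
                        n_runs = 10L, seeds = seq_len(n_runs),
                        init_scale = 1e-3, ...) {
  stopifnot(n_runs >= 1L, length(seeds) == n_runs)
  runs <- lapply(seeds, function(s)
    tt_reconstruct(data, geometry, binning, seed = s,
                   init_scale = init_scale, ...))
  vols <- lapply(runs, function(r) r$volume)
  avg <- Reduce(`+`, lapply(vols, unclass)) / n_runs
  conv <- attr(vols[[1L]], "convention")
  avg <- tt_volume(avg, conv, geometry$voxel_size)
  structure(
    list(runs = runs, average = avg, q = ensemble_q(vols),
         losses = vapply(runs, function(r) r$loss, numeric(1))),
    class = "saxstt_ensemble"
  )
}

#' @export
print.saxstt_ensemble <- function(x, ...) {
  cat("Ensemble of", length(x$runs), "reconstructions\n")
  cat("  final losses:", paste(format(x$losses, digits = 6), collapse = ", "),
      "\n")
  qv <- x$q[is.finite(x$q)]
  if (length(qv))
    cat("  median Q over non-degenerate voxels:",
        format(median(qv), digits = 6), "\n")
  invisible(x)
}
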