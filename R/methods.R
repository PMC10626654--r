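#' @export
print.saxstt_recon <- function(x, ...) {
  cat("Tensor-tomography reconstruction (regularized least squares)\n")
  cat("  mode:", x$config$mode, " ell_max:", x$config$ell_max,
      " lambda:", format(x$config$lambda, digits = 4), "\n")
  cat("  volume:", paste(dim(x$volume)[1:3], collapse = " x "),
      "voxels x", dim(x$volume)[4L], "coefficients\n")
  cat("  final loss:", format(x$loss, digits = 8), "after",
      nrow(x$convergence), "accepted iterations (",
      x$n_evaluations, "objective evaluations )\n")
  invisible(x)
}

#' Summary of a reconstruction
#'
#' Reports the configuration, convergence, and voxel-wise invariant
#' statistics (spherical mean, anisotropic power, relative anisotropy)
#' over voxels with positive mean.
#'
#' @param object a `saxstt_recon`.
#' @param reference optional ground-truth [tt_volume()]; adds the Tukey
#'   box summary (1.25 IQR whiskers) of the voxel-wise R-squared.
#' @param ... unused.
#' @export
summary.saxstt_recon <- function(object, reference = NULL, ...) {
  maps <- invariant_maps(object$volume, reference = reference)
  keep <- is.finite(maps$rel_aniso)
  out <- list(
    config = object$config,
    loss = object$loss,
    iterations = nrow(object$convergence),
    mean = summary(maps$mean[keep]),
    power = summary(maps$power[keep]),
    rel_aniso = summary(maps$rel_aniso[keep])
  )
  if (!is.null(reference)) out$r2_box <- tukey_box_stats(maps$r2)
  class(out) <- "summary.saxstt_recon"
  out
}

#' @export
print.summary.saxstt_recon <- function(x, ...) {
  cat("Reconstruction summary\n")
  cat("  ell_max", x$config$ell_max, " lambda",
      format(x$config$lambda, digits = 4), " mode", x$config$mode, "\n")
  cat("  loss", format(x$loss, digits = 8), "in", x$iterations,
      "iterations\n")
  cat("  spherical mean (textured voxels):\n")
  print(x$mean)
  cat("  relative anisotropy:\n")
  print(x$rel_aniso)
  if (!is.null(x$r2_box)) {
    b <- x$r2_box
    cat("  R^2 vs reference: median", format(b$median, digits = 4),
        " IQR [", format(b$q1, digits = 4), ",",
        format(b$q3, digits = 4), "]",
        " whiskers [", format(b$whisker_low, digits = 4), ",",
        format(b$whisker_high, digits = 4), "]\n")
  }
  invisible(x)
}

#' @export
coef.saxstt_recon <- function(object, ...) object$volume

#' Predicted binned intensities of a fitted reconstruction
#'
#' @param object a `saxstt_recon`.
#' @param geometry optional alternative [tt_geometry()] (e.g. unseen
#'   projection angles); default the fitting geometry.
#' @param binning optional alternative [tt_binning()].
#' @param ... unused.
#' @return a [tt_data()].
#' @export
predict.saxstt_recon <- function(object, geometry = object$geometry,
                                 binning = object$binning, ...) {
  tt_predict(object$volume, geometry, binning)
}

#' @export
fitted.saxstt_recon <- function(object, ...) predict(object)

#' @export
residuals.saxstt_recon <- function(object, ...) {
  fit <- predict(object)
  mapply(function(d, f) d - f, object$data$data, fit$data,
         SIMPLIFY = FALSE)
}

#' Convergence plot
#'
#' Loss of the accepted iterates on a log scale.
#'
#' @param x a `saxstt_recon`.
#' @param ... passed to [plot()].
#' @export
plot.saxstt_recon <- function(x, ...) {
  cv <- x$convergence
  plot(cv$iteration, cv$loss, type = "l", log = "y",
       xlab = "accepted iteration", ylab = "loss",
       main = "Reconstruction convergence", ...)
  invisible(x)
}

#' Simulate measurements from a fitted reconstruction
#'
#' Draws noisy binned data from the fitted volume under the package noise
#' model, e.g. for parametric-bootstrap checks.
#'
#' @param object a `saxstt_recon`.
#' @param nsim number of datasets.
#' @param seed integer seed.
#' @param snr signal-to-noise ratio of the simulated data.
#' @param ... unused.
#' @return list of [tt_data()] objects (length `nsim`).
#' @export
simulate.saxstt_recon <- function(object, nsim = 1, seed = 1L, snr = 10,
                                  ...) {
  lapply(seq_len(nsim), function(i)
    simulate_measurements(object$volume, object$geometry, object$binning,
                          snr = snr, seed = seed + i - 1L))
}
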