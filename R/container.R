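#' Write a dataset container
#'
#' Serializes a complete tensor-tomography dataset to a single RDS file
#' with a fixed group layout: `geometry` (per-projection alpha, beta in
#' radians, raster shape, voxel size), `binning` (bin centres, width,
#' count), `data` (per-projection intensity arrays and optional masks),
#' and optional `ground_truth`, `reconstruction`, `analysis` groups.
#' Every container records the basis convention (real orthonormal
#' even-order harmonics, l-major ordering, no Condon-Shortley phase), the
#' coordinate convention and the package version; arrays round-trip
#' bit-exactly.  Unknown groups supplied by the caller are preserved.
#'
#' @param path output file path.
#' @param contents named list with at least `geometry`, `binning`, `data`;
#'   any further groups are kept as-is.
#' @return `path`, invisibly.
#' @export
tt_write_container <- function(path, contents) {
  stopifnot(is.list(contents))
  contents$format <- list(
    container = "saxstt-rds",
    version = as.character(packageVersion("saxstt")),
    basis = paste("real orthonormal even-order spherical harmonics,",
                  "l-major, m = -l..l, no Condon-Shortley phase"),
    coordinates = paste("u = (cos a cos b, sin a cos b, sin b);",
                        "(u, e_j, e_k) right-handed; phi = 0 along e_j"))
  saveRDS(contents, path)
  invisible(path)
}

#' Read a dataset container
#'
#' @param path file written by [tt_write_container()].
#' @param require character vector of groups that must be present
#'   (default `c("geometry", "binning", "data")`); the first missing one
#'   is named in the error.
#' @return the container contents (named list).
#' @export
tt_read_container <- function(path, require = c("geometry", "binning",
                                                "data")) {
  contents <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("corrupted container ", path, ": ", conditionMessage(e)))
  if (!is.list(contents) || is.null(contents$format$container) ||
      contents$format$container != "saxstt-rds")
    stop("corrupted container: missing group `format`")
  ver <- contents$format$version
  cur <- as.character(packageVersion("saxstt"))
  if (!identical(ver, cur))
    warning("container written by saxstt ", ver, ", reading with ", cur)
  for (grp in require)
    if (is.null(contents[[grp]]))
      stop("container is missing required group `", grp, "`")
  contents
}

#' Export arrays as flat binary with a JSON sidecar
#'
#' Writes each array as little-endian float64 (`<name>.f64`) plus a JSON
#' sidecar describing shape (column-major), dtype and conventions, for
#' consumption by external visualization tools.
#'
#' @param arrays named list of numeric arrays (e.g. a coefficient volume
#'   and invariant maps).
#' @param prefix output path prefix.
#' @return character vector of files written, invisibly.
#' @export
tt_export_flat <- function(arrays, prefix) {
  stopifnot(is.list(arrays), length(names(arrays)) == length(arrays))
  files <- character(0)
  meta <- list()
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    f <- paste0(prefix, "_", nm, ".f64")
    con <- file(f, "wb")
    writeBin(as.numeric(a), con, size = 8L, endian = "little")
    close(con)
    files <- c(files, f)
    meta[[nm]] <- list(file = basename(f), dtype = "float64",
                       byte_order = "little",
                       shape = if (is.null(dim(a))) length(a) else dim(a),
                       order = "column-major")
  }
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(
    list(arrays = meta,
         basis = "real orthonormal even-order spherical harmonics, l-major",
         package = paste("saxstt", packageVersion("saxstt"))),
    sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, sidecar))
}
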