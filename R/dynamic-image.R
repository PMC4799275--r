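#' Dynamic (4D) image volumes
#'
#' Container for an uncompressed dynamic CT series \eqn{I(x, t)}: `n` time
#' steps of a `Z x Y x X` volume of 16-bit signed integer intensities. The
#' data array is indexed `[t, z, y, x]`; internally R's column-major layout
#' then keeps every voxel's time series contiguous in memory.
#'
#' @param data 4D integer array with dim `(n, Z, Y, X)`, or any array coercible
#'   to it; values must lie in -32768..32767 with no NA.
#' @param times Optional acquisition times in seconds, length `n`, strictly
#'   increasing.
#' @param spacing Optional voxel spacing `(z, y, x)` in millimetres.
#' @return An object of class `dynamic_image` with fields `data`, `n`, `shape`
#'   (`c(Z, Y, X)`), `times` and `spacing`.
#' @seealso [dicopp_compress()], [generate_phantom()]
#' @export
dynamic_image <- function(data, times = NULL, spacing = NULL) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop_domain("'data' must be a 4D array with dim (n, Z, Y, X)")
  if (is.double(data)) {
    if (any(data != trunc(data), na.rm = TRUE))
      stop_domain("'data' must hold integer intensities")
    storage.mode(data) <- "integer"
  }
  if (!is.integer(data)) stop_domain("'data' must be an integer array")
  if (anyNA(data)) stop_domain("'data' must not contain NA")
  r <- range(data)
  if (r[1] < -32768L || r[2] > 32767L)
    stop_domain("intensities must fit in 16 bits (signed: -32768..32767)")
  d <- dim(data)
  if (any(d < 1L)) stop_domain("all dimensions must be >= 1")
  n <- d[1]
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (length(times) != n || any(times < 0) || is.unsorted(times, strictly = TRUE))
      stop_domain("'times' must be n non-negative, strictly increasing seconds")
  }
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(spacing <= 0))
      stop_domain("'spacing' must be 3 positive values (z, y, x) in mm")
  }
  structure(
    list(data = data, n = n, shape = d[2:4], times = times, spacing = spacing),
    class = "dynamic_image"
  )
}

#' @export
dim.dynamic_image <- function(x) dim(x$data)

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("<dynamic_image: %d time steps, volume %d x %d x %d (Z Y X), 16-bit>\n",
              x$n, x$shape[1], x$shape[2], x$shape[3]))
  cat(sprintf("  intensity range: %d .. %d\n",
              min(x$data), max(x$data)))
  if (!is.null(x$times))
    cat(sprintf("  acquisition: %.1f .. %.1f s\n",
                x$times[1], x$times[x$n]))
  invisible(x)
}

#' @export
`==.dynamic_image` <- function(e1, e2) {
  identical(dim(e1$data), dim(e2$data)) && all(e1$data == e2$data)
}

# 0-based linear voxel index j = (z*Y + y)*X + x from 1-based (z, y, x),
# x fastest.  This linearisation fixes the alignment of the C/B/O/D arrays
# and the container format.
voxel_index <- function(shape, z, y, x) {
  Z <- shape[1]; Y <- shape[2]; X <- shape[3]
  z <- check_scalar_int(z, "z"); y <- check_scalar_int(y, "y")
  x <- check_scalar_int(x, "x")
  if (z < 1 || z > Z || y < 1 || y > Y || x < 1 || x > X)
    stop_bounds("voxel index (z, y, x) out of range")
  ((z - 1) * Y + (y - 1)) * X + (x - 1)
}
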