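# Internal helpers shared across modules.

#' Flatten an image matrix to a vector in row-major order
#'
#' All pixel vectors in this package use row-major (raster-scan) order:
#' the first `width` entries are the top row of the image, and so on.
#' R matrices are column-major, so the flattening transposes first.
#'
#' @param m a numeric matrix (height x width).
#' @return a numeric vector of length `nrow(m) * ncol(m)`.
#' @keywords internal
#' @noRd
vec_rowmajor <- function(m) {
  as.vector(t(m))
}

#' Reshape a row-major pixel vector back into an image matrix
#' @keywords internal
#' @noRd
unvec_rowmajor <- function(v, height, width) {
  if (length(v) != height * width) {
    stop("vector length ", length(v), " does not match shape ",
         height, " x ", width, call. = FALSE)
  }
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

# Sign with the fixed tie-break sign(0) = +1 used throughout: yes/no
# observers must answer even when the decision variable is exactly zero.
sign_pos <- function(z) {
  ifelse(z >= 0, 1, -1)
}

# Validate a (height, width) shape argument.
check_shape <- function(shape) {
  if (length(shape) != 2 || any(!is.finite(shape)) || any(shape < 1) ||
      any(shape != round(shape))) {
    stop("shape must be two positive integers (height, width)", call. = FALSE)
  }
  as.integer(shape)
}

# Coerce various inputs (reconstruction, template, matrix, vector) to a
# row-major pixel vector, checking the expected length when given.
as_pixel_vector <- function(x, m = NULL) {
  v <- if (inherits(x, "rc_template")) {
    vec_rowmajor(x$pixels)
  } else if (inherits(x, "rc_reconstruction")) {
    x$x_hat
  } else if (is.matrix(x)) {
    vec_rowmajor(x)
  } else {
    as.numeric(x)
  }
  if (!is.null(m) && length(v) != m) {
    stop("pixel vector has length ", length(v), ", expected ", m,
         call. = FALSE)
  }
  v
}

# Seed the RNG inside seeded package functions, restoring the caller's
# RNG state when the calling function exits.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
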