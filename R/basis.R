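#' Specify an orthonormal 2D discrete cosine basis
#'
#' A `basis_spec` describes the orthonormal basis \eqn{\Psi} over which a
#' latent template is assumed to be sparse. The only family currently
#' implemented is the separable two-dimensional type-II discrete cosine
#' basis (`"dct2"`), with the orthonormal scaling in each dimension so that
#' \eqn{\Psi^T \Psi = I} exactly.
#'
#' Basis columns are indexed by 2D frequency pairs `(u, v)` with
#' `u = 0, ..., height - 1` (vertical frequency) and
#' `v = 0, ..., width - 1` (horizontal frequency), ordered row-major in
#' `(u, v)`: column `u * width + v + 1` is the vectorized basis image with
#' vertical frequency `u` and horizontal frequency `v`. Images are always
#' vectorized in row-major (raster-scan) pixel order.
#'
#' @param height,width image dimensions in pixels (positive integers).
#' @param family basis family; only `"dct2"` is available.
#' @return an object of class `basis_spec` with fields `height`, `width`,
#'   `family` and `m = height * width`.
#' @examples
#' spec <- basis_spec(8, 8)
#' psi <- build_basis(spec)
#' max(abs(crossprod(psi) - diag(spec$m)))  # orthonormality
#' @export
basis_spec <- function(height, width, family = "dct2") {
  shape <- check_shape(c(height, width))
  family <- match.arg(family, "dct2")
  structure(
    list(height = shape[1], width = shape[2], family = family,
         m = shape[1] * shape[2]),
    class = "basis_spec"
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("<basis_spec> %s, %d x %d pixels (m = %d)\n",
              x$family, x$height, x$width, x$m))
  invisible(x)
}

# Orthonormal 1D type-II DCT matrix, n x n. Row u (0-based frequency)
# holds sqrt((2 - [u == 0]) / n) * cos(pi * (2j + 1) * u / (2n)).
dct_matrix_1d <- function(n) {
  u <- 0:(n - 1)
  j <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(u, 2 * j + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}

#' Materialize the dense basis matrix
#'
#' Builds the full \eqn{m \times m} matrix \eqn{\Psi} whose columns are the
#' vectorized 2D DCT basis images, in the ordering documented in
#' [basis_spec()]. Intended for inspection, debugging dumps and small-scale
#' verification; all production paths use the separable fast transform in
#' [forward_coefficients()] instead and never materialize \eqn{\Psi}.
#'
#' @param spec a [basis_spec()].
#' @return an `m x m` orthonormal matrix.
#' @export
build_basis <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  Ch <- dct_matrix_1d(spec$height)
  Cw <- dct_matrix_1d(spec$width)
  # Column for (u, v) is vec_rowmajor(outer(Ch[u + 1, ], Cw[v + 1, ])),
  # which is exactly the row-major Kronecker product Ch %x% Cw transposed
  # into column position.
  t(Ch %x% Cw)
}

#' Analyze an image into basis coefficients
#'
#' Computes \eqn{s = \Psi^T x} for a row-major vectorized image `x`, via the
#' separable transform `C_h X C_w^T` (two small matrix products) rather than
#' a dense \eqn{m \times m} multiply. Exact inverse: [inverse_coefficients()].
#'
#' @param x numeric vector of length `m` (row-major pixels), or an image
#'   matrix of the spec's shape.
#' @param spec a [basis_spec()].
#' @return numeric vector of length `m` of basis coefficients, ordered as
#'   documented in [basis_spec()].
#' @export
forward_coefficients <- function(x, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  X <- if (is.matrix(x)) {
    if (nrow(x) != spec$height || ncol(x) != spec$width) {
      stop("image shape does not match basis spec", call. = FALSE)
    }
    x
  } else {
    unvec_rowmajor(as.numeric(x), spec$height, spec$width)
  }
  Ch <- dct_matrix_1d(spec$height)
  Cw <- dct_matrix_1d(spec$width)
  vec_rowmajor(Ch %*% X %*% t(Cw))
}

#' Synthesize an image from basis coefficients
#'
#' Computes \eqn{x = \Psi s}; the exact inverse of [forward_coefficients()].
#'
#' @param s numeric vector of length `m` of basis coefficients.
#' @param spec a [basis_spec()].
#' @return numeric vector of length `m` (row-major pixels).
#' @export
inverse_coefficients <- function(s, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  S <- unvec_rowmajor(as.numeric(s), spec$height, spec$width)
  Ch <- dct_matrix_1d(spec$height)
  Cw <- dct_matrix_1d(spec$width)
  vec_rowmajor(t(Ch) %*% S %*% Cw)
}

#' Compressive sensing matrix
#'
#' Forms \eqn{\Theta = \Phi_c \Psi}, the matrix of inner products between
#' (centered) stimuli and the basis functions: row `i` is
#' [forward_coefficients()] applied to centered stimulus `i`. Estimators in
#' this package never need the full \eqn{\Theta} (they apply
#' \eqn{\Theta^T y} through the fast transform), so this is mainly useful
#' for inspection and for verifying identities at small scale.
#'
#' @param stimuli a [stimulus_set()] or a numeric `l x m` matrix of stimuli
#'   in row-major pixel order.
#' @param spec a [basis_spec()] whose `m` matches the stimulus dimension.
#' @param center subtract the stimulus-ensemble mean (0.5 per pixel for
#'   binary stimuli) from each row before transforming? Default `TRUE`,
#'   matching the geometry the simulated observer uses.
#' @return an `l x m` numeric matrix.
#' @export
sensing_matrix <- function(stimuli, spec, center = TRUE) {
  stopifnot(inherits(spec, "basis_spec"))
  phi <- if (inherits(stimuli, "rc_stimuli")) stimuli$matrix else as.matrix(stimuli)
  if (ncol(phi) != spec$m) {
    stop("stimulus dimension ", ncol(phi), " does not match basis m = ",
         spec$m, call. = FALSE)
  }
  if (center) phi <- phi - stimulus_center(stimuli, spec$m)
  # Theta^T = Psi^T Phi^T: transform the columns of t(phi) in one sweep.
  Ch <- dct_matrix_1d(spec$height)
  Cw <- dct_matrix_1d(spec$width)
  out <- matrix(0, nrow(phi), spec$m)
  for (i in seq_len(nrow(phi))) {
    X <- unvec_rowmajor(phi[i, ], spec$height, spec$width)
    out[i, ] <- vec_rowmajor(Ch %*% X %*% t(Cw))
  }
  out
}

# Per-pixel center of the stimulus ensemble: 0.5 for the binary
# equal-probability stimuli this package generates; falls back to 0.5 for
# raw matrices too (documented contract of the stimulus distribution).
stimulus_center <- function(stimuli, m) {
  0.5
}

#' Export a basis matrix as delimited text
#'
#' Debugging aid: writes `build_basis(spec)` as tab-separated text.
#'
#' @param spec a [basis_spec()].
#' @param file path to write.
#' @return `file`, invisibly.
#' @export
write_basis_text <- function(spec, file) {
  utils::write.table(build_basis(spec), file, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
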