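#' Template objects
#'
#' A template is the ground-truth latent representation the simulated
#' observer carries: a grayscale image with intensities in \[0, 1\]. It is
#' stored as a `height x width` matrix together with a human-readable
#' label; pixel vectors derived from it are always row-major.
#'
#' @param pixels numeric matrix with entries in \[0, 1\].
#' @param label short text label (e.g. `"S"`, `"dot"`).
#' @return an object of class `rc_template`.
#' @export
new_template <- function(pixels, label = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 1)) {
    stop("template intensities must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, shape = c(nrow(pixels), ncol(pixels)),
         label = as.character(label)),
    class = "rc_template"
  )
}

#' @export
print.rc_template <- function(x, ...) {
  cat(sprintf("<template '%s'> %d x %d pixels, intensity range [%.3f, %.3f]\n",
              x$label, x$shape[1], x$shape[2],
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Row-major pixel vector of a template
#'
#' @param template an [new_template()] object.
#' @return numeric vector of length `height * width`.
#' @export
template_vector <- function(template) {
  stopifnot(inherits(template, "rc_template"))
  vec_rowmajor(template$pixels)
}

#' Letter templates
#'
#' Builds a grayscale letter image to serve as the latent representation of
#' a simulated observer, emulating the "superstitious perception" letter
#' detection paradigm. The canonical lowercase "s" at 50 x 50 pixels ships
#' with the package as a fixed raster (rasterized once from a generic
#' sans-serif face, horizontally stretched to fill the square), so that the
#' canonical simulations are bit-reproducible and independent of the fonts
#' installed on the host. Any other letter or size is rasterized at call
#' time through a graphics device: the glyph is drawn large, cropped to its
#' ink bounding box, and area-resampled to the requested shape.
#'
#' @param letter a single printable character.
#' @param shape target image shape `(height, width)` in pixels.
#' @return an [new_template()] with intensities in \[0, 1\]
#'   (1 = letter foreground).
#' @examples
#' s <- make_letter_template("s", c(50, 50))
#' mean(template_vector(s) > 0.5)  # foreground fraction
#' @export
make_letter_template <- function(letter, shape = c(50, 50)) {
  shape <- check_shape(shape)
  if (!is.character(letter) || length(letter) != 1 || nchar(letter) != 1) {
    stop("letter must be a single character", call. = FALSE)
  }
  if (letter %in% c("s", "S") && all(shape == c(50L, 50L))) {
    f <- system.file("extdata", "template_s_50x50.csv", package = "revcorrcs")
    px <- as.matrix(utils::read.csv(f, header = FALSE))
    dimnames(px) <- NULL
    return(new_template(px, label = "S"))
  }
  new_template(rasterize_letter(letter, shape), label = letter)
}

# Rasterize a glyph via the png device: draw white-on-black at high
# resolution, crop to the ink bounding box, then resample so the glyph
# fills the target shape (this is where the horizontal stretch of a
# naturally narrow letter happens).
rasterize_letter <- function(letter, shape, supersample = 8L) {
  big <- max(shape) * supersample
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f), add = TRUE)
  grDevices::png(f, width = big, height = big, type = "cairo")
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1),
                        xaxs = "i", yaxs = "i")
  graphics::rect(-1, -1, 2, 2, col = "black", border = NA)
  graphics::text(0.5, 0.5, letter, cex = big / 20, col = "white",
                 family = "sans")
  grDevices::dev.off()
  img <- png::readPNG(f)
  g <- if (length(dim(img)) == 3) img[, , 1] else img
  ink_rows <- which(rowSums(g > 0.5) > 0)
  ink_cols <- which(colSums(g > 0.5) > 0)
  if (length(ink_rows) == 0 || length(ink_cols) == 0) {
    stop("character '", letter, "' produced no visible glyph", call. = FALSE)
  }
  cropped <- g[min(ink_rows):max(ink_rows), min(ink_cols):max(ink_cols),
               drop = FALSE]
  out <- resample_bilinear(cropped, shape[1], shape[2])
  pmin(pmax(out, 0), 1)
}

# Plain bilinear resampling of a grayscale matrix to (h, w).
resample_bilinear <- function(img, h, w) {
  nr <- nrow(img)
  nc <- ncol(img)
  # map target pixel centers into source coordinates
  sr <- (seq_len(h) - 0.5) / h * nr + 0.5
  sc <- (seq_len(w) - 0.5) / w * nc + 0.5
  r0 <- pmin(pmax(floor(sr), 1), nr)
  r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(sc), 1), nc)
  c1 <- pmin(c0 + 1, nc)
  fr <- sr - r0
  fc <- sc - c0
  a <- img[r0, c0, drop = FALSE]
  b <- img[r0, c1, drop = FALSE]
  d <- img[r1, c0, drop = FALSE]
  e <- img[r1, c1, drop = FALSE]
  top <- a * (1 - rep(fc, each = h)) + b * rep(fc, each = h)
  bot <- d * (1 - rep(fc, each = h)) + e * rep(fc, each = h)
  top * (1 - fr) + bot * fr
}

#' Dot (impulse) templates
#'
#' A binary disc: intensity 1 at all pixels within `radius` of `center`
#' (Euclidean distance between pixel centers), 0 elsewhere. `radius = 0`
#' gives a single-pixel impulse.
#'
#' @param shape image shape `(height, width)`.
#' @param center dot center as `(row, col)`, 1-based pixel indices.
#' @param radius nonnegative radius in pixels.
#' @return an [new_template()].
#' @export
make_dot_template <- function(shape = c(50, 50),
                              center = ceiling(shape / 2),
                              radius = 3) {
  shape <- check_shape(shape)
  if (length(center) != 2 || any(center < 1) || center[1] > shape[1] ||
      center[2] > shape[2]) {
    stop("center must lie inside the image", call. = FALSE)
  }
  if (radius < 0) stop("radius must be nonnegative", call. = FALSE)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  px <- matrix(as.numeric(d2 <= radius^2), shape[1], shape[2])
  new_template(px, label = "dot")
}
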