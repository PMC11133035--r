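#' Generate random binary stimuli
#'
#' Draws `l` binary noise images with i.i.d. Bernoulli(0.5) pixels, the
#' measurement ensemble of the yes/no reverse correlation paradigm. Each
#' row of the returned matrix is one stimulus in row-major pixel order.
#'
#' @param l number of trials (rows), at least 1.
#' @param shape stimulus shape `(height, width)` in pixels.
#' @param seed integer seed; identical seeds give identical stimulus sets.
#' @return an object of class `rc_stimuli` with fields `matrix`
#'   (`l x m`, entries in \{0, 1\}), `shape`, `l`, `m`, `seed`.
#' @examples
#' phi <- generate_stimuli(100, c(10, 10), seed = 1)
#' mean(phi$matrix)  # close to 0.5
#' @export
generate_stimuli <- function(l, shape, seed = NULL) {
  shape <- check_shape(shape)
  if (!is.numeric(l) || length(l) != 1 || l < 1 || l != round(l)) {
    stop("l must be a positive integer number of trials", call. = FALSE)
  }
  l <- as.integer(l)
  m <- shape[1] * shape[2]
  local_seed(seed)
  mat <- matrix(stats::rbinom(l * m, 1L, 0.5), nrow = l, ncol = m)
  structure(
    list(matrix = mat, shape = shape, l = l, m = m,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "rc_stimuli"
  )
}

#' Wrap an existing stimulus matrix
#'
#' For stimuli loaded from files or supplied externally. Entries must be
#' exactly 0 or 1; rows are stimuli in row-major pixel order.
#'
#' @param matrix an `l x m` matrix with entries in \{0, 1\}.
#' @param shape `(height, width)` with `height * width == ncol(matrix)`.
#' @param seed seed recorded as provenance, if known.
#' @return an `rc_stimuli` object.
#' @export
stimulus_set <- function(matrix, shape, seed = NA_integer_) {
  shape <- check_shape(shape)
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != shape[1] * shape[2]) {
    stop("ncol(matrix) must equal height * width", call. = FALSE)
  }
  if (nrow(matrix) < 1) stop("need at least one stimulus", call. = FALSE)
  if (!all(matrix %in% c(0, 1))) {
    stop("stimulus entries must be exactly 0 or 1", call. = FALSE)
  }
  structure(
    list(matrix = matrix, shape = shape, l = nrow(matrix),
         m = ncol(matrix), seed = seed),
    class = "rc_stimuli"
  )
}

#' @export
print.rc_stimuli <- function(x, ...) {
  cat(sprintf("<stimuli> %d trials of %d x %d binary pixels (seed %s)\n",
              x$l, x$shape[1], x$shape[2],
              ifelse(is.na(x$seed), "unset", x$seed)))
  invisible(x)
}

#' Observer noise specification
#'
#' The noisy observer answers incorrectly at a controlled rate `sigma`,
#' expressed in percent. Two mechanisms are available:
#'
#' * `"flip"` (default): noiseless responses are computed first, then each
#'   is independently negated with probability `sigma / 100`. This realizes
#'   the reading of `sigma` as the percent of incorrect responses directly.
#' * `"additive_gaussian"`: zero-mean Gaussian noise is added to the
#'   decision variable before the sign is taken, the classical internal-
#'   noise model. With `calibrate = TRUE` (default) the noise scale is
#'   calibrated against the empirical decision-variable distribution so
#'   that the expected fraction of flipped responses equals `sigma`
#'   percent; only rates up to 50% are attainable this way (symmetric
#'   noise can never flip more than half the responses in expectation).
#'   With `calibrate = FALSE`, `sigma` is taken literally as the
#'   *variance* of the additive noise, in the raw units of the decision
#'   variable. The literal reading matters at heavy noise: a flat 50%
#'   error rate destroys all stimulus information, whereas additive
#'   Gaussian noise of fixed variance concentrates errors on trials with
#'   weak evidence and leaves the responses partially informative however
#'   large the variance.
#'
#' @param sigma nonnegative noise level: percent incorrect for `"flip"`
#'   and calibrated `"additive_gaussian"` (at most 100 and 50
#'   respectively), the noise variance for uncalibrated
#'   `"additive_gaussian"`.
#' @param mechanism `"flip"` or `"additive_gaussian"`.
#' @param calibrate for `"additive_gaussian"` only: interpret `sigma` as a
#'   target percent of incorrect responses (`TRUE`, default) or as the
#'   raw noise variance (`FALSE`).
#' @return an object of class `rc_noise`.
#' @export
noise_spec <- function(sigma = 0, mechanism = c("flip", "additive_gaussian"),
                       calibrate = TRUE) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0) {
    stop("sigma must be a single nonnegative number", call. = FALSE)
  }
  if (mechanism == "flip" && sigma > 100) {
    stop("flip mechanism requires sigma <= 100 (percent scale)",
         call. = FALSE)
  }
  structure(list(sigma = sigma, mechanism = mechanism,
                 calibrate = isTRUE(calibrate)),
            class = "rc_noise")
}

#' Simulate yes/no responses from a template-matching observer
#'
#' The observer compares each stimulus against its internal template and
#' answers yes or no by the sign of the match. The decision variable for
#' trial `i` is computed on centered quantities,
#' \deqn{z_i = (\phi_i - 0.5) \cdot (x - \bar x),}
#' where 0.5 is the per-pixel mean of the binary stimulus ensemble and
#' \eqn{\bar x} the template mean. Centering is essential: with raw
#' nonnegative stimuli and template the inner product is always positive
#' and the observer would answer yes on every trial. Ties (`z = 0`) break
#' to +1. Noise is then applied per [noise_spec()].
#'
#' Responses are coded internally as +1 (yes) and -1 (no); file I/O
#' accepts and emits the \{1, 0\} coding (see [read_stimulus_response()]).
#'
#' @param template an [new_template()].
#' @param stimuli an `rc_stimuli` with matching pixel dimension.
#' @param noise an [noise_spec()]; default noiseless.
#' @param seed integer seed for the noise draw (ignored when `sigma = 0`).
#' @return an object of class `rc_responses` with fields `values`
#'   (`l`-vector in \{-1, +1\}), `noise_sigma`, `mechanism`, `seed`.
#' @export
simulate_responses <- function(template, stimuli, noise = noise_spec(0),
                               seed = NULL) {
  stopifnot(inherits(template, "rc_template"),
            inherits(stimuli, "rc_stimuli"),
            inherits(noise, "rc_noise"))
  x <- template_vector(template)
  if (length(x) != stimuli$m) {
    stop("template and stimuli have mismatched pixel dimension",
         call. = FALSE)
  }
  z <- decision_variable(stimuli, x)
  y0 <- sign_pos(z)
  if (noise$sigma == 0) {
    y <- y0
  } else {
    local_seed(seed)
    if (noise$mechanism == "flip") {
      flips <- stats::rbinom(stimuli$l, 1L, noise$sigma / 100)
      y <- y0 * (1 - 2 * flips)
    } else {
      sc <- if (noise$calibrate) {
        calibrate_gaussian_scale(z, noise$sigma / 100)
      } else {
        sqrt(noise$sigma)  # sigma is the noise variance, used literally
      }
      y <- sign_pos(z + stats::rnorm(stimuli$l, 0, sc))
    }
  }
  structure(
    list(values = y, noise_sigma = noise$sigma,
         mechanism = noise$mechanism,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
    class = "rc_responses"
  )
}

# z = (Phi - 0.5) (x - mean(x)); the 0.5 drops against the centered
# template (rowSums of a constant times a zero-sum vector), so a single
# matrix-vector product suffices.
decision_variable <- function(stimuli, x) {
  xc <- x - mean(x)
  drop(stimuli$matrix %*% xc)
}

# Find the Gaussian noise sd such that the mean flip probability over the
# observed decision variables equals the target rate:
#   mean_i pnorm(-|z_i| / sc) = rate.
calibrate_gaussian_scale <- function(z, rate) {
  if (rate <= 0) return(0)
  if (rate > 0.5) {
    stop("additive Gaussian noise cannot exceed a 50% flip rate; ",
         "use the flip mechanism for sigma > 50", call. = FALSE)
  }
  az <- abs(z)
  if (all(az == 0)) return(1)
  # at rate = 0.5 the flip rate only reaches 50% in the infinite-noise
  # limit; a scale vastly above the decision-variable range is as close
  # as floating point distinguishes
  if (rate == 0.5) return(1e9 * max(az))
  f <- function(log_sc) mean(stats::pnorm(-az / exp(log_sc))) - rate
  sol <- stats::uniroot(f, lower = log(1e-6 * max(az)),
                        upper = log(1e6 * max(az)), extendInt = "yes",
                        tol = 1e-10)
  exp(sol$root)
}

#' Wrap an existing response vector
#'
#' Accepts \{-1, +1\} or the \{1, 0\} yes/no coding (0 mapped to -1).
#'
#' @param values numeric vector of responses.
#' @param noise_sigma recorded noise level, if known.
#' @param seed recorded seed, if known.
#' @return an `rc_responses` object.
#' @export
response_vector <- function(values, noise_sigma = NA_real_,
                            seed = NA_integer_) {
  values <- as.numeric(values)
  if (all(values %in% c(0, 1))) values <- 2 * values - 1
  if (!all(values %in% c(-1, 1))) {
    stop("responses must be coded {-1, +1} or {1, 0}", call. = FALSE)
  }
  structure(
    list(values = values, noise_sigma = noise_sigma,
         mechanism = NA_character_, seed = seed),
    class = "rc_responses"
  )
}

#' @export
print.rc_responses <- function(x, ...) {
  cat(sprintf("<responses> %d trials, %.1f%% yes (sigma = %s)\n",
              length(x$values), 100 * mean(x$values > 0),
              ifelse(is.na(x$noise_sigma), "unknown", x$noise_sigma)))
  invisible(x)
}

#' @export
length.rc_responses <- function(x) length(x$values)
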