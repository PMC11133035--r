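#' Sparse logistic-regression reconstruction (GLM baseline)
#'
#' Comparator estimator: an L1-penalized logistic regression of the binary
#' responses on the DCT-transformed centered stimuli,
#' \deqn{\hat s = \arg\min_s \sum_i \log(1 + e^{-y_i (\Theta s)_i})
#'       + \lambda \|s\|_1,}
#' solved by proximal gradient descent (ISTA) with backtracking line
#' search, which guarantees a monotonically decreasing objective. The
#' products \eqn{\Theta s} and \eqn{\Theta^T r} are applied through the
#' fast separable DCT, so the sensing matrix is never materialized. The
#' pixel-domain reconstruction \eqn{\hat x = \Psi \hat s} is returned
#' unit-normalized for comparability with the compressive-sensing
#' estimator (both quality metrics are scale-invariant).
#'
#' @param stimuli an `rc_stimuli`.
#' @param responses an `rc_responses` of matching length.
#' @param lambda nonnegative L1 penalty weight.
#' @param spec a [basis_spec()]; defaults to the stimulus shape.
#' @param max_iter iteration cap (non-convergence is flagged, not fatal).
#' @param tol relative objective-change convergence tolerance.
#' @return a list with components `fit` (class `rc_glm_fit`: `s_glm`,
#'   `lambda_glm`, `converged`, `n_iter`, `objective`) and
#'   `reconstruction` (class `rc_reconstruction`, `method = "glm"`).
#' @export
glm_reconstruct <- function(stimuli, responses, lambda, spec = NULL,
                            max_iter = 5000, tol = 1e-6) {
  check_pair(stimuli, responses)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0) {
    stop("lambda must be a single nonnegative number", call. = FALSE)
  }
  if (is.null(spec)) spec <- basis_spec(stimuli$shape[1], stimuli$shape[2])
  if (spec$m != stimuli$m) {
    stop("basis spec does not match stimulus dimension", call. = FALSE)
  }
  y <- responses$values
  phic <- stimuli$matrix - stimulus_center(stimuli, stimuli$m)
  A <- function(s) drop(phic %*% inverse_coefficients(s, spec))
  At <- function(r) forward_coefficients(drop(crossprod(phic, r)), spec)

  loglik_loss <- function(eta) sum(log1p_exp(-y * eta))
  objective <- function(s, eta) loglik_loss(eta) + lambda * sum(abs(s))

  s <- numeric(spec$m)
  eta <- A(s)
  f_curr <- loglik_loss(eta)
  obj_curr <- f_curr  # ||0||_1 = 0
  # 1/L with L ~ sigma_max(Theta)^2 / 4; random-matrix estimate of the
  # largest singular value of the centered binary stimulus matrix
  step <- 16 / (sqrt(stimuli$l) + sqrt(stimuli$m))^2
  converged <- FALSE
  it <- 0
  obj_trace <- numeric(0)
  while (it < max_iter) {
    it <- it + 1
    g <- At(-y * stats::plogis(-y * eta))
    # backtracking proximal step
    repeat {
      s_new <- soft_shrink(s - step * g, step * lambda)
      d <- s_new - s
      eta_new <- A(s_new)
      f_new <- loglik_loss(eta_new)
      if (f_new <= f_curr + sum(g * d) + sum(d^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-14) break
    }
    obj_new <- f_new + lambda * sum(abs(s_new))
    obj_trace <- c(obj_trace, obj_new)
    rel <- abs(obj_curr - obj_new) / max(1e-12, abs(obj_curr))
    s <- s_new
    eta <- eta_new
    f_curr <- f_new
    obj_curr <- obj_new
    if (rel < tol) {
      converged <- TRUE
      break
    }
    step <- step * 1.5  # allow the step to grow back between iterations
  }
  if (!converged) {
    warning("proximal gradient did not converge in ", max_iter,
            " iterations (relative change ", signif(rel, 3), ")",
            call. = FALSE)
  }
  x_hat <- inverse_coefficients(s, spec)
  nrm <- sqrt(sum(x_hat^2))
  if (nrm > 0) x_hat <- x_hat / nrm
  fit <- structure(
    list(s_glm = s, lambda_glm = lambda, converged = converged,
         n_iter = it, objective = obj_curr, objective_trace = obj_trace),
    class = "rc_glm_fit"
  )
  rec <- new_reconstruction(x_hat, stimuli$shape, "glm",
                            n_used = stimuli$l,
                            provenance = list(lambda = lambda,
                                              converged = converged,
                                              seed = stimuli$seed))
  list(fit = fit, reconstruction = rec)
}

#' @export
print.rc_glm_fit <- function(x, ...) {
  cat(sprintf(
    "<glm fit> lambda = %.4g, %d nonzero weights, %s in %d iterations\n",
    x$lambda_glm, sum(x$s_glm != 0),
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

# Elementwise soft shrinkage by a fixed threshold.
soft_shrink <- function(v, thr) {
  sign(v) * pmax(abs(v) - thr, 0)
}

# Numerically stable log(1 + exp(u)).
log1p_exp <- function(u) {
  out <- u
  small <- u < 30
  out[small] <- log1p(exp(u[small]))
  out[!small] <- u[!small] + exp(-u[!small])
  out
}

#' Select the GLM penalty by held-out prediction accuracy
#'
#' Mirrors the sparsity-selection protocol used for the compressive-
#' sensing estimator: fit the GLM at each penalty on a simulated training
#' set, score balanced prediction accuracy on freshly simulated held-out
#' sets, and pick the penalty with the best mean accuracy (ties toward the
#' larger, more parsimonious penalty).
#'
#' @param template the generating [new_template()].
#' @param n number of training trials.
#' @param noise a [noise_spec()].
#' @param grid numeric vector of candidate penalties (e.g. log-spaced).
#' @param n_heldout_sets number of fresh evaluation sets.
#' @param heldout_n trials per held-out set (default `n`).
#' @param seed base seed; held-out set `i` uses `seed + i`.
#' @return a list with `grid`, `mean_accuracy`, `best_lambda`,
#'   `per_set_accuracy`.
#' @export
select_lambda_heldout <- function(template, n, noise = noise_spec(0),
                                  grid = 10^seq(-2, 2, length.out = 9),
                                  n_heldout_sets = 8, heldout_n = n,
                                  seed = 1) {
  stopifnot(inherits(template, "rc_template"))
  shape <- template$shape
  train_phi <- generate_stimuli(n, shape, seed = seed)
  train_y <- simulate_responses(template, train_phi, noise, seed = seed)
  recs <- lapply(grid, function(lam) {
    glm_reconstruct(train_phi, train_y, lambda = lam)$reconstruction
  })
  acc <- heldout_accuracy_matrix(recs, template, shape, noise,
                                 n_heldout_sets, heldout_n, seed)
  mean_acc <- colMeans(acc)
  best <- which(mean_acc == max(mean_acc, na.rm = TRUE))
  best_lambda <- max(grid[best])
  list(grid = grid, mean_accuracy = mean_acc, best_lambda = best_lambda,
       per_set_accuracy = acc)
}

# Score a list of reconstructions on freshly simulated held-out sets;
# returns an n_sets x length(recs) accuracy matrix. Shared by the gamma
# and lambda selection protocols.
heldout_accuracy_matrix <- function(recs, template, shape, noise,
                                    n_sets, heldout_n, seed) {
  acc <- matrix(NA_real_, n_sets, length(recs))
  for (s in seq_len(n_sets)) {
    hp <- generate_stimuli(heldout_n, shape, seed = seed + s)
    hy <- simulate_responses(template, hp, noise, seed = seed + s)
    for (j in seq_along(recs)) {
      if (is.null(recs[[j]])) next
      pred <- predict_responses(recs[[j]], hp)
      acc[s, j] <- balanced_accuracy(pred, hy)
    }
  }
  acc
}
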