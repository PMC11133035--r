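#' Squared correlation between a reconstruction and the template
#'
#' The simulation-only quality metric: the squared Pearson correlation
#' between the vectorized reconstruction and the vectorized ground-truth
#' template. Invariant to affine rescaling of either argument; note that a
#' sign-flipped reconstruction also scores 1 (r = -1). The signed
#' correlation is attached as attribute `"r"` for callers that care about
#' polarity.
#'
#' @param x_hat an `rc_reconstruction`, template, matrix or pixel vector.
#' @param template the ground-truth [new_template()] (or matrix/vector).
#' @return the squared correlation in \[0, 1\], with attribute `"r"`.
#' @export
template_r2 <- function(x_hat, template) {
  a <- as_pixel_vector(x_hat)
  b <- as_pixel_vector(template, m = length(a))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: constant input image", call. = FALSE)
  }
  r <- stats::cor(a, b)
  structure(r^2, r = r)
}

#' Predict responses from a reconstruction
#'
#' Applies the observer's decision rule with the reconstruction standing
#' in for the latent template: the sign of the centered inner product, with
#' no decision noise (predictions are deterministic given the stimuli).
#'
#' @param x_hat an `rc_reconstruction` (or template/matrix/vector).
#' @param stimuli an `rc_stimuli` of matching pixel dimension.
#' @return an `rc_responses` of predicted responses in \{-1, +1\}.
#' @export
predict_responses <- function(x_hat, stimuli) {
  stopifnot(inherits(stimuli, "rc_stimuli"))
  v <- as_pixel_vector(x_hat, m = stimuli$m)
  z <- decision_variable(stimuli, v)
  response_vector(sign_pos(z), noise_sigma = 0)
}

#' Balanced accuracy of predicted responses
#'
#' The mean of the true-positive rate (sensitivity over actual "yes") and
#' true-negative rate (specificity over actual "no"). Insensitive to class
#' imbalance: duplicating every "yes" trial leaves it unchanged.
#'
#' @param predicted,actual `rc_responses` objects (or \{-1, +1\} /
#'   \{1, 0\} vectors) of equal length; `actual` must contain both classes.
#' @return a number in \[0, 1\].
#' @export
balanced_accuracy <- function(predicted, actual) {
  p <- response_values(predicted)
  a <- response_values(actual)
  if (length(p) != length(a)) {
    stop("predicted and actual response vectors differ in length",
         call. = FALSE)
  }
  if (!any(a > 0)) stop("actual responses contain no 'yes' (+1) trials",
                        call. = FALSE)
  if (!any(a < 0)) stop("actual responses contain no 'no' (-1) trials",
                        call. = FALSE)
  tpr <- mean(p[a > 0] > 0)
  tnr <- mean(p[a < 0] < 0)
  (tpr + tnr) / 2
}

response_values <- function(y) {
  if (inherits(y, "rc_responses")) return(y$values)
  response_vector(y)$values
}

#' Cross-validated response prediction
#'
#' The response-prediction validation protocol: split the trials into `k`
#' folds, fit the requested estimator on `k - 1` folds, predict the
#' held-out fold with [predict_responses()], pool all held-out predictions,
#' and report their balanced accuracy against the actual responses. This is
#' the only quality assessment available when the true template is unknown
#' (i.e., for real observers).
#'
#' Folds are a seeded random partition by default; `contiguous = TRUE`
#' instead assigns contiguous blocks of trials in presentation order. A
#' fold whose actual responses are single-class is flagged in `per_fold`
#' (its accuracy recorded as `NA`) but its predictions still enter the
#' pooled metric.
#'
#' @param stimuli an `rc_stimuli`.
#' @param responses an `rc_responses` of matching length.
#' @param method `"revcorr"`, `"cs"` or `"glm"`.
#' @param k number of folds, between 2 and the number of trials.
#' @param method_params list of extra arguments for the estimator (e.g.
#'   `list(gamma = 64)` for `"cs"`, `list(lambda = 1)` for `"glm"`).
#' @param seed seed for the fold assignment.
#' @param contiguous use contiguous blocks instead of a random partition.
#' @return an object of class `rc_quality` with fields
#'   `balanced_accuracy` (pooled), `per_fold`, `folds`, `n_eval`, `method`.
#' @export
kfold_prediction_cv <- function(stimuli, responses,
                                method = c("revcorr", "cs", "glm"),
                                k = 5, method_params = list(),
                                seed = NULL, contiguous = FALSE) {
  method <- match.arg(method)
  check_pair(stimuli, responses)
  l <- stimuli$l
  if (k < 2 || k > l) stop("k must satisfy 2 <= k <= number of trials",
                           call. = FALSE)
  fold_id <- make_folds(l, k, seed = seed, contiguous = contiguous)
  pred <- numeric(l)
  per_fold <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    fit <- fit_method(method, subset_stimuli(stimuli, train_idx),
                      subset_responses(responses, train_idx),
                      method_params)
    pf <- predict_responses(fit, subset_stimuli(stimuli, test_idx))$values
    pred[test_idx] <- pf
    actual_f <- responses$values[test_idx]
    if (any(actual_f > 0) && any(actual_f < 0)) {
      per_fold[f] <- balanced_accuracy(pf, actual_f)
    }
  }
  structure(
    list(balanced_accuracy = balanced_accuracy(pred, responses$values),
         per_fold = per_fold, folds = k, n_eval = l, method = method),
    class = "rc_quality"
  )
}

#' @export
print.rc_quality <- function(x, ...) {
  cat(sprintf(
    "<quality> pooled balanced accuracy %.3f (%s, %d folds, %d trials)\n",
    x$balanced_accuracy, x$method, x$folds, x$n_eval))
  invisible(x)
}

# Shared dispatcher so CV and model selection fit estimators uniformly.
fit_method <- function(method, stimuli, responses, params = list()) {
  switch(method,
    revcorr = do.call(revcorr_reconstruct,
                      c(list(stimuli, responses), params)),
    cs = {
      if (is.null(params$gamma)) params$gamma <- 64L
      do.call(cs_reconstruct,
              c(list(stimuli, responses), params))$reconstruction
    },
    glm = {
      if (is.null(params$lambda)) params$lambda <- 1
      do.call(glm_reconstruct,
              c(list(stimuli, responses), params))$reconstruction
    },
    stop("unknown method '", method, "'", call. = FALSE)
  )
}

make_folds <- function(l, k, seed = NULL, contiguous = FALSE) {
  base <- rep(seq_len(k), length.out = l)
  if (contiguous) {
    sort(base)
  } else {
    local_seed(seed)
    sample(base)
  }
}

subset_stimuli <- function(stimuli, idx) {
  structure(
    list(matrix = stimuli$matrix[idx, , drop = FALSE],
         shape = stimuli$shape, l = length(idx), m = stimuli$m,
         seed = stimuli$seed),
    class = "rc_stimuli"
  )
}

subset_responses <- function(responses, idx) {
  structure(
    list(values = responses$values[idx],
         noise_sigma = responses$noise_sigma,
         mechanism = responses$mechanism, seed = responses$seed),
    class = "rc_responses"
  )
}

#' Paired test on per-subject accuracies
#'
#' Convenience wrapper around a standard paired t test for comparing two
#' methods' balanced accuracies across subjects. This is ordinary
#' inferential machinery, not part of the reconstruction method itself.
#'
#' @param acc_a,acc_b numeric vectors of per-subject accuracies, paired.
#' @return the `htest` object from [stats::t.test()].
#' @export
accuracy_paired_test <- function(acc_a, acc_b) {
  stats::t.test(acc_a, acc_b, paired = TRUE)
}
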