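#' Default sparsity grids
#'
#' Powers of two used for selecting the sparsity level: the simulation
#' protocol searches up to 2048, the human-data protocol up to 1024.
#'
#' @name gamma_grids
#' @export
gamma_grid_simulation <- function() 2^(1:11)

#' @rdname gamma_grids
#' @export
gamma_grid_human <- function() 2^(1:10)

#' Select the sparsity level by held-out prediction accuracy
#'
#' The simulation-study protocol for choosing `gamma`: simulate one
#' training set of `n` stimulus-response pairs from the template, fit the
#' compressive-sensing estimator once per candidate `gamma`, then score
#' each fit's balanced prediction accuracy on `n_heldout_sets` freshly
#' simulated stimulus-response sets drawn from the same template and
#' noise model. The selected `gamma` maximizes the mean accuracy across
#' held-out sets; ties break toward the smaller (more parsimonious) value.
#' A `gamma` whose fit is degenerate is recorded as failed and excluded
#' from the argmax rather than scored zero.
#'
#' @param template the generating [new_template()].
#' @param n number of training trials.
#' @param noise a [noise_spec()].
#' @param grid integer vector of candidate sparsity levels.
#' @param n_heldout_sets number of fresh evaluation sets (default 8).
#' @param heldout_n trials per held-out set; defaults to `n`.
#' @param seed base seed: the training set uses `seed`, held-out set `i`
#'   uses `seed + i`.
#' @param mode thresholding mode for [cs_reconstruct()].
#' @return an object of class `rc_gamma_search` with fields `grid`,
#'   `mean_accuracy`, `best_gamma`, `per_set_accuracy`
#'   (`n_heldout_sets x length(grid)`), `failed` (logical per grid point).
#' @export
select_gamma_heldout <- function(template, n, noise = noise_spec(0),
                                 grid = gamma_grid_simulation(),
                                 n_heldout_sets = 8, heldout_n = n,
                                 seed = 1, mode = "soft") {
  stopifnot(inherits(template, "rc_template"))
  if (length(grid) < 1 || any(grid < 1)) {
    stop("grid must be a nonempty vector of sparsity levels >= 1",
         call. = FALSE)
  }
  shape <- template$shape
  train_phi <- generate_stimuli(n, shape, seed = seed)
  train_y <- simulate_responses(template, train_phi, noise, seed = seed)
  recs <- lapply(grid, function(g) {
    tryCatch(
      cs_reconstruct(train_phi, train_y, gamma = g, mode = mode)$reconstruction,
      error = function(e) NULL
    )
  })
  failed <- vapply(recs, is.null, logical(1))
  acc <- heldout_accuracy_matrix(recs, template, shape, noise,
                                 n_heldout_sets, heldout_n, seed)
  mean_acc <- colMeans(acc)
  if (all(failed)) {
    stop("all candidate gamma values produced degenerate fits",
         call. = FALSE)
  }
  ok <- which(!failed & !is.na(mean_acc))
  top <- ok[mean_acc[ok] == max(mean_acc[ok])]
  best_gamma <- min(grid[top])  # ties resolve to the smaller gamma
  structure(
    list(grid = grid, mean_accuracy = mean_acc,
         best_gamma = as.integer(best_gamma),
         per_set_accuracy = acc, failed = failed,
         n = n, noise = noise, seed = seed),
    class = "rc_gamma_search"
  )
}

#' @export
print.rc_gamma_search <- function(x, ...) {
  cat("<gamma search> best gamma =", x$best_gamma, "\n")
  tab <- data.frame(gamma = x$grid,
                    mean_accuracy = round(x$mean_accuracy, 4),
                    failed = x$failed)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Select the sparsity level by nested cross-validation
#'
#' The protocol for real observer data, where no generative template is
#' available to simulate held-out sets: the trials are split into
#' `k_outer` slices (seeded random assignment). In each rotation one slice
#' is the test slice, the next slice is the validation slice, and the
#' remaining `k_outer - 2` slices are the training set. The estimator is
#' fit on the training set at each candidate `gamma`, the `gamma` with the
#' best balanced prediction accuracy on the validation slice is that
#' fold's winner (ties toward smaller `gamma`), and its accuracy on the
#' untouched test slice is recorded. The final selection is the modal
#' per-fold winner (ties in the mode again toward smaller `gamma`). Test
#' responses are never consulted during selection; the optional `.trace`
#' hook receives `(fold, stage, indices)` for every data access so this
#' can be audited.
#'
#' @param stimuli an `rc_stimuli`.
#' @param responses an `rc_responses` of matching length.
#' @param grid integer vector of candidate sparsity levels.
#' @param k_outer number of outer slices, at least 3 (default 10).
#' @param seed seed for the slice assignment.
#' @param mode thresholding mode for [cs_reconstruct()].
#' @param .trace optional function `(fold, stage, indices)` called with
#'   the trial indices used at each stage (`"train"`, `"validate"`,
#'   `"test"`); for instrumentation only.
#' @return a list with `per_fold_gamma`, `per_fold_test_accuracy`,
#'   `modal_gamma`, `grid`, `k_outer`.
#' @export
select_gamma_nested_cv <- function(stimuli, responses,
                                   grid = gamma_grid_human(),
                                   k_outer = 10, seed = NULL,
                                   mode = "soft", .trace = NULL) {
  check_pair(stimuli, responses)
  if (k_outer < 3 || k_outer > stimuli$l) {
    stop("k_outer must satisfy 3 <= k_outer <= number of trials",
         call. = FALSE)
  }
  slice <- make_folds(stimuli$l, k_outer, seed = seed)
  per_fold_gamma <- rep(NA_integer_, k_outer)
  per_fold_acc <- rep(NA_real_, k_outer)
  for (f in seq_len(k_outer)) {
    test_idx <- which(slice == f)
    val_slice <- if (f == k_outer) 1L else f + 1L
    val_idx <- which(slice == val_slice)
    train_idx <- which(slice != f & slice != val_slice)
    if (!is.null(.trace)) {
      .trace(f, "train", train_idx)
      .trace(f, "validate", val_idx)
    }
    tr_phi <- subset_stimuli(stimuli, train_idx)
    tr_y <- subset_responses(responses, train_idx)
    val_phi <- subset_stimuli(stimuli, val_idx)
    val_y <- responses$values[val_idx]
    val_acc <- rep(NA_real_, length(grid))
    recs <- vector("list", length(grid))
    for (j in seq_along(grid)) {
      recs[[j]] <- tryCatch(
        cs_reconstruct(tr_phi, tr_y, gamma = grid[j],
                       mode = mode)$reconstruction,
        error = function(e) NULL
      )
      if (is.null(recs[[j]])) next
      pred <- predict_responses(recs[[j]], val_phi)$values
      if (any(val_y > 0) && any(val_y < 0)) {
        val_acc[j] <- balanced_accuracy(pred, val_y)
      }
    }
    if (all(is.na(val_acc))) next  # fold unusable, recorded as NA
    cand <- which(val_acc == max(val_acc, na.rm = TRUE))
    jbest <- cand[which.min(grid[cand])]  # ties toward smaller gamma
    per_fold_gamma[f] <- as.integer(grid[jbest])
    if (!is.null(.trace)) .trace(f, "test", test_idx)
    test_y <- responses$values[test_idx]
    pred_test <- predict_responses(recs[[jbest]],
                                   subset_stimuli(stimuli, test_idx))$values
    if (any(test_y > 0) && any(test_y < 0)) {
      per_fold_acc[f] <- balanced_accuracy(pred_test, test_y)
    }
  }
  winners <- per_fold_gamma[!is.na(per_fold_gamma)]
  if (length(winners) == 0) {
    stop("no fold produced a usable gamma selection", call. = FALSE)
  }
  counts <- table(winners)
  top <- as.integer(names(counts)[counts == max(counts)])
  list(per_fold_gamma = per_fold_gamma,
       per_fold_test_accuracy = per_fold_acc,
       modal_gamma = min(top), grid = grid, k_outer = k_outer)
}
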