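#' Configure a simulation experiment grid
#'
#' Describes a full simulated-observer study: for every combination of
#' estimation method, number of trials and observer noise level, run
#' seeded replicate simulations and score each reconstruction against the
#' generating template (r-squared) and on a freshly simulated test set
#' (balanced prediction accuracy). The canonical study uses the 50 x 50
#' letter-"s" template, trial counts \{1250, 2500, 5000, 10000, 20000\},
#' noise levels sigma in \{0, 25, 50\} percent, and 10 replicates per
#' cell.
#'
#' @param template_label `"S"`, `"K"`, `"dot"`, or any single character.
#' @param sample_sizes integer vector of trial counts.
#' @param sigmas noise levels in percent, each in \[0, 100\].
#' @param replicates replicate simulations per cell (>= 1).
#' @param methods subset of `c("revcorr", "cs", "glm")`.
#' @param gamma sparsity policy for `"cs"`: a fixed integer (default 64)
#'   or `"searched"` to run [select_gamma_heldout()] per cell.
#' @param glm_lambda penalty for the `"glm"` method.
#' @param noise_mechanism how `sigmas` are realized: `"flip"` (percent of
#'   responses negated uniformly at random), `"gaussian_calibrated"`
#'   (additive decision noise calibrated to `sigma` percent errors) or
#'   `"gaussian_raw"` (additive decision noise of variance `sigma`, the
#'   literal internal-noise model; the choice that keeps responses
#'   informative at large `sigma`).
#' @param shape template/stimulus shape.
#' @param test_n trials in the fresh test set used for prediction
#'   accuracy.
#' @param seed base seed; replicate `r` of each cell derives its seed
#'   from `seed`, the cell index and `r`.
#' @return an object of class `rc_experiment_config` (a validated list).
#' @export
experiment_config <- function(template_label = "S",
                              sample_sizes = c(1250, 2500, 5000, 10000, 20000),
                              sigmas = c(0, 25, 50),
                              replicates = 10,
                              methods = c("revcorr", "cs"),
                              gamma = 64,
                              glm_lambda = 1,
                              noise_mechanism = c("flip",
                                                  "gaussian_calibrated",
                                                  "gaussian_raw"),
                              shape = c(50, 50),
                              test_n = 2000,
                              seed = 1) {
  methods <- match.arg(methods, c("revcorr", "cs", "glm"),
                       several.ok = TRUE)
  noise_mechanism <- match.arg(noise_mechanism)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (any(sample_sizes < 1)) stop("sample_sizes must be >= 1", call. = FALSE)
  if (any(sigmas < 0 | sigmas > 100)) {
    stop("sigmas must lie in [0, 100]", call. = FALSE)
  }
  searched <- identical(gamma, "searched")
  if (!searched && (!is.numeric(gamma) || gamma < 1)) {
    stop("gamma must be a positive integer or \"searched\"", call. = FALSE)
  }
  structure(
    list(template_label = template_label,
         sample_sizes = as.integer(sample_sizes),
         sigmas = sigmas, replicates = as.integer(replicates),
         methods = methods, gamma = gamma, gamma_searched = searched,
         glm_lambda = glm_lambda, noise_mechanism = noise_mechanism,
         shape = check_shape(shape),
         test_n = as.integer(test_n), seed = as.integer(seed)),
    class = "rc_experiment_config"
  )
}

#' Run a simulation experiment grid
#'
#' Executes the study described by an [experiment_config()]. Each row of
#' the result is one method x n x sigma x replicate cell; failures in a
#' cell are recorded (`ok = FALSE` with the error message) and the run
#' continues. Identical configs and seeds reproduce identical tables.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-cell progress to stderr.
#' @return a `data.frame` with columns `method`, `n`, `sigma`, `replicate`,
#'   `r2`, `balanced_accuracy`, `gamma`, `seed`, `ok`, `note`.
#' @export
run_grid <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "rc_experiment_config"))
  template <- config_template(config)
  rows <- list()
  cell <- 0L
  for (n in config$sample_sizes) {
    for (sigma in config$sigmas) {
      cell <- cell + 1L
      noise <- switch(config$noise_mechanism,
        flip = noise_spec(sigma),
        gaussian_calibrated = noise_spec(sigma, "additive_gaussian"),
        gaussian_raw = noise_spec(sigma, "additive_gaussian",
                                  calibrate = FALSE))
      gamma_cell <- if (config$gamma_searched) {
        select_gamma_heldout(template, n, noise,
                             seed = config$seed + 100000L * cell)$best_gamma
      } else {
        as.integer(config$gamma)
      }
      for (r in seq_len(config$replicates)) {
        rep_seed <- config$seed + 1000L * cell + r
        phi <- generate_stimuli(n, config$shape, seed = rep_seed)
        y <- simulate_responses(template, phi, noise, seed = rep_seed)
        test_phi <- generate_stimuli(config$test_n, config$shape,
                                     seed = rep_seed + 500L)
        test_y <- simulate_responses(template, test_phi, noise,
                                     seed = rep_seed + 500L)
        for (method in config$methods) {
          if (verbose) {
            message(sprintf("n=%d sigma=%g rep=%d method=%s",
                            n, sigma, r, method))
          }
          params <- switch(method,
                           cs = list(gamma = gamma_cell),
                           glm = list(lambda = config$glm_lambda),
                           list())
          row <- tryCatch({
            rec <- fit_method(method, phi, y, params)
            pred <- predict_responses(rec, test_phi)
            data.frame(method = method, n = n, sigma = sigma,
                       replicate = r,
                       r2 = as.numeric(template_r2(rec, template)),
                       balanced_accuracy =
                         balanced_accuracy(pred, test_y),
                       gamma = if (method == "cs") gamma_cell else NA_integer_,
                       seed = rep_seed, ok = TRUE, note = "")
          }, error = function(e) {
            data.frame(method = method, n = n, sigma = sigma,
                       replicate = r, r2 = NA_real_,
                       balanced_accuracy = NA_real_,
                       gamma = if (method == "cs") gamma_cell else NA_integer_,
                       seed = rep_seed, ok = FALSE,
                       note = conditionMessage(e))
          })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Resolve the config's template label to a template object.
config_template <- function(config) {
  lab <- config$template_label
  if (identical(lab, "dot")) {
    make_dot_template(config$shape)
  } else {
    make_letter_template(lab, config$shape)
  }
}

#' Summarize a grid run with means and 95% confidence intervals
#'
#' Collapses replicates within each method x n x sigma cell to the mean
#' and a Student-t 95% confidence interval.
#'
#' @param results the `data.frame` from [run_grid()].
#' @param metric `"r2"` or `"balanced_accuracy"`.
#' @return a `data.frame` with one row per cell: `method`, `n`, `sigma`,
#'   `mean`, `ci_lo`, `ci_hi`, `replicates`.
#' @export
summarize_grid <- function(results, metric = c("r2", "balanced_accuracy")) {
  metric <- match.arg(metric)
  ok <- results[results$ok & !is.na(results[[metric]]), ]
  cells <- unique(ok[c("method", "n", "sigma")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- ok$method == cells$method[i] & ok$n == cells$n[i] &
      ok$sigma == cells$sigma[i]
    v <- ok[[metric]][sel]
    ci <- if (length(v) > 1 && stats::sd(v) > 0) {
      stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v))
    } else {
      0
    }
    data.frame(method = cells$method[i], n = cells$n[i],
               sigma = cells$sigma[i], mean = mean(v),
               ci_lo = mean(v) - ci, ci_hi = mean(v) + ci,
               replicates = length(v))
  })
  out <- do.call(rbind, out)
  out[order(out$method, out$sigma, out$n), ]
}

#' Subsampling efficiency comparison
#'
#' The trial-efficiency demonstration: simulate `n_full` noiseless
#' stimulus-response pairs from a template, reconstruct by reverse
#' correlation on all pairs and by compressive sensing on a uniformly
#' subsampled `fraction` of the pairs (without replacement), and compare
#' the two reconstructions' template r-squared. If the subsample happens
#' to contain only one response class it is redrawn with an incremented
#' seed (recorded in `redraws`).
#'
#' @param template an [new_template()] (default: the 50 x 50 letter "s").
#' @param n_full total simulated trials.
#' @param fraction fraction of trials given to the CS estimator, in
#'   (0, 1\].
#' @param gamma sparsity level for the CS estimator.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @return a list with `r2_revcorr_full`, `r2_cs_subsample`, `ratio`
#'   (CS / revcorr), `n_full`, `n_subsample`, `gamma`, `seed`, `redraws`.
#' @export
run_subsample_comparison <- function(template = make_letter_template("S"),
                                     n_full = 10000, fraction = 0.1,
                                     gamma = 64, noise = noise_spec(0),
                                     seed = 1) {
  stopifnot(inherits(template, "rc_template"))
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  phi <- generate_stimuli(n_full, template$shape, seed = seed)
  y <- simulate_responses(template, phi, noise, seed = seed)
  n_sub <- max(1L, round(fraction * n_full))
  redraws <- 0L
  repeat {
    local_seed(seed + 7919L * (redraws + 1L))
    idx <- sort(sample.int(n_full, n_sub))
    ys <- y$values[idx]
    if (any(ys > 0) && any(ys < 0)) break
    redraws <- redraws + 1L
    if (redraws > 100L) {
      stop("subsample never contained both response classes", call. = FALSE)
    }
  }
  rec_rc <- revcorr_reconstruct(phi, y)
  rec_cs <- cs_reconstruct(subset_stimuli(phi, idx),
                           subset_responses(y, idx),
                           gamma = gamma)$reconstruction
  r2_rc <- as.numeric(template_r2(rec_rc, template))
  r2_cs <- as.numeric(template_r2(rec_cs, template))
  list(r2_revcorr_full = r2_rc, r2_cs_subsample = r2_cs,
       ratio = r2_cs / r2_rc, n_full = n_full, n_subsample = n_sub,
       gamma = gamma, seed = seed, redraws = redraws)
}
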