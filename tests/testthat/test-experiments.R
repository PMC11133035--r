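quick_config <- function(replicates = 2, seed = 1) {
  experiment_config(template_label = "dot",
                    sample_sizes = c(200, 500),
                    sigmas = c(0, 50),
                    replicates = replicates,
                    methods = c("revcorr", "cs"),
                    gamma = 16,
                    shape = c(10, 10),
                    test_n = 400,
                    seed = seed)
}

test_that("a grid run has one row per method x n x sigma x replicate", {
  res <- run_grid(quick_config())
  expect_equal(nrow(res), 2 * 2 * 2 * 2)
  expect_setequal(unique(res$method), c("revcorr", "cs"))
  expect_true(all(res$ok))
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
  expect_true(all(res$balanced_accuracy >= 0 & res$balanced_accuracy <= 1))
  expect_true(all(is.na(res$gamma[res$method == "revcorr"])))
  expect_true(all(res$gamma[res$method == "cs"] == 16))
})

test_that("grid runs are bit-reproducible under a fixed seed", {
  expect_identical(run_grid(quick_config(seed = 9)),
                   run_grid(quick_config(seed = 9)))
})

test_that("noise lowers reconstruction quality", {
  res <- run_grid(quick_config(replicates = 4))
  s <- summarize_grid(res, "r2")
  for (method in c("revcorr", "cs")) {
    clean <- s$mean[s$method == method & s$sigma == 0 & s$n == 500]
    noisy <- s$mean[s$method == method & s$sigma == 50 & s$n == 500]
    expect_lt(noisy, clean)
  }
})

test_that("confidence intervals tighten with more replicates", {
  width <- function(replicates) {
    cfg <- experiment_config(template_label = "dot",
                             sample_sizes = 400, sigmas = 25,
                             replicates = replicates, methods = "revcorr",
                             shape = c(8, 8), test_n = 300, seed = 77)
    s <- summarize_grid(run_grid(cfg), "r2")
    s$ci_hi - s$ci_lo
  }
  expect_lt(width(12), width(3))
})

test_that("searched gamma policy runs the held-out grid search", {
  cfg <- experiment_config(template_label = "dot", sample_sizes = 300,
                           sigmas = 0, replicates = 1, methods = "cs",
                           gamma = "searched", shape = c(6, 6),
                           test_n = 200, seed = 31)
  res <- run_grid(cfg)
  expect_true(res$gamma %in% gamma_grid_simulation())
})

test_that("subsampling comparison reports both estimates and their ratio", {
  tpl <- make_dot_template(c(10, 10), c(5, 5), 3)
  out <- run_subsample_comparison(tpl, n_full = 2000, fraction = 0.25,
                                  gamma = 16, seed = 41)
  expect_equal(out$n_subsample, 500)
  expect_equal(out$ratio, out$r2_cs_subsample / out$r2_revcorr_full)

  # degenerate comparison: both methods see the full sample
  full <- run_subsample_comparison(tpl, n_full = 1000, fraction = 1,
                                   gamma = 16, seed = 42)
  expect_equal(full$n_subsample, 1000)

  # starving the subsample degrades the CS estimate
  tiny <- mean(vapply(1:5, function(s) run_subsample_comparison(
    tpl, n_full = 2000, fraction = 0.01, gamma = 16, seed = s)$r2_cs_subsample,
    numeric(1)))
  mid <- mean(vapply(1:5, function(s) run_subsample_comparison(
    tpl, n_full = 2000, fraction = 0.25, gamma = 16, seed = s)$r2_cs_subsample,
    numeric(1)))
  expect_lt(tiny, mid)
  expect_error(run_subsample_comparison(tpl, fraction = 0), "fraction")
})

test_that("stimulus-response tables round-trip through delimited text", {
  sim <- tiny_sim(l = 25, shape = c(4, 4), sigma = 25, seed = 51)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stimulus_response(sim$stimuli, sim$responses, f)
  back <- read_stimulus_response(f, c(4, 4))
  expect_equal(back$stimuli$matrix, sim$stimuli$matrix, ignore_attr = TRUE)
  expect_identical(back$responses$values, sim$responses$values)
  expect_error(read_stimulus_response(f, c(5, 5)), "columns")
})

test_that("templates and reconstructions round-trip with metadata", {
  tpl <- make_dot_template(c(6, 6), c(3, 3), 2)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_template_text(tpl, tf)
  expect_equal(read_template_text(tf)$pixels, tpl$pixels)

  pf <- withr::local_tempfile(fileext = ".png")
  write_template_png(tpl, pf)
  expect_true(file.exists(pf))

  sim <- tiny_sim(l = 200, shape = c(6, 6), seed = 52)
  fit <- cs_reconstruct(sim$stimuli, sim$responses, gamma = 6)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "rec")
  write_reconstruction(fit$reconstruction, prefix,
                       coefficients = fit$coefficients)
  img <- as.matrix(utils::read.table(paste0(prefix, ".txt")))
  expect_equal(unname(img), reconstruction_image(fit$reconstruction),
               tolerance = 1e-10)
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(meta$method, "cs")
  expect_equal(meta$gamma, 6)
  expect_equal(meta$basis$family, "dct2")
  expect_true(file.exists(paste0(prefix, ".png")))
  expect_true(file.exists(paste0(prefix, "_coef.txt")))
})
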