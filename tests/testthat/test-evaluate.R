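test_that("template r2 handles identity, negation and independence", {
  tpl <- make_dot_template(c(10, 10), c(5, 5), 3)
  expect_equal(as.numeric(template_r2(tpl, tpl)), 1.0)

  neg <- 1 - tpl$pixels
  r2 <- template_r2(neg, tpl)
  expect_equal(as.numeric(r2), 1.0)
  expect_equal(attr(r2, "r"), -1)

  set.seed(3)
  a <- rnorm(2500)
  b <- rnorm(2500)
  expect_lt(as.numeric(template_r2(a, b)), 0.01)

  # affine invariance
  x <- rnorm(100)
  y <- rnorm(100)
  expect_equal(as.numeric(template_r2(x, y)),
               as.numeric(template_r2(3.7 * x - 2, y)))

  expect_error(template_r2(rep(1, 100), rnorm(100)), "constant")
})

test_that("prediction from the true template reproduces noiseless responses", {
  sim <- tiny_sim(l = 400, shape = c(8, 8), seed = 81)
  pred <- predict_responses(sim$template, sim$stimuli)
  expect_identical(pred$values, sim$responses$values)
  # negated template inverts every prediction (away from exact ties,
  # where the fixed tie-break sends both signs to +1)
  xc <- template_vector(sim$template) -
    mean(template_vector(sim$template))
  z <- drop((sim$stimuli$matrix - 0.5) %*% xc)
  pred_neg <- predict_responses(-template_vector(sim$template),
                                sim$stimuli)
  nontie <- z != 0
  expect_true(any(nontie))
  expect_identical(pred_neg$values[nontie], -pred$values[nontie])
})

test_that("an estimated template predicts novel responses above chance", {
  tpl <- make_dot_template(c(12, 12), c(6, 6), 4)
  phi <- generate_stimuli(3000, c(12, 12), seed = 91)
  y <- simulate_responses(tpl, phi)
  rec <- revcorr_reconstruct(phi, y)
  fresh <- generate_stimuli(1500, c(12, 12), seed = 92)
  fresh_y <- simulate_responses(tpl, fresh)
  acc <- balanced_accuracy(predict_responses(rec, fresh), fresh_y)
  expect_gt(acc, 0.5)
})

test_that("balanced accuracy matches hand computations and is
          imbalance-invariant", {
  expect_equal(balanced_accuracy(c(1, -1, 1), c(1, -1, 1)), 1.0)

  # degenerate all-yes predictor on balanced classes
  expect_equal(balanced_accuracy(rep(1, 10), rep(c(1, -1), 5)), 0.5)

  # confusion table TP=3 FN=1 TN=2 FP=2 -> (3/4 + 2/4)/2
  actual <- c(1, 1, 1, 1, -1, -1, -1, -1)
  predicted <- c(1, 1, 1, -1, -1, -1, 1, 1)
  expect_equal(balanced_accuracy(predicted, actual), 0.625)

  # duplicating all yes trials changes nothing
  dup_p <- c(predicted, predicted[actual > 0])
  dup_a <- c(actual, actual[actual > 0])
  expect_equal(balanced_accuracy(dup_p, dup_a),
               balanced_accuracy(predicted, actual))

  expect_error(balanced_accuracy(c(1, -1), c(1, 1)), "no")
  expect_error(balanced_accuracy(c(1, -1), c(-1, -1)), "yes")
})

test_that("k-fold response prediction scores a strong simulated observer", {
  tpl <- make_letter_template("S", c(50, 50))
  phi <- generate_stimuli(10000, c(50, 50), seed = 101)
  y <- simulate_responses(tpl, phi)
  rep <- kfold_prediction_cv(phi, y, method = "revcorr", k = 5, seed = 1)
  # pooled accuracy ~0.81 at these conditions (the estimator, not the
  # oracle template, does the predicting): well above chance
  expect_gt(rep$balanced_accuracy, 0.78)
  expect_length(rep$per_fold, 5)
  expect_true(all(rep$per_fold > 0.7, na.rm = TRUE))
  # at sigma = 0 the oracle template predicts every response: the
  # estimator's CV accuracy cannot exceed it
  expect_equal(balanced_accuracy(predict_responses(tpl, phi), y), 1.0)
  expect_lte(rep$balanced_accuracy, 1.0)
})

test_that("leave-one-out on a toy set completes", {
  sim <- tiny_sim(l = 20, shape = c(3, 3), sigma = 25, seed = 111)
  rep <- kfold_prediction_cv(sim$stimuli, sim$responses,
                             method = "revcorr", k = 20, seed = 1)
  expect_gte(rep$balanced_accuracy, 0)
  expect_lte(rep$balanced_accuracy, 1)
  expect_error(kfold_prediction_cv(sim$stimuli, sim$responses, k = 21),
               "k must")
})

test_that("CV prefers compressive sensing under heavy response noise", {
  tpl <- make_letter_template("S", c(50, 50))
  heavy <- noise_spec(50, "additive_gaussian", calibrate = FALSE)
  wins <- 0
  reps <- 6
  for (r in seq_len(reps)) {
    phi <- generate_stimuli(4000, c(50, 50), seed = 120 + r)
    y <- simulate_responses(tpl, phi, heavy, seed = 120 + r)
    acc_cs <- kfold_prediction_cv(phi, y, method = "cs", k = 5,
                                  method_params = list(gamma = 64),
                                  seed = r)$balanced_accuracy
    acc_rc <- kfold_prediction_cv(phi, y, method = "revcorr", k = 5,
                                  seed = r)$balanced_accuracy
    if (acc_cs >= acc_rc) wins <- wins + 1
  }
  expect_gte(wins, reps - 1)
})

test_that("the paired accuracy test wraps a standard paired t test", {
  a <- c(0.61, 0.58, 0.63, 0.60, 0.62)
  b <- c(0.56, 0.55, 0.60, 0.58, 0.57)
  ht <- accuracy_paired_test(a, b)
  expect_s3_class(ht, "htest")
  expect_equal(unname(ht$p.value),
               unname(stats::t.test(a - b)$p.value))
})
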