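test_that("reverse correlation reproduces the hand-computed mean difference", {
  phi <- stimulus_set(rbind(c(1, 0), c(0, 1)), c(1, 2))
  y <- response_vector(c(1, -1))
  rec <- revcorr_reconstruct(phi, y)
  # centered stimuli are (.5,-.5) and (-.5,.5); mean(yes) - mean(no)
  expect_equal(rec$x_hat, c(1, -1))
  expect_equal(rec$method, "revcorr")
  expect_equal(rec$n_used, 2)
})

test_that("single-class responses fall back to the crossprod form", {
  phi <- generate_stimuli(20, c(2, 2), seed = 1)
  y <- response_vector(rep(1, 20))
  expect_warning(rec <- revcorr_reconstruct(phi, y), "identical")
  expect_equal(rec$x_hat, colSums(phi$matrix - 0.5) / 20,
               ignore_attr = TRUE)
})

test_that("the generalized-inverse form recovers a well-conditioned target", {
  sim <- tiny_sim(l = 3000, shape = c(4, 4), seed = 31)
  rec <- revcorr_reconstruct(sim$stimuli, sim$responses,
                             form = "generalized_inverse")
  expect_gt(as.numeric(template_r2(rec, sim$template)), 0.8)
})

test_that("top-gamma thresholding matches its worked examples", {
  hard <- soft_threshold_topk(c(3, -1, 2), 1, mode = "hard")
  expect_equal(hard$values, c(3, 0, 0))
  expect_equal(hard$lambda, 0)

  soft <- soft_threshold_topk(c(3, -1, 2), 1, mode = "soft")
  expect_equal(soft$values, c(1, 0, 0))
  expect_equal(soft$lambda, 2)

  noop <- soft_threshold_topk(c(3, -1, 2), 5, mode = "soft")
  expect_equal(noop$values, c(3, -1, 2))
  expect_equal(noop$lambda, 0)

  expect_error(soft_threshold_topk(c(0, 0), 1), "zero")
  expect_error(soft_threshold_topk(c(1, 2), 0), "gamma")
})

test_that("top-gamma support matches the exhaustive subset oracle", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    v <- round(rnorm(n), 2)
    v[v == 0] <- 0.01
    gamma <- sample(seq_len(n - 1), 1)
    got <- which(soft_threshold_topk(v, gamma, mode = "hard")$values != 0)
    expect_equal(sort(got), oracle_topk_support(v, gamma))
  }
})

test_that("soft survivors shrink by the (gamma+1)-th magnitude", {
  set.seed(78)
  v <- rnorm(30)
  for (gamma in c(1, 5, 15, 29)) {
    th <- soft_threshold_topk(v, gamma, mode = "soft")
    expect_equal(th$lambda, sort(abs(v), decreasing = TRUE)[gamma + 1])
    surv <- th$values != 0
    expect_lte(sum(surv), gamma)
    expect_equal(th$values[surv], sign(v[surv]) * (abs(v[surv]) - th$lambda))
  }
})

test_that("CS estimates are gamma-sparse, unit norm and scale invariant", {
  sim <- tiny_sim(l = 800, shape = c(6, 6), sigma = 25, seed = 51)
  for (gamma in c(1, 4, 12, 36)) {
    for (mode in c("soft", "hard")) {
      fit <- cs_reconstruct(sim$stimuli, sim$responses, gamma, mode = mode)
      expect_lte(sum(fit$coefficients$s_hat != 0), gamma)
      expect_lt(abs(sqrt(sum(fit$coefficients$s_hat^2)) - 1), 1e-8)
    }
  }
  # the m^-1 scalar is irrelevant after zeta-normalization: thresholding
  # then normalizing commutes with positive rescaling of the input
  set.seed(52)
  v <- rnorm(40)
  for (mode in c("soft", "hard")) {
    a <- soft_threshold_topk(v, 7, mode = mode)$values
    b <- soft_threshold_topk(v * 1234.5, 7, mode = mode)$values
    expect_lt(max(abs(a / sqrt(sum(a^2)) - b / sqrt(sum(b^2)))), 1e-8)
  }
})

test_that("gamma = m with hard thresholding is reverse correlation", {
  sim <- tiny_sim(l = 600, shape = c(5, 5), seed = 61)
  cs <- cs_reconstruct(sim$stimuli, sim$responses, gamma = 25,
                       mode = "hard")$reconstruction
  rc <- revcorr_reconstruct(sim$stimuli, sim$responses, form = "crossprod")
  cosine <- sum(cs$x_hat * rc$x_hat) /
    (sqrt(sum(cs$x_hat^2)) * sqrt(sum(rc$x_hat^2)))
  expect_lt(abs(cosine - 1), 1e-8)
})

test_that("a single-basis-function template is identified at gamma = 1", {
  spec <- basis_spec(8, 8)
  set.seed(71)
  indices <- sample(2:spec$m, 10)  # skip DC: centering removes it
  for (idx in indices) {
    tpl <- basis_function_template(spec, idx)
    phi <- generate_stimuli(4000, c(8, 8), seed = idx)
    y <- simulate_responses(tpl, phi)
    fit <- cs_reconstruct(phi, y, gamma = 1)
    expect_equal(which(fit$coefficients$s_hat != 0), idx)
  }
})

test_that("recovery improves with more trials for both estimators", {
  tpl <- make_dot_template(c(10, 10), c(5, 5), 3)
  r2 <- function(n, seed, method) {
    phi <- generate_stimuli(n, c(10, 10), seed = seed)
    y <- simulate_responses(tpl, phi)
    rec <- if (method == "cs") {
      cs_reconstruct(phi, y, gamma = 16)$reconstruction
    } else {
      revcorr_reconstruct(phi, y)
    }
    as.numeric(template_r2(rec, tpl))
  }
  for (method in c("revcorr", "cs")) {
    lo <- mean(vapply(1:8, function(s) r2(300, s, method), numeric(1)))
    hi <- mean(vapply(1:8, function(s) r2(1500, s, method), numeric(1)))
    expect_gt(hi, lo)
  }
})

test_that("degenerate CS inputs raise informative errors", {
  # complementary stimuli with equal responses back-project to zero
  phi <- stimulus_set(matrix(c(0, 1), 2, 4), c(2, 2))
  y <- response_vector(c(1, 1))
  expect_error(cs_reconstruct(phi, y, gamma = 2), "degenerate")
})
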