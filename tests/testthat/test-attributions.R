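# Oracle suite: every method has a closed form on a linear model, and the
# baseline methods satisfy completeness on ReLU networks.

lin_w <- c(1.5, -2, 0.5, 3, -1)

test_that("saliency matches the linear closed form", {
  net <- linear_net(lin_w, b = 0.3)
  with_seed(1, X <- matrix(rnorm(40 * 5), 40, 5))

  raw <- attr_saliency(net, X, global = FALSE)
  expect_equal(raw$A, matrix(lin_w, 40, 5, byrow = TRUE), tolerance = 1e-12,
               ignore_attr = TRUE)

  glob <- attr_saliency(net, X, global = TRUE)
  expect_equal(glob$A, sweep(X, 2, lin_w, "*"), tolerance = 1e-12,
               ignore_attr = TRUE)

  # constant model: all attributions zero
  zero_net <- linear_net(rep(0, 5), b = 2)
  expect_true(all(attr_saliency(zero_net, X)$A == 0))
})

test_that("integrated gradients is exact on linear models and at baseline", {
  net <- linear_net(lin_w)
  with_seed(2, X <- matrix(rnorm(30 * 5), 30, 5))
  b <- c(0, 1, 0, 2, 1)
  for (steps in c(1, 7, 50)) {
    ig <- attr_integrated_gradients(net, X, b, n_steps = steps)
    expect_equal(ig$A, sweep(sweep(X, 2, b), 2, lin_w, "*"),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # x = baseline: zero attribution
  Xb <- matrix(b, 4, 5, byrow = TRUE)
  expect_true(all(abs(attr_integrated_gradients(net, Xb, b)$A) < 1e-12))
  expect_error(attr_integrated_gradients(net, X, b, n_steps = 0),
               class = "ab_config_error")
})

test_that("deeplift equals the linear closed form and is zero at baseline", {
  net <- linear_net(lin_w, b = -1)
  with_seed(3, X <- matrix(rnorm(25 * 5), 25, 5))
  b <- c(1, 0, 2, 0, 0)
  dl <- attr_deeplift(net, X, b)
  expect_equal(dl$A, sweep(sweep(X, 2, b), 2, lin_w, "*"),
               tolerance = 1e-12, ignore_attr = TRUE)
  Xb <- matrix(b, 3, 5, byrow = TRUE)
  expect_true(all(abs(attr_deeplift(net, Xb, b)$A) < 1e-12))
})

test_that("completeness holds on random ReLU networks", {
  d <- 20
  for (s in 1:3) {
    net <- random_relu_net(d, hidden = c(12, 8, 5), seed = s)
    with_seed(100 + s, {
      X <- matrix(rnorm(5 * d), 5, d)
      b <- rnorm(d)
    })
    fx <- predict(net, X)
    fb <- predict(net, matrix(b, 1))

    # DeepLIFT rescale: summation-to-delta to 1e-6
    dl <- attr_deeplift(net, X, b)
    expect_lt(max(abs(rowSums(dl$A) - (fx - fb))), 1e-6)

    # IG at 512 midpoint steps: completeness to 1e-3
    ig <- attr_integrated_gradients(net, X, b, n_steps = 512)
    expect_lt(max(abs(rowSums(ig$A) - (fx - fb))), 1e-3)
  }
})

test_that("gradient SHAP matches the linear expectation", {
  net <- linear_net(lin_w)
  with_seed(4, X <- matrix(rnorm(20 * 5), 20, 5))
  b <- c(0, 1, 1, 0, 2)

  # degenerate baseline distribution: exact equality on a linear model
  gs0 <- attr_gradient_shap(net, X, b, n_samples = 1, noise_sd = 0, seed = 5)
  expect_equal(gs0$A, sweep(sweep(X, 2, b), 2, lin_w, "*"),
               tolerance = 1e-10, ignore_attr = TRUE)

  # jittered baselines: Monte Carlo estimate within 3 SE of the closed form
  ns <- 64; sdv <- 0.5
  gs <- attr_gradient_shap(net, X, b, n_samples = ns, noise_sd = sdv,
                           seed = 6)
  closed <- sweep(sweep(X, 2, b), 2, lin_w, "*")
  se <- matrix(abs(lin_w) * sdv / sqrt(ns), 20, 5, byrow = TRUE)
  expect_true(all(abs(gs$A - closed) < 3.5 * se + 1e-12))

  # reproducible under a fixed seed
  gs2 <- attr_gradient_shap(net, X, b, n_samples = ns, noise_sd = sdv,
                            seed = 6)
  expect_identical(gs$A, gs2$A)
})

test_that("smoothgrad reduces to the base method at zero noise", {
  net <- random_relu_net(8, hidden = c(6, 4), seed = 9)
  with_seed(10, X <- matrix(rnorm(12 * 8), 12, 8))
  b <- rep(0, 8)
  base_fun <- function(Xi) attr_deeplift(net, Xi, b)
  sg <- attr_smoothgrad(base_fun, X, n_noise = 4, noise_sd = 0, seed = 11)
  expect_equal(sg$A, base_fun(X)$A, tolerance = 1e-12)
  expect_true(sg$smoothing)

  # linear model: saliency is unchanged by input noise
  lnet <- linear_net(lin_w)
  sal_fun <- function(Xi) attr_saliency(lnet, Xi, global = FALSE)
  sgl <- attr_smoothgrad(sal_fun, matrix(rnorm(10 * 5), 10, 5),
                         n_noise = 3, noise_sd = 1, seed = 12)
  expect_equal(sgl$A, matrix(lin_w, 10, 5, byrow = TRUE), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("smoothgrad averages down attribution noise", {
  net <- random_relu_net(10, hidden = c(8, 6), seed = 13)
  with_seed(14, x <- matrix(rnorm(10), 1, 10))
  b <- rep(0, 10)
  sal <- function(Xi) attr_saliency(net, Xi, global = FALSE)
  noise_sd <- 0.5
  # base attribution at noisy inputs: per-feature variance across draws
  base_draws <- with_seed(15, t(vapply(1:30, function(k) {
    as.numeric(sal(x + matrix(rnorm(10, 0, noise_sd), 1, 10))$A)
  }, numeric(10))))
  # smoothgrad (n_noise = 10) across independent seeds
  sg_draws <- t(vapply(1:30, function(k) {
    as.numeric(attr_smoothgrad(sal, x, n_noise = 10, noise_sd = noise_sd,
                               seed = 500 + k)$A)
  }, numeric(10)))
  expect_lt(mean(apply(sg_draws, 2, var)), mean(apply(base_draws, 2, var)))
})

test_that("aggregation is the mean absolute attribution", {
  with_seed(16, A <- matrix(rnorm(15 * 6), 15, 6))
  expect_equal(aggregate_attributions(A),
               apply(A, 2, function(col) mean(abs(col))))
  # sign flips do not change importance
  expect_equal(aggregate_attributions(rbind(A, -A)),
               aggregate_attributions(A))
  # one sample: importance is the absolute attribution itself
  expect_equal(aggregate_attributions(A[1, , drop = FALSE]), abs(A[1, ]))
  expect_error(aggregate_attributions(A[0, , drop = FALSE]),
               class = "ab_config_error")
})

test_that("mode baseline picks the most frequent training genotype", {
  X <- cbind(c(0, 0, 0, 1, 2), c(1, 1, 2, 2, 2), c(0, 1, 0, 1, 2))
  expect_equal(mode_baseline(X), c(0, 2, 0))
})

test_that("attribute_model produces the full method/smoothing grid", {
  cc <- tiny_cohort(n = 250, m = 20, seed = 17)
  X <- cc$G$dosages; storage.mode(X) <- "double"
  tr <- cc$split == "train"; te <- cc$split == "test"
  net <- random_relu_net(20, hidden = c(8, 4), seed = 18)
  baseline <- mode_baseline(X[tr, ])
  train_sd <- apply(X[tr, ], 2, sd)
  res <- attribute_model(net, X[te, ], baseline, train_sd,
                         methods = c("saliency", "deeplift"),
                         seed = 19, params = list(n_noise = 2))
  expect_setequal(names(res), c("saliency.raw", "saliency.smoothed",
                                "deeplift.raw", "deeplift.smoothed"))
  # deterministic rerun
  res2 <- attribute_model(net, X[te, ], baseline, train_sd,
                          methods = c("saliency", "deeplift"),
                          seed = 19, params = list(n_noise = 2))
  expect_identical(lapply(res, `[[`, "A"), lapply(res2, `[[`, "A"))
})
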