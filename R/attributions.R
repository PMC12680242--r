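# Gradient-based feature attribution on the frozen (affine/ReLU) network:
# Saliency, Integrated Gradients, DeepLIFT (rescale rule), Gradient SHAP,
# and SmoothGrad noise averaging, plus per-SNP aggregation.

#' Mode-genotype baseline vector
#'
#' The attribution reference point x': each feature is set to its most
#' frequent genotype over the training split, so contributions are measured
#' relative to a population-representative individual. Works for dosage
#' columns in 0/1/2 (including decoy columns).
#'
#' @param X_train Training feature matrix with entries in 0/1/2.
#' @return Numeric vector of per-feature modes.
#' @export
mode_baseline <- function(X_train) {
  apply(X_train, 2, function(col) {
    tb <- tabulate(as.integer(col) + 1L, nbins = 3L)
    c(0, 1, 2)[which.max(tb)] # ties broken toward the lower genotype
  })
}

as_affine <- function(model) {
  if (inherits(model, "affine_net")) model else fold_affine(model)
}

new_attribution <- function(method, smoothing, A, feature_ids = NULL) {
  structure(
    list(method = method, smoothing = smoothing, A = A,
         S = colMeans(abs(A)), feature_ids = feature_ids %||% colnames(A)),
    class = "attribution_result"
  )
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s%s: %d samples x %d features\n",
              x$method, if (x$smoothing) " + SmoothGrad" else "",
              nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Saliency attributions
#'
#' The gradient of the scalar output with respect to each input. With
#' `global = TRUE` (the default) the gradient is multiplied elementwise by the
#' raw input, scaling attributions with input magnitude; the pure-gradient
#' form is available with `global = FALSE`.
#'
#' @param model Trained `mlp_model` or folded `affine_net`.
#' @param X Input matrix (typically the test split).
#' @param global Multiply gradients by the input.
#' @return An `attribution_result`.
#' @export
attr_saliency <- function(model, X, global = TRUE) {
  net <- as_affine(model)
  g <- input_gradient(net, X)
  A <- if (global) g * X else g
  colnames(A) <- colnames(X)
  new_attribution("saliency", FALSE, A)
}

#' Integrated Gradients attributions
#'
#' A_j = (x_j - x'_j) * mean of the gradient along the straight path from the
#' baseline to the input, approximated by a midpoint Riemann sum with
#' `n_steps` evenly spaced points. Satisfies completeness
#' (sum_j A_j = f(x) - f(x')) up to discretization error that shrinks with
#' `n_steps`; exact for any n_steps on a linear model.
#'
#' @inheritParams attr_saliency
#' @param baseline Baseline vector x' (see [mode_baseline()]).
#' @param n_steps Number of Riemann steps (>= 1, default 50).
#' @export
attr_integrated_gradients <- function(model, X, baseline, n_steps = 50L) {
  if (n_steps < 1) ab_config_error("n_steps must be >= 1")
  net <- as_affine(model)
  D <- sweep(X, 2, baseline) # x - x'
  acc <- matrix(0, nrow(X), ncol(X))
  for (k in seq_len(n_steps)) {
    alpha <- (k - 0.5) / n_steps
    Xi <- sweep(D * alpha, 2, baseline, "+")
    acc <- acc + input_gradient(net, Xi)
  }
  A <- D * acc / n_steps
  colnames(A) <- colnames(X)
  new_attribution("integrated_gradients", FALSE, A)
}

#' DeepLIFT attributions (rescale rule)
#'
#' Propagates difference-from-baseline multipliers through the folded
#' affine/ReLU network: affine layers pass multipliers through their weights;
#' ReLU units use the rescale multiplier
#' (ReLU(z) - ReLU(z')) / (z - z'), falling back to the subgradient at z when
#' |z - z'| is numerically zero. Contributions satisfy summation-to-delta,
#' sum_j A_j = f(x) - f(x'), exactly (to floating point).
#'
#' @inheritParams attr_integrated_gradients
#' @export
attr_deeplift <- function(model, X, baseline) {
  net <- as_affine(model)
  L <- length(net$layers)
  fw_x <- affine_forward(net, X)
  fw_b <- affine_forward(net, matrix(baseline, nrow = 1))
  m <- matrix(1, nrow(X), 1)
  for (l in rev(seq_len(L))) {
    if (l < L) {
      Zx <- fw_x$Z[[l]]
      Zb <- matrix(fw_b$Z[[l]], nrow(Zx), ncol(Zx), byrow = TRUE)
      dz <- Zx - Zb
      da <- Zx * (Zx > 0) - Zb * (Zb > 0)
      ratio <- ifelse(abs(dz) > 1e-10, da / dz, (Zx > 0) * 1)
      m <- m * ratio
    }
    m <- m %*% t(net$layers[[l]]$W)
  }
  A <- sweep(X, 2, baseline) * m
  colnames(A) <- colnames(X)
  new_attribution("deeplift", FALSE, A)
}

#' Gradient SHAP attributions
#'
#' Monte Carlo estimate of E over sampled baselines and path positions of
#' (x - x') * grad f at a random point on the path from x' to x. Baselines are
#' the mode vector plus optional Gaussian jitter (`noise_sd`); each of the
#' `n_samples` draws picks one interpolation coefficient per input row.
#' Deterministic given `seed`.
#'
#' @inheritParams attr_integrated_gradients
#' @param n_samples Monte Carlo draws per input (default 5).
#' @param noise_sd Gaussian jitter added to the baseline (default 0: the
#'   baseline distribution is degenerate at the mode vector).
#' @param seed Integer seed.
#' @export
attr_gradient_shap <- function(model, X, baseline, n_samples = 5L,
                               noise_sd = 0, seed = 1L) {
  if (n_samples < 1) ab_config_error("n_samples must be >= 1")
  net <- as_affine(model)
  n <- nrow(X); d <- ncol(X)
  with_seed(seed, {
    acc <- matrix(0, n, d)
    for (s in seq_len(n_samples)) {
      B <- matrix(baseline, n, d, byrow = TRUE)
      if (noise_sd > 0) B <- B + matrix(stats::rnorm(n * d, 0, noise_sd), n, d)
      alpha <- stats::runif(n)
      Xi <- B + (X - B) * alpha
      acc <- acc + (X - B) * input_gradient(net, Xi)
    }
    A <- acc / n_samples
    colnames(A) <- colnames(X)
    new_attribution("gradient_shap", FALSE, A)
  })
}

#' SmoothGrad noise averaging
#'
#' Averages a base attribution method over `n_noise` Gaussian-perturbed
#' copies of the input. `noise_sd` may be a scalar or a per-feature vector;
#' the package default in the benchmark drivers is 0.1 times the per-feature
#' training-set standard deviation. Deterministic given `seed`.
#'
#' @param base_fun Function of an input matrix returning an
#'   `attribution_result` (close over the model and method parameters).
#' @param X Input matrix.
#' @param n_noise Number of noisy replicates (>= 1).
#' @param noise_sd Scalar or per-feature noise standard deviation.
#' @param seed Integer seed.
#' @return An `attribution_result` with `smoothing = TRUE`.
#' @export
attr_smoothgrad <- function(base_fun, X, n_noise = 5L, noise_sd, seed = 1L) {
  if (n_noise < 1) ab_config_error("n_noise must be >= 1")
  n <- nrow(X); d <- ncol(X)
  sdv <- if (length(noise_sd) == 1) rep(noise_sd, d) else noise_sd
  first <- NULL
  with_seed(seed, {
    acc <- matrix(0, n, d)
    for (k in seq_len(n_noise)) {
      noise <- matrix(stats::rnorm(n * d), n, d) *
        matrix(sdv, n, d, byrow = TRUE)
      res <- base_fun(X + noise)
      if (is.null(first)) first <- res
      acc <- acc + res$A
    }
    A <- acc / n_noise
    colnames(A) <- colnames(X)
    new_attribution(first$method, TRUE, A)
  })
}

#' Aggregate per-sample attributions into per-SNP importance
#'
#' S_j = mean over attributed samples of |A_ij|.
#'
#' @param A Attribution matrix (samples x features) or `attribution_result`.
#' @return Numeric vector of non-negative per-feature importance scores.
#' @export
aggregate_attributions <- function(A) {
  if (inherits(A, "attribution_result")) A <- A$A
  if (nrow(A) == 0) ab_config_error("no samples to aggregate")
  colMeans(abs(A))
}

#' Run the configured method/smoothing grid on one model
#'
#' Computes attribution results for each requested method, with and/or
#' without SmoothGrad, on the test inputs. Method parameters follow the
#' package defaults unless overridden in `params`.
#'
#' @param model Trained `mlp_model`.
#' @param X Test-split feature matrix.
#' @param baseline Mode baseline vector.
#' @param train_sd Per-feature training-set standard deviations (for the
#'   SmoothGrad noise scale).
#' @param methods Character subset of `c("saliency", "gradient_shap",
#'   "deeplift", "integrated_gradients")`.
#' @param smoothing Logical vector of smoothing flags to evaluate (default
#'   both FALSE and TRUE).
#' @param seed Integer seed for the stochastic methods.
#' @param params Optional list overriding `n_steps`, `n_samples`,
#'   `gshap_noise_sd`, `n_noise`, `sg_noise_factor`, `global`.
#' @return Named list of `attribution_result`s keyed `method.smoothing`.
#' @export
attribute_model <- function(model, X, baseline, train_sd,
                            methods = c("saliency", "gradient_shap",
                                        "deeplift", "integrated_gradients"),
                            smoothing = c(FALSE, TRUE),
                            seed = 1L, params = list()) {
  p <- utils::modifyList(list(
    n_steps = 50L, n_samples = 5L, gshap_noise_sd = 0,
    n_noise = 5L, sg_noise_factor = 0.1, global = TRUE
  ), params)
  net <- as_affine(model)
  sg_sd <- p$sg_noise_factor * train_sd
  out <- list()
  for (meth in methods) {
    base_fun <- switch(
      meth,
      saliency = function(Xi) attr_saliency(net, Xi, global = p$global),
      gradient_shap = function(Xi) {
        attr_gradient_shap(net, Xi, baseline, n_samples = p$n_samples,
                           noise_sd = p$gshap_noise_sd,
                           seed = derive_seed(seed, 11))
      },
      deeplift = function(Xi) attr_deeplift(net, Xi, baseline),
      integrated_gradients = function(Xi) {
        attr_integrated_gradients(net, Xi, baseline, n_steps = p$n_steps)
      },
      ab_config_error(sprintf("unknown method '%s'", meth))
    )
    for (sm in smoothing) {
      key <- paste0(meth, if (sm) ".smoothed" else ".raw")
      out[[key]] <- if (sm) {
        attr_smoothgrad(base_fun, X, n_noise = p$n_noise, noise_sd = sg_sd,
                        seed = derive_seed(seed, 13))
      } else {
        base_fun(X)
      }
    }
  }
  out
}
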