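# Native feed-forward regression network: dense -> batch-norm -> ReLU ->
# dropout blocks with a linear output unit, trained with Adam on mean absolute
# error plus an explicit L2 penalty. Implemented directly in R matrix algebra
# so that the attribution module has exact analytic gradients.

#' Network architecture specification
#'
#' @param input_dim Number of input features.
#' @param hidden Integer vector of hidden-layer widths (default 1000/200/50).
#' @param dropout Dropout probability applied after each hidden block.
#' @param batch_norm Whether hidden blocks include batch normalization.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_dim, hidden = c(1000, 200, 50),
                         dropout = 0.5, batch_norm = TRUE) {
  if (length(hidden) < 1) ab_config_error("need at least one hidden layer")
  if (dropout < 0 || dropout >= 1) ab_config_error("dropout must be in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden),
                 dropout = dropout, batch_norm = isTRUE(batch_norm)),
            class = "network_spec")
}

#' Training configuration
#'
#' Mirrors the reference training recipe: Adam with decoupled-from-nothing
#' classic weight decay (an L2 term added to the gradient) *and* an explicit
#' L2 penalty in the loss. The two are not mathematically redundant under
#' Adam's adaptive scaling, so both are implemented and independently
#' switchable.
#'
#' @param lr Learning rate.
#' @param weight_decay Adam weight-decay coefficient (0 disables).
#' @param l2_factor Explicit L2 loss-penalty factor (0 disables).
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs (>= 1).
#' @param shuffle_seed Seed controlling initialization and per-epoch shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-6, weight_decay = 1e-3, l2_factor = 1e-3,
                         batch_size = 128, epochs = 100, shuffle_seed = 1L) {
  if (epochs < 1) ab_config_error("epochs must be >= 1")
  if (lr <= 0 || batch_size < 1) ab_config_error("lr and batch_size must be positive")
  structure(list(lr = lr, weight_decay = weight_decay, l2_factor = l2_factor,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "train_config")
}

# Fan-in uniform initialization (the common dense-layer default).
mlp_init <- function(spec, seed) {
  dims <- c(spec$input_dim, spec$hidden, 1L)
  with_seed(seed, {
    layers <- vector("list", length(dims) - 1)
    for (l in seq_along(layers)) {
      fi <- dims[l]
      bound <- 1 / sqrt(fi)
      layers[[l]] <- list(
        W = matrix(stats::runif(fi * dims[l + 1], -bound, bound), fi, dims[l + 1]),
        b = stats::runif(dims[l + 1], -bound, bound)
      )
      if (spec$batch_norm && l < length(layers)) {
        d <- dims[l + 1]
        layers[[l]]$gamma <- rep(1, d)
        layers[[l]]$beta <- rep(0, d)
        layers[[l]]$run_mean <- rep(0, d)
        layers[[l]]$run_var <- rep(1, d)
      }
    }
    list(spec = spec, layers = layers)
  })
}

bn_eps <- 1e-5

# Forward pass. training=TRUE uses batch statistics and dropout masks (drawn
# from the ambient RNG stream); inference uses running statistics, no dropout.
mlp_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  L <- length(model$layers)
  cache <- list(A = vector("list", L + 1), Z = vector("list", L),
                Zhat = vector("list", L), mask = vector("list", L),
                bstats = vector("list", L))
  cache$A[[1]] <- X
  H <- X
  for (l in seq_len(L)) {
    ly <- model$layers[[l]]
    Z <- H %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    cache$Z[[l]] <- Z
    if (l < L) {
      if (spec$batch_norm) {
        if (training) {
          mu <- colMeans(Z)
          v <- colMeans(sweep(Z, 2, mu)^2)
          cache$bstats[[l]] <- list(mu = mu, v = v)
        } else {
          mu <- ly$run_mean
          v <- ly$run_var
        }
        Zc <- sweep(Z, 2, mu)
        Zhat <- sweep(Zc, 2, sqrt(v + bn_eps), "/")
        cache$Zhat[[l]] <- Zhat
        H <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      } else {
        H <- Z
      }
      H <- H * (H > 0) # ReLU
      if (training && spec$dropout > 0) {
        keep <- 1 - spec$dropout
        mask <- matrix(stats::rbinom(length(H), 1L, keep) / keep,
                       nrow(H), ncol(H))
        cache$mask[[l]] <- mask
        H <- H * mask
      }
    } else {
      H <- Z
    }
    cache$A[[l + 1]] <- H
  }
  list(yhat = as.numeric(H), cache = cache)
}

#' Predict with a trained network (inference mode)
#'
#' @param object Trained model from [train_model()] (class `mlp_model`).
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  mlp_forward(object, newdata, training = FALSE)$yhat
}

# Backward pass for one training batch; returns gradients matching layers.
mlp_backward <- function(model, fw, y, l2_factor) {
  spec <- model$spec
  L <- length(model$layers)
  nb <- length(y)
  grads <- vector("list", L)
  # MAE loss
  delta <- matrix(sign(fw$yhat - y) / nb, ncol = 1)
  for (l in rev(seq_len(L))) {
    ly <- model$layers[[l]]
    Aprev <- fw$cache$A[[l]]
    if (l < L) {
      # back through dropout
      if (spec$dropout > 0) delta <- delta * fw$cache$mask[[l]]
      # back through ReLU (post-BN preactivation)
      if (spec$batch_norm) {
        bs <- fw$cache$bstats[[l]]
        Zhat <- fw$cache$Zhat[[l]]
        act <- sweep(sweep(Zhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
        delta <- delta * (act > 0)
        dgamma <- colSums(delta * Zhat)
        dbeta <- colSums(delta)
        # batch-norm backward (standard batch-statistics formula)
        inv_sd <- 1 / sqrt(bs$v + bn_eps)
        dZhat <- sweep(delta, 2, ly$gamma, "*")
        m <- nrow(delta)
        term <- dZhat - matrix(colMeans(dZhat), m, ncol(dZhat), byrow = TRUE) -
          Zhat * matrix(colMeans(dZhat * Zhat), m, ncol(dZhat), byrow = TRUE)
        delta <- sweep(term, 2, inv_sd, "*")
        grads[[l]] <- list(W = crossprod(Aprev, delta) + 2 * l2_factor * ly$W,
                           b = colSums(delta), gamma = dgamma, beta = dbeta)
      } else {
        delta <- delta * (fw$cache$Z[[l]] > 0)
        grads[[l]] <- list(W = crossprod(Aprev, delta) + 2 * l2_factor * ly$W,
                           b = colSums(delta))
      }
    } else {
      grads[[l]] <- list(W = crossprod(Aprev, delta) + 2 * l2_factor * ly$W,
                         b = colSums(delta))
    }
    if (l > 1) delta <- delta %*% t(model$layers[[l]]$W)
  }
  grads
}

adam_state_init <- function(model) {
  lapply(model$layers, function(ly) {
    lapply(ly[intersect(names(ly), c("W", "b", "gamma", "beta"))],
           function(p) list(m = p * 0, v = p * 0))
  })
}

adam_step <- function(model, grads, state, t, cfg) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (l in seq_along(model$layers)) {
    for (nm in names(state[[l]])) {
      g <- grads[[l]][[nm]]
      if (nm == "W" && cfg$weight_decay > 0) {
        g <- g + cfg$weight_decay * model$layers[[l]][[nm]]
      }
      st <- state[[l]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      model$layers[[l]][[nm]] <- model$layers[[l]][[nm]] -
        cfg$lr * mhat / (sqrt(vhat) + eps)
      state[[l]][[nm]] <- st
    }
  }
  list(model = model, state = state)
}

# Validation Pearson r with the zero-variance guard (r = 0 with a warning).
val_pearson <- function(pred, y) {
  if (stats::sd(pred) == 0 || stats::sd(y) == 0) {
    warning("zero-variance predictions: validation Pearson r set to 0")
    return(0)
  }
  stats::cor(pred, y)
}

#' Train the feed-forward network
#'
#' Trains with Adam on MAE + L2 and checkpoints the parameters (including
#' batch-norm running statistics) from the epoch with the best validation
#' Pearson correlation. Fully deterministic given the data and
#' `cfg$shuffle_seed`, which controls initialization, per-epoch shuffling,
#' dropout masks, and hence the checkpoint.
#'
#' @param X_train,y_train Training features (matrix) and targets.
#' @param X_val,y_val Validation features and targets.
#' @param spec A [network_spec()].
#' @param cfg A [train_config()].
#' @return Object of class `mlp_model`: the best-epoch parameters plus a
#'   `history` data.frame (epoch, train_loss, val_r) and `best_epoch`,
#'   `best_val_r`.
#' @export
train_model <- function(X_train, y_train, X_val, y_val, spec, cfg) {
  if (ncol(X_train) != spec$input_dim) {
    ab_config_error("spec input_dim does not match training features")
  }
  model <- mlp_init(spec, derive_seed(cfg$shuffle_seed, 77))
  state <- adam_state_init(model)
  n <- nrow(X_train)
  best <- list(val_r = -Inf, layers = NULL, epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_r = numeric())
  t_step <- 0L
  mom <- 0.1 # batch-norm running-statistic momentum
  for (epoch in seq_len(cfg$epochs)) {
    epoch_loss <- 0
    nbatches <- 0L
    with_seed(derive_seed(cfg$shuffle_seed, epoch), {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1, n)]
        if (length(idx) < 2) next # batch statistics need >= 2 samples
        Xb <- X_train[idx, , drop = FALSE]
        yb <- y_train[idx]
        fw <- mlp_forward(model, Xb, training = TRUE)
        if (any(!is.finite(fw$yhat))) {
          ab_stop("non-finite predictions during training", "ab_training_error")
        }
        loss <- mean(abs(fw$yhat - yb))
        epoch_loss <- epoch_loss + loss
        nbatches <- nbatches + 1L
        grads <- mlp_backward(model, fw, yb, cfg$l2_factor)
        t_step <- t_step + 1L
        upd <- adam_step(model, grads, state, t_step, cfg)
        model <- upd$model
        state <- upd$state
        # update running statistics from this batch
        if (spec$batch_norm) {
          nb <- length(idx)
          for (l in seq_len(length(model$layers) - 1)) {
            bs <- fw$cache$bstats[[l]]
            ub_v <- bs$v * nb / max(nb - 1, 1)
            model$layers[[l]]$run_mean <-
              (1 - mom) * model$layers[[l]]$run_mean + mom * bs$mu
            model$layers[[l]]$run_var <-
              (1 - mom) * model$layers[[l]]$run_var + mom * ub_v
          }
        }
      }
    })
    vp <- mlp_forward(model, X_val, training = FALSE)$yhat
    vr <- val_pearson(vp, y_val)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / max(nbatches, 1), val_r = vr))
    if (vr > best$val_r) {
      best <- list(val_r = vr, layers = model$layers, epoch = epoch)
    }
  }
  structure(list(spec = spec, layers = best$layers, history = history,
                 best_epoch = best$epoch, best_val_r = best$val_r,
                 cfg = cfg),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d -> %s -> 1; best epoch %d (val r = %.4f)\n",
              x$spec$input_dim, paste(x$spec$hidden, collapse = "/"),
              x$best_epoch, x$best_val_r))
  invisible(x)
}

#' Train an ensemble of independently seeded models
#'
#' Members share architecture, hyperparameters, and data; they differ only in
#' the seed controlling initialization and training-set shuffling.
#'
#' @inheritParams train_model
#' @param n_members Number of ensemble members M (default 10).
#' @param seeds Optional integer vector of per-member seeds (pairwise
#'   distinct); defaults to `cfg$shuffle_seed + 0:(M-1)`.
#' @return List of `mlp_model` objects.
#' @export
train_ensemble <- function(X_train, y_train, X_val, y_val, spec, cfg,
                           n_members = 10L, seeds = NULL) {
  if (is.null(seeds)) seeds <- cfg$shuffle_seed + seq_len(n_members) - 1L
  if (length(seeds) != n_members || anyDuplicated(seeds)) {
    ab_config_error("ensemble seeds must be pairwise distinct, one per member")
  }
  lapply(seeds, function(s) {
    cfg_m <- cfg
    cfg_m$shuffle_seed <- as.integer(s)
    train_model(X_train, y_train, X_val, y_val, spec, cfg_m)
  })
}

#' Fold a trained network into an affine/ReLU stack (inference form)
#'
#' Batch normalization is folded into the adjacent dense layer using the
#' stored running statistics, and dropout is the identity at inference, so
#' the frozen network is exactly a composition of affine maps and ReLUs.
#' This canonical form is what the attribution methods differentiate.
#'
#' @param model A trained `mlp_model`.
#' @return Object of class `affine_net`: list of `(W, b)` layers with ReLU
#'   between all but the last.
#' @export
fold_affine <- function(model) {
  L <- length(model$layers)
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    ly <- model$layers[[l]]
    W <- ly$W
    b <- ly$b
    if (!is.null(ly$gamma)) {
      scale <- ly$gamma / sqrt(ly$run_var + bn_eps)
      W <- sweep(W, 2, scale, "*")
      b <- (b - ly$run_mean) * scale + ly$beta
    }
    layers[[l]] <- list(W = W, b = b)
  }
  structure(list(layers = layers), class = "affine_net")
}

# Forward pass of the folded net, keeping preactivations.
affine_forward <- function(net, X) {
  L <- length(net$layers)
  Z <- vector("list", L)
  H <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(H %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    H <- if (l < L) Z[[l]] * (Z[[l]] > 0) else Z[[l]]
  }
  list(yhat = as.numeric(H), Z = Z)
}

#' Predict with a folded network
#' @param object An `affine_net`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @export
predict.affine_net <- function(object, newdata, ...) {
  affine_forward(object, newdata)$yhat
}

# Gradient of the scalar output with respect to the input, one row per sample.
input_gradient <- function(net, X) {
  fw <- affine_forward(net, X)
  L <- length(net$layers)
  g <- matrix(1, nrow(X), 1)
  for (l in rev(seq_len(L))) {
    if (l < L) g <- g * (fw$Z[[l]] > 0)
    g <- g %*% t(net$layers[[l]]$W)
  }
  g
}
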