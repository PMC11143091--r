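# Compact depthwise-separable CNN for 8 x 201 oddball epochs, implemented
# from scratch (forward, exact backprop, batch norm, dropout). No deep
# learning framework is available for R in this environment, and exact input
# gradients are needed by the saliency module, so the network is hand-built
# and verified against finite differences in the test-suite.
#
# Architecture (channels x time input, "same" time padding throughout):
#   input 1 x 8 x 201
#   -> temporal conv, F1 = 8 filters, kernel 1 x 64, batch norm
#   -> depthwise spatial conv, kernel 8 x 1, depth multiplier D = 2 (16 maps),
#      batch norm, ELU, average pool 1 x 4, dropout       -> 16 x 1 x 50
#   -> separable conv (depthwise 1 x 16 + pointwise), batch norm, ELU,
#      average pool 1 x 8, dropout                        -> 16 x 1 x 6
#   -> flatten (96) -> dense (2) -> softmax

#' Network architecture configuration
#'
#' Defaults give the standard compact configuration for 8-channel, 201-sample
#' epochs: F1 = 8 temporal filters of length 64, depth multiplier D = 2
#' (16 spatial filters), F2 = 16 separable filters of length 16, pooling
#' 4 then 8, flatten length `F2 * floor(floor(201/4)/8) = 96`, 2 classes.
#'
#' @param n_channels,n_samples input geometry.
#' @param F1 number of temporal filters.
#' @param temporal_kernel temporal kernel length.
#' @param D depth multiplier of the spatial depthwise stage.
#' @param F2 number of separable filters (must equal `F1 * D`).
#' @param separable_kernel separable (depthwise) kernel length.
#' @param pool1,pool2 average-pooling widths.
#' @param dropout_rate dropout probability after each pooling stage.
#' @param n_classes number of output classes.
#' @param bn_momentum running-statistics momentum of the batch-norm layers.
#' @return an object of class `eegnet_config`.
#' @export
eegnet_config <- function(n_channels = 8L, n_samples = 201L, F1 = 8L,
                          temporal_kernel = 64L, D = 2L, F2 = 16L,
                          separable_kernel = 16L, pool1 = 4L, pool2 = 8L,
                          dropout_rate = 0.5, n_classes = 2L,
                          bn_momentum = 0.9) {
  if (F1 * D != F2) stopf("F1 * D (%d) must equal F2 (%d)", F1 * D, F2)
  t1 <- floor(n_samples / pool1)
  t2 <- floor(t1 / pool2)
  if (t2 < 1) stopf("pooling produces zero-length output")
  structure(list(n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), F1 = as.integer(F1),
                 temporal_kernel = as.integer(temporal_kernel),
                 D = as.integer(D), F2 = as.integer(F2),
                 separable_kernel = as.integer(separable_kernel),
                 pool1 = as.integer(pool1), pool2 = as.integer(pool2),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
                 bn_momentum = bn_momentum,
                 t_pool1 = as.integer(t1), t_pool2 = as.integer(t2),
                 flatten = as.integer(F2 * t2)),
            class = "eegnet_config")
}

#' Exponential linear unit
#'
#' `x` for `x >= 0`, `exp(x) - 1` otherwise; continuous at 0.
#'
#' @param x numeric vector/array.
#' @return the activation, same shape.
#' @export
elu <- function(x) ifelse(x >= 0, x, exp(x) - 1)

#' Softmax over logits
#'
#' Numerically stable (max-shifted); components lie in (0, 1) and sum to 1,
#' invariant to adding a constant to all logits.
#'
#' @param logits numeric vector, or matrix with one column per case.
#' @return probabilities, same shape.
#' @export
softmax <- function(logits) {
  if (any(!is.finite(logits))) stopf("non-finite logits")
  if (is.matrix(logits)) {
    z <- sweep(logits, 2, apply(logits, 2, max))
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Focal loss
#'
#' `FL(p_t) = -(1 - p_t)^gamma * log(p_t)`; `gamma = 0` reproduces plain
#' cross-entropy. `p_t` is the predicted probability of the *true* class.
#'
#' @param p_t probability of the true class, in (0, 1].
#' @param gamma focusing parameter, `>= 0`.
#' @param eps clamp for `p_t = 0` (clamped values are flagged by a warning).
#' @return the per-sample loss.
#' @export
focal_loss <- function(p_t, gamma = 2, eps = 1e-12) {
  if (gamma < 0) stopf("gamma must be >= 0")
  if (any(p_t < 0 | p_t > 1)) stopf("p_t must lie in [0, 1]")
  if (any(p_t < eps)) {
    warning("focal_loss: p_t clamped at eps")
    p_t <- pmax(p_t, eps)
  }
  -(1 - p_t)^gamma * log(p_t)
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build an (untrained) network
#'
#' @param cfg an [eegnet_config()].
#' @param seed integer seed for the Glorot-uniform initialization.
#' @return an object of class `eegnet_model` with parameter tensors,
#'   batch-norm running statistics and a `layer_shapes` report.
#' @export
build_eegnet <- function(cfg = eegnet_config(), seed = 1L) {
  params <- with_seed(seed, {
    K1 <- cfg$temporal_kernel; Ks <- cfg$separable_kernel
    C <- cfg$n_channels
    list(
      W1 = glorot(K1, cfg$F1, K1, K1 * cfg$F1),
      g1 = rep(1, cfg$F1), b1 = rep(0, cfg$F1),
      Wd = glorot(C, cfg$F2, C, C * cfg$D),
      g2 = rep(1, cfg$F2), b2 = rep(0, cfg$F2),
      Ws = glorot(Ks, cfg$F2, Ks, Ks),
      Wp = glorot(cfg$F2, cfg$F2, cfg$F2, cfg$F2),
      g3 = rep(1, cfg$F2), b3 = rep(0, cfg$F2),
      Wf = glorot(cfg$flatten, cfg$n_classes, cfg$flatten, cfg$n_classes),
      bf = rep(0, cfg$n_classes))
  })
  running <- list(m1 = rep(0, cfg$F1), v1 = rep(1, cfg$F1),
                  m2 = rep(0, cfg$F2), v2 = rep(1, cfg$F2),
                  m3 = rep(0, cfg$F2), v3 = rep(1, cfg$F2))
  structure(list(cfg = cfg, params = params, running = running,
                 trained = FALSE, history = NULL),
            class = "eegnet_model")
}

#' Per-layer output dimensions
#'
#' Reports every stage's output dimension for the configured input in the
#' `(maps, 1, time)` convention of the architecture table (the temporal
#' stage additionally carries the 8-electrode axis internally until the
#' depthwise stage collapses it).
#'
#' @param model an `eegnet_model` (or an [eegnet_config()]).
#' @return data.frame with `layer` and `dims` (integer-vector list column).
#' @export
layer_shapes <- function(model) {
  cfg <- if (inherits(model, "eegnet_config")) model else model$cfg
  d <- list(
    input = c(cfg$n_channels, cfg$n_samples),
    reshape = c(1L, cfg$n_channels, cfg$n_samples),
    conv_temporal = c(cfg$F1, 1L, cfg$n_samples),
    batchnorm_1 = c(cfg$F1, 1L, cfg$n_samples),
    conv_depthwise = c(cfg$F2, 1L, cfg$n_samples),
    batchnorm_2 = c(cfg$F2, 1L, cfg$n_samples),
    elu_1 = c(cfg$F2, 1L, cfg$n_samples),
    avgpool_1 = c(cfg$F2, 1L, cfg$t_pool1),
    dropout_1 = c(cfg$F2, 1L, cfg$t_pool1),
    conv_separable = c(cfg$F2, 1L, cfg$t_pool1),
    batchnorm_3 = c(cfg$F2, 1L, cfg$t_pool1),
    elu_2 = c(cfg$F2, 1L, cfg$t_pool1),
    avgpool_2 = c(cfg$F2, 1L, cfg$t_pool2),
    dropout_2 = c(cfg$F2, 1L, cfg$t_pool2),
    flatten = cfg$flatten,
    dense = cfg$n_classes)
  data.frame(layer = names(d), dims = I(unname(d)))
}

# "same" padding split for an even/odd kernel
same_pad <- function(K) c(floor((K - 1) / 2), ceiling((K - 1) / 2))

# batch norm over everything but the map axis; x is any array whose *last*
# dimension (of extent M) indexes the maps, flattened column-major
bn_forward <- function(x, M, gamma, beta, run_m, run_v, training, mom,
                       eps = 1e-3) {
  if (training) {
    mo <- col_moments(x, M)
    istd <- 1 / sqrt(mo$var + eps)
    xhat <- col_standardize(x, mo$mean, istd, M)
    y <- col_affine(xhat, gamma, beta, M)
    run_m <- mom * run_m + (1 - mom) * mo$mean
    run_v <- mom * run_v + (1 - mom) * mo$var
    list(y = y, xhat = xhat, istd = istd, run_m = run_m, run_v = run_v)
  } else {
    istd <- 1 / sqrt(run_v + eps)
    a <- gamma * istd
    y <- col_affine(x, a, beta - run_m * a, M)
    list(y = y, istd = istd, run_m = run_m, run_v = run_v)
  }
}

bn_backward <- function(dy, bn, gamma, M, training) {
  if (training) {
    s <- bn_bwd_sums(dy, bn$xhat, M)
    dx <- bn_bwd_dx(dy, bn$xhat, s$s1, s$s2, gamma * bn$istd, M)
    list(dx = dx, dgamma = s$dgamma, dbeta = s$dbeta)
  } else {
    list(dx = col_affine(dy, gamma * bn$istd, numeric(M), M),
         dgamma = NULL, dbeta = NULL)
  }
}

# forward pass; X is an array n x channels x samples
eegnet_forward <- function(model, X, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg; P <- model$params
  n <- dim(X)[1]; C <- cfg$n_channels; T0 <- cfg$n_samples
  stopifnot(dim(X)[2] == C, dim(X)[3] == T0)

  Xm <- matrix(aperm(X, c(3, 2, 1)), T0, C * n)       # (t) x (c, i)
  p1 <- same_pad(cfg$temporal_kernel)
  Xp <- rbind(matrix(0, p1[1], C * n), Xm, matrix(0, p1[2], C * n))
  Y1 <- conv_cols_fwd(Xp, P$W1)                       # (t, (c,i), f1)
  bn1 <- bn_forward(Y1, cfg$F1, P$g1, P$b1,
                    model$running$m1, model$running$v1, training,
                    cfg$bn_momentum)

  # depthwise spatial conv: collapse the electrode axis
  Z <- depthwise_fwd(bn1$y, P$Wd, cfg$D)               # (t, i, m)
  bn2 <- bn_forward(Z, cfg$F2, P$g2, P$b2,
                    model$running$m2, model$running$v2, training,
                    cfg$bn_momentum)
  E1 <- elu_fwd(bn2$y)

  # average pool 1 (width pool1, stride pool1, floor)
  t_used1 <- cfg$t_pool1 * cfg$pool1
  Ppool <- E1[seq_len(t_used1), , , drop = FALSE]
  dim(Ppool) <- c(cfg$pool1, cfg$t_pool1 * n * cfg$F2)
  P1 <- array(colMeans(Ppool), c(cfg$t_pool1, n, cfg$F2))

  if (training && cfg$dropout_rate > 0) {
    mask1 <- array((runif(length(P1)) >= cfg$dropout_rate) /
                     (1 - cfg$dropout_rate), dim(P1))
    P1 <- P1 * mask1
  } else mask1 <- NULL

  # separable stage: per-map temporal depthwise conv, then 1x1 pointwise
  ps <- same_pad(cfg$separable_kernel)
  S1 <- array(0, c(cfg$t_pool1, n, cfg$F2))
  Spads <- if (keep_cache) vector("list", cfg$F2) else NULL
  for (m in seq_len(cfg$F2)) {
    P1m <- P1[, , m, drop = FALSE]
    dim(P1m) <- c(cfg$t_pool1, n)
    Xm2 <- rbind(matrix(0, ps[1], n), P1m, matrix(0, ps[2], n))
    S1[, , m] <- conv_cols_fwd(Xm2, P$Ws[, m, drop = FALSE])[, , 1]
    if (keep_cache) Spads[[m]] <- Xm2
  }
  S1flat <- S1
  dim(S1flat) <- c(cfg$t_pool1 * n, cfg$F2)
  S2flat <- S1flat %*% P$Wp
  bn3 <- bn_forward(S2flat, cfg$F2, P$g3, P$b3,
                    model$running$m3, model$running$v3, training,
                    cfg$bn_momentum)
  E2 <- elu_fwd(bn3$y)
  dim(E2) <- c(cfg$t_pool1, n, cfg$F2)

  t_used2 <- cfg$t_pool2 * cfg$pool2
  Ppool2 <- E2[seq_len(t_used2), , , drop = FALSE]
  dim(Ppool2) <- c(cfg$pool2, cfg$t_pool2 * n * cfg$F2)
  P2 <- array(colMeans(Ppool2), c(cfg$t_pool2, n, cfg$F2))

  if (training && cfg$dropout_rate > 0) {
    mask2 <- array((runif(length(P2)) >= cfg$dropout_rate) /
                     (1 - cfg$dropout_rate), dim(P2))
    P2 <- P2 * mask2
  } else mask2 <- NULL

  Feat <- matrix(aperm(P2, c(1, 3, 2)), cfg$flatten, n)  # (t, m) x i
  logits <- crossprod(P$Wf, Feat) + P$bf                 # classes x n

  out <- list(logits = logits, probs = softmax(logits))
  if (training) {
    out$running <- list(m1 = bn1$run_m, v1 = bn1$run_v,
                        m2 = bn2$run_m, v2 = bn2$run_v,
                        m3 = bn3$run_m, v3 = bn3$run_v)
  }
  if (keep_cache) {
    out$cache <- list(n = n, Xp = Xp, A1 = bn1$y,
                      bn1 = bn1, bn2 = bn2, bn3 = bn3,
                      E1 = E1, E2 = E2, mask1 = mask1, mask2 = mask2,
                      Spads = Spads, S1flat = S1flat, Feat = Feat,
                      training = training)
  }
  out
}

# backward pass from dlogits (classes x n); returns parameter gradients and
# the gradient with respect to the input (n x channels x samples)
eegnet_backward <- function(model, cache, dlogits, want_dx = TRUE) {
  cfg <- model$cfg; P <- model$params
  n <- cache$n; C <- cfg$n_channels; T0 <- cfg$n_samples
  training <- cache$training
  G <- list()

  G$Wf <- cache$Feat %*% t(dlogits)
  G$bf <- rowSums(dlogits)
  dFeat <- P$Wf %*% dlogits                              # flatten x n
  dP2 <- aperm(array(dFeat, c(cfg$t_pool2, cfg$F2, n)), c(1, 3, 2))
  if (!is.null(cache$mask2)) dP2 <- dP2 * cache$mask2

  # unpool 2
  dA3 <- array(0, c(cfg$t_pool1, n, cfg$F2))
  idx2 <- rep(seq_len(cfg$t_pool2), each = cfg$pool2)
  dA3[seq_len(cfg$t_pool2 * cfg$pool2), , ] <-
    dP2[idx2, , , drop = FALSE] / cfg$pool2

  dE2 <- dA3
  dim(dE2) <- c(cfg$t_pool1 * n, cfg$F2)
  dBN3 <- elu_bwd(dE2, cache$E2)
  dim(dBN3) <- c(cfg$t_pool1 * n, cfg$F2)
  bb3 <- bn_backward(dBN3, cache$bn3, P$g3, cfg$F2, training)
  G$g3 <- bb3$dgamma; G$b3 <- bb3$dbeta
  dS2flat <- bb3$dx
  dim(dS2flat) <- c(cfg$t_pool1 * n, cfg$F2)

  G$Wp <- crossprod(cache$S1flat, dS2flat)
  dS1 <- tcrossprod(dS2flat, P$Wp)
  dim(dS1) <- c(cfg$t_pool1, n, cfg$F2)

  ps <- same_pad(cfg$separable_kernel)
  G$Ws <- matrix(0, cfg$separable_kernel, cfg$F2)
  dP1 <- array(0, c(cfg$t_pool1, n, cfg$F2))
  for (m in seq_len(cfg$F2)) {
    dYm <- array(dS1[, , m], c(cfg$t_pool1, n, 1))
    dXm <- conv_cols_dx(dYm, P$Ws[, m, drop = FALSE],
                        cfg$t_pool1 + ps[1] + ps[2])
    dP1[, , m] <- dXm[(ps[1] + 1):(ps[1] + cfg$t_pool1), , drop = FALSE]
    G$Ws[, m] <- conv_cols_dw(cache$Spads[[m]], dYm, cfg$separable_kernel)
  }
  if (!is.null(cache$mask1)) dP1 <- dP1 * cache$mask1

  # unpool 1
  dA2 <- array(0, c(T0, n, cfg$F2))
  idx1 <- rep(seq_len(cfg$t_pool1), each = cfg$pool1)
  dA2[seq_len(cfg$t_pool1 * cfg$pool1), , ] <-
    dP1[idx1, , , drop = FALSE] / cfg$pool1

  dE1 <- elu_bwd(dA2, cache$E1)
  bb2 <- bn_backward(dE1, cache$bn2, P$g2, cfg$F2, training)
  G$g2 <- bb2$dgamma; G$b2 <- bb2$dbeta
  dZ <- bb2$dx
  dim(dZ) <- c(T0, n, cfg$F2)

  G$Wd <- depthwise_dw(cache$A1, dZ, C, cfg$D)
  dA1 <- depthwise_dx(dZ, P$Wd, cfg$F1)                  # (t, (c,i), f1)

  bb1 <- bn_backward(dA1, cache$bn1, P$g1, cfg$F1, training)
  G$g1 <- bb1$dgamma; G$b1 <- bb1$dbeta
  dY1 <- bb1$dx
  dim(dY1) <- c(T0, C * n, cfg$F1)
  G$W1 <- conv_cols_dw(cache$Xp, dY1, cfg$temporal_kernel)

  dX <- NULL
  if (want_dx) {
    p1 <- same_pad(cfg$temporal_kernel)
    dXp <- conv_cols_dx(dY1, P$W1, T0 + p1[1] + p1[2])
    dXm <- dXp[(p1[1] + 1):(p1[1] + T0), , drop = FALSE]
    dX <- aperm(array(dXm, c(T0, C, n)), c(3, 2, 1))
  }
  list(grads = G, dX = dX)
}

# gradient of mean focal loss w.r.t. logits; labels in {0, 1} index the
# logit rows (row 1 = class 0, row 2 = class 1)
focal_loss_grad <- function(logits, labels, gamma) {
  n <- ncol(logits)
  probs <- softmax(logits)
  yrow <- labels + 1L
  pt <- pmax(probs[cbind(yrow, seq_len(n))], 1e-12)
  q <- 1 - pt
  dl_dpt <- ifelse(q > 0, gamma * q^pmax(gamma - 1, 0) * log(pt), 0) - q^gamma / pt
  delta <- matrix(0, nrow(logits), n)
  delta[cbind(yrow, seq_len(n))] <- 1
  dz <- sweep(delta - probs, 2, dl_dpt * pt, "*") # dpt/dz = pt * (delta - p)
  list(dlogits = dz / n,
       loss = mean(focal_loss(pt, gamma)),
       probs = probs)
}

#' Class probabilities / input gradients of a fitted network
#'
#' `predict_eegnet` runs the network in inference mode (batch-norm running
#' statistics, no dropout). `input_gradient` returns the exact gradient of
#' the pre-softmax class score with respect to the input epochs, the
#' quantity the saliency module visualizes.
#'
#' @param model an `eegnet_model`.
#' @param x an [epoch_set()] or an `n x channels x samples` array.
#' @param batch processing chunk size.
#' @return `predict_eegnet`: matrix `n x n_classes` of probabilities.
#' @export
predict_eegnet <- function(model, x, batch = 512L) {
  X <- if (inherits(x, "epoch_set")) x$data else x
  n <- dim(X)[1]
  out <- matrix(0, n, model$cfg$n_classes)
  for (at in seq(1L, n, by = batch)) {
    idx <- at:min(at + batch - 1L, n)
    fw <- eegnet_forward(model, X[idx, , , drop = FALSE], training = FALSE)
    out[idx, ] <- t(fw$probs)
  }
  out
}

#' @rdname predict_eegnet
#' @param class_index 1-based class whose score is differentiated (2 =
#'   target at the default 2-class head).
#' @param ... passed to methods.
#' @return `input_gradient`: array `n x channels x samples` of gradients.
#' @export
input_gradient <- function(model, x, class_index = 2L, ...) {
  UseMethod("input_gradient")
}

#' @rdname predict_eegnet
#' @export
input_gradient.eegnet_model <- function(model, x, class_index = 2L,
                                        batch = 256L, ...) {
  X <- if (inherits(x, "epoch_set")) x$data else x
  cfg <- model$cfg
  if (class_index < 1L || class_index > cfg$n_classes)
    stopf("class index out of range")
  n <- dim(X)[1]
  out <- array(0, dim(X))
  for (at in seq(1L, n, by = batch)) {
    idx <- at:min(at + batch - 1L, n)
    fw <- eegnet_forward(model, X[idx, , , drop = FALSE], training = FALSE,
                         keep_cache = TRUE)
    dlog <- matrix(0, cfg$n_classes, length(idx))
    dlog[class_index, ] <- 1
    bw <- eegnet_backward(model, fw$cache, dlog, want_dx = TRUE)
    out[idx, , ] <- bw$dX
  }
  out
}
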