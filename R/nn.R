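# Minimal dense feed-forward network with Adam, used by both the
# per-cluster autoencoders (relu hidden / linear output / MAE loss) and the
# event classifier (relu hidden / sigmoid output / binary cross-entropy).
# Everything is plain matrix algebra; training is deterministic for a fixed
# seed (weight init and mini-batch shuffling both draw from the seeded RNG).

nn_init <- function(layer_sizes, seed) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1))
  with_seed(seed, {
    L <- length(layer_sizes) - 1L
    W <- vector("list", L)
    b <- vector("list", L)
    for (l in seq_len(L)) {
      fan_in <- layer_sizes[l]
      # He initialization, suited to relu hidden units
      W[[l]] <- matrix(stats::rnorm(fan_in * layer_sizes[l + 1L], sd = sqrt(2 / fan_in)),
                       nrow = fan_in)
      b[[l]] <- numeric(layer_sizes[l + 1L])
    }
    list(W = W, b = b, layer_sizes = layer_sizes)
  })
}

.act <- function(Z, kind) {
  switch(kind,
         relu = pmax(Z, 0),
         linear = Z,
         sigmoid = 1 / (1 + exp(-Z)),
         stop("unknown activation: ", kind))
}

.act_grad <- function(Z, A, kind) {
  switch(kind,
         relu = (Z > 0) * 1,
         linear = 1,
         sigmoid = A * (1 - A),
         stop("unknown activation: ", kind))
}

# Forward pass; returns the output matrix, optionally with the per-layer
# pre-activations/activations needed for backprop.
nn_forward <- function(net, X, activation, output_activation, keep = FALSE) {
  L <- length(net$W)
  A <- X
  Zs <- if (keep) vector("list", L) else NULL
  As <- if (keep) vector("list", L + 1L) else NULL
  if (keep) As[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- sweep(A %*% net$W[[l]], 2, net$b[[l]], "+")
    A <- .act(Z, if (l < L) activation else output_activation)
    if (keep) {
      Zs[[l]] <- Z
      As[[l + 1L]] <- A
    }
  }
  if (keep) list(out = A, Zs = Zs, As = As) else A
}

# One Adam step over accumulated gradients (in place on the returned net).
.adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$dW[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$dW[[l]]^2
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$db[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$db[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    net$b[[l]] <- net$b[[l]] - lr * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

# Gradient of the loss w.r.t. the output pre-activation. For bce+sigmoid the
# two derivatives combine into (A - Y); for mae the subgradient sign(A - Y)
# is used (sign(0) = 0).
.output_delta <- function(A, Y, loss, output_activation, Zs_last) {
  n <- nrow(A)
  if (loss == "bce") {
    if (output_activation != "sigmoid")
      stop("binary cross-entropy requires a sigmoid output")
    (A - Y) / n
  } else if (loss == "mae") {
    dA <- sign(A - Y) / (n * ncol(A))
    dA * .act_grad(Zs_last, A, output_activation)
  } else if (loss == "mse") {
    dA <- 2 * (A - Y) / (n * ncol(A))
    dA * .act_grad(Zs_last, A, output_activation)
  } else {
    stop("unknown loss: ", loss)
  }
}

nn_loss <- function(A, Y, loss) {
  if (loss == "mae") return(mean(abs(A - Y)))
  if (loss == "mse") return(mean((A - Y)^2))
  if (loss == "bce") {
    p <- pmin(pmax(A, 1e-12), 1 - 1e-12)
    return(-mean(Y * log(p) + (1 - Y) * log(1 - p)))
  }
  stop("unknown loss: ", loss)
}

# Train a dense network by mini-batch Adam. X: n x d input, Y: n x k target.
# Returns the fitted net (weights/biases + the training meta-data).
nn_train <- function(X, Y, layer_sizes,
                     activation = "relu", output_activation = "linear",
                     loss = "mae", lr = 0.01, epochs = 100L, batch_size = 32L,
                     seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y),
            ncol(X) == layer_sizes[1L],
            ncol(Y) == layer_sizes[length(layer_sizes)])
  n <- nrow(X)
  net <- nn_init(layer_sizes, seed = derive_seed(seed, 1L))
  state <- list(
    t = 0L,
    mW = lapply(net$W, function(w) w * 0), vW = lapply(net$W, function(w) w * 0),
    mb = lapply(net$b, function(b) b * 0), vb = lapply(net$b, function(b) b * 0)
  )
  batch_size <- max(1L, min(as.integer(batch_size), n))
  L <- length(net$W)
  with_seed(derive_seed(seed, 2L), {
    for (ep in seq_len(epochs)) {
      idx <- if (batch_size < n) sample.int(n) else seq_len(n)
      starts <- seq(1L, n, by = batch_size)
      for (s in starts) {
        rows <- idx[s:min(s + batch_size - 1L, n)]
        fw <- nn_forward(net, X[rows, , drop = FALSE], activation, output_activation,
                         keep = TRUE)
        delta <- .output_delta(fw$out, Y[rows, , drop = FALSE], loss,
                               output_activation, fw$Zs[[L]])
        dW <- vector("list", L); db <- vector("list", L)
        for (l in rev(seq_len(L))) {
          dW[[l]] <- crossprod(fw$As[[l]], delta)
          db[[l]] <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(net$W[[l]])) *
              .act_grad(fw$Zs[[l - 1L]], fw$As[[l]], activation)
          }
        }
        upd <- .adam_step(net, list(dW = dW, db = db), state, lr)
        net <- upd$net; state <- upd$state
      }
    }
  })
  net$activation <- activation
  net$output_activation <- output_activation
  net$loss <- loss
  net$seed <- seed
  net
}

nn_predict <- function(net, X) {
  nn_forward(net, as.matrix(X), net$activation, net$output_activation)
}
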