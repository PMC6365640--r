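#' Fully-connected network specification
#'
#' Describes a feed-forward multilayer perceptron: input width, hidden layer
#' widths and output width. Hidden layers use a rectified-linear activation;
#' the output layer is linear (a softmax is applied downstream where
#' probabilities are needed).
#'
#' @param input_dim integer, number of input features.
#' @param hidden_dims integer vector of hidden-layer widths.
#' @param output_dim integer, number of outputs (K actions, or 1 for a
#'   reward regression).
#' @param activation hidden-layer nonlinearity; only `"relu"` is provided.
#' @return an object of class `mlp_spec`.
#' @export
mlp_spec <- function(input_dim, hidden_dims, output_dim, activation = "relu") {
  stopifnot(input_dim >= 1, output_dim >= 1, all(hidden_dims >= 1))
  activation <- match.arg(activation, "relu")
  structure(
    list(input_dim = as.integer(input_dim),
         hidden_dims = as.integer(hidden_dims),
         output_dim = as.integer(output_dim),
         activation = activation),
    class = "mlp_spec")
}

#' @export
print.mlp_spec <- function(x, ...) {
  cat("MLP spec:", paste(c(x$input_dim, x$hidden_dims, x$output_dim),
                         collapse = " -> "),
      sprintf("(%s hidden activation)\n", x$activation))
  invisible(x)
}

layer_dims <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_dims, spec$output_dim)
  list(from = dims[-length(dims)], to = dims[-1])
}

# Glorot-uniform initialization; consumes the current RNG stream.
mlp_init <- function(spec) {
  d <- layer_dims(spec)
  W <- vector("list", length(d$from))
  b <- vector("list", length(d$from))
  for (l in seq_along(d$from)) {
    lim <- sqrt(6 / (d$from[l] + d$to[l]))
    W[[l]] <- matrix(stats::runif(d$from[l] * d$to[l], -lim, lim),
                     d$from[l], d$to[l])
    b[[l]] <- numeric(d$to[l])
  }
  structure(list(spec = spec, W = W, b = b), class = "mlp_net")
}

# Forward pass. X is n x input_dim. Returns the linear output (n x K) and,
# when keep = TRUE, the per-layer activations needed for backprop.
mlp_forward <- function(net, X, keep = FALSE) {
  A <- list(X)
  H <- X
  L <- length(net$W)
  for (l in seq_len(L)) {
    Z <- H %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], "+")
    H <- if (l < L) pmax(Z, 0) else Z
    if (keep) A[[l + 1L]] <- H
  }
  if (keep) list(out = H, acts = A) else H
}

# Backward pass from the gradient of the loss wrt the linear output
# (d_out, n x K). Returns gradients congruent with net$W / net$b.
mlp_backward <- function(net, acts, d_out) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- d_out
  for (l in L:1) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(net$W[[l]])
      delta[acts[[l]] <= 0] <- 0   # relu gate
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(net) {
  zeros <- function(p) if (is.matrix(p)) p * 0 else numeric(length(p))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros),
       t = 0L)
}

adam_step <- function(net, grads, state, eta,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      eta * (state$mW[[l]] / bc1) / (sqrt(state$vW[[l]] / bc2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      eta * (state$mb[[l]] / bc1) / (sqrt(state$vb[[l]] / bc2) + eps)
  }
  list(net = net, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Supervised training loop shared by the classification (softmax
# cross-entropy) and regression (squared error) networks. y is an integer
# class vector (1..K) for "cross_entropy", a numeric vector/matrix for "mse".
# Early stopping watches validation loss with the given patience.
mlp_train <- function(X, y, spec, loss = c("cross_entropy", "mse"),
                      eta = 1e-4, epochs = 200, batch_size = 32,
                      validation_fraction = 0.1, patience = 20,
                      weight_decay = 0, seed = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= batch_size)
  if (!is.null(seed)) set.seed(seed)

  if (loss == "cross_entropy") {
    y <- as.integer(y)
    if (any(y < 1L | y > spec$output_dim))
      stop("class label outside 1..K (K = ", spec$output_dim, ")")
  } else {
    y <- as.matrix(y)
    stopifnot(ncol(y) == spec$output_dim)
  }

  n_val <- if (validation_fraction > 0) max(1L, floor(n * validation_fraction)) else 0L
  perm <- sample.int(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- if (n_val > 0) perm[-seq_len(n_val)] else perm
  if (length(tr_idx) < batch_size) { tr_idx <- perm; val_idx <- integer(0) }

  Xtr <- X[tr_idx, , drop = FALSE]
  Xval <- X[val_idx, , drop = FALSE]
  ytr <- if (loss == "cross_entropy") y[tr_idx] else y[tr_idx, , drop = FALSE]
  yval <- if (loss == "cross_entropy") y[val_idx] else y[val_idx, , drop = FALSE]

  net <- mlp_init(spec)
  opt <- adam_state(net)
  ntr <- nrow(Xtr)
  steps <- max(1L, ceiling(ntr / batch_size))

  eval_loss <- function(net, X, y) {
    if (nrow(X) == 0) return(NA_real_)
    out <- mlp_forward(net, X)
    if (loss == "cross_entropy") {
      P <- softmax_rows(out)
      -mean(log(pmax(P[cbind(seq_len(nrow(X)), y)], 1e-12)))
    } else {
      mean((out - y)^2)
    }
  }

  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  best_val <- Inf
  best_net <- net
  stall <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample.int(ntr)
    ep_loss <- 0
    for (s in seq_len(steps)) {
      idx <- ord[((s - 1L) * batch_size + 1L):min(s * batch_size, ntr)]
      Xb <- Xtr[idx, , drop = FALSE]
      fw <- mlp_forward(net, Xb, keep = TRUE)
      m <- length(idx)
      if (loss == "cross_entropy") {
        yb <- ytr[idx]
        P <- softmax_rows(fw$out)
        ep_loss <- ep_loss + -mean(log(pmax(P[cbind(seq_len(m), yb)], 1e-12)))
        d_out <- P
        d_out[cbind(seq_len(m), yb)] <- d_out[cbind(seq_len(m), yb)] - 1
        d_out <- d_out / m
      } else {
        yb <- ytr[idx, , drop = FALSE]
        resid <- fw$out - yb
        ep_loss <- ep_loss + mean(resid^2)
        d_out <- 2 * resid / length(resid)
      }
      grads <- mlp_backward(net, fw$acts, d_out)
      if (weight_decay > 0)
        for (l in seq_along(grads$W))
          grads$W[[l]] <- grads$W[[l]] + weight_decay * net$W[[l]]
      upd <- adam_step(net, grads, opt, eta)
      net <- upd$net
      opt <- upd$state
    }
    tr_loss <- ep_loss / steps
    vl <- eval_loss(net, Xval, yval)
    log <- rbind(log, data.frame(epoch = ep, train_loss = tr_loss, val_loss = vl))
    if (!is.finite(tr_loss)) stop("non-finite training loss at epoch ", ep)
    watch <- if (is.na(vl)) tr_loss else vl
    if (watch < best_val - 1e-8) {
      best_val <- watch
      best_net <- net
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    if (verbose) message(sprintf("epoch %d  train %.5f  val %.5f", ep, tr_loss, vl))
  }
  list(net = best_net, log = log)
}
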