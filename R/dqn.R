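#' @title Offline deep Q-learning
#' @description Replay buffer, Q-network with a slowly tracked target
#'   network, temporal-difference training on logged transitions only (no
#'   environment interaction — on-policy data collection is impossible on
#'   actual patients), and greedy recommendation restricted to a screened
#'   admissible action set.
#' @name dqn_core
NULL

#' Hyperparameters for network training
#'
#' Defaults are the Q-learning configuration; the supervised trainers
#' ([train_expert_predictor()], [train_reward_predictor()]) override
#' `eta`, `batch_size`, `epochs` and `weight_decay` in their own default
#' arguments.
#'
#' @param gamma discount rate in (0, 1] (default 0.99).
#' @param tau target-network soft-update rate in (0, 1] (default 0.01).
#' @param eta learning rate (default 1e-3, the Q-network setting;
#'   supervised networks use 1e-4).
#' @param buffer_capacity replay buffer size (default 20000).
#' @param batch_size mini-batch size (default 256 for temporal-difference
#'   training, where large batches average the bootstrap noise that the
#'   max operator would otherwise amplify; supervised networks use 32).
#' @param epochs number of passes over the offline dataset (default 100;
#'   training stops earlier on a loss plateau).
#' @param patience epochs per plateau-detection window.
#' @param weight_decay L2 penalty on the weights (default 1e-3 for the
#'   Q-network, limiting memorization of nuisance baseline features; 0
#'   for supervised networks).
#' @param seed integer seed controlling initialization and sampling.
#' @return an object of class `dtr_hyper`.
#' @export
dtr_hyper <- function(gamma = 0.99, tau = 0.01, eta = 1e-3,
                      buffer_capacity = 20000, batch_size = 256,
                      epochs = 100, patience = 15, weight_decay = 1e-3,
                      seed = 1L) {
  stopifnot(gamma > 0, gamma <= 1, tau > 0, tau <= 1, eta > 0,
            buffer_capacity >= 1, batch_size >= 1, epochs >= 1,
            weight_decay >= 0)
  structure(list(gamma = gamma, tau = tau, eta = eta,
                 buffer_capacity = as.integer(buffer_capacity),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "dtr_hyper")
}

#' Bounded FIFO replay buffer
#'
#' Stores transition tuples up to `capacity`; pushing beyond capacity
#' discards the oldest samples first.
#'
#' @param capacity maximum number of stored transitions (default 20000).
#' @return an object of class `replay_buffer` (environment-backed).
#' @export
replay_buffer <- function(capacity = 20000) {
  stopifnot(capacity >= 1)
  e <- new.env(parent = emptyenv())
  e$capacity <- as.integer(capacity)
  e$s <- NULL; e$a <- integer(0); e$r <- numeric(0)
  e$s_next <- NULL; e$terminal <- logical(0)
  e$next_slot <- 1L   # ring-buffer write head
  e$size <- 0L
  class(e) <- "replay_buffer"
  e
}

#' Number of transitions currently stored
#' @param buffer a [replay_buffer()].
#' @export
buffer_size <- function(buffer) buffer$size

#' Push transitions into a replay buffer
#'
#' @param buffer a [replay_buffer()].
#' @param transitions a [transition_set()].
#' @return the buffer, invisibly.
#' @export
buffer_push <- function(buffer, transitions) {
  n <- nrow(transitions$s)
  if (n == 0) return(invisible(buffer))
  if (is.null(buffer$s)) {
    d <- ncol(transitions$s)
    buffer$s <- matrix(NA_real_, buffer$capacity, d)
    buffer$s_next <- matrix(NA_real_, buffer$capacity, d)
    buffer$a <- integer(buffer$capacity)
    buffer$r <- numeric(buffer$capacity)
    buffer$terminal <- logical(buffer$capacity)
  }
  for (i in seq_len(n)) {
    j <- buffer$next_slot
    buffer$s[j, ] <- transitions$s[i, ]
    buffer$a[j] <- transitions$a[i]
    buffer$r[j] <- transitions$r[i]
    buffer$s_next[j, ] <- transitions$s_next[i, ]
    buffer$terminal[j] <- transitions$terminal[i]
    buffer$next_slot <- if (j == buffer$capacity) 1L else j + 1L
    buffer$size <- min(buffer$size + 1L, buffer$capacity)
  }
  invisible(buffer)
}

#' Extract the stored transitions (oldest first)
#' @param buffer a [replay_buffer()].
#' @return a [transition_set()].
#' @export
buffer_contents <- function(buffer) {
  if (buffer$size == 0) stop("replay buffer is empty")
  idx <- if (buffer$size < buffer$capacity) seq_len(buffer$size)
         else c(seq(buffer$next_slot, buffer$capacity),
                if (buffer$next_slot > 1L) seq_len(buffer$next_slot - 1L))
  transition_set(s = buffer$s[idx, , drop = FALSE], a = buffer$a[idx],
                 r = buffer$r[idx],
                 s_next = buffer$s_next[idx, , drop = FALSE],
                 terminal = buffer$terminal[idx])
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat("Replay buffer:", x$size, "/", x$capacity, "transitions\n")
  invisible(x)
}

#' Initialize a Q-network and its target copy
#'
#' The target network starts as an exact copy of the Q-network (same
#' initialization) and thereafter tracks it slowly via [soft_update()].
#'
#' @param spec an [mlp_spec()]; the default Q-network architecture has two
#'   hidden layers of 32 and 64 units.
#' @param seed integer seed for weight initialization.
#' @return list with elements `q` and `target`, both `mlp_net`s.
#' @export
init_networks <- function(spec, seed = 1L) {
  set.seed(seed)
  q <- mlp_init(spec)
  list(q = q, target = q)
}

#' Soft target-network update
#'
#' Moves the target weights slowly toward the Q-network weights,
#' elementwise `theta' <- tau * theta + (1 - tau) * theta'`, which
#' stabilizes temporal-difference learning.
#'
#' @param net the Q-network (`mlp_net`) supplying `theta`.
#' @param target_net the target network to update.
#' @param tau update rate in `[0, 1]`; 1 copies the network outright, 0
#'   leaves the target unchanged.
#' @return the updated target network.
#' @export
soft_update <- function(net, target_net, tau = 0.01) {
  stopifnot(tau >= 0, tau <= 1)
  if (length(net$W) != length(target_net$W))
    stop("network shapes do not match")
  for (l in seq_along(net$W)) {
    if (!all(dim(net$W[[l]]) == dim(target_net$W[[l]])))
      stop("network shapes do not match at layer ", l)
    target_net$W[[l]] <- tau * net$W[[l]] + (1 - tau) * target_net$W[[l]]
    target_net$b[[l]] <- tau * net$b[[l]] + (1 - tau) * target_net$b[[l]]
  }
  target_net
}

#' Temporal-difference targets for a batch of transitions
#'
#' `y_i = r_i` for terminal transitions; otherwise
#' `y_i = r_i + gamma * max_a' Qhat(s'_i, a')`, with `Qhat` the target
#' network.
#'
#' @param batch a [transition_set()].
#' @param target_net the target `mlp_net`.
#' @param gamma discount rate.
#' @return numeric vector of targets.
#' @export
td_targets <- function(batch, target_net, gamma = 0.99) {
  n <- nrow(batch$s)
  if (n == 0) stop("empty batch")
  y <- batch$r
  live <- !batch$terminal
  if (any(live) && gamma > 0) {
    qn <- mlp_forward(target_net, batch$s_next[live, , drop = FALSE])
    y[live] <- y[live] + gamma * apply(qn, 1, max)
  }
  y
}

#' Fit an offline deep Q-network
#'
#' The package's central fitting function. Loads the logged transitions
#' into a bounded FIFO replay buffer, then iterates mini-batch
#' temporal-difference updates: sample transitions uniformly from the
#' buffer, form targets with the slowly tracked target network
#' ([td_targets()]), take an Adam step on the squared TD error of the
#' taken actions, and apply [soft_update()] after every step. Training is
#' purely offline: only the supplied transitions are ever consumed. Fully
#' reproducible for a fixed seed.
#'
#' @param transitions a [transition_set()] of logged experience.
#' @param spec an [mlp_spec()]; defaults to the 2-hidden-layer (32, 64)
#'   architecture sized to the data.
#' @param hyper a [dtr_hyper()].
#' @param codec optional [action_codec()] stored for recommendation.
#' @param verbose print per-epoch loss.
#' @return an object of class `dqn`: the fitted Q-network, target network,
#'   loss log and configuration. Methods: [predict.dqn()], `print`,
#'   `summary`, `plot`, `coef`.
#' @export
train_dqn <- function(transitions, spec = NULL, hyper = dtr_hyper(),
                      codec = NULL, verbose = FALSE) {
  if (!inherits(transitions, "transition_set") || nrow(transitions$s) == 0)
    stop("transitions must be a non-empty transition_set")
  n <- nrow(transitions$s)
  if (n < hyper$batch_size)
    stop("need at least batch_size (", hyper$batch_size, ") transitions")
  K <- if (!is.null(codec)) codec$K else max(transitions$a)
  if (any(transitions$a < 1L | transitions$a > K))
    stop("action index outside 1..K")
  if (is.null(spec))
    spec <- mlp_spec(ncol(transitions$s), c(32, 64), K)

  set.seed(hyper$seed)
  nets <- list(q = mlp_init(spec), target = NULL)
  nets$target <- nets$q
  opt <- adam_state(nets$q)

  buffer <- replay_buffer(hyper$buffer_capacity)
  buffer_push(buffer, transitions)
  data <- buffer_contents(buffer)
  m <- nrow(data$s)
  steps <- max(1L, ceiling(m / hyper$batch_size))

  loss_log <- numeric(0)
  for (ep in seq_len(hyper$epochs)) {
    ep_loss <- 0
    for (s in seq_len(steps)) {
      idx <- sample.int(m, hyper$batch_size, replace = TRUE)
      batch <- transition_set(data$s[idx, , drop = FALSE], data$a[idx],
                              data$r[idx],
                              data$s_next[idx, , drop = FALSE],
                              data$terminal[idx])
      y <- td_targets(batch, nets$target, hyper$gamma)
      fw <- mlp_forward(nets$q, batch$s, keep = TRUE)
      pred <- fw$out[cbind(seq_along(idx), batch$a)]
      resid <- pred - y
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop("non-finite TD loss at epoch ", ep, ", step ", s)
      ep_loss <- ep_loss + loss
      d_out <- matrix(0, length(idx), spec$output_dim)
      d_out[cbind(seq_along(idx), batch$a)] <- 2 * resid / length(idx)
      grads <- mlp_backward(nets$q, fw$acts, d_out)
      if (hyper$weight_decay > 0)
        for (l in seq_along(grads$W))
          grads$W[[l]] <- grads$W[[l]] + hyper$weight_decay * nets$q$W[[l]]
      upd <- adam_step(nets$q, grads, opt, hyper$eta)
      nets$q <- upd$net
      opt <- upd$state
      nets$target <- soft_update(nets$q, nets$target, hyper$tau)
    }
    ep_loss <- ep_loss / steps
    loss_log <- c(loss_log, ep_loss)
    if (verbose) message(sprintf("epoch %3d  TD loss %.5f", ep, ep_loss))
    # plateau stop on trailing windows: the TD loss first grows while the
    # bootstrapped values warm up, so a global-best rule would stop during
    # warm-up. Stop only when the two most recent windows are flat
    # relative to each other (neither still rising nor still falling).
    p <- hyper$patience
    if (ep >= 2L * p) {
      recent <- mean(loss_log[(ep - p + 1L):ep])
      before <- mean(loss_log[(ep - 2L * p + 1L):(ep - p)])
      if (abs(recent - before) < 0.01 * before) break
    }
  }

  structure(list(q = nets$q, target = nets$target, spec = spec,
                 hyper = hyper, codec = codec, loss = loss_log,
                 n_transitions = n),
            class = "dqn")
}

#' Predicted action values
#'
#' @param object a fitted [train_dqn()] model.
#' @param newdata numeric state vector or matrix (rows = states).
#' @param ... unused.
#' @return matrix of Q-values, one row per state, one column per action.
#' @export
predict.dqn <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(X) != object$spec$input_dim)
    stop("state dimension ", ncol(X), " does not match network input ",
         object$spec$input_dim)
  mlp_forward(object$q, X)
}

#' @export
print.dqn <- function(x, ...) {
  cat("Offline deep Q-network\n")
  cat("  architecture:",
      paste(c(x$spec$input_dim, x$spec$hidden_dims, x$spec$output_dim),
            collapse = " -> "), "\n")
  cat(sprintf("  trained on %d transitions, %d epochs, final TD loss %.5f\n",
              x$n_transitions, length(x$loss), utils::tail(x$loss, 1)))
  cat(sprintf("  gamma = %g, tau = %g, eta = %g, buffer = %d\n",
              x$hyper$gamma, x$hyper$tau, x$hyper$eta,
              x$hyper$buffer_capacity))
  invisible(x)
}

#' @export
summary.dqn <- function(object, ...) {
  print(object)
  cat("  TD loss trajectory (first/last 5 epochs):\n")
  n <- length(object$loss)
  show <- unique(c(seq_len(min(5, n)), seq(max(1, n - 4), n)))
  for (i in show)
    cat(sprintf("    epoch %3d: %.5f\n", i, object$loss[i]))
  invisible(object)
}

#' @export
plot.dqn <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "l",
                 xlab = "epoch", ylab = "mean TD loss",
                 main = "Offline DQN training", ...)
  invisible(x)
}

#' @export
coef.dqn <- function(object, ...) {
  list(W = object$q$W, b = object$q$b)
}

#' Greedy recommendation restricted to an admissible action set
#'
#' Returns the admissible action with the highest predicted Q-value for
#' the given state; ties are broken toward the lower action index. The
#' admissible set typically comes from [screen_actions()], which removes
#' actions experts would essentially never take (their value estimates are
#' too variable to trust).
#'
#' @param qnet a fitted [train_dqn()] model.
#' @param state numeric state vector.
#' @param admissible integer vector of admissible action indices (1..K);
#'   defaults to all actions.
#' @return the recommended action index.
#' @export
recommend <- function(qnet, state, admissible = NULL) {
  q <- as.numeric(predict(qnet, state))
  if (is.null(admissible)) admissible <- seq_along(q)
  if (length(admissible) == 0) stop("admissible action set is empty")
  if (any(admissible < 1 | admissible > length(q)))
    stop("admissible index outside 1..K")
  admissible <- sort(as.integer(admissible))   # ties: lower index wins
  admissible[which.max(q[admissible])]
}
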