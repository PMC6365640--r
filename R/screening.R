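#' @title Expert-action prediction and screening
#' @description Supervised networks that imitate the logged expert
#'   treatment decisions (initial conditioning, GVHD prophylaxis, and
#'   acute/chronic GVHD treatment) and screen the drug-combination action
#'   space down to the top-N choices experts would plausibly take. Q-value
#'   estimates for never-taken actions are unreliable, so downstream
#'   recommendations are restricted to the screened set.
#' @name screening_net
NULL

#' Default screening-network architecture
#'
#' Two hidden layers of 16 and 32 units. GVHD-treatment screeners take the
#' 8-feature state; the initial-treatment networks take 9 inputs (the
#' stage index is appended).
#'
#' @param input_dim network input width (default 8).
#' @param output_dim number of action classes K.
#' @export
screening_spec <- function(input_dim = 8, output_dim) {
  mlp_spec(input_dim, c(16, 32), output_dim)
}

#' Train an expert-action predictor
#'
#' Fits a multiclass network by softmax cross-entropy with the Adam
#' optimizer (learning rate 1e-4 by default) to predict the expert's drug
#' combination from the patient state. Training is reproducible for a
#' fixed seed.
#'
#' @param states numeric matrix of encoded states (rows = examples).
#' @param actions integer vector of expert action indices (1..K).
#' @param spec an [mlp_spec()]; defaults to [screening_spec()] sized to
#'   the data.
#' @param hyper a [dtr_hyper()]; `eta` defaults to 1e-4 for supervised
#'   networks.
#' @param codec optional [action_codec()] stored with the model.
#' @return an object of class `expert_net` with the fitted weights and the
#'   per-epoch loss log.
#' @export
train_expert_predictor <- function(states, actions, spec = NULL,
                                   hyper = dtr_hyper(eta = 1e-4,
                                                     epochs = 200,
                                                     patience = 20,
                                                     batch_size = 32,
                                                     weight_decay = 0),
                                   codec = NULL) {
  states <- as.matrix(states)
  actions <- as.integer(actions)
  stopifnot(nrow(states) == length(actions))
  if (nrow(states) < hyper$batch_size)
    stop("need at least batch_size (", hyper$batch_size, ") examples")
  K <- if (!is.null(codec)) codec$K else max(actions)
  if (any(actions < 1L | actions > K))
    stop("action index outside 1..K (K = ", K, ")")
  if (is.null(spec)) spec <- screening_spec(ncol(states), K)
  if (spec$output_dim != K)
    stop("spec output_dim (", spec$output_dim, ") must equal K (", K, ")")
  fit <- mlp_train(states, actions, spec, loss = "cross_entropy",
                   eta = hyper$eta, epochs = hyper$epochs,
                   batch_size = hyper$batch_size,
                   patience = hyper$patience,
                   weight_decay = hyper$weight_decay, seed = hyper$seed)
  structure(list(net = fit$net, spec = spec, codec = codec,
                 training_log = fit$log),
            class = "expert_net")
}

#' @export
print.expert_net <- function(x, ...) {
  cat("Expert-action predictor\n  architecture:",
      paste(c(x$spec$input_dim, x$spec$hidden_dims, x$spec$output_dim),
            collapse = " -> "), "\n")
  cat(sprintf("  %d training epochs, final loss %.5f\n",
              nrow(x$training_log),
              utils::tail(x$training_log$train_loss, 1)))
  invisible(x)
}

#' Predicted expert-action probabilities
#'
#' @param model an [train_expert_predictor()] fit.
#' @param state numeric state vector (length `input_dim`) or matrix.
#' @return a probability vector over the K actions (or a matrix, one row
#'   per state); entries are non-negative and sum to 1.
#' @export
predict_action_probabilities <- function(model, state) {
  X <- if (is.matrix(state)) state else matrix(state, nrow = 1)
  if (ncol(X) != model$spec$input_dim)
    stop("state dimension ", ncol(X), " does not match network input ",
         model$spec$input_dim)
  P <- softmax_rows(mlp_forward(model$net, X))
  if (is.matrix(state)) P else as.numeric(P)
}

#' @export
predict.expert_net <- function(object, newdata, type = c("prob", "class"),
                               ...) {
  type <- match.arg(type)
  P <- predict_action_probabilities(object, newdata)
  if (type == "prob") return(P)
  if (is.matrix(P)) apply(P, 1, which.max) else which.max(P)
}

#' Top-N prediction accuracy
#'
#' The fraction of test examples whose true expert action is among the N
#' highest-probability actions predicted by the model — the standard
#' screening accuracy; it is non-decreasing in N and reaches 1 at N = K.
#' Probability ties rank the lower action index first.
#'
#' @param model an [train_expert_predictor()] fit.
#' @param states test state matrix.
#' @param actions true expert action indices.
#' @param N number of top choices allowed, 1..K.
#' @return accuracy in `[0, 1]`.
#' @export
top_n_accuracy <- function(model, states, actions, N) {
  states <- as.matrix(states)
  if (nrow(states) == 0) stop("empty test set")
  K <- model$spec$output_dim
  stopifnot(N >= 1, N <= K, length(actions) == nrow(states))
  P <- predict_action_probabilities(model, states)
  if (!is.matrix(P)) P <- matrix(P, nrow = 1)
  hits <- vapply(seq_len(nrow(P)), function(i) {
    top <- order(-P[i, ], seq_len(K))[seq_len(N)]
    actions[i] %in% top
  }, logical(1))
  mean(hits)
}

#' Screen the action space to the top-N expert choices
#'
#' @param model an [train_expert_predictor()] fit.
#' @param state numeric state vector.
#' @param N number of actions to keep, 1..K.
#' @return integer vector of the N most probable action indices, in
#'   descending probability (ties toward the lower index). Screening sets
#'   are nested: the top-N set is always contained in the top-(N+1) set.
#' @export
screen_actions <- function(model, state, N) {
  K <- model$spec$output_dim
  if (N > K) stop("N (", N, ") exceeds the number of actions K (", K, ")")
  stopifnot(N >= 1)
  p <- predict_action_probabilities(model, state)
  order(-p, seq_len(K))[seq_len(N)]
}
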