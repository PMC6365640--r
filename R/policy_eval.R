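#' @title Off-policy evaluation protocols
#' @description The two evaluation routes for a learned treatment policy on
#'   held-out registry data: (i) matched reward — the mean observed outcome
#'   among records whose logged expert action coincides with the policy's
#'   recommendation, with percentile bootstrap confidence intervals — and
#'   (ii) counterfactual value — the mean predicted outcome of the policy's
#'   recommendations under a separately trained reward model. Includes the
#'   one-size-fits-all and random-forest comparison baselines.
#' @name policy_eval
NULL

#' Construct a treatment policy
#'
#' A policy maps an encoded patient state (and decision stage) to an action
#' index 1..K.
#'
#' @param fun function `(state, stage) -> action index`.
#' @param label descriptive text.
#' @return an object of class `dtr_policy`.
#' @export
dtr_policy <- function(fun, label = "policy") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, label = label), class = "dtr_policy")
}

#' @export
print.dtr_policy <- function(x, ...) {
  cat("Treatment policy:", x$label, "\n")
  invisible(x)
}

#' Greedy DQN policy, optionally screened by an expert model
#'
#' Wraps a fitted Q-network as a [dtr_policy()]: the recommendation is the
#' admissible action of highest predicted value. When an expert predictor
#' is supplied, the admissible set is its top-N screened actions.
#'
#' @param qnet a fitted [train_dqn()] model.
#' @param expert optional [train_expert_predictor()] fit used for
#'   screening.
#' @param N screening width (required with `expert`).
#' @export
dqn_policy <- function(qnet, expert = NULL, N = NULL) {
  if (!is.null(expert) && is.null(N))
    stop("N must be given when screening with an expert model")
  dtr_policy(function(state, stage) {
    adm <- if (is.null(expert)) NULL else screen_actions(expert, state, N)
    recommend(qnet, state, adm)
  }, label = if (is.null(expert)) "DQN (greedy)"
     else sprintf("DQN (screened, top-%d)", N))
}

#' Uniform-random policy
#'
#' Draws an action uniformly at each query from the current RNG stream;
#' seed the RNG before evaluation for reproducibility.
#'
#' @param K number of actions.
#' @export
random_policy <- function(K) {
  stopifnot(K >= 1)
  dtr_policy(function(state, stage) sample.int(K, 1L),
             label = "uniform random")
}

#' One-size-fits-all policy
#'
#' The constant policy that administers the most frequently observed
#' treatment to every patient (ties toward the lower combination index).
#'
#' @param train_trajectories list of [trajectory()] objects.
#' @param codec an [action_codec()].
#' @param stage optional decision stage index; `NULL` pools all stages.
#' @export
one_size_fits_all_policy <- function(train_trajectories, codec,
                                     stage = NULL) {
  counts <- integer(codec$K)
  for (tr in train_trajectories) {
    for (r in tr$records) {
      if (is.null(r$action)) next
      if (!is.null(stage) && r$stage_index != stage) next
      a <- encode_action(codec, r$action)
      counts[a] <- counts[a] + 1L
    }
  }
  if (sum(counts) == 0)
    stop("no observed actions", if (!is.null(stage))
      paste0(" at stage ", stage))
  modal <- which.max(counts)   # ties: lower index
  dtr_policy(function(state, stage) modal,
             label = sprintf("one-size-fits-all (combo %d)", modal))
}

#' Random-forest reward-regression policy
#'
#' Fits a random forest regressing the observed immediate reward on the
#' state features plus the action index, then recommends the action with
#' the highest predicted reward — a one-step fitted-value analogue used as
#' an off-the-shelf comparison baseline.
#'
#' @param train_transitions a [transition_set()].
#' @param codec an [action_codec()].
#' @param seed integer seed for the forest.
#' @param ntree number of trees.
#' @export
random_forest_policy <- function(train_transitions, codec, seed = 1L,
                                 ntree = 200) {
  stopifnot(inherits(train_transitions, "transition_set"))
  n <- nrow(train_transitions$s)
  if (n == 0) stop("no transitions to fit the forest on")
  X <- data.frame(train_transitions$s,
                  action = factor(train_transitions$a,
                                  levels = seq_len(codec$K)))
  y <- train_transitions$r
  set.seed(seed)
  if (stats::var(y) == 0) {
    const <- y[1]
    fit <- NULL
  } else {
    # rewards take few distinct values; regression on them is intentional
    fit <- suppressWarnings(
      randomForest::randomForest(x = X, y = y, ntree = ntree))
    const <- NULL
  }
  dtr_policy(function(state, stage) {
    if (!is.null(const)) return(1L)   # degenerate: constant reward
    newd <- data.frame(matrix(rep(state, codec$K), nrow = codec$K,
                              byrow = TRUE),
                       action = factor(seq_len(codec$K),
                                       levels = seq_len(codec$K)))
    names(newd) <- names(X)
    pred <- stats::predict(fit, newd)
    which.max(pred)                   # ties: lower index
  }, label = "random forest")
}

#' Matched reward of a policy on held-out trajectories
#'
#' Implements the registry evaluation protocol: walk every decision record
#' of the test trajectories, and wherever the logged expert action equals
#' the policy's recommendation, collect the reward observed on arrival in
#' the next state. Returns the mean of the collected rewards, the number
#' of matched records and the rewards themselves (for bootstrapping).
#' `policy = "observed"` scores the experts' own treatment (everything
#' matches). With `granularity = "trajectory"` a patient only counts when
#' every decision matches, and contributes the mean of their arrival
#' rewards.
#'
#' @param policy a [dtr_policy()] or `"observed"`.
#' @param test_trajectories list of [trajectory()] objects.
#' @param codec an [action_codec()].
#' @param schema a [state_schema()].
#' @param stage_filter optional decision stage indices to evaluate.
#' @param granularity `"record"` (default) or `"trajectory"`.
#' @return list with `mean_reward`, `matched`, `rewards`.
#' @export
matched_reward <- function(policy, test_trajectories, codec,
                           schema = state_schema(), stage_filter = NULL,
                           granularity = c("record", "trajectory")) {
  granularity <- match.arg(granularity)
  if (length(test_trajectories) == 0) stop("empty test set")
  observed <- identical(policy, "observed")
  if (!observed) stopifnot(inherits(policy, "dtr_policy"))
  rewards <- numeric(0)
  matched <- 0L
  for (tr in test_trajectories) {
    n <- length(tr$records)
    if (n < 2) next
    traj_rewards <- numeric(0)
    traj_all_match <- TRUE
    traj_any <- FALSE
    for (i in seq_len(n - 1L)) {
      src <- tr$records[[i]]
      dst <- tr$records[[i + 1L]]
      if (!is.null(stage_filter) && !src$stage_index %in% stage_filter) next
      if (is.null(src$action)) next
      traj_any <- TRUE
      obs_a <- encode_action(codec, src$action)
      rec_a <- if (observed) obs_a else {
        st <- encode_state(tr$baseline, src$status, src$stage_index, schema)
        policy$fun(st, src$stage_index)
      }
      if (obs_a == rec_a) {
        traj_rewards <- c(traj_rewards, dst$reward_in)
      } else {
        traj_all_match <- FALSE
      }
    }
    if (granularity == "record") {
      rewards <- c(rewards, traj_rewards)
      matched <- matched + length(traj_rewards)
    } else if (traj_any && traj_all_match) {
      rewards <- c(rewards, mean(traj_rewards))
      matched <- matched + 1L
    }
  }
  if (matched == 0L)
    stop("no matched patients: the policy's recommendations never ",
         "coincide with the observed treatment")
  list(mean_reward = mean(rewards), matched = matched, rewards = rewards)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement `B` times (default 5000) and
#' returns the percentile interval of the bootstrap distribution of the
#' mean. Deterministic for a fixed seed.
#'
#' @param values numeric vector.
#' @param B number of bootstrap resamples.
#' @param level confidence level in (0, 1).
#' @param seed integer seed.
#' @return list with `lower`, `upper`, `level`, `B`.
#' @export
bootstrap_ci <- function(values, B = 5000, level = 0.95, seed = 1L) {
  stopifnot(length(values) >= 1, B >= 1, level > 0, level < 1)
  set.seed(seed)
  n <- length(values)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  means <- .colMeans(matrix(values[idx], nrow = n), n, B)
  alpha <- (1 - level) / 2
  qs <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE,
                        type = 7)
  list(lower = qs[1], upper = qs[2], level = level, B = B)
}

#' Train a reward-prediction network
#'
#' Fits a regression network mapping (state, one-hot action) to the
#' immediate reward by squared-error loss (Adam, learning rate 1e-4
#' default). Used to estimate counterfactual rewards for recommendations
#' that were rarely or never observed.
#'
#' @param transitions a [transition_set()].
#' @param K number of actions (defaults to the maximum observed index).
#' @param spec an [mlp_spec()]; default hidden layers (16, 32), scalar
#'   output.
#' @param hyper a [dtr_hyper()].
#' @return an object of class `reward_net`.
#' @export
train_reward_predictor <- function(transitions, K = NULL, spec = NULL,
                                   hyper = dtr_hyper(eta = 1e-4,
                                                     epochs = 200,
                                                     patience = 20,
                                                     batch_size = 32,
                                                     weight_decay = 0)) {
  stopifnot(inherits(transitions, "transition_set"))
  n <- nrow(transitions$s)
  if (n == 0) stop("no transitions to train on")
  if (n < hyper$batch_size)
    stop("need at least batch_size (", hyper$batch_size, ") transitions")
  if (is.null(K)) K <- max(transitions$a)
  d <- ncol(transitions$s)
  if (is.null(spec)) spec <- mlp_spec(d + K, c(16, 32), 1)
  A <- matrix(0, n, K)
  A[cbind(seq_len(n), transitions$a)] <- 1
  X <- cbind(transitions$s, A)
  fit <- mlp_train(X, matrix(transitions$r, ncol = 1), spec, loss = "mse",
                   eta = hyper$eta, epochs = hyper$epochs,
                   batch_size = hyper$batch_size,
                   patience = hyper$patience,
                   weight_decay = hyper$weight_decay, seed = hyper$seed)
  structure(list(net = fit$net, spec = spec, K = K, state_dim = d,
                 training_log = fit$log),
            class = "reward_net")
}

#' @export
print.reward_net <- function(x, ...) {
  cat("Reward-prediction network\n  input: state(", x$state_dim,
      ") + one-hot action(", x$K, ")\n", sep = "")
  cat(sprintf("  %d training epochs, final loss %.5f\n",
              nrow(x$training_log),
              utils::tail(x$training_log$train_loss, 1)))
  invisible(x)
}

#' Predicted immediate reward for state-action pairs
#'
#' @param model a [train_reward_predictor()] fit.
#' @param states state matrix (or single vector).
#' @param actions integer action indices, recycled to the number of states.
#' @return numeric predictions clipped to `[0, 1]`.
#' @export
predict_reward <- function(model, states, actions) {
  S <- if (is.matrix(states)) states else matrix(states, nrow = 1)
  if (ncol(S) != model$state_dim)
    stop("state dimension mismatch")
  n <- nrow(S)
  actions <- rep_len(as.integer(actions), n)
  if (any(actions < 1L | actions > model$K))
    stop("action index outside 1..K")
  A <- matrix(0, n, model$K)
  A[cbind(seq_len(n), actions)] <- 1
  pred <- as.numeric(mlp_forward(model$net, cbind(S, A)))
  pmin(pmax(pred, 0), 1)
}

#' @export
predict.reward_net <- function(object, newdata, actions, ...) {
  predict_reward(object, newdata, actions)
}

# Resolve a reward model that may be a fitted reward_net or an exact
# function(state, action) -> reward (used when the true reward is known).
reward_fun <- function(reward_model) {
  if (inherits(reward_model, "reward_net"))
    function(state, action) predict_reward(reward_model, state, action)
  else if (is.function(reward_model)) reward_model
  else stop("reward_model must be a reward_net or a function")
}

#' Counterfactual value of a policy under a reward model
#'
#' The mean, over the test states, of the reward model's prediction at the
#' policy's recommended action — an estimate of the expected outcome had
#' the recommendations actually been followed.
#'
#' @param reward_model a [train_reward_predictor()] fit, or an exact
#'   function `(state, action) -> reward`.
#' @param policy a [dtr_policy()].
#' @param test_states state matrix (rows = states).
#' @param stages optional per-state decision stage indices (default 0).
#' @return the mean predicted reward.
#' @export
counterfactual_value <- function(reward_model, policy, test_states,
                                 stages = NULL) {
  S <- if (is.matrix(test_states)) test_states else matrix(test_states,
                                                           nrow = 1)
  if (nrow(S) == 0) stop("empty test state set")
  stopifnot(inherits(policy, "dtr_policy"))
  if (is.null(stages)) stages <- rep(0L, nrow(S))
  rf <- reward_fun(reward_model)
  preds <- vapply(seq_len(nrow(S)), function(i) {
    a <- policy$fun(S[i, ], stages[i])
    rf(S[i, ], a)
  }, numeric(1))
  mean(preds)
}

#' Exclusion baseline: mean reward of everything but the recommendation
#'
#' For each test state, averages the reward model's predictions over all
#' actions except the policy's top recommendation, then averages over
#' states. A policy adds value when its counterfactual value exceeds this
#' baseline.
#'
#' @inheritParams counterfactual_value
#' @param codec an [action_codec()] (supplies K; must be at least 2).
#' @export
baseline_excluding_top <- function(reward_model, test_states, policy,
                                   codec, stages = NULL) {
  if (codec$K < 2)
    stop("the exclusion baseline needs at least 2 actions")
  S <- if (is.matrix(test_states)) test_states else matrix(test_states,
                                                           nrow = 1)
  if (nrow(S) == 0) stop("empty test state set")
  if (is.null(stages)) stages <- rep(0L, nrow(S))
  rf <- reward_fun(reward_model)
  per_state <- vapply(seq_len(nrow(S)), function(i) {
    top <- policy$fun(S[i, ], stages[i])
    others <- setdiff(seq_len(codec$K), top)
    mean(vapply(others, function(a) rf(S[i, ], a), numeric(1)))
  }, numeric(1))
  mean(per_state)
}

#' Wrap the exact DP oracle as a state-vector policy
#'
#' Decodes the clinical status from the first four entries of an encoded
#' state vector and returns the oracle's optimal action, expressed as a
#' codec index. Stages beyond the oracle's horizon use the last stage's
#' rule.
#'
#' @param oracle an [optimal_policy_oracle()] result.
#' @param codec the [action_codec()] in which recommendations are indexed.
#' @export
oracle_policy <- function(oracle, codec) {
  stopifnot(inherits(oracle, "dtr_oracle"))
  cfg <- oracle$config
  H <- nrow(oracle$policy)
  dtr_policy(function(state, stage) {
    sname <- if (state[1] < 0.5) "dead"
             else if (state[4] > 0.5) "relapse"
             else if (state[3] > 0.5) "cgvhd"
             else if (state[2] > 0.5) "agvhd"
             else "healthy"
    if (!sname %in% sim_transient())
      stop("oracle policy queried on a terminal state")
    a_cfg <- oracle_action(oracle, sname, min(stage, H - 1L))
    encode_action(codec, cfg$combos[[a_cfg]])
  }, label = "exact DP oracle")
}

#' Agreement of a policy with the exact DP oracle
#'
#' Walks every decision record of the given trajectories, asks the policy
#' for its recommendation, and compares it with the oracle's optimal
#' action for that record's clinical status and stage. Action indices are
#' aligned through the codec, so the oracle's configuration combos and the
#' codec may enumerate the action space in different orders.
#'
#' @param policy a [dtr_policy()].
#' @param trajectories list of [trajectory()] objects.
#' @param oracle an [optimal_policy_oracle()] result.
#' @param codec the [action_codec()] used by the policy.
#' @param schema a [state_schema()].
#' @return fraction of decision records where the policy's action equals
#'   the oracle's.
#' @export
policy_agreement <- function(policy, trajectories, oracle, codec,
                             schema = state_schema()) {
  stopifnot(inherits(policy, "dtr_policy"), inherits(oracle, "dtr_oracle"))
  cfg <- oracle$config
  hits <- 0L
  total <- 0L
  for (tr in trajectories) {
    for (r in tr$records) {
      if (is.null(r$action)) next
      sname <- status_name_from_flags(r$status)
      if (!sname %in% sim_transient()) next
      if (r$stage_index >= nrow(oracle$policy)) next
      st <- encode_state(tr$baseline, r$status, r$stage_index, schema)
      rec <- policy$fun(st, r$stage_index)
      opt_cfg <- oracle_action(oracle, sname, r$stage_index)
      opt <- encode_action(codec, cfg$combos[[opt_cfg]])
      total <- total + 1L
      if (rec == opt) hits <- hits + 1L
    }
  }
  if (total == 0L) stop("no decision records to compare")
  hits / total
}
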