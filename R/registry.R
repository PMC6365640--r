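#' @title Registry data model for post-transplant trajectories
#' @description Constructors, invariant checks and core operations for
#'   longitudinal registry-style patient trajectories: clinical status flags,
#'   the quality-of-life immediate reward, state encoding, drug-combination
#'   action coding and replay-transition extraction.
#' @name registry_model
NULL

#' Follow-up stage times (days post transplant)
#'
#' Records are collected at transplant and at 100 days, 6 months, 1 year and
#' 2 years. Stage indices 0..4 map onto these days.
#' @export
stage_days <- function() c(0L, 100L, 180L, 365L, 730L)

#' Donor-recipient HLA matching categories
#' @export
donor_relation_levels <- function() {
  c("identical sibling", "other relative", "URD well matched",
    "URD partially matched", "URD mismatched", "other")
}

#' Patient baseline features
#'
#' @param age age at transplant in years, non-negative.
#' @param sex `"male"` or `"female"` (or 0/1).
#' @param comorbidities named or unnamed vector of 0/1 indicators
#'   (diabetes, seizure, hypertension, ...).
#' @param donor_relation one of [donor_relation_levels()].
#' @param donor_sex donor sex, `"male"`/`"female"` (or 0/1).
#' @return an object of class `patient_baseline`.
#' @export
patient_baseline <- function(age, sex, comorbidities, donor_relation,
                             donor_sex) {
  if (!is.numeric(age) || length(age) != 1L || age < 0)
    stop("age must be a single non-negative number")
  sex <- encode_binary(sex, "sex")
  donor_sex <- encode_binary(donor_sex, "donor_sex")
  comorbidities <- as.integer(comorbidities)
  if (any(!comorbidities %in% c(0L, 1L)))
    stop("comorbidities must be 0/1 indicators")
  lv <- donor_relation_levels()
  if (!is.character(donor_relation) || !donor_relation %in% lv)
    stop("unknown category in field 'donor_relation': ",
         deparse(donor_relation))
  structure(list(age = as.numeric(age), sex = sex,
                 comorbidities = comorbidities,
                 donor_relation = donor_relation, donor_sex = donor_sex),
            class = "patient_baseline")
}

encode_binary <- function(x, field) {
  if (is.character(x)) {
    if (!x %in% c("male", "female"))
      stop("unknown category in field '", field, "': ", deparse(x))
    return(as.integer(x == "female"))
  }
  x <- as.integer(x)
  if (!x %in% c(0L, 1L))
    stop("unknown category in field '", field, "': ", deparse(x))
  x
}

#' Clinical status flags at a follow-up stage
#'
#' A dead patient cannot carry GVHD flags; death or relapse is terminal.
#'
#' @param alive,acute_gvhd,chronic_gvhd,relapse logicals.
#' @return an object of class `status_flags`.
#' @export
status_flags <- function(alive, acute_gvhd = FALSE, chronic_gvhd = FALSE,
                         relapse = FALSE) {
  stopifnot(is.logical(alive), is.logical(acute_gvhd),
            is.logical(chronic_gvhd), is.logical(relapse))
  if (!alive && (acute_gvhd || chronic_gvhd))
    stop("a dead patient cannot have GVHD flags set")
  structure(list(alive = alive, acute_gvhd = acute_gvhd,
                 chronic_gvhd = chronic_gvhd, relapse = relapse),
            class = "status_flags")
}

#' Is a status terminal (absorbing)?
#'
#' Death and relapse are terminal: no further treatment decisions occur.
#' @param status a [status_flags()] object.
#' @export
is_terminal_status <- function(status) !status$alive || status$relapse

#' Immediate quality-of-life reward for a clinical status
#'
#' The reward earned on arriving in a status, a heuristic quality-of-life
#' measure on a 0-1 scale: 1 for alive, relapse-free and GVHD-free; 0.8 for
#' alive with acute GVHD; 0.7 for alive with chronic GVHD; 0 for dead.
#' When both GVHD forms are present the chronic (worse) value applies by
#' default. Relapse is terminal and is scored `relapse_reward` (default 0,
#' treating relapse as an absorbing failure like death).
#'
#' @param status a [status_flags()] object.
#' @param both_gvhd which value applies when both GVHD flags are set:
#'   `"chronic"` (0.7, the worse condition, default) or `"acute"` (0.8).
#' @param relapse_reward reward assigned on entering relapse (default 0).
#' @return a number in `[0, 1]`.
#' @export
immediate_reward <- function(status, both_gvhd = c("chronic", "acute"),
                             relapse_reward = 0) {
  both_gvhd <- match.arg(both_gvhd)
  if (!status$alive) return(0)
  if (status$relapse) return(relapse_reward)
  if (status$acute_gvhd && status$chronic_gvhd)
    return(if (both_gvhd == "chronic") 0.7 else 0.8)
  if (status$chronic_gvhd) return(0.7)
  if (status$acute_gvhd) return(0.8)
  1
}

#' Default state-encoding schema
#'
#' Defines how a baseline + status pair becomes the numeric state vector
#' consumed by the networks. The default 8-dimensional layout is the four
#' status indicators (alive, acute GVHD, chronic GVHD, relapse) followed by
#' four baseline-derived features: age/100, sex, the donor-relation category
#' integer code (1..6) and the comorbidity count.
#'
#' @param include_stage if `TRUE`, append the stage index as a ninth
#'   feature (used by the initial-treatment networks).
#' @return an object of class `state_schema` with fields `length` and
#'   `feature_names`.
#' @export
state_schema <- function(include_stage = FALSE) {
  nm <- c("alive", "acute_gvhd", "chronic_gvhd", "relapse",
          "age_scaled", "sex", "donor_relation_code", "comorbidity_count")
  if (include_stage) nm <- c(nm, "stage_index")
  structure(list(length = length(nm), feature_names = nm,
                 include_stage = include_stage),
            class = "state_schema")
}

#' Encode a patient state vector
#'
#' Deterministically maps baseline features and current clinical status to
#' the fixed-length numeric vector used as network input.
#'
#' @param baseline a [patient_baseline()].
#' @param status a [status_flags()].
#' @param stage_index integer stage 0..4.
#' @param schema a [state_schema()].
#' @return numeric vector of length `schema$length`.
#' @export
encode_state <- function(baseline, status, stage_index,
                         schema = state_schema()) {
  stopifnot(inherits(schema, "state_schema"))
  rel_code <- match(baseline$donor_relation, donor_relation_levels())
  if (is.na(rel_code))
    stop("unknown category in field 'donor_relation': ",
         deparse(baseline$donor_relation))
  v <- c(as.numeric(status$alive), as.numeric(status$acute_gvhd),
         as.numeric(status$chronic_gvhd), as.numeric(status$relapse),
         baseline$age / 100, baseline$sex, rel_code,
         sum(baseline$comorbidities))
  if (schema$include_stage) v <- c(v, stage_index)
  names(v) <- schema$feature_names
  v
}

#' Discounted cumulative reward
#'
#' Computes the discounted return `sum(gamma^k * r_k)` (k from 0) of a
#' reward sequence in a discrete-time system. An empty sequence yields 0.
#'
#' @param rewards numeric vector of per-stage rewards.
#' @param gamma discount rate in (0, 1].
#' @export
discounted_return <- function(rewards, gamma = 0.99) {
  stopifnot(gamma > 0, gamma <= 1)
  if (length(rewards) == 0) return(0)
  sum(gamma^(seq_along(rewards) - 1) * rewards)
}

#' One stage record of a trajectory
#'
#' @param stage_index integer 0..4 (mapping onto [stage_days()]).
#' @param status a [status_flags()].
#' @param action character vector of drug identifiers administered at this
#'   stage, or `NULL` (terminal or final stage: no decision).
#' @param reward_in reward earned on arriving in this state (`NA` at
#'   baseline); must equal `immediate_reward(status)`.
#' @export
stage_record <- function(stage_index, status, action = NULL,
                         reward_in = NA_real_) {
  stopifnot(stage_index %in% 0:4)
  if (!is.na(reward_in)) {
    if (reward_in < 0 || reward_in > 1)
      stop("reward_in must lie in [0, 1]")
    # relapse reward is a configurable convention; other statuses are fixed
    if (!(status$alive && status$relapse)) {
      expect <- immediate_reward(status)
      if (abs(reward_in - expect) > 1e-12)
        stop("reward_in (", reward_in, ") does not match immediate_reward (",
             expect, ")")
    }
  }
  structure(list(stage_index = as.integer(stage_index),
                 stage_time = stage_days()[stage_index + 1L],
                 status = status,
                 action = if (is.null(action)) NULL else sort(as.character(action)),
                 reward_in = reward_in),
            class = "stage_record")
}

#' A patient trajectory
#'
#' Ordered stage records for one patient: baseline at day 0, then follow-up
#' records until the horizon or the first terminal (dead/relapsed) state,
#' after which no records exist.
#'
#' @param patient_id identifier.
#' @param baseline a [patient_baseline()].
#' @param records list of [stage_record()]s with strictly increasing stage
#'   times, the first at stage 0.
#' @export
trajectory <- function(patient_id, baseline, records) {
  stopifnot(inherits(baseline, "patient_baseline"), length(records) >= 1)
  idx <- vapply(records, function(r) r$stage_index, integer(1))
  if (idx[1] != 0L) stop("first record must be at stage 0 (day 0)")
  if (any(diff(idx) <= 0)) stop("stage times must be strictly increasing")
  term <- vapply(records, function(r) is_terminal_status(r$status), logical(1))
  if (any(term) && which(term)[1] < length(records))
    stop("no records may follow the first terminal state")
  structure(list(patient_id = patient_id, baseline = baseline,
                 records = records),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory", x$patient_id, "-", length(x$records), "stage records\n")
  for (r in x$records) {
    st <- r$status
    lab <- if (!st$alive) "dead" else if (st$relapse) "relapse" else {
      g <- c(if (st$acute_gvhd) "aGVHD", if (st$chronic_gvhd) "cGVHD")
      if (length(g)) paste(g, collapse = "+") else "healthy"
    }
    cat(sprintf("  day %4d  %-10s r_in=%-4s action={%s}\n", r$stage_time, lab,
                ifelse(is.na(r$reward_in), "-", format(r$reward_in)),
                paste(r$action, collapse = ",")))
  }
  invisible(x)
}

#' Build an action codec from observed trajectories
#'
#' Enumerates the distinct drug sets observed across all stage records, in
#' first-observation order, and assigns each a combination index 1..K.
#' Rebuilding from an already-coded cohort yields the same bijection.
#'
#' @param trajectories list of [trajectory()] objects.
#' @return an object of class `action_codec` with fields `combos` (list of
#'   sorted drug-identifier vectors), `drugs` (vocabulary) and `K`.
#' @export
build_action_codec <- function(trajectories) {
  keys <- character(0)
  combos <- list()
  for (tr in trajectories) {
    for (r in tr$records) {
      if (is.null(r$action)) next
      k <- paste(r$action, collapse = ";")
      if (!k %in% keys) {
        keys <- c(keys, k)
        combos[[length(combos) + 1L]] <- r$action
      }
    }
  }
  if (length(combos) == 0) stop("no actions observed in the trajectories")
  action_codec(combos)
}

#' Construct an action codec from an explicit combination list
#'
#' @param combos list of character vectors (drug sets), distinct.
#' @export
action_codec <- function(combos) {
  combos <- lapply(combos, function(x) sort(as.character(x)))
  keys <- vapply(combos, paste, character(1), collapse = ";")
  if (anyDuplicated(keys)) stop("duplicate drug sets in combos")
  structure(list(combos = combos, keys = keys,
                 drugs = sort(unique(unlist(combos))),
                 K = length(combos)),
            class = "action_codec")
}

#' @export
print.action_codec <- function(x, ...) {
  cat("Action codec:", x$K, "drug combinations over", length(x$drugs),
      "drugs\n")
  invisible(x)
}

#' Encode a drug set to its combination index
#'
#' @param codec an [action_codec()].
#' @param drug_set character vector of drug identifiers.
#' @return integer index in 1..K.
#' @export
encode_action <- function(codec, drug_set) {
  k <- paste(sort(as.character(drug_set)), collapse = ";")
  i <- match(k, codec$keys)
  if (is.na(i))
    stop("drug set {", paste(drug_set, collapse = ","),
         "} is not in the action codec")
  i
}

#' Decode a combination index to its drug set
#' @param codec an [action_codec()].
#' @param index integer in 1..K.
#' @export
decode_action <- function(codec, index) {
  stopifnot(index >= 1, index <= codec$K)
  codec$combos[[index]]
}

#' Low-variance feature filter
#'
#' Returns the indices of columns whose sample variance exceeds the
#' threshold, in their original order — the simple dimensionality-reduction
#' screen applied before model fitting.
#'
#' @param feature_matrix numeric matrix (rows = observations).
#' @param threshold non-negative variance cutoff (default 0: drop only
#'   constant columns).
#' @export
low_variance_filter <- function(feature_matrix, threshold = 0) {
  stopifnot(is.matrix(feature_matrix), nrow(feature_matrix) >= 1,
            threshold >= 0)
  v <- apply(feature_matrix, 2, stats::var)
  which(v > threshold)
}

#' Extract replay transitions from a trajectory
#'
#' Emits one `(s, a, r, s', terminal)` tuple per consecutive record pair
#' whose source stage index is in `stage_filter`. The reward is the
#' destination record's arrival reward. The terminal (episode-end) flag is
#' set when the destination status is dead or relapsed, and also on
#' arrival at `final_stage`: patients alive and relapse-free at the end of
#' follow-up are considered cured, so no value is bootstrapped past that
#' point.
#'
#' @param traj a [trajectory()].
#' @param codec an [action_codec()].
#' @param stage_filter integer vector of decision stage indices to keep, or
#'   `NULL` for all (aGVHD models use stages 1-2, cGVHD models stages 1-4).
#' @param schema a [state_schema()].
#' @param final_stage stage index at which follow-up ends (default 4, the
#'   two-year visit); `NA` disables end-of-horizon termination.
#' @return a list with matrices/vectors `s`, `a`, `r`, `s_next`, `terminal`
#'   (class `transition_set`).
#' @export
to_transitions <- function(traj, codec, stage_filter = NULL,
                           schema = state_schema(), final_stage = 4L) {
  n <- length(traj$records)
  s <- list(); a <- integer(0); r <- numeric(0); s2 <- list(); term <- logical(0)
  if (n >= 2) {
    for (i in seq_len(n - 1L)) {
      src <- traj$records[[i]]
      dst <- traj$records[[i + 1L]]
      if (!is.null(stage_filter) && !src$stage_index %in% stage_filter) next
      if (is.null(src$action))
        stop("record at stage ", src$stage_index, " has no action")
      s[[length(s) + 1L]] <- encode_state(traj$baseline, src$status,
                                          src$stage_index, schema)
      a <- c(a, encode_action(codec, src$action))
      r <- c(r, dst$reward_in)
      s2[[length(s2) + 1L]] <- encode_state(traj$baseline, dst$status,
                                            dst$stage_index, schema)
      term <- c(term, is_terminal_status(dst$status) ||
                  (!is.na(final_stage) && dst$stage_index >= final_stage))
    }
  }
  transition_set(
    s = if (length(s)) do.call(rbind, s) else matrix(numeric(0), 0, schema$length),
    a = a, r = r,
    s_next = if (length(s2)) do.call(rbind, s2) else matrix(numeric(0), 0, schema$length),
    terminal = term)
}

#' Construct a transition set
#'
#' @param s,s_next numeric matrices of encoded states (rows = transitions).
#' @param a integer action indices (1..K).
#' @param r numeric rewards in `[0, 1]`.
#' @param terminal logical flags.
#' @export
transition_set <- function(s, a, r, s_next, terminal) {
  n <- nrow(s)
  stopifnot(length(a) == n, length(r) == n, nrow(s_next) == n,
            length(terminal) == n)
  structure(list(s = s, a = as.integer(a), r = as.numeric(r),
                 s_next = s_next, terminal = as.logical(terminal)),
            class = "transition_set")
}

#' @export
print.transition_set <- function(x, ...) {
  cat("Transition set:", nrow(x$s), "tuples,",
      sum(x$terminal), "terminal\n")
  invisible(x)
}

#' Concatenate transition sets
#' @param ... transition_set objects (or a single list of them).
#' @export
bind_transitions <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "transition_set")) xs <- xs[[1]]
  xs <- Filter(function(x) nrow(x$s) > 0, xs)
  if (length(xs) == 0) stop("no transitions to bind")
  transition_set(
    s = do.call(rbind, lapply(xs, `[[`, "s")),
    a = unlist(lapply(xs, `[[`, "a")),
    r = unlist(lapply(xs, `[[`, "r")),
    s_next = do.call(rbind, lapply(xs, `[[`, "s_next")),
    terminal = unlist(lapply(xs, `[[`, "terminal")))
}

#' Extract transitions from a whole cohort
#' @inheritParams to_transitions
#' @param trajectories list of [trajectory()] objects.
#' @export
cohort_transitions <- function(trajectories, codec, stage_filter = NULL,
                               schema = state_schema(), final_stage = 4L) {
  bind_transitions(lapply(trajectories, to_transitions, codec = codec,
                          stage_filter = stage_filter, schema = schema,
                          final_stage = final_stage))
}

#' Patient-level train/test split
#'
#' Partitions trajectories at the patient level (never splitting one
#' patient's stages across sets, which would leak information), with the
#' customary 20% held out for testing by default.
#'
#' @param trajectories list of [trajectory()] objects.
#' @param test_fraction fraction held out, in (0, 1).
#' @param seed integer seed; the same seed always yields the same partition.
#' @return list with elements `train` and `test`.
#' @export
split_trajectories <- function(trajectories, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(trajectories)
  if (n < 2) stop("need at least 2 trajectories to split")
  set.seed(seed)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) n_test <- n - 1L
  test_idx <- sort(sample.int(n, n_test))
  list(train = trajectories[-test_idx], test = trajectories[test_idx])
}
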