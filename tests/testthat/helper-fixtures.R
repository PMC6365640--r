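# Small hand-built fixtures shared across test files.

fix_baseline <- function(age = 40, sex = 0L, com = c(1L, 0L, 0L),
                         rel = "identical sibling", dsex = 1L) {
  patient_baseline(age, sex, com, rel, dsex)
}

# A three-record trajectory: healthy -> aGVHD -> cGVHD.
fix_trajectory <- function(id = "T1") {
  trajectory(id, fix_baseline(), list(
    stage_record(0, status_flags(TRUE), action = "drugA"),
    stage_record(1, status_flags(TRUE, acute_gvhd = TRUE),
                 action = c("drugA", "drugB"), reward_in = 0.8),
    stage_record(2, status_flags(TRUE, chronic_gvhd = TRUE),
                 reward_in = 0.7)))
}

# A trajectory ending in death at the second record.
fix_terminal_trajectory <- function(id = "T2") {
  trajectory(id, fix_baseline(age = 55, sex = 1L), list(
    stage_record(0, status_flags(TRUE), action = "drugB"),
    stage_record(1, status_flags(FALSE), reward_in = 0)))
}

# Tiny simulator config where chronic GVHD is unreachable: effectively a
# 2-transient-state (healthy / aGVHD), 2-action MDP.
fix_two_state_config <- function(horizon = 2, n = 10, seed = 1) {
  P <- array(0, dim = c(3, 2, 5),
             dimnames = list(c("healthy", "agvhd", "cgvhd"),
                             c("c1", "c2"),
                             c("healthy", "agvhd", "cgvhd", "relapse",
                               "dead")))
  P["healthy", "c1", ] <- c(0.7, 0.2, 0, 0.0, 0.1)
  P["healthy", "c2", ] <- c(0.4, 0.4, 0, 0.1, 0.1)
  P["agvhd", "c1", ]   <- c(0.2, 0.5, 0, 0.1, 0.2)
  P["agvhd", "c2", ]   <- c(0.5, 0.3, 0, 0.1, 0.1)
  P["cgvhd", "c1", ]   <- c(0, 0, 1, 0, 0)
  P["cgvhd", "c2", ]   <- c(0, 0, 1, 0, 0)
  sim_config(n_patients = n, combos = list("A", "B"), horizon = horizon,
             transition_model = P, seed = seed)
}

# Independent recursive policy evaluator used as an oracle against the
# package's dynamic-programming and forward-propagation code. polmat is a
# horizon x 3 matrix of action indices over (healthy, agvhd, cgvhd).
brute_policy_value <- function(cfg, polmat, gamma) {
  rv <- c(healthy = 1, agvhd = 0.8, cgvhd = 0.7,
          relapse = cfg$relapse_reward, dead = 0)
  states <- names(rv)
  value <- function(s, t) {
    if (t >= cfg$horizon || s %in% c("relapse", "dead")) return(0)
    a <- polmat[t + 1L, s]
    p <- cfg$transition_model[s, a, ]
    sum(p * (rv + gamma * vapply(states, value, numeric(1), t = t + 1L)))
  }
  value("healthy", 0L)
}

# All deterministic policies over transient states for a K-action config.
enumerate_policies <- function(cfg) {
  cells <- cfg$horizon * 3L
  grids <- rep(list(seq_len(cfg$K)), cells)
  combos <- do.call(expand.grid, grids)
  lapply(seq_len(nrow(combos)), function(i) {
    matrix(as.integer(combos[i, ]), nrow = cfg$horizon,
           dimnames = list(NULL, c("healthy", "agvhd", "cgvhd")))
  })
}
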