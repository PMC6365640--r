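# Off-policy evaluation: matched reward, bootstrap, baselines,
# counterfactual value.

test_that("matched reward averages exactly the agreeing records", {
  # 3 decision records, 2 matching with rewards 1 and 0.8 -> mean 0.9
  t1 <- trajectory("A", fix_baseline(), list(
    stage_record(0, status_flags(TRUE), action = "a1"),
    stage_record(1, status_flags(TRUE), action = "a1", reward_in = 1),
    stage_record(2, status_flags(TRUE, acute_gvhd = TRUE),
                 action = "a2", reward_in = 0.8),
    stage_record(3, status_flags(TRUE), reward_in = 1)))
  codec <- action_codec(list("a1", "a2"))
  always1 <- dtr_policy(function(s, t) 1L, "always a1")
  res <- matched_reward(always1, list(t1), codec)
  # stage-0 record uses a1 -> arrival reward 1; stage-1 uses a1 -> arrival
  # reward 0.8; stage-2 used a2 (no match)
  expect_equal(res$matched, 2)
  expect_equal(sort(res$rewards), c(0.8, 1))
  expect_equal(res$mean_reward, 0.9)
})

test_that("observed policy matches every record; impossible policy errors", {
  cohort <- list(fix_trajectory(), fix_terminal_trajectory())
  codec <- build_action_codec(cohort)
  res <- matched_reward("observed", cohort, codec)
  expect_equal(res$matched, 3)
  expect_equal(res$mean_reward, mean(c(0.8, 0.7, 0)))
  never <- dtr_policy(function(s, t) 99L, "unobserved action")
  expect_error(matched_reward(never, cohort, codec), "no matched patients")
  expect_error(matched_reward("observed", list(), codec), "empty")
})

test_that("trajectory-granularity matching requires all stages to agree", {
  cohort <- list(fix_trajectory(), fix_terminal_trajectory())
  codec <- build_action_codec(cohort)
  # policy that always plays drugB: matches only T2's single decision
  alwaysB <- dtr_policy(function(s, t) encode_action(codec, "drugB"),
                        "always drugB")
  res <- matched_reward(alwaysB, cohort, codec, granularity = "trajectory")
  expect_equal(res$matched, 1)
  expect_equal(res$mean_reward, 0)      # T2 dies: arrival reward 0
})

test_that("percentile bootstrap interval behaves as expected", {
  const <- rep(0.7, 25)
  ci <- bootstrap_ci(const, B = 200, seed = 1)
  expect_equal(ci$lower, 0.7)
  expect_equal(ci$upper, 0.7)           # zero width at a constant
  set.seed(2)
  x <- rnorm(200, mean = 3)
  ci2 <- bootstrap_ci(x, B = 5000, seed = 3)
  expect_lte(ci2$lower, mean(x))
  expect_gte(ci2$upper, mean(x))
  # seed determinism
  ci3 <- bootstrap_ci(x, B = 5000, seed = 3)
  expect_identical(ci2, ci3)
  # agreement with an independent resampling run at matched seed state
  set.seed(9)
  n <- length(x)
  means <- replicate(4000, mean(x[sample.int(n, n, replace = TRUE)]))
  ref <- quantile(means, c(0.025, 0.975), names = FALSE)
  ci4 <- bootstrap_ci(x, B = 4000, seed = 31)
  expect_equal(ci4$lower, ref[1], tolerance = 0.02)
  expect_equal(ci4$upper, ref[2], tolerance = 0.02)
})

test_that("bootstrap interval width shrinks roughly like 1/sqrt(n)", {
  set.seed(4)
  x_small <- rnorm(100)
  x_big <- rnorm(1600)
  w <- function(x) { ci <- bootstrap_ci(x, B = 2000, seed = 5); ci$upper - ci$lower }
  ratio <- w(x_small) / w(x_big)
  expect_gt(ratio, 2.5)   # theory: 4
  expect_lt(ratio, 6)
})

test_that("one-size-fits-all returns the modal action regardless of state", {
  # counts: a1 x3, a2 x1 across the two fixture trajectories
  t1 <- trajectory("A", fix_baseline(), list(
    stage_record(0, status_flags(TRUE), action = "a1"),
    stage_record(1, status_flags(TRUE), action = "a1", reward_in = 1),
    stage_record(2, status_flags(TRUE), action = "a2", reward_in = 1),
    stage_record(3, status_flags(TRUE), action = "a1", reward_in = 1)))
  codec <- action_codec(list("a1", "a2"))
  pol <- one_size_fits_all_policy(list(t1), codec)
  expect_equal(pol$fun(rnorm(8), 0), 1L)
  expect_equal(pol$fun(rnorm(8), 3), 1L)     # state-independent
  # stage restriction: stage 2 alone makes a2 modal
  pol2 <- one_size_fits_all_policy(list(t1), codec, stage = 2)
  expect_equal(pol2$fun(rnorm(8), 2), 2L)
  expect_error(one_size_fits_all_policy(list(t1), codec, stage = 4),
               "stage 4")
})

test_that("random-forest policy recovers a deterministic reward rule", {
  set.seed(6)
  n <- 500
  S <- cbind(matrix(rnorm(n * 4), n, 4), matrix(runif(n * 4), n, 4))
  a <- sample.int(3, n, replace = TRUE)
  r <- ifelse(a == 2, 1, 0)              # action 2 always pays 1
  tx <- transition_set(S, a, r, S, rep(FALSE, n))
  codec <- action_codec(list("x", "y", "z"))
  pol <- random_forest_policy(tx, codec, seed = 7)
  test_states <- S[1:100, ]
  picks <- vapply(1:100, function(i) pol$fun(test_states[i, ], 0L),
                  integer(1))
  expect_gte(mean(picks == 2), 0.95)
  expect_true(all(picks >= 1 & picks <= codec$K))
  # seed determinism
  pol2 <- random_forest_policy(tx, codec, seed = 7)
  picks2 <- vapply(1:100, function(i) pol2$fun(test_states[i, ], 0L),
                   integer(1))
  expect_identical(picks, picks2)
  # degenerate constant reward: constant prediction, no crash
  txc <- transition_set(S, a, rep(0.5, n), S, rep(FALSE, n))
  polc <- random_forest_policy(txc, codec, seed = 8)
  expect_equal(polc$fun(test_states[1, ], 0L), 1L)
})

test_that("reward predictor fits a deterministic mapping and clips output", {
  cfg <- sim_config(n_patients = 700, seed = 14)
  codec <- config_action_codec(cfg)
  tx <- cohort_transitions(simulate_cohort(cfg), codec)
  er <- cfg$expected_reward
  sname <- apply(tx$s, 1, function(s)
    if (s[2] > 0.5) "agvhd" else if (s[3] > 0.5) "cgvhd" else "healthy")
  r_true <- er[cbind(sname, paste0("c", tx$a))]
  txn <- transition_set(tx$s, tx$a, r_true, tx$s_next, tx$terminal)
  sp <- seq_len(nrow(tx$s)) <= 0.8 * nrow(tx$s)
  rmod <- train_reward_predictor(
    transition_set(txn$s[sp, ], txn$a[sp], txn$r[sp], txn$s_next[sp, ],
                   txn$terminal[sp]),
    K = codec$K,
    hyper = dtr_hyper(eta = 1e-3, epochs = 120, patience = 15,
                      batch_size = 32, weight_decay = 0, seed = 15))
  pred <- predict_reward(rmod, txn$s[!sp, , drop = FALSE], txn$a[!sp])
  expect_lte(mean((pred - r_true[!sp])^2), 0.01)
  expect_true(all(pred >= 0 & pred <= 1))
  # seed determinism
  rmod2 <- train_reward_predictor(
    transition_set(txn$s[sp, ], txn$a[sp], txn$r[sp], txn$s_next[sp, ],
                   txn$terminal[sp]),
    K = codec$K,
    hyper = dtr_hyper(eta = 1e-3, epochs = 120, patience = 15,
                      batch_size = 32, weight_decay = 0, seed = 15))
  expect_identical(rmod$net$W, rmod2$net$W)
})

test_that("counterfactual value and exclusion baseline match hand averages", {
  codec <- action_codec(list("x", "y", "z"))
  states <- rbind(c(1, 0), c(0, 1))
  # constant model c -> c for any policy
  const <- function(state, action) 0.42
  pol1 <- dtr_policy(function(s, t) 1L)
  expect_equal(counterfactual_value(const, pol1, states), 0.42)
  # two states with predictions 0.9 and 0.7 -> 0.8
  model <- function(state, action) if (state[1] == 1) 0.9 else 0.7
  expect_equal(counterfactual_value(model, pol1, states), 0.8)
  # K = 3 with per-action predictions (0.9, 0.5, 0.1), top = 1 -> 0.3
  tbl <- function(state, action) c(0.9, 0.5, 0.1)[action]
  expect_equal(baseline_excluding_top(tbl, states, pol1, codec), 0.3)
  # the exclusion average can never exceed the per-state maximum
  expect_lte(baseline_excluding_top(tbl, states, pol1, codec), 0.9)
  # K = 2: equals the prediction of the non-recommended action
  codec2 <- action_codec(list("x", "y"))
  tbl2 <- function(state, action) c(0.8, 0.3)[action]
  expect_equal(baseline_excluding_top(tbl2, states, pol1, codec2), 0.3)
  expect_error(baseline_excluding_top(tbl, states, pol1,
                                      action_codec(list("only"))),
               "at least 2")
  expect_error(counterfactual_value(const, pol1,
                                    matrix(numeric(0), 0, 2)), "empty")
})

test_that("with the true reward function the optimal policy beats random", {
  cfg <- sim_config(n_patients = 300, seed = 16)
  codec <- config_action_codec(cfg)
  cohort <- simulate_cohort(cfg)
  tx <- cohort_transitions(cohort, codec)
  orc <- optimal_policy_oracle(cfg)
  er <- cfg$expected_reward
  true_r <- function(state, action) {
    sname <- if (state[2] > 0.5) "agvhd" else if (state[3] > 0.5) "cgvhd"
             else "healthy"
    er[sname, action]
  }
  opt <- oracle_policy(orc, codec)
  v_opt <- counterfactual_value(true_r, opt, tx$s)
  set.seed(17)
  v_rnd <- counterfactual_value(true_r, random_policy(codec$K), tx$s)
  expect_gte(v_opt, v_rnd)
  # consistency with the exact one-step value on stage-0 states
  s0 <- tx$s[tx$s[, 2] < 0.5 & tx$s[, 3] < 0.5, , drop = FALSE]
  expect_equal(counterfactual_value(true_r, opt, s0),
               max(er["healthy", ]))
})
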