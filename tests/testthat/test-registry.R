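# Registry data model: rewards, state encoding, action coding, transitions.

test_that("immediate reward maps the four clinical statuses to their values", {
  expect_identical(immediate_reward(status_flags(TRUE)), 1)
  expect_identical(immediate_reward(status_flags(TRUE, acute_gvhd = TRUE)),
                   0.8)
  expect_identical(immediate_reward(status_flags(TRUE, chronic_gvhd = TRUE)),
                   0.7)
  expect_identical(immediate_reward(status_flags(FALSE)), 0)
})

test_that("both-GVHD and relapse conventions behave as configured", {
  both <- status_flags(TRUE, acute_gvhd = TRUE, chronic_gvhd = TRUE)
  expect_identical(immediate_reward(both), 0.7)          # worse dominates
  expect_identical(immediate_reward(both, both_gvhd = "acute"), 0.8)
  rel <- status_flags(TRUE, relapse = TRUE)
  expect_identical(immediate_reward(rel), 0)
  expect_identical(immediate_reward(rel, relapse_reward = 0.3), 0.3)
  expect_true(is_terminal_status(rel))
  expect_true(is_terminal_status(status_flags(FALSE)))
  expect_false(is_terminal_status(status_flags(TRUE, acute_gvhd = TRUE)))
})

test_that("reward values are monotone in clinical severity", {
  vals <- c(immediate_reward(status_flags(TRUE)),
            immediate_reward(status_flags(TRUE, acute_gvhd = TRUE)),
            immediate_reward(status_flags(TRUE, chronic_gvhd = TRUE)),
            immediate_reward(status_flags(FALSE)))
  expect_equal(vals, sort(vals, decreasing = TRUE))
  expect_setequal(vals, c(1, 0.8, 0.7, 0))
})

test_that("status flags reject a dead patient with GVHD", {
  expect_error(status_flags(FALSE, acute_gvhd = TRUE), "dead patient")
})

test_that("state encoding is deterministic, 8-long by default, 9 with stage", {
  b <- fix_baseline()
  s <- status_flags(TRUE)
  v1 <- encode_state(b, s, 0)
  v2 <- encode_state(b, s, 0)
  expect_length(v1, 8)
  expect_identical(v1, v2)
  expect_equal(unname(v1[1:4]), c(1, 0, 0, 0))
  v9 <- encode_state(b, s, 3, state_schema(include_stage = TRUE))
  expect_length(v9, 9)
  expect_equal(unname(v9[9]), 3)
  sick <- status_flags(TRUE, acute_gvhd = TRUE)
  expect_equal(unname(encode_state(b, sick, 1)[1:4]), c(1, 1, 0, 0))
})

test_that("state encoding names the offending field on bad categories", {
  expect_error(patient_baseline(40, 0L, c(0L), "cousin", 1L),
               "donor_relation")
  expect_error(patient_baseline(40, "unknown", c(0L), "other", 1L), "sex")
  expect_error(patient_baseline(-3, 0L, c(0L), "other", 1L), "age")
})

test_that("discounted return matches term-by-term summation", {
  expect_identical(discounted_return(numeric(0), 0.99), 0)
  expect_identical(discounted_return(c(1, 1, 1, 1), 1), 4)
  # oracle: literal summation
  r <- c(1, 0.8, 0.7)
  expect_equal(discounted_return(r, 0.99),
               1 * 0.99^0 + 0.8 * 0.99^1 + 0.7 * 0.99^2)
  set.seed(42)
  for (i in 1:5) {
    r <- runif(sample(1:6, 1))
    g <- runif(1, 0.5, 1)
    expect_equal(discounted_return(r, g), sum(g^(seq_along(r) - 1) * r))
  }
  expect_lte(discounted_return(runif(7), 1), 7)  # bounded by horizon
})

test_that("action codec enumerates distinct drug sets in observation order", {
  t1 <- fix_trajectory()
  codec <- build_action_codec(list(t1))
  expect_equal(codec$K, 2)             # {A}, {A,B}; {A} repeats collapse
  expect_equal(encode_action(codec, "drugA"), 1)
  expect_equal(encode_action(codec, c("drugB", "drugA")), 2)  # order-free
  expect_equal(decode_action(codec, 2), c("drugA", "drugB"))
  # idempotence: rebuilding from a coded cohort gives the same bijection
  codec2 <- build_action_codec(list(t1, fix_trajectory("T9")))
  expect_identical(codec$combos, codec2$combos)
  expect_error(encode_action(codec, "drugZ"), "drugZ")
  bare <- trajectory("X", fix_baseline(), list(
    stage_record(0, status_flags(FALSE))))
  expect_error(build_action_codec(list(bare)), "no actions")
})

test_that("low variance filter matches the per-column variance oracle", {
  set.seed(7)
  X <- cbind(const = rep(2, 20), a = rnorm(20), b = rnorm(20, sd = 0.01))
  keep <- low_variance_filter(X, 0)
  expect_equal(keep, which(apply(X, 2, var) > 0), ignore_attr = TRUE)
  expect_false(1 %in% keep)                 # constant column removed
  thr <- 1e-3
  expect_equal(low_variance_filter(X, thr),
               which(apply(X, 2, var) > thr), ignore_attr = TRUE)
  Y <- matrix(rnorm(40), 10, 4)
  expect_equal(low_variance_filter(Y, 0), 1:4, ignore_attr = TRUE)
})

test_that("transition extraction yields n-1 tuples with arrival rewards", {
  t1 <- fix_trajectory()
  codec <- build_action_codec(list(t1))
  tx <- to_transitions(t1, codec)
  expect_equal(nrow(tx$s), 2)
  expect_equal(tx$r, c(0.8, 0.7))
  expect_equal(tx$terminal, c(FALSE, FALSE))
  expect_equal(tx$a, c(1, 2))
  # destination dead: terminal with reward 0
  t2 <- fix_terminal_trajectory()
  codec2 <- build_action_codec(list(t1, t2))
  tx2 <- to_transitions(t2, codec2)
  expect_equal(nrow(tx2$s), 1)
  expect_true(tx2$terminal)
  expect_equal(tx2$r, 0)
  # stage filter keeps only selected source stages
  txf <- to_transitions(t1, codec, stage_filter = 1L)
  expect_equal(nrow(txf$s), 1)
  expect_equal(txf$r, 0.7)
  # every r equals the immediate reward of the destination status
  all_tx <- cohort_transitions(list(t1, t2), codec2)
  dest_reward <- function(row) {
    immediate_reward(status_flags(row[1] == 1, row[2] == 1, row[3] == 1,
                                  row[4] == 1))
  }
  expect_equal(all_tx$r, apply(all_tx$s_next, 1, dest_reward))
})

test_that("trajectory invariants reject malformed records", {
  b <- fix_baseline()
  expect_error(trajectory("X", b, list(
    stage_record(1, status_flags(TRUE), action = "a"))), "stage 0")
  expect_error(trajectory("X", b, list(
    stage_record(0, status_flags(FALSE)),
    stage_record(1, status_flags(TRUE)))), "terminal")
  expect_error(stage_record(1, status_flags(TRUE), reward_in = 0.5),
               "does not match")
})

test_that("patient-level split is a seed-deterministic partition", {
  cfg <- fix_two_state_config(n = 10, seed = 3)
  cohort <- simulate_cohort(cfg)
  sp <- split_trajectories(cohort, 0.2, seed = 11)
  expect_length(sp$test, 2)
  expect_length(sp$train, 8)
  ids <- function(x) sort(vapply(x, `[[`, character(1), "patient_id"))
  expect_identical(sort(c(ids(sp$train), ids(sp$test))), ids(cohort))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  sp2 <- split_trajectories(cohort, 0.2, seed = 11)
  expect_identical(ids(sp$test), ids(sp2$test))
  expect_error(split_trajectories(cohort[1], 0.2, 1), "at least 2")
})

test_that("registry CSV round trips with its JSON sidecar", {
  cohort <- list(fix_trajectory(), fix_terminal_trajectory())
  codec <- build_action_codec(cohort)
  path <- file.path(tempdir(), "registry.csv")
  write_registry(cohort, path, codec = codec)
  back <- read_registry(path)
  expect_length(back$trajectories, 2)
  expect_identical(back$codec$combos, codec$combos)
  orig_tx <- cohort_transitions(cohort, codec)
  back_tx <- cohort_transitions(back$trajectories, back$codec)
  expect_equal(back_tx$s, orig_tx$s, ignore_attr = TRUE)
  expect_equal(back_tx$a, orig_tx$a)
  expect_equal(back_tx$r, orig_tx$r)
  unlink(c(path, paste0(path, ".json")))
})
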