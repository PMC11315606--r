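test_that("forward update moves probability mass as the SPE dictates", {
  mb <- mb_state(default_tree, eta = 0.2)
  pair <- default_tree$succ1[1, ]
  up <- forward_update(mb, default_tree, 1L, 0L, 0L, pair[1])
  expect_equal(up$delta, 0.5)
  expect_equal(up$state$T1[1, pair[1] + 1L], 0.6)
  expect_equal(up$state$T1[1, pair[2] + 1L], 0.4)
  expect_error(forward_update(mb, default_tree, 1L, 0L, 0L,
                              setdiff(0:3, pair)[1]), "not a successor")
  expect_error(mb_state(default_tree, eta = 0), "eta")
})

test_that("transition rows stay stochastic after arbitrary update sequences", {
  set.seed(13)
  mb <- mb_state(default_tree, eta = 0.35)
  for (i in 1:200) {
    a1 <- sample(0:1, 1)
    s2 <- sample(default_tree$succ1[a1 + 1L, ], 1)
    mb <- forward_update(mb, default_tree, 1L, 0L, a1, s2)$state
    a2 <- sample(0:1, 1)
    s3 <- sample(default_tree$succ2[s2 + 1L, a2 + 1L, ], 1)
    mb <- forward_update(mb, default_tree, 2L, s2, a2, s3)$state
    expect_equal(rowSums(mb$T1), c(1, 1), tolerance = 1e-12)
    expect_equal(apply(mb$T2, c(1, 2), sum),
                 matrix(1, default_tree$n_s2, 2), tolerance = 1e-12)
    expect_true(all(mb$T1 >= 0 & mb$T1 <= 1))
    expect_true(all(mb$T2 >= 0 & mb$T2 <= 1))
  }
})

test_that("repeatedly observed successors approach probability 1 geometrically", {
  eta <- 0.1
  mb <- mb_state(default_tree, eta)
  target <- default_tree$succ2[1, 1, 1]
  for (k in 1:50) {
    mb <- forward_update(mb, default_tree, 2L, 0L, 0L, target)$state
    # closed form: 1 - p_k = (1 - eta)^k * (1 - p_0), p_0 = 0.5
    expect_equal(mb$T2[1, 1, target + 1L], 1 - (1 - eta)^k * 0.5,
                 tolerance = 1e-12)
  }
})

test_that("backward planning reproduces hand-computed goal values", {
  # with the true low-uncertainty transition model and a red goal, the
  # 40-coin terminal sits two likely steps away: Q(s1, best) = 0.9*0.9*40
  mb <- mb_state(default_tree, eta = 0.5)
  Tm <- true_transition_matrix(default_tree, "low")
  mb$T1 <- Tm$T1; mb$T2 <- Tm$T2
  r <- make_goal_reward_map(default_tree, "specific", "red")
  mb <- backward_plan(mb, r, default_tree)
  expect_equal(max(mb$Q1), 32.4)
  # all-zero reward map zeroes every value
  mb0 <- backward_plan(mb, rep(0, 8), default_tree)
  expect_true(all(mb0$Q1 == 0) && all(mb0$Q2 == 0))
  # idempotence
  mb2 <- backward_plan(backward_plan(mb, r, default_tree), r, default_tree)
  expect_equal(mb2$Q1, mb$Q1)
  expect_equal(mb2$Q2, mb$Q2)
})

test_that("backward planning equals brute-force expectimax on random instances", {
  set.seed(17)
  for (k in 1:100) {
    tree <- random_tree()
    mb <- random_mb_T(tree)
    goal <- sample(c("any", "yellow", "red", "blue"), 1)
    cond <- if (goal == "any") "flexible" else "specific"
    r <- make_goal_reward_map(tree, cond, goal)
    mb <- backward_plan(mb, r, tree)
    oracle <- bf_expectimax_q(mb$T1, mb$T2, r, tree$n_s2)
    expect_equal(as.numeric(mb$Q1), oracle$q1, tolerance = 1e-9)
    expect_equal(unname(mb$Q2), unname(oracle$q2), tolerance = 1e-9)
  }
})

test_that("goal reward maps implement the goal-contingency semantics", {
  r_spec <- make_goal_reward_map(default_tree, "specific", "yellow")
  expect_equal(r_spec[default_tree$terminal_colour == "yellow"],
               default_tree$terminal_value[default_tree$terminal_colour == "yellow"])
  expect_true(all(r_spec[default_tree$terminal_colour != "yellow"] == 0))
  r_flex <- make_goal_reward_map(default_tree, "flexible")
  expect_equal(r_flex, default_tree$terminal_value)
  # grey terminals are worthless in both conditions
  grey <- default_tree$terminal_colour == "grey"
  expect_true(all(r_spec[grey] == 0) && all(r_flex[grey] == 0))
  expect_error(make_goal_reward_map(default_tree, "specific"), "colour")
})

test_that("a uniform unlearned model values actions as plain averages", {
  mb <- mb_state(default_tree, eta = 0.5)
  r <- make_goal_reward_map(default_tree, "flexible")
  mb <- backward_plan(mb, r, default_tree)
  for (j in seq_len(default_tree$n_s2))
    for (a in 1:2) {
      pair <- default_tree$succ2[j, a, ]
      expect_equal(mb$Q2[j, a], mean(r[pair + 1L]))
    }
})

test_that("a goal switch changes planned values without new observations", {
  mb <- mb_state(default_tree, eta = 0.3)
  r1 <- make_goal_reward_map(default_tree, "flexible")
  r2 <- make_goal_reward_map(default_tree, "specific", "yellow")
  q_flex <- backward_plan(mb, r1, default_tree)$Q1
  q_spec <- backward_plan(mb, r2, default_tree)$Q1
  expect_false(isTRUE(all.equal(q_flex, q_spec)))
})

test_that("trial processing snapshots the values that back each choice", {
  set.seed(19)
  mb <- mb_state(default_tree, eta = 0.4)
  for (i in 1:10) {
    a1 <- sample(0:1, 1)
    s2 <- sample(default_tree$succ1[a1 + 1L, ], 1)
    a2 <- sample(0:1, 1)
    s3 <- sample(default_tree$succ2[s2 + 1L, a2 + 1L, ], 1)
    trial <- list(goal_condition = "specific", goal_colour = "red",
                  s1 = 0L, a1 = a1, s2 = s2, a2 = a2, s3 = s3)
    r <- make_goal_reward_map(default_tree, "specific", "red")
    planned <- backward_plan(mb, r, default_tree)
    out <- mb_process_trial(mb, trial, default_tree)
    # choice-1 values equal the trial-start plan; choice-2 values equal the
    # plan at the visited stage-2 state (the stage-1 update cannot move them)
    expect_equal(out$snapshots$q1, planned$Q1[1, ])
    expect_equal(out$snapshots$q2, planned$Q2[s2 + 1L, ])
    # with a converged T the snapshots equal the expectimax oracle
    mb <- out$state
  }
  Tm <- true_transition_matrix(default_tree, "low")
  mb$T1 <- Tm$T1; mb$T2 <- Tm$T2
  r <- make_goal_reward_map(default_tree, "specific", "red")
  out <- mb_process_trial(mb, list(goal_condition = "specific",
                                   goal_colour = "red", s1 = 0L, a1 = 0L,
                                   s2 = 0L, a2 = 0L, s3 = 0L), default_tree)
  oracle <- bf_expectimax_q(Tm$T1, Tm$T2, r, default_tree$n_s2)
  expect_equal(out$snapshots$q1, oracle$q1, tolerance = 1e-9)
})
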