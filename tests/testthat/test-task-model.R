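test_that("default tree satisfies its structural invariants", {
  tree <- build_default_tree()
  expect_equal(tree$n_s2, 4L)
  expect_equal(tree$n_terminal, 8L)
  # successors belong to the next stage
  expect_true(all(tree$succ1 >= 0 & tree$succ1 < tree$n_s2))
  expect_true(all(tree$succ2 >= 0 & tree$succ2 < tree$n_terminal))
  # value/colour binding: 0 is grey, the three reward values carry the three
  # reward colours, all three present
  expect_true(all(tree$terminal_colour[tree$terminal_value == 0] == "grey"))
  expect_true(all(c("yellow", "red", "blue") %in% tree$terminal_colour))
  expect_setequal(unique(tree$terminal_value), c(0, 10, 20, 40))
  # each colour reachable from both stage-1 actions
  for (a in 0:1) {
    s2s <- tree$succ1[a + 1L, ]
    terms <- unique(as.vector(tree$succ2[s2s + 1L, , ]))
    expect_true(all(c("yellow", "red", "blue") %in%
                    tree$terminal_colour[terms + 1L]))
  }
  # determinism
  expect_identical(build_default_tree(), build_default_tree())
})

test_that("tree configuration is honoured and invalid configs rejected", {
  small <- build_default_tree(list(n_s2 = 2L, n_terminal = 4L))
  expect_true(all(small$succ1 %in% 0:1))
  expect_error(build_default_tree(list(n_s2 = 1L)), "stage-2")
  expect_error(build_default_tree(list(n_s2 = 4L, n_terminal = 3L)),
               "terminal")
  expect_error(build_default_tree(list(terminal_value = rep(0, 8))),
               "yellow, red and blue")
})

test_that("block schedule has 14 blocks per type and the expected lengths", {
  for (seed in 1:5) {
    set.seed(seed)
    sch <- generate_block_schedule()
    expect_equal(nrow(sch), 56L)
    counts <- table(sch$goal_condition, sch$uncertainty)
    expect_true(all(counts == 14L))
    expect_true(all(sch$length[sch$uncertainty == "low"] %in% 3:5))
    expect_true(all(sch$length[sch$uncertainty == "high"] %in% 5:7))
    expect_true(all(sch$goal_colour[sch$goal_condition == "flexible"] == "none"))
    expect_true(all(sch$goal_colour[sch$goal_condition == "specific"] %in%
                    c("yellow", "red", "blue")))
  }
  # closed-form expectation and range arithmetic
  expect_equal(expected_session_length(), 280)
  expect_equal(28 * 3 + 28 * 5, 224)
  expect_equal(28 * 5 + 28 * 7, 336)
  # empirical mean over many schedules is near the expectation
  set.seed(42)
  lens <- replicate(300, sum(generate_block_schedule()$length))
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 280), 3 * se + 1e-9)
})

test_that("sampled transitions match the stated probabilities", {
  tree <- default_tree
  set.seed(7)
  n <- 2e4
  for (unc in c("low", "high")) {
    p <- likely_probability(unc)
    hits <- sum(replicate(n, sample_transition(tree, 1L, 0L, 0L, unc)) ==
                tree$succ1[1, "likely"])
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(hits / n - p), 4 * se)
  }
  expect_error(sample_transition(tree, 3L, 0L, 0L, "low"), "terminal")
})

test_that("true transition matrices are row-stochastic with 0.9/0.5 rows", {
  for (unc in c("low", "high")) {
    Tm <- true_transition_matrix(default_tree, unc)
    p <- likely_probability(unc)
    expect_equal(rowSums(Tm$T1), c(1, 1))
    expect_equal(apply(Tm$T2, c(1, 2), sum),
                 matrix(1, default_tree$n_s2, 2))
    expect_equal(sort(unique(as.vector(Tm$T1[Tm$T1 > 0]))),
                 sort(unique(c(p, 1 - p))))
  }
})

test_that("optimal_action_sequence equals brute-force policy enumeration", {
  set.seed(11)
  for (k in 1:100) {
    tree <- random_tree()
    unc <- sample(c("low", "high"), 1)
    goal <- sample(c("any", "yellow", "red", "blue"), 1)
    cond <- if (goal == "any") "flexible" else "specific"
    r <- goal_reward_vector(tree, cond, goal)
    Tm <- true_transition_matrix(tree, unc)
    opt <- optimal_action_sequence(tree, unc, goal)
    expect_equal(opt$expected_value, bf_optimal(Tm$T1, Tm$T2, r, tree$n_s2),
                 tolerance = 1e-12)
  }
})

test_that("optimal sequences point at obvious targets", {
  # red 40-coins sit behind the likely branches of stage-1 action 0
  opt <- optimal_action_sequence(default_tree, "low", "red")
  expect_equal(opt$a1, 0L)
  expect_equal(opt$expected_value, 0.9 * 0.9 * 40)
  # flexible goal with one clearly dominant terminal
  tree <- build_default_tree(list(terminal_value = c(40, 0, 0, 0, 10, 0, 20, 0)))
  opt2 <- optimal_action_sequence(tree, "low", "any")
  expect_equal(opt2$a1, 0L)
  expect_equal(opt2$a2[1], 0L) # terminal 0 is the likely target of (s2=0, a=0)
  expect_equal(opt2$expected_value, 0.9 * 0.9 * 40)
})

test_that("performance and optimality behave as defined", {
  s <- data.frame(reward = c(0, 40, 20))
  expect_equal(task_performance(s), 20)
  expect_error(task_performance(s[0, , drop = FALSE]), "empty")

  # an agent that always plays the optimal sequence scores 100
  tree <- default_tree
  opt <- optimal_action_sequence(tree, "low", "red")
  set.seed(3)
  rows <- lapply(1:30, function(i) {
    s2 <- sample_transition(tree, 1L, 0L, opt$a1, "low")
    a2 <- opt$a2[s2 + 1L]
    s3 <- sample_transition(tree, 2L, s2, a2, "low")
    data.frame(goal_condition = "specific", uncertainty = "low",
               goal_colour = "red", s1 = 0L, a1 = opt$a1, s2 = s2,
               a2 = a2, s3 = s3,
               reward = goal_reward_vector(tree, "specific", "red")[s3 + 1L])
  })
  expect_equal(choice_optimality(do.call(rbind, rows), tree), 100)
})

test_that("a uniformly random agent is optimal on about 25% of unique-optimum trials", {
  # all goals have unique optimal sequences under low uncertainty on the
  # default tree, so a random agent matches both choices with prob 1/4
  tree <- default_tree
  set.seed(21)
  sess <- do.call(rbind, lapply(1:10, function(i) {
    s <- simulate_subject(agent_spec("pure_mf", tau = 0), tree, seed = 500 + i)
    s[s$uncertainty == "low", ]
  }))
  n <- nrow(sess)
  opt <- choice_optimality(sess, tree) / 100
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(opt - 0.25), 4 * se)
})

test_that("generated rewards obey the goal-contingency rule", {
  tree <- default_tree
  s <- simulate_subject(agent_spec("mixture", w_specific = 0.7,
                                   w_flexible = 0.3), tree, seed = 9)
  expected <- vapply(seq_len(nrow(s)), function(i)
    goal_reward_vector(tree, s$goal_condition[i],
                       s$goal_colour[i])[s$s3[i] + 1L], numeric(1))
  expect_equal(s$reward, expected)
  # specific trials pay only on colour match; flexible pay the coin value
  spec <- s$goal_condition == "specific"
  expect_true(all(s$reward[spec & s$coin_colour != s$goal_colour] == 0))
  expect_equal(s$reward[!spec], s$coin_value[!spec])
})
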