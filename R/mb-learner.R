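#' Initialise a model-based learner
#'
#' The learner knows the tree topology (which successor pairs exist) but not
#' the transition probabilities: the transition model `T` starts uniform over
#' each (state, action) successor pair and is adjusted by state-prediction
#' errors. Action values are produced on demand by [backward_plan()] from the
#' current `T` and a goal-conditioned terminal reward map, so they respond to
#' goal changes without any new observations.
#'
#' @param tree a `decision_tree`.
#' @param eta learning rate in (0, 1).
#' @return object of class `mb_state` with `T1` (2 x `n_s2` row-stochastic
#'   matrix over stage-2 states), `T2` (`n_s2` x 2 x `n_terminal` array),
#'   `Q1`, `Q2` (planned action values, initially 0) and `eta`.
#' @export
mb_state <- function(tree, eta) {
  if (!is.numeric(eta) || eta <= 0 || eta >= 1)
    stop("eta must lie strictly in (0, 1)")
  T1 <- matrix(0, 2, tree$n_s2)
  for (a in 0:1) {
    pair <- tree$succ1[a + 1L, ]
    for (s in unique(pair)) T1[a + 1L, s + 1L] <- sum(pair == s) / 2
  }
  T2 <- array(0, dim = c(tree$n_s2, 2, tree$n_terminal))
  for (j in seq_len(tree$n_s2)) {
    for (a in 0:1) {
      pair <- tree$succ2[j, a + 1L, ]
      for (s in unique(pair)) T2[j, a + 1L, s + 1L] <- sum(pair == s) / 2
    }
  }
  structure(
    list(T1 = T1, T2 = T2, Q1 = matrix(0, 1, 2),
         Q2 = matrix(0, tree$n_s2, 2), eta = eta),
    class = "mb_state")
}

#' @export
print.mb_state <- function(x, ...) {
  cat("<mb_state> eta =", x$eta, "\n")
  cat("T1 row sums:", format(rowSums(x$T1)), "\n")
  invisible(x)
}

#' Forward transition-model update from one observed transition
#'
#' The state-prediction error is `delta = 1 - T(s, a, s_obs)` (the leading 1
#' encodes the learner's working assumption that transitions are
#' deterministic). The observed successor's probability moves up by
#' `eta * delta` and every other successor of the pair is rescaled by
#' `(1 - eta)`, which preserves the row sum exactly.
#'
#' @param mb an `mb_state`.
#' @param tree the `decision_tree` (defines the successor support).
#' @param stage stage of `(state, action)`: 1 or 2.
#' @param state,action 0-based ids.
#' @param observed 0-based id of the observed next state; must belong to the
#'   (state, action) successor pair.
#' @return list `state` (updated `mb_state`) and `delta` (the SPE).
#' @export
forward_update <- function(mb, tree, stage, state, action, observed) {
  pair <- successor_pair(tree, stage, state, action)
  if (!observed %in% pair)
    stop("observed state ", observed, " is not a successor of (",
         state, ", ", action, ") at stage ", stage)
  eta <- mb$eta
  if (stage == 1L) {
    row <- mb$T1[action + 1L, ]
    delta <- 1 - row[observed + 1L]
    row <- row * (1 - eta)
    row[observed + 1L] <- row[observed + 1L] + eta
    mb$T1[action + 1L, ] <- row
  } else {
    row <- mb$T2[state + 1L, action + 1L, ]
    delta <- 1 - row[observed + 1L]
    row <- row * (1 - eta)
    row[observed + 1L] <- row[observed + 1L] + eta
    mb$T2[state + 1L, action + 1L, ] <- row
  }
  list(state = mb, delta = delta)
}

#' Goal-conditioned terminal reward map
#'
#' Specific goals reward only terminals of the cued colour at their coin
#' value; the flexible goal rewards every coloured terminal at its coin value.
#' Grey (value 0) terminals reward nothing in either condition.
#'
#' @inheritParams goal_reward_vector
#' @return numeric vector, one reward per terminal state.
#' @export
make_goal_reward_map <- function(tree, goal_condition, goal_colour = "none") {
  goal_reward_vector(tree, goal_condition, goal_colour)
}

#' Backward goal-conditioned planning sweep
#'
#' Recomputes action values by sweeping the tree from the terminals toward
#' the start state: for stage-2 states
#' `Q(s, a) = sum_s' T(s, a, s') * r(s')` (terminal continuation value 0),
#' then for the start state
#' `Q(s1, a) = sum_s' T(s1, a, s') * max_a' Q(s', a')` (intermediate states
#' carry no reward). Idempotent given fixed `T` and goal map.
#'
#' @param mb an `mb_state`.
#' @param reward_map terminal reward vector from [make_goal_reward_map()].
#' @param tree the `decision_tree`.
#' @return the `mb_state` with refreshed `Q1`, `Q2`.
#' @export
backward_plan <- function(mb, reward_map, tree) {
  for (j in seq_len(tree$n_s2))
    for (a in 1:2)
      mb$Q2[j, a] <- sum(mb$T2[j, a, ] * reward_map)
  v2 <- apply(mb$Q2, 1, max)
  for (a in 1:2) mb$Q1[1, a] <- sum(mb$T1[a, ] * v2)
  mb
}

#' Process one trial with the model-based learner
#'
#' At trial start the goal map is refreshed from the trial's goal condition
#' and a backward planning sweep produces the values used for the first
#' choice. After the first transition is observed, the stage-1 transition row
#' is updated forward and the plan refreshed; the stage-2 values then back
#' the second choice. After the terminal state is observed, the stage-2
#' transition row is updated.
#'
#' @param mb an `mb_state`.
#' @param trial one-row data.frame (or list) with `goal_condition`,
#'   `goal_colour`, `s1`, `a1`, `s2`, `a2`, `s3`.
#' @param tree the `decision_tree`.
#' @return list `state` (updated learner), `deltas` (SPE of each of the two
#'   transition updates) and `snapshots` (`q1`: action values backing choice
#'   1; `q2`: values at the visited stage-2 state backing choice 2).
#' @export
mb_process_trial <- function(mb, trial, tree) {
  r <- make_goal_reward_map(tree, trial$goal_condition, trial$goal_colour)
  mb <- backward_plan(mb, r, tree)
  q1 <- mb$Q1[1, ]
  up1 <- forward_update(mb, tree, 1L, 0L, trial$a1, trial$s2)
  mb <- backward_plan(up1$state, r, tree)
  q2 <- mb$Q2[trial$s2 + 1L, ]
  up2 <- forward_update(mb, tree, 2L, trial$s2, trial$a2, trial$s3)
  list(state = up2$state, deltas = c(up1$delta, up2$delta),
       snapshots = list(q1 = q1, q2 = q2))
}
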