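#' Build a three-stage decision tree
#'
#' Constructs the state/action topology of the two-choice, three-stage Markov
#' decision task: one start state, a configurable set of stage-2 states, and a
#' set of terminal states carrying coloured coins. Every non-terminal state
#' offers two actions (left = 0, right = 1); each (state, action) pair has an
#' ordered successor pair (likely, unlikely). Which member of the pair is the
#' "more likely" state is fixed at construction; only the transition
#' probability (0.9 vs 0.5) varies with block uncertainty.
#'
#' Terminal coins take values in \{0, 10, 20, 40\}; the three reward-bearing
#' values each carry one fixed colour (default 40 = red, 20 = blue,
#' 10 = yellow) and value-0 coins are always grey. The default placement puts
#' all four values behind each stage-1 action so that every goal colour is
#' reachable from both first-stage choices, with an asymmetric arrangement so
#' that the optimal action sequence is unique for every goal under low
#' transition uncertainty.
#'
#' @param config optional list overriding defaults: `n_s2` (stage-2 states,
#'   default 4), `n_terminal` (default `2 * n_s2`), `terminal_value` (numeric
#'   vector of coin values, one per terminal), `value_colours` (named vector
#'   mapping value to colour).
#' @return an object of class `decision_tree` with elements `n_s2`,
#'   `n_terminal`, `succ1` (2 x 2 integer matrix, rows = actions, columns =
#'   likely/unlikely stage-2 ids), `succ2` (`n_s2` x 2 x 2 integer array,
#'   \[state, action, likely/unlikely\] terminal ids), `terminal_value` and
#'   `terminal_colour`. All state and action ids are 0-based.
#' @export
#' @examples
#' tree <- build_default_tree()
#' tree$terminal_value
build_default_tree <- function(config = list()) {
  n_s2 <- config$n_s2 %||% 4L
  n_t <- config$n_terminal %||% (2L * n_s2)
  if (n_s2 < 2L) stop("at least 2 stage-2 states are required")
  if (n_t < 4L) stop("at least 4 terminal states are required")

  value_colours <- config$value_colours %||%
    c(`40` = "red", `20` = "blue", `10` = "yellow", `0` = "grey")
  terminal_value <- config$terminal_value %||%
    rep(c(40, 20, 10, 0, 10, 0, 40, 20), length.out = n_t)
  if (length(terminal_value) != n_t)
    stop("terminal_value must have one entry per terminal state")
  if (!all(terminal_value %in% c(0, 10, 20, 40)))
    stop("terminal values must lie in {0, 10, 20, 40}")
  terminal_colour <- unname(value_colours[as.character(terminal_value)])
  if (!all(COIN_COLOURS %in% terminal_colour))
    stop("each of yellow, red and blue must appear on at least one terminal")

  # Stage 1 -> stage 2: action a's likely successor opens half a of the
  # stage-2 set; the unlikely successor is its neighbour.
  half <- floor(n_s2 / 2)
  succ1 <- matrix(NA_integer_, nrow = 2, ncol = 2,
                  dimnames = list(action = c("0", "1"), c("likely", "unlikely")))
  for (a in 0:1) {
    likely <- a * half
    unlikely <- if (likely + 1L <= n_s2 - 1L) likely + 1L else (likely + 1L) %% n_s2
    succ1[a + 1L, ] <- c(likely, unlikely)
  }

  # Stage 2 -> stage 3: state j's action 0 targets terminals (2j, 2j+1)
  # (modulo n_t) as (likely, unlikely); action 1 reverses the pair.
  succ2 <- array(NA_integer_, dim = c(n_s2, 2, 2),
                 dimnames = list(NULL, action = c("0", "1"), c("likely", "unlikely")))
  for (j in seq_len(n_s2) - 1L) {
    pair <- c((2L * j) %% n_t, (2L * j + 1L) %% n_t)
    succ2[j + 1L, 1L, ] <- pair
    succ2[j + 1L, 2L, ] <- rev(pair)
  }

  structure(
    list(n_s2 = n_s2, n_terminal = n_t, succ1 = succ1, succ2 = succ2,
         terminal_value = as.numeric(terminal_value),
         terminal_colour = terminal_colour),
    class = "decision_tree"
  )
}

#' @export
print.decision_tree <- function(x, ...) {
  cat("<decision_tree> 1 start state, ", x$n_s2, " stage-2 states, ",
      x$n_terminal, " terminals\n", sep = "")
  cat("terminal coins: ",
      paste0(x$terminal_value, " (", x$terminal_colour, ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Probability of reaching the designated likely successor
#' @param uncertainty `"low"` or `"high"`.
#' @return 0.9 for low uncertainty, 0.5 for high.
#' @export
likely_probability <- function(uncertainty) {
  switch(match.arg(uncertainty, c("low", "high")), low = 0.9, high = 0.5)
}

successor_pair <- function(tree, stage, state, action) {
  stopifnot(action %in% 0:1)
  if (stage == 1L) {
    if (state != 0L) stop("stage-1 state id must be 0")
    tree$succ1[action + 1L, ]
  } else if (stage == 2L) {
    if (state < 0L || state >= tree$n_s2) stop("invalid stage-2 state id: ", state)
    tree$succ2[state + 1L, action + 1L, ]
  } else {
    stop("terminal states have no successors")
  }
}

#' Sample one probabilistic state transition
#'
#' @param tree a `decision_tree`.
#' @param stage stage of the current state (1 or 2; terminal states error).
#' @param state 0-based state id within its stage.
#' @param action 0 (left) or 1 (right).
#' @param uncertainty `"low"` (likely state reached with probability 0.9) or
#'   `"high"` (0.5). Uses the session RNG; seed via [set.seed()].
#' @return 0-based id of the sampled next-stage state.
#' @export
sample_transition <- function(tree, stage, state, action, uncertainty) {
  pair <- successor_pair(tree, stage, state, action)
  p <- likely_probability(uncertainty)
  if (pair[1] == pair[2]) return(unname(pair[1]))
  unname(if (runif(1) < p) pair[1] else pair[2])
}

#' Ground-truth transition matrices for a tree
#'
#' Returns the row-stochastic stage-1 and stage-2 transition matrices implied
#' by the tree topology and an uncertainty level; used for optimal-policy
#' computation and as an oracle for the learned transition model.
#'
#' @inheritParams sample_transition
#' @return list with `T1` (2 x `n_s2` matrix, rows = stage-1 actions) and
#'   `T2` (`n_s2` x 2 x `n_terminal` array).
#' @export
true_transition_matrix <- function(tree, uncertainty) {
  p <- likely_probability(uncertainty)
  T1 <- matrix(0, nrow = 2, ncol = tree$n_s2)
  for (a in 0:1) {
    pair <- tree$succ1[a + 1L, ]
    T1[a + 1L, pair[1] + 1L] <- T1[a + 1L, pair[1] + 1L] + p
    T1[a + 1L, pair[2] + 1L] <- T1[a + 1L, pair[2] + 1L] + (1 - p)
  }
  T2 <- array(0, dim = c(tree$n_s2, 2, tree$n_terminal))
  for (j in seq_len(tree$n_s2)) {
    for (a in 0:1) {
      pair <- tree$succ2[j, a + 1L, ]
      T2[j, a + 1L, pair[1] + 1L] <- T2[j, a + 1L, pair[1] + 1L] + p
      T2[j, a + 1L, pair[2] + 1L] <- T2[j, a + 1L, pair[2] + 1L] + (1 - p)
    }
  }
  list(T1 = T1, T2 = T2)
}

#' Goal-contingent terminal reward vector
#'
#' Under a specific goal only coins of the cued colour are accepted; under the
#' flexible goal every coloured coin is accepted. Grey (value 0) coins reward
#' nothing in either condition.
#'
#' @param tree a `decision_tree`.
#' @param goal_condition `"specific"` or `"flexible"`.
#' @param goal_colour coin colour for specific goals; ignored (may be
#'   `"none"`) for flexible goals.
#' @return numeric vector of rewards, one per terminal state.
#' @export
goal_reward_vector <- function(tree, goal_condition, goal_colour = "none") {
  goal_condition <- match.arg(goal_condition, c("specific", "flexible"))
  if (goal_condition == "flexible") return(tree$terminal_value)
  if (!goal_colour %in% COIN_COLOURS)
    stop("a specific goal requires a colour in {",
         paste(COIN_COLOURS, collapse = ", "), "}")
  ifelse(tree$terminal_colour == goal_colour, tree$terminal_value, 0)
}

#' Generate a randomly ordered block schedule
#'
#' The session comprises `n_per_type` blocks of each of the four types
#' (specific/flexible goal x low/high transition uncertainty) in a uniformly
#' random order. Low-uncertainty blocks run 3-5 trials, high-uncertainty
#' blocks 5-7 (uniform); each specific block is cued one goal colour drawn
#' uniformly from yellow/red/blue, constant within the block.
#'
#' @param n_per_type blocks per type (default 14, i.e. 56 blocks and 280
#'   trials in expectation). Uses the session RNG; seed via [set.seed()].
#' @return data.frame with columns `block_index` (1-based), `goal_condition`,
#'   `uncertainty`, `goal_colour` (`"none"` for flexible blocks), `length`.
#' @export
generate_block_schedule <- function(n_per_type = 14L) {
  types <- expand.grid(goal_condition = c("specific", "flexible"),
                       uncertainty = c("low", "high"),
                       stringsAsFactors = FALSE)
  blocks <- types[rep(seq_len(nrow(types)), each = n_per_type), ]
  blocks <- blocks[sample.int(nrow(blocks)), , drop = FALSE]
  blocks$length <- ifelse(blocks$uncertainty == "low",
                          sample(3:5, nrow(blocks), replace = TRUE),
                          sample(5:7, nrow(blocks), replace = TRUE))
  blocks$goal_colour <- ifelse(
    blocks$goal_condition == "specific",
    sample(COIN_COLOURS, nrow(blocks), replace = TRUE),
    "none")
  blocks$block_index <- seq_len(nrow(blocks))
  rownames(blocks) <- NULL
  blocks[, c("block_index", "goal_condition", "uncertainty", "goal_colour", "length")]
}

#' Expected session length of the block schedule
#'
#' Closed form: `n_per_type` blocks each of the 2 low-uncertainty types with
#' mean length mean(3:5) = 4 and of the 2 high-uncertainty types with mean
#' length mean(5:7) = 6.
#'
#' @inheritParams generate_block_schedule
#' @return expected number of trials (280 at the default 14 blocks per type).
#' @export
expected_session_length <- function(n_per_type = 14L) {
  2 * n_per_type * mean(3:5) + 2 * n_per_type * mean(5:7)
}

#' Optimal action sequence for a goal
#'
#' Enumerates the expected goal-contingent reward of both stage-1 actions and,
#' per stage-2 state, both stage-2 actions under the true transition
#' probabilities, and returns the reward-maximising sequence. Exact ties are
#' broken toward the lexicographically first action and flagged.
#'
#' @inheritParams sample_transition
#' @param goal a coin colour (specific condition) or `"any"` (flexible).
#' @return list with `a1` (optimal stage-1 action), `a2` (vector of optimal
#'   stage-2 actions, one per stage-2 state), `expected_value` (of the optimal
#'   policy from the start state), `a1_tie` / `a2_tie` (logical tie flags) and
#'   `q2` (the `n_s2` x 2 matrix of stage-2 action values).
#' @export
optimal_action_sequence <- function(tree, uncertainty, goal = "any") {
  cond <- if (identical(goal, "any")) "flexible" else "specific"
  r <- goal_reward_vector(tree, cond, goal)
  Tm <- true_transition_matrix(tree, uncertainty)
  q2 <- matrix(0, nrow = tree$n_s2, ncol = 2)
  for (j in seq_len(tree$n_s2))
    for (a in 1:2) q2[j, a] <- sum(Tm$T2[j, a, ] * r)
  v2 <- apply(q2, 1, max)
  q1 <- as.numeric(Tm$T1 %*% v2)
  a2 <- max.col(q2, ties.method = "first") - 1L
  a2_tie <- abs(q2[, 1] - q2[, 2]) < 1e-12
  a1 <- which.max(q1) - 1L
  a1_tie <- abs(q1[1] - q1[2]) < 1e-12
  list(a1 = a1, a2 = a2, expected_value = max(q1),
       a1_tie = a1_tie, a2_tie = a2_tie, q1 = q1, q2 = q2)
}

#' Task performance: mean coins per trial
#' @param session a session data.frame (see [simulate_subject()]).
#' @return average of `reward` over trials.
#' @export
task_performance <- function(session) {
  if (nrow(session) == 0) stop("empty session")
  mean(session$reward)
}

#' Choice optimality: percentage of trials with an optimal decision sequence
#'
#' A trial counts as optimal when the stage-1 choice and the stage-2 choice at
#' the visited stage-2 state both maximise expected goal-contingent reward
#' under the trial's uncertainty and goal. With `ties = "any"` (default) an
#' action whose expected value equals the maximum is optimal even when tied;
#' `ties = "strict"` requires a match to the lexicographically tie-broken
#' sequence of [optimal_action_sequence()].
#'
#' @inheritParams task_performance
#' @param tree the `decision_tree` the session was played on.
#' @param ties `"any"` or `"strict"`.
#' @return percentage in \[0, 100\].
#' @export
choice_optimality <- function(session, tree, ties = c("any", "strict")) {
  ties <- match.arg(ties)
  if (nrow(session) == 0) stop("empty session")
  keys <- unique(session[, c("uncertainty", "goal_condition", "goal_colour")])
  ok <- logical(nrow(session))
  for (k in seq_len(nrow(keys))) {
    goal <- if (keys$goal_condition[k] == "flexible") "any" else keys$goal_colour[k]
    opt <- optimal_action_sequence(tree, keys$uncertainty[k], goal)
    idx <- which(session$uncertainty == keys$uncertainty[k] &
                 session$goal_condition == keys$goal_condition[k] &
                 session$goal_colour == keys$goal_colour[k])
    for (i in idx) {
      s2 <- session$s2[i] + 1L
      if (ties == "strict") {
        ok[i] <- session$a1[i] == opt$a1 && session$a2[i] == opt$a2[s2]
      } else {
        max1 <- max(opt$q1); max2 <- max(opt$q2[s2, ])
        ok[i] <- (opt$q1[session$a1[i] + 1L] >= max1 - 1e-12) &&
                 (opt$q2[s2, session$a2[i] + 1L] >= max2 - 1e-12)
      }
    }
  }
  100 * mean(ok)
}
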