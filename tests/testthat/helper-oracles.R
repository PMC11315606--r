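# Shared fixtures and independent oracles used across test files.

default_tree <- build_default_tree()

# Brute-force policy evaluation: the value of one fixed policy (a1, and one
# a2 per stage-2 state) is computed by explicit path enumeration; the optimal
# value is the max over all 2 * 2^n_s2 policies. Independent of the backward
# planning sweep.
bf_policy_value <- function(T1, T2, r, a1, a2vec) {
  v <- 0
  for (j in seq_along(a2vec)) {
    p_s2 <- T1[a1 + 1L, j]
    if (p_s2 == 0) next
    v <- v + p_s2 * sum(T2[j, a2vec[j] + 1L, ] * r)
  }
  v
}

bf_optimal <- function(T1, T2, r, n_s2) {
  best <- -Inf
  for (a1 in 0:1) {
    grid <- expand.grid(rep(list(0:1), n_s2))
    for (g in seq_len(nrow(grid))) {
      v <- bf_policy_value(T1, T2, r, a1, as.integer(grid[g, ]))
      if (v > best) best <- v
    }
  }
  best
}

# Brute-force expectimax action values for comparison with backward_plan():
# stage-2 values by direct expectation, stage-1 values by enumerating the
# stage-2 policy rather than sweeping.
bf_expectimax_q <- function(T1, T2, r, n_s2) {
  q2 <- matrix(0, n_s2, 2)
  for (j in seq_len(n_s2))
    for (a in 1:2) q2[j, a] <- sum(T2[j, a, ] * r)
  q1 <- numeric(2)
  for (a1 in 0:1) {
    grid <- expand.grid(rep(list(0:1), n_s2))
    vals <- apply(grid, 1, function(g)
      bf_policy_value(T1, T2, r, a1, as.integer(g)))
    q1[a1 + 1L] <- max(vals)
  }
  list(q1 = q1, q2 = q2)
}

# Brute-force Benjamini-Hochberg step-up: q_(k) = min_{j >= k} n * p_(j) / j.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (k in seq_len(n)) {
    cand <- vapply(k:n, function(j) n * p[o[j]] / j, numeric(1))
    adj[o[k]] <- min(1, min(cand))
  }
  adj
}

# A tree with random terminal-value placement (topology fixed); used for the
# oracle-equivalence sweeps.
random_tree <- function() {
  vals <- c(40, 20, 10, 0, sample(c(40, 20, 10, 0), 4, replace = TRUE))
  build_default_tree(list(terminal_value = sample(vals)))
}

# Random row-stochastic transition model on the successor supports of a tree,
# installed into an mb_state.
random_mb_T <- function(tree, eta = 0.3) {
  mb <- mb_state(tree, eta)
  for (a in 0:1) {
    pair <- tree$succ1[a + 1L, ]
    p <- runif(1)
    row <- rep(0, tree$n_s2)
    row[pair[1] + 1L] <- p
    row[pair[2] + 1L] <- row[pair[2] + 1L] + 1 - p
    mb$T1[a + 1L, ] <- row
  }
  for (j in seq_len(tree$n_s2)) {
    for (a in 0:1) {
      pair <- tree$succ2[j, a + 1L, ]
      p <- runif(1)
      row <- rep(0, tree$n_terminal)
      row[pair[1] + 1L] <- p
      row[pair[2] + 1L] <- row[pair[2] + 1L] + 1 - p
      mb$T2[j, a + 1L, ] <- row
    }
  }
  mb
}

# A deterministic variant of the default tree: every successor pair is
# collapsed onto its likely member, so transitions are certain.
deterministic_tree <- function() {
  tree <- build_default_tree()
  for (a in 1:2) tree$succ1[a, 2] <- tree$succ1[a, 1]
  for (j in seq_len(tree$n_s2))
    for (a in 1:2) tree$succ2[j, a, 2] <- tree$succ2[j, a, 1]
  tree
}

# Short synthetic session for fast fitting tests.
small_session <- function(seed = 1, agent = agent_spec("pure_mf", alpha = 0.4,
                                                       tau = 2),
                          n_per_type = 3L) {
  simulate_subject(agent, default_tree, seed = seed, n_per_type = n_per_type)
}
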