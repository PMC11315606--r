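#' Specify a synthetic agent
#'
#' Agents blend model-based and model-free action values before the softmax:
#' `Q = w * Q_MB + (1 - w) * Q_MF`, with the MB weight `w` allowed to depend
#' on the goal condition (`w_specific`, `w_flexible`). `kind = "pure_mb"`
#' fixes both weights at 1 and `"pure_mf"` at 0; a `"mixture"` agent uses the
#' supplied weights. The blend is a fixed-weight stand-in that makes the
#' arbitration metrics exercisable; it is not a reliability-based arbitration
#' controller. Both learners are always updated from experience, so an agent
#' behaves exactly like the corresponding fitted model when its weight is 0
#' or 1.
#'
#' @param kind `"pure_mb"`, `"pure_mf"` or `"mixture"`.
#' @param alpha MF learning rate in (0, 1).
#' @param eta MB learning rate in (0, 1).
#' @param tau softmax inverse temperature (on the coin-value scale).
#' @param w_specific,w_flexible MB weights per goal condition (mixture only).
#' @return object of class `agent_spec`.
#' @export
agent_spec <- function(kind = c("mixture", "pure_mb", "pure_mf"),
                       alpha = 0.5, eta = 0.5, tau = 2,
                       w_specific = 0.5, w_flexible = 0.5) {
  kind <- match.arg(kind)
  if (kind == "pure_mb") w_specific <- w_flexible <- 1
  if (kind == "pure_mf") w_specific <- w_flexible <- 0
  if (w_specific < 0 || w_specific > 1 || w_flexible < 0 || w_flexible > 1)
    stop("mixture weights must lie in [0, 1]")
  if (tau < 0) stop("tau must be non-negative")
  structure(list(kind = kind, alpha = alpha, eta = eta, tau = tau,
                 w_specific = w_specific, w_flexible = w_flexible),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat("<agent_spec>", x$kind,
      sprintf("alpha = %.2f eta = %.2f tau = %.2f w = (%.2f, %.2f)",
              x$alpha, x$eta, x$tau, x$w_specific, x$w_flexible), "\n")
  invisible(x)
}

play_blocks <- function(agent, tree, blocks, mf, mb, training = FALSE) {
  rows <- vector("list", sum(blocks$length))
  k <- 0L
  for (b in seq_len(nrow(blocks))) {
    cond <- blocks$goal_condition[b]
    unc <- blocks$uncertainty[b]
    colour <- blocks$goal_colour[b]
    w <- if (cond == "specific") agent$w_specific else agent$w_flexible
    r <- goal_reward_vector(tree, cond, colour)
    for (t in seq_len(blocks$length[b])) {
      mb <- backward_plan(mb, r, tree)
      q1 <- w * mb$Q1[1, ] + (1 - w) * mf$Q1[1, ]
      a1 <- if (runif(1) < softmax_probs(q1, agent$tau)[1]) 0L else 1L
      s2 <- sample_transition(tree, 1L, 0L, a1, unc)
      mb <- backward_plan(forward_update(mb, tree, 1L, 0L, a1, s2)$state,
                          r, tree)
      q2 <- w * mb$Q2[s2 + 1L, ] + (1 - w) * mf$Q2[s2 + 1L, ]
      a2 <- if (runif(1) < softmax_probs(q2, agent$tau)[1]) 0L else 1L
      s3 <- sample_transition(tree, 2L, s2, a2, unc)
      mb <- forward_update(mb, tree, 2L, s2, a2, s3)$state
      reward <- r[s3 + 1L]
      trial <- list(s1 = 0L, a1 = a1, s2 = s2, a2 = a2, reward = reward)
      mf <- mf_process_trial(mf, trial)$state
      k <- k + 1L
      rows[[k]] <- data.frame(
        trial_index = NA_integer_, block_index = blocks$block_index[b],
        goal_condition = cond, uncertainty = unc, goal_colour = colour,
        s1 = 0L, a1 = a1, s2 = s2, a2 = a2, s3 = s3,
        coin_value = tree$terminal_value[s3 + 1L],
        coin_colour = tree$terminal_colour[s3 + 1L],
        reward = reward, training = training)
    }
  }
  list(trials = do.call(rbind, rows), mf = mf, mb = mb)
}

training_blocks <- function() {
  # 80 flexible + 20 specific familiarisation trials, assembled from
  # standard-length blocks of both uncertainty levels and truncated to the
  # exact counts. Negative block indices mark the phase.
  make <- function(cond, n_target) {
    rows <- list()
    total <- 0L
    while (total < n_target) {
      unc <- sample(c("low", "high"), 1)
      len <- if (unc == "low") sample(3:5, 1) else sample(5:7, 1)
      len <- min(len, n_target - total)
      colour <- if (cond == "specific") sample(COIN_COLOURS, 1) else "none"
      rows[[length(rows) + 1L]] <- data.frame(
        block_index = NA_integer_, goal_condition = cond, uncertainty = unc,
        goal_colour = colour, length = len)
      total <- total + len
    }
    do.call(rbind, rows)
  }
  out <- rbind(make("flexible", 80L), make("specific", 20L))
  out$block_index <- -rev(seq_len(nrow(out)))
  out[, c("block_index", "goal_condition", "uncertainty", "goal_colour", "length")]
}

#' Simulate one subject's full session
#'
#' Generates a block schedule and plays it with a synthetic agent: at each
#' choice the agent blends the current MB plan with its MF values, samples an
#' action through the softmax, experiences a probabilistic transition, and
#' updates both learners exactly as the fitted models would (the generator
#' and the likelihood share one set of update rules). Rewards follow the
#' goal-contingency rule of the trial's block.
#'
#' @param agent an [agent_spec()].
#' @param tree a `decision_tree`.
#' @param seed integer seed; the same seed reproduces the session exactly.
#' @param n_per_type blocks per block type (default 14; 56 blocks total).
#' @param include_training if TRUE, the agent first plays an 80-flexible +
#'   20-specific trial training phase (learning from it), and those trials
#'   are returned flagged `training = TRUE`. Training trials are excluded
#'   from fitting and metrics by the pipeline.
#' @return session data.frame, one row per trial, with the columns of the
#'   session CSV schema plus a logical `training` column; the block schedule
#'   is attached as attribute `"schedule"` and the seed as `"seed"`.
#' @export
simulate_subject <- function(agent, tree, seed = 1L, n_per_type = 14L,
                             include_training = FALSE) {
  stopifnot(inherits(agent, "agent_spec"))
  set.seed(seed)
  mf <- mf_state(tree, alpha = agent$alpha)
  mb <- mb_state(tree, eta = agent$eta)
  parts <- list()
  if (include_training) {
    tb <- training_blocks()
    out <- play_blocks(agent, tree, tb, mf, mb, training = TRUE)
    mf <- out$mf; mb <- out$mb
    parts[[1]] <- out$trials
  }
  schedule <- generate_block_schedule(n_per_type)
  out <- play_blocks(agent, tree, schedule, mf, mb, training = FALSE)
  parts[[length(parts) + 1L]] <- out$trials
  session <- do.call(rbind, parts)
  session$trial_index <- seq_len(nrow(session))
  rownames(session) <- NULL
  attr(session, "schedule") <- schedule
  attr(session, "seed") <- seed
  session
}

#' Drop training-phase trials from a session
#' @param session a session data.frame.
#' @return the main-phase trials only.
#' @export
main_trials <- function(session) {
  if (!"training" %in% names(session)) return(session)
  out <- session[!session$training, , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_agent <- function(agent, i) {
  if (inherits(agent, "agent_spec")) agent
  else if (is.function(agent)) agent(i)
  else stop("agent must be an agent_spec or a function(subject_index)")
}

#' Simulate a patient and a control cohort
#'
#' Each cohort spec is a list with `label`, `n` (subjects) and `agent`
#' (either a fixed [agent_spec()] or a `function(i)` returning one per
#' subject, for heterogeneous cohorts). Every subject receives a derived,
#' recorded seed.
#'
#' @param patient,control cohort specs as described above.
#' @param tree a `decision_tree`.
#' @param seed master seed.
#' @param n_per_type blocks per type per session.
#' @return list with `sessions` (named list of session data.frames),
#'   `groups` (data.frame `subject`, `group`) and `manifest` (per-subject
#'   generating parameters and seeds).
#' @export
simulate_cohorts <- function(patient, control, tree, seed = 1L,
                             n_per_type = 14L) {
  specs <- list(patient, control)
  sessions <- list()
  groups <- list()
  manifest <- list()
  idx <- 0L
  for (g in 1:2) {
    spec <- specs[[g]]
    if (is.null(spec$n) || spec$n < 1) stop("each cohort needs n >= 1 subjects")
    for (i in seq_len(spec$n)) {
      idx <- idx + 1L
      id <- paste0(spec$label, "_", sprintf("%02d", i))
      agent <- resolve_agent(spec$agent, i)
      subj_seed <- (seed * 7919L + idx * 131L) %% .Machine$integer.max
      sessions[[id]] <- simulate_subject(agent, tree, seed = subj_seed,
                                         n_per_type = n_per_type)
      groups[[idx]] <- data.frame(subject = id, group = spec$label)
      manifest[[id]] <- c(unclass(agent), list(seed = subj_seed))
    }
  }
  list(sessions = sessions, groups = do.call(rbind, groups),
       manifest = manifest)
}
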