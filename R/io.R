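SESSION_COLUMNS <- c("trial_index", "block_index", "goal_condition",
                     "uncertainty", "goal_colour", "s1", "a1", "s2", "a2",
                     "s3", "coin_value", "coin_colour", "reward")

#' Write a session to CSV
#'
#' One row per trial with the schema columns (actions coded 0/1, states by
#' 0-based stage-local ids, colours lowercase, `goal_colour = "none"` for
#' flexible blocks). The generating seed, when known, is written as a `#`
#' comment header so every output records its provenance.
#'
#' @param session session data.frame.
#' @param path output file path.
#' @export
write_session_csv <- function(session, path) {
  cols <- intersect(c(SESSION_COLUMNS, "training"), names(session))
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(session, "seed")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.csv(session[, cols], con, row.names = FALSE, quote = FALSE)
}

#' Read a session from CSV
#'
#' Validates the schema (all columns present, state/action codes within the
#' tree's ranges, transitions consistent with the successor pairs) and warns
#' -- without failing -- when a recorded reward disagrees with the
#' goal-contingency rule, for tolerance toward externally produced data.
#'
#' @param path CSV file path (`#` lines are treated as comments).
#' @param tree optional `decision_tree`; enables the structural checks.
#' @return session data.frame.
#' @export
read_session_csv <- function(path, tree = NULL) {
  session <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(SESSION_COLUMNS, names(session))
  if (length(miss))
    stop("session CSV is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(tree)) {
    check_session_tree(session, tree)
    for (i in seq_len(nrow(session))) {
      p1 <- successor_pair(tree, 1L, session$s1[i], session$a1[i])
      if (!session$s2[i] %in% p1)
        stop("row ", i, ": s2 = ", session$s2[i],
             " is not a successor of (s1, a1)")
      p2 <- successor_pair(tree, 2L, session$s2[i], session$a2[i])
      if (!session$s3[i] %in% p2)
        stop("row ", i, ": s3 = ", session$s3[i],
             " is not a successor of (s2, a2)")
    }
    expected <- vapply(seq_len(nrow(session)), function(i)
      goal_reward_vector(tree, session$goal_condition[i],
                         session$goal_colour[i])[session$s3[i] + 1L],
      numeric(1))
    bad <- which(abs(expected - session$reward) > 1e-9)
    if (length(bad))
      warning("reward inconsistent with the goal rule in row(s): ",
              paste(utils::head(bad, 5), collapse = ", "),
              if (length(bad) > 5) " ..." else "")
  }
  session
}

config_defaults <- function() {
  list(
    seed = 1L,
    n_per_type = 14L,
    n_restarts = 200L,
    tree = list(),
    patient = list(label = "patient", n = 19L,
                   agent = list(kind = "mixture", alpha = 0.5, eta = 0.5,
                                tau = 2, w_specific = 0.5, w_flexible = 0.5)),
    control = list(label = "control", n = 19L,
                   agent = list(kind = "mixture", alpha = 0.5, eta = 0.5,
                                tau = 2, w_specific = 0.8, w_flexible = 0.2))
  )
}

#' Read a pipeline/task configuration from YAML
#' @param path YAML file path.
#' @return configuration list merged over the package defaults.
#' @export
read_pipeline_config <- function(path) {
  modifyList(config_defaults(), yaml::read_yaml(path))
}

cohort_spec_from_config <- function(spec) {
  list(label = spec$label, n = as.integer(spec$n),
       agent = do.call(agent_spec, spec$agent))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a patient and a control cohort, fits the MB and MF models to
#' every subject, derives the arbitration metrics, and runs the
#' patient-vs-control comparison with FDR correction. Deterministic given the
#' configured seed. If `out_dir` is given, writes per-subject `session_*.csv`
#' files, `metrics.csv`, `stats.csv`, `groups.csv` and a `manifest.json`
#' recording the package version, configuration and all derived seeds.
#'
#' @param config configuration list (see `read_pipeline_config()`), or a path
#'   to a YAML file; missing entries fall back to package defaults.
#' @param out_dir optional output directory (created if needed).
#' @return list with `tree`, `sessions`, `groups`, `fits`, `metrics`,
#'   `stats`, `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- modifyList(config_defaults(), config)
  if (config$n_restarts < 200)
    message("note: using ", config$n_restarts,
            " restarts (the study default is 200)")
  tree <- build_default_tree(config$tree)
  sim <- simulate_cohorts(cohort_spec_from_config(config$patient),
                          cohort_spec_from_config(config$control),
                          tree, seed = config$seed,
                          n_per_type = config$n_per_type)
  sessions <- lapply(sim$sessions, main_trials)
  fits <- fit_cohort(sessions, tree, n_restarts = config$n_restarts,
                     seed = config$seed)
  metrics <- cohort_metrics(sessions, fits, tree)
  stats <- compare_groups(metrics, sim$groups,
                          patient = config$patient$label,
                          control = config$control$label)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(sim$sessions))
      write_session_csv(sim$sessions[[id]],
                        file.path(out_dir, paste0("session_", id, ".csv")))
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(stats, file.path(out_dir, "stats.csv"), row.names = FALSE)
    write.csv(sim$groups, file.path(out_dir, "groups.csv"), row.names = FALSE)
    manifest <- list(
      package = "threestage",
      version = as.character(utils::packageVersion("threestage")),
      seed = config$seed, config = config,
      subject_seeds = lapply(sim$manifest, `[[`, "seed"),
      fit_seeds = lapply(fits, function(f) c(mb = f$seed_mb, mf = f$seed_mf)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(tree = tree, sessions = sessions, groups = sim$groups, fits = fits,
       metrics = metrics, stats = stats, config = config)
}
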