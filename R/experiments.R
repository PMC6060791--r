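# The four canonical experiments: pure epistemic exploration, navigation
# on a familiar maze, goal-directed exploration of a novel maze, and the
# familiarity (exposure-duration) sweep.

check_solvable <- function(maze) {
  if (is.null(shortest_path(maze, maze$start, maze$target))) {
    stopf("maze is unsolvable: no open path from start to target")
  }
}

#' Pure epistemic exploration of a novel maze
#'
#' Runs two-move trials on a novel model (all what-concentrations 1/8)
#' with flat preferences; behaviour is driven entirely by the novelty
#' term, so 32 trials produce 64 information-seeking moves and the learned
#' concentration map stays at 50% in, and only in, unvisited cells.
#'
#' @param maze a solvable `maze_grid`.
#' @param n_trials number of two-move trials (default 32).
#' @param config an `agent_config`.
#' @param record keep the full neural trace.
#' @return a `session_trace`.
#' @export
run_exploration <- function(maze, n_trials = 32, config = agent_config(),
                            record = TRUE) {
  check_solvable(maze)
  model <- build_model(maze, "novel")
  run_session(maze, model, config, n_trials = n_trials,
              preferences = NULL, learn = TRUE, record = record)
}

#' Goal-directed navigation
#'
#' Navigates start to target under diffusion subgoal preferences,
#' refreshed before every trial. By default the maze is familiar
#' (concentrations of 128) and learning is off; pass a concentration
#' matrix (e.g. a snapshot from exploration) to navigate under partial
#' knowledge.
#'
#' @param maze a solvable `maze_grid`.
#' @param concentrations `"familiar"`, `"novel"`, or a 2 x n_states
#'   concentration matrix.
#' @param max_trials move budget in trials (default 16, i.e. 32 moves).
#' @param config an `agent_config`.
#' @param learn accumulate concentrations while navigating (default off).
#' @param record keep the full neural trace (off by default: sweeps call
#'   this in bulk).
#' @return a `session_trace` with a `metrics` element appended.
#' @export
run_navigation <- function(maze, concentrations = "familiar",
                           max_trials = 16, config = agent_config(),
                           learn = FALSE, record = FALSE) {
  check_solvable(maze)
  model <- build_model(maze, concentrations)
  tr <- run_session(maze, model, config, n_trials = max_trials,
                    preferences = "diffusion", learn = learn,
                    stop_at_target = TRUE, record = record)
  tr$metrics <- performance_metrics(tr$path, maze)
  tr
}

#' Goal-directed exploration of a novel maze
#'
#' Several searches of a few trials each on a novel maze, with diffusion
#' subgoal preferences active from the start: epistemic and pragmatic
#' value compete. The agent returns to the start cell between searches;
#' concentration parameters persist throughout.
#'
#' @param maze a solvable `maze_grid`.
#' @param searches number of searches (default 4).
#' @param trials_per_search trials per search (default 8, i.e. 16 moves).
#' @param config an `agent_config`.
#' @param record keep the full neural trace per search.
#' @return list with `searches` (one `session_trace` each), `metrics`
#'   (one row per search: latency, mistakes, reached, distinct cells) and
#'   the final `model`.
#' @export
run_goal_exploration <- function(maze, searches = 4, trials_per_search = 8,
                                 config = agent_config(), record = FALSE) {
  check_solvable(maze)
  model <- build_model(maze, "novel")
  out <- vector("list", searches)
  met <- vector("list", searches)
  for (k in seq_len(searches)) {
    tr <- run_session(maze, model, config, n_trials = trials_per_search,
                      preferences = "diffusion", learn = TRUE,
                      start = maze$start, record = record)
    model <- tr$model
    m <- performance_metrics(tr$path, maze)
    met[[k]] <- data.frame(search = k, latency = m$latency,
                           mistakes = m$mistakes, reached = m$reached,
                           distinct_cells = length(unique(c(maze$start,
                                                            tr$path$to))))
    out[[k]] <- tr
  }
  list(searches = out, metrics = do.call(rbind, met), model = model)
}

#' Familiarity sweep: exposure duration versus navigation performance
#'
#' Runs one pure exploration session, snapshotting the accumulated
#' concentrations at increasing simulated durations (moves x outcome
#' period; 16 s at 256 ms per move is 62 moves), then freezes learning and
#' navigates start to target from each snapshot, recording latency and
#' mistakes per exposure duration.
#'
#' @param maze a solvable `maze_grid`.
#' @param durations_s exposure durations in seconds of simulated time
#'   (default 2 to 16 in 2 s steps).
#' @param config an `agent_config`.
#' @param max_trials navigation budget in trials per duration.
#' @param include_zero prepend a zero-exposure (fresh novel model) row.
#' @return data.frame with one row per duration: `duration_s`, `moves`,
#'   `latency`, `mistakes`, `reached`, `shortest_path_len`.
#' @export
run_familiarity_sweep <- function(maze, durations_s = seq(2, 16, by = 2),
                                  config = agent_config(), max_trials = 16,
                                  include_zero = FALSE) {
  check_solvable(maze)
  moves_per_trial <- config$horizon
  s_per_move <- config$outcome_ms / 1000
  trials_at <- vapply(durations_s, function(d)
    max(0L, as.integer(round(d / (moves_per_trial * s_per_move)))),
    integer(1))
  explore <- run_exploration(maze, n_trials = max(c(trials_at, 1L)),
                             config = config, record = FALSE)
  spl <- length(shortest_path(maze)) - 1L
  if (include_zero) { durations_s <- c(0, durations_s); trials_at <- c(0L, trials_at) }
  rows <- lapply(seq_along(durations_s), function(i) {
    k <- trials_at[i]
    a <- if (k == 0L) build_model(maze, "novel")$a_what else explore$a_after[[k]]
    nav <- run_navigation(maze, concentrations = a, max_trials = max_trials,
                          config = config, learn = FALSE, record = FALSE)
    m <- nav$metrics
    data.frame(duration_s = durations_s[i], moves = k * moves_per_trial,
               latency = m$latency, mistakes = m$mistakes,
               reached = m$reached, shortest_path_len = spl)
  })
  do.call(rbind, rows)
}

#' Smallest exposure achieving mistake-free navigation
#'
#' Scans exposure durations in increasing order and returns the first
#' duration whose frozen-snapshot navigation reaches the target with zero
#' mistakes (`Inf` if none in the grid does).
#'
#' @inheritParams run_familiarity_sweep
#' @return scalar duration in seconds (possibly `Inf`).
#' @export
exposure_to_zero_mistakes <- function(maze, durations_s = seq(2, 24, by = 2),
                                      config = agent_config(),
                                      max_trials = 16) {
  check_solvable(maze)
  moves_per_trial <- config$horizon
  s_per_move <- config$outcome_ms / 1000
  trials_at <- vapply(durations_s, function(d)
    max(1L, as.integer(round(d / (moves_per_trial * s_per_move)))),
    integer(1))
  explore <- run_exploration(maze, n_trials = max(trials_at),
                             config = config, record = FALSE)
  for (i in seq_along(durations_s)) {
    a <- explore$a_after[[trials_at[i]]]
    nav <- run_navigation(maze, concentrations = a, max_trials = max_trials,
                          config = config, learn = FALSE, record = FALSE)
    if (nav$metrics$reached && nav$metrics$mistakes == 0) {
      return(durations_s[i])
    }
  }
  Inf
}
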