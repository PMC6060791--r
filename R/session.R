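# Trial and session execution: runs the perception / policy selection /
# precision / action / learning cycle and accumulates the time-binned
# session trace that all neural readouts and behavioural metrics consume.

#' Run a session of trials
#'
#' Each trial comprises `horizon + 1` epochs. Per epoch the agent observes
#' its current cell, relaxes its state beliefs under every policy, scores
#' policies by expected free energy, updates precision, and (for the first
#' `horizon` epochs) executes the most likely action. Beliefs reset at
#' trial boundaries with the initial prior set to a delta at the agent's
#' location; concentration parameters persist. With
#' `preferences = "diffusion"` the location preferences are recomputed
#' before every trial from the current posterior over open cells.
#'
#' @param maze a `maze_grid`.
#' @param model a `gen_model` (modified concentrations are returned, not
#'   mutated in place).
#' @param config an `agent_config`.
#' @param n_trials number of trials to run.
#' @param policy_set a `policy_set` (defaults to all `horizon`-move
#'   policies).
#' @param preferences `NULL` (flat), `"diffusion"`, or a fixed numeric
#'   log-preference vector over states.
#' @param learn accumulate likelihood concentrations at trial ends.
#' @param start starting cell (defaults to the maze's).
#' @param stop_at_target end the session at the end of the first trial in
#'   which the target is visited.
#' @param record keep the full time-binned trace (disable for speed in
#'   large sweeps; the path log and learning are always kept).
#' @return object of class `session_trace`; see Details.
#' @details The trace contains `firing` and `depol`
#'   (`n_states * epochs_per_trial` rows by one column per
#'   `outcome_ms / iterations_per_epoch` bin, rows epoch-major so rows
#'   1..n are epoch-1 units), `gamma`, `fe`, `location`, `trial`, `epoch`
#'   and `iter` per bin, the per-move `path` log, per-epoch `outcomes`,
#'   per-trial concentration snapshots `a_after`, and the final updated
#'   `model`.
#' @export
run_session <- function(maze, model, config = agent_config(),
                        n_trials = 32,
                        policy_set = enumerate_policies(ACTIONS, config$horizon),
                        preferences = NULL, learn = TRUE,
                        start = maze$start, stop_at_target = FALSE,
                        record = TRUE) {
  n <- model$n_states
  Tn <- config$epochs_per_trial
  iters <- config$iterations_per_epoch
  nb_max <- n_trials * Tn * iters
  units <- n * Tn

  firing <- if (record) matrix(NA_real_, units, nb_max)
  depol <- if (record) matrix(NA_real_, units, nb_max)
  gamma_b <- numeric(nb_max); fe_b <- numeric(nb_max)
  loc_b <- integer(nb_max); trial_b <- integer(nb_max)
  epoch_b <- integer(nb_max); iter_b <- integer(nb_max)
  bin <- 0L

  path <- vector("list", n_trials * config$horizon)
  outcome_log <- vector("list", n_trials * Tn)
  a_after <- vector("list", n_trials)
  pref_log <- vector("list", n_trials)
  nmove <- 0L; nobs <- 0L

  loc <- as.integer(start)
  n_run <- 0L
  for (tr in seq_len(n_trials)) {
    C_where <- model$C_where
    if (identical(preferences, "diffusion")) {
      g <- build_graph_laplacian(open_probability(model), model$B)
      C_where <- as.numeric(preference_vector(g, loc, maze$target))
    } else if (is.numeric(preferences)) {
      C_where <- preferences
    }
    pref_log[[tr]] <- C_where
    model$D <- numeric(n); model$D[loc] <- 1

    v_beliefs <- NULL
    outcomes <- vector("list", Tn)
    sbar_final <- matrix(0, n, Tn)
    hit <- FALSE
    for (tau in seq_len(Tn)) {
      o <- observe_cell(maze, loc)
      outcomes[[tau]] <- o
      nobs <- nobs + 1L
      outcome_log[[nobs]] <- data.frame(trial = tr, epoch = tau,
                                        what = o$what, where = o$where)
      inf <- infer_states(model, policy_set, outcomes, beliefs = v_beliefs,
                          config = config, keep_iterates = record)
      v_beliefs <- inf$v
      efe <- expected_free_energy(model, inf$s, t_now = tau,
                                  C_what = model$C_what, C_where = C_where,
                                  novelty_on = config$novelty_on)
      prec <- update_precision(efe$G, inf$F_policy, beta0 = config$beta0,
                               iterations = iters)
      pi_post <- prec$pi_posterior
      sbar_final <- matrix(matrix(inf$s, n * Tn) %*% pi_post, n, Tn)

      idx <- bin + seq_len(iters)
      if (record) {
        for (i in seq_len(iters)) {
          sb <- matrix(inf$s_iter[, , , i], n * Tn, dim(inf$s)[3]) %*% pi_post
          firing[, idx[i]] <- sb
          depol[, idx[i]] <- ln_floor(sb)
        }
      }
      gamma_b[idx] <- prec$gamma_trace
      fe_b[idx] <- as.numeric(inf$F_iter %*% pi_post)
      loc_b[idx] <- loc; trial_b[idx] <- tr
      epoch_b[idx] <- tau; iter_b[idx] <- seq_len(iters)
      bin <- bin + iters

      if (tau <= config$horizon) {
        act <- select_action(pi_post, policy_set, tau)
        new <- maze_step(maze, loc, act)
        nmove <- nmove + 1L
        rc <- cell_rc(maze, new)
        path[[nmove]] <- data.frame(
          move = nmove, trial = tr, step = tau, from = loc, to = new,
          row = rc[1], col = rc[2], action = ACTIONS[act],
          what_observed = c("open", "closed")[observe_cell(maze, new)$what],
          mistake = !is_open(maze, new) && new != loc)
        loc <- new
        if (new == maze$target) hit <- TRUE
      }
    }
    if (learn) {
      model$a_what <- learn_likelihood(model$a_what, outcomes, sbar_final,
                                       eta = config$eta, decay = config$decay)
    }
    a_after[[tr]] <- model$a_what
    n_run <- tr
    if (stop_at_target && hit) break
  }

  used <- seq_len(bin)
  structure(list(
    firing = if (record) firing[, used, drop = FALSE],
    depol = if (record) depol[, used, drop = FALSE],
    gamma = gamma_b[used], fe = fe_b[used],
    location = loc_b[used], trial = trial_b[used],
    epoch = epoch_b[used], iter = iter_b[used],
    bin_ms = config$outcome_ms / iters,
    n_states = n, epochs_per_trial = Tn, n_trials = n_run,
    path = do.call(rbind, path[seq_len(nmove)]),
    outcomes = do.call(rbind, outcome_log[seq_len(nobs)]),
    preferences = pref_log[seq_len(n_run)],
    a_after = a_after[seq_len(n_run)],
    model = model, config = config, maze = maze,
    final_location = loc
  ), class = "session_trace")
}

#' @export
print.session_trace <- function(x, ...) {
  cat(sprintf(
    "session_trace: %d trials, %d moves, %d bins of %.1f ms, %d mistakes\n",
    x$n_trials, nrow(x$path), length(x$gamma), x$bin_ms, sum(x$path$mistake)))
  invisible(x)
}
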