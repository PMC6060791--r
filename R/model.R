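# The generative model of the maze task: likelihood concentrations,
# action-conditioned transitions, preferences, initial prior and the
# policy set.

#' Enumerate fixed-length policies
#'
#' Policies are all action sequences of a given length, listed in
#' deterministic lexicographic order with respect to the stated action
#' order (the first move is the most significant digit).
#'
#' @param actions ordered character vector of action names.
#' @param horizon number of moves per policy (>= 1).
#' @return object of class `policy_set`: list with `actions`, `horizon` and
#'   `policies`, an `n_policies x horizon` integer matrix of action indices.
#' @examples
#' nrow(enumerate_policies(ACTIONS, 2)$policies)  # 25
#' @export
enumerate_policies <- function(actions = ACTIONS, horizon = 2) {
  if (length(actions) < 1) stopf("need at least one action")
  if (horizon < 1) stopf("horizon must be >= 1")
  horizon <- as.integer(horizon)
  # expand.grid varies its first factor fastest; feed moves in reverse so
  # the first move is the slowest-varying (lexicographic order).
  g <- do.call(expand.grid, rep(list(seq_along(actions)), horizon))
  pol <- as.matrix(g[, rev(seq_len(horizon)), drop = FALSE])
  dimnames(pol) <- list(NULL, paste0("move", seq_len(horizon)))
  structure(list(actions = actions, horizon = horizon,
                 policies = matrix(as.integer(pol), nrow(pol), horizon,
                                   dimnames = dimnames(pol))),
            class = "policy_set")
}

#' Action-conditioned transition matrices
#'
#' One column-stochastic matrix per action with `B[[u]][i, j] = 1` iff
#' action `u` moves state `j` to state `i`. Moves are deterministic;
#' boundary-transgressing moves map a state to itself. CLOSED cells are
#' ordinary states: legality lives in the preferences, not the physics.
#'
#' @param maze a `maze_grid` (only its dimensions are used).
#' @return named list of `n_states x n_states` matrices, one per action.
#' @export
transition_matrices <- function(maze) {
  n <- maze$n_rows * maze$n_cols
  B <- vector("list", length(ACTIONS))
  names(B) <- ACTIONS
  for (a in seq_along(ACTIONS)) {
    dest <- vapply(seq_len(n), function(s) maze_step(maze, s, a), integer(1))
    m <- matrix(0, n, n)
    m[cbind(dest, seq_len(n))] <- 1
    B[[a]] <- m
  }
  B
}

#' Expected likelihood under Dirichlet concentrations
#'
#' Returns the normalized expectation `Abar` (columns are categorical
#' distributions) and the expected log likelihood `lnAbar`. Because the
#' likelihood columns carry Dirichlet priors, the variationally correct
#' expectation of the log is the digamma difference
#' `digamma(a) - digamma(colsum(a))`; the naive log-of-mean is available
#' behind `method = "log-mean"` for ablation.
#'
#' @param a nonnegative concentration matrix (outcomes x states), all
#'   entries strictly positive.
#' @param method `"digamma"` (default) or `"log-mean"`.
#' @return list with matrices `Abar` and `lnAbar`.
#' @export
expected_likelihood <- function(a, method = c("digamma", "log-mean")) {
  method <- match.arg(method)
  if (any(!is.finite(a)) || any(a <= 0)) {
    stopf("concentration parameters must be strictly positive")
  }
  a0 <- colSums(a)
  Abar <- sweep(a, 2, a0, "/")
  lnAbar <- if (method == "digamma") {
    sweep(digamma(a), 2, digamma(a0), "-")
  } else {
    ln_floor(Abar)
  }
  list(Abar = Abar, lnAbar = lnAbar)
}

#' Build the generative model for a maze
#'
#' Two outcome modalities: `what` (open/closed, Dirichlet-parameterised and
#' learnable) and `where` (a known identity mapping returning the veridical
#' location). A `novel` model sets every what-concentration to 1/8; a
#' `familiar` model places 128 pseudo-counts on the true outcome of each
#' cell with a 1/8 floor on the other. The initial prior D is a delta at
#' the start cell and preferences initialise flat.
#'
#' @param maze a `maze_grid`.
#' @param familiarity `"novel"`, `"familiar"`, or a 2 x n_states
#'   concentration matrix to use directly.
#' @param conc_novel,conc_familiar the two concentration levels.
#' @return object of class `gen_model`.
#' @export
build_model <- function(maze, familiarity = "novel",
                        conc_novel = 1 / 8, conc_familiar = 128) {
  n <- maze$n_rows * maze$n_cols
  if (is.matrix(familiarity)) {
    if (!all(dim(familiarity) == c(2, n)) || any(familiarity <= 0)) {
      stopf("concentration matrix must be positive and 2 x n_states")
    }
    a_what <- familiarity
  } else {
    familiarity <- match.arg(familiarity, c("novel", "familiar"))
    a_what <- matrix(conc_novel, 2, n, dimnames = list(c("open", "closed"), NULL))
    if (familiarity == "familiar") {
      truth <- ifelse(t(maze$open)[seq_len(n)], 1L, 2L)
      a_what[cbind(truth, seq_len(n))] <- conc_familiar
    }
  }
  D <- numeric(n); D[maze$start] <- 1
  structure(
    list(maze = maze, n_states = n,
         a_what = a_what,
         A_where = diag(n),
         B = transition_matrices(maze),
         C_what = c(open = 0, closed = 0),
         C_where = numeric(n),
         D = D),
    class = "gen_model"
  )
}

#' @export
print.gen_model <- function(x, ...) {
  cat(sprintf("gen_model: %d states, what-concentrations in [%.3g, %.3g]\n",
              x$n_states, min(x$a_what), max(x$a_what)))
  invisible(x)
}

#' Posterior probability that each cell is open
#'
#' @param model a `gen_model`.
#' @return numeric vector over states (first row of the normalized
#'   what-likelihood).
#' @export
open_probability <- function(model) {
  expected_likelihood(model$a_what)$Abar[1, ]
}

#' Agent run configuration
#'
#' @param horizon moves per trial (policies have this length); a trial has
#'   `horizon + 1` epochs.
#' @param iterations_per_epoch belief-update iterations (= trace bins) per
#'   epoch; with a 256 ms outcome period the default of 16 gives 16 ms bins.
#' @param outcome_ms epoch duration in milliseconds.
#' @param beta0 prior on the inverse precision of policy beliefs.
#' @param eta learning rate for concentration accumulation.
#' @param decay forgetting rate toward the concentration floor (default 0).
#' @param novelty_on include the Dirichlet novelty term in expected free
#'   energy.
#' @param step_size damping of the depolarisation update per iteration.
#' @param f_tol early-stop threshold on the free-energy change.
#' @param seed integer seed recorded in every output.
#' @return a list of class `agent_config`.
#' @export
agent_config <- function(horizon = 2, iterations_per_epoch = 16,
                         outcome_ms = 256, beta0 = 1, eta = 1, decay = 0,
                         novelty_on = TRUE, step_size = 0.25, f_tol = 1e-4,
                         seed = 1L) {
  stopifnot(horizon >= 1, iterations_per_epoch >= 1, outcome_ms > 0,
            beta0 > 0, eta >= 0, decay >= 0, step_size > 0, step_size <= 1)
  structure(list(horizon = as.integer(horizon),
                 epochs_per_trial = as.integer(horizon + 1),
                 iterations_per_epoch = as.integer(iterations_per_epoch),
                 outcome_ms = outcome_ms, beta0 = beta0, eta = eta,
                 decay = decay, novelty_on = novelty_on,
                 step_size = step_size, f_tol = f_tol,
                 seed = as.integer(seed)),
            class = "agent_config")
}
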