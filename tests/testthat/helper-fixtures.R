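# Fixtures built in code: small mazes, toy models and the independent
# enumeration oracle for exact posteriors.

fix_corridor <- function(n = 5) {
  maze_grid(matrix(TRUE, 1, n), start = 1, target = n)
}

# 4x4 maze with an internal wall; solvable.
fix_small_maze <- function() {
  parse_maze(c("S.#.",
               ".##.",
               "...T",
               ".#.."))
}

fix_open8 <- function(start = 57, target = 28) {
  maze_grid(matrix(TRUE, 8, 8), start = start, target = target)
}

# A toy generative model over `n` states with arbitrary likelihood columns
# (given as probabilities; scaled to large concentrations so the digamma
# expectation coincides with the log to ~1e-4) and explicit transitions.
toy_model <- function(A_prob, B, D, scale = 5000) {
  n <- ncol(A_prob)
  structure(
    list(maze = NULL, n_states = n,
         a_what = A_prob * scale,
         A_where = diag(n),
         B = B,
         C_what = c(0, 0), C_where = numeric(n),
         D = D),
    class = "gen_model")
}

toy_policy_set <- function(policy_matrix, actions = paste0("a", seq_len(max(policy_matrix)))) {
  structure(list(actions = actions, horizon = ncol(policy_matrix),
                 policies = policy_matrix),
            class = "policy_set")
}

# Independent oracle: exact posterior marginals by brute-force enumeration
# over all state sequences of a single-policy chain.
#  lik: list per epoch of a likelihood vector over states (NULL = unobserved)
oracle_posterior <- function(D, B_seq, lik) {
  Tn <- length(lik)
  n <- length(D)
  grids <- do.call(expand.grid, rep(list(seq_len(n)), Tn))
  w <- apply(grids, 1, function(ss) {
    p <- D[ss[1]]
    if (!is.null(lik[[1]])) p <- p * lik[[1]][ss[1]]
    if (Tn > 1) for (t in 2:Tn) {
      p <- p * B_seq[[t - 1]][ss[t], ss[t - 1]]
      if (!is.null(lik[[t]])) p <- p * lik[[t]][ss[t]]
    }
    p
  })
  w <- w / sum(w)
  sapply(seq_len(Tn), function(t)
    sapply(seq_len(n), function(s) sum(w[grids[[t]] == s])))
}

# KL(Dir(a2) || Dir(a1)) in closed form.
kl_dirichlet <- function(a2, a1) {
  lgamma(sum(a2)) - lgamma(sum(a1)) - sum(lgamma(a2) - lgamma(a1)) +
    sum((a2 - a1) * (digamma(a2) - digamma(sum(a2))))
}

# Uniform-random-action baseline agent; returns distinct cells visited.
random_walk_coverage <- function(maze, n_moves, seed) {
  set.seed(seed)
  loc <- maze$start
  vis <- loc
  for (i in seq_len(n_moves)) {
    loc <- maze_step(maze, loc, sample(length(ACTIONS), 1))
    vis <- c(vis, loc)
  }
  length(unique(vis))
}
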