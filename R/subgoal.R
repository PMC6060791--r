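# Diffusion heuristic: converts the distal target into context-sensitive
# prior preferences (subgoals) over location outcomes.

#' Build the diffusion generator from beliefs about the maze
#'
#' The graph Laplacian L has `L[i, j] = P_open(i)` for `i != j` whenever
#' some action maps state `j` to state `i`, and diagonal entries minus the
#' column sums, so every column of L sums to zero and `expm(L)` is
#' column-stochastic. Note the zero-column-sum convention: the variant with
#' `1 - colsum` on the diagonal differs only by a uniform `exp(1)` scale,
#' which becomes an additive constant after the logarithm and cannot
#' affect policy selection; it is available behind `diagonal = "stochastic"`.
#'
#' @param P_open numeric vector in `[0, 1]`: posterior probability that
#'   each cell is open (see [open_probability]).
#' @param B list of action transition matrices (see [transition_matrices]).
#' @param diagonal `"laplacian"` (zero column sums, default) or
#'   `"stochastic"` (`1 - colsum`).
#' @return object of class `diffusion_graph` with elements `L` and
#'   `P_open`.
#' @export
build_graph_laplacian <- function(P_open, B,
                                  diagonal = c("laplacian", "stochastic")) {
  diagonal <- match.arg(diagonal)
  n <- length(P_open)
  if (any(P_open < 0 | P_open > 1)) stopf("P_open must lie in [0, 1]")
  adj <- Reduce(`+`, B) > 0       # i reachable from j by some action
  L <- matrix(0, n, n)
  L[adj] <- P_open[row(L)[adj]]
  diag(L) <- 0
  diag(L) <- -colSums(L) + if (diagonal == "stochastic") 1 else 0
  structure(list(L = L, P_open = P_open, diagonal = diagonal),
            class = "diffusion_graph")
}

#' Diffusion kernel exp(L)
#'
#' One time step of diffusion over the believed-open maze graph; column
#' `j` is the occupancy distribution after diffusing from state `j`.
#'
#' @param graph a `diffusion_graph`.
#' @return dense `n x n` matrix.
#' @export
diffusion_kernel <- function(graph) {
  as.matrix(Matrix::expm(Matrix::Matrix(graph$L)))
}

#' Subgoal preferences from diffusion accessibility
#'
#' Implements the cost
#' `cost = cap * [exp(L) d_current < threshold] - ln(exp(L) d_target)`:
#' locations the agent is unlikely to reach from its current position in
#' one diffusion step incur a flat penalty, and among reachable locations
#' those most accessible *from the target* are cheapest. The returned
#' log-preference is `-cost`; the engine consumes it as `C_where`. Meant to
#' be recomputed after every trial with the agent's current location.
#'
#' The diffusion kernel is scaled by `exp(1)`, matching the generator
#' whose diagonal is one minus the column sum (its matrix exponential's
#' columns sum to e). For the `-ln` term this is an additive constant with
#' no behavioural effect, but for the reach indicator it matters: the
#' unscaled kernel drops cells two moves away below `exp(-3)` wherever the
#' local degree is high, which penalises on-path cells inside the policy
#' horizon and makes the agent idle mid-trial. With the scaled kernel the
#' penalty-free radius is the two-move policy horizon, which is what makes
#' the preferred locations act as attainable subgoals.
#'
#' @param graph a `diffusion_graph`.
#' @param current,target 1-based state indices.
#' @param cost_cap flat penalty for out-of-reach locations (default 16).
#' @param reach_threshold occupancy probability below which a location
#'   counts as out of reach (default `exp(-3)`).
#' @param kernel_scale multiplier on `exp(L)` (default `exp(1)`; see
#'   Details).
#' @return numeric log-preference vector over states (class
#'   `preference_vector`), with the diffusion masses attached as
#'   attributes `reach` and `target_mass`.
#' @export
preference_vector <- function(graph, current, target,
                              cost_cap = 16, reach_threshold = exp(-3),
                              kernel_scale = exp(1)) {
  Tm <- kernel_scale * diffusion_kernel(graph)
  reach <- Tm[, current]          # Tm %*% delta_current
  mass <- Tm[, target]
  if (all(mass <= P_FLOOR)) {
    stopf("degenerate preference: target has no diffusion mass anywhere")
  }
  cost <- cost_cap * (reach < reach_threshold) - ln_floor(mass)
  structure(-cost, class = "preference_vector",
            reach = reach, target_mass = mass,
            current = as.integer(current), target = as.integer(target))
}
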