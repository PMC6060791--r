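# Belief updates: state estimation (variational relaxation to exact
# per-policy smoothing marginals), expected free energy, policy posterior,
# precision, action selection and Dirichlet likelihood learning.

#' Variational state estimation under each policy
#'
#' For every policy the trial is a short hidden Markov chain, so the target
#' posterior marginals are computed exactly by sum-product message passing:
#' a forward (filtering) sweep combining the prior/previous expectation
#' with the likelihood evidence `lnAbar . o`, and a backward sweep carrying
#' evidence from later observed epochs. The depolarisations `v` then relax
#' toward the target log-marginals by damped gradient steps
#' (`v <- v + step * (v* - v)`), with firing `s = softmax(v)`. The recorded
#' free energy, `sum_tau KL(s_tau || s*_tau) - ln p(o | policy)`, is
#' provably non-increasing along this relaxation and equals the negative
#' log evidence at convergence. Epochs with no observation carry no
#' backward message, so an unconstrained future epoch satisfies
#' `s[tau + 1] = B s[tau]` exactly (pure prediction).
#'
#' @param model a `gen_model`.
#' @param policy_set a `policy_set`.
#' @param outcomes list of length <= epochs; element `tau` is
#'   `list(what =, where =)` (either may be `NULL` for a missing modality)
#'   or `NULL` if the epoch is unobserved. Observed epochs must be a prefix.
#' @param beliefs optional `n x epochs x n_policies` array of
#'   depolarisations to warm-start from (e.g. the previous epoch's).
#' @param config an `agent_config`.
#' @param iterations,tol override the config's iteration count and
#'   early-stop tolerance (`tol = 0` iterates to the cap).
#' @param keep_iterates if `TRUE`, also return the per-iteration firing
#'   trajectory (used for the session trace).
#' @return list with `s`, `v` (`n x epochs x n_policies`), `F_iter`
#'   (iterations x policies free-energy trajectory), `F_policy` (negative
#'   log evidence per policy), `s_target`, and optionally `s_iter`.
#' @export
infer_states <- function(model, policy_set, outcomes, beliefs = NULL,
                         config = agent_config(),
                         iterations = config$iterations_per_epoch,
                         tol = config$f_tol, keep_iterates = FALSE) {
  n <- model$n_states
  Tn <- config$epochs_per_trial
  pol <- policy_set$policies
  if (ncol(pol) != Tn - 1) stopf("policy horizon does not match config")
  P <- nrow(pol)

  obs_mask <- vapply(seq_len(Tn), function(t)
    t <= length(outcomes) && !is.null(outcomes[[t]]), logical(1))
  t_obs <- if (all(obs_mask)) Tn else which(!obs_mask)[1] - 1L
  if (any(obs_mask[-seq_len(t_obs)])) stopf("observed epochs must be a prefix")

  el <- expected_likelihood(model$a_what)
  lnA_where <- ln_floor(model$A_where)
  # per-epoch likelihood evidence vectors (log), shared across policies
  lik <- matrix(0, n, Tn)
  for (t in seq_len(t_obs)) {
    o <- outcomes[[t]]
    lv <- numeric(n)
    if (!is.null(o$what))  lv <- lv + el$lnAbar[o$what, ]
    if (!is.null(o$where)) lv <- lv + lnA_where[o$where, ]
    lik[, t] <- exp(lv)
  }

  s_target <- array(0, c(n, Tn, P))
  F_policy <- numeric(P)
  for (p in seq_len(P)) {
    alpha <- matrix(0, n, Tn)
    logev <- 0
    f <- model$D
    for (t in seq_len(Tn)) {
      if (t > 1) f <- model$B[[pol[p, t - 1]]] %*% f
      if (obs_mask[t]) {
        f <- f * lik[, t]
        ct <- sum(f)
        if (ct <= 0) stopf("numerical degeneracy: zero-evidence message")
        logev <- logev + log(ct)
        f <- f / ct
      }
      alpha[, t] <- f
    }
    F_policy[p] <- -logev
    beta <- rep(1, n)
    s_target[, Tn, p] <- alpha[, Tn]
    if (Tn > 1) for (t in (Tn - 1):1) {
      m <- beta
      if (obs_mask[t + 1]) m <- m * lik[, t + 1]
      beta <- as.numeric(crossprod(model$B[[pol[p, t]]], m))
      beta <- beta / max(beta)
      s_target[, t, p] <- normalize(alpha[, t] * beta)
    }
  }

  # relaxation in flat matrix form: columns are (epoch, policy) pairs,
  # epoch fastest-varying
  st_m <- matrix(s_target, n)
  vt_m <- ln_floor(st_m)
  ln_st <- vt_m  # ln of target with floor, reused in the KL below
  v_m <- if (is.null(beliefs)) matrix(-log(n), n, Tn * P) else matrix(beliefs, n)
  grp <- rep(seq_len(P), each = Tn)
  col_softmax <- function(vm) {
    e <- exp(sweep(vm, 2, apply(vm, 2, max), "-"))
    sweep(e, 2, colSums(e), "/")
  }
  s_m <- col_softmax(v_m)
  F_iter <- matrix(NA_real_, iterations, P)
  s_iter <- if (keep_iterates) array(0, c(n, Tn, P, iterations))
  Fprev <- NULL
  done <- FALSE
  for (i in seq_len(iterations)) {
    if (!done) {
      v_m <- v_m + config$step_size * (vt_m - v_m)
      s_m <- col_softmax(v_m)
    }
    kl <- colSums(s_m * (ln_floor(s_m) - ln_st))
    Fi <- F_policy + as.numeric(rowsum(kl, grp))
    F_iter[i, ] <- Fi
    if (keep_iterates) s_iter[, , , i] <- s_m
    if (!is.null(Fprev) && max(abs(Fi - Fprev)) < tol) done <- TRUE
    Fprev <- Fi
  }
  out <- list(s = array(s_m, c(n, Tn, P)), v = array(v_m, c(n, Tn, P)),
              F_iter = F_iter, F_policy = F_policy,
              s_target = s_target, t_obs = t_obs)
  if (keep_iterates) out$s_iter <- s_iter
  out
}

#' Dirichlet novelty kernel
#'
#' `W = (1/a - 1/colsum(a)) / 2` elementwise; the expected information gain
#' about the likelihood concentrations from one observation. Nonnegative
#' whenever concentrations are positive, and vanishing as counts grow.
#'
#' @param a concentration matrix.
#' @return matrix of the same shape.
#' @export
novelty_kernel <- function(a) {
  if (any(a <= 0)) stopf("concentration parameters must be strictly positive")
  0.5 * sweep(1 / a, 2, 1 / colSums(a), "-")
}

#' Expected free energy per policy
#'
#' For each policy, sums over the future epochs `tau > t_now` the risk
#' (divergence of predicted outcomes from log preferences), the ambiguity
#' (expected outcome entropy per state) and minus the novelty (expected
#' Dirichlet information gain, what modality only):
#' `G = risk + ambiguity - novelty`. Preferences enter as unnormalised log
#' probabilities; adding a constant to either preference vector shifts
#' every policy's G equally and cannot change behaviour.
#'
#' @param model a `gen_model`.
#' @param s `n x epochs x n_policies` state expectations (from
#'   [infer_states]).
#' @param t_now index of the last observed epoch; epochs after it count as
#'   future.
#' @param C_what,C_where log-preference vectors (default: the model's).
#' @param novelty_on include the novelty term.
#' @return list of per-policy vectors `risk`, `ambiguity`, `novelty`, `G`.
#' @export
expected_free_energy <- function(model, s, t_now,
                                 C_what = model$C_what,
                                 C_where = model$C_where,
                                 novelty_on = TRUE) {
  el <- expected_likelihood(model$a_what)
  Abar <- el$Abar
  H <- -colSums(Abar * ln_floor(Abar))          # what-modality ambiguity
  W <- novelty_kernel(model$a_what)
  Tn <- dim(s)[2]; P <- dim(s)[3]
  risk <- amb <- nov <- numeric(P)
  future <- if (t_now < Tn) (t_now + 1):Tn else integer(0)
  for (p in seq_len(P)) for (t in future) {
    sv <- s[, t, p]
    ow <- as.numeric(Abar %*% sv)
    risk[p] <- risk[p] + sum(ow * (ln_floor(ow) - C_what)) +
      sum(sv * (ln_floor(sv) - C_where))
    amb[p] <- amb[p] + sum(sv * H)
    if (novelty_on) nov[p] <- nov[p] + sum(ow * as.numeric(W %*% sv))
  }
  list(risk = risk, ambiguity = amb, novelty = nov, G = risk + amb - nov)
}

#' Policy posterior
#'
#' `softmax(-gamma * G - F)`: a softmax over (negative) expected free
#' energy with inverse temperature `gamma`, optionally weighted by the
#' accumulated evidence `F` for each policy so that policies contradicted
#' by observed outcomes lose their weight. Invariant to adding a constant
#' to `G` (or to `F`).
#'
#' @param G per-policy expected free energy.
#' @param gamma precision (> 0).
#' @param F optional per-policy negative log evidence (default zero).
#' @return categorical distribution over policies.
#' @export
policy_posterior <- function(G, gamma, F = NULL) {
  if (!is.finite(gamma) || gamma <= 0) stopf("gamma must be positive")
  if (is.null(F)) F <- numeric(length(G))
  softmax(-gamma * G - F)
}

#' Update the precision of policy beliefs
#'
#' Damped fixed-point iteration on `beta = beta0 + (pi_post - pi_prior) . G`
#' with `gamma = 1/beta`. When the posterior (after observing outcomes)
#' favours lower-G policies than the prior, the dot product is negative,
#' `beta` falls below `beta0` and confidence `gamma` rises. If
#' `pi_prior`/`pi_posterior` are supplied they are held fixed; otherwise
#' they are recomputed from the current `gamma` each iteration as
#' `softmax(-gamma G)` and `softmax(-gamma G - F)`.
#'
#' @param G per-policy expected free energy.
#' @param F per-policy negative log evidence (used when the distributions
#'   are recomputed).
#' @param beta0 prior inverse precision.
#' @param pi_prior,pi_posterior optional fixed policy distributions.
#' @param iterations maximum damped iterations (also the length of the
#'   recorded gamma trace).
#' @param damping step fraction per iteration.
#' @param beta_floor positive floor applied (with a warning) if the update
#'   drives `beta` nonpositive.
#' @return list with `beta`, `gamma`, `pi_prior`, `pi_posterior` and the
#'   per-iteration `gamma_trace`.
#' @export
update_precision <- function(G, F = NULL, beta0 = 1,
                             pi_prior = NULL, pi_posterior = NULL,
                             iterations = 16, damping = 0.5,
                             beta_floor = 1e-3) {
  fixed <- !is.null(pi_prior) && !is.null(pi_posterior)
  if (is.null(F)) F <- numeric(length(G))
  beta <- beta0
  trace <- numeric(iterations)
  q0 <- pi_prior; q <- pi_posterior
  warned <- FALSE
  for (i in seq_len(iterations)) {
    if (!fixed) {
      gamma <- 1 / beta
      q0 <- softmax(-gamma * G)
      q <- softmax(-gamma * G - F)
    }
    target <- beta0 + sum((q - q0) * G)
    new_beta <- beta + damping * (target - beta)
    if (new_beta <= 0) {
      if (!warned) {
        warning("precision update drove beta nonpositive; flooring",
                call. = FALSE)
        warned <- TRUE
      }
      new_beta <- beta_floor
    }
    converged <- abs(new_beta - beta) < 1e-6
    beta <- new_beta
    trace[i:iterations] <- 1 / beta
    if (converged) break
  }
  list(beta = beta, gamma = 1 / beta, pi_prior = q0, pi_posterior = q,
       gamma_trace = trace)
}

#' Select the next action
#'
#' Marginalises the policy posterior over the action taken at the current
#' step and returns the argmax, ties broken by the fixed action order.
#'
#' @param pi categorical distribution over policies.
#' @param policy_set a `policy_set`.
#' @param step 1-based move index within the trial.
#' @return integer action index (into `policy_set$actions`).
#' @export
select_action <- function(pi, policy_set, step) {
  if (step < 1 || step > policy_set$horizon) stopf("step out of range")
  acts <- policy_set$policies[, step]
  marg <- vapply(seq_along(policy_set$actions),
                 function(a) sum(pi[acts == a]), numeric(1))
  which.max(marg)  # first maximum = earliest action in the fixed order
}

#' Accumulate likelihood concentrations from experience
#'
#' Associative plasticity: for every observed epoch the outer product of
#' the observed what-outcome with the policy-averaged state expectation is
#' added, scaled by `eta`, so each observed epoch adds exactly `eta` total
#' mass. `decay > 0` additionally shrinks the pre-update counts
#' multiplicatively (a forgetting trace); both default to the paper-less
#' choice of `eta = 1`, no decay.
#'
#' @param a concentration matrix (2 x n_states).
#' @param outcomes list per epoch with element `what` (ignored epochs may
#'   be `NULL`).
#' @param sbar `n_states x epochs` matrix of policy-averaged state
#'   expectations.
#' @param eta learning rate.
#' @param decay forgetting rate in `[0, 1)`.
#' @return the updated concentration matrix.
#' @export
learn_likelihood <- function(a, outcomes, sbar, eta = 1, decay = 0) {
  da <- matrix(0, nrow(a), ncol(a))
  for (t in seq_along(outcomes)) {
    o <- outcomes[[t]]
    if (is.null(o) || is.null(o$what)) next
    da[o$what, ] <- da[o$what, ] + eta * sbar[, t]
  }
  (1 - decay) * a + da
}
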