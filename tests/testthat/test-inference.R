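# Inference engine: state estimation against the enumeration oracle,
# expected free energy, policy posterior, precision, action selection,
# learning.

cfg_exact <- agent_config(iterations_per_epoch = 400, f_tol = 0)

test_that("veridical where outcomes pin the current state for all policies", {
  m <- generate_maze(seed = 4)
  model <- build_model(m, "novel")
  ps <- enumerate_policies()
  inf <- infer_states(model, ps, list(observe_cell(m, m$start)),
                      config = cfg_exact)
  for (p in 1:25) expect_gt(inf$s[m$start, 1, p], 0.99)
  # categorical outputs normalized
  expect_equal(apply(inf$s, c(2, 3), sum), matrix(1, 3, 25), tolerance = 1e-8)
})

test_that("unconstrained future epochs are pure predictions s' = B s", {
  m <- generate_maze(seed = 4)
  model <- build_model(m, "novel")
  ps <- enumerate_policies()
  inf <- infer_states(model, ps, list(observe_cell(m, m$start)),
                      config = cfg_exact)
  for (p in c(1, 7, 13, 25)) {
    for (tau in 1:2) {
      pred <- as.numeric(model$B[[ps$policies[p, tau]]] %*% inf$s[, tau, p])
      expect_equal(inf$s[, tau + 1, p], pred, tolerance = 1e-6)
    }
  }
})

test_that("converged posteriors match exact enumeration on 2- and 3-state
           toys", {
  # 2-state: soft likelihood, sticky transitions, both epochs observed
  A <- matrix(c(0.8, 0.2, 0.2, 0.8), 2)
  B <- list(matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  model <- toy_model(A, B, D = c(0.5, 0.5))
  ps <- toy_policy_set(matrix(1L, 1, 1))
  lik <- expected_likelihood(model$a_what)$Abar
  cases <- list(list(o = c(1L, 1L)), list(o = c(1L, 2L)), list(o = c(2L, 2L)))
  for (cs in cases) {
    outcomes <- lapply(cs$o, function(w) list(what = w, where = NULL))
    inf <- infer_states(model, ps, outcomes,
                        config = agent_config(horizon = 1,
                                              iterations_per_epoch = 400,
                                              f_tol = 0))
    ex <- oracle_posterior(model$D, B, list(lik[cs$o[1], ], lik[cs$o[2], ]))
    expect_equal(inf$s[, 1, 1], ex[, 1], tolerance = 1e-3)
    expect_equal(inf$s[, 2, 1], ex[, 2], tolerance = 1e-3)
  }
  # 3-state, 3 epochs, middle epoch unobserved, asymmetric transitions
  A3 <- matrix(c(0.7, 0.3, 0.2, 0.8, 0.5, 0.5), 2)
  B3 <- list(matrix(c(0.6, 0.3, 0.1,
                      0.2, 0.5, 0.3,
                      0.1, 0.2, 0.7), 3))
  model3 <- toy_model(A3, B3, D = c(0.6, 0.3, 0.1))
  ps3 <- toy_policy_set(matrix(1L, 1, 2))
  lik3 <- expected_likelihood(model3$a_what)$Abar
  outcomes <- list(list(what = 1L, where = NULL), NULL, NULL)
  # observed prefix of 1 epoch: epochs 2-3 are predictions
  inf3 <- infer_states(model3, ps3, outcomes[1],
                       config = agent_config(horizon = 2,
                                             iterations_per_epoch = 400,
                                             f_tol = 0))
  ex3 <- oracle_posterior(model3$D, list(B3[[1]], B3[[1]]),
                          list(lik3[1, ], NULL, NULL))
  for (tau in 1:3) expect_equal(inf3$s[, tau, 1], ex3[, tau], tolerance = 1e-3)
  # fully observed 3 epochs
  outcomes_f <- list(list(what = 1L, where = NULL),
                     list(what = 2L, where = NULL),
                     list(what = 1L, where = NULL))
  inf3f <- infer_states(model3, ps3, outcomes_f,
                        config = agent_config(horizon = 2,
                                              iterations_per_epoch = 400,
                                              f_tol = 0))
  ex3f <- oracle_posterior(model3$D, list(B3[[1]], B3[[1]]),
                           list(lik3[1, ], lik3[2, ], lik3[1, ]))
  for (tau in 1:3) expect_equal(inf3f$s[, tau, 1], ex3f[, tau],
                                tolerance = 1e-3)
})

test_that("free energy is non-increasing over iterations and bounds the
           evidence", {
  m <- generate_maze(seed = 6)
  model <- build_model(m, "novel")
  ps <- enumerate_policies()
  inf <- infer_states(model, ps,
                      list(observe_cell(m, m$start)),
                      config = agent_config())
  for (p in 1:25) {
    f <- inf$F_iter[, p]
    expect_true(all(f - cummin(f) <= 1e-6))
    expect_gte(min(f), inf$F_policy[p] - 1e-9)
  }
})

test_that("EFE decomposes exactly and novelty behaves", {
  m <- generate_maze(seed = 4)
  ps <- enumerate_policies()
  cfg <- agent_config()
  for (fam in c("novel", "familiar")) {
    model <- build_model(m, fam)
    inf <- infer_states(model, ps, list(observe_cell(m, m$start)),
                        config = cfg)
    efe <- expected_free_energy(model, inf$s, 1)
    expect_equal(efe$G, efe$risk + efe$ambiguity - efe$novelty,
                 tolerance = 1e-9)
    expect_true(all(efe$novelty >= 0))
    if (fam == "familiar") {
      # known maze: W -> 0, novelty vanishes
      expect_true(all(efe$novelty < 1e-2))
      # ... and with flat C the policy prior is near-uniform
      expect_equal(policy_posterior(efe$G, 1), rep(1 / 25, 25),
                   tolerance = 0.02)
    } else {
      # flat C, novel maze: ranking by G equals ranking by summed novelty
      # (exhaustive over all 25 policies)
      expect_equal(order(efe$G), order(-efe$novelty))
    }
  }
  # novelty is computed only when switched on
  model <- build_model(m, "novel")
  inf <- infer_states(model, ps, list(observe_cell(m, m$start)), config = cfg)
  efe_off <- expected_free_energy(model, inf$s, 1, novelty_on = FALSE)
  expect_true(all(efe_off$novelty == 0))
})

test_that("novelty kernel is exactly half the Jeffreys divergence", {
  # W . (obar x s) = (KL(post||prior) + KL(prior||post)) / 2, any counts
  for (a1 in c(1 / 8, 0.5, 2, 17, 128)) for (a2 in c(1 / 8, 1, 128)) {
    al <- c(a1, a2)
    W <- novelty_kernel(matrix(al, 2))
    obar <- al / sum(al)
    approx <- sum(obar * W)
    jeff <- sum(obar * vapply(1:2, function(i) {
      up <- al; up[i] <- up[i] + 1
      (kl_dirichlet(up, al) + kl_dirichlet(al, up)) / 2
    }, numeric(1)))
    expect_equal(approx, jeff, tolerance = 1e-9)
  }
  expect_true(all(novelty_kernel(matrix(runif(10) + 0.05, 2)) >= 0))
  expect_error(novelty_kernel(matrix(c(1, 0), 2)), "positive")
})

test_that("policy posterior: uniform, shift-invariant, sharpening", {
  expect_equal(policy_posterior(c(2, 2, 2), 1), rep(1 / 3, 3))
  G <- c(0.3, 1.1, -0.4)
  expect_equal(policy_posterior(G, 2), policy_posterior(G + 7, 2),
               tolerance = 1e-12)
  sharp <- policy_posterior(G, 500)
  expect_equal(which.max(sharp), which.min(G))
  expect_gt(max(sharp), 1 - 1e-9)
  expect_error(policy_posterior(G, 0), "positive")
})

test_that("precision updates follow the damped fixed point", {
  # posterior equals prior -> beta = beta0 exactly
  up <- update_precision(c(1, 3), beta0 = 2,
                         pi_prior = c(0.5, 0.5), pi_posterior = c(0.5, 0.5))
  expect_equal(up$beta, 2)
  # posterior concentrates on the low-G policy -> confidence rises
  up2 <- update_precision(c(1, 3), beta0 = 1,
                          pi_prior = softmax(-c(1, 3)),
                          pi_posterior = c(1, 0))
  expect_gt(up2$gamma, 1)
  expect_equal(up2$beta, 1 + sum((c(1, 0) - softmax(-c(1, 3))) * c(1, 3)),
               tolerance = 1e-5)
  # constant G: posterior = prior at every gamma -> gamma = 1/beta0
  up3 <- update_precision(c(2, 2, 2), beta0 = 4)
  expect_equal(up3$gamma, 1 / 4)
  expect_equal(up3$pi_posterior, up3$pi_prior)
  # pathological drive below zero floors with a warning
  expect_warning(
    update_precision(c(0, 100), beta0 = 0.01,
                     pi_prior = c(0.01, 0.99), pi_posterior = c(1, 0)),
    "flooring")
})

test_that("action selection marginalises policies with fixed-order ties", {
  ps <- enumerate_policies()
  # single policy: its current action
  pi1 <- numeric(25); pi1[8] <- 1    # policy 8 = (down, left)
  expect_equal(select_action(pi1, ps, 1), 2)
  expect_equal(select_action(pi1, ps, 2), 3)
  # two equiprobable policies sharing the first action
  pi2 <- numeric(25); pi2[c(1, 2)] <- 0.5   # (up,up), (up,down)
  expect_equal(select_action(pi2, ps, 1), 1)
  # exact tie between up (policy 1) and stay (policy 25) -> up first
  pi3 <- numeric(25); pi3[c(25, 1)] <- 0.5
  expect_equal(select_action(pi3, ps, 1), 1)
  expect_error(select_action(pi1, ps, 3), "out of range")
})

test_that("learning accumulates eta mass per observed epoch", {
  a <- matrix(1 / 8, 2, 4)
  sbar <- matrix(0, 4, 1); sbar[2, 1] <- 1
  a2 <- learn_likelihood(a, list(list(what = 1L)), sbar, eta = 1)
  expect_equal(a2[1, 2], 1 / 8 + 1)
  expect_equal(sum(a2 - a), 1)
  # soft state expectation still adds exactly eta in total
  sb <- matrix(c(0.25, 0.25, 0.4, 0.1), 4, 1)
  a3 <- learn_likelihood(a, list(list(what = 2L)), sb, eta = 0.5)
  expect_equal(sum(a3 - a), 0.5, tolerance = 1e-9)
  expect_true(all((a3 - a)[1, ] == 0))
  # decay shrinks existing counts
  a4 <- learn_likelihood(a, list(NULL), matrix(0, 4, 1), eta = 1, decay = 0.1)
  expect_equal(a4, 0.9 * a)
})

test_that("counting oracle: concentrations equal 1/8 + eta per observation", {
  m <- generate_maze(seed = 5)
  tr <- run_exploration(m, n_trials = 6, record = FALSE)
  counts <- table(factor(tr$outcomes$where[tr$outcomes$what == 1], 1:64))
  expected <- 1 / 8 + as.numeric(counts)
  expect_equal(tr$model$a_what[1, ], expected, tolerance = 1e-6)
  counts2 <- table(factor(tr$outcomes$where[tr$outcomes$what == 2], 1:64))
  expect_equal(tr$model$a_what[2, ], 1 / 8 + as.numeric(counts2),
               tolerance = 1e-6)
})
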