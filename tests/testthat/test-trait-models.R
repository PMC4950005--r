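test_that("state-specific sampling fractions are plain tallies", {
  td <- trait_data(sprintf("s%d", 1:250),
                   state = rep(c(0, 1), c(200, 50)),
                   in_tree = c(rep(TRUE, 100), rep(FALSE, 100), rep(TRUE, 50)))
  expect_equal(state_sampling_fractions(td), c(f0 = 0.5, f1 = 1.0))

  td_all <- trait_data(sprintf("s%d", 1:20), rep(c(0, 1), 10), TRUE)
  expect_equal(state_sampling_fractions(td_all), c(f0 = 1, f1 = 1))

  # a large fixture: recomputed by direct tally
  tt <- make_trait_table(594, state_freq = 0.4, n_in_tree = 200, seed = 8)
  expect_equal(nrow(tt), 594)
  expect_equal(sum(tt$in_tree), 200)
  fr <- state_sampling_fractions(tt)
  expect_equal(unname(fr["f0"]),
               sum(tt$state == 0 & tt$in_tree) / sum(tt$state == 0))
  expect_equal(unname(fr["f1"]),
               sum(tt$state == 1 & tt$in_tree) / sum(tt$state == 1))

  expect_error(state_sampling_fractions(trait_data("a", 1, TRUE)),
               "absent")
})

test_that("BiSSE likelihood factorizes and reduces as the theory demands", {
  set.seed(201)
  sim <- simulate_bisse(c(lambda0 = 0.3, lambda1 = 0.3, mu0 = 0.1, mu1 = 0.1,
                          q01 = 0.08, q10 = 0.05), crown_age = 8,
                        n_range = c(40, 200))
  tr <- sim$tree; st <- sim$states
  # state-independent diversification: logL splits into BD x Mk2
  p_eq <- c(lambda0 = 0.35, lambda1 = 0.35, mu0 = 0.12, mu1 = 0.12,
            q01 = 0.07, q10 = 0.04)
  lb <- bisse_loglik(tr, st, p_eq, root = "sum", condition = FALSE)
  lbd <- crbd_loglik(tr, 0.35, 0.12, condition = FALSE)
  lmk <- mk_loglik(tr, st + 1, matrix(c(-0.07, 0.04, 0.07, -0.04), 2, 2),
                   root = "sum")
  expect_equal(lb, lbd + lmk, tolerance = 1e-5)

  # no transitions, single state observed: plain birth-death
  st0 <- setNames(rep(0, length(tr$tip.label)), tr$tip.label)
  p0 <- c(lambda0 = 0.35, lambda1 = 0.9, mu0 = 0.12, mu1 = 0.4,
          q01 = 0, q10 = 0)
  expect_equal(bisse_loglik(tr, st0, p0),
               crbd_loglik(tr, 0.35, 0.12), tolerance = 1e-5)

  # swapping state labels together with all paired parameters is a no-op
  p_asym <- c(lambda0 = 0.5, lambda1 = 0.2, mu0 = 0.05, mu1 = 0.15,
              q01 = 0.1, q10 = 0.03)
  p_swap <- c(lambda0 = 0.2, lambda1 = 0.5, mu0 = 0.15, mu1 = 0.05,
              q01 = 0.03, q10 = 0.1)
  expect_equal(bisse_loglik(tr, st, p_asym, f = c(0.7, 0.9)),
               bisse_loglik(tr, 1 - st, p_swap, f = c(0.9, 0.7)),
               tolerance = 1e-10)
})

test_that("BiSSE likelihood matches the fixed-step RK4 oracle on a small tree", {
  tr <- tree4()
  st <- setNames(c(0L, 1L, 1L, 0L), c("A", "B", "C", "D"))
  pars <- c(lambda0 = 0.3, lambda1 = 0.6, mu0 = 0.05, mu1 = 0.15,
            q01 = 0.2, q10 = 0.07)
  for (root in c("fitzjohn", "sum")) {
    expect_equal(bisse_loglik(tr, st, pars, f = c(0.8, 0.6), root = root),
                 oracle_bisse_loglik(tr, st, pars, f = c(0.8, 0.6),
                                     root = root),
                 tolerance = 1e-4)
  }
  # unconditioned variant too
  expect_equal(bisse_loglik(tr, st, pars, condition = FALSE),
               oracle_bisse_loglik(tr, st, pars, condition = FALSE),
               tolerance = 1e-4)
})

test_that("the constrained model lattice nests and the all-equal fit matches cBD", {
  set.seed(202)
  sim <- simulate_bisse(c(lambda0 = 0.25, lambda1 = 0.25, mu0 = 0.08,
                          mu1 = 0.08, q01 = 0.1, q10 = 0.1), crown_age = 10,
                        n_range = c(60, 200))
  out <- fit_bisse_models(sim$tree, sim$states, n_starts = 2,
                          models = c("null", "lambda", "full"))
  expect_gte(out$fits$full$logL, out$fits$lambda$logL - 1e-6)
  expect_gte(out$fits$full$logL, out$fits$null$logL - 1e-6)
  expect_equal(out$fits$null$k, 3)
  expect_equal(out$fits$full$k, 6)

  # diversification part of the all-equal model is the cBD fit
  f_crbd <- fit_bd_model(sim$tree, "crbd", n_starts = 3)
  expect_equal(out$fits$null$params[["lambda0"]],
               f_crbd$params[["lambda0"]], tolerance = 1e-3)
  expect_equal(out$fits$null$params[["mu0"]],
               f_crbd$params[["mu0"]], tolerance = 1e-3 +
                 1e-3 * f_crbd$params[["mu0"]])
})

test_that("the Metropolis sampler behaves as a sampler should", {
  set.seed(203)
  sim <- simulate_bisse(c(lambda0 = 0.2, lambda1 = 0.4, mu0 = 0.05,
                          mu1 = 0.05, q01 = 0.1, q10 = 0.1), crown_age = 12,
                        n_range = c(80, 250))
  fit <- fit_bisse_models(sim$tree, sim$states, n_starts = 2,
                          models = c("null", "lambda"))$fits$lambda

  # zero-variance proposals freeze the chain at its ML start
  mc0 <- bisse_mcmc(sim$tree, sim$states, fit, n_steps = 200, burn_in = 50,
                    proposal_scale = 0)
  expect_equal(sd(mc0$trace[, "lambda0"]), 0)
  expect_equal(unname(mc0$trace[1, "lambda0"]), fit$params[["lambda0"]])

  # two seeds: different traces, compatible posterior means
  set.seed(1); mc1 <- bisse_mcmc(sim$tree, sim$states, fit, n_steps = 3000,
                                 burn_in = 1000)
  set.seed(2); mc2 <- bisse_mcmc(sim$tree, sim$states, fit, n_steps = 3000,
                                 burn_in = 1000)
  expect_false(identical(mc1$trace, mc2$trace))
  for (v in c("lambda0", "lambda1")) {
    x1 <- mc1$trace[-(1:1000), v]; x2 <- mc2$trace[-(1:1000), v]
    ess_se <- function(x) sd(x) / sqrt(length(x) / (1 + 2 * sum(acf(x, 50,
      plot = FALSE)$acf[-1])))
    se <- sqrt(ess_se(x1)^2 + ess_se(x2)^2)
    expect_lt(abs(mean(x1) - mean(x2)), 4 * se + 0.02)
  }

  # the generating asymmetry shows up in the net-diversification posterior
  expect_gte(mc1$net_div$p_r1_gt_r0, 0.9)
})

test_that("the correlated-evolution test nests exactly and flags invariant traits", {
  set.seed(204)
  tr <- simulate_tree("yule", list(lambda = 0.35), crown_age = 13,
                      n_range = c(120, 260))
  a <- sim_mk2_trait(tr, 0.1, 0.1)
  b <- sim_mk2_trait(tr, 0.15, 0.08)
  pc <- pagel_correlation(tr, a, b, n_starts = 2)
  expect_gte(pc$logL_dep, pc$logL_indep)
  expect_equal(pc$lrt$df, 4)

  # the dependent chain at independent rates IS the independent model
  st <- paleodiv:::joint_states(tr, a, b)
  r8 <- paleodiv:::pagel_indep_to_dep(unname(pc$rates_indep))
  expect_equal(mk_loglik(tr, st, paleodiv:::pagel_Q(r8), root = "equal"),
               mk_loglik(tr, a + 1, paleodiv:::mk2_Q(pc$rates_indep[1],
                                                     pc$rates_indep[2]),
                         root = "equal") +
               mk_loglik(tr, b + 1, paleodiv:::mk2_Q(pc$rates_indep[3],
                                                     pc$rates_indep[4]),
                         root = "equal"),
               tolerance = 1e-9)

  invariant <- setNames(rep(0, length(tr$tip.label)), tr$tip.label)
  expect_error(pagel_correlation(tr, a, invariant), "invariant")
})

test_that("Mk pruning agrees with an independent eigen-based computation", {
  set.seed(205)
  tr <- simulate_tree("yule", list(lambda = 0.4), crown_age = 8,
                      n_range = c(20, 80))
  a <- sim_mk2_trait(tr, 0.12, 0.2)
  b <- sim_mk2_trait(tr, 0.06, 0.1)
  st <- paleodiv:::joint_states(tr, a, b)
  Q <- paleodiv:::pagel_Q(c(0.1, 0.2, 0.35, 0.15, 0.12, 0.07, 0.3, 0.22))
  # oracle: pruning with transition matrices from an eigendecomposition
  ev <- eigen(Q)
  P <- function(t) Re(ev$vectors %*% diag(exp(ev$values * t)) %*%
                        solve(ev$vectors))
  trp <- ape::reorder.phylo(tr, "postorder")
  nt <- length(trp$tip.label)
  L <- matrix(NA_real_, 2 * nt - 1, 4)
  stv <- st[trp$tip.label]
  for (i in seq_len(nt)) L[i, ] <- as.numeric(stv[i] == 1:4)
  for (e in seq_len(nrow(trp$edge))) {
    par <- trp$edge[e, 1]; ch <- trp$edge[e, 2]
    v <- P(trp$edge.length[e]) %*% L[ch, ]
    L[par, ] <- if (any(is.na(L[par, ]))) v else L[par, ] * v
  }
  oracle <- log(mean(L[nt + 1, ]))
  expect_equal(mk_loglik(tr, st, Q, root = "equal"), oracle, tolerance = 1e-8)
})
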