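# the identity curve E(t) = t lets the linear form express a purely
# time-linear rate
identity_curve <- function(t_max = 10) {
  fit_env_curve(paleo_series(seq(0, t_max, by = 0.5), seq(0, t_max, by = 0.5)),
                smoothing = 0)
}

test_that("environment-dependent likelihood reduces to its nested null models", {
  set.seed(101)
  cv <- fit_env_curve(make_paleo_curve("andean_elevation", seed = 3))
  for (rep in 1:3) {
    tr <- simulate_tree("crbd", list(lambda = 0.5, mu = 0.15), crown_age = 7,
                        n_range = c(30, 200))
    # alpha = beta = 0: exponential and linear forms both collapse to cBD
    for (form in c("env_exp", "env_lin")) {
      ll <- bd_env_loglik(tr, rate_spec(form, 0.4, 0, cv),
                          rate_spec(form, 0.1, 0, cv), f = 0.6)
      expect_equal(ll, crbd_loglik(tr, 0.4, 0.1, f = 0.6), tolerance = 1e-6)
    }
    # mu = 0, alpha = 0, f = 1: Yule closed form
    bt <- branching_times(tr)
    tbl <- 2 * bt[1] + sum(bt[-1])
    n <- length(bt) + 1
    yule_closed <- (n - 2) * log(0.3) - 0.3 * tbl
    ll_y <- bd_env_loglik(tr, rate_spec("env_exp", 0.3, 0, cv),
                          rate_spec("constant", 0), f = 1)
    expect_equal(ll_y, yule_closed, tolerance = 1e-6)
  }
})

test_that("time-varying likelihood matches the fine-grid trapezoid oracle", {
  tr <- tree4()
  cv <- identity_curve(5)
  # lambda(t) = 0.3 + 0.02 t, mu = 0.1
  ll <- bd_env_loglik(tr, rate_spec("env_lin", 0.3, 0.02, cv),
                      rate_spec("constant", 0.1), f = 1)
  oracle <- oracle_bd_loglik(tr, function(t) 0.3 + 0.02 * t,
                             function(t) rep(0.1, length(t)), f = 1)
  expect_equal(ll, oracle, tolerance = 1e-4)

  # an exponential dependency with incomplete sampling
  ll2 <- bd_env_loglik(tr, rate_spec("env_exp", 0.25, 0.15, cv),
                       rate_spec("env_exp", 0.05, 0.1, cv), f = 0.5)
  oracle2 <- oracle_bd_loglik(tr, function(t) 0.25 * exp(0.15 * pmin(t, 5)),
                              function(t) 0.05 * exp(0.1 * pmin(t, 5)), f = 0.5)
  expect_equal(ll2, oracle2, tolerance = 1e-4)
})

test_that("likelihood is quadrature-stable and permutation-invariant", {
  set.seed(102)
  tr <- simulate_tree("crbd", list(lambda = 0.5, mu = 0.1), crown_age = 8,
                      n_range = c(80, 130))
  cv <- fit_env_curve(make_paleo_curve("andean_elevation", seed = 3))
  ls <- rate_spec("env_exp", 0.2, 4e-4, cv)
  ms <- rate_spec("constant", 0.05)
  l1 <- bd_env_loglik(tr, ls, ms, n_grid = 2000)
  l2 <- bd_env_loglik(tr, ls, ms, n_grid = 4000)
  expect_lt(abs(l1 - l2), 1e-5)

  # depends on branching times only: shuffling tip labels changes nothing
  tr_perm <- tr
  tr_perm$tip.label <- sample(tr$tip.label)
  expect_equal(bd_env_loglik(tr_perm, ls, ms), l1, tolerance = 1e-12)
})

test_that("model fitting respects nesting and ranks models sensibly", {
  set.seed(103)
  cv <- fit_env_curve(make_paleo_curve("andean_elevation", seed = 3))
  tr <- simulate_tree("env_exp",
                      list(lambda0 = 0.2, alpha = 4e-4, mu0 = 0.05, curve = cv),
                      crown_age = 10, n_range = c(100, 350))
  f_crbd <- fit_bd_model(tr, "crbd", n_starts = 3)
  f_env <- fit_bd_model(tr, "lambda_exp_mu", curve = cv, n_starts = 4)
  f_yule <- fit_bd_model(tr, "yule", n_starts = 3)
  # nested model never beats its superset on logL
  expect_gte(f_env$logL, f_crbd$logL - 1e-6)
  expect_gte(f_crbd$logL, f_yule$logL - 1e-6)
  # AICc bookkeeping
  expect_equal(f_env$k, 3)
  expect_equal(f_env$aicc,
               -2 * f_env$logL + 2 * 3 + 2 * 3 * 4 / (f_env$n - 3 - 1))
  # the generating dependency is detected: positive alpha
  expect_gt(f_env$params[["alpha"]], 0)

  tab <- compare_models(list(crbd = f_crbd, yule = f_yule, env = f_env))
  expect_equal(tab$model[1], "env")
})

test_that("Yule simulations recover the generating rate", {
  set.seed(104)
  lam_hat <- replicate(100, {
    tr <- simulate_tree("yule", list(lambda = 0.3), crown_age = log(100) / 0.3)
    bt <- branching_times(tr)
    (length(bt) - 1) / (2 * bt[1] + sum(bt[-1]))  # crown-conditioned Yule MLE
  })
  expect_gt(median(lam_hat), 0.27)
  expect_lt(median(lam_hat), 0.33)
})

test_that("rates_through_time reflects the fitted functional form", {
  cv <- fit_env_curve(make_paleo_curve("andean_elevation", seed = 3))
  set.seed(105)
  tr <- simulate_tree("crbd", list(lambda = 0.5, mu = 0.1), crown_age = 6,
                      n_range = c(30, 120))
  fc <- fit_bd_model(tr, "crbd", n_starts = 2)
  rt <- rates_through_time(fc, seq(0, 6, by = 1))
  expect_equal(length(unique(round(rt$lambda, 12))), 1)  # flat
  expect_equal(rt$net_div, rt$lambda - rt$mu)

  # positive exponential dependency on a monotone curve is monotone in time
  fe <- list(model = "lambda_exp",
             lambda_spec = rate_spec("env_exp", 0.2, 4e-4, cv),
             mu_spec = rate_spec("constant", 0.05))
  class(fe) <- "bd_fit"
  rt2 <- rates_through_time(fe, seq(0, 20, by = 1))
  # lambda is an exactly monotone function of the covariate
  ev <- env_value(cv, seq(0, 20, by = 1))
  expect_true(all(diff(rt2$lambda[order(ev)]) >= -1e-12))
  expect_equal(rt2$lambda, 0.2 * exp(4e-4 * ev), tolerance = 1e-12)
  # grid refinement agrees at shared points
  rt3 <- rates_through_time(fe, seq(0, 20, by = 0.5))
  expect_equal(rt3$lambda[seq(1, 41, by = 2)], rt2$lambda)
})

test_that("fixed-shift comparison rejects degenerate clades and detects strong shifts", {
  set.seed(106)
  sh <- simulate_shift_tree(lambda_bg = 0.5, mu_bg = 0, lambda_clade = 1.83,
                            mu_clade = 0, crown_age = 8, shift_age = 3)
  expect_error(fit_fixed_shift(sh$tree, sh$clade_tips[1:2]), "at least 3")
  fs <- fit_fixed_shift(sh$tree, sh$clade_tips)
  expect_equal(fs$lrt$df, 2)
  expect_gt(fs$clade$lambda, fs$background$lambda)
  expect_equal(fs$logL_two_regime,
               fs$clade$logL + fs$background$logL, tolerance = 1e-9)
  # shared model is the constrained case of the two-regime model
  expect_gte(fs$logL_two_regime, fs$shared$logL - 1e-6)
})
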