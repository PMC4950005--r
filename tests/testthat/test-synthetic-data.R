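test_that("crown Yule simulations hit the closed-form expected richness", {
  set.seed(501)
  n <- replicate(2000, {
    length(simulate_tree("yule", list(lambda = 0.5), crown_age = 5)$tip.label)
  })
  expected <- 2 * exp(0.5 * 5)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("survival conditioning and the thinning generator are consistent", {
  set.seed(502)
  # critical birth-death: rejection still delivers surviving crowns
  for (i in 1:10) {
    tr <- simulate_tree("crbd", list(lambda = 0.4, mu = 0.4), crown_age = 3)
    expect_gte(length(tr$tip.label), 2)
  }
  # env model with alpha = 0 is the same process as cbd: compare tip counts
  cv <- fit_env_curve(make_paleo_curve("andean_elevation", seed = 3))
  n_env <- replicate(80, length(simulate_tree("env_exp",
    list(lambda0 = 0.5, alpha = 0, mu0 = 0.1, curve = cv),
    crown_age = 4)$tip.label))
  n_cbd <- replicate(80, length(simulate_tree("crbd",
    list(lambda = 0.5, mu = 0.1), crown_age = 4)$tip.label))
  expect_gt(suppressWarnings(ks.test(n_env, n_cbd)$p.value), 0.01)
})

test_that("joint trait-tree simulation respects its transition structure", {
  set.seed(503)
  # no transitions from a fixed root state: the trait never varies
  sim0 <- simulate_bisse(c(lambda0 = 0.4, lambda1 = 0.4, mu0 = 0, mu1 = 0,
                           q01 = 0, q10 = 0), crown_age = 5, root_state = 0)
  expect_true(all(sim0$states == 0))

  # symmetric process: long-run state frequency near one half
  freqs <- replicate(40, {
    s <- simulate_bisse(c(lambda0 = 0.4, lambda1 = 0.4, mu0 = 0.05,
                          mu1 = 0.05, q01 = 0.3, q10 = 0.3), crown_age = 6)
    mean(s$states)
  })
  expect_lt(abs(mean(freqs) - 0.5), 3 * sd(freqs) / sqrt(length(freqs)))

  # strong speciation asymmetry inflates the fast state beyond its
  # stationary transition frequency
  excess <- replicate(30, {
    s <- simulate_bisse(c(lambda0 = 0.1, lambda1 = 0.6, mu0 = 0.05,
                          mu1 = 0.05, q01 = 0.1, q10 = 0.1), crown_age = 7)
    mean(s$states) > 0.5
  })
  expect_gt(mean(excess), 0.5)
})

test_that("subsampling implements the requested retention schemes", {
  set.seed(504)
  tr <- simulate_tree("yule", list(lambda = 0.5), crown_age = 13,
                      n_range = c(450, 700))
  n <- length(tr$tip.label)
  expect_identical(subsample_tips(tr, 1)$tip.label, tr$tip.label)

  sub <- subsample_tips(tr, 0.35)
  kept <- length(sub$tip.label)
  p_bin <- 0.35
  expect_lt(abs(kept - n * p_bin), 4 * sqrt(n * p_bin * (1 - p_bin)))
  expect_equal(attr(sub, "realized_f")[["overall"]], kept / n)

  # trait-biased retention matches its targets within binomial error
  states <- setNames(rbinom(n, 1, 0.5), tr$tip.label)
  sub2 <- subsample_tips(tr, c(`0` = 0.2, `1` = 0.8), groups = states)
  rf <- attr(sub2, "realized_f")
  n0 <- sum(states == 0); n1 <- sum(states == 1)
  expect_lt(abs(rf[["0"]] - 0.2), 4 * sqrt(0.2 * 0.8 / n0))
  expect_lt(abs(rf[["1"]] - 0.8), 4 * sqrt(0.2 * 0.8 / n1))
})

test_that("template paleo-curves have their stated geological shape", {
  el <- make_paleo_curve("andean_elevation", seed = 7)
  expect_equal(el$value[el$age == 0], 4500, tolerance = 0.05 * 4500)
  expect_lt(el$value[el$age == 40], 150)
  # monotone nondecreasing toward the present
  expect_true(all(diff(el$value[order(-el$age)]) >= 0))
  # most uplift is recent: under 40% of the modern value 10 Myr ago
  expect_lte(el$value[el$age == 10], 0.4 * el$value[el$age == 0])
  # reproducible by seed
  expect_identical(make_paleo_curve("andean_elevation", seed = 7), el)
  expect_false(identical(make_paleo_curve("andean_elevation", seed = 8)$value,
                         el$value))

  cool <- make_paleo_curve("cenozoic_cooling", seed = 7)
  # warmer in the mid-Miocene than today
  expect_gt(mean(cool$value[cool$age > 12 & cool$age < 18]),
            mean(cool$value[cool$age < 3]) + 0.5)
})

test_that("trait-table fixtures honour their marginals and seeds", {
  tt <- make_trait_table(594, 0.5, 200, seed = 3)
  expect_equal(nrow(tt), 594)
  expect_equal(sum(tt$in_tree), 200)
  expect_lt(abs(mean(tt$state) - 0.5), 4 * sqrt(0.25 / 594))
  expect_identical(make_trait_table(594, 0.5, 200, seed = 3), tt)
  tt2 <- make_trait_table(594, 0.5, 200, seed = 4)
  expect_false(identical(tt$state, tt2$state))
  # an invariant trait is constructible for error-path testing
  tt3 <- make_trait_table(50, 1, 20, seed = 1)
  expect_true(all(tt3$state == 1))
})

test_that("the generators and likelihoods agree on where the truth is", {
  set.seed(505)
  # average log-likelihood at the generating rates beats a 2x-perturbed rate
  diffs <- replicate(50, {
    tr <- simulate_tree("crbd", list(lambda = 0.5, mu = 0.1), crown_age = 5)
    crbd_loglik(tr, 0.5, 0.1) - crbd_loglik(tr, 1.0, 0.1)
  })
  expect_gt(mean(diffs), 0)
})
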