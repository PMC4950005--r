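test_that("diversity-dependent likelihood collapses to the constant-rate models", {
  set.seed(301)
  tr <- simulate_tree("crbd", list(lambda = 0.5, mu = 0.15), crown_age = 6,
                      n_range = c(25, 120))
  # effectively infinite carrying capacity: dependence vanishes
  expect_equal(dd_loglik(tr, 0.5, 0.15, K = 1e8),
               crbd_loglik(tr, 0.5, 0.15), tolerance = 1e-4)
  # and without extinction: Yule
  expect_equal(dd_loglik(tr, 0.4, 0, K = 1e8),
               crbd_loglik(tr, 0.4, 0), tolerance = 1e-4)
  # logL approaches the constant-rate value monotonically from below as K grows
  lls <- sapply(c(50, 200, 1000, 1e5), function(K)
    dd_loglik(tr, 0.5, 0.15, K))
  expect_true(all(diff(lls) > -1e-8))
  expect_lt(abs(lls[4] - crbd_loglik(tr, 0.5, 0.15)), 1e-2)
})

test_that("master-equation likelihood matches the fixed-step RK4 oracle", {
  tr <- tree5()
  ll <- dd_loglik(tr, 0.5, 0.1, K = 20, M = 80)
  expect_equal(ll, oracle_dd_loglik(tr, 0.5, 0.1, K = 20, M = 80),
               tolerance = 1e-4)
  # with missing extant species in the terminal condition
  ll2 <- dd_loglik(tr, 0.5, 0.1, K = 20, richness = 8, M = 80,
                   condition = FALSE)
  expect_equal(ll2, oracle_dd_loglik(tr, 0.5, 0.1, K = 20, richness = 8,
                                     M = 80, condition = FALSE),
               tolerance = 1e-4)
})

test_that("truncation is stable and the N-process generator conserves probability", {
  set.seed(302)
  tr <- simulate_tree("crbd", list(lambda = 0.5, mu = 0.2), crown_age = 5,
                      n_range = c(15, 60))
  expect_lt(abs(dd_loglik(tr, 0.6, 0.2, K = 100, M = 128) -
                dd_loglik(tr, 0.6, 0.2, K = 100, M = 256)), 1e-6)

  # generator of the single-lineage N process: columns sum to zero, and the
  # evolved distribution keeps total mass 1 (up to truncation leakage)
  M <- 200
  laN <- function(N) pmax(0, 0.6 - (0.6 - 0.2) * N / 50)
  nn <- 0:M
  G <- matrix(0, M + 1, M + 1)
  for (j in seq_len(M + 1)) {
    N <- nn[j]
    if (j < M + 1) G[j + 1, j] <- N * laN(N)
    if (j > 1) G[j - 1, j] <- N * 0.2
    G[j, j] <- -(N * laN(N) + N * 0.2)
  }
  expect_lt(max(abs(colSums(G)[-(M + 1)])), 1e-12)
  p <- c(0, 1, rep(0, M - 1))
  for (s in 1:500) p <- p + 0.01 * as.numeric(G %*% p)  # Euler is fine here
  expect_equal(sum(p), 1, tolerance = 1e-8)
})

test_that("carrying-capacity estimation distinguishes bounded from unbounded growth", {
  # under constant-rate data the estimated K runs away past the richness
  set.seed(303)
  null_exceeds <- replicate(8, {
    tr <- simulate_tree("crbd", list(lambda = 0.6, mu = 0.1), crown_age = 5,
                        n_range = c(40, 120))
    fd <- fit_dd(tr, with_extinction = FALSE, n_starts = 2)
    fd$params[["K"]] > length(tr$tip.label)
  })
  expect_gte(mean(null_exceeds), 0.5)

  # under genuinely saturated growth the estimate tracks the true K
  set.seed(304)
  K_true <- 50
  k_hats <- replicate(8, {
    tr <- simulate_tree("dd", list(lambda0 = 1.2, mu = 0.05, K = K_true),
                        crown_age = 12, n_range = c(30, 80))
    fit_dd(tr, with_extinction = FALSE, n_starts = 2)$params[["K"]]
  })
  expect_gte(mean(k_hats > K_true / 2 & k_hats < K_true * 2), 0.5)

  # bookkeeping: dropping extinction removes one free parameter
  set.seed(305)
  tr <- simulate_tree("crbd", list(lambda = 0.6, mu = 0.1), crown_age = 5,
                      n_range = c(40, 120))
  f0 <- fit_dd(tr, with_extinction = FALSE, n_starts = 1)
  f1 <- fit_dd(tr, with_extinction = TRUE, n_starts = 1)
  expect_equal(f1$k - f0$k, 1)
  expect_equal(f0$params[["mu"]], 0)

  # invalid parameter regions are rejected
  expect_error(dd_loglik(tr, 0.1, 0.2, K = 100), "exceed")
  expect_error(dd_loglik(tr, 0.5, 0.1, K = -3), "K must be")
})
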