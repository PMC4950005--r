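#' Mk (continuous-time Markov chain) log-likelihood for discrete tip states
#'
#' Felsenstein pruning likelihood for a k-state Markov chain on the tree,
#' with branch transition probabilities computed by matrix exponential
#' (compiled). Used by the correlated-evolution tests and by the BiSSE
#' factorization identities.
#'
#' @param tree `phylo`.
#' @param states integer tip states in `1..k` (named by tip label), `0` or
#'   `NA` for ambiguous.
#' @param Q k x k generator (rows sum to zero).
#' @param root root-state weighting: `"equal"` (1/k each), `"sum"`
#'   (unweighted), `"obs"` (weights proportional to the root partial
#'   likelihoods).
#' @return log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, states, Q, root = c("equal", "sum", "obs")) {
  root <- match.arg(root)
  k <- nrow(Q)
  if (!is.null(names(states))) states <- states[tree$tip.label]
  st <- as.integer(states)
  st[is.na(st)] <- 0L
  if (any(st < 0 | st > k)) stop("states must be in 1..k (0/NA = ambiguous)")
  tr <- ape::reorder.phylo(tree, "postorder")
  .cpp_mk_loglik(tr$edge, tr$edge.length, length(tr$tip.label), st, Q,
                 match(root, c("equal", "sum", "obs")) - 1L)
}

# 2-state generator from gain/loss rates
mk2_Q <- function(q01, q10) {
  matrix(c(-q01, q10, q01, -q10), 2, 2)
}

# ML fit of the 2-state Mk chain; states are 0/1 named by tip
fit_mk2 <- function(tree, states, n_starts = 3) {
  st <- states[tree$tip.label] + 1L
  obj <- function(p) {
    ll <- mk_loglik(tree, st, mk2_Q(exp(p[1]), exp(p[2])), root = "equal")
    if (!is.finite(ll)) 1e10 else -ll
  }
  nc <- sum(st[1] != st)  # crude scale for the starting rate
  s0 <- log(max(nc, 1) / sum(tree$edge.length))
  starts <- matrix(s0, n_starts, 2)
  if (n_starts > 1)
    starts[-1, ] <- starts[-1, ] + matrix(rnorm((n_starts - 1) * 2, 0, 1),
                                          n_starts - 1, 2)
  best <- multi_start(obj, starts, rep(log(1e-7), 2), rep(log(1e3), 2))
  list(q01 = exp(best$par[1]), q10 = exp(best$par[2]), logL = -best$objective)
}

# 4-state generator on the joint chain {00, 01, 10, 11} of two binary
# traits (A, B); double transitions are disallowed.
# dependent rates: rAg0, rAl0, rAg1, rAl1 (A gain/loss given B = 0/1),
#                  rBg0, rBl0, rBg1, rBl1 (B gain/loss given A = 0/1)
pagel_Q <- function(r) {
  Q <- matrix(0, 4, 4)
  # states: 1 = (A0,B0), 2 = (A0,B1), 3 = (A1,B0), 4 = (A1,B1)
  Q[1, 3] <- r[1]; Q[3, 1] <- r[2]   # A changes while B = 0
  Q[2, 4] <- r[3]; Q[4, 2] <- r[4]   # A changes while B = 1
  Q[1, 2] <- r[5]; Q[2, 1] <- r[6]   # B changes while A = 0
  Q[3, 4] <- r[7]; Q[4, 3] <- r[8]   # B changes while A = 1
  diag(Q) <- -rowSums(Q)
  Q
}

# map the 4 independent-model rates (A gain, A loss, B gain, B loss) onto
# the 8-rate dependent parameterisation
pagel_indep_to_dep <- function(r4) {
  c(r4[1], r4[2], r4[1], r4[2], r4[3], r4[4], r4[3], r4[4])
}

joint_states <- function(tree, traitA, traitB) {
  a <- traitA[tree$tip.label]
  b <- traitB[tree$tip.label]
  if (any(is.na(a)) || any(is.na(b))) stop("tips without trait data")
  setNames(1L + 2L * as.integer(a) + as.integer(b), tree$tip.label)
}

#' Pagel correlated-evolution test for two binary traits
#'
#' Compares independent evolution of two binary characters (4 transition
#' rates: each trait's gain and loss) against dependent evolution on the
#' joint 4-state chain (8 rates: each trait's gain and loss depend on the
#' other trait's current state), with equal root-state weights. Support for
#' dependence is assessed by a likelihood-ratio test (df = 4) and by Bayes
#' factors computed two ways from short MCMC runs: the harmonic-mean
#' estimator (retained for comparability with classical usage despite its
#' known instability) and a stepping-stone estimator.
#'
#' @param tree ultrametric `phylo`.
#' @param traitA,traitB named 0/1 vectors covering every tip.
#' @param n_starts optimizer starts for the dependent model.
#' @param bayes_factor also run the MCMC-based marginal-likelihood
#'   estimators (slower).
#' @param mcmc_steps chain length per stepping stone.
#' @param prior_rate exponential prior rate on all transition rates.
#' @return list with `logL_indep`, `logL_dep`, `lrt` (df = 4), the fitted
#'   rates, and (when requested) `bf_harmonic` and `bf_stepping_stone`
#'   (both on the 2 ln BF scale).
#' @export
pagel_correlation <- function(tree, traitA, traitB, n_starts = 3,
                              bayes_factor = FALSE, mcmc_steps = 2000,
                              prior_rate = NULL) {
  a <- traitA[tree$tip.label]
  b <- traitB[tree$tip.label]
  if (length(unique(a)) < 2 || length(unique(b)) < 2)
    stop("invariant trait: correlation test undefined")
  # independent model factorizes over the two traits
  fa <- fit_mk2(tree, a, n_starts)
  fb <- fit_mk2(tree, b, n_starts)
  logL_indep <- fa$logL + fb$logL
  r4 <- c(fa$q01, fa$q10, fb$q01, fb$q10)

  st <- joint_states(tree, traitA, traitB)
  obj <- function(p) {
    ll <- mk_loglik(tree, st, pagel_Q(exp(p)), root = "equal")
    if (!is.finite(ll)) 1e10 else -ll
  }
  s0 <- log(pmax(pagel_indep_to_dep(r4), 1e-6))
  starts <- matrix(rep(s0, n_starts), n_starts, 8, byrow = TRUE)
  if (n_starts > 1)
    starts[-1, ] <- starts[-1, ] + matrix(rnorm((n_starts - 1) * 8, 0, 0.7),
                                          n_starts - 1, 8)
  best <- multi_start(obj, starts, rep(log(1e-7), 8), rep(log(1e3), 8))
  logL_dep <- max(-best$objective, logL_indep)  # nesting guard
  out <- list(
    logL_indep = logL_indep, logL_dep = logL_dep,
    rates_indep = setNames(r4, c("qA01", "qA10", "qB01", "qB10")),
    rates_dep = setNames(exp(best$par),
                         c("qA01.B0", "qA10.B0", "qA01.B1", "qA10.B1",
                           "qB01.A0", "qB10.A0", "qB01.A1", "qB10.A1")),
    lrt = lrt(logL_indep, logL_dep, df = 4))
  if (bayes_factor) {
    if (is.null(prior_rate)) prior_rate <- 1 / mean(c(r4, exp(best$par)))
    mz_i <- mk_marginal_lik(tree, st, n_par = 4, start = log(r4),
                            qbuild = function(r) pagel_Q(pagel_indep_to_dep(r)),
                            n_steps = mcmc_steps, prior_rate = prior_rate)
    mz_d <- mk_marginal_lik(tree, st, n_par = 8, start = best$par,
                            qbuild = pagel_Q,
                            n_steps = mcmc_steps, prior_rate = prior_rate)
    out$bf_harmonic <- 2 * (mz_d$harmonic - mz_i$harmonic)
    out$bf_stepping_stone <- 2 * (mz_d$stepping_stone - mz_i$stepping_stone)
  }
  out
}

# marginal likelihood of an Mk model by (a) the harmonic mean of sampled
# likelihoods and (b) a stepping-stone estimator over power posteriors
# p(theta) L(theta)^beta, beta on a skewed ladder.
mk_marginal_lik <- function(tree, st, n_par, start, qbuild, n_steps = 2000,
                            prior_rate = 1, n_stones = 8) {
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  stv <- as.integer(st[tr$tip.label])
  ll_fun <- function(p) {
    r <- exp(p)
    .cpp_mk_loglik(tr$edge, tr$edge.length, n, stv, qbuild(r), 0L)
  }
  lprior <- function(p) sum(dexp(exp(p), rate = prior_rate, log = TRUE)) + sum(p)
  run_chain <- function(beta, p0, n_iter) {
    p <- p0
    ll <- ll_fun(p)
    lp <- lprior(p)
    scale <- 0.3
    out_ll <- numeric(n_iter)
    for (i in seq_len(n_iter)) {
      prop <- p + rnorm(n_par, 0, scale)
      ll2 <- ll_fun(prop)
      lp2 <- lprior(prop)
      if (is.finite(ll2) &&
          log(runif(1)) < beta * (ll2 - ll) + (lp2 - lp)) {
        p <- prop; ll <- ll2; lp <- lp2
      }
      out_ll[i] <- ll
    }
    list(ll = out_ll, p = p)
  }
  # harmonic mean from the beta = 1 chain
  post <- run_chain(1, start, n_steps)
  burn <- floor(n_steps / 5)
  lls <- post$ll[(burn + 1):n_steps]
  # log HM = -log mean(1/L), computed stably around the max
  m <- max(lls)
  harmonic <- m - log(mean(exp(m - lls)))
  # stepping stone: ladder beta_k = (k/K)^(1/0.3), chains warm-started
  betas <- (seq(0, n_stones) / n_stones)^(1 / 0.3)
  logZ <- 0
  p0 <- start
  per <- max(200, floor(n_steps / n_stones))
  for (k in seq_len(n_stones)) {
    ch <- run_chain(betas[k], p0, per)
    keep <- ch$ll[(floor(per / 4) + 1):per]
    d <- (betas[k + 1] - betas[k]) * keep
    md <- max(d)
    logZ <- logZ + md + log(mean(exp(d - md)))
    p0 <- ch$p
  }
  list(harmonic = harmonic, stepping_stone = logZ)
}
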