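#' Binary trait table
#'
#' Species-level binary character data, including species absent from the
#' tree; the latter enter only the state-specific sampling fractions (the
#' correction for trait-biased taxon sampling).
#'
#' @param species character vector of species names.
#' @param state integer 0/1 states.
#' @param in_tree logical: is the species a tip of the analysed phylogeny?
#' @param name character name (e.g. `"fruit_type"`, `"pollinator_type"`,
#'   `"elevation_class"`, `"andean_occurrence"`).
#' @return data.frame of class `"trait_data"`.
#' @export
trait_data <- function(species, state, in_tree = TRUE, name = "trait") {
  if (!all(state %in% c(0, 1))) stop("states must be binary (0/1)")
  if (anyDuplicated(species)) stop("duplicate species")
  structure(data.frame(species = as.character(species),
                       state = as.integer(state),
                       in_tree = rep_len(in_tree, length(species)),
                       stringsAsFactors = FALSE),
            name = name, class = c("trait_data", "data.frame"))
}

#' @rdname trait_data
#' @param file TSV with columns `species`, `state`, `in_tree`.
#' @export
read_trait_table <- function(file, name = "trait") {
  df <- read.delim(file, stringsAsFactors = FALSE)
  trait_data(df$species, df$state, as.logical(df$in_tree), name = name)
}

#' State-specific sampling fractions
#'
#' `f_i` = (tips in the tree with state i) / (all known species with state
#' i). Requires the full trait table, i.e. including species not sampled in
#' the phylogeny.
#'
#' @param traits a [trait_data()] table.
#' @return numeric vector `c(f0, f1)`.
#' @export
state_sampling_fractions <- function(traits) {
  tot <- c(sum(traits$state == 0), sum(traits$state == 1))
  if (any(tot == 0)) stop("a state is absent from the full trait table")
  samp <- c(sum(traits$state == 0 & traits$in_tree),
            sum(traits$state == 1 & traits$in_tree))
  setNames(samp / tot, c("f0", "f1"))
}

# named tip-state vector aligned to the tree, from a trait table or vector
tip_states <- function(tree, traits) {
  if (inherits(traits, "trait_data")) {
    st <- setNames(traits$state, traits$species)
  } else {
    st <- traits
  }
  miss <- setdiff(tree$tip.label, names(st))
  if (length(miss) > 0)
    stop("tips without trait data: ", paste(head(miss, 5), collapse = ", "))
  as.integer(st[tree$tip.label])
}

#' BiSSE log-likelihood
#'
#' Joint likelihood of an ultrametric tree and binary tip states under the
#' binary-state speciation-extinction model, with state-specific sampling
#' fractions. The standard coupled ODEs are integrated tipward-to-rootward
#' along each branch with an adaptive Runge-Kutta scheme (compiled):
#' `dE_i/dt = mu_i - (lambda_i + mu_i + q_ij) E_i + q_ij E_j + lambda_i
#' E_i^2` and `dD_i/dt = -(lambda_i + mu_i + q_ij) D_i + q_ij D_j + 2
#' lambda_i E_i D_i`, with tip initialisation `D_i = f_i [state = i]`,
#' `E_i = 1 - f_i`, and node combination `D_i <- lambda_i D_i^L D_i^R`.
#'
#' @param tree ultrametric `phylo`.
#' @param states named 0/1 vector (names = tip labels) or a [trait_data()].
#' @param pars named vector `lambda0, lambda1, mu0, mu1, q01, q10`
#'   (all non-negative, per Myr).
#' @param f state-specific sampling fractions `c(f0, f1)`.
#' @param root root treatment: `"fitzjohn"` weights root states by their
#'   relative D values, `"equal"` averages them, `"sum"` adds them
#'   unweighted (no prior; useful for likelihood identities).
#' @param condition divide by `(1 - E_i(root))^2`, the state-conditional
#'   probability that both crown lineages leave sampled descendants.
#' @param rtol,atol integration tolerances.
#' @return log-likelihood (scalar).
#' @export
bisse_loglik <- function(tree, states, pars, f = c(1, 1),
                         root = c("fitzjohn", "equal", "sum"),
                         condition = TRUE, rtol = 1e-8, atol = 1e-10) {
  root <- match.arg(root)
  pars <- pars[c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")]
  if (any(is.na(pars))) stop("pars must name lambda0, lambda1, mu0, mu1, q01, q10")
  if (any(pars < 0)) stop("rates must be >= 0")
  st <- tip_states(tree, states)
  tr <- ape::reorder.phylo(tree, "postorder")
  .cpp_bisse_loglik(tr$edge, tr$edge.length, length(tr$tip.label), st,
                    as.numeric(pars), f[1], f[2],
                    match(root, c("fitzjohn", "equal", "sum")) - 1L,
                    condition, rtol, atol)
}

# the 2^3 constraint lattice: lambda, mu, q each free or equal across states
bisse_model_table <- function() {
  data.frame(
    model = c("null", "lambda", "mu", "q", "lambda.mu", "lambda.q", "mu.q",
              "full"),
    lambda_free = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    mu_free = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
    q_free = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# expand free parameters of a constrained model to the full 6-vector
bisse_expand <- function(p, row) {
  la <- exp(p[1:(1 + row$lambda_free)])
  i <- 1 + row$lambda_free
  mu <- exp(p[(i + 1):(i + 1 + row$mu_free)])
  i <- i + 1 + row$mu_free
  q <- exp(p[(i + 1):(i + 1 + row$q_free)])
  c(lambda0 = la[1], lambda1 = la[length(la)],
    mu0 = mu[1], mu1 = mu[length(mu)],
    q01 = q[1], q10 = q[length(q)])
}

#' Fit the eight constrained BiSSE models
#'
#' Fits the full 2^3 lattice of BiSSE variants in which speciation,
#' extinction and transition rates are each either shared between states or
#' free (k from 3 to 6), ranks them by AICc, and applies the two-unit
#' decisiveness rule.
#'
#' @inheritParams bisse_loglik
#' @param n_starts optimizer starts per model (first from a heuristic or the
#'   nested null fit, the rest jittered).
#' @param models subset of the eight model names.
#' @return list with `fits` (per model: parameter estimates, logL, k, AICc),
#'   `table` from [compare_models()], and `best` (model name or `"tie"`).
#' @export
fit_bisse_models <- function(tree, states, f = c(1, 1), n_starts = 3,
                             models = bisse_model_table()$model,
                             root = "fitzjohn", condition = TRUE) {
  tab <- bisse_model_table()
  st <- tip_states(tree, states)
  bt <- branching_times(tree)
  n <- length(bt) + 1
  tbl <- 2 * bt[1] + sum(bt[-1])
  la0 <- max(n - 2, 1) / tbl
  tr <- ape::reorder.phylo(tree, "postorder")
  rt <- match(root, c("fitzjohn", "equal", "sum")) - 1L

  fit_one <- function(row, start0) {
    k <- 3 + row$lambda_free + row$mu_free + row$q_free
    obj <- function(p) {
      pars <- bisse_expand(p, row)
      ll <- .cpp_bisse_loglik(tr$edge, tr$edge.length, n, st, pars,
                              f[1], f[2], rt, condition, 1e-8, 1e-10)
      if (!is.finite(ll)) 1e10 else -ll
    }
    starts <- matrix(rep(start0, n_starts), nrow = n_starts, byrow = TRUE)
    if (n_starts > 1)
      starts[-1, ] <- starts[-1, ] +
        matrix(rnorm((n_starts - 1) * k, 0, 0.8), n_starts - 1, k)
    best <- multi_start(obj, starts, rep(log(1e-7), k), rep(log(1e3), k))
    pars <- bisse_expand(best$par, row)
    list(model = row$model, params = pars, logL = -best$objective, k = k,
         aicc = aicc(-best$objective, k, n - 1), n = n - 1,
         convergence = best$convergence)
  }

  # seed the lattice from the null fit
  null_row <- tab[tab$model == "null", ]
  null_start <- c(log(la0), log(la0 / 4), log(0.1))
  fits <- list()
  null_fit <- fit_one(null_row, null_start)
  for (m in models) {
    row <- tab[tab$model == m, ]
    if (m == "null") {
      fits[[m]] <- null_fit
      next
    }
    p0 <- with(null_fit, c(
      rep(log(params[["lambda0"]]), 1 + row$lambda_free),
      rep(log(max(params[["mu0"]], 1e-6)), 1 + row$mu_free),
      rep(log(params[["q01"]]), 1 + row$q_free)))
    fits[[m]] <- fit_one(row, p0)
  }
  tabout <- compare_models(fits)
  best <- attr(tabout, "best")
  list(fits = fits, table = tabout, best = best)
}

#' Metropolis MCMC over BiSSE parameters
#'
#' Samples the free parameters of a (possibly constrained) BiSSE model under
#' independent exponential priors, starting from the ML estimates. Proposal
#' scales are adapted during burn-in only; the post-burn-in chain is a plain
#' Metropolis sampler. The default prior rate is 1/(2r) with r the
#' ML net diversification rate, following the usual convention for
#' state-speciation-extinction analyses.
#'
#' @inheritParams bisse_loglik
#' @param fit one element of `fit_bisse_models()$fits`, or a named full
#'   parameter vector (treated as the `"full"` model's start).
#' @param n_steps,burn_in chain length and burn-in (defaults 20000 / 2000).
#' @param prior_rate rate of the exponential prior on every rate parameter.
#' @param proposal_scale initial log-scale proposal SD (0 collapses the
#'   chain to its start, for degenerate-sampler checks).
#' @return object of class `"bisse_mcmc"`: `trace` (iteration, free
#'   parameters, logL, log posterior), `burn_in`, acceptance rate (with a
#'   warning flag when outside 0.05-0.9), and the posterior summary of
#'   the state-specific net diversification rates \eqn{r_i = \lambda_i - \mu_i}.
#' @export
bisse_mcmc <- function(tree, states, fit, n_steps = 20000, burn_in = 2000,
                       prior_rate = NULL, proposal_scale = 0.15,
                       f = c(1, 1), root = "fitzjohn", condition = TRUE) {
  tab <- bisse_model_table()
  if (is.numeric(fit)) {
    fit <- list(model = "full", params = fit[c("lambda0", "lambda1", "mu0",
                                               "mu1", "q01", "q10")])
  }
  row <- tab[tab$model == fit$model, ]
  st <- tip_states(tree, states)
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  rt <- match(root, c("fitzjohn", "equal", "sum")) - 1L
  ll_fun <- function(pars) {
    .cpp_bisse_loglik(tr$edge, tr$edge.length, n, st, pars, f[1], f[2],
                      rt, condition, 1e-8, 1e-10)
  }
  # free parameters on log scale
  pfull <- fit$params
  p <- c(log(pfull[["lambda0"]]), if (row$lambda_free) log(pfull[["lambda1"]]),
         log(max(pfull[["mu0"]], 1e-8)),
         if (row$mu_free) log(max(pfull[["mu1"]], 1e-8)),
         log(pfull[["q01"]]), if (row$q_free) log(pfull[["q10"]]))
  k <- length(p)
  if (is.null(prior_rate)) {
    r_hat <- max(pfull[["lambda0"]] - pfull[["mu0"]], 0.01)
    prior_rate <- 1 / (2 * r_hat)
  }
  # log posterior on the log scale: exponential prior + Jacobian
  lpost <- function(p) {
    pars <- bisse_expand(p, row)
    ll <- ll_fun(pars)
    if (!is.finite(ll)) return(list(ll = -Inf, lp = -Inf))
    lp <- ll + sum(dexp(pars[unique_idx], rate = prior_rate, log = TRUE)) +
      sum(p[seq_len(k)])
    list(ll = ll, lp = lp)
  }
  unique_idx <- c(1, if (row$lambda_free) 2, 3, if (row$mu_free) 4,
                  5, if (row$q_free) 6)
  cur <- lpost(p)
  scales <- rep(proposal_scale, k)
  trace <- matrix(NA_real_, n_steps, k + 2)
  acc <- 0L
  acc_win <- 0L
  for (i in seq_len(n_steps)) {
    prop <- p + rnorm(k, 0, scales)
    cand <- lpost(prop)
    if (is.finite(cand$lp) &&
        (cand$lp >= cur$lp || log(runif(1)) < cand$lp - cur$lp)) {
      p <- prop
      cur <- cand
      acc <- acc + 1L
      acc_win <- acc_win + 1L
    }
    # adapt only during burn-in, in windows of 100
    if (i <= burn_in && i %% 100 == 0) {
      rate <- acc_win / 100
      scales <- scales * exp(0.5 * (rate - 0.3))
      acc_win <- 0L
    }
    trace[i, ] <- c(exp(p), cur$ll, cur$lp)
  }
  free_names <- c("lambda0", if (row$lambda_free) "lambda1",
                  "mu0", if (row$mu_free) "mu1",
                  "q01", if (row$q_free) "q10")
  colnames(trace) <- c(free_names, "logL", "logpost")
  post <- trace[(burn_in + 1):n_steps, , drop = FALSE]
  la1 <- if (row$lambda_free) post[, "lambda1"] else post[, "lambda0"]
  mu1 <- if (row$mu_free) post[, "mu1"] else post[, "mu0"]
  r0 <- post[, "lambda0"] - post[, "mu0"]
  r1 <- la1 - mu1
  acc_rate <- acc / n_steps
  structure(list(
    trace = trace, burn_in = burn_in, model = fit$model,
    acceptance = acc_rate,
    acceptance_warning = proposal_scale > 0 &&
      (acc_rate < 0.05 || acc_rate > 0.9),
    prior_rate = prior_rate,
    net_div = list(
      r0 = r0, r1 = r1,
      summary = data.frame(
        state = c(0, 1),
        mean = c(mean(r0), mean(r1)),
        lo95 = c(quantile(r0, 0.025), quantile(r1, 0.025)),
        hi95 = c(quantile(r0, 0.975), quantile(r1, 0.975))),
      p_r1_gt_r0 = mean(r1 > r0))),
    class = "bisse_mcmc")
}

#' @export
print.bisse_mcmc <- function(x, ...) {
  cat(sprintf("BiSSE MCMC (%s model): %d steps, burn-in %d, acceptance %.2f\n",
              x$model, nrow(x$trace), x$burn_in, x$acceptance))
  print(x$net_div$summary)
  cat(sprintf("P(r1 > r0) = %.3f\n", x$net_div$p_r1_gt_r0))
  invisible(x)
}
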