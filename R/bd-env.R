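#' Declare a (possibly environment-dependent) rate function
#'
#' A speciation or extinction rate is either constant, an exponential
#' function of the environmental covariate, `rate(t) = base * exp(coef *
#' E(t))`, or linear, `rate(t) = base + coef * E(t)`. Evaluated rates are
#' clamped at zero by default (linear dependence can go negative).
#'
#' @param form one of `"constant"`, `"env_exp"`, `"env_lin"`.
#' @param base base rate (events/Myr/lineage, >= 0): the rate itself for the
#'   constant form, the rate at E = 0 otherwise.
#' @param coef dependency coefficient per curve unit (speciation: alpha;
#'   extinction: beta). Ignored for the constant form.
#' @param curve an `"env_curve"`; required for the env forms.
#' @return an object of class `"rate_spec"`.
#' @export
rate_spec <- function(form = c("constant", "env_exp", "env_lin"),
                      base, coef = 0, curve = NULL) {
  form <- match.arg(form)
  if (base < 0) stop("base rate must be >= 0")
  if (form != "constant" && is.null(curve))
    stop("env-dependent rate forms require a curve")
  structure(list(form = form, base = base, coef = coef, curve = curve),
            class = "rate_spec")
}

# vectorised evaluation of a rate spec at times before present
eval_rate <- function(spec, t, clamp = TRUE) {
  r <- switch(spec$form,
    constant = rep(spec$base, length(t)),
    env_exp = spec$base * exp(spec$coef * env_value(spec$curve, t)),
    env_lin = spec$base + spec$coef * env_value(spec$curve, t))
  if (clamp) pmax(r, 0) else r
}

#' Time-varying birth-death log-likelihood with incomplete sampling
#'
#' Likelihood of an ultrametric tree under a birth-death process whose
#' speciation and extinction rates vary through time (here, through an
#' environmental covariate), with uniform sampling fraction `f`, conditioned
#' by default on the crown age and on both crown lineages surviving to the
#' present.
#'
#' With time measured from the present, net rate \eqn{r(u) = \lambda(u) - \mu(u)},
#' `g(s) = exp(integral of r over [0, s])` and
#' `J(s) = integral of g(u) lambda(u) over [0, s]`, each lineage segment
#' contributes `Psi(s) = g(s) / (1 + f J(s))^2`, each branching time a
#' factor `lambda(t_i)`, and each tip a factor `f`; conditioning divides by
#' the squared probability `f g(t1) / (1 + f J(t1))` that a crown lineage
#' has sampled descendants. The cumulative integrals are evaluated on a
#' shared fine grid augmented with the branching times, so likelihoods for
#' nested models agree to quadrature accuracy.
#'
#' @param tree ultrametric `phylo`.
#' @param lambda_spec,mu_spec [rate_spec()] objects for speciation and
#'   extinction.
#' @param f sampling fraction in (0, 1].
#' @param condition condition on survival of both crown lineages.
#' @param n_grid number of quadrature subintervals over `[0, crown age]`.
#' @param clamp_negative clamp negative rates (possible under linear
#'   dependence) at zero; if `FALSE`, negative rates are an error.
#' @return log-likelihood (scalar).
#' @export
bd_env_loglik <- function(tree, lambda_spec, mu_spec, f = 1,
                          condition = TRUE, n_grid = 2000,
                          clamp_negative = TRUE) {
  if (f <= 0 || f > 1) stop("f must be in (0, 1]")
  bt <- branching_times(tree)
  t1 <- bt[1]
  grid <- sort(unique(c(seq(0, t1, length.out = n_grid + 1), bt)))
  ng <- length(grid)
  mid <- (grid[-1] + grid[-ng]) / 2
  h <- diff(grid)
  lam <- eval_rate(lambda_spec, grid, clamp = FALSE)
  mu <- eval_rate(mu_spec, grid, clamp = FALSE)
  lam_m <- eval_rate(lambda_spec, mid, clamp = FALSE)
  mu_m <- eval_rate(mu_spec, mid, clamp = FALSE)
  if (any(lam < 0) || any(mu < 0) || any(lam_m < 0) || any(mu_m < 0)) {
    if (!clamp_negative) stop("rate function is negative inside [0, crown age]")
    lam <- pmax(lam, 0); mu <- pmax(mu, 0)
    lam_m <- pmax(lam_m, 0); mu_m <- pmax(mu_m, 0)
  }
  r <- lam - mu
  r_m <- lam_m - mu_m
  # cumulative Simpson for R = int r, with an O(h^4) half-step rule for the
  # value of R at interval midpoints (needed for g = exp(R) there)
  R <- c(0, cumsum(h / 6 * (r[-ng] + 4 * r_m + r[-1])))
  R_m <- R[-ng] + h / 24 * (5 * r[-ng] + 8 * r_m - r[-1])
  gl <- exp(R) * lam
  gl_m <- exp(R_m) * lam_m
  J <- c(0, cumsum(h / 6 * (gl[-ng] + 4 * gl_m + gl[-1])))
  logPsi <- R - 2 * log1p(f * J)
  ii <- match(bt, grid)
  n <- length(bt) + 1
  lam_bt <- lam[ii]
  if (any(lam_bt <= 0)) return(-Inf)
  ll <- n * log(f) +
    sum(log(lam_bt[-1]) + logPsi[ii][-1]) +  # internal nodes below the crown
    2 * logPsi[ii][1]
  if (condition) {
    log_psurv <- log(f) + R[ii][1] - log1p(f * J[ii][1])
    ll <- ll - 2 * log_psurv
  }
  ll
}

# closed-form constant-rate birth-death log-likelihood on branching times
# (same conditioning and normalisation conventions as bd_env_loglik)
crbd_loglik_bt <- function(bt, lambda, mu = 0, f = 1, condition = TRUE) {
  if (lambda <= 0) return(-Inf)
  n <- length(bt) + 1
  r <- lambda - mu
  gJ <- function(t) {
    if (abs(r) < 1e-12) {
      list(R = r * t, J = lambda * t * (1 + r * t / 2))
    } else {
      list(R = r * t, J = lambda * (exp(r * t) - 1) / r)
    }
  }
  v <- gJ(bt)
  logPsi <- v$R - 2 * log1p(f * v$J)
  ll <- n * log(f) + sum(log(lambda) + logPsi[-1]) + 2 * logPsi[1]
  if (condition) {
    ll <- ll - 2 * (log(f) + v$R[1] - log1p(f * v$J[1]))
  }
  ll
}

#' Constant-rate birth-death log-likelihood
#'
#' Closed form of the likelihood that [bd_env_loglik()] computes numerically,
#' for constant rates. Used as the null model and by the fixed-shift and
#' diversity-dependent reductions.
#'
#' @inheritParams bd_env_loglik
#' @param lambda,mu constant speciation and extinction rates.
#' @return log-likelihood (scalar).
#' @export
crbd_loglik <- function(tree, lambda, mu = 0, f = 1, condition = TRUE) {
  crbd_loglik_bt(branching_times(tree), lambda, mu, f, condition)
}

# the ten-model family: two null models plus four exponential and four
# linear environment dependencies
bd_model_table <- function() {
  data.frame(
    model = c("yule", "crbd",
              "lambda_exp", "lambda_exp_mu", "mu_exp", "lambda_mu_exp",
              "lambda_lin", "lambda_lin_mu", "mu_lin", "lambda_mu_lin"),
    form = c("constant", "constant",
             "env_exp", "env_exp", "env_exp", "env_exp",
             "env_lin", "env_lin", "env_lin", "env_lin"),
    lambda_var = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE,
                   TRUE, TRUE, FALSE, TRUE),
    mu_var = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
               FALSE, FALSE, TRUE, TRUE),
    has_mu = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE,
               FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Fit one birth-death model by maximum likelihood
#'
#' Fits a member of the ten-model family used for paleoenvironment-dependent
#' diversification analysis: Yule and constant-rate birth-death nulls, plus
#' the four exponential and four linear dependency models (speciation
#' varying with no extinction; speciation varying, extinction constant;
#' speciation constant, extinction varying; both varying). Optimization is
#' multi-start bounded quasi-Newton in transformed space (log for base
#' rates, identity with box bounds for the dependency coefficients).
#'
#' @param tree ultrametric `phylo`.
#' @param model one of `"yule"`, `"crbd"`, `"lambda_exp"`, `"lambda_exp_mu"`,
#'   `"mu_exp"`, `"lambda_mu_exp"`, `"lambda_lin"`, `"lambda_lin_mu"`,
#'   `"mu_lin"`, `"lambda_mu_lin"`.
#' @param curve `"env_curve"`; required for the env-dependent models.
#' @param f uniform sampling fraction.
#' @param n_starts number of optimizer starts (first from a heuristic, the
#'   rest jittered).
#' @param condition condition on crown survival.
#' @param n_grid quadrature subintervals for the env-dependent likelihood.
#' @return an object of class `"bd_fit"`: model name, named parameter
#'   estimates, `logL`, `k`, `AICc`, convergence flag.
#' @export
fit_bd_model <- function(tree, model, curve = NULL, f = 1, n_starts = 10,
                         condition = TRUE, n_grid = 2000) {
  tab <- bd_model_table()
  if (!model %in% tab$model) stop("unknown model: ", model)
  row <- tab[tab$model == model, ]
  if (row$form != "constant" && is.null(curve))
    stop("model ", model, " requires an environment curve")
  bt <- branching_times(tree)
  n <- length(bt) + 1
  tbl <- 2 * bt[1] + sum(bt[-1])  # total branch length of the ultrametric tree
  lam_heur <- max((n - 2), 1) / tbl
  # covariate scale bounds the dependency coefficients
  emax <- if (is.null(curve)) 1 else max(abs(env_value(curve, seq(0, bt[1], length.out = 101))), 1e-8)

  par_names <- c("lambda0",
                 if (row$has_mu) "mu0",
                 if (row$lambda_var) "alpha",
                 if (row$mu_var) "beta")
  k <- length(par_names)

  build_specs <- function(p) {
    lambda0 <- exp(p[["log_lambda0"]])
    mu0 <- if (row$has_mu) exp(p[["log_mu0"]]) else 0
    alpha <- if (row$lambda_var) p[["alpha"]] else 0
    beta <- if (row$mu_var) p[["beta"]] else 0
    ls <- if (row$lambda_var) rate_spec(row$form, lambda0, alpha, curve)
          else rate_spec("constant", lambda0)
    ms <- if (row$mu_var) rate_spec(row$form, mu0, beta, curve)
          else rate_spec("constant", mu0)
    list(ls = ls, ms = ms)
  }

  constantish <- !row$lambda_var && !row$mu_var
  obj <- function(p) {
    names(p) <- tp_names
    sp <- build_specs(p)
    ll <- tryCatch({
      if (constantish)
        crbd_loglik_bt(bt, sp$ls$base, sp$ms$base, f, condition)
      else
        bd_env_loglik(tree, sp$ls, sp$ms, f, condition, n_grid)
    }, error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  tp_names <- c("log_lambda0",
                if (row$has_mu) "log_mu0",
                if (row$lambda_var) "alpha",
                if (row$mu_var) "beta")
  cbound <- 30 / emax
  lower <- c(log(1e-8), if (row$has_mu) log(1e-8),
             if (row$lambda_var) -cbound, if (row$mu_var) -cbound)
  upper <- c(log(1e3), if (row$has_mu) log(1e3),
             if (row$lambda_var) cbound, if (row$mu_var) cbound)

  base_start <- c(log(lam_heur), if (row$has_mu) log(lam_heur / 4),
                  if (row$lambda_var) 0, if (row$mu_var) 0)
  starts <- matrix(rep(base_start, n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1) {
    jit <- matrix(rnorm((n_starts - 1) * k, 0, 1), n_starts - 1, k)
    # coefficient jitter on the covariate scale
    scl <- c(0.7, if (row$has_mu) 1.2,
             if (row$lambda_var) 1 / emax, if (row$mu_var) 1 / emax)
    starts[-1, ] <- sweep(jit, 2, scl, "*") + rep(base_start, each = n_starts - 1)
  }
  best <- multi_start(obj, starts, lower, upper)
  p <- setNames(best$par, tp_names)
  sp <- build_specs(p)
  est <- c(lambda0 = sp$ls$base,
           if (row$has_mu) c(mu0 = sp$ms$base),
           if (row$lambda_var) c(alpha = sp$ls$coef),
           if (row$mu_var) c(beta = sp$ms$coef))
  structure(list(model = model, params = est, logL = -best$objective, k = k,
                 aicc = aicc(-best$objective, k, n - 1), n = n - 1,
                 convergence = best$convergence, f = f,
                 lambda_spec = sp$ls, mu_spec = sp$ms,
                 condition = condition),
            class = "bd_fit")
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("bd_fit '%s': logL = %.4f, k = %d, AICc = %.4f\n",
              x$model, x$logL, x$k, x$aicc))
  print(round(x$params, 6))
  invisible(x)
}

#' Fit the full environment-dependent model family
#'
#' Convenience wrapper: fits every model in the ten-model family (or a
#' subset) and ranks them by AICc with the two-unit decisiveness rule.
#'
#' @inheritParams fit_bd_model
#' @param models character vector of model names (default: all ten).
#' @return list with `fits` (named list of `bd_fit`) and `table`
#'   (see [compare_models()]).
#' @export
fit_bd_models <- function(tree, curve, f = 1, models = bd_model_table()$model,
                          n_starts = 10, condition = TRUE, n_grid = 2000) {
  fits <- lapply(models, function(m)
    fit_bd_model(tree, m, curve = curve, f = f, n_starts = n_starts,
                 condition = condition, n_grid = n_grid))
  names(fits) <- models
  list(fits = fits, table = compare_models(fits))
}

#' Fitted rates through time
#'
#' Evaluates the fitted speciation, extinction and net diversification rates
#' of a birth-death fit on a time grid, for rate-through-time plots.
#'
#' @param fit a `"bd_fit"`.
#' @param times times before present (Myr).
#' @return data.frame with `time`, `lambda`, `mu`, `net_div`.
#' @export
rates_through_time <- function(fit, times) {
  lam <- eval_rate(fit$lambda_spec, times)
  mu <- eval_rate(fit$mu_spec, times)
  data.frame(time = times, lambda = lam, mu = mu, net_div = lam - mu)
}

#' Fixed-shift two-regime birth-death comparison
#'
#' Desk-scale analogue of a Bayesian shift analysis: the tree is split into a
#' focal clade and the background (the clade collapsed to a single
#' representative lineage), and a shared constant-rate model is compared
#' against clade-specific rates by a likelihood-ratio test (df = 2) and
#' AICc. Each part's likelihood is conditioned on its own crown age, so the
#' one-regime model is the exact constraint of the two-regime model on the
#' same decomposition.
#'
#' @param tree ultrametric `phylo`.
#' @param clade_tips tip labels spanning the focal clade (its MRCA defines
#'   the shifted regime). The clade and the background must each retain at
#'   least 3 tips.
#' @param f_background,f_clade sampling fractions per regime.
#' @return list with the four constant-rate fits, log-likelihoods of the
#'   shared and two-regime models, LRT, delta AICc, and the preferred model
#'   under the two-unit rule.
#' @export
fit_fixed_shift <- function(tree, clade_tips, f_background = 1, f_clade = 1) {
  if (length(clade_tips) < 3) stop("focal clade must have at least 3 tips")
  if (!all(clade_tips %in% tree$tip.label)) stop("unknown clade tips")
  mrca <- ape::getMRCA(tree, clade_tips)
  clade <- ape::extract.clade(tree, mrca)
  if (length(clade$tip.label) < 3)
    stop("focal clade must have at least 3 tips")
  keep_one <- clade$tip.label[1]
  bg <- ape::drop.tip(tree, setdiff(clade$tip.label, keep_one))
  if (length(bg$tip.label) < 3)
    stop("background must retain at least 3 tips")

  bt_c <- branching_times(clade)
  bt_b <- branching_times(bg)
  nll_shared <- function(p) {
    la <- exp(p[1]); mu <- exp(p[2])
    -(crbd_loglik_bt(bt_c, la, mu, f_clade) +
        crbd_loglik_bt(bt_b, la, mu, f_background))
  }
  nll_part <- function(bt, f) function(p) {
    -crbd_loglik_bt(bt, exp(p[1]), exp(p[2]), f)
  }
  la0 <- log(max(length(bt_b) - 1, 1) / (2 * bt_b[1] + sum(bt_b[-1])))
  starts <- rbind(c(la0, la0 - 2), c(la0 + 1, la0 - 1), c(la0 - 1, la0 - 4))
  f1 <- multi_start(nll_shared, starts, rep(log(1e-8), 2), rep(log(1e3), 2))
  fc <- multi_start(nll_part(bt_c, f_clade), starts,
                    rep(log(1e-8), 2), rep(log(1e3), 2))
  fb <- multi_start(nll_part(bt_b, f_background), starts,
                    rep(log(1e-8), 2), rep(log(1e3), 2))
  logL1 <- -f1$objective
  logL2 <- -(fc$objective + fb$objective)
  n_bt <- length(bt_c) + length(bt_b)
  a1 <- aicc(logL1, 2, n_bt)
  a2 <- aicc(logL2, 4, n_bt)
  test <- lrt(logL1, logL2, df = 2)
  list(
    shared = list(lambda = exp(f1$par[1]), mu = exp(f1$par[2]), logL = logL1,
                  aicc = a1),
    clade = list(lambda = exp(fc$par[1]), mu = exp(fc$par[2]),
                 logL = -fc$objective),
    background = list(lambda = exp(fb$par[1]), mu = exp(fb$par[2]),
                      logL = -fb$objective),
    logL_two_regime = logL2, lrt = test,
    delta_aicc = a1 - a2,
    preferred = if (a2 < a1 - 2) "two_regime"
                else if (a1 < a2 - 2) "one_regime" else "tie")
}
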