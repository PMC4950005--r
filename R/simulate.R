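# ---------------------------------------------------------------------------
# Forward birth-death simulation engine.
#
# Time runs as age-before-present: the process starts at `crown_age` with two
# lineages and advances toward age 0. Lineage records (parent, birth age, end
# age, fate, class) are grown event by event; the reconstructed tree is built
# from the survivors. Time-varying rates are handled by Poisson thinning
# against the running maximum of the rate over the remaining interval (exact;
# no time discretisation). Diversity-dependent rates are constant between
# events, so plain Gillespie sampling is exact there.
# ---------------------------------------------------------------------------

# f_rates(age, cls, N): list(lambda = per-lineage vector, mu = vector)
# f_bound(age): upper bound on (lambda + mu) per lineage over [0, age]
# q: class transition-rate matrix (or NULL); shift: list(age, to_class)
sim_engine <- function(crown_age, init_classes, f_rates, f_bound,
                       q = NULL, shift = NULL, max_tips = 5000,
                       max_events = 1e6) {
  cap <- 256
  parent <- integer(cap); birth <- numeric(cap); endt <- numeric(cap)
  fate <- integer(cap)  # 0 alive, 1 dead, 2 split
  cls <- integer(cap)
  n_lin <- 2L
  parent[1:2] <- 0L; birth[1:2] <- crown_age; fate[1:2] <- 0L
  cls[1:2] <- init_classes
  alive <- c(1L, 2L)
  a <- crown_age
  shift_done <- is.null(shift)
  qsum <- if (is.null(q)) NULL else rowSums(q)
  ev <- 0L
  while (length(alive) > 0) {
    ev <- ev + 1L
    if (ev > max_events) return(NULL)
    if (length(alive) > max_tips) return(NULL)  # runaway: caller rejects
    B <- f_bound(a)
    qs <- if (is.null(q)) 0 else qsum[cls[alive]]
    tot <- length(alive) * B + sum(qs)
    dt <- rexp(1, tot)
    a_new <- a - dt
    if (!shift_done && a_new <= shift$age) {
      a <- shift$age
      pick <- alive[sample.int(length(alive), 1)]
      cls[pick] <- shift$to_class
      shift_done <- TRUE
      next
    }
    if (a_new <= 0) break
    a <- a_new
    r <- f_rates(a, cls[alive], length(alive))
    w <- r$lambda + r$mu + qs
    # thinning: accept the proposed event with probability sum(w)/tot
    if (runif(1) > sum(w) / tot) next
    i <- sample.int(length(alive), 1, prob = w)
    lin <- alive[i]
    u <- runif(1) * w[i]
    if (u < r$lambda[i]) {
      # birth: lineage splits into two daughters
      if (n_lin + 2 > cap) {
        cap <- cap * 2
        length(parent) <- cap; length(birth) <- cap; length(endt) <- cap
        length(fate) <- cap; length(cls) <- cap
        parent[is.na(parent)] <- 0L
      }
      endt[lin] <- a; fate[lin] <- 2L
      d <- c(n_lin + 1L, n_lin + 2L)
      parent[d] <- lin; birth[d] <- a; fate[d] <- 0L; cls[d] <- cls[lin]
      n_lin <- n_lin + 2L
      alive <- c(alive[-i], d)
    } else if (u < r$lambda[i] + r$mu[i]) {
      endt[lin] <- a; fate[lin] <- 1L
      alive <- alive[-i]
    } else {
      # class transition
      pto <- q[cls[lin], ]
      cls[lin] <- sample.int(ncol(q), 1, prob = pto)
    }
  }
  if (length(alive) < 2) return(NULL)
  endt[alive] <- 0
  list(parent = parent[1:n_lin], birth = birth[1:n_lin],
       endt = endt[1:n_lin], fate = fate[1:n_lin], cls = cls[1:n_lin],
       alive = alive)
}

# build the reconstructed (pruned) phylo from an engine record
sim_to_tree <- function(rec) {
  n_lin <- length(rec$parent)
  kids <- split(seq_len(n_lin), rec$parent)
  kids_of <- function(i) kids[[as.character(i)]]
  newick <- function(i) {
    len <- rec$birth[i] - rec$endt[i]
    if (rec$fate[i] == 2L) {
      ch <- kids_of(i)
      sprintf("(%s,%s):%.10g", newick(ch[1]), newick(ch[2]), len)
    } else {
      sprintf("t%d:%.10g", i, len)
    }
  }
  # crown: the two founding lineages
  roots <- which(rec$parent == 0L)
  s <- sprintf("(%s,%s);", newick(roots[1]), newick(roots[2]))
  tr <- ape::read.tree(text = s)
  dead <- sprintf("t%d", which(rec$fate == 1L))
  if (length(dead) > 0) tr <- ape::drop.tip(tr, dead)
  tr
}

# do both crown lineages have surviving descendants?
crown_survives <- function(rec) {
  anc <- function(i) {
    while (rec$parent[i] != 0L) i <- rec$parent[i]
    i
  }
  founders <- unique(vapply(rec$alive, anc, integer(1)))
  length(founders) == 2
}

#' Simulate an ultrametric tree under a fitted model family
#'
#' Forward simulation from two crown lineages under the Yule, constant-rate,
#' environment-dependent (exponential or linear) or diversity-dependent
#' birth-death process, conditioned by rejection on survival of both crown
#' lineages. Extinct lineages are pruned, so the returned tree is the
#' reconstructed phylogeny. Time-varying rates use exact Poisson thinning
#' against the curve's running extremum; no time discretisation is
#' involved.
#'
#' @param model one of `"yule"`, `"crbd"`, `"env_exp"`, `"env_lin"`, `"dd"`.
#' @param params named list: `lambda`, `mu` (constant models); `lambda0`,
#'   `mu0`, `alpha`, `beta`, `curve` (env models; a coefficient of 0 holds
#'   that rate constant); `lambda0`, `mu`, `K` (diversity dependence).
#' @param crown_age age of the crown (Myr).
#' @param n_range optional acceptance band on the tip count, e.g.
#'   `c(270, 330)`; trees outside are rejected and redrawn.
#' @param seed optional RNG seed (set for reproducible fixtures).
#' @param max_tips reject runaway simulations beyond this many coexisting
#'   lineages.
#' @param max_tries rejection-sampling cap.
#' @return an ultrametric `phylo`; the generating parameters are attached as
#'   attribute `"true_params"`.
#' @export
simulate_tree <- function(model = c("yule", "crbd", "env_exp", "env_lin", "dd"),
                          params, crown_age, n_range = NULL, seed = NULL,
                          max_tips = 5000, max_tries = 1000) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  fr_fb <- switch(model,
    yule = {
      la <- params$lambda
      list(r = function(a, cl, N) list(lambda = rep(la, N), mu = rep(0, N)),
           b = function(a) la)
    },
    crbd = {
      la <- params$lambda; mu <- params$mu
      list(r = function(a, cl, N) list(lambda = rep(la, N), mu = rep(mu, N)),
           b = function(a) la + mu)
    },
    env_exp = ,
    env_lin = {
      form <- if (model == "env_exp") "env_exp" else "env_lin"
      ls <- rate_spec(if ((params$alpha %||% 0) != 0) form else "constant",
                      params$lambda0, params$alpha %||% 0, params$curve)
      ms <- rate_spec(if ((params$beta %||% 0) != 0) form else "constant",
                      params$mu0 %||% 0, params$beta %||% 0, params$curve)
      # running maximum of lambda + mu over [0, a] on a fine grid
      gr <- seq(0, crown_age, length.out = 512)
      tot <- eval_rate(ls, gr) + eval_rate(ms, gr)
      runmax <- cummax(tot)
      bfun <- approxfun(gr, runmax, method = "constant", f = 1, rule = 2)
      list(r = function(a, cl, N) {
             list(lambda = rep(eval_rate(ls, a), N),
                  mu = rep(eval_rate(ms, a), N))
           },
           b = function(a) bfun(a) + 1e-12)
    },
    dd = {
      la0 <- params$lambda0; mu <- params$mu %||% 0; K <- params$K
      list(r = function(a, cl, N) {
             la <- max(0, la0 - (la0 - mu) * N / K)
             list(lambda = rep(la, N), mu = rep(mu, N))
           },
           b = function(a) la0 + mu)
    })
  for (try in seq_len(max_tries)) {
    rec <- sim_engine(crown_age, c(1L, 1L), fr_fb$r, fr_fb$b,
                      max_tips = max_tips)
    if (is.null(rec) || !crown_survives(rec)) next
    n_tip <- length(rec$alive)
    if (!is.null(n_range) && (n_tip < n_range[1] || n_tip > n_range[2])) next
    tr <- sim_to_tree(rec)
    attr(tr, "true_params") <- c(list(model = model, crown_age = crown_age),
                                 params[setdiff(names(params), "curve")])
    return(tr)
  }
  stop("no accepted simulation in ", max_tries, " tries")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Jointly simulate a tree and a binary trait under BiSSE
#'
#' Forward simulation with state-specific speciation and extinction and
#' Markov transitions between states; daughters inherit the parent state.
#' The root state is drawn from the stationary frequencies of the
#' transition process unless given.
#'
#' @param pars named vector `lambda0, lambda1, mu0, mu1, q01, q10`.
#' @param crown_age crown age (Myr).
#' @param root_state 0, 1, or `NULL` (stationary Bernoulli draw per crown
#'   lineage pair; both crown lineages share the root state).
#' @inheritParams simulate_tree
#' @return list with `tree`, `states` (named 0/1 vector over tips),
#'   `pars`, `root_state`.
#' @export
simulate_bisse <- function(pars, crown_age, root_state = NULL,
                           n_range = NULL, seed = NULL, max_tips = 5000,
                           max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  pars <- pars[c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")]
  la <- pars[c("lambda0", "lambda1")]
  mu <- pars[c("mu0", "mu1")]
  q <- matrix(c(0, pars[["q10"]], pars[["q01"]], 0), 2, 2)
  fr <- function(a, cl, N) list(lambda = unname(la[cl]), mu = unname(mu[cl]))
  fb <- function(a) max(la + mu)
  stat1 <- if (sum(q) > 0) pars[["q01"]] / (pars[["q01"]] + pars[["q10"]]) else 0.5
  for (try in seq_len(max_tries)) {
    rs <- if (is.null(root_state)) rbinom(1, 1, stat1) else root_state
    rec <- sim_engine(crown_age, rep(rs + 1L, 2), fr, fb, q = q,
                      max_tips = max_tips)
    if (is.null(rec) || !crown_survives(rec)) next
    n_tip <- length(rec$alive)
    if (!is.null(n_range) && (n_tip < n_range[1] || n_tip > n_range[2])) next
    tr <- sim_to_tree(rec)
    states <- setNames((rec$cls - 1L)[rec$alive],
                       sprintf("t%d", rec$alive))[tr$tip.label]
    return(list(tree = tr, states = states, pars = pars, root_state = rs))
  }
  stop("no accepted simulation in ", max_tries, " tries")
}

#' Simulate a tree with a single diversification-rate shift
#'
#' Background constant-rate diversification with a rate shift imposed on one
#' randomly chosen lineage (and all its descendants) at a fixed age - the
#' generative counterpart of the fixed-shift two-regime comparison. The
#' simulation is conditioned on crown survival, on the shifted clade
#' retaining at least `min_clade_tips` tips and on the background retaining
#' at least `min_bg_tips`.
#'
#' @param lambda_bg,mu_bg background rates.
#' @param lambda_clade,mu_clade rates inside the shifted clade.
#' @param crown_age crown age (Myr).
#' @param shift_age age of the shift (Myr, < crown age).
#' @inheritParams simulate_tree
#' @param min_clade_tips,min_bg_tips acceptance thresholds.
#' @return list with `tree` and `clade_tips` (tip labels of the shifted
#'   clade).
#' @export
simulate_shift_tree <- function(lambda_bg, mu_bg, lambda_clade, mu_clade,
                                crown_age, shift_age, seed = NULL,
                                min_clade_tips = 3, min_bg_tips = 3,
                                max_tips = 5000, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  la <- c(lambda_bg, lambda_clade)
  mu <- c(mu_bg, mu_clade)
  fr <- function(a, cl, N) list(lambda = unname(la[cl]), mu = unname(mu[cl]))
  fb <- function(a) max(la + mu)
  for (try in seq_len(max_tries)) {
    rec <- sim_engine(crown_age, c(1L, 1L), fr, fb,
                      shift = list(age = shift_age, to_class = 2L),
                      max_tips = max_tips)
    if (is.null(rec) || !crown_survives(rec)) next
    clade_tips_all <- which(rec$cls == 2L & rec$fate != 2L)
    alive_clade <- intersect(rec$alive, which(rec$cls == 2L))
    alive_bg <- setdiff(rec$alive, alive_clade)
    if (length(alive_clade) < min_clade_tips ||
        length(alive_bg) < min_bg_tips) next
    tr <- sim_to_tree(rec)
    clade_tips <- intersect(sprintf("t%d", alive_clade), tr$tip.label)
    return(list(tree = tr, clade_tips = clade_tips,
                pars = c(lambda_bg = lambda_bg, mu_bg = mu_bg,
                         lambda_clade = lambda_clade, mu_clade = mu_clade,
                         shift_age = shift_age)))
  }
  stop("no accepted simulation in ", max_tries, " tries")
}

#' Subsample tips to emulate incomplete taxon sampling
#'
#' Bernoulli retention of tips, uniformly or per group (clade tags or trait
#' states), mirroring how real phylogenies undersample their clades.
#'
#' @param tree `phylo`.
#' @param f retention probability: a scalar, or a named vector over groups.
#' @param groups optional named vector (tip -> group) when `f` is named.
#' @param seed optional RNG seed.
#' @param max_tries resampling cap for schemes that keep fewer than 2 tips.
#' @return pruned `phylo` with attribute `"realized_f"` (overall and, when
#'   grouped, per-group realized retention fractions).
#' @export
subsample_tips <- function(tree, f, groups = NULL, seed = NULL,
                           max_tries = 100) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  p <- if (length(f) == 1 && is.null(names(f))) rep(f, n)
       else {
         if (is.null(groups)) stop("named f requires groups")
         unname(f[as.character(groups[tree$tip.label])])
       }
  if (any(is.na(p) | p < 0 | p > 1)) stop("invalid retention probabilities")
  for (try in seq_len(max_tries)) {
    keep <- runif(n) < p
    if (sum(keep) >= 2) {
      out <- if (all(keep)) tree else ape::drop.tip(tree, tree$tip.label[!keep])
      rf <- c(overall = mean(keep))
      if (!is.null(groups)) {
        g <- as.character(groups[tree$tip.label])
        rf <- c(rf, tapply(keep, g, mean))
      }
      attr(out, "realized_f") <- rf
      return(out)
    }
  }
  stop("subsampling kept fewer than 2 tips in every attempt")
}

#' Template paleoenvironment series
#'
#' Synthetic but geologically shaped covariate series for testing and
#' examples. `"andean_elevation"` is a monotone rise from 0 m at 40 Myr to
#' about 4500 m at present in which well under half of the modern elevation
#' is attained before 10 Myr ago, with steep pulses through the late
#' Miocene (10-6 Myr) and around 4.5 Myr - the consensus shape of tropical
#' Andean surface uplift. `"cenozoic_cooling"` is a temperature proxy that
#' peaks in the mid-Miocene and declines, with noise, toward the present.
#'
#' @param kind `"andean_elevation"` or `"cenozoic_cooling"`.
#' @param seed RNG seed for the noise component (series are reproducible by
#'   seed).
#' @param by age step in Myr.
#' @return a [paleo_series()].
#' @export
make_paleo_curve <- function(kind = c("andean_elevation", "cenozoic_cooling"),
                             seed = 1, by = 0.5) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "andean_elevation") {
    ages <- seq(0, 40, by = by)
    knots_age <- c(40, 30, 20, 14, 10, 8, 6, 5, 4.5, 3.5, 2, 0)
    knots_val <- c(0, 150, 500, 900, 1300, 2300, 3100, 3250, 3500, 4300,
                   4450, 4500)
    base <- splinefun(rev(knots_age), rev(knots_val), method = "hyman")
    v <- base(ages) + rnorm(length(ages), 0, 30)
    # keep the series monotone in time (nondecreasing toward the present)
    v <- rev(cummax(rev(pmax(v, 0))))
    v <- pmin(v, 4600)
    paleo_series(ages, v)
  } else {
    ages <- seq(0, 20, by = by / 2)
    v <- 0.8 + 0.11 * ages + 1.3 * exp(-((ages - 15) / 3)^2) +
      rnorm(length(ages), 0, 0.2)
    paleo_series(ages, v)
  }
}

#' Synthetic species-level trait table
#'
#' Generates a full trait table (one row per known species, a flag for
#' presence in the tree) with a requested state frequency - the fixture
#' shape of a complete trait scoring of a large clade of which only part is
#' phylogenetically sampled.
#'
#' @param n_species total species scored.
#' @param state_freq frequency of state 1.
#' @param n_in_tree number of species flagged as tree tips.
#' @param seed RNG seed.
#' @param name trait name.
#' @return a [trait_data()] table of `n_species` rows.
#' @export
make_trait_table <- function(n_species = 594, state_freq = 0.5,
                             n_in_tree = 200, seed = 1, name = "trait") {
  if (n_in_tree > n_species) stop("n_in_tree exceeds n_species")
  set.seed(seed)
  sp <- sprintf("sp%04d", seq_len(n_species))
  st <- rbinom(n_species, 1, state_freq)
  in_tree <- seq_len(n_species) %in% sample.int(n_species, n_in_tree)
  trait_data(sp, st, in_tree, name = name)
}
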