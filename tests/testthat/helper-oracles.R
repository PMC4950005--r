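# Independent brute-force oracles. These deliberately avoid the package's
# integration machinery: fixed-step quadrature / RK4 in plain R, so that
# agreement with the package validates both the maths and the adaptive
# integrators.

# small fixed trees used across tests
tree4 <- function() read_newick("(((A:1,B:1):1,C:2):1,D:3);")
tree5 <- function() read_newick("((((A:0.5,B:0.5):0.5,C:1):0.5,D:1.5):0.5,E:2);")

# --- time-varying birth-death: fine-grid trapezoid sums -------------------
oracle_bd_loglik <- function(tree, lam_fun, mu_fun, f = 1, condition = TRUE,
                             dt = 1e-4) {
  bt <- branching_times(tree)
  t1 <- bt[1]
  grid <- seq(0, t1, by = dt)
  if (grid[length(grid)] < t1) grid <- c(grid, t1)
  lam <- pmax(lam_fun(grid), 0)
  mu <- pmax(mu_fun(grid), 0)
  ctz <- function(y) c(0, cumsum(diff(grid) * (y[-1] + y[-length(y)]) / 2))
  R <- ctz(lam - mu)
  J <- ctz(exp(R) * lam)
  at <- function(v, t) approx(grid, v, t, rule = 2)$y
  logPsi <- function(t) at(R, t) - 2 * log1p(f * at(J, t))
  n <- length(bt) + 1
  ll <- n * log(f) + sum(log(at(lam, bt[-1])) + logPsi(bt[-1])) +
    2 * logPsi(t1)
  if (condition)
    ll <- ll - 2 * (log(f) + at(R, t1) - log1p(f * at(J, t1)))
  ll
}

# --- BiSSE: fixed-step RK4 pruning ----------------------------------------
oracle_bisse_loglik <- function(tree, states, pars, f = c(1, 1),
                                root = "fitzjohn", condition = TRUE,
                                dt = 1e-5) {
  la <- pars[c("lambda0", "lambda1")]
  mu <- pars[c("mu0", "mu1")]
  qq <- pars[c("q01", "q10")]
  deriv <- function(y) {
    E <- y[1:2]; D <- y[3:4]
    dE <- mu - (la + mu + qq) * E + qq * rev(E) + la * E^2
    dD <- -(la + mu + qq) * D + qq * rev(D) + 2 * la * E * D
    c(dE, dD)
  }
  rk4 <- function(y, len) {
    ns <- max(1, ceiling(len / dt))
    h <- len / ns
    for (s in seq_len(ns)) {
      k1 <- deriv(y); k2 <- deriv(y + h / 2 * k1)
      k3 <- deriv(y + h / 2 * k2); k4 <- deriv(y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    y
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tr$tip.label)
  st <- states[tr$tip.label]
  vals <- vector("list", 2 * nt - 1)
  logc <- 0
  for (i in seq_len(nt))
    vals[[i]] <- c(1 - f, ifelse(st[i] == 0:1, f, 0))
  root_id <- nt + 1
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    y <- rk4(vals[[ch]], tr$edge.length[e])
    sc <- sum(abs(y[3:4])); y[3:4] <- y[3:4] / sc; logc <- logc + log(sc)
    if (is.null(vals[[par]])) {
      vals[[par]] <- y
    } else {
      mult <- if (par == root_id) c(1, 1) else la
      vals[[par]][3:4] <- mult * vals[[par]][3:4] * y[3:4]
      vals[[par]][1:2] <- (vals[[par]][1:2] + y[1:2]) / 2
    }
  }
  v <- vals[[root_id]]
  d <- v[3:4]
  if (condition) d <- d / (1 - v[1:2])^2
  L <- switch(root, fitzjohn = sum(d^2) / sum(d), equal = mean(d), sum = sum(d))
  logc + log(L)
}

# --- diversity dependence: fixed-step RK4 on the master equation ----------
oracle_dd_loglik <- function(tree, lambda0, mu, K, M = 80, richness = NULL,
                             condition = TRUE, dt = 1e-5) {
  laN <- function(N) pmax(0, lambda0 - (lambda0 - mu) * N / K)
  bt <- branching_times(tree)
  n <- length(bt) + 1
  if (is.null(richness)) richness <- n
  m_star <- richness - n
  m <- 0:M
  rk4vec <- function(q, k, len) {
    deriv <- function(q) {
      N <- k + m
      v <- -(N * laN(N) + N * mu) * q
      v[-1] <- v[-1] + (2 * k + m[-1] - 1) * laN(k + m[-1] - 1) * q[-(M + 1)]
      v[-(M + 1)] <- v[-(M + 1)] + mu * (m[-(M + 1)] + 1) * q[-1]
      v
    }
    ns <- max(1, ceiling(len / dt))
    h <- len / ns
    for (s in seq_len(ns)) {
      k1 <- deriv(q); k2 <- deriv(q + h / 2 * k1)
      k3 <- deriv(q + h / 2 * k2); k4 <- deriv(q + h * k3)
      q <- q + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    q
  }
  q <- c(1, rep(0, M))
  k <- 2
  times <- c(bt, 0)
  logc <- 0
  for (i in seq_len(length(times) - 1)) {
    q <- rk4vec(q, k, times[i] - times[i + 1])
    s <- sum(q); q <- q / s; logc <- logc + log(s)
    if (i < length(times) - 1) {
      q <- q * laN(k + m)
      k <- k + 1
    }
  }
  ll <- logc + log(q[m_star + 1])
  if (condition) {
    # single-lineage survival via its own RK4 master equation
    p <- c(1, rep(0, M)); nn <- 1:(M + 1) - 1
    deriv <- function(p) {
      v <- -(nn * laN(nn) + nn * mu) * p
      v[-1] <- v[-1] + (nn[-1] - 1) * laN(nn[-1] - 1) * p[-(M + 1)]
      v[-(M + 1)] <- v[-(M + 1)] + mu * (nn[-(M + 1)] + 1) * p[-1]
      v
    }
    p[1] <- 0; p[2] <- 1
    ns <- ceiling(bt[1] / dt); h <- bt[1] / ns
    for (s in seq_len(ns)) {
      k1 <- deriv(p); k2 <- deriv(p + h / 2 * k1)
      k3 <- deriv(p + h / 2 * k2); k4 <- deriv(p + h * k3)
      p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    ll <- ll - 2 * log(1 - p[1])
  }
  ll
}

# Mk2 trait simulation on a tree (generator side; wraps ape)
sim_mk2_trait <- function(tree, q01 = 0.1, q10 = 0.1, max_tries = 20) {
  Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
  for (i in seq_len(max_tries)) {
    st <- ape::rTraitDisc(tree, model = Q, states = 0:1,
                          root.value = sample(1:2, 1))
    out <- setNames(as.integer(as.character(st)), names(st))
    if (length(unique(out)) == 2) return(out)
  }
  out
}

# closed-form constant-rate birth-death likelihood on branching times
# (internal engine, used directly by the size-control checks)
crbd_loglik_bt_acc <- function(bt, lambda, mu) {
  paleodiv:::crbd_loglik_bt(bt, lambda, mu, f = 1, condition = TRUE)
}
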