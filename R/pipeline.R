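#' Rank a set of fitted models by AICc
#'
#' Builds the model-selection table used throughout the package: delta AICc
#' relative to the best model, Akaike weights, and the decisiveness rule -
#' the lowest-AICc model is called best only when it beats the runner-up by
#' at least two AICc units; otherwise the tie set (all models within two
#' units) is reported. Likelihood-ratio tests are added for declared nested
#' pairs.
#'
#' @param fits named list of fits (each with `logL`, `k`, `aicc`, `n`).
#' @param nested optional list of `c(sub, super)` name pairs for LRTs;
#'   boundary-corrected when the pair differs by one parameter that sits on
#'   the boundary (e.g. Yule vs constant-rate birth-death).
#' @param boundary_pairs character vector of `"sub>super"` ids that need the
#'   chi-squared 0/1 mixture.
#' @return data.frame (model, logL, k, AICc, delta_AICc, weight, rank) with
#'   attributes `best` (model name or `"tie"`) and `tie_set`; LRT results
#'   in attribute `lrt` when requested.
#' @export
compare_models <- function(fits, nested = NULL, boundary_pairs = character()) {
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1)
    stop("fits are not on identical data (different numbers of branching times)")
  tab <- data.frame(
    model = names(fits),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1)),
    stringsAsFactors = FALSE)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta_AICc / 2)
  tab$weight <- w / sum(w)
  tab <- tab[order(tab$AICc, tab$k), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tie_set <- tab$model[tab$delta_AICc < 2]
  best <- if (length(tie_set) == 1) tie_set[1] else "tie"
  attr(tab, "best") <- best
  attr(tab, "tie_set") <- tie_set
  if (!is.null(nested)) {
    lrts <- lapply(nested, function(pr) {
      f0 <- fits[[pr[1]]]; f1 <- fits[[pr[2]]]
      id <- paste0(pr[1], ">", pr[2])
      c(list(pair = id),
        lrt(f0$logL, f1$logL, df = f1$k - f0$k,
            boundary = id %in% boundary_pairs))
    })
    attr(tab, "lrt") <- lrts
  }
  tab
}

# nested pairs within the env model family
env_nested_pairs <- function(models) {
  all_pairs <- list(
    c("yule", "crbd"), c("yule", "lambda_exp"), c("crbd", "lambda_exp_mu"),
    c("crbd", "mu_exp"), c("lambda_exp_mu", "lambda_mu_exp"),
    c("mu_exp", "lambda_mu_exp"), c("yule", "lambda_lin"),
    c("crbd", "lambda_lin_mu"), c("crbd", "mu_lin"),
    c("lambda_lin_mu", "lambda_mu_lin"), c("mu_lin", "lambda_mu_lin"))
  Filter(function(p) all(p %in% models), all_pairs)
}

#' Run a model suite across a set of trees
#'
#' Orchestrates the replicated analysis design: a model suite is fitted to
#' every tree of a (posterior-sample-like) tree set, the best model per
#' tree is called with the two-AICc-unit rule, and results are aggregated
#' across trees (best-model frequencies; median and quantiles of parameter
#' estimates). Per-tree failures are logged and never abort the suite. The
#' `"dd"` suite runs by default on the first tree only, mirroring the
#' practice of running computationally heavy diversity-dependent fits on a
#' single summary tree.
#'
#' @param trees a `multiPhylo`, list of `phylo`, or path to a multi-tree
#'   Newick file.
#' @param suite one of `"env"`, `"bisse"`, `"dd"`, `"shift"`,
#'   `"rates_table"`.
#' @param config named list of suite inputs: `curve` (env), `states` and
#'   `f` (bisse), `richness` and `K_max` (dd), `clade_tips` (shift),
#'   `records` and `eps_list` (rates_table); plus `n_starts`, `models`,
#'   `all_trees` (force dd across all trees).
#' @param seed RNG seed (multi-start jitter), recorded in the provenance.
#' @return object of class `"suite_report"`: `per_tree` results, `summary`
#'   aggregates, `failures`, and `provenance` (seed, config hash, package
#'   version).
#' @export
run_suite <- function(trees, suite = c("env", "bisse", "dd", "shift",
                                       "rates_table"),
                      config = list(), seed = 1) {
  suite <- match.arg(suite)
  if (is.character(trees)) trees <- read_newick(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  set.seed(seed)
  n_starts <- config$n_starts %||% 3

  if (suite == "rates_table") {
    records <- config$records %||% read_clade_records()
    tab <- build_rate_table(records, config$eps_list %||% c(0, 0.5, 0.9))
    return(structure(list(per_tree = list(), summary = list(table = tab),
                          failures = list(),
                          provenance = provenance(seed, config)),
                     class = "suite_report"))
  }

  use_trees <- if (suite == "dd" && !isTRUE(config$all_trees)) trees[1]
               else trees
  per_tree <- vector("list", length(use_trees))
  failures <- list()
  for (i in seq_along(use_trees)) {
    res <- tryCatch({
      tr <- use_trees[[i]]
      switch(suite,
        env = {
          models <- config$models %||% bd_model_table()$model
          out <- fit_bd_models(tr, curve = config$curve, f = config$f %||% 1,
                               models = models, n_starts = n_starts)
          out$table <- compare_models(out$fits,
                                      nested = env_nested_pairs(models),
                                      boundary_pairs = "yule>crbd")
          out
        },
        bisse = fit_bisse_models(tr, config$states, f = config$f %||% c(1, 1),
                                 n_starts = n_starts),
        dd = dd_model_table(tr, richness = config$richness,
                            K_max = config$K_max %||% 1e6,
                            n_starts = n_starts),
        shift = fit_fixed_shift(tr, config$clade_tips,
                                f_background = config$f_background %||% 1,
                                f_clade = config$f_clade %||% 1))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- list(tree = i,
                                               message = conditionMessage(res))
      per_tree[i] <- list(NULL)
    } else {
      per_tree[[i]] <- res
    }
  }

  ok <- !vapply(per_tree, is.null, logical(1))
  summary <- list(n_trees = length(use_trees), n_ok = sum(ok))
  if (suite %in% c("env", "bisse", "dd") && any(ok)) {
    bests <- vapply(per_tree[ok], function(r) attr(r$table, "best"),
                    character(1))
    summary$best_model_freq <- sort(table(bests), decreasing = TRUE)
    # cross-tree parameter quantiles for the modal best model
    modal <- names(summary$best_model_freq)[1]
    if (modal != "tie") {
      pars <- do.call(rbind, lapply(per_tree[ok], function(r)
        r$fits[[modal]]$params))
      summary$modal_model <- modal
      summary$param_median <- apply(pars, 2, median)
      summary$param_q <- apply(pars, 2, quantile, c(0.025, 0.975))
    }
  }
  if (suite == "shift" && any(ok)) {
    summary$preferred_freq <-
      sort(table(vapply(per_tree[ok], function(r) r$preferred,
                        character(1))), decreasing = TRUE)
  }
  structure(list(per_tree = per_tree, summary = summary, failures = failures,
                 provenance = provenance(seed, config)),
            class = "suite_report")
}

provenance <- function(seed, config) {
  list(seed = seed,
       config_hash = config_hash(config[setdiff(names(config),
                                                c("curve", "states"))]),
       package_version = as.character(utils::packageVersion("paleodiv")))
}

#' @export
print.suite_report <- function(x, ...) {
  cat(sprintf("suite_report: %d/%d trees fitted (seed %s, config %s)\n",
              x$summary$n_ok %||% 0, x$summary$n_trees %||% 0,
              x$provenance$seed, x$provenance$config_hash))
  if (!is.null(x$summary$best_model_freq)) {
    cat("best-model frequencies:\n")
    print(x$summary$best_model_freq)
  }
  if (!is.null(x$summary$table)) print(x$summary$table)
  invisible(x)
}
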