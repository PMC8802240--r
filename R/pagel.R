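#' Template for Pagel's correlated-evolution models
#'
#' Two binary traits evolve as one 4-state Markov chain on the joint states
#' `00, 01, 10, 11` (trait X first; joint index `2x + y`). Double transitions
#' (both traits changing at once, `00<->11` and `01<->10`) are forbidden in
#' both models. The independent model has 4 free rates (each trait's gain
#' and loss rate, ignoring the other trait's state); the dependent model
#' frees all 8 single-trait transitions, letting each trait's rates depend
#' on the background state of the other.
#'
#' @param model `"independent"` or `"dependent"`.
#' @return An `mk_template` on 4 states (usable with all Mk machinery).
#' @export
pagel_template <- function(model = c("independent", "dependent")) {
  model <- match.arg(model)
  idx <- matrix(0L, 4L, 4L)  # rows/cols: 00, 01, 10, 11
  ## single-trait moves: (00,01) (10,11) change y; (00,10) (01,11) change x
  if (model == "independent") {
    ## p1: x 0->1, p2: x 1->0, p3: y 0->1, p4: y 1->0
    idx[1L, 3L] <- 1L; idx[2L, 4L] <- 1L
    idx[3L, 1L] <- 2L; idx[4L, 2L] <- 2L
    idx[1L, 2L] <- 3L; idx[3L, 4L] <- 3L
    idx[2L, 1L] <- 4L; idx[4L, 3L] <- 4L
  } else {
    ## 8 distinct rates, ordered: x-moves given y=0, y=1; y-moves given x=0,
    ## x=1 (gain before loss)
    idx[1L, 3L] <- 1L  # x 0->1 | y=0
    idx[3L, 1L] <- 2L  # x 1->0 | y=0
    idx[2L, 4L] <- 3L  # x 0->1 | y=1
    idx[4L, 2L] <- 4L  # x 1->0 | y=1
    idx[1L, 2L] <- 5L  # y 0->1 | x=0
    idx[2L, 1L] <- 6L  # y 1->0 | x=0
    idx[3L, 4L] <- 7L  # y 0->1 | x=1
    idx[4L, 3L] <- 8L  # y 1->0 | x=1
  }
  structure(list(name = paste0("pagel-", model), n_states = 4L, index = idx,
                 n_par = max(idx)),
            class = "mk_template")
}

## joint 0..3 state vector from two named binary vectors, complete cases only
.joint_states <- function(x, y) {
  common <- intersect(names(x), names(y))
  x <- x[common]
  y <- y[common]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!all(x %in% 0:1) || !all(y %in% 0:1)) {
    stop("traits must be binary 0/1")
  }
  out <- as.integer(2L * x + y)
  names(out) <- names(x)
  out
}

#' Log-likelihood of Pagel's dependent or independent model
#'
#' The joint chain's Mk likelihood via the pruning algorithm. Under the
#' independent model with equal root prior this factorises exactly into the
#' product of the two single-trait binary likelihoods.
#'
#' @param tree A `phylo` object (pruned to species with both traits).
#' @param x,y Named binary (0/1) vectors; only species present and non-NA in
#'   both are used and they must cover all tree tips.
#' @param model `"independent"` or `"dependent"`.
#' @param rates Length-4 (independent) or length-8 (dependent) non-negative
#'   vector.
#' @inheritParams mk_loglik
#' @return Log-likelihood.
#' @export
pagel_loglik <- function(tree, x, y, model = c("independent", "dependent"),
                         rates, root_prior = "equal") {
  model <- match.arg(model)
  tmpl <- pagel_template(model)
  if (length(rates) != tmpl$n_par) {
    stop("expected ", tmpl$n_par, " rates for the ", model, " model, got ",
         length(rates))
  }
  mk_loglik(tree, .joint_states(x, y), tmpl, rates, root_prior)
}

## Generic per-parameter Metropolis-Hastings on log-rates over a tempered
## target beta * loglik(r) + logprior(r) (+ log-scale Jacobian). Uses the
## caller's RNG stream. Returns kept draws (rate scale) and their logliks.
.mh_power <- function(loglik, logprior, beta, npar, n_burnin, n_iter, n_thin,
                      start_lr) {
  target <- function(lr, ll) beta * ll + logprior(exp(lr)) + sum(lr)
  lr <- start_lr
  ll <- loglik(exp(lr))
  if (!is.finite(ll) && beta > 0) {
    lr <- rep(0, npar); ll <- loglik(exp(lr))
  }
  tg <- target(lr, ll)
  scale <- rep(0.5, npar)
  tune_acc <- rep(0L, npar); tune_n <- 0L
  n_keep <- max(floor(n_iter / n_thin), 1L)
  draws <- matrix(NA_real_, n_keep, npar)
  lls <- numeric(n_keep)
  kept <- 0L; acc <- 0L
  for (it in seq_len(n_burnin + n_iter)) {
    for (p in seq_len(npar)) {
      prop <- lr
      prop[p] <- prop[p] + stats::rnorm(1L, 0, scale[p])
      ll_new <- loglik(exp(prop))
      tg_new <- target(prop, ll_new)
      if (is.finite(tg_new) && log(stats::runif(1L)) < tg_new - tg) {
        lr <- prop; ll <- ll_new; tg <- tg_new
        acc <- acc + 1L
        if (it <= n_burnin) tune_acc[p] <- tune_acc[p] + 1L
      }
    }
    if (it <= n_burnin) {
      tune_n <- tune_n + 1L
      if (tune_n == 50L) {
        rate <- tune_acc / 50
        scale <- scale * ifelse(rate < 0.2, 0.7, ifelse(rate > 0.4, 1.4, 1))
        scale <- pmin(pmax(scale, 1e-3), 10)
        tune_acc[] <- 0L; tune_n <- 0L
      }
    } else if ((it - n_burnin) %% n_thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- exp(lr)
      lls[kept] <- ll
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE],
       loglik = lls[seq_len(kept)],
       acceptance = acc / ((n_burnin + n_iter) * npar),
       last_lr = lr)
}

## prior densities on the rate scale
.make_logprior <- function(prior, prior_mean, upper = 100) {
  switch(prior,
    exponential = function(r) {
      sum(stats::dexp(r, rate = 1 / prior_mean, log = TRUE))
    },
    uniform = function(r) {
      if (any(r > upper)) -Inf else -length(r) * log(upper)
    }
  )
}

## crude ML rates for the joint model (used for the default prior mean and
## as the chain start)
.pagel_ml <- function(tree, joint, tmpl, root_prior) {
  llfun <- .mk_loglik_factory(tree, joint, tmpl, root_prior)
  negll <- function(lr) {
    v <- -llfun(exp(lr))
    if (!is.finite(v)) 1e10 else v
  }
  start <- rep(log(2 / max(sum(tree$edge.length), 1e-12)), tmpl$n_par)
  fit <- stats::nlminb(start, negll, lower = rep(-20, tmpl$n_par),
                       upper = rep(10, tmpl$n_par))
  list(rates = exp(fit$par), logL = -fit$objective)
}

#' MCMC for Pagel's correlated-evolution models
#'
#' Runs several independent Metropolis-Hastings chains over the free rates of
#' the chosen model, assesses convergence with the potential scale reduction
#' factor (Gelman's R, via \pkg{coda}) and merges the chains. A run with any
#' PSRF above 1.1 is flagged non-converged.
#'
#' @inheritParams pagel_loglik
#' @param prior `"exponential"` (mean defaulting to the mean ML rate) or
#'   `"uniform"` (on `[0, 100]`).
#' @param prior_mean Mean of the exponential prior; `NULL` = use the ML
#'   estimate.
#' @param n_chains,n_burnin,n_iter,n_thin Chain configuration.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @return A `pagel_result`: list with `model`, `draws` (merged), `loglik`
#'   (per kept draw), `psrf` (per parameter), `converged`, `max_logL`,
#'   `ml_rates`, `acceptance`, `prior`.
#' @export
run_pagel_mcmc <- function(tree, x, y,
                           model = c("independent", "dependent"),
                           prior = c("exponential", "uniform"),
                           prior_mean = NULL, n_chains = 2,
                           n_burnin = 2000, n_iter = 10000, n_thin = 10,
                           seed = 1, root_prior = "equal") {
  model <- match.arg(model)
  prior <- match.arg(prior)
  tmpl <- pagel_template(model)
  joint <- .joint_states(x, y)
  ml <- .pagel_ml(tree, joint, tmpl, root_prior)
  ## cap the empirical prior mean: on weakly informative data the ML rates
  ## saturate (the likelihood plateaus for fast chains) and an uncapped
  ## mean would make the prior improperly flat
  if (is.null(prior_mean)) {
    prior_mean <- min(max(mean(ml$rates), 1e-3), 100)
  }
  logprior <- .make_logprior(prior, prior_mean)
  llfun <- .mk_loglik_factory(tree, joint, tmpl, root_prior)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    start <- log(pmin(pmax(ml$rates, 1e-6), 100)) +
      stats::rnorm(tmpl$n_par, 0, 0.5)
    chains[[ch]] <- .mh_power(llfun, logprior, beta = 1, npar = tmpl$n_par,
                              n_burnin = n_burnin, n_iter = n_iter,
                              n_thin = n_thin, start_lr = start)
  }
  labels <- template_par_labels(tmpl)
  mcl <- coda::mcmc.list(lapply(chains, function(c) coda::mcmc(c$draws)))
  psrf <- if (n_chains > 1L) {
    gd <- tryCatch(coda::gelman.diag(mcl, autoburnin = FALSE,
                                     multivariate = FALSE),
                   error = function(e) NULL)
    if (is.null(gd)) rep(NA_real_, tmpl$n_par) else gd$psrf[, 1L]
  } else rep(NA_real_, tmpl$n_par)
  names(psrf) <- labels
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- labels
  structure(list(model = model, draws = draws,
                 loglik = unlist(lapply(chains, `[[`, "loglik")),
                 psrf = psrf,
                 converged = all(is.na(psrf) | psrf < 1.1),
                 max_logL = ml$logL, ml_rates = ml$rates,
                 acceptance = mean(vapply(chains, `[[`, numeric(1L),
                                          "acceptance")),
                 prior = list(kind = prior, mean = prior_mean)),
            class = "pagel_result")
}

#' @export
print.pagel_result <- function(x, ...) {
  cat("Pagel", x$model, "model:", nrow(x$draws), "merged draws\n")
  cat("  converged:", x$converged, " max PSRF:",
      if (all(is.na(x$psrf))) "NA" else format(max(x$psrf, na.rm = TRUE),
                                               digits = 4), "\n")
  print(signif(colMeans(x$draws), 3))
  invisible(x)
}

#' Stepping-stone estimate of a log marginal likelihood
#'
#' Generic power-posterior ladder: `beta_k = (k/K)^(1/0.3)` (quantiles of a
#' Beta(0.3, 1), concentrating stones near the prior), short MCMC at each
#' stone, and the stepping-stone estimator
#' `logZ = sum_k log mean_i exp((beta_{k+1} - beta_k) * logL_i)` with
#' samples drawn at stone `beta_k`. With zero free parameters the marginal
#' likelihood is the likelihood itself and is returned exactly.
#'
#' @param loglik Function of a rate vector returning the log-likelihood.
#' @param logprior Function of a rate vector returning the log prior
#'   density.
#' @param npar Number of free parameters.
#' @param n_stones Number of stones K (default 50; larger ladders reduce
#'   bias).
#' @param iters_per_stone Post-burn-in iterations per stone.
#' @param burnin_per_stone Burn-in iterations per stone (chains are warm-
#'   started from the previous stone).
#' @param seed Integer seed.
#' @param start_lr Starting log-rates (default 0).
#' @return The estimated log marginal likelihood.
#' @export
stepping_stone <- function(loglik, logprior, npar, n_stones = 50,
                           iters_per_stone = 500, burnin_per_stone = 100,
                           seed = 1, start_lr = NULL) {
  if (npar == 0L) return(loglik(numeric(0)))
  stopifnot(n_stones >= 2L)
  set.seed(seed)
  if (is.null(start_lr)) start_lr <- rep(0, npar)
  beta <- (seq(0L, n_stones) / n_stones)^(1 / 0.3)
  logz <- 0
  lr <- start_lr
  for (k in seq_len(n_stones)) {
    b_lo <- beta[k]
    b_hi <- beta[k + 1L]
    run <- .mh_power(loglik, logprior, beta = b_lo, npar = npar,
                     n_burnin = burnin_per_stone, n_iter = iters_per_stone,
                     n_thin = 1L, start_lr = lr)
    if (nrow(run$draws) == 0L) stop("degenerate stone at beta = ", b_lo)
    lr <- run$last_lr
    d <- (b_hi - b_lo) * run$loglik
    m <- max(d)
    if (!is.finite(m)) stop("degenerate stone at beta = ", b_lo)
    logz <- logz + m + log(mean(exp(d - m)))
  }
  logz
}

#' Stepping-stone marginal likelihood for a Pagel model
#'
#' @inheritParams run_pagel_mcmc
#' @inheritParams stepping_stone
#' @return The estimated log marginal likelihood of the model.
#' @export
stepping_stone_logZ <- function(tree, x, y,
                                model = c("independent", "dependent"),
                                prior = c("exponential", "uniform"),
                                prior_mean = NULL, n_stones = 50,
                                iters_per_stone = 500, seed = 1,
                                root_prior = "equal") {
  model <- match.arg(model)
  prior <- match.arg(prior)
  tmpl <- pagel_template(model)
  joint <- .joint_states(x, y)
  ml <- .pagel_ml(tree, joint, tmpl, root_prior)
  if (is.null(prior_mean)) {
    prior_mean <- min(max(mean(ml$rates), 1e-3), 100)
  }
  logprior <- .make_logprior(prior, prior_mean)
  llfun <- .mk_loglik_factory(tree, joint, tmpl, root_prior)
  stepping_stone(llfun, logprior, tmpl$n_par, n_stones = n_stones,
                 iters_per_stone = iters_per_stone, seed = seed,
                 start_lr = log(pmin(pmax(ml$rates, 1e-6), 100)))
}

#' Bayes factor from two log marginal likelihoods
#'
#' `BF = 2 (logZ_dependent - logZ_independent)`; positive values favour the
#' dependent (correlated-evolution) model.
#'
#' @param logZ_dep,logZ_ind Log marginal likelihoods.
#' @return The Bayes factor (on the 2-log scale).
#' @examples
#' bayes_factor(-100, -110)  # 20
#' @export
bayes_factor <- function(logZ_dep, logZ_ind) {
  stopifnot(is.finite(logZ_dep), is.finite(logZ_ind))
  2 * (logZ_dep - logZ_ind)
}
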