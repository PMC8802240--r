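## Matrix exponential factory: eigendecomposition fast path (one
## decomposition per Q, reused across branch lengths), with a
## scaling-and-squaring (Matrix::expm) fallback when Q is defective or
## ill-conditioned. Small negative entries from roundoff are clamped.
.expm_factory <- function(Q) {
  k <- nrow(Q)
  if (all(Q == 0)) return(function(t) diag(k))
  if (k == 2L) {
    ## closed form for a general 2-state chain
    a <- Q[1L, 2L]
    b <- Q[2L, 1L]
    s <- a + b
    return(function(t) {
      e <- exp(-s * t)
      matrix(c(b + a * e, b * (1 - e), a * (1 - e), a + b * e), 2L, 2L) / s
    })
  }
  ok <- FALSE
  E <- tryCatch(eigen(Q), error = function(e) NULL)
  if (!is.null(E)) {
    Vinv <- tryCatch(solve(E$vectors), error = function(e) NULL)
    if (!is.null(Vinv) &&
        all(is.finite(Mod(E$vectors))) && all(is.finite(Mod(Vinv))) &&
        max(Mod(Vinv)) < 1e12) {
      ok <- TRUE
    }
  }
  if (ok) {
    V <- E$vectors
    lam <- E$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vinv))
      P[P < 0] <- 0
      P[P > 1] <- 1
      P
    }
  } else {
    function(t) {
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P[P > 1] <- 1
      P
    }
  }
}

## Tip likelihood matrix (Ntip x k) from a named integer state vector
## (values 0..k-1, names = species). Every tree tip must be scored.
.tip_liks <- function(tree, states, k) {
  tips <- tree$tip.label
  if (!all(tips %in% names(states))) {
    stop("species on tree without a state: ",
         paste(utils::head(setdiff(tips, names(states)), 5L),
               collapse = ", "),
         " (prune the tree to scored species first)")
  }
  s <- states[tips]
  if (anyNA(s)) {
    stop("missing state for: ",
         paste(utils::head(tips[is.na(s)], 5L), collapse = ", "))
  }
  if (any(s < 0L | s >= k)) {
    stop("state label outside template range 0..", k - 1L)
  }
  L <- matrix(0, length(tips), k)
  L[cbind(seq_along(tips), s + 1L)] <- 1
  L
}

## Precomputed pruning context (postorder edges + tip likelihoods), so
## repeated likelihood evaluations (optimisation, MCMC) skip the per-call
## tree bookkeeping.
.mk_ctx <- function(tree, states, k) {
  post <- ape::reorder.phylo(tree, "postorder")
  list(post = post, tipL = .tip_liks(tree, states, k),
       n_tip = ape::Ntip(tree), n_all = ape::Ntip(tree) + tree$Nnode,
       k = k)
}

## Pruning likelihood on a precomputed context. The 2-state case gets a
## fully vectorised transition-probability precomputation and a scalar
## inner loop; the general case uses the expm factory.
.ctx_loglik <- function(ctx, Q, root_prior) {
  k <- ctx$k
  parents <- ctx$post$edge[, 1L]
  children <- ctx$post$edge[, 2L]
  elen <- ctx$post$edge.length
  ne <- length(elen)
  lsc <- numeric(ctx$n_all)
  if (k == 2L) {
    a <- Q[1L, 2L]
    b <- Q[2L, 1L]
    s <- a + b
    if (s == 0) {
      e <- rep(1, ne)
      p11 <- rep(1, ne); p12 <- rep(0, ne)
      p21 <- rep(0, ne); p22 <- rep(1, ne)
    } else {
      e <- exp(-s * elen)
      p11 <- (b + a * e) / s
      p12 <- (a * (1 - e)) / s
      p21 <- (b * (1 - e)) / s
      p22 <- (a + b * e) / s
    }
    L1 <- rep(1, ctx$n_all)
    L2 <- rep(1, ctx$n_all)
    L1[seq_len(ctx$n_tip)] <- ctx$tipL[, 1L]
    L2[seq_len(ctx$n_tip)] <- ctx$tipL[, 2L]
    for (i in seq_len(ne)) {
      pa <- parents[i]
      ch <- children[i]
      c1 <- L1[ch]; c2 <- L2[ch]
      L1[pa] <- L1[pa] * (p11[i] * c1 + p12[i] * c2)
      L2[pa] <- L2[pa] * (p21[i] * c1 + p22[i] * c2)
      lsc[pa] <- lsc[pa] + lsc[ch]
      m <- max(L1[pa], L2[pa])
      if (m <= 0) {
        L1[pa] <- 0; L2[pa] <- 0
      } else if (m < 1e-280) {
        L1[pa] <- L1[pa] / m; L2[pa] <- L2[pa] / m
        lsc[pa] <- lsc[pa] + log(m)
      }
    }
    root <- parents[ne]
    prior <- .root_prior_vec(root_prior, Q, ctx$tipL)
    lik <- prior[1L] * L1[root] + prior[2L] * L2[root]
    if (lik <= 0) return(-Inf)
    return(log(lik) + lsc[root])
  }
  pfun <- .expm_factory(Q)
  L <- matrix(1, ctx$n_all, k)
  L[seq_len(ctx$n_tip), ] <- ctx$tipL
  for (i in seq_len(ne)) {
    pa <- parents[i]
    ch <- children[i]
    L[pa, ] <- L[pa, ] * as.vector(pfun(elen[i]) %*% L[ch, ])
    lsc[pa] <- lsc[pa] + lsc[ch]
    m <- max(L[pa, ])
    if (m <= 0) {
      L[pa, ] <- 0
    } else if (m < 1e-280) {
      L[pa, ] <- L[pa, ] / m
      lsc[pa] <- lsc[pa] + log(m)
    }
  }
  root <- parents[ne]
  prior <- .root_prior_vec(root_prior, Q, ctx$tipL)
  lik <- sum(prior * L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + lsc[root]
}

## Closure evaluating the Mk log-likelihood as a function of the rate
## vector, with the tree bookkeeping done once.
.mk_loglik_factory <- function(tree, states, template, root_prior) {
  ctx <- .mk_ctx(tree, states[tree$tip.label], template$n_states)
  function(rates) .ctx_loglik(ctx, mk_Q(template, rates), root_prior)
}

## Felsenstein pruning up-pass. Returns per-node partial likelihoods
## (rescaled rows) plus the per-node log scaling factors, the postorder edge
## table, and the per-edge transition matrices — everything both the
## likelihood and the stochastic-mapping down-pass need.
.mk_partials <- function(tree, tip_liks, Q) {
  k <- ncol(tip_liks)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  pfun <- .expm_factory(Q)
  ne <- nrow(post$edge)
  P <- vector("list", ne)
  L <- matrix(1, n_all, k)
  L[seq_len(n_tip), ] <- tip_liks
  lsc <- numeric(n_all)
  for (i in seq_len(ne)) {
    parent <- post$edge[i, 1L]
    child <- post$edge[i, 2L]
    P[[i]] <- pfun(post$edge.length[i])
    contrib <- as.vector(P[[i]] %*% L[child, ])
    L[parent, ] <- L[parent, ] * contrib
    lsc[parent] <- lsc[parent] + lsc[child]
    m <- max(L[parent, ])
    if (m <= 0) {
      ## impossible data under this Q (forbidden transitions): likelihood 0
      L[parent, ] <- 0
    } else if (m < 1e-280) {
      L[parent, ] <- L[parent, ] / m
      lsc[parent] <- lsc[parent] + log(m)
    }
  }
  root <- post$edge[ne, 1L]
  list(post = post, P = P, L = L, lsc = lsc, root = root)
}

## Root prior vector for a fitted/assembled Q
.root_prior_vec <- function(root_prior, Q, tip_liks) {
  k <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("equal", "stationary", "observed")),
    equal = rep(1 / k, k),
    stationary = {
      ## left null vector of Q; fall back to equal for reducible chains
      ns <- tryCatch({
        A <- rbind(t(Q), rep(1, k))
        b <- c(rep(0, k), 1)
        pi <- qr.solve(A, b)
        if (any(pi < -1e-8)) NULL else pmax(pi, 0) / sum(pmax(pi, 0))
      }, error = function(e) NULL)
      if (is.null(ns)) rep(1 / k, k) else ns
    },
    observed = {
      f <- colSums(tip_liks)
      f / sum(f)
    }
  )
}

#' Mk log-likelihood of tip states on a tree
#'
#' Computes the log probability of the observed tip states under a
#' continuous-time Markov model with rate matrix built from `template` and
#' `rates`, integrating over all internal-node states by Felsenstein's
#' pruning algorithm (post-order, with per-branch transition matrices
#' `expm(Q t)`), and combining root states under the chosen prior.
#' Multifurcating nodes are handled directly.
#'
#' @param tree A `phylo` object whose tips are all scored.
#' @param states Named integer vector (values `0..k-1`, names = species).
#' @param template An `mk_template` from [build_template()].
#' @param rates Non-negative rates, one per free template parameter.
#' @param root_prior `"equal"` (default), `"stationary"`, `"observed"`, or a
#'   numeric probability vector of length k.
#' @return The log-likelihood (scalar; `-Inf` if the data are impossible
#'   under a constrained template).
#' @examples
#' tr <- read_tree("(A:1,B:1);")
#' tmpl <- build_template("ER", 2)
#' mk_loglik(tr, c(A = 0L, B = 0L), tmpl, rates = 0.5)
#' @export
mk_loglik <- function(tree, states, template, rates, root_prior = "equal") {
  ctx <- .mk_ctx(tree, states, template$n_states)
  .ctx_loglik(ctx, mk_Q(template, rates), root_prior)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of species).
#' @return The AICc value.
#' @examples
#' aicc(-46.2, 1, 127)  # 94.43
#' @export
aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0) {
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  }
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`.
#'
#' @param aicc_values Numeric vector (may contain `Inf` for failed models).
#' @return Weights summing to 1.
#' @examples
#' round(aicc_weights(c(98.2, 94.4, 95.5)), 3)
#' @export
aicc_weights <- function(aicc_values) {
  stopifnot(any(is.finite(aicc_values)))
  d <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-d / 2)
  w[!is.finite(aicc_values)] <- 0
  w / sum(w)
}

#' Maximum-likelihood fit of a constrained Mk model
#'
#' Rates are optimised on the log scale (box-constrained quasi-Newton via
#' [stats::nlminb()]) from multiple seeded starting points jittered around a
#' parsimony-flavoured heuristic rate. Boundary MLEs (rates indistinguishable
#' from 0) are reported as-is, not clamped away.
#'
#' @inheritParams mk_loglik
#' @param n_starts Number of optimisation restarts (default 10).
#' @param seed Integer seed controlling the restart jitter.
#' @return An `mk_fit`: list with `template`, `rates` (named by transition),
#'   `logL`, `k` (free parameters), `n` (species), `aicc`, `root_prior` and
#'   `convergence`.
#' @export
fit_mk <- function(tree, states, template, root_prior = "equal",
                   n_starts = 10, seed = 1) {
  states <- states[tree$tip.label]
  n_obs_states <- length(unique(states))
  if (n_obs_states < 2L) {
    warning("fewer than 2 distinct observed states; fit is degenerate")
  }
  n <- ape::Ntip(tree)
  npar <- template$n_par
  total_len <- sum(tree$edge.length)
  q0 <- max(n_obs_states, 2L) / max(total_len, .Machine$double.eps)

  llfun <- .mk_loglik_factory(tree, states, template, root_prior)
  negll <- function(lr) {
    v <- -llfun(exp(lr))
    if (!is.finite(v)) 1e10 else v
  }
  set.seed(seed)
  best <- NULL
  ok <- FALSE
  for (s in seq_len(n_starts)) {
    start <- log(q0) + stats::rnorm(npar, 0, if (s == 1L) 0 else 1.5)
    fit <- tryCatch(
      stats::nlminb(start, negll, lower = rep(-20, npar),
                    upper = rep(10, npar)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
    ## "false/singular convergence" is nlminb's usual report at a boundary
    ## MLE (a rate on the zero bound) or on a locally flat likelihood; the
    ## estimate is still the optimum when several starts agree, so these
    ## count as converged
    msg <- if (is.null(fit$message)) "" else fit$message
    if (fit$convergence == 0L ||
        grepl("false convergence|singular convergence", msg)) {
      ok <- TRUE
    }
  }
  if (is.null(best)) stop("Mk optimisation failed from every start")
  if (!ok) {
    warning("optimizer did not report convergence; returning best-so-far")
  }
  rates <- exp(best$par)
  names(rates) <- template_par_labels(template)
  structure(list(template = template, rates = rates,
                 logL = -best$objective, k = npar, n = n,
                 aicc = if (n > npar + 1L) aicc(-best$objective, npar, n)
                        else NA_real_,
                 root_prior = root_prior,
                 convergence = ok),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit:", x$template$name, "(", x$template$n_states, "states )\n")
  cat("  logL =", format(x$logL, digits = 6),
      " AICc =", format(x$aicc, digits = 6),
      " k =", x$k, " n =", x$n, "\n")
  cat("  rates:\n")
  print(signif(x$rates, 4))
  invisible(x)
}

#' Fit and rank a set of Mk models by AICc
#'
#' Fits each named model to the same data, then tabulates log-likelihood,
#' AICc, delta-AICc and Akaike weights, sorted by AICc. Models whose weight
#' exceeds `map_threshold` are flagged for stochastic character mapping.
#'
#' @inheritParams fit_mk
#' @param models Character vector of template names (see [build_template()]).
#' @param map_threshold Weight above which a model is flagged for mapping
#'   (default 0.15).
#' @return A list of class `mk_comparison`: `table` (data.frame with columns
#'   `model`, `dfs`, `logL`, `AICc`, `dAICc`, `AICcw`, `map`) and `fits`
#'   (named list of `mk_fit` objects).
#' @export
compare_models <- function(tree, states, models, root_prior = "equal",
                           n_starts = 10, seed = 1, map_threshold = 0.15) {
  n_states <- max(states, na.rm = TRUE) + 1L
  fits <- lapply(models, function(m) {
    fit_mk(tree, states, build_template(m, n_states), root_prior,
           n_starts = n_starts, seed = seed)
  })
  names(fits) <- models
  tab <- data.frame(
    model = models,
    dfs = vapply(fits, function(f) f$k, integer(1L)),
    logL = vapply(fits, function(f) f$logL, numeric(1L)),
    AICc = vapply(fits, function(f) f$aicc, numeric(1L)),
    stringsAsFactors = FALSE
  )
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$AICcw <- aicc_weights(tab$AICc)
  tab$map <- tab$AICcw > map_threshold
  ord <- order(tab$AICc)
  structure(list(table = tab[ord, , drop = FALSE], fits = fits),
            class = "mk_comparison")
}

#' @export
print.mk_comparison <- function(x, ...) {
  cat("Mk model comparison (", nrow(x$table), "models )\n")
  tab <- x$table
  tab$logL <- round(tab$logL, 2)
  tab$AICc <- round(tab$AICc, 2)
  tab$dAICc <- round(tab$dAICc, 2)
  tab$AICcw <- round(tab$AICcw, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
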