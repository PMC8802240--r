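#' Sample Mk rate matrices from their posterior
#'
#' Metropolis-Hastings sampling of the free rates of a constrained Mk
#' template, targeting `likelihood x prior` with independent gamma priors on
#' each free rate (default shape = 1, rate = 1, i.e. a prior favouring a low
#' rate of transitions). Proposals are multiplicative log-normal per-rate
#' updates whose scale is auto-tuned during burn-in to a 20-40% acceptance
#' rate.
#'
#' @inheritParams mk_loglik
#' @param prior_shape,prior_rate Gamma prior parameters (alpha, beta).
#' @param n_burnin,n_iter,n_thin Chain settings: burn-in iterations,
#'   post-burn-in iterations, thinning interval. Defaults follow common
#'   practice for stochastic mapping (10,000 / 10,000 / 10, retaining 1000
#'   draws); use smaller values for quick exploratory runs.
#' @param seed Integer seed (mandatory; chains are reproducible).
#' @return A `q_posterior`: list with `draws` (kept draws x free rates),
#'   `template`, `acceptance`, `prior` and `settings`.
#' @export
sample_q_posterior <- function(tree, states, template,
                               prior_shape = 1, prior_rate = 1,
                               n_burnin = 10000, n_iter = 10000, n_thin = 10,
                               seed = 1, root_prior = "equal") {
  set.seed(seed)
  npar <- template$n_par
  states <- states[tree$tip.label]
  llfun <- .mk_loglik_factory(tree, states, template, root_prior)
  ## posterior density of log-rates (includes the Jacobian of the log map)
  logpost <- function(lr) {
    r <- exp(lr)
    ll <- llfun(r)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dgamma(r, shape = prior_shape, rate = prior_rate,
                           log = TRUE)) + sum(lr)
  }
  ## start at a crude ML-ish rate
  lr <- rep(log(max(2, length(unique(states))) /
                  max(sum(tree$edge.length), .Machine$double.eps)), npar)
  lp <- logpost(lr)
  if (!is.finite(lp)) {
    lr <- rep(0, npar)
    lp <- logpost(lr)
  }
  scale <- rep(0.5, npar)
  acc <- rep(0L, npar)
  tune_acc <- rep(0L, npar)
  tune_n <- 0L
  n_keep <- floor(n_iter / n_thin)
  draws <- matrix(NA_real_, n_keep, npar)
  colnames(draws) <- template_par_labels(template)
  kept <- 0L
  total_acc <- 0L
  for (it in seq_len(n_burnin + n_iter)) {
    for (p in seq_len(npar)) {
      prop <- lr
      prop[p] <- prop[p] + stats::rnorm(1L, 0, scale[p])
      lp_new <- logpost(prop)
      if (is.finite(lp_new) && log(stats::runif(1L)) < lp_new - lp) {
        lr <- prop
        lp <- lp_new
        acc[p] <- acc[p] + 1L
        if (it <= n_burnin) tune_acc[p] <- tune_acc[p] + 1L
        if (it > n_burnin) total_acc <- total_acc + 1L
      }
    }
    if (it <= n_burnin) {
      tune_n <- tune_n + 1L
      if (tune_n == 100L) {  # retune every 100 burn-in sweeps
        rate <- tune_acc / 100
        scale <- scale * ifelse(rate < 0.2, 0.7, ifelse(rate > 0.4, 1.4, 1))
        scale <- pmin(pmax(scale, 1e-3), 10)
        tune_acc[] <- 0L
        tune_n <- 0L
      }
      if (it == n_burnin && sum(acc) == 0L) {
        stop("no accepted moves during burn-in; adjust the proposal scale ",
             "or check the data/template")
      }
    } else if ((it - n_burnin) %% n_thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- exp(lr)
    }
  }
  structure(list(draws = draws, template = template,
                 acceptance = total_acc / (n_iter * npar),
                 prior = c(shape = prior_shape, rate = prior_rate),
                 settings = list(n_burnin = n_burnin, n_iter = n_iter,
                                 n_thin = n_thin, seed = seed,
                                 root_prior = root_prior)),
            class = "q_posterior")
}

#' @export
print.q_posterior <- function(x, ...) {
  cat("Posterior sample of Mk rates (", nrow(x$draws), "draws,",
      x$template$name, "template )\n")
  cat("  acceptance:", format(x$acceptance, digits = 3),
      " gamma prior (", x$prior["shape"], ",", x$prior["rate"], ")\n")
  print(signif(colMeans(x$draws), 4))
  invisible(x)
}

## Uniformization sampler for one branch: a state path conditional on the
## endpoint pair (a, b), branch length t, and rate matrix Q. Returns a
## two-column matrix (state, segment length); adjacent segments differ.
## `Rpow` is a mutable cache of powers of the uniformized kernel.
.sample_branch_path <- function(a, b, t, Q, Omega, R, Rpow, P_ab) {
  k <- nrow(Q)
  if (Omega <= 0) {
    if (a != b) stop("impossible endpoint pair on a zero-rate chain")
    return(cbind(state = a, length = t))
  }
  if (P_ab <= 0) {
    stop("conditionally impossible endpoint pair (", a - 1L, " -> ", b - 1L,
         ") under this rate matrix")
  }
  getR <- function(n) {  # R^n with caching (n >= 0)
    while (length(Rpow$p) < n + 1L) {
      Rpow$p[[length(Rpow$p) + 1L]] <- Rpow$p[[length(Rpow$p)]] %*% R
    }
    Rpow$p[[n + 1L]]
  }
  ## number of uniformized jumps: P(N = n) = dpois(n, Omega t) R^n[a,b] / P_ab
  u <- stats::runif(1L) * P_ab
  n <- -1L
  cum <- 0
  repeat {
    n <- n + 1L
    cum <- cum + stats::dpois(n, Omega * t) * getR(n)[a, b]
    if (cum >= u || n > 5000L) break
  }
  if (n == 0L) return(cbind(state = a, length = t))
  ## states at the jump epochs (forward filtering with the remaining-steps
  ## backward term), then collapse virtual self-transitions
  s <- integer(n + 1L)
  s[1L] <- a
  s[n + 1L] <- b
  if (n > 1L) {
    for (i in 2L:n) {
      back <- getR(n + 1L - i)[, b]
      w <- R[s[i - 1L], ] * back
      s[i] <- sample.int(k, 1L, prob = w)
    }
  }
  times <- c(0, sort(stats::runif(n)) * t, t)
  keep_state <- s[1L]
  states_out <- integer(0)
  lens_out <- numeric(0)
  seg_start <- 0
  for (i in seq_len(n)) {
    if (s[i + 1L] != keep_state) {
      states_out <- c(states_out, keep_state)
      lens_out <- c(lens_out, times[i + 1L] - seg_start)
      seg_start <- times[i + 1L]
      keep_state <- s[i + 1L]
    }
  }
  states_out <- c(states_out, keep_state)
  lens_out <- c(lens_out, t - seg_start)
  cbind(state = states_out, length = lens_out)
}

#' Simulate one stochastic character history conditional on tip states
#'
#' Draws a complete history (state along every branch) from the distribution
#' of histories given the tip data and rate matrix `Q`: a pruning down-pass
#' computes partial likelihoods, internal-node states are drawn from their
#' joint conditional distribution on a pre-order up-pass, and each branch
#' path is then drawn conditional on its endpoint states by uniformization
#' (exact conditional sampling of the jump chain).
#'
#' @inheritParams mk_loglik
#' @param Q Rate matrix (k x k, rows summing to zero), e.g. one posterior
#'   draw assembled with [mk_Q()].
#' @param seed Optional integer seed.
#' @return A `character_history`: list with `edge` (postorder edge matrix),
#'   `edge.length`, `paths` (per-edge matrices of `(state, length)` segments,
#'   0-based states), `node_states` (0-based, all nodes incl. tips),
#'   `tip_states` (named) and `n_tip`.
#' @export
simulate_history <- function(tree, states, Q, root_prior = "equal",
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Q)
  tl <- .tip_liks(tree, states, k)
  pr <- .mk_partials(tree, tl, Q)
  prior <- .root_prior_vec(root_prior, Q, tl)
  post <- pr$post
  ne <- nrow(post$edge)
  n_all <- ape::Ntip(tree) + tree$Nnode
  node_state <- integer(n_all)  # 1-based internally
  w_root <- prior * pr$L[pr$root, ]
  if (sum(w_root) <= 0) stop("tip data impossible under this rate matrix")
  node_state[pr$root] <- sample.int(k, 1L, prob = w_root)
  ## pre-order: reverse postorder visits parents before children
  for (i in rev(seq_len(ne))) {
    parent <- post$edge[i, 1L]
    child <- post$edge[i, 2L]
    w <- pr$P[[i]][node_state[parent], ] * pr$L[child, ]
    if (sum(w) <= 0) stop("conditionally impossible node state")
    node_state[child] <- sample.int(k, 1L, prob = w)
  }
  Omega <- max(-diag(Q))
  R <- if (Omega > 0) diag(k) + Q / Omega else diag(k)
  Rpow <- new.env()
  Rpow$p <- list(diag(k))
  paths <- vector("list", ne)
  for (i in seq_len(ne)) {
    a <- node_state[post$edge[i, 1L]]
    b <- node_state[post$edge[i, 2L]]
    seg <- .sample_branch_path(a, b, post$edge.length[i], Q, Omega, R, Rpow,
                               pr$P[[i]][a, b])
    seg[, "state"] <- seg[, "state"] - 1L  # back to 0-based states
    paths[[i]] <- seg
  }
  tip_states <- node_state[seq_len(ape::Ntip(tree))] - 1L
  names(tip_states) <- tree$tip.label
  structure(list(edge = post$edge, edge.length = post$edge.length,
                 paths = paths, node_states = node_state - 1L,
                 tip_states = tip_states, n_tip = ape::Ntip(tree),
                 n_states = k),
            class = "character_history")
}

#' @export
print.character_history <- function(x, ...) {
  cat("Character history:", x$n_tip, "tips,", x$n_states, "states,",
      sum(count_transitions(x)), "transitions\n")
  invisible(x)
}

#' Count transitions in one character history
#'
#' @param history A `character_history`.
#' @return k x k integer matrix of ordered transition counts (row = from
#'   state, column = to state, 0-based labels).
#' @export
count_transitions <- function(history) {
  k <- history$n_states
  cnt <- matrix(0L, k, k,
                dimnames = list(as.character(0:(k - 1L)),
                                as.character(0:(k - 1L))))
  for (seg in history$paths) {
    s <- seg[, "state"]
    if (length(s) > 1L) {
      for (i in seq_len(length(s) - 1L)) {
        cnt[s[i] + 1L, s[i + 1L] + 1L] <- cnt[s[i] + 1L, s[i + 1L] + 1L] + 1L
      }
    }
  }
  cnt
}

#' Run stochastic character mapping
#'
#' Convenience wrapper: sample rate matrices from their posterior
#' ([sample_q_posterior()]), then simulate one conditional history per
#' retained draw (cycling over draws if `n_maps` exceeds the number of
#' draws).
#'
#' @inheritParams sample_q_posterior
#' @param n_maps Number of histories to reconstruct (default: one per
#'   retained posterior draw).
#' @return List with `histories` (list of `character_history`) and
#'   `posterior` (the `q_posterior`).
#' @export
map_character <- function(tree, states, template,
                          prior_shape = 1, prior_rate = 1,
                          n_burnin = 10000, n_iter = 10000, n_thin = 10,
                          n_maps = NULL, seed = 1, root_prior = "equal") {
  qp <- sample_q_posterior(tree, states, template, prior_shape, prior_rate,
                           n_burnin, n_iter, n_thin, seed, root_prior)
  nd <- nrow(qp$draws)
  if (is.null(n_maps)) n_maps <- nd
  histories <- vector("list", n_maps)
  for (i in seq_len(n_maps)) {
    Q <- mk_Q(template, qp$draws[((i - 1L) %% nd) + 1L, ])
    histories[[i]] <- simulate_history(tree, states, Q, root_prior)
  }
  list(histories = histories, posterior = qp)
}

#' Summarise a sample of stochastic maps
#'
#' Aggregates transition counts (mean and empirical 2.5% / 97.5% quantiles,
#' per ordered state pair and in total) and per-node state posterior
#' probabilities (the frequency of each state at each node across
#' histories).
#'
#' @param histories List of `character_history` objects on the same tree.
#' @return A `mapping_summary`: list with `node_posterior` (nodes x states,
#'   rows sum to 1; tip rows first), `transitions` (data.frame `from`, `to`,
#'   `mean`, `q2.5`, `q97.5`), `total` (named vector), `counts` (histories x
#'   ordered-pair count matrix), `n_maps`, `n_tip`, `tip_labels`, `edge`.
#' @export
summarize_maps <- function(histories) {
  stopifnot(length(histories) >= 1L)
  h1 <- histories[[1L]]
  for (h in histories) {
    if (!identical(dim(h$edge), dim(h1$edge)) ||
        !identical(h$edge, h1$edge) || h$n_states != h1$n_states) {
      stop("histories are not all on the same tree")
    }
  }
  k <- h1$n_states
  n_all <- max(h1$edge)
  nh <- length(histories)
  pairs <- which(matrix(TRUE, k, k) & !diag(k) > 0, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  pair_names <- sprintf("%d->%d", pairs[, 1L] - 1L, pairs[, 2L] - 1L)
  counts <- matrix(0L, nh, nrow(pairs), dimnames = list(NULL, pair_names))
  node_post <- matrix(0, n_all, k,
                      dimnames = list(NULL, as.character(0:(k - 1L))))
  for (i in seq_len(nh)) {
    cm <- count_transitions(histories[[i]])
    counts[i, ] <- cm[pairs]
    node_post[cbind(seq_len(n_all), histories[[i]]$node_states + 1L)] <-
      node_post[cbind(seq_len(n_all), histories[[i]]$node_states + 1L)] + 1
  }
  node_post <- node_post / nh
  q <- function(x, p) as.numeric(stats::quantile(x, p, type = 1L))
  transitions <- data.frame(
    from = pairs[, 1L] - 1L, to = pairs[, 2L] - 1L,
    mean = colMeans(counts),
    q2.5 = apply(counts, 2L, q, 0.025),
    q97.5 = apply(counts, 2L, q, 0.975),
    row.names = NULL)
  tot <- rowSums(counts)
  structure(list(node_posterior = node_post, transitions = transitions,
                 total = c(mean = mean(tot), q2.5 = q(tot, 0.025),
                           q97.5 = q(tot, 0.975)),
                 counts = counts, n_maps = nh, n_tip = h1$n_tip,
                 tip_labels = names(h1$tip_states), edge = h1$edge),
            class = "mapping_summary")
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat("Stochastic-map summary over", x$n_maps, "histories\n")
  cat("  total changes:", round(x$total["mean"], 1), "(",
      x$total["q2.5"], ",", x$total["q97.5"], ")\n")
  print(transform(x$transitions, mean = round(mean, 1)), row.names = FALSE)
  invisible(x)
}

#' Lower bound on the number of independent origins of a derived state
#'
#' A deliberately conservative counting rule: two occurrences of the derived
#' state are accepted as independent origins only if the node path between
#' them passes through at least one node whose posterior probability of the
#' ancestral state exceeds `threshold`; otherwise they are merged into a
#' single origin. Concretely: (1) every tip/node whose summarised (majority)
#' state is the derived state is marked; (2) marked vertices are grouped
#' into connected patches, and patches are merged whenever the path between
#' them contains no high-confidence ancestral node; (3) the merged groups
#' are counted. The separating node reported for each surviving pair of
#' groups makes every non-merge auditable.
#'
#' Because the ancestral state at the root is often uncertain, the count is
#' also reported excluding root-adjacent origins (groups whose path to the
#' root never crosses a high-confidence ancestral node).
#'
#' @param summary A `mapping_summary`.
#' @param tree The tree the maps were simulated on.
#' @param derived,ancestral 0-based state labels.
#' @param threshold Posterior-probability cutoff in `(0.5, 1]` (default
#'   0.95).
#' @return List with `count`, `count_excluding_root_adjacent`, `groups`
#'   (list of vertex-id vectors), `separators` (data.frame of group pairs
#'   and one separating high-confidence node each).
#' @export
lower_bound_origins <- function(summary, tree, derived, ancestral,
                                threshold = 0.95) {
  stopifnot(threshold > 0.5, threshold <= 1)
  np <- summary$node_posterior
  n_all <- nrow(np)
  n_tip <- summary$n_tip
  ## majority state per vertex (ties broken toward the lower state index)
  maj <- max.col(np, ties.method = "first") - 1L
  derived_set <- which(maj == derived)
  if (length(derived_set) == 0L) {
    return(list(count = 0L, count_excluding_root_adjacent = 0L,
                groups = list(),
                separators = data.frame(group_a = integer(0),
                                        group_b = integer(0),
                                        node = integer(0))))
  }
  strong <- which(np[, as.character(ancestral)] > threshold)
  ## parent pointers (0 = root)
  parent <- integer(n_all)
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  }
  root <- which(parent == 0L & seq_len(n_all) > n_tip)
  if (length(root) == 0L) root <- which(parent == 0L)[1L]
  path_to_root <- function(v) {
    p <- v
    while (parent[v] != 0L) {
      v <- parent[v]
      p <- c(p, v)
    }
    p
  }
  path_between <- function(u, v) {
    pu <- path_to_root(u)
    pv <- path_to_root(v)
    common <- intersect(pu, pv)
    mrca <- common[1L]  # paths are ordered leaf-to-root
    c(pu[seq_len(match(mrca, pu))], rev(pv[seq_len(match(mrca, pv) - 1L)]))
  }
  ## initial patches: connected components of the derived-majority subgraph
  in_set <- logical(n_all)
  in_set[derived_set] <- TRUE
  comp <- integer(n_all)
  nc <- 0L
  adj <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge))) {
    a <- tree$edge[i, 1L]; b <- tree$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  for (v in derived_set) {
    if (comp[v] == 0L) {
      nc <- nc + 1L
      queue <- v
      comp[v] <- nc
      while (length(queue) > 0L) {
        u <- queue[[1L]]
        queue <- queue[-1L]
        for (w in adj[[u]]) {
          if (in_set[w] && comp[w] == 0L) {
            comp[w] <- nc
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  groups <- split(which(comp > 0L), comp[comp > 0L])
  ## representative: the shallowest vertex of each patch
  depth <- node_depths(tree)
  reps <- vapply(groups, function(g) g[which.min(depth[g])], integer(1L))
  ## union-find merge when no strong ancestral node separates two patches
  uf <- seq_along(groups)
  find <- function(i) { while (uf[i] != i) i <- uf[i]; i }
  sep_node <- matrix(NA_integer_, length(groups), length(groups))
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      pb <- path_between(reps[i], reps[j])
      inter <- setdiff(pb, c(groups[[i]], groups[[j]]))
      strong_on_path <- intersect(inter, strong)
      if (length(strong_on_path) == 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) uf[ri] <- rj
      } else {
        sep_node[i, j] <- strong_on_path[1L]
      }
    }
  }
  final <- vapply(seq_along(groups), find, integer(1L))
  merged <- lapply(unique(final), function(f) {
    sort(unlist(groups[final == f], use.names = FALSE))
  })
  ## separators between surviving (distinct) merged groups
  seps <- data.frame(group_a = integer(0), group_b = integer(0),
                     node = integer(0))
  uf_ids <- unique(final)
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      if (find(i) != find(j) && !is.na(sep_node[i, j])) {
        seps <- rbind(seps, data.frame(
          group_a = match(find(i), uf_ids),
          group_b = match(find(j), uf_ids),
          node = sep_node[i, j]))
      }
    }
  }
  ## root-adjacent: no strong ancestral node between the group and the root
  root_adj <- vapply(merged, function(g) {
    rep_v <- g[which.min(depth[g])]
    pb <- setdiff(path_to_root(rep_v), g)
    length(intersect(pb, strong)) == 0L
  }, logical(1L))
  list(count = length(merged),
       count_excluding_root_adjacent = sum(!root_adj),
       groups = merged,
       separators = unique(seps))
}
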