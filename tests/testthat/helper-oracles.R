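# Independent oracles used across the suite.

# Exhaustive-enumeration Mk likelihood: sums the joint probability over all
# internal-node state assignments. Feasible only for tiny trees; stays
# independent of the pruning code path (it never calls .ctx_loglik).
enum_loglik <- function(tree, states, Q, prior) {
  k <- nrow(Q)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  P <- lapply(seq_len(nrow(post$edge)), function(i) {
    as.matrix(Matrix::expm(Q * post$edge.length[i]))
  })
  internals <- (n_tip + 1L):n_all
  root <- post$edge[nrow(post$edge), 1L]
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asn <- integer(n_all)
    asn[seq_len(n_tip)] <- states[tree$tip.label] + 1L
    asn[internals] <- grid[g, ]
    p <- prior[asn[root]]
    for (i in seq_len(nrow(post$edge))) {
      p <- p * P[[i]][asn[post$edge[i, 1L]], asn[post$edge[i, 2L]]]
    }
    tot <- tot + p
  }
  log(tot)
}

# Random small test instance: tree, template, rates, states
random_mk_instance <- function(n_tips, n_states, seed) {
  set.seed(seed)
  tree <- ape::rphylo(n_tips, 1, 0)
  template_name <- sample(
    if (n_states == 2L) c("ER", "ARD", "Dollo")
    else c("ER", "SYM", "ARD", "ORD", "ORD-Dollo", "Dollo"), 1L)
  template <- build_template(template_name, n_states)
  rates <- stats::runif(template$n_par, 0.1, 2)
  states <- stats::setNames(sample(0:(n_states - 1L), n_tips, TRUE),
                            tree$tip.label)
  list(tree = tree, template = template, rates = rates, states = states)
}

# Build a mapping_summary by hand (for the origin-rule unit tests)
fake_summary <- function(node_posterior, tree) {
  structure(list(node_posterior = node_posterior,
                 n_tip = ape::Ntip(tree),
                 tip_labels = tree$tip.label,
                 edge = tree$edge, n_maps = 1L),
            class = "mapping_summary")
}
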