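test_that("posterior sampling is reproducible under a fixed seed", {
  tr <- simulate_tree(30, seed = 2)
  sim <- simulate_discrete(tr, build_template("ER", 2), 1, root_state = 1,
                           seed = 3)
  qp1 <- sample_q_posterior(tr, sim$tip_states, build_template("ER", 2),
                            n_burnin = 200, n_iter = 400, n_thin = 4,
                            seed = 7)
  qp2 <- sample_q_posterior(tr, sim$tip_states, build_template("ER", 2),
                            n_burnin = 200, n_iter = 400, n_thin = 4,
                            seed = 7)
  expect_identical(qp1$draws, qp2$draws)
  expect_true(all(qp1$draws > 0))
})

test_that("posterior mean recovers the generating rate on a large tree", {
  tr <- simulate_tree(150, seed = 4)
  tr$edge.length <- tr$edge.length * 2
  sim <- simulate_discrete(tr, build_template("ER", 2), 1, root_state = 1,
                           seed = 5)
  qp <- sample_q_posterior(tr, sim$tip_states, build_template("ER", 2),
                           n_burnin = 600, n_iter = 1500, n_thin = 5,
                           seed = 1)
  expect_lt(abs(mean(qp$draws) - 1), 0.3)
})

test_that("a zero-rate matrix yields a constant history", {
  tr <- simulate_tree(10, seed = 6)
  st <- setNames(rep(1L, 10), tr$tip.label)
  Q <- matrix(0, 2, 2)
  h <- simulate_history(tr, st, Q, seed = 1)
  expect_equal(sum(count_transitions(h)), 0)
  expect_true(all(vapply(h$paths, nrow, integer(1L)) == 1L))
})

test_that("simulated histories always reproduce the observed tip states", {
  tr <- simulate_tree(15, seed = 8)
  sim <- simulate_discrete(tr, build_template("ER", 3), 0.8, root_state = 2,
                           seed = 9)
  Q <- mk_Q(build_template("ER", 3), 0.8)
  set.seed(10)
  for (i in 1:50) {
    h <- simulate_history(tr, sim$tip_states, Q)
    expect_identical(h$tip_states[names(sim$tip_states)], sim$tip_states)
    # segment lengths on each edge sum to the edge length
    lens <- vapply(seq_along(h$paths),
                   function(j) sum(h$paths[[j]][, "length"]), numeric(1L))
    expect_equal(lens, h$edge.length, tolerance = 1e-9)
  }
})

test_that("single-branch conditional change counts match the uniformized
          chain's analytic expectation", {
  q <- 0.9
  t <- 1.4
  Q <- mk_Q(build_template("ER", 2), q)
  Omega <- q
  R <- diag(2) + Q / Omega
  Rpow <- new.env()
  Rpow$p <- list(diag(2))
  P <- phylosyndrome:::.expm_factory(Q)(t)
  set.seed(3)
  n <- 2e4
  nch <- replicate(n, nrow(phylosyndrome:::.sample_branch_path(
    1L, 1L, t, Q, Omega, R, Rpow, P[1, 1])) - 1L)
  # for a symmetric binary chain the uniformized jump chain has zero
  # diagonal, so jumps are true changes: E[N | X0 = Xt = 0] has a series
  # form over even jump counts
  m <- 0:200
  EN <- sum(m * dpois(m, Omega * t) * (m %% 2 == 0)) / P[1, 1]
  expect_lt(abs(mean(nch) - EN), 3 * sd(nch) / sqrt(n))
})

test_that("map summaries aggregate counts and node posteriors coherently", {
  tr <- simulate_tree(12, seed = 11)
  sim <- simulate_discrete(tr, build_template("ER", 2), 1.5, root_state = 1,
                           seed = 12)
  Q <- mk_Q(build_template("ER", 2), 1.5)
  set.seed(13)
  hs <- lapply(1:200, function(i) simulate_history(tr, sim$tip_states, Q))
  sm <- summarize_maps(hs)
  # ordered-pair counts sum to the per-draw totals and means to the mean
  per_draw_totals <- vapply(hs, function(h) sum(count_transitions(h)),
                            integer(1L))
  expect_equal(unname(rowSums(sm$counts)), per_draw_totals)
  expect_equal(sum(sm$transitions$mean), unname(sm$total["mean"]),
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(sm$node_posterior) - 1) < 1e-12))
  # quantiles are integer-valued and ordered
  expect_equal(sm$transitions$q2.5, round(sm$transitions$q2.5))
  expect_true(all(sm$transitions$q2.5 <= sm$transitions$q97.5))
  # single history: degenerate intervals at the observed counts
  s1 <- summarize_maps(hs[1])
  expect_equal(s1$transitions$q2.5, s1$transitions$mean)
  expect_equal(s1$transitions$q97.5, s1$transitions$mean)
  # mixed trees are rejected
  tr2 <- simulate_tree(13, seed = 14)
  other <- simulate_discrete(tr2, build_template("ER", 2), 1,
                             root_state = 1, seed = 15)
  h2 <- simulate_history(tr2, other$tip_states, Q)
  expect_error(summarize_maps(list(hs[[1]], h2)), "same tree")
})

test_that("node posteriors from maps agree with independent marginal
          ancestral-state reconstruction", {
  tr <- simulate_tree(20, seed = 5)
  sim <- simulate_discrete(tr, build_template("ER", 2), 1.2, root_state = 1,
                           seed = 6)
  st <- sim$tip_states
  Q <- mk_Q(build_template("ER", 2), 1.2)
  set.seed(2)
  n <- 600
  hs <- lapply(seq_len(n), function(i) simulate_history(tr, st, Q))
  sm <- summarize_maps(hs)
  qm <- phytools::as.Qmatrix(matrix(c(-1.2, 1.2, 1.2, -1.2), 2, 2,
                                    dimnames = list(0:1, 0:1)))
  fit <- phytools::fitMk(tr, setNames(as.character(st), names(st)),
                         fixedQ = qm, pi = "equal")
  anc <- phytools::ancr(fit)$ace
  ours <- sm$node_posterior[(ape::Ntip(tr) + 1):(ape::Ntip(tr) + tr$Nnode), ]
  tol <- pmax(3 * sqrt(anc * (1 - anc) / n), 0.02)
  expect_true(all(abs(ours - anc) < tol))
})

test_that("Dollo posterior draws and histories never contain forbidden
          gains", {
  tr <- simulate_tree(40, seed = 16)
  sim <- simulate_discrete(tr, build_template("Dollo", 2), 0.8,
                           root_state = 1, seed = 17)
  tmpl <- build_template("Dollo", 2)
  mp <- map_character(tr, sim$tip_states, tmpl, n_burnin = 300,
                      n_iter = 600, n_thin = 3, n_maps = 200, seed = 1)
  expect_true(all(mp$posterior$draws > 0))
  gains <- vapply(mp$histories,
                  function(h) count_transitions(h)["0", "1"], integer(1L))
  expect_true(all(gains == 0L))
})

test_that("the lower-bound origin rule separates and merges per the
          posterior evidence", {
  tr <- read_tree("((D1:1,A1:1):1,(D2:1,A2:1):1);")
  # vertices: tips 1..4 (D1,A1,D2,A2), root 5, inner 6,7
  post_sep <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1),  # tips
                    c(0, 1), c(0, 1), c(0, 1))           # nodes: ancestral
  colnames(post_sep) <- c("0", "1")
  sm <- fake_summary(post_sep, tr)
  res <- lower_bound_origins(sm, tr, derived = 0, ancestral = 1,
                             threshold = 0.95)
  expect_equal(res$count, 2L)
  expect_equal(nrow(res$separators), 1L)

  post_weak <- post_sep
  post_weak[5:7, ] <- rep(c(0.4, 0.6), each = 3)
  res2 <- lower_bound_origins(fake_summary(post_weak, tr), tr, 0, 1, 0.95)
  expect_equal(res2$count, 1L)

  # derived state absent
  post_none <- post_sep
  post_none[1:4, ] <- rep(c(0, 1), each = 4)
  expect_equal(lower_bound_origins(fake_summary(post_none, tr),
                                   tr, 0, 1, 0.95)$count, 0L)
})

test_that("the origin count is monotonically non-increasing in the
          threshold and bounded by the mean gain count", {
  pl <- simulate_planted_origins(n_tips = 60, n_origins = 4, seed = 21)
  mp <- map_character(pl$tree, pl$states, build_template("ARD", 2),
                      n_burnin = 300, n_iter = 600, n_thin = 6,
                      n_maps = 100, seed = 2)
  sm <- summarize_maps(mp$histories)
  counts <- vapply(c(0.6, 0.8, 0.95, 0.99), function(th) {
    lower_bound_origins(sm, pl$tree, 0, 1, th)$count
  }, integer(1L))
  expect_true(all(diff(counts) <= 0))
  mean_losses <- sm$transitions$mean[sm$transitions$from == 1 &
                                       sm$transitions$to == 0]
  expect_lte(counts[3], mean_losses)
})
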