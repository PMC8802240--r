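test_that("templates have the expected free-parameter counts and keep
          forbidden cells at zero", {
  expect_equal(build_template("ER", 2)$n_par, 1L)
  expect_equal(build_template("ARD", 2)$n_par, 2L)
  expect_equal(build_template("Dollo", 2)$n_par, 1L)
  expect_equal(build_template("ER", 3)$n_par, 1L)
  expect_equal(build_template("SYM", 3)$n_par, 3L)
  expect_equal(build_template("ARD", 3)$n_par, 6L)
  expect_equal(build_template("ORD", 3)$n_par, 4L)
  expect_equal(build_template("ORD-Dollo", 3)$n_par, 3L)
  expect_equal(build_template("Dollo", 3)$n_par, 4L)
  expect_error(build_template("ORD", 2), "3 states")

  set.seed(2)
  for (nm in c("Dollo", "ORD", "ORD-Dollo")) {
    tmpl <- build_template(nm, 3)
    Q <- mk_Q(tmpl, runif(tmpl$n_par, 0.5, 5))
    off <- Q[tmpl$index == 0L & row(Q) != col(Q)]
    expect_true(all(off == 0))
  }
  # trinary Dollo allows the direct 2->0 loss but no gains out of 0
  d3 <- build_template("Dollo", 3)
  expect_gt(d3$index[3, 1], 0L)
  expect_equal(d3$index[1, 2], 0L)
  expect_equal(d3$index[1, 3], 0L)
})

test_that("two-tip likelihood matches the closed form for a symmetric
          binary chain", {
  q <- 0.7
  t <- 1.3
  tr <- read_tree(sprintf("(A:%f,B:%f);", t, t))
  tmpl <- build_template("ER", 2)
  same <- 0.5 + 0.5 * exp(-2 * q * t)
  expected <- log(0.5 * same^2 + 0.5 * (1 - same)^2)
  expect_equal(mk_loglik(tr, c(A = 0L, B = 0L), tmpl, q), expected,
               tolerance = 1e-12)
  # q = 0: both tips fixed at the root state, equal prior
  expect_equal(exp(mk_loglik(tr, c(A = 0L, B = 0L), tmpl, 0)), 0.5)
})

test_that("pruning equals exhaustive enumeration on small random
          instances", {
  for (s in 1:30) {
    inst <- random_mk_instance(n_tips = sample(3:6, 1L),
                               n_states = sample(2:3, 1L), seed = s)
    Q <- mk_Q(inst$template, inst$rates)
    ours <- mk_loglik(inst$tree, inst$states, inst$template, inst$rates)
    oracle <- enum_loglik(inst$tree, inst$states, Q,
                          rep(1 / nrow(Q), nrow(Q)))
    if (is.finite(oracle)) {
      expect_equal(ours, oracle, tolerance = 1e-9)
    } else {
      expect_identical(ours, -Inf)
    }
  }
})

test_that("likelihood is invariant to tip order and, for reversible models,
          to root placement", {
  inst <- random_mk_instance(8, 2, seed = 99)
  ll <- mk_loglik(inst$tree, inst$states, inst$template, inst$rates)
  perm <- sample(names(inst$states))
  expect_equal(mk_loglik(inst$tree, inst$states[perm], inst$template,
                         inst$rates), ll, tolerance = 1e-12)

  set.seed(4)
  tr <- ape::rphylo(8, 1, 0)
  st <- setNames(sample(0:1, 8, TRUE), tr$tip.label)
  tmpl <- build_template("ER", 2)
  ll1 <- mk_loglik(tr, st, tmpl, 0.8)
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[5],
                        resolve.root = TRUE)
  ll2 <- mk_loglik(rerooted, st, tmpl, 0.8)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("AICc arithmetic, error guard and large-n limit", {
  expect_equal(aicc(0, 1, 100), 2 + 4 / 98, tolerance = 1e-12)
  expect_error(aicc(-10, 5, 6), "n > k")
  # AICc converges to AIC
  expect_lt(abs(aicc(-100, 3, 1e6) - (2 * 100 + 2 * 3)), 1e-3)
})

test_that("AICc weights normalise correctly", {
  expect_equal(aicc_weights(c(10, 10, 10)), rep(1 / 3, 3))
  w <- aicc_weights(c(100, Inf))
  expect_equal(w, c(1, 0))
  expect_equal(sum(aicc_weights(c(98.2, 94.4, 95.5))), 1)
})

test_that("ML fit dominates a dense grid search on a small instance", {
  set.seed(21)
  tr <- ape::rphylo(8, 1, 0)
  sim <- simulate_discrete(tr, build_template("ARD", 2), c(0.8, 0.4),
                           root_state = 1, seed = 3)
  tmpl <- build_template("ARD", 2)
  fit <- fit_mk(tr, sim$tip_states, tmpl, n_starts = 5)
  grid <- exp(seq(log(0.01), log(20), length.out = 50))
  best_grid <- -Inf
  for (a in grid) for (b in grid) {
    best_grid <- max(best_grid,
                     mk_loglik(tr, sim$tip_states, tmpl, c(a, b)))
  }
  expect_gte(fit$logL, best_grid - 1e-6)
  expect_equal(fit$aicc, aicc(fit$logL, 2, 8))
})

test_that("monomorphic data drive the ER rate to the zero boundary", {
  tr <- read_tree("(A:1,B:1);")
  expect_warning(
    fit <- fit_mk(tr, c(A = 1L, B = 1L), build_template("ER", 2),
                  n_starts = 3),
    "degenerate")
  expect_lt(fit$rates[1], 1e-6)
})

test_that("simulated ER rates are recovered at moderate tree sizes", {
  rel_err <- vapply(1:5, function(s) {
    tr <- simulate_tree(200, seed = 8 + s)
    tr$edge.length <- tr$edge.length * 4  # deeper tree: more events
    sim <- simulate_discrete(tr, build_template("ER", 2), 0.5,
                             root_state = 1, seed = 90 + s)
    fit <- fit_mk(tr, sim$tip_states, build_template("ER", 2),
                  n_starts = 3)
    abs(fit$rates[1] - 0.5) / 0.5
  }, numeric(1L))
  expect_lt(median(rel_err), 0.3)
})

test_that("model comparison table is ranked, weighted and flagged", {
  tr <- simulate_tree(60, seed = 14)
  sim <- simulate_discrete(tr, build_template("ER", 2), 1, root_state = 1,
                           seed = 15)
  cmp <- compare_models(tr, sim$tip_states, c("ER", "Dollo", "ARD"),
                        n_starts = 3)
  expect_equal(nrow(cmp$table), 3L)
  expect_true(!is.unsorted(cmp$table$AICc))
  expect_equal(sum(cmp$table$AICcw), 1)
  expect_identical(cmp$table$map, cmp$table$AICcw > 0.15)
  one <- compare_models(tr, sim$tip_states, "ER", n_starts = 2)
  expect_equal(one$table$AICcw, 1)
})
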