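star_tree <- function(n, depth = 1) {
  txt <- paste0("(", paste(sprintf("s%d:%g", seq_len(n), depth),
                           collapse = ","), ");")
  read_tree(txt)
}

test_that("pPCA on a star tree equals ordinary correlation-matrix PCA", {
  set.seed(51)
  star <- star_tree(40)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(star$tip.label, paste0("t", 1:6)))
  pp <- ppca(X, star, lambda = 1)
  e0 <- eigen(cor(X), symmetric = TRUE)$values
  expect_lt(max(abs(pp$eigenvalues - e0)), 1e-8)
  expect_equal(sum(pp$eigenvalues), 6, tolerance = 1e-10)
  expect_equal(unname(pp$anc_mean), unname(colMeans(X)), tolerance = 1e-10)
})

test_that("two collinear traits load entirely on PC1", {
  set.seed(52)
  tr <- simulate_tree(30, seed = 53)
  a <- rnorm(30)
  X <- cbind(t1 = a, t2 = 2 * a + 5)
  rownames(X) <- tr$tip.label
  pp <- ppca(X, tr, lambda = 1)
  expect_equal(unname(pp$percent_var["PC1"]), 100, tolerance = 1e-8)
})

test_that("pPCA scores are invariant to trait rescaling", {
  set.seed(54)
  tr <- simulate_tree(35, seed = 55)
  R <- matrix(0.4, 5, 5)
  diag(R) <- 1
  X <- simulate_continuous(tr, R, lambda = 0.8, sigma = 0.3,
                           seed = 56)$values
  X2 <- sweep(X, 2, c(10, 0.01, 3, 1, 100), "*")
  p1 <- ppca(X, tr, lambda = 0.8)
  p2 <- ppca(X2, tr, lambda = 0.8)
  expect_lt(max(abs(p1$scores - p2$scores)), 1e-8)
  expect_lt(max(abs(p1$eigenvalues - p2$eigenvalues)), 1e-10)
})

test_that("pPCA rejects constant traits by name", {
  tr <- simulate_tree(10, seed = 57)
  X <- cbind(a = rnorm(10), flat = rep(2, 10))
  rownames(X) <- tr$tip.label
  expect_error(ppca(X, tr), "flat")
})

test_that("pPCA recovers a planted one-factor structure", {
  hits <- 0L
  for (s in 1:10) {
    tr <- simulate_tree(80, seed = 100 + s)
    R <- matrix(0.65, 15, 15)
    diag(R) <- 1
    X <- simulate_continuous(tr, R, lambda = 0.9, sigma = 0.3,
                             seed = 200 + s)$values
    pp <- ppca(X, tr)
    v <- pp$loadings[, 1]
    if (all(abs(v) > 0.5 / sqrt(15)) && (all(v > 0) || all(v < 0))) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 9L)
})

test_that("PGLS with identity correlation and unit weights equals OLS", {
  set.seed(58)
  star <- star_tree(30)
  y <- setNames(rnorm(30), star$tip.label)
  x <- matrix(rnorm(30), dimnames = list(star$tip.label, "x"))
  f <- pgls_fit(y, x, star, structure = "none")
  o <- lm(y ~ x[names(y), ])
  expect_lt(max(abs(f$coefficients$estimate - coef(o))), 1e-10)
  expect_lt(max(abs(f$coefficients$se -
                      summary(o)$coefficients[, 2])), 1e-10)
})

test_that("sample-size weights scale residual variances as 1/n", {
  tr <- simulate_tree(20, seed = 59)
  y <- setNames(rnorm(20), tr$tip.label)
  w1 <- setNames(rep(1, 20), tr$tip.label)
  wk <- w1
  wk[3] <- 4  # quadruple one species' measurement count
  f1 <- pgls_fit(y, NULL, tr, structure = "BM", weights = w1)
  fk <- pgls_fit(y, NULL, tr, structure = "BM", weights = wk)
  i <- match(names(wk)[3], f1$species)
  expect_equal(f1$Vcorr[i, i] / fk$Vcorr[i, i], 4)
  off <- setdiff(seq_len(20), i)
  expect_equal(f1$Vcorr[off, off], fk$Vcorr[off, off])
})

test_that("the lambda profile endpoints reproduce the non-phylogenetic and
          Brownian fits", {
  set.seed(60)
  tr <- simulate_tree(40, seed = 61)
  X <- simulate_continuous(tr, diag(2), lambda = 1, sigma = 0.4,
                           seed = 62)$values
  y <- setNames(X[, 1] + 0.3 * X[, 2], rownames(X))
  x <- X[, 2, drop = FALSE]
  colnames(x) <- "x"
  f_lam <- pgls_fit(y, x, tr, structure = "lambda")
  f_none <- pgls_fit(y, x, tr, structure = "none")
  f_bm <- pgls_fit(y, x, tr, structure = "BM")
  prof <- f_lam$profile
  expect_equal(prof$logL[prof$theta == 0], f_none$logL, tolerance = 1e-8)
  expect_equal(prof$logL[prof$theta == 1], f_bm$logL, tolerance = 1e-8)
})

test_that("OU with vanishing alpha converges to the Brownian fit", {
  set.seed(63)
  tr <- simulate_tree(30, seed = 64)
  X <- simulate_continuous(tr, diag(2), lambda = 1, sigma = 0.4,
                           seed = 65)$values
  y <- X[, 1] + 0.5 * X[, 2]
  M <- cbind(1, X[, 2])
  Vou <- phylosyndrome:::.pgls_corr(tr, "OU", 1e-6)
  Vbm <- phylosyndrome:::.pgls_corr(tr, "BM", NA)
  fou <- phylosyndrome:::.pgls_profile(y, M, Vou)
  fbm <- phylosyndrome:::.pgls_profile(y, M, Vbm)
  expect_lt(max(abs(fou$beta - fbm$beta)), 1e-4)
})

test_that("predictive R-squared is 0 for identical models, 1 for a perfect
          fit, and matches a direct conditional computation", {
  set.seed(66)
  star <- star_tree(12)
  y <- setNames(rnorm(12), star$tip.label)
  x <- matrix(rnorm(12), dimnames = list(star$tip.label, "x"))
  f <- pgls_fit(y, x, star, structure = "none")
  expect_equal(r2_pred(f, f), 0)

  y_perfect <- setNames(2 + 3 * x[, 1], rownames(x))
  fp <- pgls_fit(y_perfect, x, star, structure = "none")
  f0 <- pgls_fit(y_perfect, NULL, star, structure = "none")
  expect_equal(r2_pred(fp, f0), 1, tolerance = 1e-9)

  # 8-species phylogenetic instance vs the precision-matrix identity
  # y_i - E[y_i | y_-i] = (V^-1 r)_i / (V^-1)_ii
  tr <- simulate_tree(8, seed = 67)
  Xs <- simulate_continuous(tr, diag(2), lambda = 1, sigma = 0.5,
                            seed = 68)$values
  yb <- setNames(Xs[, 1] + 0.8 * Xs[, 2], rownames(Xs))
  xb <- Xs[, 2, drop = FALSE]
  colnames(xb) <- "x"
  full <- pgls_fit(yb, xb, tr, structure = "BM")
  red <- pgls_fit(yb, NULL, tr, structure = "none")
  sse_direct <- function(fit) {
    Vi <- solve(fit$Vcorr)
    r <- fit$residuals
    sum(((Vi %*% r) / diag(Vi))^2)
  }
  r2_direct <- 1 - sse_direct(full) / sse_direct(red)
  expect_equal(r2_pred(full, red), r2_direct, tolerance = 1e-9)
  expect_error(r2_pred(full, pgls_fit(yb[1:7], NULL, tr,
                                      structure = "none")),
               "different species")
})

test_that("structure comparison ranks BM/lambda/OU by AICc", {
  set.seed(69)
  tr <- simulate_tree(50, seed = 70)
  X <- simulate_continuous(tr, diag(2), lambda = 1, sigma = 0.4,
                           seed = 71)$values
  y <- setNames(X[, 1] + 0.5 * X[, 2], rownames(X))
  x <- X[, 2, drop = FALSE]
  colnames(x) <- "x"
  cmp <- pgls_compare_structures(y, x, tr)
  expect_equal(nrow(cmp$table), 3L)
  expect_true(!is.unsorted(cmp$table$AICc))
  expect_equal(sum(cmp$table$AICcw), 1)
})

test_that("coevolution analysis returns paired pPCAs and is unchanged when
          the exclusion filter removes nothing", {
  set.seed(72)
  tr <- simulate_tree(60, seed = 73)
  R <- matrix(0.5, 9, 9)
  diag(R) <- 1
  X <- simulate_continuous(tr, R, lambda = 0.9, sigma = 0.3,
                           seed = 74)$values
  S <- X[, 1:5]
  A <- X[, 6:9]
  full <- coevolution_analysis(S, A, tr)
  expect_s3_class(full$ppca_stylet, "ppca_result")
  expect_s3_class(full$pgls, "pgls_fit")
  noop <- coevolution_analysis(S, A, tr, exclude_species = "not_a_species")
  expect_equal(noop$pgls_subset$coefficients$estimate,
               full$pgls$coefficients$estimate, tolerance = 1e-10)
  expect_error(
    coevolution_analysis(S, A, tr,
                         exclude_species = rownames(S)[1:55]),
    "subset leaves")
})

test_that("a planted stylet-antrum correlation is detected", {
  set.seed(75)
  tr <- simulate_tree(120, seed = 76)
  ## shared factor induces a PC1-PC1 association between the two blocks
  R <- diag(9)
  R[1:5, 1:5] <- 0.6
  R[6:9, 6:9] <- 0.6
  R[1:5, 6:9] <- 0.36
  R[6:9, 1:5] <- 0.36
  diag(R) <- 1
  X <- simulate_continuous(tr, R, lambda = 0.9, sigma = 0.3,
                           seed = 77)$values
  res <- coevolution_analysis(X[, 1:5], X[, 6:9], tr)
  slope <- res$pgls$coefficients["antrum_PC1", ]
  expect_lt(slope$p, 0.05)
})
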