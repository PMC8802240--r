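## Residual correlation matrix on the tree under the chosen evolutionary
## model, normalised to unit diagonal (ultrametric trees).
.pgls_corr <- function(tree, structure, theta) {
  C <- ape::vcv.phylo(tree)
  T0 <- max(diag(C))
  switch(structure,
    none = diag(nrow(C)),
    BM = C / T0,
    lambda = {
      R <- C / T0 * theta
      diag(R) <- 1
      R
    },
    OU = {
      D <- 2 * (T0 - C)  # patristic distance on an ultrametric tree
      exp(-theta * D)
    }
  )
}

## Profile (over beta, sigma2) ML log-likelihood and GLS estimates for a
## fixed residual correlation. W is the diagonal weight adjustment.
.pgls_profile <- function(y, M, Vc) {
  n <- length(y)
  ch <- tryCatch(chol(Vc), error = function(e) NULL)
  if (is.null(ch)) return(list(logL = -Inf))
  yw <- forwardsolve(t(ch), y)
  Mw <- forwardsolve(t(ch), M)
  qrM <- qr(Mw)
  if (qrM$rank < ncol(M)) stop("singular design matrix")
  beta <- qr.coef(qrM, yw)
  res <- yw - Mw %*% beta
  rss <- sum(res^2)
  sigma2 <- rss / n
  logdet <- 2 * sum(log(diag(ch)))
  logL <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(logL = logL, beta = beta, sigma2 = sigma2, Mw = Mw, yw = yw,
       res_w = as.numeric(res), chol = ch)
}

#' Phylogenetic generalized least squares with sample-size weights
#'
#' Fits `y ~ X` by ML under residual covariance
#' `sigma^2 W^{1/2} Corr(theta) W^{1/2}` where `Corr` is the phylogenetic
#' correlation under a Brownian-motion, Pagel's-lambda or Ornstein-Uhlenbeck
#' model (or the identity, for a non-phylogenetic fit) and `W` encodes
#' response sample sizes: by default `Var(e_i)` is proportional to `1/n_i`,
#' so duplicating a species' measurement count halves its residual variance.
#' The structure parameter (lambda or alpha) is estimated by ML jointly with
#' `sigma^2`, and its profile likelihood is retained so unimodality and
#' boundary estimates can be inspected.
#'
#' @param response Named numeric vector of species values.
#' @param predictors Named numeric matrix/data.frame of predictors (rownames
#'   = species), or `NULL` for an intercept-only model. An intercept is
#'   always included.
#' @param tree A `phylo` object; pruned to the complete-case species.
#' @param structure `"BM"`, `"lambda"`, `"OU"` or `"none"` (identity
#'   correlation).
#' @param weights Named vector of response sample sizes (default: 1 for all
#'   species).
#' @param weight_form `"variance"` (`Var ~ 1/n`, default) or `"sd"`
#'   (`SD ~ 1/n`).
#' @return A `pgls_fit`: coefficients with SE/t/p, `structure`, `theta`
#'   (estimated lambda or alpha, `NA` if none), `sigma2`, `logL`, `k`, `n`,
#'   `aicc`, `profile` (grid of structure parameter vs logL),
#'   `boundary` flag, whitened residuals, fitted values and the pieces
#'   needed for predictive R-squared.
#' @export
pgls_fit <- function(response, predictors = NULL, tree,
                     structure = c("BM", "lambda", "OU", "none"),
                     weights = NULL,
                     weight_form = c("variance", "sd")) {
  structure <- match.arg(structure)
  weight_form <- match.arg(weight_form)
  y_all <- response[!is.na(response)]
  if (!is.null(predictors)) {
    P <- as.matrix(predictors)
    if (is.null(rownames(P))) stop("predictors need species rownames")
    P <- P[stats::complete.cases(P), , drop = FALSE]
    common <- intersect(names(y_all), rownames(P))
  } else {
    P <- NULL
    common <- names(y_all)
  }
  common <- intersect(common, tree$tip.label)
  p_fixed <- 1L + if (is.null(P)) 0L else ncol(P)
  if (length(common) <= p_fixed + 1L) stop("too few complete cases")
  tree_f <- if (length(common) < ape::Ntip(tree)) prune_to(tree, common) else tree
  sp <- tree_f$tip.label
  y <- as.numeric(y_all[sp])
  M <- cbind(`(Intercept)` = rep(1, length(sp)))
  if (!is.null(P)) M <- cbind(M, P[sp, , drop = FALSE])
  w <- if (is.null(weights)) rep(1, length(sp)) else as.numeric(weights[sp])
  if (anyNA(w) || any(w <= 0)) stop("weights must be positive for all species")
  wvar <- if (weight_form == "variance") 1 / w else 1 / w^2
  n <- length(y)

  Vc_at <- function(theta) {
    Corr <- .pgls_corr(tree_f, structure, theta)
    sqrt(wvar) * t(sqrt(wvar) * t(Corr))  # W^(1/2) Corr W^(1/2)
  }
  ll_at <- function(theta) .pgls_profile(y, M, Vc_at(theta))$logL

  theta <- NA_real_
  profile <- NULL
  boundary <- FALSE
  n_theta <- 0L
  if (structure == "lambda") {
    grid <- seq(0, 1, length.out = 21L)
    profile <- data.frame(theta = grid,
                          logL = vapply(grid, ll_at, numeric(1L)))
    opt <- stats::optimize(ll_at, c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    theta <- cand[which.max(c(opt$objective, ll_at(0), ll_at(1)))]
    boundary <- theta %in% c(0, 1)
    n_theta <- 1L
  } else if (structure == "OU") {
    grid <- exp(seq(-6, 6, length.out = 25L))
    profile <- data.frame(theta = grid,
                          logL = vapply(grid, ll_at, numeric(1L)))
    opt <- stats::optimize(function(la) ll_at(exp(la)), c(-8, 8),
                           maximum = TRUE, tol = 1e-8)
    theta <- exp(opt$maximum)
    boundary <- opt$maximum <= -7.9 || opt$maximum >= 7.9
    n_theta <- 1L
  }
  Vc <- Vc_at(theta)
  fit <- .pgls_profile(y, M, Vc)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(M)
  XtVX_inv <- chol2inv(qr.R(qr(fit$Mw)))
  se <- sqrt(fit$sigma2 * n / (n - ncol(M)) * diag(XtVX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - ncol(M))
  k <- ncol(M) + 1L + n_theta
  fitted <- as.numeric(M %*% beta)
  structure(list(coefficients = data.frame(estimate = beta, se = se,
                                           t = tval, p = pval,
                                           row.names = colnames(M)),
                 structure = structure, theta = theta, sigma2 = fit$sigma2,
                 logL = fit$logL, k = k, n = n,
                 aicc = aicc(fit$logL, k, n),
                 species = sp, y = y, design = M, weights = w,
                 Vcorr = Vc, fitted = fitted,
                 residuals = y - fitted,
                 residuals_whitened = fit$res_w,
                 profile = profile, boundary = boundary),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS fit (", x$structure, "residuals ), n =", x$n, "\n")
  if (!is.na(x$theta)) {
    cat("  structure parameter =", format(x$theta, digits = 4),
        if (x$boundary) "(boundary)" else "", "\n")
  }
  cat("  logL =", format(x$logL, digits = 6),
      " AICc =", format(x$aicc, digits = 6), "\n")
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' Compare residual structures for a PGLS model
#'
#' Fits the same regression under Brownian-motion, lambda and
#' Ornstein-Uhlenbeck residuals and ranks them by AICc.
#'
#' @inheritParams pgls_fit
#' @param structures Structures to compare.
#' @return List with `table` (AICc ranking) and `fits`; the best fit is
#'   `fits[[table$structure[1]]]`.
#' @export
pgls_compare_structures <- function(response, predictors = NULL, tree,
                                    structures = c("BM", "lambda", "OU"),
                                    weights = NULL) {
  fits <- lapply(structures, function(s) {
    pgls_fit(response, predictors, tree, structure = s, weights = weights)
  })
  names(fits) <- structures
  tab <- data.frame(structure = structures,
                    logL = vapply(fits, `[[`, numeric(1L), "logL"),
                    AICc = vapply(fits, `[[`, numeric(1L), "aicc"))
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$AICcw <- aicc_weights(tab$AICc)
  tab <- tab[order(tab$AICc), ]
  list(table = tab, fits = fits)
}

#' Predictive R-squared for nested (phylogenetic) models
#'
#' Each species' prediction under a fitted model is its conditional
#' expectation given all other species' residuals under the fitted residual
#' covariance: `yhat_i = x_i b + V[i,-i] V[-i,-i]^-1 (y_-i - X_-i b)`.
#' The statistic is `1 - SSE_pred(full) / SSE_pred(reduced)`; the reduced
#' model is typically intercept-only without phylogeny (`structure =
#' "none"`), or intercept-only with phylogeny to isolate the predictors'
#' contribution.
#'
#' @param full,reduced `pgls_fit` objects on the same response and species.
#' @return Predictive R-squared in `(-Inf, 1]`.
#' @export
r2_pred <- function(full, reduced) {
  if (!setequal(full$species, reduced$species)) {
    stop("full and reduced fits use different species sets")
  }
  if (max(abs(full$y[order(full$species)] -
                reduced$y[order(reduced$species)])) > 1e-12) {
    stop("full and reduced fits have different responses")
  }
  1 - .sse_pred(full) / .sse_pred(reduced)
}

.sse_pred <- function(fit) {
  V <- fit$Vcorr
  n <- fit$n
  r <- fit$residuals
  sse <- 0
  if (max(abs(V[upper.tri(V)])) < 1e-14) {
    return(sum(r^2))  # independent residuals: prediction is the mean part
  }
  for (i in seq_len(n)) {
    vi <- V[i, -i]
    Vii <- V[-i, -i]
    cond <- as.numeric(vi %*% solve(Vii, r[-i]))
    sse <- sse + (r[i] - cond)^2
  }
  sse
}

#' Male-female genital coevolution analysis
#'
#' Summarises the male (stylet) and female (antrum) trait blocks with two
#' independent phylogenetic PCAs, then regresses stylet PC1 on antrum PC1
#' with PGLS. A second model excluding a given species set (typically the
#' hypodermic-syndrome species, whose uniformly simple genitalia could drive
#' the relationship) is fitted when `exclude_species` is non-empty.
#'
#' @param stylet_traits,antrum_traits Species x trait matrices (numerically
#'   coded; complete cases across both blocks are used).
#' @param tree A `phylo` object.
#' @param exclude_species Species to drop in the subset rerun.
#' @param structure Residual structure for the PGLS (default `"lambda"`).
#' @param min_n Minimum species left after filtering (default 10).
#' @return List with `ppca_stylet`, `ppca_antrum`, `pgls` (full),
#'   `pgls_subset` (or `NULL`), `species`.
#' @export
coevolution_analysis <- function(stylet_traits, antrum_traits, tree,
                                 exclude_species = character(0),
                                 structure = "lambda", min_n = 10) {
  S <- as.matrix(stylet_traits)
  A <- as.matrix(antrum_traits)
  common <- intersect(rownames(S)[stats::complete.cases(S)],
                      rownames(A)[stats::complete.cases(A)])
  common <- intersect(common, tree$tip.label)
  if (length(common) < min_n) {
    stop("only ", length(common), " complete-case species (need >= ", min_n,
         ")")
  }
  run <- function(keep) {
    tr <- prune_to(tree, keep)
    ps <- ppca(S[keep, , drop = FALSE], tr)
    pa <- ppca(A[keep, , drop = FALSE], tr)
    fit <- pgls_fit(ps$scores[, "PC1"],
                    cbind(antrum_PC1 = pa$scores[, "PC1"]),
                    tr, structure = structure)
    list(ppca_stylet = ps, ppca_antrum = pa, pgls = fit)
  }
  full <- run(common)
  subset_fit <- NULL
  keep2 <- setdiff(common, exclude_species)
  if (length(exclude_species) > 0L) {
    if (length(keep2) < min_n) {
      stop("subset leaves only ", length(keep2), " species (need >= ",
           min_n, ")")
    }
    subset_fit <- run(keep2)
  }
  list(ppca_stylet = full$ppca_stylet, ppca_antrum = full$ppca_antrum,
       pgls = full$pgls,
       pgls_subset = if (is.null(subset_fit)) NULL else subset_fit$pgls,
       species = common)
}
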