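#' Phylogenetically corrected principal component analysis
#'
#' PCA of the evolutionary correlation matrix under a Pagel's-lambda
#' residual model. For a trait matrix X and phylogenetic covariance
#' C(lambda), the ancestral (root) mean is the GLS estimate
#' `a = (1' C^-1 1)^-1 1' C^-1 X`, the evolutionary covariance is
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`, and components are the
#' eigenvectors of the corresponding correlation matrix (traits are measured
#' on different scales, so the correlation matrix is used throughout).
#' Lambda is estimated by maximising the multivariate GLS likelihood.
#' Scores are computed from the centred traits standardised by their
#' evolutionary standard deviations.
#'
#' @param X Numeric matrix, species x traits, rownames = species; complete
#'   cases only (mixed ordinal traits should be numerically coded).
#' @param tree A `phylo` object; tips not in `X` are pruned.
#' @param lambda Fix lambda instead of estimating it (`NULL` = estimate by
#'   ML over `[0, 1]`).
#' @return A `ppca_result`: list with `lambda`, `logL`, `eigenvalues`
#'   (summing to the number of traits), `loadings` (trait x component
#'   eigenvectors, columns orthonormal, sign-fixed so the dominant trait
#'   loads positively), `scores` (species x component), `anc_mean` (GLS root
#'   estimates), `percent_var`, `correlation` (the evolutionary correlation
#'   matrix).
#' @export
ppca <- function(X, tree, lambda = NULL) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("X needs species rownames")
  if (anyNA(X)) {
    stop("X contains missing values; supply complete cases only")
  }
  common <- intersect(tree$tip.label, rownames(X))
  if (length(common) < 3L) stop("need at least 3 species")
  if (length(common) < ape::Ntip(tree)) tree <- prune_to(tree, common)
  X <- X[tree$tip.label, , drop = FALSE]
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant trait(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  n <- nrow(X)
  p <- ncol(X)
  one <- matrix(1, n, 1L)

  fit_at <- function(lam) {
    C <- phylo_covariance(tree, lam)$matrix[rownames(X), rownames(X)]
    ch <- chol(C)
    Xi <- backsolve(ch, forwardsolve(t(ch), X))   # C^-1 X pieces via chol
    oi <- backsolve(ch, forwardsolve(t(ch), one))
    a <- solve(crossprod(one, oi), crossprod(oi, X))  # 1 x p GLS mean
    Xc <- X - one %*% a
    Xci <- backsolve(ch, forwardsolve(t(ch), Xc))
    Rml <- crossprod(Xc, Xci) / n
    logdetC <- 2 * sum(log(diag(ch)))
    ld <- determinant(Rml, logarithm = TRUE)
    logL <- -0.5 * (n * p * log(2 * pi) + p * logdetC +
                      n * as.numeric(ld$modulus) + n * p)
    list(logL = logL, a = a, Xc = Xc, Xci = Xci, C = C)
  }

  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) fit_at(l)$logL, c(0, 1),
                           maximum = TRUE, tol = 1e-8)
    ## compare against the boundaries explicitly
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, fit_at(0)$logL, fit_at(1)$logL)
    lambda <- cand[which.max(vals)]
  }
  ft <- fit_at(lambda)
  R <- crossprod(ft$Xc, ft$Xci) / (n - 1)
  Rcor <- stats::cov2cor(R)
  eg <- eigen(Rcor, symmetric = TRUE)
  V <- eg$vectors
  ## deterministic sign: dominant trait of each component loads positively
  for (j in seq_len(p)) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  Xs <- sweep(ft$Xc, 2L, sqrt(diag(R)), "/")
  scores <- Xs %*% V
  comp_names <- paste0("PC", seq_len(p))
  dimnames(V) <- list(colnames(X), comp_names)
  dimnames(scores) <- list(rownames(X), comp_names)
  structure(list(lambda = lambda, logL = ft$logL,
                 eigenvalues = stats::setNames(eg$values, comp_names),
                 loadings = V, scores = scores,
                 anc_mean = stats::setNames(as.numeric(ft$a), colnames(X)),
                 percent_var = stats::setNames(100 * eg$values / p,
                                               comp_names),
                 correlation = Rcor),
            class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  cat("Phylogenetic PCA (lambda model): lambda =",
      format(x$lambda, digits = 4), "\n")
  cat("  variance explained (%):",
      paste(round(utils::head(x$percent_var, 4L), 1), collapse = ", "),
      "...\n")
  invisible(x)
}
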