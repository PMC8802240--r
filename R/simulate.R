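#' Simulate a pure-birth tree rescaled to unit depth
#'
#' A Yule tree guarantees the requested number of tips and, after rescaling
#' to unit root-to-tip depth, gives branch lengths in relative-time units
#' comparable across simulations.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate per unit time.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` with depth 1 and tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth = 1, seed = 1) {
  stopifnot(n_tips >= 2L)
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  depth <- max(node_depths(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length / depth
  validate_tree(tr)
}

## Gillespie simulation of one branch: returns (state, length) segments
.gillespie_branch <- function(a, t, Q) {
  k <- nrow(Q)
  states <- integer(0)
  lens <- numeric(0)
  cur <- a
  remaining <- t
  seg <- 0
  repeat {
    rate <- -Q[cur, cur]
    dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
    if (dt >= remaining) {
      states <- c(states, cur)
      lens <- c(lens, seg + remaining)
      break
    }
    states <- c(states, cur)
    lens <- c(lens, seg + dt)
    remaining <- remaining - dt
    seg <- 0
    cur <- sample.int(k, 1L, prob = Q[cur, ] * (seq_len(k) != cur))
  }
  cbind(state = states, length = lens)
}

#' Simulate a discrete character forward along a tree
#'
#' Gillespie simulation from the root state down every branch, recording the
#' full (true) character history alongside the tip states — the ground truth
#' against which stochastic-map summaries can be calibrated.
#'
#' @param tree A `phylo` object.
#' @param template An `mk_template`.
#' @param rates Rates for the template's free parameters.
#' @param root_state 0-based starting state. Starting in an absorbing state
#'   is allowed (with a warning) — the data are then monomorphic.
#' @param seed Integer seed.
#' @return List with `tip_states` (named, 0-based), `history` (a
#'   `character_history`), `Q`.
#' @export
simulate_discrete <- function(tree, template, rates, root_state = NULL,
                              seed = 1) {
  set.seed(seed)
  Q <- mk_Q(template, rates)
  k <- nrow(Q)
  if (is.null(root_state)) root_state <- k - 1L
  stopifnot(root_state >= 0L, root_state < k)
  if (-Q[root_state + 1L, root_state + 1L] == 0 && any(Q > 0)) {
    warning("root state ", root_state,
            " is absorbing; all tips will share it")
  }
  post <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(post$edge)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  node_state <- integer(n_all)
  root <- post$edge[ne, 1L]
  node_state[root] <- root_state + 1L
  paths <- vector("list", ne)
  for (i in rev(seq_len(ne))) {  # preorder
    a <- node_state[post$edge[i, 1L]]
    seg <- .gillespie_branch(a, post$edge.length[i], Q)
    node_state[post$edge[i, 2L]] <- as.integer(seg[nrow(seg), "state"])
    seg[, "state"] <- seg[, "state"] - 1L
    paths[[i]] <- seg
  }
  tip_states <- as.integer(node_state[seq_len(n_tip)] - 1L)
  names(tip_states) <- tree$tip.label
  history <- structure(list(edge = post$edge, edge.length = post$edge.length,
                            paths = paths, node_states = node_state - 1L,
                            tip_states = tip_states, n_tip = n_tip,
                            n_states = k),
                       class = "character_history")
  list(tip_states = tip_states, history = history, Q = Q)
}

#' Simulate correlated continuous traits under Brownian motion
#'
#' Species values follow a matrix-normal distribution: rows (species)
#' covary as the lambda-scaled phylogenetic covariance, columns (traits) as
#' `diag(sigma) R diag(sigma)`. Per-species specimen replicates add
#' independent measurement noise, with specimen counts drawn from a shifted
#' negative binomial (guaranteeing at least one specimen per species).
#'
#' @param tree A `phylo` object.
#' @param R Trait correlation matrix (PSD, p x p).
#' @param lambda Pagel's lambda of the simulated signal.
#' @param sigma Per-trait BM rates (scalar or length p).
#' @param root_mean Trait values at the root (scalar or length p).
#' @param specimen_mean Mean of the shifted negative binomial specimen
#'   counts (default 8).
#' @param specimen_size Negative-binomial size (dispersion) parameter.
#' @param noise_sd Within-species measurement SD (on the trait scale).
#' @param seed Integer seed.
#' @return List with `values` (species x trait matrix), `n` (specimen-count
#'   matrix), `specimens` (long data.frame `species`, `trait`, `value`).
#' @export
simulate_continuous <- function(tree, R, lambda = 1, sigma = 1,
                                root_mean = 0, specimen_mean = 8,
                                specimen_size = 2, noise_sd = 0.1,
                                seed = 1) {
  set.seed(seed)
  R <- as.matrix(R)
  p <- nrow(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("trait correlation matrix is not PSD")
  sigma <- rep(sigma, length.out = p)
  root_mean <- rep(root_mean, length.out = p)
  C <- phylo_covariance(tree, lambda)$matrix
  n <- nrow(C)
  Rf <- diag(sigma, p) %*% R %*% diag(sigma, p)
  cR <- if (all(Rf == 0)) matrix(0, p, p)
        else chol(Rf + diag(1e-12 * max(diag(Rf)), p))
  cC <- chol(C + diag(1e-10, n))
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- t(cC) %*% Z %*% cR
  X <- sweep(X, 2L, root_mean, "+")
  rownames(X) <- rownames(C)
  if (is.null(colnames(R))) colnames(X) <- paste0("trait", seq_len(p))
  else colnames(X) <- colnames(R)
  counts <- matrix(1L + stats::rnbinom(n * p, mu = specimen_mean - 1,
                                       size = specimen_size),
                   n, p, dimnames = dimnames(X))
  specimens <- do.call(rbind, lapply(seq_len(p), function(j) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(species = rownames(X)[i], trait = colnames(X)[j],
                 value = X[i, j] + stats::rnorm(counts[i, j], 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(values = X, n = counts, specimens = specimens)
}

#' Plant a known number of independent origins of a derived state
#'
#' Picks `n_origins` mutually disjoint clades of a simulated tree and
#' assigns the derived state 0 to all their tips (the rest stay ancestral,
#' state 1) — a ground-truth configuration for testing the conservativeness
#' of the lower-bound origin count.
#'
#' @param n_tips Tree size.
#' @param n_origins Number of planted origins.
#' @param clade_size Range of clade tip counts eligible for planting.
#' @param seed Integer seed.
#' @return List with `tree`, `states` (named 0/1 vector; 0 = derived),
#'   `clades` (list of tip-label vectors, one per planted origin).
#' @export
simulate_planted_origins <- function(n_tips = 100, n_origins = 9,
                                     clade_size = c(2, 6), seed = 1) {
  tree <- simulate_tree(n_tips, seed = seed)
  set.seed(seed + 1L)
  n_all <- n_tips + tree$Nnode
  desc <- vector("list", n_all)
  for (i in seq_len(n_tips)) desc[[i]] <- i
  post <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(post$edge))) {
    a <- post$edge[i, 1L]; b <- post$edge[i, 2L]
    desc[[a]] <- c(desc[[a]], desc[[b]])
  }
  sizes <- lengths(desc)
  cand <- which(sizes >= clade_size[1L] & sizes <= clade_size[2L] &
                  seq_len(n_all) > n_tips)
  cand <- sample(cand)
  used <- logical(n_tips)
  clades <- list()
  for (v in cand) {
    tips <- desc[[v]][desc[[v]] <= n_tips]
    if (!any(used[tips])) {
      used[tips] <- TRUE
      clades[[length(clades) + 1L]] <- tree$tip.label[tips]
      if (length(clades) == n_origins) break
    }
  }
  if (length(clades) < n_origins) {
    stop("could not place ", n_origins, " disjoint clades; grow the tree")
  }
  states <- stats::setNames(rep(1L, n_tips), tree$tip.label)
  states[unlist(clades)] <- 0L
  list(tree = tree, states = states, clades = clades)
}

#' Generate a study-shaped synthetic dataset
#'
#' Emulates the shape of a genus-wide reproductive-morphology survey: an
#' ultrametric tree (default 145 tips); a received-sperm-location /
#' sperm-bristle pair evolved jointly under a dependent (correlated)
#' process in which bristle loss accelerates sharply once sperm are received
#' hypodermically; an antrum-state character that tracks sperm location with
#' a small decoupling probability; trinary refinements of location and
#' bristle state in which lineages with a recent loss are scored
#' intermediate ("both" / "reduced"); stylet sharpness consistent with the
#' syndrome; 15 continuous traits with a planted one-factor correlation
#' structure whose factor tracks the mating syndrome (sperm length loads on
#' it); and missing-completely-at-random gaps per trait.
#'
#' @param n_tips Number of species.
#' @param seed Integer seed (every stochastic step derives from it).
#' @param missingness Named fractions of species set to `NA` per categorical
#'   trait.
#' @return A `synthetic_dataset`: list with `tree`, `records` (categorical
#'   table, one row per species), `quant` (list `values`/`n` of transformed
#'   species means), `specimens` (long raw table), `histories` (true
#'   character histories), `truth` (generating parameters and true
#'   transition counts).
#' @export
generate_study_like <- function(n_tips = 145, seed = 1,
                                missingness = c(sperm_location = 0.30,
                                                bristle_state = 0.10,
                                                antrum_state = 0.12,
                                                stylet_sharpness = 0.05)) {
  tree <- simulate_tree(n_tips, seed = seed)
  ## dependent pair: x = sperm location (0 hypodermic, 1 antrum),
  ## y = bristle (0 absent/reduced, 1 present); gains forbidden, bristle
  ## loss 8x faster on a hypodermic background
  dep <- pagel_template("dependent")
  dep_rates <- c(0, 0.45, 0, 0.45,  # x gains 0; x losses 0.45 either bg
                 0, 2.4, 0, 0.3)    # y gain 0; y loss 2.4 | x=0, 0.3 | x=1
  joint <- simulate_discrete(tree, dep, dep_rates, root_state = 3L,
                             seed = seed + 1L)
  x_bin <- joint$tip_states %/% 2L   # location: 0 hypodermic, 1 antrum
  y_bin <- joint$tip_states %% 2L    # bristle: 0 lost, 1 present
  ## time since the lineage last left the "11" joint state, for trinary
  ## intermediate scoring: a loss within the last 15% of tree depth scores
  ## as intermediate ("both" received sperm / "reduced" bristles)
  recent <- .time_in_current_state(joint$history)
  loc3 <- ifelse(x_bin == 1L, 2L, ifelse(recent$x < 0.15, 1L, 0L))
  bri3 <- ifelse(y_bin == 1L, 2L, ifelse(recent$y < 0.15, 1L, 0L))
  set.seed(seed + 2L)
  ## antrum tracks location with a 7% decoupling probability
  antrum <- ifelse(stats::runif(n_tips) < 0.93, x_bin,
                   1L - x_bin)
  sharp <- ifelse(x_bin == 0L, "sharp",
                  sample(c("blunt", "neutral", "sharp"), n_tips, TRUE,
                         prob = c(0.7, 0.2, 0.1)))
  vocab_loc <- c("hypodermic", "both", "antrum")
  vocab_bri <- c("absent", "reduced", "present")
  records <- data.frame(
    species = tree$tip.label,
    sperm_location = vocab_loc[loc3 + 1L],
    bristle_state = vocab_bri[bri3 + 1L],
    antrum_state = c("simple", "thickened")[antrum + 1L],
    stylet_sharpness = sharp,
    brush = c("absent", "present")[y_bin + 1L],
    velum = sample(c("absent", "present"), n_tips, TRUE, prob = c(0.8, 0.2)),
    n_genital_openings = sample(c("1", "2"), n_tips, TRUE,
                                prob = c(0.95, 0.05)),
    antrum_thickness = antrum + stats::rbinom(n_tips, 1L, 0.15),
    cellular_valve = antrum * stats::rbinom(n_tips, 2L, 0.7),
    chamber_complexity = antrum + stats::rbinom(n_tips, 1L, 0.3),
    stringsAsFactors = FALSE)
  ## 15 continuous traits, one-factor structure (rho = 0.6), factor shifted
  ## by the mating syndrome so that hypodermic species have lower values
  p <- 15L
  R <- matrix(0.6, p, p)
  diag(R) <- 1
  trait_names <- c("body_area", "stylet_length", "stylet_curviness",
                   "proximal_opening_width", "distal_opening_width",
                   "distal_asymmetry", "sperm_length", "bristle_length",
                   paste0("aux", 1:7))
  colnames(R) <- rownames(R) <- trait_names
  cont <- simulate_continuous(tree, R, lambda = 0.9, sigma = 0.25,
                              root_mean = 2, noise_sd = 0.05,
                              seed = seed + 3L)
  ## syndrome effect: hypodermic species' traits shifted down ~ -0.3
  shift <- ifelse(x_bin[rownames(cont$values)] == 0L, -0.3, 0)
  cont$values <- cont$values + shift
  cont$specimens$value <- cont$specimens$value +
    shift[cont$specimens$species]
  ## measurements live on a positive scale: the simulated values are log10
  ## species means, specimens are back-transformed
  cont$specimens$value <- 10^cont$specimens$value
  set.seed(seed + 4L)
  for (trait in names(missingness)) {
    drop <- stats::runif(n_tips) < missingness[[trait]]
    records[[trait]][drop] <- NA
  }
  truth <- list(seed = seed, dep_rates = dep_rates,
                joint_transitions = count_transitions(joint$history),
                x_bin = x_bin, y_bin = y_bin, antrum = antrum,
                factor_rho = 0.6, syndrome_shift = -0.3, lambda = 0.9)
  structure(list(tree = tree, records = records,
                 quant = list(values = cont$values, n = cont$n),
                 specimens = cont$specimens,
                 histories = list(location_bristle = joint$history),
                 truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", ape::Ntip(x$tree), "species,",
      ncol(x$quant$values), "quantitative traits\n")
  invisible(x)
}

## For each tip and each of the two traits embedded in a joint 4-state
## history, the time since the lineage entered its current marginal state
## (capped at tree depth). Used to score recent losses as intermediate.
.time_in_current_state <- function(history) {
  n_tip <- history$n_tip
  edge <- history$edge
  ne <- nrow(edge)
  n_all <- max(edge)
  ## accumulate, walking rootward from each tip, the time spent in the
  ## current marginal state of each trait
  marg <- function(s, which) if (which == "x") s %/% 2L else s %% 2L
  out_x <- numeric(n_tip)
  out_y <- numeric(n_tip)
  parent_edge <- integer(n_all)
  for (i in seq_len(ne)) parent_edge[edge[i, 2L]] <- i
  for (tip in seq_len(n_tip)) {
    for (which in c("x", "y")) {
      cur <- marg(history$tip_states[tip], which)
      tt <- 0
      v <- tip
      done <- FALSE
      while (!done && parent_edge[v] > 0L) {
        i <- parent_edge[v]
        seg <- history$paths[[i]]
        for (j in rev(seq_len(nrow(seg)))) {
          if (marg(seg[j, "state"], which) == cur) {
            tt <- tt + seg[j, "length"]
          } else {
            done <- TRUE
            break
          }
        }
        v <- edge[i, 1L]
      }
      if (which == "x") out_x[tip] <- tt else out_y[tip] <- tt
    }
  }
  list(x = out_x, y = out_y)
}
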