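#' Read a rooted phylogeny from Newick or NEXUS text
#'
#' Parses a tree from a file path or a literal string. Newick is detected by a
#' leading `(`; NEXUS by a leading `#NEXUS` (TREES blocks with translate
#' tables are supported via [ape::read.nexus()]). Branch lengths are required
#' because every downstream computation (likelihoods, covariances) is in units
#' of branch length. Polytomies are retained as-is: the pruning algorithm
#' handles multifurcating nodes, and arbitrary resolution would alter
#' transition counts.
#'
#' @param source Path to a tree file, or the tree text itself.
#' @return An object of class `phylo` (see [ape::read.tree()]) with an added
#'   attribute `ultrametric` (logical): `TRUE` iff all root-to-tip path
#'   lengths agree within a relative tolerance of `1e-6` times tree depth.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' attr(tr, "ultrametric")
#' @export
read_tree <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  txt <- source
  if (!grepl("^\\s*[(#]", source) || file.exists(source)) {
    if (!file.exists(source)) {
      stop("tree source is neither parseable tree text nor an existing file: ",
           source)
    }
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  txt <- trimws(txt)
  if (grepl("^#NEXUS", txt, ignore.case = TRUE)) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(txt, tf)
    tree <- tryCatch(ape::read.nexus(tf), error = function(e) {
      stop("failed to parse NEXUS tree: ", conditionMessage(e))
    })
    if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  } else {
    tree <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                     error = function(e) {
      stop("failed to parse Newick tree near position ",
           .newick_error_position(txt), ": ", conditionMessage(e))
    })
    if (is.null(tree)) {
      stop("failed to parse Newick tree near position ",
           .newick_error_position(txt))
    }
  }
  validate_tree(tree)
}

## crude localisation of the first structural problem in a Newick string,
## used only to make parse errors actionable
.newick_error_position <- function(txt) {
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(nchar(txt))
  1L
}

#' Validate a phylogeny for comparative analysis
#'
#' Checks the invariants every downstream routine relies on: a single root,
#' unique tip labels, finite non-negative branch lengths present on every
#' edge. Attaches the `ultrametric` attribute.
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance for the ultrametricity check, as a fraction
#'   of tree depth.
#' @return The validated tree with attribute `ultrametric` set.
#' @export
validate_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; branch lengths are required")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("tree has missing or non-finite branch lengths")
  }
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  ## exactly one root: one node with no incoming edge
  n_node <- ape::Ntip(tree) + tree$Nnode
  has_parent <- tabulate(tree$edge[, 2L], nbins = n_node)
  roots <- setdiff(seq_len(n_node)[has_parent == 0L], integer(0))
  roots <- roots[roots > ape::Ntip(tree) | n_node == 1L]
  if (length(roots) != 1L) stop("tree must have exactly one root")
  depths <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(depths)
  attr(tree, "ultrametric") <-
    if (depth == 0) TRUE else (max(depths) - min(depths)) <= tol * depth
  tree
}

#' Root-to-node path lengths
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `Ntip + Nnode`: the summed branch length
#'   from the root to every node (tips first, in `tip.label` order).
#' @export
node_depths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  depth <- numeric(n_all)
  ## preorder: parents before children
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(ord$edge)))) {
    parent <- ord$edge[i, 1L]
    child <- ord$edge[i, 2L]
    depth[child] <- depth[parent] + ord$edge.length[i]
  }
  depth
}

#' Restrict a tree to a subset of species
#'
#' Drops all tips outside `keep`, collapsing the resulting degree-2 internal
#' nodes and summing their branch lengths, so root-to-tip depths of retained
#' species are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned tree, revalidated.
#' @export
prune_to <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("species not on the tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("need at least 2 species to keep")
  validate_tree(ape::keep.tip(tree, keep))
}

#' Phylogenetic covariance matrix under Pagel's lambda
#'
#' Under Brownian motion the covariance between species i and j is the depth
#' of their most recent common ancestor; Pagel's lambda rescales the
#' off-diagonal (shared) part, interpolating between the full tree
#' (`lambda = 1`) and a star phylogeny (`lambda = 0`).
#'
#' @param tree A `phylo` object (expected ultrametric; a non-ultrametric tree
#'   triggers a warning and proceeds on root-to-tip depths as given).
#' @param lambda Pagel's lambda in `[0, 1]`.
#' @return A list of class `phylo_covariance` with elements `species`
#'   (tip-label order of the matrix), `matrix` (n x n covariance) and
#'   `lambda`.
#' @examples
#' tr <- read_tree("((A:1,B:1):1,C:2);")
#' phylo_covariance(tr, lambda = 0.5)$matrix
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0, lambda <= 1)
  tree <- validate_tree(tree)
  if (!isTRUE(attr(tree, "ultrametric"))) {
    warning("tree is not ultrametric; using root-to-tip depths as given")
  }
  C <- ape::vcv.phylo(tree)
  d <- diag(C)
  C <- C * lambda
  diag(C) <- d
  structure(list(species = rownames(C), matrix = C, lambda = lambda),
            class = "phylo_covariance")
}

#' @export
print.phylo_covariance <- function(x, ...) {
  cat("Phylogenetic covariance:", length(x$species), "species, lambda =",
      format(x$lambda), "\n")
  invisible(x)
}
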