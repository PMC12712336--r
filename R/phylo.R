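# Tree algebra: ingestion, covariance, model branch-length transforms,
# rerooting.  Trees are ape "phylo" objects; branch lengths in Ma.

#' Parse a phylogenetic tree
#'
#' Reads a rooted tree from Newick or NEXUS text or a file.  Square
#' bracket comments/annotations are tolerated (stripped by the parser);
#' zero-length branches and polytomies are retained.
#'
#' @param x A file path, or a character string containing the tree.
#' @return An `ape` \link[ape]{phylo} object.
#' @export
#' @examples
#' tr <- parse_tree("((A:1,B:1):1,C:2):0;")
#' tree_height(tr)
parse_tree <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- if (file.exists(x)) {
    head <- toupper(trimws(readLines(x, n = 1L)))
    if (startsWith(head, "#NEXUS")) ape::read.nexus(x) else ape::read.tree(x)
  } else {
    ape::read.tree(text = x)
  }
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) == 1L) tr <- tr[[1L]]
    else return(validate_tree_sample(tr))
  }
  if (is.null(tr)) stop_mm("malformed tree text: parser returned nothing")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop_mm("not a phylogenetic tree")
  if (anyDuplicated(tr$tip.label))
    stop_mm("duplicate tip labels: %s",
            paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                  collapse = ", "))
  if (is.null(tr$edge.length)) stop_mm("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop_mm("negative branch lengths")
  tr
}

#' Validate a tree sample
#'
#' Checks that all members of a `multiPhylo` collection share the same
#' tip set.
#'
#' @param trees A \link[ape]{multiPhylo} object or list of trees.
#' @return The validated `multiPhylo`.
#' @export
validate_tree_sample <- function(trees) {
  trees <- lapply(trees, validate_tree)
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stop_mm("tree %d has a different tip set", i)
  class(trees) <- "multiPhylo"
  trees
}

#' Tree height
#'
#' Maximum root-to-tip path length.
#'
#' @param tree A `phylo` object.
#' @return Height in the tree's branch-length units (Ma).
#' @export
tree_height <- function(tree) max(ape::node.depth.edgelength(tree))

#' Test ultrametricity
#'
#' A tree is treated as ultrametric when the relative spread of
#' root-to-tip distances is within `tol` of the tree height (dated
#' consensus trees carry rounding noise).
#'
#' @param tree A `phylo` object.
#' @param tol Relative tolerance (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

#' Phylogenetic covariance (shared path length) matrix
#'
#' Entry (i, j) is the total branch length shared by the root-to-tip
#' paths of tips i and j; the diagonal holds root-to-tip distances.
#' Under Brownian motion with unit rate this is the trait covariance.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Symmetric tip-by-tip matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  ape::vcv(validate_tree(tree))
}

#' Model-based branch-length transforms
#'
#' Rescales branch lengths so that Brownian motion on the transformed
#' tree induces the same tip covariance as the source model on the
#' original tree:
#' \describe{
#'   \item{OU}{single-optimum, fixed-root Ornstein-Uhlenbeck with pull
#'     \eqn{\alpha}: a branch segment spanning node times \eqn{t_1 \to
#'     t_2} (from the root) becomes \eqn{e^{-2\alpha T}(e^{2\alpha t_2} -
#'     e^{2\alpha t_1})/(2\alpha)} where T is tree height; requires an
#'     ultrametric tree.}
#'   \item{EB}{early burst with rate decay \eqn{a \le 0}: segment becomes
#'     \eqn{(e^{a t_2} - e^{a t_1})/a} (identity in the \eqn{a \to 0}
#'     limit).}
#'   \item{lambda}{Pagel's \eqn{\lambda}: off-diagonal covariance scaled
#'     by \eqn{\lambda}, implemented by scaling internal branches by
#'     \eqn{\lambda} and restoring each tip's original depth on its
#'     terminal branch.}
#' }
#'
#' @param tree A rooted `phylo` object.
#' @param model One of `"OU"`, `"EB"`, `"lambda"`.
#' @param par The model parameter (\eqn{\alpha > 0}, \eqn{a \le 0}, or
#'   \eqn{\lambda \ge 0}).
#' @return The transformed `phylo` object.
#' @export
transform_tree <- function(tree, model = c("OU", "EB", "lambda"), par) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  depth <- ape::node.depth.edgelength(tree)  # node time from root
  e1 <- tree$edge[, 1L]; e2 <- tree$edge[, 2L]
  t1 <- depth[e1]; t2 <- depth[e2]
  out <- tree
  if (model == "OU") {
    if (par <= 0) stop_mm("OU transform requires alpha > 0")
    if (!is_ultrametric(tree))
      stop_mm("OU transform requires an ultrametric tree")
    T <- max(depth)
    out$edge.length <-
      exp(-2 * par * T) * (exp(2 * par * t2) - exp(2 * par * t1)) / (2 * par)
  } else if (model == "EB") {
    if (par > 0) stop_mm("EB transform requires a <= 0")
    out$edge.length <- if (par == 0) tree$edge.length
      else (exp(par * t2) - exp(par * t1)) / par
  } else {
    if (par < 0) stop_mm("lambda must be >= 0")
    ntip <- length(tree$tip.label)
    is_tip <- e2 <= ntip
    len <- tree$edge.length * par
    # terminal branches keep each tip at its original depth
    len[is_tip] <- depth[e2[is_tip]] - par * t1[is_tip]
    if (any(len < -1e-12))
      stop_mm("lambda = %g exceeds the maximum for this tree", par)
    len[len < 0] <- 0
    out$edge.length <- len
  }
  out
}

#' Largest admissible Pagel's lambda
#'
#' The largest \eqn{\lambda} for which the lambda transform keeps all
#' terminal branch lengths non-negative (and hence the covariance
#' positive semi-definite).
#'
#' @param tree A rooted `phylo` object.
#' @return Numeric \eqn{\lambda_{max} \ge 1} for ultrametric trees.
#' @export
lambda_max <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  tipe <- tree$edge[, 2L] <= ntip
  t1 <- depth[tree$edge[tipe, 1L]]   # parent-of-tip depth
  td <- depth[tree$edge[tipe, 2L]]   # tip depth
  pos <- t1 > 0
  if (!any(pos)) return(Inf)
  min(td[pos] / t1[pos])
}

#' Reroot a tree at an internal node
#'
#' Returns the tree rooted at `node`.  All tip-to-tip path lengths are
#' preserved; rerooting at the current root is the identity.
#'
#' @param tree A rooted `phylo` object.
#' @param node Internal node id (ape numbering: `ntip + 1` is the
#'   current root).
#' @return Rerooted `phylo` object.
#' @export
reroot <- function(tree, node) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  if (!(node %in% (ntip + seq_len(nnode))))
    stop_mm("node %s is not an internal node id", format(node))
  root <- ntip + 1L
  if (node == root) return(tree)
  ape::root(tree, node = node, resolve.root = FALSE)
}
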