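# Independent oracles and small fixtures used across test files.
# These deliberately avoid the package's own covariance / likelihood
# code paths: paths are enumerated by brute force and densities built
# with solve()/determinant() on dense matrices.

# Brute-force shared-path-length matrix: for every pair of tips, walk
# both root-to-tip paths along the edge list and sum the lengths of the
# edges they share.
oracle_shared_paths <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  path_edges <- function(tip) {
    edges <- integer()
    nd <- tip
    while (nd != root) {
      e <- which(tree$edge[, 2L] == nd)
      edges <- c(edges, e)
      nd <- tree$edge[e, 1L]
    }
    edges
  }
  paths <- lapply(seq_len(ntip), path_edges)
  S <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip))
    for (j in seq_len(ntip))
      S[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  S
}

# Dense multivariate-normal log density via explicit inverse/determinant.
oracle_mvn_logdens <- function(y, mean, V) {
  n <- length(y)
  r <- y - mean
  ld <- determinant(V, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(V) %*% r))
}

# Analytic model covariances built directly from the shared-time matrix
# (fixed-root forms), independent of the package's builders.
oracle_model_cov <- function(model, S, sigma2, par = NULL) {
  ti <- diag(S)
  V0 <- switch(model,
    BM = S,
    OU = {
      al <- par
      (exp(-al * (outer(ti, ti, "+") - 2 * S)) *
         (1 - exp(-2 * al * S))) / (2 * al)
    },
    EB = if (par == 0) S else (exp(par * S) - 1) / par)
  sigma2 * V0
}

# A reproducible non-ultrametric random tree (coalescent + jitter).
rand_tree <- function(n, seed, ultrametric = TRUE) {
  with_seed(seed, {
    tr <- ape::rcoal(n)
    if (!ultrametric)
      tr$edge.length <- tr$edge.length * runif(length(tr$edge.length),
                                               0.5, 1.5)
    tr
  })
}

# Random full trait-score target vector (illusion on its legal levels).
rand_targets <- function(seed) {
  with_seed(seed, {
    s <- runif(8L, 0, 0.99)
    tgt <- setNames(c(s, sample(c(0, 0.334, 0.667, 1), 1L)), trait_names())
    tgt
  })
}

# Minimal valid measurement record used as an editing base in tests.
base_specimen <- function(...) {
  args <- utils::modifyList(
    list(specimen_id = "s", femur3_length = 1, femur3_width = 0.3,
         ceph_width = 0.6, ceph_length = 1, abd_width = 0.5,
         abd_length = 1, pedicel_length = 0.1),
    list(...))
  do.call(specimen_measurements, args)
}
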