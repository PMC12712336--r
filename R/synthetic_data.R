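# Synthetic trees, traits and measurement tables: every stage of the
# analysis is testable without external data.  All randomness flows
# from the seed supplied per call; the caller's RNG state is untouched.

#' Simulation configuration
#'
#' @param seed Integer seed (mandatory for any stochastic operation).
#' @param n_tips Number of extant tips (>= 3).
#' @param birth,death Speciation and extinction rates (1/Ma); `death <
#'   birth`, both >= 0.
#' @param model Trait-simulation model id (`"BM"`, `"OU"`, `"EB"`,
#'   `"WN"`, `"FPK"`).
#' @param params Named list of trait-model parameters.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed, n_tips = 100L, birth = 0.15, death = 0.05,
                       model = "BM", params = list(sigma2 = 1, z0 = 0)) {
  if (missing(seed)) stop_mm("a seed is mandatory")
  if (n_tips < 3L) stop_mm("need at least 3 tips")
  if (birth < 0 || death < 0 || death >= birth)
    stop_mm("rates must satisfy 0 <= death < birth")
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 birth = birth, death = death, model = model,
                 params = params),
            class = "sim_config")
}

#' Simulate an ultrametric birth-death tree
#'
#' A time-calibrated tree of extant species conditioned on the tip
#' count, via the birth-death process (ape's `rphylo`).  Reproducible
#' from the seed.
#'
#' @param cfg A [sim_config()].
#' @return Ultrametric `phylo` with `cfg$n_tips` tips labelled
#'   `t1, t2, ...`.
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    tr <- ape::rphylo(cfg$n_tips, birth = cfg$birth, death = cfg$death,
                      fossils = FALSE)
    validate_tree(tr)
  })
}

#' Simulate trait evolution on a tree
#'
#' Exact branchwise simulation under each model class, retaining the
#' true internal-node states:
#' \describe{
#'   \item{BM}{normal increments, variance \eqn{\sigma^2 \ell}.}
#'   \item{OU}{conditional mean \eqn{\theta + (x - \theta)e^{-\alpha
#'     \ell}}, variance \eqn{\sigma^2(1 - e^{-2\alpha\ell})/(2\alpha)}.}
#'   \item{EB}{BM on the time-transformed branch (increment variance
#'     \eqn{\sigma^2 (e^{a t_2} - e^{a t_1})/a}).}
#'   \item{WN}{tips drawn independently, no phylogenetic structure.}
#'   \item{FPK}{jump process on the same discretized grid/generator as
#'     [fpk_loglik()] (exact transition sampling per branch), root drawn
#'     from the stationary density; simulator and likelihood are
#'     mutually consistent by construction.}
#' }
#'
#' @param tree Rooted `phylo`.
#' @param model Model id.
#' @param params Named list: `sigma2`, `z0` (BM/EB); plus `alpha`,
#'   `theta` (OU; `theta` defaults to `z0`); `a` (EB); `wn_mean`,
#'   `wn_variance` (WN); an [fpk_model()] as `fpk` (FPK).
#' @param seed Integer seed.
#' @return List: `tips` (named vector), `node_states` (internal nodes,
#'   ape ids as names), `model`, `params`.
#' @export
simulate_trait <- function(tree, model = c("BM", "OU", "EB", "WN", "FPK"),
                           params, seed) {
  model <- match.arg(model)
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  with_seed(seed, {
    if (model == "WN") {
      tips <- setNames(rnorm(ntip, params$wn_mean,
                             sqrt(params$wn_variance)), tree$tip.label)
      states <- rep(params$wn_mean, tree$Nnode)
      names(states) <- ntip + seq_len(tree$Nnode)
      return(list(tips = tips, node_states = states, model = model,
                  params = params))
    }
    depth <- ape::node.depth.edgelength(tree)
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    x <- numeric(nnode)
    if (model == "FPK") {
      m <- params$fpk
      stopifnot(inherits(m, "fpk_model"))
      eig <- .fpk_eig(m)
      pi0 <- stationary_density(m)$density
      st <- integer(nnode)
      st[ntip + 1L] <- sample.int(m$N, 1L, prob = pi0)
      for (j in seq_len(nrow(tr$edge))) {
        p <- tr$edge[j, 1L]; ch <- tr$edge[j, 2L]
        v <- numeric(m$N); v[st[p]] <- 1
        # column of exp(Q len) for the parent state
        pr <- (eig$U %*% (exp(eig$lam * tr$edge.length[j]) *
                          crossprod(eig$U, v * eig$ev))) / eig$ev
        pr <- pmax(as.numeric(pr), 0)
        st[ch] <- sample.int(m$N, 1L, prob = pr)
      }
      x <- m$x[st]
    } else {
      theta <- params$theta %||% params$z0
      x[ntip + 1L] <- params$z0
      for (j in seq_len(nrow(tr$edge))) {
        p <- tr$edge[j, 1L]; ch <- tr$edge[j, 2L]
        len <- tr$edge.length[j]
        x[ch] <- switch(model,
          BM = x[p] + rnorm(1L, 0, sqrt(params$sigma2 * len)),
          OU = {
            e <- exp(-params$alpha * len)
            v <- params$sigma2 * -expm1(-2 * params$alpha * len) /
              (2 * params$alpha)
            theta + (x[p] - theta) * e + rnorm(1L, 0, sqrt(v))
          },
          EB = {
            a <- params$a
            t1 <- depth[p]; t2 <- depth[ch]
            v <- if (a == 0) params$sigma2 * len
                 else params$sigma2 * (exp(a * t2) - exp(a * t1)) / a
            x[p] + rnorm(1L, 0, sqrt(v))
          })
      }
    }
    tips <- setNames(x[seq_len(ntip)], tree$tip.label)
    states <- x[ntip + seq_len(tree$Nnode)]
    names(states) <- ntip + seq_len(tree$Nnode)
    list(tips = tips, node_states = states, model = model, params = params)
  })
}

#' Synthesize a measurement row from target trait scores
#'
#' Inverts the trait formulas: reference lengths are fixed at 1 mm and
#' widths/constrictions derived so [score_traits()] reproduces the
#' targets exactly (round-trip).  The illusion target must be one of
#' 0, 0.334, 0.667, 1.
#'
#' @param target_scores Named numeric vector over [trait_names()] (or a
#'   `trait_scores` object).
#' @param seed Optional seed; used to pick which illusion flags are set
#'   and, with `scale_noise`, a realistic overall body scale.
#' @param specimen_id Identifier for the synthesized row.
#' @param scale_noise If `TRUE`, all lengths are multiplied by a common
#'   random scale (lognormal around ~3 mm, the typical body size of
#'   myrmecomorphic spiders); ratios, and hence scores, are unchanged.
#' @return A [specimen_measurements()] record.
#' @export
synthesize_measurements <- function(target_scores, seed = NULL,
                                    specimen_id = "synthetic",
                                    scale_noise = FALSE) {
  s <- unclass(target_scores)[trait_names()]
  if (anyNA(s)) stop_mm("all nine target scores are required")
  if (any(s < 0 | s > 1)) stop_mm("targets must lie in [0, 1]")
  ill <- s[["illusion_coloration"]]
  lvl <- which(abs(.illusion_levels - ill) < 1e-9)
  if (!length(lvl))
    stop_mm("unreachable illusion target %g (must be 0, 0.334, 0.667 or 1)",
            ill)
  nflag <- lvl - 1L
  ratio <- s[c("thin_legs", "elong_ceph", "elong_abd",
               "constr_ceph_lat", "constr_ceph_dors",
               "constr_abd_lat", "constr_abd_dors")]
  if (any(ratio >= 1))
    stop_mm("ratio targets must be < 1 (a score of 1 needs a zero measurement)")
  if (s[["elong_pedicel"]] >= 1)
    stop_mm("pedicel target must be < 1")

  run <- function() {
    scale <- if (scale_noise) exp(rnorm(1L, log(3), 0.3)) else 1
    flags <- rep(FALSE, 3L)
    if (nflag > 0L)
      flags[if (is.null(seed)) seq_len(nflag)
            else sample.int(3L, nflag)] <- TRUE
    # pedicel: f / (c + e + f) = s  =>  f = s (c + e) / (1 - s)
    f <- s[["elong_pedicel"]] * 2 / (1 - s[["elong_pedicel"]])
    specimen_measurements(
      specimen_id = specimen_id,
      femur3_length = scale, femur3_width = (1 - s[["thin_legs"]]) * scale,
      ceph_width = (1 - s[["elong_ceph"]]) * scale, ceph_length = scale,
      abd_width = (1 - s[["elong_abd"]]) * scale, abd_length = scale,
      pedicel_length = f * scale,
      ceph_width_at_constriction =
        (1 - s[["constr_ceph_dors"]]) * (1 - s[["elong_ceph"]]) * scale,
      ceph_height_at_constriction =
        (1 - s[["constr_ceph_lat"]]) * scale,
      ceph_height_max = scale,
      abd_width_at_constriction =
        (1 - s[["constr_abd_dors"]]) * (1 - s[["elong_abd"]]) * scale,
      abd_height_at_constriction = (1 - s[["constr_abd_lat"]]) * scale,
      abd_height_max = scale,
      illusion_abd_band = flags[1L], illusion_ceph_band = flags[2L],
      illusion_eye_dark = flags[3L])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Perturb a tree into a pseudo-posterior sample
#'
#' Emulates posterior spread around a consensus tree: internal-node ages
#' are multiplied by independent lognormal noise (mean 1, log-sd =
#' `jitter`), clipped below each node's parent so the trees stay
#' ultrametric with non-negative branches; topology is unchanged.
#'
#' @param tree Ultrametric `phylo`.
#' @param count Number of trees to generate.
#' @param jitter Lognormal log-sd (0 returns exact copies).
#' @param seed Integer seed.
#' @return A `multiPhylo` of `count` trees.
#' @export
perturb_tree_sample <- function(tree, count, jitter, seed) {
  tree <- validate_tree(tree)
  if (jitter < 0) stop_mm("jitter must be >= 0")
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth) - depth
  age[seq_len(ntip)] <- 0
  # preorder over internal nodes (parents before children)
  ord <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1L])
  parent_of <- integer(length(age))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  with_seed(seed, {
    out <- vector("list", count)
    for (k in seq_len(count)) {
      a2 <- age
      if (jitter > 0) {
        for (nd in ord) {
          prop <- age[nd] * exp(rnorm(1L, -jitter^2 / 2, jitter))
          cap <- if (nd == ntip + 1L) Inf else a2[parent_of[nd]]
          a2[nd] <- min(prop, cap)
        }
      }
      tr <- tree
      tr$edge.length <- a2[tree$edge[, 1L]] - a2[tree$edge[, 2L]]
      out[[k]] <- tr
    }
    class(out) <- "multiPhylo"
    out
  })
}
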