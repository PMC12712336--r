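test_that("birth-death trees are ultrametric, sized and reproducible", {
  cfg <- sim_config(seed = 11, n_tips = 50)
  t1 <- simulate_tree(cfg)
  expect_equal(length(t1$tip.label), 50L)
  expect_true(is_ultrametric(t1, tol = 1e-9))
  expect_identical(ape::write.tree(simulate_tree(cfg)), ape::write.tree(t1))
  expect_error(sim_config(seed = 1, n_tips = 2), "3 tips")
  expect_error(sim_config(seed = 1, birth = 0.1, death = 0.2), "death")
  expect_error(sim_config(), "seed")
})

test_that("pure-birth internode intervals follow the Exp(k*lambda) law", {
  # while k lineages exist, the waiting time to the next speciation is
  # exponential with rate k*lambda, so k*lambda*w_k has mean 1; the last
  # (present-truncated) interval is excluded
  b <- 0.3; n <- 30
  vals <- unlist(lapply(1:300, function(r) {
    tr <- simulate_tree(sim_config(seed = 5000 + r, n_tips = n,
                                   birth = b, death = 0))
    bt <- sort(ape::branching.times(tr), decreasing = TRUE)
    ks <- 2:(n - 1)
    ks * b * (bt[ks - 1] - bt[ks])
  }))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 1), 3 * se)
})

test_that("extinction shortens relative terminal branches at equal tip count", {
  # reconstructed trees with extinction have nodes pushed toward the
  # present; heights differ between the death regimes, so terminal
  # branches are compared relative to tree height
  term_med <- function(dth, off) median(vapply(1:100, function(r) {
    tr <- simulate_tree(sim_config(seed = off + r, n_tips = 40,
                                   birth = 0.3, death = dth))
    median(tr$edge.length[tr$edge[, 2] <= 40]) / tree_height(tr)
  }, numeric(1)))
  expect_lt(term_med(0.15, 6000), term_med(0, 7000))
})

test_that("trait simulation matches the model variance laws", {
  # zero-height tree: tips equal the root state under every model
  star0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  for (md in c("BM", "OU", "EB")) {
    p <- list(sigma2 = 1, z0 = 0.37, alpha = 2, a = -0.5)
    expect_equal(unname(simulate_trait(star0, md, p, seed = 1)$tips),
                 rep(0.37, 3))
  }
  # BM on one branch of length T: Var(tip - root) = sigma2 * T
  t2 <- parse_tree("(A:4,B:4):0;")
  d <- vapply(1:2000, function(r)
    simulate_trait(t2, "BM", list(sigma2 = 0.5, z0 = 0), seed = r)$tips[["A"]],
    numeric(1))
  expect_lt(abs(var(d) / (0.5 * 4) - 1), 0.05)
  # OU with alpha*T >> 1: tip variance = sigma2 / (2 alpha)
  tou <- parse_tree("(A:30,B:30):0;")
  d2 <- vapply(1:2000, function(r)
    simulate_trait(tou, "OU", list(sigma2 = 0.4, z0 = 0, alpha = 0.5),
                   seed = 10000 + r)$tips[["A"]], numeric(1))
  expect_lt(abs(var(d2) / (0.4 / (2 * 0.5)) - 1), 0.05)
  # EB(a=0) increments match BM exactly at equal seed
  tr <- rand_tree(10, 150)
  expect_equal(
    simulate_trait(tr, "EB", list(sigma2 = 1, z0 = 0, a = 0), seed = 3)$tips,
    simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 3)$tips)
  # node states are returned for every internal node
  sim <- simulate_trait(tr, "BM", list(sigma2 = 1, z0 = 0), seed = 4)
  expect_equal(length(sim$node_states), tr$Nnode)
})

test_that("FPK simulation is consistent with its own likelihood grid", {
  m <- fpk_model(0, 3, 1.8, sigma2 = 0.02, bounds = c(0, 0.5), N = 50)
  tr <- simulate_tree(sim_config(seed = 31, n_tips = 150))
  sim <- simulate_trait(tr, "FPK", list(fpk = m), seed = 32)
  expect_true(all(sim$tips > 0 & sim$tips < 0.5))  # bounded by construction
  expect_true(all(sim$tips %in% m$x))              # states live on the grid
  # long branches: tip spread approximates the stationary density spread
  pi0 <- stationary_density(m)$density
  sd_stat <- sqrt(sum(pi0 * m$x^2) - sum(pi0 * m$x)^2)
  expect_lt(abs(sd(sim$tips) / sd_stat - 1), 0.35)
})

test_that("measurement synthesis inverts the scoring formulas", {
  tgt <- setNames(c(0.71, rep(0, 7), 0), trait_names())
  m <- synthesize_measurements(tgt)
  expect_equal(m$femur3_width / m$femur3_length, 0.29)
  expect_equal(score_traits(m)[["thin_legs"]], 0.71)
  tgt2 <- setNames(c(rep(0, 8), 0.667), trait_names())
  m2 <- synthesize_measurements(tgt2, seed = 1)
  expect_equal(sum(m2$illusion_abd_band, m2$illusion_ceph_band,
                   m2$illusion_eye_dark), 2)
  z <- setNames(rep(0, 9), trait_names())
  mz <- synthesize_measurements(z)
  expect_equal(unname(unclass(score_traits(mz))), rep(0, 9))
  expect_equal(mz$ceph_width, mz$ceph_length)
  bad <- z; bad[["illusion_coloration"]] <- 0.5
  expect_error(synthesize_measurements(bad), "unreachable")
  bad2 <- z; bad2[["thin_legs"]] <- 1
  expect_error(synthesize_measurements(bad2), "< 1")
})

test_that("tree perturbation keeps topology and ultrametricity", {
  tr <- simulate_tree(sim_config(seed = 41, n_tips = 40))
  same <- perturb_tree_sample(tr, 3, jitter = 0, seed = 42)
  for (k in 1:3) expect_equal(same[[k]]$edge.length, tr$edge.length)
  jit <- perturb_tree_sample(tr, 200, jitter = 0.05, seed = 43)
  expect_true(all(vapply(jit, function(t) identical(t$edge, tr$edge),
                         logical(1))))
  expect_true(all(vapply(jit, is_ultrametric, logical(1))))
  expect_true(all(vapply(jit, function(t) min(t$edge.length) >= 0,
                         logical(1))))
  hts <- vapply(jit, tree_height, numeric(1))
  expect_lt(abs(mean(hts) / tree_height(tr) - 1), 0.02)
  expect_error(perturb_tree_sample(tr, 2, jitter = -1, seed = 1), "jitter")
})
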