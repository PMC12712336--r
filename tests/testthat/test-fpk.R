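test_that("stationary density matches the potential analytically", {
  # flat potential -> uniform, flat flag, midpoint optimum
  m0 <- fpk_model(0, 0, 0, 1, bounds = c(0, 1), N = 40)
  l0 <- stationary_density(m0)
  expect_true(l0$flat)
  expect_equal(l0$density, rep(1 / 40, 40))
  expect_equal(l0$optimum, 0.5)
  # symmetric bowl -> unimodal, optimum at the centre
  m1 <- fpk_model(0, 3, 0, 1, bounds = c(-2, 2), N = 41)
  l1 <- stationary_density(m1)
  expect_equal(l1$optimum, 0)
  expect_equal(l1$n_modes, 1L)
  expect_equal(l1$density, rev(l1$density))
  # tilted bowl: optimum at z = -c/(2b) within one grid step
  m2 <- fpk_model(0, 3, 1.2, 1, bounds = c(0, 1), N = 100)
  l2 <- stationary_density(m2)
  zopt <- m2$z[which.max(l2$density)]
  expect_lt(abs(zopt - (-1.2 / 6)), m2$hz + 1e-12)
  # double well from a < 0 is flagged multimodal
  m3 <- fpk_model(-4, 4, 0, 1, bounds = c(0, 1), N = 80)
  expect_gt(stationary_density(m3)$n_modes, 1L)
  # extreme potentials never overflow
  m4 <- fpk_model(0, 500, 100, 1, bounds = c(0, 1), N = 50)
  expect_true(all(is.finite(stationary_density(m4)$density)))
})

test_that("generator conserves probability and fixes exp(-V)", {
  m <- fpk_model(1, 2, 0.5, 0.05, bounds = c(0, 1), N = 50)
  Q <- fpk_generator(m)
  expect_lt(max(abs(colSums(Q))), 1e-10)
  pi0 <- stationary_density(m)$density
  expect_lt(max(abs(Q %*% pi0)), 1e-10)
  # branch transition tables are stochastic: propagate basis vectors
  eig <- .fpk_eig(m)
  for (len in c(0.1, 1, 10)) {
    P <- sapply(seq_len(m$N), function(i) {
      v <- numeric(m$N); v[i] <- 1
      as.numeric((eig$U %*% (exp(eig$lam * len) *
                             crossprod(eig$U, v * eig$ev))) / eig$ev)
    })
    expect_lt(max(abs(colSums(P) - 1)), 1e-10)
    expect_gt(min(P), -1e-12)
  }
})

test_that("pruning likelihood: star-tree base case and mass conservation", {
  m <- fpk_model(0, 2, 0.4, 0.05, bounds = c(0, 1), N = 50)
  # zero-length star tree, all tips in one grid cell: no propagation,
  # the root partial is the shared indicator, so lnL = log pi(cell) - n log h
  star <- ape::read.tree(text = "(A:0,B:0,C:0);")
  yv <- m$x[20] + c(A = 0, B = 0, C = 0)
  pi0 <- stationary_density(m)$density
  expect_equal(fpk_loglik(m, star, yv),
               log(pi0[20]) - 3 * log(m$hx), tolerance = 1e-10)
  # any initial distribution keeps total mass 1 along any branch
  eig <- .fpk_eig(m)
  for (r in 1:5) {
    v <- with_seed(r, runif(m$N)); v <- v / sum(v)
    w <- as.numeric((eig$U %*% (exp(eig$lam * with_seed(r, runif(1, 0, 20))) *
                                crossprod(eig$U, v * eig$ev))) / eig$ev)
    expect_lt(abs(sum(w) - 1), 1e-10)
    expect_gt(min(w), -1e-12)
  }
})

test_that("flat potential with wide bounds approaches the BM likelihood", {
  tr <- rand_tree(6, 90)
  y <- simulate_trait(tr, "BM", list(sigma2 = 0.02, z0 = 0.3),
                      seed = 91)$tips
  b <- c(mean(y) - 20 * sd(y), mean(y) + 20 * sd(y))
  m <- fpk_model(0, 0, 0, sigma2 = 0.02, bounds = b, N = 400)
  z0 <- fit_model("BM", tr, y)$params$z0
  bm <- loglik_gaussian("BM", list(sigma2 = 0.02, z0 = z0), tr, y)
  expect_lt(abs(fpk_loglik(m, tr, y, root = "ml") - bm), 0.1)
})

test_that("likelihood is stable under grid refinement", {
  tr <- rand_tree(8, 95)
  y <- simulate_trait(tr, "BM", list(sigma2 = 0.02, z0 = 0.3),
                      seed = 96)$tips
  r <- range(y); w <- diff(r)
  b <- c(r[1] - 0.5 * w, r[2] + 0.5 * w)
  l1 <- fpk_loglik(fpk_model(0, 2, 0.5, 0.02, b, N = 50), tr, y)
  l2 <- fpk_loglik(fpk_model(0, 2, 0.5, 0.02, b, N = 100), tr, y)
  expect_lt(abs(l2 - l1), 0.05)
})

test_that("quadratic potential reproduces the matched OU stationary normal", {
  # V = b z^2 -> stationary N(0, 1/(2b)) on the normalized axis
  b <- 4
  m <- fpk_model(0, b, 0, 1, bounds = c(-1, 1), N = 100)
  dens <- stationary_density(m)$density
  ref <- dnorm(m$z, 0, sqrt(1 / (2 * b))) * m$hz
  ref <- ref / sum(ref)
  expect_lt(0.5 * sum(abs(dens - ref)), 0.02)
})

test_that("tip values outside the bounds are rejected with guidance", {
  m <- fpk_model(0, 1, 0, 1, bounds = c(0, 1), N = 30)
  tr <- parse_tree("(A:1,B:1):0;")
  expect_error(fpk_loglik(m, tr, c(A = 0.5, B = 1.4)), "expand the bounds")
})

test_that("FPK fitting recovers a known landscape optimum", {
  # stationary world: optimum at trait 0.20 inside bounds [0, 0.5],
  # mixing fast relative to tree height (t1/2 << height)
  n_rep <- 8
  opt <- vapply(seq_len(n_rep), function(r) {
    tr <- simulate_tree(sim_config(seed = 3000 + r, n_tips = 100))
    m_true <- fpk_model(0, 3, 1.8, sigma2 = 0.01, bounds = c(0, 0.5), N = 50)
    sim <- simulate_trait(tr, "FPK", list(fpk = m_true), seed = 4000 + r)
    suppressWarnings(fit_fpk(tr, sim$tips))$landscape$optimum
  }, numeric(1))
  expect_lt(median(abs(opt - 0.20)), 0.03)
})
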