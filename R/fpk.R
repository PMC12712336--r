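# Bounded trait diffusion under a quartic evolutionary potential
# (FPK / bounded-Brownian-motion-with-potential family).
#
# The trait lives on a bounded interval [x_min, x_max], mapped affinely
# to a normalized axis z in [-1.5, 1.5] on which the potential
# V(z) = a z^4 + b z^2 + c z is expressed; exp(-V) is the stationary
# (adaptive-landscape) density.  The likelihood discretizes the axis to
# N grid points and propagates distributions along branches with the
# exponential of a tridiagonal generator whose off-diagonal rates
# combine diffusion (sigma^2, on the ORIGINAL trait scale) and drift
# down the potential gradient; detailed balance makes exp(-V) exactly
# stationary at any N.

.fpk_zhalf <- 1.5  # normalized axis is [-zhalf, zhalf]

#' Construct an FPK (bounded-diffusion) model
#'
#' @param a,b,c Coefficients of the potential \eqn{V(z) = a z^4 + b z^2
#'   + c z} on the normalized axis \eqn{z \in [-1.5, 1.5]}.
#' @param sigma2 Diffusion rate on the original trait scale
#'   (trait\eqn{^2}/Ma).
#' @param bounds Numeric length-2: trait bounds `(x_min, x_max)`.
#' @param N Grid size (>= 20; default 50).
#' @return List of class `fpk_model` with the grid (`x` original scale,
#'   `z` normalized) and potential values `V`.
#' @export
fpk_model <- function(a = 0, b = 0, c = 0, sigma2 = 1,
                      bounds = c(0, 1), N = 50L) {
  if (bounds[1L] >= bounds[2L]) stop_mm("x_min must be < x_max")
  if (N < 20L) stop_mm("grid size N must be >= 20")
  if (sigma2 <= 0) stop_mm("sigma2 must be > 0")
  z <- seq(-.fpk_zhalf, .fpk_zhalf, length.out = N)
  x <- bounds[1L] + (z + .fpk_zhalf) / (2 * .fpk_zhalf) * diff(bounds)
  V <- a * z^4 + b * z^2 + c * z
  if (any(!is.finite(V))) stop_mm("potential not finite on grid")
  structure(list(a = a, b = b, c = c, sigma2 = sigma2,
                 bounds = as.numeric(bounds), N = as.integer(N),
                 z = z, x = x, V = V,
                 hx = diff(bounds) / (N - 1),
                 hz = 2 * .fpk_zhalf / (N - 1)),
            class = "fpk_model")
}

#' Stationary density / adaptive landscape of an FPK model
#'
#' The normalized discrete density \eqn{\pi \propto \exp(-V)} over the
#' grid, with the optimum (grid argmax) and a modality flag.
#'
#' @param m An [fpk_model()].
#' @return List of class `fpk_landscape`: `x`, `z`, `density` (sums to
#'   1), `optimum` (trait value at the maximum; interval midpoint when
#'   the landscape is flat), `n_modes`, `flat`.
#' @export
stationary_density <- function(m) {
  stopifnot(inherits(m, "fpk_model"))
  lw <- -m$V
  dens <- exp(lw - logsumexp(lw))
  flat <- diff(range(m$V)) < 1e-12
  d <- diff(dens)
  # local maxima of the discrete density (plateau-tolerant)
  sgn <- sign(d)[sign(d) != 0]
  n_modes <- if (flat || length(sgn) == 0L) 1L
             else sum(diff(sgn) < 0) + as.integer(sgn[1L] < 0) +
                  as.integer(sgn[length(sgn)] > 0)
  optimum <- if (flat) mean(m$bounds) else m$x[which.max(dens)]
  structure(list(x = m$x, z = m$z, density = dens, optimum = optimum,
                 n_modes = n_modes, flat = flat),
            class = "fpk_landscape")
}

# sigma^2 on the normalized z axis
.fpk_sigma2_z <- function(m) {
  m$sigma2 * (2 * .fpk_zhalf / diff(m$bounds))^2
}

#' FPK generator matrix
#'
#' The N-by-N tridiagonal rate matrix Q of the discretized diffusion:
#' nearest-neighbour rates \eqn{(\sigma_z^2/2h^2)\exp((V_i - V_j)/2)}
#' so that columns sum to zero and \eqn{\exp(-V)} satisfies detailed
#' balance.  `exp(Q t)` maps a state distribution at a branch start to
#' the distribution at its end.
#'
#' @param m An [fpk_model()].
#' @return Matrix Q (columns sum to 0).
#' @export
fpk_generator <- function(m) {
  N <- m$N; V <- m$V
  k <- .fpk_sigma2_z(m) / (2 * m$hz^2)
  Q <- matrix(0, N, N)
  i <- seq_len(N - 1L)
  up <- k * exp((V[i] - V[i + 1L]) / 2)      # rate i -> i+1
  dn <- k * exp((V[i + 1L] - V[i]) / 2)      # rate i+1 -> i
  Q[cbind(i + 1L, i)] <- up
  Q[cbind(i, i + 1L)] <- dn
  diag(Q) <- -colSums(Q)
  Q
}

# eigendecomposition of the symmetrized generator; exp(Q t) p =
# D^-1 U exp(L t) U' D p with D = diag(exp(V/2))
.fpk_eig <- function(m) {
  Q <- fpk_generator(m)
  S <- Q
  # conjugation by diag(exp(V/2)) leaves the diagonal and, by
  # construction, makes off-diagonals equal to the symmetric rate k
  ev <- exp(m$V / 2)
  S <- diag(ev) %*% Q %*% diag(1 / ev)
  S <- (S + t(S)) / 2  # kill rounding asymmetry
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors, lam = e$values, ev = ev)
}

#' FPK log-likelihood by pruning
#'
#' Felsenstein pruning on the discretized trait grid: tip states are
#' point masses at the nearest grid cell, branch propagation uses the
#' matrix exponential of the generator (via eigendecomposition of its
#' symmetrization), and the root partial likelihood is combined with
#' the chosen root measure.  Cell masses are converted to densities on
#' the trait scale (division by the grid step per tip) so values are
#' comparable with Gaussian model log-likelihoods.
#'
#' @param m An [fpk_model()].
#' @param tree Rooted `phylo` object.
#' @param y Named tip values; all must lie inside `m$bounds`.
#' @param root Root-state treatment: `"stationary"` (default) integrates
#'   against the stationary density \eqn{\propto \exp(-V)}; `"ml"`
#'   profiles (maximizes over) the root state -- the form in which the
#'   flat-potential/wide-bounds limit equals the fixed-root Brownian
#'   likelihood; `"flat"` integrates against a uniform measure.
#' @return Log-likelihood (scalar).
#' @export
fpk_loglik <- function(m, tree, y,
                       root = c("stationary", "ml", "flat")) {
  root <- match.arg(root)
  stopifnot(inherits(m, "fpk_model"))
  y <- check_tip_match(tree, y)
  if (any(y <= m$bounds[1L] | y >= m$bounds[2L]))
    stop_mm(paste("tip value(s) outside the FPK bounds [%g, %g];",
                  "expand the bounds"), m$bounds[1L], m$bounds[2L])
  eig <- .fpk_eig(m)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")

  partial <- matrix(NA_real_, m$N, nnode)
  scaler <- numeric(nnode)
  # tip mass split linearly between the two flanking grid cells, so the
  # likelihood is first-order exact in the tip position (nearest-cell
  # rounding is what dominates grid sensitivity otherwise)
  pos <- (y - m$bounds[1L]) / m$hx
  lo <- pmin(pmax(floor(pos) + 1L, 1L), m$N - 1L)
  frac <- pmin(pmax(pos - (lo - 1L), 0), 1)
  for (i in seq_len(ntip)) {
    v <- numeric(m$N)
    v[lo[i]] <- 1 - frac[i]
    v[lo[i] + 1L] <- frac[i]
    partial[, i] <- v
  }
  # propagate child partial up a branch of length len
  prop <- function(v, len) {
    w <- eig$ev * (eig$U %*% (exp(eig$lam * len) *
                              crossprod(eig$U, v / eig$ev)))
    pmax(as.numeric(w), 0)
  }
  parents <- unique(tr$edge[, 1L])  # postorder: children before parents
  for (p in parents) {
    idx <- which(tr$edge[, 1L] == p)
    acc <- rep(1, m$N); sc <- 0
    for (j in idx) {
      ch <- tr$edge[j, 2L]
      w <- prop(partial[, ch], tr$edge.length[j])
      acc <- acc * w
      sc <- sc + scaler[ch]
      mx <- max(acc)
      if (mx > 0 && (mx < 1e-12 || mx > 1e12)) {
        acc <- acc / mx; sc <- sc + log(mx)
      }
    }
    partial[, p] <- acc
    scaler[p] <- sc
  }
  rt <- ntip + 1L
  ll_mass <- switch(root,
    stationary = {
      pi0 <- stationary_density(m)$density
      tot <- sum(pi0 * partial[, rt])
      if (tot <= 0) -Inf else log(tot)
    },
    ml = {
      mx <- max(partial[, rt])
      if (mx <= 0) -Inf else log(mx)
    },
    flat = {
      tot <- mean(partial[, rt])
      if (tot <= 0) -Inf else log(tot)
    })
  ll_mass + scaler[rt] - ntip * log(m$hx)
}

#' Fit the FPK model by maximum likelihood
#'
#' Estimates the potential coefficients (a, b, c) and diffusion rate
#' \eqn{\sigma^2} by bounded multi-start quasi-Newton optimization, and
#' returns the fitted adaptive landscape.  AICc uses k = 5 (a, b, c,
#' \eqn{\sigma^2}, root measure) so the fit is comparable with the
#' Gaussian models.
#'
#' @param tree Rooted `phylo`.
#' @param y Named tip values.
#' @param bounds Trait bounds; default expands the observed range by
#'   50\% on each side.
#' @param N Grid size (default 50).
#' @param n_starts Number of optimizer starts (>= 1); starts are a fixed
#'   design (flat, bowl, tilted) so the fit is deterministic.
#' @param coef_bound Box bound on |a|, |b|, |c|.
#' @param root Root-state treatment passed to [fpk_loglik()].
#' @return List of class `fpk_fit`: `model` (an [fpk_model()]),
#'   `landscape`, `lnL`, `k`, `n`, `AICc`, `convergence`.
#' @export
fit_fpk <- function(tree, y, bounds = NULL, N = 50L, n_starts = 3L,
                    coef_bound = 20, root = "stationary") {
  y <- check_tip_match(tree, y)
  n <- length(y)
  if (n < 6L) stop_mm("FPK fit needs at least 6 tips")
  if (is.null(bounds)) {
    r <- range(y); w <- diff(r)
    if (w == 0) w <- max(abs(r[1L]), 1e-3)
    bounds <- c(r[1L] - 0.5 * w, r[2L] + 0.5 * w)
  }
  s2_bm <- fit_model("BM", tree, y)$params$sigma2

  negll <- function(p) {
    m <- fpk_model(a = p[1L], b = p[2L], c = p[3L], sigma2 = exp(p[4L]),
                   bounds = bounds, N = N)
    ll <- tryCatch(fpk_loglik(m, tree, y, root = root),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(c(0, 0, 0, log(s2_bm)),
                 c(0, 2, 0, log(s2_bm)),
                 c(-1, 4, 1, log(s2_bm)))
  starts <- starts[seq_len(max(1L, min(n_starts, length(starts))))]
  lower <- c(-coef_bound, -coef_bound, -coef_bound, log(1e-8))
  upper <- c(coef_bound, coef_bound, coef_bound, log(1e3))
  best <- NULL
  conv_ok <- FALSE
  for (s in starts) {
    o <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300L)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv_ok <- o$convergence == 0L
    }
  }
  if (is.null(best)) stop_mm("FPK optimization failed from every start")
  p <- best$par
  m <- fpk_model(a = p[1L], b = p[2L], c = p[3L], sigma2 = exp(p[4L]),
                 bounds = bounds, N = N)
  land <- stationary_density(m)
  lnL <- -best$value
  at_edge <- !land$flat &&
    which.max(land$density) %in% c(1L, m$N)
  if (at_edge)
    warning("fitted landscape optimum lies at a grid boundary",
            call. = FALSE)
  structure(list(model = m, landscape = land, lnL = lnL, k = 5L, n = n,
                 AICc = .aicc(lnL, 5L, n),
                 convergence = list(converged = conv_ok,
                                    optimum_at_boundary = at_edge)),
            class = "fpk_fit")
}

#' @export
print.fpk_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf(
    "FPK fit: lnL = %.4f, AICc = %.4f (n = %d)\n", x$lnL, x$AICc, x$n))
  cat(sprintf("  V(z) = %.4g z^4 + %.4g z^2 + %.4g z; sigma2 = %.4g\n",
              m$a, m$b, m$c, m$sigma2))
  cat(sprintf("  bounds [%.4g, %.4g]; landscape optimum at %.4g (%s)\n",
              m$bounds[1L], m$bounds[2L], x$landscape$optimum,
              if (x$landscape$n_modes > 1L) "multimodal" else "unimodal"))
  invisible(x)
}
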