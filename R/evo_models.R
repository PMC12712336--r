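# Maximum-likelihood fitting and AICc comparison of Gaussian
# trait-evolution models: BM, single-optimum OU (fixed root, theta
# identified with the root state, k = 3), early burst, white noise.
#
# All likelihoods are exact multivariate-normal densities computed via
# Cholesky factorization of the model covariance; sigma^2 and the mean
# are profiled out analytically so OU and EB fitting reduce to bounded
# one-dimensional optimization (deterministic grid scan + refinement).

.sigma2_bounds <- c(1e-8, 1e3)

# unit-rate covariance structure for each model; S = shared-time matrix
model_structure <- function(model, tree, par = NULL) {
  S <- phylo_covariance(tree)
  switch(model,
    BM = S,
    OU = {
      alpha <- par
      ti <- diag(S)
      # fixed-root OU: cov_ij = exp(-a(ti+tj-2s)) * (1-exp(-2as)) / (2a)
      exp(-alpha * (outer(ti, ti, `+`) - 2 * S)) *
        (-expm1(-2 * alpha * S)) / (2 * alpha)
    },
    EB = {
      a <- par
      if (a == 0) S else expm1(a * S) / a
    },
    WN = diag(nrow(S)) * mean(diag(S)),  # placeholder; WN handled directly
    stop_mm("unknown model '%s'", model))
}

# profile statistics for y ~ N(mu 1, sigma2 * V0)
.gauss_profile <- function(V0, y) {
  R <- tryCatch(chol(V0), error = function(e)
    stop_mm("singular covariance: %s", conditionMessage(e)))
  logdet <- 2 * sum(log(diag(R)))
  iy <- backsolve(R, forwardsolve(t(R), y))
  i1 <- backsolve(R, forwardsolve(t(R), rep(1, length(y))))
  mu <- sum(i1 * y) / sum(i1)
  r <- y - mu
  Q <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  list(mu = mu, Q = max(Q, 0), logdet = logdet,
       mu_var_unit = 1 / sum(i1))
}

.profile_lnl <- function(prof, n, sigma2) {
  -0.5 * (n * log(2 * pi) + n * log(sigma2) + prof$logdet + prof$Q / sigma2)
}

# concentrated lnL with sigma2 at its (bounded) ML value
.conc_fit <- function(V0, y) {
  n <- length(y)
  prof <- .gauss_profile(V0, y)
  s2 <- min(max(prof$Q / n, .sigma2_bounds[1L]), .sigma2_bounds[2L])
  list(prof = prof, sigma2 = s2, lnL = .profile_lnl(prof, n, s2),
       at_bound = prof$Q / n < .sigma2_bounds[1L] ||
                  prof$Q / n > .sigma2_bounds[2L])
}

#' Gaussian trait-evolution log-likelihood
#'
#' Exact multivariate-normal log-density of tip values under a named
#' model and explicit parameters.  Models: `BM` (`sigma2`, `z0`), `OU`
#' (`sigma2`, `z0` = optimum/root state, `alpha`), `EB` (`sigma2`, `z0`,
#' `a` <= 0), `WN` (`wn_mean`, `wn_variance`; tips independent).
#'
#' @param model Model id.
#' @param params Named list of parameters (see Details).
#' @param tree A rooted `phylo` object.
#' @param y Named numeric vector of tip values.
#' @return Log-likelihood (scalar).
#' @export
loglik_gaussian <- function(model = c("BM", "OU", "EB", "WN"), params,
                            tree, y) {
  model <- match.arg(model)
  y <- check_tip_match(tree, y)
  n <- length(y)
  if (model == "WN") {
    return(sum(dnorm(y, params$wn_mean, sqrt(params$wn_variance),
                     log = TRUE)))
  }
  if (model == "OU" && params$alpha <= 0) stop_mm("OU requires alpha > 0")
  if (model == "EB" && params$a > 0) stop_mm("EB requires a <= 0")
  if (params$sigma2 <= 0) stop_mm("sigma2 must be > 0")
  V0 <- model_structure(model, tree,
                        par = switch(model, OU = params$alpha,
                                     EB = params$a, NULL))
  R <- tryCatch(chol(params$sigma2 * V0), error = function(e)
    stop_mm("singular covariance (duplicate zero-length tips?): %s",
            conditionMessage(e)))
  r <- y - params$z0
  q <- sum(forwardsolve(t(R), r)^2)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + q)
}

.aicc <- function(lnL, k, n) {
  if (n - k - 1 <= 0) stop_mm("AICc undefined: n <= k + 1")
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# deterministic bounded 1-D ML: grid scan then golden-section refinement
.scan_optimize <- function(f, lower, upper, ngrid = 25L, log_scale = FALSE) {
  grid <- if (log_scale) exp(seq(log(lower), log(upper), length.out = ngrid))
          else seq(lower, upper, length.out = ngrid)
  vals <- vapply(grid, f, numeric(1L))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(ngrid, i + 1L)]
  opt <- optimize(f, lower = lo, upper = hi, maximum = TRUE,
                  tol = 1e-10 * (hi - lo) + 1e-14)
  if (opt$objective >= vals[i])
    list(par = opt$maximum, value = opt$objective,
         at_bound = i %in% c(1L, ngrid))
  else
    list(par = grid[i], value = vals[i], at_bound = i %in% c(1L, ngrid))
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' Fits one of BM, OU, EB or WN to tip data on a phylogeny.  The rate
#' \eqn{\sigma^2} and the mean are profiled out analytically; the OU
#' pull \eqn{\alpha} and EB decay `a` are estimated by a deterministic
#' bounded scan-and-refine search (bounds: \eqn{\sigma^2 \in [10^{-8},
#' 10^3]}, \eqn{\alpha \in [10^{-8}, 10^3/H]}, \eqn{a \in [-10/H, 0]}
#' with H the tree height).
#'
#' @param model Model id: `"BM"`, `"OU"`, `"EB"` or `"WN"`.
#' @param tree Rooted `phylo`; must be ultrametric for OU.
#' @param y Named tip values.
#' @param ngrid Grid size of the deterministic parameter scan.
#' @return A `model_fit` list: `model`, `params`, `lnL`, `k`, `n`,
#'   `AICc`, `convergence` (including boundary flags), `tree_height`.
#' @export
#' @examples
#' tr <- simulate_tree(sim_config(seed = 1, n_tips = 40))
#' y <- simulate_trait(tr, model = "BM", params = list(sigma2 = 1, z0 = 0),
#'                     seed = 2)$tips
#' fit_model("BM", tr, y)
fit_model <- function(model = c("BM", "OU", "EB", "WN"), tree, y,
                      ngrid = 25L) {
  model <- match.arg(model)
  y <- check_tip_match(tree, y)
  n <- length(y)
  k <- switch(model, BM = 2L, OU = 3L, EB = 3L, WN = 2L)
  if (n < k + 2L) stop_mm("need at least %d tips for %s", k + 2L, model)
  H <- tree_height(tree)
  degenerate <- var(y) == 0
  if (degenerate)
    warning("constant tip values: rate estimate at lower bound",
            call. = FALSE)
  conv <- list(converged = TRUE, param_at_bound = FALSE,
               sigma2_at_bound = FALSE, degenerate = degenerate)

  if (model == "WN") {
    mu <- mean(y); v <- max(sum((y - mu)^2) / n, .sigma2_bounds[1L])
    lnL <- sum(dnorm(y, mu, sqrt(v), log = TRUE))
    params <- list(wn_mean = mu, wn_variance = v)
  } else if (model == "BM") {
    cf <- .conc_fit(model_structure("BM", tree), y)
    conv$sigma2_at_bound <- cf$at_bound
    params <- list(sigma2 = cf$sigma2, z0 = cf$prof$mu)
    lnL <- cf$lnL
  } else {
    S <- phylo_covariance(tree)
    ti <- diag(S)
    structure_at <- function(p) {
      if (model == "OU")
        exp(-p * (outer(ti, ti, `+`) - 2 * S)) *
          (-expm1(-2 * p * S)) / (2 * p)
      else if (p == 0) S else expm1(p * S) / p
    }
    obj <- function(p) .conc_fit(structure_at(p), y)$lnL
    if (model == "OU") {
      if (!is_ultrametric(tree))
        stop_mm("OU fit requires an ultrametric tree")
      opt <- .scan_optimize(obj, 1e-8, 1e3 / H, ngrid = ngrid,
                            log_scale = TRUE)
      cf <- .conc_fit(structure_at(opt$par), y)
      params <- list(sigma2 = cf$sigma2, z0 = cf$prof$mu,
                     theta = cf$prof$mu, alpha = opt$par)
    } else {
      obj_eb <- function(p) obj(min(p, 0))
      opt <- .scan_optimize(obj_eb, -10 / H, 0, ngrid = ngrid)
      a <- min(opt$par, 0)
      cf <- .conc_fit(structure_at(a), y)
      params <- list(sigma2 = cf$sigma2, z0 = cf$prof$mu, a = a)
    }
    conv$param_at_bound <- opt$at_bound
    conv$sigma2_at_bound <- cf$at_bound
    lnL <- cf$lnL
  }
  structure(list(model = model, params = params, lnL = lnL, k = k, n = n,
                 AICc = .aicc(lnL, k, n), convergence = conv,
                 tree_height = H),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, AICc = %.4f (k = %d, n = %d)\n",
              x$model, x$lnL, x$AICc, x$k, x$n))
  cat("  ", paste(names(x$params),
                  vapply(x$params, function(p) sprintf("%.6g", p), ""),
                  sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Compare fitted models by AICc weight
#'
#' Computes \eqn{\Delta}AICc relative to the best model and Akaike
#' weights \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param fits List of `model_fit` objects (same data and tree).
#' @return Data frame: `model`, `k`, `lnL`, `AICc`, `dAICc`, `weight`,
#'   ordered as given.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "model_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L)
  ns <- vapply(fits, `[[`, integer(1L), "n")
  if (length(unique(ns)) != 1L)
    stop_mm("fits are not on identical data (tip counts differ)")
  aicc <- vapply(fits, `[[`, numeric(1L), "AICc")
  d <- aicc - min(aicc)
  w <- exp(-d / 2); w <- w / sum(w)
  data.frame(model = vapply(fits, `[[`, character(1L), "model"),
             k = vapply(fits, `[[`, integer(1L), "k"),
             lnL = vapply(fits, `[[`, numeric(1L), "lnL"),
             AICc = aicc, dAICc = d, weight = w,
             stringsAsFactors = FALSE)
}

#' Phylogenetic half-life
#'
#' Time for the expected trait value to move halfway to the OU optimum:
#' \eqn{t_{1/2} = \ln 2 / \alpha}, also reported relative to tree
#' height.
#'
#' @param alpha OU pull parameter (> 0), units 1/Ma.
#' @param tree The phylogeny whose height scales the relative value.
#' @return List with `absolute` (Ma) and `relative` (fraction of tree
#'   height).
#' @export
phylogenetic_half_life <- function(alpha, tree) {
  if (!is.numeric(alpha) || alpha <= 0) stop_mm("alpha must be > 0")
  abs_hl <- log(2) / alpha
  list(absolute = abs_hl, relative = abs_hl / tree_height(tree))
}
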