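# Ancestral character estimation by rerooting model-transformed trees,
# and phylogenetic-signal statistics (Pagel's lambda, Blomberg's K).

# GLS root state (phylogenetic weighted mean) and its unit-rate variance
.gls_root <- function(V, y) {
  R <- chol(V)
  i1 <- backsolve(R, forwardsolve(t(R), rep(1, length(y))))
  list(mu = sum(i1 * y) / sum(i1), var_unit = 1 / sum(i1))
}

#' Ancestral states by rerooting the model-transformed tree
#'
#' Estimates internal-node trait values under the best-fitting Gaussian
#' model: the tree is first transformed so Brownian motion on it matches
#' the fitted model (identity for BM, the \eqn{\alpha} transform for OU,
#' the `a` scaling for EB), then for every internal node the transformed
#' tree is rerooted at that node and the node state taken as the GLS
#' root estimate (phylogenetic weighted mean) on the rerooted tree.
#'
#' @param tree Rooted `phylo` (ultrametric for OU).
#' @param y Named tip values.
#' @param best_model A `model_fit` from [fit_model()] (BM, OU or EB), or
#'   a model id string for a transform with explicit `par`.
#' @param par Transform parameter when `best_model` is a string.
#' @return Data frame: `node` (ape ids `ntip+1 ...`), `estimate`,
#'   `variance` (GLS root-state variance scaled by the fitted rate, `NA`
#'   when no rate is available).
#' @export
ancestral_states <- function(tree, y, best_model = "BM", par = NULL) {
  tree <- validate_tree(tree)
  y <- check_tip_match(tree, y)
  if (inherits(best_model, "model_fit")) {
    model <- best_model$model
    par <- switch(model, OU = best_model$params$alpha,
                  EB = best_model$params$a, NULL)
    sigma2 <- best_model$params$sigma2
  } else {
    model <- match.arg(best_model, c("BM", "OU", "EB"))
    sigma2 <- NA_real_
  }
  tt <- switch(model,
    BM = tree,
    OU = transform_tree(tree, "OU", par),
    EB = transform_tree(tree, "EB", par))
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  est <- vapply(nodes, function(nd) {
    rt <- reroot(tt, nd)
    g <- .gls_root(phylo_covariance(rt), y[rt$tip.label])
    c(g$mu, g$var_unit)
  }, numeric(2L))
  data.frame(node = nodes, estimate = est[1L, ],
             variance = if (is.na(sigma2)) NA_real_ else sigma2 * est[2L, ])
}

#' Pagel's lambda
#'
#' Maximum-likelihood estimate of the phylogenetic-signal parameter
#' \eqn{\lambda}: the Brownian-motion likelihood is maximized over
#' \eqn{\lambda}-transformed trees, \eqn{\lambda \in [0,
#' \lambda_{max}]}.
#'
#' @param tree Rooted `phylo`.
#' @param y Named tip values (non-constant).
#' @param cap_at_1 Restrict the search to \eqn{[0, 1]} (default `FALSE`:
#'   the upper limit is the largest \eqn{\lambda} keeping the covariance
#'   positive definite).
#' @param ngrid Grid size of the deterministic scan.
#' @return List of class `signal_estimate`: `statistic = "lambda"`,
#'   `estimate`, `lnL` (at the optimum), `lnL0` (at \eqn{\lambda = 0}),
#'   `lnL_max_endpoint` (at the upper limit), `upper`.
#' @export
pagel_lambda <- function(tree, y, cap_at_1 = FALSE, ngrid = 21L) {
  tree <- validate_tree(tree)
  y <- check_tip_match(tree, y)
  if (var(y) == 0) stop_mm("phylogenetic signal undefined for constant data")
  if (length(y) < 10L)
    warning("fewer than 10 tips: lambda estimate will be unstable",
            call. = FALSE)
  upper <- lambda_max(tree)
  if (cap_at_1) upper <- min(upper, 1)
  if (!is.finite(upper)) upper <- 1
  S <- phylo_covariance(tree)
  struct <- function(lam) {
    V <- S * lam
    diag(V) <- diag(S)
    V
  }
  # the covariance is exactly singular at lambda_max (a terminal branch
  # hits zero): treat failures as -Inf so the scan just avoids them
  obj <- function(lam) tryCatch(.conc_fit(struct(lam), y)$lnL,
                                error = function(e) -Inf)
  opt <- .scan_optimize(obj, 0, upper, ngrid = ngrid)
  structure(list(statistic = "lambda", estimate = opt$par,
                 lnL = opt$value, lnL0 = obj(0),
                 lnL_max_endpoint = obj(upper), upper = upper),
            class = "signal_estimate")
}

#' Blomberg's K
#'
#' Ratio-based phylogenetic-signal statistic calibrated so that its
#' expectation is 1 under Brownian motion:
#' \deqn{K = \frac{MSE_0 / MSE}{(\mathrm{tr}(C) - n / (\mathbf{1}^T
#' C^{-1} \mathbf{1})) / (n - 1)}}
#' where \eqn{MSE_0} is the mean squared deviation of the tips from the
#' phylogenetic (GLS) mean and \eqn{MSE} the GLS phylogenetically
#' corrected mean squared error.
#'
#' @param tree Rooted `phylo`.
#' @param y Named tip values (non-constant).
#' @return List of class `signal_estimate` with `statistic = "K"` and
#'   `estimate`.
#' @export
blomberg_k <- function(tree, y) {
  tree <- validate_tree(tree)
  y <- check_tip_match(tree, y)
  if (var(y) == 0) stop_mm("phylogenetic signal undefined for constant data")
  if (length(y) < 10L)
    warning("fewer than 10 tips: K estimate will be unstable",
            call. = FALSE)
  C <- phylo_covariance(tree)
  n <- length(y)
  R <- chol(C)
  i1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  a_hat <- sum(i1 * y) / sum(i1)
  r <- y - a_hat
  mse0 <- sum(r^2) / (n - 1)
  mse <- sum(r * backsolve(R, forwardsolve(t(R), r))) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(i1)) / (n - 1)
  structure(list(statistic = "K",
                 estimate = (mse0 / mse) / expected),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f\n",
              if (x$statistic == "lambda") "Pagel's lambda"
              else "Blomberg's K", x$estimate))
  invisible(x)
}
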