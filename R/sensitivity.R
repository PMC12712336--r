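# Phylogenetic sensitivity: replicate every model fit across a sample
# of trees (e.g., a posterior sample) and summarize the spread of fit
# statistics and derived parameters.

#' Replicate model fits across a tree sample
#'
#' Fits the requested models to the same tip data on every tree of a
#' sample and summarizes AICc, \eqn{\Delta}AICc, AICc weight, rate
#' \eqn{\sigma^2}, OU phylogenetic half-life and the FPK landscape
#' optimum across trees.  Per-tree fit failures are recorded and
#' excluded from the summaries (they do not abort the analysis).
#'
#' @param trees A `multiPhylo` (>= 2 trees, identical tip sets) or list
#'   of trees.
#' @param y Named tip values shared by all trees.
#' @param models Character vector from `BM`, `OU`, `EB`, `WN`, `FPK`.
#' @param sample_size Optional: draw this many trees (seeded, uniform,
#'   without replacement) before fitting; default uses all trees.
#' @param burnin_fraction Optional fraction of leading trees dropped
#'   before sampling (for raw posterior files; default 0).
#' @param seed Seed for the subsample draw.
#' @param fpk_N FPK grid size.
#' @return List of class `sensitivity_summary`: `per_tree` (long data
#'   frame: tree, model, lnL, AICc, dAICc, weight, sigma2,
#'   half_life_abs, half_life_rel, fpk_optimum), `summary` (median, min,
#'   max, IQR per model and statistic), `failures` (data frame), `n_trees`.
#' @export
analyze_tree_sample <- function(trees, y,
                                models = c("BM", "OU", "EB", "WN", "FPK"),
                                sample_size = NULL, burnin_fraction = 0,
                                seed = 1L, fpk_N = 50L) {
  trees <- validate_tree_sample(trees)
  if (length(trees) < 2L) stop_mm("need at least 2 trees")
  y <- check_tip_match(trees[[1L]], y)
  models <- match.arg(models, several.ok = TRUE)
  if (burnin_fraction > 0) {
    drop <- floor(length(trees) * burnin_fraction)
    trees <- trees[(drop + 1L):length(trees)]
    class(trees) <- "multiPhylo"
  }
  if (!is.null(sample_size) && sample_size < length(trees)) {
    idx <- with_seed(seed, sample.int(length(trees), sample_size))
    trees <- trees[sort(idx)]
    class(trees) <- "multiPhylo"
  }

  rows <- list()
  fails <- list()
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    res <- list()
    for (md in models) {
      out <- tryCatch({
        if (md == "FPK") {
          f <- suppressWarnings(fit_fpk(tr, y, N = fpk_N))
          list(lnL = f$lnL, AICc = f$AICc, sigma2 = f$model$sigma2,
               hl_abs = NA_real_, hl_rel = NA_real_,
               fpk_opt = f$landscape$optimum)
        } else {
          f <- suppressWarnings(fit_model(md, tr, y))
          hl <- if (md == "OU")
            phylogenetic_half_life(f$params$alpha, tr)
          else list(absolute = NA_real_, relative = NA_real_)
          list(lnL = f$lnL, AICc = f$AICc,
               sigma2 = f$params$sigma2 %||% NA_real_,
               hl_abs = hl$absolute, hl_rel = hl$relative,
               fpk_opt = NA_real_)
        }
      }, error = function(e) e)
      if (inherits(out, "error")) {
        fails[[length(fails) + 1L]] <-
          data.frame(tree = i, model = md,
                     message = conditionMessage(out),
                     stringsAsFactors = FALSE)
      } else res[[md]] <- out
    }
    if (!length(res)) next
    aicc <- vapply(res, `[[`, numeric(1L), "AICc")
    d <- aicc - min(aicc)
    w <- exp(-d / 2); w <- w / sum(w)
    for (md in names(res))
      rows[[length(rows) + 1L]] <- data.frame(
        tree = i, model = md, lnL = res[[md]]$lnL,
        AICc = res[[md]]$AICc, dAICc = d[[md]], weight = w[[md]],
        sigma2 = res[[md]]$sigma2,
        half_life_abs = res[[md]]$hl_abs,
        half_life_rel = res[[md]]$hl_rel,
        fpk_optimum = res[[md]]$fpk_opt,
        stringsAsFactors = FALSE)
  }
  per_tree <- do.call(rbind, rows)
  if (is.null(per_tree)) stop_mm("every fit failed on every tree")

  stats <- c("AICc", "dAICc", "weight", "sigma2",
             "half_life_abs", "half_life_rel", "fpk_optimum")
  summ <- do.call(rbind, lapply(unique(per_tree$model), function(md) {
    sub <- per_tree[per_tree$model == md, ]
    do.call(rbind, lapply(stats, function(st) {
      x <- sub[[st]]
      x <- x[is.finite(x)]
      if (!length(x)) return(NULL)
      data.frame(model = md, statistic = st, median = median(x),
                 min = min(x), max = max(x),
                 iqr = unname(diff(quantile(x, c(0.25, 0.75)))),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(per_tree = per_tree, summary = summ,
                 failures = if (length(fails)) do.call(rbind, fails)
                            else data.frame(tree = integer(), model = character(),
                                            message = character()),
                 n_trees = length(trees)),
            class = "sensitivity_summary")
}

#' @export
print.sensitivity_summary <- function(x, ...) {
  cat(sprintf("Sensitivity analysis across %d trees (%d fit failures)\n",
              x$n_trees, nrow(x$failures)))
  print(x$summary[x$summary$statistic %in% c("weight", "fpk_optimum",
                                             "half_life_rel"), ],
        row.names = FALSE)
  invisible(x)
}
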