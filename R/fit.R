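#' Fit the empirical Bayes ODP model to a two-class expression matrix
#'
#' The main entry point. Translates each gene to its working statistics
#' (class-0-centered, variance-matched), estimates the hyperparameters
#' `eta = (pi0, pi1, p, alpha, beta)` of the hierarchical mixture model by
#' EM unless a fitted `eta` is supplied, then computes for every gene the
#' ODP statistic (marginal likelihood ratio), the posterior null
#' probability, the q-value, and the posterior mean and credible interval
#' of the mean difference `d`.
#'
#' @param object a numeric genes x samples matrix (genes in rows, with
#'   rownames as gene identifiers), or an `"odp_expression"` from
#'   [read_expression()].
#' @param labels binary class labels per sample (0 = reference class;
#'   ignored when `object` carries its own labels).
#' @param grid effect-size support grid, see [odp_grid()].
#' @param control EM control parameters, see [odp_control()].
#' @param eta optional fitted `"odp_eta"`; when given, the EM step is
#'   skipped and the supplied hyperparameters are applied as-is.
#' @param ci_level credible level for the per-gene effect-size interval.
#' @param conditional_ci report the interval conditional on the gene being
#'   differential (excluding the null point mass)?
#' @return An object of class `"odp_fit"` with components `eta`,
#'   `loglik_trace`, `n_iter`, `converged`, `results` (per-gene data frame
#'   with columns `gene_id`, `R_odp`, `pr_null`, `q_value`, `rank`,
#'   `posterior_mean_d`, `ci_low`, `ci_high`), `stats`, `n0`, `n1`, `call`.
#' @examples
#' sim <- odp_simulate(odp_sim_config(m = 200, n0 = 8, n1 = 8, seed = 1))
#' fit <- odp_fit(sim$expr, sim$labels, grid = odp_grid(step = 0.1),
#'                control = odp_control(max_iter = 50))
#' head(fit$results)
#' @export
odp_fit <- function(object, labels = NULL, grid = odp_grid(),
                    control = odp_control(), eta = NULL,
                    ci_level = 0.95, conditional_ci = FALSE) {
  cl <- match.call()
  if (inherits(object, "odp_expression")) {
    expr <- object$matrix
    labels <- object$labels
    rownames(expr) <- object$gene_ids
  } else {
    expr <- as.matrix(object)
    if (is.null(labels)) stop("labels are required")
    if (length(labels) != ncol(expr))
      stop("labels length must match the number of samples")
  }
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("gene_%d", seq_len(nrow(expr)))
  stats <- translate_matrix(expr, labels)

  if (is.null(eta)) {
    em <- fit_em(stats, grid, control)
    eta <- em$eta
    trace <- em$loglik_trace; n_iter <- em$n_iter; conv <- em$converged
  } else {
    if (!inherits(eta, "odp_eta")) stop("eta must be an 'odp_eta'")
    grid <- eta$grid
    trace <- numeric(0); n_iter <- 0L; conv <- NA
  }

  res <- build_results(stats, eta, ci_level, conditional_ci)
  structure(list(eta = eta, loglik_trace = trace, n_iter = n_iter,
                 converged = conv, results = res, stats = stats,
                 n0 = stats$n0, n1 = stats$n1,
                 ci_level = ci_level, conditional_ci = conditional_ci,
                 call = cl),
            class = "odp_fit")
}

# Per-gene results table at fixed hyperparameters; everything in log space.
build_results <- function(stats, eta, ci_level = 0.95,
                          conditional_ci = FALSE) {
  cm <- component_logmat(stats, eta$grid, eta$alpha, eta$beta)
  lw <- sweep(cm$log_c1, 2L, log(eta$p), `+`)
  log_h1 <- row_logsumexp(lw)
  log_R <- log_h1 - cm$log_c0
  R_odp <- exp(log_R)
  pr_null <- if (eta$pi0 == 0) rep(0, length(log_R))
             else if (eta$pi0 == 1) rep(1, length(log_R))
             else 1 / (1 + exp(log(eta$pi1) - log(eta$pi0) + log_R))
  qv <- odp_qvalues(R_odp, pr_null)
  es <- effect_summaries_all(stats, eta, pr_null, cm$log_c1,
                             level = ci_level, conditional = conditional_ci)
  ids <- stats$gene_id
  if (is.null(ids)) ids <- sprintf("gene_%d", seq_along(R_odp))
  data.frame(gene_id = ids, R_odp = R_odp, pr_null = pr_null,
             q_value = qv$q_value, rank = qv$rank,
             posterior_mean_d = es$mean, ci_low = es$lower,
             ci_high = es$upper,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.odp_fit <- function(x, ...) {
  cat("Empirical Bayes ODP fit\n")
  cat(sprintf("  genes: %d   samples: %d (class 0) + %d (class 1)\n",
              nrow(x$results), x$n0, x$n1))
  cat(sprintf("  grid: L = %d on [%g, %g]\n", length(x$eta$grid),
              min(x$eta$grid), max(x$eta$grid)))
  cat(sprintf("  pi0 = %.4f  pi1 = %.4f  alpha = %.4f  beta = %.4f\n",
              x$eta$pi0, x$eta$pi1, x$eta$alpha, x$eta$beta))
  if (x$n_iter > 0)
    cat(sprintf("  EM: %d iterations, log-likelihood %.4f, %s\n",
                x$n_iter, x$loglik_trace[x$n_iter],
                if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.odp_fit <- function(object, q_levels = c(0.01, 0.05, 0.1, 0.2),
                            ...) {
  counts <- vapply(q_levels,
                   function(q) sum(object$results$q_value <= q), integer(1))
  out <- list(fit = object,
              table = data.frame(q_level = q_levels, n_significant = counts))
  class(out) <- "summary.odp_fit"
  out
}

#' @export
print.summary.odp_fit <- function(x, ...) {
  print(x$fit)
  cat("\nSignificant genes by q-value level:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.odp_fit <- function(object, ...) {
  c(pi0 = object$eta$pi0, pi1 = object$eta$pi1,
    alpha = object$eta$alpha, beta = object$eta$beta)
}

#' @export
plot.odp_fit <- function(x, which = c("prior", "trace"), ...) {
  which <- match.arg(which)
  if (which == "prior") {
    graphics::plot(as.numeric(x$eta$grid), x$eta$p, type = "h",
                   xlab = expression(theta), ylab = "mass",
                   main = "Estimated effect-size distribution G", ...)
  } else {
    graphics::plot(seq_along(x$loglik_trace), x$loglik_trace, type = "l",
                   xlab = "EM iteration", ylab = "log-likelihood",
                   main = "EM trace", ...)
  }
  invisible(x)
}

#' Apply a fitted model to new genes
#'
#' Computes ODP statistics, posterior null probabilities, q-values and
#' effect-size summaries for a new expression matrix under the
#' hyperparameters of an existing fit (no re-estimation).
#'
#' @param object an `"odp_fit"`.
#' @param newdata genes x samples matrix.
#' @param labels class labels for `newdata` columns.
#' @param ... unused.
#' @return A per-gene results data frame as in [odp_fit()].
#' @export
predict.odp_fit <- function(object, newdata, labels, ...) {
  stats <- translate_matrix(as.matrix(newdata), labels)
  build_results(stats, object$eta, object$ci_level, object$conditional_ci)
}

#' Simulate expression data from a fitted model
#'
#' Draws new genes from the fitted hierarchical mixture: component and
#' effect size from `(pi0, p)` over the grid, variance from
#' `InvGamma(alpha, beta)`, then normal data at the fitted design.
#'
#' @param object an `"odp_fit"`.
#' @param nsim number of genes to simulate.
#' @param seed integer seed.
#' @param ... unused.
#' @return As [odp_simulate()]: list with `expr`, `labels`, `truth`.
#' @export
simulate.odp_fit <- function(object, nsim = nrow(object$results),
                             seed = 1L, ...) {
  scale <- sqrt((object$n0 + 1) / object$n0)  # theta -> d back-transform
  cfg <- odp_sim_config(
    m = nsim, n0 = object$n0, n1 = object$n1, pi0 = object$eta$pi0,
    effect = list(type = "point", at = scale * as.numeric(object$eta$grid),
                  w = object$eta$p),
    alpha = object$eta$alpha, beta = object$eta$beta, seed = seed)
  odp_simulate(cfg)
}
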