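#' Per-gene ODP statistic
#'
#' The optimal discovery procedure statistic is the marginal likelihood
#' ratio `R_ODP = h1 / h0` of the differential to the nondifferential
#' component, evaluated at the fitted hyperparameters. Computed as
#' `exp(log h1 - log h0)` so that no intermediate density underflows.
#'
#' @param stats an `"odp_gene_stats"` from [odp_translate()].
#' @param eta a fitted `"odp_eta"`.
#' @return Nonnegative scalar likelihood ratio.
#' @export
odp_statistic <- function(stats, eta) {
  if (!all(is.finite(c(stats$Sw, stats$Sz, stats$Tz))))
    stop("non-finite gene statistics")
  exp(odp_loglik1(stats, eta) - odp_loglik0(stats, eta))
}

#' Posterior null probability of one gene
#'
#' `Pr(H0 | w, z) = pi0 h0 / (pi0 h0 + pi1 h1)`, computed in log space.
#'
#' @inheritParams odp_statistic
#' @export
odp_posterior_null <- function(stats, eta) {
  l0 <- log(eta$pi0) + odp_loglik0(stats, eta)
  l1 <- log(eta$pi1) + odp_loglik1(stats, eta)
  if (is.infinite(l0) && is.infinite(l1)) {
    # pi0 in {0, 1}: the mixture degenerates
    return(if (eta$pi0 == 0) 0 else 1)
  }
  1 / (1 + exp(l1 - l0))
}

#' Estimated FDR of the rejection region at a threshold
#'
#' Selects all genes with `R_ODP >= lambda` and estimates the false
#' discovery rate of the selection as the average posterior null
#' probability over the selected set.
#'
#' @param results a data frame with columns `R_odp` and `pr_null`
#'   (e.g. the `results` component of an [odp_fit()]).
#' @param lambda nonnegative likelihood-ratio cutoff.
#' @return A list of class `"odp_selection"` with elements `lambda`,
#'   `selected` (integer indices), `n_selected` and `fdr_hat` (`NA` when the
#'   selection is empty).
#' @export
odp_fdr_at <- function(results, lambda) {
  if (!(lambda >= 0)) stop("lambda must be nonnegative")
  sel <- which(results$R_odp >= lambda)
  fdr <- if (length(sel)) mean(results$pr_null[sel]) else NA_real_
  structure(list(lambda = lambda, selected = sel,
                 n_selected = length(sel), fdr_hat = fdr),
            class = "odp_selection")
}

#' @export
print.odp_selection <- function(x, ...) {
  if (x$n_selected == 0L)
    cat("Empty selection (no gene passes the threshold)\n")
  else
    cat(sprintf("%d genes selected; estimated FDR = %.4g\n",
                x$n_selected, x$fdr_hat))
  invisible(x)
}

#' q-values from ODP statistics and posterior null probabilities
#'
#' Genes are sorted by decreasing `R_ODP`; the running mean of `pr_null`
#' down the sorted list is the estimated FDR of each nested rejection
#' region, and the q-value of a gene is the smallest estimated FDR among
#' regions that contain it (running minimum from the bottom up). Genes tied
#' on `R_ODP` cannot be separated by any threshold and share one q-value.
#'
#' @param R_odp numeric vector of ODP statistics.
#' @param pr_null matching vector of posterior null probabilities.
#' @return A list with `q_value` and dense `rank` (1 = most significant),
#'   in the input gene order.
#' @export
odp_qvalues <- function(R_odp, pr_null) {
  stopifnot(length(R_odp) == length(pr_null))
  ord <- order(R_odp, decreasing = TRUE)
  fdr_step <- cumsum(pr_null[ord]) / seq_along(ord)
  q_sorted <- rev(cummin(rev(fdr_step)))
  # tie blocks share the q at the block end (largest within the block,
  # since q_sorted is non-decreasing down the list)
  Rs <- R_odp[ord]
  q_sorted <- stats::ave(q_sorted, match(Rs, Rs), FUN = max)
  q <- numeric(length(ord)); q[ord] <- q_sorted
  rnk <- match(R_odp, sort(unique(R_odp), decreasing = TRUE))
  list(q_value = q, rank = rnk)
}

#' Select genes at a target q-value level
#'
#' All genes with `q_value <= q_level`; the estimated FDR of the selection
#' is recomputed as the mean posterior null probability over it.
#'
#' @param results a data frame with columns `q_value` and `pr_null`.
#' @param q_level target level in \[0, 1\].
#' @return An `"odp_selection"` (see [odp_fdr_at()]); `lambda` is the
#'   smallest selected `R_odp` (or `Inf` for an empty selection).
#' @export
odp_select <- function(results, q_level) {
  if (!is.numeric(q_level) || q_level < 0 || q_level > 1)
    stop("q_level must be in [0, 1]")
  sel <- which(results$q_value <= q_level)
  fdr <- if (length(sel)) mean(results$pr_null[sel]) else NA_real_
  lam <- if (length(sel)) min(results$R_odp[sel]) else Inf
  structure(list(lambda = lam, selected = sel, n_selected = length(sel),
                 fdr_hat = fdr, q_level = q_level),
            class = "odp_selection")
}

#' Count local modes of the estimated effect-size distribution
#'
#' Smooths the fitted grid masses with a Gaussian kernel of the given
#' bandwidth (on the theta scale) and counts strict local maxima of the
#' smoothed density over the grid. Useful for judging whether the estimated
#' prior is multimodal, i.e. whether a unimodal parametric family would
#' have been adequate.
#'
#' @param eta a fitted `"odp_eta"`.
#' @param bandwidth Gaussian kernel standard deviation.
#' @return Integer number of local modes.
#' @export
odp_prior_modes <- function(eta, bandwidth = 0.05) {
  a <- as.numeric(eta$grid)
  dens <- vapply(a, function(t)
    sum(eta$p * stats::dnorm(t, mean = a, sd = bandwidth)), numeric(1))
  d <- diff(dens)
  sign_change <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  n_modes <- length(sign_change)
  # boundary modes
  if (d[1] < 0) n_modes <- n_modes + 1L
  if (d[length(d)] > 0) n_modes <- n_modes + 1L
  n_modes
}
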