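#' Marginal posterior distribution of the effect size theta
#'
#' Under the fitted model the posterior of `theta_k` is discrete: a mass at
#' 0 equal to the posterior null probability, and masses over the grid
#' proportional to `p_j c_kj`, where `c_kj` is the closed-form component
#' marginal likelihood at support point `a_j`.
#'
#' @param stats an `"odp_gene_stats"` from [odp_translate()].
#' @param eta a fitted `"odp_eta"`.
#' @return A list of class `"odp_posterior_theta"`: `mass0`, `masses`
#'   (length L, summing with `mass0` to 1), `grid`, and `n0` (kept for the
#'   back-transformation to the raw mean-difference scale).
#' @export
odp_posterior_theta <- function(stats, eta) {
  mass0 <- odp_posterior_null(stats, eta)
  lc <- odp_component_loglik(stats, as.numeric(eta$grid), eta$alpha, eta$beta)
  lw <- log(eta$p) + lc
  masses <- (1 - mass0) * exp(lw - logsumexp(lw))
  structure(list(mass0 = mass0, masses = masses, grid = eta$grid,
                 n0 = stats$n0),
            class = "odp_posterior_theta")
}

#' Posterior distribution of the gene variance
#'
#' The posterior of `sigma^2_k` is a mixture of inverse-gamma laws, one per
#' component (the null at `a = 0` plus each grid point): component `j` has
#' weight proportional to the prior-weighted component marginal likelihood
#' and law `InvGamma(alpha + n/2, beta + (Sw + sum_i (z_i - a_j)^2)/2)`.
#'
#' @inheritParams odp_posterior_theta
#' @return A list of class `"odp_posterior_sigma2"`: `weights` (length
#'   L + 1; element 1 is the null component), `shape` (common scalar
#'   `alpha + n/2`), `rates` (length L + 1), `support` (0 and the grid).
#' @export
odp_posterior_sigma2 <- function(stats, eta) {
  a <- c(0, as.numeric(eta$grid))
  lc <- odp_component_loglik(stats, a, eta$alpha, eta$beta)
  lw <- log(c(eta$pi0, eta$pi1 * eta$p)) + lc
  w <- exp(lw - logsumexp(lw))
  S <- stats$Sw + stats$Sz - 2 * a * stats$Tz + stats$n1 * a^2
  structure(list(weights = w, shape = eta$alpha + stats$n / 2,
                 rates = eta$beta + S / 2, support = a),
            class = "odp_posterior_sigma2")
}

#' Posterior density of sigma^2 at given points
#'
#' @param ps an `"odp_posterior_sigma2"`.
#' @param s2 numeric vector of evaluation points (> 0).
#' @return Mixture density values.
#' @export
odp_sigma2_density <- function(ps, s2) {
  vapply(s2, function(v)
    sum(ps$weights * exp(ps$shape * log(ps$rates) - lgamma(ps$shape) -
                           (ps$shape + 1) * log(v) - ps$rates / v)),
    numeric(1))
}

#' Effect-size estimate and credible interval on the raw scale
#'
#' Back-transforms the discrete posterior of `theta` to the mean-difference
#' scale `d = sqrt((n0+1)/n0) * theta` and returns the posterior mean plus a
#' central (equal-tail) credible interval on the discrete support. By
#' default the interval is over the full mixture (including the point mass
#' at 0); with `conditional = TRUE` it conditions on the gene being
#' differential (the null mass is excluded and the grid masses
#' renormalized), in which case the separately reported null mass qualifies
#' the interval.
#'
#' @param pt an `"odp_posterior_theta"`.
#' @param level credible level (default 0.95).
#' @param conditional condition on the differential component?
#' @return A list with `mean` (posterior mean of d), `lower`, `upper`, and
#'   `mass0`.
#' @export
odp_effect_summary <- function(pt, level = 0.95, conditional = FALSE) {
  scale <- sqrt((pt$n0 + 1) / pt$n0)
  d_grid <- scale * as.numeric(pt$grid)
  mean_d <- sum(pt$masses * d_grid)  # the null point contributes 0
  if (conditional) {
    tot <- sum(pt$masses)
    if (tot <= 0) return(list(mean = 0, lower = 0, upper = 0,
                              mass0 = pt$mass0))
    support <- d_grid; mass <- pt$masses / tot
  } else {
    pos <- sum(as.numeric(pt$grid) < 0)
    support <- append(d_grid, 0, after = pos)
    mass <- append(pt$masses, pt$mass0, after = pos)
  }
  gamma <- 1 - level
  cs <- cumsum(mass)
  lower <- support[which(cs >= gamma / 2 - 1e-12)[1L]]
  upper <- support[which(cs >= 1 - gamma / 2 - 1e-12)[1L]]
  list(mean = mean_d, lower = lower, upper = upper, mass0 = pt$mass0)
}

# Vectorized effect summaries for all genes from the final component
# matrices; mirrors odp_effect_summary() row by row.
effect_summaries_all <- function(stats, eta, pr_null, log_c1,
                                 level = 0.95, conditional = FALSE) {
  a <- as.numeric(eta$grid)
  lw <- sweep(log_c1, 2L, log(eta$p), `+`)
  Mstar <- exp(lw - row_logsumexp(lw))          # normalized grid masses
  scale <- sqrt((stats$n0 + 1) / stats$n0)
  d_grid <- scale * a
  mean_d <- (1 - pr_null) * drop(Mstar %*% d_grid)
  gamma <- 1 - level
  if (conditional) {
    P <- Mstar
    support <- d_grid
  } else {
    pos <- sum(a < 0)
    left <- if (pos > 0) Mstar[, seq_len(pos), drop = FALSE] * (1 - pr_null)
    right <- if (pos < length(a))
      Mstar[, (pos + 1):length(a), drop = FALSE] * (1 - pr_null)
    P <- cbind(left, pr_null, right)
    support <- append(d_grid, 0, after = pos)
  }
  cs <- t(apply(P, 1L, cumsum))
  lo_idx <- max.col(1 * (cs >= gamma / 2 - 1e-12), ties.method = "first")
  hi_idx <- max.col(1 * (cs >= 1 - gamma / 2 - 1e-12), ties.method = "first")
  list(mean = mean_d, lower = support[lo_idx], upper = support[hi_idx])
}
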