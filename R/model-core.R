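#' @keywords internal
"_PACKAGE"

#' Translate a two-class gene into its working statistics
#'
#' Centers both classes on the class-0 sample mean and rescales so that the
#' translated values are homoscedastic with variance `sigma^2` under the
#' two-class normal model: `w_i = sqrt(n0/(n0-1)) (x_i - xbar)` and
#' `z_i = sqrt(n0/(n0+1)) (y_i - xbar)`. The translation eliminates the
#' class-0 baseline mean (a nuisance parameter), leaving `w ~ N(0, sigma^2)`
#' and `z ~ N(theta, sigma^2)` with `theta = sqrt(n0/(n0+1)) d`, where `d` is
#' the class mean difference on the original scale.
#'
#' @param x numeric vector of class-0 log-expression values (length >= 2).
#' @param y numeric vector of class-1 log-expression values (length >= 1).
#' @return An object of class `"odp_gene_stats"`: a list with the translated
#'   vectors `w`, `z` and the sufficient statistics `Sw = sum(w^2)`,
#'   `Sz = sum(z^2)`, `Tz = sum(z)`, plus the counts `n0`, `n1`, `n`.
#' @examples
#' odp_translate(c(1, 3), 2)
#' @export
odp_translate <- function(x, y) {
  if (length(x) < 2L)
    stop("class-0 needs at least 2 samples (n0 >= 2)")
  if (length(y) < 1L)
    stop("class-1 needs at least 1 sample")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite expression values")
  n0 <- length(x); n1 <- length(y)
  xbar <- mean(x)
  w <- sqrt(n0 / (n0 - 1)) * (x - xbar)
  z <- sqrt(n0 / (n0 + 1)) * (y - xbar)
  structure(list(w = w, z = z,
                 Sw = sum(w^2), Sz = sum(z^2), Tz = sum(z),
                 n0 = n0, n1 = n1, n = n0 + n1),
            class = "odp_gene_stats")
}

# Vectorized translation of a full genes x samples matrix.
# Returns per-gene sufficient statistics only (enough for every likelihood).
translate_matrix <- function(expr, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  i0 <- which(labels == 0L); i1 <- which(labels == 1L)
  n0 <- length(i0); n1 <- length(i1)
  if (n0 < 2L) stop("class-0 needs at least 2 samples (n0 >= 2)")
  if (n1 < 1L) stop("class-1 needs at least 1 sample")
  if (anyNA(expr) || !all(is.finite(expr))) stop("non-finite expression values")
  xbar <- rowMeans(expr[, i0, drop = FALSE])
  w <- sqrt(n0 / (n0 - 1)) * (expr[, i0, drop = FALSE] - xbar)
  z <- sqrt(n0 / (n0 + 1)) * (expr[, i1, drop = FALSE] - xbar)
  structure(list(Sw = rowSums(w^2), Sz = rowSums(z^2), Tz = rowSums(z),
                 n0 = n0, n1 = n1, n = n0 + n1,
                 gene_id = rownames(expr)),
            class = "odp_stats")
}

as_stats_set <- function(stats) {
  # accept a single odp_gene_stats or an odp_stats collection
  if (inherits(stats, "odp_gene_stats")) {
    structure(list(Sw = stats$Sw, Sz = stats$Sz, Tz = stats$Tz,
                   n0 = stats$n0, n1 = stats$n1, n = stats$n,
                   gene_id = NULL),
              class = "odp_stats")
  } else if (inherits(stats, "odp_stats")) stats
  else stop("expected odp_gene_stats or odp_stats")
}

#' Effect-size support grid
#'
#' Equally spaced nonzero support points for the discrete representation of
#' the effect-size distribution G(theta). The default, 200 points on
#' \[-1, 1\] spaced by 0.01 with 0 excluded, follows the published guideline
#' that at least 200 grid points be used for the smoothing-by-roughening
#' estimate of a mixing distribution.
#'
#' @param min,max grid range (on the theta scale).
#' @param step spacing between adjacent points.
#' @return Ordered numeric vector of distinct nonzero support points,
#'   class `"odp_grid"`.
#' @export
odp_grid <- function(min = -1, max = 1, step = 0.01) {
  if (!(step > 0) || !(max > min)) stop("need max > min and step > 0")
  a <- seq(min, max, by = step)
  a <- a[abs(a) > step / 2]  # exclude 0 robustly against fp noise
  if (length(a) < 1L) stop("grid is empty")
  structure(a, class = "odp_grid")
}

#' Hyperparameters of the hierarchical mixture model
#'
#' Bundles and validates eta = (pi0, pi1, p, alpha, beta): the null mixing
#' proportion, the grid masses of the differential component, and the
#' inverse-gamma shape/rate of the variance prior.
#'
#' @param pi0 null-component mixing proportion, in \[0, 1\].
#' @param p numeric vector of grid masses (nonnegative, summing to 1).
#' @param alpha,beta inverse-gamma shape and rate, both > 0.
#' @param grid the [odp_grid()] the masses `p` live on.
#' @return A list of class `"odp_eta"`.
#' @export
odp_eta <- function(pi0, p, alpha, beta, grid) {
  if (!is.numeric(pi0) || pi0 < 0 || pi0 > 1) stop("pi0 must be in [0, 1]")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be nonnegative and sum to 1 (tolerance 1e-8)")
  if (length(p) != length(grid)) stop("length(p) must match the grid")
  if (!(alpha > 0) || !(beta > 0)) stop("alpha and beta must be positive")
  structure(list(pi0 = pi0, pi1 = 1 - pi0, p = as.numeric(p),
                 alpha = alpha, beta = beta, grid = grid),
            class = "odp_eta")
}

# log Gamma(n/2+alpha) - log Gamma(alpha) + alpha log beta - (n/2) log(2 pi)
lik_const <- function(n, alpha, beta) {
  lgamma(n / 2 + alpha) - lgamma(alpha) + alpha * log(beta) -
    (n / 2) * log(2 * pi)
}

#' Log marginal likelihood of one mixture component
#'
#' Closed form of the per-gene data density with the variance integrated out
#' against its inverse-gamma prior, at a fixed effect-size support point `a`
#' (`a = 0` gives the null component):
#' \deqn{\log\left[\frac{\Gamma(n/2+\alpha)}{\Gamma(\alpha)}\,\beta^\alpha
#'   (2\pi)^{-n/2}\left(\frac{S_w + \sum_i (z_i-a)^2}{2}+\beta\right)^{-(n/2+\alpha)}\right]}
#' evaluated entirely in log space, with
#' \eqn{\sum_i (z_i-a)^2 = S_z - 2 a T_z + n_1 a^2}.
#'
#' @param stats an `"odp_gene_stats"` object from [odp_translate()].
#' @param a support point (0 allowed).
#' @param alpha,beta inverse-gamma shape and rate, both > 0.
#' @return log marginal density (scalar, or vector if `a` is a vector).
#' @export
odp_component_loglik <- function(stats, a, alpha, beta) {
  if (!(alpha > 0) || !(beta > 0)) stop("alpha and beta must be positive")
  S <- stats$Sw + stats$Sz - 2 * a * stats$Tz + stats$n1 * a^2
  lik_const(stats$n, alpha, beta) - (stats$n / 2 + alpha) * log(S / 2 + beta)
}

#' Log marginal null likelihood h0
#'
#' The null component's marginal likelihood: [odp_component_loglik()] at
#' `a = 0`.
#'
#' @inheritParams odp_component_loglik
#' @param eta an `"odp_eta"` object (only `alpha`, `beta` are used).
#' @export
odp_loglik0 <- function(stats, eta) {
  odp_component_loglik(stats, 0, eta$alpha, eta$beta)
}

#' Log marginal alternative likelihood h1
#'
#' Grid-mixture marginal likelihood of the differential component,
#' `log sum_j p_j exp(component loglik at a_j)`, computed by log-sum-exp.
#'
#' @inheritParams odp_loglik0
#' @export
odp_loglik1 <- function(stats, eta) {
  check_masses(eta$p)
  lc <- odp_component_loglik(stats, as.numeric(eta$grid), eta$alpha, eta$beta)
  logsumexp(log(eta$p) + lc)
}

check_masses <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("grid masses must be nonnegative and sum to 1 (tolerance 1e-8)")
  invisible(p)
}

# log(sum(exp(x))) along a vector, -Inf-safe
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of (log-weight + log-density) matrices.
row_logsumexp <- function(M) {
  m <- apply(M, 1L, max)
  out <- m + log(rowSums(exp(M - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# m x (L) matrix of log component likelihoods at the grid, plus the null
# column; the workhorse shared by the E-step, the ODP statistic and the
# posteriors. Returns list(log_c0 = m-vector, log_c1 = m x L matrix).
component_logmat <- function(stats, grid, alpha, beta) {
  a <- as.numeric(grid)
  half <- stats$Sw + stats$Sz            # Sw + Sz per gene
  const <- lik_const(stats$n, alpha, beta)
  k <- stats$n / 2 + alpha
  M0 <- half / 2 + beta
  # S_kj/2 + beta = (Sw+Sz)/2 + beta - a_j Tz + n1 a_j^2 / 2
  M1 <- M0 - outer(stats$Tz, a) +
    matrix(stats$n1 * a^2 / 2, nrow = length(half), ncol = length(a),
           byrow = TRUE)
  list(log_c0 = const - k * log(M0),
       log_c1 = const - k * log(M1),
       M0 = M0, M1 = M1, post_shape = k)
}
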