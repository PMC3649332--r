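#' Starting hyperparameters for the EM fit
#'
#' The smoothing-by-roughening scheme starts from a smooth estimate of the
#' effect-size distribution: uniform masses over the grid. The null
#' proportion starts at `pi0_init` (default 0.9, a high-null start suited to
#' the screening setting). The inverse-gamma parameters are initialized by
#' matching moments of the per-gene pooled variance estimates
#' `s2_k = (Sw + Sz - Tz^2/n1) / (n - 2)` to the inverse-gamma mean and
#' variance, with the shape clipped to \[0.5, 100\]; if the empirical spread
#' is degenerate the fallback is `alpha = 2`, `beta = mean(s2)`.
#'
#' @param stats an `"odp_stats"` collection (from the internal matrix
#'   translation, or [odp_translate()] stats combined by [odp_fit()]).
#' @param grid an [odp_grid()].
#' @param pi0_init initial null proportion.
#' @return An `"odp_eta"` object.
#' @export
odp_init_eta <- function(stats, grid, pi0_init = 0.9) {
  m <- length(stats$Sw)
  if (m < 2L) stop("need at least 2 genes")
  s2 <- (stats$Sw + stats$Sz - stats$Tz^2 / stats$n1) / (stats$n - 2)
  mu <- mean(s2); v <- stats::var(s2)
  if (!is.finite(v) || v <= 1e-12 * max(mu^2, 1e-12)) {
    alpha <- 2; beta <- mu
  } else {
    # InvGamma(alpha, beta): mean = beta/(alpha-1), var = mean^2/(alpha-2)
    alpha <- mu^2 / v + 2
    alpha <- min(max(alpha, 0.5), 100)
    beta <- mu * (alpha - 1)
  }
  if (!(beta > 0)) beta <- max(mu, 1e-8)
  L <- length(grid)
  odp_eta(pi0 = pi0_init, p = rep(1 / L, L), alpha = alpha, beta = beta,
          grid = grid)
}

#' E-step: posterior responsibilities and variance expectations
#'
#' Computes, per gene, the posterior null probability
#' `r0_k = pi0 h0_k / (pi0 h0_k + pi1 h1_k)`, the joint masses
#' `R1_kj = pi1 p_j c_kj / (pi0 h0_k + pi1 h1_k)` over the grid, and the
#' conditional inverse-gamma posterior of `sigma^2_k` given each component
#' (shape `alpha + n/2`, rate `beta + S_kj/2`), from which the expectations
#' `E[1/sigma^2]` and `E[log sigma^2]` needed by the M-step follow in closed
#' form. All likelihood work is done in log space.
#'
#' @param stats an `"odp_stats"` collection.
#' @param eta an `"odp_eta"`.
#' @return A list of class `"odp_resp"`: `r0` (m-vector), `R1` (m x L),
#'   `Einv0`, `Elog0` (m-vectors), `Einv1`, `Elog1` (m x L),
#'   `loglik` (observed-data log-likelihood at `eta`).
#' @export
odp_estep <- function(stats, eta) {
  cm <- component_logmat(stats, eta$grid, eta$alpha, eta$beta)
  lp <- log(eta$p)
  lw <- sweep(cm$log_c1, 2L, lp, `+`)          # log(p_j c_kj)
  log_h1 <- row_logsumexp(lw)
  log_num0 <- log(eta$pi0) + cm$log_c0
  log_num1 <- log(eta$pi1) + log_h1
  log_mix <- pmax(log_num0, log_num1) +
    log1p(exp(-abs(log_num0 - log_num1)))
  log_mix[is.infinite(log_num0) & is.infinite(log_num1)] <- -Inf
  if (any(!is.finite(log_mix)))
    stop("non-finite marginal likelihood at gene ",
         which(!is.finite(log_mix))[1L])
  r0 <- exp(log_num0 - log_mix)
  R1 <- exp(log(eta$pi1) + lw - log_mix)
  shape <- cm$post_shape
  structure(list(r0 = r0, R1 = R1,
                 Einv0 = shape / cm$M0, Elog0 = log(cm$M0) - digamma(shape),
                 Einv1 = shape / cm$M1, Elog1 = log(cm$M1) - digamma(shape),
                 loglik = sum(log_mix)),
            class = "odp_resp")
}

#' M-step: update the hyperparameters from responsibilities
#'
#' `pi0` becomes the mean of the per-gene null responsibilities; `p_j` is
#' proportional to the total mass assigned to grid point `a_j`. The
#' inverse-gamma parameters maximize the expected complete-data
#' log-likelihood `Q(alpha, beta) = alpha log beta - log Gamma(alpha)
#' - (alpha+1) A - beta B` (per gene), where `A` and `B` are the
#' responsibility-weighted means of `E[log sigma^2]` and `E[1/sigma^2]`:
#' `beta = alpha / B` and `alpha` solves `log(alpha) - digamma(alpha) =
#' A + log(B)` by monotone root-finding on \[1e-3, 1e3\].
#'
#' @param resp an `"odp_resp"` from [odp_estep()].
#' @param grid the [odp_grid()].
#' @return An `"odp_eta"`.
#' @export
odp_mstep <- function(resp, grid) {
  m <- length(resp$r0)
  pi0 <- mean(resp$r0)
  mass <- colSums(resp$R1)
  tot <- sum(mass)
  if (tot <= 0) {
    if (1 - pi0 > 1e-12)
      warning("no mass on any grid point; keeping p unchanged")
    p <- rep(1 / length(grid), length(grid))
  } else p <- mass / tot
  A <- (sum(resp$r0 * resp$Elog0) + sum(resp$R1 * resp$Elog1)) / m
  B <- (sum(resp$r0 * resp$Einv0) + sum(resp$R1 * resp$Einv1)) / m
  target <- A + log(B)
  g <- function(la) { al <- exp(la); log(al) - digamma(al) - target }
  lo <- log(1e-3); hi <- log(1e3)
  if (g(hi) > 0) alpha <- 1e3          # extremely concentrated variances
  else if (g(lo) < 0) alpha <- 1e-3
  else {
    r <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
    alpha <- exp(r$root)
  }
  beta <- alpha / B
  odp_eta(pi0 = pi0, p = p, alpha = alpha, beta = beta, grid = grid)
}

#' Fitting control parameters
#'
#' @param max_iter maximum EM iterations. Under smoothing-by-roughening the
#'   iteration count doubles as the smoothing control: fewer iterations keep
#'   the estimated effect-size distribution closer to the smooth (uniform)
#'   start.
#' @param tol convergence tolerance on the change in observed-data
#'   log-likelihood; the default scales with the number of genes as
#'   `tol_per_gene * m`.
#' @param tol_per_gene per-gene tolerance used when `tol` is `NULL`.
#' @param pi0_init initial null proportion for [odp_init_eta()].
#' @export
odp_control <- function(max_iter = 500L, tol = NULL, tol_per_gene = 1e-6,
                        pi0_init = 0.9) {
  stopifnot(max_iter >= 1L, tol_per_gene > 0, pi0_init >= 0, pi0_init <= 1)
  list(max_iter = as.integer(max_iter), tol = tol,
       tol_per_gene = tol_per_gene, pi0_init = pi0_init)
}

# EM driver: deterministic given (stats, grid, control).
fit_em <- function(stats, grid, control = odp_control()) {
  m <- length(stats$Sw)
  if (m < 2L) stop("need at least 2 genes")
  tol <- if (is.null(control$tol)) control$tol_per_gene * m else control$tol
  eta <- odp_init_eta(stats, grid, control$pi0_init)
  trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(control$max_iter)) {
    resp <- odp_estep(stats, eta)
    trace <- c(trace, resp$loglik)
    eta_new <- odp_mstep(resp, grid)
    if (it > 1L && abs(trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    eta <- eta_new
  }
  list(eta = eta, loglik_trace = trace, n_iter = length(trace),
       converged = converged, resp = resp)
}
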