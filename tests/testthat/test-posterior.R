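test_that("posterior of theta normalizes and matches the two-stage route", {
  grid <- structure(c(-0.6, 0.4), class = "odp_grid")
  eta <- odp_eta(0.65, c(0.35, 0.65), 2.8, 1.9, grid)
  g <- random_wz(3, 2, seed = 55)
  s <- wz_stats(g$w, g$z)
  pt <- odp_posterior_theta(s, eta)
  expect_equal(pt$mass0 + sum(pt$masses), 1, tolerance = 1e-8)
  expect_true(all(c(pt$mass0, pt$masses) >= 0))
  expect_equal(pt$mass0, odp_posterior_null(s, eta))

  # two-stage: Pr(theta = a_j | s2, data) integrated against p(s2 | data),
  # all by quadrature from raw w/z - no closed forms shared with the package
  a <- as.numeric(grid)
  cond_lik <- function(aj, s2)
    exp(-(s$n / 2) * log(2 * pi * s2) -
          (sum(g$w^2) + sum((g$z - aj)^2)) / (2 * s2))
  prior_s2 <- function(s2)
    exp(eta$alpha * log(eta$beta) - lgamma(eta$alpha) -
          (eta$alpha + 1) * log(s2) - eta$beta / s2)
  # p(s2 | data, differential) ~ sum_j p_j f(w,z|a_j,s2) prior(s2)
  joint <- function(s2) sum(eta$p * vapply(a, cond_lik, numeric(1), s2 = s2))
  norm <- stats::integrate(function(v) vapply(v, function(s2)
    joint(s2) * prior_s2(s2), numeric(1)), 0, Inf, rel.tol = 1e-11)$value
  two_stage <- vapply(seq_along(a), function(j) {
    stats::integrate(function(v) vapply(v, function(s2) {
      jt <- joint(s2)
      if (jt <= 0) return(0)  # both factors vanish in the tails
      w_theta <- eta$p[j] * cond_lik(a[j], s2) / jt
      w_theta * jt * prior_s2(s2) / norm
    }, numeric(1)), 0, Inf, rel.tol = 1e-11)$value
  }, numeric(1))
  direct <- pt$masses / sum(pt$masses)
  expect_equal(direct, two_stage, tolerance = 1e-6)
})

test_that("posterior of theta handles degenerate mixtures", {
  grid1 <- structure(0.3, class = "odp_grid")
  eta <- odp_eta(0, 1, 2, 2, grid1)
  g <- random_wz(3, 2, seed = 6)
  pt <- odp_posterior_theta(wz_stats(g$w, g$z), eta)
  expect_equal(pt$mass0, 0)
  expect_equal(pt$masses, 1)
})

test_that("posterior of sigma^2 is the conjugate inverse-gamma mixture", {
  grid <- structure(c(-0.5, 0.5), class = "odp_grid")
  eta <- odp_eta(0.6, c(0.5, 0.5), 3, 2, grid)
  g <- random_wz(4, 3, seed = 31)
  s <- wz_stats(g$w, g$z)
  ps <- odp_posterior_sigma2(s, eta)
  expect_equal(sum(ps$weights), 1, tolerance = 1e-8)
  expect_equal(ps$shape, eta$alpha + s$n / 2)
  expect_true(all(ps$rates > 0))
  # conjugate rate for each component
  expect_equal(ps$rates,
               eta$beta + (s$Sw + s$Sz - 2 * ps$support * s$Tz +
                             s$n1 * ps$support^2) / 2)

  # single-component posterior mean: (beta + S/2)/(alpha + n/2 - 1)
  mean_null <- (eta$beta + (s$Sw + s$Sz) / 2) / (eta$alpha + s$n / 2 - 1)
  w_eta <- odp_eta(1, c(0.5, 0.5), 3, 2, grid)
  ps_null <- odp_posterior_sigma2(s, w_eta)
  expect_equal(ps_null$weights[1], 1, tolerance = 1e-12)
  expect_equal(ps_null$rates[1] / (ps_null$shape - 1), mean_null)

  # mixture density at test points matches the quadrature-normalized Bayes rule
  full_joint <- function(s2) {
    comp <- vapply(ps$support, function(aj)
      exp(-(s$n / 2) * log(2 * pi * s2) -
            (sum(g$w^2) + sum((g$z - aj)^2)) / (2 * s2)), numeric(1))
    sum(c(eta$pi0, eta$pi1 * eta$p) * comp) *
      exp(eta$alpha * log(eta$beta) - lgamma(eta$alpha) -
            (eta$alpha + 1) * log(s2) - eta$beta / s2)
  }
  norm <- stats::integrate(function(v) vapply(v, full_joint, numeric(1)),
                           0, Inf, rel.tol = 1e-11)$value
  for (v in c(0.3, 0.7, 1, 1.8, 3)) {
    expect_equal(odp_sigma2_density(ps, v), full_joint(v) / norm,
                 tolerance = 1e-6)
  }
})

test_that("effect-size summaries back-transform and bracket correctly", {
  grid <- structure(c(-0.4, 0.4), class = "odp_grid")
  # all mass at zero
  pt0 <- structure(list(mass0 = 1, masses = c(0, 0), grid = grid, n0 = 10),
                   class = "odp_posterior_theta")
  es <- odp_effect_summary(pt0)
  expect_equal(c(es$mean, es$lower, es$upper), c(0, 0, 0))

  # symmetric masses, no null mass: mean 0
  pt1 <- structure(list(mass0 = 0, masses = c(0.5, 0.5), grid = grid,
                        n0 = 10), class = "odp_posterior_theta")
  expect_equal(odp_effect_summary(pt1)$mean, 0)

  # frozen posterior: mean equals the brute-force dot product
  grid3 <- structure(c(-0.6, 0.2, 0.8), class = "odp_grid")
  pt2 <- structure(list(mass0 = 0.3, masses = c(0.1, 0.4, 0.2),
                        grid = grid3, n0 = 8),
                   class = "odp_posterior_theta")
  sc <- sqrt(9 / 8)
  expect_equal(odp_effect_summary(pt2)$mean,
               sum(c(0.1, 0.4, 0.2) * sc * c(-0.6, 0.2, 0.8)))
  # equal-tail interval on the discrete support
  es2 <- odp_effect_summary(pt2, level = 0.5)
  support <- sc * c(-0.6, 0, 0.2, 0.8)
  mass <- c(0.1, 0.3, 0.4, 0.2)
  cdf <- cumsum(mass)
  expect_equal(es2$lower, support[which(cdf >= 0.25)[1]])
  expect_equal(es2$upper, support[which(cdf >= 0.75)[1]])

  # conditional interval excludes the null point mass
  esc <- odp_effect_summary(pt2, level = 0.5, conditional = TRUE)
  cdfc <- cumsum(c(0.1, 0.4, 0.2) / 0.7)
  supc <- sc * c(-0.6, 0.2, 0.8)
  expect_equal(esc$lower, supc[which(cdfc >= 0.25)[1]])
  expect_equal(esc$upper, supc[which(cdfc >= 0.75)[1]])
})

test_that("vectorized effect summaries agree with the per-gene construction", {
  sim <- odp_simulate_translated(odp_sim_config(m = 40, n0 = 5, n1 = 4,
                                                seed = 14))
  grid <- odp_grid(-1, 1, 0.25)
  L <- length(grid)
  eta <- odp_eta(0.7, rep(1 / L, L), 3, 2, grid)
  res <- odpmix:::build_results(sim$stats, eta)
  for (k in c(1, 7, 40)) {
    s1 <- structure(list(Sw = sim$stats$Sw[k], Sz = sim$stats$Sz[k],
                         Tz = sim$stats$Tz[k], n0 = sim$stats$n0,
                         n1 = sim$stats$n1, n = sim$stats$n),
                    class = "odp_gene_stats")
    pt <- odp_posterior_theta(s1, eta)
    es <- odp_effect_summary(pt)
    expect_equal(res$posterior_mean_d[k], es$mean, tolerance = 1e-10)
    expect_equal(res$ci_low[k], es$lower)
    expect_equal(res$ci_high[k], es$upper)
    expect_equal(pt$mass0, res$pr_null[k], tolerance = 1e-10)
  }
})

test_that("monotone evidence: larger Tz pulls the posterior mean of theta up", {
  grid <- odp_grid(-1, 1, 0.25)
  L <- length(grid)
  eta <- odp_eta(0.5, rep(1 / L, L), 3, 2, grid)
  set.seed(12)
  base <- wz_stats(rnorm(5), rnorm(4))
  means <- vapply(seq(-2, 2, by = 0.5), function(shift) {
    s <- base
    s$Tz <- base$Tz + shift
    pt <- odp_posterior_theta(s, eta)
    sum(pt$masses * as.numeric(grid))
  }, numeric(1))
  expect_false(is.unsorted(means))
})

test_that("posterior mode lands on the generating grid point for clean data", {
  grid <- odp_grid(-1, 1, 0.25)
  a_star <- 0.5
  n1 <- 6
  s <- structure(list(Sw = 1e-4, Sz = n1 * a_star^2 + 1e-4,
                      Tz = n1 * a_star, n0 = 6, n1 = n1, n = 12),
                 class = "odp_gene_stats")
  L <- length(grid)
  eta <- odp_eta(0.5, rep(1 / L, L), 3, 2, grid)
  pt <- odp_posterior_theta(s, eta)
  expect_equal(as.numeric(grid)[which.max(pt$masses)], a_star)
})
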