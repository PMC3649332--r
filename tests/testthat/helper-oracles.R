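# Independent oracles used across test files. These deliberately avoid the
# package's algebraic shortcuts: they work from the raw w/z vectors and
# numerical integration only.

# Marginal component likelihood by adaptive quadrature over sigma^2:
# integral of N(w; 0, s2) N(z; a, s2) InvGamma(s2; alpha, beta) d s2.
# Integrates exp(log integrand - shift) for stability; returns the log value.
quad_component_loglik <- function(w, z, a, alpha, beta) {
  n <- length(w) + length(z)
  logint <- function(s2)
    -(n / 2) * log(2 * pi * s2) - (sum(w^2) + sum((z - a)^2)) / (2 * s2) +
      alpha * log(beta) - lgamma(alpha) - (alpha + 1) * log(s2) - beta / s2
  shift <- max(vapply(exp(seq(log(1e-4), log(1e4), length.out = 200)),
                      logint, numeric(1)))
  val <- stats::integrate(function(s2) exp(logint(s2) - shift),
                          lower = 0, upper = Inf,
                          rel.tol = 1e-11, abs.tol = 0)$value
  shift + log(val)
}

# A reproducible small random gene on the working-data scale.
random_wz <- function(n0 = 3, n1 = 2, seed = 1) {
  set.seed(seed)
  list(w = rnorm(n0, 0, runif(1, 0.5, 2)),
       z = rnorm(n1, runif(1, -1, 1), runif(1, 0.5, 2)))
}

wz_stats <- function(w, z) {
  structure(list(w = w, z = z, Sw = sum(w^2), Sz = sum(z^2), Tz = sum(z),
                 n0 = length(w), n1 = length(z), n = length(w) + length(z)),
            class = "odp_gene_stats")
}

stats_set <- function(genes) {
  # genes: list of odp_gene_stats with equal n0/n1
  structure(list(Sw = vapply(genes, `[[`, numeric(1), "Sw"),
                 Sz = vapply(genes, `[[`, numeric(1), "Sz"),
                 Tz = vapply(genes, `[[`, numeric(1), "Tz"),
                 n0 = genes[[1]]$n0, n1 = genes[[1]]$n1,
                 n = genes[[1]]$n, gene_id = NULL),
            class = "odp_stats")
}
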