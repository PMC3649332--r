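#' Configuration for the synthetic expression generator
#'
#' Describes the generative model the sampler emulates: per gene, a
#' null/differential indicator with null probability `pi0`, a mean
#' difference `d` drawn from `effect` for differential genes (0 otherwise),
#' a variance from `InvGamma(alpha, beta)`, a class-0 baseline mean from a
#' normal, and conditionally normal expression values in both classes with
#' that common variance.
#'
#' @param m number of genes.
#' @param n0,n1 samples per class.
#' @param pi0 true null proportion, in \[0, 1\].
#' @param effect effect-size distribution for `d` (raw mean-difference
#'   scale): `list(type = "point", at =, w =)` for point masses,
#'   `list(type = "uniform", min =, max =)`, or
#'   `list(type = "normal", mean =, sd =)`.
#' @param alpha,beta true inverse-gamma shape and rate for the variances.
#' @param mu0_mean,mu0_sd law of the class-0 baseline means (a nuisance the
#'   translation removes; its choice must not affect downstream results).
#' @param seed integer master seed.
#' @return A validated list of class `"odp_sim_config"`.
#' @export
odp_sim_config <- function(m = 5000L, n0 = 20L, n1 = 20L, pi0 = 0.8,
                           effect = list(type = "point",
                                         at = c(-0.5, 0.5),
                                         w = c(0.5, 0.5)),
                           alpha = 4, beta = 3,
                           mu0_mean = 0, mu0_sd = 1, seed = 1L) {
  if (!(pi0 >= 0 && pi0 <= 1)) stop("pi0 must be in [0, 1]")
  if (m < 1L || n0 < 1L || n1 < 1L) stop("m, n0, n1 must be >= 1")
  if (!(alpha > 0) || !(beta > 0)) stop("alpha and beta must be positive")
  if (is.null(effect$type) ||
      !effect$type %in% c("point", "uniform", "normal"))
    stop("effect$type must be 'point', 'uniform' or 'normal'")
  if (effect$type == "point") {
    if (length(effect$at) != length(effect$w) || any(effect$w < 0) ||
        sum(effect$w) <= 0)
      stop("point effect needs matching 'at' and nonnegative 'w'")
    effect$w <- effect$w / sum(effect$w)
  }
  structure(list(m = as.integer(m), n0 = as.integer(n0),
                 n1 = as.integer(n1), pi0 = pi0, effect = effect,
                 alpha = alpha, beta = beta,
                 mu0_mean = mu0_mean, mu0_sd = mu0_sd,
                 seed = as.integer(seed)),
            class = "odp_sim_config")
}

draw_effect <- function(effect) {
  switch(effect$type,
         point = sample(effect$at, 1L, prob = effect$w),
         uniform = stats::runif(1L, effect$min, effect$max),
         normal = stats::rnorm(1L, effect$mean, effect$sd))
}

#' Generate a synthetic two-class expression matrix with ground truth
#'
#' Samples exactly the hierarchical model the ODP fit assumes. Each gene
#' gets its own deterministic random stream derived from the master seed
#' and the gene index, so gene `k` is identical across runs regardless of
#' `m` (growing `m` appends genes without reshuffling earlier ones).
#'
#' @param config an [odp_sim_config()].
#' @return A list with `expr` (m x (n0+n1) matrix, gene ids as rownames),
#'   `labels` (0/1 per column, class 0 first) and `truth` (data frame with
#'   `gene_id`, `is_null`, `d_true`, `sigma2_true`).
#' @export
odp_simulate <- function(config) {
  if (!inherits(config, "odp_sim_config"))
    stop("config must come from odp_sim_config()")
  m <- config$m; n0 <- config$n0; n1 <- config$n1
  expr <- matrix(NA_real_, nrow = m, ncol = n0 + n1)
  is_null <- logical(m); d_true <- numeric(m); s2_true <- numeric(m)
  for (k in seq_len(m)) {
    set.seed(gene_seed(config$seed, k))
    is_null[k] <- stats::runif(1L) < config$pi0
    d_true[k] <- if (is_null[k]) 0 else draw_effect(config$effect)
    s2 <- 1 / stats::rgamma(1L, shape = config$alpha, rate = config$beta)
    s2_true[k] <- s2
    mu0 <- stats::rnorm(1L, config$mu0_mean, config$mu0_sd)
    expr[k, ] <- stats::rnorm(n0 + n1,
                              mean = c(rep(mu0, n0), rep(mu0 + d_true[k], n1)),
                              sd = sqrt(s2))
  }
  ids <- sprintf("gene_%05d", seq_len(m))
  rownames(expr) <- ids
  colnames(expr) <- c(sprintf("s0_%03d", seq_len(n0)),
                      sprintf("s1_%03d", seq_len(n1)))
  list(expr = expr, labels = c(rep(0L, n0), rep(1L, n1)),
       truth = data.frame(gene_id = ids, is_null = is_null,
                          d_true = d_true, sigma2_true = s2_true,
                          stringsAsFactors = FALSE))
}

# Counter-based per-gene sub-seed, kept inside the 32-bit integer range.
gene_seed <- function(seed, k) {
  as.integer((as.double(seed) * 69069 + as.double(k) * 1000003) %%
               2147483647)
}

#' Realized error rates of a selection against simulation truth
#'
#' @param selected logical vector (or integer indices) of selected genes.
#' @param truth the `truth` data frame from [odp_simulate()].
#' @return A list with `fdp` (false discoveries / selected, 0 when nothing
#'   is selected) and `tpr` (true selections / number of non-null genes).
#' @export
odp_evaluate <- function(selected, truth) {
  m <- nrow(truth)
  if (is.logical(selected)) {
    if (length(selected) != m) stop("selection and truth lengths differ")
    sel <- which(selected)
  } else {
    sel <- as.integer(selected)
    if (length(sel) && (min(sel) < 1L || max(sel) > m))
      stop("selection indices out of range")
  }
  n_sel <- length(sel)
  n_alt <- sum(!truth$is_null)
  fdp <- if (n_sel == 0L) 0 else sum(truth$is_null[sel]) / n_sel
  tpr <- if (n_alt == 0L) 0 else sum(!truth$is_null[sel]) / n_alt
  list(fdp = fdp, tpr = tpr, n_selected = n_sel)
}

#' Two-sample t-test with Benjamini-Hochberg selection
#'
#' The standard per-gene comparator: equal-variance two-sample t statistics
#' with pooled variance, two-sided p-values, BH adjustment, and selection
#' at the given level. Useful as a baseline when benchmarking the ODP's
#' information sharing across genes.
#'
#' @param expr genes x samples matrix.
#' @param labels 0/1 class labels per column.
#' @param q_level BH level.
#' @return A list with `p_value`, `p_adj` and `selected` (logical).
#' @export
ttest_bh <- function(expr, labels, q_level = 0.1) {
  labels <- as.integer(labels)
  x <- expr[, labels == 0L, drop = FALSE]
  y <- expr[, labels == 1L, drop = FALSE]
  n0 <- ncol(x); n1 <- ncol(y)
  if (n0 < 2L || n1 < 2L) stop("t-test needs at least 2 samples per class")
  mx <- rowMeans(x); my <- rowMeans(y)
  vp <- (rowSums((x - mx)^2) + rowSums((y - my)^2)) / (n0 + n1 - 2)
  tstat <- (my - mx) / sqrt(vp * (1 / n0 + 1 / n1))
  p <- 2 * stats::pt(-abs(tstat), df = n0 + n1 - 2)
  padj <- stats::p.adjust(p, method = "BH")
  list(p_value = p, p_adj = padj, selected = padj <= q_level)
}

#' Generate translated working-model data directly
#'
#' Samples the working model itself rather than raw expression values:
#' per gene, `theta` from the point-null + effect mixture (on the theta
#' scale, `theta = sqrt(n0/(n0+1)) d`), `sigma^2` from
#' `InvGamma(alpha, beta)`, then `w_1..w_n0 ~ N(0, sigma^2)` and
#' `z_1..z_n1 ~ N(theta, sigma^2)` independently. Because this sampler
#' satisfies the working likelihood's independence assumption exactly, it
#' isolates the estimation machinery from the approximation made by the
#' class-0-centering translation (which leaves the translated class-1
#' values weakly equicorrelated when applied to raw data).
#'
#' @param config an [odp_sim_config()]; `mu0_mean`/`mu0_sd` are unused
#'   (there is no baseline mean in the working model).
#' @return A list with `stats` (an `"odp_stats"` collection ready for
#'   [odp_fit()]'s internals and [odp_estep()]) and `truth` as in
#'   [odp_simulate()].
#' @export
odp_simulate_translated <- function(config) {
  if (!inherits(config, "odp_sim_config"))
    stop("config must come from odp_sim_config()")
  m <- config$m; n0 <- config$n0; n1 <- config$n1
  scale <- sqrt(n0 / (n0 + 1))
  Sw <- Sz <- Tz <- numeric(m)
  is_null <- logical(m); d_true <- numeric(m); s2_true <- numeric(m)
  for (k in seq_len(m)) {
    set.seed(gene_seed(config$seed, k))
    is_null[k] <- stats::runif(1L) < config$pi0
    d_true[k] <- if (is_null[k]) 0 else draw_effect(config$effect)
    s2 <- 1 / stats::rgamma(1L, shape = config$alpha, rate = config$beta)
    s2_true[k] <- s2
    w <- stats::rnorm(n0, 0, sqrt(s2))
    z <- stats::rnorm(n1, scale * d_true[k], sqrt(s2))
    Sw[k] <- sum(w^2); Sz[k] <- sum(z^2); Tz[k] <- sum(z)
  }
  ids <- sprintf("gene_%05d", seq_len(m))
  list(stats = structure(list(Sw = Sw, Sz = Sz, Tz = Tz, n0 = n0, n1 = n1,
                              n = n0 + n1, gene_id = ids),
                         class = "odp_stats"),
       truth = data.frame(gene_id = ids, is_null = is_null,
                          d_true = d_true, sigma2_true = s2_true,
                          stringsAsFactors = FALSE))
}
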