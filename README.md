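# odpmix

Empirical Bayes **optimal discovery procedure** (ODP) for two-class
differential expression, under a **semiparametric hierarchical mixture
model**. For statisticians and bioinformaticians screening thousands of
genes (microarray-style normalized log-expression) for differences between
two sample classes, who want the power of information sharing across genes
without committing to a parametric effect-size distribution.

## The model and the statistic

Per gene *k*, expression is two-class normal with a common within-gene
variance:

    x_k1..x_kn0 ~ N(mu_0k, sigma_k^2),   y_k1..y_kn1 ~ N(mu_1k, sigma_k^2)

Centering both classes on the class-0 sample mean (with variance-matching
factors sqrt(n0/(n0-1)) and sqrt(n0/(n0+1))) removes the nuisance baseline
and gives working data `w ~ N(0, sigma^2)`, `z ~ N(theta, sigma^2)` with
`theta = sqrt(n0/(n0+1)) d`, `d` the class mean difference. Across genes,

    theta_k ~ pi0 * delta_0 + pi1 * G,      sigma_k^2 ~ InvGamma(alpha, beta)

where `G` is arbitrary, represented by masses `p_1..p_L` on a grid of
nonzero support points (default: 200 points on [-1, 1], spacing 0.01).
The hyperparameters `eta = (pi0, pi1, p, alpha, beta)` are estimated by a
smoothing-by-roughening EM (smooth uniform start for `p`, roughened toward
the nonparametric MLE; closed-form E-step via conjugacy). Each gene is then
scored by the closed-form marginal likelihood ratio — the ODP statistic —

    R_ODP = sum_j p_j ((Sw + sum_i (z_i - a_j)^2)/2 + beta)^-(n/2+alpha)
            / ((Sw + Sz)/2 + beta)^-(n/2+alpha)

which maximizes expected true positives at each expected-false-positive
level. Significance is assessed by the empirical Bayes FDR (mean posterior
null probability over a rejection set) and q-values; analytic posteriors
give per-gene effect estimates and credible intervals.

## Worked example

```r
library(odpmix)
sim <- odp_simulate(odp_sim_config(m = 1000, n0 = 20, n1 = 20, seed = 7))
fit <- odp_fit(sim$expr, sim$labels)
print(fit)
#> Empirical Bayes ODP fit
#>   genes: 1000   samples: 20 (class 0) + 20 (class 1)
#>   grid: L = 200 on [-1, 1]
#>   pi0 = 0.4738  pi1 = 0.5262  alpha = 3.7047  beta = 2.6914
#>   EM: 361 iterations, log-likelihood -54737.1287, converged

summary(fit)
#> Significant genes by q-value level:
#>  q_level n_significant
#>     0.01            92
#>     0.05           190
#>     0.10           276
#>     0.20           426

head(fit$results[order(fit$results$rank), ], 5)
#>     gene_id R_odp  pr_null  q_value posterior_mean_d ci_low ci_high
#>  gene_00926 78825 1.14e-05 1.14e-05           -0.978 -1.025  -0.533
#>  gene_00374 67137 1.34e-05 1.24e-05            0.783  0.564   0.912
#>  gene_00662 13588 6.63e-05 3.04e-05           -0.592 -1.025  -0.430
#>  gene_00490 10001 9.00e-05 4.53e-05           -0.987 -1.025  -0.543
#>  gene_00329  8766 1.03e-04 5.68e-05           -0.978 -1.025  -0.533

odp_select(fit$results, 0.1)
#> 276 genes selected; estimated FDR = 0.09978
```

`R_odp` is the marginal likelihood ratio (large = strong evidence of
differential expression), `pr_null` the posterior probability the gene is
non-differential, `q_value` the smallest estimated FDR of a rejection set
containing the gene, and `posterior_mean_d` with `ci_low`/`ci_high` the
posterior mean and 95% credible interval of the class mean difference.
The data here were simulated with true `pi0 = 0.8` and effects of ±0.5:
the fitted `pi0 = 0.47` and the gap between the estimated FDR (0.10) and
the realized false-discovery proportion against the simulation truth
(`odp_evaluate()` reports 0.51 here) illustrate the optimism of the
working likelihood on raw two-class data that the methods vignette
analyzes in detail; the ranking itself is substantially more powerful
than a per-gene t-test with BH correction (`ttest_bh()`).

Plots: `plot(fit)` draws the estimated effect-size distribution
(`which = "trace"` the EM log-likelihood trace). `odp_prior_modes(fit$eta)`
counts smoothed local modes of the estimated prior — multimodality is the
signature that a unimodal parametric prior would have been inadequate.

A small CLI wraps the same functions
(`Rscript $(Rscript -e 'cat(system.file("cli/odp.R", package="odpmix"))') simulate|fit|test ...`),
reading/writing TSV expression matrices, a labels file and a JSON
hyperparameter sidecar.

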