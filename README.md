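# cormotif

Joint detection of differential gene expression across multiple two-condition
studies using **correlation motifs**.

## The problem

Given $D$ related expression studies, each comparing cases against controls,
one wants to know which genes are differential in which studies. Analysing
each study alone misses genes with weak but consistent signals; forcing full
concordance (differential everywhere or nowhere) misses study-specific
regulation; and modelling all $2^D$ differential configurations explicitly
stops scaling beyond a handful of studies.

The correlation-motif model threads this needle. Each study $d$ is reduced to
moderated $t$-statistics $t_{gd}$ (limma-style empirical-Bayes variance
shrinkage), so that a non-differential gene has
$t_{gd} \sim t_{\nu_d}$ with $\nu_d = n_{0d} + n_d - 2$, and a differential
gene has $t_{gd} \sim \sqrt{1 + w_d/v_d}\; t_{\nu_d}$. A hierarchical mixture
then assigns each gene $g$ a latent class $b_g \sim \mathrm{Cat}(\pi)$, and
given $b_g = k$ its differential indicators are independent
$a_{gd} \sim \mathrm{Bernoulli}(q_{kd})$. Each row $q_k$ of the $K \times D$
matrix $Q$ is a *motif*: a probabilistic differential-expression pattern. The
model needs only $O(KD)$ parameters yet gives every configuration positive
probability, so it pools information across studies and genes while remaining
flexible and scalable. $(\pi, Q)$ is estimated at its posterior mode by EM
under $\mathrm{Dir}(2,\dots,2)$ / $\mathrm{Beta}(2,2)$ priors; $K$ is chosen
by BIC; genes are ranked per study by
$\Pr(a_{gd} = 1 \mid T, \hat\pi, \hat Q)$ and called differential above a
0.5 cutoff.

The package also provides the in-family comparison methods sharing the same
densities (`fit_separate_limma()`, the $K = 1$ model; `fit_all_concord()`,
the two-configuration concordance model; `fit_full_motif()`, the saturated
$2^D$-configuration model), a seeded model-based simulation generator with
recorded ground truth, and evaluation tools (true-positive curves,
configuration confusion matrices).

## Worked example

Regenerate the reference four-study simulation (10 000 genes; 100 genes
differential in all four studies, 400 in studies 1–2, 400 in studies 2–3,
9100 null; 3 cases vs 3 controls; variance prior $n_0 = 4$,
$s_0^2 = 0.02$; case shifts with sd $4\sigma$), moderate it, scan $K$, and
evaluate:

```r
library(cormotif)
spec  <- preset_simulation(1, seed = 7)
sim   <- simulate_model_based(spec)
tstat <- moderate_studies(sim$data)          # n0, s0^2, w estimated per study
scan  <- scan_cormotif(tstat, k_grid = 1:6, seed = 7)
scan
#> <cormotif_scan> K in {1, 2, 3, 4, 5, 6}; best K = 4 by BIC
#>  K      BIC
#>  1 136976.4
#>  2 135876.2
#>  3 135848.8
#>  4 135848.1
#>  5 135895.6
#>  6 135943.0
fit <- scan$best_fit
fit$model
#> <motif_model> K = 4 motifs, D = 4 studies
#>            pi
#> motif1 0.9061 0.003 0.003 0.003 0.001
#> motif2 0.0421 0.932 0.949 0.046 0.015
#> motif3 0.0410 0.048 0.949 0.936 0.034
#> motif4 0.0108 0.875 0.895 0.941 0.843
```

The scan lands on four motifs whose rows track the true patterns: a null
motif carrying ~91% of genes, the two study-specific block motifs
($[1,1,0,0]$ and $[0,1,1,0]$, ~420/410 genes) and a small all-differential
motif (~108 genes). Ranking study 1 by the per-study posterior and counting
true positives:

```r
tp <- tp_curve(rank_genes(fit, study = 1, t = tstat$t), sim$truth_a[, 1])
tp[500]
#> 363
confusion_table(call_differential(fit), sim)
#> <confusion_table> called configuration (rows) vs truth (columns)
#>            true
#> called      [1,1,1,1] [1,1,0,0] [0,1,1,0] [0,0,0,0]
#>   [1,1,1,1]        46         1         2         0
#>   [1,1,0,0]        12       215        11        21
#>   [0,1,1,0]        10         9       214        10
#>   [0,0,0,0]         2       121       116      9022
#>   other            30        54        57        47
```

363 of the top 500 study-1 genes are truly differential (of 500 possible),
and most genes' full cross-study configurations are called exactly right —
the joint model recovers study-specific patterns that a per-study analysis
labels inconsistently. `tidy()`, `glance()`, `autoplot()` and
`plot_tp_curves()` give tibble and ggplot views of every result;
`run_simulation_pipeline()` chains the whole workflow (and
`inst/scripts/cormotif-pipeline.R` wraps it for the shell). Real data enter
via `load_multistudy()` (TSV/CSV expression tables plus a design) followed by
the same `moderate_studies()` → `fit`/`scan` → `evaluate` path.

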