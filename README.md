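# mptsource

Hierarchical Bayesian modelling of **multidimensional source memory**: did
participants bind two context features of a studied item — *veracity*
(true/false feedback) and *importance* (important/unimportant feedback) —
into one joint memory representation, or retrieve them independently?

The package is for memory researchers running two-dimensional
source-monitoring experiments: it turns trial-level old/new +
Remember/Know + source-attribution responses into latent process
estimates, with the guessing processes separated out.

## The model

Responses are modelled with the multidimensional source-memory multinomial
processing tree (MPT), a two-high-threshold recognition model extended
with two crossed source dimensions.  For a target studied with source
combination $(i, j)$:

$$P(\mathrm{OLD}_{vm} \mid i,j) = D_{ij}\big[d_{ij}\,1\{v{=}i,m{=}j\} +
(1-d_{ij})\,A(v \mid i)\,B(m \mid j,v)\big] + (1-D_{ij})\,b\,G(v)\,H(m \mid v)$$

where $D_{ij}$ is item detection, $d_{ij}$ **joint retrieval** of both
source features (the parameter of substantive interest: it produces
stochastic dependence between the two attributions),
$A$/$B$ mix independent feature retrieval ($e^{\mathrm{ver}}$,
$e^{\mathrm{imp}}$) with guessing ($a$), and $b$, $G$, $H$ govern "old"
guessing for undetected items; distractors are detected as new with
$D_{\mathrm{new}}$.  The standard restriction set
($D_{\mathrm{new}} = D_{TI}$, one $e$ per dimension, $g = a$) leaves 14
free parameters.

Estimation is hierarchical (latent-trait): participant parameters are
probit transforms $\theta_{pk} = \Phi(\mu_k + \delta_{pk})$ with
$\delta_p \sim \mathcal{N}(0, \Sigma)$, standard-normal priors on the
$\mu_k$ and a scaled inverse-Wishart prior on $\Sigma$, sampled with JAGS.
Model fit is checked with posterior-predictive statistics on mean
frequencies (T1) and the across-participant covariance structure (T2), and
hypotheses are tested with sampled posterior differences and 95% Bayesian
credibility intervals.

## Worked example

Simulate a cohort at the emulated study's design (82 participants, 9
studied statements per source combination, 18 distractors), fit, check,
and test the joint-retrieval hypothesis:

```r
library(mptsource)

constraints <- standard_constraints()
design <- design_spec()                      # 82 participants, 54 test items

# generating regime: joint retrieval concentrated on "true and important"
group <- default_group_distribution()        # d_TI=.42, d_TU=.06, d_FI=.05, d_FU=.04
params <- draw_participants(group, design$n_participants, seed = 1)
tables <- simulate_frequencies(params, design, seed = 2)

fit <- fit_mpt(tables, constraints, design,
               config = inference_config(n_chains = 2, n_iterations = 2500,
                                         n_burnin = 500, thinning = 2,
                                         n_adapt = 400, seed = 3))
summarize_posterior(fit)
contrast_battery(fit)
ppc_T1(fit, n_rep = 300, seed = 4)
ppc_T2(fit, n_rep = 300, seed = 5)
```

Output (abridged; the chains here are short for illustration and the
fitter warns that the potential scale reduction exceeds 1.05 — production
runs use the 50,000-iteration default):

```
     parameter median  mean  lower upper rhat
1         D_TI  0.676 0.676 0.6350  0.72  1.1
2         D_TU  0.616 0.610 0.4630  0.71  1.1
...
5         d_TI  0.428 0.417 0.1956  0.57  1.0
6         d_TU  0.063 0.083 0.0025  0.27  1.1
7         d_FI  0.080 0.092 0.0050  0.25  1.0
8         d_FU  0.086 0.098 0.0021  0.26  1.0
...
      name median  lower upper excludes_zero
1  delta_d  0.348  0.068 0.521          TRUE
2 delta_d1  0.331  0.090 0.511          TRUE
3 delta_d2  0.326  0.093 0.502          TRUE
4  delta_e -0.049 -0.172 0.058         FALSE
5  delta_D  0.056 -0.053 0.228         FALSE
6 delta_D1  0.012 -0.092 0.126         FALSE
7 delta_D2  0.018 -0.064 0.111         FALSE
Posterior-predictive check T1: p = 0.117 (300 replications)
Posterior-predictive check T2: p = 0.347 (300 replications)
```

Reading the output: the group-level posterior median of `d_TI` (.428,
generated at .42) is far above those of the other three source
combinations — the simulated participants jointly retrieved "true and
important" feedback, while the other combinations show essentially no
binding.  The contrasts `delta_d`, `delta_d1`, `delta_d2` quantify those
gaps with 95% credibility intervals excluding zero.  `delta_e` is
consistent with zero because the default generator gives both dimensions
equal independent-retrieval rates; the published-regime scenario in
`scripts/acceptance.R` (e_ver = .80, e_imp = .16) produces a large
positive `delta_e` instead.  The T1/T2 posterior-predictive p values are
far from 0, so the model's predicted mean frequencies and covariance
structure are consistent with the (here: simulated) data.

The same pipeline runs end-to-end from a config, writing posterior draws,
summary JSON, PPC and contrast reports plus a run log:

```r
run_pipeline(list(simulation = list(n_participants = 82)), out_dir = "run1", seed = 1)
```

External data enter as tab-separated trial records (with a configurable
column-name dialect) or pre-aggregated frequency tables; Remember/Know
coding (`remember_only` vs `remember_plus_know`) is applied at table
construction.  A thin command-line front end with `simulate`, `fit`,
`check`, `contrast` and `run` subcommands ships in `inst/cli/mptsource.R`,
and `write_eqn()` exports the model in the standard `.eqn` format for
general MPT software.

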