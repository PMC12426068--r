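---
title: "Modelling multidimensional source memory with mptsource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multidimensional source memory with mptsource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptsource)
```

## The measurement problem

In a two-dimensional source-monitoring experiment, participants study
statements that each carry two crossed context features — here *veracity*
feedback (true/false) and *importance* feedback (important/unimportant) —
and are later tested on a list mixing studied statements with new
distractors.  A test response has up to three components: an old/new
judgment, optionally a Remember/Know judgment, and (for "old" responses) an
attribution to one of the four source combinations.  The substantive
question is whether the two context features are retrieved *jointly*, as a
bound compound (producing stochastic dependence between the two
attributions), or *independently*.

Raw accuracy confounds memory with guessing.  The multidimensional
source-memory multinomial processing tree (MPT) model separates these
processes.  For a target studied with source combination $(i, j)$, the
response-category probabilities are sums over the branches of a processing
tree:

* with probability $D_{ij}$ the item is recognized (two-high-threshold
  detection);
* a recognized item's sources are retrieved jointly with probability
  $d_{ij}$, forcing the correct compound attribution;
* otherwise each dimension is retrieved independently
  ($e^{\mathrm{ver}}_{ij}$, $e^{\mathrm{imp}}_{ij}$) or guessed
  ($a^{\mathrm{ver}}$; $a^{\mathrm{imp}}_{|T}$, $a^{\mathrm{imp}}_{|F}$,
  conditioned on the veracity *response*);
* an unrecognized item attracts an "old" guess with probability $b$, with
  $g$-parameters governing the guessed attribution;
* distractors are detected as new with probability $D_{\mathrm{new}}$.

Formally, writing $A(v \mid i)$ and $B(m \mid j, v)$ for the independent
attribution probabilities on the veracity and importance dimensions,

$$P(\mathrm{OLD}_{vm} \mid i,j) = D_{ij}\,[\,d_{ij}\,1\{v{=}i, m{=}j\} +
(1-d_{ij})\,A(v \mid i)\,B(m \mid j, v)\,] + (1-D_{ij})\,b\,G(v)\,H(m \mid v),$$

with $G$ and $H$ the corresponding guessing terms for undetected items, and
$P(\mathrm{NEW} \mid i,j) = (1-D_{ij})(1-b)$.  `category_probabilities()`
implements this closed form; `enumerate_tree_paths()` independently builds
the explicit tree, and the two are cross-checked against each other in the
test suite to $10^{-12}$.  The path enumeration also generates the model's
EQN export, while the sampler code is generated from the closed-form
factorization (with shared attribution terms hoisted into helper nodes)
and is itself verified against `category_probabilities()` in the test
suite.

Two representational choices are worth stating.  Guessing "false" (or
"unimportant") is the complement of the corresponding "true" ("important")
guessing probability, not a free parameter.  And the enumeration orders the
two independent-retrieval dimensions veracity-first; because the two
factors multiply, the order does not affect any probability — it only fixes
which veracity response conditions the importance-guessing parameter,
matching the conditioning of $a^{\mathrm{imp}}_{|T}$ and
$a^{\mathrm{imp}}_{|F}$ on the item's assignment to "true" or "false".

## The standard restriction set

The full tree has 24 parameters; the canonical application equates
$D_{\mathrm{new}} = D_{TI}$, collapses the independent-retrieval
parameters to one per dimension ($e^{\mathrm{ver}}$, $e^{\mathrm{imp}}$),
and equates guessing across detection states ($g = a$, all three), leaving
14 free parameters:

```{r}
free_parameters(standard_constraints())
```

`constraint_set()` accepts arbitrary equality groupings, so other
restriction schemes can be explored; `apply_constraints()` expands free
values back to the full vector and is idempotent by construction.

## Hierarchical latent-trait estimation

Aggregating frequencies across participants can manufacture spurious
dependence, so estimation is hierarchical.  Each participant $p$'s free
parameters are probit transforms of person-specific effects around group
means:

$$\theta_{pk} = \Phi(\mu_k + \delta_{pk}), \qquad
\delta_p \sim \mathcal{N}(0, \Sigma).$$

Priors follow the usual latent-trait defaults: $\mu_k \sim
\mathcal{N}(0, 1)$ on the probit scale (a flat-ish prior centred on
$\theta = .5$), and a scaled inverse-Wishart prior on $\Sigma$ — a
Wishart with identity scale and $K + 1$ degrees of freedom on the unscaled
precision matrix, with per-parameter scaling factors uniform on $(0, 10)$.
The likelihood is the product over participants and the five processing
trees of multinomial likelihoods with fixed item totals.  Sampling is
Markov chain Monte Carlo via JAGS; the JAGS model source is generated at
run time from the package's own path enumeration and constraint map.

Defaults: 2 chains of 50,000 iterations, the first 20% discarded as
burn-in, thinning 10 (bounding memory at the default length); equal-tailed
credibility intervals (the reported bounds are the 2.5% and 97.5% posterior
quantiles, using R's default quantile interpolation); convergence is
gated at a potential scale reduction of 1.05 on every group-level
parameter — exceeding it raises a warning, not an error, so that
simulation studies with deliberately short chains remain usable.
Group-level summaries are reported on the probability scale as
$\Phi(\mu_k)$ per draw.

A degenerate complete-pooling variant (`pooling = "complete"`, all
participants sharing one parameter vector) exists for calibration and
misfit studies only.

## Posterior-predictive checks

Model fit is assessed with two discrepancy statistics computed per
retained posterior draw, each compared against a replicated cohort
simulated from the same participant-level parameters:

* **T1 (mean frequencies):** $\sum_{c} (\bar{y}_c - \bar{E}_c)^2 /
  \bar{E}_c$ over the 25 item-type × category cells, where $\bar{y}$ and
  $\bar{E}$ are observed and expected mean frequencies across
  participants.
* **T2 (covariance structure):** $\sum_{c \le c'}
  (S_{cc'} - \hat\Sigma_{cc'})^2 / (\hat\sigma_c \hat\sigma_{c'})$, where
  $S$ is the observed across-participant covariance matrix of the 25
  frequency cells and $\hat\Sigma$ its expectation under the draw — the
  between-participant covariance of expected counts plus the average
  within-participant multinomial covariance (block-diagonal by tree).
  Frequencies, not proportions, enter the statistic.

The posterior-predictive $p$ value is the fraction of draws whose
replicated discrepancy meets or exceeds the observed one; cells with zero
expectation (possible under degenerate parameter values) are skipped with
a warning.  Replications reuse the fitted participant-level parameters
rather than redrawing participants, matching the "observed mean
frequencies" framing of T1.  Calibration is verified in the test suite:
cohorts generated from the model give non-extreme $p$ values, while a
pooled fit of a heterogeneous cohort drives the T2 $p$ value below .05.

## Contrasts

Hypotheses about joint retrieval are tested with sampled posterior
differences on the probability scale (the scale on which the differences
are substantively interpreted): per draw, $\Delta = \Phi(\mu_a) -
\Phi(\mu_b)$, summarized by the median and an equal-tailed 95% interval,
with evidence for a difference when the interval excludes zero.
`contrast_battery()` computes the seven standard contrasts — joint
retrieval of the true-and-important source against the three other
combinations, the veracity-versus-importance gap in independent retrieval,
and the three item-memory contrasts.  No multiplicity correction is
applied across the battery, and the exported report says so.

## The synthetic cohort generator

`design_spec()` defaults mirror the emulated study: 82 participants, 36
studied statements (9 per source combination), 54 test items of which 18
are new.  `default_group_distribution()` fixes the generating regime used
throughout the package's simulations: joint-retrieval group means at the
published medians ($d_{TI} = .42$, $d_{TU} = .06$, $d_{FI} = .05$,
$d_{FU} = .04$), moderate detection ($D = .70$ — high enough for realistic
hit rates, below the ceiling effects such experiments often meet), neutral
guessing and independent retrieval ($.5$), and independent probit-scale
heterogeneity with standard deviation $0.4$ — a moderate degree of
individual variation typical of hierarchical MPT applications, chosen once
and not revisited.  Scenario studies that need a strong dimension gap use
$e^{\mathrm{ver}} = .80$, $e^{\mathrm{imp}} = .16$, consistent with a
dimension contrast of $.64$.

The Remember/Know tag in `simulate_trials()` is an independent Bernoulli
overlay with rate $.5$ (neutral, exercising both coding paths equally); it
is a data-selection device, not a modelled cognitive state.  Item
responses are drawn per item in a fixed order shared with
`simulate_frequencies()`, and the tags are drawn afterwards, so collapsing
trials under the `remember_plus_know` rule reproduces the frequency
generator exactly at the same seed.

What the generator does *not* emulate: statement content and plausibility,
counterbalancing versions, serial-position or buffer effects, correlated
individual differences (the default $\Sigma$ is diagonal), and any genuine
cognitive Remember/Know process.  Passing recovery and calibration tests
therefore shows that the estimation machinery is sound under the model's
own assumptions — not that real data satisfy those assumptions.

## Response coding

Under the `remember_only` rule (the focal analysis, since stochastic
dependence is carried by recollection), an "old" response tagged Know is
*recoded as new* rather than dropped: the multinomial likelihood needs
fixed item totals per tree.  Dropping such trials would change row totals
per participant and break the likelihood bookkeeping; both behaviours were
considered, recoding is the default, and the coding rule in force is
written to the run log.

## Numerical choices and degenerate inputs

* $0 \cdot \log 0 = 0$ in the multinomial log-likelihood; a positive count
  on a zero-probability category yields $-\infty$.
* Probabilities outside $[0,1]$, non-PSD covariances, mismatched row sums,
  duplicate trials and incomplete participants are rejected at the door
  (incomplete participants are excluded with a warning rather than an
  error, since single dropped participants are routine in practice).
* Chain initialization sets all probit means to 0 ($\theta = .5$) and
  person effects to 0; chain RNGs are seeded deterministically from the
  configuration seed, making fits bit-reproducible.
* At chance-level regimes ($e = a = .5$) the joint-retrieval parameters
  other than the dominant one sit on a likelihood ridge — joint and
  independent retrieval become indistinguishable — so their posteriors are
  wide and prior-influenced.  Recovery of such parameters is assessed by
  interval coverage, not point error; this is a property of the model, not
  of the sampler.

## Problem sizes used in the shipped studies

The package's simulation studies (test suite and the acceptance script)
run at the study's own size — 82 participants, 9 items per source, 18
distractors — with deliberately short chains (single chains of 900–1,500
iterations for replication studies, the longer end where interval
endpoints rather than medians are assessed; 2 × 4,000 for the headline
fit), 20 replications for recovery, and 10 seeds for calibration checks.  These
lengths were chosen as the smallest that keep Monte-Carlo error well below
the effects under study; production analyses should use the 50,000
iteration default and at least two chains, and respect the 1.05
convergence gate.

## Limitations

* The sampler backend is JAGS; no gradient-based alternative is bundled.
* No model-comparison machinery (DIC/WAIC) and no maximum-likelihood
  aggregate fitting interface are provided.
* The latent-trait prior's scaling-factor bound (10) and Wishart degrees
  of freedom ($K+1$) follow the conventional defaults; sensitivity
  analyses beyond prior reporting are left to the user.
* External data enter through the dialect-mapped trial reader; the
  package assumes complete 54-item test protocols per retained
  participant.
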