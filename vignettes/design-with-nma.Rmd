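---
title: "Designing a two-arm trial to be analysed with an existing network meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing a two-arm trial to be analysed with an existing network meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmadesign)
```

## The model

`nmadesign` plans a new two-arm trial with a binary outcome when the two
treatments, A and B, already belong to a connected network of earlier
trials but have never been compared directly. The network is synthesised
with the fixed-effect contrast-based model: each study contributes one
row per pairwise comparison, an observed log odds ratio `TE` with
standard error `seTE`, and under the consistency assumption every
contrast is a linear combination of the basic parameters $\mu$ (each
treatment versus a baseline). The weighted least-squares solution

$$\hat\mu = (X^\top S^{-1} X)^{-1} X^\top S^{-1} y,
\qquad \mathrm{Var}(\hat\mu) = (X^\top S^{-1} X)^{-1},$$

with $S$ the diagonal matrix of squared standard errors, is computed by
`fit_nma()` via a Cholesky factorisation of the normal equations rather
than an explicit inverse. All pairwise effects and standard errors
derive from $\hat\mu$, so they do not depend on the baseline choice (the
default baseline, the alphabetically first label, only fixes a
parameterisation). `indirect_se()` extracts the one number the design
formulas borrow from the network: $\sigma_{AB,\mathrm{eNMA}}$, the
standard error of the indirect A-vs-B estimate.

$S$ is taken fully diagonal, as the model above states: the within-study
covariance between the contrasts of a three-arm trial is ignored. A
correlation-adjusted multi-arm weighting (as some general-purpose NMA
software applies) would change indirect standard errors slightly; it is
deliberately out of scope, and the one consequence worth knowing is that
reference values produced by such software on multi-arm data may differ
from `fit_nma()` in the third decimal.

When the new trial's estimate (variance
$\sigma^2_{AB,\mathrm{trial}} = 1/(n_1 p_1 q_1) + 1/(n_2 p_2 q_2)$, the
Wald/logistic-regression variance at risks $p_i$, $q_i = 1 - p_i$) is
added to the network, the updated precision is the sum of precisions:

$$\sigma^{-2}_{AB,\mathrm{uNMA}} = \sigma^{-2}_{AB,\mathrm{trial}}
  + \sigma^{-2}_{AB,\mathrm{eNMA}}.$$

`update_network()` realises this by refitting the enlarged network; the
identity holds to numerical precision and is asserted in the test suite
at $10^{-10}$.

Power uses the two-sided normal approximation at level $\alpha$
(default 0.05, $z$ always computed from `sig.level`, never hard-coded):

$$\mathrm{Power} = \Phi\!\left(\frac{lor}{sd} - z_{1-\alpha/2}\right)
 + \Phi\!\left(-\frac{lor}{sd} - z_{1-\alpha/2}\right),$$

where $lor = \mathrm{logit}(p_2) - \mathrm{logit}(p_1)$ and $sd$ is the
design standard deviation of the chosen analysis plan (`design_sd()`),
i.e. the trial-only standard error (`method = "without"`) or the pooled
one (`method = "with"`). At $lor = 0$ the expression equals $\alpha$
exactly. The supplied risks are treated as known plug-in values
throughout; no uncertainty is propagated through $p_1$, $p_2$ or
$\sigma_{AB,\mathrm{eNMA}}$.

## The two design problems and their numerical conventions

**Fixed total (`ssanma()`).** The variance
$a/n_1 + b/n_2$ with $a = 1/(p_1 q_1)$, $b = 1/(p_2 q_2)$ is minimised
subject to $n_1 + n_2 = N$. The continuous optimum is
$n_1^\ast = N\sqrt a/(\sqrt a + \sqrt b)$; the integer solution is the
better of its floor and ceiling, which equals exhaustive search because
the objective is convex in $n_1$. More subjects go to the arm with the
smaller $p(1-p)$ — the arm carrying less information per subject.
Because pooling with the network adds a constant precision, the optimal
split is the same under both analysis plans; only the achieved power
differs. Exact ties (possible only at symmetric risks) assign the extra
subject to the higher-variance arm. `allocation = "even"` with an odd
$N$ is rejected rather than silently rounded.

**Target power (`ssnma()`).** The required design standard deviation is
found by bisection on the full two-term power expression (tolerance
$10^{-12}$), not the one-tailed shortcut that drops the second $\Phi$
term. For the with-network analysis the network's precision
$1/\sigma^2_{AB,\mathrm{eNMA}}$ is subtracted, leaving the precision the
trial itself must supply; the Lagrange solution then gives continuous
per-arm sizes. Two integer conventions are offered:

* `rounding = "ceiling"` (default): each arm's continuous size is
  rounded up. This conservative rule always meets the target and
  overshoots the exact integer optimum by at most one subject per arm.
  It is the convention whose results the package prints by default, and
  the convention under which the worked examples in the README hold.
* `rounding = "minimal"`: the exact smallest feasible integer total,
  found by scanning totals upward from the continuous lower bound
  $(\sqrt a + \sqrt b)^2 / v$ (only the convexity-certified best split
  of each total needs checking). The test suite certifies minimality by
  showing no split of `total − 1` attains the target, and checks
  agreement with the brute-force `grid_design()` on hundreds of random
  problems.

The two conventions genuinely differ: for risks 0.2/0.3, network SE
0.3 and target 0.8, ceiling rounding gives 187 + 163 = 350 subjects
while the exact optimum is 186 + 163 = 349. We keep the conservative
rule as the default because a guaranteed, reproducible convention
matters more in practice than a single subject, and because it is the
convention practitioners of this method will recognise; the exact mode
is there for anyone optimising to the last subject.

If the network alone already attains the target (`method = "with"` with
a very small $\sigma_{AB,\mathrm{eNMA}}$), the required trial precision
is non-positive; `ssnma()` then warns and returns the minimum allocation
(1, 1) flagged as degenerate instead of failing, since "no trial needed"
is an answer, not an error.

`grid_design()` is the independent verifier: pure enumeration of
integer allocations against the power formula. One numerical subtlety:
at large totals the power saturates at 1 in floating point, so
allocations are compared on the trial variance — mathematically
equivalent (power is strictly decreasing in the variance) and free of
spurious ties.

## Data handling

Contrast-level CSVs use the conventional five columns `studlab, treat1,
treat2, TE, seTE`, with `TE` the log odds ratio of `treat1` relative to
`treat2`; extra columns are dropped with a warning, labels are
whitespace-trimmed and compared exactly, and multi-arm studies are
simply multiple rows sharing a `studlab`. Arm-level counts convert to
contrasts with the Wald estimator; when any cell of the 2×2 table is
zero, 0.5 is added to all four cells (Haldane–Anscombe) before both the
estimate and its standard error. The correction rate is reported by the
simulation summaries so a scenario dominated by corrected tables is
visible.

## What the simulations emulate — and what they do not

The synthetic-network generator (`network_spec()`,
`generate_network()`) draws each arm's event count from
$\mathrm{Binomial}(n, p_j)$ at fixed per-treatment risks, then converts
to contrasts. `brd_network_spec()` reproduces the scale of the bovine
respiratory disease network that motivates the method: 13 treatments,
98 trials, 204 arms (8 of them in three-arm trials), an untreated
control with risk 0.68, the two planned treatments (risks 0.1868955 and
0.2366667) never compared directly. The underlying arm-level data are
not public, so the study layout, the remaining active-treatment risks
(0.15–0.40, typical of feedlot trials) and the arm size (150 animals)
are this package's own realistic stand-ins; nothing downstream depends
on those choices beyond the resulting indirect standard error.

Two validation protocols mirror how the method itself is justified:

* `simulate_design_fixed_total()` — per replicate: redraw the network's
  event counts, fit the NMA to get that replicate's
  $\sigma_{AB,\mathrm{eNMA}}$, simulate the new trial at the optimal and
  the even split of a fixed total, and test the comparison at level
  $\alpha$ both alone and inside the updated network. Simulated
  rejection rates and mean standard errors sit next to their closed-form
  counterparts.
* `simulate_design_target_power()` — per replicate, solve `ssnma()` at
  the replicate's indirect SE (uneven and even variants), simulate at
  the solved sizes, analyse both ways, and record the achieved sizes
  and rejections.

Replicates use per-replicate child seeds derived from one root seed, so
runs are exactly reproducible and both allocation strategies see the
same resampled network within a replicate. The default 2000 replicates
keep a full protocol under ten seconds on a laptop-class core while
holding Monte-Carlo noise on a power estimate near ±2.7 percentage
points (3 binomial SEs); the original protocols' 10,000 replicates are a
single argument away. Inside the replicate loop the NMA is refitted
through a precomputed design matrix and a rank-one update for the new
trial — the test suite verifies this equals `fit_nma()` /
`update_network()` to $10^{-10}$.

The tests exercise these protocols on scaled-down connected networks
(four treatments, six studies, 150–300 subjects per arm) rather than the
full 98-trial layout; the closed-form identities they validate are
size-free, so this choice only trades Monte-Carlo tightness against run
time. One scenario-design caveat discovered while validating: with
300-subject arms the example network's indirect SE is so small that an
80%-power design problem at $lor = 0.5$ becomes degenerate (the network
alone suffices), so the target-power protocol is demonstrated on the
150-subject variant where the new trial must contribute information.

What passing these simulations does **not** show about real data: the
generator draws from exactly the fixed-effect binomial model the
formulas assume — no between-study heterogeneity, no inconsistency
between direct and indirect evidence, no risk drift across studies, and
known true risks. Agreement therefore validates the algebra and the
code, not the model's adequacy for any particular network.

## Known limitations

* All power statements are normal approximations. The Wald test with an
  estimated standard error is slightly anticonservative at moderate arm
  sizes — about one percentage point above the formula at 150–300
  subjects per arm, vanishing by 1000 per arm. The formulas inherit
  this; exact binomial power is out of scope.
* Fixed-effect synthesis only: no random-effects NMA, heterogeneity or
  inconsistency diagnostics, and no correlation adjustment for
  multi-arm studies.
* The planned trial must compare two treatments already connected in
  the network; designs introducing a new treatment are not covered.
* Effect measure is the log odds ratio throughout; risk differences,
  risk ratios and continuous outcomes are not supported.
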