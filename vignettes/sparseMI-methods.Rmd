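---
title: "Estimating mutual information when one variable is severely undersampled"
author: "sparseMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutual information when one variable is severely undersampled}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparseMI)
```

## The problem

Many data sets pair a huge-alphabet discrete variable $X$ (neural population
words, genotypes, behavioural sequences) with a small, well-sampled one $Y$
(a binary choice, a phenotype class). The mutual information

$$I(X;Y) = H(Y) - H(Y|X) = \sum_x q_x\, D_{\mathrm{KL}}(q_{y|x}\,\|\,q_y)$$

measures their dependence, but when $N \lesssim e^{H(X)}$ most observed $x$
states carry one or two samples, the plug-in estimator badly underestimates
$H(Y|x)$ per state and therefore overestimates $I$. Entropy-difference
Bayesian estimators (NSB-style, Pitman–Yor mixtures) select a different
concentration for each entropy term and can even return negative
information. `sparseMI` implements a Bayesian estimator built for the
*asymmetric* regime: $Y$ well sampled, $X$ (and the joint) arbitrarily
undersampled.

## The model

The $y$ marginal is taken as known, $\hat q_y = n_y / N$, and the whole
collection of conditionals $\{q_{y|x}\}$ receives a product Dirichlet prior
centered at $\hat q_y$ with a single concentration $\beta$:

$$p(\{q_{y|x}\}\mid\beta) = \prod_x \mathrm{Dir}\!\left(q_{y|x};\,
\beta \hat q_y\right).$$

$\beta$ encodes exactly the quantity that drives the information — the
spread of the conditionals around the marginal. Large $\beta$ pins every
conditional at $\hat q_y$ (no information); small $\beta$ pushes them to the
corners of the simplex (maximal information). The conjugate structure gives
every needed quantity in closed form:

* **Posterior mean.** $\langle I\mid n,\beta\rangle = \hat H(Y) - \sum_x
  \frac{n_x}{N}\big[\psi_0(\beta+n_x+1) - \sum_y
  \frac{\beta\hat q_y + n_{xy}}{\beta+n_x}\,
  \psi_0(\beta\hat q_y+n_{xy}+1)\big]$ — `posteriorMeanInformation()`.
* **Marginal likelihood of $\beta$.** A product over $x$ states of Gamma
  ratios, computed entirely in log space — `logMarginalLikelihoodBeta()`.
  Singleton states contribute a constant factor, so only *coincidences*
  (states with $n_x \ge 2$) inform $\beta$. Grouping equal terms shows that
  the multiplicities $m_{nn'}$ (how many states carry a given count
  pattern) are sufficient statistics — `multiplicities()`.
* **Closed-form maximizer.** For binary symmetric $Y$ with at most double
  coincidences, with $f_{11}$ the fraction of 2-count states split across
  both $y$ values, $\beta^* = f_{11}/(1/2 - f_{11})$, infinite when
  $f_{11}\ge 1/2$ (the data look independent) — `betaMAP()`.
* **Prior mean and the prior on $\log\beta$.** The information expected
  under the prior alone decreases monotonically from $H(\hat q_y)$ to $0$;
  requesting a *uniform* distribution over that prior information yields
  the reference prior density $p(\log\beta)\propto
  |\partial_{\log\beta}\langle I\mid\beta\rangle|$ —
  `priorMeanInformation()`, `logBetaPrior()`, `sampleLogBetaPrior()`.

### Posterior variance

Conditional on $\beta$, the posterior factorizes over $x$ states into
independent Dirichlet laws $q_{y|x}\sim\mathrm{Dir}(\beta\hat q_y + n_{x\cdot})$,
with $q_x$ held at $n_x/N$ and $H(Y)$ at its plug-in value. The variance of
$I$ is therefore a weighted sum of per-state entropy variances,

$$\sigma^2(I\mid n,\beta) = \sum_x \left(\frac{n_x}{N}\right)^2
\mathrm{Var}\big[H(q_{y|x})\big],$$

with the Dirichlet entropy variance evaluated from the classical
digamma/trigamma moment formulas. Because the weights enter squared, the
variance scales as $1/k_x$ when a multiplicity pattern is replicated across
more states: the method *gains* precision from a large state space even
though each state is undersampled. Every use of this expression in the
package is validated against a conjugate-posterior Monte-Carlo oracle in
the test suite.

### Unobserved states

A Dirichlet-process prior on $q_x$ with concentration $\alpha$ adds the
never-observed states back in: the posterior mean becomes a mixture
$\frac{N}{N+\alpha}\langle I\rangle_{\mathrm{obs}} +
\frac{\alpha}{N+\alpha}\langle I\rangle_{\mathrm{prior}}$, and the marginal
likelihood of $\alpha$ depends only on $(N, k_1)$
(`logMarginalLikelihoodAlpha()`, `alphaMAP()`,
`posteriorMeanInformationDP()`). When the data contain no coincidences the
$\alpha$ likelihood increases without bound; the MAP is flagged divergent
and the correction is disabled with a warning.

## The estimation pipeline

`estimateMI()` ties these together. The default method evaluates the
posterior moments at the likelihood maximizer $\beta^*$. When the table
holds **two or fewer coincidences** the likelihood peak is too weak to
dominate the prior, so the posterior is integrated over
$p(\log\beta)\,p(n\mid\beta)$ by the trapezoid rule on the $\beta$ grid
instead (always, not optionally — with this little evidence the prior
matters). With *no* coincidences the integration is the only option and the
result is flagged. We found integration and MAP otherwise indistinguishable
on the benchmarks, which is why MAP is the default.

Numerical choices:

* $\beta$ grid: 400 log-spaced points in $[10^{-4}, 10^5]$, refined around
  the grid argmax by golden-section (`optimize`). An infinite maximizer is
  detected by comparing the best finite grid value against the *exact*
  $\beta\to\infty$ limit of the log likelihood ($\sum_x\sum_y n_{xy}\log
  \hat q_y$, every conditional pinned at the center) — far more robust than
  probing `lgamma` differences at huge $\beta$, where rounding swamps the
  slope — and is then treated analytically ($I\to 0$, variance $\to 0$).
* $\alpha$ grid: 300 log-spaced points in $[10^{-2}, 10^8]$, MAP only.
* All Gamma-function ratios go through `lgamma`; digamma/trigamma come from
  base R's `digamma`/`trigamma`. No raw `gamma()` anywhere, so overflow is
  structurally impossible.
* Degenerate inputs: a single-state $Y$ yields $I=0$ with a warning; a
  declared $y$ level with zero counts is dropped with a warning (the prior
  center must be strictly positive, and the model presumes every $y$
  observed); a small minimum $n_y$ (below 10) triggers an undersampled-$Y$
  warning because the method's premise is a well-sampled marginal.
* Units are nats internally; `units = "bits"` divides by $\log 2$ on
  output.

```{r example}
set.seed(1)
model <- makePYBetaModel(beta = 2.3, maxAtoms = 1e5)
ct <- sampleCounts(model, 500)
estimateMI(ct)
c(truth = trueInformation(model),
  plugin = pluginInformation(ct))
```

## What the generators emulate

Three synthetic families reproduce the benchmark settings used to validate
the estimator, each stressing the prior assumptions differently:

1. **`makePYBetaModel()`** — $q_x$ from a Pitman–Yor process
   ($d = 0.55$, $\alpha = 50$: a heavy-tailed marginal with effective size
   $e^{H_{XY}} \approx 800$ at $\beta = 2.3$), conditionals drawn from the
   estimator's own prior. The in-model case.
2. **`makeSphereModel()`** — 12 delta functions at icosahedron vertices
   (the unique equal-spacing arrangement of 12 points, chosen for maximal
   symmetry), all $2^{12}$ subsets equiprobable, and a conditional that is
   a sigmoid of the rotation-invariant spherical-harmonic power score
   $\pi_0-\pi_1-\pi_2$ ($\ell\le 2$). The offset is tuned by root finding
   so $q_{y=1}=0.5$ and the gain so $I=0.5$ nats; any rotation-invariant
   harmonic normalization works because both parameters are re-tuned to
   those targets. The conditional law is *rough* (delta peaks from the
   rotation classes), deliberately outside the Dirichlet family; the tuned
   model pins $e^{H_{XY}} = 4096\,e^{\log 2 - I} \approx 5000$.
3. **`makeParityModel()`** — $X$ a Bernoulli($p=0.05$)$^{40}$ vector,
   $q_{1|x} = 1/2$ on even parity and $q_0$ or $1-q_0$ on odd parity. The
   conditional law is a three-delta mixture that *no* single concentration
   can represent. The branch is assigned by a deterministic keyed hash of
   the bit pattern: equal probability across states, consistent within a
   run. The exact information uses the ideal three-class aggregation,
   $I = P(\mathrm{odd})\,(\log 2 - H_2(q_0))$; a realized hash split
   deviates from the ideal half/half *mass* split by $O(\text{imbalance}^2)
   \approx 10^{-3}$ nats at these parameters, well inside the Monte-Carlo
   tolerances used to validate it.

**Truncation.** Stick-breaking runs until the residual mass drops below
`truncation` (default $10^{-8}$) *or* `maxAtoms` sticks (default $5\times
10^5$) are broken. For heavy tails ($d=0.55$) the residual decays only like
$n^{-(1-d)/d}\approx n^{-0.82}$, so the atom cap binds; at the default cap
the truncated tail removes about 0.02 nats of marginal entropy (roughly 2%
of $e^{H_{XY}}$), negligible relative to the draw-to-draw spread of the
ensemble.

What the generators do *not* emulate: real data with structured,
metric-correlated conditionals (the method deliberately ignores any
geometry on $X$), non-stationary sampling, or an undersampled $Y$. Passing
the benchmark suites therefore shows calibration under exchangeable
sampling from fixed joints — not robustness to those failure modes, and
the estimator is expected to break down when $Y$ itself is undersampled.

## Experiments

`biasVsSamples()` and `biasVsInformation()` reproduce the bias curves: mean
and SD of each estimator over replicate sample sets (50 by default), either
against $N$ or against the information swept through the family parameter
($\beta \in [0.04, 14]$ for the heavy-tail family at $N = 500$, the sigmoid
gain for the sphere, $q_0 \in [0.01, 0.4]$ for parity at $N = 2000$). The
$x$-marginal of the heavy-tail family is drawn once and reused across a
sweep, so truth varies only through the conditionals. The sweep grids are
log-spaced over those ranges (5 points by default); exact grids are a free
choice.

`calibrationStudy()` checks Bayesian calibration in the same spirit as the
estimator's own derivation: 13,500 joint models with $q_x \sim DP(\alpha)$,
$\alpha$ equiprobable in $\{e^4, e^5, e^6\}$, $\log\beta$ from the
information-uniform prior, and binary conditionals from the centered Beta;
5 sets of $N=40$ samples per model. Cases that land in the same
multiplicity class are exchangeable given the class, so within each class
the mean and SD of the *true* information can be compared to the analytic
posterior mean and SD given the class, integrated over
$p(\log\beta)p(n|\beta)$ (single classes rarely hold more than a couple of
coincidences, which is exactly where integration matters). Class
predictions use the symmetric center $q_y = 1/2$ and $H(Y)=\log 2$ — the
class carries no $\hat q_y$ of its own and the generating conditionals are
symmetric. The top-100 classes cover about 70% of the 67,500 cases, and
predicted versus empirical class means cluster on the diagonal (the test
suite checks a weighted regression slope near 1 on a scaled run). The
full-scale study runs in about a minute; `nModels` scales it down.

## Known limitations

* $H(Y)$ is always the plug-in value; there is no Bayesian correction on
  the marginal of $Y$ (its error is negligible exactly when the method's
  premise — $Y$ well sampled — holds, and the implementation warns when it
  does not).
* The estimator is non-negative by construction, hence positively biased
  when the true information is zero; under independence the bias shrinks
  like the inverse square root of the number of pairwise coincidences
  (inverse of $N$ for a near-uniform $q_x$), which the test suite checks
  empirically.
* Only $d=0$ (Dirichlet-process) inference is offered for $q_x$; the
  Pitman–Yor discount is a generator-side parameter, not an inference
  target.
* The multiplicity decomposition of the conditional entropy
  (`conditionalEntropyMultiplicities`) is implemented for binary $Y$; the
  estimator itself handles any $k_y \ge 2$.
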