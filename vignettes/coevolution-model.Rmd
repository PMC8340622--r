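---
title: "A continuous-time co-evolution model for friendship networks and continuous behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A continuous-time co-evolution model for friendship networks and continuous behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevolnet)
```

## The problem

Two-wave panel studies of adolescent friendship networks record, at each
wave, who names whom a friend and a behavior value per person -- here a
continuous one such as body mass index (BMI). Two social processes are
confounded in such data: *selection* (people befriend others with similar
behavior) and *influence* (people's behavior drifts toward their friends').
Discrete-choice actor-based models (SAOM) separate the two for bounded,
integer-valued behaviors, but their exponential behavior objective behaves
poorly for genuinely continuous variables with a wide range: transition
probabilities depend on the arbitrary discretization, and the implied change
distribution is not consistent under composition of time intervals.

`coevolnet` implements a joint model built around a *linear* behavior
process that composes exactly over time, together with everything needed to
fit it to two-wave data: a forward simulator, the complete-data likelihood,
a Metropolis-Hastings sampler that imputes the latent event history between
the waves, and a Monte Carlo EM (MCEM) maximum-likelihood estimator. A
small forward-probability calculator for the SAOM behavior step is included
as the comparison baseline.

## The model

**States.** A directed binary adjacency matrix $y$ ($y_{ij} = 1$ iff $i$
names $j$; zero diagonal) and a real behavior vector $z$ of length $n$.

**Events.** Network changes happen at the points of a Poisson process with
rate $\lambda$ per unit time; over a horizon $T$ the event count is
Poisson($\lambda T$) and, given the count, event times are ordered
uniforms. Every event toggles exactly one edge: an actor $i$ is drawn
uniformly, then edge $(i, j')$ is toggled with probability

$$P(i, j') \propto \exp\{(2 y_{ij'} - 1)\, \theta^\top \delta_{ij'}(y, z)\},$$

where $\delta_{ij'}$ is the vector of change statistics (the effect values
with the edge forced on minus forced off). The built-in effects are
outdegree, reciprocity, transitive triplets, same-attribute, and centered
behavior similarity $\sum_j y_{ij}(1 - |z_i - z_j|/\text{range} -
\overline{\text{sim}})$; the similarity range and centering constant are
user-supplied inputs, never computed silently. The sign factor
$(2y_{ij}-1)$ is implemented exactly as the model defines it; because it
makes high-utility existing ties the *most* likely to be dismantled --
arguably counterintuitive -- `edge_change_distribution()` exposes a
`sign = "reversed"` option, with the printed convention as the default used
everywhere else.

**Behavior.** Between events the behavior increment over an interval of
length $dt$ satisfies a spatial-lag (network autocorrelation) equation

$$(I - \alpha W)\,\Delta z = dt\, X\gamma + \varepsilon, \qquad
\varepsilon \sim N(0,\; dt\,\sigma^2 I_n),$$

with $W$ the row-normalized adjacency of the interval's network: $(Wz)_i$
is the mean behavior of $i$'s named friends, and $\alpha$ measures how
strongly a person's change follows their friends' average change. Rows of
$W$ for friendless actors are set to zero -- the natural limit of "average
of friends" with no friends; those actors follow the covariate trend plus
noise only, and the choice keeps $I - \alpha W$ invertible whenever
$|\alpha| < 1$ (row-stochastic $W$ has spectral radius at most 1; the
estimator constrains $\alpha$ to $(-0.99, 0.99)$). Because the noise
variance is linear in $dt$, the increment law composes exactly: the sum of
independent increments over $(t_0, t_1)$ and $(t_1, t_2)$ has precisely the
one-interval distribution over $(t_0, t_2)$ for a fixed network -- the
property the SAOM behavior step lacks, and one the test suite asserts both
analytically and distributionally. $W$ is piecewise constant between
events, which is also how the likelihood reads it.

**Ordering at an event.** Within the interval ending at $t_u$ the behavior
increment is realized first (using the pre-event network's $W$), then the
edge toggle is drawn with weights evaluated at the pre-event network and
the post-increment behavior. The simulator, the likelihood and the
imputation sampler all share this one convention.

## Complete-data likelihood

For a complete path (event count $k$, times, toggles, increments) the
log-likelihood is

$$\ell = -\lambda T + k \log \lambda
  + \sum_{u=1}^{k} \log P(\text{toggle}_u)
  + \sum_{u=1}^{k+1} \log f(\Delta z_u),$$

where the first two terms merge the Poisson count pmf with the
ordered-uniform times density, each toggle probability includes the uniform
$1/n$ actor factor, and each increment density is the Gaussian above with
its change-of-variables Jacobian $\log|\det(I - \alpha W)|$. All constants
are kept, so `exp(complete_log_likelihood(...))` is the exact joint path
density -- the test suite checks it term by term against independently
accumulated per-step probabilities at $10^{-10}$ relative tolerance.

## Imputation of the latent history

The observed data are only the two panels $(y^0, z^0)$ and $(y^T, z^T)$.
Let $d$ be the number of dyads on which the two networks disagree (the
*important list*); any latent history must contain $k = d + 2a$ events for
some $a \ge 0$. One whole-path proposal draws:

1. $k$ from the Poisson($\lambda T$) pmf restricted to $\{d, d+2, \dots\}$
   and renormalized by direct series summation (truncated at $10^{-12}$
   tail mass);
2. event times as ordered uniforms;
3. for each interval, a behavior increment from a bridge normal pinned to
   the endpoint: mean $\frac{dt_u}{T - t_{u-1}} (z^T - z^{u-1})$, covariance
   $\frac{(T-t_u)\,dt_u}{T-t_{u-1}} \sigma^2 \left[(I-\alpha W^{u-1})
   (I-\alpha W^{u-1})^\top\right]^{-1}$, which treats all future influence
   matrices as frozen at the current one (the accept/reject step corrects
   for the approximation); the covariate trend is likewise left to the
   correction step;
4. for each of the first $k-1$ events, an edge with the exponential
   change-statistic weights -- over all $n(n-1)$ ordered dyads while
   surplus pairs remain ($a > 0$, with the important-list bookkeeping:
   resolving a listed dyad decrements $d$, toggling an unlisted one adds it
   and decrements $a$), and restricted to the list once $a = 0$. The final
   toggle closes the last listed dyad and the final increment is forced to
   land exactly on $z^T$, so every proposal hits both endpoints exactly.

A Metropolis-Hastings step then accepts the proposal with probability
$\min\{1, [L' g]/[L g']\}$ where $L$ is the complete-data likelihood and
$g$ the full proposal density. One bookkeeping subtlety matters here: the
proposal's event-count pmf times its times density equals
$e^{-\lambda T} \lambda^k / C$ (with $C$ the parity normalizer), so its
$k$-dependent part, $k \log \lambda$, must appear in the ratio -- it
exactly cancels the $\lambda$ factor of the likelihood. Dropping it (i.e.
using only the bridge and edge proposal densities in the ratio) inflates
the sampled event count by a factor $\lambda^2$ per surplus event pair; we
verified this against an exact enumeration oracle on a 3-actor instance,
where the corrected sampler reproduces the enumerated conditional
distribution of $k$ to Monte Carlo error while the uncorrected one is off
by precisely that factor.

The sampler is a whole-path independence sampler: acceptance rates around
10-60% are typical at the scales below, and every retained path satisfies
the parity constraint and hits both endpoints exactly (asserted for every
draw in the tests).

## MCEM estimation

`coevol_fit()` alternates:

* **E-step:** `run_imputation()` at the current parameters ($R$ retained
  paths after burn-in). By default every E-step reuses one fixed seed
  (common random numbers), which removes Monte Carlo jitter from the EM
  trajectory; it can be disabled.
* **M-step:** $\hat\lambda$ = mean imputed $k$ divided by $T$; closed-form
  generalized-least-squares $\hat\gamma$ and residual $\hat\sigma^2$ at
  fixed $\alpha$ (their exactness as block argmaxes is unit-tested by
  numeric perturbation); and a box-constrained L-BFGS-B maximization of
  the profiled objective over $(\theta, \alpha)$, with the $\alpha$-only
  block cached so finite-difference moves in $\theta$ are cheap.

Iteration stops when the largest relative parameter change drops below
`tol` (default $10^{-3}$) or after `max_iter` iterations, in which case a
warning is issued and the convergence flag set to `FALSE` -- never an
error. Defaults ($R = 50$, burn-in 100, `max_iter = 50`) are sized for
30-actor problems on a desk machine.

Standard errors are parametric bootstrap: simulate two-wave datasets
forward at the fitted parameters, refit each with reduced settings, and
report coordinate-wise standard deviations. The method name is recorded in
the fit's diagnostics.

### What to expect from two waves

A caution worth stating plainly: a single two-wave panel of $n \approx 30$
actors identifies $\lambda$, $\theta_1$ (outdegree) and $\sigma$ well, but
carries little information about the influence strength $\alpha$ -- the
peer-influence signal in the *total* behavior change is small relative to
the accumulated noise at the bundled study's parameter values
($\alpha = 0.1$, $\sigma = 0.1$, $T = 60$). Pooling many independent
increment observations recovers $\alpha$ accurately (we verify this at
desk scale), but single-dataset estimates of $\alpha$ wander within
roughly $\pm 0.3$ and their bootstrap standard errors are correspondingly
large. Estimates of $\gamma$ and the non-outdegree network effects are
similarly noisy at this scale, mirroring the reference study's own
non-significant entries.

## The synthetic-data generator

`make_fixture()` produces the study's starting conditions: a directed
Bernoulli (Erdos-Renyi) graph with tie density 0.3, BMI-like behavior from
a normal with mean 22.9 truncated to [14, 46] (kg/m$^2$; the truncated
normal mimics plausible BMI support -- the sd default 4.4 matches the
reference population), and a single constant covariate column, since the
bundled design models only a common behavior trend ($\gamma$ scalar).
`bmi_study_spec()` / `bmi_study_params()` bundle the study's effect list
and generating values: $\lambda = 1$/day, $\theta = (-3.42, 2.33, 0.50,
0.39)$ for (outdegree, reciprocity, transitive triplets, similarity with
range 32 and centering 0.8619), $\gamma = 0.001$/day, $\alpha = 0.1$,
$\sigma = 0.1$, $T = 60$ days.

What the generator deliberately does *not* emulate: covariate structure
beyond a constant, actor-specific event rates, degree heterogeneity beyond
what a Bernoulli graph produces, and measurement error in either panel.
Passing tests therefore demonstrate correctness of the algorithms under
the model's own assumptions, not robustness to their violation in real
data.

## Numerical choices

* Edge-choice log-weights are max-shifted before exponentiation; the
  profiled objective floors $\hat\sigma^2$ at $10^{-12}$ and the event
  rate at $10^{-8}$ to keep degenerate no-signal inputs from erroring.
* $|\alpha| < 1$ is enforced at construction; near-singular
  $I - \alpha W$ (determinant below $10^{-12}$) raises a model-validity
  error naming $\alpha$.
* The parity-restricted Poisson series is truncated when the remaining
  tail mass falls below $10^{-12}$.
* Path JSON is written with 17 significant digits so write/read
  round-trips are bit-exact.
* Test and example problem sizes are the package's own desk-scale choices:
  the enumeration-exactness check uses 3 actors with 30,000 retained
  draws per case, and the study-scale EM check uses $R = 25$, burn-in 50,
  8 iterations with a 4-replicate bootstrap.

## Known limitations

* Dense matrices throughout: intended for a few hundred actors at most.
* Only two-wave panels; no continuous observation schemes or more than
  two waves.
* No valued or weighted ties; the row-normalized adjacency is the single
  built-in influence matrix (swap in another via `influence_matrix()`'s
  seam if needed).
* The SAOM reference module computes forward probabilities only; it does
  not estimate SAOM parameters.

## Reproducibility

All randomness flows through R's global random number stream: call
`set.seed()` before any simulating, imputing or fitting call to make runs
exactly reproducible. `scripts/acceptance.R` regenerates the package's
headline reference numbers from scratch for a given `--seed`.
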