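---
title: "Variance estimation under fine stratification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance estimation under fine stratification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finestrat)
library(dplyr)
```

## The problem

Fine stratification splits a finite population into many small strata —
establishment, health and expenditure surveys routinely run hundreds of
strata with one or two primary sampling units (PSUs) selected per stratum by
simple random sampling without replacement (SRSWOR). The Horvitz–Thompson
(HT) estimator of the population total,

$$\hat t = \sum_{i=1}^{H}\hat t_i,\qquad
  \hat t_i = \sum_{k \in s_i} y_k/\pi_k,$$

is design-unbiased with design variance $\mathrm{var}(\hat t)=\sum_i V_i$,
the strata being sampled independently. With a single PSU per stratum,
however, $V_i$ has **no** unbiased estimator: there is no within-stratum
spread to observe. Every practical estimator therefore borrows information
across strata, and pays for it with design bias. This package implements
three such estimators, an exact-enumeration oracle that verifies their
design moments on small populations, and a simulation framework that
compares them on synthetic populations.

## The three estimators

**Collapsed stratum.** Strata are paired by adjacency in a stratum-level
auxiliary score $x_i$ (pairing must use population structure, never sample
values, or the estimator loses its interpretation), and

$$\hat V_{\mathrm{col}}
  = \tfrac12 \sum_{i=1}^H \Bigl(\hat t_i - \sum_j c_j(i)\,\hat t_j\Bigr)^2,$$

with $c_j(i)=1$ when $i\neq j$ share a pair. For pure pairs this is the sum
of squared within-pair differences, and its exact design bias is the same
quadratic form evaluated at the *true* stratum totals — always nonnegative,
small only when paired totals match. `collapsed_bias_exact()` evaluates it;
`fs_selftest()` and the test suite confirm the identity
$E[\hat V_{\mathrm{col}}] - \mathrm{var}(\hat t) = \text{closed form}$ by
brute-force enumeration. The identity is exact for pairs only: a group of
three (unavoidable when $H$ is odd) contributes an extra variance term, so
the oracle checks use even $H$.

**Kernel-weighted.** The binary pair indicator is replaced by smooth local
weights over the stratum scores,
$d_j(i) = K\!\bigl((x_j-x_i)/h\bigr) / \sum_m K\!\bigl((x_m-x_i)/h\bigr)$
with the Epanechnikov kernel $K(s)=\tfrac34(1-s^2)$ on $|s|\le 1$, and

$$\hat V_{\mathrm{ker}} = \frac{1}{c_d}\sum_i
  \Bigl(\hat t_i - \sum_j d_j(i)\hat t_j\Bigr)^2,\qquad
  c_d = \frac1H\sum_i\Bigl(1 - 2d_i(i) + \sum_j d_j^2(i)\Bigr).$$

The weight formula is not uniquely pinned down by the published expectation
functional; we adopt row-normalised weights *including self* and no boundary
correction, the convention consistent with a functional that contains
$d_i(i)$ and with the known boundary bias/variance trade-off of kernel
smoothers on a finite range. With binary pair weights ($d_j(i)=c_j(i)$,
giving $c_d=2$) the estimator reduces to $\hat V_{\mathrm{col}}$ exactly — a
degenerate-equivalence identity the tests assert to $10^{-12}$ relative.
The published expectation functional multiplies $V_i$ by
$\bigl(1-2d_i(i)+\sum_j d_j^2(i)\bigr)$, which is exact only when the $V_i$
are constant across strata (the case the normalising constant is designed
for); `kernel_expectation_general()` carries the heteroscedastic-exact form
($\sum_j d_j^2(i)V_j$ in place of $V_i\sum_j d_j^2(i)$), and the enumeration
oracle confirms each on its own ground.

**Bootstrap.** Single-unit strata are first merged into pseudo-strata
(each singleton joins the not-yet-merged stratum with the smallest sample
size; ties resolved by nearest score, then smallest label). Within each
pseudo-stratum $j$ holding $m_j$ HT contributions $z_k=y_k/\pi_k$, $B$
resamples of $n^*$ draws with replacement give replicate totals
$t^*_{bj} = (m_j/n^*)\sum z$, exactly unbiased for $t_{bj}=\sum_k z_k$. The
bootstrap bias corrector is $\hat a_{bj} = 2t_{bj} - \bar t^*_{\cdot j}$,
which is $t_{bj}$ plus pure Monte-Carlo noise of order $B^{-1/2}$ (zero
exactly under the enumerated resampling law).

### Which bootstrap variance estimator? (an open design point)

The published corrector-weight form

$$\hat V_{\mathrm{boot}} = \frac{1}{c_b}\sum_i
  \Bigl(t_{bi} - \sum_j w_j\, t_{bj}\Bigr)^2$$

leaves two things unresolved: its normalising constant is never stated (we
reconstruct $c_b = \frac1J\sum_i(1-2w_i+\sum_j w_j^2)$ by strict analogy
with $c_d$), and the correctors $\hat a_{bj}$ occupy a slot that the kernel
form reserves for weights summing to one, while themselves having the units
of totals. `v_bootstrap()` implements this form with both conventions
(`sum_to_one` normalised weights, and `raw`). But the form has a structural
property worth stating plainly: its centring term $\sum_j w_j t_{bj}$ is the
*same* for every stratum, so its expectation is dominated by
$\sum_i (t_i - \mathrm{const})^2/c_b$ — the spread of the stratum totals
around one number. Whenever the mean function makes totals vary across
strata (every benchmark shape here), that term is orders of magnitude larger
than $\mathrm{var}(\hat t)$, and no choice of $w$ or $c_b$ repairs it.

The default pipeline (`estimate_bootstrap(mode = "resample")`) therefore
estimates the variance from the *variability of the replicate totals*,
which is also how the method is described in words in the survey-bootstrap
tradition: per pseudo-stratum,

$$\hat V_{\mathrm{boot}} = \sum_j \frac{n^*(1-f_j)}{m_j-1}\cdot
  \frac1B\sum_b \bigl(t^*_{bj}-t_{bj}\bigr)^2,$$

with $f_j = m_j/N_j$ the pseudo-stratum sampling fraction. The rescale makes
each term exactly design-unbiased for $V_j$ when pseudo-strata are intact
strata sampled at $m_j\ge 2$ (it is the classical rescaling-bootstrap
correction), and the centring at the exact resampling expectation $t_{bj}$
removes the corrector's Monte-Carlo noise from the location. At $n_i=2$ the
pipeline is: no merging, $J=H$, and the estimator is a Monte-Carlo version
of the textbook unbiased stratified variance estimator — which is what gives
it the near-zero bias and the smallest RMSE in the benchmark comparison
below. Both corrector modes remain available and tested; the `mode` argument
and the diagnostics record which convention produced a number.

## The synthetic populations

`make_population()` builds the study conditions: $N = 3000$ units in $H$
evenly sized strata ($H \in \{50, 100, 200\}$ in the study), stratum scores
on the grid $x_i = i/H$, and unit values
$y_k = \mu^*(x_i) + \sigma e_k$ with $e_k$ iid standard normal and
$\sigma \in \{0, 0.25, 0.5\}$. The seven benchmark shapes (`linear`,
`quadratic`, `bump`, `jump`, `exponential`, `cycle1`, `cycle4`) are each
rescaled to $[0, 2]$ so that $\sigma$ means the same thing across shapes;
extrema are located on a $10^5$-point grid with spacing $10^{-5}$, chosen so
that the jump shape's breakpoint $x = 0.65$ lies on the grid. The noise is
drawn once and the population held fixed across the $R$ replicated samples,
so all randomness in the comparison is design randomness (plus bootstrap
Monte-Carlo noise).

Two statements about the auxiliary variable coexist in the study design: a
deterministic stratum grid $x_i = i/H$ (which drives the mean function and
the kernel windows) and unit-level uniform scores. With only the grid,
every stratified sample of fixed $n_i$ has the *same* sample mean
$\bar x$, and conditioning on $\bar x$ is vacuous. We reconcile the two by
giving each unit a score drawn uniformly on its stratum's interval
$((i-1)/H,\, i/H]$ (option `unit_x = "stratified_uniform"`, the default;
`"grid"` pins unit scores to the stratum score). Stratum-level quantities
are unchanged; only the conditional analysis sees the unit scores.

Bandwidths: on the grid, $h \in (1/H, 2/H)$ is the smallest window that
brings in the immediate neighbours and nothing else; the default $1.5/H$
sits mid-window. Outside that range the package warns but proceeds (wider
windows are legitimate, just more biased under curvature); a bandwidth so
small that every window holds only its own stratum makes $c_d = 0$ and is
an error, not a silent fix-up.

One further published setting — "$H = 30$ to be collapsed" — does not
uniquely determine a procedure (30 strata? 30 pseudo-strata? which 30?).
It is exposed as the `n_pseudo` option (group the strata in score order
into a fixed number of pseudo-strata before resampling) and left off by
default.

## Simulation studies

`run_unconditional()` draws $R$ samples (default 1000; the acceptance
script and the seed-fixed benchmark test use $R = 200$, $B = 200$ to keep a
single-CPU run in seconds-to-minutes) and reports, per estimator, empirical
bias and RMSE against the true $\mathrm{var}(\hat t)$ computed from the
population, and the CV across replicates. At $\sigma = 0$ and $n_i = 2$
every unit in a stratum is identical, the totals are recovered exactly, and
the empirical bias of the collapsed (resp. kernel) estimator equals its
closed-form bias *exactly* — a sharp end-to-end test the suite asserts at
$10^{-10}$.

`run_conditional()` sorts the $R$ replicates by the sample mean of the unit
scores, forms consecutive groups of 20 (50 groups at $R = 1000$), and
reports per group the conditional bias and conditional RMSE (CRMSE).
Because groups are equally sized, the equally weighted average of the
conditional biases reproduces the unconditional bias to floating-point
accuracy — asserted as an algebraic-decomposition check.

Reproducibility: every run takes one root seed; the population, each
replicate's sample, and each replicate's bootstrap get substream seeds
derived deterministically from (root, replicate index, purpose), so
extending $R$ leaves earlier replicates unchanged and any replicate can be
re-run in isolation.

## What the oracle does and does not show

`enumerate_design()` visits every SRSWOR sample of a small population
(hard cap $10^6$ outcomes, loud error beyond — never silent subsampling)
and returns the exact design distribution of any statistic;
`exact_bootstrap_law()` does the same for the $m^{n^*}$ ordered resampling
draws. Probabilities are doubles ($1/\prod_i\binom{N_i}{n_i}$ and
$1/m^{n^*}$, exactly representable at these sizes) and identity checks use
a $10^{-12}$ tolerance. The oracle certifies the *estimators' design
moments* — HT unbiasedness, the collapsed bias identity, the kernel
expectation functional, resampling unbiasedness — on populations small
enough to enumerate. It does not certify finite-sample behaviour on
realistic sizes; that is what the simulation study samples, with
Monte-Carlo error, and why the benchmark assertions are directional
(ordering of biases and RMSEs under a fixed seed) rather than numeric
table reproduction.

What passing tests on synthetic populations do **not** show about real
surveys: the generator has equal stratum sizes, a stratum-constant mean, iid
Gaussian noise, and exact SRSWOR — no unequal selection probabilities,
clustering, nonresponse or measurement error. The worked application path
(`smho_prepare()` + `smho_study()`) exercises the estimators on a real
frame's shape — unequal strata, log-scale expenditure-type variables,
strata ordered by log total beds, small-cell merges — but with user-supplied
data; the packaged tests use a synthetic fixture of that shape. The
coefficient of variation it reports is sd/mean across repeated subsamples,
stated here because the application literature leaves the definition
implicit.

## A worked benchmark

The package's headline comparison (also what `scripts/acceptance.R`
recomputes from scratch):

```{r benchmark, eval = FALSE}
cfg <- sim_config(N = 3000, H = 100, sigma = 0.25, mean_fn = "linear",
                  n_per_stratum = 2, R = 200, B = 200, seed = 1)
sim <- run_unconditional(cfg)
sim$true_var
sim$summary
autoplot(run_conditional(sim))
```

Under seed 1 this prints a true design variance of about 2553 and the
summary ordering the estimators: bootstrap bias $\approx 44$ and RMSE
$\approx 377$, against collapsed bias $\approx 249$ / RMSE $\approx 613$
and kernel in between — the qualitative pattern the estimator was designed
for. (Run the chunk to regenerate; the numbers are deterministic given the
seed.)

## Known limitations

* Only SRSWOR within stratum is generated and enumerated; samples carrying
  other fixed-probability designs pass through the HT layer, but the
  true-variance and enumeration oracles assume SRSWOR.
* The corrector-weight bootstrap form is kept faithful to its published
  shape, including its structural bias; it is not the default for exactly
  that reason.
* Pair collapsing assumes the score order is meaningful; with an
  uninformative score the collapsed estimator's bias is simply the spread
  of arbitrary total pairs.
* The kernel estimator has no boundary correction; its edge rows lean
  inward, which is visible in the conditional plots at the extremes of
  $\bar x$.
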