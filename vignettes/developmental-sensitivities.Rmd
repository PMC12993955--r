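---
title: "Developmental sensitivities and quantitative genetics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developmental sensitivities and quantitative genetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devqg)
```

## The model

`devqg` treats development as a dynamical system: a state vector
$x(t) \in \mathbb{R}^n$ of phenotypic variables (here, gene expression
levels) evolves according to

$$\dot x = f(t, x, \lambda), \qquad x(t_0) = x_0,$$

where $\lambda \in \mathbb{R}^p$ collects *developmental parameters* of
genetic or environmental origin (regulatory strengths, decay rates, and so
on). For a reference parameter vector $\lambda^*$ the *sensitivity vector*
of parameter $k$,

$$s_k(t) = \left.\frac{\partial x(t,\lambda)}{\partial \lambda_k}
\right|_{\lambda = \lambda^*},$$

describes how every trait responds, at every developmental time, to an
infinitesimal change in that parameter. It solves the variational
(forward-sensitivity) equation $\dot s_k = A(t)\,s_k + b_k(t)$ with
$s_k(t_0) = 0$, where $A$ is the Jacobian of $f$ with respect to the state
and $b_k$ its direct derivative with respect to $\lambda_k$, both evaluated
along the reference trajectory.

The bridge to quantitative genetics comes from viewing an allelic
substitution as a small perturbation of $\lambda$. With an additive
genotype-to-parameter map (a locus with per-allele effect $\gamma$ shifts
its target parameter by $-\gamma$, $0$, $+\gamma$ for genotypes bb, Bb,
BB), a Taylor expansion of the trajectory around the heterozygote gives
time-resolved versions of the classical quantities:

* additive value $a(t) = (x_{BB} - x_{bb})/2 = s(t)\gamma + O(\gamma^3)$
  (odd orders only),
* dominance value $d(t) = x_{Bb} - (x_{BB}+x_{bb})/2
  = -s^{(1)}(t)\gamma^2/2 - \dots$ (even orders only), with $s^{(1)}$ the
  second derivative of the trajectory with respect to the parameter,
* average effect $\alpha(t) = a(t) + d(t)(p - q) \approx s(t)\gamma$ for
  small $\gamma$.

On the sign convention: we code genotypes as the B-allele count minus one
(+1 = BB), so the per-time regression slope of phenotype on genotype code
*is* $\alpha(t)$ and the small-effect proportionality carries a plus sign,
$\alpha \approx +s\gamma$. Under this coding, direct algebra on a
population at exact Hardy–Weinberg proportions gives the dominance
correction as $d(t)(p-q)$ with $q$ the B-allele frequency (Falconer's
average effect of substituting *toward* the allele of frequency $q$).
Conventions that instead count the b allele flip both signs; the package
uses the one convention consistently.

From sensitivities, time-indexed covariance matrices follow directly.
Under Hardy–Weinberg equilibrium and small effects, locus $i$ (targeting
parameter $w(i)$, frequencies $p_i, q_i$) contributes the rank-1 matrix

$$G_i(t) = 2 p_i q_i \gamma_i^2 \; s_{w(i)}(t)\, s_{w(i)}(t)^{\mathsf T},$$

and $G(t) = \sum_i G_i(t)$. An environmental factor perturbing parameter
$v(j)$ with variance $\sigma_j^2$ contributes
$E_j(t) = \sigma_j^2\, s_{v(j)} s_{v(j)}^{\mathsf T}$, and to first order
$P(t) = G(t) + E(t)$. Proportionality between G and P therefore requires
two things at once: sensitivity vectors of the contributing factors that
point in similar directions (a property of development), and enough
variance in the aligned factors to dominate the sums (a property of the
population). The package quantifies proportionality for two-trait systems
by the axial angle between the leading eigenvectors Gmax and Pmax.

Finally, the multivariate breeder's equation
$\Delta\bar z = G\beta$, $\beta = P^{-1}S$, predicts the one-generation
response to a selection differential $S$; substituting P for G collapses
the prediction to $S$ itself, which is exactly what makes the quality of
the P-as-proxy shortcut depend on G–P proportionality.

## The built-in developmental system

The bundled model is a two-gene toggle switch, a minimal model of cell-fate
determination:

$$\dot x_1 = \frac{2+\lambda_1}{(1+x_2^2)^2} - 0.4\,x_1, \qquad
  \dot x_2 = \frac{2+\lambda_2}{(1+x_1^3+\lambda_3)^2} - 0.4\,x_2.$$

$\lambda_1, \lambda_2$ modulate the regulatory input of each gene and are
genetically determined in the population scenarios; $\lambda_3$ shifts the
repression of gene 2 and is environmentally determined (the two-parameter
variant fixes it at 0). The algebraic form of the Hill terms is confined to
the `toggle_switch()` factory so it can be revised in one place.

At the reference $\lambda^* = (0,0,0)$ the circuit is bistable. From the
default initial state $x_0 = (0,0)$ (not dictated by the science; chosen as
a deterministic point whose basin is resolved identically by all
integrators, with the headline properties robust to the choice) the
trajectory settles in the gene-2-high state $\approx (0.0074, 5.0)$ by
$t \approx 25$. Consequently at $t = 50$:

* $s_2(50) \approx (-0.014, 2.50)$ and $s_3(50) \approx (0.057, -10.0)$ are
  near-perfectly aligned (axial angle $< 10^{-6}$ degrees) because both
  parameters force only the gene-2 equation — the "developmental condition"
  holds between $\lambda_2$ and $\lambda_3$ by construction;
* $s_1(50) \approx (0.0037, -6\times10^{-6})$ is nearly orthogonal to them
  ($\approx 89.6^\circ$).

## Estimation

At each unit time step the observed trait is regressed on all genotype
codes with an intercept ($y(t) = \mu(t)\mathbf 1 + Z\alpha(t) +
\epsilon(t)$); the slopes are the *static* estimates
$\hat\alpha^s_i(t)$, with observation variances taken from the OLS
standard errors. Because average effects inherit the dynamics of the
sensitivities, the *dynamic* estimator models each $\alpha_i(t)$ as a
random walk, $\alpha_i(t) = \alpha_i(t-1) + \eta(t)$,
$\eta \sim N(0, Q)$, and runs an independent scalar Kalman filter per
locus with the static estimates as observations.

Filter choices that matter:

* **Initialisation.** $\alpha(t_0) = 0$ with variance $10^{-12}$: the
  sensitivity vectors vanish at $t_0$, so the initial average effect is
  known to be zero.
* **Observation variance** $R_t$: the squared OLS standard error at time
  $t$ (per locus), i.e. no free parameter.
* **Process variance** $Q$: per locus, by method of moments. Under the
  model $E[(\Delta\hat\alpha^s)^2] = Q + R_t + R_{t-1}$, so the default is
  $\hat Q = \max\{\overline{(\Delta\hat\alpha^s)^2} -
  \overline{R_t + R_{t-1}},\; 10^{-3}\,\overline{(\Delta\hat\alpha^s)^2}\}$.
  The subtraction removes the observation-noise contribution that would
  otherwise inflate $Q$ and make the filter track noise; the floor keeps
  $Q$ positive so the filter never freezes entirely. A naive plug-in
  without the correction loses to the static estimator precisely in the
  easy regimes (many individuals, little noise), where most of the
  increment variance is observation noise.
* **No smoothing by default.** The filtered value at $t$ uses observations
  up to $t$ only; a backward (RTS) pass is available behind
  `smooth = TRUE`.

Estimator quality is scored by the relative error
$|\hat\alpha_i(t) - s(t)\gamma_i| / |s(t)\gamma_i|$, averaged over loci
and all time points after $t_0$ (where the truth is zero and the ratio is
undefined). Note the truth here is the small-effect linear prediction, so
even a perfect estimator retains an $O(\gamma)$ floor; and because the
per-replicate allelic effects are drawn from a zero-mean Gaussian, loci
with near-zero $\gamma_i$ make the mean relative error large in absolute
terms — the informative quantity is the static/dynamic comparison, not the
absolute level.

## What the synthetic populations emulate — and what they do not

`simulate_population()` maps genotypes (plus an optional per-individual
Gaussian environmental draw) to parameters, integrates development
deterministically within unit steps, and adds two kinds of noise:

* **developmental noise**: independent Gaussian perturbations applied to
  each state at each unit-step boundary, with SD proportional to the
  current absolute state value (1–20% in the study scenarios). The
  proportional-to-current-state reading is a modelling choice (exposed via
  the noise configuration); the alternative — relative to a fixed
  reference value — changes the noise profile in the low-expression gene.
  Perturbed states may go negative; the model's dynamics remain defined
  there and no clipping is applied.
* **measurement noise**: Gaussian, SD proportional to the state value
  (1–8%), added once to the recorded values.

This is a deliberately simple error model: real developmental noise is
intrinsic to the dynamics and temporally correlated, whereas unit-step
Gaussian kicks are serially independent by construction (their *effects*
still propagate through the dynamics). Tests passing under this generator
therefore demonstrate the estimator machinery and the covariance algebra,
not robustness to realistic noise spectra, linkage, dominance at the
parameter map, or population structure (all out of scope; individuals are
unrelated and loci unlinked).

Scenario defaults follow the study conditions: the single-locus
demonstration uses 20 individuals at $p = q = 0.5$ (with genotype counts
fixed at exact Hardy–Weinberg proportions 5/10/5, so the regression slope
equals the additive value without genotype-sampling error); the estimator
grid uses 10 loci per parameter with $\gamma_i \sim N(0, 0.01^2)$, 100
replicates per cell, and population sizes 64 and 512 (scaled down from the
largest published settings to keep a full grid affordable on one CPU; the
static–dynamic ordering is insensitive to this); the alignment and
selection scenarios use 10 loci per genetic parameter with
$\gamma_i \sim N(0, (10^{-4})^2)$, $\lambda_3 \sim N(0, (1.5\times
10^{-3})^2)$, development to $t = 50$, truncation selection of the closest
50% to the optimum $(4,4)$, monogamous random pairing and 4 offspring per
pair (population size preserved). The selection scenario runs at 2,000
individuals over 20 seeds in the acceptance checks (down from 5,000; the
angle comparisons stabilise well before that).

## Numerical choices

* Reference trajectories and variational systems: `deSolve::lsoda` with
  `rtol = 1e-8`, `atol = 1e-10` (sensitivity work amplifies solver error;
  the finite-difference routes tighten this further to `1e-10`/`1e-12`
  because they difference nearly equal trajectories).
* Populations: a vectorised classical RK4 with fixed step `h_int = 0.02`
  (0.05 in the large selection scenarios), stepping all individuals
  simultaneously between unit-step boundaries. A single individual
  integrated this way is bit-identical to `integrate_system(method =
  "rk4")`, which is what makes the noise-free population invariant exact.
  Step-halving changes the endpoint by $< 10^{-6}$ relative.
* Finite-difference default $\Delta\lambda = 10^{-4}$ for first-order
  sensitivities (validated by step-halving), $10^{-3}$–$10^{-2}$ for
  second-order differences, which divide by $\Delta\lambda^2$ and so trade
  truncation against solver-noise amplification.
* Angle conventions: directed $[0^\circ, 180^\circ]$ for sensitivity
  vectors; axial $[0^\circ, 90^\circ]$ (absolute cosine) wherever a sign
  is arbitrary — eigenvectors and response-prediction comparisons.
* Leading eigenvectors come from the symmetric eigendecomposition with the
  sign fixed so the largest-magnitude component is positive; a tie between
  the two leading eigenvalues (relative gap below $10^{-10}$) is an error,
  not a silent choice.
* Equilibria: damped Newton iterations on $f = 0$ using the model
  Jacobian, deduplicated at $10^{-6}$; non-convergence returns an empty
  set rather than an error.
* Relative comparisons exclude $t_0$ throughout, because $s(t_0) = 0$.

## Design decisions on genuinely open points

* **Reference parameters for population work** are the expected parameter
  vector of the population; with the additive map this is the
  all-heterozygote individual, so the reference trajectory is the
  heterozygote trajectory.
* **Per-locus average effects in multi-locus settings** are defined
  against the all-heterozygote background, consistent with the additive
  map and the small-effect regime.
* **The P used in the selection gradient** $\beta = P^{-1}S$ is the
  empirical phenotypic covariance of the full parental generation at the
  final time; the "true G" prediction uses the architecture-based
  $G(t)$ from sensitivities. The "parental mean" in both $S$ and the
  realized response is the pre-selection mean.
* **The P-proxy prediction** follows the Lande convention
  $P P^{-1} S = S$.
* **Genotypes store explicit haplotypes**, so Mendelian segregation from
  heterozygotes is exact rather than approximated through code-level
  resampling.

## Known limitations

* The G-matrix is additive-only (consistent with the small-effect
  expansion); dominance variance exists in the model output but is not
  decomposed into a D-matrix.
* Proportionality diagnostics report a single leading-axis angle, which is
  adequate for the two-trait switch; for $n > 2$ a fuller subspace
  comparison (variance profiles across orthogonal axes) would be needed
  and is not implemented.
* Under the alignment-scenario parameter scales (allelic effects
  $\sim 10^{-4}$, environmental SD $1.5\times10^{-3}$), the realized
  one-generation response is dominated by the resampling of the
  environmental parameter between generations: its sample-mean
  fluctuation ($\sim 3\times10^{-4}$ in trait units along the dominant
  sensitivity direction) exceeds the expected genetic response
  ($\sim 10^{-6}$). In that regime the realized change aligns with the
  environmental axis rather than with $G\beta$, so the G-based prediction
  does *not* outperform the P-proxy in our simulations; the acceptance
  suite reports this configuration honestly rather than rescaling the
  generator to force the opposite ordering. Larger allelic effects and/or
  smaller environmental variance restore the expected advantage of G.
* Sensitivities are defined on the deterministic reference system; there
  are no adjoint methods and no sensitivities of stochastic trajectories.
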