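---
title: "Bayesian and maximum-likelihood estimation of pairwise dN/dS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian and maximum-likelihood estimation of pairwise dN/dS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairomega)
```

## The problem

The nonsynonymous/synonymous rate ratio $\omega = d_N/d_S$ summarises the
mode and strength of selection on a protein-coding gene: $\omega < 1$
indicates purifying selection, $\omega \approx 1$ neutral evolution and
$\omega > 1$ positive selection averaged over sites and time.  The
simplest estimate compares two aligned coding sequences.  Maximum
likelihood under a codon substitution model works well for most pairs,
but genome-scale screens routinely contain pairs for which the MLEs of
$\omega$ and of the evolutionary distance $t$ are degenerate:

* identical sequences — $\hat t = 0$ and $\hat\omega$ is not unique;
* only synonymous differences — $\hat\omega = 0$;
* only nonsynonymous differences — $\hat\omega = \infty$;
* near-random (saturated) pairs — $\hat t$, and often $\hat\omega$,
  $\to \infty$.

Because such estimates occur with positive probability, the MLEs have no
finite mean or variance across genes, and genome-wide summary statistics
are ill-defined.  `pairomega` implements a Bayesian treatment: with
diffuse gamma priors on $t$ and $\omega$, the posterior means are finite
for every possible alignment, and the posterior probability
$P(\omega > 1 \mid x)$ replaces the likelihood ratio test as the measure
of evidence for positive selection.

## Model

The codon substitution process is the simplified Goldman–Yang Markov
model on the 61 sense codons of the standard genetic code (stop codons
are assumed not to occur).  The instantaneous rate from codon $i$ to
codon $j \ne i$ is

$$q_{ij} = \begin{cases}
0 & \text{more than one position differs} \\
\pi_j & \text{synonymous transversion} \\
\kappa\,\pi_j & \text{synonymous transition} \\
\omega\,\pi_j & \text{nonsynonymous transversion} \\
\omega\kappa\,\pi_j & \text{nonsynonymous transition,}
\end{cases}$$

where $\pi_j$ is the equilibrium frequency of codon $j$ (all $1/61$
under `Fequal`; the observed frequencies under `F61`) and $\kappa$ is
the transition/transversion rate ratio.  $Q$ is scaled so that
$-\sum_i \pi_i q_{ii} = 1$: time $t$ counts expected nucleotide
substitutions *per codon*.  This calibration is confirmed internally by
the identical-sequence posterior (below), whose mean
$\bar t \approx \alpha_t/(\beta_t + L_c)$ only holds on the per-codon
scale.  Sites are independent, so the likelihood for an alignment $x$
of $L_c$ cleaned codon sites is

$$f(x \mid t, \omega) = \prod_{h=1}^{L_c} \pi_{i_h}\,
P_{i_h j_h}(t), \qquad P(t) = e^{Qt},$$

which depends on the data only through the counts of ordered codon
pairs; the package stores alignments as compressed site patterns.
$P(t)$ is evaluated through the spectral decomposition of the
reversible generator (similarity to a symmetric matrix via
$\mathrm{diag}(\sqrt{\pi})$), computed in compiled code because the
likelihood optimisation and the quadrature below require one
decomposition per $(\kappa, \omega)$ value.

## Priors

The joint prior is the product of independent gammas,

$$t \sim G(\alpha_t, \beta_t), \qquad \omega \sim G(\alpha_\omega, \beta_\omega),$$

with defaults $G(1.1, 1.1)$ and $G(1.1, 2.2)$: prior means 1 and 0.5,
shapes barely above 1 so the density is diffuse yet vanishes at 0 and
decays at $\infty$, penalising the degenerate corners of the parameter
space.  All four numbers are user-configurable (`gamma_prior()`); the
more informative alternatives $G(2,2) \times G(2,4)$ (same means,
shape 2) behave as expected — posterior means of $\omega$ are pulled
towards the prior mean for uninformative genes, which the test suite
checks directionally.

$\kappa$ is not integrated over: it is plugged in at its MLE from the
joint likelihood fit, and fixed at 2 when the sequences are identical
(the MLE is then undefined).

## Posterior summaries by transformed quadrature

Six double integrals over $(0,\infty)^2$ are needed: the normalising
constant $C$ and the posterior expectations of $t$, $\omega$, $t^2$,
$\omega^2$ and $t\omega$ (means, variances, covariance).  The integrand
$g(t,\omega) = f(x \mid t,\omega) f(t) f(\omega)$ can be extremely
spiky — for a long informative gene the posterior occupies a tiny
region — so a fixed quadrature rule in $(t, \omega)$ would be hopeless.
The package:

1. works on $(y_1, y_2) = (\log t, \log\omega)$, with log-scale
   overflow protection $h = \exp\{\log g - \ell_{\max}\}$, where
   $\ell_{\max}$ is the maximum of $\log g$ over the evaluated grid and
   the located mode (the factor $e^{\ell_{\max}}$ cancels in every
   reported ratio);
2. maps each axis through the CDF of a logistic distribution
   $\mathrm{Logistic}(\mu_k, \sigma_k)$ chosen to resemble the
   posterior of $y_k$, taking the integral to $(-1,1)^2$; a perfectly
   matched logistic would make the transformed integrand constant;
3. applies an $n \times n$ Gauss–Legendre product rule (default
   $n = 32$, i.e. 1,024 likelihood evaluations, all six integrals
   sharing one grid).

$P(\omega > 1 \mid x)$ is computed with the same machinery: the
sub-interval of $z_2$ above the transform image of $\omega = 1$ is
remapped to $(-1,1)$ and quadratured with a fresh $n$-point rule (the
likelihood is re-evaluated on that sub-grid), so the tail integral
keeps full resolution near $\omega = 1$ instead of inheriting an
indicator-function discontinuity on the global grid.

### Centring and scaling the transform

Two branches set $(\mu_k, \sigma_k)$, mirroring how the estimates are
screened:

* **Counting branch** — when the MLEs of $t$ and $\omega$ are interior
  and the Nei–Gojobori proportions satisfy $p_S, p_N < 0.74$ (so the
  JC69 correction and its variance are trustworthy; the correction
  diverges at $p = 3/4$): $\mu_1 = \log\hat t$,
  $\mu_2 = \log\hat\omega$, and the scales come from the delta-method
  standard deviations of the log counting estimates,
  $\mathrm{SD}(\log\hat\theta) \approx \mathrm{SD}(\hat\theta)/\hat\theta$,
  with the counting proxies $\hat\omega_{NG} = d_N/d_S$ and
  $\hat t_{NG} = (S\,d_S + N\,d_N)/L_c$ (variances propagated treating
  $d_S$ and $d_N$ as independent).
* **Hessian branch** — in all other cases (boundary MLEs, saturation,
  no data) the mode of the *transformed* log density
  $\log g + y_1 + y_2$ is located numerically on the log scale (it
  always exists because of the prior), and scales come from the inverse
  finite-difference Hessian (central second differences, step
  $10^{-3}$; if the Hessian is not positive definite the step is
  doubled up to three times, then unit scales are used).  The density
  being approximated by the logistic is the Jacobian-corrected
  integrand of the change of variables, hence the $+y_1+y_2$ term; the
  located mode also feeds $\ell_{\max}$.

Two numerical choices matter for accuracy and were fixed by examining
the integrand analytically, with a dense-grid Simpson oracle verifying
the outcome:

* **Overdispersion.** Scales are set to *twice* the variance-matched
  value, $\sigma_k = 2\sqrt{3}/\pi \cdot \mathrm{SD}(\log\hat\theta_k)$.
  A logistic slightly wider than the target makes the transformed
  integrand decay smoothly to zero at both endpoints; the exactly
  matched scale leaves heavy relative tails that limit the $n = 32$
  rule to $\sim 10^{-3}$ relative error in second moments, whereas the
  overdispersed rule agrees with dense-grid integration to
  $\sim 10^{-6}$ or better on the tested fixtures.
* **Tail-slope floor.** As $y_1 \to -\infty$ the transformed posterior
  behaves as $e^{(\alpha_t + K)y_1}$, where $K$ is the total minimum
  number of substitutions implied by the site patterns (for $\omega$:
  $\alpha_\omega + M$, $M$ counting amino-acid-changing patterns).  If
  the logistic tail $e^{y/\sigma}$ is lighter than this, the
  transformed integrand diverges at $z = -1$ — an integrable endpoint
  singularity that degrades Gauss–Legendre convergence (for the
  prior-only posterior it biases the mean of $t$ by $\sim 0.7\%$ at
  $n = 32$).  Each $\sigma_k$ is therefore floored at the reciprocal
  slope, $1/(\alpha + K)$; the floor binds only for weak data, where
  the posterior is wide anyway.

If every grid value underflows to zero (a catastrophically mis-centred
transform), the grid is recentred once at the argmax of $\log g$ over
the evaluated grid and recomputed; a still-degenerate grid is an error.
Posterior variances that come out as tiny negatives from round-off
(above $-10^{-10}$) are clamped to zero.

### Worked behaviour in the degenerate cases

* *Identical sequences* (100 codons, `Fequal`, $\kappa = 2$): the
  posterior means are $\bar t \approx 0.011$ and
  $\bar\omega \approx 0.496$ — $t$ is pulled just off zero by the
  prior, and $\omega$ sits essentially at its prior mean because the
  data carry no information about it.
* *No usable sites* ($L_c = 0$): the posterior equals the prior; the
  package reproduces the prior means (1, 0.5) and the analytic gamma
  tail $P(\omega > 1) = 0.1304$ to about $10^{-4}$.
* *Saturated/random pairs*: the prior damps $t$ and $\omega$; all
  summaries remain finite.

## Maximum likelihood, boundaries, and the LRT

`mle_pairwise()` maximises the likelihood over $(t, \omega, \kappa)$ on
the log scale within $t \in [10^{-6}, 50]$, $\omega \in [10^{-6}, 99]$,
$\kappa \in [0.01, 99]$ — bounds wide enough that the degenerate cases
actually reach them.  The search profiles $t$ in an inner 1-D
optimisation (each $(\kappa, \omega)$ requires one spectral
decomposition; $t$ reuses it), with a Nei–Gojobori-based start plus two
perturbations.  An estimate within $10^{-4}$ of a lower bound is
reported as the 0 sentinel, within 2% of an upper bound as $\infty$,
with a machine-readable `boundary` flag (`t_zero`, `omega_zero`,
`omega_inf`, `t_inf`).  Standard errors come from the
finite-difference observed information at interior optima, with 95%
intervals formed on the log scale.

The test of positive selection compares the unconstrained fit with
$\omega = 1$: one-sided LRT, significant at the 5% level when
$2\Delta\ell > 2.71$ *and* $\hat\omega > 1$.  The Bayesian counterpart
flags $P(\omega > 1 \mid x) > 0.95$.

## Nei–Gojobori counting

Counting estimates parameterise the transform and are reported
alongside the model-based estimates.  Site counts give each codon
position one site, split as (synonymous single-nucleotide changes)/3 —
changes into stop codons are simply not synonymous — so
$S + N = 3L_c$ exactly and uniform codon usage gives
$S \approx 73$ per 100 codons.  Difference counts average over all
orderings of the changes between two codons, skipping pathways through
stop codons (with a fallback counting stop-involving steps as
nonsynonymous in the never-observed case that every pathway is
blocked).  Proportions are JC69-corrected,
$d = -\tfrac34\log(1 - \tfrac43 p)$, with variance
$V(d) = 9p(1-p) / ((3-4p)^2 \cdot \text{sites})$; $p \ge 3/4$ is
flagged as saturation and $p \ge 0.74$ already routes the Bayesian
transform to the Hessian branch.

## The simulator

`simulate_pair()` draws each site independently: codon $i$ from $\pi$,
codon $j$ from row $i$ of $P(t)$.  By reversibility this equals
evolving both sequences from a common ancestor with total path length
$t$.  `simulate_study()` derives a deterministic per-replicate seed
from the study seed, so any replicate is reproducible in isolation.
The generator emulates the i.i.d.-site model exactly — which is also
the inference model — so simulation tests validate estimator
calibration *under the model*; they do not probe indels, among-site
rate variation, codon usage bias beyond `F61`, or alignment error,
all of which real data contain.

The default study conditions are those of the simulation design the
package reproduces: alignments of $L_c = 500$ codons, $\kappa = 2$,
equal codon frequencies, a $4\times4$ grid of
$t \in \{0.1, 0.5, 1, 5\}$ and $\omega \in \{0.01, 0.1, 0.5, 2\}$, and
the default prior.  The bundled tests use 1,000 replicates for the
targeted recovery cell $(t, \omega) = (0.5, 0.5)$, a few hundred for
the positive-selection power cell $(1, 2)$, and smaller counts for
behavioural checks — sizes chosen so the whole suite completes in
minutes while keeping Monte-Carlo error well below the tolerances
being asserted.

## Batch screens

`run_batch()` applies the cleaning rules (codon columns containing
gaps, ambiguity characters or stop codons are dropped; genes of
$\le 50$ retained codons are excluded by default — the screen-level
filter, switchable off for single-pair use), then runs counting, ML and
Bayesian estimation per gene.  Summary tables follow the genome-screen
conventions: ML means and quartiles are computed after removing
infinite estimates while Bayesian columns use every gene, and the
counts $N_0$, $N_\infty$ (boundary MLEs), $N_L$ (significant LRTs) and
$N_B$ ($P(\omega>1|x) > 0.95$) are recomputable from the per-gene
table, where sentinels are written as literal `0`/`inf` plus the
`boundary` column.

## Known limitations

* Exactly two sequences; no phylogenetic (branch/site) tests, which
  are both more powerful and more appropriate when more genomes are
  available.
* One $\omega$ averaged over sites and time; episodic selection on a
  subset of sites will usually not push the average above 1.
* Standard nuclear genetic code only; `Fequal` and `F61` frequency
  models only (no F1x4/F3x4).
* $\kappa$ is a plug-in, not integrated over, so posterior spreads
  slightly understate uncertainty for short genes.
* Counting-method variants other than Nei–Gojobori (LWL85, YN00) are
  out of scope.
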