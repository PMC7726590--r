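---
title: "Mixture modelling of spatial working-memory errors with locmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture modelling of spatial working-memory errors with locmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The model

In a spatial continuous-report task a participant sees a set of items,
and after a delay reproduces the location of one of them (the target) on
the screen. locmix decomposes the resulting 2D errors into three latent
sources. With response $\hat\theta$, target location $\theta$, nontarget
locations $\varphi_1,\dots,\varphi_m$ and screen area $A$, the response
density of the misbinding model is

$$
P(\hat\theta) \;=\; \alpha\,\psi_\sigma(\hat\theta-\theta)
\;+\; \beta\,\frac{1}{m}\sum_{i=1}^{m}\psi_\sigma(\hat\theta-\varphi_i)
\;+\; \gamma\,\frac{1}{A},
$$

where $\psi_\sigma$ is an isotropic bivariate Gaussian with SD $\sigma$
per axis and zero covariance. $\alpha$ is the proportion of responses
centred on the target, $\beta$ the proportion of misbinding (swap)
responses centred on a nontarget, and $\gamma$ the proportion of guesses,
uniform over the screen. The weights sum to one, so $\alpha$ is derived
and the free parameters are $(\beta, \gamma, \sigma)$. The classic 1D
circular analogue — von Mises components with concentration $\kappa$ and a
$\gamma/2\pi$ guess term — is included as a reference implementation, and a
two-nontarget-class variant splits $\beta$ into $\beta_1,\beta_2$ for
designs with qualitatively different nonprobed items.

The screen is a closed rectangle $[0, W]\times[0, H]$ with the origin at
the top-left corner; its dimensions implicitly set the spatial units
(pixels in all defaults here, with 1366 × 768 as the default screen).
Helpers convert pixels to centimetres and visual degrees assuming a flat
screen at 40 cm viewed at 42 px/cm, under which 1° ≈ 29.3 px and 3° ≈ 88 px.

### Screen edges and truncation

The generative model resamples any Gaussian draw that lands off-screen,
so simulated responses never leave the screen. Strictly this implies a
truncation-renormalised fitting density. By default `locmix` evaluates
*untruncated* Gaussians, the common practice for these models, which is
accurate whenever items sit more than a few $\sigma$ from the edges; the
mass lost off-screen is exactly
$1-\Phi_x\Phi_y$ per component and the option `truncated = TRUE`
renormalises each component by its on-screen mass (analytic, because the
covariance is zero). Both modes are exposed because the choice is a
genuine modelling decision, and the difference between them quantifies
the edge approximation for a given design.

## Fitting

**Maximum likelihood.** The simplex constraint $\beta+\gamma\le 1$ is
handled by optimising an additive log-ratio transform of the weights, and
$\sigma$ (or $\kappa$) on the log scale with bounds
$\sigma \in [0.01, \max(W,H)]$, $\kappa \in [10^{-4}, 10^4]$. A coarse
3×3(×3) grid over the transformed weights and spread, plus one
method-of-moments start (a lower-quartile estimate of $\sigma$ from
squared target distances, which resists guess contamination), is
evaluated; Nelder–Mead refinement (relative tolerance $10^{-8}$, up to
500 iterations) is run from the best few starts and the best optimum is
returned. Evaluating the full start grid but refining only the top
candidates keeps a single 100-trial fit at roughly 20–30 ms, which is
what makes full parameter-recovery sweeps practical on one CPU.

**MCMC.** Posteriors use adaptive random-walk Metropolis in the natural
parameter space under flat priors over the bounds: three chains started
overdispersed around the MLE, proposal covariance adapted to the chain
history (scaled by $2.38^2/d$) during burn-in, convergence declared when
the Gelman–Rubin statistic of every parameter is below 1.1, and 10,000
pooled post-convergence draws retained by default. Draws violating the
simplex are rejected by the prior, so every retained draw is a valid
parameter vector.

**Model comparison** uses BIC, $k\ln n - 2\ln L$, with $k$ the number of
free parameters; bias terms add to $k$ (constant: 2, proportional or
radial: 1) while a KDE guess adds none. Two fitted conditions can be
compared with a Wald test built from the inverse-Hessian covariances of
the two fits (`condition_compare()`).

## Response biases

Three parametric distortions are supported, each usable generatively and
as a fitted correction:

* **constant** — a fixed translation subtracted from responses;
* **edge-proportional** — responses shift a proportion $b$ of their
  distance to a named screen edge, along that axis only;
* **radial** — responses contract toward (or expand away from) a centre:
  the screen centre, a fixed point, or per trial the nontarget location,
  which models a nontarget "pull" that is distinguishable from misbinding
  because pulled responses sit between target and nontarget rather than
  on the nontarget.

Conventions, fixed and tested: simulation applies the bias to sampled
responses and then *clips* to the screen boundary (mixture-component
sampling, by contrast, resamples); fitting applies the same transform to
the component means before the density is evaluated, so the recovered
bias parameter matches the simulated one in sign and size. The
edge-proportional and radial maps are affine, so they also shrink the
effective component SD by $1-b$; like the source models, the fitted
correction shifts means only, which is part of why very large biases are
not fully corrected. With several nontargets a per-trial "pull" centre is
ambiguous, so the nontarget-centred radial bias is only defined for
one-nontarget trials.

## Response-sampling guess distributions

Instead of assuming uniform guessing, the guess component can be a
kernel density estimate built from all of a participant's own responses:
a guess then looks like a response drawn from a random other trial,
inheriting the participant's idiosyncratic response biases. The KDE uses
product Gaussian kernels with Scott's-rule bandwidths
$h_j = s_j\,n^{-1/6}$ (overridable), and — because kernel mass can fall
off-screen — is renormalised over the screen rectangle so that $\gamma$
remains a probability. The renormalisation redistributes the lost edge
mass globally (a few percent for uniform data), which slightly inflates
the interior density; the unnormalised estimate is available via
`normalize = FALSE`. Whether the KDE helps is assessed out-of-sample:
`crossval_response_sampling()` fits 90% of trials and evaluates the mean
per-trial likelihood of the held-out 10% (100 splits by default),
rebuilding the KDE from training responses only so the comparison cannot
reward overfitting.

## Change detection

For 2AFC change-detection data the probability of rejecting a probe
displaced by $d$ from the target is the integral of the continuous
mixture density over the on-screen disc of radius $d$ around the target.
The uniform component uses the exact disc–rectangle overlap (angular
quadrature of the clipped polar radius, exact for interior discs); the
Gaussian components use the noncentral-$\chi^2$ disc probability,
consistent with the untruncated fitting density; a full polar-grid
quadrature of the density (Simpson in radius, midpoint in angle, clipped
to the screen) is available as a cross-check and for truncated or KDE
variants. Near an edge the analytic Gaussian term includes a small
off-screen residual; the quadrature mode quantifies it. The default 2AFC
model is the standard mixture without misbinding, because the misbinding
probe integral must account for every nontarget and is markedly slower.
A simple response-bias summary (the mean acceptance proportion) can be
computed directly from the data; no signal-detection bias parameter is
modelled.

## Behavioural metrics

The package implements the distance metrics these models are meant to
replace, so the two approaches can be compared on the same data: mean
target distance; nearest-neighbour distance (ties broken toward the
target); their difference; and swap errors — the proportion of responses
within a threshold (fixed at 1.5° ≈ 44 px, or the participant's mean
target distance) of a nontarget. Swap errors are chance-corrected by
subtracting, per trial, the fraction of 360 evenly spaced points on the
circle of radius equal to that trial's target distance (centred on the
target, off-screen points dropped) that would count as swaps. The
discretisation and the clipping of the candidate circle to the screen
are implementation choices; 360 points make the discretisation error
negligible next to the sampling noise of 100-trial datasets.
`split_half_reliability()` estimates measure reliability by repeatedly
halving each participant's trials and Spearman-correlating the halves
across participants.

## The simulator and what passing tests show

The built-in simulator defines the study conditions used throughout the
tests: a 3-item task (one target, two nontargets), 100 trials, a
1366 × 768 px screen, uniformly placed stimuli — optionally constrained to
at least 88 px between items and from the screen centre and 29 px from
the edges — and the canonical recovery sweep of 11 evenly spaced values of
$\gamma, \beta \in [0.01, 0.98]$ and $\sigma \in [0.1, 100]$ with cells
$\gamma+\beta>1$ excluded (726 cells). Stimulus placement uses rejection
sampling capped at $10^4$ attempts per trial so infeasible constraint
sets fail fast, naming the violated constraint.

The simulator draws the response type per trial from
$(\alpha,\beta,\gamma)$, which is exactly the fitted model's data-generating
process. Recovery results therefore validate the *estimator* — that the
fitting machinery returns the parameters that generated the data — not
the model's adequacy for human behaviour, where guesses are not uniform,
biases are idiosyncratic, and memory noise need not be isotropic
Gaussian. The bias, KDE and two-class variants exist precisely to relax
those assumptions, and the cross-validation tools measure whether doing
so helps out-of-sample.

## Scale choices

Simulation experiments in the tests and the acceptance script use
reduced replication chosen to keep full runs at desk scale: 10 iterations
per sweep cell for the recovery and metric-validity sweeps (the pooled
correlations over ~7,260 runs are stable at this replication), 10,000
retained MCMC draws, and small replicate counts (5–25) for the
direction-only comparisons (trials, nontargets, constraints, bias
corrections, 2AFC versus continuous report). Sweep-level Spearman
correlations computed this way are treated as stochastic quantities with
a tolerance of a few hundredths.

Two of the direction-only experiments deserve a note on design. Trend
tests over the *whole* sweep need replication far beyond desk scale,
because cells where recovery is intrinsically hard (near-total guessing
or misbinding) contribute large, design-insensitive errors that swamp a
small trend. The trial-count trend is therefore evaluated on moderate
cells ($\beta,\gamma \in \{.1,.3\}$, $\sigma \in \{20,40\}$), where
recovery accuracy is limited by the number of trials; the nontarget-count
trend on noisier cells ($\beta,\gamma \in \{.2,.4\}$,
$\sigma \in \{50,90\}$), because extra nontargets hurt recovery through
overlap between component distributions, which requires appreciable
spread to occur at all. The posterior trade-off correlation between
guessing and misbinding is a one-dataset quantity with an across-dataset
SD of about 0.04; its magnitude is checked on a mean over three
simulated datasets, its sign on every one.

## Known limitations

* Anisotropic or covarying imprecision, separate target/nontarget SDs,
  and variable-precision or slot-family models are out of scope.
* Hierarchical (multi-participant) MCMC is not provided.
* The untruncated default density slightly misstates the likelihood for
  items very close to screen edges; use `truncated = TRUE` where that
  matters.
* The chance correction for swap errors assumes response directions are
  exchangeable on the target-distance circle, which is only
  approximately true under strong response biases.
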