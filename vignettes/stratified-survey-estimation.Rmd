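---
title: "Design-based estimation for stratified towed-video surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based estimation for stratified towed-video surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seastrat)
library(dplyr)
```

## The problem

seastrat estimates the abundance of benthic epifauna — it was built for the
European flat oyster, *Ostrea edulis*, at the northern fringe of its range in
the Swedish Skagerrak — from a stratified random towed-video survey. The
sampling frame divides the coast into geographic areas crossed with three
depth bands (0.5–3, 3–6 and 6–10 m), each cell with a known areal extent
$A_{st}$ from nautical-chart intervals. Sites are placed at random within
cells; at each site a camera sled films two 20 m transects of 0.8 m width,
so that counts of individuals over a nominal 32 m$^2$ per site give a
density. Because the design is probability-based, mean densities scale to
population totals with design-based standard errors — no habitat model, no
extrapolation beyond the sampled frame.

## The estimator

Let $\bar y_{st}$ and $s^2_{st}$ be the mean and the unbiased ($n-1$
denominator) sample variance of site densities in stratum $st$, sampled with
$n_{st}$ sites, and $W_{st} = A_{st} / \sum_{st} A_{st}$ the areal weight
within a survey domain. The stratified mean and its variance are the
classical (Cochran) forms

$$\bar y = \sum_{st} W_{st}\,\bar y_{st}, \qquad
  V(\bar y) = \sum_{st} W_{st}^2\, \frac{s^2_{st}}{n_{st}},$$

and the population total over the domain's extent $N = \sum_{st} A_{st}$ is

$$\hat T = \bar y \times N \;\pm\; \sqrt{V(\bar y)} \times N .$$

The error term is the standard error of the total, $\sqrt{V}\,N$; the
per-stratum partial totals $A_{st}\bar y_{st}$ and partial SEs
$A_{st}\sqrt{s^2_{st}/n_{st}}$ add up to the domain total and its variance.
Independently planned surveys (here: the four coastal areas versus the
separately commissioned Koster survey) are estimated separately and
combined by summing totals and taking the root sum of squares of their SEs.

Design choices made where the design was genuinely open:

* **The site is the sampling unit.** The two transects of a site are pooled
  into one count over one filmed area before estimation; transect-level
  densities are used only for the concentration curve. Sites, not transects,
  are the independently placed spatial units of the design.
* **Rocky, visually inspected sites are density-zero sites.** Sites too
  rocky to film are recorded absent after visual inspection; they stay in
  $n_{st}$ with density exactly 0, because they remain part of the
  population of sites the design drew from.
* **No finite-population correction.** Sites are random positions in
  continuous habitat, not draws from a finite list, so the without-
  replacement correction factor has no design justification here. (The
  synthetic validation below discretises habitat into cells for
  convenience; at its default 2,000 cells per stratum the neglected factor
  $1-f$ is 0.975 for 50-site samples.)
* **An unsampled frame cell is an error, not an imputation.** A cell with
  no sites cannot be extrapolated silently; `allow_missing_strata = TRUE`
  excludes the cell from both the weights and $N$, shrinking the estimated
  domain rather than guessing a density.
* **Per-site filmed area is stored, not assumed.** The nominal geometry is
  32 m$^2$, but the area is carried per site so that deviating transects do
  not bias densities.
* **Living and dead counts run through the same pipeline independently**;
  no joint covariance model is attempted.

## Derived stock metrics

* *Frequency of occurrence*: share of sites with at least one individual,
  with the plain binomial SE $\sqrt{p(1-p)/n}$ (the field convention for
  such presence profiles; nothing finer is warranted by error bars alone).
* *Living ratio*: living/(living + dead) per site, averaged over sites that
  contain any oysters; a crude condition proxy that declines with depth.
* *Concentration curve and bed share*: observation units sorted by density
  (ties kept in original order), cumulative fraction of counted individuals;
  the bed share is the fraction at or above 5 per m$^2$, the OSPAR oyster-bed
  threshold, compared with `>=` to match the "five or more" phrasing. The
  unit share can be quoted against all units or only those holding at least
  one individual (the convention behind "x out of n occupied transects").
* *Detection correction*: video counting misses on average 20% of
  individuals through burial and overgrowth, so totals are rescaled by
  1.25 = 1/0.8. The SE is rescaled identically; no uncertainty is attached
  to the factor itself.
* *Biomass*: 63 g mean individual weight by default; exactly linear.
* *Exploitation rate*: annual landings (default 88,000 individuals) as a
  percentage of the standing total, with a scenario multiplier for
  unreported catch.
* *Habitat-restricted estimate*: per stratum, the suitable area is
  estimated as $\hat A_{st} = (k_{st}/n_{st}) A_{st}$ from the $k_{st}$
  suitable sites, the density over suitable sites only. When every
  non-zero-density site is suitable this is algebraically the unrestricted
  estimator, which makes it a robustness check rather than a new model.
  A stratum with exactly one suitable site has no variance estimate and is
  an error unless explicitly dropped.

## The synthetic population

The generator exists so that the full pipeline can be validated against
known truth; its defaults (the "skagerrak-like" parameterisation) emulate
the survey conditions of the original inventory:

| parameter | default | why |
|---|---|---|
| occupancy by depth | 0.25 / 0.19 / 0.06 | observed living-oyster occurrence declines with depth |
| conditional mean density | 1.68 / 1.03 / 0.28 m$^{-2}$ | puts stratum mean densities at the magnitudes the frame supports (a total near 40 million) |
| lognormal `sdlog` | 1.8 | places roughly 60% of individuals in cells of ≥ 5 m$^{-2}$, the concentration the real stock shows |
| dead-per-living | 0.55 / 1.0 / 2.5 | living ratio declining with depth (shells persist and accumulate downslope) |
| dead-only occupancy | 0.15 / 0.16 / 0.14 | dead shells occur more widely than living oysters |
| detection efficiency | 0.8 | the 20% average miss rate of video counting |
| cells per stratum | 2,000 | sampling fractions stay small at survey-scale $n$ |

Each stratum is discretised into equal-area cells; a cell's living density
is zero-inflated lognormal (the lognormal parameterised by its conditional
mean, $\mu = \log m - \sigma^2/2$). All overdispersion lives in this density
field; counting is Poisson over the filmed area, thinned per individual by
the detection probability, and split over transects multinomially with
equal probabilities (no information exists on within-site variance, so
uniform splitting is the minimal assumption). Observation in *expectation
mode* replaces counts by their exact means, which gives the census limit:
sampling every cell at perfect detection must and does return the true
total to floating precision.

What the generator does **not** emulate: spatial autocorrelation beyond the
stratum level, substrate–density coupling, size structure, or dynamics.
Passing recovery tests therefore demonstrate the estimator's design
properties — unbiasedness, variance calibration, correction arithmetic —
not the realism of any particular map of the seafloor.

## What the validation shows — and a caveat on SEs

Replicated synthetic surveys (the acceptance suite uses 1,000 replicates of
50 sites per stratum; the acceptance script, 400) confirm that the
estimator is design-unbiased and that the variance estimator is calibrated:
the mean of the estimated variances matches the empirical variance of the
totals to within a few percent, and at 80% detection efficiency the raw
totals are low by the expected 20% while the ×1.25 correction restores
them.

One property deserves emphasis because it concerns real surveys of this
stock, not only simulations. Under density fields patchy enough to hold
more than ~40% of individuals in bed densities, the *estimated SE* is
strongly right-skewed at realistic sample sizes: most samples miss the rare
high-density cells and underestimate the spread, while a few catch one and
overestimate it. The mean of the estimated SEs then falls well below their
root mean square even though the variance estimator is unbiased — in the
replicate experiment the ratio of the empirical SD of totals to the mean
estimated SE sits near 1.8, while the variance-scale ratio is within a few
percent of 1. This is Jensen's inequality acting on a heavy-tailed $s^2$,
not an implementation defect, and it is intrinsic to design-based SEs for
strongly aggregated organisms: a single reported SE from one survey of a
bed-forming stock is itself an uncertain quantity, more often too small
than too large.

## Numerical choices and degenerate inputs

* Stratum variance requires $n_{st} \ge 2$; fewer sites is an error, never
  a silent zero.
* Weights must sum to 1 per survey domain to $10^{-12}$ (they do by
  construction; tests assert it).
* The concentration curve is undefined on an all-zero table (error), and a
  single observation unit jumps from 0 to 1 at its density.
* Areal extents are converted km$^2 \to$ m$^2$ exactly once, at load.
* Shallow-band extents may be derived from 0–3 m chart extents as
  $5/6$ of the raw value, reflecting the un-navigable 0–0.5 m sliver.
* Reported grids round totals to 2 decimals in millions; full precision is
  kept in the breakdown tables.
* Problem sizes: the packaged validation uses 2,000 cells per stratum,
  replicate counts of 400–1,000 and census checks over 30,000 cells —
  sizes chosen to make Monte-Carlo error a small fraction of the tolerance
  bands being asserted.

## Known limitations

* The frame's printed total extent in the original inventory does not equal
  the sum of its cells; the package carries the per-cell extents and makes
  no attempt to reconcile printed margins.
* Two deep coastal cells of the original design were never sampled; real
  data for them require `allow_missing_strata = TRUE`, and the synthetic
  default assigns them a typical deep-stratum intensity instead.
* Habitat-restricted estimation implements the documented area-and-density
  contract; published habitat-restricted figures for this stock are not
  reproducible from printed data and are not a target.
* Detection efficiency enters as a single known constant; surveys with
  estimated efficiency would need an extra variance term the original
  method does not define.
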