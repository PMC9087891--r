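---
title: "Unidentifiable towers in BDI introgression models and how to relabel them"
author: "msciTowers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unidentifiable towers in BDI introgression models and how to relabel them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msciTowers)
```

## The model and the problem

A multispecies-coalescent-with-introgression (MSci) model is a rooted,
ultrametric species tree whose branches may be connected by horizontal
edges at fixed times. Three kinds of parameters describe it, all in units
of expected substitutions per site: node times $\tau$, per-branch
population sizes $\theta$ (pairwise coalescent rate $2/\theta$), and, at
every hybridization node, an introgression probability $\varphi$ — the
probability that a lineage traced backwards through the node takes the
*horizontal* (cross-population) parent path, with $1-\varphi$ for the
vertical path. This orientation of $\varphi$ is used consistently
everywhere in the package; external sample tables whose columns follow a
different convention can be renamed through the `colmap` argument of the
relabeling functions.

A *bidirectional introgression* (BDI) event places one hybrid node on each
of two contemporaneous branches, with the horizontal edges pointing at each
other. BDI events make the model unidentifiable in a label-switching way:
complementing the two introgression probabilities and swapping the two
parental population sizes,
$$\varphi_X' = 1-\varphi_X,\quad \varphi_Y' = 1-\varphi_Y,\quad
\theta_X' = \theta_Y,\quad \theta_Y' = \theta_X,$$
produces a parameter point with exactly the same gene-tree distribution:
tracing any lineage through the hybrid pair, the path probabilities and the
coalescent rates it meets are identical, only the labels "left/right" have
been exchanged. The posterior therefore contains symmetric *towers* —
modes of equal height that mean different parameter labelings. An MCMC
sampler that wanders between towers changes the meaning of $\varphi_X$
mid-run, and naive posterior means collapse toward $1/2$ regardless of the
data.

Whether the two towers live in the same model or in two mirrored models
depends on topology. The package classifies each event on the *condensed*
graph in which every BDI pair is merged into one node: if the two condensed
parents coincide the event is a **sister** event (within-model towers),
otherwise **nonsister** (cross-model). With $m$ sister and $n$ nonsister
events there are $2^n$ unidentifiable models, each with $2^m$ within-model
towers. `enumerateTowers()` constructs all of them, with explicit
per-parameter mappings, by composing the event-wise involutions; two BDI
events stacked between the same pair of lineages are treated as one unit
with the four-transform set of `doubleBdiMappings()`, whose transforms form
a Klein four-group (verified by brute-force composition in the tests).

```{r}
model <- readMSciModel(system.file("extdata", "bdi5_sisters.msci",
                                   package = "msciTowers"))
enumerateTowers(model)
```

For nonsister events the mapping additionally mirrors part of the topology;
the package reports these variants (topology tag plus parameter renames)
but does not apply them to sample tables: a fixed-model MCMC run visits a
single variant, and mapping summaries across variants is a reporting
operation, not a relabeling one. Species names are kept; the topology edit
is reported rather than renaming leaves.

## Condensation beyond the canonical cases

The condensation rule is defined here by merging all BDI pairs
simultaneously, which is its own fixed point for every configuration with
BDI pairs on ordinary branches. Models in which a BDI pair's parental
branches are themselves hybrid edges of different events fall outside the
canonical configurations; the classification machinery still answers, but
such models should be treated with care — the enumeration only claims the
$2^n \times 2^m$ structure for the canonical cases.

## The relabeling algorithms

Given an MCMC sample table $\Theta_t$, $t = 1,\dots,N$, and the transform
set of one sister event (2 transforms) or one stacked pair (4 transforms),
all three algorithms assign each row a transform indicator $z_t$ and
replace the row by its image. Initialization prefers the tower with small
introgression probabilities: $z_t = 0$ if $\varphi_X + \varphi_Y < 1$,
else 1; with four transforms, the lowest-index transform whose image
satisfies $\varphi_X + \varphi_Y < 1$, then $\varphi_Z + \varphi_W < 1$,
falling back to the lowest index minimizing $\varphi_X + \varphi_Y$ (the
boundary $\varphi_X + \varphi_Y = 1$ deliberately falls on the mirror side,
matching the initialization rule's strict inequality).

* **CoG0** iterates: compute the center of gravity $\mu$ (coordinate
  means) of the currently selected positions; move each row to the image
  closest to $\mu$ in Euclidean distance. The recorded objective
  $\sum_t d_0^2$ is nonincreasing by the usual k-means argument.
* **CoGN** additionally rescales each coordinate by its current sample
  variance $\nu_j$. Because the weights are refreshed each iteration the
  plain sum of squared normalized distances is constant ($4(N-1)$ after
  every center step), so monotonicity of the recorded trajectory is only
  guaranteed for CoG0; in practice CoGN converges in the same handful of
  iterations.
* **beta–gamma** fits, by maximum likelihood, an independent beta density
  to every $\varphi$ column and a gamma density to every $\theta$ column
  of the selected positions, then moves each row to the image with the
  highest log density. Both half-steps increase the joint log likelihood
  $\ell(\omega, z)$, so the algorithm is nondecreasing and converges. With
  four transforms, four beta and four gamma densities (16 parameters) are
  fitted as eight independent 2-D problems — the joint optimum factorizes
  because the densities are independent per column.

Replacing the beta/gamma densities by normal densities with a common
(pooled) variance reproduces the CoG0 label choice exactly, and per-column
variances give CoGN; both are available through the `family` argument of
`betaGammaRelabel()` and are asserted in the tests.

Ties in step 2 keep the current label, which guarantees termination
together with the monotone objective; a hard cap of 1000 iterations (with
a warning) protects against pathological inputs, though a handful of
iterations is typical. With several sister events, `relabelAll()` applies
the chosen algorithm once per event in ascending event time (ties broken
by node label — the ordering is a package choice, as sequential passes
operate on disjoint parameter blocks). Samples from multiple runs may be
concatenated before relabeling.

### Numerical choices

The beta and gamma MLEs depend on the data only through sufficient
statistics ($\sum \log \xi$, $\sum \log(1-\xi)$ for beta; $\sum \xi$,
$\sum \log \xi$ for gamma). The beta fit is a BFGS quasi-Newton
optimization on the log-parameter scale started from moment matching; the
gamma fit profiles the rate out ($b = a/\bar\xi$ exactly, so the fitted
mean equals the sample mean) and solves a 1-D Newton iteration for the
shape. For density evaluation only, $\varphi$ values are clamped to
$[10^{-9}, 1-10^{-9}]$ and $\theta$ to $\ge 10^{-12}$ — reported CIs can
legitimately touch 0, where the log densities diverge; stored sample
values are never modified.

## Posterior summaries

`summarizeSamples()` reports per-column means, 95% HPD intervals and
effective sample sizes, and is meant to run on *processed* tables; a dip
heuristic (mass in the middle decile of $[0,1]$ versus the flanks,
advisory only, active from 200 draws) warns when a probability column
still looks bimodal. The HPD interval is the shortest window of
$\lceil 0.95\,N \rceil$ order statistics, ties broken toward the smallest
lower endpoint — deterministic and cross-checked against exhaustive window
search. ESS uses $N/(1 + 2\sum_k \hat\rho_k)$ with Geyer's
initial-positive-sequence truncation, clipped to $[1, N]$; it is computed
on the sample in its given order (row permutation changes ESS, not the
mean).

## What the synthetic generator emulates — and what it does not

`simulateLabelSwitchingSamples()` emulates the *posterior sample* a
Bayesian MSci analysis would produce under label switching, not the
sampler itself: within the reference tower each $\varphi$ column is beta
and each $\theta$ column gamma; the other towers are exact mapping images;
and the true tower label follows a sticky Markov chain (stay probability
$s$, jumps drawn from the stationary weights). The defaults encode the
study condition used throughout: reference means
$(\varphi_X, \varphi_Y) = (0.7, 0.2)$ at moderate concentration (beta
shapes summing to 10), $\theta$ means $0.005$ and $0.02$ (gamma shape 4),
two equal-weight towers, $s = 0.999$, $N = 2 \times 10^5$. Real posteriors
are not exactly beta/gamma, have correlated columns, and their towers need
not be exact mirror images when priors are asymmetric; passing tests on
this generator therefore validate the algorithms' mechanics (label
recovery, monotonicity, symmetry collapse), not their behaviour on any
particular dataset. The well-separated fixtures used for the accuracy
checks sharpen the concentrations tenfold so that towers barely overlap.

The gene-tree simulator is a backwards-in-time coalescent with episodic
introgression: exponential waiting times at rate $k(k-1)/\theta$ within
each population, binomial path choices at each hybridization time, one
independent RNG stream per locus derived from (seed, locus) so extending
the locus count never perturbs earlier loci. Sequence evolution is out of
scope — gene trees are the terminal output. For the basic two-species BDI
shape the package also carries the analytic density of the pairwise
coalescent time (a two-term exponential mixture before the root plus the
surviving mass in the root population); it integrates to one, matches the
simulator's histograms (chi-square cross-validation in the tests), and is
*pointwise identical* under the mirror mapping — while a deliberately
broken mapping that complements the $\varphi$s without swapping the
$\theta$s is detected by a Kolmogorov–Smirnov test, confirming that the
invariance is exactly the complement-and-swap mapping and nothing looser.

## Problem sizes

The test-suite simulations use $10^4$ rows for accuracy checks,
$2 \times 10^5$ rows for the symmetry-collapse check, and $10^5$ loci per
arm of the KS invariance checks; these sizes give Monte-Carlo tolerances
(3$\sigma$) comfortably inside the asserted bounds while keeping the whole
suite to a few minutes on one core.

## Site-pattern heuristics

For contrast with the full-likelihood treatment, the package includes the
genome-wide site-pattern statistics for a quartet ((S1,S2),S3)+outgroup:
pattern counts over two-state 2/2 sites (gap/ambiguity columns dropped
entirely), the $D$ statistic
$(n_{ABBA}-n_{BABA})/(n_{ABBA}+n_{BABA})$, and the hybrid-speciation
estimate $\hat\varphi = (n_{BBAA}-n_{BABA})/(n_{BBAA}-2n_{BABA}+n_{ABBA})$,
whose symmetry assumptions (equal divergence times and population sizes on
the two sides) are not checked — when they fail the estimate is biased,
and no correction is attempted. These statistics carry no information
about the direction or timing of gene flow and none about gene flow
between sister species; that contrast is the reason they are here.

## Known limitations

* Tower enumeration is exponential in the number of BDI events by nature
  ($2^{m+n}$); models with more than a handful of events are enumerable
  but rarely meaningful, and more than two stacked events between one
  species pair are not given special treatment.
* Nonsister (cross-model) samples are reported, never auto-relabeled; a
  model-label column and an explicit decision are required to merge
  cross-model samples.
* The relabeling algorithms remove label switching only; genuine
  multimodality not caused by the tower symmetry is left untouched, and
  the unidentifiability itself cannot be removed — choosing between
  towers needs external information.
* UDI (unidirectional) events are represented, counted and simulated, but
  no tower enumeration is attempted for them beyond reporting the nodes.
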