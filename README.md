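# msciTowers

Unidentifiable towers and relabeling algorithms for
bidirectional-introgression multispecies coalescent (MSci) models.

## The problem

An MSci model is a rooted, ultrametric species tree with episodic gene-flow
edges at fixed times, parameterized by node times τ, per-branch population
sizes θ (pairwise coalescent rate 2/θ) and, at every hybridization node, an
introgression probability φ — the probability that a lineage traced
backwards takes the horizontal (cross-species) parent path. All three are
in units of expected substitutions per site.

A **bidirectional introgression (BDI)** event — a pair of hybridization
nodes at the same time exchanging migrants in both directions — makes the
model unidentifiable in a label-switching way. Complementing the two
introgression probabilities and swapping the two parental population sizes,

    φX' = 1 − φX,   φY' = 1 − φY,   θX' = θY,   θY' = θX,

yields a parameter point with *exactly* the same gene-tree distribution.
With *m* BDI events between sister lineages and *n* between nonsister
lineages, the posterior contains 2^*n* unidentifiable models, each with
2^*m* within-model towers. An MCMC chain that wanders between towers
switches the meaning of its parameter columns mid-run: the raw posterior
mean of each φ drifts to ½ regardless of what fits the data.

msciTowers is for people who fit BDI models (e.g. with a Bayesian MSci
sampler) and need to (1) know how many unidentifiable towers their model
implies and what the exact parameter mappings between them are, and (2)
map every MCMC draw onto one chosen tower before summarizing. It
implements three relabeling algorithms — the center-of-gravity algorithms
**CoG0** and **CoGN** (iteratively move each draw to whichever mirror
image is closer to the current center of gravity, unweighted or
variance-weighted) and the **beta–gamma** algorithm (alternate
maximum-likelihood fitting of beta densities to φ columns and gamma
densities to θ columns with per-draw selection of the best-fitting image;
its log likelihood never decreases) — plus posterior summaries (means,
95% HPD intervals, ESS), a coalescent gene-tree simulator with episodic
introgression, a generator of synthetic label-switching samples with known
tower labels, and ABBA–BABA site-pattern statistics for contrast.

## Worked example

Parse the basic two-species BDI model, enumerate its towers, simulate a
label-switching posterior sample, and relabel it:

```r
library(msciTowers)

model <- readMSciModel(system.file("extdata", "bdi2_basic.msci",
                                   package = "msciTowers"))
model
#> MSciModel: 2 species, 1 BDI event(s), 0 UDI event(s)
#>   parameters: 9 (5 theta, 2 tau, 2 phi)
#>   BDI X-Y at tau=0.00125 [sister]

towers <- enumerateTowers(model)
towers
#> TowerSet: 1 sister and 0 nonsister BDI event(s) -> 1 model variant(s) x 2 within-model tower(s)
#>   variant-0
towerMappings(towers)[[2]]
#> TowerMapping tower-1
#>    phi_X <- 1 - phi_X
#>    phi_Y <- 1 - phi_Y
#>    theta_X <- theta_Y
#>    theta_Y <- theta_X

## synthetic posterior: two equal-weight mirror towers, reference means
## (phi_X, phi_Y) = (0.7, 0.2), theta means (0.005, 0.02), sticky label chain
event <- detectBdiEvents(model)[[1]]
mappings <- list(identityMapping(), singleBdiMapping(event))
sim <- simulateLabelSwitchingSamples(towerSpec(n = 50000L, stay = 0.995),
                                     mappings, seed = 42)
round(colMeans(sim$samples), 4)
#>   phi_X   phi_Y theta_X theta_Y
#>  0.5079  0.4875  0.0122  0.0128
```

The raw means sit at the symmetric-mixture values (φ ≈ ½, θ at the midpoint
of the two parental sizes) — the label-switching signature, and exactly the
misleading numbers a naive summary would report. Relabeling recovers the
tower:

```r
res <- betaGammaRelabel(sim$samples, mappings)
res
#> RelabelResult [betagamma]: 50000 rows, 2 transforms, 3 iteration(s)
#>   final objective: 466251.7
#>   label counts: z=0: 26057, z=1: 23943
round(colMeans(res@samples), 4)
#>   phi_X   phi_Y theta_X theta_Y
#>  0.7002  0.2004  0.0050  0.0200
summarizeSamples(res@samples)
#>      name        mean       hpd_lo      hpd_hi      ess     n
#> 1   phi_X 0.700172687 0.4338774353 0.946876737 50000.00 50000
#> 2   phi_Y 0.200421716 0.0068067357 0.430953946 47690.31 50000
#> 3 theta_X 0.005006622 0.0008993841 0.009928501 50000.00 50000
#> 4 theta_Y 0.020028925 0.0039586781 0.040214116 49863.32 50000
```

After relabeling, every column is unimodal and the posterior means sit on
the selected tower (the mirror tower, with φX near 0.3, would have been an
equally correct answer). `relabelAll()` runs one pass per sister BDI event
of a model — with the four-transform set for a stacked double-BDI pair —
and `cogRelabel()` provides the CoG0/CoGN alternatives, which agree with
beta–gamma to within 0.1% of labels on well-separated towers.

A thin command-line front end in `inst/scripts/msci.R` exposes the same
operations (`model validate/count`, `towers`, `relabel`, `summarize`,
`simulate-samples`, `simulate-genetrees`, `dstat`); bpp-style `mcmc.txt`
sample tables are read directly, and column naming differences are handled
by `--map` / the `colmap` argument.

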