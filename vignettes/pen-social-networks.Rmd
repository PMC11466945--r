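---
title: "Association and tail-biting networks in growing-finishing pig pens: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association and tail-biting networks in growing-finishing pig pens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailnet)
```

## The problem

Tail biting is one of the most damaging abnormal behaviors in commercial
pig production. A line of work in applied ethology asks whether a pig's
*social-network position* within its pen — who it rests with, who bites
whom — carries information about its risk of becoming a victim of tail
biting, and whether litter origin (raising littermates, half-littermates,
or non-littermates together) shapes pen social structure. `tailnet`
implements that analysis end to end: from scan-sampled lying observations
and tail-biting event logs to association and interaction networks,
network metrics, tail-injury scoring, and the statistical models that
relate network position to injury.

Because raw video-derived observations from such studies are rarely
deposited, the package includes a synthetic-data generator that reproduces
the statistical structure of the standard design — 12 pens of 8 pigs
(4 barrows, 4 gilts) in three litter-origin treatments, three 6-h
observation periods at 15, 19 and 23 weeks of age scanned every 10 min
(36 scans per period), and twice-weekly tail-injury assessments over the
14-week growing-finishing phase. Every downstream stage is therefore
testable without any external data.

## Association networks: the half-weight index

Two pigs are "lying together" at a scan when they rest in bodily contact.
Aggregating the 36 binary scan matrices of one observation period gives,
for every dyad, the count $x$ of scans spent lying together, and for every
pig the count $n_a$ of scans spent lying. The edge weight of the
undirected association network is the half-weight association index

$$\mathrm{HWI}(a,b) = \frac{x}{(n_a + n_b)/2},$$

which corrects the raw co-occurrence for the time each pig was observable
in the lying state and ranges from 0 to 1. Properties relied on downstream
(and enforced by tests): symmetry, scale-freeness (doubling $x$, $n_a$,
$n_b$ leaves it unchanged), monotonicity in $x$ and in the $n$'s. Dyads in
which neither pig ever lay get HWI 0 rather than NaN, a convention that
keeps pen-level metrics defined; no strong-tie threshold is applied by
default (`min_hwi = 0`).

## Tail-biting interaction networks

A tail-biting event is a directed incident: an initiator bites a recipient
hard enough to cause a reaction. Arcs run initiator → recipient and are
weighted by bite counts, so in-strength is "bites received" and
out-strength "bites performed", regardless of how many distinct partners
were involved. Because events are sparse within single 6-h windows, the
per-period matrices are aggregated over the three observation periods by
default — one network per pen — exactly mirroring how the per-period
matrices sum entrywise.

## The graph-metric engine

The package carries its own metric engine for small weighted networks
rather than delegating to a graph library, so every number can be checked
against brute-force enumeration. (The test suite also cross-checks against
`igraph`, which is never used in the computation itself.)

* **Density** — realized dyads over possible dyads; an edge exists iff its
  weight is positive.
* **Strength** — row/column sums of the weight matrix.
* **Betweenness** — unnormalized Brandes accumulation
  $B(v) = \sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$, all shortest
  paths counted fractionally, disconnected pairs contributing zero (no
  harmonic fallback). Weighted betweenness uses the standard
  strength-to-length inversion $\ell = 1/w$. Ties among equal-length paths
  are resolved by exact $\sigma$ accounting with a $10^{-10}$ length
  tolerance, never arbitrarily.
* **Freeman centralizations** —
  $C = \sum_v (c_{\max} - c(v)) / D_{\max}$ with the star-graph
  denominator: $(n-1)(n-2)$ for undirected degree, $(n-1)^2$ for directed
  in-/out-degree, $(n-1)^2(n-2)/2$ (undirected) and $(n-1)^2(n-2)$
  (directed) for betweenness. Stars (and in-/out-stars) score exactly 1,
  complete graphs exactly 0; an edgeless network is assigned 0 by
  convention so fully sparse bite pens stay in-frame.

Two genuinely open choices are exposed as switches rather than decided
silently:

* Degree centralization defaults to *unweighted* degrees (the classical
  Freeman definition) even for HWI-weighted networks; a strength-based
  variant (normalized by the same-size star with all edges at the observed
  maximum weight) is available via `weighted_centralization = TRUE`.
  Dense HWI networks are near-complete, so the binary variant is close to
  0 by construction; the weighted variant is the informative one there,
  and it is the one the recovery tests use.
* Pig-level betweenness defaults to weighted ($1/\mathrm{HWI}$ lengths)
  in association networks and to unweighted paths in the sparse bite
  networks; both are switchable per call.

## Injury scoring

Tail injuries are scored on the 0–4 scale (0 none; 1 healed lesions or
minor scabs; 2 blood without infection; 3 blood with infection; 4 partial
or complete tail loss). A pig's **maximal tail score (MTS)** is the
highest score it ever received; a pig is a **victim** when MTS ≥ 2. MTS
values are classed as {0, 1, ≥2} and tabulated against litter origin; the
class table is tested with Pearson's chi-square (no continuity
correction), df $(r-1)(c-1)$. Medians and IQRs use the default
linear-interpolation quantile convention (type 7); the convention is a
parameter because quartiles of small ordinal samples depend on it.

## The statistical layer

* **Correlation screen** — pairwise Pearson correlations among candidate
  metrics; one member of each pair with $|r| > 0.8$ is removed, the
  unweighted member when the pair is an (unweighted, weighted) version of
  the same quantity, otherwise the later-listed metric. Constant columns
  are reported and retained.
* **Kruskal–Wallis** — omnibus H from `stats::kruskal.test` (mid-ranks,
  tie correction); post hoc pairwise comparisons use the pooled-rank
  least-significant-difference criterion on mean ranks with $N - k$
  degrees of freedom, optionally Bonferroni-adjusted. The LSD form was
  chosen because it is the common default of the agronomic rank-comparison
  routines this analysis style relies on; the adjustment switch is exposed
  because that default is contested.
* **Linear mixed models** — `lme4::lmer` (REML) with pen (or pig nested in
  pen) random intercepts; estimated marginal means average predictions
  over the other factor levels with *equal* weights, and all pairwise
  treatment contrasts are Tukey-adjusted through the multivariate-$t$
  reference distribution (`emmeans`). Singular random-effect fits are
  returned with a convergence flag rather than refused, since pen
  variances near zero are common at 12-pen scale. Association-network
  betweenness is square-root transformed before modelling to tame its
  skew.
* **Proportional-odds MTS model** — `MASS::polr` by maximum likelihood,
  per-unit odds ratios with 95% Wald intervals, no pen random effect. The
  proportional-odds assumption is always checked by a likelihood-ratio
  test against the unconstrained multinomial logit; when it rejects, the
  odds ratios are flagged as withheld because cumulative odds ratios are
  then not interpretable — the pipeline reports the diagnostic rather than
  the estimates. MTS levels 3–4 can be collapsed into 2 via
  `collapse_sparse` when the top levels are empty.
* **Victimization model** — `lme4::glmer` binomial logit with a pen random
  intercept, odds ratios with Wald intervals.
* **Model selection** — candidate fits on identical rows ranked by AIC
  with ΔAIC; differing row counts are an error.

## The synthetic-data generator

The generator emulates the *statistical* structure the analysis assumes,
not pen physics:

* **Lying scans.** Each pig lies with probability `p_lie` (default 0.8 — a
  free choice, as lying-time budgets are not numerically anchored;
  growing-finishing pigs rest for most of a midday observation window).
  Among lying pigs, dyads draw exponential scores with rate equal to their
  preference weight and are accepted greedily in increasing score order —
  successive sampling proportional to the weights — under two constraints:
  at most two neighbors per pig (row-lying), and at most $\lfloor L/2
  \rfloor$ pairs per scan for $L$ lying pigs (the size of a matching).
  The second constraint is essential: if the greedy ran until every pig
  held two neighbors, the accepted edge set would be determined almost
  entirely by the caps and hardly at all by the weights, and preference
  structure would be invisible in the aggregated data. Stopping at
  matching size keeps the per-scan contact graph sparse enough that
  preferences propagate into HWI values, while preserving symmetry, the
  two-neighbor bound, and the forced-pairing limit (a 2-pig pen that
  always lies is always together).
* **Preference structures.** `uniform` (exchangeable dyads), `hub` (one
  highly social pig whose dyads carry weight $1+\kappa$), `block` (two
  4-pig blocks with elevated within-block weight, the half-littermate
  situation). $\kappa = 0$ collapses all three to uniform.
* **Bite events.** Directed dyad counts are Poisson with mean
  $\lambda_0 \exp(s_{out}(i) + s_{in}(j))$; the log-additive
  sender/receiver form is the simplest that lets biter and victim
  heterogeneity be dialed independently ($\sigma_{out} = 0.8$,
  $\sigma_{in} = 0.5$ by default, giving a few prolific biters per pen and
  moderate victim concentration). Timestamps are uniform over the 6-h
  window.
* **Injury trajectories.** Between assessments a score escalates one
  level with probability $1 - (1-g)^b$ for $b$ bites received in the
  window, capped at 4; scores 1–2 heal one level with probability `heal_prob`
  in bite-free windows (higher scores represent infected wounds that do
  not resolve between assessments). The defaults ($\lambda_0 = 0.25$
  bites/dyad/period, $g = 0.4$, heal 0.08) were fixed once by matching the
  generator's MTS class distribution to the published one (about 10% of
  pigs at MTS 0, half at 1, 40% victims) and have not been revisited.
* **Reproducibility.** One pseudo-random substream per pen is derived from
  the global seed, so identical configurations are byte-identical and
  adding pens never perturbs existing pens.

What the generator does *not* emulate — and hence what passing recovery
tests do and do not show: there is no pen geometry or thermoregulatory
clustering (real lying proximity responds to temperature), no diurnal
activity rhythm, no two-staged versus sudden-forceful biting typology, no
behavioral feedback from injury to subsequent lying or biting, and bites
occur only inside the observed 6-h windows whereas real biting continues
around the clock. Recovery results demonstrate that the *pipeline*
detects structure of the assumed kind at realistic effect sizes; they are
not evidence about real pens.

## Problem sizes used in the verification battery

The test battery verifies the metric engine against exhaustive
enumeration on every connected labeled graph with up to 6 nodes (about
27,500 graphs) and 1000 random 8-node graphs, using two independent
oracles (DFS path enumeration and minimal-walk counting via matrix
powers) that are first cross-validated against each other. Parameter
recovery uses 200 replicates of $n = 400$ for the ordinal model over
coefficients $\{0, 0.2, 0.4\}$ and 100 replicates of 40 pens × 8 pigs for
the mixed logistic model; generator-to-metric recovery uses 20 replicate
pens per preference arm. These sizes give Monte-Carlo standard errors
small enough that the assertions are sharp while the full suite runs in
about a minute and a half.

## Known limitations

* Pen-level inference at 4 pens per treatment is intrinsically weak; the
  package reproduces the analysis structure, it cannot manufacture power.
* The proportional-odds diagnostic is a global LR test; graphical
  per-cutpoint diagnostics are not provided.
* The Kruskal–Wallis post hoc is one defensible convention among several;
  the exact variant used in legacy analyses of this type is not
  standardized.
* Mid-study pig removals are supported by the data model (aggregates use
  only complete scans) but the generator does not simulate removals.
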