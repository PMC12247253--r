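---
title: "Methods: kinship, inbreeding depression and breeding-interval analysis in closed colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinship, inbreeding depression and breeding-interval analysis in closed colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonykin)
```

## The problem

Closed captive colonies — populations bred for decades without outside
animals — inevitably accumulate relatedness between mates. When related
parents produce litters, recessive deleterious alleles are exposed and
offspring survival drops: inbreeding depression. `colonykin` analyses
multi-decade breeding records of such colonies (one row per litter: mating
cage, dam, sire, dates, pups born, pups weaned, weaned sexes) to quantify
that depression and to detect the compensatory changes in breeding
behaviour — more frequent litters from more related pairs — that can mask
it at the level of total output.

## Record cleaning

Sixty years of record keeping produce duplicates, gaps and impossible
entries. `cleanRecords()` applies, in order: exact-duplicate removal
(identical on every mapped column — the safest reading of "duplicate",
reported transparently so stricter keys can be compared); removal of rows
with missing or invalid cage id, stock, birth date or counts, and of rows
whose weaned sex counts do not sum to the weaned total; capping of weaning
counts at birth counts (a data-entry safeguard — the records cannot tell
entry error from fostering, so the cap is applied without interpretation);
and derivation of `dead = born - weaned`. Every action is tallied in a
`CleaningReport`. Completeness filtering can be applied row-wise (default)
or cage-wise (`pairwise = TRUE`), because archival quality control is
sometimes applied to whole breeding pairs; both behaviours are exposed
rather than guessed. Dates are parsed in one declared dialect (ISO or US)
for the whole file, never guessed per row. A litter's year is the calendar
year of its birth date.

## Kinship and relatedness

The pedigree is a parent map over individual identifiers; individuals with
no recorded parents are founders, assumed unrelated and non-inbred. The
kinship coefficient $\varphi(a,b)$ — the probability that random alleles
drawn from $a$ and $b$ are identical by descent — follows the classical
recursion

$$\varphi(x,x) = \tfrac12\,(1 + \varphi(f_x, m_x)), \qquad
\varphi(a,b) = \tfrac12\,(\varphi(f_a, b) + \varphi(m_a, b))$$

for $a$ not an ancestor of $b$, with unknown parents contributing zero.
The recursion is anchored on generation depth (an ancestor is always
shallower than its descendant under longest-path depth), memoised, and
tested against two independent oracles: exhaustive path counting with
inbreeding correction, and gene-dropping Monte Carlo. Relatedness is
reported as $r = 2\varphi$ in percent: 0 for no shared ancestry, 50 for a
full-sibling mating of non-inbred parents, 100 for genetic identity.

Ancestor tracing is truncated at five generations by default
(`maxGenerations = 5`), counted in meioses from the mating pair (the pair
is generation 0, parents are 1, and so on; an ancestor reachable by
several paths counts at its shortest). Ancestors at the boundary are
treated as founders. This mirrors studbook practice: the oldest entries
are the least reliable, and a fixed cap keeps ambiguous deep records out
of the calculation at the cost of underestimating kinship contributed by
deeper common ancestors — truncated kinship is non-decreasing in the cap,
a property the tests assert. The window is anchored at the mating pair
rather than the litter; the choice is configurable and flagged for
sensitivity analysis.

## Loss metrics and models

Two loss summaries are computed per breeding pair: the fraction of pups
lost before weaning (`total_dead / total_born`) and the fraction of
litters with at least one loss. Association with relatedness is
quantified three ways:

* a **binomial-logit GLM** of losses out of events, which weights each
  pair by its number of events (mice born, or litters). Model fit is
  summarised by McFadden's pseudo $R^2 = 1 - \ell_1/\ell_0$ and the slope
  tested by a likelihood-ratio test against $\chi^2_1$. Log-likelihoods
  are Bernoulli-expanded (no binomial coefficient), which makes them
  invariant to aggregating litters into pair totals — the sufficiency
  property the tests assert numerically. The covariate is relatedness in
  percent; McFadden's $R^2$ is invariant to that scaling choice.
  Complete separation and failed IRLS set an honest `converged = FALSE`
  rather than returning a silently huge coefficient.
* a **Pearson correlation** between per-pair relatedness and the loss
  ratio, unweighted — matching the per-pair framing of scatter displays;
  correlations are two-sided throughout.
* a **five-band comparison** (relatedness $[0,25)$, $[25,30)$, $[30,35)$,
  $[35,40)$, $[40,100]$ percent — half-open bands resolve the gap between
  printed labels exhaustively and without overlap) with per-band mean and
  standard error and a one-way fixed-effects ANOVA. The banded bar data
  default to pairs with at least three litters so that per-pair averages
  are meaningful; the GLMs default to all pairs. Both thresholds are
  configurable.

Pairs with zero pups born are excluded from ratio metrics with a logged
count; pairs with an unknown dam or sire carry litter statistics but a
missing relatedness, and drop out of relatedness analyses only.

## Cumulative trend scans and phases

The signature longitudinal procedure recomputes the association statistics
on cumulative windows: for every cutoff year $Y$, all litters born up to
$Y$ are aggregated and the Pearson and GLM statistics recomputed. This
shows when in a colony's history an association emerged or faded, which a
single pooled analysis masks. Points are estimated only from `minPairs`
eligible pairs on (default 10; the early years of a colony simply do not
determine a correlation, and the default refuses to pretend otherwise —
set `minPairs = 1` to force estimates from the first year). `n_pairs` is
non-decreasing by construction and the final cutoff reproduces the pooled
analysis exactly — both asserted in tests. $-\log_{10} p$ is reported with
$p$ floored at $10^{-300}$ to keep the transform finite.

Breeding phases are descriptive labels: boundary years (default 1985 and
2015) split the series into eras I/II/III, with a boundary year assigned
to the later phase. They are deliberately *not* fitted. A separate
utility, `detectChangepoints()`, makes the by-eye reading reproducible:
an exhaustive search for the piecewise-constant fit with $k \le 2$ breaks
minimising squared error over the Pearson-$r$ sequence, ties broken
earliest and reported. On cumulative series its second break systematically
lands where the rise of $r$ levels off rather than where an effect was
switched off, because cumulative aggregation dilutes a vanished effect
only gradually — a structural property of cumulative windows worth
keeping in mind when interpreting its output (see below).

Sex-specific losses are imputed, not observed: sexes are recorded only at
weaning, so each litter is assumed to contribute `born / 2` pups of each
sex at birth (fractional for odd litters) and the per-sex loss is the
shortfall of weaned pups of that sex, floored at zero. Negative shortfalls
(more males weaned than half the litter) are uninterpretable as deaths;
flooring events are counted and an unfloored variant is kept behind a
flag for sensitivity.

## Breeding intervals

`computeIntervals()` derives, per cage, the days from mating to first
birth and the gaps between consecutive births. Same-day repeat litters
are biologically impossible and treated as data errors (excluded,
tallied), never as zero intervals. The correlation unit is the per-pair
mean delivery interval — matching the averaged-interval framing of the
association — with the per-gap variant available. The association with
relatedness is computed pooled or as a cumulative scan; the scan's final
point equals the pooled value exactly.

## The synthetic colony

The simulator exists so every stage can be verified by parameter
recovery. It is a discrete-event model in days:

* founders (default 40, unrelated) seed a fixed number of breeding cages
  (default 40 active);
* a pair's litters arrive at intervals
  $\Delta = \max(\Delta_{\min},\ \delta_0 - \gamma r + \varepsilon)$,
  $\varepsilon \sim N(0, \sigma)$, with defaults
  $\delta_0 = 40$ d, $\Delta_{\min} = 21$ d, $\sigma = 8$ d and
  $\gamma = 12$ d per unit relatedness proportion — the interval
  shortening *is* the compensation mechanism, so it is first-class rather
  than an afterthought of a generational model;
* litter sizes are zero-truncated Poisson (default mean 4: a recorded
  litter implies at least one pup);
* each pup dies before weaning independently with probability
  $\mathrm{logit}^{-1}(\beta_0 + \beta_1 r)$, defaults
  $\beta_0 = \mathrm{logit}(0.15)$ and $\beta_1 = 1.4$, which gives an
  odds ratio near 2 across the relatedness range a colony actually
  realises ($r \in [0, 0.5]$);
* surviving pups are male with probability one half;
* breeders retire after a uniform 1.5–2-year tenure and are replaced from
  a pool of weaned offspring. Pair formation avoids kin two ways, as
  colony managers do: candidates above the relatedness cap (default 50
  percent — full siblings and closer are never paired) are excluded
  outright, and among acceptable males a small tournament picks the one
  least related to the female. Relatedness still drifts upward because
  the colony is closed; the tournament is what lets a 40-pair colony
  survive six decades, as the real one did, instead of breeding itself
  into a corner.

Kinship among potential breeders is tracked exactly (each newborn's
kinship row derives from its parents' rows), and the emitted truth is
asserted to agree with the pedigree module's untruncated recursion. If
eligible mates run out entirely the simulator reports the extinction year
instead of crashing. `makeThreePhaseColony()` switches $(\beta_1, \gamma)$
to zero outside a middle era, reproducing a no-effect / effect /
decoupled phase history.

What the simulator deliberately does **not** model: demand-driven culling
of the colony, seasonality, cannibalism as distinct from death (the
records cannot distinguish them either), allele-level purging, and the
pedigree-recording errors that motivate generation truncation (simulated
pedigrees are exact). Passing tests therefore validate the statistical
machinery under the stated generative assumptions, not the historical
accuracy of any particular colony's archive.

## Verification choices and problem sizes

The test-suite experiments use colony sizes chosen to keep the full suite
fast while preserving the scales that matter:

* **oracle equivalence** — 50 random pedigrees of up to 30 individuals
  against path counting (exact) and gene dropping ($2 \times 10^5$
  drops, 3 Monte-Carlo standard errors);
* **null calibration** — 500 replicates of a 30-year, 12-cage colony
  (about 210 pairs each) with $\beta_1 = \gamma = 0$: the loss LRT and
  the interval correlation must reject at $5\% \pm 3$ points;
* **parameter recovery** — 100 replicates of a 30-year, 18-cage colony
  (about 320 pairs): median recovered $\beta_1$ within 30 percent of
  truth, and a positive significant loss correlation in at least 90
  percent;
* **three-phase signature** — 100 replicates of a 62-year, 30-cage
  colony (about 1100 pairs) with eras switching at 1985 and 2015,
  scanned with `minPairs = 30` (3 percent of the final sample; smaller
  thresholds admit early small-sample correlation spikes that say
  nothing about the colony): the scan's peak $|r|$ must fall in or after
  the middle era and the final $r$ must sit below the peak.

On the changepoint utility: the *first* era boundary coincides with the
onset of the cumulative rise, the kind of level shift a piecewise-constant
criterion is built to find; the *second* boundary leaves no comparable
feature, for the structural reason above — after the effect switches off,
the cumulative correlation decays only at the rate null pairs accumulate,
so no criterion applied to a cumulative series can localise the offset to
within a couple of years. The utility is therefore documented as a
reproducible reading aid rather than an era-boundary estimator.

## Numerical notes

* GLM fitting is IRLS via `stats::glm`; coefficients are verified against
  brute-force likelihood grid refinement to $10^{-4}$.
* Likelihoods are clamped at $10^{-12}$ probability bounds only for
  degenerate fitted values; McFadden's $R^2$ is reported in $[0, 1)$.
* Kinship values are dyadic rationals computed exactly in double
  precision; truncation monotonicity and symmetry are asserted over
  random pedigrees.
* All simulator randomness flows from a single seed; replicate $k$ of an
  experiment uses `seed + k`.

## Limitations

Relatedness computed with five-generation truncation underestimates deep
kinship, so GLM slopes against truncated relatedness are larger than
slopes against the full-pedigree value (the covariate is compressed);
parameter-recovery tests therefore compare against the generative
covariate. The binomial models ignore overdispersion by design (no
quasi-binomial option), multiple testing across scan cutoffs is not
corrected (cutoffs are nested, not independent), and the sex-loss
imputation inherits the 1:1 birth-ratio assumption entirely.
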