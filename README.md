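# colonykin

Pedigree kinship and inbreeding-depression analysis for closed breeding
colonies.

Closed captive colonies — populations bred for decades without introducing
outside animals — accumulate relatedness between mates, and litters of
related parents lose more pups before weaning (inbreeding depression).
`colonykin` turns raw breeding-record tables (one row per litter: mating
cage, dam, sire, dates, pups born and weaned, weaned sexes) into a full
analysis of that process, for colony managers, studbook keepers and
population geneticists working from records rather than genotypes.

## What it computes

* **Record cleaning** — duplicate removal, completeness filtering, capping
  of weaning counts at birth counts, derivation of `dead = born − weaned`,
  with every action tallied in a `CleaningReport`.
* **Kinship and relatedness** — the classical recursion
  φ(x,x) = ½(1 + φ(f,m)), φ(a,b) = ½(φ(f_a,b) + φ(m_a,b)), with ancestor
  tracing truncated at a configurable depth (default five generations);
  relatedness r = 2φ reported in percent (full-sibling mating = 50).
* **Inbreeding-depression statistics** — per-pair loss ratios (by mice
  and by litters) modelled by weighted binomial-logit GLMs with McFadden's
  pseudo R² = 1 − ℓ₁/ℓ₀ and likelihood-ratio tests, Pearson correlations,
  and five relatedness bands ([0,25), [25,30), [30,35), [35,40), [40,100]
  percent) compared by one-way ANOVA.
* **Cumulative trend scans** — every statistic recomputed on cumulative
  year windows (all litters up to each cutoff year) with breeding-phase
  annotation, sex-specific losses imputed under a 1:1 birth sex ratio, and
  an exhaustive piecewise-constant changepoint search.
* **Breeding intervals** — mating-to-first-litter and between-litter
  intervals and their (typically negative) association with relatedness:
  the compensation mechanism by which related pairs breed more often.
* **A synthetic colony simulator** — a discrete-event generative model
  (kin-avoiding pair formation, zero-truncated Poisson litters,
  relatedness-dependent mortality and delivery intervals, three-era phase
  schedules) so every stage is testable by parameter recovery.

## Worked example

```r
library(colonykin)

# simulate a 30-year colony with the default inbreeding-depression effect
sim <- simulateColony(colonySimConfig(n_years = 30L, pairs_active = 12L),
                      seed = 5)
rec   <- simRecords(sim)
truth <- simPairs(sim)

pairs <- summarizePairs(rec)
pairs$relatedness_pct <- truth$relatedness_pct[
  match(pairs$mating_id, truth$mating_id)]

fit <- fitBinomialGlm(pairs$relatedness_pct, pairs$total_dead,
                      pairs$total_born)
fit
#> Binomial-logit fit (n = 212 , total weight = 13823 )
#>   beta0 = -1.7638  beta1 = 0.015170
#>   McFadden R2 = 0.0061  LRT p = 1.13e-19  converged = TRUE

pearsonCorrelation(pairs$relatedness_pct, lossRatioByMice(pairs))$r
#> [1] 0.4908
```

The slope 0.0152 per percent relatedness (1.52 per relatedness proportion)
recovers the generative value 1.4: pup mortality rises from the 15 %
baseline with parental relatedness. The Pearson r ≈ 0.49 is the pooled
per-pair correlation between relatedness and the fraction of pups lost.
A cumulative scan shows when the association was detectable:

```r
scan <- cumulativeScan(rec, truth, outcome = "loss_by_mice", minPairs = 10)
scan
#> TrendSeries (loss_by_mice): 30 cutoffs, 25 with estimates; phases at 1985, 2015
#>   final r = 0.4908 (p = 2.98e-14); peak |r| = 0.5377 at 1987
```

and `intervalRelatednessAssociation(rec, truth, mode = "delivery")` returns
the negative relatedness-interval correlation (more related pairs deliver
litters at shorter intervals).

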